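#' @keywords internal
"_PACKAGE"

# Stage offsets for deriving per-stage RNG streams from one root seed.
# Kept below 2^31 - 1 after the modulo so seeds stay valid R integers.
.stage_offsets <- c(
  droplets   = 101L,
  expression = 202L,
  variants   = 303L,
  breakends  = 404L,
  demux      = 505L,
  jitter     = 606L,
  splits     = 707L,
  subsample  = 808L
)

#' Derive a per-stage seed from a root seed
#'
#' One root seed fans out deterministically to independent per-stage streams
#' so each pipeline stage is reproducible in isolation.
#'
#' @param root_seed integer root seed.
#' @param stage character, one of the known stage names, or an arbitrary label
#'   (hashed by character codes).
#' @param index optional integer for repeated draws within a stage
#'   (e.g. split number).
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(root_seed, stage, index = 0L) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L)
  off <- if (stage %in% names(.stage_offsets)) {
    .stage_offsets[[stage]]
  } else {
    sum(utf8ToInt(stage)) %% 1000L
  }
  as.integer((abs(root_seed) * 1009 + off * 9973 + index * 31) %% (2^31 - 1))
}

.assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

.assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  }
  as.numeric(x)
}

.assert_range <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || x[1] > x[2]) {
    stop(sprintf("`%s` must be a nondecreasing length-2 numeric range", name),
         call. = FALSE)
  }
  as.numeric(x)
}

# Reverse complement for plain character DNA (used by the simulator so the
# generator stays independent of the Biostrings-based scanner it feeds).
revcomp_chr <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", vapply(strsplit(x, NULL), function(s) {
    paste(rev(s), collapse = "")
  }, character(1)))
}
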