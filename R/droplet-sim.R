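#' Configuration for the droplet / cell-hashing simulator
#'
#' Describes a simulated cell-hashing run: droplets carry per-hashtag
#' antibody counts composed of an ambient (lognormal on the log1p scale)
#' background plus, for cell-containing droplets, an elevated signal on the
#' hashtag(s) of the cell(s) inside.
#'
#' @param n_hashtags number of sample hashtags (>= 2).
#' @param n_singlets_per_tag singlet cells simulated per hashtag.
#' @param n_doublets doublet droplets (two cells, two distinct hashtags).
#' @param n_empty empty (ambient-only) droplets.
#' @param ambient_log_mean,ambient_log_sd mean / sd of the ambient
#'   background on the log1p-count scale.
#' @param signal_shift mean elevation (log1p scale) of a positive hashtag
#'   above ambient; the separation knob. Both elevated hashtags of a doublet
#'   receive the full shift.
#' @param rna_count_range integer range of RNA totals for cell-containing
#'   droplets.
#' @param empty_rna_range integer range of RNA totals for empty droplets
#'   (kept > 1 so empties are eligible for background estimation).
#' @param mito_range range of mitochondrial fractions.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return a `droplet_sim_config` list.
#' @export
droplet_sim_config <- function(n_hashtags = 6L,
                               n_singlets_per_tag = 300L,
                               n_doublets = 100L,
                               n_empty = 5000L,
                               ambient_log_mean = 2,
                               ambient_log_sd = 0.5,
                               signal_shift = 8 * ambient_log_sd,
                               rna_count_range = c(1000L, 20000L),
                               empty_rna_range = c(2L, 100L),
                               mito_range = c(0, 0.1),
                               seed = 1L) {
  cfg <- list(
    n_hashtags = .assert_count(n_hashtags, "n_hashtags", min = 2L),
    n_singlets_per_tag = .assert_count(n_singlets_per_tag, "n_singlets_per_tag"),
    n_doublets = .assert_count(n_doublets, "n_doublets"),
    n_empty = .assert_count(n_empty, "n_empty"),
    ambient_log_mean = as.numeric(ambient_log_mean),
    ambient_log_sd = as.numeric(ambient_log_sd),
    signal_shift = as.numeric(signal_shift),
    rna_count_range = .assert_range(rna_count_range, "rna_count_range"),
    empty_rna_range = .assert_range(empty_rna_range, "empty_rna_range"),
    mito_range = .assert_range(mito_range, "mito_range"),
    seed = .assert_count(seed, "seed")
  )
  if (cfg$signal_shift < 0) stop("`signal_shift` must be >= 0", call. = FALSE)
  if (cfg$ambient_log_sd <= 0) stop("`ambient_log_sd` must be > 0", call. = FALSE)
  if (any(cfg$mito_range < 0) || any(cfg$mito_range > 1)) {
    stop("`mito_range` must lie in [0, 1]", call. = FALSE)
  }
  class(cfg) <- "droplet_sim_config"
  cfg
}

# log1p-scale normal draw -> nonnegative integer count
.count_from_log1p <- function(n, mean, sd) {
  pmax(0, round(expm1(stats::rnorm(n, mean, sd))))
}

#' Simulate a hashed droplet dataset with ground truth
#'
#' Generates empty droplets (ambient hashtag background only, low RNA),
#' singlets (one hashtag elevated by `signal_shift`) and doublets (two
#' distinct hashtags elevated). Counts are nonnegative integers obtained by
#' rounding `expm1` of normal draws on the log1p scale and flooring at zero.
#'
#' @param cfg a [droplet_sim_config()].
#' @return a list with
#'   \describe{
#'     \item{droplets}{data.frame: `droplet_id`, `rna_total`,
#'       `protein_total`, `mito_fraction`, `is_cell`.}
#'     \item{hashtag_counts}{droplets x hashtags integer matrix.}
#'     \item{truth}{data.frame: `droplet_id`, `truth` (`"empty"`,
#'       `"singlet"`, `"doublet"`), `tag1`, `tag2` (NA where unused).}
#'   }
#' @export
simulate_droplets <- function(cfg) {
  stopifnot(inherits(cfg, "droplet_sim_config"))
  set.seed(cfg$seed)
  N <- cfg$n_hashtags
  n_sing <- cfg$n_singlets_per_tag * N
  n_total <- cfg$n_empty + n_sing + cfg$n_doublets

  type <- rep(c("empty", "singlet", "doublet"),
              times = c(cfg$n_empty, n_sing, cfg$n_doublets))
  tag1 <- rep(NA_integer_, n_total)
  tag2 <- rep(NA_integer_, n_total)
  if (n_sing > 0) {
    tag1[type == "singlet"] <- rep(seq_len(N), each = cfg$n_singlets_per_tag)
  }
  if (cfg$n_doublets > 0) {
    pairs <- t(vapply(seq_len(cfg$n_doublets),
                      function(i) sort(sample.int(N, 2L)), integer(2)))
    tag1[type == "doublet"] <- pairs[, 1]
    tag2[type == "doublet"] <- pairs[, 2]
  }

  # ambient background for every droplet x hashtag, then add signal shift
  counts <- matrix(
    .count_from_log1p(n_total * N, cfg$ambient_log_mean, cfg$ambient_log_sd),
    nrow = n_total, ncol = N,
    dimnames = list(NULL, paste0("HTO", seq_len(N)))
  )
  shift_one <- function(rows, tags) {
    idx <- cbind(rows, tags)
    counts[idx] <<- .count_from_log1p(
      length(rows), cfg$ambient_log_mean + cfg$signal_shift, cfg$ambient_log_sd)
  }
  rs <- which(type == "singlet"); if (length(rs)) shift_one(rs, tag1[rs])
  rd <- which(type == "doublet")
  if (length(rd)) { shift_one(rd, tag1[rd]); shift_one(rd, tag2[rd]) }

  rna <- integer(n_total)
  is_empty <- type == "empty"
  rna[is_empty] <- sample(seq(cfg$empty_rna_range[1], cfg$empty_rna_range[2]),
                          sum(is_empty), replace = TRUE)
  rna[!is_empty] <- sample(seq(cfg$rna_count_range[1], cfg$rna_count_range[2]),
                           sum(!is_empty), replace = TRUE)
  mito <- stats::runif(n_total, cfg$mito_range[1], cfg$mito_range[2])

  ids <- sprintf("BC%06d", seq_len(n_total))
  rownames(counts) <- ids
  droplets <- data.frame(
    droplet_id = ids,
    rna_total = rna,
    protein_total = as.integer(rowSums(counts)),
    mito_fraction = mito,
    is_cell = !is_empty,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(droplet_id = ids, truth = type,
                      tag1 = tag1, tag2 = tag2, stringsAsFactors = FALSE)
  structure(list(droplets = droplets, hashtag_counts = counts, truth = truth),
            class = "droplet_dataset")
}
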