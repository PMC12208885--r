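#' Configuration for the cell-type-structured expression simulator
#'
#' Emulates log-normalized single-cell expression where designated
#' transcription factors drive correlated target-gene modules, optionally
#' only in a subset of cell types (type-specific activity). Targets of
#' distinct TFs must not overlap unless declared.
#'
#' @param n_cell_types number of cell types.
#' @param n_cells_per_type cells per type.
#' @param n_genes total genes (must accommodate all TFs and targets).
#' @param tf_specs list of specs, each a list with `tf_id` (character),
#'   `n_targets` (integer), `r` (target-TF Pearson correlation in `[0, 1]`),
#'   and optional `active_cell_types` (integer indices of types where the TF
#'   module is elevated; default all types equally).
#' @param noise_sd sd of gene-level noise on the lognorm scale.
#' @param base_mean baseline lognorm mean for all genes.
#' @param active_shift elevation of a TF's mean in its active types.
#' @param allow_overlap permit target sets of distinct TFs to overlap.
#' @param seed integer seed.
#' @return an `expression_sim_config` list.
#' @export
expression_sim_config <- function(n_cell_types = 5L, n_cells_per_type = 500L,
                                  n_genes = 1000L, tf_specs = list(),
                                  noise_sd = 1, base_mean = 2,
                                  active_shift = 3, allow_overlap = FALSE,
                                  seed = 1L) {
  for (sp in tf_specs) {
    stopifnot(is.character(sp$tf_id), is.numeric(sp$n_targets))
    if (sp$r < 0 || sp$r > 1) stop("target correlation r must be in [0, 1]",
                                   call. = FALSE)
  }
  total_targets <- sum(vapply(tf_specs, function(s) s$n_targets, numeric(1)))
  if (!allow_overlap && length(tf_specs) &&
      total_targets + length(tf_specs) > n_genes) {
    stop(sprintf("n_genes = %d cannot host %d TFs plus %d disjoint targets",
                 n_genes, length(tf_specs), total_targets), call. = FALSE)
  }
  structure(list(
    n_cell_types = .assert_count(n_cell_types, "n_cell_types", min = 1L),
    n_cells_per_type = .assert_count(n_cells_per_type, "n_cells_per_type", 1L),
    n_genes = .assert_count(n_genes, "n_genes", min = 1L),
    tf_specs = tf_specs, noise_sd = as.numeric(noise_sd),
    base_mean = as.numeric(base_mean), active_shift = as.numeric(active_shift),
    allow_overlap = isTRUE(allow_overlap),
    seed = .assert_count(seed, "seed")), class = "expression_sim_config")
}

#' Simulate cell-type-labeled expression with planted regulons
#'
#' TF values are normal on the lognorm scale around `base_mean`, elevated by
#' `active_shift` in the TF's active cell types. Each target is generated as
#' `r * TF + e` with the noise variance chosen so the population Pearson
#' correlation between target and TF equals `r` exactly; non-target genes
#' are independent noise. Counts are derived as `round(expm1(...))` floored
#' at zero.
#'
#' @param cfg an [expression_sim_config()].
#' @return list: `lognorm` (cells x genes), `counts`, `cell_type` (per
#'   cell), `regulons` (true planted regulons, a list of
#'   [regulon()] objects), `tf_ids`.
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "expression_sim_config"))
  set.seed(cfg$seed)
  n_cells <- cfg$n_cell_types * cfg$n_cells_per_type
  cell_type <- rep(paste0("type", seq_len(cfg$n_cell_types)),
                   each = cfg$n_cells_per_type)
  genes <- paste0("gene", seq_len(cfg$n_genes))

  # background: independent noise around the baseline
  X <- matrix(stats::rnorm(n_cells * cfg$n_genes, cfg$base_mean, cfg$noise_sd),
              nrow = n_cells, ncol = cfg$n_genes,
              dimnames = list(sprintf("cell%05d", seq_len(n_cells)), genes))

  truth <- list()
  used <- integer(0)
  next_free <- 1L
  take_genes <- function(n) {
    avail <- setdiff(seq_len(cfg$n_genes), used)
    if (length(avail) < n) stop("gene capacity exhausted", call. = FALSE)
    avail[seq_len(n)]
  }
  for (sp in cfg$tf_specs) {
    tf_idx <- take_genes(1L)
    if (!cfg$allow_overlap) used <- c(used, tf_idx)
    tgt_idx <- if (sp$n_targets > 0) take_genes(sp$n_targets) else integer(0)
    if (!cfg$allow_overlap) used <- c(used, tgt_idx)

    active <- sp$active_cell_types
    mu <- rep(cfg$base_mean, n_cells)
    if (!is.null(active)) {
      mu[cell_type %in% paste0("type", active)] <-
        cfg$base_mean + cfg$active_shift
    }
    tf_val <- stats::rnorm(n_cells, mu, cfg$noise_sd)
    X[, tf_idx] <- tf_val
    colnames(X)[tf_idx] <- sp$tf_id

    # r * TF + e with Var(e) = Var(TF) (1 - r^2) gives population cor = r
    sd_tf <- stats::sd(tf_val)
    r <- sp$r
    for (j in tgt_idx) {
      e <- stats::rnorm(n_cells, 0, sd_tf * sqrt(max(0, 1 - r^2)))
      X[, j] <- r * (tf_val - mean(tf_val)) + e + cfg$base_mean
    }
    if (length(tgt_idx)) {
      truth[[sp$tf_id]] <- regulon(tf = sp$tf_id, targets = genes[tgt_idx])
    }
  }

  counts <- matrix(as.integer(pmax(0, round(expm1(pmax(X, 0))))),
                   nrow = nrow(X), dimnames = dimnames(X))
  list(lognorm = X, counts = counts, cell_type = cell_type,
       regulons = truth,
       tf_ids = vapply(cfg$tf_specs, function(s) s$tf_id, character(1)))
}
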