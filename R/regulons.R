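#' Construct a regulon
#'
#' A regulon is a transcription factor together with its putative target
#' gene set; per-cell activity is later scored by rank-based recovery of the
#' targets.
#'
#' @param tf gene id of the transcription factor.
#' @param targets character vector of target gene ids (must not contain
#'   `tf`).
#' @param sign `"activating"` (default) or `"repressing"` (reserved).
#' @param provenance optional character tags recording discovery runs.
#' @return a `regulon` object.
#' @export
regulon <- function(tf, targets, sign = "activating", provenance = character()) {
  stopifnot(is.character(tf), length(tf) == 1L, is.character(targets))
  targets <- unique(targets)
  if (tf %in% targets) stop("a TF cannot be its own target", call. = FALSE)
  if (length(targets) == 0) stop("regulon has no targets", call. = FALSE)
  structure(list(tf = tf, targets = targets,
                 sign = match.arg(sign, c("activating", "repressing")),
                 provenance = provenance),
            class = "regulon")
}

#' @exportS3Method base::print
print.regulon <- function(x, ...) {
  cat(sprintf("regulon %s: %d targets (%s)\n", x$tf, length(x$targets), x$sign))
  invisible(x)
}

#' Sample an equal number of cells per cell type
#'
#' Equalizes cell-type abundances before regulon discovery so abundant types
#' do not dominate the correlation structure. Types with fewer than
#' `n_per_type` cells are sampled with replacement (with a warning).
#'
#' @param cell_type cell-type label per cell.
#' @param n_per_type cells to draw per type.
#' @param seed integer seed.
#' @return integer vector of cell indices (length `n_per_type` x number of
#'   types).
#' @export
sample_balanced <- function(cell_type, n_per_type, seed = 1L) {
  n_per_type <- .assert_count(n_per_type, "n_per_type", min = 1L)
  types <- if (is.factor(cell_type)) levels(cell_type) else
    sort(unique(as.character(cell_type)))
  if (length(types) == 0) stop("cell type labels have no cells",
                               call. = FALSE)
  set.seed(seed)
  idx <- lapply(types, function(tp) {
    pool <- which(cell_type == tp)
    if (length(pool) == 0) stop(sprintf("cell type '%s' has no cells", tp),
                                call. = FALSE)
    if (length(pool) < n_per_type) {
      warning(sprintf("type '%s': %d cells < %d, sampling with replacement",
                      tp, length(pool), n_per_type), call. = FALSE)
      sample(pool, n_per_type, replace = TRUE)
    } else {
      sample(pool, n_per_type)
    }
  })
  unlist(idx, use.names = FALSE)
}

#' Discover regulons by expression correlation to each TF
#'
#' The reference discovery backend: a small uniform pseudocount jitter
#' (default range -0.01..0.01) is added to every matrix entry so constant
#' genes acquire defined (near-zero) correlations, then each candidate TF's
#' targets are the genes whose Pearson correlation to the TF across all
#' cells reaches `r_min`. Regulons with fewer than `min_targets` targets are
#' dropped.
#'
#' @param lognorm cells x genes log-normalized matrix.
#' @param tf_list character vector of candidate TF gene ids.
#' @param r_min minimum Pearson correlation for a target (default 0.3).
#' @param min_targets minimum regulon size (default 10).
#' @param jitter half-width of the uniform pseudocount (default 0.01).
#' @param seed seed for the jitter stream.
#' @return named list of [regulon()] objects (possibly empty).
#' @export
discover_regulons <- function(lognorm, tf_list, r_min = 0.3,
                              min_targets = 10L, jitter = 0.01, seed = 1L) {
  stopifnot(is.matrix(lognorm), is.character(tf_list))
  set.seed(seed)
  X <- lognorm + stats::runif(length(lognorm), -jitter, jitter)
  out <- list()
  for (tf in tf_list) {
    if (!tf %in% colnames(X)) {
      warning(sprintf("TF '%s' absent from matrix, skipped", tf),
              call. = FALSE)
      next
    }
    r <- suppressWarnings(as.vector(stats::cor(X[, tf], X)))
    r[is.na(r)] <- 0
    hits <- colnames(X)[r >= r_min]
    hits <- setdiff(hits, tf)
    if (length(hits) >= min_targets) {
      out[[tf]] <- regulon(tf, hits, provenance = sprintf("cor>=%.2f", r_min))
    }
  }
  out
}

# per-cell descending ranks with average ties
.rank_desc <- function(lognorm) {
  t(apply(lognorm, 1, function(x) rank(-x, ties.method = "average")))
}

#' Score per-cell regulon activity by rank-based target recovery
#'
#' For each cell, genes are ranked by expression (descending, average ranks
#' for ties) and the score is the area under the target-recovery curve
#' within the top `q` fraction of ranks, normalized so that a regulon whose
#' targets occupy the very top ranks scores 1. Scores depend on expression
#' only through ranks, so any strictly monotone per-cell transform leaves
#' them unchanged.
#'
#' @param lognorm cells x genes matrix.
#' @param regulons list of [regulon()] objects.
#' @param q top fraction of the ranking considered (default 0.05).
#' @return cells x regulons matrix of scores in `[0, 1]`.
#' @export
score_regulons <- function(lognorm, regulons, q = 0.05) {
  if (length(regulons) == 0) stop("no regulons to score", call. = FALSE)
  q <- .assert_fraction(q, "q")
  G <- ncol(lognorm)
  Tn <- max(1L, floor(q * G))
  R <- .rank_desc(lognorm)
  scores <- matrix(NA_real_, nrow = nrow(lognorm), ncol = length(regulons),
                   dimnames = list(rownames(lognorm),
                                   vapply(regulons, `[[`, character(1), "tf")))
  for (j in seq_along(regulons)) {
    tg <- intersect(regulons[[j]]$targets, colnames(lognorm))
    if (length(tg) == 0) stop(sprintf("regulon '%s' has no targets in matrix",
                                      regulons[[j]]$tf), call. = FALSE)
    m <- length(tg)
    # area under the step recovery curve: sum over k=1..T of #targets at
    # rank <= k, i.e. per target max(0, T - ceiling(rank) + 1)
    raw <- rowSums(pmax(Tn - ceiling(R[, tg, drop = FALSE]) + 1, 0))
    mx <- if (m >= Tn) Tn * (Tn + 1) / 2 else m * (m + 1) / 2 + m * (Tn - m)
    scores[, j] <- raw / mx
  }
  scores
}

#' Train-test stability filter for regulons
#'
#' Repeats balanced 70:30 train-test splits (stratified by cell type):
#' regulons are discovered on the train cells, both halves are scored, and
#' for each regulon the per-cell-type mean-score vector on train is
#' correlated (Pearson) with the one on test. A TF is retained when its
#' regulon was discovered in at least half the splits and the median
#' correlation p-value over those splits is at most `alpha`.
#'
#' @param lognorm cells x genes matrix.
#' @param cell_type label per cell; at least 3 types (the correlation test
#'   needs >= 3 points).
#' @param tf_list candidate TFs.
#' @param n_splits number of splits (default 10).
#' @param train_frac train fraction (default 0.7).
#' @param alpha p-value cutoff (default 0.001).
#' @param n_per_type cells sampled per type per split (default the smallest
#'   type size).
#' @param seed root seed; per-split streams are derived from it.
#' @param backend discovery backend, a function
#'   `(lognorm, tf_list, seed) -> regulon list`; default wraps
#'   [discover_regulons()] with `...` passed through.
#' @param ... passed to [discover_regulons()] by the default backend.
#' @return list: `retained` (TF names), `report` (data.frame with one row
#'   per TF x split: `r`, `p`), `summary` (per TF: `n_discovered`,
#'   `median_p`, `retained`).
#' @export
stability_filter <- function(lognorm, cell_type, tf_list, n_splits = 10L,
                             train_frac = 0.7, alpha = 0.001,
                             n_per_type = NULL, seed = 1L, backend = NULL,
                             ...) {
  n_splits <- .assert_count(n_splits, "n_splits", min = 1L)
  types <- sort(unique(as.character(cell_type)))
  if (length(types) < 3) {
    stop("stability filter needs >= 3 cell types", call. = FALSE)
  }
  if (is.null(n_per_type)) {
    n_per_type <- min(table(cell_type))
  }
  if (is.null(backend)) {
    backend <- function(X, tfs, seed) {
      discover_regulons(X, tfs, seed = seed, ...)
    }
  }
  rows <- list()
  for (s in seq_len(n_splits)) {
    split_seed <- derive_seed(seed, "splits", s)
    idx <- sample_balanced(cell_type, n_per_type, seed = split_seed)
    # stratified 70:30 within the balanced sample
    set.seed(derive_seed(seed, "subsample", s))
    n_train <- floor(train_frac * n_per_type)
    per_type <- split(idx, rep(types, each = n_per_type))
    tr <- unlist(lapply(per_type, function(v) v[seq_len(n_train)]),
                 use.names = FALSE)
    te <- unlist(lapply(per_type, function(v) v[-seq_len(n_train)]),
                 use.names = FALSE)
    regs <- backend(lognorm[tr, , drop = FALSE], tf_list,
                    derive_seed(seed, "jitter", s))
    if (length(regs) == 0) next
    names(regs) <- vapply(regs, `[[`, character(1), "tf")
    sc_tr <- score_regulons(lognorm[tr, , drop = FALSE], regs)
    sc_te <- score_regulons(lognorm[te, , drop = FALSE], regs)
    ct_tr <- as.character(cell_type)[tr]
    ct_te <- as.character(cell_type)[te]
    for (tf in names(regs)) {
      m_tr <- tapply(sc_tr[, tf], factor(ct_tr, levels = types), mean)
      m_te <- tapply(sc_te[, tf], factor(ct_te, levels = types), mean)
      test <- suppressWarnings(stats::cor.test(m_tr, m_te))
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf, split = s,
        r = unname(test$estimate),
        p = if (is.na(test$p.value)) 1 else test$p.value,
        stringsAsFactors = FALSE)
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tf = character(), split = integer(), r = numeric(),
               p = numeric())
  summ <- do.call(rbind, lapply(tf_list, function(tf) {
    sub <- report[report$tf == tf, , drop = FALSE]
    nd <- nrow(sub)
    med_p <- if (nd) stats::median(sub$p) else NA_real_
    data.frame(tf = tf, n_discovered = nd, median_p = med_p,
               retained = nd >= n_splits / 2 && !is.na(med_p) &&
                 med_p <= alpha,
               stringsAsFactors = FALSE)
  }))
  list(retained = summ$tf[summ$retained], report = report, summary = summ)
}

#' One-way coefficient of determination per score column
#'
#' `R^2 = 1 - SSE/SST` of the one-way model `score ~ group`, i.e. the
#' between-group fraction of variance, computed from group means. Equals
#' `summary(lm(score ~ group))$r.squared`. Affine transforms of a column
#' leave its value unchanged; a column with zero total variance returns 0.
#'
#' @param scores cells x regulons numeric matrix (a single column is fine).
#' @param groups group label per row.
#' @return named numeric vector of R-squared values in `[0, 1]`.
#' @export
r2_one_way <- function(scores, groups) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1)
  stopifnot(nrow(scores) == length(groups))
  .r2_by_group(scores, groups)
}

# one-way R^2 for every column of `scores` at once
.r2_by_group <- function(scores, groups) {
  g <- as.factor(groups)
  n <- nrow(scores)
  tot_mean <- colMeans(scores)
  sst <- colSums(scores^2) - n * tot_mean^2
  gm <- rowsum(scores, g) / as.vector(table(g))
  ssb <- colSums(gm^2 * as.vector(table(g))) - n * tot_mean^2
  r2 <- ifelse(sst > 0, ssb / sst, 0)
  pmin(pmax(r2, 0), 1)
}

#' Cell-type discriminability filter by subsampled one-way R-squared
#'
#' For each of `n_reps` repetitions, `n_per_type` cells per type are sampled
#' (with replacement when a type is short) and a one-way linear model
#' `score ~ cell_type` is evaluated per regulon; its coefficient of
#' determination `R^2 = 1 - SSE/SST` measures how much score variance the
#' type labels explain. Regulons are kept when their mean `R^2` over the
#' repetitions reaches `r2_min`.
#'
#' @param scores cells x regulons score matrix.
#' @param cell_type label per cell; at least 2 types.
#' @param n_reps repetitions (default 100).
#' @param n_per_type cells per type per repetition (default 500).
#' @param r2_min retention threshold on the mean R^2 (default 0.5).
#' @param seed root seed.
#' @return list: `retained` (regulon names), `mean_r2` (named vector),
#'   `r2` (reps x regulons matrix).
#' @export
discriminability_filter <- function(scores, cell_type, n_reps = 100L,
                                    n_per_type = 500L, r2_min = 0.5,
                                    seed = 1L) {
  n_reps <- .assert_count(n_reps, "n_reps", min = 1L)
  if (length(unique(cell_type)) < 2) {
    stop("discriminability needs >= 2 cell types", call. = FALSE)
  }
  stopifnot(nrow(scores) == length(cell_type))
  r2 <- matrix(NA_real_, nrow = n_reps, ncol = ncol(scores),
               dimnames = list(NULL, colnames(scores)))
  for (b in seq_len(n_reps)) {
    idx <- sample_balanced(cell_type, n_per_type,
                           seed = derive_seed(seed, "subsample", b))
    r2[b, ] <- .r2_by_group(scores[idx, , drop = FALSE], cell_type[idx])
  }
  mean_r2 <- colMeans(r2)
  list(retained = colnames(scores)[mean_r2 >= r2_min], mean_r2 = mean_r2,
       r2 = r2)
}

#' Score a new cell population against frozen regulons
#'
#' Applies [score_regulons()] to a new dataset using regulons discovered on
#' a reference, after checking that enough of each regulon's targets exist
#' in the new gene universe.
#'
#' @param lognorm cells x genes matrix of the new population.
#' @param regulons retained [regulon()] list (frozen from the reference).
#' @param cell_type optional label per cell; when given, a per-type mean
#'   score matrix is returned for heatmap export.
#' @param overlap_min minimum fraction of a regulon's targets that must be
#'   present (default 0.8).
#' @param on_low_overlap `"error"` (default) or `"warn"`; warned regulons
#'   are scored on their present targets.
#' @param q top fraction for scoring (default 0.05).
#' @return list: `scores`, `type_means` (types x regulons, or NULL),
#'   `overlap` (named fraction per regulon).
#' @export
project_scores <- function(lognorm, regulons, cell_type = NULL,
                           overlap_min = 0.8,
                           on_low_overlap = c("error", "warn"), q = 0.05) {
  on_low_overlap <- match.arg(on_low_overlap)
  if (length(regulons) == 0) stop("no retained regulons", call. = FALSE)
  overlap <- vapply(regulons, function(rg) {
    mean(rg$targets %in% colnames(lognorm))
  }, numeric(1))
  names(overlap) <- vapply(regulons, `[[`, character(1), "tf")
  low <- overlap < overlap_min
  if (any(low)) {
    msg <- sprintf("regulons below target overlap %.2f: %s", overlap_min,
                   paste(sprintf("%s (%.2f)", names(overlap)[low],
                                 overlap[low]), collapse = ", "))
    if (on_low_overlap == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  scores <- score_regulons(lognorm, regulons, q = q)
  type_means <- NULL
  if (!is.null(cell_type)) {
    type_means <- rowsum(scores, as.factor(cell_type)) /
      as.vector(table(as.factor(cell_type)))
  }
  list(scores = scores, type_means = type_means, overlap = overlap)
}

#' Full regulon discovery, filtering and scoring pipeline
#'
#' Balanced sampling, train-test stability filtering, re-discovery of the
#' final regulon set on the full balanced sample restricted to retained
#' TFs, scoring of the whole dataset, and the subsampled R-squared
#' discriminability filter.
#'
#' @param lognorm cells x genes matrix.
#' @param cell_type label per cell.
#' @param tf_list candidate TFs.
#' @param n_per_type balanced-sample size per type (default 500).
#' @param seed root seed.
#' @param r_min,min_targets,jitter passed to [discover_regulons()].
#' @param n_splits,train_frac,alpha passed to [stability_filter()].
#' @param n_reps,r2_min passed to [discriminability_filter()].
#' @param q passed to [score_regulons()].
#' @return list: `regulons` (final retained), `scores` (whole dataset x
#'   retained regulons), `stability`, `discriminability`.
#' @export
run_regulon_pipeline <- function(lognorm, cell_type, tf_list,
                                 n_per_type = 500L, seed = 1L, r_min = 0.3,
                                 min_targets = 10L, jitter = 0.01,
                                 n_splits = 10L, train_frac = 0.7,
                                 alpha = 0.001, n_reps = 100L, r2_min = 0.5,
                                 q = 0.05) {
  stab <- stability_filter(lognorm, cell_type, tf_list, n_splits = n_splits,
                           train_frac = train_frac, alpha = alpha,
                           n_per_type = n_per_type, seed = seed,
                           r_min = r_min, min_targets = min_targets,
                           jitter = jitter)
  if (length(stab$retained) == 0) {
    return(list(regulons = list(), scores = NULL, stability = stab,
                discriminability = NULL))
  }
  idx <- sample_balanced(cell_type, n_per_type,
                         seed = derive_seed(seed, "subsample", 0L))
  final <- discover_regulons(lognorm[idx, , drop = FALSE], stab$retained,
                             r_min = r_min, min_targets = min_targets,
                             jitter = jitter,
                             seed = derive_seed(seed, "jitter", 0L))
  if (length(final) == 0) {
    return(list(regulons = list(), scores = NULL, stability = stab,
                discriminability = NULL))
  }
  scores <- score_regulons(lognorm, final, q = q)
  disc <- discriminability_filter(scores, cell_type, n_reps = n_reps,
                                  n_per_type = n_per_type, r2_min = r2_min,
                                  seed = derive_seed(seed, "subsample", 1L))
  keep <- disc$retained
  list(regulons = final[keep],
       scores = scores[, keep, drop = FALSE],
       stability = stab, discriminability = disc)
}
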