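#' Select empty droplets for background estimation
#'
#' Empty droplets anchor the ambient-background model of the hashtag
#' demultiplexer. A droplet qualifies when all of the following hold: RNA
#' total > 1, protein (hashtag) total > 1, not flagged as a cell by the
#' upstream caller; its log10 RNA and log10 protein totals each lie within 2
#' median absolute deviations of the respective median (computed over the
#' subset passing the first three criteria); and mitochondrial read fraction
#' < 0.25.
#'
#' @param droplets data.frame with columns `droplet_id`, `rna_total`,
#'   `protein_total`, `mito_fraction`, `is_cell`.
#' @param n_min minimum number of surviving droplets (default 100).
#' @param mad_mult multiplier on the median absolute deviation (default 2).
#' @param max_mito mitochondrial fraction cutoff (default 0.25).
#' @return character vector of selected `droplet_id`s, with a `report`
#'   attribute counting droplets removed per criterion.
#' @export
select_empty_droplets <- function(droplets, n_min = 100L, mad_mult = 2,
                                  max_mito = 0.25) {
  req <- c("droplet_id", "rna_total", "protein_total", "mito_fraction", "is_cell")
  stopifnot(all(req %in% names(droplets)))

  base <- droplets$rna_total > 1 & droplets$protein_total > 1 & !droplets$is_cell
  sub <- droplets[base, , drop = FALSE]
  report <- c(fail_counts_or_cell = sum(!base))
  if (nrow(sub) == 0) {
    stop(sprintf(
      "background estimation failed: 0 droplets pass counts/cell criteria (%d removed)",
      sum(!base)), call. = FALSE)
  }

  # plain median absolute deviation (no consistency constant) on log10 totals
  lr <- log10(sub$rna_total)
  lp <- log10(sub$protein_total)
  mad0 <- function(x) stats::median(abs(x - stats::median(x)))
  ok_mad <- abs(lr - stats::median(lr)) < mad_mult * mad0(lr) &
            abs(lp - stats::median(lp)) < mad_mult * mad0(lp)
  ok_mito <- sub$mito_fraction < max_mito
  report <- c(report, fail_mad = sum(!ok_mad),
              fail_mito = sum(ok_mad & !ok_mito))

  keep <- sub$droplet_id[ok_mad & ok_mito]
  if (length(keep) < n_min) {
    stop(sprintf(paste0(
      "background estimation failed: %d empty droplets survive (need >= %d); ",
      "removed: %s"), length(keep), n_min,
      paste(names(report), report, sep = "=", collapse = ", ")), call. = FALSE)
  }
  attr(keep, "report") <- report
  keep
}

#' Fit the ambient background model from empty droplets
#'
#' Per hashtag, the background is summarized by the mean and sample standard
#' deviation (n-1 denominator) of `log1p` counts over the selected empty
#' droplets. No denoising and no isotype controls are applied. Standard
#' deviations are floored at `sigma_floor` so standardization is always
#' defined.
#'
#' @param hashtag_counts droplets x hashtags count matrix.
#' @param empty_ids droplet ids (rownames) of the empty set.
#' @param sigma_floor lower bound on the per-hashtag sd (default 1e-8).
#' @return a `background_model` list: `mu`, `sigma` (floored), `sigma_raw`,
#'   `n_empty`.
#' @export
fit_background <- function(hashtag_counts, empty_ids, sigma_floor = 1e-8) {
  if (length(empty_ids) == 0) stop("empty droplet set is empty", call. = FALSE)
  miss <- setdiff(empty_ids, rownames(hashtag_counts))
  if (length(miss)) {
    stop(sprintf("%d empty ids missing from count matrix", length(miss)),
         call. = FALSE)
  }
  lg <- log1p(hashtag_counts[empty_ids, , drop = FALSE])
  mu <- colMeans(lg)
  sigma_raw <- apply(lg, 2, stats::sd)
  structure(list(mu = mu,
                 sigma = pmax(sigma_raw, sigma_floor),
                 sigma_raw = sigma_raw,
                 n_empty = length(empty_ids)),
            class = "background_model")
}

#' Standardize hashtag counts against the ambient background
#'
#' `s = (log1p(x) - mu_bg) / sigma_bg` per hashtag (natural log).
#'
#' @param hashtag_counts droplets x hashtags count matrix (nonnegative).
#' @param background a [fit_background()] model.
#' @return matrix of scaled signals, same shape as the input.
#' @export
scale_signals <- function(hashtag_counts, background) {
  stopifnot(inherits(background, "background_model"))
  if (any(hashtag_counts < 0)) stop("negative hashtag counts", call. = FALSE)
  sweep(sweep(log1p(hashtag_counts), 2, background$mu, "-"),
        2, background$sigma, "/")
}

#' Over-cluster scaled signals and derive the positivity cutoff
#'
#' Cells (droplets with at least one raw hashtag count >= 1) are clustered
#' with k-means into `K = N + N(N-1)/2 + 1` clusters (one per hashtag, one
#' per hashtag pair, one background) with 100 random restarts. A normal
#' distribution is fit by moments to the pooled scaled values of the cluster
#' with the lowest mean signal, its 99th percentile is taken, and the cutoff
#' is clamped into `[3, 5]`.
#'
#' @param scaled cells x hashtags scaled-signal matrix (cells only).
#' @param n_hashtags number of hashtags N.
#' @param nstart k-means restarts (default 100).
#' @param clamp cutoff range (default `c(3, 5)`).
#' @param seed seed for the k-means restart stream.
#' @return list: `K`, `kmeans` fit, `background_cluster`, `mu_hat`,
#'   `sigma_hat`, `q99` (raw), `cutoff` (clamped), `fit_method`.
#' @export
cluster_and_cutoff <- function(scaled, n_hashtags, nstart = 100L,
                               clamp = c(3, 5), seed = 1L) {
  N <- .assert_count(n_hashtags, "n_hashtags", min = 2L)
  K <- N + N * (N - 1L) / 2L + 1L
  if (nrow(scaled) < K) {
    stop(sprintf("clustering needs >= %d cells, got %d", K, nrow(scaled)),
         call. = FALSE)
  }
  set.seed(seed)
  km <- stats::kmeans(scaled, centers = K, nstart = nstart, iter.max = 100L)
  cl_mean <- vapply(seq_len(K), function(k) {
    mean(scaled[km$cluster == k, , drop = FALSE])
  }, numeric(1))
  bg <- which.min(cl_mean)
  pooled <- as.vector(scaled[km$cluster == bg, , drop = FALSE])
  fit <- fit_cutoff(pooled, clamp = clamp)
  c(list(K = K, kmeans = km, background_cluster = bg), fit)
}

#' Fit the positivity cutoff from background-cluster values
#'
#' Fits a normal by the method of moments (sample mean and sd) to the
#' pooled scaled values of the background cluster, takes its 99th
#' percentile (`mu + 2.326348 * sd`), and clamps the result into the
#' allowed cutoff range.
#'
#' @param values numeric vector of pooled background scaled signals.
#' @param clamp cutoff range (default `c(3, 5)`).
#' @return list: `mu_hat`, `sigma_hat`, `q99` (raw percentile), `cutoff`
#'   (clamped), `fit_method`.
#' @export
fit_cutoff <- function(values, clamp = c(3, 5)) {
  stopifnot(length(values) >= 2)
  mu_hat <- mean(values)
  sigma_hat <- stats::sd(values)
  z99 <- 2.326348
  q99 <- mu_hat + z99 * sigma_hat
  list(mu_hat = mu_hat, sigma_hat = sigma_hat, q99 = q99,
       cutoff = min(max(q99, clamp[1]), clamp[2]), fit_method = "moments")
}

#' Assign hashtag identities from scaled signals and a cutoff
#'
#' A cell is positive for a hashtag when its scaled signal strictly exceeds
#' the cutoff. Exactly one positive hashtag gives a singlet assignment, two
#' or more a doublet, none a negative.
#'
#' @param scaled cells x hashtags scaled-signal matrix.
#' @param cutoff positivity cutoff.
#' @return data.frame: `droplet_id`, `assignment` (hashtag name, `"doublet"`
#'   or `"negative"`), `n_positive`.
#' @export
assign_hashtags <- function(scaled, cutoff) {
  pos <- scaled > cutoff
  npos <- rowSums(pos)
  tags <- colnames(scaled)
  assignment <- ifelse(npos == 0, "negative",
                ifelse(npos >= 2, "doublet",
                       tags[max.col(pos, ties.method = "first")]))
  data.frame(droplet_id = rownames(scaled), assignment = assignment,
             n_positive = as.integer(npos), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Demultiplex a hashed droplet dataset end to end
#'
#' Runs the full pipeline: empty-droplet selection, background fit,
#' standardization, k-means over-clustering with the clamped 99th-percentile
#' cutoff, and per-cell assignment. Only droplets flagged as cells with at
#' least one detected hashtag (raw count >= 1) are assigned.
#'
#' @param dataset a list with `droplets` and `hashtag_counts` as produced by
#'   [simulate_droplets()] or [read_droplet_dataset()].
#' @param n_min,mad_mult,max_mito passed to [select_empty_droplets()].
#' @param sigma_floor passed to [fit_background()].
#' @param nstart,clamp passed to [cluster_and_cutoff()].
#' @param seed seed for the k-means restart stream.
#' @return a `demux_result` list: `assignments` (data.frame), `scaled`
#'   matrix, `cutoff`, `q99`, `K`, `mu_hat`, `sigma_hat`, `background`
#'   model, `empty_ids`.
#' @export
demux_hashtags <- function(dataset, n_min = 100L, mad_mult = 2,
                           max_mito = 0.25, sigma_floor = 1e-8,
                           nstart = 100L, clamp = c(3, 5), seed = 1L) {
  droplets <- dataset$droplets
  counts <- dataset$hashtag_counts
  empty_ids <- select_empty_droplets(droplets, n_min = n_min,
                                     mad_mult = mad_mult, max_mito = max_mito)
  bg <- fit_background(counts, empty_ids, sigma_floor = sigma_floor)

  is_cell <- droplets$is_cell
  detected <- rowSums(counts >= 1) > 0
  cell_ids <- droplets$droplet_id[is_cell & detected]
  scaled <- scale_signals(counts[cell_ids, , drop = FALSE], bg)

  fit <- cluster_and_cutoff(scaled, ncol(counts), nstart = nstart,
                            clamp = clamp, seed = seed)
  assignments <- assign_hashtags(scaled, fit$cutoff)
  structure(list(assignments = assignments, scaled = scaled,
                 cutoff = fit$cutoff, q99 = fit$q99, K = fit$K,
                 mu_hat = fit$mu_hat, sigma_hat = fit$sigma_hat,
                 background = bg, empty_ids = empty_ids),
            class = "demux_result")
}

#' @exportS3Method base::print
print.demux_result <- function(x, ...) {
  tab <- table(x$assignments$assignment)
  cat(sprintf("hashtag demux: %d cells, K = %d, q99 = %.3f, cutoff = %.3f\n",
              nrow(x$assignments), x$K, x$q99, x$cutoff))
  cat(sprintf("background: %d empty droplets\n", x$background$n_empty))
  print(tab)
  invisible(x)
}
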