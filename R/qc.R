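#' Quality-control thresholds for cell and gene filtering
#'
#' Defaults fall inside the ranges typically used for droplet scRNA-seq of
#' sorted B-cell precursors: mitochondrial fraction at most 1%, cell totals
#' between 500 and 30,000, detected genes between 400 and 6,000, and genes
#' kept only when present in strictly more than 10 cells.
#'
#' @param max_mito maximum mitochondrial fraction per cell.
#' @param min_counts,max_counts per-cell total-count bounds (inclusive).
#' @param min_genes,max_genes per-cell detected-gene bounds (inclusive).
#' @param min_cells_per_gene a gene must be present (count > 0) in strictly
#'   more than this many cells.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(max_mito = 0.01, min_counts = 500L,
                          max_counts = 30000L, min_genes = 400L,
                          max_genes = 6000L, min_cells_per_gene = 10L) {
  stopifnot(min_counts < max_counts, min_genes < max_genes)
  structure(list(max_mito = .assert_fraction(max_mito, "max_mito"),
                 min_counts = .assert_count(min_counts, "min_counts"),
                 max_counts = .assert_count(max_counts, "max_counts"),
                 min_genes = .assert_count(min_genes, "min_genes"),
                 max_genes = .assert_count(max_genes, "max_genes"),
                 min_cells_per_gene =
                   .assert_count(min_cells_per_gene, "min_cells_per_gene")),
            class = "qc_thresholds")
}

#' Filter cells and genes on quality criteria
#'
#' Keeps genes present (count > 0) in strictly more than
#' `min_cells_per_gene` cells and cells with mitochondrial fraction at most
#' `max_mito`, total counts in `[min_counts, max_counts]` and detected genes
#' in `[min_genes, max_genes]`. Gene and cell masks are recomputed and
#' reapplied until stable, so the operation is idempotent. Removal counts
#' per criterion refer to the first pass.
#'
#' @param counts cells x genes count matrix (rows named by cell).
#' @param mito_fraction numeric vector, one value per row of `counts`.
#' @param thr a [qc_thresholds()] object.
#' @return list: `counts` (filtered), `mito_fraction` (filtered), `report`
#'   (named removal counts), `kept_cells`, `kept_genes`.
#' @export
filter_cells_genes <- function(counts, mito_fraction, thr = qc_thresholds()) {
  stopifnot(inherits(thr, "qc_thresholds"),
            length(mito_fraction) == nrow(counts))
  cur <- counts
  mito <- mito_fraction
  report <- NULL
  repeat {
    gene_ok <- colSums(cur > 0) > thr$min_cells_per_gene
    m <- cur[, gene_ok, drop = FALSE]
    totals <- rowSums(m)
    ngene <- rowSums(m > 0)
    ok_mito <- mito <= thr$max_mito
    ok_counts <- totals >= thr$min_counts & totals <= thr$max_counts
    ok_genes <- ngene >= thr$min_genes & ngene <= thr$max_genes
    cell_ok <- ok_mito & ok_counts & ok_genes
    if (is.null(report)) {
      report <- c(genes_low_prevalence = sum(!gene_ok),
                  cells_high_mito = sum(!ok_mito),
                  cells_count_range = sum(ok_mito & !ok_counts),
                  cells_gene_range = sum(ok_mito & ok_counts & !ok_genes))
    }
    nxt <- m[cell_ok, , drop = FALSE]
    stable <- ncol(nxt) == ncol(cur) && nrow(nxt) == nrow(cur)
    cur <- nxt
    mito <- mito[cell_ok]
    if (stable) break
    if (nrow(cur) == 0 || ncol(cur) == 0) {
      stop(sprintf(
        "QC removed everything (removed: %s)",
        paste(names(report), report, sep = "=", collapse = ", ")),
        call. = FALSE)
    }
  }
  list(counts = cur, mito_fraction = mito, report = report,
       kept_cells = rownames(cur), kept_genes = colnames(cur))
}

#' Size-factor normalization and log transform
#'
#' Divides each cell's counts by its size factor and applies `log1p`. The
#' default estimator is library size over the median library size; a
#' pooling-based estimator (e.g. from scran) can be plugged in by supplying
#' the factors directly or an estimator function.
#'
#' @param counts cells x genes count matrix.
#' @param size_factors either `NULL` (default estimator), a positive numeric
#'   vector (one per cell), or a function `counts -> factors`.
#' @return list: `lognorm` matrix, `size_factors`.
#' @export
normalize_log <- function(counts, size_factors = NULL) {
  if (is.null(size_factors)) {
    totals <- rowSums(counts)
    size_factors <- totals / stats::median(totals)
  } else if (is.function(size_factors)) {
    size_factors <- size_factors(counts)
  }
  if (length(size_factors) != nrow(counts) || any(size_factors <= 0) ||
      any(!is.finite(size_factors))) {
    stop("size factors must be positive and one per cell", call. = FALSE)
  }
  lognorm <- log1p(counts / size_factors)
  list(lognorm = lognorm, size_factors = size_factors)
}

#' Flag clusters dominated by low-quality cells
#'
#' A cluster is flagged when the mean per-cell fraction of counts falling in
#' a housekeeping (ribosomal) gene set is strictly below `min_fraction`.
#' Flagging is a report; removal is the caller's decision.
#'
#' @param counts cells x genes count matrix.
#' @param clusters cluster label per cell.
#' @param housekeeping_genes character vector of gene names (nonempty).
#' @param min_fraction flag threshold (default 0.1, strict `<`).
#' @return data.frame: `cluster`, `mean_hk_fraction`, `flagged`.
#' @export
flag_low_quality_clusters <- function(counts, clusters, housekeeping_genes,
                                      min_fraction = 0.1) {
  if (length(housekeeping_genes) == 0) {
    stop("housekeeping gene set is empty", call. = FALSE)
  }
  stopifnot(length(clusters) == nrow(counts))
  hk <- intersect(housekeeping_genes, colnames(counts))
  frac <- if (length(hk)) {
    rowSums(counts[, hk, drop = FALSE]) / pmax(rowSums(counts), 1)
  } else {
    rep(0, nrow(counts))
  }
  mean_frac <- tapply(frac, clusters, mean)
  data.frame(cluster = names(mean_frac),
             mean_hk_fraction = as.numeric(mean_frac),
             flagged = as.numeric(mean_frac) < min_fraction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-cluster differential abundance by chi-squared test
#'
#' For each cluster, a 2x2 table of (in cluster vs not) x (genotype) is
#' tested with Pearson's chi-squared (df = 1, no continuity correction).
#' Expected counts below 5 raise a warning flag in the output rather than a
#' correction.
#'
#' @param clusters cluster label per cell.
#' @param genotype genotype label per cell; exactly two levels must be
#'   present (e.g. WT / mutant).
#' @return data.frame: `cluster`, cell counts per genotype, `chisq`, `p`,
#'   `min_expected`, `low_expected` flag.
#' @export
cluster_abundance_test <- function(clusters, genotype) {
  stopifnot(length(clusters) == length(genotype))
  glev <- unique(as.character(genotype))
  if (length(glev) != 2) {
    stop(sprintf("need exactly 2 genotype groups, got %d", length(glev)),
         call. = FALSE)
  }
  clev <- sort(unique(as.character(clusters)))
  res <- lapply(clev, function(k) {
    tab <- table(factor(clusters == k, levels = c(TRUE, FALSE)),
                 factor(genotype, levels = glev))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(cluster = k,
               n_g1 = as.integer(tab[1, 1]), n_g2 = as.integer(tab[1, 2]),
               chisq = unname(ct$statistic), p = ct$p.value,
               min_expected = min(ct$expected),
               low_expected = min(ct$expected) < 5,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  names(out)[2:3] <- paste0("n_", glev)
  out
}
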