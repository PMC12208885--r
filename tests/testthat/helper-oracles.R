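# Independent, deliberately naive re-implementations used as oracles.
# They are scalar / loop-based on purpose and share no code with the
# package internals they check.

# empty-droplet selection, droplet by droplet
oracle_select_empty <- function(droplets, mad_mult = 2, max_mito = 0.25) {
  pass1 <- character(0)
  for (i in seq_len(nrow(droplets))) {
    d <- droplets[i, ]
    if (d$rna_total > 1 && d$protein_total > 1 && !d$is_cell) {
      pass1 <- c(pass1, d$droplet_id)
    }
  }
  sub <- droplets[droplets$droplet_id %in% pass1, ]
  med_r <- median(log10(sub$rna_total))
  med_p <- median(log10(sub$protein_total))
  mad_r <- median(abs(log10(sub$rna_total) - med_r))
  mad_p <- median(abs(log10(sub$protein_total) - med_p))
  keep <- character(0)
  for (i in seq_len(nrow(sub))) {
    d <- sub[i, ]
    if (abs(log10(d$rna_total) - med_r) < mad_mult * mad_r &&
        abs(log10(d$protein_total) - med_p) < mad_mult * mad_p &&
        d$mito_fraction < max_mito) {
      keep <- c(keep, d$droplet_id)
    }
  }
  keep
}

# QC survivors, clause by clause with the same fixpoint loop
oracle_qc <- function(counts, mito, thr) {
  repeat {
    gene_keep <- logical(ncol(counts))
    for (j in seq_len(ncol(counts))) {
      gene_keep[j] <- sum(counts[, j] > 0) > thr$min_cells_per_gene
    }
    counts2 <- counts[, gene_keep, drop = FALSE]
    cell_keep <- logical(nrow(counts2))
    for (i in seq_len(nrow(counts2))) {
      tot <- sum(counts2[i, ])
      ng <- sum(counts2[i, ] > 0)
      cell_keep[i] <- mito[i] <= thr$max_mito &&
        tot >= thr$min_counts && tot <= thr$max_counts &&
        ng >= thr$min_genes && ng <= thr$max_genes
    }
    nxt <- counts2[cell_keep, , drop = FALSE]
    if (nrow(nxt) == nrow(counts) && ncol(nxt) == ncol(counts)) break
    counts <- nxt
    mito <- mito[cell_keep]
  }
  list(cells = rownames(counts), genes = colnames(counts))
}

# closed-form Pearson chi-squared for a 2x2 table
oracle_chisq_2x2 <- function(tab) {
  a <- as.numeric(tab[1, 1]); b <- as.numeric(tab[1, 2])
  c2 <- as.numeric(tab[2, 1]); d <- as.numeric(tab[2, 2])
  n <- a + b + c2 + d
  n * (a * d - b * c2)^2 /
    ((a + b) * (c2 + d) * (a + c2) * (b + d))
}

# permutation null of the per-cluster chi-squared
oracle_perm_p <- function(in_cluster, genotype, n_perm = 10000, seed = 1) {
  set.seed(seed)
  obs <- oracle_chisq_2x2(table(in_cluster, genotype))
  ge <- 0
  for (b in seq_len(n_perm)) {
    stat <- oracle_chisq_2x2(table(in_cluster, sample(genotype)))
    if (stat >= obs - 1e-12) ge <- ge + 1
  }
  (ge + 1) / (n_perm + 1)
}

# scalar clause evaluation of the somatic filters
oracle_snv_mutect <- function(r) {
  r$nalod > 0 && r$tlod >= 10 &&
    (r$af_tumor >= 0.05 || r$alt_reads_tumor >= 3) &&
    r$alt_reads_normal == 0 && r$alt_fwd >= 1 && r$alt_rev >= 1 &&
    r$median_bq_alt > 30 && r$median_mq_alt >= 60
}
oracle_sv <- function(r) {
  r$filter_field == "PASS" && r$pr_alt >= 1 && r$sr_alt >= 1 &&
    (r$pr_alt + r$sr_alt) >= 5
}
oracle_cnv <- function(r) {
  (r$copy_number <= 1 || r$copy_number >= 3) &&
    (r$end - r$start + 1) >= 10000
}

# naive both-strand exact scan by substring comparison
oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), NULL)[[1]]), collapse = "")
}
oracle_scan <- function(seqc, motif) {
  seqc <- toupper(seqc)
  L <- nchar(seqc)
  k <- nchar(motif)
  hits <- data.frame(start0 = integer(), strand = character())
  if (k > L) return(hits)
  starts <- seq_len(L - k + 1)
  subs <- substring(seqc, starts, starts + k - 1)
  fwd <- which(subs == motif)
  rev <- which(subs == oracle_revcomp(motif))
  rbind(
    data.frame(start0 = fwd - 1L, strand = rep("+", length(fwd))),
    data.frame(start0 = rev - 1L, strand = rep("-", length(rev)))
  )
}

# balanced planted-regulon simulation shared by regulon tests
make_planted_sim <- function(seed, n_planted = 10, n_decoys = 10,
                             n_types = 5, n_cells_per_type = 500,
                             n_genes = 1000, n_targets = 30, r = 0.6) {
  specs <- c(
    lapply(seq_len(n_planted), function(i) {
      list(tf_id = sprintf("TF%02d", i), n_targets = n_targets, r = r,
           active_cell_types = ((i - 1) %% n_types) + 1)
    }),
    lapply(seq_len(n_decoys), function(i) {
      list(tf_id = sprintf("TF%02d", n_planted + i), n_targets = 0L, r = 0)
    })
  )
  cfg <- expression_sim_config(
    n_cell_types = n_types, n_cells_per_type = n_cells_per_type,
    n_genes = n_genes, tf_specs = specs, seed = seed)
  sim <- simulate_expression(cfg)
  sim$planted <- sprintf("TF%02d", seq_len(n_planted))
  sim$decoys <- sprintf("TF%02d", n_planted + seq_len(n_decoys))
  sim
}
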