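test_that("droplet simulator handles degenerate and zero-effect configs", {
  # only empty droplets
  cfg <- droplet_sim_config(n_singlets_per_tag = 0L, n_doublets = 0L,
                            n_empty = 50L, seed = 3)
  ds <- simulate_droplets(cfg)
  expect_equal(nrow(ds$droplets), 50L)
  expect_true(all(ds$truth$truth == "empty"))

  # zero signal shift: positive-tag counts indistinguishable from ambient
  cfg0 <- droplet_sim_config(n_hashtags = 2L, n_singlets_per_tag = 500L,
                             n_doublets = 0L, n_empty = 500L,
                             signal_shift = 0, seed = 4)
  ds0 <- simulate_droplets(cfg0)
  sing <- ds0$truth$truth == "singlet" & ds0$truth$tag1 == 1L
  empt <- ds0$truth$truth == "empty"
  ks <- suppressWarnings(ks.test(log1p(ds0$hashtag_counts[sing, 1]),
                                 log1p(ds0$hashtag_counts[empt, 1])))
  expect_gt(ks$p.value, 0.01)

  # counts are nonnegative integers; protein totals consistent
  expect_true(all(ds0$hashtag_counts >= 0))
  expect_true(all(ds0$hashtag_counts == floor(ds0$hashtag_counts)))
  expect_equal(ds0$droplets$protein_total, as.integer(rowSums(ds0$hashtag_counts)))

  expect_error(droplet_sim_config(n_hashtags = 1L), "n_hashtags")
  expect_error(droplet_sim_config(signal_shift = -1), "signal_shift")
})

test_that("expression simulator realizes the requested target correlations", {
  spec <- list(list(tf_id = "TFA", n_targets = 50L, r = 0.8),
               list(tf_id = "TFB", n_targets = 50L, r = 0))
  cfg <- expression_sim_config(n_cell_types = 5, n_cells_per_type = 400,
                               n_genes = 300, tf_specs = spec, seed = 7)
  sim <- simulate_expression(cfg)
  ra <- abs(cor(sim$lognorm[, "TFA"],
                sim$lognorm[, sim$regulons$TFA$targets]))
  expect_gte(mean(ra >= 0.7 & ra <= 0.9), 0.95)
  rb <- abs(cor(sim$lognorm[, "TFB"],
                sim$lognorm[, sim$regulons$TFB$targets]))
  expect_gte(mean(rb < 0.1), 0.95)

  # non-target genes independent of the TFs
  others <- setdiff(colnames(sim$lognorm),
                    c("TFA", "TFB", sim$regulons$TFA$targets,
                      sim$regulons$TFB$targets))
  ro <- abs(cor(sim$lognorm[, "TFA"], sim$lognorm[, others]))
  expect_gte(mean(ro < 0.1), 0.95)

  # capacity check
  expect_error(
    expression_sim_config(n_genes = 40, tf_specs = spec),
    "cannot host")
})

test_that("somatic-call simulator truth labels equal brute-force clause evaluation", {
  cfg <- variant_sim_config(n_snv = 1000L, n_sv = 1000L, n_cnv = 1000L,
                            seed = 12)
  calls <- simulate_somatic_calls(cfg)
  snv_oracle <- vapply(seq_len(nrow(calls$snv)),
                       function(i) oracle_snv_mutect(calls$snv[i, ]),
                       logical(1))
  expect_identical(calls$snv$truth_pass, snv_oracle)
  sv_oracle <- vapply(seq_len(nrow(calls$sv)),
                      function(i) oracle_sv(calls$sv[i, ]), logical(1))
  expect_identical(calls$sv$truth_pass, sv_oracle)
  cnv_oracle <- vapply(seq_len(nrow(calls$cnv)),
                       function(i) oracle_cnv(calls$cnv[i, ]), logical(1))
  expect_identical(calls$cnv$truth_pass, cnv_oracle)

  # forced pass / forced fail
  all_pass <- simulate_somatic_calls(variant_sim_config(
    n_snv = 200L, n_sv = 200L, n_cnv = 200L,
    fraction_pass = as.list(setNames(rep(1, 12),
      c("nalod", "tlod", "af_or_reads", "normal_clean", "both_strands",
        "base_quality", "mapping_quality", "strelka_pass", "sv_pass",
        "sv_support", "cnv_state", "cnv_size"))), seed = 13))
  expect_true(all(all_pass$snv$truth_pass))
  expect_true(all(all_pass$sv$truth_pass))
  expect_true(all(all_pass$cnv$truth_pass))
  no_tlod <- simulate_somatic_calls(variant_sim_config(
    n_snv = 200L, fraction_pass = list(tlod = 0), seed = 14))
  expect_false(any(no_tlod$snv$truth_pass))

  expect_error(variant_sim_config(fraction_pass = list(tlodd = 1)),
               "unknown fraction_pass")
})

test_that("breakend-genome simulator plants motifs at exact coordinates", {
  pm <- data.frame(motif = "CACAGTG", offset = c(10L, -20L),
                   strand = c("+", "-"))
  cfg <- breakend_sim_config(n_breakends = 4L, planted_motifs = pm, seed = 9)
  sim <- simulate_breakend_genome(cfg)
  # plus-strand plant reads as the motif, minus-strand as its revcomp
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    contig <- if (tr$breakend == 1L) {
      sim$svs$chrom1[sim$svs$id == tr$sv_id]
    } else {
      sim$svs$chrom2[sim$svs$id == tr$sv_id]
    }
    got <- substr(sim$genome[[contig]], tr$hit_start + 1,
                  tr$hit_start + nchar(tr$planted_seq))
    expect_identical(got, tr$planted_seq)
    expected <- if (tr$strand == "-") oracle_revcomp(tr$motif) else tr$motif
    expect_identical(got, expected)
  }

  # no plants + background scrubbed of the motif -> truth empty, scan empty
  cfg0 <- breakend_sim_config(n_breakends = 2L, seed = 10,
                              contig_lengths = c(chrA = 5000L))
  sim0 <- simulate_breakend_genome(cfg0)
  expect_equal(nrow(sim0$truth), 0L)
  naive <- oracle_scan(sim0$genome[["chrA"]], "CACAGTG")
  if (nrow(naive) == 0) {
    wins <- extend_breakends(sim0$svs, sim0$genome)
    hits <- scan_exact(wins, motif_set(c(h = "CACAGTG")))
    expect_equal(nrow(hits), 0L)
  }

  # offsets outside the window are a configuration error
  expect_error(breakend_sim_config(planted_motifs = data.frame(
    motif = "CACAGTG", offset = 99L, strand = "+")), "outside")
})

test_that("all simulators are deterministic under a fixed seed", {
  d1 <- simulate_droplets(droplet_sim_config(n_empty = 200L,
                                             n_singlets_per_tag = 20L,
                                             seed = 7))
  d2 <- simulate_droplets(droplet_sim_config(n_empty = 200L,
                                             n_singlets_per_tag = 20L,
                                             seed = 7))
  expect_identical(d1, d2)

  spec <- list(list(tf_id = "TFA", n_targets = 12L, r = 0.5))
  ec <- expression_sim_config(n_cell_types = 3, n_cells_per_type = 40,
                              n_genes = 60, tf_specs = spec, seed = 7)
  expect_identical(simulate_expression(ec), simulate_expression(ec))

  vc <- variant_sim_config(n_snv = 50L, n_sv = 50L, n_cnv = 50L, seed = 7)
  expect_identical(simulate_somatic_calls(vc), simulate_somatic_calls(vc))

  bc <- breakend_sim_config(n_breakends = 3L, seed = 7)
  expect_identical(simulate_breakend_genome(bc), simulate_breakend_genome(bc))
})
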