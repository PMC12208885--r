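# a record that passes every clause; tests perturb one field at a time
passing_snv <- function(...) {
  rec <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                    caller = "mutect-like", nalod = 2, tlod = 50,
                    af_tumor = 0.3, alt_reads_tumor = 20L,
                    alt_reads_normal = 0L, alt_fwd = 10L, alt_rev = 10L,
                    median_bq_alt = 35, median_mq_alt = 60)
  mod <- list(...)
  for (k in names(mod)) rec[[k]] <- mod[[k]]
  rec
}

test_that("mutect-style filter honors every printed boundary", {
  expect_true(filter_snv_mutect(passing_snv())$pass)
  # inclusive / strict bounds, clause by clause
  expect_true(filter_snv_mutect(passing_snv(tlod = 10))$pass)
  expect_false(filter_snv_mutect(passing_snv(tlod = 9.999))$pass)
  expect_false(filter_snv_mutect(passing_snv(nalod = 0))$pass)
  expect_true(filter_snv_mutect(
    passing_snv(af_tumor = 0.05, alt_reads_tumor = 0L, alt_fwd = 0L,
                alt_rev = 0L))$pass == FALSE)  # strand clause still applies
  v <- filter_snv_mutect(passing_snv(af_tumor = 0.05, alt_reads_tumor = 2L,
                                     alt_fwd = 1L, alt_rev = 1L))
  expect_true(v$pass)  # AF bound inclusive
  # OR clause: low AF rescued by >= 3 reads
  expect_true(filter_snv_mutect(passing_snv(af_tumor = 0.02,
                                            alt_reads_tumor = 3L,
                                            alt_fwd = 2L,
                                            alt_rev = 1L))$pass)
  expect_false(filter_snv_mutect(passing_snv(af_tumor = 0.02,
                                             alt_reads_tumor = 2L,
                                             alt_fwd = 1L,
                                             alt_rev = 1L))$pass)
  expect_false(filter_snv_mutect(passing_snv(alt_reads_normal = 1L))$pass)
  # strand: evidence solely on one strand fails
  expect_false(filter_snv_mutect(passing_snv(alt_fwd = 20L,
                                             alt_rev = 0L))$pass)
  expect_false(filter_snv_mutect(passing_snv(median_bq_alt = 30))$pass)
  expect_true(filter_snv_mutect(passing_snv(median_mq_alt = 60))$pass)
  expect_false(filter_snv_mutect(passing_snv(median_mq_alt = 59.9))$pass)

  # diagnostics name all failed clauses, no short-circuiting
  v2 <- filter_snv_mutect(passing_snv(tlod = 1, median_bq_alt = 10))
  expect_match(v2$failed_clauses, "tlod")
  expect_match(v2$failed_clauses, "base_quality")
  # missing fields are unevaluable, never PASS
  v3 <- filter_snv_mutect(passing_snv(nalod = NA))
  expect_false(v3$pass)
  expect_match(v3$unevaluable, "nalod")
})

test_that("strelka filter requires exactly PASS", {
  df <- data.frame(filter_field = c("PASS", "LowEVS", "", NA))
  v <- filter_snv_strelka(df)
  expect_equal(v$pass, c(TRUE, FALSE, FALSE, FALSE))
  expect_match(v$unevaluable[3], "default_pass")
})

test_that("union merge deduplicates, keeps provenance, and is commutative", {
  a <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                  ref = "A", alt = "T", caller = "mutect-like")
  b <- data.frame(chrom = "chr1", pos = c(30L, 40L, 50L, 60L),
                  ref = "A", alt = "T", caller = "strelka-like")
  u <- merge_union(a, b)
  expect_equal(nrow(u), 6)
  expect_equal(u$callers[u$pos == 30], "mutect-like,strelka-like")
  expect_identical(merge_union(a, b), merge_union(b, a))
  expect_identical(merge_union(u), u[, names(u)])  # idempotent
  # conflicting ref at the same locus/alt is an input-consistency error
  b2 <- b; b2$ref[1] <- "G"
  expect_error(merge_union(a, b2), "conflicting ref")
})

test_that("SV and CNV filters follow printed support and size rules", {
  sv <- data.frame(filter_field = c("PASS", "PASS", "PASS", "MinQual"),
                   pr_alt = c(4L, 5L, 2L, 10L),
                   sr_alt = c(1L, 0L, 2L, 10L))
  v <- filter_sv(sv)
  expect_equal(v$pass, c(TRUE, FALSE, FALSE, FALSE))
  expect_match(v$failed_clauses[2], "split_reads")
  expect_match(v$failed_clauses[3], "total_support")

  cnv <- data.frame(chrom = "chr1",
                    start = c(1L, 1L, 1L, 1L),
                    end = c(10000L, 9999L, 20000L, 10000L),
                    copy_number = c(1L, 3L, 2L, 0L))
  vc <- filter_cnv(cnv)
  expect_equal(vc$pass, c(TRUE, FALSE, FALSE, TRUE))
  expect_match(vc$failed_clauses[3], "copy_state")
})

test_that("vectorized filters equal record-by-record brute force on 1000 records", {
  calls <- simulate_somatic_calls(variant_sim_config(
    n_snv = 1000L, n_sv = 1000L, n_cnv = 1000L, seed = 77))
  vm <- filter_snv_mutect(calls$snv)
  expect_identical(vm$pass, vapply(seq_len(1000),
    function(i) oracle_snv_mutect(calls$snv[i, ]), logical(1)))
  vs <- filter_sv(calls$sv)
  expect_identical(vs$pass, vapply(seq_len(1000),
    function(i) oracle_sv(calls$sv[i, ]), logical(1)))
  vc <- filter_cnv(calls$cnv)
  expect_identical(vc$pass, vapply(seq_len(1000),
    function(i) oracle_cnv(calls$cnv[i, ]), logical(1)))
})

test_that("impact selection keeps HIGH/MODERATE and reports exclusions", {
  recs <- data.frame(id = 1:5,
                     impact = c("HIGH", "HIGH", "MODERATE", "LOW", "MODIFIER"))
  kept <- select_impact(recs)
  expect_equal(nrow(kept), 3)
  expect_true(all(kept$impact %in% c("HIGH", "MODERATE")))
  recs2 <- data.frame(id = 1:3, impact = c("HIGH", NA, "LOW"))
  kept2 <- select_impact(recs2)
  expect_equal(unname(attr(kept2, "report")),
               c(1L, 1L, 1L))
})

test_that("recurrence matrix merges SV/CNV deletion categories and counts samples", {
  v <- data.frame(
    sample = c("s1", "s2", "s3", "s1", "s2", "s1"),
    gene = c("Pax5", "Pax5", "Pax5", "Jak1", "Jak1", "Stat5b"),
    vtype = c("SNV", "SNV", "SNV", "DEL", "CNV_LOSS", "DUP"))
  rec <- build_recurrence(v)
  r <- rec$recurrence
  expect_equal(r$n_samples[r$gene == "Pax5" & r$category == "SNV"], 3L)
  # SV DEL in s1 + CNV loss in s2 -> deletion recurrence 2
  expect_equal(r$n_samples[r$gene == "Jak1" & r$category == "deletion"], 2L)
  expect_equal(rec$matrix["Stat5b", "s1"], "duplication")
  expect_equal(rec$matrix["Stat5b", "s2"], "")
  # driver-list row ordering
  rec2 <- build_recurrence(v, gene_order = c("Stat5b", "Pax5"))
  expect_equal(rownames(rec2$matrix), c("Stat5b", "Pax5", "Jak1"))
  # empty input
  empty <- build_recurrence(v[0, ])
  expect_equal(dim(empty$matrix), c(0L, 0L))
})

test_that("simulated SNVs round-trip through VCF and refilter identically", {
  calls <- simulate_somatic_calls(variant_sim_config(n_snv = 100L, seed = 31))
  path <- tempfile(fileext = ".vcf")
  write_snv_vcf(calls$snv, path)
  back <- read_snv_vcf(path)
  expect_equal(nrow(back), 100)
  expect_equal(back$tlod, calls$snv$tlod, tolerance = 1e-4)
  expect_identical(filter_snv_mutect(back)$pass,
                   filter_snv_mutect(calls$snv)$pass)
})
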