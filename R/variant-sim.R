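#' Configuration for the somatic-call simulator
#'
#' Generates caller-like SNV, SV and CNV records carrying every field the
#' filter battery consumes. `fraction_pass` sets, per filter clause, the
#' probability that a record is drawn from the passing side of the clause;
#' where clauses interact (read counts feed both the allele-support and the
#' strand clause) realized fractions are approximate, but every record's
#' truth verdict is recomputed by brute-force clause evaluation, so truth
#' labels are exact by construction.
#'
#' @param n_snv,n_sv,n_cnv record counts per type.
#' @param fraction_pass named list of clause pass-probabilities; recognized
#'   names: `nalod`, `tlod`, `af_or_reads`, `normal_clean`, `both_strands`,
#'   `base_quality`, `mapping_quality`, `strelka_pass`, `sv_pass`,
#'   `sv_support`, `cnv_state`, `cnv_size`. Defaults 0.7 each.
#' @param seed integer seed.
#' @return a `variant_sim_config` list.
#' @export
variant_sim_config <- function(n_snv = 100L, n_sv = 50L, n_cnv = 50L,
                               fraction_pass = list(), seed = 1L) {
  defaults <- list(nalod = 0.7, tlod = 0.7, af_or_reads = 0.7,
                   normal_clean = 0.7, both_strands = 0.7,
                   base_quality = 0.7, mapping_quality = 0.7,
                   strelka_pass = 0.7, sv_pass = 0.7, sv_support = 0.7,
                   cnv_state = 0.7, cnv_size = 0.7)
  unknown <- setdiff(names(fraction_pass), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown fraction_pass clause(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  fp <- utils::modifyList(defaults, fraction_pass)
  for (nm in names(fp)) .assert_fraction(fp[[nm]], nm)
  structure(list(n_snv = .assert_count(n_snv, "n_snv"),
                 n_sv = .assert_count(n_sv, "n_sv"),
                 n_cnv = .assert_count(n_cnv, "n_cnv"),
                 fraction_pass = fp,
                 seed = .assert_count(seed, "seed")),
            class = "variant_sim_config")
}

# scalar brute-force re-evaluations, deliberately written record-by-record
# and kept apart from the vectorized filters they label
.snv_truth_one <- function(r) {
  isTRUE(r$nalod > 0) && isTRUE(r$tlod >= 10) &&
    isTRUE(r$af_tumor >= 0.05 || r$alt_reads_tumor >= 3) &&
    isTRUE(r$alt_reads_normal == 0) &&
    isTRUE(r$alt_fwd >= 1 && r$alt_rev >= 1) &&
    isTRUE(r$median_bq_alt > 30) && isTRUE(r$median_mq_alt >= 60)
}
.sv_truth_one <- function(r) {
  isTRUE(r$filter_field == "PASS") && isTRUE(r$pr_alt >= 1) &&
    isTRUE(r$sr_alt >= 1) && isTRUE(r$pr_alt + r$sr_alt >= 5)
}
.cnv_truth_one <- function(r) {
  isTRUE(r$copy_number <= 1 || r$copy_number >= 3) &&
    isTRUE(r$end - r$start + 1 >= 10000)
}

.pick <- function(n, p) stats::runif(n) < p

#' Simulate caller-like somatic variant records with truth verdicts
#'
#' @param cfg a [variant_sim_config()].
#' @return list of data.frames `snv` (mutect-like), `strelka`, `sv`, `cnv`,
#'   each carrying a logical `truth_pass` column computed by brute-force
#'   clause evaluation.
#' @export
simulate_somatic_calls <- function(cfg) {
  stopifnot(inherits(cfg, "variant_sim_config"))
  set.seed(cfg$seed)
  fp <- cfg$fraction_pass
  chroms <- paste0("chr", c(1:19, "X"))
  bases <- c("A", "C", "G", "T")

  n <- cfg$n_snv
  snv <- data.frame(
    chrom = sample(chroms, n, TRUE),
    pos = sample.int(1e8, n),
    ref = sample(bases, n, TRUE),
    caller = "mutect-like",
    stringsAsFactors = FALSE)
  snv$alt <- vapply(snv$ref, function(b) sample(setdiff(bases, b), 1),
                    character(1))
  snv$nalod <- ifelse(.pick(n, fp$nalod),
                      stats::runif(n, 0.1, 10), stats::runif(n, -5, 0))
  snv$tlod <- ifelse(.pick(n, fp$tlod),
                     stats::runif(n, 10, 500), stats::runif(n, 0, 9.99))
  ok_afr <- .pick(n, fp$af_or_reads)
  via_af <- .pick(n, 0.5)
  snv$af_tumor <- ifelse(ok_afr,
                         ifelse(via_af, stats::runif(n, 0.05, 1),
                                stats::runif(n, 0, 0.049)),
                         stats::runif(n, 0, 0.049))
  # 2 alt reads keeps the strand clause satisfiable while failing (or, for
  # the AF-rescued case, not triggering) the >= 3-read arm of the OR clause
  snv$alt_reads_tumor <- ifelse(ok_afr & !via_af, sample(3:60, n, TRUE), 2L)
  snv$alt_reads_normal <- ifelse(.pick(n, fp$normal_clean), 0L,
                                 sample(1:5, n, TRUE))
  ok_str <- .pick(n, fp$both_strands) & snv$alt_reads_tumor >= 2
  snv$alt_fwd <- ifelse(ok_str,
                        pmax(1L, as.integer(round(snv$alt_reads_tumor / 2))),
                        snv$alt_reads_tumor)
  snv$alt_rev <- snv$alt_reads_tumor - snv$alt_fwd
  snv$median_bq_alt <- ifelse(.pick(n, fp$base_quality),
                              stats::runif(n, 30.01, 45),
                              stats::runif(n, 10, 30))
  snv$median_mq_alt <- ifelse(.pick(n, fp$mapping_quality),
                              stats::runif(n, 60, 70), stats::runif(n, 0, 59.9))
  snv$impact <- sample(c("HIGH", "MODERATE", "LOW", "MODIFIER"), n, TRUE)
  snv$truth_pass <- vapply(seq_len(max(n, 0)),
                           function(i) .snv_truth_one(snv[i, ]), logical(1))

  n2 <- cfg$n_snv
  strelka <- data.frame(
    chrom = sample(chroms, n2, TRUE),
    pos = sample.int(1e8, n2),
    ref = sample(bases, n2, TRUE),
    caller = "strelka-like",
    stringsAsFactors = FALSE)
  strelka$alt <- vapply(strelka$ref, function(b) sample(setdiff(bases, b), 1),
                        character(1))
  strelka$filter_field <- ifelse(.pick(n2, fp$strelka_pass), "PASS",
                                 sample(c("LowEVS", "LowDepth"), n2, TRUE))
  strelka$truth_pass <- strelka$filter_field == "PASS"

  ns <- cfg$n_sv
  sv <- data.frame(
    id = sprintf("SV%04d", seq_len(ns)),
    chrom1 = sample(chroms, ns, TRUE), pos1 = sample.int(1e8, ns),
    chrom2 = sample(chroms, ns, TRUE), pos2 = sample.int(1e8, ns),
    svtype = sample(c("DEL", "DUP", "INV", "TRA"), ns, TRUE),
    filter_field = ifelse(.pick(ns, fp$sv_pass), "PASS", "MinQual"),
    stringsAsFactors = FALSE)
  ok_sup <- .pick(ns, fp$sv_support)
  sv$pr_alt <- ifelse(ok_sup, sample(2:20, ns, TRUE),
                      sample(0:2, ns, TRUE))
  sv$sr_alt <- ifelse(ok_sup, sample(3:20, ns, TRUE),
                      ifelse(.pick(ns, 0.5), 0L, sample(0:1, ns, TRUE)))
  sv$affected_genes <- sprintf("Gene%02d", sample.int(30, ns, TRUE))
  sv$truth_pass <- vapply(seq_len(max(ns, 0)),
                          function(i) .sv_truth_one(sv[i, ]), logical(1))

  nc <- cfg$n_cnv
  cnv <- data.frame(
    chrom = sample(chroms, nc, TRUE),
    start = sample.int(1e8, nc),
    stringsAsFactors = FALSE)
  len <- ifelse(.pick(nc, fp$cnv_size),
                sample(10000:2000000, nc, TRUE), sample(100:9999, nc, TRUE))
  cnv$end <- cnv$start + len - 1L
  cnv$copy_number <- ifelse(.pick(nc, fp$cnv_state),
                            sample(c(0L, 1L, 3L, 4L, 5L), nc, TRUE), 2L)
  cnv$affected_genes <- sprintf("Gene%02d", sample.int(30, nc, TRUE))
  cnv$truth_pass <- vapply(seq_len(max(nc, 0)),
                           function(i) .cnv_truth_one(cnv[i, ]), logical(1))

  list(snv = snv, strelka = strelka, sv = sv, cnv = cnv)
}
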