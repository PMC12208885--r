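# Verdict helper: `clauses` is a named list of logical vectors (NA =
# unevaluable). A record passes iff every clause is TRUE; failed and
# unevaluable clause names are reported per record, never short-circuited.
.verdict <- function(clauses, n) {
  cm <- do.call(cbind, clauses)
  failed <- apply(cm, 1, function(z) {
    paste(colnames(cm)[!is.na(z) & !z], collapse = ";")
  })
  uneval <- apply(cm, 1, function(z) paste(colnames(cm)[is.na(z)],
                                           collapse = ";"))
  data.frame(pass = failed == "" & uneval == "",
             failed_clauses = failed, unevaluable = uneval,
             stringsAsFactors = FALSE)
}

#' Filter Mutect2-style SNV/indel records
#'
#' A record passes when all of the following hold: NALOD > 0 (no evidence of
#' the artifact in the matched normal), TLOD >= 10, tumor allele fraction
#' >= 0.05 or at least 3 alt-supporting reads, zero alt reads in the normal,
#' alt evidence on both strands (>= 1 read each), median base quality of the
#' alt allele > 30, and median mapping quality of the alt allele >= 60.
#' Missing fields make the record unevaluable (not PASS) and are named in
#' the verdict.
#'
#' @param snv data.frame with columns `nalod`, `tlod`, `af_tumor`,
#'   `alt_reads_tumor`, `alt_reads_normal`, `alt_fwd`, `alt_rev`,
#'   `median_bq_alt`, `median_mq_alt`.
#' @return data.frame of verdicts: `pass`, `failed_clauses`, `unevaluable`.
#' @export
filter_snv_mutect <- function(snv) {
  with(snv, .verdict(list(
    nalod = nalod > 0,
    tlod = tlod >= 10,
    af_or_reads = af_tumor >= 0.05 | alt_reads_tumor >= 3,
    normal_clean = alt_reads_normal == 0,
    both_strands = alt_fwd >= 1 & alt_rev >= 1,
    base_quality = median_bq_alt > 30,
    mapping_quality = median_mq_alt >= 60
  ), nrow(snv)))
}

#' Filter Strelka-style records on the caller's own default filters
#'
#' A record passes iff its FILTER field is exactly `PASS`. An empty FILTER
#' field is unevaluable.
#'
#' @param snv data.frame with a `filter_field` column (semicolon-separated
#'   filter names).
#' @return verdict data.frame as in [filter_snv_mutect()].
#' @export
filter_snv_strelka <- function(snv) {
  ff <- as.character(snv$filter_field)
  ok <- ifelse(is.na(ff) | ff == "", NA, ff == "PASS")
  .verdict(list(default_pass = ok), nrow(snv))
}

#' Union-merge passing variant lists from multiple callers
#'
#' Deduplicates on (chrom, pos, ref, alt); the `caller` column of
#' contributing records is collected into a comma-separated provenance
#' column. Records sharing (chrom, pos, alt) but disagreeing on the
#' reference allele indicate un-normalized input and raise an error.
#'
#' @param ... data.frames of passing records, each with `chrom`, `pos`,
#'   `ref`, `alt` and optionally `caller`.
#' @return merged data.frame with a `callers` provenance column, sorted by
#'   (chrom, pos, ref, alt).
#' @export
merge_union <- function(...) {
  lists <- list(...)
  lists <- lists[vapply(lists, function(x) !is.null(x) && nrow(x) > 0,
                        logical(1))]
  if (length(lists) == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      callers = character(), stringsAsFactors = FALSE))
  }
  all <- do.call(rbind, lapply(lists, function(x) {
    if (!"caller" %in% names(x)) {
      # re-merging an already-merged list: expand its provenance column
      if ("callers" %in% names(x)) {
        reps <- strsplit(x$callers, ",", fixed = TRUE)
        x <- x[rep(seq_len(nrow(x)), lengths(reps)), , drop = FALSE]
        x$caller <- unlist(reps)
      } else {
        x$caller <- "unknown"
      }
    }
    x[, c("chrom", "pos", "ref", "alt", "caller")]
  }))
  key_pa <- paste(all$chrom, all$pos, all$alt, sep = ":")
  refs_by_pa <- tapply(all$ref, key_pa, function(r) length(unique(r)))
  if (any(refs_by_pa > 1)) {
    stop(sprintf("conflicting ref alleles at %s",
                 paste(names(refs_by_pa)[refs_by_pa > 1], collapse = ", ")),
         call. = FALSE)
  }
  key <- paste(all$chrom, all$pos, all$ref, all$alt, sep = ":")
  callers <- tapply(all$caller, key,
                    function(cc) paste(sort(unique(cc)), collapse = ","))
  first <- all[!duplicated(key), c("chrom", "pos", "ref", "alt")]
  first$callers <- as.character(callers[paste(first$chrom, first$pos,
                                              first$ref, first$alt,
                                              sep = ":")])
  first <- first[order(first$chrom, first$pos, first$ref, first$alt), ]
  rownames(first) <- NULL
  first
}

#' Filter structural-variant records
#'
#' A record passes when it carries the caller's PASS flag, has both paired-
#' and split-read support for the alternative allele (>= 1 each), and at
#' least 5 supporting reads in total.
#'
#' @param sv data.frame with `filter_field`, `pr_alt`, `sr_alt`.
#' @return verdict data.frame.
#' @export
filter_sv <- function(sv) {
  ff <- as.character(sv$filter_field)
  with(sv, .verdict(list(
    default_pass = ifelse(is.na(ff) | ff == "", NA, ff == "PASS"),
    paired_reads = pr_alt >= 1,
    split_reads = sr_alt >= 1,
    total_support = pr_alt + sr_alt >= 5
  ), nrow(sv)))
}

#' Filter copy-number segments
#'
#' A segment passes when its integer copy number is 0, 1, or at least 3
#' (i.e. not copy-neutral) and it spans at least 10,000 bp (1-based
#' inclusive coordinates).
#'
#' @param cnv data.frame with `chrom`, `start`, `end`, `copy_number`.
#' @param min_size minimum segment size in bp (default 10000).
#' @return verdict data.frame.
#' @export
filter_cnv <- function(cnv, min_size = 10000L) {
  with(cnv, .verdict(list(
    copy_state = copy_number <= 1 | copy_number >= 3,
    min_size = (end - start + 1) >= min_size
  ), nrow(cnv)))
}

#' Select coding variants by predicted impact
#'
#' Keeps records whose annotated impact is HIGH or MODERATE. Records with
#' missing impact are excluded and counted in the attached report.
#'
#' @param records data.frame with an `impact` column.
#' @return the kept subset, with attribute `report` (named counts:
#'   `kept`, `dropped_low`, `dropped_missing`).
#' @export
select_impact <- function(records) {
  imp <- as.character(records$impact)
  keep <- !is.na(imp) & imp %in% c("HIGH", "MODERATE")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- c(kept = sum(keep),
                           dropped_low = sum(!is.na(imp) &
                                             !imp %in% c("HIGH", "MODERATE")),
                           dropped_missing = sum(is.na(imp) | imp == ""))
  out
}

# map raw variant types onto recurrence categories; SV deletions/
# duplications and CNV losses/gains fold into shared categories
.recurrence_category <- function(vtype) {
  map <- c(SNV = "SNV", INDEL = "indel", DEL = "deletion",
           CNV_LOSS = "deletion", DUP = "duplication",
           CNV_GAIN = "duplication", INV = "inversion", TRA = "translocation",
           BND = "translocation")
  out <- unname(map[vtype])
  ifelse(is.na(out), vtype, out)
}

#' Build a gene x sample recurrence (oncoprint) matrix
#'
#' One matrix cell per (gene, sample) lists the variant categories present,
#' and per-category recurrence counts the samples carrying that category in
#' that gene. Large deletions and duplications are merged across SV and CNV
#' calls before counting (`DEL`/`CNV_LOSS` -> deletion, `DUP`/`CNV_GAIN` ->
#' duplication).
#'
#' @param variants data.frame with `sample`, `gene`, `vtype` (one row per
#'   variant-gene-sample hit; `vtype` in SNV, INDEL, DEL, DUP, INV,
#'   TRA/BND, CNV_LOSS, CNV_GAIN).
#' @param gene_order optional character vector fixing row order (e.g. a
#'   driver-gene list); unlisted genes follow alphabetically.
#' @return list: `matrix` (gene x sample, comma-joined categories, `""` if
#'   none), `recurrence` (data.frame gene / category / n_samples).
#' @export
build_recurrence <- function(variants, gene_order = NULL) {
  if (nrow(variants) == 0) {
    return(list(matrix = matrix(character(), 0, 0),
                recurrence = data.frame(gene = character(),
                                        category = character(),
                                        n_samples = integer())))
  }
  v <- variants
  v$category <- .recurrence_category(as.character(v$vtype))
  genes <- sort(unique(v$gene))
  if (!is.null(gene_order)) {
    genes <- c(intersect(gene_order, genes), setdiff(genes, gene_order))
  }
  samples <- sort(unique(v$sample))
  m <- matrix("", nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  agg <- unique(v[, c("gene", "sample", "category")])
  for (i in seq_len(nrow(agg))) {
    cur <- m[agg$gene[i], agg$sample[i]]
    m[agg$gene[i], agg$sample[i]] <-
      if (cur == "") agg$category[i] else paste(cur, agg$category[i],
                                                sep = ",")
  }
  rec <- stats::aggregate(sample ~ gene + category, data = agg,
                          FUN = function(s) length(unique(s)))
  names(rec)[3] <- "n_samples"
  rec <- rec[order(match(rec$gene, genes), rec$category), ]
  rownames(rec) <- NULL
  list(matrix = m, recurrence = rec)
}
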