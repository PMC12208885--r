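#' Write a droplet dataset to MatrixMarket + TSV files
#'
#' Layout: `hashtag_counts.mtx` (droplets x hashtags, sparse MatrixMarket),
#' `droplets.tsv` (droplet metadata), `hashtags.tsv` (feature names), and,
#' when truth labels are present, `truth.tsv`.
#'
#' @param dataset a [simulate_droplets()] result (or compatible list).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_droplet_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(dataset$hashtag_counts, sparse = TRUE),
                  file.path(dir, "hashtag_counts.mtx"))
  utils::write.table(dataset$droplets, file.path(dir, "droplets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(hashtag = colnames(dataset$hashtag_counts)),
    file.path(dir, "hashtags.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(dataset$truth)) {
    utils::write.table(dataset$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a droplet dataset written by [write_droplet_dataset()]
#'
#' @param dir directory containing the files.
#' @return list with `droplets`, `hashtag_counts`, and `truth` when
#'   present.
#' @export
read_droplet_dataset <- function(dir) {
  counts <- as.matrix(Matrix::readMM(file.path(dir, "hashtag_counts.mtx")))
  droplets <- utils::read.delim(file.path(dir, "droplets.tsv"),
                                stringsAsFactors = FALSE)
  hashtags <- utils::read.delim(file.path(dir, "hashtags.tsv"),
                                stringsAsFactors = FALSE)
  dimnames(counts) <- list(droplets$droplet_id, hashtags$hashtag)
  storage.mode(counts) <- "integer"
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    utils::read.delim(truth_path, stringsAsFactors = FALSE)
  }
  structure(list(droplets = droplets, hashtag_counts = counts,
                 truth = truth), class = "droplet_dataset")
}

#' Write simulated SNV records as a minimal VCF 4.2 file
#'
#' Serializes the simulator's caller-like SNV records with their filter
#' fields in INFO so they round-trip through standard VCF readers. This is
#' output serialization for synthetic records only; real VCFs should be
#' read with a dedicated reader (see [read_snv_vcf()]).
#'
#' @param snv data.frame from [simulate_somatic_calls()] (`snv` or
#'   `strelka` element).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(snv, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=leukotrace-simulator",
    "##INFO=<ID=NALOD,Number=1,Type=Float,Description=\"Negative log10 odds of artifact in normal\">",
    "##INFO=<ID=TLOD,Number=1,Type=Float,Description=\"Log10 likelihood ratio of variant existence\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Tumor allele fraction\">",
    "##INFO=<ID=ALTT,Number=1,Type=Integer,Description=\"Alt reads tumor\">",
    "##INFO=<ID=ALTN,Number=1,Type=Integer,Description=\"Alt reads normal\">",
    "##INFO=<ID=SBF,Number=1,Type=Integer,Description=\"Alt reads forward strand\">",
    "##INFO=<ID=SBR,Number=1,Type=Integer,Description=\"Alt reads reverse strand\">",
    "##INFO=<ID=MBQ,Number=1,Type=Float,Description=\"Median base quality of alt\">",
    "##INFO=<ID=MMQ,Number=1,Type=Float,Description=\"Median mapping quality of alt\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  num <- function(x) ifelse(is.na(x), ".",
                            formatC(x, format = "g", digits = 10))
  has <- function(col) col %in% names(snv)
  info <- sprintf(
    "NALOD=%s;TLOD=%s;AF=%s;ALTT=%s;ALTN=%s;SBF=%s;SBR=%s;MBQ=%s;MMQ=%s",
    if (has("nalod")) num(snv$nalod) else ".",
    if (has("tlod")) num(snv$tlod) else ".",
    if (has("af_tumor")) num(snv$af_tumor) else ".",
    if (has("alt_reads_tumor")) num(snv$alt_reads_tumor) else ".",
    if (has("alt_reads_normal")) num(snv$alt_reads_normal) else ".",
    if (has("alt_fwd")) num(snv$alt_fwd) else ".",
    if (has("alt_rev")) num(snv$alt_rev) else ".",
    if (has("median_bq_alt")) num(snv$median_bq_alt) else ".",
    if (has("median_mq_alt")) num(snv$median_mq_alt) else ".")
  filt <- if (has("filter_field")) as.character(snv$filter_field) else "."
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                  snv$chrom, snv$pos, snv$ref, snv$alt, filt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read SNV records from a VCF into the filter battery's layout
#'
#' Uses vcfR to parse the file; INFO keys are configurable so different
#' caller dialects can be mapped onto the fields the filters consume.
#'
#' @param path VCF file.
#' @param info_map named character vector mapping record columns to INFO
#'   keys; defaults match [write_snv_vcf()].
#' @return data.frame usable by [filter_snv_mutect()] /
#'   [filter_snv_strelka()].
#' @export
read_snv_vcf <- function(path, info_map = c(
    nalod = "NALOD", tlod = "TLOD", af_tumor = "AF",
    alt_reads_tumor = "ALTT", alt_reads_normal = "ALTN",
    alt_fwd = "SBF", alt_rev = "SBR",
    median_bq_alt = "MBQ", median_mq_alt = "MMQ")) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF files requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  out <- data.frame(chrom = fx$CHROM, pos = as.integer(fx$POS),
                    ref = fx$REF, alt = fx$ALT,
                    filter_field = fx$FILTER, stringsAsFactors = FALSE)
  for (col in names(info_map)) {
    val <- vcfR::extract.info(v, element = info_map[[col]])
    out[[col]] <- suppressWarnings(as.numeric(val))
  }
  out
}

#' Write CNV segments or any record table as TSV
#'
#' @param x data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
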