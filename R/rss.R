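#' Construct a motif set for RSS scanning
#'
#' Defaults to the consensus recombination-signal-sequence pair: the
#' heptamer CACAGTG and the nonamer ACAAAAACC. Additional motifs (e.g. a
#' top-motif list from a cryptic-RSS screen) can be supplied as a named
#' character vector or read from a file with [read_motifs()].
#'
#' @param motifs named character vector of uppercase A/C/G/T sequences;
#'   names are motif ids.
#' @return a `motif_set` named character vector.
#' @export
motif_set <- function(motifs = c(RSS_heptamer = "CACAGTG",
                                 RSS_nonamer = "ACAAAAACC")) {
  motifs <- toupper(motifs)
  if (length(motifs) == 0 || any(nchar(motifs) == 0) ||
      any(grepl("[^ACGT]", motifs))) {
    stop("motifs must be nonempty sequences over A/C/G/T", call. = FALSE)
  }
  if (is.null(names(motifs)) || any(names(motifs) == "")) {
    names(motifs) <- paste0("motif", seq_along(motifs))
  }
  structure(motifs, class = c("motif_set", "character"))
}

#' Read motifs from a plain-text or FASTA file
#'
#' @param path one motif per line (`id<TAB>sequence` or bare sequence), or
#'   a FASTA file.
#' @return a [motif_set()].
#' @export
read_motifs <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    ss <- Biostrings::readDNAStringSet(path)
    return(motif_set(stats::setNames(as.character(ss), names(ss))))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  has_id <- lengths(parts) >= 2
  seqs <- vapply(parts, function(p) trimws(p[[length(p)]]), character(1))
  ids <- ifelse(has_id, vapply(parts, function(p) trimws(p[[1]]),
                               character(1)), "")
  names(seqs) <- ifelse(ids == "", paste0("motif", seq_along(seqs)), ids)
  motif_set(seqs)
}

#' Extract flanking windows around SV breakends
#'
#' For a breakend at 1-based position p on a contig of length L, the window
#' is `[max(0, p - 1 - flank), min(L, p + flank))` in 0-based half-open
#' coordinates — up to `2*flank + 1` bases (the breakend base included),
#' clipped at contig edges. Both breakends of each record produce windows.
#'
#' @param svs data.frame with `id`, `chrom1`, `pos1`, `chrom2`, `pos2`
#'   (1-based breakend positions).
#' @param genome a named `DNAStringSet` (or named character vector of
#'   sequences).
#' @param flank flank size in bp (default 100).
#' @return data.frame: `sv_id`, `breakend` (1 or 2), `contig`, `start`,
#'   `end` (0-based half-open), `sequence` (uppercase).
#' @export
extend_breakends <- function(svs, genome, flank = 100L) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(toupper(genome))
  }
  flank <- .assert_count(flank, "flank")
  one <- function(sv_id, contig, pos) {
    if (!contig %in% names(genome)) {
      stop(sprintf("contig '%s' not in genome", contig), call. = FALSE)
    }
    L <- length(genome[[contig]])
    if (pos < 1 || pos > L) {
      stop(sprintf("breakend position %d outside contig '%s' (1..%d)",
                   pos, contig, L), call. = FALSE)
    }
    s <- max(0L, pos - 1L - flank)
    e <- min(L, pos + flank)
    seqc <- toupper(as.character(Biostrings::subseq(genome[[contig]],
                                                    s + 1L, e)))
    data.frame(sv_id = sv_id, contig = contig, start = s, end = e,
               sequence = seqc, stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(svs)), function(i) {
    w1 <- one(svs$id[i], svs$chrom1[i], svs$pos1[i])
    w1$breakend <- 1L
    w2 <- one(svs$id[i], svs$chrom2[i], svs$pos2[i])
    w2$breakend <- 2L
    rbind(w1, w2)
  })
  out <- do.call(rbind, rows)
  out[, c("sv_id", "breakend", "contig", "start", "end", "sequence")]
}

#' Scan windows for exact motif occurrences on both strands
#'
#' Every position where a motif matches the plus strand of a window yields
#' a `+` hit; every position where it matches the reverse complement yields
#' a `-` hit, reported in plus-strand coordinates. Overlapping occurrences
#' are all reported, matching is case-insensitive, and `N` matches nothing.
#' Exact matching is delegated to Biostrings.
#'
#' @param windows data.frame from [extend_breakends()] (needs `sv_id`,
#'   `breakend`, `contig`, `start`, `sequence`).
#' @param motifs a [motif_set()].
#' @param both_strands scan the minus strand too (default TRUE).
#' @return data.frame: `sv_id`, `breakend`, `motif_id`, `contig`,
#'   `hit_start` (0-based plus-strand), `strand`, `matched_seq`.
#' @export
scan_exact <- function(windows, motifs, both_strands = TRUE) {
  stopifnot(inherits(motifs, "motif_set"))
  hits <- list()
  for (i in seq_len(nrow(windows))) {
    subj <- Biostrings::DNAString(toupper(windows$sequence[i]))
    for (mi in seq_along(motifs)) {
      strands <- if (both_strands) c("+", "-") else "+"
      for (strand in strands) {
        pat <- if (strand == "+") motifs[[mi]] else
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(motifs[[mi]])))
        mt <- Biostrings::matchPattern(pat, subj, fixed = TRUE)
        if (length(mt) == 0) next
        hits[[length(hits) + 1L]] <- data.frame(
          sv_id = windows$sv_id[i], breakend = windows$breakend[i],
          motif_id = names(motifs)[mi], contig = windows$contig[i],
          hit_start = windows$start[i] + BiocGenerics::start(mt) - 1L,
          strand = strand,
          matched_seq = as.character(mt),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(sv_id = character(), breakend = integer(),
                      motif_id = character(), contig = character(),
                      hit_start = integer(), strand = character(),
                      matched_seq = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Annotate SV records with their RSS motif hits
#'
#' Joins motif hits back onto their source SVs; SVs without hits are kept
#' with empty hit lists so the output is complete over the input.
#'
#' @param hits data.frame from [scan_exact()].
#' @param svs SV data.frame with `id` and optionally `affected_genes`.
#' @return data.frame, one row per SV: `sv_id`, `n_hits`, `hits_breakend1`,
#'   `hits_breakend2` (semicolon lists `motif@start(strand)`),
#'   `affected_genes`.
#' @export
annotate_hits <- function(hits, svs) {
  orphan <- setdiff(hits$sv_id, svs$id)
  if (length(orphan)) {
    stop(sprintf("hits reference unknown SV id(s): %s",
                 paste(unique(orphan), collapse = ", ")), call. = FALSE)
  }
  fmt <- function(h) {
    if (nrow(h) == 0) return("")
    paste(sprintf("%s@%d(%s)", h$motif_id, h$hit_start, h$strand),
          collapse = ";")
  }
  rows <- lapply(seq_len(nrow(svs)), function(i) {
    h <- hits[hits$sv_id == svs$id[i], , drop = FALSE]
    data.frame(
      sv_id = svs$id[i], n_hits = nrow(h),
      hits_breakend1 = fmt(h[h$breakend == 1L, , drop = FALSE]),
      hits_breakend2 = fmt(h[h$breakend == 2L, , drop = FALSE]),
      affected_genes = if ("affected_genes" %in% names(svs))
        svs$affected_genes[i] else NA_character_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
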