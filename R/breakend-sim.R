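#' Configuration for the breakend-genome simulator
#'
#' Builds a random genome at a stated GC content, places SV breakends on
#' it, and plants motif sequences at exact offsets from chosen breakends
#' (reverse-complemented for minus-strand plants) so scanner recovery can
#' be checked against known truth.
#'
#' @param contig_lengths named integer vector (contig name -> length).
#' @param n_breakends number of SV records (two breakends each).
#' @param planted_motifs data.frame with `motif` (A/C/G/T string), `offset`
#'   (signed bp relative to a breakend position; must fit inside the
#'   scan window), `strand` (`"+"`/`"-"`), and optionally `breakend_index`
#'   (which breakend receives the plant; recycled over breakends when
#'   absent).
#' @param background_gc GC fraction of the random background (default 0.42).
#' @param flank scan flank the plants must respect (default 100).
#' @param seed integer seed.
#' @return a `breakend_sim_config` list.
#' @export
breakend_sim_config <- function(contig_lengths = c(chrA = 100000L,
                                                   chrB = 100000L),
                                n_breakends = 10L,
                                planted_motifs = NULL,
                                background_gc = 0.42, flank = 100L,
                                seed = 1L) {
  stopifnot(!is.null(names(contig_lengths)), all(contig_lengths > 0))
  flank <- .assert_count(flank, "flank")
  if (!is.null(planted_motifs)) {
    stopifnot(all(c("motif", "offset", "strand") %in% names(planted_motifs)))
    if (any(grepl("[^ACGT]", toupper(planted_motifs$motif)))) {
      stop("planted motifs must be A/C/G/T", call. = FALSE)
    }
    too_far <- abs(planted_motifs$offset) +
      nchar(planted_motifs$motif) - 1 > flank
    if (any(too_far)) {
      stop("planted offset(s) fall outside the +/-flank scan window",
           call. = FALSE)
    }
  }
  structure(list(contig_lengths = contig_lengths,
                 n_breakends = .assert_count(n_breakends, "n_breakends", 1L),
                 planted_motifs = planted_motifs,
                 background_gc = .assert_fraction(background_gc,
                                                  "background_gc"),
                 flank = flank,
                 seed = .assert_count(seed, "seed")),
            class = "breakend_sim_config")
}

#' Simulate a genome with SV breakends and planted RSS motifs
#'
#' The background is i.i.d. A/C/G/T at the configured GC fraction.
#' Breakend positions are drawn away from contig edges so full windows
#' exist, then each planted motif is written into the plus strand at
#' `position + offset` (its reverse complement when `strand == "-"`). The
#' truth table records each plant's expected hit coordinates.
#'
#' @param cfg a [breakend_sim_config()].
#' @return list: `genome` (named character vector of contig sequences),
#'   `svs` (data.frame `id`, `chrom1`, `pos1`, `chrom2`, `pos2`, `svtype`,
#'   `filter_field`, `pr_alt`, `sr_alt`, `affected_genes`), `truth`
#'   (data.frame `sv_id`, `breakend`, `motif`, `offset`, `strand`,
#'   `hit_start` 0-based plus-strand, `planted_seq`).
#' @export
simulate_breakend_genome <- function(cfg) {
  stopifnot(inherits(cfg, "breakend_sim_config"))
  set.seed(cfg$seed)
  gc <- cfg$background_gc
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  genome <- vapply(cfg$contig_lengths, function(L) {
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, character(1))

  margin <- cfg$flank + 50L
  draw_pos <- function() {
    ctg <- sample(names(genome), 1L)
    L <- cfg$contig_lengths[[ctg]]
    if (L <= 2L * margin) stop("contig too short to host windows",
                               call. = FALSE)
    list(contig = ctg, pos = sample(seq(margin, L - margin), 1L))
  }
  nb <- cfg$n_breakends
  b1 <- replicate(nb, draw_pos(), simplify = FALSE)
  b2 <- replicate(nb, draw_pos(), simplify = FALSE)
  svs <- data.frame(
    id = sprintf("SV%04d", seq_len(nb)),
    chrom1 = vapply(b1, `[[`, character(1), "contig"),
    pos1 = vapply(b1, `[[`, numeric(1), "pos"),
    chrom2 = vapply(b2, `[[`, character(1), "contig"),
    pos2 = vapply(b2, `[[`, numeric(1), "pos"),
    svtype = sample(c("DEL", "DUP", "INV", "TRA"), nb, TRUE),
    filter_field = "PASS",
    pr_alt = sample(3:10, nb, TRUE), sr_alt = sample(2:10, nb, TRUE),
    affected_genes = sprintf("Gene%02d", sample.int(30, nb, TRUE)),
    stringsAsFactors = FALSE)

  truth <- data.frame(sv_id = character(), breakend = integer(),
                      motif = character(), offset = integer(),
                      strand = character(), hit_start = integer(),
                      planted_seq = character(), stringsAsFactors = FALSE)
  pm <- cfg$planted_motifs
  if (!is.null(pm) && nrow(pm) > 0) {
    for (i in seq_len(nrow(pm))) {
      bidx <- if ("breakend_index" %in% names(pm)) pm$breakend_index[i] else
        ((i - 1L) %% (2L * nb)) + 1L
      sv_row <- ((bidx - 1L) %/% 2L) + 1L
      side <- ((bidx - 1L) %% 2L) + 1L
      contig <- if (side == 1L) svs$chrom1[sv_row] else svs$chrom2[sv_row]
      pos <- if (side == 1L) svs$pos1[sv_row] else svs$pos2[sv_row]
      motif <- toupper(pm$motif[i])
      planted <- if (pm$strand[i] == "-") revcomp_chr(motif) else motif
      # 0-based plus-strand start of the planted sequence
      start0 <- pos - 1L + pm$offset[i]
      substr(genome[[contig]], start0 + 1L,
             start0 + nchar(planted)) <- planted
      truth <- rbind(truth, data.frame(
        sv_id = svs$id[sv_row], breakend = side, motif = motif,
        offset = pm$offset[i], strand = pm$strand[i],
        hit_start = start0, planted_seq = planted,
        stringsAsFactors = FALSE))
    }
  }
  list(genome = genome, svs = svs, truth = truth)
}

#' Write a genome to an uncompressed FASTA file
#'
#' @param genome named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
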