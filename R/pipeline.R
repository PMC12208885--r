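# Config schema: every default is either a value printed in the methods
# this package implements or a documented package design choice (see the
# methods vignette).
.config_schema <- function() {
  list(
    root_seed = 1L,
    out_dir = NULL,
    stages = c("droplets", "demux"),
    log_level = "info",
    droplets = list(n_hashtags = 6L, n_singlets_per_tag = 300L,
                    n_doublets = 100L, n_empty = 5000L,
                    ambient_log_mean = 2, ambient_log_sd = 0.5,
                    signal_shift = 4),
    demux = list(n_min = 100L, mad_mult = 2, max_mito = 0.25,
                 sigma_floor = 1e-8, nstart = 100L, clamp = c(3, 5)),
    qc = list(max_mito = 0.01, min_counts = 500L, max_counts = 30000L,
              min_genes = 400L, max_genes = 6000L, min_cells_per_gene = 10L),
    regulons = list(n_per_type = 500L, r_min = 0.3, min_targets = 10L,
                    jitter = 0.01, n_splits = 10L, train_frac = 0.7,
                    alpha = 0.001, n_reps = 100L, r2_min = 0.5, q = 0.05),
    variants = list(n_snv = 100L, n_sv = 50L, n_cnv = 50L),
    rss = list(flank = 100L, n_breakends = 10L, background_gc = 0.42)
  )
}

.merge_config <- function(schema, user, path = "") {
  unknown <- setdiff(names(user), names(schema))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s",
                 paste0(path, unknown, collapse = ", ")), call. = FALSE)
  }
  for (k in names(user)) {
    if (is.list(schema[[k]]) && !is.null(names(schema[[k]]))) {
      if (!is.list(user[[k]])) {
        stop(sprintf("config key '%s%s' must be a mapping", path, k),
             call. = FALSE)
      }
      schema[[k]] <- .merge_config(schema[[k]], user[[k]],
                                   paste0(path, k, "."))
    } else {
      schema[k] <- list(user[[k]])  # preserves explicit NULLs
    }
  }
  schema
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, checks every key against the schema (unknown keys are
#' an error naming the key), and fills unset keys with defaults. An empty
#' file yields the all-defaults configuration.
#'
#' @param path YAML file; `NULL` for pure defaults.
#' @return a `run_config` list.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                                 call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  cfg <- .merge_config(.config_schema(), user)
  class(cfg) <- "run_config"
  cfg
}

#' Serialize a resolved configuration to YAML
#'
#' @param cfg a `run_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run selected pipeline stages end to end
#'
#' Executes the configured stages in dependency order on synthetic inputs
#' (`droplets` then `demux`; `variants`; `rss`), fanning the root seed out
#' into per-stage streams. A manifest records seeds, per-stage summaries
#' and package version; when `out_dir` is set, primary outputs, the
#' resolved config and the manifest are written there.
#'
#' @param cfg a [load_config()] result.
#' @return the manifest, invisibly a list with one entry per executed
#'   stage.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_config(cfg, file.path(out_dir, "config_resolved.yaml"))
  }
  manifest <- list(root_seed = cfg$root_seed,
                   package_version = as.character(
                     utils::packageVersion("leukotrace")),
                   stages = list())
  state <- list()

  if ("droplets" %in% cfg$stages) {
    seed <- derive_seed(cfg$root_seed, "droplets")
    dcfg <- do.call(droplet_sim_config, c(cfg$droplets, list(seed = seed)))
    state$droplets <- simulate_droplets(dcfg)
    manifest$stages$droplets <- list(
      seed = seed, n_droplets = nrow(state$droplets$droplets))
    if (!is.null(out_dir)) {
      write_droplet_dataset(state$droplets, file.path(out_dir, "droplets"))
    }
  }
  if ("demux" %in% cfg$stages) {
    if (is.null(state$droplets)) {
      stop("demux stage needs the droplets stage", call. = FALSE)
    }
    seed <- derive_seed(cfg$root_seed, "demux")
    res <- do.call(demux_hashtags,
                   c(list(dataset = state$droplets, seed = seed),
                     cfg$demux))
    truth <- state$droplets$truth
    merged <- merge(res$assignments, truth, by = "droplet_id")
    sing <- merged[merged$truth == "singlet", ]
    dbl <- merged[merged$truth == "doublet", ]
    acc <- mean(sing$assignment == paste0("HTO", sing$tag1))
    manifest$stages$demux <- list(
      seed = seed, K = res$K, q99 = res$q99, cutoff = res$cutoff,
      n_empty = res$background$n_empty,
      singlet_recovery = acc,
      doublet_flag_rate = mean(dbl$assignment == "doublet"))
    state$demux <- res
    if (!is.null(out_dir)) {
      write_tsv(res$assignments, file.path(out_dir, "assignments.tsv"))
      jsonlite::write_json(manifest$stages$demux,
                           file.path(out_dir, "demux_report.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  if ("variants" %in% cfg$stages) {
    seed <- derive_seed(cfg$root_seed, "variants")
    vcfg <- do.call(variant_sim_config, c(cfg$variants, list(seed = seed)))
    calls <- simulate_somatic_calls(vcfg)
    vm <- filter_snv_mutect(calls$snv)
    vs <- filter_sv(calls$sv)
    vc <- filter_cnv(calls$cnv)
    manifest$stages$variants <- list(
      seed = seed,
      snv_pass = sum(vm$pass), sv_pass = sum(vs$pass),
      cnv_pass = sum(vc$pass),
      truth_agreement = mean(c(vm$pass == calls$snv$truth_pass,
                               vs$pass == calls$sv$truth_pass,
                               vc$pass == calls$cnv$truth_pass)))
    state$variants <- calls
    if (!is.null(out_dir)) {
      write_snv_vcf(calls$snv, file.path(out_dir, "snv.vcf"))
      write_tsv(cbind(calls$cnv, vc), file.path(out_dir, "cnv_verdicts.tsv"))
    }
  }
  if ("rss" %in% cfg$stages) {
    seed <- derive_seed(cfg$root_seed, "breakends")
    plants <- data.frame(motif = "CACAGTG",
                         offset = c(10L, -20L), strand = c("+", "-"))
    bcfg <- breakend_sim_config(
      n_breakends = cfg$rss$n_breakends,
      planted_motifs = plants,
      background_gc = cfg$rss$background_gc,
      flank = cfg$rss$flank, seed = seed)
    sim <- simulate_breakend_genome(bcfg)
    wins <- extend_breakends(sim$svs, sim$genome, flank = cfg$rss$flank)
    hits <- scan_exact(wins, motif_set())
    ann <- annotate_hits(hits, sim$svs)
    recov <- all(sim$truth$hit_start %in% hits$hit_start)
    manifest$stages$rss <- list(seed = seed, n_hits = nrow(hits),
                                planted_recovered = recov)
    state$rss <- ann
    if (!is.null(out_dir)) {
      write_genome_fasta(sim$genome, file.path(out_dir, "genome.fasta"))
      write_tsv(ann, file.path(out_dir, "rss_annotated.tsv"))
    }
  }

  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(manifest)
}
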