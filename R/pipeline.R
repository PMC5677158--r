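#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_simulate()] and
#' [run_analyze()]. Any element can be overridden via `...` (nested lists
#' are merged). A configuration can also be stored as YAML and loaded with
#' [read_config()].
#'
#' @param out_dir Output directory.
#' @param ... Overrides, e.g. `sim = list(n_insertions = 200)`.
#' @return A named list of class `cc_config`.
#' @export
cc_config <- function(out_dir = ".", ...) {
  base <- list(
    out_dir = out_dir,
    construct = "construct",
    genome = list(n_chrom = 1L, lengths = 100000L, gc = 0.38),
    features = list(counts = list(ACS_CONFIRMED_LIKELY = 20L),
                    spacing_min = 2000L),
    timing = list(origin_spacing = 50000L, fork_rate = 1000, t0 = 10,
                  t_max = 70),
    sim = list(n_insertions = 1000L, background_rate = 1,
               feature_enrichment = list(), tau = Inf,
               pcr_meanlog = 2.3, pcr_sdlog = 0.8),
    reads = list(read_length = 50L, tag = "TGTTGGAATAGCAAGGCAGT",
                 max_mismatch = 0L, min_frag = 18L),
    windows = list(width = 5, bin = 500L),
    profile = list(flank = 1000L, bin_width = 100L, t_filter = 30),
    paths = list(genome = "genome.fa", reads = "reads.fastq",
                 truth = "truth.tsv", features = "features.bed",
                 timing = "timing.bedgraph"),
    seed = 1L)
  over <- list(...)
  structure(utils::modifyList(base, over), class = "cc_config")
}

#' @rdname cc_config
#' @param path Path to a YAML configuration file.
#' @export
read_config <- function(path) {
  over <- yaml::read_yaml(path)
  do.call(cc_config, c(list(out_dir = over$out_dir %||% "."),
                       over[setdiff(names(over), "out_dir")]))
}

#' Reproducible hash of the analysis-relevant configuration
#'
#' @param config A `cc_config` list.
#' @return A character hash that changes iff any analysis-relevant parameter
#'   changes (the output directory is excluded).
#' @export
config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "out_dir")])
}

cfg_path <- function(config, key) file.path(config$out_dir,
                                            config$paths[[key]])

#' Simulate a full calling-cards input bundle
#'
#' Generates (deterministically for a fixed `seed`) a genome FASTA, feature
#' BED, timing bedGraph, ground-truth TSV and junction-read FASTQ under the
#' configured model, plus a `manifest.json` listing the outputs.
#'
#' @param config A `cc_config` list.
#' @return Invisibly, a manifest list (files, counts, config hash).
#' @export
run_simulate <- function(config = cc_config()) {
  if (!dir.exists(config$out_dir) &&
      !dir.create(config$out_dir, recursive = TRUE)) {
    abort_io(sprintf("cannot create output directory '%s'", config$out_dir))
  }
  g <- config$genome
  genome <- sim_genome(g$n_chrom, g$lengths, g$gc, seed = config$seed)
  sizes <- chrom_sizes(genome)
  features <- sim_features(genome, config$features$counts,
                           spacing_min = config$features$spacing_min,
                           seed = config$seed + 1L)
  tm <- config$timing
  origins <- purrr::imap(as.list(sizes), function(L, ch) {
    tibble::tibble(chrom = ch,
                   pos = seq.int(tm$origin_spacing %/% 2L, L - 1L,
                                 by = tm$origin_spacing))
  }) %>% dplyr::bind_rows()
  timing <- sim_timing(genome, origins, fork_rate = tm$fork_rate,
                       t0 = tm$t0, t_max = tm$t_max)
  params <- sim_params(
    n_insertions = config$sim$n_insertions,
    background_rate = config$sim$background_rate,
    feature_enrichment = config$sim$feature_enrichment,
    tau = config$sim$tau %||% Inf,
    pcr_meanlog = config$sim$pcr_meanlog, pcr_sdlog = config$sim$pcr_sdlog,
    read_length = config$reads$read_length, tag = config$reads$tag,
    seed = config$seed + 2L)
  truth <- sim_insertions(genome, features, timing, params)
  reads <- sim_library(genome, truth, params)

  write_genome(genome, cfg_path(config, "genome"))
  write_features(features, cfg_path(config, "features"))
  write_timing(timing, cfg_path(config, "timing"))
  write_truth(truth, cfg_path(config, "truth"))
  write_fastq(reads, cfg_path(config, "reads"))
  manifest <- list(
    files = lapply(config$paths, function(p) file.path(config$out_dir, p)),
    n_insertions = nrow(truth),
    reads_emitted = attr(reads, "reads_emitted"),
    reads_dropped = attr(reads, "reads_dropped"),
    fragments_dropped = attr(reads, "fragments_dropped"),
    config_hash = config_hash(config))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run the full analysis on an input bundle
#'
#' Reads the configured genome/reads/features/timing files, calls insertion
#' events, writes both normalised tracks, timing-window summaries,
#' feature-centred meta-profiles (under the early-replication filter) and a
#' run report. Stages whose inputs are missing are skipped with a warning,
#' so a profile-only or track-only run works from partial inputs.
#'
#' @param config A `cc_config` list.
#' @return Invisibly, the run report list.
#' @export
run_analyze <- function(config = cc_config()) {
  t_start <- Sys.time()
  genome <- read_genome(cfg_path(config, "genome"))
  reads <- read_fastq(cfg_path(config, "reads"))
  mappings <- reads %>%
    trim_junction(tag = config$reads$tag,
                  max_mismatch = config$reads$max_mismatch,
                  min_frag = config$reads$min_frag) %>%
    map_fragments(genome)
  events <- call_insertions(mappings, construct = config$construct)
  write_insertions(events, file.path(config$out_dir, "insertions.tsv"))
  jsonlite::write_json(as.list(qc_report(events)),
                       file.path(config$out_dir, "qc.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  rpm <- NULL
  if (total_aligned_reads(events) > 0) {
    rpm <- rpm_track(events)
    write_bedgraph(rpm, file.path(config$out_dir, "rpm.bedgraph"))
  }
  uniq <- unique_track(events)
  write_bedgraph(uniq, file.path(config$out_dir, "unique.bedgraph"))

  timing <- NULL
  timing_path <- cfg_path(config, "timing")
  if (file.exists(timing_path)) {
    timing <- read_timing(timing_path)
    ws <- window_signal(uniq, timing, width = config$windows$width,
                        bin = config$windows$bin)
    readr::write_tsv(dplyr::select(ws, -"values"),
                     file.path(config$out_dir, "windows.tsv"))
  } else {
    warn("timing profile missing: skipping window analysis")
  }

  profiles <- list()
  features_path <- cfg_path(config, "features")
  if (file.exists(features_path)) {
    features <- read_features(features_path)
    ev_prof <- events
    if (!is.null(timing)) {
      ev_prof <- filter_by_timing(events, timing,
                                  t_max = config$profile$t_filter)
    }
    for (cls in unique(features$class)) {
      sites <- dplyr::filter(features, .data$class == cls)
      track <- if (!is.null(rpm)) {
        rpm_track(ev_prof, total = total_aligned_reads(events))
      } else unique_track(ev_prof)
      prof <- feature_profile(track, sites, flank = config$profile$flank,
                              bin_width = config$profile$bin_width,
                              sizes = chrom_sizes(genome))
      readr::write_tsv(prof, file.path(
        config$out_dir, sprintf("profile_%s.tsv", cls)))
      profiles[[cls]] <- prof
    }
  } else {
    warn("feature annotation missing: skipping meta-profiles")
  }

  report <- list(
    construct = config$construct,
    config_hash = config_hash(config),
    version = as.character(utils::packageVersion("callingcardr")),
    qc = as.list(qc_report(events)),
    n_events = nrow(events),
    total_aligned_reads = total_aligned_reads(events),
    stages = list(windows = !is.null(timing),
                  profiles = length(profiles) > 0),
    wall_clock_sec = as.numeric(difftime(Sys.time(), t_start,
                                         units = "secs")))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}
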