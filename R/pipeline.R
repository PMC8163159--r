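# End-to-end orchestration: cluster -> sprinzl -> profile -> call ->
# classify -> timecourse, with a validated configuration pinned to the
# published operating point and a machine-readable run manifest.

#' Pipeline configuration
#'
#' All tunables with defaults at the published operating point. Every value
#' is validated on construction; the object serialises losslessly to YAML.
#'
#' @param min_intensity RTa intensity call threshold (fraction).
#' @param min_reads Minimum read support for both callers.
#' @param min_conf_phred Phred-scaled mismatch-confidence threshold.
#' @param error_rate Null per-base mismatch rate for the binomial model.
#' @param tgirt_window TGIRT artifact window (nt, 3' side).
#' @param min_len,max_len Read length retention window (nt).
#' @param qual_cutoff 3'-trimming quality cutoff.
#' @param accuracy_pct Mapping accuracy contract (percent).
#' @param weak_cut Weak/strong arrest-intensity boundary for classification.
#' @param sprinzl_min_score Score floor below which a cluster is unfittable.
#' @return A validated `run_config` list.
#' @export
run_config <- function(min_intensity = 0.20, min_reads = 10,
                       min_conf_phred = 20, error_rate = 0.01,
                       tgirt_window = 3, min_len = 8, max_len = 95,
                       qual_cutoff = 25, accuracy_pct = 80,
                       weak_cut = 0.4, sprinzl_min_score = 60) {
  cfg <- list(
    min_intensity = min_intensity, min_reads = min_reads,
    min_conf_phred = min_conf_phred, error_rate = error_rate,
    tgirt_window = tgirt_window, min_len = min_len, max_len = max_len,
    qual_cutoff = qual_cutoff, accuracy_pct = accuracy_pct,
    weak_cut = weak_cut, sprinzl_min_score = sprinzl_min_score
  )
  stopifnot(
    cfg$min_intensity >= 0, cfg$min_intensity <= 1,
    cfg$min_reads >= 1, cfg$min_conf_phred >= 0,
    cfg$error_rate > 0, cfg$error_rate < 0.5,
    cfg$tgirt_window >= 0, cfg$min_len >= 1,
    cfg$max_len >= cfg$min_len, cfg$qual_cutoff >= 0,
    cfg$accuracy_pct >= 0, cfg$accuracy_pct <= 100,
    cfg$weak_cut > 0, cfg$weak_cut < 1
  )
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML
#'
#' Unknown keys are rejected; listed keys override the defaults
#' (precedence: explicit `...` overrides > file > defaults).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param ... Named overrides applied after the file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path = NULL, ...) {
  vals <- list()
  if (!is.null(path)) {
    vals <- yaml::read_yaml(path)
    unknown <- setdiff(names(vals), names(formals(run_config)))
    if (length(unknown) > 0L) {
      abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
    }
  }
  vals <- modifyList(vals, list(...))
  do.call(run_config, vals)
}

#' Save a run configuration as YAML
#' @param config A `run_config`.
#' @param path Output path.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full pipeline on one or more samples
#'
#' Builds the cluster reference from gene annotations, fits Sprinzl
#' numbering, profiles each sample's alignments, calls and classifies
#' modification sites, and (for multiple samples) aggregates the time
#' course. All outputs are written as TSV under `out_dir`, together with a
#' JSON run manifest (configuration, input checksums, output checksums);
#' reruns on identical inputs produce identical data files.
#'
#' @param genes Gene tibble (or path to a gene annotation TSV).
#' @param samples Tibble with `sample_id`, `time_label`, `sam` (alignment
#'   path) — or a named list of alignment tibbles plus `time_labels`.
#' @param out_dir Output directory.
#' @param config A [run_config()].
#' @param genome_fasta Genome FASTA when `genes` is a TSV without sequences.
#' @param time_labels Named character sample_id -> time label, used when
#'   `samples` is a list of alignment tibbles.
#' @return Invisibly, a list with `clusters`, `sprinzl`, `profiles`,
#'   `calls`, `summary`, `presence`, `correlation`, `manifest`.
#' @export
run_pipeline <- function(genes, samples, out_dir, config = run_config(),
                         genome_fasta = NULL, time_labels = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(genes)) {
    if (!file.exists(genes)) abort(paste0("gene annotation not found: ", genes))
    genes <- read_trna_genes(genes, genome_fasta)
  }
  clusters <- cluster_trnas(genes)
  write_reference(clusters, file.path(out_dir, "reference"))
  smap <- fit_sprinzl(clusters, min_score = config$sprinzl_min_score)
  write_sprinzl(smap, file.path(out_dir, "sprinzl.tsv"))

  if (is.data.frame(samples)) {
    miss <- samples$sam[!file.exists(samples$sam)]
    if (length(miss) > 0L) {
      abort(paste0("alignment file not found: ", paste(miss, collapse = ", ")))
    }
    aln_list <- setNames(lapply(samples$sam, read_alignments),
                         samples$sample_id)
    time_labels <- setNames(samples$time_label, samples$sample_id)
  } else {
    aln_list <- samples
    if (is.null(time_labels)) {
      time_labels <- setNames(names(aln_list), names(aln_list))
    }
  }

  profiles_list <- list()
  calls_list <- list()
  for (sid in names(aln_list)) {
    prof <- build_profiles(aln_list[[sid]], clusters) |>
      label_profiles(smap) |>
      add_rta_intensity()
    calls <- call_sites(
      prof, min_intensity = config$min_intensity,
      min_reads = config$min_reads,
      min_conf_phred = config$min_conf_phred,
      error_rate = config$error_rate, tgirt_window = config$tgirt_window
    ) |>
      classify_calls(weak_cut = config$weak_cut)
    write_profiles(prof, file.path(out_dir,
                                   paste0("profiles_", sid, ".tsv")))
    write_calls(calls, file.path(out_dir, paste0("calls_", sid, ".tsv")),
                file.path(out_dir, paste0("calls_", sid, ".bed")))
    profiles_list[[sid]] <- prof
    calls_list[[sid]] <- calls
  }

  stacked <- bind_samples(profiles_list, calls_list, time_labels)
  summary_tbl <- aggregate_rta_distribution(
    stacked$profiles, min_intensity = config$min_intensity,
    min_reads = config$min_reads
  )
  presence <- presence_matrix(stacked$calls)
  correlation <- expression_rta_correlation(stacked$profiles, stacked$calls)
  write_tsv_stable(as_tibble(summary_tbl),
                   file.path(out_dir, "position_summary.tsv"))
  write_tsv_stable(presence, file.path(out_dir, "presence_matrix.tsv"))
  write_tsv_stable(as_tibble(correlation),
                   file.path(out_dir, "expression_correlation.tsv"))

  manifest <- write_run_manifest(out_dir, config)
  invisible(list(
    clusters = clusters, sprinzl = smap, profiles = stacked$profiles,
    calls = stacked$calls, summary = summary_tbl, presence = presence,
    correlation = correlation, manifest = manifest
  ))
}

write_run_manifest <- function(out_dir, config) {
  outputs <- sort(setdiff(list.files(out_dir, full.names = TRUE),
                          file.path(out_dir, "run_manifest.json")))
  manifest <- list(
    package = "rtamod",
    version = as.character(utils::packageVersion("rtamod")),
    config = unclass(config),
    outputs = lapply(outputs, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  manifest
}
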