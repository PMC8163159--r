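# Candidate modification-site calling at the published operating point:
# misincorporation sites by Phred-scaled binomial confidence (>= 20, >= 10
# reads) and RTa sites by arrest intensity (>= 20%, >= 10 reads), followed by
# the TGIRT artifact filter. Calling is fully deterministic.

#' Phred-scaled misincorporation confidence
#'
#' Confidence that the mismatches at a site exceed random sequencing error:
#' the upper binomial tail P(X >= k | n, error_rate), Phred-scaled
#' (`-10*log10(p)`) and capped at 1000.
#'
#' @param k Mismatch count.
#' @param n Coverage.
#' @param error_rate Null per-base error rate.
#' @return Phred-scaled confidence (vectorised).
#' @export
phred_confidence <- function(k, n, error_rate = 0.01) {
  phred_binom_tail(k, n, error_rate)
}

mismatch_spectrum <- function(profiles) {
  base_cols <- c(A = "n_A", C = "n_C", G = "n_G", T = "n_T")
  spec <- purrr::map(names(base_cols), function(b) {
    x <- profiles[[base_cols[[b]]]]
    ifelse(profiles$ref_base == b | profiles$coverage == 0, 0,
           x / profiles$coverage)
  })
  names(spec) <- paste0("mm_", names(base_cols))
  spec_tbl <- as_tibble(spec)
  dom <- apply(as.matrix(spec_tbl), 1L, function(r) {
    if (all(r == 0)) NA_character_ else c("A", "C", "G", "T")[which.max(r)]
  })
  spec_tbl$dominant_mismatch <- dom
  spec_tbl
}

#' Call misincorporation sites
#'
#' Tests every position against a null model in which mismatches arise
#' independently at `error_rate`; sites are emitted where the Phred-scaled
#' upper binomial tail reaches `min_conf_phred` and coverage reaches
#' `min_reads`. The mismatch spectrum (per-target-base fractions) is
#' recorded with each call.
#'
#' @param profiles A `cluster_profiles` tibble.
#' @param min_conf_phred Confidence threshold (Phred scale).
#' @param min_reads Minimum coverage.
#' @param error_rate Null per-base mismatch rate.
#' @return Tibble of mismatch calls with `confidence_phred`,
#'   `mismatch_fraction`, spectrum columns and `dominant_mismatch`.
#' @export
call_mismatch_sites <- function(profiles, min_conf_phred = 20,
                                min_reads = 10, error_rate = 0.01) {
  stopifnot(error_rate > 0, error_rate < 0.5)
  ann <- profiles |>
    mutate(
      confidence_phred = phred_binom_tail(.data$mismatch_count,
                                          .data$coverage, error_rate),
      mismatch_fraction = ifelse(.data$coverage > 0,
                                 .data$mismatch_count / .data$coverage, 0)
    )
  ann <- bind_cols(ann, mismatch_spectrum(profiles))
  ann |>
    filter(.data$confidence_phred >= min_conf_phred,
           .data$coverage >= min_reads) |>
    mutate(evidence_mismatch = TRUE) |>
    select(dplyr::any_of(c(
      "cluster_id", "position", "sprinzl_label", "ref_base", "coverage",
      "mismatch_count", "mismatch_fraction", "confidence_phred",
      "mm_A", "mm_C", "mm_G", "mm_T", "dominant_mismatch",
      "evidence_mismatch"
    )))
}

#' Call RTa sites
#'
#' Emits position n as a modification signal when the RTa intensity — the
#' fraction of reads covering n+1 that stop there — is at least
#' `min_intensity` and at least `min_reads` reads cover n+1.
#'
#' @param profiles A `cluster_profiles` tibble.
#' @param min_intensity Intensity threshold (fraction).
#' @param min_reads Minimum read support at n+1.
#' @return Tibble of RTa calls with `rta_intensity` and `cov_next`.
#' @export
call_rta_sites <- function(profiles, min_intensity = 0.20, min_reads = 10) {
  with_rta <- if ("rta" %in% names(profiles)) profiles
              else add_rta_intensity(profiles)
  with_rta |>
    filter(!is.na(.data$rta), .data$rta >= min_intensity,
           .data$cov_next >= min_reads) |>
    mutate(evidence_rta = TRUE, rta_intensity = .data$rta) |>
    select(dplyr::any_of(c(
      "cluster_id", "position", "sprinzl_label", "ref_base", "coverage",
      "cov_next", "rta_intensity", "evidence_rta"
    )))
}

#' TGIRT artifact filter
#'
#' The TGIRT enzyme can leave weak secondary arrest signals with a mismatch
#' pattern up to `window` positions before the modification it actually
#' stalls at (before in the direction of reverse transcription, i.e. on the
#' 3' side in mature coordinates). An RTa call at p is suppressed when (a) a
#' call at q exists with `q < p <= q + window`, (b) p's intensity is strictly
#' below q's, and (c) p carries sub-threshold mismatches (mismatches present
#' but below the confident-call threshold). The primary call is never
#' removed.
#'
#' @param rta_calls Output of [call_rta_sites()].
#' @param profiles The `cluster_profiles` the calls came from.
#' @param window Artifact window in nt (3' side of the primary call).
#' @param min_conf_phred,error_rate Parameters of the confident-mismatch
#'   criterion used to decide "sub-threshold".
#' @return `rta_calls` with a logical `suppressed` column.
#' @export
filter_tgirt_artifacts <- function(rta_calls, profiles, window = 3,
                                   min_conf_phred = 20, error_rate = 0.01) {
  mm <- profiles |>
    mutate(
      .conf = phred_binom_tail(.data$mismatch_count, .data$coverage,
                               error_rate),
      .sub_mm = .data$mismatch_count > 0L & .conf < min_conf_phred
    ) |>
    select("cluster_id", "position", ".sub_mm")
  calls <- rta_calls |> left_join(mm, by = c("cluster_id", "position"))
  calls$suppressed <- vapply(seq_len(nrow(calls)), function(i) {
    p <- calls$position[i]
    cl <- calls$cluster_id[i]
    others <- calls[calls$cluster_id == cl &
                      calls$position < p &
                      calls$position >= p - window, , drop = FALSE]
    any(others$rta_intensity > calls$rta_intensity[i]) &&
      isTRUE(calls$.sub_mm[i])
  }, logical(1L))
  calls |> select(-".sub_mm")
}

#' Merge mismatch and RTa evidence into modification calls
#'
#' Union by (cluster, position); both evidence flags are set where both
#' callers fire. Calls suppressed by the TGIRT artifact filter keep their
#' flag and are excluded from reports downstream.
#'
#' @param mismatch_calls From [call_mismatch_sites()].
#' @param rta_calls From [call_rta_sites()], optionally with a `suppressed`
#'   column from [filter_tgirt_artifacts()].
#' @return A `mod_calls` tibble, one row per candidate site.
#' @export
merge_calls <- function(mismatch_calls, rta_calls) {
  mm <- mismatch_calls
  rta <- rta_calls
  if (!"suppressed" %in% names(rta)) rta$suppressed <- FALSE
  key <- c("cluster_id", "position")
  shared <- intersect(setdiff(names(mm), key), setdiff(names(rta), key))
  out <- full_join(mm, rta, by = key, suffix = c("", ".rta"))
  for (col in shared) {
    out[[col]] <- dplyr::coalesce(out[[col]], out[[paste0(col, ".rta")]])
    out[[paste0(col, ".rta")]] <- NULL
  }
  out <- out |>
    mutate(
      evidence_mismatch = !is.na(.data$evidence_mismatch) &
        .data$evidence_mismatch,
      evidence_rta = !is.na(.data$evidence_rta) & .data$evidence_rta,
      suppressed = !is.na(.data$suppressed) & .data$suppressed
    ) |>
    arrange(.data$cluster_id, .data$position)
  stopifnot(all(out$evidence_mismatch | out$evidence_rta))
  class(out) <- c("mod_calls", class(out))
  out
}

#' Call modification sites from profiles (one-step wrapper)
#'
#' Runs the mismatch caller, the RTa caller, the TGIRT artifact filter and
#' evidence merging with the published operating-point defaults.
#'
#' @param profiles A `cluster_profiles` tibble (Sprinzl-labelled or not).
#' @param min_intensity,min_reads,min_conf_phred,error_rate,tgirt_window
#'   Operating-point parameters; see the individual callers.
#' @return A `mod_calls` tibble.
#' @export
call_sites <- function(profiles, min_intensity = 0.20, min_reads = 10,
                       min_conf_phred = 20, error_rate = 0.01,
                       tgirt_window = 3) {
  mm <- call_mismatch_sites(profiles, min_conf_phred = min_conf_phred,
                            min_reads = min_reads, error_rate = error_rate)
  rta <- call_rta_sites(profiles, min_intensity = min_intensity,
                        min_reads = min_reads)
  rta <- filter_tgirt_artifacts(rta, profiles, window = tgirt_window,
                                min_conf_phred = min_conf_phred,
                                error_rate = error_rate)
  merge_calls(mm, rta)
}

#' Write calls as TSV and BED
#'
#' The BED uses 0-based half-open intervals on the cluster references with
#' `score = round(100 * rta_intensity)` (0 where only mismatch evidence
#' exists). Suppressed calls are not written.
#'
#' @param calls A `mod_calls` tibble.
#' @param tsv_path,bed_path Output paths (either may be `NULL`).
#' @return Invisibly, the written paths.
#' @export
write_calls <- function(calls, tsv_path = NULL, bed_path = NULL) {
  emitted <- calls |> filter(!.data$suppressed)
  if (!is.null(tsv_path)) write_tsv_stable(as_tibble(emitted), tsv_path)
  if (!is.null(bed_path)) {
    bed <- emitted |>
      mutate(
        chromStart = .data$position - 1L,
        chromEnd = .data$position,
        name = paste0(.data$cluster_id, ":", .data$position),
        score = as.integer(round(100 * dplyr::coalesce(.data$rta_intensity,
                                                       0))),
        strand = "+"
      ) |>
      select("cluster_id", "chromStart", "chromEnd", "name", "score",
             "strand")
    readr::write_tsv(bed, bed_path, col_names = FALSE, progress = FALSE)
  }
  invisible(c(tsv = tsv_path, bed = bed_path))
}
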