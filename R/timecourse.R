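# Aggregation across developmental time points: per-Sprinzl-position RTa
# summaries, presence/absence dynamics of modified clusters, the
# expression-vs-RTa correlation check, and per-cluster grid reports.

# Canonical ordering of Sprinzl labels: numeric prefix first, insertion
# suffix after the parent position ("17" < "17a" < "18"); variable-loop
# e-positions sort between 45 and 46.
sprinzl_order_key <- function(labels) {
  num <- suppressWarnings(as.numeric(sub("^([0-9]+).*", "\\1", labels)))
  rest <- sub("^[0-9]+", "", labels)
  e_idx <- grepl("^e[0-9]+$", labels)
  num[e_idx] <- 45.5
  rest[e_idx] <- labels[e_idx]
  letters_part <- gsub("[0-9]+", "", rest)
  digits_part <- suppressWarnings(
    as.integer(sub("^[^0-9]*", "", rest))
  )
  digits_part[is.na(digits_part)] <- 0L
  order(num, letters_part, digits_part)
}

#' Sort Sprinzl labels into canonical order
#' @param labels Character vector of Sprinzl labels.
#' @return The labels sorted canonically.
#' @export
sort_sprinzl_labels <- function(labels) {
  labels[sprinzl_order_key(labels)]
}

#' Bind per-sample results into timecourse input
#'
#' Convenience: stacks Sprinzl-labelled profile tables and call tables from
#' several samples, adding `sample_id` and `time_label` columns.
#'
#' @param profiles_list,calls_list Named lists (names = sample ids) of
#'   profile / call tibbles.
#' @param time_labels Named character vector sample_id -> time label
#'   (e.g. `"0h"`).
#' @return A list with elements `profiles` and `calls`.
#' @export
bind_samples <- function(profiles_list, calls_list, time_labels) {
  stopifnot(identical(names(profiles_list), names(calls_list)))
  add_ids <- function(lst) {
    out <- purrr::imap(lst, function(df, id) {
      mutate(as_tibble(df), sample_id = id,
             time_label = unname(time_labels[id]), .before = 1L)
    }) |> purrr::list_rbind()
    class(out) <- unique(c(setdiff(class(lst[[1L]]), class(out)),
                           class(out)))
    out
  }
  list(profiles = add_ids(profiles_list), calls = add_ids(calls_list))
}

#' Aggregate RTa intensity per Sprinzl position across samples
#'
#' For each label and sample, sums arrest and coverage counts over the
#' clusters that qualify at that label — clusters reaching the call
#' threshold (intensity >= `min_intensity`, support >= `min_reads`) in at
#' least one sample — and reports `sum(stops) / sum(coverage)`, i.e. a
#' coverage-weighted mean intensity normalised over all reads. The
#' qualifying cluster set is shared by all samples so time points stay
#' comparable. Labels with no qualifying cluster are reported as 0.
#'
#' @param profiles Stacked labelled profiles with `sample_id` (see
#'   [bind_samples()]).
#' @param min_intensity,min_reads Qualification thresholds.
#' @return A `position_summary` tibble: `sprinzl_label`, `sample_id`,
#'   `time_label` (if present), `agg_intensity`, `n_modified_trnas`,
#'   `n_qualifying`.
#' @export
aggregate_rta_distribution <- function(profiles, min_intensity = 0.20,
                                       min_reads = 10) {
  prof <- if ("rta" %in% names(profiles)) profiles
          else add_rta_intensity(profiles)
  prof <- prof |> filter(!is.na(.data$sprinzl_label))
  qualifying <- prof |>
    filter(!is.na(.data$rta), .data$rta >= min_intensity,
           .data$cov_next >= min_reads) |>
    distinct(.data$sprinzl_label, .data$cluster_id)
  has_time <- "time_label" %in% names(prof)
  samples <- prof |>
    distinct(dplyr::across(dplyr::any_of(c("sample_id", "time_label"))))
  all_labels <- prof |> distinct(.data$sprinzl_label)
  grid <- tidyr::crossing(all_labels, samples)
  agg <- prof |>
    inner_join(qualifying, by = c("sprinzl_label", "cluster_id")) |>
    filter(!is.na(.data$rta)) |>
    group_by(dplyr::across(dplyr::any_of(
      c("sprinzl_label", "sample_id", "time_label")
    ))) |>
    summarise(
      agg_intensity = sum(.data$rta * .data$cov_next) / sum(.data$cov_next),
      n_modified_trnas = dplyr::n_distinct(
        .data$cluster_id[.data$rta >= min_intensity &
                           .data$cov_next >= min_reads]
      ),
      n_qualifying = dplyr::n_distinct(.data$cluster_id),
      .groups = "drop"
    )
  out <- grid |>
    left_join(agg, by = intersect(names(grid), names(agg))) |>
    mutate(
      agg_intensity = dplyr::coalesce(.data$agg_intensity, 0),
      n_modified_trnas = dplyr::coalesce(.data$n_modified_trnas, 0L),
      n_qualifying = dplyr::coalesce(.data$n_qualifying, 0L)
    ) |>
    arrange(match(.data$sprinzl_label,
                  sort_sprinzl_labels(unique(.data$sprinzl_label))))
  class(out) <- c("position_summary", class(out))
  out
}

#' Presence matrix: modified-cluster counts per position and sample
#'
#' Counts, per (Sprinzl label, reference base, sample), the clusters with an
#' emitted (unsuppressed) call — the raw material for presence/absence
#' dynamics across the time course. Counts are monotone under threshold
#' relaxation.
#'
#' @param calls Stacked call tibble with `sample_id` (and optionally
#'   `time_label`).
#' @return A tibble `sprinzl_label`, `ref_base`, `sample_id`
#'   (`time_label`), `n_clusters`.
#' @export
presence_matrix <- function(calls) {
  calls |>
    filter(!.data$suppressed, !is.na(.data$sprinzl_label)) |>
    group_by(dplyr::across(dplyr::any_of(
      c("sprinzl_label", "ref_base", "sample_id", "time_label")
    ))) |>
    summarise(n_clusters = dplyr::n_distinct(.data$cluster_id),
              .groups = "drop") |>
    arrange(match(.data$sprinzl_label,
                  sort_sprinzl_labels(unique(.data$sprinzl_label))))
}

#' Expression vs RTa-intensity rank correlation
#'
#' Checks, per sample and per modified Sprinzl label, whether clusters with
#' higher read totals (expression proxy) show systematically different RTa
#' intensities: Spearman rank correlation with a two-sided p-value. Labels
#' with fewer than `min_clusters` contributing clusters are reported as
#' missing — a rank correlation on 3 points is meaningless.
#'
#' @param profiles Stacked labelled profiles with `sample_id`.
#' @param calls Stacked calls; labels with at least one emitted RTa call
#'   define the modified labels tested.
#' @param min_clusters Minimum clusters per (label, sample).
#' @return An `rta_cor` tibble: `sample_id`, `sprinzl_label`, `n`, `rho`,
#'   `p_value`.
#' @export
expression_rta_correlation <- function(profiles, calls, min_clusters = 4) {
  prof <- if ("rta" %in% names(profiles)) profiles
          else add_rta_intensity(profiles)
  expr <- prof |>
    group_by(.data$sample_id, .data$cluster_id) |>
    summarise(total_reads = sum(.data$stop_count), .groups = "drop")
  mod_labels <- calls |>
    filter(!.data$suppressed, .data$evidence_rta,
           !is.na(.data$sprinzl_label)) |>
    distinct(.data$sprinzl_label)
  dat <- prof |>
    filter(.data$sprinzl_label %in% mod_labels$sprinzl_label,
           !is.na(.data$rta)) |>
    left_join(expr, by = c("sample_id", "cluster_id"))
  out <- dat |>
    group_by(.data$sample_id, .data$sprinzl_label) |>
    summarise(
      n = dplyr::n(),
      rho = if (dplyr::n() >= min_clusters) {
        suppressWarnings(cor.test(.data$total_reads, .data$rta,
                                  method = "spearman",
                                  exact = FALSE)$estimate[[1]])
      } else NA_real_,
      p_value = if (dplyr::n() >= min_clusters) {
        suppressWarnings(cor.test(.data$total_reads, .data$rta,
                                  method = "spearman",
                                  exact = FALSE)$p.value)
      } else NA_real_,
      .groups = "drop"
    )
  class(out) <- c("rta_cor", class(out))
  out
}

#' Per-cluster modification grid for one sample
#'
#' One row per cluster (ordered by isotype then anticodon), one column per
#' Sprinzl label, each cell carrying the RTa intensity and the evidence
#' class — `rta+mismatch`, `mismatch`, `rta`, or `none` — mirroring the
#' three symbol classes of per-sample overview figures.
#'
#' @param profiles Labelled profiles for one sample.
#' @param calls Calls for the same sample.
#' @param clusters Cluster tibble (for isotype/anticodon ordering).
#' @return A long tibble `cluster_id`, `isotype`, `anticodon`,
#'   `sprinzl_label`, `rta_intensity`, `evidence`.
#' @export
grid_report <- function(profiles, calls, clusters) {
  prof <- if ("rta" %in% names(profiles)) profiles
          else add_rta_intensity(profiles)
  emitted <- calls |>
    filter(!.data$suppressed) |>
    mutate(evidence = dplyr::case_when(
      .data$evidence_rta & .data$evidence_mismatch ~ "rta+mismatch",
      .data$evidence_mismatch ~ "mismatch",
      .data$evidence_rta ~ "rta"
    )) |>
    select("cluster_id", "position", "evidence")
  out <- prof |>
    filter(!is.na(.data$sprinzl_label)) |>
    left_join(emitted, by = c("cluster_id", "position")) |>
    left_join(clusters |> select("cluster_id", "isotype", "anticodon"),
              by = "cluster_id") |>
    mutate(evidence = dplyr::coalesce(.data$evidence, "none"),
           rta_intensity = .data$rta) |>
    select("cluster_id", "isotype", "anticodon", "sprinzl_label",
           "rta_intensity", "evidence") |>
    arrange(.data$isotype, .data$anticodon, .data$cluster_id,
            match(.data$sprinzl_label,
                  sort_sprinzl_labels(unique(.data$sprinzl_label))))
  class(out) <- c("mod_grid", class(out))
  out
}
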