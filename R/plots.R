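# ggplot2 views of the main result types: per-cluster arrest profiles,
# the per-position RTa distribution across samples, and the per-cluster
# modification grid.

#' Plot coverage and RTa intensity along one cluster
#'
#' @param profiles A `cluster_profiles` tibble (RTa columns added on the
#'   fly if absent).
#' @param cluster_id Cluster to draw.
#' @return A ggplot: coverage (area) with RTa intensity overlaid (points,
#'   secondary scale in \[0, 1\]).
#' @export
plot_rta_profile <- function(profiles, cluster_id) {
  prof <- if ("rta" %in% names(profiles)) profiles
          else add_rta_intensity(profiles)
  sub <- prof |> filter(.data$cluster_id == !!cluster_id)
  if (nrow(sub) == 0L) abort(paste0("no profile for cluster ", cluster_id))
  cov_max <- max(sub$coverage, 1L)
  ggplot(sub, aes(x = .data$position)) +
    geom_area(aes(y = .data$coverage), fill = "grey80") +
    geom_point(
      data = sub |> filter(!is.na(.data$rta), .data$rta > 0),
      aes(y = .data$rta * cov_max), colour = "firebrick", size = 1.2
    ) +
    scale_y_continuous(
      name = "coverage",
      sec.axis = sec_axis(~ . / cov_max, name = "RTa intensity")
    ) +
    labs(x = "mature position", title = cluster_id) +
    theme_minimal()
}

#' Plot the aggregated RTa distribution per Sprinzl position
#'
#' One bar per standard position and sample: the coverage-weighted RTa
#' intensity summed over qualifying clusters (the per-sample view of
#' modification dynamics along the tRNA body).
#'
#' @param summary A `position_summary` from [aggregate_rta_distribution()].
#' @return A ggplot, faceted by sample.
#' @export
plot_position_summary <- function(summary) {
  lv <- sort_sprinzl_labels(unique(summary$sprinzl_label))
  facet_var <- if ("time_label" %in% names(summary)) "time_label"
               else "sample_id"
  ggplot(summary, aes(x = factor(.data$sprinzl_label, levels = lv),
                      y = .data$agg_intensity)) +
    geom_col(fill = "black") +
    facet_grid(rows = facet_var) +
    labs(x = "Sprinzl position", y = "aggregated RTa intensity") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, size = 6))
}

#' Plot the per-cluster modification grid
#'
#' Clusters (rows, ordered by isotype and anticodon) against Sprinzl
#' positions (columns); tile fill encodes RTa intensity and shape the
#' evidence class (arrest + misincorporation, misincorporation only,
#' arrest only).
#'
#' @param grid A `mod_grid` from [grid_report()].
#' @return A ggplot.
#' @export
plot_modification_grid <- function(grid) {
  lv <- sort_sprinzl_labels(unique(grid$sprinzl_label))
  called <- grid |> filter(.data$evidence != "none")
  ggplot(grid, aes(x = factor(.data$sprinzl_label, levels = lv),
                   y = .data$cluster_id)) +
    geom_point(colour = "grey85", size = 0.4) +
    geom_point(
      data = called,
      aes(colour = .data$rta_intensity, shape = .data$evidence), size = 1.8
    ) +
    scale_shape_manual(values = c("rta+mismatch" = 18, "mismatch" = 5,
                                  "rta" = 16)) +
    scale_colour_viridis_c(limits = c(0, 1), na.value = "black") +
    labs(x = "Sprinzl position", y = NULL, colour = "RTa intensity",
         shape = "evidence") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, size = 6),
          axis.text.y = element_text(size = 5))
}

#' @export
autoplot.position_summary <- function(object, ...) {
  plot_position_summary(object)
}

#' @export
autoplot.mod_grid <- function(object, ...) {
  plot_modification_grid(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
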