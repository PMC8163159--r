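# broom-style accessors for result objects.

#' Tidy modification calls
#'
#' One row per emitted (unsuppressed) candidate site with the columns an
#' analyst filters on; suppressed artifact calls are dropped.
#'
#' @param x A `mod_calls` tibble.
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.mod_calls <- function(x, ...) {
  as_tibble(x) |>
    filter(!.data$suppressed) |>
    select(dplyr::any_of(c(
      "sample_id", "time_label", "cluster_id", "position", "sprinzl_label",
      "ref_base", "coverage", "rta_intensity", "mismatch_fraction",
      "confidence_phred", "dominant_mismatch", "evidence_rta",
      "evidence_mismatch", "candidate_identities", "top_identity", "novelty"
    )))
}

#' Summarise a call set
#'
#' @param x A `mod_calls` tibble.
#' @param ... Unused.
#' @return One-row tibble: emitted/suppressed counts, evidence breakdown,
#'   clusters and labels touched.
#' @export
glance.mod_calls <- function(x, ...) {
  emitted <- as_tibble(x) |> filter(!.data$suppressed)
  tibble(
    n_calls = nrow(emitted),
    n_suppressed = sum(x$suppressed),
    n_rta_only = sum(emitted$evidence_rta & !emitted$evidence_mismatch),
    n_mismatch_only = sum(emitted$evidence_mismatch & !emitted$evidence_rta),
    n_both = sum(emitted$evidence_rta & emitted$evidence_mismatch),
    n_clusters = dplyr::n_distinct(emitted$cluster_id),
    n_positions = dplyr::n_distinct(
      emitted$sprinzl_label[!is.na(emitted$sprinzl_label)]
    )
  )
}

#' Tidy an expression-vs-RTa correlation result
#' @param x An `rta_cor` tibble.
#' @param ... Unused.
#' @return A plain tibble (`sample_id`, `sprinzl_label`, `n`, `rho`,
#'   `p_value`).
#' @export
tidy.rta_cor <- function(x, ...) {
  as_tibble(x)
}

#' Summarise an expression-vs-RTa correlation result
#' @param x An `rta_cor` tibble.
#' @param ... Unused.
#' @return One-row tibble: labels tested, median |rho|, fraction of tests
#'   with p > 0.05 (the "no correlation" share).
#' @export
glance.rta_cor <- function(x, ...) {
  ok <- !is.na(x$p_value)
  tibble(
    n_tests = sum(ok),
    n_missing = sum(!ok),
    median_abs_rho = stats::median(abs(x$rho[ok])),
    frac_nonsignificant = if (any(ok)) mean(x$p_value[ok] > 0.05)
                          else NA_real_
  )
}

#' Tidy a Sprinzl map
#' @param x A `sprinzl_map`.
#' @param ... Unused.
#' @return Tibble `cluster_id`, `mature_pos`, `base`, `sprinzl_label`.
#' @export
tidy.sprinzl_map <- function(x, ...) {
  as_tibble(x)
}

#' Summarise a Sprinzl map
#' @param x A `sprinzl_map`.
#' @param ... Unused.
#' @return One row per cluster: alignment score and unfittable flag.
#' @export
glance.sprinzl_map <- function(x, ...) {
  as_tibble(attr(x, "scores"))
}
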