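# Minimal labelled two-position profiles (positions n, n+1) per cluster so
# rta(n) = stops(n+1)/cov(n+1) and total reads = stops(n) + stops(n+1).
null_profile_rows <- function(sample_id, cluster_id, cov, stops_next,
                              label = "58", pos = 58L) {
  tibble::tibble(
    sample_id = sample_id, time_label = sample_id, cluster_id = cluster_id,
    position = c(pos, pos + 1L), ref_base = "A",
    coverage = c(cov - stops_next, cov),
    stop_count = c(cov - stops_next, stops_next),
    n_A = c(cov - stops_next, cov), n_C = 0L, n_G = 0L, n_T = 0L,
    n_del = 0L, mismatch_count = 0L,
    sprinzl_label = c(label, "59")
  )
}

mk_rta_call <- function(sample_id, cluster_id, label = "58", pos = 58L,
                        intensity = 0.5) {
  tibble::tibble(
    sample_id = sample_id, time_label = sample_id, cluster_id = cluster_id,
    position = pos, sprinzl_label = label, ref_base = "A",
    evidence_rta = TRUE, evidence_mismatch = FALSE,
    rta_intensity = intensity, suppressed = FALSE
  )
}

test_that("aggregation is the coverage-weighted mean over qualifying clusters", {
  prof <- dplyr::bind_rows(
    null_profile_rows("s1", "c1", 100L, 30L),   # intensity 0.30
    null_profile_rows("s1", "c2", 100L, 10L),   # intensity 0.10
    null_profile_rows("s2", "c1", 100L, 40L),
    null_profile_rows("s2", "c2", 100L, 25L)    # c2 qualifies via s2
  )
  s <- aggregate_rta_distribution(prof)
  a58 <- s[s$sprinzl_label == "58", ]
  expect_equal(a58$agg_intensity[a58$sample_id == "s1"], (30 + 10) / 200)
  expect_equal(a58$agg_intensity[a58$sample_id == "s2"], (40 + 25) / 200)
  expect_equal(a58$n_modified_trnas[a58$sample_id == "s1"], 1L)
  expect_equal(a58$n_modified_trnas[a58$sample_id == "s2"], 2L)

  # single qualifying cluster: aggregate equals its own intensity
  solo <- aggregate_rta_distribution(null_profile_rows("s1", "c1", 200L, 90L))
  expect_equal(solo$agg_intensity[solo$sprinzl_label == "58"], 0.45)

  # label that never reaches threshold reports zero
  never <- aggregate_rta_distribution(null_profile_rows("s1", "c1", 100L, 5L))
  expect_equal(never$agg_intensity[never$sprinzl_label == "58"], 0)
})

test_that("presence counts never exceed cluster counts and grow as the
           threshold relaxes", {
  prof <- dplyr::bind_rows(
    null_profile_rows("s1", "c1", 100L, 30L),
    null_profile_rows("s1", "c2", 100L, 15L),
    null_profile_rows("s1", "c3", 100L, 8L)
  )
  prof_rta <- add_rta_intensity(prof)
  calls_strict <- dplyr::mutate(
    call_rta_sites(prof_rta, min_intensity = 0.25),
    sample_id = "s1", suppressed = FALSE
  )
  calls_loose <- dplyr::mutate(
    call_rta_sites(prof_rta, min_intensity = 0.10),
    sample_id = "s1", suppressed = FALSE
  )
  pm_strict <- presence_matrix(calls_strict)
  pm_loose <- presence_matrix(calls_loose)
  n_strict <- sum(pm_strict$n_clusters[pm_strict$sprinzl_label == "58"])
  n_loose <- sum(pm_loose$n_clusters[pm_loose$sprinzl_label == "58"])
  expect_equal(n_strict, 1L)
  expect_equal(n_loose, 2L)
  expect_lte(n_strict, n_loose)
  expect_lte(n_loose, 3L)
})

test_that("expression-RTa correlation matches rank-based reference values", {
  # perfectly rank-correlated input: rho exactly 1
  cov <- c(100L, 200L, 400L, 800L, 1600L)
  stops <- as.integer(cov * seq(0.2, 0.6, by = 0.1))
  prof <- purrr::map2(
    sprintf("c%d", 1:5), seq_along(cov),
    function(id, i) null_profile_rows("s1", id, cov[i], stops[i])
  ) |> dplyr::bind_rows()
  calls <- mk_rta_call("s1", "c1")
  res <- expression_rta_correlation(prof, calls)
  expect_equal(res$rho[res$sprinzl_label == "58"], 1)
  expect_equal(res$n[res$sprinzl_label == "58"], 5L)

  # independent reference: Pearson on ranks, to 1e-9
  totals <- vapply(sprintf("c%d", 1:5), function(id) {
    sum(prof$stop_count[prof$cluster_id == id])
  }, numeric(1L))
  rta <- stops / cov
  ref_rho <- stats::cor(rank(totals), rank(rta))
  expect_equal(res$rho[res$sprinzl_label == "58"], ref_rho,
               tolerance = 1e-9)

  # fewer than 4 clusters: reported missing
  small <- dplyr::bind_rows(
    null_profile_rows("s1", "c1", 100L, 30L),
    null_profile_rows("s1", "c2", 100L, 40L),
    null_profile_rows("s1", "c3", 100L, 50L)
  )
  res_small <- expression_rta_correlation(small, calls)
  expect_true(is.na(res_small$rho[res_small$sprinzl_label == "58"]))

  g <- glance(res)
  expect_identical(g$n_tests, 1L)
})

test_that("grid reports order clusters by isotype/anticodon with evidence
           classes", {
  cfg <- sim_config(n_clusters = 5, n_mito = 1, n_genes = 7, depth = 300,
                    background_error = 0, seed = 13)
  cl <- cluster_trnas(simulate_genes(cfg)$genes)
  smap <- fit_sprinzl(cl)
  tr <- simulate_truth(cl, sites_per_cluster = 2, seed = 13)
  prof <- build_profiles(simulate_reads(cl, tr, cfg)$alignments, cl) |>
    label_profiles(smap) |>
    add_rta_intensity()
  calls <- call_sites(prof)
  grid <- grid_report(prof, calls, cl)
  expect_true(all(c("cluster_id", "isotype", "anticodon", "sprinzl_label",
                    "rta_intensity", "evidence") %in% names(grid)))
  expect_true(all(grid$evidence %in%
                    c("none", "rta", "mismatch", "rta+mismatch")))
  expect_gt(sum(grid$evidence != "none"), 0L)
  iso_order <- unique(grid$isotype)
  expect_identical(iso_order, sort(iso_order))
  # every called site appears in the grid with its evidence class
  emitted <- dplyr::filter(calls, !suppressed, !is.na(sprinzl_label))
  hit <- dplyr::semi_join(
    grid |> dplyr::filter(evidence != "none"),
    emitted, by = c("cluster_id", "sprinzl_label")
  )
  expect_equal(nrow(hit), nrow(dplyr::distinct(
    emitted, cluster_id, sprinzl_label
  )))
})
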