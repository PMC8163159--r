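test_that("mismatch calling matches the exact binomial-tail oracle (cov <= 30)", {
  eps <- 0.01
  for (cov in 1:30) {
    for (k in 0:cov) {
      prof <- counts_profile(ref = "ACGTACGTAC", coverage = cov,
                             mismatch = c(k, rep(0, 9)))
      calls <- call_mismatch_sites(prof, min_conf_phred = 20,
                                   min_reads = 10, error_rate = eps)
      called <- 1L %in% calls$position
      # brute-force oracle: sum the binomial pmf over the upper tail
      p <- sum(stats::dbinom(k:cov, cov, eps))
      oracle <- (-10 * log10(p) >= 20) && cov >= 10
      expect_identical(called, oracle)
    }
  }
})

test_that("mismatch-caller examples behave at the operating point", {
  strong <- counts_profile(ref = strrep("A", 5), coverage = 100,
                           mismatch = c(40, 0, 0, 0, 0))
  calls <- call_mismatch_sites(strong)
  expect_true(1L %in% calls$position)
  expect_gt(calls$confidence_phred[calls$position == 1L], 20)
  expect_equal(calls$mismatch_fraction[calls$position == 1L], 0.4)
  expect_equal(calls$dominant_mismatch[calls$position == 1L], "G")

  low_cov <- counts_profile(ref = strrep("A", 5), coverage = 9,
                            mismatch = c(9, 0, 0, 0, 0))
  expect_equal(nrow(call_mismatch_sites(low_cov)), 0L)

  weak <- counts_profile(ref = strrep("A", 5), coverage = 100,
                         mismatch = c(1, 0, 0, 0, 0))
  expect_equal(nrow(call_mismatch_sites(weak)), 0L)
  expect_lt(phred_confidence(1, 100, 0.01), 3)
})

test_that("RTa call boundary sits exactly at intensity 0.20 and coverage 10", {
  mk <- function(stops_at_n1, cov) {
    counts_profile(ref = strrep("A", 5), coverage = cov,
                   stops = c(cov - stops_at_n1, stops_at_n1, 0, 0, 0))
  }
  # intensity bisection at cov 1000: smallest called stop count is 200
  called_at <- function(s) {
    calls <- call_rta_sites(mk(s, 1000))
    1L %in% calls$position
  }
  lo <- 0L; hi <- 1000L
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (called_at(mid)) hi <- mid else lo <- mid
  }
  expect_identical(hi, 200L)          # 0.200 called, 0.199 not
  expect_true(called_at(200L))
  expect_false(called_at(199L))

  # coverage bisection at fixed 20% intensity: boundary exactly 10
  cov_called <- function(cov) {
    stops <- as.integer(round(cov * 0.2))
    calls <- call_rta_sites(counts_profile(
      ref = strrep("A", 5), coverage = cov,
      stops = c(cov - stops, stops, 0, 0, 0)
    ))
    1L %in% calls$position
  }
  expect_true(cov_called(10L))
  expect_false(cov_called(9L))

  # uniform full-length reads: no calls
  flat <- counts_profile(ref = strrep("A", 10), coverage = 100,
                         stops = c(100, rep(0, 9)))
  expect_equal(nrow(call_rta_sites(flat)), 0L)
})

test_that("TGIRT artifact filter suppresses weak trailing echoes only", {
  ref <- strrep("A", 40)
  base_cov <- 100L
  mk_prof <- function(stops, mismatch = integer(40)) {
    counts_profile(ref = ref, coverage = base_cov, stops = stops,
                   mismatch = mismatch)
  }
  # primary at 32 (intensity 0.6 via stops at 33), echo at 34 (stops at 35)
  stops <- integer(40); stops[33] <- 60L; stops[35] <- 25L
  mism <- integer(40); mism[34] <- 2L  # sub-threshold mismatches at the echo
  prof <- mk_prof(stops, mism)
  rta <- call_rta_sites(prof)
  flt <- filter_tgirt_artifacts(rta, prof)
  expect_true(flt$suppressed[flt$position == 34L])
  expect_false(flt$suppressed[flt$position == 32L])

  # two strong independent calls 10 nt apart: neither suppressed
  stops2 <- integer(40); stops2[21] <- 50L; stops2[31] <- 40L
  mism2 <- integer(40); mism2[c(20, 30)] <- 2L
  prof2 <- mk_prof(stops2, mism2)
  flt2 <- filter_tgirt_artifacts(call_rta_sites(prof2), prof2)
  expect_false(any(flt2$suppressed))

  # secondary stronger than primary: not suppressed
  stops3 <- integer(40); stops3[33] <- 30L; stops3[35] <- 60L
  mism3 <- integer(40); mism3[34] <- 2L
  prof3 <- mk_prof(stops3, mism3)
  flt3 <- filter_tgirt_artifacts(call_rta_sites(prof3), prof3)
  expect_false(any(flt3$suppressed))

  # no mismatches at the echo: kept despite being weaker
  prof4 <- mk_prof(stops)
  flt4 <- filter_tgirt_artifacts(call_rta_sites(prof4), prof4)
  expect_false(any(flt4$suppressed))
})

test_that("evidence merging unions by site and flags both channels", {
  prof <- counts_profile(ref = strrep("A", 20), coverage = 100,
                         stops = c(rep(0, 9), 30, rep(0, 10)),
                         mismatch = c(rep(0, 8), 40, rep(0, 11)))
  calls <- call_sites(prof)
  # position 9: both mismatch (40/100) and RTa (stops at 10 -> n = 9)
  both <- calls[calls$position == 9L, ]
  expect_true(both$evidence_mismatch && both$evidence_rta)
  expect_equal(both$rta_intensity, 0.3)
  expect_equal(both$mismatch_fraction, 0.4)
  expect_true(all(calls$evidence_mismatch | calls$evidence_rta))
})

test_that("calling is deterministic", {
  cfg <- sim_config(n_clusters = 4, n_mito = 0, n_genes = 6, depth = 100,
                    seed = 31)
  cl <- cluster_trnas(simulate_genes(cfg)$genes)
  tr <- simulate_truth(cl, seed = 31)
  prof <- build_profiles(simulate_reads(cl, tr, cfg)$alignments, cl)
  expect_identical(call_sites(prof), call_sites(prof))
})
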