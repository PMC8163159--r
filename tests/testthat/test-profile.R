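test_that("full-length identical reads give flat coverage, stops at 1", {
  ref <- template_mature()
  L <- nchar(ref)
  reads <- tibble::tibble(
    qname = sprintf("r%02d", 1:10), rname = "F-GAA-1", pos = 1L,
    cigar = sprintf("%dM", L), seq = ref
  )
  sam <- write_toy_sam(reads, toy_cluster())
  prof <- build_profiles(sam, toy_cluster())
  expect_equal(nrow(prof), L)
  expect_true(all(prof$coverage == 10L))
  expect_equal(prof$stop_count[1L], 10L)
  expect_true(all(prof$stop_count[-1L] == 0L))
  expect_true(all(prof$mismatch_count == 0L))
  # uniform full-length reads: zero RTa everywhere
  with_rta <- add_rta_intensity(prof)
  expect_true(all(with_rta$rta[!is.na(with_rta$rta)] == 0))
})

test_that("5'-truncated reads produce the documented stop/coverage pattern", {
  ref <- template_mature()
  L <- nchar(ref)
  full <- tibble::tibble(
    qname = sprintf("f%d", 1:6), rname = "F-GAA-1", pos = 1L,
    cigar = sprintf("%dM", L), seq = ref
  )
  stopped <- tibble::tibble(
    qname = sprintf("s%d", 1:4), rname = "F-GAA-1", pos = 59L,
    cigar = sprintf("%dM", L - 58L), seq = substr(ref, 59L, L)
  )
  sam <- write_toy_sam(dplyr::bind_rows(full, stopped), toy_cluster())
  prof <- build_profiles(sam, toy_cluster())
  expect_equal(prof$stop_count[prof$position == 59L], 4L)
  expect_equal(prof$coverage[prof$position == 58L], 6L)
  expect_equal(prof$coverage[prof$position == 59L], 10L)
  # rta_intensity(58) = stops(59)/coverage(59)
  expect_equal(rta_intensity(prof, "F-GAA-1", 58L), 0.4)
  # conservation
  expect_equal(sum(prof$stop_count), 10L)
})

test_that("empty alignments give empty profiles", {
  sam <- write_toy_sam(
    tibble::tibble(qname = character(), rname = character(),
                   pos = integer(), cigar = character(), seq = character()),
    toy_cluster()
  )
  prof <- build_profiles(sam, toy_cluster())
  expect_true(all(prof$coverage == 0L))
  expect_equal(sum(prof$stop_count), 0L)
})

test_that("deletions count toward coverage but not mismatch; clips ignored", {
  ref <- template_mature()
  L <- nchar(ref)
  # read covering 1..L with a 2-nt deletion at 30-31 and a 5-nt soft clip
  seq_del <- paste0("AAAAA", substr(ref, 1, 29), substr(ref, 32, L))
  reads <- tibble::tibble(
    qname = "d1", rname = "F-GAA-1", pos = 1L,
    cigar = sprintf("5S29M2D%dM", L - 31L), seq = seq_del
  )
  prof <- build_profiles(write_toy_sam(reads, toy_cluster()), toy_cluster())
  expect_equal(prof$coverage[prof$position %in% c(30L, 31L)], c(1L, 1L))
  expect_equal(prof$n_del[prof$position %in% c(30L, 31L)], c(1L, 1L))
  expect_equal(prof$mismatch_count[prof$position %in% c(30L, 31L)],
               c(0L, 0L))
  expect_equal(prof$stop_count[1L], 1L)  # clip does not shift the 5' end
})

test_that("multi-mapped reads are dropped; unknown references error", {
  ref <- template_mature()
  L <- nchar(ref)
  reads <- tibble::tibble(
    qname = c("u1", "m1"), rname = "F-GAA-1", pos = 1L,
    cigar = sprintf("%dM", L), seq = ref,
    flag = c(0L, 256L)
  )
  sam <- write_toy_sam(reads, toy_cluster())
  prof <- build_profiles(sam, toy_cluster())
  expect_true(all(prof$coverage <= 1L))

  aln <- read_alignments(sam)
  aln$rname[1] <- "nope"
  expect_error(build_profiles(aln, toy_cluster()), "nope")
})

test_that("3'-anchored simulations obey conservation, monotonicity and the
           two intensity formulations agree", {
  cfg <- sim_config(n_clusters = 5, n_mito = 1, n_genes = 8, depth = 120,
                    background_error = 0, seed = 21)
  cl <- cluster_trnas(simulate_genes(cfg)$genes)
  tr <- simulate_truth(cl, seed = 21)
  sim <- simulate_reads(cl, tr, cfg)
  prof <- add_rta_intensity(build_profiles(sim$alignments, cl))
  expect_equal(sum(prof$stop_count), nrow(sim$alignments))
  for (id in cl$cluster_id) {
    sub <- dplyr::arrange(dplyr::filter(prof, cluster_id == id), position)
    expect_true(all(diff(sub$coverage) >= 0L))  # 3'-anchored coverage
    ok <- !is.na(sub$rta)
    expect_equal(sub$rta[ok], (1 - sub$read_through)[ok], tolerance = 1e-12)
    expect_true(all(sub$rta[ok] >= 0 & sub$rta[ok] <= 1))
  }
})

test_that("planted stop probabilities are recovered within binomial noise", {
  cl <- toy_cluster()
  truth <- tibble::tibble(
    cluster_id = "F-GAA-1", position = 58L,
    planted_modification_code = "sim_rta", type = "rta", stop_prob = 0.5,
    mis_A = 0, mis_C = 0, mis_G = 0, mis_T = 0
  )
  cfg <- sim_config(background_error = 0, seed = 5)
  sim <- simulate_reads(cl, truth, cfg, depths = c("F-GAA-1" = 1000L))
  prof <- build_profiles(sim$alignments, cl)
  est <- rta_intensity(prof, "F-GAA-1", 58L)
  expect_lt(abs(est - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("degenerate stop probability 1 empties upstream coverage", {
  cl <- toy_cluster()
  truth <- tibble::tibble(
    cluster_id = "F-GAA-1", position = 58L,
    planted_modification_code = "sim_rta", type = "rta", stop_prob = 1,
    mis_A = 0, mis_C = 0, mis_G = 0, mis_T = 0
  )
  sim <- simulate_reads(cl, truth, sim_config(background_error = 0, seed = 2),
                        depths = c("F-GAA-1" = 200L))
  prof <- build_profiles(sim$alignments, cl)
  expect_equal(rta_intensity(prof, "F-GAA-1", 58L), 1)
  expect_true(all(prof$coverage[prof$position <= 58L] == 0L))
})
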