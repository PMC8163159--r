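mk_call <- function(sprinzl_label, ref_base, evidence_rta, evidence_mismatch,
                    rta_intensity = NA_real_,
                    dominant_mismatch = NA_character_,
                    mismatch_fraction = NA_real_) {
  out <- tibble::tibble(
    cluster_id = "c1", position = 10L, sprinzl_label = sprinzl_label,
    ref_base = ref_base, coverage = 100L,
    evidence_rta = evidence_rta, evidence_mismatch = evidence_mismatch,
    rta_intensity = rta_intensity, mismatch_fraction = mismatch_fraction,
    dominant_mismatch = dominant_mismatch, suppressed = FALSE
  )
  class(out) <- c("mod_calls", class(out))
  out
}

test_that("canonical signatures classify to the expected identities", {
  # A58 with A->T/A->G mismatches and strong arrest: m1A on top
  m1a <- classify_calls(mk_call("58", "A", TRUE, TRUE, 0.6, "T", 0.3))
  expect_identical(m1a$top_identity, "m1A")
  expect_identical(m1a$novelty, "known_position")

  # A34 pure A->G mismatch, no arrest: inosine
  ino <- classify_calls(mk_call("34", "A", FALSE, TRUE, NA, "G", 0.5))
  expect_identical(ino$top_identity, "I")

  # G26 mismatch + arrest: m2G/m22G stay an unresolved set
  g26 <- classify_calls(mk_call("26", "G", TRUE, TRUE, 0.5, "A", 0.3))
  expect_match(g26$candidate_identities, "m1G\\|m2G\\|m22G")
  expect_identical(g26$novelty, "known_position")

  # A37 arrest-dominant, no mismatch: hypermodification set
  a37 <- classify_calls(mk_call("37", "A", TRUE, FALSE, 0.7))
  expect_match(a37$candidate_identities, "t6A\\|i6A\\|ms2i6A\\|m6t6A")

  # weak arrest at U: dihydrouridine
  d20 <- classify_calls(mk_call("20", "T", TRUE, FALSE, 0.25))
  expect_identical(d20$top_identity, "D")
})

test_that("classification is total and never drops a call", {
  # a signature matching no rule: T with a strong C mismatch, no arrest
  odd <- classify_calls(mk_call("13", "T", FALSE, TRUE, NA, "C", 0.4))
  expect_equal(nrow(odd), 1L)
  expect_match(odd$candidate_identities, "^unknown\\[T>C\\]$")

  # property: every combination yields at least one candidate
  combos <- expand.grid(
    ref = c("A", "C", "G", "T"), rta = c(TRUE, FALSE),
    mm = c(TRUE, FALSE), stringsAsFactors = FALSE
  )
  combos <- combos[combos$rta | combos$mm, ]
  for (i in seq_len(nrow(combos))) {
    cc <- classify_calls(mk_call(
      "11", combos$ref[i], combos$rta[i], combos$mm[i],
      rta_intensity = ifelse(combos$rta[i], 0.5, NA),
      dominant_mismatch = ifelse(combos$mm[i], "G", NA),
      mismatch_fraction = ifelse(combos$mm[i], 0.3, NA)
    ))
    expect_gte(nchar(cc$candidate_identities), 1L)
  }
})

test_that("novelty flags follow the catalogue; unlabeled calls are noted", {
  expect_identical(novelty_flag("58", "A"), "known_position")
  expect_identical(novelty_flag("64", "A"), "novel_position")
  expect_identical(novelty_flag(NA_character_, "A"),
                   "novel_position(unlabeled)")
  unl <- classify_calls(mk_call(NA_character_, "A", TRUE, TRUE, 0.6, "T",
                                0.3))
  expect_identical(unl$novelty, "novel_position(unlabeled)")
  expect_identical(unl$top_identity, "m1A")  # signature-only still works
})

test_that("catalogue entries reorder but never remove candidates", {
  call <- mk_call("37", "G", TRUE, TRUE, 0.5, "T", 0.3)
  base_cat <- load_catalogue()
  no37 <- base_cat[!(base_cat$sprinzl_label == "37" &
                       base_cat$ref_base == "G"), ]
  with_cat <- classify_calls(call, catalogue = base_cat)
  without_cat <- classify_calls(call, catalogue = no37)
  split_ids <- function(x) unlist(strsplit(x, "|", fixed = TRUE))
  expect_setequal(split_ids(with_cat$candidate_identities),
                  split_ids(without_cat$candidate_identities))
})

test_that("default tables round-trip through TSV byte-identically", {
  d <- tempfile()
  paths <- write_default_tables(d)
  expect_identical(load_signature_table(paths[["signatures"]]),
                   signature_rules())
  expect_identical(load_catalogue(paths[["catalogue"]]),
                   position_catalogue())
  # and re-writing gives identical bytes
  d2 <- tempfile()
  paths2 <- write_default_tables(d2)
  expect_identical(readLines(paths[["signatures"]]),
                   readLines(paths2[["signatures"]]))
  expect_identical(readLines(paths[["catalogue"]]),
                   readLines(paths2[["catalogue"]]))
})
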