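# Fixture builders shared across the suite. Everything is generated in code;
# no binary files on disk.

# A minimal valid gene tibble from raw parts.
toy_genes <- function(seqs, anticodon = "GAA", isotype = "F",
                      origin = "nuclear", introns = NULL,
                      ids = sprintf("g%02d", seq_along(seqs))) {
  n <- length(seqs)
  tibble::tibble(
    gene_id = ids,
    contig = if (identical(origin, "mitochondrial")) "chrM" else "chr1",
    start = cumsum(c(1L, utils::head(nchar(seqs), -1L) + 10L)),
    end = cumsum(c(1L, utils::head(nchar(seqs), -1L) + 10L)) +
      nchar(seqs) - 1L,
    strand = "+",
    isotype = rep(isotype, n),
    anticodon = rep(anticodon, n),
    origin = rep(origin, n),
    sequence = seqs,
    intron_intervals = if (is.null(introns)) {
      replicate(n, matrix(integer(), ncol = 2L), simplify = FALSE)
    } else introns
  )
}

# The packaged 76-nt consensus as a ready-made mature sequence (ends in CCA,
# anticodon GAA at 34-36): the identity case for Sprinzl fitting.
template_mature <- function() {
  paste(rtamod::sprinzl_template()$base, collapse = "")
}

# One cluster tibble around a single mature sequence.
toy_cluster <- function(mature = template_mature(), id = "F-GAA-1",
                        anticodon = "GAA", isotype = "F",
                        origin = "nuclear") {
  tibble::tibble(
    cluster_id = id, mature_sequence = mature, anticodon = anticodon,
    isotype = isotype, origin = origin, n_members = 1L,
    member_gene_ids = list("g01")
  )
}

# Build a cluster_profiles tibble directly from count vectors (bypassing
# alignments) for calling-level tests. Extra per-position vectors may
# override any column.
counts_profile <- function(cluster_id = "c1", ref, coverage, stops = NULL,
                           mismatch = NULL, mm_target = "G") {
  L <- nchar(ref)
  ref_chars <- strsplit(ref, "")[[1]]
  coverage <- rep_len(coverage, L)
  stops <- if (is.null(stops)) integer(L) else rep_len(stops, L)
  mismatch <- if (is.null(mismatch)) integer(L) else rep_len(mismatch, L)
  counts <- matrix(0L, L, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_len(L)) {
    tgt <- if (ref_chars[i] == mm_target) setdiff(c("A", "C", "G", "T"),
                                                  ref_chars[i])[1L]
           else mm_target
    counts[i, ref_chars[i]] <- coverage[i] - mismatch[i]
    counts[i, tgt] <- mismatch[i]
  }
  out <- tibble::tibble(
    cluster_id = cluster_id, position = seq_len(L), ref_base = ref_chars,
    coverage = as.integer(coverage), stop_count = as.integer(stops),
    n_A = counts[, "A"], n_C = counts[, "C"], n_G = counts[, "G"],
    n_T = counts[, "T"], n_del = 0L,
    mismatch_count = as.integer(mismatch)
  )
  class(out) <- c("cluster_profiles", class(out))
  out
}

# Write an ad-hoc SAM file for a set of simple reads against one or more
# references. reads: tibble(qname, rname, pos, cigar, seq).
write_toy_sam <- function(reads, refs, path = tempfile(fileext = ".sam")) {
  if (!"flag" %in% names(reads)) reads$flag <- 0L
  if (!"mapq" %in% names(reads)) reads$mapq <- 60L
  rtamod::write_sam(reads, refs, path)
  path
}
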