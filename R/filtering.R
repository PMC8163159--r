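# Raw-read retention rules and alignment-level pre-tRNA exclusion.
# Retention trims low-quality 3' tails at the quality cutoff first, then
# keeps reads whose trimmed length falls in [min_len, max_len].

# 3'-quality trimming (cutadapt/BWA-style): walking in from the 3' end,
# accumulate (cutoff - q) and cut at the position where the running sum is
# maximal. Returns the kept length.
#' Trimmed length after 3' quality trimming
#'
#' @param qualities Integer vector of per-base Phred scores (5'->3').
#' @param qual_cutoff Quality cutoff; bases are trimmed from the 3' end where
#'   the running sum of `cutoff - q` is maximised.
#' @return Number of bases kept.
#' @export
quality_trim_length <- function(qualities, qual_cutoff = 25) {
  n <- length(qualities)
  if (n == 0L) return(0L)
  run <- cumsum(rev(qual_cutoff - qualities))
  best <- max(run)
  if (best <= 0) return(n)
  n - max(which(run == best))
}

#' Read retention predicate
#'
#' A read is retained when, after 3'-end quality trimming at `qual_cutoff`,
#' its length lies within `[min_len, max_len]` (defaults 8-95 nt at Q25).
#'
#' @param sequence Read sequence (used only for its length when `qualities`
#'   is `NULL`).
#' @param qualities Integer Phred scores, same length as `sequence`; `NULL`
#'   skips trimming.
#' @param min_len,max_len Inclusive length bounds after trimming.
#' @param qual_cutoff 3'-trimming quality cutoff.
#' @return Logical: keep the read?
#' @export
retain_read <- function(sequence, qualities = NULL, min_len = 8,
                        max_len = 95, qual_cutoff = 25) {
  len <- nchar(sequence)
  if (!is.null(qualities)) {
    stopifnot(length(qualities) == len)
    len <- quality_trim_length(qualities, qual_cutoff)
  }
  len >= min_len && len <= max_len
}

#' Filter a FASTQ file by the retention rules
#'
#' Reads a FASTQ, applies 3' quality trimming and the length window, and
#' writes the retained (trimmed) reads.
#'
#' @param fastq_in,fastq_out Input/output FASTQ paths.
#' @inheritParams retain_read
#' @return A tibble with `read_id`, `raw_len`, `trimmed_len`, `kept`.
#' @export
filter_fastq <- function(fastq_in, fastq_out = NULL, min_len = 8,
                         max_len = 95, qual_cutoff = 25) {
  reads <- Biostrings::readDNAStringSet(fastq_in, format = "fastq",
                                        with.qualities = TRUE)
  quals <- S4Vectors::mcols(reads)$qualities
  qchar <- as.character(quals)
  trimmed <- vapply(seq_along(reads), function(i) {
    quality_trim_length(utf8ToInt(qchar[i]) - 33L, qual_cutoff)
  }, integer(1L))
  kept <- trimmed >= min_len & trimmed <= max_len
  if (!is.null(fastq_out)) {
    out <- Biostrings::subseq(reads[kept], 1L, trimmed[kept])
    S4Vectors::mcols(out)$qualities <-
      Biostrings::subseq(quals[kept], 1L, trimmed[kept])
    Biostrings::writeXStringSet(out, fastq_out, format = "fastq",
                                qualities = S4Vectors::mcols(out)$qualities)
  }
  tibble(
    read_id = names(reads) %||% as.character(seq_along(reads)),
    raw_len = Biostrings::width(reads),
    trimmed_len = trimmed,
    kept = kept
  )
}

#' Mismatch budget for a given mapping accuracy
#'
#' The mapping contract requires a minimum alignment accuracy; the number of
#' mismatches tolerated for a read is `floor((1 - accuracy/100) * read_len)`
#' (20 mismatches for a 100-nt read at 80% accuracy).
#'
#' @param read_len Read length in nt.
#' @param accuracy_pct Minimum accuracy in percent.
#' @return Integer mismatch budget.
#' @export
max_mismatches <- function(read_len, accuracy_pct = 80) {
  stopifnot(accuracy_pct >= 0, accuracy_pct <= 100, read_len >= 0)
  # tiny epsilon guards the exact-percentage boundaries against
  # floating-point round-down (e.g. 20% of 100 nt must be 20, not 19)
  as.integer(floor(read_len * (100 - accuracy_pct) / 100 + 1e-9))
}

#' Pre-tRNA read exclusion
#'
#' Reads aligned against extended (precursor) contigs are excluded when their
#' aligned span reaches at least `k` nt outside the mature interval on either
#' side — the hallmark of retained 5' leader or 3' trailer sequence.
#'
#' @param aln_start,aln_end 1-based inclusive aligned span on the extended
#'   contig (vectorised).
#' @param mature_start,mature_end 1-based inclusive mature interval on the
#'   same contig.
#' @param k Minimum overhang (nt) outside the mature interval that triggers
#'   exclusion.
#' @return Logical vector: `TRUE` = exclude as pre-tRNA.
#' @export
exclude_pre_trna <- function(aln_start, aln_end, mature_start, mature_end,
                             k = 1) {
  (mature_start - aln_start >= k) | (aln_end - mature_end >= k)
}
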