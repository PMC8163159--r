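# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    abort(sprintf(
      "%s contains non-ACGT characters: %s", what,
      paste(head(x[bad], 3L), collapse = ", ")
    ))
  }
  invisible(x)
}

# Phred-scaled upper binomial tail: P(X >= k | n, eps), capped at `cap`.
# k = 0 gives p = 1, confidence 0.
phred_binom_tail <- function(k, n, error_rate, cap = 1000) {
  p <- pbinom(k - 1, n, error_rate, lower.tail = FALSE)
  conf <- -10 * log10(p)
  conf[!is.finite(conf) | conf > cap] <- cap
  conf[k <= 0] <- 0
  conf
}

# Split "12-34,56-70" style intron annotations into a 2-column matrix.
parse_intervals <- function(x) {
  if (is.na(x) || !nzchar(x) || identical(x, ".")) {
    return(matrix(integer(), ncol = 2L))
  }
  parts <- strsplit(strsplit(x, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- t(vapply(parts, function(p) as.integer(p[1:2]), integer(2L)))
  m
}

format_intervals <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return(".")
  paste(sprintf("%d-%d", m[, 1], m[, 2]), collapse = ",")
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

write_tsv_stable <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}
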