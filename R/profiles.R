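# Per-position profiles over mature cluster references: coverage, 5'-end
# stop counts and base composition. These are the raw material for RTa and
# misincorporation calling. LOTTE-seq reads are 3'-anchored, so an RT arrest
# at position n leaves a read whose 5'-most aligned base is n+1.

#' Read alignments from SAM or BAM into a tibble
#'
#' SAM text input is converted on the fly with [Rsamtools::asBam()].
#' Unmapped records are dropped. Reads are marked multi-mapped when they are
#' secondary/supplementary alignments or carry an `NH` tag greater than 1;
#' the profiler discards those, keeping only uniquely mapped reads.
#'
#' @param path SAM (`.sam`) or BAM file.
#' @return Tibble: `qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`, `seq`,
#'   `multi`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) abort(paste0("alignment file not found: ", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  prm <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    tag = "NH"
  )
  x <- Rsamtools::scanBam(bam, param = prm)[[1]]
  nh <- x$tag$NH %||% rep(NA_integer_, length(x$qname))
  out <- tibble(
    qname = x$qname,
    flag = x$flag,
    rname = as.character(x$rname),
    pos = x$pos,
    mapq = x$mapq,
    cigar = x$cigar,
    seq = as.character(x$seq),
    nh = as.integer(nh)
  )
  out <- out |> filter(bitwAnd(.data$flag, 4L) == 0L)
  out |>
    mutate(multi = bitwAnd(.data$flag, 256L) > 0L |
             bitwAnd(.data$flag, 2048L) > 0L |
             (!is.na(.data$nh) & .data$nh > 1L)) |>
    select(-"nh")
}

# Walk one CIGAR string; returns reference positions covered and the read
# base at each (deletion = "-"). Soft clips and insertions consume query
# only; hard clips/padding consume nothing.
cigar_walk <- function(pos, cigar, seq) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  ref_pos <- integer(0)
  bases <- character(0)
  r <- pos
  q <- 1L
  chars <- strsplit(seq, "")[[1]]
  for (k in seq_along(op)) {
    n <- len[k]
    if (op[k] %in% c("M", "=", "X")) {
      ref_pos <- c(ref_pos, r:(r + n - 1L))
      bases <- c(bases, chars[q:(q + n - 1L)])
      r <- r + n
      q <- q + n
    } else if (op[k] == "D") {
      ref_pos <- c(ref_pos, r:(r + n - 1L))
      bases <- c(bases, rep("-", n))
      r <- r + n
    } else if (op[k] == "N") {
      r <- r + n
    } else if (op[k] %in% c("I", "S")) {
      q <- q + n
    }
  }
  list(ref_pos = ref_pos, bases = bases)
}

#' Build per-position profiles from alignments
#'
#' Counts, for every position of every cluster reference: coverage (aligned
#' bases plus deletions), the number of reads whose 5'-most aligned base is
#' that position (`stop_count`), and the base composition. Multi-mapped
#' reads are dropped; soft-clipped bases are ignored; insertions do not
#' contribute positional counts.
#'
#' @param alignments Tibble from [read_alignments()] (or a SAM/BAM path).
#' @param reference Cluster tibble from [cluster_trnas()], a named character
#'   vector of mature sequences, or a FASTA path.
#' @return A `cluster_profiles` tibble: `cluster_id`, `position`, `ref_base`,
#'   `coverage`, `stop_count`, `n_A`, `n_C`, `n_G`, `n_T`, `n_del`,
#'   `mismatch_count`. Positions are contiguous 1..L per cluster.
#' @export
build_profiles <- function(alignments, reference) {
  if (is.character(alignments) && length(alignments) == 1L) {
    alignments <- read_alignments(alignments)
  }
  seqs <- reference_seqs(reference)
  aln <- alignments |> filter(!.data$multi)
  unknown <- setdiff(unique(aln$rname), names(seqs))
  if (length(unknown) > 0L) {
    abort(paste0("alignments reference sequences absent from the reference: ",
                 paste(unknown, collapse = ", ")))
  }
  base_idx <- setNames(1:5, c("A", "C", "G", "T", "-"))
  profiles <- purrr::map(names(seqs), function(cl) {
    L <- nchar(seqs[[cl]])
    ref_chars <- strsplit(seqs[[cl]], "")[[1]]
    sub <- aln[aln$rname == cl, , drop = FALSE]
    counts <- matrix(0L, L, 5L)
    stops <- integer(L)
    if (nrow(sub) > 0L) {
      all_pos <- vector("list", nrow(sub))
      all_base <- vector("list", nrow(sub))
      for (i in seq_len(nrow(sub))) {
        w <- cigar_walk(sub$pos[i], sub$cigar[i], sub$seq[i])
        if (length(w$ref_pos) == 0L) next
        keep <- w$ref_pos >= 1L & w$ref_pos <= L
        all_pos[[i]] <- w$ref_pos[keep]
        all_base[[i]] <- w$bases[keep]
        p5 <- min(w$ref_pos)
        if (p5 >= 1L && p5 <= L) stops[p5] <- stops[p5] + 1L
      }
      pos_v <- unlist(all_pos)
      bi <- base_idx[unlist(all_base)]
      ok <- !is.na(bi)
      idx <- (bi[ok] - 1L) * L + pos_v[ok]
      counts <- matrix(tabulate(idx, nbins = 5L * L), L, 5L)
    }
    coverage <- as.integer(rowSums(counts))
    match_n <- counts[cbind(seq_len(L), base_idx[ref_chars])]
    tibble(
      cluster_id = cl, position = seq_len(L), ref_base = ref_chars,
      coverage = coverage, stop_count = stops,
      n_A = counts[, 1], n_C = counts[, 2], n_G = counts[, 3],
      n_T = counts[, 4], n_del = counts[, 5],
      mismatch_count = as.integer(coverage - counts[, 5] - match_n)
    )
  })
  out <- purrr::list_rbind(profiles)
  class(out) <- c("cluster_profiles", class(out))
  out
}

reference_seqs <- function(reference) {
  if (is.data.frame(reference)) {
    return(setNames(reference$mature_sequence, reference$cluster_id))
  }
  if (inherits(reference, "DNAStringSet")) {
    return(setNames(as.character(reference), names(reference)))
  }
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    s <- Biostrings::readDNAStringSet(reference)
    return(setNames(as.character(s), sub("\\s.*$", "", names(s))))
  }
  if (is.character(reference) && !is.null(names(reference))) {
    return(reference)
  }
  abort("reference must be a cluster tibble, named sequences, or FASTA path")
}

#' Add RTa intensity columns to a profile table
#'
#' The RTa intensity at position n is the fraction of reads covering n+1
#' whose 5' end is n+1 — reads arrested by a modification at n:
#' `stop_count(n+1) / coverage(n+1)`. Where `coverage(n+1)` is zero the
#' intensity is missing, not 0. `cov_next` records `coverage(n+1)` (the
#' read support behind the intensity) and `read_through` the complementary
#' literal ratio `coverage(n)/coverage(n+1)` as a debug column.
#'
#' @param profiles A `cluster_profiles` tibble.
#' @return The tibble with `rta`, `cov_next` and `read_through` appended;
#'   both are `NA` at the last position of each cluster.
#' @export
add_rta_intensity <- function(profiles) {
  grp <- intersect(c("sample_id", "cluster_id"), names(profiles))
  profiles |>
    group_by(dplyr::across(dplyr::all_of(grp))) |>
    arrange(.data$position, .by_group = TRUE) |>
    mutate(
      cov_next = lead(.data$coverage),
      rta = ifelse(.data$cov_next > 0,
                   lead(.data$stop_count) / .data$cov_next, NA_real_),
      read_through = ifelse(.data$cov_next > 0,
                            .data$coverage / .data$cov_next, NA_real_)
    ) |>
    ungroup()
}

#' RTa intensity at one position
#'
#' @param profiles A `cluster_profiles` tibble.
#' @param cluster_id Cluster to query.
#' @param n Position (modification site candidate); intensity uses the stop
#'   and coverage counts at n+1.
#' @return Fraction in \[0, 1\], or `NA` when `coverage(n+1)` is 0.
#' @export
rta_intensity <- function(profiles, cluster_id, n) {
  sub <- profiles[profiles$cluster_id == cluster_id, ]
  L <- max(sub$position)
  if (n < 1L || n >= L) abort(sprintf("position %d outside [1, L-1]", n))
  covn1 <- sub$coverage[sub$position == n + 1L]
  if (covn1 == 0L) return(NA_real_)
  sub$stop_count[sub$position == n + 1L] / covn1
}

#' Attach Sprinzl labels to a profile table
#'
#' @param profiles A `cluster_profiles` tibble.
#' @param sprinzl_map A `sprinzl_map` from [fit_sprinzl()].
#' @return Profiles with a `sprinzl_label` column (NA for unfittable
#'   clusters).
#' @export
label_profiles <- function(profiles, sprinzl_map) {
  profiles |>
    left_join(
      as_tibble(sprinzl_map)[, c("cluster_id", "mature_pos", "sprinzl_label")],
      by = c("cluster_id", "position" = "mature_pos")
    )
}

#' Write profiles as TSV
#' @param profiles A `cluster_profiles` tibble.
#' @param path Output path. Positions are 1-based.
#' @export
write_profiles <- function(profiles, path) {
  write_tsv_stable(as_tibble(profiles), path)
}
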