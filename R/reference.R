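# Mature tRNA cluster reference: splice introns, append CCA, deduplicate
# identical mature sequences. Reads are later mapped per cluster, so all
# downstream analysis is per group of indistinguishable mature tRNAs.

#' Read a tRNA gene annotation table
#'
#' Loads a tab-separated gene annotation (one row per tRNA gene) and, when the
#' table has no `sequence` column, extracts gene sequences from a genome FASTA
#' using the 1-based inclusive coordinates. Minus-strand genes are
#' reverse-complemented so `sequence` is always in gene orientation (5'->3').
#'
#' Expected columns: `gene_id`, `contig`, `start`, `end`, `strand` (+/-),
#' `isotype`, `anticodon`, `introns` (`.` or `s1-e1,s2-e2`, 1-based inclusive
#' intervals relative to the gene sequence), `origin`
#' (`nuclear`/`mitochondrial`), optionally `sequence`.
#'
#' @param genes_tsv Path to the annotation TSV.
#' @param genome_fasta Optional genome FASTA; required when the TSV carries no
#'   `sequence` column.
#' @return A tibble of validated genes with a list-column `intron_intervals`.
#' @export
read_trna_genes <- function(genes_tsv, genome_fasta = NULL) {
  genes <- read_tsv_quiet(genes_tsv, col_types = readr::cols(
    gene_id = "c", contig = "c", start = "i", end = "i", strand = "c",
    isotype = "c", anticodon = "c", introns = "c", origin = "c",
    .default = "c"
  ))
  if (!"sequence" %in% names(genes)) {
    if (is.null(genome_fasta)) {
      abort("annotation has no `sequence` column and no genome FASTA was given")
    }
    genome <- Biostrings::readDNAStringSet(genome_fasta)
    names(genome) <- sub("\\s.*$", "", names(genome))
    missing <- setdiff(unique(genes$contig), names(genome))
    if (length(missing) > 0L) {
      abort(paste0("contigs absent from genome FASTA: ",
                   paste(missing, collapse = ", ")))
    }
    seqs <- as.character(Biostrings::subseq(
      genome[genes$contig], start = genes$start, end = genes$end
    ))
    minus <- genes$strand == "-"
    seqs[minus] <- reverse_complement(seqs[minus])
    genes$sequence <- unname(seqs)
  }
  genes$intron_intervals <- lapply(genes$introns %||% rep(".", nrow(genes)),
                                   parse_intervals)
  genes$introns <- NULL
  validate_trna_genes(as_tibble(genes))
}

#' Validate a tRNA gene table
#'
#' Checks the invariants every downstream step relies on: unique gene ids,
#' ACGT sequences whose length matches the coordinates, sorted non-overlapping
#' intron intervals strictly inside the gene, and the annotated anticodon
#' occurring in the spliced sequence.
#'
#' @param genes A gene tibble as produced by [read_trna_genes()] or
#'   [simulate_genes()].
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_trna_genes <- function(genes) {
  required <- c("gene_id", "contig", "start", "end", "strand", "isotype",
                "anticodon", "origin", "sequence", "intron_intervals")
  miss <- setdiff(required, names(genes))
  if (length(miss) > 0L) {
    abort(paste0("gene table is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(genes$gene_id)) {
    dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
    abort(paste0("duplicate gene_ids: ", paste(head(dup, 3L), collapse = ", ")))
  }
  assert_dna(genes$sequence, "gene sequence")
  len_ok <- nchar(genes$sequence) == genes$end - genes$start + 1L
  if (!all(len_ok)) {
    abort(paste0("sequence length disagrees with coordinates for: ",
                 paste(head(genes$gene_id[!len_ok], 3L), collapse = ", ")))
  }
  if (!all(genes$strand %in% c("+", "-"))) abort("strand must be + or -")
  if (!all(genes$origin %in% c("nuclear", "mitochondrial"))) {
    abort("origin must be nuclear or mitochondrial")
  }
  for (i in seq_len(nrow(genes))) {
    check_introns(genes$intron_intervals[[i]], nchar(genes$sequence[i]),
                  genes$gene_id[i])
    spliced <- splice_introns(genes$sequence[i], genes$intron_intervals[[i]])
    if (!grepl(genes$anticodon[i], spliced, fixed = TRUE)) {
      abort(sprintf("anticodon %s not found in spliced sequence of %s",
                    genes$anticodon[i], genes$gene_id[i]))
    }
  }
  genes
}

check_introns <- function(intervals, gene_len, gene_id) {
  if (nrow(intervals) == 0L) return(invisible(TRUE))
  if (any(intervals[, 1] > intervals[, 2]) ||
      any(intervals[, 1] < 1L) || any(intervals[, 2] > gene_len)) {
    abort(sprintf("intron intervals out of range for gene %s", gene_id))
  }
  if (is.unsorted(intervals[, 1], strictly = TRUE) ||
      any(intervals[-1L, 1] <= intervals[-nrow(intervals), 2])) {
    abort(sprintf("intron intervals overlap or are unsorted for gene %s",
                  gene_id))
  }
  invisible(TRUE)
}

#' Excise intron intervals from a gene sequence
#'
#' @param sequence Gene-orientation nucleotide string.
#' @param intron_intervals Two-column matrix of 1-based inclusive intervals
#'   relative to `sequence`; must be sorted, non-overlapping and strictly
#'   inside the gene.
#' @param gene_id Used in error messages only.
#' @return The spliced sequence with intervals removed, order preserved.
#' @export
#' @examples
#' splice_introns("ACGTTTACGT", cbind(5L, 6L))  # "ACGTACGT"
splice_introns <- function(sequence, intron_intervals = NULL,
                           gene_id = "<gene>") {
  if (is.null(intron_intervals) || nrow(intron_intervals) == 0L) {
    return(sequence)
  }
  check_introns(intron_intervals, nchar(sequence), gene_id)
  keep_start <- c(1L, intron_intervals[, 2] + 1L)
  keep_end <- c(intron_intervals[, 1] - 1L, nchar(sequence))
  pieces <- substring(sequence, keep_start, keep_end)
  paste(pieces, collapse = "")
}

#' Append the 3'-CCA tail
#'
#' Mature tRNAs carry a 3'-terminal CCA that is usually not genomically
#' encoded. The tail is appended only when the spliced sequence does not
#' already end in CCA, so genomically encoded tails are not duplicated.
#'
#' @param spliced Spliced nucleotide string (uppercase ACGT, non-empty).
#' @return `spliced`, guaranteed to end in "CCA".
#' @export
append_cca <- function(spliced) {
  if (any(!nzchar(spliced))) abort("empty sequence cannot receive a CCA tail")
  assert_dna(spliced, "spliced sequence")
  ifelse(endsWith(spliced, "CCA"), spliced, paste0(spliced, "CCA"))
}

#' Cluster identical mature tRNA sequences
#'
#' Splices each gene, appends the CCA tail and groups genes whose mature
#' sequences are identical. Reads cannot distinguish members of a cluster, so
#' clusters are the unit of all downstream profiling. Nuclear and
#' mitochondrial genes are clustered separately even when sequences coincide.
#'
#' Cluster ids are deterministic: `isotype-anticodon-ordinal` (mitochondrial
#' clusters prefixed `mt-`), with ordinals assigned by lexicographic mature
#' sequence within an isotype/anticodon group.
#'
#' @param genes Validated gene tibble.
#' @return A tibble with one row per cluster: `cluster_id`, `mature_sequence`,
#'   `anticodon`, `isotype`, `origin`, `n_members`, list-column
#'   `member_gene_ids`.
#' @export
cluster_trnas <- function(genes) {
  genes <- validate_trna_genes(genes)
  if (nrow(genes) == 0L) {
    return(tibble(
      cluster_id = character(), mature_sequence = character(),
      anticodon = character(), isotype = character(), origin = character(),
      n_members = integer(), member_gene_ids = list()
    ))
  }
  mature <- vapply(seq_len(nrow(genes)), function(i) {
    append_cca(splice_introns(genes$sequence[i], genes$intron_intervals[[i]],
                              genes$gene_id[i]))
  }, character(1L))
  clusters <- genes |>
    mutate(mature_sequence = mature) |>
    group_by(.data$mature_sequence, .data$origin) |>
    summarise(
      anticodon = .data$anticodon[1L],
      isotype = .data$isotype[1L],
      n_members = dplyr::n(),
      member_gene_ids = list(sort(.data$gene_id)),
      .groups = "drop"
    ) |>
    arrange(.data$isotype, .data$anticodon, .data$origin,
            .data$mature_sequence) |>
    group_by(.data$isotype, .data$anticodon, .data$origin) |>
    mutate(cluster_id = sprintf(
      "%s%s-%s-%d", ifelse(.data$origin == "mitochondrial", "mt-", ""),
      .data$isotype, .data$anticodon, dplyr::row_number()
    )) |>
    ungroup() |>
    select("cluster_id", "mature_sequence", "anticodon", "isotype",
           "origin", "n_members", "member_gene_ids")
  stopifnot(sum(clusters$n_members) == nrow(genes))
  clusters
}

#' Write the mature cluster reference
#'
#' Writes the cluster sequences as FASTA (headers are cluster ids) and the
#' gene-to-cluster membership plus cluster metadata as TSV, so the reference
#' round-trips losslessly through [read_reference()].
#'
#' @param clusters Cluster tibble from [cluster_trnas()].
#' @param out_prefix Output path prefix; writes `<prefix>.fa` and
#'   `<prefix>.clusters.tsv`.
#' @return Invisibly, the two file paths.
#' @export
write_reference <- function(clusters, out_prefix) {
  fa <- paste0(out_prefix, ".fa")
  tsv <- paste0(out_prefix, ".clusters.tsv")
  seqs <- Biostrings::DNAStringSet(setNames(clusters$mature_sequence,
                                            clusters$cluster_id))
  Biostrings::writeXStringSet(seqs, fa)
  membership <- clusters |>
    mutate(member_gene_ids = vapply(.data$member_gene_ids, paste,
                                    character(1L), collapse = ",")) |>
    select("cluster_id", "mature_sequence", "anticodon", "isotype",
           "origin", "n_members", "member_gene_ids")
  write_tsv_stable(membership, tsv)
  invisible(c(fasta = fa, tsv = tsv))
}

#' Read a mature cluster reference written by [write_reference()]
#'
#' @param out_prefix The prefix passed to [write_reference()].
#' @return The cluster tibble.
#' @export
read_reference <- function(out_prefix) {
  fa <- paste0(out_prefix, ".fa")
  tsv <- paste0(out_prefix, ".clusters.tsv")
  for (p in c(fa, tsv)) {
    if (!file.exists(p)) abort(paste0("reference file not found: ", p))
  }
  seqs <- Biostrings::readDNAStringSet(fa)
  meta <- read_tsv_quiet(tsv)
  if (!setequal(names(seqs), meta$cluster_id)) {
    abort("FASTA headers and membership TSV disagree on cluster ids")
  }
  stopifnot(identical(
    as.character(seqs[meta$cluster_id]) |> unname(),
    meta$mature_sequence
  ))
  meta |>
    mutate(member_gene_ids = strsplit(.data$member_gene_ids, ",", fixed = TRUE)) |>
    as_tibble()
}
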