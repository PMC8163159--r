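# Deterministic generator of LOTTE-seq-like synthetic data: tRNA gene sets
# built on the cloverleaf consensus, 3'-anchored reads with planted
# arrest/misincorporation signatures, and the ground truth needed to score
# recovery. Reads are emitted both as FASTQ and as truth-aligned SAM so no
# aligner is needed downstream.

#' Simulation configuration
#'
#' Defaults emulate the study conditions: 421 tRNA genes collapsing into 70
#' clusters (55 cytosolic + 15 mitochondrial), read depths of a few hundred
#' per cluster, Q40 base qualities and a low background sequencing error.
#' The seed fully determines every output.
#'
#' @param n_clusters Distinct mature sequences to generate.
#' @param n_mito How many of them are mitochondrial.
#' @param n_genes Total gene count (multiplicities are distributed over
#'   clusters; every cluster keeps at least one gene).
#' @param n_mutations Per-cluster count of point differences from the
#'   consensus template (drawn uniformly from this range).
#' @param n_vloop_extra Range of extra variable-loop nucleotides.
#' @param intron_prob Probability that a cluster's genes carry an intron.
#' @param intron_len Intron length range (inserted 3' of the anticodon loop).
#' @param depth Mean reads per cluster; per-cluster depths are negative
#'   binomial with dispersion `depth_size`.
#' @param depth_size Negative-binomial size (smaller = more overdispersed
#'   expression).
#' @param background_error Per-base background substitution probability.
#' @param quality Constant Phred quality for simulated bases.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_clusters = 70, n_mito = 15, n_genes = 421,
                       n_mutations = c(1, 6), n_vloop_extra = c(0, 5),
                       intron_prob = 0.05, intron_len = c(8, 20),
                       depth = 200, depth_size = 5,
                       background_error = 0.001, quality = 40, seed = 1) {
  cfg <- list(
    n_clusters = n_clusters, n_mito = n_mito, n_genes = n_genes,
    n_mutations = n_mutations, n_vloop_extra = n_vloop_extra,
    intron_prob = intron_prob, intron_len = intron_len,
    depth = depth, depth_size = depth_size,
    background_error = background_error, quality = quality, seed = seed
  )
  stopifnot(cfg$n_genes >= cfg$n_clusters, cfg$n_mito < cfg$n_clusters)
  class(cfg) <- "sim_config"
  cfg
}

ANTICODONS <- c(
  "AGC", "GGC", "TGC", "ACG", "TCG", "GTT", "ATT", "GCA", "TGA", "AGA",
  "GGA", "TTC", "CTC", "GCC", "TCC", "GTG", "AAT", "GAT", "TAA", "CAA",
  "AAG", "TAG", "CTT", "TTT", "CAT", "GAA", "AGG", "TGG", "CTG", "TTG",
  "AGT", "GGT", "TGT", "CGT"
)

random_other_base <- function(base, n = length(base)) {
  vapply(base, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1L))
}

# One cloverleaf-compatible mature body (no CCA): consensus backbone,
# anticodon written onto 34-36, point mutations at non-conserved positions
# outside the anchors, optional extra variable-loop nucleotides after 45.
make_mature_body <- function(anticodon, n_mut, n_extra) {
  body <- strsplit(TEMPLATE_SEQ, "")[[1]][1:73]
  body[34:36] <- strsplit(anticodon, "")[[1]]
  mutable <- setdiff(which(!(seq_len(73L) %in% TEMPLATE_CONSERVED)),
                     33:37)
  if (n_mut > 0L) {
    at <- sample(mutable, n_mut)
    body[at] <- random_other_base(body[at])
  }
  if (n_extra > 0L) {
    ins <- sample(DNA_BASES, n_extra, replace = TRUE)
    body <- append(body, ins, after = 45L)
  }
  paste(body, collapse = "")
}

#' Simulate a tRNA gene set
#'
#' Generates `n_clusters` distinct mature sequences compatible with the
#' cloverleaf template (so Sprinzl fitting succeeds), distributes `n_genes`
#' gene copies over them, and optionally inserts introns 3' of the
#' anticodon loop. Gene sequences omit the CCA tail (it is appended during
#' clustering, as for genomic tRNA genes).
#'
#' @param config A [sim_config()].
#' @return A list: `genes` (validated gene tibble) and `truth` (one row per
#'   planted cluster: mature sequence, multiplicity, origin).
#' @export
simulate_genes <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_clusters
  anticodons <- sample(rep(ANTICODONS, length.out = n))
  origin <- c(rep("nuclear", n - config$n_mito),
              rep("mitochondrial", config$n_mito))
  bodies <- character(n)
  seen <- character(0)
  for (i in seq_len(n)) {
    repeat {
      b <- make_mature_body(
        anticodons[i],
        sample(config$n_mutations[1]:config$n_mutations[2], 1L),
        sample(config$n_vloop_extra[1]:config$n_vloop_extra[2], 1L)
      )
      key <- paste0(b, "|", origin[i])
      if (!key %in% seen) break
    }
    seen <- c(seen, key)
    bodies[i] <- b
  }
  extra <- config$n_genes - n
  mult <- rep(1L, n) + as.integer(rmultinom(1L, extra, rep(1, n)))
  isotype <- unname(Biostrings::GENETIC_CODE[
    reverse_complement(anticodons)
  ])
  isotype[is.na(isotype) | isotype == "*"] <- "X"
  rows <- list()
  offset <- c(nuclear = 0L, mitochondrial = 0L)
  for (i in seq_len(n)) {
    has_intron <- runif(1L) < config$intron_prob
    gene_seq <- bodies[i]
    introns <- matrix(integer(), ncol = 2L)
    if (has_intron) {
      ilen <- sample(config$intron_len[1]:config$intron_len[2], 1L)
      iseq <- paste(sample(DNA_BASES, ilen, replace = TRUE), collapse = "")
      at <- 37L  # 3' of the anticodon loop
      gene_seq <- paste0(substr(bodies[i], 1L, at), iseq,
                         substr(bodies[i], at + 1L, nchar(bodies[i])))
      introns <- matrix(c(at + 1L, at + ilen), ncol = 2L)
    }
    contig <- if (origin[i] == "nuclear") "chr1" else "chrM"
    for (k in seq_len(mult[i])) {
      start <- offset[[if (origin[i] == "nuclear") "nuclear"
                       else "mitochondrial"]] + 1L
      len <- nchar(gene_seq)
      rows[[length(rows) + 1L]] <- tibble(
        gene_id = sprintf("g%03d_%02d", i, k),
        contig = contig, start = start, end = start + len - 1L,
        strand = "+", isotype = isotype[i], anticodon = anticodons[i],
        origin = origin[i], sequence = gene_seq,
        intron_intervals = list(introns)
      )
      if (origin[i] == "nuclear") {
        offset[["nuclear"]] <- offset[["nuclear"]] + len + 50L
      } else {
        offset[["mitochondrial"]] <- offset[["mitochondrial"]] + len + 50L
      }
    }
  }
  genes <- validate_trna_genes(purrr::list_rbind(rows))
  truth <- tibble(
    cluster_index = seq_len(n),
    mature_sequence = append_cca(bodies),
    anticodon = anticodons, isotype = isotype, origin = origin,
    multiplicity = mult
  )
  list(genes = genes, truth = truth)
}

#' Plant modification truth on a cluster reference
#'
#' Chooses `sites_per_cluster` internal positions per cluster and assigns
#' each a stop probability, a misincorporation spectrum, or both, drawn
#' uniformly from the given ranges. Planted positions keep at least 4 nt
#' clearance from the 3' end so arrests remain observable.
#'
#' @param clusters Cluster tibble.
#' @param sites_per_cluster Planted sites per cluster.
#' @param stop_prob Range for planted stop probabilities (used for types
#'   `"rta"` and `"both"`).
#' @param mismatch_total Range for the total planted mismatch fraction
#'   (types `"mismatch"` and `"both"`); the fraction is split over the
#'   non-reference bases with one dominant target.
#' @param types Site types to cycle through.
#' @param min_gap Minimum spacing (nt) between planted sites within a
#'   cluster, so each planted signal stays independently measurable.
#' @param seed Integer seed.
#' @return A `sim_truth` tibble: `cluster_id`, `position`,
#'   `planted_modification_code`, `type`, `stop_prob`, `mis_A..mis_T`.
#' @export
simulate_truth <- function(clusters, sites_per_cluster = 3,
                           stop_prob = c(0.3, 0.9),
                           mismatch_total = c(0.2, 0.8),
                           types = c("rta", "mismatch", "both"),
                           min_gap = 4, seed = 1) {
  set.seed(seed)
  rows <- purrr::map(seq_len(nrow(clusters)), function(i) {
    L <- nchar(clusters$mature_sequence[i])
    ref <- strsplit(clusters$mature_sequence[i], "")[[1]]
    repeat {
      pos <- sort(sample(10:(L - 6L), sites_per_cluster))
      if (sites_per_cluster < 2L || all(diff(pos) >= min_gap)) break
    }
    purrr::map(seq_along(pos), function(k) {
      type <- types[(k - 1L) %% length(types) + 1L]
      sp <- if (type %in% c("rta", "both")) {
        runif(1L, stop_prob[1], stop_prob[2])
      } else 0
      mis <- setNames(rep(0, 4L), DNA_BASES)
      if (type %in% c("mismatch", "both")) {
        total <- runif(1L, mismatch_total[1], mismatch_total[2])
        target <- sample(setdiff(DNA_BASES, ref[pos[k]]), 1L)
        mis[target] <- total * 0.9
        minor <- setdiff(DNA_BASES, c(ref[pos[k]], target))
        mis[minor] <- total * 0.1 / length(minor)
      }
      tibble(
        cluster_id = clusters$cluster_id[i], position = pos[k],
        planted_modification_code = paste0("sim_", type), type = type,
        stop_prob = sp,
        mis_A = mis[["A"]], mis_C = mis[["C"]], mis_G = mis[["G"]],
        mis_T = mis[["T"]]
      )
    }) |> purrr::list_rbind()
  })
  out <- purrr::list_rbind(rows)
  class(out) <- c("sim_truth", class(out))
  out
}

#' Simulate 3'-anchored reads with planted RT signatures
#'
#' Every read starts at the 3' CCA end of its cluster. Walking 5'-ward, the
#' reverse transcriptase arrests at each planted site with the site's stop
#' probability (the read's 5'-most base becomes site+1); at planted sites it
#' reads through, a base is misincorporated per the site's spectrum.
#' Background substitutions are applied at `background_error` per base.
#' Reads are returned as an alignment tibble (correct by construction) and
#' optionally written as SAM, FASTQ and truth TSV.
#'
#' @param clusters Cluster tibble.
#' @param truth A `sim_truth` tibble ([simulate_truth()]), or `NULL` for
#'   none (negative control).
#' @param config A [sim_config()]; `depth`, `depth_size`,
#'   `background_error`, `quality` and `seed` are used.
#' @param out_dir If non-`NULL`, writes `reads.sam`, `reads.fastq`,
#'   `truth.tsv` there.
#' @param depths Optional named per-cluster read counts overriding the
#'   depth distribution.
#' @return A list: `alignments` (tibble `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `seq`, `multi`), `depths`, `truth`, and `paths` when
#'   written.
#' @export
simulate_reads <- function(clusters, truth = NULL, config = sim_config(),
                           out_dir = NULL, depths = NULL) {
  set.seed(config$seed)
  if (is.null(truth)) {
    truth <- simulate_truth(clusters, seed = config$seed)[0, ]
  }
  if (is.null(depths)) {
    depths <- setNames(
      rnbinom(nrow(clusters), size = config$depth_size,
              mu = config$depth) + 1L,
      clusters$cluster_id
    )
  }
  all_rows <- purrr::map(seq_len(nrow(clusters)), function(i) {
    cl <- clusters$cluster_id[i]
    ref <- strsplit(clusters$mature_sequence[i], "")[[1]]
    L <- length(ref)
    sites <- truth[truth$cluster_id == cl, , drop = FALSE]
    sites <- sites[order(-sites$position), , drop = FALSE]
    nreads <- depths[[cl]]
    if (is.na(nreads) || nreads == 0L) return(NULL)
    starts <- integer(nreads)
    seqs <- character(nreads)
    for (r in seq_len(nreads)) {
      s <- 1L
      if (nrow(sites) > 0L) {
        stopped <- runif(nrow(sites)) < sites$stop_prob
        hit <- which(stopped)
        if (length(hit) > 0L) s <- sites$position[hit[1L]] + 1L
      }
      bases <- ref[s:L]
      if (nrow(sites) > 0L) {
        covered <- which(sites$position >= s)
        for (j in covered) {
          p <- c(sites$mis_A[j], sites$mis_C[j], sites$mis_G[j],
                 sites$mis_T[j])
          u <- runif(1L)
          cum <- cumsum(p)
          pick <- which(u < cum)
          if (length(pick) > 0L) {
            bases[sites$position[j] - s + 1L] <- DNA_BASES[pick[1L]]
          }
        }
      }
      if (config$background_error > 0) {
        err <- which(runif(length(bases)) < config$background_error)
        if (length(err) > 0L) {
          bases[err] <- random_other_base(bases[err])
        }
      }
      starts[r] <- s
      seqs[r] <- paste(bases, collapse = "")
    }
    tibble(
      qname = sprintf("%s_r%05d", cl, seq_len(nreads)),
      flag = 0L, rname = cl, pos = starts, mapq = 60L,
      cigar = sprintf("%dM", L - starts + 1L), seq = seqs, multi = FALSE
    )
  })
  aln <- purrr::list_rbind(all_rows)
  out <- list(alignments = aln, depths = depths, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    sam <- file.path(out_dir, "reads.sam")
    fastq <- file.path(out_dir, "reads.fastq")
    truth_tsv <- file.path(out_dir, "truth.tsv")
    write_sam(aln, clusters, sam, quality = config$quality)
    write_sim_fastq(aln, fastq, quality = config$quality)
    write_tsv_stable(as_tibble(truth), truth_tsv)
    out$paths <- c(sam = sam, fastq = fastq, truth = truth_tsv)
  }
  out
}

#' Write an alignment tibble as SAM
#'
#' @param alignments Tibble with `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `seq`.
#' @param reference Cluster tibble / named sequences for the `@SQ` header.
#' @param path Output SAM path.
#' @param quality Constant Phred quality used for the QUAL field.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(alignments, reference, path, quality = 40) {
  seqs <- reference_seqs(reference)
  hdr <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(seqs), nchar(seqs))
  )
  qchar <- rawToChar(as.raw(quality + 33L))
  body <- if (nrow(alignments) > 0L) {
    sprintf(
      "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNH:i:1",
      alignments$qname, alignments$flag, alignments$rname,
      alignments$pos, alignments$mapq, alignments$cigar, alignments$seq,
      vapply(nchar(alignments$seq),
             function(n) strrep(qchar, n), character(1L))
    )
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

write_sim_fastq <- function(alignments, path, quality = 40) {
  qchar <- rawToChar(as.raw(quality + 33L))
  if (nrow(alignments) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- as.vector(rbind(
    paste0("@", alignments$qname),
    alignments$seq,
    "+",
    vapply(nchar(alignments$seq),
           function(n) strrep(qchar, n), character(1L))
  ))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a developmental time course
#'
#' One sample per time label, with independently drawn per-cluster depths
#' and (optionally) per-sample stop-probability scale factors, mirroring a
#' five-point starvation time course.
#'
#' @param clusters Cluster tibble.
#' @param truth Base `sim_truth`.
#' @param config A [sim_config()]; per-sample seeds are derived from
#'   `config$seed`.
#' @param time_labels Sample time labels.
#' @param stop_scale Optional named numeric (per time label) multiplying the
#'   planted stop probabilities (capped at 1); models presence/absence
#'   dynamics.
#' @param out_dir If non-`NULL`, writes per-sample subdirectories and a
#'   `manifest.tsv`.
#' @return A list: `samples` (named list of [simulate_reads()] results) and
#'   `manifest` tibble.
#' @export
simulate_timecourse <- function(clusters, truth, config = sim_config(),
                                time_labels = c("0h", "6h", "16h", "20h",
                                                "24h"),
                                stop_scale = NULL, out_dir = NULL) {
  samples <- list()
  manifest <- list()
  for (k in seq_along(time_labels)) {
    lab <- time_labels[k]
    cfg_k <- config
    cfg_k$seed <- config$seed + 1000L * k
    truth_k <- truth
    if (!is.null(stop_scale) && lab %in% names(stop_scale)) {
      truth_k$stop_prob <- pmin(1, truth_k$stop_prob * stop_scale[[lab]])
    }
    dir_k <- if (is.null(out_dir)) NULL else file.path(out_dir, lab)
    samples[[lab]] <- simulate_reads(clusters, truth_k, cfg_k,
                                     out_dir = dir_k)
    manifest[[k]] <- tibble(
      sample_id = paste0("s_", lab), time_label = lab,
      sam = if (is.null(dir_k)) NA_character_
            else file.path(dir_k, "reads.sam")
    )
  }
  manifest <- purrr::list_rbind(manifest)
  if (!is.null(out_dir)) {
    write_tsv_stable(manifest, file.path(out_dir, "manifest.tsv"))
  }
  list(samples = samples, manifest = manifest)
}
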