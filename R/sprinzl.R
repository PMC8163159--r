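# Sprinzl standard numbering by alignment to a packaged consensus template.
# The highest-scoring global fit of a mature sequence to the labelled template
# columns defines the numbering; the terminal CCA is anchored onto 74-76 and,
# when the anticodon is known, a score bonus pulls it onto 34-36.

# Canonical 76-column cloverleaf consensus (yeast tRNA-Phe backbone, DNA
# alphabet, positions 1..76 one per column). Weight 2 marks positions that are
# near-universally conserved across cytosolic tRNAs.
TEMPLATE_SEQ <- "GCGGATTTAGCTCAGTTGGGAGAGCGCCAGACTGAAGATCTGGAGGTCCTGTGTTCGATCCACAGAATTCGCACCA"
TEMPLATE_STRUCT <- "(((((((..((((........)))).(((((.......))))).....(((((.......))))))))))))...."
TEMPLATE_CONSERVED <- c(8L, 14L, 18L, 19L, 21L, 33L, 53L, 54L, 55L, 56L,
                        58L, 61L, 74L, 75L, 76L)

#' Sprinzl consensus template
#'
#' Returns the packaged cloverleaf consensus used to assign standard position
#' labels 1..76. Each column carries a consensus base and a conservation
#' weight; the secondary structure (dot-bracket, pairing acceptor, D,
#' anticodon and T stems) is attached as an attribute. The mitochondrial
#' template shares the columns but down-weights conservation, since
#' mitochondrial tRNAs frequently deviate from the canonical cloverleaf.
#'
#' @param domain `"cytosolic"` or `"mitochondrial"`.
#' @return A tibble with columns `label`, `base`, `weight`; attributes
#'   `structure` and `domain`. Class `sprinzl_template`.
#' @export
sprinzl_template <- function(domain = c("cytosolic", "mitochondrial")) {
  domain <- match.arg(domain)
  bases <- strsplit(TEMPLATE_SEQ, "")[[1]]
  stopifnot(length(bases) == 76L)
  weight <- rep(1, 76L)
  weight[TEMPLATE_CONSERVED] <- 2
  if (domain == "mitochondrial") weight <- pmin(weight, 1.25)
  tpl <- tibble(label = as.character(1:76), base = bases, weight = weight)
  attr(tpl, "structure") <- TEMPLATE_STRUCT
  attr(tpl, "domain") <- domain
  class(tpl) <- c("sprinzl_template", class(tpl))
  tpl
}

# Affine-gap global alignment of sequence characters against template
# columns. Returns for each sequence position the consumed template column
# (NA = insertion relative to the template). Deterministic traceback prefers
# substitution over deletion over insertion.
align_to_columns <- function(seq_chars, tpl_bases, tpl_weight,
                             match = 2, mismatch = -1,
                             gap_open = 5, gap_extend = 1,
                             bonus = NULL) {
  n <- length(seq_chars)
  m <- length(tpl_bases)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)  # ends in substitution
  X <- matrix(NEG, n + 1L, m + 1L)  # ends in gap-in-template (insertion)
  Y <- matrix(NEG, n + 1L, m + 1L)  # ends in gap-in-sequence (deletion)
  M[1L, 1L] <- 0
  if (n >= 1L) X[2:(n + 1L), 1L] <- -gap_open - gap_extend * (0:(n - 1L))
  if (m >= 1L) Y[1L, 2:(m + 1L)] <- -gap_open - gap_extend * (0:(m - 1L))
  sub_score <- function(i, j) {
    s <- if (seq_chars[i] == tpl_bases[j]) match * tpl_weight[j]
         else mismatch * tpl_weight[j]
    if (!is.null(bonus)) s <- s + bonus[i, j]
    s
  }
  for (i in 1:n) {
    for (j in 1:m) {
      best_prev <- max(M[i, j], X[i, j], Y[i, j])
      M[i + 1L, j + 1L] <- best_prev + sub_score(i, j)
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - gap_open,
                               X[i, j + 1L] - gap_extend)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - gap_open,
                               Y[i + 1L, j] - gap_extend)
    }
  }
  score <- max(M[n + 1L, m + 1L], Y[n + 1L, m + 1L], X[n + 1L, m + 1L])
  # traceback
  state <- which.max(c(M[n + 1L, m + 1L], Y[n + 1L, m + 1L],
                       X[n + 1L, m + 1L]))  # 1=M, 2=Y, 3=X
  i <- n; j <- m
  col_of <- rep(NA_integer_, n)
  while (i > 0L || j > 0L) {
    if (state == 1L) {
      col_of[i] <- j
      prev <- c(M[i, j], Y[i, j], X[i, j])
      i <- i - 1L; j <- j - 1L
      state <- which.max(prev)
    } else if (state == 2L) {  # gap in sequence: template col j unmatched
      open_sc <- M[i + 1L, j] - gap_open
      ext_sc <- Y[i + 1L, j] - gap_extend
      j <- j - 1L
      state <- if (open_sc >= ext_sc) 1L else 2L
    } else {                   # gap in template: seq position i is insertion
      open_sc <- M[i, j + 1L] - gap_open
      ext_sc <- X[i, j + 1L] - gap_extend
      i <- i - 1L
      state <- if (open_sc >= ext_sc) 1L else 3L
    }
    if (i == 0L && j == 0L) break
    if (i == 0L) state <- 2L
    if (j == 0L) state <- 3L
  }
  list(col_of = col_of, score = score)
}

# Name the insertion columns created when a sequence carries more nucleotides
# than the canonical template: 17a after 17; 20a/20b (then 20b1, 20b2, ...)
# after 20; e1..eN in the variable loop (after columns 44-47); elsewhere
# "<label>i<k>".
insertion_labels <- function(prev_label, k) {
  if (prev_label == "17") {
    if (k == 1L) return("17a")
    return(paste0("17a", k - 1L))
  }
  if (prev_label == "20") {
    if (k == 1L) return("20a")
    if (k == 2L) return("20b")
    return(paste0("20b", k - 2L))
  }
  if (prev_label == "45") return(paste0("e", k))
  paste0(prev_label, "i", k)
}

#' Fit one mature sequence to the Sprinzl template
#'
#' Global affine-gap alignment of the sequence (minus its anchored 3'-CCA)
#' against template columns 1..73; every aligned position receives the label
#' of its column, insertions receive derived labels (17a, 20a/20b, e1..eN).
#' The terminal C, C, A are forced onto 74, 75, 76. If an anticodon is given,
#' a score bonus favours placing it on columns 34-36.
#'
#' @param mature_sequence Nucleotide string ending in "CCA", length 60-120.
#' @param template A [sprinzl_template()].
#' @param anticodon Optional 3-mer used to anchor columns 34-36.
#' @param min_score Alignments scoring below this floor are flagged
#'   unfittable (labels all NA) rather than mislabelled.
#' @param match,mismatch,gap_open,gap_extend Alignment scores; defaults make
#'   canonical tRNAs align gap-free.
#' @return Tibble `mature_pos`, `base`, `sprinzl_label` with attributes
#'   `score` and `unfittable`.
#' @export
fit_to_template <- function(mature_sequence, template = sprinzl_template(),
                            anticodon = NULL, min_score = 60,
                            match = 2, mismatch = -1,
                            gap_open = 5, gap_extend = 1) {
  assert_dna(mature_sequence, "mature sequence")
  L <- nchar(mature_sequence)
  if (!endsWith(mature_sequence, "CCA")) {
    abort("mature sequence must end in CCA")
  }
  if (L < 60L || L > 120L) {
    abort(sprintf("mature sequence length %d outside [60, 120]", L))
  }
  seq_chars <- strsplit(mature_sequence, "")[[1]]
  body <- seq_chars[1:(L - 3L)]
  tpl_body <- template[1:73, ]
  bonus <- NULL
  if (!is.null(anticodon)) {
    ac <- strsplit(anticodon, "")[[1]]
    stopifnot(length(ac) == 3L)
    bonus <- matrix(0, length(body), 73L)
    for (k in 1:3) {
      bonus[body == ac[k], 33L + k] <- 10
    }
  }
  aln <- align_to_columns(body, tpl_body$base, tpl_body$weight,
                          match, mismatch, gap_open, gap_extend, bonus)
  labels <- rep(NA_character_, L)
  if (aln$score >= min_score) {
    ins_count <- 0L
    prev_label <- "0"
    for (i in seq_along(body)) {
      j <- aln$col_of[i]
      if (is.na(j)) {
        ins_count <- ins_count + 1L
        labels[i] <- insertion_labels(prev_label, ins_count)
      } else {
        ins_count <- 0L
        labels[i] <- tpl_body$label[j]
        prev_label <- tpl_body$label[j]
      }
    }
    # renumber variable-loop insertions e1..eN in order across the loop
    e_idx <- grepl("^e[0-9]+$", labels)
    if (any(e_idx)) labels[e_idx] <- paste0("e", seq_len(sum(e_idx)))
    labels[(L - 2L):L] <- c("74", "75", "76")
  }
  out <- tibble(
    mature_pos = seq_len(L),
    base = seq_chars,
    sprinzl_label = labels
  )
  attr(out, "score") <- aln$score
  attr(out, "unfittable") <- aln$score < min_score
  out
}

#' Assign Sprinzl numbering to every cluster of a reference
#'
#' @param clusters Cluster tibble from [cluster_trnas()] (or any tibble with
#'   `cluster_id`, `mature_sequence`, optionally `anticodon` and `origin`).
#' @param min_score Score floor below which a cluster is flagged unfittable;
#'   unfittable clusters keep NA labels and stay analyzable by raw position.
#' @inheritParams fit_to_template
#' @return A `sprinzl_map` tibble: `cluster_id`, `mature_pos`, `base`,
#'   `sprinzl_label`; per-cluster scores in `attr(, "scores")`.
#' @export
fit_sprinzl <- function(clusters, min_score = 60, ...) {
  use_ac <- "anticodon" %in% names(clusters)
  domain_of <- function(origin) {
    if (identical(origin, "mitochondrial")) "mitochondrial" else "cytosolic"
  }
  maps <- purrr::map(seq_len(nrow(clusters)), function(i) {
    tpl <- sprinzl_template(domain_of(clusters$origin[i] %||% "nuclear"))
    m <- fit_to_template(
      clusters$mature_sequence[i], template = tpl,
      anticodon = if (use_ac) clusters$anticodon[i] else NULL,
      min_score = min_score, ...
    )
    tibble(cluster_id = clusters$cluster_id[i], m,
           .score = attr(m, "score"), .unfittable = attr(m, "unfittable"))
  })
  out <- purrr::list_rbind(maps)
  scores <- out |>
    distinct(.data$cluster_id, score = .data$.score,
             unfittable = .data$.unfittable)
  out <- out |> select(-".score", -".unfittable")
  attr(out, "scores") <- scores
  class(out) <- c("sprinzl_map", class(out))
  out
}

#' Invert a Sprinzl map: label to mature position
#'
#' @param map A `sprinzl_map` (or the single-sequence tibble from
#'   [fit_to_template()]).
#' @param label Sprinzl label string, e.g. `"58"` or `"20a"`.
#' @param cluster_id Required when `map` covers several clusters.
#' @return The 1-based mature position, or `NA` when the label is absent.
#' @export
sprinzl_invert <- function(map, label, cluster_id = NULL) {
  if (!is.null(cluster_id)) {
    map <- map[map$cluster_id == cluster_id, , drop = FALSE]
  }
  hit <- map$mature_pos[!is.na(map$sprinzl_label) &
                          map$sprinzl_label == label]
  if (length(hit) == 0L) return(NA_integer_)
  hit[1L]
}

#' Write a Sprinzl map as TSV (cluster_id, mature_pos, sprinzl_label)
#' @param map A `sprinzl_map`.
#' @param path Output TSV path.
#' @export
write_sprinzl <- function(map, path) {
  write_tsv_stable(
    as_tibble(map)[, c("cluster_id", "mature_pos", "base", "sprinzl_label")],
    path
  )
}
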