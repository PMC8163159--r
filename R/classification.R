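# Classify candidate sites by their RT signature (reference base, arrest
# requirement, dominant mismatch targets, intensity class) and rank
# candidates using a catalogue of modifications known at homologous Sprinzl
# positions in other species. Classification never drops a call: sites
# matching no rule are reported as "unknown" with their observed signature.

#' Default RT-signature rule table
#'
#' Curated reconstruction of the arrest/misincorporation signatures visible
#' in untreated TGIRT tRNA-seq data: m1A reads as A-to-T/A-to-G mismatches
#' with arrest; inosine as a pure A-to-G mismatch without arrest; m1G, m2G
#' and m22G as G mismatches with arrest; m3C as arrest with C mismatches;
#' dihydrouridine as a weak signal at U; 2'-O-methylations (Cm, Gm) as weak
#' arrest without a dominant mismatch; position-37 adenosine hypermods
#' (t6A, i6A, ms2i6A, m6t6A) as arrest-dominant. User tables with the same
#' columns can replace it.
#'
#' Columns: `rule_id`, `ref_base`, `requires_rta` (yes/no/optional),
#' `mismatch_targets` (e.g. `"T,G"`; `"."` = the modification shows no
#' dominant misincorporation, so confident mismatch evidence rules it out),
#' `intensity_class` (weak/strong/any), `modification_codes`
#' (pipe-separated), `provenance`.
#'
#' @return A tibble of signature rules.
#' @export
signature_rules <- function() {
  tibble::tribble(
    ~rule_id, ~ref_base, ~requires_rta, ~mismatch_targets, ~intensity_class,
      ~modification_codes, ~provenance,
    "m1A",      "A", "yes",      "T,G", "any",    "m1A",                 "curated",
    "inosine",  "A", "no",       "G",   "any",    "I",                   "curated",
    "m1I",      "A", "yes",      "G",   "any",    "m1I",                 "curated",
    "A37-hyper","A", "yes",      ".",   "strong", "t6A|i6A|ms2i6A|m6t6A","curated",
    "mG-methyl","G", "yes",      "A,C,T","any",   "m1G|m2G|m22G",        "curated",
    "Gm",       "G", "optional", ".",   "weak",   "Gm",                  "curated",
    "m3C",      "C", "yes",      "T,A,G","any",   "m3C",                 "curated",
    "Cm",       "C", "optional", ".",   "weak",   "Cm",                  "curated",
    "D",        "T", "optional", ".",   "weak",   "D",                   "curated"
  )
}

#' Default known-position catalogue
#'
#' Sprinzl position / reference base pairs with modifications reported at
#' homologous positions in other species, used to rank signature-compatible
#' candidates. Ambiguous identities are preserved verbatim (e.g.
#' `"m2G|m22G"`).
#'
#' @return A tibble: `sprinzl_label`, `ref_base`, `known_modifications`,
#'   `provenance`.
#' @export
position_catalogue <- function() {
  tibble::tribble(
    ~sprinzl_label, ~ref_base, ~known_modifications, ~provenance,
    "9",   "G", "m1G",                          "catalogue",
    "10",  "G", "m2G|m22G",                     "catalogue",
    "20",  "T", "D",                            "catalogue",
    "20a", "T", "D",                            "catalogue",
    "26",  "G", "m2G|m22G",                     "catalogue",
    "32",  "C", "Cm|m3C",                       "catalogue",
    "34",  "A", "I",                            "catalogue",
    "34",  "G", "Gm",                           "catalogue",
    "37",  "G", "m1G|m2G|Gm",                   "catalogue",
    "37",  "A", "t6A|i6A|ms2i6A|m6t6A",         "catalogue",
    "46",  "G", "m1G",                          "catalogue",
    "47",  "T", "D",                            "catalogue",
    "58",  "A", "m1A",                          "catalogue",
    "60",  "A", "m1A",                          "catalogue"
  )
}

#' Load a signature rule table from TSV (or the packaged default)
#'
#' @param path TSV with the [signature_rules()] columns; `NULL` loads the
#'   packaged default. Rule invariants (non-empty codes, valid fields) are
#'   validated.
#' @return A tibble of rules.
#' @export
load_signature_table <- function(path = NULL) {
  rules <- if (is.null(path)) signature_rules() else read_tsv_quiet(path)
  required <- c("rule_id", "ref_base", "requires_rta", "mismatch_targets",
                "intensity_class", "modification_codes", "provenance")
  miss <- setdiff(required, names(rules))
  if (length(miss) > 0L) {
    abort(paste0("signature table missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  stopifnot(
    all(rules$ref_base %in% DNA_BASES),
    all(rules$requires_rta %in% c("yes", "no", "optional")),
    all(rules$intensity_class %in% c("weak", "strong", "any")),
    all(nzchar(rules$modification_codes))
  )
  as_tibble(rules)
}

#' Load a known-position catalogue from TSV (or the packaged default)
#' @param path TSV with the [position_catalogue()] columns, or `NULL`.
#' @return A tibble catalogue.
#' @export
load_catalogue <- function(path = NULL) {
  cat <- if (is.null(path)) position_catalogue() else read_tsv_quiet(path)
  miss <- setdiff(c("sprinzl_label", "ref_base", "known_modifications"),
                  names(cat))
  if (length(miss) > 0L) {
    abort(paste0("catalogue missing columns: ", paste(miss, collapse = ", ")))
  }
  as_tibble(cat)
}

rule_matches <- function(rule, ref_base, has_rta, has_mismatch,
                         dominant_mismatch, intensity, weak_cut) {
  if (rule$ref_base != ref_base) return(FALSE)
  if (rule$requires_rta == "yes" && !has_rta) return(FALSE)
  if (rule$requires_rta == "no" && has_rta) return(FALSE)
  targets <- rule$mismatch_targets
  if (identical(targets, ".")) {
    # modifications without a dominant misincorporation are incompatible
    # with confident mismatch evidence
    if (has_mismatch) return(FALSE)
  } else {
    tset <- strsplit(targets, ",", fixed = TRUE)[[1]]
    if (!has_mismatch || is.na(dominant_mismatch) ||
        !dominant_mismatch %in% tset) {
      return(FALSE)
    }
  }
  if (rule$intensity_class != "any") {
    inten <- if (is.na(intensity)) 0 else intensity
    if (rule$intensity_class == "weak" && inten >= weak_cut) return(FALSE)
    if (rule$intensity_class == "strong" && inten < weak_cut) return(FALSE)
  }
  TRUE
}

#' Classify modification calls
#'
#' For each call, collects the modification codes of every compatible
#' signature rule, then ranks them: codes also catalogued at the call's
#' Sprinzl position and base come first, signature-only codes after.
#' Ambiguous identity sets stay verbatim (`"m2G|m22G"`). Calls matching no
#' rule get identity `"unknown"` with the observed signature attached.
#' Suppressed calls are carried through unclassified.
#'
#' @param calls A `mod_calls` tibble (ideally Sprinzl-labelled).
#' @param rules Signature rule tibble ([load_signature_table()]).
#' @param catalogue Known-position tibble ([load_catalogue()]).
#' @param weak_cut Intensity boundary between "weak" and "strong" arrest
#'   classes.
#' @return `calls` with `candidate_identities` (pipe-separated, ranked),
#'   `top_identity` and `novelty` columns.
#' @export
classify_calls <- function(calls, rules = load_signature_table(),
                           catalogue = load_catalogue(), weak_cut = 0.4) {
  has_label <- "sprinzl_label" %in% names(calls)
  res <- purrr::map(seq_len(nrow(calls)), function(i) {
    row <- calls[i, ]
    label <- if (has_label) row$sprinzl_label else NA_character_
    matched <- purrr::map_lgl(seq_len(nrow(rules)), function(r) {
      rule_matches(rules[r, ], row$ref_base, isTRUE(row$evidence_rta),
                   isTRUE(row$evidence_mismatch),
                   row$dominant_mismatch %||% NA_character_,
                   row$rta_intensity %||% NA_real_, weak_cut)
    })
    codes <- rules$modification_codes[matched]
    known <- catalogue$known_modifications[
      !is.na(label) & catalogue$sprinzl_label == label &
        catalogue$ref_base == row$ref_base
    ]
    in_cat <- codes[codes %in% known |
                      vapply(codes, function(cd) {
                        any(strsplit(cd, "|", fixed = TRUE)[[1]] %in%
                              unlist(strsplit(known, "|", fixed = TRUE)))
                      }, logical(1L))]
    ranked <- unique(c(in_cat, codes))
    if (length(ranked) == 0L) {
      sig <- paste0(
        row$ref_base,
        if (isTRUE(row$evidence_mismatch) && !is.na(row$dominant_mismatch))
          paste0(">", row$dominant_mismatch) else "",
        if (isTRUE(row$evidence_rta)) "+RTa" else ""
      )
      ranked <- paste0("unknown[", sig, "]")
    }
    novelty <- if (is.na(label)) {
      "novel_position(unlabeled)"
    } else if (any(catalogue$sprinzl_label == label &
                     catalogue$ref_base == row$ref_base)) {
      "known_position"
    } else {
      "novel_position"
    }
    tibble(candidate_identities = paste(ranked, collapse = "|"),
           top_identity = strsplit(ranked[1L], "|", fixed = TRUE)[[1]][1L],
           novelty = novelty)
  })
  out <- bind_cols(calls, purrr::list_rbind(res))
  class(out) <- unique(c("mod_calls", class(out)))
  out
}

#' Known/novel position flag for a single call
#'
#' @param sprinzl_label Sprinzl label (or `NA` for unlabeled calls).
#' @param ref_base Reference base at the call.
#' @param catalogue Known-position tibble.
#' @return `"known_position"`, `"novel_position"`, or
#'   `"novel_position(unlabeled)"`.
#' @export
novelty_flag <- function(sprinzl_label, ref_base,
                         catalogue = load_catalogue()) {
  if (is.na(sprinzl_label)) return("novel_position(unlabeled)")
  hit <- any(catalogue$sprinzl_label == sprinzl_label &
               catalogue$ref_base == ref_base)
  if (hit) "known_position" else "novel_position"
}

#' Write the packaged signature and catalogue tables as TSV
#'
#' Written tables reload byte-identically through [load_signature_table()] /
#' [load_catalogue()].
#'
#' @param dir Output directory.
#' @return Invisibly, the two paths.
#' @export
write_default_tables <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig <- file.path(dir, "signature_rules.tsv")
  cat <- file.path(dir, "position_catalogue.tsv")
  write_tsv_stable(signature_rules(), sig)
  write_tsv_stable(position_catalogue(), cat)
  invisible(c(signatures = sig, catalogue = cat))
}
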