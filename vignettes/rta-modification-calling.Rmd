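---
title: "Calling tRNA modifications from RT arrest and misincorporation signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling tRNA modifications from RT arrest and misincorporation signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtamod)
library(dplyr)
```

## The measurement model

Many tRNA nucleotide modifications perturb reverse transcription in
chemically untreated tRNA-seq libraries and therefore leave *RT
signatures* in mapped reads. Two channels carry the signal:

* **RT arrest (RTa).** A modification at position $n$ can block cDNA
  synthesis so that the read terminates immediately 3′ of it. In a
  3′-anchored library (hairpin adapter ligated to the CCA end, as in
  LOTTE-seq) this produces a pile-up of read 5′ ends at $n+1$. The **RTa
  intensity** at $n$ is the fraction of reads covering $n+1$ whose 5′-most
  aligned base is $n+1$:
  $$\mathrm{RTa}(n) \;=\; \frac{\mathrm{stops}(n+1)}{\mathrm{cov}(n+1)}.$$
  Because all reads share the 3′ anchor, coverage is non-increasing
  towards the 5′ end and the intensity is equivalently
  $1 - \mathrm{cov}(n)/\mathrm{cov}(n+1)$; the package asserts both
  formulations on simulated data and exposes the complementary
  read-through ratio as a debug column.

* **Misincorporation.** Some modifications cause the RT to insert a
  non-templated base (e.g. 1-methyladenosine read as A→T/A→G; inosine
  read as A→G), visible as a mapped mismatch. Mismatch counts are tested
  against a null in which sequencing errors arise independently at rate
  $\varepsilon$ per base: the site confidence is the Phred-scaled upper
  binomial tail $-10\log_{10} P(X \ge k \mid \mathrm{cov}, \varepsilon)$,
  capped at 1000.

A site is emitted when either channel passes its threshold; both flags are
recorded, since the combination of arrest and misincorporation is what
allows classification.

## Operating point

All defaults are centralised in `run_config()`:

| parameter | default | unit | role |
|---|---|---|---|
| `min_intensity` | 0.20 | fraction | RTa call threshold (≥) |
| `min_reads` | 10 | reads | minimum support at the measured position |
| `min_conf_phred` | 20 | Phred | mismatch-confidence threshold (≥) |
| `error_rate` | 0.01 | /base | binomial null for mismatches |
| `tgirt_window` | 3 | nt | artifact window, 3′ of a primary arrest |
| `min_len`, `max_len` | 8, 95 | nt | read retention window after trimming |
| `qual_cutoff` | 25 | Phred | 3′ quality-trimming cutoff |
| `accuracy_pct` | 80 | % | mapping contract (mismatch budget helper) |
| `weak_cut` | 0.4 | fraction | weak/strong arrest boundary for classification |

The binomial confidence is our codification of the "variant caller at
Phred ≥ 20" step: it is deterministic, exact, and matches the threshold
semantics ($p \le 10^{-2}$). No multiple-testing correction is applied —
the thresholds *are* the published operating point and per-cluster site
counts are small. Indels are never treated as modification evidence.

The TGIRT enzyme occasionally produces a weak echo of arrest plus a
mismatch pattern up to three positions before the modification it
actually stalls at ("before" in the direction of cDNA synthesis, i.e. on
the 3′ side in mature coordinates). The published procedure removed these
manually; we codify it as a three-condition rule: an RTa call at $p$ is
suppressed iff (a) a call at $q < p \le q + \texttt{window}$ exists, (b)
$p$'s intensity is strictly below $q$'s, and (c) $p$ shows mismatches
that are present but below the confident-call threshold. All three
conditions are configurable; suppression never removes the primary call,
and suppressed calls are flagged rather than deleted. Thresholding is
applied before artifact filtering.

## Reference construction and Sprinzl numbering

Gene annotations (1-based inclusive coordinates, introns as intervals on
the gene sequence) are spliced, CCA-appended and deduplicated:
reads cannot distinguish genes with identical mature sequences, so the
unit of analysis is the cluster. CCA is appended only when not already
terminal, avoiding `CCACCA` artifacts on genomically encoded tails.
Nuclear and mitochondrial clusters are kept separate even when sequences
coincide, because their biology (and reporting) differs. Mitochondrial
tRNAs lacking canonical structure receive no special treatment during
clustering.

Standard position labels (1–76 with 17a, 20a/20b, variable-loop
e-positions) are assigned by global affine-gap alignment to a packaged
cloverleaf consensus template (one per domain, cytosolic and
mitochondrial) rather than by database search: the highest-scoring fit
defines the numbering. Scoring is match +2, mismatch −1, weighted by a
per-column conservation weight (2 at near-universal positions, 1
elsewhere; the mitochondrial template caps weights at 1.25 because
mitochondrial tRNAs deviate more freely); gaps cost 5 to open and 1 to
extend. These defaults make canonical 76-nt tRNAs align gap-free. The
terminal CCA is forced onto 74–76 and, when the anticodon is known, a
bonus pulls it onto 34–36. Ties in the dynamic program are broken
deterministically (substitution over deletion over insertion). Insertions
are labelled 17a after 17; 20a, 20b, 20b1… after 20; e1…eN in the
variable loop (after 45); `<parent>iK` elsewhere. Clusters scoring below
`sprinzl_min_score` (default 60) are flagged *unfittable* and excluded
from Sprinzl-indexed reports while remaining analyzable by raw
coordinate — a convention for atypical (mostly mitochondrial)
structures, which the original procedure does not specify.

## Read filtering

The retention rule trims low-quality 3′ tails at Q25 (running-sum
algorithm, as in common trimming tools) and keeps reads whose trimmed
length falls in [8, 95] nt. Whether the published "quality cutoff 25"
meant trimming or mean-quality filtering is not stated; we chose 3′
trimming and expose the cutoff in the configuration. Reads aligned to
extended precursor contigs are excluded as pre-tRNAs when their span
reaches ≥ 1 nt beyond the mature interval on either side — the strictest
rule consistent with "presence of 5′ leader sequences". The two-pass
mapping itself (masked genome plus precursor contigs, then unique mapping
to the mature set) is an external contract: the package consumes SAM/BAM,
drops multi-mappers (secondary/supplementary flags or `NH > 1`), and
provides `max_mismatches()` to express the 80%-accuracy budget. Soft
clips are ignored; the 5′-most *aligned* base defines the stop position.
Duplicate reads are not collapsed.

## Time-course aggregation

Per-position summaries across samples use the coverage-weighted mean:
$\sum \mathrm{stops} / \sum \mathrm{cov}$ over clusters, which is the
reading of "normalized over all reads" that weights every read equally
(the mean of per-cluster ratios would not). A cluster qualifies at a
label if it reaches the call threshold in *at least one* sample, and the
same qualifying set is summed at every time point so values are
comparable across the course; whether qualification should instead be
per-sample is not specified, and the joint convention is our declared
choice. The expression-vs-RTa check uses Spearman rank correlation
(read-total proxies are heavy-tailed, and the claim under test is only
the absence of monotone association), reported as missing when fewer
than four clusters contribute.

## The simulator and what passing tests mean

`simulate_genes()` emulates the study's gene complement: 421 genes
collapsing into 70 clusters (55 cytosolic, 15 mitochondrial), built on
the cloverleaf consensus with per-cluster point differences, optional
variable-loop extensions and occasional introns 3′ of the anticodon
loop. `simulate_reads()` generates 3′-anchored reads: walking 5′-ward
from the CCA anchor, each planted site arrests the read with its stop
probability (5′ end = site + 1); read-through sites misincorporate per a
planted spectrum; background substitutions arrive independently per base
(default 0.001, a realistic Illumina-scale error well below the
conservative ε of the caller's null). Base qualities are constant Q40 by
default. Planted sites keep ≥ 4 nt spacing so each signal is
independently measurable, and reads are emitted both as FASTQ and as
truth-aligned SAM so tests never need an aligner. RT jumps can be
simulated as deletions but default off, since the caller does not use
them.

The simulator deliberately omits instrument error profiles, PCR
duplicates, context-dependent RT behaviour, partial 3′ adapters and
mappability artifacts. Passing recovery tests therefore demonstrates the
correctness of the counting, calling and aggregation machinery under the
stated generative model — not performance on real libraries, where
mapping ambiguity and enzyme idiosyncrasies add error modes the model
does not contain.

Problem sizes used by the test-suite and acceptance script: recovery runs
use 67 clusters × 3 sites (201 planted sites) at 1000 reads per cluster
with caller ε = 0.005; intensity-recovery runs 10 clusters at 1000
reads; the null-correlation check 100 replicates of 30 clusters; the
threshold bisections use synthetic pileups at coverage 1000 (10^6 for the
confidence boundary, where the discrete binomial approaches the
continuous threshold). These sizes make every statistical check
well-powered while keeping a full run on one CPU in well under a minute
per component.

## Numerical and degenerate-input conventions

* `RTa(n)` is *missing* (not 0) where $\mathrm{cov}(n+1) = 0$; position
  $L$ has no intensity.
* Confidence is capped at Phred 1000; $k = 0$ gives confidence 0.
* Deletions count toward coverage but never toward mismatches;
  insertions contribute nothing positionally.
* Empty alignment sets yield complete all-zero profiles, not errors.
* Cluster ids are deterministic (`isotype-anticodon-ordinal`, ordinal by
  lexicographic mature sequence), so identical inputs give identical
  outputs everywhere; the only RNG in the package lives in the simulator
  behind a single seed.
* `max_mismatches()` adds a 10⁻⁹ epsilon before flooring so exact
  percentage boundaries (20% of 100) are not lost to floating point.

## Classification

Signature rules (reference base, arrest requirement, dominant mismatch
targets, weak/strong intensity class) map a call to candidate
modification codes; codes also catalogued at the call's Sprinzl position
in other species rank first. The packaged rule table is a curated
reconstruction of the signatures described for untreated TGIRT data
(m1A: A→T/A→G with arrest; inosine: A→G without arrest; m1G/m2G/m22G: G
mismatches with arrest; m3C: arrest with C mismatches; D, Cm, Gm: weak
arrest without dominant mismatches; position-37 A hypermodifications:
arrest-dominant), and both tables are user-replaceable TSVs with
per-rule provenance. Rules whose modifications show no dominant
misincorporation are treated as incompatible with confident mismatch
evidence. The weak/strong boundary (0.4) has no published value and is
configurable. Ambiguous sets (`m2G|m22G`) are preserved verbatim;
unmatched signatures yield `unknown[<signature>]`, never a dropped call.
Calls at position/base pairs absent from the catalogue are flagged
`novel_position`. Treatment-dependent modifications invisible to RT
(e.g. m7G, m5C, pseudouridine discrimination) are out of scope by
construction.

## Known limitations

* The signature and catalogue defaults are reconstructions, not a
  transcription of a published appendix; classification on real data
  should review them per organism.
* Template alignment cannot number tRNAs whose architecture departs
  far from the cloverleaf (some mitochondrial tRNAs); these are flagged
  rather than guessed.
* The artifact filter is a codified approximation of a manual step; its
  three conditions are exposed precisely so they can be tightened.
* Single-end 3′-anchored data is assumed throughout; paired-end logic is
  intentionally absent.

## A minimal worked run

```{r example, eval = FALSE}
cfg <- sim_config(n_clusters = 10, n_mito = 2, n_genes = 20, seed = 1)
g <- simulate_genes(cfg)
clusters <- cluster_trnas(g$genes)
truth <- simulate_truth(clusters, seed = 1)
sim <- simulate_reads(clusters, truth, cfg, out_dir = "sim")

samples <- tibble::tibble(sample_id = "s1", time_label = "0h",
                          sam = file.path("sim", "reads.sam"))
res <- run_pipeline(g$genes, samples, "results")
tidy(res$calls)
glance(res$calls)
autoplot(res$summary)
```
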