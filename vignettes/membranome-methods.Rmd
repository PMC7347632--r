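---
title: "Methods: surface membranome discovery from sorting signals and expression screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surface membranome discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`membranome` predicts which gene products of a cell population of
interest are plasma-membrane surface proteins, and narrows them to
condition-insensitive, population-specific, proteomically confirmed
marker candidates. The pipeline composes presence/absence expression
screens over bulk abundance tables with per-protein sorting-signal
prediction, set algebra over labeled gene sets, an annotation-table
screen, and an intersection with a mass-spectrometry protein list. A
single-cell module summarizes marker co-expression per cell cluster.

The package assumes the upstream steps of a standard RNA-seq workflow
(trimming, alignment, transcript quantification) have already produced
transcript-level expected counts, and that MS spectra have been reduced
to an identified-protein list. Neither step is reimplemented here.

## The sorting-signal predictor stack

Server-based predictors of the classic era (signal-peptide, TM-helix,
NLS predictors) are irreproducible as black boxes: versions and
parameters are rarely recoverable. The package instead implements the
canonical published mechanisms directly, trading a few points of
real-data accuracy for full transparency and determinism. Every
threshold is a visible argument.

**Signal peptide.** Tripartite model. The n-region (first 5 residues)
must carry non-negative net charge (K/R = +1, D/E = −1). The h-region
must contain a run of ≥ 6 residues within positions 3–30 (0-based) whose
mean Kyte–Doolittle hydropathy is ≥ 2.0. The c-region follows the
von Heijne −3,−1 rule: a cleavage position p in [12, 40] with a small
residue (A, G, S, C, T) at p−1 and a small-or-aliphatic residue at p−3,
located 2–8 residues after an h-region end. The call is positive iff all
three hold; the reported cleavage position is the smallest valid p.

**Transmembrane segments.** Smoothed hydropathy (19-residue window,
truncated at the ends) thresholded at 1.6; runs separated by fewer than
3 residues merge; runs shorter than 15 residues are discarded. The
Kyte–Doolittle scale is the default; the GES scale is available. A
cleaved signal peptide is not a membrane anchor, so TM segments wholly
inside `[0, cleavage_pos)` are removed.

**NLS.** Union of regex evidence (monopartite `K[KR]x[KR]`, bipartite
`[KR]{2}x{9,12}[KR]{3,5}`) and a two-state hidden Markov model decoded
by forward–backward. The NLS state emits K with 0.30 and R with 0.25
(remaining mass uniform); the background state emits the observed
composition of the scored sequence; transitions are bg→nls 0.01 and
nls→bg 0.10; the chain starts at its stationary distribution. Runs of
≥ 4 residues with NLS posterior > 0.5 become hits. Overlapping hits
merge, keeping the kind of the higher-scoring source (regex hits score
1.0; HMM hits score their peak posterior; HMM-only hits carry the kind
`NLS_hmm`). These HMM parameters are surrogate defaults, not values
recovered from any published tool, and are fully overridable.

**NES.** The leucine-rich pattern `Φx{2,3}Φx{2,3}ΦxΦ` with
Φ ∈ {L, I, V, F, M}. This pattern unavoidably matches any hydrophobic
helix, so the report builder masks NES matches lying inside the signal
peptide or overlapping a predicted TM segment: a functional export
signal must be exposed to the cytosol. Unmasked raw matches remain
available through `detect_nes()`.

**ER retention.** Strictly C-terminal: the last four residues matching
`[KRHQSA][DENQ]EL` (KDEL class), or lysines at −3 and −4/−5 (di-lysine
class). Internal occurrences never count.

**Mitochondrial presequence.** Over residues 0–29: ≥ 3 arginines, ≤ 1
acidic residue, and hydrophobic moment μ = |Σₖ hₖ·exp(ik·δ)|/n ≥ 0.32
with δ = 100°/residue over residues 0–17 on the normalized Eisenberg
scale — an amphipathic, positively charged, acid-poor N-terminus. A
predicted signal peptide takes precedence (no mTP call).

**Decision rule.** A protein is a membranome candidate iff it has a
signal peptide, at least one TM segment, and none of the enabled
exclusion signals (NLS, NES, ER retention, mTP — all enabled by default,
individually toggleable; the NES exclusion is kept on by default even
though some screens only name the NLS, because an export signal implies
a cytosolic/nuclear life cycle). `failed_filters` lists every violated
clause, which makes downstream provenance exact.

## Expression screens

A transcript (or gene) counts as expressed in a sample group when its
abundance exceeds 10 in more than two samples — both thresholds strict
and configurable, because the inclusive reading of "higher than" /
"more than" is also defensible. Transcript rows are summed to genes
before set construction; expected counts may be fractional, so all
comparisons are numeric.

Two grouping modes exist. The default filters each
population-by-condition group on its own samples, which is the screen
that gives per-condition expressed sets. Small reference groups (2
samples) cannot satisfy "more than two samples", so the per-group
threshold is capped at group size − 1 — effectively "expressed in all
samples of a small group". A `joint` mode additionally applies the
filter across all samples together, matching the whole-study reading of
the filter; it is not the default because per-condition sets are what
the condition-intersection stage consumes.

## The candidate funnel

Per target condition, the membranome is the intersection of the
expressed set with the topology candidates. The funnel then proceeds:

1. **Condition intersection** — candidates present under every target
   condition (condition-insensitive).
2. **Plasma-membrane screen** — genes whose annotation includes the
   plasma membrane. Genes absent from the annotation table are excluded
   *and reported*; silently passing unverifiable genes would inflate the
   candidate list.
3. **Specificity screen** — by default the set difference against the
   union of the reference-population membranomes (mode `specific`).
   The alternative reading (intersection, mode `shared`) is implemented
   and selectable; the default follows the population-specific intent of
   a marker screen.
4. **Proteomic cross-validation** — intersection with the
   membrane-flagged, plasma-membrane-annotated genes of the MS list,
   after identifier normalization (case-insensitive canonical symbols,
   alias resolution; unmapped symbols are reported, never dropped).

Stage sizes are asserted non-increasing at run time, and the per-gene
provenance ledger assigns every input gene exactly one terminal state
(elimination stage + reason, or final candidate).

## The synthetic-data generator

The generator emulates the study design the analysis assumes: five
populations — the target stromal population under sham and infarct
conditions (3 samples each) and three references (cardiomyocytes,
non-myocytes, embryonic stem cells; 2 samples each, 12 samples total);
500 genes by default, assigned to membership categories (housekeeping
20%, target-both 15%, target-single-condition 5% + 5%, one category per
reference population 15% each, silent 10%) and protein classes
(plasma-membrane 25%, secreted 15%, nuclear 15%, ER-resident 10%,
mitochondrial 10%, cytosolic 25%).

Counts are negative binomial with mean 200 and dispersion 0.3
(variance = μ + μ²·dispersion — the mean/dispersion convention, stated
here to avoid the two-convention ambiguity) for expressed genes and
mean 0.5 for silent genes; each gene splits over 1–3 transcripts by
fixed Dirichlet weights so aggregation is genuinely exercised. The
`zero` noise preset (the closure benchmark) sets silent means to 0,
draws expressed counts as Poisson(200) (the dispersion → 0 limit, so no
expressed gene can fall below the expression filter by chance), uses an
error-free annotation table, and detects every target plasma-membrane
protein in the MS list.

Proteins are assembled from planted signal blocks (the
`MK + 10×L + ASA` signal peptide; 21-residue L/I/V/F TM blocks; an
SV40-type `PKKKRKV` NLS; a `LAQLAELSL` NES in half the cytosolic
proteins, so the NES detector has planted positives; C-terminal KDEL or
di-lysine tails; an amphipathic R/A presequence) joined by background
drawn uniformly over the 20 residues. Backgrounds are rejection-sampled
and then verified with the package's own detectors so that a finished
protein carries *exactly* its planted signals: a "negative" sequence
containing a chance NLS would be a labeling error of the benchmark, not
a detector error. Consequently, specificity measured on this corpus
demonstrates the absence of spurious calls on signal-free background —
it does not estimate false-positive rates on natural sequences, whose
composition is neither uniform nor signal-free. Sensitivity likewise
reflects idealized, full-strength signals. Annotation corruption
(per-gene compartment replacement with the configured probability) and
partial MS detection are the two noise channels used for degradation
experiments.

The single-cell generator emulates a droplet experiment with six labeled
clusters (60 cells each by default) and Bernoulli × (1 + NB) counts; in
the designated co-expression cluster one Bernoulli draw gates both
marker genes jointly (rate 0.8), elsewhere the markers are independent
at rate 0.25. It does not model library-size variation, ambient RNA, or
doublets.

## Single-cell summaries and population clustering

"Expressing" means count > 0 — the droplet-sparsity convention, with the
threshold configurable. Means are computed on counts scaled to 10,000
per cell then `log1p`-transformed, the de facto droplet normalization.
Joint expression is the per-cluster fraction of cells with both markers
> 0; the reported top cluster is the argmax with deterministic
label-order tie-breaking and all ties reported, and
`fraction_joint ≤ min(fraction_a, fraction_b)` holds by construction.

Population dendrograms use distance 1 − Pearson correlation across the
marker panel with average linkage — the metric/linkage pair of the
standard marker-panel heatmap; both are configurable, and a
zero-variance profile (correlation undefined) falls back to scaled
Euclidean distance for the affected pairs with a warning. Labels are
sorted before clustering so leaf order is deterministic; trees serialize
to Newick via `ape`.

## Numerical choices and degenerate inputs

* Hydropathy scales live on a 0.1 grid, so window means sit on a coarse
  rational grid; profiles are rounded to 9 decimals before threshold
  comparisons to keep strict inequalities stable against binary
  accumulation order.
* All intervals are 0-based half-open; cleavage positions index the
  first mature residue.
* ORF finding (for nucleotide input) translates the longest ATG→stop
  reading frame with the standard code, ties broken by lowest frame then
  smallest start; ORFs shorter than 30 aa (configurable) yield an
  explicit no-ORF result. Default frames are the three forward frames,
  because quantified transcripts are strand-oriented mRNA; six-frame
  scanning is a flag. Pre-translated protein FASTA is the first-class
  input path.
* Sequences shorter than the hydropathy window yield an empty TM list
  with a warning, not an error; sequences shorter than hard minimums for
  SP (25) and mTP (30) scoring raise errors at the single-protein level
  and are treated as signal-free by the batch report builder.
* `X` residues score 0 hydropathy, match no motif class, and are
  emission-uninformative in the HMM.
* Candidate sets are kept sorted and unique, so set results are
  order-independent and reproducible.

## Problem sizes used by the test suite

The shipped verification uses 1,000 proteins per class for detector
performance, 10 replicate 500-gene studies for exact zero-noise closure,
50 replicates × 4 annotation error rates at 120 genes for the
degradation trend, 100 randomized 60-gene runs for funnel/provenance
invariants, and 100 single-cell simulations for co-expression recovery;
the HMM is checked against exhaustive path enumeration on all reduced-
alphabet sequences to length 5 plus sampled sequences to length 10.
These sizes give tight Monte-Carlo error on every rate while keeping the
suite comfortably runnable on a laptop.

## Known limitations

* The predictors are deliberately simple surrogates: no positional
  weight matrices, no machine-learned models, no TM topology (in/out
  orientation), no glycosylation or GPI-anchor prediction. On natural
  proteomes they will under- and over-call relative to modern tools;
  within this package they serve as a fully specified, testable
  screening rule.
* The annotation table abstracts "available databases"; its quality
  bounds the plasma-membrane screen exactly as database quality does in
  practice (the degradation experiments quantify this).
* The MS arm starts from an identified-protein list; identification FDR
  and quantitation are out of scope.
* Bulk counts are presence/absence material here; no normalization or
  differential expression is performed or needed by the screens.
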