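---
title: "Consensus voting and staged prioritization of pathogenic nsSNPs"
author: "VariantVote"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus voting and staged prioritization of pathogenic nsSNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VariantVote)
```

## The problem

Nonsynonymous SNPs (nsSNPs) change one amino acid of a protein and are a
major source of disease risk, cancers included. For most nsSNPs no
experimental evidence of effect exists, so practitioners lean on in-silico
predictors — but individual predictors disagree, and each has a published
threshold on a different scale. VariantVote implements a complete consensus
framework around five widely used functional-effect predictors, a
benchmarking harness to quantify how k-of-n voting trades sensitivity for
specificity, and a staged prioritization cascade that narrows a candidate
list down to the variants with convergent functional, evolutionary,
energetic and structural evidence.

## Per-tool significance calls

Each predictor's raw output (a numeric score, a categorical label, or both)
is reduced to `significant` / `not_significant` / `missing`:

| tool | significant when | scale |
|---|---|---|
| SIFT | score ≤ 0.05 | 0–1, low = damaging |
| PolyPhen-2 | score > 0.9 (label `Prob_dam`) | 0–1, high = damaging |
| Condel | score > 0.5 (label `Del`) | 0–1 weighted ensemble |
| PROVEAN | score ≤ −2.5 (label `Del`) | alignment delta |
| PANTHER | PSEP > 450 (label `Prob_dam`) | preservation time, My |

Three boundary choices deserve a note, each exposed in
`thresholdConfig()`:

* **SIFT** is inclusive (`≤ 0.05`) by default — the damaging side of the
  published cut includes the boundary — with a strict `<` variant available.
* **Condel** uses `> 0.5`. A requirement of *exactly* 1.0 appears in some
  descriptions of the ensemble but is unusable for a continuous score; it
  is available via `condel_exact_one = TRUE` for completeness.
* **PolyPhen-2's** `pos_dam` ("possibly damaging") sits below the 0.9 score
  cut and is therefore *not* significant — this matters, as several cohort
  variants carry that label.

When a score and a label are both present and disagree, the score wins (it
is the primary output the labels discretize). Labels suffixed `_low_con`
carry the base label's call with a preserved low-confidence flag.

## The eight consensus models

Models A–D call a variant deleterious when at least 1–4 of the five tools
are significant. Models A3–D3 add two evidence gates: the residue must be
evolutionarily conserved (ConSurf grade ≥ 7 on the 1–9 scale) and the
mutation must destabilize the protein. The two gates are conjunctive —
they mirror the cascade below, where conservation and stability act as
successive pass/fail filters; no disjunctive weighting is offered.

The stability gate inside the X3 models uses the I-Mutant *direction*
(predicted stability decrease), not the ΔΔG class. The free-energy classes
(destabilizing < −0.5 kcal/mol < neutral < +0.5 < stabilizing) are
reported, but a prediction of −0.48 kcal/mol with direction "decrease" is
still a decrease; the reference data treat it exactly that way, excluding
such variants only through the reliability index. A ΔΔG-class gate is
available per model via `consensusModel(..., stabilityGate = "ddg")`.

**Missing-data policies.** An absent predictor output is not evidence.
Under the default `strict` policy a missing call counts against the vote —
chosen because the benchmark denominators are fixed at the class sizes,
implying every variant received a binary decision. `permissive` counts
missing as significant (an upper envelope), and `fraction` rescales the
threshold to the available tools (k of 5 becomes k·a/5 of a available;
a variant with no available tools is benign). All three policies preserve
the nesting A ⊇ B ⊇ C ⊇ D and X3 ⊆ X, which the test suite verifies
against a brute-force counter over all 3⁵ call-state combinations.

## Benchmark metrics

Given confusion counts against a labeled standard set,

$$Se = \frac{TP}{TP+FN}\times100\%,\quad
Sp = \frac{TN}{TN+FP}\times100\%,\quad
Ac = \frac{TP+TN}{TP+TN+FP+FN}\times100\%.$$

The numerator is scaled by 100 *before* dividing so that integer counts
give exact percentages (50/50 class sizes make all the packaged reference
percentages whole numbers). Empty denominators propagate as `NA`, never as
0 or 100. Rounding, when requested, is display-only.

```{r}
metricsReport(referenceData()$confusion)
```

On the packaged standard-set counts the monotone trade is visible: from
model A to D sensitivity falls (100 → 84) while specificity rises
(50 → 94); the evidence-gated D3 reaches the highest specificity (96) at
the lowest sensitivity (76).

## The prioritization cascade

`runCascade()` applies four gates in order, each recorded per variant as
`pass` / `fail` / `not_evaluated` (evidence absent — deliberately distinct
from a failure):

1. **consensus** — a `consensusModel()` (default D, strict);
2. **conservation** — ConSurf grade ≥ 7;
3. **stability** — direction `decrease` *and* reliability index RI ≥ 5.
   RI, not the ΔΔG class, is the exclusion criterion: it screens out
   low-confidence stability predictions regardless of the ΔΔG magnitude;
4. **structure** — TM-score > 0.5 and RMSD < 6.5 Å between native and
   mutant models, the regime where template-based models share the native
   fold.

Survivors are annotated — never eliminated — with the MutPred2 pathogenic
flag (score ≥ 0.5) and the ModPred PTM confidence (score < 0.7 low,
≥ 0.7 medium, ≥ 0.9 high; a coarser legacy scheme with a single 0.5 cut is
available in `modpredConfidence()`).

```{r}
res <- runCascade(referenceCandidates(), cascadeConfig(consensus = NULL))
res$survivors
as.data.frame(res$shortlist)
```

**Why `consensus = NULL` here.** The packaged candidate set is the eight
high-risk variants of the reference study, selected by its authors from
per-tool outputs that are only partially printed: one of the eight
(rs3124765) shows just three significant calls at label level (its PANTHER
cell is unpredicted), while a non-candidate (rs671) has the same
3-significant/1-missing structure. No single consistent label-level rule
separates the two, so the package does not pretend to re-derive the
selection: the candidate set is accepted as an input (`consensus = NULL`,
stage recorded as passed), and with the consensus gate enforced instead,
strict model D certifies 7 of the 8 — both behaviours are tested, and
every decision carries its vote breakdown so the discrepancy is visible in
output rather than patched over.

## Cohort matching

`matchDataset()` marks a dataset variant present in a cohort VCF when a
record passing the quality filter (depth ≥ 5 *and* Phred quality ≥ 30 —
sites exactly at a bound pass, only strictly-below values are excluded)
shares chromosome and position and the alternate allele is observed in at
least one sample. Multi-allelic records are split per alternate allele;
when the dataset row names a risk allele only that allele counts. Site
depth comes from `INFO/DP` when present, else the sum of `FORMAT/DP` (the
choice is recorded in the result metadata). Contig names are compared
after stripping any `chr` prefix. Missing depth/quality fails closed by
default. Allele frequency is the alternate-allele count over called
alleles, with missing genotypes excluded from the denominator.

The published cohort-specific counts (52 of 80 dataset nsSNPs found across
the two cohorts, 43 per population) require the underlying whole-genome
data and are therefore not reproducible from this package; the matching
*mechanism* is instead exercised end-to-end on generated VCFs with known
truth.

## Synthetic data: what it emulates, and what it does not

`simulateBenchmark()` emulates a 50/50 labeled standard set. Per tool, a
score lands on its truth side of the threshold with probability
`toolAccuracy` (default 0.85, i.e. marginal per-tool accuracy in the
0.8–0.9 band — the regime where the k-of-5 models visibly trade
sensitivity for specificity) and is drawn uniformly within that side's
score region. Conservation and stability evidence agree with the class
with probability `evidenceAccuracy` (default 0.9). One master seed fans
out to per-component substreams, so changing one tool's settings leaves
the other tools' draws untouched. The generator does **not** emulate
correlation between tools (real predictors share training data and
alignments, so their errors correlate; synthetic votes are conditionally
independent given the class) nor realistic score densities near the
thresholds. Passing tests therefore demonstrate the correctness of the
voting, metric and filtering machinery — not field performance of the
predictors on real variants.

`simulateVcf()` draws genotypes from Hardy–Weinberg proportions at the
requested allele frequency and forces a configurable fraction of sites to
fail the depth/quality filter, recording ground truth for the matcher.
Sequencing error profiles and linkage are out of scope.

## Packaged reference data

The five tables under `inst/extdata/` transcribe the printed evaluation
tables of the reference study: the 8-model confusion counts, the cohort
nsSNP label table, and the conservation / stability–structure / annotation
tables for the high-risk candidates. Two caveats are recorded rather than
hidden:

* the cohort label table is a **partial transcription** — 48 of the 52
  published rows were recoverable from the source text (all eight
  high-risk variants among them);
* for two shortlisted variants the source's prose and its annotation table
  disagree on the MutPred2 score (0.78/0.73 vs 0.74/0.70); the table
  values are packaged. Both versions sit above the 0.5 pathogenicity cut.

All tables are validated against the domain invariants at load time.

## Numerical and design choices

* Percentages are computed exactly on integers (`tp * 100 / (tp + fn)`);
  no floating-point boundary enters the vote arithmetic either
  (`fraction` compares `5·nSig ≥ k·available`).
* Catalog keyword matching is case-insensitive substring by default:
  compound phenotype names ("Leiomyosarcoma", "Non-glioblastoma glioma")
  are intended matches; word-boundary matching is available. Filtering
  deduplicates on (rsid, trait), so one variant associated with two
  cancers is kept once per trait.
* Coordinates are 1-based GRCh37 throughout; VCF positions are consumed
  as-is.
* Problem sizes in the test suite — 1,000-profile property sweeps, the
  full 243-combination oracle, 30–40-sample simulated VCFs, 500 samples
  for the allele-frequency calibration check — were chosen to exercise
  every code path and invariant at comfortable margins.

## Limitations

* The consensus engine votes; it does not fuse scores probabilistically
  (Condel-style weighted averaging belongs to the upstream tool).
* Running the upstream predictors, alignment/variant calling, homology
  modeling, docking and interaction networks are all out of scope: the
  package consumes their outputs.
* The X3 models' raw confusion counts on the original standard set depend
  on unpublished per-variant conservation/stability outputs; only their
  metric arithmetic is reproducible here, and only the mechanisms are
  testable on synthetic data.
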