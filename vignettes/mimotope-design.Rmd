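---
title: "Designing and ranking K-ras mimotopes: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and ranking K-ras mimotopes: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimorank)
```

## The design problem

Codon 12/13 point mutations of K-ras (G12A/C/D/R/S/V, G13D) are
tumour-specific, but the mutant epitopes are poor immunogens. A *mimotope*
keeps the disease-defining anchor mutation and adds one engineered
substitution at a flanking residue, hoping to improve MHC presentation and
B-cell recognition while still raising antibodies that cross-react with the
natural mutant epitope. mimorank implements the in-silico arm of this
strategy: saturation enumeration of single flanking substitutions over the
exon-2 epitope region (codons 4–18, `YKLVVVGAGGVGKSA`), scoring of every
candidate on seven immunological parameters, conversion of raw scores to
priority-weighted percentages, and ranking into a shortlist.

## Candidate enumeration

Starting from an anchor-mutated 15-mer, `enumerate_library()` emits one
candidate per (flank codon, residue) pair. Two modes exist because the two
natural readings of "19 substitutions at each flanking position" lead to
different catalog sizes:

* `paper_compat` (default): 12 flank codons {4–11, 15–18} × the full
  20-letter alphabet = 240 candidates per library and 1,680 over the seven
  anchors. No-op substitutions (the wild-type residue re-inserted) are
  retained as distinct catalog entries. This reproduces the published
  per-library and total counts, which a 13-position × 19-residue scheme
  (247/library) cannot. The exclusion of codon 14 is reverse-engineered
  from those counts, not stated anywhere; treat it as a calibrated default,
  and pass your own `flank_codons` to change it.
* `strict_19`: the literal reading — 19 true substitutions per position
  (228/library with the default flank set).

Candidates are ordered deterministically (codons ascending, residues in
alphabetical one-letter order) and identified as `"<index>-<anchor
residue>"` (e.g. `164-D` in a G13D library). The published catalog's
numeric identifiers come from an unknown within-position residue order and
cannot be regenerated exactly; published ids are therefore treated as
aliases (`golden_scorecards()` carries them verbatim), while this package's
ids are reproducible from its own documented order. All coordinates
throughout are 1-based protein codon numbers, matching the field notation
`G12V` / `V7D`; `apply_mutation()` refuses a substitution whose stated
original residue does not match the sequence, which catches off-by-one
coordinate errors early.

## B-cell propensity parameters

Four sequence-profile parameters are computed from published residue
scales, transcribed in `R/scales.R` with their citations (Emini 1985
surface fractions; Parker 1986 hydrophilicity; Kolaskar–Tongaonkar 1990
antigenic propensity; Levitt 1978 reverse-turn propensity):

* **SA** — surface accessibility: per hexapeptide window, the product of
  Emini surface fractions divided by a normalization constant to the 6th
  power.
* **HY** — hydrophilicity: 7-residue window mean of the Parker scale.
* **AT** — antigenicity: 7-residue window mean of the Kolaskar–Tongaonkar
  scale; 1.0 is the conventional antigenic threshold.
* **LE** — linear-epitope propensity: a weighted sum (default equal
  weights) of Parker and Levitt window means. This is a deliberate
  simplification of HMM-based linear-epitope predictors, which combine the
  same two scales with a trained hidden Markov model; the trained model is
  not reproducible from published material, so the package computes the
  two-scale combination and lets users import externally computed
  per-candidate scores instead whenever they have them.

Window sizes default to the methods' original choices (6 for SA, 7 for the
window means); positions lacking a full window are reported as undefined
rather than zero-filled, so summaries are not biased toward edges. The
published workflow reports a single raw value per candidate per parameter
without stating the window-to-peptide reduction; the package defaults to
the **maximum** over defined windows — the candidates are scored by their
best epitope region, which matches the "hexapeptide mimotope region"
reading — and every scorer accepts `summary = "mean"`.

### The surface-accessibility normalization constant

The original hexapeptide formulation divides the six-fold product by
0.37^6, describing the result as scaled so a random hexapeptide scores 1.
With the published residue fractions (arithmetic mean 0.6225) that is not
numerically true: the expected window score under uniformly random
composition is `(0.6225/0.37)^6 ≈ 23`. Both conventions are therefore
exposed: the default `norm = "calibrated"` divides by the scale's
arithmetic mean, which makes the random expectation exactly 1 (the tests
verify this by Monte Carlo), while `norm = 0.37` reproduces the published
constant (verified against its closed form on homopolymers). The choice
does not affect ranking when the conversion bins are calibrated on the
same convention, because the normalization is a strictly monotone
rescaling.

## RNA secondary structure

Each candidate is reverse-translated (default: a most-frequent-codon table
for *Lactococcus lactis*, the expression host context; any table or an
explicit nucleotide sequence may be supplied) and the 45-nt coding
sequence is folded by Nussinov-style base-pair maximization — nested
structures, Watson–Crick plus G·U wobble pairs, minimum hairpin loop of 3
(the steric minimum) — with a fixed traceback order so results are
deterministic. A transcript is called hairpin-forming when some run of at
least 4 stacked pairs encloses a terminal loop of 3–8 bases
(`classify_hairpin()`, all thresholds configurable).

This is an explicit stand-in for posterior-decoding folders: the scoring
scheme consumes only the binary hairpin/no-hairpin outcome, and a
maximization fold plus an explicit stem/loop rule makes that call
reproducible and testable (the tests check the dynamic program against
exhaustive enumeration on all short sequences). It does not model
thermodynamics, pseudoknots or ensembles, and the plasmid context around
the insert is unknown, so the default folds the insert alone;
`context5`/`context3` accept flanking vector sequence when it is known.

## MHC binding parameters

Trained class I/II binding predictors are never re-implemented. Real
studies export per-allele prediction tables (class I as IC50 in nM, class
II as percentile rank) and import them with `parse_prediction_table()`;
`filter_alleles()` restricts mouse predictions to the Balb/c *d*-haplotype
sets (H-2Dd/Kd/Ld; I-Ad/Ed) by default, and `aggregate_best()` collapses
alleles and subpeptides to one raw value per candidate by the minimum
(strongest predicted binder — the conventional shortlisting readout; the
median is available). Class II scores are treated as unitless percentiles
throughout: the conversion table's class II bins are labelled in nM in the
published scheme but are fed from percentile exports, so the unit label is
carried as metadata only. For offline work and tests,
`toy_matrix_predict()` provides a seeded position-weight-matrix stand-in
that is flagged synthetic in its output and has no biological meaning.

## The conversion and ranking scheme

`conversion_table()` holds the published bin scheme verbatim: each
parameter maps its raw value into two or three bins carrying fixed
percentage weights, with the weights expressing the stated parameter
priority (MHC II 58/39/20 > MHC I 42/28/14 > SA 34/23/12 > HY 29/19/9 >
AT 19/13 > LE 12/8/4 > RNA 6/4). T-cell totals (MHC II + MHC I, per
species) and the B-cell total (SA + HY + AT + LE + RNA) each reach a
maximum of exactly 100.

Numerical conventions where the printed scheme is ambiguous:

* Printed bin edges overlap or leave gaps at display precision (e.g. SA
  2.530 vs 2.531). Bins are implemented as half-open intervals anchored at
  the printed lower edges, so every real value maps to exactly one bin;
  printed upper edges are treated as display rounding.
* The class I low bin is printed as 501–5,000 nM but is unbounded above
  here: IC50 values beyond 5,000 nM are still low-affinity.
* Values below a parameter's lowest printed edge (e.g. SA below 1.294)
  clamp into the nearest bin with a diagnostic, since the scheme is
  exhaustive in intent.
* The SA boundaries are consistent with equal-width terciles of an
  observed score range; `calibrate_equal_width_bins()` reproduces them
  from the range endpoints to within 0.001 and can recalibrate any
  parameter on new data. The fixed printed bins remain the default.

`rank_candidates()` orders by a grand total — by default the sum of human
T-cell, mouse T-cell and B-cell category totals, since the published
shortlists are printed per category without a stated combination rule, and
per-category keys are available to reproduce each table independently.
Ties break by the individual converted weights in the stated priority
order (MHC II > MHC I > SA > HY > AT > LE > RNA, human before mouse), then
by candidate id, making the order total and permutation-invariant.
`shortlist()` keeps the top 20 by default.

## Golden reference rows and their limits

`golden_scorecards()` carries the 23 published shortlist rows (20
candidates, the G12V/G13D controls, wild type) with their converted
weights and totals. Two fidelity boundaries are explicit:

* The published **raw** per-candidate prediction values are not available,
  so the goldens store converted scores only; tests reproduce the printed
  totals exactly from raw values drawn inside the implied bins, not from
  the original predictor outputs.
* The published T-cell and B-cell tables print different sequences for
  candidate 78-D (the T-cell version contradicts its own G13D + V7D
  annotation). Both variants are recorded with
  `sequence_discrepancy = TRUE` rather than silently choosing one; the
  annotation-consistent sequence is the B-cell one.

## The synthetic fixture generator

`synth_mhc_table()` emits seeded IEDB-style prediction tables whose
per-candidate best scores land in the conversion bins with controllable
occupancy, and `random_peptides()` emits uniform random peptides. These
emulate the *format and bin structure* of real exports — enough to test
parsing, filtering, aggregation, conversion and ranking end to end — and
deliberately nothing else: no allele-frequency realism, no correlation
between alleles, no sequence-to-score relationship. A green pipeline on
fixtures demonstrates the machinery, not predictive accuracy on real
antigens.

## Problem sizes and determinism

The full workflow (1,680 candidates: four propensity scores, one 45-nt
fold and four MHC streams each, then conversion and ranking) runs in
seconds on a single core, so all tests and examples use either the full
catalog or small three-codon libraries for speed of illustration. The only
randomness anywhere is in fixture generation and the toy predictor; both
are seeded, and repeated runs of `run_pipeline()` with the same
configuration produce byte-identical reports.

## Known limitations

* Propensity profiling is a weak predictor of real B-cell epitopes;
  the parameters here are ranking heuristics, not validated predictors.
* The LE score is a two-scale surrogate for trained linear-epitope
  predictors; imported scores should be preferred when available.
* The hairpin call ignores thermodynamics and folding context.
* MHC coverage is limited to whatever alleles the imported tables contain;
  the scheme weights parameters, not population HLA coverage.
* `paper_compat` enumeration calibrates to published catalog counts whose
  exact generating scheme is not stated; `strict_19` and custom flank sets
  are provided for sensitivity analysis.

```{r example}
lib <- enumerate_library(apply_mutation(kras_region(), "G13D"))
nrow(lib$candidates)
cand <- apply_mutation(apply_mutation(kras_region(), "G13D"), "G15Y")
cand$sequence
unlist(score_candidate_bcell(cand))
transcript_hairpin(cand)
```
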