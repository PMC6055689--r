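# mimorank

Design and priority-weighted ranking of K-ras mimotope vaccine candidates.

## The problem

Oncogenic K-ras carries point mutations at codons 12/13 (G12A/C/D/R/S/V,
G13D) that are perfectly tumour-specific but weakly immunogenic. A
*mimotope* keeps the disease-defining anchor mutation and adds one
engineered substitution at a flanking residue of the exon-2 epitope region
(codons 4–18, `YKLVVVGAGGVGKSA`), aiming to improve MHC presentation and
B-cell recognition while preserving antigenic mimicry. mimorank is for
immunoinformaticians who want to enumerate, score, and shortlist such
candidates reproducibly.

## The method

1. **Enumeration** — saturation single-substitution libraries per anchor
   mutation: 12 flank codons {4–11, 15–18} × 20 residues = 240 candidates
   per library, 1,680 over the seven anchors (a strict 19-substitution
   mode is also provided).
2. **Seven immunological parameters** per candidate:
   human/mouse MHC class II and class I binding (imported IEDB-style
   prediction tables, reduced to the strongest binder per candidate);
   Emini surface accessibility (SA); Parker hydrophilicity (HY);
   Kolaskar–Tongaonkar antigenicity (AT); a Parker+Levitt two-scale
   linear-epitope score (LE); and a hairpin call on the candidate's
   coding transcript (Nussinov base-pair maximization + stem/loop rule).
3. **Conversion and ranking** — each raw value maps into a weighted bin,
   with weights encoding the parameter priority
   (MHC II 58/39/20 > MHC I 42/28/14 > SA 34/23/12 > HY 29/19/9 >
   AT 19/13 > LE 12/8/4 > RNA 2° 6/4). Category totals
   (T-cell = MHC II + MHC I per species, B-cell = SA + HY + AT + LE + RNA 2°)
   each max out at 100; candidates are ranked by the grand total with
   deterministic priority tie-breaking and the top 20 shortlisted.

See `vignettes/mimotope-design.Rmd` for the modelling choices and their
rationale.

## Worked example

```r
library(mimorank)

# the G13D + G15Y candidate
cand <- apply_mutation(apply_mutation(kras_region(), "G13D"), "G15Y")
cand$sequence
#> [1] "YKLVVVGAGDVYKSA"

round(unlist(score_candidate_bcell(cand)), 3)   # raw B-cell scores
#>    sa    hy    at    le
#> 1.133 3.486 1.195 2.287

transcript_hairpin(cand)                        # RNA 2° parameter
#> [1] FALSE

# convert raw scores (here with externally supplied human MHC values:
# class II percentile 2.0, class I IC50 30 nM) and total the categories
raw <- data.frame(mhc2_human = 2.0, mhc1_human = 30,
                  sa = 1.133, hy = 3.486, at = 1.195, le = 2.287,
                  hairpin = FALSE)
category_totals(convert_scores(raw))
#>   conv_mhc2_human conv_mhc1_human conv_sa conv_hy conv_at conv_le conv_rna2
#> 1              58              42      12      29      19       8         6
#>   tcell_human bcell grand_total
#> 1         100    74         174
```

The converted row reads: this candidate is a predicted strong human MHC
class II and class I binder (58 + 42, a perfect T-cell total of 100), is
hydrophilic and antigenic but with modest surface accessibility and
linear-epitope propensity (B-cell total 74 of 100), and its transcript
forms no hairpin. `run_pipeline()` chains all stages over the full
1,680-candidate catalog and returns the ranked shortlist;
`inst/cli/mimorank.R` exposes `generate`, `predict-bcell`, `fold`,
`rank`, and `fixtures` subcommands for shell use.

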