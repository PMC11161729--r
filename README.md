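# ptxrank

Discovery and prioritization of protein biomarkers that predict response to
platinum-based adjuvant chemotherapy (ACT) in non-small cell lung cancer
(NSCLC), from label-free spectral-count proteomics of paired patient
cohorts.

## The problem

Resected stage II–IIIA NSCLC is treated with platinum-based ACT in a
one-size-fits-all manner, yet many patients derive no benefit. A
tissue-based predictive biomarker would spare non-responders the toxicity
and redirect them to alternative regimens. Mass-spectrometry proteomics of
treatment-naive resection material offers a direct read-out of the protein
pathways (DNA damage repair, stromal/EMT state, cytoskeletal regulation)
that determine platinum sensitivity — but turning two cohorts of count
matrices into a defensible, ranked candidate list takes a long chain of
statistical steps. `ptxrank` implements that chain as a tested, reusable
pipeline.

## What it computes

Given protein-by-sample spectral-count and MS1-intensity matrices for a
discovery cohort and a validation cohort (treated + untreated arms), with
recurrence-free survival (RFS) annotations:

1. **Normalization** — counts scaled per sample to the average sample sum.
2. **Differential expression** — samples split into poor (PRG, RFS ≤ 16
   months) and good (GRG, RFS > 24 months) response groups; a
   beta-binomial likelihood-ratio test (shared overdispersion φ, group
   means π_A vs π_B, 2(ℓ₁−ℓ₀) ~ χ²₁) per protein, per histology subtype
   and pan-NSCLC; nested tiers T1 (p < 0.05), T2 (+ ≥ 60% data presence in
   the upregulated group), T3 (+ fold-change > 1.5).
3. **Cross-cohort candidates** — proteins significant with concordant
   direction in both cohorts; hypergeometric overlap testing; candidates
   also differential in the untreated arm flagged as prognostic rather
   than predictive.
4. **Signature search** — exhaustive 4-protein and random 5-protein
   combinations scored by leave-one-out cross-validated AUC of
   ridge-stabilized logistic classifiers, plus forward stepwise signature
   construction.
5. **Scoring** — a 0–11 robustness rubric (count:intensity correlation,
   abundance, tier pair, peptides/MW) plus a 0–4 signature score, combined
   into a composite ranking; the robustness ≥ 7 subset is the reported
   shortlist.
6. **Survival & structure** — Kaplan–Meier / log-rank comparisons,
   top-quartile abundance splits, and unsupervised clustering that
   isolates the mixed-histology poor-response/survival (PR/S) sub-cluster.
7. **Synthetic cohorts** — a generator with planted ground truth
   (overdispersed zero-inflated counts, stromal PR/S block, histology
   block, predictive and prognostic planted markers, group-dependent
   survival) so the whole pipeline is testable without patient data.

See `vignettes/biomarker-discovery.Rmd` for the full model description and
every numerical convention.

## Worked example

```r
library(ptxrank)

res <- run_pipeline(pipeline_config(seed = 7))
res
#> <ptx_pipeline_result>
#>   DE contrasts run: discovery_panNSCLC, discovery_LUAD, discovery_LUSC,
#>     validation_panNSCLC, validation_LUAD, validation_LUSC, untreated_panNSCLC
#>   candidates: 95 (robust subset: 79)

truth <- res$cohorts$truth
mean(truth$planted$protein_id %in% res$candidates$protein_id)
#> [1] 0.94

head(res$scored[, c("protein_id", "direction", "robustness_total",
                    "signature_score", "composite", "rank")])
#>  protein_id direction robustness_total signature_score composite rank
#>       P0335    GRG_up                9               4        13    1
#>       P0337    GRG_up                9               4        13    2
#>       P0363    GRG_up                9               4        13    3
#>       P0381    GRG_up                9               3        12    4
#>       P0494    GRG_up                9               3        12    5
#>       P0357    GRG_up                9               3        12    6
```

Reading the output: the run simulated the default two-cohort design (45
discovery, 22 + 10 validation samples, 500 proteins, 50 planted markers at
fold-change 2), ran all seven differential contrasts, and intersected them
into 95 cross-cohort candidates — recovering 94% of the planted markers.
The top-ranked candidates combine a robustness score of 9 (of 11) with
signature scores of 3–4 (of 4): they sit in the best LOOCV-AUC protein
combinations *and* are well-quantified, reproducibly significant and
abundant in both cohorts. The pan-NSCLC hit lists of the two cohorts
overlapped in 67 of 495 co-tested proteins (hypergeometric p ≈ 7e-23).

A thin command-line wrapper is installed with the package
(`inst/scripts/ptxrank`): `ptxrank simulate`, `ptxrank preprocess`,
`ptxrank run`.

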