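# sighub

Seed-gene-guided discovery and survival validation of transcriptional
**signaling hub signatures** in tumor expression cohorts.

## The scientific problem

Multidomain signaling effectors (chemotactic receptors, their kinases,
phosphatases and adaptors) often rise and fall together. When a tumor
cohort is split 50:50 by the expression of one such *seed gene*, the
patients in the high half may carry a whole co-expressed signaling
repertoire — and shorter survival with it. `sighub` implements that
discovery procedure end to end, for anyone with a gene × sample expression
matrix, overall-survival follow-up, and a signaling-protein annotation:

1. **Stratify** samples 50:50 by seed expression (deterministic tie rule).
2. **Rank** every gene by Spearman correlation ρ with the seed, separately
   per stratum, and cut the rankings into quartiles (`ceiling(G/4)` genes
   in the top quartile).
3. **Intersect** the high-stratum top quartile with the signaling
   annotation.
4. **Contrast filter**: keep genes with ρ<sub>high</sub> ≥ 0.2 and
   ρ<sub>high</sub> > ρ<sub>low</sub>.
5. **Survival filter**: per gene, median-split the cohort on that gene and
   keep it iff the log-rank p < 0.05 *and* the high half fares worse
   (direction = sign of observed − expected events in the high half).
6. Optionally **expand** retained kinases to their phosphosubstrates,
   which must independently pass filters 4–5.

The signature (seed + partners) is then scored per sample as the mean
z-score of log2(x+1) expression over signature genes and validated as a
risk factor with a **univariate Cox proportional-hazards model**
(self-implemented: Newton–Raphson with step-halving, Efron tie handling),
alongside median-split Kaplan–Meier curves and the log-rank test. A
microenvironment module correlates signature genes with cell-type markers
and computes rank-based single-sample immune/stromal enrichment scores; a
genomic-context module filters dependency screens (T ≤ −0.5 inclusive,
T < −3 strict) and relates mutation status to seed expression.

Because real discovery cohorts are external downloads, the package ships a
**synthetic cohort generator** that plants known structure — a seed gene, a
partner module whose Spearman correlation with the seed is
stratum-dependent (Gaussian-copula loading `2·sin(πρ/6)`), Weibull survival
whose log-hazard follows the planted module, calibrated uniform
right-censoring — so every stage is testable against ground truth.

## Worked example

```r
library(sighub)

co  <- generate_cohort(cohort_params(n_samples = 510, n_genes = 2000,
                                     n_partners = 20, rng_seed = 2024))
sig <- build_hub_signature(co$expression, co$clinical, co$annotation,
                           seed_gene = "SEED1")
print(sig)
#> Signaling hub signature around 'SEED1': 20 partner(s)
#>   funnel: 2000 genes -> 500 top-quartile -> 21 contrast -> 20 signaling
#>           (+0 substrates) -> 20 survival-retained
#>    gene     rho_low rho_high quartile_low quartile_high logrank_p ...
#>  1 G000006 -0.00583    0.574            2             4  3.75e- 5
#>  2 G000001  0.0141     0.561            3             4  2.30e-13
#>  ...

risk <- cox_risk_validation(signature_score(co$expression, sig), co$clinical)
glance(risk)
#>       n n.events hazard.ratio    cox.p logrank.p n.genes.used n.genes.missing
#> 1   510      354         4.84 2.69e-38  5.66e-31           21               0
```

The funnel line mirrors the stage-by-stage gene counts (total → top
quartile → contrast → signaling → survival-retained); here all 20 planted
partners are recovered with no false positives, and a unit increase of the
standardized risk score multiplies the hazard by ≈ 4.8. `autoplot(risk)`
draws the two KM curves; `tidy(sig)` returns the per-gene statistics
table. `run_pipeline(sighub_config(...))` drives the same stages from file
inputs and writes a reproducibility manifest;
`inst/cli/sighub.R` is a thin command-line wrapper.

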