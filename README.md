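# glnfate

Quantitative toolkit for resolving the fate of glutamine nitrogen in cancer
cells: is the amide (γ) nitrogen released as ammonia by glutaminase (GLS1)
while the carbon skeleton feeds the TCA cycle (glutaminolysis), or is it
transferred by amidophosphoribosyl transferase (PPAT) onto PRPP to build
purines de novo? The package is written for metabolism researchers who work
with dual [¹³C₅/¹⁵N₂]glutamine tracing, targeted (MRM) proteomics and
prognostic cohort data, and want the full analysis chain as tested,
reusable functions.

Four layers, usable separately or chained:

* **Isotopologue engine** — exact masses of (n¹³C, n¹⁵N) isotopologues
  (¹³C adds 1.0033548 Da, ¹⁵N adds 0.9970349 Da; their 0.0063199 Da gap is
  the mass defect that makes the dual tracer readable at high resolving
  power), resolution-aware peak assignment, natural-abundance correction by
  non-negative least squares, and the percent-labeled atom fraction
  `Σ k·f_k / n_atoms`.
* **Kinetic labeling model** — first-order enrichment balance equations for
  well-mixed pools, `dx/dt = (v·s − (v+d)·x)/P`, with an editable atom map
  (purine nitrogens from glutamine amide, aspartate and glycine), pathway
  scores from early/late time points, and flux recovery by bounded least
  squares.
* **MRM quantification** — endogenous amount = (Σ light / Σ heavy) × spike,
  protein aggregation (mean ± s.d. over peptides), copies per cell via
  Avogadro scaling, and enzyme-panel summaries (z-scores, PPAT/GLS1 ratio).
* **Survival meta-analysis** — median-split univariate Cox hazard ratios
  per cohort (Efron ties), Kaplan-Meier and log-rank, inverse-variance
  fixed-effects and DerSimonian-Laird random-effects pooling with Q, τ²
  and I², per organ and integrated.

A synthetic-data module generates every input with known ground truth
(labeled peak lists, transition tables, survival cohorts), so each estimator
has a closed-loop recovery test.

## Worked example

Simulate the premalignant ("TSM-like") and malignant ("AIG3-like") presets
and score the nitrogen shift:

```r
library(glnfate)
library(dplyr)

tsm  <- pathway_scores(simulate_labeling(scenario_presets("TSM-like")$pool_model))
aig3 <- pathway_scores(simulate_labeling(scenario_presets("AIG3-like")$pool_model))
bind_rows(TSM = tsm, AIG3 = aig3, .id = "preset")
#> # A tibble: 2 × 4
#>   preset glutaminolysis_score denovo_score nitrogen_shift_index
#>   <chr>                 <dbl>        <dbl>                <dbl>
#> 1 TSM                 0.0454         0.146                 1.69
#> 2 AIG3                0.00998        0.430                 5.43
```

The glutaminolysis score is the ¹³C atom fraction of α-ketoglutarate at
0.25 h (fast pools report anaplerotic flux early); the de novo score is the
¹⁵N atom fraction of IMP at 6 h (slow nucleotide pools report PPAT flux
late). The malignant preset shows the shift: less early carbon labeling
(GLS1 down), about three-fold more late nucleotide nitrogen labeling (PPAT
up), and a higher log2 shift index.

Pooling two discrepant cohort effects (log HR 0 and 1, both SE 0.1)
reproduces the textbook DerSimonian-Laird arithmetic:

```r
pool_effects(tibble::tibble(log_hr = c(0, 1), se = c(0.1, 0.1)), model = "fixed")
#> fixed-effects pooling of 2 cohorts
#> HR 1.649 [1.364, 1.994], p = 2.58e-07
#> Q = 50.00 (df 1), tau2 = 0.490, I2 = 98.0%
```

And the copies-per-cell conversion at 10 fmol/µg with 2.5 × 10⁻⁴ µg protein
per cell:

```r
copies_per_cell(10, 2.5e-4)
#> [1] 1505535
```

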