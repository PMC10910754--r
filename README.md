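# ngrscreen

Quantification of drug response in imaging-based 2D and 3D cell-culture
screens using the **Normalized Growth Rate (NGR)** and the **area over the
dose–response curve (AOC)** — the metrics that make cytostatic and cytotoxic
drug effects distinguishable, and 2D monolayer and 3D spheroid screens
directly comparable, where a classical viability IC50 cannot.

The intended user runs 384-well screens in which whole-well brightfield and
green-fluorescence (dead-cell) images have already been segmented into a
*total area* and a *dead area* per well per timepoint — for example TKI
resistance profiling of kinase-mutant cell lines. `ngrscreen` takes those
area tables and produces per-replicate dose–response fits, sensitivity
scores, fold changes versus a reference line, and Dunnett-adjusted
significance calls. A seeded synthetic-plate generator makes the whole
pipeline runnable and testable with no external data.

## The model

Per well, with viability floored at zero:

```
V = max(0, total_area − dead_area)            viability
G = (V(x) − V(0)) / V(0)                      fractional growth to time x
```

Growth is normalized per plate against the median vehicle control
(`GmedNeg > 0`) and the median positive (staurosporine) control
(`GmedPos < 0`):

```
NGR =  G / GmedNeg        if G > 0
    = −(G / GmedPos)      if G < 0          (0 maps to 0)
NGR = clip(NGR, [−1, 1])
```

so NGR = 1 is untreated-like growth, 0 is complete growth inhibition
(cytostasis), and −1 is complete killing as in the positive control.
Note the explicit minus sign in the `G < 0` branch: the convention is
sometimes printed without it, which would assign +1 to complete killing and
contradict the classification legend; this package uses the signed form so
the anchors above hold.

NGR versus concentration is fitted with the sigmoidal GR equation

```
GR(c) = GRinf + (1 − GRinf) / (1 + (c / GEC50)^h_GR)
```

by bounded nonlinear least squares (initial guesses 0.1 / median tested
concentration / 2; bounds GRinf ∈ [−1,1], GEC50 ∈ [c_min/10, 10·c_max],
h_GR ∈ (0,10]). After the first convergence a single outlier pass removes
points whose absolute residual exceeds **both** 2.5× the mean absolute
residual **and** 0.25, and refits once. From the fitted curve:

* **NGR50** — the concentration where the curve crosses 0.5 (closed form;
  right-censored `"> c_max"` when unreachable);
* **AOC** — the area between `y = 1` and the curve over the tested
  log10-concentration range, normalized by its maximum (2 × log-range), so
  AOC ∈ [0, 1]: 0 = inert, 0.5 = full cytostasis, 1 = complete killing.

Replicate-level AOCs are compared by two-way ANOVA (cell line × drug, with
interaction, 2D and 3D analysed separately) with Dunnett many-to-one
contrasts against the reference line (exact multivariate-t adjustment,
α = 0.05), and summarized as signed fold changes: `+test/ref` when the test
line is more sensitive, `−ref/test` when less.

## Worked example

Simulate a resistant-line scenario, run the pipeline, and compare against
the wild-type reference:

```r
library(ngrscreen)
cfg <- pipeline_config("g2032r_like_resistant", seed = 7,
                       out_dir = "demo_run")
res <- run_pipeline(cfg)
summarize_metrics(res$metrics)
#>     cell_line  drug culture n_replicates AOC_mean  AOC_sd NGR50_mean NGR50_sd
#> 1 G2032R_like tki_a      3D            3   0.0702 0.00165     1806.0   300.00
#> 2          WT tki_a      3D            3   0.4786 0.01859       21.6     3.63
#> 3 G2032R_like tki_b      3D            3   0.0555 0.00245     2348.7   362.63
#> 4          WT tki_b      3D            3   0.3658 0.02088       48.3    12.75
```

The sensitive WT line has high AOC (≈ 0.48: strong, partly cytotoxic
response) and low NGR50 (≈ 22 nM); the solvent-front-mutant-like line barely
responds (AOC ≈ 0.07, NGR50 ≈ 1.8 µM). The comparison stage quantifies this:

```r
res$comparison$contrasts
#>   culture  drug   cell_line n n_ref estimate     se     t df p_unadjusted p_adjusted significant
#> 1      3D tki_a G2032R_like 3     3   -0.408 0.0115 -35.6  8     4.26e-10   4.26e-10        TRUE
#> 2      3D tki_b G2032R_like 3     3   -0.310 0.0115 -27.0  8     3.77e-09   3.77e-09        TRUE

fold_change_table(summarize_metrics(res$metrics), "WT")
#>   culture  drug   cell_line aoc_ref aoc_test fold_change direction
#> 1      3D tki_a G2032R_like   0.479   0.0702       -6.82  decrease
#> 2      3D tki_b G2032R_like   0.366   0.0555       -6.59  decrease
```

i.e. the mutant's AOC is 6.8-fold lower than wild type under `tki_a`
(p ≪ 0.05 after Dunnett adjustment) — the signature of a strong resistance
mutation.

The same stages are available from the shell via the installed
`exec/ngrscreen` script (`simulate`, `ngr`, `fit`, `compare`, `report`,
`run`), e.g.

```sh
Rscript exec/ngrscreen run --scenario g2032r_like_resistant --seed 7 \
    --out-dir demo_run
```

## Published reference values

`published_aoc_reference()` returns the printed AOC table (mean ± SD) from a
ROS1-rearranged NSCLC TKI screen (wild-type vs G2032R / L2026M / S1986Y
lines, five TKIs, 2D and 3D). These values are **inputs** to the fold-change
worked examples — e.g. 3D ceritinib wild-type 0.51 vs G2032R 0.18 gives
`fold_change(0.51, 0.18)` = −2.83 — not outputs the package claims to
reproduce; the underlying wet-lab screen is not reproducible at desk scale.

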