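# chromlogd

Chromatographic estimation of the apparent *n*-octanol/water distribution
coefficient (logD) of basic compounds from ion-suppression reversed-phase
HPLC retention, for analytical and environmental chemists who need
experimental lipophilicity values for anilines, pyridines, imidazoles and
related bases without shake-flask measurements.

## What it computes

Given isocratic retention times of each solute at several methanol
fractions φ and mobile-phase pH values, the package:

1. corrects retention times for run-to-run drift with two anchor
   compounds (the unique affine map through both anchors);
2. extrapolates the retention factor *k* = (*t*<sub>R</sub> − *t*₀)/*t*₀
   to a fully aqueous mobile phase with the linear solvent strength model

   log₁₀ *k* = log *k*<sub>w</sub> − *S* φ;

3. computes literature logD of calibration compounds from logP and pKa by
   ionization correction (monoprotic base; a second site adds a
   doubly-protonated term):

   logD = logP − log₁₀(1 + 10^(pKa₁ − pH) [+ 10^(pKa₁ + pKa₂ − 2 pH)]);

4. fits per-pH QSRR models logD = *a*·log *k*<sub>w</sub> + Σ *b*ᵢ·descᵢ + *c*
   by OLS over all subsets of the descriptors {*n*ₑ (electrostatic charge),
   A, B (hydrogen-bond acidity/basicity)}, selecting the most parsimonious
   subset not significantly worse than the best fit (partial F test);
5. validates externally by signed percent error against literature logD
   (flagged at the conventional 20% band) and predicts logD of unknowns.

A seeded generator (`generate_study()`) simulates complete studies with
known ground truth, so the whole pipeline is testable offline.

## Worked example

The study tables ship as plain-text fixtures: 42 basic compounds
(23 calibration, 4 verification, 15 samples) with literature logP/pKa, and
their extrapolated log *k*<sub>w</sub> values at pH 7–10.

```r
library(chromlogd)
run <- run_pipeline(
  compounds = chromlogd_example("study_compounds.csv"),
  logkw     = chromlogd_example("study_logkw.csv"))
print(run)
#> chromlogd pipeline run
#>   pH 7    logD = (1.05 ± 0.07) logkw - (0.87 ± 0.15) ne - (0.13 ± 0.12)  [R2 0.9483, N 23]
#>   pH 8    logD = (0.95 ± 0.03) logkw - (0.56 ± 0.11) ne - (0.08 ± 0.06)  [R2 0.9781, N 23]
#>   pH 9    logD = (0.97 ± 0.03) logkw - (0.41 ± 0.16) ne - (0.16 ± 0.06)  [R2 0.9764, N 23]
#>   pH 10   logD = (0.98 ± 0.04) logkw - (0.23 ± 0.07)  [R2 0.9674, N 23]
#>   validation records: 16; predictions: 15
```

Each line is the selected QSRR model at that pH with OLS estimates ±
standard errors.  At pH 7–8 retention alone correlates poorly with logD
because strongly basic solutes are protonated; the charge descriptor *n*ₑ
(here derived from pKa, since curated descriptor values are not shipped)
absorbs the electrostatic retention loss and lifts R² at pH 7 from ~0.86
to 0.95.  At pH 10 dissociation is suppressed and the plain
logD–log *k*<sub>w</sub> line is selected.

External validation against the four held-out compounds:

```r
head(subset(run$validation, pH == 7), 4)
#>    compound_id pH literature_logD determined_logD error_pct  pass
#> 1           24  7        2.049663        1.863892 -9.063510  TRUE
#> 5           25  7        1.738983        1.820702  4.699233  TRUE
#> 9           26  7        1.631251        1.612732 -1.135218  TRUE
#> 13          27  7        1.262518        1.545388 22.405290 FALSE
```

`error_pct` is 100·(determined − literature)/literature; negative means
under-prediction.  Dibenzylamine (id 27, pKa 8.76) at pH 7 is the hardest
case — almost fully ionized — and with pKa-derived charges it lands just
outside the 20% band (the original study, using curated descriptor
values, reported 20.63% for the same cell).

Sample predictions require either supplied descriptor columns or the
univariate model (`candidates = character(0)`), which predicts all
15 samples at every pH from log *k*<sub>w</sub> alone.

Raw retention input works the same way through `retention =` (long CSV of
`compound_id,pH,phi,tR,t0` plus optional anchor columns); see
`?fit_lss` and `?run_pipeline`.

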