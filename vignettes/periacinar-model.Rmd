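---
title: "Modelling peri-insular acinar expansion and pancreas volume"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling peri-insular acinar expansion and pancreas volume}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periacinar)
```

## The scientific problem

The pancreas of individuals with longstanding type 1 diabetes is 30–40%
smaller than that of non-diabetic controls, far more than the 1–3% of organ
volume that beta cells themselves occupy. A leading explanation is loss of
insulin's local trophic effect: histology shows a halo of hypertrophic and
hyperplastic acinar cells surrounding islets, and this peri-insular expansion
disappears when beta cells are destroyed. `periacinar` implements a
geometric model of this mechanism, mapping beta-cell density, islet (cluster)
size, the spatial extent of insulin action, and the magnitude of acinar
expansion to whole-pancreas volume — and inverting an observed pancreas
volume back to a beta-cell density estimate, the radiological use case.

## The model

**Cells and clusters.** A beta cell is a sphere of radius $r = 5\ \mu m$,
volume $\tfrac{4}{3}\pi r^3 \approx 524\ \mu m^3$. A cluster of $n$ cells is
a single sphere of the same total volume (no extracellular space), so its
radius is $r\,n^{1/3}$.

**Insulin action.** Two alternatives describe the insulin-affected acinar
region around a cluster of radius $r_0$:

- *Constant shell*: insulin acts homogeneously within a concentric shell of
  thickness $t$ beyond the cluster edge, affected volume
  $\tfrac{4}{3}\pi\left[(r_0+t)^3 - r_0^3\right]$.
- *Exponential gradient*: insulin action is maximal at the cluster edge and
  decays with distance with decay length $\lambda$; the effective
  (distance-weighted) volume is
  $\int_{r_0}^{r_0+5\lambda} 4\pi r^2 e^{-(r-r_0)/\lambda}\,dr$,
  truncated at $5\lambda$ where the weight has fallen below 1%. The closed
  form (see `?gradient_effective_volume`) is verified in the test suite
  against adaptive quadrature to $10^{-9}$ relative; a Monte-Carlo rejection
  sampler provides an independent stochastic oracle for the shell volume.

**Acinar expansion.** Within the affected region, acinar volume grows by a
fraction $f$ ($f = 1$ is doubling; $0.2$ and $0.5$ model weaker responses).
The added acinar volume per cluster is $f$ times the affected volume — for
the gradient model the effective volume already carries the distance
weighting, so a single multiplicative $f$ applies to both models.

**Whole organ.** The dimensionless *expansion ratio* $k$ is added acinar
volume per unit beta-cell volume; for a mixture of cluster sizes,
$k_{\mathrm{eff}}$ is the weighted mean with weights the fractions of total
beta-cell volume held in each size. With baseline volume $V_0 = 60$ ml (the
beta-cell-free, longstanding-T1D average), reference volume
$V_{\mathrm{ref}} = 90$ ml (non-diabetic), and beta-cell density $d$ (up to
3%), the predicted pancreas volume is

$$V(d) = V_0 + d\,V_{\mathrm{ref}}\,(1 + f\,k_{\mathrm{raw}}),$$

where $d\,V_{\mathrm{ref}}$ is the total beta-cell volume and
$d\,V_{\mathrm{ref}}\,f\,k_{\mathrm{raw}}$ the insulin-driven acinar
increment. The relation is affine in $d$, with intercept $V_0$ and slope
$V_{\mathrm{ref}}(1 + k_{\mathrm{eff}})$, and inverts in closed form:
$\hat d = (V_{\mathrm{obs}} - V_0)/(V_{\mathrm{ref}}(1 + k_{\mathrm{eff}}))$.

```{r}
calib <- calibration_config()            # 60 ml baseline, 90 ml reference
singles <- size_distribution(1, 1)
pancreas_volume(0.03, calib, singles, shell_action(10))   # 132.9 ml
estimate_density(96.45, calib, singles, shell_action(10)) # 0.015
```

## The overlap argument

Cells inside a large cluster share one zone of influence, so the trophic
footprint per beta cell shrinks with cluster size — the model's central
qualitative prediction, and the reason pancreas volume should be especially
sensitive to the loss of single beta cells and small islets early in type 1
diabetes:

```{r}
per_cell_added_volume(1,   shell_action(20))   # ~64,900 um^3 per cell
per_cell_added_volume(100, shell_action(20))   # ~2,855 um^3 per cell: ~23x less
```

## Parameters and defaults

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| cell radius | 5 | µm | histological beta-cell diameter of 10 µm |
| cluster sizes | 1, 5, 25, 100, 250, 500, 1000 | cells | autopsy-informed islet-size range |
| shell thickness $t$ | 1, 5, 10, 20, 30 | µm | brackets the ~33 µm peri-islet action width reported histologically |
| decay length $\lambda$ | 1, 5, 10, 20, 30 | µm | same spatial range as $t$ |
| gradient truncation | 5 | $\lambda$ | weight < 1% beyond; configurable |
| expansion $f$ | 1.0 (also 0.5, 0.2) | — | doubling of acinar volume, per histology; weaker responses for sensitivity |
| $V_0$ | 60 | ml | meta-analytic longstanding-T1D mean |
| $V_{\mathrm{ref}}$ | 90 | ml | meta-analytic non-diabetic mean |
| density range | 0–0.03 (step 0.001) | fraction | updated beta-cell density estimate of up to 3% |
| mixed distribution | 5/10/20/40/20/5% across 1/10/25/100/250/1000 cells | beta-volume fractions | approximates autopsy islet-size findings |

The mixture weights are fractions of **total beta-cell volume**, not counts
of clusters; this is the reading under which the expansion-magnitude
thresholds (50% expansion reaching 90 ml only at the 30 µm shell; 20% only
at the 30 µm decay length) hold numerically.

## Design choices

- **Density basis.** "Beta-cell volume comprising 3% of the pancreas" is
  taken as 3% of the *non-diabetic reference* volume, so total beta volume
  is $d\,V_{\mathrm{ref}}$ and $V(d)$ is affine. The self-consistent
  alternative — density relative to the predicted volume itself, giving
  $V = V_0/(1 - d(1+k_{\mathrm{eff}}))$ — is available via
  `calibration_config(density_basis = "modeled")` for sensitivity analysis;
  only the default reproduces the reference-volume threshold pattern.
- **Composition formula.** $V(d) = V_0 + dV_{\mathrm{ref}}(1 + f k)$ is the
  minimal additive decomposition (baseline exocrine tissue + beta-cell
  volume + acinar increment) consistent with the 60 ml intercept, linearity
  in density, and the threshold pattern. Whether the beta-cell volume itself
  sits inside the 60 ml baseline or on top of it is unresolvable from the
  calibration alone; the default adds it, a $\le 2.7$ ml effect at 3%
  density.
- **Shell semantics.** The shell parameter is a *thickness beyond the
  cluster edge*: outer radius $= r_0 + t$. For clusters, $r_0$ is the
  equivalent-sphere cluster radius in both action models.
- **No inter-cluster overlap.** Affected regions of distinct clusters are
  assumed disjoint, so added volumes sum; 100 disjoint single cells add
  exactly 100 times one cell's increment.
- **Insulin output per cell** is independent of cluster size; no secretion
  scaling, consumption, binding, or vascular geometry.

## Numerical choices

- All geometry is exact closed-form in µm³; the single unit conversion
  (1 ml = $10^{12}$ µm³, `UM3_PER_ML`) lives in one exported constant.
- The gradient closed form must agree with `stats::integrate` quadrature to
  $10^{-9}$ relative over $r_0 \in [5, 50]$, $\lambda \in [1, 30]$; the
  Monte-Carlo shell oracle must bracket the closed form within 3 binomial
  standard errors at $10^6$ samples. Both checks run in the test suite.
- The Monte-Carlo oracle takes an explicit seed and restores the caller's
  RNG state; nothing else in the package is stochastic.
- Distribution weights within $10^{-6}$ of summing to one are renormalised
  with a warning; larger deviations are an error. Degenerate inputs
  (zero thickness, $f = 0$, $d = 0$) are valid and return exact zeros or the
  baseline volume.
- Published worked-example figures (64,973; 6,497,300; 287,431 µm³) differ
  from the exact closed forms by 0.07–0.7%, presumably printing/rounding in
  the source material; the implementation is exact and comparisons against
  those figures use a 1% relative tolerance.

## Known limitations

- One published claim — that for single beta cells *every* decay length
  reaches the 90 ml reference at 3% density — is not reproducible under this
  (or any additive) composition: $\lambda = 1\ \mu m$ yields ≈65 ml. All
  other threshold statements reproduce exactly; this one is excluded from
  the package's checks and flagged here.
- The model is cross-sectional (one time point); temporal T1D progression,
  hypertrophy-vs-hyperplasia, non-spherical cells, non-beta endocrine
  cells, insulin consumption and vasculature are out of scope by design.
- Predictions are organ-scale averages; body size, age and sex covariates of
  pancreas volume are not modelled — calibrate $V_0$ and
  $V_{\mathrm{ref}}$ to the population of interest instead.

## Reproducing the figure-style sweeps

The packaged presets rebuild each figure's parameter grid as a tidy table
(one row per density × configuration; sizes as in the table above, density
step 0.001, i.e. 31 grid points per curve — seconds of CPU):

```{r, eval = FALSE}
fig2 <- run_figure2_sweep()            # shell model, single sizes, f = 1
fig3 <- run_figure3_sweep()            # gradient model, single sizes, f = 1
fig4 <- run_figure4_sweep()            # mixed distribution, f in {0.2, 0.5, 1}
write_sweep_csv(fig4, "figure4.csv")
```

The same sweeps are available from the shell via the `periacinar` script
installed in `exec/`.
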