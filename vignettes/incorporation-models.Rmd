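---
title: "Isotope incorporation models for diet-switch experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope incorporation models for diet-switch experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoturn)
```

## The models and their assumptions

After a diet switch, tissue isotope values are assumed to follow a
first-order one-compartment process: the whole animal is a single,
well-mixed isotope pool relaxing toward equilibrium with the new diet.
`isoturn` fits the two standard parameterizations of that process.

**Growth-based model G** expresses the relaxation against the fold
increase in dry weight since the switch, $W_R = W_t / W_i$:

$$\delta = \delta_{eq} + a\,W_R^{\,c}$$

$\delta_{eq}$ (‰) is the fitted equilibrium value, $a = \delta_i -
\delta_{eq}$ (‰) the fitted initial offset, and $c$ (dimensionless,
negative) the metabolic decay constant. $c = -1$ is the simple dilution
model — isotopic change caused purely by new biomass diluting old — and
$c < -1$ means metabolic replacement adds to the shift.

**Time-based model D** expresses it against days since the switch:

$$\delta = \delta_{eq} + a\,e^{-(m+k)t}$$

with $k$ (day⁻¹) the specific growth rate and $m$ (day⁻¹) the metabolic
constant. Crucially, $k$ is *measured* from dry weights —
$k = \ln(W_R)/t$ over the switch-to-final interval, averaged over
replicate tanks — and held fixed during fitting; only $(\delta_{eq}, a,
m)$ are estimated. $m$ and $k$ enter the model only as their sum, so a
mis-measured $k$ shifts $\hat m$ one-for-one in the opposite direction
(the test suite asserts this identity). Both models assume growth and
metabolism act independently; under exponential growth they are the same
curve with $c = -(m+k)/k$.

## Derived quantities

Solving each model for a percentage $\alpha$ of completed turnover gives

$$G_\alpha = e^{\ln(1-\alpha/100)/c}, \qquad
  D_\alpha = \frac{|\ln(1-\alpha/100)|}{m+k}.$$

The absolute value in $D_\alpha$ is deliberate: the raw logarithm is
negative and a turnover time must be a positive duration. Defaults are
$\alpha \in \{50, 95\}$ (half-life and practical equilibrium); any pair
can be supplied. Whatever the rate, $D_{95}/D_{50} = \ln 0.05/\ln 0.5
\approx 4.32$ — equilibrium after four to five half-lives.

The partition of turnover between growth and metabolism is
$P_g = 2(G_{50}-1)/G_{50}$ and $P_m = (2-G_{50})/G_{50}$. Raw $P_m$ is
negative whenever $G_{50} > 2$; `partition_turnover()` clips $P_m$ to
$[0,1]$ and sets $P_g = 1 - P_m$, reading any $G_{50} \ge 2$ as "no
metabolic contribution". The clipped pair always sums to one.

Discrimination factors are $\Delta\delta = \delta_{eq} -
\delta_{diet}$ per model, and `average_discrimination()` reports the
cross-model mean ± sd per diet and isotope (sd is `NA`, flagged by
`n_models`, when only one model is available).

## Preprocessing conventions

**Lipid normalization.** Lipids are ¹³C-depleted, so lipid-rich samples
(C:N mass ratio above 3.56, strict) are corrected before fitting. The
correction is a taxon- and isotope-specific *multiplicative* factor on the
raw δ value (`lipid_factors()`: 0.940/0.922/0.903 for δ¹³C and
1.370/1.059/1.019 for δ¹⁵N in copepods, *Artemia* and seahorse tissue).
The factors are dimensionless scalars, which is the only convention a
bare conversion factor supports; because this choice is not forced by
theory, the factor table is exposed as data so an additive-offset scheme
can be substituted by pre-transforming inputs without code changes.
Normalization is applied per sample, only where the C:N trigger fires.

**Growth rate.** $k$ uses endpoint weights only (switch day and final
day), which is the definition embedded in the model; a log-linear
regression through all days is available (`method = "regression"`) but is
never the default. Models are fitted on replicate-mean values per
sampling day, with $k$ the mean of per-tank endpoint rates; a
per-replicate fitting mode (`fit_mode = "replicates"`, SE from the
between-tank spread) is provided because the provenance of reported
standard errors in this kind of study is often ambiguous.

## Fitting

Estimation is bounded nonlinear least squares: `stats::nls` with the
`"port"` trust-region algorithm, falling back to Levenberg–Marquardt
(`minpack.lm::nlsLM`) if port fails to start. Starting values exploit the
monotone trajectories — $\delta_{eq}$ from the last observation, $a$ from
the endpoint difference, $c = -1$, $m = 0$. Bounds are $c \in [-10,
-0.01]$ (an equilibrium-approaching system needs $c < 0$) and $m \in [0,
1]$ ($m < 0$ is biologically unidentified in this design). Non-convergence
and degenerate inputs (a flat δ series leaves the rate unidentifiable) are
reported through the `converged` and `flags` fields of the returned
`incorp_fit`, never raised as errors and never silently retried.
Standard errors come from the NLLS covariance of the pooled (replicate-
mean) fit by default; confidence intervals are Wald intervals with
$n - 3$ degrees of freedom.

## Scale conversion

To compare the models, turnover estimates are moved between the fold-mass
and chronological scales through a `growth_curve()`. The default is
monotone piecewise-linear interpolation of $\ln W$ against day through
the observed mean weights, which makes the two directions exact inverses
within the observed range (extrapolation beyond it is flagged with a
warning). A closed-form exponential option ($W_R = e^{kd}$) is available
and is what the tests use, since it is exact under the generator's growth
model. The interpolated and exponential conversions differ on real data
precisely where growth is not exponential — early development, in
particular — and this is why cross-scale columns computed here do not
reproduce the reference trial's printed cross-converted columns, whose
transformation was produced with the original per-batch weight curves
(see "Reference inconsistencies").

## The synthetic generator

`simulate_experiment()` generates complete experiments in the same CSV
schema the pipeline reads. What it emulates: the reference design (two
diets switching at day 6/11, two tanks, sampling at days 6, 11, 18, 25,
32, 46, 60, pooled samples), near-exponential growth
($W = w_0 e^{k(d-\text{switch})}$ times lognormal tank noise, CV 0.12,
matched to the day-60 between-tank spread of the reference weights),
isotope relaxation by the model-D forward process, and i.i.d. Gaussian
analytical noise of 0.15 ‰ (the reference laboratory's 1-σ precision).
Default kinetic truths are the reference model-D estimates; the offsets
$a$ are back-computed so the simulated first-five-day enrichments match
the observed trajectories (A11: 1.3 ‰ δ¹³C and 2.7 ‰ δ¹⁵N). One root
seed drives deterministic per-(diet, tank) streams, so adding a replicate
never perturbs existing ones. Simulated C:N is held at 3.0: generated δ
values are defined as already lipid-normalized.

What it does **not** emulate: biological scatter beyond analytical noise
(tank effects on δ, individual condition, diet batch variation),
mortality, non-exponential growth (a logistic option would be the natural
extension), or autocorrelated residuals. Consequences worth knowing:
synthetic fits are *cleaner* than real ones — R² on synthetic series at
the reference design is ≈ 0.99, whereas the reference fits ranged
0.78–0.96 — so passing recovery tests demonstrates the estimator works,
not that real data are this kind; and since isotope noise enters through
time, not weights, the model-D truth is exact even with weight noise,
while the model-G truth $c = -(m+k)/k$ is defined only for the
deterministic growth trajectory. Validation therefore checks model-D
coverage at the full defaults and model-G coverage with `weight_cv = 0`;
with tank-weight noise on, $W_R$ is an error-contaminated regressor and
measured coverage for $c$ drops to roughly 0.85–0.90 — a real
errors-in-variables limitation of growth-based fitting, documented rather
than hidden.

## Validation and problem sizes

The test suite checks, among others: exact recovery of generating
parameters from noise-free data (tolerance 1e−6, R² = 1); Wald 95% CI
coverage of every parameter ≥ 90% across 200 simulated experiments at
0.15 ‰ noise (both models, both diets and isotopes — about 1600 fits,
well under a minute); mean recovery of $(\delta_{eq}, a)$ within two
Monte-Carlo standard errors over 500 noisy fits, with median recovery for
the boundary-constrained $m$ (its sampling distribution is truncated at
zero, so the mean is not the right centre); the $1/\sqrt{n}$ scaling of
standard errors under design replication; and the algebraic invariants
(dilution limit, fixed $D_{95}/D_{50}$ ratio, partition closure,
discrimination antisymmetry). These sizes were chosen as the smallest
that make the Monte-Carlo assertions stable.

## Reference inconsistencies

Recomputing the reference trial's derived columns from its own printed
parameters (`reproduce_reference()`) reproduces almost every cell to the
printed decimal. Four cells do not reproduce, and the package documents
rather than matches them:

- Model G, δ¹³C, diet A11: printed $G_{95} = 43.7$ versus
  $e^{\ln 0.05 / -1.037} = 18.0$; and printed $\Delta\delta = 3.4$ ‰
  versus $-15.7 - (-18.03) = 2.3$ ‰ (the trial itself flags 3.4 as
  overestimated). Most plausibly these were computed per replicate from
  divergent tank fits; only pooled parameters are printed.
- Model D, δ¹³C A11 $D_{95}$ (printed 28.6, recomputed 28.7 — the printed
  $D_{50}/D_{95}$ pair also violates the fixed 4.32 ratio) and δ¹⁵N A6
  $D_{95}$ / δ¹⁵N A11 $D_{50}$ (0.1–0.2 day differences), consistent with
  per-tank $k$ values that endpoint means cannot recover.

The printed cross-converted columns (model-G turnover re-expressed in
days and vice versa) are likewise not recoverable because the original
transformation used unpublished per-batch weight curves; `isoturn`
replaces them with the explicit, invertible conversion described above.

## Known limitations

Single-compartment, single-tissue only; no Bayesian fitting or model
selection (both models are reported side by side, as is conventional);
the multiplicative lipid-normalization convention is an interpretation of
bare conversion factors; and growth-based fits inherit the
errors-in-variables caveat above whenever weights are noisy.
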