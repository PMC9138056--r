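# isoturn

Stable-isotope turnover and diet–tissue discrimination after a laboratory
diet switch.

## The problem

When a consumer is moved onto an isotopically distinct diet, its tissue
δ¹³C and δ¹⁵N values relax toward equilibrium with the new diet. How fast
that happens — and how much of it is due to growth (old tissue diluted by
new biomass) versus metabolism (existing tissue replaced) — is central to
interpreting field isotope data and, in aquaculture, to judging how well a
prey is assimilated. `isoturn` implements the standard first-order
one-compartment analysis of such diet-switch experiments. It was developed
around the early rearing of seahorse *Hippocampus reidi* juveniles switched
from copepods to *Artemia* nauplii at day 6 or day 11 after release (diet
groups A6 and A11), but applies to any single-tissue diet-switch design.

Two models are fitted to each post-switch isotope series:

- **growth-based model G**: δ = δ_eq + a·W_R^c, where W_R = W_t/W_i is the
  fold increase in dry weight since the switch. c = −1 is pure growth
  dilution; c < −1 indicates additional metabolic turnover.
- **time-based model D**: δ = δ_eq + a·e^(−(m+k)t), where t is days since
  the switch, k = ln(W_R)/t is the specific growth rate measured from dry
  weights (held fixed), and m is the fitted metabolic constant.

From the fits the package derives:

- turnover: G_α = e^(ln(1−α/100)/c) (fold mass) and
  D_α = |ln(1−α/100)|/(m+k) (days), at α = 50 (half-life) and 95
  (practical equilibrium);
- the growth/metabolism partition P_g = 2(G₅₀−1)/G₅₀,
  P_m = (2−G₅₀)/G₅₀ (clipped to [0, 1]);
- diet–tissue discrimination factors Δδ = δ_eq − δ_diet, per model and
  averaged across models.

It also provides lipid normalization of raw δ values (triggered at
C:N > 3.56), conversion of turnover estimates between the fold-mass and
chronological scales through an observed growth curve, and a synthetic
experiment generator with known ground truth for validation.

## Worked example

Simulate a diet-switch experiment at the reference design (two diets, two
tanks, sampling days 6–60, analytical noise 0.15‰), fit the time-based
model to the A11 δ¹⁵N series, and run the full pipeline:

```r
library(isoturn)
exp <- simulate_experiment(default_config(seed = 42))
means <- subset(replicate_means(exp$observations), diet_group == "A11")
fitd <- fit_model_d(means$day - 11, means$d15N, k = 0.0694,
                    isotope = "d15N", diet = "A11")
summary(fitd)
#> Incorporation model D: n = 6, R2 = 1.000, sigma = 0.041
#>           Estimate Std. Error t value
#> delta_eq 14.571008   0.033722  432.09
#> a        -6.793319   0.049626 -136.89
#> m         0.031678   0.001809   17.52
#> k (fixed): 0.0694 / day
#> Turnover:
#>   d50   d95
#>  6.86 29.64
```

The fitted tissue reaches δ¹⁵N equilibrium at 14.57‰ (truth 14.6), the
metabolic constant is 0.032/day (truth 0.030), half the isotopic shift is
complete 6.9 days after the switch and 95% after 29.6 days (about 4.3
half-lives, as the first-order model requires).

```r
report <- run_analysis(exp$observations, exp$prey)
print(report)
#>   diet_group isotope model delta_eq ... g50 d50  d95   p_g   p_m delta_delta
#> 5        A11    d13C     G    -15.6 ... 1.6 6.1 29.6 0.759 0.241         2.4
#> 6        A11    d13C     D    -15.6 ... 1.7 6.9 30.0 0.842 0.158         2.4
#> ...
#> Cross-model discrimination averages (permil):
#>   diet_group isotope n_models dd_mean dd_sd
#> 1         A6    d13C        2     1.6   0.1
#> 2         A6    d15N        2     2.0   0.1
#> 3        A11    d13C        2     2.4   0.0
#> 4        A11    d15N        2     2.3   0.0
```

Each report row is one (diet, isotope, model) fit: parameters ± SE, R²,
turnover on both scales (the non-native scale converted through the
observed weight curve), the growth/metabolism partition and the
discrimination factor against the *Artemia* baseline (−18.0‰ δ¹³C,
12.3‰ δ¹⁵N).

A thin command-line wrapper with `simulate`, `fit`, `report` and
`reproduce` verbs is installed at `inst/cli/isoturn.R`.

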