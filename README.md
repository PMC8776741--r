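# imkfit

Cell-survival modelling for acquired radioresistance: a two-population
integrated microdosimetric-kinetic (IMK) model with closed-form surviving
fractions under arbitrary irradiation protocols, a split-dose estimator of
the sub-lethal damage repair (SLDR) rate, and Bayesian MCMC joint fitting
of matched non-radioresistant / radioresistant cell-line families.

## Who this is for

Radiation biologists and medical physicists analysing clonogenic-assay
data from paired cell lines (a parental line and a radioresistant
derivative established by fractionated irradiation), who want to ask: how
much of the acquired resistance is an increased cancer stem-like cell
(CSC) fraction, and how much is enhanced DNA repair in the non-stem
progeny cells? The model matters most when dose delivery is protracted —
split doses, multi-fractionated schedules, low average dose rates — where
repair during and between fractions drives cell recovery.

## The model

Survival of a single cell population after dose $D$ delivered over time
$T$:

$$-\ln S = (\alpha_0 + \gamma\beta_0)\,D + F(T)\,\beta_0 D^2,
\qquad \gamma = \frac{y_D}{\rho\pi r_d^2},\qquad
F = \frac{2}{(a+c)^2T^2}\left[(a+c)T + e^{-(a+c)T} - 1\right],$$

with $\alpha_0$ (Gy⁻¹), $\beta_0$ (Gy⁻²) the lethality coefficients,
$(a+c)$ (h⁻¹) the SLDR rate, $y_D$ the dose-mean lineal energy and $r_d$
the domain radius; $F$ is the Lea–Catcheside protraction factor. For $n$
timed fractions the quadratic term generalises to per-fraction protraction
plus pairwise cross terms $2\beta_0 e^{-(a+c)\tau_{ij}}D_iD_j$.

A cell line is a mixture $S = (1-f_s)S_p + f_s S_s$ of progeny cells and
stem-like cells. A radioresistant line differs from its parent by a larger
$f_s$ and a repair-enhancement ratio $w_{SLDR} = (a+c)_H/(a+c)_p \ge 1$
that modulates the progeny parameters:
$\alpha_{0p}^* = \alpha_{0p}/w$, $\beta_{0p}^* = \beta_{0p}/w$,
$(a+c)_p^* = w\,(a+c)_p$.

The SLDR rate is estimated from split-dose recovery curves via
$(a+c) = \left[\tfrac1S \tfrac{dS}{d\tau}\big|_{\tau\to0}\right] /
\ln\!\big(S(\infty)/S(0)\big)$, and the full parameter vector of a family
is fitted jointly by seeded random-walk Metropolis with a Gaussian
likelihood on $-\ln S$, flow-cytometry priors on $f_s$, and the split-dose
rate as the prior on $(a+c)_p$. See the vignette
(`vignettes/imk-two-population-model.Rmd`) for the full account.

## Worked example

Predicted acute dose response of the SAS parental line (progeny
$\alpha_0 = 0.208$, $\beta_0 = 0.044$, $(a+c) = 1.279$; stem 0.074/0.027;
$f_s = 0.012$):

```r
library(imkfit)
ctx <- microdosimetric_context(y_D = 4.68)   # gamma = 0.9547 Gy
sas <- population_params(0.208, 0.044, 1.279)
m <- two_population_model(sas, stem_alpha0 = 0.074, stem_beta0 = 0.027,
                          f_s = 0.012, w_SLDR = 1.059)
survival_curve(m, ctx, c(0, 2, 4, 6, 8, 10))
#>   dose_Gy surviving_fraction neg_log_S
#> 1       0        1.000000000 0.0000000
#> 2       2        0.511359888 0.6706817
#> 3       4        0.184992747 1.6874387
#> 4       6        0.047719539 3.0424143
#> 5       8        0.008961031 4.7148700
#> 6      10        0.001292970 6.6508135
```

2 Gy survival is ~0.51 and the curve bends with $\beta_0 D^2$; at high
dose the small stem-like compartment (1.2%) flattens the log-survival
tail. Estimating the SLDR rate from a noisy synthetic split-dose
experiment (2 Gy + 2 Gy, intervals 0–24 h, 3 replicates, σ = 0.05):

```r
rc <- simulate_recovery_curve(sas, gamma = ctx$gamma, sigma = 0.05,
                              replicates = 3, seed = 7)
est <- estimate_sldr_rate(rc, n_boot = 200, seed = 8)
#> SLDR rate: 1.507 +/- 0.584 h^-1   (generating rate: 1.279)
```

Joint Bayesian fit of a synthetic SAS-like family (both lines, 6 doses ×
3 replicates, σ = 0.1):

```r
sim <- simulate_family_datasets(sas_family_parameters(), ctx, seed = 1)
pr <- prior_spec(repair_mean = 1.31, repair_sd = 0.69,
                 f_s_parent = c(0.0097, 0.0068),
                 f_s_resistant = c(0.0965, 0.0365))
fit <- imk_fit(sim$parent, sim$resistant, priors = pr, ctx = ctx,
               sigma = 0.1,
               protocols = list(acute = list(dose_rate_Gy_min = 1.0)),
               control = imk_control(n_iter = 10000), seed = 1)
fit
#> Two-population IMK survival model fit (random-walk Metropolis)
#>   lines: SAS + SAS-R
#>   retained samples: 8000, sigma = 0.1 (fixed)
#>   mean acceptance rate: 0.34
#>   posterior means:
#>     alpha0p        0.2305 (sd 0.0257)
#>     beta0p         0.04155 (sd 0.00417)
#>     repair_p       1.532 (sd 0.67)
#>     alpha0s        0.1317 (sd 0.0665)
#>     beta0s         0.02569 (sd 0.00688)
#>     w_SLDR         1.104 (sd 0.0413)
#>     f_s_parent     0.01167 (sd 0.00577)
#>     f_s_resistant  0.08902 (sd 0.0361)
#>   R^2: parent 0.998, resistant 0.998
```

Every generating parameter is recovered within its posterior spread
(e.g. $w_{SLDR}$: truth 1.059, posterior 1.104 ± 0.041; $f_s$ of the
resistant line: truth 0.083, posterior 0.089 ± 0.036). `summary()`,
`coef()`, `predict()`, `plot()`, `residuals()` and `simulate()` methods
operate on the fit; `run_full_analysis()` drives the whole two-stage
pipeline (split-dose rate → priors → joint fit → posterior summary and
fitted-curve CSVs) from one config list or JSON file.

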