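# fcrnpk

Mechanistic modelling of FcRn-mediated IgG recycling and antibody
pharmacokinetics, for scientists engineering Fc domains for long serum
persistence and for PK analysts working with human-FcRn mouse models.

IgG is rescued from lysosomal degradation by the neonatal Fc receptor
(FcRn), which binds Fc at endosomal pH (~5.8) and releases it at
extracellular pH (~7.4). Engineered Fc variants (YTE, LS, DHS) strengthen
the endosomal interaction, but residual binding at pH 7.4 causes antibody
presented at the cell surface to be re-endocytosed — *recaptured* —
instead of released, shortening circulation half-life. This package
quantifies that trade-off with a linear three-compartment trafficking
model (central, peripheral and endosomal concentrations `C_c, C_p, C_e`):

    dC_c/dt     = Q (C_p − C_c)
    V_p dC_p/dt = Q C_c − Q C_p − Q_u C_p + Q_u C_e f_sort f_release
    V_e dC_e/dt = Q_u [ C_p + C_e ((1 − f_release) f_sort − 1) ]

where `f_sort` is the fraction of endosomal IgG recycled and `f_release`
the fraction of surface-presented IgG released; `1 − f_release` is the
surface recapture fraction. The model is propagated by matrix exponential,
half-lives are extracted either from the slowest eigenvalue
(`terminal_half_life()`) or by Newton root-finding on the central
concentration (`time_to_half()`), and the per-variant fractions plus
shared volumes/flows are inferred by parallel-tempered MCMC from observed
beta-phase half-lives under affinity-ordered flat priors
(`fit_trafficking()`). Around this core the package provides
noncompartmental PK (linear-up/log-down AUC, clearance, Vss,
biexponential fits), SPR 1:1 equilibrium and kinetic binding fits,
plasmon-wavelength extraction for self-interaction assays, and seeded
synthetic-data generators for every input.

## Worked example

Fit the trafficking model to the packaged Tg276 half-life observations
and summarize the inferred surface recapture:

```r
library(fcrnpk)

obs    <- half_life_observations("Tg276")   # wt/DHS/YTE/LS, mean ± SD, n = 11
priors <- build_priors(fcrn_affinities())   # affinity-ordered constraints
fit    <- fit_trafficking(obs, priors, seed = 101)
recapture_summary(fit)
#> # A tibble: 4 × 6
#>   variant recapture_mean recapture_sd  q2.5 q97.5 fixed
#>   <chr>            <dbl>        <dbl> <dbl> <dbl> <lgl>
#> 1 YTE              0.475       0.109  0.249 0.674 FALSE
#> 2 LS               0.580       0.0959 0.381 0.746 FALSE
#> 3 wt               0           0      0     0     TRUE
#> 4 DHS              0           0      0     0     TRUE
```

About half of the surface-presented YTE and LS antibody is re-internalized
per recycling round, while wt and DHS (no detectable pH 7.4 binding) are
fully released by construction. Ranking half-life sensitivities at the
posterior mean shows recapture is the dominant lever for YTE:

```r
sensitivity_analysis(posterior_mean_params(fit), "YTE")
#> # A tibble: 6 × 7
#>   parameter  value elasticity abs_elasticity scale    boundary  rank
#> 1 f_release 0.525      -1.79           1.79  loss-log FALSE        1
#> 2 V_e       0.306      -1.54           1.54  log      FALSE        2
#> 3 V_p       0.288      -0.763          0.763 log      FALSE        3
#> 4 Q         0.0171     -0.546          0.546 log      FALSE        4
#> 5 Q_u       0.540      -0.454          0.454 log      FALSE        5
#> 6 f_sort    0.998      -0.447          0.447 loss-log FALSE        6
```

(`loss-log` rows are elasticities with respect to the complementary loss
fraction, `ln(1 − f)`; see the methods vignette.) A simulated PK study
round-trips through the NCA machinery:

```r
truth  <- tibble::tibble(variant = "DHS", A_ug_ml = 15, alpha_per_day = 1.5,
                         B_ug_ml = 25, beta_per_day = log(2) / (290.9 / 24))
design <- study_design(truth, cv = 0.1, n_animals = 3, seed = 7)
nca(simulate_pk_study(design))
#> # A tibble: 3 × 12
#>   subject_id variant n_obs c_max_ug_ml auc_last auc_inf_ug_day_ml ...
#> 1 DHS_01     DHS        10        49.0     354.              484.
#> 2 DHS_02     DHS        10        45.8     379.              474.
#> 3 DHS_03     DHS        10        42.4     368.              444.
```

A thin command-line pipeline over the same functions ships at
`inst/cli/fcrnpk.R` (subcommands `simulate`, `nca`, `fit-trafficking`,
`sensitivity`, `assays`, all driven by JSON configs and writing manifests).

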