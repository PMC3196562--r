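# dcepop

Multi-compartment **population pharmacokinetic modelling of multi-tissue
DCE-MRI tracer curves** in R.

Dynamic contrast-enhanced MRI (DCE-MRI) records the concentration of a
gadolinium tracer (Gd-DTPA) over time in tissue regions of interest after
an intravenous bolus. When several tissues are imaged simultaneously —
spinal muscle as a treatment-insensitive reference, liver, and a liver
tumor fed by the hepatic supply — their curves share one latent plasma
pool and can be analysed jointly in a nonlinear mixed-effects framework,
without ever measuring an arterial input function. `dcepop` is aimed at
pharmacometricians and quantitative-imaging researchers who want that
analysis as a tested, scriptable pipeline.

## The model

The reference structural model has nine compartments: a latent central
pool `C` (dose compartment, first-order elimination `k_C0`), a
three-deep muscle chain `C–M1–M2–M3` (observed: `M2`), a three-deep liver
chain `C–L1–L2–L3` (observed: `L2`) and a two-deep tumor chain `T2–T3`
(observed: `T2`) attached to `L1` — the tumor is supplied through the
liver. Amounts follow linear first-order kinetics

    dA/dt = K A,     A(t) = expm(K (t − t_lag)) A0,

with a compartmental (Metzler) rate matrix `K` built from 17 transfer
constants `k` [1/s], solved analytically (eigendecomposition, expm
fallback) — the rate spread of ~7 orders of magnitude makes the system
stiff. With clearance fixed at `Cl = 0.04 ml/s`, volumes follow from
`V_c = Cl / k_C0` and the flow-balance relation `k = Q/V` along the
compartment tree; measured concentrations are `C = A/V` [mM].

The population layer places log-normal inter-individual variability on
every transfer constant, `k_i = θ·exp(β x_i + η_i)`,
`η_i ~ N(0, ω²)`, supports binary (`anest`) and ordered 4-level (`vti`)
covariates, a mixed additive + proportional residual error
`y ~ N(f, σ_add² + (σ_prop f)²)` and a zero-truncated normal injection
lag per dataset. Estimation mirrors the two-stage protocol of the study
the package emulates: SAEM initial estimates (120 iterations by
default), then full MCMC Bayesian sampling (3000 burn-in + 3000 retained
by default) with weakly informative priors. Model selection uses
per-dataset objective function values (Laplace-marginal −2 log
likelihood; `ΔOFV`) and the deviance information criterion (DIC);
diagnostics include conditional weighted residuals (CWRES), chain
stability scoring and correlation flattening factors `f = 1 − r`.

Because the original animal datasets are not deposited, the package
ships a synthetic study generator reproducing the design (33 datasets,
three tissues, 6 s/24 s two-phase sampling to 15 min, 0.2 mmol/kg bolus,
four vital-tumor-tissue groups, anesthesia covariate) with a recorded
truth ledger for recovery scoring.

## Worked example

Simulate a small study from the full model, fit it with a short
two-stage run, and inspect the posterior:

```r
library(dcepop)
library(dplyr)

g <- graph_preset("mtl3")
study <- generate_study(
  study_design(n_datasets = 6, vti_sizes = c(6, 0, 0, 0)), seed = 7
)
study
#> <study_data> 6 datasets, 1080 observations

fit <- fit_population(
  study$data, g,
  config = sampler_config("custom", saem_iterations = 20,
                          burn_in = 150, samples = 150, seed = 8)
)
fit
#> <pop_fit> 6 datasets, 150 retained samples, 17 transfer constants
#>   joint-deviance OFV -5631.06; acceptance psi 0.26

tidy(fit) |> filter(grepl("^theta_", parameter)) |> head(5)
#>      parameter estimate    lower    upper se_pct
#> 1  theta_k_CM1   0.3164 2.64e-01   0.3868   9.30
#> 2  theta_k_M1C   0.0157 9.56e-03   0.0211  18.86
#> 3 theta_k_M1M2   4.0486 3.27e+00   4.9116  12.46
#> 4 theta_k_M2M1 403.3611 2.61e+02 705.3495  25.42
#> 5 theta_k_M2M3   0.2339 2.12e-01   0.2735   6.18

glance(fit)
#>   n_datasets n_obs n_samples      ofv      dic      pd acceptance_psi
#> 1          6  1080      150 -5423.29 -5575.96 55.0946       0.260476
```

Each `theta_*` row is a population typical transfer constant [1/s] with
its equal-tailed 95% credible interval and SE% (posterior SD/mean); the
generating truth here was `k_CM1 = 0.3`, `k_M1C = 0.012`,
`k_M1M2 = 3.6`, `k_M2M1 = 300`, `k_M2M3 = 0.24`, so even this short run
recovers the well-identified rates within their intervals. In `glance()`,
`ofv` is the total marginal objective function value, `dic` the deviance
information criterion and `pd` the effective parameter count.

Model comparison and diagnostics follow the same grammar:
`compare_models(list(mtl3 = f1, no_t3 = f2))` tabulates ΔOFV/DIC,
`compute_cwres(fit)` returns the residual table (`plot_cwres()` renders
it), `chain_stability(fit)` scores the chains, `central_curve(fit, t)`
reconstructs the posterior central-compartment concentration — the
model-based surrogate for the arterial input function — and
`run_pipeline()` chains simulate → fit → diagnose → compare with a
reproducibility manifest.

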