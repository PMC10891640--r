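# photostab

Chemometric assessment of the photostability of 1,4-dihydropyridine (DHP)
drugs from UV spectral time series, for analytical and medicinal chemists
working with light-sensitive calcium-channel blockers.

Under irradiation a DHP's spectrum shows a decaying band near 350–370 nm
(the dihydropyridine chromophore) and a growing band near 260–280 nm (the
aromatized pyridine photoproduct). `photostab` turns a sequence of such
spectra into rate constants and structure–property models:

- **Constrained MCR-ALS** — the data matrix *D* (time × wavelength) is
  decomposed as *D = C Sᵀ + E* by alternating least squares under
  non-negativity, unimodality and concentration closure, yielding
  concentration profiles *C* and pure spectra *S* with quality metrics
  %lof = 100·√(SS_res/SS_data) and %R² = 100 − lof²/100. Chemical rank
  estimation and SIMPLISMA-style purest-variable initialization included.
- **First-order kinetics** — ln(% parent) = −k₁·t + b fitted by OLS on
  the resolved parent profile; t₀.₁ = ln(10/9)/k₁ summarizes stability;
  a joint Bateman fit recovers (k₁, k₂) when a second photoproduct forms.
- **QSPR** — rates regressed on molecular descriptors: constant-column
  pruning, autoscaling, OLS and principal-component regression, forward
  selection by leave-one-out RMSECV, external validation reports
  (RMSEC/RMSECV/RMSEP, per-compound error %), and PCA exploration with
  biplot coordinates.
- **Packaged study tables** — kinetics, the 17 selected PaDEL descriptors
  and the leave-one-out validation table for 30 hexahydroquinoline-type
  DHPs, with audit functions that flag the tables' known internal
  inconsistencies rather than correcting them.
- **Synthetic generator** — bilinear spectra with Gaussian bands,
  first-order decay on the experimental time grid, seeded proportional
  noise, and descriptor/response sets with planted sparse structure, so
  every stage is testable end to end.

## Worked example

Simulate a degradation series at a known rate, resolve it, and refit the
rate:

```r
library(photostab)

ser <- simulate_dhp_series(k1 = 4.435e-4, relative_sd = 0.003, seed = 1)
m <- mcr_als(ser, 2, constraints = list(unimodal_C = FALSE))
m
#> Constrained MCR-ALS decomposition of synthetic-DHP
#>   2 components, 21 iterations (converged)
#>   lack of fit 0.959%, explained variance 99.9908%
#>   constraints: nonneg_C, nonneg_S, closure_C

fit_parent_kinetics(m)
#> First-order photodegradation fit
#>   k1 = 0.000447416 s^-1 (SE 6.29e-07), intercept = 4.6109 (ln 100 = 4.6052)
#>   R2 = 99.9968% on 18 points; t0.1 = 3.925 min
```

At 0.3% noise the decomposition explains 99.99% of the variance and the
refitted rate (4.474×10⁻⁴ s⁻¹) sits within 1% of the generating
4.435×10⁻⁴ s⁻¹; the intercept lands at ln 100 as first-order kinetics
demands, and t₀.₁ ≈ 3.9 min marks a fairly photolabile compound. On
noiseless input the rate is recovered to machine precision.

The packaged tables drive the QSPR side:

```r
b <- reproduce()
round(b$pca$calibration_ev_percent[1:2], 2)
#> [1] 28.45 21.95
b$validation$ols$rmsecv
#> [1] 0.03828943
```

`reproduce()` fits OLS and 8-component PCR on the 20-compound calibration
set, cross-validates both, predicts the 10 external compounds, runs the
PCA (20- and 30-compound variants), checks the descriptor correlation
signs, and audits the printed tables; pass `out_dir =` to write the
bundle as CSV/JSON.

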