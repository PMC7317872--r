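# dimerlab

Solution-biophysics toolkit for characterizing adhesive protein
trans-dimers — homophilic complexes such as the one formed by the two
outermost extracellular repeats (EC1-2) of cadherin-23, the
tip-link cadherin whose unusually long-lived handshake dimer underlies
strong cell-cell adhesion. No raw instrument data are deposited for such
studies, so every analysis stage here ships with a synthetic-data
generator that emulates the corresponding experiment, and the whole
pipeline is validated by parameter recovery.

The package covers six techniques:

| Stage | Model at its core | Key functions |
|---|---|---|
| Dynamic force spectroscopy | FJC tether `l(F) = Lc[coth(Fa/kBT) − kBT/Fa]`; series-compliance loading rate; Bell–Evans `F = (kBT/xβ)·ln(vF·xβ·τ0/kBT)` | `make_dfs_dataset`, `select_single_events`, `fit_force_distribution`, `effective_loading_rate`, `fit_bell_evans`, `dfs_analysis` |
| smFRET | `E = (I_A−b_A)/[(I_A−b_A)+γ(I_D−b_D)]`, `E = 1/(1+(R/R0)^6)` | `make_fret_traces`, `trace_efficiency`, `most_probable_efficiency`, `distance_from_efficiency` |
| Time-resolved anisotropy | `r(t) = r0[A1·e^(−t/φ1) + A2·e^(−t/φ2)]` | `make_anisotropy_decay`, `anisotropy_curve`, `fit_biexponential` |
| Sedimentation equilibrium | two-species Boltzmann gradient with mass action, global `K_D` | `make_se_scans`, `se_profile`, `global_fit_se` |
| SAXS | Guinier, normalized Kratky, regularized P(r) inversion, volume of correlation | `make_saxs_profile`, `guinier_fit`, `normalized_kratky`, `ift_pr`, `scan_dmax`, `vc_molecular_weight`, `model_consistency_z` |
| SEC calibration | `Kav = (Ve−V0)/(Vc−V0)` linear in `log10(MW)` | `kav`, `fit_calibration`, `apparent_mw` |

`run_study()` drives everything end to end on synthetic data and reports
planted vs recovered parameters. The methods vignette
(`vignettes/dimerlab-methods.Rmd`) documents every model, default and
design decision.

## Worked example: recovering bond kinetics from rupture statistics

Simulate the weak single-interface bound state (lifetime 1.86 s,
transition distance 0.55 nm) at the seven experimental pulling speeds,
1000 ruptures each, then run the analysis chain — Scott-binned Gaussian
force distributions, tether-compliance loading-rate correction,
Bell–Evans fit:

```r
library(dimerlab)
set.seed(42)
kBT    <- 4.11
tether <- fjc_params(Lc = 58.7, kuhn = 0.7)
speeds <- c(500, 750, 2000, 5000, 7500, 10000, 15000)
low    <- bell_evans_params(tau0 = 1.86, x_beta = 0.55, kBT = kBT)

points <- do.call(rbind, lapply(speeds, function(v) {
  pull <- pulling_config(kc = 20, v = v, noise_sd = 5)
  rate <- self_consistent_loading_rate(low, pull, tether, kBT)
  dist <- fit_force_distribution(sample_rupture_forces(low, rate$vF, 1000), 1)
  data.frame(vF  = effective_loading_rate(dist$components$Fmp, pull, tether, kBT),
             Fmp = dist$components$Fmp, se_Fmp = dist$components$se_Fmp)
}))
fit_bell_evans(points, kBT = kBT, state = "low-force")
#> Bell-Evans fit [low-force] (7 rates):
#>   tau0   = 1.472 +/- 0.079 s
#>   x_beta = 0.548 +/- 0.0038 nm
```

The transition distance comes back within 1% of the planted 0.55 nm. The
lifetime lands ~20% below the planted 1.86 s: τ0 is a log-extrapolated
intercept, and the least-squares Gaussian mean of the left-skewed
first-passage histogram sits slightly below its mode — the same offset
the real analysis chain carries. The other stages in brief:

```r
fit <- global_fit_se(make_se_scans(se_ground_truth(KD = 18e-6), seed = 11),
                     species_params())
fit
#> Sedimentation equilibrium: KD = 1.8e-05 M (95% CI 1.76e-05 - 1.83e-05), RMS 0.0047 AU

traces <- make_fret_traces(0.60, n_traces = 25, seed = 12)
mp <- most_probable_efficiency(vapply(traces, trace_efficiency, numeric(1)))
mp
#> Most probable FRET efficiency: 0.600 (sd 0.003, n = 24)
distance_from_efficiency(mp$EFRETmp, fret_config(R0 = 6))
#> [1] 5.609582
```

The planted dissociation constant (18 µM) and FRET efficiency (0.60) are
both recovered; the donor–acceptor distance follows from the Förster
relation at the supplied `R0`.

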