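#' Configuration for the end-to-end synthetic study
#'
#' A flat, human-readable list of every tunable parameter of the
#' reproduction pipeline, with the study conditions as defaults: the two
#' Bell-Evans states, seven pulling speeds from 500 to 15000 nm/s, the
#' PEG tether, the two sedimentation-equilibrium experiments (dimerizing
#' two-domain fragment at KD 18 uM and single-domain fragment at 52 uM),
#' the 25-trace FRET experiment at efficiency 0.60, a biexponential
#' anisotropy decay, and the sphere scattering oracle. `scale` in (0, 1]
#' shrinks the simulated sample sizes proportionally for quick runs.
#'
#' @param seed integer seed controlling every stage.
#' @param kBT thermal energy (pN nm) for the force-spectroscopy stages.
#' @param scale sample-size scale factor.
#' @return a named list (class `study_config`).
#' @export
study_config <- function(seed = 1, kBT = .kBT_default, scale = 1) {
  stopifnot(scale > 0, scale <= 1)
  structure(list(
    seed = seed, kBT = kBT, scale = scale,
    dfs = list(
      speeds = c(500, 750, 2000, 5000, 7500, 10000, 15000),
      kc = 20, sampling_rate = 6000, noise_sd = 5,
      n_per_speed = max(round(1000 * scale), 100),
      low = c(tau0 = 1.86, x_beta = 0.55),
      high = c(tau0 = 1224.2, x_beta = 0.31),
      tether = c(Lc = 58.7, kuhn = 0.7)),
    fjc = list(n_curves = max(round(500 * scale), 50), speed = 2000),
    se = list(
      ec12 = list(KD = 18e-6, M = 26000, c_load = 36e-6,
                  speeds_rpm = c(24000, 28000, 32000)),
      ec1 = list(KD = 52e-6, M = 15000, c_load = 45e-6,
                 speeds_rpm = c(18000, 20000, 25000)),
      noise_sd = 0.005, n_points = 80),
    fret = list(E_true = 0.60, n_traces = 25),
    aniso = list(r0 = 0.3, A1 = 0.4, phi1 = 0.5, A2 = 0.6, phi2 = 10,
                 noise_sd = 0.002),
    saxs = list(R = 3, noise_frac = 0.005)
  ), class = "study_config")
}

.report_row <- function(stage, quantity, planted, recovered, tol_rel) {
  data.frame(stage = stage, quantity = quantity, planted = planted,
             recovered = recovered,
             rel_err = abs(recovered - planted) / abs(planted),
             tol_rel = tol_rel,
             pass = abs(recovered - planted) <= tol_rel * abs(planted),
             stringsAsFactors = FALSE)
}

#' Run the whole synthetic study and report parameter recovery
#'
#' Executes the pipeline end to end on synthetic data: Bell-Evans
#' rupture generation and kinetics recovery for both bound states, FJC
#' contour-length recovery from simulated tether curves,
#' sedimentation-equilibrium dissociation-constant recovery for both
#' constructs, FRET efficiency recovery, anisotropy correlation-time
#' recovery and the SAXS sphere oracles. Stages are independent: a
#' failure in one is recorded in the report and later stages still run.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory for intermediate files (curves,
#'   scans, traces are written there when given).
#' @return object of class `study_report`: data frame of recovered vs
#'   planted values with per-row pass flags, plus an `errors` attribute
#'   listing failed stages.
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  seeds <- sample.int(2^31 - 1, 12)
  kBT <- config$kBT
  rows <- list()
  errors <- list()
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  # --- dynamic force spectroscopy: one experiment per bound state
  d <- config$dfs
  tether <- fjc_params(d$tether[["Lc"]], d$tether[["kuhn"]])
  pulls <- lapply(d$speeds, function(v) {
    pulling_config(kc = d$kc, v = v, sampling_rate = d$sampling_rate,
                   noise_sd = d$noise_sd)
  })
  for (st in c("low", "high")) {
    run_stage(paste0("dfs_", st), function() {
      pars <- bell_evans_params(d[[st]][["tau0"]], d[[st]][["x_beta"]], kBT)
      set.seed(seeds[if (st == "low") 1 else 2])
      pts <- lapply(pulls, function(pull) {
        r <- self_consistent_loading_rate(pars, pull, tether, kBT)
        f <- sample_rupture_forces(pars, r$vF, d$n_per_speed)
        dfit <- fit_force_distribution(f, n_components = 1)
        data.frame(speed_nm_s = pull$v,
                   Fmp = dfit$components$Fmp,
                   se_Fmp = dfit$components$se_Fmp,
                   vF = effective_loading_rate(dfit$components$Fmp, pull,
                                               tether, kBT))
      })
      fit <- fit_bell_evans(do.call(rbind, pts), kBT = kBT, state = st)
      rows[[length(rows) + 1]] <<- .report_row(
        paste0("dfs_", st), "tau0_s", pars$tau0, fit$tau0,
        if (st == "low") 0.30 else 1.0)
      rows[[length(rows) + 1]] <<- .report_row(
        paste0("dfs_", st), "x_beta_nm", pars$x_beta, fit$x_beta, 0.10)
    })
  }

  # --- FJC contour-length recovery from full synthetic curves
  run_stage("fjc", function() {
    pull <- pulling_config(kc = d$kc, v = config$fjc$speed,
                           sampling_rate = d$sampling_rate,
                           noise_sd = d$noise_sd)
    mix <- two_state_mixture(kBT)
    curves <- make_dfs_dataset(mix, tether, list(pull),
                               n_per_speed = config$fjc$n_curves,
                               event_fraction = 1, kBT = kBT,
                               seed = seeds[3])
    if (!is.null(out_dir)) {
      write_force_curves(curves[seq_len(min(20, length(curves)))],
                         file.path(out_dir, "force_curves"),
                         seed = config$seed)
    }
    ev <- select_single_events(curves, kBT = kBT, noise_sd = d$noise_sd)
    lfit <- fit_force_distribution(ev$Lc_nm, n_components = 1)
    rows[[length(rows) + 1]] <<- .report_row(
      "fjc", "Lc_nm", tether$Lc, lfit$components$Fmp, 1 / tether$Lc)
  })

  # --- sedimentation equilibrium, both constructs
  for (cons in c("ec12", "ec1")) {
    run_stage(paste0("se_", cons), function() {
      sc <- config$se[[cons]]
      truth <- se_ground_truth(KD = sc$KD, M_monomer = sc$M,
                               c_load = sc$c_load, speeds_rpm = sc$speeds_rpm)
      scans <- make_se_scans(truth, n_points = config$se$n_points,
                             noise_sd = config$se$noise_sd,
                             seed = seeds[if (cons == "ec12") 4 else 5])
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        for (k in seq_along(scans)) {
          write_radial_scan(scans[[k]],
                            file.path(out_dir, sprintf("se_%s_%drpm.csv",
                                                       cons, scans[[k]]$rpm)),
                            seed = config$seed)
        }
      }
      sp <- species_params(M = sc$M)
      fit <- global_fit_se(scans, sp)
      rows[[length(rows) + 1]] <<- .report_row(
        paste0("se_", cons), "KD_M", sc$KD, fit$KD, 0.20)
    })
  }

  # --- smFRET efficiency recovery
  run_stage("fret", function() {
    traces <- make_fret_traces(config$fret$E_true,
                               n_traces = config$fret$n_traces,
                               seed = seeds[6])
    if (!is.null(out_dir)) {
      write_fret_traces(traces, file.path(out_dir, "fret_traces"),
                        seed = config$seed)
    }
    Es <- vapply(traces, trace_efficiency, numeric(1))
    mp <- most_probable_efficiency(Es)
    rows[[length(rows) + 1]] <<- .report_row(
      "fret", "EFRETmp", config$fret$E_true, mp$EFRETmp,
      0.02 / config$fret$E_true)
  })

  # --- time-resolved anisotropy recovery
  run_stage("aniso", function() {
    a <- config$aniso
    decay <- make_anisotropy_decay(a$r0, a$A1, a$phi1, a$A2, a$phi2,
                                   noise_sd = a$noise_sd, seed = seeds[7])
    rt <- anisotropy_curve(decay)
    fit <- fit_biexponential(rt$r, rt$t)
    rows[[length(rows) + 1]] <<- .report_row("aniso", "phi1_ns", a$phi1,
                                             fit$phi1, 0.10)
    rows[[length(rows) + 1]] <<- .report_row("aniso", "phi2_ns", a$phi2,
                                             fit$phi2, 0.10)
  })

  # --- SAXS sphere oracles
  run_stage("saxs", function() {
    s <- config$saxs
    prof <- make_saxs_profile(sphere_model(R = s$R, noise_frac = s$noise_frac),
                              seed = seeds[8])
    if (!is.null(out_dir)) {
      write_saxs_profile(prof, file.path(out_dir, "sphere.dat"),
                         seed = config$seed)
    }
    g <- guinier_fit(prof)
    rows[[length(rows) + 1]] <<- .report_row(
      "saxs", "Rg_nm", s$R * sqrt(3 / 5), g$Rg, 0.02)
    pr <- ift_pr(prof, Dmax = 2 * s$R * 1.2)
    rows[[length(rows) + 1]] <<- .report_row(
      "saxs", "Dmax_nm", 2 * s$R, pr$Dmax_effective, 0.05)
  })

  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stage = character(0))
  structure(report, errors = errors, seed = config$seed,
            class = c("study_report", "data.frame"))
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Synthetic study report (seed %d)\n", attr(x, "seed")))
  print.data.frame(x, digits = 4)
  errs <- attr(x, "errors")
  if (length(errs)) {
    cat("Failed stages:\n")
    for (nm in names(errs)) cat(sprintf("  %s: %s\n", nm, errs[[nm]]))
  }
  invisible(x)
}
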