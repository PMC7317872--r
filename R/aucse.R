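.R_gas_erg <- 8.31446e7  # gas constant, erg/(mol K) = g cm^2 s^-2 mol^-1 K^-1

#' Convert rotor speed in rpm to angular velocity
#'
#' @param rpm revolutions per minute.
#' @return angular velocity in rad/s.
#' @export
rpm_to_omega <- function(rpm) rpm * 2 * pi / 60

#' Sedimenting species parameters
#'
#' Molar mass `M` (Da), partial specific volume `vbar` (mL/g), solvent
#' density `rho` (g/mL) and signal coefficient `eps_l` (extinction
#' coefficient times optical path length, AU per molar). The buoyancy
#' factor `1 - vbar*rho` must be positive (the species sediments).
#' Defaults describe the 26-kDa two-domain cadherin fragment monomer with
#' generic protein `vbar` and an assumed eps(280 nm) of 30000 /M/cm over a
#' 1.2 cm path.
#'
#' @param M molar mass (Da).
#' @param vbar partial specific volume (mL/g).
#' @param rho solvent density (g/mL).
#' @param eps_l extinction times path length (AU/M).
#' @return object of class `species_params`.
#' @export
species_params <- function(M = 26000, vbar = 0.73, rho = 1.0, eps_l = 36000) {
  .check_pos(M, "M")
  .check_pos(eps_l, "eps_l")
  if (vbar * rho <= 0 || vbar * rho >= 1) {
    stop("unphysical parameters: vbar*rho must lie in (0, 1)")
  }
  structure(list(M = M, vbar = vbar, rho = rho, eps_l = eps_l),
            class = "species_params")
}

#' Reduced buoyant molar mass term for sedimentation equilibrium
#'
#' `sigma = M * (1 - vbar*rho) * omega^2 / (R * T)` in cm^-2 (radii in
#' cm), the exponent scale of the Boltzmann radial distribution at
#' equilibrium. Linear in `M`, so a dimer has exactly twice the monomer
#' value.
#'
#' @param species a [species_params()].
#' @param omega angular velocity (rad/s), >= 0.
#' @param T_K absolute temperature (K).
#' @return sigma in cm^-2.
#' @export
reduced_buoyant_term <- function(species, omega, T_K = 293.15) {
  stopifnot(inherits(species, "species_params"))
  if (omega < 0) stop("omega must be >= 0")
  .check_pos(T_K, "T_K")
  species$M * (1 - species$vbar * species$rho) * omega^2 / (.R_gas_erg * T_K)
}

#' Radial absorbance profile of a monomer-dimer system at equilibrium
#'
#' Two-species Boltzmann model with mass action built in:
#' \deqn{A(r) = \epsilon l\, c_m^{ref} e^{\sigma_m (r^2 - r_{ref}^2)/2}
#'  + 2 \epsilon l \frac{(c_m^{ref})^2}{K_D} e^{2\sigma_m (r^2 - r_{ref}^2)/2}
#'  + baseline}
#' with `r_ref` at the meniscus. The dimer signal coefficient is
#' `2*eps_l` (two chromophoric monomers) and its buoyant term exactly
#' twice the monomer's, so `c_dimer(r) = c_monomer(r)^2 / KD` holds at
#' every radius by construction.
#'
#' @param r radii (cm), vectorised.
#' @param c_mono_ref monomer molar concentration at the meniscus.
#' @param KD monomer-dimer dissociation constant (molar).
#' @param species monomer [species_params()].
#' @param omega angular velocity (rad/s).
#' @param meniscus reference radius (cm).
#' @param T_K temperature (K).
#' @param baseline optical baseline offset (AU).
#' @return absorbance values (AU).
#' @export
se_profile <- function(r, c_mono_ref, KD, species, omega, meniscus,
                       T_K = 293.15, baseline = 0) {
  .check_pos(c_mono_ref, "c_mono_ref")
  .check_pos(KD, "KD")
  sig <- reduced_buoyant_term(species, omega, T_K)
  xi <- sig * (r^2 - meniscus^2) / 2
  if (any(2 * xi > 500)) {
    stop("exponent overflow in the equilibrium profile; rescale the geometry or speed")
  }
  eps <- species$eps_l
  eps * c_mono_ref * exp(xi) + 2 * eps * (c_mono_ref^2 / KD) * exp(2 * xi) +
    baseline
}

#' Ground truth for synthetic sedimentation-equilibrium experiments
#'
#' Defaults describe the dimerizing two-domain fragment study conditions:
#' 26-kDa monomer loaded at 36 uM, dissociation constant 18 uM, scans at
#' 24, 28 and 32 krpm at 20 C in a 6.00-6.15 cm solution column.
#'
#' @param KD dissociation constant (molar).
#' @param M_monomer monomer mass (Da).
#' @param vbar partial specific volume (mL/g).
#' @param rho solvent density (g/mL).
#' @param c_load loading concentration (molar, monomer equivalents).
#' @param speeds_rpm rotor speeds (rpm).
#' @param meniscus,bottom solution column radii (cm).
#' @param eps_l extinction times path (AU/M).
#' @param T_K temperature (K).
#' @param baseline optical baseline (AU).
#' @return object of class `se_ground_truth`.
#' @export
se_ground_truth <- function(KD = 18e-6, M_monomer = 26000, vbar = 0.73,
                            rho = 1.0, c_load = 36e-6,
                            speeds_rpm = c(24000, 28000, 32000),
                            meniscus = 6.00, bottom = 6.15,
                            eps_l = 36000, T_K = 293.15, baseline = 0) {
  .check_pos(KD, "KD")
  .check_pos(c_load, "c_load")
  if (meniscus >= bottom) stop("meniscus must be smaller than bottom")
  if (vbar * rho >= 1) stop("unphysical parameters: the species would float")
  structure(list(KD = KD, M_monomer = M_monomer, vbar = vbar, rho = rho,
                 c_load = c_load, speeds_rpm = speeds_rpm,
                 meniscus = meniscus, bottom = bottom, eps_l = eps_l,
                 T_K = T_K, baseline = baseline),
            class = "se_ground_truth")
}

# Sector-averaged mean of exp(sigma*(r^2 - m^2)/2) over [meniscus, bottom].
.se_radial_mean <- function(sig, meniscus, bottom) {
  if (abs(sig) < 1e-12) return(1)
  num <- (exp(sig * (bottom^2 - meniscus^2) / 2) - 1) / sig
  den <- (bottom^2 - meniscus^2) / 2
  num / den
}

#' Simulate sedimentation-equilibrium radial scans
#'
#' For each rotor speed, solves for the meniscus monomer concentration
#' that conserves the loaded material (sector-shaped cell), evaluates the
#' exact two-species equilibrium profile, and adds Gaussian optical noise.
#'
#' @param truth a [se_ground_truth()].
#' @param n_points radial points per scan (>= 20).
#' @param noise_sd absorbance noise (AU).
#' @param seed optional integer seed.
#' @return list of `radial_scan` objects: each has `r` (cm), `A` (AU),
#'   `rpm`, `omega`, `T_K`, `meniscus`, `bottom`; the planted meniscus
#'   concentrations are attached as attribute `c_ref`.
#' @export
make_se_scans <- function(truth, n_points = 80, noise_sd = 0.005, seed = NULL) {
  stopifnot(inherits(truth, "se_ground_truth"))
  if (n_points < 20) stop("need at least 20 points per scan")
  if (!is.null(seed)) set.seed(seed)
  sp <- species_params(truth$M_monomer, truth$vbar, truth$rho, truth$eps_l)
  scans <- list()
  crefs <- numeric(length(truth$speeds_rpm))
  for (k in seq_along(truth$speeds_rpm)) {
    rpm <- truth$speeds_rpm[k]
    omega <- rpm_to_omega(rpm)
    sig <- reduced_buoyant_term(sp, omega, truth$T_K)
    mono_mean <- .se_radial_mean(sig, truth$meniscus, truth$bottom)
    dim_mean <- .se_radial_mean(2 * sig, truth$meniscus, truth$bottom)
    # conservation: mean monomer-equivalents = c_load
    balance <- function(cm) cm * mono_mean + 2 * (cm^2 / truth$KD) * dim_mean -
      truth$c_load
    cm_ref <- stats::uniroot(balance, c(truth$c_load * 1e-8, truth$c_load * 2),
                             tol = 1e-16)$root
    crefs[k] <- cm_ref
    r <- seq(truth$meniscus, truth$bottom, length.out = n_points)
    A <- se_profile(r, cm_ref, truth$KD, sp, omega, truth$meniscus,
                    truth$T_K, truth$baseline)
    A <- A + stats::rnorm(n_points, 0, noise_sd)
    scans[[k]] <- structure(list(r = r, A = A, rpm = rpm, omega = omega,
                                 T_K = truth$T_K, meniscus = truth$meniscus,
                                 bottom = truth$bottom),
                            class = "radial_scan")
  }
  attr(scans, "c_ref") <- crefs
  scans
}

#' Global monomer-dimer fit of sedimentation-equilibrium scans
#'
#' Nonlinear least squares over all scans simultaneously with one shared
#' dissociation constant; the meniscus monomer concentration and the
#' optical baseline float per scan. Meniscus and bottom are treated as
#' known geometry. The confidence interval on `KD` is obtained by profile
#' likelihood (refitting the nuisance parameters along a log-KD grid). A
#' fit running to the upper KD bound is reported as a no-association
#' outcome rather than a silent boundary value.
#'
#' @param scans list of `radial_scan` objects (>= 2 distinct speeds).
#' @param species monomer [species_params()].
#' @param conf_level confidence level for the profile interval.
#' @param KD_max upper bound (molar) beyond which no association is
#'   declared.
#' @return object of class `equilibrium_fit`: `KD`, `KD_ci`, per-scan
#'   `c_ref` and `baseline`, `rms` (AU), `no_association` flag.
#' @export
global_fit_se <- function(scans, species, conf_level = 0.95, KD_max = 0.1) {
  stopifnot(is.list(scans), length(scans) >= 2)
  lapply(scans, function(s) stopifnot(inherits(s, "radial_scan")))
  if (length(unique(vapply(scans, `[[`, numeric(1), "rpm"))) < 2) {
    stop("need scans at >= 2 distinct rotor speeds")
  }
  ns <- length(scans)
  eps <- species$eps_l
  resid_fun <- function(par) {
    lKD <- par[1]
    unlist(lapply(seq_len(ns), function(k) {
      sc <- scans[[k]]
      cm <- exp(par[1 + k])
      bl <- par[1 + ns + k]
      scans[[k]]$A - se_profile(sc$r, cm, exp(lKD), species, sc$omega,
                                sc$meniscus, sc$T_K, bl)
    }))
  }
  cm0 <- vapply(scans, function(sc) {
    max(min(sc$A) / eps, 1e-9)
  }, numeric(1))
  start <- c(log(1e-4), log(cm0), rep(0, ns))
  fit <- minpack.lm::nls.lm(start, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  par <- fit$par
  KD_hat <- exp(par[1])
  rss_min <- sum(fit$fvec^2)
  n_obs <- length(fit$fvec)
  n_par <- length(par)
  no_assoc <- KD_hat >= KD_max
  # profile-likelihood interval on log KD
  prof_rss <- function(lKD) {
    pf <- minpack.lm::nls.lm(par[-1], fn = function(q) resid_fun(c(lKD, q)),
                             control = minpack.lm::nls.lm.control(maxiter = 300))
    sum(pf$fvec^2)
  }
  dfree <- n_obs - n_par
  thresh <- rss_min * (1 + stats::qf(conf_level, 1, dfree) / dfree)
  ci <- c(NA_real_, NA_real_)
  if (!no_assoc) {
    lo_fun <- function(l) prof_rss(l) - thresh
    step <- 0.1
    l_lo <- par[1]
    repeat {
      l_lo <- l_lo - step
      if (lo_fun(l_lo) > 0 || par[1] - l_lo > 12) break
    }
    if (lo_fun(l_lo) > 0) {
      ci[1] <- exp(stats::uniroot(lo_fun, c(l_lo, par[1]), tol = 1e-4)$root)
    } else ci[1] <- 0
    l_hi <- par[1]
    repeat {
      l_hi <- l_hi + step
      if (lo_fun(l_hi) > 0 || l_hi - par[1] > 12) break
    }
    if (lo_fun(l_hi) > 0) {
      ci[2] <- exp(stats::uniroot(lo_fun, c(par[1], l_hi), tol = 1e-4)$root)
    } else ci[2] <- Inf
  }
  structure(list(KD = KD_hat, KD_ci = ci,
                 c_ref = exp(par[2:(1 + ns)]),
                 baseline = par[(2 + ns):(1 + 2 * ns)],
                 rms = sqrt(rss_min / n_obs), n = n_obs,
                 converged = fit$info %in% 1:4,
                 no_association = no_assoc, conf_level = conf_level),
            class = "equilibrium_fit")
}

#' @export
print.equilibrium_fit <- function(x, ...) {
  if (x$no_association) {
    cat("Sedimentation equilibrium: no association detected (KD at bound)\n")
  } else {
    cat(sprintf("Sedimentation equilibrium: KD = %.3g M (%.0f%% CI %.3g - %.3g), RMS %.2g AU\n",
                x$KD, 100 * x$conf_level, x$KD_ci[1], x$KD_ci[2], x$rms))
  }
  invisible(x)
}
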