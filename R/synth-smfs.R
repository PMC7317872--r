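#' Two-state mixture of Bell-Evans bonds
#'
#' A mixture of one or two bound states, each a [bell_evans_params()]
#' object with a weight. Used by [make_dfs_dataset()] to emulate the
#' two binding conformations of a trans-dimer: a weak, partially engaged
#' state and a strong, fully engaged one. Weights must sum to 1.
#'
#' @param states list of [bell_evans_params()] objects (at most 2).
#' @param weights numeric vector of the same length, in (0, 1], summing to 1.
#' @return object of class `mixture_spec`.
#' @export
mixture_spec <- function(states, weights = rep(1 / length(states), length(states))) {
  if (!is.list(states) || length(states) < 1 || length(states) > 2) {
    stop("'states' must be a list of 1 or 2 bell_evans_params objects")
  }
  lapply(states, function(s) stopifnot(inherits(s, "bell_evans_params")))
  if (length(weights) != length(states) || any(weights <= 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be positive and sum to 1")
  }
  structure(list(states = states, weights = weights), class = "mixture_spec")
}

#' Default two-state mixture for the cadherin-23 EC1-2 trans-dimer
#'
#' The two bound states resolved by dynamic force spectroscopy: a
#' low-force state (tau0 = 1.86 s, x_beta = 0.55 nm; single-interface
#' binding, also seen for the EC1 fragment alone) and a high-force state
#' (tau0 = 1224.2 s, x_beta = 0.31 nm; the fully engaged trans-dimer),
#' taken with equal weights.
#'
#' @param kBT thermal energy (pN nm).
#' @return a [mixture_spec()].
#' @export
two_state_mixture <- function(kBT = .kBT_default) {
  mixture_spec(list(
    bell_evans_params(tau0 = 1.86, x_beta = 0.55, kBT = kBT),
    bell_evans_params(tau0 = 1224.2, x_beta = 0.31, kBT = kBT)
  ), weights = c(0.5, 0.5))
}

#' Force curve container
#'
#' A sampled retraction trace: tip-sample separation (`extension`, nm,
#' monotone non-decreasing) and measured `force` (pN), with the pulling
#' metadata needed for loading-rate correction.
#'
#' @param extension numeric vector (nm).
#' @param force numeric vector (pN), same length (>= 50 samples).
#' @param v pulling speed (nm/s).
#' @param kc cantilever spring constant (pN/nm).
#' @param sampling_rate samples per second.
#' @param id curve identifier.
#' @return object of class `force_curve`.
#' @export
force_curve <- function(extension, force, v, kc, sampling_rate, id = "curve") {
  if (length(extension) != length(force)) stop("extension and force must have equal length")
  if (length(force) < 50) stop("force curve must have at least 50 samples")
  structure(list(extension = extension, force = force, v = v, kc = kc,
                 sampling_rate = sampling_rate, id = id),
            class = "force_curve")
}

#' Simulate one FJC tether stretching curve with a rupture
#'
#' Builds a constant-velocity retraction in which the tip displacement
#' `v*t` is shared between the FJC tether extension and the cantilever
#' deflection `F/kc`. The recorded extension is the tip-sample separation
#' (displacement minus deflection). At the prescribed rupture force the
#' trace drops sharply to the force baseline. Gaussian force noise of
#' standard deviation `pull$noise_sd` is added to the force channel.
#'
#' @param tether an [fjc_params()] object.
#' @param pull a [pulling_config()].
#' @param rupture_force force (pN) at which the tether detaches.
#' @param kBT thermal energy (pN nm).
#' @param seed optional integer seed.
#' @param id curve identifier.
#' @return a [force_curve()].
#' @export
make_force_curve <- function(tether, pull, rupture_force, kBT = .kBT_default,
                             seed = NULL, id = "curve") {
  stopifnot(inherits(tether, "fjc_params"), inherits(pull, "pulling_config"))
  .check_pos(rupture_force, "rupture_force")
  if (rupture_force * tether$kuhn / kBT > 350) {
    stop("rupture force beyond the numeric range of the FJC model")
  }
  if (!is.null(seed)) set.seed(seed)
  f_grid <- seq(0, rupture_force, length.out = 1500)
  d_grid <- fjc_extension(f_grid, tether, kBT) + f_grid / pull$kc
  d_rup <- d_grid[length(d_grid)]
  d_total <- d_rup * 1.05 + 15
  dt <- 1 / pull$sampling_rate
  d_t <- seq(0, d_total, by = pull$v * dt)
  if (length(d_t) < 60) d_t <- seq(0, d_total, length.out = 60)
  # rupture occurs at a sampled instant: the last above-baseline sample
  # carries exactly the drawn rupture force (plus noise)
  d_t <- sort(unique(c(d_t[d_t < d_rup], d_rup, d_t[d_t > d_rup])))
  pre <- d_t <= d_rup
  F_t <- numeric(length(d_t))
  F_t[pre] <- stats::approx(d_grid, f_grid, xout = d_t[pre], rule = 2)$y
  extension <- ifelse(pre, d_t - F_t / pull$kc, d_t)
  force <- F_t + stats::rnorm(length(F_t), 0, pull$noise_sd)
  force_curve(extension, force, v = pull$v, kc = pull$kc,
              sampling_rate = pull$sampling_rate, id = id)
}

.make_baseline_curve <- function(pull, length_nm = 120, seed = NULL, id = "curve") {
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / pull$sampling_rate
  d_t <- seq(0, length_nm, by = pull$v * dt)
  if (length(d_t) < 60) d_t <- seq(0, length_nm, length.out = 60)
  force_curve(d_t, stats::rnorm(length(d_t), 0, max(pull$noise_sd, 1e-6)),
              v = pull$v, kc = pull$kc, sampling_rate = pull$sampling_rate,
              id = id)
}

#' Simulate a dynamic force spectroscopy dataset
#'
#' For each pulling configuration, generates `n_per_speed` retraction
#' curves of which a fraction `event_fraction` contain a single tether
#' rupture; the remaining curves are featureless noise baselines. For
#' event curves the bound state is chosen according to the mixture
#' weights, and the rupture force is drawn from the Bell-Evans
#' first-passage distribution at the state's self-consistent loading rate
#' for that speed (see [self_consistent_loading_rate()]).
#'
#' @param mix a [mixture_spec()].
#' @param tether an [fjc_params()] object.
#' @param pulls list of [pulling_config()] objects (one per speed).
#' @param n_per_speed curves per speed.
#' @param event_fraction fraction of curves carrying a rupture, in (0, 1].
#' @param kBT thermal energy (pN nm).
#' @param seed optional integer seed.
#' @return list of [force_curve()] objects, with a `manifest` attribute
#'   (data frame: id, pulling speed, spring constant, sampling rate,
#'   planted state and rupture force; NA for baselines).
#' @export
make_dfs_dataset <- function(mix, tether, pulls, n_per_speed,
                             event_fraction = 0.08, kBT = .kBT_default,
                             seed = NULL) {
  stopifnot(inherits(mix, "mixture_spec"), inherits(tether, "fjc_params"))
  if (!is.list(pulls) || length(pulls) == 0) stop("'pulls' must be a non-empty list")
  lapply(pulls, function(p) stopifnot(inherits(p, "pulling_config")))
  if (event_fraction <= 0 || event_fraction > 1) stop("event_fraction must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  curves <- list()
  man <- list()
  for (pull in pulls) {
    rates <- lapply(mix$states, self_consistent_loading_rate,
                    pull = pull, tether = tether, kBT = kBT)
    is_event <- stats::rbinom(n_per_speed, 1, event_fraction) == 1
    state_idx <- sample.int(length(mix$states), n_per_speed,
                            replace = TRUE, prob = mix$weights)
    for (i in seq_len(n_per_speed)) {
      id <- sprintf("v%g_%05d", pull$v, i)
      if (is_event[i]) {
        s <- state_idx[i]
        f_rup <- sample_rupture_forces(mix$states[[s]], rates[[s]]$vF, 1)
        f_rup <- max(f_rup, 0.5)
        cv <- make_force_curve(tether, pull, f_rup, kBT, id = id)
        man[[length(man) + 1]] <- data.frame(
          id = id, pulling_speed_nm_s = pull$v, spring_constant_pN_nm = pull$kc,
          sampling_rate_hz = pull$sampling_rate, state = s,
          planted_force_pN = f_rup, stringsAsFactors = FALSE)
      } else {
        cv <- .make_baseline_curve(pull, id = id)
        man[[length(man) + 1]] <- data.frame(
          id = id, pulling_speed_nm_s = pull$v, spring_constant_pN_nm = pull$kc,
          sampling_rate_hz = pull$sampling_rate, state = NA_integer_,
          planted_force_pN = NA_real_, stringsAsFactors = FALSE)
      }
      curves[[length(curves) + 1]] <- cv
    }
  }
  attr(curves, "manifest") <- do.call(rbind, man)
  curves
}
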