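#' Bell-Evans bond parameters
#'
#' Kinetic parameters of a slip bond under force in the Bell-Evans
#' picture: the intrinsic (zero-force) bond lifetime `tau0` in seconds
#' (off-rate `koff = 1/tau0`) and the distance from the bound state to the
#' transition state `x_beta` in nanometres.
#'
#' @param tau0 intrinsic lifetime at zero force (s).
#' @param x_beta distance to the transition state (nm).
#' @param kBT thermal energy (pN nm).
#' @return an object of class `bell_evans_params`.
#' @examples
#' # the two binding states resolved for the cadherin-23 EC1-2 trans-dimer
#' high <- bell_evans_params(tau0 = 1224.2, x_beta = 0.31)
#' low  <- bell_evans_params(tau0 = 1.86,   x_beta = 0.55)
#' @export
bell_evans_params <- function(tau0, x_beta, kBT = .kBT_default) {
  .check_pos(tau0, "tau0")
  .check_pos(x_beta, "x_beta")
  .check_pos(kBT, "kBT")
  structure(list(tau0 = tau0, x_beta = x_beta, kBT = kBT,
                 koff = 1 / tau0), class = "bell_evans_params")
}

#' @export
print.bell_evans_params <- function(x, ...) {
  cat(sprintf("Bell-Evans bond: tau0 = %.4g s, x_beta = %.3g nm (kBT = %.3g pN nm)\n",
              x$tau0, x$x_beta, x$kBT))
  invisible(x)
}

#' Most probable rupture force at a given loading rate
#'
#' Forward Bell-Evans relation
#' `F(vF) = (kBT/x_beta) * ln(vF * x_beta * tau0 / kBT)`.
#' When the logarithm's argument is at or below 1 the most probable
#' rupture force is zero (most bonds dissociate thermally before force
#' builds up) and 0 is returned.
#'
#' @param vF loading rate (pN/s), vectorised.
#' @param params a [bell_evans_params()] object.
#' @return most probable rupture force (pN).
#' @export
bell_evans_force <- function(vF, params) {
  stopifnot(inherits(params, "bell_evans_params"))
  arg <- vF * params$x_beta * params$tau0 / params$kBT
  ifelse(arg <= 1, 0, (params$kBT / params$x_beta) * log(pmax(arg, 1)))
}

#' Rupture-force distribution under a constant loading rate
#'
#' Density and distribution function of the first-passage rupture force of
#' a Bell-Evans bond loaded at constant rate `r`:
#' \deqn{p(F) = (k_{off}/r) e^{F x_\beta/k_BT}
#'   \exp[-(k_{off} k_BT/(r x_\beta)) (e^{F x_\beta/k_BT} - 1)]}
#'
#' @param F rupture force (pN), vectorised.
#' @param params a [bell_evans_params()] object.
#' @param loading_rate constant loading rate `r` (pN/s).
#' @return density (`rupture_force_pdf`) or cumulative probability
#'   (`rupture_force_cdf`).
#' @export
rupture_force_pdf <- function(F, params, loading_rate) {
  stopifnot(inherits(params, "bell_evans_params"))
  .check_pos(loading_rate, "loading_rate")
  beta <- params$x_beta / params$kBT
  cc <- params$koff / (loading_rate * beta)
  ifelse(F < 0, 0,
         (params$koff / loading_rate) * exp(beta * F) *
           exp(-cc * (exp(beta * F) - 1)))
}

#' @rdname rupture_force_pdf
#' @export
rupture_force_cdf <- function(F, params, loading_rate) {
  stopifnot(inherits(params, "bell_evans_params"))
  .check_pos(loading_rate, "loading_rate")
  beta <- params$x_beta / params$kBT
  cc <- params$koff / (loading_rate * beta)
  ifelse(F < 0, 0, 1 - exp(-cc * (exp(beta * F) - 1)))
}

#' Sample rupture forces from the Bell-Evans first-passage distribution
#'
#' Draws i.i.d. rupture forces by inverse transform of the closed-form
#' CDF of the constant-loading-rate Bell-Evans model. Reproducible for a
#' fixed `seed`.
#'
#' @param params a [bell_evans_params()] object.
#' @param loading_rate constant loading rate (pN/s).
#' @param n number of ruptures to draw.
#' @param seed optional integer seed (sets the R RNG).
#' @return numeric vector of `n` rupture forces (pN).
#' @export
sample_rupture_forces <- function(params, loading_rate, n, seed = NULL) {
  stopifnot(inherits(params, "bell_evans_params"))
  .check_pos(loading_rate, "loading_rate")
  if (!is.numeric(n) || n < 1) stop("'n' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  beta <- params$x_beta / params$kBT
  cc <- params$koff / (loading_rate * beta)
  u <- stats::runif(n)
  (1 / beta) * log1p(-log1p(-u) / cc)
}

#' Self-consistent loading rate for a bound state at one pulling speed
#'
#' The loading rate experienced at rupture depends (through the tether
#' compliance) on the force at which the bond breaks, which itself depends
#' on the loading rate. This helper solves the fixed point
#' `r = vF(F_mode(r))`, i.e. the constant rate whose most probable rupture
#' force sits exactly where the compliance correction evaluates it. It is
#' used by the generators so that analysis-time correction at the fitted
#' most probable force is self-consistent with generation.
#'
#' @param params a [bell_evans_params()] object.
#' @param pull a [pulling_config()].
#' @param tether an [fjc_params()] object.
#' @param kBT thermal energy (pN nm).
#' @param tol relative convergence tolerance.
#' @return list with elements `vF` (pN/s) and `F_mode` (pN).
#' @export
self_consistent_loading_rate <- function(params, pull, tether,
                                         kBT = .kBT_default, tol = 1e-10) {
  stopifnot(inherits(params, "bell_evans_params"))
  F <- max(kBT / params$x_beta, 1)
  vF <- effective_loading_rate(F, pull, tether, kBT)
  for (i in seq_len(200)) {
    F_new <- bell_evans_force(vF, params)
    if (F_new <= 0) {
      # thermal regime: rate correction evaluated at a token small force
      F_new <- 0.1
    }
    vF_new <- effective_loading_rate(F_new, pull, tether, kBT)
    conv <- abs(vF_new - vF) <= tol * vF
    F <- F_new
    vF <- vF_new
    if (conv) break
  }
  list(vF = vF, F_mode = bell_evans_force(vF, params))
}

#' Fit the Bell-Evans model to most-probable-force vs loading-rate data
#'
#' Weighted linear least squares of the most probable force against the
#' natural logarithm of the loading rate (the exact re-parameterization of
#' the Bell-Evans relation): slope `= kBT/x_beta`, intercept
#' `= (kBT/x_beta) * ln(x_beta*tau0/kBT)`. Standard errors of `x_beta` and
#' `tau0` are propagated from the linear fit by the delta method.
#'
#' @param points data frame with columns `vF` (pN/s), `Fmp` (pN) and
#'   optionally `se_Fmp` (pN; used as inverse-variance weights).
#' @param kBT thermal energy (pN nm).
#' @param state optional label stored in the result.
#' @return object of class `bell_evans_fit` with `tau0`, `x_beta`, their
#'   standard errors, the underlying `lm` fit and the thermal energy used.
#' @export
fit_bell_evans <- function(points, kBT = .kBT_default, state = NA_character_) {
  stopifnot(is.data.frame(points), all(c("vF", "Fmp") %in% names(points)))
  points <- points[is.finite(points$vF) & is.finite(points$Fmp), , drop = FALSE]
  if (nrow(points) < 3) stop("need at least 3 (vF, Fmp) points")
  if (max(points$vF) / min(points$vF) < 10) {
    warning("loading rates span less than one decade; extrapolated tau0 will be poorly determined")
  }
  w <- if ("se_Fmp" %in% names(points) && all(is.finite(points$se_Fmp)) &&
           all(points$se_Fmp > 0)) 1 / points$se_Fmp^2 else rep(1, nrow(points))
  fit <- stats::lm(Fmp ~ log(vF), data = points, weights = w)
  cf <- stats::coef(fit)
  slope <- cf[[2]]
  intercept <- cf[[1]]
  if (slope <= 0) stop("non-positive slope of Fmp vs ln(vF): unphysical x_beta (fit failure)")
  x_beta <- kBT / slope
  tau0 <- slope * exp(intercept / slope)   # seconds, loading rate in pN/s
  V <- suppressWarnings(stats::vcov(fit))  # exact fits trip summary.lm
  # delta method: tau0 = s*exp(b/s); d/db = tau0/s, d/ds = tau0*(1/s - b/s^2)
  g <- c(tau0 / slope, tau0 * (1 / slope - intercept / slope^2))
  se_tau0 <- sqrt(drop(t(g) %*% V[c(1, 2), c(1, 2)] %*% g))
  se_slope <- sqrt(V[2, 2])
  se_x_beta <- kBT * se_slope / slope^2
  structure(list(tau0 = tau0, x_beta = x_beta,
                 se_tau0 = se_tau0, se_x_beta = se_x_beta,
                 slope = slope, intercept = intercept,
                 kBT = kBT, state = state, n = nrow(points), lm = fit),
            class = "bell_evans_fit")
}

#' @export
print.bell_evans_fit <- function(x, ...) {
  cat(sprintf("Bell-Evans fit%s (%d rates):\n",
              if (is.na(x$state)) "" else paste0(" [", x$state, "]"), x$n))
  cat(sprintf("  tau0   = %.4g +/- %.2g s\n", x$tau0, x$se_tau0))
  cat(sprintf("  x_beta = %.3g +/- %.2g nm\n", x$x_beta, x$se_x_beta))
  invisible(x)
}
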