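#' Small-angle scattering profile
#'
#' One-dimensional scattering profile: scattering vector `q` (nm^-1,
#' strictly increasing, positive), intensity `I` and its standard
#' deviation `sigma`.
#'
#' @param q scattering vector (nm^-1).
#' @param I intensities (arbitrary units).
#' @param sigma intensity standard deviations (> 0); defaults to unit
#'   weights.
#' @param metadata optional named list (sample id, concentration, ...).
#' @return object of class `saxs_profile`.
#' @export
saxs_profile <- function(q, I, sigma = rep(1, length(q)), metadata = list()) {
  if (length(q) != length(I) || length(q) != length(sigma)) {
    stop("q, I, sigma must have equal length")
  }
  if (any(q <= 0) || any(diff(q) <= 0)) stop("q must be positive and strictly increasing")
  if (any(sigma <= 0)) stop("sigma must be positive where given")
  structure(list(q = q, I = I, sigma = sigma, metadata = metadata),
            class = "saxs_profile")
}

#' Homogeneous sphere scattering model
#'
#' Analytic oracle for the SAXS stage: a solid sphere of radius `R` has
#' form factor `I(q) = I0 * [3 (sin(qR) - qR cos(qR)) / (qR)^3]^2`, a
#' radius of gyration `R*sqrt(3/5)` and maximum dimension `2R`.
#'
#' @param R sphere radius (nm).
#' @param I0 forward scattering.
#' @param q_grid scattering vector values (nm^-1).
#' @param noise_frac relative intensity noise.
#' @return object of class `sphere_model`.
#' @export
sphere_model <- function(R = 3, I0 = 1, q_grid = seq(0.02, 3, by = 0.01),
                         noise_frac = 0.01) {
  .check_pos(R, "R")
  .check_pos(I0, "I0")
  if (any(q_grid <= 0) || any(diff(q_grid) <= 0)) {
    stop("q_grid must be positive and strictly increasing")
  }
  if (noise_frac < 0) stop("noise_frac must be >= 0")
  structure(list(R = R, I0 = I0, q_grid = q_grid, noise_frac = noise_frac),
            class = "sphere_model")
}

.sphere_form_factor <- function(q, R) {
  x <- q * R
  (3 * (sin(x) - x * cos(x)) / x^3)^2
}

#' Simulate a sphere scattering profile
#'
#' Evaluates the sphere form factor on the model's q grid and adds
#' shot-noise-like Gaussian noise: the standard deviation scales with
#' `sqrt(I * I0)` (Poisson counting statistics) plus a small detector
#' floor, all scaled by `noise_frac`. The sigma column records that noise
#' level (unit weights when noiseless).
#'
#' @param model a [sphere_model()].
#' @param seed optional integer seed.
#' @return a [saxs_profile()].
#' @export
make_saxs_profile <- function(model, seed = NULL) {
  stopifnot(inherits(model, "sphere_model"))
  if (!is.null(seed)) set.seed(seed)
  I <- model$I0 * .sphere_form_factor(model$q_grid, model$R)
  if (model$noise_frac > 0) {
    sd <- model$noise_frac * (sqrt(pmax(I, 0) * model$I0) + 0.01 * model$I0)
    I <- I + stats::rnorm(length(I), 0, sd)
  } else {
    sd <- rep(1, length(I))
  }
  saxs_profile(model$q_grid, I, sd,
               metadata = list(model = "sphere", R = model$R))
}

#' Guinier analysis
#'
#' Weighted linear regression of `ln I` on `q^2` over the low-q window,
#' iterated until `q_max * Rg <= qRg_max` (default 1.3, the standard
#' globular limit): `Rg = sqrt(-3*slope)`, `I0 = exp(intercept)`.
#' A non-negative slope (low-q upturn, typical of aggregation) is an
#' error.
#'
#' @param profile a [saxs_profile()].
#' @param qRg_max Guinier window limit on `q*Rg`.
#' @param min_points minimum points in the final window.
#' @return object of class `guinier_result`: `Rg` (nm), `I0`, `n_used`,
#'   `qmin`, `qmax`, `qmax_Rg`, `r_squared`.
#' @export
guinier_fit <- function(profile, qRg_max = 1.3, min_points = 8) {
  stopifnot(inherits(profile, "saxs_profile"))
  q <- profile$q; I <- profile$I; s <- profile$sigma
  ok <- I > 0
  q <- q[ok]; I <- I[ok]; s <- s[ok]
  n_use <- min(length(q), max(min_points, 20L))
  Rg <- NA_real_
  for (iter in 1:60) {
    idx <- seq_len(n_use)
    y <- log(I[idx]); x <- q[idx]^2
    w <- (I[idx] / s[idx])^2    # delta-method weights for ln I
    fit <- stats::lm(y ~ x, weights = w)
    slope <- stats::coef(fit)[[2]]
    if (slope >= 0) stop("non-negative Guinier slope: low-q upturn suggests aggregation")
    Rg <- sqrt(-3 * slope)
    n_new <- sum(q * Rg <= qRg_max)
    n_new <- max(n_new, min_points)
    if (n_new >= n_use) break
    n_use <- n_new
  }
  if (n_use < min_points) stop("fewer than min_points usable Guinier points")
  idx <- seq_len(n_use)
  I0 <- exp(stats::coef(fit)[[1]])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(Rg = Rg, I0 = I0, n_used = n_use, qmin = q[1],
                 qmax = q[n_use], qmax_Rg = q[n_use] * Rg, r_squared = r2),
            class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf("Guinier fit: Rg = %.3f nm, I0 = %.4g (%d pts, qmax*Rg = %.2f, R2 = %.4f)\n",
              x$Rg, x$I0, x$n_used, x$qmax_Rg, x$r_squared))
  invisible(x)
}

#' Dimensionless (normalized) Kratky curve
#'
#' `(q*Rg)^2 * I(q)/I(0)` against `q*Rg`. A globular (Gaussian-like)
#' scatterer peaks at `q*Rg = sqrt(3) ~ 1.73` with height `3/e ~ 1.10`;
#' elongated, rod-like particles peak later and higher, which the
#' `rod_like` flag reports (peak position more than 5% beyond sqrt(3)).
#'
#' @param profile a [saxs_profile()].
#' @param g a [guinier_fit()] result.
#' @return list with the `curve` (data frame `x = q*Rg`, `y`), the
#'   parabola-refined `peak_x`, `peak_y`, and a `rod_like` flag.
#' @export
normalized_kratky <- function(profile, g) {
  stopifnot(inherits(profile, "saxs_profile"), inherits(g, "guinier_result"))
  x <- profile$q * g$Rg
  y <- x^2 * profile$I / g$I0
  i <- which.max(y)
  # quadratic refinement of the discrete peak
  if (i > 1 && i < length(y)) {
    xi <- x[(i - 1):(i + 1)]; yi <- y[(i - 1):(i + 1)]
    cf <- stats::coef(stats::lm(yi ~ poly(xi, 2, raw = TRUE)))
    px <- -cf[[2]] / (2 * cf[[3]])
    py <- cf[[1]] + cf[[2]] * px + cf[[3]] * px^2
  } else {
    px <- x[i]; py <- y[i]
  }
  list(curve = data.frame(x = x, y = y), peak_x = px, peak_y = py,
       rod_like = px > sqrt(3) * 1.05)
}

# Lawson-Hanson active-set non-negative least squares: min ||Ax - b||, x >= 0.
.nnls <- function(A, b, tol = NULL) {
  n <- ncol(A)
  x <- numeric(n)
  P <- logical(n)
  w <- crossprod(A, b - A %*% x)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * sum(abs(A)) * max(dim(A))
  for (outer in seq_len(10 * n)) {
    if (all(P) || max(w[!P]) <= tol) break
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      z <- numeric(n)
      z[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > tol)) { x <- z; break }
      bad <- P & (z <= tol)
      alpha <- min(x[bad] / (x[bad] - z[bad]))
      x <- x + alpha * (z - x)
      P[P & (x <= tol)] <- FALSE
      x[!P] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  as.numeric(x)
}

# trapezoidal integration
.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Pair-distance distribution by regularized indirect Fourier transform
#'
#' Solves the linear inverse problem
#' `I(q) = 4*pi * sum_j p(r_j) * sin(q r_j)/(q r_j) * dr`
#' on an `n_r`-point grid over `[0, Dmax]`, with `p(0) = p(Dmax) = 0`,
#' non-negativity, and a second-difference smoothness penalty of weight
#' `alpha` (chi-squared + alpha * seminorm). When `alpha` is `NULL` it is
#' chosen by the corner of a discrete L-curve. Real-space invariants are
#' derived from the solution: `Rg_real` from the second moment of `p(r)`
#' and `I0_real = 4*pi * integral(p)`.
#'
#' @param profile a [saxs_profile()].
#' @param Dmax assumed maximum particle dimension (nm).
#' @param alpha regularization weight, or `NULL` for L-curve selection.
#' @param n_r real-space grid size.
#' @return object of class `pr_distribution`: `r`, `p`, `Dmax`,
#'   `Dmax_effective` (interpolated radius beyond which p stays below
#'   0.5% of its peak),
#'   `Rg_real`, `I0_real`, `alpha`, `chi2` (reduced), `residuals`.
#' @export
ift_pr <- function(profile, Dmax, alpha = NULL, n_r = 61) {
  stopifnot(inherits(profile, "saxs_profile"))
  .check_pos(Dmax, "Dmax")
  q <- profile$q
  if (max(q) * Dmax < 6) {
    warning("profile extends only to q*Dmax < 6; P(r) will be poorly resolved")
  }
  r <- seq(0, Dmax, length.out = n_r)
  dr <- r[2] - r[1]
  interior <- 2:(n_r - 1)
  QR <- outer(q, r[interior])
  A <- 4 * pi * dr * sin(QR) / QR
  Aw <- A / profile$sigma
  bw <- profile$I / profile$sigma
  # second differences over the full grid (zero endpoints included)
  m <- length(interior)
  D2 <- matrix(0, m, m)
  for (j in seq_len(m)) {
    D2[j, j] <- -2
    if (j > 1) D2[j, j - 1] <- 1
    if (j < m) D2[j, j + 1] <- 1
  }
  D2 <- D2 / dr^2
  solve_for <- function(a) {
    Astack <- rbind(Aw, sqrt(a) * D2)
    bstack <- c(bw, numeric(m))
    p <- .nnls(Astack, bstack)
    res <- bw - Aw %*% p
    list(p = p, rss = sum(res^2), seminorm = sum((D2 %*% p)^2),
         residuals = as.numeric(res))
  }
  scale0 <- sum(Aw^2) / sum(D2^2)
  if (is.null(alpha)) {
    alphas <- scale0 * 10^seq(-6, 2, length.out = 25)
    sols <- lapply(alphas, solve_for)
    lr <- log(vapply(sols, `[[`, numeric(1), "rss"))
    ls <- log(pmax(vapply(sols, `[[`, numeric(1), "seminorm"), 1e-300))
    # discrete curvature of the L-curve; take the corner
    k <- seq(2, length(alphas) - 1)
    curv <- (lr[k + 1] - 2 * lr[k] + lr[k - 1])
    best <- k[which.max(curv)]
    alpha <- alphas[best]
    sol <- sols[[best]]
  } else {
    sol <- solve_for(alpha)
    cond <- kappa(rbind(Aw, sqrt(alpha) * D2), exact = FALSE)
    if (cond > 1e10) {
      warning(sprintf(
        "system ill-conditioned at this alpha (kappa ~ %.1g); consider alpha near %.3g",
        cond, scale0))
    }
  }
  p_full <- c(0, sol$p, 0)
  ip <- .trapz(r, p_full)
  if (ip <= 0) stop("P(r) integrates to zero; no signal")
  Rg_real <- sqrt(.trapz(r, r^2 * p_full) / (2 * ip))
  I0_real <- 4 * pi * ip
  peak <- max(p_full)
  thr <- 0.005 * peak
  above <- which(p_full >= thr)
  j <- max(above)
  # sub-grid estimate: interpolate the threshold crossing
  if (j < length(r)) {
    Dmax_eff <- r[j] + dr * (p_full[j] - thr) /
      max(p_full[j] - p_full[j + 1], 1e-12)
    Dmax_eff <- min(Dmax_eff, r[j + 1])
  } else {
    Dmax_eff <- r[j]
  }
  chi2 <- sol$rss / max(length(q) - m, 1)
  structure(list(r = r, p = p_full, Dmax = Dmax, Dmax_effective = Dmax_eff,
                 Rg_real = Rg_real, I0_real = I0_real, alpha = alpha,
                 chi2 = chi2, residuals = sol$residuals),
            class = "pr_distribution")
}

#' @export
print.pr_distribution <- function(x, ...) {
  cat(sprintf("P(r): Dmax = %.2f nm (effective %.2f), Rg = %.3f nm, I0 = %.4g, alpha = %.3g, chi2 = %.3g\n",
              x$Dmax, x$Dmax_effective, x$Rg_real, x$I0_real, x$alpha, x$chi2))
  invisible(x)
}

#' Scan candidate maximum dimensions
#'
#' Runs [ift_pr()] across candidate `Dmax` values and picks the smallest
#' whose fit quality is within 5% of the large-Dmax plateau and whose
#' `p(r)` decays naturally before the endpoint (no forced truncation
#' artifact). If the quality curve shows no plateau a warning is issued
#' and the full curve returned for inspection.
#'
#' @param profile a [saxs_profile()].
#' @param candidates numeric vector of Dmax values to try (nm).
#' @param alpha regularization weight passed to [ift_pr()].
#' @param n_r real-space grid size.
#' @return list with `Dmax` (chosen), `candidates`, `chi2` (quality
#'   curve) and the chosen `pr`.
#' @export
scan_dmax <- function(profile, candidates, alpha = NULL, n_r = 61) {
  stopifnot(length(candidates) >= 3)
  candidates <- sort(candidates)
  prs <- lapply(candidates, function(d) ift_pr(profile, d, alpha = alpha, n_r = n_r))
  chi2 <- vapply(prs, `[[`, numeric(1), "chi2")
  plateau <- stats::median(chi2[seq(max(1, length(chi2) - 2), length(chi2))])
  ok <- chi2 <= 1.05 * plateau
  # endpoint artifact: p still high at the last free grid point
  natural <- vapply(prs, function(pr) {
    pr$p[length(pr$p) - 1] < 0.05 * max(pr$p)
  }, logical(1))
  pick <- which(ok & natural)
  if (length(pick) == 0) {
    warning("no chi-squared plateau with a naturally decaying P(r): Dmax ambiguous")
    pick <- which.min(chi2)
  }
  i <- min(pick)
  list(Dmax = candidates[i], candidates = candidates, chi2 = chi2,
       pr = prs[[i]])
}

#' Molecular weight from the volume of correlation
#'
#' `Vc = I(0) / integral(q*I(q) dq)` (with the q -> 0 limit anchored at
#' the Guinier `I0`), the ratio `QR = Vc^2 / Rg`, and the protein
#' mass calibration `MW = QR[A^3] / 0.1231` (Rambo-Tainer constants,
#' exposed as arguments). Vc is invariant to uniform intensity rescaling.
#' A truncation sensitivity estimate (MW recomputed with the upper
#' integration limit reduced by 20%) is reported.
#'
#' @param profile a [saxs_profile()] with q in nm^-1.
#' @param g a [guinier_fit()] result.
#' @param qmax upper integration limit (nm^-1); defaults to the full
#'   profile.
#' @param mw_coef,mw_exp protein calibration constants (QR in Angstrom^3):
#'   `MW = (QR / mw_coef)^(1/mw_exp)`.
#' @return object of class `vc_result`: `Vc` (nm^2), `QR` (nm^3),
#'   `MW_Da`, `MW_sensitivity_Da`.
#' @export
vc_molecular_weight <- function(profile, g, qmax = NULL,
                                mw_coef = 0.1231, mw_exp = 1.0) {
  stopifnot(inherits(profile, "saxs_profile"), inherits(g, "guinier_result"))
  if (is.null(qmax)) qmax <- max(profile$q)
  keep <- profile$q <= qmax
  q <- c(0, profile$q[keep])
  qi <- c(0, profile$q[keep] * profile$I[keep])
  integral <- .trapz(q, qi)
  tail_frac <- abs(qi[length(qi)] * (q[length(q)] - q[length(q) - 1])) / integral
  if (tail_frac > 0.01) {
    warning("q*I(q) integral has not converged at qmax; Vc is truncation-sensitive")
  }
  Vc <- g$I0 / integral
  QR <- Vc^2 / g$Rg
  QR_A3 <- QR * 1000    # nm^3 -> A^3
  MW <- (QR_A3 / mw_coef)^(1 / mw_exp)
  # sensitivity: recompute with qmax reduced by 20%
  q2max <- qmax * 0.8
  keep2 <- profile$q <= q2max
  q2 <- c(0, profile$q[keep2])
  qi2 <- c(0, profile$q[keep2] * profile$I[keep2])
  Vc2 <- g$I0 / .trapz(q2, qi2)
  MW2 <- ((Vc2^2 / g$Rg * 1000) / mw_coef)^(1 / mw_exp)
  structure(list(Vc = Vc, QR = QR, MW_Da = MW, MW_sensitivity_Da = MW2 - MW,
                 qmax = qmax),
            class = "vc_result")
}

#' @export
print.vc_result <- function(x, ...) {
  cat(sprintf("Volume of correlation: Vc = %.3g nm^2, QR = %.3g nm^3, MW = %.3g kDa (trunc. sens. %+.2g kDa)\n",
              x$Vc, x$QR, x$MW_Da / 1000, x$MW_sensitivity_Da / 1000))
  invisible(x)
}

#' Z-test consistency of a structural model with solution constraints
#'
#' Per-parameter z-scores `z = (model - experimental)/sd` with two-sided
#' normal p-values, comparing model-derived quantities (radius of
#' gyration, maximum dimension, end-to-end distances) with their
#' experimental estimates. The worst (minimum-p) parameter and a rejection
#' flag at `p_threshold` are reported.
#'
#' @param model named numeric vector of model-derived values.
#' @param experimental data frame with rownames (or a `param` column)
#'   matching `names(model)` and columns `value`, `sd` (> 0).
#' @param p_threshold rejection threshold (default 0.05).
#' @return object of class `model_z_test`: a `table` of z and p per
#'   parameter, `min_p`, `worst_param`, `consistent` flag.
#' @export
model_consistency_z <- function(model, experimental, p_threshold = 0.05) {
  if (!is.null(experimental$param)) rownames(experimental) <- experimental$param
  params <- names(model)
  if (!all(params %in% rownames(experimental))) {
    stop("every model parameter needs an experimental value and sd")
  }
  ex <- experimental[params, , drop = FALSE]
  if (any(ex$sd <= 0)) stop("experimental sds must be positive")
  z <- (as.numeric(unlist(model)) - ex$value) / ex$sd
  p <- 2 * stats::pnorm(-abs(z))
  tab <- data.frame(param = params, model = unlist(model),
                    experimental = ex$value, sd = ex$sd, z = z, p = p,
                    row.names = NULL)
  i <- which.min(p)
  structure(list(table = tab, min_p = p[i], worst_param = params[i],
                 consistent = p[i] >= p_threshold,
                 p_threshold = p_threshold),
            class = "model_z_test")
}

#' @export
print.model_z_test <- function(x, ...) {
  cat("Model vs experiment z-test:\n")
  print(x$table, digits = 3)
  cat(sprintf("  worst parameter: %s (p = %.3g) -> %s at p >= %.2f\n",
              x$worst_param, x$min_p,
              if (x$consistent) "consistent" else "rejected", x$p_threshold))
  invisible(x)
}
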