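#' Scott's rule histogram bin width
#'
#' `h = 3.49 * sd(x) * n^(-1/3)`, the bin width used throughout the
#' package for force and efficiency histograms.
#'
#' @param values numeric vector (n >= 2, non-constant).
#' @return bin width on the scale of `values`.
#' @export
scott_bin_width <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  s <- stats::sd(values)
  if (s == 0) stop("degenerate input: constant values have no bin width")
  3.49 * s * n^(-1 / 3)
}

# Robust per-curve force noise estimate from first differences.
.force_noise_sd <- function(force) {
  stats::mad(diff(force)) / sqrt(2)
}

# Locate sharp drops in a force trace. Returns the indices of the last
# sample before each drop (clustered). A drop is a decrease of more than
# k*noise_sd within at most 3 samples of the median-filtered trace.
.find_drops <- function(force, noise_sd, k = 5) {
  n <- length(force)
  fs <- stats::runmed(force, 3)
  # skip the sample blended by the median filter: compare to samples i+2..i+4
  shift <- function(k) c(fs[-seq_len(k)], rep(Inf, k))
  lead_min <- pmin(shift(2), shift(3), shift(4))
  drop <- fs - lead_min
  cand <- which(drop > k * noise_sd & fs > k * noise_sd)
  if (length(cand) == 0) return(integer(0))
  # cluster candidates closer than 5 samples; keep the last index of each
  splits <- c(0, which(diff(cand) > 5), length(cand))
  vapply(seq_len(length(splits) - 1), function(j) {
    idx <- cand[(splits[j] + 1):splits[j + 1]]
    idx[which.max(fs[idx])]
  }, integer(1))
}

# Weighted profile fit of the FJC in extension space. For a trial Kuhn
# length the contour length enters linearly: Lc = sum(w*x*g)/sum(w*g^2)
# with g(F) the normalized FJC extension. Weights 1/(dg/dF)^2 make the
# extension-space objective equivalent (to first order) to force-space
# least squares, appropriate because the noise lives in the force channel.
.fjc_profile_fit <- function(ext, frc, kBT, kuhn_range = c(0.15, 2.5)) {
  g_of <- function(a) {
    x <- frc * a / kBT
    ifelse(x < 1e-4, x / 3, 1 / tanh(x) - 1 / x)
  }
  gprime_of <- function(a) {
    x <- frc * a / kBT
    csch2 <- ifelse(x > 350, 0, 1 / sinh(x)^2)
    (a / kBT) * ifelse(x < 1e-4, 1 / 3, 1 / x^2 - csch2)
  }
  obj <- function(a) {
    g <- g_of(a)
    w <- 1 / pmax(gprime_of(a), 1e-12)^2
    Lc <- sum(w * ext * g) / sum(w * g^2)
    sum(w * (ext - Lc * g)^2)
  }
  opt <- stats::optimize(obj, kuhn_range, tol = 1e-6)
  a <- opt$minimum
  g <- g_of(a)
  w <- 1 / pmax(gprime_of(a), 1e-12)^2
  Lc <- sum(w * ext * g) / sum(w * g^2)
  list(Lc = Lc, kuhn = a)
}

#' Fit the FJC model to the stretching segment of a force curve
#'
#' Identifies the rupture (the largest sharp drop in the median-filtered
#' trace), takes the stretching segment from lift-off (force rising above
#' 3x the noise floor) to the peak immediately preceding the drop, and
#' least-squares fits the freely-jointed chain there. Curves with no
#' rising segment or no drop are reported as no-event rather than as
#' errors.
#'
#' @param curve a [force_curve()].
#' @param kBT thermal energy (pN nm).
#' @param noise_sd known force noise (pN); estimated robustly from the
#'   trace when `NULL`.
#' @return list with `no_event` flag and, for events: `params`
#'   ([fjc_params()] with the fitted `Lc` and Kuhn length), `residual`
#'   (RMS force residual on the stretching segment, pN), `r_squared`
#'   (force-space, over the whole pre-rupture trace), `F_rupture`
#'   (the fitted peak force immediately preceding the drop, pN) and
#'   `i_rupture` (sample index).
#' @export
fit_fjc <- function(curve, kBT = .kBT_default, noise_sd = NULL) {
  stopifnot(inherits(curve, "force_curve"))
  frc <- curve$force
  ext <- curve$extension
  if (is.null(noise_sd)) noise_sd <- .force_noise_sd(frc)
  noise_sd <- max(noise_sd, 1e-3)
  drops <- .find_drops(frc, noise_sd)
  no_event <- list(no_event = TRUE, n_drops = length(drops))
  if (length(drops) == 0) return(no_event)
  fs <- stats::runmed(frc, 3)
  i_rup <- drops[which.max(fs[drops])]
  # the median filter blurs the last sample of the peak; refine the
  # rupture index to the last raw sample above half the peak level
  # (the 50% crossing of the drop)
  half <- fs[i_rup] / 2
  while (i_rup < length(frc) - 1 && frc[i_rup + 1] > half) {
    i_rup <- i_rup + 1L
  }
  # lift-off: last run of samples below 3*noise before the rupture
  below <- which(fs[seq_len(i_rup)] < 3 * noise_sd)
  i_start <- if (length(below) == 0) 1L else max(below) + 1L
  if (i_rup - i_start + 1 < 8) return(c(no_event, list(reason = "segment too short")))
  seg <- i_start:i_rup
  fit <- .fjc_profile_fit(ext[seg], pmax(frc[seg], 1e-3), kBT)
  if (!is.finite(fit$Lc) || fit$Lc <= 0) return(c(no_event, list(reason = "fit failed")))
  p <- structure(list(Lc = fit$Lc, kuhn = fit$kuhn), class = "fjc_params")
  # force-space residuals via inversion of the fitted model; RMS on the
  # stretching segment, R-squared over the whole pre-rupture trace (the
  # baseline-to-peak swing is part of what the model must explain)
  fmax <- max(frc[seg])
  fg <- seq(1e-3, 1.5 * fmax + 10, length.out = 400)
  lg <- fjc_extension(fg, p, kBT)
  keep <- ext[seg] < max(lg)
  predict_force <- function(idx) {
    stats::approx(lg, fg, xout = pmin(ext[idx], max(lg) * 0.999999),
                  rule = 2)$y
  }
  res <- frc[seg] - predict_force(seg)
  rms <- sqrt(mean(res^2))
  pre <- seq_len(i_rup)
  res_pre <- frc[pre] - predict_force(pre)
  ss_tot <- sum((frc[pre] - mean(frc[pre]))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res_pre^2) / ss_tot else 0
  # rupture force = raw force at the refined peak sample; a single-sample
  # read is unbiased at every pulling speed, unlike a max over a window
  # (max-statistic bias) or a local extrapolation (curvature bias)
  F_rupture <- frc[i_rup]
  list(no_event = FALSE, params = p, residual = rms, r_squared = r2,
       F_rupture = F_rupture, i_rupture = i_rup, n_drops = length(drops),
       segment = seg, used = all(keep))
}

#' Select single-molecule rupture events from a set of force curves
#'
#' Applies the single-molecule criteria: exactly one sharp rupture drop in
#' the retraction trace and an acceptable FJC fit of the stretching
#' segment. The rupture force is the peak maximum immediately preceding
#' the drop, and the per-event loading rate is the tether-compliance
#' corrected rate evaluated at that force.
#'
#' @param curves list of [force_curve()] objects (e.g. from
#'   [make_dfs_dataset()]).
#' @param criteria list with `max_residual_factor` (default 2.5; an event
#'   is kept when its RMS force residual is below this multiple of the
#'   curve's noise floor), `lc_range` (default `c(20, 120)` nm, bracketing
#'   two 5-kDa PEG tethers), and optionally `min_r2` (force-space R-squared
#'   floor, default 0.5) or an absolute `max_residual` (pN RMS).
#' @param kBT thermal energy (pN nm).
#' @param noise_sd known force noise (pN) or `NULL` to estimate per curve.
#' @return data frame of rupture events: `id`, `F_rupture_pN`, `Lc_nm`,
#'   `kuhn_nm`, `residual_pN`, `r_squared`, `speed_nm_s`, `kc_pN_nm`,
#'   `vF_pN_s`. Possibly empty.
#' @export
select_single_events <- function(curves,
                                 criteria = list(max_residual_factor = 2.5,
                                                 lc_range = c(20, 120)),
                                 kBT = .kBT_default, noise_sd = NULL) {
  min_r2 <- criteria[["min_r2"]] %||% 0.5
  lc_range <- criteria[["lc_range"]] %||% c(20, 120)
  max_residual <- criteria[["max_residual"]] %||% Inf
  resid_factor <- criteria[["max_residual_factor"]] %||% 2.5
  rows <- lapply(curves, function(cv) {
    ns <- if (is.null(noise_sd)) .force_noise_sd(cv$force) else noise_sd
    f <- fit_fjc(cv, kBT = kBT, noise_sd = ns)
    if (isTRUE(f$no_event) || f$n_drops != 1) return(NULL)
    if (f$r_squared < min_r2 || f$residual > max_residual) return(NULL)
    if (f$residual > resid_factor * max(ns, 1e-3)) return(NULL)
    if (f$params$Lc < lc_range[1] || f$params$Lc > lc_range[2]) return(NULL)
    pull <- pulling_config(kc = cv$kc, v = cv$v,
                           sampling_rate = cv$sampling_rate, noise_sd = 1)
    vF <- effective_loading_rate(f$F_rupture, pull, f$params, kBT)
    data.frame(id = cv$id, F_rupture_pN = f$F_rupture,
               Lc_nm = f$params$Lc, kuhn_nm = f$params$kuhn,
               residual_pN = f$residual, r_squared = f$r_squared,
               speed_nm_s = cv$v, kc_pN_nm = cv$kc, vF_pN_s = vF,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(id = character(0), F_rupture_pN = numeric(0),
                      Lc_nm = numeric(0), kuhn_nm = numeric(0),
                      residual_pN = numeric(0), r_squared = numeric(0),
                      speed_nm_s = numeric(0), kc_pN_nm = numeric(0),
                      vF_pN_s = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Least-squares Gaussian (or sum of Gaussians) fit to histogram counts.
.fit_gaussian_hist <- function(x, counts, k = 1, start = NULL) {
  df <- data.frame(x = x, counts = counts)
  if (k == 1) {
    if (is.null(start)) {
      start <- list(A = max(counts), mu = x[which.max(counts)],
                    s = sqrt(sum(counts * (x - sum(counts * x) / sum(counts))^2) /
                               sum(counts)))
    }
    fit <- minpack.lm::nlsLM(counts ~ A * exp(-(x - mu)^2 / (2 * s^2)),
                             data = df, start = start,
                             lower = c(0, min(x), 1e-6 * diff(range(x))),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    fit <- minpack.lm::nlsLM(
      counts ~ A1 * exp(-(x - mu1)^2 / (2 * s1^2)) +
               A2 * exp(-(x - mu2)^2 / (2 * s2^2)),
      data = df, start = start,
      lower = c(0, min(x), 1e-6 * diff(range(x)), 0, min(x),
                1e-6 * diff(range(x))),
      control = minpack.lm::nls.lm.control(maxiter = 400))
  }
  fit
}

#' Fit the rupture-force distribution with one or two Gaussian components
#'
#' Builds a histogram with Scott's-rule bins and least-squares fits a
#' Gaussian (or a sum of two) to the bin counts, as done for the force
#' distributions at each loading rate. Component means (`Fmp`) are
#' returned in ascending order. If the two requested components are not
#' separated by at least their combined standard deviation, the fit falls
#' back to a single component with a warning (guard against over-fitting
#' a unimodal distribution).
#'
#' @param forces numeric vector of rupture forces (pN); at least 30 for one
#'   component, 60 for two.
#' @param n_components 1 or 2.
#' @return object of class `force_dist_fit`: data frame `components` with
#'   columns `Fmp`, `sd`, `weight`, `se_Fmp`; plus the histogram used.
#' @export
fit_force_distribution <- function(forces, n_components = 1) {
  forces <- forces[is.finite(forces)]
  if (!n_components %in% c(1, 2)) stop("n_components must be 1 or 2")
  if (n_components == 1 && length(forces) < 30) stop("need >= 30 forces for 1 component")
  if (n_components == 2 && length(forces) < 60) stop("need >= 60 forces for 2 components")
  h <- scott_bin_width(forces)
  breaks <- seq(min(forces) - h, max(forces) + h, by = h)
  if (breaks[length(breaks)] < max(forces)) breaks <- c(breaks, breaks[length(breaks)] + h)
  hh <- graphics::hist(forces, breaks = breaks, plot = FALSE)
  x <- hh$mids
  counts <- hh$counts
  fallback <- FALSE
  fit <- NULL
  if (n_components == 2) {
    km <- stats::kmeans(forces, centers = stats::quantile(forces, c(0.25, 0.75)))
    mu0 <- sort(km$centers)
    sd0 <- vapply(1:2, function(j) stats::sd(forces[km$cluster == order(km$centers)[j]]),
                  numeric(1))
    sd0[!is.finite(sd0) | sd0 <= 0] <- h
    A0 <- vapply(mu0, function(m) max(counts[which.min(abs(x - m))], 1), numeric(1))
    start <- list(A1 = A0[1], mu1 = mu0[1], s1 = sd0[1],
                  A2 = A0[2], mu2 = mu0[2], s2 = sd0[2])
    fit <- tryCatch(.fit_gaussian_hist(x, counts, k = 2, start = start),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      if (abs(cf[["mu2"]] - cf[["mu1"]]) < (cf[["s1"]] + cf[["s2"]])) {
        warning("two-component fit collapsed (means within one combined sd); falling back to one component")
        fallback <- TRUE
      }
    } else {
      warning("two-component fit did not converge; falling back to one component")
      fallback <- TRUE
    }
  }
  if (n_components == 1 || fallback) {
    fit <- tryCatch(.fit_gaussian_hist(x, counts, k = 1), error = function(e) NULL)
    if (is.null(fit)) {
      stop(sprintf("Gaussian histogram fit failed (n = %d, %d bins, width %.3g)",
                   length(forces), length(x), h))
    }
    cf <- stats::coef(fit)
    se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, 3))
    comp <- data.frame(Fmp = cf[["mu"]], sd = abs(cf[["s"]]), weight = 1,
                       se_Fmp = se[[2]])
  } else {
    cf <- stats::coef(fit)
    se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, 6))
    area <- c(cf[["A1"]] * abs(cf[["s1"]]), cf[["A2"]] * abs(cf[["s2"]]))
    comp <- data.frame(Fmp = c(cf[["mu1"]], cf[["mu2"]]),
                       sd = abs(c(cf[["s1"]], cf[["s2"]])),
                       weight = area / sum(area),
                       se_Fmp = c(se[[2]], se[[5]]))
    o <- order(comp$Fmp)
    comp <- comp[o, , drop = FALSE]
    rownames(comp) <- NULL
  }
  structure(list(components = comp, n = length(forces), bin_width = h,
                 breaks = breaks, counts = counts, mids = x,
                 n_components = nrow(comp), fit = fit,
                 fell_back = fallback),
            class = "force_dist_fit")
}

#' @export
print.force_dist_fit <- function(x, ...) {
  cat(sprintf("Force distribution fit: %d component(s), n = %d, Scott bin width %.3g pN\n",
              x$n_components, x$n, x$bin_width))
  print(x$components, digits = 4)
  invisible(x)
}

#' Assign rupture events to mixture components by posterior weight
#'
#' Events are attributed to the Gaussian component with the larger
#' posterior density at the event force; ties go to the low-force state.
#'
#' @param forces rupture forces (pN).
#' @param dist_fit a `force_dist_fit` from [fit_force_distribution()].
#' @return integer vector of component indices (1 = low-force state).
#' @export
assign_states <- function(forces, dist_fit) {
  stopifnot(inherits(dist_fit, "force_dist_fit"))
  comp <- dist_fit$components
  post <- vapply(seq_len(nrow(comp)), function(j) {
    comp$weight[j] * stats::dnorm(forces, comp$Fmp[j], comp$sd[j])
  }, numeric(length(forces)))
  post <- matrix(post, nrow = length(forces))
  idx <- max.col(post, ties.method = "first")
  as.integer(idx)
}

#' Dynamic force spectroscopy analysis: events to Bell-Evans kinetics
#'
#' The per-speed stage of the pipeline: for each pulling speed, fit the
#' rupture-force histogram with `n_components` Gaussians, evaluate the
#' tether-compliance corrected loading rate at each component's most
#' probable force, and fit the Bell-Evans model per state across speeds.
#'
#' @param events data frame from [select_single_events()] (or any frame
#'   with `F_rupture_pN`, `speed_nm_s`, `kc_pN_nm`).
#' @param tether an [fjc_params()] object used for the loading-rate
#'   correction (the mean fitted tether is a good choice).
#' @param n_components Gaussians per speed (1 or 2).
#' @param kBT thermal energy (pN nm).
#' @return list with `points` (data frame: speed, state, Fmp, se_Fmp, vF)
#'   and `fits` (list of [fit_bell_evans()] results, one per state).
#' @export
dfs_analysis <- function(events, tether, n_components = 1, kBT = .kBT_default) {
  stopifnot(is.data.frame(events), inherits(tether, "fjc_params"))
  speeds <- sort(unique(events$speed_nm_s))
  pts <- list()
  for (v in speeds) {
    ev <- events[events$speed_nm_s == v, , drop = FALSE]
    if (nrow(ev) < 30) next
    dfit <- fit_force_distribution(ev$F_rupture_pN, n_components = n_components)
    pull <- pulling_config(kc = ev$kc_pN_nm[1], v = v,
                           sampling_rate = 6000, noise_sd = 1)
    comp <- dfit$components
    for (j in seq_len(nrow(comp))) {
      pts[[length(pts) + 1]] <- data.frame(
        speed_nm_s = v, state = j, Fmp = comp$Fmp[j], se_Fmp = comp$se_Fmp[j],
        sd = comp$sd[j], weight = comp$weight[j],
        vF = effective_loading_rate(comp$Fmp[j], pull, tether, kBT),
        n = nrow(ev))
    }
  }
  points <- do.call(rbind, pts)
  if (is.null(points) || nrow(points) == 0) stop("no speed had enough events to fit")
  fits <- lapply(sort(unique(points$state)), function(s) {
    sub <- points[points$state == s, , drop = FALSE]
    fit_bell_evans(sub, kBT = kBT,
                   state = if (max(points$state) == 1) "single" else
                     c("low-force", "high-force")[s])
  })
  list(points = points, fits = fits)
}
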