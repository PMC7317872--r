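#' FRET pair configuration
#'
#' Forster radius `R0` (nm) of the donor-acceptor pair and the detection
#' correction factor `gamma`. `gamma = 1` (no correction) is the default;
#' `R0` has no default and must be supplied for distance conversion.
#'
#' @param R0 Forster radius (nm).
#' @param gamma detection correction factor (dimensionless).
#' @return object of class `fret_config`.
#' @export
fret_config <- function(R0 = NA_real_, gamma = 1) {
  if (!is.na(R0)) .check_pos(R0, "R0")
  .check_pos(gamma, "gamma")
  structure(list(R0 = R0, gamma = gamma), class = "fret_config")
}

#' Single-molecule FRET intensity trace
#'
#' Donor and acceptor intensity time traces of one immobilized molecule,
#' with per-channel background levels.
#'
#' @param time frame times (s).
#' @param donor donor-channel intensities (counts).
#' @param acceptor acceptor-channel intensities (counts).
#' @param bg_donor,bg_acceptor background levels (counts, >= 0).
#' @param id trace identifier.
#' @return object of class `fret_trace`.
#' @export
fret_trace <- function(time, donor, acceptor, bg_donor = 0, bg_acceptor = 0,
                       id = "trace") {
  if (length(time) != length(donor) || length(donor) != length(acceptor)) {
    stop("time, donor and acceptor must have equal length")
  }
  if (bg_donor < 0 || bg_acceptor < 0) stop("backgrounds must be >= 0")
  structure(list(time = time, donor = donor, acceptor = acceptor,
                 bg_donor = bg_donor, bg_acceptor = bg_acceptor, id = id),
            class = "fret_trace")
}

#' Simulate single-molecule FRET traces with acceptor photobleaching
#'
#' Each trace has acceptor mean `E_true * I_total` and donor mean
#' `(1 - E_true) * I_total` (plus channel backgrounds) until the acceptor
#' photobleaches in a single step at a geometrically distributed random
#' frame, after which the acceptor falls to background and the donor rises
#' to the full `I_total` (the anticorrelated signature used to validate a
#' genuine FRET pair). Shot noise is approximated as Gaussian with
#' variance equal to the mean count.
#'
#' @param E_true ground-truth FRET efficiency in `[0, 1]`.
#' @param n_traces number of traces.
#' @param n_frames frames per trace (default 400, i.e. 400 s at 1 Hz).
#' @param I_total mean total signal photons per frame.
#' @param bg_donor,bg_acceptor background count levels.
#' @param bleach_mean mean of the geometric acceptor-bleach frame.
#' @param seed optional integer seed.
#' @return list of [fret_trace()] objects with a `bleach_frame` attribute
#'   (integer vector of planted bleach frames).
#' @export
make_fret_traces <- function(E_true, n_traces = 25, n_frames = 400,
                             I_total = 500, bg_donor = 50, bg_acceptor = 50,
                             bleach_mean = 150, seed = NULL) {
  if (E_true < 0 || E_true > 1) stop("E_true must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  bleach <- pmin(stats::rgeom(n_traces, 1 / bleach_mean) + 1L, n_frames)
  traces <- lapply(seq_len(n_traces), function(i) {
    t <- seq_len(n_frames) - 1
    pre <- seq_len(n_frames) <= bleach[i]
    mu_a <- ifelse(pre, E_true * I_total, 0) + bg_acceptor
    mu_d <- ifelse(pre, (1 - E_true) * I_total, I_total) + bg_donor
    fret_trace(time = t,
               donor = stats::rnorm(n_frames, mu_d, sqrt(mu_d)),
               acceptor = stats::rnorm(n_frames, mu_a, sqrt(mu_a)),
               bg_donor = bg_donor, bg_acceptor = bg_acceptor,
               id = sprintf("trace%03d", i))
  })
  attr(traces, "bleach_frame") <- bleach
  traces
}

#' Per-trace FRET efficiency
#'
#' Detects the acceptor photobleaching step as the largest single-step
#' drop in the 3-frame median-filtered acceptor trace and averages the
#' background- and gamma-corrected intensity ratio
#' `(I_A - bg_A) / ((I_A - bg_A) + gamma*(I_D - bg_D))` over the
#' pre-bleach frames. Traces with no detectable acceptor signal, or with
#' fewer than `min_prebleach` usable frames, are excluded (returned as
#' `NA`), not treated as errors.
#'
#' @param trace a [fret_trace()].
#' @param cfg a [fret_config()] (only `gamma` is used).
#' @param min_prebleach minimum number of pre-bleach frames (default 10).
#' @return the efficiency (scalar), or `NA` if the trace is excluded.
#' @export
trace_efficiency <- function(trace, cfg = fret_config(), min_prebleach = 10) {
  stopifnot(inherits(trace, "fret_trace"))
  acc <- trace$acceptor
  don <- trace$donor
  n <- length(acc)
  if (n < min_prebleach) return(NA_real_)
  accs <- stats::runmed(acc, 3)
  noise <- max(stats::mad(diff(acc)) / sqrt(2), 1e-6)
  # no acceptor signal at the start of the trace -> exclude (median is
  # robust against a lone bright frame before an immediate bleach)
  head_sig <- stats::median(utils::head(acc, min_prebleach)) - trace$bg_acceptor
  if (head_sig < 3 * noise) return(NA_real_)
  step <- accs[-n] - accs[-1]
  i <- which.max(step)
  has_bleach <- step[i] > 4 * noise &&
    mean(accs[seq_len(i)]) > mean(accs[(i + 1):n])
  pre <- if (has_bleach) seq_len(max(i - 1, 1)) else seq_len(n)
  if (length(pre) < min_prebleach) return(NA_real_)
  ia <- acc[pre] - trace$bg_acceptor
  id <- don[pre] - trace$bg_donor
  mean(ia / (ia + cfg$gamma * id))
}

#' Most probable FRET efficiency of a population
#'
#' Histograms the per-trace efficiencies with Scott's-rule bins and fits a
#' Gaussian by least squares; the fitted mean is the most probable
#' efficiency. When the histogram is too coarse for a stable
#' three-parameter fit (fewer than 5 occupied bins) the sample mean and
#' standard deviation are used directly. A simple unimodality check
#' (secondary histogram mode above half the main peak) is reported.
#'
#' @param Es numeric vector of per-trace efficiencies (`NA`s dropped);
#'   at least 10 required.
#' @return object of class `efficiency_distribution` with `EFRETmp`,
#'   `sd`, `n`, the efficiencies and a `bimodal` flag.
#' @export
most_probable_efficiency <- function(Es) {
  Es <- Es[is.finite(Es)]
  n <- length(Es)
  if (n < 10) stop("need at least 10 efficiencies")
  h <- scott_bin_width(Es)
  breaks <- seq(min(Es) - h, max(Es) + h, by = h)
  if (breaks[length(breaks)] < max(Es)) breaks <- c(breaks, breaks[length(breaks)] + h)
  hh <- graphics::hist(Es, breaks = breaks, plot = FALSE)
  occupied <- sum(hh$counts > 0)
  fit <- NULL
  if (occupied >= 5) {
    fit <- tryCatch(.fit_gaussian_hist(hh$mids, hh$counts, k = 1),
                    error = function(e) NULL)
  }
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    mp <- cf[["mu"]]
    s <- abs(cf[["s"]])
  } else {
    mp <- mean(Es)
    s <- stats::sd(Es)
  }
  # unimodality: a secondary local maximum above half the main peak
  cnt <- hh$counts
  locmax <- which(diff(sign(diff(c(-1, cnt, -1)))) == -2)
  bimodal <- FALSE
  if (length(locmax) > 1) {
    tops <- sort(cnt[locmax], decreasing = TRUE)
    bimodal <- tops[2] >= 0.5 * tops[1]
  }
  if (bimodal) warning("efficiency distribution looks bimodal; reporting the dominant mode")
  structure(list(E = Es, EFRETmp = mp, sd = s, n = n, bimodal = bimodal,
                 bin_width = h),
            class = "efficiency_distribution")
}

#' @export
print.efficiency_distribution <- function(x, ...) {
  cat(sprintf("Most probable FRET efficiency: %.3f (sd %.3f, n = %d)%s\n",
              x$EFRETmp, x$sd, x$n, if (x$bimodal) " [bimodal!]" else ""))
  invisible(x)
}

#' Donor-acceptor distance from FRET efficiency
#'
#' Inverts `E = 1 / (1 + (R/R0)^6)`: `R = R0 * (1/E - 1)^(1/6)`.
#' Defined only for `0 < E < 1`.
#'
#' @param E efficiency in (0, 1), vectorised.
#' @param cfg a [fret_config()] with `R0` set.
#' @return distance in the units of `R0`.
#' @export
distance_from_efficiency <- function(E, cfg) {
  stopifnot(inherits(cfg, "fret_config"))
  if (is.na(cfg$R0)) stop("R0 must be set in the fret_config for distance conversion")
  if (any(E <= 0 | E >= 1)) stop("efficiency out of the open interval (0, 1)")
  cfg$R0 * (1 / E - 1)^(1 / 6)
}

#' @rdname distance_from_efficiency
#' @param R distance (same units as `R0`).
#' @export
efficiency_from_distance <- function(R, cfg) {
  stopifnot(inherits(cfg, "fret_config"))
  if (is.na(cfg$R0)) stop("R0 must be set in the fret_config")
  .check_pos(R, "R")
  1 / (1 + (R / cfg$R0)^6)
}
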