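#' Default thermal energy
#'
#' Thermal energy kB*T in piconewton-nanometres. The package default of
#' 4.11 pN nm corresponds to 298 K; use [thermal_energy()] for other
#' temperatures.
#'
#' @param T_K temperature in kelvin.
#' @return kB*T in pN nm.
#' @examples
#' thermal_energy(298.15)
#' @export
thermal_energy <- function(T_K = 298.15) {
  if (T_K <= 0) stop("temperature must be positive (kelvin)")
  1.380649e-2 * T_K
}

.kBT_default <- 4.11

.check_pos <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be a positive finite number", name), call. = FALSE)
  }
  invisible(x)
}

#' Freely-jointed-chain tether parameters
#'
#' Parameters of the freely-jointed chain (FJC) used to model the PEG
#' tethers that couple the protein to the cantilever and the surface:
#' contour length `Lc` and Kuhn length `kuhn`, both in nanometres. Defaults
#' describe two 5-kDa PEG spacers in series (contour length 58.7 nm) with a
#' literature-typical PEG Kuhn length of 0.7 nm.
#'
#' @param Lc contour length (nm).
#' @param kuhn Kuhn (statistical segment) length (nm); must be much smaller
#'   than `Lc`.
#' @return an object of class `fjc_params`.
#' @export
fjc_params <- function(Lc = 58.7, kuhn = 0.7) {
  .check_pos(Lc, "Lc")
  .check_pos(kuhn, "kuhn")
  if (kuhn >= Lc) stop("Kuhn length must be much smaller than the contour length")
  structure(list(Lc = Lc, kuhn = kuhn), class = "fjc_params")
}

#' @export
print.fjc_params <- function(x, ...) {
  cat(sprintf("FJC tether: Lc = %.2f nm, Kuhn length = %.3f nm\n", x$Lc, x$kuhn))
  invisible(x)
}

#' FJC force-extension relation (extension from force)
#'
#' Extension of a freely-jointed chain at force `F`:
#' `l(F) = Lc * (coth(F*a/kBT) - kBT/(F*a))`, with Kuhn length `a`.
#' The limit `F -> 0` is continuous (`l -> 0`, series `Lc*F*a/(3*kBT)`),
#' and `l -> Lc` as `F -> Inf`.
#'
#' @param F force in pN (vectorised); must be non-negative.
#' @param p an [fjc_params()] object.
#' @param kBT thermal energy (pN nm).
#' @return extension in nm.
#' @export
fjc_extension <- function(F, p, kBT = .kBT_default) {
  stopifnot(inherits(p, "fjc_params"))
  .check_pos(kBT, "kBT")
  if (any(F < 0)) stop("force must be non-negative")
  x <- F * p$kuhn / kBT
  l <- numeric(length(x))
  small <- x < 1e-4
  # Taylor: coth(x) - 1/x = x/3 - x^3/45 + ...
  l[small] <- p$Lc * (x[small] / 3 - x[small]^3 / 45)
  xs <- x[!small]
  l[!small] <- p$Lc * (1 / tanh(xs) - 1 / xs)
  l
}

#' FJC force at a given extension (numerical inversion)
#'
#' Inverts [fjc_extension()] by root bracketing. Extensions must lie in
#' `[0, Lc)`; the force diverges at full extension.
#'
#' @param extension extension in nm (vectorised).
#' @param p an [fjc_params()] object.
#' @param kBT thermal energy (pN nm).
#' @return force in pN.
#' @export
fjc_force <- function(extension, p, kBT = .kBT_default) {
  stopifnot(inherits(p, "fjc_params"))
  if (any(extension >= p$Lc)) {
    stop("extension at or beyond the contour length: FJC force diverges")
  }
  vapply(extension, function(e) {
    if (e <= 0) return(0)
    f_hi <- 10
    while (fjc_extension(f_hi, p, kBT) < e && f_hi < 1e8) f_hi <- f_hi * 4
    stats::uniroot(function(f) fjc_extension(f, p, kBT) - e,
                   lower = 1e-12, upper = f_hi, tol = 1e-12)$root
  }, numeric(1))
}

#' Pulling configuration for force spectroscopy
#'
#' Instrument settings of one constant-velocity retraction: cantilever
#' spring constant `kc` (pN/nm), pulling velocity `v` (nm/s), sampling rate
#' (Hz) and Gaussian force-noise standard deviation (pN). Defaults follow
#' the study conditions: a nominal 20 pN/nm silicon-nitride lever sampled
#' at 6 kHz with 5 pN of force noise.
#'
#' @param kc cantilever spring constant (pN/nm).
#' @param v pulling velocity (nm/s).
#' @param sampling_rate samples per second.
#' @param noise_sd force noise standard deviation (pN), may be zero.
#' @return an object of class `pulling_config`.
#' @export
pulling_config <- function(kc = 20, v = 2000, sampling_rate = 6000, noise_sd = 5) {
  .check_pos(kc, "kc")
  .check_pos(v, "v")
  .check_pos(sampling_rate, "sampling_rate")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(kc = kc, v = v, sampling_rate = sampling_rate,
                 noise_sd = noise_sd), class = "pulling_config")
}

#' Effective loading rate with tether compliance
#'
#' The rate of force increase at force `F` for a cantilever of stiffness
#' `kc` pulled at velocity `v` through a compliant FJC tether in series:
#' \deqn{v_F = k_c v / (1 + k_c (L_c a / k_BT) [ (k_BT/(F a))^2 -
#'   \mathrm{csch}^2(F a/k_BT) ])}
#' It is bounded above by the rigid-tether limit `kc*v`, which it
#' approaches as `F -> Inf` (or `Lc -> 0`), and is monotone increasing
#' in `F`.
#'
#' @param F force at which the rate is evaluated (pN), typically the most
#'   probable rupture force of a state; vectorised.
#' @param pull a [pulling_config()].
#' @param tether an [fjc_params()] object.
#' @param kBT thermal energy (pN nm).
#' @return loading rate in pN/s.
#' @export
effective_loading_rate <- function(F, pull, tether, kBT = .kBT_default) {
  stopifnot(inherits(pull, "pulling_config"), inherits(tether, "fjc_params"))
  if (any(F <= 0)) stop("force must be positive")
  x <- F * tether$kuhn / kBT
  csch2 <- ifelse(x > 350, 0, 1 / sinh(x)^2)
  bracket <- (1 / x)^2 - csch2
  pull$kc * pull$v / (1 + pull$kc * (tether$Lc * tether$kuhn / kBT) * bracket)
}
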