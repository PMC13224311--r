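# Frequency-domain observation function: linearise around the fixed point,
# form the loop transfer function of the three-population circuit (with the
# intrinsic delay as an exact phase factor on sigmoid-mediated couplings),
# and return the unit-area-normalised log PSD.

#' Spectral observation container
#'
#' A frequency grid with log power values and a provenance record.
#'
#' @param freqs strictly increasing frequency grid (Hz).
#' @param log_psd log power values, same length as `freqs`.
#' @param source one of `"model"`, `"synthetic"`, `"empirical"`.
#' @param normalised logical; whether `exp(log_psd)` integrates to one over
#'   the grid (rectangular rule).
#' @param band optional band edges `c(low, high)` in Hz.
#' @return An object of class `spectral_observation`.
#' @export
spectral_observation <- function(freqs, log_psd,
                                 source = c("model", "synthetic", "empirical"),
                                 normalised = FALSE, band = range(freqs)) {
  source <- match.arg(source)
  if (length(freqs) != length(log_psd))
    stop("freqs and log_psd must have equal length")
  if (any(!is.finite(freqs)) || any(!is.finite(log_psd)))
    stop("freqs and log_psd must be finite")
  if (any(diff(freqs) <= 0)) stop("freqs must be strictly increasing")
  if (normalised) {
    df <- stats::median(diff(freqs))
    z <- sum(exp(log_psd)) * df
    if (abs(z - 1) > 1e-6)
      stop("normalisation flag set but area = ", format(z, digits = 8))
  }
  structure(list(freqs = as.numeric(freqs), log_psd = as.numeric(log_psd),
                 meta = list(source = source, normalised = normalised,
                             band = band)),
            class = "spectral_observation")
}

#' @export
print.spectral_observation <- function(x, ...) {
  cat("<spectral_observation>", length(x$freqs), "bins,",
      x$freqs[1], "-", x$freqs[length(x$freqs)], "Hz,",
      "source =", x$meta$source,
      if (isTRUE(x$meta$normalised)) "(unit area)" else "", "\n")
  invisible(x)
}

# rectangular-rule unit-area normalisation of a positive PSD vector
.unit_area <- function(psd, freqs) {
  df <- stats::median(diff(freqs))
  psd / (sum(psd) * df)
}

#' Re-normalise a spectral observation to unit area
#'
#' Idempotent: applying it twice equals applying it once.
#' @param obs a [spectral_observation()].
#' @return The normalised observation.
#' @export
normalise_spectrum <- function(obs) {
  p <- .unit_area(exp(obs$log_psd), obs$freqs)
  spectral_observation(obs$freqs, log(p), obs$meta$source, normalised = TRUE,
                       band = obs$meta$band)
}

# ---- vectorised transfer PSD over a population of parameter vectors -------

# Closed-loop degree-6 characteristic polynomial (zero-delay linearisation).
# Columns: coefficients of s^6 ... s^0, one row per individual.
.charpoly6 <- function(Te, Ti, He, Hi, G1, G2, G3, G4, G5, a) {
  be <- He / Te; bi <- Hi / Ti
  ae <- 1 / Te; ai <- 1 / Ti
  # pe = (s + ae)^2 ; pe2 = pe^2 (degree 4)
  p4 <- cbind(1, 4 * ae, 6 * ae^2, 4 * ae^3, ae^4)
  p4[, 5L] <- p4[, 5L] - be^2 * G1 * G2 * a^2          # pe^2 - be^2 ce1 ce2
  q2 <- cbind(1, 2 * ai, ai^2 + bi * G5 * a)            # pi + bi ce5
  # convolution of degree-4 and degree-2 coefficient rows -> degree 6
  out <- matrix(0, nrow = length(Te), ncol = 7L)
  for (i in 1:5) for (j in 1:3) out[, i + j - 1L] <- out[, i + j - 1L] + p4[, i] * q2[, j]
  add <- be * bi * G3 * G4 * a^2                        # + be bi ce3 ce4 * pe
  out[, 5L] <- out[, 5L] + add
  out[, 6L] <- out[, 6L] + add * 2 * ae
  out[, 7L] <- out[, 7L] + add * ae^2
  out
}

# Routh-Hurwitz stability of degree-6 polynomials (rows of coefficients,
# highest order first). Marginal/zero pivots count as unstable.
.routh_stable6 <- function(coef) {
  a0 <- coef[, 1L]; a1 <- coef[, 2L]; a2 <- coef[, 3L]; a3 <- coef[, 4L]
  a4 <- coef[, 5L]; a5 <- coef[, 6L]; a6 <- coef[, 7L]
  eps <- .Machine$double.xmin
  b1 <- (a1 * a2 - a0 * a3) / pmax(a1, eps)
  b2 <- (a1 * a4 - a0 * a5) / pmax(a1, eps)
  b3 <- a6
  c1 <- (b1 * a3 - a1 * b2) / pmax(b1, eps)
  c2 <- (b1 * a5 - a1 * b3) / pmax(b1, eps)
  d1 <- (c1 * b2 - b1 * c2) / pmax(c1, eps)
  d2 <- b3
  e1 <- (d1 * c2 - c1 * d2) / pmax(d1, eps)
  f1 <- d2
  ok <- a0 > 0 & a1 > 0 & b1 > 0 & c1 > 0 & d1 > 0 & e1 > 0 & f1 > 0
  ok & is.finite(b1) & is.finite(c1) & is.finite(d1) & is.finite(e1)
}

# Transfer-function PSD for a matrix of log-parameter vectors.
# theta_mat: n x 15 (columns in .PARAM_NAMES order). Returns list(psd = n x F
# matrix of raw PSDs, stable = logical n).
.batch_psd <- function(theta_mat, scales, freqs, innovations = "white") {
  if (is.null(dim(theta_mat))) theta_mat <- matrix(theta_mat, nrow = 1L)
  ph <- sweep(exp(theta_mat), 2L, scales, "*")
  colnames(ph) <- .PARAM_NAMES
  n <- nrow(ph); nf <- length(freqs)
  w <- 2 * pi * freqs
  Te <- ph[, "Te"]; Ti <- ph[, "Ti"]; He <- ph[, "He"]; Hi <- ph[, "Hi"]
  s0 <- stats::plogis(-ph[, "R1"] * ph[, "R2"])
  a <- ph[, "R1"] * s0 * (1 - s0)
  ce1 <- ph[, "G1"] * a; ce2 <- ph[, "G2"] * a; ce3 <- ph[, "G3"] * a
  ce4 <- ph[, "G4"] * a; ce5 <- ph[, "G5"] * a
  W2 <- matrix(w^2, n, nf, byrow = TRUE)
  IW <- matrix(1i * w, n, nf, byrow = TRUE)
  ke <- (He / Te) / (1 / Te^2 - W2 + 2 * IW / Te)
  ki <- (Hi / Ti) / (1 / Ti^2 - W2 + 2 * IW / Ti)
  d <- exp(-IW * ph[, "Di"])
  Tr <- ke^2 * ce2 * d * ph[, "input_gain"] /
    (1 - ke^2 * ce1 * ce2 * d^2 + ke * ki * ce3 * ce4 * d^2 / (1 + ki * ce5 * d))
  psd <- Mod(Tr)^2 * ph[, "obs_gain"]^2
  if (innovations == "pink") {
    Fm <- matrix(freqs, n, nf, byrow = TRUE)
    psd <- psd * Fm^(-ph[, "noise_exponent"])
  }
  stable <- .routh_stable6(.charpoly6(Te, Ti, He, Hi, ph[, "G1"], ph[, "G2"],
                                      ph[, "G3"], ph[, "G4"], ph[, "G5"], a))
  stable <- stable & apply(is.finite(psd) & psd > 0, 1L, all)
  list(psd = psd, stable = stable)
}

#' Transfer-function power spectral density
#'
#' Squared magnitude of the closed-loop transfer function from the exogenous
#' input to the pyramidal potential, evaluated on a frequency grid, times the
#' innovation spectrum (white by default, optionally `1/f^noise_exponent`).
#' The intrinsic delay enters as an exact phase factor on the
#' sigmoid-mediated couplings. Stability of the zero-delay linearisation is
#' assessed by a Routh--Hurwitz test on the closed-loop characteristic
#' polynomial; an unstable parameter set is flagged via the `"stable"`
#' attribute rather than an error, so global searches can traverse it.
#'
#' @param params an [nmm_params()] object.
#' @param freqs frequency grid (Hz).
#' @param innovations `"white"` or `"pink"`.
#' @return Positive PSD vector with attribute `stable` (logical).
#' @export
transfer_psd <- function(params, freqs, innovations = c("white", "pink")) {
  innovations <- match.arg(innovations)
  out <- .batch_psd(matrix(params$theta_log, nrow = 1L), params$scales, freqs,
                    innovations)
  structure(drop(out$psd), stable = out$stable[1L])
}

#' Model log power spectrum (the shared observation function)
#'
#' Computes the transfer-function PSD, normalises it to unit area over the
#' grid (rectangular rule, matching the preprocessing applied to data), and
#' log-transforms. Deterministic: identical parameters and grid give
#' bit-identical output.
#'
#' @inheritParams transfer_psd
#' @param normalise normalise to unit area before the log (default `TRUE`;
#'   when `TRUE` the overall observation gain cancels).
#' @return A [spectral_observation()] with `meta$source = "model"`; the
#'   `"stable"` attribute carries the stability flag.
#' @export
observe_log_psd <- function(params, freqs, innovations = c("white", "pink"),
                            normalise = TRUE) {
  innovations <- match.arg(innovations)
  psd <- transfer_psd(params, freqs, innovations)
  st <- attr(psd, "stable")
  p <- if (normalise) .unit_area(as.numeric(psd), freqs) else as.numeric(psd)
  obs <- spectral_observation(freqs, log(p), source = "model",
                              normalised = normalise)
  attr(obs, "stable") <- st
  obs
}

# fast internal path used by the GA and VL: full theta matrix -> log-PSD
# matrix (unit area), unstable rows flagged
.batch_log_psd <- function(theta_mat, params, freqs, innovations = "white") {
  out <- .batch_psd(theta_mat, params$scales, freqs, innovations)
  df <- stats::median(diff(freqs))
  lp <- log(out$psd / (rowSums(out$psd) * df))
  list(log_psd = lp, stable = out$stable)
}
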