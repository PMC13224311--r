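# Synthetic-data generation: spectra with known ground truth, condition
# pairs, stochastic time-domain simulation, and empirical-style epoch
# preprocessing.

#' Synthetic-data specification
#'
#' @param theta_star ground-truth [nmm_params()].
#' @param freqs frequency grid (Hz).
#' @param noise_sd standard deviation of additive Gaussian noise on the log
#'   PSD (default 0.1).
#' @param seed integer seed.
#' @param delta_map optional named log-scale shifts defining a second
#'   condition.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(theta_star = nmm_params(), freqs = seq(2, 45, 0.5),
                           noise_sd = 0.1, seed = 1, delta_map = NULL) {
  stopifnot(noise_sd >= 0)
  if (!is.null(delta_map)) {
    bad <- setdiff(names(delta_map), theta_star$names)
    if (length(bad)) stop("unknown parameter(s) in delta_map: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(theta_star = theta_star, freqs = freqs, noise_sd = noise_sd,
                 seed = seed, delta_map = delta_map),
            class = "synthetic_spec")
}

#' Generate a synthetic spectrum
#'
#' The model's noise-free unit-area log PSD at the ground-truth parameters,
#' plus independent Gaussian noise of standard deviation `noise_sd` on the
#' log scale, seeded.
#'
#' @param spec a [synthetic_spec()].
#' @param innovations innovation spectrum.
#' @return A [spectral_observation()] with `meta$source = "synthetic"` and
#'   the generating spec embedded in `meta$spec`.
#' @export
generate_spectrum <- function(spec, innovations = "white") {
  base <- observe_log_psd(spec$theta_star, spec$freqs, innovations)
  if (!isTRUE(attr(base, "stable")))
    stop("forward model unstable at theta_star")
  noise <- .with_seed(spec$seed,
                      stats::rnorm(length(spec$freqs), 0, spec$noise_sd))
  obs <- spectral_observation(spec$freqs, base$log_psd + noise,
                              source = "synthetic", normalised = FALSE)
  obs$meta$spec <- spec
  obs
}

#' Generate a matched condition pair
#'
#' Condition A is drawn at `theta_star`; condition B at `theta_star` with the
#' `delta_map` shifts applied in log space. Noise realisations are
#' independent, with seeds derived from the spec's seed. An empty/NULL
#' `delta_map` yields a null (placebo-like) pair from the same parameters.
#'
#' @inheritParams generate_spectrum
#' @param bounds optional [param_bounds()]; shifted parameters must stay
#'   inside.
#' @return List with elements `a` and `b` ([spectral_observation()]s).
#' @export
generate_condition_pair <- function(spec, bounds = NULL,
                                    innovations = "white") {
  spec_a <- spec
  theta_b <- spec$theta_star
  if (!is.null(spec$delta_map) && length(spec$delta_map)) {
    theta_b$theta_log[names(spec$delta_map)] <-
      theta_b$theta_log[names(spec$delta_map)] + unlist(spec$delta_map)
  }
  if (!is.null(bounds)) {
    out <- theta_b$theta_log < bounds$lower | theta_b$theta_log > bounds$upper
    if (any(out)) stop("shifted parameter(s) exit the bounds: ",
                       paste(theta_b$names[out], collapse = ", "))
  }
  spec_b <- spec
  spec_b$theta_star <- theta_b
  spec_a$seed <- spec$seed
  spec_b$seed <- spec$seed + 911L
  list(a = generate_spectrum(spec_a, innovations),
       b = generate_spectrum(spec_b, innovations))
}

#' Stochastic time-domain simulation of the neural mass model
#'
#' Integrates the delayed stochastic model driven by white noise through the
#' stellate population. Each second-order synaptic channel is advanced by its
#' exact zero-order-hold propagator (the channel dynamics are linear given
#' the drive), with the sigmoid couplings evaluated on delayed potentials;
#' this avoids the numerical damping a first-order Euler scheme introduces at
#' the oscillation frequencies of interest.
#'
#' @param params an [nmm_params()].
#' @param duration length of the simulation (seconds).
#' @param dt time step (seconds, at most 1e-3).
#' @param seed integer seed.
#' @param burn_in discarded initial stretch (seconds).
#' @return Numeric vector: the pyramidal membrane potential sampled at
#'   `1/dt` Hz, with attribute `fs`.
#' @export
simulate_timeseries <- function(params, duration, dt = 1e-3, seed = 1,
                                burn_in = 2) {
  stopifnot(dt <= 1e-3, duration > 0)
  ph <- to_physical(params)
  n <- round((duration + burn_in) / dt)
  n_keep <- round(duration / dt)
  tau <- ifelse(.CHAN_EXC, ph[["Te"]], ph[["Ti"]])
  H <- ifelse(.CHAN_EXC, ph[["He"]], ph[["Hi"]])
  G <- unname(ph[.CHAN_GAIN])
  R1 <- ph[["R1"]]; R2 <- ph[["R2"]]
  s0 <- stats::plogis(-R1 * R2)
  L <- max(1L, round(ph[["Di"]] / dt))
  # exact propagator of the critically damped kernel (eigenvalue -1/tau,
  # doubled): expm(A dt) and the zero-order-hold input integral
  a <- 1 / tau; ed <- exp(-a * dt)
  E11 <- ed * (1 + a * dt); E12 <- ed * dt
  E21 <- -ed * a^2 * dt;    E22 <- ed * (1 - a * dt)
  # F = A^-1 (expm(A dt) - I) B with B = (0, H/tau)
  F1 <- (H / a) * (1 - ed * (1 + a * dt))
  F2 <- H * a * dt * ed
  v <- numeric(5); dv <- numeric(5)
  buf <- matrix(0, L, 3L)   # delayed potentials: v_s, v_i, v_p
  u <- .with_seed(seed, stats::rnorm(n, 0, 1 / sqrt(dt))) * ph[["input_gain"]]
  out <- numeric(n)
  ptr <- 1L
  for (k in seq_len(n)) {
    sd_ <- stats::plogis(R1 * (buf[ptr, ] - R2)) - s0
    drive <- c(G[1L] * sd_[3L] + u[k], G[2L] * sd_[3L], G[3L] * sd_[2L],
               G[4L] * sd_[1L], G[5L] * sd_[2L])
    vn <- E11 * v + E12 * dv + F1 * drive
    dv <- E21 * v + E22 * dv + F2 * drive
    v <- vn
    vp <- v[4L] - v[5L]
    buf[ptr, ] <- c(v[1L], v[2L] - v[3L], vp)
    ptr <- ptr %% L + 1L
    if (!is.finite(vp) || abs(vp) > 1e6)
      stop("numerical blow-up: unstable regime at t = ", round(k * dt, 3), " s")
    out[k] <- vp
  }
  structure(out[(n - n_keep + 1L):n], fs = 1 / dt)
}

#' Welch power spectral density estimate
#'
#' Hamming-windowed, mean-removed, 50%-overlapping segment average of
#' periodograms (one-sided, density scaling).
#'
#' @param x numeric time series.
#' @param fs sampling rate (Hz).
#' @param nseg segment length (samples).
#' @param overlap fractional overlap in `[0, 1)`.
#' @return List with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, nseg = 512, overlap = 0.5) {
  if (length(x) < nseg) stop("series shorter than one segment (", nseg, " samples)")
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nseg - 1)) / (nseg - 1))
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  nb <- nseg %/% 2L + 1L
  acc <- numeric(nb)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[1:nb]
    acc <- acc + Mod(X)^2
  }
  psd <- acc / length(starts) / (fs * sum(w^2))
  psd[2:(nb - 1L)] <- 2 * psd[2:(nb - 1L)]   # one-sided
  list(freq = (0:(nb - 1L)) * fs / nseg, psd = psd)
}

#' Reduce epochs to an averaged unit-area log PSD
#'
#' Per-epoch PSD estimation (plain rectangular-window FFT periodogram on a
#' fixed-resolution grid, or Welch's method), unit-area normalisation of each
#' epoch's PSD, arithmetic averaging across epochs, re-normalisation, and a
#' final log transform -- the order used for grand-average spectra.
#'
#' @param epochs list of numeric vectors (or a single vector), equal lengths.
#' @param fs sampling rate (Hz).
#' @param mode `"fft"` (periodogram at the epoch's native resolution) or
#'   `"welch"`.
#' @param band retained frequency band `c(low, high)` in Hz.
#' @param nseg,overlap Welch settings (welch mode).
#' @return A [spectral_observation()] with `meta$source = "empirical"`,
#'   unit-area normalised.
#' @export
preprocess_epochs <- function(epochs, fs, mode = c("fft", "welch"),
                              band = c(2, 45), nseg = 512, overlap = 0.5) {
  mode <- match.arg(mode)
  if (is.numeric(epochs)) epochs <- list(epochs)
  if (!length(epochs)) stop("at least one epoch is required")
  len <- unique(vapply(epochs, length, 0L))
  if (length(len) != 1L) stop("epochs must have equal length")
  one <- function(x) {
    if (mode == "fft") {
      nb <- length(x) %/% 2L + 1L
      X <- stats::fft(x - mean(x))[1:nb]
      psd <- Mod(X)^2 / (fs * length(x))
      psd[2:(nb - 1L)] <- 2 * psd[2:(nb - 1L)]
      list(freq = (0:(nb - 1L)) * fs / length(x), psd = psd)
    } else {
      if (length(x) < nseg)
        stop("epoch shorter than the Welch window (", nseg, " samples)")
      welch_psd(x, fs, nseg, overlap)
    }
  }
  first <- one(epochs[[1L]])
  keep <- first$freq >= band[1L] & first$freq <= band[2L]
  freqs <- first$freq[keep]
  acc <- matrix(0, length(epochs), sum(keep))
  acc[1L, ] <- .unit_area(first$psd[keep], freqs)
  if (length(epochs) > 1L)
    for (i in 2L:length(epochs))
      acc[i, ] <- .unit_area(one(epochs[[i]])$psd[keep], freqs)
  avg <- .unit_area(colMeans(acc), freqs)
  spectral_observation(freqs, log(avg), source = "empirical",
                       normalised = TRUE, band = band)
}
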