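# Named study presets bundling the frequency grid, preprocessing mode,
# objective bands and mixture size used by the two reference analyses.

#' Study presets
#'
#' `"study1"`: resting EEG; 2-45 Hz grid at 0.5 Hz (per-epoch FFT
#' periodograms on 2-s epochs), objective bands `[6.5, 12.5]` and
#' `[11.5, 30]` Hz (alpha/beta), `m = 500`. `"study2"`: task MEG with gamma
#' activity; 2-85 Hz Welch grid (512-point Hamming window, 50% overlap),
#' bands `[10.7, 65.8]` and `[35.6, 85]` Hz, `m = 400`.
#'
#' @param name `"study1"` or `"study2"`.
#' @return List with `freqs`, `bands` (an [objective_bands()]), `mode`,
#'   `welch` settings, `m`, `n`, and the whole-band RMSE `span`.
#' @export
study_preset <- function(name = c("study1", "study2")) {
  name <- match.arg(name)
  if (name == "study1") {
    bands <- objective_bands(c(6.5, 12.5), c(11.5, 30))
    list(name = name, freqs = seq(2, 45, 0.5), mode = "fft",
         welch = NULL, bands = bands, span = c(6.5, 30), n = 1000, m = 500)
  } else {
    bands <- objective_bands(c(10.7, 65.8), c(35.6, 85))
    list(name = name, freqs = NULL, mode = "welch",
         welch = list(nseg = 512, overlap = 0.5), bands = bands,
         span = c(10.7, 85), n = 1000, m = 400)
  }
}

#' Preset scan range of the gain-profile diagnostic
#'
#' The log-space range `[-1, 0.85]` over which the prior mean of the
#' pyramidal-to-stellate gain `G1` is scanned in the free-energy profile,
#' containing the standard prior `log(G1) = 0`.
#' @param n number of grid points.
#' @return Numeric grid.
#' @export
g1_profile_grid <- function(n = 38) seq(-1, 0.85, length.out = n)
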