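# Diagnostic surfaces: free-energy profiles along one prior-mean axis, and
# RMSE maps over two-parameter grids with local-minimum detection.

#' Free-energy profile along one prior-mean axis
#'
#' For each grid value, the prior mean of the chosen parameter is moved there
#' (all other parameters at the base prior), a variational inversion is run,
#' and the resulting free energy and posterior mean are recorded. Free
#' energies are min-max scaled to `[0, 1]` (maximum pinned to 1); raw values
#' are retained.
#'
#' @param param parameter name (must be free).
#' @param grid vector of prior-mean values (log scale).
#' @param data a [spectral_observation()].
#' @param base_prior base [gaussian_belief()] prior (defaults to the standard
#'   priors).
#' @param params an [nmm_params()] template.
#' @param vl a [vl_config()].
#' @return A list of class `profile_result`: `grid`, `free_energy_raw`,
#'   `free_energy_scaled`, `posterior_means` (per-point inversion failures
#'   are recorded as `NA`, not fatal).
#' @export
free_energy_profile <- function(param, grid, data,
                                base_prior = standard_priors(),
                                params = nmm_params(), vl = vl_config()) {
  if (!param %in% params$names || !params$free_mask[[param]])
    stop("param must name a free parameter")
  f_raw <- post <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    pr <- base_prior
    pr$mean[[param]] <- grid[i]
    fit <- tryCatch(vl_invert(pr, data, vl, params = params),
                    error = function(e) NULL)
    if (is.null(fit)) next
    f_raw[i] <- fit$posterior$free_energy
    post[i] <- fit$posterior$mean[[param]]
  }
  ok <- is.finite(f_raw)
  scaled <- rep(NA_real_, length(grid))
  if (sum(ok) == 1L) scaled[ok] <- 1
  else if (sum(ok) > 1L) {
    rng <- range(f_raw[ok])
    scaled[ok] <- if (diff(rng) == 0) 1 else (f_raw[ok] - rng[1L]) / diff(rng)
  }
  structure(list(grid = grid, free_energy_raw = f_raw,
                 free_energy_scaled = scaled, posterior_means = post),
            class = "profile_result")
}

#' RMSE landscape over a two-parameter grid
#'
#' The reference spectrum is the model's own (noise-free) log PSD at
#' `theta_ref`; each cell holds the band-restricted RMSE between that
#' reference and the model with the two scanned parameters set to the cell's
#' coordinates (all others at `theta_ref`). Unstable cells are marked with
#' the penalty value and excluded from minima.
#'
#' @param p1,p2 names of the scanned parameters.
#' @param grid1,grid2 log-scale grid vectors.
#' @param theta_ref reference [nmm_params()].
#' @param band RMSE band `c(low, high)` in Hz.
#' @param freqs frequency grid of the reference spectrum.
#' @param innovations innovation spectrum.
#' @return A list of class `landscape_result`: `axis1`, `axis2`, `rmse`
#'   matrix (`length(grid1) x length(grid2)`), and `minima` (matrix of
#'   `(i, j)` strict 8-neighbourhood local minima, sorted by value).
#' @export
rmse_landscape <- function(p1, p2, grid1, grid2, theta_ref, band,
                           freqs = seq(2, 45, 0.5), innovations = "white") {
  ref <- observe_log_psd(theta_ref, freqs, innovations)
  if (!isTRUE(attr(ref, "stable"))) stop("reference spectrum is unstable")
  idx <- .band_idx(freqs, band)
  cells <- expand.grid(i = seq_along(grid1), j = seq_along(grid2))
  th <- matrix(theta_ref$theta_log, nrow(cells), length(theta_ref$names),
               byrow = TRUE)
  colnames(th) <- theta_ref$names
  th[, p1] <- grid1[cells$i]
  th[, p2] <- grid2[cells$j]
  out <- .batch_log_psd(th, theta_ref, freqs, innovations)
  r <- sweep(out$log_psd[, idx, drop = FALSE], 2L, ref$log_psd[idx])
  val <- sqrt(rowMeans(r^2))
  val[!out$stable] <- .PENALTY
  rmse <- matrix(val, length(grid1), length(grid2))
  structure(list(axis1 = grid1, axis2 = grid2, rmse = rmse,
                 minima = find_local_minima(rmse, exclusion = .PENALTY)),
            class = "landscape_result")
}

#' Strict local minima of a matrix
#'
#' Cells strictly smaller than all existing 8-neighbours; boundary cells are
#' compared over their existing neighbours only. Cells at or above the
#' exclusion value never qualify and are ignored as neighbours.
#'
#' @param mat numeric matrix.
#' @param exclusion penalty value marking invalid cells.
#' @return Integer matrix with columns `i`, `j`, `value`, rows sorted by
#'   value ascending; zero rows when no strict minimum exists.
#' @export
find_local_minima <- function(mat, exclusion = 1e6) {
  nr <- nrow(mat); nc <- ncol(mat)
  res <- NULL
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- mat[i, j]
    if (!is.finite(v) || v >= exclusion) next
    nb <- expand.grid(di = -1:1, dj = -1:1)
    nb <- nb[!(nb$di == 0 & nb$dj == 0), ]
    ii <- i + nb$di; jj <- j + nb$dj
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    nv <- mat[cbind(ii[ok], jj[ok])]
    nv <- nv[is.finite(nv) & nv < exclusion]
    if (length(nv) && all(v < nv)) res <- rbind(res, c(i, j, v))
  }
  if (is.null(res)) return(matrix(numeric(0), 0, 3,
                                  dimnames = list(NULL, c("i", "j", "value"))))
  colnames(res) <- c("i", "j", "value")
  res[order(res[, "value"]), , drop = FALSE]
}
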