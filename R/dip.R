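# DIP-DCM orchestration: rank GA estimates by model-dynamics RMSE, build
# unit-variance dynamics-informed priors, run one variational inversion per
# prior, and average the posteriors into an equal-weight Gaussian mixture.

#' Rank GA estimates and select the top m
#'
#' Sorts ascending by whole-band RMSE (ties broken by `J1^2 + J2^2`, then row
#' order) and returns the first `m` rows.
#'
#' @param estimates a `ga_estimates` data.frame from [ga_realisations()].
#' @param m number of estimates to keep.
#' @return The top-`m` rows of `estimates`.
#' @export
rank_and_select <- function(estimates, m) {
  if (!nrow(estimates)) stop("empty estimate table")
  if (m > nrow(estimates))
    stop("m = ", m, " exceeds the ", nrow(estimates),
         " available estimates; lower m or raise the number of realisations")
  o <- order(estimates$rmse, estimates$J1^2 + estimates$J2^2,
             seq_len(nrow(estimates)))
  estimates[o[seq_len(m)], , drop = FALSE]
}

#' Build dynamics-informed priors
#'
#' Each selected estimate becomes the mean of a Gaussian prior whose free
#' parameters all take unit variance on the log scale -- a deliberately
#' uninformative value, larger than every "standard" prior variance, treating
#' all estimates as equally plausible. Frozen parameters keep the standard
#' prior variance.
#'
#' @param top_m data.frame of selected estimates (rows from
#'   [rank_and_select()]) or a matrix of log-parameter vectors.
#' @param params an [nmm_params()] template supplying the free mask.
#' @param standard the standard prior supplying frozen-parameter variances.
#' @return List of `gaussian_belief` priors.
#' @export
dip_priors <- function(top_m, params = nmm_params(),
                       standard = standard_priors()) {
  th <- as.matrix(as.data.frame(top_m)[params$names])
  v <- standard$var[params$names]
  v[params$free_mask] <- 1
  lapply(seq_len(nrow(th)), function(i)
    gaussian_belief(stats::setNames(as.numeric(th[i, ]), params$names), v,
                    kind = "prior"))
}

#' Equal-weight Gaussian posterior mixture
#'
#' @param posteriors list of aligned `gaussian_belief` posteriors (diagonal
#'   covariance).
#' @return An object of class `posterior_mixture` with equal weights `1/m`.
#' @export
average_posteriors <- function(posteriors) {
  if (!length(posteriors)) stop("at least one posterior is required")
  nm <- names(posteriors[[1L]]$mean)
  for (p in posteriors)
    if (!identical(names(p$mean), nm)) stop("posteriors have misaligned parameter names")
  structure(list(names = nm,
                 components = posteriors,
                 weights = rep(1 / length(posteriors), length(posteriors)),
                 free_energies = vapply(posteriors, function(p)
                   if (is.null(p$free_energy)) NA_real_ else p$free_energy, 0)),
            class = "posterior_mixture")
}

#' @export
print.posterior_mixture <- function(x, ...) {
  cat("<posterior_mixture>", length(x$components), "equal-weight components,",
      length(x$names), "parameters\n")
  invisible(x)
}

# component means / vars for one parameter as vectors
.mix_marg <- function(mix, param) {
  if (!param %in% mix$names) stop("unknown parameter: ", param)
  list(mean = vapply(mix$components, function(p) p$mean[[param]], 0),
       var = vapply(mix$components, function(p) p$var[[param]], 0))
}

#' Mixture marginal density, CDF, and quantiles
#'
#' @param mix a [average_posteriors()] mixture.
#' @param param parameter name.
#' @param x evaluation points (log scale).
#' @return `mixture_density`/`mixture_cdf`: numeric vector;
#'   `mixture_quantile`: quantiles at `probs`.
#' @export
mixture_density <- function(mix, param, x) {
  m <- .mix_marg(mix, param)
  rowMeans(matrix(vapply(seq_along(m$mean), function(k)
    stats::dnorm(x, m$mean[k], sqrt(m$var[k])), numeric(length(x))),
    nrow = length(x)))
}

#' @rdname mixture_density
#' @export
mixture_cdf <- function(mix, param, x) {
  m <- .mix_marg(mix, param)
  rowMeans(matrix(vapply(seq_along(m$mean), function(k)
    stats::pnorm(x, m$mean[k], sqrt(m$var[k])), numeric(length(x))),
    nrow = length(x)))
}

#' @rdname mixture_density
#' @param probs probabilities.
#' @export
mixture_quantile <- function(mix, param, probs) {
  m <- .mix_marg(mix, param)
  lo <- min(m$mean - 8 * sqrt(m$var)); hi <- max(m$mean + 8 * sqrt(m$var))
  vapply(probs, function(p)
    stats::uniroot(function(x) mixture_cdf(mix, param, x) - p, c(lo, hi),
                   tol = 1e-9)$root, 0)
}

#' Modes of a mixture marginal
#'
#' Grid-based peak finding on the marginal density: strict interior local
#' maxima exceeding `min_height` times the global maximum.
#'
#' @inheritParams mixture_density
#' @param n grid resolution.
#' @param min_height discard peaks below this fraction of the highest peak.
#' @return Numeric vector of mode locations (log scale).
#' @export
mixture_modes <- function(mix, param, n = 512, min_height = 0.05) {
  m <- .mix_marg(mix, param)
  lo <- min(m$mean - 4 * sqrt(m$var)); hi <- max(m$mean + 4 * sqrt(m$var))
  x <- seq(lo, hi, length.out = n)
  d <- mixture_density(mix, param, x)
  # strict on the left, non-strict on the right, so a peak landing exactly
  # between two grid points (equal samples) is still reported once
  i <- which(d > c(-Inf, d[-n]) & d >= c(d[-1L], -Inf) & d >= min_height * max(d))
  x[i]
}

#' Sample a mixture marginal
#'
#' Draws a component uniformly (equal weights) and samples its Gaussian
#' marginal; reproducible under the seed.
#'
#' @inheritParams mixture_density
#' @param n_draws number of draws.
#' @param seed integer seed.
#' @return Numeric vector of log-scale draws.
#' @export
mixture_sample <- function(mix, param, n_draws, seed = 1) {
  m <- .mix_marg(mix, param)
  .with_seed(seed, {
    k <- sample.int(length(m$mean), n_draws, replace = TRUE)
    stats::rnorm(n_draws, m$mean[k], sqrt(m$var[k]))
  })
}

#' Run the full DIP-DCM pipeline
#'
#' Two steps: (1) `n` GA realisations explore the bounded parameter space
#' globally; (2) the top `m` estimates (ranked by whole-band RMSE) become
#' unit-variance Gaussian prior means for `m` variational-Laplace inversions,
#' whose posteriors are averaged into an equal-weight mixture. Failed or
#' unconverged inversions are dropped with a warning; if more than 10% fail
#' the run errors out.
#'
#' @inheritParams ga_realisations
#' @param m number of dynamics-informed priors / inversions.
#' @param vl a [vl_config()] for the inversions.
#' @param estimates optional precomputed `ga_estimates` table (skips step 1).
#' @return A list of class `dip_result`: `mixture` (a `posterior_mixture`),
#'   `report` (data.frame with per-inversion GA seed RMSE, posterior RMSE,
#'   free energy, convergence), and `estimates` (the full GA table).
#' @export
run_dip <- function(data, bounds, bands, params = nmm_params(),
                    n = 1000, m = 500, control = ga_control(n_generations = 150),
                    vl = vl_config(), seed0 = 1, threads = 1,
                    innovations = "white", estimates = NULL) {
  if (is.null(estimates))
    estimates <- ga_realisations(data, bounds, bands, control, n, seed0,
                                 threads, params, innovations)
  top <- rank_and_select(estimates, m)
  priors <- dip_priors(top, params)
  span <- c(min(bands$omega1[1], bands$omega2[1]),
            max(bands$omega1[2], bands$omega2[2]))
  posts <- vector("list", length(priors))
  rows <- vector("list", length(priors))
  for (i in seq_along(priors)) {
    fit <- tryCatch(vl_invert(priors[[i]], data, vl, params = params),
                    error = function(e) NULL)
    if (is.null(fit)) {
      rows[[i]] <- data.frame(ga_seed = top$seed[i], ga_rmse = top$rmse[i],
                              vl_rmse = NA_real_, free_energy = NA_real_,
                              converged = FALSE, kept = FALSE)
      next
    }
    vr <- band_rmse(fit$posterior$mean, data, span, params, innovations)
    posts[[i]] <- fit$posterior
    rows[[i]] <- data.frame(ga_seed = top$seed[i], ga_rmse = top$rmse[i],
                            vl_rmse = vr, free_energy = fit$posterior$free_energy,
                            converged = fit$converged, kept = TRUE)
  }
  report <- do.call(rbind, rows)
  kept <- !vapply(posts, is.null, TRUE)
  if (sum(!kept) > 0.1 * length(priors))
    stop(sum(!kept), " of ", length(priors), " inversions failed (> 10%)")
  if (any(!kept))
    warning(sum(!kept), " failed inversion(s) dropped from the mixture")
  structure(list(mixture = average_posteriors(posts[kept]),
                 report = report, estimates = estimates),
            class = "dip_result")
}
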