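# Variational Laplace: Gaussian posterior over log parameters by maximising
# the negative variational free energy (accuracy minus complexity) with a
# Levenberg-Marquardt-regularised Gauss-Newton update and an interleaved
# update of a single log-precision noise hyperparameter.

#' Gaussian belief over log-scale parameters
#'
#' @param mean named numeric vector (log scale).
#' @param var diagonal variances, strictly positive, same names as `mean`.
#' @param kind `"prior"` or `"posterior"`.
#' @param free_energy optional scalar (posteriors).
#' @return An object of class `gaussian_belief`.
#' @export
gaussian_belief <- function(mean, var, kind = c("prior", "posterior"),
                            free_energy = NULL) {
  kind <- match.arg(kind)
  if (is.null(names(mean))) stop("mean must be named")
  if (length(mean) != length(var)) stop("mean and var must have equal length")
  var <- stats::setNames(as.numeric(var), names(mean))
  if (any(!is.finite(mean)) || any(!is.finite(var)) || any(var <= 0))
    stop("mean must be finite and variances strictly positive and finite")
  structure(list(mean = mean, var = var, kind = kind,
                 free_energy = free_energy),
            class = "gaussian_belief")
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat("<gaussian_belief:", x$kind, ">", length(x$mean), "parameters")
  if (!is.null(x$free_energy)) cat(", F =", format(x$free_energy, digits = 6))
  cat("\n")
  print(round(rbind(mean = x$mean, sd = sqrt(x$var)), 4))
  invisible(x)
}

# KL(q || p) for diagonal Gaussians over the same names
.kl_gauss <- function(q_mean, q_var, p_mean, p_var) {
  0.5 * sum(q_var / p_var + (q_mean - p_mean)^2 / p_var - 1 + log(p_var / q_var))
}

#' Variational-Laplace settings
#'
#' @param max_iter maximum Gauss-Newton iterations.
#' @param tol free-energy change below which an accepted step counts towards
#'   convergence.
#' @param tol_hits consecutive small accepted steps required to stop.
#' @param fd_step central-difference step (log scale) for sensitivities.
#' @param lambda0 initial Levenberg-Marquardt regularisation.
#' @param lambda_factor factor applied on rejection (multiplied) and
#'   acceptance (divided).
#' @param noise_prior_mean,noise_prior_var Gaussian prior on the shared
#'   log-precision of the residuals.
#' @param update_noise update the noise hyperparameter (disable for fixed,
#'   known precision).
#' @param noise_log_precision initial (or fixed) log precision.
#' @param innovations innovation spectrum for the model forward path.
#' @return A list of class `vl_config`.
#' @export
vl_config <- function(max_iter = 64, tol = 1e-2, tol_hits = 3, fd_step = 1e-4,
                      lambda0 = 1e-4, lambda_factor = 10,
                      noise_prior_mean = 0, noise_prior_var = 16,
                      update_noise = TRUE, noise_log_precision = 0,
                      innovations = "white") {
  structure(as.list(environment()), class = "vl_config")
}

# default forward model: unit-area model log PSD on the data grid, as a
# function of the FREE log parameters (frozen entries held at `params`)
.nmm_forward <- function(params, freqs, innovations = "white") {
  free <- params$free_mask
  theta0 <- params$theta_log
  f <- function(theta_free) {
    th <- theta0; th[free] <- theta_free
    out <- .batch_log_psd(matrix(th, nrow = 1L), params, freqs, innovations)
    if (!out$stable[1L]) stop("unstable parameter set in forward model")
    drop(out$log_psd)
  }
  attr(f, "batch") <- function(theta_free_mat) {
    n <- nrow(theta_free_mat)
    th <- matrix(theta0, n, length(theta0), byrow = TRUE)
    th[, free] <- theta_free_mat
    out <- .batch_log_psd(th, params, freqs, innovations)
    if (!all(out$stable)) stop("unstable parameter set in forward model")
    out$log_psd
  }
  f
}

# central-difference Jacobian of forward at mu (free dims), using the batch
# path when available
.fd_jacobian <- function(forward, mu, step) {
  p <- length(mu)
  batch <- attr(forward, "batch")
  if (!is.null(batch)) {
    pts <- matrix(mu, 2L * p, p, byrow = TRUE)
    for (j in seq_len(p)) {
      pts[2L * j - 1L, j] <- mu[j] + step
      pts[2L * j, j] <- mu[j] - step
    }
    val <- batch(pts)
    J <- t(vapply(seq_len(p), function(j)
      (val[2L * j - 1L, ] - val[2L * j, ]) / (2 * step), numeric(ncol(val))))
    return(t(J))
  }
  g0 <- forward(mu)
  J <- matrix(0, length(g0), p)
  for (j in seq_len(p)) {
    up <- mu; up[j] <- up[j] + step
    dn <- mu; dn[j] <- dn[j] - step
    J[, j] <- (forward(up) - forward(dn)) / (2 * step)
  }
  J
}

# Laplace free energy given residuals e, Jacobian J, posterior covariance
# Sigma (free dims), log precision h, and the KL complexity terms
.laplace_F <- function(e, J, Sigma, h, kl_theta, kl_h) {
  n <- length(e)
  acc <- -0.5 * exp(h) * sum(e^2) + 0.5 * n * (h - log(2 * pi)) -
    0.5 * exp(h) * sum(diag(Sigma %*% crossprod(J)))
  acc - kl_theta - kl_h
}

#' Negative variational free energy of a Gaussian belief
#'
#' Accuracy (expected Gaussian log-likelihood of the log-PSD residuals at the
#' belief mean, with the Laplace curvature correction) minus complexity (the
#' closed-form Gaussian KL divergence from the belief to the prior).
#'
#' @param q,prior aligned [gaussian_belief()] objects.
#' @param data a [spectral_observation()].
#' @param noise_log_precision scalar log precision of the residuals.
#' @param forward forward model mapping the belief mean to a predicted
#'   log-PSD vector; defaults to the neural mass observation function when
#'   `params` is given.
#' @param params optional [nmm_params()] template for the default forward.
#' @param fd_step sensitivity step for the curvature term.
#' @return Scalar free energy (finite), or an error if the forward model
#'   fails at `q$mean`.
#' @export
free_energy <- function(q, prior, data, noise_log_precision = 0,
                        forward = NULL, params = NULL, fd_step = 1e-4) {
  stopifnot(identical(names(q$mean), names(prior$mean)))
  if (is.null(forward)) {
    if (is.null(params)) stop("supply either `forward` or `params`")
    params <- set_theta(params, q$mean[params$names])
    forward <- .nmm_forward(params, data$freqs)
    mu <- q$mean[params$names][params$free_mask]
    qv <- q$var[params$names][params$free_mask]
  } else {
    mu <- q$mean; qv <- q$var
  }
  g <- forward(if (is.null(params)) q$mean else mu)
  e <- data$log_psd - g
  J <- .fd_jacobian(forward, if (is.null(params)) q$mean else mu, fd_step)
  kl <- .kl_gauss(q$mean, q$var, prior$mean, prior$var)
  .laplace_F(e, J, diag(qv, length(qv)), noise_log_precision, kl, 0)
}

#' Variational-Laplace inversion
#'
#' Maximises the negative variational free energy with respect to the free
#' parameter means (Levenberg-Marquardt-regularised Gauss-Newton on
#' finite-difference sensitivities of the forward model), taking the Laplace
#' covariance as the inverse curvature, and interleaving Newton updates of a
#' single Gaussian-distributed log-precision noise hyperparameter. Free
#' energy over accepted iterations is non-decreasing. Deterministic.
#'
#' @param prior a [gaussian_belief()] prior.
#' @param data a [spectral_observation()] on a fixed grid.
#' @param config a [vl_config()].
#' @param forward optional forward model over the free means; must accept the
#'   free-parameter vector and return a predicted vector matching
#'   `data$log_psd`. Defaults to the neural mass observation function.
#' @param params optional [nmm_params()] template (names, scales, free mask)
#'   for the default forward model.
#' @return A list with `posterior` (a `gaussian_belief` with `free_energy`,
#'   full covariance in attribute `"cov"`), and `trace` (data.frame of
#'   iterations with `free_energy`, `accepted`, `lambda`), plus `converged`
#'   and `n_iter`.
#' @export
vl_invert <- function(prior, data, config = vl_config(), forward = NULL,
                      params = NULL) {
  free <- rep(TRUE, length(prior$mean))
  nm <- names(prior$mean)
  if (is.null(forward)) {
    if (is.null(params)) stop("supply either `forward` or `params`")
    stopifnot(identical(nm, params$names))
    params <- set_theta(params, prior$mean)
    forward <- .nmm_forward(params, data$freqs, config$innovations)
    free <- params$free_mask
  }
  y <- data$log_psd
  mu_full <- prior$mean
  mu <- mu_full[free]
  p0_var <- prior$var[free]
  P0 <- diag(1 / p0_var, length(mu))
  h <- config$noise_log_precision
  h0 <- config$noise_prior_mean; vh <- config$noise_prior_var
  lam <- config$lambda0
  n_fail <- 0L
  eval_state <- function(mu, h) {
    g <- tryCatch(forward(mu), error = function(e) NULL)
    if (is.null(g) || any(!is.finite(g))) return(NULL)
    e <- y - g
    J <- tryCatch(.fd_jacobian(forward, mu, config$fd_step),
                  error = function(err) NULL)
    if (is.null(J) || any(!is.finite(J))) return(NULL)
    H <- exp(h) * crossprod(J) + P0
    Sigma <- tryCatch(solve(H), error = function(err) NULL)
    if (is.null(Sigma)) return(NULL)
    kl <- .kl_gauss(mu, diag(Sigma), prior$mean[free], p0_var)
    kl_h <- if (config$update_noise) (h - h0)^2 / (2 * vh) else 0
    Fv <- .laplace_F(e, J, Sigma, h, kl, kl_h)
    list(g = g, e = e, J = J, H = H, Sigma = Sigma, F = Fv)
  }
  st <- eval_state(mu, h)
  if (is.null(st)) stop("inversion failure: forward model failed at the prior mean")
  trace <- data.frame(iter = 0L, free_energy = st$F, accepted = TRUE, lambda = lam)
  hits <- 0L; converged <- FALSE; it <- 0L
  while (it < config$max_iter) {
    it <- it + 1L
    grad <- exp(h) * crossprod(st$J, st$e) - P0 %*% (mu - prior$mean[free])
    H_lm <- st$H + lam * diag(diag(st$H), nrow(st$H))
    step <- tryCatch(drop(solve(H_lm, grad)), error = function(e) NULL)
    if (is.null(step)) { lam <- lam * config$lambda_factor; next }
    cand <- eval_state(mu + step, h)
    accepted <- !is.null(cand) && is.finite(cand$F) && cand$F >= st$F
    if (accepted) {
      dF <- cand$F - st$F
      mu <- mu + step
      st <- cand
      lam <- max(lam / config$lambda_factor, 1e-12)
      if (config$update_noise) {
        # stationarity of F in h: exp(h) ss / 2 = n/2 - (h - h0)/vh,
        # solved by safeguarded root finding (monotone decreasing gradient)
        ss <- sum(st$e^2) + sum(diag(st$Sigma %*% crossprod(st$J)))
        gh <- function(hh) -0.5 * exp(hh) * ss + 0.5 * length(y) - (hh - h0) / vh
        br <- c(h0 - 45, h0 + 45)
        if (gh(br[1L]) > 0 && gh(br[2L]) < 0) {
          h_new <- stats::uniroot(gh, br, tol = 1e-8)$root
          st2 <- eval_state(mu, h_new)
          if (!is.null(st2) && is.finite(st2$F) && st2$F >= st$F) {
            h <- h_new
            st <- st2
          }
        }
      }
      hits <- if (abs(dF) < config$tol) hits + 1L else 0L
    } else {
      if (is.null(cand)) {
        n_fail <- n_fail + 1L
        if (n_fail > 8L && !any(trace$accepted[-1L]))
          stop("inversion failure: repeated forward failures from this prior")
      }
      lam <- lam * config$lambda_factor
    }
    trace <- rbind(trace, data.frame(iter = it, free_energy = st$F,
                                     accepted = accepted, lambda = lam))
    if (hits >= config$tol_hits) { converged <- TRUE; break }
    if (lam > 1e9) { converged <- TRUE; break }  # no improving step remains
  }
  post_mean <- mu_full
  post_mean[free] <- mu
  post_var <- prior$var
  post_var[free] <- diag(st$Sigma)
  posterior <- gaussian_belief(post_mean, post_var, kind = "posterior",
                               free_energy = st$F)
  attr(posterior, "cov") <- st$Sigma
  attr(posterior, "noise_log_precision") <- h
  list(posterior = posterior, trace = trace, converged = converged, n_iter = it)
}
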