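# Three-population "LFP"-style neural mass model.
#
# Five second-order synaptic channels (state pairs (v, v')):
#   1 stellate  excitatory   drive: G1*S(v_p) + input_gain*u
#   2 inhibitory excitatory  drive: G3*S(v_p)
#   3 inhibitory inhibitory  drive: G5*S(v_i)   (recurrent self-inhibition)
#   4 pyramidal excitatory   drive: G2*S(v_s)
#   5 pyramidal inhibitory   drive: G4*S(v_i)
# Membrane potentials: v_s = v1, v_i = v2 - v3, v_p = v4 - v5 (observed).
# Excitatory channels use (He, Te); inhibitory channels use (Hi, Ti).

.N_CHANNELS <- 5L
.STATE_DIM <- 10L
# per-channel kernel class (TRUE = excitatory) and drive sources
.CHAN_EXC <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
# which potential drives each channel: 1 = v_s, 2 = v_i, 3 = v_p
.CHAN_SRC <- c(3L, 3L, 2L, 1L, 2L)
# which gain multiplies each channel's sigmoid drive
.CHAN_GAIN <- c("G1", "G3", "G5", "G2", "G4")

#' Baseline-subtracted sigmoid firing rate
#'
#' The wave-to-pulse nonlinearity converting membrane potential to a
#' normalised firing rate, shifted so that the resting potential `v = 0` maps
#' to zero rate: `S(v) = 1/(1 + exp(-R1 (v - R2))) - 1/(1 + exp(R1 R2))`.
#'
#' @param v membrane potential (mV); vectorised.
#' @param R1 sigmoid slope (1/mV), physical value, positive.
#' @param R2 firing threshold (mV), physical value, positive.
#' @return Normalised firing rate in `(-baseline, 1 - baseline)`.
#' @export
sigmoid_rate <- function(v, R1, R2) {
  stopifnot(R1 > 0, R2 > 0)
  stats::plogis(R1 * (v - R2)) - stats::plogis(-R1 * R2)
}

# slope of sigmoid_rate at rest (v = 0)
.sigmoid_slope0 <- function(R1, R2) {
  s0 <- stats::plogis(-R1 * R2)
  R1 * s0 * (1 - s0)
}

# membrane potentials (v_s, v_i, v_p) from a state vector
.potentials <- function(x) c(x[1L], x[3L] - x[5L], x[7L] - x[9L])

#' State derivative of the neural mass model
#'
#' Each synaptic channel obeys the critically damped second-order kernel
#' `v'' = (H/tau) drive - (2/tau) v' - v/tau^2`, with drives formed from
#' sigmoid-transformed potentials weighted by the intrinsic gains and the
#' exogenous input `u` entering the stellate population. Delays are not part
#' of the ODE form; they enter the spectral observation as phase factors.
#'
#' @param x state vector of length 10 (five (v, v') pairs).
#' @param params an [nmm_params()] object.
#' @param u exogenous input (scalar).
#' @return The state derivative (length 10).
#' @export
state_derivative <- function(x, params, u = 0) {
  if (length(x) != .STATE_DIM) stop("state vector must have length ", .STATE_DIM)
  ph <- to_physical(params)
  tau <- ifelse(.CHAN_EXC, ph[["Te"]], ph[["Ti"]])
  H <- ifelse(.CHAN_EXC, ph[["He"]], ph[["Hi"]])
  pot <- .potentials(x)
  s <- sigmoid_rate(pot, ph[["R1"]], ph[["R2"]])
  drive <- unname(ph[.CHAN_GAIN]) * s[.CHAN_SRC]
  drive[1L] <- drive[1L] + ph[["input_gain"]] * u
  v <- x[seq(1L, 9L, 2L)]; dv <- x[seq(2L, 10L, 2L)]
  acc <- (H / tau) * drive - (2 / tau) * dv - v / tau^2
  out <- numeric(.STATE_DIM)
  out[seq(1L, 9L, 2L)] <- dv
  out[seq(2L, 10L, 2L)] <- acc
  out
}

#' Find a fixed point of the model
#'
#' Damped Newton iteration on the state derivative, started at the origin
#' (which is exact for `u0 = 0` under the baseline-subtracted sigmoid), with
#' seeded randomised restarts if the residual tolerance is not met.
#'
#' @param params an [nmm_params()] object.
#' @param u0 constant exogenous input.
#' @param tol residual tolerance on the derivative norm.
#' @param restarts number of randomised restarts.
#' @param seed seed for the restart perturbations.
#' @return The fixed-point state vector.
#' @export
find_fixed_point <- function(params, u0 = 0, tol = 1e-9, restarts = 5, seed = 1) {
  f <- function(x) state_derivative(x, params, u0)
  if (u0 == 0) {
    x0 <- numeric(.STATE_DIM)
    if (sqrt(sum(f(x0)^2)) < tol) return(x0)
  }
  starts <- list(numeric(.STATE_DIM))
  rng <- .with_seed(seed, lapply(seq_len(restarts), function(i) stats::rnorm(.STATE_DIM, 0, 0.5)))
  starts <- c(starts, rng)
  best <- NULL; best_res <- Inf
  for (x in starts) {
    for (it in 1:100) {
      fx <- f(x)
      res <- sqrt(sum(fx^2))
      if (res < best_res) { best <- x; best_res <- res }
      if (res < tol) return(x)
      J <- .state_jacobian(x, params)
      step <- tryCatch(solve(J, -fx), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      repeat {
        xn <- x + lam * step
        if (sqrt(sum(f(xn)^2)) < res || lam < 1e-4) break
        lam <- lam / 2
      }
      x <- x + lam * step
    }
  }
  stop("fixed-point search did not converge; residual norm = ",
       format(best_res, digits = 4))
}

# analytic Jacobian of state_derivative at x
.state_jacobian <- function(x, params) {
  ph <- to_physical(params)
  tau <- ifelse(.CHAN_EXC, ph[["Te"]], ph[["Ti"]])
  H <- ifelse(.CHAN_EXC, ph[["He"]], ph[["Hi"]])
  pot <- .potentials(x)
  R1 <- ph[["R1"]]; R2 <- ph[["R2"]]
  sig <- stats::plogis(R1 * (pot - R2))
  dS <- R1 * sig * (1 - sig)          # slope at each potential
  gain <- unname(ph[.CHAN_GAIN])
  A <- matrix(0, .STATE_DIM, .STATE_DIM)
  # derivative of each potential wrt state entries: list of (index, sign)
  pot_d <- list(cbind(1L, 1), cbind(c(3L, 5L), c(1, -1)), cbind(c(7L, 9L), c(1, -1)))
  for (k in seq_len(.N_CHANNELS)) {
    vi <- 2L * k - 1L; di <- 2L * k
    A[vi, di] <- 1
    A[di, vi] <- A[di, vi] - 1 / tau[k]^2
    A[di, di] <- -2 / tau[k]
    pd <- pot_d[[.CHAN_SRC[k]]]
    coef <- (H[k] / tau[k]) * gain[k] * dS[.CHAN_SRC[k]]
    A[di, pd[, 1L]] <- A[di, pd[, 1L]] + coef * pd[, 2L]
  }
  A
}

#' Linearise the model around a fixed point
#'
#' Returns the state Jacobian `A` (analytic, cross-checkable against finite
#' differences), the input column `B`, the observation row `C` reading the
#' pyramidal membrane potential scaled by `obs_gain`, and the sigmoid-mediated
#' coupling part `A_delay` of the Jacobian, whose entries carry the intrinsic
#' delay as a phase factor in the frequency domain
#' (`A(omega) = (A - A_delay) + A_delay * exp(-i omega Di)`).
#'
#' @param params an [nmm_params()] object.
#' @param x_star fixed-point state vector (defaults to the origin).
#' @return A list of class `linear_system` with elements `A`, `A_delay`, `B`,
#'   `C`, `delay` (seconds).
#' @export
linearize <- function(params, x_star = numeric(.STATE_DIM)) {
  ph <- to_physical(params)
  A <- .state_jacobian(x_star, params)
  if (any(!is.finite(A))) stop("degenerate Jacobian at the supplied state")
  Ad <- A - .state_jacobian_kernel(params)
  B <- numeric(.STATE_DIM)
  B[2L] <- (ph[["He"]] / ph[["Te"]]) * ph[["input_gain"]]
  C <- numeric(.STATE_DIM)
  C[7L] <- ph[["obs_gain"]]; C[9L] <- -ph[["obs_gain"]]
  structure(list(A = A, A_delay = Ad, B = B, C = C, delay = ph[["Di"]]),
            class = "linear_system")
}

# kernel-only (uncoupled) part of the Jacobian: second-order synaptic
# dynamics without the sigmoid-mediated couplings
.state_jacobian_kernel <- function(params) {
  ph <- to_physical(params)
  tau <- ifelse(.CHAN_EXC, ph[["Te"]], ph[["Ti"]])
  A <- matrix(0, .STATE_DIM, .STATE_DIM)
  for (k in seq_len(.N_CHANNELS)) {
    vi <- 2L * k - 1L; di <- 2L * k
    A[vi, di] <- 1
    A[di, vi] <- -1 / tau[k]^2
    A[di, di] <- -2 / tau[k]
  }
  A
}

# seeded evaluation without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
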