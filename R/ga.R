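# Multi-objective genetic algorithm: NSGA-II (fast non-dominated sorting,
# crowding distance, binary tournament, simulated-binary crossover,
# polynomial mutation) minimising two band-limited squared-error objectives
# over closed log-scale parameter bounds.

.PENALTY <- 1e6

#' Frequency bands of the two objectives
#'
#' @param omega1,omega2 numeric intervals `c(low, high)` in Hz; band
#'   membership of grid points is closed-interval inclusion.
#' @return An object of class `objective_bands`.
#' @export
objective_bands <- function(omega1, omega2) {
  stopifnot(length(omega1) == 2, length(omega2) == 2,
            omega1[1] < omega1[2], omega2[1] < omega2[2])
  structure(list(omega1 = omega1, omega2 = omega2), class = "objective_bands")
}

# indices of grid points inside a closed band
.band_idx <- function(freqs, band) which(freqs >= band[1] & freqs <= band[2])

#' Band-limited squared-error objectives
#'
#' `J1` is the sum over grid frequencies inside the first band of the squared
#' difference between the data log PSD and the model log PSD; `J2` likewise
#' over the second band. A forward-model failure (unstable parameter set)
#' yields the penalty value `1e6` for both, keeping dominance sorting
#' well-defined.
#'
#' @param theta_log full log-parameter vector (all entries, frozen ones
#'   included), or a matrix with one row per candidate.
#' @param data a [spectral_observation()] whose grid covers both bands.
#' @param bands an [objective_bands()].
#' @param params an [nmm_params()] template (names and scales).
#' @param innovations innovation spectrum, as in [transfer_psd()].
#' @return Numeric vector `c(J1, J2)` (or a matrix with columns J1, J2).
#' @export
band_objectives <- function(theta_log, data, bands, params = nmm_params(),
                            innovations = "white") {
  i1 <- .band_idx(data$freqs, bands$omega1)
  i2 <- .band_idx(data$freqs, bands$omega2)
  if (!length(i1) || !length(i2)) stop("data grid does not cover the bands")
  single <- is.null(dim(theta_log))
  th <- if (single) matrix(theta_log, nrow = 1L) else theta_log
  out <- .batch_log_psd(th, params, data$freqs, innovations)
  r <- sweep(out$log_psd, 2L, data$log_psd)
  J <- cbind(J1 = rowSums(r[, i1, drop = FALSE]^2),
             J2 = rowSums(r[, i2, drop = FALSE]^2))
  J[!out$stable | !is.finite(J[, 1L]) | !is.finite(J[, 2L]), ] <- .PENALTY
  if (single) drop(J) else J
}

#' Latin-hypercube initial population
#'
#' Stratified sample of the free dimensions within the bounds: exactly one
#' sample per equal-width bin of `[lower, upper]` in every free dimension.
#' Frozen dimensions are fixed at the template's values.
#'
#' @param bounds a [param_bounds()].
#' @param pop_size number of individuals (at least 2).
#' @param seed integer seed; identical seeds give identical populations.
#' @param params an [nmm_params()] template supplying the free mask and
#'   frozen values.
#' @return Matrix `pop_size x n_parameters` of log-scale vectors.
#' @export
lh_population <- function(bounds, pop_size, seed, params = nmm_params()) {
  if (pop_size < 2) stop("pop_size must be at least 2")
  free <- params$free_mask
  d <- sum(free)
  u <- .with_seed(seed, lhs::randomLHS(pop_size, d))
  lo <- bounds$lower[free]; hi <- bounds$upper[free]
  pop <- matrix(params$theta_log, pop_size, length(params$names), byrow = TRUE)
  pop[, free] <- sweep(sweep(u, 2L, hi - lo, "*"), 2L, lo, "+")
  colnames(pop) <- params$names
  pop
}

# ---- NSGA-II machinery -----------------------------------------------------

# fast non-dominated sort; returns integer rank per row of J (n x 2)
.nds_rank <- function(J) {
  n <- nrow(J)
  # dominance: i dominates j iff both objectives <= and at least one <
  le1 <- outer(J[, 1L], J[, 1L], "<="); le2 <- outer(J[, 2L], J[, 2L], "<=")
  lt1 <- outer(J[, 1L], J[, 1L], "<"); lt2 <- outer(J[, 2L], J[, 2L], "<")
  dom <- le1 & le2 & (lt1 | lt2)       # dom[i, j]: i dominates j
  n_dom <- colSums(dom)
  rank <- integer(n)
  cur <- which(n_dom == 0L); r <- 1L
  while (length(cur)) {
    rank[cur] <- r
    n_dom[cur] <- -1L
    n_dom <- n_dom - colSums(dom[cur, , drop = FALSE])
    cur <- which(n_dom == 0L)
    r <- r + 1L
  }
  rank
}

# crowding distance within one front (rows of J)
.crowding <- function(J) {
  n <- nrow(J)
  if (n <= 2L) return(rep(Inf, n))
  d <- numeric(n)
  for (k in 1:2) {
    o <- order(J[, k])
    rng <- J[o[n], k] - J[o[1L], k]
    d[o[c(1L, n)]] <- Inf
    if (rng > 0)
      d[o[2:(n - 1L)]] <- d[o[2:(n - 1L)]] +
        (J[o[3:n], k] - J[o[1:(n - 2L)], k]) / rng
  }
  d
}

# binary tournament by (rank, -crowding)
.tournament <- function(rank, crowd, n_pick) {
  n <- length(rank)
  a <- sample.int(n, n_pick, replace = TRUE)
  b <- sample.int(n, n_pick, replace = TRUE)
  pick_a <- rank[a] < rank[b] | (rank[a] == rank[b] & crowd[a] > crowd[b])
  ifelse(pick_a, a, b)
}

# simulated binary crossover on free columns, probability pc per pair
.sbx <- function(parents, lo, hi, pc, eta) {
  n <- nrow(parents); d <- ncol(parents)
  child <- parents
  for (i in seq(1L, n - 1L, 2L)) {
    if (stats::runif(1) > pc) next
    u <- stats::runif(d)
    beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                   (1 / (2 * (1 - u)))^(1 / (eta + 1)))
    p1 <- parents[i, ]; p2 <- parents[i + 1L, ]
    child[i, ] <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
    child[i + 1L, ] <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
  }
  child <- pmin(pmax(child, matrix(lo, n, d, byrow = TRUE)),
                matrix(hi, n, d, byrow = TRUE))
  child
}

# polynomial mutation, probability pm per gene
.polymut <- function(pop, lo, hi, pm, eta) {
  n <- nrow(pop); d <- ncol(pop)
  lo_m <- matrix(lo, n, d, byrow = TRUE); hi_m <- matrix(hi, n, d, byrow = TRUE)
  rng <- hi_m - lo_m
  hit <- matrix(stats::runif(n * d) < pm, n, d)
  u <- matrix(stats::runif(n * d), n, d)
  delta <- ifelse(u < 0.5, (2 * u)^(1 / (eta + 1)) - 1,
                  1 - (2 * (1 - u))^(1 / (eta + 1)))
  out <- pop + hit * delta * rng
  pmin(pmax(out, lo_m), hi_m)
}

#' NSGA-II control settings
#'
#' Defaults follow common toolbox practice: population 60, simulated-binary
#' crossover (probability 0.9, distribution index 15), polynomial mutation
#' (probability `1/d` over the free dimensions, index 20), 500 generations by
#' default, reducible to 150 with little loss of fit quality.
#'
#' @param pop_size population size.
#' @param n_generations number of generations.
#' @param pc,eta_c crossover probability and distribution index.
#' @param pm,eta_m mutation probability (default `1/d`) and index.
#' @return A list of class `ga_control`.
#' @export
ga_control <- function(pop_size = 60, n_generations = 500, pc = 0.9,
                       eta_c = 15, pm = NULL, eta_m = 20) {
  structure(as.list(environment()), class = "ga_control")
}

#' Evolve a Pareto front with NSGA-II
#'
#' Minimises the two band-limited objectives over the free parameters within
#' closed bounds, using elitist NSGA-II. Returns the final non-dominated
#' front with the selected solution (smallest Euclidean norm in objective
#' space) marked.
#'
#' @inheritParams band_objectives
#' @param bounds a [param_bounds()].
#' @param control a [ga_control()].
#' @param seed integer seed; runs are reproducible.
#' @param objective_fn optional custom objective: `function(theta_mat)`
#'   returning an `n x 2` matrix. Defaults to [band_objectives()].
#' @return A list of class `pareto_set`: `solutions` (data.frame with the
#'   full log-parameter vectors and `J1`, `J2`), `selected_index`, `seed`,
#'   `n_generations`.
#' @export
nsga2_evolve <- function(data, bounds, bands, control = ga_control(), seed = 1,
                         params = nmm_params(), innovations = "white",
                         objective_fn = NULL) {
  free <- params$free_mask
  d <- sum(free)
  pm <- if (is.null(control$pm)) 1 / d else control$pm
  lo <- bounds$lower[free]; hi <- bounds$upper[free]
  if (is.null(objective_fn))
    objective_fn <- function(th) band_objectives(th, data, bands, params, innovations)
  pop <- lh_population(bounds, control$pop_size, seed, params)
  .with_seed(seed + 104729L, {
    J <- objective_fn(pop)
    for (gen in seq_len(control$n_generations)) {
      rank <- .nds_rank(J)
      crowd <- numeric(nrow(J))
      for (r in unique(rank)) {
        i <- rank == r
        crowd[i] <- .crowding(J[i, , drop = FALSE])
      }
      idx <- .tournament(rank, crowd, control$pop_size)
      off <- pop
      off[, free] <- .polymut(
        .sbx(pop[idx, free, drop = FALSE], lo, hi, control$pc, control$eta_c),
        lo, hi, pm, control$eta_m)
      Joff <- objective_fn(off)
      # elitist environmental selection on the combined population
      Pc <- rbind(pop, off); Jc <- rbind(J, Joff)
      rk <- .nds_rank(Jc)
      keep <- integer(0)
      for (r in sort(unique(rk))) {
        i <- which(rk == r)
        if (length(keep) + length(i) <= control$pop_size) {
          keep <- c(keep, i)
        } else {
          cd <- .crowding(Jc[i, , drop = FALSE])
          keep <- c(keep, i[order(cd, decreasing = TRUE)][seq_len(control$pop_size - length(keep))])
          break
        }
      }
      pop <- Pc[keep, , drop = FALSE]
      J <- Jc[keep, , drop = FALSE]
    }
  })
  front <- .nds_rank(J) == 1L
  if (all(J[front, 1L] >= .PENALTY))
    stop("degenerate front: every individual hit the penalty value")
  sol <- data.frame(pop[front, , drop = FALSE], J1 = J[front, 1L],
                    J2 = J[front, 2L])
  structure(list(solutions = sol,
                 selected_index = select_from_front(sol[, c("J1", "J2")]),
                 seed = seed, n_generations = control$n_generations),
            class = "pareto_set")
}

#' Select one solution from a Pareto front
#'
#' The solution with the smallest Euclidean distance to the objective-space
#' origin, `sqrt(J1^2 + J2^2)`; ties break to the lowest index.
#'
#' @param front data.frame or matrix with columns `J1`, `J2`.
#' @return Integer index into the front.
#' @export
select_from_front <- function(front) {
  front <- as.matrix(front)
  if (!nrow(front)) stop("empty front")
  unname(which.min(sqrt(front[, 1L]^2 + front[, 2L]^2)))
}

#' Repeated GA realisations
#'
#' Runs [nsga2_evolve()] `n` times with seeds `seed0 ... seed0 + n - 1`, each
#' from a fresh Latin-hypercube population, and collects the selected
#' solution of every run together with its objectives and the whole-band RMSE
#' (over the union span of the two bands). A failed run is recorded as a
#' penalty row rather than aborting the batch. With `threads > 1` runs are
#' distributed over forked workers; results are identical to serial
#' execution.
#'
#' @inheritParams nsga2_evolve
#' @param n number of realisations.
#' @param seed0 first seed.
#' @param threads number of forked workers.
#' @return A data.frame (class `ga_estimates`) with one row per realisation:
#'   `seed`, the log-parameter columns, `J1`, `J2`, `rmse`.
#' @export
ga_realisations <- function(data, bounds, bands, control = ga_control(),
                            n = 1000, seed0 = 1, threads = 1,
                            params = nmm_params(), innovations = "white") {
  stopifnot(n >= 1)
  span <- c(min(bands$omega1[1], bands$omega2[1]),
            max(bands$omega1[2], bands$omega2[2]))
  one <- function(seed) {
    res <- tryCatch(
      nsga2_evolve(data, bounds, bands, control, seed, params, innovations),
      error = function(e) NULL)
    if (is.null(res)) {
      row <- c(params$theta_log, J1 = .PENALTY, J2 = .PENALTY, rmse = .PENALTY)
      return(data.frame(seed = seed, t(row)))
    }
    sel <- res$solutions[res$selected_index, ]
    th <- as.numeric(sel[params$names])
    r <- band_rmse(th, data, span, params, innovations)
    data.frame(seed = seed, t(stats::setNames(th, params$names)),
               J1 = sel$J1, J2 = sel$J2, rmse = r)
  }
  seeds <- seed0 + seq_len(n) - 1L
  rows <- if (threads > 1) {
    parallel::mclapply(seeds, one, mc.cores = threads, mc.preschedule = TRUE)
  } else lapply(seeds, one)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ga_estimates", "data.frame")
  out
}

#' Whole-band RMSE between model and data log PSD
#'
#' @param theta_log full log-parameter vector.
#' @param data a [spectral_observation()].
#' @param span frequency interval `c(low, high)` in Hz.
#' @param params an [nmm_params()] template.
#' @param innovations innovation spectrum.
#' @return RMSE in log units; the penalty value for unstable sets.
#' @export
band_rmse <- function(theta_log, data, span, params = nmm_params(),
                      innovations = "white") {
  i <- .band_idx(data$freqs, span)
  out <- .batch_log_psd(matrix(theta_log, nrow = 1L), params, data$freqs,
                        innovations)
  if (!out$stable[1L]) return(.PENALTY)
  sqrt(mean((data$log_psd[i] - out$log_psd[1L, i])^2))
}
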