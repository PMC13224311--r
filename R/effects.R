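# Group-level inference on condition differences: difference distributions
# on the physical scale, equal-tailed credible intervals, Cohen's d, and the
# joint BCI + effect-size selection rule.

# draws (log scale) from a mixture, a gaussian_belief, an estimate table, or
# a numeric vector of point estimates
.draw_param <- function(src, param, n_draws, seed) {
  if (inherits(src, "posterior_mixture"))
    return(mixture_sample(src, param, n_draws, seed))
  if (inherits(src, "gaussian_belief"))
    return(.with_seed(seed,
      stats::rnorm(n_draws, src$mean[[param]], sqrt(src$var[[param]]))))
  if (is.data.frame(src)) {
    if (!param %in% names(src)) stop("unknown parameter: ", param)
    return(.with_seed(seed,
      sample(src[[param]], n_draws, replace = TRUE)))
  }
  if (is.numeric(src))
    return(.with_seed(seed, sample(src, n_draws, replace = TRUE)))
  stop("unsupported distribution source")
}

#' Difference distribution between two conditions
#'
#' Independent draws from each condition's parameter distribution (a
#' posterior mixture, a single Gaussian posterior, or the empirical
#' distribution of GA point estimates), exponentiated and scaled to the
#' physical units of the parameter, then differenced `B - A`.
#'
#' @param a,b condition distributions.
#' @param param parameter name.
#' @param params an [nmm_params()] template (supplies the physical scale).
#' @param n_draws number of draws (default `1e5`).
#' @param seed integer seed; condition B uses a derived seed.
#' @return Numeric vector of physical-scale differences.
#' @export
difference_distribution <- function(a, b, param, params = nmm_params(),
                                    n_draws = 1e5, seed = 1) {
  sc <- params$scales[[param]]
  da <- sc * exp(.draw_param(a, param, n_draws, seed))
  db <- sc * exp(.draw_param(b, param, n_draws, seed + 500009L))
  db - da
}

#' Equal-tailed credible interval
#'
#' @param draws numeric vector of draws.
#' @param level interval mass in (0, 1); 0.95 by default.
#' @return `c(low, high)` empirical quantiles at `(1-level)/2` and
#'   `(1+level)/2`.
#' @export
credible_interval <- function(draws, level = 0.95) {
  if (!length(draws)) stop("empty draws")
  stopifnot(level > 0, level < 1)
  unname(stats::quantile(draws, c((1 - level) / 2, (1 + level) / 2)))
}

#' Cohen's d between two draw vectors
#'
#' Standardised mean difference `(mean(b) - mean(a)) / s_pooled`, with the
#' pooled standard deviation taken as the square root of the average of the
#' two variances (equal draw counts).
#'
#' @param a,b numeric draw vectors.
#' @return Scalar effect size.
#' @export
cohens_d <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty draws")
  sp <- sqrt((stats::var(a) + stats::var(b)) / 2)
  if (!is.finite(sp) || sp == 0) stop("undefined effect: zero pooled SD")
  (mean(b) - mean(a)) / sp
}

#' Per-parameter effect report for two conditions
#'
#' For every free parameter, draws the difference distribution on the
#' physical scale and summarises it: headline effect `mean(diff)` (with
#' `|mean(diff)|` and `mean(|diff|)` reported alongside), the equal-tailed
#' 95% credible interval, Cohen's d, and the selection flag
#' (interval excludes zero AND `|d| >= d_threshold`).
#'
#' @inheritParams difference_distribution
#' @param level credible level.
#' @param d_threshold minimal practically relevant `|d|` (0.2 = small).
#' @param parameters parameter names to report (default: free parameters).
#' @return A data.frame of class `effect_report`, one row per parameter:
#'   `parameter`, `mean_diff`, `abs_mean_diff`, `mean_abs_diff`, `bci_low`,
#'   `bci_high`, `cohens_d`, `selected`, `n_draws`.
#' @export
effect_table <- function(a, b, params = nmm_params(), n_draws = 1e5, seed = 1,
                         level = 0.95, d_threshold = 0.2, parameters = NULL) {
  if (is.null(parameters)) parameters <- params$names[params$free_mask]
  rows <- lapply(seq_along(parameters), function(i) {
    pm <- parameters[i]
    sc <- params$scales[[pm]]
    da <- sc * exp(.draw_param(a, pm, n_draws, seed + 7L * i))
    db <- sc * exp(.draw_param(b, pm, n_draws, seed + 7L * i + 500009L))
    dd <- db - da
    ci <- credible_interval(dd, level)
    d <- cohens_d(da, db)
    data.frame(parameter = pm, mean_diff = mean(dd),
               abs_mean_diff = abs(mean(dd)), mean_abs_diff = mean(abs(dd)),
               bci_low = ci[1L], bci_high = ci[2L], cohens_d = d,
               selected = (ci[1L] > 0 || ci[2L] < 0) && abs(d) >= d_threshold,
               n_draws = n_draws)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("effect_report", "data.frame")
  out
}

#' Select practically relevant effects
#'
#' Retains parameters whose credible interval excludes zero AND whose
#' `|Cohen's d|` meets the threshold; input order is preserved.
#'
#' @param reports an `effect_report` data.frame from [effect_table()].
#' @param d_threshold effect-size threshold (default 0.2).
#' @return The selected subset of rows.
#' @export
select_effects <- function(reports, d_threshold = 0.2) {
  keep <- (reports$bci_low > 0 | reports$bci_high < 0) &
    abs(reports$cohens_d) >= d_threshold
  reports[keep, , drop = FALSE]
}
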