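test_that("ranking sorts by RMSE with deterministic tie-breaks", {
  est <- data.frame(seed = 1:3, Te = c(0.1, 0.2, 0.3),
                    J1 = c(1, 1, 1), J2 = c(1, 1, 1),
                    rmse = c(0.3, 0.1, 0.2))
  top <- rank_and_select(est, 2)
  expect_equal(top$seed, c(2, 3))
  expect_equal(rank_and_select(est, 3)$seed, c(2, 3, 1))
  # ties on rmse break by J1^2 + J2^2, then row order
  est2 <- data.frame(seed = 1:3, rmse = c(0.2, 0.2, 0.2),
                     J1 = c(2, 1, 1), J2 = c(0, 1, 1))
  expect_equal(rank_and_select(est2, 3)$seed, c(2, 3, 1))
  expect_error(rank_and_select(est, 4), "lower m")
})

test_that("dynamics-informed priors have unit variance on free parameters", {
  p <- nmm_params()
  top <- data.frame(t(stats::setNames(stats::runif(15, -0.5, 0.5), p$names)))
  top <- rbind(top, top + 0.1)
  priors <- dip_priors(top, p)
  std <- standard_priors()
  for (i in 1:2) {
    pr <- priors[[i]]
    expect_equal(unname(pr$mean), as.numeric(top[i, p$names]))
    expect_true(all(pr$var[p$free_mask] == 1))
    expect_true(all(pr$var[p$free_mask] > std$var[p$free_mask]))
    expect_equal(pr$var[!p$free_mask], std$var[!p$free_mask])
  }
})

test_that("equal-weight mixtures behave as densities", {
  nm <- c("x", "y")
  g1 <- gaussian_belief(stats::setNames(c(-2, 0), nm),
                        stats::setNames(c(0.25, 1), nm), kind = "posterior")
  g2 <- gaussian_belief(stats::setNames(c(2, 0), nm),
                        stats::setNames(c(0.25, 1), nm), kind = "posterior")
  single <- average_posteriors(list(g1))
  xg <- seq(-5, 5, 0.01)
  expect_equal(mixture_density(single, "x", xg),
               stats::dnorm(xg, -2, 0.5), tolerance = 1e-12)
  mix <- average_posteriors(list(g1, g2))
  expect_equal(sum(mix$weights), 1)
  expect_true(all(mix$weights == mix$weights[1]))
  # marginal integrates to one
  expect_equal(sum(mixture_density(mix, "x", xg)) * 0.01, 1, tolerance = 1e-3)
  # marginal mean is the average of component means
  expect_equal(sum(xg * mixture_density(mix, "x", xg)) * 0.01, 0,
               tolerance = 1e-3)
  # two well-separated components -> two modes
  expect_length(mixture_modes(mix, "x"), 2)
  expect_length(mixture_modes(single, "x"), 1)
  g3 <- gaussian_belief(stats::setNames(0, "z"), stats::setNames(1, "z"))
  expect_error(average_posteriors(list(g1, g3)), "misaligned")
})

test_that("mixture sampling matches the analytic distribution", {
  nm <- "x"
  mix <- average_posteriors(list(
    gaussian_belief(stats::setNames(-1, nm), stats::setNames(0.5, nm), kind = "posterior"),
    gaussian_belief(stats::setNames(1.5, nm), stats::setNames(0.25, nm), kind = "posterior")))
  dr <- mixture_sample(mix, "x", 1e5, seed = 42)
  expect_identical(mixture_sample(mix, "x", 1e5, seed = 42), dr)
  mu <- (-1 + 1.5) / 2
  se <- stats::sd(dr) / sqrt(length(dr))
  expect_lt(abs(mean(dr) - mu), 3 * se)
  # Kolmogorov distance against the analytic mixture CDF
  xs <- sort(dr)
  emp <- seq_along(xs) / length(xs)
  ks <- max(abs(emp - mixture_cdf(mix, "x", xs)))
  expect_lt(ks, 0.01)
  # quantiles invert the CDF
  q <- mixture_quantile(mix, "x", c(0.1, 0.5, 0.9))
  expect_equal(mixture_cdf(mix, "x", q), c(0.1, 0.5, 0.9), tolerance = 1e-6)
  expect_error(mixture_sample(mix, "nope", 10), "unknown")
})

test_that("a single realisation with m = 1 degenerates to one GA-seeded inversion", {
  dat <- quick_data()
  p <- recovery_params()
  res <- run_dip(dat, default_bounds(), study1_bands(), params = p,
                 n = 1, m = 1, control = ga_control(pop_size = 20, n_generations = 20),
                 seed0 = 5)
  expect_length(res$mixture$components, 1)
  expect_equal(nrow(res$report), 1)
  # equals a manual GA -> DIP prior -> VL chain with the same seed
  est <- ga_realisations(dat, default_bounds(), study1_bands(),
                         ga_control(pop_size = 20, n_generations = 20),
                         n = 1, seed0 = 5, params = p)
  pr <- dip_priors(est, p)[[1]]
  fit <- vl_invert(pr, dat, vl_config(), params = p)
  expect_equal(res$mixture$components[[1]]$mean, fit$posterior$mean)
})

test_that("zero-noise recovery pulls the mixture mean to the truth with VL refinement", {
  # small-scale version of the recovery protocol on noise-free data
  p <- recovery_params()
  pstar <- set_theta(p, recovery_truth())
  dat <- generate_spectrum(synthetic_spec(pstar, noise_sd = 0, seed = 11))
  res <- run_dip(dat, default_bounds(), study1_bands(), params = p,
                 n = 10, m = 5,
                 control = ga_control(pop_size = 60, n_generations = 150),
                 seed0 = 100)
  fp <- p$names[p$free_mask]
  mm <- vapply(fp, function(nm)
    mean(vapply(res$mixture$components, function(cc) cc$mean[[nm]], 0)), 0)
  expect_lt(max(abs(mm - pstar$theta_log[fp])), 0.1)
  # on noise-free data every VL refinement fits at least as well as its seed
  expect_gte(mean(res$report$vl_rmse <= res$report$ga_rmse, na.rm = TRUE), 0.9)
  expect_equal(nrow(res$report), sum(res$report$kept) + sum(!res$report$kept))
})

test_that("mixture serialisation round-trips", {
  nm <- c("x", "y")
  mix <- average_posteriors(list(
    gaussian_belief(stats::setNames(c(0, 1), nm), stats::setNames(c(1, 2), nm),
                    kind = "posterior", free_energy = -12.5),
    gaussian_belief(stats::setNames(c(0.5, -1), nm), stats::setNames(c(0.5, 1), nm),
                    kind = "posterior", free_energy = -13)))
  path <- withr::local_tempfile(fileext = ".json")
  write_mixture(mix, path)
  back <- read_mixture(path)
  expect_equal(back$names, mix$names)
  expect_equal(back$components[[1]]$mean, mix$components[[1]]$mean, tolerance = 1e-12)
  expect_equal(back$free_energies, mix$free_energies)
  write_mixture(back, paste0(path, "2"))
  expect_identical(readLines(path), readLines(paste0(path, "2")))
})
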