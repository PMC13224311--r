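test_that("band objectives are exact sums of squared residuals per band", {
  # construct data = model + known residuals so J1/J2 follow by arithmetic
  p <- nmm_params()
  f <- c(7, 8, 9, 20)          # first three in band 1, last in band 2
  bands <- objective_bands(c(6.5, 12.5), c(11.5, 30))
  model <- observe_log_psd(p, f)
  data <- spectral_observation(f, model$log_psd + c(1, 0, 0, 2))
  J <- band_objectives(p$theta_log, data, bands, p)
  expect_equal(unname(J), c(1, 4), tolerance = 1e-10)
  # perfect match on both bands -> (0, 0)
  J0 <- band_objectives(p$theta_log, model, bands, p)
  expect_equal(unname(J0), c(0, 0), tolerance = 1e-12)
})

test_that("unstable parameter sets receive the penalty value", {
  p <- nmm_params()
  dat <- quick_data()
  th <- p$theta_log
  th[c("G1", "G2", "He", "R1")] <- c(2, 2, 2, 1)  # far outside, unstable
  expect_false(attr(transfer_psd(set_theta(p, stats::setNames(th, p$names)),
                                 c(5, 10)), "stable"))
  J <- band_objectives(th, dat, study1_bands(), p)
  expect_equal(unname(J), c(1e6, 1e6))
})

test_that("Latin hypercube stratifies every free dimension", {
  b <- default_bounds()
  p <- nmm_params()
  pop <- lh_population(b, 25, seed = 7, params = p)
  free <- p$names[p$free_mask]
  for (nm in free) {
    x <- pop[, nm]
    expect_true(all(x >= b$lower[nm] & x <= b$upper[nm]))
    bins <- cut(x, seq(b$lower[nm], b$upper[nm], length.out = 26),
                include.lowest = TRUE)
    expect_true(all(table(bins) == 1))   # exactly one per bin
  }
  frozen <- p$names[!p$free_mask]
  expect_true(all(pop[, frozen] == rep(p$theta_log[frozen], each = 25)))
  expect_identical(lh_population(b, 25, seed = 7, params = p), pop)
  expect_false(identical(lh_population(b, 25, seed = 8, params = p), pop))
  expect_error(lh_population(b, 1, seed = 1, params = p), "pop_size")
})

test_that("NSGA-II recovers the analytic Pareto set of two quadratics", {
  # single free parameter; objectives (theta-a)^2, (theta-b)^2 with Pareto
  # set theta in [a, b]
  a <- -0.4; bb <- 0.3
  p <- nmm_params(free_mask = c(Te = TRUE, Ti = FALSE, He = FALSE, Hi = FALSE,
                                G1 = FALSE, G2 = FALSE, G3 = FALSE, G4 = FALSE,
                                G5 = FALSE, R1 = FALSE, R2 = FALSE, Di = FALSE,
                                input_gain = FALSE))
  dat <- quick_data()
  obj <- function(th) cbind((th[, "Te"] - a)^2, (th[, "Te"] - bb)^2)
  res <- nsga2_evolve(dat, default_bounds(), study1_bands(),
                      ga_control(pop_size = 60, n_generations = 100),
                      seed = 3, params = p, objective_fn = obj)
  sol <- res$solutions$Te
  expect_true(all(sol >= a - 1e-2 & sol <= bb + 1e-2))
  # coverage: every point of the Pareto set is near some solution
  gaps <- vapply(seq(a, bb, length.out = 50),
                 function(t) min(abs(sol - t)), 0)
  expect_lt(max(gaps), 0.05)
  # non-domination, brute force
  J <- as.matrix(res$solutions[, c("J1", "J2")])
  for (i in seq_len(nrow(J))) for (j in seq_len(nrow(J)))
    if (i != j)
      expect_false(all(J[i, ] <= J[j, ]) && any(J[i, ] < J[j, ]))
})

test_that("front selection minimises the Euclidean norm with stable ties", {
  front <- data.frame(J1 = c(1, 0.5, 2), J2 = c(1, 2, 0.5))
  expect_equal(select_from_front(front), 1)
  # brute force agreement on random fronts
  for (s in 1:10) {
    Jr <- withr::with_seed(s, matrix(stats::runif(20), 10, 2,
                                     dimnames = list(NULL, c("J1", "J2"))))
    expect_equal(select_from_front(Jr),
                 which.min(sqrt(Jr[, 1]^2 + Jr[, 2]^2)))
    expect_equal(sqrt(sum(Jr[select_from_front(Jr), ]^2)),
                 sqrt(sum(Jr[select_from_front(Jr[, 2:1]), 2:1]^2)))
  }
  expect_equal(select_from_front(data.frame(J1 = 2, J2 = 3)), 1)
  expect_equal(select_from_front(data.frame(J1 = c(3, 3), J2 = c(4, 4))), 1)
  expect_error(select_from_front(data.frame(J1 = numeric(0), J2 = numeric(0))),
               "empty")
})

test_that("realisation batches are deterministic, serial equals parallel", {
  dat <- quick_data()
  p <- recovery_params()
  ctl <- ga_control(pop_size = 20, n_generations = 15)
  t1 <- ga_realisations(dat, default_bounds(), study1_bands(), ctl,
                        n = 4, seed0 = 11, threads = 1, params = p)
  t2 <- ga_realisations(dat, default_bounds(), study1_bands(), ctl,
                        n = 4, seed0 = 11, threads = 2, params = p)
  expect_identical(t1, t2)
  # n = 1 returns exactly the evolve selection
  one <- ga_realisations(dat, default_bounds(), study1_bands(), ctl,
                         n = 1, seed0 = 11, params = p)
  ev <- nsga2_evolve(dat, default_bounds(), study1_bands(), ctl, seed = 11,
                     params = p)
  sel <- ev$solutions[ev$selected_index, ]
  expect_equal(as.numeric(one[1, p$names]), as.numeric(sel[p$names]))
  expect_equal(one$J1, sel$J1)
})

test_that("study band presets carry the published intervals", {
  s1 <- study_preset("study1"); s2 <- study_preset("study2")
  expect_equal(s1$bands$omega1, c(6.5, 12.5))
  expect_equal(s1$bands$omega2, c(11.5, 30))
  expect_equal(s2$bands$omega1, c(10.7, 65.8))
  expect_equal(s2$bands$omega2, c(35.6, 85))
  expect_equal(s1$m, 500)
  expect_equal(s2$m, 400)
})
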