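test_that("synthetic spectra are exact at zero noise and seeded", {
  spec <- synthetic_spec(nmm_params(), noise_sd = 0, seed = 9)
  obs <- generate_spectrum(spec)
  model <- observe_log_psd(nmm_params(), spec$freqs)
  expect_identical(obs$log_psd, model$log_psd)
  spec2 <- synthetic_spec(nmm_params(), noise_sd = 0.1, seed = 9)
  expect_identical(generate_spectrum(spec2)$log_psd,
                   generate_spectrum(spec2)$log_psd)
  expect_false(identical(
    generate_spectrum(synthetic_spec(nmm_params(), noise_sd = 0.1, seed = 10))$log_psd,
    generate_spectrum(spec2)$log_psd))
})

test_that("noise realisations have the requested standard deviation", {
  p <- nmm_params()
  base <- observe_log_psd(p, seq(5, 20, 0.5))$log_psd
  draws <- vapply(1:200, function(s)
    generate_spectrum(synthetic_spec(p, freqs = seq(5, 20, 0.5),
                                     noise_sd = 0.1, seed = s))$log_psd - base,
    numeric(length(base)))
  sds <- apply(draws, 1, stats::sd)
  expect_true(all(abs(sds - 0.1) < 0.01 * 3))  # within ~10% per bin
  expect_lt(abs(mean(sds) - 0.1), 0.005)
})

test_that("condition pairs apply log shifts with independent noise", {
  spec <- synthetic_spec(nmm_params(), noise_sd = 0, seed = 3,
                         delta_map = list(Te = -0.3))
  pair <- generate_condition_pair(spec)
  a_params <- pair$a$meta$spec$theta_star
  b_params <- pair$b$meta$spec$theta_star
  expect_equal(to_physical(b_params)[["Te"]],
               to_physical(a_params)[["Te"]] * exp(-0.3), tolerance = 1e-12)
  # empty map: same generating parameters, different noise
  null_spec <- synthetic_spec(nmm_params(), noise_sd = 0.1, seed = 3)
  null_pair <- generate_condition_pair(null_spec)
  expect_equal(null_pair$a$meta$spec$theta_star$theta_log,
               null_pair$b$meta$spec$theta_star$theta_log)
  expect_false(identical(null_pair$a$log_psd, null_pair$b$log_psd))
  # out-of-bounds shift is rejected
  far <- synthetic_spec(nmm_params(), delta_map = list(Te = -5))
  expect_error(generate_condition_pair(far, bounds = default_bounds()),
               "exit the bounds")
})

test_that("time-domain simulation is quiescent without forcing and scales with drive", {
  p <- nmm_params()
  p0 <- p; p0$scales[["input_gain"]] <- 1e-12
  x <- simulate_timeseries(p0, duration = 1, dt = 1e-3, seed = 1)
  expect_lt(max(abs(x)), 1e-9)    # fixed point at the origin
  vars <- vapply(c(0.5, 1, 2), function(g) {
    pg <- p; pg$scales[["input_gain"]] <- g
    mean(vapply(1:8, function(s)
      stats::var(simulate_timeseries(pg, duration = 4, dt = 1e-3, seed = s)), 0))
  }, 0)
  expect_true(all(diff(vars) > 0))
  expect_equal(vars[3] / vars[1], 16, tolerance = 0.2)  # variance ~ gain^2
})

test_that("Welch estimate locates a pure sinusoid at its bin", {
  fs <- 256
  t <- seq(0, 8, by = 1 / fs)[-1]
  x <- sin(2 * pi * 10 * t)
  W <- welch_psd(x, fs, nseg = 256)
  expect_equal(W$freq[which.max(W$psd)], 10)
  ep <- preprocess_epochs(split(x, rep(1:4, each = length(x) / 4)), fs,
                          mode = "fft", band = c(2, 45))
  expect_equal(ep$freqs[which.max(ep$log_psd)], 10)
  expect_equal(sum(exp(ep$log_psd)) * (ep$freqs[2] - ep$freqs[1]), 1,
               tolerance = 1e-6)
})

test_that("epoch averaging is idempotent and order-invariant", {
  fs <- 200
  e1 <- withr::with_seed(1, stats::rnorm(400))
  e2 <- withr::with_seed(2, stats::rnorm(400))
  same <- preprocess_epochs(list(e1, e1, e1), fs, mode = "fft", band = c(2, 45))
  single <- preprocess_epochs(list(e1), fs, mode = "fft", band = c(2, 45))
  expect_equal(same$log_psd, single$log_psd, tolerance = 1e-12)
  # averaging unit-area PSDs then renormalising == renormalising then averaging
  both <- preprocess_epochs(list(e1, e2), fs, mode = "fft", band = c(2, 45))
  p1 <- exp(single$log_psd)
  p2 <- exp(preprocess_epochs(list(e2), fs, mode = "fft", band = c(2, 45))$log_psd)
  manual <- (p1 + p2) / 2
  manual <- manual / (sum(manual) * (both$freqs[2] - both$freqs[1]))
  expect_equal(exp(both$log_psd), manual, tolerance = 1e-9)
  expect_error(preprocess_epochs(list(stats::rnorm(100)), fs, mode = "welch",
                                 nseg = 512), "shorter")
  expect_error(preprocess_epochs(list(e1, stats::rnorm(10)), fs), "equal length")
})

test_that("spectrum files round-trip byte-identically and reject bad input", {
  obs <- observe_log_psd(nmm_params(), seq(4, 30, 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(obs, path)
  back <- read_spectrum(path)
  expect_equal(back$freqs, obs$freqs, tolerance = 1e-12)
  expect_equal(back$log_psd, obs$log_psd, tolerance = 1e-12)
  expect_true(back$meta$normalised)
  write_spectrum(back, paste0(path, "2"))
  expect_identical(readLines(path), readLines(paste0(path, "2")))
  # decreasing frequency named by row
  writeLines(c("freq_hz,log_psd", "2,-1", "3,-1.2", "2.5,-1.1"), path)
  expect_error(read_spectrum(path), "row 4")
  writeLines(c("freq_hz,log_psd", "2,-1", "3,abc"), path)
  expect_error(read_spectrum(path), "row 3")
  writeLines("wrong,header", path)
  expect_error(read_spectrum(path), "header")
})

test_that("estimate tables round-trip through CSV", {
  p <- recovery_params()
  est <- ga_realisations(quick_data(), default_bounds(), study1_bands(),
                         ga_control(pop_size = 12, n_generations = 5),
                         n = 2, seed0 = 1, params = p)
  path <- withr::local_tempfile(fileext = ".csv")
  write_estimates(est, path)
  back <- read_estimates(path)
  expect_equal(back$rmse, est$rmse, tolerance = 1e-12)
  expect_equal(back$Te, est$Te, tolerance = 1e-12)
})

test_that("the command-line wrapper round-trips a simulated spectrum", {
  cli <- system.file("cli", "dipdcm", package = "dipdcm")
  out <- withr::local_tempfile(fileext = ".csv")
  status <- system2("Rscript", c(cli, "simulate", "--seed", "2",
                                 "--noise-sd", "0", "--out", out),
                    stdout = NULL, stderr = NULL)
  expect_equal(status, 0)
  obs <- read_spectrum(out)
  expect_equal(obs$log_psd, observe_log_psd(nmm_params(), obs$freqs)$log_psd,
               tolerance = 1e-10)
  expect_true(file.exists(paste0(out, ".manifest.json")))
})
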