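# Monte Carlo machinery: sampling, correlation, error budget, and the
# statistical behaviour of the transit-time study.

test_that("parameter sampling respects the stated distributions", {
  d <- list(D = param_dist("D", "normal", mu = 3600, sigma = 30),
            epsilon = param_dist("epsilon", "uniform", lo = 0.5, hi = 1.5))
  s <- sample_params(d, 1e5, seed = 13)
  expect_lt(abs(mean(s$D) - 3600), 3 * 30 / sqrt(1e5))
  expect_lt(abs(sd(s$D) - 30), 1)
  expect_true(all(s$epsilon >= 0.5 & s$epsilon <= 1.5))
  s2 <- sample_params(d, 1e5, seed = 13)
  expect_identical(s, s2)
  # positive-only redraw: a wide normal never yields non-positive draws
  dpos <- list(alpha = param_dist("alpha", "normal", mu = 1, sigma = 5))
  expect_true(all(sample_params(dpos, 2e4, seed = 14)$alpha > 0))
  expect_error(param_dist("D", "normal", mu = 1, sigma = 0), "sigma")
  expect_error(param_dist("omega", "uniform", lo = 1, hi = 1), "lo < hi")
})

test_that("Pearson r matches hand evaluation and stays bounded", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 2)), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  set.seed(15)
  for (k in 1:50) {
    r <- pearson_r(rnorm(10), rnorm(10))
    expect_gte(r, -1); expect_lte(r, 1)
  }
})

test_that("Richardson constant and error budget are exact arithmetic", {
  expect_equal(richardson_constant(0.4, 0.4, 0.1), 0)
  expect_equal(richardson_constant(0.5, 0.4, 0.1), 1)
  eb <- error_budget(C = 133, dt = 1e-4, S_n = 0.0687, N_s = 1e4)
  expect_equal(eb$E_ti, 1.33e-2)
  expect_equal(eb$E_mc, 6.87e-4)
  expect_equal(eb$E_total, 0.013987, tolerance = 1e-12)
  expect_equal(error_budget(133, 1e-4, 0, 100)$E_total, 1.33e-2)
  e1 <- error_budget(0, 0, 0.1, 100)$E_mc
  e4 <- error_budget(0, 0, 0.1, 400)$E_mc
  expect_equal(e1 / e4, 2)
})

test_that("histogram/CDF summaries behave and recover lognormal fits", {
  const <- cdf_hist(rep(0.3, 50))
  expect_equal(const$cdf(0.3), 1)
  expect_equal(const$cdf(0.299), 0)
  set.seed(16)
  x <- stats::rlnorm(1e4, meanlog = -1, sdlog = 0.3)
  ch <- cdf_hist(x)
  expect_equal(ch$cdf(max(x)), 1)
  expect_equal(ch$cdf(min(x) - 1e-9), 0)
  expect_equal(ch$lognormal$mu_log, -1, tolerance = 0.05)
  expect_equal(ch$lognormal$sigma_log, 0.3, tolerance = 0.05)
  expect_equal(sum(ch$hist$rel_freq), 1, tolerance = 1e-12)
})

test_that("a single-sample study reduces to one seeded scenario run", {
  dists <- default_mc_dists("four")
  mc <- run_mc("channel", dists, n_samples = 1, seed = 31)
  set.seed(31)
  samples <- sample_params(dists, 1)
  run_seed <- sample.int(.Machine$integer.max - 1L, 1)
  sc <- celldeform:::apply_param_overrides(build_scenario("channel"),
                                           as.list(samples[1, ]))
  traj <- run_scenario(sc, step_config(seed = run_seed, t_end = 3.7,
                                       record_every = 0,
                                       stop_after_exit = TRUE))
  expect_equal(mc$tau, penetration_time(traj), tolerance = 1e-12)
})

test_that("tidy/glance expose the study summary", {
  mc <- run_mc("channel", default_mc_dists("two"), n_samples = 4, seed = 5)
  td <- tidy(mc)
  expect_identical(td$parameter, c("epsilon", "omega"))
  expect_true(all(abs(td$r) <= 1))
  gl <- glance(mc)
  expect_identical(gl$n_samples, 4)
  expect_identical(gl$n_ok + gl$n_failed, 4L)
  expect_equal(gl$E_mc, gl$S_n / sqrt(gl$n_ok))
})

test_that("Monte Carlo error shrinks as 1/sqrt(N_s)", {
  # repeated small studies at a coarser step: the standard deviation of the
  # mean transit time must fall roughly twofold per fourfold sample size
  cfg <- step_config(dt = 5e-4)
  dists <- default_mc_dists("four")
  means <- function(n_s, reps) {
    vapply(seq_len(reps), function(r) {
      run_mc("channel", dists, n_samples = n_s, seed = 1000 + 17 * r + n_s,
             cfg = cfg)$mean_tau
    }, 0)
  }
  sd25 <- sd(means(25, 8))
  sd100 <- sd(means(100, 8))
  sd400 <- sd(means(400, 5))
  # true ratios are 2 and 4; few-replicate sd estimates are noisy, so the
  # assertions bound the trend rather than the exact exponent
  expect_gt(sd25, sd400)
  expect_gt(sd25 / sd400, 1.5)
  expect_lt(sd25 / sd400, 12)
  expect_gt(sd25 / sd100, 1.1)
})
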