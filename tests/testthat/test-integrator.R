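# IMEX stepping: fixed points, stability, determinism, engine parity and
# the scenario-level behaviours.

test_that("Wiener increments have variance dt and are seed-reproducible", {
  set.seed(11)
  z <- replicate(2, wiener_increment(50000, 1e-4))
  v <- var(as.vector(z))
  se <- 1e-4 * sqrt(2 / length(z))
  expect_lt(abs(v - 1e-4), 3 * se)
  set.seed(99); a <- wiener_increment(10, 0.01)
  set.seed(99); b <- wiener_increment(10, 0.01)
  expect_identical(a, b)
})

test_that("implicit relaxation reproduces the scalar closed form", {
  # a node displaced from its target approaches it by the factor
  # dt*alpha/(1 + dt*alpha) per step (= 0.02439 at alpha = 250, dt = 1e-4)
  p <- cell_params(alpha = 250, beta = 0, eta = 0)
  st <- init_cell_2d(p)
  st$x[1, ] <- st$x[1, ] + c(1, 0)    # 1 um outward along +x
  cfg <- step_config(dt = 1e-4, eta = 0)
  st$phi <- 0
  xn <- step_membrane(st, NULL, NULL, cfg)
  target <- st$x_n[1, ] + st$xhat[1, ]
  gain <- (st$x[1, 1] - xn[1, 1]) / (st$x[1, 1] - target[1])
  expect_equal(gain, 1e-4 * 250 / (1 + 1e-4 * 250), tolerance = 1e-12)
  expect_equal(gain, 0.02439, tolerance = 1e-4)
})

test_that("exact equilibrium is a fixed point to machine precision", {
  sc <- build_scenario("free")
  sc$field <- NULL
  traj <- run_scenario(sc, step_config(eta = 0, t_end = 0.1, record_every = 0))
  st0 <- init_cell_2d(cell_params())
  expect_lt(max(abs(traj$state$x - st0$x)), 1e-10)
  expect_lt(max(abs(traj$state$x_n - st0$x_n)), 1e-10)
})

test_that("shape memory restores a perturbed cell monotonically", {
  p <- cell_params(beta = 0, eta = 0)
  st <- init_cell_2d(p)
  set.seed(12)
  st$x <- st$x + matrix(rnorm(60, sd = 0.8), 30, 2)
  cfg <- step_config(dt = 1e-4, eta = 0)
  dev <- function(s) {
    B <- rotation_matrix_2d(fit_rotation_2d(s))
    sqrt(mean(rowSums((s$x - (s$x_n + s$xhat %*% t(B)))^2)))
  }
  devs <- dev(st)
  for (k in 1:100) {
    st <- advance(st, NULL, NULL, cfg)$state
    devs <- c(devs, dev(st))
  }
  expect_true(all(diff(devs) < 1e-12))
  expect_lt(tail(devs, 1), 0.1 * devs[1])
})

test_that("nucleus follows a displaced membrane and pins at large alpha_n", {
  st <- init_cell_2d(cell_params(eta = 0))
  st$phi <- 0
  cfg <- step_config(dt = 1e-4, eta = 0)
  shifted <- st$x + matrix(c(1, 0), 30, 2, byrow = TRUE)
  xn <- step_nucleus(st, shifted, cfg)
  expect_true(all(xn[, 1] > st$x_n[, 1]))    # moves toward the membrane
  # alpha_n -> infinity pins nucleus nodes to x_c + B xhat_n
  stp <- init_cell_2d(cell_params(alpha_n = 1e12, eta = 0))
  stp$phi <- 0
  shifted <- stp$x + matrix(c(1, 0), 30, 2, byrow = TRUE)
  xn2 <- step_nucleus(stp, shifted, cfg)
  pinned <- sweep(stp$xhat_n, 2, stp$x_c, `+`)
  expect_equal(xn2, pinned, tolerance = 1e-7)
})

test_that("a free cell approaches a distant source monotonically", {
  sc <- build_scenario("free")
  st <- sc$state
  cfg <- step_config(dt = 1e-4, eta = 0)
  src <- sc$field$sources[[1]]$position
  d_prev <- sqrt(sum((colMeans(st$x) - src)^2))
  field <- sc$field
  for (k in 1:100) {
    res <- advance(st, field, NULL, cfg)
    st <- res$state; field <- res$field
    d <- sqrt(sum((colMeans(st$x) - src)^2))
    expect_lt(d, d_prev)
    d_prev <- d
  }
})

test_that("noise-free runs are identical; seeded noisy runs reproduce", {
  a <- channel_run(t_end = 0.02, record_every = 0)
  b <- channel_run(t_end = 0.02, record_every = 0)
  expect_identical(a$state$x, b$state$x)
  n1 <- channel_run(eta = 20, seed = 5, t_end = 0.02, record_every = 0)
  n2 <- channel_run(eta = 20, seed = 5, t_end = 0.02, record_every = 0)
  expect_identical(n1$state$x, n2$state$x)
  n3 <- channel_run(eta = 20, seed = 6, t_end = 0.02, record_every = 0)
  expect_false(identical(n1$state$x, n3$state$x))
})

test_that("compiled engine and reference R integrator agree", {
  sc <- build_scenario("channel")
  cfg <- step_config(eta = 0, t_end = 0.02, record_every = 0, seed = 5)
  a <- run_scenario(sc, cfg, engine = "cpp")
  b <- run_scenario(sc, cfg, engine = "r")
  expect_lt(max(abs(a$state$x - b$state$x)), 1e-10)
  expect_lt(max(abs(a$state$x_n - b$state$x_n)), 1e-10)
  cfg2 <- step_config(eta = 20, t_end = 0.01, record_every = 0, seed = 42)
  a2 <- run_scenario(sc, cfg2, engine = "cpp")
  b2 <- run_scenario(sc, cfg2, engine = "r")
  expect_lt(max(abs(a2$state$x - b2$state$x)), 1e-10)
})

test_that("the cell fully traverses the channel preset", {
  traj <- channel_run()
  expect_false(is.na(traj$events$exit_time))
  ch <- traj$channel
  last <- traj$membrane[length(traj$times), , 1]
  expect_true(all(last > ch$x_entry + ch$length))
})

test_that("the nucleus deforms below its diameter inside the cavity", {
  traj <- run_scenario("cavity", step_config(eta = 0, seed = 1,
                                             record_every = 50))
  wmin <- Inf
  for (f in seq_along(traj$times)) {
    nx <- traj$nucleus[f, , 1]
    if (min(nx) > -6 && max(nx) < 6) {      # between the discs
      wmin <- min(wmin, diff(range(traj$nucleus[f, , 2])))
    }
  }
  expect_lt(wmin, 2 * 5)
})

test_that("the cell recovers its shape after consuming the source", {
  traj <- run_scenario("free", step_config(eta = 0, seed = 1,
                                           record_every = 0))
  expect_false(is.na(traj$events$consumed[1]))
  st <- traj$state
  B <- rotation_matrix_2d(fit_rotation_2d(st))
  rms <- sqrt(mean(rowSums((st$x - (st$x_n + st$xhat %*% t(B)))^2)))
  expect_lt(rms, 0.1)
})

test_that("instability aborts with a diagnostic", {
  sc <- build_scenario("free")
  sc$field$sources[[1]]$rate <- 1e14
  expect_error(run_scenario(sc, step_config(eta = 0, t_end = 0.01)),
               "reduce dt")
})

test_that("a 3D cell migrates over a spherical obstacle toward the source", {
  p <- cell_params(N = 12, M = 8, dimension = 3)
  sc <- build_scenario("obstacle3d", params = p)
  traj <- run_scenario(sc, step_config(eta = 0, t_end = 0.4,
                                       record_every = 10, seed = 1))
  cen <- centroid_series(traj)
  src <- sc$field$sources[[1]]$position
  d0 <- sqrt(sum((cen[1, ] - src)^2))
  d1 <- sqrt(sum((cen[nrow(cen), ] - src)^2))
  expect_lt(d1, d0)
  # sphere obstacle is respected
  for (f in seq_along(traj$times)) {
    r <- sqrt(rowSums(traj$membrane[f, , ]^2))
    expect_gte(min(r), 8 - 1e-2 - 1e-9)
  }
})
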