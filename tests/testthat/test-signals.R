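# Chemoattractant field: fundamental solutions, superposition, the
# linear-implicit gradient convention and source consumption.

test_that("2D concentration matches the logarithmic kernel", {
  f <- ref_field()
  # ln(1) = 0 at unit distance
  expect_equal(concentration(f, c(1, 0)), 0)
  # direct arithmetic at 10 um: -(gamma/(2 pi D)) * ln 10
  expected <- -(1.2e6 / (2 * pi * 3600)) * log(10)
  expect_equal(concentration(f, c(10, 0)), expected, tolerance = 1e-12)
  expect_equal(expected, -122.156, tolerance = 1e-4)
  # negative values far from the source are permitted
  expect_lt(concentration(f, c(50, 0)), 0)
})

test_that("superposition holds to machine precision", {
  set.seed(1)
  srcs <- lapply(1:4, function(i) {
    chemokine_source(runif(2, -30, 30), rate = runif(1, 1e5, 2e6))
  })
  all4 <- signal_field(srcs, D = 3600)
  x <- c(5, -7)
  singles_c <- sum(vapply(srcs, function(s) {
    concentration(signal_field(s, D = 3600), x)
  }, 0))
  expect_equal(concentration(all4, x), singles_c, tolerance = 1e-13)
  singles_g <- Reduce(`+`, lapply(srcs, function(s) {
    imex_gradient(signal_field(s, D = 3600), x)
  }))
  expect_equal(imex_gradient(all4, x), singles_g, tolerance = 1e-13)
  # two coincident identical sources give exactly twice one source
  twin <- signal_field(list(srcs[[1]], srcs[[1]]), D = 3600)
  expect_identical(concentration(twin, x),
                   2 * concentration(signal_field(srcs[[1]], D = 3600), x))
})

test_that("IMEX gradient follows the old/new split and its constants", {
  f <- ref_field()
  # evaluation at the source position gives a zero vector
  expect_equal(imex_gradient(f, c(0, 0), c(10, 0)), c(0, 0))
  # magnitude gamma/(pi D r) at r = 10, pointing toward the source
  g <- imex_gradient(f, c(10, 0))
  expect_equal(g, c(-1.2e6 / (pi * 3600 * 10), 0), tolerance = 1e-12)
  expect_equal(sqrt(sum(g^2)), 10.6103, tolerance = 1e-4)
  # doubling D halves the gradient
  f2 <- ref_field(D = 7200)
  expect_equal(imex_gradient(f2, c(10, 0)), g / 2, tolerance = 1e-13)
  # direction: always toward the source for x_new = x_old
  set.seed(2)
  for (k in 1:20) {
    x <- runif(2, -40, 40)
    gg <- imex_gradient(f, x)
    to_src <- -x / sqrt(sum(x^2))
    expect_gt(sum(gg * to_src) / sqrt(sum(gg^2)), 1 - 1e-12)
  }
})

test_that("the drift constant is twice the analytic kernel gradient", {
  # regression pin: the analytic gradient of the log kernel has denominator
  # 2 pi D; the drift convention uses pi D, i.e. exactly a factor 2
  f <- ref_field()
  r <- 7.3
  analytic <- 1.2e6 / (2 * pi * 3600 * r)
  drift <- sqrt(sum(imex_gradient(f, c(r, 0))^2))
  expect_equal(drift / analytic, 2, tolerance = 1e-12)
})

test_that("3D kernels: printed 1/r^2 form by default, physical optional", {
  s <- chemokine_source(c(0, 0, 0), 1.2e6)
  fp <- signal_field(s, D = 3600)
  expect_equal(concentration(fp, c(10, 0, 0)),
               1.2e6 / (4 * pi * 3600 * 100), tolerance = 1e-12)
  gp <- imex_gradient(fp, c(10, 0, 0))
  expect_equal(gp, c(-2 * 1.2e6 * 10 / (4 * pi * 3600 * 1e4), 0, 0),
               tolerance = 1e-12)
  fq <- signal_field(s, D = 3600, greens_3d = "physical")
  expect_equal(concentration(fq, c(10, 0, 0)),
               1.2e6 / (4 * pi * 3600 * 10), tolerance = 1e-12)
  # physical 3D gradient equals the analytic derivative (no extra factor)
  gq <- imex_gradient(fq, c(10, 0, 0))
  expect_equal(gq, c(-1.2e6 / (4 * pi * 3600 * 100), 0, 0), tolerance = 1e-12)
})

test_that("singular evaluations raise errors", {
  f <- ref_field()
  expect_error(concentration(f, c(0, 0)), "singular")
  expect_error(imex_gradient(f, c(1, 1), c(0, 0)), "singular")
})

test_that("sources inside the cell are consumed permanently", {
  poly <- init_cell_2d(cell_params())$x
  f <- signal_field(list(chemokine_source(c(0, 0), 1e6),
                         chemokine_source(c(100, 0), 1e6)), D = 3600)
  f2 <- consume_sources(f, poly)
  expect_false(f2$sources[[1]]$active)   # at the centroid
  expect_true(f2$sources[[2]]$active)    # 100 um away
  expect_identical(attr(f2, "consumed"), 1L)
  # boundary tie-break: a point exactly on an edge counts as inside
  sq <- unit_square
  fb <- signal_field(chemokine_source(c(0.5, 0), 1e6), D = 3600)
  expect_false(consume_sources(fb, sq)$sources[[1]]$active)
  # inactive sources contribute nothing
  expect_identical(concentration(f2, c(3, 0)),
                   concentration(signal_field(f$sources[[2]], D = 3600), c(3, 0)))
  # degenerate boundary is a geometry error
  expect_error(consume_sources(f, poly[1:2, ]), "polygon")
})

test_that("time gating switches sources on and off", {
  s <- chemokine_source(c(0, 0), 1e6, t_on = 1, t_off = 2)
  f <- signal_field(s, D = 3600)
  expect_identical(concentration(f, c(10, 0), t = 0.5), 0)
  expect_lt(concentration(f, c(10, 0), t = 1.5), 0)
  expect_identical(concentration(f, c(10, 0), t = 2.0), 0)
})
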