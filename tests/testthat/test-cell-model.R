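# Cell meshing, equilibrium offsets and rotation (polarity) fitting.

test_that("2D initialisation places nodes on concentric circles", {
  st <- init_cell_2d(cell_params(N = 4, R = 1, R_n = 0.5))
  expect_equal(st$x,
               rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1)),
               tolerance = 1e-12)
  # offsets are radial with length R - R_n, and the offset identities hold
  st2 <- init_cell_2d(cell_params(), center = c(3, -2))
  expect_equal(sqrt(rowSums(st2$xhat^2)), rep(12.5 - 5, 30), tolerance = 1e-12)
  expect_equal(st2$x, st2$x_n + st2$xhat)
  expect_equal(st2$x_n, sweep(st2$xhat_n, 2, st2$x_c, `+`))
  # enclosed area of the N-gon matches the closed form (N/2) R^2 sin(2pi/N)
  st3 <- init_cell_2d(cell_params(N = 30, R = 12.5))
  expect_equal(polygon_area(st3$x), 15 * 12.5^2 * sin(2 * pi / 30),
               tolerance = 1e-12)
  expect_equal(polygon_area(st3$x), 487.29, tolerance = 1e-4)
  expect_error(cell_params(R = 5, R_n = 5), "R > R_n")
})

test_that("3D initialisation builds a closed spherical lattice", {
  p <- cell_params(N = 30, M = 30, dimension = 3)
  st <- init_cell_3d(p, center = c(1, 2, 3))
  expect_equal(nrow(st$x), 30 * 29 + 2)    # merged pole duplicates
  r <- sqrt(rowSums(sweep(st$x, 2, c(1, 2, 3))^2))
  expect_equal(r, rep(10, nrow(st$x)), tolerance = 1e-12)
  # closed triangulation: volume near the sphere's (the inscribed lattice
  # undershoots by ~1% at this resolution)
  expect_equal(mesh_volume(st), 4 / 3 * pi * 1000, tolerance = 0.015)
  expect_lt(mesh_volume(st), 4 / 3 * pi * 1000)
  # pole collapse: exactly one node at each pole
  expect_equal(sum(abs(st$x[, 3] - 13) < 1e-9), 1)
  expect_equal(sum(abs(st$x[, 3] + 7) < 1e-9), 1)
})

test_that("2D rotation fit is exact and matches the grid-search oracle", {
  st <- init_cell_2d(cell_params(N = 12))
  expect_equal(fit_rotation_2d(st), 0)
  # deform the reference a little so the problem is not degenerate,
  # then rotate rigidly by pi/6
  set.seed(3)
  st$x_ref <- st$x_ref * (1 + 0.2 * runif(12))
  B <- rotation_matrix_2d(pi / 6)
  st$x <- st$x_ref %*% t(B) + 5
  expect_equal(fit_rotation_2d(st), pi / 6, tolerance = 1e-9)
  expect_equal(grid_rotation_oracle(st), pi / 6, tolerance = 1e-5)
  # fitted angle beats 360 uniformly sampled angles
  st$x <- st$x + matrix(rnorm(24, sd = 0.5), 12, 2)
  phi <- fit_rotation_2d(st)
  obj <- rotation_objective_2d(st, phi)
  for (a in seq(0, 2 * pi, length.out = 360)) {
    expect_lte(obj, rotation_objective_2d(st, a) + 1e-12)
  }
})

test_that("2D rotation fit is equivariant and handles degeneracy", {
  st <- init_cell_2d(cell_params(N = 10))
  set.seed(4)
  st$x_ref <- st$x_ref + matrix(rnorm(20, sd = 0.4), 10, 2)
  st$x <- st$x_ref %*% t(rotation_matrix_2d(0.7)) + matrix(rnorm(20, sd = 0.1), 10, 2)
  phi0 <- fit_rotation_2d(st)
  for (th in c(0.5, 2.2, 5.0)) {
    st2 <- st
    st2$x <- st$x %*% t(rotation_matrix_2d(th))
    expect_equal((fit_rotation_2d(st2) - phi0) %% (2 * pi), th,
                 tolerance = 1e-9)
  }
  stc <- st
  stc$x <- matrix(1, 10, 2)
  expect_warning(phi <- fit_rotation_2d(stc), "coincident")
  expect_identical(phi, 0)
})

test_that("3D rotation fit recovers known angles via Procrustes", {
  p <- cell_params(N = 12, M = 8, dimension = 3)
  st <- init_cell_3d(p)
  expect_equal(fit_rotation_3d(st), c(0, 0, 0))
  set.seed(5)
  st$x_ref <- st$x_ref * (1 + 0.15 * runif(nrow(st$x_ref)))
  ang <- c(0.3, -0.2, 0.5)
  st$x <- st$x_ref %*% t(rotation_matrix_3d(ang)) + 2
  expect_equal(fit_rotation_3d(st), ang, tolerance = 1e-6)
  # fitted objective beats 1000 random angle triples
  st$x <- st$x + matrix(rnorm(length(st$x), sd = 0.2), nrow(st$x), 3)
  phi <- fit_rotation_3d(st)
  obj <- rotation_objective_3d(st, phi)
  for (k in 1:1000) {
    expect_lte(obj, rotation_objective_3d(st, runif(3, -pi / 2, pi / 2)) + 1e-10)
  }
})

test_that("rotation matrices follow the stated conventions", {
  # By carries -sin in its (1,3) entry
  By <- rotation_matrix_3d(c(0, 0.4, 0))
  expect_equal(By[1, 3], -sin(0.4))
  expect_equal(By[3, 1], sin(0.4))
  # factor order Bx By Bz
  ang <- c(0.2, 0.3, 0.4)
  expect_equal(rotation_matrix_3d(ang),
               rotation_matrix_3d(c(ang[1], 0, 0)) %*%
                 rotation_matrix_3d(c(0, ang[2], 0)) %*%
                 rotation_matrix_3d(c(0, 0, ang[3])),
               tolerance = 1e-14)
  expect_equal(det(rotation_matrix_3d(ang)), 1, tolerance = 1e-12)
})
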