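# Obstacles, rough-channel geometry, contact detection and projection.

test_that("channel wall heights follow y = +/-(y0 + eps sin(omega x))", {
  ch0 <- rough_channel(y0 = 5, epsilon = 0, omega = 0)
  xs <- seq(0, 60, by = 7)
  expect_equal(channel_wall(ch0, xs, "upper"), rep(5, length(xs)))
  ch <- rough_channel(y0 = 5, epsilon = 1, omega = 0.5)
  expect_equal(channel_wall(ch, pi, "upper"), 5 + sin(pi / 2), tolerance = 1e-12)
  expect_equal(channel_wall(ch, xs, "lower"), -channel_wall(ch, xs, "upper"))
  expect_error(rough_channel(y0 = 1, epsilon = 2), "y0 > epsilon")
})

test_that("wall normals are inward-facing units", {
  ch0 <- rough_channel(5, 0, 0)
  expect_equal(wall_normal(ch0, 3, "upper"), c(0, -1))
  expect_equal(wall_normal(ch0, 3, "lower"), c(0, 1))
  chw0 <- rough_channel(5, 1, 0)   # omega = 0: flat walls whatever eps
  expect_equal(wall_normal(chw0, 12, "upper"), c(0, -1))
  ch <- rough_channel(5, 1, 0.5)
  n <- wall_normal(ch, 0, "upper")
  expect_equal(n, c(0.5, -1) / sqrt(1.25), tolerance = 1e-12)
  expect_equal(n, c(0.4472, -0.8944), tolerance = 1e-4)
  xs <- seq(0, 60, by = 3)
  nm <- wall_normal(ch, xs, "upper")
  expect_equal(rowSums(nm^2), rep(1, length(xs)), tolerance = 1e-12)
})

test_that("displacement projection removes exactly the normal component", {
  expect_equal(project_displacement(c(1, -1), c(0, 1)), c(1, 0))
  expect_equal(project_displacement(c(0, -3), c(0, 1)), c(0, 0))
  dx <- c(2, 0)
  expect_equal(project_displacement(dx, c(0, 1)), dx)  # already tangential
  expect_warning(out <- project_displacement(c(1, 1), c(0, 2)), "unit")
  expect_equal(out, c(1, 0))
  set.seed(6)
  for (k in 1:25) {
    dx <- rnorm(2); th <- runif(1, 0, 2 * pi)
    n <- c(cos(th), sin(th))
    pr <- project_displacement(dx, n)
    expect_lt(abs(sum(pr * n)), 1e-12)              # orthogonal
    expect_lte(sqrt(sum(pr^2)), sqrt(sum(dx^2)) + 1e-12)  # never longer
  }
})

test_that("contact detection reports normals and swept crossings", {
  w <- cell_world(discs = disc_obstacle(c(0, 0), 5))
  # far node, small step: nothing
  expect_false(detect_contact(c(20, 0), c(-0.1, 0), w)$contact)
  # node on the disc surface moving inward: radial normal
  hit <- detect_contact(c(5, 0), c(-0.5, 0), w)
  expect_true(hit$contact)
  expect_equal(hit$normal, c(1, 0), tolerance = 1e-12)
  # moving away is not a contact
  expect_false(detect_contact(c(5, 0), c(0.5, 0), w)$contact)
  # a step crossing a flat wall is caught even from a distance
  wall <- cell_world(bands = band_obstacle(-10, 10, ylo = 1, yhi = 3))
  cross <- detect_contact(c(0, 0.5), c(0, 1), wall)
  expect_true(cross$contact)
  # after projection + clamp the node is not inside the wall (oracle:
  # the segment (0,0.5)->(0,1.5) intersects y = 1 at (0,1))
  pos <- celldeform:::resolve_contact_step(c(0, 0.5), c(0, 1), wall)
  expect_lte(pos[2], 1 + 1e-12)
})

test_that("clamping never leaves a node inside an obstacle", {
  set.seed(7)
  w <- cell_world(discs = disc_obstacle(c(0, 0), 5),
                  bands = band_obstacle(-20, 20, ylo = 8, yhi = 12),
                  channel = rough_channel(5, 1, 0.5, x_entry = 30, length = 40))
  for (k in 1:200) {
    x <- runif(2, c(-30, -15), c(80, 15))
    dx <- rnorm(2, sd = 2)
    pos <- celldeform:::resolve_contact_step(x, dx, w)
    depths <- vapply(celldeform:::world_evals(w, pos), `[[`, 0, "sdist")
    expect_lte(max(depths), 1e-9)
  }
})

test_that("colliding cells see each other's boundary normals", {
  a <- init_cell_2d(cell_params(), center = c(0, 0))
  b <- init_cell_2d(cell_params(), center = c(50, 0))
  expect_equal(nrow(cell_cell_contact(list(a, b))), 0)     # disjoint
  expect_equal(nrow(cell_cell_contact(list(a))), 0)        # single cell
  # mirror-symmetric overlap: contact normals antiparallel
  c1 <- init_cell_2d(cell_params(), center = c(-12, 0))
  c2 <- init_cell_2d(cell_params(), center = c(12, 0))
  cc <- cell_cell_contact(list(c1, c2))
  expect_gt(nrow(cc), 0)
  n1 <- colMeans(cc[cc$cell == 1, c("nx", "ny")])
  n2 <- colMeans(cc[cc$cell == 2, c("nx", "ny")])
  n1 <- n1 / sqrt(sum(n1^2)); n2 <- n2 / sqrt(sum(n2^2))
  expect_equal(sum(n1 * n2), -1, tolerance = 1e-6)
})

test_that("presets are well formed", {
  ch <- build_scenario("channel", channel = rough_channel(5, 0, 0))
  expect_equal(channel_wall(ch$channel, 30, "upper") -
                 channel_wall(ch$channel, 30, "lower"), 10)
  for (nm in c("channel", "cavity", "obstacle2d", "vessel", "free")) {
    sc <- build_scenario(nm)
    nodes <- rbind(sc$state$x, sc$state$x_n)
    for (i in seq_len(nrow(nodes))) {
      evs <- celldeform:::world_evals(sc$world, nodes[i, ])
      if (length(evs)) {
        expect_lte(max(vapply(evs, `[[`, 0, "sdist")), 0)
      }
    }
  }
  expect_length(build_scenario("vessel")$apertures, 2)
  expect_error(build_scenario("nope"), "unknown scenario")
})

test_that("no node penetrates deeper than tol across a full channel run", {
  traj <- channel_run(t_end = 0.6, record_every = 10)
  w <- traj$world
  worst <- 0
  for (f in seq_along(traj$times)) {
    nodes <- rbind(traj$membrane[f, , ], traj$nucleus[f, , ])
    for (i in seq_len(nrow(nodes))) {
      depths <- vapply(celldeform:::world_evals(w, nodes[i, ]), `[[`, 0, "sdist")
      worst <- max(worst, depths)
    }
  }
  expect_lte(worst, 1e-2)
})
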