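# Shared fixtures, built in code.

# unit field: one source at the origin with the reference diffusivity
ref_field <- function(rate = 1.2e6, D = 3600, pos = c(0, 0), ...) {
  signal_field(chemokine_source(pos, rate), D = D, ...)
}

unit_square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))

# closed unit cube surface (12 outward triangles)
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  tri <- rbind(
    c(1, 3, 2), c(2, 3, 4),      # z = 0 (outward -z)
    c(5, 6, 7), c(6, 8, 7),      # z = 1
    c(1, 2, 5), c(2, 6, 5),      # y = 0
    c(3, 7, 4), c(4, 7, 8),      # y = 1
    c(1, 5, 3), c(3, 5, 7),      # x = 0
    c(2, 4, 6), c(4, 8, 6))      # x = 1
  list(vertices = v, triangles = tri)
}

# brute-force grid oracle for the 2D rotation fit (coarse-to-fine)
grid_rotation_oracle <- function(state, res = 1e-6) {
  obj <- function(phi) {
    B <- rotation_matrix_2d(phi)
    d <- sweep(state$x, 2, colMeans(state$x))
    sum((state$x_ref %*% t(B) - d)^2)
  }
  phis <- seq(0, 2 * pi, by = 1e-3)
  best <- phis[which.min(vapply(phis, obj, 0))]
  fine <- seq(best - 2e-3, best + 2e-3, by = res)
  fine[which.min(vapply(fine, obj, 0))] %% (2 * pi)
}

rotation_objective_2d <- function(state, phi) {
  B <- rotation_matrix_2d(phi)
  d <- sweep(state$x, 2, colMeans(state$x))
  sum((state$x_ref %*% t(B) - d)^2)
}

rotation_objective_3d <- function(state, phi) {
  B <- rotation_matrix_3d(phi)
  d <- sweep(state$x, 2, colMeans(state$x))
  sum((state$x_ref %*% t(B) - d)^2)
}

# quick deterministic channel run
channel_run <- function(N = 30, dt = 1e-4, eta = 0, seed = 1, t_end = 2, ...) {
  sc <- build_scenario("channel", params = cell_params(N = N))
  run_scenario(sc, step_config(dt = dt, eta = eta, seed = seed,
                               t_end = t_end, ...))
}
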