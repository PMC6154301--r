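# Cell/nucleus state: node rings (2D) or spherical lattices (3D), the
# equilibrium offset vectors that encode the rest shape, and the rigid
# rotation (polarity) fit used to re-orient those offsets each step.

#' Cell model parameters
#'
#' Defaults are the package's reference parameter set for a migrating cell:
#' a 12.5 um cell with a 5 um nucleus in 2D (10 um / 8 um in 3D), cytoskeletal
#' deformation relaxation `alpha` = 250/h, nuclear relaxation `alpha_n` =
#' 2500/h, signal mobility `beta` = 60/h and chemokine secretion rate
#' `gamma_s` = 1.2e6 mol/(h um^3).
#'
#' @param R Cell radius (um).
#' @param R_n Nucleus radius (um); must satisfy `0 < R_n < R`.
#' @param N Number of membrane nodes (>= 3); each has a paired nucleus node.
#' @param M Number of latitude bands for the 3D lattice (>= 3).
#' @param alpha Cell deformation relaxation rate (1/h).
#' @param alpha_n Nucleus deformation relaxation rate (1/h).
#' @param beta Mobility of membrane nodes in response to the signal (1/h).
#' @param eta Random-walk amplitude (um per sqrt hour). The default (20)
#'   keeps node fluctuations around their equilibrium offsets below ~1 um
#'   (the stationary spread is `eta/sqrt(2*alpha)`) while giving the cell
#'   the stochastic transit-time dispersion of amoeboid migration; see the
#'   methods vignette.
#' @param gamma_s Default secretion rate for sources built from these
#'   parameters (mol/(h um^3)).
#' @param dimension 2 or 3; switches the radius defaults.
#' @return An object of class `cell_params`.
#' @export
#' @examples
#' cell_params()
#' cell_params(dimension = 3)
cell_params <- function(R = NULL, R_n = NULL, N = 30L, M = 30L,
                        alpha = 250, alpha_n = 2500, beta = 60,
                        eta = 20, gamma_s = 1.2e6, dimension = 2L) {
  dimension <- as.integer(dimension)
  stopifnot(dimension %in% c(2L, 3L))
  if (is.null(R)) R <- if (dimension == 2L) 12.5 else 10
  if (is.null(R_n)) R_n <- if (dimension == 2L) 5 else 8
  if (!(R > R_n && R_n > 0)) {
    stop("cell radii must satisfy R > R_n > 0", call. = FALSE)
  }
  N <- as.integer(N); M <- as.integer(M)
  if (N < 3L) stop("need at least N = 3 membrane nodes", call. = FALSE)
  if (dimension == 3L && M < 3L) stop("need at least M = 3 latitudes", call. = FALSE)
  if (alpha < 0 || alpha_n < 0 || beta < 0 || eta < 0 || gamma_s < 0) {
    stop("rates alpha, alpha_n, beta, eta, gamma_s must be non-negative",
         call. = FALSE)
  }
  structure(
    list(R = R, R_n = R_n, N = N, M = M, alpha = alpha, alpha_n = alpha_n,
         beta = beta, eta = eta, gamma_s = gamma_s, dimension = dimension),
    class = "cell_params"
  )
}

new_cell_state <- function(x, x_n, x_c, params, triangles = NULL) {
  xhat <- x - x_n
  xhat_n <- sweep(x_n, 2, x_c)
  structure(
    list(x = x, x_n = x_n, xhat = xhat, xhat_n = xhat_n, x_c = x_c,
         x_ref = sweep(x, 2, colMeans(x)), phi = if (ncol(x) == 2L) 0 else c(0, 0, 0),
         params = params, dimension = ncol(x), triangles = triangles),
    class = "cell_state"
  )
}

#' Initialise a circular 2D cell
#'
#' Membrane nodes are placed on a circle of radius `R` and nucleus nodes on a
#' concentric circle of radius `R_n`, node `i` at angle `2*pi*(i-1)/N`. The
#' equilibrium offsets are fixed from this configuration: `xhat_i` connects
#' nucleus node `i` to membrane node `i` and `xhat_n_i` the nucleus centre to
#' nucleus node `i`, so the initial shape is the exact rest shape.
#'
#' @param params A [cell_params()] with `dimension == 2`.
#' @param center Cell centre coordinate (um).
#' @return A `cell_state`.
#' @export
#' @examples
#' init_cell_2d(cell_params(N = 4, R = 1, R_n = 0.5))
init_cell_2d <- function(params = cell_params(), center = c(0, 0)) {
  stopifnot(inherits(params, "cell_params"), params$dimension == 2L,
            length(center) == 2L)
  ang <- 2 * pi * (seq_len(params$N) - 1) / params$N
  x <- cbind(center[1] + params$R * cos(ang), center[2] + params$R * sin(ang))
  x_n <- cbind(center[1] + params$R_n * cos(ang), center[2] + params$R_n * sin(ang))
  new_cell_state(x, x_n, x_c = as.numeric(center), params = params)
}

#' Initialise a spherical 3D cell
#'
#' Nodes are placed on a longitude/latitude lattice: `N` longitudes and
#' latitude angles `pi*(j-1)/M` running pole to pole. The degenerate pole
#' rings collapse to single points which are merged, giving `N*(M-1) + 2`
#' distinct nodes and a closed, consistently oriented triangulation (pole
#' fans plus split quads) used by the mesh volume/area metrics.
#'
#' @param params A [cell_params()] with `dimension == 3`.
#' @param center Cell centre coordinate (um), length 3.
#' @return A `cell_state` with a `triangles` index matrix.
#' @export
init_cell_3d <- function(params = cell_params(dimension = 3), center = c(0, 0, 0)) {
  stopifnot(inherits(params, "cell_params"), params$dimension == 3L,
            length(center) == 3L)
  lat <- sphere_lattice(params$N, params$M)
  x <- sweep(params$R * lat$units, 2, center, `+`)
  x_n <- sweep(params$R_n * lat$units, 2, center, `+`)
  st <- new_cell_state(x, x_n, x_c = as.numeric(center), params = params,
                       triangles = lat$triangles)
  # orient triangles outward (positive enclosed volume)
  if (mesh_volume(list(vertices = st$x, triangles = st$triangles),
                  check = FALSE) < 0) {
    st$triangles <- st$triangles[, c(1L, 3L, 2L)]
  }
  st
}

# Unit sphere lattice with merged poles; returns unit vectors and triangles.
sphere_lattice <- function(N, M) {
  phi <- 2 * pi * (seq_len(N) - 1) / N
  units <- rbind(c(0, 0, 1))            # north pole (j = 1)
  for (j in 2:M) {                      # interior latitude rings
    th <- pi * (j - 1) / M
    units <- rbind(units, cbind(cos(phi) * sin(th), sin(phi) * sin(th),
                                rep(cos(th), N)))
  }
  units <- rbind(units, c(0, 0, -1))    # south pole (j = M + 1)
  ring <- function(j) 1L + (j - 2L) * N + seq_len(N)  # j in 2..M
  south <- nrow(units)
  tri <- list()
  r1 <- ring(2)
  tri[[1]] <- cbind(1L, r1, c(r1[-1], r1[1]))
  if (M > 2) {
    for (j in 2:(M - 1)) {
      a <- ring(j); b <- ring(j + 1)
      a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
      tri[[length(tri) + 1L]] <- cbind(a, b, b2)
      tri[[length(tri) + 1L]] <- cbind(a, b2, a2)
    }
  }
  rM <- ring(M)
  tri[[length(tri) + 1L]] <- cbind(south, c(rM[-1], rM[1]), rM)
  list(units = units, triangles = do.call(rbind, tri))
}

#' 2D rotation matrix
#'
#' @param phi Rotation angle in radians (counter-clockwise about the origin).
#' @return A 2x2 rotation matrix.
#' @export
rotation_matrix_2d <- function(phi) {
  matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
}

#' 3D rotation matrix as the product Bx(phi_x) By(phi_y) Bz(phi_z)
#'
#' The factor order and the sign convention of the `y` factor (with
#' `-sin(phi_y)` in the (1,3) entry) follow the model's stated convention.
#'
#' @param phi Numeric length-3 vector of angles `(phi_x, phi_y, phi_z)`.
#' @return A 3x3 rotation matrix.
#' @export
rotation_matrix_3d <- function(phi) {
  cx <- cos(phi[1]); sx <- sin(phi[1])
  cy <- cos(phi[2]); sy <- sin(phi[2])
  cz <- cos(phi[3]); sz <- sin(phi[3])
  Bx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  By <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3)
  Bz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Bx %*% By %*% Bz
}

#' Fit the cell's in-plane rotation (polarity) angle
#'
#' Finds the angle minimising the summed squared distance between the
#' rotated reference shape (translated to the current membrane centroid) and
#' the current membrane nodes. Solved in closed form:
#' `phi = atan2(sum(xref x d), sum(xref . d))` with `d_i` the node offsets
#' from the centroid; a grid search is kept only as a test oracle.
#'
#' @param state A 2D `cell_state`.
#' @return Fitted angle in `[0, 2*pi)`.
#' @export
fit_rotation_2d <- function(state) {
  stopifnot(inherits(state, "cell_state"), state$dimension == 2L)
  d <- sweep(state$x, 2, colMeans(state$x))
  if (all(abs(d) < 1e-12)) {
    warning("all nodes coincident; returning phi = 0")
    return(0)
  }
  xr <- state$x_ref
  s_dot <- sum(xr * d)
  s_cross <- sum(xr[, 1] * d[, 2] - xr[, 2] * d[, 1])
  phi <- atan2(s_cross, s_dot)
  if (phi < 0) phi <- phi + 2 * pi
  phi
}

#' Fit the cell's 3D rotation angles
#'
#' Solves the orthogonal Procrustes problem (best proper rotation of the
#' translated reference shape onto the current nodes, via SVD) and extracts
#' the Euler angles in the model's `Bx By Bz` factor order.
#'
#' @param state A 3D `cell_state`.
#' @return Numeric length-3 vector `(phi_x, phi_y, phi_z)`.
#' @export
fit_rotation_3d <- function(state) {
  stopifnot(inherits(state, "cell_state"), state$dimension == 3L)
  d <- sweep(state$x, 2, colMeans(state$x))
  xr <- state$x_ref
  H <- t(xr) %*% d
  if (!all(is.finite(H)) || qr(d)$rank < 2) {
    warning("degenerate node configuration; returning identity rotation")
    return(c(0, 0, 0))
  }
  sv <- svd(H)
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  B <- sv$v %*% S %*% t(sv$u)
  euler_from_rotation(B)
}

# Extract (phi_x, phi_y, phi_z) with B = Bx(phi_x) By(phi_y) Bz(phi_z),
# By carrying -sin in its (1,3) entry. Assumes |phi_y| < pi/2 branch.
euler_from_rotation <- function(B) {
  phi_y <- asin(max(-1, min(1, -B[1, 3])))
  phi_x <- atan2(-B[2, 3], B[3, 3])
  phi_z <- atan2(-B[1, 2], B[1, 1])
  c(phi_x, phi_y, phi_z)
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("<cell_state: %dD, %d membrane + %d nucleus nodes>\n",
              x$dimension, nrow(x$x), nrow(x$x_n)))
  cat(sprintf("  centre: (%s) um\n", paste(signif(x$x_c, 4), collapse = ", ")))
  invisible(x)
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf(
    "<cell_params %dD> R=%g R_n=%g N=%d alpha=%g alpha_n=%g beta=%g eta=%g\n",
    x$dimension, x$R, x$R_n, x$N, x$alpha, x$alpha_n, x$beta, x$eta))
  invisible(x)
}
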