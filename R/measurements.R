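# Shape and transit metrics: polygon area/centroid (2D), triangulated mesh
# volume and surface area (3D, divergence-theorem form), channel
# penetration time and centroid speed traces.

#' Polygon area (shoelace)
#'
#' The signed shoelace sum is wrapped in an absolute value so that vertex
#' orientation never flips downstream metrics.
#'
#' @param vertices Matrix of ordered ring vertices (rows), >= 3.
#' @return Area in um^2.
#' @export
#' @examples
#' polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
polygon_area <- function(vertices) {
  vertices <- as.matrix(vertices)
  n <- nrow(vertices)
  if (n < 3L) stop("polygon needs at least 3 vertices", call. = FALSE)
  x <- vertices[, 1]; y <- vertices[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(0.5 * sum((xn + x) * (yn - y)))
}

#' Area-weighted polygon centroid
#'
#' @inheritParams polygon_area
#' @return Centroid coordinate; for degenerate (zero-area) rings the vertex
#'   mean, with a warning.
#' @export
polygon_centroid <- function(vertices) {
  vertices <- as.matrix(vertices)
  n <- nrow(vertices)
  if (n < 3L) stop("polygon needs at least 3 vertices", call. = FALSE)
  x <- vertices[, 1]; y <- vertices[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a2 <- sum(cr)
  if (abs(a2) < 1e-12) {
    warning("zero-area polygon; returning vertex mean")
    return(colMeans(vertices))
  }
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (3 * a2)
}

#' Volume of a closed triangulated surface
#'
#' Divergence-theorem estimate using the x-projection: per triangle the
#' un-normalised cross product's x-component times the mean vertex
#' x-coordinate, summed and divided by 6. Orientation matters: outward
#' triangles give a positive volume, inverting every triangle flips the
#' sign. With `check = TRUE` the y- and z-projection estimates are also
#' computed and a warning is raised when they disagree by more than 1%
#' (open or inconsistently oriented mesh).
#'
#' @param mesh A list with `vertices` (V x 3 matrix) and `triangles`
#'   (T x 3 index matrix), or a 3D `cell_state`.
#' @param check Cross-validate against the y/z projections.
#' @return Signed volume in um^3.
#' @export
mesh_volume <- function(mesh, check = TRUE) {
  m <- as_mesh(mesh)
  v <- m$vertices; tr <- m$triangles
  p1 <- v[tr[, 1], , drop = FALSE]
  e1 <- v[tr[, 2], , drop = FALSE] - p1
  e2 <- v[tr[, 3], , drop = FALSE] - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sums <- v[tr[, 1], , drop = FALSE] + v[tr[, 2], , drop = FALSE] +
    v[tr[, 3], , drop = FALSE]
  vx <- sum(cr[, 1] * sums[, 1]) / 6
  if (check) {
    vy <- sum(cr[, 2] * sums[, 2]) / 6
    vz <- sum(cr[, 3] * sums[, 3]) / 6
    ref <- max(abs(c(vx, vy, vz)), 1e-12)
    if (max(abs(c(vx - vy, vx - vz))) > 0.01 * ref) {
      warning("x/y/z divergence-theorem volume estimates disagree by > 1%; ",
              "the mesh may be open or inconsistently oriented")
    }
  }
  vx
}

#' Surface area of a triangulated mesh
#'
#' Half the summed norms of the triangle cross products; degenerate
#' (collinear) triangles contribute zero.
#'
#' @inheritParams mesh_volume
#' @return Area in um^2.
#' @export
mesh_surface_area <- function(mesh) {
  m <- as_mesh(mesh)
  v <- m$vertices; tr <- m$triangles
  p1 <- v[tr[, 1], , drop = FALSE]
  e1 <- v[tr[, 2], , drop = FALSE] - p1
  e2 <- v[tr[, 3], , drop = FALSE] - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sum(sqrt(rowSums(cr^2)))
}

as_mesh <- function(mesh) {
  if (inherits(mesh, "cell_state")) {
    stopifnot(mesh$dimension == 3L, !is.null(mesh$triangles))
    return(list(vertices = mesh$x, triangles = mesh$triangles))
  }
  stopifnot(is.list(mesh), !is.null(mesh$vertices), !is.null(mesh$triangles))
  mesh
}

# volume centroid of a closed mesh (tetrahedra against the vertex mean)
mesh_centroid <- function(vertices, triangles) {
  m0 <- colMeans(vertices)
  p1 <- sweep(vertices[triangles[, 1], , drop = FALSE], 2, m0)
  p2 <- sweep(vertices[triangles[, 2], , drop = FALSE], 2, m0)
  p3 <- sweep(vertices[triangles[, 3], , drop = FALSE], 2, m0)
  cr <- cbind(p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2],
              p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3],
              p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  vol6 <- rowSums(p1 * cr)
  tot <- sum(vol6)
  if (abs(tot) < 1e-12) return(m0)
  cent <- (p1 + p2 + p3) / 4           # tet centroid incl. origin at 0
  m0 + colSums(cent * vol6) / tot
}

# ray-crossing (along +x) containment test for a closed triangulated mesh
point_in_mesh <- function(p, vertices, triangles) {
  crossings <- 0L
  for (k in seq_len(nrow(triangles))) {
    a <- vertices[triangles[k, 1], ]
    b <- vertices[triangles[k, 2], ]
    cc <- vertices[triangles[k, 3], ]
    # solve p + t*(1,0,0) = a + u*(b-a) + v*(c-a)
    e1 <- b - a; e2 <- cc - a
    det <- e1[2] * e2[3] - e1[3] * e2[2]
    if (abs(det) < 1e-14) next
    rhs <- p[2:3] - a[2:3]
    u <- (rhs[1] * e2[3] - rhs[2] * e2[2]) / det
    v <- (e1[2] * rhs[2] - e1[3] * rhs[1]) / det
    if (u >= 0 && v >= 0 && u + v <= 1) {
      tt <- a[1] + u * e1[1] + v * e2[1] - p[1]
      if (tt > 0) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

# geodesic icosphere (test oracle helper for the mesh metrics)
icosphere <- function(subdiv = 3L, R = 1) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    edge_key <- function(i, j) paste(min(i, j), max(i, j))
    mid <- new.env()
    newf <- matrix(0L, 0, 3)
    for (k in seq_len(nrow(f))) {
      tri <- f[k, ]
      m <- integer(3)
      for (e in 1:3) {
        i <- tri[e]; j <- tri[if (e == 3) 1 else e + 1]
        key <- edge_key(i, j)
        if (is.null(mid[[key]])) {
          p <- (v[i, ] + v[j, ]) / 2
          p <- p / sqrt(sum(p^2))
          v <- rbind(v, p)
          mid[[key]] <- nrow(v)
        }
        m[e] <- mid[[key]]
      }
      newf <- rbind(newf,
                    c(tri[1], m[1], m[3]), c(tri[2], m[2], m[1]),
                    c(tri[3], m[3], m[2]), m)
    }
    f <- newf
  }
  list(vertices = R * v, triangles = f)
}

#' Channel penetration (transit) time
#'
#' The transit interval starts when the first membrane node passes the
#' entry plane (`x > x_entry`) and ends when the last membrane node has
#' passed the exit plane (`x > x_entry + length`). When the trajectory was
#' produced by [run_scenario()] the step-resolution entry/exit events
#' recorded by the integrator are used; otherwise both times are recovered
#' from the trajectory frames.
#'
#' @param traj A `cell_trajectory`.
#' @param channel A [rough_channel()]; defaults to the trajectory's own.
#' @return Transit time in hours, or `NA` if the cell never completed the
#'   transit.
#' @export
penetration_time <- function(traj, channel = NULL) {
  stopifnot(inherits(traj, "cell_trajectory"))
  channel <- channel %||% traj$channel
  if (is.null(channel)) return(NA_real_)
  use_events <- !is.null(traj$events$entry_time) && !is.null(traj$channel) &&
    identical(channel, traj$channel)
  if (use_events) {
    ent <- traj$events$entry_time
    ext <- traj$events$exit_time
  } else {
    xs <- traj$membrane[, , 1, drop = FALSE]
    dim(xs) <- dim(traj$membrane)[1:2]
    x_in <- channel$x_entry
    x_out <- channel$x_entry + channel$length
    ent_i <- which(apply(xs, 1, function(r) any(r > x_in)))[1]
    ext_i <- which(apply(xs, 1, function(r) all(r > x_out)))[1]
    ent <- if (is.na(ent_i)) NA_real_ else traj$times[ent_i]
    ext <- if (is.na(ext_i)) NA_real_ else traj$times[ext_i]
  }
  if (is.na(ent) || is.na(ext)) return(NA_real_)
  ext - ent
}

#' Membrane centroid per frame
#'
#' The node-mean centroid of the membrane ring. (The node mean, not the
#' area-weighted polygon centroid, so that thin fast protrusions -- e.g.
#' the runaway nodes near a singular source -- contribute to the centroid
#' speed the way they do to the mean node velocity.)
#'
#' @param traj A `cell_trajectory`.
#' @return Matrix of centroids, one row per frame.
#' @export
centroid_series <- function(traj) {
  stopifnot(inherits(traj, "cell_trajectory"))
  nf <- length(traj$times)
  d <- dim(traj$membrane)[3]
  out <- matrix(NA_real_, nf, d)
  for (f in seq_len(nf)) {
    out[f, ] <- colMeans(matrix(traj$membrane[f, , ], ncol = d))
  }
  out
}

#' Finite-difference speed of the cell centroid
#'
#' @param traj A `cell_trajectory` with at least 2 frames.
#' @return A tibble with `t` (frame midpoints, h), `speed` (um/h) and `x`,
#'   the centroid position at the midpoint (used to select in-channel
#'   frames).
#' @export
speed_series <- function(traj) {
  stopifnot(inherits(traj, "cell_trajectory"))
  if (length(traj$times) < 2L) stop("need at least 2 frames", call. = FALSE)
  cen <- centroid_series(traj)
  dtv <- diff(traj$times)
  disp <- sqrt(rowSums(diff(cen)^2))
  tibble::tibble(
    t = (head(traj$times, -1) + tail(traj$times, -1)) / 2,
    speed = disp / dtv,
    x = (head(cen[, 1], -1) + tail(cen[, 1], -1)) / 2)
}

#' Mean centroid speed while inside the channel
#'
#' Averages the finite-difference centroid speed over the frames whose
#' centroid lies within the channel's x-extent.
#'
#' @inheritParams penetration_time
#' @return Mean speed in um/h.
#' @export
in_channel_speed <- function(traj, channel = NULL) {
  channel <- channel %||% traj$channel
  stopifnot(!is.null(channel))
  ss <- speed_series(traj)
  inside <- ss$x >= channel$x_entry & ss$x < channel$x_entry + channel$length
  if (!any(inside)) return(NA_real_)
  mean(ss$speed[inside])
}
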