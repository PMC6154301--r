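# Rigid obstacles and contact handling. Obstacles are perfectly rigid and
# immobile; a node in contact loses the normal component of its displacement
# (tangential projection) and any residual interior point is clamped back to
# the boundary, so finite time steps cannot tunnel through walls.
#
# Two 2D primitives cover all presets:
#   * disc  (cx, cy, r)
#   * band  (x0, x1, ylo0, yhi0, eps_lo, eps_hi, omega): the region
#     x0 < x < x1,  ylo0 + eps_lo*sin(omega*x) < y < yhi0 + eps_hi*sin(omega*x)
#     with +/-BAND_INF for half-infinite walls. A trigonometric rough channel
#     is the complement of two such bands; flat rectangular walls are bands
#     with eps = 0.
# 3D uses spheres (cx, cy, cz, r).

BAND_INF <- 1e6

#' Disc obstacle
#' @param center Centre (um), length 2.
#' @param radius Radius (um).
#' @return A 1-row obstacle matrix usable in [cell_world()].
#' @export
disc_obstacle <- function(center, radius) {
  stopifnot(length(center) == 2L, radius > 0)
  matrix(c(center, radius), 1, 3,
         dimnames = list(NULL, c("cx", "cy", "r")))
}

#' Band (wall) obstacle with sinusoidal faces
#'
#' @param x0,x1 Horizontal extent (um).
#' @param ylo,yhi Base heights of the lower/upper faces (um); use `-Inf` /
#'   `Inf` for half-infinite walls.
#' @param eps_lo,eps_hi Sinusoidal amplitudes of the faces (um).
#' @param omega Spatial frequency (1/um).
#' @param faces If `TRUE` the band has solid vertical end faces at `x0` and
#'   `x1` (finite wall segments, e.g. vessel walls). If `FALSE` only the
#'   sinusoidal surfaces constrain motion: the wall boundary is the curve
#'   itself, nodes beyond the band's x-extent are unconstrained, and a node
#'   carried into the region is clamped back to the curve (channel walls).
#' @return A 1-row obstacle matrix usable in [cell_world()].
#' @export
band_obstacle <- function(x0, x1, ylo, yhi, eps_lo = 0, eps_hi = 0,
                          omega = 0, faces = TRUE) {
  stopifnot(x1 > x0, yhi > ylo)
  ylo <- max(ylo, -BAND_INF); yhi <- min(yhi, BAND_INF)
  matrix(c(x0, x1, ylo, yhi, eps_lo, eps_hi, omega, as.numeric(faces)), 1, 8,
         dimnames = list(NULL, c("x0", "x1", "ylo0", "yhi0",
                                 "eps_lo", "eps_hi", "omega", "faces")))
}

#' Rough channel specification
#'
#' A tube whose walls are `y = +/- (y0 + epsilon * sin(omega * x))`; the
#' amplitude `epsilon` and frequency `omega` control the wall roughness.
#'
#' @param y0 Half-width offset (um); must exceed `epsilon`.
#' @param epsilon Roughness amplitude (um), >= 0.
#' @param omega Roughness frequency (1/um), >= 0.
#' @param x_entry Entry plane (um).
#' @param length Channel length (um); default 60.
#' @return An object of class `rough_channel`.
#' @export
#' @examples
#' rough_channel(y0 = 5, epsilon = 1, omega = 0.5)
rough_channel <- function(y0 = 5, epsilon = 1, omega = 0.5,
                          x_entry = 0, length = 60) {
  stopifnot(y0 > epsilon, epsilon >= 0, omega >= 0, length > 0)
  structure(list(y0 = y0, epsilon = epsilon, omega = omega,
                 x_entry = x_entry, length = length),
            class = "rough_channel")
}

#' Wall height of a rough channel
#' @param spec A [rough_channel()].
#' @param x Axial coordinate(s) (um).
#' @param side `"upper"` or `"lower"`.
#' @return Wall `y` coordinate(s).
#' @export
channel_wall <- function(spec, x, side = c("upper", "lower")) {
  stopifnot(inherits(spec, "rough_channel"))
  side <- match.arg(side)
  y <- spec$y0 + spec$epsilon * sin(spec$omega * x)
  if (side == "upper") y else -y
}

#' Inward unit normal of a rough-channel wall
#'
#' For the upper wall the normal is `normalize(c(eps*omega*cos(omega*x), -1))`
#' (pointing into the channel); the lower wall is mirrored.
#'
#' @inheritParams channel_wall
#' @return Unit vector (length 2) or a 2-column matrix for vector `x`.
#' @export
wall_normal <- function(spec, x, side = c("upper", "lower")) {
  stopifnot(inherits(spec, "rough_channel"))
  side <- match.arg(side)
  slope <- spec$epsilon * spec$omega * cos(spec$omega * x)
  n <- if (side == "upper") cbind(slope, -1) else cbind(slope, 1)
  n <- n / sqrt(rowSums(n^2))
  if (length(x) == 1L) as.numeric(n) else n
}

# the two wall bands of a channel: the obstacle boundary is the wall curve
# itself (no end faces; nodes beyond the channel extent are unconstrained)
channel_bands <- function(spec) {
  rbind(
    band_obstacle(spec$x_entry, spec$x_entry + spec$length,
                  ylo = spec$y0, yhi = Inf,
                  eps_lo = spec$epsilon, omega = spec$omega, faces = FALSE),
    band_obstacle(spec$x_entry, spec$x_entry + spec$length,
                  ylo = -Inf, yhi = -spec$y0,
                  eps_hi = -spec$epsilon, omega = spec$omega, faces = FALSE)
  )
}

#' Rigid world of obstacles
#'
#' @param discs Matrix of disc obstacles (rows from [disc_obstacle()]).
#' @param bands Matrix of band obstacles (rows from [band_obstacle()]).
#' @param channel Optional [rough_channel()]; its two wall bands are added.
#' @param spheres Matrix of 3D sphere obstacles (cx, cy, cz, r).
#' @return An object of class `cell_world`.
#' @export
cell_world <- function(discs = NULL, bands = NULL, channel = NULL,
                       spheres = NULL) {
  if (!is.null(channel)) {
    stopifnot(inherits(channel, "rough_channel"))
    bands <- rbind(bands, channel_bands(channel))
  }
  structure(list(discs = discs, bands = bands, spheres = spheres,
                 channel = channel),
            class = "cell_world")
}

# ---- signed distance / normal per obstacle -------------------------------
# Returns list(sdist, normal, bpoint): sdist > 0 inside the obstacle
# (penetration depth), < 0 outside (minus the clearance); normal is the
# outward obstacle normal at the nearest boundary feature; bpoint the
# nearest boundary point. Curved band faces use the vertical nearest-point
# approximation (exact for flat faces, slope-bounded error otherwise).

disc_eval <- function(d, p) {
  d <- unname(d); p <- unname(p)
  v <- p - d[1:2]
  r <- sqrt(sum(v^2))
  n <- if (r > 0) v / r else c(1, 0)
  list(sdist = d[3] - r, normal = n, bpoint = d[1:2] + d[3] * n)
}

band_eval <- function(b, p) {
  b <- unname(b); p <- unname(p)
  x0 <- b[1]; x1 <- b[2]; ylo0 <- b[3]; yhi0 <- b[4]
  el <- b[5]; eh <- b[6]; om <- b[7]
  faces <- length(b) < 8L || b[8] > 0
  px <- p[1]; py <- p[2]
  ylo_at <- function(x) ylo0 + el * sin(om * x)
  yhi_at <- function(x) yhi0 + eh * sin(om * x)
  n_bot <- function(x) { v <- c(el * om * cos(om * x), -1); v / sqrt(sum(v^2)) }
  n_top <- function(x) { v <- c(-eh * om * cos(om * x), 1); v / sqrt(sum(v^2)) }
  if (px > x0 && px < x1) {
    ylo <- ylo_at(px); yhi <- yhi_at(px)
    if (py > ylo && py < yhi) {  # interior
      d <- c(if (faces) px - x0 else Inf, if (faces) x1 - px else Inf,
             py - ylo, yhi - py)
      k <- which.min(d)
      out <- switch(k,
        list(normal = c(-1, 0), bpoint = c(x0, py)),
        list(normal = c(1, 0), bpoint = c(x1, py)),
        list(normal = n_bot(px), bpoint = c(px, ylo)),
        list(normal = n_top(px), bpoint = c(px, yhi)))
      return(c(list(sdist = d[k]), out))
    }
    if (py <= ylo) {
      return(list(sdist = -(ylo - py), normal = n_bot(px), bpoint = c(px, ylo)))
    }
    return(list(sdist = -(py - yhi), normal = n_top(px), bpoint = c(px, yhi)))
  }
  if (!faces) {   # beyond the wall's x-extent: unconstrained
    return(list(sdist = -BAND_INF, normal = c(-1, 0), bpoint = p))
  }
  qx <- min(max(px, x0), x1)
  ylo <- ylo_at(qx); yhi <- yhi_at(qx)
  if (py >= ylo && py <= yhi) {
    n <- if (px <= x0) c(-1, 0) else c(1, 0)
    return(list(sdist = -abs(px - qx), normal = n, bpoint = c(qx, py)))
  }
  corner <- c(qx, min(max(py, ylo), yhi))
  v <- p - corner
  d <- sqrt(sum(v^2))
  n <- if (d > 0) v / d else c(if (px <= x0) -1 else 1, 0)
  list(sdist = -d, normal = n, bpoint = corner)
}

sphere_eval <- function(s, p) {
  s <- unname(s); p <- unname(p)
  v <- p - s[1:3]
  r <- sqrt(sum(v^2))
  n <- if (r > 0) v / r else c(1, 0, 0)
  list(sdist = s[4] - r, normal = n, bpoint = s[1:3] + s[4] * n)
}

world_evals <- function(world, p) {
  out <- list()
  if (length(p) == 2L) {
    if (!is.null(world$discs)) {
      for (i in seq_len(nrow(world$discs))) {
        out[[length(out) + 1L]] <- disc_eval(world$discs[i, ], p)
      }
    }
    if (!is.null(world$bands)) {
      for (i in seq_len(nrow(world$bands))) {
        out[[length(out) + 1L]] <- band_eval(world$bands[i, ], p)
      }
    }
  } else if (!is.null(world$spheres)) {
    for (i in seq_len(nrow(world$spheres))) {
      out[[length(out) + 1L]] <- sphere_eval(world$spheres[i, ], p)
    }
  }
  out
}

#' Remove the normal component of a displacement
#'
#' Contact kinematics: the displacement of a node on an obstacle boundary
#' may have no component along the obstacle normal, so `dx` is replaced by
#' `dx - (dx . n) n`. The result is orthogonal to `n` and never longer than
#' `dx` (obstacles slow migration down).
#'
#' @param dx Displacement vector.
#' @param n Unit normal; a non-unit vector is normalised with a warning.
#' @return The projected displacement.
#' @export
#' @examples
#' project_displacement(c(1, -1), c(0, 1))
project_displacement <- function(dx, n) {
  stopifnot(length(dx) == length(n))
  len <- sqrt(sum(n^2))
  if (abs(len - 1) > 1e-8) {
    warning("normal vector is not unit length; normalising")
    n <- n / len
  }
  dx - sum(dx * n) * n
}

#' Detect contact between a node and the rigid world
#'
#' Contact is reported when the node is within `tol` of (or inside) an
#' obstacle boundary while moving inward (`dx . n < 0`), or when the
#' proposed step lands inside an obstacle (swept crossing). Pure point
#' membership on the boundary almost never triggers in floating point,
#' hence the tolerance.
#'
#' @param x Node position.
#' @param dx Proposed displacement.
#' @param world A [cell_world()].
#' @param tol Contact tolerance (um); default 1e-2.
#' @return A list with `contact` (logical), and when in contact the outward
#'   obstacle `normal`, the `sdist` at `x`, and the nearest boundary point.
#' @export
detect_contact <- function(x, dx, world, tol = 1e-2) {
  stopifnot(inherits(world, "cell_world"), tol > 0)
  evs <- world_evals(world, x)
  best <- NULL
  for (ev in evs) {
    if (ev$sdist >= -tol && sum(dx * ev$normal) < 0) {
      if (is.null(best) || ev$sdist > best$sdist) best <- ev
    }
  }
  if (is.null(best)) {  # swept crossing of the proposed step
    evs2 <- world_evals(world, x + dx)
    for (k in seq_along(evs2)) {
      if (evs2[[k]]$sdist > 0) {
        if (is.null(best) || evs2[[k]]$sdist > best$sdist) best <- evs[[k]]
      }
    }
  }
  if (is.null(best)) return(list(contact = FALSE))
  list(contact = TRUE, normal = best$normal, sdist = best$sdist,
       bpoint = best$bpoint)
}

# Full per-node contact resolution used by the reference integrator:
# tangential projection at contact, then clamp any residual interior point
# to the nearest boundary. Mirrors the compiled engine exactly.
resolve_contact_step <- function(x, dx, world, tol = 1e-2) {
  if (is.null(world)) return(x + dx)
  for (ev in world_evals(world, x)) {
    if (ev$sdist >= -tol && sum(dx * ev$normal) < 0) {
      dx <- dx - sum(dx * ev$normal) * ev$normal
    }
  }
  cand <- x + dx
  for (ev in world_evals(world, cand)) {
    if (ev$sdist > 0) cand <- ev$bpoint
  }
  cand
}

#' Contact normals between cells
#'
#' For every membrane node of one cell lying inside, or within `tol` of,
#' another cell's membrane polygon, reports the outward normal of the other
#' cell's nearest boundary segment. The same tangential projection rule as
#' for rigid obstacles then applies to colliding cells.
#'
#' @param cells List of 2D `cell_state` objects.
#' @param tol Contact tolerance (um).
#' @return A tibble with columns `cell`, `node`, `other`, `nx`, `ny`;
#'   zero rows when there are no contacts.
#' @export
cell_cell_contact <- function(cells, tol = 1e-2) {
  stopifnot(is.list(cells), all(vapply(cells, inherits, TRUE, "cell_state")))
  res <- list()
  if (length(cells) >= 2L) {
    for (a in seq_along(cells)) {
      for (b in seq_along(cells)) {
        if (a == b) next
        poly <- cells[[b]]$x
        for (i in seq_len(nrow(cells[[a]]$x))) {
          p <- cells[[a]]$x[i, ]
          hit <- polygon_nearest(p, poly)
          if (hit$dist <= tol || point_in_polygon(p, poly)) {
            res[[length(res) + 1L]] <- tibble::tibble(
              cell = a, node = i, other = b,
              nx = hit$normal[1], ny = hit$normal[2])
          }
        }
      }
    }
  }
  if (length(res)) do.call(rbind, res) else {
    tibble::tibble(cell = integer(), node = integer(), other = integer(),
                   nx = numeric(), ny = numeric())
  }
}

# nearest segment of a CCW polygon and its outward normal
polygon_nearest <- function(p, poly) {
  n <- nrow(poly)
  best <- list(dist = Inf, normal = c(NA_real_, NA_real_))
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    d <- point_segment_distance(p, a, b)
    if (d < best$dist) {
      e <- b - a
      nv <- c(e[2], -e[1])      # outward for counter-clockwise ordering
      nv <- nv / sqrt(sum(nv^2))
      best <- list(dist = d, normal = nv)
    }
  }
  best
}
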