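# Chemoattractant fields built from Green's fundamental solutions of the
# steady diffusion equation -D * Laplacian(c) = gamma_S * delta(x - x_S).

#' Point source of a chemoattractant
#'
#' A secreting point source. Sources can be gated in time (`t_on`, `t_off`)
#' and are permanently deactivated once a cell engulfs them (see
#' [consume_sources()]).
#'
#' @param position Numeric coordinate vector (um), length 2 or 3.
#' @param rate Secretion rate \eqn{\gamma_S} in mol/(h um^3); must be >= 0.
#' @param t_on,t_off Activity window in hours; the source contributes for
#'   `t_on <= t < t_off`.
#' @param active Logical; inactive sources contribute zero to the field and
#'   its gradient.
#' @return An object of class `chemokine_source`.
#' @export
#' @examples
#' chemokine_source(c(90, 0), rate = 1.2e6)
chemokine_source <- function(position, rate, t_on = 0, t_off = Inf,
                             active = TRUE) {
  position <- as.numeric(position)
  stopifnot(length(position) %in% c(2L, 3L), is.finite(position))
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0) {
    stop("secretion `rate` must be a single non-negative number", call. = FALSE)
  }
  structure(
    list(position = position, rate = rate, t_on = t_on, t_off = t_off,
         active = isTRUE(active)),
    class = "chemokine_source"
  )
}

#' Chemoattractant field from point sources
#'
#' The field is the superposition of the free-space fundamental solutions of
#' the steady diffusion equation for each active source: logarithmic in 2D,
#' and in 3D either the form proportional to \eqn{1/r^2} (`greens_3d =
#' "paper"`, the package default) or the standard \eqn{1/(4 \pi D r)}
#' fundamental solution (`greens_3d = "physical"`).
#'
#' @param sources A `chemokine_source` or a list of them.
#' @param D Diffusivity of the chemokine in um^2/h; must be > 0.
#' @param dimension 2 or 3. Defaults to the dimension of the first source.
#' @param greens_3d Which 3D kernel to use; ignored in 2D.
#' @return An object of class `signal_field`.
#' @export
signal_field <- function(sources, D = 3600, dimension = NULL,
                         greens_3d = c("paper", "physical")) {
  if (inherits(sources, "chemokine_source")) sources <- list(sources)
  stopifnot(is.list(sources),
            all(vapply(sources, inherits, TRUE, "chemokine_source")))
  if (!is.numeric(D) || length(D) != 1L || D <= 0) {
    stop("diffusivity `D` must be a single positive number", call. = FALSE)
  }
  if (is.null(dimension)) {
    dimension <- if (length(sources)) length(sources[[1L]]$position) else 2L
  }
  dimension <- as.integer(dimension)
  stopifnot(dimension %in% c(2L, 3L))
  for (s in sources) stopifnot(length(s$position) == dimension)
  structure(
    list(sources = sources, D = D, dimension = dimension,
         greens_3d = match.arg(greens_3d)),
    class = "signal_field"
  )
}

# sources active at time t (activity window and not consumed)
active_sources <- function(field, t = 0) {
  Filter(function(s) s$active && t >= s$t_on && t < s$t_off, field$sources)
}

#' Concentration of the chemoattractant field
#'
#' Evaluates the superposed fundamental solutions at a point. In 2D the
#' single-source value is \eqn{-\gamma_S/(2 \pi D) \ln \|x - x_S\|}; note the
#' logarithm goes negative for distances beyond 1 um, which is a known
#' property of the free-space 2D kernel -- only the gradient enters the cell
#' dynamics. In 3D the default kernel is \eqn{\gamma_S / (4 \pi D \|x - x_S\|^2)}.
#'
#' @param field A [signal_field()].
#' @param x Evaluation point (um); must not coincide with an active source.
#' @param t Time in hours (gates sources by their activity window).
#' @return Scalar concentration.
#' @export
#' @examples
#' f <- signal_field(chemokine_source(c(0, 0), 1.2e6), D = 3600)
#' concentration(f, c(10, 0))
concentration <- function(field, x, t = 0) {
  stopifnot(inherits(field, "signal_field"))
  x <- as.numeric(x)
  stopifnot(length(x) == field$dimension)
  total <- 0
  for (s in active_sources(field, t)) {
    r <- sqrt(sum((x - s$position)^2))
    if (r == 0) {
      stop("singular evaluation: point coincides with an active source",
           call. = FALSE)
    }
    total <- total + if (field$dimension == 2L) {
      -s$rate / (2 * pi * field$D) * log(r)
    } else if (field$greens_3d == "paper") {
      s$rate / (4 * pi * field$D * r^2)
    } else {
      s$rate / (4 * pi * field$D * r)
    }
  }
  total
}

#' IMEX gradient of the chemoattractant field
#'
#' The linear-implicit gradient used by the time integrator: per source the
#' 2D drift direction is evaluated at the new position while the singular
#' denominator is frozen at the old position,
#' \deqn{\nabla c = \gamma_S (x_S - x_{new}) / (\pi D \|x_S - x_{old}\|^2).}
#' The denominator constant \eqn{\pi D} is used as such even though
#' differentiating the 2D kernel gives \eqn{2 \pi D}; the drift is
#' phenomenological and the mobility \eqn{\beta} absorbs constant factors.
#' A regression test pins this factor-2 convention. In 3D the same old/new
#' split is applied to the selected kernel: the default \eqn{1/r^2} form
#' yields \eqn{2 \gamma_S (x_S - x_{new}) / (4 \pi D \|x_S - x_{old}\|^4)},
#' the physical form \eqn{\gamma_S (x_S - x_{new}) / (4 \pi D \|x_S - x_{old}\|^3)}.
#'
#' @inheritParams concentration
#' @param x_new,x_old New (implicit) and old (explicit) evaluation points.
#' @return Gradient vector, same length as `x_new`.
#' @export
imex_gradient <- function(field, x_new, x_old = x_new, t = 0) {
  stopifnot(inherits(field, "signal_field"))
  x_new <- as.numeric(x_new); x_old <- as.numeric(x_old)
  stopifnot(length(x_new) == field$dimension,
            length(x_old) == field$dimension)
  g <- numeric(field$dimension)
  for (s in active_sources(field, t)) {
    r_old <- sqrt(sum((x_old - s$position)^2))
    if (r_old == 0) {
      stop("singular evaluation: old position coincides with an active source",
           call. = FALSE)
    }
    coef <- imex_gradient_coef(field, s$rate, r_old)
    g <- g + coef * (s$position - x_new)
  }
  g
}

# scalar coefficient gamma-tilde such that grad c = coef * (x_S - x_new)
imex_gradient_coef <- function(field, rate, r_old) {
  if (field$dimension == 2L) {
    rate / (pi * field$D * r_old^2)
  } else if (field$greens_3d == "paper") {
    2 * rate / (4 * pi * field$D * r_old^4)
  } else {
    rate / (4 * pi * field$D * r_old^3)
  }
}

#' Deactivate sources engulfed by a cell
#'
#' A source whose position lies inside the closed cell boundary polygon is
#' consumed: it is marked inactive and never reactivates. Points exactly on
#' the boundary count as inside (tie-break convention).
#'
#' @param field A [signal_field()].
#' @param cell_boundary Matrix of polygon vertices (rows, ordered ring).
#' @return The field with consumed sources deactivated, plus an attribute
#'   `consumed` holding the indices deactivated by this call.
#' @export
consume_sources <- function(field, cell_boundary) {
  stopifnot(inherits(field, "signal_field"))
  cell_boundary <- as.matrix(cell_boundary)
  if (nrow(cell_boundary) < 3L) {
    stop("cell boundary must be a closed polygon with >= 3 vertices",
         call. = FALSE)
  }
  if (any(!is.finite(cell_boundary))) {
    stop("cell boundary contains non-finite vertices", call. = FALSE)
  }
  consumed <- integer(0)
  for (k in seq_along(field$sources)) {
    s <- field$sources[[k]]
    if (!s$active) next
    if (point_in_polygon(s$position[1:2], cell_boundary[, 1:2, drop = FALSE])) {
      field$sources[[k]]$active <- FALSE
      consumed <- c(consumed, k)
    }
  }
  attr(field, "consumed") <- consumed
  field
}

# Even-odd ray crossing containment; points on the boundary count as inside.
point_in_polygon <- function(p, poly, tol = 1e-9) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # boundary tie-break: distance from p to segment (i, j)
    if (point_segment_distance(p, c(xi, yi), c(xj, yj)) <= tol) return(TRUE)
    if ((yi > p[2]) != (yj > p[2])) {
      xcross <- xi + (p[2] - yi) / (yj - yi) * (xj - xi)
      if (p[1] < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  tt <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((a + tt * ab - p)^2))
}
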