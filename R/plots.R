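# Plotting. Figure conventions: cell membrane red, nucleus green,
# obstacles gray, sources as asterisks.

#' Plot a trajectory snapshot
#'
#' Draws the membrane and nucleus polygons at one frame together with the
#' obstacles and sources of the trajectory's world.
#'
#' @param traj A `cell_trajectory`.
#' @param frame Frame index (default the last frame).
#' @return A ggplot object.
#' @export
plot_snapshot <- function(traj, frame = length(traj$times)) {
  stopifnot(inherits(traj, "cell_trajectory"))
  ring <- function(arr) {
    v <- arr[frame, , 1:2]
    tibble::tibble(x = c(v[, 1], v[1, 1]), y = c(v[, 2], v[1, 2]))
  }
  g <- ggplot2::ggplot() +
    world_layers(traj$world) +
    ggplot2::geom_polygon(data = ring(traj$membrane),
                          ggplot2::aes(x = .data$x, y = .data$y),
                          fill = "red", alpha = 0.35, colour = "red3") +
    ggplot2::geom_polygon(data = ring(traj$nucleus),
                          ggplot2::aes(x = .data$x, y = .data$y),
                          fill = "green3", alpha = 0.6, colour = "green4") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("t = %.3f h", traj$times[frame])) +
    ggplot2::theme_minimal()
  g + source_layer(traj$field)
}

world_layers <- function(world) {
  if (is.null(world)) return(list())
  layers <- list()
  if (!is.null(world$discs)) {
    th <- seq(0, 2 * pi, length.out = 90)
    for (i in seq_len(nrow(world$discs))) {
      d <- world$discs[i, ]
      layers[[length(layers) + 1L]] <- ggplot2::geom_polygon(
        data = tibble::tibble(x = d[1] + d[3] * cos(th),
                              y = d[2] + d[3] * sin(th)),
        ggplot2::aes(x = .data$x, y = .data$y), fill = "gray60")
    }
  }
  if (!is.null(world$bands)) {
    for (i in seq_len(nrow(world$bands))) {
      b <- world$bands[i, ]
      xs <- seq(b[1], b[2], length.out = 120)
      ylo <- pmax(b[3] + b[5] * sin(b[7] * xs), -50)
      yhi <- pmin(b[4] + b[6] * sin(b[7] * xs), 50)
      layers[[length(layers) + 1L]] <- ggplot2::geom_ribbon(
        data = tibble::tibble(x = xs, ymin = ylo, ymax = yhi),
        ggplot2::aes(x = .data$x, ymin = .data$ymin, ymax = .data$ymax),
        fill = "gray60")
    }
  }
  layers
}

source_layer <- function(field) {
  if (is.null(field) || !length(field$sources)) return(list())
  pos <- do.call(rbind, lapply(field$sources, function(s) s$position[1:2]))
  ggplot2::geom_point(
    data = tibble::tibble(x = pos[, 1], y = pos[, 2]),
    ggplot2::aes(x = .data$x, y = .data$y),
    shape = 8, colour = "blue", size = 3)
}

#' Autoplot methods
#'
#' For a `cell_trajectory`: `type = "snapshot"` (default, final frame),
#' `"path"` (centroid path over the world) or `"speed"` (centroid speed
#' trace). For an `mc_result`: `type = "hist"`, `"cdf"` or `"scatter"`
#' (per-parameter scatter of transit time against the sampled value).
#'
#' @param object The object to plot.
#' @param type Plot flavour, see Details.
#' @param ... Passed on (e.g. `frame` for snapshots).
#' @return A ggplot object.
#' @name autoplot
NULL

#' @rdname autoplot
#' @export
autoplot.cell_trajectory <- function(object,
                                     type = c("snapshot", "path", "speed"),
                                     ...) {
  type <- match.arg(type)
  if (type == "snapshot") return(plot_snapshot(object, ...))
  if (type == "path") {
    cen <- centroid_series(object)
    return(ggplot2::ggplot() +
             world_layers(object$world) +
             ggplot2::geom_path(
               data = tibble::tibble(x = cen[, 1], y = cen[, 2]),
               ggplot2::aes(x = .data$x, y = .data$y), colour = "red3") +
             source_layer(object$field) +
             ggplot2::coord_equal() +
             ggplot2::labs(x = "x (µm)", y = "y (µm)") +
             ggplot2::theme_minimal())
  }
  ss <- speed_series(object)
  ggplot2::ggplot(ss, ggplot2::aes(x = .data$t, y = .data$speed)) +
    ggplot2::geom_line(colour = "red3") +
    ggplot2::labs(x = "t (h)", y = "centroid speed (µm/h)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot
#' @export
autoplot.mc_result <- function(object, type = c("hist", "cdf", "scatter"),
                               ...) {
  type <- match.arg(type)
  if (type == "hist") {
    return(ggplot2::ggplot(object$dist$hist,
                           ggplot2::aes(x = .data$mid, y = .data$rel_freq)) +
             ggplot2::geom_col(fill = "steelblue", colour = "white") +
             ggplot2::labs(x = "penetration time τ (h)",
                           y = "relative frequency") +
             ggplot2::theme_minimal())
  }
  if (type == "cdf") {
    return(ggplot2::ggplot(object$dist$cdf_points,
                           ggplot2::aes(x = .data$tau, y = .data$p)) +
             ggplot2::geom_step(colour = "steelblue") +
             ggplot2::labs(x = "penetration time τ (h)",
                           y = "P(T ≤ τ)") +
             ggplot2::theme_minimal())
  }
  df <- object$samples[object$samples$status == "ok", ]
  long <- do.call(rbind, lapply(names(object$r), function(nm) {
    tibble::tibble(parameter = nm, value = df[[nm]], tau = df$tau)
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$tau)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8, colour = "steelblue") +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::labs(x = "sampled value", y = "penetration time τ (h)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
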