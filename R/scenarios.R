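# Scenario presets. Each preset fixes the full study conditions: cell
# parameters, world geometry, source configuration and integration
# horizon. The channel preset is the reference transmigration experiment
# used by the transit-time and Monte Carlo analyses.
#
# The channel source strength and position are the preset's calibration
# constants: the geometry of the transmigration experiment (where the cell
# starts and where the attractant sits) is a scenario choice, fixed once so
# that the deterministic default-parameter transit reproduces the reference
# transit time (~0.36 h) and in-channel speed (~200 um/h) for a 60 um
# capillary-scale channel. See the methods vignette.

CHANNEL_SOURCE_X <- 105
CHANNEL_SOURCE_RATE <- 8.7e6
CHANNEL_START_X <- -20

#' Build a preset scenario
#'
#' Available presets:
#' \describe{
#'   \item{`channel`}{A cell squeezing through a 60 um trigonometric rough
#'     channel (half-width 5 um, default roughness `epsilon = 1` um,
#'     `omega = 0.5` /um) toward a source beyond the exit. The reference
#'     transmigration experiment.}
#'   \item{`cavity`}{Two disc obstacles forming a pore narrower than the
#'     nucleus; the nucleus must deform to pass.}
#'   \item{`obstacle2d`}{A cell crawling along a rigid disc obstacle toward
#'     a weak source (secretion rate 2e5).}
#'   \item{`obstacle3d`}{The 3D analogue with a spherical obstacle.}
#'   \item{`vessel`}{Two parallel rough walls with an entry and an exit
#'     aperture: intravasation, transit and extravasation of a vessel.}
#'   \item{`free`}{An unobstructed cell and a nearby source; used for
#'     shape-recovery studies.}
#' }
#'
#' @param name Preset name.
#' @param params Optional [cell_params()] override.
#' @param channel Optional [rough_channel()] override (channel preset).
#' @return An object of class `cell_scenario`.
#' @export
#' @examples
#' sc <- build_scenario("channel")
#' sc$channel
build_scenario <- function(name, params = NULL, channel = NULL) {
  switch(
    name,
    channel = {
      p <- params %||% cell_params()
      ch <- channel %||% rough_channel(y0 = 5, epsilon = 1, omega = 0.5,
                                       x_entry = 0, length = 60)
      new_scenario(
        name = "channel", params = p,
        state = init_cell_2d(p, center = c(CHANNEL_START_X, 0)),
        field = signal_field(chemokine_source(c(CHANNEL_SOURCE_X, 0),
                                              CHANNEL_SOURCE_RATE)),
        world = cell_world(channel = ch), channel = ch,
        dt = 1e-4, t_end = 3.7, stop_after_exit = TRUE)
    },
    cavity = {
      p <- params %||% cell_params()
      discs <- rbind(disc_obstacle(c(0, 16), 12), disc_obstacle(c(0, -16), 12))
      new_scenario(
        name = "cavity", params = p,
        state = init_cell_2d(p, center = c(-26, 0)),
        field = signal_field(chemokine_source(c(26, 0), 5e6)),
        world = cell_world(discs = discs),
        dt = 1e-4, t_end = 1.5)
    },
    obstacle2d = {
      p <- params %||% cell_params()
      new_scenario(
        name = "obstacle2d", params = p,
        state = init_cell_2d(p, center = c(-26, -4)),
        field = signal_field(chemokine_source(c(18, 6), 2e5)),
        world = cell_world(discs = disc_obstacle(c(0, 0), 10)),
        dt = 1e-4, t_end = 3)
    },
    obstacle3d = {
      p <- params %||% cell_params(dimension = 3)
      new_scenario(
        name = "obstacle3d", params = p,
        state = init_cell_3d(p, center = c(-22, 0, 0)),
        field = signal_field(chemokine_source(c(14, 0, 0), 2e9)),
        world = structure(list(spheres = matrix(c(0, 0, 0, 8), 1, 4),
                               discs = NULL, bands = NULL, channel = NULL),
                          class = "cell_world"),
        dt = 0.01, t_end = 1.5)
    },
    vessel = {
      p <- params %||% cell_params()
      eps <- 0.8; om <- 0.5
      bands <- rbind(
        band_obstacle(-45, -9, ylo = -9, yhi = -5, eps, eps, om),
        band_obstacle(9, 45, ylo = -9, yhi = -5, eps, eps, om),
        band_obstacle(-45, -9, ylo = 5, yhi = 9, eps, eps, om),
        band_obstacle(9, 45, ylo = 5, yhi = 9, eps, eps, om))
      sc <- new_scenario(
        name = "vessel", params = p,
        state = init_cell_2d(p, center = c(-10, -23)),
        field = signal_field(chemokine_source(c(0, 50), 5.5e6)),
        world = cell_world(bands = bands),
        dt = 1e-4, t_end = 3.7)
      sc$apertures <- list(
        list(wall = "lower", x = c(-9, 9)),
        list(wall = "upper", x = c(-9, 9)))
      sc
    },
    free = {
      p <- params %||% cell_params()
      new_scenario(
        name = "free", params = p,
        state = init_cell_2d(p, center = c(0, 0)),
        field = signal_field(chemokine_source(c(35, 0), 1.2e6)),
        world = cell_world(),
        dt = 1e-4, t_end = 1.5)
    },
    stop("unknown scenario '", name, "'; available: channel, cavity, ",
         "obstacle2d, obstacle3d, vessel, free", call. = FALSE)
  )
}

new_scenario <- function(name, params, state, field, world, channel = NULL,
                         dt = NULL, t_end = NULL, stop_after_exit = FALSE) {
  structure(list(name = name, params = params, state = state, field = field,
                 world = world, channel = channel, dt = dt, t_end = t_end,
                 stop_after_exit = stop_after_exit),
            class = "cell_scenario")
}

#' @export
print.cell_scenario <- function(x, ...) {
  cat(sprintf("<cell_scenario '%s'> %dD, %d sources, dt = %g h\n",
              x$name, x$state$dimension,
              length(x$field$sources %||% list()), x$dt %||% NA))
  invisible(x)
}

# Apply Monte Carlo parameter overrides to a scenario. Recognised names:
# D (field diffusivity), beta, alpha, alpha_n, eta (cell parameters),
# epsilon, omega (channel roughness; rebuilds the wall bands).
apply_param_overrides <- function(scenario, overrides) {
  overrides <- as.list(overrides)
  p <- scenario$params
  for (nm in intersect(names(overrides), c("alpha", "alpha_n", "beta", "eta"))) {
    p[[nm]] <- overrides[[nm]]
  }
  scenario$params <- p
  scenario$state$params <- p
  if (!is.null(overrides$D)) scenario$field$D <- overrides$D
  if ((!is.null(overrides$epsilon) || !is.null(overrides$omega))) {
    if (is.null(scenario$channel)) {
      stop("scenario has no channel; epsilon/omega overrides do not apply",
           call. = FALSE)
    }
    ch <- scenario$channel
    ch$epsilon <- overrides$epsilon %||% ch$epsilon
    ch$omega <- overrides$omega %||% ch$omega
    ch <- rough_channel(ch$y0, ch$epsilon, ch$omega, ch$x_entry, ch$length)
    scenario$channel <- ch
    nonchannel <- NULL
    scenario$world <- cell_world(discs = scenario$world$discs,
                                 bands = nonchannel, channel = ch)
  }
  scenario
}
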