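# IMEX Euler time stepping of the coupled membrane/nucleus SDE system.
#
# Update order within a step is fixed by the scheme: (1) fit the rotation,
# (2) advance the membrane (linear-implicit relaxation and chemotactic
# terms, explicit singular denominator), (3) advance the nucleus against
# the already-advanced membrane, (4) refresh the nucleus centre, (5) check
# source consumption. Contact projection is applied to the realised
# displacement of every node, after the noise, so obstacles also constrain
# random motion.

#' Time-stepping configuration
#'
#' @param dt Time step in hours; `NULL` uses the scenario default
#'   (1e-4 h in 2D, 0.01 h in 3D).
#' @param eta Random-walk amplitude override (um/sqrt(h)); `NULL` uses the
#'   cell parameter value.
#' @param seed RNG seed for reproducible noise; `NULL` leaves the RNG state
#'   untouched.
#' @param t_end Integration horizon in hours; `NULL` uses the scenario
#'   default.
#' @param record_every Record a trajectory frame every this many steps;
#'   `0` records only the first and final state.
#' @param tol Contact tolerance in um.
#' @param stop_after_exit Stop as soon as the whole cell has exited the
#'   channel (used by transit-time studies); `NULL` uses the scenario
#'   default.
#' @param relax_tail Extra integration time (h) after all sources are
#'   consumed, letting the shape relax (default 0.05 h, i.e. 12.5
#'   relaxation times at alpha = 250/h).
#' @param explicit_gradient Evaluate the chemotactic term fully at the old
#'   position instead of the default old/new split (both are first order).
#' @return An object of class `step_config`.
#' @export
step_config <- function(dt = NULL, eta = NULL, seed = NULL, t_end = NULL,
                        record_every = 25L, tol = 1e-2,
                        stop_after_exit = NULL, relax_tail = 0.05,
                        explicit_gradient = FALSE) {
  if (!is.null(dt) && dt <= 0) stop("dt must be > 0", call. = FALSE)
  structure(list(dt = dt, eta = eta, seed = seed, t_end = t_end,
                 record_every = as.integer(record_every), tol = tol,
                 stop_after_exit = stop_after_exit, relax_tail = relax_tail,
                 explicit_gradient = isTRUE(explicit_gradient)),
            class = "step_config")
}

#' Wiener process increment
#'
#' Independent samples from a normal distribution with zero mean and
#' variance `dt`, one per component.
#'
#' @param dim Number of components.
#' @param dt Time step (h); must be > 0.
#' @return Numeric vector of length `dim`.
#' @export
wiener_increment <- function(dim, dt) {
  stopifnot(dt > 0, dim >= 1)
  rnorm(dim, mean = 0, sd = sqrt(dt))
}

# chemotactic coefficients for all membrane nodes against all active
# sources: returns G (per-node coefficient sum), sterm (per-node
# coefficient-weighted source positions) and eterm (explicit form)
chemo_terms <- function(field, x_old, t) {
  N <- nrow(x_old); d <- ncol(x_old)
  G <- numeric(N)
  sterm <- matrix(0, N, d)
  eterm <- matrix(0, N, d)
  for (s in active_sources(field, t)) {
    dv <- sweep(-x_old, 2, s$position, `+`)    # x_S - x_old
    r <- sqrt(rowSums(dv^2))
    if (any(r == 0)) {
      stop("singular evaluation: node coincides with an active source",
           call. = FALSE)
    }
    coef <- vapply(r, function(ri) imex_gradient_coef(field, s$rate, ri), 0)
    G <- G + coef
    sterm <- sterm + coef * matrix(s$position, N, d, byrow = TRUE)
    eterm <- eterm + coef * dv
  }
  list(G = G, sterm = sterm, eterm = eterm)
}

#' Advance the membrane nodes by one IMEX step
#'
#' Solves, per node, the linear-implicit update
#' `(1 + dt*alpha + dt*beta*G) x_new = x_old + dt*(beta*sum(coef*x_S) +
#' alpha*(x_n + B(phi) xhat)) + eta*dW`, where `G = sum(coef)` uses the
#' old-position singular denominators, then applies contact projection to
#' the realised displacement. The rotation `phi` must already be fitted
#' (it is read from `state$phi`).
#'
#' @param state A `cell_state`.
#' @param field A [signal_field()] (or `NULL` for no signal).
#' @param world A [cell_world()] (or `NULL`).
#' @param cfg A [step_config()] with a concrete `dt`.
#' @param t Current time (h).
#' @return Updated membrane node matrix.
#' @export
step_membrane <- function(state, field, world, cfg, t = 0) {
  p <- state$params
  dt <- cfg$dt
  eta <- if (is.null(cfg$eta)) p$eta else cfg$eta
  N <- nrow(state$x); d <- state$dimension
  B <- if (d == 2L) rotation_matrix_2d(state$phi) else rotation_matrix_3d(state$phi)
  target <- state$x_n + state$xhat %*% t(B)
  if (!is.null(field)) {
    ct <- chemo_terms(field, state$x, t)
  } else {
    ct <- list(G = numeric(N), sterm = matrix(0, N, d), eterm = matrix(0, N, d))
  }
  noise <- if (eta > 0) {
    eta * sqrt(dt) * matrix(rnorm(N * d), ncol = d, byrow = TRUE)
  } else matrix(0, N, d)
  if (cfg$explicit_gradient) {
    denom <- rep(1 + dt * p$alpha, N)
    rhs <- state$x + dt * (p$beta * ct$eterm + p$alpha * target) + noise
  } else {
    denom <- 1 + dt * p$alpha + dt * p$beta * ct$G
    rhs <- state$x + dt * (p$beta * ct$sterm + p$alpha * target) + noise
  }
  prop <- rhs / denom
  disp <- prop - state$x
  if (any(sqrt(rowSums(disp^2)) > p$R)) {
    stop("integration unstable: node displacement exceeded the cell radius ",
         "in one step; reduce dt", call. = FALSE)
  }
  out <- prop
  if (!is.null(world)) {
    for (i in seq_len(N)) {
      out[i, ] <- resolve_contact_step(state$x[i, ], disp[i, ], world, cfg$tol)
    }
  }
  out
}

#' Advance the nucleus nodes by one IMEX step
#'
#' Per node: `(1 + dt*alpha_n) x_n_new = x_n_old + dt*(-alpha*(x_n_old +
#' B xhat - x_mem_new) + alpha_n*(x_c + B xhat_n)) + eta*dW`, followed by
#' contact projection. The membrane must already be advanced.
#'
#' @inheritParams step_membrane
#' @param updated_membrane Membrane node matrix at the new time level.
#' @return Updated nucleus node matrix.
#' @export
step_nucleus <- function(state, updated_membrane, cfg, world = NULL, t = 0) {
  p <- state$params
  dt <- cfg$dt
  eta <- if (is.null(cfg$eta)) p$eta else cfg$eta
  N <- nrow(state$x_n); d <- state$dimension
  B <- if (d == 2L) rotation_matrix_2d(state$phi) else rotation_matrix_3d(state$phi)
  bhat <- state$xhat %*% t(B)
  bhatn <- state$xhat_n %*% t(B)
  noise <- if (eta > 0) {
    eta * sqrt(dt) * matrix(rnorm(N * d), ncol = d, byrow = TRUE)
  } else matrix(0, N, d)
  ctr <- matrix(state$x_c, N, d, byrow = TRUE)
  rhs <- state$x_n + dt * (-p$alpha * (state$x_n + bhat - updated_membrane) +
                             p$alpha_n * (ctr + bhatn)) + noise
  prop <- rhs / (1 + dt * p$alpha_n)
  out <- prop
  if (!is.null(world)) {
    disp <- prop - state$x_n
    for (i in seq_len(N)) {
      out[i, ] <- resolve_contact_step(state$x_n[i, ], disp[i, ], world, cfg$tol)
    }
  }
  out
}

#' Advance the full cell state by one time step
#'
#' Reference (pure R) implementation of one IMEX step: rotation fit,
#' membrane update, nucleus update, nucleus-centre refresh and source
#' consumption, in that order. The compiled engine used by
#' [run_scenario()] performs the identical update.
#'
#' @inheritParams step_membrane
#' @return A list with the updated `state`, the (possibly consumed)
#'   `field`, and `consumed` (indices of sources consumed this step).
#' @export
advance <- function(state, field, world, cfg, t = 0) {
  stopifnot(inherits(state, "cell_state"), inherits(cfg, "step_config"),
            !is.null(cfg$dt))
  state$phi <- if (state$dimension == 2L) fit_rotation_2d(state) else
    fit_rotation_3d(state)
  x_new <- step_membrane(state, field, world, cfg, t)
  xn_new <- step_nucleus(state, x_new, cfg, world, t)
  state$x <- x_new
  state$x_n <- xn_new
  state$x_c <- if (state$dimension == 2L) {
    polygon_centroid(xn_new)
  } else {
    mesh_centroid(xn_new, state$triangles)
  }
  consumed <- integer(0)
  if (!is.null(field)) {
    if (state$dimension == 2L) {
      field <- consume_sources(field, x_new)
    } else {
      field <- consume_sources_3d(field, x_new, state$triangles)
    }
    consumed <- attr(field, "consumed")
  }
  list(state = state, field = field, consumed = consumed)
}

# 3D consumption: source inside the closed membrane mesh (ray crossing)
consume_sources_3d <- function(field, vertices, triangles) {
  consumed <- integer(0)
  for (k in seq_along(field$sources)) {
    s <- field$sources[[k]]
    if (!s$active) next
    if (point_in_mesh(s$position, vertices, triangles)) {
      field$sources[[k]]$active <- FALSE
      consumed <- c(consumed, k)
    }
  }
  attr(field, "consumed") <- consumed
  field
}

#' Run a scenario to completion
#'
#' Integrates a scenario until its time horizon, until the whole cell has
#' exited the channel (`stop_after_exit`), or until a fixed relaxation tail
#' after the last source is consumed. 2D scenarios use the compiled engine
#' by default; `engine = "r"` selects the pure-R reference integrator
#' (identical update, used for cross-checking). 3D scenarios always use the
#' R path.
#'
#' @param scenario A scenario from [build_scenario()] (or a preset name).
#' @param cfg A [step_config()]; unset entries fall back to scenario
#'   defaults.
#' @param engine `"auto"`, `"cpp"` or `"r"`.
#' @return A `cell_trajectory`.
#' @export
#' @examples
#' \donttest{
#' traj <- run_scenario("channel", step_config(eta = 0, t_end = 0.05))
#' penetration_time(traj)
#' }
run_scenario <- function(scenario, cfg = step_config(),
                         engine = c("auto", "cpp", "r")) {
  engine <- match.arg(engine)
  if (is.character(scenario)) scenario <- build_scenario(scenario)
  stopifnot(inherits(scenario, "cell_scenario"))
  state <- scenario$state
  d <- state$dimension
  cfg <- resolve_config(cfg, scenario)
  if (engine == "auto") engine <- if (d == 2L) "cpp" else "r"
  if (engine == "cpp" && d == 3L) {
    stop("the compiled engine supports 2D scenarios only", call. = FALSE)
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (engine == "cpp") run_engine_cpp(scenario, state, cfg) else
    run_engine_r(scenario, state, cfg)
}

resolve_config <- function(cfg, scenario) {
  d <- scenario$state$dimension
  if (is.null(cfg$dt)) cfg$dt <- scenario$dt %||% (if (d == 2L) 1e-4 else 0.01)
  if (is.null(cfg$t_end)) cfg$t_end <- scenario$t_end %||% 1
  if (is.null(cfg$stop_after_exit)) {
    cfg$stop_after_exit <- scenario$stop_after_exit %||% FALSE
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_engine_cpp <- function(scenario, state, cfg) {
  p <- state$params
  field <- scenario$field
  srcs <- field$sources
  src_mat <- if (length(srcs)) {
    do.call(rbind, lapply(srcs, function(s) {
      c(s$position, s$rate, s$t_on, min(s$t_off, BAND_INF), as.numeric(s$active))
    }))
  } else matrix(0, 0, 6)
  world <- scenario$world
  discs <- world$discs %||% matrix(0, 0, 3)
  bands <- world$bands %||% matrix(0, 0, 8)
  ch <- scenario$channel
  chvec <- if (is.null(ch)) numeric(0) else c(ch$x_entry, ch$x_entry + ch$length)
  eta <- if (is.null(cfg$eta)) p$eta else cfg$eta
  max_steps <- ceiling(cfg$t_end / cfg$dt)
  res <- engine_run_2d(
    state$x, state$x_n, state$xhat, state$xhat_n, state$x_ref, state$x_c,
    list(alpha = p$alpha, alpha_n = p$alpha_n, beta = p$beta, eta = eta,
         R = p$R, D = field$D %||% 3600),
    src_mat, discs, bands, cfg$dt, as.integer(max_steps), cfg$tol,
    cfg$record_every, isTRUE(cfg$stop_after_exit), cfg$relax_tail, chvec,
    cfg$explicit_gradient)
  if (res$status == 1L) {
    stop("singular evaluation: node coincides with an active source",
         call. = FALSE)
  }
  if (res$status == 2L) {
    stop("integration unstable: node displacement exceeded the cell radius ",
         "in one step; reduce dt", call. = FALSE)
  }
  N <- p$N
  nf <- length(res$times)
  final_state <- state
  final_state$x <- res$mem_final
  final_state$x_n <- res$nuc_final
  final_state$x_c <- res$x_c
  for (k in seq_along(field$sources)) {
    field$sources[[k]]$active <- res$source_active[k] > 0
  }
  new_trajectory(
    times = res$times,
    membrane = array(res$mem, dim = c(nf, N, 2)),
    nucleus = array(res$nuc, dim = c(nf, N, 2)),
    contacts = res$contacts,
    events = list(entry_time = res$entry_time, exit_time = res$exit_time,
                  consumed = as.numeric(res$consumed),
                  t_final = res$t_final, steps = res$steps),
    scenario = scenario, state = final_state, field = field, cfg = cfg)
}

run_engine_r <- function(scenario, state, cfg) {
  field <- scenario$field
  world <- scenario$world
  ch <- scenario$channel
  N <- nrow(state$x); d <- state$dimension
  max_steps <- ceiling(cfg$t_end / cfg$dt)
  rec <- if (cfg$record_every > 0) cfg$record_every else max_steps + 1L
  times <- 0
  mem_frames <- list(state$x)
  nuc_frames <- list(state$x_n)
  contacts <- 0L
  entry_time <- NA_real_; exit_time <- NA_real_
  consumed_t <- rep(NA_real_, length(field$sources %||% list()))
  last_consumed <- NA_real_
  t <- 0
  steps <- 0L
  for (p in seq_len(max_steps)) {
    stepres <- advance(state, field, world, cfg, t)
    state <- stepres$state; field <- stepres$field
    t <- t + cfg$dt
    steps <- p
    if (length(stepres$consumed)) {
      consumed_t[stepres$consumed] <- t
      last_consumed <- t
    }
    if (!is.null(ch)) {
      if (is.na(entry_time) && any(state$x[, 1] > ch$x_entry)) entry_time <- t
      if (!is.na(entry_time) && is.na(exit_time) &&
          all(state$x[, 1] > ch$x_entry + ch$length)) exit_time <- t
    }
    if (p %% rec == 0L) {
      times <- c(times, t)
      mem_frames[[length(mem_frames) + 1L]] <- state$x
      nuc_frames[[length(nuc_frames) + 1L]] <- state$x_n
      contacts <- c(contacts, NA_integer_)
    }
    if (isTRUE(cfg$stop_after_exit) && !is.na(exit_time)) break
    srcs <- if (is.null(field)) list() else field$sources
    any_active <- any(vapply(srcs, function(s) s$active, TRUE))
    if (!any_active && !is.na(last_consumed) &&
        t - last_consumed >= cfg$relax_tail) break
  }
  if (tail(times, 1) != t) {
    times <- c(times, t)
    mem_frames[[length(mem_frames) + 1L]] <- state$x
    nuc_frames[[length(nuc_frames) + 1L]] <- state$x_n
    contacts <- c(contacts, NA_integer_)
  }
  nf <- length(times)
  mem <- array(NA_real_, c(nf, N, d))
  nuc <- array(NA_real_, c(nf, N, d))
  for (f in seq_len(nf)) {
    mem[f, , ] <- mem_frames[[f]]
    nuc[f, , ] <- nuc_frames[[f]]
  }
  new_trajectory(
    times = times, membrane = mem, nucleus = nuc, contacts = contacts,
    events = list(entry_time = entry_time, exit_time = exit_time,
                  consumed = consumed_t, t_final = t, steps = steps),
    scenario = scenario, state = state, field = field, cfg = cfg)
}

new_trajectory <- function(times, membrane, nucleus, contacts, events,
                           scenario, state, field, cfg) {
  structure(
    list(times = times, membrane = membrane, nucleus = nucleus,
         contacts = contacts, events = events,
         channel = scenario$channel, world = scenario$world,
         params = state$params, scenario_name = scenario$name,
         state = state, field = field, cfg = cfg),
    class = "cell_trajectory")
}

#' @export
print.cell_trajectory <- function(x, ...) {
  cat(sprintf("<cell_trajectory '%s'>: %d frames to t = %.4g h\n",
              x$scenario_name %||% "custom", length(x$times),
              x$events$t_final))
  if (!is.null(x$channel)) {
    cat(sprintf("  channel entry %.4g h, exit %.4g h (tau = %.4g h)\n",
                x$events$entry_time, x$events$exit_time,
                x$events$exit_time - x$events$entry_time))
  }
  invisible(x)
}

#' Tidy trajectory table
#'
#' One row per frame, entity (membrane/nucleus) and node, in the layout
#' written by [write_outputs()].
#'
#' @param x A `cell_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `t`, `entity`, `node_id`, `x`, `y`[, `z`].
#' @export
as_tibble.cell_trajectory <- function(x, ...) {
  nf <- length(x$times); N <- dim(x$membrane)[2]; d <- dim(x$membrane)[3]
  ent <- function(arr, label) {
    slice <- function(k) {
      m <- matrix(arr[, , k], nrow = nf)
      as.vector(t(m))
    }
    out <- tibble::tibble(
      t = rep(x$times, each = N),
      entity = label,
      node_id = rep(seq_len(N), nf),
      x = slice(1), y = slice(2))
    if (d == 3L) out$z <- slice(3)
    out
  }
  rbind(ent(x$membrane, "membrane"), ent(x$nucleus, "nucleus"))
}
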