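# Monte Carlo uncertainty quantification of the channel transit time:
# parameter sampling, batched simulations, Pearson correlation screens,
# histogram/CDF summaries and the Richardson-based error budget.

#' Parameter distribution for Monte Carlo sampling
#'
#' @param name Parameter name: one of `D`, `beta`, `alpha`, `alpha_n`,
#'   `epsilon`, `omega` (and `eta` for completeness).
#' @param kind `"normal"` or `"uniform"`.
#' @param mu,sigma Mean and standard deviation (normal).
#' @param lo,hi Bounds (uniform).
#' @return An object of class `param_dist`.
#' @export
#' @examples
#' param_dist("D", "normal", mu = 3600, sigma = 30)
#' param_dist("omega", "uniform", lo = 0, hi = 0.6)
param_dist <- function(name, kind = c("normal", "uniform"),
                       mu = NULL, sigma = NULL, lo = NULL, hi = NULL) {
  kind <- match.arg(kind)
  name <- match.arg(name, c("D", "beta", "alpha", "alpha_n",
                            "epsilon", "omega", "eta"))
  if (kind == "normal") {
    if (is.null(mu) || is.null(sigma) || sigma <= 0) {
      stop("normal distribution needs mu and sigma > 0", call. = FALSE)
    }
  } else if (is.null(lo) || is.null(hi) || !(lo < hi)) {
    stop("uniform distribution needs lo < hi", call. = FALSE)
  }
  structure(list(name = name, kind = kind, mu = mu, sigma = sigma,
                 lo = lo, hi = hi),
            class = "param_dist")
}

#' Default Monte Carlo distribution sets
#'
#' `"four"`: the kinetic parameters `D ~ N(3600, 30^2)`,
#' `beta ~ N(60, 3^2)`, `alpha ~ N(250, 40^2)`, `alpha_n ~ N(2500, 125^2)`.
#' `"two"`: the channel roughness `epsilon ~ U(0.5, 1.5)`,
#' `omega ~ U(0, 0.6)`. `"six"`: both sets combined.
#'
#' @param set `"four"`, `"two"` or `"six"`.
#' @return A named list of [param_dist()] objects.
#' @export
default_mc_dists <- function(set = c("four", "two", "six")) {
  set <- match.arg(set)
  four <- list(
    D = param_dist("D", "normal", mu = 3600, sigma = 30),
    beta = param_dist("beta", "normal", mu = 60, sigma = 3),
    alpha = param_dist("alpha", "normal", mu = 250, sigma = 40),
    alpha_n = param_dist("alpha_n", "normal", mu = 2500, sigma = 125))
  two <- list(
    epsilon = param_dist("epsilon", "uniform", lo = 0.5, hi = 1.5),
    omega = param_dist("omega", "uniform", lo = 0, hi = 0.6))
  switch(set, four = four, two = two, six = c(four, two))
}

#' Sample parameter vectors
#'
#' Independent draws from each listed distribution. Draws of
#' strictly-positive parameters from a normal distribution are redrawn
#' when non-positive (astronomically rare at the default spreads, but
#' guarded anyway).
#'
#' @param dists List of [param_dist()] objects.
#' @param n Number of samples.
#' @param seed Optional RNG seed.
#' @return A tibble with one column per parameter and `n` rows.
#' @export
sample_params <- function(dists, n, seed = NULL) {
  stopifnot(is.list(dists), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  cols <- lapply(dists, function(d) {
    stopifnot(inherits(d, "param_dist"))
    if (d$kind == "normal") {
      x <- rnorm(n, d$mu, d$sigma)
      bad <- which(x <= 0)
      while (length(bad)) {
        x[bad] <- rnorm(length(bad), d$mu, d$sigma)
        bad <- bad[x[bad] <= 0]
      }
      x
    } else {
      runif(n, d$lo, d$hi)
    }
  })
  names(cols) <- vapply(dists, `[[`, "", "name")
  tibble::as_tibble(cols)
}

#' Pearson correlation coefficient
#'
#' \deqn{r = \frac{\sum_j (X_j - \bar X)(\tau_j - \bar\tau)}
#'   {[\sum_j (X_j - \bar X)^2 \sum_j (\tau_j - \bar\tau)^2]^{1/2}}}
#' Always bounded by \eqn{[-1, 1]}.
#'
#' @param x,y Equal-length numeric vectors (length >= 2) with non-zero
#'   variance.
#' @return Scalar correlation.
#' @export
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  dx <- x - mean(x); dy <- y - mean(y)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) {
    stop("undefined correlation: zero variance input", call. = FALSE)
  }
  sum(dx * dy) / den
}

#' Richardson estimate of the time-integration error constant
#'
#' From transit times computed at steps `dt` and `2 dt`:
#' `C = (tau_dt - tau_2dt) / dt`, so that the integration error at step
#' `dt` is bounded by `C * dt` (first-order scheme).
#'
#' @param tau_dt,tau_2dt Transit times at the two step sizes (h).
#' @param dt The finer time step (h).
#' @return The constant `C`.
#' @export
richardson_constant <- function(tau_dt, tau_2dt, dt) {
  stopifnot(dt > 0)
  (tau_dt - tau_2dt) / dt
}

#' Error budget of a Monte Carlo transit-time estimate
#'
#' Combines the IMEX time-integration error bound `E_ti = C * dt` with the
#' Monte Carlo sampling error `E_mc = S_n / sqrt(N_s)`:
#' `E_total = E_ti + E_mc`.
#'
#' @param C Richardson constant (h/h).
#' @param dt Time step (h).
#' @param S_n Sample standard deviation of the transit time (h).
#' @param N_s Number of Monte Carlo samples.
#' @return An object of class `error_budget` (a named list with `E_ti`,
#'   `E_mc`, `E_total`).
#' @export
#' @examples
#' error_budget(C = 133, dt = 1e-4, S_n = 0.0687, N_s = 1e4)
error_budget <- function(C, dt, S_n, N_s) {
  stopifnot(C >= 0, dt >= 0, S_n >= 0, N_s >= 1)
  E_ti <- C * dt
  E_mc <- S_n / sqrt(N_s)
  structure(list(C = C, dt = dt, S_n = S_n, N_s = N_s,
                 E_ti = E_ti, E_mc = E_mc, E_total = E_ti + E_mc),
            class = "error_budget")
}

#' @export
print.error_budget <- function(x, ...) {
  cat(sprintf("<error_budget> E_ti = %.4g + E_mc = %.4g -> E_total = %.4g h\n",
              x$E_ti, x$E_mc, x$E_total))
  invisible(x)
}

#' Histogram, empirical CDF and lognormal fit of transit times
#'
#' @param tau Numeric vector of transit times (non-finite values dropped).
#' @param bins Number of histogram bins.
#' @return A list with `hist` (tibble: `mid`, `count`, `rel_freq`), `cdf`
#'   (right-continuous step function), `cdf_points` (tibble) and
#'   `lognormal` (moment/ML fit `mu_log`, `sigma_log`).
#' @export
cdf_hist <- function(tau, bins = 30L) {
  tau <- tau[is.finite(tau)]
  if (!length(tau)) stop("need at least one finite value", call. = FALSE)
  rng <- range(tau)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  brk <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- graphics::hist(tau, breaks = brk, plot = FALSE)
  cdf <- stats::ecdf(tau)
  xs <- sort(unique(tau))
  logn <- if (all(tau > 0)) {
    list(mu_log = mean(log(tau)),
         sigma_log = sqrt(mean((log(tau) - mean(log(tau)))^2)))
  } else list(mu_log = NA_real_, sigma_log = NA_real_)
  list(hist = tibble::tibble(mid = h$mids, count = h$counts,
                             rel_freq = h$counts / length(tau)),
       cdf = cdf,
       cdf_points = tibble::tibble(tau = xs, p = cdf(xs)),
       lognormal = logn,
       n = length(tau))
}

#' Monte Carlo study of the channel transit time
#'
#' Draws `n_samples` parameter vectors, runs one seeded channel simulation
#' per sample (random walk enabled at the cell's `eta`), and aggregates
#' transit-time statistics: mean, sample standard deviation `S_n`,
#' per-parameter Pearson correlations, histogram/CDF and the Monte Carlo
#' error `S_n / sqrt(N_s)`. Samples that never complete the transit within
#' `t_cap` are recorded (`status = "not_penetrated"`) and excluded from
#' the transit statistics, with the count reported.
#'
#' Per-sample RNG streams are derived from the master seed by sample
#' index, so results do not depend on scheduling when `workers > 1`.
#'
#' @param scenario A channel scenario (or preset name, default
#'   `"channel"`).
#' @param dists List of [param_dist()] (default the four kinetic
#'   parameters).
#' @param n_samples Number of Monte Carlo samples.
#' @param seed Master seed.
#' @param workers Parallel workers (forked; results are
#'   worker-invariant).
#' @param cfg Base [step_config()] for each run.
#' @param t_cap Per-run time cap (h); default ten times the reference
#'   transit time.
#' @param C Optional Richardson constant; when given, a full
#'   [error_budget()] is attached.
#' @return An object of class `mc_result`.
#' @export
run_mc <- function(scenario = "channel", dists = default_mc_dists("four"),
                   n_samples = 100, seed = 1, workers = 1L,
                   cfg = step_config(), t_cap = 3.7, C = NULL) {
  if (is.character(scenario)) scenario <- build_scenario(scenario)
  stopifnot(inherits(scenario, "cell_scenario"))
  if (is.null(scenario$channel)) {
    stop("Monte Carlo transit study needs a scenario with a channel",
         call. = FALSE)
  }
  set.seed(seed)
  samples <- sample_params(dists, n_samples)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_samples)
  one <- function(j) {
    sc <- apply_param_overrides(scenario, as.list(samples[j, ]))
    cfg_j <- cfg
    cfg_j$seed <- run_seeds[j]
    cfg_j$t_end <- t_cap
    cfg_j$stop_after_exit <- TRUE
    cfg_j$record_every <- 0L
    res <- tryCatch(run_scenario(sc, cfg_j), error = function(e) e)
    if (inherits(res, "error")) {
      return(list(tau = NA_real_, status = paste("error:", conditionMessage(res))))
    }
    tau <- penetration_time(res)
    list(tau = tau,
         status = if (is.na(tau)) "not_penetrated" else "ok")
  }
  runs <- if (workers > 1L) {
    parallel::mclapply(seq_len(n_samples), one, mc.cores = workers)
  } else {
    lapply(seq_len(n_samples), one)
  }
  tau <- vapply(runs, function(r) r$tau, 0)
  status <- vapply(runs, function(r) r$status, "")
  ok <- status == "ok"
  if (!any(ok)) stop("all Monte Carlo samples failed to penetrate", call. = FALSE)
  tau_ok <- tau[ok]
  r <- if (sum(ok) >= 2) {
    vapply(names(samples), function(nm) pearson_r(samples[[nm]][ok], tau_ok), 0)
  } else {
    setNames(rep(NA_real_, ncol(samples)), names(samples))
  }
  S_n <- sd(tau_ok)
  budget <- if (!is.null(C)) {
    error_budget(C, cfg$dt %||% scenario$dt %||% 1e-4, S_n, sum(ok))
  } else NULL
  structure(
    list(samples = tibble::as_tibble(cbind(samples,
                                           tibble::tibble(tau = tau,
                                                          status = status,
                                                          seed = run_seeds))),
         tau = tau_ok, n_samples = n_samples, n_ok = sum(ok),
         n_failed = sum(!ok), mean_tau = mean(tau_ok), S_n = S_n,
         E_mc = S_n / sqrt(sum(ok)), r = r,
         dist = cdf_hist(tau_ok), budget = budget, seed = seed),
    class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(
    "<mc_result> %d/%d samples completed; mean tau = %.4f h, S_n = %.4f h\n",
    x$n_ok, x$n_samples, x$mean_tau, x$S_n))
  cat("  Pearson r vs tau:\n")
  for (nm in names(x$r)) cat(sprintf("    %-8s %+0.4f\n", nm, x$r[[nm]]))
  invisible(x)
}

#' Tidy a Monte Carlo result
#'
#' `tidy()` returns one row per sampled parameter with its Pearson
#' correlation against the transit time; `glance()` returns the one-row
#' study summary.
#'
#' @param x An `mc_result`.
#' @param ... Unused.
#' @return A tibble.
#' @rdname tidy
#' @export
tidy.mc_result <- function(x, ...) {
  tibble::tibble(parameter = names(x$r), r = unname(x$r))
}

#' @rdname tidy
#' @export
glance.mc_result <- function(x, ...) {
  tibble::tibble(n_samples = x$n_samples, n_ok = x$n_ok,
                 n_failed = x$n_failed, mean_tau = x$mean_tau,
                 S_n = x$S_n, E_mc = x$E_mc)
}
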