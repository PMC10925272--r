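#' Simulate the four-region velocity model
#'
#' Integrates the force-balance ODEs for the x-velocity of the bulk,
#' leading-edge, trailing-edge and top-edge regions of a stimulated
#' monolayer (see [region_params()] for the equations). The driving signal
#' `s_eff_plus(t)` is computed exactly on a fine auxiliary grid and each
#' linear velocity equation is advanced with an exponential integrator that
#' is exact for piecewise-linear forcing, so the error is controlled by
#' `dt_fine` alone (second order in `dt_fine`).
#'
#' @param params A [region_params()] object.
#' @param protocol A [stimulus_protocol()].
#' @param initial Named or ordered numeric of four initial velocities
#'   `(bulk, leading, trailing, top)` in um/h at `times[1]`. Default: the
#'   pre-stimulation steady state from [default_initial_velocities()].
#' @param times Strictly increasing output time grid (h).
#' @param dt_fine Internal integration step bound (h). Default `5e-4`.
#' @return A tibble of class `region_traces` with columns `time_h`,
#'   `v_bulk`, `v_leading`, `v_trailing`, `v_top` (um/h).
#' @examples
#' tr <- simulate_regions(default_region_params(), step_protocol(),
#'   times = seq(0, 7, 1 / 12)
#' )
#' head(tr)
#' @export
simulate_regions <- function(params, protocol, initial = NULL, times,
                             dt_fine = 5e-4) {
  stopifnot(inherits(params, "region_params"))
  stopifnot(inherits(protocol, "stimulus_protocol"))
  check_times(times)
  if (is.null(initial)) initial <- default_initial_velocities(params)
  initial <- as.numeric(initial)
  if (length(initial) != 4L || anyNA(initial) || any(!is.finite(initial))) {
    rlang::abort("`initial` must be four finite velocities.",
      class = "voltaxis_invalid_input"
    )
  }

  basis <- region_basis(params$gamma, params$signal, protocol, times, dt_fine)
  tr <- region_traces_from_basis(basis, params, initial)
  class(tr) <- c("region_traces", class(tr))
  attr(tr, "region_params") <- params
  tr
}

# Precompute, on the output grid, the three response functions from which
# every region trace is a linear combination:
#   e_gt = exp(-gamma t)                     (decay of the initial condition)
#   g(t) = int_0^t exp(-gamma (t-u)) s_eff_plus(u) du   (signal convolution)
#   h(t) = (1 - exp(-gamma t)) / gamma       (step response of the edge force)
# g is evaluated by exact stepping of the scalar linear ODE with the
# piecewise-linear interpolant of s_eff_plus on a fine grid that contains
# all output times as nodes. Shared by simulate_regions() and the fast
# likelihood used in MCMC (gamma and the signal timescales are fixed during
# calibration, so this is computed once per fit).
region_basis <- function(gamma, signal, protocol, times, dt_fine = 5e-4) {
  fine <- refine_grid(times, dt_fine)
  sig <- integrate_signal(protocol, signal, fine)
  f <- sig$s_eff_plus
  dt <- diff(fine)
  E <- exp(-gamma * dt)
  w0 <- (1 - E) / gamma                 # weight of f at step start
  w1 <- (dt - w0) / (gamma * dt)        # weight of the linear ramp
  incr <- f[-length(f)] * (w0 - w1) + f[-1] * w1
  # recurrence g_{n+1} = E_n g_n + incr_n (nonuniform E: explicit loop in C
  # via filter only works for constant E; fall back to cumulative products)
  g <- numeric(length(fine))
  if (length(unique(round(dt, 15))) == 1L) {
    g[-1] <- stats::filter(incr, E[1], method = "recursive")
  } else {
    for (n in seq_along(incr)) g[n + 1L] <- E[n] * g[n] + incr[n]
  }
  idx <- match(round(times, 12), round(fine, 12))
  t_rel <- times - times[1]
  list(
    times = times,
    e_gt = exp(-gamma * t_rel),
    g = g[idx],
    h = (1 - exp(-gamma * t_rel)) / gamma,
    gamma = gamma
  )
}

region_traces_from_basis <- function(basis, params, initial) {
  ap <- params$alpha_par
  at <- params$alpha_perp
  de <- params$delta
  ae <- params$alpha_edge
  tibble::tibble(
    time_h = basis$times,
    v_bulk = initial[1] * basis$e_gt + ap * basis$g,
    v_leading = initial[2] * basis$e_gt + de * ap * basis$g + ae * basis$h,
    v_trailing = initial[3] * basis$e_gt + de * ap * basis$g - ae * basis$h,
    v_top = initial[4] * basis$e_gt + de * at * basis$g
  )
}

#' Pre-stimulation steady-state velocities
#'
#' Before stimulation the effective signal is zero and the only active force
#' is the outward edge force, so the regions settle to
#' `(0, alpha_edge/gamma, -alpha_edge/gamma, 0)` for (bulk, leading,
#' trailing, top).
#'
#' @param params A [region_params()].
#' @return Named numeric of length 4, um/h.
#' @examples
#' default_initial_velocities(default_region_params())
#' @export
default_initial_velocities <- function(params) {
  stopifnot(inherits(params, "region_params"))
  if (params$gamma <= 0) {
    rlang::abort("`gamma` must be > 0.", class = "voltaxis_invalid_parameter")
  }
  v <- params$alpha_edge / params$gamma
  c(bulk = 0, leading = v, trailing = -v, top = 0)
}

#' Estimate the friction rate from post-stimulation velocity decay
#'
#' With the field off and the signal adapted, the bulk velocity obeys
#' `v(t) = v0 * exp(-gamma (t - t0))`, so `gamma` can be fitted directly
#' from the decay of the measured bulk velocity after stimulation ends. The
#' fit is performed in two stages: a log-linear least-squares fit of
#' `log|v|` against time (valid because all samples share a sign), refined
#' by nonlinear least squares on the original scale, which is the
#' appropriate estimator for additive Gaussian velocity noise.
#'
#' @param data A data frame with a `time_h` column and one velocity column
#'   (um/h), named by `velocity`; defaults to `v_bulk` if present, else the
#'   single non-time column.
#' @param window Length-2 numeric `(t0, t1)`: the post-stimulation interval
#'   to fit, in hours. Default: all rows.
#' @param velocity Name of the velocity column.
#' @return An object of class `gamma_fit` with elements `gamma`, `v0`, `t0`,
#'   `data`, `fitted`, `sigma`. Supports [tidy()] and [glance()].
#' @examples
#' tr <- simulate_regions(default_region_params(), step_protocol(),
#'   times = seq(0, 7, 1 / 12)
#' )
#' estimate_gamma(tr, window = c(4.25, 7))
#' @export
estimate_gamma <- function(data, window = NULL, velocity = NULL) {
  if (!"time_h" %in% names(data)) {
    rlang::abort("`data` must have a `time_h` column.",
      class = "voltaxis_invalid_input"
    )
  }
  if (is.null(velocity)) {
    velocity <- if ("v_bulk" %in% names(data)) {
      "v_bulk"
    } else {
      setdiff(names(data), "time_h")[1]
    }
  }
  if (!velocity %in% names(data)) {
    rlang::abort(sprintf("Velocity column `%s` not found.", velocity),
      class = "voltaxis_invalid_input"
    )
  }
  d <- tibble::tibble(time_h = data$time_h, v = data[[velocity]])
  if (!is.null(window)) {
    d <- dplyr::filter(d, .data$time_h >= window[1], .data$time_h <= window[2])
  }
  if (nrow(d) < 3L) {
    rlang::abort("Fit window must contain at least 3 samples.",
      class = "voltaxis_invalid_input"
    )
  }
  sgn <- sign(d$v)
  if (any(d$v == 0) || length(unique(sgn)) > 1L) {
    rlang::abort(
      paste(
        "Exponential decay fit requires all velocities to be nonzero and",
        "share a sign in the window; got a zero or a sign change.",
        "Narrow `window` to the clean post-stimulation decay."
      ),
      class = "voltaxis_fit_failure"
    )
  }
  t0 <- d$time_h[1]
  # stage 1: convex log-linear fit
  ll <- stats::lm(log(abs(v)) ~ I(time_h - t0), data = d)
  g0 <- max(-coef(ll)[2], 1e-8)
  v00 <- sgn[1] * exp(coef(ll)[1])
  # stage 2: nonlinear refinement on the original scale
  fit <- minpack.lm::nlsLM(
    v ~ v0 * exp(-g * (time_h - t0)),
    data = d,
    start = list(v0 = unname(v00), g = unname(g0)),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- coef(fit)
  fitted_v <- est["v0"] * exp(-est["g"] * (d$time_h - t0))
  structure(
    list(
      gamma = unname(est["g"]),
      v0 = unname(est["v0"]),
      t0 = t0,
      data = d,
      fitted = fitted_v,
      sigma = sqrt(mean((d$v - fitted_v)^2)),
      n = nrow(d)
    ),
    class = "gamma_fit"
  )
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf(
    "<gamma_fit> gamma = %.6g 1/h, v0 = %.6g um/h (n = %d, from t0 = %g h)\n",
    x$gamma, x$v0, x$n, x$t0
  ))
  invisible(x)
}

#' @rdname estimate_gamma
#' @param x A `gamma_fit` object.
#' @param ... Unused.
#' @export
tidy.gamma_fit <- function(x, ...) {
  tibble::tibble(
    term = c("gamma", "v0"),
    estimate = c(x$gamma, x$v0),
    unit = c("1/h", "um/h")
  )
}

#' @rdname estimate_gamma
#' @export
glance.gamma_fit <- function(x, ...) {
  tibble::tibble(
    gamma = x$gamma, v0 = x$v0, sigma = x$sigma, nobs = x$n, t0 = x$t0
  )
}
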