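#' Calibrate the four-region velocity model by MCMC
#'
#' Bayesian calibration of `(alpha_par, alpha_perp, delta, alpha_edge)` and
#' the observation noise `sigma` from measured region velocity traces, with
#' the friction rate `gamma` and the signal timescales held fixed (gamma is
#' identified separately from post-stimulation decay, see
#' [estimate_gamma()]). The likelihood is i.i.d. Gaussian over all four
#' regions' residuals; regions enter symmetrically, so their ordering is
#' irrelevant. Because `gamma` and the signal timescales are fixed, the
#' model traces are linear in the sampled parameters and each likelihood
#' evaluation reuses a precomputed signal convolution, making full-length
#' adaptive MCMC runs cheap.
#'
#' Initial velocities are taken to be the pre-stimulation steady state
#' implied by the sampled `alpha_edge` (see
#' [default_initial_velocities()]).
#'
#' @param data A `region_traces` tibble (columns `time_h`, `v_bulk`,
#'   `v_leading`, `v_trailing`, `v_top`, um/h).
#' @param protocol The [stimulus_protocol()] under which `data` was
#'   recorded.
#' @param gamma Fixed friction rate (1/h). Default 1.765.
#' @param signal Fixed [signal_params()].
#' @param priors A [uniform_priors()] over
#'   `alpha_par, alpha_perp, delta, alpha_edge, sigma`. Defaults:
#'   responses in `[0, 500]` um/h^2, `delta` in `[0, 1]`, edge force in
#'   `[0, 100]` um/h^2, noise in `[0, 20]` um/h.
#' @param n_chains,max_iter,seed Passed to [run_adaptive_mcmc()].
#' @param dt_fine Signal-integration step (h).
#' @return An `electro_fit` object wrapping the `posterior_result`; supports
#'   [tidy()], [glance()], [autoplot()][ggplot2::autoplot] and
#'   [posterior_predictive_band()].
#' @export
fit_regions <- function(data, protocol, gamma = 1.765,
                        signal = signal_params(), priors = NULL,
                        n_chains = 4, max_iter = 2e4, seed = NULL,
                        dt_fine = 1e-3) {
  req <- c("time_h", "v_bulk", "v_leading", "v_trailing", "v_top")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    rlang::abort(
      sprintf("`data` is missing column(s): %s.", toString(missing_cols)),
      class = "voltaxis_schema_error"
    )
  }
  if (is.null(priors)) {
    priors <- uniform_priors(
      alpha_par = c(0, 500), alpha_perp = c(0, 500), delta = c(0, 1),
      alpha_edge = c(0, 100), sigma = c(0, 20)
    )
  }
  basis <- region_basis(gamma, signal, protocol, data$time_h, dt_fine)
  obs <- c(data$v_bulk, data$v_leading, data$v_trailing, data$v_top)

  log_lik <- function(theta) {
    ve <- theta[["alpha_edge"]] / gamma
    model <- c(
      theta[["alpha_par"]] * basis$g,
      ve * basis$e_gt + theta[["delta"]] * theta[["alpha_par"]] * basis$g +
        theta[["alpha_edge"]] * basis$h,
      -ve * basis$e_gt + theta[["delta"]] * theta[["alpha_par"]] * basis$g -
        theta[["alpha_edge"]] * basis$h,
      theta[["delta"]] * theta[["alpha_perp"]] * basis$g
    )
    s <- theta[["sigma"]]
    if (s <= 0) return(-Inf)
    gaussian_log_likelihood(model, obs, s)
  }

  post <- run_adaptive_mcmc(log_lik, priors,
    n_chains = n_chains,
    max_iter = max_iter, seed = seed
  )
  new_electro_fit(post,
    model = "regions", data = data, protocol = protocol,
    fixed = list(gamma = gamma, signal = signal)
  )
}

#' Calibrate the one-dimensional continuum model by MCMC
#'
#' Bayesian calibration of `(alpha, D, delta, r, K)` and the density
#' observation noise `sigma` from one-dimensional density kymographs, with
#' the signal timescales fixed. Each likelihood evaluation solves the
#' reaction-advection-diffusion model with the finite-volume solver on the
#' data grid and scores all observed profiles under i.i.d. Gaussian error.
#'
#' @param data Long kymograph tibble with columns `time_h`, `x` (mm), `rho`
#'   (cells/mm), on a fixed spatial grid per time.
#' @param protocol The [stimulus_protocol()] used.
#' @param initial A `density_field_1d` giving the initial density in
#'   cells/mm on the same grid. Default: the earliest profile in `data`
#'   (sensible only for low-noise data).
#' @param signal Fixed [signal_params()].
#' @param priors [uniform_priors()] over `alpha, D, delta, r, K, sigma`.
#'   Defaults: `alpha` in `[0, 2]` mm/h, `D` in `[0, 20]` mm^2/h, `delta` in
#'   `[0, 1]`, `r` in `[0, 1]` 1/h, `K` in `[0, 300]` cells/mm, `sigma` in
#'   `[0, 50]` cells/mm.
#' @param n_chains,max_iter,seed Passed to [run_adaptive_mcmc()].
#' @param dt_max Solver step bound (h).
#' @return An `electro_fit` object.
#' @export
fit_continuum_1d <- function(data, protocol, initial = NULL,
                             signal = signal_params(), priors = NULL,
                             n_chains = 4, max_iter = 4000, seed = NULL,
                             dt_max = 0.01) {
  req <- c("time_h", "x", "rho")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    rlang::abort(
      sprintf("`data` is missing column(s): %s.", toString(missing_cols)),
      class = "voltaxis_schema_error"
    )
  }
  if (is.null(priors)) {
    priors <- uniform_priors(
      alpha = c(0, 2), D = c(0, 20), delta = c(0, 1), r = c(0, 1),
      K = c(0, 300), sigma = c(0, 50)
    )
  }
  times <- sort(unique(data$time_h))
  xg <- sort(unique(data$x))
  wide <- tidyr::pivot_wider(
    dplyr::arrange(data, .data$time_h, .data$x),
    id_cols = "x", names_from = "time_h", values_from = "rho"
  )
  obs <- as.matrix(wide[, -1, drop = FALSE]) # x by time
  if (is.null(initial)) {
    initial <- density_field_1d(xg, obs[, 1], time = times[1])
  }
  rho0 <- initial$rho
  fit_times <- times[times > times[1] + 1e-12]
  obs_fit <- obs[, match(fit_times, times), drop = FALSE]
  nx <- length(xg)
  h <- xg[2] - xg[1]
  out_t <- c(times[1], fit_times)
  # the signal timescales are fixed during calibration, so the forcing is
  # shared by every likelihood evaluation; the solver core is called
  # directly to keep each evaluation cheap
  frc <- solver_forcing(protocol, signal, times[1], max(times))
  mask1 <- matrix(1L, nx, 1)
  Ex1 <- matrix(1, nx, 1)
  Ey0 <- matrix(0, nx, 1)
  my0 <- rep(0, length(frc$t))

  log_lik <- function(theta) {
    if (theta[["sigma"]] <= 0 || theta[["K"]] <= 0 || theta[["D"]] <= 0) {
      return(-Inf)
    }
    sol <- tryCatch(
      solve_rad_cpp(
        matrix(rho0 / theta[["K"]], nx, 1), mask1, h,
        theta[["D"]], theta[["alpha"]], theta[["delta"]], theta[["r"]],
        frc$t, frc$s_plus, frc$t, frc$mx, my0, Ex1, Ey0,
        out_t, dt_max, 0.4
      ),
      error = function(e) NULL
    )
    if (is.null(sol)) return(-Inf)
    model <- vapply(sol[-1], as.numeric, numeric(nx)) * theta[["K"]]
    gaussian_log_likelihood(model, obs_fit, theta[["sigma"]])
  }

  post <- run_adaptive_mcmc(log_lik, priors,
    n_chains = n_chains,
    max_iter = max_iter, seed = seed
  )
  new_electro_fit(post,
    model = "continuum_1d", data = data, protocol = protocol,
    fixed = list(signal = signal, initial = initial)
  )
}

new_electro_fit <- function(posterior, model, data, protocol, fixed) {
  structure(
    list(
      posterior = posterior, model = model, data = data,
      protocol = protocol, fixed = fixed
    ),
    class = "electro_fit"
  )
}

#' @export
print.electro_fit <- function(x, ...) {
  cat(sprintf("<electro_fit> model: %s\n", x$model))
  print(x$posterior)
  invisible(x)
}

#' @rdname fit_regions
#' @param x An `electro_fit`.
#' @param ... Unused.
#' @export
tidy.electro_fit <- function(x, ...) tidy(x$posterior)

#' @rdname fit_regions
#' @export
glance.electro_fit <- function(x, ...) {
  dplyr::mutate(glance(x$posterior), model = x$model, .before = 1)
}
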