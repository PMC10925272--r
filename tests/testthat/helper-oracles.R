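# Independent fixed-step RK4 integrator used as the reference for the ODE
# modules. Deliberately naive: it knows nothing about the package's
# piecewise-exact propagation and integrates the right-hand side directly.
rk4 <- function(deriv, y0, times) {
  n <- length(times)
  out <- matrix(NA_real_, n, length(y0))
  out[1, ] <- y0
  y <- y0
  for (i in seq_len(n - 1)) {
    t0 <- times[i]
    dt <- times[i + 1] - t0
    k1 <- deriv(t0, y)
    k2 <- deriv(t0 + dt / 2, y + dt / 2 * k1)
    k3 <- deriv(t0 + dt / 2, y + dt / 2 * k2)
    k4 <- deriv(t0 + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1, ] <- y
  }
  out
}

# refine each interval of `times` into `m` RK4 substeps, return values at
# the original nodes
rk4_fine <- function(deriv, y0, times, m = 10) {
  fine <- unique(as.numeric(t(outer(
    seq_len(length(times) - 1),
    seq(0, 1, length.out = m + 1)[-(m + 1)],
    function(i, w) times[i] + w * (times[i + 1] - times[i])
  ))))
  fine <- c(fine, times[length(times)])
  sol <- rk4(deriv, y0, fine)
  sol[match(round(times, 12), round(fine, 12)), , drop = FALSE]
}

# RK4 reference that respects the protocol's stimulus discontinuities:
# each constant-stimulus segment is integrated separately with the fixed
# magnitude, so no RK4 step straddles a jump. rhs_factory(s) must return
# the derivative function for constant stimulus s.
rk4_piecewise <- function(protocol, rhs_factory, y0, times, m = 20) {
  bp <- protocol$breakpoints
  inner <- bp[bp > times[1] & bp < times[length(times)]]
  edges <- sort(unique(round(c(times, inner), 12)))
  out <- matrix(NA_real_, length(times), length(y0))
  y <- y0
  t_prev <- edges[1]
  if (any(abs(times - t_prev) < 1e-9)) out[which.min(abs(times - t_prev)), ] <- y
  for (k in seq_len(length(edges) - 1)) {
    a <- edges[k]
    b <- edges[k + 1]
    s <- protocol_magnitude(protocol, a)
    deriv <- rhs_factory(s)
    grid <- seq(a, b, length.out = m + 1)
    y <- rk4(deriv, y, grid)[m + 1, ]
    hit <- which(abs(times - b) < 1e-9)
    if (length(hit)) out[hit, ] <- y
  }
  out
}

# signal model right-hand side for a piecewise-constant protocol
signal_rhs <- function(protocol, params) {
  function(t, y) {
    s <- protocol_magnitude(protocol, t)
    signal_rhs_const(params)(s)(t, y)
  }
}

# factory form for rk4_piecewise: constant-stimulus right-hand sides
signal_rhs_const <- function(params) {
  function(s) {
    function(t, y) {
      c(
        (s - y[1] - y[2]) / params$tau_e,
        (s - y[2]) / params$tau_a
      )
    }
  }
}

# full six-state region system (s_eff, I, v_bulk, v_leading, v_trailing,
# v_top) for the RK4 oracle, constant-stimulus factory form
region_rhs_const <- function(params) {
  sig <- params$signal
  function(s) {
    function(t, y) {
      sp <- max(y[1], 0)
      c(
        (s - y[1] - y[2]) / sig$tau_e,
        (s - y[2]) / sig$tau_a,
        -params$gamma * y[3] + params$alpha_par * sp,
        -params$gamma * y[4] + params$delta * params$alpha_par * sp +
          params$alpha_edge,
        -params$gamma * y[5] + params$delta * params$alpha_par * sp -
          params$alpha_edge,
        -params$gamma * y[6] + params$delta * params$alpha_perp * sp
      )
    }
  }
}

calibrated_region_truth <- function() {
  c(alpha_par = 171.95, alpha_perp = 217.08, delta = 0.31, alpha_edge = 24.93)
}

calibrated_continuum_truth <- function() {
  c(alpha = 0.837, D = 13.30, delta = 0.625, r = 0.180, K = 260.29)
}
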