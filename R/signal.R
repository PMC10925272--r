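#' Integrate the adaptation-excitation signal model
#'
#' Solves
#' \deqn{\tau_e \dot s_{eff} = s(t) - s_{eff} - I, \qquad
#'       \tau_a \dot I = s(t) - I,}
#' for a piecewise-constant stimulus `s(t)` given by `protocol`. On each
#' constant-stimulus interval the linear system is propagated with its exact
#' (matrix-exponential) solution, so the returned values carry no step-size
#' error. The fixed point under sustained `s` is `s_eff = 0`, `I = s`
#' (perfect adaptation); after the field is switched off `s_eff` transiently
#' goes negative, which is why the motility drive uses the positive part
#' `s_eff_plus = max(s_eff, 0)`.
#'
#' In two dimensions the signal senses only the field magnitude, so the same
#' scalar equations apply with `s(t) = |s(t)|`.
#'
#' @param protocol A [stimulus_protocol()].
#' @param params A [signal_params()].
#' @param times Strictly increasing time grid (h) on which to report the
#'   solution.
#' @param initial Length-2 numeric `(s_eff, I)` at `times[1]`. Default
#'   `c(0, 0)`, the pre-stimulation rest state.
#' @return A tibble of class `signal_trace` with columns `time_h`, `s_eff`,
#'   `inhibitor`, `s_eff_plus`.
#' @examples
#' tr <- integrate_signal(step_protocol(), signal_params(), seq(0, 7, 1 / 12))
#' head(tr)
#' @export
integrate_signal <- function(protocol, params, times, initial = c(0, 0)) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  stopifnot(inherits(params, "signal_params"))
  check_times(times)
  if (!is.numeric(initial) || length(initial) != 2L || anyNA(initial) ||
    any(!is.finite(initial))) {
    rlang::abort("`initial` must be two finite values (s_eff, I).",
      class = "voltaxis_invalid_input"
    )
  }

  # segment boundaries: protocol breakpoints falling strictly inside the grid
  bp <- protocol$breakpoints
  inner <- bp[bp > times[1] & bp < times[length(times)]]
  seg_edges <- sort(unique(c(times[1], inner, times[length(times)])))

  s_eff <- numeric(length(times))
  inhib <- numeric(length(times))
  state <- as.numeric(initial)

  for (k in seq_len(length(seg_edges) - 1L)) {
    t0 <- seg_edges[k]
    t1 <- seg_edges[k + 1L]
    s <- protocol_magnitude(protocol, t0)
    sel <- which(times >= t0 & times <= t1)
    if (length(sel)) {
      vals <- propagate_signal(state, s, times[sel] - t0, params)
      s_eff[sel] <- vals[, 1]
      inhib[sel] <- vals[, 2]
    }
    state <- propagate_signal(state, s, t1 - t0, params)[1, ]
  }

  out <- tibble::tibble(
    time_h = as.numeric(times),
    s_eff = s_eff,
    inhibitor = inhib,
    s_eff_plus = pmax(s_eff, 0)
  )
  class(out) <- c("signal_trace", class(out))
  attr(out, "signal_params") <- params
  out
}

# Exact propagation of (s_eff, I) under constant stimulus s for elapsed
# times dt (vector). The system matrix is upper triangular with distinct
# eigenvalues -1/tau_e and -1/tau_a, so expm has a two-exponential closed
# form. Fixed point: (0, s).
propagate_signal <- function(state, s, dt, params) {
  a <- -1 / params$tau_e
  d <- -1 / params$tau_a
  c_off <- -1 / params$tau_e
  ea <- exp(a * dt)
  ed <- exp(d * dt)
  y1 <- state[1] - 0
  y2 <- state[2] - s
  cbind(
    ea * y1 + c_off * (ea - ed) / (a - d) * y2,
    ed * y2 + s
  )
}

#' Reset the positive part of a signal trace
#'
#' Recomputes `s_eff_plus = max(s_eff, 0)` elementwise; useful after manual
#' edits to a trace.
#'
#' @param trace A `signal_trace` tibble (or any tibble with an `s_eff`
#'   column).
#' @return The trace with `s_eff_plus` set.
#' @export
positive_part <- function(trace) {
  if (!"s_eff" %in% names(trace)) {
    rlang::abort("`trace` must have an `s_eff` column.",
      class = "voltaxis_invalid_input"
    )
  }
  trace$s_eff_plus <- pmax(trace$s_eff, 0)
  trace
}

# Fine uniform-in-segment grid containing all of `times` as exact nodes:
# every output interval is split into substeps no longer than dt_max.
refine_grid <- function(times, dt_max) {
  pieces <- lapply(seq_len(length(times) - 1L), function(i) {
    n <- max(1L, ceiling((times[i + 1L] - times[i]) / dt_max))
    seq(times[i], times[i + 1L], length.out = n + 1L)[-(n + 1L)]
  })
  c(unlist(pieces), times[length(times)])
}
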