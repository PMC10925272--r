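#' Piecewise-constant stimulation protocol
#'
#' Describes the applied electric field as a piecewise-constant function of
#' time: magnitude `magnitudes[i]` (dimensionless; 1 corresponds to 3 V/cm)
#' on the interval `[breakpoints[i], breakpoints[i + 1])`, and 0 after the
#' final breakpoint. In two dimensions each interval additionally carries a
#' unit direction vector; the signal model only senses the magnitude.
#'
#' @param breakpoints Strictly increasing times (h) at which the field
#'   changes; `length(magnitudes) == length(breakpoints) - 1`.
#' @param magnitudes Non-negative field magnitude on each interval.
#' @param directions Optional matrix with one row per interval and columns
#'   `(x, y)`; rows are normalised to unit length. Defaults to the +x axis.
#' @return An object of class `stimulus_protocol`.
#' @seealso [step_protocol()] for the usual off/on/off experiment.
#' @export
stimulus_protocol <- function(breakpoints, magnitudes, directions = NULL) {
  if (!is.numeric(breakpoints) || length(breakpoints) < 2L ||
    any(diff(breakpoints) <= 0)) {
    rlang::abort("`breakpoints` must be strictly increasing, length >= 2.",
      class = "voltaxis_invalid_input"
    )
  }
  if (!is.numeric(magnitudes) ||
    length(magnitudes) != length(breakpoints) - 1L) {
    rlang::abort("`magnitudes` must have one value per interval.",
      class = "voltaxis_invalid_input"
    )
  }
  if (any(magnitudes < 0)) {
    rlang::abort("Field magnitudes must be >= 0.",
      class = "voltaxis_invalid_input"
    )
  }
  n_int <- length(magnitudes)
  if (is.null(directions)) {
    directions <- matrix(rep(c(1, 0), each = n_int), ncol = 2)
  }
  directions <- as.matrix(directions)
  if (nrow(directions) != n_int || ncol(directions) != 2L) {
    rlang::abort("`directions` must be an n_interval x 2 matrix.",
      class = "voltaxis_invalid_input"
    )
  }
  nrm <- sqrt(rowSums(directions^2))
  if (any(nrm == 0)) {
    rlang::abort("Direction vectors must be nonzero.",
      class = "voltaxis_invalid_input"
    )
  }
  directions <- directions / nrm
  colnames(directions) <- c("x", "y")
  structure(
    list(
      breakpoints = as.numeric(breakpoints),
      magnitudes = as.numeric(magnitudes),
      directions = directions
    ),
    class = "stimulus_protocol"
  )
}

#' Standard off/on/off step stimulation
#'
#' The canonical monolayer electrotaxis experiment: a pre-stimulation rest,
#' a constant field step, and a post-stimulation rest. The default protocol
#' used throughout the package is 1 h off, 3 h on at magnitude 1
#' (3 V/cm), 3 h off.
#'
#' @param pre Hours before the field is switched on.
#' @param on Hours of stimulation.
#' @param post Hours after the field is switched off.
#' @param magnitude Dimensionless field magnitude during stimulation.
#' @param direction Length-2 field direction (2D use only).
#' @return A `stimulus_protocol`.
#' @examples
#' step_protocol()
#' @export
step_protocol <- function(pre = 1, on = 3, post = 3, magnitude = 1,
                          direction = c(1, 0)) {
  check_number(pre, "pre", nonnegative = TRUE)
  check_number(on, "on", positive = TRUE)
  check_number(post, "post", nonnegative = TRUE)
  bp <- c(0, pre, pre + on, pre + on + post)
  mags <- c(0, magnitude, 0)
  dirs <- matrix(rep(direction, 3), ncol = 2, byrow = TRUE)
  keep <- diff(bp) > 0
  bp <- c(bp[c(keep, TRUE)])
  # collapse zero-length leading/trailing intervals
  stimulus_protocol(bp, mags[keep], dirs[keep, , drop = FALSE])
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("<stimulus_protocol>\n")
  n <- length(x$magnitudes)
  for (i in seq_len(n)) {
    cat(sprintf(
      "  [%g, %g) h: |s| = %g, direction (%.3g, %.3g)\n",
      x$breakpoints[i], x$breakpoints[i + 1], x$magnitudes[i],
      x$directions[i, 1], x$directions[i, 2]
    ))
  }
  cat(sprintf("  t >= %g h: field off\n", x$breakpoints[n + 1]))
  invisible(x)
}

#' Stimulation window of a protocol
#'
#' @param protocol A [stimulus_protocol()].
#' @return Named numeric `c(on, off)`: first time a nonzero magnitude starts
#'   and the end of the last nonzero interval. `NA` if the field never turns
#'   on.
#' @export
stimulation_window <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  idx <- which(protocol$magnitudes > 0)
  if (length(idx) == 0L) {
    return(c(on = NA_real_, off = NA_real_))
  }
  c(
    on = protocol$breakpoints[min(idx)],
    off = protocol$breakpoints[max(idx) + 1L]
  )
}

#' Evaluate protocol magnitude at given times
#'
#' Right-continuous lookup: a breakpoint belongs to the interval it starts.
#'
#' @param protocol A [stimulus_protocol()].
#' @param times Numeric times (h).
#' @return Numeric vector of field magnitudes.
#' @export
protocol_magnitude <- function(protocol, times) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  idx <- findInterval(times, protocol$breakpoints)
  out <- numeric(length(times))
  inside <- idx >= 1L & idx <= length(protocol$magnitudes)
  out[inside] <- protocol$magnitudes[idx[inside]]
  out
}

#' Field direction at given times (2D)
#'
#' @inheritParams protocol_magnitude
#' @return A 2-column matrix of unit direction vectors (the +x axis outside
#'   defined intervals).
#' @export
protocol_direction <- function(protocol, times) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  idx <- findInterval(times, protocol$breakpoints)
  out <- matrix(rep(c(1, 0), each = length(times)), ncol = 2)
  inside <- idx >= 1L & idx <= length(protocol$magnitudes)
  out[inside, ] <- protocol$directions[idx[inside], , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Read a stimulation protocol from a YAML or JSON config
#'
#' The config is a list of intervals, each with fields `t_start`, `t_end`,
#' `magnitude` and optionally `direction` (length-2). Intervals must be
#' contiguous and ordered.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [stimulus_protocol()].
#' @export
read_protocol <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(spec$intervals)) spec <- spec$intervals
  t0 <- purrr::map_dbl(spec, "t_start")
  t1 <- purrr::map_dbl(spec, "t_end")
  if (any(abs(t1[-length(t1)] - t0[-1]) > 1e-12)) {
    rlang::abort("Protocol intervals must be contiguous.",
      class = "voltaxis_invalid_input"
    )
  }
  dirs <- t(vapply(
    spec,
    function(iv) as.numeric(iv$direction %||% c(1, 0)),
    numeric(2)
  ))
  stimulus_protocol(
    breakpoints = c(t0, t1[length(t1)]),
    magnitudes = purrr::map_dbl(spec, "magnitude"),
    directions = dirs
  )
}
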