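#' Read and write region velocity tables
#'
#' Velocity traces are stored as tab-separated tables with a `time_h`
#' column and the four region columns `v_bulk`, `v_leading`, `v_trailing`,
#' `v_top` in um/h. Reading validates the schema (missing columns are
#' named) and rejects non-finite rows by index; write-then-read is the
#' identity.
#'
#' @param path File path.
#' @param traces A `region_traces` tibble.
#' @return `read_velocity_traces()` returns a `region_traces` tibble;
#'   `write_velocity_traces()` returns `path` invisibly.
#' @export
read_velocity_traces <- function(path) {
  d <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  req <- c("time_h", "v_bulk", "v_leading", "v_trailing", "v_top")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols)) {
    rlang::abort(
      sprintf("Velocity table is missing column(s): %s.",
        toString(missing_cols)
      ),
      class = "voltaxis_schema_error"
    )
  }
  bad <- which(!stats::complete.cases(d[req]) |
    rowSums(!is.finite(as.matrix(d[req]))) > 0)
  if (length(bad)) {
    rlang::abort(
      sprintf("Non-finite values in row(s): %s.",
        toString(utils::head(bad, 5))
      ),
      class = "voltaxis_schema_error"
    )
  }
  out <- tibble::as_tibble(d[req])
  class(out) <- c("region_traces", class(out))
  out
}

#' @rdname read_velocity_traces
#' @export
write_velocity_traces <- function(traces, path) {
  req <- c("time_h", "v_bulk", "v_leading", "v_trailing", "v_top")
  missing_cols <- setdiff(req, names(traces))
  if (length(missing_cols)) {
    rlang::abort(
      sprintf("`traces` is missing column(s): %s.", toString(missing_cols)),
      class = "voltaxis_schema_error"
    )
  }
  readr::write_tsv(tibble::as_tibble(traces)[req], path)
  invisible(path)
}

#' Read and write density grids
#'
#' Density fields are stored as tab-separated long tables (`x`, `rho` for
#' 1D; `x`, `y`, `rho`, `mask` for 2D) preceded by `#key value` metadata
#' lines carrying the grid spacing, field time and dimensionality at full
#' precision. Round trips are lossless. A missing `mask` column on read
#' defaults to all-`TRUE` with a warning.
#'
#' @param path File path.
#' @param field A `density_field_1d` or `density_field_2d`.
#' @return `read_density_grid()` returns the density field;
#'   `write_density_grid()` returns `path` invisibly.
#' @export
write_density_grid <- function(field, path) {
  is2d <- inherits(field, "density_field_2d")
  if (!is2d && !inherits(field, "density_field_1d")) {
    rlang::abort("`field` must be a density field.",
      class = "voltaxis_invalid_input"
    )
  }
  meta <- c(
    sprintf("#dim %d", if (is2d) 2L else 1L),
    sprintf("#spacing %.17g", attr(field, "spacing")),
    sprintf("#time_h %.17g", attr(field, "time_h") %||% 0)
  )
  writeLines(meta, path)
  cols <- if (is2d) c("x", "y", "rho", "mask") else c("x", "rho")
  readr::write_tsv(tibble::as_tibble(field)[cols], path, append = TRUE,
    col_names = TRUE
  )
  invisible(path)
}

#' @rdname write_density_grid
#' @export
read_density_grid <- function(path) {
  hdr <- readLines(path, n = 10)
  meta_lines <- grep("^#", hdr, value = TRUE)
  meta <- strsplit(sub("^#", "", meta_lines), " ")
  vals <- setNames(
    purrr::map_chr(meta, 2),
    purrr::map_chr(meta, 1)
  )
  d <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  dim_n <- as.integer(vals[["dim"]])
  time_h <- as.numeric(vals[["time_h"]])
  if (dim_n == 1L) {
    if (!all(c("x", "rho") %in% names(d))) {
      rlang::abort("1D density grid needs `x` and `rho` columns.",
        class = "voltaxis_schema_error"
      )
    }
    return(density_field_1d(d$x, d$rho, time = time_h))
  }
  if (!all(c("x", "y", "rho") %in% names(d))) {
    rlang::abort("2D density grid needs `x`, `y`, `rho` columns.",
      class = "voltaxis_schema_error"
    )
  }
  xg <- sort(unique(d$x))
  yg <- sort(unique(d$y))
  if (nrow(d) != length(xg) * length(yg)) {
    rlang::abort("Grid rows do not form a complete x-y lattice.",
      class = "voltaxis_schema_error"
    )
  }
  d <- dplyr::arrange(d, .data$y, .data$x)
  if (!"mask" %in% names(d)) {
    rlang::warn("No `mask` column; defaulting to all-TRUE.")
    d$mask <- TRUE
  }
  density_field_2d(xg, yg,
    matrix(d$rho, length(xg), length(yg)),
    mask = matrix(d$mask, length(xg), length(yg)), time = time_h
  )
}

#' Write a run manifest
#'
#' Records, next to an analysis output, the configuration needed to
#' reproduce it: free-form parameters, the seed, and the package version.
#'
#' @param path Output path (`.json`).
#' @param config Named list of run parameters.
#' @param seed Integer seed used for the run.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, seed = NULL) {
  manifest <- list(
    package = "voltaxis",
    version = as.character(utils::packageVersion("voltaxis")),
    seed = seed,
    config = config,
    written = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Unit conversion between the ODE and PDE velocity scales
#'
#' The region ODE model works in um/h, the continuum model in mm/h.
#'
#' @param v Numeric velocities.
#' @return Converted velocities.
#' @export
um_to_mm <- function(v) v / 1000

#' @rdname um_to_mm
#' @export
mm_to_um <- function(v) v * 1000
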