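#' Class-binning rule for a bioclimatic variable
#'
#' Continuous climate surfaces are reclassified into fixed-width half-open
#' bins before the analog search: class k covers
#' [anchor + k*width, anchor + (k+1)*width). Default widths follow the
#' established choices for these variables: 50 deg C days for GDD,
#' 0.5 deg C for T_Jan, 50 mm for WAB. The anchor is fixed at 0 in variable
#' units, giving data- and resolution-independent class edges.
#'
#' @param variable one of "GDD", "TJAN", "WAB".
#' @param width bin width in variable units (> 0).
#' @param anchor bin edge reference value.
#' @return an object of class `binning_rule`.
#' @export
binning_rule <- function(variable = c("GDD", "TJAN", "WAB"),
                         width = c(GDD = 50, TJAN = 0.5, WAB = 50)[[variable[1]]],
                         anchor = 0) {
  variable <- match.arg(variable)
  if (width <= 0) stop("bin width must be positive")
  structure(list(variable = variable, width = width, anchor = anchor),
            class = "binning_rule")
}

#' Reclassify a continuous climate surface into climate classes
#'
#' @param grid a `clim_grid` in the rule's variable units.
#' @param rule a [binning_rule()].
#' @return an object of class `class_grid`: integer labels
#'   floor((value - anchor)/width) with the grid geometry and rule attached;
#'   nodata cells keep `NA` labels.
#' @export
classify <- function(grid, rule) {
  lab <- floor((grid$values - rule$anchor) / rule$width)
  structure(list(labels = lab, rule = rule,
                 cell_size = grid$cell_size, origin = grid$origin),
            class = "class_grid")
}

#' @export
print.class_grid <- function(x, ...) {
  cat(sprintf("<class_grid> %s (width %g), classes %d..%d, %d nodata\n",
              x$rule$variable, x$rule$width,
              min(x$labels, na.rm = TRUE), max(x$labels, na.rm = TRUE),
              sum(is.na(x$labels))))
  invisible(x)
}

#' Distance to the nearest future climate analog
#'
#' For every present-day cell of class c, the straight-line (Euclidean,
#' cell centre to cell centre) distance in metres to the nearest cell whose
#' future class equals c; 0 where the cell's own future class matches.
#' Cells whose present class occurs nowhere in the future surface have no
#' analog (disappearing climate) and get `Inf`. Nodata cells are excluded
#' both as search origins and as analog targets.
#'
#' The per-class search uses an exact Euclidean distance transform of the
#' future label raster; see [climate_velocity()] for the full pipeline.
#'
#' @param present,future `class_grid`s with identical geometry and rule.
#' @return a `clim_grid` of distances (m; `Inf` = no analog, `NA` = nodata).
#' @export
analog_distance <- function(present, future) {
  if (!identical(dim(present$labels), dim(future$labels)) ||
      !isTRUE(all.equal(present$cell_size, future$cell_size)) ||
      !isTRUE(all.equal(present$origin, future$origin)))
    stop("present and future class grids must share geometry")
  if (!identical(present$rule, future$rule))
    stop("present and future class grids must share the binning rule")
  pl <- present$labels; fl <- future$labels
  out <- matrix(NA_real_, nrow(pl), ncol(pl))
  classes <- sort(unique(pl[!is.na(pl)]))
  for (cl in classes) {
    src <- !is.na(pl) & pl == cl
    tgt <- !is.na(fl) & fl == cl
    if (!any(tgt)) { out[src] <- Inf; next }
    # distmap: distance of nonzero pixels to the nearest zero pixel
    img <- matrix(1, nrow(fl), ncol(fl))
    img[tgt] <- 0
    d <- EBImage::distmap(img, metric = "euclidean")
    out[src] <- as.numeric(d)[src] * present$cell_size
  }
  clim_grid(out, present$cell_size, present$origin)
}

#' Convert analog distances to climate velocities
#'
#' @param dist a `clim_grid` of analog distances (m), `Inf` = no analog.
#' @param years number of years separating the two period midpoints (> 0);
#'   89 years separates the midpoints of 1981-2010 and 2070-2099.
#' @return an object of class `velocity_grid`: `velocity` (a `clim_grid`,
#'   km/yr, `NA` where disappeared or nodata), `disappeared` (logical
#'   matrix) and `years`.
#' @export
velocity_from_distance <- function(dist, years = 89) {
  if (length(years) != 1L || years <= 0) stop("years must be positive")
  disappeared <- is.infinite(dist$values)
  vel <- dist$values / 1000 / years
  vel[disappeared] <- NA_real_
  structure(list(velocity = clim_grid(vel, dist$cell_size, dist$origin),
                 disappeared = disappeared, years = years),
            class = "velocity_grid")
}

#' @export
print.velocity_grid <- function(x, ...) {
  v <- x$velocity$values
  cat(sprintf("<velocity_grid> %d x %d, %d disappeared; velocity [%.3g, %.3g] km/yr over %g yr\n",
              nrow(v), ncol(v), sum(x$disappeared),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), x$years))
  invisible(x)
}

#' Climate-analog velocity of a bioclimatic variable
#'
#' Composition classify -> analog_distance -> velocity_from_distance:
#' reclassifies the present and future surfaces with a shared binning rule,
#' finds for each present cell the nearest future cell of the same class,
#' and divides the distance by the number of years between the period
#' midpoints.
#'
#' @param present_var,future_var `clim_grid`s of one bioclimatic variable.
#' @param rule a [binning_rule()].
#' @param years years between period midpoints (default 89).
#' @return a `velocity_grid`.
#' @export
climate_velocity <- function(present_var, future_var, rule, years = 89) {
  if (!same_geometry(present_var, future_var))
    stop("present and future grids must share geometry")
  velocity_from_distance(
    analog_distance(classify(present_var, rule), classify(future_var, rule)),
    years)
}
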