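#' Monthly climate normals
#'
#' Bundle of twelve monthly mean-temperature grids (January..December, deg C)
#' and one annual-precipitation grid (mm) on a shared geometry, the input to
#' all bioclimatic-variable calculations. A 365-day climatological calendar
#' (no leap day) is used throughout.
#'
#' @param temps list of 12 `clim_grid`s, January first.
#' @param precip_annual `clim_grid` of annual precipitation (mm).
#' @param days_per_month integer vector of month lengths, summing to 365.
#' @return an object of class `monthly_normals`.
#' @export
monthly_normals <- function(temps, precip_annual,
                            days_per_month = c(31L, 28L, 31L, 30L, 31L, 30L,
                                               31L, 31L, 30L, 31L, 30L, 31L)) {
  stopifnot(length(temps) == 12L, sum(days_per_month) == 365L)
  for (m in 2:12) {
    if (!same_geometry(temps[[1]], temps[[m]]))
      stop("monthly temperature grids do not share geometry (month ", m, ")")
  }
  if (!same_geometry(temps[[1]], precip_annual))
    stop("precipitation grid does not share the temperature geometry")
  structure(list(temps = temps, precip_annual = precip_annual,
                 days_per_month = as.integer(days_per_month)),
            class = "monthly_normals")
}

#' @export
print.monthly_normals <- function(x, ...) {
  d <- dim(x$temps[[1]]$values)
  cat(sprintf("<monthly_normals> 12 temperature grids + annual precip, %d x %d cells\n",
              d[1], d[2]))
  invisible(x)
}

#' Growing degree days above a base temperature
#'
#' Annual effective temperature sum (deg C days) estimated from monthly
#' normals: months whose mean temperature exceeds `base_T` contribute
#' (T_m - base_T) times the number of days in the month; months at or below
#' the base contribute nothing, so the result is never negative.
#'
#' @param normals a [monthly_normals()] object.
#' @param base_T base temperature in deg C (default 5, the conventional
#'   threshold for high-latitude growing-season warmth).
#' @return a `clim_grid` of GDD (deg C days).
#' @export
gdd5 <- function(normals, base_T = 5) {
  g1 <- normals$temps[[1]]
  acc <- matrix(0, nrow(g1$values), ncol(g1$values))
  for (m in 1:12) {
    tm <- normals$temps[[m]]$values
    acc <- acc + ifelse(tm > base_T, (tm - base_T), 0) * normals$days_per_month[m]
  }
  clim_grid(acc, g1$cell_size, g1$origin)
}

#' Potential evapotranspiration (temperature-based)
#'
#' PET (mm per year) from the linear monthly formulation
#' PET = 58.93 * sum_m max(T_m, 0) / 12, i.e. 58.93 times the annual mean of
#' the monthly temperatures clamped at 0 deg C.
#'
#' @param normals a [monthly_normals()] object.
#' @return a `clim_grid` of PET (mm).
#' @export
pet <- function(normals) {
  g1 <- normals$temps[[1]]
  acc <- matrix(0, nrow(g1$values), ncol(g1$values))
  for (m in 1:12) acc <- acc + pmax(normals$temps[[m]]$values, 0)
  clim_grid(58.93 * acc / 12, g1$cell_size, g1$origin)
}

#' Climatic water balance
#'
#' WAB = annual precipitation - potential evapotranspiration (mm); negative
#' values indicate climatic drought stress.
#'
#' @param normals a [monthly_normals()] object.
#' @return a `clim_grid` of WAB (mm).
#' @export
wab <- function(normals) {
  p <- normals$precip_annual
  e <- pet(normals)
  clim_grid(p$values - e$values, p$cell_size, p$origin)
}

#' Mean January temperature
#'
#' @param normals a [monthly_normals()] object.
#' @return the January `clim_grid` (deg C), unchanged.
#' @export
t_jan <- function(normals) normals$temps[[1]]

#' The three bioclimatic variables for one period/scenario
#'
#' Computes GDD5, T_Jan and WAB from monthly normals and bundles them with
#' period/scenario labels. All three grids share geometry and nodata mask.
#'
#' @param normals a [monthly_normals()] object.
#' @param period_label,scenario_label free-text labels carried along.
#' @return an object of class `bioclim_set` with fields `gdd`, `t_jan`,
#'   `wab`, `period_label`, `scenario_label`.
#' @export
bioclim_set <- function(normals, period_label = "baseline",
                        scenario_label = "baseline") {
  structure(list(gdd = gdd5(normals), t_jan = t_jan(normals),
                 wab = wab(normals),
                 period_label = period_label, scenario_label = scenario_label),
            class = "bioclim_set")
}

#' @export
print.bioclim_set <- function(x, ...) {
  cat(sprintf("<bioclim_set> %s / %s\n", x$period_label, x$scenario_label))
  for (v in c("gdd", "t_jan", "wab")) {
    r <- range(x[[v]]$values, na.rm = TRUE)
    cat(sprintf("  %-5s [%.1f, %.1f]\n", v, r[1], r[2]))
  }
  invisible(x)
}
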