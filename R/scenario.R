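#' Add coarse scenario deltas to baseline monthly normals
#'
#' Each monthly temperature delta and the annual precipitation delta are
#' bilinearly resampled onto the baseline geometry and added cell-wise
#' (precipitation change is additive, in mm). Nodata masks of the baseline
#' are preserved.
#'
#' @param baseline a [monthly_normals()] object.
#' @param t_deltas list of 12 coarse `clim_grid`s (deg C change), Jan first.
#' @param p_delta coarse `clim_grid` of annual precipitation change (mm).
#' @return a [monthly_normals()] object for the future period.
#' @export
apply_deltas <- function(baseline, t_deltas, p_delta) {
  stopifnot(length(t_deltas) == 12L)
  g1 <- baseline$temps[[1]]
  tdim <- dim(g1$values)
  .check_covers(t_deltas[[1]], g1)
  .check_covers(p_delta, g1)
  res <- function(d) bilinear_resample(d, g1$cell_size, tdim, g1$origin)
  temps <- vector("list", 12L)
  for (m in 1:12) {
    dm <- res(t_deltas[[m]])
    temps[[m]] <- clim_grid(baseline$temps[[m]]$values + dm$values,
                            g1$cell_size, g1$origin)
  }
  dp <- res(p_delta)
  monthly_normals(temps,
                  clim_grid(baseline$precip_annual$values + dp$values,
                            g1$cell_size, g1$origin),
                  baseline$days_per_month)
}

.check_covers <- function(coarse, fine) {
  cxmin <- coarse$origin[1]
  cxmax <- cxmin + ncol(coarse$values) * coarse$cell_size
  cymax <- coarse$origin[2]
  cymin <- cymax - nrow(coarse$values) * coarse$cell_size
  fxmin <- fine$origin[1]
  fxmax <- fxmin + ncol(fine$values) * fine$cell_size
  fymax <- fine$origin[2]
  fymin <- fymax - nrow(fine$values) * fine$cell_size
  if (cxmin > fxmin || cxmax < fxmax || cymin > fymin || cymax < fymax)
    stop("delta grid extent does not cover the baseline extent")
  invisible(TRUE)
}

#' Build a future-scenario climate from baseline normals and deltas
#'
#' Applies the deltas and recomputes the bioclimatic variables from the
#' delta-adjusted monthly normals (they are never delta-adjusted directly,
#' because GDD and PET are nonlinear in temperature).
#'
#' @inheritParams apply_deltas
#' @param label scenario label, e.g. "RCP8.5".
#' @return an object of class `scenario_climate` with fields
#'   `scenario_label`, `normals` (future) and `bioclim` (future).
#' @export
build_scenario <- function(baseline, t_deltas, p_delta, label) {
  fut <- apply_deltas(baseline, t_deltas, p_delta)
  structure(list(scenario_label = label, normals = fut,
                 bioclim = bioclim_set(fut, period_label = "future",
                                       scenario_label = label)),
            class = "scenario_climate")
}

#' @export
print.scenario_climate <- function(x, ...) {
  cat(sprintf("<scenario_climate> %s\n", x$scenario_label))
  print(x$bioclim)
  invisible(x)
}
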