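#' Run the full velocity/exposure analysis on one synthetic landscape
#'
#' Generates a topoclimatic landscape (DEM, monthly normals, reserve
#' polygons), builds baseline bioclimatic surfaces on a fine and an
#' areal-mean aggregated coarse track, applies scenario delta fields
#' (resampled to each track's working resolution) and recomputes the
#' bioclimatic variables per scenario, computes class-binned climate-analog
#' velocities for GDD, T_Jan and WAB on both tracks, and summarises
#' per-reserve exposure and present-vs-future range overlap.
#'
#' @param seed integer; drives every random component.
#' @param relief_class terrain class 1-3 (see [relief_spec()]).
#' @param shape fine-grid (rows, cols).
#' @param cell_size fine cell size (m).
#' @param agg_factor aggregation factor for the coarse track (e.g. 20 for
#'   a 50 m to 1 km comparison).
#' @param n_pas number of reserve polygons.
#' @param area_range reserve area range (ha).
#' @param scenarios list of [delta_spec()]s; defaults to the three-pathway
#'   ensemble with ordered mean warming.
#' @param years years between period midpoints.
#' @param trend_range regional west-east elevation ramp passed to
#'   [make_dem()]; the default scales with relief class so the domain's
#'   climate span exceeds the warming signal.
#' @param keep_grids also return the DEM, bioclim sets and velocity grids.
#' @return list with `velocity_records` (per reserve x variable x scenario
#'   x resolution), `rd_records` (GDD relative differences with covariates),
#'   `paired_tests` (per scenario, GDD, coarse vs fine), `overlap_results`,
#'   `overlap_summary`, `pas`, and optionally `grids`.
#' @export
run_landscape_analysis <- function(seed,
                                   relief_class = 3,
                                   shape = c(400, 400),
                                   cell_size = 50,
                                   agg_factor = 20,
                                   n_pas = 200,
                                   area_range = c(2, 100),
                                   scenarios = default_scenarios(seed),
                                   years = 89,
                                   trend_range = c(150, 400, 800)[relief_class],
                                   keep_grids = FALSE) {
  dem <- make_dem(shape, cell_size, relief_spec(relief_class), seed = seed,
                  trend_range = trend_range)
  normals_fine <- make_monthly_climate(dem, climate_gen_params(seed = seed + 1))
  normals_coarse <- aggregate_normals(normals_fine, agg_factor)
  base_fine <- bioclim_set(normals_fine)
  base_coarse <- bioclim_set(normals_coarse)
  pas <- make_pa_polygons(dem, n_pas, area_range, seed = seed + 2)

  rules <- list(GDD = binning_rule("GDD"), TJAN = binning_rule("TJAN"),
                WAB = binning_rule("WAB"))
  pick <- function(bs, v) switch(v, GDD = bs$gdd, TJAN = bs$t_jan, WAB = bs$wab)

  vel_records <- list(); overlap_rows <- list(); paired <- list()
  rd_records <- list(); grids <- list()
  for (sc in scenarios) {
    deltas <- make_delta_fields(sc, dem)
    fut_fine <- build_scenario(normals_fine, deltas$t_deltas, deltas$p_delta,
                               sc$scenario)
    fut_coarse <- build_scenario(normals_coarse, deltas$t_deltas,
                                 deltas$p_delta, sc$scenario)
    per_var <- list()
    for (v in names(rules)) {
      vf <- climate_velocity(pick(base_fine, v), pick(fut_fine$bioclim, v),
                             rules[[v]], years)
      vc <- climate_velocity(pick(base_coarse, v), pick(fut_coarse$bioclim, v),
                             rules[[v]], years)
      zf <- zonal_mean(vf, pas, dem); zf$variable <- v
      zf$scenario <- sc$scenario; zf$resolution <- "fine"
      zc <- zonal_mean(vc, pas, dem); zc$variable <- v
      zc$scenario <- sc$scenario; zc$resolution <- "coarse"
      vel_records[[paste(sc$scenario, v)]] <- rbind(zf, zc)
      per_var[[v]] <- list(fine = zf, coarse = zc)
      overlap_rows[[paste(sc$scenario, v, "fine")]] <-
        pa_range_overlap(pick(base_fine, v), pick(fut_fine$bioclim, v), pas,
                         variable = v, scenario = sc$scenario,
                         resolution_track = "fine")
      overlap_rows[[paste(sc$scenario, v, "coarse")]] <-
        pa_range_overlap(pick(base_coarse, v), pick(fut_coarse$bioclim, v),
                         pas, variable = v, scenario = sc$scenario,
                         resolution_track = "coarse")
      if (keep_grids)
        grids[[paste(sc$scenario, v)]] <- list(fine = vf, coarse = vc)
    }
    # resolution comparison on GDD only: WAB velocities are localised and
    # T_Jan suffers wholesale climate disappearance under strong warming
    zf <- per_var$GDD$fine; zc <- per_var$GDD$coarse
    n_pairs <- sum(!is.na(zf$mean_velocity_kmyr) &
                   !is.na(zc$mean_velocity_kmyr))
    paired[[sc$scenario]] <-
      if (n_pairs >= 2) paired_velocity_test(zf$mean_velocity_kmyr,
                                             zc$mean_velocity_kmyr)
      else list(n = n_pairs, mean_diff = NA_real_, t = NA_real_,
                df = NA_real_, p = NA_real_, prop_coarse_gt_fine = NA_real_,
                degenerate = TRUE)
    rd <- zf[c("pa_id", "area_ha", "relief_region", "elev_range_m")]
    rd$scenario <- sc$scenario
    rd$fine <- zf$mean_velocity_kmyr
    rd$coarse <- zc$mean_velocity_kmyr[match(zf$pa_id, zc$pa_id)]
    ok <- !is.na(rd$fine) & !is.na(rd$coarse) & (rd$fine + rd$coarse) > 0
    rd <- rd[ok, , drop = FALSE]
    rd$rel_diff <- relative_difference(rd$fine, rd$coarse)
    rd_records[[sc$scenario]] <- rd
  }
  overlap_results <- do.call(rbind, overlap_rows)
  rownames(overlap_results) <- NULL
  out <- list(velocity_records = do.call(rbind, vel_records),
              rd_records = do.call(rbind, rd_records),
              paired_tests = paired,
              overlap_results = overlap_results,
              overlap_summary = overlap_summary(overlap_results),
              pas = pas,
              dem = if (keep_grids) dem else NULL,
              grids = if (keep_grids) grids else NULL)
  rownames(out$velocity_records) <- NULL
  rownames(out$rd_records) <- NULL
  out
}

#' Default three-pathway scenario ensemble
#'
#' Mean warmings 1.5, 2.6 and 4.6 deg C for RCP2.6, RCP4.5 and RCP8.5 --
#' typical late-century ensemble-mean signals for a high-latitude domain --
#' with a +40 mm precipitation change and a 5-km delta grid.
#'
#' @param seed integer; each pathway gets a derived seed.
#' @return list of three [delta_spec()]s with ordered mean warming.
#' @export
default_scenarios <- function(seed = 1L) {
  list(delta_spec("RCP2.6", seed = seed + 101),
       delta_spec("RCP4.5", seed = seed + 102),
       delta_spec("RCP8.5", seed = seed + 103))
}

#' Areal-mean aggregation of monthly normals
#'
#' Aggregates all twelve temperature grids and the precipitation grid with
#' [aggregate_mean()], preserving the month-length calendar.
#'
#' @param normals a [monthly_normals()] object.
#' @param factor positive integer aggregation factor.
#' @return a [monthly_normals()] object on the coarse geometry.
#' @export
aggregate_normals <- function(normals, factor) {
  monthly_normals(lapply(normals$temps, aggregate_mean, factor = factor),
                  aggregate_mean(normals$precip_annual, factor),
                  normals$days_per_month)
}
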