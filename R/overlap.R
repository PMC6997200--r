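#' Within-reserve range of a climate variable
#'
#' Min and max of the nodata-free cell values covered by the polygon
#' (cell-centre membership with the intersection fallback of
#' [cells_in_polygon()]).
#'
#' @param var_grid a `clim_grid`.
#' @param poly one element of a `pa_set`.
#' @return numeric length-2 `c(min, max)`.
#' @export
within_pa_range <- function(var_grid, poly) {
  idx <- cells_in_polygon(var_grid, poly)
  if (nrow(idx) == 0L) stop("polygon covers no grid cells")
  v <- var_grid$values[idx]
  v <- v[!is.na(v)]
  if (!length(v)) stop("polygon covers only nodata cells")
  c(min(v), max(v))
}

#' Overlap and gap between present and future climate ranges
#'
#' Two intervals overlap when neither lies entirely beyond the other;
#' touching intervals (present max equal to future min) count as
#' overlapping with gap 0. For disjoint intervals the gap is the distance
#' between the nearer endpoints and the direction records whether the
#' future range sits above (warming/wetting) or below (drying) the present
#' one.
#'
#' @param present,future numeric length-2 `c(min, max)` intervals.
#' @return list: `overlaps` (logical), `gap` (variable units, 0 when
#'   overlapping), `direction` ("overlap", "future_above", "future_below").
#' @export
range_overlap <- function(present, future) {
  if (present[1] > present[2] || future[1] > future[2])
    stop("malformed interval (min > max)")
  if (present[2] >= future[1] && future[2] >= present[1])
    return(list(overlaps = TRUE, gap = 0, direction = "overlap"))
  if (future[1] > present[2])
    list(overlaps = FALSE, gap = future[1] - present[2],
         direction = "future_above")
  else
    list(overlaps = FALSE, gap = present[1] - future[2],
         direction = "future_below")
}

#' Present-vs-future range overlap for every reserve
#'
#' @param present_grid,future_grid `clim_grid`s of one climate variable for
#'   the two periods, same geometry.
#' @param pas a `pa_set`.
#' @param variable,scenario,resolution_track labels copied into the output.
#' @return data.frame: pa_id, variable, scenario, resolution_track,
#'   present_min/max, future_min/max, overlaps, gap, direction.
#' @export
pa_range_overlap <- function(present_grid, future_grid, pas,
                             variable = "", scenario = "",
                             resolution_track = "fine") {
  rows <- lapply(pas, function(p) {
    pr <- within_pa_range(present_grid, p)
    fu <- within_pa_range(future_grid, p)
    ro <- range_overlap(pr, fu)
    data.frame(pa_id = p$pa_id, variable = variable, scenario = scenario,
               resolution_track = resolution_track,
               present_min = pr[1], present_max = pr[2],
               future_min = fu[1], future_max = fu[2],
               overlaps = ro$overlaps, gap = ro$gap, direction = ro$direction)
  })
  do.call(rbind, rows)
}

#' Summarise range-overlap results
#'
#' Counts of overlapping reserves and the mean gap among non-overlapping
#' ones, per variable x scenario x resolution track.
#'
#' @param results data.frame as produced by [pa_range_overlap()] (rows from
#'   several calls may be concatenated).
#' @return data.frame: variable, scenario, resolution_track, n, n_overlap,
#'   mean_gap (NA when every reserve overlaps).
#' @export
overlap_summary <- function(results) {
  if (nrow(results) == 0L) stop("empty results")
  key <- interaction(results$variable, results$scenario,
                     results$resolution_track, drop = TRUE)
  out <- lapply(split(results, key), function(g) {
    gaps <- g$gap[!g$overlaps]
    data.frame(variable = g$variable[1], scenario = g$scenario[1],
               resolution_track = g$resolution_track[1],
               n = nrow(g), n_overlap = sum(g$overlaps),
               mean_gap = if (length(gaps)) mean(gaps) else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
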