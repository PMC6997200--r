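#' Grid cells covered by a polygon
#'
#' Membership is cell-centre-inside-polygon. When no cell centre falls
#' inside (a reserve smaller than one cell of a coarse grid), membership
#' falls back to the single cell containing the polygon's centroid -- the
#' cell the reserve effectively sits in, mirroring how zonal statistics
#' treat sub-cell polygons. Spreading such a reserve over every straddled
#' cell would assign it the climate variation of a neighbourhood many times
#' its own size.
#'
#' @param grid a `clim_grid`.
#' @param poly one element of a `pa_set` (list with `xy` ring).
#' @return integer matrix of (row, col) indices; zero rows if the polygon
#'   misses the grid entirely.
#' @export
cells_in_polygon <- function(grid, poly) {
  cs <- grid$cell_size
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  xy <- poly$xy
  cmin <- max(1L, floor((min(xy[, 1]) - grid$origin[1]) / cs) + 1L)
  cmax <- min(nc, ceiling((max(xy[, 1]) - grid$origin[1]) / cs))
  rmin <- max(1L, floor((grid$origin[2] - max(xy[, 2])) / cs) + 1L)
  rmax <- min(nr, ceiling((grid$origin[2] - min(xy[, 2])) / cs))
  if (cmin > cmax || rmin > rmax) return(matrix(integer(0), 0, 2))
  rows <- rmin:rmax; cols <- cmin:cmax
  px <- grid$origin[1] + (rep(cols, each = length(rows)) - 0.5) * cs
  py <- grid$origin[2] - (rep(rows, times = length(cols)) - 0.5) * cs
  inside <- .points_in_polygon(px, py, xy)
  idx <- cbind(rep(rows, times = length(cols))[inside],
               rep(cols, each = length(rows))[inside])
  if (nrow(idx) == 0L) {
    # sub-cell fallback: the cell containing the polygon centroid
    vx <- mean(xy[, 1]); vy <- mean(xy[, 2])
    r <- floor((grid$origin[2] - vy) / cs) + 1L
    c <- floor((vx - grid$origin[1]) / cs) + 1L
    if (r >= 1L && r <= nr && c >= 1L && c <= nc) idx <- cbind(r, c)
  }
  idx
}

#' Per-reserve zonal velocity statistics
#'
#' For each polygon: mean velocity over its nodata-free, non-disappeared
#' cells, the fraction of cells with disappeared climate, polygon area,
#' within-polygon elevation range and relief region (majority relief class
#' of the polygon's DEM cells).
#'
#' @param vel a `velocity_grid`.
#' @param pas a `pa_set`.
#' @param dem the fine-resolution DEM `clim_grid` (used for elevation range
#'   and relief class regardless of the velocity grid's resolution).
#' @return data.frame with columns pa_id, area_ha, relief_region,
#'   elev_range_m, mean_velocity_kmyr, frac_disappeared, n_cells.
#' @export
zonal_mean <- function(vel, pas, dem) {
  relief <- relief_class_grid(dem)
  rows <- lapply(pas, function(p) {
    idx <- cells_in_polygon(vel$velocity, p)
    if (nrow(idx) == 0L)
      stop("polygon ", p$pa_id, " covers no grid cells even after fallback")
    v <- vel$velocity$values[idx]
    dis <- vel$disappeared[idx]
    valid <- !dis & !is.na(v)
    didx <- cells_in_polygon(dem, p)
    elev <- dem$values[didx]
    rcl <- relief$values[didx]
    data.frame(
      pa_id = p$pa_id,
      area_ha = .polygon_area(p$xy) / 1e4,
      relief_region = as.integer(stats::median(rcl, na.rm = TRUE)),
      elev_range_m = max(elev, na.rm = TRUE) - min(elev, na.rm = TRUE),
      mean_velocity_kmyr = if (any(valid)) mean(v[valid]) else NA_real_,
      frac_disappeared = mean(dis, na.rm = TRUE),
      n_cells = nrow(idx))
  })
  do.call(rbind, rows)
}

#' Top-fraction velocity hotspots
#'
#' The floor(fraction * N) reserves with the highest mean velocity;
#' ties at the cutoff are broken by ascending `pa_id` for determinism.
#' Reserves whose climate has entirely disappeared (no finite mean) are
#' excluded from the ranking.
#'
#' @param records data.frame with `pa_id` and `mean_velocity_kmyr` columns
#'   (one row per reserve).
#' @param fraction fraction in (0, 1); default 0.05, the conventional
#'   hotspot cut.
#' @return integer vector of hotspot `pa_id`s.
#' @export
top_fraction <- function(records, fraction = 0.05) {
  if (nrow(records) == 0L) stop("empty record set")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  k <- floor(fraction * nrow(records))
  ranked <- records[!is.na(records$mean_velocity_kmyr), , drop = FALSE]
  ord <- order(-ranked$mean_velocity_kmyr, ranked$pa_id)
  ranked$pa_id[ord][seq_len(min(k, nrow(ranked)))]
}

#' Overlap between hotspot sets
#'
#' @param setA,setB,setC vectors of reserve ids from the same universe
#'   (`setC` optional).
#' @return list with `n_shared`, `pct_shared` (100 * |A n B| / |A|), and,
#'   when `setC` is given, `n_shared_triple`.
#' @export
hotspot_overlap <- function(setA, setB, setC = NULL) {
  ab <- intersect(setA, setB)
  out <- list(n_shared = length(ab),
              pct_shared = if (length(setA)) 100 * length(ab) / length(setA)
                           else NA_real_)
  if (!is.null(setC)) out$n_shared_triple <- length(intersect(ab, setC))
  out
}

#' Paired comparison of coarse- vs fine-resolution velocities
#'
#' Paired t-test on per-reserve differences (coarse - fine), plus the
#' proportion of reserves where the coarse velocity is strictly higher.
#' A zero-variance difference vector (all differences identical) is
#' reported with `degenerate = TRUE` and an `NA` t statistic rather than
#' an error.
#'
#' @param fine,coarse numeric vectors of per-reserve mean velocities
#'   (km/yr), aligned; pairs with any NA are dropped.
#' @return list: n, mean_diff, t, df, p, prop_coarse_gt_fine, degenerate.
#' @export
paired_velocity_test <- function(fine, coarse) {
  ok <- !is.na(fine) & !is.na(coarse)
  d <- coarse[ok] - fine[ok]
  n <- length(d)
  if (n < 2) stop("fewer than 2 complete pairs")
  s <- stats::sd(d)
  degenerate <- s == 0
  tt <- if (degenerate) NA_real_ else mean(d) / (s / sqrt(n))
  list(n = n, mean_diff = mean(d), t = tt, df = n - 1,
       p = if (degenerate) NA_real_ else 2 * stats::pt(-abs(tt), n - 1),
       prop_coarse_gt_fine = mean(d > 0),
       degenerate = degenerate)
}

#' Relative difference between coarse and fine velocities
#'
#' Symmetric mean-normalised difference
#' RD = (coarse - fine) / ((coarse + fine)/2), bounded in (-2, 2);
#' positive where the coarse-resolution velocity is larger. Pairs with both
#' velocities zero are undefined and returned as `NA` with a warning.
#'
#' @param fine,coarse non-negative velocities (km/yr), vectorised.
#' @return numeric vector of relative differences.
#' @export
relative_difference <- function(fine, coarse) {
  stopifnot(all(fine >= 0, na.rm = TRUE), all(coarse >= 0, na.rm = TRUE))
  both0 <- !is.na(fine) & !is.na(coarse) & fine == 0 & coarse == 0
  if (any(both0))
    warning(sum(both0), " pair(s) with both velocities zero; RD undefined, ",
            "returned as NA")
  out <- (coarse - fine) / ((coarse + fine) / 2)
  out[both0] <- NA_real_
  out
}

#' GLM of relative velocity differences on reserve characteristics
#'
#' Gaussian identity-link fit of RD on relief region (ordinal, coded 1-3 as
#' a single linear term), log reserve area, log within-reserve elevation
#' range, and climate scenario (categorical factor). Effect sizes of the
#' three terrain predictors are the response-scale range between the
#' prediction at the predictor's observed minimum and maximum with all
#' other predictors fixed at their means -- for the identity link this
#' equals |coefficient| x observed range; the slope sign is recorded
#' separately.
#'
#' @param records data.frame with columns `rel_diff`, `relief_region`,
#'   `area_ha`, `elev_range_m`, `scenario`.
#' @return an object of class `glm_result`: `fit` (the `glm` object),
#'   `coefficients` (summary table) and `effect_sizes` (data.frame with
#'   predictor, effect_size, sign).
#' @export
glm_relative_diff <- function(records) {
  need <- c("rel_diff", "relief_region", "area_ha", "elev_range_m", "scenario")
  stopifnot(all(need %in% names(records)))
  records <- records[stats::complete.cases(records[need]), , drop = FALSE]
  if (nrow(records) < 30) stop("need at least 30 complete records")
  if (any(records$area_ha <= 0) || any(records$elev_range_m <= 0))
    stop("area and elevation range must be positive for log transforms")
  df <- data.frame(rd = records$rel_diff,
                   relief = as.numeric(records$relief_region),
                   log_area = log(records$area_ha),
                   log_elev_range = log(records$elev_range_m),
                   scenario = factor(records$scenario))
  drop_scen <- nlevels(df$scenario) < 2
  form <- if (drop_scen) rd ~ relief + log_area + log_elev_range
          else rd ~ relief + log_area + log_elev_range + scenario
  fit <- stats::glm(form, family = stats::gaussian(), data = df)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient fit: a covariate is constant or collinear")
  cf <- summary(fit)$coefficients
  es <- do.call(rbind, lapply(c("relief", "log_area", "log_elev_range"),
    function(p) {
      rng <- range(df[[p]])
      lo <- hi <- data.frame(relief = mean(df$relief),
                             log_area = mean(df$log_area),
                             log_elev_range = mean(df$log_elev_range),
                             scenario = factor(levels(df$scenario)[1],
                                               levels = levels(df$scenario)))
      lo[[p]] <- rng[1]; hi[[p]] <- rng[2]
      d <- stats::predict(fit, hi, type = "response") -
           stats::predict(fit, lo, type = "response")
      data.frame(predictor = p, effect_size = abs(d), sign = sign(d))
    }))
  rownames(es) <- NULL
  structure(list(fit = fit, coefficients = cf, effect_sizes = es),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat("<glm_result> RD ~ relief + log(area) + log(elev range) [+ scenario]\n")
  print(round(x$coefficients, 4))
  cat("effect sizes (prediction range, others at means):\n")
  print(x$effect_sizes)
  invisible(x)
}
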