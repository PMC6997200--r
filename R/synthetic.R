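#' Relief specification for synthetic terrain
#'
#' Terrain classes follow the conventional three-way division of boreal
#' landscapes by the height range within 10 km x 10 km blocks:
#' 1 = flatlands (< 50 m), 2 = gently undulating hilly terrain (50-200 m),
#' 3 = rugged terrain (> 200 m).
#'
#' @param region_class integer 1, 2 or 3.
#' @param relief_amplitude target height range (m) per 10-km block; must be
#'   consistent with `region_class`.
#' @param correlation_length horizontal correlation length of the terrain (m).
#' @return an object of class `relief_spec`.
#' @export
relief_spec <- function(region_class,
                        relief_amplitude = c(35, 120, 400)[region_class],
                        correlation_length = 1500) {
  stopifnot(region_class %in% 1:3, relief_amplitude > 0, correlation_length > 0)
  ok <- switch(region_class,
               relief_amplitude < 50,
               relief_amplitude >= 50 && relief_amplitude <= 200,
               relief_amplitude > 200)
  if (!ok) stop("relief_amplitude ", relief_amplitude,
                " inconsistent with region class ", region_class)
  structure(list(region_class = as.integer(region_class),
                 relief_amplitude = relief_amplitude,
                 correlation_length = correlation_length),
            class = "relief_spec")
}

# Evaluate expr with a temporary RNG state so generators are deterministic
# per seed without clobbering the caller's stream.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Separable Gaussian smoothing of a matrix (sd in cells), edge-renormalised.
.gauss_smooth <- function(m, sd_cells) {
  if (sd_cells <= 0) return(m)
  smat <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-0.5 * (d / sd_cells)^2)
    k[d > 4 * sd_cells] <- 0
    k / rowSums(k)
  }
  smat(nrow(m)) %*% m %*% t(smat(ncol(m)))
}

# Height range (max - min) inside each full 10-km tiling block.
.block_ranges <- function(values, cell_size, block_m = 10000) {
  bk <- max(1L, as.integer(round(block_m / cell_size)))
  nrb <- nrow(values) %/% bk; ncb <- ncol(values) %/% bk
  if (nrb < 1 || ncb < 1)
    stop("domain smaller than one ", block_m / 1000, "-km block")
  out <- matrix(NA_real_, nrb, ncb)
  for (i in seq_len(nrb)) for (j in seq_len(ncb)) {
    blk <- values[((i - 1) * bk + 1):(i * bk), ((j - 1) * bk + 1):(j * bk)]
    out[i, j] <- max(blk, na.rm = TRUE) - min(blk, na.rm = TRUE)
  }
  out
}

#' Generate a synthetic digital elevation model
#'
#' A smooth correlated random surface (Gaussian-filtered white noise),
#' optionally superposed on a regional west-east elevation ramp, rescaled so
#' that the height range within 10-km blocks matches the relief
#' specification to within +/-20% (the field is scaled so the geometric
#' midpoint of the extreme block ranges equals `relief_amplitude`).
#' The regional ramp widens the domain's total elevation -- and hence
#' climate -- span beyond the local relief, the role the 1,000-km
#' south-north macrogradient plays in a full national analysis; without it a
#' desk-scale domain offers no warm-to-cold axis for analogs to move along.
#'
#' @param shape integer (rows, cols).
#' @param cell_size cell size in metres (< 10 km).
#' @param relief a [relief_spec()].
#' @param seed integer RNG seed; same seed gives a bit-identical DEM.
#' @param trend_range total elevation rise (m) of a linear west-east ramp
#'   across the domain before rescaling; 0 disables it.
#' @param base_elevation elevation added uniformly after scaling (m).
#' @return a `clim_grid` of elevations (m).
#' @export
make_dem <- function(shape, cell_size, relief, seed, trend_range = 0,
                     base_elevation = 100) {
  if (cell_size >= 10000) stop("cell_size must be below 10 km")
  nr <- shape[1]; nc <- shape[2]
  z <- .with_seed(seed, {
    w <- matrix(rnorm(nr * nc), nr, nc)
    .gauss_smooth(w, relief$correlation_length / cell_size)
  })
  z <- z / stats::sd(as.vector(z))
  if (trend_range != 0)
    z <- z * 0.5 + matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc) *
      (trend_range / relief$relief_amplitude)
  br <- .block_ranges(z, cell_size)
  s <- relief$relief_amplitude / sqrt(max(br) * min(br))
  z <- z * s
  z <- z - min(z) + base_elevation
  clim_grid(z, cell_size, origin = c(0, nr * cell_size))
}

#' Per-cell relief region classes from a DEM
#'
#' Assigns each cell the relief class of the 10-km tiling block it falls in
#' (partial edge blocks inherit the nearest full block's class is not
#' attempted: edge blocks are classified from their own, smaller, range).
#'
#' @param dem a `clim_grid` of elevations.
#' @param block_m block edge length in metres.
#' @return a `clim_grid` of integer classes 1-3.
#' @export
relief_class_grid <- function(dem, block_m = 10000) {
  bk <- max(1L, as.integer(round(block_m / dem$cell_size)))
  v <- dem$values
  nr <- nrow(v); nc <- ncol(v)
  cls <- matrix(NA_real_, nr, nc)
  for (i0 in seq(1L, nr, by = bk)) for (j0 in seq(1L, nc, by = bk)) {
    i1 <- min(i0 + bk - 1L, nr); j1 <- min(j0 + bk - 1L, nc)
    blk <- v[i0:i1, j0:j1]
    rg <- max(blk, na.rm = TRUE) - min(blk, na.rm = TRUE)
    cls[i0:i1, j0:j1] <- if (rg < 50) 1 else if (rg <= 200) 2 else 3
  }
  clim_grid(cls, dem$cell_size, dem$origin)
}

#' Parameters of the synthetic monthly-climate generator
#'
#' Additive generative stand-in for a topoclimate model driven by elevation,
#' potential solar radiation and relative elevation: monthly temperature is
#' a sea-level annual cycle plus an elevation lapse term, a south-north
#' macrogradient, a radiation (southness) term, a winter-weighted cold-air
#' pooling term on negative relative elevation, and Gaussian noise.
#' Annual precipitation is a base value plus an orographic elevation term
#' and noise.
#'
#' @param sea_level_monthly_T 12 monthly sea-level temperatures (deg C),
#'   January first. The default is a boreal cycle (-8 to 16 deg C).
#' @param lapse_rate deg C per metre, negative (default -0.0065).
#' @param meridional_gradient deg C per km of northing (negative = colder
#'   northwards). The default -0.3 deg C/km compresses a continental-scale
#'   south-north macrogradient (roughly -6 to -8 deg C per 1000 km) into a
#'   desk-scale domain of a few tens of km, so that a late-century warming
#'   signal still has reachable analogs inside the domain; it is a
#'   scaled-down stand-in, not an observed local gradient.
#' @param radiation_coeff deg C per unit southness index (default 0.8).
#' @param cold_pool_coeff deg C per metre of negative relative elevation,
#'   applied with full weight in winter months (default 0.015, i.e. a 40-m
#'   deep depression is 0.6 deg C colder in January).
#' @param noise_sd temperature noise sd (deg C).
#' @param precip_base annual precipitation at zero elevation (mm).
#' @param orographic_coeff mm per metre of elevation (default 0.5).
#' @param precip_noise_sd precipitation noise sd (mm).
#' @param seed integer RNG seed.
#' @return an object of class `climate_gen_params`.
#' @export
climate_gen_params <- function(sea_level_monthly_T = c(-8, -8, -4, 2, 8, 13,
                                                       16, 14, 9, 3, -2, -6),
                               lapse_rate = -0.0065,
                               meridional_gradient = -0.3,
                               radiation_coeff = 0.8,
                               cold_pool_coeff = 0.015,
                               noise_sd = 0.1,
                               precip_base = 600,
                               orographic_coeff = 0.5,
                               precip_noise_sd = 10,
                               seed = 1L) {
  stopifnot(length(sea_level_monthly_T) == 12L, lapse_rate < 0,
            noise_sd >= 0, precip_noise_sd >= 0)
  structure(list(sea_level_monthly_T = sea_level_monthly_T,
                 lapse_rate = lapse_rate,
                 meridional_gradient = meridional_gradient,
                 radiation_coeff = radiation_coeff,
                 cold_pool_coeff = cold_pool_coeff,
                 noise_sd = noise_sd, precip_base = precip_base,
                 orographic_coeff = orographic_coeff,
                 precip_noise_sd = precip_noise_sd, seed = as.integer(seed)),
            class = "climate_gen_params")
}

# Winter weight of the cold-air-pooling term: 1 in Dec-Feb, 0 in Jun-Aug,
# linear in between (Jan..Dec order).
.winter_weight <- c(1, 1, 0.75, 0.5, 0.25, 0, 0, 0, 0.25, 0.5, 0.75, 1)

#' Southness radiation index from a DEM
#'
#' sin(slope) * cos(aspect from south): +1 on steep south-facing slopes,
#' -1 on steep north-facing ones, 0 on flat ground. Gradients are central
#' differences; the grid's row 1 is the northern edge.
#'
#' @param dem a `clim_grid` of elevations (m).
#' @return a `clim_grid` of the dimensionless index in [-1, 1].
#' @export
radiation_index <- function(dem) {
  v <- dem$values
  cs <- dem$cell_size
  nr <- nrow(v); nc <- ncol(v)
  # d(elev)/d(east): columns increase eastwards
  ge <- (v[, c(2:nc, nc)] - v[, c(1, 1:(nc - 1))]) /
    (cs * rep(ifelse(seq_len(nc) %in% c(1, nc), 1, 2), each = nr))
  # d(elev)/d(north): rows increase southwards, so negate the row difference
  gn <- -(v[c(2:nr, nr), ] - v[c(1, 1:(nr - 1)), ]) /
    (cs * ifelse(seq_len(nr) %in% c(1, nr), 1, 2))
  gmag <- sqrt(ge^2 + gn^2)
  slope <- atan(gmag)
  southness <- ifelse(gmag > 0, -gn / pmax(gmag, .Machine$double.eps), 0)
  clim_grid(sin(slope) * southness, cs, dem$origin)
}

#' Relative elevation (elevation minus focal-mean elevation)
#'
#' Negative values mark depressions prone to cold-air pooling.
#'
#' @param dem a `clim_grid` of elevations.
#' @param radius_m focal window half-width in metres.
#' @return a `clim_grid` (m).
#' @export
relative_elevation <- function(dem, radius_m = 1000) {
  fm <- focal_mean(dem, radius_m)
  clim_grid(dem$values - fm$values, dem$cell_size, dem$origin)
}

#' Generate synthetic monthly climate normals from a DEM
#'
#' @param dem a `clim_grid` of elevations (m).
#' @param params a [climate_gen_params()].
#' @param relelev_radius focal radius (m) for relative elevation.
#' @return a [monthly_normals()] object; deterministic for a fixed
#'   `params$seed`.
#' @export
make_monthly_climate <- function(dem, params, relelev_radius = 1000) {
  v <- dem$values
  nr <- nrow(v); nc <- ncol(v)
  rad <- radiation_index(dem)$values
  rel <- relative_elevation(dem, relelev_radius)$values
  pool <- pmin(rel, 0)
  y_km <- matrix(rep((grid_centres(dem)$y) / 1000, times = nc), nr, nc)
  .with_seed(params$seed, {
    temps <- vector("list", 12L)
    for (m in 1:12) {
      # cold_pool_coeff is a positive magnitude and pool <= 0, so
      # depressions are cooled, most strongly in winter
      tm <- params$sea_level_monthly_T[m] +
        params$lapse_rate * v +
        params$meridional_gradient * y_km +
        params$radiation_coeff * rad +
        params$cold_pool_coeff * pool * .winter_weight[m]
      if (params$noise_sd > 0)
        tm <- tm + matrix(rnorm(nr * nc, sd = params$noise_sd), nr, nc)
      temps[[m]] <- clim_grid(tm, dem$cell_size, dem$origin)
    }
    pr <- params$precip_base + params$orographic_coeff * v
    if (params$precip_noise_sd > 0)
      pr <- pr + matrix(rnorm(nr * nc, sd = params$precip_noise_sd), nr, nc)
    monthly_normals(temps, clim_grid(pr, dem$cell_size, dem$origin))
  })
}

#' Scenario delta-field specification
#'
#' Stand-in for an ensemble-mean climate change signal under one
#' representative concentration pathway: a smooth coarse field with a stated
#' domain-mean warming, a south-north warming gradient, and a small
#' correlated perturbation.
#'
#' @param scenario one of "RCP2.6", "RCP4.5", "RCP8.5".
#' @param mean_warming domain-mean temperature change (deg C); callers
#'   requesting an ensemble must order it RCP2.6 < RCP4.5 < RCP8.5.
#' @param warming_gradient deg C per km of northing.
#' @param precip_change annual precipitation change (mm).
#' @param delta_cell_size cell size of the coarse delta grid (m).
#' @param perturb_sd sd of the smooth perturbation (deg C / mm).
#' @param seed integer RNG seed.
#' @return an object of class `delta_spec`.
#' @export
delta_spec <- function(scenario = c("RCP2.6", "RCP4.5", "RCP8.5"),
                       mean_warming = c("RCP2.6" = 1.5, "RCP4.5" = 2.6,
                                        "RCP8.5" = 4.6)[[scenario[1]]],
                       warming_gradient = 0,
                       precip_change = 40,
                       delta_cell_size = 5000,
                       perturb_sd = 0.05,
                       seed = 1L) {
  scenario <- match.arg(scenario)
  structure(list(scenario = scenario, mean_warming = mean_warming,
                 warming_gradient = warming_gradient,
                 precip_change = precip_change,
                 delta_cell_size = delta_cell_size,
                 perturb_sd = perturb_sd, seed = as.integer(seed)),
            class = "delta_spec")
}

#' Generate coarse scenario delta fields
#'
#' Twelve monthly temperature-delta grids and one annual precipitation-delta
#' grid on a coarse grid fully covering the target geometry.
#'
#' @param spec a [delta_spec()].
#' @param target a `clim_grid` supplying the extent to cover.
#' @return list with `t_deltas` (12 `clim_grid`s) and `p_delta`.
#' @export
make_delta_fields <- function(spec, target) {
  if (spec$delta_cell_size < target$cell_size)
    stop("delta_cell_size must be at least the target cell size")
  cs <- spec$delta_cell_size
  width <- ncol(target$values) * target$cell_size
  height <- nrow(target$values) * target$cell_size
  # one extra coarse cell on each side so fine centres are interior
  nc <- ceiling(width / cs) + 2L
  nr <- ceiling(height / cs) + 2L
  org <- c(target$origin[1] - cs, target$origin[2] + cs)
  ykm <- matrix(rep((org[2] - (seq_len(nr) - 0.5) * cs) / 1000, times = nc),
                nr, nc)
  base <- spec$mean_warming + spec$warming_gradient * (ykm - mean(ykm))
  .with_seed(spec$seed, {
    perturb <- function(sd) {
      if (sd <= 0) return(matrix(0, nr, nc))
      p <- .gauss_smooth(matrix(rnorm(nr * nc), nr, nc), 2)
      p <- p - mean(p)
      if (stats::sd(as.vector(p)) > 0) p <- p * (sd / stats::sd(as.vector(p)))
      p
    }
    t_deltas <- lapply(1:12, function(m)
      clim_grid(base + perturb(spec$perturb_sd), cs, org))
    p_delta <- clim_grid(matrix(spec$precip_change, nr, nc) +
                           perturb(spec$perturb_sd * 20), cs, org)
    list(t_deltas = t_deltas, p_delta = p_delta)
  })
}

#' Generate random non-overlapping reserve polygons
#'
#' Places `n` star-shaped polygons (jittered-radius 14-gons rescaled to an
#' exact target area) with log-uniform areas inside the domain, pairwise
#' disjoint and fully inside the grid extent.
#'
#' @param domain a `clim_grid` giving the extent.
#' @param n number of polygons.
#' @param area_range hectares (min, max); minimum must be >= 2 ha, the
#'   conventional lower size cut for reserve polygons.
#' @param seed integer RNG seed.
#' @param max_tries placement attempts per polygon before giving up.
#' @return an object of class `pa_set`: a list of polygons, each with
#'   `pa_id` and a closed coordinate ring `xy` (metres).
#' @export
make_pa_polygons <- function(domain, n, area_range = c(2, 100), seed = 1L,
                             max_tries = 1000L) {
  stopifnot(n >= 1, area_range[1] >= 2, area_range[2] >= area_range[1])
  xmin <- domain$origin[1]
  xmax <- xmin + ncol(domain$values) * domain$cell_size
  ymax <- domain$origin[2]
  ymin <- ymax - nrow(domain$values) * domain$cell_size
  .with_seed(seed, {
    areas_m2 <- exp(stats::runif(n, log(area_range[1]), log(area_range[2]))) * 1e4
    polys <- vector("list", n)
    centres <- matrix(NA_real_, n, 2)
    radii <- numeric(n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        r0 <- sqrt(areas_m2[i] / pi) * 1.6       # generous bounding radius
        cx <- stats::runif(1, xmin + r0, xmax - r0)
        cy <- stats::runif(1, ymin + r0, ymax - r0)
        nv <- 14L
        ang <- sort(stats::runif(nv, 0, 2 * pi))
        rr <- sqrt(areas_m2[i] / pi) * stats::runif(nv, 0.75, 1.25)
        xy <- cbind(cx + rr * cos(ang), cy + rr * sin(ang))
        a <- .polygon_area(xy)
        xy <- cbind(cx + (xy[, 1] - cx) * sqrt(areas_m2[i] / a),
                    cy + (xy[, 2] - cy) * sqrt(areas_m2[i] / a))
        vr <- max(sqrt((xy[, 1] - cx)^2 + (xy[, 2] - cy)^2))
        # rare pathological rings can outgrow the bounding radius: retry
        if (vr > r0) next
        # disjointness against placed polygons uses true vertex radii
        if (i > 1) {
          dd <- sqrt((centres[seq_len(i - 1), 1] - cx)^2 +
                     (centres[seq_len(i - 1), 2] - cy)^2)
          if (any(dd < radii[seq_len(i - 1)] + vr)) next
        }
        xy <- rbind(xy, xy[1, , drop = FALSE])   # close the ring
        centres[i, ] <- c(cx, cy); radii[i] <- vr
        polys[[i]] <- list(pa_id = i, xy = xy)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place ", n, " non-overlapping polygons (failed at ",
             i, " after ", max_tries, " tries); reduce n or areas")
    }
    structure(polys, class = "pa_set")
  })
}

#' @export
print.pa_set <- function(x, ...) {
  a <- vapply(x, function(p) .polygon_area(p$xy) / 1e4, numeric(1))
  cat(sprintf("<pa_set> %d polygons, areas %.1f-%.1f ha\n",
              length(x), min(a), max(a)))
  invisible(x)
}

# Shoelace area of a (possibly open) coordinate ring, in native units^2.
.polygon_area <- function(xy) {
  n <- nrow(xy)
  if (all(xy[1, ] == xy[n, ])) { xy <- xy[-n, , drop = FALSE]; n <- n - 1L }
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Polygon areas of a `pa_set`
#' @param pas a `pa_set`.
#' @return numeric vector of areas in hectares, named by `pa_id`.
#' @export
pa_areas <- function(pas) {
  stats::setNames(vapply(pas, function(p) .polygon_area(p$xy) / 1e4,
                         numeric(1)),
                  vapply(pas, function(p) as.character(p$pa_id), character(1)))
}

# Even-odd ray-casting point-in-polygon test, vectorised over points.
.points_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  if (all(xy[1, ] == xy[n, ])) { xy <- xy[-n, , drop = FALSE]; n <- n - 1L }
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]; xj <- xy[j, 1]; yj <- xy[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Write / read reserve polygons as CSV with WKT geometry
#'
#' One row per polygon: `pa_id` and a `wkt` column holding a
#' `POLYGON ((x y, ...))` ring, the standard text encoding for vector
#' polygon interchange.
#'
#' @param pas a `pa_set`.
#' @param path CSV file path.
#' @return `path` invisibly (write) or a `pa_set` (read).
#' @export
write_pa_csv <- function(pas, path) {
  wkt <- vapply(pas, function(p) {
    ring <- paste(sprintf("%.6f %.6f", p$xy[, 1], p$xy[, 2]), collapse = ", ")
    sprintf("POLYGON ((%s))", ring)
  }, character(1))
  utils::write.csv(data.frame(pa_id = vapply(pas, `[[`, integer(1), "pa_id"),
                              wkt = wkt),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pa_csv
#' @export
read_pa_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  polys <- lapply(seq_len(nrow(df)), function(i) {
    body <- sub("^POLYGON \\(\\(", "", sub("\\)\\)$", "", df$wkt[i]))
    pts <- do.call(rbind, lapply(strsplit(body, ", ")[[1]], function(s)
      as.numeric(strsplit(s, " ")[[1]])))
    list(pa_id = df$pa_id[i], xy = pts)
  })
  structure(polys, class = "pa_set")
}
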