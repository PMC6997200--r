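#' Gridded raster data model
#'
#' A `clim_grid` is a single-variable raster on a projected, metre-based
#' coordinate system: a numeric matrix of cell values (row 1 = northernmost
#' row), a square cell size in metres, and the projected coordinates of the
#' upper-left corner of the grid. Nodata cells are stored as `NA` and are
#' excluded from every statistic and distance search in the package.
#'
#' The coordinate convention is fixed package-wide: cell-centre registration,
#' 0-based row/column offsets, so cell (row r, col c) (1-based R indices) has
#' centre x = origin_x + (c - 0.5) * cell_size and
#' centre y = origin_y - (r - 0.5) * cell_size.
#'
#' @param values numeric matrix; `NA` marks nodata cells.
#' @param cell_size cell edge length in metres (> 0).
#' @param origin numeric length-2, projected (x, y) of the upper-left corner.
#' @return An object of class `clim_grid`.
#' @examples
#' g <- clim_grid(matrix(1:12, 3, 4), cell_size = 50, origin = c(0, 150))
#' grid_centres(g)$x
#' @export
clim_grid <- function(values, cell_size, origin = c(0, nrow(values) * cell_size)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.numeric(cell_size), length(cell_size) == 1L, cell_size > 0,
            length(origin) == 2L, is.finite(origin[1]), is.finite(origin[2]))
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin)),
            class = "clim_grid")
}

#' @export
print.clim_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<clim_grid> %d x %d cells, cell_size %g m, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2]))
  cat(sprintf("  values: [%g, %g], %d nodata cells\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' @export
dim.clim_grid <- function(x) dim(x$values)

#' Cell-centre coordinates of a grid
#'
#' @param grid a `clim_grid`.
#' @return list with `x` (length ncol) and `y` (length nrow) centre
#'   coordinates in projected metres.
#' @export
grid_centres <- function(grid) {
  v <- grid$values
  list(x = grid$origin[1] + (seq_len(ncol(v)) - 0.5) * grid$cell_size,
       y = grid$origin[2] - (seq_len(nrow(v)) - 0.5) * grid$cell_size)
}

#' Test that two grids share geometry
#' @param a,b `clim_grid` objects.
#' @return logical scalar.
#' @export
same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Read a raster from an ESRI ASCII Grid file
#'
#' Reads the plain-text `.asc` interchange format (ncols/nrows/xllcorner/
#' yllcorner/cellsize/NODATA_value header followed by row-major values,
#' north row first). The cell size must be in projected metres; `.asc`
#' carries no CRS, so a geographic (degree) grid is detected heuristically:
#' a cellsize below 1 combined with corner coordinates inside [-361, 361]
#' is rejected with an explicit error.
#'
#' @param path file path.
#' @return a `clim_grid`; nodata cells are `NA`.
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("cannot read raster file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]+$", tok[1])) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2]); i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid (missing header fields): ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  cs <- hdr$cellsize
  if (cs < 1 && abs(hdr$xllcorner) <= 361 && abs(hdr$yllcorner) <= 361)
    stop("grid appears to be in geographic (degree) coordinates; ",
         "a projected metre-based CRS is required")
  vals <- scan(text = paste(lines[-seq_len(i)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("raster body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  clim_grid(m, cell_size = cs,
            origin = c(hdr$xllcorner, hdr$yllcorner + nr * cs))
}

#' Write a raster to an ESRI ASCII Grid file
#'
#' Inverse of [read_grid()]: the written file round-trips values, nodata
#' mask, cell size and origin exactly (values are printed with 17
#' significant digits).
#'
#' @param grid a `clim_grid`.
#' @param path output file path.
#' @param nodata nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, nodata = -9999) {
  v <- grid$values
  if (any(v == nodata, na.rm = TRUE))
    stop("grid contains the nodata sentinel ", nodata, " as a real value")
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
           sprintf("xllcorner %.10f", grid$origin[1]),
           sprintf("yllcorner %.10f", grid$origin[2] - nr * grid$cell_size),
           sprintf("cellsize %.10f", grid$cell_size),
           sprintf("NODATA_value %g", nodata))
  v[is.na(v)] <- nodata
  body <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Areal-mean aggregation to a coarser resolution
#'
#' Each coarse cell is the mean of the nodata-free fine cells it covers;
#' it is nodata only when all covered fine cells are nodata. Fine grid
#' dimensions need not be multiples of `factor`: partial blocks at the
#' right/bottom edge are averaged over the cells present.
#'
#' @param fine a `clim_grid`.
#' @param factor positive integer aggregation factor (e.g. 20 for
#'   50 m -> 1 km).
#' @return a `clim_grid` with cell_size `factor * fine$cell_size`.
#' @export
aggregate_mean <- function(fine, factor) {
  if (length(factor) != 1L || factor < 1 || factor != round(factor))
    stop("aggregation factor must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(fine)
  v <- fine$values
  nr <- nrow(v); nc <- ncol(v)
  Nr <- ceiling(nr / factor); Nc <- ceiling(nc / factor)
  ri <- (seq_len(nr) - 1L) %/% factor          # coarse row of each fine row
  ci <- (seq_len(nc) - 1L) %/% factor
  grp <- rep(ri, times = nc) + rep(ci, each = nr) * Nr + 1L
  ok <- !is.na(v)
  sums <- rowsum(as.vector(ifelse(ok, v, 0)), grp)
  cnts <- rowsum(as.vector(ok * 1), grp)
  out <- as.vector(sums / cnts)                # NaN where count 0
  out[cnts == 0] <- NA_real_
  clim_grid(matrix(out, Nr, Nc), cell_size = fine$cell_size * factor,
            origin = fine$origin)
}

#' Bilinear resampling onto a target grid geometry
#'
#' Interpolates bilinearly between coarse cell centres at the target cell
#' centres. Outside the outermost coarse centres the interpolation clamps
#' to the nearest valid coordinate (constant extrapolation), so a coarse
#' delta field still covers fine border cells. Nodata coarse cells are
#' excluded by renormalising the bilinear weights over the valid
#' neighbours; the output cell is nodata only when all four neighbours are.
#'
#' @param coarse a `clim_grid`.
#' @param target_cell_size target cell size in metres.
#' @param target_dim integer (nrow, ncol) of the target grid.
#' @param target_origin upper-left (x, y) of the target grid; defaults to
#'   the coarse grid's origin.
#' @return a `clim_grid` with the requested geometry.
#' @export
bilinear_resample <- function(coarse, target_cell_size, target_dim,
                              target_origin = coarse$origin) {
  if (any(target_dim < 1)) stop("empty target geometry")
  v <- coarse$values
  nr <- nrow(v); nc <- ncol(v)
  cc <- grid_centres(coarse)
  tx <- target_origin[1] + (seq_len(target_dim[2]) - 0.5) * target_cell_size
  ty <- target_origin[2] - (seq_len(target_dim[1]) - 0.5) * target_cell_size
  # clamp queries to the span of coarse centres, then locate bracketing cells
  tx <- pmin(pmax(tx, cc$x[1]), cc$x[nc])
  ty <- pmin(pmax(ty, cc$y[nr]), cc$y[1])
  fx <- (tx - cc$x[1]) / coarse$cell_size       # fractional column offset
  fy <- (cc$y[1] - ty) / coarse$cell_size
  c0 <- pmin(pmax(floor(fx), 0), nc - 1L); c1 <- pmin(c0 + 1L, nc - 1L)
  r0 <- pmin(pmax(floor(fy), 0), nr - 1L); r1 <- pmin(r0 + 1L, nr - 1L)
  wx <- fx - c0; wy <- fy - r0
  R0 <- r0 + 1L; R1 <- r1 + 1L; C0 <- c0 + 1L; C1 <- c1 + 1L
  # outer-product weights: rows vary with y, cols with x
  W00 <- outer(1 - wy, 1 - wx); W01 <- outer(1 - wy, wx)
  W10 <- outer(wy, 1 - wx);     W11 <- outer(wy, wx)
  V00 <- v[R0, C0, drop = FALSE]; V01 <- v[R0, C1, drop = FALSE]
  V10 <- v[R1, C0, drop = FALSE]; V11 <- v[R1, C1, drop = FALSE]
  num <- W00 * ifelse(is.na(V00), 0, V00) + W01 * ifelse(is.na(V01), 0, V01) +
         W10 * ifelse(is.na(V10), 0, V10) + W11 * ifelse(is.na(V11), 0, V11)
  den <- W00 * (!is.na(V00)) + W01 * (!is.na(V01)) +
         W10 * (!is.na(V10)) + W11 * (!is.na(V11))
  out <- num / den
  out[den == 0] <- NA_real_
  clim_grid(out, cell_size = target_cell_size, origin = target_origin)
}

#' Focal (moving-window) mean of a grid
#'
#' Box-filter mean over a square window of half-width `radius_m` metres,
#' computed with an integral image; edge windows average over the cells
#' available. Nodata cells are excluded from the window mean.
#'
#' @param grid a `clim_grid`.
#' @param radius_m window half-width in metres.
#' @return a `clim_grid` of local means.
#' @export
focal_mean <- function(grid, radius_m) {
  k <- max(0L, as.integer(round(radius_m / grid$cell_size)))
  v <- grid$values
  ok <- !is.na(v)
  z <- ifelse(ok, v, 0)
  S <- .integral_image(z)
  C <- .integral_image(ok * 1)
  nr <- nrow(v); nc <- ncol(v)
  r1 <- pmax(seq_len(nr) - k, 1L); r2 <- pmin(seq_len(nr) + k, nr)
  c1 <- pmax(seq_len(nc) - k, 1L); c2 <- pmin(seq_len(nc) + k, nc)
  boxsum <- function(M) {
    M[r2 + 1L, c2 + 1L, drop = FALSE] - M[r1, c2 + 1L, drop = FALSE] -
      M[r2 + 1L, c1, drop = FALSE] + M[r1, c1, drop = FALSE]
  }
  out <- boxsum(S) / boxsum(C)
  out[!ok] <- NA_real_
  clim_grid(out, grid$cell_size, grid$origin)
}

.integral_image <- function(m) {
  s <- m
  if (nrow(s) > 1L) s <- apply(s, 2L, cumsum)
  s <- matrix(s, nrow(m), ncol(m))
  if (ncol(s) > 1L) s <- t(apply(s, 1L, cumsum))
  s <- matrix(s, nrow(m), ncol(m))
  rbind(0, cbind(0, s))
}
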