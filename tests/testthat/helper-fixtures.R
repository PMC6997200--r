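# Shared fixtures and independent oracles.

# A small grid with a deterministic value pattern.
toy_grid <- function(nr = 4, nc = 5, cell_size = 50, origin = c(0, nr * cell_size)) {
  clim_grid(matrix(seq_len(nr * nc), nr, nc), cell_size, origin)
}

# Flat-DEM monthly normals with every generator term silenced: all twelve
# months at `temps` (recycled), precipitation constant.
constant_normals <- function(temps, precip = 500, nr = 2, nc = 2,
                             cell_size = 100) {
  temps <- rep(temps, length.out = 12)
  monthly_normals(
    lapply(temps, function(t) clim_grid(matrix(t, nr, nc), cell_size)),
    clim_grid(matrix(precip, nr, nc), cell_size))
}

# Independent brute-force analog-distance oracle: per present cell, the
# all-pairs minimum distance to a future cell of the same class.
brute_force_analog <- function(pl, fl, cell_size) {
  out <- matrix(NA_real_, nrow(pl), ncol(pl))
  for (cl in unique(pl[!is.na(pl)])) {
    src <- which(!is.na(pl) & pl == cl, arr.ind = TRUE)
    tg <- which(!is.na(fl) & fl == cl, arr.ind = TRUE)
    if (nrow(tg) == 0L) { out[src] <- Inf; next }
    d2 <- outer(src[, 1], tg[, 1], "-")^2 + outer(src[, 2], tg[, 2], "-")^2
    out[src] <- sqrt(apply(d2, 1L, min)) * cell_size
  }
  out
}

# Random class-grid pair on a shared geometry, optionally with nodata holes
# and with classes that can be absent from the future surface.
random_class_pair <- function(nr, nc, n_classes = 6, p_na = 0.05,
                              cell_size = 50) {
  rule <- binning_rule("GDD", width = 1)
  mk <- function() {
    m <- matrix(sample(0:(n_classes - 1), nr * nc, replace = TRUE), nr, nc)
    m[stats::runif(nr * nc) < p_na] <- NA
    g <- clim_grid(m + 0.5, cell_size)   # values landing mid-bin
    classify(g, rule)
  }
  list(present = mk(), future = mk())
}
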