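# Thermal-erosion budgeting: cliff-retreat statistics from dated boundary
# polylines, eroded volume from DEM differencing, and the thaw-front
# N-mobilization / N2O emission-factor chain.
#
# Coordinates are planar metric (projected); grids must be co-registered.

#' Read an ESRI ASCII grid
#'
#' Parses the plain-text ESRI ASCII raster format (header lines ncols, nrows,
#' xllcorner/xllcenter, yllcorner/yllcenter, cellsize, optional NODATA_value,
#' followed by rows of elevations from the top of the grid down). NODATA
#' cells are returned as `NA`.
#'
#' @param path File path.
#' @return A list of class `"ascii_grid"`: `data` (matrix, row 1 = northern
#'   row), `cell_size`, `xll`, `yll`, `nodata`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) == 2 && is.na(suppressWarnings(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1
    } else break
  }
  ncols <- hdr$ncols
  nrows <- hdr$nrows
  if (is.null(ncols) || is.null(nrows)) stop("not an ESRI ASCII grid: ", path)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != ncols * nrows) stop("grid body does not match header dims")
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  nodata <- hdr$nodata_value
  if (!is.null(nodata)) m[m == nodata] <- NA
  structure(list(data = m, cell_size = hdr$cellsize,
                 xll = if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter,
                 yll = if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter,
                 nodata = if (is.null(nodata)) -9999 else nodata),
            class = "ascii_grid")
}

#' Write an ESRI ASCII grid
#'
#' @param grid An `"ascii_grid"` list (or a bare matrix, with the remaining
#'   fields given via arguments).
#' @param path Output file path.
#' @param cell_size,xll,yll,nodata Header fields when `grid` is a matrix.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, cell_size = 1, xll = 0, yll = 0,
                             nodata = -9999) {
  if (is.matrix(grid)) {
    grid <- list(data = grid, cell_size = cell_size, xll = xll, yll = yll,
                 nodata = nodata)
  }
  m <- grid$data
  m[is.na(m)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", format(grid$xll, scientific = FALSE)),
    paste("yllcorner", format(grid$yll, scientific = FALSE)),
    paste("cellsize", format(grid$cell_size, scientific = FALSE)),
    paste("NODATA_value", format(grid$nodata, scientific = FALSE))
  ), con)
  writeLines(apply(m, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Eroded volume from DEM differencing
#'
#' Positive-only differencing: sum over valid cells of
#' max(0, old - new) x cell area. A positive difference means subsidence due
#' to thaw and erosion; negative differences (deposition) are excluded.
#'
#' @param dem_old,dem_new Co-registered elevation matrices (m) or
#'   `"ascii_grid"` objects; `NA` = nodata.
#' @param cell_size Cell size, m (taken from the grids when they are
#'   `"ascii_grid"` objects).
#' @param mask Optional logical matrix; only `TRUE` cells contribute.
#' @return Eroded volume, m3.
#' @export
dem_volume <- function(dem_old, dem_new, cell_size = NULL, mask = NULL) {
  if (inherits(dem_old, "ascii_grid")) {
    if (is.null(cell_size)) cell_size <- dem_old$cell_size
    dem_old <- dem_old$data
  }
  if (inherits(dem_new, "ascii_grid")) dem_new <- dem_new$data
  if (is.null(cell_size)) stop("`cell_size` is required with bare matrices")
  if (!all(dim(dem_old) == dim(dem_new))) stop("grids are not co-registered")
  d <- dem_old - dem_new
  valid <- !is.na(d)
  if (!is.null(mask)) valid <- valid & mask
  if (!any(valid)) stop("no valid (non-nodata) cells")
  sum(pmax(d[valid], 0)) * cell_size^2
}

# --- planar polyline geometry -------------------------------------------

# intersection parameters of ray p + t*d with segment a->b; returns t or NA
.ray_segment_t <- function(px, py, dx, dy, ax, ay, bx, by) {
  ex <- bx - ax
  ey <- by - ay
  den <- dx * ey - dy * ex
  if (abs(den) < 1e-12) return(NA_real_)
  s <- (dx * (py - ay) - dy * (px - ax)) / den
  if (s < 0 || s > 1) return(NA_real_)
  ((ax - px) * ey - (ay - py) * ex) / den
}

# all |t| intersection distances of the line through p with direction d
# against a polyline data.frame(x, y); returns smallest |t| or NA
.nearest_intersection <- function(px, py, dx, dy, line) {
  ts <- vapply(seq_len(nrow(line) - 1), function(k) {
    .ray_segment_t(px, py, dx, dy,
                   line$x[k], line$y[k], line$x[k + 1], line$y[k + 1])
  }, numeric(1))
  ts <- ts[!is.na(ts)]
  if (!length(ts)) return(NA_real_)
  ts[which.min(abs(ts))]
}

# stations every `spacing` m along a polyline, with unit normals
.baseline_stations <- function(line, spacing) {
  seg <- cbind(diff(line$x), diff(line$y))
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  total <- cum[length(cum)]
  at <- seq(0, total, by = spacing)
  out <- lapply(at, function(s) {
    k <- max(which(cum <= s + 1e-12))
    if (k >= length(len) + 1) k <- length(len)
    f <- if (len[k] > 0) (s - cum[k]) / len[k] else 0
    tx <- seg[k, 1] / len[k]
    ty <- seg[k, 2] / len[k]
    c(x = line$x[k] + f * seg[k, 1], y = line$y[k] + f * seg[k, 2],
      nx = -ty, ny = tx)
  })
  do.call(rbind, out)
}

#' Cliff-retreat statistics from dated boundary polylines
#'
#' Casts transects perpendicular to a baseline (typically the shoreline) at a
#' fixed spacing, intersects each transect with the dated cliff-boundary
#' polylines, and converts the change in baseline-to-cliff distance into a
#' retreat rate per transect. When a transect crosses a sinuous cliff line
#' several times, the intersection nearest the baseline is used; transects
#' missing an intersection on either date are dropped (and counted).
#'
#' @param baseline Polyline data frame with columns `x`, `y` (m), or an
#'   `"erosion_scene"` object from [sim_dem_pair()] (its shoreline and cliff
#'   boundaries are used and `cliff_lines`/`years` may be omitted).
#' @param cliff_lines Named list of two (or more) polyline data frames; the
#'   first and last are compared.
#' @param years Numeric years matching `cliff_lines` (defaults to their names).
#' @param spacing Transect spacing along the baseline, m.
#' @return A list of class `"retreat_stats"`: `per_transect` data frame
#'   (station coordinates, distances, `rate` m yr-1), `median`, `q25`, `q75`,
#'   `n_transects`, `n_dropped`.
#' @export
transect_retreat <- function(baseline, cliff_lines = NULL, years = NULL,
                             spacing = 50) {
  if (inherits(baseline, "erosion_scene")) {
    scene <- baseline
    baseline <- scene$shoreline
    if (is.null(cliff_lines)) cliff_lines <- scene$cliff_boundaries
    if (is.null(years)) years <- scene$years
  }
  if (spacing <= 0) stop("`spacing` must be positive")
  if (length(cliff_lines) < 2) stop("need at least two dated cliff boundaries")
  if (is.null(years)) years <- as.numeric(names(cliff_lines))
  if (anyNA(years)) stop("`years` could not be derived from cliff line names")
  ord <- order(years)
  early <- cliff_lines[[ord[1]]]
  late <- cliff_lines[[ord[length(ord)]]]
  dy <- years[ord[length(ord)]] - years[ord[1]]
  if (dy <= 0) stop("dated boundaries span zero years")

  st <- .baseline_stations(baseline, spacing)
  d0 <- numeric(nrow(st))
  d1 <- numeric(nrow(st))
  for (i in seq_len(nrow(st))) {
    d0[i] <- abs(.nearest_intersection(st[i, "x"], st[i, "y"],
                                       st[i, "nx"], st[i, "ny"], early))
    d1[i] <- abs(.nearest_intersection(st[i, "x"], st[i, "y"],
                                       st[i, "nx"], st[i, "ny"], late))
  }
  ok <- !is.na(d0) & !is.na(d1)
  if (!any(ok)) stop("no transect intersects both dated boundaries")
  rate <- (d1[ok] - d0[ok]) / dy
  q <- stats::quantile(rate, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(
    per_transect = data.frame(x = st[ok, "x"], y = st[ok, "y"],
                              dist_early = d0[ok], dist_late = d1[ok],
                              rate = rate),
    median = q[2], q25 = q[1], q75 = q[3],
    n_transects = sum(ok), n_dropped = sum(!ok)
  ), class = "retreat_stats")
}

# --- N-mobilization and emission-factor chain ----------------------------

#' Annually eroded volume per unit area
#'
#' Normalises the DEM-difference volume by the epoch length and by the
#' annually eroded footprint (median retreat rate x cliff section length) —
#' the normalisation that makes the volume, retreat and section length
#' mutually consistent in the downstream N budget.
#'
#' @param eroded_volume DEM-difference eroded volume over the epoch, m3.
#' @param epoch_years Years between the two DEMs.
#' @param retreat_rate Median cliff retreat rate, m yr-1.
#' @param section_length Length of the studied cliff section, m.
#' @return m3 of thawed material per m2 of annually eroded footprint per year.
#' @examples
#' annual_volume_per_area(223502, 7, 3.7, 1700)  # ~5.08
#' @export
annual_volume_per_area <- function(eroded_volume, epoch_years, retreat_rate,
                                   section_length) {
  if (any(c(epoch_years, retreat_rate, section_length) <= 0)) {
    stop("epoch, retreat rate and section length must be positive")
  }
  if (eroded_volume < 0) stop("`eroded_volume` must be non-negative")
  (eroded_volume / epoch_years) / (retreat_rate * section_length)
}

#' Thaw-front nitrogen mobilization budget
#'
#' Converts the annually eroded volume per unit area into N release at the
#' thaw front: the ice fraction is removed to get sediment volume, bulk
#' density gives sediment dry mass, and the total-N and mineral-N contents of
#' freshly thawed material give total and mineral N release.
#'
#' @param annual_volume_per_area m3 m-2 yr-1, from [annual_volume_per_area()].
#' @param ice_fraction Volumetric ground-ice content, fraction (default 0.82,
#'   typical of ice-rich Yedoma).
#' @param bulk_density Sediment dry bulk density, kg m-3 (default 1220).
#' @param total_n_frac Total N mass fraction of dry sediment (default 0.0016,
#'   i.e. 0.16 %).
#' @param mineral_n_content Mineral (NH4+) N content, mg N per kg DW
#'   (default 35.3).
#' @return A list of class `"n_budget"`: `sediment_volume` (m3 m-2 yr-1),
#'   `sediment_mass` (kg m-2 yr-1), `total_n_release` (kg N m-2 yr-1),
#'   `mineral_n_release` (g N m-2 yr-1), plus the inputs.
#' @export
n_mobilization <- function(annual_volume_per_area, ice_fraction = 0.82,
                           bulk_density = 1220, total_n_frac = 0.0016,
                           mineral_n_content = 35.3) {
  if (ice_fraction < 0 || ice_fraction >= 1) stop("need 0 <= ice_fraction < 1")
  if (annual_volume_per_area < 0) stop("volume per area must be non-negative")
  sediment_volume <- annual_volume_per_area * (1 - ice_fraction)
  sediment_mass <- sediment_volume * bulk_density        # kg m-2 yr-1
  structure(list(
    annual_volume_per_area = annual_volume_per_area,
    ice_fraction = ice_fraction, bulk_density = bulk_density,
    total_n_frac = total_n_frac, mineral_n_content = mineral_n_content,
    sediment_volume = sediment_volume, sediment_mass = sediment_mass,
    total_n_release = sediment_mass * total_n_frac,      # kg N m-2 yr-1
    mineral_n_release = sediment_mass * mineral_n_content / 1000  # g N m-2 yr-1
  ), class = "n_budget")
}

#' Seasonal N2O loss and emission factor
#'
#' Scales the median daily N2O flux of the high-emitting surfaces to a
#' snow-free season, and expresses the seasonal loss as a percentage of the
#' mineral N liberated annually at the thaw front (the emission factor),
#' compared against the IPCC emission factor for N inputs to managed mineral
#' soils (1 %).
#'
#' @param daily_flux_median Median N2O flux, ug N m-2 d-1.
#' @param season_days Snow-free season length, days (default 100).
#' @param mineral_n_release Mineral N release, g N m-2 yr-1 (e.g. from
#'   [n_mobilization()]).
#' @param ipcc_ef IPCC reference emission factor, % (default 1).
#' @return A list of class `"emission_budget"`: `seasonal_loss` (mg N m-2
#'   yr-1), `emission_factor` (%), `fold_below_ipcc`, plus the inputs.
#' @examples
#' b <- n_mobilization(annual_volume_per_area(223502, 7, 3.7, 1700))
#' emission_budget(548, 100, b$mineral_n_release)
#' @export
emission_budget <- function(daily_flux_median, season_days = 100,
                            mineral_n_release, ipcc_ef = 1) {
  if (season_days <= 0) stop("`season_days` must be positive")
  if (mineral_n_release <= 0) stop("`mineral_n_release` must be positive")
  seasonal_loss <- daily_flux_median * season_days / 1000   # ug -> mg
  emission_factor <- seasonal_loss / (mineral_n_release * 1000) * 100
  structure(list(
    daily_flux_median = daily_flux_median, season_days = season_days,
    mineral_n_release = mineral_n_release, ipcc_ef = ipcc_ef,
    seasonal_loss = seasonal_loss, emission_factor = emission_factor,
    fold_below_ipcc = if (emission_factor > 0) ipcc_ef / emission_factor
                      else NA_real_
  ), class = "emission_budget")
}

#' @export
print.emission_budget <- function(x, ...) {
  cat(sprintf(
    "seasonal N2O-N loss: %.1f mg N m-2 yr-1\nemission factor: %.3f %% of mineral N released\n%.1f-fold below the IPCC %g %% factor\n",
    x$seasonal_loss, x$emission_factor, x$fold_below_ipcc, x$ipcc_ef))
  invisible(x)
}
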