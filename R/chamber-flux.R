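# Static-chamber flux computation and quality control.
#
# A closed chamber of height h (= volume/area) accumulates gas; the areal flux
# follows from the OLS slope of the headspace mixing ratio vs. time via the
# ideal gas law. Sign convention: positive = emission, negative = uptake.

.R_GAS <- 8.314                                  # J mol-1 K-1
.MASS_PER_MOL <- c(N2O = 28.0134, CH4 = 12.011, CO2 = 12.011)  # g of N or C per mol gas
.MASS_SCALE <- c(N2O = 1e6, CH4 = 1e3, CO2 = 1e3)  # g -> ug (N2O) or mg (CH4/CO2)
.FLUX_UNITS <- c(N2O = "ug N m-2 d-1", CH4 = "mg C m-2 d-1", CO2 = "mg C m-2 d-1")

#' Chamber headspace time series
#'
#' Bundle one enclosure's headspace mixing-ratio series with the chamber
#' geometry and ambient conditions needed to convert a concentration slope
#' into an areal flux.
#'
#' @param times Sampling times, minutes since chamber closure; strictly
#'   increasing, at least 3 samples.
#' @param conc Mixing ratios at `times`, ppm (N2O, CH4) or umol mol-1 (CO2).
#' @param analyte One of `"N2O"`, `"CH4"`, `"CO2"`.
#' @param chamber_height Effective chamber height (volume/area), m.
#' @param air_temp Air temperature inside the chamber, K.
#' @param pressure Air pressure, Pa.
#' @param standard_sd Analytical standard deviation of standard-gas mixtures
#'   in the relevant concentration range, ppm; used by the RMSE quality rule.
#' @return An object of class `"chamber_series"`.
#' @seealso [compute_flux()], [sim_chamber_series()]
#' @export
chamber_series <- function(times, conc, analyte = c("N2O", "CH4", "CO2"),
                           chamber_height, air_temp, pressure = 101325,
                           standard_sd = 0) {
  analyte <- match.arg(analyte)
  if (length(times) != length(conc)) {
    stop("`times` and `conc` must have the same length")
  }
  if (length(times) < 3) stop("a chamber series needs at least 3 samples")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (!is.finite(chamber_height) || chamber_height <= 0) {
    stop("`chamber_height` must be positive")
  }
  if (!is.finite(air_temp) || air_temp <= 0) stop("`air_temp` must be positive (K)")
  if (standard_sd < 0) stop("`standard_sd` must be non-negative")
  structure(
    list(times = as.numeric(times), conc = as.numeric(conc), analyte = analyte,
         chamber_height = chamber_height, air_temp = air_temp,
         pressure = pressure, standard_sd = standard_sd),
    class = "chamber_series"
  )
}

# flux per unit concentration slope (1 ppm min-1), in the analyte's flux units
.flux_per_slope <- function(analyte, chamber_height, air_temp, pressure) {
  1e-6 * pressure / (.R_GAS * air_temp) * chamber_height *
    .MASS_PER_MOL[[analyte]] * .MASS_SCALE[[analyte]] * 1440
}

#' Compute an areal gas flux from a chamber series
#'
#' Fits an ordinary least-squares line through all samples of the series and
#' converts the slope (ppm min-1) into an areal mass flux using the ideal gas
#' law: flux = slope x chamber_height x P/(R T) x M x unit factors, with
#' M = 28.0134 g N per mol N2O or 12.011 g C per mol CH4/CO2. Quality control
#' follows the RMSE rule: a series is rejected when the regression RMSE (ppm)
#' exceeds three times the analytical standard deviation of standard gas
#' mixtures in the same range.
#'
#' @param series A [chamber_series()] object.
#' @return A list of class `"flux_result"` with elements `slope` (ppm min-1),
#'   `intercept` (ppm), `flux` (ug N m-2 d-1 for N2O; mg C m-2 d-1 for
#'   CH4/CO2), `flux_units`, `r2`, `rmse` (ppm) and `qc_pass`. `r2` is `NA`
#'   for a perfectly constant series.
#' @examples
#' s <- chamber_series(times = c(0, 12.5, 25, 37.5, 50),
#'                     conc = 0.33 + 0.001 * c(0, 12.5, 25, 37.5, 50),
#'                     analyte = "N2O", chamber_height = 0.15,
#'                     air_temp = 278, pressure = 101325)
#' compute_flux(s)$flux  # 265.3 ug N m-2 d-1
#' @export
compute_flux <- function(series) {
  stopifnot(inherits(series, "chamber_series"))
  t <- series$times
  y <- series$conc
  tm <- mean(t)
  ym <- mean(y)
  sxx <- sum((t - tm)^2)
  if (sxx == 0) stop("zero time span")
  slope <- sum((t - tm) * (y - ym)) / sxx
  intercept <- ym - slope * tm
  resid <- y - (intercept + slope * t)
  rmse <- sqrt(mean(resid^2))
  syy <- sum((y - ym)^2)
  r2 <- if (syy > 0) 1 - sum(resid^2) / syy else NA_real_
  flux <- slope * .flux_per_slope(series$analyte, series$chamber_height,
                                  series$air_temp, series$pressure)
  structure(
    list(slope = slope, intercept = intercept, flux = flux,
         flux_units = unname(.FLUX_UNITS[[series$analyte]]),
         r2 = r2, rmse = rmse,
         qc_pass = quality_flag(rmse, series$standard_sd)),
    class = "flux_result"
  )
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf("flux: %.4g %s (slope %.4g ppm/min, r2 %s, RMSE %.4g ppm, QC %s)\n",
              x$flux, x$flux_units, x$slope,
              ifelse(is.na(x$r2), "NA", sprintf("%.4f", x$r2)),
              x$rmse, ifelse(x$qc_pass, "pass", "REJECT")))
  invisible(x)
}

#' RMSE-based chamber quality rule
#'
#' A flux measurement is rejected when the regression RMSE exceeds three times
#' the analytical standard deviation of the standard gas mixtures
#' (rejection strictly at RMSE > 3 x SD; a tie is accepted).
#'
#' @param rmse Regression root-mean-square error, ppm.
#' @param standard_sd Analytical SD of standards in the relevant range, ppm.
#' @return `TRUE` (accept) or `FALSE` (reject).
#' @export
quality_flag <- function(rmse, standard_sd) {
  if (any(rmse < 0) || any(standard_sd < 0)) stop("inputs must be non-negative")
  !(rmse > 3 * standard_sd)
}

#' Diffusive N2O flux from a soil pore-gas profile
#'
#' Fick's-first-law estimate of the surface flux sustained by an elevated N2O
#' concentration at depth: F = Ds (C_pore - C_surface) / depth, with the
#' effective diffusivity from the Millington-Quirk tortuosity model
#' Ds = D0 theta_a^(10/3) / phi^2 and D0 = 1.43e-5 m2 s-1 for N2O in air at
#' 293 K, scaled by (T/293)^1.75. Concentrations are converted from ppm to
#' mol m-3 via the ideal gas law and the result to mass-of-N units.
#'
#' @param pore_ppm N2O mixing ratio in the soil pore gas at `depth`, ppm.
#' @param surface_ppm N2O mixing ratio at the soil surface, ppm (atmospheric
#'   baseline 0.33 ppm by default).
#' @param depth Depth of the pore-gas sample, m.
#' @param air_filled_porosity Air-filled porosity theta_a, fraction.
#' @param total_porosity Total porosity phi, fraction.
#' @param temp Soil temperature, K.
#' @param pressure Air pressure, Pa.
#' @param d0 Free-air diffusivity of N2O at `d0_temp`, m2 s-1.
#' @param d0_temp Reference temperature for `d0`, K.
#' @return Flux in ug N m-2 d-1 (positive = emission).
#' @export
pore_gradient_flux <- function(pore_ppm, surface_ppm = 0.33, depth,
                               air_filled_porosity, total_porosity,
                               temp, pressure = 101325,
                               d0 = 1.43e-5, d0_temp = 293) {
  if (depth <= 0) stop("`depth` must be positive")
  if (air_filled_porosity < 0 || total_porosity <= 0 ||
      air_filled_porosity > total_porosity || total_porosity > 1) {
    stop("need 0 <= air_filled_porosity <= total_porosity <= 1")
  }
  if (air_filled_porosity == 0 && pore_ppm != surface_ppm) {
    stop("air-filled porosity 0 with a nonzero gradient")
  }
  ds <- d0 * (temp / d0_temp)^1.75 * air_filled_porosity^(10 / 3) /
    total_porosity^2                                   # m2 s-1
  dconc <- (pore_ppm - surface_ppm) * 1e-6 * pressure / (.R_GAS * temp)  # mol m-3
  ds * dconc / depth * .MASS_PER_MOL[["N2O"]] * 1e6 * 86400
}

#' Per-enclosure fluxes from a long-format chamber table
#'
#' Applies [compute_flux()] to each enclosure of a long table in the standard
#' chamber CSV layout (one row per gas sample).
#'
#' @param df A data frame with columns `plot_id`, `time_min`, `conc_ppm`,
#'   `height_m`, `temp_C`, and optionally `analyte` (default `"N2O"`),
#'   `pressure_Pa` (default 101325), `standard_sd_ppm` (default 0) and
#'   `surface_class` (carried through).
#' @return A data frame with one row per enclosure: the identifiers plus
#'   `slope`, `flux`, `flux_units`, `r2`, `rmse`, `qc_pass`.
#' @export
compute_flux_table <- function(df) {
  need <- c("plot_id", "time_min", "conc_ppm", "height_m", "temp_C")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (is.null(df$analyte)) df$analyte <- "N2O"
  if (is.null(df$pressure_Pa)) df$pressure_Pa <- 101325
  if (is.null(df$standard_sd_ppm)) df$standard_sd_ppm <- 0
  key <- interaction(df$plot_id, df$analyte, drop = TRUE)
  out <- lapply(split(df, key), function(g) {
    g <- g[order(g$time_min), ]
    s <- chamber_series(g$time_min, g$conc_ppm, analyte = g$analyte[1],
                        chamber_height = g$height_m[1],
                        air_temp = g$temp_C[1] + 273.15,
                        pressure = g$pressure_Pa[1],
                        standard_sd = g$standard_sd_ppm[1])
    r <- compute_flux(s)
    data.frame(plot_id = g$plot_id[1], analyte = g$analyte[1],
               surface_class = if (!is.null(g$surface_class)) g$surface_class[1] else NA,
               slope = r$slope, flux = r$flux, flux_units = r$flux_units,
               r2 = r$r2, rmse = r$rmse, qc_pass = r$qc_pass)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
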