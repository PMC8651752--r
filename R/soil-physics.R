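# Soil physical and chemical derivations used throughout the pipeline.

#' Water-filled pore space
#'
#' WFPS = volumetric water content / total porosity, with porosity
#' phi = 1 - bulk_density/particle_density. Values above 1 (possible with
#' field VWC error) are reported as-is with a warning rather than clipped.
#'
#' @param vwc Volumetric water content, fraction.
#' @param bulk_density Dry bulk density, g cm-3.
#' @param particle_density Particle density, g cm-3; 2.65 is the usual
#'   mineral-soil default when unmeasured.
#' @return WFPS as a fraction (vectorised).
#' @examples
#' wfps(0.27, 1.22, 2.65)  # 0.5004
#' @export
wfps <- function(vwc, bulk_density, particle_density = 2.65) {
  if (any(vwc < 0)) stop("`vwc` must be non-negative")
  phi <- 1 - bulk_density / particle_density
  if (any(phi <= 0)) stop("porosity <= 0: bulk density must be below particle density")
  out <- vwc / phi
  if (any(out > 1)) {
    warning("WFPS > 1 for ", sum(out > 1),
            " sample(s); reported unclipped (check field VWC)")
  }
  out
}

#' Extract concentration to a dry-weight soil basis
#'
#' Converts a salt-extract mineral-N concentration to mg N per kg of dry soil:
#' dry mass = fresh mass / (1 + gravimetric water), result =
#' concentration x extract volume / dry mass.
#'
#' @param extract_conc Concentration in the extract, mg N L-1.
#' @param extract_volume Extractant volume, L.
#' @param soil_fresh_mass Fresh soil mass extracted, g.
#' @param gravimetric_water Gravimetric water content, g water per g dry soil.
#' @return mg N per kg dry weight (vectorised).
#' @examples
#' extract_to_dw(1, 0.03, 10, 0.25)  # 3.75 mg N kg-1 DW
#' @export
extract_to_dw <- function(extract_conc, extract_volume, soil_fresh_mass,
                          gravimetric_water) {
  if (any(soil_fresh_mass <= 0)) stop("`soil_fresh_mass` must be positive")
  if (any(gravimetric_water < 0)) stop("`gravimetric_water` must be non-negative")
  dry_g <- soil_fresh_mass / (1 + gravimetric_water)
  extract_conc * extract_volume / (dry_g / 1000)
}

#' Soil C/N mass ratio
#'
#' @param total_c Total carbon, % of dry weight.
#' @param total_n Total nitrogen, % of dry weight.
#' @return Dimensionless mass ratio (vectorised).
#' @examples
#' cn_ratio(1.6, 0.16)  # 10
#' @export
cn_ratio <- function(total_c, total_n) {
  if (any(total_n <= 0)) stop("`total_n` must be positive")
  total_c / total_n
}

#' Append derived soil columns to a soil-property table
#'
#' Adds `wfps`, `nh4_dw`, `no3_dw` (mg N kg-1 DW) and `cn` columns computed
#' from the standard soil CSV columns.
#'
#' @param df Data frame with columns `vwc`, `bulk_density`,
#'   `particle_density` (optional; 2.65 default), `extract_nh4`,
#'   `extract_no3` (mg N L-1), `extract_volume` (L), `soil_fresh_mass` (g),
#'   `gravimetric_water`, `total_c`, `total_n`.
#' @return The input with the derived columns appended.
#' @export
derive_soil_table <- function(df) {
  pd <- if (is.null(df$particle_density)) 2.65 else df$particle_density
  df$wfps <- wfps(df$vwc, df$bulk_density, pd)
  df$nh4_dw <- extract_to_dw(df$extract_nh4, df$extract_volume,
                             df$soil_fresh_mass, df$gravimetric_water)
  df$no3_dw <- extract_to_dw(df$extract_no3, df$extract_volume,
                             df$soil_fresh_mass, df$gravimetric_water)
  df$cn <- cn_ratio(df$total_c, df$total_n)
  df
}
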