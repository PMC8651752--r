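# Synthetic-data generators emulating the statistical structure of each
# field and laboratory measurement: linear chamber accumulation with
# analytical (GC) noise, pool-dilution dynamics under constant gross rates,
# incubation curves with a production-then-consumption phase, DEM pairs with
# a known eroded volume, multinomial gene-count profiles, and per-surface
# soil/flux tables drawn from the printed ranges.
#
# Every generator inverts exactly the arithmetic its analysis counterpart
# applies, so zero-noise output round-trips to the generating parameters.

#' Simulate a chamber headspace series
#'
#' Generates mixing ratios ambient + slope * t where the slope is the exact
#' inversion of the flux unit conversion used by [compute_flux()], plus
#' i.i.d. Gaussian noise on the mixing ratios (modelling GC analytical
#' error, not slope error).
#'
#' @param true_flux Generating flux; ug N m-2 d-1 for N2O, mg C m-2 d-1 for
#'   CH4/CO2.
#' @param chamber_height Chamber height, m.
#' @param air_temp Air temperature, K.
#' @param pressure Pressure, Pa.
#' @param times Sampling times, minutes (default 5 samples over a 50-minute
#'   enclosure: 0, 12.5, 25, 37.5, 50).
#' @param noise_sd Gaussian noise SD on mixing ratios, ppm.
#' @param seed Optional RNG seed for reproducibility.
#' @param ambient Ambient mixing ratio at closure, ppm (atmospheric N2O
#'   baseline 0.33).
#' @param analyte `"N2O"`, `"CH4"` or `"CO2"`.
#' @param standard_sd Analytical SD recorded on the series for QC
#'   (defaults to `noise_sd`).
#' @return A [chamber_series()] object.
#' @export
sim_chamber_series <- function(true_flux, chamber_height, air_temp,
                               pressure = 101325,
                               times = c(0, 12.5, 25, 37.5, 50),
                               noise_sd = 0, seed = NULL, ambient = 0.33,
                               analyte = c("N2O", "CH4", "CO2"),
                               standard_sd = noise_sd) {
  analyte <- match.arg(analyte)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (!is.null(seed)) set.seed(seed)
  slope <- true_flux / .flux_per_slope(analyte, chamber_height, air_temp,
                                       pressure)
  conc <- ambient + slope * times
  if (noise_sd > 0) conc <- conc + stats::rnorm(length(times), 0, noise_sd)
  chamber_series(times, conc, analyte = analyte,
                 chamber_height = chamber_height, air_temp = air_temp,
                 pressure = pressure, standard_sd = standard_sd)
}

#' Simulate a two-point pool-dilution observation
#'
#' Exact solution of the constant-rate pool-dilution model
#' dM/dt = p - c, dH/dt = -c H / M (H = 15N excess mass, APE = H/M):
#' M(t) = M0 + (p - c) t and APE(t) = APE0 (M0/M(t))^(p/(p-c)) for p != c,
#' APE(t) = APE0 exp(-p t / M0) for p = c.
#'
#' @param gross_production Gross production p, mg N kg-1 DW d-1.
#' @param gross_consumption Gross consumption c, mg N kg-1 DW d-1.
#' @param M0 Initial labeled pool, mg N kg-1 DW.
#' @param APE0 Initial atom-% excess.
#' @param dt Interval between the two extractions, days (default 20 h, the
#'   4 h -> 24 h window).
#' @param target_pool `"NH4"` or `"NO3"`.
#' @return A [pool_dilution_pair()] with `t0 = 0`, `t1 = dt`.
#' @examples
#' sim_pool_dilution(2, 1, M0 = 5, APE0 = 8, dt = 1)  # Mt 6, APEt 5.556
#' @export
sim_pool_dilution <- function(gross_production, gross_consumption, M0, APE0,
                              dt = 20 / 24, target_pool = "NH4") {
  p <- gross_production
  cc <- gross_consumption
  if (p < 0 || cc < 0) stop("rates must be non-negative")
  if (M0 <= 0) stop("`M0` must be positive")
  if (APE0 <= 0) stop("`APE0` must be positive")
  Mt <- M0 + (p - cc) * dt
  if (Mt <= 0) stop("parameters drive the pool non-positive within `dt`")
  APEt <- if (abs(p - cc) < 1e-12) {
    APE0 * exp(-p * dt / M0)
  } else {
    APE0 * (M0 / Mt)^(p / (p - cc))
  }
  pool_dilution_pair(M0 = M0, Mt = Mt, APE0 = APE0, APEt = APEt,
                     t0 = 0, t1 = dt, target_pool = target_pool)
}

#' Simulate a flask incubation series
#'
#' Cumulative headspace N2O rises linearly at `production_rate` until
#' `consumption_onset`, then declines (net N2O reduction to N2; the plain
#' anoxic behaviour) or plateaus (steady state; the acetylene behaviour).
#'
#' @param production_rate ug N kg-1 DW d-1.
#' @param consumption_onset Onset of net consumption/steady state, days, or
#'   `NULL` for uninterrupted linear production (oxic behaviour).
#' @param times Sampling days (default 0, 1, 2, 3, 6).
#' @param soil_dw Dry soil mass, kg.
#' @param noise_sd Gaussian noise SD on amounts, ug N.
#' @param seed Optional RNG seed.
#' @param after_onset `"decline"` or `"plateau"`.
#' @param decline_frac Post-onset decline rate as a fraction of
#'   `production_rate` (default 0.5); amounts are floored at 0.
#' @param treatment Treatment label; inferred from the shape when missing.
#' @return An [incubation_series()] object.
#' @export
sim_incubation_series <- function(production_rate, consumption_onset = NULL,
                                  times = c(0, 1, 2, 3, 6), soil_dw,
                                  noise_sd = 0, seed = NULL,
                                  after_onset = c("decline", "plateau"),
                                  decline_frac = 0.5, treatment = NULL) {
  after_onset <- match.arg(after_onset)
  if (soil_dw <= 0) stop("`soil_dw` must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(treatment)) {
    treatment <- if (is.null(consumption_onset)) "oxic"
                 else if (after_onset == "decline") "anoxic" else "anoxic_c2h2"
  }
  amt <- if (is.null(consumption_onset)) {
    production_rate * soil_dw * times
  } else {
    peak <- production_rate * soil_dw * consumption_onset
    ifelse(times <= consumption_onset,
           production_rate * soil_dw * times,
           if (after_onset == "plateau") peak else
             pmax(0, peak - decline_frac * production_rate * soil_dw *
                    (times - consumption_onset)))
  }
  if (noise_sd > 0) amt <- amt + stats::rnorm(length(times), 0, noise_sd)
  incubation_series(times, amt, soil_dw = soil_dw, treatment = treatment)
}

#' Simulate a DEM pair with a known eroded volume
#'
#' Builds a plateau-cliff-shore scene: elevation 0 on the shore side and
#' `cliff_height` on the plateau, with the cliff foot placed on a cell edge.
#' The second DEM moves the cliff foot inland by `retreat`, so the true
#' eroded volume is retreat x cliff length x cliff height. Dated cliff
#' boundary polylines and a shoreline baseline are included for
#' [transect_retreat()].
#'
#' @param nx,ny Grid cell counts (x = across the cliff, y = along it).
#' @param cell_size Cell size, m.
#' @param cliff_height Cliff height, m.
#' @param retreat Inland cliff-foot displacement between the two dates, m.
#' @param seed Optional RNG seed (used when `noise_sd > 0`).
#' @param epoch_years Years between the two DEMs.
#' @param noise_sd Gaussian elevation noise, m (default 0).
#' @param foot_frac Initial cliff-foot position as a fraction of the x
#'   extent (snapped to a cell edge).
#' @return A list of class `"erosion_scene"`: `dem_old`, `dem_new`
#'   (matrices, row 1 = northern row), `cell_size`, `shoreline`,
#'   `cliff_boundaries` (named list of polylines by year), `years`,
#'   `epoch_years`, `section_length`, `cliff_height`, `retreat`,
#'   `true_volume`.
#' @export
sim_dem_pair <- function(nx, ny, cell_size = 1, cliff_height, retreat,
                         seed = NULL, epoch_years = 1, noise_sd = 0,
                         foot_frac = 0.4) {
  if (cliff_height <= 0) stop("`cliff_height` must be positive")
  if (retreat < 0) stop("`retreat` must be non-negative")
  extent_x <- nx * cell_size
  foot_old <- floor(foot_frac * nx) * cell_size
  if (foot_old + retreat >= extent_x) stop("`retreat` exceeds the domain extent")
  if (!is.null(seed)) set.seed(seed)
  xc <- (seq_len(nx) - 0.5) * cell_size       # cell-centre x
  profile <- function(foot) ifelse(xc < foot, 0, cliff_height)
  dem_old <- matrix(rep(profile(foot_old), each = ny), nrow = ny)
  dem_new <- matrix(rep(profile(foot_old + retreat), each = ny), nrow = ny)
  if (noise_sd > 0) {
    dem_old <- dem_old + matrix(stats::rnorm(nx * ny, 0, noise_sd), ny)
    dem_new <- dem_new + matrix(stats::rnorm(nx * ny, 0, noise_sd), ny)
  }
  section_length <- ny * cell_size
  vline <- function(x) data.frame(x = c(x, x), y = c(0, section_length))
  years <- c(0, epoch_years)
  structure(list(
    dem_old = dem_old, dem_new = dem_new, cell_size = cell_size,
    shoreline = vline(cell_size),
    cliff_boundaries = stats::setNames(
      list(vline(foot_old), vline(foot_old + retreat)), as.character(years)),
    years = years, epoch_years = epoch_years,
    section_length = section_length, cliff_height = cliff_height,
    retreat = retreat,
    true_volume = retreat * section_length * cliff_height
  ), class = "erosion_scene")
}

#' Simulate a functional gene count table
#'
#' Multinomial draw of `total_reads` captured sequences per sample over the
#' profiled gene families, with the unprofiled remainder assigned to
#' `other`. Expected relative abundances equal the profile.
#'
#' @param profile Named numeric vector of relative abundances, %, summing to
#'   at most 100.
#' @param total_reads Captured functional-gene sequences per sample.
#' @param seed Optional RNG seed.
#' @param n Number of replicate samples (rows).
#' @return Data frame of counts, one row per sample, columns = profiled
#'   families plus `other`.
#' @export
sim_gene_counts <- function(profile, total_reads, seed = NULL, n = 1) {
  if (any(profile < 0)) stop("profile percentages must be non-negative")
  if (sum(profile) > 100 + 1e-9) stop("profile percentages must sum to <= 100")
  if (is.null(names(profile))) stop("`profile` must be a named vector")
  if (!is.null(seed)) set.seed(seed)
  prob <- c(profile, other = 100 - sum(profile)) / 100
  counts <- t(stats::rmultinom(n, size = total_reads, prob = prob))
  out <- as.data.frame(counts)
  names(out) <- names(prob)
  rownames(out) <- NULL
  out
}

#' Built-in per-surface gene-abundance profiles
#'
#' Relative-abundance profiles (%) along the thaw/revegetation gradient for
#' the gene families driving N2O production potential: amoA rising from
#' 0.6 % in freshly thawed Yedoma to 2.5-3.5 % in revegetated surfaces, nir
#' (nirK + nirS) doubling from 15 % to 29 % in grass-revegetated Yedoma with
#' a halved nosZ share, and nrfA rising from 0.4 % to 3.2 %. Values not
#' reported for a surface (and the 50/50 nirK/nirS split) are field-realistic
#' assumptions, marked in the `assumed_fields` column.
#'
#' @return Data frame with `surface_class`, `amoA`, `nirK`, `nirS`, `nosZ`,
#'   `nrfA` (%), `assumed_fields`.
#' @export
default_gene_profiles <- function() {
  data.frame(
    surface_class = c("vegetated_holocene", "bare_fresh_yedoma",
                      "bare_earlier_yedoma", "yedoma_moss", "yedoma_grass"),
    amoA = c(0.4, 0.6, 1.5, 2.5, 3.5),
    nirK = c(5, 7.5, 9, 11, 14.5),
    nirS = c(5, 7.5, 9, 11, 14.5),
    nosZ = c(16, 14, 12, 10, 7),
    nrfA = c(0.4, 1.7, 1.8, 2.0, 3.2),
    assumed_fields = c("amoA;nirK;nirS;nosZ", "nosZ", "amoA;nirK;nirS;nosZ",
                       "nirK;nirS;nosZ", "nirK;nirS (50/50 split)")
  )
}

#' Surface-type profiles for the synthetic soil/flux tables
#'
#' Reads the packaged per-surface profile table (WFPS, mineral N and N2O
#' flux ranges, C/N ratio). Fields printed in the source observations are
#' used verbatim; the rest are field-realistic assumptions listed in the
#' `assumed_fields` column.
#'
#' @return Data frame, one row per surface class.
#' @export
surface_profiles <- function() {
  path <- system.file("extdata", "surface_profiles.csv",
                      package = "yedomaflux", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# one median-anchored draw: half the mass below the median, half above;
# log-uniform halves when the bounds are positive, linear halves otherwise
.median_anchored_draw <- function(n, lo, med, hi) {
  stopifnot(lo <= med, med <= hi)
  if (lo == hi) return(rep(lo, n))
  side_hi <- stats::runif(n) >= 0.5
  u <- stats::runif(n)
  draw_between <- function(a, b, u) {
    if (a == b) return(rep(a, length(u)))
    if (a > 0) exp(log(a) + u * (log(b) - log(a))) else a + u * (b - a)
  }
  ifelse(side_hi, draw_between(med, hi, u), draw_between(lo, med, u))
}

#' Simulate a per-surface soil property and flux table
#'
#' Draws `n` plot rows for one surface class: WFPS and mineral N uniformly
#' within the profile's ranges, and the N2O flux from a median-anchored
#' distribution (half the probability mass below the profile median, half
#' above, log-uniform within each positive half) so the generating median
#' equals the profile's `flux_median`.
#'
#' @param profile A single row of [surface_profiles()] or a surface-class
#'   name found there.
#' @param n Number of plots (replicates).
#' @param seed Optional RNG seed.
#' @return Data frame with `surface_class`, `wfps`, `no3_dw`, `nh4_dw`
#'   (mg N kg-1 DW), `cn`, `flux` (ug N m-2 d-1).
#' @export
sim_surface_table <- function(profile, n = 5, seed = NULL) {
  if (is.character(profile)) {
    tab <- surface_profiles()
    profile <- tab[tab$surface_class == profile, ]
    if (nrow(profile) != 1) stop("unknown surface class")
  }
  if (n < 1) stop("`n` must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    surface_class = profile$surface_class,
    wfps = stats::runif(n, profile$wfps_lo, profile$wfps_hi),
    no3_dw = stats::runif(n, profile$no3_lo, profile$no3_hi),
    nh4_dw = stats::runif(n, profile$nh4_lo, profile$nh4_hi),
    cn = profile$cn_ratio,
    flux = .median_anchored_draw(n, profile$flux_lo, profile$flux_median,
                                 profile$flux_hi)
  )
}
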