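#' Configure a synthetic trawl-survey scenario
#'
#' Builds the configuration object driving the synthetic survey generator.
#' The generator emulates a multi-decadal bottom-trawl monitoring programme
#' in a high-latitude shelf sea: a regular environmental grid warms at a
#' known rate on top of a north-south temperature gradient, species occupy
#' Gaussian thermal niches in bottom temperature, and catches follow a
#' hurdle structure (Bernoulli presence, lognormal biomass given presence).
#' Because the temperature field is linear in latitude and time, the
#' latitude of any isotherm drifts north at `warming_rate /
#' |lat_temp_gradient|` degrees per year, giving every downstream shift
#' estimator a closed-form ground truth to be checked against.
#'
#' @param n_species number of species in the synthetic community.
#' @param years integer vector of consecutive survey years (span >= 10,
#'   otherwise the default curation filters empty the data by construction).
#' @param region_bounds named list with `lat` and `lon`, each a length-2
#'   numeric range in degrees.
#' @param n_hauls_per_year hauls sampled each year (>= 5).
#' @param warming_rate bottom-temperature trend in degrees C per year (>= 0).
#' @param lat_temp_gradient degrees C per degree latitude; must be negative
#'   (cooler northward).
#' @param noise_sd_temp standard deviation (degrees C) of cell-level
#'   temperature noise, drawn independently per cell, year and variable.
#' @param t_ref mean bottom temperature (degrees C) at `lat_ref` in the
#'   first survey year.
#' @param lat_ref reference latitude for `t_ref`; defaults to the
#'   mid-latitude of `region_bounds`.
#' @param sst_offset fixed surface-minus-bottom temperature offset (degrees C).
#' @param niche data frame with one row per species and columns `species`,
#'   `t_opt` (thermal optimum, degrees C), `sigma_t` (niche breadth, degrees
#'   C, > 0), `p_max` (peak presence probability in (0, 1]), `mu_b` and
#'   `sigma_b` (log-biomass mean and sd). Defaults place the thermal optima
#'   on a regular ladder spanning the region's temperature range so that the
#'   community mixes interior species (which feel the full isotherm drift)
#'   with edge-truncated species (which shift less).
#' @param biomass_temp_coef optional Gaussian biomass-temperature response
#'   added to the log-biomass mean given presence (0 disables it; presence
#'   alone carries the niche by default so the ground truth stays closed
#'   form).
#' @param footprint_drift northward drift of the haul sampling window in
#'   degrees latitude per year (0 = stationary survey design).
#' @param season_months months hauls are drawn from (3-month field season).
#' @param depth_field function of (lat, lon) returning bottom depth in
#'   metres; the default is a smooth synthetic bathymetry within 50-450 m.
#' @param resolution environmental grid resolution in degrees.
#' @param region_name region label stamped on generated hauls.
#' @param seed master seed; per-stage child seeds are derived from it.
#'
#' @return An object of class `sim_config`.
#' @seealso [simulate_survey()], [compute_ground_truth()]
#' @export
sim_config <- function(n_species = 20,
                       years = 2001:2020,
                       region_bounds = list(lat = c(70, 78), lon = c(20, 40)),
                       n_hauls_per_year = 120,
                       warming_rate = 0.0675,
                       lat_temp_gradient = -0.5,
                       noise_sd_temp = 0.3,
                       t_ref = 3,
                       lat_ref = NULL,
                       sst_offset = 2,
                       niche = NULL,
                       biomass_temp_coef = 0,
                       footprint_drift = 0,
                       season_months = 7:9,
                       depth_field = NULL,
                       resolution = 0.25,
                       region_name = "synthetic",
                       seed = 1) {
  if (is.null(lat_ref)) lat_ref <- mean(region_bounds$lat)
  if (is.null(depth_field)) {
    # Default bathymetry varies with longitude only. Keeping depth
    # independent of latitude makes the centroid-depth covariate exogenous
    # to the centroid-latitude sampling noise (species biomass has no depth
    # response in the generator), so null calibration of the shift test is
    # interpretable; supply a custom depth_field for sloped bathymetry.
    depth_field <- function(lat, lon) {
      250 + 120 * sin((lon - 30) / 4)
    }
  }
  if (is.null(niche)) {
    niche <- tibble::tibble(
      species = sprintf("sp%02d", seq_len(n_species)),
      t_opt = seq(1, 6.5, length.out = n_species),
      sigma_t = 0.7,
      p_max = 0.85,
      mu_b = 0,
      sigma_b = 0.6
    )
  }
  cfg <- structure(
    list(n_species = as.integer(n_species), years = as.integer(years),
         region_bounds = region_bounds,
         n_hauls_per_year = as.integer(n_hauls_per_year),
         warming_rate = warming_rate, lat_temp_gradient = lat_temp_gradient,
         noise_sd_temp = noise_sd_temp, t_ref = t_ref, lat_ref = lat_ref,
         sst_offset = sst_offset, niche = niche,
         biomass_temp_coef = biomass_temp_coef,
         footprint_drift = footprint_drift,
         season_months = as.integer(season_months),
         depth_field = depth_field, resolution = resolution,
         region_name = region_name, seed = as.integer(seed)),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d species, years %d-%d, %d hauls/yr\n",
              x$n_species, min(x$years), max(x$years), x$n_hauls_per_year))
  cat(sprintf("  region lat [%g, %g], lon [%g, %g], grid %g deg\n",
              x$region_bounds$lat[1], x$region_bounds$lat[2],
              x$region_bounds$lon[1], x$region_bounds$lon[2], x$resolution))
  cat(sprintf("  warming %g C/yr, gradient %g C/deg lat, footprint drift %g deg/yr\n",
              x$warming_rate, x$lat_temp_gradient, x$footprint_drift))
  invisible(x)
}

validate_sim_config <- function(cfg) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  if (length(cfg$years) < 10) add("years must span at least 10 survey years")
  if (any(diff(cfg$years) != 1L)) add("years must be consecutive")
  if (cfg$n_hauls_per_year < 5) add("n_hauls_per_year must be >= 5")
  if (cfg$warming_rate < 0) add("warming_rate must be >= 0")
  if (cfg$lat_temp_gradient >= 0) add("lat_temp_gradient must be negative (cooler northward)")
  if (cfg$noise_sd_temp < 0) add("noise_sd_temp must be >= 0")
  if (length(cfg$season_months) != 3 || any(!cfg$season_months %in% 1:12)) {
    add("season_months must be three months in 1..12")
  }
  nn <- cfg$niche
  req <- c("species", "t_opt", "sigma_t", "p_max", "mu_b", "sigma_b")
  if (!all(req %in% names(nn))) {
    add(paste("niche table needs columns:", paste(req, collapse = ", ")))
  } else {
    if (nrow(nn) != cfg$n_species) add("niche table must have n_species rows")
    if (any(nn$sigma_t <= 0)) add("sigma_t must be > 0")
    if (any(nn$p_max <= 0 | nn$p_max > 1)) add("p_max must be in (0, 1]")
    if (anyDuplicated(nn$species)) add("species names must be unique")
  }
  if (diff(cfg$region_bounds$lat) <= 0 || diff(cfg$region_bounds$lon) <= 0) {
    add("region_bounds ranges must be increasing")
  }
  if (length(problems) > 0) {
    stop("invalid sim_config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  cfg
}

# Deterministic (noise-free) mean bottom temperature of the generator.
.mean_sbt <- function(cfg, lat, year) {
  cfg$t_ref + cfg$lat_temp_gradient * (lat - cfg$lat_ref) +
    cfg$warming_rate * (year - cfg$years[1])
}

# Sea-ice concentration as a deterministic decreasing ramp in SBT:
# full cover at/below -3 C, ice-free at/above 1 C.
.sic_from_sbt <- function(sbt) pmin(1, pmax(0, (1 - sbt) / 4))

#' Generate the synthetic environmental grid
#'
#' One seasonal-mean field set per survey year on a regular lat/lon grid:
#' sea bottom temperature (SBT) with a linear latitudinal gradient plus a
#' linear warming trend and iid cell noise; sea surface temperature (SST)
#' as SBT plus a fixed offset plus its own independent noise draw (so the
#' two fields are correlated but not collinear, as in real shelf seas);
#' sea-ice concentration (SIC) as a deterministic decreasing ramp in SBT
#' clipped to [0, 1]; and static bottom depth from the configured
#' bathymetry.
#'
#' @param config a [sim_config()].
#' @return A tibble of class `env_grid` with columns `lat`, `lon`, `year`,
#'   `sbt`, `sst`, `sic`, `depth`.
#' @export
simulate_environment <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(.child_seed(cfg$seed, "environment"))
  # The grid must cover the haul sampling window in every year, so it is
  # extended by the total footprint drift over the study period.
  total_drift <- cfg$footprint_drift * (length(cfg$years) - 1)
  lat_lo <- cfg$region_bounds$lat[1] + min(0, total_drift)
  lat_hi <- cfg$region_bounds$lat[2] + max(0, total_drift)
  lats <- seq(lat_lo, lat_hi, by = cfg$resolution)
  # seq() stops short of lat_hi unless the span is a multiple of the
  # resolution; add a cell so every haul is within half a cell of a center
  if (max(lats) + cfg$resolution / 2 < lat_hi) {
    lats <- c(lats, max(lats) + cfg$resolution)
  }
  lons <- seq(cfg$region_bounds$lon[1], cfg$region_bounds$lon[2],
              by = cfg$resolution)
  grid <- tidyr::expand_grid(year = cfg$years, lat = lats, lon = lons)
  n <- nrow(grid)
  sbt <- .mean_sbt(cfg, grid$lat, grid$year) +
    rnorm(n, 0, cfg$noise_sd_temp)
  sst <- sbt + cfg$sst_offset + rnorm(n, 0, cfg$noise_sd_temp)
  env <- tibble::tibble(
    lat = grid$lat, lon = grid$lon, year = grid$year,
    sbt = sbt, sst = sst, sic = .sic_from_sbt(sbt),
    depth = cfg$depth_field(grid$lat, grid$lon)
  )
  structure(env, class = c("env_grid", class(env)),
            resolution = cfg$resolution)
}

#' Generate synthetic haul records
#'
#' Haul positions are uniform within the region bounds; under a non-zero
#' `footprint_drift` the latitudinal sampling window translates north by
#' `footprint_drift * (year - first_year)`, emulating interannual drift in
#' survey coverage. Months are drawn from the configured field season and
#' measured haul depth is read from the bathymetry.
#'
#' @param config a [sim_config()].
#' @return A tibble of haul records with the standard haul-table schema
#'   (`haul_id`, `region`, `year`, `month`, `lat`, `lon`, `depth`, `gear`,
#'   `dist_coast`).
#' @export
simulate_hauls <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(.child_seed(cfg$seed, "hauls"))
  per_year <- lapply(cfg$years, function(yr) {
    offset <- cfg$footprint_drift * (yr - cfg$years[1])
    lat <- runif(cfg$n_hauls_per_year,
                 cfg$region_bounds$lat[1] + offset,
                 cfg$region_bounds$lat[2] + offset)
    lon <- runif(cfg$n_hauls_per_year,
                 cfg$region_bounds$lon[1], cfg$region_bounds$lon[2])
    tibble::tibble(
      year = yr,
      month = sample(cfg$season_months, cfg$n_hauls_per_year, replace = TRUE),
      lat = lat, lon = lon,
      depth = cfg$depth_field(lat, lon),
      dist_coast = runif(cfg$n_hauls_per_year, 25, 150)
    )
  })
  hauls <- dplyr::bind_rows(per_year)
  tibble::tibble(
    haul_id = sprintf("H%05d", seq_len(nrow(hauls))),
    region = cfg$region_name,
    hauls,
    gear = "SIM-TRAWL"
  )
}

#' Generate synthetic catch records
#'
#' For each haul x species pair the species is present with probability
#' `p_max * exp(-(SBT - t_opt)^2 / (2 sigma_t^2))`, where SBT is looked up
#' from the nearest environmental grid cell for the haul's year. Present
#' species contribute a lognormal biomass `exp(Normal(mu_b, sigma_b))` kg
#' (plus an optional Gaussian biomass-temperature response when
#' `biomass_temp_coef != 0`). Absences emit no record.
#'
#' @param hauls haul records from [simulate_hauls()].
#' @param env environmental grid from [simulate_environment()].
#' @param config the same [sim_config()].
#' @return A tibble of catch records (`haul_id`, `species`, `biomass`).
#' @export
simulate_catches <- function(hauls, env, config) {
  cfg <- validate_sim_config(config)
  set.seed(.child_seed(cfg$seed, "catches"))
  env_at_haul <- extract_environment(hauls, env)
  sbt <- env_at_haul$sbt
  out <- lapply(seq_len(nrow(cfg$niche)), function(i) {
    sp <- cfg$niche[i, ]
    niche_resp <- exp(-(sbt - sp$t_opt)^2 / (2 * sp$sigma_t^2))
    p <- sp$p_max * niche_resp
    present <- runif(length(p)) < p
    n_pres <- sum(present)
    if (n_pres == 0) return(NULL)
    log_mu <- sp$mu_b + cfg$biomass_temp_coef * niche_resp[present]
    tibble::tibble(
      haul_id = hauls$haul_id[present],
      species = sp$species,
      biomass = exp(rnorm(n_pres, log_mu, sp$sigma_b))
    )
  })
  dplyr::bind_rows(out)
}

#' Generate a synthetic trait table
#'
#' Emulates a FishBase-style trait table for the synthetic community. The
#' thermal traits are tied to the generating niches (`preferred_temp =
#' t_opt`, `temp_range = 4 * sigma_t`) and the zoogeography label is a
#' coarse binning of the thermal optimum, so trait regressions run
#' downstream have real structure to find; the remaining life-history
#' traits are drawn independently of the niche.
#'
#' @param config a [sim_config()].
#' @return A tibble with one row per species and the standard trait schema.
#' @export
simulate_traits <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(.child_seed(cfg$seed, "traits"))
  nn <- cfg$niche
  n <- nrow(nn)
  zoo <- cut(nn$t_opt, breaks = c(-Inf, 2, 3.5, Inf),
             labels = c("Arctic", "Arctic-Boreal", "Boreal"))
  tibble::tibble(
    species = nn$species,
    max_length = round(rlnorm(n, log(40), 0.5), 1),
    age_maturity_min = round(runif(n, 1, 10), 1),
    fecundity = round(rlnorm(n, log(5e4), 1.2)),
    habitat = sample(c("demersal", "pelagic"), n, replace = TRUE,
                     prob = c(0.75, 0.25)),
    trophic_level = round(runif(n, 2.8, 4.6), 2),
    preferred_temp = nn$t_opt,
    temp_range = 4 * nn$sigma_t,
    max_depth = round(rlnorm(n, log(400), 0.6)),
    zoogeography = as.character(zoo)
  )
}

#' Ground-truth shift rates of a synthetic scenario
#'
#' Computes, from the generator's noise-free mean field, the expected
#' biomass-weighted centroid latitude of every species in every year by
#' numerical integration of `E[biomass](lat) * lat` over that year's
#' surveyed latitude window, and reports the linear trend of these
#' centroids (x 111 km/deg) as the true geographic shift rate. The true
#' thermal-envelope shift rate is the drift speed of the `t_opt` isotherm,
#' `warming_rate / |lat_temp_gradient| * 111` km/yr, identical for all
#' species because the mean field is linear in latitude and time.
#'
#' Species whose niche is truncated by the region boundary have a true
#' geographic shift smaller in magnitude than the isotherm drift; species
#' whose full niche stays interior to the surveyed window match it.
#'
#' @param config a [sim_config()].
#' @param n_quad number of quadrature nodes for the latitude integral.
#' @return A tibble of class `ground_truth` with columns `species`,
#'   `true_shift_km_per_yr`, `true_envelope_shift_km_per_yr`.
#' @export
compute_ground_truth <- function(config, n_quad = 2000) {
  cfg <- validate_sim_config(config)
  iso_drift_deg <- cfg$warming_rate / abs(cfg$lat_temp_gradient)
  years <- cfg$years
  truth <- lapply(seq_len(nrow(cfg$niche)), function(i) {
    sp <- cfg$niche[i, ]
    cents <- vapply(years, function(yr) {
      offset <- cfg$footprint_drift * (yr - years[1])
      lat <- seq(cfg$region_bounds$lat[1] + offset,
                 cfg$region_bounds$lat[2] + offset, length.out = n_quad)
      sbt <- .mean_sbt(cfg, lat, yr)
      niche_resp <- exp(-(sbt - sp$t_opt)^2 / (2 * sp$sigma_t^2))
      # E[biomass | present] is constant unless the optional
      # biomass-temperature response is on.
      w <- sp$p_max * niche_resp *
        exp(sp$mu_b + cfg$biomass_temp_coef * niche_resp + sp$sigma_b^2 / 2)
      sum(w * lat) / sum(w)
    }, numeric(1))
    slope <- if (stats::sd(cents) == 0) 0 else
      unname(coef(lm(cents ~ years))[2])
    tibble::tibble(species = sp$species,
                   true_shift_km_per_yr = 111 * slope,
                   true_envelope_shift_km_per_yr = 111 * iso_drift_deg)
  })
  out <- dplyr::bind_rows(truth)
  structure(out, class = c("ground_truth", class(out)))
}

#' Generate a complete synthetic survey
#'
#' Runs all generator stages in order and returns the four input tables the
#' analysis pipeline consumes, plus the ground truth.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_survey` with elements `env`, `hauls`,
#'   `catches`, `traits`, `truth` and `config`.
#' @export
simulate_survey <- function(config) {
  cfg <- validate_sim_config(config)
  env <- simulate_environment(cfg)
  hauls <- simulate_hauls(cfg)
  catches <- simulate_catches(hauls, env, cfg)
  traits <- simulate_traits(cfg)
  truth <- compute_ground_truth(cfg)
  structure(list(env = env, hauls = hauls, catches = catches,
                 traits = traits, truth = truth, config = cfg),
            class = "sim_survey")
}

#' @export
print.sim_survey <- function(x, ...) {
  cat("<sim_survey>\n")
  cat(sprintf("  %d hauls, %d catch records, %d species, %d years\n",
              nrow(x$hauls), nrow(x$catches), x$config$n_species,
              length(x$config$years)))
  invisible(x)
}

#' Write a synthetic survey to CSV files
#'
#' Writes `hauls.csv`, `catches.csv`, `env.csv`, `traits.csv` and
#' `ground_truth.csv` (schemas matching what the readers in this package
#' expect) plus a `scenario.yaml` capturing the scalar configuration.
#'
#' @param survey a [simulate_survey()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(survey, dir) {
  stopifnot(inherits(survey, "sim_survey"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_csv_fixed(survey$hauls, file.path(dir, "hauls.csv"))
  .write_csv_fixed(survey$catches, file.path(dir, "catches.csv"))
  .write_csv_fixed(survey$env, file.path(dir, "env.csv"))
  .write_csv_fixed(survey$traits, file.path(dir, "traits.csv"))
  .write_csv_fixed(survey$truth, file.path(dir, "ground_truth.csv"))
  cfg <- survey$config
  scal <- cfg[!names(cfg) %in% c("niche", "depth_field")]
  scal$region_bounds <- list(lat = as.numeric(cfg$region_bounds$lat),
                             lon = as.numeric(cfg$region_bounds$lon))
  yaml::write_yaml(list(scenario = scal,
                        niche = as.data.frame(cfg$niche)),
                   file.path(dir, "scenario.yaml"))
  invisible(dir)
}
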