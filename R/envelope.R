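# Two-part (hurdle) GAM thermal-envelope model: binomial presence part,
# Gaussian log-biomass part, Duan smearing retransformation, annual
# spatial projection and envelope shift estimation.

# Build smooth terms with graceful degradation: covariates with too few
# unique values for the basis enter linearly; constant covariates drop.
.gam_terms <- function(df, vars, k) {
  terms <- character(0)
  notes <- character(0)
  for (v in vars) {
    u <- length(unique(df[[v]]))
    if (u > k) {
      terms <- c(terms, sprintf("s(%s, k = %d)", v, k))
    } else if (u > 1) {
      terms <- c(terms, v)
      notes <- c(notes, sprintf("%s entered linearly (only %d unique values)", v, u))
    } else {
      notes <- c(notes, sprintf("%s dropped (constant)", v))
    }
  }
  list(terms = terms, notes = notes)
}

.env_vars <- function(include_sic) {
  c("sbt", "sst", if (include_sic) "sic", "depth")
}

# Newton-based smoothness selection can fail on near-degenerate likelihoods
# (e.g. completely separable presence data); fall back to BFGS, then GCV.
.fit_gam_robust <- function(fml, data, family = stats::gaussian(), method) {
  tryCatch(
    mgcv::gam(fml, data = data, family = family, method = method),
    error = function(e1) tryCatch(
      mgcv::gam(fml, data = data, family = family, method = method,
                optimizer = c("outer", "bfgs")),
      error = function(e2)
        mgcv::gam(fml, data = data, family = family, method = "GCV.Cp"))
  )
}

#' Fit the presence part of the hurdle model
#'
#' Binomial GAM of presence/absence on penalized regression splines
#' (basis dimension `basis_dim`) of bottom temperature, surface
#' temperature and depth, optionally sea-ice concentration.
#'
#' @param data one row per haul with columns `presence` (0/1), `sbt`,
#'   `sst`, `depth` and, if `include_sic`, `sic`. Absences are the region
#'   hauls without a catch record for the species.
#' @param basis_dim spline basis dimension per term.
#' @param include_sic include a smooth of sea-ice concentration.
#' @param method smoothing-parameter selection method passed to
#'   [mgcv::gam()].
#' @return The fitted `gam` object.
#' @export
fit_presence_gam <- function(data, basis_dim = 4, include_sic = FALSE,
                             method = "REML") {
  df <- as.data.frame(data)
  .assert_columns(df, c("presence", .env_vars(include_sic)), "presence data")
  if (nrow(df) < 50) stop("presence model needs >= 50 hauls")
  if (length(unique(df$presence)) < 2) {
    stop("species present in all or no hauls; no binomial contrast to fit")
  }
  tm <- .gam_terms(df, .env_vars(include_sic), basis_dim)
  fml <- as.formula(paste("presence ~", paste(tm$terms, collapse = " + ")))
  fit <- .fit_gam_robust(fml, df, stats::binomial(), method)
  attr(fit, "notes") <- tm$notes
  fit
}

#' Fit the biomass part of the hurdle model
#'
#' Gaussian GAM of log(biomass) on the same smooths as the presence part
#' plus a linear term for the annual mean biomass of the species (computed
#' from the presence hauls of each year), which absorbs year-to-year
#' abundance changes so the smooths capture the thermal envelope.
#'
#' @param data presence hauls only, with columns `biomass` (> 0 kg),
#'   `year`, `sbt`, `sst`, `depth` and, if `include_sic`, `sic`.
#' @inheritParams fit_presence_gam
#' @return The fitted `gam` object, with the per-year mean biomass table
#'   and the training mean attached as attributes.
#' @export
fit_biomass_gam <- function(data, basis_dim = 4, include_sic = FALSE,
                            method = "REML") {
  df <- as.data.frame(data)
  .assert_columns(df, c("biomass", "year", .env_vars(include_sic)),
                  "biomass data")
  if (nrow(df) < 30) stop("biomass model needs >= 30 presence hauls")
  if (any(df$biomass <= 0)) stop("biomass must be strictly positive")
  df$log_biomass <- log(df$biomass)
  ann <- dplyr::summarise(dplyr::group_by(df, .data$year),
                          ann_mean_biomass = mean(.data$biomass),
                          .groups = "drop")
  df <- dplyr::left_join(df, ann, by = "year")
  tm <- .gam_terms(df, .env_vars(include_sic), basis_dim)
  terms <- c(tm$terms,
             if (sd(df$ann_mean_biomass) > 1e-12) "ann_mean_biomass")
  fml <- as.formula(paste("log_biomass ~", paste(terms, collapse = " + ")))
  fit <- .fit_gam_robust(fml, df, stats::gaussian(), method)
  attr(fit, "notes") <- tm$notes
  attr(fit, "annual_mean_biomass") <- ann
  attr(fit, "train_mean_biomass") <- mean(ann$ann_mean_biomass)
  fit
}

#' Duan smearing factor
#'
#' Nonparametric retransformation correction for predictions back-
#' transformed from a log-scale model: the arithmetic mean of the
#' exponentiated residuals, `Phi = sum(exp(e_i)) / n`.
#'
#' @param residuals residuals of the log-scale (biomass) model.
#' @return The smearing factor, a positive scalar.
#' @export
smearing_factor <- function(residuals) {
  if (length(residuals) == 0) stop("smearing_factor() needs >= 1 residual")
  if (anyNA(residuals)) stop("smearing_factor(): missing residuals")
  mean(exp(residuals))
}

#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney form with ties averaged: the probability that a randomly
#' chosen presence scores above a randomly chosen absence, counting ties
#' as 1/2.
#'
#' @param labels 0/1 vector.
#' @param scores numeric prediction scores.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: labels contain a single class")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit the full thermal-envelope (hurdle GAM) model for one species
#'
#' Combines the presence and biomass parts fitted on all years pooled
#' (the realized thermal envelope is assumed stable over the study
#' period; only its geographic projection moves), the smearing factor
#' from the biomass-part residuals, the in-sample AUC of the presence
#' part and the percentage of deviance explained by the biomass part.
#'
#' @param species species name.
#' @param curated a `curated_dataset` whose hauls carry environmental
#'   columns (see [curate_dataset()]).
#' @inheritParams fit_presence_gam
#' @return An object of class `delta_gam`: list with `species`, `part1`,
#'   `part2`, `phi`, `auc`, `deviance_explained_pct`, `residuals`,
#'   `include_sic`, `train_mean_biomass`, `train_ranges`, `depth_band`.
#' @export
fit_envelope_model <- function(species, curated, basis_dim = 4,
                               include_sic = FALSE, method = "REML") {
  stopifnot(inherits(curated, "curated_dataset"))
  hauls <- curated$hauls
  .assert_columns(hauls, .env_vars(include_sic),
                  "curated hauls (run extract_environment first)")
  sp_catch <- curated$catches[curated$catches$species == species, , drop = FALSE]
  if (nrow(sp_catch) == 0) stop("no retained catches for species ", species)
  hauls$presence <- as.integer(hauls$haul_id %in% sp_catch$haul_id)
  part1 <- fit_presence_gam(hauls, basis_dim, include_sic, method)
  pres <- dplyr::inner_join(hauls,
                            sp_catch[, c("haul_id", "biomass")], by = "haul_id")
  part2 <- fit_biomass_gam(pres, basis_dim, include_sic, method)
  eps <- resid(part2)
  dev_expl <- summary(part2)$dev.expl * 100
  if (!is.finite(dev_expl)) {
    warning("zero-variance log-biomass response; reporting 100% deviance explained by convention")
    dev_expl <- 100
  }
  vars <- .env_vars(include_sic)
  ranges <- lapply(setNames(vars, vars), function(v) range(hauls[[v]]))
  structure(list(
    species = species,
    part1 = part1, part2 = part2,
    phi = smearing_factor(eps),
    auc = auc_rank(hauls$presence, predict(part1, type = "response")),
    deviance_explained_pct = dev_expl,
    residuals = eps,
    include_sic = include_sic,
    train_mean_biomass = attr(part2, "train_mean_biomass"),
    train_ranges = ranges,
    depth_band = c(curated$spec$depth_min, curated$spec$depth_max)
  ), class = "delta_gam")
}

#' @export
print.delta_gam <- function(x, ...) {
  cat("<delta_gam>", x$species, "\n")
  cat(sprintf("  AUC %.3f | deviance explained %.1f%% | smearing Phi %.4f\n",
              x$auc, x$deviance_explained_pct, x$phi))
  invisible(x)
}

#' Model evaluation summary
#'
#' @param model a `delta_gam`.
#' @return List with `auc` (presence part, in-sample, rank statistic with
#'   ties averaged) and `deviance_explained_pct` (biomass part).
#' @export
evaluate_model <- function(model) {
  stopifnot(inherits(model, "delta_gam"))
  list(auc = model$auc, deviance_explained_pct = model$deviance_explained_pct)
}

#' Project the thermal envelope onto one year's environmental grid
#'
#' Cellwise predicted biomass `b = p * exp(u) * Phi`, where `p` is the
#' presence-part prediction, `u` the biomass-part prediction (with the
#' annual-mean-biomass covariate held at its training-period mean so that
#' interannual envelope movement reflects the environment only), and
#' `Phi` the smearing factor. Cells outside the region's surveyed depth
#' band are masked out. The envelope centroid is the b-weighted mean
#' position of the unmasked cells, mirroring the observed-centroid
#' definition.
#'
#' @param model a `delta_gam`.
#' @param env_year environmental grid rows of a single year.
#' @param depth_band length-2 depth mask in metres; defaults to the
#'   band stored in the model.
#' @return A list of class `envelope_prediction`: `species`, `year`,
#'   `grid` (lat, lon, b), `centroid_lat`, `centroid_lon`,
#'   `extrapolation_fraction`.
#' @export
predict_envelope <- function(model, env_year, depth_band = NULL) {
  stopifnot(inherits(model, "delta_gam"))
  if (length(unique(env_year$year)) != 1) {
    stop("predict_envelope() expects the grid of a single year")
  }
  if (is.null(depth_band)) depth_band <- model$depth_band
  g <- as.data.frame(env_year)
  g <- g[g$depth >= depth_band[1] & g$depth <= depth_band[2], , drop = FALSE]
  if (nrow(g) == 0) stop("no grid cells inside the depth band")
  vars <- .env_vars(model$include_sic)
  extrap <- rep(FALSE, nrow(g))
  for (v in vars) {
    rng <- model$train_ranges[[v]]
    extrap <- extrap | g[[v]] < rng[1] | g[[v]] > rng[2]
  }
  g$ann_mean_biomass <- model$train_mean_biomass
  p <- predict(model$part1, newdata = g, type = "response")
  u <- predict(model$part2, newdata = g)
  b <- as.numeric(p) * exp(as.numeric(u)) * model$phi
  if (sum(b) <= 0 || !any(b > 1e-300)) {
    stop("zero envelope: predicted biomass vanishes over the whole grid")
  }
  structure(list(
    species = model$species,
    year = g$year[1],
    grid = tibble::tibble(lat = g$lat, lon = g$lon, b = b),
    centroid_lat = sum(b * g$lat) / sum(b),
    centroid_lon = sum(b * g$lon) / sum(b),
    extrapolation_fraction = mean(extrap)
  ), class = "envelope_prediction")
}

#' Project the envelope across all years
#'
#' @param model a `delta_gam`.
#' @param env an `env_grid` covering the projection years.
#' @param years years to project; defaults to all years in `env`.
#' @param ... passed to [predict_envelope()].
#' @return A tibble with one row per year: `species`, `year`,
#'   `centroid_lat`, `centroid_lon`, `extrapolation_fraction`.
#' @export
project_envelope <- function(model, env, years = NULL, ...) {
  if (is.null(years)) years <- sort(unique(env$year))
  rows <- lapply(years, function(yr) {
    pr <- predict_envelope(model, env[env$year == yr, , drop = FALSE], ...)
    tibble::tibble(species = pr$species, year = pr$year,
                   centroid_lat = pr$centroid_lat,
                   centroid_lon = pr$centroid_lon,
                   extrapolation_fraction = pr$extrapolation_fraction)
  })
  dplyr::bind_rows(rows)
}

#' Estimate a species' thermal-envelope shift rate
#'
#' Ordinary least-squares regression of the annual envelope-centroid
#' latitude on year; the slope (x 111) is the envelope shift rate in
#' km/yr.
#'
#' @param predictions per-year envelope centroids from
#'   [project_envelope()] (>= 10 years).
#' @return A one-row tibble: `species`, `n_years`,
#'   `envelope_shift_deg_per_yr`, `envelope_shift_km_per_yr`, `r2`,
#'   `p_value`.
#' @export
estimate_envelope_shift <- function(predictions) {
  df <- as.data.frame(predictions)
  if (nrow(df) < 10) {
    stop(sprintf("need >= 10 annual envelope predictions (got %d)", nrow(df)))
  }
  fit <- lm(centroid_lat ~ year, data = df)
  smr <- summary(fit)
  slope <- unname(coef(fit)["year"])
  p <- if (nrow(smr$coefficients) >= 2 && !is.na(smr$coefficients["year", 4]))
    smr$coefficients["year", 4] else NA_real_
  if (smr$sigma < 1e-10) p <- if (abs(slope) < 1e-12) 1 else 0
  tibble::tibble(
    species = df$species[1],
    n_years = nrow(df),
    envelope_shift_deg_per_yr = slope,
    envelope_shift_km_per_yr = 111 * slope,
    r2 = smr$r.squared,
    p_value = p
  )
}

#' Fit and project envelopes for every retained species
#'
#' Species failing the hurdle-model preconditions (too few presence
#' hauls, no binomial contrast, zero envelope) are skipped with a
#' message and recorded in the `skipped` attribute.
#'
#' @param curated a `curated_dataset` with environmental columns.
#' @param env an `env_grid` for the projection.
#' @param region region label stamped on the output.
#' @param ... passed to [fit_envelope_model()].
#' @return A tibble of class `envelope_shifts`, one row per species, with
#'   the per-species model diagnostics (`phi`, `auc`,
#'   `deviance_explained_pct`, `mean_extrapolation_fraction`) alongside
#'   the shift estimates; fitted models in the `models` attribute.
#' @export
estimate_envelope_shifts <- function(curated, env, region = "region", ...) {
  species <- sort(unique(curated$n_records$species))
  models <- list()
  skipped <- character(0)
  rows <- list()
  for (sp in species) {
    res <- tryCatch({
      m <- fit_envelope_model(sp, curated, ...)
      proj <- project_envelope(m, env)
      est <- estimate_envelope_shift(proj)
      models[[sp]] <- m
      dplyr::bind_cols(tibble::tibble(region = region), est,
                       tibble::tibble(
                         phi = m$phi, auc = m$auc,
                         deviance_explained_pct = m$deviance_explained_pct,
                         mean_extrapolation_fraction = mean(proj$extrapolation_fraction)))
    }, error = function(e) {
      message(sprintf("skipping %s: %s", sp, conditionMessage(e)))
      skipped <<- c(skipped, sp)
      NULL
    })
    if (!is.null(res)) rows[[sp]] <- res
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("envelope_shifts", class(out)),
            models = models, skipped = skipped)
}
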