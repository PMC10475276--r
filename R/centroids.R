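# Annual biomass-weighted centroids and latitudinal shift estimation.

#' Annual biomass-weighted centroids
#'
#' For every retained species-year, the centroid latitude is the
#' biomass-weighted mean latitude over the presence hauls of that year,
#' and the centroid depth the biomass-weighted mean of measured haul
#' depth. Alongside each centroid the function records the mean and median
#' latitude of *all* hauls of that region-year (species present or not);
#' these survey-footprint covariates enter the shift model to partly
#' correct for spatio-temporal heterogeneity in survey coverage.
#'
#' @param curated a `curated_dataset` from [filter_species_years()] or
#'   [curate_dataset()].
#' @return A tibble of class `annual_centroids` with columns `species`,
#'   `year`, `lat_c`, `depth_c`, `n_presence_hauls`, `survey_mean_lat`,
#'   `survey_median_lat`.
#' @export
compute_annual_centroids <- function(curated) {
  stopifnot(inherits(curated, "curated_dataset"))
  hauls <- curated$hauls
  survey <- dplyr::summarise(dplyr::group_by(hauls, .data$year),
                             survey_mean_lat = mean(.data$lat),
                             survey_median_lat = median(.data$lat),
                             .groups = "drop")
  cat_h <- dplyr::inner_join(curated$catches,
                             hauls[, c("haul_id", "year", "lat", "depth")],
                             by = "haul_id")
  if (any(cat_h$biomass <= 0)) {
    stop("non-positive biomass in curated catches; curation should have removed these")
  }
  cent <- dplyr::summarise(
    dplyr::group_by(cat_h, .data$species, .data$year),
    lat_c = weighted.mean(.data$lat, .data$biomass),
    depth_c = weighted.mean(.data$depth, .data$biomass),
    n_presence_hauls = dplyr::n(), .groups = "drop"
  )
  out <- dplyr::left_join(cent, survey, by = "year")
  out <- dplyr::arrange(out, .data$species, .data$year)
  structure(out, class = c("annual_centroids", class(out)))
}

# Build the centroid-model formula, degrading gracefully on degenerate
# inputs: the depth smooth is dropped when depth_c is (near-)constant or
# has too few unique values for the basis, and the survey-median covariate
# is dropped when it is collinear with the survey mean.
.shift_terms <- function(df, basis_dim, footprint_correction) {
  terms <- "year"
  notes <- character(0)
  du <- unique(df$depth_c)
  if (length(du) > basis_dim && sd(df$depth_c) > 1e-8) {
    terms <- c(terms, sprintf("s(depth_c, k = %d)", basis_dim))
  } else {
    notes <- c(notes, "depth smooth dropped (depth_c constant or too few unique values)")
  }
  if (footprint_correction) {
    if (sd(df$survey_mean_lat) > 1e-10) {
      terms <- c(terms, "survey_mean_lat")
      cr <- suppressWarnings(cor(df$survey_mean_lat, df$survey_median_lat))
      if (!is.na(cr) && abs(cr) > 0.999) {
        notes <- c(notes, "survey_median_lat dropped (collinear with survey_mean_lat)")
      } else if (sd(df$survey_median_lat) > 1e-10) {
        terms <- c(terms, "survey_median_lat")
      } else {
        notes <- c(notes, "survey_median_lat dropped (constant)")
      }
    } else {
      notes <- c(notes, "survey covariates dropped (constant)")
    }
  }
  list(terms = terms, notes = notes)
}

#' Estimate one species' latitudinal shift rate
#'
#' Fits the centroid model `lat_c ~ s(depth_c) + year + survey_mean_lat +
#' survey_median_lat` with a penalized regression spline on centroid depth
#' (basis dimension `basis_dim`). The year coefficient is the latitudinal
#' shift rate in degrees/yr, converted to km/yr by multiplying by 111.
#' Significance of the year term is assessed by a likelihood-ratio
#' comparison of the model with and without year, with smoothing
#' parameters held at the full-model estimates; for this Gaussian model
#' the comparison is carried out in its exact-F form (change in deviance
#' over the full-model scale against F(1, residual df)). A Wald t-test on
#' the year coefficient is available as `p_method = "wald"`.
#'
#' @param centroids annual centroids of a single species (>= 10 years).
#' @param alpha significance level for the `significant` flag.
#' @param p_method `"lr"` (default) or `"wald"`.
#' @param footprint_correction include the survey-latitude covariates
#'   (default TRUE); FALSE gives the uncorrected estimator for comparison.
#' @param basis_dim basis dimension of the depth smooth.
#' @param conf_level confidence level of the reported shift interval.
#' @return A one-row tibble: `species`, `n_years`, `shift_deg_per_yr`,
#'   `shift_km_per_yr` (= 111 x degrees), `se_km_per_yr`, `ci_low_km`,
#'   `ci_high_km`, `r2` (adjusted), `p_value`, `significant`, `notes`.
#' @export
estimate_shift <- function(centroids, alpha = 0.05,
                           p_method = c("lr", "wald"),
                           footprint_correction = TRUE,
                           basis_dim = 4, conf_level = 0.95) {
  p_method <- match.arg(p_method)
  df <- as.data.frame(centroids)
  if (length(unique(df$species)) > 1) {
    stop("estimate_shift() expects centroids of a single species; see estimate_shifts()")
  }
  if (nrow(df) < 10) {
    stop(sprintf("need >= 10 annual centroids to estimate a shift (got %d)",
                 nrow(df)))
  }
  if (sd(df$lat_c) < 1e-12) {
    # perfectly flat series: zero shift, no evidence against the null
    return(tibble::tibble(
      species = df$species[1], n_years = nrow(df),
      shift_deg_per_yr = 0, shift_km_per_yr = 0, se_km_per_yr = 0,
      ci_low_km = 0, ci_high_km = 0, r2 = NA_real_, p_value = 1,
      significant = FALSE, notes = "constant centroid latitude"))
  }
  tm <- .shift_terms(df, basis_dim, footprint_correction)
  full_fml <- as.formula(paste("lat_c ~", paste(tm$terms, collapse = " + ")))
  has_smooth <- any(grepl("^s\\(", tm$terms))
  full <- mgcv::gam(full_fml, data = df, method = "REML")
  smr <- summary(full)
  beta <- unname(coef(full)["year"])
  se <- unname(smr$p.table["year", "Std. Error"])
  dfres <- df.residual(full)
  tcrit <- qt(1 - (1 - conf_level) / 2, dfres)

  if (p_method == "wald") {
    p <- unname(smr$p.table["year", "Pr(>|t|)"])
  } else {
    red_terms <- setdiff(tm$terms, "year")
    red_fml <- if (length(red_terms) == 0) lat_c ~ 1 else
      as.formula(paste("lat_c ~", paste(red_terms, collapse = " + ")))
    red <- if (has_smooth) {
      mgcv::gam(red_fml, data = df, sp = full$sp, method = "REML")
    } else {
      mgcv::gam(red_fml, data = df, method = "REML")
    }
    dev_full <- stats::deviance(full)
    dev_red <- stats::deviance(red)
    scale <- dev_full / dfres
    if (scale < 1e-12) {
      # Noiseless data: any deviance drop is decisive, none is null.
      p <- if (dev_red - dev_full < 1e-12) 1 else 0
    } else {
      Fstat <- max(0, dev_red - dev_full) / scale
      p <- pf(Fstat, 1, dfres, lower.tail = FALSE)
    }
  }
  tibble::tibble(
    species = df$species[1],
    n_years = nrow(df),
    shift_deg_per_yr = beta,
    shift_km_per_yr = 111 * beta,
    se_km_per_yr = 111 * se,
    ci_low_km = 111 * (beta - tcrit * se),
    ci_high_km = 111 * (beta + tcrit * se),
    r2 = smr$r.sq,
    p_value = p,
    significant = is.finite(p) && p < alpha,
    notes = paste(tm$notes, collapse = "; ")
  )
}

#' Estimate shift rates for every species
#'
#' @param centroids an `annual_centroids` table (all species).
#' @param region region label stamped on the output.
#' @param min_years species with fewer annual centroids are skipped with a
#'   message.
#' @param ... passed to [estimate_shift()].
#' @return A tibble of class `shift_estimates`, one row per species.
#' @export
estimate_shifts <- function(centroids, region = "region", min_years = 10, ...) {
  split_c <- split(as.data.frame(centroids), centroids$species)
  too_few <- names(split_c)[vapply(split_c, nrow, 0L) < min_years]
  if (length(too_few) > 0) {
    message(sprintf("skipping %d species with < %d years of centroids",
                    length(too_few), min_years))
    split_c <- split_c[setdiff(names(split_c), too_few)]
  }
  out <- dplyr::bind_rows(lapply(split_c, estimate_shift, ...))
  out <- dplyr::bind_cols(tibble::tibble(region = region), out)
  structure(out, class = c("shift_estimates", class(out)))
}

#' Hodges-Lehmann pseudomedian with signed-rank confidence interval
#'
#' The pseudomedian is the median of all `n(n+1)/2` Walsh averages
#' `(x_i + x_j)/2`, `i <= j` - the location estimate associated with the
#' Wilcoxon signed-rank test. The confidence interval inverts the
#' signed-rank distribution: exactly for `n <= exact_n_max`, by normal
#' approximation above.
#'
#' @param x numeric vector, `n >= 3`.
#' @param conf_level confidence level.
#' @param exact_n_max largest n for which the exact signed-rank
#'   distribution is used.
#' @return A list with `pseudomedian`, `ci_low`, `ci_high`.
#' @export
hodges_lehmann <- function(x, conf_level = 0.95, exact_n_max = 25) {
  n <- length(x)
  if (n < 3) stop("hodges_lehmann() needs at least 3 values")
  if (anyNA(x)) stop("hodges_lehmann(): missing values not allowed")
  w <- outer(x, x, "+")[upper.tri(diag(n), diag = TRUE)] / 2
  w <- sort(w)
  m <- length(w)  # n(n+1)/2
  alpha <- 1 - conf_level
  if (n <= exact_n_max) {
    # largest k with P(V <= k - 1) <= alpha/2
    k <- qsignrank(alpha / 2, n)
    if (k > 0 && psignrank(k - 1, n) > alpha / 2) k <- k - 1
    k <- max(k, 0)
    lo <- if (k >= 1) w[k] else w[1]
    hi <- if (k >= 1) w[m + 1 - k] else w[m]
  } else {
    mu <- n * (n + 1) / 4
    sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    k <- max(1, floor(mu - qnorm(1 - alpha / 2) * sig))
    lo <- w[k]
    hi <- w[m + 1 - k]
  }
  list(pseudomedian = median(w), ci_low = lo, ci_high = hi)
}

#' Community-level shift test
#'
#' Tests whether the community of species-level shift rates differs from
#' zero. Normality of the shift rates is assessed with a Shapiro-Wilk
#' test; when it is not rejected (p >= alpha) a one-sample two-sided
#' t-test is used and the central estimate is the mean with its t-interval,
#' otherwise a two-sided Wilcoxon signed-rank test is used and the central
#' estimate is the Hodges-Lehmann pseudomedian with its signed-rank
#' interval.
#'
#' @param shifts a `shift_estimates` table (>= 3 species).
#' @param alpha significance level (used both for the normality gate and
#'   for counting individually significant species).
#' @param conf_level confidence level of the interval.
#' @return A list of class `community_summary`: `region`, `n_species`,
#'   `normality_p`, `test_used`, `central_estimate`, `ci_low`, `ci_high`,
#'   `p_value`, `n_north_significant`, `n_south_significant`.
#' @export
community_shift_test <- function(shifts, alpha = 0.05, conf_level = 0.95) {
  v <- shifts$shift_km_per_yr
  if (length(v) < 3) stop("community test needs >= 3 species")
  region <- if ("region" %in% names(shifts)) shifts$region[1] else "region"
  n_north <- sum(shifts$significant & v > 0, na.rm = TRUE)
  n_south <- sum(shifts$significant & v < 0, na.rm = TRUE)
  base <- list(region = region, n_species = length(v),
               n_north_significant = n_north, n_south_significant = n_south)
  if (sd(v) < 1e-12) {
    warning("zero variance in shift rates; skipping community tests")
    out <- c(base, list(normality_p = NA_real_, test_used = "none",
                        central_estimate = v[1], ci_low = v[1], ci_high = v[1],
                        p_value = NA_real_))
    return(structure(out, class = "community_summary"))
  }
  norm_p <- shapiro.test(v)$p.value
  if (norm_p >= alpha) {
    tt <- t.test(v, mu = 0, conf.level = conf_level)
    out <- c(base, list(normality_p = norm_p, test_used = "t-test",
                        central_estimate = unname(tt$estimate),
                        ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
                        p_value = tt$p.value))
  } else {
    wt <- suppressWarnings(wilcox.test(v, mu = 0))
    hl <- hodges_lehmann(v, conf_level = conf_level)
    out <- c(base, list(normality_p = norm_p, test_used = "wilcoxon",
                        central_estimate = hl$pseudomedian,
                        ci_low = hl$ci_low, ci_high = hl$ci_high,
                        p_value = wt$p.value))
  }
  structure(out, class = "community_summary")
}

#' @export
print.community_summary <- function(x, ...) {
  cat("<community_summary>", x$region, "\n")
  cat(sprintf("  n = %d species; normality p = %s -> %s\n", x$n_species,
              format(x$normality_p, digits = 3), x$test_used))
  cat(sprintf("  central shift %.2f km/yr [%.2f, %.2f], p = %s\n",
              x$central_estimate, x$ci_low, x$ci_high,
              format(x$p_value, digits = 3)))
  cat(sprintf("  individually significant: %d north, %d south\n",
              x$n_north_significant, x$n_south_significant))
  invisible(x)
}
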