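# Observed-vs-envelope shift comparison and trait regressions.

.match_shifts <- function(observed, envelope) {
  obs <- tibble::tibble(species = observed$species,
                        observed = observed$shift_km_per_yr)
  env <- tibble::tibble(species = envelope$species,
                        envelope = envelope$envelope_shift_km_per_yr)
  m <- dplyr::inner_join(obs, env, by = "species")
  m <- m[complete.cases(m), , drop = FALSE]
  dropped <- length(union(obs$species, env$species)) - nrow(m)
  if (dropped > 0) {
    message(sprintf("%d species dropped (missing one of the two shift estimates)",
                    dropped))
  }
  m
}

#' Pearson correlation between observed and envelope shifts
#'
#' @param observed a `shift_estimates` table.
#' @param envelope an `envelope_shifts` table.
#' @return List with `r`, `p_value`, `n` (matched species).
#' @export
correlate_shifts <- function(observed, envelope) {
  m <- .match_shifts(observed, envelope)
  if (nrow(m) < 3) stop("need >= 3 matched species for a correlation test")
  if (sd(m$observed) < 1e-12 || sd(m$envelope) < 1e-12) {
    stop("zero variance in one of the shift vectors; correlation undefined")
  }
  ct <- cor.test(m$observed, m$envelope, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(m))
}

#' Direction correspondence between observed and envelope shifts
#'
#' Classifies each matched species by the sign pair of its observed and
#' envelope shift (an exactly-zero shift counts as northward, a
#' measure-zero convention) and reports the percentage of species in each
#' of the four cells.
#'
#' @inheritParams correlate_shifts
#' @param region label for the output row.
#' @return A tibble of class `correspondence_table` with columns `region`,
#'   `obs_down_env_up`, `obs_up_env_down`, `both_down`, `both_up`
#'   (percentages summing to 100) and `n_species`.
#' @export
direction_correspondence <- function(observed, envelope, region = "region") {
  m <- .match_shifts(observed, envelope)
  if (nrow(m) == 0) stop("no matched species")
  up_o <- m$observed >= 0
  up_e <- m$envelope >= 0
  pct <- function(x) 100 * sum(x) / nrow(m)
  out <- tibble::tibble(
    region = region,
    obs_down_env_up = pct(!up_o & up_e),
    obs_up_env_down = pct(up_o & !up_e),
    both_down = pct(!up_o & !up_e),
    both_up = pct(up_o & up_e),
    n_species = nrow(m)
  )
  structure(out, class = c("correspondence_table", class(out)))
}

#' Frequency-ordered incremental tracking correlation
#'
#' Orders species by sampling frequency (`n_records`, descending; ties
#' broken alphabetically) and recomputes the Pearson correlation between
#' observed and envelope shifts on the `k` most-recorded species for
#' `k = 3 ... N`, showing how the tracking signal changes as rarer,
#' noisier species enter.
#'
#' @inheritParams correlate_shifts
#' @param n_records tibble with columns `species`, `n_records`.
#' @return A tibble with one row per `k`: `k`, `species_added`, `r`, `p_value`
#'   (`r` is `NA` where the correlation is undefined).
#' @export
incremental_correlation <- function(observed, envelope, n_records) {
  m <- .match_shifts(observed, envelope)
  if (nrow(m) < 3) stop("need >= 3 matched species")
  m <- dplyr::left_join(m, n_records[, c("species", "n_records")],
                        by = "species")
  if (anyNA(m$n_records)) stop("n_records missing for some matched species")
  m <- m[order(-m$n_records, m$species), , drop = FALSE]
  rows <- lapply(3:nrow(m), function(k) {
    sub <- m[seq_len(k), ]
    if (sd(sub$observed) < 1e-12 || sd(sub$envelope) < 1e-12) {
      tibble::tibble(k = k, species_added = m$species[k],
                     r = NA_real_, p_value = NA_real_)
    } else {
      ct <- cor.test(sub$observed, sub$envelope)
      tibble::tibble(k = k, species_added = m$species[k],
                     r = unname(ct$estimate), p_value = ct$p.value)
    }
  })
  dplyr::bind_rows(rows)
}

#' Generalized least squares with a power variance structure
#'
#' Fits `formula` by GLS with error variance `Var(e_i) = sigma^2 *
#' |v_i|^(2 delta)`, the power-of-covariate heteroscedasticity model.
#' The default variance covariate is the absolute fitted mean (updated
#' iteratively during estimation); any strictly positive column of
#' `data` can be used instead via `variance_covariate`. Estimation is
#' delegated to [nlme::gls()] with [nlme::varPower()]; `delta` can be
#' fixed (e.g. `delta = 0` reproduces OLS exactly).
#'
#' @param formula model formula.
#' @param data data frame; rows with missing values in the model
#'   variables are dropped listwise with a message.
#' @param variance_covariate optional name of the variance covariate
#'   column; `NULL` (default) uses the fitted values.
#' @param delta optional fixed variance power; `NULL` estimates it.
#' @return An object of class `gls_fit`: list with `coefficients` (tibble
#'   with estimate, SE, t, p), `delta`, `r2` (squared correlation between
#'   fitted and observed), `n`, `n_dropped`, `converged`, `note`,
#'   `variance_covariate` and the underlying `model`.
#' @export
gls_power <- function(formula, data, variance_covariate = NULL, delta = NULL) {
  df <- as.data.frame(data)
  used_vars <- unique(c(all.vars(formula), variance_covariate))
  used_vars <- intersect(used_vars, names(df))
  cc <- complete.cases(df[, used_vars, drop = FALSE])
  n_dropped <- sum(!cc)
  if (n_dropped > 0) {
    message(sprintf("gls_power: %d row(s) dropped (missing values)", n_dropped))
  }
  df <- df[cc, , drop = FALSE]
  p_terms <- length(attr(stats::terms(formula, data = df), "term.labels"))
  if (nrow(df) <= p_terms + 3) stop("too few observations for the GLS model")
  if (!is.null(variance_covariate)) {
    v <- df[[variance_covariate]]
    if (any(v <= 0)) stop("variance covariate must be strictly positive")
    vform <- as.formula(paste("~", variance_covariate))
  } else {
    vform <- ~fitted(.)
  }
  wts <- if (is.null(delta)) {
    nlme::varPower(form = vform)
  } else {
    nlme::varPower(form = vform, fixed = delta)
  }
  note <- ""
  converged <- TRUE
  fit <- tryCatch(
    nlme::gls(formula, data = df, weights = wts, method = "ML"),
    error = function(e) {
      note <<- paste("power-variance fit failed, OLS fallback:",
                     conditionMessage(e))
      converged <<- FALSE
      nlme::gls(formula, data = df, method = "ML")
    }
  )
  smr <- summary(fit)
  tt <- smr$tTable
  delta_hat <- if (!converged) NA_real_
  else if (!is.null(delta)) delta
  else unname(coef(fit$modelStruct$varStruct, unconstrained = FALSE)[1])
  y <- stats::model.response(stats::model.frame(formula, df))
  structure(list(
    coefficients = tibble::tibble(
      term = rownames(tt), estimate = tt[, "Value"],
      se = tt[, "Std.Error"], t = tt[, "t-value"], p_value = tt[, "p-value"]),
    delta = delta_hat,
    r2 = cor(fitted(fit), y)^2,
    n = nrow(df), n_dropped = n_dropped,
    converged = converged, note = note,
    variance_covariate = if (is.null(variance_covariate)) "fitted" else variance_covariate,
    model = fit
  ), class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat("<gls_fit> n =", x$n, "| delta =", format(x$delta, digits = 4),
      "| variance covariate:", x$variance_covariate, "\n")
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 4)
  if (!x$converged) cat("  NOTE:", x$note, "\n")
  invisible(x)
}

#' Effect of sampling frequency on shift estimates
#'
#' Regresses species shift rates (or their absolute values) on the number
#' of records by power-variance GLS: a significant effect indicates that
#' estimated shifts depend on how well a species is sampled, and flags
#' `n_records` for inclusion as a covariate in the trait models.
#'
#' @param shifts a `shift_estimates` table (or any table with `species`
#'   and `shift_km_per_yr`).
#' @param n_records tibble with `species` and `n_records`.
#' @param absolute regress `|shift|` instead of the signed shift.
#' @param alpha significance level for the `significant` flag.
#' @param ... passed to [gls_power()].
#' @return A `gls_fit` with extra elements `significant` and `response`.
#' @export
records_effect <- function(shifts, n_records, absolute = FALSE,
                           alpha = 0.05, ...) {
  df <- dplyr::inner_join(
    tibble::tibble(species = shifts$species, shift = shifts$shift_km_per_yr),
    n_records[, c("species", "n_records")], by = "species")
  if (absolute) df$shift <- abs(df$shift)
  fit <- gls_power(shift ~ n_records, df, ...)
  p <- fit$coefficients$p_value[fit$coefficients$term == "n_records"]
  fit$significant <- is.finite(p) && p < alpha
  fit$response <- if (absolute) "abs_shift" else "shift"
  fit
}

# Reference-level convention: zoogeography contrasts reported versus
# "Arctic" when that level is present, else the alphabetical first level.
.prep_trait_factors <- function(df) {
  for (v in intersect(c("zoogeography", "habitat"), names(df))) {
    f <- factor(df[[v]])
    if (v == "zoogeography" && "Arctic" %in% levels(f)) {
      f <- stats::relevel(f, ref = "Arctic")
    }
    df[[v]] <- f
  }
  df
}

#' Single-trait GLS regressions of shift rates
#'
#' Fits one power-variance GLS per trait, with `n_records` added as a
#' covariate when [records_effect()] finds it significant (the inclusion
#' decision is automated and recorded in the output). Categorical traits
#' contribute one row per non-reference level.
#'
#' @param shifts a `shift_estimates` table.
#' @param traits a trait table (see [read_trait_table()]).
#' @param n_records tibble with `species`, `n_records`.
#' @param region label for the output.
#' @param traits_to_fit trait column names; defaults to the nine standard
#'   traits present in `traits`.
#' @param alpha significance level.
#' @param ... passed to [gls_power()].
#' @return A tibble of class `trait_models`: `region`, `trait`, `term`,
#'   `slope`, `se`, `r2`, `p_value`, `p_holm`, `n`,
#'   `n_records_included`. Holm-adjusted p-values are reported alongside
#'   the raw ones for transparency; inference follows the raw values.
#' @export
trait_models <- function(shifts, traits, n_records, region = "region",
                         traits_to_fit = NULL, alpha = 0.05, ...) {
  std <- c("max_length", "age_maturity_min", "fecundity", "habitat",
           "trophic_level", "preferred_temp", "temp_range", "max_depth",
           "zoogeography")
  if (is.null(traits_to_fit)) traits_to_fit <- intersect(std, names(traits))
  df <- dplyr::inner_join(
    tibble::tibble(species = shifts$species, shift = shifts$shift_km_per_yr),
    traits, by = "species")
  df <- dplyr::left_join(df, n_records[, c("species", "n_records")],
                         by = "species")
  df <- .prep_trait_factors(df)
  rec <- tryCatch(records_effect(shifts, n_records, alpha = alpha, ...),
                  error = function(e) {
                    message("records-effect regression not fitted: ",
                            conditionMessage(e))
                    NULL
                  })
  include_records <- isTRUE(rec$significant)
  rows <- list()
  for (tr in traits_to_fit) {
    sub <- df[!is.na(df[[tr]]), , drop = FALSE]
    rhs <- if (include_records) paste(tr, "+ n_records") else tr
    fml <- as.formula(paste("shift ~", rhs))
    fit <- tryCatch(gls_power(fml, sub, ...), error = function(e) NULL)
    if (is.null(fit)) {
      message("trait model skipped for ", tr)
      next
    }
    co <- fit$coefficients
    co <- co[grepl(paste0("^", tr), co$term), , drop = FALSE]
    rows[[tr]] <- tibble::tibble(
      region = region, trait = tr, term = co$term, slope = co$estimate,
      se = co$se, r2 = fit$r2, p_value = co$p_value, n = fit$n,
      n_records_included = include_records)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) out$p_holm <- p.adjust(out$p_value, method = "holm")
  structure(out, class = c("trait_models", class(out)),
            records_effect = rec)
}

#' Combined biogeography and thermal-preference regression
#'
#' The named multiple-regression analysis: shift rate on zoogeography and
#' preferred temperature jointly (plus `n_records` when the rarity effect
#' is significant), by power-variance GLS. Useful to ask whether
#' biogeographic class carries information beyond thermal preference.
#'
#' @inheritParams trait_models
#' @param ... passed to [gls_power()].
#' @return A `gls_fit`.
#' @export
trait_multiple_model <- function(shifts, traits, n_records, alpha = 0.05,
                                 ...) {
  df <- dplyr::inner_join(
    tibble::tibble(species = shifts$species, shift = shifts$shift_km_per_yr),
    traits, by = "species")
  df <- dplyr::left_join(df, n_records[, c("species", "n_records")],
                         by = "species")
  df <- .prep_trait_factors(df)
  rec <- tryCatch(records_effect(shifts, n_records, alpha = alpha, ...),
                  error = function(e) NULL)
  rhs <- "zoogeography + preferred_temp"
  if (isTRUE(rec$significant)) rhs <- paste(rhs, "+ n_records")
  gls_power(as.formula(paste("shift ~", rhs)), df, ...)
}
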