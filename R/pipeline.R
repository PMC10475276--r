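# End-to-end orchestration: config validation, region runs, provenance.

#' Validate a run configuration
#'
#' Accepts a YAML path or a list. A configuration is either simulation
#' mode (a `scenario` block, see [sim_config()]) or real-data mode
#' (`inputs` block with `hauls`, `catches`, `env` and optionally `traits`
#' paths); the two are mutually exclusive. All violations are collected
#' and reported together, not first-failure.
#'
#' @param config YAML file path or list.
#' @return An object of class `run_config`, or an error listing every
#'   problem found.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  has_sim <- !is.null(config$scenario)
  has_real <- !is.null(config$inputs)
  if (has_sim && has_real) add("simulation mode (scenario) and real-data mode (inputs) are mutually exclusive")
  if (!has_sim && !has_real) add("one of 'scenario' or 'inputs' is required")
  if (has_real) {
    for (f in c("hauls", "catches", "env")) {
      p <- config$inputs[[f]]
      if (is.null(p)) add(sprintf("inputs$%s is required", f))
      else if (!file.exists(p)) add(sprintf("inputs$%s: file not found: %s", f, p))
    }
    tp <- config$inputs$traits
    if (!is.null(tp) && !file.exists(tp)) add(sprintf("inputs$traits: file not found: %s", tp))
  }
  fs <- config$filter
  if (!is.null(fs)) {
    if (!is.null(fs$depth_min) && !is.null(fs$depth_max) &&
        fs$depth_min >= fs$depth_max) {
      add("filter: depth_min must be < depth_max")
    }
    if (!is.null(fs$min_trawls_per_year) && fs$min_trawls_per_year < 1) {
      add("filter: min_trawls_per_year must be >= 1")
    }
  }
  alpha <- config$alpha %||% 0.05
  if (alpha <= 0 || alpha >= 1) add("alpha must be in (0, 1)")
  if (has_sim) {
    sc <- tryCatch({
      do.call(sim_config, config$scenario)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(sc)) add(sc)
  }
  if (length(problems) > 0) {
    stop("invalid run config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(list(
    region = config$region %||% "region",
    scenario = config$scenario,
    inputs = config$inputs,
    filter = fs %||% list(),
    envelope = config$envelope %||% list(),
    alpha = alpha,
    seed = config$seed %||% 1L,
    out = config$out %||% "trawlshift-out"
  ), class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.provenance_new <- function(config) {
  list(config = config[setdiff(names(config), "out")],
       r_version = as.character(getRversion()),
       counts = list(), warnings = character(0),
       failed_stage = NULL)
}

#' Run the full range-shift analysis for one region
#'
#' Executes curation, centroid shift estimation, community testing,
#' thermal-envelope modelling, tracking comparison and (when traits are
#' available) trait regressions, writing all report tables to the output
#' directory: `centroids.csv`, `shifts.csv`, `community.json`,
#' `envelope_shifts.csv`, `correspondence.csv`, `tracking.json`,
#' `trait_models.csv` and `provenance.json`. A stage failure retains the
#' outputs written so far and records the failure in the provenance.
#'
#' @param config a `run_config` (or anything [validate_config()] accepts).
#' @param out output directory; overrides the config's `out`.
#' @return Invisibly, a list with the in-memory results and provenance.
#' @export
run_region <- function(config, out = NULL) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  out <- out %||% cfg$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  # state lives in environments so stage expressions (evaluated in this
  # frame) can update it by reference
  prov <- list2env(.provenance_new(cfg))
  res <- new.env()
  finish <- function() {
    p <- as.list(prov)
    p <- p[c("config", "r_version", "counts", "warnings", "failed_stage")]
    jsonlite::write_json(p, file.path(out, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(c(as.list(res), list(provenance = p)))
  }
  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        prov$failed_stage <- list(stage = name, error = conditionMessage(e))
        NULL
      }),
      warning = function(w) {
        prov$warnings <- c(prov$warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        prov$warnings <- c(prov$warnings, trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
  }

  # --- inputs ---------------------------------------------------------
  dat <- stage("inputs", {
    if (!is.null(cfg$scenario)) {
      sc <- do.call(sim_config, c(cfg$scenario,
                                  if (is.null(cfg$scenario$seed)) list(seed = cfg$seed)))
      sv <- simulate_survey(sc)
      .write_csv_fixed(sv$truth, file.path(out, "ground_truth.csv"))
      list(hauls = sv$hauls, catches = sv$catches, env = sv$env,
           traits = sv$traits, n_read = nrow(sv$hauls), n_rejected = 0L)
    } else {
      hauls <- read_haul_table(cfg$inputs$hauls,
                               rejects_path = file.path(out, "hauls.rejects.csv"))
      catches <- read_catch_table(cfg$inputs$catches, hauls = hauls,
                                  rejects_path = file.path(out, "catches.rejects.csv"))
      env <- read_env_grid(cfg$inputs$env)
      traits <- if (!is.null(cfg$inputs$traits)) read_trait_table(cfg$inputs$traits)
      list(hauls = hauls, catches = catches, env = env, traits = traits,
           n_read = nrow(hauls) + nrow(rejects(hauls)),
           n_rejected = nrow(rejects(hauls)))
    }
  })
  if (is.null(dat)) return(finish())
  prov$counts$hauls_read <- dat$n_read
  prov$counts$hauls_rejected <- dat$n_rejected

  # --- curate ---------------------------------------------------------
  curated <- stage("curate", {
    spec <- do.call(region_filter_spec, cfg$filter)
    curate_dataset(dat$hauls, dat$catches, dat$env, spec)
  })
  if (is.null(curated)) return(finish())
  prov$counts$hauls_kept <- nrow(curated$hauls)
  prov$counts$species_retained <- nrow(curated$n_records)
  if (nrow(curated$n_records) == 0) {
    prov$warnings <- c(prov$warnings,
                       "no species retained after curation filters; empty run")
    return(finish())
  }

  # --- centroids & shifts ---------------------------------------------
  shifts <- stage("centroids", {
    cents <- compute_annual_centroids(curated)
    .write_csv_fixed(cents, file.path(out, "centroids.csv"))
    res$centroids <- cents
    sh <- estimate_shifts(cents, region = cfg$region, alpha = cfg$alpha)
    .write_csv_fixed(sh, file.path(out, "shifts.csv"))
    sh
  })
  if (is.null(shifts)) return(finish())
  res$shifts <- shifts
  prov$counts$species_with_shift <- nrow(shifts)

  stage("community", {
    comm <- community_shift_test(shifts, alpha = cfg$alpha)
    jsonlite::write_json(unclass(comm), file.path(out, "community.json"),
                         auto_unbox = TRUE, digits = NA)
    res$community <- comm
  })

  # --- thermal envelopes ----------------------------------------------
  env_shifts <- stage("envelope", {
    include_sic <- isTRUE(cfg$envelope$include_sic)
    es <- estimate_envelope_shifts(
      curated, dat$env, region = cfg$region, include_sic = include_sic,
      basis_dim = cfg$envelope$basis_dim %||% 4,
      method = cfg$envelope$method %||% "REML")
    .write_csv_fixed(es, file.path(out, "envelope_shifts.csv"))
    es
  })
  if (!is.null(env_shifts) && nrow(env_shifts) > 0) {
    res$envelope_shifts <- env_shifts
    prov$counts$species_modelled <- nrow(env_shifts)
    stage("tracking", {
      track <- correlate_shifts(shifts, env_shifts)
      corr <- direction_correspondence(shifts, env_shifts, region = cfg$region)
      incr <- incremental_correlation(shifts, env_shifts, curated$n_records)
      .write_csv_fixed(corr, file.path(out, "correspondence.csv"))
      jsonlite::write_json(list(pearson = track,
                                incremental = as.data.frame(.signif_cols(incr))),
                           file.path(out, "tracking.json"),
                           auto_unbox = TRUE, digits = NA)
      res$tracking <- track
      res$correspondence <- corr
      res$incremental <- incr
    })
  }

  # --- traits ----------------------------------------------------------
  if (!is.null(dat$traits)) {
    stage("traits", {
      tm <- trait_models(shifts, dat$traits, curated$n_records,
                         region = cfg$region, alpha = cfg$alpha)
      .write_csv_fixed(tm, file.path(out, "trait_models.csv"))
      res$trait_models <- tm
    })
  }
  finish()
}
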