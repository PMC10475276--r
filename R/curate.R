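# Reading, validation and filtering of haul / catch / environment tables.
#
# Readers never drop rows silently: every malformed row goes to a rejects
# table (attached as an attribute, optionally written to disk) with the
# reason, so that |input| = |kept| + |rejects| always holds.

.reject_report <- function(df, keep, reason) {
  rejects <- df[!keep, , drop = FALSE]
  if (nrow(rejects) > 0) rejects$reason <- reason[!keep]
  rejects
}

.finish_reader <- function(kept, rejects, rejects_path) {
  rejects <- dplyr::bind_rows(rejects)
  if (!is.null(rejects_path) && nrow(rejects) > 0) {
    readr::write_csv(rejects, rejects_path)
  }
  attr(kept, "rejects") <- rejects
  kept
}

#' Rejected rows of a read table
#'
#' @param x a table returned by one of the `read_*_table()` readers.
#' @return A tibble of rejected input rows with a `reason` column.
#' @export
rejects <- function(x) {
  r <- attr(x, "rejects")
  if (is.null(r)) tibble::tibble() else r
}

# Coerce selected columns to numeric, flagging rows where coercion fails
# or the value is missing. Returns list(df, bad_field) where bad_field is
# NA for clean rows, else the first offending column name.
.coerce_numeric <- function(df, cols) {
  bad <- rep(NA_character_, nrow(df))
  for (cl in cols) {
    val <- suppressWarnings(as.numeric(df[[cl]]))
    bad[is.na(bad) & is.na(val)] <- cl
    df[[cl]] <- val
  }
  list(df = df, bad = bad)
}

#' Read a haul table
#'
#' Expected columns: `haul_id`, `region`, `year`, `month`, `lat`, `lon`,
#' `depth`, `gear`, `dist_coast`. Rows with missing or non-numeric values
#' in the numeric columns, out-of-range months, non-positive depths or
#' duplicated haul ids are rejected with a reason, never silently dropped.
#'
#' @param path CSV file path.
#' @param rejects_path optional path for a CSV of rejected rows; by default
#'   rejects are only attached to the result (see [rejects()]).
#' @return A tibble of haul records with a `rejects` attribute.
#' @export
read_haul_table <- function(path, rejects_path = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  .assert_columns(df, c("haul_id", "region", "year", "month", "lat", "lon",
                        "depth", "gear", "dist_coast"), "haul table")
  co <- .coerce_numeric(df, c("year", "month", "lat", "lon", "depth", "dist_coast"))
  df <- co$df
  bad <- co$bad
  bad[is.na(bad) & !df$month %in% 1:12] <- "month"
  bad[is.na(bad) & df$depth <= 0] <- "depth"
  bad[is.na(bad) & df$dist_coast < 0] <- "dist_coast"
  bad[is.na(bad) & (is.na(df$haul_id) | df$haul_id == "")] <- "haul_id"
  bad[is.na(bad) & duplicated(df$haul_id)] <- "duplicate haul_id"
  keep <- is.na(bad)
  rej <- .reject_report(df, keep, bad)
  kept <- df[keep, , drop = FALSE]
  kept$year <- as.integer(kept$year)
  kept$month <- as.integer(kept$month)
  .finish_reader(kept, rej, rejects_path)
}

#' Read a catch table
#'
#' Expected columns: `haul_id`, `species`, `biomass` (kg). Absence is
#' encoded by the absence of a row; zero-biomass rows are therefore dropped
#' with a warning, negative or non-numeric biomass is rejected, and rows
#' referencing a haul id not present in `hauls` (when supplied) are
#' rejected with reason "orphan".
#'
#' @param path CSV file path.
#' @param hauls optional haul table used to detect orphan catch rows.
#' @inheritParams read_haul_table
#' @return A tibble of catch records with a `rejects` attribute.
#' @export
read_catch_table <- function(path, hauls = NULL, rejects_path = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  .assert_columns(df, c("haul_id", "species", "biomass"), "catch table")
  co <- .coerce_numeric(df, "biomass")
  df <- co$df
  bad <- co$bad
  bad[is.na(bad) & df$biomass < 0] <- "biomass"
  bad[is.na(bad) & (is.na(df$species) | df$species == "")] <- "species"
  if (!is.null(hauls)) {
    bad[is.na(bad) & !df$haul_id %in% hauls$haul_id] <- "orphan"
  }
  zero <- is.na(bad) & df$biomass == 0
  if (any(zero)) {
    warning(sprintf("dropping %d zero-biomass catch row(s); absence is encoded by no row",
                    sum(zero)))
    bad[zero] <- "zero biomass"
  }
  keep <- is.na(bad)
  .finish_reader(df[keep, , drop = FALSE], .reject_report(df, keep, bad),
                 rejects_path)
}

#' Read a long-format environmental grid
#'
#' Expected columns: `lat`, `lon`, `year`, `sbt`, `sst`, `sic`, `depth`,
#' and optionally `month` for monthly fields (seasonal averaging is then
#' done by [extract_environment()]). SIC values outside [0, 1] are an
#' error.
#'
#' @param path CSV file path.
#' @return A tibble of class `env_grid`.
#' @export
read_env_grid <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  .assert_columns(df, c("lat", "lon", "year", "sbt", "sst", "sic", "depth"),
                  "environment grid")
  if (any(df$sic < 0 | df$sic > 1, na.rm = TRUE)) {
    stop("environment grid: SIC values outside [0, 1]")
  }
  lats <- sort(unique(df$lat))
  res <- if (length(lats) > 1) min(diff(lats)) else NA_real_
  structure(tibble::as_tibble(df), class = c("env_grid", class(tibble::as_tibble(df))),
            resolution = res)
}

#' Read a species trait table
#'
#' @param path CSV file path with a `species` column plus trait columns
#'   (see [simulate_traits()] for the standard schema).
#' @return A tibble of trait records.
#' @export
read_trait_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  .assert_columns(df, "species", "trait table")
  tibble::as_tibble(df)
}

#' Region filtering specification
#'
#' Encodes the region-level inclusion rules applied to hauls and the
#' species/year retention thresholds. All numeric bounds are closed
#' (`>=` / `<=`): a haul exactly at `min_dist_coast` km from the coast, or
#' a species recorded in exactly `min_trawls_per_year` trawls, is kept.
#'
#' @param depth_min,depth_max haul depth bounds in metres.
#' @param months survey months retained.
#' @param gear_whitelist gear codes retained (`NULL` keeps all gears).
#' @param min_dist_coast minimum distance to coast, km.
#' @param min_trawls_per_year minimum presence trawls for a species-year to
#'   count as a qualifying year.
#' @param min_years minimum qualifying years for a species to be retained.
#' @param exclude_years survey years removed outright (e.g. years with
#'   anomalous spatial coverage).
#' @return An object of class `region_filter_spec`.
#' @export
region_filter_spec <- function(depth_min = 30, depth_max = 600,
                               months = 7:9, gear_whitelist = NULL,
                               min_dist_coast = 20,
                               min_trawls_per_year = 5, min_years = 10,
                               exclude_years = integer(0)) {
  if (depth_min >= depth_max) stop("depth_min must be < depth_max")
  if (min_trawls_per_year < 1) stop("min_trawls_per_year must be >= 1")
  if (min_years < 1) stop("min_years must be >= 1")
  structure(list(depth_min = depth_min, depth_max = depth_max,
                 months = as.integer(months), gear_whitelist = gear_whitelist,
                 min_dist_coast = min_dist_coast,
                 min_trawls_per_year = as.integer(min_trawls_per_year),
                 min_years = as.integer(min_years),
                 exclude_years = as.integer(exclude_years)),
            class = "region_filter_spec")
}

#' Filter hauls by region rules
#'
#' Retains hauls with depth in `[depth_min, depth_max]`, month in `months`,
#' gear in the whitelist (if any), `dist_coast >= min_dist_coast`, and year
#' not excluded. Bounds are closed; input order is preserved.
#'
#' @param hauls a haul table.
#' @param spec a [region_filter_spec()].
#' @return The retained haul rows.
#' @export
filter_hauls <- function(hauls, spec) {
  stopifnot(inherits(spec, "region_filter_spec"))
  keep <- hauls$depth >= spec$depth_min & hauls$depth <= spec$depth_max &
    hauls$month %in% spec$months &
    hauls$dist_coast >= spec$min_dist_coast &
    !hauls$year %in% spec$exclude_years
  if (!is.null(spec$gear_whitelist)) {
    keep <- keep & hauls$gear %in% spec$gear_whitelist
  }
  hauls[keep, , drop = FALSE]
}

#' Apply the species-year retention filter
#'
#' Two passes: (1) drop every (species, year) with fewer than
#' `min_trawls_per_year` presence hauls ("recorded in at least five
#' trawls" counts hauls where the species was actually caught); (2) drop
#' species left with fewer than `min_years` qualifying years. The rarity
#' covariate `n_records` (total presence hauls over qualifying years) is
#' computed after pass 1.
#'
#' @param hauls hauls already passed through [filter_hauls()].
#' @param catches a catch table.
#' @param spec a [region_filter_spec()].
#' @return An object of class `curated_dataset`: list with `hauls`,
#'   `catches` (restricted to retained species-years), `species_years`
#'   (qualifying-year index with presence counts), `n_records`, and `spec`.
#' @export
filter_species_years <- function(hauls, catches, spec) {
  stopifnot(inherits(spec, "region_filter_spec"))
  catches <- catches[catches$haul_id %in% hauls$haul_id, , drop = FALSE]
  catches <- dplyr::left_join(catches,
                              hauls[, c("haul_id", "year")], by = "haul_id")
  counts <- dplyr::count(catches, .data$species, .data$year,
                         name = "n_presence")
  qualifying <- counts[counts$n_presence >= spec$min_trawls_per_year, ,
                       drop = FALSE]
  n_records <- dplyr::summarise(dplyr::group_by(qualifying, .data$species),
                                n_records = sum(.data$n_presence),
                                n_years = dplyr::n(), .groups = "drop")
  retained <- n_records[n_records$n_years >= spec$min_years, , drop = FALSE]
  qualifying <- qualifying[qualifying$species %in% retained$species, ,
                           drop = FALSE]
  keep_key <- paste(catches$species, catches$year)
  ok <- keep_key %in% paste(qualifying$species, qualifying$year)
  catches <- catches[ok, setdiff(names(catches), "year"), drop = FALSE]
  structure(list(hauls = hauls, catches = catches,
                 species_years = qualifying,
                 n_records = retained, spec = spec),
            class = "curated_dataset")
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat("<curated_dataset>\n")
  cat(sprintf("  %d hauls, %d catch records, %d retained species\n",
              nrow(x$hauls), nrow(x$catches), nrow(x$n_records)))
  invisible(x)
}

#' Join environmental values to hauls by nearest grid cell
#'
#' Looks up, for each haul, the environmental values of the nearest grid
#' cell of the haul's year (no interpolation, matching raster-extract
#' semantics). A haul exactly midway between two cells resolves to the
#' lower-index (smaller-coordinate) cell. When the grid carries a `month`
#' column, fields are first averaged over `season_months` per cell-year.
#'
#' @param hauls a haul table.
#' @param env an `env_grid`.
#' @param season_months months averaged when the grid is monthly.
#' @return `hauls` with columns `sbt`, `sst`, `sic` and `grid_depth`
#'   appended (measured haul depth is kept; grid depth is used for
#'   projection grids).
#' @export
extract_environment <- function(hauls, env, season_months = NULL) {
  if ("month" %in% names(env)) {
    if (is.null(season_months)) season_months <- sort(unique(env$month))[1:3]
    env <- env[env$month %in% season_months, , drop = FALSE]
    env <- dplyr::summarise(dplyr::group_by(env, .data$lat, .data$lon, .data$year),
                            sbt = mean(.data$sbt), sst = mean(.data$sst),
                            sic = mean(.data$sic), depth = mean(.data$depth),
                            .groups = "drop")
  }
  lats <- sort(unique(env$lat))
  lons <- sort(unique(env$lon))
  res <- attr(env, "resolution")
  if (is.null(res) || is.na(res)) {
    res <- if (length(lats) > 1) min(diff(lats)) else Inf
  }
  bad_pos <- .outside_grid(hauls$lat, lats, res) |
    .outside_grid(hauls$lon, lons, res)
  bad_year <- !hauls$year %in% unique(env$year)
  if (any(bad_pos | bad_year)) {
    ids <- hauls$haul_id[bad_pos | bad_year]
    stop("haul(s) outside environmental grid coverage: ",
         paste(utils::head(ids, 10), collapse = ", "),
         if (length(ids) > 10) sprintf(" (+%d more)", length(ids) - 10) else "")
  }
  key <- paste(lats[.nearest_index(hauls$lat, lats)],
               lons[.nearest_index(hauls$lon, lons)],
               hauls$year)
  env_key <- paste(env$lat, env$lon, env$year)
  idx <- match(key, env_key)
  if (anyNA(idx)) {
    stop("haul(s) map to grid cells absent from the environment table: ",
         paste(utils::head(hauls$haul_id[is.na(idx)], 10), collapse = ", "))
  }
  hauls$sbt <- env$sbt[idx]
  hauls$sst <- env$sst[idx]
  hauls$sic <- env$sic[idx]
  hauls$grid_depth <- env$depth[idx]
  hauls
}

#' Curate a dataset end to end
#'
#' Convenience wrapper: filters hauls, joins environmental values, and
#' applies the species-year retention filter.
#'
#' @param hauls,catches,env input tables.
#' @param spec a [region_filter_spec()].
#' @return A `curated_dataset` whose hauls carry environmental columns.
#' @export
curate_dataset <- function(hauls, catches, env, spec) {
  hauls <- filter_hauls(hauls, spec)
  hauls <- extract_environment(hauls, env, season_months = spec$months)
  filter_species_years(hauls, catches, spec)
}
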