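# Small scenario configs and hand-built tables used across tests.

small_config <- function(...) {
  sim_config(n_species = 4, years = 2001:2012, n_hauls_per_year = 40,
             niche = tibble::tibble(
               species = paste0("sp", 1:4),
               t_opt = c(2, 3, 4, 5), sigma_t = 0.8,
               p_max = 0.9, mu_b = 0, sigma_b = 0.5),
             resolution = 0.5, seed = 42, ...)
}

# A tiny, fully hand-checkable haul/catch pair: 3 years would fail the
# default retention filters, so tests pair it with permissive specs.
toy_hauls <- function() {
  tibble::tibble(
    haul_id = sprintf("T%02d", 1:6),
    region = "toy",
    year = c(2000, 2000, 2001, 2001, 2002, 2002),
    month = 7L, lat = c(60, 62, 60.5, 61.5, 60, 63),
    lon = 5, depth = c(100, 200, 150, 150, 120, 180),
    gear = "G", dist_coast = 50
  )
}

toy_env <- function(years = 2000:2002) {
  g <- tidyr::expand_grid(year = years, lat = seq(59, 64, 0.5),
                          lon = seq(4, 6, 0.5))
  structure(
    tibble::tibble(g, sbt = 5, sst = 7, sic = 0, depth = 150),
    class = c("env_grid", class(tibble::tibble())), resolution = 0.5)
}

write_temp_csv <- function(df, name = "t.csv") {
  p <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(df, p)
  p
}
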