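# Naive reference implementation: per-group loops, no vectorized joins.
naive_centroids <- function(hauls, catches) {
  out <- list()
  for (sp in unique(catches$species)) {
    cs <- catches[catches$species == sp, ]
    yrs <- unique(hauls$year[hauls$haul_id %in% cs$haul_id])
    for (y in sort(yrs)) {
      ids <- hauls$haul_id[hauls$year == y]
      rows <- cs[cs$haul_id %in% ids, ]
      if (nrow(rows) == 0) next
      lat <- hauls$lat[match(rows$haul_id, hauls$haul_id)]
      dep <- hauls$depth[match(rows$haul_id, hauls$haul_id)]
      out[[length(out) + 1]] <- data.frame(
        species = sp, year = y,
        lat_c = sum(rows$biomass * lat) / sum(rows$biomass),
        depth_c = sum(rows$biomass * dep) / sum(rows$biomass))
    }
  }
  do.call(rbind, out)
}

as_curated <- function(hauls, catches) {
  structure(list(hauls = hauls, catches = catches,
                 species_years = NULL, n_records = NULL,
                 spec = region_filter_spec()),
            class = "curated_dataset")
}

test_that("centroids match hand-computed biomass-weighted means", {
  hauls <- toy_hauls()
  catches <- tibble::tibble(
    haul_id = c("T01", "T02", "T03", "T04", "T05"),
    species = c("a", "a", "a", "a", "b"),
    biomass = c(1, 1, 1, 3, 2))
  cents <- compute_annual_centroids(as_curated(hauls, catches))
  a2000 <- cents[cents$species == "a" & cents$year == 2000, ]
  expect_equal(a2000$lat_c, 61)               # equal weights, lats 60 & 62
  a2001 <- cents[cents$species == "a" & cents$year == 2001, ]
  expect_equal(a2001$lat_c, (60.5 + 3 * 61.5) / 4)  # 1 kg vs 3 kg
  b2002 <- cents[cents$species == "b" & cents$year == 2002, ]
  expect_equal(b2002$lat_c, 60)               # single presence haul
  expect_equal(b2002$n_presence_hauls, 1)
  # survey stats use ALL hauls of the year, not just presence hauls
  expect_equal(a2000$survey_mean_lat, 61)
  expect_equal(b2002$survey_mean_lat, 61.5)
  expect_equal(b2002$survey_median_lat, 61.5)
})

test_that("centroids agree with a naive loop implementation on random fixtures", {
  set.seed(99)
  for (i in 1:20) {
    n_hauls <- sample(20:60, 1)
    hauls <- tibble::tibble(
      haul_id = sprintf("H%03d", 1:n_hauls), region = "r",
      year = sample(2000:2004, n_hauls, replace = TRUE), month = 7L,
      lat = runif(n_hauls, 55, 75), lon = runif(n_hauls, 0, 10),
      depth = runif(n_hauls, 30, 500), gear = "G", dist_coast = 50)
    n_cat <- sample(30:120, 1)
    catches <- tibble::tibble(
      haul_id = sample(hauls$haul_id, n_cat, replace = TRUE),
      species = sample(letters[1:4], n_cat, replace = TRUE),
      biomass = rlnorm(n_cat))
    catches <- catches[!duplicated(catches[, 1:2]), ]
    got <- compute_annual_centroids(as_curated(hauls, catches))
    ref <- naive_centroids(hauls, catches)
    ref <- ref[order(ref$species, ref$year), ]
    expect_equal(got$lat_c, ref$lat_c, tolerance = 1e-12)
    expect_equal(got$depth_c, ref$depth_c, tolerance = 1e-12)
  }
})

test_that("noiseless linear centroid drift is recovered exactly", {
  years <- 2000:2014
  cents <- tibble::tibble(
    species = "s", year = years,
    lat_c = 60 + 0.01 * (years - 2000),
    depth_c = 100, survey_mean_lat = 60, survey_median_lat = 60,
    n_presence_hauls = 10)
  est <- estimate_shift(cents)
  expect_equal(est$shift_km_per_yr, 1.11, tolerance = 1e-8)
  expect_equal(est$shift_deg_per_yr, 0.01, tolerance = 1e-8)
  expect_lt(est$p_value, 1e-6)

  flat <- cents
  flat$lat_c <- 60
  est0 <- estimate_shift(flat)
  expect_equal(est0$shift_km_per_yr, 0, tolerance = 1e-10)
})

test_that("km/deg unit identity holds exactly for every estimate", {
  sv <- simulate_survey(small_config())
  cur <- curate_dataset(sv$hauls, sv$catches, sv$env,
                        region_filter_spec(min_years = 8))
  sh <- suppressMessages(estimate_shifts(compute_annual_centroids(cur),
                                         region = "sim", min_years = 8))
  expect_gt(nrow(sh), 0)
  expect_identical(sh$shift_km_per_yr, 111 * sh$shift_deg_per_yr)
})

test_that("shift estimates are equivariant under a latitude translation", {
  sv <- simulate_survey(small_config())
  cur <- curate_dataset(sv$hauls, sv$catches, sv$env,
                        region_filter_spec(min_years = 8))
  cents <- compute_annual_centroids(cur)
  shifted <- cents
  shifted$lat_c <- shifted$lat_c + 5
  shifted$survey_mean_lat <- shifted$survey_mean_lat + 5
  shifted$survey_median_lat <- shifted$survey_median_lat + 5
  sp <- cents$species[1]
  a <- estimate_shift(cents[cents$species == sp, ])
  b <- estimate_shift(shifted[shifted$species == sp, ])
  expect_equal(a$shift_km_per_yr, b$shift_km_per_yr, tolerance = 1e-6)
})

test_that("estimate_shift refuses short series and collapses gracefully", {
  cents <- tibble::tibble(
    species = "s", year = 2000:2008,
    lat_c = 60, depth_c = 100, survey_mean_lat = 60,
    survey_median_lat = 60, n_presence_hauls = 10)
  expect_error(estimate_shift(cents), ">= 10")
})

test_that("collinear survey covariates are dropped with a note", {
  years <- 2000:2014
  set.seed(3)
  cents <- tibble::tibble(
    species = "s", year = years,
    lat_c = 60 + rnorm(15, 0, 0.1),
    depth_c = runif(15, 90, 110),
    survey_mean_lat = 60 + 0.001 * (years - 2000),
    n_presence_hauls = 10)
  cents$survey_median_lat <- cents$survey_mean_lat  # exactly collinear
  est <- estimate_shift(cents)
  expect_match(est$notes, "survey_median_lat dropped")
})

test_that("pseudomedian equals the brute-force median of Walsh averages", {
  expect_equal(hodges_lehmann(c(1, 2, 3))$pseudomedian, 2)
  # hand-enumerated: {1,1,1,3,3,5} -> median 2
  expect_equal(hodges_lehmann(c(1, 1, 5))$pseudomedian, 2)
  hl_const <- hodges_lehmann(rep(4.2, 6))
  expect_equal(hl_const$pseudomedian, 4.2)
  expect_equal(hl_const$ci_low, 4.2)
  expect_equal(hl_const$ci_high, 4.2)

  brute <- function(x) {
    w <- c()
    for (i in seq_along(x)) for (j in i:length(x)) w <- c(w, (x[i] + x[j]) / 2)
    median(w)
  }
  set.seed(11)
  for (i in 1:50) {
    x <- rnorm(sample(3:12, 1), sd = sample(1:5, 1))
    expect_equal(hodges_lehmann(x)$pseudomedian, brute(x), tolerance = 1e-12)
  }
  expect_error(hodges_lehmann(c(1, 2)), "at least 3")
})

test_that("pseudomedian and CI agree with the signed-rank test implementation", {
  set.seed(21)
  for (n in c(8, 15, 40)) {
    x <- rnorm(n, 1)
    hl <- hodges_lehmann(x)
    wt <- wilcox.test(x, conf.int = TRUE, exact = (n <= 25))
    expect_equal(hl$pseudomedian, unname(wt$estimate), tolerance = 1e-3)
    expect_equal(hl$ci_low, wt$conf.int[1], tolerance = 0.15)
    expect_equal(hl$ci_high, wt$conf.int[2], tolerance = 0.15)
  }
})

test_that("community test gates on normality and handles symmetric and constant input", {
  mk <- function(v) tibble::tibble(
    region = "r", species = paste0("s", seq_along(v)),
    shift_km_per_yr = v, significant = FALSE)

  sym <- community_shift_test(mk(c(-2, -1, 0, 1, 2)))
  expect_equal(sym$central_estimate, 0, tolerance = 1e-10)
  expect_gt(sym$p_value, 0.9)

  # heavy outlier breaks normality -> wilcoxon branch
  heavy <- community_shift_test(mk(c(rnorm(20, 0, 0.1), 50)))
  expect_equal(heavy$test_used, "wilcoxon")

  # near-constant positive shifts: signed-rank all one-sided
  pos <- community_shift_test(mk(1.6 + seq(-0.01, 0.01, length.out = 12)))
  expect_equal(pos$central_estimate, 1.6, tolerance = 0.02)
  expect_lt(pos$p_value, 0.05)

  expect_warning(const <- community_shift_test(mk(rep(1.5, 5))), "zero variance")
  expect_equal(const$central_estimate, 1.5)
  expect_equal(const$test_used, "none")
})

test_that("normal data take the t-test branch with a t-interval", {
  set.seed(5)
  sh <- tibble::tibble(region = "r", species = paste0("s", 1:30),
                       shift_km_per_yr = rnorm(30, 1), significant = FALSE)
  cs <- community_shift_test(sh)
  expect_equal(cs$test_used, "t-test")
  tt <- t.test(sh$shift_km_per_yr)
  expect_equal(cs$central_estimate, unname(tt$estimate))
  expect_equal(cs$ci_low, tt$conf.int[1])
  expect_equal(cs$p_value, tt$p.value)
})
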