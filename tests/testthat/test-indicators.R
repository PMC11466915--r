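test_that("biomass penalty follows the proportional-loss formula", {
  expect_equal(biomass_penalty(rep(100, 5), rep(38, 5)), 0.62)
  expect_equal(biomass_penalty(c(90, 110), c(100, 100)), 0)
  expect_equal(biomass_penalty(100, 110), -0.10)       # drought outgrew control
  expect_lte(biomass_penalty(100, 0), 1)               # penalty is capped at 1
  expect_warning(p <- biomass_penalty(c(0, 0), 50), "not positive")
  expect_true(is.na(p))
})

test_that("WUE points cover drying intervals only, with the growth sign convention", {
  s <- data.frame(das = c(18, 25, 29), shoot_area = c(100, 120, 110),
                  soil_moisture = c(0.50, 0.40, 0.35))
  pts <- wue_points(s)
  expect_equal(pts$wue, c(200, -200))
  expect_equal(pts$mean_moisture, c(0.45, 0.375))
  # rewatering interval (moisture rises) is excluded
  s2 <- data.frame(das = c(18, 25, 29), shoot_area = c(100, 120, 140),
                   soil_moisture = c(0.50, 0.18, 0.60))
  expect_equal(nrow(wue_points(s2)), 1L)
  # all intervals rising -> empty with warning
  s3 <- data.frame(das = c(18, 25), shoot_area = c(100, 120),
                   soil_moisture = c(0.2, 0.6))
  expect_warning(e <- wue_points(s3), "no drying")
  expect_equal(nrow(e), 0L)
  # row order does not matter
  expect_equal(wue_points(s[c(3, 1, 2), ]), pts)
})

test_that("monotone WUE fit reproduces a linear trend and its x-intercept exactly", {
  m <- seq(0.20, 0.50, length.out = 24)
  fit <- fit_monotone_wue(x = m, y = 2000 * (m - 0.34))
  expect_lt(fit$rss, 1e-6)
  expect_true(fit$monotone_certified)
  expect_equal(fit$x_intercept$sentinel, "ok")
  expect_lt(abs(fit$x_intercept$value - 0.34), 1e-6)
  # second anchor at the low end of the observed scale
  m2 <- seq(0.15, 0.45, length.out = 24)
  fit2 <- fit_monotone_wue(x = m2, y = 1000 * (m2 - 0.23))
  expect_lt(abs(fit2$x_intercept$value - 0.23), 1e-6)
})

test_that("monotone WUE fit recovers the wilting moisture under noise", {
  set.seed(2024)
  m <- runif(40, 0.20, 0.50)
  y <- 2000 * (m - 0.34) + rnorm(40, 0, 50)
  fit <- fit_monotone_wue(x = m, y = y)
  expect_true(fit$monotone_certified)
  expect_lt(abs(fit$x_intercept$value - 0.34), 0.02)
})

test_that("monotone constraint dominates decreasing data and sentinels fire", {
  m <- seq(0.2, 0.5, length.out = 12)
  fit <- fit_monotone_wue(x = m, y = rev(seq_along(m)) * 10)   # decreasing
  grid <- seq(0.2, 0.5, length.out = 200)
  expect_true(all(diff(fit$predict(grid)) >= -1e-10))
  expect_true(fit$monotone_certified)

  pos <- fit_monotone_wue(x = m, y = 100 + 50 * m)   # never crosses zero
  expect_equal(pos$x_intercept$sentinel, "below_range")
  expect_true(is.na(pos$x_intercept$value))
  neg <- fit_monotone_wue(x = m, y = -100 + 50 * m - 50)
  expect_equal(neg$x_intercept$sentinel, "above_range")

  expect_error(fit_monotone_wue(x = m[1:4], y = m[1:4]), "at least 5")
  expect_error(fit_monotone_wue(x = rep(0.3, 6) + 1e-4 * (1:6), y = 1:6),
               "0.05 moisture range")
})

test_that("linear-plateau fit recovers exact parameters from its model class", {
  x <- seq(0.15, 0.55, length.out = 30)
  y <- 0.5 + 1.0 * pmin(x, 0.31)
  fit <- fit_linear_plateau(x, y)
  expect_lt(abs(fit$a - 0.5), 1e-6)
  expect_lt(abs(fit$b - 1.0), 1e-6)
  expect_lt(abs(fit$x0 - 0.31), 1e-6)
  expect_lt(fit$rss, 1e-12)
  expect_true(fit$converged)
})

test_that("linear-plateau junction is recovered within 0.02 under noise", {
  set.seed(7)
  x <- runif(40, 0.15, 0.55)
  y <- 0.5 + 1.0 * pmin(x, 0.31) + rnorm(40, 0, 0.01)
  fit <- fit_linear_plateau(x, y)
  expect_lt(abs(fit$x0 - 0.31), 0.02)
})

test_that("pure-linear data push the junction to max(x) at the plain-regression rss", {
  x <- seq(0.2, 0.5, length.out = 20)
  set.seed(3)
  y <- 1 + 2 * x + rnorm(20, 0, 0.01)
  fit <- fit_linear_plateau(x, y)
  expect_equal(fit$x0, max(x), tolerance = 1e-8)
  expect_lt(abs(fit$rss - sum(lm(y ~ x)$residuals^2)), 1e-8)
  expect_error(fit_linear_plateau(rep(0.3, 10), rnorm(10)), "degenerate")
})

test_that("plateau fit rss matches the exhaustive profiled oracle and nested fits", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(10:40, 1)
    x <- sort(runif(n, 0, 1))
    y <- runif(1, -1, 1) + runif(1, 0, 3) * pmin(x, runif(1, 0.2, 0.8)) +
      rnorm(n, 0, 0.05)
    fit <- fit_linear_plateau(x, y)
    expect_lt(abs(fit$rss - oracle_plateau_rss(x, y)) / max(fit$rss, 1e-12), 1e-6)
    rss_lin <- sum(lm(y ~ x)$residuals^2)
    rss_const <- sum((y - mean(y))^2)
    expect_lte(fit$rss, min(rss_lin, rss_const) + 1e-8)
  }
})

test_that("spectral indices follow their definitions", {
  expect_equal(rwc_index(0.2, 0.2), 1.0)
  expect_equal(rwc_index(0.3, 0.2), 1.5)
  expect_equal(rwc_index(0.6, 0.4), rwc_index(0.3, 0.2))  # scale invariant
  expect_true(is.na(rwc_index(0.3, 0)))

  expect_equal(ndvi(0.3, 0.3), 0)
  expect_equal(ndvi(0, 0.5), 1)
  expect_equal(ndvi(0.5, 0.2), -ndvi(0.2, 0.5))           # antisymmetric
  expect_true(is.na(ndvi(0, 0)))
})

test_that("breakpoint indicators recover noiseless truth exactly and flag degeneracies", {
  sim <- simulate_experiment(simulation_config(n_accessions = 3, seed = 31,
                                               area_sd = 0, moisture_sd = 0,
                                               reflectance_sd = 0))
  for (aid in sim$truth$accession_id) {
    tr <- sim$truth[sim$truth$accession_id == aid, ]
    drt <- sim$plants[sim$plants$accession_id == aid &
                        sim$plants$treatment == "drought", ]
    lo <- min(drt$soil_moisture[!drt$rewatered])
    if (tr$theta_rwc > lo + 0.02) {
      expect_equal(desiccation_moisture(drt)$value, tr$theta_rwc, tolerance = 1e-4)
    }
    if (tr$theta_ndvi > lo + 0.02) {
      expect_equal(chlorosis_moisture(drt)$value, tr$theta_ndvi, tolerance = 1e-4)
    }
  }
  # constant index series: boundary junction flagged, no crash
  flat <- data.frame(soil_moisture = seq(0.2, 0.6, length.out = 10),
                     r680 = 0.2, r800 = 0.5, r1417 = 0.25, r1528 = 0.2,
                     rewatered = FALSE)
  res <- chlorosis_moisture(flat)
  expect_true(nzchar(res$qc))
})

test_that("root/shoot ratio is the mean of per-plant ratios", {
  expect_equal(root_shoot_ratio(100, 10), 0.10)
  expect_equal(root_shoot_ratio(c(100, 100), c(10, 30)), 0.20)
  expect_warning(r <- root_shoot_ratio(c(0, 100), c(5, 20)), "excluded")
  expect_equal(r, 0.20)
  expect_warning(r2 <- root_shoot_ratio(c(0, 0), c(5, 5)), "excluded")
  expect_true(is.na(r2))
})

test_that("indicator table has one row per accession and is order invariant", {
  ind <- shared_ind_151()
  expect_identical(nrow(ind), 151L)
  expect_identical(anyDuplicated(ind$accession_id), 0L)
  ok <- function(v) all(is.na(v) | (v > 0 & v < 1))
  expect_true(ok(ind$wue_wilting_moisture[!nzchar(ind$qc_wue)]))
  expect_true(ok(ind$rwc_desiccation_moisture[!nzchar(ind$qc_rwc)]))
  expect_true(ok(ind$ndvi_chlorosis_moisture[!nzchar(ind$qc_ndvi)]))
  expect_true(all(ind$biomass_penalty <= 1, na.rm = TRUE))

  sim <- simulate_experiment(simulation_config(n_accessions = 5, seed = 17))
  base <- build_indicator_table(sim$plants, sim$accessions)
  set.seed(1)
  shuffled <- sim$plants[sample.int(nrow(sim$plants)), ]
  expect_equal(build_indicator_table(shuffled, sim$accessions), base)

  empty <- build_indicator_table(sim$plants[0, ], sim$accessions)
  expect_identical(nrow(empty), 0L)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_indicator_table(base, tsv)
  back <- read.delim(tsv)
  expect_equal(back$wue_wilting_moisture, base$wue_wilting_moisture,
               tolerance = 1e-10)
  expect_true(all(c("qc_wue", "qc_rwc") %in% names(back)))
})
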