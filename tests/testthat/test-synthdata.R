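test_that("config validation rejects inconsistent protocols", {
  expect_error(simulation_config(field_capacity = 1.2), "0,1")
  expect_error(simulation_config(rewater_threshold = 0.7), "below field_capacity")
  expect_error(simulation_config(das_schedule = c(18, 25, 25)), "increasing")
  expect_error(simulation_config(plants_per_treatment = 1), "at least 2")
  expect_error(simulation_config(area_sd = NaN), "finite")
  expect_error(simulation_config(moisture_sd = -0.1), "non-negative")
})

test_that("same seed gives byte-identical experiments", {
  cfg <- simulation_config(n_accessions = 4, seed = 11)
  expect_identical(simulate_experiment(cfg), simulate_experiment(cfg))
})

test_that("drought moisture decays monotonically and controls hold field capacity", {
  cfg <- simulation_config(n_accessions = 6, seed = 3)
  sim <- simulate_experiment(cfg)
  drt <- sim$plants[sim$plants$treatment == "drought", ]
  for (pid in unique(drt$plant_id)) {
    s <- drt[drt$plant_id == pid, ]
    s <- s[order(s$das), ]
    expect_identical(sum(s$rewatered), 1L)
    expect_true(s$rewatered[nrow(s)])               # rewatering ends the series
    pre <- s$soil_moisture[!s$rewatered]
    expect_true(all(diff(pre) < 0))                 # strictly drying
    expect_lt(pre[length(pre)], cfg$field_capacity) # stress actually developed
  }
  ctrl <- sim$plants[sim$plants$treatment == "control", ]
  expect_true(all(abs(ctrl$soil_moisture - cfg$field_capacity) <=
                    3 * cfg$moisture_sd + 1e-12))
})

test_that("noiseless generation has exact structure", {
  cfg <- simulation_config(n_accessions = 2, seed = 5, area_sd = 0,
                           moisture_sd = 0, reflectance_sd = 0)
  sim <- simulate_experiment(cfg)
  for (aid in sim$truth$accession_id) {
    tr <- sim$truth[sim$truth$accession_id == aid, ]
    drt <- sim$plants[sim$plants$accession_id == aid &
                        sim$plants$treatment == "drought", ]

    # NDVI: exact plateau at m >= theta_ndvi, strictly increasing in m below
    nd <- ndvi(drt$r680, drt$r800)
    hi <- drt$soil_moisture >= tr$theta_ndvi
    expect_equal(nd[hi], rep(0.75, sum(hi)), tolerance = 1e-12)
    lo_ord <- order(drt$soil_moisture[!hi])
    if (sum(!hi) >= 2) expect_true(all(diff(nd[!hi][lo_ord]) > 0))

    # interval WUE changes sign exactly at the true wilting moisture
    for (pid in unique(drt$plant_id)) {
      pts <- suppressWarnings(wue_points(drt[drt$plant_id == pid, ]))
      expect_true(all(pts$wue[pts$mean_moisture > tr$theta_w] > 0))
      expect_true(all(pts$wue[pts$mean_moisture < tr$theta_w] < 0))
    }
  }
})

test_that("reflectances are clipped into [0,1] and NDVI into [-1,1]", {
  sim <- simulate_experiment(simulation_config(n_accessions = 3, seed = 9,
                                               reflectance_sd = 0.2))
  p <- sim$plants
  for (cl in c("r1417", "r1528", "r680", "r800")) {
    expect_true(all(p[[cl]] >= 0 & p[[cl]] <= 1))
  }
  expect_gt(sum(sim$clipping$n_clipped), 0)   # heavy noise must be logged
  nd <- ndvi(p$r680, p$r800)
  expect_true(all(is.na(nd) | (nd >= -1 & nd <= 1)))
})

test_that("latent resistance couples to annual precipitation as configured", {
  cfg <- simulation_config(n_accessions = 400, plants_per_treatment = 2,
                           seed = 61)
  sim <- simulate_experiment(cfg)
  m <- merge(sim$truth, sim$climate, by = "accession_id")
  expect_gte(nrow(m), 100)
  expect_lt(abs(cor(m$latent_resistance, m$annual_precipitation) -
                  cfg$climate_coupling), 0.1)
})

test_that("adding accessions leaves earlier accessions unchanged", {
  s5 <- simulate_experiment(simulation_config(n_accessions = 5, seed = 21))
  s8 <- simulate_experiment(simulation_config(n_accessions = 8, seed = 21))
  first5 <- s8$plants[s8$plants$accession_id %in% s5$plants$accession_id, ]
  expect_equal(as.data.frame(first5), as.data.frame(s5$plants))
  expect_equal(as.data.frame(s8$truth[1:5, ]), as.data.frame(s5$truth))
})

test_that("silhouette rendering conserves pixel count across shapes", {
  r1 <- render_plant_silhouette(100, calibration = 1, shape_seed = 1)
  expect_identical(r1$pixel_count, 100L)
  r2 <- render_plant_silhouette(100, calibration = 0.25, shape_seed = 1)
  expect_identical(r2$pixel_count, 400L)     # 100 mm2 at 0.25 mm2/px
  a <- render_plant_silhouette(150, shape_seed = 2)
  b <- render_plant_silhouette(150, shape_seed = 3)
  expect_identical(a$pixel_count, b$pixel_count)
  expect_false(identical(a$mask, b$mask))
  expect_error(render_plant_silhouette(1e6, calibration = 1,
                                       canvas = c(64L, 64L)), "capacity")
})

test_that("experiment round-trips through CSV including percent moisture", {
  cfg <- simulation_config(n_accessions = 2, seed = 13)
  sim <- simulate_experiment(cfg)
  dir <- withr::local_tempdir()
  write_experiment(sim, dir, config = cfg, moisture_unit = "percent")
  back <- read_plant_table(file.path(dir, "plants.csv"), moisture_unit = "percent")
  expect_equal(back$soil_moisture, sim$plants$soil_moisture, tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "config.yaml")))
})
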