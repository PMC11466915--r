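rand_ind <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(accession_id = sprintf("A%03d", seq_len(n)),
                 biomass_penalty = rnorm(n), wue_wilting_moisture = rnorm(n),
                 rwc_desiccation_moisture = rnorm(n),
                 ndvi_chlorosis_moisture = rnorm(n), root_shoot_ratio = rnorm(n))
}

rand_clim <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(accession_id = sprintf("A%03d", seq_len(n)),
                 annual_mean_temperature = rnorm(n), temperature_seasonality = rnorm(n),
                 annual_precipitation = rnorm(n), precipitation_seasonality = rnorm(n),
                 isothermality = rnorm(n))
}

test_that("Manhattan distances are a metric on the indicator rows", {
  ind <- rand_ind(3, 1)
  ind[2, -1] <- ind[1, -1]
  d <- manhattan_distances(ind)
  expect_equal(d[1, 2], 0)
  ind2 <- rand_ind(2, 1)
  ind2[1, -1] <- as.list(rep(0, 5)); ind2[2, -1] <- as.list(rep(1, 5))
  expect_equal(manhattan_distances(ind2)[1, 2], 5)
  d100 <- manhattan_distances(rand_ind(100, 2))
  for (trip in list(c(1, 2, 3), c(10, 40, 70), c(5, 50, 95))) {
    expect_lte(d100[trip[1], trip[3]],
               d100[trip[1], trip[2]] + d100[trip[2], trip[3]] + 1e-12)
  }
  ind3 <- rand_ind(5, 3); ind3$root_shoot_ratio[2] <- NA
  expect_warning(d3 <- manhattan_distances(ind3), "dropped")
  expect_identical(nrow(d3), 4L)
})

test_that("Ward clustering equals brute-force agglomeration on 8-point instances", {
  for (seed in 1:20) {
    ind <- rand_ind(8, seed + 100)
    d <- manhattan_distances(ind)
    hc <- ward_cluster(d)
    oracle <- oracle_ward(d)
    expect_equal(hc$height, oracle$heights, tolerance = 1e-9)
    for (k in 2:7) {
      expect_true(same_partition(cutree(hc, k),
                                 oracle$partitions[[8 - k]]))
    }
    expect_true(all(diff(hc$height) >= -1e-12))   # monotone linkage
  }
  expect_error(ward_cluster(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("small Ward examples merge as expected", {
  ind <- rand_ind(3, 1)
  ind[1, -1] <- as.list(c(0, 0, 0, 0, 0))
  ind[2, -1] <- as.list(c(1, 0, 0, 0, 0))
  ind[3, -1] <- as.list(c(10, 0, 0, 0, 0))
  hc <- ward_cluster(manhattan_distances(ind))
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))    # closest pair first
  two <- rand_ind(2, 2)
  hc2 <- ward_cluster(manhattan_distances(two))
  expect_equal(hc2$height, manhattan_distances(two)[1, 2])
})

test_that("tree cuts nest and cover the k extremes", {
  ind <- rand_ind(30, 5)
  hc <- ward_cluster(manhattan_distances(ind))
  expect_equal(unname(cut_tree(hc, 1)), rep(1L, 30))
  expect_equal(sort(unname(cut_tree(hc, 30))), 1:30)
  for (k in 3:8) {
    fine <- cut_tree(hc, k); coarse <- cut_tree(hc, k - 1)
    tab <- table(fine, coarse)
    expect_true(all(rowSums(tab > 0) == 1))       # each fine cluster in one coarse
  }
  expect_error(cut_tree(hc, 31), "1..n")
})

test_that("cutting the 151-accession tree at five gives five populated clusters", {
  ind <- shared_ind_151()
  cl <- cut_tree(ward_cluster(manhattan_distances(suppressWarnings(ind))), 5)
  expect_identical(sort(unique(unname(cl))), 1:5)
  expect_true(all(table(cl) >= 1))
})

test_that("WSS scree is non-increasing and vanishes at k = n", {
  ind <- rand_ind(25, 8)
  sc <- wss_scree(ind, 1:25)
  expect_true(all(diff(sc$wss) <= 1e-10))
  expect_equal(sc$wss[sc$k == 25], 0)
})

test_that("archetype-structured data show their strongest WSS drop by k = 5", {
  sim <- simulate_experiment(simulation_config(n_accessions = 60, seed = 77,
                                               n_archetypes = 5))
  ind <- build_indicator_table(sim$plants, sim$accessions)
  sc <- wss_scree(suppressWarnings(ind), 1:10)
  drops <- -diff(sc$wss) / sc$wss[-nrow(sc)]
  expect_lte(sc$k[which.max(drops)] + 1L, 5L)
})

test_that("covariance PCA reconstructs, explains, and flags Kaiser components", {
  ind <- rand_ind(40, 9)
  ind$wue_wilting_moisture <- 2 * ind$biomass_penalty   # collinear pair
  ind$rwc_desiccation_moisture <- 0.5
  ind$ndvi_chlorosis_moisture <- 0.5
  ind$root_shoot_ratio <- 0.5
  pc <- pca_indicators(ind)
  expect_equal(pc$variance_fraction[1], 1.0, tolerance = 1e-12)

  ind2 <- rand_ind(50, 10)
  pc2 <- pca_indicators(ind2)
  expect_equal(sum(pc2$variance_fraction), 1.0, tolerance = 1e-12)
  recon <- pc2$scores %*% t(pc2$loadings)
  centred <- scale(as.matrix(ind2[, -1]), center = TRUE, scale = FALSE)
  expect_lt(max(abs(recon - centred)), 1e-10)
  gram <- crossprod(pc2$scores)
  expect_lt(max(abs(gram - diag(diag(gram)))), 1e-8)    # orthogonal scores

  set.seed(11)
  iso <- rand_ind(500, 12)
  frac <- pca_indicators(iso)$variance_fraction
  expect_true(all(frac > 0.14 & frac < 0.26))           # isotropic Gaussian
})

test_that("RDA matches vegan on eigenvalues and adjusted R2", {
  skip_if_not_installed("vegan")
  ind <- rand_ind(60, 21)
  clim <- rand_clim(60, 22)
  ours <- rda_climate(ind, clim, n_perm = 49, seed = 1)
  y <- scale(as.matrix(ind[, -1]), center = TRUE, scale = FALSE)
  x <- scale(as.matrix(clim[, -1]))
  vfit <- vegan::rda(y ~ x)
  expect_equal(unname(ours$eigenvalues),
               unname(vfit$CCA$eig), tolerance = 1e-8)
  expect_equal(ours$r2, unname(vegan::RsquareAdj(vfit)$r.squared), tolerance = 1e-10)
  expect_equal(ours$adj_r2, unname(vegan::RsquareAdj(vfit)$adj.r.squared),
               tolerance = 1e-10)
})

test_that("RDA permutation p hits the add-one floor for exact linear responses", {
  n <- 40
  clim <- rand_clim(n, 31)
  xm <- as.matrix(clim[, -1])
  ind <- tibble::tibble(accession_id = clim$accession_id,
                        biomass_penalty = drop(xm %*% c(1, 0, 0.5, 0, 0)),
                        wue_wilting_moisture = drop(xm %*% c(0, 1, 0, 0, 0)),
                        rwc_desiccation_moisture = drop(xm %*% c(0, 0, 1, 1, 0)),
                        ndvi_chlorosis_moisture = drop(xm %*% c(0.2, 0, 0, 0, 1)),
                        root_shoot_ratio = drop(xm %*% c(0, 0.3, 0, 0.7, 0)))
  res <- rda_climate(ind, clim, n_perm = 199, seed = 5)
  expect_equal(res$r2, 1, tolerance = 1e-10)
  expect_equal(res$p_model, 1 / 200)
})

test_that("RDA R2 is invariant to invertible reparameterisation of climate", {
  ind <- rand_ind(45, 41)
  clim <- rand_clim(45, 42)
  base <- rda_climate(ind, clim, n_perm = 9, seed = 1,
                      standardize_climate = FALSE)
  xm <- as.matrix(clim[, -1])
  set.seed(43)
  tm <- matrix(rnorm(25), 5, 5) + diag(5)
  clim2 <- clim
  clim2[, -1] <- as.data.frame(xm %*% tm)
  names(clim2) <- names(clim)
  re <- rda_climate(ind, clim2, n_perm = 9, seed = 1,
                    standardize_climate = FALSE)
  expect_equal(re$r2, base$r2, tolerance = 1e-10)
})

test_that("indicator-climate Pearson table matches its definition and star code", {
  ind <- rand_ind(30, 51)
  clim <- rand_clim(30, 52)
  clim$annual_precipitation <- ind$biomass_penalty          # r = 1
  clim$isothermality <- -ind$root_shoot_ratio               # r = -1
  ct <- indicator_climate_correlations(ind, clim)
  expect_equal(ct$r["biomass_penalty", "annual_precipitation"], 1)
  expect_equal(ct$r["root_shoot_ratio", "isothermality"], -1)
  expect_equal(ct$stars["biomass_penalty", "annual_precipitation"], "**")
  # null columns: correlations stay small at n = 118
  ind2 <- rand_ind(118, 53); clim2 <- rand_clim(118, 54)
  ct2 <- indicator_climate_correlations(ind2, clim2)
  expect_gte(mean(abs(ct2$r) < 0.3), 0.95)
})

test_that("generator climate coupling reaches the ordination and correlations", {
  sim <- shared_sim_151()
  ind <- shared_ind_151()
  res <- rda_climate(suppressWarnings(ind), sim$climate, n_perm = 99, seed = 3)
  # penalty dominates the unscaled indicator covariance, so the first
  # constrained axis must pair it with annual precipitation
  precip <- res$climate_scores["annual_precipitation", 1]
  expect_identical(sign(res$loadings["biomass_penalty", 1]), sign(precip))
  expect_lt(res$p_model, 0.05)
  # penalty/wilting/desiccation indicators all rise with site precipitation
  ct <- indicator_climate_correlations(ind, sim$climate)
  expect_true(all(ct$r[c("biomass_penalty", "wue_wilting_moisture",
                         "rwc_desiccation_moisture"),
                       "annual_precipitation"] > 0))
})
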