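#' Configuration for a synthetic drought-phenotyping experiment
#'
#' Builds and validates the configuration of the synthetic experiment
#' generator. The defaults emulate the stop-watering drought protocol of a
#' high-throughput bean phenotyping screen: pots watered to field capacity
#' (volumetric soil moisture ~0.60), watering stopped so that moisture decays
#' until it falls below a rewatering threshold (0.20), one post-rewatering
#' recovery measurement, and imaging on a fixed days-after-sowing (DAS)
#' schedule.
#'
#' @param n_accessions number of accessions to simulate.
#' @param plants_per_treatment plants per accession in each arm (control and
#'   drought); the platform default is 5.
#' @param das_schedule strictly increasing integer measurement days
#'   (days after sowing).
#' @param field_capacity volumetric soil-moisture fraction at field capacity.
#' @param rewater_threshold moisture fraction below which a drought pot is
#'   rewatered; must be below `field_capacity`.
#' @param area_sd relative (lognormal) measurement noise on projected areas.
#' @param moisture_sd absolute noise scale for soil moisture. Controls get
#'   additive truncated-Gaussian noise around field capacity; drought pots
#'   get an equivalent lognormal jitter on the daily decay rate so their
#'   series stay physically non-increasing between rewaterings.
#' @param reflectance_sd absolute Gaussian noise on each reflectance band.
#' @param climate_coupling target Pearson correlation between the latent
#'   drought-resistance score and annual precipitation at the collection
#'   site. Negative by default: resistant accessions originate from arid
#'   sites, so the indicators (which all decrease with resistance) come out
#'   positively related to precipitation.
#' @param n_archetypes 0 for continuous variation in drought response;
#'   k in 1..5 superimposes k well-separated response archetypes (used to
#'   exercise the cluster analyses).
#' @param seed integer seed; the same seed yields byte-identical output.
#'   Per-accession substreams are derived from it, so increasing
#'   `n_accessions` leaves earlier accessions unchanged.
#'
#' @return a validated list of class `"sim_config"`.
#' @export
simulation_config <- function(n_accessions = 151,
                              plants_per_treatment = 5,
                              das_schedule = c(18L, 25L, 29L, 33L, 36L, 39L, 43L, 46L),
                              field_capacity = 0.60,
                              rewater_threshold = 0.20,
                              area_sd = 0.05,
                              moisture_sd = 0.01,
                              reflectance_sd = 0.005,
                              climate_coupling = -0.45,
                              n_archetypes = 0,
                              seed = 1L) {
  cfg <- list(
    n_accessions = as.integer(n_accessions),
    plants_per_treatment = as.integer(plants_per_treatment),
    das_schedule = as.integer(das_schedule),
    field_capacity = field_capacity,
    rewater_threshold = rewater_threshold,
    area_sd = area_sd,
    moisture_sd = moisture_sd,
    reflectance_sd = reflectance_sd,
    climate_coupling = climate_coupling,
    n_archetypes = as.integer(n_archetypes),
    seed = as.integer(seed)
  )
  num <- unlist(cfg[c("field_capacity", "rewater_threshold", "area_sd",
                      "moisture_sd", "reflectance_sd", "climate_coupling")])
  assert_that(all(is.finite(num)), "all numeric config values must be finite")
  assert_that(all(is.finite(cfg$das_schedule)) && length(cfg$das_schedule) >= 2,
              "das_schedule must hold at least two finite days")
  assert_that(all(diff(cfg$das_schedule) > 0),
              "das_schedule must be strictly increasing")
  assert_that(cfg$field_capacity > 0 && cfg$field_capacity < 1,
              "field_capacity must lie in (0,1)")
  assert_that(cfg$rewater_threshold > 0 && cfg$rewater_threshold < 1,
              "rewater_threshold must lie in (0,1)")
  assert_that(cfg$rewater_threshold < cfg$field_capacity,
              "rewater_threshold must be below field_capacity")
  assert_that(cfg$plants_per_treatment >= 2,
              "plants_per_treatment must be at least 2")
  assert_that(cfg$n_accessions >= 1, "n_accessions must be at least 1")
  assert_that(all(c(cfg$area_sd, cfg$moisture_sd, cfg$reflectance_sd) >= 0),
              "noise standard deviations must be non-negative")
  assert_that(abs(cfg$climate_coupling) <= 1,
              "climate_coupling must lie in [-1,1]")
  assert_that(cfg$n_archetypes >= 0 && cfg$n_archetypes <= 5,
              "n_archetypes must lie in 0..5")
  class(cfg) <- "sim_config"
  cfg
}

# Subgenus pool (labels from the Phaseolinae subtribe) with uneven sampling
# weights so that small subgenera (<= 3 accessions) occur and exercise the
# group-dropping rule of the variance-component analysis.
.subgenus_pool <- data.frame(
  subgenus = c("Vigna", "Ceratotropis", "Plectotropis", "Haydonia",
               "Lasiospron", "Sigmoidotropis", "Condylostylis", "Phaseolus",
               "Macroptilium", "Strophostyles", "Ramirezella", "Oxyrhynchus"),
  genus = c("Vigna", "Vigna", "Vigna", "Vigna",
            "Vigna", "Vigna", "Condylostylis", "Phaseolus",
            "Macroptilium", "Strophostyles", "Ramirezella", "Oxyrhynchus"),
  weight = c(30, 18, 12, 6, 4, 8, 3, 22, 2, 2, 1, 1),
  stringsAsFactors = FALSE
)

# Archetype shifts on (logit penalty, theta_w, theta_rwc, theta_ndvi, log root/shoot),
# loosely mirroring the five response profiles seen in real screens.
.archetype_offsets <- rbind(
  c( 1.6,  0.00,  0.00,  0.00,  0.0),  # big biomass penalty
  c( 1.6,  0.00,  0.00,  0.00,  0.9),  # big penalty despite high root/shoot
  c( 0.0,  0.00,  0.12,  0.14,  0.0),  # photosynthetic response (RWC + NDVI)
  c(-0.8, -0.07, -0.10,  0.00,  0.0),  # resistant: late wilting + desiccation
  c(-0.8,  0.09, -0.08, -0.10,  0.0)   # WUE-dominated response
)

# Per-accession RNG substreams use L'Ecuyer-CMRG parallel streams: stream 0
# carries the shared pools, stream i the i-th accession, so streams are
# mutually independent by construction and adding accessions never perturbs
# earlier ones. (Seeding many Mersenne-Twister streams from related integer
# seeds induces measurable cross-stream correlation; CMRG streams do not.)
.use_stream <- function(s) assign(".Random.seed", s, envir = globalenv())

# Deterministic logistic trajectory on the measurement grid. `g` multiplies
# the per-interval growth rate (1 for well-watered controls).
.step_area <- function(a0, r, k, das, g) {
  a <- numeric(length(das))
  a[1] <- a0
  for (j in seq_len(length(das) - 1L)) {
    dt <- das[j + 1L] - das[j]
    a[j + 1L] <- max(a[j] + r * a[j] * (1 - a[j] / k) * dt * g[j], 1e-6)
  }
  a
}

# Clip a reflectance into [0,1]; returns value and whether clipping occurred.
.clip_band <- function(x) {
  cl <- x < 0 | x > 1
  list(value = clamp(x, 0, 1), clipped = cl)
}

#' Simulate a multi-accession drought-phenotyping experiment
#'
#' Generates per-plant measurement records, accession metadata, site-of-origin
#' climate, and the generative ground truth used for parameter-recovery
#' testing. Control pots hold soil moisture near field capacity; drought pots
#' decay piecewise-exponentially with a rate proportional to
#' `1 + shoot_area / 1500` (bigger plants dry their pots faster), are
#' rewatered once moisture falls below the threshold, and carry exactly one
#' post-rewatering record flagged `rewatered`. Shoot growth is logistic with
#' the per-interval rate multiplied by
#' `g(m) = clamp((m - theta_w) / 0.12, -0.3, 1)`, so interval water-use
#' efficiency changes sign exactly at the accession's true wilting moisture
#' `theta_w`. The short-wave-infrared water index (1528/1417 nm) and NDVI
#' follow plateau-then-linear-decline curves with true breakpoints
#' `theta_rwc` and `theta_ndvi`.
#'
#' @param config a [simulation_config()] object.
#' @return list with tibbles `plants`, `accessions`, `climate`, `truth`, and a
#'   `clipping` log (one row per reflectance value clipped into \[0,1\]).
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(simulation_config, config)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    else {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
      RNGkind("default")
    }
  }, add = TRUE)

  fc <- config$field_capacity
  thr <- config$rewater_threshold
  das <- config$das_schedule
  ppt <- config$plants_per_treatment
  g_scale <- 0.12            # moisture span over which growth ramps from 0 to full
  a_ref <- 1500              # mm2 reference area in the drying-rate model
  alpha <- 0.05              # baseline daily moisture decay rate; paired with
                             # the plant-size factor this puts most threshold
                             # crossings at 29-36 DAS as on the real platform

  # shared per-indicator subgenus effects, drawn from a fixed substream so
  # the pools do not shift when accessions are added; each pool is
  # standardised to weighted mean 0 and its nominal variance, so the
  # between-subgenus variance share is what the design states rather than
  # the luck of twelve draws. Keeping subgenus structure out of the latent
  # resistance score itself leaves the climate coupling an iid construction.
  set.seed(config$seed, kind = "L'Ecuyer-CMRG")
  stream <- get(".Random.seed", globalenv())
  w <- .subgenus_pool$weight / sum(.subgenus_pool$weight)
  pool_sds <- c(pen = 0.45,   # logit-penalty scale
                w = 0.020,    # wilting moisture
                rwc = 0.035,  # desiccation moisture
                ndvi = 0.045, # chlorosis moisture
                rs = 0.25)    # log root/shoot
  # weighted Gram-Schmidt: the five pools are made mutually orthogonal
  # (and centred) under the sampling weights, then scaled to their nominal
  # sds - otherwise the twelve-level pools carry a random cluster-level
  # cross-covariance into every indicator pair that no sample size removes
  pools <- matrix(rnorm(nrow(.subgenus_pool) * 5), ncol = 5)
  for (j in 1:5) {
    b <- pools[, j] - sum(w * pools[, j])
    if (j > 1) for (l in seq_len(j - 1)) {
      b <- b - sum(w * b * pools[, l]) / sum(w * pools[, l]^2) * pools[, l]
    }
    pools[, j] <- b
  }
  pools <- sweep(pools, 2, pool_sds / sqrt(colSums(w * pools^2)), `*`)
  b_pen <- pools[, 1]; b_w <- pools[, 2]; b_rwc <- pools[, 3]
  b_ndvi <- pools[, 4]; b_rs <- pools[, 5]

  plants <- vector("list", config$n_accessions)
  acc <- vector("list", config$n_accessions)
  clim <- vector("list", config$n_accessions)
  truth <- vector("list", config$n_accessions)
  clips <- vector("list", config$n_accessions)

  for (i in seq_len(config$n_accessions)) {
    stream <- parallel::nextRNGStream(stream)
    .use_stream(stream)
    acc_id <- sprintf("ACC%04d", i)

    sg_idx <- sample.int(nrow(.subgenus_pool), 1L, prob = .subgenus_pool$weight)
    wild <- runif(1) > 0.15
    latent <- rnorm(1)
    off <- if (config$n_archetypes > 0) {
      .archetype_offsets[sample.int(config$n_archetypes, 1L), ]
    } else rep(0, 5)

    theta_lo <- max(0.14, thr * 0.5 + 1e-3)
    theta_hi <- min(0.58, fc - 1e-3)
    theta_w <- clamp(0.34 - 0.036 * latent + b_w[sg_idx] +
                       rnorm(1, 0, 0.028) + off[2], theta_lo, theta_hi)
    theta_rwc <- clamp(0.31 - 0.045 * latent + b_rwc[sg_idx] +
                         rnorm(1, 0, 0.060) + off[3], theta_lo, theta_hi)
    theta_ndvi <- clamp(0.39 - 0.050 * latent + b_ndvi[sg_idx] +
                          rnorm(1, 0, 0.080) + off[4], theta_lo, theta_hi)
    true_penalty <- clamp(stats::plogis(stats::qlogis(0.62) - 0.55 * latent + b_pen[sg_idx] +
                                          rnorm(1, 0, 0.58) + off[1]), 0, 0.999)
    temp_z <- rnorm(1)
    true_rs <- exp(log(0.075) + 0.35 * temp_z - 0.15 * latent + b_rs[sg_idx] +
                     rnorm(1, 0, 0.45) + off[5])

    # climate at the collection site (wild accessions with usable coordinates)
    has_climate <- wild && runif(1) < 0.92
    rho <- config$climate_coupling
    precip_z <- rho * latent + sqrt(max(0, 1 - rho^2)) * rnorm(1)
    climate_row <- tibble(
      accession_id = acc_id,
      annual_mean_temperature = 21 + 4 * temp_z,
      temperature_seasonality = exp(log(2200) + 0.5 * (-0.4 * precip_z + 0.92 * rnorm(1))),
      annual_precipitation = max(50, 1300 + 620 * precip_z),
      precipitation_seasonality = clamp(65 + 25 * (-0.3 * precip_z + 0.95 * rnorm(1)), 5, 150),
      isothermality = clamp(60 + 13 * (0.3 * precip_z - 0.25 * temp_z + 0.92 * rnorm(1)), 5, 95)
    )

    # accession-level growth parameters and deterministic control trajectory
    k_cap <- rlnorm(1, log(2800), 0.35)
    r_gr <- rlnorm(1, log(0.22), 0.15)
    a0 <- rlnorm(1, log(110), 0.20)
    ctrl_ref <- .step_area(a0, r_gr, k_cap, das, rep(1, length(das) - 1L))

    n_clip <- 0L
    rec <- list()

    make_bands <- function(m) {
      rwc_t <- 0.85 - 1.20 * pmax(0, theta_rwc - m)
      ndvi_t <- 0.75 - 1.50 * pmax(0, theta_ndvi - m)
      r1417 <- 0.25 + rnorm(length(m), 0, config$reflectance_sd)
      r1528 <- 0.25 * rwc_t + rnorm(length(m), 0, config$reflectance_sd)
      r800 <- 0.45 + rnorm(length(m), 0, config$reflectance_sd)
      r680 <- 0.45 * (1 - ndvi_t) / (1 + ndvi_t) + rnorm(length(m), 0, config$reflectance_sd)
      bands <- lapply(list(r1417 = r1417, r1528 = r1528, r680 = r680, r800 = r800), .clip_band)
      n_clip <<- n_clip + sum(vapply(bands, function(b) sum(b$clipped), integer(1)))
      lapply(bands, `[[`, "value")
    }

    for (p in seq_len(ppt)) {           # control plants: full schedule
      pid <- sprintf("%s_C%02d", acc_id, p)
      eta <- rnorm(1, 0, 0.08)
      m <- fc + clamp(rnorm(length(das), 0, config$moisture_sd),
                      -3 * config$moisture_sd, 3 * config$moisture_sd)
      m <- clamp(m, 0.01, 0.99)
      a_obs <- ctrl_ref * exp(eta + rnorm(length(das), 0, config$area_sd))
      b <- make_bands(m)
      rec[[length(rec) + 1L]] <- tibble(
        plant_id = pid, accession_id = acc_id, treatment = "control",
        das = das, shoot_area = a_obs,
        root_area = true_rs * a_obs * exp(rnorm(length(das), 0, 1.5 * config$area_sd)),
        soil_moisture = m, r1417 = b$r1417, r1528 = b$r1528,
        r680 = b$r680, r800 = b$r800, rewatered = FALSE
      )
    }

    for (p in seq_len(ppt)) {           # drought plants: decay then rewater once
      pid <- sprintf("%s_D%02d", acc_id, p)
      alpha_p <- alpha * exp(rnorm(1, 0, 0.15))
      eta <- rnorm(1, 0, 0.08)
      a_true <- a0 * exp(eta)

      # daily moisture path; growth stepped on the measurement grid
      m_meas <- numeric(length(das))
      a_path <- numeric(length(das))
      m_meas[1] <- fc
      a_path[1] <- a_true
      cross_idx <- NA_integer_
      m_day <- fc
      for (j in seq_len(length(das) - 2L)) {
        for (d in seq_len(das[j + 1L] - das[j])) {
          jit <- if (config$moisture_sd > 0) exp(rnorm(1, 0, 10 * config$moisture_sd)) else 1
          rate <- alpha_p * (1 + a_path[j] / a_ref) * jit
          m_day <- max(m_day * exp(-rate), 0.02)
        }
        m_meas[j + 1L] <- m_day
        g <- clamp(((m_meas[j] + m_meas[j + 1L]) / 2 - theta_w) / g_scale, -0.3, 1)
        a_path[j + 1L] <- max(a_path[j] + r_gr * a_path[j] * (1 - a_path[j] / k_cap) * dtw(das, j) * g, 1e-6)
        if (m_meas[j + 1L] < thr) { cross_idx <- j + 1L; break }
      }
      if (is.na(cross_idx)) cross_idx <- length(das) - 1L  # end-of-run rewatering
      final_idx <- min(cross_idx + 1L, length(das))

      idx <- seq_len(cross_idx)
      m_out <- m_meas[idx]
      a_out <- a_path[idx] * exp(rnorm(length(idx), 0, config$area_sd))
      das_out <- das[idx]
      rewat <- rep(FALSE, length(idx))

      # post-rewatering recovery record; area encodes the accession's true
      # biomass penalty relative to the deterministic control trajectory
      m_re <- clamp(fc + clamp(rnorm(1, 0, config$moisture_sd),
                               -3 * config$moisture_sd, 3 * config$moisture_sd), 0.01, 0.99)
      a_re <- ctrl_ref[final_idx] * (1 - true_penalty) * exp(rnorm(1, 0, config$area_sd))
      m_out <- c(m_out, m_re)
      a_out <- c(a_out, a_re)
      das_out <- c(das_out, das[final_idx])
      rewat <- c(rewat, TRUE)

      b <- make_bands(m_out)
      rec[[length(rec) + 1L]] <- tibble(
        plant_id = pid, accession_id = acc_id, treatment = "drought",
        das = das_out, shoot_area = a_out,
        root_area = true_rs * a_out * exp(rnorm(length(a_out), 0, 1.5 * config$area_sd)),
        soil_moisture = m_out, r1417 = b$r1417, r1528 = b$r1528,
        r680 = b$r680, r800 = b$r800, rewatered = rewat
      )
    }

    plants[[i]] <- do.call(rbind, rec)
    acc[[i]] <- tibble(
      accession_id = acc_id,
      genus = .subgenus_pool$genus[sg_idx],
      subgenus = .subgenus_pool$subgenus[sg_idx],
      species = sprintf("%s_sp%02d", tolower(.subgenus_pool$genus[sg_idx]),
                        sample.int(12, 1L)),
      status = if (wild) "wild" else "cultivated"
    )
    clim[[i]] <- if (has_climate) climate_row else NULL
    truth[[i]] <- tibble(
      accession_id = acc_id, theta_w = theta_w, theta_rwc = theta_rwc,
      theta_ndvi = theta_ndvi, true_penalty = true_penalty,
      true_root_shoot = true_rs, latent_resistance = latent,
      subgenus = .subgenus_pool$subgenus[sg_idx],
      status = if (wild) "wild" else "cultivated"
    )
    clips[[i]] <- tibble(accession_id = acc_id, n_clipped = n_clip)
  }

  list(
    plants = as_tibble(do.call(rbind, plants)),
    accessions = as_tibble(do.call(rbind, acc)),
    climate = as_tibble(do.call(rbind, clim[!vapply(clim, is.null, logical(1))])),
    truth = as_tibble(do.call(rbind, truth)),
    clipping = as_tibble(do.call(rbind, clips))
  )
}

# interval length helper kept separate for readability of the stepping loop
dtw <- function(das, j) das[j + 1L] - das[j]

#' Render a synthetic plant silhouette raster
#'
#' Grows a connected, compact green blob of exactly
#' `round(target_area / calibration)` pixels on a desaturated background.
#' Used as ground-truth fixture for the segmentation module.
#'
#' @param target_area target projected area in mm2.
#' @param calibration mm2 per pixel.
#' @param shape_seed seed controlling the blob shape only; different seeds
#'   give different masks with identical pixel counts.
#' @param canvas height/width of the canvas in pixels.
#' @return list with `image` (H x W x 3 array in \[0,1\]), `mask`, and
#'   `pixel_count`.
#' @export
render_plant_silhouette <- function(target_area, calibration = 1, shape_seed = 1,
                                    canvas = c(96L, 96L)) {
  assert_that(is.finite(target_area) && target_area > 0, "target_area must be > 0")
  assert_that(is.finite(calibration) && calibration > 0, "calibration must be > 0")
  n_px <- max(1L, as.integer(round(target_area / calibration)))
  h <- canvas[1]; w <- canvas[2]
  if (n_px > floor(0.5 * h * w)) {
    stop("target_area exceeds canvas capacity", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(shape_seed))

  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  # compactness key: distance to centre plus seeded roughness
  key <- sqrt((rr - cy)^2 + (cc - cx)^2) + matrix(runif(h * w, 0, 1.5), h, w)

  mask <- matrix(FALSE, h, w)
  in_frontier <- matrix(FALSE, h, w)
  start <- c(round(cy), round(cx))
  frontier <- matrix(start, 1, 2)
  in_frontier[start[1], start[2]] <- TRUE
  for (step in seq_len(n_px)) {
    ks <- key[frontier[, 1] + (frontier[, 2] - 1L) * h]
    pick <- which.min(ks)
    py <- frontier[pick, 1]; px <- frontier[pick, 2]
    frontier <- frontier[-pick, , drop = FALSE]
    mask[py, px] <- TRUE
    for (nb in list(c(py - 1L, px), c(py + 1L, px), c(py, px - 1L), c(py, px + 1L))) {
      if (nb[1] >= 1 && nb[1] <= h && nb[2] >= 1 && nb[2] <= w &&
          !mask[nb[1], nb[2]] && !in_frontier[nb[1], nb[2]]) {
        frontier <- rbind(frontier, nb)
        in_frontier[nb[1], nb[2]] <- TRUE
      }
    }
  }

  img <- array(0, dim = c(h, w, 3))
  bg <- c(0.82, 0.82, 0.86); fg <- c(0.20, 0.65, 0.25)
  for (ch in 1:3) {
    plane <- matrix(bg[ch], h, w)
    plane[mask] <- fg[ch]
    img[, , ch] <- plane
  }
  list(image = img, mask = mask, pixel_count = n_px)
}

#' Render a synthetic calibration plate raster
#'
#' Draws a bright rectangular plate of exactly `plate_px` pixels on a dark
#' background, for testing pixel-to-area calibration.
#'
#' @param plate_px number of plate pixels.
#' @param canvas canvas height/width in pixels.
#' @return list with `image` and `pixel_count`.
#' @export
render_calibration_plate <- function(plate_px, canvas = c(128L, 128L)) {
  h <- canvas[1]; w <- canvas[2]
  assert_that(plate_px >= 1 && plate_px <= h * w, "plate_px must fit the canvas")
  side <- max(1L, floor(sqrt(plate_px)))
  mask <- matrix(FALSE, h, w)
  r0 <- max(1L, floor((h - side) / 2)); c0 <- max(1L, floor((w - side) / 2))
  full_rows <- plate_px %/% side
  rest <- plate_px %% side
  for (r in seq_len(full_rows)) mask[r0 + r - 1L, c0:(c0 + side - 1L)] <- TRUE
  if (rest > 0) mask[r0 + full_rows, c0:(c0 + rest - 1L)] <- TRUE
  img <- array(0.08, dim = c(h, w, 3))
  for (ch in 1:3) {
    plane <- img[, , ch]; plane[mask] <- 0.95; img[, , ch] <- plane
  }
  list(image = img, pixel_count = as.integer(plate_px))
}

#' Render a synthetic pot-bottom root raster
#'
#' Draws a gray pot disc on a dark background and paints dark root strands
#' (seeded random walks from the disc centre) until exactly `n_px` root
#' pixels are set. Used as ground truth for the root segmentation.
#'
#' @param n_px number of root pixels to paint.
#' @param seed shape seed.
#' @param size canvas side length in pixels.
#' @return list with `image`, root `mask`, `pixel_count`, and the disc
#'   parameters (`centre`, `radius`).
#' @export
render_root_fixture <- function(n_px = 250L, seed = 1L, size = 128L) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  ctr <- (size + 1) / 2
  radius <- floor(0.42 * size)
  rr <- matrix(seq_len(size), size, size)
  cc <- matrix(seq_len(size), size, size, byrow = TRUE)
  disc <- (rr - ctr)^2 + (cc - ctr)^2 <= radius^2
  assert_that(n_px <= sum(disc) / 3, "n_px too large for the pot disc")

  mask <- matrix(FALSE, size, size)
  painted <- 0L
  while (painted < n_px) {
    ang <- runif(1, 0, 2 * pi)
    y <- ctr + runif(1, -3, 3); x <- ctr + runif(1, -3, 3)
    while (painted < n_px) {
      ang <- ang + rnorm(1, 0, 0.35)
      y <- y + sin(ang); x <- x + cos(ang)
      iy <- round(y); ix <- round(x)
      if ((iy - ctr)^2 + (ix - ctr)^2 > (radius - 6)^2) break
      if (!mask[iy, ix]) {
        mask[iy, ix] <- TRUE
        painted <- painted + 1L
      }
    }
  }
  gray <- matrix(0.05, size, size)
  gray[disc] <- 0.45
  gray[mask] <- 0.15
  img <- array(rep(gray, 3), dim = c(size, size, 3))
  list(image = img, mask = mask, pixel_count = as.integer(n_px),
       centre = c(ctr, ctr), radius = radius)
}

#' Write a simulated experiment to CSV files
#'
#' Writes `plants.csv`, `accessions.csv`, `climate.csv`, `truth.csv` and the
#' generator configuration (`config.yaml`) into `dir`. Soil moisture is
#' written as a volumetric fraction; use `moisture_unit = "percent"` to emit
#' percentages (the unit is recorded in the YAML header).
#'
#' @param sim result of [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @param config the [simulation_config()] used (stored alongside the data).
#' @param moisture_unit `"fraction"` (canonical) or `"percent"`.
#' @return invisibly, the vector of files written.
#' @export
write_experiment <- function(sim, dir, config = NULL,
                             moisture_unit = c("fraction", "percent")) {
  moisture_unit <- match.arg(moisture_unit)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  plants <- sim$plants
  if (moisture_unit == "percent") plants$soil_moisture <- plants$soil_moisture * 100
  files <- file.path(dir, c("plants.csv", "accessions.csv", "climate.csv", "truth.csv"))
  write.csv(plants, files[1], row.names = FALSE)
  write.csv(sim$accessions, files[2], row.names = FALSE)
  write.csv(sim$climate, files[3], row.names = FALSE)
  write.csv(sim$truth, files[4], row.names = FALSE)
  if (!is.null(config)) {
    cfg <- unclass(config)
    cfg$moisture_unit <- moisture_unit
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
    files <- c(files, file.path(dir, "config.yaml"))
  }
  invisible(files)
}

#' Read a plant measurement table
#'
#' Reads a plants CSV and converts soil moisture to the package's canonical
#' volumetric fraction scale.
#'
#' @param path CSV path.
#' @param moisture_unit unit used in the file: `"fraction"` or `"percent"`.
#' @return tibble of plant records with moisture as a fraction.
#' @export
read_plant_table <- function(path, moisture_unit = c("fraction", "percent")) {
  moisture_unit <- match.arg(moisture_unit)
  x <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (moisture_unit == "percent") x$soil_moisture <- x$soil_moisture / 100
  x
}
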