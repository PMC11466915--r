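#' Biomass penalty of drought relative to control
#'
#' Proportion of projected shoot area lost under drought:
#' `(mean control area - mean drought area) / mean control area`, using the
#' drought plants' post-rewatering areas and the control areas from the
#' matching measurement day. Negative when drought plants outgrew controls.
#'
#' @param control_areas projected areas (mm2) of the control arm at the
#'   matched day.
#' @param drought_areas post-rewatering projected areas of the drought arm.
#' @return unitless penalty (at most 1); `NA` with a warning when the
#'   control mean is not positive.
#' @export
biomass_penalty <- function(control_areas, drought_areas) {
  assert_that(length(control_areas) >= 1 && length(drought_areas) >= 1,
              "both arms need at least one plant")
  mc <- mean(control_areas)
  if (!is.finite(mc) || mc <= 0) {
    warning("control mean area is not positive; penalty flagged missing")
    return(NA_real_)
  }
  (mc - mean(drought_areas)) / mc
}

#' Interval water-use-efficiency points for one plant
#'
#' For each consecutive drying interval of a drought plant's time series,
#' computes `wue = (area_t2 - area_t1) / (m_t1 - m_t2)` (projected area gained
#' per unit of soil moisture consumed) at the interval's mean moisture
#' `(m_t1 + m_t2) / 2`. Intervals over which moisture rose (rewatering) are
#' excluded: the formula presumes drying. Positive values indicate growth,
#' negative values wilting.
#'
#' @param series data frame with columns `das`, `shoot_area`,
#'   `soil_moisture` for a single plant (any row order).
#' @return tibble with columns `das1`, `das2`, `mean_moisture`, `wue`; empty
#'   (with a warning) when no interval is drying.
#' @export
wue_points <- function(series) {
  assert_that(all(c("das", "shoot_area", "soil_moisture") %in% names(series)),
              "series needs das, shoot_area, soil_moisture columns")
  series <- series[order(series$das), , drop = FALSE]
  assert_that(nrow(series) >= 2, "at least 2 records are required")
  n <- nrow(series)
  m1 <- series$soil_moisture[-n]; m2 <- series$soil_moisture[-1]
  a1 <- series$shoot_area[-n]; a2 <- series$shoot_area[-1]
  drying <- is.finite(m1) & is.finite(m2) & m1 > m2
  out <- tibble(
    das1 = series$das[-n][drying], das2 = series$das[-1][drying],
    mean_moisture = (m1[drying] + m2[drying]) / 2,
    wue = (a2[drying] - a1[drying]) / (m1[drying] - m2[drying])
  )
  if (nrow(out) == 0) warning("no drying intervals; empty WUE point set")
  out
}

#' Short-wave-infrared water index (RWC proxy)
#'
#' Ratio of reflectance at 1528 nm to reflectance at 1417 nm. Water absorbs
#' strongly in this band, so the ratio tracks leaf relative water content.
#' Scale-invariant in the overall illumination level.
#'
#' @param r1528,r1417 reflectance fractions.
#' @return unitless ratio; `NA` where `r1417 <= 0`.
#' @export
rwc_index <- function(r1528, r1417) {
  out <- ifelse(is.finite(r1417) & r1417 > 0, r1528 / r1417, NA_real_)
  as.numeric(out)
}

#' Normalised difference vegetation index
#'
#' `(r800 - r680) / (r800 + r680)`: near-infrared minus red reflectance over
#' their sum; a proxy for relative chlorophyll content, in \[-1, 1\].
#'
#' @param r680 red reflectance (680 nm).
#' @param r800 near-infrared reflectance (800 nm).
#' @return index value; `NA` where the band sum is not positive.
#' @export
ndvi <- function(r680, r800) {
  s <- r680 + r800
  out <- ifelse(is.finite(s) & s > 0, (r800 - r680) / s, NA_real_)
  as.numeric(out)
}

#' Root/shoot ratio before drought onset
#'
#' Mean over plants of the per-plant ratio of projected root area to
#' projected shoot area at the first measurement day (mean of ratios, not
#' ratio of means). Plants with non-positive shoot area are excluded with a
#' warning.
#'
#' @param shoot_areas,root_areas projected areas (mm2) of the accession's
#'   plants at the first measurement day.
#' @return unitless ratio; `NA` when every plant is excluded.
#' @export
root_shoot_ratio <- function(shoot_areas, root_areas) {
  assert_that(length(shoot_areas) == length(root_areas),
              "area vectors must have equal length")
  ok <- is.finite(shoot_areas) & is.finite(root_areas) & shoot_areas > 0
  if (any(!ok)) warning(sum(!ok), " plant(s) excluded (non-positive shoot area)")
  if (!any(ok)) return(NA_real_)
  mean(root_areas[ok] / shoot_areas[ok])
}

# shared breakpoint wrapper: (moisture, index) points -> junction + QC.
# The index is expected to be flat at high moisture and to decline as pots
# dry, i.e. slope b > 0 with the plateau at high moisture; fits violating
# that orientation are flagged rather than reported. The junction is the
# moisture where the index starts dropping *significantly*, so fits whose
# plateau model does not beat a constant fit (partial F-test at alpha) are
# flagged as well: with no detectable decline the junction is meaningless
# and typically drifts into the plateau.
.breakpoint_moisture <- function(m, idx, alpha = 0.05) {
  keep <- is.finite(m) & is.finite(idx)
  m <- m[keep]; idx <- idx[keep]
  if (length(m) < 4 || length(unique(m)) < 3) {
    return(list(value = NA_real_, qc = "too_few_points"))
  }
  fit <- tryCatch(fit_linear_plateau(m, idx), error = function(e) NULL)
  if (is.null(fit)) return(list(value = NA_real_, qc = "fit_error"))
  qc <- character(0)
  if (!fit$converged) qc <- c(qc, "not_converged")
  if (fit$x0 <= min(m) + 1e-6 || fit$x0 >= max(m) - 1e-6) qc <- c(qc, "boundary_x0")
  if (fit$b <= 0) qc <- c(qc, "plateau_at_low_moisture")
  n <- length(m)
  rss_const <- sum((idx - mean(idx))^2)
  if (fit$rss <= 0 || n <= 3) {
    p_decl <- 0
  } else {
    f <- ((rss_const - fit$rss) / 2) / (fit$rss / (n - 3))
    p_decl <- stats::pf(f, 2, n - 3, lower.tail = FALSE)
  }
  if (p_decl > alpha) qc <- c(qc, "decline_not_significant")
  list(value = fit$x0, qc = paste(qc, collapse = ";"), fit = fit)
}

#' Soil moisture at leaf desiccation (RWC breakpoint)
#'
#' Pools an accession's drought-phase records (post-rewatering records
#' excluded), computes the 1528/1417 nm water index against soil moisture,
#' fits the linear-plateau model and returns the junction point: the
#' moisture at which relative water content starts dropping.
#'
#' @param records drought-arm plant records of one accession (columns
#'   `soil_moisture`, `r1528`, `r1417`, optional logical `rewatered`).
#' @return list with `value` (moisture fraction or `NA`) and `qc` (empty
#'   string when clean).
#' @export
desiccation_moisture <- function(records) {
  if ("rewatered" %in% names(records)) records <- records[!records$rewatered, , drop = FALSE]
  .breakpoint_moisture(records$soil_moisture,
                       rwc_index(records$r1528, records$r1417))[c("value", "qc")]
}

#' Soil moisture at chlorosis (NDVI breakpoint)
#'
#' As [desiccation_moisture()], but on NDVI: the junction point estimates
#' the moisture at which relative chlorophyll content starts dropping.
#'
#' @param records drought-arm plant records of one accession (columns
#'   `soil_moisture`, `r680`, `r800`, optional logical `rewatered`).
#' @return list with `value` and `qc`.
#' @export
chlorosis_moisture <- function(records) {
  if ("rewatered" %in% names(records)) records <- records[!records$rewatered, , drop = FALSE]
  .breakpoint_moisture(records$soil_moisture,
                       ndvi(records$r680, records$r800))[c("value", "qc")]
}

#' Build the per-accession indicator table
#'
#' Computes all five drought-resistance indicators for every accession in a
#' plant record table: biomass penalty (each drought plant matched to the
#' control-arm mean area on its own rewatering day), soil moisture at
#' wilting (monotone WUE fit over points pooled across the accession's
#' drought plants), soil moisture at leaf desiccation and at chlorosis
#' (linear-plateau junctions), and the root/shoot ratio at the first
#' measurement day. Indicators that cannot be computed are `NA` with a
#' reason code in the matching `qc_*` column. Output is deterministic and
#' invariant to input row order.
#'
#' @param plants plant record table (see [simulate_experiment()] for the
#'   schema).
#' @param metadata optional accession metadata joined onto the result.
#' @return tibble with one row per accession: the five indicators plus
#'   `qc_*` reason-code columns (empty string = clean).
#' @export
build_indicator_table <- function(plants, metadata = NULL) {
  cols <- c("accession_id", "biomass_penalty", "wue_wilting_moisture",
            "rwc_desiccation_moisture", "ndvi_chlorosis_moisture",
            "root_shoot_ratio", "qc_penalty", "qc_wue", "qc_rwc",
            "qc_ndvi", "qc_root_shoot")
  if (is.null(plants) || nrow(plants) == 0) {
    out <- tibble(accession_id = character(), biomass_penalty = numeric(),
                  wue_wilting_moisture = numeric(),
                  rwc_desiccation_moisture = numeric(),
                  ndvi_chlorosis_moisture = numeric(),
                  root_shoot_ratio = numeric(), qc_penalty = character(),
                  qc_wue = character(), qc_rwc = character(),
                  qc_ndvi = character(), qc_root_shoot = character())
    return(out)
  }
  plants <- plants[order(plants$accession_id, plants$plant_id, plants$das), , drop = FALSE]
  acc_ids <- sort(unique(plants$accession_id))

  rows <- lapply(acc_ids, function(aid) {
    px <- plants[plants$accession_id == aid, , drop = FALSE]
    ctrl <- px[px$treatment == "control", , drop = FALSE]
    drt <- px[px$treatment == "drought", , drop = FALSE]

    # biomass penalty: per-plant matching to the control mean on the
    # plant's own rewatering day, then averaged over drought plants
    pen <- NA_real_; qc_pen <- ""
    rew <- drt[isTRUE_vec(drt$rewatered), , drop = FALSE]
    if (nrow(drt) == 0) {
      qc_pen <- "no_drought_plants"
    } else if (nrow(rew) == 0) {
      qc_pen <- "no_rewatered_record"
    } else {
      per_plant <- vapply(seq_len(nrow(rew)), function(r) {
        cmatch <- ctrl$shoot_area[ctrl$das == rew$das[r]]
        if (length(cmatch) == 0) return(NA_real_)
        suppressWarnings(biomass_penalty(cmatch, rew$shoot_area[r]))
      }, numeric(1))
      if (all(is.na(per_plant))) qc_pen <- "no_matched_controls"
      else pen <- mean(per_plant, na.rm = TRUE)
    }

    # wilting moisture from pooled WUE points
    wue_val <- NA_real_; qc_wue <- ""
    if (nrow(drt) == 0) {
      qc_wue <- "no_drought_plants"
    } else {
      pts <- do.call(rbind, lapply(split(drt, drt$plant_id), function(s) {
        suppressWarnings(wue_points(s))
      }))
      if (is.null(pts) || nrow(pts) < 5 ||
          diff(range(pts$mean_moisture)) < 0.05) {
        qc_wue <- "too_few_points"
      } else {
        fit <- tryCatch(fit_monotone_wue(pts), error = function(e) NULL)
        if (is.null(fit)) {
          qc_wue <- "fit_error"
        } else {
          if (!fit$monotone_certified) qc_wue <- "not_monotone"
          if (fit$x_intercept$sentinel == "ok") wue_val <- fit$x_intercept$value
          else qc_wue <- paste(c(qc_wue[nzchar(qc_wue)], fit$x_intercept$sentinel),
                               collapse = ";")
        }
      }
    }

    rwc <- if (nrow(drt) > 0) desiccation_moisture(drt) else list(value = NA_real_, qc = "no_drought_plants")
    ndv <- if (nrow(drt) > 0) chlorosis_moisture(drt) else list(value = NA_real_, qc = "no_drought_plants")
    # flagged junctions are unreliable (boundary, wrong orientation, or no
    # significant decline): record them as missing with their reason code so
    # downstream complete-case analyses filter them explicitly
    if (nzchar(rwc$qc)) rwc$value <- NA_real_
    if (nzchar(ndv$qc)) ndv$value <- NA_real_

    # root/shoot at the first measurement day, both arms
    first_das <- min(px$das)
    fx <- px[px$das == first_das, , drop = FALSE]
    rs <- suppressWarnings(root_shoot_ratio(fx$shoot_area, fx$root_area))
    qc_rs <- if (is.na(rs)) "all_plants_excluded" else ""

    flag_range <- function(v, qc) {
      if (!is.na(v) && (v <= 0 || v >= 1)) paste(c(qc[nzchar(qc)], "out_of_range"), collapse = ";")
      else qc
    }
    tibble(
      accession_id = aid, biomass_penalty = pen,
      wue_wilting_moisture = wue_val,
      rwc_desiccation_moisture = rwc$value,
      ndvi_chlorosis_moisture = ndv$value,
      root_shoot_ratio = rs,
      qc_penalty = qc_pen,
      qc_wue = flag_range(wue_val, qc_wue),
      qc_rwc = flag_range(rwc$value, rwc$qc),
      qc_ndvi = flag_range(ndv$value, ndv$qc),
      qc_root_shoot = qc_rs
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(metadata)) {
    out <- merge(out, metadata, by = "accession_id", all.x = TRUE, sort = TRUE)
    out <- as_tibble(out[order(out$accession_id), , drop = FALSE])
  }
  as_tibble(out)
}

# missing-safe logical subset helper
isTRUE_vec <- function(x) !is.na(x) & x

#' Export an indicator table as tab-separated text
#'
#' Writes the per-accession indicator table, including the QC reason-code
#' columns, as a TSV file.
#'
#' @param indicators table from [build_indicator_table()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
export_indicator_table <- function(indicators, path) {
  utils::write.table(indicators, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
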