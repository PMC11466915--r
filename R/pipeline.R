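#' Validate experiment tables
#'
#' Checks referential integrity between the plant, accession and climate
#' tables, unit ranges (moisture as fraction or percent, reflectances in
#' \[0,1\], non-negative areas), per-plant schedule monotonicity, duplicate
#' records, and the one-rewatering-per-drought-plant contract. Every
#' violation is reported with its table, row and column.
#'
#' @param plants plant record table.
#' @param accessions accession metadata table.
#' @param climate climate table (optional).
#' @param moisture_unit unit the plants table uses.
#' @return tibble of violations (zero rows when clean).
#' @export
validate_tables <- function(plants, accessions = NULL, climate = NULL,
                            moisture_unit = c("fraction", "percent")) {
  moisture_unit <- match.arg(moisture_unit)
  v <- list()
  bad <- function(tab, row, col, msg) {
    v[[length(v) + 1L]] <<- tibble(table = tab, row = as.integer(row),
                                   column = col, message = msg)
  }

  m_hi <- if (moisture_unit == "fraction") 1 else 100
  i <- which(!is.finite(plants$soil_moisture) | plants$soil_moisture < 0 |
               plants$soil_moisture > m_hi)
  for (r in i) bad("plants", r, "soil_moisture",
                   sprintf("moisture %.4g outside [0, %g] for declared %s units",
                           plants$soil_moisture[r], m_hi, moisture_unit))
  for (cl in c("r1417", "r1528", "r680", "r800")) {
    if (!cl %in% names(plants)) next
    i <- which(!is.finite(plants[[cl]]) | plants[[cl]] < 0 | plants[[cl]] > 1)
    for (r in i) bad("plants", r, cl, "reflectance outside [0, 1]")
  }
  for (cl in c("shoot_area", "root_area")) {
    if (!cl %in% names(plants)) next
    i <- which(!is.finite(plants[[cl]]) | plants[[cl]] < 0)
    for (r in i) bad("plants", r, cl, "negative or non-finite area")
  }

  key <- paste(plants$plant_id, plants$das)
  dup <- which(duplicated(key))
  for (r in dup) bad("plants", r, "plant_id/das", "duplicate record")

  for (pid in unique(plants$plant_id)) {
    rows <- which(plants$plant_id == pid)
    if (is.unsorted(plants$das[rows], strictly = TRUE)) {
      bad("plants", rows[1], "das",
          sprintf("measurement days not strictly increasing for %s", pid))
    }
  }

  if ("rewatered" %in% names(plants) && "treatment" %in% names(plants)) {
    drt <- plants[plants$treatment == "drought", , drop = FALSE]
    n_rw <- tapply(drt$rewatered, drt$plant_id, sum)
    for (pid in names(n_rw)[n_rw != 1]) {
      bad("plants", which(plants$plant_id == pid)[1], "rewatered",
          sprintf("%s has %d rewatered records (expected 1)", pid, n_rw[[pid]]))
    }
  }

  if (!is.null(accessions)) {
    orphan <- which(!plants$accession_id %in% accessions$accession_id)
    for (r in orphan) bad("plants", r, "accession_id",
                          sprintf("orphan accession id %s", plants$accession_id[r]))
    if (!is.null(climate)) {
      orph <- which(!climate$accession_id %in% accessions$accession_id)
      for (r in orph) bad("climate", r, "accession_id",
                          sprintf("orphan accession id %s", climate$accession_id[r]))
    }
  }
  if (length(v) == 0) {
    return(tibble(table = character(), row = integer(), column = character(),
                  message = character()))
  }
  do.call(rbind, v)
}

# CSV with a provenance comment header; read back with comment.char = "#"
.write_table <- function(df, path, provenance) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(provenance), unlist(provenance)), con)
  write.csv(df, con, row.names = FALSE)
}

# minimal Newick export of an hclust tree (heights as branch lengths)
.hclust_newick <- function(hc) {
  lab <- if (is.null(hc$labels)) as.character(seq_along(hc$order)) else hc$labels
  node <- function(i, parent_h) {
    if (i < 0) return(sprintf("%s:%.6g", lab[-i], parent_h))
    h <- hc$height[i]
    kids <- vapply(hc$merge[i, ], node, character(1), parent_h = h / 2)
    sprintf("(%s,%s):%.6g", kids[1], kids[2], max(parent_h - h / 2, 0))
  }
  root <- nrow(hc$merge)
  paste0("(", node(hc$merge[root, 1], hc$height[root] / 2), ",",
         node(hc$merge[root, 2], hc$height[root] / 2), ");")
}

#' Run the full drought-phenotyping analysis pipeline
#'
#' Orchestrates simulate (or load) -> validate -> indicators -> descriptive /
#' correlation / variance-component statistics -> clustering and ordination,
#' writing every result table into `out_dir` with a provenance header
#' (configuration hash, seed, package version). Re-running with an identical
#' configuration is byte-identical.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   `simulate` (a list of [simulation_config()] arguments) *or* `input`
#'   (list with `plants`, `accessions`, `climate` CSV paths and optional
#'   `moisture_unit`); `out_dir`; optional `seed` (overrides the simulate
#'   seed), `n_clusters` (default 5), `k_range` (default 1:10), `n_perm`
#'   (default 999), `ward_dialect`, `run_rda` (default TRUE).
#' @return invisibly, a list with all intermediate objects and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  assert_that(!is.null(config$out_dir), "config$out_dir is required")
  n_clusters <- config$n_clusters %||% 5L
  k_range <- config$k_range %||% 1:10
  n_perm <- config$n_perm %||% 999L
  dialect <- config$ward_dialect %||% "ward.D"
  run_rda <- config$run_rda %||% TRUE

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (!is.null(config$seed)) sim_args$seed <- config$seed
    scfg <- do.call(simulation_config, sim_args)
    seed <- scfg$seed
    sim <- simulate_experiment(scfg)
    plants <- sim$plants; accessions <- sim$accessions; climate <- sim$climate
  } else {
    assert_that(!is.null(config$input), "config needs a simulate or input block")
    inp <- config$input
    for (f in c("plants", "accessions", if (run_rda) "climate")) {
      if (is.null(inp[[f]]) || !file.exists(inp[[f]])) {
        stop("input file for '", f, "' not found: ",
             if (is.null(inp[[f]])) "(not specified)" else inp[[f]], call. = FALSE)
      }
    }
    unit <- inp$moisture_unit %||% "fraction"
    plants <- read_plant_table(inp$plants, moisture_unit = unit)
    accessions <- as_tibble(read.csv(inp$accessions, stringsAsFactors = FALSE))
    climate <- if (!is.null(inp$climate) && file.exists(inp$climate)) {
      as_tibble(read.csv(inp$climate, stringsAsFactors = FALSE))
    } else NULL
    seed <- config$seed %||% 1L
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sci_cfg <- config[setdiff(names(config), c("out_dir", "verbose"))]
  prov <- list(config_hash = rlang::hash(sci_cfg), seed = seed,
               package = paste0("droughtphen ",
                                as.character(utils::packageVersion("droughtphen"))))
  wt <- function(df, name) .write_table(df, file.path(config$out_dir, name), prov)

  violations <- validate_tables(plants, accessions, climate)
  wt(violations, "validation.csv")

  indicators <- build_indicator_table(plants, metadata = accessions)
  wt(indicators, "indicator_table.csv")

  qc_cols <- grep("^qc_", names(indicators), value = TRUE)
  qc_log <- unlist(lapply(qc_cols, function(cl) {
    i <- which(nzchar(indicators[[cl]]))
    sprintf("accession %s %s: %s", indicators$accession_id[i], cl, indicators[[cl]][i])
  }))
  writeLines(c(sprintf("# %s: %s", names(prov), unlist(prov)), qc_log),
             file.path(config$out_dir, "qc_log.txt"))

  desc <- descriptive_stats(indicators)
  wt(desc, "descriptive_stats.csv")
  spear <- spearman_matrix(indicators)
  wt(cbind(tibble(indicator = rownames(spear$rho)),
           as.data.frame(round(spear$rho, 4)),
           setNames(as.data.frame(spear$stars), paste0("sig_", colnames(spear$stars)))),
     "spearman_rho.csv")

  vc_rows <- list()
  for (cl in .indicator_cols) {
    vc <- tryCatch(
      fit_heteroscedastic_mixed(indicators[[cl]], indicators$subgenus),
      error = function(e) NULL)
    if (is.null(vc)) next
    pr <- within_total_proportion(vc)
    vc_rows[[cl]] <- tibble(indicator = cl, subgenus = names(pr),
                            sigma2_between = vc$sigma2_between,
                            sigma2_within = as.numeric(vc$sigma2_within),
                            within_total_proportion = as.numeric(pr))
  }
  vc_tab <- if (length(vc_rows)) do.call(rbind, vc_rows) else
    tibble(indicator = character(), subgenus = character(),
           sigma2_between = numeric(), sigma2_within = numeric(),
           within_total_proportion = numeric())
  wt(vc_tab, "variance_proportions.csv")

  dmat <- manhattan_distances(indicators)
  tree <- ward_cluster(dmat, dialect = dialect)
  clusters <- cut_tree(tree, min(n_clusters, nrow(dmat)))
  wt(tibble(accession_id = names(clusters), cluster = as.integer(clusters)),
     "clusters.csv")
  wt(as.data.frame(cbind(tree$merge, height = tree$height)), "dendrogram_merges.csv")
  writeLines(.hclust_newick(tree), file.path(config$out_dir, "dendrogram.nwk"))
  scree <- wss_scree(indicators, k_range, dialect = dialect)
  wt(scree, "wss_scree.csv")

  pca <- pca_indicators(indicators)
  wt(cbind(tibble(accession_id = rownames(pca$scores)), as.data.frame(pca$scores)),
     "pca_scores.csv")
  wt(cbind(tibble(indicator = rownames(pca$loadings)), as.data.frame(pca$loadings)),
     "pca_loadings.csv")
  wt(tibble(component = seq_along(pca$eigenvalues),
            eigenvalue = pca$eigenvalues,
            variance_fraction = pca$variance_fraction,
            kaiser_retained = pca$kaiser_retained), "pca_summary.csv")

  rda <- NULL; climcor <- NULL
  if (run_rda && !is.null(climate) && nrow(climate) > 0) {
    rda <- rda_climate(indicators, climate, n_perm = n_perm, seed = seed + 1L)
    wt(tibble(axis = seq_along(rda$eigenvalues), eigenvalue = rda$eigenvalues,
              variance_fraction = rda$variance_fraction, p_axis = rda$p_axes,
              r2 = rda$r2, adj_r2 = rda$adj_r2, p_model = rda$p_model,
              n = rda$n, n_perm = rda$n_perm), "rda_summary.csv")
    wt(cbind(tibble(accession_id = rownames(rda$site_scores)),
             as.data.frame(rda$site_scores)), "rda_scores.csv")
    wt(cbind(tibble(variable = rownames(rda$loadings)),
             as.data.frame(rda$loadings)), "rda_loadings.csv")
    climcor <- indicator_climate_correlations(indicators, climate)
    wt(cbind(tibble(indicator = rownames(climcor$r)),
             as.data.frame(round(climcor$r, 4)),
             setNames(as.data.frame(climcor$stars), paste0("sig_", colnames(climcor$stars)))),
       "climate_correlations.csv")
  }

  invisible(list(
    out_dir = config$out_dir, provenance = prov, violations = violations,
    plants = plants, accessions = accessions, climate = climate,
    indicators = indicators, descriptives = desc, spearman = spear,
    variance_components = vc_tab, tree = tree, clusters = clusters,
    wss = scree, pca = pca, rda = rda, climate_correlations = climcor
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
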