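.climate_cols <- c("annual_mean_temperature", "temperature_seasonality",
                   "annual_precipitation", "precipitation_seasonality",
                   "isothermality")

# complete-case indicator matrix with accession ids as rownames
.indicator_matrix <- function(indicators, warn = TRUE) {
  x <- as.matrix(indicators[, .indicator_cols])
  rownames(x) <- indicators$accession_id
  ok <- stats::complete.cases(x)
  if (warn && any(!ok)) {
    warning(sum(!ok), " accession(s) dropped (missing indicators): ",
            paste(head(rownames(x)[!ok], 5), collapse = ", "),
            if (sum(!ok) > 5) ", ..." else "")
  }
  x[ok, , drop = FALSE]
}

#' Manhattan distances between accessions
#'
#' `d(i, j) = sum_k |x_ik - x_jk|` over the five indicators, on complete
#' rows only (accessions with flagged-missing indicators are dropped with a
#' warning).
#'
#' @param indicators indicator table.
#' @return symmetric distance matrix with accession ids as dimnames.
#' @export
manhattan_distances <- function(indicators) {
  x <- .indicator_matrix(indicators)
  as.matrix(dist(x, method = "manhattan"))
}

#' Ward hierarchical clustering on a precomputed distance matrix
#'
#' Agglomerative clustering with the Lance-Williams Ward update applied to
#' the given (unsquared) dissimilarities - the classic `"ward.D"` dialect,
#' which is the historical behaviour of clustering a precomputed Manhattan
#' matrix. The squared-dissimilarity variant (`"ward.D2"`) is available
#' behind the `dialect` flag.
#'
#' @param d symmetric distance matrix or `dist` object.
#' @param dialect `"ward.D"` (default) or `"ward.D2"`.
#' @return an `hclust` object (merge sequence, merge heights, labels), with
#'   the method recorded.
#' @export
ward_cluster <- function(d, dialect = c("ward.D", "ward.D2")) {
  dialect <- match.arg(dialect)
  if (is.matrix(d)) {
    assert_that(nrow(d) == ncol(d) && isTRUE(all.equal(d, t(d), tolerance = 1e-10)),
                "distance matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  assert_that(attr(d, "Size") >= 2, "need at least 2 rows to cluster")
  hclust(d, method = dialect)
}

#' Cut a dendrogram into k clusters
#'
#' Severs the k-1 highest merges; labels are 1..k in order of first leaf
#' appearance.
#'
#' @param tree an `hclust` object.
#' @param k number of clusters (1..n).
#' @return integer cluster labels named by leaf label.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$order)
  assert_that(k >= 1 && k <= n, "k must lie in 1..n")
  raw <- cutree(tree, k = k)
  relab <- match(raw, unique(raw))
  setNames(relab, names(raw))
}

#' Within-cluster sum of squares over a range of k
#'
#' For each k, cuts the Ward tree of the Manhattan distances at k and sums
#' the squared Euclidean deviations of the indicator rows from their cluster
#' centroids - the scree used to choose the number of clusters.
#'
#' @param indicators indicator table.
#' @param k_range integer vector of cluster counts.
#' @param dialect Ward dialect passed to [ward_cluster()].
#' @return tibble with columns `k` and `wss` (non-increasing in k).
#' @export
wss_scree <- function(indicators, k_range = 1:10, dialect = "ward.D") {
  x <- .indicator_matrix(indicators)
  tree <- ward_cluster(dist(x, method = "manhattan"), dialect = dialect)
  k_range <- k_range[k_range >= 1 & k_range <= nrow(x)]
  wss <- vapply(k_range, function(k) {
    cl <- cut_tree(tree, k)
    sum(vapply(split(seq_len(nrow(x)), cl), function(idx) {
      xc <- x[idx, , drop = FALSE]
      sum(sweep(xc, 2, colMeans(xc))^2)
    }, numeric(1)))
  }, numeric(1))
  tibble(k = as.integer(k_range), wss = wss)
}

#' Principal component analysis of the indicators
#'
#' Covariance PCA: columns are centred but NOT rescaled (the indicators
#' share the same order of magnitude, so no transformation is applied). The
#' Kaiser-retained count for covariance PCA is the number of eigenvalues
#' above the mean eigenvalue.
#'
#' @param indicators indicator table.
#' @param scale. rescale columns to unit variance first (off by default).
#' @return list of class `ordination`: `scores`, `loadings`, `eigenvalues`,
#'   `variance_fraction` (sums to 1), `kaiser_retained`, `center`.
#' @export
pca_indicators <- function(indicators, scale. = FALSE) {
  x <- .indicator_matrix(indicators)
  assert_that(nrow(x) >= 2, "need at least 2 complete rows")
  pc <- prcomp(x, center = TRUE, scale. = scale.)
  eig <- pc$sdev^2
  structure(list(
    scores = pc$x, loadings = pc$rotation, eigenvalues = eig,
    variance_fraction = eig / sum(eig),
    kaiser_retained = sum(eig > mean(eig)),
    center = pc$center, method = "pca"
  ), class = "ordination")
}

# projection of y onto the column space of x via SVD (pseudo-inverse
# least squares); warns on rank deficiency
.fit_pinv <- function(x, y) {
  sv <- svd(x)
  tol <- max(dim(x)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  if (sum(pos) < ncol(x)) warning("rank-deficient climate matrix; pseudo-inverse used")
  u <- sv$u[, pos, drop = FALSE]
  u %*% (t(u) %*% y) # fitted values H y, H = U U'
}

#' Redundancy analysis of indicators on climate
#'
#' Regresses the centred indicator matrix on the (by default) standardised
#' climate variables, eigen-decomposes the fitted values into constrained
#' axes, and tests the whole model and each axis by permuting the rows of
#' the climate matrix. `R2 = trace(fitted) / trace(total)`; the adjusted R2
#' uses the Ezekiel correction `1 - (1 - R2)(n - 1)/(n - p - 1)`. P-values
#' follow the add-one convention `p = (1 + #{perm >= obs}) / (1 + n_perm)`.
#' Only accessions present in both tables with complete rows are used; the
#' dropped ids are returned.
#'
#' @param indicators indicator table.
#' @param climate climate table (one row per accession).
#' @param n_perm number of permutations.
#' @param seed seed for the permutation stream (restored on exit).
#' @param standardize_climate centre/scale climate columns (on: units are
#'   incommensurable).
#' @param scale_indicators rescale indicator columns too (off, mirroring the
#'   PCA choice).
#' @return list of class `ordination` with `site_scores`, `loadings`
#'   (indicator loadings), `climate_scores` (correlations of climate with
#'   the site scores), `eigenvalues`, `variance_fraction` (of total
#'   indicator variance per constrained axis), `r2`, `adj_r2`,
#'   `p_model`, `p_axes`, `n_perm`, `n`, `dropped`.
#' @export
rda_climate <- function(indicators, climate, n_perm = 999, seed = NULL,
                        standardize_climate = TRUE, scale_indicators = FALSE) {
  yx <- merge(indicators[, c("accession_id", .indicator_cols)],
              climate[, c("accession_id", .climate_cols)], by = "accession_id")
  yx <- yx[order(yx$accession_id), , drop = FALSE]
  ok <- stats::complete.cases(yx)
  dropped <- union(setdiff(indicators$accession_id, yx$accession_id[ok]),
                   yx$accession_id[!ok])
  yx <- yx[ok, , drop = FALSE]
  n <- nrow(yx)
  assert_that(n >= 8, "too few accessions with complete indicators + climate")

  y <- scale(as.matrix(yx[, .indicator_cols]), center = TRUE,
             scale = scale_indicators)
  x <- scale(as.matrix(yx[, .climate_cols]), center = TRUE,
             scale = standardize_climate)
  rownames(y) <- rownames(x) <- yx$accession_id
  p <- ncol(x)
  tot <- sum(y^2)

  yhat <- .fit_pinv(x, y)
  sv <- svd(yhat)
  keep <- sv$d^2 > max(sv$d^2) * 1e-12
  d <- sv$d[keep]
  eig <- d^2 / (n - 1)
  r2 <- sum(d^2) / tot
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  ge_model <- 0L
  ge_axes <- integer(length(d))
  for (b in seq_len(n_perm)) {
    xp <- x[sample.int(n), , drop = FALSE]
    yhp <- .fit_pinv(xp, y)
    dp <- svd(yhp, nu = 0, nv = 0)$d
    if (sum(dp^2) >= sum(d^2)) ge_model <- ge_model + 1L
    dp <- dp[seq_along(d)]
    ge_axes <- ge_axes + as.integer(dp^2 >= d^2)
  }
  p_model <- (1 + ge_model) / (1 + n_perm)
  p_axes <- (1 + ge_axes) / (1 + n_perm)

  site <- sv$u[, keep, drop = FALSE] %*% diag(d, length(d))
  rownames(site) <- yx$accession_id
  colnames(site) <- paste0("RDA", seq_along(d))
  loadings <- sv$v[, keep, drop = FALSE]
  rownames(loadings) <- .indicator_cols
  colnames(loadings) <- colnames(site)
  climate_scores <- cor(x, site)

  structure(list(
    site_scores = site, loadings = loadings, climate_scores = climate_scores,
    eigenvalues = eig, variance_fraction = d^2 / tot,
    r2 = r2, adj_r2 = adj_r2, p_model = p_model, p_axes = p_axes,
    n_perm = n_perm, n = n, dropped = dropped, method = "rda"
  ), class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  if (identical(x$method, "rda")) {
    cat(sprintf("RDA on %d accessions: R2 = %.3f, adjusted R2 = %.3f\n",
                x$n, x$r2, x$adj_r2))
    cat(sprintf("whole-model permutation p = %.4g (%d permutations)\n",
                x$p_model, x$n_perm))
    cat("per-axis p:", paste(sprintf("%.3g", x$p_axes), collapse = ", "), "\n")
  } else {
    cat("PCA variance fractions:",
        paste(sprintf("%.3f", x$variance_fraction), collapse = ", "), "\n")
    cat("Kaiser-retained components:", x$kaiser_retained, "\n")
  }
  invisible(x)
}

#' Pearson correlations between indicators and climate
#'
#' 5 x 5 table of Pearson r between the five drought-resistance indicators
#' and the five climate variables, over complete pairs, with two-sided
#' p-values and star coding (* p < 0.05, ** p < 0.01).
#'
#' @param indicators indicator table.
#' @param climate climate table.
#' @return list of class `correlation_table` with matrices `r`, `p`,
#'   `stars`, `n`.
#' @export
indicator_climate_correlations <- function(indicators, climate) {
  yx <- merge(indicators[, c("accession_id", .indicator_cols)],
              climate[, c("accession_id", .climate_cols)], by = "accession_id")
  r <- p <- nmat <- matrix(NA_real_, length(.indicator_cols), length(.climate_cols),
                           dimnames = list(.indicator_cols, .climate_cols))
  for (i in .indicator_cols) {
    for (j in .climate_cols) {
      ok <- is.finite(yx[[i]]) & is.finite(yx[[j]])
      assert_that(sum(ok) >= 4, "fewer than 4 complete pairs")
      ct <- cor.test(yx[[i]][ok], yx[[j]][ok], method = "pearson")
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
      nmat[i, j] <- sum(ok)
    }
  }
  stars <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  stars[p < 0.05] <- "*"
  stars[p < 0.01] <- "**"
  structure(list(r = r, p = p, stars = stars, n = nmat),
            class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, ...) {
  m <- matrix(sprintf("%.2f%s", x$r, x$stars), nrow(x$r), dimnames = dimnames(x$r))
  print(m, quote = FALSE)
  invisible(x)
}
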