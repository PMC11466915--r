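.indicator_cols <- c("biomass_penalty", "wue_wilting_moisture",
                     "rwc_desiccation_moisture", "ndvi_chlorosis_moisture",
                     "root_shoot_ratio")

#' Descriptive statistics of the indicator table
#'
#' N, minimum, maximum, mean, standard deviation (n-1 denominator) and
#' variance for each of the five indicators, over non-missing accessions.
#'
#' @param indicators indicator table from [build_indicator_table()].
#' @return tibble with one row per indicator.
#' @export
descriptive_stats <- function(indicators) {
  rows <- lapply(.indicator_cols, function(cl) {
    v <- indicators[[cl]]
    v <- v[is.finite(v)]
    assert_that(length(v) >= 1, paste0("no non-missing values for ", cl))
    tibble(indicator = cl, n = length(v), min = min(v), max = max(v),
           mean = mean(v), sd = sd(v), var = var(v))
  })
  do.call(rbind, rows)
}

#' Spearman rank-correlation matrix of the indicators
#'
#' Pairwise Spearman rho (average ranks for ties) over complete pairs, with
#' two-sided p-values and Bonferroni adjustment over the k = 10 distinct
#' pairs. P-values use the large-sample t approximation, except that the
#' exact permutation distribution is used when fewer than 10 complete pairs
#' are available.
#'
#' @param indicators indicator table.
#' @param alpha base significance level for the star coding.
#' @return list of class `spearman_matrix` with matrices `rho`, `p`,
#'   `p_bonferroni`, `stars`, and `n` (complete pairs per cell).
#' @export
spearman_matrix <- function(indicators, alpha = 0.05) {
  x <- as.matrix(indicators[, .indicator_cols])
  k <- ncol(x)
  n_tests <- k * (k - 1) / 2
  rho <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(.indicator_cols, .indicator_cols))
  diag(rho) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- is.finite(x[, i]) & is.finite(x[, j])
      assert_that(sum(ok) >= 4, "fewer than 4 complete pairs")
      exact <- sum(ok) < 10
      ct <- suppressWarnings(cor.test(x[ok, i], x[ok, j], method = "spearman",
                                      exact = exact))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
      nmat[i, j] <- nmat[j, i] <- sum(ok)
    }
  }
  p_adj <- pmin(p * n_tests, 1)
  diag(p_adj) <- 0
  stars <- matrix("", k, k, dimnames = dimnames(rho))
  stars[p_adj < alpha] <- "*"
  stars[p_adj < 0.001] <- "**"
  diag(stars) <- ""
  structure(list(rho = rho, p = p, p_bonferroni = p_adj, stars = stars,
                 n = nmat, k_tests = n_tests),
            class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, ...) {
  cat("Spearman rank correlations (Bonferroni k =", x$k_tests, ")\n")
  m <- matrix(sprintf("%.2f%s", x$rho, x$stars), nrow(x$rho),
              dimnames = dimnames(x$rho))
  print(m, quote = FALSE)
  invisible(x)
}

#' Heteroscedastic variance components by subgenus (REML)
#'
#' Fits the one-way random-effects model
#' `y_ij = mu + b_i + e_ij`, `b_i ~ N(0, sigma2_between)`,
#' `e_ij ~ N(0, sigma2_within[i])` with a separate residual variance per
#' subgenus, by restricted maximum likelihood. Groups are independent given
#' the random effect, so the REML criterion has a closed group-wise form
#' (Woodbury identity on the compound-symmetric group covariance) which is
#' optimised numerically over log-variances. Subgenera with three or fewer
#' observations are dropped before fitting.
#'
#' @param values numeric indicator values.
#' @param groups subgenus labels (same length).
#' @param min_group_size groups of this size or smaller are dropped
#'   (default 3, i.e. "three or fewer").
#' @return object of class `variance_components`: `sigma2_between`,
#'   `sigma2_within` (named per subgenus), `mu`, `reml_loglik`, `n` (per
#'   subgenus), `converged`, `singular` (variances at the zero floor),
#'   `dropped` (labels of omitted groups).
#' @export
fit_heteroscedastic_mixed <- function(values, groups, min_group_size = 3L) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  tab <- table(groups)
  keep_g <- names(tab)[tab > min_group_size]
  dropped <- setdiff(names(tab), keep_g)
  assert_that(length(keep_g) >= 2,
              "need at least 2 subgenera after dropping small groups")
  sel <- groups %in% keep_g
  y <- values[sel]; g <- factor(groups[sel], levels = sort(keep_g))
  ys <- split(y, g)
  ni <- vapply(ys, length, integer(1))
  G <- length(ys)

  if (var(y) < 1e-14) {           # degenerate: no variability at all
    return(structure(list(
      sigma2_between = 0, sigma2_within = setNames(rep(0, G), levels(g)),
      mu = mean(y), reml_loglik = NA_real_, n = ni, converged = TRUE,
      singular = setNames(rep(TRUE, G + 1), c("between", levels(g))),
      dropped = dropped
    ), class = "variance_components"))
  }

  # REML criterion: sum_i log|V_i| + log(sum_i 1'V_i^-1 1) + r'V^-1 r,
  # with V_i = s2w_i I + s2b J, evaluated via Woodbury.
  crit <- function(par) {
    s2b <- exp(par[1]); s2w <- exp(par[-1])
    logdet <- 0; sw <- 0; swy <- 0
    for (i in seq_len(G)) {
      n <- ni[i]; v <- s2w[i]
      logdet <- logdet + n * log(v) + log1p(n * s2b / v)
      w1 <- n / v - (n / v)^2 * s2b / (1 + n * s2b / v)  # 1'V^-1 1
      sw <- sw + w1
      swy <- swy + w1 * mean(ys[[i]])
    }
    mu <- swy / sw
    quad <- 0
    for (i in seq_len(G)) {
      r <- ys[[i]] - mu; n <- ni[i]; v <- s2w[i]
      sr <- sum(r)
      quad <- quad + sum(r^2) / v - (s2b / (v * (v + n * s2b))) * sr^2
    }
    out <- logdet + log(sw) + quad
    if (!is.finite(out)) 1e10 else out
  }

  v0 <- vapply(ys, var, numeric(1))
  v0[!is.finite(v0) | v0 < 1e-8] <- 1e-8
  m0 <- vapply(ys, mean, numeric(1))
  b0 <- max(var(m0) - mean(v0 / ni), 1e-8)
  start <- pmin(pmax(log(c(b0, v0)), -25), 25)
  opt <- optim(start, crit, method = "L-BFGS-B", lower = -30, upper = 30,
               control = list(maxit = 1000, factr = 1e4))
  # Nelder-Mead polish guards against L-BFGS-B stalling on the flat floor
  opt2 <- optim(opt$par, crit, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-12))
  if (opt2$value <= opt$value) opt <- opt2
  if (opt$convergence != 0) {
    stop("REML optimisation did not converge (code ", opt$convergence, ")",
         call. = FALSE)
  }

  s2b <- unname(exp(opt$par[1])); s2w <- setNames(exp(opt$par[-1]), levels(g))
  floor_tol <- 1e-7
  singular <- c(between = s2b < floor_tol, s2w < floor_tol)
  s2b <- ifelse(s2b < floor_tol, 0, s2b)
  s2w[s2w < floor_tol] <- 0

  # recompute mu at the optimum (guard the zero floor for the algebra)
  s2b_e <- max(s2b, 1e-12); s2w_e <- pmax(s2w, 1e-12)
  sw <- 0; swy <- 0
  for (i in seq_len(G)) {
    n <- ni[i]; v <- s2w_e[i]
    w1 <- n / v - (n / v)^2 * s2b_e / (1 + n * s2b_e / v)
    sw <- sw + w1; swy <- swy + w1 * mean(ys[[i]])
  }
  loglik <- -0.5 * (opt$value + (sum(ni) - 1) * log(2 * pi))
  structure(list(
    sigma2_between = s2b, sigma2_within = s2w, mu = swy / sw,
    reml_loglik = loglik, n = ni, converged = TRUE,
    singular = singular, dropped = dropped
  ), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("between-subgenus variance: %.4g\n", x$sigma2_between))
  cat("within-subgenus variances:\n")
  print(round(x$sigma2_within, 6))
  cat(sprintf("REML log-likelihood: %.4f\n", x$reml_loglik))
  if (length(x$dropped)) cat("dropped (<= 3 obs):", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Within/total variance proportion per subgenus
#'
#' `sigma2_within[g] / (sigma2_between + sigma2_within[g])` for every
#' retained subgenus: the proportion of an indicator's variability that is
#' within-subgenus rather than between.
#'
#' @param vc a `variance_components` object.
#' @return named numeric vector of proportions in \[0, 1\].
#' @export
within_total_proportion <- function(vc) {
  assert_that(inherits(vc, "variance_components"), "vc must be variance_components")
  tot <- vc$sigma2_between + vc$sigma2_within
  out <- ifelse(tot > 0, vc$sigma2_within / tot, NA_real_)
  setNames(as.numeric(out), names(vc$sigma2_within))
}
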