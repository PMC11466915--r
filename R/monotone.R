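#' Shape-constrained (monotone increasing) WUE curve fit
#'
#' Least-squares fit of a smooth non-decreasing curve to water-use-efficiency
#' points pooled over an accession's drought plants. The curve is built from
#' an I-spline basis (integrated cubic B-splines, each non-decreasing from 0
#' to 1) with three interior knots at the 0.25/0.5/0.75 moisture quantiles of
#' the points; non-negative basis coefficients plus a free intercept make the
#' fit monotone by construction. The non-negative least-squares problem is
#' solved with [pracma::lsqnonneg()] (the free intercept is split into a
#' positive and a negative column).
#'
#' @param points data frame with columns `mean_moisture` and `wue`
#'   (see [wue_points()]), or two numeric vectors via `x`/`y`.
#' @param x,y alternative to `points`.
#' @param n_grid grid size for the monotonicity certificate.
#' @return object of class `monotone_fit`: `predict` (function of moisture),
#'   `coef`, `intercept`, `knots`, `range`, `rss`, `monotone_certified`, and
#'   `x_intercept` (see [wilting_moisture()]).
#' @export
fit_monotone_wue <- function(points = NULL, x = NULL, y = NULL, n_grid = 401L) {
  if (!is.null(points)) {
    x <- points$mean_moisture
    y <- points$wue
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  assert_that(length(x) >= 5, "at least 5 WUE points are required")
  lo <- min(x); hi <- max(x)
  assert_that(hi - lo >= 0.05, "points must span at least 0.05 moisture range")

  ik <- unique(as.numeric(quantile(x, c(0.25, 0.5, 0.75))))
  ik <- ik[ik > lo + 1e-9 & ik < hi - 1e-9]
  basis <- .ispline_basis(x, lo, hi, ik)

  design <- cbind(1, -1, basis)
  sc <- max(abs(y), 1)                      # lsqnonneg is happier scaled
  sol <- pracma::lsqnonneg(design, y / sc)
  coefs <- sol$x * sc
  intercept <- coefs[1] - coefs[2]
  beta <- coefs[-(1:2)]

  predict_fn <- function(newx) {
    newx <- clamp(newx, lo, hi)
    intercept + as.vector(.ispline_basis(newx, lo, hi, ik) %*% beta)
  }
  fitted <- predict_fn(x)
  grid <- seq(lo, hi, length.out = n_grid)
  certified <- all(diff(predict_fn(grid)) >= -1e-10)

  fit <- structure(list(
    predict = predict_fn, coef = beta, intercept = intercept,
    knots = ik, range = c(lo, hi), rss = sum((y - fitted)^2),
    monotone_certified = certified, n = length(x)
  ), class = "monotone_fit")
  fit$x_intercept <- wilting_moisture(fit)
  fit
}

# I-spline basis of order 3 on [lo, hi] with interior knots ik: cumulative
# sums of cubic B-splines; each column is non-decreasing from 0 to 1. The
# constant column (j = 1) is dropped - the model carries a free intercept.
.ispline_basis <- function(x, lo, hi, ik) {
  kx <- c(rep(lo, 4), ik, rep(hi, 4))
  b <- splines::splineDesign(kx, x, ord = 4, outer.ok = FALSE)
  k <- ncol(b)
  # I_j(x) = sum_{m >= j} B_m(x), for j = 2..k
  cum <- t(apply(b, 1, function(r) rev(cumsum(rev(r)))))
  if (length(x) == 1L) cum <- matrix(cum, nrow = 1L)
  cum[, 2:k, drop = FALSE]
}

#' Soil moisture at wilting from a monotone WUE fit
#'
#' The wilting moisture is the x-intercept of the fitted WUE curve
#' (WUE = 0). By monotonicity the crossing is unique when the curve changes
#' sign over the observed moisture range; it is located by bisection. Curves
#' that are positive over the whole range never exhibit wilting
#' (`below_range`); all-negative curves never exhibit growth
#' (`above_range`). In both sentinel cases the value is `NA` rather than a
#' clamped range edge, so downstream analyses can filter explicitly.
#'
#' @param fit a `monotone_fit`.
#' @param tol bisection tolerance on the root.
#' @return list with `value` (moisture fraction or `NA`) and `sentinel`
#'   (`"ok"`, `"below_range"` or `"above_range"`).
#' @export
wilting_moisture <- function(fit, tol = 1e-12) {
  assert_that(inherits(fit, "monotone_fit"), "fit must be a monotone_fit")
  lo <- fit$range[1]; hi <- fit$range[2]
  f_lo <- fit$predict(lo); f_hi <- fit$predict(hi)
  if (f_lo > 0) return(list(value = NA_real_, sentinel = "below_range"))
  if (f_hi < 0) return(list(value = NA_real_, sentinel = "above_range"))
  if (f_lo == 0) return(list(value = lo, sentinel = "ok"))
  if (f_hi == 0) return(list(value = hi, sentinel = "ok"))
  root <- uniroot(function(m) fit$predict(m), c(lo, hi), tol = tol)$root
  list(value = root, sentinel = "ok")
}

#' @export
print.monotone_fit <- function(x, ...) {
  xi <- if (x$x_intercept$sentinel == "ok") {
    sprintf("%.4f", x$x_intercept$value)
  } else x$x_intercept$sentinel
  cat(sprintf(
    "monotone WUE fit on %d points over [%.3f, %.3f]\n  rss = %.4g, monotone certificate: %s, x-intercept (wilting moisture): %s\n",
    x$n, x$range[1], x$range[2], x$rss, x$monotone_certified, xi))
  invisible(x)
}
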