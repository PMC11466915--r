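#' Linear-plateau breakpoint regression
#'
#' Fits the linear-plateau model
#' `y = a + b * x` for `x <= x0`, constant `a + b * x0` for `x > x0`
#' (continuous at the junction), minimising the residual sum of squares.
#' Initial values come from profiling: for every candidate junction on the
#' midpoints of the sorted distinct `x` (plus `max(x)`, the unbroken-line
#' limit), the conditional ordinary least squares in `(a, b)` is solved
#' exactly; the best few candidates are then refined jointly in
#' `(a, b, x0)` with the Levenberg-Marquardt algorithm
#' ([minpack.lm::nls.lm()]). The returned fit is never worse than the best
#' profiled candidate, so its RSS is bounded by both the plain linear and
#' the constant fit.
#'
#' @param x,y numeric vectors (moisture fractions and index values).
#' @param n_refine number of top profile candidates passed to the joint
#'   refinement.
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @param gtol gradient tolerance for convergence.
#' @return object of class `linear_plateau_fit` with elements `a`, `b`,
#'   `x0`, `plateau`, `rss`, `converged`, `n`, and `predict` (a function of
#'   new `x`).
#' @export
fit_linear_plateau <- function(x, y, n_refine = 3L, max_iter = 200L, gtol = 1e-10) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  assert_that(length(x) >= 4, "at least 4 points are required")
  xs <- sort(unique(x))
  assert_that(length(xs) >= 2, "degenerate x: all values equal")

  mids <- (xs[-1] + xs[-length(xs)]) / 2
  cand <- c(mids, max(xs))

  prof_rss <- function(c0) .plateau_rss(x, y, c0)$rss
  prof <- vapply(cand, prof_rss, numeric(1))
  ord <- order(prof)
  best_c <- cand[ord[1]]
  best <- .plateau_rss(x, y, best_c)
  best_par <- c(best$a, best$b, best_c)
  best_rss <- best$rss
  converged <- FALSE

  # continuous profiling of the junction: the profiled RSS is smooth
  # between x order statistics but not across them, so every segment is
  # minimised separately (sub-grid plus 1-D search); the joint LM step
  # below then polishes (a, b, x0) together from the best candidates
  refine_c <- numeric(0)
  for (c0 in cand[ord]) {
    seg_lo <- if (any(xs < c0 - 1e-12)) max(xs[xs < c0 - 1e-12]) else min(xs)
    seg_hi <- if (any(xs > c0 + 1e-12)) min(xs[xs > c0 + 1e-12]) else max(xs)
    sub <- seq(seg_lo, seg_hi, length.out = 17)
    vals <- vapply(sub, prof_rss, numeric(1))
    j <- which.min(vals)
    opt <- optimize(prof_rss, c(sub[max(1, j - 1)], sub[min(17, j + 1)]),
                    tol = 1e-12)
    c_best <- if (opt$objective < min(vals)) opt$minimum else sub[j]
    st <- .plateau_rss(x, y, c_best)
    refine_c <- rbind(refine_c, c(c_best, st$rss))
    if (st$rss < best_rss) {
      best_rss <- st$rss
      best_par <- c(st$a, st$b, c_best)
    }
  }
  refine_c <- refine_c[order(refine_c[, 2]), , drop = FALSE]
  polish <- refine_c[seq_len(min(n_refine, nrow(refine_c))), 1]

  resid_fn <- function(p) y - (p[1] + p[2] * pmin(x, p[3]))
  for (c0 in polish) {
    st <- .plateau_rss(x, y, c0)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(st$a, st$b, c0), fn = resid_fn,
        lower = c(-Inf, -Inf, min(xs)), upper = c(Inf, Inf, max(xs)),
        control = minpack.lm::nls.lm.control(maxiter = max_iter, gtol = gtol)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (rss < best_rss - 0 || (rss <= best_rss && fit$info %in% 1:4)) {
      best_rss <- rss
      best_par <- unname(coef(fit))
      converged <- converged || fit$info %in% 1:4
    } else if (fit$info %in% 1:4 && rss <= best_rss * (1 + 1e-12)) {
      converged <- TRUE
    }
  }

  a <- best_par[1]; b <- best_par[2]; x0 <- clamp(best_par[3], min(xs), max(xs))
  structure(list(
    a = a, b = b, x0 = x0, plateau = a + b * x0, rss = best_rss,
    converged = converged, n = length(x),
    predict = function(newx) a + b * pmin(newx, x0)
  ), class = "linear_plateau_fit")
}

# conditional OLS of (a, b) given a junction candidate
.plateau_rss <- function(x, y, c0) {
  z <- pmin(x, c0)
  if (stats::sd(z) < 1e-12) {          # junction at/below min(x): constant fit
    a <- mean(y)
    return(list(a = a, b = 0, rss = sum((y - a)^2)))
  }
  fit <- stats::lm.fit(cbind(1, z), y)
  list(a = fit$coefficients[1], b = fit$coefficients[2],
       rss = sum(fit$residuals^2))
}

#' @export
print.linear_plateau_fit <- function(x, ...) {
  cat(sprintf(
    "linear-plateau fit: a = %.4g, b = %.4g, junction x0 = %.4g, plateau = %.4g\n  rss = %.4g, n = %d, converged = %s\n",
    x$a, x$b, x$x0, x$plateau, x$rss, x$n, x$converged))
  invisible(x)
}
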