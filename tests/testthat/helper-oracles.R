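# Independent oracles used to cross-check the package implementations.
# These deliberately share no code with the functions they verify.

# Exhaustive profiled-breakpoint search for the linear-plateau model:
# within every segment between adjacent distinct x order statistics the
# junction is profiled by 1-D minimisation of the conditional-OLS rss
# (plus the segment endpoints and the unbroken-line limit x0 = max(x)).
oracle_plateau_rss <- function(x, y) {
  rss_at <- function(c0) {
    z <- pmin(x, c0)
    if (sd(z) < 1e-12) return(sum((y - mean(y))^2))
    sum(lsfit(z, y)$residuals^2)
  }
  xs <- sort(unique(x))
  best <- rss_at(max(xs))
  for (i in seq_len(length(xs) - 1)) {
    lo <- xs[i]; hi <- xs[i + 1]
    sub <- seq(lo, hi, length.out = 25)
    vals <- vapply(sub, rss_at, numeric(1))
    best <- min(best, vals)
    j <- which.min(vals)
    opt <- optimize(rss_at, c(sub[max(1, j - 1)], sub[min(25, j + 1)]),
                    tol = 1e-12)
    best <- min(best, opt$objective)
  }
  best
}

# Brute-force Ward agglomeration on an unsquared dissimilarity matrix
# (the classic "ward.D" dialect): at every step the Lance-Williams Ward
# criterion is evaluated for every candidate pair and the minimum merged,
# ties broken by lowest pair index. Returns merge heights and the cluster
# membership after each merge.
oracle_ward <- function(dmat) {
  n <- nrow(dmat)
  d <- dmat
  sizes <- rep(1, n)
  active <- seq_len(n)
  membership <- lapply(seq_len(n), function(i) i)
  heights <- numeric(n - 1)
  partitions <- vector("list", n - 1)
  labels <- -(seq_len(n))            # hclust convention
  merge <- matrix(0L, n - 1, 2)
  for (step in seq_len(n - 1)) {
    best <- c(Inf, NA, NA)
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        dij <- d[active[ii], active[jj]]
        if (dij < best[1]) best <- c(dij, ii, jj)
      }
    }
    i <- active[best[2]]; j <- active[best[3]]
    heights[step] <- best[1]
    merge[step, ] <- sort(c(labels[i], labels[j]))
    # Lance-Williams Ward update against every other active cluster
    for (k in active) {
      if (k == i || k == j) next
      d_new <- ((sizes[i] + sizes[k]) * d[i, k] +
                  (sizes[j] + sizes[k]) * d[j, k] -
                  sizes[k] * d[i, j]) / (sizes[i] + sizes[j] + sizes[k])
      d[i, k] <- d[k, i] <- d_new
    }
    sizes[i] <- sizes[i] + sizes[j]
    membership[[i]] <- c(membership[[i]], membership[[j]])
    labels[i] <- step
    active <- setdiff(active, j)
    part <- integer(n)
    for (a in seq_along(active)) part[membership[[active[a]]]] <- a
    partitions[[step]] <- part
  }
  list(heights = heights, merge = merge, partitions = partitions)
}

# closed-form one-way ANOVA (method-of-moments) variance components for
# balanced homoscedastic data; equals REML when both components are interior
oracle_anova_vc <- function(y, g) {
  g <- factor(g)
  n0 <- length(y) / nlevels(g)
  msb <- n0 * var(tapply(y, g, mean))
  mse <- mean(tapply(y, g, var))
  list(sigma2_within = mse, sigma2_between = max((msb - mse) / n0, 0))
}

# same partition up to label permutation
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}
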