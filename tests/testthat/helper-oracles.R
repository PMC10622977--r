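# Independent oracles, coded without reference to the package internals.

# Plain (monofractal) DFA at q = 2: literal textbook loop, order-1
# detrending, segments from the start only is the common simple variant;
# here we mirror the two-sided segmentation so the comparison isolates
# the fluctuation/regression machinery, not the segmentation convention.
oracle_dfa_h2 <- function(x, scales, order = 1) {
  y <- cumsum(x - mean(x))
  n <- length(y)
  f2 <- vapply(scales, function(s) {
    ns <- n %/% s
    v <- numeric(2 * ns)
    for (k in seq_len(ns)) {
      seg <- y[((k - 1) * s + 1):(k * s)]
      v[k] <- mean(resid(lm(seg ~ poly(seq_len(s), order)))^2)
      seg2 <- y[(n - k * s + 1):(n - (k - 1) * s)]
      v[ns + k] <- mean(resid(lm(seg2 ~ poly(seq_len(s), order)))^2)
    }
    sqrt(mean(v))
  }, numeric(1))
  unname(coef(lm(log(f2) ~ log(scales)))[2])
}

# Textbook pooled two-sample t from raw data.
oracle_pooled_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Brute-force PERMANOVA for two groups: enumerate every assignment of
# group-1 labels, computing pseudo-F from first principles each time.
oracle_permanova_enum <- function(d, groups) {
  dm2 <- as.matrix(d)^2
  n <- nrow(dm2)
  lv <- levels(factor(groups))
  n1 <- sum(groups == lv[1])
  ss_tot <- sum(dm2) / (2 * n)
  fstat <- function(g) {
    ssw <- 0
    for (l in lv) {
      i <- which(g == l)
      ssw <- ssw + sum(dm2[i, i]) / (2 * length(i))
    }
    ((ss_tot - ssw) / (length(lv) - 1)) / (ssw / (n - length(lv)))
  }
  obs <- fstat(groups)
  combs <- combn(n, n1)
  fs <- apply(combs, 2, function(idx) {
    g <- rep(lv[2], n); g[idx] <- lv[1]
    fstat(g)
  })
  list(F = obs, p = mean(fs >= obs - 1e-12), n_arrangements = ncol(combs))
}

# Brute-force minimal-mean stable window for BMR extraction.
oracle_bmr_window <- function(x, w, cv_max) {
  best <- Inf; start <- NA
  for (i in seq_len(length(x) - w + 1)) {
    seg <- x[i:(i + w - 1)]
    if (sd(seg) / mean(seg) <= cv_max && mean(seg) < best) {
      best <- mean(seg); start <- i
    }
  }
  list(mean = best, start = start)
}

cascade_fixture_16 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- gen_binomial_cascade(0.6, 16)
    cache
  }
})
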