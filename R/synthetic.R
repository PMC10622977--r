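#' Binomial multiplicative cascade
#'
#' Generates the measure of a binomial (two-scale multiplicative) cascade
#' over the dyadic cells at the finest level: a strictly positive series
#' of length `2^n_levels` whose multifractal scaling is known in closed
#' form (see [theory_h_binomial()]). At each refinement level every cell
#' splits its mass into fractions `p` and `1 - p`. The deterministic
#' variant always assigns `p` to the left child; the randomized variant
#' draws the branch direction per cell under `seed`.
#'
#' @param p multiplier weight in (0, 1).
#' @param n_levels number of dyadic refinement levels (>= 4); the output
#'   has length `2^n_levels`.
#' @param randomize if `TRUE`, branch directions are random (seeded);
#'   the deterministic placement is the default.
#' @param seed integer seed for the randomized variant; ignored when
#'   `randomize = FALSE`.
#' @param normalize if `TRUE` (default) the measure sums to 1; otherwise
#'   it is rescaled to mean 1.
#' @return numeric vector of length `2^n_levels`, all values > 0.
#' @examples
#' w <- gen_binomial_cascade(0.6, 10)
#' sum(w)              # 1
#' range(w) > 0        # strictly positive
#' @seealso [theory_h_binomial()] for the closed-form h(q) of this
#'   construction.
#' @export
gen_binomial_cascade <- function(p, n_levels, randomize = FALSE,
                                 seed = NULL, normalize = TRUE) {
  check_scalar(p, "p", 0, 1, strict = TRUE)
  check_scalar(n_levels, "n_levels", lower = 4, upper = 30, integer = TRUE)
  n_levels <- as.integer(n_levels)
  build <- function() {
    w <- 1
    for (lev in seq_len(n_levels)) {
      if (randomize) {
        flip <- runif(length(w)) < 0.5
        left <- ifelse(flip, 1 - p, p)
      } else {
        left <- rep(p, length(w))
      }
      w <- as.vector(rbind(w * left, w * (1 - left)))
    }
    w
  }
  w <- if (randomize) with_seed(seed, build()) else build()
  if (normalize) w / sum(w) else w / mean(w)
}

#' Closed-form generalized Hurst exponent of the binomial cascade
#'
#' For the binomial cascade with multiplier `p` the fluctuation scaling
#' recovered by MF-DFA follows
#' \deqn{h(q) = 1/q - \log_2(p^q + (1-p)^q)/q,}
#' with the continuous limit
#' \eqn{h(0) = -(\log_2 p + \log_2(1-p))/2} at `q = 0`. `h(q)` is
#' strictly decreasing in `q` for `p != 0.5` and identically 1 for
#' `p = 0.5` (degenerate monofractal case). This is the independent
#' oracle used to validate [mfdfa()].
#'
#' @param q moment order(s); vectorized.
#' @param p multiplier weight in (0, 1).
#' @return h(q), same length as `q`.
#' @examples
#' theory_h_binomial(2, 0.5)   # 1
#' theory_h_binomial(2, 0.6)   # ~0.9717
#' @export
theory_h_binomial <- function(q, p) {
  check_scalar(p, "p", 0, 1, strict = TRUE)
  check_finite_vector(q, "q")
  h <- numeric(length(q))
  at0 <- abs(q) < 1e-10
  h[at0] <- -(log2(p) + log2(1 - p)) / 2
  qq <- q[!at0]
  h[!at0] <- 1 / qq - log2(p^qq + (1 - p)^qq) / qq
  h
}

#' Fractional Gaussian noise via circulant embedding
#'
#' Exact simulation of zero-mean fractional Gaussian noise (fGn) with
#' Hurst exponent `hurst` by the Davies-Harte circulant-embedding
#' construction: the fGn autocovariance is embedded in a circulant
#' matrix whose eigenvalues are obtained by FFT, and a complex Gaussian
#' vector is colored accordingly. The returned sample is standardized to
#' zero mean and unit variance. `hurst = 0.5` is white noise; larger
#' values give long-range persistence.
#'
#' @param hurst target Hurst exponent in (0, 1).
#' @param n series length (a power of 2 is recommended for the FFT).
#' @param seed integer seed; fixed seed gives a bit-identical series.
#' @return numeric vector of length `n`, mean 0, sd 1.
#' @examples
#' x <- gen_fgn(0.8, 1024, seed = 1)
#' @export
gen_fgn <- function(hurst, n, seed = NULL) {
  check_scalar(hurst, "hurst", 0, 1, strict = TRUE)
  check_scalar(n, "n", lower = 8, integer = TRUE)
  n <- as.integer(n)
  k <- 0:(n - 1)
  g <- 0.5 * ((k + 1)^(2 * hurst) - 2 * k^(2 * hurst) +
                abs(k - 1)^(2 * hurst))
  c_emb <- c(g, 0, rev(g[-1]))
  lam <- Re(fft(c_emb))
  # Davies-Harte validity: eigenvalues nonnegative for fGn; clip tiny
  # negative values from floating-point roundoff only.
  if (min(lam) < -1e-8 * max(lam)) {
    stop("circulant embedding failed: negative eigenvalues", call. = FALSE)
  }
  lam[lam < 0] <- 0
  m <- length(c_emb)
  x <- with_seed(seed, {
    z <- complex(real = rnorm(m), imaginary = rnorm(m))
    Re(fft(sqrt(lam / (2 * m)) * z))[seq_len(n)]
  })
  (x - mean(x)) / sd(x)
}

#' Synthetic respirometry (VO2) trace with planted increment structure
#'
#' Builds a strictly positive oxygen-consumption series emulating a long
#' flow-through respirometry record: a baseline level, a slow sinusoidal
#' drift (a nuisance term, not a circadian model), and log10-ratio
#' increments drawn from a chosen source process. The series is
#' constructed as
#' `VO2(t) = baseline * 10^cumsum(increments) * (1 + drift(t))`,
#' so with `drift_amplitude = 0` the log-ratio increments
#' ([log_ratio_increments()]) recover the planted source exactly.
#'
#' @param duration_s record duration in seconds (default 32400, i.e. 9 h).
#' @param dt_s sampling interval in seconds (default 1).
#' @param baseline_vo2 baseline oxygen consumption, mL O2 h^-1 (> 0).
#' @param drift_amplitude drift amplitude as a fraction of baseline, in
#'   \[0, 1); positivity of the trace requires < 1.
#' @param increment_source one of `"cascade"`, `"fgn"`, `"white"` — the
#'   process planted in the log10 increments. Cascade increments carry
#'   multifractality from long-range correlated multiplicative structure;
#'   fGn carries tunable monofractal persistence; white is uncorrelated.
#' @param increment_scale standard deviation of the planted log10
#'   increments (dimensionless).
#' @param seed integer seed.
#' @param cascade_p cascade multiplier when `increment_source = "cascade"`.
#' @param fgn_hurst Hurst exponent when `increment_source = "fgn"`.
#' @param drift_period_s period of the sinusoidal drift (default: one
#'   full period over the record).
#' @return data.frame with columns `t_seconds`, `vo2_ml_per_h`;
#'   attributes `increments` (the planted log10 increments),
#'   `increment_source`, and `dt_s` record the ground truth.
#' @examples
#' tr <- gen_respirometry_trace(duration_s = 4096, increment_source = "white",
#'                              seed = 1)
#' all(tr$vo2_ml_per_h > 0)
#' @export
gen_respirometry_trace <- function(duration_s = 32400, dt_s = 1,
                                   baseline_vo2 = 250,
                                   drift_amplitude = 0.05,
                                   increment_source = c("cascade", "fgn",
                                                        "white"),
                                   increment_scale = 0.002,
                                   seed = NULL,
                                   cascade_p = 0.6, fgn_hurst = 0.8,
                                   drift_period_s = duration_s) {
  increment_source <- match.arg(increment_source)
  check_scalar(duration_s, "duration_s", lower = 1)
  check_scalar(dt_s, "dt_s", lower = 1e-9)
  n <- floor(duration_s / dt_s)
  if (n < 2^10) {
    stop("duration_s/dt_s must be at least 2^10 samples", call. = FALSE)
  }
  check_scalar(baseline_vo2, "baseline_vo2", lower = 0, strict = TRUE)
  check_scalar(drift_amplitude, "drift_amplitude", lower = 0, upper = 1 - 1e-9)
  check_scalar(increment_scale, "increment_scale", lower = 0)

  m <- n - 1L  # number of increments
  inc <- switch(increment_source,
    cascade = {
      lev <- ceiling(log2(m))
      w <- gen_binomial_cascade(cascade_p, max(lev, 4L), randomize = TRUE,
                                seed = seed, normalize = FALSE)
      w[seq_len(m)]
    },
    fgn = gen_fgn(fgn_hurst, m, seed = seed),
    white = with_seed(seed, rnorm(m))
  )
  if (increment_scale > 0) {
    inc <- (inc - mean(inc)) / sd(inc) * increment_scale
  } else {
    inc <- rep(0, m)
  }
  tt <- (seq_len(n) - 1L) * dt_s
  drift <- drift_amplitude * sin(2 * pi * tt / drift_period_s)
  vo2 <- baseline_vo2 * 10^cumsum(c(0, inc)) * (1 + drift)
  if (any(vo2 <= 0)) {
    stop("generated VO2 is not strictly positive; reduce drift_amplitude",
         call. = FALSE)
  }
  out <- data.frame(t_seconds = tt, vo2_ml_per_h = vo2)
  attr(out, "increments") <- inc
  attr(out, "increment_source") <- increment_source
  attr(out, "dt_s") <- dt_s
  out
}

#' Synthetic two-group behavioral table
#'
#' Draws per-animal values for a set of behavioral measures in two
#' groups from normal distributions matching target group means and
#' standard errors: the generating SD for a measure is
#' `sem * sqrt(n_per_group)`.
#'
#' @param measures data.frame with columns `name`, `mean_1`, `sem_1`,
#'   `mean_2`, `sem_2` (one row per measure; see
#'   [behavior_reference_summary()] for a ready-made set).
#' @param n_per_group animals per group (>= 2; default 12).
#' @param seed integer seed.
#' @param group_labels length-2 character vector of group names.
#' @return tidy data.frame: `animal_id`, `group`, one numeric column per
#'   measure (measure names are used as-is for column names).
#' @examples
#' m <- data.frame(name = "latency", mean_1 = 10, sem_1 = 2,
#'                 mean_2 = 20, sem_2 = 3)
#' tab <- gen_two_group_table(m, n_per_group = 12, seed = 1)
#' @export
gen_two_group_table <- function(measures, n_per_group = 12, seed = NULL,
                                group_labels = c("CTRL", "TREAT")) {
  need <- c("name", "mean_1", "sem_1", "mean_2", "sem_2")
  if (!is.data.frame(measures) || !all(need %in% names(measures))) {
    stop("`measures` must be a data.frame with columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  check_scalar(n_per_group, "n_per_group", lower = 2, integer = TRUE)
  if (any(measures$sem_1 <= 0) || any(measures$sem_2 <= 0)) {
    stop("all SEMs must be > 0", call. = FALSE)
  }
  if (length(group_labels) != 2L) {
    stop("`group_labels` must have length 2", call. = FALSE)
  }
  n <- as.integer(n_per_group)
  out <- data.frame(
    animal_id = sprintf("%s_%02d", rep(group_labels, each = n),
                        rep(seq_len(n), 2)),
    group = factor(rep(group_labels, each = n), levels = group_labels),
    stringsAsFactors = FALSE
  )
  vals <- with_seed(seed, {
    lapply(seq_len(nrow(measures)), function(i) {
      sd1 <- measures$sem_1[i] * sqrt(n)
      sd2 <- measures$sem_2[i] * sqrt(n)
      c(rnorm(n, measures$mean_1[i], sd1),
        rnorm(n, measures$mean_2[i], sd2))
    })
  })
  names(vals) <- measures$name
  cbind(out, as.data.frame(vals, check.names = FALSE))
}

#' Published two-group behavioral reference summary
#'
#' Returns the group summary statistics (mean and SEM per measure,
#' n = 12 per group) reported for control versus chronically isolated
#' degus across open-field, novel-object, light-dark box, social
#' interaction and object/location recognition tests. These printed
#' values serve as inputs: as targets for [gen_two_group_table()] and as
#' summaries for [t_from_summary()].
#'
#' @return data.frame with columns `name`, `mean_1`, `sem_1`, `mean_2`,
#'   `sem_2` (group 1 = control, group 2 = chronic isolation).
#' @examples
#' head(behavior_reference_summary())
#' @export
behavior_reference_summary <- function() {
  path <- system.file("extdata", "degu_behavior_summary.csv",
                      package = "metabofract", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Published multifractal width reference summary
#'
#' Returns the reported group-level singularity-spectrum widths (original,
#' shuffled and AAFT-surrogate) for the control and chronic-isolation
#' groups, used as inputs to the shuffle/surrogate ratio diagnostics.
#'
#' @return data.frame with columns `group`, `delta_alpha_original`,
#'   `delta_alpha_shuffled`, `delta_alpha_surrogate`.
#' @examples
#' mf_reference_widths()
#' @export
mf_reference_widths <- function() {
  path <- system.file("extdata", "degu_mf_summary.csv",
                      package = "metabofract", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
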