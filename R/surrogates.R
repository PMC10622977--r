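#' Random shuffle of a series
#'
#' Exact multiset-preserving random permutation. Shuffling destroys all
#' temporal correlations while keeping the value distribution, so a
#' collapse of the multifractal width after shuffling attributes the
#' multifractality to long-range correlations.
#'
#' @param x finite numeric series.
#' @param seed integer seed; fixed seed gives an identical permutation.
#' @return permuted series, same length.
#' @export
shuffle_series <- function(x, seed = NULL) {
  check_finite_vector(x, "x")
  with_seed(seed, sample(x))
}

#' Amplitude-adjusted Fourier transform (AAFT) surrogate
#'
#' Classic single-pass AAFT: (i) rank-remap a Gaussian white series onto
#' the ranks of `x` (gaussianization); (ii) randomize the Fourier phases
#' of the gaussianized series while keeping its amplitude spectrum
#' (phases drawn conjugate-symmetric, with the DC component — and, for
#' even lengths, the Nyquist bin — left real); (iii) rank-remap the
#' sorted values of `x` onto the phase-randomized series. The surrogate
#' preserves the amplitude distribution of `x` exactly and its linear
#' autocorrelation/power spectrum approximately, while destroying
#' nonlinear structure — so a preserved multifractal width under AAFT
#' attributes the multifractality to the (heavy-tailed) value
#' distribution rather than to nonlinear correlations.
#'
#' @param x finite numeric series, length >= 128, not constant.
#' @param seed integer seed.
#' @return surrogate series, same multiset of values as `x`.
#' @export
aaft_surrogate <- function(x, seed = NULL) {
  check_finite_vector(x, "x", min_len = 128L)
  if (max(x) == min(x)) {
    stop("constant series: AAFT phases are undefined", call. = FALSE)
  }
  n <- length(x)
  rk <- rank(x, ties.method = "first")
  with_seed(seed, {
    g <- sort(rnorm(n))[rk]
    amp <- Mod(fft(g))
    ph <- numeric(n)
    if (n %% 2 == 0) {
      half <- n / 2
      if (half > 1) {
        draw <- runif(half - 1, 0, 2 * pi)
        ph[2:half] <- draw
        ph[n:(half + 2)] <- -draw
      }
    } else {
      half <- (n + 1) / 2
      draw <- runif(half - 1, 0, 2 * pi)
      ph[2:half] <- draw
      ph[n:(half + 1)] <- -draw
    }
    gp <- Re(fft(amp * exp(1i * ph), inverse = TRUE)) / n
    sort(x)[rank(gp, ties.method = "first")]
  })
}

#' Attribute multifractality to correlations vs heavy tails
#'
#' Computes the singularity-spectrum width `delta_alpha` of the original
#' series and of `n_replicates` shuffles and AAFT surrogates (replicate
#' means), and forms the diagnostic ratios
#' `shuffle_ratio = delta_alpha_shuffled / delta_alpha_original` and
#' `surrogate_ratio = delta_alpha_surrogate / delta_alpha_original`.
#' Verdict logic (thresholds configurable): a small shuffle ratio with a
#' surrogate ratio near 1 means long-range correlations between small
#' and large fluctuations dominate (`"correlation-dominated"`); the
#' converse pattern means the heavy-tailed value distribution dominates
#' (`"fat-tail-dominated"`); both ratios near 1 means there is nothing
#' to attribute (`"none"`, e.g. monofractal noise); anything else is
#' `"mixed"`.
#'
#' @param x increment series.
#' @param n_replicates surrogates of each kind (default 19, the classic
#'   one-sided five-percent rank-test count).
#' @param seed integer seed; replicate seeds are derived
#'   deterministically from it.
#' @param small_threshold ratio below which a width collapse counts as
#'   "small" (default 0.6).
#' @param unity_band length-2 range counting as "near 1"
#'   (default `c(0.8, 1.2)`).
#' @param ... passed to [mfdfa()] (e.g. `order`, `scale_max`, `q`).
#' @return object of class `"mf_source"`: widths (with replicate
#'   dispersion), ratios, per-replicate width vectors, failed-replicate
#'   counts, and the verdict.
#' @examples
#' x <- gen_binomial_cascade(0.6, 12)
#' multifractality_source(x, n_replicates = 3, seed = 1, scale_max = 2^9)
#' @export
multifractality_source <- function(x, n_replicates = 19, seed = 1,
                                   small_threshold = 0.6,
                                   unity_band = c(0.8, 1.2), ...) {
  check_scalar(n_replicates, "n_replicates", lower = 1, integer = TRUE)
  width_of <- function(z) singularity_spectrum(mfdfa(z, ...))$delta_alpha
  d_orig <- width_of(x)

  run_reps <- function(maker, tag) {
    ok <- logical(n_replicates)
    w <- rep(NA_real_, n_replicates)
    for (i in seq_len(n_replicates)) {
      res <- tryCatch(width_of(maker(child_seed(seed, match(tag, c("shuffle", "surrogate")), i))),
                      error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("%s replicate %d failed: %s", tag, i,
                        conditionMessage(res)))
      } else {
        w[i] <- res
        ok[i] <- TRUE
      }
    }
    list(w = w[ok], n_failed = sum(!ok))
  }
  sh <- run_reps(function(s) shuffle_series(x, seed = s), "shuffle")
  su <- run_reps(function(s) aaft_surrogate(x, seed = s), "surrogate")
  if (!length(sh$w) || !length(su$w)) {
    stop("all replicates of a surrogate type failed", call. = FALSE)
  }
  d_sh <- mean(sh$w)
  d_su <- mean(su$w)
  shuffle_ratio <- d_sh / d_orig
  surrogate_ratio <- d_su / d_orig

  near1 <- function(r) r >= unity_band[1] && r <= unity_band[2]
  small <- function(r) r < small_threshold
  verdict <- if (near1(shuffle_ratio) && near1(surrogate_ratio)) {
    "none"
  } else if (small(shuffle_ratio) && near1(surrogate_ratio)) {
    "correlation-dominated"
  } else if (small(surrogate_ratio) && near1(shuffle_ratio)) {
    "fat-tail-dominated"
  } else {
    "mixed"
  }

  structure(list(
    delta_alpha_original = d_orig,
    delta_alpha_shuffled = d_sh,
    delta_alpha_surrogate = d_su,
    sd_shuffled = if (length(sh$w) > 1) sd(sh$w) else NA_real_,
    sd_surrogate = if (length(su$w) > 1) sd(su$w) else NA_real_,
    shuffle_widths = sh$w, surrogate_widths = su$w,
    shuffle_ratio = shuffle_ratio, surrogate_ratio = surrogate_ratio,
    n_replicates = n_replicates,
    n_failed = c(shuffle = sh$n_failed, surrogate = su$n_failed),
    verdict = verdict
  ), class = "mf_source")
}

#' @export
print.mf_source <- function(x, ...) {
  cat("Multifractality source attribution\n")
  cat(sprintf("  delta_alpha: original %.4f | shuffled %.4f (sd %.3g) | surrogate %.4f (sd %.3g)\n",
              x$delta_alpha_original, x$delta_alpha_shuffled, x$sd_shuffled,
              x$delta_alpha_surrogate, x$sd_surrogate))
  cat(sprintf("  shuffle ratio = %.3f   surrogate ratio = %.3f   (%d replicates)\n",
              x$shuffle_ratio, x$surrogate_ratio, x$n_replicates))
  if (any(x$n_failed > 0)) {
    cat(sprintf("  failed replicates: shuffle %d, surrogate %d\n",
                x$n_failed[["shuffle"]], x$n_failed[["surrogate"]]))
  }
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}
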