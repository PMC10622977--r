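#' Oxygen consumption from flow-through respirometry channels
#'
#' Converts raw respirometry channels to oxygen consumption under the
#' standard open-flow equation for a system in which CO2 is scrubbed
#' before the O2 analyzer:
#' \deqn{VO_2 = FR \times 60 \times (F_IO_2 - F_EO_2) / (1 - F_IO_2),}
#' where `fr` is the STP-corrected flow rate in mL min^-1 and
#' `fio2`/`feo2` are the fractional O2 concentrations of incurrent and
#' excurrent air. The factor 60 converts to mL O2 h^-1.
#'
#' @param fr flow rate, mL min^-1 (single value >= 0).
#' @param fio2 fractional incurrent O2, a single value in (0, 1).
#' @param feo2 fractional excurrent O2 per sample (vector), each in
#'   (0, `fio2`\]; values above `fio2` indicate a data-quality problem
#'   and raise an error listing the offending indices.
#' @return numeric vector of VO2 in mL O2 h^-1, same length as `feo2`.
#' @examples
#' compute_vo2(800, 0.2095, 0.2045)  # ~303.6 mL O2/h
#' @export
compute_vo2 <- function(fr, fio2, feo2) {
  check_scalar(fr, "fr", lower = 0)
  check_scalar(fio2, "fio2", 0, 1, strict = TRUE)
  check_finite_vector(feo2, "feo2")
  bad <- which(feo2 > fio2)
  if (length(bad)) {
    stop(sprintf("FEO2 exceeds FIO2 at indices: %s", fmt_idx(bad)),
         call. = FALSE)
  }
  if (any(feo2 <= 0) || any(feo2 >= 1)) {
    stop("feo2 values must lie in (0, 1)", call. = FALSE)
  }
  fr * 60 * (fio2 - feo2) / (1 - fio2)
}

#' Basal metabolic rate from a steady-state VO2 window
#'
#' Scans all contiguous windows of `window_s` seconds with a rolling
#' mean and rolling coefficient of variation (CV), and returns the mean
#' over the lowest-mean window whose CV is below `cv_threshold` — a
#' deterministic, auditable reading of "the 10-minute steady-state
#' minimum". If no window meets the stability criterion, the global
#' minimum-mean window is used and the estimate is flagged unstable.
#'
#' @param vo2 positive VO2 series, mL O2 h^-1.
#' @param window_s window length in seconds (default 600 = 10 min).
#' @param dt_s sampling interval in seconds (default 1).
#' @param cv_threshold maximum rolling CV (sd/mean) for a window to
#'   count as steady state (default 0.05).
#' @param burn_in_s initial equilibration period to discard, seconds
#'   (default 0).
#' @return object of class `"bmr_estimate"`: a list with `bmr`
#'   (mL O2 h^-1), `window_start_s`, `window_end_s`, `cv` of the chosen
#'   window, and `stable` (logical flag).
#' @examples
#' vo2 <- c(rnorm(900, 300, 3), rnorm(600, 200, 2), rnorm(300, 320, 3))
#' extract_bmr(abs(vo2))
#' @export
extract_bmr <- function(vo2, window_s = 600, dt_s = 1,
                        cv_threshold = 0.05, burn_in_s = 0) {
  check_finite_vector(vo2, "vo2")
  check_scalar(window_s, "window_s", lower = dt_s)
  check_scalar(dt_s, "dt_s", lower = 1e-9)
  check_scalar(cv_threshold, "cv_threshold", lower = 0)
  check_scalar(burn_in_s, "burn_in_s", lower = 0)
  if (any(vo2 <= 0)) {
    stop("`vo2` must be strictly positive", call. = FALSE)
  }
  skip <- floor(burn_in_s / dt_s)
  x <- if (skip > 0) vo2[-seq_len(skip)] else vo2
  w <- round(window_s / dt_s)
  n <- length(x)
  if (n < w) {
    stop(sprintf("series (%d samples after burn-in) is shorter than the %d-sample window",
                 n, w), call. = FALSE)
  }
  # rolling mean and sd via cumulative sums
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  k <- seq_len(n - w + 1L)
  s1 <- cs[k + w] - cs[k]
  s2 <- cs2[k + w] - cs2[k]
  mu <- s1 / w
  v <- pmax((s2 - s1^2 / w) / (w - 1), 0)
  cv <- sqrt(v) / mu
  stable <- cv <= cv_threshold
  if (any(stable)) {
    cand <- k[stable]
    best <- cand[which.min(mu[stable])]
    flag <- TRUE
  } else {
    best <- k[which.min(mu)]
    flag <- FALSE
  }
  structure(list(
    bmr = mu[best],
    window_start_s = (best - 1L + skip) * dt_s,
    window_end_s = (best - 1L + skip + w) * dt_s,
    cv = cv[best],
    stable = flag
  ), class = "bmr_estimate")
}

#' @export
print.bmr_estimate <- function(x, ...) {
  cat(sprintf("BMR estimate: %.4g mL O2/h over [%g, %g] s (CV = %.3g%s)\n",
              x$bmr, x$window_start_s, x$window_end_s, x$cv,
              if (x$stable) "" else "; UNSTABLE - no steady-state window"))
  invisible(x)
}

#' Log10-ratio increments of a VO2 series
#'
#' Forms the dimensionless increment series
#' `r(t) = log10(VO2(t+1) / VO2(t))` analyzed by MF-DFA. The input must
#' be strictly positive; nonpositive samples raise an error naming the
#' offending indices rather than being dropped silently.
#'
#' @param vo2 strictly positive series (numeric vector, or a data.frame
#'   with a `vo2_ml_per_h` column as produced by
#'   [gen_respirometry_trace()]).
#' @return numeric vector of length `length(vo2) - 1`.
#' @examples
#' log_ratio_increments(c(1, 2, 4, 8))  # all ~0.30103
#' @export
log_ratio_increments <- function(vo2) {
  if (is.data.frame(vo2)) {
    if (!"vo2_ml_per_h" %in% names(vo2)) {
      stop("data.frame input must have a `vo2_ml_per_h` column",
           call. = FALSE)
    }
    vo2 <- vo2$vo2_ml_per_h
  }
  check_finite_vector(vo2, "vo2", min_len = 2L)
  bad <- which(vo2 <= 0)
  if (length(bad)) {
    stop(sprintf("nonpositive VO2 at indices: %s", fmt_idx(bad)),
         call. = FALSE)
  }
  n <- length(vo2)
  log10(vo2[-1] / vo2[-n])
}
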