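#' Profile (cumulative deviation series) of an increment series
#'
#' First step of detrended fluctuation analysis: the cumulative sum of
#' the mean-subtracted increments,
#' \eqn{y_i = \sum_{k \le i} (x_k - \bar{x})}.
#'
#' @param x finite numeric increment series (length >= 64 for a
#'   meaningful MF-DFA; shorter inputs are rejected).
#' @return numeric profile, same length as `x`; its last value is 0 up
#'   to floating error.
#' @examples
#' mf_profile(c(1, -1, 1, -1) + 5)
#' @export
mf_profile <- function(x) {
  check_finite_vector(x, "x", min_len = 4L)
  cumsum(x - mean(x))
}

default_scales <- function(n, scale_min = 16, scale_max = NULL,
                           n_scales = 20) {
  if (is.null(scale_max)) scale_max <- floor(n / 4)
  sort(unique(round(exp(seq(log(scale_min), log(scale_max),
                            length.out = n_scales)))))
}

# Per-scale segment variances after local polynomial detrending.
# Segments are taken from the start AND from the end (2*Ns total) so the
# tail discarded by floor(N/s) still contributes.
segment_variances <- function(y, s, order) {
  n <- length(y)
  ns <- n %/% s
  idx1 <- seq_len(ns * s)
  idx2 <- (n - ns * s + 1L):n
  Y <- cbind(matrix(y[idx1], nrow = s), matrix(y[idx2], nrow = s))
  X <- outer(seq_len(s) / s, 0:order, `^`)
  Q <- qr.Q(qr(X))
  R <- Y - Q %*% crossprod(Q, Y)
  colMeans(R^2)
}

#' Multifractal detrended fluctuation analysis
#'
#' Fits the MF-DFA scaling model to an increment series: the profile is
#' split, at each scale `s`, into `2*floor(N/s)` non-overlapping
#' segments (from both ends), each segment is detrended by a polynomial
#' of order `order`, and the detrended variances
#' \eqn{\sigma^2(v, s)} are aggregated into the fluctuation function
#' \deqn{F_q(s) = \left\{ \frac{1}{2N_s}\sum_v [\sigma^2(v,s)]^{q/2}
#'   \right\}^{1/q},}
#' with the standard logarithmic average
#' \eqn{F_0(s) = \exp(\tfrac12 \langle \ln \sigma^2 \rangle)} at
#' `q = 0`. The generalized Hurst exponent `h(q)` is the OLS slope of
#' `ln F_q(s)` on `ln s` over `fit_range`; `H = h(2)` is the classical
#' Hurst exponent and `delta_h = h(q_min) - h(q_max)` measures
#' multifractal strength. Renyi exponents are `tau(q) = q h(q) - 1`.
#'
#' For moments up to `|q| = 5` the largest scales should retain enough
#' segments for stable moment averages; keeping
#' `scale_max <= length(x)/8` (>= 16 segments) is recommended, while the
#' default `length(x)/4` follows the usual DFA convention.
#'
#' @param x increment series (e.g. from [log_ratio_increments()]).
#' @param q moment orders; must span negative and positive values and
#'   contain `q = 2` (default `seq(-5, 5, 0.25)`).
#' @param order detrending polynomial order, 1, 2 or 3 (default 2).
#' @param scales integer vector of segment lengths; default ~20
#'   log-spaced scales from `scale_min` to `scale_max`.
#' @param scale_min,scale_max,n_scales used to build the default scale
#'   grid; `scale_max` defaults to `floor(length(x)/4)`.
#' @param fit_range length-2 numeric giving the scale range used in the
#'   `h(q)` regression (default: all scales).
#' @return object of class `"mfdfa"`: list with `q`, `scales`, `Fq`
#'   (matrix, q by scales), `hq`, `hq_se`, `r2`, `H`, `delta_h`, `tau`,
#'   `order`, `fit_scales`, `n`, and `flags` (character; e.g.
#'   `"nonmonotone_hq"` when h(q) is not non-increasing).
#' @examples
#' x <- gen_binomial_cascade(0.6, 12)
#' fit <- mfdfa(x, scale_max = 2^9)
#' fit$H
#' theory_h_binomial(2, 0.6)
#' @seealso [singularity_spectrum()] for the Legendre spectrum,
#'   [multifractality_source()] for surrogate attribution.
#' @export
mfdfa <- function(x, q = seq(-5, 5, 0.25), order = 2, scales = NULL,
                  scale_min = 16, scale_max = NULL, n_scales = 20,
                  fit_range = NULL) {
  check_finite_vector(x, "x", min_len = 64L)
  check_finite_vector(q, "q", min_len = 1L)
  q <- sort(unique(q))
  check_scalar(order, "order", lower = 1, upper = 3, integer = TRUE)
  n <- length(x)
  if (is.null(scales)) {
    scales <- default_scales(n, scale_min, scale_max, n_scales)
  }
  scales <- sort(unique(as.integer(scales)))
  if (min(scales) <= order + 2) {
    stop("smallest scale must exceed order + 2", call. = FALSE)
  }
  if (max(scales) > n / 4) {
    warning("largest scale exceeds length(x)/4; estimates may be unstable")
  }
  if (!any(abs(q - 2) < 1e-8)) {
    warning("q grid does not contain 2; H will be NA")
  }

  y <- cumsum(x - mean(x))
  nq <- length(q)
  ns <- length(scales)
  Fq <- matrix(NA_real_, nq, ns,
               dimnames = list(format(q, trim = TRUE), scales))
  has_neg <- any(q < 0)
  for (j in seq_len(ns)) {
    v <- segment_variances(y, scales[j], order)
    if (has_neg && any(v == 0)) {
      stop(sprintf(
        "zero detrended variance in segment(s) %s at scale %d: negative-q moments are undefined",
        fmt_idx(which(v == 0)), scales[j]), call. = FALSE)
    }
    for (i in seq_len(nq)) {
      qi <- q[i]
      Fq[i, j] <- if (abs(qi) < 1e-10) {
        exp(0.5 * mean(log(v)))
      } else {
        mean(v^(qi / 2))^(1 / qi)
      }
    }
  }

  if (is.null(fit_range)) fit_range <- range(scales)
  in_fit <- scales >= fit_range[1] & scales <= fit_range[2]
  if (sum(in_fit) < 3L) {
    stop("fewer than 3 scales in fit_range", call. = FALSE)
  }
  if (sum(in_fit) < 5L) {
    warning("fewer than 5 scales in fit_range; h(q) standard errors unreliable")
  }
  ls <- log(scales[in_fit])
  hq <- hq_se <- r2 <- numeric(nq)
  for (i in seq_len(nq)) {
    lf <- log(Fq[i, in_fit])
    fit <- lm.fit(cbind(1, ls), lf)
    hq[i] <- fit$coefficients[2]
    res <- fit$residuals
    dfree <- length(ls) - 2L
    s2 <- sum(res^2) / dfree
    hq_se[i] <- sqrt(s2 / sum((ls - mean(ls))^2))
    r2[i] <- 1 - sum(res^2) / sum((lf - mean(lf))^2)
  }

  H <- if (any(abs(q - 2) < 1e-8)) hq[which.min(abs(q - 2))] else NA_real_
  delta_h <- hq[1L] - hq[nq]
  flags <- character(0)
  if (delta_h < 0) flags <- c(flags, "negative_delta_h")
  if (any(diff(hq) > 1e-6)) flags <- c(flags, "nonmonotone_hq")

  structure(list(
    q = q, scales = scales, Fq = Fq, hq = hq, hq_se = hq_se, r2 = r2,
    H = H, delta_h = delta_h, tau = q * hq - 1,
    order = order, fit_scales = scales[in_fit], n = n, flags = flags
  ), class = "mfdfa")
}

#' Renyi mass scaling exponents from generalized Hurst exponents
#'
#' `tau(q) = q * h(q) - 1`; the inverse `h = (tau + 1)/q` holds for
#' `q != 0`, and `tau(0) = -1` by normalization.
#'
#' @param hq generalized Hurst exponents.
#' @param q matching moment orders.
#' @return numeric vector of tau(q).
#' @export
renyi_tau <- function(hq, q) {
  if (length(hq) != length(q)) {
    stop("`hq` and `q` must have equal length", call. = FALSE)
  }
  q * hq - 1
}

#' Singularity spectrum by Legendre transform
#'
#' From the Renyi exponents `tau(q)` of an MF-DFA fit, computes the
#' singularity strengths `alpha(q) = dtau/dq` (central finite
#' differences, one-sided at the ends) and the spectrum
#' `f(alpha) = q * alpha - tau(q)`. Summary descriptors:
#' `alpha0` (alpha at the spectrum peak, the dominant exponent),
#' `delta_alpha = max(alpha) - min(alpha)` (multifractal width),
#' `delta_f = f(alpha_min) - f(alpha_max)` (which extreme fluctuation
#' rate is the more probable; positive means the strongest fluctuations
#' dominate), and the asymmetry
#' `B = ((alpha_max - alpha0) - (alpha0 - alpha_min)) / delta_alpha`
#' (positive = right-skewed spectrum). A spectrum that is not
#' single-peaked (non-concave tau) is flagged, not rejected.
#'
#' @param fit an `"mfdfa"` object, or a list with elements `tau` and `q`
#'   (at least 7 q points).
#' @return object of class `"singularity_spectrum"`: list with `alpha`,
#'   `f_alpha`, `q`, `alpha0`, `delta_alpha`, `delta_f`, `B`, `flags`.
#' @examples
#' fit <- mfdfa(gen_binomial_cascade(0.6, 12), scale_max = 2^9)
#' sp <- singularity_spectrum(fit)
#' sp$delta_alpha
#' @export
singularity_spectrum <- function(fit) {
  tau <- fit$tau
  q <- fit$q
  if (is.null(tau) || is.null(q) || length(q) < 7L) {
    stop("need `tau` and `q` on at least 7 q points", call. = FALSE)
  }
  n <- length(q)
  alpha <- numeric(n)
  alpha[2:(n - 1)] <- (tau[3:n] - tau[1:(n - 2)]) / (q[3:n] - q[1:(n - 2)])
  alpha[1] <- (tau[2] - tau[1]) / (q[2] - q[1])
  alpha[n] <- (tau[n] - tau[n - 1]) / (q[n] - q[n - 1])
  f <- q * alpha - tau

  i_min <- which.min(alpha)
  i_max <- which.max(alpha)
  alpha0 <- alpha[which.max(f)]
  delta_alpha <- alpha[i_max] - alpha[i_min]
  flags <- character(0)
  # single-peaked iff alpha is non-increasing in q (tau concave)
  if (any(diff(alpha) > 1e-6)) flags <- c(flags, "nonconcave_tau")
  if (max(f) > 1 + 0.05) flags <- c(flags, "f_exceeds_support_dimension")
  # a width below numerical resolution is a point spectrum: no asymmetry
  B <- if (delta_alpha > 1e-8) {
    ((alpha[i_max] - alpha0) - (alpha0 - alpha[i_min])) / delta_alpha
  } else 0
  structure(list(
    alpha = alpha, f_alpha = f, q = q, alpha0 = alpha0,
    delta_alpha = delta_alpha, delta_f = f[i_min] - f[i_max],
    B = B, flags = flags
  ), class = "singularity_spectrum")
}

#' One-row multifractal summary
#'
#' Collects the six descriptors used to characterize a series —
#' `H`, `delta_h`, `alpha0`, `delta_alpha`, `delta_f`, `B` — into a
#' one-row data.frame, convenient for per-animal tables.
#'
#' @param fit an `"mfdfa"` object.
#' @param spectrum optional precomputed [singularity_spectrum()] of
#'   `fit`.
#' @return one-row data.frame.
#' @export
mfdfa_summary_row <- function(fit, spectrum = singularity_spectrum(fit)) {
  data.frame(H = fit$H, delta_h = fit$delta_h, alpha0 = spectrum$alpha0,
             delta_alpha = spectrum$delta_alpha,
             delta_f = spectrum$delta_f, B = spectrum$B)
}

#' @export
print.mfdfa <- function(x, ...) {
  cat("Multifractal DFA fit\n")
  cat(sprintf("  series length %d, detrend order %d, %d scales [%d, %d], %d q values in [%g, %g]\n",
              x$n, x$order, length(x$scales), min(x$scales), max(x$scales),
              length(x$q), min(x$q), max(x$q)))
  cat(sprintf("  H = h(2) = %.4f   delta_h = %.4f   median R^2 = %.4f\n",
              x$H, x$delta_h, stats::median(x$r2)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.mfdfa <- function(object, ...) {
  setNames(object$hq, format(object$q, trim = TRUE))
}

#' @export
summary.mfdfa <- function(object, ...) {
  sp <- singularity_spectrum(object)
  out <- list(fit = object, spectrum = sp,
              descriptors = mfdfa_summary_row(object, sp))
  class(out) <- "summary.mfdfa"
  out
}

#' @export
print.summary.mfdfa <- function(x, ...) {
  print(x$fit)
  d <- x$descriptors
  cat(sprintf("  singularity spectrum: alpha0 = %.4f  delta_alpha = %.4f  delta_f = %.4f  B = %.3f\n",
              d$alpha0, d$delta_alpha, d$delta_f, d$B))
  if (length(x$spectrum$flags)) {
    cat("  spectrum flags:", paste(x$spectrum$flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn mfdfa diagnostic plot: fluctuation functions, h(q) and
#'   the singularity spectrum.
#' @param show_q q values whose `F_q(s)` curves are drawn (default
#'   -5, 0, 2, 5 where available).
#' @param ... unused.
#' @export
plot.mfdfa <- function(x, show_q = c(-5, 0, 2, 5), ...) {
  op <- par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  rows <- vapply(show_q, function(qq) which.min(abs(x$q - qq)), 1L)
  rows <- unique(rows)
  matplot(log(x$scales), t(log(x$Fq[rows, , drop = FALSE])), type = "b",
          pch = 1, lty = 1, xlab = "ln s", ylab = "ln Fq(s)",
          main = "Fluctuation functions")
  legend("topleft", legend = paste("q =", x$q[rows]), col = seq_along(rows),
         lty = 1, bty = "n", cex = 0.8)
  plot(x$q, x$hq, type = "b", pch = 16, xlab = "q", ylab = "h(q)",
       main = "Generalized Hurst")
  abline(h = x$H, lty = 2)
  sp <- singularity_spectrum(x)
  plot(sp$alpha, sp$f_alpha, type = "b", pch = 16, xlab = expression(alpha),
       ylab = expression(f(alpha)), main = "Singularity spectrum")
  invisible(x)
}

#' @export
print.singularity_spectrum <- function(x, ...) {
  cat(sprintf("Singularity spectrum: alpha0 = %.4f, delta_alpha = %.4f, delta_f = %.4f, B = %.3f\n",
              x$alpha0, x$delta_alpha, x$delta_f, x$B))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.singularity_spectrum <- function(x, ...) {
  plot(x$alpha, x$f_alpha, type = "b", pch = 16,
       xlab = expression(alpha), ylab = expression(f(alpha)), ...)
  abline(v = x$alpha0, lty = 2)
  invisible(x)
}
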