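# internal helpers shared across modules

# Evaluate `code` under set.seed(seed) without clobbering the caller's RNG
# stream; seed = NULL leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child-seed scheme: fold indices into the parent seed so
# each pipeline stage/replicate gets its own reproducible stream. Kept
# strictly below 2^31 - 1 (R integer seeds are 32-bit).
child_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in idx) s <- (s * 31 + as.double(i) + 1) %% 2147483647
  as.integer(s)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  if (!ok) {
    stop(sprintf("`%s` = %g is outside its allowed range (%g, %g)",
                 name, x, lower, upper), call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  }
  invisible(x)
}

check_finite_vector <- function(x, name, min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len) {
    stop(sprintf("`%s` must be a numeric vector of length >= %d",
                 name, min_len), call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- which(!is.finite(x))
    stop(sprintf("`%s` contains non-finite values at indices: %s",
                 name, paste(head(bad, 10L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

fmt_idx <- function(idx, max_show = 10L) {
  shown <- paste(head(idx, max_show), collapse = ", ")
  if (length(idx) > max_show) shown <- paste0(shown, ", ...")
  shown
}
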