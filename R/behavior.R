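#' Recognition index
#'
#' Ratio of the time spent exploring the target stimulus (novel partner,
#' moved object, novel object, ...) to the total exploration time:
#' `RI = t_target / (t_target + t_reference)`, in \[0, 1\]. Values at or
#' below 0.5 indicate indifference — absence of social affiliation or of
#' recognition memory, depending on the task.
#'
#' @param t_target time with the target stimulus, seconds (>= 0);
#'   vectorized.
#' @param t_reference time with the reference stimulus, seconds (>= 0).
#' @return recognition index in \[0, 1\].
#' @examples
#' recognition_index(210.2, 30.12)  # ~0.87
#' @export
recognition_index <- function(t_target, t_reference) {
  if (length(t_target) != length(t_reference)) {
    stop("`t_target` and `t_reference` must have equal length",
         call. = FALSE)
  }
  if (any(t_target < 0) || any(t_reference < 0)) {
    stop("exploration times must be nonnegative", call. = FALSE)
  }
  tot <- t_target + t_reference
  if (any(tot == 0)) {
    stop(sprintf("both times are zero at indices: %s (RI undefined)",
                 fmt_idx(which(tot == 0))), call. = FALSE)
  }
  t_target / tot
}

new_group_ttest <- function(t, df, p, estimate, method) {
  structure(list(t = t, df = df, p = p, estimate = estimate,
                 method = method), class = "group_ttest")
}

#' Pooled two-sample t-test from printed summary statistics
#'
#' Student (pooled-variance) unpaired t computed from group means, SEMs
#' and sizes, as needed to recompute published comparisons from a
#' "mean +/- SEM" table. The group SD is recovered as `sem * sqrt(n)`;
#' for equal group sizes the statistic reduces to
#' `(mean_1 - mean_2) / sqrt(sem_1^2 + sem_2^2)` with
#' `df = n_1 + n_2 - 2`. The sign convention is group 1 minus group 2
#' and p-values are two-sided.
#'
#' @param mean_1,sem_1,n_1 group 1 mean, standard error (> 0), size
#'   (>= 2).
#' @param mean_2,sem_2,n_2 group 2 summaries.
#' @return object of class `"group_ttest"`: list with `t`, `df`, `p`,
#'   `estimate` (the two means), `method`.
#' @examples
#' t_from_summary(21.74, 3.66, 12, 7.86, 2.75, 12)  # t ~ 3.03, df 22
#' @export
t_from_summary <- function(mean_1, sem_1, n_1, mean_2, sem_2, n_2) {
  check_scalar(sem_1, "sem_1", lower = 0, strict = TRUE)
  check_scalar(sem_2, "sem_2", lower = 0, strict = TRUE)
  check_scalar(n_1, "n_1", lower = 2, integer = TRUE)
  check_scalar(n_2, "n_2", lower = 2, integer = TRUE)
  s1 <- sem_1 * sqrt(n_1)
  s2 <- sem_2 * sqrt(n_2)
  df <- n_1 + n_2 - 2
  sp2 <- ((n_1 - 1) * s1^2 + (n_2 - 1) * s2^2) / df
  t <- (mean_1 - mean_2) / sqrt(sp2 * (1 / n_1 + 1 / n_2))
  p <- 2 * pt(-abs(t), df)
  new_group_ttest(t, df, p, c(mean_1 = mean_1, mean_2 = mean_2),
                  "pooled t from summary statistics")
}

#' Unpaired two-sample t-test from raw group values
#'
#' Pooled-variance (Student) unpaired t by default, Welch optionally;
#' agrees with [t_from_summary()] applied to the groups' own mean/SEM.
#' Sign convention: group 1 minus group 2; two-sided p.
#'
#' @param x1,x2 numeric vectors, each of length >= 2.
#' @param welch if `TRUE`, use the Welch (unequal-variance) test.
#' @return object of class `"group_ttest"`.
#' @export
t_from_raw <- function(x1, x2, welch = FALSE) {
  check_finite_vector(x1, "x1", min_len = 2L)
  check_finite_vector(x2, "x2", min_len = 2L)
  if (var(x1) == 0 && var(x2) == 0) {
    if (mean(x1) == mean(x2)) {
      return(new_group_ttest(0, length(x1) + length(x2) - 2, 1,
                             c(mean_1 = mean(x1), mean_2 = mean(x2)),
                             "pooled t (degenerate: zero variance)"))
    }
    stop("zero pooled variance with unequal means: t undefined",
         call. = FALSE)
  }
  ht <- t.test(x1, x2, var.equal = !welch)
  new_group_ttest(unname(ht$statistic), unname(ht$parameter),
                  ht$p.value,
                  c(mean_1 = mean(x1), mean_2 = mean(x2)),
                  if (welch) "Welch t" else "pooled t")
}

#' @export
print.group_ttest <- function(x, ...) {
  cat(sprintf("%s: t = %.3f, df = %.4g, p = %.4g (means %.4g vs %.4g)\n",
              x$method, x$t, x$df, x$p,
              x$estimate[["mean_1"]], x$estimate[["mean_2"]]))
  invisible(x)
}

#' Two-group behavioral summary table
#'
#' For each measure in a tidy per-animal table, reports the group means
#' and SEMs, the unpaired t statistic (group 1 minus group 2, in the
#' order of the factor levels), degrees of freedom, two-sided p, and
#' two-tier significance stars (`*` p < 0.05, `**` p < 0.01).
#'
#' @param table tidy data.frame: one row per animal, a group column and
#'   numeric measure columns.
#' @param group_col name of the group column (default `"group"`).
#' @param measures measure column names (default: all numeric columns
#'   except `group_col`).
#' @param welch use Welch instead of pooled t.
#' @return data.frame, one row per measure: `measure`, `mean_1`,
#'   `sem_1`, `mean_2`, `sem_2`, `t`, `df`, `p`, `stars`.
#' @examples
#' tab <- gen_two_group_table(behavior_reference_summary(), seed = 1)
#' head(behavior_report(tab))
#' @export
behavior_report <- function(table, group_col = "group", measures = NULL,
                            welch = FALSE) {
  if (!group_col %in% names(table)) {
    stop(sprintf("missing group column `%s`", group_col), call. = FALSE)
  }
  g <- factor(table[[group_col]])
  if (nlevels(g) != 2L) {
    stop("exactly two groups are required", call. = FALSE)
  }
  if (anyNA(g)) stop("missing group labels", call. = FALSE)
  if (is.null(measures)) {
    measures <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                        group_col)
  }
  sem <- function(v) sd(v) / sqrt(length(v))
  rows <- lapply(measures, function(m) {
    v1 <- table[[m]][g == levels(g)[1]]
    v2 <- table[[m]][g == levels(g)[2]]
    tt <- t_from_raw(v1, v2, welch = welch)
    data.frame(measure = m,
               mean_1 = mean(v1), sem_1 = sem(v1),
               mean_2 = mean(v2), sem_2 = sem(v2),
               t = tt$t, df = tt$df, p = tt$p,
               stars = if (tt$p < 0.01) "**" else if (tt$p < 0.05) "*" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
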