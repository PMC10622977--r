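#' Manhattan dissimilarity matrix
#'
#' Pairwise Manhattan (city-block) distances
#' `d(i, j) = sum_k |x_ik - x_jk|` between animals. Because behavioral
#' and physiological variables live on incommensurable scales (seconds,
#' counts, mL O2 h^-1), columns are z-score standardized first by
#' default.
#'
#' @param x numeric matrix or data.frame (rows = animals); non-numeric
#'   columns such as ids or group labels must be removed first (see
#'   [integrate_animals()]).
#' @param standardize z-score columns before computing distances
#'   (default `TRUE`).
#' @return a `"dist"` object.
#' @export
manhattan_distances <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) {
    stop("`x` must be numeric", call. = FALSE)
  }
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)
    stop(sprintf("missing values at (row, col): %s",
                 paste(apply(head(bad, 10L), 1L, paste, collapse = ","),
                       collapse = "; ")), call. = FALSE)
  }
  if (standardize) {
    x <- scale(x)
    # constant columns scale to NaN; they carry no information
    x[, apply(!is.finite(x), 2, any)] <- 0
  }
  dist(x, method = "manhattan")
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a dissimilarity matrix: Gower double
#' centering of `-D^2/2` followed by eigendecomposition; coordinates are
#' eigenvectors scaled by the square root of their (positive)
#' eigenvalues. Manhattan dissimilarities are generally non-Euclidean,
#' so negative eigenvalues can occur; they are reported and excluded
#' from the variance-explained denominator.
#'
#' @param d a `"dist"` object or symmetric distance matrix, n >= 3.
#' @return object of class `"mf_pcoa"`: `points` (coordinates, axes
#'   ordered by decreasing eigenvalue), `eig` (all eigenvalues),
#'   `rel_eig` (proportion of summed positive eigenvalues per retained
#'   axis), `n_negative`, `negative_sum`.
#' @examples
#' x <- matrix(rnorm(30), 10)
#' ord <- pcoa(manhattan_distances(x))
#' ord$rel_eig
#' @export
pcoa <- function(d) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (is.null(n) || n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (all(d == 0)) stop("all distances are zero", call. = FALSE)
  fit <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))
  pts <- fit$points
  eig <- fit$eig
  pos <- eig[eig > sqrt(.Machine$double.eps) * max(abs(eig))]
  k <- ncol(pts)
  structure(list(
    points = pts,
    eig = eig,
    rel_eig = eig[seq_len(k)] / sum(pos),
    n_negative = sum(eig < -sqrt(.Machine$double.eps) * max(abs(eig))),
    negative_sum = sum(eig[eig < 0])
  ), class = "mf_pcoa")
}

#' @export
print.mf_pcoa <- function(x, ...) {
  k <- min(4L, length(x$rel_eig))
  cat(sprintf("PCoA ordination: %d points, %d axes retained\n",
              nrow(x$points), ncol(x$points)))
  cat(sprintf("  variance explained (first %d axes): %s\n", k,
              paste(sprintf("%.1f%%", 100 * x$rel_eig[seq_len(k)]),
                    collapse = ", ")))
  if (x$n_negative > 0) {
    cat(sprintf("  %d negative eigenvalues (sum %.3g) excluded from the denominator\n",
                x$n_negative, x$negative_sum))
  }
  invisible(x)
}

#' @describeIn pcoa scatter of the first two axes, optionally colored
#'   by group.
#' @param x an `"mf_pcoa"` object.
#' @param groups optional factor of group labels per point.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mf_pcoa <- function(x, groups = NULL, ...) {
  lab <- sprintf("Axis %d (%.1f%%)", 1:2, 100 * x$rel_eig[1:2])
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  plot(x$points[, 1], x$points[, 2], col = col, pch = 16,
       xlab = lab[1], ylab = lab[2], ...)
  if (!is.null(groups)) {
    legend("topright", legend = levels(factor(groups)),
           col = seq_len(nlevels(factor(groups))), pch = 16, bty = "n")
  }
  invisible(x)
}

permanova_ss_within <- function(d2, groups) {
  ss <- 0
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    ss <- ss + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ss
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-factor PERMANOVA on a dissimilarity matrix. Sums of squares are
#' computed from the distances directly
#' (`SS_total = sum of squared pairwise distances / n`, within-group
#' analogously per group), the pseudo-F is
#' `(SS_between/df_between) / (SS_within/df_within)`, and the p-value is
#' obtained by permuting group labels with the add-one convention
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations)`. When the
#' number of distinct two-group label arrangements is small (or
#' `complete = TRUE`), all arrangements are enumerated instead and
#' `p = #\{F_perm >= F_obs\} / n_arrangements` (the identity counts
#' itself).
#'
#' @param d a `"dist"` object or symmetric distance matrix.
#' @param groups factor of group labels (>= 2 groups, each of size
#'   >= 2).
#' @param n_permutations Monte-Carlo permutations (default 9999).
#' @param seed integer seed for the permutation stream.
#' @param complete force (`TRUE`) or forbid (`FALSE`) complete
#'   enumeration; default `NULL` enumerates two-group designs with at
#'   most 10000 distinct arrangements.
#' @return object of class `"permanova"`: `F`, `p`, `df_between`,
#'   `df_within`, `ss_between`, `ss_within`, `ss_total`, `method`,
#'   `n_permutations`.
#' @examples
#' x <- matrix(rnorm(48), 24)
#' g <- factor(rep(c("A", "B"), each = 12))
#' permanova(dist(x), g, n_permutations = 199, seed = 1)
#' @export
permanova <- function(d, groups, n_permutations = 9999, seed = NULL,
                      complete = NULL) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  groups <- factor(groups)
  if (length(groups) != n) {
    stop("`groups` length must match the distance matrix", call. = FALSE)
  }
  tab <- table(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(tab < 2L)) {
    stop(sprintf("singleton group(s): %s",
                 paste(names(tab)[tab < 2], collapse = ", ")), call. = FALSE)
  }
  check_scalar(n_permutations, "n_permutations", lower = 1, integer = TRUE)

  d2 <- as.matrix(d)^2
  ss_total <- sum(d2) / (2 * n)
  a <- nlevels(groups)
  df_b <- a - 1L
  df_w <- n - a
  f_of <- function(g) {
    ss_w <- permanova_ss_within(d2, g)
    ((ss_total - ss_w) / df_b) / (ss_w / df_w)
  }
  f_obs <- f_of(groups)

  n_arr <- if (a == 2L) choose(n, tab[1]) else Inf
  do_complete <- isTRUE(complete) || (is.null(complete) && n_arr <= 10000)
  if (isFALSE(complete)) do_complete <- FALSE
  if (do_complete && a == 2L) {
    combs <- utils::combn(n, tab[1])
    f_perm <- apply(combs, 2L, function(idx) {
      g <- factor(replace(rep(levels(groups)[2], n), idx, levels(groups)[1]),
                  levels = levels(groups))
      f_of(g)
    })
    p <- mean(f_perm >= f_obs - 1e-12)
    method <- sprintf("complete enumeration (%d arrangements)", ncol(combs))
    nperm <- ncol(combs)
  } else {
    f_perm <- with_seed(seed, {
      vapply(seq_len(n_permutations),
             function(i) f_of(sample(groups)), numeric(1))
    })
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_permutations)
    method <- "Monte-Carlo permutation"
    nperm <- n_permutations
  }
  structure(list(
    F = f_obs, p = p, df_between = df_b, df_within = df_w,
    ss_between = ss_total - permanova_ss_within(d2, groups),
    ss_within = permanova_ss_within(d2, groups), ss_total = ss_total,
    method = method, n_permutations = nperm
  ), class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s): pseudo-F(%d, %d) = %.3f, p = %.4g\n",
              x$method, x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Join behavioral, physiological and multifractal variables per animal
#'
#' Assembles the feature matrix for the integrative ordination: joins a
#' tidy behavioral table, a physiology table (e.g. BMR and body mass)
#' and optional per-animal multifractal summaries by animal id,
#' validating that ids match one-to-one.
#'
#' @param behavior data.frame with `animal_id`, a group column and
#'   numeric measures.
#' @param physiology data.frame with `animal_id` and numeric columns.
#' @param mf optional data.frame with `animal_id` and numeric columns
#'   (e.g. from [mfdfa_summary_row()]).
#' @param id_col id column name (default `"animal_id"`).
#' @param group_col group column name in `behavior` (default
#'   `"group"`).
#' @param variables optional character vector restricting the feature
#'   columns.
#' @return data.frame: `animal_id`, `group`, then numeric feature
#'   columns; one row per animal.
#' @export
integrate_animals <- function(behavior, physiology, mf = NULL,
                              id_col = "animal_id", group_col = "group",
                              variables = NULL) {
  pieces <- list(behavior = behavior, physiology = physiology)
  if (!is.null(mf)) pieces$mf <- mf
  for (nm in names(pieces)) {
    p <- pieces[[nm]]
    if (!id_col %in% names(p)) {
      stop(sprintf("`%s` lacks id column `%s`", nm, id_col), call. = FALSE)
    }
    dup <- p[[id_col]][duplicated(p[[id_col]])]
    if (length(dup)) {
      stop(sprintf("duplicate ids in `%s`: %s", nm,
                   paste(unique(dup), collapse = ", ")), call. = FALSE)
    }
  }
  ids <- behavior[[id_col]]
  for (nm in setdiff(names(pieces), "behavior")) {
    other <- pieces[[nm]][[id_col]]
    miss <- setdiff(ids, other)
    extra <- setdiff(other, ids)
    if (length(miss) || length(extra)) {
      stop(sprintf("id mismatch with `%s` — missing: %s | unexpected: %s",
                   nm,
                   if (length(miss)) paste(miss, collapse = ", ") else "none",
                   if (length(extra)) paste(extra, collapse = ", ") else "none"),
           call. = FALSE)
    }
  }
  out <- behavior
  for (nm in setdiff(names(pieces), "behavior")) {
    out <- merge(out, pieces[[nm]], by = id_col, sort = FALSE)
  }
  out <- out[match(ids, out[[id_col]]), ]
  num <- names(out)[vapply(out, is.numeric, TRUE)]
  keep <- if (is.null(variables)) num else {
    missing_vars <- setdiff(variables, num)
    if (length(missing_vars)) {
      stop(sprintf("unknown variables: %s",
                   paste(missing_vars, collapse = ", ")), call. = FALSE)
    }
    variables
  }
  res <- cbind(out[c(id_col, group_col)], out[keep])
  if (anyNA(res[keep])) {
    stop("missing values in the assembled feature matrix", call. = FALSE)
  }
  rownames(res) <- NULL
  res
}
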