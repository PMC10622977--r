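#' Default pipeline configuration
#'
#' Builds the configuration list consumed by [run_all()]: a fully
#' synthetic two-group study (control vs treatment, 12 animals each)
#' with multifractal increments planted in the respirometry traces and
#' group shifts planted in the behavioral measures (the published
#' reference summary by default). Every field can be overridden, and
#' [run_all()] also accepts a YAML or JSON file with the same structure.
#'
#' The planted contrast mirrors the study design qualitatively: the
#' control group receives cascade increments with a stronger multiplier
#' asymmetry (wider singularity spectrum) than the treatment group.
#'
#' @param seed global seed; per-stage and per-animal seeds are derived
#'   from it deterministically.
#' @param out_dir output directory for stage CSVs and the manifest.
#' @param n_per_group animals per group (default 12).
#' @return nested configuration list.
#' @export
default_run_config <- function(seed = 1, out_dir = tempfile("metabofract_run_"),
                               n_per_group = 12) {
  list(
    seed = seed,
    out_dir = out_dir,
    n_per_group = n_per_group,
    group_labels = c("CTRL", "TREAT"),
    series = list(
      duration_s = 2^15, dt_s = 1, baseline_vo2 = 250,
      drift_amplitude = 0.05, increment_scale = 0.002,
      source = "cascade", cascade_p = c(0.65, 0.58), fgn_hurst = 0.8
    ),
    mfdfa = list(
      q_min = -5, q_max = 5, q_step = 0.25,
      order = 2, scale_min = 16, scale_max_div = 8, n_scales = 20
    ),
    surrogates = list(enabled = FALSE, n_replicates = 19),
    behavior = list(measures = NULL),  # NULL = published reference summary
    physiology = list(mb_mean_g = 180, mb_sd_g = 15),
    bmr = list(window_s = 600, cv_threshold = 0.05),
    multivariate = list(standardize = TRUE, n_permutations = 9999,
                        include_mfdfa = TRUE)
  )
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    }
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("invalid config", call. = FALSE)
  base <- default_run_config(seed = config$seed %||% 1)
  modifyList(base, config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a two-column time-series CSV
#'
#' Strict reader for the package's time-series format: a header line
#' `t_seconds,vo2_ml_per_h` (units carried in the column names) followed
#' by numeric rows. Malformed rows raise an error with the line number.
#'
#' @param path CSV path.
#' @return data.frame with columns `t_seconds`, `vo2_ml_per_h`.
#' @seealso [write_timeseries_csv()]
#' @export
load_timeseries_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  hdr <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (!identical(trimws(hdr), c("t_seconds", "vo2_ml_per_h"))) {
    stop("header must be `t_seconds,vo2_ml_per_h` (units are part of the contract)",
         call. = FALSE)
  }
  x <- read.csv(path, colClasses = "character")
  for (col in names(x)) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(is.na(v) & nzchar(trimws(x[[col]])) | !nzchar(trimws(x[[col]])))
    if (length(bad)) {
      stop(sprintf("malformed value in column `%s` at line %d", col,
                   bad[1] + 1L), call. = FALSE)
    }
    x[[col]] <- v
  }
  x
}

#' Write a two-column time-series CSV
#'
#' @param x data.frame with `t_seconds` and `vo2_ml_per_h` columns.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(x, path) {
  if (!all(c("t_seconds", "vo2_ml_per_h") %in% names(x))) {
    stop("`x` must have columns t_seconds, vo2_ml_per_h", call. = FALSE)
  }
  # %.17g guarantees a lossless read(write(x)) round trip for doubles
  lines <- c("t_seconds,vo2_ml_per_h",
             sprintf("%.17g,%.17g", x$t_seconds, x$vo2_ml_per_h))
  writeLines(lines, path)
  invisible(path)
}

#' Run the full synthetic-study pipeline
#'
#' Orchestrates the complete chain from one configuration (a list from
#' [default_run_config()], possibly modified, or a path to a YAML/JSON
#' file with the same structure): simulate per-animal respirometry
#' traces, form log-ratio increments and extract BMR, fit MF-DFA and the
#' singularity spectrum per animal, optionally run the shuffle/AAFT
#' source attribution, simulate the behavioral table and its two-group
#' report, join everything into a feature matrix, and run the
#' Manhattan-distance PCoA and PERMANOVA. All stage outputs are written
#' as CSV/JSON to `out_dir`, together with a manifest (parameters,
#' seeds, file checksums, warnings, stage status). The run is
#' deterministic for a fixed seed.
#'
#' @param config configuration list or file path; see
#'   [default_run_config()].
#' @return the manifest, invisibly (a list; also written as
#'   `manifest.json`). Key results are attached under
#'   `$results` (mfdfa summary table, behavior report, PERMANOVA).
#' @examples
#' \donttest{
#' cfg <- default_run_config(seed = 1)
#' cfg$series$duration_s <- 2^12
#' cfg$multivariate$n_permutations <- 199
#' man <- run_all(cfg)
#' man$results$permanova$p
#' }
#' @export
run_all <- function(config) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("metabofract")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list(), warnings = character(0), files = list()
  )
  seed <- cfg$seed
  labels <- cfg$group_labels
  n <- cfg$n_per_group
  ids <- sprintf("%s_%02d", rep(labels, each = n), rep(seq_len(n), 2))
  grp <- factor(rep(labels, each = n), levels = labels)

  note <- function(w) {
    manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  finish_stage <- function(name, status = "ok") {
    manifest$stages[[name]] <<- status
  }
  write_out <- function(obj, file) {
    path <- file.path(cfg$out_dir, file)
    if (is.data.frame(obj)) {
      write.csv(obj, path, row.names = FALSE)
    } else {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
    manifest$files[[file]] <<- unname(tools::md5sum(path))
    path
  }
  fail <- function(stage, e) {
    finish_stage(stage, paste("failed:", conditionMessage(e)))
    manifest$completed <- FALSE
    manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stop(sprintf("pipeline stage `%s` failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  withCallingHandlers({
    ## ---- simulate respirometry + mfdfa per animal --------------------
    stage <- "respirometry_mfdfa"
    res <- tryCatch({
      qgrid <- seq(cfg$mfdfa$q_min, cfg$mfdfa$q_max, cfg$mfdfa$q_step)
      ns <- floor(cfg$series$duration_s / cfg$series$dt_s)
      smax <- floor((ns - 1) / cfg$mfdfa$scale_max_div)
      mf_rows <- vector("list", length(ids))
      bmr_rows <- vector("list", length(ids))
      src_rows <- vector("list", length(ids))
      for (i in seq_along(ids)) {
        p_i <- rep(cfg$series$cascade_p, length.out = 2)[as.integer(grp[i])]
        tr <- gen_respirometry_trace(
          duration_s = cfg$series$duration_s, dt_s = cfg$series$dt_s,
          baseline_vo2 = cfg$series$baseline_vo2,
          drift_amplitude = cfg$series$drift_amplitude,
          increment_source = cfg$series$source,
          increment_scale = cfg$series$increment_scale,
          cascade_p = p_i, fgn_hurst = cfg$series$fgn_hurst,
          seed = child_seed(seed, 1, i))
        inc <- log_ratio_increments(tr)
        bmr <- extract_bmr(tr$vo2_ml_per_h, window_s = cfg$bmr$window_s,
                           dt_s = cfg$series$dt_s,
                           cv_threshold = cfg$bmr$cv_threshold)
        fit <- mfdfa(inc, q = qgrid, order = cfg$mfdfa$order,
                     scale_min = cfg$mfdfa$scale_min, scale_max = smax,
                     n_scales = cfg$mfdfa$n_scales)
        mf_rows[[i]] <- cbind(animal_id = ids[i], mfdfa_summary_row(fit))
        bmr_rows[[i]] <- data.frame(animal_id = ids[i], bmr = bmr$bmr,
                                    window_start_s = bmr$window_start_s,
                                    window_end_s = bmr$window_end_s,
                                    stable = bmr$stable)
        if (isTRUE(cfg$surrogates$enabled)) {
          src <- multifractality_source(
            inc, n_replicates = cfg$surrogates$n_replicates,
            seed = child_seed(seed, 2, i), q = qgrid,
            order = cfg$mfdfa$order, scale_min = cfg$mfdfa$scale_min,
            scale_max = smax, n_scales = cfg$mfdfa$n_scales)
          src_rows[[i]] <- data.frame(
            animal_id = ids[i],
            delta_alpha_original = src$delta_alpha_original,
            delta_alpha_shuffled = src$delta_alpha_shuffled,
            delta_alpha_surrogate = src$delta_alpha_surrogate,
            shuffle_ratio = src$shuffle_ratio,
            surrogate_ratio = src$surrogate_ratio,
            verdict = src$verdict)
        }
      }
      list(mf = do.call(rbind, mf_rows), bmr = do.call(rbind, bmr_rows),
           src = if (isTRUE(cfg$surrogates$enabled)) do.call(rbind, src_rows))
    }, error = function(e) fail(stage, e))
    write_out(res$mf, "mfdfa_summary.csv")
    write_out(res$bmr, "bmr_estimates.csv")
    if (!is.null(res$src)) write_out(res$src, "surrogate_report.csv")
    finish_stage(stage)

    ## ---- behavior ----------------------------------------------------
    stage <- "behavior"
    beh <- tryCatch({
      measures <- cfg$behavior$measures %||% behavior_reference_summary()
      tab <- gen_two_group_table(measures, n_per_group = n,
                                 seed = child_seed(seed, 3),
                                 group_labels = labels)
      list(table = tab, report = behavior_report(tab))
    }, error = function(e) fail(stage, e))
    write_out(beh$table, "behavior_table.csv")
    write_out(beh$report, "behavior_report.csv")
    finish_stage(stage)

    ## ---- integrate + ordination --------------------------------------
    stage <- "multivariate"
    mv <- tryCatch({
      phys <- data.frame(
        animal_id = ids,
        bmr = res$bmr$bmr,
        mb_g = with_seed(child_seed(seed, 4),
                         rnorm(length(ids), cfg$physiology$mb_mean_g,
                               cfg$physiology$mb_sd_g)))
      mf_feat <- if (isTRUE(cfg$multivariate$include_mfdfa)) res$mf
      feat <- integrate_animals(beh$table, phys, mf = mf_feat)
      X <- feat[setdiff(names(feat), c("animal_id", "group"))]
      D <- manhattan_distances(X,
                               standardize = isTRUE(cfg$multivariate$standardize))
      ord <- pcoa(D)
      pmv <- permanova(D, feat$group,
                       n_permutations = cfg$multivariate$n_permutations,
                       seed = child_seed(seed, 5), complete = FALSE)
      list(feat = feat, ord = ord, permanova = pmv)
    }, error = function(e) fail(stage, e))
    coords <- data.frame(animal_id = ids, group = as.character(grp),
                         mv$ord$points[, seq_len(min(4, ncol(mv$ord$points)))])
    names(coords)[-(1:2)] <- paste0("axis", seq_len(ncol(coords) - 2L))
    write_out(coords, "pcoa_coordinates.csv")
    write_out(data.frame(eigenvalue = mv$ord$eig), "pcoa_eigenvalues.csv")
    write_out(list(F = mv$permanova$F, p = mv$permanova$p,
                   df_between = mv$permanova$df_between,
                   df_within = mv$permanova$df_within,
                   n_permutations = mv$permanova$n_permutations),
              "permanova.json")
    finish_stage(stage)
  }, warning = note)

  manifest$completed <- TRUE
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifest$results <- list(
    mfdfa_summary = res$mf,
    bmr = res$bmr,
    surrogate_report = res$src,
    behavior_report = beh$report,
    ordination = mv$ord,
    permanova = mv$permanova
  )
  jsonlite::write_json(
    manifest[setdiff(names(manifest), "results")],
    file.path(cfg$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(manifest)
}
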