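# Study-level orchestration: the session (chapter-based) analysis and the
# time-course (injection-based) analysis, both driven by a plain config list
# and fully reproducible under fixed seeds.

#' Configuration for a study pipeline
#'
#' A validated container for the inputs [run_session_study()] and
#' [run_timecourse_study()] consume. Only the fields a given analysis needs
#' must be present.
#'
#' @param participants Data frame of per-participant covariates, ratings and
#'   (optionally precomputed) physiological summaries.
#' @param rr_list Optional named list of [rr_series()], keyed by participant
#'   id; when present, physiological summaries are computed from the signals.
#' @param windows Optional [segment_windows()] used with `rr_list`.
#' @param aggregates Optional named list of label aggregates (see
#'   [window_average()]).
#' @param metrics Metrics computed from `rr_list`:
#'   any of `"hrv_amplitude"`, `"rmssd"`, `"hr"`.
#' @param correlations Data frame with columns `x`, `y` naming rating and
#'   physio columns to correlate (partial Spearman), plus optional `family`
#'   for FDR grouping.
#' @param covariates Character vector of covariate column names (default
#'   `c("age", "gender", "bmi")`).
#' @param group_compare Character vector of columns to compare between the
#'   levels of `participants$group` via the normality-gated test.
#' @param segmented Optional `list(x =, y =)` for the segmented regression.
#' @param mediation Optional `list(x =, m =, y =)` for bootstrap mediation.
#' @param normalize Min-max normalize analysis variables first (default TRUE,
#'   matching the correlation battery's preprocessing).
#' @param fdr Apply FDR within correlation families (default TRUE).
#' @param n_boot,seed Bootstrap size and seed for mediation.
#' @param post_window For the time-course study: post-injection averaging
#'   window in minutes, default `c(4, 20)`.
#' @param questionnaires For the time-course study: data frame `id` +
#'   questionnaire scale columns.
#' @return A list of class `study_config`.
#' @export
study_config <- function(participants = NULL, rr_list = NULL, windows = NULL,
                         aggregates = list(), metrics = "hrv_amplitude",
                         correlations = NULL,
                         covariates = c("age", "gender", "bmi"),
                         group_compare = character(0), segmented = NULL,
                         mediation = NULL, normalize = TRUE, fdr = TRUE,
                         n_boot = 5000, seed = 1,
                         post_window = c(4, 20), questionnaires = NULL) {
  cfg <- list(participants = participants, rr_list = rr_list,
              windows = windows, aggregates = aggregates, metrics = metrics,
              correlations = correlations, covariates = covariates,
              group_compare = group_compare, segmented = segmented,
              mediation = mediation, normalize = normalize, fdr = fdr,
              n_boot = n_boot, seed = seed, post_window = post_window,
              questionnaires = questionnaires)
  class(cfg) <- "study_config"
  cfg
}

need_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s: column(s) not found: %s", what,
                 paste(missing, collapse = ", ")))
}

metric_series_fun <- function(metric) {
  switch(metric,
         hrv_amplitude = function(rr) hrv_amplitude_timeseries(rr),
         rmssd = function(rr) sliding_rmssd(rr),
         hr = function(rr) sliding_hr(rr),
         stop("unknown metric: ", metric))
}

#' Run the session (chapter-based) study analysis
#'
#' Per participant: quality screening of the RR series (failures are dropped
#' and logged), metric time series, window averages over the configured
#' chapters and chapter aggregates. Study level: partial Spearman
#' correlations between ratings and physiological summaries (optionally
#' min-max normalized first, FDR-corrected within declared families),
#' normality-gated group comparisons, segmented regression with Davies test,
#' and bootstrap mediation for the configured triplet.
#'
#' @param cfg A [study_config()].
#' @return A list of class `study_report`: `participants` (analysis table),
#'   `exclusions`, `correlations`, `group_comparison`, `segmented`,
#'   `mediation`, `config`.
#' @export
run_session_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  pt <- cfg$participants
  if (is.null(pt)) stop("config must provide a participants table")
  exclusions <- data.frame(id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)

  # compute physiological summaries from raw RR series if provided
  if (!is.null(cfg$rr_list)) {
    if (is.null(cfg$windows)) stop("rr_list requires windows in the config")
    rows <- list()
    for (id in names(cfg$rr_list)) {
      rr <- cfg$rr_list[[id]]
      scr <- screen_quality(rr)
      if (scr$verdict == "exclude") {
        exclusions <- rbind(exclusions, data.frame(
          id = id, reason = sprintf("quality screen: %.0f%% poor windows",
                                    100 * scr$bad_frac)))
        next
      }
      vals <- list(id = id)
      for (metric in cfg$metrics) {
        ser <- metric_series_fun(metric)(scr$rr)
        wa <- window_average(ser, cfg$windows, cfg$aggregates)
        for (r in seq_len(nrow(wa)))
          vals[[paste(metric, wa$label[r], sep = ".")]] <- wa$mean[r]
      }
      rows[[id]] <- as.data.frame(vals, stringsAsFactors = FALSE,
                                  check.names = FALSE)
    }
    physio <- do.call(rbind, rows)
    pt <- merge(pt, physio, by = "id")
  }
  if (nrow(exclusions))
    pt <- pt[!pt$id %in% exclusions$id, , drop = FALSE]

  norm_col <- function(v) if (cfg$normalize) minmax_normalize(v) else v

  correlations <- NULL
  if (!is.null(cfg$correlations)) {
    rec <- cfg$correlations
    need_cols(pt, unique(c(rec$x, rec$y, cfg$covariates)), "correlations")
    correlations <- do.call(rbind, lapply(seq_len(nrow(rec)), function(k) {
      xv <- norm_col(pt[[rec$x[k]]]); yv <- norm_col(pt[[rec$y[k]]])
      res <- partial_spearman(xv, yv,
                              pt[, cfg$covariates, drop = FALSE])
      data.frame(x = rec$x[k], y = rec$y[k],
                 family = if ("family" %in% names(rec)) rec$family[k]
                          else "all",
                 rho = res$rho, ci_lo = res$ci95[1], ci_hi = res$ci95[2],
                 p = res$p, n = res$n, stringsAsFactors = FALSE)
    }))
    correlations$p_fdr <- if (cfg$fdr) {
      stats::ave(correlations$p, correlations$family,
                 FUN = fdr_adjust)
    } else correlations$p
  }

  group_comparison <- NULL
  if (length(cfg$group_compare)) {
    need_cols(pt, c("group", cfg$group_compare), "group_compare")
    gl <- unique(pt$group)
    if (length(gl) != 2) stop("group comparison needs exactly 2 groups")
    group_comparison <- do.call(rbind, lapply(cfg$group_compare,
                                              function(col) {
      a <- pt[[col]][pt$group == gl[1]]
      b <- pt[[col]][pt$group == gl[2]]
      test <- normality_gate(a, b)
      if (test == "mann_whitney") {
        mw <- mann_whitney(a, b)
        data.frame(variable = col, test = test, statistic = mw$U,
                   z = mw$z, p = mw$p, stringsAsFactors = FALSE)
      } else {
        tt <- stats::t.test(a, b)
        data.frame(variable = col, test = test,
                   statistic = unname(tt$statistic), z = NA_real_,
                   p = tt$p.value, stringsAsFactors = FALSE)
      }
    }))
  }

  segmented <- NULL
  if (!is.null(cfg$segmented)) {
    need_cols(pt, c(cfg$segmented$x, cfg$segmented$y, cfg$covariates),
              "segmented")
    # fitted on the original scales so the breakpoint is reported in rating
    # units (min-max scaling applies to the correlation battery only)
    segmented <- segmented_fit(pt[[cfg$segmented$x]],
                               pt[[cfg$segmented$y]],
                               pt[, cfg$covariates, drop = FALSE])
  }

  mediation <- NULL
  if (!is.null(cfg$mediation)) {
    need_cols(pt, c(cfg$mediation$x, cfg$mediation$m, cfg$mediation$y,
                    cfg$covariates), "mediation")
    mediation <- mediation_bootstrap(pt[[cfg$mediation$x]],
                                     pt[[cfg$mediation$m]],
                                     pt[[cfg$mediation$y]],
                                     pt[, cfg$covariates, drop = FALSE],
                                     n_boot = cfg$n_boot, seed = cfg$seed)
  }

  structure(list(participants = pt, exclusions = exclusions,
                 correlations = correlations,
                 group_comparison = group_comparison,
                 segmented = segmented, mediation = mediation,
                 config = cfg),
            class = "study_report")
}

#' Run the time-course (injection-based) study analysis
#'
#' Per participant: the HRV-amplitude time series over the whole session on
#' a common 1 s grid. Study level: the group-mean time course with standard
#' errors (suitable for a mean +/- SE plot), per-participant means over the
#' configured post-injection window (default minutes 4-20, skipping the
#' acute surge), and Spearman correlations of those means against every
#' questionnaire column, FDR-corrected.
#'
#' @param cfg A [study_config()] whose `rr_list` holds one session
#'   [rr_series()] per participant, with `injection_time` passed separately.
#' @param injection_time Injection time in seconds from session start
#'   (a scalar, or a named vector per participant).
#' @return A list of class `timecourse_report`: `timecourse` (grid, mean,
#'   se, n), `window_means`, `correlations`, `exclusions`, `config`.
#' @export
run_timecourse_study <- function(cfg, injection_time) {
  stopifnot(inherits(cfg, "study_config"))
  if (is.null(cfg$rr_list)) stop("config must provide rr_list")
  ids <- names(cfg$rr_list)
  inj <- if (length(injection_time) == 1)
    stats::setNames(rep(injection_time, length(ids)), ids)
  else injection_time

  exclusions <- data.frame(id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  series <- list()
  wmeans <- numeric(0)
  for (id in ids) {
    rr <- cfg$rr_list[[id]]
    scr <- screen_quality(rr)
    if (scr$verdict == "exclude") {
      exclusions <- rbind(exclusions, data.frame(
        id = id, reason = sprintf("quality screen: %.0f%% poor windows",
                                  100 * scr$bad_frac)))
      next
    }
    ser <- hrv_amplitude_timeseries(scr$rr)
    series[[id]] <- ser
    w <- segment_windows("post",
                         inj[[id]] + cfg$post_window[1] * 60,
                         inj[[id]] + cfg$post_window[2] * 60)
    wmeans[id] <- suppressWarnings(window_average(ser, w)$mean)
  }
  if (!length(series)) stop("all sessions excluded by quality screening")

  t_max <- min(vapply(series, function(s) max(s$times), 0))
  grid <- seq(0, t_max, by = series[[1]]$step)
  mat <- vapply(series, function(s)
    stats::approx(s$times, s$values, xout = grid, rule = 2)$y,
    numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  timecourse <- data.frame(
    time_s = grid, mean = rowMeans(mat),
    se = apply(mat, 1, stats::sd) / sqrt(ncol(mat)), n = ncol(mat))

  correlations <- NULL
  if (!is.null(cfg$questionnaires)) {
    qt <- cfg$questionnaires
    need_cols(qt, "id", "questionnaires")
    qt <- qt[match(names(wmeans), qt$id), , drop = FALSE]
    scales <- setdiff(names(qt), "id")
    correlations <- do.call(rbind, lapply(scales, function(sc) {
      v <- qt[[sc]]
      ok <- is.finite(v) & is.finite(wmeans)
      if (sum(ok) < 3 || stats::sd(v[ok]) == 0 ||
          stats::sd(wmeans[ok]) == 0) {
        message(sprintf("scale '%s': correlation undefined (zero variance)",
                        sc))
        return(data.frame(scale = sc, rho = NA_real_, p = NA_real_,
                          n = sum(ok), stringsAsFactors = FALSE))
      }
      ct <- suppressWarnings(
        stats::cor.test(wmeans[ok], v[ok], method = "spearman"))
      data.frame(scale = sc, rho = unname(ct$estimate), p = ct$p.value,
                 n = sum(ok), stringsAsFactors = FALSE)
    }))
    if (cfg$fdr && !is.null(correlations)) {
      ok <- !is.na(correlations$p)
      correlations$p_fdr <- NA_real_
      correlations$p_fdr[ok] <- fdr_adjust(correlations$p[ok])
    }
  }

  structure(list(timecourse = timecourse,
                 window_means = data.frame(id = names(wmeans),
                                           mean_amplitude = unname(wmeans),
                                           stringsAsFactors = FALSE),
                 correlations = correlations, exclusions = exclusions,
                 config = cfg),
            class = "timecourse_report")
}

#' Write a study report bundle to disk
#'
#' Tidy CSV per table plus a single JSON summary.
#'
#' @param report A `study_report` or `timecourse_report`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list()
  for (nm in names(report)) {
    obj <- report[[nm]]
    if (is.data.frame(obj)) {
      utils::write.csv(obj, file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    } else if (inherits(obj, "segmented_fit")) {
      summary$segmented <- obj[c("breakpoint", "breakpoint_ci95",
                                 "slope_below", "slope_above_combined",
                                 "r2", "f_stat", "davies_p", "supported",
                                 "n")]
    } else if (inherits(obj, "mediation_result")) {
      summary$mediation <- obj[c("indirect", "indirect_ci95", "direct",
                                 "direct_ci95", "total", "n", "n_boot",
                                 "seed")]
    }
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
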