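#' Write a synthetic study to disk
#'
#' Generates a full synthetic study (\code{\link{generate_study}}) and writes
#' the canonical on-disk tables: \code{gaze.csv}, \code{markers.csv},
#' \code{scores.csv}, \code{ibi.csv}, \code{truth.csv}.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed RNG seed.
#' @param ... Passed to \code{\link{generate_study}}.
#' @return Invisibly, a list with the study object and the file paths.
#' @export
run_simulate <- function(out_dir, seed = 1, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- generate_study(seed = seed, ...)
  paths <- list(gaze = file.path(out_dir, "gaze.csv"),
                markers = file.path(out_dir, "markers.csv"),
                scores = file.path(out_dir, "scores.csv"),
                ibi = file.path(out_dir, "ibi.csv"),
                truth = file.path(out_dir, "truth.csv"))
  write_gaze_table(study$streams, paths$gaze)
  utils::write.table(study$markers, paths$markers, sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(study$scores, paths$scores, sep = ",",
                     row.names = FALSE, quote = FALSE)
  write_ibi_table(study$ibi, paths$ibi)
  utils::write.table(study$truth, paths$truth, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(list(study = study, paths = paths))
}

.group_streams <- function(streams) {
  keys <- vapply(streams, function(s) s$video_id, character(1))
  split(streams, keys)
}

#' Compute per-video iGDI scores across all modes
#'
#' The full gaze branch: epoch streams to their video markers, build the
#' sliding-window dispersion series per video in the three modes (between
#' viewings, within viewing 1, within viewing 2), sample each video's
#' Monte-Carlo null, classify windows against the null mean and compute the
#' eye-gaze Divergence Index. Also reports the agreement between the two
#' within-viewing classifications per video.
#'
#' @param gaze Path to a gaze table, or a list of \code{gaze_stream} objects.
#' @param markers Path to a markers table, a data frame, or \code{NULL} when
#'   the streams are already epoched.
#' @param window_ms,step_ms Sliding-window parameters (defaults 250/50 ms).
#' @param metric Dispersion metric mode (default \code{"as_printed"}).
#' @param variant iGDI variant (default \code{"fraction"}).
#' @param n_null Monte-Carlo null draws per video and mode (default 1000).
#' @param min_valid_fraction Valid-fraction rule threshold (default 0.5).
#' @param seed RNG seed for the null sampling.
#' @param pre_ms,post_ms Epoch padding (defaults 1000 ms).
#' @return An object of class \code{"igdi_run"}: list with \code{summary}
#'   (video, mode, igdi, t_usable, threshold), \code{windows} (window-level
#'   table), \code{agreement} (per-video within-model agreement) and
#'   \code{params}.
#' @export
run_igdi <- function(gaze, markers = NULL, window_ms = 250, step_ms = 50,
                     metric = c("as_printed", "euclidean"),
                     variant = c("fraction", "weighted"),
                     n_null = 1000, min_valid_fraction = 0.5, seed = NULL,
                     pre_ms = 1000, post_ms = 1000) {
  metric <- match.arg(metric)
  variant <- match.arg(variant)
  if (is.character(gaze)) gaze <- read_gaze_table(gaze)
  if (is.character(markers)) markers <- read_markers_table(markers)
  if (!is.null(markers)) {
    gaze <- lapply(gaze, epoch_stream, markers = markers,
                   pre_ms = pre_ms, post_ms = post_ms)
  }
  if (!is.null(seed)) set.seed(seed)
  by_video <- .group_streams(gaze)
  series_list <- list(); labels_list <- list(); scores_list <- list()
  agreement <- data.frame(video = character(0), agreement = numeric(0),
                          stringsAsFactors = FALSE)
  for (vid in sort(names(by_video))) {
    pool <- by_video[[vid]]
    viewings <- vapply(pool, function(s) s$viewing, integer(1))
    v1 <- pool[viewings == 1L]
    v2 <- pool[viewings == 2L]
    if (length(v1) == 0 && length(v2) == 0) next
    grid <- window_grid(common_duration(pool), window_ms = window_ms,
                        step_ms = step_ms)
    one <- function(sa, sb, mode) {
      ser <- dispersion_series(sa, sb, grid = grid, metric = metric,
                               min_valid_fraction = min_valid_fraction,
                               mode = mode)
      null <- sample_null(sa, sb, grid = grid, n_samples = n_null,
                          metric = metric,
                          min_valid_fraction = min_valid_fraction,
                          mode = mode)
      lab <- classify_windows(ser, null)
      list(series = ser, labels = lab,
           score = compute_igdi(ser, lab, variant = variant))
    }
    res <- list()
    if (length(v1) > 0 && length(v2) > 0) {
      res$between <- one(v1, v2, "between")
    } else {
      warning("video ", vid, ": missing viewing ",
              if (length(v1) == 0) 1 else 2,
              "; between-viewings mode skipped")
    }
    if (length(v1) > 0) res$within_v1 <- one(v1, NULL, "within_v1")
    if (length(v2) > 0) res$within_v2 <- one(v2, NULL, "within_v2")
    for (m in names(res)) {
      series_list[[paste(vid, m)]] <- res[[m]]$series
      labels_list[[paste(vid, m)]] <- res[[m]]$labels
      scores_list[[paste(vid, m)]] <- res[[m]]$score
    }
    if (!is.null(res$within_v1) && !is.null(res$within_v2)) {
      agreement <- rbind(agreement, data.frame(
        video = vid,
        agreement = model_agreement(res$within_v1$labels, res$within_v2$labels),
        stringsAsFactors = FALSE))
    }
  }
  if (length(scores_list) == 0) stop("no video could be scored")
  tabs <- write_igdi_tables(series_list, labels_list, scores_list)
  structure(list(summary = tabs$summary, windows = tabs$windows,
                 agreement = agreement,
                 params = list(window_ms = window_ms, step_ms = step_ms,
                               metric = metric, variant = variant,
                               n_null = n_null,
                               min_valid_fraction = min_valid_fraction,
                               seed = seed)),
            class = "igdi_run")
}

#' @export
print.igdi_run <- function(x, ...) {
  cat(sprintf("<igdi_run> %d video x mode scores (%s metric, %s variant, %d null draws)\n",
              nrow(x$summary), x$params$metric, x$params$variant,
              x$params$n_null))
  print(utils::head(x$summary, 12))
  invisible(x)
}

.igdi_summary_of <- function(x) {
  if (inherits(x, "igdi_run")) x$summary else as.data.frame(x)
}

#' Fit and cross-validate the preference models
#'
#' For each iGDI mode present in the summary (between, within_v1, within_v2),
#' fits the univariate least-squares model of preference score on iGDI and
#' runs leave-one-out cross-validation.
#'
#' @param igdi An \code{igdi_run} or its summary data frame (columns
#'   \code{video}, \code{mode}, \code{igdi}).
#' @param scores Path to a scores table or a data frame (\code{video},
#'   \code{score}).
#' @param r2_method Passed to \code{\link{loocv}}.
#' @return An object of class \code{"igdi_prediction"}: per-mode list of
#'   \code{model} (\code{igdi_lm}) and \code{cv} (\code{igdi_cv}), plus a
#'   flat \code{table} data frame of all report fields.
#' @export
run_predict <- function(igdi, scores, r2_method = c("press", "cor")) {
  r2_method <- match.arg(r2_method)
  summary <- .igdi_summary_of(igdi)
  if (is.character(scores)) scores <- read_scores_table(scores)
  missing_scores <- setdiff(unique(summary$video), scores$video)
  if (length(missing_scores))
    stop("no preference score for video(s): ",
         paste(missing_scores, collapse = ", "))
  blocks <- list()
  rows <- list()
  for (m in intersect(c("between", "within_v1", "within_v2"),
                      unique(summary$mode))) {
    sub <- summary[summary$mode == m, , drop = FALSE]
    y <- scores$score[match(sub$video, scores$video)]
    model <- fit_linear(sub$igdi, y)
    cv <- loocv(sub$igdi, y, r2_method = r2_method)
    blocks[[m]] <- list(model = model, cv = cv)
    rows[[m]] <- data.frame(
      mode = m, n = model$n, b0 = model$b0, b1 = model$b1, r = model$r,
      r2 = model$r2, f_stat = model$f_stat, p_value = model$p_value,
      rmse = cv$rmse, mape = cv$mape, r2_cv = cv$r2_cv,
      shrinkage = cv$shrinkage, sd_b1 = cv$coef_sd[["b1"]],
      sd_b0 = cv$coef_sd[["b0"]], stringsAsFactors = FALSE)
  }
  structure(c(blocks, list(table = do.call(rbind, rows))),
            class = "igdi_prediction")
}

#' @export
print.igdi_prediction <- function(x, ...) {
  for (m in setdiff(names(x), "table")) {
    cat("==", m, "==\n")
    print(x[[m]]$model)
    print(x[[m]]$cv)
  }
  invisible(x)
}

#' Write a prediction report as JSON
#'
#' @param prediction An \code{igdi_prediction}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_prediction_report <- function(prediction, path) {
  tab <- prediction$table
  out <- lapply(split(tab, tab$mode), function(row) as.list(row[1, -1]))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Heart-rate-variability branch: RMSSD change and iGDI correlation
#'
#' Computes per subject-video-viewing the RMSSD percent change from the
#' subject's resting baseline, averages it across subjects per
#' video-viewing, and correlates the group-level change with the
#' between-viewings iGDI (one pair per video x viewing). First- and
#' second-viewing RMSSD are compared with a paired t-test across videos
#' before pooling; the test is reported for transparency.
#'
#' @param ibi Path to an IBI table or a data frame (\code{subject},
#'   \code{context}, \code{video}, \code{viewing}, \code{interval_ms}).
#' @param igdi An \code{igdi_run} or summary data frame containing
#'   between-viewings iGDI values.
#' @return An object of class \code{"igdi_hrv"}: list with \code{changes}
#'   (per subject x video x viewing), \code{group} (per video x viewing mean
#'   percent change), \code{correlation} (\code{igdi_hrv_cor}) and
#'   \code{viewing_test} (paired t-test of viewing 1 vs 2).
#' @export
run_hrv <- function(ibi, igdi) {
  if (is.character(ibi)) ibi <- read_ibi_table(ibi)
  summary <- .igdi_summary_of(igdi)
  between <- summary[summary$mode == "between", , drop = FALSE]
  if (nrow(between) == 0) stop("no between-viewings iGDI in summary")
  changes <- list()
  for (subj in unique(ibi$subject)) {
    sub <- ibi[ibi$subject == subj, , drop = FALSE]
    base <- sub$interval_ms[sub$context == "baseline"]
    if (length(base) < 2) {
      warning("subject ", subj, ": no baseline IBI series; skipped")
      next
    }
    vids <- sub[sub$context == "video", , drop = FALSE]
    for (key in unique(paste(vids$video, vids$viewing))) {
      rows <- vids[paste(vids$video, vids$viewing) == key, , drop = FALSE]
      if (nrow(rows) < 2) next
      pc <- percent_change(rows$interval_ms, base)
      changes[[length(changes) + 1]] <- data.frame(
        subject = subj, video = rows$video[1], viewing = rows$viewing[1],
        rmssd_baseline = pc$rmssd_baseline, rmssd_video = pc$rmssd_video,
        percent_change = pc$percent_change, stringsAsFactors = FALSE)
    }
  }
  if (length(changes) == 0) stop("no usable IBI data")
  changes <- do.call(rbind, changes)
  group <- stats::aggregate(percent_change ~ video + viewing, data = changes,
                            FUN = mean)
  names(group)[names(group) == "percent_change"] <- "mean_percent_change"
  group$igdi <- between$igdi[match(group$video, between$video)]
  group <- group[!is.na(group$igdi), , drop = FALSE]
  correlation <- correlate_igdi_hrv(group$igdi, group$mean_percent_change)
  # viewing 1 vs 2 comparison (pooling rationale), paired over videos
  g1 <- group[group$viewing == 1, ]
  g2 <- group[group$viewing == 2, ]
  common <- intersect(g1$video, g2$video)
  viewing_test <- if (length(common) >= 2) {
    stats::t.test(g1$mean_percent_change[match(common, g1$video)],
                  g2$mean_percent_change[match(common, g2$video)],
                  paired = TRUE)
  } else NULL
  structure(list(changes = changes, group = group,
                 correlation = correlation, viewing_test = viewing_test),
            class = "igdi_hrv")
}

#' @export
print.igdi_hrv <- function(x, ...) {
  cat(sprintf("<igdi_hrv> %d subject-video-viewing changes, %d group pairs\n",
              nrow(x$changes), nrow(x$group)))
  print(x$correlation)
  if (!is.null(x$viewing_test))
    cat(sprintf("  viewing 1 vs 2 (paired): t = %.3f, p = %.3f\n",
                unname(x$viewing_test$statistic), x$viewing_test$p.value))
  invisible(x)
}
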