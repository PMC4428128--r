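#' Monte-Carlo null distribution of dispersion scores
#'
#' Samples the distribution of dispersion scores under the null hypothesis
#' that the video does not guide viewers' attention in any systematic
#' pattern. Each draw assembles surrogate renditions by giving every
#' contributing stream an independently uniform-random usable window start
#' within the same video — destroying cross-subject temporal alignment while
#' preserving each stream's marginal gaze distribution — and computes the
#' corresponding dispersion score. A normal distribution is fitted by moments;
#' its mean \code{mu} is the classification threshold consumed by
#' \code{\link{classify_windows}}.
#'
#' Surrogate windows are drawn only from windows passing the valid-fraction
#' rule in the viewing pool they replace, so each video (and each mode) gets
#' its own threshold.
#'
#' @inheritParams dispersion_series
#' @param n_samples Number of Monte-Carlo draws (default 1000, minimum 100).
#' @param seed Optional integer seed applied before drawing; \code{NULL}
#'   continues the current RNG stream.
#' @return An object of class \code{"null_model"}: list with \code{samples},
#'   \code{mu}, \code{sigma}, \code{n_samples}, \code{seed}, \code{mode}.
#' @export
sample_null <- function(streams_a, streams_b = NULL, grid = NULL,
                        n_samples = 1000,
                        metric = c("as_printed", "euclidean"),
                        min_valid_fraction = 0.5, seed = NULL, mode = NULL) {
  metric <- match.arg(metric)
  if (n_samples < 100) stop("n_samples must be at least 100")
  if (inherits(streams_a, "gaze_stream")) streams_a <- list(streams_a)
  if (inherits(streams_b, "gaze_stream")) streams_b <- list(streams_b)
  if (is.null(grid)) grid <- window_grid(common_duration(c(streams_a, streams_b)))
  between <- !is.null(streams_b)
  if (is.null(mode)) mode <- if (between) "between" else "within"
  if (!is.null(seed)) set.seed(seed)

  stats_a <- lapply(streams_a, .stream_window_stats, grid = grid)
  pool_a <- .pool_window_stats(stats_a, min_valid_fraction)
  ua <- which(pool_a$usable)
  if (between) {
    stats_b <- lapply(streams_b, .stream_window_stats, grid = grid)
    pool_b <- .pool_window_stats(stats_b, min_valid_fraction)
    ub <- which(pool_b$usable)
  }
  if (length(ua) < 2 || (between && length(ub) < 2))
    stop("degenerate null: fewer than 2 usable windows to randomize over")

  draw_pool <- function(stats_list, usable_idx) {
    # one random usable window per stream per draw; pooled sums per draw
    acc <- list(n = 0, sx = 0, sy = 0, s2 = 0)
    for (st in stats_list) {
      idx <- usable_idx[sample.int(length(usable_idx), n_samples, replace = TRUE)]
      acc$n <- acc$n + st$n_valid[idx]
      acc$sx <- acc$sx + st$sx[idx]
      acc$sy <- acc$sy + st$sy[idx]
      acc$s2 <- acc$s2 + st$s2[idx]
    }
    acc
  }

  if (metric == "as_printed") {
    if (between) {
      da <- draw_pool(stats_a, ua)
      db <- draw_pool(stats_b, ub)
      ok <- da$n > 0 & db$n > 0
      samples <- .between_from_stats(da, db)[ok]
    } else {
      da <- draw_pool(stats_a, ua)
      ok <- da$n > 0
      samples <- .within_from_stats(da)[ok]
    }
  } else {
    starts <- window_starts(grid)
    blocks_of <- function(streams) lapply(streams, function(s) {
      lapply(seq_len(grid$n_windows), function(w) {
        m <- build_window_matrix(list(s), starts[w], grid, min_valid_fraction = 0)
        m$coords
      })
    })
    ba <- blocks_of(streams_a)
    if (between) bb <- blocks_of(streams_b)
    assemble <- function(blocks, usable_idx)
      do.call(cbind, lapply(blocks, function(bl)
        bl[[usable_idx[sample.int(length(usable_idx), 1)]]]))
    samples <- vapply(seq_len(n_samples), function(k) {
      V <- assemble(ba, ua)
      if (between) {
        W <- assemble(bb, ub)
        if (ncol(V) == 0 || ncol(W) == 0) return(NA_real_)
        pairwise_dispersion(V, W, metric)
      } else {
        if (ncol(V) == 0) return(NA_real_)
        within_dispersion(V, metric)
      }
    }, numeric(1))
    samples <- samples[is.finite(samples)]
  }

  structure(list(samples = samples,
                 mu = mean(samples),
                 sigma = stats::sd(samples),
                 n_samples = length(samples),
                 seed = seed,
                 mode = mode,
                 metric = metric),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("<null_model> mode %s, %d draws: threshold mu = %.4g, sigma = %.4g\n",
              x$mode, x$n_samples, x$mu, x$sigma))
  invisible(x)
}

#' Classify windows as divergent
#'
#' Applies the decision rule: a window is divergent when its dispersion score
#' is at or above the null-model mean (ties count as divergent). Unusable
#' windows are labeled 0 and excluded from downstream fractions.
#'
#' @param series A \code{\link{dispersion_series}}.
#' @param null A \code{\link{sample_null}} result; its mode family must match
#'   the series.
#' @return A data frame of class \code{"divergence_labels"} with columns
#'   \code{window_start_ms}, \code{f} (0/1), \code{usable}; attribute
#'   \code{threshold}.
#' @export
classify_windows <- function(series, null) {
  stopifnot(inherits(series, "dispersion_series"), inherits(null, "null_model"))
  fam <- function(m) if (startsWith(m, "within")) "within" else "between"
  if (fam(attr(series, "mode")) != fam(null$mode))
    stop("null model mode (", null$mode, ") does not match series mode (",
         attr(series, "mode"), ")")
  f <- as.integer(series$usable & !is.na(series$d) & series$d >= null$mu)
  out <- data.frame(window_start_ms = series$window_start_ms,
                    f = f, usable = series$usable)
  attr(out, "threshold") <- null$mu
  attr(out, "mode") <- attr(series, "mode")
  attr(out, "video_id") <- attr(series, "video_id")
  class(out) <- c("divergence_labels", "data.frame")
  out
}

#' Eye-gaze Divergence Index of one video
#'
#' The default \code{"fraction"} variant is the proportion of usable windows
#' labeled divergent, which lies in [0, 1]. The \code{"weighted"} variant is
#' the divergence-weighted mean dispersion \eqn{(1/T) d^\top f} over usable
#' windows (squared-pixel units under the default metric).
#'
#' @param series A \code{\link{dispersion_series}}.
#' @param labels Matching \code{\link{classify_windows}} result.
#' @param variant \code{"fraction"} (default) or \code{"weighted"}.
#' @return An object of class \code{"igdi_score"}: list with
#'   \code{video_id}, \code{mode}, \code{value}, \code{t_usable},
#'   \code{variant}, \code{threshold}.
#' @export
compute_igdi <- function(series, labels, variant = c("fraction", "weighted")) {
  variant <- match.arg(variant)
  if (nrow(series) != nrow(labels))
    stop("series and labels have different lengths")
  usable <- series$usable & labels$usable
  t_usable <- sum(usable)
  if (t_usable == 0) stop("undefined iGDI: zero usable windows")
  value <- if (variant == "fraction") {
    sum(labels$f[usable]) / t_usable
  } else {
    sum(series$d[usable] * labels$f[usable]) / t_usable
  }
  structure(list(video_id = attr(series, "video_id"),
                 mode = attr(series, "mode"),
                 value = value,
                 t_usable = t_usable,
                 variant = variant,
                 threshold = attr(labels, "threshold")),
            class = "igdi_score")
}

#' @export
print.igdi_score <- function(x, ...) {
  cat(sprintf("<igdi_score> video %s [%s, %s]: %.4f over %d usable windows\n",
              x$video_id, x$mode, x$variant, x$value, x$t_usable))
  invisible(x)
}

#' Agreement between two window classifications
#'
#' Proportion of jointly-usable windows on which two divergence labelings
#' agree (used to compare the first- and second-viewing within-viewings
#' models on the same video).
#'
#' @param labels_1,labels_2 \code{divergence_labels} over the same grid.
#' @return Proportion in [0, 1]; \code{NA} if no jointly-usable window.
#' @export
model_agreement <- function(labels_1, labels_2) {
  if (nrow(labels_1) != nrow(labels_2))
    stop("label vectors have different lengths")
  joint <- labels_1$usable & labels_2$usable
  if (!any(joint)) return(NA_real_)
  mean(labels_1$f[joint] == labels_2$f[joint])
}

#' Write window labels and iGDI summaries
#'
#' @param series_list,labels_list Parallel lists of series and labels.
#' @param scores_list List of \code{igdi_score} objects.
#' @param windows_path,summary_path Output paths (either may be NULL to skip).
#' @return Invisibly, a list with the two data frames written.
#' @export
write_igdi_tables <- function(series_list, labels_list, scores_list,
                              windows_path = NULL, summary_path = NULL) {
  windows <- do.call(rbind, Map(function(s, l) {
    data.frame(video = attr(s, "video_id"), mode = attr(s, "mode"),
               window_start_ms = s$window_start_ms, dispersion = s$d,
               divergent = l$f, usable = as.integer(s$usable),
               stringsAsFactors = FALSE)
  }, series_list, labels_list))
  summary <- do.call(rbind, lapply(scores_list, function(g) {
    data.frame(video = g$video_id, mode = g$mode, igdi = g$value,
               t_usable = g$t_usable, threshold = g$threshold,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(windows_path))
    utils::write.table(windows, windows_path, sep = ",", row.names = FALSE,
                       quote = FALSE)
  if (!is.null(summary_path))
    utils::write.table(summary, summary_path, sep = ",", row.names = FALSE,
                       quote = FALSE)
  invisible(list(windows = windows, summary = summary))
}
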