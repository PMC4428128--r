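#' Construct a gaze stream
#'
#' A gaze stream is one subject's timestamped gaze trace for one viewing of
#' one video: screen-pixel coordinates (origin top-left, x rightward,
#' y downward) sampled at a nominal rate, with a per-sample validity flag
#' (\code{FALSE} = blink or track loss).
#'
#' Samples whose coordinates are not finite are forced invalid so that every
#' valid sample carries finite coordinates. Timestamps must be strictly
#' increasing.
#'
#' @param subject_id Opaque subject label.
#' @param video_id Opaque video label.
#' @param viewing Viewing index, 1 or 2.
#' @param t_ms Numeric vector of sample times in milliseconds.
#' @param x_px,y_px Numeric gaze coordinates in screen pixels.
#' @param valid Logical validity flags; defaults to all \code{TRUE}.
#' @param rate_hz Nominal sampling rate in Hz (default 60).
#' @return An object of class \code{"gaze_stream"}: a list with fields
#'   \code{subject_id}, \code{video_id}, \code{viewing}, \code{rate_hz} and a
#'   \code{samples} data frame (\code{t_ms}, \code{x_px}, \code{y_px},
#'   \code{valid}).
#' @export
gaze_stream <- function(subject_id, video_id, viewing, t_ms, x_px, y_px,
                        valid = NULL, rate_hz = 60) {
  n <- length(t_ms)
  if (length(x_px) != n || length(y_px) != n)
    stop("t_ms, x_px and y_px must have equal length")
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (length(valid) != n) stop("valid must match the number of samples")
  if (n > 0) {
    if (anyNA(t_ms) || any(!is.finite(t_ms)))
      stop("t_ms must be finite")
    if (any(diff(t_ms) <= 0))
      stop("t_ms must be strictly increasing")
  }
  valid <- as.logical(valid) & is.finite(x_px) & is.finite(y_px)
  structure(list(
    subject_id = as.character(subject_id),
    video_id   = as.character(video_id),
    viewing    = as.integer(viewing),
    rate_hz    = rate_hz,
    samples    = data.frame(t_ms = as.numeric(t_ms),
                            x_px = as.numeric(x_px),
                            y_px = as.numeric(y_px),
                            valid = valid)
  ), class = "gaze_stream")
}

#' @export
print.gaze_stream <- function(x, ...) {
  cat(sprintf("<gaze_stream> subject %s, video %s, viewing %d: %d samples (%.1f%% valid), t %.0f..%.0f ms\n",
              x$subject_id, x$video_id, x$viewing, nrow(x$samples),
              100 * mean(x$samples$valid),
              if (nrow(x$samples)) min(x$samples$t_ms) else NA_real_,
              if (nrow(x$samples)) max(x$samples$t_ms) else NA_real_))
  invisible(x)
}

.detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a multi-subject gaze table
#'
#' Reads a delimited text table (comma or tab, autodetected) with header
#' columns \code{subject}, \code{video}, \code{viewing}, \code{t_ms},
#' \code{x_px}, \code{y_px}, \code{valid} and splits it into one
#' \code{\link{gaze_stream}} per (subject, video, viewing) triple. Rows whose
#' coordinates fail to parse as numbers are kept with \code{valid = FALSE};
#' streams are sorted by time.
#'
#' @param path Path to the table.
#' @param delim Field delimiter; autodetected from the header when \code{NULL}.
#' @param rate_hz Nominal sampling rate recorded on each stream.
#' @return A list of \code{gaze_stream} objects, named
#'   \code{"subject|video|viewing"}.
#' @export
read_gaze_table <- function(path, delim = NULL, rate_hz = 60) {
  if (!file.exists(path)) stop("gaze table not found: ", path)
  if (file.size(path) == 0) stop("empty gaze table: ", path)
  if (is.null(delim)) delim <- .detect_delim(path)
  tab <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("empty gaze table: ", path)
  need <- c("subject", "video", "viewing", "t_ms", "x_px", "y_px", "valid")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("gaze table is missing required column(s): ", paste(miss, collapse = ", "))
  t_ms <- suppressWarnings(as.numeric(tab$t_ms))
  x <- suppressWarnings(as.numeric(tab$x_px))
  y <- suppressWarnings(as.numeric(tab$y_px))
  valid <- .parse_flag(tab$valid) & is.finite(x) & is.finite(y)
  bad_t <- !is.finite(t_ms)
  if (any(bad_t)) {
    warning(sum(bad_t), " row(s) with unparseable t_ms dropped")
    keep <- !bad_t
    tab <- tab[keep, , drop = FALSE]
    t_ms <- t_ms[keep]; x <- x[keep]; y <- y[keep]; valid <- valid[keep]
  }
  key <- paste(tab$subject, tab$video, tab$viewing, sep = "|")
  out <- lapply(split(seq_along(key), key), function(idx) {
    idx <- idx[order(t_ms[idx])]
    gaze_stream(tab$subject[idx[1]], tab$video[idx[1]],
                as.integer(tab$viewing[idx[1]]),
                t_ms[idx], x[idx], y[idx], valid[idx], rate_hz = rate_hz)
  })
  out[order(names(out))]
}

.parse_flag <- function(v) {
  v <- trimws(tolower(as.character(v)))
  v %in% c("1", "true", "t", "yes")
}

.fmt_num <- function(x) {
  # full-precision round-trippable decimal text
  out <- formatC(x, digits = 17, format = "g")
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  trimws(out)
}

#' Write gaze streams to a delimited table
#'
#' Inverse of \code{\link{read_gaze_table}}; numeric fields are written with
#' enough digits to round-trip at full double precision.
#'
#' @param streams A list of \code{gaze_stream} objects.
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @return \code{path}, invisibly.
#' @export
write_gaze_table <- function(streams, path, delim = ",") {
  if (inherits(streams, "gaze_stream")) streams <- list(streams)
  rows <- do.call(rbind, lapply(streams, function(s) {
    data.frame(subject = s$subject_id, video = s$video_id, viewing = s$viewing,
               t_ms = .fmt_num(s$samples$t_ms),
               x_px = .fmt_num(s$samples$x_px),
               y_px = .fmt_num(s$samples$y_px),
               valid = as.integer(s$samples$valid),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a video event-marker table
#'
#' Columns: \code{video}, \code{t_start_ms}, \code{t_end_ms} (recording time).
#'
#' @param path Path to the table.
#' @param delim Delimiter; autodetected when \code{NULL}.
#' @return A data frame with one row per video.
#' @export
read_markers_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("markers table not found: ", path)
  if (is.null(delim)) delim <- .detect_delim(path)
  tab <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE)
  miss <- setdiff(c("video", "t_start_ms", "t_end_ms"), names(tab))
  if (length(miss))
    stop("markers table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (any(tab$t_end_ms <= tab$t_start_ms))
    stop("markers must satisfy t_end_ms > t_start_ms")
  tab$video <- as.character(tab$video)
  tab
}

#' Read an audience preference-score table
#'
#' Columns: \code{video}, \code{score} (e.g. Ad-Meter likeability ratings).
#'
#' @param path Path to the table.
#' @param delim Delimiter; autodetected when \code{NULL}.
#' @return A data frame with one row per video.
#' @export
read_scores_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("scores table not found: ", path)
  if (is.null(delim)) delim <- .detect_delim(path)
  tab <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE)
  miss <- setdiff(c("video", "score"), names(tab))
  if (length(miss))
    stop("scores table is missing required column(s): ",
         paste(miss, collapse = ", "))
  tab$video <- as.character(tab$video)
  tab
}

#' Epoch a gaze stream around a video presentation
#'
#' Keeps the samples with recording time in
#' \code{[t_start - pre_ms, t_end + post_ms]} and re-references time so that
#' the video onset maps to 0 ms.
#'
#' @param stream A \code{\link{gaze_stream}} in recording time.
#' @param markers Either a one-row marker list/data frame with
#'   \code{t_start_ms}/\code{t_end_ms}, or a multi-video marker table from
#'   which the row matching \code{stream$video_id} is taken.
#' @param pre_ms,post_ms Padding before onset / after offset (default 1000 ms
#'   each).
#' @return The epoched \code{gaze_stream}; its samples carry negative times in
#'   the pre-onset pad.
#' @export
epoch_stream <- function(stream, markers, pre_ms = 1000, post_ms = 1000) {
  stopifnot(inherits(stream, "gaze_stream"))
  if (is.data.frame(markers) && nrow(markers) > 1) {
    row <- markers[markers$video == stream$video_id, , drop = FALSE]
    if (nrow(row) != 1)
      stop("no unique marker row for video ", stream$video_id)
    markers <- row
  }
  t0 <- as.numeric(markers$t_start_ms)
  t1 <- as.numeric(markers$t_end_ms)
  if (t1 <= t0) stop("marker interval must satisfy t_end_ms > t_start_ms")
  keep <- stream$samples$t_ms >= t0 - pre_ms & stream$samples$t_ms <= t1 + post_ms
  if (!any(keep))
    stop("empty epoch: no samples in [", t0 - pre_ms, ", ", t1 + post_ms,
         "] for subject ", stream$subject_id, ", video ", stream$video_id)
  out <- stream
  out$samples <- stream$samples[keep, , drop = FALSE]
  out$samples$t_ms <- out$samples$t_ms - t0
  rownames(out$samples) <- NULL
  attr(out, "epoched") <- TRUE
  attr(out, "video_duration_ms") <- t1 - t0
  out
}

#' Define a sliding-window grid
#'
#' The default 250 ms windows shifted by 50 ms give 80\% overlap between
#' successive windows. Window \code{w} spans
#' \code{[t0 + (w-1)*step, t0 + (w-1)*step + window)}.
#'
#' @param duration_ms Video duration covered by the grid.
#' @param window_ms Window length (default 250 ms).
#' @param step_ms Window shift (default 50 ms); must satisfy
#'   \code{0 < step_ms <= window_ms}.
#' @param t0_ms First window start (default 0, the video onset).
#' @return An object of class \code{"window_grid"} with \code{n_windows =
#'   floor((duration - window)/step) + 1}.
#' @export
window_grid <- function(duration_ms, window_ms = 250, step_ms = 50, t0_ms = 0) {
  if (window_ms <= 0) stop("window_ms must be positive")
  if (step_ms <= 0 || step_ms > window_ms)
    stop("step_ms must satisfy 0 < step_ms <= window_ms")
  if (duration_ms < window_ms)
    stop("duration_ms shorter than one window")
  n <- floor((duration_ms - window_ms) / step_ms) + 1L
  structure(list(window_ms = window_ms, step_ms = step_ms, t0_ms = t0_ms,
                 n_windows = as.integer(n), duration_ms = duration_ms),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("<window_grid> %d windows of %g ms every %g ms from %g ms (duration %g ms)\n",
              x$n_windows, x$window_ms, x$step_ms, x$t0_ms, x$duration_ms))
  invisible(x)
}

#' Window start times of a grid
#' @param grid A \code{\link{window_grid}}.
#' @return Numeric vector of the \code{n_windows} window start times (ms).
#' @export
window_starts <- function(grid) {
  grid$t0_ms + (seq_len(grid$n_windows) - 1) * grid$step_ms
}

#' Shortest common nominal duration of a set of epoched streams
#'
#' The duration each stream supports is its last sample time plus one nominal
#' sample period; the grid is truncated to the minimum across streams so that
#' every window is populated by every stream.
#'
#' @param streams List of epoched \code{gaze_stream} objects.
#' @return Duration in ms.
#' @export
common_duration <- function(streams) {
  min(vapply(streams, function(s)
    max(s$samples$t_ms) + 1000 / s$rate_hz, numeric(1)))
}

#' Pool one time window across streams into a gaze matrix
#'
#' Builds the 2xN matrix of valid gaze positions falling in
#' \code{[window_start, window_start + window)} across all streams,
#' concatenated stream after stream. Invalid samples are dropped; the window
#' is flagged insufficient when the pooled valid-sample fraction falls below
#' \code{min_valid_fraction}.
#'
#' @param streams List of epoched \code{gaze_stream} objects (one viewing
#'   pool).
#' @param window_start_ms Window start time (ms, video-onset referenced).
#' @param grid A \code{\link{window_grid}} supplying the window length.
#' @param min_valid_fraction Minimum pooled valid fraction (default 0.5).
#' @return An object of class \code{"gaze_matrix"}: list with \code{coords}
#'   (2xN, row 1 = x, row 2 = y), \code{origin} (data frame of subject and
#'   viewing per column), \code{n_present}, \code{n_valid},
#'   \code{valid_fraction} and \code{insufficient}.
#' @export
build_window_matrix <- function(streams, window_start_ms, grid,
                                min_valid_fraction = 0.5) {
  if (inherits(streams, "gaze_stream")) streams <- list(streams)
  w <- grid$window_ms
  cols <- lapply(streams, function(s) {
    inw <- s$samples$t_ms >= window_start_ms &
           s$samples$t_ms < window_start_ms + w
    sub <- s$samples[inw, , drop = FALSE]
    list(n_present = nrow(sub),
         sub = sub[sub$valid, , drop = FALSE],
         subject = s$subject_id, viewing = s$viewing)
  })
  n_present <- sum(vapply(cols, `[[`, numeric(1), "n_present"))
  xs <- unlist(lapply(cols, function(c) c$sub$x_px))
  ys <- unlist(lapply(cols, function(c) c$sub$y_px))
  origin <- do.call(rbind, lapply(cols, function(c) {
    if (nrow(c$sub) == 0) return(NULL)
    data.frame(subject = c$subject, viewing = c$viewing,
               stringsAsFactors = FALSE)[rep(1, nrow(c$sub)), , drop = FALSE]
  }))
  n_valid <- length(xs)
  frac <- if (n_present > 0) n_valid / n_present else 0
  coords <- unname(rbind(if (n_valid) xs else numeric(0),
                         if (n_valid) ys else numeric(0)))
  structure(list(coords = coords,
                 origin = origin,
                 n_cols = n_valid,
                 n_present = n_present,
                 n_valid = n_valid,
                 valid_fraction = frac,
                 insufficient = frac < min_valid_fraction || n_valid == 0),
            class = "gaze_matrix")
}
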