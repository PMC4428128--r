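#' Construct an inter-beat-interval series
#'
#' @param intervals Numeric vector of consecutive inter-beat intervals (ms);
#'   all must be positive.
#' @param context \code{"baseline"} (resting recording) or \code{"video"}.
#' @param subject_id,video_id,viewing Labels (video context only).
#' @return An object of class \code{"ibi_series"}.
#' @export
ibi_series <- function(intervals, context = c("video", "baseline"),
                       subject_id = NA_character_, video_id = NA_character_,
                       viewing = NA_integer_) {
  context <- match.arg(context)
  intervals <- as.numeric(intervals)
  if (anyNA(intervals) || any(intervals <= 0))
    stop("all inter-beat intervals must be positive")
  structure(list(intervals = intervals, context = context,
                 subject_id = as.character(subject_id),
                 video_id = as.character(video_id),
                 viewing = viewing),
            class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series> %s: %d intervals, mean %.0f ms, RMSSD %.1f ms\n",
              x$context, length(x$intervals), mean(x$intervals),
              if (length(x$intervals) >= 2) rmssd(x) else NA_real_))
  invisible(x)
}

.ibi_intervals <- function(x) {
  if (inherits(x, "ibi_series")) x$intervals else as.numeric(x)
}

#' Root mean square of successive differences (RMSSD)
#'
#' The time-domain heart-rate-variability index
#' \deqn{\mathrm{RMSSD}(r) = \sqrt{\frac{1}{I-1} \sum_{i=1}^{I-1}
#'   (r(i) - r(i+1))^2}}
#' over a vector of I consecutive inter-beat intervals. RMSSD reflects
#' beat-to-beat (parasympathetically mediated) variability; it is invariant
#' to adding a constant to all intervals and scales linearly with the
#' interval units.
#'
#' @param ibi An \code{\link{ibi_series}} or numeric vector of intervals (ms).
#' @return RMSSD in the same units as the intervals.
#' @export
rmssd <- function(ibi) {
  r <- .ibi_intervals(ibi)
  if (length(r) < 2) stop("RMSSD requires at least 2 intervals")
  sqrt(sum(diff(r)^2) / (length(r) - 1))
}

#' Baseline-adjusted RMSSD percent change
#'
#' Normalizes a video-viewing RMSSD against the subject's resting baseline:
#' \code{100 * (rmssd_video - rmssd_baseline) / rmssd_baseline}.
#'
#' @param video,baseline \code{\link{ibi_series}} objects or numeric interval
#'   vectors for the video viewing and the resting baseline.
#' @return An object of class \code{"hrv_change"}: list with
#'   \code{rmssd_baseline}, \code{rmssd_video}, \code{percent_change}.
#' @export
percent_change <- function(video, baseline) {
  rb <- rmssd(baseline)
  rv <- rmssd(video)
  if (rb <= 0) stop("undefined percent change: baseline RMSSD is 0")
  structure(list(rmssd_baseline = rb, rmssd_video = rv,
                 percent_change = 100 * (rv - rb) / rb),
            class = "hrv_change")
}

#' Correlate gaze divergence with HRV change
#'
#' Pearson product-moment correlation between per-video iGDI values and
#' group-level RMSSD percent changes, with the two-tailed p-value from the t
#' distribution on n-2 degrees of freedom. Shapiro-Wilk normality checks on
#' both variables are reported (not enforced) alongside, mirroring standard
#' practice before a Pearson correlation.
#'
#' @param igdi_values Numeric vector of iGDI values.
#' @param hrv_changes Numeric vector of RMSSD percent changes, same length.
#' @return An object of class \code{"igdi_hrv_cor"}: list with \code{r},
#'   \code{p_value}, \code{df} (n-2), \code{t}, \code{n},
#'   \code{shapiro_igdi}, \code{shapiro_hrv} (each with W and p).
#' @export
correlate_igdi_hrv <- function(igdi_values, hrv_changes) {
  x <- as.numeric(igdi_values); y <- as.numeric(hrv_changes)
  n <- length(x)
  if (length(y) != n) stop("inputs must have equal length")
  if (n < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  sw <- function(v) {
    if (n >= 3 && n <= 5000) {
      s <- stats::shapiro.test(v)
      list(W = unname(s$statistic), p = s$p.value)
    } else list(W = NA_real_, p = NA_real_)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 df = n - 2, t = unname(ct$statistic), n = n,
                 shapiro_igdi = sw(x), shapiro_hrv = sw(y)),
            class = "igdi_hrv_cor")
}

#' @export
print.igdi_hrv_cor <- function(x, ...) {
  cat(sprintf("<igdi_hrv_cor> r_(%d) = %.3f, p = %.4g (n = %d)\n",
              x$df, x$r, x$p_value, x$n))
  cat(sprintf("  Shapiro-Wilk: iGDI W = %.3f (p = %.3g); HRV W = %.3f (p = %.3g)\n",
              x$shapiro_igdi$W, x$shapiro_igdi$p,
              x$shapiro_hrv$W, x$shapiro_hrv$p))
  invisible(x)
}

#' Programmatic IBI artifact filter
#'
#' Deterministic stand-in for manual IBI artifact editing: drops intervals
#' outside a physiological plausibility band and intervals exceeding a
#' multiple of the running median (spike rule). Dropped counts are recorded
#' as attributes.
#'
#' @param intervals Numeric intervals (ms) or \code{\link{ibi_series}}.
#' @param band Plausibility band in ms (default 300--2000).
#' @param spike_factor Interval is flagged when it exceeds
#'   \code{spike_factor} times the running median (default 1.3).
#' @param spike_k Running-median window (odd, default 5).
#' @return Cleaned numeric interval vector with attributes
#'   \code{n_dropped_band} and \code{n_dropped_spike}.
#' @export
clean_ibi <- function(intervals, band = c(300, 2000), spike_factor = 1.3,
                      spike_k = 5) {
  r <- .ibi_intervals(intervals)
  in_band <- r >= band[1] & r <= band[2]
  r2 <- r[in_band]
  spike <- rep(FALSE, length(r2))
  if (length(r2) >= spike_k) {
    med <- stats::runmed(r2, spike_k, endrule = "median")
    spike <- r2 > spike_factor * med
  }
  out <- r2[!spike]
  attr(out, "n_dropped_band") <- sum(!in_band)
  attr(out, "n_dropped_spike") <- sum(spike)
  out
}

#' Extract inter-beat intervals from a photoplethysmography trace
#'
#' Low-pass filters the raw PPG waveform with a zero-phase 4th-order
#' Butterworth filter (7 Hz cutoff, removing high-frequency noise while
#' preserving the pulse wave), detects pulse peaks above an adaptive
#' amplitude threshold with a 300 ms refractory period, and returns the
#' successive peak-to-peak intervals in ms after the
#' \code{\link{clean_ibi}} plausibility filter.
#'
#' @param signal Numeric PPG amplitude samples.
#' @param rate_hz Sampling rate; must exceed 14 Hz (Nyquist for the 7 Hz
#'   cutoff).
#' @param cutoff_hz Low-pass cutoff (default 7 Hz).
#' @param band Plausibility band passed to \code{\link{clean_ibi}}.
#' @param ... Further arguments to \code{\link{clean_ibi}}.
#' @return An \code{\link{ibi_series}} (video context) of peak-to-peak
#'   intervals in ms.
#' @export
ppg_to_ibi <- function(signal, rate_hz, cutoff_hz = 7, band = c(300, 2000),
                       ...) {
  if (rate_hz <= 2 * cutoff_hz)
    stop("rate_hz must exceed twice the low-pass cutoff (", 2 * cutoff_hz,
         " Hz)")
  if (length(signal) < rate_hz)
    stop("insufficient signal: need at least 1 s of samples")
  bf <- signal::butter(4, cutoff_hz / (rate_hz / 2), type = "low")
  filt <- as.numeric(signal::filtfilt(bf, signal))
  if (stats::sd(filt) == 0)
    stop("insufficient signal: no peaks in a flat trace")
  thr <- mean(filt) + 0.5 * stats::sd(filt)
  refractory <- max(1L, round(0.3 * rate_hz))
  pk <- pracma::findpeaks(filt, minpeakheight = thr,
                          minpeakdistance = refractory)
  if (is.null(pk) || nrow(pk) < 3)
    stop("insufficient signal: fewer than 3 pulse peaks detected")
  peak_t_ms <- sort(pk[, 2]) / rate_hz * 1000
  intervals <- clean_ibi(diff(peak_t_ms), band = band, ...)
  ibi_series(as.numeric(intervals), context = "video")
}

#' Read an inter-beat-interval table
#'
#' Columns: \code{subject}, \code{context} (baseline/video), \code{video},
#' \code{viewing}, \code{interval_ms}; one row per interval, in order.
#'
#' @param path Path to the delimited table.
#' @param delim Delimiter; autodetected when \code{NULL}.
#' @return The table as a data frame.
#' @export
read_ibi_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("IBI table not found: ", path)
  if (is.null(delim)) delim <- .detect_delim(path)
  tab <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE)
  miss <- setdiff(c("subject", "context", "video", "viewing", "interval_ms"),
                  names(tab))
  if (length(miss))
    stop("IBI table is missing required column(s): ",
         paste(miss, collapse = ", "))
  tab$subject <- as.character(tab$subject)
  tab$video <- as.character(tab$video)
  tab
}

#' Write an inter-beat-interval table
#' @param tab Data frame as returned by \code{\link{read_ibi_table}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_ibi_table <- function(tab, path) {
  utils::write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
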