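#' Dispersion between two gaze renditions
#'
#' The dispersion score between two pooled gaze matrices V and W (2xN each,
#' columns = gaze positions) is the average over all column pairs of the
#' squared Euclidean distance:
#' \deqn{D(V, W) = \frac{1}{N_V N_W} \sum_{n_1} \sum_{n_2} \sum_{i=1}^{2}
#'   (v_i(n_1) - w_i(n_2))^2}
#' The default \code{"as_printed"} mode carries no square root (squared-pixel
#' units); \code{"euclidean"} takes the square root of the per-pair
#' coordinate sum before averaging (pixel units). Both are symmetric in their
#' arguments and invariant to a common translation of both matrices. The
#' prefactor generalizes to \code{1/(N_V N_W)} when the matrices have unequal
#' column counts after blink-dropping, keeping the score a mean over all
#' pairs.
#'
#' @param V,W 2-row numeric matrices, or \code{gaze_matrix} objects.
#' @param metric \code{"as_printed"} (default, squared distances) or
#'   \code{"euclidean"}.
#' @return A non-negative scalar dispersion score.
#' @seealso \code{\link{within_dispersion}} for the single-rendition variant.
#' @export
pairwise_dispersion <- function(V, W, metric = c("as_printed", "euclidean")) {
  metric <- match.arg(metric)
  V <- .as_coords(V); W <- .as_coords(W)
  nv <- ncol(V); nw <- ncol(W)
  if (nv == 0 || nw == 0) stop("empty gaze matrix")
  if (metric == "as_printed") {
    # center on the pooled mean first: the score is translation-invariant,
    # and centering avoids cancellation for far-from-origin coordinates
    ctr <- (rowSums(V) + rowSums(W)) / (nv + nw)
    V <- V - ctr; W <- W - ctr
    s2v <- sum(V^2); s2w <- sum(W^2)
    cross <- sum(rowSums(V) * rowSums(W))
    (nw * s2v + nv * s2w - 2 * cross) / (nv * nw)
  } else {
    d2 <- .cross_sqdist(V, W)
    mean(sqrt(pmax(d2, 0)))
  }
}

#' Dispersion within a single gaze rendition
#'
#' Sums the (squared) distances over all ordered column pairs with
#' \eqn{n_1 \neq n_2} of one pooled matrix, normalized by \eqn{N^2} exactly as
#' printed (the diagonal contributes zero, so no \eqn{N(N-1)} correction is
#' applied). A single-column matrix returns 0.
#'
#' @inheritParams pairwise_dispersion
#' @param V 2-row numeric matrix or \code{gaze_matrix}.
#' @return A non-negative scalar.
#' @export
within_dispersion <- function(V, metric = c("as_printed", "euclidean")) {
  metric <- match.arg(metric)
  V <- .as_coords(V)
  n <- ncol(V)
  if (n == 0) stop("empty gaze matrix")
  if (n == 1) return(0)
  if (metric == "as_printed") {
    Vc <- V - rowMeans(V)   # centering: rowSums vanish, and it is stabler
    2 * sum(Vc^2) / n
  } else {
    d2 <- .cross_sqdist(V, V)
    sum(sqrt(pmax(d2, 0))) / n^2
  }
}

.as_coords <- function(m) {
  if (inherits(m, "gaze_matrix")) m <- m$coords
  m <- as.matrix(m)
  if (length(m) == 0) return(matrix(numeric(0), nrow = 2))
  if (nrow(m) != 2) stop("gaze matrix must have 2 rows (x; y)")
  m
}

.cross_sqdist <- function(V, W) {
  # direct coordinate differences: free of the cancellation that the
  # sum-of-squares expansion suffers for far-from-origin coordinates
  outer(V[1, ], W[1, ], `-`)^2 + outer(V[2, ], W[2, ], `-`)^2
}

# Per-stream, per-window sufficient statistics for the squared-distance
# dispersion: counts and first/second moments of the valid samples in each
# grid window. Both dispersion variants in "as_printed" mode are linear in
# these sums, which is what makes the Monte-Carlo null tractable.
.stream_window_stats <- function(stream, grid) {
  s <- stream$samples
  starts <- window_starts(grid)
  eps <- 1e-9
  lo <- findInterval(starts - eps, s$t_ms) + 1L
  hi <- findInterval(starts + grid$window_ms - eps, s$t_ms)
  v <- as.numeric(s$valid)
  cx <- c(0, cumsum(ifelse(s$valid, s$x_px, 0)))
  cy <- c(0, cumsum(ifelse(s$valid, s$y_px, 0)))
  c2 <- c(0, cumsum(ifelse(s$valid, s$x_px^2 + s$y_px^2, 0)))
  cv <- c(0, cumsum(v))
  n_present <- pmax(hi - lo + 1L, 0L)
  take <- function(cs) ifelse(hi >= lo, cs[hi + 1L] - cs[lo], 0)
  list(n_present = n_present,
       n_valid = take(cv),
       sx = take(cx), sy = take(cy), s2 = take(c2))
}

# Pool per-stream stats for one viewing; returns per-window pooled sums and
# the usability mask under the valid-fraction rule.
.pool_window_stats <- function(stats_list, min_valid_fraction) {
  add <- function(field) Reduce(`+`, lapply(stats_list, `[[`, field))
  n_present <- add("n_present")
  n_valid <- add("n_valid")
  frac <- ifelse(n_present > 0, n_valid / n_present, 0)
  list(n = n_valid, sx = add("sx"), sy = add("sy"), s2 = add("s2"),
       n_present = n_present,
       usable = frac >= min_valid_fraction & n_valid > 0)
}

# Squared-distance dispersion scores from pooled sufficient statistics,
# in variance-decomposition form (scatter of each rendition plus squared
# mean separation), which is numerically stabler than the raw expansion.
.between_from_stats <- function(a, b) {
  mvx <- a$sx / a$n; mvy <- a$sy / a$n
  mwx <- b$sx / b$n; mwy <- b$sy / b$n
  (a$s2 / a$n - mvx^2 - mvy^2) + (b$s2 / b$n - mwx^2 - mwy^2) +
    (mvx - mwx)^2 + (mvy - mwy)^2
}

.within_from_stats <- function(a) {
  ifelse(a$n > 1, 2 * (a$s2 - (a$sx^2 + a$sy^2) / a$n) / a$n,
         ifelse(a$n == 1, 0, NA_real_))
}

#' Window-wise dispersion series over a sliding grid
#'
#' Computes one dispersion score per grid window across a video. With two
#' stream pools (viewing 1 in \code{streams_a}, viewing 2 in
#' \code{streams_b}) each window is scored by \code{\link{pairwise_dispersion}}
#' between the two pooled renditions (between-viewings mode); with a single
#' pool each window is scored by \code{\link{within_dispersion}} on the pooled
#' matrix (within-viewings mode). Windows whose pooled valid-sample fraction
#' falls below \code{min_valid_fraction} in either rendition are masked
#' unusable (\code{d = NA}).
#'
#' @param streams_a List of epoched \code{gaze_stream} objects (viewing pool).
#' @param streams_b Optional second viewing pool; its presence selects
#'   between-viewings mode.
#' @param grid A \code{\link{window_grid}}; when \code{NULL}, built with
#'   default 250/50 ms windows over the shortest common stream duration.
#' @param metric Dispersion metric mode, see \code{\link{pairwise_dispersion}}.
#' @param min_valid_fraction Valid-fraction rule threshold (default 0.5).
#' @param mode Optional mode label recorded on the result (e.g.
#'   \code{"within_v1"}); defaults to \code{"between"} or \code{"within"}.
#' @return A data frame of class \code{"dispersion_series"} with columns
#'   \code{window_start_ms}, \code{d}, \code{usable}; attributes \code{mode},
#'   \code{video_id}, \code{grid}, \code{metric}.
#' @export
dispersion_series <- function(streams_a, streams_b = NULL, grid = NULL,
                              metric = c("as_printed", "euclidean"),
                              min_valid_fraction = 0.5, mode = NULL) {
  metric <- match.arg(metric)
  if (inherits(streams_a, "gaze_stream")) streams_a <- list(streams_a)
  if (inherits(streams_b, "gaze_stream")) streams_b <- list(streams_b)
  all_streams <- c(streams_a, streams_b)
  dur <- common_duration(all_streams)
  if (is.null(grid)) {
    grid <- window_grid(dur)
  } else if (grid$t0_ms + (grid$n_windows - 1) * grid$step_ms + grid$window_ms >
             dur + 1e-6) {
    stop("grid extends beyond the shortest common stream duration (",
         round(dur), " ms)")
  }
  between <- !is.null(streams_b)
  if (is.null(mode)) mode <- if (between) "between" else "within"
  a <- .pool_window_stats(lapply(streams_a, .stream_window_stats, grid = grid),
                          min_valid_fraction)
  if (between) {
    b <- .pool_window_stats(lapply(streams_b, .stream_window_stats, grid = grid),
                            min_valid_fraction)
    usable <- a$usable & b$usable
  } else {
    usable <- a$usable
  }
  if (metric == "as_printed") {
    d <- if (between) .between_from_stats(a, b) else .within_from_stats(a)
  } else {
    starts <- window_starts(grid)
    d <- vapply(seq_len(grid$n_windows), function(w) {
      if (!usable[w]) return(NA_real_)
      ma <- build_window_matrix(streams_a, starts[w], grid, min_valid_fraction)
      if (between) {
        mb <- build_window_matrix(streams_b, starts[w], grid, min_valid_fraction)
        pairwise_dispersion(ma, mb, metric)
      } else within_dispersion(ma, metric)
    }, numeric(1))
  }
  d[!usable] <- NA_real_
  out <- data.frame(window_start_ms = window_starts(grid), d = d,
                    usable = usable)
  attr(out, "mode") <- mode
  attr(out, "video_id") <- streams_a[[1]]$video_id
  attr(out, "grid") <- grid
  attr(out, "metric") <- metric
  class(out) <- c("dispersion_series", "data.frame")
  out
}

#' Write dispersion series to a delimited table
#'
#' Emits the per-video, per-mode window traces (the substrate of
#' dispersion-over-time figures) with columns \code{video}, \code{mode},
#' \code{window_start_ms}, \code{dispersion}, \code{usable}.
#'
#' @param series A \code{dispersion_series} or list of them.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_dispersion_table <- function(series, path) {
  if (inherits(series, "dispersion_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(video = attr(s, "video_id"), mode = attr(s, "mode"),
               window_start_ms = s$window_start_ms,
               dispersion = s$d, usable = as.integer(s$usable),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
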