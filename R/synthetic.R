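#' Configuration for the synthetic gaze cohort generator
#'
#' Defaults emulate the acquisition conditions the method targets: 10
#' subjects viewing a 30-s spot twice, gaze sampled at 60 Hz on a 1024x758 px
#' display. The attention path is a fixation/saccade process: piecewise-
#' constant fixation targets with Gaussian jumps pulled toward screen center
#' (a mean-reverting jump process), connected by short linearly-interpolated
#' saccades. Outside divergent segments all subject-viewings follow one
#' shared path; inside them each subject-viewing follows an independent path
#' drawn from the same process.
#'
#' @param n_subjects Number of subjects S (default 10).
#' @param duration_ms Video length in ms (default 30000).
#' @param rate_hz Gaze sampling rate (default 60).
#' @param screen_px Display width and height in pixels (default c(1024, 758)).
#' @param fixation_mean_ms Mean fixation duration (default 300 ms,
#'   exponential with an 80 ms floor).
#' @param jump_scale_px SD of the Gaussian saccade-target jump (default 120).
#' @param home_pull Mean-reversion of targets toward screen center per
#'   fixation, in (0, 1) (default 0.4; stationary target SD is
#'   \code{jump_scale_px / sqrt(1 - (1 - home_pull)^2)}).
#' @param saccade_ms Saccade (linear-interpolation) duration (default 30 ms).
#' @param subject_noise_px Per-subject fixational/measurement noise SD
#'   (default 20 px, roughly 0.5 degrees at a desktop viewing distance).
#' @param divergent_segments List of \code{c(start_ms, end_ms)} intervals in
#'   which subjects follow independent paths; must lie within the video.
#' @param blink_rate_hz Blink/dropout events per second (default 0.15).
#' @param blink_duration_ms Dropout length per event (default 200 ms).
#' @param seed Optional RNG seed.
#' @return A validated list of class \code{"synth_config"}.
#' @export
synth_config <- function(n_subjects = 10, duration_ms = 30000, rate_hz = 60,
                         screen_px = c(1024, 758),
                         fixation_mean_ms = 300, jump_scale_px = 120,
                         home_pull = 0.4, saccade_ms = 30,
                         subject_noise_px = 20,
                         divergent_segments = list(),
                         blink_rate_hz = 0.15, blink_duration_ms = 200,
                         seed = NULL) {
  stopifnot(n_subjects >= 1, duration_ms > 0, rate_hz > 0,
            length(screen_px) == 2, all(screen_px > 0),
            fixation_mean_ms > 0, jump_scale_px > 0,
            home_pull > 0, home_pull < 1, saccade_ms >= 0,
            subject_noise_px >= 0, blink_rate_hz >= 0, blink_duration_ms >= 0)
  for (seg in divergent_segments) {
    if (length(seg) != 2 || seg[1] >= seg[2] || seg[1] < 0 ||
        seg[2] > duration_ms)
      stop("divergent segments must be (start_ms, end_ms) within the video")
  }
  structure(list(n_subjects = n_subjects, duration_ms = duration_ms,
                 rate_hz = rate_hz, screen_px = screen_px,
                 fixation_mean_ms = fixation_mean_ms,
                 jump_scale_px = jump_scale_px, home_pull = home_pull,
                 saccade_ms = saccade_ms, subject_noise_px = subject_noise_px,
                 divergent_segments = divergent_segments,
                 blink_rate_hz = blink_rate_hz,
                 blink_duration_ms = blink_duration_ms, seed = seed),
            class = "synth_config")
}

# One attention path sampled at the gaze clock: fixation onsets with
# exponential durations, mean-reverting Gaussian target jumps, linear
# saccade ramps between targets.
.gen_path <- function(cfg, t_ms) {
  dur <- cfg$duration_ms
  durs <- numeric(0); total <- 0
  while (total < dur + 2 * cfg$fixation_mean_ms) {
    block <- pmax(80, stats::rexp(32, 1 / cfg$fixation_mean_ms))
    durs <- c(durs, block); total <- sum(durs)
  }
  onsets <- c(0, cumsum(durs))
  k <- which(onsets >= dur)[1]
  onsets <- onsets[seq_len(k + 1)]
  n_fix <- length(onsets) - 1
  center <- cfg$screen_px / 2
  tx <- numeric(n_fix); ty <- numeric(n_fix)
  keep <- 1 - cfg$home_pull
  px <- center[1]; py <- center[2]
  jumps <- matrix(stats::rnorm(2 * n_fix, 0, cfg$jump_scale_px), ncol = 2)
  for (i in seq_len(n_fix)) {
    px <- center[1] + keep * (px - center[1]) + jumps[i, 1]
    py <- center[2] + keep * (py - center[2]) + jumps[i, 2]
    tx[i] <- px; ty[i] <- py
  }
  # knots: hold each target from its onset until the next onset minus the
  # saccade duration, then ramp linearly to the next target
  hold_end <- pmax(onsets[-1] - cfg$saccade_ms, onsets[-length(onsets)])
  kt <- as.vector(rbind(onsets[-length(onsets)], hold_end))
  kx <- rep(tx, each = 2)
  ky <- rep(ty, each = 2)
  list(x = stats::approx(kt, kx, xout = t_ms, rule = 2)$y,
       y = stats::approx(kt, ky, xout = t_ms, rule = 2)$y)
}

#' Generate a synthetic two-viewing gaze cohort with known ground truth
#'
#' All subject-viewings follow one shared attention path outside the
#' configured divergent segments and independent paths (same process) inside
#' them; per-subject Gaussian noise, Poisson blink dropouts (coordinates
#' lost, validity flag cleared) and screen-bound clipping are applied on top.
#' Streams are returned epoched (t = 0 at video onset).
#'
#' @param config A \code{\link{synth_config}}.
#' @return A list with \code{viewing1} and \code{viewing2} (lists of
#'   \code{\link{gaze_stream}}), \code{segments} (the divergent intervals),
#'   \code{n_clipped} (count of samples clipped to screen bounds) and
#'   \code{config}.
#' @seealso \code{\link{divergent_truth}} for the per-window truth indicator.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- floor(config$duration_ms * config$rate_hz / 1000)
  t_ms <- (seq_len(n) - 1) * 1000 / config$rate_hz
  shared <- .gen_path(config, t_ms)
  segs <- config$divergent_segments
  in_seg <- rep(FALSE, n)
  for (seg in segs) in_seg <- in_seg | (t_ms >= seg[1] & t_ms < seg[2])
  n_clipped <- 0L
  make_stream <- function(subject, viewing) {
    x <- shared$x; y <- shared$y
    if (any(in_seg)) {
      own <- .gen_path(config, t_ms)
      x[in_seg] <- own$x[in_seg]
      y[in_seg] <- own$y[in_seg]
    }
    x <- x + stats::rnorm(n, 0, config$subject_noise_px)
    y <- y + stats::rnorm(n, 0, config$subject_noise_px)
    clip <- x < 0 | x > config$screen_px[1] - 1 |
            y < 0 | y > config$screen_px[2] - 1
    n_clipped <<- n_clipped + sum(clip)
    x <- pmin(pmax(x, 0), config$screen_px[1] - 1)
    y <- pmin(pmax(y, 0), config$screen_px[2] - 1)
    valid <- rep(TRUE, n)
    n_blinks <- stats::rpois(1, config$blink_rate_hz * config$duration_ms / 1000)
    if (n_blinks > 0) {
      starts <- stats::runif(n_blinks, 0, config$duration_ms)
      for (b in starts) {
        hit <- t_ms >= b & t_ms < b + config$blink_duration_ms
        valid[hit] <- FALSE
      }
    }
    x[!valid] <- NA_real_; y[!valid] <- NA_real_
    gaze_stream(subject, "video", viewing, t_ms, x, y, valid,
                rate_hz = config$rate_hz)
  }
  subjects <- sprintf("S%02d", seq_len(config$n_subjects))
  v1 <- lapply(subjects, make_stream, viewing = 1L)
  v2 <- lapply(subjects, make_stream, viewing = 2L)
  list(viewing1 = v1, viewing2 = v2, segments = segs,
       n_clipped = n_clipped, config = config)
}

#' Ground-truth divergent windows of a grid
#'
#' Marks the grid windows that overlap any configured divergent segment.
#'
#' @param grid A \code{\link{window_grid}}.
#' @param segments List of \code{c(start_ms, end_ms)} divergent intervals.
#' @return Logical vector of length \code{grid$n_windows}.
#' @export
divergent_truth <- function(grid, segments) {
  starts <- window_starts(grid)
  out <- rep(FALSE, grid$n_windows)
  for (seg in segments) {
    out <- out | (starts < seg[2] & starts + grid$window_ms > seg[1])
  }
  out
}

#' The 2014 Super Bowl Ad-Meter ratings used as the reference score fixture
#'
#' Twelve narrative advertisements aired during the 2014 Super Bowl telecast
#' with their USA TODAY Ad-Meter likeability ratings, the preference scores
#' the prediction harness regresses against.
#'
#' @return A data frame with columns \code{video}, \code{description},
#'   \code{score}.
#' @export
admeter_2014 <- function() {
  data.frame(
    video = as.character(1:12),
    description = c("Grace (Cheerios)", "Puppet Master (Go Daddy)",
                    "Hero's Welcome (Budweiser)", "Time Machine (Doritos)",
                    "100,000 Miles (Volkswagen)", "Nice (Hyundai)",
                    "Puppy Love (Budweiser)", "Romance (Chevrolet)",
                    "Cowboy Kid (Doritos)", "Bodybuilder (Go Daddy)",
                    "Sixth Sense (Hyundai)", "Luxury (KIA)"),
    score = c(6.75, 4.66, 7.21, 7.13, 6.24, 6.10, 8.29, 6.18, 7.58, 4.04,
              6.87, 6.09),
    stringsAsFactors = FALSE
  )
}

#' Generate a full synthetic study with known regression ground truth
#'
#' Builds a 12-video (by default) end-to-end fixture: each video's divergent-
#' segment coverage is a decreasing linear map of its target preference
#' score, so that true divergence and preference are perfectly (negatively)
#' monotonically linked. Gaze is placed in recording time with a 1000 ms
#' pre-roll and accompanied by event markers; inter-beat-interval series are
#' generated per subject (a resting baseline plus one series per
#' video-viewing) with RMSSD targets that decrease with divergence coverage,
#' so the gaze and cardiac branches share a common ground truth.
#'
#' @param scores Data frame with \code{video} and \code{score} columns
#'   (default \code{\link{admeter_2014}}).
#' @param n_subjects,duration_ms,rate_hz,subject_noise_px Passed to
#'   \code{\link{synth_config}} per video.
#' @param coverage_range Divergence coverage mapped linearly (and
#'   decreasingly) from score onto this interval (default 0.05--0.70).
#' @param onset_ms Recording-time video onset written to the markers table
#'   (default 1000 ms).
#' @param ibi_mean_ms Mean inter-beat interval (default 850 ms).
#' @param rmssd_base_ms Baseline RMSSD target (default 45 ms).
#' @param baseline_minutes Resting baseline length (default 5 min).
#' @param seed RNG seed for the whole study.
#' @return A list with \code{streams} (recording-time gaze streams across all
#'   videos), \code{markers}, \code{scores}, \code{ibi} (long interval
#'   table), \code{truth} (per-video coverage and segment) and \code{params}.
#' @export
generate_study <- function(scores = admeter_2014(), n_subjects = 10,
                           duration_ms = 30000, rate_hz = 60,
                           subject_noise_px = 20,
                           coverage_range = c(0.05, 0.70),
                           onset_ms = 1000,
                           ibi_mean_ms = 850, rmssd_base_ms = 45,
                           baseline_minutes = 5, seed = NULL) {
  stopifnot(all(c("video", "score") %in% names(scores)))
  if (!is.null(seed)) set.seed(seed)
  s <- scores$score
  coverage <- coverage_range[1] +
    (max(s) - s) / (max(s) - min(s)) * diff(coverage_range)
  subjects <- sprintf("S%02d", seq_len(n_subjects))

  all_streams <- list()
  markers <- data.frame(video = character(0), t_start_ms = numeric(0),
                        t_end_ms = numeric(0), stringsAsFactors = FALSE)
  truth <- data.frame(video = character(0), coverage = numeric(0),
                      seg_start_ms = numeric(0), seg_end_ms = numeric(0),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(scores))) {
    q <- coverage[i]
    seg <- c((1 - q) / 2, (1 + q) / 2) * duration_ms
    segs <- if (q > 1e-9) list(seg) else list()
    cfg <- synth_config(n_subjects = n_subjects, duration_ms = duration_ms,
                        rate_hz = rate_hz,
                        subject_noise_px = subject_noise_px,
                        divergent_segments = segs, seed = NULL)
    cohort <- generate_cohort(cfg)
    vid <- as.character(scores$video[i])
    shift <- function(st) {
      st$video_id <- vid
      st$samples$t_ms <- st$samples$t_ms + onset_ms
      st
    }
    all_streams <- c(all_streams, lapply(c(cohort$viewing1, cohort$viewing2),
                                         shift))
    markers <- rbind(markers, data.frame(video = vid, t_start_ms = onset_ms,
                                         t_end_ms = onset_ms + duration_ms,
                                         stringsAsFactors = FALSE))
    truth <- rbind(truth, data.frame(video = vid, coverage = q,
                                     seg_start_ms = seg[1],
                                     seg_end_ms = seg[2],
                                     stringsAsFactors = FALSE))
  }

  ibi_rows <- list()
  for (subj in subjects) {
    base <- generate_ibi(baseline_minutes, mean_ms = ibi_mean_ms,
                         rmssd_target_ms = rmssd_base_ms)
    ibi_rows[[length(ibi_rows) + 1]] <-
      data.frame(subject = subj, context = "baseline", video = NA_character_,
                 viewing = NA_integer_, interval_ms = base$intervals,
                 stringsAsFactors = FALSE)
    for (i in seq_len(nrow(scores))) {
      for (vw in 1:2) {
        target <- rmssd_base_ms * (1.05 - 0.5 * coverage[i]) *
          exp(stats::rnorm(1, 0, 0.08))
        ser <- generate_ibi(duration_ms / 60000, mean_ms = ibi_mean_ms,
                            rmssd_target_ms = target)
        ibi_rows[[length(ibi_rows) + 1]] <-
          data.frame(subject = subj, context = "video",
                     video = as.character(scores$video[i]), viewing = vw,
                     interval_ms = ser$intervals, stringsAsFactors = FALSE)
      }
    }
  }
  list(streams = all_streams, markers = markers,
       scores = scores[, c("video", "score")],
       ibi = do.call(rbind, ibi_rows), truth = truth,
       params = list(n_subjects = n_subjects, duration_ms = duration_ms,
                     rate_hz = rate_hz, coverage_range = coverage_range,
                     onset_ms = onset_ms, seed = seed))
}

#' Generate a synthetic inter-beat-interval series
#'
#' First-order autoregressive interval process around \code{mean_ms} whose
#' innovation scale is set so that the expected RMSSD equals
#' \code{rmssd_target_ms}: for AR(1) with coefficient \eqn{\phi} the
#' successive-difference variance is \eqn{2\sigma^2/(1+\phi)}, so the
#' innovation SD used is \code{rmssd_target_ms * sqrt((1 + phi)/2)}.
#'
#' @param minutes Recording length in minutes.
#' @param mean_ms Mean inter-beat interval (default 850 ms, ~70 bpm).
#' @param rmssd_target_ms Target expected RMSSD (0 gives a constant series).
#' @param phi AR(1) coefficient (default 0.5).
#' @param seed Optional RNG seed.
#' @return An \code{\link{ibi_series}} (video context unless relabeled).
#' @export
generate_ibi <- function(minutes, mean_ms = 850, rmssd_target_ms = 40,
                         phi = 0.5, seed = NULL) {
  stopifnot(minutes > 0, mean_ms > 0, rmssd_target_ms >= 0,
            phi >= 0, phi < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- max(2L, round(minutes * 60000 / mean_ms))
  if (rmssd_target_ms == 0) {
    return(ibi_series(rep(mean_ms, n)))
  }
  s <- rmssd_target_ms * sqrt((1 + phi) / 2)
  e <- stats::rnorm(n, 0, s)
  z <- as.numeric(stats::filter(e, phi, method = "recursive"))
  ibi_series(pmax(mean_ms + z, 1))
}
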