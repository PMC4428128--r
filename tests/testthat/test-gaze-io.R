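test_that("gaze tables parse into one stream per subject/video/viewing", {
  path <- write_tmp_csv(c(
    "subject,video,viewing,t_ms,x_px,y_px,valid",
    sprintf("s1,v1,1,%d,%d,%d,1", seq(0, 100, 20), 100:105, 200:205)))
  streams <- read_gaze_table(path)
  expect_length(streams, 1)
  expect_equal(nrow(streams[[1]]$samples), 6)
  expect_equal(streams[[1]]$subject_id, "s1")
  expect_equal(streams[[1]]$viewing, 1L)
  expect_true(all(streams[[1]]$samples$valid))
})

test_that("unparseable coordinates mark the sample invalid, keeping length", {
  path <- write_tmp_csv(c(
    "subject,video,viewing,t_ms,x_px,y_px,valid",
    "s1,v1,1,0,100,200,1",
    "s1,v1,1,20,NaN,210,1",
    "s1,v1,1,40,120,220,1"))
  s <- read_gaze_table(path)[[1]]
  expect_equal(nrow(s$samples), 3)
  expect_equal(s$samples$valid, c(TRUE, FALSE, TRUE))
})

test_that("format errors name the offending column; empty input errors", {
  path <- write_tmp_csv(c("subject,video,viewing,t_ms,x_px,valid",
                          "s1,v1,1,0,100,1"))
  expect_error(read_gaze_table(path), "y_px")
  empty <- tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(read_gaze_table(empty), "empty")
})

test_that("writer/reader round-trip preserves numeric fields to full precision", {
  set.seed(42)
  streams <- list(
    make_stream("s1", "v1", 1, duration_ms = 500),
    make_stream("s1", "v1", 2, duration_ms = 500),
    make_stream("s2", "v1", 1, duration_ms = 500,
                valid = c(rep(TRUE, 20), rep(FALSE, 10))),
    make_stream("s2", "v1", 2, duration_ms = 500))
  path <- tempfile(fileext = ".csv")
  write_gaze_table(streams, path)
  back <- read_gaze_table(path)
  expect_length(back, 4)
  keys <- sort(vapply(streams, function(s)
    paste(s$subject_id, s$video_id, s$viewing, sep = "|"), character(1)))
  expect_equal(names(back), keys)
  orig <- streams[order(vapply(streams, function(s)
    paste(s$subject_id, s$video_id, s$viewing, sep = "|"), character(1)))]
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$samples$t_ms, orig[[i]]$samples$t_ms)
    ok <- orig[[i]]$samples$valid
    expect_identical(back[[i]]$samples$x_px[ok], orig[[i]]$samples$x_px[ok])
    expect_identical(back[[i]]$samples$y_px[ok], orig[[i]]$samples$y_px[ok])
    expect_identical(back[[i]]$samples$valid, orig[[i]]$samples$valid)
  }
})

test_that("tab-delimited tables are autodetected", {
  path <- write_tmp_csv(c("subject\tvideo\tviewing\tt_ms\tx_px\ty_px\tvalid",
                          "s1\tv1\t1\t0\t10\t20\t1"))
  expect_length(read_gaze_table(path), 1)
})

test_that("epoching selects the padded interval and re-references to onset", {
  s <- make_stream(duration_ms = 40000, rate = 60)
  marker <- data.frame(video = "v", t_start_ms = 5000, t_end_ms = 35000)
  e <- epoch_stream(s, marker, pre_ms = 1000, post_ms = 1000)
  expect_gte(min(e$samples$t_ms), -1000)
  expect_lte(max(e$samples$t_ms), 31000)
  # original recording times 4000..36000 survive
  expect_equal(nrow(e$samples),
               sum(s$samples$t_ms >= 4000 & s$samples$t_ms <= 36000))
  # marker at stream start with no pre-padding: first sample at onset
  e0 <- epoch_stream(s, data.frame(video = "v", t_start_ms = 0,
                                   t_end_ms = 1000), pre_ms = 0, post_ms = 0)
  expect_equal(e0$samples$t_ms[1], 0)
  expect_error(epoch_stream(s, data.frame(video = "v", t_start_ms = 1e6,
                                          t_end_ms = 2e6)), "empty epoch")
})

test_that("epoching matches a brute-force filter-and-shift oracle", {
  set.seed(7)
  for (rep in 1:20) {
    s <- make_stream(duration_ms = 20000)
    t0 <- runif(1, 1000, 8000)
    t1 <- t0 + runif(1, 2000, 10000)
    pre <- runif(1, 0, 1500); post <- runif(1, 0, 1500)
    e <- epoch_stream(s, data.frame(video = "v", t_start_ms = t0,
                                    t_end_ms = t1), pre, post)
    keep <- s$samples$t_ms >= t0 - pre & s$samples$t_ms <= t1 + post
    expect_equal(e$samples$t_ms, s$samples$t_ms[keep] - t0)
    expect_equal(e$samples$x_px, s$samples$x_px[keep])
  }
})

test_that("window grid arithmetic follows floor((dur - win)/step) + 1", {
  g <- window_grid(10000)
  expect_equal(g$n_windows, 196L)
  expect_equal(window_starts(g)[1:3], c(0, 50, 100))
  expect_equal(window_grid(250)$n_windows, 1L)
  expect_error(window_grid(100), "shorter")
  expect_error(window_grid(10000, step_ms = 300), "step_ms")
  expect_error(window_grid(10000, window_ms = -1), "window_ms")
})

test_that("pooled window matrices concatenate valid samples subject-wise", {
  s1 <- make_stream("s1", duration_ms = 1000)
  s2 <- make_stream("s2", duration_ms = 1000)
  g <- window_grid(1000)
  m <- build_window_matrix(list(s1, s2), 0, g)
  expect_equal(ncol(m$coords), 30)           # 2 subjects x 15 samples @60 Hz
  expect_false(m$insufficient)
  expect_equal(m$origin$subject, rep(c("s1", "s2"), each = 15))

  # one subject fully blinking: 15 of 30 valid = exactly the 0.5 boundary
  s2b <- make_stream("s2", duration_ms = 1000,
                     valid = c(rep(FALSE, 15), rep(TRUE, 45)))
  mb <- build_window_matrix(list(s1, s2b), 0, g, min_valid_fraction = 0.5)
  expect_equal(ncol(mb$coords), 15)
  expect_equal(mb$valid_fraction, 0.5)
  expect_false(mb$insufficient)              # >= threshold is retained
})

test_that("random validity masks match a per-sample filter oracle", {
  set.seed(11)
  g <- window_grid(2000)
  for (rep in 1:15) {
    streams <- lapply(1:3, function(i)
      make_stream(paste0("s", i), duration_ms = 2000,
                  valid = runif(120) > 0.3))
    start <- sample(window_starts(g), 1)
    m <- build_window_matrix(streams, start, g)
    ref <- do.call(cbind, lapply(streams, function(s) {
      sub <- s$samples[s$samples$t_ms >= start &
                       s$samples$t_ms < start + g$window_ms & s$samples$valid, ]
      rbind(sub$x_px, sub$y_px)
    }))
    expect_equal(unname(m$coords), unname(ref))
    expect_equal(m$n_valid, sum(vapply(streams, function(s)
      sum(s$samples$valid[s$samples$t_ms >= start &
                          s$samples$t_ms < start + g$window_ms]), numeric(1))))
  }
})

test_that("epoch-then-window equals windowing the raw stream at shifted starts", {
  set.seed(13)
  s <- make_stream(duration_ms = 12000)
  t0 <- 2000
  e <- epoch_stream(s, data.frame(video = "v", t_start_ms = t0,
                                  t_end_ms = 10000), pre_ms = 0, post_ms = 0)
  g <- window_grid(4000)
  for (start in c(0, 500, 1250)) {
    m_epoched <- build_window_matrix(list(e), start, g)
    m_raw <- build_window_matrix(list(s), start + t0, g)
    expect_equal(m_epoched$coords, m_raw$coords)
  }
})

test_that("stream construction enforces time ordering and finite-valid coupling", {
  expect_error(gaze_stream("s", "v", 1, c(0, 0, 1), 1:3, 1:3), "increasing")
  s <- gaze_stream("s", "v", 1, c(0, 10, 20), c(1, NA, 3), c(1, 2, 3))
  expect_equal(s$samples$valid, c(TRUE, FALSE, TRUE))
})
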