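test_that("between-rendition dispersion matches its closed-form examples", {
  p <- matrix(c(5, 5), ncol = 1)
  expect_equal(pairwise_dispersion(p, p, "as_printed"), 0)
  expect_equal(pairwise_dispersion(p, p, "euclidean"), 0)

  a <- matrix(c(0, 0), ncol = 1)
  b <- matrix(c(3, 4), ncol = 1)
  expect_equal(pairwise_dispersion(a, b, "as_printed"), 25)
  expect_equal(pairwise_dispersion(a, b, "euclidean"), 5)

  V <- cbind(c(0, 0), c(2, 0))
  W <- cbind(c(1, 1), c(3, 1))
  expect_equal(pairwise_dispersion(V, W, "as_printed"), 4.0)
  expect_equal(pairwise_dispersion(V, W, "as_printed"), oracle_pairwise(V, W))
})

test_that("within-rendition dispersion handles degenerate and toy cases", {
  const <- matrix(rep(c(7, 9), 5), nrow = 2)
  expect_equal(within_dispersion(const, "as_printed"), 0)
  expect_equal(within_dispersion(matrix(c(1, 2), ncol = 1)), 0)

  V <- cbind(c(0, 0), c(0, 2))   # two ordered pairs, each distance^2 = 4
  expect_equal(within_dispersion(V, "as_printed"), 2.0)
  expect_equal(within_dispersion(V, "as_printed"), oracle_within(V))

  expect_error(pairwise_dispersion(matrix(numeric(0), nrow = 2), V), "empty")
  expect_error(within_dispersion(matrix(numeric(0), nrow = 2)), "empty")
})

test_that("closed forms agree with loop oracles on random matrices", {
  set.seed(101)
  for (rep in 1:40) {
    V <- rand_matrix(sample(1:30, 1))
    W <- rand_matrix(sample(1:30, 1))
    for (m in c("as_printed", "euclidean")) {
      expect_equal(pairwise_dispersion(V, W, m), oracle_pairwise(V, W, m),
                   tolerance = 1e-9)
      expect_equal(within_dispersion(V, m), oracle_within(V, m),
                   tolerance = 1e-9)
    }
  }
})

test_that("dispersion is symmetric, translation-invariant and scales as c^2 / |c|", {
  set.seed(7)
  for (rep in 1:25) {
    V <- rand_matrix(sample(2:20, 1))
    W <- rand_matrix(sample(2:20, 1))
    expect_identical(pairwise_dispersion(V, W), pairwise_dispersion(W, V))
    shift <- stats::rnorm(2, 0, 500)
    for (m in c("as_printed", "euclidean")) {
      d0 <- pairwise_dispersion(V, W, m)
      expect_equal(pairwise_dispersion(V + shift, W + shift, m), d0,
                   tolerance = 1e-9)
      expect_equal(within_dispersion(V + shift, m), within_dispersion(V, m),
                   tolerance = 1e-9)
      cc <- stats::runif(1, -3, 3)
      fac <- if (m == "as_printed") cc^2 else abs(cc)
      expect_equal(pairwise_dispersion(cc * V, cc * W, m), fac * d0,
                   tolerance = 1e-9)
    }
  }
})

test_that("unequal column counts average over all N_V x N_W pairs", {
  set.seed(3)
  V <- rand_matrix(7); W <- rand_matrix(13)
  expect_equal(pairwise_dispersion(V, W), oracle_pairwise(V, W),
               tolerance = 1e-12)
})

test_that("series over the default grid has the expected window count", {
  set.seed(5)
  v1 <- lapply(1:2, function(i) make_stream(paste0("s", i), viewing = 1,
                                            duration_ms = 10000))
  v2 <- lapply(1:2, function(i) make_stream(paste0("s", i), viewing = 2,
                                            duration_ms = 10000))
  ser <- dispersion_series(v1, v2)
  expect_equal(nrow(ser), 196)
  expect_equal(attr(ser, "mode"), "between")
  expect_true(all(ser$d[ser$usable] >= 0))
})

test_that("identical renditions reduce to self-dispersion; a shared constant
          fixation gives exactly zero", {
  set.seed(9)
  # identical gaze in both viewings: the all-pairs average against itself,
  # equal to the explicit D(V, V) oracle on each pooled window
  x <- runif(240, 0, 1000); y <- runif(240, 0, 700)
  mk <- function(i, v) make_stream(paste0("s", i), viewing = v,
                                   duration_ms = 2000,
                                   x = x[1:120 + (i - 1) * 120],
                                   y = y[1:120 + (i - 1) * 120])
  v1 <- lapply(1:2, mk, v = 1)
  v2 <- lapply(1:2, mk, v = 2)
  ser <- dispersion_series(v1, v2)
  grid <- attr(ser, "grid")
  starts <- window_starts(grid)
  for (w in seq(1, grid$n_windows, by = 9)) {
    V <- build_window_matrix(v1, starts[w], grid)$coords
    expect_equal(ser$d[w], oracle_pairwise(V, V), tolerance = 1e-9)
  }
  # every subject fixating one shared constant point: all scores vanish
  const1 <- lapply(1:2, function(i)
    make_stream(paste0("s", i), viewing = 1, duration_ms = 2000,
                x = rep(512, 120), y = rep(379, 120)))
  const2 <- lapply(1:2, function(i)
    make_stream(paste0("s", i), viewing = 2, duration_ms = 2000,
                x = rep(512, 120), y = rep(379, 120)))
  ser0 <- dispersion_series(const1, const2)
  expect_true(all(abs(ser0$d[ser0$usable]) < 1e-8))
})

test_that("series equals per-window brute-force recomputation, and injected
          divergence carries the largest scores", {
  cfg <- synth_config(n_subjects = 3, duration_ms = 6000,
                      divergent_segments = list(c(2000, 4000)), seed = 21)
  co <- generate_cohort(cfg)
  for (metric in c("as_printed", "euclidean")) {
    ser <- dispersion_series(co$viewing1, co$viewing2, metric = metric)
    grid <- attr(ser, "grid")
    starts <- window_starts(grid)
    idx <- seq(1, grid$n_windows, by = 7)
    for (w in idx) {
      if (!ser$usable[w]) next
      V <- build_window_matrix(co$viewing1, starts[w], grid)
      W <- build_window_matrix(co$viewing2, starts[w], grid)
      expect_equal(ser$d[w], oracle_pairwise(V$coords, W$coords, metric),
                   tolerance = 1e-9)
    }
    truth <- divergent_truth(grid, co$segments)
    top <- order(ser$d, decreasing = TRUE)[1:10]
    expect_true(all(truth[top]))
  }
  # within mode against its own oracle
  ser_w <- dispersion_series(co$viewing1)
  grid <- attr(ser_w, "grid")
  starts <- window_starts(grid)
  for (w in seq(1, grid$n_windows, by = 11)) {
    if (!ser_w$usable[w]) next
    V <- build_window_matrix(co$viewing1, starts[w], grid)
    expect_equal(ser_w$d[w], oracle_within(V$coords), tolerance = 1e-9)
  }
})

test_that("windows failing the valid-fraction rule are masked unusable", {
  # subject 2 blinks throughout the first 500 ms; with 2 subjects the pooled
  # fraction is exactly 0.5 there (not masked at the default threshold), and
  # masked at a stricter threshold
  s1 <- make_stream("s1", viewing = 1, duration_ms = 2000)
  s2 <- make_stream("s2", viewing = 1, duration_ms = 2000,
                    valid = c(rep(FALSE, 30), rep(TRUE, 90)))
  ser_default <- dispersion_series(list(s1, s2))
  expect_true(all(ser_default$usable))
  ser_strict <- dispersion_series(list(s1, s2), min_valid_fraction = 0.75)
  early <- ser_default$window_start_ms + 250 <= 500
  expect_true(all(!ser_strict$usable[early]))
  expect_true(all(is.na(ser_strict$d[early])))
})

test_that("a grid longer than the common duration is rejected", {
  s <- make_stream(duration_ms = 1000)
  expect_error(dispersion_series(list(s), grid = window_grid(5000)),
               "grid extends")
})
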