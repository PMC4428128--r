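# Shared fixtures and independent brute-force oracles.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A gaze stream sampled on a regular clock; random coordinates unless given.
make_stream <- function(subject = "s1", video = "v", viewing = 1, rate = 60,
                        duration_ms = 1000, x = NULL, y = NULL, valid = NULL,
                        t0 = 0) {
  n <- floor(duration_ms * rate / 1000)
  t <- t0 + (seq_len(n) - 1) * 1000 / rate
  if (is.null(x)) x <- stats::runif(n, 0, 1023)
  if (is.null(y)) y <- stats::runif(n, 0, 757)
  gaze_stream(subject, video, viewing, t, x, y, valid %||% rep(TRUE, n),
              rate_hz = rate)
}

rand_matrix <- function(n, scale = 100) {
  matrix(stats::rnorm(2 * n, 0, scale), nrow = 2)
}

# Explicit double-loop dispersion between two renditions (reference route,
# kept independent of the package's closed forms).
oracle_pairwise <- function(V, W, metric = "as_printed") {
  tot <- 0
  for (i in seq_len(ncol(V))) {
    for (j in seq_len(ncol(W))) {
      ss <- (V[1, i] - W[1, j])^2 + (V[2, i] - W[2, j])^2
      tot <- tot + if (metric == "as_printed") ss else sqrt(ss)
    }
  }
  tot / (ncol(V) * ncol(W))
}

# Explicit ordered-pair loop for the within-rendition score (N^2 norm).
oracle_within <- function(V, metric = "as_printed") {
  n <- ncol(V)
  tot <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ss <- (V[1, i] - V[1, j])^2 + (V[2, i] - V[2, j])^2
      tot <- tot + if (metric == "as_printed") ss else sqrt(ss)
    }
  }
  tot / n^2
}

# Hand-built dispersion series / null model for unit tests of the
# classification layer.
fake_series <- function(d, usable = rep(TRUE, length(d)), mode = "between",
                        video = "v") {
  out <- data.frame(window_start_ms = (seq_along(d) - 1) * 50, d = d,
                    usable = usable)
  out$d[!usable] <- NA_real_
  attr(out, "mode") <- mode
  attr(out, "video_id") <- video
  class(out) <- c("dispersion_series", "data.frame")
  out
}

fake_null <- function(mu, mode = "between", sigma = 0) {
  structure(list(samples = mu, mu = mu, sigma = sigma, n_samples = 1,
                 seed = NULL, mode = mode, metric = "as_printed"),
            class = "null_model")
}

write_tmp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
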