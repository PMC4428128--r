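#' Univariate least-squares preference model
#'
#' Fits \eqn{y = b_0 + b_1 \, x} by ordinary least squares, where x is the
#' per-video iGDI and y the audience preference score, and reports the fit
#' statistics in the form used for such models: Pearson r, R^2, the F
#' statistic on (1, n-2) degrees of freedom and its two-tailed p-value.
#'
#' @param x Numeric iGDI values (one per video).
#' @param y Numeric preference scores, same length.
#' @return An object of class \code{"igdi_lm"}: list with \code{b0},
#'   \code{b1}, \code{r}, \code{r2}, \code{f_stat}, \code{df}, \code{p_value},
#'   \code{n} and the underlying \code{\link[stats]{lm}} fit.
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("x and y must not contain NA")
  if (stats::var(x) == 0) stop("degenerate predictor: x is constant")
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  b <- stats::coef(fit)
  # suppressed: summary.lm warns on zero-residual (perfect) fits, which are
  # legitimate inputs here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  r <- sign(b[["x"]]) * sqrt(r2)
  if (stats::var(y) == 0) { r <- 0; r2 <- 0 }
  f_stat <- if (r2 < 1) r2 * (n - 2) / (1 - r2) else Inf
  p <- stats::pf(f_stat, 1, n - 2, lower.tail = FALSE)
  structure(list(b0 = unname(b[1]), b1 = unname(b[2]),
                 r = r, r2 = r2, f_stat = f_stat, df = c(1, n - 2),
                 p_value = p, n = n, fit = fit),
            class = "igdi_lm")
}

#' @export
print.igdi_lm <- function(x, ...) {
  cat(sprintf("<igdi_lm> y = %.4g %+.4g x  (n = %d)\n", x$b0, x$b1, x$n))
  cat(sprintf("  R = %.3f, R^2 = %.4f, F(1, %d) = %.3f, p = %.4g\n",
              x$r, x$r2, x$df[2], x$f_stat, x$p_value))
  invisible(x)
}

#' Leave-one-out cross-validation of the preference model
#'
#' Refits the univariate model n times, each time excluding one video, and
#' predicts the held-out score. Reports root mean squared error, mean
#' absolute percentage error, the cross-validated R^2, the shrinkage (full-fit
#' R^2 minus cross-validated R^2, a generalization-optimism estimate) and the
#' standard deviations of slope and intercept across the n refits.
#'
#' @param x,y As in \code{\link{fit_linear}}; n must be at least 4.
#' @param r2_method \code{"press"} (default): \eqn{R^2_{cv} = 1 -
#'   SS_{res}(\hat y)/SS_{tot}(y)} on held-out predictions; or \code{"cor"}:
#'   squared correlation of held-out predictions with y.
#' @return An object of class \code{"igdi_cv"}: list with \code{rmse},
#'   \code{mape} (\code{NA} with a warning if any y is 0), \code{r2_cv},
#'   \code{shrinkage}, \code{coef_sd} (named b1, b0), \code{predictions},
#'   \code{n}.
#' @export
loocv <- function(x, y, r2_method = c("press", "cor")) {
  r2_method <- match.arg(r2_method)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4) stop("need at least 4 observations for leave-one-out")
  full <- fit_linear(x, y)
  b1s <- numeric(n); b0s <- numeric(n); yhat <- numeric(n)
  for (i in seq_len(n)) {
    fi <- fit_linear(x[-i], y[-i])
    b1s[i] <- fi$b1; b0s[i] <- fi$b0
    yhat[i] <- fi$b0 + fi$b1 * x[i]
  }
  err <- y - yhat
  rmse <- sqrt(mean(err^2))
  if (any(y == 0)) {
    warning("MAPE undefined: at least one observed score is 0")
    mape <- NA_real_
  } else {
    mape <- 100 * mean(abs(err) / abs(y))
  }
  r2_cv <- if (r2_method == "press") {
    1 - sum(err^2) / sum((y - mean(y))^2)
  } else {
    stats::cor(yhat, y)^2
  }
  structure(list(rmse = rmse, mape = mape, r2_cv = r2_cv,
                 shrinkage = full$r2 - r2_cv,
                 coef_sd = c(b1 = stats::sd(b1s), b0 = stats::sd(b0s)),
                 predictions = yhat, n = n, r2_full = full$r2,
                 r2_method = r2_method),
            class = "igdi_cv")
}

#' @export
print.igdi_cv <- function(x, ...) {
  cat(sprintf("<igdi_cv> leave-one-out over n = %d:\n", x$n))
  cat(sprintf("  RMSE = %.4f, MAPE = %s%%, R^2_cv = %.4f, shrinkage = %.4f\n",
              x$rmse, ifelse(is.na(x$mape), "NA", sprintf("%.1f", x$mape)),
              x$r2_cv, x$shrinkage))
  cat(sprintf("  sd(b1) = %.4g, sd(b0) = %.4g across refits\n",
              x$coef_sd[["b1"]], x$coef_sd[["b0"]]))
  invisible(x)
}
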