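# Shape-constrained piecewise-cubic smoothing of fed-batch timecourses.
#
# Measured concentrations and cell densities are interpolated with
# continuously differentiable piecewise cubics: at most four segments
# (to avoid overfitting) joined with C1 continuity, and optionally
# constrained to non-negative values on the data interval. The fit is a
# linear least-squares problem in a truncated-power basis; when the
# unconstrained fit dips below zero it is re-solved as a quadratic
# program with non-negativity enforced on a dense grid.

#' Create a timecourse
#'
#' @param times sampling times in hours, strictly increasing.
#' @param values measured values (concentration or cell density).
#' @param unit declared unit token (e.g. `"mmol/L"`, `"g/L"`, `"cells/mL"`).
#' @param errors optional per-point standard deviations (same length,
#'   non-negative).
#' @return A `chofba_timecourse`.
#' @export
timecourse <- function(times, values, unit = "mmol/L", errors = NULL) {
  assert_that(length(times) == length(values) && length(times) > 0,
              "times and values must have equal positive length")
  assert_that(all(diff(times) > 0), "times must be strictly increasing")
  assert_that(all(is.finite(values)), "values must be finite")
  if (!is.null(errors)) {
    assert_that(length(errors) == length(values) && all(errors >= 0),
                "errors must be non-negative and match values in length")
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 unit = unit, errors = errors),
            class = "chofba_timecourse")
}

# truncated-power C1 cubic basis on scaled time u in [0, 1] with k segments:
# 1, u, u^2, u^3 and (u - b_j)^2_+, (u - b_j)^3_+ at interior boundaries b_j
tp_basis <- function(u, k, deriv = 0) {
  knots <- if (k > 1) seq_len(k - 1) / k else numeric()
  p <- 2 * k + 2
  B <- matrix(0, length(u), p)
  if (deriv == 0) {
    B[, 1] <- 1; B[, 2] <- u; B[, 3] <- u^2; B[, 4] <- u^3
    for (j in seq_along(knots)) {
      z <- pmax(u - knots[j], 0)
      B[, 3 + 2 * j] <- z^2
      B[, 4 + 2 * j] <- z^3
    }
  } else if (deriv == 1) {
    B[, 2] <- 1; B[, 3] <- 2 * u; B[, 4] <- 3 * u^2
    for (j in seq_along(knots)) {
      z <- pmax(u - knots[j], 0)
      B[, 3 + 2 * j] <- 2 * z
      B[, 4 + 2 * j] <- 3 * z^2
    }
  } else stop_chofba("deriv must be 0 or 1")
  B
}

# non-negative least squares on the basis via quadratic programming;
# falls back to an interior barrier (constrOptim) if the QP solver fails
fit_nonneg_ls <- function(B, y, Bgrid) {
  H <- crossprod(B) + diag(1e-9 * mean(diag(crossprod(B))), ncol(B))
  d <- crossprod(B, y)
  qp <- tryCatch(
    pracma::quadprog(C = H, d = -as.numeric(d), A = -Bgrid, b = rep(0, nrow(Bgrid))),
    error = function(e) NULL)
  if (!is.null(qp) && all(is.finite(qp$xmin)) &&
      min(Bgrid %*% qp$xmin) >= -1e-8) {
    return(qp$xmin)
  }
  # barrier fallback: start from a strictly positive constant fit
  beta0 <- qr.solve(B, rep(max(mean(y), max(abs(y)) * 1e-3, 1e-6), length(y)))
  fn <- function(beta) sum((y - B %*% beta)^2)
  gr <- function(beta) as.numeric(-2 * crossprod(B, y - B %*% beta))
  res <- stats::constrOptim(beta0, fn, gr, ui = Bgrid, ci = rep(0, nrow(Bgrid)),
                            mu = 1e-8, outer.iterations = 200)
  res$par
}

#' Fit a shape-constrained smooth profile
#'
#' Least-squares piecewise cubic with continuous first derivative,
#' at most `max_segments` equally spaced segments, and optional
#' non-negativity of the fitted curve on the data interval. The number of
#' segments used is the smallest one whose residual RMS is within 10% of
#' the RMS of the maximal fit, which guards against overfitting sparse
#' fed-batch timecourses.
#'
#' @param tc a [timecourse()].
#' @param max_segments maximum number of cubic segments (default 4).
#' @param nonneg enforce fitted values >= 0 (default `TRUE`).
#' @param segments force an exact segment count (overrides selection).
#' @param target_rms optional known measurement noise level (same unit
#'   as the values, e.g. the replicate standard deviation). When given,
#'   the smallest segment count whose residual RMS reaches
#'   `1.2 * target_rms` is preferred (discrepancy principle), which
#'   stops the spline from spending its flexibility on measurement
#'   noise; the 10%-of-maximal-fit rule remains the fallback.
#' @param errors optional per-point standard deviations used as inverse
#'   weights (defaults to the timecourse's own `errors` field). With
#'   weights, residuals are in sigma units and the discrepancy target
#'   defaults to 1.
#' @return A `chofba_smooth_profile` with fields `coef`, `segments`,
#'   `t_range`, `nonneg`, `rms`.
#' @export
fit_shape_constrained <- function(tc, max_segments = 4, nonneg = TRUE,
                                  segments = NULL, target_rms = NULL,
                                  errors = NULL) {
  assert_that(inherits(tc, "chofba_timecourse"), "tc must be a chofba_timecourse")
  assert_that(max_segments >= 1, "max_segments must be >= 1")
  n <- length(tc$times)
  assert_that(n >= 5,
              "need at least 5 points to fit a smooth profile (got %d)", n)
  t0 <- tc$times[1]
  t1 <- tc$times[n]
  u <- (tc$times - t0) / (t1 - t0)
  y <- tc$values
  ugrid <- seq(0, 1, length.out = 401)

  # heteroscedastic weighting: with per-point standard deviations the fit
  # minimizes sum((y - f)^2 / sigma^2); low-noise points (e.g. the early,
  # near-zero titer under multiplicative noise) then anchor the local
  # derivative. Floored to avoid infinite weights at exact zeros.
  errors <- errors %||% tc$errors
  w <- NULL
  if (!is.null(errors) && any(errors > 0)) {
    sig <- pmax(errors, 0.2 * mean(errors[errors > 0]))
    w <- 1 / sig
    if (is.null(target_rms)) target_rms <- 1   # weighted residuals ~ N(0,1)
  }

  fit_k <- function(k) {
    p <- 2 * k + 2
    if (n < p) return(NULL)
    B <- tp_basis(u, k)
    Bw <- if (is.null(w)) B else B * w
    yw <- if (is.null(w)) y else y * w
    beta <- tryCatch(qr.solve(Bw, yw), error = function(e) NULL)
    if (is.null(beta)) return(NULL)
    Bgrid <- tp_basis(ugrid, k)
    if (nonneg && min(Bgrid %*% beta) < 0) {
      beta <- fit_nonneg_ls(Bw, yw, Bgrid)
    }
    list(k = k, coef = beta, rms = sqrt(mean((yw - Bw %*% beta)^2)))
  }

  if (!is.null(segments)) {
    assert_that(segments >= 1 && segments <= max_segments,
                "segments must be in [1, max_segments]")
    ft <- fit_k(segments)
    assert_that(!is.null(ft),
                "too few points (%d) for %d segments (%d coefficients); reduce segments",
                n, segments, 2 * segments + 2)
  } else {
    fits <- Filter(Negate(is.null), lapply(seq_len(max_segments), fit_k))
    assert_that(length(fits) > 0,
                "too few points (%d) for even one cubic segment; need >= %d",
                n, 4)
    rms_max <- fits[[length(fits)]]$rms
    ok <- vapply(fits, function(f) f$rms <= 1.1 * rms_max + 1e-12, NA)
    if (!is.null(target_rms) && target_rms > 0) {
      hit <- vapply(fits, function(f) f$rms <= 1.2 * target_rms, NA)
      if (any(hit)) ok <- hit
    }
    ft <- fits[[which(ok)[1]]]
  }
  structure(list(coef = ft$coef, segments = ft$k, t_range = c(t0, t1),
                 nonneg = nonneg, rms = ft$rms, unit = tc$unit),
            class = "chofba_smooth_profile")
}

#' Evaluate a smooth profile
#'
#' @param object a `chofba_smooth_profile`.
#' @param t times (hours) inside the fitted range.
#' @param deriv 0 for the value, 1 for the first time derivative
#'   (per hour).
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.chofba_smooth_profile <- function(object, t, deriv = 0, ...) {
  t0 <- object$t_range[1]; t1 <- object$t_range[2]
  assert_that(all(t >= t0 - 1e-9 & t <= t1 + 1e-9),
              "evaluation time outside the fitted interval [%g, %g] h", t0, t1)
  u <- (t - t0) / (t1 - t0)
  B <- tp_basis(u, object$segments, deriv = deriv)
  val <- as.numeric(B %*% object$coef)
  if (deriv == 1) val <- val / (t1 - t0)
  if (deriv == 0 && object$nonneg) val <- pmax(val, 0)
  val
}

#' @export
print.chofba_smooth_profile <- function(x, ...) {
  cat(sprintf("smooth profile: %d segment(s) on [%g, %g] h, RMS %.4g%s\n",
              x$segments, x$t_range[1], x$t_range[2], x$rms,
              if (x$nonneg) ", non-negative" else ""))
  invisible(x)
}

#' Detect bolus additions in a concentration timecourse
#'
#' Flags upward jumps between consecutive samples exceeding
#' `jump_threshold`. Analytes with boluses show intrinsic step functions
#' and must not be smoothed directly; downstream fitting removes the
#' detected (or recorded) step increments and fits the continuous
#' cumulative-consumption signal instead.
#'
#' @param tc a [timecourse()].
#' @param jump_threshold minimal upward jump (same unit as the values).
#' @return data frame with columns `time_before`, `time_after`, `jump`;
#'   zero rows when no bolus is detected.
#' @export
detect_boluses <- function(tc, jump_threshold) {
  assert_that(inherits(tc, "chofba_timecourse"), "tc must be a chofba_timecourse")
  d <- diff(tc$values)
  idx <- which(d > jump_threshold)
  data.frame(time_before = tc$times[idx], time_after = tc$times[idx + 1],
             jump = d[idx])
}

#' Fit a positive profile on the log scale
#'
#' Fits the shape-constrained piecewise cubic to `log(values)` and
#' exponentiates on evaluation. Appropriate for strictly positive
#' signals spanning orders of magnitude (viable cell density): absolute
#' least squares on the raw scale would ignore the relative error of the
#' small early values and destabilize ratios such as `dC/dt / X` there.
#'
#' @inheritParams fit_shape_constrained
#' @return A `chofba_log_profile` (supports [predict()] with
#'   `deriv = 0, 1` like a `chofba_smooth_profile`).
#' @export
fit_log_profile <- function(tc, max_segments = 4, segments = NULL,
                            target_rms = NULL, errors = NULL) {
  assert_that(all(tc$values > 0), "log-scale fit requires strictly positive values")
  ltc <- timecourse(tc$times, log(tc$values), unit = paste0("log(", tc$unit, ")"))
  prof <- fit_shape_constrained(ltc, max_segments = max_segments,
                                nonneg = FALSE, segments = segments,
                                target_rms = target_rms, errors = errors)
  structure(list(logprof = prof, unit = tc$unit),
            class = "chofba_log_profile")
}

#' @export
predict.chofba_log_profile <- function(object, t, deriv = 0, ...) {
  val <- exp(predict(object$logprof, t))
  if (deriv == 0) return(val)
  assert_that(deriv == 1, "deriv must be 0 or 1")
  val * predict(object$logprof, t, deriv = 1)
}

#' @export
print.chofba_log_profile <- function(x, ...) {
  cat("log-scale ")
  print(x$logprof)
  invisible(x)
}

# Remove known bolus step increments from a concentration series so the
# remainder is a continuous consumption signal. jumps: data.frame with
# time_after and jump (concentration increment applied before that sample).
deconvolve_boluses <- function(tc, jumps) {
  v <- tc$values
  if (nrow(jumps) > 0) {
    for (i in seq_len(nrow(jumps))) {
      after <- tc$times >= jumps$time_after[i] - 1e-9
      v[after] <- v[after] - jumps$jump[i]
    }
  }
  timecourse(tc$times, v, unit = tc$unit, errors = tc$errors)
}
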