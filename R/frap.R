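## FRAP quantification: background/reference correction, pre-bleach
## normalization, exponential recovery fitting and the nuage:cytoplasm
## intensity ratio.
##
## Recovery model: y = a * (1 - exp(-b * t)) + c, fitted to the normalized
## post-bleach series with t = 0 at the first post-bleach frame.  The mobile
## fraction is a + c, the maximal extent of recovery.

#' Construct a FRAP trace
#'
#' @param times frame times in seconds, strictly increasing.
#' @param BL,BG,REF mean intensities of the bleach, background and
#'   reference zones per frame (arbitrary units).
#' @param n_prebleach number of pre-bleach frames at the start of the
#'   series (default 5).
#' @return object of class `frap_trace` (a data.frame with attribute
#'   `n_prebleach`).
#' @export
frap_trace <- function(times, BL, BG, REF, n_prebleach = 5L) {
  n <- length(times)
  if (length(BL) != n || length(BG) != n || length(REF) != n)
    stop("times, BL, BG, REF must have equal length", call. = FALSE)
  if (n >= 2 && any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (n_prebleach < 1L || n_prebleach >= n)
    stop("n_prebleach must be >= 1 and < the series length", call. = FALSE)
  out <- data.frame(time = times, BL = BL, BG = BG, REF = REF)
  attr(out, "n_prebleach") <- as.integer(n_prebleach)
  class(out) <- c("frap_trace", "data.frame")
  out
}

#' Read a FRAP trace from CSV
#'
#' Expects a header with columns `time,BL,BG,REF`.  When the `time` column
#' is absent, frames are assumed at the acquisition layout used throughout:
#' one frame every 0.6144 s.
#'
#' @param path CSV file.
#' @param n_prebleach number of pre-bleach frames (default 5).
#' @return a `frap_trace`.
#' @export
read_frap_trace <- function(path, n_prebleach = 5L) {
  d <- utils::read.csv(path)
  if (!all(c("BL", "BG", "REF") %in% names(d)))
    stop("FRAP CSV must have columns BL, BG, REF (and optionally time)",
         call. = FALSE)
  if (is.null(d$time)) d$time <- (seq_len(nrow(d)) - 1) * 0.6144
  frap_trace(d$time, d$BL, d$BG, d$REF, n_prebleach = n_prebleach)
}

#' Background/reference correction of a FRAP trace
#'
#' `BLcorr = (BL - BG) / (REF - BG)` per frame; invariant under
#' multiplicative rescaling of all three channels.
#'
#' @param trace a `frap_trace`.
#' @return numeric vector of corrected intensities.
#' @export
correct_trace <- function(trace) {
  denom <- trace$REF - trace$BG
  if (any(denom <= 0)) {
    frame <- which(denom <= 0)[1]
    stop(sprintf("REF - BG is not positive at frame %d", frame),
         call. = FALSE)
  }
  (trace$BL - trace$BG) / denom
}

#' Normalize a corrected series to the pre-bleach mean
#'
#' Post-bleach values are divided by the mean of the first `n_prebleach`
#' corrected values (the 100% intensity estimate); times are re-zeroed at
#' the first post-bleach frame.
#'
#' @param corrected corrected intensity series (from [correct_trace()]).
#' @param times frame times (same length).
#' @param n_prebleach number of pre-bleach frames (default 5).
#' @return list with `times` (post-bleach, starting at 0) and `values`
#'   (normalized post-bleach intensities).
#' @export
normalize_prebleach <- function(corrected, times, n_prebleach = 5L) {
  n <- length(corrected)
  if (n_prebleach >= n)
    stop("n_prebleach must be smaller than the series length", call. = FALSE)
  pre <- mean(corrected[seq_len(n_prebleach)])
  if (pre <= 0) stop("pre-bleach mean is not positive", call. = FALSE)
  post <- (n_prebleach + 1L):n
  list(times = times[post] - times[post[1]],
       values = corrected[post] / pre)
}

#' Fit the exponential recovery model to a normalized FRAP series
#'
#' Bounded least squares (Levenberg-Marquardt) fit of
#' `y = a * (1 - exp(-b * t)) + c` with `a, c` in `[0, 2]` and `b > 0`.
#' Initialization: `c0` = first post-bleach value, `a0` = last value - `c0`
#' (floored at 0.01), `b0 = log(2) / t_half` where `t_half` is the time at
#' which half of the (last - first) recovery is reached, floored at the
#' first frame interval.
#'
#' @param times post-bleach times (>= 5 points, starting at 0).
#' @param values normalized post-bleach intensities.
#' @return object of class `frap_fit`: coefficients `a`, `b`, `c`, the
#'   `mobile_fraction` (= a + c), `residual_sse`, and the data for the
#'   method functions (`print`, `coef`, `summary`, `predict`, `residuals`,
#'   `plot`).
#' @export
fit_recovery <- function(times, values) {
  if (length(times) < 5L)
    stop("need at least 5 post-bleach points", call. = FALSE)
  if (length(times) != length(values))
    stop("times and values must have equal length", call. = FALSE)
  c0 <- values[1]
  a0 <- max(values[length(values)] - c0, 0.01)
  half_level <- c0 + (values[length(values)] - c0) / 2
  t_half <- times[which(values >= half_level)[1]]
  dt1 <- if (length(times) >= 2) times[2] - times[1] else 1
  if (is.na(t_half) || t_half < dt1) t_half <- dt1
  b0 <- log(2) / t_half
  start <- c(a = min(max(a0, 0), 2), b = b0, c = min(max(c0, 0), 2))
  model <- function(p, t) p[1] * (1 - exp(-p[2] * t)) + p[3]
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(p) values - model(p, times),
    lower = c(0, 1e-9, 0), upper = c(2, Inf, 2),
    control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-12,
                                         maxiter = 500))
  if (fit$info %in% c(0, 5, 9))
    stop(sprintf("recovery fit did not converge (nls.lm info %d: %s)",
                 fit$info, fit$message), call. = FALSE)
  p <- fit$par
  structure(list(a = unname(p["a"]), b = unname(p["b"]),
                 c = unname(p["c"]),
                 mobile_fraction = unname(p["a"] + p["c"]),
                 residual_sse = sum(fit$fvec^2),
                 times = times, values = values,
                 convergence = fit$message),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat("FRAP exponential recovery fit: y = a(1 - exp(-b t)) + c\n")
  cat(sprintf("  a = %.4f, b = %.4f /s, c = %.4f\n", x$a, x$b, x$c))
  cat(sprintf("  mobile fraction (a + c) = %.4f\n", x$mobile_fraction))
  cat(sprintf("  half-time ln2/b = %.2f s, residual SSE = %.3g (n = %d)\n",
              log(2) / x$b, x$residual_sse, length(x$times)))
  invisible(x)
}

#' @method coef frap_fit
#' @export
coef.frap_fit <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c)
}

#' @method summary frap_fit
#' @export
summary.frap_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @method predict frap_fit
#' @export
predict.frap_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$times else
    if (is.list(newdata)) newdata$times else newdata
  object$a * (1 - exp(-object$b * t)) + object$c
}

#' @method residuals frap_fit
#' @export
residuals.frap_fit <- function(object, ...) {
  object$values - predict(object)
}

#' @method plot frap_fit
#' @export
plot.frap_fit <- function(x, ...) {
  graphics::plot(x$times, x$values, pch = 16, cex = 0.5,
                 xlab = "time after bleach (s)",
                 ylab = "normalized intensity", ...)
  tt <- seq(min(x$times), max(x$times), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = "red3", lwd = 2)
  graphics::abline(h = x$mobile_fraction, lty = 2, col = "grey40")
  invisible(x)
}

#' Fit a FRAP trace end to end
#'
#' Convenience wrapper: correction, pre-bleach normalization, recovery fit.
#'
#' @param trace a `frap_trace`.
#' @return a `frap_fit`.
#' @export
fit_frap_trace <- function(trace) {
  corr <- correct_trace(trace)
  norm <- normalize_prebleach(corr, trace$time,
                              attr(trace, "n_prebleach"))
  fit_recovery(norm$times, norm$values)
}

#' Simulate a raw FRAP trace from known recovery parameters
#'
#' Generates BL/BG/REF channels whose corrected, normalized post-bleach
#' series follows `a(1 - exp(-b t)) + c` plus Gaussian noise, at the
#' acquisition layout used throughout (default 5 pre-bleach + 115
#' post-bleach frames every 0.6144 s).
#'
#' @param a,b,c generating parameters.
#' @param sigma Gaussian noise sd on the normalized scale (default 0).
#' @param n_prebleach,n_postbleach frame counts.
#' @param dt frame interval in seconds.
#' @param seed optional integer seed.
#' @return a `frap_trace`.
#' @export
simulate_frap_trace <- function(a, b, c, sigma = 0, n_prebleach = 5L,
                                n_postbleach = 115L, dt = 0.6144,
                                seed = NULL) {
  build <- function() {
    n <- n_prebleach + n_postbleach
    times <- (seq_len(n) - 1) * dt
    t_post <- times[(n_prebleach + 1):n] - times[n_prebleach + 1]
    y <- c(rep(1, n_prebleach), a * (1 - exp(-b * t_post)) + c)
    if (sigma > 0) y <- y + stats::rnorm(n, 0, sigma)
    BG <- rep(50, n); REF <- rep(150, n)
    plateau <- 0.8                       # corrected pre-bleach level
    BL <- BG + plateau * y * (REF - BG)
    frap_trace(times, BL, BG, REF, n_prebleach = n_prebleach)
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Nuage:cytoplasm intensity ratio
#'
#' `N:C = (N - G) / (C - G)` from the mean intensities of a perinuclear
#' nuage area (N), an adjacent equal-area cytoplasmic area (C) and a
#' background area (G).
#'
#' @param N,C,G mean intensities.
#' @return the ratio.
#' @export
#' @examples
#' nc_ratio(80, 50, 20)  # 2
nc_ratio <- function(N, C, G) {
  if (any(C - G <= 0))
    stop("C - G must be positive", call. = FALSE)
  (N - G) / (C - G)
}
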