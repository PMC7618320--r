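## Fluorescence trace conditioning and in vivo / in vitro coordinate
## registration.

#' Running-percentile detrend
#'
#' Removes slow drift (bleaching, z-drift) by subtracting the running 40th
#' percentile of the trace computed in a sliding window, less its median over
#' the entire trace, so the overall signal level is preserved. Windows are
#' truncated at the trace boundaries (no padding).
#'
#' @param x Numeric fluorescence trace.
#' @param window Window length in frames (default 500). If longer than the
#'   trace, falls back to the global percentile with a message.
#' @param percentile Percentile in (0, 100), default 40.
#' @return Detrended trace, same length as `x`.
#' @export
detrend <- function(x, window = 500, percentile = 40) {
  stopifnot(window >= 1, is.numeric(x), all(is.finite(x)))
  n <- length(x)
  prob <- percentile / 100
  if (window > n) {
    message("detrend: window exceeds trace length; using global percentile")
    rp <- rep(stats::quantile(x, prob, names = FALSE), n)
  } else {
    half <- window %/% 2
    rp <- vapply(seq_len(n), function(i) {
      lo <- max(1, i - half)
      hi <- min(n, lo + window - 1)
      lo <- max(1, hi - window + 1)
      stats::quantile(x[lo:hi], prob, names = FALSE)
    }, numeric(1))
  }
  x - (rp - stats::median(rp))
}

#' Baseline fluorescence from a two-Gaussian mixture
#'
#' Fits a mixture of two Gaussians to the distribution of fluorescence values
#' by EM (k-means initialization, multiple restarts, best log-likelihood kept)
#' and returns the mean of the baseline component.
#'
#' @param x Fluorescence values (>= 100 samples; a constant trace is returned
#'   as-is).
#' @param component `"smaller_mean"` (default: the baseline component is the
#'   one with the smaller mean) or `"smaller_weight"`.
#' @param n_restarts EM restarts (default 10).
#' @param seed Seed for the restarts.
#' @return Scalar baseline estimate F0.
#' @export
estimate_f0 <- function(x, component = c("smaller_mean", "smaller_weight"),
                        n_restarts = 10, seed = 1L) {
  component <- match.arg(component)
  x <- x[is.finite(x)]
  if (stats::sd(x) == 0) return(x[1])
  stopifnot(length(x) >= 100)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    km <- tryCatch(stats::kmeans(x, 2, nstart = 1), error = function(e) NULL)
    if (is.null(km)) next
    mu <- as.vector(km$centers)
    sdv <- pmax(vapply(1:2, function(k) stats::sd(x[km$cluster == k]),
                       numeric(1)), 1e-6)
    sdv[is.na(sdv)] <- stats::sd(x)
    w <- km$size / length(x)
    ll_old <- -Inf
    for (it in 1:200) {
      d1 <- w[1] * stats::dnorm(x, mu[1], sdv[1])
      d2 <- w[2] * stats::dnorm(x, mu[2], sdv[2])
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      ll <- sum(log(tot))
      g <- d1 / tot
      w <- c(mean(g), 1 - mean(g))
      mu <- c(sum(g * x) / sum(g), sum((1 - g) * x) / sum(1 - g))
      sdv <- pmax(c(sqrt(sum(g * (x - mu[1])^2) / sum(g)),
                    sqrt(sum((1 - g) * (x - mu[2])^2) / sum(1 - g))), 1e-6)
      if (abs(ll - ll_old) < 1e-9) break
      ll_old <- ll
    }
    if (is.null(best) || ll > best$ll)
      best <- list(ll = ll, mu = mu, w = w)
  }
  if (is.null(best)) stop("mixture fit failed")
  if (component == "smaller_mean") best$mu[which.min(best$mu)]
  else best$mu[which.min(best$w)]
}

#' dF/F normalization
#'
#' @param x Fluorescence trace.
#' @param f0 Baseline (> 0), e.g. from [estimate_f0()].
#' @return `(x - f0) / f0`.
#' @export
dff <- function(x, f0) {
  if (f0 <= 0) stop("f0 must be positive")
  (x - f0) / f0
}

#' Least-squares 3-D affine registration from control points
#'
#' Estimates the affine map `dst = A %*% src + b` minimizing the summed
#' squared residuals over >= 4 non-coplanar control-point pairs, as used to
#' register in vivo imaging volumes to in vitro slice volumes.
#'
#' @param src,dst Numeric matrices, one row per control point, 3 columns.
#' @return An `affine_transform`: list with 3x3 `A`, length-3 `b`, and
#'   `rms` residual.
#' @export
fit_affine <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(ncol(src) == 3, ncol(dst) == 3, nrow(src) == nrow(dst))
  if (nrow(src) < 4)
    stop("need at least 4 control points, got ", nrow(src))
  X <- cbind(src, 1)
  if (qr(X)$rank < 4)
    stop("control points are coplanar/degenerate; affine not identifiable")
  coef <- qr.solve(X, dst)                 # 4 x 3
  A <- t(coef[1:3, , drop = FALSE])
  b <- as.vector(coef[4, ])
  res <- apply_affine(list(A = A, b = b), src) - dst
  out <- list(A = A, b = b, rms = sqrt(mean(rowSums(res^2))))
  class(out) <- "affine_transform"
  out
}

#' @rdname fit_affine
#' @param transform An `affine_transform`.
#' @param points Matrix of points (rows) to map.
#' @export
apply_affine <- function(transform, points) {
  points <- matrix(points, ncol = 3)
  t(transform$A %*% t(points)) + rep(transform$b, each = nrow(points))
}

#' @rdname fit_affine
#' @export
invert_affine <- function(transform) {
  Ai <- solve(transform$A)
  out <- list(A = Ai, b = as.vector(-Ai %*% transform$b), rms = NA_real_)
  class(out) <- "affine_transform"
  out
}
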