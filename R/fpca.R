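# Functional PCA of fingerprint rows: spline smoothing on the bin-center
# grid, quadrature-weighted covariance eigendecomposition, per-sample
# scores and variance proportions.

#' Smooth one fingerprint row with a cubic smoothing spline
#'
#' Fits the penalized least-squares spline minimizing
#' `sum((y - f(t))^2) + lambda * integral(f''(t)^2)`, on the bin-center
#' grid. `lambda = "gcv"` selects the penalty by generalized
#' cross-validation; `lambda = 0` performs no smoothing and returns the
#' data unchanged (the interpolation limit).
#'
#' @param values numeric vector (a fingerprint row), length >= 4.
#' @param grid evaluation grid (default the bin centers).
#' @param lambda non-negative penalty, or `"gcv"`.
#' @return object of class `smooth_curve`: list with `grid`, `fitted`,
#'   `lambda`, `edf` (effective degrees of freedom).
#' @export
smooth_profile <- function(values, grid = bin_centers(length(values)),
                           lambda = "gcv") {
  if (length(values) < 4) stop("need at least 4 points to smooth")
  if (identical(lambda, 0) || identical(lambda, 0L)) {
    return(structure(list(grid = grid, fitted = as.numeric(values),
                          lambda = 0, edf = length(values)),
                     class = "smooth_curve"))
  }
  if (identical(lambda, "gcv")) {
    fit <- stats::smooth.spline(grid, values, cv = FALSE, all.knots = TRUE,
                                keep.data = FALSE)
  } else {
    if (!is.numeric(lambda) || lambda < 0) {
      stop("lambda must be a non-negative number or \"gcv\"")
    }
    fit <- stats::smooth.spline(grid, values, lambda = lambda,
                                all.knots = TRUE, keep.data = FALSE)
  }
  structure(list(grid = grid,
                 fitted = stats::predict(fit, grid)$y,
                 lambda = fit$lambda,
                 edf = fit$df),
            class = "smooth_curve")
}

quadrature_weights <- function(grid, scheme = c("trapezoid", "uniform")) {
  scheme <- match.arg(scheme)
  h <- mean(diff(grid))
  w <- rep(h, length(grid))
  if (scheme == "trapezoid") w[c(1, length(grid))] <- h / 2
  w
}

#' Functional PCA of a fingerprint matrix
#'
#' Each row is smoothed (a single penalty shared across rows keeps the
#' basis common: with `lambda = "gcv"` the shared value is the median of
#' the per-row GCV selections), centered by the pointwise mean curve, and
#' the quadrature-weighted sample covariance is eigendecomposed. Harmonics
#' (eigenfunctions) have unit quadrature norm and are sign-flipped so their
#' largest-magnitude value is positive; scores are the weighted inner
#' products of the centered curves with the harmonics.
#'
#' @param matrix a [fingerprint_matrix()] (or plain numeric matrix).
#' @param k number of harmonics to retain; `NULL` retains the smallest
#'   number reaching `varprop_threshold` cumulative variance.
#' @param varprop_threshold cumulative variance proportion target
#'   (default 0.9).
#' @param lambda smoothing penalty shared by all rows, or `"gcv"`, or 0
#'   for no smoothing.
#' @param quadrature `"trapezoid"` (default) or `"uniform"` weights.
#' @return object of class `fpca_model`: `grid`, `mean_curve`, `harmonics`
#'   (bins x k), `eigenvalues` (all computable components), `scores`
#'   (samples x k), `varprop` (all components), `k`, `lambda`, `weights`.
#' @export
fit_fpca <- function(matrix, k = NULL, varprop_threshold = 0.9,
                     lambda = "gcv", quadrature = "trapezoid") {
  X <- unclass(matrix)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("need at least 2 samples")
  grid <- bin_centers(p)
  if (identical(lambda, "gcv")) {
    lams <- apply(X, 1, function(r) smooth_profile(r, grid, "gcv")$lambda)
    lambda <- stats::median(lams)
  }
  if (!identical(lambda, 0)) {
    X <- t(apply(X, 1, function(r) smooth_profile(r, grid, lambda)$fitted))
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  w <- quadrature_weights(grid, quadrature)
  sw <- sqrt(w)
  C <- crossprod(Xc) / (n - 1)
  M <- C * tcrossprod(sw)            # D_w^{1/2} C D_w^{1/2}
  eig <- eigen(M, symmetric = TRUE)
  n_comp <- min(n - 1, p)
  ev <- pmax(eig$values[seq_len(n_comp)], 0)
  varprop <- if (sum(ev) > 0) ev / sum(ev) else rep(0, n_comp)
  if (is.null(k)) {
    k <- which(cumsum(varprop) >= varprop_threshold - 1e-12)[1]
    if (is.na(k)) k <- n_comp
  }
  if (k > n_comp) {
    stop("k = ", k, " exceeds the ", n_comp, " computable components")
  }
  harmonics <- sweep(eig$vectors[, seq_len(k), drop = FALSE], 1, sw, "/")
  scores <- Xc %*% (harmonics * w)
  # sign convention: largest-magnitude harmonic value is positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(harmonics[, j]))
    if (harmonics[i_max, j] < 0) {
      harmonics[, j] <- -harmonics[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(rownames(X), paste0("harmonic_", seq_len(k)))
  structure(list(grid = grid, mean_curve = mu, harmonics = harmonics,
                 eigenvalues = ev, scores = scores, varprop = varprop,
                 k = k, lambda = lambda, weights = w),
            class = "fpca_model")
}

#' @export
print.fpca_model <- function(x, ...) {
  cat(sprintf(
    "<fpca_model: %d samples, %d harmonics (%.1f%% of variance), lambda = %.3g>\n",
    nrow(x$scores), x$k, 100 * sum(x$varprop[seq_len(x$k)]), x$lambda))
  invisible(x)
}

#' Reconstruct curves from a truncated FPCA expansion
#'
#' @param model an `fpca_model`.
#' @param k number of harmonics to use (default all retained).
#' @return samples x bins matrix `mean + scores[, 1:k] %*% t(harmonics[, 1:k])`.
#' @export
fpca_reconstruct <- function(model, k = model$k) {
  if (k < 1 || k > model$k) stop("k out of range")
  sweep(model$scores[, seq_len(k), drop = FALSE] %*%
          t(model$harmonics[, seq_len(k), drop = FALSE]),
        2, model$mean_curve, "+")
}

#' Euclidean distances on FPCA scores
#'
#' @param model an `fpca_model`.
#' @param k_used number of leading score columns to use (default all
#'   retained harmonics).
#' @return a [distance_matrix()].
#' @export
scores_distance <- function(model, k_used = model$k) {
  if (k_used <= 0) stop("k_used must be positive")
  if (k_used > ncol(model$scores)) stop("k_used exceeds retained harmonics")
  D <- as.matrix(stats::dist(model$scores[, seq_len(k_used), drop = FALSE]))
  distance_matrix(D, rownames(model$scores))
}
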