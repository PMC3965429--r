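# Lane processing: background subtraction, peak detection, alignment
# through monotone warps, binning into 101-bin relative-intensity
# fingerprints, and bin masking for sensitivity analyses.

#' Lane intensity profile
#'
#' @param positions strictly increasing pixel positions (Rf scale).
#' @param intensities non-negative intensities, same length.
#' @param lane_id lane identifier.
#' @return object of class `lane_profile`.
#' @export
lane_profile <- function(positions, intensities, lane_id = "lane") {
  if (length(positions) != length(intensities) || length(positions) < 2) {
    stop("positions and intensities must have equal length >= 2")
  }
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  structure(list(positions = as.numeric(positions),
                 intensities = as.numeric(intensities),
                 lane_id = lane_id),
            class = "lane_profile")
}

#' @export
print.lane_profile <- function(x, ...) {
  cat(sprintf("<lane_profile '%s': %d pixels on [%.3g, %.3g]>\n",
              x$lane_id, length(x$positions), min(x$positions),
              max(x$positions)))
  invisible(x)
}

#' Monotone piecewise-linear warp map
#'
#' Maps source coordinates onto reference coordinates through anchor pairs,
#' with linear extrapolation outside the anchor span. Both anchor sequences
#' must be strictly increasing (monotone warp).
#'
#' @param source,reference equal-length strictly increasing anchor vectors
#'   (at least 2 anchors).
#' @return object of class `warp_map`.
#' @export
warp_map <- function(source, reference) {
  if (length(source) != length(reference) || length(source) < 2) {
    stop("warp needs at least 2 anchor pairs of equal length")
  }
  if (any(diff(source) <= 0) || any(diff(reference) <= 0)) {
    stop("warp anchors must be strictly increasing (monotone warp)")
  }
  structure(list(source = as.numeric(source),
                 reference = as.numeric(reference)),
            class = "warp_map")
}

# piecewise-linear interpolation with linear extrapolation at both ends
pl_interp <- function(x, y, xout) {
  n <- length(x)
  out <- stats::approx(x, y, xout = xout, rule = 2)$y
  lo <- xout < x[1]
  hi <- xout > x[n]
  if (any(lo)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    out[lo] <- y[1] + s * (xout[lo] - x[1])
  }
  if (any(hi)) {
    s <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    out[hi] <- y[n] + s * (xout[hi] - x[n])
  }
  out
}

#' Apply a warp map
#' @param warp a [warp_map()].
#' @param t source coordinates.
#' @return warped coordinates.
#' @export
warp_apply <- function(warp, t) pl_interp(warp$source, warp$reference, t)

#' Invert a warp map
#' @param warp a [warp_map()].
#' @param r reference coordinates.
#' @return source coordinates mapping onto `r`.
#' @export
warp_invert <- function(warp, r) pl_interp(warp$reference, warp$source, r)

# moving minimum / mean over +- half-window (in index units); O(n w) --
# lanes are ~1e3 pixels so this is plenty fast.
roll_stat <- function(y, half, fun) {
  n <- length(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- fun(y[max(1, i - half):min(n, i + half)])
  }
  out
}

#' Subtract background from a lane profile
#'
#' Estimates the baseline by a moving minimum over `window` followed by a
#' moving average of the same width (a morphological-opening analogue), and
#' subtracts it; residual negative values are clamped to zero.
#'
#' @param profile a [lane_profile()].
#' @param window baseline window width in Rf units; must exceed the pixel
#'   spacing.
#' @return background-subtracted [lane_profile()].
#' @export
subtract_background <- function(profile, window = 0.05) {
  if (window <= 0) stop("window must be positive")
  spacing <- mean(diff(profile$positions))
  if (window <= spacing) stop("window must exceed the pixel spacing")
  half <- max(1L, floor(window / spacing / 2))
  baseline <- roll_stat(profile$intensities, half, min)
  baseline <- roll_stat(baseline, half, mean)
  out <- pmax(profile$intensities - baseline, 0)
  lane_profile(profile$positions, out, profile$lane_id)
}

#' Detect peaks by topographic prominence
#'
#' Local maxima whose prominence (height above the higher of the two
#' saddles separating them from higher terrain) is at least
#' `min_prominence` times the profile maximum. A flat profile yields an
#' empty result.
#'
#' @param profile a [lane_profile()].
#' @param min_prominence prominence threshold as a fraction of the maximum
#'   intensity, in (0, 1).
#' @return data frame with columns `position`, `height`, sorted by
#'   position.
#' @export
detect_peaks <- function(profile, min_prominence = 0.05) {
  if (min_prominence <= 0 || min_prominence >= 1) {
    stop("min_prominence must lie in (0, 1)")
  }
  y <- profile$intensities
  n <- length(y)
  ymax <- max(y)
  if (ymax == min(y)) {
    return(data.frame(position = numeric(0), height = numeric(0)))
  }
  # strict local maxima; plateau maxima take the leftmost point
  is_peak <- logical(n)
  for (i in seq_len(n)) {
    left_ok <- i == 1 || y[i] > y[i - 1]
    j <- i
    while (j < n && y[j + 1] == y[i]) j <- j + 1
    right_ok <- j == n || y[j + 1] < y[i]
    is_peak[i] <- left_ok && right_ok && !(i == 1 && j == n)
  }
  idx <- which(is_peak)
  keep <- logical(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    h <- y[i]
    # walk left/right to the nearest strictly higher point, tracking the
    # minimum along the way; a side with no higher ground contributes its
    # full minimum
    left_min <- h
    j <- i
    while (j > 1 && y[j - 1] <= h) {
      j <- j - 1
      left_min <- min(left_min, y[j])
    }
    if (j == 1) left_min <- min(y[1:i])
    right_min <- h
    j <- i
    while (j < n && y[j + 1] <= h) {
      j <- j + 1
      right_min <- min(right_min, y[j])
    }
    if (j == n) right_min <- min(y[i:n])
    prom <- h - max(left_min, right_min)
    # the global maximum has no higher ground; its prominence is its height
    # above the global minimum
    if (h == ymax) prom <- h - min(y)
    keep[k] <- prom >= min_prominence * ymax
  }
  idx <- idx[keep]
  data.frame(position = profile$positions[idx], height = y[idx])
}

#' Align a lane profile onto a reference coordinate system
#'
#' Remaps the profile's positions through the monotone piecewise-linear
#' warp defined by matched anchor pairs (source anchor in the lane's own
#' coordinates, reference anchor on the common Rf scale; linear
#' extrapolation outside the anchor span), then resamples the intensities
#' back onto the original pixel grid by linear interpolation.
#'
#' @param profile a [lane_profile()].
#' @param source_anchors,reference_anchors equal-length strictly increasing
#'   vectors with at least 2 anchors.
#' @return aligned [lane_profile()] on the same pixel grid.
#' @export
align_profile <- function(profile, source_anchors, reference_anchors) {
  w <- warp_map(source_anchors, reference_anchors)
  mapped <- warp_apply(w, profile$positions)
  res <- stats::approx(mapped, profile$intensities,
                       xout = profile$positions, rule = 2)$y
  lane_profile(profile$positions, pmax(res, 0), profile$lane_id)
}

#' Integrate a lane profile into a fingerprint row
#'
#' Crops the profile to `crop`, splits the crop into `n_bins` equal-width
#' sub-intervals, trapezoid-integrates the (linearly interpolated)
#' intensity over each, and divides by the total so the row sums to one.
#'
#' @param profile a [lane_profile()].
#' @param n_bins number of bins (default 101; bin 1 is the top of the gel,
#'   i.e. the low-Rf end).
#' @param crop length-2 vector, the Rf interval to keep.
#' @return numeric vector of length `n_bins` summing to 1.
#' @export
bin_and_normalize <- function(profile, n_bins = 101, crop = c(0, 1)) {
  lo <- crop[1]; hi <- crop[2]
  if (!(lo < hi)) stop("crop must satisfy lo < hi")
  if (n_bins < 2) stop("n_bins must be at least 2")
  if (lo < min(profile$positions) - 1e-12 ||
      hi > max(profile$positions) + 1e-12) {
    stop("crop must lie within the profile's position span")
  }
  edges <- seq(lo, hi, length.out = n_bins + 1)
  inside <- profile$positions > lo & profile$positions < hi
  x <- sort(unique(c(edges, profile$positions[inside])))
  y <- stats::approx(profile$positions, profile$intensities, xout = x,
                     rule = 2)$y
  seg <- diff(x) * (y[-1] + y[-length(y)]) / 2
  mid <- (x[-1] + x[-length(x)]) / 2
  bin <- findInterval(mid, edges, all.inside = TRUE)
  out <- as.numeric(tapply(seg, factor(bin, levels = seq_len(n_bins)), sum))
  out[is.na(out)] <- 0
  total <- sum(out)
  if (total <= 0) stop("empty lane: no intensity inside the crop")
  out / total
}

#' Fingerprint matrix (samples x bins of relative intensities)
#'
#' @param values numeric matrix, one row per sample; rows must be
#'   non-negative. Rows of an unmasked matrix must sum to 1 within 1e-9.
#' @param sample_ids row identifiers (default rownames).
#' @param mask integer vector of masked bin indices (empty when unmasked);
#'   masked rows may sum to less than 1.
#' @return object of class `fingerprint_matrix` (a matrix with `sample_ids`
#'   rownames, `bin_###` colnames, and a `mask` attribute).
#' @export
fingerprint_matrix <- function(values, sample_ids = rownames(values),
                               mask = integer(0)) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(values)))
  if (any(values < 0)) stop("fingerprint values must be non-negative")
  rs <- rowSums(values)
  if (length(mask) == 0 && any(abs(rs - 1) > 1e-9)) {
    stop("unmasked fingerprint rows must sum to 1 (worst deviation ",
         format(max(abs(rs - 1))), ")")
  }
  if (length(mask) > 0 && any(rs > 1 + 1e-9)) {
    stop("masked fingerprint rows must sum to at most 1")
  }
  dimnames(values) <- list(sample_ids,
                           sprintf("bin_%03d", seq_len(ncol(values))))
  structure(values, mask = as.integer(mask), class = "fingerprint_matrix")
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  m <- attr(x, "mask")
  cat(sprintf("<fingerprint_matrix: %d samples x %d bins%s>\n",
              nrow(x), ncol(x),
              if (length(m)) paste0(", masked bins ", min(m), "-", max(m))
              else ""))
  invisible(x)
}

#' Assemble a fingerprint matrix from lane profiles
#'
#' Applies [bin_and_normalize()] to each profile.
#'
#' @param profiles list of [lane_profile()] objects.
#' @param n_bins,crop passed to [bin_and_normalize()].
#' @return a [fingerprint_matrix()].
#' @export
fingerprints_from_profiles <- function(profiles, n_bins = 101,
                                       crop = c(0, 1)) {
  rows <- t(vapply(profiles, bin_and_normalize, numeric(n_bins),
                   n_bins = n_bins, crop = crop))
  ids <- vapply(profiles, function(p) p$lane_id, character(1))
  fingerprint_matrix(rows, ids)
}

#' Mask a bin range in a fingerprint matrix
#'
#' Sets the listed bins to exactly zero in every row, without
#' renormalizing, and records the mask. Used for sensitivity re-analyses
#' that exclude a dominant band (default: bins 71-74).
#'
#' @param matrix a [fingerprint_matrix()].
#' @param bin_range inclusive `c(lo, hi)` bin range, 1-based.
#' @return masked [fingerprint_matrix()].
#' @export
mask_bins <- function(matrix, bin_range = c(71, 74)) {
  lo <- bin_range[1]; hi <- bin_range[2]
  if (lo < 1 || hi > ncol(matrix) || lo > hi) {
    stop("bin_range must satisfy 1 <= lo <= hi <= n_bins")
  }
  values <- unclass(matrix)
  attr(values, "mask") <- NULL
  values[, lo:hi] <- 0
  if (any(rowSums(values) <= 0)) {
    stop("degenerate lane: masking removed all remaining intensity")
  }
  fingerprint_matrix(values, rownames(matrix),
                     mask = sort(unique(c(attr(matrix, "mask"), lo:hi))))
}

#' Bin centers on the Rf scale
#' @param n_bins number of bins.
#' @param crop Rf interval covered.
#' @return numeric vector of bin-center coordinates.
#' @export
bin_centers <- function(n_bins = 101, crop = c(0, 1)) {
  h <- (crop[2] - crop[1]) / n_bins
  crop[1] + h * (seq_len(n_bins) - 0.5)
}
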