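# Synthetic gel generator: known communities, planted treatment effects,
# lane warping and a dominant settled-plankton band, so that every
# downstream stage can be tested against ground truth.

#' Default synthetic community
#'
#' Draws a community of taxa with unique band positions (standardized
#' migration distance, Rf, in (0,1)) and a common band width. Positions are
#' uniform on (0.05, 0.95); baseline log-abundances are zero so that, absent
#' effects and noise, all taxa are equally abundant.
#'
#' @param n_taxa number of taxa (default 30).
#' @param width band standard deviation in Rf units (default 0.004).
#' @param seed RNG seed for the positions.
#' @return data frame with columns `taxon_id`, `position`, `width`, `base`,
#'   `tag` (tag is `NA` until planted).
#' @export
default_community <- function(n_taxa = 30, width = 0.004, seed = 1) {
  set.seed(seed)
  pos <- sort(stats::runif(n_taxa, 0.05, 0.95))
  data.frame(
    taxon_id = sprintf("taxon_%02d", seq_len(n_taxa)),
    position = pos,
    width = width,
    base = 0,
    tag = NA_character_,
    stringsAsFactors = FALSE
  )
}

validate_taxa <- function(taxa) {
  stopifnot(all(c("taxon_id", "position", "width") %in% names(taxa)))
  if (anyDuplicated(taxa$position)) stop("taxon band positions must be unique")
  if (any(taxa$width <= 0)) stop("band widths must be positive")
  if (anyDuplicated(taxa$taxon_id)) stop("taxon ids must be unique")
  invisible(taxa)
}

#' Simulate relative abundances with planted factorial effects
#'
#' Log abundance of taxon j in sample i is
#' `base_j + sum of effects matching sample i + noise`, with independent
#' Gaussian noise of standard deviation `sigma`; rows are then closed to
#' sum to one (compositional).
#'
#' @param metadata sample inventory (one row per sample; see
#'   [build_sample_inventory()]).
#' @param taxa taxon table (see [default_community()]).
#' @param effects `NULL`, or data frame with columns `factor`, `level`,
#'   `taxon_id`, `delta` (log-scale additive effect applied to samples whose
#'   metadata `factor` equals `level`).
#' @param sigma log-scale noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @return An object of class `synthetic_truth`: list with the `taxa`
#'   table, `abundance` (samples x taxa matrix, rows summing to 1),
#'   `effects`, `sigma`, and `seed`.
#' @export
simulate_abundances <- function(metadata, taxa, effects = NULL, sigma = 0,
                                seed = 1) {
  validate_taxa(taxa)
  if (sigma < 0) stop("sigma must be >= 0")
  n <- nrow(metadata)
  p <- nrow(taxa)
  log_a <- matrix(rep(taxa$base %||% 0, each = n), nrow = n)
  if (!is.null(effects) && nrow(effects) > 0) {
    for (i in seq_len(nrow(effects))) {
      fac <- effects$factor[i]
      if (!fac %in% names(metadata)) {
        stop("effect refers to unknown factor '", fac, "'")
      }
      if (!effects$level[i] %in% metadata[[fac]]) {
        stop("effect refers to unknown level '", effects$level[i],
             "' of factor '", fac, "'")
      }
      j <- match(effects$taxon_id[i], taxa$taxon_id)
      if (is.na(j)) {
        stop("effect refers to unknown taxon '", effects$taxon_id[i], "'")
      }
      sel <- metadata[[fac]] == effects$level[i]
      log_a[sel, j] <- log_a[sel, j] + effects$delta[i]
    }
  }
  set.seed(seed)
  if (sigma > 0) log_a <- log_a + matrix(stats::rnorm(n * p, 0, sigma), n, p)
  a <- exp(log_a)
  a <- a / rowSums(a)
  dimnames(a) <- list(metadata$sample_id, taxa$taxon_id)
  structure(
    list(taxa = taxa, abundance = a, effects = effects, sigma = sigma,
         seed = seed),
    class = "synthetic_truth"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spike a dominant band into selected samples
#'
#' Re-closes the selected abundance rows so that the spiked taxon carries
#' exactly `target_mass` of the composition, other taxa rescaled
#' proportionally. Emulates a dominant band of settled plankton DNA
#' confined to a subset of stations and fractions. Non-selected rows are
#' untouched.
#'
#' @param truth a `synthetic_truth` object.
#' @param taxon_id taxon to spike.
#' @param target_mass relative abundance to assign, in (0, 1).
#' @param samples logical vector over rows, or character vector of
#'   sample ids.
#' @return the modified `synthetic_truth`.
#' @export
spike_dominant_band <- function(truth, taxon_id, target_mass, samples) {
  if (!(target_mass > 0 && target_mass < 1)) {
    stop("target_mass must lie strictly between 0 and 1")
  }
  j <- match(taxon_id, truth$taxa$taxon_id)
  if (is.na(j)) stop("unknown taxon '", taxon_id, "'")
  if (is.character(samples)) {
    sel <- rownames(truth$abundance) %in% samples
  } else {
    sel <- samples
  }
  if (!any(sel)) return(truth)
  a <- truth$abundance
  for (i in which(sel)) {
    rest <- sum(a[i, -j])
    a[i, -j] <- a[i, -j] * (1 - target_mass) / rest
    a[i, j] <- target_mass
  }
  truth$abundance <- a
  truth
}

#' Render one gel lane from abundances
#'
#' A lane's intensity at pixel position t is
#' `baseline(t) + sum_j a_j * dnorm(warp(t); position_j, width_j) + noise`,
#' clamped at zero, so each taxon contributes a Gaussian band whose
#' integrated area is proportional to its abundance. The warp maps the
#' lane's own coordinate onto true Rf, emulating lane-to-lane migration
#' distortion.
#'
#' @param abundances named numeric vector (taxon abundances for one sample).
#' @param taxa taxon table.
#' @param baseline `NULL`, or a function of position giving smooth
#'   background intensity.
#' @param noise_sd additive Gaussian noise sd (truncated at zero intensity).
#' @param warp `NULL` (identity) or a [warp_map()].
#' @param n_pixels number of pixels on the [0,1] grid (>= 2 x taxa).
#' @param seed RNG seed for the noise (`NULL` leaves the RNG state alone).
#' @param lane_id lane identifier.
#' @return a [lane_profile()].
#' @export
render_lane <- function(abundances, taxa, baseline = NULL, noise_sd = 0,
                        warp = NULL, n_pixels = 1024, seed = NULL,
                        lane_id = "lane") {
  validate_taxa(taxa)
  if (n_pixels < 2 * nrow(taxa)) {
    stop("n_pixels must be at least twice the number of taxa")
  }
  t <- seq(0, 1, length.out = n_pixels)
  rf <- if (is.null(warp)) t else warp_apply(warp, t)
  if (any(diff(rf) <= 0)) stop("warp must be strictly monotone")
  y <- if (is.null(baseline)) numeric(n_pixels) else baseline(t)
  a <- abundances[taxa$taxon_id]
  for (j in seq_len(nrow(taxa))) {
    y <- y + a[j] * stats::dnorm(rf, taxa$position[j], taxa$width[j])
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(n_pixels, 0, noise_sd)
  }
  y <- pmax(y, 0)
  lane_profile(t, y, lane_id)
}

#' Render a marker lane
#'
#' Noise-free unit-height Gaussian bands at the given Rf positions; used as
#' the alignment reference.
#'
#' @param positions band positions in (0,1).
#' @param n_pixels pixel count.
#' @param width band sd in Rf units.
#' @return a [lane_profile()] with `lane_id = "marker"`.
#' @export
make_marker_lane <- function(positions, n_pixels = 1024, width = 0.004) {
  if (length(positions) == 0) stop("marker needs at least one band position")
  if (any(positions <= 0 | positions >= 1)) {
    stop("marker band positions must lie strictly inside (0, 1)")
  }
  t <- seq(0, 1, length.out = n_pixels)
  y <- numeric(n_pixels)
  for (p in positions) {
    y <- pmax(y, exp(-(t - p)^2 / (2 * width^2)))
  }
  lane_profile(t, y, "marker")
}

#' Expected noiseless fingerprint of a synthetic truth
#'
#' Computes each taxon's exact Gaussian band mass per bin (differences of
#' the normal CDF over the bin edges) and sums over taxa, giving the
#' fingerprint a noise-free, unwarped rendering would produce. Useful as an
#' analytic oracle and as a fast generator for statistical power and
#' type-I-error studies that do not exercise the pixel-level path.
#'
#' @param truth a `synthetic_truth` object.
#' @param n_bins number of bins (default 101).
#' @param crop Rf interval covered by the bins (default `c(0, 1)`).
#' @return a [fingerprint_matrix()] with rows summing to 1.
#' @export
truth_fingerprint <- function(truth, n_bins = 101, crop = c(0, 1)) {
  edges <- seq(crop[1], crop[2], length.out = n_bins + 1)
  p <- nrow(truth$taxa)
  # taxa x bins matrix of band masses
  mass <- matrix(0, p, n_bins)
  for (j in seq_len(p)) {
    cdf <- stats::pnorm(edges, truth$taxa$position[j], truth$taxa$width[j])
    mass[j, ] <- diff(cdf)
  }
  values <- truth$abundance %*% mass
  values <- values / rowSums(values)
  fingerprint_matrix(values, rownames(truth$abundance))
}

#' Generate a complete synthetic gel study
#'
#' Builds the full sample inventory (incubation design plus in-situ and
#' whole-cell samples), simulates compositional abundances with optional
#' planted effects, spikes a dominant band near bin 72 into the bulk DNA
#' in-situ samples of the shallow stations, draws a random monotone warp
#' per lane, and renders every lane plus a marker lane.
#'
#' @param seed master RNG seed; all stage seeds are derived from it.
#' @param taxa taxon table (default [default_community()] drawn from the
#'   master seed).
#' @param effects planted effects passed to [simulate_abundances()].
#' @param sigma log-scale abundance noise sd (default 0.3).
#' @param spike_mass relative abundance of the dominant band in the spiked
#'   lanes (default 0.35); `NULL` disables the spike.
#' @param spike_position Rf of the dominant band (default the center of bin
#'   72 of 101, 0.7079).
#' @param warp_sd sd of the random anchor jitter generating each lane's
#'   monotone warp, in Rf units (default 0.01; 0 disables warping).
#' @param noise_sd pixel noise sd (default 0.5).
#' @param n_pixels pixels per lane (default 1024).
#' @param marker_positions marker band Rf values.
#' @return list with `metadata`, `truth` (`synthetic_truth`), `profiles`
#'   (list of [lane_profile()]), `marker` (the reference marker lane),
#'   `warps` (list of [warp_map()] or `NULL`), `marker_positions`, `seed`.
#' @export
synth_gel_study <- function(seed = 1,
                            taxa = NULL,
                            effects = NULL,
                            sigma = 0.3,
                            spike_mass = 0.35,
                            spike_position = 71.5 / 101,
                            warp_sd = 0.01,
                            noise_sd = 0.5,
                            n_pixels = 1024,
                            marker_positions = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  lv <- design_levels()
  design <- build_incubation_design(lv$station, c("oxic", "anoxic"),
                                    c("control", "cnp"), 3)
  metadata <- build_sample_inventory(design)
  if (is.null(taxa)) {
    taxa <- default_community(seed = seed)
    # move the taxon nearest the spike position exactly onto it
    j <- which.min(abs(taxa$position - spike_position))
    taxa$position[j] <- spike_position
    taxa$tag[j] <- "Cyanobacteria"
  }
  truth <- simulate_abundances(metadata, taxa, effects, sigma,
                               seed = seed + 1L)
  if (!is.null(spike_mass)) {
    spike_taxon <- taxa$taxon_id[which.min(abs(taxa$position - spike_position))]
    shallow <- metadata$station %in% c("LF1", "LF1.5")
    # settled-plankton DNA: dominant in the in-situ bulk DNA lanes of the
    # shallow stations, diluted but still visible in their incubated bulk
    # DNA lanes, faint in the in-situ RNA, absent from whole cells
    sel_insitu <- metadata$fraction == "bulk_dna" &
      metadata$redox == "in_situ" & shallow
    sel_incub <- metadata$fraction == "bulk_dna" &
      metadata$redox != "in_situ" & shallow
    sel_rna <- metadata$fraction == "rna" & metadata$redox == "in_situ" &
      shallow
    truth <- spike_dominant_band(truth, spike_taxon, spike_mass, sel_insitu)
    truth <- spike_dominant_band(truth, spike_taxon, 0.3 * spike_mass,
                                 sel_incub)
    truth <- spike_dominant_band(truth, spike_taxon, 0.15 * spike_mass,
                                 sel_rna)
  }
  n <- nrow(metadata)
  profiles <- vector("list", n)
  warps <- vector("list", n)
  set.seed(seed + 2L)
  warp_anchors <- seq(0, 1, length.out = 5)
  for (i in seq_len(n)) {
    w <- NULL
    if (warp_sd > 0) {
      # jitter interior anchor images; sort() keeps the warp monotone
      img <- warp_anchors
      img[2:4] <- sort(img[2:4] + stats::rnorm(3, 0, warp_sd))
      w <- warp_map(warp_anchors, img)
    }
    warps[[i]] <- w
    profiles[[i]] <- render_lane(
      truth$abundance[i, ], taxa, baseline = NULL, noise_sd = noise_sd,
      warp = w, n_pixels = n_pixels, seed = NULL,
      lane_id = metadata$sample_id[i]
    )
  }
  marker <- make_marker_lane(marker_positions, n_pixels)
  list(metadata = metadata, truth = truth, profiles = profiles,
       marker = marker, warps = warps, marker_positions = marker_positions,
       seed = seed)
}
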