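# End-to-end orchestration: configuration, tag planting for synthetic
# studies, and the run_pipeline() driver that chains every stage and
# writes a run directory.

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with its default. When `profiles`
#' is `NULL` the run simulates a synthetic gel study with the `simulate`
#' settings; otherwise `profiles`/`metadata` (and optionally `tags`,
#' `anchors`) are read from the given TSV paths. All stochastic stages
#' derive their seeds from `seed`.
#'
#' @param seed master RNG seed.
#' @param profiles,metadata,tags,anchors input TSV paths (`NULL` to
#'   simulate; `anchors` columns: `lane_id`, `source`, `reference`).
#' @param simulate named list of synthetic-study settings passed to
#'   [synth_gel_study()] (`sigma`, `spike_mass`, `warp_sd`, `noise_sd`,
#'   `n_pixels`, `effects`).
#' @param background_window baseline-removal window in Rf units.
#' @param align whether to align profiles before binning.
#' @param n_bins,crop binning settings.
#' @param mask inclusive bin range set to zero for the masked re-analysis
#'   (`NULL` disables it).
#' @param lambda,k,varprop_threshold FPCA settings (see [fit_fpca()]).
#' @param n_perm,envfit_n_perm permutation counts for PERMANOVA and vector
#'   fitting.
#' @param terms sequential model terms for PERMANOVA.
#' @param ward_variant `"ward.D2"` or `"ward.D"`.
#' @param ordination `"ca"` or `"pcoa"`.
#' @return object of class `run_config` (a named list).
#' @export
run_config <- function(seed = 1,
                       profiles = NULL, metadata = NULL, tags = NULL,
                       anchors = NULL,
                       simulate = list(),
                       background_window = 0.05,
                       align = TRUE,
                       n_bins = 101, crop = c(0, 1),
                       mask = c(71, 74),
                       lambda = "gcv", k = NULL, varprop_threshold = 0.9,
                       n_perm = 199, envfit_n_perm = 199,
                       terms = default_term_order(),
                       ward_variant = "ward.D2",
                       ordination = "ca") {
  sim_defaults <- list(sigma = 0.3, spike_mass = 0.35, warp_sd = 0.01,
                       noise_sd = 0.5, n_pixels = 1024, effects = NULL)
  simulate <- utils::modifyList(sim_defaults, simulate)
  structure(list(seed = seed, profiles = profiles, metadata = metadata,
                 tags = tags, anchors = anchors, simulate = simulate,
                 background_window = background_window, align = align,
                 n_bins = n_bins, crop = crop, mask = mask, lambda = lambda,
                 k = k, varprop_threshold = varprop_threshold,
                 n_perm = n_perm, envfit_n_perm = envfit_n_perm,
                 terms = terms, ward_variant = ward_variant,
                 ordination = ordination),
            class = "run_config")
}

#' Serialize / restore a run configuration
#'
#' The configuration round-trips losslessly through R's text
#' representation.
#' @param config a `run_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  dput(unclass(config), file = path, control = c("all", "hexNumeric"))
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  structure(dget(path), class = "run_config")
}

config_digest <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)) %%
            .Machine$integer.max)
}

#' Plant band tags from a synthetic truth
#'
#' For every taxon with a non-`NA` tag, emits one band-tag record per
#' requested lane at the bin containing the taxon's band position,
#' emulating the excision and sequencing of bands from a few lanes.
#'
#' @param truth a `synthetic_truth`.
#' @param metadata sample inventory matching the truth's abundance rows.
#' @param lanes_per_taxon number of lanes to tag per taxon.
#' @param n_bins,crop binning settings (the bin of a band is determined by
#'   its Rf position).
#' @return data frame with columns `lane_id`, `station`, `bin`, `tag`.
#' @export
plant_tags <- function(truth, metadata, lanes_per_taxon = 2, n_bins = 101,
                       crop = c(0, 1)) {
  tagged <- which(!is.na(truth$taxa$tag))
  rows <- list()
  for (j in tagged) {
    bin <- findInterval(truth$taxa$position[j],
                        seq(crop[1], crop[2], length.out = n_bins + 1),
                        all.inside = TRUE)
    lanes <- utils::head(order(truth$abundance[, j], decreasing = TRUE),
                         lanes_per_taxon)
    rows[[length(rows) + 1L]] <- data.frame(
      lane_id = metadata$sample_id[lanes],
      station = metadata$station[lanes],
      bin = bin,
      tag = truth$taxa$tag[j],
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    return(data.frame(lane_id = character(0), station = character(0),
                      bin = integer(0), tag = character(0)))
  }
  do.call(rbind, rows)
}

process_profiles <- function(profiles, anchors, config) {
  out <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    p <- subtract_background(profiles[[i]], config$background_window)
    a <- anchors[[i]]
    if (config$align && !is.null(a)) {
      p <- align_profile(p, a$source, a$reference)
    }
    out[[i]] <- p
  }
  out
}

analyse_fingerprints <- function(fm, metadata, config) {
  model <- fit_fpca(fm, k = config$k,
                    varprop_threshold = config$varprop_threshold,
                    lambda = config$lambda)
  D <- scores_distance(model)
  tree <- ward_cluster(D, config$ward_variant)
  ord <- ordinate(D, config$ordination)
  env <- fit_vectors(ord$site_scores[, 1:2, drop = FALSE], unclass(fm),
                     n_perm = config$envfit_n_perm, seed = config$seed)
  perm <- permanova(D, metadata, config$terms, n_perm = config$n_perm,
                    seed = config$seed)
  list(fingerprints = fm, fpca = model, distance = D, tree = tree,
       ordination = ord, envfit = env, permanova = perm)
}

write_analysis <- function(res, name, out_dir) {
  pathf <- function(stem, ext = "tsv") {
    file.path(out_dir, sprintf("%s_%s.%s", stem, name, ext))
  }
  write_fingerprints(res$fingerprints, pathf("fingerprints"))
  write_scores(res$fpca, pathf("scores"))
  write_harmonics(res$fpca, pathf("harmonics"))
  write_distance(res$distance, pathf("distance"))
  write_newick(tree_to_newick(res$tree), pathf("dendrogram", "nwk"))
  ord <- res$ordination
  write_tsv(data.frame(sample_id = rownames(ord$site_scores),
                       ord$site_scores[, 1:2, drop = FALSE],
                       check.names = FALSE), pathf("ordination"))
  write_tsv(as.data.frame(res$envfit), pathf("envfit"))
  write_permanova(res$permanova, pathf("permanova"))
  invisible(NULL)
}

#' Run the full fingerprint pipeline
#'
#' Simulates (or reads) lane profiles, processes them into 101-bin
#' fingerprints, and runs FPCA, Ward clustering, ordination, bin vector
#' fitting and sequential PERMANOVA on the unmasked matrix and, when a
#' mask is configured, on the masked re-analysis as well. When band tags
#' are available they are propagated and summed into group abundances.
#' Every output is written to `out_dir` as TSV/Newick plus a plain-text
#' log with a machine-readable `key: value` header.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `metadata`, per-analysis results
#'   (`original`, and `masked` when configured), `abundance` (or `NULL`),
#'   and `truth` for simulated runs.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    paste0("seed: ", config$seed),
    paste0("config_digest: ", config_digest(config)),
    paste0("started: pipeline")
  )
  truth <- NULL
  tags <- NULL
  if (is.null(config$profiles)) {
    sim <- config$simulate
    study <- synth_gel_study(seed = config$seed, sigma = sim$sigma,
                             effects = sim$effects,
                             spike_mass = sim$spike_mass,
                             warp_sd = sim$warp_sd, noise_sd = sim$noise_sd,
                             n_pixels = sim$n_pixels)
    metadata <- study$metadata
    profiles <- study$profiles
    truth <- study$truth
    anchors <- lapply(study$warps, function(w) {
      if (is.null(w)) return(NULL)
      list(source = warp_invert(w, study$marker_positions),
           reference = study$marker_positions)
    })
    tags <- plant_tags(truth, metadata, n_bins = config$n_bins,
                       crop = config$crop)
  } else {
    profiles <- read_profiles(config$profiles)
    metadata <- read_metadata(config$metadata)
    if (!setequal(metadata$sample_id,
                  vapply(profiles, function(p) p$lane_id, character(1)))) {
      stop("stage input: profile lane ids and metadata sample ids differ")
    }
    profiles <- profiles[metadata$sample_id]
    anchors <- rep(list(NULL), length(profiles))
    if (!is.null(config$anchors)) {
      adf <- read_tsv_checked(config$anchors,
                              c("lane_id", "source", "reference"), "anchor")
      anchors <- lapply(metadata$sample_id, function(id) {
        sub <- adf[adf$lane_id == id, , drop = FALSE]
        if (nrow(sub) == 0) NULL
        else list(source = sub$source, reference = sub$reference)
      })
    }
    if (!is.null(config$tags)) tags <- read_tags(config$tags)
  }
  log_lines <- c(log_lines, paste0("n_samples: ", nrow(metadata)),
                 paste0("n_profiles: ", length(profiles)))

  processed <- process_profiles(profiles, anchors, config)
  fm <- fingerprints_from_profiles(processed, config$n_bins, config$crop)
  analyses <- list(original = analyse_fingerprints(fm, metadata, config))
  if (!is.null(config$mask)) {
    fm_masked <- mask_bins(fm, config$mask)
    analyses$masked <- analyse_fingerprints(fm_masked, metadata, config)
  }
  for (name in names(analyses)) {
    write_analysis(analyses[[name]], name, out_dir)
    log_lines <- c(log_lines,
                   sprintf("analysis_%s_rows: %d", name,
                           nrow(analyses[[name]]$fingerprints)))
  }
  write_metadata(metadata, file.path(out_dir, "metadata.tsv"))
  abundance <- NULL
  if (!is.null(tags) && nrow(tags) > 0) {
    labeling <- propagate_tags(tags, unique(metadata$station), config$n_bins)
    abundance <- group_abundance(fm, labeling, metadata$station)
    write_tsv(data.frame(sample_id = rownames(abundance),
                         unclass(abundance), check.names = FALSE),
              file.path(out_dir, "abundance_groups.tsv"))
    log_lines <- c(log_lines,
                   paste0("abundance_groups: ", ncol(abundance)))
  }
  write_config(config, file.path(out_dir, "config.R"))
  log_lines <- c(log_lines, "finished: pipeline")
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(metadata = metadata, original = analyses$original,
                 masked = analyses$masked, abundance = abundance,
                 truth = truth))
}
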