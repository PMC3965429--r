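# Taxon tag propagation: sequence-derived tags from excised bands are
# propagated to all lanes at the same gel height (bin), with station-wise
# conflict resolution, then summed into group abundance tables.

#' Propagate band tags to a per-bin labeling
#'
#' Every tag is propagated to all lanes at the same bin. Conflicts are
#' resolved per bin: (a) all tags agree -> one global label; (b) tags are
#' consistent within each tagged station but differ across stations -> a
#' per-station label map, with untagged stations labeled `"unknown"`;
#' (c) any station received two or more different tags -> a double label
#' `"A/B"` (alphabetical) built from the two most frequent tag names in the
#' bin (ties broken alphabetically); (d) no tags -> `"unknown"`.
#' `"unknown"` counts as an ordinary tag value (bands whose sequence fell
#' below the classifier's confidence threshold arrive already labeled
#' `"unknown"`).
#'
#' @param tags data frame with columns `lane_id`, `station`, `bin`, `tag`.
#' @param stations character vector of all stations in the study.
#' @param n_bins number of bins (default 101).
#' @return object of class `bin_labeling`: a list of length `n_bins` whose
#'   elements are lists with `mode` (`"global"`, `"per_station"`,
#'   `"double"`, `"unknown"`) and `label` or `station_labels`.
#' @export
propagate_tags <- function(tags, stations = design_levels()$station,
                           n_bins = 101) {
  if (nrow(tags) > 0) {
    if (any(tags$bin < 1 | tags$bin > n_bins | tags$bin != round(tags$bin))) {
      stop("tag bin indices must be integers in 1..", n_bins)
    }
    if (any(!nzchar(tags$tag))) stop("tags must be non-empty strings")
    if (any(!tags$station %in% stations)) {
      stop("tag refers to a station outside the study: ",
           setdiff(tags$station, stations)[1])
    }
  }
  labeling <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    tb <- tags[tags$bin == b, , drop = FALSE]
    if (nrow(tb) == 0) {
      labeling[[b]] <- list(mode = "unknown", label = "unknown")
      next
    }
    distinct <- unique(tb$tag)
    if (length(distinct) == 1) {
      labeling[[b]] <- list(mode = "global", label = distinct)
      next
    }
    per_station <- tapply(tb$tag, tb$station, function(v) unique(v),
                          simplify = FALSE)
    within_conflict <- any(vapply(per_station, length, integer(1)) > 1)
    if (!within_conflict) {
      sl <- stats::setNames(rep("unknown", length(stations)), stations)
      for (st in names(per_station)) sl[st] <- per_station[[st]][1]
      labeling[[b]] <- list(mode = "per_station", station_labels = sl)
    } else {
      freq <- sort(table(tb$tag), decreasing = TRUE)
      # two most frequent, alphabetical tie-break, then alphabetical label
      ord <- order(-as.integer(freq), names(freq))
      two <- sort(names(freq)[ord][1:2])
      labeling[[b]] <- list(mode = "double",
                            label = paste(two, collapse = "/"))
    }
  }
  structure(labeling, stations = stations, class = "bin_labeling")
}

#' @export
print.bin_labeling <- function(x, ...) {
  modes <- vapply(x, function(e) e$mode, character(1))
  cat(sprintf(
    "<bin_labeling: %d bins (%d global, %d per-station, %d double, %d unknown)>\n",
    length(x), sum(modes == "global"), sum(modes == "per_station"),
    sum(modes == "double"), sum(modes == "unknown")))
  invisible(x)
}

# group name of bin b for a sample at station st
resolve_bin_label <- function(entry, station) {
  switch(entry$mode,
         global = entry$label,
         unknown = entry$label,
         double = entry$label,
         per_station = {
           if (is.na(station) || !station %in% names(entry$station_labels)) {
             stop("sample station required to resolve a per-station label")
           }
           entry$station_labels[[station]]
         })
}

#' Roll a class-level labeling up to phylum level
#'
#' Single labels are mapped through a two-column class-to-phylum table;
#' unmapped classes become `"unknown"`. Double labels map both components;
#' if they collapse to one phylum the label becomes single.
#'
#' @param labeling a `bin_labeling`.
#' @param class_map data frame with columns `class`, `phylum`.
#' @return a `bin_labeling` at phylum level.
#' @export
roll_up_labels <- function(labeling, class_map) {
  lookup <- stats::setNames(class_map$phylum, class_map$class)
  map1 <- function(lab) {
    if (lab == "unknown") return("unknown")
    out <- unname(lookup[lab])
    if (is.na(out)) "unknown" else out
  }
  out <- lapply(unclass(labeling), function(entry) {
    switch(entry$mode,
           unknown = entry,
           global = list(mode = "global", label = map1(entry$label)),
           per_station = {
             sl <- vapply(entry$station_labels, map1, character(1))
             list(mode = "per_station", station_labels = sl)
           },
           double = {
             parts <- sort(unique(vapply(strsplit(entry$label, "/",
                                                  fixed = TRUE)[[1]],
                                         map1, character(1))))
             if (length(parts) == 1) {
               list(mode = "global", label = parts)
             } else {
               list(mode = "double", label = paste(parts, collapse = "/"))
             }
           })
  })
  structure(out, stations = attr(labeling, "stations"),
            class = "bin_labeling")
}

#' Sum fingerprint bins into group abundances
#'
#' For each sample, each group's abundance is the sum of the relative
#' intensities of the bins labeled with that group (per-station labels are
#' resolved by the sample's station; double labels are their own
#' categories; unlabeled mass goes to `"unknown"`). Row sums equal the
#' fingerprint row sums, so mass is conserved.
#'
#' @param matrix a [fingerprint_matrix()].
#' @param labeling a `bin_labeling` covering all bins.
#' @param stations per-sample station vector (required when the labeling
#'   contains per-station entries; may be `NULL` otherwise).
#' @param level label of the taxonomic level, recorded on the result
#'   (`"phylum"` or `"class"`).
#' @return object of class `group_abundance`: samples x groups matrix with
#'   a `level` attribute.
#' @export
group_abundance <- function(matrix, labeling, stations = NULL,
                            level = "phylum") {
  values <- unclass(matrix)
  n_bins <- ncol(values)
  if (length(labeling) != n_bins) {
    stop("labeling must cover all ", n_bins, " bins")
  }
  modes <- vapply(labeling, function(e) e$mode, character(1))
  needs_station <- any(modes == "per_station")
  if (needs_station && is.null(stations)) {
    stop("per-station labels present: per-sample stations are required")
  }
  if (is.null(stations)) stations <- rep(NA_character_, nrow(values))
  # group of each bin per distinct station
  groups_for <- function(st) {
    vapply(labeling, resolve_bin_label, character(1), station = st)
  }
  sts <- unique(stations)
  bin_groups <- lapply(sts, groups_for)
  names(bin_groups) <- sts
  all_groups <- sort(unique(unlist(bin_groups)))
  out <- matrix(0, nrow(values), length(all_groups),
                dimnames = list(rownames(values), all_groups))
  for (i in seq_len(nrow(values))) {
    g <- bin_groups[[match(stations[i], sts)]]
    sums <- tapply(values[i, ], factor(g, levels = all_groups), sum)
    sums[is.na(sums)] <- 0
    out[i, ] <- sums
  }
  structure(out, level = level, class = "group_abundance")
}

#' Compare one group's abundance across factor levels
#'
#' One-way ANOVA of the named group's summed relative intensities across
#' the levels of a metadata factor (delegates to [group_anova()]).
#'
#' @param abundance a `group_abundance` matrix.
#' @param metadata sample inventory, rows matching `abundance`.
#' @param group_name column of `abundance` to test.
#' @param factor_name metadata column to group by.
#' @return a [group_anova()] result list.
#' @export
compare_groups <- function(abundance, metadata, group_name, factor_name) {
  if (!group_name %in% colnames(abundance)) {
    stop("unknown group '", group_name, "'")
  }
  if (!factor_name %in% names(metadata)) {
    stop("unknown factor '", factor_name, "'")
  }
  group_anova(unclass(abundance)[, group_name], metadata[[factor_name]])
}
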