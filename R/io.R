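# TSV readers/writers for the pipeline's tabular interfaces. All files are
# tab-separated, UTF-8, '.' decimal, with a header row.

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s file '%s' is missing columns: %s", what, path,
                 paste(miss, collapse = ", ")))
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' Read lane profiles from TSV
#'
#' Expects a first column `position` (ascending) and one intensity column
#' per lane, named by lane id.
#'
#' @param path TSV file path.
#' @return named list of [lane_profile()] objects.
#' @export
read_profiles <- function(path) {
  df <- read_tsv_checked(path, "position", "lane profile")
  if (ncol(df) < 2) stop("lane profile file '", path, "' has no lane columns")
  pos <- df$position
  if (any(!is.finite(pos)) || any(diff(pos) <= 0)) {
    stop("lane profile file '", path,
         "': position column must be finite and strictly increasing")
  }
  lanes <- setdiff(names(df), "position")
  out <- lapply(lanes, function(id) {
    y <- df[[id]]
    bad <- which(!is.finite(y))
    if (length(bad) > 0) {
      stop(sprintf("lane profile file '%s', line %d, column '%s': %s",
                   path, bad[1] + 1L, id, "non-numeric or missing intensity"))
    }
    lane_profile(pos, y, id)
  })
  stats::setNames(out, lanes)
}

#' Write lane profiles to TSV
#'
#' All profiles must share one position grid.
#' @param profiles list of [lane_profile()] objects.
#' @param path output path.
#' @export
write_profiles <- function(profiles, path) {
  pos <- profiles[[1]]$positions
  for (p in profiles) {
    if (!isTRUE(all.equal(p$positions, pos, tolerance = 1e-12))) {
      stop("all profiles must share one position grid to be written together")
    }
  }
  df <- data.frame(position = pos, check.names = FALSE)
  for (p in profiles) df[[p$lane_id]] <- p$intensities
  write_tsv(df, path)
}

#' Read sample metadata from TSV
#'
#' Columns `sample_id`, `fraction`, `station`, `redox`, `amendment`,
#' `replicate`; enum values must match [design_levels()] exactly.
#'
#' @param path TSV file path.
#' @return validated metadata data frame.
#' @export
read_metadata <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "fraction", "station", "redox",
                                 "amendment", "replicate"), "metadata")
  lv <- design_levels()
  for (col in c("fraction", "redox", "amendment")) {
    bad <- which(!df[[col]] %in% lv[[col]])
    if (length(bad) > 0) {
      stop(sprintf("metadata file '%s', line %d, column '%s': unknown value '%s'",
                   path, bad[1] + 1L, col, df[[col]][bad[1]]))
    }
  }
  validate_metadata(df)
  df
}

#' @rdname read_metadata
#' @param metadata metadata data frame.
#' @export
write_metadata <- function(metadata, path) write_tsv(metadata, path)

#' Read/write fingerprint matrices as TSV
#'
#' Layout: first column `sample_id`, then `bin_001` .. `bin_NNN`. A masked
#' matrix carries its mask in a `# mask:` comment line.
#'
#' @param path TSV file path.
#' @return a [fingerprint_matrix()].
#' @export
read_fingerprints <- function(path) {
  first <- readLines(path, n = 1)
  mask <- integer(0)
  if (startsWith(first, "# mask:")) {
    mask <- as.integer(strsplit(sub("# mask:", "", first), ",")[[1]])
  }
  df <- read_tsv_checked(path, "sample_id", "fingerprint")
  if (anyDuplicated(df$sample_id)) {
    stop("fingerprint file '", path, "': duplicated sample_id")
  }
  values <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  if (!is.numeric(values)) {
    stop("fingerprint file '", path, "': non-numeric bin values")
  }
  fingerprint_matrix(values, df$sample_id, mask = mask)
}

#' @rdname read_fingerprints
#' @param matrix a [fingerprint_matrix()].
#' @export
write_fingerprints <- function(matrix, path) {
  mask <- attr(matrix, "mask")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(mask) > 0) {
    writeLines(paste0("# mask:", paste(mask, collapse = ",")), con)
  }
  df <- data.frame(sample_id = rownames(matrix), unclass(matrix),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read band tags from TSV
#'
#' Columns `lane_id`, `station`, `bin`, `tag`.
#' @param path TSV file path.
#' @return data frame of band tags.
#' @export
read_tags <- function(path) {
  df <- read_tsv_checked(path, c("lane_id", "station", "bin", "tag"),
                         "band tag")
  bad <- which(!is.finite(df$bin) | df$bin != round(df$bin))
  if (length(bad) > 0) {
    stop(sprintf("band tag file '%s', line %d: non-integer bin", path,
                 bad[1] + 1L))
  }
  df
}

#' Read/write a distance matrix as square TSV
#'
#' First column and header row carry the sample ids; the numeric block is
#' checked for symmetry on read.
#'
#' @param path TSV file path.
#' @return a [distance_matrix()].
#' @export
read_distance <- function(path) {
  df <- read_tsv_checked(path, "sample_id", "distance matrix")
  ids <- df$sample_id
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  if (!identical(colnames(m), ids)) {
    stop("distance file '", path, "': header ids differ from row ids")
  }
  if (max(abs(m - t(m))) > 1e-12) {
    stop("distance file '", path, "': matrix is not symmetric")
  }
  distance_matrix(m, ids)
}

#' @rdname read_distance
#' @param D a [distance_matrix()].
#' @export
write_distance <- function(D, path) {
  df <- data.frame(sample_id = rownames(D), unclass(D), check.names = FALSE)
  write_tsv(df, path)
}

#' Write a PERMANOVA table as TSV
#'
#' Columns `term`, `Df`, `SS`, `F`, `R2`, `p`, `stars`, with `Residuals`
#' and `Total` rows.
#' @param result a `permanova_result`.
#' @param path output path.
#' @export
write_permanova <- function(result, path) {
  write_tsv(as.data.frame(result), path)
}

#' Write a Newick string to file
#' @param newick Newick string (from [tree_to_newick()]).
#' @param path output path.
#' @export
write_newick <- function(newick, path) writeLines(newick, path)

#' Write FPCA scores / harmonics as TSV
#'
#' Scores: `sample_id` plus one column per harmonic. Harmonics:
#' `bin_center` plus one column per harmonic.
#'
#' @param model an `fpca_model`.
#' @param path output path.
#' @export
write_scores <- function(model, path) {
  write_tsv(data.frame(sample_id = rownames(model$scores), model$scores,
                       check.names = FALSE), path)
}

#' @rdname write_scores
#' @export
write_harmonics <- function(model, path) {
  write_tsv(data.frame(bin_center = model$grid, model$harmonics,
                       check.names = FALSE), path)
}
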