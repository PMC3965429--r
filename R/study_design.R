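# Study design: sample inventory construction and sequential degrees of
# freedom for an unbalanced factorial with confounded in-situ levels.

#' Factor levels used throughout the pipeline
#'
#' The four experimental factors of the sediment incubation study: sample
#' fraction (bulk DNA, RNA, or density-separated whole cells), sampling
#' station along the redox transect, redox condition of the incubation, and
#' carbon/nutrient amendment. Samples taken before incubation carry the
#' level `in_situ` on both `redox` and `amendment`; the two are perfectly
#' confounded by construction.
#'
#' @return A named list of character vectors (`fraction`, `station`,
#'   `redox`, `amendment`), each in its canonical level order.
#' @export
#' @examples
#' design_levels()$station
design_levels <- function() {
  list(
    fraction  = c("bulk_dna", "rna", "whole_cell"),
    station   = c("LF1", "LF1.5", "LF3", "LF5"),
    redox     = c("oxic", "anoxic", "in_situ"),
    amendment = c("control", "cnp", "in_situ")
  )
}

#' Build the slurry incubation design
#'
#' Expands stations, redox conditions, amendments and replicates into the
#' full factorial set of incubations, one row per incubation bottle.
#' Ordering is deterministic: stations vary slowest, then redox, then
#' amendment, then replicate.
#'
#' @param stations character vector of station names.
#' @param redox_levels character vector of incubation redox conditions
#'   (must not contain `"in_situ"`; in-situ samples are not incubations).
#' @param amendments character vector of amendment levels (no `"in_situ"`).
#' @param replicates number of replicate bottles per treatment cell.
#' @return A data frame with columns `station`, `redox`, `amendment`,
#'   `replicate`.
#' @export
#' @examples
#' d <- build_incubation_design(design_levels()$station,
#'                              c("oxic", "anoxic"),
#'                              c("control", "cnp"), 3)
#' nrow(d)  # 48
build_incubation_design <- function(stations, redox_levels, amendments,
                                    replicates) {
  if (length(stations) == 0 || length(redox_levels) == 0 ||
      length(amendments) == 0) {
    stop("invalid design: every factor needs at least one level")
  }
  if (length(replicates) != 1 || replicates < 1 ||
      replicates != round(replicates)) {
    stop("invalid design: 'replicates' must be a positive integer")
  }
  if ("in_situ" %in% c(redox_levels, amendments)) {
    stop("invalid design: 'in_situ' is not an incubation condition")
  }
  out <- expand.grid(
    replicate = seq_len(replicates),
    amendment = amendments,
    redox     = redox_levels,
    station   = stations,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  out <- out[, c("station", "redox", "amendment", "replicate")]
  rownames(out) <- NULL
  out
}

#' Build the full sample inventory
#'
#' Expands an incubation design into the per-fraction sample inventory used
#' for fingerprint analysis: the bulk DNA and RNA fractions get one sample
#' per incubation plus a stated number of pre-incubation (in-situ) samples
#' per station; the whole-cell fraction covers a configurable subset of
#' incubations and has no in-situ samples. In-situ samples carry
#' `redox = "in_situ"` and `amendment = "in_situ"` (the two levels are
#' perfectly confounded).
#'
#' @param design incubation design from [build_incubation_design()].
#' @param in_situ_reps named integer vector: in-situ samples per station for
#'   each fraction (default `c(bulk_dna = 2, rna = 1)`; fractions absent
#'   from the vector get none). `whole_cell` must be absent or zero.
#' @param whole_cell_total total number of whole-cell samples, distributed
#'   round-robin over the treatment cells in design order (each cell keeps
#'   at least one when the total allows). Ignored when
#'   `whole_cell_coverage` is given. Default 39.
#' @param whole_cell_coverage optional data frame with columns `station`,
#'   `redox`, `amendment`, `n` giving the number of whole-cell samples per
#'   treatment cell (0 to the number of replicates).
#' @return A data frame with columns `sample_id`, `fraction`, `station`,
#'   `redox`, `amendment`, `replicate`, one row per sample.
#' @export
#' @examples
#' d <- build_incubation_design(design_levels()$station,
#'                              c("oxic", "anoxic"),
#'                              c("control", "cnp"), 3)
#' inv <- build_sample_inventory(d)
#' table(inv$fraction)  # 56 bulk_dna, 52 rna, 39 whole_cell
build_sample_inventory <- function(design,
                                   in_situ_reps = c(bulk_dna = 2, rna = 1),
                                   whole_cell_total = 39,
                                   whole_cell_coverage = NULL) {
  stations <- unique(design$station)
  if (!is.null(in_situ_reps) && "whole_cell" %in% names(in_situ_reps) &&
      in_situ_reps[["whole_cell"]] > 0) {
    stop("invariant violation: whole-cell in-situ samples do not exist")
  }
  cells <- unique(design[, c("station", "redox", "amendment")])
  rownames(cells) <- NULL
  reps_per_cell <- as.integer(table(interaction(
    design$station, design$redox, design$amendment, drop = TRUE
  ))[interaction(cells$station, cells$redox, cells$amendment, drop = TRUE)])

  if (is.null(whole_cell_coverage)) {
    n_cells <- nrow(cells)
    counts <- integer(n_cells)
    # round-robin passes over cells in design order until the total is spent
    remaining <- whole_cell_total
    while (remaining > 0) {
      takers <- which(counts < reps_per_cell)
      if (length(takers) == 0) break
      takers <- takers[seq_len(min(length(takers), remaining))]
      counts[takers] <- counts[takers] + 1L
      remaining <- remaining - length(takers)
    }
    whole_cell_coverage <- cbind(cells, n = counts)
  } else {
    key_a <- interaction(whole_cell_coverage$station, whole_cell_coverage$redox,
                         whole_cell_coverage$amendment, drop = TRUE)
    key_b <- interaction(cells$station, cells$redox, cells$amendment,
                         drop = TRUE)
    if (!all(as.character(key_a) %in% as.character(key_b))) {
      stop("whole_cell_coverage refers to cells absent from the design")
    }
    if ("in_situ" %in% c(whole_cell_coverage$redox,
                         whole_cell_coverage$amendment)) {
      stop("invariant violation: whole-cell in-situ samples do not exist")
    }
  }

  rows <- list()
  add <- function(fraction, station, redox, amendment, replicate) {
    data.frame(fraction = fraction, station = station, redox = redox,
               amendment = amendment, replicate = replicate,
               stringsAsFactors = FALSE)
  }
  for (fr in c("bulk_dna", "rna")) {
    rows[[length(rows) + 1L]] <-
      add(fr, design$station, design$redox, design$amendment,
          design$replicate)
    n_is <- if (fr %in% names(in_situ_reps)) in_situ_reps[[fr]] else 0L
    if (n_is > 0) {
      for (st in stations) {
        rows[[length(rows) + 1L]] <-
          add(fr, st, "in_situ", "in_situ", seq_len(n_is))
      }
    }
  }
  for (i in seq_len(nrow(whole_cell_coverage))) {
    n_i <- whole_cell_coverage$n[i]
    if (n_i > 0) {
      rows[[length(rows) + 1L]] <-
        add("whole_cell", whole_cell_coverage$station[i],
            whole_cell_coverage$redox[i], whole_cell_coverage$amendment[i],
            seq_len(n_i))
    }
  }
  inv <- do.call(rbind, rows)
  inv$sample_id <- paste(inv$fraction, inv$station, inv$redox, inv$amendment,
                         paste0("r", inv$replicate), sep = "_")
  inv <- inv[, c("sample_id", "fraction", "station", "redox", "amendment",
                 "replicate")]
  rownames(inv) <- NULL
  validate_metadata(inv)
  inv
}

#' Validate sample metadata invariants
#'
#' Checks the structural invariants of a sample inventory: enum values,
#' perfect confounding of the in-situ levels of `redox` and `amendment`, no
#' whole-cell in-situ samples, and uniqueness of
#' (fraction, station, redox, amendment, replicate).
#'
#' @param metadata data frame with the inventory columns.
#' @param strict_levels if `TRUE` (default) enum columns must only use the
#'   canonical levels from [design_levels()].
#' @return `metadata`, invisibly; stops on violation.
#' @export
validate_metadata <- function(metadata, strict_levels = TRUE) {
  need <- c("sample_id", "fraction", "station", "redox", "amendment",
            "replicate")
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0) {
    stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  }
  lv <- design_levels()
  if (strict_levels) {
    for (col in c("fraction", "redox", "amendment")) {
      bad <- which(!metadata[[col]] %in% lv[[col]])
      if (length(bad) > 0) {
        stop(sprintf("metadata row %d: unknown %s value '%s'",
                     bad[1], col, metadata[[col]][bad[1]]))
      }
    }
  }
  confound <- (metadata$redox == "in_situ") != (metadata$amendment == "in_situ")
  if (any(confound)) {
    stop("invariant violation: redox == in_situ must coincide with ",
         "amendment == in_situ (rows ",
         paste(utils::head(which(confound), 3), collapse = ", "), ")")
  }
  wc_is <- metadata$fraction == "whole_cell" & metadata$redox == "in_situ"
  if (any(wc_is)) {
    stop("invariant violation: whole-cell in-situ samples do not exist")
  }
  key <- interaction(metadata$fraction, metadata$station, metadata$redox,
                     metadata$amendment, metadata$replicate, drop = TRUE)
  if (anyDuplicated(key)) {
    stop("invariant violation: duplicated ",
         "(fraction, station, redox, amendment, replicate) tuples")
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop("invariant violation: duplicated sample_id")
  }
  invisible(metadata)
}

#' Default sequential term order
#'
#' Main effects, then all two-, three- and four-way interactions of
#' fraction, station, redox, and amendment, in the order used for the
#' sequential PERMANOVA table.
#'
#' @return character vector of term labels (`":"`-separated factor names).
#' @export
default_term_order <- function() {
  c("fraction", "station", "redox", "amendment",
    "fraction:station", "fraction:redox", "station:redox",
    "fraction:amendment", "station:amendment", "redox:amendment",
    "fraction:station:redox", "fraction:station:amendment",
    "fraction:redox:amendment", "station:redox:amendment",
    "fraction:station:redox:amendment")
}

# Indicator (one column per observed level combination) coding of one term.
term_indicator <- function(metadata, term) {
  facs <- strsplit(term, ":", fixed = TRUE)[[1]]
  unknown <- setdiff(facs, c("fraction", "station", "redox", "amendment"))
  if (length(unknown) > 0) {
    stop("unknown factor in term '", term, "': ",
         paste(unknown, collapse = ", "))
  }
  g <- interaction(metadata[facs], drop = TRUE, sep = ":")
  stats::model.matrix(~ 0 + g)
}

rank_tol <- 1e-8

matrix_rank <- function(X) {
  if (ncol(X) == 0) return(0L)
  d <- svd(X, nu = 0, nv = 0)$d
  sum(d > rank_tol * d[1])
}

#' Sequential degrees of freedom for model terms
#'
#' Computes the degrees of freedom of each term as the increase in column
#' rank of the cumulative design matrix (intercept first, then each term's
#' indicator columns in the given order). Columns aliased with previously
#' fitted terms contribute nothing, so confounded levels (such as the
#' in-situ level shared by redox and amendment) and empty design cells are
#' attributed to the first term that spans them. Rank is determined by
#' singular values above `1e-8` times the largest.
#'
#' @param metadata sample inventory data frame (see
#'   [build_sample_inventory()]).
#' @param terms character vector of term labels, e.g. `"fraction"` or
#'   `"station:redox"`; default [default_term_order()].
#' @return An object of class `term_df_table`: a data frame with columns
#'   `term` and `df`, with attributes `residual_df` and `total_df`.
#' @export
#' @examples
#' inv <- build_sample_inventory(build_incubation_design(
#'   design_levels()$station, c("oxic", "anoxic"), c("control", "cnp"), 3))
#' term_degrees_of_freedom(inv)
term_degrees_of_freedom <- function(metadata, terms = default_term_order()) {
  n <- nrow(metadata)
  X <- matrix(1, nrow = n, ncol = 1)
  r_prev <- 1L
  df <- integer(length(terms))
  for (i in seq_along(terms)) {
    X <- cbind(X, term_indicator(metadata, terms[i]))
    r_now <- matrix_rank(X)
    df[i] <- r_now - r_prev
    r_prev <- r_now
  }
  out <- data.frame(term = terms, df = df, stringsAsFactors = FALSE)
  attr(out, "residual_df") <- (n - 1L) - sum(df)
  attr(out, "total_df") <- n - 1L
  class(out) <- c("term_df_table", "data.frame")
  out
}

#' @export
print.term_df_table <- function(x, ...) {
  cat("Sequential degrees of freedom\n")
  print(data.frame(term = x$term, Df = x$df), row.names = FALSE)
  cat(sprintf("Residuals %d\nTotal     %d\n",
              attr(x, "residual_df"), attr(x, "total_df")))
  invisible(x)
}

# Orthonormal bases of the cumulative design matrices, one per term, shared
# by permanova(). Returns list of n x r_k matrices (intercept excluded from
# attribution but included in the projection).
cumulative_bases <- function(metadata, terms) {
  n <- nrow(metadata)
  X <- matrix(1, nrow = n, ncol = 1)
  bases <- vector("list", length(terms))
  for (i in seq_along(terms)) {
    X <- cbind(X, term_indicator(metadata, terms[i]))
    s <- svd(X, nv = 0)
    keep <- s$d > rank_tol * s$d[1]
    bases[[i]] <- s$u[, keep, drop = FALSE]
  }
  bases
}
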