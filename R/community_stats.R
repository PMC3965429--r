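# Distance-based multivariate statistics: Ward clustering, correspondence
# analysis, vector fitting, sequential-SS PERMANOVA, one-way ANOVA, and the
# pooled two-sample t-test.

#' Distance matrix container
#'
#' @param m square numeric matrix: symmetric (to 1e-12), zero diagonal,
#'   non-negative.
#' @param sample_ids row/column identifiers (default rownames).
#' @return object of class `distance_matrix` (a plain matrix underneath).
#' @export
distance_matrix <- function(m, sample_ids = rownames(m)) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(diag(m) != 0)) stop("distance matrix diagonal must be exactly 0")
  if (any(m < 0)) stop("distances must be non-negative")
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(m)))
  dimnames(m) <- list(sample_ids, sample_ids)
  structure(m, class = "distance_matrix")
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering with the Ward objective via the Lance-Williams
#' update on squared distances (the `ward.D2` convention, appropriate for
#' Euclidean input). The historical variant that applies the update to the
#' raw distances is available as `variant = "ward.D"`.
#'
#' @param D a [distance_matrix()].
#' @param variant `"ward.D2"` (default) or `"ward.D"`.
#' @return an [stats::hclust] tree with leaf labels from the sample ids.
#' @export
ward_cluster <- function(D, variant = c("ward.D2", "ward.D")) {
  variant <- match.arg(variant)
  m <- unclass(D)
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix must be symmetric")
  if (nrow(m) < 2) stop("need at least 2 samples to cluster")
  d <- stats::as.dist(m)
  stats::hclust(d, method = variant)
}

quote_newick_label <- function(x) {
  bad <- grepl("[][ \t(),:;']", x)
  x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
  x
}

#' Serialize an hclust tree to Newick
#'
#' Branch lengths follow the usual ultrametric convention: a leaf hangs at
#' half the height of its parent merge, and an internal node's branch is
#' half the difference between its parent's and its own merge height. Leaf
#' labels containing spaces or Newick metacharacters are single-quoted.
#'
#' @param tree an [stats::hclust] object.
#' @return a single Newick string (terminated by `;`).
#' @export
tree_to_newick <- function(tree) {
  labs <- quote_newick_label(tree$labels %||%
                               as.character(seq_len(nrow(tree$merge) + 1)))
  h <- tree$height
  node_str <- function(i) {
    parts <- vapply(tree$merge[i, ], function(v) {
      if (v < 0) {
        sprintf("%s:%.10g", labs[-v], h[i] / 2)
      } else {
        sprintf("%s:%.10g", node_str(v), (h[i] - h[v]) / 2)
      }
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(node_str(nrow(tree$merge)), ";")
}

#' Correspondence analysis of a non-negative table
#'
#' Chi-square decomposition: with `P` the table divided by its grand total
#' and `r`, `c` the margins, the standardized residuals
#' `S = Dr^{-1/2} (P - r c') Dc^{-1/2}` are decomposed by SVD; row (site)
#' scores are reported in principal coordinates and each axis carries
#' inertia proportion `sigma_k^2 / sum(sigma^2)`.
#'
#' @param M non-negative matrix with no all-zero row or column.
#' @return object of class `ordination_result`: `site_scores` (rows x
#'   axes), `inertia_prop`, `total_inertia`, `singular_values`.
#' @export
correspondence_analysis <- function(M) {
  M <- as.matrix(M)
  if (any(M < 0)) stop("correspondence analysis requires non-negative entries")
  rs <- rowSums(M); cs <- colSums(M)
  if (any(rs == 0)) {
    stop("all-zero row in CA input: ",
         (rownames(M) %||% as.character(seq_len(nrow(M))))[which(rs == 0)[1]])
  }
  if (any(cs == 0)) {
    stop("all-zero column in CA input: ",
         (colnames(M) %||% as.character(seq_len(ncol(M))))[which(cs == 0)[1]])
  }
  total <- sum(M)
  P <- M / total
  r <- rs / total; cc <- cs / total
  S <- (P - tcrossprod(r, cc)) / sqrt(tcrossprod(r, cc))
  sv <- svd(S)
  n_axes <- min(nrow(M), ncol(M)) - 1
  sigma <- sv$d[seq_len(n_axes)]
  total_inertia <- sum(sv$d^2)
  # row principal coordinates: Dr^{-1/2} U Sigma
  scores <- sweep(sv$u[, seq_len(n_axes), drop = FALSE], 1, sqrt(r), "/") %*%
    diag(sigma, n_axes)
  inertia_prop <- if (total_inertia > 1e-14) sigma^2 / total_inertia
                  else rep(0, n_axes)
  dimnames(scores) <- list(rownames(M), paste0("CA", seq_len(n_axes)))
  structure(list(site_scores = scores, inertia_prop = inertia_prop,
                 total_inertia = total_inertia, singular_values = sigma,
                 method = "ca"),
            class = "ordination_result")
}

#' Ordinate a distance matrix
#'
#' `method = "ca"` applies [correspondence_analysis()] directly to the
#' distance-matrix entries (the procedure used for the gel fingerprints;
#' chi-square machinery on distances is unorthodox but reproduced
#' faithfully). `method = "pcoa"` is the classical principal-coordinates
#' alternative ([stats::cmdscale]); its axis proportions are computed over
#' the positive eigenvalues.
#'
#' @param D a [distance_matrix()].
#' @param method `"ca"` (default) or `"pcoa"`.
#' @return an `ordination_result`.
#' @export
ordinate <- function(D, method = c("ca", "pcoa")) {
  method <- match.arg(method)
  if (method == "ca") return(correspondence_analysis(unclass(D)))
  n <- nrow(D)
  eig <- stats::cmdscale(stats::as.dist(unclass(D)), k = 1, eig = TRUE)$eig
  pos <- eig > 1e-10 * max(abs(eig))
  k <- sum(pos)
  fit <- stats::cmdscale(stats::as.dist(unclass(D)), k = k, eig = TRUE)
  scores <- fit$points
  dimnames(scores) <- list(rownames(D), paste0("PCoA", seq_len(k)))
  structure(list(site_scores = scores,
                 inertia_prop = fit$eig[seq_len(k)] / sum(fit$eig[pos]),
                 total_inertia = sum(fit$eig[pos]),
                 singular_values = sqrt(pmax(fit$eig[seq_len(k)], 0)),
                 method = "pcoa"),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("<ordination_result (%s): %d sites, axis 1-2 = %.1f%% / %.1f%%>\n",
              x$method, nrow(x$site_scores),
              100 * x$inertia_prop[1],
              100 * (if (length(x$inertia_prop) > 1) x$inertia_prop[2] else 0)))
  invisible(x)
}

#' Fit variables as vectors in an ordination plane
#'
#' Each variable is regressed by ordinary least squares on the first two
#' ordination axes; `r2` is the regression R-squared, the direction is the
#' unit coefficient vector, and the p-value comes from permuting the
#' variable's values (`p = (1 + #{r2* >= r2}) / (1 + n_perm)`). Constant
#' variables get `r2 = 0`, `p = 1` and are flagged.
#'
#' @param site_scores samples x 2 matrix of ordination coordinates.
#' @param variables samples x V matrix (e.g. one column per fingerprint
#'   bin).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @param permutations optional integer matrix, one permutation of
#'   `1:n` per row, used instead of random draws (e.g. an exhaustive
#'   enumeration); overrides `n_perm`.
#' @return object of class `envfit_result`: data frame with columns
#'   `variable`, `r2`, `p`, `dir1`, `dir2`, `constant`.
#' @export
fit_vectors <- function(site_scores, variables, n_perm = 999, seed = 1,
                        permutations = NULL) {
  axes <- as.matrix(site_scores)[, 1:2, drop = FALSE]
  n <- nrow(axes)
  if (n < 3) stop("need at least 3 samples")
  variables <- as.matrix(variables)
  if (nrow(variables) != n) stop("variables and site_scores disagree on n")
  X <- cbind(1, axes)
  qrX <- qr(X)
  Q <- qr.Q(qrX)
  if (is.null(permutations)) {
    if (n_perm < 1) stop("n_perm must be at least 1")
    set.seed(seed)
    perms <- replicate(n_perm, sample.int(n))
  } else {
    perms <- t(permutations)
    n_perm <- ncol(perms)
  }
  r2_of <- function(v) {
    tss <- sum((v - mean(v))^2)
    if (tss == 0) return(NA_real_)
    # ||Q'v||^2 includes the intercept component mean(v)^2 * n
    fit_ss <- sum(crossprod(Q, v)^2) - n * mean(v)^2
    fit_ss / tss
  }
  V <- ncol(variables)
  out <- data.frame(variable = colnames(variables) %||%
                      paste0("v", seq_len(V)),
                    r2 = NA_real_, p = NA_real_,
                    dir1 = NA_real_, dir2 = NA_real_,
                    constant = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(V)) {
    v <- variables[, j]
    r2 <- r2_of(v)
    if (is.na(r2)) {
      out$r2[j] <- 0; out$p[j] <- 1; out$constant[j] <- TRUE
      next
    }
    coefs <- qr.coef(qrX, v)[-1]
    nrm <- sqrt(sum(coefs^2))
    if (nrm > 0) {
      out$dir1[j] <- coefs[1] / nrm
      out$dir2[j] <- coefs[2] / nrm
    }
    Vp <- matrix(v[perms], nrow = n)
    tss <- sum((v - mean(v))^2)
    fit_ss <- colSums(crossprod(Q, Vp)^2) - n * mean(v)^2
    r2_perm <- fit_ss / tss
    out$r2[j] <- r2
    out$p[j] <- (1 + sum(r2_perm >= r2 - 1e-12)) / (1 + n_perm)
  }
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("envfit_result", "data.frame")
  out
}

significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p <= 0.001, "***",
                ifelse(p <= 0.01, "**",
                       ifelse(p <= 0.05, "*",
                              ifelse(p <= 0.1, ".", "")))))
}

#' Sequential (Type-I) PERMANOVA on a distance matrix
#'
#' Gower-centers the squared distances (`G = -1/2 J D^2 J`) and attributes
#' `SS_term = tr(H_cum G) - tr(H_prev G)` to each term in order, with `H`
#' the hat matrix of the cumulative dummy design. Degrees of freedom come
#' from [term_degrees_of_freedom()], so aliased columns (confounded in-situ
#' levels, empty design cells) contribute nothing. Pseudo-F is
#' `(SS/df) / (SS_res/df_res)` and p-values come from free permutation of
#' the sample rows (rows and columns of `D` permuted together), with the
#' observed statistic included (`p = (1 + #{F* >= F}) / (1 + n_perm)`).
#'
#' @param D a [distance_matrix()].
#' @param metadata sample inventory, rows matching `D`.
#' @param terms ordered character vector of model terms (default
#'   [default_term_order()]).
#' @param n_perm number of permutations (default 999; 0 skips p-values).
#' @param seed RNG seed for the permutations.
#' @param permutations optional integer matrix, one permutation of `1:n`
#'   per row, used instead of random draws (e.g. an exhaustive
#'   enumeration); overrides `n_perm`.
#' @return object of class `permanova_result`: data frame with one row per
#'   term plus `Residuals` and `Total`, columns `term`, `Df`, `SS`, `F`,
#'   `R2`, `p`, `stars`; attributes `n_perm` and `seed`.
#' @export
permanova <- function(D, metadata, terms = default_term_order(),
                      n_perm = 999, seed = 1, permutations = NULL) {
  m <- unclass(D)
  n <- nrow(m)
  if (nrow(metadata) != n) stop("metadata rows must match the distance matrix")
  if (n_perm < 0) stop("n_perm must be >= 0")
  A <- -0.5 * m^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  ss_total <- sum(diag(G))
  dftab <- term_degrees_of_freedom(metadata, terms)
  df <- dftab$df
  df_res <- attr(dftab, "residual_df")
  if (df_res <= 0) stop("saturated model: no residual degrees of freedom")
  bases <- cumulative_bases(metadata, terms)
  H <- lapply(bases, tcrossprod)
  traces <- vapply(H, function(h) sum(h * G), numeric(1))
  ss <- diff(c(0, traces))
  ss_res <- ss_total - traces[length(traces)]
  degenerate <- ss_total <= 1e-12
  f_obs <- ifelse(df > 0, (ss / pmax(df, 1)) / (ss_res / df_res), NA_real_)
  if (degenerate) f_obs[] <- NA_real_
  if (!is.null(permutations)) n_perm <- nrow(permutations)
  p <- rep(NA_real_, length(terms))
  if (n_perm > 0 && !degenerate) {
    count <- integer(length(terms))
    set.seed(seed)
    for (b in seq_len(n_perm)) {
      idx <- if (is.null(permutations)) sample.int(n) else permutations[b, ]
      Gp <- G[idx, idx]
      tr_p <- vapply(H, function(h) sum(h * Gp), numeric(1))
      ss_p <- diff(c(0, tr_p))
      ss_res_p <- ss_total - tr_p[length(tr_p)]
      f_p <- (ss_p / pmax(df, 1)) / (ss_res_p / df_res)
      count <- count + (f_p >= f_obs - 1e-12 & df > 0)
    }
    p <- ifelse(df > 0, (1 + count) / (1 + n_perm), NA_real_)
  }
  r2 <- if (ss_total > 0) ss / ss_total else rep(NA_real_, length(terms))
  tab <- data.frame(
    term = c(terms, "Residuals", "Total"),
    Df = c(df, df_res, n - 1L),
    SS = c(ss, ss_res, ss_total),
    F = c(f_obs, NA, NA),
    R2 = c(r2, if (ss_total > 0) ss_res / ss_total else NA, 1),
    p = c(p, NA, NA),
    stringsAsFactors = FALSE
  )
  tab$stars <- significance_stars(tab$p)
  attr(tab, "n_perm") <- n_perm
  attr(tab, "seed") <- seed
  attr(tab, "degenerate") <- degenerate
  class(tab) <- c("permanova_result", "data.frame")
  tab
}

#' @export
print.permanova_result <- function(x, digits = 4, ...) {
  cat(sprintf("Sequential PERMANOVA (%d permutations, seed %s)%s\n",
              attr(x, "n_perm"), format(attr(x, "seed")),
              if (isTRUE(attr(x, "degenerate"))) " [degenerate: SS_total = 0]"
              else ""))
  tab <- data.frame(term = x$term, Df = x$Df,
                    SS = signif(x$SS, digits),
                    F = signif(x$F, digits),
                    R2 = signif(x$R2, 3),
                    p = x$p, stars = x$stars)
  print(tab, row.names = FALSE, na.print = "")
  cat("Significance codes: *** <= 0.001, ** <= 0.01, * <= 0.05\n")
  invisible(x)
}

#' One-way ANOVA
#'
#' Classical one-way analysis of variance via [stats::aov], with explicit
#' handling of the degenerate cases: all values identical gives `F = 0`,
#' and zero within-group variance with distinct means gives `F = Inf`
#' flagged as exact separation.
#'
#' @param values numeric response.
#' @param groups grouping factor (>= 2 non-empty groups).
#' @return list with `F`, `df_between`, `df_within`, `p`,
#'   `exact_separation`.
#' @export
group_anova <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  df_b <- nlevels(groups) - 1L
  df_w <- length(values) - nlevels(groups)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  if (ssw <= 1e-300) {
    if (ssb <= 1e-300) {
      return(list(F = 0, df_between = df_b, df_within = df_w, p = 1,
                  exact_separation = FALSE))
    }
    return(list(F = Inf, df_between = df_b, df_within = df_w, p = 0,
                exact_separation = TRUE))
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  list(F = tab[["F value"]][1], df_between = tab[["Df"]][1],
       df_within = tab[["Df"]][2], p = tab[["Pr(>F)"]][1],
       exact_separation = FALSE)
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Pooled-variance two-sample t with `df = n_x + n_y - 2` and a two-sided
#' p-value. Zero pooled variance with equal means gives `t = 0, p = 1`;
#' with distinct means, infinite t.
#'
#' @param x,y numeric samples with at least 2 observations each.
#' @return list with `t`, `df`, `p`.
#' @export
students_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need at least 2 values per sample")
  df <- length(x) + length(y) - 2L
  pooled <- sum((x - mean(x))^2) + sum((y - mean(y))^2)
  if (pooled <= 1e-300) {
    if (mean(x) == mean(y)) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = df, p = 0))
  }
  fit <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}
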