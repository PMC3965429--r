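test_that("Ward clustering matches a naive within-variance implementation", {
  set.seed(31)
  for (r in 1:5) {
    X <- matrix(rnorm(16), 8, 2)
    D <- distance_matrix(as.matrix(dist(X)), paste0("s", 1:8))
    tree <- ward_cluster(D)
    expect_lt(max(abs(tree$height - naive_ward_heights(X))), 1e-10)
    expect_true(all(diff(tree$height) >= -1e-12))
  }
  # forced merges under clear separation
  D4 <- distance_matrix(as.matrix(dist(c(0, 1, 10, 11))), letters[1:4])
  t4 <- ward_cluster(D4)
  expect_equal(sort(abs(t4$merge[1, ])), c(1, 2))
  expect_equal(sort(abs(t4$merge[2, ])), c(3, 4))
  # two identical points merge at height zero
  D0 <- distance_matrix(matrix(0, 2, 2), c("a", "b"))
  expect_equal(ward_cluster(D0)$height, 0)
  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(ward_cluster(structure(bad, class = "distance_matrix")),
               "symmetric")
})

test_that("Newick serialization round-trips through an independent parser", {
  skip_if_not_installed("ape")
  set.seed(32)
  X <- matrix(rnorm(14), 7, 2)
  ids <- c("a", "b", "lane c", "d", "e", "f", "g")  # one label with a space
  D <- distance_matrix(as.matrix(dist(X)), ids)
  tree <- ward_cluster(D)
  nwk <- tree_to_newick(tree)
  expect_true(grepl("'lane c'", nwk, fixed = TRUE))
  parsed <- ape::read.tree(text = nwk)
  tips <- gsub("'", "", parsed$tip.label)  # ape keeps the quote characters
  expect_setequal(tips, c("a", "b", "lane c", "d", "e", "f", "g"))
  # leaf-to-leaf path lengths in an ultrametric tree equal the cophenetic
  # merge heights
  coph <- as.matrix(cophenetic(tree))
  pd <- ape::cophenetic.phylo(parsed)
  dimnames(pd) <- list(gsub("'", "", rownames(pd)),
                       gsub("'", "", colnames(pd)))
  expect_equal(pd[rownames(coph), colnames(coph)], coph, tolerance = 1e-8)

  two <- ward_cluster(distance_matrix(as.matrix(dist(c(0, 3))), c("x", "y")))
  expect_equal(tree_to_newick(two), "(x:1.5,y:1.5);")
})

test_that("correspondence analysis reproduces the chi-square decomposition", {
  # rank-1 table: the independence model fits exactly
  M <- outer(c(1, 2, 3), c(4, 1, 5))
  expect_lt(correspondence_analysis(M)$total_inertia, 1e-12)

  # perfect association in a 2x2 table: one axis with all the inertia
  ca2 <- correspondence_analysis(rbind(c(10, 0), c(0, 10)))
  expect_equal(ca2$inertia_prop[1], 1, tolerance = 1e-12)
  expect_equal(ca2$total_inertia, 1, tolerance = 1e-12)

  # 3x3 toy table against a direct chi-square SVD coded here
  M <- rbind(c(6, 2, 1), c(1, 5, 2), c(2, 1, 7))
  n <- sum(M); P <- M / n
  r <- rowSums(P); cc <- colSums(P)
  E <- outer(r, cc)
  S <- (P - E) / sqrt(E)
  sv <- svd(S)
  ca <- correspondence_analysis(M)
  expect_lt(max(abs(ca$singular_values - sv$d[1:2])), 1e-10)
  expect_lt(abs(ca$total_inertia - sum(sv$d^2)), 1e-10)
  ref_scores <- diag(1 / sqrt(r)) %*% sv$u[, 1:2] %*% diag(sv$d[1:2])
  for (j in 1:2) {
    expect_lt(min(max(abs(ca$site_scores[, j] - ref_scores[, j])),
                  max(abs(ca$site_scores[, j] + ref_scores[, j]))), 1e-10)
  }

  expect_error(correspondence_analysis(rbind(c(-1, 2), c(1, 1))),
               "non-negative")
  expect_error(correspondence_analysis(rbind(c(0, 0), c(1, 1))), "row")
})

test_that("CA eigenvalues agree with vegan on a fingerprint-like table", {
  skip_if_not_installed("vegan")
  fm <- rand_fingerprint(10, 25, seed = 33)
  ca <- correspondence_analysis(unclass(fm))
  vg <- vegan::cca(as.data.frame(unclass(fm)))
  ev <- vg$CA$eig
  expect_equal(unname(ca$singular_values[seq_along(ev)]^2), unname(ev),
               tolerance = 1e-8)
})

test_that("PCoA ordination is available as the orthodox alternative", {
  set.seed(34)
  X <- matrix(rnorm(30), 10, 3)
  D <- distance_matrix(as.matrix(dist(X)))
  ord <- ordinate(D, "pcoa")
  # PCoA on Euclidean distances recovers the centered configuration
  expect_equal(sort(ord$inertia_prop, decreasing = TRUE), ord$inertia_prop)
  expect_equal(sum(ord$inertia_prop), 1, tolerance = 1e-9)
  d_ord <- as.matrix(dist(ord$site_scores))
  expect_equal(d_ord, unclass(D), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("vector fitting matches geometry and exhaustive permutation", {
  set.seed(35)
  scores <- cbind(rnorm(8), rnorm(8))
  colnames(scores) <- c("ax1", "ax2")

  # a variable identical to axis 1 fits perfectly along (1, 0)
  res <- fit_vectors(scores, cbind(v = scores[, 1]), n_perm = 39, seed = 1)
  expect_equal(res$r2, 1, tolerance = 1e-12)
  expect_equal(c(res$dir1, res$dir2), c(1, 0), tolerance = 1e-9)

  # a residualized variable is orthogonal to the plane: r2 ~ 0
  v <- rnorm(8)
  v_orth <- residuals(lm(v ~ scores[, 1] + scores[, 2]))
  res <- fit_vectors(scores, cbind(v = v_orth), n_perm = 39, seed = 1)
  expect_lt(res$r2, 1e-10)

  # constant variable: flagged, r2 = 0, p = 1
  res <- fit_vectors(scores, cbind(v = rep(2, 8)), n_perm = 39, seed = 1)
  expect_true(res$constant)
  expect_equal(res$r2, 0)
  expect_equal(res$p, 1)

  # exact p under full enumeration of all 8! orderings
  v <- rnorm(8)
  P <- all_perms(8)
  identity_row <- which(apply(P, 1, function(r) all(r == 1:8)))
  res <- fit_vectors(scores, cbind(v = v),
                     permutations = P[-identity_row, , drop = FALSE])
  # oracle: enumerate r2 over all orderings directly
  r2_of <- function(vv) summary(lm(vv ~ scores[, 1] + scores[, 2]))$r.squared
  r2_all <- apply(P, 1, function(idx) r2_of(v[idx]))
  r2_obs <- r2_of(v)
  expect_equal(res$p, sum(r2_all >= r2_obs - 1e-12) / nrow(P))
})

test_that("null vector-fit p-values are super-uniform", {
  set.seed(36)
  scores <- cbind(rnorm(12), rnorm(12))
  V <- matrix(rnorm(12 * 300), 12)
  res <- fit_vectors(scores, V, n_perm = 99, seed = 7)
  expect_gte(min(res$p), 1 / 100)
  for (t in c(0.05, 0.1, 0.25, 0.5)) {
    emp <- mean(res$p <= t)
    expect_lte(emp, t + 3 * sqrt(t * (1 - t) / 300))
  }
})

test_that("PERMANOVA reduces to classical ANOVA in one dimension", {
  x <- c(1.2, 0.7, 2.1, 3.9, 4.4, 3.1)
  g <- rep(c("oxic", "anoxic"), each = 3)
  md <- data.frame(sample_id = paste0("s", 1:6), fraction = "rna",
                   station = "LF1", redox = g, amendment = "control",
                   replicate = 1:6)
  D <- distance_matrix(as.matrix(dist(x)), md$sample_id)
  P <- all_perms(6)
  identity_row <- which(apply(P, 1, function(r) all(r == 1:6)))
  res <- permanova(D, md, terms = "redox",
                   permutations = P[-identity_row, , drop = FALSE])
  f_classic <- anova(lm(x ~ g))$`F value`[1]
  expect_equal(res$F[1], f_classic, tolerance = 1e-10)

  # exhaustive p over the 20 distinct relabelings of 3 + 3
  f_of <- function(idx) anova(lm(x[idx] ~ g))$`F value`[1]
  f_all <- apply(P, 1, f_of)
  expect_equal(res$p[1], sum(f_all >= f_classic - 1e-12) / nrow(P))
  labelings <- combn(6, 3)
  f_lab <- apply(labelings, 2, function(cols) {
    gg <- rep("b", 6); gg[cols] <- "a"
    anova(lm(x ~ gg))$`F value`[1]
  })
  expect_equal(res$p[1], mean(f_lab >= f_classic - 1e-12))
})

test_that("PERMANOVA agrees with vegan::adonis2 on an unbalanced design", {
  skip_if_not_installed("vegan")
  d <- build_incubation_design(c("LF1", "LF3"), c("oxic", "anoxic"),
                               c("control", "cnp"), 2)
  md <- build_sample_inventory(d, in_situ_reps = c(bulk_dna = 1),
                               whole_cell_total = 5)
  set.seed(37)
  Y <- matrix(rnorm(nrow(md) * 3), ncol = 3)
  D <- distance_matrix(as.matrix(dist(Y)), md$sample_id)
  terms <- c("fraction", "station", "redox", "amendment", "station:redox")
  res <- permanova(D, md, terms = terms, n_perm = 0)
  va <- vegan::adonis2(
    as.dist(unclass(D)) ~ fraction + station + redox + amendment +
      station:redox,
    data = md, permutations = 2, by = "terms")
  expect_equal(res$SS[1:5], va$SumOfSqs[1:5], tolerance = 1e-8)
  expect_equal(res$F[1:5], va$F[1:5], tolerance = 1e-8)
  expect_equal(res$R2[1:5], va$R2[1:5], tolerance = 1e-8)
  expect_equal(res$Df[1:5], va$Df[1:5])
})

test_that("PERMANOVA bookkeeping invariants hold on random inputs", {
  set.seed(38)
  md <- small_metadata()
  for (r in 1:5) {
    Y <- matrix(rnorm(24 * 4), ncol = 4)
    D <- distance_matrix(as.matrix(dist(Y)), md$sample_id)
    res <- permanova(D, md, terms = c("redox", "amendment",
                                      "redox:amendment"), n_perm = 19)
    terms_rows <- seq_len(nrow(res) - 2)
    ss_total <- res$SS[res$term == "Total"]
    expect_equal(sum(res$SS[terms_rows]) + res$SS[res$term == "Residuals"],
                 ss_total, tolerance = 1e-9)
    expect_equal(sum(res$R2[terms_rows]) + res$R2[res$term == "Residuals"],
                 1, tolerance = 1e-9)
    # R2 invariant to translating the underlying coordinates
    D2 <- distance_matrix(as.matrix(dist(Y + 100)), md$sample_id)
    res2 <- permanova(D2, md, terms = c("redox", "amendment",
                                        "redox:amendment"), n_perm = 0)
    expect_equal(res$R2, res2$R2, tolerance = 1e-9)
  }
  # all-zero distances: degenerate, flagged
  D0 <- distance_matrix(matrix(0, 24, 24), md$sample_id)
  res0 <- permanova(D0, md, terms = "redox", n_perm = 9)
  expect_true(attr(res0, "degenerate"))
  expect_equal(res0$SS[res0$term == "Total"], 0)
  expect_true(all(is.na(res0$F)))
})

test_that("one-way ANOVA handles the textbook and degenerate cases", {
  # hand-computed sums of squares for a small 3-group dataset
  v <- c(2, 3, 4, 6, 7, 8, 10, 12, 14)
  g <- rep(c("a", "b", "c"), each = 3)
  grand <- mean(v)
  ssb <- sum(3 * (tapply(v, g, mean) - grand)^2)
  ssw <- sum((v - rep(tapply(v, g, mean), each = 3))^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  res <- group_anova(v, g)
  expect_equal(res$F, f_hand, tolerance = 1e-12)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 6)
  expect_equal(res$p, pf(f_hand, 2, 6, lower.tail = FALSE), tolerance = 1e-12)

  # exact separation: infinite F, flagged
  sep <- group_anova(c(0, 0, 1, 1), c("a", "a", "b", "b"))
  expect_true(is.infinite(sep$F))
  expect_true(sep$exact_separation)
  # all values identical: F = 0 by convention
  expect_equal(group_anova(rep(2, 6), rep(c("a", "b"), 3))$F, 0)

  # under the null, E[F] = df_within / (df_within - 2)
  set.seed(39)
  fs <- replicate(400, group_anova(rnorm(30), rep(c("a", "b"), 15))$F)
  expect_lt(abs(mean(fs) - 28 / 26), 0.15)
})

test_that("pooled t-test matches the hand formula and its symmetries", {
  res <- students_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t, -1 / sqrt(2 / 3), tolerance = 1e-10)  # pooled sd = 1
  expect_equal(res$df, 4)
  swapped <- students_t(c(2, 3, 4), c(1, 2, 3))
  expect_equal(swapped$t, -res$t, tolerance = 1e-12)
  expect_equal(swapped$p, res$p, tolerance = 1e-12)
  same <- students_t(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p, 0.99)
  degen <- students_t(c(2, 2), c(2, 2))
  expect_equal(degen$t, 0)
  expect_equal(degen$p, 1)
  # squared two-group t equals the one-way ANOVA F
  set.seed(40)
  x <- rnorm(7); y <- rnorm(8, 1)
  tt <- students_t(x, y)
  av <- group_anova(c(x, y), rep(c("x", "y"), c(7, 8)))
  expect_equal(tt$t^2, av$F, tolerance = 1e-10)
})
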