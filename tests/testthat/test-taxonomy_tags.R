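stations4 <- c("LF1", "LF1.5", "LF3", "LF5")

test_that("tag propagation follows the per-bin conflict rules", {
  tags <- data.frame(
    lane_id = c("l1", "l2", "l3", "l4", "l5", "l6", "l7"),
    station = c("LF1", "LF1", "LF1", "LF3", "LF3", "LF1", "LF1"),
    bin = c(10, 20, 20, 20, 20, 30, 30),
    tag = c("Firmicutes", "Bacteroidetes", "Bacteroidetes", "Firmicutes",
            "Firmicutes", "Cyanobacteria", "Proteobacteria"),
    stringsAsFactors = FALSE
  )
  lab <- propagate_tags(tags, stations4)
  # one tag anywhere propagates globally
  expect_equal(lab[[10]], list(mode = "global", label = "Firmicutes"))
  # consistent within stations, different across: per-station labels
  expect_equal(lab[[20]]$mode, "per_station")
  expect_equal(unname(lab[[20]]$station_labels[c("LF1", "LF3")]),
               c("Bacteroidetes", "Firmicutes"))
  expect_equal(unname(lab[[20]]$station_labels[c("LF1.5", "LF5")]),
               c("unknown", "unknown"))
  # disagreement within one station: alphabetical double tag
  expect_equal(lab[[30]],
               list(mode = "double", label = "Cyanobacteria/Proteobacteria"))
  # untouched bins are unknown
  expect_equal(lab[[55]]$mode, "unknown")

  expect_error(propagate_tags(transform(tags, bin = c(10, 20, 20, 20, 20,
                                                      30, 200)),
                              stations4), "bin indices")
  expect_error(propagate_tags(transform(tags, station = "X1"), stations4),
               "outside the study")
})

test_that("more than two conflicting tags keep the two most frequent", {
  tags <- data.frame(
    lane_id = paste0("l", 1:6), station = "LF1", bin = 40,
    tag = c("Cyanobacteria", "Cyanobacteria", "Proteobacteria",
            "Proteobacteria", "Firmicutes", "Proteobacteria"),
    stringsAsFactors = FALSE
  )
  lab <- propagate_tags(tags, stations4)
  expect_equal(lab[[40]]$label, "Cyanobacteria/Proteobacteria")
  # frequency tie among three: alphabetical tie-break keeps the first two
  tags2 <- tags[c(1, 3, 5), ]
  lab2 <- propagate_tags(tags2, stations4)
  expect_equal(lab2[[40]]$label, "Cyanobacteria/Firmicutes")
})

test_that("propagation is idempotent under duplicated records", {
  tags <- data.frame(lane_id = c("l1", "l2"), station = c("LF1", "LF3"),
                     bin = c(20, 20),
                     tag = c("Bacteroidetes", "Firmicutes"))
  lab1 <- propagate_tags(tags, stations4)
  lab2 <- propagate_tags(rbind(tags, tags, tags), stations4)
  expect_identical(unclass(lab1), unclass(lab2))
})

test_that("group abundance sums bins and conserves lane mass", {
  # toy 5-bin fingerprint with hand-computed group sums
  fm <- fingerprint_matrix(matrix(c(0.1, 0.2, 0.3, 0.25, 0.15), 1),
                           sample_ids = "s1")
  tags <- data.frame(lane_id = c("s1", "s1", "s1"), station = "LF1",
                     bin = c(1, 2, 3), tag = c("A", "A", "B"))
  lab <- propagate_tags(tags, stations4, n_bins = 5)
  ab <- group_abundance(fm, lab, stations = "LF1")
  expect_equal(unclass(ab)[1, c("A", "B", "unknown")],
               c(A = 0.3, B = 0.3, unknown = 0.4), tolerance = 1e-12)

  # no tags at all: everything is unknown
  ab0 <- group_abundance(fm, propagate_tags(tags[0, ], stations4, 5))
  expect_equal(unname(unclass(ab0)[1, "unknown"]), 1, tolerance = 1e-12)

  # conservation on random fingerprints with random labelings, masked too
  set.seed(41)
  fm <- rand_fingerprint(6, 101, seed = 41)
  tags <- data.frame(
    lane_id = "x", station = sample(stations4, 40, replace = TRUE),
    bin = sample(101, 40, replace = TRUE),
    tag = sample(c("A", "B", "C", "unknown"), 40, replace = TRUE)
  )
  lab <- propagate_tags(tags, stations4)
  sts <- sample(stations4, 6, replace = TRUE)
  for (m in list(fm, mask_bins(fm, c(71, 74)))) {
    ab <- group_abundance(m, lab, stations = sts)
    expect_equal(unname(rowSums(ab)), unname(rowSums(m)), tolerance = 1e-9)
  }

  # per-station labels require sample stations
  expect_error(group_abundance(fm, lab), "stations are required")
})

test_that("class labels roll up to phyla through the mapping table", {
  tags <- data.frame(
    lane_id = c("l1", "l2", "l3", "l4"), station = "LF1",
    bin = c(5, 6, 6, 7),
    tag = c("Alphaproteobacteria", "Alphaproteobacteria",
            "Epsilonproteobacteria", "Bacilli"))
  lab <- propagate_tags(tags, stations4, n_bins = 10)
  cmap <- data.frame(class = c("Alphaproteobacteria", "Epsilonproteobacteria"),
                     phylum = c("Proteobacteria", "Proteobacteria"))
  up <- roll_up_labels(lab, cmap)
  expect_equal(up[[5]]$label, "Proteobacteria")
  # a double class label collapses when both classes share a phylum
  expect_equal(up[[6]], list(mode = "global", label = "Proteobacteria"))
  # unmapped classes fall back to unknown
  expect_equal(up[[7]]$label, "unknown")
})

test_that("group comparisons recover planted effects with high power", {
  md <- small_metadata()
  taxa <- default_community(seed = 99)
  taxa$tag <- NA
  taxa$tag[c(1, 11, 21)] <- "TargetPhylum"
  taxa$tag[c(6, 16, 26)] <- "OtherPhylum"
  hits <- 0
  for (s in 1:100) {
    truth <- simulate_abundances(md, taxa, redox_effects(taxa, 2),
                                 sigma = 0.3, seed = 1000 + s)
    fm <- truth_fingerprint(truth)
    tags <- plant_tags(truth, md, lanes_per_taxon = 1)
    lab <- propagate_tags(tags, unique(md$station))
    ab <- group_abundance(fm, lab, stations = md$station)
    res <- compare_groups(ab, md, "TargetPhylum", "redox")
    if (res$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 90)

  # identical abundances across levels: F = 0
  ab_const <- structure(matrix(0.5, 24, 1, dimnames = list(md$sample_id, "A")),
                        class = "group_abundance")
  expect_equal(compare_groups(ab_const, md, "A", "redox")$F, 0)
  # for a two-level factor, F is the squared pooled t
  set.seed(43)
  ab2 <- structure(matrix(runif(24), 24, 1,
                          dimnames = list(md$sample_id, "A")),
                   class = "group_abundance")
  f <- compare_groups(ab2, md, "A", "redox")$F
  t2 <- students_t(unclass(ab2)[md$redox == "oxic", 1],
                   unclass(ab2)[md$redox == "anoxic", 1])$t^2
  expect_equal(f, t2, tolerance = 1e-10)
  expect_error(compare_groups(ab2, md, "Nope", "redox"), "unknown group")
})
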