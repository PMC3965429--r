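# Independent oracles and small generators shared across tests. These are
# deliberately naive implementations kept separate from the package's own
# code paths.

# Greedy Ward clustering computed directly from coordinates: at each step
# merge the pair of clusters whose union minimally increases the within-
# cluster sum of squares; report heights on the sqrt(2 * delta-ESS) scale.
naive_ward_heights <- function(X) {
  n <- nrow(X)
  members <- lapply(seq_len(n), identity)
  heights <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    k <- length(members)
    best <- Inf; bi <- bj <- NA
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        ci <- colMeans(X[members[[i]], , drop = FALSE])
        cj <- colMeans(X[members[[j]], , drop = FALSE])
        ni <- length(members[[i]]); nj <- length(members[[j]])
        cost <- 2 * ni * nj / (ni + nj) * sum((ci - cj)^2)
        if (cost < best) { best <- cost; bi <- i; bj <- j }
      }
    }
    heights[s] <- sqrt(best)
    members[[bi]] <- c(members[[bi]], members[[bj]])
    members[[bj]] <- NULL
  }
  heights
}

# all permutations of 1..n as an n! x n integer matrix
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, p + (p >= i))
  }))
}

# random compositional fingerprint matrix
rand_fingerprint <- function(n, p = 101, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rexp(n * p), n, p)
  fingerprint_matrix(X / rowSums(X),
                     sample_ids = paste0("s", seq_len(n)))
}

# scaled-down two-factor incubation metadata: 24 samples, one station,
# one fraction, 2 redox x 2 amendment x 6 replicates
small_metadata <- function() {
  md <- expand.grid(replicate = 1:6, amendment = c("control", "cnp"),
                    redox = c("oxic", "anoxic"),
                    stringsAsFactors = FALSE)
  md$fraction <- "bulk_dna"
  md$station <- "LF1"
  md$sample_id <- paste0("s", seq_len(nrow(md)))
  md[, c("sample_id", "fraction", "station", "redox", "amendment",
         "replicate")]
}

# planted redox effects: 3 taxa up, 3 taxa down in the anoxic incubations
redox_effects <- function(taxa, delta) {
  if (delta == 0) return(NULL)
  up <- taxa$taxon_id[c(1, 11, 21)]
  down <- taxa$taxon_id[c(6, 16, 26)]
  data.frame(factor = "redox", level = "anoxic",
             taxon_id = c(up, down),
             delta = rep(c(delta, -delta), each = 3),
             stringsAsFactors = FALSE)
}

# simulate one scaled dataset and run the fingerprint -> FPCA -> distance
# chain; returns the sequential PERMANOVA table for redox + amendment
small_permanova <- function(seed, delta = 0, n_perm = 999) {
  md <- small_metadata()
  taxa <- default_community(seed = 99)
  truth <- simulate_abundances(md, taxa, redox_effects(taxa, delta),
                               sigma = 0.3, seed = seed)
  fm <- truth_fingerprint(truth)
  model <- fit_fpca(fm, lambda = 0, varprop_threshold = 0.9)
  D <- scores_distance(model)
  permanova(D, md, terms = c("redox", "amendment"), n_perm = n_perm,
            seed = seed + 1000L)
}

paper_df_table <- function() {
  data.frame(
    term = c("fraction", "station", "redox", "amendment",
             "fraction:station", "fraction:redox", "station:redox",
             "fraction:amendment", "station:amendment", "redox:amendment",
             "fraction:station:redox", "fraction:station:amendment",
             "fraction:redox:amendment", "station:redox:amendment",
             "fraction:station:redox:amendment"),
    df = c(2, 3, 2, 1, 6, 3, 6, 2, 3, 1, 9, 6, 2, 3, 6),
    stringsAsFactors = FALSE
  )
}
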