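# Independent oracles and small generators used across the suite.
# These deliberately avoid the package's own code paths: the Jaccard oracle
# counts sets pair by pair, and the UPGMA oracle recomputes every
# leaf-pair average from the original distance matrix at every step
# (no Lance-Williams update).

# random binary band matrix with no all-zero rows
rand_band_matrix <- function(n_loci, n_genotypes, p = 0.5) {
  repeat {
    m <- matrix(rbinom(n_loci * n_genotypes, 1, p), n_loci, n_genotypes)
    if (all(rowSums(m) > 0)) break
  }
  dimnames(m) <- list(sprintf("L%02d", seq_len(n_loci)),
                      sprintf("G%02d", seq_len(n_genotypes)))
  band_matrix(m)
}

# pairwise Jaccard by explicit set counting
jaccard_oracle <- function(bm) {
  p <- bm$presence
  n <- ncol(p)
  s <- diag(1, n)
  dimnames(s) <- list(colnames(p), colnames(p))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    a <- sum(p[, i] == 1 & p[, j] == 1)
    b <- sum(p[, i] == 1 & p[, j] == 0)
    cc <- sum(p[, i] == 0 & p[, j] == 1)
    s[i, j] <- s[j, i] <- if (a + b + cc == 0) 0 else a / (a + b + cc)
  }
  s
}

# brute-force UPGMA: clusters as label sets; every step averages all
# leaf-pair distances from the original matrix; same tie-break contract
# (lexicographically smallest member label, then partner label)
upgma_oracle <- function(s) {
  d0 <- 1 - s
  labs <- rownames(s)
  clusters <- as.list(labs)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        dd <- mean(d0[clusters[[i]], clusters[[j]]])
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        better <- is.null(best) || dd < best$d - 1e-12 ||
          (abs(dd - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
                (key[1] == best$key[1] && key[2] < best$key[2])))
        if (better) best <- list(i = i, j = j, d = dd, key = key)
      }
    }
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    heights <- c(heights, best$d)
    partitions <- c(partitions, list(sort(merged)))
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  list(heights = heights, partitions = partitions)
}

# leaf sets of all internal nodes of an upgma_tree, each sorted
tree_partitions <- function(tree) {
  members <- list()
  get <- function(v) if (v < 0) tree$labels[-v] else members[[v]]
  for (k in seq_len(nrow(tree$merge)))
    members[[k]] <- sort(c(get(tree$merge[k, 1]), get(tree$merge[k, 2])))
  members
}

# canonical form of a partition (list of leaf sets) for comparison
canon_partition <- function(parts) {
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, min, character(1)))]
}

# printed 3-decimal similarity tables, read from the packaged fixtures
printed_table5 <- function()
  read_similarity(bg_fixture_path("protein_table5_similarity"))
printed_table9 <- function()
  read_similarity(bg_fixture_path("pooled_table9_similarity"))
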