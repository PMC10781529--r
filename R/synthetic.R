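#' Specify a synthetic dominant-marker band matrix
#'
#' Describes a band matrix to simulate: genotypes, bands grouped under
#' primers, a presence-frequency law, optional planted genotype clusters
#' and optional planted unique (genotype-specific) bands. The generator
#' emulates scored gel data — bands grouped by primer with heterogeneous
#' presence frequencies — so every pipeline stage can be exercised against
#' a known truth.
#'
#' @param n_genotypes number of genotypes (>= 1; >= 2 for planted unique
#'   bands, >= number of cluster blocks for a cluster plan).
#' @param groups named integer vector: band count per primer/group.
#' @param freq presence-probability law per band: a single probability, or
#'   a length-2 vector `c(lo, hi)` for independent uniform draws per band.
#' @param clusters optional cluster plan: a list with `blocks` (a partition
#'   of genotype indices or labels into >= 2 blocks) and `delta`, the
#'   per-band probability in \[0, 1\] that a member's score flips away from
#'   its block's template profile (gel scoring dropout/ghost bands).
#' @param n_unique_pos,n_unique_neg number of planted unique-positive /
#'   unique-negative bands, appended as a dedicated `"planted"` group with
#'   randomly chosen carrier genotypes.
#' @param labels genotype labels (default `G1..Gn`).
#' @param seed integer seed governing all randomness of [generate_bands()]
#'   and [planted_truth()].
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_genotypes, groups, freq = c(0.2, 0.8),
                       clusters = NULL, n_unique_pos = 0, n_unique_neg = 0,
                       labels = paste0("G", seq_len(n_genotypes)),
                       seed = 1L) {
  stopifnot(n_genotypes >= 1, length(groups) >= 1, all(groups >= 1))
  if (is.null(names(groups))) names(groups) <- paste0("P", seq_along(groups))
  if (!length(freq) %in% 1:2 || any(freq < 0 | freq > 1))
    stop("freq must be one probability or c(lo, hi) within [0, 1]")
  if ((n_unique_pos > 0 || n_unique_neg > 0) && n_genotypes < 2)
    stop("planted unique bands need at least 2 genotypes")
  if (!is.null(clusters)) {
    if (!is.list(clusters) || is.null(clusters$blocks) ||
        is.null(clusters$delta))
      stop("clusters must be list(blocks = ..., delta = ...)")
    if (clusters$delta < 0 || clusters$delta > 1)
      stop("delta must be in [0, 1]")
    blocks <- lapply(clusters$blocks, function(b)
      if (is.character(b)) match(b, labels) else as.integer(b))
    idx <- sort(unlist(blocks))
    if (!identical(idx, seq_len(n_genotypes)))
      stop("cluster blocks must partition the genotypes")
    clusters$blocks <- blocks
  }
  structure(list(n_genotypes = as.integer(n_genotypes), groups = groups,
                 freq = freq, clusters = clusters,
                 n_unique_pos = as.integer(n_unique_pos),
                 n_unique_neg = as.integer(n_unique_neg),
                 labels = labels, seed = as.integer(seed)),
            class = "synth_spec")
}

# Randomness stream order (stable contract, do not reorder):
#   1. carriers of planted unique-positive bands
#   2. carriers of planted unique-negative bands
#   3. per-band presence probabilities
#   4. templates / presence draws, then per-member flips, band by band
#   5. resampling of all-zero rows
draw_carriers <- function(spec) {
  set.seed(spec$seed)
  list(pos = if (spec$n_unique_pos)
         sample.int(spec$n_genotypes, spec$n_unique_pos, replace = TRUE)
       else integer(0),
       neg = if (spec$n_unique_neg)
         sample.int(spec$n_genotypes, spec$n_unique_neg, replace = TRUE)
       else integer(0))
}

#' Generate a synthetic band matrix
#'
#' Draws a [band_matrix()] from a [synth_spec()]. Without a cluster plan,
#' each band's presence is independent Bernoulli per genotype at the band's
#' frequency. With a cluster plan, each block gets a Bernoulli template
#' score per band and members deviate from it independently with
#' probability `delta`. All-zero band rows (never-observed bands) are
#' redrawn; a band still empty after 100 redraws is given a single random
#' carrier. Planted unique bands occupy a final `"planted"` group and are
#' present in (or absent from) exactly their carrier genotype. The result
#' is a deterministic function of the spec, including its seed.
#'
#' @param spec a [synth_spec()].
#' @return a `band_matrix` with `sum(groups) + n_unique_pos + n_unique_neg`
#'   loci; synthetic band sizes (bp) are attached so summaries print.
#' @export
#' @examples
#' spec <- synth_spec(6, c(A = 5, B = 5), freq = 0.5, seed = 42)
#' identical(generate_bands(spec)$presence, generate_bands(spec)$presence)
generate_bands <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  carriers <- draw_carriers(spec)     # seeds the stream (steps 1-2)
  n <- spec$n_genotypes
  n_core <- sum(spec$groups)
  p_band <- if (length(spec$freq) == 1) rep(spec$freq, n_core) else
    stats::runif(n_core, spec$freq[1], spec$freq[2])
  draw_row <- function(p) {
    if (is.null(spec$clusters)) {
      stats::rbinom(n, 1L, p)
    } else {
      row <- integer(n)
      for (b in spec$clusters$blocks) {
        tmpl <- stats::rbinom(1L, 1L, p)
        flip <- stats::rbinom(length(b), 1L, spec$clusters$delta)
        row[b] <- ifelse(flip == 1L, 1L - tmpl, tmpl)
      }
      row
    }
  }
  presence <- matrix(0L, n_core, n)
  for (i in seq_len(n_core)) {
    row <- draw_row(p_band[i])
    tries <- 0L
    while (sum(row) == 0L && tries < 100L) {
      row <- draw_row(p_band[i])
      tries <- tries + 1L
    }
    if (sum(row) == 0L) row[sample.int(n, 1L)] <- 1L
    presence[i, ] <- row
  }
  group <- rep(names(spec$groups), spec$groups)
  if (spec$n_unique_pos) {
    for (g in carriers$pos) {
      row <- integer(n); row[g] <- 1L
      presence <- rbind(presence, row)
      group <- c(group, "planted")
    }
  }
  if (spec$n_unique_neg) {
    for (g in carriers$neg) {
      row <- rep(1L, n); row[g] <- 0L
      presence <- rbind(presence, row)
      group <- c(group, "planted")
    }
  }
  ids <- sprintf("L%03d", seq_len(nrow(presence)))
  dimnames(presence) <- list(ids, spec$labels)
  loci <- data.frame(locus_id = ids, assay = "scot", group = group,
                     size = 100 + 10 * seq_len(nrow(presence)),
                     stringsAsFactors = FALSE)
  band_matrix(presence = presence, loci = loci)
}

#' Planted truth of a synthetic spec
#'
#' Returns what [generate_bands()] planted, for comparison with pipeline
#' output: the cluster partition (the trivial one-block partition when no
#' plan was given) and the planted unique-marker table in the same layout
#' as [genotype_specific_markers()].
#'
#' @param spec a [synth_spec()].
#' @return list with `partition` (list of genotype-label vectors) and
#'   `markers` (data frame `genotype`, `polarity`).
#' @export
planted_truth <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  carriers <- draw_carriers(spec)
  partition <- if (is.null(spec$clusters)) list(sort(spec$labels)) else
    lapply(spec$clusters$blocks, function(b) sort(spec$labels[b]))
  partition <- partition[order(vapply(partition, min, character(1)))]
  markers <- data.frame(
    genotype = spec$labels[c(carriers$pos, carriers$neg)],
    polarity = rep(c("positive", "negative"),
                   c(spec$n_unique_pos, spec$n_unique_neg)),
    stringsAsFactors = FALSE)
  list(partition = partition, markers = markers)
}
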