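#' UPGMA clustering of a similarity matrix
#'
#' Unweighted pair-group method with arithmetic mean, the standard
#' agglomerative algorithm for dominant-marker similarity matrices.
#' Similarities are converted to distances d = 1 - s; at each step the two
#' clusters with the smallest average inter-cluster distance are merged,
#' the average being taken over all leaf pairs (i.e. size-weighted in the
#' Lance-Williams update — UPGMA proper, not WPGMA). The recorded merge
#' height is that average leaf-pair distance; under the ultrametric
#' branch-length convention each merged node sits at depth height/2 from
#' its leaves (see [to_newick()]).
#'
#' Ties (two candidate pairs at the same minimal distance, common with
#' 3-decimal printed similarity tables) are broken deterministically: the
#' pair whose lexicographically smallest leaf label is first wins, then the
#' smaller partner label.
#'
#' @param s symmetric similarity matrix with unit diagonal and values in
#'   \[0, 1\], as from [band_similarity()] or [read_similarity()].
#' @return an object of class `upgma_tree`: list with `labels` (leaf
#'   labels in input order), `merge` (n-1 x 2 matrix, negative entries are
#'   leaves, positive entries earlier merges, as in [stats::hclust()]), and
#'   `height` (average leaf-pair distance at each merge, non-decreasing).
#' @seealso [to_newick()], [cut_clusters()], [stats::cophenetic()]
#' @export
#' @examples
#' s <- matrix(c(1, .8, .4, .8, 1, .4, .4, .4, 1), 3, 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' tr <- upgma(s)
#' tr$height        # 0.2, 0.6
#' to_newick(tr)
upgma <- function(s) {
  s <- validate_similarity(s)
  n <- nrow(s)
  if (n < 2L) stop("need at least 2 genotypes to cluster")
  labels <- rownames(s)
  d <- 1 - s
  diag(d) <- Inf
  # active clusters: id (negative leaf / positive merge), size, min label
  id <- -seq_len(n)
  size <- rep(1L, n)
  minlab <- labels
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(id)
    dmin <- min(d)
    best <- NULL
    for (i in seq_len(m - 1L)) for (j in seq(i + 1L, m)) {
      if (d[i, j] <= dmin + 1e-12) {
        key <- sort(c(minlab[i], minlab[j]))
        if (is.null(best) || key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2]))
          best <- list(i = i, j = j, key = key)
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- d[i, j]
    # size-weighted average distance from the new cluster to the rest
    newd <- (size[i] * d[i, ] + size[j] * d[j, ]) / (size[i] + size[j])
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], Inf))
    id <- c(id[keep], step)
    size <- c(size[keep], size[i] + size[j])
    minlab <- c(minlab[keep], min(minlab[i], minlab[j]))
  }
  if (any(diff(height) < -1e-9))
    stop("internal error: UPGMA produced non-monotone merge heights")
  structure(list(labels = labels, merge = merge, height = height,
                 method = "upgma"), class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("UPGMA tree: %d leaves, root height %.4f (depth %.4f)\n",
              length(x$labels), max(x$height), max(x$height) / 2))
  cat(" ", to_newick(x), "\n")
  invisible(x)
}

# leaf label sets of every internal node, in merge order
node_members <- function(tree) {
  members <- vector("list", nrow(tree$merge))
  get <- function(v) if (v < 0) tree$labels[-v] else members[[v]]
  for (k in seq_len(nrow(tree$merge)))
    members[[k]] <- c(get(tree$merge[k, 1]), get(tree$merge[k, 2]))
  members
}

#' Serialize an UPGMA tree as Newick text
#'
#' Branch lengths follow the ultrametric convention: a node merged at
#' height h sits at depth h/2 from its leaves, so every root-to-leaf path
#' has length (root height)/2. Child order is deterministic: the subtree
#' containing the lexicographically smallest leaf comes first.
#'
#' @param tree an [upgma()] tree.
#' @param digits significant digits for branch lengths.
#' @return a Newick string (terminated by `;`) parseable by standard tree
#'   readers such as `ape::read.tree`.
#' @export
to_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "upgma_tree"))
  fmt <- function(x) format(x, digits = digits, scientific = FALSE,
                            trim = TRUE)
  members <- node_members(tree)
  rec <- function(v, parent_depth) {
    if (v < 0) {
      lab <- tree$labels[-v]
      return(list(str = paste0(lab, ":", fmt(parent_depth)), min = lab))
    }
    depth <- tree$height[v] / 2
    ch <- lapply(tree$merge[v, ], rec, parent_depth = depth)
    if (ch[[2]]$min < ch[[1]]$min) ch <- ch[c(2, 1)]
    list(str = paste0("(", ch[[1]]$str, ",", ch[[2]]$str, "):",
                      fmt(parent_depth - depth)),
         min = min(ch[[1]]$min, ch[[2]]$min))
  }
  root <- nrow(tree$merge)
  depth <- tree$height[root] / 2
  ch <- lapply(tree$merge[root, ], rec, parent_depth = depth)
  if (ch[[2]]$min < ch[[1]]$min) ch <- ch[c(2, 1)]
  paste0("(", ch[[1]]$str, ",", ch[[2]]$str, ");")
}

#' Cophenetic distances of an UPGMA tree
#'
#' The cophenetic distance between two leaves is the merge height at which
#' they first join a common cluster. The resulting matrix is ultrametric:
#' for any triple, the largest of the three distances is attained at least
#' twice. When the input distances 1 - s are themselves ultrametric, UPGMA
#' is exact and the cophenetic matrix reproduces them.
#'
#' @param x an [upgma()] tree.
#' @return a symmetric numeric matrix of cophenetic distances with zero
#'   diagonal.
#' @export
#' @method cophenetic upgma_tree
#' @importFrom stats cophenetic as.hclust
cophenetic.upgma_tree <- function(x) {
  n <- length(x$labels)
  out <- matrix(0, n, n, dimnames = list(x$labels, x$labels))
  members <- node_members(x)
  get <- function(v) if (v < 0) x$labels[-v] else members[[v]]
  for (k in seq_len(nrow(x$merge))) {
    left <- get(x$merge[k, 1]); right <- get(x$merge[k, 2])
    out[left, right] <- x$height[k]
    out[right, left] <- x$height[k]
  }
  out
}

#' Cut an UPGMA tree into k clusters
#'
#' Removes the k - 1 highest merges and returns the resulting leaf sets.
#'
#' @param tree an [upgma()] tree.
#' @param k number of clusters, between 1 and the leaf count.
#' @return a list of `k` character vectors of leaf labels, ordered by each
#'   cluster's smallest label; labels within a cluster are sorted.
#' @export
cut_clusters <- function(tree, k) {
  stopifnot(inherits(tree, "upgma_tree"))
  n <- length(tree$labels)
  if (!(k >= 1 && k <= n)) stop("k must be between 1 and ", n)
  keep <- seq_len(n - k)              # merges retained (lowest n-k)
  grp <- seq_len(n)                   # leaf -> cluster id
  members <- node_members(tree)
  for (m in keep) {
    mem <- match(members[[m]], tree$labels)
    grp[grp %in% grp[mem]] <- min(grp[mem])
  }
  parts <- split(tree$labels, grp)
  parts <- lapply(parts, function(v) sort(v))
  parts <- unname(parts[order(vapply(parts, min, character(1)))])
  parts
}

#' @export
as.hclust.upgma_tree <- function(x, ...) {
  members <- node_members(x)
  order <- match(members[[length(members)]], x$labels)
  structure(list(merge = x$merge, height = x$height, order = order,
                 labels = x$labels, method = "average",
                 call = match.call(), dist.method = "1 - similarity"),
            class = "hclust")
}
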