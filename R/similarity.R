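#' Pairwise genotype similarity from binary band data
#'
#' Computes a symmetric genotype-by-genotype similarity matrix from a band
#' matrix under one of three binary coefficients. With, for a genotype pair,
#' a = bands present in both, b = bands present only in the first,
#' c = only in the second and d = bands absent from both:
#' \describe{
#'   \item{jaccard}{a / (a + b + c) — shared absences carry no information
#'     about relatedness of dominant-marker profiles and are ignored.}
#'   \item{dice}{2a / (2a + b + c).}
#'   \item{simple_matching}{(a + d) / (a + b + c + d).}
#' }
#' A pair with an empty union (a + b + c = 0, possible only if both
#' genotypes carry no band) is assigned similarity 0 under jaccard/dice,
#' with a warning; the case cannot arise from a valid single band matrix
#' (no all-zero locus rows) but is defined for completeness.
#'
#' @param x a [band_matrix()]; intensity grades, if any, are collapsed
#'   first.
#' @param method one of `"jaccard"`, `"dice"`, `"simple_matching"`.
#' @return a symmetric numeric matrix with unit diagonal and the genotype
#'   labels as dimnames.
#' @export
#' @examples
#' m <- matrix(c(1, 1, 1, 0, 0, 1), 3, 2,
#'             dimnames = list(paste0("b", 1:3), c("G1", "G2")))
#' band_similarity(band_matrix(m))            # Jaccard: 1/3
#' band_similarity(band_matrix(m), "dice")    # 1/2
band_similarity <- function(x, method = c("jaccard", "dice",
                                          "simple_matching")) {
  method <- match.arg(method)
  validate_band_matrix(x)
  x <- collapse_intensity(x)
  p <- x$presence
  n <- ncol(p)
  if (n < 2L) stop("similarity needs at least 2 genotypes")
  a <- crossprod(p)                 # shared presences
  tot <- diag(a)                    # per-genotype band counts
  b <- matrix(tot, n, n) - a        # presences only in row genotype
  cc <- t(b)
  d <- nrow(p) - a - b - cc
  s <- switch(method,
    jaccard = {
      u <- a + b + cc
      if (any(u == 0)) warning("band-free genotype pair; similarity set to 0")
      out <- ifelse(u == 0, 0, a / u)
      diag(out) <- 1
      out
    },
    dice = {
      u <- 2 * a + b + cc
      if (any(u == 0)) warning("band-free genotype pair; similarity set to 0")
      out <- ifelse(u == 0, 0, 2 * a / u)
      diag(out) <- 1
      out
    },
    simple_matching = (a + d) / nrow(p))
  dimnames(s) <- list(colnames(p), colnames(p))
  s
}

#' @rdname band_similarity
#' @export
jaccard_similarity <- function(x) band_similarity(x, "jaccard")

validate_similarity <- function(s) {
  s <- as.matrix(s)
  if (nrow(s) != ncol(s)) stop("similarity matrix must be square")
  if (is.null(rownames(s))) stop("similarity matrix must be labelled")
  if (!isTRUE(all.equal(s, t(s), tolerance = 1e-8)))
    stop("similarity matrix must be symmetric")
  if (any(s < -1e-12 | s > 1 + 1e-12)) stop("similarity values outside [0, 1]")
  if (any(abs(diag(s) - 1) > 1e-9)) stop("similarity diagonal must be 1")
  s
}

#' Extremes of a similarity matrix
#'
#' Reports the minimum and maximum off-diagonal similarity and every
#' genotype pair attaining them (ties reported exhaustively).
#'
#' @param s a symmetric similarity matrix with unit diagonal, e.g. from
#'   [band_similarity()].
#' @param tol tie tolerance when matching the extreme values.
#' @return a list with `min`, `min_pairs` (data frame `g1`, `g2`), `max`,
#'   `max_pairs`.
#' @export
similarity_report <- function(s, tol = 1e-9) {
  s <- validate_similarity(s)
  n <- nrow(s)
  if (n < 2L) stop("need at least 2 genotypes")
  labs <- rownames(s)
  ij <- which(upper.tri(s), arr.ind = TRUE)
  vals <- s[upper.tri(s)]
  pairs_at <- function(v) {
    k <- which(abs(vals - v) <= tol)
    data.frame(g1 = labs[ij[k, 1]], g2 = labs[ij[k, 2]],
               stringsAsFactors = FALSE)
  }
  list(min = min(vals), min_pairs = pairs_at(min(vals)),
       max = max(vals), max_pairs = pairs_at(max(vals)))
}

#' Write a similarity matrix as delimited text
#'
#' @param s similarity matrix.
#' @param path output file.
#' @param lower if `TRUE` (default) write the lower triangle including the
#'   diagonal, upper cells empty, as such matrices are conventionally
#'   printed; otherwise the full square matrix.
#' @param digits decimals (default 3, half-up as printed), or `NULL` for
#'   full precision.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(s, path, lower = TRUE, digits = 3, sep = ",") {
  s <- validate_similarity(s)
  out <- if (is.null(digits)) s else round_half_up(s, digits)
  out <- format(out, trim = TRUE, digits = 15)
  if (lower) out[upper.tri(out)] <- ""
  df <- cbind(data.frame(genotype = rownames(s), stringsAsFactors = FALSE),
              as.data.frame(out, check.names = FALSE))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a similarity matrix from delimited text
#'
#' Accepts full square or lower-triangular layouts (empty upper cells are
#' mirrored from the lower triangle), with a leading genotype-label column
#' and a header row.
#'
#' @param path file to read.
#' @return a symmetric similarity matrix.
#' @export
read_similarity <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  labs <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(m), labs))
    stop("similarity file header does not match genotype column: ", path)
  m[m == ""] <- NA
  s <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = list(labs, labs))
  up <- upper.tri(s)
  s[up][is.na(s[up])] <- t(s)[up][is.na(s[up])]
  validate_similarity(s)
}

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero, matching how
#' similarity tables are conventionally printed (base [round()] rounds half
#' to even). Used at the reporting boundary when comparing against printed
#' 3-decimal tables.
#'
#' @param x numeric vector or matrix.
#' @param digits decimals to keep.
#' @return `x` rounded.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
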