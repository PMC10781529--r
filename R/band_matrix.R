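#' Construct a band matrix
#'
#' A `band_matrix` holds a binary presence/absence scoring of electrophoretic
#' bands (loci) across a set of genotypes, together with per-locus metadata:
#' the assay that produced the band (`protein`, `isozyme` or `scot`), the
#' group it belongs to (a SCoT primer, an isozyme system such as POD, or the
#' gel system e.g. "SDS-PAGE") and a band size. Band size is a molecular
#' weight in kDa for proteins, a fragment length in bp for SCoT amplicons,
#' or a relative mobility (Rm, a fraction in \[0, 1\]) for isozymes.
#'
#' An optional intensity grid carries staining-density grades 0-3
#' (absent / + / ++ / +++). Grades are metadata: all downstream statistics
#' use presence only (see [collapse_intensity()]).
#'
#' @param presence numeric or integer matrix of 0/1, loci in rows and
#'   genotypes in columns. Row names are locus ids, column names genotype
#'   labels (both required and unique).
#' @param loci data frame with one row per locus and columns `locus_id`,
#'   `assay`, `group`, `size`. May be omitted when `presence` has row names,
#'   in which case a minimal metadata frame is built with `assay` and
#'   `group` set to `"unknown"` and `size` `NA`.
#' @param intensity optional matrix of grades in 0-3, same shape and
#'   dimnames as `presence`; must satisfy `intensity > 0` exactly where
#'   `presence == 1`.
#'
#' @return An object of class `band_matrix`: a list with elements
#'   `presence` (integer matrix), `loci` (data frame) and `intensity`
#'   (matrix or `NULL`).
#'
#' @details Loci observed in no genotype (all-zero rows) are rejected: a
#'   band that was never seen on a gel is not a locus. Entries outside
#'   \{0, 1\} (or grades outside 0-3) are rejected with the offending
#'   row/column named.
#'
#' @seealso [read_band_matrix()], [pool_bands()], [locus_stats()]
#' @export
#' @examples
#' m <- matrix(c(1, 1, 1, 0), 2, 2,
#'             dimnames = list(c("b1", "b2"), c("G1", "G2")))
#' bm <- band_matrix(m)
#' n_loci(bm)
band_matrix <- function(presence, loci = NULL, intensity = NULL) {
  presence <- as.matrix(presence)
  if (is.null(rownames(presence)) || is.null(colnames(presence)))
    stop("presence matrix must have locus row names and genotype column names")
  storage.mode(presence) <- "integer"
  if (is.null(loci)) {
    loci <- data.frame(locus_id = rownames(presence),
                       assay = "unknown", group = "unknown",
                       size = NA_real_, stringsAsFactors = FALSE)
  }
  if (!is.null(intensity)) {
    intensity <- as.matrix(intensity)
    storage.mode(intensity) <- "integer"
  }
  x <- structure(list(presence = presence, loci = loci, intensity = intensity),
                 class = "band_matrix")
  validate_band_matrix(x)
  x
}

#' Validate a band matrix
#'
#' Checks the structural invariants of a [band_matrix()]: binary entries,
#' unique genotype and locus labels, metadata aligned with the presence
#' grid, per-assay size ranges (Rm in \[0,1\], kDa/bp positive), no
#' all-zero locus rows, and intensity/presence consistency.
#'
#' @param x a `band_matrix`.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_band_matrix <- function(x) {
  if (!inherits(x, "band_matrix")) stop("not a band_matrix")
  p <- x$presence
  if (ncol(p) < 1L) stop("band matrix has no genotypes")
  if (nrow(p) < 1L) stop("band matrix has no loci")
  if (anyDuplicated(colnames(p)))
    stop("duplicate genotype labels: ",
         paste(unique(colnames(p)[duplicated(colnames(p))]), collapse = ", "))
  if (anyDuplicated(rownames(p)))
    stop("duplicate locus ids: ",
         paste(unique(rownames(p)[duplicated(rownames(p))]), collapse = ", "))
  bad <- which(!(p %in% c(0L, 1L)))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(p)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(p)) + 1L
    stop(sprintf("non-binary presence entry at locus '%s', genotype '%s'",
                 rownames(p)[i], colnames(p)[j]))
  }
  zero <- rowSums(p) == 0L
  if (any(zero))
    stop("all-zero locus rows (a band never observed is not a locus): ",
         paste(rownames(p)[zero], collapse = ", "))
  lo <- x$loci
  need <- c("locus_id", "assay", "group", "size")
  if (!all(need %in% names(lo)))
    stop("loci metadata must have columns: ", paste(need, collapse = ", "))
  if (nrow(lo) != nrow(p) || !identical(as.character(lo$locus_id), rownames(p)))
    stop("loci metadata rows do not match presence row names")
  sz <- lo$size
  rm_bad <- lo$assay == "isozyme" & !is.na(sz) & (sz < 0 | sz > 1)
  if (any(rm_bad))
    stop("isozyme Rm outside [0,1] for: ",
         paste(lo$locus_id[rm_bad], collapse = ", "))
  pos_bad <- lo$assay %in% c("protein", "scot") & !is.na(sz) & sz <= 0
  if (any(pos_bad))
    stop("non-positive band size for: ",
         paste(lo$locus_id[pos_bad], collapse = ", "))
  if (!is.null(x$intensity)) {
    g <- x$intensity
    if (!identical(dim(g), dim(p)) || !identical(dimnames(g), dimnames(p)))
      stop("intensity grid does not match presence grid")
    if (any(!(g %in% 0:3)))
      stop("intensity grades must be integers in 0-3")
    if (any((g > 0L) != (p == 1L)))
      stop("intensity > 0 must coincide exactly with presence = 1")
  }
  invisible(x)
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf("band_matrix: %d loci x %d genotypes\n",
              nrow(x$presence), ncol(x$presence)))
  tab <- table(x$loci$assay)
  cat("  assays: ",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  cat("  groups: ", paste(unique(x$loci$group), collapse = ", "), "\n")
  if (!is.null(x$intensity)) cat("  intensity grades: present\n")
  invisible(x)
}

#' @rdname band_matrix
#' @export
n_loci <- function(x) nrow(x$presence)

#' @rdname band_matrix
#' @export
n_genotypes <- function(x) ncol(x$presence)

#' @rdname band_matrix
#' @export
genotypes <- function(x) colnames(x$presence)

#' Read a band matrix from delimited text
#'
#' The dialect is one row per locus with metadata columns
#' `locus_id, assay, group, size` followed by one column per genotype, and a
#' header row naming the genotypes. Comma or tab separation is auto-detected
#' from the header line.
#'
#' @param path file to read.
#' @param intensity if `TRUE`, genotype entries are staining grades 0-3;
#'   presence is derived as `grade > 0` and the grades kept. If `FALSE`
#'   entries must be 0/1.
#' @return a validated [band_matrix()].
#' @export
read_band_matrix <- function(path, intensity = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("locus_id", "assay", "group", "size")
  if (!all(meta_cols %in% names(df)[1:4]))
    stop("malformed band matrix file '", path,
         "': first four columns must be ", paste(meta_cols, collapse = ", "))
  gcols <- setdiff(names(df), meta_cols)
  if (!length(gcols)) stop("no genotype columns in ", path)
  grid <- as.matrix(df[, gcols, drop = FALSE])
  if (!is.numeric(grid)) {
    bad <- gcols[!vapply(df[gcols], is.numeric, logical(1))][1]
    stop("non-numeric entries in genotype column '", bad, "' of ", path)
  }
  dimnames(grid) <- list(df$locus_id, gcols)
  loci <- data.frame(locus_id = as.character(df$locus_id),
                     assay = df$assay, group = as.character(df$group),
                     size = as.numeric(df$size), stringsAsFactors = FALSE)
  if (intensity) {
    band_matrix(presence = (grid > 0) * 1L, loci = loci, intensity = grid)
  } else {
    band_matrix(presence = grid, loci = loci)
  }
}

#' Write a band matrix to delimited text
#'
#' Emits the same dialect [read_band_matrix()] reads: metadata columns then
#' genotype columns in stored order, so write-then-read is the identity.
#' When the matrix carries intensity grades they are written in place of the
#' 0/1 entries (re-read with `intensity = TRUE`).
#'
#' @param x a `band_matrix`.
#' @param path output file.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_band_matrix <- function(x, path, sep = ",") {
  validate_band_matrix(x)
  grid <- if (!is.null(x$intensity)) x$intensity else x$presence
  df <- cbind(x$loci[, c("locus_id", "assay", "group", "size")],
              as.data.frame(grid, check.names = FALSE))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse intensity grades to presence/absence
#'
#' Staining-density grades (+/++/+++, coded 1-3) are recorded from native
#' gels but similarity and polymorphism statistics are defined on presence
#' only; this maps any grade >= 1 to presence 1 and drops the grade grid.
#' Idempotent: an already-binary matrix is returned unchanged.
#'
#' @param x a `band_matrix`.
#' @return a `band_matrix` without intensity grades.
#' @export
collapse_intensity <- function(x) {
  validate_band_matrix(x)
  if (is.null(x$intensity)) return(x)
  band_matrix(presence = (x$intensity > 0L) * 1L, loci = x$loci)
}

#' Pool band matrices across assays
#'
#' Concatenates the loci of several band matrices scored on the same
#' genotypes, e.g. to combine protein and isozyme data before computing a
#' pooled similarity matrix. Genotypes are aligned by label (input column
#' order may differ); the output genotype order is that of the first
#' matrix. Assay and group metadata are preserved. Matrices with intensity
#' grades are collapsed to presence first.
#'
#' @param ... `band_matrix` objects, or a single list of them.
#' @return a `band_matrix` with `sum(n_loci)` loci.
#' @export
#' @examples
#' m1 <- band_matrix(matrix(1L, 1, 2, dimnames = list("a", c("G1", "G2"))))
#' m2 <- band_matrix(matrix(c(1L, 0L), 1, 2,
#'                          dimnames = list("b", c("G2", "G1"))))
#' n_loci(pool_bands(m1, m2))
pool_bands <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && !inherits(mats[[1]], "band_matrix"))
    mats <- mats[[1]]
  if (!length(mats)) stop("no matrices to pool")
  lapply(mats, validate_band_matrix)
  mats <- lapply(mats, collapse_intensity)
  ref <- genotypes(mats[[1]])
  for (i in seq_along(mats)) {
    g <- genotypes(mats[[i]])
    if (!setequal(g, ref)) {
      only_ref <- setdiff(ref, g)
      only_i <- setdiff(g, ref)
      stop(sprintf(
        "genotype sets differ between matrix 1 and matrix %d (%s%s)", i,
        if (length(only_ref)) paste0("missing: ",
                                     paste(only_ref, collapse = ", ")) else "",
        if (length(only_i)) paste0(" extra: ",
                                   paste(only_i, collapse = ", ")) else ""))
    }
  }
  presence <- do.call(rbind, lapply(mats, function(m)
    m$presence[, ref, drop = FALSE]))
  loci <- do.call(rbind, lapply(mats, function(m) m$loci))
  rownames(loci) <- NULL
  if (anyDuplicated(loci$locus_id)) {
    # disambiguate ids colliding across assays (e.g. two "band1" rows)
    loci$locus_id <- make.unique(as.character(loci$locus_id), sep = "_")
    rownames(presence) <- loci$locus_id
  }
  band_matrix(presence = presence, loci = loci)
}
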