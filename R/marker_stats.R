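#' Per-locus polymorphism statistics
#'
#' For each locus computes the band frequency p (fraction of genotypes
#' carrying the band), its polymorphism class, its contribution to the
#' dominant-marker polymorphism information content, and its band
#' informativeness.
#'
#' Classes: a band present in every genotype is `monomorphic`; any other
#' band is `polymorphic`. Two polymorphic subclasses are flagged because
#' they fingerprint individual genotypes: `unique_positive` (present in
#' exactly one genotype, an M+ marker) and `unique_negative` (absent from
#' exactly one genotype, an M- marker). For counting purposes the unique
#' classes are polymorphic.
#'
#' Per band, `pic_locus = 2 p (1 - p)` (the dominant-marker PIC term, at
#' most 0.5, attained at p = 0.5) and `ib = 1 - 2|0.5 - p|` (band
#' informativeness, the summand of resolving power).
#'
#' @param x a [band_matrix()].
#' @return data frame with columns `locus_id`, `assay`, `group`, `size`,
#'   `n_present`, `p`, `klass`, `pic_locus`, `ib`.
#' @export
#' @examples
#' m <- matrix(c(1, 1, 1, 0), 2, 2,
#'             dimnames = list(c("b1", "b2"), c("G1", "G2")))
#' locus_stats(band_matrix(m))
locus_stats <- function(x) {
  validate_band_matrix(x)
  x <- collapse_intensity(x)
  n <- n_genotypes(x)
  cnt <- rowSums(x$presence)
  p <- cnt / n
  klass <- ifelse(cnt == n, "monomorphic",
           ifelse(cnt == 1L & n > 1L, "unique_positive",
           ifelse(cnt == n - 1L & n > 1L, "unique_negative", "polymorphic")))
  data.frame(locus_id = x$loci$locus_id, assay = x$loci$assay,
             group = x$loci$group, size = x$loci$size,
             n_present = as.integer(cnt), p = p, klass = klass,
             pic_locus = 2 * p * (1 - p), ib = 1 - 2 * abs(0.5 - p),
             stringsAsFactors = FALSE, row.names = NULL)
}

is_polymorphic <- function(klass) klass != "monomorphic"

#' Percentage of polymorphic loci
#'
#' 100 * (polymorphic loci) / (total loci), overall or per group (primer or
#' enzyme). Unique positive/negative bands count as polymorphic. Values are
#' reported rounded to 2 decimals; set `digits = NULL` for unrounded.
#'
#' @param x a [band_matrix()].
#' @param by_group if `TRUE`, return a named vector with one percentage per
#'   locus group.
#' @param digits decimals for reporting (default 2), or `NULL`.
#' @return a percentage, or a named vector of percentages.
#' @export
polymorphism_percent <- function(x, by_group = FALSE, digits = 2) {
  ls <- locus_stats(x)
  pct <- function(k) 100 * sum(is_polymorphic(k)) / length(k)
  out <- if (by_group) {
    vapply(split(ls$klass, factor(ls$group, levels = unique(ls$group))),
           pct, numeric(1))
  } else pct(ls$klass)
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Genotype-specific (unique) markers
#'
#' Lists every band that fingerprints a single genotype: unique positive
#' markers (band present in exactly one genotype — its carrier) and unique
#' negative markers (band absent from exactly one genotype). Genotypes with
#' no unique band do not appear.
#'
#' @param x a [band_matrix()].
#' @return data frame with columns `genotype`, `polarity`
#'   (`"positive"`/`"negative"`), `group`, `size`, `locus_id`, ordered by
#'   genotype then polarity.
#' @export
genotype_specific_markers <- function(x) {
  ls <- locus_stats(x)
  x <- collapse_intensity(x)
  rows <- which(ls$klass %in% c("unique_positive", "unique_negative"))
  out <- data.frame(genotype = character(0), polarity = character(0),
                    group = character(0), size = numeric(0),
                    locus_id = character(0), stringsAsFactors = FALSE)
  for (i in rows) {
    pos <- ls$klass[i] == "unique_positive"
    carrier <- if (pos) which(x$presence[i, ] == 1L) else
                        which(x$presence[i, ] == 0L)
    out <- rbind(out, data.frame(
      genotype = genotypes(x)[carrier],
      polarity = if (pos) "positive" else "negative",
      group = ls$group[i], size = ls$size[i], locus_id = ls$locus_id[i],
      stringsAsFactors = FALSE))
  }
  out[order(out$genotype, out$polarity), , drop = FALSE]
}

#' Dominant-marker PIC of a band group
#'
#' Polymorphism information content for dominant markers: the mean over a
#' primer's bands of `2 p (1 - p)`, where p is the band frequency. The
#' maximum is 0.5, attained when every band has p = 0.5; a fully
#' monomorphic primer scores 0.
#'
#' @param freqs band frequencies in \[0, 1\].
#' @return PIC in \[0, 0.5\].
#' @export
#' @examples
#' pic_group(c(1, 1, 1))   # 0: monomorphic primer
#' pic_group(0.5)          # 0.5: maximally informative band
pic_group <- function(freqs) {
  if (!length(freqs)) stop("empty frequency list")
  if (any(freqs < 0 | freqs > 1)) stop("frequencies must be in [0, 1]")
  mean(2 * freqs * (1 - freqs))
}

#' Effective multiplex ratio of a primer
#'
#' EMR = (number of polymorphic bands) * (fraction of the primer's bands
#' that are polymorphic) = pbn^2 / tbn, the standard dominant-marker form.
#'
#' @param tbn total band number (> 0).
#' @param pbn polymorphic band number, `0 <= pbn <= tbn`.
#' @return EMR >= 0.
#' @export
emr_group <- function(tbn, pbn) {
  if (any(tbn <= 0)) stop("tbn must be positive")
  if (any(pbn < 0 | pbn > tbn)) stop("need 0 <= pbn <= tbn")
  pbn * (pbn / tbn)
}

#' Resolving power of a primer
#'
#' Rp = sum over the primer's bands of the band informativeness
#' `ib = 1 - 2 |0.5 - p|`. Zero exactly when every band is monomorphic
#' (p = 1) or, degenerately, when p = 0.
#'
#' @param freqs band frequencies in \[0, 1\].
#' @return Rp >= 0.
#' @export
rp_group <- function(freqs) {
  if (!length(freqs)) stop("empty frequency list")
  if (any(freqs < 0 | freqs > 1)) stop("frequencies must be in [0, 1]")
  sum(1 - 2 * abs(0.5 - freqs))
}

#' Per-primer informativeness summary
#'
#' One row per locus group (primer/enzyme): total, monomorphic and
#' polymorphic band counts (TBN, MBN, PBN), polymorphism percentage,
#' unique-band count (positive + negative), PIC, effective multiplex ratio,
#' marker index (MI = PIC * EMR), resolving power, and the band size range.
#'
#' @param x a [band_matrix()].
#' @param totals if `TRUE`, append a `Total` row (sums of TBN/MBN/PBN/UB)
#'   and an `Average` row (means over groups of P%, PIC, EMR, MI, RP), as
#'   such tables are conventionally printed.
#' @param digits decimals for `p_pct` reporting (default 2), or `NULL` for
#'   unrounded. Index columns are left unrounded.
#' @return data frame with columns `group`, `tbn`, `mbn`, `pbn`, `p_pct`,
#'   `ub`, `pic`, `emr`, `mi`, `rp`, `size_min`, `size_max`.
#' @export
primer_summary <- function(x, totals = FALSE, digits = 2) {
  ls <- locus_stats(x)
  groups <- unique(ls$group)
  rows <- lapply(groups, function(g) {
    s <- ls[ls$group == g, , drop = FALSE]
    tbn <- nrow(s)
    pbn <- sum(is_polymorphic(s$klass))
    ub <- sum(s$klass %in% c("unique_positive", "unique_negative"))
    pic <- pic_group(s$p)
    emr <- emr_group(tbn, pbn)
    data.frame(group = g, tbn = tbn, mbn = tbn - pbn, pbn = pbn,
               p_pct = 100 * pbn / tbn, ub = ub, pic = pic, emr = emr,
               mi = pic * emr, rp = rp_group(s$p),
               size_min = suppressWarnings(min(s$size, na.rm = TRUE)),
               size_max = suppressWarnings(max(s$size, na.rm = TRUE)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (totals) {
    tot <- data.frame(group = "Total", tbn = sum(out$tbn), mbn = sum(out$mbn),
                      pbn = sum(out$pbn), p_pct = NA_real_, ub = sum(out$ub),
                      pic = NA_real_, emr = NA_real_, mi = NA_real_,
                      rp = NA_real_, size_min = NA_real_, size_max = NA_real_,
                      stringsAsFactors = FALSE)
    avg <- data.frame(group = "Average", tbn = NA_real_, mbn = NA_real_,
                      pbn = NA_real_, p_pct = mean(out$p_pct), ub = NA_real_,
                      pic = mean(out$pic), emr = mean(out$emr),
                      mi = mean(out$mi), rp = mean(out$rp),
                      size_min = NA_real_, size_max = NA_real_,
                      stringsAsFactors = FALSE)
    out <- rbind(out, tot, avg)
  }
  if (!is.null(digits)) out$p_pct <- round(out$p_pct, digits)
  rownames(out) <- NULL
  out
}
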