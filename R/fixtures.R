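#' Packaged bottle gourd band data
#'
#' The package ships, as plain delimited text under `extdata/`, the printed
#' band data of a diversity study of ten Egyptian bottle gourd
#' (*Lagenaria siceraria*) cultivars S1-S10:
#' \describe{
#'   \item{`bg_protein()`}{SDS-PAGE water-soluble protein profile: 17 bands
#'     (126-9 kDa) scored 0/1 across the ten cultivars.}
#'   \item{`bg_isozyme("pod")`, `bg_isozyme("ppo")`}{peroxidase and
#'     polyphenol oxidase native-gel isozyme patterns: 5 bands each
#'     (Rm 0.3-0.75) with staining-density grades 1-3.}
#'   \item{`bg_scot_counts()`}{per-primer summary counts of the 8-primer
#'     SCoT assay (44 amplicons, 210-1680 bp): total, monomorphic and
#'     polymorphic band numbers and unique-band counts. The underlying
#'     44-band matrix was not published, only these counts and the
#'     similarity matrix below.}
#'   \item{`bg_scot_similarity()`}{the published Jaccard similarity matrix
#'     of the SCoT assay, to 3 decimals.}
#' }
#'
#' @param enzyme which isozyme system, `"pod"` or `"ppo"`.
#' @return `bg_protein()` and `bg_isozyme()` return a [band_matrix()];
#'   `bg_scot_counts()` a data frame with columns `primer`, `tbn`, `mbn`,
#'   `pbn`, `ub`, `bsr_max`, `bsr_min`; `bg_scot_similarity()` a symmetric
#'   similarity matrix; `bg_fixture_path()` the file path of a named
#'   fixture.
#' @name bottle_gourd_data
#' @examples
#' n_loci(bg_protein())
#' polymorphism_percent(bg_protein())
NULL

#' @rdname bottle_gourd_data
#' @param name fixture file name (without extension), one of
#'   `"protein_table4"`, `"pod_table6"`, `"ppo_table7"`,
#'   `"scot_table10_counts"`, `"scot_table12_similarity"`.
#' @export
bg_fixture_path <- function(name) {
  p <- system.file("extdata", paste0(name, ".csv"), package = "bandiv")
  if (p == "") stop("no packaged fixture named '", name, "'")
  p
}

#' @rdname bottle_gourd_data
#' @export
bg_protein <- function() read_band_matrix(bg_fixture_path("protein_table4"))

#' @rdname bottle_gourd_data
#' @export
bg_isozyme <- function(enzyme = c("pod", "ppo")) {
  enzyme <- match.arg(enzyme)
  read_band_matrix(bg_fixture_path(paste0(enzyme, "_table",
                                          if (enzyme == "pod") 6 else 7)),
                   intensity = TRUE)
}

#' @rdname bottle_gourd_data
#' @export
bg_scot_counts <- function() {
  utils::read.csv(bg_fixture_path("scot_table10_counts"),
                  stringsAsFactors = FALSE)
}

#' @rdname bottle_gourd_data
#' @export
bg_scot_similarity <- function() {
  read_similarity(bg_fixture_path("scot_table12_similarity"))
}
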