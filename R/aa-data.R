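#' @keywords internal
"_PACKAGE"

## Canonical amino-acid alphabet. All descriptor scales, composition counts
## and motif wildcards are defined over exactly these 20 letters; the
## ambiguity letter X is tolerated only under the permissive input policy
## and is excluded from every average and count.
AA_CANONICAL <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

.leap_cache <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "leaptools")
  if (!nzchar(path)) {
    # during development (pkgload) system.file resolves inst/ automatically;
    # a miss here means the installation is broken
    stop("packaged data file not found: ", file)
  }
  path
}

.read_packaged_tsv <- function(file) {
  key <- paste0("tsv_", file)
  if (!is.null(.leap_cache[[key]])) return(.leap_cache[[key]])
  x <- utils::read.delim(.extdata(file), stringsAsFactors = FALSE,
                         check.names = FALSE)
  .leap_cache[[key]] <- x
  x
}

#' Per-residue property scales
#'
#' Returns one of the packaged 20-entry amino-acid property scales as a named
#' numeric vector. The packaged scales are the ones used throughout the LEAP
#' descriptor suite: Kyte-Doolittle hydropathy, Hopp-Woods hydrophilicity,
#' the Eisenberg consensus hydrophobicity, Zimmerman bulkiness,
#' Bhaskaran-Ponnuswamy average flexibility, the Janin accessible and buried
#' molar fractions, and the Zhao-London transmembrane tendency.
#'
#' @param name Scale name, one of `"kyte_doolittle"`, `"hopp_woods"`,
#'   `"eisenberg"`, `"bulkiness_zimmerman"`, `"flexibility_bhaskaran"`,
#'   `"janin_accessible"`, `"janin_buried"`, `"zhao_london_tm"`.
#' @return Named numeric vector with one finite value per canonical residue.
#' @examples
#' aa_scale("kyte_doolittle")[["I"]] # 4.5, the most hydropathic residue
#' @export
aa_scale <- function(name = c("kyte_doolittle", "hopp_woods", "eisenberg",
                              "bulkiness_zimmerman", "flexibility_bhaskaran",
                              "janin_accessible", "janin_buried",
                              "zhao_london_tm")) {
  name <- match.arg(name)
  tab <- .read_packaged_tsv("aa_scales.tsv")
  v <- stats::setNames(tab[[name]], tab$residue)
  v[AA_CANONICAL]
}

#' List the packaged scale names with their citation tags
#'
#' @return A tibble with columns `scale` and `citation_tag`.
#' @export
aa_scale_citations <- function() {
  tibble::as_tibble(.read_packaged_tsv("aa_scale_citations.tsv"))
}

#' Average residue masses
#'
#' Average (not monoisotopic) masses of the 20 amino-acid residues in a
#' polypeptide chain, in daltons. A free amino acid weighs one water more.
#'
#' @return Named numeric vector of residue masses.
#' @export
aa_residue_masses <- function() {
  tab <- .read_packaged_tsv("residue_masses.tsv")
  stats::setNames(tab$avg_mass, tab$residue)[AA_CANONICAL]
}

#' Ionizable-group pKa set
#'
#' The pinned pKa table used for net-charge and isoelectric-point
#' calculations: free N- and C-termini plus the seven ionizable side chains
#' (D, E, C, Y, H, K, R), with the sign of the charge each group carries when
#' ionized. Values follow a standard biochemistry reference set.
#'
#' @return Data frame with columns `group`, `pka`, `sign`.
#' @export
pka_set <- function() {
  .read_packaged_tsv("pka_set.tsv")
}

#' Background amino-acid composition
#'
#' The packaged default background composition (percent of each amino acid
#' over all proteins of a large sequence database), emulating the
#' UniProtKB/Swiss-Prot release composition of the early-2010s. Used as the
#' denominator of amino-acid usage ratios. Any user table with the same
#' columns can be supplied instead.
#'
#' @param path Optional path to a user TSV with columns
#'   `residue`, `percent`, `release_tag`.
#' @return List with elements `percent` (named numeric vector, one entry per
#'   canonical residue) and `release_tag` (string).
#' @export
background_composition <- function(path = NULL) {
  tab <- if (is.null(path)) {
    .read_packaged_tsv("background_composition.tsv")
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("residue", "percent") %in% names(tab)))
  pct <- stats::setNames(tab$percent, tab$residue)
  if (!all(AA_CANONICAL %in% names(pct))) {
    stop("background composition must cover all 20 canonical residues")
  }
  pct <- pct[AA_CANONICAL]
  if (any(pct <= 0)) stop("background composition entries must be > 0")
  total <- sum(pct)
  if (total < 99 || total > 101) {
    stop("background composition percentages sum to ", round(total, 2),
         "; expected a value in [99, 101]")
  }
  list(
    percent = pct,
    release_tag = if ("release_tag" %in% names(tab)) tab$release_tag[1] else "user"
  )
}

#' The packaged LEAP class table
#'
#' One row per LEAP class: class identifier, PFAM accession, the class motif
#' in the motif dialect, the number of LEAPdb sequences carrying the motif,
#' the observed sequence length range, and the character/gap counts of the
#' class multiple-alignment consensus.
#'
#' @return A tibble with 12 rows.
#' @export
leap_class_table <- function() {
  tibble::as_tibble(.read_packaged_tsv("leap_classes.tsv"))
}

#' Per-class amino-acid usage signs
#'
#' The +1/-1 usage signature of each LEAP class: +1 where the class median
#' usage ratio against the background composition exceeds 1, -1 otherwise.
#' Used by the synthetic-corpus generator to bias residue draws.
#'
#' @return Data frame with `class_id` plus one column per canonical residue.
#' @export
leap_usage_signs <- function() {
  .read_packaged_tsv("class_usage_signs.tsv")
}
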