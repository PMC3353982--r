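## Charge-hydropathy (Uversky-style) order/disorder plane.
##
## Each sequence is placed at (<R>, h): <R> is the absolute mean net charge
## per residue at pH 7, clipped to [0, 1]; h is the mean hydropathy rescaled
## to [0, 1] over its scale's range. Two plane variants are supported, one on
## the Eisenberg <H> scale and one on the Kyte-Doolittle GRAVY scale, each
## with its own published boundary line; points on or above the line are
## called folded, points below unfolded.

.PLANE_BOUNDARY <- list(
  eisenberg_h = c(slope = 0.560, intercept = 0.645),
  gravy = c(slope = 0.359, intercept = 0.413)
)

.plane_scale_name <- function(variant) {
  switch(variant, eisenberg_h = "eisenberg", gravy = "kyte_doolittle",
         stop("unknown plane variant: ", variant))
}

#' Normalize a mean hydropathy value to [0, 1]
#'
#' Min-max rescaling over the scale's own range,
#' `(value - min) / (max - min)`, clipped to `[0, 1]`. Because a sequence
#' mean can never leave the scale range, clipping only guards rounding.
#'
#' @param mean_value Numeric vector of mean scale values.
#' @param scale Scale name or named vector (see [aa_scale()]).
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_hydropathy <- function(mean_value, scale) {
  s <- .resolve_scale(scale)
  lo <- min(s)
  hi <- max(s)
  if (hi <= lo) stop("degenerate scale: min equals max")
  pmin(1, pmax(0, (mean_value - lo) / (hi - lo)))
}

#' Boundary hydropathy of the order/disorder line
#'
#' The normalized hydropathy on the folded/unfolded boundary at a given
#' normalized mean net charge: `0.560 * r + 0.645` for the Eisenberg `<H>`
#' plane, `0.359 * r + 0.413` for the GRAVY plane.
#'
#' @param r Normalized mean net charge in `[0, 1]`.
#' @param variant `"eisenberg_h"` or `"gravy"`.
#' @return Numeric vector of boundary hydropathies.
#' @export
boundary_value <- function(r, variant = c("eisenberg_h", "gravy")) {
  variant <- match.arg(variant)
  stopifnot(all(r >= 0 & r <= 1))
  b <- .PLANE_BOUNDARY[[variant]]
  b[["slope"]] * r + b[["intercept"]]
}

#' Classify a plane point as folded or unfolded
#'
#' Folded iff `h >= boundary_value(r, variant)`: the boundary itself belongs
#' to the folded side (the published convention assigns "above" to folded;
#' equality is a documented tie-break).
#'
#' @inheritParams boundary_value
#' @param h Normalized hydropathy in `[0, 1]`.
#' @return Character vector, `"folded"` or `"unfolded"`.
#' @export
classify_plane <- function(r, h, variant = c("eisenberg_h", "gravy")) {
  variant <- match.arg(variant)
  stopifnot(all(h >= 0 & h <= 1))
  ifelse(h >= boundary_value(r, variant), "folded", "unfolded")
}

#' Charge-hydropathy plane coordinates for a set of sequences
#'
#' Computes, for each sequence and requested plane variant, the normalized
#' mean net charge `r = min(|mean net charge at pH 7|, 1)`, the normalized
#' hydropathy `h`, and the folded/unfolded label. Both variants share the
#' same `r`, so variant disagreements for a sequence are directly visible in
#' the output.
#'
#' @param sequences Sequence tibble.
#' @param variant `"eisenberg_h"`, `"gravy"` or `"both"`.
#' @param maturity Tag recorded in the output (`"full_length"` or
#'   `"mature"`).
#' @param pka pKa table for the net-charge calculation.
#' @return A tibble with columns `id`, `r`, `h`, `variant`, `label`,
#'   `maturity`.
#' @export
plane_coordinates <- function(sequences,
                              variant = c("both", "eisenberg_h", "gravy"),
                              maturity = "full_length", pka = pka_set()) {
  variant <- match.arg(variant)
  variants <- if (variant == "both") c("eisenberg_h", "gravy") else variant
  r <- pmin(1, abs(net_charge(sequences$residues, ph = 7, pka = pka)$mean_charge))
  out <- lapply(variants, function(v) {
    scale_name <- .plane_scale_name(v)
    h <- normalize_hydropathy(mean_scale_value(sequences$residues, scale_name),
                              scale_name)
    tibble::tibble(
      id = sequences$id, r = r, h = h, variant = v,
      label = classify_plane(r, h, v), maturity = maturity
    )
  })
  dplyr::bind_rows(out)
}

#' Trim a cleavable N-terminal pre-sequence
#'
#' Removes the first `cleavage_after` residues of each matched sequence to
#' obtain the putative mature protein (the form after import and
#' targeting-peptide cleavage), so that disorder-plane placement can be
#' re-evaluated without pre-sequence bias. Sequences without an entry in
#' `cleavages` are dropped from the result.
#'
#' @param sequences Sequence tibble.
#' @param cleavages Tibble with columns `id` and `cleavage_after` (1-based
#'   count of pre-sequence residues; 0 means no trimming). Must satisfy
#'   `0 <= cleavage_after < length(sequence)`.
#' @return Sequence tibble of mature sequences (`source = "mature"`).
#' @export
trim_presequence <- function(sequences, cleavages) {
  stopifnot(all(c("id", "cleavage_after") %in% names(cleavages)))
  idx <- match(cleavages$id, sequences$id)
  if (anyNA(idx)) {
    stop("cleavage table references unknown id(s): ",
         paste(cleavages$id[is.na(idx)], collapse = ", "))
  }
  kept <- sequences[idx, ]
  cut <- cleavages$cleavage_after
  len <- nchar(kept$residues)
  if (any(cut < 0 | cut >= len)) {
    bad <- kept$id[cut < 0 | cut >= len]
    stop("cleavage position out of range for: ", paste(bad, collapse = ", "))
  }
  kept$residues <- substring(kept$residues, cut + 1)
  kept$source <- "mature"
  kept
}
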