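## Per-sequence physico-chemical descriptors.
##
## Every quantity here is composition-determined: a per-residue table value
## averaged (or summed) over the sequence. X positions, tolerated under the
## permissive input policy, are excluded from both numerator and denominator
## of every average and from composition counts; molecular weight is defined
## only for fully canonical sequences.

#' Residue count matrix
#'
#' Counts each canonical residue in each sequence (X positions ignored).
#'
#' @param residues Character vector of residue strings.
#' @return Integer matrix, one row per sequence, 20 named columns.
#' @export
aa_counts <- function(residues) {
  split <- .split_canonical(residues)
  m <- t(vapply(split, function(ch) {
    tabulate(factor(ch, levels = AA_CANONICAL), nbins = 20L)
  }, integer(20L)))
  colnames(m) <- AA_CANONICAL
  m
}

#' Amino-acid composition in percent
#'
#' @inheritParams aa_counts
#' @return Numeric matrix of percentages; rows sum to 100 for sequences
#'   without X.
#' @export
aa_percent <- function(residues) {
  m <- aa_counts(residues)
  100 * m / rowSums(m)
}

.resolve_scale <- function(scale) {
  if (is.character(scale) && length(scale) == 1) scale <- aa_scale(scale)
  if (!is.numeric(scale) || !all(AA_CANONICAL %in% names(scale))) {
    stop("scale must be a scale name or a named vector over the 20 residues")
  }
  scale[AA_CANONICAL]
}

#' Mean per-residue scale value
#'
#' Arithmetic mean of a property-scale value over all (canonical) positions
#' of each sequence. This single operation implements GRAVY (Kyte-Doolittle),
#' mean hydrophilicity (Hopp-Woods), mean hydrophobicity `<H>` (Eisenberg),
#' mean bulkiness, mean flexibility, the Janin accessible/buried fractions
#' and the transmembrane tendency, depending on the scale supplied.
#'
#' @inheritParams aa_counts
#' @param scale Scale name (see [aa_scale()]) or named numeric vector.
#' @return Numeric vector of means.
#' @examples
#' mean_scale_value("AIV", "kyte_doolittle") # (1.8 + 4.5 + 4.2) / 3 = 3.5
#' @export
mean_scale_value <- function(residues, scale) {
  s <- .resolve_scale(scale)
  counts <- aa_counts(residues)
  n <- rowSums(counts)
  if (any(n == 0)) {
    stop("sequence with no canonical residues: ",
         paste(which(n == 0), collapse = ", "))
  }
  drop(counts %*% s) / n
}

.WATER_MASS <- 18.01524

#' Molecular weight
#'
#' Average-mass molecular weight of each polypeptide: sum of residue masses
#' plus one water. Defined only for fully canonical sequences.
#'
#' @inheritParams aa_counts
#' @return Numeric vector of masses in daltons.
#' @export
molecular_weight <- function(residues) {
  if (any(grepl("X", residues, fixed = TRUE))) {
    stop("molecular weight is undefined for sequences containing X")
  }
  counts <- aa_counts(residues)
  drop(counts %*% aa_residue_masses()) + .WATER_MASS
}

.charge_from_counts <- function(counts, ph, pka) {
  n <- nrow(counts)
  total <- numeric(n)
  for (i in seq_len(nrow(pka))) {
    g <- pka$group[i]
    k <- pka$pka[i]
    mult <- if (g %in% c("nterm", "cterm")) rep(1, n) else counts[, g]
    frac <- if (pka$sign[i] > 0) {
      1 / (1 + 10^(ph - k)) # protonated fraction of a basic group
    } else {
      -1 / (1 + 10^(k - ph)) # deprotonated fraction of an acidic group
    }
    total <- total + mult * frac
  }
  unname(total)
}

#' Net charge at a given pH
#'
#' Henderson-Hasselbalch net charge over the ionizable side chains
#' (D, E, C, Y, H, K, R) plus the free N- and C-termini, using the packaged
#' pKa set ([pka_set()]). The mean charge divides by the number of
#' (canonical) residues.
#'
#' @inheritParams aa_counts
#' @param ph pH, in `[0, 14]`.
#' @param pka pKa table, defaults to the packaged set.
#' @return A tibble with columns `total_charge` and `mean_charge`.
#' @export
net_charge <- function(residues, ph = 7, pka = pka_set()) {
  stopifnot(ph >= 0, ph <= 14)
  counts <- aa_counts(residues)
  total <- .charge_from_counts(counts, ph, pka)
  tibble::tibble(total_charge = total,
                 mean_charge = total / rowSums(counts))
}

#' Isoelectric point
#'
#' The pH at which the Henderson-Hasselbalch net charge crosses zero, found
#' by bisection on `[0, 14]`. The net charge is strictly decreasing in pH, so
#' the root is unique.
#'
#' @inheritParams net_charge
#' @param tol Bisection tolerance in pH units.
#' @return Numeric vector of pI values.
#' @export
isoelectric_point <- function(residues, pka = pka_set(), tol = 1e-4) {
  counts <- aa_counts(residues)
  vapply(seq_len(nrow(counts)), function(i) {
    ci <- counts[i, , drop = FALSE]
    lo <- 0
    hi <- 14
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (.charge_from_counts(ci, mid, pka) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' FoldIndex disorder propensity
#'
#' Whole-sequence FoldIndex:
#' `FI = 2.785 * <H>_n - |<R>| - 1.151`,
#' where `<H>_n` is the mean Kyte-Doolittle hydropathy rescaled per residue
#' to `[0, 1]` via `(v + 4.5) / 9`, and `<R>` is the mean net charge at pH 7.
#' Negative values indicate intrinsic disorder. Computed globally (one value
#' per protein), not in sliding windows.
#'
#' @inheritParams net_charge
#' @return Numeric vector of FoldIndex values.
#' @export
foldindex <- function(residues, pka = pka_set()) {
  kd <- mean_scale_value(residues, "kyte_doolittle")
  h_norm <- (kd + 4.5) / 9
  r <- net_charge(residues, ph = 7, pka = pka)$mean_charge
  2.785 * h_norm - abs(r) - 1.151
}

#' Full per-sequence descriptor table
#'
#' Computes every descriptor of the suite for each sequence: length, MW,
#' MW/length, pI, total and mean net charge at pH 7, FoldIndex, mean
#' hydrophilicity (Hopp-Woods), GRAVY (Kyte-Doolittle), mean hydrophobicity
#' `<H>` (Eisenberg), mean bulkiness, mean flexibility, mean molar fractions
#' of accessible and buried residues (Janin), mean transmembrane tendency
#' (Zhao-London), and the 20 amino-acid percentages (`pct_*` columns).
#'
#' @param sequences Sequence tibble (see [read_fasta()]); sequences must be
#'   fully canonical (molecular weight is undefined with X).
#' @param pka pKa table for charge-based descriptors.
#' @return A tibble with one row per sequence.
#' @export
compute_descriptors <- function(sequences, pka = pka_set()) {
  res <- sequences$residues
  counts <- aa_counts(res)
  len <- rowSums(counts)
  mw <- molecular_weight(res)
  charge <- net_charge(res, ph = 7, pka = pka)
  out <- tibble::tibble(
    id = sequences$id,
    length = as.integer(len),
    mw = mw,
    mw_per_length = mw / len,
    pi = isoelectric_point(res, pka = pka),
    net_charge_ph7 = charge$total_charge,
    mean_net_charge = charge$mean_charge,
    foldindex = foldindex(res, pka = pka),
    hydrophilicity = mean_scale_value(res, "hopp_woods"),
    gravy = mean_scale_value(res, "kyte_doolittle"),
    hydrophobicity_h = mean_scale_value(res, "eisenberg"),
    bulkiness = mean_scale_value(res, "bulkiness_zimmerman"),
    flexibility = mean_scale_value(res, "flexibility_bhaskaran"),
    frac_accessible = mean_scale_value(res, "janin_accessible"),
    frac_buried = mean_scale_value(res, "janin_buried"),
    tm_tendency = mean_scale_value(res, "zhao_london_tm")
  )
  pct <- aa_percent(res)
  colnames(pct) <- paste0("pct_", colnames(pct))
  dplyr::bind_cols(out, tibble::as_tibble(pct))
}
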