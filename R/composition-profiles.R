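## Amino-acid usage profiling, combination fractions, binary class
## signatures, and the consensus gap/similarity arithmetic.

#' Amino-acid usage ratio against a background composition
#'
#' Divides per-sequence (or per-class) amino-acid percentages by a background
#' composition. A ratio of 1 means the residue is used exactly as often as in
#' the background proteome; a residue absent from the sequence gives 0.
#'
#' @param percent Numeric matrix (or vector) of amino-acid percentages with
#'   residue names, e.g. from [aa_percent()].
#' @param background Background composition list from
#'   [background_composition()].
#' @return Matrix (or vector) of usage ratios, same shape as `percent`.
#' @export
usage_ratio <- function(percent, background = background_composition()) {
  bg <- background$percent
  if (is.null(dim(percent))) {
    stopifnot(all(AA_CANONICAL %in% names(percent)))
    return(percent[AA_CANONICAL] / bg)
  }
  stopifnot(all(AA_CANONICAL %in% colnames(percent)))
  sweep(percent[, AA_CANONICAL, drop = FALSE], 2, bg, "/")
}

#' Parse a residue-combination name
#'
#' Combination names follow the bracketed field convention, e.g.
#' `"[D+E-K-R]"`: residues after a `+` count positively, residues after a
#' `-` negatively. The first residue counts positively. ASCII `-` and the
#' typographic minus are both accepted.
#'
#' @param name Combination name string.
#' @return List with `name`, `plus` and `minus` residue sets.
#' @export
parse_combination <- function(name) {
  body <- gsub("^\\[|\\]$", "", gsub("−", "-", name))
  if (!grepl("^[A-Z]([+-][A-Z])*$", body)) {
    stop("malformed combination name: ", name)
  }
  parts <- regmatches(body, gregexpr("[+-]?[A-Z]", body))[[1]]
  signs <- ifelse(substr(parts, 1, 1) == "-", -1L, 1L)
  res <- sub("^[+-]", "", parts)
  if (!all(res %in% AA_CANONICAL)) {
    stop("combination '", name, "' contains non-canonical residue(s): ",
         paste(setdiff(res, AA_CANONICAL), collapse = ", "))
  }
  plus <- res[signs > 0]
  minus <- res[signs < 0]
  if (length(intersect(plus, minus))) {
    stop("combination '", name, "' lists a residue on both sides")
  }
  list(name = name, plus = plus, minus = minus)
}

#' The packaged combination set
#'
#' The chain-length-normalized residue combinations profiled by default:
#' charged fractions `[K+R]`, `[D+E]`, `[D+E+K+R]`, the signed charge balance
#' `[D+E-K-R]`, amide fraction `[N+Q]`, aliphatic fraction `[A+I+L+V]`, the
#' strongest disorder-promoting set `[R+E+S+P]` and the strongest
#' order-promoting set `[C+F+Y+W]`.
#'
#' @return Character vector of combination names.
#' @export
default_combinations <- function() {
  c("[K+R]", "[D+E]", "[D+E+K+R]", "[D+E-K-R]",
    "[N+Q]", "[A+I+L+V]", "[R+E+S+P]", "[C+F+Y+W]")
}

#' Residue-combination fraction
#'
#' `(count(plus set) - count(minus set)) / length` for each sequence, the
#' fractional content convention for charged / disorder-promoting /
#' order-promoting residue groups.
#'
#' @inheritParams aa_counts
#' @param spec Combination name (see [parse_combination()]) or a parsed list.
#' @return Numeric vector of fractions.
#' @examples
#' combination_fraction("KRAA", "[K+R]") # 0.5
#' @export
combination_fraction <- function(residues, spec) {
  if (is.character(spec)) spec <- parse_combination(spec)
  counts <- aa_counts(residues)
  len <- rowSums(counts)
  plus <- rowSums(counts[, spec$plus, drop = FALSE])
  minus <- if (length(spec$minus)) {
    rowSums(counts[, spec$minus, drop = FALSE])
  } else 0
  (plus - minus) / len
}

#' Combination-fraction matrix
#'
#' @inheritParams aa_counts
#' @param combinations Character vector of combination names.
#' @return Numeric matrix, one column per combination.
#' @export
combination_matrix <- function(residues, combinations = default_combinations()) {
  m <- vapply(combinations, function(nm) combination_fraction(residues, nm),
              numeric(length(residues)))
  matrix(m, nrow = length(residues),
         dimnames = list(NULL, combinations))
}

#' Default reference map for the binary physico-chemical encoding
#'
#' Variables with a natural fixed reference (7 for pI, 0 for the signed
#' scales: mean net charge, hydrophilicity, GRAVY, FoldIndex, `<H>`) are
#' compared against it; the remaining variables (MW/length, bulkiness,
#' flexibility, buried/accessible fractions, transmembrane tendency) are
#' compared against the overall median computed over the whole input dataset.
#'
#' @param descriptors Descriptor tibble from [compute_descriptors()]; used
#'   for the overall medians.
#' @return A tibble with columns `variable`, `kind`
#'   (`"fixed_reference"` or `"overall_median"`) and `reference`.
#' @export
default_reference_map <- function(descriptors) {
  fixed <- c(pi = 7, mean_net_charge = 0, hydrophilicity = 0,
             gravy = 0, foldindex = 0, hydrophobicity_h = 0)
  median_vars <- c("mw_per_length", "bulkiness", "flexibility",
                   "frac_buried", "frac_accessible", "tm_tendency")
  tibble::tibble(
    variable = c(names(fixed), median_vars),
    kind = c(rep("fixed_reference", length(fixed)),
             rep("overall_median", length(median_vars))),
    reference = unname(c(fixed,
                         vapply(median_vars,
                                function(v) stats::median(descriptors[[v]]),
                                numeric(1))))
  )
}

#' Binary physico-chemical class profile
#'
#' Encodes each class-level summary value as +1 when it strictly exceeds its
#' reference and -1 otherwise (ties encode as -1; ties have probability zero
#' for continuous data). The class summary statistic is the class median (the
#' boxplot center).
#'
#' @param descriptors Descriptor tibble from [compute_descriptors()].
#' @param labels Character vector of class labels, one per row of
#'   `descriptors`.
#' @param reference_map Reference tibble, defaults to
#'   [default_reference_map()] computed on `descriptors`.
#' @return List with `profile` (class x variable matrix of +1/-1),
#'   `class_medians` (same shape, the medians) and `reference_map`.
#' @export
binary_physchem_profile <- function(descriptors, labels,
                                    reference_map = default_reference_map(descriptors)) {
  stopifnot(nrow(descriptors) == length(labels))
  vars <- reference_map$variable
  missing <- setdiff(vars, names(descriptors))
  if (length(missing)) {
    stop("descriptor table lacks variable(s): ", paste(missing, collapse = ", "))
  }
  classes <- sort(unique(labels))
  med <- t(vapply(classes, function(cl) {
    vapply(vars, function(v) {
      stats::median(descriptors[[v]][labels == cl])
    }, numeric(1))
  }, numeric(length(vars))))
  dimnames(med) <- list(classes, vars)
  prof <- med
  for (j in seq_along(vars)) {
    prof[, j] <- ifelse(med[, j] > reference_map$reference[j], 1, -1)
  }
  list(profile = prof, class_medians = med, reference_map = reference_map)
}

#' Binary amino-acid usage profile
#'
#' Per-class medians of the per-sequence usage ratios, encoded +1 when the
#' median ratio strictly exceeds 1 and -1 otherwise (ties encode as -1).
#'
#' @param sequences Sequence tibble.
#' @param labels Class labels, one per sequence.
#' @param background Background composition.
#' @return List with `profile` (class x residue matrix of +1/-1) and
#'   `median_ratios` (the medians).
#' @export
binary_usage_profile <- function(sequences, labels,
                                 background = background_composition()) {
  stopifnot(nrow(sequences) == length(labels))
  ratios <- usage_ratio(aa_percent(sequences$residues), background)
  classes <- sort(unique(labels))
  med <- t(vapply(classes, function(cl) {
    apply(ratios[labels == cl, , drop = FALSE], 2, stats::median)
  }, numeric(20L)))
  dimnames(med) <- list(classes, AA_CANONICAL)
  list(profile = ifelse(med > 1, 1, -1), median_ratios = med)
}

#' Consensus gap and similarity percentages
#'
#' Recomputes the gap percentage of a class multiple-alignment consensus from
#' its total character count and gap count, rounded to one decimal, together
#' with the complementary similarity percentage.
#'
#' @param total_chars Total characters of the consensus sequence(s).
#' @param gap_count Gap characters among them.
#' @return A tibble with columns `percent_gap` and `percent_similarity`
#'   (their sum is exactly 100: similarity is computed from the rounded gap
#'   percentage).
#' @examples
#' consensus_gap_metrics(790, 680) # 86.1 / 13.9
#' @export
consensus_gap_metrics <- function(total_chars, gap_count) {
  stopifnot(length(total_chars) == length(gap_count))
  if (any(total_chars <= 0)) stop("total_chars must be positive")
  if (any(gap_count < 0 | gap_count > total_chars)) {
    stop("gap_count must lie in [0, total_chars]")
  }
  pg <- round(100 * gap_count / total_chars, 1)
  tibble::tibble(percent_gap = pg, percent_similarity = 100 - pg)
}
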