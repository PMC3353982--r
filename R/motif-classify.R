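## Classification of sequences into the 12 LEAP classes.

#' Load and compile the LEAP class motif set
#'
#' Compiles the 12 packaged class motifs (or a user motif table with the same
#' columns) into matchers. The motif set is a plain-text config so it can be
#' revised without a code change.
#'
#' @param path Optional path to a TSV with columns `class_id`, `pfam_acc`,
#'   `pattern`; defaults to the packaged class table.
#' @return Named list of `leap_motif` objects, one per class, names the
#'   class ids.
#' @export
leap_motifs <- function(path = NULL) {
  tab <- if (is.null(path)) {
    leap_class_table()
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("class_id", "pattern") %in% names(tab)))
  if (anyDuplicated(tab$class_id)) stop("duplicate class_id in motif table")
  motifs <- lapply(tab$pattern, compile_motif)
  names(motifs) <- as.character(tab$class_id)
  for (i in seq_along(motifs)) {
    motifs[[i]]$class_id <- tab$class_id[i]
    motifs[[i]]$pfam_acc <-
      if ("pfam_acc" %in% names(tab)) tab$pfam_acc[i] else NA_character_
  }
  motifs
}

#' Classify sequences into LEAP classes
#'
#' Matches every sequence against every class motif. A sequence is assigned a
#' class label only when exactly one class motif matches; sequences matching
#' no motif are `"unclassified"` and sequences matching several are
#' `"ambiguous"` (reported, never silently assigned: the class motifs are
#' designed to be mutually exclusive on curated data, so overlap is a
#' data-quality signal).
#'
#' @param sequences Sequence tibble (see [read_fasta()]).
#' @param motifs Named list of compiled motifs from [leap_motifs()].
#' @return A tibble with columns `id`, `label` (class id as character,
#'   `"unclassified"` or `"ambiguous"`), `n_matched`, and `matched_classes`
#'   (comma-separated class ids).
#' @export
classify_sequences <- function(sequences, motifs = leap_motifs()) {
  if (!length(motifs)) stop("empty motif list")
  if (nrow(sequences) == 0) {
    return(tibble::tibble(id = character(), label = character(),
                          n_matched = integer(), matched_classes = character()))
  }
  hits <- vapply(motifs, function(m) motif_match(m, sequences$residues),
                 logical(nrow(sequences)))
  hits <- matrix(hits, nrow = nrow(sequences),
                 dimnames = list(NULL, names(motifs)))
  n_matched <- rowSums(hits)
  matched <- apply(hits, 1, function(h) paste(names(motifs)[h], collapse = ","))
  label <- ifelse(n_matched == 0, "unclassified",
                  ifelse(n_matched > 1, "ambiguous", matched))
  tibble::tibble(
    id = sequences$id,
    label = label,
    n_matched = as.integer(n_matched),
    matched_classes = matched
  )
}

#' Audit the non-overlap of the class motifs on a dataset
#'
#' Partitions a dataset by motif match and reports per-class counts together
#' with the ids of ambiguous (multi-motif) and unclassified sequences. The
#' counts always partition the dataset:
#' `sum(class_counts) + n_ambiguous + n_unclassified == nrow(sequences)`.
#'
#' @inheritParams classify_sequences
#' @return List with elements `class_counts` (named integer vector over the
#'   motif set), `ambiguous_ids`, `unclassified_ids`, `n` and the
#'   classification tibble itself (`calls`).
#' @export
audit_nonoverlap <- function(sequences, motifs = leap_motifs()) {
  if (nrow(sequences) == 0) {
    counts <- stats::setNames(integer(length(motifs)), names(motifs))
    return(list(class_counts = counts, ambiguous_ids = character(),
                unclassified_ids = character(), n = 0L,
                calls = classify_sequences(
                  tibble::tibble(id = character(), description = character(),
                                 residues = character(), source = character()),
                  motifs)))
  }
  calls <- classify_sequences(sequences, motifs)
  counts <- vapply(names(motifs), function(k) sum(calls$label == k),
                   integer(1))
  list(
    class_counts = counts,
    ambiguous_ids = calls$id[calls$label == "ambiguous"],
    unclassified_ids = calls$id[calls$label == "unclassified"],
    n = nrow(sequences),
    calls = calls
  )
}
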