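## Sequence input/output and validation.
##
## Sequences travel through the package as a plain tibble with one row per
## record: columns id, description, residues, source. Residues are uppercase
## strings over the canonical alphabet (plus X under the permissive policy).

.check_residues <- function(id, residues, policy = c("strict", "permissive")) {
  policy <- match.arg(policy)
  if (!nzchar(residues)) stop("record '", id, "' has an empty sequence")
  allowed <- if (policy == "strict") AA_CANONICAL else c(AA_CANONICAL, "X")
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), allowed)
  if (length(bad)) {
    stop("record '", id, "' contains non-canonical residue(s): ",
         paste(bad, collapse = ", "),
         if (policy == "strict") " (strict policy)" else
           " (B/Z/U/O and other codes are rejected even permissively)")
  }
  invisible(residues)
}

.new_sequence_tbl <- function(id, description, residues, source) {
  tibble::tibble(
    id = as.character(id),
    description = as.character(description),
    residues = as.character(residues),
    source = as.character(source)
  )
}

#' Read a protein FASTA file
#'
#' Reads a multi-record protein FASTA file into a sequence table. Lowercase
#' letters are uppercased, `*` stop characters and surrounding whitespace are
#' stripped, and wrapped sequence lines are joined. The first
#' whitespace-delimited token of each header is the record id; the remainder
#' is kept as the description.
#'
#' @param path Path to a FASTA file.
#' @param policy `"strict"` (default) rejects any letter outside the 20
#'   canonical amino acids; `"permissive"` additionally tolerates `X`, whose
#'   positions are excluded from every scale average and composition count
#'   downstream. Ambiguity codes B/Z/U/O are rejected under both policies
#'   because the descriptor suite is defined only for the canonical residues.
#' @param source Tag recorded in the `source` column
#'   (`"input"`, `"synthetic"` or `"mature"`).
#' @return A tibble with columns `id`, `description`, `residues`, `source`,
#'   one row per FASTA record, input order preserved.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 a toy record", "mkv"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, policy = c("strict", "permissive"),
                       source = "input") {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("FASTA file contains no records: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  residues <- toupper(gsub("[*[:space:]]", "", as.character(set)))
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  for (i in seq_along(ids)) .check_residues(ids[i], residues[i], policy)
  .new_sequence_tbl(ids, desc, residues, source)
}

#' Write a sequence table to FASTA
#'
#' @param sequences Sequence tibble as returned by [read_fasta()].
#' @param path Output file path.
#' @param width Line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60) {
  stopifnot(all(c("id", "residues") %in% names(sequences)))
  desc <- if ("description" %in% names(sequences)) sequences$description else ""
  header <- ifelse(nzchar(desc), paste(sequences$id, desc), sequences$id)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(sequences))) {
    writeLines(paste0(">", header[i]), con)
    s <- sequences$residues[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Validate a sequence table against an input policy
#'
#' Returns the table unchanged when every record is valid under `policy`,
#' with a logical `has_ambiguous` column flagging X-containing records so
#' that downstream scale means can exclude X positions.
#'
#' @inheritParams write_fasta
#' @inheritParams read_fasta
#' @return The validated tibble with a `has_ambiguous` column.
#' @export
validate_sequences <- function(sequences, policy = c("strict", "permissive")) {
  policy <- match.arg(policy)
  for (i in seq_len(nrow(sequences))) {
    .check_residues(sequences$id[i], sequences$residues[i], policy)
  }
  sequences$has_ambiguous <- grepl("X", sequences$residues, fixed = TRUE)
  sequences
}

## Residue strings -> character matrix-free list of per-position letters,
## X positions dropped (they carry no descriptor information).
.split_canonical <- function(residues) {
  lapply(strsplit(residues, "", fixed = TRUE),
         function(ch) ch[ch != "X"])
}

#' Read a cleavage-position table
#'
#' Tab-separated table with columns `id` and `cleavage_after` (1-based count
#' of pre-sequence residues removed upon maturation), as produced by external
#' targeting-peptide predictors.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `id` (character) and `cleavage_after`
#'   (integer).
#' @export
read_cleavage_table <- function(path) {
  if (!file.exists(path)) stop("cleavage table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "cleavage_after") %in% names(tab)))
  tibble::tibble(id = as.character(tab$id),
                 cleavage_after = as.integer(tab$cleavage_after))
}
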