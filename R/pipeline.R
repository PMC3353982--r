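## End-to-end orchestration: classify, describe, profile, place on the
## disorder planes, run the statistical battery, and write a reproducible
## output bundle with a manifest.

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     dec = ".")
  path
}

#' Assemble a pipeline run configuration
#'
#' All knobs of a full analysis run, fully serializable: the resolved
#' configuration is echoed next to the outputs so a run can be reproduced
#' from its output directory alone.
#'
#' @param fasta Input protein FASTA path.
#' @param out_dir Output directory (created if absent).
#' @param policy Input policy, `"strict"` or `"permissive"`.
#' @param cleavages Optional path to a cleavage-position TSV
#'   (see [read_cleavage_table()]); triggers the mature-sequence re-analysis.
#' @param variant Disorder-plane variant: `"both"`, `"eisenberg_h"` or
#'   `"gravy"`.
#' @param background Optional path to a background-composition TSV; `NULL`
#'   uses the packaged table.
#' @param threshold Spearman grouping threshold.
#' @param n_axes PCA axes retained for Ward clustering.
#' @param seed Seed recorded and set at the start of the run.
#' @return A `leap_config` list.
#' @export
leap_config <- function(fasta, out_dir, policy = "strict", cleavages = NULL,
                        variant = "both", background = NULL,
                        threshold = 0.75, n_axes = 3, seed = 1) {
  structure(list(
    fasta = fasta, out_dir = out_dir, policy = policy, cleavages = cleavages,
    variant = variant, background = background, threshold = threshold,
    n_axes = n_axes, seed = seed
  ), class = "leap_config")
}

#' Run the full LEAP analysis pipeline
#'
#' Reads the input sequences, classifies them against the 12 class motifs,
#' computes the descriptor table, the binary physico-chemical and usage
#' profiles (over sequences with a unique class call), the charge-hydropathy
#' plane coordinates (full-length and, when cleavage positions are given,
#' mature), and the statistical battery (Kruskal-Wallis screen, Nemenyi
#' post-hoc, Spearman groups, PCA, Ward clustering). Every output is written
#' under `config$out_dir` and listed, with row counts, in
#' `manifest.json`.
#'
#' @param config A [leap_config()] list.
#' @return The manifest, invisibly (a list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "leap_config"))
  if (!file.exists(config$fasta)) stop("input FASTA not found: ", config$fasta)
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  files <- list()
  warnings <- character()
  note <- function(path, rows) files[[basename(path)]] <<- list(rows = rows)

  sequences <- validate_sequences(read_fasta(config$fasta, config$policy),
                                  config$policy)
  if (any(sequences$has_ambiguous)) {
    warnings <- c(warnings, paste0(sum(sequences$has_ambiguous),
                                   " record(s) contain ambiguous residue X"))
  }
  background <- background_composition(config$background)
  motifs <- leap_motifs()

  ## classification
  calls <- classify_sequences(sequences, motifs)
  .write_tsv(calls, out("classification.tsv"))
  note(out("classification.tsv"), nrow(calls))

  ## descriptors (X-containing records cannot get a molecular weight)
  canon <- sequences[!sequences$has_ambiguous, ]
  if (nrow(canon) < nrow(sequences)) {
    warnings <- c(warnings,
                  "X-containing record(s) excluded from the descriptor table")
  }
  descriptors <- compute_descriptors(canon)
  .write_tsv(descriptors, out("descriptors.tsv"))
  note(out("descriptors.tsv"), nrow(descriptors))

  ## binary profiles over uniquely classified sequences
  lab <- calls$label[match(canon$id, calls$id)]
  in_class <- !(lab %in% c("unclassified", "ambiguous"))
  profiles_written <- FALSE
  if (any(in_class) && length(unique(lab[in_class])) >= 1) {
    dsub <- descriptors[in_class, ]
    ssub <- canon[in_class, ]
    lsub <- lab[in_class]
    phys <- binary_physchem_profile(dsub, lsub)
    m <- data.frame(class = rownames(phys$profile), phys$profile,
                    check.names = FALSE)
    .write_tsv(m, out("binary_physchem.tsv"))
    note(out("binary_physchem.tsv"), nrow(m))
    usg <- binary_usage_profile(ssub, lsub, background)
    m2 <- data.frame(class = rownames(usg$profile), usg$profile,
                     check.names = FALSE)
    .write_tsv(m2, out("binary_usage.tsv"))
    note(out("binary_usage.tsv"), nrow(m2))
    profiles_written <- TRUE
  } else {
    warnings <- c(warnings, "no uniquely classified sequences; binary profiles skipped")
  }

  ## disorder planes
  plane <- plane_coordinates(canon, config$variant)
  .write_tsv(plane, out("plane.tsv"))
  note(out("plane.tsv"), nrow(plane))
  if (!is.null(config$cleavages)) {
    mature <- trim_presequence(canon, read_cleavage_table(config$cleavages))
    plane_m <- plane_coordinates(mature, config$variant, maturity = "mature")
    .write_tsv(plane_m, out("plane_mature.tsv"))
    note(out("plane_mature.tsv"), nrow(plane_m))
  }

  ## statistical battery (needs >= 2 classes)
  stats_written <- FALSE
  if (profiles_written && length(unique(lab[in_class])) >= 2) {
    vm <- build_variable_matrix(canon[in_class, ], lab[in_class], background)
    kw <- kw_screen(vm)
    .write_tsv(kw, out("kruskal_wallis.tsv"))
    note(out("kruskal_wallis.tsv"), nrow(kw))

    nem <- lapply(colnames(vm$values), function(v) {
      p <- nemenyi_posthoc(vm$values[, v], vm$labels)
      pairs <- which(upper.tri(p), arr.ind = TRUE)
      tibble::tibble(variable = v,
                     class_a = rownames(p)[pairs[, 1]],
                     class_b = colnames(p)[pairs[, 2]],
                     p_value = p[pairs])
    })
    nem <- dplyr::bind_rows(nem)
    .write_tsv(nem, out("nemenyi.tsv"))
    note(out("nemenyi.tsv"), nrow(nem))

    sg <- spearman_groups(vm$values, config$threshold)
    jsonlite::write_json(
      list(threshold = sg$threshold, groups = sg$groups),
      out("correlation_groups.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE
    )
    note(out("correlation_groups.json"), length(sg$groups))

    pca <- pca_variables(vm$values)
    .write_tsv(data.frame(variable = rownames(pca$loadings), pca$loadings),
               out("pca_loadings.tsv"))
    note(out("pca_loadings.tsv"), nrow(pca$loadings))
    .write_tsv(data.frame(id = vm$ids, class = vm$labels, pca$scores),
               out("pca_scores.tsv"))
    note(out("pca_scores.tsv"), nrow(pca$scores))
    .write_tsv(data.frame(component = seq_along(pca$eigen_fractions),
                          eigen_fraction = pca$eigen_fractions),
               out("pca_eigen_fractions.tsv"))
    note(out("pca_eigen_fractions.tsv"), length(pca$eigen_fractions))

    hc <- ward_hca(pca$scores, config$n_axes)
    .write_tsv(data.frame(merge_a = hc$merge[, 1], merge_b = hc$merge[, 2],
                          height = hc$height),
               out("dendrogram_merges.tsv"))
    note(out("dendrogram_merges.tsv"), nrow(hc$merge))
    stats_written <- TRUE
  } else if (profiles_written) {
    warnings <- c(warnings, "fewer than two classes; statistical battery skipped")
  }

  manifest <- list(
    config = unclass(config),
    n_input = nrow(sequences),
    n_canonical = nrow(canon),
    n_classified = sum(in_class),
    n_ambiguous = sum(calls$label == "ambiguous"),
    n_unclassified = sum(calls$label == "unclassified"),
    stats_written = stats_written,
    warnings = warnings,
    files = files
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(manifest)
}
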