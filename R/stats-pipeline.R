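## The statistical battery over the per-sequence variable matrix:
## normality screening, Kruskal-Wallis with Nemenyi post-hoc comparisons,
## Spearman correlation grouping, correlation PCA, and Ward clustering on
## principal-component coordinates.

#' Build the quantitative variable matrix
#'
#' Assembles the per-sequence analysis matrix: the 12 physico-chemical
#' variables (MW/length, FoldIndex, bulkiness, flexibility, buried and
#' accessible fractions, transmembrane tendency, pI, mean net charge,
#' hydrophilicity, GRAVY, `<H>`), the 20 amino-acid usage ratios against the
#' background composition, and the chain-length-normalized combination
#' fractions.
#'
#' @param sequences Sequence tibble.
#' @param labels Class labels, one per sequence.
#' @param background Background composition for the usage ratios.
#' @param combinations Combination names (see [default_combinations()]).
#' @return List with `values` (numeric matrix, rows = sequences), `labels`
#'   and `ids`.
#' @export
build_variable_matrix <- function(sequences, labels,
                                  background = background_composition(),
                                  combinations = default_combinations()) {
  stopifnot(nrow(sequences) == length(labels))
  d <- compute_descriptors(sequences)
  physchem <- as.matrix(d[, c("mw_per_length", "foldindex", "bulkiness",
                              "flexibility", "frac_buried", "frac_accessible",
                              "tm_tendency", "pi", "mean_net_charge",
                              "hydrophilicity", "gravy", "hydrophobicity_h")])
  ratios <- usage_ratio(aa_percent(sequences$residues), background)
  colnames(ratios) <- paste0("usage_", colnames(ratios))
  comb <- combination_matrix(sequences$residues, combinations)
  values <- cbind(physchem, ratios, comb)
  rownames(values) <- sequences$id
  if (anyNA(values)) stop("variable matrix contains missing values")
  list(values = values, labels = labels, ids = sequences$id)
}

#' Normality screening of one variable
#'
#' Shapiro-Wilk test plus a Kolmogorov-Smirnov test against a normal
#' distribution with the sample's estimated mean and standard deviation.
#' Both are screening devices here: the pipeline switches to nonparametric
#' tests when normality fails.
#'
#' @param values Numeric vector, `n >= 3`, non-constant.
#' @return List with `shapiro_p` and `ks_p`.
#' @export
normality_battery <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("need at least 3 finite observations")
  if (stats::sd(values) == 0) stop("constant vector: normality undefined")
  shapiro_p <- stats::shapiro.test(
    if (length(values) > 5000) values[seq_len(5000)] else values
  )$p.value
  ks_p <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values))$p.value
  )
  list(shapiro_p = shapiro_p, ks_p = ks_p)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with the chi-square approximation
#' (`df = k - 1`). An all-equal sample returns `H = 0`, `p = 1` (the tie
#' correction would otherwise produce 0/0).
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels (coerced to factor), at least two non-empty
#'   groups.
#' @return List with `h_statistic`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (length(unique(values)) == 1) {
    return(list(h_statistic = 0, df = nlevels(groups) - 1L, p_value = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  list(h_statistic = unname(kt$statistic),
       df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Kruskal-Wallis screen over a variable matrix
#'
#' @param vm Variable matrix list from [build_variable_matrix()].
#' @return A tibble with one row per variable: `variable`, `h_statistic`,
#'   `df`, `p_value`.
#' @export
kw_screen <- function(vm) {
  res <- lapply(colnames(vm$values), function(v) {
    kw <- kruskal_wallis(vm$values[, v], vm$labels)
    tibble::tibble(variable = v, h_statistic = kw$h_statistic,
                   df = kw$df, p_value = kw$p_value)
  })
  dplyr::bind_rows(res)
}

#' Nemenyi all-pairs post-hoc test
#'
#' Rank-based all-pairs comparison following a Kruskal-Wallis test. The
#' default uses the studentized-range approximation on mean rank differences;
#' `method = "chisq"` uses the tie-corrected chi-square variant.
#'
#' @inheritParams kruskal_wallis
#' @param method `"tukey"` (studentized range) or `"chisq"`.
#' @return Symmetric matrix of pairwise p-values, diagonal 1.
#' @export
nemenyi_posthoc <- function(values, groups, method = c("tukey", "chisq")) {
  method <- match.arg(method)
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) stop("need at least two groups")
  N <- length(values)
  r <- rank(values)
  n_i <- tabulate(groups, nbins = k)
  if (any(n_i == 0)) stop("empty group")
  rbar <- tapply(r, groups, mean)
  ties <- table(r)
  tie_c <- 1 - sum(ties^3 - ties) / (N^3 - N)
  p <- matrix(1, k, k, dimnames = list(levels(groups), levels(groups)))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      se2 <- (N * (N + 1) / 12) * (1 / n_i[i] + 1 / n_i[j])
      diff <- abs(rbar[i] - rbar[j])
      pij <- if (method == "tukey") {
        stats::ptukey(diff / sqrt(se2) * sqrt(2), nmeans = k, df = Inf,
                      lower.tail = FALSE)
      } else {
        stats::pchisq(diff^2 / se2 / tie_c, df = k - 1, lower.tail = FALSE)
      }
      p[i, j] <- p[j, i] <- unname(pij)
    }
  }
  p
}

#' Spearman correlation groups
#'
#' Computes Spearman rank correlations between all variable pairs, links
#' pairs with `|r| >= threshold`, and reports the connected components of
#' size two or more, each with the minimum and maximum intra-group `|r|`
#' (over all pairs inside the group, so sub-threshold pairs swallowed by
#' transitivity remain visible). Constant columns are excluded with a
#' warning.
#'
#' @param values Numeric matrix, variables in columns (e.g.
#'   `build_variable_matrix(...)$values`).
#' @param threshold Absolute correlation threshold for linking (default
#'   0.75).
#' @return List with `groups` (each a list: `variables`, `min_abs_r`,
#'   `max_abs_r`), `threshold`, and the full `correlation` matrix.
#' @export
spearman_groups <- function(values, threshold = 0.75) {
  if (ncol(values) < 2) stop("need at least two variables")
  constant <- apply(values, 2, function(x) stats::sd(x) == 0)
  if (any(constant)) {
    warning("excluding constant column(s): ",
            paste(colnames(values)[constant], collapse = ", "))
    values <- values[, !constant, drop = FALSE]
  }
  rho <- stats::cor(values, method = "spearman")
  adj <- abs(rho) >= threshold
  diag(adj) <- FALSE
  # connected components by label propagation (union-find on a small graph)
  p <- ncol(values)
  comp <- seq_len(p)
  find <- function(i) {
    while (comp[i] != i) i <- comp[i]
    i
  }
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      if (adj[i, j]) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(p), find, integer(1))
  groups <- list()
  for (root in unique(roots)) {
    members <- which(roots == root)
    if (length(members) < 2) next
    sub <- abs(rho[members, members])
    off <- sub[upper.tri(sub)]
    groups[[length(groups) + 1]] <- list(
      variables = colnames(values)[members],
      min_abs_r = min(off),
      max_abs_r = max(off)
    )
  }
  # largest groups first, ties by first variable name for determinism
  if (length(groups)) {
    ord <- order(-vapply(groups, function(g) length(g$variables), integer(1)),
                 vapply(groups, function(g) g$variables[1], character(1)))
    groups <- groups[ord]
  }
  list(groups = groups, threshold = threshold, correlation = rho)
}

#' Correlation principal component analysis
#'
#' PCA on z-scored columns (correlation PCA) by default, since the variables
#' mix units and scales. Eigen-fractions are the per-component shares of
#' total inertia, in descending order.
#'
#' @param values Numeric matrix, variables in columns.
#' @param standardize Scale columns to unit variance (default TRUE).
#' @return List with `loadings` (variables x components), `eigen_fractions`,
#'   `scores` (rows x components) and `sdev`.
#' @export
pca_variables <- function(values, standardize = TRUE) {
  constant <- apply(values, 2, function(x) stats::sd(x) == 0)
  if (any(constant)) {
    stop("constant column(s) cannot be standardized: ",
         paste(colnames(values)[constant], collapse = ", "))
  }
  fit <- stats::prcomp(values, center = TRUE, scale. = standardize)
  list(
    loadings = fit$rotation,
    eigen_fractions = fit$sdev^2 / sum(fit$sdev^2),
    scores = fit$x,
    sdev = fit$sdev
  )
}

#' Ward hierarchical clustering on principal-component coordinates
#'
#' Agglomerative clustering with Ward's inertia criterion on Euclidean
#' distances over the first `n_axes` PCA score columns.
#'
#' @param scores Score matrix from [pca_variables()].
#' @param n_axes Number of leading components to use (default 3).
#' @return An object of class `hclust`.
#' @export
ward_hca <- function(scores, n_axes = 3) {
  if (nrow(scores) < 2) stop("need at least two rows to cluster")
  n_axes <- min(n_axes, ncol(scores))
  stats::hclust(stats::dist(scores[, seq_len(n_axes), drop = FALSE]),
                method = "ward.D2")
}
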