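# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# full-scale synthetic corpus at the default class counts (710 sequences)
full_corpus <- function() {
  if (is.null(.fixture_env$corpus)) {
    .fixture_env$corpus <- generate_corpus(default_class_specs(), seed = 42)
  }
  .fixture_env$corpus
}

# reduced corpus (~1/5 of the class counts) for the heavier statistics tests
small_corpus <- function() {
  if (is.null(.fixture_env$small)) {
    specs <- lapply(default_class_specs(), function(s) {
      s$count <- max(8L, as.integer(round(s$count / 5)))
      s
    })
    .fixture_env$small <- generate_corpus(specs, seed = 11)
  }
  .fixture_env$small
}

# exact Kruskal-Wallis permutation p-value by full enumeration of the group
# relabelings (two or three equal-sized groups, n <= 12)
kw_permutation_p <- function(values, groups) {
  groups <- as.integer(factor(groups))
  n <- length(values)
  k <- max(groups)
  sizes <- tabulate(groups)
  obs <- kruskal_wallis(values, groups)$h_statistic
  hits <- 0L
  total <- 0L
  if (k == 2) {
    picks <- utils::combn(n, sizes[1])
    for (a in seq_len(ncol(picks))) {
      lab <- rep(2L, n)
      lab[picks[, a]] <- 1L
      h <- kruskal_wallis(values, lab)$h_statistic
      total <- total + 1L
      if (h >= obs - 1e-9) hits <- hits + 1L
    }
  } else if (k == 3) {
    picks1 <- utils::combn(n, sizes[1])
    for (a in seq_len(ncol(picks1))) {
      g1 <- picks1[, a]
      rest <- setdiff(seq_len(n), g1)
      picks2 <- utils::combn(rest, sizes[2])
      for (b in seq_len(ncol(picks2))) {
        lab <- rep(3L, n)
        lab[g1] <- 1L
        lab[picks2[, b]] <- 2L
        h <- kruskal_wallis(values, lab)$h_statistic
        total <- total + 1L
        if (h >= obs - 1e-9) hits <- hits + 1L
      }
    }
  } else {
    stop("oracle supports 2 or 3 groups")
  }
  hits / total
}

seq_tbl <- function(residues, id = sprintf("s%02d", seq_along(residues))) {
  tibble::tibble(id = id, description = "", residues = residues,
                 source = "input")
}
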