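test_that("normality battery rejects heavy skew and passes normal draws", {
  set.seed(3)
  nb <- normality_battery(rexp(500))
  expect_lt(nb$shapiro_p, 0.001)
  expect_lt(nb$ks_p, 0.001)
  # normal draws pass in at least 18 of 20 seeds at the 1% level
  passes <- 0
  for (s in 1:20) {
    set.seed(s)
    nb <- normality_battery(rnorm(500))
    if (nb$shapiro_p > 0.01 && nb$ks_p > 0.01) passes <- passes + 1
  }
  expect_gte(passes, 18)
  expect_error(normality_battery(rep(1, 10)), "constant")
  expect_error(normality_battery(c(1, 2)), "at least 3")
})

test_that("Kruskal-Wallis reproduces the closed-form rank statistic", {
  # H = 12/(N(N+1)) * sum(R_i^2/n_i) - 3(N+1) for {1,2,3} vs {4,5,6}:
  # rank sums 6 and 15 -> H = 12/42 * (36/3 + 225/3) - 21 = 3.857
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(1:2, each = 3))
  expect_equal(kw$h_statistic, 3.857, tolerance = 5e-4)
  expect_equal(kw$df, 1L)
  # all-equal sample: H = 0, p = 1 under the tie-correction convention
  kw0 <- kruskal_wallis(rep(2, 9), rep(1:3, each = 3))
  expect_equal(kw0$h_statistic, 0)
  expect_equal(kw0$p_value, 1)
  expect_equal(kw0$df, 2L)
  expect_error(kruskal_wallis(1:5, rep(1, 5)), "two groups")
})

test_that("Kruskal-Wallis holds its nominal type-I level on null draws", {
  rejections <- 0
  n_rep <- 200
  for (s in seq_len(n_rep)) {
    set.seed(s)
    v <- rnorm(24)
    kw <- kruskal_wallis(v, rep(1:2, each = 12))
    if (kw$p_value <= 0.05) rejections <- rejections + 1
  }
  # nominal 5% level; bound leaves ~3 binomial standard deviations of slack
  expect_lte(rejections / n_rep, 0.10)
})

test_that("chi-square p stays near the exact permutation p at small n", {
  # in the significance regime the approximation is close; across the whole
  # p range the gap stays bounded (the approximation is anti-conservative
  # for mid-range p at n = 12)
  worst <- 0
  for (s in 1:6) {
    set.seed(s + 50)
    v <- round(rnorm(12), 2)
    g <- rep(1:2, each = 6)
    gap <- abs(kruskal_wallis(v, g)$p_value - kw_permutation_p(v, g))
    worst <- max(worst, gap)
  }
  expect_lte(worst, 0.08)
})

test_that("Nemenyi post-hoc matrices are symmetric with sensible ordering", {
  set.seed(21)
  v <- c(rnorm(10, 0), rnorm(10, 0.3), rnorm(10, 6))
  g <- rep(c("a", "b", "c"), each = 10)
  p <- nemenyi_posthoc(v, g)
  expect_equal(p, t(p))
  expect_true(all(diag(p) == 1))
  expect_true(all(p >= 0 & p <= 1))
  # the widely separated pair (a, c) has the smallest p; the overlapping
  # pair (a, b) the largest
  off <- c(ab = p["a", "b"], ac = p["a", "c"], bc = p["b", "c"])
  expect_equal(names(which.min(off)), "ac")
  expect_equal(names(which.max(off)), "ab")
  # identical duplicated groups are not separated
  set.seed(22)
  base <- rnorm(12)
  p2 <- nemenyi_posthoc(c(base, base), rep(1:2, each = 12))
  expect_gt(p2[1, 2], 0.5)
  # chisq variant agrees qualitatively
  p3 <- nemenyi_posthoc(v, g, method = "chisq")
  expect_equal(names(which.min(c(ab = p3["a", "b"], ac = p3["a", "c"],
                                 bc = p3["b", "c"]))), "ac")
  expect_error(nemenyi_posthoc(1:5, rep(1, 5)), "two groups")
})

test_that("Spearman groups are rank-based components over |r| >= threshold", {
  set.seed(31)
  n <- 200
  base <- rnorm(n)
  m <- cbind(
    v1 = base,
    v2 = base^3,            # monotone transform: rho = 1
    v3 = -base,             # rho = -1, linked through |r|
    v4 = base + rnorm(n, sd = 0.3),
    v5 = base + rnorm(n, sd = 0.3),
    n1 = rnorm(n),
    n2 = rnorm(n)
  )
  sg <- spearman_groups(m, threshold = 0.75)
  expect_length(sg$groups, 1L)
  expect_setequal(sg$groups[[1]]$variables, c("v1", "v2", "v3", "v4", "v5"))
  expect_gte(sg$groups[[1]]$max_abs_r, sg$groups[[1]]$min_abs_r)
  expect_equal(sg$groups[[1]]$max_abs_r, 1)
  # invariance to monotone transforms of any column
  m2 <- m
  m2[, "v4"] <- exp(m2[, "v4"])
  sg2 <- spearman_groups(m2, threshold = 0.75)
  expect_equal(sg2$groups, sg$groups)
  # constant columns excluded with a warning
  expect_warning(spearman_groups(cbind(m, cst = 1)), "constant")
  expect_error(spearman_groups(m[, 1, drop = FALSE]), "two variables")
})

test_that("correlation PCA normalizes inertia and reconstructs the data", {
  set.seed(41)
  x <- matrix(rnorm(300), ncol = 6)
  colnames(x) <- paste0("v", 1:6)
  fit <- pca_variables(x)
  expect_equal(sum(fit$eigen_fractions), 1, tolerance = 1e-9)
  expect_true(all(diff(fit$eigen_fractions) <= 1e-12))
  # orthogonal scores: covariance diagonal
  cv <- crossprod(fit$scores) / (nrow(x) - 1)
  expect_equal(unname(cv), diag(diag(cv)), tolerance = 1e-8)
  # reconstruction of the standardized matrix with all components
  z <- scale(x)
  rec <- fit$scores %*% t(fit$loadings)
  expect_equal(unname(rec), unname(z[, ]), tolerance = 1e-8)
  # two perfectly correlated standardized columns: first axis carries all
  y <- cbind(a = x[, 1], b = 2 * x[, 1] + 3)
  fit2 <- pca_variables(y)
  expect_equal(fit2$eigen_fractions[1], 1, tolerance = 1e-12)
  expect_error(pca_variables(cbind(x, cst = 1)), "constant")
})

test_that("Ward clustering recovers separated blobs with monotone heights", {
  set.seed(51)
  blob1 <- matrix(rnorm(60, mean = 0), ncol = 3)
  blob2 <- matrix(rnorm(60, mean = 8), ncol = 3)
  scores <- rbind(blob1, blob2)
  hc <- ward_hca(scores, n_axes = 3)
  expect_true(!is.unsorted(hc$height))
  cut <- stats::cutree(hc, k = 2)
  expect_equal(length(unique(cut[1:20])), 1L)
  expect_equal(length(unique(cut[21:40])), 1L)
  expect_true(cut[1] != cut[21])
  # duplicated rows merge first at height zero
  dup <- rbind(scores, scores[1, , drop = FALSE])
  hc2 <- ward_hca(dup, n_axes = 3)
  expect_equal(hc2$height[1], 0, tolerance = 1e-12)
  expect_error(ward_hca(scores[1, , drop = FALSE]), "two rows")
})

test_that("class factor separates the strongly biased variables on the corpus", {
  corp <- small_corpus()
  vm <- build_variable_matrix(corp, as.character(corp$class_id))
  expect_equal(ncol(vm$values), 40L) # 12 physchem + 20 ratios + 8 combinations
  expect_false(anyNA(vm$values))
  kw <- kw_screen(vm)
  strong <- c("usage_H", "usage_C", "usage_K", "foldindex", "gravy",
              "mean_net_charge", "flexibility", "[K+R]", "[D+E]")
  expect_true(all(kw$p_value[kw$variable %in% strong] < 0.001))
  expect_true(all(kw$df == 11L))
})
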