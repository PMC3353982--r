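test_that("packaged scales are complete and match cited spot values", {
  scales <- c("kyte_doolittle", "hopp_woods", "eisenberg",
              "bulkiness_zimmerman", "flexibility_bhaskaran",
              "janin_accessible", "janin_buried", "zhao_london_tm")
  for (s in scales) {
    v <- aa_scale(s)
    expect_length(v, 20L)
    expect_true(all(is.finite(v)), info = s)
    expect_setequal(names(v), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  }
  # three spot values per scale against the cited publications
  kd <- aa_scale("kyte_doolittle")
  expect_equal(unname(kd[c("I", "R", "G")]), c(4.5, -4.5, -0.4))
  hw <- aa_scale("hopp_woods")
  expect_equal(unname(hw[c("K", "W", "G")]), c(3.0, -3.4, 0.0))
  ei <- aa_scale("eisenberg")
  expect_equal(unname(ei[c("I", "R", "A")]), c(1.38, -2.53, 0.62))
  bu <- aa_scale("bulkiness_zimmerman")
  expect_equal(unname(bu[c("G", "W", "A")]), c(3.40, 21.67, 11.50))
  fl <- aa_scale("flexibility_bhaskaran")
  expect_equal(unname(fl[c("G", "M", "K")]), c(0.544, 0.295, 0.466))
  ja <- aa_scale("janin_accessible")
  expect_equal(unname(ja[c("K", "C", "S")]), c(10.3, 0.9, 9.4))
  jb <- aa_scale("janin_buried")
  expect_equal(unname(jb[c("V", "K", "G")]), c(12.9, 0.5, 11.8))
  zl <- aa_scale("zhao_london_tm")
  expect_equal(unname(zl[c("F", "K", "A")]), c(1.98, -3.46, 0.38))
  expect_equal(nrow(aa_scale_citations()), length(scales))
})

test_that("scale means average per included position and exclude X", {
  expect_equal(mean_scale_value("AIV", "kyte_doolittle"), 3.5) # (1.8+4.5+4.2)/3
  expect_equal(mean_scale_value("G", "hopp_woods"),
               unname(aa_scale("hopp_woods")["G"]))
  expect_equal(mean_scale_value("GXG", "kyte_doolittle"),
               mean_scale_value("GG", "kyte_doolittle"))
  expect_error(mean_scale_value("XXX", "kyte_doolittle"), "no canonical")
  # composition-determined: invariant under permutation/reversal
  set.seed(5)
  for (i in 1:10) {
    s <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 50,
                      replace = TRUE), collapse = "")
    r <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(mean_scale_value(s, "eisenberg"),
                 mean_scale_value(r, "eisenberg"))
  }
  # means stay within the scale range
  v <- mean_scale_value(full_corpus()$residues[1:50], "bulkiness_zimmerman")
  sc <- aa_scale("bulkiness_zimmerman")
  expect_true(all(v >= min(sc) & v <= max(sc)))
})

test_that("molecular weight is residue masses plus one water", {
  # free glycine 75.07 Da; condensation arithmetic for the dipeptide
  expect_equal(molecular_weight("G"), 57.0519 + 18.01524, tolerance = 1e-6)
  expect_equal(molecular_weight("GG"), 2 * 57.0519 + 18.01524,
               tolerance = 1e-6)
  # mw/length of poly-G decreases monotonically toward the residue mass
  lens <- c(2, 5, 20, 100)
  mwl <- molecular_weight(strrep("G", lens)) / lens
  expect_true(all(diff(mwl) < 0))
  expect_gt(min(mwl), 57.0519)
  expect_error(molecular_weight("GXG"), "X")
})

test_that("net charge follows Henderson-Hasselbalch expectations", {
  expect_lt(net_charge("DDDD", ph = 7)$total_charge, 0)
  # at pH 0 every basic group is protonated: + (nH + nK + nR + 1)
  expect_equal(net_charge("KKHR", ph = 0)$total_charge, 5, tolerance = 0.01)
  # closed-form single lysine at pH 7 with the packaged pKa set
  pk <- pka_set()
  expected <- sum(vapply(c("K", "nterm"), function(g) {
    1 / (1 + 10^(7 - pk$pka[pk$group == g]))
  }, numeric(1))) - 1 / (1 + 10^(pk$pka[pk$group == "cterm"] - 7))
  got <- net_charge("K", ph = 7)
  expect_equal(got$total_charge, expected, tolerance = 1e-12)
  expect_equal(got$mean_charge, expected, tolerance = 1e-12)
  expect_equal(got$total_charge, 1, tolerance = 0.05)
  # monotone non-increasing in pH
  phs <- seq(0, 14, by = 0.5)
  tc <- vapply(phs, function(p) net_charge("MKDERHCY", ph = p)$total_charge,
               numeric(1))
  expect_true(all(diff(tc) < 0))
})

test_that("isoelectric point is the zero of the net charge", {
  seqs <- c("DDDD", "KKKK", "MKDERH", "GGG")
  pis <- isoelectric_point(seqs)
  for (i in seq_along(seqs)) {
    expect_lt(abs(net_charge(seqs[i], ph = pis[i])$total_charge), 1e-3)
  }
  expect_lt(pis[1], 7) # acidic
  expect_gt(pis[2], 7) # basic
})

test_that("FoldIndex combines rescaled hydropathy and mean charge", {
  # poly-K: <H>_n = (-3.9+4.5)/9, <R> ~ +1
  expect_equal(foldindex(strrep("K", 20)), -1.96, tolerance = 0.01)
  # poly-I: maximal hydropathy, essentially no charge
  expect_gt(foldindex(strrep("I", 20)), 0)
  # identity FI = 2.785*<H>_n - |<R>| - 1.151 holds exactly (FI crosses 0
  # where <H>_n hits (|<R>| + 1.151)/2.785)
  s <- full_corpus()$residues[1:20]
  h <- (mean_scale_value(s, "kyte_doolittle") + 4.5) / 9
  r <- net_charge(s, ph = 7)$mean_charge
  expect_equal(foldindex(s), 2.785 * h - abs(r) - 1.151, tolerance = 1e-12)
})

test_that("descriptor table is consistent with the single-purpose operations", {
  recs <- seq_tbl(c("GGGG", "MKVLDERHW", "AAAACCCC"))
  d <- compute_descriptors(recs)
  expect_equal(d$mw_per_length, d$mw / d$length)
  expect_equal(d$gravy, mean_scale_value(recs$residues, "kyte_doolittle"))
  expect_equal(d$hydrophobicity_h, mean_scale_value(recs$residues, "eisenberg"))
  expect_equal(d$foldindex, foldindex(recs$residues))
  expect_equal(d$pct_G[1], 100)
  pct_cols <- as.matrix(d[, grepl("^pct_", names(d))])
  expect_equal(unname(rowSums(pct_cols)), rep(100, 3), tolerance = 1e-9)
})
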