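test_that("dialect tokens behave as documented", {
  # end anchor
  m <- compile_motif("DSD$")
  expect_equal(motif_match(m, c("MKDSD", "MKDSDA")), c(TRUE, FALSE))
  expect_true(m$anchored_end)
  # token-by-token expansion of a bounded repetition
  expect_true(motif_match(compile_motif("[HY]K.{2,2}[AG]Y"), "MHKAAGY"))
  expect_false(motif_match(compile_motif("[HY]K.{2,2}[AG]Y"), "MHKAGY"))
  # negated set semantics (and the typographic wedge glyph)
  expect_false(motif_match(compile_motif("[^LNP]"), "L"))
  expect_true(motif_match(compile_motif("[^LNP]"), "A"))
  expect_false(motif_match(compile_motif("[∧LNP]"), "N"))
  # optional token and alternation
  m46 <- compile_motif("QQN(KTGCD)?$")
  expect_true(all(motif_match(m46, c("AQQN", "AQQNKTGCD"))))
  expect_false(motif_match(m46, "AQQNK"))
  malt <- compile_motif("(TAGEALEA)|(PGGVA)")
  expect_true(all(motif_match(malt, c("XXPGGVAXX", "TAGEALEAKK"))))
  # wildcards match amino acids only, never the ambiguity letter X
  expect_false(motif_match(compile_motif("K.K"), "KXK"))
  expect_false(motif_match(compile_motif("K[^A]K"), "KXK"))
  expect_true(motif_match(compile_motif("K.K"), "KGK"))
})

test_that("malformed patterns are rejected with informative errors", {
  expect_error(compile_motif("A[GC"), "unbalanced")
  expect_error(compile_motif("A(GC"), "unbalanced")
  expect_error(compile_motif("A{2}"), "repetition")
  expect_error(compile_motif("A{3,1}"), "bound")
  expect_error(compile_motif("AG#"), "unknown token")
  expect_error(compile_motif("AB"), "unknown token") # B is not canonical
  expect_error(compile_motif("A$B"), "after")
  expect_error(compile_motif(""), "empty")
  expect_error(compile_motif("[]A"), "empty residue set")
})

test_that("all 12 packaged class motifs compile, with unique class ids", {
  motifs <- leap_motifs()
  expect_length(motifs, 12L)
  expect_equal(names(motifs), as.character(1:12))
  expect_s3_class(motifs[["4"]], "leap_motif")
  # class 4 is a pure 19-branch alternation; class 6 parses its nested tokens
  expect_length(motifs[["4"]]$ast$branches, 19L)
  expect_length(motifs[["6"]]$ast$branches, 1L)
})

test_that("classification assigns a class iff exactly one motif matches", {
  motifs <- leap_motifs()
  recs <- seq_tbl(c(
    "MMMKGSSEADKMMM",        # class-1 motif [GS]SSE.[DEG]
    "MMMM",                  # nothing
    "MMWADPAGMMMDSD"         # class-9 motif and class-3 anchored DSD
  ))
  calls <- classify_sequences(recs, motifs)
  expect_equal(calls$label, c("1", "unclassified", "ambiguous"))
  expect_equal(calls$matched_classes[3], "3,9")
  expect_error(classify_sequences(recs, list()), "empty motif list")
})

test_that("classification is order-independent with respect to the motif list", {
  motifs <- leap_motifs()
  corp <- small_corpus()[seq(1, 150, by = 7), ]
  a <- classify_sequences(corp, motifs)
  b <- classify_sequences(corp, rev(motifs))
  expect_equal(a$label, b$label)
  expect_equal(
    lapply(strsplit(a$matched_classes, ","), sort),
    lapply(strsplit(b$matched_classes, ","), sort)
  )
})

test_that("audit_nonoverlap partitions any dataset", {
  motifs <- leap_motifs()
  empty <- seq_tbl(character())
  aud0 <- audit_nonoverlap(empty, motifs)
  expect_equal(sum(aud0$class_counts), 0L)
  expect_equal(aud0$n, 0L)

  dual <- seq_tbl("MMWADPAGMMMDSD")
  aud1 <- audit_nonoverlap(dual, motifs)
  expect_equal(length(aud1$ambiguous_ids), 1L)

  corp <- small_corpus()
  aud <- audit_nonoverlap(corp, motifs)
  expect_equal(sum(aud$class_counts) + length(aud$ambiguous_ids) +
                 length(aud$unclassified_ids), nrow(corp))
  expect_length(aud$ambiguous_ids, 0L)
})

test_that("compiled matchers agree with the brute-force interpreter", {
  # fixed corner cases first
  cases <- list(
    c("DSD$", "MKDSD"), c("DSD$", "DSDM"), c("A?G?C?", ""),
    c("[^A]{2,}$", "GCD"), c("(AG)|(CD$)", "KCD"), c("(AG)|(CD$)", "CDK"),
    c("G{3,}", "AGGGGA"), c("G{3,}", "AGGA")
  )
  for (cs in cases) {
    expect_equal(motif_match(compile_motif(cs[1]), cs[2]),
                 oracle_match(cs[1], cs[2]),
                 info = paste(cs, collapse = " on "))
  }
  # randomized agreement, with motif-expansion implants to balance positives
  set.seed(101)
  n_pos <- 0
  for (i in 1:1000) {
    pat <- random_pattern()
    s <- random_sequence()
    if (runif(1) < 0.5 && !grepl("\\$", pat)) {
      imp <- tryCatch(expand_motif(pat)$residues, error = function(e) "")
      s <- paste0(s, imp, random_sequence(0, 5))
    }
    got <- motif_match(compile_motif(pat), s)
    want <- oracle_match(pat, s)
    if (want) n_pos <- n_pos + 1
    expect_equal(got, want, info = paste0("pattern=", pat, " seq=", s))
  }
  expect_gt(n_pos, 200) # the case mix genuinely exercises both outcomes
})
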