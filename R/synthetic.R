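## Synthetic LEAPdb-like corpora.
##
## The generator emulates the structure of the curated LEAP corpus so every
## pipeline stage is testable without external data: per-class sequence
## counts and length ranges from the class table, exactly one implanted
## occurrence of the class motif per sequence (and no match to any other
## class motif, enforced by rejection), and residue usage biased to follow
## the per-class +1/-1 usage signs. It makes no attempt to reproduce real
## LEAP sequences or the true per-class property distributions.

.BIAS_UP <- 1.6    # multiplier for residues with a +1 usage sign
.BIAS_DOWN <- 0.6  # multiplier for residues with a -1 usage sign

## residues reported (nearly) absent from specific classes: forced to zero
.CLASS_FORBID <- list(
  `3` = c("C", "W"),
  `5` = "C",
  `10` = c("C", "F", "W"),
  `12` = c("C", "F", "W")
)

## class-specific multiplier overrides (class 3 uses His up to 6-fold)
.CLASS_OVERRIDE <- list(`3` = c(H = 6.0))

#' Default per-class generation specs
#'
#' One spec per LEAP class: the class motif, the class sequence count and
#' length range from the packaged class table, usage-bias multipliers derived
#' from the per-class usage signs (+1 -> 1.6, -1 -> 0.6, with class-specific
#' overrides such as the 6-fold His enrichment of class 3), and the residues
#' forced absent where the class is reported to lack them.
#'
#' @param background Background composition the biases multiply.
#' @return Named list of specs; each spec has `class_id`, `count`,
#'   `length_range`, `weights` (renormalized sampling probabilities),
#'   `forbid` and `motif`.
#' @export
default_class_specs <- function(background = background_composition()) {
  tab <- leap_class_table()
  signs <- leap_usage_signs()
  motifs <- leap_motifs()
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    cid <- tab$class_id[i]
    key <- as.character(cid)
    sg <- unlist(signs[signs$class_id == cid, AA_CANONICAL])
    mult <- ifelse(sg > 0, .BIAS_UP, .BIAS_DOWN)
    names(mult) <- AA_CANONICAL
    over <- .CLASS_OVERRIDE[[key]]
    if (!is.null(over)) mult[names(over)] <- over
    forbid <- .CLASS_FORBID[[key]]
    if (is.null(forbid)) forbid <- character()
    w <- background$percent * mult
    w[forbid] <- 0
    list(
      class_id = cid,
      count = tab$n_sequences[i],
      length_range = c(tab$len_min[i], tab$len_max[i]),
      weights = w / sum(w),
      forbid = forbid,
      motif = motifs[[key]]
    )
  })
  names(specs) <- as.character(tab$class_id)
  specs
}

#' Sample a concrete expansion of a motif
#'
#' Draws one residue string matching the motif: repetition counts are sampled
#' uniformly within their bounds (open-ended `{n,}` capped at `n + cap`),
#' alternation branches uniformly, and free positions (`.` and negated sets)
#' uniformly over the canonical alphabet minus `forbid`.
#'
#' @param motif `leap_motif` object (or a dialect pattern string).
#' @param forbid Residues excluded from free-position draws.
#' @param cap Cap added to `n` for open-ended repetitions.
#' @return List with `residues` (the expansion) and `anchored` (TRUE when
#'   the sampled branch carries a `'$'` anchor, i.e. must sit at the
#'   sequence end).
#' @export
expand_motif <- function(motif, forbid = character(), cap = 10) {
  if (is.character(motif)) motif <- compile_motif(motif)
  pool_any <- setdiff(AA_CANONICAL, forbid)
  pick <- function(x) x[sample.int(length(x), 1)] # safe for length-1 pools

  expand_atom <- function(term) {
    switch(term$type,
      lit = term$chars,
      any = pick(pool_any),
      set = {
        pool <- if (term$negated) {
          setdiff(AA_CANONICAL, c(term$chars, forbid))
        } else {
          p <- setdiff(term$chars, forbid)
          if (length(p)) p else term$chars
        }
        pick(pool)
      },
      group = expand_alt(term$node)$residues,
      stop("internal: unexpected term type")
    )
  }

  expand_seq <- function(node) {
    parts <- vapply(node$terms, function(term) {
      hi <- if (is.infinite(term$max)) term$min + cap else term$max
      k <- if (hi > term$min) sample(seq(term$min, hi), 1) else term$min
      if (k == 0) return("")
      paste(vapply(seq_len(k), function(.) expand_atom(term), character(1)),
            collapse = "")
    }, character(1))
    list(residues = paste(parts, collapse = ""), anchored = node$anchored)
  }

  expand_alt <- function(node) {
    expand_seq(node$branches[[sample(length(node$branches), 1)]])
  }

  expand_alt(motif$ast)
}

#' Generate one class-conditioned sequence
#'
#' Draws a sequence length uniformly within the class length range, fills it
#' with background residues reweighted by the class usage bias, implants one
#' motif expansion at a random position (at the end for `'$'`-anchored
#' expansions), and rejection-resamples until the record matches its own
#' class motif and no other.
#'
#' @param spec One spec from [default_class_specs()].
#' @param motifs The full compiled motif set (for cross-match rejection).
#' @param max_tries Rejection budget.
#' @return Single-row sequence tibble (without id).
#' @export
generate_class_sequence <- function(spec, motifs = leap_motifs(),
                                    max_tries = 200) {
  for (try in seq_len(max_tries)) {
    len <- sample(seq(spec$length_range[1], spec$length_range[2]), 1)
    exp <- NULL
    for (e in seq_len(100)) {
      cand <- expand_motif(spec$motif, forbid = spec$forbid)
      if (nchar(cand$residues) <= len) {
        exp <- cand
        break
      }
    }
    if (is.null(exp)) next
    chars <- sample(AA_CANONICAL, len, replace = TRUE, prob = spec$weights)
    m <- nchar(exp$residues)
    start <- if (exp$anchored) len - m + 1 else sample(seq_len(len - m + 1), 1)
    chars[seq(start, start + m - 1)] <-
      strsplit(exp$residues, "", fixed = TRUE)[[1]]
    seq_str <- paste(chars, collapse = "")
    hits <- vapply(motifs, function(mo) motif_match(mo, seq_str), logical(1))
    own <- names(motifs) == as.character(spec$class_id)
    if (all(hits[own]) && !any(hits[!own])) {
      return(.new_sequence_tbl(NA_character_, "", seq_str, "synthetic"))
    }
  }
  stop("rejection budget exhausted for class ", spec$class_id)
}

#' Generate a labelled synthetic corpus
#'
#' Generates class-conditioned sequences for every spec (defaults: the
#' class-table counts, 710 sequences in total) and returns them with their
#' intended class labels. Reproducible under a fixed seed.
#'
#' @param specs List of class specs (see [default_class_specs()]).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return Sequence tibble with an extra `class_id` column of intended
#'   labels.
#' @export
generate_corpus <- function(specs = default_class_specs(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  motifs <- lapply(specs, function(s) s$motif)
  names(motifs) <- vapply(specs, function(s) as.character(s$class_id),
                          character(1))
  out <- lapply(specs, function(spec) {
    recs <- dplyr::bind_rows(lapply(seq_len(spec$count), function(i) {
      generate_class_sequence(spec, motifs)
    }))
    recs$id <- sprintf("c%02d_%04d", spec$class_id, seq_len(spec$count))
    recs$class_id <- spec$class_id
    recs
  })
  dplyr::bind_rows(out)
}

#' Generate disorder / structure control sets
#'
#' `idp_like`: draws enriched in charged and flexibility-promoting residues,
#' rejection-filtered to FoldIndex <= 0 (the plant-IDP control convention).
#' `fs_like`: draws enriched in hydrophobic residues, filtered to
#' FoldIndex > 0 (a fully-structured-protein stand-in).
#'
#' @param kind `"idp_like"` or `"fs_like"`.
#' @param n Number of sequences.
#' @param length_range Length range (uniform draw).
#' @param background Background composition the enrichment multiplies.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param max_tries Rejection budget per sequence.
#' @return Sequence tibble (`source = "synthetic"`).
#' @export
generate_controls <- function(kind = c("idp_like", "fs_like"), n,
                              length_range = c(80, 300),
                              background = background_composition(),
                              seed = NULL, max_tries = 200) {
  kind <- match.arg(kind)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  mult <- stats::setNames(rep(1, 20), AA_CANONICAL)
  if (kind == "idp_like") {
    mult[c("D", "E", "K", "R")] <- 3
    mult[c("S", "G", "P", "Q")] <- 2
  } else {
    mult[c("I", "L", "V", "F")] <- 3
    mult[c("A", "M", "W", "C")] <- 2
  }
  w <- background$percent * mult
  w <- w / sum(w)
  keep <- if (kind == "idp_like") {
    function(fi) fi <= 0
  } else {
    function(fi) fi > 0
  }
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      len <- sample(seq(length_range[1], length_range[2]), 1)
      s <- paste(sample(AA_CANONICAL, len, replace = TRUE, prob = w),
                 collapse = "")
      if (keep(foldindex(s))) {
        recs[[i]] <- s
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("rejection budget exhausted for ", kind, " control set")
  }
  .new_sequence_tbl(
    sprintf("%s_%04d", sub("_like$", "", kind), seq_len(n)),
    "", unlist(recs), "synthetic"
  )
}
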