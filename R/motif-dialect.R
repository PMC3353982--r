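## The LEAP motif dialect.
##
## Class signatures are written in a compact regular-expression-like syntax:
##   literal residues        one of the 20 canonical letters
##   .                       any amino acid (canonical letters only, never X)
##   [XY]  [^XY]             residue set / negated residue set
##   T{n,}  T{n,m}           repetition (at least n / n to m times)
##   T?                      optional token
##   (M1)|(M2)               alternation: M1 or M2 (or both) occur
##   M$                      motif anchored to the sequence end
## A motif matches a sequence when at least one occurrence is found anywhere
## (or, with '$', ending exactly at the last residue). The negation glyph may
## be written as ASCII '^' or as the typographic wedge.

.NEGATION_GLYPHS <- c("^", "∧")

#' Parse a motif-dialect pattern
#'
#' Parses a pattern of the LEAP motif dialect into an abstract syntax tree.
#' Mostly useful internally ([compile_motif()] and [expand_motif()] both
#' operate on the tree), exported for inspection and testing.
#'
#' @param pattern Dialect pattern string. Whitespace is ignored.
#' @return A nested list: alternation nodes (`type = "alt"`) hold branches;
#'   branch nodes (`type = "seq"`) hold terms and an `anchored` flag; terms
#'   are `lit`, `any`, `set` or `group` atoms with `min`/`max` repetition
#'   counts (`max = Inf` for open-ended repetition).
#' @export
parse_motif <- function(pattern) {
  chars <- strsplit(gsub("[[:space:]]", "", pattern), "", fixed = TRUE)[[1]]
  if (!length(chars)) stop("empty motif pattern")
  pos <- 1L
  n <- length(chars)
  peek <- function() if (pos <= n) chars[pos] else NA_character_
  take <- function() {
    ch <- peek()
    pos <<- pos + 1L
    ch
  }
  fail <- function(...) stop("motif '", pattern, "': ", ...)

  parse_set <- function() {
    take() # '['
    negated <- FALSE
    if (!is.na(peek()) && peek() %in% .NEGATION_GLYPHS) {
      negated <- TRUE
      take()
    }
    members <- character()
    repeat {
      ch <- peek()
      if (is.na(ch)) fail("unbalanced '['")
      if (ch == "]") {
        take()
        break
      }
      if (!(ch %in% AA_CANONICAL)) fail("illegal residue '", ch, "' in set")
      members <- c(members, take())
    }
    if (!length(members)) fail("empty residue set")
    list(type = "set", chars = unique(members), negated = negated)
  }

  parse_repeat <- function() {
    take() # '{'
    digits1 <- character()
    while (!is.na(peek()) && grepl("[0-9]", peek())) digits1 <- c(digits1, take())
    if (!length(digits1) || is.na(peek()) || peek() != ",") {
      fail("malformed repetition (expected '{n,}' or '{n,m}')")
    }
    take() # ','
    digits2 <- character()
    while (!is.na(peek()) && grepl("[0-9]", peek())) digits2 <- c(digits2, take())
    if (is.na(peek()) || peek() != "}") fail("malformed repetition (missing '}')")
    take() # '}'
    lo <- as.integer(paste(digits1, collapse = ""))
    hi <- if (length(digits2)) as.integer(paste(digits2, collapse = "")) else Inf
    if (hi < lo) fail("repetition upper bound below lower bound")
    list(min = lo, max = hi)
  }

  parse_atom <- function() {
    ch <- peek()
    if (is.na(ch)) fail("unexpected end of pattern")
    if (ch == ".") {
      take()
      return(list(type = "any"))
    }
    if (ch == "[") return(parse_set())
    if (ch == "(") {
      take()
      node <- parse_alt()
      if (is.na(peek()) || peek() != ")") fail("unbalanced '('")
      take()
      return(list(type = "group", node = node))
    }
    if (ch %in% AA_CANONICAL) {
      take()
      return(list(type = "lit", chars = ch))
    }
    fail("unknown token '", ch, "'")
  }

  parse_seq <- function() {
    terms <- list()
    anchored <- FALSE
    repeat {
      ch <- peek()
      if (is.na(ch) || ch == "|" || ch == ")") break
      if (anchored) fail("tokens after '$'")
      if (ch == "$") {
        take()
        anchored <- TRUE
        next
      }
      atom <- parse_atom()
      atom$min <- 1
      atom$max <- 1
      ch <- peek()
      if (!is.na(ch) && ch == "?") {
        take()
        atom$min <- 0
      } else if (!is.na(ch) && ch == "{") {
        rep <- parse_repeat()
        atom$min <- rep$min
        atom$max <- rep$max
      }
      terms <- c(terms, list(atom))
    }
    if (!length(terms)) fail("empty motif branch")
    list(type = "seq", terms = terms, anchored = anchored)
  }

  parse_alt <- function() {
    branches <- list(parse_seq())
    while (!is.na(peek()) && peek() == "|") {
      take()
      branches <- c(branches, list(parse_seq()))
    }
    list(type = "alt", branches = branches)
  }

  ast <- parse_alt()
  if (pos <= n) fail("unexpected '", chars[pos], "'")
  ast
}

.regex_char_class <- function(chars, negated) {
  if (negated) chars <- setdiff(AA_CANONICAL, chars)
  if (!length(chars)) stop("residue set negates the whole alphabet")
  paste0("[", paste(chars, collapse = ""), "]")
}

.ast_to_regex <- function(node) {
  switch(node$type,
    alt = paste(vapply(node$branches, .ast_to_regex, character(1)),
                collapse = "|"),
    seq = {
      body <- paste(vapply(node$terms, .term_to_regex, character(1)),
                    collapse = "")
      if (node$anchored) paste0(body, "$") else body
    },
    stop("internal: unexpected node type ", node$type)
  )
}

.term_to_regex <- function(term) {
  atom <- switch(term$type,
    lit = term$chars,
    any = .regex_char_class(AA_CANONICAL, FALSE),
    set = .regex_char_class(term$chars, term$negated),
    group = paste0("(?:", .ast_to_regex(term$node), ")"),
    stop("internal: unexpected term type ", term$type)
  )
  quant <-
    if (term$min == 1 && term$max == 1) ""
    else if (term$min == 0 && term$max == 1) "?"
    else if (is.infinite(term$max)) paste0("{", term$min, ",}")
    else paste0("{", term$min, ",", term$max, "}")
  paste0(atom, quant)
}

#' Compile a motif-dialect pattern into a matcher
#'
#' Translates a dialect pattern into a PCRE regular expression over the
#' canonical alphabet. `'.'` and negated sets expand to explicit canonical
#' residue classes, so an ambiguous `X` in a sequence can never satisfy a
#' motif position.
#'
#' @inheritParams parse_motif
#' @return An object of class `leap_motif` with elements `pattern`, `regex`,
#'   `ast` and `anchored_end` (TRUE when any alternation branch carries a
#'   `'$'` anchor).
#' @examples
#' m <- compile_motif("DSD$")
#' motif_match(m, c("MKDSD", "MKDSDA"))
#' @export
compile_motif <- function(pattern) {
  ast <- parse_motif(pattern)
  structure(
    list(
      pattern = pattern,
      regex = .ast_to_regex(ast),
      ast = ast,
      anchored_end = any(vapply(ast$branches, function(b) b$anchored,
                                logical(1)))
    ),
    class = "leap_motif"
  )
}

#' @export
print.leap_motif <- function(x, ...) {
  cat("<leap_motif> ", x$pattern, "\n  regex: ", x$regex, "\n", sep = "")
  invisible(x)
}

#' Test sequences against a compiled motif
#'
#' @param motif A `leap_motif` from [compile_motif()].
#' @param residues Character vector of residue strings.
#' @return Logical vector: does each sequence contain at least one occurrence
#'   of the motif?
#' @export
motif_match <- function(motif, residues) {
  stopifnot(inherits(motif, "leap_motif"))
  grepl(motif$regex, residues, perl = TRUE)
}
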