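# Brute-force motif-dialect interpreter, independent of the package's
# regex-translation path. Parses a dialect pattern into token lists and walks
# an explicit position-set automaton over every start position. Used as the
# oracle for randomized compiler-vs-interpreter agreement tests.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

oracle_parse <- function(pattern) {
  src <- strsplit(gsub("[[:space:]]", "", pattern), "")[[1]]
  i <- 1L
  n <- length(src)
  cur <- function() if (i <= n) src[i] else NA_character_
  adv <- function() i <<- i + 1L

  read_int <- function() {
    d <- character()
    while (!is.na(cur()) && grepl("[0-9]", cur())) {
      d <- c(d, cur())
      adv()
    }
    if (!length(d)) NA_integer_ else as.integer(paste(d, collapse = ""))
  }

  p_atom <- function() {
    ch <- cur()
    if (ch == ".") {
      adv()
      return(list(kind = "class", ok = AA20))
    }
    if (ch == "[") {
      adv()
      neg <- FALSE
      if (cur() %in% c("^", "∧")) {
        neg <- TRUE
        adv()
      }
      mem <- character()
      while (cur() != "]") {
        mem <- c(mem, cur())
        adv()
      }
      adv()
      return(list(kind = "class",
                  ok = if (neg) setdiff(AA20, mem) else intersect(mem, AA20)))
    }
    if (ch == "(") {
      adv()
      node <- p_alt()
      stopifnot(cur() == ")")
      adv()
      return(list(kind = "group", node = node))
    }
    adv()
    list(kind = "class", ok = ch)
  }

  p_branch <- function() {
    toks <- list()
    anchored <- FALSE
    while (!is.na(cur()) && !(cur() %in% c("|", ")"))) {
      if (cur() == "$") {
        adv()
        anchored <- TRUE
        next
      }
      a <- p_atom()
      lo <- 1L
      hi <- 1L
      if (!is.na(cur()) && cur() == "?") {
        adv()
        lo <- 0L
      } else if (!is.na(cur()) && cur() == "{") {
        adv()
        lo <- read_int()
        stopifnot(cur() == ",")
        adv()
        hi <- read_int()
        if (is.na(hi)) hi <- .Machine$integer.max
        stopifnot(cur() == "}")
        adv()
      }
      a$lo <- lo
      a$hi <- hi
      toks <- c(toks, list(a))
    }
    list(tokens = toks, anchored = anchored)
  }

  p_alt <- function() {
    branches <- list(p_branch())
    while (!is.na(cur()) && cur() == "|") {
      adv()
      branches <- c(branches, list(p_branch()))
    }
    branches
  }

  out <- p_alt()
  stopifnot(i > n)
  out
}

# position-set automaton: every "position" is the index of the next character
# to consume (1-based; len+1 means the whole sequence is consumed)
oracle_match <- function(pattern, sequence) {
  branches <- oracle_parse(pattern)
  chars <- strsplit(sequence, "")[[1]]
  len <- length(chars)

  atom_once <- function(atom, pos) {
    if (atom$kind == "class") {
      if (pos <= len && chars[pos] %in% atom$ok) pos + 1L else integer()
    } else {
      ends <- integer()
      for (b in atom$node) {
        e <- run_tokens(b$tokens, pos)
        if (b$anchored) e <- e[e == len + 1L]
        ends <- c(ends, e)
      }
      unique(ends)
    }
  }

  step_token <- function(tok, positions) {
    reach <- if (tok$lo == 0L) positions else integer()
    frontier <- positions
    k <- 0L
    while (length(frontier) && k < tok$hi) {
      k <- k + 1L
      frontier <- unique(unlist(lapply(frontier, function(p) atom_once(tok, p))))
      if (k >= tok$lo) reach <- unique(c(reach, frontier))
      if (k > len + 1L) break
    }
    reach
  }

  run_tokens <- function(tokens, pos) {
    positions <- pos
    for (tok in tokens) {
      positions <- step_token(tok, positions)
      if (!length(positions)) return(integer())
    }
    positions
  }

  for (start in seq_len(len + 1L)) {
    for (b in branches) {
      ends <- run_tokens(b$tokens, start)
      hit <- if (b$anchored) any(ends == len + 1L) else length(ends) > 0
      if (hit) return(TRUE)
    }
  }
  FALSE
}

# random dialect pattern for the agreement property
random_pattern <- function() {
  atom <- function(allow_group = TRUE) {
    r <- runif(1)
    if (r < 0.35) {
      sample(AA20, 1)
    } else if (r < 0.5) {
      "."
    } else if (r < 0.7) {
      paste0("[", paste(sample(AA20, sample(2:4, 1)), collapse = ""), "]")
    } else if (r < 0.85) {
      paste0("[^", paste(sample(AA20, sample(1:3, 1)), collapse = ""), "]")
    } else if (allow_group) {
      inner <- paste(vapply(seq_len(sample(1:2, 1)), function(.) atom(FALSE),
                            character(1)), collapse = "")
      paste0("(", inner, ")")
    } else {
      sample(AA20, 1)
    }
  }
  quant <- function() {
    r <- runif(1)
    if (r < 0.6) "" else if (r < 0.7) "?" else if (r < 0.8) "{0,2}"
    else if (r < 0.9) "{1,3}" else if (r < 0.95) "{2,2}" else "{1,}"
  }
  branch <- function() {
    body <- paste(vapply(seq_len(sample(2:5, 1)),
                         function(.) paste0(atom(), quant()), character(1)),
                  collapse = "")
    if (runif(1) < 0.3) paste0(body, "$") else body
  }
  paste(vapply(seq_len(sample(1:2, 1)), function(.) branch(), character(1)),
        collapse = "|")
}

random_sequence <- function(min_len = 0, max_len = 30) {
  len <- sample(min_len:max_len, 1)
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}
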