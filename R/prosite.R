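# PROSITE-pattern grammar: parser, matcher and conserved-pattern induction.
# Syntax supported: residue literals, `x` wildcards, `[...]` ambiguity classes,
# `{...}` exclusion classes, `(n)` / `(n,m)` repetition ranges on any element,
# `<` / `>` anchors, `-` separators, optional trailing `.`.

#' Parse a PROSITE pattern
#'
#' @param text Pattern text, e.g. `"F-G-D-F-[GA]-N-D"` or `"<M-x(2,3)-[DE]>"`.
#' @return A `prosite_pattern` with the raw text, the compiled element list and
#'   anchor flags. Parsing and serialization ([format()]) round-trip.
#' @export
#' @examples
#' parse_prosite("F-G-D-F-[GA]-N-D")
parse_prosite <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- text
  s <- trimws(text)
  if (!nzchar(s)) stop("empty PROSITE pattern")
  s <- sub("\\.$", "", s)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  pos <- 1L
  anchor_start <- FALSE; anchor_end <- FALSE
  if (chars[pos] == "<") { anchor_start <- TRUE; pos <- pos + 1L }
  if (n >= 1L && chars[n] == ">") { anchor_end <- TRUE; n <- n - 1L }
  if (pos > n) stop("PROSITE parse error at column ", pos, ": no elements")

  err <- function(p, msg) stop("PROSITE parse error at column ", p, ": ", msg)
  elements <- list()
  expect_sep <- FALSE
  while (pos <= n) {
    ch <- chars[pos]
    if (expect_sep) {
      if (ch != "-") err(pos, "expected '-' separator")
      pos <- pos + 1L
      expect_sep <- FALSE
      next
    }
    el <- list(type = NULL, residues = NULL, min = 1L, max = 1L)
    if (ch %in% LETTERS && ch != "X") {
      el$type <- "literal"; el$residues <- ch; pos <- pos + 1L
    } else if (ch == "x" || ch == "X") {
      el$type <- "any"; pos <- pos + 1L
    } else if (ch == "[" || ch == "{") {
      close <- if (ch == "[") "]" else "}"
      el$type <- if (ch == "[") "class" else "exclusion"
      p2 <- pos + 1L
      res <- character(0)
      repeat {
        if (p2 > n) err(pos, paste0("unterminated '", ch, "' class"))
        if (chars[p2] == close) break
        if (!(chars[p2] %in% LETTERS)) err(p2, "illegal residue in class")
        res <- c(res, chars[p2]); p2 <- p2 + 1L
      }
      if (length(res) == 0L) err(p2, "empty class")
      el$residues <- res
      pos <- p2 + 1L
    } else {
      err(pos, paste0("unexpected character '", ch, "'"))
    }
    # optional repetition range
    if (pos <= n && chars[pos] == "(") {
      p2 <- pos + 1L
      digits <- ""
      while (p2 <= n && chars[p2] != ")") { digits <- paste0(digits, chars[p2]); p2 <- p2 + 1L }
      if (p2 > n) err(pos, "unterminated repetition range")
      if (!grepl("^[0-9]+(,[0-9]+)?$", digits)) err(pos + 1L, "malformed repetition range")
      parts <- as.integer(strsplit(digits, ",")[[1]])
      el$min <- parts[1]
      el$max <- if (length(parts) == 2L) parts[2] else parts[1]
      if (el$max < el$min) err(pos + 1L, "range maximum below minimum")
      pos <- p2 + 1L
    }
    elements[[length(elements) + 1L]] <- el
    expect_sep <- TRUE
  }
  if (!expect_sep) err(n, "trailing separator")
  structure(list(raw = raw, elements = elements,
                 anchor_start = anchor_start, anchor_end = anchor_end),
            class = "prosite_pattern")
}

#' @export
format.prosite_pattern <- function(x, ...) {
  fmt_el <- function(el) {
    core <- switch(el$type,
      literal = el$residues,
      any = "x",
      class = paste0("[", paste(el$residues, collapse = ""), "]"),
      exclusion = paste0("{", paste(el$residues, collapse = ""), "}"))
    if (el$min == 1L && el$max == 1L) return(core)
    if (el$min == el$max) return(paste0(core, "(", el$min, ")"))
    paste0(core, "(", el$min, ",", el$max, ")")
  }
  paste0(if (x$anchor_start) "<" else "",
         paste(vapply(x$elements, fmt_el, character(1)), collapse = "-"),
         if (x$anchor_end) ">" else "")
}

#' @export
print.prosite_pattern <- function(x, ...) {
  cat("<prosite_pattern> ", format(x), " (", length(x$elements),
      " elements)\n", sep = "")
  invisible(x)
}

element_allows <- function(el, ch) {
  switch(el$type,
    any = TRUE,
    literal = ch == el$residues,
    class = ch %in% el$residues,
    exclusion = !(ch %in% el$residues))
}

# backtracking matcher: greedy repetition with backtracking, i.e. the match
# semantics of the pattern's regular-expression translation
match_from <- function(chars, start, elements, ei, anchor_end) {
  if (ei > length(elements)) {
    if (anchor_end && start != length(chars) + 1L) return(NA_integer_)
    return(start - 1L) # end position of the match
  }
  el <- elements[[ei]]
  # longest admissible run of this element beginning at `start`
  kmax <- el$max
  run <- 0L
  while (run < kmax && (start + run) <= length(chars) &&
         element_allows(el, chars[start + run])) run <- run + 1L
  if (run < el$min) return(NA_integer_)
  for (k in seq(run, el$min)) {
    res <- match_from(chars, start + k, elements, ei + 1L, anchor_end)
    if (!is.na(res)) return(res)
  }
  NA_integer_
}

#' Match a PROSITE pattern against a protein
#'
#' Returns all non-overlapping leftmost matches; repetition ranges are matched
#' greedily with backtracking, equivalent to the regular-expression translation
#' of the pattern. Anchors `<` / `>` pin matches to the protein ends.
#'
#' @param pattern A [parse_prosite()] object (or pattern text).
#' @param protein Protein string.
#' @return Data frame with 1-based inclusive columns `start`, `end`.
#' @export
#' @examples
#' match_prosite("F-G-D-F-[GA]-N-D", "MKFGDFANDQ") # span 3-9
match_prosite <- function(pattern, protein) {
  if (is.character(pattern)) pattern <- parse_prosite(pattern)
  stopifnot(inherits(pattern, "prosite_pattern"))
  chars <- strsplit(protein, "")[[1]]
  out <- list()
  s <- 1L
  while (s <= length(chars)) {
    e <- match_from(chars, s, pattern$elements, 1L, pattern$anchor_end)
    if (!is.na(e) && e >= s) {
      out[[length(out) + 1L]] <- c(start = s, end = e)
      s <- e + 1L
    } else {
      s <- s + 1L
    }
    if (pattern$anchor_start) break
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  as.data.frame(do.call(rbind, out))
}

#' Induce a conserved PROSITE pattern from aligned sequences
#'
#' Simplified conserved-column induction (a PRATT-like summary of a gapless
#' alignment): per column, a single residue becomes a literal, at most
#' `max_class_size` distinct residues an ambiguity class (sorted), more a
#' wildcard; runs of wildcards are collapsed to `x(n)`. The induced pattern
#' matches every input sequence.
#'
#' @param proteins Character vector of equal-length (pre-aligned, gapless)
#'   sequences.
#' @param max_class_size Largest ambiguity class before collapsing to `x`.
#' @return A `prosite_pattern`.
#' @export
#' @examples
#' format(discover_pattern(c("FGDFGND", "FGDFAND"))) # "F-G-D-F-[AG]-N-D"
discover_pattern <- function(proteins, max_class_size = 3L) {
  stopifnot(length(proteins) >= 1L)
  lens <- nchar(proteins)
  if (length(unique(lens)) != 1L)
    stop("sequences must have equal length (align them first)")
  mat <- do.call(rbind, strsplit(proteins, ""))
  cols <- apply(mat, 2, function(col) sort(unique(col)))
  if (is.matrix(cols)) cols <- asplit(cols, 2) # single distinct residue per col
  toks <- vapply(cols, function(u) {
    if (length(u) == 1L) u
    else if (length(u) <= max_class_size) paste0("[", paste(u, collapse = ""), "]")
    else "x"
  }, character(1))
  # collapse wildcard runs
  out <- character(0)
  i <- 1L
  while (i <= length(toks)) {
    if (toks[i] == "x") {
      j <- i
      while (j < length(toks) && toks[j + 1L] == "x") j <- j + 1L
      out <- c(out, if (j > i) paste0("x(", j - i + 1L, ")") else "x")
      i <- j + 1L
    } else {
      out <- c(out, toks[i])
      i <- i + 1L
    }
  }
  parse_prosite(paste(out, collapse = "-"))
}

#' Shipped pattern strings
#'
#' Default PROSITE-syntax patterns used by the annotation layer: the
#' `F-G-D-F-[AG]-N-D` N-terminal transporter motif core, and synthetic
#' stand-in signatures for the GUS glucuronidase and the AraC-family regulator
#' DNA-binding segment that are matched to the bundled synthetic templates.
#' For real data, supply the curated PROSITE entries (e.g. PS00719, PS00608,
#' PS01124) through a patterns file instead.
#'
#' @param path Optional patterns file (TSV: name, pattern) overriding the
#'   shipped defaults.
#' @return Named character vector of pattern strings.
#' @export
default_patterns <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "prosite_patterns.tsv", package = "gusloci")
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "#")
  stopifnot(all(c("name", "pattern") %in% names(tab)))
  setNames(tab$pattern, tab$name)
}
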