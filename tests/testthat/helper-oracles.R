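# Independent oracles used by the tests: exhaustive alignment enumeration,
# regex translation of PROSITE patterns, hypergeometric enumeration for the
# Fisher test, and rank-assignment enumeration for the Mann-Whitney test.
# These deliberately share no code with the package implementation.

# --- exhaustive alignment enumeration --------------------------------------
# Enumerates alignments as monotone paths (diag / gap-in-target / gap-in-query)
# with affine gap costs (open + L * extend), tracking the lexicographic best
# (score, matches). Local alignments are enumerated from every start cell and
# scored at every diagonal step (a maximal local alignment never ends in a
# gap). Exponential: for sequences up to ~8 residues only.
oracle_align <- function(a, b, scheme = scoring_scheme(), local = FALSE) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  S <- scheme$matrix; go <- scheme$gap_open; ge <- scheme$gap_extend
  best <- c(score = if (local) 0 else -Inf, matches = 0)
  consider <- function(sc, mt) {
    if (sc > best[1] + 1e-9 ||
        (abs(sc - best[1]) <= 1e-9 && mt > best[2])) best <<- c(sc, mt)
  }
  if (local) {
    rec <- function(i, j, state, sc, mt) {
      # called after consuming column ending at (i, j); candidates end on diag
      if (state == "m") consider(sc, mt)
      if (i <= n && j <= m)
        rec(i + 1L, j + 1L, "m", sc + S[av[i], bv[j]], mt + (av[i] == bv[j]))
      if (i <= n)
        rec(i + 1L, j, "x", sc - (if (state == "x") ge else go + ge), mt)
      if (j <= m)
        rec(i, j + 1L, "y", sc - (if (state == "y") ge else go + ge), mt)
    }
    for (i0 in seq_len(n)) {
      for (j0 in seq_len(m)) {
        rec(i0 + 1L, j0 + 1L, "m", S[av[i0], bv[j0]],
            as.integer(av[i0] == bv[j0]))
      }
    }
  } else {
    rec <- function(i, j, state, sc, mt) {
      if (i > n && j > m) { consider(sc, mt); return(invisible()) }
      if (i <= n && j <= m)
        rec(i + 1L, j + 1L, "m", sc + S[av[i], bv[j]], mt + (av[i] == bv[j]))
      if (i <= n)
        rec(i + 1L, j, "x", sc - (if (state == "x") ge else go + ge), mt)
      if (j <= m)
        rec(i, j + 1L, "y", sc - (if (state == "y") ge else go + ge), mt)
    }
    rec(1L, 1L, "s", 0, 0)
  }
  list(score = unname(best[1]), matches = unname(best[2]))
}

# --- independent ORF scan --------------------------------------------------
# Direct codon-walk reimplementation of the ORF rule: first ATG after the
# previous in-frame stop opens the ORF; ends at the next stop or the edge.
oracle_orfs <- function(dna, min_aa) {
  L <- nchar(dna)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- paste(rev(comp[strsplit(dna, "")[[1]]]), collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else rc
    for (f in 1:3) {
      starts <- seq(f, L - 2L, by = 3L)
      codons <- substring(s, starts, starts + 2L)
      open <- NA_integer_
      for (k in seq_along(codons)) {
        if (is.na(open) && codons[k] == "ATG") open <- k
        if (!is.na(open) && codons[k] %in% stops) {
          len <- k - open
          if (len >= min_aa) {
            # codon c spans nt (f + 3(c-1)) .. (f + 3c - 1); stop included
            nt_a <- f + 3L * (open - 1L); nt_b <- f + 3L * k - 1L
            span <- if (strand == "+") c(nt_a, nt_b) else
              c(L - nt_b + 1L, L - nt_a + 1L)
            out[[length(out) + 1L]] <- data.frame(
              start = span[1], end = span[2], strand = strand,
              length_aa = len, partial = FALSE)
          }
          open <- NA_integer_
        }
      }
      if (!is.na(open)) { # runs off the edge
        k <- length(codons)
        len <- k - open + 1L
        if (len >= min_aa) {
          nt_a <- f + 3L * (open - 1L); nt_b <- f + 3L * k - 1L
          span <- if (strand == "+") c(nt_a, nt_b) else
            c(L - nt_b + 1L, L - nt_a + 1L)
          out[[length(out) + 1L]] <- data.frame(
            start = span[1], end = span[2], strand = strand,
            length_aa = len, partial = TRUE)
        }
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      length_aa = integer(), partial = logical()))
  o <- do.call(rbind, out)
  o <- o[order(o$start, o$end, o$strand), , drop = FALSE]
  rownames(o) <- NULL
  o
}

# --- PROSITE -> regular expression -----------------------------------------
prosite_to_regex <- function(text) {
  s <- sub("\\.$", "", trimws(text))
  s <- gsub("\\{([A-Z]+)\\}", "[^\\1]", s)
  s <- gsub("\\(([0-9]+(,[0-9]+)?)\\)", "{\\1}", s)
  s <- gsub("(?<![A-Z^])x", ".", s, perl = TRUE)
  s <- gsub("-", "", s)
  s <- sub("^<", "^", s)
  s <- sub(">$", "$", s)
  s
}

regex_prosite_matches <- function(text, protein) {
  re <- prosite_to_regex(text)
  m <- gregexpr(re, protein, perl = TRUE)[[1]]
  if (m[1] < 0) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

# random PROSITE pattern generator for matcher/oracle comparisons
random_prosite <- function(n_elements = sample(2:8, 1)) {
  AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  els <- vapply(seq_len(n_elements), function(i) {
    kind <- sample(c("lit", "class", "excl", "x"), 1,
                   prob = c(0.4, 0.25, 0.15, 0.2))
    core <- switch(kind,
      lit = sample(AA, 1),
      class = paste0("[", paste(sort(sample(AA, sample(2:4, 1))), collapse = ""), "]"),
      excl = paste0("{", paste(sort(sample(AA, sample(1:3, 1))), collapse = ""), "}"),
      x = "x")
    if (runif(1) < 0.25) {
      lo <- sample(1:3, 1)
      if (runif(1) < 0.5) core <- paste0(core, "(", lo, ")")
      else core <- paste0(core, "(", lo, ",", lo + sample(1:2, 1), ")")
    }
    core
  }, character(1))
  paste(els, collapse = "-")
}

# --- Fisher exact: full hypergeometric enumeration -------------------------
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0L, k - n2); hi <- min(k, m)
  xs <- lo:hi
  probs <- dhyper(xs, m, n2, k)
  pobs <- dhyper(a, m, n2, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# --- Mann-Whitney exact: rank-assignment enumeration -----------------------
oracle_mwu <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2 # U1
  combos <- combn(n1 + n2, n1)
  all_ranks <- seq_len(n1 + n2)
  w_all <- apply(combos, 2, function(idx) sum(all_ranks[idx])) -
    n1 * (n1 + 1) / 2
  p <- if (w_obs > n1 * n2 / 2) 2 * mean(w_all >= w_obs) else
    2 * mean(w_all <= w_obs)
  list(U = min(w_obs, n1 * n2 - w_obs), p = min(1, p))
}
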