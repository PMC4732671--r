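#' Reverse complement of a DNA sequence
#'
#' @param dna A single DNA string over A, C, G, T, N.
#' @return The reverse complement (N maps to N). `reverse_complement()` is an
#'   involution: applying it twice returns the input.
#' @export
#' @examples
#' reverse_complement("ATG") # "CAT"
reverse_complement <- function(dna) {
  check_dna(dna)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

check_dna <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1L)
  if (nchar(dna) == 0L) stop("empty DNA sequence")
  if (grepl("[^ACGTN]", dna)) {
    bad <- regmatches(dna, regexpr("[^ACGTN]", dna))
    stop("illegal DNA character '", bad, "'")
  }
  invisible(dna)
}

frame_substring <- function(dna, offset) {
  len <- nchar(dna) - offset
  len <- len - (len %% 3L)
  if (len < 3L) "" else substr(dna, offset + 1L, offset + len)
}

#' Translate a contig in all six reading frames
#'
#' Frames +1, +2, +3 translate the forward strand starting at offsets 0, 1, 2;
#' frames -1, -2, -3 translate the reverse complement the same way. Stop codons
#' are rendered as `*`; trailing partial codons are dropped; codons containing
#' `N` translate to `X`.
#'
#' @param dna A DNA string of length >= 3.
#' @return Named character vector of six protein strings
#'   (`"+1", "+2", "+3", "-1", "-2", "-3"`).
#' @export
#' @examples
#' six_frame_translate("ATGAAATAA")[["+1"]] # "MK*"
six_frame_translate <- function(dna) {
  check_dna(dna)
  if (nchar(dna) < 3L) stop("contig shorter than one codon")
  rc <- reverse_complement(dna)
  subs <- c(frame_substring(dna, 0L), frame_substring(dna, 1L),
            frame_substring(dna, 2L),
            frame_substring(rc, 0L), frame_substring(rc, 1L),
            frame_substring(rc, 2L))
  out <- setNames(character(6L), c("+1", "+2", "+3", "-1", "-2", "-3"))
  nonempty <- nzchar(subs)
  if (any(nonempty)) {
    # one vectorized translate call for all frames; the fuzzy-codon path is
    # much slower and only needed when the contig contains N
    set <- Biostrings::DNAStringSet(subs[nonempty])
    prot <- if (grepl("N", dna, fixed = TRUE))
      Biostrings::translate(set, if.fuzzy.codon = "X")
    else Biostrings::translate(set)
    out[nonempty] <- as.character(prot)
  }
  out
}

#' Call open reading frames on both strands
#'
#' Deterministic ORF caller: an ORF starts at an ATG, ends at the first
#' in-frame stop codon (or at the contig edge, in which case it is flagged
#' partial), and nested ORFs sharing a stop are collapsed to the longest
#' (first ATG after the previous in-frame stop). Both strands are scanned.
#'
#' @param dna Contig sequence (A, C, G, T, N).
#' @param min_aa Minimum protein length (stop excluded), default 50.
#' @param contig_id Optional contig label copied into the output.
#' @return A data frame sorted by `start` with columns `contig_id`, `start`,
#'   `end` (1-based inclusive forward-strand nucleotide coordinates, stop codon
#'   included when present), `strand`, `frame`, `length_aa`, `partial` and
#'   `protein` (no stop character).
#' @export
#' @examples
#' call_orfs("ATGAAATAA", min_aa = 2)
call_orfs <- function(dna, min_aa = 50L, contig_id = NA_character_) {
  check_dna(dna)
  stopifnot(min_aa >= 0L)
  L <- nchar(dna)
  frames <- six_frame_translate(dna)
  rows <- list()
  for (fname in names(frames)) {
    prot <- frames[[fname]]
    if (!nzchar(prot)) next
    f <- abs(as.integer(fname))
    minus <- startsWith(fname, "-")
    # segments delimited by stops; the first M of each segment opens the ORF
    stops <- c(0L, which(strsplit(prot, "")[[1]] == "*"), nchar(prot) + 1L)
    stops <- unique(stops)
    seg_starts <- head(stops, -1L) + 1L
    seg_ends <- stops[-1L] - 1L
    for (s in seq_along(seg_starts)) {
      a <- seg_starts[s]; b <- seg_ends[s]
      if (b < a) next
      seg <- substr(prot, a, b)
      m <- regexpr("M", seg, fixed = TRUE)
      if (m < 0L) next
      p_start <- a + as.integer(m) - 1L        # first residue (M)
      p_end <- b                               # last residue before stop/edge
      has_stop <- (b + 1L) <= nchar(prot) && substr(prot, b + 1L, b + 1L) == "*"
      len_aa <- p_end - p_start + 1L
      if (len_aa < min_aa) next
      protein <- substr(prot, p_start, p_end)
      # nucleotide span in the translated strand, stop codon included if present
      nt_a <- f + 3L * (p_start - 1L)
      nt_b <- f + 3L * (p_end + (if (has_stop) 1L else 0L)) - 1L
      if (minus) {
        fwd_a <- L - nt_b + 1L; fwd_b <- L - nt_a + 1L
      } else {
        fwd_a <- nt_a; fwd_b <- nt_b
      }
      rows[[length(rows) + 1L]] <- data.frame(
        contig_id = contig_id, start = fwd_a, end = fwd_b,
        strand = if (minus) "-" else "+", frame = if (minus) -f else f,
        length_aa = len_aa, partial = !has_stop, protein = protein,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(), frame = integer(),
                      length_aa = integer(), partial = logical(),
                      protein = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select non-overlapping gene models from called ORFs
#'
#' [call_orfs()] reports every ORF on both strands, including heavily
#' overlapping ones (e.g. reverse-strand ORFs inside a real gene). For
#' neighborhood analysis a single gene model per region is wanted: ORFs are
#' selected greedily by decreasing length, discarding any ORF overlapping an
#' already-selected one by more than `max_overlap` nt (small operon-style
#' overlaps allowed).
#'
#' @param orfs ORF table from [call_orfs()].
#' @param max_overlap Maximum tolerated overlap in nt (default 30).
#' @return Filtered ORF table sorted by `start`.
#' @export
select_gene_models <- function(orfs, max_overlap = 30L) {
  if (nrow(orfs) <= 1L) return(orfs)
  ord <- order(-orfs$length_aa, orfs$start, orfs$end)
  o <- orfs[ord, , drop = FALSE]
  kept_start <- integer(0); kept_end <- integer(0)
  keep <- logical(nrow(o))
  for (i in seq_len(nrow(o))) {
    ov <- pmin(o$end[i], kept_end) - pmax(o$start[i], kept_start) + 1L
    if (length(ov) == 0L || max(ov) <= max_overlap) {
      keep[i] <- TRUE
      kept_start <- c(kept_start, o$start[i])
      kept_end <- c(kept_end, o$end[i])
    }
  }
  out <- o[keep, , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- alignment -------------------------------------------------------------

#' Protein scoring scheme
#'
#' Substitution matrix plus affine gap penalties. The default is BLOSUM62 with
#' gap open 10 and gap extend 0.5 (a gap of length L costs
#' `gap_open + L * gap_extend`). The `X` row and column of the matrix are set
#' to zero: unknown residues score 0 against everything.
#'
#' @param matrix Substitution matrix name (`"BLOSUM62"`, `"BLOSUM45"`,
#'   `"BLOSUM80"`, `"PAM30"`, `"PAM70"`, `"PAM250"`) or a symmetric numeric
#'   matrix with residue dimnames.
#' @param gap_open,gap_extend Non-negative penalties, `gap_extend <= gap_open`.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 0.5) {
  if (is.character(matrix)) {
    name <- match.arg(matrix, c("BLOSUM62", "BLOSUM45", "BLOSUM80",
                                "PAM30", "PAM70", "PAM250"))
    env <- new.env()
    utils::data(list = name, package = "Biostrings", envir = env)
    mat <- get(name, envir = env)
  } else {
    name <- "custom"
    mat <- as.matrix(matrix)
  }
  stopifnot(is.numeric(mat), nrow(mat) == ncol(mat),
            identical(rownames(mat), colnames(mat)))
  if (!isTRUE(all.equal(mat, t(mat)))) stop("substitution matrix must be symmetric")
  stopifnot(gap_open >= 0, gap_extend >= 0, gap_extend <= gap_open)
  if ("X" %in% rownames(mat)) {
    mat["X", ] <- 0
    mat[, "X"] <- 0
  }
  structure(list(name = name, matrix = mat,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("<scoring_scheme>", x$name, " gap_open=", x$gap_open,
      " gap_extend=", x$gap_extend, "\n", sep = "")
  invisible(x)
}

encode_protein <- function(seq, alphabet) {
  chars <- strsplit(toupper(seq), "")[[1]]
  idx <- match(chars, alphabet)
  x <- match("X", alphabet)
  idx[is.na(idx)] <- x
  idx - 1L # 0-based for C++
}

align_pair <- function(query, target, scheme, local) {
  stopifnot(is.character(query), is.character(target))
  if (nchar(query) == 0L || nchar(target) == 0L) stop("empty sequence")
  mat <- scheme$matrix
  sub2 <- round(2 * mat)
  storage.mode(sub2) <- "integer"
  alphabet <- rownames(mat)
  res <- .align_pair_cpp(encode_protein(query, alphabet),
                         encode_protein(target, alphabet), sub2,
                         as.integer(round(2 * scheme$gap_open)),
                         as.integer(round(2 * scheme$gap_extend)), local)
  if (!res$hit) return(NULL)
  cols <- res$columns
  out <- list(
    query_span = c(res$q_start, res$q_end),
    target_span = c(res$t_start, res$t_end),
    aligned_columns = cols,
    matches = res$matches,
    score = res$score2 / 2,
    identity_pct = if (cols > 0) 100 * res$matches / cols else 0,
    coverage_pct = 100 * (res$q_end - res$q_start + 1) / nchar(query)
  )
  class(out) <- "alignment_result"
  out
}

#' Local (Smith-Waterman) protein alignment
#'
#' Best-scoring local alignment under an affine-gap scheme. Among score-optimal
#' alignments the one with most identical residue pairs is returned; remaining
#' ties are resolved by the smallest coordinates, so results are deterministic.
#'
#' @param query,target Protein strings (non-empty).
#' @param scheme A [scoring_scheme()].
#' @return An `alignment_result` list with 1-based inclusive `query_span` and
#'   `target_span`, `aligned_columns` (gap columns included), `matches`,
#'   `score`, `identity_pct` (= 100 * matches / aligned_columns) and
#'   `coverage_pct` (= 100 * query span length / query length) — or `NULL`
#'   when no alignment scores above zero (no hit).
#' @export
#' @examples
#' align_local("MKTAYIAKQR", "MKTAYIAKQR")$identity_pct # 100
align_local <- function(query, target, scheme = scoring_scheme()) {
  align_pair(query, target, scheme, local = TRUE)
}

#' Global (Needleman-Wunsch) protein alignment
#'
#' End-to-end alignment; `identity_pct` is defined over all alignment columns
#' including gap columns (terminal gaps counted).
#'
#' @inheritParams align_local
#' @param a,b Protein strings (non-empty).
#' @return An `alignment_result` list; see [align_local()].
#' @export
#' @examples
#' align_global("MKT", "MRT")$identity_pct # 66.7
align_global <- function(a, b, scheme = scoring_scheme()) {
  align_pair(a, b, scheme, local = FALSE)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment> score %.1f, identity %.1f%% (%d/%d), coverage %.1f%%, q %d-%d, t %d-%d\n",
    x$score, x$identity_pct, x$matches, x$aligned_columns, x$coverage_pct,
    x$query_span[1], x$query_span[2], x$target_span[1], x$target_span[2]))
  invisible(x)
}

#' Percent identity of a global alignment
#'
#' Convenience wrapper: `100 * matches / aligned_columns` from
#' [align_global()].
#'
#' @inheritParams align_global
#' @return Numeric percent identity in `[0, 100]`.
#' @export
global_identity <- function(a, b, scheme = scoring_scheme()) {
  align_global(a, b, scheme)$identity_pct
}
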