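# The tBlastn-equivalent stage: six-frame translated search of contigs with
# protein queries, identity/coverage filtering, and transporter classification.

#' Screen configuration
#'
#' Thresholds of the published screen: hits are retained at >= 30% identity
#' and >= 80% query coverage (after rounding to one decimal); clades group at
#' >= 42% identity; reference assignment requires >= 98% identity.
#'
#' @param min_identity_pct,min_coverage_pct Retention filters.
#' @param clade_identity_pct Single-linkage clade threshold.
#' @param assign_identity_pct Reference (e.g. plasmid) assignment threshold.
#' @return A `screen_config` object.
#' @export
screen_config <- function(min_identity_pct = 30, min_coverage_pct = 80,
                          clade_identity_pct = 42, assign_identity_pct = 98) {
  vals <- c(min_identity_pct, min_coverage_pct, clade_identity_pct,
            assign_identity_pct)
  stopifnot(all(vals > 0), all(vals <= 100))
  structure(list(min_identity_pct = min_identity_pct,
                 min_coverage_pct = min_coverage_pct,
                 clade_identity_pct = clade_identity_pct,
                 assign_identity_pct = assign_identity_pct),
            class = "screen_config")
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             contig_id = character(), frame = integer(), sstart = integer(),
             send = integer(), qstart = integer(), qend = integer(),
             identity_pct = numeric(), coverage_pct = numeric(),
             matches = integer(), aligned_columns = integer(),
             score = numeric(), stringsAsFactors = FALSE)
}

# map a span on a frame translation back to forward-strand contig coordinates
frame_span_to_contig <- function(frame, p_start, p_end, contig_len) {
  f <- abs(frame)
  a <- f + 3L * (p_start - 1L)
  b <- f + 3L * p_end - 1L
  if (frame > 0) c(a, b) else c(contig_len - b + 1L, contig_len - a + 1L)
}

#' Six-frame translated homology search
#'
#' For every (query, contig, frame) triple, the best local alignment of the
#' query against the frame translation is retained iff it passes the identity
#' and coverage filters. Alignments never profitably cross stop codons (`*`
#' scores -4 against residues under BLOSUM62), so hits effectively live inside
#' coding regions.
#'
#' @param contigs Data frame with columns `contig_id`, `subject_id`, `seq`
#'   (DNA), e.g. the `contigs` element of [generate_cohort()].
#' @param queries Data frame with columns `id`, `role`, `seq` (protein), e.g.
#'   [default_queries()].
#' @param scheme A [scoring_scheme()].
#' @param config A [screen_config()].
#' @return Data frame of retained hits sorted by score (descending):
#'   `query_id`, `subject_id`, `contig_id`, `frame`, `sstart`/`send` (1-based
#'   forward-strand contig nt), `qstart`/`qend` (query residues),
#'   `identity_pct`, `coverage_pct`, `matches`, `aligned_columns`, `score`.
#' @export
translated_search <- function(contigs, queries, scheme = scoring_scheme(),
                              config = screen_config()) {
  stopifnot(is.data.frame(contigs), nrow(contigs) >= 1L,
            all(c("contig_id", "subject_id", "seq") %in% names(contigs)))
  if (!is.data.frame(queries) || nrow(queries) == 0L)
    stop("empty query set")
  stopifnot(all(c("id", "seq") %in% names(queries)))
  rows <- list()
  for (ci in seq_len(nrow(contigs))) {
    dna <- contigs$seq[ci]
    L <- nchar(dna)
    frames <- six_frame_translate(dna)
    frame_num <- c(1L, 2L, 3L, -1L, -2L, -3L)
    for (fi in seq_along(frames)) {
      prot <- frames[[fi]]
      if (nchar(prot) == 0L) next
      for (qi in seq_len(nrow(queries))) {
        aln <- align_local(queries$seq[qi], prot, scheme)
        if (is.null(aln)) next
        idy <- round(aln$identity_pct, 1)
        cov <- round(aln$coverage_pct, 1)
        if (idy < config$min_identity_pct || cov < config$min_coverage_pct)
          next
        span <- frame_span_to_contig(frame_num[fi], aln$target_span[1],
                                     aln$target_span[2], L)
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = queries$id[qi], subject_id = contigs$subject_id[ci],
          contig_id = contigs$contig_id[ci], frame = frame_num[fi],
          sstart = span[1], send = span[2],
          qstart = aln$query_span[1], qend = aln$query_span[2],
          identity_pct = idy, coverage_pct = cov,
          matches = aln$matches, aligned_columns = aln$aligned_columns,
          score = aln$score, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty_hits())
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$query_id, out$contig_id, out$frame), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best hit per subject and query
#'
#' Maximum identity per (subject, query); ties broken by higher coverage, then
#' higher score, then contig id.
#'
#' @param hits Filtered hit table from [translated_search()].
#' @return One row per (subject_id, query_id) with the winning hit's fields.
#'   Subjects without hits are absent.
#' @export
best_hit_per_subject <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$subject_id, hits$query_id, -hits$identity_pct,
               -hits$coverage_pct, -hits$score, hits$contig_id)
  h <- hits[ord, , drop = FALSE]
  keep <- !duplicated(h[, c("subject_id", "query_id")])
  out <- h[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

transporter_roles <- c(C7D2 = "C7D2_transporter", H11G11 = "H11G11_transporter",
                       GusB = "GusB")

#' Classify a subject's transporter carrier status
#'
#' The transporter class of a subject is the transporter query with the
#' highest retained identity; an exact tie reports all tied classes
#' (multi-carrier). Subjects with no retained transporter hit are
#' `"unclassified"`.
#'
#' @param best Best-hit table from [best_hit_per_subject()].
#' @param queries Query table with `id` and `role` columns.
#' @param subjects Optional character vector of all subject ids (so subjects
#'   without hits appear as unclassified).
#' @return Data frame with `subject_id`, `class` (top class(es), `";"`-joined
#'   on exact ties) and `carriers` (all transporter classes present,
#'   `";"`-joined, `""` when none).
#' @export
classify_transporter <- function(best, queries, subjects = NULL) {
  roles <- queries$role[match(best$query_id, queries$id)]
  tr_class <- names(transporter_roles)[match(roles, transporter_roles)]
  b <- best[!is.na(tr_class), , drop = FALSE]
  b$tr_class <- tr_class[!is.na(tr_class)]
  ids <- unique(c(subjects, b$subject_id))
  out <- lapply(ids, function(sid) {
    rows <- b[b$subject_id == sid, , drop = FALSE]
    if (nrow(rows) == 0L)
      return(data.frame(subject_id = sid, class = "unclassified",
                        carriers = "", stringsAsFactors = FALSE))
    top <- rows$tr_class[rows$identity_pct == max(rows$identity_pct)]
    data.frame(subject_id = sid,
               class = paste(sort(unique(top)), collapse = ";"),
               carriers = paste(sort(unique(rows$tr_class)), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assign a protein to a labeled reference panel
#'
#' A sequence is assigned the label of the reference it matches at or above
#' the assignment threshold (default 98% global identity, the published
#' plasmid-assignment rule); below that it is `"unassigned"`. The highest
#' identity wins; exact ties go to the lexicographically smallest label.
#'
#' @param protein Protein string.
#' @param panel Data frame with columns `id`, `label`, `seq`.
#' @param scheme A [scoring_scheme()].
#' @param config A [screen_config()] (uses `assign_identity_pct`).
#' @return Single character label.
#' @export
assign_to_reference <- function(protein, panel, scheme = scoring_scheme(),
                                config = screen_config()) {
  stopifnot(is.data.frame(panel), all(c("label", "seq") %in% names(panel)))
  idy <- vapply(panel$seq, function(ref)
    align_global(protein, ref, scheme)$identity_pct, numeric(1))
  ok <- round(idy, 1) >= config$assign_identity_pct
  if (!any(ok)) return("unassigned")
  cand <- panel$label[ok][order(-idy[ok], panel$label[ok])]
  cand[1]
}

#' Subjects-by-queries identity profile matrix
#'
#' Rectangular matrix of best retained identities (0 where a subject has no
#' retained hit for a query); the substrate of the Bray-Curtis PCoA
#' ordinations.
#'
#' @param best Best-hit table from [best_hit_per_subject()].
#' @param subjects Character vector of subject ids (row order).
#' @param query_ids Character vector of query ids (column order).
#' @return Numeric matrix, rows ordered by `subjects`.
#' @export
identity_profile_matrix <- function(best, subjects, query_ids) {
  m <- matrix(0, nrow = length(subjects), ncol = length(query_ids),
              dimnames = list(subjects, query_ids))
  if (nrow(best)) {
    keep <- best$subject_id %in% subjects & best$query_id %in% query_ids
    b <- best[keep, , drop = FALSE]
    m[cbind(b$subject_id, b$query_id)] <- b$identity_pct
  }
  m
}
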