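# Motif and synteny layer: N-terminal motif-variant calling, ORF annotation
# against the query panel, and classification of the GUS/C7D2/AFTR locus.

#' Scan the N-terminal window for the transporter motif
#'
#' Searches the exact strings `FGDFGND` (G variant) then `FGDFAND` (A variant)
#' starting within residues 1..`window_aa`. The G variant wins when both occur.
#'
#' @param protein Protein string, length >= 7.
#' @param window_aa Window size in residues (default 50; the motif is
#'   N-terminal in the transporter).
#' @return List with `variant` (`"G"`, `"A"` or `"none"`) and `position`
#'   (1-based motif start, `NA` when absent).
#' @export
#' @examples
#' scan_nterminal_motif("MKFGDFGNDLL") # variant G at position 3
scan_nterminal_motif <- function(protein, window_aa = 50L) {
  stopifnot(is.character(protein), length(protein) == 1L)
  if (nchar(protein) < 7L) stop("protein shorter than the 7-residue motif")
  head_seq <- substr(protein, 1L, min(nchar(protein), window_aa + 6L))
  for (v in c(G = "FGDFGND", A = "FGDFAND")) {
    at <- regexpr(v, head_seq, fixed = TRUE)
    if (at > 0L && at <= window_aa)
      return(list(variant = names(which(c(G = "FGDFGND", A = "FGDFAND") == v)),
                  position = as.integer(at)))
  }
  list(variant = "none", position = NA_integer_)
}

role_label <- function(role) {
  switch(role,
    GusA = "glucuronidase:GUS",
    C7D2_BG = "glucuronidase:BG",
    H11G11_BG = "glucuronidase:BG",
    C7D2_transporter = "transporter:C7D2",
    H11G11_transporter = "transporter:H11G11",
    GusB = "transporter:GusB",
    "putative")
}

#' Annotate the ORFs of a contig against the query panel
#'
#' Each ORF is labeled by the role family of its best query hit that passes
#' the screen filters (`glucuronidase:GUS`, `glucuronidase:BG`,
#' `transporter:C7D2`, `transporter:H11G11`, `transporter:GusB`). ORFs
#' without a retained query hit are labeled `glucuronidase:GUS` when all GUS
#' consensus signature patterns match (the signature-based GUS identification
#' of divergent homologs), `AFTR` when the regulator pattern matches, and
#' `putative` otherwise. Gene order and strands are preserved; the partial
#' flag of ORFs interrupted by the sequence end is propagated.
#'
#' @param orfs ORF table from [call_orfs()].
#' @param queries Query table (`id`, `role`, `seq`), e.g. [default_queries()].
#' @param scheme A [scoring_scheme()].
#' @param config A [screen_config()].
#' @param patterns Named pattern strings (needs `aftr_hth*` entries for the
#'   regulator and the `c7d2_motif` core); default [default_patterns()].
#' @return The `orfs` data frame (ordered by `start`) with added columns
#'   `label`, `best_query`, `identity_pct`, `motif_variant`, `motif_position`.
#' @export
annotate_neighborhood <- function(orfs, queries, scheme = scoring_scheme(),
                                  config = screen_config(),
                                  patterns = default_patterns()) {
  stopifnot(is.data.frame(orfs))
  n <- nrow(orfs)
  labels <- character(n); best_q <- rep(NA_character_, n)
  idy <- rep(NA_real_, n); mvar <- rep(NA_character_, n)
  mpos <- rep(NA_integer_, n)
  aftr_pats <- patterns[grepl("^aftr", names(patterns))]
  gus_pats <- patterns[grepl("^gus_sig", names(patterns))]
  for (i in seq_len(n)) {
    prot <- orfs$protein[i]
    best_identity <- -1; best_role <- NA_character_; best_id <- NA_character_
    for (qi in seq_len(nrow(queries))) {
      # coverage bound: the query span cannot exceed the ORF length, so short
      # ORFs can never reach the coverage threshold — skip the alignment
      if (round(100 * nchar(prot) / nchar(queries$seq[qi]), 1) <
            config$min_coverage_pct) next
      aln <- align_local(queries$seq[qi], prot, scheme)
      if (is.null(aln)) next
      if (round(aln$identity_pct, 1) >= config$min_identity_pct &&
          round(aln$coverage_pct, 1) >= config$min_coverage_pct &&
          aln$identity_pct > best_identity) {
        best_identity <- aln$identity_pct
        best_role <- queries$role[qi]
        best_id <- queries$id[qi]
      }
    }
    if (!is.na(best_role)) {
      labels[i] <- role_label(best_role)
      best_q[i] <- best_id
      idy[i] <- best_identity
    } else if (length(gus_pats) > 0 && all(vapply(gus_pats, function(p)
        nrow(match_prosite(p, prot)) > 0, logical(1)))) {
      labels[i] <- "glucuronidase:GUS" # divergent GUS caught by its signatures
    } else if (length(aftr_pats) > 0 && any(vapply(aftr_pats, function(p)
        nrow(match_prosite(p, prot)) > 0, logical(1)))) {
      labels[i] <- "AFTR"
    } else {
      labels[i] <- "putative"
    }
    if (nchar(prot) >= 7L) {
      mc <- scan_nterminal_motif(prot)
      mvar[i] <- mc$variant
      mpos[i] <- mc$position
    } else {
      mvar[i] <- "none"
    }
  }
  out <- orfs
  out$label <- labels
  out$best_query <- best_q
  out$identity_pct <- idy
  out$motif_variant <- mvar
  out$motif_position <- mpos
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the locus around each transporter gene
#'
#' For every transporter in the annotated neighborhood, genes on the same
#' strand within a window of `window` consecutive genes are inspected: the
#' locus label concatenates the glucuronidase class (if any), the transporter
#' class, and `"/AFTR"` when the regulator is present — e.g.
#' `"GUS/C7D2/AFTR"`. A transporter with no co-localized glucuronidase gets
#' its class alone. The same-strand requirement reflects the single
#' transcriptional unit of the marker locus.
#'
#' @param neighborhood Output of [annotate_neighborhood()].
#' @param subject_id,contig_id Labels copied into the result.
#' @param window Number of consecutive genes forming a neighborhood
#'   (default 4).
#' @return Data frame with one row per transporter gene: `subject_id`,
#'   `contig_id`, `transporter_class`, `glucuronidase` (`GUS`, `BG` or
#'   `none`), `regulator` (logical), `label`, `motif_variant`, `partial`,
#'   `gene_order` (the window's labels, 5'-3', `|`-joined with strands).
#' @export
classify_locus <- function(neighborhood, subject_id = NA_character_,
                           contig_id = NA_character_, window = 4L) {
  nb <- neighborhood[order(neighborhood$start), , drop = FALSE]
  tr_idx <- which(startsWith(nb$label, "transporter:"))
  if (length(tr_idx) == 0L) {
    return(data.frame(subject_id = character(), contig_id = character(),
                      transporter_class = character(),
                      glucuronidase = character(), regulator = logical(),
                      label = character(), motif_variant = character(),
                      partial = logical(), gene_order = character(),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(tr_idx, function(i) {
    near <- which(abs(seq_len(nrow(nb)) - i) <= (window - 1L) &
                  nb$strand == nb$strand[i])
    gl <- near[startsWith(nb$label[near], "glucuronidase:")]
    glc <- if (length(gl) == 0L) "none" else {
      gl <- gl[order(abs(gl - i), nb$label[gl])] # nearest first, GUS before BG on ties
      sub("glucuronidase:", "", nb$label[gl[1]])
    }
    reg <- any(nb$label[near] == "AFTR")
    trc <- sub("transporter:", "", nb$label[i])
    label <- paste0(if (glc != "none") paste0(glc, "/") else "", trc,
                    if (reg) "/AFTR" else "")
    data.frame(
      subject_id = subject_id, contig_id = contig_id,
      transporter_class = trc, glucuronidase = glc, regulator = reg,
      label = label, motif_variant = nb$motif_variant[i],
      partial = any(nb$partial[near]),
      gene_order = paste(paste0(nb$label[near], "(", nb$strand[near], ")"),
                         collapse = "|"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Annotate and classify every contig of a cohort
#'
#' Convenience driver: calls ORFs, annotates them and classifies transporter
#' loci for each contig.
#'
#' @param contigs Contig table (`contig_id`, `subject_id`, `seq`).
#' @param queries Query table; default [default_queries()].
#' @param scheme,config,patterns See [annotate_neighborhood()].
#' @param min_aa Minimum ORF length in residues.
#' @param window Synteny window; see [classify_locus()].
#' @return Data frame of locus calls (see [classify_locus()]); zero rows when
#'   no transporter gene is found.
#' @export
annotate_cohort <- function(contigs, queries = default_queries(),
                            scheme = scoring_scheme(),
                            config = screen_config(),
                            patterns = default_patterns(), min_aa = 50L,
                            window = 4L) {
  calls <- list()
  for (ci in seq_len(nrow(contigs))) {
    orfs <- select_gene_models(call_orfs(contigs$seq[ci], min_aa = min_aa,
                                         contig_id = contigs$contig_id[ci]))
    if (nrow(orfs) == 0L) next
    nb <- annotate_neighborhood(orfs, queries, scheme, config, patterns)
    lc <- classify_locus(nb, subject_id = contigs$subject_id[ci],
                         contig_id = contigs$contig_id[ci], window = window)
    if (nrow(lc)) calls[[length(calls) + 1L]] <- lc
  }
  if (length(calls) == 0L)
    return(classify_locus(data.frame(start = integer(), end = integer(),
                                     label = character(), strand = character(),
                                     motif_variant = character(),
                                     partial = logical())))
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
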