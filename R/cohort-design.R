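# Cohort design and generation: the study conditions of the synthetic screen.

#' Cohort design
#'
#' Describes a synthetic two-cohort study: subject counts, per-locus carrier
#' counts (or probabilities), identity ranges, motif-variant allocation, and
#' subject metadata distributions. The defaults mirror the published study
#' conditions: 13 CDR (4 patients + 9 unaffected relatives) vs 32 CDU healthy
#' subjects; 12/13 and 8/32 C7D2-transporter carriers; the FGDFGND (G) variant
#' in every CDR carrier and in 3 CDU carriers with FGDFAND (A) in the other 5;
#' the full GUS/C7D2/AFTR locus in 8 CDR and 3 CDU (A-variant) carriers; BG /
#' H11G11 loci predominantly in healthy subjects; highly conserved C7D2 genes
#' in CDR (85-100% identity to the query) and more divergent ones in CDU
#' (60-90%); BMI normal(19, 2) for patients, normal(27, 3) for relatives and
#' normal(23, 3) for healthy subjects.
#'
#' @param n_cdr,n_cdu Subject counts per cohort.
#' @param n_patients CD patients among CDR (affects BMI only).
#' @param contig_length Contig length in nt (default 10000).
#' @param gc Background GC fraction.
#' @param seed Integer seed; the generator is a pure function of the design.
#' @param c7d2,h11g11,gusb Per-locus settings: lists with `carriers_cdr`,
#'   `carriers_cdu` (integer counts, or probabilities in `[0, 1)` given as
#'   `prob_cdr`/`prob_cdu`), identity ranges, and for `c7d2` the motif and
#'   AFTR allocation (`motif_g_cdu`, `aftr_cdr`, `aftr_cdu`).
#' @param bmi Named list of `c(mean, sd)` for `patient`, `relative`, `healthy`.
#' @param p_female Probability a subject is female.
#' @return A `cohort_design` object.
#' @export
cohort_design <- function(n_cdr = 13L, n_cdu = 32L, n_patients = 4L,
                          contig_length = 10000L, gc = 0.45, seed = 1L,
                          c7d2 = list(carriers_cdr = 12L, carriers_cdu = 8L,
                                      motif_g_cdu = 3L, aftr_cdr = 8L,
                                      aftr_cdu = 3L,
                                      identity_cdr = c(85, 100),
                                      identity_cdu = c(60, 90)),
                          h11g11 = list(carriers_cdr = 4L, carriers_cdu = 16L,
                                        identity = c(60, 95)),
                          gusb = list(carriers_cdr = 2L, carriers_cdu = 5L,
                                      identity = c(60, 95)),
                          bmi = list(patient = c(19, 2), relative = c(27, 3),
                                     healthy = c(23, 3)),
                          p_female = 0.5) {
  stopifnot(n_cdr >= 1L, n_cdu >= 1L, n_patients <= n_cdr,
            gc > 0, gc < 1, p_female >= 0, p_female <= 1)
  d <- list(n_cdr = as.integer(n_cdr), n_cdu = as.integer(n_cdu),
            n_patients = as.integer(n_patients),
            contig_length = as.integer(contig_length), gc = gc,
            seed = as.integer(seed), c7d2 = c7d2, h11g11 = h11g11,
            gusb = gusb, bmi = bmi, p_female = p_female)
  class(d) <- "cohort_design"
  d
}

n_carriers <- function(spec, cohort, n) {
  key <- paste0("carriers_", cohort)
  pkey <- paste0("prob_", cohort)
  if (!is.null(spec[[key]])) {
    k <- as.integer(spec[[key]])
    if (k > n) stop("more carriers than subjects in cohort ", cohort)
    return(k)
  }
  if (!is.null(spec[[pkey]])) {
    p <- spec[[pkey]]
    stopifnot(p >= 0, p <= 1)
    return(sum(runif(n) < p))
  }
  0L
}

#' Generate a synthetic cohort
#'
#' Deterministic for a fixed design (including its seed): emits one or more
#' 10 kb contigs per subject (one per planted locus plus one background-only
#' contig), a ground-truth table of every planted gene, and subject metadata.
#'
#' @param design A [cohort_design()].
#' @return List of class `synthetic_cohort` with elements
#'   `metadata` (subject_id, cohort, status, bmi, gender),
#'   `contigs` (contig_id, subject_id, seq) and
#'   `truth` (subject_id, contig_id, locus, role, start, end, strand,
#'   target_identity, realized_identity, motif_variant, aftr_present,
#'   protein).
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(design$seed, generate_cohort_impl(design))
}

generate_cohort_impl <- function(design) {
  subjects <- data.frame(
    subject_id = c(sprintf("CDR%02d", seq_len(design$n_cdr)),
                   sprintf("CDU%02d", seq_len(design$n_cdu))),
    cohort = rep(c("CDR", "CDU"), c(design$n_cdr, design$n_cdu)),
    stringsAsFactors = FALSE
  )
  subjects$status <- ifelse(
    subjects$cohort == "CDU", "healthy",
    ifelse(seq_len(nrow(subjects)) <= design$n_patients, "patient", "relative"))
  bmi_par <- design$bmi
  subjects$bmi <- round(vapply(subjects$status, function(s)
    rnorm(1, bmi_par[[s]][1], bmi_par[[s]][2]), numeric(1)), 1)
  subjects$gender <- ifelse(runif(nrow(subjects)) < design$p_female, "F", "M")

  cdr_ids <- subjects$subject_id[subjects$cohort == "CDR"]
  cdu_ids <- subjects$subject_id[subjects$cohort == "CDU"]

  pick <- function(ids, k) if (k == 0L) character(0) else sort(sample(ids, k))

  # --- C7D2 locus assignment -----------------------------------------------
  c7 <- design$c7d2
  c7_cdr <- pick(cdr_ids, n_carriers(c7, "cdr", length(cdr_ids)))
  c7_cdu <- pick(cdu_ids, n_carriers(c7, "cdu", length(cdu_ids)))
  # CDR carriers all bear the G variant; CDU carriers split G/A
  g_cdu <- pick(c7_cdu, min(c7$motif_g_cdu %||% 0L, length(c7_cdu)))
  a_cdu <- setdiff(c7_cdu, g_cdu)
  # AFTR (full locus): a subset of CDR carriers; in CDU only among A-carriers
  aftr_cdr <- pick(c7_cdr, min(c7$aftr_cdr %||% length(c7_cdr), length(c7_cdr)))
  aftr_cdu <- pick(a_cdu, min(c7$aftr_cdu %||% 0L, length(a_cdu)))

  h11 <- design$h11g11
  h_carriers <- c(pick(cdr_ids, n_carriers(h11, "cdr", length(cdr_ids))),
                  pick(cdu_ids, n_carriers(h11, "cdu", length(cdu_ids))))
  gb <- design$gusb
  gb_carriers <- c(pick(cdr_ids, n_carriers(gb, "cdr", length(cdr_ids))),
                   pick(cdu_ids, n_carriers(gb, "cdu", length(cdu_ids))))

  tmpl_full <- c7d2_locus_template(include_aftr = TRUE)
  tmpl_noreg <- c7d2_locus_template(include_aftr = FALSE)
  tmpl_h11 <- h11g11_locus_template()
  tmpl_gusb <- gusb_locus_template()

  contigs <- list(); truth <- list()
  for (s in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[s]
    cohort <- subjects$cohort[s]
    loci <- list()
    if (sid %in% c(c7_cdr, c7_cdu)) {
      rng <- if (cohort == "CDR") c7$identity_cdr else c7$identity_cdu
      loci[[length(loci) + 1L]] <- list(
        template = if (sid %in% c(aftr_cdr, aftr_cdu)) tmpl_full else tmpl_noreg,
        identity = runif(1, rng[1], rng[2]),
        motif = if (sid %in% c(c7_cdr, g_cdu)) "G" else "A")
    }
    if (sid %in% h_carriers)
      loci[[length(loci) + 1L]] <- list(template = tmpl_h11,
                                        identity = runif(1, h11$identity[1],
                                                         h11$identity[2]),
                                        motif = "G")
    if (sid %in% gb_carriers)
      loci[[length(loci) + 1L]] <- list(template = tmpl_gusb,
                                        identity = runif(1, gb$identity[1],
                                                         gb$identity[2]),
                                        motif = "G")

    n_contig <- length(loci) + 1L
    for (k in seq_len(n_contig)) {
      cid <- sprintf("%s_c%d", sid, k)
      bg <- random_dna(design$contig_length, design$gc)
      if (k <= length(loci)) {
        pl <- plant_locus(bg, loci[[k]]$template,
                          target_identity = loci[[k]]$identity,
                          motif_variant = loci[[k]]$motif)
        tr <- pl$truth
        tr$subject_id <- sid; tr$contig_id <- cid
        tr$locus <- loci[[k]]$template$name
        tr$aftr_present <- "regulator_AFTR" %in% tr$role
        truth[[length(truth) + 1L]] <- tr
        seqs <- pl$seq
      } else {
        seqs <- bg
      }
      contigs[[length(contigs) + 1L]] <- data.frame(
        contig_id = cid, subject_id = sid, seq = seqs, stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(subject_id = character(), contig_id = character(),
               locus = character(), role = character(), start = integer(),
               end = integer(), strand = character(),
               target_identity = numeric(), realized_identity = numeric(),
               motif_variant = character(), aftr_present = logical(),
               protein = character(), stringsAsFactors = FALSE)
  if (nrow(truth)) {
    truth <- truth[, c("subject_id", "contig_id", "locus", "role", "start",
                       "end", "strand", "target_identity",
                       "realized_identity", "motif_variant", "aftr_present",
                       "protein")]
    rownames(truth) <- NULL
  }
  structure(list(metadata = subjects, contigs = do.call(rbind, contigs),
                 truth = truth, design = design),
            class = "synthetic_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic cohort to disk
#'
#' One FASTA per subject (`<subject_id>.fasta`), `truth.tsv` (the protein
#' column dropped from the TSV but kept in memory) and `metadata.tsv`.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in unique(cohort$contigs$subject_id)) {
    rec <- cohort$contigs[cohort$contigs$subject_id == sid, ]
    write_fasta(data.frame(id = rec$contig_id, seq = rec$seq),
                file.path(dir, paste0(sid, ".fasta")))
  }
  tr <- cohort$truth
  tr$protein <- NULL
  write.table(tr, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$metadata, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Print method for synthetic cohorts
#' @param x A `synthetic_cohort`.
#' @param ... Ignored.
#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$metadata), " subjects (",
      sum(x$metadata$cohort == "CDR"), " CDR / ",
      sum(x$metadata$cohort == "CDU"), " CDU), ",
      nrow(x$contigs), " contigs, ", nrow(x$truth), " planted genes\n",
      sep = "")
  invisible(x)
}
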