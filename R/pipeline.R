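# Pipeline orchestration: simulate -> screen -> annotate -> tree -> stats,
# with file-based stage contracts, a run manifest and deterministic seeds.

#' Read a cohort design from JSON
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' [cohort_design()].
#'
#' @param path JSON file with (a subset of) the [cohort_design()] fields.
#' @return A `cohort_design`.
#' @export
design_from_json <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(cohort_design))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown design keys: ", paste(bad, collapse = ", "))
  do.call(cohort_design, raw)
}

#' Read a directory of per-subject contig FASTA files
#'
#' Each `<subject_id>.fasta` contributes its records with `subject_id` taken
#' from the file name.
#'
#' @param dir Directory containing `*.fasta` files.
#' @return Contig data frame (`contig_id`, `subject_id`, `seq`).
#' @export
read_contig_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(fasta|fa|fna)$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no FASTA files in ", dir)
  out <- lapply(files, function(f) {
    rec <- read_fasta(f, alphabet = "dna")
    data.frame(contig_id = rec$id,
               subject_id = sub("\\.[^.]+$", "", basename(f)),
               seq = rec$seq, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read a protein query FASTA
#'
#' Roles are taken from a `role=<role>` token on the header line when present,
#' otherwise matched from the id against the known role names.
#'
#' @param path Query FASTA file.
#' @return Query data frame (`id`, `role`, `seq`).
#' @export
read_queries <- function(path) {
  lines <- readLines(path, warn = FALSE)
  headers <- grep("^>", lines, value = TRUE)
  rec <- read_fasta(path, alphabet = "protein")
  role_token <- function(h) {
    m <- regmatches(h, regexpr("role=\\S+", h))
    if (length(m)) sub("role=", "", m) else NA_character_
  }
  roles <- vapply(headers, role_token, character(1), USE.NAMES = FALSE)
  known <- c("GusA", "GusB", "H11G11_BG", "H11G11_transporter", "C7D2_BG",
             "C7D2_transporter")
  for (k in which(is.na(roles))) {
    hit <- known[vapply(known, function(r) grepl(r, rec$id[k], fixed = TRUE),
                        logical(1))]
    roles[k] <- if (length(hit)) hit[[which.max(nchar(hit))]] else rec$id[k]
  }
  missing <- setdiff(known, roles)
  if (length(missing))
    warning("query roles not represented: ", paste(missing, collapse = ", "))
  data.frame(id = rec$id, role = roles, seq = rec$seq, stringsAsFactors = FALSE)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(out_dir, stage, seed, params = list()) {
  manifest <- list(stage = stage, seed = seed,
                   package = as.character(utils::packageVersion("gusloci")),
                   params = params)
  jsonlite::write_json(manifest, file.path(out_dir, paste0(stage, ".manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Pipeline stage: simulate a cohort
#'
#' @param design A [cohort_design()], or path to a design JSON.
#' @param out_dir Output directory.
#' @param seed Optional seed overriding the design's.
#' @return The generated `synthetic_cohort`, invisibly.
#' @export
pipeline_simulate <- function(design, out_dir, seed = NULL) {
  if (is.character(design)) design <- design_from_json(design)
  stopifnot(inherits(design, "cohort_design"))
  if (!is.null(seed)) design$seed <- as.integer(seed)
  cohort <- generate_cohort(design)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(cohort, out_dir)
  write_manifest(out_dir, "simulate", design$seed,
                 list(n_cdr = design$n_cdr, n_cdu = design$n_cdu,
                      contig_length = design$contig_length))
  invisible(cohort)
}

#' Pipeline stage: translated screen
#'
#' Writes `hits.tsv` (BLAST-tabular-like columns) and `best_hits.tsv`.
#'
#' @param contigs Contig data frame or directory of per-subject FASTA files.
#' @param queries Query data frame or query FASTA path.
#' @param out_dir Output directory.
#' @param scheme,config See [translated_search()].
#' @return The hit table, invisibly.
#' @export
pipeline_screen <- function(contigs, queries, out_dir,
                            scheme = scoring_scheme(),
                            config = screen_config()) {
  if (is.character(contigs)) contigs <- read_contig_dir(contigs)
  if (is.character(queries)) queries <- read_queries(queries)
  hits <- translated_search(contigs, queries, scheme, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- data.frame(qseqid = hits$query_id, sseqid = hits$contig_id,
                    subject = hits$subject_id, pident = hits$identity_pct,
                    length = hits$aligned_columns, qcovs = hits$coverage_pct,
                    frame = hits$frame, sstart = hits$sstart,
                    send = hits$send, score = hits$score)
  write_tsv(tab, file.path(out_dir, "hits.tsv"))
  best <- best_hit_per_subject(hits)
  write_tsv(best, file.path(out_dir, "best_hits.tsv"))
  invisible(hits)
}

#' Pipeline stage: locus annotation
#'
#' Writes `locus_calls.tsv`.
#'
#' @inheritParams pipeline_screen
#' @param patterns Patterns file path or named pattern vector.
#' @param window Synteny window (genes).
#' @param min_aa Minimum ORF length.
#' @return The locus-call table, invisibly.
#' @export
pipeline_annotate <- function(contigs, queries, out_dir,
                              patterns = default_patterns(),
                              scheme = scoring_scheme(),
                              config = screen_config(), window = 4L,
                              min_aa = 50L) {
  if (is.character(contigs)) contigs <- read_contig_dir(contigs)
  if (is.character(queries)) queries <- read_queries(queries)
  if (is.character(patterns) && length(patterns) == 1L && file.exists(patterns))
    patterns <- default_patterns(patterns)
  calls <- annotate_cohort(contigs, queries, scheme, config, patterns,
                           min_aa = min_aa, window = window)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(calls, file.path(out_dir, "locus_calls.tsv"))
  invisible(calls)
}

#' Extract the aligned protein region of each retained hit
#'
#' @param contigs Contig data frame.
#' @param hits Hit table from [translated_search()].
#' @return Named character vector (`query_id/contig_id`) of hit proteins.
#' @export
hit_proteins <- function(contigs, hits) {
  out <- character(0)
  for (k in seq_len(nrow(hits))) {
    dna <- contigs$seq[match(hits$contig_id[k], contigs$contig_id)]
    frames <- six_frame_translate(dna)
    fname <- sprintf("%+d", hits$frame[k])
    prot <- frames[[fname]]
    # recover the frame-translation span from contig coordinates
    L <- nchar(dna)
    f <- abs(hits$frame[k])
    if (hits$frame[k] > 0) {
      p1 <- (hits$sstart[k] - f) / 3 + 1
      p2 <- (hits$send[k] + 1 - f) / 3
    } else {
      a <- L - hits$send[k] + 1
      b <- L - hits$sstart[k] + 1
      p1 <- (a - f) / 3 + 1
      p2 <- (b + 1 - f) / 3
    }
    out[paste0(hits$query_id[k], "/", hits$contig_id[k])] <-
      substr(prot, p1, p2)
  }
  out
}

#' Deduplicate hits covering the same contig region
#'
#' When two queries hit the same gene, only the highest-identity hit is kept
#' (ties: higher coverage, then score), so each contig region contributes one
#' sequence, named after its best query. Two hits are considered the same
#' region when their contig spans overlap by more than half of the shorter
#' span.
#'
#' @param hits Hit table from [translated_search()].
#' @return Filtered hit table.
#' @export
dedupe_hits_by_region <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  ord <- order(-hits$identity_pct, -hits$coverage_pct, -hits$score,
               hits$query_id)
  h <- hits[ord, , drop = FALSE]
  keep <- logical(nrow(h))
  for (cid in unique(h$contig_id)) {
    idx <- which(h$contig_id == cid)
    kept <- integer(0)
    for (i in idx) {
      dup <- FALSE
      for (j in kept) {
        ov <- min(h$send[i], h$send[j]) - max(h$sstart[i], h$sstart[j]) + 1L
        shorter <- min(h$send[i] - h$sstart[i], h$send[j] - h$sstart[j]) + 1L
        if (ov > shorter / 2) { dup <- TRUE; break }
      }
      if (!dup) { keep[i] <- TRUE; kept <- c(kept, i) }
    }
  }
  out <- h[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pipeline stage: transporter tree and clades
#'
#' Builds a neighbor-joining tree and identity clades over the retained
#' transporter hit regions plus the transporter queries; writes
#' `transporters.nwk` and `clades.tsv`. Each contig region enters once, under
#' its best query's name ([dedupe_hits_by_region()]). Requires at least three
#' sequences.
#'
#' @inheritParams pipeline_screen
#' @param hits Hit table (or `hits.tsv` is recomputed from contigs/queries).
#' @param clade_threshold Identity threshold for clade grouping.
#' @return List with `tree` and `clades`, invisibly.
#' @export
pipeline_tree <- function(contigs, queries, hits, out_dir,
                          scheme = scoring_scheme(), clade_threshold = 42) {
  if (is.character(contigs)) contigs <- read_contig_dir(contigs)
  if (is.character(queries)) queries <- read_queries(queries)
  tr_roles <- c("C7D2_transporter", "H11G11_transporter", "GusB")
  tr_q <- queries[queries$role %in% tr_roles, , drop = FALSE]
  best <- best_hit_per_subject(hits[hits$query_id %in% tr_q$id, , drop = FALSE])
  best <- dedupe_hits_by_region(best)
  seqs <- hit_proteins(contigs, best)
  seqs <- c(setNames(tr_q$seq, tr_q$id), seqs)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (length(seqs) < 3L) stop("tree stage needs at least 3 sequences")
  d <- pdistance_matrix(seqs, scheme)
  tree <- nj_build(d)
  writeLines(to_newick(tree), file.path(out_dir, "transporters.nwk"))
  clades <- identity_clades(seqs, scheme, threshold_pct = clade_threshold)
  write_tsv(clades, file.path(out_dir, "clades.tsv"))
  invisible(list(tree = tree, clades = clades))
}

report_to_list <- function(report) {
  out <- list()
  for (nm in setdiff(names(report), c("bias", "n"))) {
    m <- report[[nm]]
    out[[nm]] <- list(
      carriers_cdr = unname(m$counts[1, 1]), n_cdr = unname(sum(m$counts[1, ])),
      carriers_cdu = unname(m$counts[2, 1]), n_cdu = unname(sum(m$counts[2, ])),
      freq_cdr_pct = m$freq_cdr_pct, freq_cdu_pct = m$freq_cdu_pct,
      fisher_p = m$fisher_p)
  }
  out$bias <- report$bias
  out$n <- as.list(report$n)
  out
}

#' Pipeline stage: cohort statistics
#'
#' Writes `report.json`, a readable `report.txt`, and the Bray-Curtis PCoA
#' coordinates of the identity profiles (`pcoa.tsv`).
#'
#' @param locus_calls Locus-call table (or `locus_calls.tsv` path).
#' @param metadata Metadata data frame (or `metadata.tsv` path).
#' @param best Best-hit table used for the identity-profile PCoA.
#' @param queries Query table.
#' @param out_dir Output directory.
#' @return The `marker_report`, invisibly.
#' @export
pipeline_stats <- function(locus_calls, metadata, best, queries, out_dir) {
  if (is.character(locus_calls)) locus_calls <- read.delim(locus_calls)
  if (is.character(metadata)) metadata <- read.delim(metadata)
  report <- marker_frequency_report(locus_calls, metadata)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_to_list(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(utils::capture.output(print(report)),
             file.path(out_dir, "report.txt"))
  prof <- identity_profile_matrix(best, metadata$subject_id, queries$id)
  keep <- rowSums(prof) > 0
  if (sum(keep) >= 3L) {
    d <- as.matrix(vegan::vegdist(prof[keep, , drop = FALSE], method = "bray"))
    ord <- pcoa(d, n_axes = 2L)
    coords <- data.frame(subject_id = rownames(ord$coordinates),
                         ord$coordinates, row.names = NULL)
    write_tsv(coords, file.path(out_dir, "pcoa.tsv"))
  }
  invisible(report)
}

#' Run the full pipeline
#'
#' simulate -> screen -> annotate -> tree -> stats on a synthetic design, or
#' screen onward on an existing contig directory. Stage failures are
#' re-raised with the failing stage named.
#'
#' @param design A [cohort_design()] or design JSON path (used unless
#'   `contigs_dir` is given).
#' @param out_dir Output directory (stage outputs in subdirectories).
#' @param seed Seed overriding the design's.
#' @param contigs_dir Optional directory of real contig FASTA files.
#' @param queries Query table or FASTA path; default [default_queries()].
#' @param patterns Named pattern vector or patterns file.
#' @param scheme,config See [translated_search()].
#' @return List with `cohort` (or `NULL`), `hits`, `locus_calls`, `report`,
#'   invisibly.
#' @export
pipeline_run_all <- function(design = cohort_design(), out_dir, seed = NULL,
                             contigs_dir = NULL, queries = default_queries(),
                             patterns = default_patterns(),
                             scheme = scoring_scheme(),
                             config = screen_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(queries)) queries <- stage("screen", read_queries(queries))
  cohort <- NULL
  if (is.null(contigs_dir)) {
    cohort <- stage("simulate",
                    pipeline_simulate(design, file.path(out_dir, "cohort"),
                                      seed = seed))
    contigs <- cohort$contigs
    metadata <- cohort$metadata
  } else {
    contigs <- stage("screen", read_contig_dir(contigs_dir))
    meta_path <- file.path(contigs_dir, "metadata.tsv")
    metadata <- if (file.exists(meta_path)) read.delim(meta_path) else
      data.frame(subject_id = unique(contigs$subject_id),
                 cohort = NA_character_)
  }
  hits <- stage("screen",
                pipeline_screen(contigs, queries, file.path(out_dir, "screen"),
                                scheme, config))
  calls <- stage("annotate",
                 pipeline_annotate(contigs, queries,
                                   file.path(out_dir, "annotate"),
                                   patterns, scheme, config))
  tree <- stage("tree", tryCatch(
    pipeline_tree(contigs, queries, hits, file.path(out_dir, "tree"), scheme,
                  clade_threshold = config$clade_identity_pct),
    error = function(e) {
      if (grepl("at least 3 sequences", conditionMessage(e))) NULL else stop(e)
    }))
  report <- NULL
  if (all(c("CDR", "CDU") %in% metadata$cohort)) {
    best <- best_hit_per_subject(hits)
    report <- stage("stats",
                    pipeline_stats(calls, metadata, best, queries,
                                   file.path(out_dir, "stats")))
  }
  write_manifest(out_dir, "run_all",
                 if (!is.null(seed)) seed else
                   if (!is.null(cohort)) cohort$design$seed else NA)
  invisible(list(cohort = cohort, hits = hits, locus_calls = calls,
                 tree = tree, report = report))
}
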