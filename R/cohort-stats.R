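# Cohort statistics: exact 2x2 tests, rank tests, Bray-Curtis PCoA, quartile
# summaries and the marker-frequency report.

check_2x2 <- function(table) {
  t <- as.matrix(table)
  stopifnot(all(dim(t) == c(2L, 2L)))
  if (any(t < 0) || any(t != round(t))) stop("2x2 table needs non-negative integer counts")
  if (sum(t) == 0L) stop("empty 2x2 table")
  t
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric test with margins fixed; the two-sided p-value is the
#' sum of probabilities of all tables at most as probable as the observed one
#' (the standard R convention).
#'
#' @param table 2x2 matrix of counts (rows = cohort, cols = marker
#'   present/absent).
#' @return Two-sided p-value in `(0, 1]`.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)) # 34/70
fisher_exact_2x2 <- function(table) {
  t <- check_2x2(table)
  stats::fisher.test(t)$p.value
}

#' Pearson chi-squared test for a 2x2 table
#'
#' @param table 2x2 matrix of counts.
#' @param continuity_correction Apply the Yates correction (default `FALSE`).
#' @return List with `statistic` and `p`.
#' @export
chi2_2x2 <- function(table, continuity_correction = FALSE) {
  t <- check_2x2(table)
  if (any(rowSums(t) == 0L) || any(colSums(t) == 0L))
    stop("chi-squared test undefined for a zero margin")
  res <- suppressWarnings(stats::chisq.test(t, correct = continuity_correction))
  list(statistic = unname(res$statistic), p = res$p.value)
}

#' Mann-Whitney U test
#'
#' `U = min(U1, U2)`. Exact mode enumerates rank assignments (requires no ties
#' and `n1 + n2 <= 12`); normal mode uses the tie-corrected normal
#' approximation with continuity correction (identical groups still give
#' p = 1, since the correction vanishes at the null center).
#'
#' @param x,y Numeric value vectors (non-empty).
#' @param mode `"auto"` (exact when admissible), `"exact"` or `"normal"`.
#' @return List with `U` and two-sided `p`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4), mode = "exact") # U = 0, p = 1/3
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (mode == "exact" && (ties || n1 + n2 > 12L))
    stop("exact mode requires no ties and n1 + n2 <= 12")
  exact <- switch(mode, exact = TRUE, normal = FALSE,
                  auto = !ties && n1 + n2 <= 12L)
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact))
  u1 <- unname(res$statistic) # rank-sum U for x
  list(U = min(u1, n1 * n2 - u1), p = res$p.value)
}

#' Bray-Curtis dissimilarity between two profiles
#'
#' `BC = sum |u_i - v_i| / sum (u_i + v_i)`, computed with
#' [vegan::vegdist()]. 0 iff identical, 1 iff the supports are disjoint.
#'
#' @param u,v Equal-length non-negative numeric vectors, not both all-zero.
#' @return Distance in `[0, 1]`.
#' @export
#' @examples
#' bray_curtis(c(1, 2), c(3, 0)) # 4/6
bray_curtis <- function(u, v) {
  stopifnot(length(u) == length(v), all(u >= 0), all(v >= 0))
  if (sum(u) + sum(v) == 0) stop("both profiles are all-zero")
  as.numeric(vegan::vegdist(rbind(u, v), method = "bray"))
}

#' Principal coordinates analysis
#'
#' Gower double-centering and eigendecomposition via [stats::cmdscale()].
#' Axes are ordered by eigenvalue; axes with non-positive eigenvalues are
#' recorded but dropped from the coordinates. Axis signs are fixed so the
#' largest-magnitude loading on each axis is positive.
#'
#' @param d Distance matrix (symmetric numeric matrix or `dist`).
#' @param n_axes Number of axes requested.
#' @return List of class `pcoa_ordination`: `coordinates` (subjects x axes),
#'   `eigenvalues` (all, descending), `proportion_explained` (over positive
#'   eigenvalues).
#' @export
pcoa <- function(d, n_axes = 2L) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  stopifnot(n >= 2L, isTRUE(all.equal(dm, t(dm))), all(diag(dm) == 0))
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("s", seq_len(n))
  if (all(dm == 0)) {
    k <- min(n_axes, n - 1L)
    return(structure(list(
      coordinates = matrix(0, n, k, dimnames = list(labels, paste0("Axis", seq_len(k)))),
      eigenvalues = rep(0, n - 1L), proportion_explained = rep(0, n - 1L)),
      class = "pcoa_ordination"))
  }
  res <- cmdscale(as.dist(dm), k = min(n_axes, n - 1L), eig = TRUE)
  eig <- sort(res$eig, decreasing = TRUE)
  pos <- eig > sqrt(.Machine$double.eps)
  coords <- res$points
  keep <- seq_len(min(ncol(coords), sum(pos), n_axes))
  coords <- coords[, keep, drop = FALSE]
  for (a in seq_len(ncol(coords))) {
    big <- which.max(abs(coords[, a]))
    if (coords[big, a] < 0) coords[, a] <- -coords[, a]
  }
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  rownames(coords) <- labels
  structure(list(coordinates = coords, eigenvalues = eig,
                 proportion_explained = ifelse(eig > 0, eig / sum(eig[eig > 0]), 0)),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat("<pcoa_ordination> ", nrow(x$coordinates), " points, ",
      ncol(x$coordinates), " axes; first axes explain ",
      paste(sprintf("%.1f%%", 100 * head(x$proportion_explained,
                                         ncol(x$coordinates))),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Five-number quartile summary
#'
#' Linear-interpolation (type 7) quartiles, the convention behind the identity
#' boxplots.
#'
#' @param values Non-empty numeric vector.
#' @return Named vector `min`, `q1`, `median`, `q3`, `max`.
#' @export
quartile_summary <- function(values) {
  stopifnot(length(values) >= 1L, is.numeric(values))
  q <- quantile(values, probs = c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  c(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
}

marker_2x2 <- function(carrier, cohort) {
  # rows CDR/CDU, cols present/absent
  matrix(c(sum(carrier & cohort == "CDR"), sum(!carrier & cohort == "CDR"),
           sum(carrier & cohort == "CDU"), sum(!carrier & cohort == "CDU")),
         2, 2, byrow = TRUE,
         dimnames = list(c("CDR", "CDU"), c("present", "absent")))
}

#' Marker-frequency report
#'
#' Per-cohort carrier counts and frequencies for (i) the C7D2-class
#' transporter, (ii) the FGDFGND (G) motif, (iii) the FGDFAND (A) motif and
#' (iv) the full GUS/C7D2/AFTR locus, each with its exact Fisher p-value,
#' plus BMI (Mann-Whitney) and gender (chi-squared) bias checks between C7D2
#' carriers and non-carriers. Frequencies are carriers / cohort size, one
#' decimal.
#'
#' @param locus_calls Locus-call table from [annotate_cohort()].
#' @param metadata Subject metadata (`subject_id`, `cohort`, and optionally
#'   `bmi`, `gender`).
#' @return A `marker_report` list with one element per marker (`counts`
#'   2x2 matrix, `freq_cdr_pct`, `freq_cdu_pct`, `fisher_p`) plus `bias`
#'   (`bmi_mwu_p`, `gender_chi2_p`, or `NA` where undefined) and `n` per
#'   cohort.
#' @export
marker_frequency_report <- function(locus_calls, metadata) {
  stopifnot(all(c("subject_id", "cohort") %in% names(metadata)))
  if (nrow(metadata) == 0L) stop("empty metadata")
  if (!all(c("CDR", "CDU") %in% metadata$cohort))
    stop("empty cohort: need both CDR and CDU subjects")
  lc <- locus_calls
  subj_flag <- function(flag_by_subject) {
    metadata$subject_id %in% flag_by_subject
  }
  has <- function(cond) unique(lc$subject_id[cond])
  flags <- list(
    c7d2_transporter = subj_flag(has(lc$transporter_class == "C7D2")),
    motif_fgdfgnd = subj_flag(has(lc$transporter_class == "C7D2" &
                                    lc$motif_variant == "G")),
    motif_fgdfand = subj_flag(has(lc$transporter_class == "C7D2" &
                                    lc$motif_variant == "A")),
    gus_c7d2_aftr_locus = subj_flag(has(lc$label == "GUS/C7D2/AFTR"))
  )
  cohort <- metadata$cohort
  markers <- lapply(flags, function(fl) {
    tab <- marker_2x2(fl, cohort)
    list(counts = tab,
         freq_cdr_pct = round(100 * tab[1, 1] / sum(tab[1, ]), 1),
         freq_cdu_pct = round(100 * tab[2, 1] / sum(tab[2, ]), 1),
         fisher_p = fisher_exact_2x2(tab))
  })
  carrier <- flags$c7d2_transporter
  bias <- list(bmi_mwu_p = NA_real_, gender_chi2_p = NA_real_)
  if ("bmi" %in% names(metadata) && any(carrier) && any(!carrier))
    bias$bmi_mwu_p <- mann_whitney_u(metadata$bmi[carrier],
                                     metadata$bmi[!carrier], mode = "normal")$p
  if ("gender" %in% names(metadata) && any(carrier) && any(!carrier) &&
      length(unique(metadata$gender)) == 2L) {
    tab <- table(factor(carrier, c(TRUE, FALSE)), metadata$gender)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      bias$gender_chi2_p <- chi2_2x2(tab)$p
  }
  structure(c(markers, list(
    bias = bias,
    n = c(CDR = sum(cohort == "CDR"), CDU = sum(cohort == "CDU")))),
    class = "marker_report")
}

#' @export
print.marker_report <- function(x, ...) {
  cat("Marker frequencies (CDR n=", x$n[["CDR"]], ", CDU n=", x$n[["CDU"]],
      ")\n", sep = "")
  for (nm in setdiff(names(x), c("bias", "n"))) {
    m <- x[[nm]]
    cat(sprintf("  %-20s CDR %d/%d (%.1f%%)  CDU %d/%d (%.1f%%)  Fisher p = %.3g\n",
                nm, m$counts[1, 1], sum(m$counts[1, ]), m$freq_cdr_pct,
                m$counts[2, 1], sum(m$counts[2, ]), m$freq_cdu_pct,
                m$fisher_p))
  }
  cat(sprintf("  bias checks: BMI MWU p = %.3g, gender chi2 p = %.3g\n",
              x$bias$bmi_mwu_p, x$bias$gender_chi2_p))
  invisible(x)
}
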