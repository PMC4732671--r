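# Distance computation, Saitou-Nei neighbor joining, Newick I/O and
# identity-threshold clade grouping.

#' Pairwise p-distance matrix from global-alignment identities
#'
#' `d(i, j) = 1 - identity_pct / 100` from [align_global()]; each pair is
#' aligned once, so the matrix is symmetric by construction.
#'
#' @param proteins Named character vector of protein sequences (>= 2).
#' @param scheme A [scoring_scheme()].
#' @return Symmetric numeric matrix with zero diagonal and the sequence names
#'   as dimnames.
#' @export
pdistance_matrix <- function(proteins, scheme = scoring_scheme()) {
  n <- length(proteins)
  stopifnot(n >= 2L)
  labels <- names(proteins)
  if (is.null(labels)) labels <- paste0("seq", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      idy <- align_global(proteins[[i]], proteins[[j]], scheme)$identity_pct
      d[i, j] <- d[j, i] <- 1 - idy / 100
    }
  }
  d
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Canonical neighbor joining: at each step the pair minimising the
#' Q criterion `Q(i,j) = (n-2) d(i,j) - r(i) - r(j)` is merged; branch
#' lengths follow the standard three-point formulas; ties are broken by the
#' lowest index pair in the current node order. Negative branch-length
#' estimates are clamped to zero and flagged in the `clamped` attribute of
#' the result. On additive distance matrices the generating tree is recovered
#' exactly (topology and branch lengths).
#'
#' @param d Symmetric distance matrix with labels as dimnames, n >= 3.
#' @return An unrooted `ape::phylo` tree with attribute `clamped` (TRUE if
#'   any negative branch length was clamped).
#' @export
nj_build <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  stopifnot(isTRUE(all.equal(d, t(d))), all(diag(d) == 0), all(d >= 0))
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  frags <- labels # newick fragment per active node
  active <- seq_len(n)
  D <- d
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) clamped <<- TRUE
    max(x, 0)
  }
  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(D)
    # Q criterion; lowest (i, j) pair on ties
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        q <- (m - 2) * D[i, j] - r[i] - r[j]
        if (q < best[1] - 1e-12) best <- c(q, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    li <- clamp(D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    lj <- clamp(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frags[i], li, frags[j], lj)
    newdist <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newdist[keep]),
                c(newdist[keep], 0))
    D <- D2
    frags <- c(frags[keep], newfrag)
    active <- seq_len(m - 1L)
  }
  # final three nodes: star resolution
  la <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frags[1], la, frags[2], lb, frags[3], lc)
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

#' Newick export / import
#'
#' Round-trips topology and branch lengths (to at least 6 decimals) through
#' [ape::write.tree()] / [ape::read.tree()]. `from_newick()` reports the
#' character position of unbalanced parentheses before delegating to ape.
#'
#' @param tree An `ape::phylo` object.
#' @return `to_newick()`: a single Newick string; `from_newick()`: a `phylo`.
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' @rdname to_newick
#' @param text Newick text.
#' @export
from_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (k in seq_along(chars)) {
    if (chars[k] == "(") depth <- depth + 1L
    if (chars[k] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("newick parse error at position ", k,
                           ": unbalanced ')'")
    }
  }
  if (depth != 0L) stop("newick parse error at position ", length(chars),
                        ": ", depth, " unclosed '('")
  tree <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree)) stop("newick parse error: unreadable tree text")
  tree
}

#' Identity-threshold clade grouping
#'
#' Single-linkage components of the graph linking sequence pairs with global
#' identity at or above the threshold (the published clade rule groups
#' transporters at > 42% identity). Groups are numbered by their smallest
#' member index, so the partition is deterministic.
#'
#' @param proteins Named character vector of protein sequences.
#' @param scheme A [scoring_scheme()].
#' @param threshold_pct Linking threshold (percent identity).
#' @return Data frame with columns `label` and `group` (1-based integer).
#' @export
identity_clades <- function(proteins, scheme = scoring_scheme(),
                            threshold_pct = 42) {
  n <- length(proteins)
  stopifnot(n >= 1L)
  labels <- names(proteins)
  if (is.null(labels)) labels <- paste0("seq", seq_len(n))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        idy <- align_global(proteins[[i]], proteins[[j]], scheme)$identity_pct
        if (idy >= threshold_pct) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  group <- match(roots, sort(unique(roots)))
  data.frame(label = labels, group = group, stringsAsFactors = FALSE)
}
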