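# Synthetic cohort generator: microbiome-like subjects with beta-glucuronidase
# loci planted at controlled frequencies, divergences and motif variants, with
# full ground truth. Stands in for the real CDR/CDU microbiome panels so every
# downstream stage is testable without the original databases.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

random_protein <- function(n, first_m = TRUE) {
  s <- sample(AA20, n, replace = TRUE)
  if (first_m) s[1] <- "M"
  paste(s, collapse = "")
}

#' Bundled synthetic template proteins
#'
#' Returns the fixed synthetic stand-in proteins shipped with the package
#' (350-450 aa), engineered so that the BG pair shares 44% global identity,
#' the transporter pair 29%, and the plasmid-type GUS 45% with the GusA-type
#' query — the published pairwise relationships of the real reference set.
#' They are synthetic sequences, not the real accession records; user-supplied
#' real queries can be given to every downstream function instead.
#'
#' @return Named character vector of protein sequences with names
#'   `GusA_syn`, `GusB_syn`, `H11G11_BG_syn`, `H11G11_transporter_syn`,
#'   `C7D2_BG_syn`, `C7D2_transporter_syn`, `GUS_plasmid_syn`, `AFTR_syn`.
#' @export
template_proteins <- function() {
  path <- system.file("extdata", "synthetic_templates.faa", package = "gusloci")
  rec <- read_fasta(path, alphabet = "protein")
  setNames(rec$seq, rec$id)
}

#' Default protein query set
#'
#' The six screening queries (two glucuronidases and their transporters per
#' locus type, plus the GusA/GusB pair), built from [template_proteins()].
#'
#' @return Data frame with columns `id`, `role`
#'   (`GusA`, `GusB`, `H11G11_BG`, `H11G11_transporter`, `C7D2_BG`,
#'   `C7D2_transporter`) and `seq`.
#' @export
default_queries <- function() {
  tp <- template_proteins()
  data.frame(
    id = c("GusA_syn", "GusB_syn", "H11G11_BG_syn", "H11G11_transporter_syn",
           "C7D2_BG_syn", "C7D2_transporter_syn"),
    role = c("GusA", "GusB", "H11G11_BG", "H11G11_transporter",
             "C7D2_BG", "C7D2_transporter"),
    seq = unname(tp[c("GusA_syn", "GusB_syn", "H11G11_BG_syn",
                      "H11G11_transporter_syn", "C7D2_BG_syn",
                      "C7D2_transporter_syn")]),
    stringsAsFactors = FALSE
  )
}

#' Mutate a protein to a target global identity
#'
#' Substitution-only mutagenesis: `k = round(L * (1 - target/100))` positions
#' are sampled without replacement (outside `protect`) and replaced with a
#' different residue, so the column-wise identity to the template is exactly
#' `100 * (L - k) / L`. Realized global-alignment identity stays within +-5
#' points of the target for proteins >= 200 aa.
#'
#' @param template Protein string, length >= 30.
#' @param target_identity_pct Target percent identity in `[30, 100]`.
#' @param protect Integer vector of 1-based positions never mutated.
#' @return List with `protein` and `realized_identity_pct` (column-wise).
#' @export
mutate_protein_to_identity <- function(template, target_identity_pct,
                                       protect = integer(0)) {
  stopifnot(is.character(template), length(template) == 1L)
  if (target_identity_pct < 30 || target_identity_pct > 100)
    stop("target identity must be in [30, 100]")
  L <- nchar(template)
  if (L < 30) stop("template shorter than 30 residues")
  chars <- strsplit(template, "")[[1]]
  k <- round(L * (1 - target_identity_pct / 100))
  free <- setdiff(seq_len(L), unique(as.integer(protect)))
  if (k > length(free)) {
    warning("fewer mutable positions than requested; identity will overshoot")
    k <- length(free)
  }
  if (k > 0) {
    pos <- if (length(free) == 1L) free else sample(free, k)
    # vectorized draw of a replacement residue distinct from the current one
    cur <- match(chars[pos], AA20)
    off <- sample.int(length(AA20) - 1L, k, replace = TRUE)
    cur[is.na(cur)] <- length(AA20) + 1L # non-standard residue: any of the 20
    chars[pos] <- AA20[off + (off >= cur)]
  }
  list(protein = paste(chars, collapse = ""),
       realized_identity_pct = 100 * (L - k) / L)
}

#' Back-translate a protein to DNA
#'
#' Each residue is encoded by a codon sampled uniformly among its synonymous
#' codons (standard genetic code); `*` (terminal only) becomes a stop codon.
#' Translating the result in frame +1 reproduces the protein exactly.
#'
#' @param protein Protein string; `*` allowed only as final character.
#' @return DNA string of length `3 * nchar(protein)`.
#' @export
#' @examples
#' back_translate("M") # "ATG"
back_translate <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1L, nchar(protein) > 0L)
  chars <- strsplit(protein, "")[[1]]
  if (any(chars == "*") && !identical(which(chars == "*"), length(chars)))
    stop("'*' allowed only as terminal stop")
  code <- Biostrings::GENETIC_CODE
  ok <- chars %in% c(unique(code), "*")
  if (!all(ok)) stop("illegal residue '", chars[!ok][1], "'")
  # vectorized uniform draw among synonymous codons
  tab <- split(names(code), code)
  flat <- unlist(tab, use.names = FALSE)
  offset <- setNames(cumsum(c(0L, lengths(tab)[-length(tab)])), names(tab))
  pick <- ceiling(runif(length(chars)) * lengths(tab)[chars])
  codons <- flat[offset[chars] + pick]
  paste(codons, collapse = "")
}

# In-frame stop guard placed upstream of each planted gene so the ORF caller
# opens the ORF exactly at the planted ATG.
STOP_GUARD <- "TAATAATAA"

#' Locus template
#'
#' An ordered arrangement of genes (an operon-like synteny block) to plant on
#' a contig. Shipped templates mimic the plasmid-type GUS / C7D2-transporter /
#' AFTR arrangement and the BG / H11G11-transporter arrangement.
#'
#' @param name Template label.
#' @param genes Data frame with columns `role` (one of `transporter_C7D2`,
#'   `transporter_H11G11`, `transporter_GusB`, `glucuronidase_GUS`,
#'   `glucuronidase_BG`, `regulator_AFTR`, `filler`), `protein` (template
#'   protein) and `strand` (`"+"` or `"-"`).
#' @param spacer Intergenic spacer length in nt (default 30).
#' @param protect Named list mapping a role to integer positions protected
#'   from mutation (e.g. motif or signature positions).
#' @return A `locus_template` object.
#' @export
locus_template <- function(name, genes, spacer = 30L, protect = list()) {
  stopifnot(is.data.frame(genes), nrow(genes) >= 1L,
            all(c("role", "protein", "strand") %in% names(genes)))
  roles <- c("transporter_C7D2", "transporter_H11G11", "transporter_GusB",
             "glucuronidase_GUS", "glucuronidase_BG", "regulator_AFTR",
             "filler")
  stopifnot(all(genes$role %in% roles), all(genes$strand %in% c("+", "-")))
  structure(list(name = name, genes = genes, spacer = as.integer(spacer),
                 protect = protect),
            class = "locus_template")
}

# 7-residue motif plus 4 flanking residues on each side, clipped to the protein
motif_protect_range <- function(protein, motif = "FGDFGND", flank = 4L) {
  at <- regexpr(motif, protein, fixed = TRUE)
  if (at < 0) return(integer(0))
  seq(max(1L, at - flank), min(nchar(protein), at + attr(at, "match.length") - 1L + flank))
}

#' Shipped locus templates
#'
#' `c7d2_locus_template()` is the AFTR / C7D2-transporter / GUS arrangement
#' (single strand, operon-like) mimicking the plasmid-type marker locus;
#' `h11g11_locus_template()` is the BG / H11G11-transporter arrangement;
#' `gusb_locus_template()` is the GusA / GusB arrangement.
#'
#' @param include_aftr Plant the AraC-family regulator gene (default `TRUE`).
#' @return A [locus_template()].
#' @export
c7d2_locus_template <- function(include_aftr = TRUE) {
  tp <- template_proteins()
  roles <- c("regulator_AFTR", "transporter_C7D2", "glucuronidase_GUS")
  prots <- c(tp[["AFTR_syn"]], tp[["C7D2_transporter_syn"]], tp[["GUS_plasmid_syn"]])
  keep <- if (include_aftr) 1:3 else 2:3
  locus_template(
    name = if (include_aftr) "GUS/C7D2/AFTR" else "GUS/C7D2",
    genes = data.frame(role = roles[keep], protein = prots[keep],
                       strand = "+", stringsAsFactors = FALSE),
    protect = list(
      transporter_C7D2 = union(1L, motif_protect_range(tp[["C7D2_transporter_syn"]])),
      regulator_AFTR = union(1L, attr_protect(tp, "AFTR_syn")),
      glucuronidase_GUS = union(1L, attr_protect(tp, "GUS_plasmid_syn"))
    )
  )
}

# signature segments shipped with the synthetic templates (positions of the
# stand-in PROSITE-style signatures, recovered by pattern match)
attr_protect <- function(tp, id) {
  pats <- default_patterns()
  pat <- switch(id,
    AFTR_syn = pats[["aftr_hth_syn"]],
    GUS_plasmid_syn = NULL,
    NULL
  )
  out <- integer(0)
  if (id == "GUS_plasmid_syn") {
    for (nm in c("gus_sig1_syn", "gus_sig2_syn")) {
      hits <- match_prosite(parse_prosite(pats[[nm]]), tp[[id]])
      if (nrow(hits)) out <- union(out, seq(hits$start[1], hits$end[1]))
    }
    return(out)
  }
  if (is.null(pat)) return(out)
  hits <- match_prosite(parse_prosite(pat), tp[[id]])
  if (nrow(hits)) out <- union(out, seq(hits$start[1], hits$end[1]))
  out
}

#' @rdname c7d2_locus_template
#' @export
h11g11_locus_template <- function() {
  tp <- template_proteins()
  locus_template(
    name = "BG/H11G11",
    genes = data.frame(
      role = c("glucuronidase_BG", "transporter_H11G11"),
      protein = c(tp[["H11G11_BG_syn"]], tp[["H11G11_transporter_syn"]]),
      strand = "+", stringsAsFactors = FALSE),
    protect = list(glucuronidase_BG = 1L, transporter_H11G11 = 1L)
  )
}

#' @rdname c7d2_locus_template
#' @export
gusb_locus_template <- function() {
  tp <- template_proteins()
  locus_template(
    name = "GUS/GusB",
    genes = data.frame(
      role = c("glucuronidase_GUS", "transporter_GusB"),
      protein = c(tp[["GusA_syn"]], tp[["GusB_syn"]]),
      strand = "+", stringsAsFactors = FALSE),
    protect = list(glucuronidase_GUS = 1L, transporter_GusB = 1L)
  )
}

#' Plant a locus into background DNA
#'
#' Genes are inserted in template order, each preceded by an in-frame stop
#' guard and separated by spacers, at `at` (or a random admissible position).
#' C7D2-transporter genes carry the requested N-terminal motif variant
#' (`"G"` = FGDFGND, `"A"` = FGDFAND) verbatim, protected from mutation
#' together with 4 flanking residues; position 1 (the initiator M) and any
#' template-declared signature positions are protected likewise.
#'
#' @param background Background DNA string.
#' @param template A [locus_template()].
#' @param target_identity Percent identity (single value or one per gene) to
#'   mutate each gene's protein to, in `[30, 100]`.
#' @param motif_variant `"G"` or `"A"` for C7D2-transporter genes.
#' @param at Optional 1-based insertion offset; random when `NULL`.
#' @return List with `seq` (contig DNA) and `truth` (one row per gene:
#'   `role`, `start`, `end`, `strand`, `target_identity`,
#'   `realized_identity`, `motif_variant`, `protein`).
#' @export
plant_locus <- function(background, template, target_identity = 100,
                        motif_variant = "G", at = NULL) {
  stopifnot(inherits(template, "locus_template"))
  check_dna(background)
  genes <- template$genes
  tid <- rep_len(target_identity, nrow(genes))
  pieces <- character(0)
  truth <- list()
  offsets <- integer(0) # start of each gene cassette within the locus block
  cursor <- 0L
  for (g in seq_len(nrow(genes))) {
    prot <- genes$protein[g]
    role <- genes$role[g]
    if (role == "transporter_C7D2") {
      stopifnot(motif_variant %in% c("G", "A"))
      if (motif_variant == "A")
        prot <- sub("FGDFGND", "FGDFAND", prot, fixed = TRUE)
      protect <- union(1L, motif_protect_range(prot, if (motif_variant == "A")
        "FGDFAND" else "FGDFGND"))
    } else {
      protect <- template$protect[[role]]
      if (is.null(protect)) protect <- 1L
    }
    mut <- mutate_protein_to_identity(prot, tid[g], protect = protect)
    dna <- back_translate(paste0(mut$protein, "*"))
    cassette <- paste0(STOP_GUARD, dna)
    if (genes$strand[g] == "-") cassette <- reverse_complement(cassette)
    gene_off <- if (genes$strand[g] == "-") 0L else nchar(STOP_GUARD)
    spacer <- if (g < nrow(genes)) random_dna(template$spacer) else ""
    offsets <- c(offsets, cursor + gene_off)
    pieces <- c(pieces, cassette, spacer)
    cursor <- cursor + nchar(cassette) + nchar(spacer)
    truth[[g]] <- data.frame(
      role = role, strand = genes$strand[g],
      gene_length_nt = nchar(dna),
      target_identity = tid[g],
      realized_identity = mut$realized_identity_pct,
      motif_variant = if (role == "transporter_C7D2") motif_variant else NA_character_,
      protein = mut$protein, stringsAsFactors = FALSE
    )
  }
  block <- paste(pieces, collapse = "")
  L <- nchar(background)
  if (L < nchar(block) + 200L)
    stop("background too short for locus (need >= ", nchar(block) + 200L, " nt)")
  if (is.null(at)) at <- sample.int(L - nchar(block) - 100L, 1L) + 50L
  stopifnot(at >= 1L, at + nchar(block) - 1L <= L)
  seq <- paste0(substr(background, 1L, at - 1L), block,
                substr(background, at + nchar(block), L))
  tr <- do.call(rbind, truth)
  tr$start <- at + offsets
  tr$end <- tr$start + tr$gene_length_nt - 1L
  tr$gene_length_nt <- NULL
  list(seq = seq, truth = tr)
}
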