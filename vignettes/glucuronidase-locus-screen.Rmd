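---
title: "Screening gut microbiomes for beta-glucuronidase loci: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening gut microbiomes for beta-glucuronidase loci: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gusloci)
```

## The scientific problem

Bacterial beta-glucuronidases (EC 3.2.1.31) hydrolyse glucuronidated
compounds in the gut, releasing the aglycone — often a reactivated toxin,
hormone or drug metabolite. Two sequence families occur in the human gut
microbiota: the GUS family (homologous to *E. coli* GusA, variably present,
with known harmful reactivation activities) and the BG family (homologous to
the metagenomically identified H11G11 enzyme, part of the healthy functional
core). Each is co-encoded with a glucuronide transporter that imports the
substrate.

`gusloci` implements a sequence-based screen that asks whether a microbiome
carries a particular glucuronide transporter class — C7D2, H11G11 or GusB —
and in what genomic context. The marker of interest is a conserved C7D2-class
transporter that occurs at high frequency in Crohn's-disease-related (CDR)
microbiomes and rarely in unrelated healthy (CDU) ones, typically in synteny
with a GUS glucuronidase and an AraC-family transcriptional regulator (AFTR),
the arrangement otherwise seen on an *Eubacterium eligens* plasmid. A
seven-residue N-terminal motif of the transporter, FGDFGND, marks the
disease-related variant; the single-substitution variant FGDFAND appears in
transporters from healthy subjects.

The pipeline is: translated homology search of contigs -> best-hit
classification -> ORF calling and neighborhood annotation -> motif and locus
calls -> neighbor-joining tree and identity clades -> cohort statistics.
Because the original microbiome databases are not redistributable, the
package ships a fully ground-truthed synthetic cohort generator, so every
stage is testable end to end.

## Translated search

`translated_search()` is a full-sensitivity equivalent of a tBlastn screen at
desk scale: each protein query is aligned (Smith–Waterman, affine gaps,
BLOSUM62, gap open 10 / extend 0.5) against all six reading-frame
translations of every contig; there is no heuristic seeding, so no hit can be
missed. Stops are rendered `*` and score −4 against residues, which confines
local alignments to coding regions without an explicit ORF step. A hit is
retained iff identity ≥ 30% and query coverage ≥ 80% (after rounding to one
decimal), the thresholds of the original screen. Coverage is measured on the
query, matching tBlastn reporting — the original report does not state the
denominator, so this is a documented choice.

Alignment details that matter for reproducibility:

* identity is `matches / alignment columns` *including* gap columns
  (ClustalW-style), for both local and global alignments; the convention is
  stated because reported identities shift a point or two between
  conventions;
* among score-optimal alignments the traceback maximises the number of
  identical pairs (the DP optimises the pair `(score, matches)`
  lexicographically, packed into one 64-bit integer), then takes the smallest
  end coordinates — alignments are fully deterministic;
* `X` (unknown, including translated `N`) scores 0 against everything;
* gap of length *L* costs `open + L * extend`.

The alignment engine is ~40 lines of C++ (Rcpp); its scores are cross-checked
in the tests against `Biostrings::pairwiseAlignment` on hundreds of random
pairs and against an exhaustive alignment-enumeration oracle on all length
combinations up to 8 residues.

## ORF calling and neighborhood annotation

`call_orfs()` is a deterministic stand-in for an HMM gene caller, adequate
for planted loci and clean prokaryotic-style genes: ATG-initiated,
first-in-frame-stop terminated, both strands, minimum 50 aa, nested ORFs
sharing a stop collapsed to the longest. ORFs truncated by the contig edge
are flagged partial and the flag propagates into locus calls.
`select_gene_models()` then keeps a single gene model per region (greedy by
length, ≤ 30 nt overlap allowed), because raw six-frame ORF lists contain
reverse-strand shadows of real genes that would otherwise dilute gene-order
windows.

`annotate_neighborhood()` labels each gene model by the role family of its
best query hit passing the screen filters. Two pattern-based labels
complement homology: an ORF matching *all* GUS consensus signature patterns
is `glucuronidase:GUS` even when it is too diverged for the GusA query
(divergent GUS homologs conserve the signatures), and an ORF matching the
regulator pattern is `AFTR`. A short ORF that cannot reach 80% query coverage
is skipped without aligning — the bound `coverage <= ORF length / query
length` makes this exact, not a heuristic.

`classify_locus()` applies the synteny rule: within a window of 4 consecutive
gene models containing a transporter, on the same strand (the marker locus is
a single transcriptional unit), the label concatenates glucuronidase class,
transporter class and `/AFTR` — e.g. `GUS/C7D2/AFTR`. The window size is a
design choice; the original report never quantifies "neighborhood", and 4
genes spans the three-gene marker locus plus one interloper.

## PROSITE patterns

`parse_prosite()`/`match_prosite()` implement the PROSITE grammar (literals,
`x` wildcards, `[..]` classes, `{..}` exclusions, `(n)`/`(n,m)` ranges,
`<`/`>` anchors). Matching is leftmost non-overlapping with greedy,
backtracking repetition — by construction equivalent to the pattern's
regular-expression translation, which serves as the test oracle on 1000
random fixtures. `discover_pattern()` is a deliberately simple conserved-
column inducer for gapless alignments (literal / ≤3-residue class / wildcard
per column, wildcard runs collapsed), sufficient to recover the
`F-G-D-F-[AG]-N-D` motif core from aligned transporter N-termini; it is not a
full flexible-gap pattern search.

The shipped signature patterns for GUS and the AFTR DNA-binding segment are
*synthetic stand-ins* matched to the bundled template proteins. The curated
PROSITE entries (PS00719, PS00608, PS01124) are not transcribed into the
package — copying them from memory risks silent corruption — but any patterns
file supplied via `default_patterns(path)` or the CLI `--patterns` option
replaces the defaults, which is the intended route for real data.

The N-terminal motif scan (`scan_nterminal_motif()`) looks for the exact
strings FGDFGND then FGDFAND starting within the first 50 residues; the
transporter motif is N-terminal and 50 aa bounds the region generously while
excluding chance internal matches.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions: two cohorts (13 CDR
subjects of whom 4 are patients, 32 CDU subjects), one 10 kb contig per
planted locus plus one background contig per subject, i.i.d. background DNA
at GC 0.45. The default design plants:

* the C7D2 locus (AFTR – C7D2 transporter – GUS, one strand, operon-like
  spacing) in 12/13 CDR and 8/32 CDU subjects; every CDR carrier has the
  FGDFGND motif; CDU carriers split 3 G / 5 A; the full three-gene locus is
  planted in 8 CDR carriers and in 3 CDU A-carriers (so no CDU subject ever
  carries the GUS + FGDFGND + AFTR combination, and the per-cohort full-locus
  frequencies land at 61.5% vs 9.4%, inside the reported 50–75% and 8–16%
  bands);
* C7D2 gene identities to the query drawn uniformly from 85–100% in CDR and
  60–90% in CDU — CDR transporters are highly conserved, CDU homologs
  diverse, which reproduces the clade structure at the 42% threshold;
* the BG/H11G11 locus mostly in healthy subjects (4/13 vs 16/32, identities
  60–95%), and a GusA/GusB locus sporadically (2/13 vs 5/32);
* BMI from normal(19, 2) for patients (underweight, as in active disease),
  normal(27, 3) for unaffected relatives (reported as high-BMI), normal(23, 3)
  for healthy subjects; gender Bernoulli(0.5).

Mutagenesis is substitution-only: `k = round(L (1 - t/100))` positions are
replaced by a different residue, so column-wise identity is exactly
`(L-k)/L` and realized global-alignment identity stays within ±5 points of
target. The initiator methionine, the 7-residue motif ± 4 flanking residues,
and the signature segments are protected from mutation — the marker must be
controllable independently of divergence. Back-translation samples synonymous
codons uniformly. Each gene cassette is preceded by an in-frame stop guard so
the ORF caller opens exactly at the planted ATG.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: read-level noise and assembly artifacts, repeats
and compositional bias in background DNA, indel divergence between homologs
(indel robustness is exercised separately with hand-built fixtures), strain
phylogenies, and horizontal transfer. The generator is a pure function of its
design (including the seed): identical designs give byte-identical FASTA.

The bundled template proteins (350–450 aa) are synthetic sequences engineered
to the published pairwise identities of the real reference set — 44% between
the BG pair, 29% between the transporter pair, 45% between the plasmid-type
GUS and GusA — with cross-family identities of 15–18%, far below the 30%
screen threshold. They are stand-ins, not the real accession records; real
query FASTA files drop in via `read_queries()`.

## Phylogenetics and clades

`pdistance_matrix()` uses `d = 1 - identity/100` from global alignments
rather than model-corrected distances, because the groupings of interest are
defined directly by raw identity percentages. `nj_build()` is canonical
Saitou–Nei neighbor joining (Q-criterion, standard branch-length formulas,
lowest-index tie-break); negative branch estimates are clamped to zero with a
flag. On additive matrices the generating tree is recovered exactly —
verified on 100 random 4–6-taxon trees against `ape`-generated references.
`identity_clades()` forms single-linkage components of the ≥ 42%-identity
graph, the published clade rule. In the tree stage each contig region enters
once, under its best query's name: without that deduplication a single gene
hit by two queries bridges otherwise distinct clades.

## Statistics

* Fisher exact test (`fisher_exact_2x2()`): two-sided p as the sum of
  hypergeometric probabilities ≤ the observed table's (the R convention;
  stated because two-sided conventions differ). Verified against full
  enumeration for every 2×2 table with N ≤ 40.
* Pearson chi-squared with optional Yates correction for the gender check.
* Mann–Whitney U (`mann_whitney_u()`): U = min(U1, U2); exact p by
  rank-assignment enumeration (no ties, n1+n2 ≤ 12), otherwise the
  tie-corrected normal approximation *with* continuity correction — identical
  groups still give p = 1 (the correction vanishes at the null center), and
  the approximation stays within 0.1 of the exact p from n1+n2 ≥ 6; below
  that it is poor and exact mode should be used. The original methods speak
  of comparing "variances of amino acid sequence convergence"; this package
  implements the standard MWU on the identity values themselves, reading the
  phrasing as imprecise rather than as a dispersion test.
* Bray–Curtis dissimilarities (via `vegan`) on the subjects × queries
  identity-profile matrix (best retained identity, 0 when absent) feed
  `pcoa()`: Gower double-centering eigendecomposition, axes ordered by
  eigenvalue, negative-eigenvalue axes recorded but dropped, axis signs fixed
  by making the largest-magnitude loading positive.
* Quartiles are type-7 (linear interpolation).

`marker_frequency_report()` assembles per-cohort carrier counts and
frequencies (one decimal) for the C7D2 transporter, each motif variant and
the full `GUS/C7D2/AFTR` locus, a Fisher p per marker, and BMI/gender bias
checks between carriers and non-carriers. No multiple-testing correction is
applied, matching the original analysis. A frequently puzzling constant: the
published carrier counts imply an exact Fisher p of about 4e-5 for the
12/13-vs-8/32 table, while the original text prints p = 0.088 next to the
92%-vs-32% comparison; no 2×2 assembled from any printed counts yields 0.088,
so this package always reports the computed exact value.

## Problem sizes used by the tests

The default pipeline run and the acceptance script use the full 45-subject
design with 10 kb contigs (~1 minute on one core). The planted-recovery suite
runs 20 seeded cohorts at full subject count with C7D2-only planting — the
other locus types cannot produce C7D2 carrier calls at these thresholds, so
omitting them leaves the checked quantities unchanged while keeping the sweep
to a few minutes. Oracle-equivalence suites run exhaustively at small n
(alignments ≤ 8 aa; all 2×2 tables with N ≤ 40 up to their p-value
symmetries; all MWU group splits with n1+n2 ≤ 8).

## Known limitations

* The ORF caller has no start-codon model beyond ATG and no GTG/TTG starts;
  real Firmicute genes occasionally start otherwise.
* Substitution-only divergence means the identity targeting is analytic but
  real homologs also differ by indels; the alignment layer handles indels
  (affine gaps), the generator simply does not produce them.
* The PRATT-like inducer requires pre-aligned, gapless input.
* PCoA axes for strongly non-Euclidean dissimilarity matrices drop
  negative-eigenvalue components rather than applying a correction.
* The shipped signature patterns are synthetic; real-data runs should supply
  curated PROSITE entries.
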