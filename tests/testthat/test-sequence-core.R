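# Sequence I/O, translation, ORF calling and the alignment primitives.

test_that("FASTA round-trip is lossless for ids and sequences", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT"), f)
  rec <- read_fasta(f, alphabet = "dna")
  expect_equal(rec$id, "a")
  expect_equal(rec$seq, "ACGT")

  set.seed(3)
  recs <- data.frame(
    id = sprintf("r%03d_%s", 1:100, replicate(100, random_peptide(4))),
    seq = replicate(100, random_contig(sample(1:200, 1))))
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f2)
  back <- read_fasta(f2, alphabet = "dna")
  expect_identical(back$id, recs$id)
  expect_identical(back$seq, recs$seq)
  # 60-column wrap on write
  lines <- readLines(f2)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
})

test_that("FASTA parse errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "AC!T"), f)
  expect_error(read_fasta(f, alphabet = "dna"), "line 2")
  writeLines(c("ACGT", ">a"), f)
  expect_error(read_fasta(f), "line 1")
  writeLines(c(">", "ACGT"), f)
  expect_error(read_fasta(f), "line 1.*header")
  writeLines(c(">p", "MK*T"), f) # internal stop is still alphabet-legal
  expect_silent(read_fasta(f, alphabet = "protein"))
  expect_error(read_fasta("no/such/file.fasta"), "not found")
})

test_that("reverse_complement is an involution and maps N to N", {
  expect_equal(reverse_complement("ATG"), "CAT")
  expect_equal(reverse_complement("ANT"), "ANT")
  set.seed(4)
  x <- random_contig(1000)
  expect_equal(reverse_complement(reverse_complement(x)), x)
  expect_error(reverse_complement(""), "empty")
  expect_error(reverse_complement("ACGU"), "illegal")
})

test_that("six-frame translation follows the standard genetic code", {
  fr <- six_frame_translate("ATGAAATAA")
  expect_equal(fr[["+1"]], "MK*")
  expect_equal(six_frame_translate("ATG")[["-1"]], "H") # revcomp CAT
  expect_equal(six_frame_translate("ATGNAA")[["+1"]], "MX")
  # per-frame residue counts follow floor((L - offset) / 3) on both strands
  set.seed(5)
  for (L in c(9, 10, 11, 23, 40)) {
    dna <- random_contig(L)
    fr <- six_frame_translate(dna)
    for (off in 0:2) {
      expect_equal(nchar(fr[[paste0("+", off + 1)]]), (L - off) %/% 3)
      expect_equal(nchar(fr[[paste0("-", off + 1)]]), (L - off) %/% 3)
    }
  }
})

test_that("ORF caller matches a direct codon-walk oracle", {
  o <- call_orfs("ATGAAATAA", min_aa = 2)
  expect_equal(nrow(o), 1L)
  expect_equal(o$protein, "MK")
  expect_equal(c(o$start, o$end, o$strand, o$partial),
               c("1", "9", "+", "FALSE"))
  expect_equal(nrow(call_orfs("CCCCCC", min_aa = 0)), 0L)

  set.seed(6)
  for (rep in 1:6) {
    dna <- random_contig(2000, gc = runif(1, 0.3, 0.6))
    for (min_aa in c(0, 20)) {
      got <- call_orfs(dna, min_aa = min_aa)
      want <- oracle_orfs(dna, min_aa = min_aa)
      expect_equal(got[, c("start", "end", "strand", "length_aa", "partial")],
                   want, ignore_attr = TRUE)
    }
  }
})

test_that("re-translating a called ORF's nucleotide slice reproduces its protein", {
  set.seed(7)
  dna <- random_contig(3000)
  orfs <- call_orfs(dna, min_aa = 10)
  expect_gt(nrow(orfs), 0L)
  for (k in seq_len(nrow(orfs))) {
    slice <- substr(dna, orfs$start[k], orfs$end[k])
    if (orfs$strand[k] == "-") slice <- reverse_complement(slice)
    prot <- six_frame_translate(paste0(slice, "AAA"))[["+1"]]
    prot <- substr(prot, 1, orfs$length_aa[k])
    expect_equal(prot, orfs$protein[k])
  }
})

test_that("gene-model selection keeps the longest non-overlapping ORFs", {
  orfs <- data.frame(
    contig_id = "c", start = c(1, 50, 400, 1000), end = c(390, 250, 900, 1200),
    strand = "+", frame = 1L, length_aa = c(129, 66, 166, 66),
    partial = FALSE, protein = "M")
  sel <- select_gene_models(orfs)
  expect_equal(sel$start, c(1, 400, 1000)) # 50-250 lost to the longer 1-390
})

test_that("scoring scheme validates penalties and zeroes the X column", {
  sch <- scoring_scheme()
  expect_true(all(sch$matrix["X", ] == 0))
  expect_error(scoring_scheme(gap_open = 1, gap_extend = 2), "gap_extend")
})

test_that("alignment identities and spans behave on reference examples", {
  sch <- scoring_scheme()
  pep <- "MKTAYIAKQR"
  aln <- align_local(pep, pep, sch)
  expect_equal(aln$identity_pct, 100)
  expect_equal(aln$coverage_pct, 100)

  g <- align_global("MKT", "MRT", sch)
  expect_equal(g$matches, 2L)
  expect_equal(g$aligned_columns, 3L)
  expect_equal(g$identity_pct, 200 / 3)

  # symmetry of the global score and identity
  set.seed(8)
  for (i in 1:10) {
    a <- random_peptide(sample(5:25, 1)); b <- random_peptide(sample(5:25, 1))
    ab <- align_global(a, b, sch); ba <- align_global(b, a, sch)
    expect_equal(ab$score, ba$score)
    expect_equal(ab$identity_pct, ba$identity_pct)
  }

  # unrelated single residue: no positive-scoring alignment, reported no-hit
  expect_null(align_local("MKT", "W", sch))
  expect_error(align_local("", "MKT", sch), "empty")
})

test_that("local score dominates the zero-clipped global score", {
  sch <- scoring_scheme()
  set.seed(9)
  for (i in 1:15) {
    a <- random_peptide(sample(3:12, 1)); b <- random_peptide(sample(3:12, 1))
    l <- align_local(a, b, sch); g <- align_global(a, b, sch)
    ls <- if (is.null(l)) 0 else l$score
    expect_gte(ls, 0)
    expect_gte(ls, max(g$score, 0))
  }
})

test_that("alignments match the exhaustive-enumeration oracle on small pairs", {
  sch <- scoring_scheme()
  set.seed(10)
  for (i in 1:25) {
    a <- random_peptide(sample(2:5, 1)); b <- random_peptide(sample(2:5, 1))
    for (local in c(TRUE, FALSE)) {
      o <- oracle_align(a, b, sch, local = local)
      m <- if (local) align_local(a, b, sch) else align_global(a, b, sch)
      ms <- if (is.null(m)) 0 else m$score
      expect_equal(ms, o$score, tolerance = 1e-9)
      if (!is.null(m) && m$score > 0) expect_equal(m$matches, o$matches)
    }
  }
})
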