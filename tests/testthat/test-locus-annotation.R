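# PROSITE parsing/matching, pattern induction, motif calls and synteny
# classification.

test_that("PROSITE parser compiles the grammar and reports error columns", {
  p <- parse_prosite("F-G-D-F-[GA]-N-D")
  expect_length(p$elements, 7L)
  expect_equal(sum(vapply(p$elements, function(e) e$type == "class", TRUE)), 1L)
  expect_equal(p$elements[[5]]$residues, c("G", "A"))

  r <- parse_prosite("A-x(2,3)-C")
  expect_equal(r$elements[[2]]$min, 2L)
  expect_equal(r$elements[[2]]$max, 3L)

  a <- parse_prosite("<M-K>")
  expect_true(a$anchor_start && a$anchor_end)
  e <- parse_prosite("A-{ST}-C")
  expect_equal(e$elements[[2]]$type, "exclusion")

  expect_error(parse_prosite("A-["), "column 3")
  expect_error(parse_prosite("A--C"), "column")
  expect_error(parse_prosite("A-x(3,2)"), "maximum below minimum")
  expect_error(parse_prosite(""), "empty")
})

test_that("parse/format round-trips the pattern text", {
  for (txt in c("F-G-D-F-[GA]-N-D", "<M-x(2,3)-[DE]-{KR}(2)-C>",
                "A-x-x(4)-W", "[AG]-[ILV]-x(2)-H")) {
    p <- parse_prosite(txt)
    expect_equal(format(parse_prosite(format(p))), format(p))
  }
})

test_that("matcher finds leftmost non-overlapping spans and honors anchors", {
  m <- match_prosite("F-G-D-F-[GA]-N-D", "MKFGDFANDQ")
  expect_equal(m, data.frame(start = 3L, end = 9L), ignore_attr = TRUE)
  expect_equal(nrow(match_prosite("<M-K", "AMK")), 0L)
  expect_equal(match_prosite("<M-K", "MKA"),
               data.frame(start = 1L, end = 2L), ignore_attr = TRUE)
  expect_equal(nrow(match_prosite("A-C>", "ACA")), 0L)
  # non-overlap: AAAA with A-A gives two spans
  expect_equal(match_prosite("A-A", "AAAA")$start, c(1L, 3L))
})

test_that("matcher agrees with the regex translation on random fixtures", {
  set.seed(60)
  n_checked <- 0L
  for (i in 1:300) {
    pat <- random_prosite()
    prot <- random_peptide(sample(5:30, 1))
    got <- match_prosite(pat, prot)
    want <- regex_prosite_matches(pat, prot)
    expect_equal(got, want, ignore_attr = TRUE,
                 label = paste("pattern", pat, "on", prot))
    n_checked <- n_checked + nrow(want)
  }
  expect_gt(n_checked, 50L) # the fixtures actually exercise matches
})

test_that("N-terminal motif scanning distinguishes the G and A variants", {
  expect_equal(scan_nterminal_motif("MKFGDFGNDLL"),
               list(variant = "G", position = 3L))
  expect_equal(scan_nterminal_motif("MKFGDFANDLL"),
               list(variant = "A", position = 3L))
  expect_equal(scan_nterminal_motif("MKAAAAAA")$variant, "none")
  # G wins when both variants occur in the window
  both <- paste0("MK", "FGDFGND", "FGDFAND", random_peptide(30))
  expect_equal(scan_nterminal_motif(both)$variant, "G")
  # a motif starting beyond the window is not called
  late <- paste0(paste(rep("L", 60), collapse = ""), "FGDFGND")
  expect_equal(scan_nterminal_motif(late, window_aa = 50)$variant, "none")
  expect_equal(scan_nterminal_motif(late, window_aa = 61)$variant, "G")
})

test_that("pattern induction follows the conserved-column rule", {
  expect_equal(format(discover_pattern(c("FGDFGND", "FGDFAND"))),
               "F-G-D-F-[AG]-N-D")
  expect_equal(format(discover_pattern("MKT")), "M-K-T")
  # five distinct residues in a column collapse to x; runs collapse to x(n)
  seqs <- c("AAKAA", "ACRCA", "ADDDA", "AEWEA", "AFYFA")
  expect_equal(format(discover_pattern(seqs)), "A-x(3)-A")
  expect_error(discover_pattern(c("AA", "AAA")), "equal length")
})

test_that("induced patterns always match their inputs", {
  set.seed(61)
  for (i in 1:20) {
    base <- random_peptide(sample(8:15, 1))
    seqs <- vapply(1:4, function(j) {
      ch <- strsplit(base, "")[[1]]
      k <- sample(0:3, 1)
      if (k > 0) {
        pos <- sample(length(ch), k)
        ch[pos] <- sample(AA_STD, k, replace = TRUE)
      }
      paste(ch, collapse = "")
    }, character(1))
    pat <- discover_pattern(seqs, max_class_size = 3)
    for (s in seqs) expect_gt(nrow(match_prosite(pat, s)), 0L)
  }
})

test_that("neighborhood annotation labels planted genes in order", {
  pl <- planted_contig(seed = 62, identity = 90)
  orfs <- select_gene_models(call_orfs(pl$seq, min_aa = 50, contig_id = "c"))
  nb <- annotate_neighborhood(orfs, default_queries())
  lab <- nb$label[nb$label != "putative"]
  expect_equal(lab, c("AFTR", "transporter:C7D2", "glucuronidase:GUS"))
  tr <- nb[nb$label == "transporter:C7D2", ]
  expect_equal(tr$motif_variant, "G")
})

test_that("filler-only contigs are annotated putative throughout", {
  set.seed(63)
  contig <- random_contig(5000)
  orfs <- select_gene_models(call_orfs(contig, min_aa = 50, contig_id = "c"))
  if (nrow(orfs)) {
    nb <- annotate_neighborhood(orfs, default_queries())
    expect_true(all(nb$label == "putative"))
  }
  succeed()
})

test_that("a sequence end mid-gene propagates the partial flag", {
  pl <- planted_contig(seed = 64, identity = 95, len = 6000)
  tr <- pl$truth[pl$truth$role == "glucuronidase_GUS", ]
  cut <- substr(pl$seq, 1, tr$start + 300L) # GUS gene interrupted by the end
  contigs <- data.frame(contig_id = "cut", subject_id = "s", seq = cut)
  calls <- annotate_cohort(contigs, default_queries())
  if (nrow(calls)) expect_true(any(calls$partial))
})

test_that("locus classification concatenates classes within the window", {
  mk_nb <- function(labels, strands = "+", gap = 1500L) {
    n <- length(labels)
    data.frame(contig_id = "c", start = seq(1L, by = gap, length.out = n),
               end = seq(1300L, by = gap, length.out = n),
               strand = rep_len(strands, n), frame = 1L, length_aa = 433L,
               partial = FALSE, protein = "M",
               label = labels, best_query = NA, identity_pct = NA,
               motif_variant = "none", motif_position = NA)
  }
  lc <- classify_locus(mk_nb(c("glucuronidase:GUS", "transporter:C7D2", "AFTR")))
  expect_equal(lc$label, "GUS/C7D2/AFTR")
  lc <- classify_locus(mk_nb(c("glucuronidase:BG", "transporter:H11G11")))
  expect_equal(lc$label, "BG/H11G11")
  # glucuronidase six genes away (window 4): transporter-only label
  lc <- classify_locus(mk_nb(c("glucuronidase:GUS", rep("putative", 5),
                               "transporter:C7D2")))
  expect_equal(lc$label, "C7D2")
  # opposite strand breaks co-localization
  lc <- classify_locus(mk_nb(c("glucuronidase:GUS", "transporter:C7D2"),
                             strands = c("-", "+")))
  expect_equal(lc$label, "C7D2")
  expect_equal(nrow(classify_locus(mk_nb("putative"))), 0L)
})
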