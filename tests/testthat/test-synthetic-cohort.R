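# Synthetic cohort generator: mutation targeting, back-translation, locus
# planting and whole-cohort ground truth.

test_that("back-translation samples synonymous codons and round-trips", {
  expect_equal(back_translate("M"), "ATG")
  set.seed(20)
  d <- back_translate("MK*")
  expect_equal(nchar(d), 9L)
  expect_equal(six_frame_translate(d)[["+1"]], "MK*")
  ser <- Biostrings::GENETIC_CODE
  ser <- names(ser)[ser == "S"]
  seen <- replicate(60, back_translate("S"))
  expect_true(all(seen %in% ser))
  expect_gt(length(unique(seen)), 1L) # actually samples, not a fixed codon
  expect_error(back_translate("M*K"), "terminal")
  expect_error(back_translate("M1"), "illegal")
})

test_that("mutation hits its identity target and respects protections", {
  tpl <- gusloci:::with_seed(21, random_peptide(300))
  expect_identical(mutate_protein_to_identity(tpl, 100)$protein, tpl)
  expect_error(mutate_protein_to_identity(tpl, 20), "\\[30, 100\\]")
  expect_error(mutate_protein_to_identity(random_peptide(20), 50), "30 residues")

  set.seed(22)
  realized <- replicate(20, {
    mut <- mutate_protein_to_identity(tpl, 50)$protein
    align_global(mut, tpl)$identity_pct
  })
  expect_true(mean(realized) >= 45 && mean(realized) <= 55)
  expect_true(all(abs(realized - 50) <= 5))

  # protected positions survive heavy mutation
  set.seed(23)
  for (i in 1:5) {
    mut <- mutate_protein_to_identity(tpl, 30, protect = 11:25)$protein
    expect_equal(substr(mut, 11, 25), substr(tpl, 11, 25))
  }
})

test_that("planted loci carry the requested motif variant verbatim", {
  pl_g <- planted_contig(seed = 31, identity = 70, motif = "G")
  pl_a <- planted_contig(seed = 31, identity = 70, motif = "A")
  tr_g <- pl_g$truth$protein[pl_g$truth$role == "transporter_C7D2"]
  tr_a <- pl_a$truth$protein[pl_a$truth$role == "transporter_C7D2"]
  expect_true(grepl("FGDFGND", tr_g, fixed = TRUE))
  expect_false(grepl("FGDFAND", tr_g, fixed = TRUE))
  expect_true(grepl("FGDFAND", tr_a, fixed = TRUE))
  expect_false(grepl("FGDFGND", tr_a, fixed = TRUE))
})

test_that("a 100%-identity planted locus is recovered by annotation", {
  pl <- planted_contig(seed = 32, identity = 100)
  contigs <- data.frame(contig_id = "c1", subject_id = "s1", seq = pl$seq)
  calls <- annotate_cohort(contigs, default_queries())
  expect_equal(calls$label[calls$transporter_class == "C7D2"], "GUS/C7D2/AFTR")
  expect_equal(calls$motif_variant[calls$transporter_class == "C7D2"], "G")
})

test_that("two loci planted on one contig occupy disjoint intervals", {
  set.seed(33)
  bg <- random_contig(12000)
  p1 <- plant_locus(bg, c7d2_locus_template(), target_identity = 90, at = 100)
  p2 <- plant_locus(p1$seq, h11g11_locus_template(), target_identity = 80,
                    at = 6000)
  t1 <- p1$truth; t2 <- p2$truth
  expect_true(max(t1$end) < 6000)
  expect_true(all(t2$start >= 6000))
  expect_error(plant_locus(random_contig(1000), c7d2_locus_template(),
                           target_identity = 100), "too short")
})

test_that("generate_cohort is deterministic and honors explicit carrier counts", {
  d <- tiny_design(seed = 41)
  co1 <- generate_cohort(d)
  co2 <- generate_cohort(d)
  expect_identical(co1$contigs, co2$contigs)
  expect_identical(co1$truth, co2$truth)

  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_cohort(co1, dir1); write_cohort(co2, dir2)
  f1 <- list.files(dir1, pattern = "fasta$")
  expect_true(length(f1) == 6L)
  for (f in f1)
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))

  # planted carrier marginals equal the design exactly
  tr <- co1$truth[co1$truth$role == "transporter_C7D2", ]
  expect_equal(sum(startsWith(tr$subject_id, "CDR")), 2L)
  expect_equal(sum(startsWith(tr$subject_id, "CDU")), 1L)

  # the paper-mirroring default design: 12/13 CDR and 8/32 CDU carriers
  # (4.5 kb contigs keep this fast; the planted loci are ~4 kb)
  co_def <- generate_cohort(cohort_design(seed = 42, contig_length = 4500))
  tr <- unique(co_def$truth$subject_id[co_def$truth$role == "transporter_C7D2"])
  expect_equal(sum(startsWith(tr, "CDR")), 12L)
  expect_equal(sum(startsWith(tr, "CDU")), 8L)
  g <- unique(co_def$truth$subject_id[co_def$truth$motif_variant %in% "G"])
  expect_equal(sum(startsWith(g, "CDR")), 12L)
  expect_equal(sum(startsWith(g, "CDU")), 3L)
})

test_that("an all-zero design plants nothing", {
  d <- cohort_design(n_cdr = 2, n_cdu = 2, n_patients = 1,
                     contig_length = 5000, seed = 43,
                     c7d2 = list(carriers_cdr = 0, carriers_cdu = 0),
                     h11g11 = list(carriers_cdr = 0, carriers_cdu = 0),
                     gusb = list(carriers_cdr = 0, carriers_cdu = 0))
  co <- generate_cohort(d)
  expect_equal(nrow(co$truth), 0L)
  expect_equal(nrow(co$contigs), 4L) # one background contig per subject
})

test_that("truth coordinates translate back to the planted protein", {
  co <- generate_cohort(tiny_design(seed = 44))
  expect_gt(nrow(co$truth), 0L)
  for (k in seq_len(nrow(co$truth))) {
    row <- co$truth[k, ]
    dna <- co$contigs$seq[co$contigs$contig_id == row$contig_id]
    slice <- substr(dna, row$start, row$end)
    if (row$strand == "-") slice <- reverse_complement(slice)
    expect_equal(six_frame_translate(slice)[["+1"]], paste0(row$protein, "*"))
  }
})

test_that("planted genes re-align to their role query within 5 identity points", {
  co <- generate_cohort(tiny_design(seed = 45))
  q <- default_queries()
  role_query <- c(transporter_C7D2 = "C7D2_transporter",
                  transporter_H11G11 = "H11G11_transporter",
                  transporter_GusB = "GusB",
                  glucuronidase_BG = "H11G11_BG", glucuronidase_GUS = "GusA")
  tr <- co$truth[co$truth$role %in% c("transporter_C7D2",
                                      "transporter_H11G11"), ]
  for (k in seq_len(nrow(tr))) {
    qseq <- q$seq[q$role == role_query[[tr$role[k]]]]
    idy <- align_global(tr$protein[k], qseq)$identity_pct
    expect_lt(abs(idy - tr$target_identity[k]), 5)
  }
})
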