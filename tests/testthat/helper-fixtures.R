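# Shared fixtures built in code.

AA_STD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_peptide <- function(n, alphabet = AA_STD) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_contig <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# a small planted single-subject contig set: one C7D2 full locus
planted_contig <- function(seed = 1, identity = 100, motif = "G",
                           len = 6000, include_aftr = TRUE) {
  gusloci:::with_seed(seed, {
    pl <- plant_locus(random_contig(len),
                      c7d2_locus_template(include_aftr = include_aftr),
                      target_identity = identity, motif_variant = motif)
    pl
  })
}

tiny_design <- function(seed = 1, ...) {
  cohort_design(n_cdr = 3, n_cdu = 3, n_patients = 1, contig_length = 5000,
                seed = seed,
                c7d2 = list(carriers_cdr = 2, carriers_cdu = 1,
                            motif_g_cdu = 0, aftr_cdr = 2, aftr_cdu = 1,
                            identity_cdr = c(85, 100),
                            identity_cdu = c(60, 90)),
                h11g11 = list(carriers_cdr = 1, carriers_cdu = 2,
                              identity = c(60, 95)),
                gusb = list(carriers_cdr = 0, carriers_cdu = 1,
                            identity = c(60, 95)),
                ...)
}
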