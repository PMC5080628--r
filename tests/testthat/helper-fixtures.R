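# Fixture builders shared across test files. All fixtures are generated in
# code; nothing binary is stored.

STD_CODE <- standard_genetic_code()
EI_TAB <- load_ei_ranking(system.file("extdata", "ei_ranking_synthetic.tsv",
                                      package = "khscan"))

make_aln <- function(codons_a, codons_b, gene_id = "test") {
  codon_alignment(gene_id, paste(codons_a, collapse = ""),
                  paste(codons_b, collapse = ""))
}

# random pairwise alignment: per codon column, second sequence mutated with
# up to `max_muts` random nucleotide changes; occasional gap/N columns
random_alignment <- function(n_codons, p_mut = 0.06, max_muts = 3,
                             p_gap = 0.02, gene_id = "rand") {
  sense <- names(STD_CODE)[STD_CODE != "*"]
  a <- sample(sense, n_codons, replace = TRUE)
  b <- a
  for (i in seq_len(n_codons)) {
    if (runif(1) < p_mut) {
      for (k in seq_len(sample.int(max_muts, 1))) {
        pos <- sample.int(3, 1)
        substr(b[i], pos, pos) <- sample(c("A", "C", "G", "T"), 1)
      }
    }
    if (runif(1) < p_gap) {
      ch <- sample(c("-", "N"), 1)
      which_seq <- sample(2, 1)
      if (which_seq == 1) substr(a[i], sample.int(3, 1), sample.int(3, 1)) <- ch
      else substr(b[i], sample.int(3, 1), sample.int(3, 1)) <- ch
    }
  }
  make_aln(a, b, gene_id)
}

# deterministic gene fixture: `n` copies of a calm base codon with specified
# numbers of planted synonymous and class-specific elementary changes.
#   syn:      CCA -> CCG / CCT alternating (Pro, synonymous; mixes
#             transitions and transversions so kappa stays estimable)
#   P/S:      CCA -> TCA   (Pro -> Ser, the top-ranked class in the bundled
#                           synthetic EI file)
#   low rank: CCA -> GCA   (Pro -> Ala) ranks outside the top 10 there
planted_gene <- function(n_codons, n_syn = 0, n_high = 0, n_low = 0,
                         gene_id = "planted") {
  stopifnot(n_syn + n_high + n_low <= n_codons)
  a <- rep("CCA", n_codons)
  b <- a
  idx <- seq_len(n_syn + n_high + n_low)
  b[idx[seq_len(n_syn)]] <- rep_len(c("CCG", "CCT"), n_syn)
  if (n_high > 0) b[idx[n_syn + seq_len(n_high)]] <- "TCA"
  if (n_low > 0) b[idx[n_syn + n_high + seq_len(n_low)]] <- "GCA"
  make_aln(a, b, gene_id)
}

# Six constructed genes spanning every threshold of the screen. Base codon
# CCA; planted_gene() plants synonymous (CCG/CCT), top-class (TCA, P/S) and
# lower-class (GCA, A/P) changes in known numbers.
fixture_screen <- function() {
  list(
    # Ka comfortably above 0.05: many amino-acid changes
    ka_high = planted_gene(400, n_syn = 8, n_high = 30, n_low = 30,
                           gene_id = "ka_high"),
    # Ks above 0.08: ~40 synonymous changes over ~400 synonymous sites
    ks_high = planted_gene(400, n_syn = 40, n_high = 2, gene_id = "ks_high"),
    # Ks below 0.005: a single synonymous change
    ks_low = planted_gene(400, n_syn = 1, n_high = 2, gene_id = "ks_low"),
    # PSG: strong excess of top-class changes over synonymous background
    psg = planted_gene(500, n_syn = 3, n_high = 25, gene_id = "psg"),
    # Kh/Ks > 1 but too few changes for significance
    weak = planted_gene(500, n_syn = 3, n_high = 4, gene_id = "weak"),
    # Kh/Ks < 1: only low-exchangeability changes
    lowx = planted_gene(500, n_syn = 6, n_low = 6, gene_id = "lowx"))
}

write_fasta_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
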