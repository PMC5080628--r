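#!/usr/bin/env Rscript
# Generate the synthetic study cohorts used by the downstream analyses.
# Three cohorts of ortholog codon-alignment pairs at Ks ~ 0.02 (the
# low-divergence regime of a recently separated species pair):
#   neutral/  — all classes neutral (omega = 1): calibration baseline
#   masked/   — purifying selection confined to low-exchangeability classes
#               (omega_l = 0.1, omega_h = 1): the regime the Kh statistic is
#               designed to detect
#   contrast/ — 10 genes with the top classes accelerated (omega_h = 2)
#               against 90 purifying background genes: PSG-calling exercise
# Each cohort is written as per-gene FASTA + manifest.tsv + truth.tsv.

suppressPackageStartupMessages(library(khscan))

ei <- load_ei_ranking(system.file("extdata", "ei_ranking_synthetic.tsv",
                                  package = "khscan"))
out <- "results/sim"
seed <- 20260929 %% 2^30

message("simulating neutral cohort (200 genes x 500 codons) ...")
neutral <- simulate_cohort(
  simulation_config(n_codons = 500, n_genes = 200, kappa = 2,
                    branch_length = 0.01, seed = seed), ei)
write_cohort(neutral, file.path(out, "neutral"))

message("simulating masked-selection cohort (omega_l = 0.1) ...")
masked <- simulate_cohort(
  simulation_config(n_codons = 500, n_genes = 200, kappa = 2,
                    branch_length = 0.01, omega_high = 1, omega_low = 0.1,
                    seed = seed + 1), ei)
write_cohort(masked, file.path(out, "masked"))

message("simulating contrast cohort (10 selected + 90 background genes) ...")
alns <- list()
for (g in 1:10) {
  co <- simulate_cohort(
    simulation_config(n_codons = 500, n_genes = 1, branch_length = 0.01,
                      omega_high = 2, omega_low = 0.1, seed = seed + 100 + g),
    ei)
  aln <- co$alignments[[1]]
  aln$gene_id <- sprintf("sel%02d", g)
  alns[[aln$gene_id]] <- aln
}
for (g in 1:90) {
  co <- simulate_cohort(
    simulation_config(n_codons = 500, n_genes = 1, branch_length = 0.01,
                      omega_high = 0.1, omega_low = 0.1,
                      seed = seed + 200 + g), ei)
  aln <- co$alignments[[1]]
  aln$gene_id <- sprintf("bg%02d", g)
  alns[[aln$gene_id]] <- aln
}
dir.create(file.path(out, "contrast"), recursive = TRUE, showWarnings = FALSE)
paths <- character(0)
for (nm in names(alns)) {
  p <- file.path(out, "contrast", paste0(nm, ".fasta"))
  write_codon_alignment(alns[[nm]], p)
  paths[nm] <- basename(p)
}
write.table(data.frame(gene_id = names(paths), path = paths),
            file.path(out, "contrast", "manifest.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("cohorts written under ", out)
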