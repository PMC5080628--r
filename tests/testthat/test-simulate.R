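# The mutation-selection codon-pair simulator.

test_that("zero branch length yields identical sequences", {
  cfg <- simulation_config(n_codons = 200, branch_length = 0, seed = 3)
  co <- simulate_cohort(cfg, EI_TAB)
  aln <- co$alignments[[1]]
  expect_identical(aln$seq_a, aln$seq_b)
  expect_equal(co$truth$Ns_true, 0)
})

test_that("a fixed seed reproduces the cohort byte-identically, order-independently", {
  cfg <- simulation_config(n_codons = 100, n_genes = 5,
                           branch_length = 0.02, seed = 77)
  co1 <- simulate_cohort(cfg, EI_TAB)
  co2 <- simulate_cohort(cfg, EI_TAB)
  expect_identical(lapply(co1$alignments, `[[`, "seq_a"),
                   lapply(co2$alignments, `[[`, "seq_a"))
  expect_identical(co1$Ni_true, co2$Ni_true)
  # gene i is unchanged when the cohort is enlarged (substreams by index)
  cfg10 <- simulation_config(n_codons = 100, n_genes = 10,
                             branch_length = 0.02, seed = 77)
  co3 <- simulate_cohort(cfg10, EI_TAB)
  expect_identical(co3$alignments[[3]]$seq_b, co1$alignments[[3]]$seq_b)
})

test_that("omega_low = 0 confines amino-acid changes to the top classes", {
  cfg <- simulation_config(n_codons = 3000, n_genes = 3,
                           branch_length = 0.03, omega_high = 1,
                           omega_low = 0, h_ranks = 10, seed = 21)
  co <- simulate_cohort(cfg, EI_TAB)
  expect_true(all(co$Ni_true[, 11:75] == 0))
  # endpoint-level flatness needs one hit per codon: two accepted top-class
  # events at the same position in different lineages can masquerade as one
  # lower-class change (e.g. V->I and V->L showing as I/L)
  cfg1 <- simulation_config(n_codons = 3000, n_genes = 3,
                            branch_length = 0.03, omega_high = 1,
                            omega_low = 0, h_ranks = 10, seed = 21,
                            one_hit_per_codon = TRUE)
  co <- simulate_cohort(cfg1, EI_TAB)
  cnts <- lapply(co$alignments, count_substitutions, table = EI_TAB,
                 kappa = 2)
  pooled <- pool_counts(cnts)
  # observed (single-hit) elementary changes only in ranks 1-10, so the
  # cumulative count is flat beyond the cutoff
  Ncum <- cumsum(pooled$Ni)
  expect_equal(Ncum[75], Ncum[10])
})

test_that("the event log matches pipeline counts exactly in one-hit mode", {
  cfg <- simulation_config(n_codons = 400, n_genes = 30,
                           branch_length = 0.004, seed = 13,
                           one_hit_per_codon = TRUE)
  co <- simulate_cohort(cfg, EI_TAB)
  for (i in seq_along(co$alignments)) {
    cnt <- count_substitutions(co$alignments[[i]], EI_TAB, kappa = 2)
    expect_equal(unname(cnt$Ns), co$truth$Ns_true[i])
    expect_equal(unname(cnt$Ni), unname(co$Ni_true[i, ]),
                 ignore_attr = TRUE)
  }
})

test_that("simulated fourfold sites recover the true kappa", {
  cfg <- simulation_config(n_codons = 100000, n_genes = 1, kappa = 2,
                           branch_length = 0.01, seed = 8)
  co <- simulate_cohort(cfg, EI_TAB)
  est <- estimate_kappa(co$alignments[[1]])
  expect_gt(est$n_4fold_sites, 5000)
  expect_equal(est$kappa, 2, tolerance = 0.1)  # within 2.0 +/- 0.2
})

test_that("cohort Kh/Ks is monotone in the planted omega_high", {
  grid <- c(0.5, 1, 2)
  khks <- vapply(seq_along(grid), function(gi) {
    cfg <- simulation_config(n_codons = 500, n_genes = 40,
                             branch_length = 0.01, omega_high = grid[gi],
                             omega_low = 0.2, seed = 100 + gi)
    co <- simulate_cohort(cfg, EI_TAB)
    cnts <- lapply(co$alignments, count_substitutions, table = EI_TAB,
                   kappa = 2)
    r <- compute_rates(pool_counts(cnts), kappa = 2, fisher = FALSE)
    r$Kh_Ks
  }, numeric(1))
  expect_identical(order(khks), 1:3)  # Spearman rho = 1 over the grid
})

test_that("written cohorts round-trip through manifest and truth files", {
  cfg <- simulation_config(n_codons = 60, n_genes = 3,
                           branch_length = 0.02, seed = 4)
  co <- simulate_cohort(cfg, EI_TAB)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  alns <- read_alignment_manifest(file.path(dir, "manifest.tsv"))
  expect_named(alns, names(co$alignments))
  expect_identical(alns$gene0002$seq_a, co$alignments$gene0002$seq_a)
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(truth$Ns_true, co$truth$Ns_true)
  expect_equal(truth$Ni_5, unname(co$Ni_true[, 5]))
})
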