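# Codon-change classification, site counting, substitution counting, kappa.

test_that("classify_codon_change covers the kind taxonomy", {
  syn <- classify_codon_change("TTA", "CTA", EI_TAB)
  expect_identical(syn$kind, "synonymous")  # both Leu
  expect_equal(syn$n_diffs, 1)
  expect_true(syn$is_transition)

  el <- classify_codon_change("AAA", "AGA", EI_TAB)
  expect_identical(el$kind, "elementary")
  expect_equal(sort(el$aa_pair), c("K", "R"))
  expect_true(el$is_transition)
  expect_identical(el$class_rank, unname(EI_TAB$pair_rank[["K/R"]]))

  ne <- classify_codon_change("AAA", "AGG", EI_TAB)
  expect_identical(ne$kind, "nonelementary_aa_change")
  expect_equal(ne$n_diffs, 2)
  expect_true(is.na(ne$class_rank))

  expect_identical(classify_codon_change("TGG", "TGA", EI_TAB)$kind,
                   "stop_involving")
  expect_identical(classify_codon_change("AAA", "AAA", EI_TAB)$kind,
                   "identical")
  expect_identical(classify_codon_change("TTA", "CTG", EI_TAB)$kind,
                   "multihit_synonymous")
  expect_error(classify_codon_change("AXA", "AAA", EI_TAB), "codon")
})

test_that("count_sites matches hand-enumerated neighbour weights", {
  # TTT (Phe), kappa = 1: each of the 9 neighbours weighs 1/3
  s <- count_sites("TTT", 1, EI_TAB)
  expect_equal(s$Ls, 1 / 3)          # TTC only
  expect_equal(s$stop_weight, 0)
  li <- setNames(s$Li, names(EI_TAB$pair_rank)[order(EI_TAB$pair_rank)])
  expect_equal(unname(li[["F/L"]]), 1)      # CTT, TTA, TTG
  for (key in c("F/I", "F/V", "F/S", "F/Y", "C/F"))
    expect_equal(unname(li[[key]]), 1 / 3)
  expect_equal(s$Ls + sum(s$Li) + s$stop_weight, 3)

  # kappa = 2: the position-3 transition TTC gets weight 0.5
  s2 <- count_sites("TTT", 2, EI_TAB)
  expect_equal(s2$Ls, 0.5)
  expect_equal(sum(s2$Li), 2.5)

  # TGG (Trp): TGA and TAG create stops
  s3 <- count_sites("TGG", 1, EI_TAB)
  expect_equal(s3$stop_weight, 2 / 3)
  expect_equal(s3$Ls + sum(s3$Li), 7 / 3)

  expect_error(count_sites("TAA", 1, EI_TAB), "stop codon")
})

test_that("per-codon site weights always sum to 3, any kappa", {
  sense <- names(STD_CODE)[STD_CODE != "*"]
  for (kappa in c(0.5, 1, 2, 5.7)) {
    s <- count_sites(sense, kappa, EI_TAB)
    expect_equal(s$Ls + sum(s$Li) + s$stop_weight, 3 * length(sense),
                 tolerance = 1e-9)
  }
})

test_that("count_substitutions handles hand-classified small alignments", {
  ident <- make_aln(rep("GAA", 100), rep("GAA", 100))
  c0 <- count_substitutions(ident, EI_TAB, kappa = 2)
  expect_equal(c0$Ns, 0)
  expect_equal(sum(c0$Ni), 0)
  expect_equal(c0$n_codons_used, 100)

  # AAA|TTT vs AGA|TTC: one K/R elementary change + one synonymous change
  aln <- make_aln(c("AAA", "TTT"), c("AGA", "TTC"))
  cc <- count_substitutions(aln, EI_TAB, kappa = 1)
  expect_equal(cc$Ns, 1)
  expect_equal(sum(cc$Ni), 1)
  expect_equal(cc$Ni[EI_TAB$pair_rank[["K/R"]]], 1)
  expect_equal(cc$n_aa_changes_total, 1)
  expect_equal(cc$n_nonelementary, 0)

  # gap and N columns are skipped, not fatal
  gappy <- codon_alignment("g", "A-AAAATTT", "AAAAGATTN")
  cg <- count_substitutions(gappy, EI_TAB, kappa = 1)
  expect_equal(cg$n_codons_used, 1)
  expect_equal(cg$n_skipped, 2)
  expect_equal(sum(cg$Ni), 1)  # the AAA/AGA column

  expect_error(count_substitutions(codon_alignment("e", "N--", "AAA"),
                                   EI_TAB), "usable")
})

test_that("counting is symmetric in the two sequences", {
  set.seed(42)
  for (r in 1:20) {
    aln <- random_alignment(40)
    rev <- codon_alignment("r", aln$seq_b, aln$seq_a)
    ca <- count_substitutions(aln, EI_TAB, kappa = 2)
    cb <- count_substitutions(rev, EI_TAB, kappa = 2)
    expect_equal(ca$Ns, cb$Ns)
    expect_equal(ca$Ni, cb$Ni)
    expect_equal(ca$Li, cb$Li)
    expect_equal(ca$n_nonelementary, cb$n_nonelementary)
  }
})

test_that("multi-hit synonymous columns credit pathway-averaged Ns", {
  # TTA vs CTG (Leu/Leu, 2 diffs): both orders give 2 synonymous steps
  aln <- make_aln("TTA", "CTG")
  expect_equal(count_substitutions(aln, EI_TAB, kappa = 1)$Ns, 2)
  # package pathway averaging equals independent pathway enumeration
  sense <- names(STD_CODE)[STD_CODE != "*"]
  set.seed(42)
  pairs <- cbind(sample(sense, 120, replace = TRUE),
                 sample(sense, 120, replace = TRUE))
  ct <- code_tables(STD_CODE)
  for (i in seq_len(nrow(pairs))) {
    expect_equal(ct$synsteps[pairs[i, 1], pairs[i, 2]],
                 oracle_synsteps(pairs[i, 1], pairs[i, 2], STD_CODE),
                 info = paste(pairs[i, ], collapse = " vs "))
  }
})

test_that("kappa estimator matches the K80 closed form and its edge cases", {
  expect_equal(kappa_from_pq(0.1, 0.2)$kappa, 1.0, tolerance = 1e-9)
  expect_equal(kappa_from_pq(0.2, 0.1)$kappa,
               (-0.5 * log(1 - 0.4 - 0.1) + 0.25 * log(1 - 0.2)) /
                 (-0.25 * log(1 - 0.2)), tolerance = 1e-12)
  z <- kappa_from_pq(0, 0)
  expect_equal(z$kappa, 2)
  expect_identical(z$flag, "default_no_information")
  cap <- kappa_from_pq(0.2, 0)
  expect_equal(cap$kappa, 50)
  expect_identical(cap$flag, "capped_no_transversions")
  expect_error(kappa_from_pq(0.45, 0.1), "saturated")
})

test_that("estimate_kappa uses fourfold-degenerate third positions only", {
  # 8 fourfold columns with identical prefixes: 2 ts diffs, 2 tv diffs,
  # plus twofold-family and prefix-mismatched columns that must be ignored
  a <- c("GGA", "CCA", "GGC", "ACA", "GGT", "CCA", "ACG", "GTA",
         "TTT", "AAA", "GTT")
  b <- c("GGG", "CCG", "GGA", "ACC", "GGT", "CCA", "ACG", "GTA",
         "TTC", "AAG", "CTT")
  est <- estimate_kappa(make_aln(a, b), STD_CODE)
  expect_equal(est$n_4fold_sites, 8)  # TTT (twofold), AAA, GTT/CTT ignored
  expect_equal(est$n_ts, 2)           # GGA/GGG, CCA/CCG
  expect_equal(est$n_tv, 2)           # GGC/GGA, ACA/ACC
  expect_equal(est$kappa,
               kappa_from_pq(2 / 8, 2 / 8)$kappa)
})
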