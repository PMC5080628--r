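# Filters, PSG calls, supergenes, twofold regression, Ks summary.

test_that("filters and PSG calls follow the screen's rules exactly", {
  scr <- run_screen(fixture_screen(), EI_TAB, screen_config())
  r <- scr$results
  rownames(r) <- r$gene_id
  expect_true(r["ka_high", "Ka"] > 0.05)
  expect_equal(r["ka_high", "filter_reason"], "ka_gt_max")
  expect_true(r["ks_high", "Ks"] > 0.08)
  expect_equal(r["ks_high", "filter_reason"], "ks_gt_max")
  expect_true(r["ks_low", "Ks"] < 0.005)
  expect_equal(r["ks_low", "filter_reason"], "ks_lt_min")
  expect_false(r["psg", "filtered"])
  expect_true(r["psg", "Kh_Ks"] > 1)
  expect_true(r["psg", "p_Kh_Ks"] < 0.05)
  expect_true(r["psg", "is_psg"])
  expect_false(r["weak", "is_psg"])
  expect_true(r["weak", "p_Kh_Ks"] >= 0.05)
  expect_false(r["lowx", "is_psg"])
  expect_true(is.na(r["lowx", "Kh_Ks"]) || r["lowx", "Kh_Ks"] <= 1)
  # PSG implies unfiltered, ratio > 1 and significant — on every row
  expect_true(all(!r$is_psg |
                    (!r$filtered & r$Kh_Ks > 1 & r$p_Kh_Ks < 0.05)))
})

test_that("analyze_gene runs the single-gene pipeline end to end", {
  row <- analyze_gene(fixture_screen()$psg, EI_TAB, screen_config())
  expect_equal(nrow(row), 1)
  expect_true(row$is_psg)
  expect_false(row$filtered)
  expect_true(row$Kh_Ks > 1 && row$p_Kh_Ks < 0.05)
  # fixed kappa policy is honoured
  fixed <- analyze_gene(fixture_screen()$psg, EI_TAB,
                        screen_config(kappa_policy = "fixed:3"))
  expect_equal(fixed$kappa, 3)
})

test_that("filtering is idempotent and PSG calls ignore input order", {
  genes <- fixture_screen()
  scr1 <- run_screen(genes, EI_TAB)
  scr2 <- run_screen(rev(genes), EI_TAB)
  expect_setequal(scr1$results$gene_id[scr1$results$is_psg],
                  scr2$results$gene_id[scr2$results$is_psg])
  r <- scr1$results
  reapplied <- vapply(seq_len(nrow(r)), function(i)
    khscan:::filter_gene(r$Ks[i], r$Ka[i], screen_config()), character(1))
  expect_identical(is.na(reapplied), !r$filtered)
  expect_identical(reapplied[r$filtered], r$filter_reason[r$filtered])
})

test_that("PSG calls are enriched in genes simulated under positive selection", {
  set.seed(42)
  alns <- list()
  for (g in 1:10) {
    cfg <- simulation_config(n_codons = 500, n_genes = 1,
                             branch_length = 0.01, omega_high = 2,
                             omega_low = 0.1, seed = 300 + g)
    alns[[paste0("sel", g)]] <- simulate_cohort(cfg, EI_TAB)$alignments[[1]]
  }
  for (g in 1:40) {
    cfg <- simulation_config(n_codons = 500, n_genes = 1,
                             branch_length = 0.01, omega_high = 0.1,
                             omega_low = 0.1, seed = 400 + g)
    alns[[paste0("bg", g)]] <- simulate_cohort(cfg, EI_TAB)$alignments[[1]]
  }
  for (nm in names(alns)) alns[[nm]]$gene_id <- nm
  scr <- run_screen(alns, EI_TAB)
  psg <- scr$results$gene_id[scr$results$is_psg]
  expect_gt(sum(grepl("^sel", psg)), 0)   # some planted genes recovered
  expect_equal(sum(grepl("^bg", psg)), 0) # no background false calls
})

test_that("identical gene pairs yield no PSGs", {
  genes <- list(make_aln(rep("GAA", 60), rep("GAA", 60), "a"),
                make_aln(rep("CCA", 60), rep("CCA", 60), "b"))
  scr <- run_screen(genes, EI_TAB)
  expect_equal(sum(scr$results$is_psg), 0)
})

test_that("supergene binning pools counts of 100-gene blocks and drops the tail", {
  set.seed(42)
  cfg <- simulation_config(n_codons = 120, n_genes = 260,
                           branch_length = 0.03, seed = 9)
  co <- simulate_cohort(cfg, EI_TAB)
  scr <- run_screen(co$alignments, EI_TAB)
  n_elig <- sum(scr$results$Ka > 0, na.rm = TRUE)
  expect_gte(n_elig, 200)
  sg <- build_supergenes(scr, bin_size = 100)
  expect_equal(nrow(sg$supergenes), n_elig %/% 100)
  expect_equal(sg$n_genes_used, (n_elig %/% 100) * 100)
  expect_equal(sg$n_genes_dropped, n_elig - sg$n_genes_used)
  # pooled Ns of the top bin equals the sum over its members (Ka-descending)
  r <- scr$results
  elig <- r[!is.na(r$Ka) & r$Ka > 0, ]
  elig <- elig[order(-elig$Ka, elig$gene_id), ]
  top <- elig$gene_id[1:100]
  expect_equal(sg$supergenes$Ns[1],
               sum(vapply(scr$counts[top], `[[`, 0, "Ns")))
  expect_equal(sg$supergenes$n_genes, rep(100, nrow(sg$supergenes)))
  expect_error(build_supergenes(scr, bin_size = n_elig + 1), "at least")
})

test_that("twofold regression recovers exact and hand-computed slopes", {
  exact <- data.frame(Ka_Ks = c(0.5, 1, 2), Kh_Ks = c(1, 2, 4))
  expect_equal(twofold_regression(exact)$slope, 2)
  hand <- data.frame(Ka_Ks = c(1, 2), Kh_Ks = c(1.5, 3.5))
  expect_equal(twofold_regression(hand)$slope, 1.7)  # (1.5 + 7) / (1 + 4)
  with_int <- twofold_regression(hand, intercept = TRUE)
  expect_equal(with_int$slope, 2)
  expect_equal(with_int$intercept, -0.5)
  expect_error(twofold_regression(data.frame(Ka_Ks = c(0, 0),
                                             Kh_Ks = c(1, 2))),
               "degenerate")
  expect_error(twofold_regression(data.frame(Ka_Ks = c(1, 1),
                                             Kh_Ks = c(1, 2)),
                                  intercept = TRUE), "degenerate")
  expect_error(twofold_regression(data.frame(Ka_Ks = 1, Kh_Ks = 2)),
               "at least 2")
})

test_that("summarize_ks finds the modal bin and tolerates empty input", {
  res <- data.frame(Ks = rep(0.02, 20))
  s <- summarize_ks(res, bin_width = 0.01)
  expect_true(s$modal_mid >= 0.015 && s$modal_mid <= 0.025)
  empty <- summarize_ks(data.frame(Ks = NA_real_), bin_width = 0.01)
  expect_equal(empty$n, 0L)
  expect_length(empty$counts, 0)
})
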