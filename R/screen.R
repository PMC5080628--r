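# The per-gene screen: counts -> kappa -> rates -> filters -> PSG calls,
# plus supergene concatenation, the twofold regression and the Ks
# distribution summary.

#' Screen configuration
#'
#' Thresholds and policies of the positive-selection screen. Defaults follow
#' the published procedure for a recently diverged species pair: genes with
#' `Ka > 0.05`, `Ks > 0.08` or `Ks < 0.005` are removed (alignment artefacts
#' and uninformative genes), and the remainder are called candidate PSGs when
#' `Kh/Ks > 1` with Fisher's exact p < 0.05.
#'
#' @param ka_max maximum Ka retained (default 0.05).
#' @param ks_max maximum Ks retained (default 0.08).
#' @param ks_min minimum Ks retained (default 0.005).
#' @param p_threshold PSG significance threshold (default 0.05).
#' @param h_cutoff_rank top exchange classes defining Kh (default 10).
#' @param bin_size genes per supergene (default 100).
#' @param fisher_sided `"two"` or `"greater"`.
#' @param kappa_policy `"per-gene"` (per-gene estimate when at least
#'   `kappa_min_sites` fourfold sites, else the cohort-wide pooled estimate),
#'   `"global"` (always pooled), or `"fixed:X"` (a constant, e.g.
#'   `"fixed:2"`).
#' @param kappa_min_sites fourfold sites required for a per-gene kappa.
#' @return list of class `screen_config`.
#' @export
screen_config <- function(ka_max = 0.05, ks_max = 0.08, ks_min = 0.005,
                          p_threshold = 0.05, h_cutoff_rank = 10,
                          bin_size = 100, fisher_sided = c("two", "greater"),
                          kappa_policy = "per-gene", kappa_min_sites = 50) {
  fisher_sided <- match.arg(fisher_sided)
  stopifnot(ks_min > 0, ks_min < ks_max, h_cutoff_rank >= 1,
            h_cutoff_rank <= 75, bin_size >= 1)
  fixed <- grepl("^fixed:", kappa_policy)
  if (!fixed && !kappa_policy %in% c("per-gene", "global"))
    stop("kappa_policy must be 'per-gene', 'global' or 'fixed:X'")
  structure(list(ka_max = ka_max, ks_max = ks_max, ks_min = ks_min,
                 p_threshold = p_threshold, h_cutoff_rank = h_cutoff_rank,
                 bin_size = bin_size, fisher_sided = fisher_sided,
                 kappa_policy = if (fixed) "fixed" else kappa_policy,
                 kappa_fixed = if (fixed)
                   as.numeric(sub("^fixed:", "", kappa_policy)) else NA_real_,
                 kappa_min_sites = kappa_min_sites),
            class = "screen_config")
}

# Filter predicates in reporting order; first violated one names the reason.
filter_gene <- function(Ks, Ka, config) {
  if (is.na(Ks)) return("ks_undefined")
  if (is.na(Ka)) return("ka_undefined")
  if (Ka > config$ka_max) return("ka_gt_max")
  if (Ks > config$ks_max) return("ks_gt_max")
  if (Ks < config$ks_min) return("ks_lt_min")
  NA_character_
}

gene_result_row <- function(aln, counts, rates, kap, config) {
  reason <- filter_gene(rates$Ks, rates$Ka, config)
  filtered <- !is.na(reason)
  is_psg <- !filtered && !is.na(rates$Kh_Ks) && !is.na(rates$p_Kh_Ks) &&
    rates$Kh_Ks > 1 && rates$p_Kh_Ks < config$p_threshold
  data.frame(
    gene_id = aln$gene_id, species_a_id = aln$species_a,
    species_b_id = aln$species_b,
    Ns = counts$Ns, Ls = counts$Ls, Nh = rates$Nh, Lh = rates$Lh,
    Na = rates$Na, La = rates$La, kappa = rates$kappa,
    Ks = rates$Ks, Ka = rates$Ka, Kh = rates$Kh,
    Ka_Ks = rates$Ka_Ks, Kh_Ks = rates$Kh_Ks,
    p_Ka_Ks = rates$p_Ka_Ks, p_Kh_Ks = rates$p_Kh_Ks,
    n_nonelementary = counts$n_nonelementary,
    filtered = filtered, filter_reason = reason, is_psg = is_psg,
    n_codons_used = counts$n_codons_used,
    n_4fold_sites = kap$n_4fold_sites, n_ts_4fold = kap$n_ts,
    n_tv_4fold = kap$n_tv, kappa_flag = kap$flag,
    stringsAsFactors = FALSE)
}

#' Analyse a single gene
#'
#' Runs the full per-gene pipeline: substitution/site counting, kappa
#' estimation, Jukes-Cantor-corrected rates, Fisher's exact p-values, the
#' screen's filters and the PSG call.
#'
#' @param aln a `codon_alignment`.
#' @param table a ranked [exchange_class_table()].
#' @param config a [screen_config()].
#' @param global_kappa optional fallback kappa estimate (list as from
#'   [estimate_kappa()]) used when the gene has too few fourfold sites;
#'   [run_screen()] supplies the cohort-pooled estimate, standalone calls
#'   fall back to the uninformative default of 2.
#' @return One-row data.frame (gene result).
#' @export
analyze_gene <- function(aln, table, config = screen_config(),
                         global_kappa = NULL) {
  kap <- estimate_kappa(aln, table$code)
  use <- kap
  if (config$kappa_policy == "fixed") {
    use$kappa <- config$kappa_fixed
    use$flag <- "fixed"
  } else if (config$kappa_policy == "global" ||
             kap$n_4fold_sites < config$kappa_min_sites ||
             kap$flag == "default_no_information") {
    if (!is.null(global_kappa)) {
      use$kappa <- global_kappa$kappa
      use$flag <- "global"
    } else if (config$kappa_policy == "global") {
      use$kappa <- 2
      use$flag <- "default_no_information"
    }
    # else: keep the per-gene value (already defaulted when uninformative)
  }
  counts <- count_substitutions(aln, table, kappa = use$kappa)
  rates <- compute_rates(counts, kappa = use$kappa,
                         h_cutoff_rank = config$h_cutoff_rank,
                         fisher_sided = config$fisher_sided)
  gene_result_row(aln, counts, rates, use, config)
}

#' Run the screen over a collection of alignments
#'
#' Estimates a cohort-pooled kappa from all genes' fourfold-degenerate sites,
#' analyses every gene under the configured kappa policy, and reports the
#' per-gene result table together with the raw counts needed for supergene
#' concatenation. Deterministic given inputs and config.
#'
#' @param alignments list of `codon_alignment` (e.g. from
#'   [read_alignment_manifest()] or [simulate_cohort()]).
#' @param table a ranked [exchange_class_table()].
#' @param config a [screen_config()].
#' @param verbose print per-stage gene counts to stderr.
#' @return An object of class `screen_result`: list(results = data.frame,
#'   counts = named list of `substitution_counts`, global_kappa, config).
#' @export
run_screen <- function(alignments, table, config = screen_config(),
                       verbose = FALSE) {
  stopifnot(length(alignments) >= 1)
  kaps <- lapply(alignments, estimate_kappa, code = table$code)
  gk <- kappa_from_pq(
    P = sum(vapply(kaps, `[[`, 0, "n_ts")) /
      max(1, sum(vapply(kaps, `[[`, 0, "n_4fold_sites"))),
    Q = sum(vapply(kaps, `[[`, 0, "n_tv")) /
      max(1, sum(vapply(kaps, `[[`, 0, "n_4fold_sites"))),
    n = sum(vapply(kaps, `[[`, 0, "n_4fold_sites")))

  counts <- vector("list", length(alignments))
  rows <- vector("list", length(alignments))
  for (i in seq_along(alignments)) {
    aln <- alignments[[i]]
    kap <- kaps[[i]]
    use <- kap
    if (config$kappa_policy == "fixed") {
      use$kappa <- config$kappa_fixed; use$flag <- "fixed"
    } else if (config$kappa_policy == "global" ||
               kap$n_4fold_sites < config$kappa_min_sites ||
               kap$flag != "ok") {
      use$kappa <- gk$kappa; use$flag <- "global"
    }
    cnt <- count_substitutions(aln, table, kappa = use$kappa)
    rates <- compute_rates(cnt, kappa = use$kappa,
                           h_cutoff_rank = config$h_cutoff_rank,
                           fisher_sided = config$fisher_sided)
    counts[[i]] <- cnt
    rows[[i]] <- gene_result_row(aln, cnt, rates, use, config)
  }
  results <- do.call(rbind, rows)
  if (anyDuplicated(results$gene_id))
    stop("duplicate gene_id: ",
         results$gene_id[duplicated(results$gene_id)][1])
  names(counts) <- results$gene_id
  if (verbose) {
    message(sprintf(
      "screen: %d genes; %d filtered; %d with Ka/Ks > 1; %d PSGs",
      nrow(results), sum(results$filtered),
      sum(results$Ka_Ks > 1, na.rm = TRUE), sum(results$is_psg)))
  }
  structure(list(results = results, counts = counts, global_kappa = gk,
                 config = config), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  r <- x$results
  cat("khscan screen:", nrow(r), "genes |", sum(r$filtered), "filtered |",
      sum(r$Ka_Ks > 1, na.rm = TRUE), "with Ka/Ks > 1 |",
      sum(r$is_psg), "PSGs\n")
  invisible(x)
}

#' Pooled (concatenated) rates of a whole cohort
#'
#' Concatenates all genes into one unit by summing substitution and site
#' counts, pools the fourfold-degenerate differences for a cohort kappa, and
#' recomputes the corrected rates — the cohort-level Ki*/Ks curve.
#'
#' @param screen a `screen_result`.
#' @return A `rate_estimates` for the pooled cohort.
#' @export
cohort_rates <- function(screen) {
  stopifnot(inherits(screen, "screen_result"))
  pooled <- pool_counts(screen$counts)
  compute_rates(pooled, kappa = screen$global_kappa$kappa,
                h_cutoff_rank = screen$config$h_cutoff_rank,
                fisher_sided = screen$config$fisher_sided)
}

#' Concatenate genes into supergenes of similar Ka
#'
#' Genes with `Ka > 0` are sorted by Ka in descending order (ties broken by
#' gene_id) and consecutive blocks of `bin_size` genes are pooled by summing
#' their Ns, Ls, Ni and Li; the trailing remainder is dropped and rates are
#' recomputed per supergene. This stabilises the Kh/Ks and Ka/Ks ratios of
#' low-divergence genes for the twofold regression.
#'
#' @param screen a `screen_result`.
#' @param bin_size genes per supergene (default from the screen config).
#' @return list of class `supergene_set`: supergenes (data.frame with pooled
#'   counts, rates and ratios), n_genes_used, n_genes_dropped, bin_size.
#' @export
build_supergenes <- function(screen, bin_size = screen$config$bin_size) {
  stopifnot(inherits(screen, "screen_result"))
  r <- screen$results
  eligible <- which(!is.na(r$Ka) & r$Ka > 0)
  if (length(eligible) < bin_size)
    stop("need at least ", bin_size, " genes with Ka > 0; have ",
         length(eligible))
  ord <- eligible[order(-r$Ka[eligible], r$gene_id[eligible])]
  n_bins <- length(ord) %/% bin_size
  used <- ord[seq_len(n_bins * bin_size)]
  bin <- rep(seq_len(n_bins), each = bin_size)

  rows <- lapply(seq_len(n_bins), function(b) {
    idx <- used[bin == b]
    pooled <- pool_counts(screen$counts[idx])
    kap <- kappa_from_pq(
      P = sum(r$n_ts_4fold[idx]) / max(1, sum(r$n_4fold_sites[idx])),
      Q = sum(r$n_tv_4fold[idx]) / max(1, sum(r$n_4fold_sites[idx])),
      n = sum(r$n_4fold_sites[idx]))
    rates <- compute_rates(pooled, kappa = kap$kappa,
                           h_cutoff_rank = screen$config$h_cutoff_rank,
                           fisher_sided = screen$config$fisher_sided)
    data.frame(supergene = b, n_genes = length(idx),
               Ns = pooled$Ns, Ls = pooled$Ls,
               Nh = rates$Nh, Lh = rates$Lh, Na = rates$Na, La = rates$La,
               kappa = kap$kappa, Ks = rates$Ks, Ka = rates$Ka,
               Kh = rates$Kh, Ka_Ks = rates$Ka_Ks, Kh_Ks = rates$Kh_Ks,
               stringsAsFactors = FALSE)
  })
  structure(list(supergenes = do.call(rbind, rows),
                 n_genes_used = length(used),
                 n_genes_dropped = length(eligible) - length(used),
                 bin_size = bin_size), class = "supergene_set")
}

#' Regression of Kh/Ks on Ka/Ks over supergenes
#'
#' Least-squares slope of `Kh/Ks` on `Ka/Ks` across supergenes, through the
#' origin by default (the twofold approximation is a proportionality claim);
#' set `intercept = TRUE` for an ordinary intercept fit.
#'
#' @param sg a `supergene_set` (or data.frame with columns Ka_Ks, Kh_Ks).
#' @param intercept fit an intercept? default FALSE.
#' @return list(slope, intercept, n) — intercept is 0 for the origin fit.
#' @export
twofold_regression <- function(sg, intercept = FALSE) {
  df <- if (inherits(sg, "supergene_set")) sg$supergenes else sg
  ok <- !is.na(df$Ka_Ks) & !is.na(df$Kh_Ks)
  x <- df$Ka_Ks[ok]; y <- df$Kh_Ks[ok]
  if (length(x) < 2) stop("need at least 2 supergenes with defined ratios")
  if (!intercept) {
    if (sum(x^2) == 0) stop("degenerate fit: all Ka/Ks are zero")
    return(list(slope = sum(x * y) / sum(x^2), intercept = 0,
                n = length(x)))
  }
  if (stats::var(x) == 0)
    stop("degenerate fit: all Ka/Ks identical, intercept not estimable")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n = length(x))
}

#' Histogram summary of the pairwise Ks distribution
#'
#' @param results per-gene result data.frame (from [run_screen()]).
#' @param bin_width histogram bin width (default 0.01).
#' @return list(breaks, counts, mids, modal_mid, n); empty (n = 0) when no
#'   gene has a defined Ks.
#' @export
summarize_ks <- function(results, bin_width = 0.01) {
  ks <- results$Ks[!is.na(results$Ks)]
  if (length(ks) == 0)
    return(list(breaks = numeric(0), counts = integer(0),
                mids = numeric(0), modal_mid = NA_real_, n = 0L))
  breaks <- seq(0, (max(ks) %/% bin_width + 1) * bin_width, by = bin_width)
  h <- graphics::hist(ks, breaks = breaks, plot = FALSE, right = FALSE)
  list(breaks = h$breaks, counts = h$counts, mids = h$mids,
       modal_mid = h$mids[which.max(h$counts)], n = length(ks))
}
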