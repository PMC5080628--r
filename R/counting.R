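# Substitution and site counting over pairwise codon alignments.
#
# For each gene we count observed synonymous substitutions (Ns) against
# synonymous sites (Ls), and per exchange class i = 1..75 the observed
# elementary substitutions (Ni) against class-i sites (Li). Sites are
# kappa-weighted mutation opportunities: at each codon position one site unit
# is split kappa/(kappa+2) to the transition neighbour and 1/(kappa+2) to each
# transversion neighbour, accruing to the category (synonymous / exchange
# class / stop) of that neighbour. Stop-creating opportunities are excluded
# from both numerator and denominator and reported as stop_weight.

KIND_LEVELS <- c("identical", "synonymous", "elementary",
                 "nonelementary_aa_change", "multihit_synonymous",
                 "stop_involving")

#' Classify a single codon change
#'
#' Compares two ungapped codons and reports the kind of change: `identical`,
#' `synonymous` (single-nt, same amino acid), `elementary` (single-nt,
#' different amino acids — carries its exchange-class rank),
#' `nonelementary_aa_change` (2-3 nt, different amino acids),
#' `multihit_synonymous` (2-3 nt, same amino acid) or `stop_involving`.
#'
#' @param codon_a,codon_b uppercase DNA triplets without gaps or ambiguity.
#' @param table a ranked [exchange_class_table()].
#' @return A list with `kind`, `n_diffs`, `aa_pair` (sorted 2-vector or NULL),
#'   `class_rank` (elementary only), `is_transition` (single-diff only) and
#'   `syn_steps` (pathway-averaged synonymous steps credited to Ns).
#' @examples
#' tab <- synthetic_ei_ranking()
#' classify_codon_change("AAA", "AGA", tab)$kind  # elementary (K/R)
#' @export
classify_codon_change <- function(codon_a, codon_b, table) {
  stopifnot(inherits(table, "exchange_class_table"))
  for (cd in c(codon_a, codon_b))
    if (!grepl("^[ACGT]{3}$", cd))
      stop("not an unambiguous DNA codon: ", cd)
  ct <- code_tables(table$code)
  kind <- ct$kind[codon_a, codon_b]
  aa <- table$code[c(codon_a, codon_b)]
  pair <- if (kind %in% c("elementary", "nonelementary_aa_change"))
    sort(unname(aa)) else NULL
  list(kind = kind,
       n_diffs = ct$ndiff[codon_a, codon_b],
       aa_pair = pair,
       class_rank = if (kind == "elementary")
         unname(table$rank_mat[codon_a, codon_b]) else NA_integer_,
       is_transition = ct$is_ts[codon_a, codon_b],
       syn_steps = ct$synsteps[codon_a, codon_b])
}

#' Count mutation-opportunity sites of one sequence
#'
#' Enumerates, for every codon, its nine single-nucleotide neighbours and
#' splits one site unit per codon position as kappa-weighted opportunities
#' (transition : each transversion = kappa : 1). Weights accrue to `Ls`
#' (synonymous neighbour), to `Li` of the neighbour's exchange class
#' (elementary neighbour), or to `stop_weight` (stop neighbour, excluded from
#' the screen's denominators).
#'
#' @param codons character vector of ungapped sense codons (one gene).
#' @param kappa transition/transversion rate ratio, > 0.
#' @param table a ranked [exchange_class_table()].
#' @return list(Ls, Li = numeric(75), stop_weight); Ls + sum(Li) +
#'   stop_weight == 3 * length(codons).
#' @export
count_sites <- function(codons, kappa, table) {
  stopifnot(inherits(table, "exchange_class_table"), kappa > 0)
  if (is.null(table$site_ts))
    stop("count_sites requires a ranked exchange-class table")
  bad <- !codons %in% rownames(table$site_ts)
  if (any(bad)) stop("invalid codon(s): ", paste(codons[bad], collapse = ", "))
  aa <- table$code[codons]
  if (any(aa == "*"))
    stop("stop codon in sequence at codon position ",
         which(aa == "*")[1])
  counts <- tabulate(match(codons, rownames(table$site_ts)),
                     nbins = nrow(table$site_ts))
  w <- crossprod(table$site_ts, counts) * (kappa / (kappa + 2)) +
    crossprod(table$site_tv, counts) * (1 / (kappa + 2))
  n <- table$n_classes
  list(Ls = w[n + 1], Li = as.numeric(w[seq_len(n)]), stop_weight = w[n + 2])
}

split_codons <- function(seq) {
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

# Usable columns of an alignment: both codons free of gaps/ambiguity and
# neither a stop codon. Returns codon vectors plus bookkeeping counts.
usable_columns <- function(aln, code) {
  a <- split_codons(aln$seq_a)
  b <- split_codons(aln$seq_b)
  clean <- grepl("^[ACGT]{3}$", a) & grepl("^[ACGT]{3}$", b)
  stop_col <- clean & (code[ifelse(clean, a, "AAA")] == "*" |
                         code[ifelse(clean, b, "AAA")] == "*")
  use <- clean & !stop_col
  list(a = a[use], b = b[use],
       n_skipped = sum(!clean), n_stop_columns = sum(stop_col, na.rm = TRUE))
}

#' Count substitutions and sites for one gene
#'
#' Per usable codon column (no gap/ambiguity, no stop codon in either
#' sequence): identical columns contribute nothing; single-difference
#' synonymous columns add 1 to `Ns`; single-difference amino-acid changes are
#' elementary and add 1 to the `Ni` of their exchange class; multi-difference
#' columns with differing amino acids are tallied once as non-elementary
#' (excluded from every class and from Ka); multi-difference synonymous
#' columns credit `Ns` with the synonymous steps averaged over minimal
#' stop-avoiding mutational pathways. Site totals are the mean of
#' [count_sites()] over the two sequences.
#'
#' @param aln a `codon_alignment` (see [read_codon_alignment()] /
#'   [codon_alignment()]).
#' @param table a ranked [exchange_class_table()].
#' @param kappa transition/transversion ratio used for site weighting.
#' @return An object of class `substitution_counts`: list(Ns, Ls, Ni, Li,
#'   n_aa_changes_total, n_nonelementary, n_codons_used, n_stop_columns,
#'   n_skipped, stop_weight, kappa).
#' @export
count_substitutions <- function(aln, table, kappa = 2) {
  stopifnot(inherits(table, "exchange_class_table"))
  uc <- usable_columns(aln, table$code)
  if (length(uc$a) == 0L)
    stop("no usable codon columns in gene ", aln$gene_id)
  ct <- code_tables(table$code)

  diffs <- which(uc$a != uc$b)
  idx <- cbind(match(uc$a[diffs], rownames(ct$kind)),
               match(uc$b[diffs], colnames(ct$kind)))
  kind <- ct$kind[idx]
  Ns <- sum(ct$synsteps[idx])
  n <- table$n_classes
  Ni <- numeric(n)
  ranks <- table$rank_mat[idx[kind == "elementary", , drop = FALSE]]
  if (length(ranks)) Ni <- tabulate(ranks, nbins = n)
  n_nonel <- sum(kind == "nonelementary_aa_change")

  sa <- count_sites(uc$a, kappa, table)
  sb <- count_sites(uc$b, kappa, table)

  structure(list(
    Ns = Ns, Ls = (sa$Ls + sb$Ls) / 2,
    Ni = Ni, Li = (sa$Li + sb$Li) / 2,
    n_aa_changes_total = sum(kind == "elementary") + n_nonel,
    n_nonelementary = n_nonel,
    n_codons_used = length(uc$a),
    n_stop_columns = uc$n_stop_columns,
    n_skipped = uc$n_skipped,
    stop_weight = (sa$stop_weight + sb$stop_weight) / 2,
    kappa = kappa), class = "substitution_counts")
}

#' Pool substitution counts across genes
#'
#' Sums Ns, Ls, Ni, Li (and the bookkeeping tallies) over a list of
#' `substitution_counts`, as used for supergene concatenation and cohort-level
#' rate estimation.
#'
#' @param counts_list list of `substitution_counts`.
#' @return A single `substitution_counts`.
#' @export
pool_counts <- function(counts_list) {
  stopifnot(length(counts_list) > 0)
  add <- function(field) Reduce(`+`, lapply(counts_list, `[[`, field))
  structure(list(
    Ns = add("Ns"), Ls = add("Ls"), Ni = add("Ni"), Li = add("Li"),
    n_aa_changes_total = add("n_aa_changes_total"),
    n_nonelementary = add("n_nonelementary"),
    n_codons_used = add("n_codons_used"),
    n_stop_columns = add("n_stop_columns"),
    n_skipped = add("n_skipped"),
    stop_weight = add("stop_weight"),
    kappa = NA_real_), class = "substitution_counts")
}

# Fourfold-degenerate codon families: third position fully degenerate.
fourfold_prefixes <- function(code) {
  pre <- unique(substr(sense_codons(code), 1, 2))
  keep <- vapply(pre, function(p) {
    aas <- code[paste0(p, NUCS)]
    all(aas != "*") && length(unique(aas)) == 1L
  }, logical(1))
  pre[keep]
}

#' Estimate kappa from fourfold-degenerate sites
#'
#' Collects codon columns whose first two positions are identical in both
#' sequences and belong to a fourfold-degenerate family, computes the
#' proportions of transition (P) and transversion (Q) differences at the third
#' position, and applies the Kimura two-parameter closed form
#' \deqn{\kappa = \frac{-\tfrac12 \log(1-2P-Q) + \tfrac14 \log(1-2Q)}
#'                     {-\tfrac14 \log(1-2Q)}.}
#'
#' With no observed differences (P = Q = 0) the estimator is uninformative and
#' a default of 2 is returned, flagged. With transitions but no transversions
#' (Q = 0, P > 0) kappa is unbounded and is capped at 50, flagged. Saturation
#' (1 - 2P - Q <= 0) is an error.
#'
#' @param aln a `codon_alignment`.
#' @param code a genetic code.
#' @param cap upper bound returned when Q = 0 but P > 0.
#' @return list(kappa, n_4fold_sites, n_ts, n_tv, P, Q, flag) where flag is
#'   one of "ok", "default_no_information", "capped_no_transversions".
#' @export
estimate_kappa <- function(aln, code = standard_genetic_code(), cap = 50) {
  uc <- usable_columns(aln, code)
  ff <- fourfold_prefixes(code)
  pre_a <- substr(uc$a, 1, 2)
  pre_b <- substr(uc$b, 1, 2)
  sel <- pre_a == pre_b & pre_a %in% ff
  n <- sum(sel)
  if (n == 0L)
    return(list(kappa = 2, n_4fold_sites = 0L, n_ts = 0L, n_tv = 0L,
                P = NA_real_, Q = NA_real_, flag = "default_no_information"))
  t3a <- substr(uc$a[sel], 3, 3)
  t3b <- substr(uc$b[sel], 3, 3)
  diff <- t3a != t3b
  ts <- sum(diff & is_transition(t3a, t3b), na.rm = TRUE)
  tv <- sum(diff) - ts
  kappa_from_pq(ts / n, tv / n, n, ts, tv, cap)
}

#' Kimura two-parameter kappa from difference proportions
#'
#' @param P transition difference proportion.
#' @param Q transversion difference proportion.
#' @param n,n_ts,n_tv optional counts carried through to the result.
#' @param cap value returned when Q = 0 but P > 0.
#' @param floor_at lower bound: sparse data can drive the closed form to or
#'   below zero; such estimates are floored and flagged `"floored_low"` (the
#'   screen then falls back to the cohort-pooled estimate).
#' @return As [estimate_kappa()].
#' @export
kappa_from_pq <- function(P, Q, n = NA_integer_, n_ts = NA_integer_,
                          n_tv = NA_integer_, cap = 50, floor_at = 0.1) {
  stopifnot(P >= 0, Q >= 0, P + Q <= 1)
  res <- list(kappa = NA_real_, n_4fold_sites = n, n_ts = n_ts, n_tv = n_tv,
              P = P, Q = Q, flag = "ok")
  if (P == 0 && Q == 0) {
    res$kappa <- 2
    res$flag <- "default_no_information"
    return(res)
  }
  if (1 - 2 * P - Q <= 0)
    stop("fourfold-degenerate sites saturated (1 - 2P - Q <= 0)")
  if (Q == 0) {
    res$kappa <- cap
    res$flag <- "capped_no_transversions"
    return(res)
  }
  if (1 - 2 * Q <= 0)
    stop("fourfold-degenerate sites saturated (1 - 2Q <= 0)")
  res$kappa <- (-0.5 * log(1 - 2 * P - Q) + 0.25 * log(1 - 2 * Q)) /
    (-0.25 * log(1 - 2 * Q))
  # sparse data can push the closed form to or below zero (fewer transitions
  # than transversion-implied expectation); floor and flag as unreliable
  if (res$kappa < floor_at) {
    res$kappa <- floor_at
    res$flag <- "floored_low"
  }
  res
}
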