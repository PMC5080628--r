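# Corrected substitution rates and exact-test significance.
#
# Ks = JC(Ns/Ls); per class Ki = JC(Ni/Li); the cumulative rate over the i
# most exchangeable classes pools counts first, then corrects:
#   Ki* = JC( sum_{rank<=i} Nj / sum_{rank<=i} Lj ).
# K75* is exactly the classical Ka computed from pooled nonsynonymous counts;
# Kh = K10* is the screen's sensitive numerator.

#' Jukes-Cantor multiple-hit correction
#'
#' Corrects an observed difference proportion for multiple hits:
#' `-(3/4) * log(1 - (4/3) * p)`.
#'
#' @param p observed proportion of differences, `0 <= p < 0.75`.
#' @return Corrected distance (substitutions per site).
#' @examples
#' jukes_cantor(0.3)  # 0.3831192...
#' @export
jukes_cantor <- function(p) {
  if (any(p < 0)) stop("proportion must be non-negative")
  if (any(p >= 0.75)) stop("saturated: proportion >= 0.75")
  -0.75 * log(1 - p * 4 / 3)
}

jc_or_na <- function(N, L) {
  if (is.na(L) || L <= 0) return(NA_real_)
  p <- N / L
  if (p >= 0.75) return(NA_real_)
  jukes_cantor(p)
}

round_half_up <- function(x) floor(x + 0.5)

#' Fisher's exact test for a substitutions-vs-sites contrast
#'
#' Tests whether substitution density N1/L1 differs from N2/L2 via Fisher's
#' exact test on the 2x2 table `[[N1, round(L1) - N1], [N2, round(L2) - N2]]`.
#' Fractional site totals are rounded half-away-from-zero for the test only.
#' The two-sided p-value uses the probability-ordering definition (the sum of
#' the probabilities of all tables with the fixed margins that are no more
#' probable than the observed one), as in [stats::fisher.test()].
#'
#' @param N1,N2 substitution counts.
#' @param L1,L2 site totals (may be fractional).
#' @param sided `"two"` (default) or `"greater"` (N1/L1 enriched).
#' @return The p-value, or NA if a margin is empty.
#' @examples
#' fisher_ratio_test(5, 10, 0, 10)  # 0.03250...
#' @export
fisher_ratio_test <- function(N1, L1, N2, L2, sided = c("two", "greater")) {
  sided <- match.arg(sided)
  # counts may be fractional too (pathway-averaged synonymous steps); the
  # exact test needs integers, rates always use the fractional values
  N1 <- round_half_up(N1); N2 <- round_half_up(N2)
  r1 <- round_half_up(L1)
  r2 <- round_half_up(L2)
  cells <- c(N1, r1 - N1, N2, r2 - N2)
  if (anyNA(cells)) return(NA_real_)
  if (any(cells < 0))
    stop("negative cell in Fisher table after rounding sites: ",
         paste(cells, collapse = ", "))
  if (r1 == 0 || r2 == 0) return(NA_real_)
  m <- matrix(cells, nrow = 2, byrow = TRUE)
  alternative <- if (sided == "two") "two.sided" else "greater"
  stats::fisher.test(m, alternative = alternative)$p.value
}

#' Corrected rates and significance for one gene (or pooled unit)
#'
#' Turns substitution/site counts into Jukes-Cantor-corrected rates: `Ks`,
#' per-class `Ki`, cumulative `Kistar[i]` (counts pooled over ranks `1..i`,
#' then corrected), `Ka = Kistar[75]`, `Kh = Kistar[h_cutoff_rank]`, the
#' ratios `Ka/Ks` and `Kh/Ks`, and Fisher's exact p-values contrasting the
#' pooled nonsynonymous (resp. high-exchangeability) counts with the
#' synonymous counts.
#'
#' @param counts a `substitution_counts` (single gene or pooled).
#' @param kappa kappa estimate to report (list as from [estimate_kappa()] or
#'   a bare number); does not alter the counts.
#' @param h_cutoff_rank number of top exchangeability classes defining Kh
#'   (default 10).
#' @param fisher_sided sidedness of the exact tests, `"two"` or `"greater"`.
#' @param fisher compute p-values? (skipped for speed in large calibrations).
#' @return An object of class `rate_estimates`: list(kappa, Ks, Ki, Kistar,
#'   Ka, Kh, Na, La, Nh, Lh, Ka_Ks, Kh_Ks, p_Ka_Ks, p_Kh_Ks, h_cutoff_rank).
#'   Undefined quantities are NA.
#' @export
compute_rates <- function(counts, kappa = counts$kappa, h_cutoff_rank = 10,
                          fisher_sided = c("two", "greater"), fisher = TRUE) {
  stopifnot(inherits(counts, "substitution_counts"))
  fisher_sided <- match.arg(fisher_sided)
  kap <- if (is.list(kappa)) kappa$kappa else kappa
  n <- length(counts$Ni)
  stopifnot(h_cutoff_rank >= 1, h_cutoff_rank <= n)

  Ncum <- cumsum(counts$Ni)
  Lcum <- cumsum(counts$Li)
  Kistar <- vapply(seq_len(n), function(i) jc_or_na(Ncum[i], Lcum[i]),
                   numeric(1))
  Ki <- vapply(seq_len(n), function(i) {
    if (counts$Li[i] > 0) jc_or_na(counts$Ni[i], counts$Li[i]) else NA_real_
  }, numeric(1))

  Ks <- jc_or_na(counts$Ns, counts$Ls)
  Ka <- Kistar[n]
  Kh <- Kistar[h_cutoff_rank]
  Nh <- Ncum[h_cutoff_rank]; Lh <- Lcum[h_cutoff_rank]
  Na <- Ncum[n]; La <- Lcum[n]

  ratio <- function(num) {
    if (is.na(num) || is.na(Ks) || Ks == 0) NA_real_ else num / Ks
  }
  p_Ka <- p_Kh <- NA_real_
  if (fisher) {
    p_Ka <- fisher_ratio_test(Na, La, counts$Ns, counts$Ls, fisher_sided)
    p_Kh <- fisher_ratio_test(Nh, Lh, counts$Ns, counts$Ls, fisher_sided)
  }

  structure(list(
    kappa = kap, Ks = Ks, Ki = Ki, Kistar = Kistar, Ka = Ka, Kh = Kh,
    Na = Na, La = La, Nh = Nh, Lh = Lh,
    Ka_Ks = ratio(Ka), Kh_Ks = ratio(Kh),
    p_Ka_Ks = p_Ka, p_Kh_Ks = p_Kh,
    h_cutoff_rank = h_cutoff_rank), class = "rate_estimates")
}
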