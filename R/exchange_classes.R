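# Elementary amino-acid exchange classes and the exchangeability (EI) ranking.
#
# An "elementary" amino-acid change is one reachable by a single nucleotide
# substitution between two sense codons; under the standard genetic code there
# are exactly 75 such unordered amino-acid pairs. The screen partitions
# nonsynonymous substitutions over these classes, ranked from most (rank 1) to
# least (rank 75) exchangeable.

.kh_cache <- new.env(parent = emptyenv())

code_fingerprint <- function(code) {
  paste(code[all_codons()], collapse = "")
}

# Code-level lookups that do not depend on the ranking:
#  * neighbors: per sense codon, its 9 single-nt neighbours with transition
#    flag and category ("syn", "stop", or an unordered aa-pair key)
#  * pair_kind / pair_ndiff / pair_synsteps / pair_key: 64x64 codon-pair
#    classification matrices (kind coded as character)
code_tables <- function(code) {
  fp <- code_fingerprint(code)
  hit <- .kh_cache[[fp]]
  if (!is.null(hit)) return(hit)

  codons <- all_codons()
  n <- length(codons)
  aa <- code[codons]

  neigh <- lapply(codons, function(cd) {
    nb <- codon_neighbors(cd)
    nb$category <- ifelse(
      aa[nb$neighbor] == "*", "stop",
      ifelse(aa[nb$neighbor] == aa[cd], "syn",
             aa_pair_key(aa[cd], aa[nb$neighbor])))
    nb
  })
  names(neigh) <- codons

  ndiff <- matrix(0L, n, n, dimnames = list(codons, codons))
  for (p in 1:3) {
    ch <- substr(codons, p, p)
    ndiff <- ndiff + outer(ch, ch, "!=")
  }

  kind <- matrix(NA_character_, n, n, dimnames = list(codons, codons))
  key <- matrix(NA_character_, n, n, dimnames = list(codons, codons))
  synsteps <- matrix(0, n, n, dimnames = list(codons, codons))
  is_ts <- matrix(NA, n, n, dimnames = list(codons, codons))

  stop_a <- matrix(aa == "*", n, n)
  stop_b <- t(stop_a)
  same_aa <- outer(aa, aa, "==")

  kind[ndiff == 0L] <- "identical"
  kind[stop_a | stop_b] <- "stop_involving"
  todo <- which(is.na(kind), arr.ind = TRUE)
  for (r in seq_len(nrow(todo))) {
    i <- todo[r, 1]; j <- todo[r, 2]
    d <- ndiff[i, j]
    if (d == 1L) {
      if (same_aa[i, j]) {
        kind[i, j] <- "synonymous"
        synsteps[i, j] <- 1
      } else {
        kind[i, j] <- "elementary"
        key[i, j] <- aa_pair_key(aa[i], aa[j])
      }
      pos <- which(strsplit(codons[i], "")[[1]] != strsplit(codons[j], "")[[1]])
      is_ts[i, j] <- is_transition(substr(codons[i], pos, pos),
                                   substr(codons[j], pos, pos))
    } else {
      if (same_aa[i, j]) kind[i, j] <- "multihit_synonymous"
      else {
        kind[i, j] <- "nonelementary_aa_change"
        key[i, j] <- aa_pair_key(aa[i], aa[j])
      }
      synsteps[i, j] <- pathway_syn_steps(codons[i], codons[j], code)
    }
  }

  out <- list(neighbors = neigh, ndiff = ndiff, kind = kind, key = key,
              synsteps = synsteps, is_ts = is_ts)
  .kh_cache[[fp]] <- out
  out
}

# Mean number of synonymous steps over all minimal mutational pathways between
# two codons that avoid stop intermediates; falls back to all pathways when
# every ordering passes through a stop (then stop-passing steps still count by
# amino-acid identity). Used to credit Ns from multi-hit codon columns.
pathway_syn_steps <- function(ca, cb, code) {
  a <- strsplit(ca, "")[[1]]
  b <- strsplit(cb, "")[[1]]
  pos <- which(a != b)
  d <- length(pos)
  if (d == 0L) return(0)
  perms <- list()
  if (d == 1L) perms <- list(pos)
  if (d == 2L) perms <- list(pos, pos[2:1])
  if (d == 3L) perms <- lapply(list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                                    c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)),
                               function(o) pos[o])
  score <- function(order) {
    cur <- a
    syn <- 0
    ok <- TRUE
    for (p in order) {
      nxt <- cur
      nxt[p] <- b[p]
      aa_cur <- code[[paste(cur, collapse = "")]]
      aa_nxt <- code[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*" || aa_cur == "*") ok <- FALSE
      if (aa_cur == aa_nxt && aa_cur != "*") syn <- syn + 1
      cur <- nxt
    }
    c(syn = syn, ok = as.numeric(ok))
  }
  sc <- vapply(perms, score, numeric(2))
  admissible <- sc["ok", ] == 1
  if (any(admissible)) mean(sc["syn", admissible]) else mean(sc["syn", ])
}

#' Enumerate the elementary amino-acid exchange classes
#'
#' Derives, from a genetic code, the set of all unordered amino-acid pairs
#' \{A1, A2\} such that some sense codon of A1 differs from some sense codon
#' of A2 at exactly one nucleotide position. Under the standard code there are
#' exactly 75 such classes. Ranks are left unset (`NA`); attach a ranking with
#' [load_ei_ranking()] or [synthetic_ei_ranking()].
#'
#' @param code a genetic code, as returned by [standard_genetic_code()].
#' @return An object of class `exchange_class_table` (see
#'   [exchange_class_table()]) with `NA` ranks.
#' @examples
#' tab <- build_exchange_classes(standard_genetic_code())
#' nrow(tab$classes)  # 75
#' @export
build_exchange_classes <- function(code) {
  validate_genetic_code(code)
  ct <- code_tables(code)
  keys <- sort(unique(stats::na.omit(as.vector(
    ct$key[ct$kind == "elementary"]))))
  aa <- do.call(rbind, strsplit(keys, "/", fixed = TRUE))
  exchange_class_table(
    data.frame(aa1 = aa[, 1], aa2 = aa[, 2], rank = NA_integer_,
               stringsAsFactors = FALSE),
    code = code, provenance = "enumerated from genetic code; unranked")
}

#' Construct an exchange-class table
#'
#' Low-level constructor; most users want [load_ei_ranking()] or
#' [synthetic_ei_ranking()]. Validates that the pairs are exactly the
#' elementary classes of `code` and, when ranks are present, that they form a
#' permutation of `1..n_classes`. Ranked tables carry precomputed codon-level
#' lookup matrices used by the counting engine.
#'
#' @param classes data.frame with columns `aa1`, `aa2`, `rank` (rank may be
#'   all-`NA` for an unranked table).
#' @param code a genetic code.
#' @param provenance free-text label recording where the ranking came from.
#' @return An `exchange_class_table`: a list with elements `classes`, `code`,
#'   `provenance`, `pair_rank` and (ranked only) internal lookup matrices.
#' @export
exchange_class_table <- function(classes, code, provenance = "") {
  stopifnot(is.data.frame(classes),
            all(c("aa1", "aa2", "rank") %in% names(classes)))
  validate_genetic_code(code)
  ct <- code_tables(code)
  valid_keys <- sort(unique(stats::na.omit(as.vector(
    ct$key[ct$kind == "elementary"]))))

  keys <- aa_pair_key(classes$aa1, classes$aa2)
  dup <- keys[duplicated(keys)]
  if (length(dup))
    stop("duplicate amino-acid pair(s): ", paste(unique(dup), collapse = ", "))
  missing <- setdiff(valid_keys, keys)
  if (length(missing))
    stop("missing elementary pair(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(keys, valid_keys)
  if (length(extra))
    stop("pair(s) not reachable by a single nucleotide change: ",
         paste(extra, collapse = ", "))

  n <- length(valid_keys)
  ranked <- !all(is.na(classes$rank))
  if (ranked && !setequal(classes$rank, seq_len(n)))
    stop("ranks must be a permutation of 1..", n)

  classes <- classes[order(if (ranked) classes$rank else keys), ,
                     drop = FALSE]
  rownames(classes) <- NULL
  pair_rank <- classes$rank
  names(pair_rank) <- aa_pair_key(classes$aa1, classes$aa2)

  obj <- list(classes = classes, code = code, provenance = provenance,
              n_classes = n, pair_rank = pair_rank)
  if (ranked) {
    obj$rank_mat <- matrix(pair_rank[ct$key], nrow(ct$key),
                           dimnames = dimnames(ct$key))
    obj$rank_mat[ct$kind != "elementary"] <- NA_integer_
    obj <- c(obj, build_site_matrices(ct, pair_rank, n))
  }
  structure(obj, class = "exchange_class_table")
}

# Per-codon counts of transition / transversion neighbours landing in each
# category: columns 1..n = exchange classes by rank, n+1 = synonymous,
# n+2 = stop. Site weights for any kappa follow as
#   ts_counts * kappa/(kappa+2) + tv_counts * 1/(kappa+2).
build_site_matrices <- function(ct, pair_rank, n) {
  codons <- names(ct$neighbors)
  ts <- matrix(0, length(all_codons()), n + 2,
               dimnames = list(all_codons(), NULL))
  tv <- ts
  for (cd in codons) {
    nb <- ct$neighbors[[cd]]
    col <- ifelse(nb$category == "syn", n + 1,
                  ifelse(nb$category == "stop", n + 2,
                         pair_rank[nb$category]))
    for (k in seq_len(nrow(nb))) {
      if (nb$transition[k]) ts[cd, col[k]] <- ts[cd, col[k]] + 1
      else tv[cd, col[k]] <- tv[cd, col[k]] + 1
    }
  }
  list(site_ts = ts, site_tv = tv)
}

#' @export
print.exchange_class_table <- function(x, ...) {
  ranked <- !all(is.na(x$classes$rank))
  cat("Exchange-class table:", x$n_classes, "elementary amino-acid classes",
      if (ranked) "(ranked)" else "(unranked)", "\n")
  cat("Provenance:", x$provenance, "\n")
  invisible(x)
}

#' Load an exchangeability (EI) ranking from a TSV file
#'
#' Reads a tab-separated file with header columns `aa1`, `aa2`, `rank`
#' (one-letter amino acids; `#`-prefixed comment lines allowed) and validates
#' it against the elementary classes of `code`: every class present exactly
#' once, ranks a permutation of 1..75, no stop codons, every pair reachable by
#' one nucleotide change. Rank 1 is the most exchangeable class.
#'
#' @param path file path of the ranking TSV.
#' @param code a genetic code; defaults to the standard code.
#' @return A ranked `exchange_class_table`.
#' @examples
#' path <- system.file("extdata", "ei_ranking_synthetic.tsv",
#'                     package = "khscan")
#' tab <- load_ei_ranking(path)
#' head(tab$classes)
#' @export
load_ei_ranking <- function(path, code = standard_genetic_code()) {
  if (!file.exists(path)) stop("EI ranking file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("aa1", "aa2", "rank")
  if (!all(need %in% names(df)))
    stop("EI ranking must have columns aa1, aa2, rank; got: ",
         paste(names(df), collapse = ", "))
  df$rank <- as.integer(df$rank)
  exchange_class_table(df[, need], code,
                       provenance = paste("loaded from", basename(path)))
}

#' Write an exchange-class ranking to TSV
#'
#' @param table a ranked `exchange_class_table`.
#' @param path output file path.
#' @param comment optional header comment lines (written `#`-prefixed).
#' @return `path`, invisibly.
#' @export
write_ei_ranking <- function(table, path, comment = character()) {
  stopifnot(inherits(table, "exchange_class_table"))
  con <- file(path, "w")
  on.exit(close(con))
  for (line in comment) writeLines(paste("#", line), con)
  writeLines("aa1\taa2\trank", con)
  cl <- table$classes
  writeLines(sprintf("%s\t%s\t%d", cl$aa1, cl$aa2, cl$rank), con)
  invisible(path)
}

# Amino-acid properties used only to order the synthetic stand-in ranking:
# Kyte-Doolittle hydropathy and van der Waals volume (A^3), standard values.
aa_hydropathy <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
                   E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                   M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
                   Y = -1.3, V = 4.2)
aa_volume <- c(A = 67, R = 148, N = 96, D = 91, C = 86, Q = 114, E = 109,
               G = 48, H = 118, I = 124, L = 124, K = 135, M = 124, F = 135,
               P = 90, S = 73, T = 93, W = 163, Y = 141, V = 105)

#' Synthetic stand-in exchangeability ranking
#'
#' Generates a deterministic ranking of the 75 elementary classes to stand in
#' for a published evolutionary exchangeability index when none is supplied.
#' It is *synthetic*: classes are ordered by a composite of codon connectivity
#' (how many transition-weighted single-nucleotide codon interchanges connect
#' the two amino acids, a proxy for mutational opportunity) and physicochemical
#' similarity (scaled hydropathy and residue-volume distance), so that common,
#' conservative changes (e.g. D/E, K/R, S/T, I/V) rank high and rare radical
#' ones rank low — the qualitative shape of empirical exchangeability indices.
#' It is not a transcription of any published index; supply a real index via
#' [load_ei_ranking()] for substantive analyses.
#'
#' @param code a genetic code.
#' @return A ranked `exchange_class_table` with provenance `"synthetic"`.
#' @export
synthetic_ei_ranking <- function(code = standard_genetic_code()) {
  base <- build_exchange_classes(code)
  ct <- code_tables(code)
  cl <- base$classes
  keys <- aa_pair_key(cl$aa1, cl$aa2)

  # transition-weighted count of codon interchanges per class (kappa = 2)
  conn <- setNames(numeric(length(keys)), keys)
  for (cd in sense_codons(code)) {
    nb <- ct$neighbors[[cd]]
    el <- nb$category %in% keys
    w <- ifelse(nb$transition[el], 2, 1)
    conn[nb$category[el]] <- conn[nb$category[el]] + w
  }

  hyd <- abs(aa_hydropathy[cl$aa1] - aa_hydropathy[cl$aa2]) /
    diff(range(aa_hydropathy))
  vol <- abs(aa_volume[cl$aa1] - aa_volume[cl$aa2]) / diff(range(aa_volume))
  chem_dist <- sqrt(hyd^2 + vol^2)

  # high connectivity and low chemical distance => exchangeable => low rank
  score <- scale(conn / max(conn))[, 1] - scale(chem_dist)[, 1]
  ord <- order(-score, keys)  # key lexicographic tie-break for determinism
  cl$rank[ord] <- seq_along(ord)
  exchange_class_table(cl, code, provenance = "synthetic")
}
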