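# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package internals: neighbour
# enumeration, pathway expansion and hypergeometric sums are written from
# first principles (plain loops, choose()).

ORACLE_NUCS <- c("A", "C", "G", "T")

oracle_is_transition <- function(x, y) {
  (x %in% c("A", "G") && y %in% c("A", "G")) ||
    (x %in% c("C", "T") && y %in% c("C", "T"))
}

oracle_pair_key <- function(a1, a2) paste(sort(c(a1, a2)), collapse = "/")

# all single-nucleotide neighbours of a codon, as character vector
oracle_neighbors <- function(codon) {
  out <- character(0)
  for (pos in 1:3) {
    for (nt in ORACLE_NUCS) {
      if (nt != substr(codon, pos, pos)) {
        nb <- codon
        substr(nb, pos, pos) <- nt
        out <- c(out, nb)
      }
    }
  }
  out
}

# enumerate elementary amino-acid pairs by scanning all sense codon pairs
oracle_elementary_pairs <- function(code) {
  keys <- character(0)
  for (cd in names(code)) {
    if (code[[cd]] == "*") next
    for (nb in oracle_neighbors(cd)) {
      if (code[[nb]] == "*" || code[[nb]] == code[[cd]]) next
      keys <- c(keys, oracle_pair_key(code[[cd]], code[[nb]]))
    }
  }
  sort(unique(keys))
}

# site counts for one codon vector: list(Ls, Li named by pair key, stop)
oracle_sites <- function(codons, kappa, code) {
  Ls <- 0; stopw <- 0
  Li <- new.env(parent = emptyenv())
  w_ts <- kappa / (kappa + 2)
  w_tv <- 1 / (kappa + 2)
  for (cd in codons) {
    for (pos in 1:3) {
      from <- substr(cd, pos, pos)
      for (nt in ORACLE_NUCS) {
        if (nt == from) next
        nb <- cd
        substr(nb, pos, pos) <- nt
        w <- if (oracle_is_transition(from, nt)) w_ts else w_tv
        if (code[[nb]] == "*") stopw <- stopw + w
        else if (code[[nb]] == code[[cd]]) Ls <- Ls + w
        else {
          key <- oracle_pair_key(code[[cd]], code[[nb]])
          Li[[key]] <- (if (is.null(Li[[key]])) 0 else Li[[key]]) + w
        }
      }
    }
  }
  list(Ls = Ls, Li = as.list(Li), stop = stopw)
}

oracle_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in oracle_permutations(v[-i]))
      out <- c(out, list(c(v[i], rest)))
  out
}

# mean synonymous steps over minimal stop-avoiding pathways (all pathways if
# none avoids a stop; stop-involving steps then never count as synonymous)
oracle_synsteps <- function(ca, cb, code) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  if (length(pos) == 0) return(0)
  res <- data.frame(syn = numeric(0), clean = logical(0))
  for (ord in oracle_permutations(pos)) {
    cur <- ca; syn <- 0; clean <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (code[[cur]] == "*" || code[[nxt]] == "*") clean <- FALSE
      else if (code[[cur]] == code[[nxt]]) syn <- syn + 1
      cur <- nxt
    }
    res <- rbind(res, data.frame(syn = syn, clean = clean))
  }
  if (any(res$clean)) mean(res$syn[res$clean]) else mean(res$syn)
}

# full column-by-column counting reference; returns Ns, Ls, named Ni/Li,
# n_nonelementary. `ranks` is a named vector pair-key -> rank.
oracle_count <- function(aln, code, ranks, kappa) {
  n <- nchar(aln$seq_a) / 3
  ca <- substring(aln$seq_a, 3 * (1:n) - 2, 3 * (1:n))
  cb <- substring(aln$seq_b, 3 * (1:n) - 2, 3 * (1:n))
  keep <- logical(n)
  for (i in 1:n) {
    clean <- grepl("^[ACGT]{3}$", ca[i]) && grepl("^[ACGT]{3}$", cb[i])
    keep[i] <- clean && code[[ca[i]]] != "*" && code[[cb[i]]] != "*"
  }
  ca <- ca[keep]; cb <- cb[keep]
  Ns <- 0; Ni <- setNames(numeric(length(ranks)), names(ranks))
  nonel <- 0L
  for (i in seq_along(ca)) {
    if (ca[i] == cb[i]) next
    d <- sum(strsplit(ca[i], "")[[1]] != strsplit(cb[i], "")[[1]])
    same <- code[[ca[i]]] == code[[cb[i]]]
    if (d == 1 && same) Ns <- Ns + 1
    else if (d == 1) {
      key <- oracle_pair_key(code[[ca[i]]], code[[cb[i]]])
      Ni[key] <- Ni[key] + 1
    } else {
      Ns <- Ns + oracle_synsteps(ca[i], cb[i], code)
      if (!same) nonel <- nonel + 1L
    }
  }
  sa <- oracle_sites(ca, kappa, code)
  sb <- oracle_sites(cb, kappa, code)
  Li <- setNames(numeric(length(ranks)), names(ranks))
  for (key in names(ranks)) {
    la <- if (is.null(sa$Li[[key]])) 0 else sa$Li[[key]]
    lb <- if (is.null(sb$Li[[key]])) 0 else sb$Li[[key]]
    Li[key] <- (la + lb) / 2
  }
  list(Ns = Ns, Ls = (sa$Ls + sb$Ls) / 2, Ni = Ni, Li = Li,
       n_nonelementary = nonel, n_codons_used = length(ca))
}

# two-sided Fisher p by full enumeration over tables with fixed margins
oracle_fisher2 <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x)
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1), numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
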