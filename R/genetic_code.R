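#' The standard genetic code
#'
#' Returns the standard (nuclear) genetic code as a named character vector
#' mapping all 64 DNA codons to one-letter amino acids, with `"*"` marking the
#' three stop codons. The table is taken from
#' [Biostrings::GENETIC_CODE] so the mapping is never re-typed by hand.
#'
#' @return Named character vector of length 64; names are uppercase DNA
#'   triplets, values are one-letter amino acids or `"*"`.
#' @examples
#' code <- standard_genetic_code()
#' code[["ATG"]]  # "M"
#' sum(code == "*")  # 3 stop codons
#' @export
standard_genetic_code <- function() {
  code <- as.character(Biostrings::GENETIC_CODE)
  names(code) <- names(Biostrings::GENETIC_CODE)
  validate_genetic_code(code)
  code
}

validate_genetic_code <- function(code) {
  if (length(code) != 64L || is.null(names(code)))
    stop("genetic code must map exactly 64 named codons")
  if (!setequal(names(code), all_codons()))
    stop("genetic code keys must be the 64 DNA triplets")
  aas <- setdiff(unique(code), "*")
  if (length(aas) > 20L)
    stop("genetic code maps to more than 20 amino acids")
  invisible(code)
}

NUCS <- c("A", "C", "G", "T")

all_codons <- function() {
  g <- expand.grid(p3 = NUCS, p2 = NUCS, p1 = NUCS,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

#' @noRd
sense_codons <- function(code) {
  sort(names(code)[code != "*"])
}

#' Transition or transversion?
#'
#' @param a,b single nucleotides (A/C/G/T), vectorised.
#' @return logical: TRUE where a<->b is a transition (purine<->purine or
#'   pyrimidine<->pyrimidine). `a == b` yields NA.
#' @noRd
is_transition <- function(a, b) {
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  ifelse(a == b, NA, purine[a] == purine[b])
}

# The 9 single-nucleotide neighbours of a codon, with the mutated position and
# whether the change is a transition. Deterministic order: position 1..3, then
# target nucleotide alphabetically.
codon_neighbors <- function(codon) {
  stopifnot(nchar(codon) == 3L)
  nts <- strsplit(codon, "")[[1]]
  out <- data.frame(neighbor = character(9), pos = integer(9),
                    transition = logical(9), stringsAsFactors = FALSE)
  k <- 0L
  for (pos in 1:3) {
    for (nt in setdiff(NUCS, nts[pos])) {
      k <- k + 1L
      mut <- nts
      mut[pos] <- nt
      out$neighbor[k] <- paste(mut, collapse = "")
      out$pos[k] <- pos
      out$transition[k] <- is_transition(nts[pos], nt)
    }
  }
  out
}

# Number of nucleotide differences between two codons (scalar).
codon_ndiff <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Canonical unordered amino-acid pair label, e.g. "D/E".
aa_pair_key <- function(a1, a2) {
  ifelse(a1 < a2, paste(a1, a2, sep = "/"), paste(a2, a1, sep = "/"))
}
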