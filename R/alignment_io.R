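# Reading pairwise in-frame codon alignments and writing result tables.

#' Construct a pairwise codon alignment
#'
#' @param gene_id gene identifier.
#' @param seq_a,seq_b aligned uppercase DNA strings of equal length divisible
#'   by 3; `-` (gap) and `N` (ambiguity) allowed — codon columns containing
#'   either in either sequence are skipped by the counting engine.
#' @param species_a,species_b sequence / species labels.
#' @return An object of class `codon_alignment`.
#' @export
codon_alignment <- function(gene_id, seq_a, seq_b,
                            species_a = "A", species_b = "B") {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b))
    stop("gene ", gene_id, ": sequences differ in length (",
         nchar(seq_a), " vs ", nchar(seq_b), ")")
  if (nchar(seq_a) %% 3 != 0)
    stop("gene ", gene_id, ": alignment length ", nchar(seq_a),
         " not divisible by 3")
  for (s in list(a = seq_a, b = seq_b)) {
    bad <- regexpr("[^ACGTN-]", s)
    if (bad > 0)
      stop("gene ", gene_id, ": invalid character '",
           substr(s, bad, bad), "' at position ", bad)
  }
  structure(list(gene_id = gene_id, seq_a = seq_a, seq_b = seq_b,
                 species_a = species_a, species_b = species_b,
                 n_codons = nchar(seq_a) %/% 3),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment", x$gene_id, ":", x$n_codons, "codon columns (",
      x$species_a, "vs", x$species_b, ")\n")
  invisible(x)
}

#' Read a pairwise codon alignment from FASTA
#'
#' Expects a FASTA file with exactly two aligned records of equal length
#' divisible by 3 (an in-frame codon alignment, e.g. a Pal2nal-style
#' back-translation). Record names become the species/sequence labels.
#'
#' @param path FASTA file path.
#' @param gene_id gene identifier; defaults to the file name without
#'   extension.
#' @return A `codon_alignment`.
#' @export
read_codon_alignment <- function(path, gene_id = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) != 2L)
    stop(path, ": expected exactly 2 FASTA records, found ", length(recs))
  if (is.null(gene_id))
    gene_id <- sub("\\.[^.]*$", "", basename(path))
  ids <- sub("\\s.*$", "", names(recs))
  codon_alignment(gene_id, as.character(recs[[1]]), as.character(recs[[2]]),
                  species_a = ids[1], species_b = ids[2])
}

#' Read a manifest of per-gene alignment files
#'
#' @param path TSV with header columns `gene_id` and `path`
#'   (`#` comments allowed); relative paths are resolved against the
#'   manifest's directory.
#' @return list of `codon_alignment`, named by gene_id.
#' @export
read_alignment_manifest <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "path") %in% names(df)))
    stop("manifest must have columns gene_id, path")
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in manifest: ",
         df$gene_id[duplicated(df$gene_id)][1])
  base <- dirname(path)
  alns <- lapply(seq_len(nrow(df)), function(i) {
    p <- df$path[i]
    if (!file.exists(p)) p <- file.path(base, df$path[i])
    read_codon_alignment(p, gene_id = df$gene_id[i])
  })
  names(alns) <- df$gene_id
  alns
}

RESULT_COLUMNS <- c("gene_id", "species_a_id", "species_b_id",
                    "Ns", "Ls", "Nh", "Lh", "Na", "La", "kappa",
                    "Ks", "Ka", "Kh", "Ka_Ks", "Kh_Ks",
                    "p_Ka_Ks", "p_Kh_Ks", "n_nonelementary",
                    "filtered", "filter_reason", "is_psg")

#' Write a per-gene result table to TSV
#'
#' Writes the screen's per-gene results (one row per ortholog pair, Table-3
#' style layout) with floats rendered to 6 significant digits and undefined
#' values as `NA`.
#'
#' @param table data.frame of gene results as produced by [run_screen()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table), nrow(table) > 0)
  missing <- setdiff(RESULT_COLUMNS, names(table))
  if (length(missing))
    stop("result table lacks column(s): ", paste(missing, collapse = ", "))
  out <- table[, RESULT_COLUMNS]
  num <- vapply(out, is.numeric, logical(1)) &
    !names(out) %in% c("Ns", "Nh", "Na", "n_nonelementary")
  for (j in which(num)) out[[j]] <- signif(out[[j]], 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path TSV path.
#' @return data.frame with the standard result columns.
#' @export
read_results <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(RESULT_COLUMNS, names(df))
  if (length(missing))
    stop("not a khscan result table; lacks: ",
         paste(missing, collapse = ", "))
  df
}

#' Write a two-record alignment to FASTA
#'
#' @param aln a `codon_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_codon_alignment <- function(aln, path) {
  set <- Biostrings::DNAStringSet(c(aln$seq_a, aln$seq_b))
  names(set) <- c(aln$species_a, aln$species_b)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
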