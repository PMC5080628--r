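# Mutation-selection codon-pair simulator.
#
# Two lineages evolve independently from a common ancestor (a star tree of
# two). Mutations are proposed per codon position at transition :
# transversion rates of kappa : 1, scaled so a fully neutral site accrues
# `branch_length` expected substitutions per lineage. Synonymous proposals
# are always accepted; an elementary nonsynonymous proposal is accepted with
# the acceptance probability (omega) of its exchange class; stop-creating
# proposals are rejected. Every accepted event is logged by class, giving an
# exact per-gene truth table against which the counting engine can be
# verified.

#' Simulation configuration
#'
#' @param n_codons codons per gene.
#' @param n_genes number of independent ortholog pairs.
#' @param kappa true transition/transversion rate ratio (default 2).
#' @param branch_length expected neutral substitutions per site per lineage;
#'   the pairwise divergence is about twice this. The default 0.01 targets a
#'   synonymous divergence Ks of about 0.02, the low-divergence regime of a
#'   recently separated species pair.
#' @param omega_high,omega_low relative fixation rates (omega) of elementary
#'   changes in the top `h_ranks` exchange classes resp. the remaining
#'   classes (defaults 1, 1: neutral). Values below 1 act as acceptance
#'   probabilities (purifying selection); values above 1 proportionally
#'   accelerate the class beyond the neutral rate (positive selection).
#' @param h_ranks number of top classes taking `omega_high` (default 10).
#' @param omega_by_rank optional full length-75 vector of per-rank acceptance
#'   probabilities, overriding the two-level scheme.
#' @param codon_freqs optional probability vector over the 61 sense codons
#'   (named by codon); default uniform.
#' @param seed master seed; per-gene substream seeds are drawn from it up
#'   front so cohorts are order-independent and fully reproducible.
#' @param one_hit_per_codon if TRUE, a codon (across both lineages) accepts
#'   at most one substitution; used to verify the counting engine against the
#'   event log without multi-hit ambiguity.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_codons = 500, n_genes = 1, kappa = 2,
                              branch_length = 0.01, omega_high = 1,
                              omega_low = 1, h_ranks = 10,
                              omega_by_rank = NULL, codon_freqs = NULL,
                              seed = 1, one_hit_per_codon = FALSE) {
  stopifnot(n_codons > 0, n_genes >= 1, kappa > 0, branch_length >= 0,
            omega_high >= 0, omega_low >= 0, h_ranks >= 1, h_ranks <= 75)
  if (is.null(omega_by_rank))
    omega_by_rank <- c(rep(omega_high, h_ranks), rep(omega_low, 75 - h_ranks))
  stopifnot(length(omega_by_rank) == 75, all(omega_by_rank >= 0))
  structure(list(n_codons = as.integer(n_codons),
                 n_genes = as.integer(n_genes),
                 kappa = kappa, branch_length = branch_length,
                 omega_by_rank = omega_by_rank, h_ranks = h_ranks,
                 codon_freqs = codon_freqs, seed = as.integer(seed),
                 one_hit_per_codon = isTRUE(one_hit_per_codon)),
            class = "simulation_config")
}

TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")

# Evolve one lineage in place; `hit` is the shared accepted-event indicator
# used by one_hit_per_codon mode. Returns list(codons, hit, log).
evolve_lineage <- function(codons, config, table, hit) {
  n <- length(codons)
  # thinning: proposals run at M times the neutral intensity so classes with
  # omega > 1 (positive selection) can exceed the neutral rate; a synonymous
  # proposal is then accepted with 1/M and a class-i proposal with omega_i/M,
  # leaving the synonymous substitution rate at branch_length per site
  M <- max(1, config$omega_by_rank)
  n_ev <- stats::rpois(n, 3 * config$branch_length * M)
  log_syn <- 0L
  log_class <- integer(75)
  w_ts <- config$kappa / (config$kappa + 2)
  code <- table$code
  for (ci in which(n_ev > 0L)) {
    for (e in seq_len(n_ev[ci])) {
      if (config$one_hit_per_codon && hit[ci]) next
      cur <- codons[ci]
      pos <- sample.int(3L, 1L)
      from <- substr(cur, pos, pos)
      if (stats::runif(1) < w_ts) {
        to <- TRANSITION_OF[[from]]
      } else {
        to <- sample(setdiff(NUCS, c(from, TRANSITION_OF[[from]])), 1L)
      }
      prop <- cur
      substr(prop, pos, pos) <- to
      if (code[[prop]] == "*") next
      if (code[[prop]] == code[[cur]]) {
        if (stats::runif(1) < 1 / M) {
          codons[ci] <- prop
          hit[ci] <- TRUE
          log_syn <- log_syn + 1L
        }
      } else {
        rank <- table$rank_mat[cur, prop]
        if (stats::runif(1) < config$omega_by_rank[rank] / M) {
          codons[ci] <- prop
          hit[ci] <- TRUE
          log_class[rank] <- log_class[rank] + 1L
        }
      }
    }
  }
  list(codons = codons, hit = hit,
       log = list(syn = log_syn, class = log_class))
}

#' Simulate one ortholog codon-alignment pair
#'
#' Draws an ancestor from the codon frequencies and evolves two independent
#' lineages under the mutation-selection scheme of the config. Uses the
#' current RNG state; seed management is done by [simulate_cohort()].
#'
#' @param config a [simulation_config()].
#' @param table a ranked [exchange_class_table()].
#' @param gene_id identifier for the returned alignment.
#' @return list(alignment = `codon_alignment`, truth = list(Ns_true,
#'   Ni_true[75], n_nonsyn_true)) — realized accepted-event counts by class,
#'   summed over both lineages.
#' @export
simulate_pair <- function(config, table, gene_id = "g1") {
  stopifnot(inherits(config, "simulation_config"),
            inherits(table, "exchange_class_table"))
  if (is.null(table$rank_mat))
    stop("simulate_pair requires a ranked exchange-class table")
  sense <- sense_codons(table$code)
  freqs <- config$codon_freqs
  if (is.null(freqs)) freqs <- setNames(rep(1 / length(sense),
                                            length(sense)), sense)
  anc <- sample(names(freqs), config$n_codons, replace = TRUE, prob = freqs)
  hit <- rep(FALSE, config$n_codons)
  la <- evolve_lineage(anc, config, table, hit)
  lb <- evolve_lineage(anc, config, table, la$hit)
  aln <- codon_alignment(gene_id,
                         paste(la$codons, collapse = ""),
                         paste(lb$codons, collapse = ""),
                         species_a = paste0(gene_id, "_sp1"),
                         species_b = paste0(gene_id, "_sp2"))
  list(alignment = aln,
       truth = list(Ns_true = la$log$syn + lb$log$syn,
                    Ni_true = la$log$class + lb$log$class,
                    n_nonsyn_true = sum(la$log$class + lb$log$class)))
}

#' Simulate a cohort of ortholog pairs with an event-log truth table
#'
#' Generates `config$n_genes` independent pairs. Per-gene substream seeds are
#' drawn up front from the master seed, so gene `i` is identical no matter
#' how many genes are simulated or in which order they are consumed.
#'
#' @param config a [simulation_config()].
#' @param table a ranked [exchange_class_table()].
#' @return list(alignments = named list of `codon_alignment`, truth =
#'   data.frame(gene_id, Ns_true, n_nonsyn_true), Ni_true = n_genes x 75
#'   matrix, config = config).
#' @export
simulate_cohort <- function(config, table) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  gene_seeds <- sample.int(.Machine$integer.max - 1L, config$n_genes)
  ids <- sprintf("gene%04d", seq_len(config$n_genes))
  alns <- vector("list", config$n_genes)
  Ns_true <- integer(config$n_genes)
  Ni_true <- matrix(0L, config$n_genes, 75)
  for (i in seq_len(config$n_genes)) {
    set.seed(gene_seeds[i])
    sim <- simulate_pair(config, table, gene_id = ids[i])
    alns[[i]] <- sim$alignment
    Ns_true[i] <- sim$truth$Ns_true
    Ni_true[i, ] <- sim$truth$Ni_true
  }
  names(alns) <- ids
  list(alignments = alns,
       truth = data.frame(gene_id = ids, Ns_true = Ns_true,
                          n_nonsyn_true = rowSums(Ni_true),
                          stringsAsFactors = FALSE),
       Ni_true = Ni_true, config = config)
}

#' Write a simulated cohort to disk
#'
#' Writes one 2-record FASTA per gene, a manifest TSV (`gene_id`, `path`) and
#' a truth TSV (`gene_id`, `Ns_true`, per-class `Ni_true`).
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(cohort$alignments)
  paths <- file.path(dir, paste0(ids, ".fasta"))
  for (i in seq_along(ids))
    write_codon_alignment(cohort$alignments[[i]], paths[i])
  utils::write.table(
    data.frame(gene_id = ids, path = basename(paths)),
    file.path(dir, "manifest.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cbind(cohort$truth,
                 as.data.frame(cohort$Ni_true) |>
                   stats::setNames(paste0("Ni_", 1:75)))
  utils::write.table(truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
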