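#' Simulation configuration
#'
#' One validated bundle of parameters for the synthetic-data generators.
#' Identical configurations (including the seed) give bit-identical output
#' from every simulator. Defaults describe a desk-scale version of a
#' transcriptome sampling design: 20 species, 50 gene clusters, two isoforms
#' per species, modest paralogy/chimera/contamination rates, a 2-state
#' equal-rates trait model, and pure-BM continuous evolution.
#'
#' @param seed integer RNG seed.
#' @param n_species number of species (>= 2).
#' @param birth_rate,death_rate birth-death rates (events / unit time);
#'   `birth_rate > 0`, `death_rate >= 0`.
#' @param n_clusters number of gene families to simulate.
#' @param isoforms_per_species isoform copies per species per cluster (>= 1).
#' @param p_paralog,p_chimera,p_contaminant probabilities in `[0, 1]`.
#' @param gene_length_codons codons per gene (>= 50).
#' @param q_matrix k x k trait rate matrix (rows sum to 0).
#' @param sigma2 BM variance rate (> 0).
#' @param lambda_true Pagel's lambda used when simulating continuous traits.
#' @param srh_violation `"none"` or `"clade_shift"`.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_species = 20L, birth_rate = 1,
                       death_rate = 0, n_clusters = 50L,
                       isoforms_per_species = 2L, p_paralog = 0.1,
                       p_chimera = 0.1, p_contaminant = 0.05,
                       gene_length_codons = 200L,
                       q_matrix = matrix(c(-0.5, 0.5, 0.5, -0.5), 2, 2,
                                         dimnames = list(c("0", "1"),
                                                         c("0", "1"))),
                       sigma2 = 1, lambda_true = 1,
                       srh_violation = c("none", "clade_shift")) {
  srh_violation <- match.arg(srh_violation)
  stopifnot(n_species >= 2, birth_rate > 0, death_rate >= 0,
            n_clusters >= 1, isoforms_per_species >= 1,
            gene_length_codons >= 50, sigma2 > 0,
            lambda_true >= 0, lambda_true <= 1)
  for (p in c(p_paralog, p_chimera, p_contaminant))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  .check_q(q_matrix)
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 birth_rate = birth_rate, death_rate = death_rate,
                 n_clusters = as.integer(n_clusters),
                 isoforms_per_species = as.integer(isoforms_per_species),
                 p_paralog = p_paralog, p_chimera = p_chimera,
                 p_contaminant = p_contaminant,
                 gene_length_codons = as.integer(gene_length_codons),
                 q_matrix = q_matrix, sigma2 = sigma2,
                 lambda_true = lambda_true, srh_violation = srh_violation),
            class = "sim_config")
}

#' Simulate a rooted binary tree under a birth-death process
#'
#' Wraps `ape::rphylo`, which simulates a birth-death tree conditioned on
#' the number of extant tips (so the simulation cannot die out; the
#' classical retry-on-extinction loop is unnecessary). With
#' `death_rate = 0` the tree is a pure-birth (Yule) tree; trees are
#' ultrametric. Tips are labelled `sp01..spNN`.
#'
#' @param config a [sim_config].
#' @return rooted binary `phylo` with `config$n_species` tips and positive
#'   branch lengths.
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tr <- ape::rphylo(config$n_species, config$birth_rate, config$death_rate,
                    fossils = FALSE)
  tr$tip.label <- sprintf("sp%02d", seq_len(config$n_species))
  tr
}
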