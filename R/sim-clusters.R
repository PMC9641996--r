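# Sequence simulators. Sites evolve under F81 (equal frequencies = JC in
# the stationary case); realism beyond what the downstream filters test is
# deliberately out of scope.

.BASES <- c("A", "C", "G", "T")

# F81 transition matrix for branch length t and base frequencies pi.
.f81_p <- function(t, pi) {
  beta <- 1 / (1 - sum(pi^2))
  e <- exp(-beta * t)
  P <- matrix(rep(pi, each = 4), 4, 4)
  P <- (1 - e) * P
  diag(P) <- diag(P) + e
  P
}

# Evolve integer-coded sites (1..4) along one branch, vectorised over sites.
.evolve_sites <- function(parent, P) {
  child <- integer(length(parent))
  u <- runif(length(parent))
  for (s in 1:4) {
    idx <- which(parent == s)
    if (!length(idx)) next
    cp <- cumsum(P[s, ])
    child[idx] <- findInterval(u[idx], cp, left.open = TRUE) + 1L
  }
  child
}

#' Simulate a codon alignment with known conserved blocks
#'
#' Sites evolve independently under F81 with equal base frequencies
#' (stationary, reversible, homogeneous) except, under
#' `srh_violation = "clade_shift"`, on branches inside one clade (the larger
#' child subtree of the root) where the designated codon positions evolve
#' towards a strongly shifted base composition — a sustained compositional
#' drive that violates stationarity across the alignment. A central run of
#' codons is simulated at a reduced rate and emitted as the true conserved
#' block (1-based inclusive nucleotide coordinates, codon-aligned).
#'
#' @param tree rooted `phylo`.
#' @param gene_length_codons number of codons (>= 50).
#' @param srh_violation `"none"` or `"clade_shift"`.
#' @param seed integer seed.
#' @param shift_positions codon positions (subset of 1:3) carrying the
#'   compositional shift.
#' @param pi_shift shifted equilibrium frequencies inside the clade.
#' @param shift_scale branch-length multiplier at shifted positions inside
#'   the clade (drives composition close to `pi_shift`).
#' @param conserved_frac fraction of codons in the central conserved block.
#' @param rate_conserved,rate_variable relative site rates inside/outside
#'   the block.
#' @return list: `alignment` (character matrix taxa x sites), `blocks`
#'   (data.frame start/end, nt coordinates), `clade_tips`, `tree`.
#' @export
simulate_codon_alignment <- function(tree, gene_length_codons = 200L,
                                     srh_violation = c("none", "clade_shift"),
                                     seed = 1L, shift_positions = c(1L, 2L),
                                     pi_shift = c(0.7, 0.1, 0.1, 0.1),
                                     shift_scale = 5,
                                     conserved_frac = 0.6,
                                     rate_conserved = 0.3,
                                     rate_variable = 1) {
  srh_violation <- match.arg(srh_violation)
  .check_tree(tree)
  stopifnot(gene_length_codons >= 50)
  set.seed(as.integer(seed))
  L <- 3L * gene_length_codons
  pos <- rep(1:3, gene_length_codons)
  c0 <- floor(gene_length_codons * (1 - conserved_frac) / 2) + 1L
  c1 <- c0 + ceiling(gene_length_codons * conserved_frac) - 1L
  conserved <- rep(FALSE, L)
  conserved[(3L * (c0 - 1L) + 1L):(3L * c1)] <- TRUE
  site_rate <- ifelse(conserved, rate_conserved, rate_variable)
  pi0 <- rep(0.25, 4)
  # clade = larger child subtree of the root
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- tree$edge[tree$edge[, 1L] == root, 2L]
  sz <- vapply(kids, function(n)
    if (n <= ntip) 1L else length(.subtree_tips(tree, n)), 0L)
  clade_node <- kids[which.max(sz)]
  clade_tips <- if (clade_node <= ntip) clade_node
  else .subtree_tips(tree, clade_node)
  clade_nodes <- c(clade_node,
                   if (clade_node > ntip) .subtree_nodes(tree, clade_node))
  po <- .postorder(tree)
  nnode <- po$ntip + po$nnode
  seqs <- matrix(0L, nnode, L)
  seqs[po$root, ] <- sample.int(4L, L, replace = TRUE, prob = pi0)
  shifted_site <- pos %in% shift_positions
  for (e in rev(seq_len(nrow(po$edge)))) {
    par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    t0 <- po$el[e]
    in_clade <- srh_violation == "clade_shift" && ch %in% clade_nodes
    child <- seqs[par, ]
    for (r in unique(site_rate)) {
      sel <- site_rate == r & (!in_clade | !shifted_site)
      if (any(sel))
        child[sel] <- .evolve_sites(seqs[par, sel], .f81_p(t0 * r, pi0))
      if (in_clade) {
        sel2 <- site_rate == r & shifted_site
        if (any(sel2))
          child[sel2] <- .evolve_sites(seqs[par, sel2],
                                       .f81_p(t0 * r * shift_scale, pi_shift))
      }
    }
    seqs[ch, ] <- child
  }
  aln <- matrix(.BASES[seqs[seq_len(ntip), ]], ntip, L)
  rownames(aln) <- po$tree$tip.label
  list(alignment = aln,
       blocks = data.frame(start = 3L * (c0 - 1L) + 1L, end = 3L * c1),
       clade_tips = po$tree$tip.label[clade_tips], tree = tree)
}

# Tip / all-descendant indices of a subtree rooted at `node`.
.subtree_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- integer(0); stack <- node
  while (length(stack)) {
    n <- stack[1]; stack <- stack[-1]
    if (n <= ntip) out <- c(out, n)
    else stack <- c(stack, tree$edge[tree$edge[, 1L] == n, 2L])
  }
  out
}
.subtree_nodes <- function(tree, node) {
  out <- integer(0); stack <- tree$edge[tree$edge[, 1L] == node, 2L]
  while (length(stack)) {
    n <- stack[1]; stack <- stack[-1]
    out <- c(out, n)
    stack <- c(stack, tree$edge[tree$edge[, 1L] == n, 2L])
  }
  out
}

# Distinct k-mer sets from sequence strings.
.kmer_sets <- function(seq_strings, k = 8L) {
  lapply(seq_strings, function(s) {
    L <- nchar(s)
    unique(substring(s, 1:(L - k + 1L), k:L))
  })
}

#' Simulate ortholog clusters with isoforms, paralogs, chimeras and
#' contaminants
#'
#' Builds `n_clusters` gene families over the species of
#' `simulate_tree(config)`. Each family descends from a random root gene
#' evolved along the tree (scaled so within-family identity stays high);
#' every sampled species contributes `isoforms_per_species` near-identical
#' isoforms (>= 99.5% identity). With probability `p_paralog` a species
#' gains a diverged paralog; with probability `p_chimera` the cluster is
#' merged with a second, independently evolved family covering ~60% of its
#' species (emulating a chimeric cluster joined by a fused transcript whose
#' breakpoint sits at the sequence midpoint +/- 10%); with probability
#' `p_contaminant` a species gains a contaminant transcript recorded in the
#' truth and given a qualifying hit in the contaminant hit table.
#'
#' The intra-cluster hit table reports, for every transcript pair sharing
#' enough distinct 8-mers, a bitscore-like similarity
#' `shared-kmer-fraction * 2 * min(length) / 8`, the position-wise percent
#' identity, alignment/query/subject lengths, and a pseudo e-value
#' `1e3 * 2^(-bitscore)` (monotone decreasing in score).
#'
#' @param config a [sim_config].
#' @param seed seed; defaults to `config$seed`.
#' @return object of class `sim_clusters`: `transcripts` (data.frame
#'   species_id/transcript_id/sequence/length), `clusters` (cluster_id/
#'   species_id/transcript_id), `hits`, `contaminant_hits` (outfmt-6-like
#'   data.frames), `truth` (tree, per-cluster family memberships,
#'   `chimera_map`, `contaminant_ids`), `config`.
#' @export
simulate_ortholog_clusters <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (config$p_chimera > 0 && config$n_clusters < 2)
    stop("p_chimera > 0 requires at least 2 gene families")
  tree <- simulate_tree(config)
  set.seed(as.integer(seed) + 1L)
  n <- config$n_species
  L <- 3L * config$gene_length_codons
  mu <- 0.05 / max(.node_depths(tree))      # keep within-family identity >= ~90%
  sc_tree <- tree; sc_tree$edge.length <- tree$edge.length * mu
  species <- tree$tip.label
  tx_rows <- list(); cl_rows <- list(); hit_rows <- list()
  chim_map <- list(); families <- list(); contam_ids <- character(0)
  contam_rows <- list()

  evolve_family <- function(present_idx) {
    po <- .postorder(sc_tree)
    nnode <- po$ntip + po$nnode
    seqs <- matrix(0L, nnode, L)
    seqs[po$root, ] <- sample.int(4L, L, replace = TRUE)
    P_cache <- lapply(po$el, .f81_p, pi = rep(0.25, 4))
    for (e in rev(seq_len(nrow(po$edge))))
      seqs[po$edge[e, 2L], ] <- .evolve_sites(seqs[po$edge[e, 1L], ],
                                              P_cache[[e]])
    seqs[present_idx, , drop = FALSE]
  }
  mutate <- function(s, p) {
    hit <- which(runif(length(s)) < p)
    if (length(hit)) s[hit] <- sample.int(4L, length(hit), replace = TRUE)
    s
  }

  for (cl in seq_len(config$n_clusters)) {
    cid <- sprintf("cl%03d", cl)
    p_present <- runif(1, 0.65, 1)
    present <- which(runif(n) <= p_present)
    if (length(present) < 2) present <- sort(sample.int(n, 2))
    fam_a <- evolve_family(present)
    members <- list()   # list of (species, id, intseq, family)
    add_member <- function(sp_i, id, s, fam) {
      members[[length(members) + 1L]] <<- list(sp = species[sp_i], id = id,
                                               seq = s, fam = fam)
    }
    for (i in seq_along(present)) {
      sp_i <- present[i]
      base <- fam_a[i, ]
      for (iso in seq_len(config$isoforms_per_species)) {
        s <- if (iso == 1) base else mutate(base, 0.002)
        add_member(sp_i, sprintf("%s_%s_t%d", species[sp_i], cid, iso), s, "A")
      }
      if (runif(1) < config$p_paralog)
        add_member(sp_i, sprintf("%s_%s_par", species[sp_i], cid),
                   mutate(base, 0.12), "A")
    }
    is_chim <- runif(1) < config$p_chimera
    if (is_chim) {
      nb <- max(2L, round(0.6 * length(present)))
      present_b <- sort(sample(present, min(nb, length(present) - 1L)))
      fam_b <- evolve_family(present_b)
      for (i in seq_along(present_b))
        add_member(present_b[i],
                   sprintf("%s_%s_B_t1", species[present_b[i]], cid),
                   fam_b[i, ], "B")
      # fused transcript: 5' half family A + 3' half family B
      sp_c <- sample(present_b, 1)
      bp <- round(L * (0.5 + runif(1, -0.1, 0.1)))
      sa <- fam_a[match(sp_c, present), ]
      sb <- fam_b[match(sp_c, present_b), ]
      chim_id <- sprintf("%s_%s_chim", species[sp_c], cid)
      add_member(sp_c, chim_id, c(sa[1:bp], sb[(bp + 1L):L]), "chimera")
      chim_map[[chim_id]] <- list(cluster_id = cid, gene_a = paste0(cid, "A"),
                                  gene_b = paste0(cid, "B"), breakpoint = bp,
                                  species = species[sp_c])
    }
    if (runif(1) < config$p_contaminant) {
      sp_k <- sample(present, 1)
      con_id <- sprintf("%s_%s_contam", species[sp_k], cid)
      contam_ids <- c(contam_ids, con_id)
      add_member_seq <- sample.int(4L, L, replace = TRUE)
      tx_rows[[length(tx_rows) + 1L]] <-
        data.frame(species_id = species[sp_k], transcript_id = con_id,
                   sequence = paste(.BASES[add_member_seq], collapse = ""),
                   length = L)
      contam_rows[[length(contam_rows) + 1L]] <-
        data.frame(qseqid = con_id, sseqid = sprintf("db|contam%04d", cl),
                   pident = round(runif(1, 91, 99.5), 2),
                   length = round(L * runif(1, 0.3, 0.9)), qlen = L, slen = L,
                   evalue = 10^-runif(1, 20, 80),
                   bitscore = round(runif(1, 100, 500), 1))
    }
    ids <- vapply(members, `[[`, "", "id")
    sps <- vapply(members, `[[`, "", "sp")
    fams <- vapply(members, `[[`, "", "fam")
    seq_mat <- do.call(rbind, lapply(members, `[[`, "seq"))
    seq_str <- apply(seq_mat, 1, function(s) paste(.BASES[s], collapse = ""))
    tx_rows[[length(tx_rows) + 1L]] <-
      data.frame(species_id = sps, transcript_id = ids,
                 sequence = seq_str, length = L)
    cl_rows[[length(cl_rows) + 1L]] <-
      data.frame(cluster_id = cid, species_id = sps, transcript_id = ids)
    families[[cid]] <- split(ids, fams)
    # intra-cluster hits via shared distinct 8-mers + positionwise identity
    m <- length(members)
    if (m >= 2) {
      ksets <- .kmer_sets(seq_str)
      allk <- unique(unlist(ksets, use.names = FALSE))
      M <- matrix(0, m, length(allk))
      for (i in seq_len(m)) M[i, match(ksets[[i]], allk)] <- 1
      shared <- tcrossprod(M)
      nk <- vapply(ksets, length, 0L)
      matches <- matrix(0, m, m)
      for (b in 1:4) {
        Ib <- (seq_mat == b) * 1
        matches <- matches + tcrossprod(Ib)
      }
      frac <- shared / outer(nk, nk, pmin)
      bits <- frac * 2 * L / 8
      # emit a hit when the shared-kmer fraction clears random background
      # (~0.01 for unrelated sequences); scale-free so short genes keep
      # their within-family and chimera half-hits
      keep <- which(frac >= 0.05 & row(bits) != col(bits))
      if (length(keep)) {
        qi <- row(bits)[keep]; si <- col(bits)[keep]
        hit_rows[[length(hit_rows) + 1L]] <-
          data.frame(qseqid = ids[qi], sseqid = ids[si],
                     pident = 100 * matches[cbind(qi, si)] / L,
                     length = round(frac[keep] * L), qlen = L, slen = L,
                     evalue = 1e3 * 2^(-bits[keep]), bitscore = bits[keep])
      }
    }
  }
  structure(list(transcripts = do.call(rbind, tx_rows),
                 clusters = do.call(rbind, cl_rows),
                 hits = do.call(rbind, hit_rows),
                 contaminant_hits = if (length(contam_rows))
                   do.call(rbind, contam_rows)
                 else data.frame(qseqid = character(), sseqid = character(),
                                 pident = numeric(), length = numeric(),
                                 qlen = numeric(), slen = numeric(),
                                 evalue = numeric(), bitscore = numeric()),
                 truth = list(tree = tree, families = families,
                              chimera_map = chim_map,
                              contaminant_ids = contam_ids),
                 config = config),
            class = "sim_clusters")
}
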