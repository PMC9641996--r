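# Synthetic-data generators: determinism, recorded-truth consistency, and
# the distributional guarantees the downstream tests rely on.

test_that("simulate_tree: smallest tree, determinism, ultrametricity", {
  cfg2 <- sim_config(seed = 5, n_species = 2)
  tr2 <- simulate_tree(cfg2)
  expect_equal(length(tr2$tip.label), 2L)
  expect_equal(tr2$Nnode, 1L)

  expect_identical(ape::write.tree(simulate_tree(cfg2)),
                   ape::write.tree(simulate_tree(cfg2)))

  cfg50 <- sim_config(seed = 11, n_species = 50, death_rate = 0)
  tr50 <- simulate_tree(cfg50)
  expect_equal(length(tr50$tip.label), 50L)
  expect_true(all(tr50$edge.length > 0))
  # direct root-to-tip path summation
  depths <- gerrophylo:::.node_depths(tr50)[1:50]
  expect_lt(max(depths) - min(depths), 1e-8 * max(depths))
})

test_that("simulate_discrete_trait: zero matrix, bookkeeping identity", {
  tr <- random_tree(8, seed = 2)
  Q0 <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  sim <- simulate_discrete_trait(tr, Q0, "b", seed = 3)
  expect_true(all(sim$tip_states == "b"))
  expect_equal(unname(sim$true_transition_count), c(0, 0))

  Q <- matrix(c(-1, 1, 1.5, -1.5), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  sim2 <- simulate_discrete_trait(tr, Q, "a", seed = 9)
  # recorded transition count equals change points in the emitted history
  changes <- matrix(0, 2, 2)
  for (h in sim2$histories) {
    if (length(h$states) > 1) {
      from <- h$states[-length(h$states)]; to <- h$states[-1]
      for (i in seq_along(from))
        changes[from[i], to[i]] <- changes[from[i], to[i]] + 1
    }
  }
  expect_equal(unname(sim2$transition_counts), changes)
  expect_equal(unname(sim2$true_transition_count), colSums(changes))
  # per-branch durations sum to branch lengths
  po_el <- gerrophylo:::.postorder(tr)$el
  sums <- vapply(sim2$histories, function(h) sum(h$durations), 0)
  expect_equal(sums, po_el, tolerance = 1e-12)
})

test_that("simulate_discrete_trait: 2-state flip probability matches closed form", {
  # single branch of length t inside a 2-tip tree; P(end != start) = (1-e^{-2qt})/2
  tr <- ape::read.tree(text = "(a:0.7,b:0.7);")
  q <- 0.9; t <- 0.7
  Q <- matrix(c(-q, q, q, -q), 2, 2, dimnames = list(c("0", "1"), c("0", "1")))
  nrep <- 10000
  flips <- vapply(seq_len(nrep), function(s)
    simulate_discrete_trait(tr, Q, "0", seed = s)$tip_states[["a"]] != "0",
    TRUE)
  p_true <- (1 - exp(-2 * q * t)) / 2
  se <- sqrt(p_true * (1 - p_true) / nrep)
  expect_lt(abs(mean(flips) - p_true), 3 * se)
})

test_that("simulate_continuous_trait covariance matches the analytic matrix", {
  tr <- random_tree(5, seed = 4)
  C <- ape::vcv.phylo(tr)
  sigma2 <- 0.8
  nrep <- 5000
  X <- t(vapply(seq_len(nrep), function(s)
    simulate_continuous_trait(tr, sigma2, 1, 0, seed = s)$tip_values[
      rownames(C)], numeric(5)))
  emp <- cov(X)
  # entrywise 3 SE of a normal-sample covariance estimate
  for (i in 1:5) for (j in 1:5) {
    truth <- sigma2 * C[i, j]
    se <- sqrt((sigma2^2 * (C[i, j]^2 + C[i, i] * C[j, j])) / nrep)
    expect_lt(abs(emp[i, j] - truth), 3 * se + 1e-12)
  }
  # lambda = 0: tips i.i.d., off-diagonal covariances ~ 0
  X0 <- t(vapply(seq_len(nrep), function(s)
    simulate_continuous_trait(tr, sigma2, 0, 0, seed = s)$tip_values[
      rownames(C)], numeric(5)))
  emp0 <- cov(X0)
  offd <- abs(emp0[upper.tri(emp0)])
  ses <- sqrt(sigma2^2 * outer(diag(C), diag(C)))[upper.tri(C)] / sqrt(nrep)
  expect_true(all(offd < 3 * ses))
  # sigma2 -> 0 limit: all tips at the root value
  tiny <- simulate_continuous_trait(tr, 1e-12, 1, 2.5, seed = 1)
  expect_equal(unname(tiny$tip_values), rep(2.5, 5), tolerance = 1e-4)
})

test_that("simulate_ortholog_clusters: construction guarantees", {
  cfg <- sim_config(seed = 21, n_species = 8, n_clusters = 5,
                    isoforms_per_species = 1, p_paralog = 0,
                    p_chimera = 0, p_contaminant = 0,
                    gene_length_codons = 60)
  sim <- simulate_ortholog_clusters(cfg)
  # exactly one transcript per sampled species per cluster
  per <- table(sim$clusters$cluster_id, sim$clusters$species_id)
  expect_true(all(per %in% c(0L, 1L)))
  agg <- aggregate(transcript_id ~ cluster_id + species_id,
                   sim$clusters, length)
  expect_true(all(agg$transcript_id == 1L))
  # determinism: identical config => identical outputs
  sim2 <- simulate_ortholog_clusters(cfg)
  expect_identical(sim$transcripts, sim2$transcripts)
  expect_identical(sim$hits, sim2$hits)

  # e-value ordering is the reverse of score ordering per query
  for (q in unique(sim$hits$qseqid)[1:5]) {
    h <- sim$hits[sim$hits$qseqid == q, ]
    expect_equal(order(h$evalue), order(-h$bitscore))
  }

  # planted chimera appears in hits of both parent families
  cfgc <- sim_config(seed = 22, n_species = 8, n_clusters = 4,
                     isoforms_per_species = 1, p_paralog = 0,
                     p_chimera = 1, p_contaminant = 0,
                     gene_length_codons = 60)
  simc <- simulate_ortholog_clusters(cfgc)
  expect_gt(length(simc$truth$chimera_map), 0)
  ch <- names(simc$truth$chimera_map)[1]
  info <- simc$truth$chimera_map[[1]]
  fam <- simc$truth$families[[info$cluster_id]]
  partners <- unique(c(simc$hits$sseqid[simc$hits$qseqid == ch],
                       simc$hits$qseqid[simc$hits$sseqid == ch]))
  expect_gt(length(intersect(partners, fam$A)), 0)
  expect_gt(length(intersect(partners, fam$B)), 0)
  # breakpoint strictly inside the sequence
  L <- 3 * cfgc$gene_length_codons
  expect_true(info$breakpoint > 0 && info$breakpoint < L)
  # chimera error path
  expect_error(simulate_ortholog_clusters(
    sim_config(seed = 1, n_clusters = 1, p_chimera = 0.5)),
    "2 gene families")
})

test_that("simulate_codon_alignment: block coordinates and stationarity", {
  tr <- simulate_tree(sim_config(seed = 3, n_species = 6))
  ca <- simulate_codon_alignment(tr, 80, "none", seed = 5)
  expect_equal(ncol(ca$alignment), 240)
  expect_true(all(ca$blocks$start >= 1 & ca$blocks$end <= 240))
  expect_true(all((ca$blocks$start - 1) %% 3 == 0 |
                    ca$blocks$start %% 3 == 1))
  expect_identical(ca$alignment,
                   simulate_codon_alignment(tr, 80, "none", seed = 5)$alignment)
})

test_that("clade shift at position 3 fails SRH there but not at 1+2", {
  tr <- simulate_tree(sim_config(seed = 8, n_species = 6))
  nrep <- 50
  res <- vapply(seq_len(nrep), function(s) {
    ca <- simulate_codon_alignment(tr, 120, "clade_shift", seed = s,
                                   shift_positions = 3L)
    c(p12 = srh_filter_cluster(ca$alignment, positions = c(1, 2),
                               correction = "bonferroni")$verdict == "pass",
      f3 = srh_filter_cluster(ca$alignment, positions = 3,
                              correction = "bonferroni")$verdict == "fail")
  }, c(TRUE, TRUE))
  expect_gte(mean(res["p12", ]), 0.9)
  expect_gte(mean(res["f3", ]), 0.9)
})
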