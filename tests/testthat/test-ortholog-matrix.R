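# Contaminant flagging, redundancy reduction, coverage filtering,
# cumulative scores, chimera splitting and representative selection.

test_that("flag_contaminants applies the general and cricket rules", {
  h <- rbind(hit_row("t1", "db1", pident = 95, length = 30, qlen = 100),
             hit_row("t2", "db1", pident = 90.0, length = 90, qlen = 100),
             hit_row("t3", "db1", pident = 99, length = 20, qlen = 100),
             hit_row("t4", "db1", pident = 92, length = 10, qlen = 100))
  # coverage 30 > 25 and 95 > 90 -> flagged; 90.0 exactly -> not (strict >);
  # coverage 20 <= 25 -> not; t4 has coverage 10 -> general drops it but
  # the cricket rule (identity >= 90, no coverage floor) flags it
  expect_setequal(flag_contaminants(h, "general"), "t1")
  expect_false("t2" %in% flag_contaminants(h, "general"))
  expect_false("t3" %in% flag_contaminants(h, "general"))
  expect_setequal(flag_contaminants(h, "cricket"), c("t1", "t2", "t3", "t4"))
  hbad <- h; hbad$qlen[2] <- 0
  expect_error(flag_contaminants(hbad, "general"), "qlen")
})

test_that("reduce_redundancy is greedy, longest-first, deterministic", {
  s <- paste(rep("ACGT", 150), collapse = "")   # 600 nt
  recs <- data.frame(transcript_id = c("b", "a"), sequence = c(s, s))
  kept <- reduce_redundancy(recs)
  expect_equal(kept$transcript_id, "a")         # lexicographically smaller id

  mut <- function(s, n, seed) {                 # mutate n positions
    set.seed(seed); v <- strsplit(s, "")[[1]]
    i <- sample(length(v), n)
    v[i] <- ifelse(v[i] == "A", "C", "A")       # guaranteed change
    paste(v, collapse = "")
  }
  far <- mut(s, 60, 1)                          # 90% identity
  expect_equal(nrow(reduce_redundancy(
    data.frame(transcript_id = c("a", "b"), sequence = c(s, far)))), 2L)
  near <- mut(s, 2, 2)                          # ~99.7% identity
  expect_equal(nrow(reduce_redundancy(
    data.frame(transcript_id = c("a", "b"), sequence = c(s, near)))), 1L)
})

test_that("coverage filter boundary arithmetic and monotonicity", {
  mk <- function(nsp, cid = "c1")
    data.frame(cluster_id = cid, species_id = sprintf("s%03d", seq_len(nsp)),
               transcript_id = sprintf("s%03d_t", seq_len(nsp)))
  expect_equal(nrow(filter_clusters_by_coverage(mk(84), 104)$clusters), 84L)
  expect_equal(nrow(filter_clusters_by_coverage(mk(83), 104)$clusters), 0L)
  expect_equal(nrow(filter_clusters_by_coverage(mk(8), 10)$clusters), 8L)
  # monotone: adding a species to a retained cluster never drops it
  set.seed(3)
  for (i in 1:20) {
    n <- sample(5:30, 1); tot <- sample(n:40, 1)
    cl <- mk(n)
    kept <- nrow(filter_clusters_by_coverage(cl, tot)$clusters) > 0
    if (kept) {
      cl2 <- rbind(cl, data.frame(cluster_id = "c1", species_id = "extra",
                                  transcript_id = "extra_t"))
      expect_gt(nrow(filter_clusters_by_coverage(cl2, tot)$clusters), 0)
    }
  }
})

test_that("cumulative_scores sums per-species best bitscores", {
  mem <- data.frame(species_id = c("s1", "s2", "s2", "s3"),
                    transcript_id = c("t", "u1", "u2", "v"))
  h <- rbind(hit_row("t", "u1", bitscore = 50),
             hit_row("t", "u2", bitscore = 70),
             hit_row("t", "v", bitscore = 40))
  sc <- cumulative_scores(mem, h)
  expect_equal(sc[["t"]], 110)                  # max(50,70) + 40
  expect_equal(sc[["v"]], 0)                    # no outgoing hits
  # adding a weaker second hit to an already-hit species changes nothing
  h2 <- rbind(h, hit_row("t", "u1", bitscore = 10))
  expect_equal(cumulative_scores(mem, h2)[["t"]], 110)
})

test_that("split_chimeric_cluster: seeds, components, determinism", {
  mem2 <- data.frame(species_id = c("s1", "s2"),
                     transcript_id = c("hi", "lo"))
  h2 <- hit_row("hi", "lo", bitscore = 80)
  d2 <- split_chimeric_cluster(mem2, h2)
  expect_setequal(c(d2$longest_list, d2$other_list), c("hi", "lo"))
  expect_equal(length(intersect(d2$longest_list, d2$other_list)), 0L)

  # two connected components are exactly recovered in round 1
  memc <- data.frame(
    species_id = c("s1", "s2", "s3", "s1", "s2"),
    transcript_id = c("a1", "a2", "a3", "b1", "b2"))
  hc <- rbind(hit_row("a1", "a2", bitscore = 90), hit_row("a2", "a1", bitscore = 90),
              hit_row("a1", "a3", bitscore = 85), hit_row("a3", "a1", bitscore = 85),
              hit_row("a2", "a3", bitscore = 88), hit_row("a3", "a2", bitscore = 88),
              hit_row("b1", "b2", bitscore = 60), hit_row("b2", "b1", bitscore = 60))
  d <- split_chimeric_cluster(memc, hc, rounds = 1)
  expect_setequal(d$longest_list, c("a1", "a2", "a3"))
  expect_setequal(d$other_list, c("b1", "b2"))
  # bipartition property + determinism
  d_again <- split_chimeric_cluster(memc, hc, rounds = 1)
  expect_identical(d, d_again)
  # size < 2 returned unchanged
  one <- split_chimeric_cluster(memc[1, ], hc)
  expect_equal(one$longest_list, "a1")
})

test_that("split is a bipartition on random synthetic clusters", {
  cfg <- sim_config(seed = 31, n_species = 8, n_clusters = 6,
                    isoforms_per_species = 2, p_chimera = 0.5,
                    gene_length_codons = 60)
  sim <- simulate_ortholog_clusters(cfg)
  for (cid in unique(sim$clusters$cluster_id)) {
    mem <- sim$clusters[sim$clusters$cluster_id == cid, ]
    d <- split_chimeric_cluster(mem, sim$hits)
    expect_setequal(c(d$longest_list, d$other_list), mem$transcript_id)
    expect_length(intersect(d$longest_list, d$other_list), 0)
  }
})

test_that("select_representatives: identity map, isoform choice, coverage", {
  # coherent one-per-species cluster -> identity mapping
  mem <- data.frame(species_id = c("s1", "s2", "s3"),
                    transcript_id = c("x1", "x2", "x3"))
  h <- rbind(hit_row("x1", "x2", bitscore = 50), hit_row("x2", "x1", bitscore = 50),
             hit_row("x1", "x3", bitscore = 45), hit_row("x3", "x1", bitscore = 45),
             hit_row("x2", "x3", bitscore = 48), hit_row("x3", "x2", bitscore = 48))
  reps <- select_representatives(mem, h)
  expect_equal(reps[c("s1", "s2", "s3")], c(s1 = "x1", s2 = "x2", s3 = "x3"))

  # species with 3 isoforms: the max-cumulative-score isoform wins
  mem3 <- data.frame(species_id = c("s1", "s1", "s1", "s2", "s3"),
                     transcript_id = c("i1", "i2", "i3", "y2", "y3"))
  h3 <- rbind(hit_row("i1", "y2", bitscore = 40), hit_row("i1", "y3", bitscore = 40),
              hit_row("i2", "y2", bitscore = 70), hit_row("i2", "y3", bitscore = 65),
              hit_row("i3", "y2", bitscore = 55),
              hit_row("y2", "i2", bitscore = 70), hit_row("y3", "i2", bitscore = 65),
              hit_row("y2", "y3", bitscore = 80), hit_row("y3", "y2", bitscore = 80))
  reps3 <- select_representatives(mem3, h3)
  expect_equal(reps3[["s1"]], "i2")             # cumulative 135 beats 80 and 55
  expect_length(reps3, 3L)

  # on synthetic runs: <= 1 transcript per species, every species covered
  cfg <- sim_config(seed = 41, n_species = 10, n_clusters = 8,
                    gene_length_codons = 60)
  sim <- simulate_ortholog_clusters(cfg)
  for (cid in unique(sim$clusters$cluster_id)) {
    mem <- sim$clusters[sim$clusters$cluster_id == cid, ]
    reps <- select_representatives(mem, sim$hits)
    expect_equal(anyDuplicated(names(reps)), 0L)
    expect_setequal(names(reps), unique(mem$species_id))
    expect_true(all(reps %in% mem$transcript_id))
  }
})
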