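# Stochastic maps, transition counting, Sankoff parsimony.

test_that("stochastic_map: tiny rates give constant maps, durations conserve", {
  tr <- simulate_tree(sim_config(seed = 17, n_species = 8))
  sts <- c("0", "1")
  Qtiny <- matrix(c(-1e-10, 1e-10, 1e-10, -1e-10), 2, 2,
                  dimnames = list(sts, sts))
  tips0 <- setNames(rep("0", 8), tr$tip.label)
  sm <- stochastic_map(tr, discrete_trait(tips0, sts), Qtiny, nsim = 25,
                       seed = 4)
  for (m in sm$maps) {
    expect_true(all(m$node_states == 1L))
    expect_true(all(vapply(m$histories, function(h) length(h$states) == 1L,
                           TRUE)))
  }
  expect_equal(sum(sm$transition_counts), 0)
  # per-branch duration conservation on a non-trivial map set
  Q <- matrix(c(-0.8, 0.8, 0.8, -0.8), 2, 2, dimnames = list(sts, sts))
  sim <- simulate_discrete_trait(tr, Q, "0", seed = 5)
  sm2 <- stochastic_map(tr, discrete_trait(sim$tip_states, sts), Q,
                        nsim = 50, seed = 6)
  for (m in sm2$maps) {
    sums <- vapply(m$histories, function(h) sum(h$durations), 0)
    expect_true(all(abs(sums - sm2$edge.length) < 1e-12))
    # tip segment states equal observed tip states
    for (e in seq_len(nrow(sm2$edge))) {
      ch <- sm2$edge[e, 2]
      if (ch <= 8) {
        h <- m$histories[[e]]
        expect_equal(sm2$states[h$states[length(h$states)]],
                     unname(sim$tip_states[sm2$tree$tip.label[ch]]))
      }
    }
    # adjacent segments always differ in state
    for (h in m$histories)
      if (length(h$states) > 1)
        expect_true(all(h$states[-1] != h$states[-length(h$states)]))
  }
})

test_that("map node frequencies approach marginals; seeds reproduce", {
  tr <- simulate_tree(sim_config(seed = 23, n_species = 10))
  sts <- c("0", "1")
  Q <- matrix(c(-0.6, 0.6, 0.6, -0.6), 2, 2, dimnames = list(sts, sts))
  sim <- simulate_discrete_trait(tr, Q, "0", seed = 3)
  dt <- discrete_trait(sim$tip_states, sts)
  sm <- stochastic_map(tr, dt, Q, nsim = 600, seed = 9)
  marg <- marginal_ancestrals(tr, dt, Q)
  expect_lt(max(abs(sm$node_freq - marg)), 0.07)  # coarse at nsim = 600
  sm_b <- stochastic_map(tr, dt, Q, nsim = 600, seed = 9)
  expect_identical(sm$maps, sm_b$maps)
})

test_that("count_transitions: exact history and truth identity", {
  tr <- simulate_tree(sim_config(seed = 29, n_species = 15))
  sts <- c("fresh", "saline")
  Q <- matrix(c(-0.25, 0.25, 0.05, -0.05), 2, 2, byrow = TRUE,
              dimnames = list(sts, sts))
  sim <- simulate_discrete_trait(tr, Q, "fresh", seed = 12)
  ct <- count_transitions(sim, "saline")
  expect_equal(ct$n_origins, unname(sim$true_transition_count["saline"]))
  expect_equal(ct$n_reversals, unname(sim$transition_counts["saline", "fresh"]))
  expect_error(count_transitions(sim, "brackish"), "state space")

  # hand-built single-change history
  h1 <- list(states = list(
    list(states = c(1L, 2L), durations = c(0.3, 0.2)),
    list(states = 2L, durations = 0.5)))
  one <- list(histories = h1$states, states = c("0", "1"))
  ct1 <- count_transitions(one, "1")
  expect_equal(ct1$n_origins, 1L)
  expect_equal(ct1$n_reversals, 0L)
})

test_that("sankoff_parsimony: exact cases and cost schemes", {
  sts2 <- c("0", "1")
  # all tips identical -> zero cost, every node set {state}
  tr <- random_tree(6, seed = 41)
  same <- setNames(rep("1", 6), tr$tip.label)
  sp0 <- sankoff_parsimony(tr, discrete_trait(same, sts2), "all_equal")
  expect_equal(sp0$total_cost, 0)
  expect_true(all(vapply(sp0$node_sets, identical, TRUE, "1")))

  # balanced 4-tip tree with sister pairs (0,0),(1,1): one change
  bt <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  sp1 <- sankoff_parsimony(bt, discrete_trait(
    c(a = "0", b = "0", c = "1", d = "1"), sts2), "all_equal")
  expect_equal(sp1$total_cost, 1)

  # ordered 3 states, exponential costs: two steps (cost 2) beat one jump (3)
  expect_equal(parsimony_costs(3, "exponential"),
               matrix(c(0, 1, 3, 1, 0, 1, 3, 1, 0), 3, 3))
  tr3 <- ape::read.tree(text = "((a:1,b:1):1,c:1);")
  sts3 <- c("0", "1", "2")
  spE <- sankoff_parsimony(tr3, discrete_trait(
    c(a = "0", b = "2", c = "0"), sts3), "exponential")
  o <- oracle_sankoff(tr3, c(a = "0", b = "2", c = "0"), sts3,
                      parsimony_costs(3, "exponential"))
  expect_equal(spE$total_cost, o$cost)
  got <- lapply(spE$node_sets[4:5], function(s) sort(match(s, sts3)))
  expect_identical(unname(got), o$sets)

  # missing tips are all-states-possible
  spNA <- sankoff_parsimony(bt, discrete_trait(
    c(a = "0", b = NA, c = "1", d = "1"), states = sts2), "all_equal")
  expect_equal(spNA$total_cost, 1)
})

test_that("sankoff equals the exhaustive oracle on random trees", {
  set.seed(55)
  for (rep in 1:30) {
    n <- sample(3:6, 1); k <- sample(2:3, 1)
    tr <- random_tree(n)
    sts <- as.character(seq_len(k))
    ts <- setNames(sample(sts, n, replace = TRUE), tr$tip.label)
    for (scheme in c("all_equal", "exponential")) {
      sp <- sankoff_parsimony(tr, discrete_trait(ts, sts), scheme)
      o <- oracle_sankoff(tr, ts, sts, parsimony_costs(k, scheme))
      expect_equal(sp$total_cost, o$cost)
      got <- lapply((n + 1):(n + tr$Nnode), function(v)
        sort(match(sp$node_sets[[v]], sts)))
      expect_identical(got, o$sets)
    }
  }
})

test_that("parsimony cost lower-bounds stochastic-map change counts", {
  tr <- simulate_tree(sim_config(seed = 31, n_species = 12))
  sts <- c("0", "1")
  Q <- matrix(c(-0.5, 0.5, 0.5, -0.5), 2, 2, dimnames = list(sts, sts))
  sim <- simulate_discrete_trait(tr, Q, "0", seed = 7)
  dt <- discrete_trait(sim$tip_states, sts)
  fit <- fit_mk(tr, dt, "ER")
  sm <- stochastic_map(tr, dt, fit$Q, nsim = 100, seed = 2)
  pars <- sankoff_parsimony(tr, dt, "all_equal")$total_cost
  changes <- vapply(sm$per_map_transitions, sum, 0)
  expect_true(all(changes >= pars))
})
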