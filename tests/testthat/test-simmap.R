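test_that("sampled histories are endpoint-consistent and reproducible", {
  set.seed(1)
  phy <- simulate_bd_tree(0.5, 0, 15, seed = 5)$phy
  hs <- build_habitat_space(c("P1", "P2"))
  Q <- mk_Q(c(0.08, 0.1, 0.05, 0.12), hs$rate_index)
  sim <- simulate_mk_tips(phy, Q, hs$space, "epigean", seed = 6)
  prior <- root_prior(hs$space, "fixed", "epigean")
  maps <- simmap_sample(phy, sim$tip_states, Q, hs$space, prior,
                        n_sims = 25, seed = 7)
  expect_length(maps$histories, 25)
  lab <- hs$space$labels
  for (h in maps$histories) {
    # root forced epigean
    expect_equal(lab[h$node_states[16]], "epigean")
    for (r in seq_len(nrow(phy$edge))) {
      m <- h$maps[[r]]
      expect_true(all(m > 0))
      expect_equal(sum(m), phy$edge.length[r], tolerance = 1e-9)
      # first segment = parent state, last = child state
      expect_equal(names(m)[1], lab[h$node_states[phy$edge[r, 1]]])
      expect_equal(names(m)[length(m)],
                   lab[h$node_states[phy$edge[r, 2]]])
      if (length(m) > 1)
        expect_true(all(names(m)[-1] != names(m)[-length(m)]))
      child <- phy$edge[r, 2]
      if (child <= 15)
        expect_equal(lab[h$node_states[child]],
                     unname(sim$tip_states[phy$tip.label[child]]))
    }
  }
  maps2 <- simmap_sample(phy, sim$tip_states, Q, hs$space, prior,
                         n_sims = 25, seed = 7)
  expect_identical(maps, maps2)
})

test_that("dwell proportions across many maps track the marginal
          reconstruction", {
  set.seed(2)
  phy <- parse_newick("((A:1,B:1):1,C:2);")
  sp <- trait_space(c("s1", "s2"))
  Q <- mk_Q(c(0.4, 0.3), matrix(c(0L, 1L, 2L, 0L), 2, 2, byrow = TRUE))
  tips <- c(A = "s1", B = "s2", C = "s1")
  marg <- marginal_ancestral_states(phy, tips, Q, sp)
  maps <- simmap_sample(phy, tips, Q, sp, n_sims = 4000, seed = 3)
  node_freq <- rowMeans(vapply(maps$histories,
                               function(h) h$node_states[4:5] == 1L,
                               logical(2)))
  expect_equal(node_freq, unname(marg$marginals[, "s1"]),
               tolerance = 0.05)
})

test_that("colonization counting follows its definitions", {
  phy <- parse_newick("((A:1,B:1):1,C:2);")
  hs <- build_habitat_space(c("P1", "P2"))
  lab <- hs$space$labels
  idx <- function(s) match(s, lab)
  # hand-built history: epigean root; edge to internal switches to
  # subterranean P1 at its midpoint; both daughters stay subterranean P1
  edge <- phy$edge
  maps <- vector("list", nrow(edge))
  node_states <- integer(5)
  node_states[4] <- idx("epigean")
  node_states[5] <- idx("subterranean:P1")
  for (r in seq_len(nrow(edge))) {
    par <- edge[r, 1]; ch <- edge[r, 2]
    len <- phy$edge.length[r]
    if (par == 4 && ch == 5) {
      maps[[r]] <- setNames(c(len / 2, len / 2),
                            c("epigean", "subterranean:P1"))
    } else {
      st <- if (par == 5) "subterranean:P1" else "epigean"
      maps[[r]] <- setNames(len, st)
      node_states[ch] <- idx(st)
    }
  }
  node_states[1:2] <- idx("subterranean:P1")
  node_states[3] <- idx("epigean")
  hist1 <- list(node_states = node_states, maps = maps)
  fake <- structure(list(histories = list(hist1), space = hs$space,
                         phy = phy, Q = NULL, n_sims = 1),
                    class = "simmap_histories")
  cc <- count_colonizations(fake, hs$rate_index)
  expect_equal(unname(cc$counts[1, "subterranean_entries"]), 1L)
  expect_equal(unname(cc$counts[1, "interstitial_entries"]), 0L)
  expect_equal(unname(cc$counts[1, "subterranean_speciation"]), 1L)
  expect_equal(unname(cc$counts[1, "within_palaeovalley_speciation"]), 1L)
  # a masked transition trips the integrity check
  bad <- hist1
  bad$maps[[which(edge[, 1] == 4 & edge[, 2] == 5)]] <-
    setNames(c(1, 1) / 2 * phy$edge.length[1],
             c("subterranean:P2", "subterranean:P1"))
  fake$histories <- list(bad)
  expect_error(count_colonizations(fake, hs$rate_index), "masked")
})

test_that("within-palaeovalley speciation never exceeds the total and the
          event log matches the maps", {
  set.seed(4)
  phy <- simulate_bd_tree(0.5, 0, 20, seed = 9)$phy
  hs <- build_habitat_space(paste0("P", 1:3))
  Q <- mk_Q(c(0.05, 0.08, 0.06, 0.1), hs$rate_index)
  sim <- simulate_mk_tips(phy, Q, hs$space, "epigean", seed = 10)
  maps <- simmap_sample(phy, sim$tip_states, Q, hs$space,
                        root_prior(hs$space, "fixed", "epigean"),
                        n_sims = 40, seed = 11)
  cc <- count_colonizations(maps, hs$rate_index)
  expect_true(all(cc$counts[, "within_palaeovalley_speciation"] <=
                    cc$counts[, "subterranean_speciation"]))
  log <- simmap_event_log(maps)
  n_changes <- sum(vapply(maps$histories, function(h)
    sum(lengths(h$maps) - 1L), 0L))
  expect_equal(nrow(log), n_changes)
})
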