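test_that("habitat space has one epigean plus two states per palaeovalley
          and the documented mask", {
  hs <- build_habitat_space(c("P1", "P2", "P3"))
  expect_equal(hs$space$n_states, 7L)
  ri <- hs$rate_index
  expect_equal(ri["subterranean:P1", "subterranean:P2"], 0L)
  expect_gt(ri["interstitial:P1", "subterranean:P1"], 0L)
  expect_equal(ri["interstitial:P1", "subterranean:P2"], 0L)
  # irreversibility: no exits from subterranean states by default
  sub <- grep("^subterranean", hs$space$labels)
  expect_true(all(ri[sub, ] == 0L))
  # sensitivity flag restores exits
  hs2 <- build_habitat_space(c("P1", "P2"), allow_subterranean_exit = TRUE)
  expect_gt(hs2$rate_index["subterranean:P1", "epigean"], 0L)
  # colonization only via interstitial when direct transitions are off
  hs3 <- build_habitat_space(c("P1", "P2"), direct_colonization = FALSE)
  expect_equal(hs3$rate_index["epigean", "subterranean:P1"], 0L)
  expect_error(build_habitat_space(c("P1", "P1")), "duplicate")
})

test_that("altitude space is five bands under an unconstrained ARD index", {
  as5 <- build_altitude_space()
  expect_equal(as5$space$n_states, 5L)
  expect_equal(max(as5$rate_index), 20L)
  expect_true(all(diag(as5$rate_index) == 0L))
})

test_that("two-state symmetric likelihood matches the closed form", {
  # single branch t = 1, rate q = 0.5 each way:
  # P(stay) = (1 + exp(-2qt))/2 = 0.6839397206
  q <- 0.5
  sp <- trait_space(c("s1", "s2"))
  Q <- mk_Q(c(q, q), matrix(c(0L, 1L, 2L, 0L), 2, 2, byrow = TRUE))
  phy <- parse_newick("(A:0.5,B:0.5);")   # root-to-tip path = 1 tip-to-tip
  p_stay <- (1 + exp(-2 * q * 1)) / 2
  expect_equal((1 + exp(-1)) / 2, 0.6839397206, tolerance = 1e-10)
  # both tips equal under a flat prior: sum over root states
  ll <- mk_loglik(phy, c(A = "s1", B = "s1"), Q, sp)
  p05 <- (1 + exp(-2 * q * 0.5)) / 2
  expect_equal(ll, log(0.5 * (p05^2 + (1 - p05)^2)), tolerance = 1e-10)
  # frozen process with differing tips is impossible
  Q0 <- mk_Q(c(1e-8, 1e-8), matrix(c(0L, 1L, 2L, 0L), 2, 2,
                                   byrow = TRUE)) * 0
  expect_identical(mk_loglik(phy, c(A = "s1", B = "s2"), Q0, sp), -Inf)
})

test_that("pruning equals brute-force enumeration on random Mk instances", {
  set.seed(202)
  for (rep in 1:40) {
    n_tip <- sample(2:4, 1)
    ns <- sample(2:3, 1)
    phy <- random_coal_tree(n_tip)
    sp <- trait_space(paste0("s", seq_len(ns)))
    ri <- matrix(0L, ns, ns)
    ri[row(ri) != col(ri)] <- seq_len(ns * ns - ns)
    Q <- mk_Q(runif(ns * ns - ns, 0.01, 1.5), ri)
    tips <- setNames(sample(sp$labels, n_tip, TRUE), phy$tip.label)
    prior <- rep(1 / ns, ns)
    ll <- mk_loglik(phy, tips, Q, sp)
    tipL <- matrix(0, n_tip, ns)
    tipL[cbind(seq_len(n_tip), match(tips[phy$tip.label], sp$labels))] <- 1
    expect_equal(ll, oracle_mk_loglik(phy, tipL, Q, prior),
                 tolerance = 1e-8)
  }
})

test_that("marginal reconstructions match enumeration and honor a fixed
          root prior", {
  set.seed(33)
  phy <- random_coal_tree(3)
  sp <- trait_space(c("s1", "s2", "s3"))
  ri <- matrix(0L, 3, 3); ri[row(ri) != col(ri)] <- 1:6
  Q <- mk_Q(runif(6, 0.05, 1), ri)
  tips <- setNames(c("s1", "s2", "s3"), phy$tip.label)
  m <- marginal_ancestral_states(phy, tips, Q, sp)
  expect_equal(rowSums(m$marginals), c(1, 1), ignore_attr = TRUE,
               tolerance = 1e-9)
  tipL <- diag(3)[match(tips[phy$tip.label], sp$labels), ]
  om <- oracle_mk_marginals(phy, tipL, Q, rep(1 / 3, 3))
  expect_equal(unname(m$marginals), om, tolerance = 1e-8)
  mf <- marginal_ancestral_states(phy, tips, Q, sp,
                                  root_prior(sp, "fixed", "s2"))
  expect_equal(unname(mf$marginals[1, ]), c(0, 1, 0), tolerance = 1e-12)
})

test_that("relabeling states consistently leaves the likelihood
          unchanged", {
  set.seed(44)
  phy <- random_coal_tree(12)
  as5 <- build_altitude_space()
  Q <- mk_Q(runif(20, 0.01, 0.4), as5$rate_index)
  tips <- setNames(sample(as5$space$labels, 12, TRUE), phy$tip.label)
  ll <- mk_loglik(phy, tips, Q, as5$space)
  perm <- sample(5)
  sp2 <- trait_space(as5$space$labels[perm])
  Q2 <- Q[perm, perm]
  tips2 <- tips  # same data, same labels; only the space order changed
  ll2 <- mk_loglik(phy, tips2, Q2, sp2)
  expect_equal(ll, ll2, tolerance = 1e-10)
})

test_that("ARD fitting respects the mask, beats the generating
          parameters, and agrees with an independent Mk implementation", {
  skip_if_not_installed("phytools")
  set.seed(99)
  phy <- simulate_bd_tree(0.4, 0, 80, seed = 99)$phy
  sp <- trait_space(c("s1", "s2"))
  ri <- matrix(c(0L, 1L, 2L, 0L), 2, 2, byrow = TRUE)
  Qgen <- mk_Q(c(0.15, 0.08), ri)
  sim <- simulate_mk_tips(phy, Qgen, sp, "s1", seed = 100)
  fit <- fit_ard(phy, sim$tip_states, ri, sp)
  expect_true(all(fit$Q[ri == 0L & row(ri) != col(ri)] == 0))
  ll_gen <- mk_loglik(phy, sim$tip_states, Qgen, sp)
  expect_gte(fit$lnL, ll_gen - 1e-6)
  # independent implementation at the fitted Q (flat root prior)
  x <- factor(sim$tip_states[phy$tip.label], levels = sp$labels)
  names(x) <- phy$tip.label
  fm <- phytools::fitMk(phy, x, fixedQ = fit$Q, pi = "equal")
  expect_equal(fit$lnL, as.numeric(fm$logLik), tolerance = 1e-6)
})

test_that("tip ambiguity spreads likelihood over the listed states", {
  phy <- parse_newick("(A:1,B:1);")
  sp <- trait_space(c("s1", "s2"))
  Q <- mk_Q(c(0.3, 0.3), matrix(c(0L, 1L, 2L, 0L), 2, 2, byrow = TRUE))
  ll_amb <- mk_loglik(phy, c(A = "s1|s2", B = "s1"), Q, sp)
  l1 <- exp(mk_loglik(phy, c(A = "s1", B = "s1"), Q, sp))
  l2 <- exp(mk_loglik(phy, c(A = "s2", B = "s1"), Q, sp))
  expect_equal(exp(ll_amb), l1 + l2, tolerance = 1e-12)
})
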