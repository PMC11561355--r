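test_that("birth-death trees are ultrametric, right-sized and
          seed-reproducible", {
  sim <- simulate_bd_tree(1, 0, 50, seed = 123)
  expect_length(sim$phy$tip.label, 50)
  expect_silent(validate_timetree(sim$phy))
  sim2 <- simulate_bd_tree(1, 0, 50, seed = 123)
  expect_identical(write_newick(sim$phy), write_newick(sim2$phy))
  simd <- simulate_bd_tree(0.6, 0.25, 40, seed = 7)
  expect_length(simd$phy$tip.label, 40)
  expect_silent(validate_timetree(simd$phy))
  resc <- simulate_bd_tree(0.6, 0.25, 40, seed = 7, root_age = 17)
  expect_equal(root_age(resc$phy), 17, tolerance = 1e-9)
  expect_error(simulate_bd_tree(0.1, 0.2, 10), "birth_rate > death_rate")
})

test_that("pure-birth crown ages match the Yule expectation", {
  n <- 40; lam <- 1
  expected <- sum(1 / (lam * (2:n)))
  set.seed(77)
  ages <- vapply(1:300, function(i)
    root_age(simulate_bd_tree(lam, 0, n)$phy), 0)
  se <- stats::sd(ages) / sqrt(length(ages))
  expect_lt(abs(mean(ages) - expected), 3 * se)
})

test_that("DEC tip simulation respects frozen processes and stratum
          closures", {
  phy <- simulate_bd_tree(0.5, 0, 20, seed = 31)$phy
  disp <- stratified_dispersal(areas = LETTERS[1:3])
  sim0 <- simulate_dec_tips(phy, dec_params(0, 0, 0), disp,
                            root_range = "A", seed = 32)
  expect_true(all(sim0$tip_ranges == "A"))
  # area C closed in the old stratum: no event may introduce C there
  phy2 <- rescale_tree_age(phy, 30)
  m_open <- matrix(1, 3, 3); m_closed <- m_open
  m_closed[, 3] <- 0; m_closed[3, ] <- 0; m_closed[3, 3] <- 1
  disp2 <- stratified_dispersal(list(m_closed, m_open),
                                stratification(23), LETTERS[1:3])
  boundary_hits <- 0L
  for (s in 1:10) {
    sim <- simulate_dec_tips(phy2, dec_params(0.08, 0.01, 0.2), disp2,
                             root_range = "A", seed = 100 + s)
    for (ev in sim$truth$events) {
      if (is.null(ev)) next
      gains_C <- grepl("C", ev$to) & !grepl("C", ev$from)
      expect_true(all(!(gains_C & ev$age > 23)))
      if (any(ev$age > 23)) boundary_hits <- boundary_hits + 1L
    }
  }
  expect_gt(boundary_hits, 0)   # the old stratum was actually exercised
})

test_that("same seed reproduces DEC and Mk simulations exactly", {
  phy <- simulate_bd_tree(0.5, 0, 15, seed = 41)$phy
  disp <- stratified_dispersal(areas = LETTERS[1:3])
  a <- simulate_dec_tips(phy, dec_params(0.05, 0.02, 0.3), disp,
                         root_range = "B", seed = 42)
  b <- simulate_dec_tips(phy, dec_params(0.05, 0.02, 0.3), disp,
                         root_range = "B", seed = 42)
  expect_identical(a$tip_ranges, b$tip_ranges)
  expect_identical(a$truth$events, b$truth$events)
  hs <- build_habitat_space(c("P1", "P2"))
  Q <- mk_Q(c(0.1, 0.1, 0.05, 0.1), hs$rate_index)
  m1 <- simulate_mk_tips(phy, Q, hs$space, "epigean", seed = 43)
  m2 <- simulate_mk_tips(phy, Q, hs$space, "epigean", seed = 43)
  expect_identical(m1, m2)
})

test_that("Mk simulation truth never contains masked transitions and its
          empirical rates approach the generating rates", {
  set.seed(51)
  phy <- simulate_bd_tree(0.5, 0, 60, seed = 51)$phy
  hs <- build_habitat_space(paste0("P", 1:3))
  rates <- c(0.08, 0.12, 0.04, 0.15)
  Q <- mk_Q(rates, hs$rate_index)
  lab <- hs$space$labels
  n_event <- 0; dwell_epi <- 0; epi_to_int <- 0
  for (s in 1:50) {
    sim <- simulate_mk_tips(phy, Q, hs$space, "epigean", seed = 500 + s)
    for (ev in sim$truth$events) {
      if (is.null(ev)) next
      fi <- match(ev$from, lab); ti <- match(ev$to, lab)
      expect_true(all(hs$rate_index[cbind(fi, ti)] > 0L))
      n_event <- n_event + nrow(ev)
      epi_to_int <- epi_to_int +
        sum(ev$from == "epigean" & grepl("^interstitial", ev$to))
    }
    dwell_epi <- dwell_epi + sim$truth$dwell[["epigean"]]
  }
  expect_gt(n_event, 0)
  # empirical epigean -> interstitial rate (3 target valleys, rate 1 each)
  emp <- epi_to_int / dwell_epi / 3
  expect_gt(emp, rates[1] / 2)
  expect_lt(emp, rates[1] * 2)
})

test_that("coding-alignment fixtures contain exactly the planned lesions", {
  plan <- data.frame(seq = c("seq2", "seq3", "seq3"),
                     kind = c("premature_stop", "premature_stop",
                              "frameshift"),
                     codon = c(10, 10, 25), detail = c(NA, NA, 2))
  sim <- simulate_coding_alignment(4, 60, plan, seed = 9)
  stops <- detect_premature_stops(sim$aln)
  fs <- detect_frameshifts(sim$aln)
  expect_equal(nrow(stops), 2L)
  expect_equal(sort(stops$seq), c("seq2", "seq3"))
  expect_true(all(stops$codon == 10))
  expect_equal(nrow(fs), 1L)
  expect_equal(fs$seq, "seq3")
  expect_equal(fs$detail, "2")
  sh <- shared_deleterious(rbind(stops, fs), list(c("seq2", "seq3")))
  expect_equal(sh$reports[[1]]$n_shared, 1L)
  # clean fixture yields zero calls
  clean <- simulate_coding_alignment(5, 40, NULL, seed = 10)
  expect_equal(nrow(scan_pseudogenes(clean$aln)), 0L)
  # terminal-codon stop plans are rejected
  expect_error(simulate_coding_alignment(
    2, 20, data.frame(seq = "seq2", kind = "premature_stop", codon = 20),
    seed = 1), "terminal")
})
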