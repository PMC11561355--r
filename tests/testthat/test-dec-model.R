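test_that("anagenetic Q matches its definition on two areas", {
  st <- range_states(c("A", "B"), 2)
  Q <- build_anagenetic_Q(dec_params(0.1, 0.05), st)
  expect_equal(Q["A", "AB"], 0.1)
  expect_equal(Q["A", "0"], 0.05)
  expect_equal(Q["AB", "A"], 0.05)
  expect_equal(Q["AB", "B"], 0.05)
  expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-12)
  expect_true(all(Q["0", ] == 0))   # null range absorbing
  # forbidden sink
  m <- matrix(1, 2, 2); m[1, 2] <- 0
  Q2 <- build_anagenetic_Q(dec_params(0.1, 0.05), st, m)
  expect_equal(Q2["A", "AB"], 0)
  # frozen process
  expect_equal(max(abs(build_anagenetic_Q(dec_params(0, 0), st))), 0)
})

test_that("Q rows sum to zero with nonnegative off-diagonals, any w", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    st <- range_states(LETTERS[1:n], sample(seq_len(n), 1))
    m <- matrix(runif(n * n), n, n)
    m[sample(length(m), n)] <- 0
    p <- dec_params(runif(1, 0, 2), runif(1, 0, 2), 0, runif(1, 0, 5))
    Q <- build_anagenetic_Q(p, st, m)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    offd <- Q; diag(offd) <- 0
    expect_true(all(offd >= 0))
  }
})

test_that("w softens interior multipliers but never unforbids zeros", {
  st <- range_states(c("A", "B"), 2)
  m <- matrix(c(1, 0.3, 0, 1), 2, 2, byrow = TRUE)
  p1 <- dec_params(0.2, 0.1, 0, 1)
  Q1 <- build_anagenetic_Q(p1, st, m)
  expect_equal(build_anagenetic_Q(dec_params(0.2, 0.1, 0, 1), st, m), Q1)
  for (w in c(0, 0.5, 3)) {
    Qw <- build_anagenetic_Q(dec_params(0.2, 0.1, 0, w), st, m)
    expect_equal(Qw["B", "AB"], 0)          # zero stays zero for every w
    expect_equal(Qw["A", "AB"], 0.2 * 0.3^w)
  }
})

test_that("cladogenesis distributions match hand enumeration", {
  st <- range_states(c("A", "B"), 2)
  d0 <- cladogenesis_distribution("A", st, "DEC", dec_params(0.1, 0.1, 0))
  expect_equal(nrow(d0), 1L)
  expect_equal(st$labels[d0$left], "A")
  expect_equal(d0$prob, 1)
  # widespread DEC ancestor: six equiprobable outcomes
  dAB <- cladogenesis_distribution("AB", st, "DEC", dec_params(0.1, 0.1, 0))
  expect_equal(nrow(dAB), 6L)
  expect_equal(dAB$prob, rep(1 / 6, 6))
  keys <- sort(paste(st$labels[dAB$left], st$labels[dAB$right]))
  expect_equal(keys, sort(c("A B", "B A", "AB A", "A AB", "AB B", "B AB")))
  # founder event: P(sympatry) = 1/(1+j), jump mass j/(1+j) split by order
  dj <- cladogenesis_distribution("A", st, "DEC",
                                  dec_params(0.1, 0.1, 0.5))
  sym <- dj$left == 2 & dj$right == 2
  expect_equal(sum(dj$prob[sym]), 2 / 3, tolerance = 1e-12)
  expect_equal(sum(dj$prob[!sym]), 1 / 3, tolerance = 1e-12)
  expect_error(cladogenesis_distribution("0", st, "DEC"), "null range")
})

test_that("cladogenesis distributions sum to one for every family", {
  set.seed(5)
  st <- range_states(LETTERS[1:4], 4)
  m <- matrix(runif(16, 0.1, 1), 4, 4)
  for (fam in c("DEC", "DIVALIKE", "BAYAREALIKE"))
    for (s in 2:st$n_states) {
      tab <- cladogenesis_distribution(s, st, fam,
                                       dec_params(0.1, 0.1, 0.7), m)
      expect_equal(sum(tab$prob), 1, tolerance = 1e-12)
    }
})

test_that("family structure: DIVALIKE and BAYAREALIKE outcome sets", {
  st <- range_states(LETTERS[1:3], 3)
  dv <- cladogenesis_distribution("ABC", st, "DIVALIKE",
                                  dec_params(0.1, 0.1, 0))
  # every ordered nonempty bipartition of {A,B,C}: 2^3 - 2 = 6
  expect_equal(nrow(dv), 6L)
  expect_false(any(dv$left == dv$right))
  ba <- cladogenesis_distribution("ABC", st, "BAYAREALIKE",
                                  dec_params(0.1, 0.1, 0))
  expect_equal(nrow(ba), 1L)
  expect_equal(st$labels[ba$left], "ABC")
  expect_equal(st$labels[ba$right], "ABC")
})

test_that("two-tip likelihood equals direct summation, and the frozen
          process is impossible", {
  disp <- stratified_dispersal(areas = c("A", "B"))
  phy <- parse_newick("(A:1,B:1);")
  g <- geography(c(A = "A", B = "A"), areas = c("A", "B"))
  ll <- dec_loglik(phy, g, dec_params(0.1, 0.05), disp)
  expect_equal(ll, -1.3909029976, tolerance = 1e-9)
  g2 <- geography(c(A = "A", B = "B"), areas = c("A", "B"))
  expect_identical(dec_loglik(phy, g2, dec_params(0, 0), disp), -Inf)
})

test_that("pruning equals brute-force enumeration on random instances", {
  set.seed(101)
  reps <- 60
  worst <- 0
  for (rep in seq_len(reps)) {
    n_tip <- sample(2:4, 1)
    n_areas <- sample(2:3, 1)
    phy <- random_coal_tree(n_tip)
    st <- range_states(LETTERS[1:n_areas], n_areas)
    disp <- stratified_dispersal(areas = LETTERS[1:n_areas])
    p <- dec_params(runif(1, 0.01, 0.6), runif(1, 0.01, 0.4),
                    sample(c(0, runif(1, 0, 1.5)), 1))
    tip_idx <- sample(2:st$n_states, n_tip, replace = TRUE)
    gm <- st$bits[tip_idx, , drop = FALSE] * 1L
    rownames(gm) <- phy$tip.label
    g <- geography(gm)
    ll <- dec_loglik(phy, g, p, disp)
    Q <- build_anagenetic_Q(p, st)
    oracle <- oracle_dec_loglik(phy, tip_idx, st, Q,
                                oracle_clado_dec(st, p$j))
    expect_equal(ll, oracle, tolerance = 1e-8)
    if (is.finite(ll)) worst <- max(worst, abs(ll - oracle))
  }
  expect_lt(worst, 1e-8)
})

test_that("stratified likelihood with identical matrices per stratum
          equals the unstratified one", {
  set.seed(21)
  phy <- random_coal_tree(8)
  areas <- LETTERS[1:3]
  m <- matrix(runif(9, 0.2, 1), 3, 3)
  p <- dec_params(0.15, 0.05, 0.4)
  g <- geography(setNames(sample(c("A", "B", "C", "AB"), 8, TRUE),
                          phy$tip.label), areas = areas)
  one <- stratified_dispersal(list(m), areas = areas)
  ra <- root_age(phy)
  three <- stratified_dispersal(list(m, m, m),
                                stratification(c(ra * 0.6, ra * 0.25)),
                                areas = areas)
  expect_equal(dec_loglik(phy, g, p, one), dec_loglik(phy, g, p, three),
               tolerance = 1e-10)
})

test_that("w = 1 leaves the likelihood unchanged and j = 0 nests DEC", {
  set.seed(31)
  phy <- random_coal_tree(6)
  areas <- LETTERS[1:3]
  m <- matrix(runif(9, 0.1, 0.9), 3, 3); diag(m) <- 1
  disp <- stratified_dispersal(list(m), areas = areas)
  g <- geography(setNames(sample(c("A", "B", "C"), 6, TRUE),
                          phy$tip.label), areas = areas)
  llw <- dec_loglik(phy, g, dec_params(0.2, 0.1, 0, 1), disp)
  ll <- dec_loglik(phy, g, dec_params(0.2, 0.1, 0), disp)
  expect_equal(llw, ll, tolerance = 1e-12)
})

test_that("ancestral marginals normalize, respect symmetry, and match
          enumeration on three tips", {
  disp <- stratified_dispersal(areas = c("A", "B"))
  phy <- parse_newick("(A:1,B:1);")
  g <- geography(c(A = "A", B = "B"), areas = c("A", "B"))
  m <- ancestral_range_marginals(phy, g, dec_params(0.1, 0.1, 0), disp)
  expect_equal(rowSums(m$marginals), 1, ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(unname(m$marginals[1, "A"]), unname(m$marginals[1, "B"]),
               tolerance = 1e-12)   # symmetric problem
  # 3 tips vs enumeration: marginals from brute-force joint
  set.seed(55)
  phy3 <- random_coal_tree(3)
  st <- range_states(c("A", "B"), 2)
  p <- dec_params(0.3, 0.1, 0.5)
  tip_idx <- c(2L, 3L, 2L)
  gm <- st$bits[tip_idx, , drop = FALSE] * 1L
  rownames(gm) <- phy3$tip.label
  mm <- ancestral_range_marginals(phy3, geography(gm), p, disp)
  # brute force joint over internal states and clado outcomes
  Q <- build_anagenetic_Q(p, st)
  clado <- oracle_clado_dec(st, p$j)
  prior <- as.numeric(st$sizes > 0); prior <- prior / sum(prior)
  edge <- phy3$edge
  P <- lapply(seq_len(nrow(edge)), function(i)
    as.matrix(Matrix::expm(Q * phy3$edge.length[i])))
  root <- 4L
  joint <- matrix(0, 2, st$n_states)
  kidsr <- which(edge[, 1] == root)
  other <- 5L
  kidso <- which(edge[, 1] == other)
  for (sr in seq_len(st$n_states)) for (so in seq_len(st$n_states)) {
    w <- prior[sr]
    if (w == 0) next
    st_all <- c(tip_idx, sr, so)
    for (v in c(root, other)) {
      rows <- which(edge[, 1] == v)
      c1 <- edge[rows[1], 2]; c2 <- edge[rows[2], 2]
      if (v == root) {
        w <- w * P[[rows[1]]][sr, st_all[c1]] * P[[rows[2]]][sr, st_all[c2]]
      } else {
        tab <- clado[[so]]
        if (is.null(tab)) { w <- 0; break }
        w <- w * sum(tab$prob * P[[rows[1]]][cbind(tab$left, st_all[c1])] *
                       P[[rows[2]]][cbind(tab$right, st_all[c2])])
      }
    }
    joint[1, sr] <- joint[1, sr] + w
    joint[2, so] <- joint[2, so] + w
  }
  joint <- joint / rowSums(joint)
  expect_equal(unname(mm$marginals), unname(joint), tolerance = 1e-8)
})

test_that("root-areas summary reports the smallest 95% state set", {
  disp <- stratified_dispersal(areas = c("A", "B"))
  phy <- parse_newick("(A:0.2,B:0.2);")
  g <- geography(c(A = "A", B = "A"), areas = c("A", "B"))
  m <- ancestral_range_marginals(phy, g, dec_params(0.05, 0.01), disp)
  expect_true("A" %in% m$root_states)
  expect_match(m$root_areas, "A")
})
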