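# Independent oracles: brute-force likelihoods by explicit enumeration
# over internal-node state assignments (with Matrix::expm for branch
# transition probabilities), a naive cladogenesis enumerator, and the
# uniformization series for conditional change counts. These share no
# code with the package's pruning engine.

# naive DEC(+J) cladogenesis table: list over ancestor indices of
# data.frame(left, right, prob); equal base weights, jumps j/2 per order
oracle_clado_dec <- function(states, j = 0) {
  ns <- states$n_states
  bits <- states$bits
  n_areas <- ncol(bits)
  find <- function(v) which(apply(bits, 1, function(r) all(r == v)))
  out <- vector("list", ns)
  for (s in seq_len(ns)) {
    R <- bits[s, ]
    if (!any(R)) next
    L <- integer(0); Rt <- integer(0); W <- numeric(0)
    if (sum(R) == 1) {
      L <- s; Rt <- s; W <- 1
    } else {
      for (a in which(R)) {
        single <- rep(FALSE, n_areas); single[a] <- TRUE
        rest <- R & !single
        si <- find(single); ri <- find(rest)
        # subset sympatry both orders
        L <- c(L, s, si); Rt <- c(Rt, si, s); W <- c(W, 1, 1)
        # vicariance (single vs rest) both orders, dedup for size 2
        L <- c(L, si); Rt <- c(Rt, ri); W <- c(W, 1)
        if (sum(R) > 2) { L <- c(L, ri); Rt <- c(Rt, si); W <- c(W, 1) }
      }
    }
    if (j > 0) {
      for (a in which(!R)) {
        single <- rep(FALSE, n_areas); single[a] <- TRUE
        si <- find(single)
        L <- c(L, s, si); Rt <- c(Rt, si, s); W <- c(W, j / 2, j / 2)
      }
    }
    out[[s]] <- data.frame(left = L, right = Rt, prob = W / sum(W))
  }
  out
}

# brute-force DEC likelihood: enumerate the state of every node plus the
# cladogenetic daughter pair at every internal node (root included only
# when root_clado). Single stratum, all multipliers 1.
oracle_dec_loglik <- function(phy, tip_idx, states, Q, clado,
                              root_clado = FALSE) {
  n_tip <- length(phy$tip.label)
  edge <- phy$edge
  ages <- stygodec::node_ages(phy)
  P <- lapply(seq_len(nrow(edge)), function(i)
    as.matrix(Matrix::expm(Q * phy$edge.length[i])))
  ns <- states$n_states
  root <- n_tip + 1L
  internal <- root:(n_tip + phy$Nnode)
  prior <- as.numeric(states$sizes > 0)
  prior <- prior / sum(prior)
  kids <- lapply(seq_len(n_tip + phy$Nnode), function(v)
    which(edge[, 1] == v))
  # enumerate assignments of internal node states
  n_int <- phy$Nnode
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), n_int)))
  total <- 0
  node_state <- integer(n_tip + n_int)
  node_state[seq_len(n_tip)] <- tip_idx
  for (g in seq_len(nrow(grid))) {
    node_state[internal] <- grid[g, ]
    s_root <- node_state[root]
    if (prior[s_root] == 0) next
    w <- prior[s_root]
    ok <- TRUE
    for (v in internal) {
      s_v <- node_state[v]
      rows <- kids[[v]]
      c1 <- edge[rows[1], 2]; c2 <- edge[rows[2], 2]
      if (v == root && !root_clado) {
        pr <- P[[rows[1]]][s_v, node_state[c1]] *
          P[[rows[2]]][s_v, node_state[c2]]
      } else {
        tab <- clado[[s_v]]
        if (is.null(tab)) { ok <- FALSE; break }
        pr <- sum(tab$prob *
                    P[[rows[1]]][cbind(tab$left, node_state[c1])] *
                    P[[rows[2]]][cbind(tab$right, node_state[c2])])
      }
      w <- w * pr
      if (w == 0) { ok <- FALSE; break }
    }
    if (ok) total <- total + w
  }
  if (total <= 0) -Inf else log(total)
}

# brute-force Mk likelihood: enumerate internal node states
oracle_mk_loglik <- function(phy, tipL, Q, prior) {
  n_tip <- nrow(tipL); ns <- ncol(tipL)
  edge <- phy$edge
  P <- lapply(seq_len(nrow(edge)), function(i)
    as.matrix(Matrix::expm(Q * phy$edge.length[i])))
  root <- n_tip + 1L
  n_int <- phy$Nnode
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), n_int)))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    st <- grid[g, ]
    w <- prior[st[1]]
    if (w == 0) next
    for (i in seq_len(nrow(edge))) {
      par <- edge[i, 1]; ch <- edge[i, 2]
      s_par <- st[par - n_tip]
      if (ch <= n_tip) {
        w <- w * sum(P[[i]][s_par, ] * tipL[ch, ])
      } else {
        w <- w * P[[i]][s_par, st[ch - n_tip]]
      }
      if (w == 0) break
    }
    total <- total + w
  }
  if (total <= 0) -Inf else log(total)
}

# brute-force Mk node marginals by the same enumeration
oracle_mk_marginals <- function(phy, tipL, Q, prior) {
  n_tip <- nrow(tipL); ns <- ncol(tipL)
  edge <- phy$edge
  P <- lapply(seq_len(nrow(edge)), function(i)
    as.matrix(Matrix::expm(Q * phy$edge.length[i])))
  n_int <- phy$Nnode
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), n_int)))
  marg <- matrix(0, n_int, ns)
  for (g in seq_len(nrow(grid))) {
    st <- grid[g, ]
    w <- prior[st[1]]
    if (w == 0) next
    for (i in seq_len(nrow(edge))) {
      par <- edge[i, 1]; ch <- edge[i, 2]
      s_par <- st[par - n_tip]
      if (ch <= n_tip) w <- w * sum(P[[i]][s_par, ] * tipL[ch, ])
      else w <- w * P[[i]][s_par, st[ch - n_tip]]
      if (w == 0) break
    }
    for (v in seq_len(n_int)) marg[v, st[v]] <- marg[v, st[v]] + w
  }
  marg / rowSums(marg)
}

# expected number of real state changes on a branch of length t,
# conditional on endpoints (a, b), by the uniformization series
oracle_expected_changes <- function(Q, a, b, t, tol = 1e-12) {
  n <- nrow(Q)
  Om <- max(-diag(Q))
  R <- diag(n) + Q / Om
  lt <- Om * t
  nmax <- max(20, stats::qpois(1 - 1e-14, lt) + 10)
  pows <- vector("list", nmax + 1)
  pows[[1]] <- diag(n)
  for (m in seq_len(nmax)) pows[[m + 1]] <- pows[[m]] %*% R
  pn <- stats::dpois(0:nmax, lt) *
    vapply(0:nmax, function(m) pows[[m + 1]][a, b], 0)
  pn <- pn / sum(pn)
  Rreal <- R; diag(Rreal) <- 0
  e_real <- vapply(0:nmax, function(nj) {
    if (nj == 0 || pows[[nj + 1]][a, b] <= 0) return(0)  # P(N = nj) = 0
    tot <- 0
    for (k in seq_len(nj)) {
      # P(jump k is a real change | nj virtual jumps, endpoints)
      num <- sum(pows[[k]][a, ] * (Rreal %*% pows[[nj - k + 1]][, b]))
      tot <- tot + num / pows[[nj + 1]][a, b]
    }
    tot
  }, 0)
  sum(pn * e_real)
}

# simulate a DEC dataset conditioned on observable (nonempty) tip
# ranges, redrawing the tree itself when a given tree cannot yield a
# clean dataset within the redraw budget
sim_clean_dec <- function(n_tips, root_age, params, disp, root_range,
                          tree_seed, data_seed) {
  for (bump in 0:19) {
    phy <- simulate_bd_tree(1, 0, n_tips,
                            seed = tree_seed + bump * 100000L,
                            root_age = root_age)$phy
    sim <- tryCatch(
      simulate_dec_tips(phy, params, disp, root_range = root_range,
                        seed = data_seed + bump * 100000L,
                        redraw_null = TRUE, max_retries = 60),
      error = function(e) NULL)
    if (!is.null(sim)) return(list(phy = phy, sim = sim))
  }
  stop("no observable dataset after 20 tree redraws")
}

# random ultrametric tree (coalescent branch lengths)
random_coal_tree <- function(n) {
  validate_timetree(ape::rcoal(n))
}
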