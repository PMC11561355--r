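#' DEC process parameters
#'
#' @param d per-area dispersal (range-gain) rate, events/Ma, `>= 0`.
#' @param e per-area range-loss rate, events/Ma, `>= 0`.
#' @param j founder-event (jump) cladogenesis weight, `>= 0`; `j = 0`
#'   recovers the no-founder model. Under the default unit base weights the
#'   weight budget caps usable `j` below 3.
#' @param w exponent applied to dispersal multipliers strictly inside
#'   `(0, 1)`; exact zeros stay zero for every `w` so that forbidden routes
#'   (unemerged areas) remain forbidden, and exact ones stay one.
#' @return list of class `dec_params`.
#' @export
dec_params <- function(d, e, j = 0, w = 1) {
  vals <- c(d = d, e = e, j = j, w = w)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("DEC parameters must be finite and >= 0")
  structure(as.list(vals), class = "dec_params")
}

# effective multipliers: w applies only to entries strictly in (0,1)
effective_multipliers <- function(m, w) {
  inner <- m > 0 & m < 1
  m[inner] <- m[inner]^w
  m
}

#' Anagenetic DEC rate matrix for one stratum
#'
#' Off-diagonal rates: range expansion `R -> R + {a}` at rate
#' `d * sum_{i in R} m'[i, a]` (for `a` outside `R`, result within the
#' allowed range size), where `m'` is the multiplier matrix after applying
#' the `w` exponent; range contraction `R -> R - {a}` at rate `e` per area
#' held (singletons decay to the null range, which is absorbing). Rows sum
#' to zero.
#'
#' @param params a [dec_params()].
#' @param multipliers square multiplier matrix over the areas for one
#'   stratum (defaults to all ones).
#' @param states a [range_states()] space.
#' @return dense rate matrix over the states.
#' @export
build_anagenetic_Q <- function(params, states,
                               multipliers = NULL) {
  n_areas <- length(states$areas)
  if (is.null(multipliers))
    multipliers <- matrix(1, n_areas, n_areas)
  if (any(multipliers < 0)) stop("negative dispersal multipliers")
  m <- effective_multipliers(multipliers, params$w)
  ns <- states$n_states
  Q <- matrix(0, ns, ns, dimnames = list(states$labels, states$labels))
  bits <- states$bits
  for (s in seq_len(ns)) {
    R <- bits[s, ]
    if (!any(R)) next                       # null range absorbing
    # contractions
    for (a in which(R)) {
      v <- R; v[a] <- FALSE
      Q[s, state_index(states, v)] <- params$e
    }
    # expansions
    if (sum(R) < states$max_range_size) {
      for (a in which(!R)) {
        rate <- params$d * sum(m[which(R), a])
        if (rate > 0) {
          v <- R; v[a] <- TRUE
          Q[s, state_index(states, v)] <- rate
        }
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# ---- cladogenesis ---------------------------------------------------------

#' Cladogenetic outcome distribution for one ancestor range
#'
#' Enumerates the ordered daughter-range pairs permitted by the model
#' family and normalizes their weights to a probability distribution.
#' Base event weights are `y = s = v = 1` (sympatry, subset sympatry,
#' vicariance); founder events carry weight `j`, split evenly between the
#' two daughter orders, and may optionally be scaled by the mean dispersal
#' multiplier from the ancestor's areas into the jump target.
#'
#' Families: `DEC` (singleton sympatry; subset sympatry; vicariance with
#' one single-area daughter), `DIVALIKE` (singleton sympatry; all
#' vicariant bipartitions; no subset sympatry), `BAYAREALIKE` (both
#' daughters copy the ancestor; no cladogenetic range change).
#'
#' @param ancestor state index (or range label) of the ancestor; nonempty.
#' @param states a [range_states()].
#' @param family `"DEC"`, `"DIVALIKE"` or `"BAYAREALIKE"`.
#' @param params a [dec_params()] (only `j`, `w` used here).
#' @param multipliers multiplier matrix used to scale jump weights when
#'   `scale_jump = TRUE`.
#' @param scale_jump logical; scale founder weights by mean multiplier
#'   into the target area (default `TRUE`).
#' @return data.frame with columns `left`, `right` (state indices) and
#'   `prob`, summing to 1.
#' @export
cladogenesis_distribution <- function(ancestor, states, family = "DEC",
                                      params = dec_params(0, 0),
                                      multipliers = NULL,
                                      scale_jump = TRUE) {
  if (is.character(ancestor)) ancestor <- state_index_label(states, ancestor)
  tab <- clado_events(ancestor, states, family, params, multipliers,
                      scale_jump)
  if (!length(tab$weight) || sum(tab$weight) <= 0)
    stop("no legal cladogenetic outcome for ancestor ",
         states$labels[ancestor])
  data.frame(left = tab$left, right = tab$right,
             prob = tab$weight / sum(tab$weight))
}

# raw weighted ordered outcomes for one ancestor state (plain vectors,
# hot path: called for every nonempty state when building clado tables)
clado_events <- function(anc, states, family, params, multipliers,
                         scale_jump) {
  if (!family %in% c("DEC", "DIVALIKE", "BAYAREALIKE"))
    stop("unknown model family: ", family)
  bits <- states$bits
  R <- bits[anc, ]
  if (!any(R)) stop("cladogenesis undefined for the null range")
  size <- sum(R)
  n_areas <- length(R)
  if (is.null(multipliers)) multipliers <- matrix(1, n_areas, n_areas)
  m <- effective_multipliers(multipliers, params$w)
  left <- integer(0); right <- integer(0); weight <- numeric(0)
  target <- integer(0)                     # jump target area, 0 otherwise
  add <- function(l, r, w, tg = 0L) {
    left <<- c(left, l); right <<- c(right, r); weight <<- c(weight, w)
    target <<- c(target, tg)
  }
  idx_of <- function(v) state_index(states, v)
  if (family == "BAYAREALIKE") {
    add(anc, anc, 1)
  } else if (size == 1L) {
    add(anc, anc, 1)                               # sympatric speciation
  } else {
    singles <- which(R)
    if (family == "DEC") {
      for (a in singles) {
        sa <- idx_of(seq_len(n_areas) == a)
        # subset sympatry, both orders
        add(anc, sa, 1); add(sa, anc, 1)
        # vicariance with a single-area daughter, both orders
        rest <- R; rest[a] <- FALSE
        sr <- idx_of(rest)
        add(sa, sr, 1)
        if (size > 2L) add(sr, sa, 1)
        # size == 2: the (sr, sa) order arises from the other area's split
      }
    } else { # DIVALIKE: every ordered bipartition into two nonempty sets
      areas_in <- which(R)
      n_sub <- 2^size - 2L
      for (code in seq_len(n_sub)) {
        sel <- as.logical(bitwAnd(code, 2^(seq_len(size) - 1L)))
        v1 <- rep(FALSE, n_areas); v1[areas_in[sel]] <- TRUE
        v2 <- R & !v1
        add(idx_of(v1), idx_of(v2), 1)
      }
    }
  }
  # founder events: one daughter keeps the range, the other jumps to a
  # single area outside it (both orders, weight j/2 each)
  if (params$j > 0 && family %in% c("DEC", "DIVALIKE", "BAYAREALIKE")) {
    for (a in which(!R)) {
      sa <- idx_of(seq_len(n_areas) == a)
      wj <- params$j / 2
      if (scale_jump) wj <- wj * mean(m[which(R), a])
      if (wj > 0) { add(anc, sa, wj, a); add(sa, anc, wj, a) }
    }
  }
  list(left = left, right = right, weight = weight, target = target)
}

# family-specific outcome structure, parameter independent: flat vectors
# over all ancestors (jumps included with base 0; their weight is filled
# in per stratum from j and the multipliers)
clado_structure <- function(states, family) {
  anc <- integer(0); left <- integer(0); right <- integer(0)
  base <- numeric(0); target <- integer(0)
  p1 <- dec_params(0, 0, j = 1)
  for (s in seq_len(states$n_states)) {
    if (states$sizes[s] == 0) next
    ev <- clado_events(s, states, family, p1, NULL, FALSE)
    anc <- c(anc, rep(s, length(ev$left)))
    left <- c(left, ev$left); right <- c(right, ev$right)
    base <- c(base, ifelse(ev$target > 0L, 0, ev$weight))
    target <- c(target, ev$target)
  }
  ns <- states$n_states
  # dense ancestor-accumulation matrix: Dp[2:ns] = group_mat %*% contrib
  group_mat <- matrix(0, ns - 1L, length(anc))
  group_mat[cbind(anc - 1L, seq_along(anc))] <- 1
  list(anc = anc, left = left, right = right, base = base,
       target = target, is_jump = target > 0L, group_mat = group_mat)
}

# per-stratum outcome probabilities from a structure: jump weight
# j/2 * (mean effective multiplier from the ancestor areas into the
# target), normalized within each ancestor state
clado_probs <- function(cs, states, j, m_eff, scale_jump) {
  w <- cs$base
  if (j > 0 && any(cs$is_jump)) {
    scale <- 1
    if (scale_jump) {
      meanmat <- (states$bits / pmax(states$sizes, 1)) %*% m_eff
      scale <- meanmat[cbind(cs$anc[cs$is_jump], cs$target[cs$is_jump])]
    }
    w[cs$is_jump] <- (j / 2) * scale
  }
  tot <- as.numeric(cs$group_mat %*% w)    # per-ancestor weight budget
  w / tot[cs$anc - 1L]
}

# full cladogenesis table: list over ancestor states of lists
# (left, right, prob vectors); NULL for the null range
clado_table <- function(states, family, params, multipliers, scale_jump) {
  lapply(seq_len(states$n_states), function(s) {
    if (states$sizes[s] == 0) return(NULL)
    tab <- clado_events(s, states, family, params, multipliers,
                        scale_jump)
    tot <- sum(tab$weight)
    if (!length(tab$weight) || tot <= 0)
      stop("no legal cladogenetic outcome for ancestor ",
           states$labels[s])
    list(left = tab$left, right = tab$right, prob = tab$weight / tot)
  })
}

# ---- propagators ----------------------------------------------------------

# dense matrix exponential, scaling-and-squaring with the order-13 Pade
# approximant (Higham 2005); plain double matrices on the hot path, used
# when an eigendecomposition of Q is unreliable (near-defective Q, e.g.
# range-loss rate at its lower bound)
expm_pade <- function(A) {
  n <- nrow(A)
  nrmA <- max(colSums(abs(A)))
  s <- if (nrmA > 5.37) ceiling(log2(nrmA / 5.37)) else 0
  if (s > 0) A <- A / 2^s
  b <- c(64764752532480000, 32382376266240000, 7771770303897600,
         1187353796428800, 129060195264000, 10559470521600,
         670442572800, 33522128640, 1323241920, 40840800, 960960,
         16380, 182, 1)
  I <- diag(n)
  A2 <- A %*% A; A4 <- A2 %*% A2; A6 <- A2 %*% A4
  U <- A %*% (A6 %*% (b[14] * A6 + b[12] * A4 + b[10] * A2) +
                b[8] * A6 + b[6] * A4 + b[4] * A2 + b[2] * I)
  V <- A6 %*% (b[13] * A6 + b[11] * A4 + b[9] * A2) +
    b[7] * A6 + b[5] * A4 + b[3] * A2 + b[1] * I
  P <- solve(V - U, V + U)
  if (s > 0) for (k in seq_len(s)) P <- P %*% P
  P
}

# returns function(t) -> transition probability matrix exp(Q t);
# eigendecomposition when well-conditioned, dense Pade expm otherwise
make_propagator <- function(Q) {
  n <- nrow(Q)
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  ok <- !is.null(eg) && all(is.finite(Mod(eg$values)))
  V <- NULL; Vi <- NULL
  if (ok) {
    V <- eg$vectors
    Vi <- tryCatch(solve(V), error = function(e) NULL)
    ok <- !is.null(Vi) &&
      max(Mod(V %*% Vi - diag(n))) < 1e-8
  }
  if (ok) {
    lam <- eg$values
    if (max(abs(Im(lam))) < 1e-12 && max(abs(Im(V))) < 1e-12) {
      V <- Re(V); Vi <- Re(Vi); lam <- Re(lam)    # real spectrum
      return(function(t) {
        P <- V %*% (exp(lam * t) * Vi)
        P[P < 0] <- 0
        P
      })
    }
    function(t) {
      P <- Re(V %*% (exp(lam * t) * Vi))
      P[P < 0] <- 0
      P
    }
  } else {
    function(t) expm_pade(Q * t)
  }
}

# ---- likelihood engine ----------------------------------------------------

# Static, parameter-independent structure: state space, node ages, branch
# segments per stratum, child-edge rows, tip state indices. Built once per
# dataset and reused across optimizer iterations.
dec_precompute <- function(phy, geog, dispersal, max_range_size) {
  validate_timetree(phy)
  n_tip <- length(phy$tip.label)
  states <- range_states(dispersal$areas, max_range_size)
  if (!all(phy$tip.label %in% rownames(geog)))
    stop("geography missing tips: ",
         paste(setdiff(phy$tip.label, rownames(geog)), collapse = ", "))
  geog <- geog[phy$tip.label, , drop = FALSE]
  if (!identical(colnames(geog), states$areas))
    stop("geography areas do not match the dispersal model's areas")
  if (any(rowSums(geog) > states$max_range_size))
    stop("tip range exceeds max_range_size: ",
         rownames(geog)[rowSums(geog) > states$max_range_size][1L])
  ages <- node_ages(phy)
  strat <- dispersal$strat
  edge <- phy$edge
  seg_list <- lapply(seq_len(nrow(edge)), function(i) {
    sg <- slice_branch_by_strata(ages[edge[i, 1L]], ages[edge[i, 2L]],
                                 strat)
    list(stratum = sg$stratum, duration = sg$duration,
         n = nrow(sg))                    # plain vectors: hot path
  })
  kid_rows <- vector("list", n_tip + phy$Nnode)
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1L]
    kid_rows[[p]] <- c(kid_rows[[p]], i)
  }
  tip_idx <- vapply(seq_len(n_tip),
                    function(i) state_index(states, geog[i, ] != 0), 0L)
  postorder <- ape::reorder.phylo(phy, "postorder")$edge
  cladewise <- ape::reorder.phylo(phy, "cladewise")$edge
  stratum_of_age <- function(a) sum(strat$boundaries >= a - 1e-12) + 1L
  node_stratum <- vapply(ages, stratum_of_age, 0L)
  # Q sparsity structure (parameter independent): gains R -> R+{a} with
  # the source-sum of multipliers into a, losses R -> R-{a} at rate e
  gain_from <- integer(0); gain_to <- integer(0); gain_area <- integer(0)
  loss_from <- integer(0); loss_to <- integer(0)
  for (s in seq_len(states$n_states)) {
    R <- states$bits[s, ]
    if (!any(R)) next
    for (a in which(R)) {
      v <- R; v[a] <- FALSE
      loss_from <- c(loss_from, s)
      loss_to <- c(loss_to, state_index(states, v))
    }
    if (sum(R) < states$max_range_size) {
      for (a in which(!R)) {
        v <- R; v[a] <- TRUE
        gain_from <- c(gain_from, s)
        gain_to <- c(gain_to, state_index(states, v))
        gain_area <- c(gain_area, a)
      }
    }
  }
  pre <- new.env(parent = emptyenv())
  pre$phy <- phy; pre$geog <- geog; pre$states <- states
  pre$ages <- ages; pre$segs <- seg_list; pre$edge <- edge
  pre$n_tip <- n_tip; pre$kid_rows <- kid_rows; pre$tip_idx <- tip_idx
  pre$postorder <- postorder; pre$cladewise <- cladewise
  pre$node_stratum <- node_stratum; pre$dispersal <- dispersal
  pre$Qstruct <- list(gain_from = gain_from, gain_to = gain_to,
                      gain_area = gain_area, loss_from = loss_from,
                      loss_to = loss_to)
  pre$cstruct <- list()                   # per-family cache
  pre
}

# fast anagenetic Q from the precomputed sparsity structure; agrees with
# build_anagenetic_Q (asserted in the test suite)
dec_Q_fast <- function(d, e, m_eff, pre) {
  states <- pre$states; qs <- pre$Qstruct
  ns <- states$n_states
  Q <- matrix(0, ns, ns)
  M <- states$bits %*% m_eff              # source-sum of multipliers
  Q[cbind(qs$gain_from, qs$gain_to)] <-
    d * M[cbind(qs$gain_from, qs$gain_area)]
  Q[cbind(qs$loss_from, qs$loss_to)] <- e
  diag(Q) <- -rowSums(Q)
  Q
}

# Parameter-dependent parts on top of a precompute: per-stratum Q and
# propagators, per-edge transition matrices (product over strata segments,
# oldest first), per-stratum flat cladogenesis probabilities.
dec_engine <- function(phy, geog, params, dispersal, family,
                       max_range_size, scale_jump, precomp = NULL) {
  if (!inherits(params, "dec_params")) params <- do.call(dec_params, params)
  if (is.null(precomp))
    precomp <- dec_precompute(phy, geog, dispersal, max_range_size)
  states <- precomp$states
  if (is.null(precomp$cstruct[[family]]))
    precomp$cstruct[[family]] <- clado_structure(states, family)
  cs <- precomp$cstruct[[family]]
  m_effs <- lapply(dispersal$matrices, effective_multipliers, w = params$w)
  Qs <- lapply(m_effs, function(m) dec_Q_fast(params$d, params$e, m,
                                              precomp))
  eigs <- lapply(Qs, eig_decompose)
  edge <- precomp$edge
  segs <- precomp$segs
  # matrix-free propagation: exp(Qt) x per segment, youngest first going
  # up (action on conditional likelihoods), or its transpose, oldest
  # first going down
  apply_edge <- function(r, x) {
    sg <- segs[[r]]
    for (k in sg$n:1L) {
      x <- eig_apply(eigs[[sg$stratum[k]]], sg$duration[k], x)
      x[x < 0] <- 0
    }
    x
  }
  apply_edge_T <- function(r, x) {
    sg <- segs[[r]]
    for (k in 1L:sg$n) {
      x <- eig_apply_T(eigs[[sg$stratum[k]]], sg$duration[k], x)
      x[x < 0] <- 0
    }
    x
  }
  cprobs <- lapply(m_effs, function(m)
    clado_probs(cs, states, params$j, m, scale_jump))
  list(phy = precomp$phy, geog = precomp$geog, states = states,
       ages = precomp$ages, edge = edge, n_tip = precomp$n_tip,
       kid_rows = precomp$kid_rows, tip_idx = precomp$tip_idx,
       postorder = precomp$postorder, cladewise = precomp$cladewise,
       node_stratum = precomp$node_stratum,
       params = params, Qs = Qs,
       apply_edge = apply_edge, apply_edge_T = apply_edge_T,
       cs = cs, cprobs = cprobs,
       dispersal = dispersal, family = family, scale_jump = scale_jump)
}

# eigendecomposition with a dense-expm fallback marker; the eigen basis
# is accepted only if it reproduces a Pade-computed exponential on probe
# times bracketing the branch-duration scale
eig_decompose <- function(Q, probe_t = c(1, 25)) {
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  ok <- !is.null(eg) && all(is.finite(Mod(eg$values)))
  V <- NULL; Vi <- NULL
  if (ok) {
    V <- eg$vectors
    Vi <- tryCatch(solve(V), error = function(e) NULL)
    ok <- !is.null(Vi) && all(is.finite(Mod(Vi)))
  }
  if (ok) {
    lam <- eg$values
    for (t0 in probe_t) {
      P_eig <- Re(V %*% (exp(lam * t0) * Vi))
      if (max(abs(P_eig - expm_pade(Q * t0))) > 1e-9) {
        ok <- FALSE; break
      }
    }
  }
  if (!ok) return(list(ok = FALSE, Q = Q))
  lam <- eg$values
  if (max(abs(Im(lam))) < 1e-12 && max(abs(Im(V))) < 1e-12) {
    V <- Re(V); Vi <- Re(Vi); lam <- Re(lam)
  }
  list(ok = TRUE, V = V, Vi = Vi, tV = t(V), tVi = t(Vi), lam = lam,
       Q = Q)
}

# exp(Qt) %*% x without forming exp(Qt)
eig_apply <- function(eg, t, x) {
  if (!eg$ok) return(as.numeric(expm_pade(eg$Q * t) %*% x))
  y <- eg$V %*% (exp(eg$lam * t) * (eg$Vi %*% x))
  if (is.complex(y)) as.numeric(Re(y)) else as.numeric(y)
}

# t(exp(Qt)) %*% x without forming exp(Qt)
eig_apply_T <- function(eg, t, x) {
  if (!eg$ok) return(as.numeric(crossprod(expm_pade(eg$Q * t), x)))
  y <- eg$tVi %*% (exp(eg$lam * t) * (eg$tV %*% x))
  if (is.complex(y)) as.numeric(Re(y)) else as.numeric(y)
}

# flat prior over nonempty states (null range excluded)
dec_root_prior <- function(states) {
  pr <- as.numeric(states$sizes > 0)
  pr / sum(pr)
}

# post-order pruning: returns D (per-node conditional likelihoods, scaled),
# E (per-edge top-of-branch likelihoods), log scalers, and total loglik
dec_uppass <- function(eng, root_clado = FALSE) {
  phy <- eng$phy; states <- eng$states
  ns <- states$n_states; n_tip <- eng$n_tip
  n_node <- n_tip + phy$Nnode
  D <- matrix(0, n_node, ns)
  logscale <- numeric(n_node)
  D[cbind(seq_len(n_tip), eng$tip_idx)] <- 1
  edge <- eng$postorder
  E <- vector("list", nrow(eng$edge))   # indexed like eng$edge rows
  # child edge rows per internal node, in eng$edge order so the up- and
  # down-passes agree on left/right slots
  kid_rows <- eng$kid_rows
  done <- rep(FALSE, n_node)
  for (i in seq_len(nrow(edge))) {
    par <- edge[i, 1L]
    if (done[par]) next
    rows <- kid_rows[[par]]
    Evec <- vector("list", length(rows))
    for (k in seq_along(rows)) {
      r <- rows[k]
      Evec[[k]] <- eng$apply_edge(r, D[eng$edge[r, 2L], ])
      E[[r]] <- Evec[[k]]
    }
    root <- par == n_tip + 1L
    if (root && !root_clado) {
      Dp <- Evec[[1L]] * Evec[[2L]]
    } else {
      cs <- eng$cs
      prob <- eng$cprobs[[eng$node_stratum[par]]]
      contrib <- prob * Evec[[1L]][cs$left] * Evec[[2L]][cs$right]
      Dp <- c(0, cs$group_mat %*% contrib)  # ancestors are states 2..ns
    }
    sc <- max(Dp)
    if (sc > 0) { Dp <- Dp / sc; logscale[par] <- log(sc) }
    D[par, ] <- Dp
    done[par] <- TRUE
  }
  root <- n_tip + 1L
  prior <- dec_root_prior(states)
  lik <- sum(prior * D[root, ])
  loglik <- if (lik <= 0) -Inf else log(lik) + sum(logscale)
  list(D = D, E = E, logscale = logscale, loglik = loglik, prior = prior)
}

#' DEC-family log-likelihood
#'
#' Felsenstein pruning over the range state space: branch propagation by
#' matrix exponentials of the per-stratum anagenetic rate matrices (branch
#' segments applied oldest to youngest), node merging through the
#' cladogenetic outcome distribution, and a flat root prior over nonempty
#' ranges. By default no cladogenetic event is placed at the root (the two
#' basal lineages inherit the root range); set `root_clado = TRUE` to
#' treat the root like any other node.
#'
#' @param phy validated ultrametric `phylo`.
#' @param geog a [geography()] matrix covering every tip.
#' @param params a [dec_params()].
#' @param dispersal a [stratified_dispersal()] model (areas define the
#'   state space).
#' @param family `"DEC"`, `"DIVALIKE"` or `"BAYAREALIKE"`.
#' @param max_range_size largest permitted range (default all areas).
#' @param root_clado place a cladogenetic event at the root?
#' @param scale_jump scale founder weights by dispersal multipliers?
#' @param precomp optional structure from an earlier call on the same
#'   tree/geography/dispersal (internal reuse by the fitters).
#' @return log-likelihood (finite `<= 0` or `-Inf`).
#' @export
dec_loglik <- function(phy, geog, params, dispersal,
                       family = "DEC",
                       max_range_size = length(dispersal$areas),
                       root_clado = FALSE, scale_jump = TRUE,
                       precomp = NULL) {
  eng <- dec_engine(phy, geog, params, dispersal, family,
                    max_range_size, scale_jump, precomp)
  dec_uppass(eng, root_clado)$loglik
}

#' Marginal ancestral range probabilities
#'
#' Computes, for every internal node, the marginal posterior distribution
#' over range states (the node's state immediately before its cladogenetic
#' event), by the standard up-pass/down-pass algorithm. Also returns the
#' root-areas summary: the smallest set of root states whose cumulative
#' probability reaches `level`, and the union of their areas.
#'
#' @inheritParams dec_loglik
#' @param level credibility level for the root-areas summary (default 0.95).
#' @return list with `marginals` (matrix, internal nodes x states, rows sum
#'   to 1), `loglik`, `root_states` (labels in the credible set),
#'   `root_areas` (string, union of areas, e.g. `"BCDE"`).
#' @export
ancestral_range_marginals <- function(phy, geog, params, dispersal,
                                      family = "DEC",
                                      max_range_size =
                                        length(dispersal$areas),
                                      root_clado = FALSE,
                                      scale_jump = TRUE, level = 0.95,
                                      precomp = NULL) {
  eng <- dec_engine(phy, geog, params, dispersal, family,
                    max_range_size, scale_jump, precomp)
  up <- dec_uppass(eng, root_clado)
  states <- eng$states; ns <- states$n_states
  n_tip <- eng$n_tip; phy <- eng$phy
  root <- n_tip + 1L
  n_node <- n_tip + phy$Nnode
  # Ftop[[edge row]] = outside likelihood at the top (parent end) of edge;
  # F at a node = t(P_edge) %*% Ftop, normalized to avoid underflow
  Fnode <- matrix(0, n_node, ns)
  Fnode[root, ] <- up$prior
  marg <- matrix(0, phy$Nnode, ns,
                 dimnames = list(NULL, states$labels))
  rootm <- up$prior * up$D[root, ]
  marg[1L, ] <- rootm / sum(rootm)
  # preorder traversal
  edge <- eng$edge
  pre <- eng$cladewise
  row_of <- function(p, c) which(edge[, 1L] == p & edge[, 2L] == c)
  for (i in seq_len(nrow(pre))) {
    par <- pre[i, 1L]; v <- pre[i, 2L]
    if (v <= n_tip) next
    r_v <- row_of(par, v)
    sib <- edge[edge[, 1L] == par & edge[, 2L] != v, 2L]
    r_s <- row_of(par, sib)
    Esib <- up$E[[r_s]]
    v_is_left <- which(edge[edge[, 1L] == par, 2L] == v) == 1L
    Fp <- Fnode[par, ]
    Ftop <- numeric(ns)
    if (par == root && !root_clado) {
      # no cladogenesis at root: daughter top state = root state
      Ftop <- Fp * Esib
    } else {
      cs <- eng$cs
      prob <- eng$cprobs[[eng$node_stratum[par]]]
      if (v_is_left) {
        contrib <- Fp[cs$anc] * prob * Esib[cs$right]
        agg <- rowsum(contrib, cs$left)
      } else {
        contrib <- Fp[cs$anc] * prob * Esib[cs$left]
        agg <- rowsum(contrib, cs$right)
      }
      Ftop[as.integer(rownames(agg))] <- agg
    }
    Fv <- eng$apply_edge_T(r_v, Ftop)
    if (sum(Fv) > 0) Fv <- Fv / sum(Fv)
    Fnode[v, ] <- Fv
    m <- Fv * up$D[v, ]
    tot <- sum(m)
    if (tot > 0) m <- m / tot
    marg[v - n_tip, ] <- m
  }
  rootp <- marg[1L, ]
  ord <- order(rootp, decreasing = TRUE)
  k <- which(cumsum(rootp[ord]) >= level)[1L]
  sel <- ord[seq_len(k)]
  in_set <- colSums(states$bits[sel, , drop = FALSE] * rootp[sel]) > 0
  list(marginals = marg, loglik = up$loglik,
       root_states = states$labels[sel],
       root_areas = paste(states$areas[in_set], collapse = ""))
}
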