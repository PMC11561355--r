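#' Discrete trait state space
#'
#' A plain ordered set of state labels, optionally structured: each state
#' may carry a habitat class (`epigean`, `interstitial`, `subterranean`)
#' and a palaeovalley id, which the colonization counters read.
#'
#' @param labels unique state labels.
#' @param class optional habitat class per state.
#' @param valley optional palaeovalley id per state (NA for unstructured
#'   states such as epigean).
#' @return object of class `trait_space`.
#' @export
trait_space <- function(labels, class = NULL, valley = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("state labels must be unique")
  if (!is.null(class)) {
    class <- as.character(class)
    stopifnot(length(class) == length(labels))
    bad <- setdiff(unique(class), c("epigean", "interstitial",
                                    "subterranean"))
    if (length(bad)) stop("unknown habitat class: ", bad[1L])
  }
  if (!is.null(valley)) stopifnot(length(valley) == length(labels))
  structure(list(labels = labels, class = class, valley = valley,
                 n_states = length(labels)),
            class = "trait_space")
}

#' @export
print.trait_space <- function(x, ...) {
  cat("Trait state space with", x$n_states, "states:",
      paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Palaeovalley-structured habitat state space and transition mask
#'
#' States: one epigean state, one interstitial and one subterranean state
#' per palaeovalley. The rate-index matrix encodes which transitions are
#' permitted and ties rates by class pair (0 = forbidden; equal positive
#' indices share one rate):
#' rate 1 epigean -> interstitial, rate 2 interstitial -> epigean,
#' rate 3 epigean -> subterranean, rate 4 interstitial -> subterranean
#' (same palaeovalley only). Subterranean states are absorbing by default
#' (underground specialization is treated as irreversible); dispersal of
#' subterranean or interstitial lineages between different palaeovalleys
#' is forbidden.
#'
#' @param palaeovalleys vector of unique palaeovalley ids.
#' @param allow_subterranean_exit permit subterranean -> epigean reversals
#'   (adds tied rate class 5); default `FALSE`, for sensitivity analyses.
#' @param direct_colonization permit direct epigean -> subterranean
#'   transitions (default `TRUE`); when `FALSE` groundwater is reachable
#'   only through the interstitial.
#' @return list with `space` (a [trait_space()]) and `rate_index`
#'   (integer matrix; its `> 0` entries are the boolean transition mask).
#' @export
build_habitat_space <- function(palaeovalleys,
                                allow_subterranean_exit = FALSE,
                                direct_colonization = TRUE) {
  pv <- as.character(palaeovalleys)
  if (!length(pv)) stop("need at least one palaeovalley")
  if (anyDuplicated(pv)) stop("duplicate palaeovalley ids")
  labels <- c("epigean", paste0("interstitial:", pv),
              paste0("subterranean:", pv))
  cls <- c("epigean", rep("interstitial", length(pv)),
           rep("subterranean", length(pv)))
  val <- c(NA, pv, pv)
  space <- trait_space(labels, cls, val)
  n <- length(labels)
  ri <- matrix(0L, n, n, dimnames = list(labels, labels))
  epi <- 1L
  int_i <- 1L + seq_along(pv)
  sub_i <- 1L + length(pv) + seq_along(pv)
  ri[epi, int_i] <- 1L
  ri[int_i, epi] <- 2L
  if (direct_colonization) ri[epi, sub_i] <- 3L
  ri[cbind(int_i, sub_i)] <- 4L             # same palaeovalley only
  if (allow_subterranean_exit) ri[sub_i, epi] <- 5L
  diag(ri) <- 0L
  list(space = space, rate_index = ri)
}

#' Five-band altitude state space with an unconstrained ARD rate index
#'
#' Bands of maximum altitude (m): `<=1000`, `1001-2000`, `2001-3000`,
#' `3001-4000`, `>4000`; every ordered pair gets its own free rate.
#'
#' @return list with `space` and `rate_index` (20 free rates).
#' @export
build_altitude_space <- function() {
  labels <- c("<=1000", "1001-2000", "2001-3000", "3001-4000", ">4000")
  space <- trait_space(labels)
  n <- 5L
  ri <- matrix(0L, n, n, dimnames = list(labels, labels))
  ri[row(ri) != col(ri)] <- seq_len(n * n - n)
  list(space = space, rate_index = ri)
}

#' Assemble a rate matrix from a rate-index matrix and rate values
#'
#' @param rates numeric vector, one value per distinct positive index.
#' @param rate_index integer matrix (0 = fixed at zero).
#' @return rate matrix with rows summing to zero.
#' @export
mk_Q <- function(rates, rate_index) {
  if (any(rates < 0)) stop("rates must be >= 0")
  k <- max(rate_index)
  if (length(rates) != k)
    stop("need ", k, " rates, got ", length(rates))
  Q <- matrix(0, nrow(rate_index), ncol(rate_index),
              dimnames = dimnames(rate_index))
  pos <- which(rate_index > 0, arr.ind = TRUE)
  Q[pos] <- rates[rate_index[pos]]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Root prior over trait states
#'
#' @param space a [trait_space()].
#' @param type one of `"flat"`, `"stationary"`, `"fixed"`, `"restricted"`.
#' @param states state label (for `fixed`) or labels (for `restricted`).
#' @param Q rate matrix, required for `"stationary"`.
#' @return numeric probability vector over the states.
#' @export
root_prior <- function(space, type = c("flat", "stationary", "fixed",
                                       "restricted"),
                       states = NULL, Q = NULL) {
  type <- match.arg(type)
  n <- space$n_states
  pr <- switch(type,
    flat = rep(1 / n, n),
    stationary = {
      if (is.null(Q)) stop("stationary prior needs Q")
      ns <- MASS_null(t(Q))
      p <- abs(ns); p / sum(p)
    },
    fixed = {
      i <- match(states, space$labels)
      if (is.na(i)) stop("unknown state: ", states)
      p <- numeric(n); p[i] <- 1; p
    },
    restricted = {
      i <- match(states, space$labels)
      if (anyNA(i)) stop("unknown state in restriction")
      p <- numeric(n); p[i] <- 1 / length(i); p
    })
  names(pr) <- space$labels
  pr
}

# one vector spanning the null space of M (for the stationary distribution)
MASS_null <- function(M) {
  sv <- svd(M)
  sv$v[, ncol(sv$v)]
}

# tip conditional-likelihood matrix from coded states; ambiguity coded as
# "a|b" gets likelihood 1 on each listed state
tip_likelihoods <- function(phy, tip_states, space) {
  n_tip <- length(phy$tip.label)
  if (is.null(names(tip_states))) stop("tip states must be named")
  miss <- setdiff(phy$tip.label, names(tip_states))
  if (length(miss)) stop("tips without state: ",
                         paste(miss, collapse = ", "))
  L <- matrix(0, n_tip, space$n_states)
  for (i in seq_len(n_tip)) {
    parts <- strsplit(tip_states[[phy$tip.label[i]]], "|", fixed = TRUE)[[1]]
    idx <- match(parts, space$labels)
    if (anyNA(idx)) stop("tip state not in space: ",
                         parts[is.na(idx)][1L], " (tip ",
                         phy$tip.label[i], ")")
    L[i, idx] <- 1
  }
  L
}

# pruning up-pass for the Mk model; returns D, E per edge, loglik
mk_uppass <- function(phy, tipL, Q, prior) {
  n_tip <- nrow(tipL); ns <- ncol(tipL)
  n_node <- n_tip + phy$Nnode
  prop <- make_propagator(Q)
  edge <- phy$edge
  Pedge <- lapply(seq_len(nrow(edge)),
                  function(i) prop(phy$edge.length[i]))
  D <- matrix(0, n_node, ns)
  D[seq_len(n_tip), ] <- tipL
  logscale <- numeric(n_node)
  po <- ape::reorder.phylo(phy, "postorder")$edge
  E <- vector("list", nrow(edge))
  done <- rep(FALSE, n_node)
  for (i in seq_len(nrow(po))) {
    par <- po[i, 1L]
    if (done[par]) next
    rows <- which(edge[, 1L] == par)
    Dp <- rep(1, ns)
    for (r in rows) {
      Er <- as.numeric(Pedge[[r]] %*% D[edge[r, 2L], ])
      E[[r]] <- Er
      Dp <- Dp * Er
    }
    sc <- max(Dp)
    if (sc > 0) { Dp <- Dp / sc; logscale[par] <- log(sc) }
    D[par, ] <- Dp
    done[par] <- TRUE
  }
  root <- n_tip + 1L
  lik <- sum(prior * D[root, ])
  loglik <- if (lik <= 0) -Inf else log(lik) + sum(logscale)
  list(D = D, E = E, Pedge = Pedge, logscale = logscale, loglik = loglik,
       prior = prior, edge = edge, n_tip = n_tip)
}

#' Log-likelihood of a discrete trait under a fixed rate matrix
#'
#' Standard Felsenstein pruning for a continuous-time Markov chain on the
#' tree, with an arbitrary root prior. Tip ambiguity is coded as
#' `"state1|state2"`.
#'
#' @param phy validated `phylo`.
#' @param tip_states named character vector of state labels.
#' @param Q rate matrix over the space (rows sum to 0; forbidden
#'   transitions already masked to 0).
#' @param space a [trait_space()].
#' @param prior root prior vector (see [root_prior()]); default flat.
#' @return log-likelihood.
#' @export
mk_loglik <- function(phy, tip_states, Q, space,
                      prior = root_prior(space, "flat")) {
  validate_timetree(phy)
  tipL <- tip_likelihoods(phy, tip_states, space)
  mk_uppass(phy, tipL, Q, prior)$loglik
}

#' Marginal ancestral state probabilities for a discrete trait
#'
#' @inheritParams mk_loglik
#' @return list with `marginals` (internal nodes x states, rows sum to 1,
#'   row 1 = root) and `loglik`.
#' @export
marginal_ancestral_states <- function(phy, tip_states, Q, space,
                                      prior = root_prior(space, "flat")) {
  validate_timetree(phy)
  tipL <- tip_likelihoods(phy, tip_states, space)
  up <- mk_uppass(phy, tipL, Q, prior)
  ns <- ncol(tipL); n_tip <- up$n_tip
  root <- n_tip + 1L
  n_node <- n_tip + phy$Nnode
  Fnode <- matrix(0, n_node, ns)
  Fnode[root, ] <- prior
  marg <- matrix(0, phy$Nnode, ns, dimnames = list(NULL, space$labels))
  m0 <- prior * up$D[root, ]
  marg[1L, ] <- m0 / sum(m0)
  pre <- ape::reorder.phylo(phy, "cladewise")$edge
  edge <- up$edge
  for (i in seq_len(nrow(pre))) {
    par <- pre[i, 1L]; v <- pre[i, 2L]
    if (v <= n_tip) next
    r_v <- which(edge[, 1L] == par & edge[, 2L] == v)
    sibs <- which(edge[, 1L] == par & edge[, 2L] != v)
    Ftop <- Fnode[par, ]
    for (r in sibs) Ftop <- Ftop * up$E[[r]]
    Fv <- as.numeric(crossprod(up$Pedge[[r_v]], Ftop))
    if (sum(Fv) > 0) Fv <- Fv / sum(Fv)
    Fnode[v, ] <- Fv
    m <- Fv * up$D[v, ]
    marg[v - n_tip, ] <- m / sum(m)
  }
  list(marginals = marg, loglik = up$loglik)
}
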