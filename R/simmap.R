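#' Stochastic character maps under a fixed rate matrix
#'
#' Samples complete trait histories conditional on the tip data: node
#' states are drawn from their joint conditional distribution (root from
#' the prior times its partial likelihood, then each child given its
#' parent), and each branch path is drawn exactly from the
#' endpoint-conditioned chain by uniformization. Histories therefore never
#' contain transitions whose rate is zero.
#'
#' @inheritParams mk_loglik
#' @param n_sims number of histories (default 1000).
#' @param seed optional integer seed for reproducibility.
#' @return object of class `simmap_histories`: list of histories, each
#'   with `node_states` (named by ape node number) and `maps` (per edge of
#'   `phy$edge`, a named numeric vector of segment durations ordered
#'   parent to child, names = states).
#' @export
simmap_sample <- function(phy, tip_states, Q, space,
                          prior = root_prior(space, "flat"),
                          n_sims = 1000, seed = NULL) {
  stopifnot(n_sims >= 1)
  if (!is.null(seed)) set.seed(seed)
  validate_timetree(phy)
  tipL <- tip_likelihoods(phy, tip_states, space)
  up <- mk_uppass(phy, tipL, Q, prior)
  if (!is.finite(up$loglik))
    stop("data have zero likelihood under Q; cannot condition")
  ns <- ncol(tipL); n_tip <- up$n_tip
  edge <- up$edge
  root <- n_tip + 1L
  pre <- ape::reorder.phylo(phy, "cladewise")$edge
  ps <- make_path_sampler(Q)
  histories <- vector("list", n_sims)
  root_p <- prior * up$D[root, ]
  root_p <- root_p / sum(root_p)
  for (h in seq_len(n_sims)) {
    node_state <- integer(n_tip + phy$Nnode)
    node_state[root] <- sample.int(ns, 1L, prob = root_p)
    maps <- vector("list", nrow(edge))
    for (i in seq_len(nrow(pre))) {
      par <- pre[i, 1L]; v <- pre[i, 2L]
      r <- which(edge[, 1L] == par & edge[, 2L] == v)
      s_par <- node_state[par]
      pk <- up$Pedge[[r]][s_par, ] * up$D[v, ]
      if (sum(pk) <= 0)
        stop("conditional sampling failed on edge to node ", v)
      s_v <- sample.int(ns, 1L, prob = pk / sum(pk))
      node_state[v] <- s_v
      path <- ps(s_par, s_v, phy$edge.length[r])
      names(path) <- space$labels[as.integer(names(path))]
      maps[[r]] <- path
    }
    histories[[h]] <- list(node_states = node_state, maps = maps)
  }
  structure(list(histories = histories, space = space, phy = phy,
                 Q = Q, n_sims = n_sims),
            class = "simmap_histories")
}

#' @export
print.simmap_histories <- function(x, ...) {
  cat("simmap_histories:", x$n_sims, "stochastic maps over",
      x$space$n_states, "states on", length(x$phy$tip.label), "tips\n")
  invisible(x)
}

# endpoint-conditioned CTMC path sampler by uniformization.
# Returns function(a, b, t) -> named numeric (names = state indices,
# values = durations, parent to child, adjacent states differ).
make_path_sampler <- function(Q) {
  n <- nrow(Q)
  Om <- max(-diag(Q))
  if (Om <= 0) {
    return(function(a, b, t) {
      if (a != b) stop("zero-rate chain cannot connect differing endpoints")
      stats::setNames(t, a)
    })
  }
  R <- diag(n) + Q / Om
  pows <- list(diag(n), R)        # R^0, R^1
  get_pow <- function(m) {        # R^m
    while (length(pows) < m + 1L)
      pows[[length(pows) + 1L]] <<- pows[[length(pows)]] %*% R
    pows[[m + 1L]]
  }
  function(a, b, t) {
    lt <- Om * t
    nmax <- max(10L, stats::qpois(1 - 1e-12, lt) + 5L)
    get_pow(nmax)
    pn <- stats::dpois(0:nmax, lt) *
      vapply(0:nmax, function(m) pows[[m + 1L]][a, b], 0)
    tot <- sum(pn)
    if (tot <= 0) stop("endpoint-conditioned sampling failed (a=", a,
                       ", b=", b, ", t=", t, ")")
    nj <- sample.int(nmax + 1L, 1L, prob = pn) - 1L
    if (nj == 0L) return(stats::setNames(t, a))
    jumps <- sort(stats::runif(nj, 0, t))
    s <- integer(nj + 1L); s[1L] <- a
    for (k in seq_len(nj)) {
      rem <- nj - k
      pk <- R[s[k], ] * get_pow(rem)[, b]
      s[k + 1L] <- sample.int(n, 1L, prob = pk)
    }
    # collapse virtual (self) jumps into dwell segments
    bounds <- c(0, jumps, t)
    keep <- c(TRUE, diff(s) != 0L)
    starts <- bounds[-length(bounds)][keep]
    states <- s[keep]
    durations <- diff(c(starts, t))
    stats::setNames(durations, states)
  }
}

#' Count groundwater colonizations and subterranean speciation events
#'
#' Reads a set of stochastic maps over a palaeovalley-structured habitat
#' space and counts, per history: transitions into the subterranean class
#' (from any non-subterranean state), transitions into the interstitial
#' class, subterranean speciation events (internal nodes whose own state
#' and both daughters' initial branch states are subterranean), and the
#' subset of those where node and daughters share one palaeovalley.
#' Summaries across histories are medians with 2.5/97.5 percentiles.
#'
#' @param maps a [simmap_sample()] result over a structured habitat space.
#' @param rate_index optional integrity check: error if any observed
#'   transition has index 0 (masked).
#' @return object of class `colonization_summary` with per-history
#'   `counts` and a `summary` table.
#' @export
count_colonizations <- function(maps, rate_index = NULL) {
  space <- maps$space
  if (is.null(space$class))
    stop("colonization counting needs a class-structured habitat space")
  cls <- space$class; val <- space$valley
  phy <- maps$phy
  edge <- phy$edge
  n_tip <- length(phy$tip.label)
  internal <- n_tip + seq_len(phy$Nnode)
  counts <- t(vapply(maps$histories, function(hst) {
    sub_in <- 0L; int_in <- 0L
    for (m in hst$maps) {
      st <- match(names(m), space$labels)
      if (!is.null(rate_index) && length(st) > 1L) {
        from <- st[-length(st)]; to <- st[-1L]
        if (any(rate_index[cbind(from, to)] == 0L))
          stop("history contains a masked transition: ",
               space$labels[from[rate_index[cbind(from, to)] == 0L][1L]])
      }
      if (length(st) > 1L) {
        from <- st[-length(st)]; to <- st[-1L]
        sub_in <- sub_in +
          sum(cls[to] == "subterranean" & cls[from] != "subterranean")
        int_in <- int_in +
          sum(cls[to] == "interstitial" & cls[from] != "interstitial")
      }
    }
    spec <- 0L; spec_pv <- 0L
    for (nd in internal) {
      rows <- which(edge[, 1L] == nd)
      s_node <- hst$node_states[nd]
      d_init <- vapply(rows, function(r)
        match(names(hst$maps[[r]])[1L], space$labels), 0L)
      trio <- c(s_node, d_init)
      if (all(cls[trio] == "subterranean")) {
        spec <- spec + 1L
        if (length(unique(val[trio])) == 1L) spec_pv <- spec_pv + 1L
      }
    }
    c(subterranean_entries = sub_in, interstitial_entries = int_in,
      subterranean_speciation = spec,
      within_palaeovalley_speciation = spec_pv)
  }, c(subterranean_entries = 0L, interstitial_entries = 0L,
       subterranean_speciation = 0L, within_palaeovalley_speciation = 0L)))
  qs <- apply(counts, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975))
  summary <- data.frame(statistic = colnames(counts),
                        median = qs["50%", ],
                        lower95 = qs["2.5%", ],
                        upper95 = qs["97.5%", ],
                        row.names = NULL)
  structure(list(counts = counts, summary = summary,
                 n_histories = nrow(counts)),
            class = "colonization_summary")
}

#' @export
print.colonization_summary <- function(x, ...) {
  cat("Colonization summary over", x$n_histories, "stochastic maps\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Export stochastic maps as a TSV event log
#'
#' One row per state change: edge (ape child-node number), time from the
#' parent node (Ma along the branch), source and target states.
#'
#' @param maps a [simmap_sample()] result.
#' @param path optional output path; the data.frame is returned invisibly
#'   (or visibly when `path` is `NULL`).
#' @export
simmap_event_log <- function(maps, path = NULL) {
  rows <- list()
  for (h in seq_along(maps$histories)) {
    hst <- maps$histories[[h]]
    for (r in seq_along(hst$maps)) {
      m <- hst$maps[[r]]
      if (length(m) < 2L) next
      tfp <- cumsum(m)[-length(m)]
      rows[[length(rows) + 1L]] <- data.frame(
        history = h, edge_child = maps$phy$edge[r, 2L],
        time_from_parent = as.numeric(tfp),
        from_state = names(m)[-length(m)], to_state = names(m)[-1L])
    }
  }
  log <- if (length(rows)) do.call(rbind, rows) else
    data.frame(history = integer(0), edge_child = integer(0),
               time_from_parent = numeric(0), from_state = character(0),
               to_state = character(0))
  if (!is.null(path)) {
    utils::write.table(log, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(log))
  }
  log
}
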