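#' Simulate a dated birth-death tree conditioned on its tip count
#'
#' Forward (Gillespie) simulation from two crown lineages. Events are
#' applied until the next birth would raise the extant count above
#' `n_tips`; the simulation stops at that event's time, so under a pure
#' birth process the expected crown age is `sum_{k=2}^{n} 1/(k*lambda)`.
#' Attempts in which the clade dies out are rejected and redrawn
#' (simple rejection conditioning on survival). Extinct side branches are
#' pruned, so the returned tree is ultrametric with exactly `n_tips`
#' extant tips.
#'
#' @param birth_rate,death_rate per-lineage rates (events/Ma),
#'   `birth_rate > death_rate >= 0`.
#' @param n_tips number of extant tips (`>= 2`).
#' @param seed optional integer seed.
#' @param root_age optional target crown age (Ma); the tree is rescaled.
#' @param max_retries rejection budget for total extinction.
#' @return list with `phy` (validated `phylo`) and `truth` (generating
#'   parameters, seed, number of rejected attempts).
#' @export
simulate_bd_tree <- function(birth_rate, death_rate = 0, n_tips,
                             seed = NULL, root_age = NULL,
                             max_retries = 1000L) {
  if (!(birth_rate > death_rate) || death_rate < 0)
    stop("need birth_rate > death_rate >= 0")
  if (n_tips < 2L) stop("need n_tips >= 2")
  if (!is.null(seed)) set.seed(seed)
  rejected <- 0L
  repeat {
    res <- bd_forward_once(birth_rate, death_rate, n_tips)
    if (!is.null(res)) break
    rejected <- rejected + 1L
    if (rejected > max_retries)
      stop("total extinction in every attempt (", max_retries,
           " retries)")
  }
  phy <- res
  if (!is.null(root_age)) phy <- rescale_tree_age(phy, root_age)
  phy <- validate_timetree(phy)
  list(phy = phy,
       truth = list(birth_rate = birth_rate, death_rate = death_rate,
                    n_tips = n_tips, seed = seed, rejected = rejected,
                    root_age = root_age))
}

# one forward attempt; NULL on extinction
bd_forward_once <- function(b, d, n_tips) {
  # lineage records
  start <- c(0, 0); end <- c(NA_real_, NA_real_)
  kid1 <- c(0L, 0L); kid2 <- c(0L, 0L)
  dead <- logical(2)
  active <- c(1L, 2L)
  t <- 0
  repeat {
    k <- length(active)
    if (k == 0L) return(NULL)
    rate <- k * (b + d)
    dt <- stats::rexp(1L, rate)
    is_birth <- stats::runif(1L) < b / (b + d + (b + d == 0))
    if (d == 0) is_birth <- TRUE
    if (is_birth && k == n_tips) { t <- t + dt; break }
    t <- t + dt
    who <- active[sample.int(k, 1L)]
    end[who] <- t
    if (is_birth) {
      id1 <- length(start) + 1L; id2 <- id1 + 1L
      start <- c(start, t, t); end <- c(end, NA_real_, NA_real_)
      kid1 <- c(kid1, 0L, 0L); kid2 <- c(kid2, 0L, 0L)
      dead <- c(dead, FALSE, FALSE)
      kid1[who] <- id1; kid2[who] <- id2
      active <- c(setdiff(active, who), id1, id2)
    } else {
      dead[who] <- TRUE
      active <- setdiff(active, who)
    }
  }
  end[active] <- t
  phy <- lineages_to_phylo(start, end, kid1, kid2, dead)
  if (length(phy$tip.label) != n_tips) return(NULL)
  phy
}

# convert lineage records (crown lineages 1 and 2) to a pruned phylo
lineages_to_phylo <- function(start, end, kid1, kid2, dead) {
  is_leaf <- kid1 == 0L
  n_all <- sum(is_leaf)
  tip_no <- integer(length(start)); node_no <- integer(length(start))
  tip_ct <- 0L; node_ct <- n_all + 1L   # crown node gets n_all + 1
  edges <- matrix(0L, 0L, 2L); elen <- numeric(0)
  labels <- character(0); drop <- character(0)
  assign_no <- function(L) {
    if (is_leaf[L]) {
      tip_ct <<- tip_ct + 1L
      tip_no[L] <<- tip_ct
      labels <<- c(labels, paste0("t", tip_ct))
      if (dead[L]) drop <<- c(drop, paste0("t", tip_ct))
      tip_ct
    } else {
      node_ct <<- node_ct + 1L
      node_no[L] <<- node_ct
      node_ct
    }
  }
  walk <- function(L, parent_no) {
    my <- assign_no(L)
    edges <<- rbind(edges, c(parent_no, my))
    elen <<- c(elen, end[L] - start[L])
    if (!is_leaf[L]) {
      walk(kid1[L], my)
      walk(kid2[L], my)
    }
  }
  root_no <- n_all + 1L
  walk(1L, root_no); walk(2L, root_no)
  phy <- list(edge = edges, edge.length = elen, tip.label = labels,
              Nnode = n_all - 1L)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  if (length(drop)) phy <- ape::drop.tip(phy, drop)
  phy$tip.label <- paste0("t", seq_along(phy$tip.label))
  phy
}

#' Forward-simulate geographic ranges along a tree under a DEC model
#'
#' Exact stochastic simulation of the anagenetic process (per-stratum rate
#' matrices, Gillespie within each branch segment, oldest segment first)
#' with cladogenetic daughter ranges drawn from the cladogenesis
#' distribution at each internal node. The two basal lineages inherit the
#' root range (matching the default likelihood model). Lineages hitting
#' the null range stay there; datasets containing null-range tips are
#' flagged, and optionally redrawn.
#'
#' @inheritParams dec_loglik
#' @param root_range range label at the root (e.g. `"B"`).
#' @param seed optional integer seed.
#' @param redraw_null redraw datasets with null-range tips (default
#'   `FALSE`; the flag is reported either way).
#' @param max_retries redraw budget.
#' @return list with `geog` (a [geography()] matrix; `NULL` if a null
#'   tip survived), `tip_ranges` (labels incl. `"0"`), and `truth`
#'   (node states, per-edge daughter start states and event lists, flags).
#' @export
simulate_dec_tips <- function(phy, params, dispersal, family = "DEC",
                              root_range, seed = NULL,
                              max_range_size = length(dispersal$areas),
                              scale_jump = TRUE, redraw_null = FALSE,
                              max_retries = 100L) {
  if (!inherits(params, "dec_params")) params <- do.call(dec_params, params)
  if (!is.null(seed)) set.seed(seed)
  validate_timetree(phy)
  states <- range_states(dispersal$areas, max_range_size)
  Qs <- lapply(dispersal$matrices, function(m)
    build_anagenetic_Q(params, states, m))
  ctabs <- lapply(dispersal$matrices, function(m)
    clado_table(states, family, params, m, scale_jump))
  ages <- node_ages(phy)
  strat <- dispersal$strat
  stratum_of_age <- function(a) sum(strat$boundaries >= a - 1e-12) + 1L
  root_idx <- state_index_label(states, root_range)
  n_tip <- length(phy$tip.label)
  edge <- phy$edge
  pre <- ape::reorder.phylo(phy, "cladewise")$edge
  seg_list <- lapply(seq_len(nrow(edge)), function(i) {
    sg <- slice_branch_by_strata(ages[edge[i, 1L]], ages[edge[i, 2L]],
                                 strat)
    list(stratum = sg$stratum, duration = sg$duration, n = nrow(sg))
  })
  edge_row_of <- integer(max(edge)); edge_row_of[edge[, 2L]] <-
    seq_len(nrow(edge))
  tries <- 0L
  repeat {
    node_state <- integer(n_tip + phy$Nnode)
    node_state[n_tip + 1L] <- root_idx
    start_state <- integer(nrow(edge))   # daughter state at top of edge
    events <- vector("list", nrow(edge))
    # assign daughter start states at the root (inherited)
    for (i in seq_len(nrow(pre))) {
      par <- pre[i, 1L]; v <- pre[i, 2L]
      r <- edge_row_of[v]
      if (par == n_tip + 1L) {
        start_state[r] <- node_state[par]
      } else if (start_state[r] == 0L) {
        # cladogenesis at par already sampled when par was reached
        stop("internal error: unassigned daughter state")
      }
      # anagenesis along the branch (events recorded as flat vectors)
      s <- start_state[r]
      segs <- seg_list[[r]]
      age_now <- ages[par]
      ev_age <- numeric(0); ev_from <- integer(0); ev_to <- integer(0)
      for (k in seq_len(segs$n)) {
        Q <- Qs[[segs$stratum[k]]]
        rem <- segs$duration[k]
        repeat {
          rate <- -Q[s, s]
          if (rate <= 0) break
          dt <- stats::rexp(1L, rate)
          if (dt > rem) break
          rem <- rem - dt; age_now <- age_now - dt
          p <- Q[s, ]; p[s] <- 0
          s_new <- sample.int(states$n_states, 1L, prob = p)
          ev_age <- c(ev_age, age_now)
          ev_from <- c(ev_from, s); ev_to <- c(ev_to, s_new)
          s <- s_new
        }
        age_now <- age_now - rem
      }
      events[[r]] <- if (length(ev_age))
        data.frame(age = ev_age, from = states$labels[ev_from],
                   to = states$labels[ev_to]) else NULL
      node_state[v] <- s
      # cladogenesis at v (if internal and nonempty)
      if (v > n_tip) {
        kid_rows <- which(edge[, 1L] == v)
        if (states$sizes[s] == 0) {
          start_state[kid_rows] <- s
        } else {
          ct <- ctabs[[stratum_of_age(ages[v])]][[s]]
          pick <- sample.int(length(ct$prob), 1L, prob = ct$prob)
          start_state[kid_rows[1L]] <- ct$left[pick]
          start_state[kid_rows[2L]] <- ct$right[pick]
        }
      }
    }
    tip_idx <- node_state[seq_len(n_tip)]
    has_null <- any(states$sizes[tip_idx] == 0)
    if (!has_null || !redraw_null) break
    tries <- tries + 1L
    if (tries > max_retries)
      stop("null-range tips in every redraw (", max_retries, " retries)")
  }
  tip_ranges <- stats::setNames(states$labels[tip_idx], phy$tip.label)
  geog <- if (has_null) NULL else {
    m <- states$bits[tip_idx, , drop = FALSE]
    rownames(m) <- phy$tip.label
    geography(m * 1L)
  }
  list(geog = geog, tip_ranges = tip_ranges,
       truth = list(params = params, family = family, seed = seed,
                    root_range = root_range, node_states =
                      stats::setNames(states$labels[node_state],
                                      seq_along(node_state)),
                    start_states = states$labels[start_state],
                    events = events, has_null_tip = has_null,
                    redraws = tries))
}

#' Forward-simulate a discrete trait along a tree
#'
#' Gillespie simulation under a fixed rate matrix from a given root
#' state; both daughters inherit the parent's state at each node. Truth
#' records every transition with the age at which it occurred.
#'
#' @inheritParams mk_loglik
#' @param root_state state label at the root.
#' @param seed optional integer seed.
#' @return list with `tip_states` (named labels) and `truth` (per-edge
#'   event data.frames, per-node states, dwell-time totals per state).
#' @export
simulate_mk_tips <- function(phy, Q, space, root_state, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_timetree(phy)
  ns <- space$n_states
  stopifnot(nrow(Q) == ns, ncol(Q) == ns)
  ages <- node_ages(phy)
  n_tip <- length(phy$tip.label)
  edge <- phy$edge
  pre <- ape::reorder.phylo(phy, "cladewise")$edge
  node_state <- integer(n_tip + phy$Nnode)
  node_state[n_tip + 1L] <- match(root_state, space$labels)
  if (is.na(node_state[n_tip + 1L]))
    stop("unknown root state: ", root_state)
  events <- vector("list", nrow(edge))
  dwell <- stats::setNames(numeric(ns), space$labels)
  edge_row_of <- integer(max(edge))
  edge_row_of[edge[, 2L]] <- seq_len(nrow(edge))
  for (i in seq_len(nrow(pre))) {
    par <- pre[i, 1L]; v <- pre[i, 2L]
    r <- edge_row_of[v]
    s <- node_state[par]
    rem <- phy$edge.length[r]
    age_now <- ages[par]
    ev_age <- numeric(0); ev_from <- integer(0); ev_to <- integer(0)
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) { dwell[s] <- dwell[s] + rem; break }
      dt <- stats::rexp(1L, rate)
      if (dt > rem) { dwell[s] <- dwell[s] + rem; break }
      dwell[s] <- dwell[s] + dt
      rem <- rem - dt; age_now <- age_now - dt
      p <- Q[s, ]; p[s] <- 0
      s_new <- sample.int(ns, 1L, prob = p)
      ev_age <- c(ev_age, age_now)
      ev_from <- c(ev_from, s); ev_to <- c(ev_to, s_new)
      s <- s_new
    }
    events[[r]] <- if (length(ev_age))
      data.frame(age = ev_age, from = space$labels[ev_from],
                 to = space$labels[ev_to]) else NULL
    node_state[v] <- s
  }
  tip_states <- stats::setNames(space$labels[node_state[seq_len(n_tip)]],
                                phy$tip.label)
  list(tip_states = tip_states,
       truth = list(root_state = root_state, seed = seed,
                    node_states = space$labels[node_state],
                    events = events, dwell = dwell))
}

#' Simulate a coding alignment with planned deleterious lesions
#'
#' Builds a clean reference open reading frame (ATG start, random
#' non-stop codons, single terminal stop), copies it to the other
#' sequences, and injects exactly the planned lesions: a
#' `premature_stop` replaces the target codon with `TAA`; a `frameshift`
#' deletes `detail` bases (default 1) at the target codon's start,
#' represented as gaps. No other differences are introduced, so the
#' detectors' output on the fixture is exactly the plan.
#'
#' @param n_seqs number of sequences (first is the reference, id `ref`;
#'   others `seq2`, `seq3`, ...).
#' @param n_codons reference length in codons (>= 4).
#' @param lesion_plan data.frame with columns `seq`, `kind`
#'   (`"premature_stop"` / `"frameshift"`), `codon`, and optional
#'   `detail` (frameshift deletion length, default 1). `NULL` = clean.
#' @param seed optional integer seed.
#' @return list with `aln` (a [coding_alignment()]) and `truth` (the
#'   normalized plan with expected call columns).
#' @export
simulate_coding_alignment <- function(n_seqs, n_codons,
                                      lesion_plan = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_seqs >= 1, n_codons >= 4)
  stops <- c("TAA", "TAG", "TGA")
  all_codons <- apply(expand.grid(c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T")), 1L,
                      paste, collapse = "")
  safe <- setdiff(all_codons, stops)
  body <- sample(safe, n_codons - 2L, replace = TRUE)
  ref <- c("ATG", body, "TAA")
  ids <- c("ref", if (n_seqs > 1L) paste0("seq", 2:n_seqs))
  seqs <- stats::setNames(rep(paste(ref, collapse = ""), n_seqs), ids)
  truth <- empty_calls()
  if (!is.null(lesion_plan) && nrow(lesion_plan)) {
    if (is.null(lesion_plan$detail)) lesion_plan$detail <- 1L
    lesion_plan$detail[is.na(lesion_plan$detail)] <- 1L
    for (i in seq_len(nrow(lesion_plan))) {
      id <- as.character(lesion_plan$seq[i])
      kind <- as.character(lesion_plan$kind[i])
      ci <- as.integer(lesion_plan$codon[i])
      if (!id %in% ids || id == "ref")
        stop("lesion plan names an invalid sequence: ", id)
      if (ci < 1L || ci > n_codons) stop("lesion codon out of range")
      s <- strsplit(seqs[[id]], "")[[1]]
      col1 <- (ci - 1L) * 3L + 1L
      if (kind == "premature_stop") {
        if (ci >= n_codons)
          stop("premature stop cannot be planned at the terminal codon")
        if (ci == 1L) stop("cannot replace the start codon with a stop")
        s[col1:(col1 + 2L)] <- c("T", "A", "A")
        truth <- rbind(truth, data.frame(
          seq = id, kind = kind, column = col1, codon = ci,
          detail = "TAA", post_frameshift = NA))
      } else if (kind == "frameshift") {
        len <- as.integer(lesion_plan$detail[i])
        if (len < 1L || col1 + len - 1L > length(s))
          stop("frameshift run out of range")
        s[col1:(col1 + len - 1L)] <- "-"
        if (len %% 3L != 0L)
          truth <- rbind(truth, data.frame(
            seq = id, kind = kind, column = col1, codon = ci,
            detail = as.character(len %% 3L), post_frameshift = FALSE))
      } else stop("unknown lesion kind: ", kind)
      seqs[[id]] <- paste(s, collapse = "")
    }
  }
  aln <- coding_alignment(seqs, reference = "ref")
  list(aln = aln, truth = truth[order(truth$seq, truth$column), ,
                                drop = FALSE])
}
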