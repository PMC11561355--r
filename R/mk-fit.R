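#' Maximum-likelihood fit of a constrained all-rates-different Mk model
#'
#' Free rates are defined by the rate-index matrix (0 = forbidden, shared
#' positive index = tied); each is optimized on the log scale by
#' `L-BFGS-B` from a fixed, deterministic start grid (all rates equal to
#' 0.01, 0.1 or 1 per unit time; best two screened starts refined).
#' Masked entries are exactly zero in the fitted matrix.
#'
#' @inheritParams mk_loglik
#' @param rate_index integer matrix over the states (see
#'   [build_habitat_space()], [build_altitude_space()]).
#' @param prior root prior vector, or the string `"stationary"` to
#'   recompute the stationary distribution of each candidate `Q`.
#' @param n_refine screened starts to polish (default 2).
#' @param aicc_n AICc sample size; defaults to the number of tips.
#' @return object of class `mk_fit`.
#' @export
fit_ard <- function(phy, tip_states, rate_index, space,
                    prior = root_prior(space, "flat"),
                    n_refine = 2L, aicc_n = length(phy$tip.label)) {
  validate_timetree(phy)
  k <- max(rate_index)
  if (k < 1L) stop("rate_index allows no transitions")
  tipL <- tip_likelihoods(phy, tip_states, space)
  obs <- unique(unlist(lapply(seq_len(nrow(tipL)),
                              function(i) which(tipL[i, ] > 0))))
  if (length(obs) < 2L) stop("need at least 2 observed states")
  stationary <- identical(prior, "stationary")
  nll <- function(lx) {
    Q <- mk_Q(exp(lx), rate_index)
    pr <- if (stationary) root_prior(space, "stationary", Q = Q) else prior
    ll <- tryCatch(mk_uppass(phy, tipL, Q, pr)$loglik,
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  starts <- lapply(c(0.01, 0.1, 1), function(r) rep(log(r), k))
  screened <- vapply(starts, nll, 0)
  ord <- order(screened)
  best <- NULL
  trace <- data.frame(start = ord[seq_len(min(n_refine, length(ord)))],
                      screen_nll = screened[ord][seq_len(min(n_refine,
                                                             length(ord)))],
                      refined_nll = NA_real_, convergence = NA_integer_)
  for (ii in seq_len(nrow(trace))) {
    o <- tryCatch(
      stats::optim(starts[[trace$start[ii]]], nll, method = "L-BFGS-B",
                   lower = rep(log(1e-8), k), upper = rep(log(100), k),
                   control = list(maxit = 300, factr = 1e9)),
      error = function(e) NULL)
    if (is.null(o)) next
    trace$refined_nll[ii] <- o$value
    trace$convergence[ii] <- o$convergence
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best) || best$value >= 1e10)
    stop("ARD optimization failed; best screened -lnL = ", min(screened))
  rates <- exp(best$par)
  Q <- mk_Q(rates, rate_index)
  pr <- if (stationary) root_prior(space, "stationary", Q = Q) else prior
  lnL <- -best$value
  structure(list(rates = rates, Q = Q, rate_index = rate_index,
                 space = space, prior = pr, lnL = lnL, k = k,
                 AICc = aicc(lnL, k, aicc_n), aicc_n = aicc_n,
                 phy = phy, tip_states = tip_states, trace = trace,
                 call = match.call()),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Constrained ARD Markov model:", x$space$n_states, "states,",
      x$k, "free rates\n")
  cat(sprintf("  lnL = %.4f   AICc = %.4f (n = %d tips)\n",
              x$lnL, x$AICc, x$aicc_n))
  cat("  rates:", paste(sprintf("q%d = %.6g", seq_along(x$rates),
                                x$rates), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.mk_fit <- function(object, ...)
  stats::setNames(object$rates, paste0("q", seq_along(object$rates)))

#' @export
logLik.mk_fit <- function(object, ...)
  structure(object$lnL, df = object$k, nobs = object$aicc_n,
            class = "logLik")

#' @export
summary.mk_fit <- function(object, ...) {
  print(object)
  cat("\nFitted rate matrix:\n")
  print(round(object$Q, 6))
  cat("\nOptimizer trace:\n")
  print(object$trace, row.names = FALSE)
  invisible(object)
}

#' @export
simulate.mk_fit <- function(object, nsim = 1, seed = NULL,
                            root_state = NULL, ...) {
  if (is.null(root_state))
    root_state <- object$space$labels[which.max(object$prior)]
  out <- lapply(seq_len(nsim), function(i)
    simulate_mk_tips(object$phy, object$Q, object$space,
                     root_state = root_state,
                     seed = if (is.null(seed)) NULL else seed + i - 1L))
  if (nsim == 1L) out[[1L]] else out
}

#' Read a tip trait table (TSV: `tip_label<TAB>state`)
#' @param path file path.
#' @return named character vector of state labels.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("tip", "state"),
                          colClasses = "character", quote = "")
  stats::setNames(df$state, df$tip)
}

#' Write a tip trait table
#' @param tip_states named character vector.
#' @param path output path.
#' @export
write_trait_table <- function(tip_states, path) {
  writeLines(paste0(names(tip_states), "\t", tip_states), path)
  invisible(path)
}
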