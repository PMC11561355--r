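#' Small-sample corrected Akaike information criterion
#'
#' `AICc = 2k - 2 lnL + 2k(k+1)/(n - k - 1)`; undefined when
#' `n <= k + 1`.
#'
#' @param lnL maximized log-likelihood.
#' @param k number of free parameters.
#' @param n sample size (here: number of tips).
#' @export
aicc <- function(lnL, k, n) {
  if (n <= k + 1) stop("AICc undefined: need n > k + 1 (n = ", n,
                       ", k = ", k, ")")
  2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
}

#' Declare a biogeographic hypothesis
#'
#' A hypothesis is a stratified dispersal-multiplier model (or `NULL` for
#' an unguided analysis: all multipliers 1, single stratum) plus whether
#' the multiplier exponent `w` is free.
#'
#' @param id short identifier, e.g. `"M0"`.
#' @param dispersal a [stratified_dispersal()] model or `NULL` (unguided).
#' @param w_free fit the `w` exponent? (only meaningful with multipliers).
#' @param description optional human-readable assumption text.
#' @export
hypothesis_spec <- function(id, dispersal = NULL, w_free = FALSE,
                            description = "") {
  if (is.null(dispersal) && w_free)
    stop("w is only free when a multiplier matrix is supplied")
  structure(list(id = id, dispersal = dispersal, w_free = w_free,
                 description = description), class = "hypothesis_spec")
}

# deterministic start grid, coarse screen, refine from the best `n_refine`
dec_start_grid <- function(free_j, free_w) {
  de <- c(0.01, 0.1, 1)
  g <- expand.grid(d = de, e = de)
  if (free_j) g <- merge(g, data.frame(j = c(0, 0.5)))
  if (free_w) g <- merge(g, data.frame(w = c(0.5, 1)))
  g
}

#' Maximum-likelihood fit of a DEC-family range model
#'
#' Fits `d` and `e` (always free), optionally the founder-event weight `j`
#' and the multiplier exponent `w`, by bounded quasi-Newton (`L-BFGS-B` on
#' log scale for `d`, `e`) from a fixed start grid: all grid points are
#' screened, the best two are refined, and the best refined optimum is
#' returned, so the fit is deterministic. Bounds: `d, e` in
#' `[1e-12, 5]`, `j` in `[0, 3)`, `w` in `[0, 10]`.
#'
#' @inheritParams dec_loglik
#' @param free_j fit the founder-event weight `j`?
#' @param free_w fit the multiplier exponent `w`?
#' @param n_refine how many screened starts to polish (default 1; the
#'   coarse screen over the full grid picks the basin).
#' @param extra_starts optional list of named parameter vectors (natural
#'   scale) added to the start set and always refined — e.g. the optimum
#'   of a nested fit.
#' @param aicc_n sample size for AICc; defaults to the number of tips.
#' @param marginals compute ancestral-range marginals and the root-areas
#'   summary at the MLE (default `TRUE`; turn off in tight simulation
#'   loops that only need parameter estimates).
#' @return object of class `dec_fit`.
#' @export
fit_dec <- function(phy, geog, dispersal, family = "DEC",
                    free_j = FALSE, free_w = FALSE,
                    max_range_size = length(dispersal$areas),
                    root_clado = FALSE, scale_jump = TRUE,
                    n_refine = 1L, extra_starts = NULL,
                    aicc_n = length(phy$tip.label), marginals = TRUE) {
  validate_timetree(phy)
  lb <- c(d = log(1e-12), e = log(1e-12), j = 0, w = 0)
  ub <- c(d = log(5), e = log(5), j = 3 - 1e-6, w = 10)
  par_names <- c("d", "e", if (free_j) "j", if (free_w) "w")
  to_params <- function(x) {
    # clamp into bounds: L-BFGS-B probes finite-difference points a step
    # outside the box, and the objective must stay smooth there
    names(x) <- par_names
    dec_params(d = exp(x[["d"]]), e = exp(x[["e"]]),
               j = if (free_j) min(max(x[["j"]], 0), 3 - 1e-6) else 0,
               w = if (free_w) min(max(x[["w"]], 0), 10) else 1)
  }
  precomp <- dec_precompute(phy, geog, dispersal, max_range_size)
  nll <- function(x) {
    p <- to_params(x)
    ll <- tryCatch(dec_loglik(phy, geog, p, dispersal, family,
                              max_range_size, root_clado, scale_jump,
                              precomp = precomp),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  grid <- dec_start_grid(free_j, free_w)
  starts <- lapply(seq_len(nrow(grid)), function(i) {
    x <- c(d = log(grid$d[i]), e = log(grid$e[i]))
    if (free_j) x <- c(x, j = grid$j[i])
    if (free_w) x <- c(x, w = grid$w[i])
    x
  })
  n_grid <- length(starts)
  for (es in extra_starts) {
    x <- c(d = log(max(es[["d"]], 1e-12)),
           e = log(max(es[["e"]], 1e-12)))
    if (free_j) x <- c(x, j = min(max(es[["j"]] %||% 0, 0), 3 - 1e-6))
    if (free_w) x <- c(x, w = min(max(es[["w"]] %||% 1, 0), 10))
    starts[[length(starts) + 1L]] <- x
  }
  screened <- vapply(starts, nll, 0)
  ord <- order(screened)
  refine <- unique(c(ord[seq_len(min(n_refine, n_grid))],
                     if (length(starts) > n_grid)
                       (n_grid + 1L):length(starts)))
  best <- NULL
  trace <- data.frame(start = refine, screen_nll = screened[refine],
                      refined_nll = NA_real_, convergence = NA_integer_)
  for (ii in seq_len(nrow(trace))) {
    x0 <- starts[[trace$start[ii]]]
    o <- tryCatch(
      stats::optim(x0, nll, method = "L-BFGS-B",
                   lower = lb[par_names], upper = ub[par_names],
                   control = list(maxit = 150, factr = 1e9)),
      error = function(e) NULL)
    if (is.null(o)) next
    trace$refined_nll[ii] <- o$value
    trace$convergence[ii] <- o$convergence
    # refinement must never end below its own start
    if (o$value > screened[trace$start[ii]]) {
      o$value <- screened[trace$start[ii]]
      o$par <- x0
    }
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best) || best$value >= 1e10)
    stop("DEC optimization failed to find a finite-likelihood optimum; ",
         "best screened -lnL = ", min(screened))
  params <- to_params(best$par)
  lnL <- -best$value
  k <- 2L + free_j + free_w
  marg <- if (marginals)
    ancestral_range_marginals(phy, geog, params, dispersal, family,
                              max_range_size, root_clado, scale_jump,
                              precomp = precomp)
  else list(root_areas = NA_character_, root_states = NA_character_,
            marginals = NULL)
  structure(list(family = family, params = params,
                 free = par_names, lnL = lnL, k = k,
                 AICc = aicc(lnL, k, aicc_n), aicc_n = aicc_n,
                 root_areas = marg$root_areas,
                 root_states = marg$root_states,
                 marginals = marg$marginals,
                 dispersal = dispersal, phy = phy, geog = geog,
                 max_range_size = max_range_size,
                 root_clado = root_clado, scale_jump = scale_jump,
                 trace = trace,
                 call = match.call()),
            class = "dec_fit")
}

#' @export
print.dec_fit <- function(x, ...) {
  jlab <- if ("j" %in% x$free) "+J" else ""
  cat("DEC-family ancestral range model: ", x$family, jlab, "\n", sep = "")
  cat(sprintf("  lnL = %.4f   k = %d   AICc = %.4f (n = %d tips)\n",
              x$lnL, x$k, x$AICc, x$aicc_n))
  p <- unlist(x$params)
  cat("  parameters:",
      paste(sprintf("%s = %.6g%s", names(p), p,
                    ifelse(names(p) %in% x$free, "", " (fixed)")),
            collapse = ", "), "\n")
  cat("  root areas (95% set):", x$root_areas, "\n")
  invisible(x)
}

#' @export
coef.dec_fit <- function(object, ...) unlist(object$params)[object$free]

#' @export
logLik.dec_fit <- function(object, ...)
  structure(object$lnL, df = object$k, nobs = object$aicc_n,
            class = "logLik")

#' @export
summary.dec_fit <- function(object, ...) {
  print(object)
  cat("\nOptimizer trace (screened starts refined):\n")
  print(object$trace, row.names = FALSE)
  invisible(object)
}

#' @export
simulate.dec_fit <- function(object, nsim = 1, seed = NULL,
                             root_range = NULL, ...) {
  if (is.null(root_range)) root_range <- object$root_states[1L]
  out <- lapply(seq_len(nsim), function(i)
    simulate_dec_tips(object$phy, object$params, object$dispersal,
                      family = object$family, root_range = root_range,
                      seed = if (is.null(seed)) NULL else seed + i - 1L,
                      max_range_size = object$max_range_size,
                      scale_jump = object$scale_jump))
  if (nsim == 1L) out[[1L]] else out
}

#' Fit and compare a suite of biogeographic hypotheses
#'
#' For each hypothesis, each model family is fitted with and without the
#' founder-event parameter; the family/J combination with the lowest AICc
#' is that hypothesis's best model (ties broken by fewer parameters, then
#' family order DEC < DIVALIKE < BAYAREALIKE). The comparison table
#' mirrors the usual presentation: hypothesis, assumption, best model,
#' AICc, delta AICc against the overall best, and the root-areas summary.
#'
#' @inheritParams fit_dec
#' @param hypotheses list of [hypothesis_spec()] objects.
#' @param families model families to try.
#' @param try_j also fit each family with free `j`? (default `TRUE`).
#' @param areas area universe used for unguided hypotheses (taken from the
#'   first hypothesis with a dispersal model if omitted).
#' @return object of class `hypothesis_suite`: `table` (data.frame sorted
#'   by hypothesis id) and `fits` (nested list of `dec_fit`s; failed fits
#'   recorded as condition messages).
#' @export
hypothesis_suite <- function(phy, geog, hypotheses,
                             families = c("DEC", "DIVALIKE",
                                          "BAYAREALIKE"),
                             try_j = TRUE, areas = NULL,
                             max_range_size = NULL, ...) {
  if (!length(hypotheses)) stop("need at least one hypothesis")
  if (is.null(areas)) {
    for (h in hypotheses)
      if (!is.null(h$dispersal)) { areas <- h$dispersal$areas; break }
    if (is.null(areas)) areas <- colnames(geog)
  }
  if (is.null(max_range_size)) max_range_size <- length(areas)
  fam_order <- c(DEC = 1L, DIVALIKE = 2L, BAYAREALIKE = 3L)
  ids <- vapply(hypotheses, `[[`, "", "id")
  hypotheses <- hypotheses[order(ids)]
  rows <- list(); fits <- list()
  for (h in hypotheses) {
    disp <- if (is.null(h$dispersal))
      stratified_dispersal(areas = areas) else h$dispersal
    hfits <- list(); best <- NULL; notes <- character(0)
    for (fam in families) for (fj in if (try_j) c(FALSE, TRUE) else FALSE) {
      tag <- paste0(fam, if (fj) "+J" else "")
      # seed the +J fit with the nested fixed-j optimum so the free-j
      # likelihood can never fall below it
      es <- if (fj && !inherits(hfits[[fam]], "error") &&
                !is.null(hfits[[fam]]))
        list(unlist(hfits[[fam]]$params)) else NULL
      f <- tryCatch(
        fit_dec(phy, geog, disp, family = fam, free_j = fj,
                free_w = h$w_free, max_range_size = max_range_size,
                extra_starts = es, ...),
        error = function(e) e)
      hfits[[tag]] <- f
      if (inherits(f, "error")) {
        notes <- c(notes, paste0(tag, ": ", conditionMessage(f)))
        next
      }
      if (is.null(best) ||
          f$AICc < best$AICc - 1e-9 ||
          (abs(f$AICc - best$AICc) <= 1e-9 &&
           (f$k < best$k ||
            (f$k == best$k &&
             fam_order[fam] < fam_order[best$family]))))
        best <- f
    }
    fits[[h$id]] <- hfits
    rows[[h$id]] <- data.frame(
      hypothesis = h$id, assumption = h$description,
      best_model = if (is.null(best)) NA_character_ else
        paste0(best$family, if ("j" %in% best$free) "+J" else ""),
      lnL = if (is.null(best)) NA_real_ else best$lnL,
      k = if (is.null(best)) NA_integer_ else best$k,
      AICc = if (is.null(best)) NA_real_ else best$AICc,
      root_areas = if (is.null(best)) NA_character_ else best$root_areas,
      notes = paste(notes, collapse = "; "))
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$hypothesis), , drop = FALSE]
  best_aicc <- min(tab$AICc, na.rm = TRUE)
  tab$delta_AICc <- tab$AICc - best_aicc
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits), class = "hypothesis_suite")
}

#' @export
print.hypothesis_suite <- function(x, ...) {
  cat("Biogeographic hypothesis comparison\n")
  cols <- c("hypothesis", "assumption", "best_model", "AICc",
            "delta_AICc", "root_areas")
  print(x$table[, cols], row.names = FALSE, digits = 5)
  invisible(x)
}

#' Write a hypothesis-suite report as TSV and JSON
#' @param suite a [hypothesis_suite()] result.
#' @param tsv,json output paths (either may be `NULL`).
#' @export
write_suite_report <- function(suite, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    utils::write.table(suite$table, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(suite$table, json, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  invisible(suite)
}
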