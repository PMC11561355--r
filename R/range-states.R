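#' Enumerate geographic range states
#'
#' The DEC state space over an area universe: the null range (no areas,
#' a valid internal state but never an observation) plus every nonempty
#' subset of at most `max_range_size` areas. States are ordered by size,
#' then lexicographically by area order, so the layout is deterministic
#' and documented: index 1 is the null range.
#'
#' @param areas character vector of unique area labels
#'   (default `c("A","B","C","D","E")`: East Asia, Australia, New Guinea,
#'   Pacific archipelagos, New Zealand).
#' @param max_range_size largest permitted range (default all areas).
#' @return an object of class `range_states`: list with `areas`, `bits`
#'   (n_states x n_areas logical), `labels`, `sizes`, `max_range_size`.
#' @export
range_states <- function(areas = c("A", "B", "C", "D", "E"),
                         max_range_size = length(areas)) {
  areas <- as.character(areas)
  if (anyDuplicated(areas)) stop("area labels must be unique")
  n <- length(areas)
  if (n < 1L) stop("need at least one area")
  if (max_range_size < 1L || max_range_size > n)
    stop("max_range_size must be in [1, ", n, "]")
  rows <- list(rep(FALSE, n))
  for (k in seq_len(max_range_size)) {
    combs <- utils::combn(n, k)
    for (j in seq_len(ncol(combs))) {
      v <- rep(FALSE, n)
      v[combs[, j]] <- TRUE
      rows[[length(rows) + 1L]] <- v
    }
  }
  bits <- do.call(rbind, rows)
  colnames(bits) <- areas
  labels <- apply(bits, 1L, function(v) {
    if (!any(v)) "0" else paste(areas[v], collapse = "")
  })
  keys <- as.integer(bits %*% 2^(seq_len(n) - 1L))
  lookup <- rep(NA_integer_, 2^n)
  lookup[keys + 1L] <- seq_len(nrow(bits))
  structure(list(areas = areas, bits = bits, labels = labels,
                 sizes = rowSums(bits), n_states = nrow(bits),
                 lookup = lookup, pow2 = 2^(seq_len(n) - 1L),
                 max_range_size = as.integer(max_range_size)),
            class = "range_states")
}

#' @export
print.range_states <- function(x, ...) {
  cat("Range state space: ", x$n_states, " states over ",
      length(x$areas), " areas (", paste(x$areas, collapse = ","),
      "), max range size ", x$max_range_size, "\n", sep = "")
  invisible(x)
}

# index of the state whose area set matches `v` (logical over areas)
state_index <- function(states, v) {
  hit <- states$lookup[as.integer(sum(states$pow2[v])) + 1L]
  if (is.na(hit)) stop("range not in state space: ",
                       paste(states$areas[v], collapse = ""))
  hit
}

# index from a label like "BC"
state_index_label <- function(states, label) {
  if (label %in% c("0", "")) return(1L)
  v <- states$areas %in% strsplit(label, "")[[1]]
  if (sum(v) != nchar(label)) stop("unknown area in range label ", label)
  state_index(states, v)
}

#' Tip range data
#'
#' @param ranges named character vector (tip label -> range label such as
#'   `"B"` or `"BC"`) or a logical/0-1 matrix with tip rownames and area
#'   colnames.
#' @param areas area universe, defaults to the columns / letters seen.
#' @return object of class `geography`: 0/1 integer matrix, tips x areas.
#' @export
geography <- function(ranges, areas = NULL) {
  if (is.matrix(ranges)) {
    m <- ranges != 0
    if (is.null(rownames(m)) || is.null(colnames(m)))
      stop("matrix input needs tip rownames and area colnames")
    if (!is.null(areas)) m <- m[, areas, drop = FALSE]
  } else {
    if (is.null(names(ranges))) stop("ranges must be named by tip label")
    if (is.null(areas))
      areas <- sort(unique(unlist(strsplit(unname(ranges), ""))))
    if (!length(areas))
      stop("tip with empty range: ", names(ranges)[1L])
    m <- matrix(unlist(lapply(ranges, function(r)
      areas %in% strsplit(r, "")[[1]])),
      ncol = length(areas), byrow = TRUE,
      dimnames = list(names(ranges), areas))
  }
  if (anyDuplicated(rownames(m))) stop("duplicate tip label in geography")
  if (any(rowSums(m) == 0))
    stop("tip with empty range: ", rownames(m)[rowSums(m) == 0][1L])
  storage.mode(m) <- "integer"
  structure(m, class = c("geography", "matrix"))
}

#' Read a PHYLIP-style geography table
#'
#' Format: header `"n_tips n_areas (A B C ...)"`, then one row per tip,
#' `"label<TAB>01001"` (0/1 presence over the areas in header order).
#'
#' @param path file path.
#' @return a [geography()] matrix.
#' @export
read_geography <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- trimws(lines[1L])
  m <- regmatches(hdr, regexec("^(\\d+)\\s+(\\d+)\\s*\\(([^)]*)\\)", hdr))[[1]]
  if (length(m) != 4L) stop("bad geography header: ", hdr)
  n_tips <- as.integer(m[2]); n_areas <- as.integer(m[3])
  areas <- strsplit(trimws(m[4]), "\\s+")[[1]]
  if (length(areas) != n_areas) stop("header area count mismatch")
  body <- lines[-1L]
  if (length(body) != n_tips) stop("expected ", n_tips, " rows, found ",
                                   length(body))
  parts <- strsplit(body, "[\t ]+")
  labs <- vapply(parts, `[`, "", 1L)
  codes <- vapply(parts, `[`, "", 2L)
  if (any(nchar(codes) != n_areas))
    stop("presence string of wrong length for tip ",
         labs[nchar(codes) != n_areas][1L])
  mat <- t(vapply(codes,
                  function(s) as.integer(strsplit(s, "")[[1]] != "0"),
                  integer(n_areas)))
  rownames(mat) <- labs
  colnames(mat) <- areas
  geography(mat)
}

#' Write a geography table in the PHYLIP-style dialect
#' @param geog a [geography()] matrix.
#' @param path output path.
#' @export
write_geography <- function(geog, path) {
  hdr <- sprintf("%d %d (%s)", nrow(geog), ncol(geog),
                 paste(colnames(geog), collapse = " "))
  rows <- paste0(rownames(geog), "\t",
                 apply(geog, 1L, paste, collapse = ""))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Time-stratified dispersal multiplier model
#'
#' One square multiplier matrix per stratum (source area row, sink area
#' column), entries in `[0, 1]`; a 0 forbids dispersal into the sink from
#' that source (e.g. an area not yet emerged). Stratum 1 is the oldest.
#'
#' @param matrices list of square numeric matrices over the areas (a single
#'   matrix may be given directly); `NULL` means all multipliers 1.
#' @param strat a [stratification()] (or boundary-age vector) with
#'   `length(matrices)` strata.
#' @param areas area labels; defaults to matrix dimnames or LETTERS.
#' @return object of class `dispersal_model`.
#' @export
stratified_dispersal <- function(matrices = NULL, strat = stratification(),
                                 areas = NULL) {
  if (!inherits(strat, "stratification")) strat <- stratification(strat)
  if (is.matrix(matrices)) matrices <- list(matrices)
  if (is.null(matrices)) {
    if (is.null(areas)) stop("areas needed when matrices are omitted")
    matrices <- replicate(strat$n_strata, {
      m <- matrix(1, length(areas), length(areas),
                  dimnames = list(areas, areas))
      m
    }, simplify = FALSE)
  }
  if (length(matrices) != strat$n_strata)
    stop("need one multiplier matrix per stratum (",
         strat$n_strata, "), got ", length(matrices))
  if (is.null(areas)) areas <- colnames(matrices[[1]])
  if (is.null(areas)) areas <- LETTERS[seq_len(ncol(matrices[[1]]))]
  matrices <- lapply(matrices, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != length(areas) || ncol(m) != length(areas))
      stop("multiplier matrix dimension mismatch")
    if (any(m < 0 | m > 1)) stop("multipliers must lie in [0, 1]")
    dimnames(m) <- list(areas, areas)
    m
  })
  structure(list(matrices = matrices, strat = strat, areas = areas),
            class = "dispersal_model")
}

#' Read stratified dispersal multiplier matrices
#'
#' Plain-text format: for each stratum a header line
#' `"stratum <old_age> <young_age>"` followed by a whitespace-delimited
#' square matrix (oldest stratum first; `<old_age>` of the first stratum
#' may be `Inf`, `<young_age>` of the last must be 0).
#'
#' @param path file path.
#' @param areas area labels for the matrix rows/columns.
#' @return a [stratified_dispersal()] model.
#' @export
read_dispersal <- function(path, areas) {
  if (!file.exists(path)) stop("dispersal matrix file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  hdr_i <- grep("^stratum\\b", lines)
  if (!length(hdr_i)) stop("no 'stratum' header lines found")
  n <- length(areas)
  mats <- list(); young <- numeric(0)
  for (k in seq_along(hdr_i)) {
    h <- strsplit(lines[hdr_i[k]], "\\s+")[[1]]
    if (length(h) != 3L) stop("bad stratum header: ", lines[hdr_i[k]])
    young <- c(young, as.numeric(h[3]))
    block <- lines[(hdr_i[k] + 1L):(hdr_i[k] + n)]
    mats[[k]] <- do.call(rbind, lapply(strsplit(block, "\\s+"), as.numeric))
  }
  boundaries <- young[-length(young)]
  stratified_dispersal(mats, stratification(boundaries), areas = areas)
}

#' Write a dispersal model in the stratified plain-matrix format
#' @param model a [stratified_dispersal()] model.
#' @param path output path.
#' @export
write_dispersal <- function(model, path) {
  b <- model$strat$boundaries
  old <- c(Inf, b); young <- c(b, 0)
  out <- character(0)
  for (k in seq_along(model$matrices)) {
    out <- c(out, sprintf("stratum %s %s", format(old[k]), format(young[k])),
             apply(model$matrices[[k]], 1L, paste, collapse = " "))
  }
  writeLines(out, path)
  invisible(path)
}
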