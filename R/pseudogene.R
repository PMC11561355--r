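#' A gapped coding alignment with a designated reference
#'
#' Equal-length aligned nucleotide sequences (alphabet `ACGTN-`), one of
#' which is the reference open reading frame. Codon boundaries for every
#' sequence are projected from the reference's coordinates: codon `i`
#' occupies the alignment columns holding the reference's bases
#' `3i-2 .. 3i` (after the frame offset), so insertions relative to the
#' reference never shift downstream codon indices.
#'
#' @param seqs named character vector of aligned sequences.
#' @param reference id of the reference sequence (default: first).
#' @param frame reading-frame offset on the reference (0, 1 or 2 bases
#'   skipped at its 5' end).
#' @param stop_codons the stop set (standard nuclear code).
#' @return object of class `coding_alignment`.
#' @export
coding_alignment <- function(seqs, reference = names(seqs)[1L],
                             frame = 0L,
                             stop_codons = c("TAA", "TAG", "TGA")) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  seqs <- toupper(vapply(seqs, as.character, ""))
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned sequences must all have the same length")
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("illegal character in sequence ", names(seqs)[bad][1L],
         " (alphabet is ACGTN and '-'; normalize strand upstream)")
  if (!reference %in% names(seqs))
    stop("reference id not in alignment: ", reference)
  frame <- as.integer(frame)
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
  ref <- strsplit(seqs[[reference]], "")[[1]]
  ref_cols <- which(ref != "-")
  if (frame > 0) ref_cols <- ref_cols[-seq_len(frame)]
  if (length(ref_cols) %% 3L != 0L)
    stop("reference ungapped length (after frame offset) not a multiple ",
         "of 3")
  n_codons <- length(ref_cols) %/% 3L
  codon_cols <- matrix(ref_cols, nrow = 3L)    # column j = codon j
  ref_codons <- apply(codon_cols, 2L,
                      function(ix) paste(ref[ix], collapse = ""))
  if (any(ref_codons[-n_codons] %in% stop_codons))
    stop("reference not a valid ORF: internal stop at codon ",
         which(ref_codons %in% stop_codons)[1L])
  structure(list(seqs = seqs, reference = reference, frame = frame,
                 stop_codons = stop_codons, n_codons = n_codons,
                 codon_cols = codon_cols, width = nchar(seqs[[1L]])),
            class = "coding_alignment")
}

#' @export
print.coding_alignment <- function(x, ...) {
  cat("Coding alignment:", length(x$seqs), "sequences x", x$width,
      "columns;", x$n_codons, "reference codons (reference",
      x$reference, ")\n")
  invisible(x)
}

#' Read an aligned FASTA as a coding alignment
#' @param path FASTA file.
#' @inheritParams coding_alignment
#' @export
read_coding_alignment <- function(path, reference = NULL, frame = 0L,
                                  stop_codons = c("TAA", "TAG", "TGA")) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- stats::setNames(as.character(ss), names(ss))
  if (is.null(reference)) reference <- names(seqs)[1L]
  coding_alignment(seqs, reference, frame, stop_codons)
}

#' Write a coding alignment as FASTA
#' @param aln a [coding_alignment()].
#' @param path output path.
#' @export
write_coding_alignment <- function(aln, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln$seqs), path)
  invisible(path)
}

#' Detect premature stop codons
#'
#' Each non-reference sequence is translated in the frame projected from
#' the reference; every stop codon strictly before the reference's
#' terminal codon is reported. Codons containing `N` or gap characters
#' are not called. Stops downstream of an earlier frameshift in the same
#' sequence are still reported, flagged `post_frameshift`.
#'
#' @param aln a [coding_alignment()].
#' @return data.frame of calls: `seq`, `kind`, `column` (1-based alignment
#'   column of the codon start), `codon` (1-based reference codon index),
#'   `detail` (the stop triplet), `post_frameshift`.
#' @export
detect_premature_stops <- function(aln) {
  stopifnot(inherits(aln, "coding_alignment"))
  fs <- detect_frameshifts(aln)
  calls <- list()
  for (id in setdiff(names(aln$seqs), aln$reference)) {
    s <- strsplit(aln$seqs[[id]], "")[[1]]
    first_fs <- if (any(fs$seq == id)) min(fs$column[fs$seq == id]) else Inf
    for (ci in seq_len(aln$n_codons - 1L)) {   # terminal codon exempt
      ix <- aln$codon_cols[, ci]
      cod <- paste(s[ix], collapse = "")
      if (grepl("[N-]", cod)) next
      if (cod %in% aln$stop_codons)
        calls[[length(calls) + 1L]] <- data.frame(
          seq = id, kind = "premature_stop", column = ix[1L],
          codon = ci, detail = cod,
          post_frameshift = ix[1L] > first_fs)
    }
  }
  if (!length(calls)) return(empty_calls())
  do.call(rbind, calls)
}

#' Detect frameshift indels
#'
#' Scans each non-reference sequence for maximal insertion or deletion
#' runs relative to the reference (a deletion run: consecutive columns
#' where the reference has a base and the query a gap; an insertion run:
#' the converse). Each maximal run whose length is not a multiple of 3 is
#' one frameshift call at the run's first column, with
#' `detail = length mod 3`.
#'
#' @param aln a [coding_alignment()].
#' @return data.frame of calls (`detail` is `"1"` or `"2"`).
#' @export
detect_frameshifts <- function(aln) {
  stopifnot(inherits(aln, "coding_alignment"))
  ref <- strsplit(aln$seqs[[aln$reference]], "")[[1]]
  calls <- list()
  for (id in setdiff(names(aln$seqs), aln$reference)) {
    s <- strsplit(aln$seqs[[id]], "")[[1]]
    del <- ref != "-" & s == "-"
    ins <- ref == "-" & s != "-"
    for (kindvec in list(del, ins)) {
      r <- rle(kindvec)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values & r$lengths %% 3L != 0L)
      for (k in runs) {
        col1 <- starts[k]
        calls[[length(calls) + 1L]] <- data.frame(
          seq = id, kind = "frameshift", column = col1,
          codon = ref_codon_of_column(aln, col1),
          detail = as.character(r$lengths[k] %% 3L),
          post_frameshift = FALSE)
      }
    }
  }
  if (!length(calls)) return(empty_calls())
  out <- do.call(rbind, calls)
  out[order(out$seq, out$column), , drop = FALSE]
}

# reference codon index containing (or immediately following) a column
ref_codon_of_column <- function(aln, col) {
  last_cols <- aln$codon_cols[3L, ]
  idx <- which(last_cols >= col)[1L]
  if (is.na(idx)) aln$n_codons else idx
}

empty_calls <- function() {
  data.frame(seq = character(0), kind = character(0),
             column = integer(0), codon = integer(0),
             detail = character(0), post_frameshift = logical(0))
}

#' Scan an alignment for deleterious lesions
#'
#' Convenience wrapper: premature stops plus frameshifts in one table.
#' @param aln a [coding_alignment()].
#' @export
scan_pseudogenes <- function(aln) {
  out <- rbind(detect_premature_stops(aln), detect_frameshifts(aln))
  out[order(out$seq, out$column), , drop = FALSE]
}

#' Lesions shared within designated sequence pairs
#'
#' A call is shared between the two members of a pair iff the kind
#' matches and, for premature stops, the reference codon index matches
#' exactly; for frameshifts, the run start column and the
#' length-mod-3 detail match exactly.
#'
#' @param calls a call table (from [scan_pseudogenes()] or the two
#'   detectors).
#' @param pairs two-column matrix/data.frame of sequence-id pairs, or a
#'   list of length-2 character vectors.
#' @param ids all sequence ids present in the alignment (for validation);
#'   optional.
#' @return object of class `shared_mutation_report`: list per pair with
#'   `pair` and `shared` (the matching calls).
#' @export
shared_deleterious <- function(calls, pairs, ids = NULL) {
  if (is.data.frame(pairs) || is.matrix(pairs))
    pairs <- lapply(seq_len(nrow(pairs)),
                    function(i) as.character(unlist(pairs[i, 1:2])))
  reports <- lapply(pairs, function(p) {
    if (length(p) != 2L) stop("each pair must have exactly two ids")
    if (!is.null(ids) && !all(p %in% ids))
      stop("unknown sequence id in pair: ",
           paste(setdiff(p, ids), collapse = ", "))
    a <- calls[calls$seq == p[1L], , drop = FALSE]
    b <- calls[calls$seq == p[2L], , drop = FALSE]
    key <- function(df) ifelse(df$kind == "premature_stop",
                               paste0("stop@codon", df$codon),
                               paste0("fs@col", df$column, "+", df$detail))
    shared_keys <- intersect(key(a), key(b))
    shared <- a[key(a) %in% shared_keys, , drop = FALSE]
    list(pair = p, shared = shared, n_shared = nrow(shared))
  })
  structure(list(reports = reports), class = "shared_mutation_report")
}

#' @export
print.shared_mutation_report <- function(x, ...) {
  for (r in x$reports) {
    cat(r$pair[1L], "~", r$pair[2L], ":", r$n_shared,
        "shared lesion(s)\n")
    if (r$n_shared)
      print(r$shared[, c("kind", "column", "codon", "detail")],
            row.names = FALSE)
  }
  invisible(x)
}

#' Read a two-column TSV of sister-species pairs
#' @param path file path (no header).
#' @export
read_pairs <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character")
  lapply(seq_len(nrow(df)), function(i) c(df[i, 1L], df[i, 2L]))
}
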