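#' One-hot encode an alignment
#'
#' Builds the binary occupancy tensor of the family: entry `(i, k, l)` is 1
#' when sequence `i` carries residue type `k` (0 = gap, 1..20 = amino acids)
#' at column `l`, else 0. Each `(i, l)` slice contains exactly one 1.
#'
#' @param alignment A `cmca_alignment` object.
#' @param alphabet The 21-symbol alphabet, from [cmca_alphabet()].
#' @return A binary integer array of dimension `N x 21 x L0`, with dimnames
#'   `(ids, symbols, columns)`.
#' @export
encode_alignment <- function(alignment, alphabet = cmca_alphabet()) {
  stopifnot(inherits(alignment, "cmca_alignment"))
  chars <- do.call(rbind, strsplit(alignment$rows, "", fixed = TRUE))
  k <- alphabet$index[chars]                     # N x L matrix of type indices
  if (anyNA(k)) {
    stop("internal error: symbol outside the 21-type alphabet after normalization")
  }
  dim(k) <- dim(chars)
  N <- alignment$N
  L <- alignment$L0
  M <- length(alphabet$symbols)
  tensor <- array(0L, dim = c(N, M, L),
                  dimnames = list(alignment$ids, alphabet$symbols, seq_len(L)))
  idx <- cbind(rep(seq_len(N), L), as.vector(k) + 1L, rep(seq_len(L), each = N))
  tensor[idx] <- 1L
  tensor
}

#' Position frequency matrix
#'
#' Counts, for every residue type and alignment column, how many sequences
#' carry that type at that column. Every column of the result sums to the
#' number of sequences N.
#'
#' @param tensor Binary occupancy array from [encode_alignment()].
#' @return A `cmca_freq` object: list with `counts` (21 x L integer matrix,
#'   rows named by symbol, columns by original 1-based position), `N`, `L`,
#'   and `reduced` (FALSE for an unreduced matrix).
#' @export
position_frequencies <- function(tensor) {
  stopifnot(length(dim(tensor)) == 3L)
  counts <- apply(tensor, c(2, 3), sum)
  storage.mode(counts) <- "integer"
  new_freq(counts, N = dim(tensor)[1], reduced = FALSE)
}

new_freq <- function(counts, N, reduced) {
  stopifnot(is.matrix(counts), nrow(counts) == 21L)
  if (any(colSums(counts) != N)) {
    stop("internal error: frequency column sums differ from N")
  }
  structure(
    list(counts = counts, N = as.integer(N), L = ncol(counts),
         reduced = isTRUE(reduced)),
    class = "cmca_freq"
  )
}

#' @export
print.cmca_freq <- function(x, ...) {
  cat("cmca_freq: 21 x", x$L, if (x$reduced) "(reduced)" else "(unreduced)",
      "counts over N =", x$N, "sequences\n")
  invisible(x)
}

#' Natural-residue fraction per column
#'
#' For each column, the fraction of sequences carrying one of the 20 natural
#' amino acids (i.e. excluding the gap type). This is the quantity the gap
#' reduction rule thresholds at 20 percent.
#'
#' @param freq An unreduced `cmca_freq` object.
#' @return Numeric vector of length L with values in `[0, 1]`.
#' @export
natural_fraction <- function(freq) {
  stopifnot(inherits(freq, "cmca_freq"))
  colSums(freq$counts[-1L, , drop = FALSE]) / freq$N
}

#' Delete gap-dominated columns
#'
#' Removes every column whose natural-residue fraction is strictly below the
#' threshold (default 0.20): such a column has more than 80 percent gaps and
#' carries little family-level signal. The comparison is strict, so a column
#' with exactly 20 percent natural residues is kept.
#'
#' @param freq An unreduced `cmca_freq` object.
#' @param threshold Minimum natural-residue fraction to keep a column.
#' @return A list with `freq` (the reduced `cmca_freq`) and `position_map`
#'   (a `cmca_posmap`: `kept` = original 1-based indices of surviving
#'   columns, `q` = per-original-column natural fraction, `reference` =
#'   `NULL` until [map_reference_numbering()] is applied).
#' @export
reduce_gaps <- function(freq, threshold = 0.20) {
  stopifnot(inherits(freq, "cmca_freq"))
  stopifnot(threshold >= 0, threshold <= 1)
  q <- unname(natural_fraction(freq))
  kept <- which(q >= threshold)
  if (length(kept) == 0L) {
    stop("all ", freq$L, " columns fall below the natural-residue threshold ",
         threshold, "; nothing left to analyse")
  }
  # column names keep their original 1-based labels, so re-reducing an
  # already-reduced matrix neither renames nor removes anything
  counts <- freq$counts[, kept, drop = FALSE]
  pm <- structure(
    list(kept = kept, q = unname(q), reference = NULL),
    class = "cmca_posmap"
  )
  list(freq = new_freq(counts, freq$N, reduced = TRUE), position_map = pm)
}

#' @export
print.cmca_posmap <- function(x, ...) {
  cat("cmca_posmap:", length(x$kept), "of", length(x$q), "columns kept")
  if (!is.null(x$reference)) cat("; reference", x$reference$id)
  cat("\n")
  invisible(x)
}

#' Attach reference-sequence numbering to a position map
#'
#' Reports every kept column in the residue numbering of one named family
#' member: the 1-based ordinal of the reference's non-gap residues up to that
#' column, or `NA` where the reference itself has a gap (rendered "-" in
#' reports). This is the dual numbering used in all pair tables so positions
#' can be located on a well-characterized structure.
#'
#' @param alignment The original `cmca_alignment`.
#' @param position_map A `cmca_posmap` from [reduce_gaps()].
#' @param reference_id Identifier of the reference sequence.
#' @return The position map with a `reference` component:
#'   `list(id, numbering)` where `numbering[p]` is the reference residue
#'   number of kept column `p`, `NA` if the reference is gapped there.
#' @export
map_reference_numbering <- function(alignment, position_map, reference_id) {
  stopifnot(inherits(alignment, "cmca_alignment"),
            inherits(position_map, "cmca_posmap"))
  hit <- match(reference_id, alignment$ids)
  if (is.na(hit)) {
    stop("reference sequence '", reference_id, "' not found in alignment")
  }
  res <- strsplit(alignment$rows[hit], "", fixed = TRUE)[[1L]]
  is_res <- res != "-"
  ordinal <- cumsum(is_res)            # residue count up to each column
  numbering <- ifelse(is_res[position_map$kept],
                      ordinal[position_map$kept], NA_integer_)
  position_map$reference <- list(id = reference_id,
                                 numbering = as.integer(numbering))
  position_map
}

#' Write a position map as JSON
#'
#' @param position_map A `cmca_posmap`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_position_map <- function(position_map, path) {
  obj <- list(kept = position_map$kept, q = position_map$q)
  if (!is.null(position_map$reference)) {
    obj$reference <- list(id = position_map$reference$id,
                          numbering = position_map$reference$numbering)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
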