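#' Read an aligned protein family from FASTA
#'
#' Parses an aligned FASTA file into a validated alignment object. Sequences
#' are uppercased; `.` and space are normalized to the gap symbol `-`;
#' non-standard residue codes (X, B, Z, U, O, J, `*`) are replaced by the gap
#' symbol with a warning, since the analysis model has exactly 21 residue
#' types (20 amino acids plus gap).
#'
#' @param path Path to an aligned FASTA file.
#' @param dialect Input dialect; only `"fasta"` is supported.
#' @return An object of class `cmca_alignment`: a list with `ids` (unique
#'   sequence identifiers), `rows` (character vector of equal-length aligned
#'   sequences), `N` (number of sequences), `L0` (alignment length) and
#'   `replaced` (count of non-standard residue codes mapped to gap).
#' @seealso [write_alignment()], [encode_alignment()]
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "AC-D", ">s2", "AGGD"), fa)
#' aln <- read_alignment(fa)
#' aln$N   # 2
#' aln$L0  # 4
#' @export
read_alignment <- function(path, dialect = c("fasta")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("alignment file not found: ", path)
  }
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) {
    stop("empty alignment: no FASTA records in ", path)
  }
  ids <- sub("\\s.*$", "", names(set))
  rows <- as.character(set)
  names(rows) <- NULL
  new_alignment(ids, rows, source = path)
}

#' Construct a validated alignment object
#'
#' Validates and normalizes raw sequences into the alignment container used
#' throughout the package. Called by [read_alignment()] and by the synthetic
#' family generator; useful directly when sequences come from another source.
#'
#' @param ids Character vector of unique, non-empty sequence identifiers.
#' @param rows Character vector of aligned sequences, all of equal length.
#' @param source Optional label used in error messages.
#' @return A `cmca_alignment` object (see [read_alignment()]).
#' @export
new_alignment <- function(ids, rows, source = "<memory>") {
  if (length(rows) != length(ids)) {
    stop("ids and rows differ in length")
  }
  if (length(rows) < 2L) {
    stop("alignment must contain at least 2 sequences, got ", length(rows))
  }
  if (any(!nzchar(ids))) {
    stop("empty sequence identifier in ", source)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifiers in ", source, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1L])[1L]
    stop("unequal sequence lengths in ", source, ": record '", ids[bad],
         "' has length ", lens[bad], ", expected ", lens[1L])
  }
  if (lens[1L] < 1L) {
    stop("alignment has zero columns in ", source)
  }

  rows <- toupper(rows)
  rows <- gsub("[. ]", "-", rows)
  n_replaced <- 0L
  amb <- paste0("[", gsub("\\*", "\\\\*", paste(.ambiguous_codes, collapse = "")), "]")
  hits <- gregexpr(amb, rows)
  n_replaced <- sum(vapply(hits, function(h) sum(h > 0L), integer(1)))
  if (n_replaced > 0L) {
    warning("replaced ", n_replaced,
            " non-standard residue code(s) (X/B/Z/U/O/J/*) with gap")
    rows <- gsub(amb, "-", rows)
  }

  ab <- cmca_alphabet()
  ok <- paste0("^[", paste(ab$symbols, collapse = ""), "]*$")
  bad <- which(!grepl(ok, rows))
  if (length(bad) > 0L) {
    stop("record '", ids[bad[1L]], "' contains characters outside the ",
         "20 amino acids + gap alphabet")
  }

  structure(
    list(ids = ids, rows = rows, N = length(rows), L0 = lens[1L],
         replaced = n_replaced),
    class = "cmca_alignment"
  )
}

#' @export
print.cmca_alignment <- function(x, ...) {
  cat("cmca_alignment:", x$N, "sequences x", x$L0, "columns\n")
  invisible(x)
}

#' Write an alignment to aligned FASTA
#'
#' @param alignment A `cmca_alignment` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "cmca_alignment"))
  set <- Biostrings::BStringSet(alignment$rows)
  names(set) <- alignment$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a labelled matrix as TSV
#'
#' Serializes any result matrix (frequency counts, mutative factors,
#' correlation matrices) as a tab-separated file with a header row of column
#' labels and a leading column of row labels. Floating-point values are
#' written with 6 decimal places; integer matrices are written as integers.
#'
#' @param matrix A numeric or integer matrix.
#' @param row_labels,col_labels Labels matching the matrix dimensions.
#'   Default to the matrix dimnames.
#' @param path Output file path.
#' @param corner Label for the top-left header cell.
#' @return The path, invisibly.
#' @export
write_matrix <- function(matrix, path, row_labels = rownames(matrix),
                         col_labels = colnames(matrix), corner = "pos") {
  if (is.null(row_labels)) row_labels <- seq_len(nrow(matrix))
  if (is.null(col_labels)) col_labels <- seq_len(ncol(matrix))
  if (length(row_labels) != nrow(matrix) || length(col_labels) != ncol(matrix)) {
    stop("label counts (", length(row_labels), " x ", length(col_labels),
         ") do not match matrix dimensions (", nrow(matrix), " x ",
         ncol(matrix), ")")
  }
  if (is.integer(matrix) || all(matrix == round(matrix))) {
    body <- format(matrix, trim = TRUE, scientific = FALSE)
  } else {
    body <- formatC(matrix, format = "f", digits = 6)
  }
  body <- matrix(body, nrow = nrow(matrix))
  lines <- c(
    paste(c(corner, as.character(col_labels)), collapse = "\t"),
    vapply(seq_len(nrow(matrix)), function(i) {
      paste(c(as.character(row_labels)[i], body[i, ]), collapse = "\t")
    }, character(1))
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a matrix written by [write_matrix()]
#'
#' @param path Path to a TSV file with header row and row-label column.
#' @return A numeric matrix with dimnames taken from the labels.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1,
                          stringsAsFactors = FALSE)
  as.matrix(df)
}
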