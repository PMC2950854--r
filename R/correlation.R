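#' Residue-type diversity per column
#'
#' The number of distinct residue types (gap included) observed at each
#' column of a reduced frequency matrix. A value of 1 means the column is
#' invariant; larger values mean a more diversified, more mutable position.
#'
#' @param freq A reduced `cmca_freq` object.
#' @return Integer vector `n` of length L with values in 1..21.
#' @export
amino_acid_types <- function(freq) {
  stopifnot(inherits(freq, "cmca_freq"))
  colSums(freq$counts > 0L)
}

#' Mutative factor of one residue type at one position
#'
#' The per-symbol mutability score at a column with `n` residue types in a
#' family of `N` sequences:
#'
#'   t(f; N, n) = (n - 1) / (|f - N/n| + 1)
#'
#' It is 0 for every frequency when the column is invariant (n = 1), grows
#' with the column's diversity n, and for fixed n is maximal (value n - 1)
#' exactly when the type's frequency f equals the column's average frequency
#' N/n: residue types sitting at the average frequency are the ones free to
#' drift, while types much more (conserved) or much less (absent) frequent
#' than average are evolutionarily pinned. The +1 in the denominator keeps
#' the score finite at f = N/n.
#'
#' @param f Integer frequency (or vector of frequencies) in `[0, N]`.
#' @param N Number of sequences, >= 1.
#' @param n Number of residue types at the position, in 1..21.
#' @return Numeric vector of non-negative mutative factors, one per `f`.
#' @examples
#' mutative_factor(5, N = 100, n = 20)   # 19, the global maximum for n = 20
#' mutative_factor(60, N = 100, n = 2)   # 1/11
#' @export
mutative_factor <- function(f, N, n) {
  if (length(N) != 1L || length(n) != 1L) stop("N and n must be scalars")
  if (N < 1) stop("N must be >= 1, got ", N)
  if (n < 1 || n > 21) stop("n must lie in 1..21, got ", n)
  if (any(f < 0) || any(f > N)) stop("f must lie in [0, N]")
  (n - 1) / (abs(f - N / n) + 1)
}

#' Position mutation matrix
#'
#' Applies [mutative_factor()] to every cell of the reduced frequency
#' matrix, including residue types absent from a column (f = 0), yielding the
#' 21 x L matrix of mutability scores whose column profiles feed the
#' mutation correlation matrix.
#'
#' @param freq A reduced `cmca_freq` object.
#' @return A `cmca_mutmat` object: list with `values` (21 x L numeric
#'   matrix, dimnames as in `freq$counts`), `N`, and `n` (per-column type
#'   counts).
#' @export
mutation_matrix <- function(freq) {
  stopifnot(inherits(freq, "cmca_freq"))
  n <- amino_acid_types(freq)
  values <- freq$counts
  storage.mode(values) <- "double"
  for (l in seq_len(freq$L)) {
    values[, l] <- mutative_factor(freq$counts[, l], freq$N, n[l])
  }
  structure(list(values = values, N = freq$N, n = n), class = "cmca_mutmat")
}

#' @export
print.cmca_mutmat <- function(x, ...) {
  cat("cmca_mutmat: 21 x", ncol(x$values), "mutative factors, N =", x$N, "\n")
  invisible(x)
}

#' Pearson correlation between column profiles
#'
#' The workhorse behind both correlation flavors: every alignment column is
#' summarized by its 21-dimensional profile over residue types (frequency
#' counts for the conservation flavor, mutative factors for the mutation
#' flavor), and positions i, j are compared by the Pearson correlation of
#' their profiles. Internally the population covariance
#' c_ij = (1/M) * sum_k (x_ki - mean_i)(x_kj - mean_j) is formed and
#' normalized as r_ij = c_ij / sqrt(c_ii * c_jj); the divisor cancels in r.
#'
#' Positions whose profile has zero variance (e.g. an invariant column in
#' the mutation flavor, whose mutative factors are all 0) have no defined
#' correlation: their rows and columns are set to 0 off-diagonal, their
#' diagonal to 1 by convention, and they are listed in `undefined`.
#'
#' @param profile An M x L numeric matrix of column profiles (M symbol
#'   rows, L position columns).
#' @param flavor Label stored on the result, `"conservation"` or
#'   `"mutation"`.
#' @param include_gap_row If `FALSE`, the first (gap) profile row is dropped
#'   before correlating, so profiles are compared over the 20 amino acids
#'   only. Default `TRUE`: residual gaps in kept columns are a 21st residue
#'   type and participate in the statistics.
#' @return A `cmca_cor` object: list with `values` (L x L symmetric matrix
#'   with unit diagonal, dimnames = profile column names), `flavor`, and
#'   `undefined` (integer positions with zero-variance profiles).
#' @export
profile_correlation <- function(profile,
                                flavor = c("conservation", "mutation"),
                                include_gap_row = TRUE) {
  flavor <- match.arg(flavor)
  stopifnot(is.matrix(profile))
  if (ncol(profile) < 2L) {
    stop("need at least 2 positions to correlate, got ", ncol(profile))
  }
  if (!include_gap_row) {
    profile <- profile[-1L, , drop = FALSE]
  }
  M <- nrow(profile)
  centered <- sweep(profile, 2L, colMeans(profile), "-")
  cov <- crossprod(centered) / M             # population covariance over types
  v <- diag(cov)
  undefined <- which(v <= 0 | !is.finite(v))
  sd <- sqrt(v)
  sd[undefined] <- 1                          # placeholder; rows zeroed below
  r <- cov / tcrossprod(sd)
  r <- (r + t(r)) / 2                         # enforce exact symmetry
  if (length(undefined) > 0L) {
    r[undefined, ] <- 0
    r[, undefined] <- 0
  }
  diag(r) <- 1
  dimnames(r) <- list(colnames(profile), colnames(profile))
  structure(
    list(values = r, flavor = flavor, undefined = as.integer(undefined)),
    class = "cmca_cor"
  )
}

#' @export
print.cmca_cor <- function(x, ...) {
  cat("cmca_cor (", x$flavor, "): ", nrow(x$values), " x ", ncol(x$values),
      ", ", length(x$undefined), " undefined position(s)\n", sep = "")
  invisible(x)
}

#' Position conservation correlation matrix
#'
#' Correlates the raw frequency profiles of every pair of kept columns:
#' positions whose residue-type usage rises and falls together across the
#' 21 types are reported as conservation-coupled.
#'
#' @inheritParams mutation_matrix
#' @inheritParams profile_correlation
#' @return A `cmca_cor` with flavor `"conservation"`.
#' @export
conservation_correlation <- function(freq, include_gap_row = TRUE) {
  stopifnot(inherits(freq, "cmca_freq"))
  profile <- freq$counts
  storage.mode(profile) <- "double"
  profile_correlation(profile, flavor = "conservation",
                      include_gap_row = include_gap_row)
}

#' Position mutation correlation matrix
#'
#' Correlates the mutative-factor profiles of every pair of kept columns.
#' Because the mutative factor peaks at the average frequency, this flavor
#' highlights pairs of positions whose patterns of mutability — rather than
#' of conservation — covary, the signature of a mutually mutative couple.
#'
#' @inheritParams conservation_correlation
#' @return A `cmca_cor` with flavor `"mutation"`.
#' @export
mutation_correlation <- function(freq, include_gap_row = TRUE) {
  stopifnot(inherits(freq, "cmca_freq"))
  tm <- mutation_matrix(freq)
  profile_correlation(tm$values, flavor = "mutation",
                      include_gap_row = include_gap_row)
}
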