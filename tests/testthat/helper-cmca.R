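# Shared fixtures and independent oracles for the test suite.

# Write records to a temporary FASTA file and return its path.
tmp_fasta <- function(ids, rows) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), rows)), path)
  path
}

# Independent per-pair Pearson correlation: explicit loop over the textbook
# formula, no shared code with profile_correlation().
brute_force_pearson <- function(profile) {
  L <- ncol(profile)
  out <- matrix(NA_real_, L, L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      x <- profile[, i]
      y <- profile[, j]
      cx <- x - mean(x)
      cy <- y - mean(y)
      out[i, j] <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
    }
  }
  out
}

# Independent connected components by transitive closure over a boolean
# adjacency matrix (no graph library).
transitive_closure_components <- function(pairs) {
  verts <- sort(unique(c(pairs$i, pairs$j)))
  n <- length(verts)
  adj <- diag(n) > 0
  for (k in seq_len(nrow(pairs))) {
    a <- match(pairs$i[k], verts)
    b <- match(pairs$j[k], verts)
    adj[a, b] <- adj[b, a] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comps <- unique(apply(adj, 1, function(row) paste(which(row), collapse = ",")))
  lapply(comps, function(key) verts[as.integer(strsplit(key, ",")[[1]])])
}

# Small noisy family used by several tests: 2 coupled pairs, one gap column.
small_family <- function(seed = 101L) {
  generate_family(family_spec(
    N = 120L, L = 20L, background = 0.85,
    gap_columns = data.frame(column = 5L, fraction = 0.9),
    coupled_sets = list(c(3L, 11L), c(8L, 17L)),
    states_per_set = 3L, seed = seed
  ))
}
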