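test_that("residue-type diversity counts nonzero symbol rows", {
  counts <- matrix(0L, 21, 3, dimnames = list(cmca_alphabet()$symbols, 1:3))
  counts["A", 1] <- 10L
  counts[c("A", "C", "-"), 2] <- c(5L, 4L, 1L)
  counts[c("-", "Y"), 3] <- c(1L, 9L)
  freq <- structure(list(counts = counts, N = 10L, L = 3L, reduced = TRUE),
                    class = "cmca_freq")
  expect_equal(amino_acid_types(freq), c(1L, 3L, 2L), ignore_attr = TRUE)
})

test_that("mutative factor matches its defining constraints", {
  # printed reference point: N = 100, n = 20 peaks at 19 when f = N/n = 5
  expect_equal(mutative_factor(5, N = 100, n = 20), 19)
  # invariant column scores 0 at every frequency
  expect_equal(mutative_factor(0:100, N = 100, n = 1), rep(0, 101))
  # direct evaluation of the closed form
  expect_equal(mutative_factor(60, N = 100, n = 2), 1 / 11)

  # constraint suite over several family sizes and all diversities:
  for (N in c(10L, 100L, 240L)) {
    for (n in 2:21) {
      t <- mutative_factor(0:N, N = N, n = n)
      expect_true(all(is.finite(t)) && all(t >= 0))
      # maximal exactly at the integer frequencies closest to N/n,
      # with peak value n - 1 iff N/n is attainable as an integer
      mean_f <- N / n
      expect_equal(which.max(t) - 1L, round(mean_f))
      if (mean_f == round(mean_f)) expect_equal(max(t), n - 1)
      # strict monotone decay away from the average frequency
      d <- abs((0:N) - mean_f)
      ord <- order(d)
      expect_true(all(diff(t[ord]) <= 0))
      expect_true(max(t) <= n - 1)
    }
  }

  expect_error(mutative_factor(5, N = 100, n = 25), "1\\.\\.21")
  expect_error(mutative_factor(-1, N = 100, n = 2), "\\[0, N\\]")
  expect_error(mutative_factor(5, N = 0, n = 2), ">= 1")
})

test_that("mutation matrix applies the factor to every symbol, absent ones too", {
  counts <- matrix(0L, 21, 2, dimnames = list(cmca_alphabet()$symbols, 1:2))
  counts["A", 1] <- 100L                   # invariant column
  counts[c("A", "C"), 2] <- c(50L, 50L)    # two types at the average
  freq <- structure(list(counts = counts, N = 100L, L = 2L, reduced = TRUE),
                    class = "cmca_freq")
  tm <- mutation_matrix(freq)
  expect_equal(tm$n, c(1L, 2L), ignore_attr = TRUE)
  expect_equal(tm$values[, 1], rep(0, 21), ignore_attr = TRUE)
  expect_equal(tm$values["A", 2], 1)
  expect_equal(tm$values["C", 2], 1)
  expect_equal(tm$values["G", 2], 1 / 51)  # absent symbol, f = 0
  expect_true(all(tm$values <= 20))
})

test_that("profile correlation matches brute-force Pearson and stats::cor", {
  set.seed(7)
  for (rep in 1:100) {
    profile <- matrix(stats::rnorm(21 * 10), 21, 10)
    r <- profile_correlation(profile)$values
    expect_equal(unname(r), brute_force_pearson(profile), tolerance = 1e-10)
    expect_equal(unname(r), unname(stats::cor(profile)), tolerance = 1e-10)
  }
})

test_that("correlation matrices are symmetric, bounded, unit-diagonal", {
  fam <- small_family()
  freq <- reduce_gaps(position_frequencies(encode_alignment(fam$alignment)))$freq
  for (corr in list(conservation_correlation(freq), mutation_correlation(freq))) {
    v <- corr$values
    expect_identical(v, t(v))
    expect_true(all(v >= -1 - 1e-9 & v <= 1 + 1e-9))
    expect_equal(diag(v), rep(1, ncol(v)), ignore_attr = TRUE)
  }
})

test_that("identical columns correlate at exactly 1 in both flavors", {
  # two positions with identical profiles {A:9, C:1} among noise
  mat <- cbind(c(rep("A", 9), "C"), c(rep("A", 9), "C"),
               c(rep("G", 5), rep("H", 5)))
  aln <- new_alignment(sprintf("s%02d", 1:10), apply(mat, 1, paste, collapse = ""))
  freq <- reduce_gaps(position_frequencies(encode_alignment(aln)))$freq
  expect_equal(conservation_correlation(freq)$values[1, 2], 1)
  expect_equal(mutation_correlation(freq)$values[1, 2], 1)
})

test_that("zero-variance positions are flagged undefined and zeroed", {
  # column 1 invariant -> mutation profile all zero -> undefined
  mat <- cbind(rep("A", 10), c(rep("C", 5), rep("D", 5)),
               c(rep("E", 3), rep("F", 7)))
  aln <- new_alignment(sprintf("s%02d", 1:10), apply(mat, 1, paste, collapse = ""))
  freq <- reduce_gaps(position_frequencies(encode_alignment(aln)))$freq
  rmut <- mutation_correlation(freq)
  expect_equal(rmut$undefined, 1L)
  expect_equal(rmut$values[1, -1], c(0, 0), ignore_attr = TRUE)
  expect_equal(rmut$values[1, 1], 1)
})

test_that("correlations are invariant to profile scaling and covariance divisor", {
  set.seed(11)
  profile <- matrix(stats::rexp(21 * 8), 21, 8)
  r <- profile_correlation(profile)$values
  # positive scaling of all profiles
  expect_true(max(abs(profile_correlation(profile * 37.5)$values - r)) < 1e-12)
  # sample-covariance (divisor M-1) route computed independently
  r_sample <- stats::cov(profile) /
    tcrossprod(sqrt(diag(stats::cov(profile))))
  expect_true(max(abs(unname(r) - unname(r_sample))) < 1e-12)
})

test_that("gap row participation is switchable", {
  fam <- small_family()
  freq <- reduce_gaps(position_frequencies(encode_alignment(fam$alignment)))$freq
  r21 <- conservation_correlation(freq, include_gap_row = TRUE)$values
  r20 <- conservation_correlation(freq, include_gap_row = FALSE)$values
  expect_equal(dim(r20), dim(r21))
  # independent check of the 20-type convention on one pair
  prof <- freq$counts[-1, , drop = FALSE]
  expect_equal(r20[1, 2], stats::cor(prof[, 1], prof[, 2]), tolerance = 1e-12)
})

test_that("degenerate shapes are rejected", {
  expect_error(profile_correlation(matrix(1:21, ncol = 1)), "at least 2")
})
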