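mk_cor <- function(values, flavor = "mutation", undefined = integer(0)) {
  structure(list(values = values, flavor = flavor, undefined = undefined),
            class = "cmca_cor")
}

test_that("display masking keeps >= floor and always hides the diagonal", {
  v <- diag(3)
  v[2, 1] <- v[1, 2] <- 0.49
  v[3, 1] <- v[1, 3] <- 0.50
  v[3, 2] <- v[2, 3] <- 0.95
  m <- filter_display(mk_cor(v), floor = 0.5)
  expect_true(is.na(m[2, 1]))          # below the floor
  expect_equal(m[3, 1], 0.50)          # exactly at the floor is retained
  expect_equal(m[3, 2], 0.95)
  expect_true(all(is.na(diag(m))))

  expect_true(all(is.na(filter_display(mk_cor(diag(3))))))  # identity: all masked
  m0 <- filter_display(mk_cor(v), floor = 0)
  expect_equal(sum(is.na(m0)), 3L)     # floor 0: only the diagonal masked
})

test_that("pair extraction is strict, one-sided, and sorted", {
  v <- diag(4)
  v[3, 1] <- v[1, 3] <- 0.85
  v[4, 2] <- v[2, 4] <- 0.80    # exactly at threshold: excluded
  v[4, 3] <- v[3, 4] <- 0.91
  pairs <- extract_pairs(mk_cor(v), threshold = 0.80)
  expect_equal(nrow(pairs), 2L)
  expect_equal(pairs$i, c(3L, 4L))
  expect_equal(pairs$j, c(1L, 3L))
  expect_true(all(pairs$i > pairs$j))  # never both (i,j) and (j,i)
  expect_equal(pairs$r, c(0.85, 0.91))

  none <- extract_pairs(mk_cor(diag(4)), threshold = 0.8)
  expect_equal(nrow(none), 0L)
})

test_that("region clustering is single linkage under Chebyshev distance", {
  p <- data.frame(i = c(10L, 12L), j = c(3L, 4L), r = c(0.9, 0.9))
  one <- cluster_regions(p, radius = 5L)
  expect_equal(unique(one$region), "R1")

  p2 <- data.frame(i = c(10L, 80L), j = c(3L, 60L), r = c(0.9, 0.9))
  two <- cluster_regions(p2, radius = 5L)
  expect_equal(two$region, c("R1", "R2"))
  boxes <- attr(two, "regions")
  expect_equal(boxes$region, c("R1", "R2"))
  expect_equal(boxes$i_min, c(10L, 80L))

  # chains link transitively: (1,..) - (6,..) - (11,..) all one region at radius 5
  p3 <- data.frame(i = c(11L, 16L, 21L), j = c(1L, 2L, 3L), r = rep(0.9, 3))
  expect_equal(unique(cluster_regions(p3, radius = 5L)$region), "R1")
  # ... but split at radius 2
  expect_equal(length(unique(cluster_regions(p3, radius = 2L)$region)), 3L)

  empty <- cluster_regions(extract_pairs(mk_cor(diag(3))), radius = 5L)
  expect_equal(nrow(empty), 0L)
  expect_equal(nrow(attr(empty, "regions")), 0L)
})

test_that("groups are connected components of the pair graph", {
  p <- data.frame(i = c(46L, 83L), j = c(14L, 14L), r = c(0.8522, 0.8922))
  g <- build_groups(p)
  expect_length(g, 1L)
  expect_equal(g[[1]]$members, c(14L, 46L, 83L))

  # a published-style pair list in reference numbering closes into {16,41,78}
  p2 <- data.frame(i = c(41L, 78L, 78L), j = c(16L, 16L, 41L), r = rep(0.9, 3))
  g2 <- build_groups(p2)
  expect_length(g2, 1L)
  expect_equal(g2[[1]]$members, c(16L, 41L, 78L))
  expect_equal(nrow(g2[[1]]$pairs), 3L)

  expect_length(build_groups(p[0, , drop = FALSE]), 0L)

  # min_size filters but never merges
  p3 <- data.frame(i = c(2L, 5L, 6L), j = c(1L, 4L, 4L), r = rep(0.9, 3))
  expect_length(build_groups(p3, min_size = 2L), 2L)
  g3 <- build_groups(p3, min_size = 3L)
  expect_length(g3, 1L)
  expect_equal(g3[[1]]$members, 4:6)
})

test_that("groups agree with a transitive-closure oracle on random pair sets", {
  set.seed(5)
  for (rep in 1:20) {
    n_pairs <- sample(1:50, 1)
    ij <- t(replicate(n_pairs, sort(sample.int(40, 2), decreasing = TRUE)))
    p <- unique(data.frame(i = ij[, 1], j = ij[, 2], r = 0.9))
    got <- lapply(build_groups(p, min_size = 2L), `[[`, "members")
    want <- transitive_closure_components(p)
    want <- want[order(vapply(want, min, integer(1)))]
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("report renders dual numbering with '-' for reference gaps", {
  # reduced positions 14 and 83 map to reference residues 16 and 78;
  # position 34 falls on a reference gap
  kept <- 1:90
  numbering <- rep(NA_integer_, 90)
  numbering[14] <- 16L
  numbering[83] <- 78L
  numbering[46] <- 41L
  pm <- structure(list(kept = kept, q = rep(1, 95),
                       reference = list(id = "REF", numbering = numbering)),
                  class = "cmca_posmap")
  pairs <- data.frame(i = c(83L, 83L), j = c(14L, 34L),
                      r = c(0.892220, 0.81), region = c("R8", "R9"))
  attr(pairs, "regions") <- data.frame(region = c("R8", "R9"))
  groups <- build_groups(pairs)
  rep_ <- coupling_report(pairs, groups, pm, undefined = 7L,
                          parameters = list(pair_threshold = 0.8))
  path <- tempfile(fileext = ".tsv")
  write_pairs_tsv(rep_, path)
  lines <- readLines(path)
  expect_equal(lines[2], "R8\t83\t14\t0.892220\t78\t16")
  expect_equal(lines[3], "R9\t83\t34\t0.810000\t78\t-")

  jpath <- tempfile(fileext = ".json")
  write_report_json(rep_, jpath)
  back <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(back$undefined_positions, 7L)
  expect_equal(back$pairs$r[1], 0.892220)
  expect_equal(back$parameters$pair_threshold, 0.8)

  # inconsistent indices are caught
  bad <- data.frame(i = 99L, j = 1L, r = 0.9)
  expect_error(coupling_report(bad, list(), pm), "inconsistent")

  # empty analysis yields a valid empty report
  e <- coupling_report(pairs[0, , drop = FALSE], list(), pm)
  expect_equal(nrow(e$pairs), 0L)
  write_pairs_tsv(e, path)
  expect_length(readLines(path), 1L)
})
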