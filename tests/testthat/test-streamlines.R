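tract_spec <- function(name = "t1", from = c(40, -80, -10),
                       to = c(45, -40, 5), n_streamlines = 50) {
  list(name = name, from = from, to = to, n_streamlines = n_streamlines)
}

test_that("degenerate scatter puts all endpoints of a tract into two voxels", {
  sets <- simulate_tract_endpoints(3, list(tract_spec()), scatter_sd = 0,
                                   rng_seed = 1)
  expect_length(sets, 3)
  s <- sets[[1]]
  firsts <- unique(t(vapply(s$streamlines, function(m) floor(m[1, ]),
                            numeric(3))))
  lasts <- unique(t(vapply(s$streamlines,
                           function(m) floor(m[nrow(m), ]), numeric(3))))
  expect_equal(nrow(firsts), 1)
  expect_equal(nrow(lasts), 1)
  # per-subject x tract count and validation
  many <- simulate_tract_endpoints(20, list(tract_spec(), tract_spec("t2")),
                                   rng_seed = 2)
  expect_length(many, 40)
  expect_error(simulate_tract_endpoints(0, list(tract_spec())), "n_subjects")
  expect_error(simulate_tract_endpoints(2, list()), "tract_specs")
  expect_error(simulate_tract_endpoints(2, list(tract_spec()),
                                        scatter_sd = -1), "scatter_sd")
})

test_that("outlier cleaning matches an independently coded brute-force filter", {
  set.seed(51)
  s <- simulate_tract_endpoints(1, list(tract_spec(n_streamlines = 50)),
                                scatter_sd = 2, rng_seed = 3)[[1]]
  # inject a length outlier and a displaced streamline
  long <- s$streamlines[[1]]
  long[, 2] <- long[, 2] * 10
  s$streamlines[[51]] <- long
  far <- s$streamlines[[2]] + 500
  s$streamlines[[52]] <- far
  cleaned <- clean_streamline_outliers(s)
  # brute force with plain loops
  cents <- t(sapply(s$streamlines, colMeans))
  cd <- sqrt(rowSums((cents - matrix(colMeans(cents), nrow(cents), 3,
                                     byrow = TRUE))^2))
  lens <- sapply(s$streamlines, function(m) sum(sqrt(rowSums(diff(m)^2))))
  bad <- (abs(cd - mean(cd)) > 4 * sd(cd)) |
    (abs(lens - mean(lens)) > 4 * sd(lens))
  expect_setequal(attr(cleaned, "removed"), which(bad))
  expect_length(cleaned$streamlines, 52 - sum(bad))
  expect_true(51 %in% attr(cleaned, "removed") ||
                52 %in% attr(cleaned, "removed"))
})

test_that("identical streamlines survive cleaning (zero SD is no-removal)", {
  m <- cbind(seq(0, 10, length.out = 5), 0, 0)
  s <- structure(list(tract = "t", subject = "s",
                      streamlines = rep(list(m), 10)),
                 class = "streamline_set")
  cleaned <- clean_streamline_outliers(s)
  expect_length(cleaned$streamlines, 10)
  expect_length(attr(cleaned, "removed"), 0)
})

test_that("a grossly longer streamline among near-identical ones is removed", {
  set.seed(52)
  base <- lapply(1:100, function(i)
    cbind(seq(0, 10, length.out = 10) + rnorm(10, 0, 0.01), 0, 0))
  long <- cbind(seq(0, 100, length.out = 10), 0, 0)
  s <- structure(list(tract = "t", subject = "s",
                      streamlines = c(base, list(long))),
                 class = "streamline_set")
  cleaned <- clean_streamline_outliers(s)
  expect_true(101 %in% attr(cleaned, "removed"))
})

test_that("reorientation aligns flipped streamlines without moving points", {
  set.seed(53)
  s <- simulate_tract_endpoints(1, list(tract_spec()), scatter_sd = 2,
                                rng_seed = 4)[[1]]
  flipped <- s
  rev_idx <- seq(2, 50, by = 2)
  for (i in rev_idx)
    flipped$streamlines[[i]] <-
      flipped$streamlines[[i]][rev(seq_len(nrow(flipped$streamlines[[i]]))), ]
  out <- reorient_streamlines(flipped)
  # already-aligned sets are untouched
  expect_identical(reorient_streamlines(s)$streamlines, s$streamlines)
  # after reorientation every first endpoint sits near the "from" centroid:
  # brute-force pairing bound from the generator's scatter
  firsts <- t(vapply(out$streamlines, function(m) m[1, ], numeric(3)))
  expect_true(all(sqrt(rowSums(sweep(firsts, 2, c(40, -80, -10))^2)) < 10))
  # reorienting the flipped copies restores the original point order
  for (i in rev_idx)
    expect_equal(out$streamlines[[i]], s$streamlines[[i]])
  # a single streamline is its own reference
  one <- structure(list(tract = "t", subject = "s",
                        streamlines = s$streamlines[1]),
                   class = "streamline_set")
  expect_identical(reorient_streamlines(one)$streamlines, one$streamlines)
})

test_that("streamline sets round-trip through the TSV interchange format", {
  s <- simulate_tract_endpoints(1, list(tract_spec(n_streamlines = 5)),
                                rng_seed = 5)[[1]]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_streamlines_tsv(s, path)
  s2 <- read_streamlines_tsv(path, tract = s$tract, subject = s$subject)
  expect_length(s2$streamlines, 5)
  for (i in 1:5)
    expect_equal(s2$streamlines[[i]], s$streamlines[[i]], tolerance = 1e-6)
})
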