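# Genotype frequency models: Hardy-Weinberg binomial, hypergeometric
# gametes, F1 convolution, parent-pair enumeration and priors.

test_that("Hardy-Weinberg frequencies match the explicit binomial formula", {
  # independent oracle: write the pmf out by hand
  bin_oracle <- function(m, p)
    sapply(0:m, function(g) choose(m, g) * p^g * (1 - p)^(m - g))
  expect_equal(hw_frequencies(4, 0), c(1, 0, 0, 0, 0))
  expect_equal(hw_frequencies(2, 0.5), c(0.25, 0.5, 0.25))
  expect_equal(hw_frequencies(4, 0.5), c(0.0625, 0.25, 0.375, 0.25, 0.0625))
  for (m in c(1, 2, 3, 6, 16))
    for (p in c(0, 0.17, 0.5, 0.83, 1))
      expect_equal(hw_frequencies(m, p), bin_oracle(m, p), tolerance = 1e-12)
  expect_error(hw_frequencies(4, 1.2), "\\[0, 1\\]")
})

test_that("gamete pmf matches the explicit hypergeometric formula", {
  hyp_oracle <- function(m, d) {
    k <- m / 2
    sapply(0:k, function(j) choose(d, j) * choose(m - d, k - j) / choose(m, k))
  }
  expect_equal(gamete_pmf(2, 1), c(0.5, 0.5))
  expect_equal(gamete_pmf(4, 2), c(1 / 6, 2 / 3, 1 / 6))
  expect_equal(gamete_pmf(4, 0), c(1, 0, 0))
  for (m in c(2, 4, 8, 16))
    for (d in 0:m)
      expect_equal(gamete_pmf(m, d), hyp_oracle(m, d), tolerance = 1e-12)
  expect_error(gamete_pmf(3, 1), "odd ploidy")
})

test_that("F1 frequencies are the gamete convolution and are symmetric", {
  conv_oracle <- function(m, p1, p2) {
    g1 <- gamete_pmf(m, p1)
    g2 <- gamete_pmf(m, p2)
    sapply(0:m, function(t) {
      js <- max(0, t - m / 2):min(m / 2, t)
      sum(g1[js + 1] * g2[t - js + 1])
    })
  }
  expect_equal(f1_frequencies(2, 0, 0), c(1, 0, 0))
  expect_equal(f1_frequencies(2, 1, 1), c(0.25, 0.5, 0.25))
  expect_equal(f1_frequencies(4, 1, 0), c(0.5, 0.5, 0, 0, 0))
  for (m in c(2, 4, 10)) {
    for (p1 in 0:m) for (p2 in 0:m) {
      f <- f1_frequencies(m, p1, p2)
      expect_equal(f, conv_oracle(m, p1, p2), tolerance = 1e-12)
      expect_equal(f, f1_frequencies(m, p2, p1), tolerance = 1e-14)
    }
  }
})

test_that("every frequency vector is a unimodal (no internal gap) simplex point", {
  check_vec <- function(f, what) {
    expect_equal(sum(f), 1, tolerance = 1e-12, label = what)
    expect_true(all(f >= 0), label = what)
    # no nonzero-zero-nonzero pattern: support must be one contiguous run
    nz <- which(f > 1e-14)
    expect_true(all(diff(nz) == 1), label = what)
  }
  for (m in seq(2, 16, by = 2)) {
    for (p in seq(0, 1, by = 0.1))
      check_vec(hw_frequencies(m, p), sprintf("hw m=%d p=%g", m, p))
    for (p1 in 0:m) for (p2 in p1:m)
      check_vec(f1_frequencies(m, p1, p2),
                sprintf("f1 m=%d (%d,%d)", m, p1, p2))
  }
})

test_that("HW frequencies obey the allele-swap mirror symmetry", {
  for (m in c(2, 4, 6)) for (p in c(0.1, 0.3, 0.77))
    expect_equal(hw_frequencies(m, p), rev(hw_frequencies(m, 1 - p)),
                 tolerance = 1e-14)
})

test_that("parent-pair enumeration counts follow the combinatorics", {
  pairs <- enumerate_parent_pairs(2, distinct_only = TRUE)
  expect_equal(nrow(pairs), 3)
  expect_setequal(paste(pairs[, 1], pairs[, 2]), c("0 1", "0 2", "1 2"))
  expect_equal(nrow(enumerate_parent_pairs(2)), 6)
  for (m in seq(2, 16, by = 2)) {
    expect_equal(nrow(enumerate_parent_pairs(m)), (m + 1) * (m + 2) / 2)
    expect_equal(nrow(enumerate_parent_pairs(m, ordered = TRUE)), (m + 1)^2)
    expect_equal(nrow(enumerate_parent_pairs(m, distinct_only = TRUE)),
                 m * (m + 1) / 2)
  }
})

test_that("parent-pair priors are uniform and match the pair counts", {
  expect_equal(parent_pair_prior(2, has_parent_data = FALSE), 1 / 6)
  expect_equal(parent_pair_prior(2, has_parent_data = TRUE), 1 / 9)
  for (m in c(4, 10)) {
    expect_equal(parent_pair_prior(m, FALSE),
                 1 / nrow(enumerate_parent_pairs(m)))
    expect_equal(parent_pair_prior(m, TRUE),
                 1 / nrow(enumerate_parent_pairs(m, ordered = TRUE)))
  }
})

test_that("parental replicate likelihood is additive and peaks at the true dosage", {
  pts <- data.frame(x = c(30, 30), y = c(70, 70)) # r = 0.3 = 3/10
  ll <- sapply(0:10, function(d) parent_data_loglik(pts, d, 10, 0.05))
  expect_equal(which.max(ll) - 1, 3)
  one <- parent_data_loglik(pts[1, ], 3, 10, 0.05)
  expect_equal(ll[4], 2 * one, tolerance = 1e-12)
  expect_identical(parent_data_loglik(NULL, 3, 10, 0.05), 0)
  expect_identical(parent_data_loglik(pts[0, ], 3, 10, 0.05), 0)
})

test_that("custom frequency models round-trip through the TSV interface", {
  path <- tempfile(fileext = ".tsv")
  tab <- data.frame(param_id = rep(c("a", "b"), each = 3),
                    dosage = rep(0:2, 2),
                    frequency = c(0.2, 0.5, 0.3, 1, 0, 0))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  mod <- read_custom_model(path)
  expect_named(mod, c("a", "b"))
  expect_equal(mod$a, c(0.2, 0.5, 0.3))
  expect_equal(mod$b, c(1, 0, 0))
})
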