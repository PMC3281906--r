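# Shared generators for small randomized test instances.

# a random oracle-sized instance: small enough for exhaustive enumeration
random_small_instance <- function(seed, n_range = 5:8, ploidies = c(2L, 4L)) {
  set.seed(seed)
  m <- sample(ploidies, 1)
  n <- sample(n_range, 1)
  model <- if (stats::runif(1) < 0.5) {
    list(type = "hw", p = stats::runif(1, 0.1, 0.9))
  } else {
    list(type = "f1", p1 = sample(0:m, 1), p2 = sample(0:m, 1))
  }
  sigma_gen <- stats::runif(1, 0.03, 0.12)
  sim <- simulate_locus(m, model, n = n, sigma = sigma_gen, seed = seed + 1)
  sigma_fit <- stats::runif(1, 0.03, 0.3)
  list(m = m, n = n, model = model, sim = sim,
       F = sim$params$F,
       table = build_table(sim$dataset, m, sigma_fit))
}

# is the assignment contiguous (dosage non-decreasing) along the sorted
# normalized coordinate?
is_contiguous <- function(assignment, table) {
  a <- assignment[table$ids]
  all(diff(a) >= 0)
}

# all distinct permutations of a small vector, by recursion
combinat_perms <- function(v) {
  if (length(v) == 1) return(matrix(v, 1))
  out <- NULL
  for (u in unique(v)) {
    rest <- v[-match(u, v)]
    sub <- combinat_perms(rest)
    out <- rbind(out, cbind(u, sub))
  }
  unname(out)
}
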