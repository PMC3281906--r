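# MAP inference engines: joint scoring, greedy baseline, exact engines,
# posterior approximation.

make_table <- function(r, m, sigma) {
  df <- data.frame(individual_id = sprintf("i%02d", seq_along(r)),
                   x = 100 * r, y = 100 * (1 - r))
  build_table(locus_dataset(df), m, sigma)
}

test_that("the joint multinomial term matches dmultinom and handles zeros", {
  expect_equal(log_joint(c(2, 0), 0, c(1, 0)), 0) # n!/n! * 1^n
  expect_equal(exp(log_joint(c(1, 1), 0, c(0.5, 0.5))), 0.5)
  expect_equal(exp(log_joint(c(2, 0), 0, c(0.5, 0.5))), 0.25)
  expect_identical(log_joint(c(1, 1), 0, c(1, 0)), -Inf)
  # cross-check against the reference implementation on positive vectors
  set.seed(3)
  for (i in 1:20) {
    F <- as.numeric(rmultinom(1, 50, rep(1, 4))) / 50
    F <- (F + 0.01) / sum(F + 0.01)
    c_ <- as.numeric(rmultinom(1, 12, F))
    expect_equal(log_joint(c_, 0, F),
                 dmultinom(c_, prob = F, log = TRUE), tolerance = 1e-12)
  }
  expect_equal(log_joint(c(1, 1), -3, c(0.5, 0.5), prior_terms = -1),
               log(0.5) - 4)
})

test_that("greedy assigns nearest dosage but can miss the coupled optimum", {
  tab <- make_table(0.02, 2, 0.1)
  g <- greedy_fit(tab, hw_frequencies(2, 0.5))
  expect_equal(unname(g$assignment), 0)
  # four individuals exactly between clusters: the multinomial rewards
  # splitting them even though each is individually likeliest at g = 1
  tab <- make_table(rep(0.5, 4), 2, 0.3)
  F <- c(0.45, 0.1, 0.45)
  g <- greedy_fit(tab, F)
  nv <- naive_map(tab, F)
  expect_equal(unname(g$assignment), rep(1, 4))
  expect_true(any(nv$assignment != 1))
  expect_gt(nv$log_joint, g$log_joint)
})

test_that("greedy equals the exhaustive MAP when the frequency vector is flat and points sit on angles", {
  tab <- make_table(c(0, 0.5, 0.5, 1), 2, 0.08)
  F <- rep(1 / 3, 3)
  g <- greedy_fit(tab, F)
  nv <- naive_map(tab, F)
  expect_equal(g$log_joint, nv$log_joint, tolerance = 1e-12)
})

test_that("the naive oracle refuses oversized instances and excludes zero classes", {
  tab <- make_table(runif(50), 2, 0.1)
  expect_error(naive_map(tab, hw_frequencies(2, 0.5)),
               class = "polydose_guard")
  tab <- make_table(c(0.1, 0.9), 2, 0.1)
  nv <- naive_map(tab, c(0.5, 0, 0.5))
  expect_true(all(nv$assignment != 1))
})

test_that("contiguous block assignment is likelihood-optimal for fixed counts", {
  tab <- make_table(c(0.05, 0.45, 0.55, 0.95), 2, 0.1)
  res <- best_config_for_distribution(tab, c(1, 2, 1))
  expect_equal(unname(res$assignment), c(0, 1, 1, 2))
  # brute force over all placements with the same counts
  perms <- unique(combinat_perms(c(0, 1, 1, 2)))
  lls <- apply(perms, 1, function(a)
    sum(tab$logL[cbind(1:4, a + 1)]))
  expect_equal(res$config_loglik, max(lls), tolerance = 1e-12)
})


test_that("exact engines agree with the exhaustive oracle on random instances", {
  for (i in 1:25) {
    inst <- random_small_instance(3000 + i)
    nv <- naive_map(inst$table, inst$F)
    ge <- geometric_map(inst$table, inst$F)
    dp <- dp_map(inst$table, inst$F)
    expect_equal(ge$log_joint, nv$log_joint, tolerance = 1e-9)
    expect_equal(dp$log_joint, nv$log_joint, tolerance = 1e-9)
    gr <- greedy_fit(inst$table, inst$F)
    expect_gte(ge$log_joint, gr$log_joint - 1e-12)
    expect_true(is_contiguous(ge$assignment, inst$table))
  }
})

test_that("the geometric optimum does not depend on the starting incumbent", {
  for (i in 1:10) {
    inst <- random_small_instance(4500 + i, n_range = 6:9)
    warm <- geometric_map(inst$table, inst$F)           # greedy incumbent
    cold <- geometric_map(inst$table, inst$F, incumbent = -Inf)
    expect_equal(warm$log_joint, cold$log_joint, tolerance = 1e-12)
    # visited leaves never exceed the total number of distributions
    n <- nrow(inst$table$logL); m <- inst$m
    expect_lte(cold$visited_nodes, choose(n + m, m))
    expect_lte(warm$visited_nodes, cold$visited_nodes)
  }
})

test_that("tau scales the posterior slack by the number of settings", {
  expect_equal(tau_from_epsilon(0.01, 101), 1e-4)
  expect_equal(tau_from_epsilon(0.01, 1), 0.01)
  expect_error(tau_from_epsilon(0, 5))
})

test_that("the posterior approximation normalizes per-setting MAP joints", {
  expect_equal(approximate_posterior(0.3), 1)
  expect_equal(approximate_posterior(c(-5, -5), 1), 0.5)
  expect_equal(approximate_posterior(c(0, -log(2), -log(2)), 1), 0.5)
  expect_equal(approximate_posterior(c(-1000, -1001), 1),
               1 / (1 + exp(-1)), tolerance = 1e-12)
})

test_that("the full fit recovers the generating ploidy and parameters", {
  sim <- simulate_locus(4, list(type = "hw", p = 0.5), n = 200,
                        sigma = 0.05, seed = 1)
  st <- search_settings(ploidy_range = c(2, 4, 6))
  fit <- fit_locus(sim$dataset, "hw", st)
  expect_equal(fit$m, 4)
  expect_equal(fit$theta$p, 0.5, tolerance = 0.06)
  acc <- mean(fit$assignment[names(sim$genotypes)] == sim$genotypes)
  expect_gt(acc, 0.95)
  expect_true(is_contiguous(fit$assignment,
                            build_table(sim$dataset, fit$m, fit$sigma)))
  expect_equal(fit$n_settings, nrow(fit$settings_table))
  expect_gte(fit$config_posterior, 0)
  expect_lte(fit$config_posterior, 1)
})

test_that("a single-cluster locus falls back to the lowest searched ploidy", {
  df <- data.frame(individual_id = sprintf("i%02d", 1:30),
                   x = rep(50, 30), y = rep(50, 30))
  ds <- locus_dataset(df)
  fit <- fit_locus(ds, "hw", search_settings(ploidy_range = c(2, 4, 6),
                                             sigma_grid = c(0.05, 0.1)))
  expect_equal(fit$m, 2)
})

test_that("F1 fits with parental data pin the parent dosages", {
  sim <- simulate_locus(4, list(type = "f1", p1 = 1, p2 = 0), n = 150,
                        sigma = 0.05, parent_replicates = 12, seed = 77)
  st <- search_settings(ploidy_range = c(2, 4))
  fit <- fit_locus(sim$dataset, "f1", st)
  expect_equal(fit$m, 4)
  expect_equal(c(fit$theta$p1, fit$theta$p2), c(1, 0))
})

test_that("the dp engine aborts via its guard on wide layers", {
  sim <- simulate_locus(10, list(type = "f1", p1 = 5, p2 = 3), n = 120,
                        sigma = 0.16, seed = 9)
  tab <- build_table(sim$dataset, 10, 0.16)
  expect_error(dp_map(tab, f1_frequencies(10, 5, 3), max_states = 2000),
               class = "polydose_dp_guard")
})
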