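#' Simulate a two-channel intensity dataset for one locus
#'
#' Generates data by the same process the model assumes: genotype counts
#' drawn from the population model's multinomial (or i.i.d. genotypes),
#' each replicate's normalized coordinate drawn as
#' `N(g / m, sigma^2)` truncated to `[0, 1]`, and channel intensities
#' emitted as `(T r, T (1 - r))` with total signal `T` drawn around
#' `total_intensity`. The total cancels in the L1 normalization, so its
#' scale is immaterial to the likelihood; it exists to make realistic raw
#' tables. An optional raw-channel noise mode adds Gaussian noise to x and
#' y directly, breaking the model's assumptions for robustness studies.
#'
#' @param m Ploidy.
#' @param model List describing the population model: `list(type = "hw",
#'   p = ...)`, `list(type = "f1", p1 = , p2 = )`, or
#'   `list(type = "custom", F = <frequency vector>)`.
#' @param n Number of individuals.
#' @param sigma Noise standard deviation of the normalized coordinate.
#' @param total_intensity Mean total signal per observation.
#' @param intensity_cv Coefficient of variation of the total signal.
#' @param replicates Replicate observations per individual.
#' @param parent_replicates For the F1 model: replicate observations per
#'   parent (0 for none).
#' @param counts_mode `"multinomial"` (default; matches the model's count
#'   coupling) or `"iid"` (independent genotype draws).
#' @param noise_on `"ratio"` (default; noise on the normalized coordinate,
#'   the generative model assumed by the likelihood) or `"channels"`
#'   (model-mismatch mode: Gaussian noise on each raw channel).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return List with `dataset` (a [locus_dataset()]), `genotypes` (named
#'   true dosage vector), and `params` (the generating parameters).
#' @export
simulate_locus <- function(m, model, n, sigma,
                           total_intensity = 100, intensity_cv = 0.1,
                           replicates = 1L, parent_replicates = 0L,
                           counts_mode = c("multinomial", "iid"),
                           noise_on = c("ratio", "channels"),
                           seed = NULL) {
  counts_mode <- match.arg(counts_mode)
  noise_on <- match.arg(noise_on)
  stopifnot(n >= 1, sigma > 0, replicates >= 1, total_intensity > 0)
  if (!is.null(seed)) set.seed(seed)
  F <- switch(model$type,
              hw = hw_frequencies(m, model$p),
              f1 = f1_frequencies(m, model$p1, model$p2),
              custom = model$F,
              stop("unknown model type: ", model$type))
  if (counts_mode == "multinomial") {
    counts <- as.integer(stats::rmultinom(1, n, F))
    genotypes <- rep.int(0:m, counts)
  } else {
    genotypes <- sample(0:m, n, replace = TRUE, prob = F)
  }
  ids <- sprintf("ind%04d", seq_len(n))
  names(genotypes) <- ids

  emit <- function(g_per_row) {
    k <- length(g_per_row)
    tot <- pmax(stats::rnorm(k, total_intensity,
                             intensity_cv * total_intensity),
                0.01 * total_intensity)
    if (noise_on == "ratio") {
      r <- pmin(pmax(stats::rnorm(k, g_per_row / m, sigma), 0), 1)
      data.frame(x = tot * r, y = tot * (1 - r), r = r)
    } else {
      x <- pmax(tot * g_per_row / m +
                  stats::rnorm(k, 0, sigma * total_intensity), 0)
      y <- pmax(tot * (1 - g_per_row / m) +
                  stats::rnorm(k, 0, sigma * total_intensity), 0)
      bad <- x + y <= 0
      x[bad] <- 1e-6
      data.frame(x = x, y = y)
    }
  }

  rows <- emit(rep(genotypes, each = replicates))
  drawn_r <- rows$r # NULL in channel-noise mode
  prog <- cbind(data.frame(individual_id = rep(ids, each = replicates),
                           stringsAsFactors = FALSE),
                rows[, c("x", "y")])
  p1 <- p2 <- NULL
  if (model$type == "f1" && parent_replicates > 0) {
    p1 <- emit(rep.int(model$p1, parent_replicates))[, c("x", "y")]
    p2 <- emit(rep.int(model$p2, parent_replicates))[, c("x", "y")]
  }
  dataset <- locus_dataset(prog, locus_id = sprintf("sim_m%d_%s", m,
                                                    model$type),
                           parent1 = p1, parent2 = p2)
  list(dataset = dataset, genotypes = genotypes, r = drawn_r,
       params = list(m = m, model = model, n = n, sigma = sigma,
                     F = F, seed = seed))
}

#' Write the canonical simulated fixture suite
#'
#' Produces the seeded delimited-text fixtures the test suite and the
#' benchmark harness read: a handful of oracle-sized instances (small
#' enough for exhaustive enumeration), two recovery-study instances, and a
#' synthetic sugarcane-like benchmark locus: 180 F1 progeny at ploidy 10
#' from a triplex x nulliplex cross with 12 replicates of each parent.
#' All files are regenerated identically on every call.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Base seed for the suite.
#' @return Data frame manifest (file, description), invisibly written to
#'   `manifest.tsv` as well.
#' @export
make_fixture_suite <- function(out_dir, seed = 42L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  put <- function(sim, file, what) {
    write_locus(sim$dataset, file.path(out_dir, file))
    truth <- data.frame(individual_id = names(sim$genotypes),
                        dosage = as.integer(sim$genotypes))
    utils::write.table(truth,
                       file.path(out_dir, sub("\\.tsv$", "_truth.tsv", file)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest[[length(manifest) + 1L]] <<- data.frame(file = file,
                                                     description = what)
  }
  for (i in 1:4) {
    sim <- simulate_locus(2, list(type = "hw", p = 0.5), n = 6, sigma = 0.08,
                          seed = seed + i)
    put(sim, sprintf("oracle_hw_m2_%d.tsv", i), "oracle-size HW diploid")
  }
  for (i in 1:2) {
    sim <- simulate_locus(4, list(type = "f1", p1 = 1, p2 = 0), n = 6,
                          sigma = 0.06, seed = seed + 10 + i)
    put(sim, sprintf("oracle_f1_m4_%d.tsv", i), "oracle-size F1 tetraploid")
  }
  sim <- simulate_locus(4, list(type = "hw", p = 0.5), n = 200, sigma = 0.05,
                        seed = seed + 100)
  put(sim, "recovery_hw_m4.tsv", "HW recovery study, n=200")
  sim <- simulate_locus(6, list(type = "f1", p1 = 2, p2 = 1), n = 200,
                        sigma = 0.05, parent_replicates = 12,
                        seed = seed + 101)
  put(sim, "recovery_f1_m6.tsv", "F1 recovery study, n=200")
  sim <- simulate_locus(10, list(type = "f1", p1 = 3, p2 = 0), n = 180,
                        sigma = 0.16, parent_replicates = 12,
                        seed = seed + 200)
  put(sim, "benchmark_sugarcane_like.tsv",
      "synthetic sugarcane-like locus: 180 progeny, m=10, triplex x nulliplex, 12 parental replicates")
  man <- do.call(rbind, manifest)
  utils::write.table(man, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(man)
}
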