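#' Theoretical genotype frequencies under Hardy-Weinberg equilibrium
#'
#' For a locus of ploidy `m` in a panmictic population with allele-A
#' frequency `p`, the dosage g (number of copies of the allele read on the
#' x channel) is binomial: `F_g = choose(m, g) p^g (1-p)^(m-g)`.
#'
#' @param m Ploidy (positive integer). Odd ploidies are allowed here; the
#'   F1 gamete model is the one that requires even `m`.
#' @param p Allele-A frequency in `[0, 1]`.
#' @return Numeric vector of length `m + 1`, indexed by dosage `0:m`,
#'   summing to 1.
#' @examples
#' hw_frequencies(4, 0.5)
#' @export
hw_frequencies <- function(m, p) {
  stopifnot(length(m) == 1L, m >= 1, m == as.integer(m))
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("allele frequency `p` must be a single value in [0, 1]")
  stats::dbinom(0:m, size = m, prob = p)
}

#' Hypergeometric gamete dosage distribution
#'
#' A parent of even ploidy `m` carrying dosage `d` of allele A transmits
#' gametes of `m/2` chromosomes drawn without replacement, so the gamete
#' dosage j follows `P(j) = choose(d, j) choose(m-d, m/2-j) / choose(m, m/2)`.
#' This is the polysomic (random bivalent) meiotic model; preferential
#' pairing and double reduction are not modelled.
#'
#' @param m Even ploidy.
#' @param d Parental dosage in `0:m`.
#' @return Numeric vector over gamete dosage `0:(m/2)`, summing to 1.
#' @examples
#' gamete_pmf(4, 2)
#' @export
gamete_pmf <- function(m, d) {
  stopifnot(length(m) == 1L, length(d) == 1L)
  if (m %% 2 != 0)
    stop("gamete model undefined for odd ploidy m = ", m)
  if (d < 0 || d > m || d != as.integer(d))
    stop("parental dosage must be an integer in 0..m")
  k <- m %/% 2
  stats::dhyper(0:k, m = d, n = m - d, k = k)
}

#' F1 offspring genotype frequencies
#'
#' Offspring dosage is the sum of two independent gamete dosages, so the
#' frequency vector is the discrete convolution of the two parental gamete
#' distributions.
#'
#' @param m Even ploidy.
#' @param p1,p2 Parental dosages in `0:m`.
#' @return Numeric vector over offspring dosage `0:m`, summing to 1.
#' @examples
#' f1_frequencies(4, 1, 0)  # simplex x nulliplex segregates 1:1
#' @export
f1_frequencies <- function(m, p1, p2) {
  g1 <- gamete_pmf(m, p1)
  g2 <- gamete_pmf(m, p2)
  # direct convolution: keeps structural zeros exact (FFT would smear them)
  prod <- outer(g1, g2)
  tot <- outer(seq_along(g1) - 1L, seq_along(g2) - 1L, "+")
  as.numeric(tapply(prod, tot, sum))
}

#' Enumerate candidate F1 parent dosage pairs
#'
#' @param m Even ploidy.
#' @param ordered If `TRUE`, all `(m+1)^2` ordered pairs (used when parental
#'   intensity data makes the two parents distinguishable); otherwise
#'   unordered pairs with `p1 <= p2`.
#' @param distinct_only Exclude pairs with equal parental dosages.
#' @return Integer matrix with columns `p1`, `p2`, one row per pair.
#' @export
enumerate_parent_pairs <- function(m, ordered = FALSE, distinct_only = FALSE) {
  if (m %% 2 != 0) stop("F1 parent pairs require even ploidy")
  d <- 0:m
  if (ordered) {
    pairs <- expand.grid(p1 = d, p2 = d, KEEP.OUT.ATTRS = FALSE)
  } else {
    pairs <- expand.grid(p1 = d, p2 = d, KEEP.OUT.ATTRS = FALSE)
    pairs <- pairs[pairs$p1 <= pairs$p2, , drop = FALSE]
  }
  if (distinct_only) pairs <- pairs[pairs$p1 != pairs$p2, , drop = FALSE]
  out <- as.matrix(pairs)
  rownames(out) <- NULL
  storage.mode(out) <- "integer"
  out
}

#' Uniform prior on an F1 parent pair
#'
#' Without parental data the parents are exchangeable, so the prior is
#' uniform over the `(m+1)(m+2)/2` unordered dosage pairs (repeats
#' included). With parental data the parents are distinguishable and the
#' prior is uniform over the `(m+1)^2` ordered pairs.
#'
#' @param m Even ploidy.
#' @param has_parent_data Logical.
#' @return A single prior probability (the same for every pair).
#' @export
parent_pair_prior <- function(m, has_parent_data = FALSE) {
  if (m %% 2 != 0) stop("F1 parent prior requires even ploidy")
  if (has_parent_data) 1 / (m + 1)^2 else 2 / ((m + 1) * (m + 2))
}

#' Log-likelihood of parental replicate intensities given a dosage
#'
#' Parental replicates are conditionally independent given the parent's
#' genotype, so the log-likelihood is the sum over replicates of the
#' Gaussian log-density of the normalized coordinate at the expected angle
#' `dosage / m`.
#'
#' @param parent_points Data frame with columns `x` and `y` (one replicate
#'   per row), or `NULL` / zero rows for no data.
#' @param dosage Candidate parental dosage in `0:m`.
#' @param m Ploidy.
#' @param sigma Cluster standard deviation (> 0).
#' @return Log-likelihood; 0 when there are no replicates (no evidence).
#' @export
parent_data_loglik <- function(parent_points, dosage, m, sigma) {
  if (is.null(parent_points) || nrow(parent_points) == 0L) return(0)
  stopifnot(dosage >= 0, dosage <= m)
  r <- normalize_point(parent_points$x, parent_points$y)
  sum(genotype_loglik(r, dosage, m, sigma))
}

#' Read a user-supplied genotype frequency model
#'
#' Accepts a delimited table with columns `param_id`, `dosage`, `frequency`
#' describing one frequency vector per parameter index, for use as the
#' "custom" population model.
#'
#' @param path File path.
#' @param sep Field delimiter (default tab).
#' @return Named list of frequency vectors, one per `param_id`; each is
#'   indexed by dosage `0:m` where `m` is the largest dosage listed for
#'   that parameter.
#' @export
read_custom_model <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("param_id", "dosage", "frequency")
  if (!all(need %in% names(tab)))
    stop("custom model file must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(tab, tab$param_id), function(blk) {
    m <- max(blk$dosage)
    f <- numeric(m + 1)
    f[blk$dosage + 1] <- blk$frequency
    if (abs(sum(f) - 1) > 1e-6)
      stop("frequencies for param_id ", blk$param_id[1], " do not sum to 1")
    f / sum(f)
  })
  out
}
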