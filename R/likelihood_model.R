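#' L1-normalize a two-channel intensity pair
#'
#' Projects an observation (x, y) onto the line x + y = 1; the resulting
#' coordinate r = `x/(x + y)` is the allele-A intensity fraction, with
#' expected value `g / m` for dosage g at ploidy m. Scale-invariant:
#' `normalize_point(l * x, l * y) == normalize_point(x, y)` for l > 0.
#'
#' @param x,y Non-negative intensities (vectorized); `x + y` must be > 0.
#' @return `x / (x + y)` in `[0, 1]`.
#' @export
normalize_point <- function(x, y) {
  if (any(x < 0 | y < 0)) stop("intensities must be non-negative")
  tot <- x + y
  if (any(tot <= 0)) stop("cannot normalize a point with x + y = 0")
  x / tot
}

#' Gaussian log-likelihood of a normalized coordinate given a dosage
#'
#' The likelihood places dosage g of ploidy m at the expected angle
#' `g / m` on the normalized line and penalizes deviation with a normal
#' density of unknown standard deviation `sigma` (searched on a grid
#' elsewhere).
#'
#' @param r Normalized coordinate(s) in `[0, 1]`.
#' @param g Dosage in `0:m`.
#' @param m Ploidy.
#' @param sigma Standard deviation, > 0.
#' @return Log-density, vectorized over `r`.
#' @export
genotype_loglik <- function(r, g, m, sigma) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (any(g < 0 | g > m)) stop("dosage out of 0..m")
  stats::dnorm(r, mean = g / m, sd = sigma, log = TRUE)
}

# Parameter-free per-locus geometry: replicate coordinates grouped by
# individual and the sort order along the normalized line. Computed once
# per dataset and reused for every (m, sigma) in the grid search.
locus_coordinates <- function(dataset) {
  df <- dataset$data
  r <- normalize_point(df$x, df$y)
  ids <- unique(df$individual_id)
  groups <- split(r, factor(df$individual_id, levels = ids))
  rbar <- vapply(groups, mean, numeric(1))
  # ties on the mean coordinate broken by individual id, stable
  ord <- order(rbar, ids, method = "radix")
  list(ids = ids[ord], groups = groups[ord], rbar = unname(rbar[ord]),
       order = ord, n_reps = lengths(groups)[ord])
}

#' Per-individual genotype log-likelihood table
#'
#' Aggregates each individual's replicate log-densities (replicates are
#' conditionally independent given the genotype) into an n x (m+1) matrix,
#' with rows ordered by the individual's mean normalized coordinate — the
#' ordering along the line x + y = 1 that the geometric search exploits.
#' The sort is parameter-free, so callers fitting a grid of (m, sigma)
#' values reuse it.
#'
#' @param dataset A [locus_dataset()].
#' @param m Ploidy.
#' @param sigma Cluster standard deviation.
#' @param coords Optional precomputed result of the internal coordinate
#'   grouping (for grid-search callers); computed from `dataset` if `NULL`.
#' @return An object of class `likelihood_table`: list with `m`, `sigma`,
#'   `logL` (rows follow `ids`), `ids` (sorted individual ids), `rbar`
#'   (sorted mean coordinates), `n_reps`.
#' @export
build_table <- function(dataset, m, sigma, coords = NULL) {
  if (is.null(coords)) coords <- locus_coordinates(dataset)
  n <- length(coords$ids)
  if (n == 0L) stop("dataset has no individuals")
  if (length(unique(coords$n_reps)) > 1L)
    warning("unequal replicate counts across individuals; ",
            "the exact-MAP guarantee is proven for equal counts")
  angles <- (0:m) / m
  logL <- matrix(0, nrow = n, ncol = m + 1L,
                 dimnames = list(coords$ids, as.character(0:m)))
  for (g in 0:m) {
    dens <- lapply(coords$groups, function(rr)
      sum(stats::dnorm(rr, angles[g + 1L], sigma, log = TRUE)))
    logL[, g + 1L] <- unlist(dens, use.names = FALSE)
  }
  structure(list(m = m, sigma = sigma, logL = logL, ids = coords$ids,
                 rbar = coords$rbar, n_reps = coords$n_reps),
            class = "likelihood_table")
}

#' Per-individual genotype posteriors by relative likelihood
#'
#' Normalizes each individual's likelihood row: the posterior that
#' individual i carries dosage g is `exp(logL[i,g])` over the sum across
#' dosages. This is the relative-likelihood approximation used for
#' reporting and filtering; theoretical genotype frequencies do not enter.
#'
#' @param table A [build_table()] result at the MAP (m, sigma).
#' @return Matrix (individuals x dosages) of posteriors, rows summing to 1,
#'   rownames the individual ids in sorted-coordinate order.
#' @export
individual_posteriors <- function(table) {
  L <- table$logL
  mx <- apply(L, 1L, max)
  w <- exp(L - mx)
  w / rowSums(w)
}
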