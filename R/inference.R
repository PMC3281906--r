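#' @useDynLib polydose, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

log_sum_exp <- function(x) {
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(x - m)))
}

# log multinomial pmf of count vector `counts` under class probabilities F,
# with explicit -Inf for counts in zero-frequency classes (dmultinom would
# reject a zero prob vectorized this way; the semantics matter for model
# exclusion, so it is written out)
log_multinomial <- function(counts, F) {
  n <- sum(counts)
  lp <- ifelse(counts > 0, counts * log(F), 0)
  if (any(counts > 0 & F == 0)) return(-Inf)
  lgamma(n + 1) - sum(lgamma(counts + 1)) + sum(lp)
}

#' Joint log-score of a genotype distribution and configuration
#'
#' The model couples every individual through the genotype count
#' distribution: the joint is the multinomial probability of the counts
#' under the theoretical frequencies, times the configuration likelihood,
#' times any prior terms — all in log space.
#'
#' @param counts Integer vector of individuals per dosage class (length
#'   m + 1, summing to n).
#' @param config_loglik Log-likelihood of the genotype configuration that
#'   produced `counts`.
#' @param F Theoretical genotype frequency vector.
#' @param prior_terms Additive log-prior terms (default 0).
#' @return The joint log-score; `-Inf` when a zero-frequency class has a
#'   positive count (a validly excluded configuration).
#' @export
log_joint <- function(counts, config_loglik, F, prior_terms = 0) {
  stopifnot(length(counts) == length(F), all(counts >= 0))
  log_multinomial(counts, F) + config_loglik + prior_terms
}

#' Greedy maximum-likelihood genotype configuration
#'
#' Assigns every individual its individually most likely dosage (ties
#' broken toward the lower dosage), ignoring the multinomial coupling; the
#' induced count distribution is then scored by [log_joint()]. Used as the
#' branch-and-bound incumbent and as a fast baseline.
#'
#' @param table A [build_table()] result.
#' @param F Theoretical frequency vector of length `table$m + 1`.
#' @param prior_terms Additive log-prior terms.
#' @return List with `assignment` (named dosage vector, sorted-coordinate
#'   order), `counts`, `config_loglik`, `log_joint`.
#' @export
greedy_fit <- function(table, F, prior_terms = 0) {
  L <- table$logL
  g <- max.col(L, ties.method = "first") # first = lowest dosage on ties
  counts <- tabulate(g, nbins = ncol(L))
  ll <- sum(L[cbind(seq_len(nrow(L)), g)])
  assignment <- stats::setNames(g - 1L, table$ids)
  list(assignment = assignment, counts = counts, config_loglik = ll,
       log_joint = log_joint(counts, ll, F, prior_terms))
}

#' Exhaustive MAP genotype configuration (test oracle)
#'
#' Enumerates all `(m+1)^n` genotype configurations and maximizes
#' [log_joint()]. Exponential: refuses instances beyond `guard`
#' configurations. Ties broken toward the lexicographically smallest
#' assignment along the sorted order.
#'
#' @inheritParams greedy_fit
#' @param guard Maximum number of configurations to enumerate.
#' @return As [greedy_fit()].
#' @export
naive_map <- function(table, F, prior_terms = 0, guard = 1e6) {
  L <- table$logL
  n <- nrow(L)
  M <- ncol(L)
  if (M^n > guard) {
    stop(structure(class = c("polydose_guard", "error", "condition"),
                   list(message = sprintf(
                          "naive enumeration of %d^%d configurations exceeds the guard (%g)",
                          M, n, guard),
                        call = sys.call(-1))))
  }
  # rows in lexicographic order of (g_1, ..., g_n): first individual varies
  # slowest, so which.max's first-hit tie-break is the lexicographic one
  cfg <- as.matrix(expand.grid(rev(replicate(n, 0:(M - 1), simplify = FALSE)),
                               KEEP.OUT.ATTRS = FALSE))[, n:1, drop = FALSE]
  ll <- numeric(nrow(cfg))
  for (i in seq_len(n)) ll <- ll + unname(L[i, cfg[, i] + 1L])
  counts <- sapply(0:(M - 1), function(g) rowSums(cfg == g))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  logFmat <- matrix(rep(log(F), each = nrow(cfg)), nrow = nrow(cfg))
  term <- counts * logFmat
  term[counts == 0] <- 0
  term[counts > 0 & !is.finite(logFmat)] <- -Inf
  mult <- lgamma(n + 1) - rowSums(lgamma(counts + 1)) + rowSums(term)
  tot <- ll + mult
  best <- which.max(tot)
  assignment <- stats::setNames(as.integer(cfg[best, ]), table$ids)
  list(assignment = assignment, counts = as.integer(counts[best, ]),
       config_loglik = unname(ll[best]),
       log_joint = unname(tot[best]) + prior_terms)
}

#' Likelihood-optimal configuration for a fixed genotype distribution
#'
#' With individuals sorted along the normalized line, the best
#' configuration with count image `counts` assigns contiguous blocks:
#' the first `counts[1]` individuals dosage 0, the next `counts[2]`
#' dosage 1, and so on (any crossing pair of assignments could be swapped
#' to shrink total distance without changing the counts).
#'
#' @param table A [build_table()] result.
#' @param counts Integer counts per dosage, summing to the number of
#'   individuals.
#' @return List with `assignment` (named, sorted order) and
#'   `config_loglik`.
#' @export
best_config_for_distribution <- function(table, counts) {
  L <- table$logL
  stopifnot(length(counts) == ncol(L), sum(counts) == nrow(L))
  g <- rep.int(0:(ncol(L) - 1L), counts)
  ll <- sum(L[cbind(seq_len(nrow(L)), g + 1L)])
  list(assignment = stats::setNames(as.integer(g), table$ids),
       config_loglik = ll)
}

#' Exact MAP genotype configuration by geometric branch-and-bound
#'
#' Searches prefixes of the genotype count distribution `(c_0, ..., c_m)`
#' depth-first (tree depth m + 1, not n), using the contiguity property to
#' fix the likelihood-optimal configuration of each prefix and an
#' admissible upper bound (multinomial bound x prefix likelihood x best
#' remaining suffix likelihood) to prune. Returns the exact MAP for the
#' given frequency vector — identical to [naive_map()] wherever the latter
#' is feasible — regardless of the starting incumbent, which affects only
#' the amount of pruning.
#'
#' @inheritParams greedy_fit
#' @param incumbent Starting lower bound on the joint (log scale,
#'   excluding `prior_terms`). Default `NULL` seeds with [greedy_fit()];
#'   `-Inf` starts cold.
#' @param prune_below Prune any subtree whose bound falls below this value
#'   even if above the incumbent (used for posterior-approximation slack;
#'   default `-Inf` = fully exact). If the returned `log_joint` is at or
#'   below this threshold the result is flagged `pruned` and is only a
#'   lower bound.
#' @return List with `assignment`, `counts`, `config_loglik`, `log_joint`
#'   (includes `prior_terms`), `visited_nodes` (leaf distributions
#'   evaluated), `pruned`.
#' @export
geometric_map <- function(table, F, prior_terms = 0, incumbent = NULL,
                          prune_below = -Inf) {
  logF <- log(F)
  if (is.null(incumbent)) {
    g0 <- greedy_fit(table, F)
    init_counts <- as.integer(g0$counts)
    init_val <- g0$log_joint
  } else {
    init_counts <- integer(0)
    init_val <- incumbent
  }
  res <- .geometric_bnb(table$logL, logF, init_counts, init_val,
                        prune_below - prior_terms)
  counts <- as.integer(res$counts)
  if (length(counts) == 0L || !is.finite(res$log_joint)) {
    return(list(assignment = NULL, counts = NULL, config_loglik = -Inf,
                log_joint = -Inf, visited_nodes = res$leaves, pruned = TRUE))
  }
  cfg <- best_config_for_distribution(table, counts)
  list(assignment = cfg$assignment, counts = counts,
       config_loglik = cfg$config_loglik,
       log_joint = res$log_joint + prior_terms,
       visited_nodes = res$leaves, pruned = isTRUE(res$pruned))
}

#' Exact MAP by layered dynamic programming over count prefixes
#'
#' Assigns individuals one at a time; prefixes reaching the same partial
#' count vector are merged, keeping the best prefix likelihood (the
#' suffix problem depends on the prefix only through its counts). Each
#' layer is pruned with the conservative bound: prefix likelihood + best
#' possible suffix likelihood + 0 (the multinomial factor is at most 1)
#' against the greedy incumbent. Exact, but the layer width can grow
#' combinatorially; a state guard aborts with a diagnostic when it does.
#'
#' @inheritParams greedy_fit
#' @param max_states Abort when a layer exceeds this many merged states.
#' @return As [geometric_map()], plus `peak_layer_size`.
#' @export
dp_map <- function(table, F, prior_terms = 0, max_states = 2e5) {
  L <- table$logL
  n <- nrow(L)
  M <- ncol(L)
  logF <- log(F)
  live <- which(F > 0) # zero-frequency classes cannot hold any individual
  if (length(live) == 0L) stop("frequency vector is all zero")
  incumbent <- greedy_fit(table, F)$log_joint
  smax <- apply(L, 1L, max)
  SS <- rev(cumsum(rev(c(smax, 0)))) # SS[i] = sum_{i' >= i} max_g logL
  states <- matrix(0L, nrow = 1, ncol = M)
  vals <- 0
  layers <- vector("list", n)
  visited <- 0
  peak <- 0
  for (i in seq_len(n)) {
    s <- nrow(states)
    k <- length(live)
    new_states <- states[rep(seq_len(s), times = k), , drop = FALSE]
    gs <- rep(live, each = s)
    new_states[cbind(seq_len(s * k), gs)] <-
      new_states[cbind(seq_len(s * k), gs)] + 1L
    new_vals <- rep(vals, times = k) + unname(L[i, gs])
    parent <- rep(seq_len(s), times = k)
    # Eq.-style bound: multinomial <= 1, suffix likelihood at its maximum
    keep <- new_vals + SS[i + 1] >= incumbent
    if (!any(keep)) keep[which.max(new_vals)] <- TRUE
    new_states <- new_states[keep, , drop = FALSE]
    new_vals <- new_vals[keep]
    parent <- parent[keep]
    gs <- gs[keep]
    key <- do.call(paste, c(as.data.frame(new_states), sep = ","))
    ord <- order(new_vals, decreasing = TRUE)
    first <- ord[!duplicated(key[ord])]
    first <- sort(first) # deterministic layout
    states <- new_states[first, , drop = FALSE]
    vals <- new_vals[first]
    layers[[i]] <- list(parent = parent[first], dosage = gs[first] - 1L)
    visited <- visited + nrow(states)
    peak <- max(peak, nrow(states))
    if (nrow(states) > max_states) {
      stop(structure(class = c("polydose_dp_guard", "polydose_guard",
                               "error", "condition"),
                     list(message = sprintf(
                            "dynamic-programming layer at depth %d holds %d states (guard %g); the geometric engine handles this instance",
                            i, nrow(states), max_states),
                          call = sys.call(-1))))
    }
  }
  mult <- apply(states, 1L, function(cs) log_multinomial(cs, F))
  tot <- vals + mult
  best <- which.max(tot)
  # backtrack through the layers
  assignment <- integer(n)
  idx <- best
  for (i in rev(seq_len(n))) {
    assignment[i] <- layers[[i]]$dosage[idx]
    idx <- layers[[i]]$parent[idx]
  }
  list(assignment = stats::setNames(assignment, table$ids),
       counts = as.integer(states[best, ]),
       config_loglik = unname(vals[best]),
       log_joint = unname(tot[best]) + prior_terms,
       visited_nodes = visited, peak_layer_size = peak, pruned = FALSE)
}

#' Slack level for posterior-preserving pruning
#'
#' During marginalization over parameter settings, a setting may be pruned
#' once its upper bound falls below `tau` times the current best joint;
#' each pruned setting then perturbs the approximate posterior by at most
#' `tau`, so choosing `tau = epsilon / (n_settings - 1)` caps the absolute
#' posterior error at `epsilon`.
#'
#' @param epsilon_max Target absolute posterior error, in (0, 1).
#' @param n_settings Number of parameter settings searched.
#' @return The pruning ratio `tau`.
#' @export
tau_from_epsilon <- function(epsilon_max, n_settings) {
  stopifnot(epsilon_max > 0, epsilon_max < 1, n_settings >= 1)
  epsilon_max / max(1, n_settings - 1)
}

#' Approximate posterior of the MAP parameter setting
#'
#' Approximates the configuration posterior by normalizing the per-setting
#' MAP joints over every setting searched (settings pruned during the
#' search contribute `-Inf`): the mass near each setting's MAP is assumed
#' to scale comparably across settings.
#'
#' @param log_joints Numeric vector: each searched setting's MAP joint
#'   log-score (including priors).
#' @param map_index Index of the MAP setting within `log_joints`.
#' @return Approximate posterior in `[0, 1]`.
#' @export
approximate_posterior <- function(log_joints, map_index = which.max(log_joints)) {
  stopifnot(length(log_joints) >= 1, map_index >= 1,
            map_index <= length(log_joints))
  exp(log_joints[map_index] - log_sum_exp(log_joints))
}
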