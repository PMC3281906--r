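#' Search settings for a locus fit
#'
#' Bundles the grids and knobs of the joint search over ploidy, cluster
#' standard deviation and population-model parameters.
#'
#' @param ploidy_range Integer vector of ploidies to search. Default the
#'   even ploidies 2..16 (sugarcane-scale range; the gamete model needs
#'   even m). Odd ploidies are accepted for the Hardy-Weinberg model only.
#' @param sigma_grid Geometric grid of cluster standard deviations.
#'   Default `0.01 * 2^(0:5)` plus 0.16.
#' @param p_resolution Allele-frequency grid step for the Hardy-Weinberg
#'   model (default 0.01 over `[0, 1]`).
#' @param epsilon Maximum absolute error tolerated in the approximate
#'   configuration posterior, in (0, 1).
#' @param posterior_threshold Default per-individual reporting threshold.
#' @param engine MAP engine: `"geometric"` (exact, recommended), `"dp"`
#'   (exact, memory-bound), `"naive"` (exact, tiny instances only),
#'   `"greedy"` (approximate).
#' @param ploidy_tiebreak `"lowest"` resolves exact score ties toward the
#'   smallest ploidy (single-cluster data cannot identify m; prefer the
#'   parsimonious answer), `"none"` keeps the first encountered.
#' @param naive_guard,dp_max_states Guards for the exponential engines.
#' @return An object of class `search_settings`.
#' @export
search_settings <- function(ploidy_range = seq(2L, 16L, by = 2L),
                            sigma_grid = c(0.01 * 2^(0:5), 0.16),
                            p_resolution = 0.01,
                            epsilon = 0.01,
                            posterior_threshold = 0.8,
                            engine = c("geometric", "dp", "naive", "greedy"),
                            ploidy_tiebreak = c("lowest", "none"),
                            naive_guard = 1e6,
                            dp_max_states = 1e5) {
  engine <- match.arg(engine)
  ploidy_tiebreak <- match.arg(ploidy_tiebreak)
  stopifnot(length(ploidy_range) >= 1, all(ploidy_range >= 1),
            length(sigma_grid) >= 1, all(sigma_grid > 0),
            p_resolution > 0, p_resolution <= 1,
            epsilon > 0, epsilon < 1)
  structure(list(ploidy_range = sort(unique(as.integer(ploidy_range))),
                 sigma_grid = sort(unique(sigma_grid)),
                 p_resolution = p_resolution,
                 epsilon = epsilon,
                 posterior_threshold = posterior_threshold,
                 engine = engine,
                 ploidy_tiebreak = ploidy_tiebreak,
                 naive_guard = naive_guard,
                 dp_max_states = dp_max_states),
            class = "search_settings")
}

# enumerate the model's parameter set for one ploidy
theta_set <- function(model, m, settings, has_parents, custom_model) {
  switch(model,
    hw = {
      grid <- seq(0, 1, by = settings$p_resolution)
      list(F = lapply(grid, function(p) hw_frequencies(m, p)),
           label = sprintf("p=%g", grid),
           theta = lapply(grid, function(p) list(p = p)),
           log_prior = rep(-log(length(grid)), length(grid)))
    },
    f1 = {
      pairs <- enumerate_parent_pairs(m, ordered = has_parents)
      list(F = lapply(seq_len(nrow(pairs)), function(i)
             f1_frequencies(m, pairs[i, 1], pairs[i, 2])),
           label = sprintf("p1=%d,p2=%d", pairs[, 1], pairs[, 2]),
           theta = lapply(seq_len(nrow(pairs)), function(i)
             list(p1 = unname(pairs[i, 1]), p2 = unname(pairs[i, 2]))),
           log_prior = rep(log(parent_pair_prior(m, has_parents)),
                           nrow(pairs)))
    },
    custom = {
      keep <- vapply(custom_model, function(f) length(f) == m + 1, logical(1))
      Fs <- custom_model[keep]
      if (length(Fs) == 0L) return(NULL)
      list(F = Fs, label = sprintf("custom:%s", names(Fs)),
           theta = lapply(names(Fs), function(nm) list(param_id = nm)),
           log_prior = rep(-log(length(Fs)), length(Fs)))
    })
}

#' Fit the dosage-calling model to one locus
#'
#' Runs the full grid search over ploidy, sigma and model parameters,
#' computing for each setting the MAP genotype configuration with the
#' selected engine, and returns the joint MAP together with the
#' approximate configuration posterior (normalized over every setting
#' searched, with pruning slack chosen so the approximation error is at
#' most `settings$epsilon`) and per-individual genotype posteriors.
#'
#' For the F1 model with parental replicate blocks present, the flat
#' parent-pair prior is replaced by the ordered-pair prior times the
#' parental data likelihood at each candidate pair of dosages.
#'
#' @param dataset A [locus_dataset()] (or the result of [read_locus()]).
#' @param model `"hw"`, `"f1"`, or `"custom"`.
#' @param settings A [search_settings()] object.
#' @param custom_model For `model = "custom"`: a named list of frequency
#'   vectors as returned by [read_custom_model()].
#' @return An object of class `polydose_fit`.
#' @export
fit_locus <- function(dataset, model = c("hw", "f1", "custom"),
                      settings = search_settings(), custom_model = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(dataset, "locus_dataset"))
  coords <- locus_coordinates(dataset)
  if (length(coords$ids) == 0L) stop("empty dataset")
  has_parents <- !is.null(dataset$parent1)
  ploidies <- settings$ploidy_range
  if (model == "f1" && any(ploidies %% 2 != 0))
    stop("the F1 gamete model requires even ploidies; got ",
         paste(ploidies[ploidies %% 2 != 0], collapse = ", "))
  if (model == "custom" && is.null(custom_model))
    stop("model = \"custom\" needs `custom_model`")

  # pre-enumerate so tau (the posterior slack per setting) is known up front
  grids <- list()
  for (m in ploidies) {
    ts <- theta_set(model, m, settings, has_parents, custom_model)
    if (!is.null(ts)) grids[[as.character(m)]] <- ts
  }
  if (length(grids) == 0L) stop("no parameter settings to search")
  n_settings <- length(settings$sigma_grid) *
    sum(vapply(grids, function(g) length(g$F), integer(1)))
  tau <- tau_from_epsilon(settings$epsilon, n_settings)
  log_tau <- log(tau)
  log_m_prior <- -log(length(grids))
  log_s_prior <- -log(length(settings$sigma_grid))

  rows <- vector("list", n_settings)
  ri <- 0L
  best <- list(total = -Inf)
  total_leaves <- 0
  for (mc in names(grids)) {
    m <- as.integer(mc)
    ts <- grids[[mc]]
    for (sigma in settings$sigma_grid) {
      table <- build_table(dataset, m, sigma, coords)
      if (model == "f1" && has_parents) {
        p1l <- vapply(0:m, function(d)
          parent_data_loglik(dataset$parent1, d, m, sigma), numeric(1))
        p2l <- vapply(0:m, function(d)
          parent_data_loglik(dataset$parent2, d, m, sigma), numeric(1))
      }
      for (k in seq_along(ts$F)) {
        F <- ts$F[[k]]
        prior_terms <- log_m_prior + log_s_prior + ts$log_prior[k]
        if (model == "f1" && has_parents) {
          th <- ts$theta[[k]]
          prior_terms <- prior_terms + p1l[th$p1 + 1L] + p2l[th$p2 + 1L]
        }
        res <- switch(settings$engine,
          greedy = greedy_fit(table, F, prior_terms),
          naive = naive_map(table, F, prior_terms,
                            guard = settings$naive_guard),
          dp = dp_map(table, F, prior_terms,
                      max_states = settings$dp_max_states),
          geometric = geometric_map(table, F, prior_terms,
                                    prune_below = best$total + log_tau))
        total <- res$log_joint
        total_leaves <- total_leaves + (res$visited_nodes %||% 0)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(m = m, sigma = sigma, theta = ts$label[k],
                                 log_joint = total,
                                 pruned = isTRUE(res$pruned))
        if (total > best$total) {
          best <- list(total = total, m = m, sigma = sigma,
                       theta = ts$theta[[k]], theta_label = ts$label[k],
                       F = F, res = res)
        }
      }
    }
  }
  tab <- do.call(rbind, rows[seq_len(ri)])
  config_posterior <- approximate_posterior(tab$log_joint,
                                            which.max(tab$log_joint))
  map_table <- build_table(dataset, best$m, best$sigma, coords)
  post <- individual_posteriors(map_table)
  structure(list(m = best$m, sigma = best$sigma, theta = best$theta,
                 theta_label = best$theta_label, model = model,
                 F = best$F,
                 assignment = best$res$assignment,
                 counts = best$res$counts,
                 log_joint = best$total,
                 config_posterior = config_posterior,
                 individual_posteriors = post,
                 settings = settings,
                 settings_table = tab,
                 n_settings = n_settings,
                 visited_nodes = total_leaves,
                 engine = settings$engine),
            class = "polydose_fit")
}

#' @export
print.polydose_fit <- function(x, ...) {
  cat(sprintf("<polydose_fit> model=%s engine=%s\n", x$model, x$engine))
  cat(sprintf("  MAP ploidy m = %d, sigma = %g, %s\n",
              x$m, x$sigma, x$theta_label))
  cat(sprintf("  joint log-score = %.4f, configuration posterior ~ %.4f\n",
              x$log_joint, x$config_posterior))
  cat(sprintf("  genotype counts: %s\n",
              paste(x$counts, collapse = " ")))
  cat(sprintf("  settings searched: %d\n", x$n_settings))
  invisible(x)
}
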