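---
title: "Joint Bayesian dosage calling in polyploids: model, inference and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint Bayesian dosage calling in polyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polydose)
```

## The problem

Two-channel SNP assays (Illumina GoldenGate fluorescence, Sequenom
MassARRAY mass-spectrometry peaks) report a pair of signal intensities
(x, y), one per allele, for every sample at a locus. In a polyploid of
ploidy m, the dosage g of the x-channel allele runs from 0 to m, and the
expected intensity fraction x/(x + y) is g/m. Dosage calling means turning
the cloud of intensity pairs into integer dosages — and, for crops such as
sugarcane where the ploidy itself is unknown and varies across the genome,
estimating m at the same time.

The usual mixture-model approach classifies each individual independently.
That discards a strong piece of information: in a real population the
*numbers* of individuals per dosage class follow a known law (Hardy-Weinberg
proportions in a panel, hypergeometric-gamete segregation in an F1 cross).
`polydose` models that coupling explicitly and computes the exact joint
maximum a posteriori assignment.

## The model

For each individual i with replicate observations d_i, the likelihood of
dosage g is a Gaussian on the L1-normalized coordinate r = x/(x + y):

    L(d_i | g) = N(r_i ; g/m, sigma^2),

with sigma unknown and searched on a grid. Replicates multiply (sum in log
space). We collapse the normalized pair (r, 1 − r) to the scalar r; the
two conventions differ only by a constant factor, and the scalar form makes
the "expected angle" g/m explicit.

A genotype configuration G assigns a dosage to every individual; its count
image c = (c_0, ..., c_m) is scored against the model's theoretical
frequency vector F by a multinomial:

    P(c | F) = n! / (prod_g c_g!) * prod_g F_g^{c_g}.

The joint score of a configuration is the product of the multinomial, the
per-individual likelihoods, and the priors. The multinomial term is what
couples all individuals: a configuration that dumps everyone into the
single most probable class is combinatorially penalized, because only one
assignment realizes those counts.

Population models supply F:

* **Hardy-Weinberg**: F_g = C(m, g) p^g (1 − p)^{m − g}, with the allele
  frequency p on a uniform grid (step 0.01 by default).
* **F1 cross**: each parent of dosage d transmits hypergeometric gametes
  P(j) = C(d, j) C(m − d, m/2 − j) / C(m, m/2); offspring frequencies are
  the convolution of the two gamete distributions. Parent dosage pairs get
  a uniform prior over the (m+1)(m+2)/2 unordered pairs, or over the
  (m+1)^2 ordered pairs when parental replicate intensities are supplied —
  in that case the parental data likelihood multiplies the prior of each
  candidate pair. Equal-dosage pairs are kept in the default prior
  (simplex x simplex crosses are real).
* **Custom**: any table of frequency vectors; the inference is agnostic to
  where F comes from.

Ploidy and sigma carry uniform priors over their grids. Exact score ties
across ploidies are resolved toward the smallest m (`ploidy_tiebreak =
"lowest"`): a locus whose individuals all sit on one angle is consistent
with every multiple of a ploidy, and only parsimony can choose.

## Exact inference

Enumerating all (m+1)^n configurations is hopeless, and the count node c
makes the graphical model's treewidth scale with n, so generic junction-tree
methods are hopeless too. The package implements three exact engines plus a
greedy baseline:

* `greedy_fit()` assigns each individual its individually most likely
  dosage — fast, ignores the coupling, used as the branch-and-bound
  incumbent.
* `naive_map()` enumerates everything (a test oracle, guarded).
* `dp_map()` assigns individuals one at a time and merges search prefixes
  that induce the same partial counts, keeping the best prefix likelihood
  per merged node, with a conservative bound (multinomial factor bounded by
  1, suffix likelihood bounded by its per-individual maximum). Exact, but
  the layer width grows like C(n + m, m) when the noise is large, so a
  state guard aborts with a diagnostic rather than exhausting memory.
* `geometric_map()` — the workhorse. Sorting individuals by r once per
  locus (the sort is parameter-free and cached across the whole grid
  search), the likelihood-optimal configuration for any fixed c assigns
  *contiguous blocks* along the sorted order: two crossed assignments can
  always be swapped to shrink both distances without changing c. The
  search therefore runs over count-vector prefixes (c_0, ..., c_g) — a
  tree of depth m + 1 rather than n — and each node is bounded above by

      log n! − Σ_{j ≤ g} log c_j! + Σ_{j ≤ g} c_j log F_j   (prefix multinomial)
    + prefix block log-likelihood
    + Σ_{unassigned i} max_{j > g} (log L_i(j) + log F_j)    (suffix)
    − min over suffix counts of Σ_{j > g} log c_j!,

  where the last term is the closed-form even-spread floor of the suffix
  factorials. Every term is admissible (never below any completion of the
  prefix), so pruning against the incumbent preserves exactness; the
  incumbent affects speed only. Children are explored best-bound-first.

The bound's composition ("multinomial bound x prefix likelihood x best
remaining suffix likelihood") follows the method's design; the particular
admissible strengthening — taking the per-individual maximum of the
*sum* of likelihood and log-frequency, and flooring the suffix factorials
— was chosen after profiling showed the separated form collapses in the
flat-likelihood regime (large sigma), where the multinomial dominates the
optimum. Correctness never rests on the bound's tightness: the test suite
checks the geometric and dp engines against exhaustive enumeration on
hundreds of randomized instances.

Floating-point note: node bounds are compared against the incumbent with a
slack of 1e-10 so that rounding in the cached prefix sums can never prune
an exact optimum; reported equalities in the oracle tests are at 1e-9.

## Grid search and posteriors

`fit_locus()` scans m × sigma × theta, keeps the per-setting MAP, and
returns the global argmax plus an approximate configuration posterior: the
per-setting MAP joints are normalized by log-sum-exp, under the assumption
that the probability mass in the neighborhood of each setting's MAP scales
comparably across settings. Settings are pruned during the scan only when
their upper bound falls below tau times the current best joint, with
tau = epsilon / (n_settings − 1); each pruned setting then shifts the
approximate posterior by less than tau, so the total absolute error is at
most epsilon (0.01 by default, user-settable). With epsilon small nothing
of consequence is pruned and the posterior equals exact normalization over
per-setting MAPs; the test suite verifies the bound at epsilon = 0.1, 0.01
and 0.001 on fully enumerable grids.

Per-individual posteriors are relative likelihoods across dosages at the
MAP (m, sigma) — theoretical frequencies are deliberately not folded in,
matching the reporting semantics of intensity-based callers: the
`posterior_threshold` (default 0.8) marks which calls are reported, which
formalizes the common practice of discarding low-total-intensity points.

## Defaults and their rationale

| parameter | default | why |
|---|---|---|
| sigma grid | 0.01·2^k, k = 0..5, plus 0.16 | geometric coverage of the plausible range of normalized-coordinate noise; 0.16 is the scale observed on real mass-spectrometry loci |
| p resolution | 0.01 | grid error far below the multinomial's discrimination at n ≈ 200 |
| ploidy range | 2, 4, ..., 16 | spans sugarcane's reported 5–16 with the even-ploidy gamete model |
| epsilon | 0.01 | posterior reported to two digits is stable |
| posterior threshold | 0.8 | reports calls with ≥ 4:1 likelihood ratio over all alternatives combined |
| dp layer guard | 1e5 states | keeps an intentionally memory-hungry baseline from stalling a session; the geometric engine is the supported path |

Odd ploidies are legal for the Hardy-Weinberg model; the F1 model refuses
them (meiosis with half-integer gametes is undefined here).

## The simulator

`simulate_locus()` draws genotype counts from the model's multinomial
(or i.i.d. genotypes on request), replicate coordinates from
N(g/m, sigma^2) truncated to [0, 1], and emits (x, y) = (T·r, T·(1 − r))
with the total signal T drawn around `total_intensity` (default 100,
CV 0.1). The total cancels in normalization, so its scale is a free
cosmetic choice. Truncation rather than rejection at the boundary is
negligible for sigma ≤ 0.16 at interior angles and keeps draws countable.
A `noise_on = "channels"` mode adds Gaussian noise to the raw channels
instead, breaking the model's assumptions on purpose for robustness
studies.

What the simulator does *not* emulate: channel-specific proportionality
constants ("skew", the known failure mode of some fluorescence assays —
the likelihood has no latent skew variable, so skewed loci are out of
scope), aneuploid mixtures of ploidies within a locus, and intensity-
dependent noise. Passing recovery tests on simulated data therefore
demonstrates correctness of the inference under the model's assumptions,
not robustness to assay artifacts.

Test and validation problem sizes are the package's own choices: oracle
equivalence uses n ≤ 8 and m ≤ 4 (where exhaustive enumeration is cheap),
recovery studies use n = 200 individuals at sigma = 0.05 across m ∈ {2, 4, 6},
and the scalability fixture mirrors a real F1 design — 180 progeny at
m = 10 from a triplex × nulliplex cross with 12 replicates per parent.

## Known limitations

* No skew correction; loci with strongly unequal per-allele gains will be
  mis-modelled and typically show as low configuration posteriors.
* The meiotic model is polysomic random segregation: no preferential
  pairing, no double reduction. Violations are informative (they surface
  as poor fits) but not modelled.
* Per-individual posteriors are relative-likelihood approximations, not
  exact marginals; the exact-marginal extension via a second
  branch-and-bound is not implemented.
* The exact-MAP guarantee is proven for equal replicate counts per
  individual; `build_table()` warns when counts differ.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_locus(4, list(type = "f1", p1 = 1, p2 = 0), n = 150,
                      sigma = 0.05, parent_replicates = 12, seed = 77)
fit <- fit_locus(sim$dataset, model = "f1",
                 settings = search_settings(ploidy_range = c(2, 4)))
print(fit)
mean(fit$assignment[names(sim$genotypes)] == sim$genotypes)
```

The fit recovers the tetraploid simplex × nulliplex cross and its 1:1
segregation; the README shows the printed output.
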