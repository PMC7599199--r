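---
title: "Latent-state models for polytomous questionnaire data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-state models for polytomous questionnaire data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polikst)
```

## The model

Knowledge space theory describes a respondent by a *state*: in the
polytomous setting, a function $K$ assigning one of the ordered levels
$L = \{\ell_0, \dots, \ell_n\}$ to every item $q$ in a domain $Q$. A
*structure* $\mathcal{K}$ is a finite nonempty set of admissible states.
`polikst` codes levels as integers $0, \dots, n$ and represents a structure
as an integer matrix with one state per row.

The polytomous local independence model (PoLIM) links latent states to
observed response patterns $R \in L^Q$ through two assumptions:

* **Response rule.** The observed level on item $q$ depends only on the
  latent level for that item: $P(\mathbf{R}_q = j \mid K) =
  \epsilon_q(K(q), j)$, with one row-stochastic $|L| \times |L|$ error
  matrix $E_q$ per item.
* **Local independence.** Given the state, responses are independent
  across items, so $P(R \mid K) = \prod_q \epsilon_q(K(q), R(q))$ and
  $P(R) = \sum_{K \in \mathcal{K}} P(R \mid K)\, \pi_K$ for a state
  distribution $\pi$.

The model has $|Q|\,|L|\,(|L|-1) + |\mathcal{K}| - 1$ free parameters
(`count_free_parameters()`). With two levels it reduces to the classical
dichotomous model with careless-error and lucky-guess rates
$\beta_q = \epsilon_q(1,0)$ and $\eta_q = \epsilon_q(0,1)$; this reduction
is verified against a direct four-factor product in the tests.

## Monotonicity of the error matrices

An unrestricted $E_q$ can assign high probability to responses far from
the latent level. Restrictions of increasing strength are implemented as
row checks (and, through `column_view()`, as column checks):

* **Modality** (`check_modality()`): the true level is the single most
  probable response in its row.
* **$\delta$-monotonicity** (`is_delta_monotone()`): for a level metric
  $\delta$, $\delta(i,j) < \delta(i,k) \iff \epsilon_q(i,j) >
  \epsilon_q(i,k)$ over all level triples — probabilities decay strictly
  with distance from the true level.
* **$\delta$-half-monotonicity** (`is_delta_half_monotone()`): the same
  condition confined to the same-side triples of `restricted_triples()`,
  i.e. $i \preceq \min\{j,k\}$ or $\max\{j,k\} \prec i$. With this
  one-bound-strict rule a 4-level chain yields 44 restricted triples out of
  the $4^3 = 64$; this is the variant whose count matches the reference
  value, and the fully reflexive and fully strict variants (56 and 28
  triples) are therefore not used.
* **Overall error** (`check_overall_error()`): each diagonal entry exceeds
  the sum of the rest of its row, which forces it above $1/2$.

Two numerical choices deserve a note. First, *ties in the metric impose no
constraint*: both orderings of every pair are tested, so strict distance
inequalities are fully enforced, but two levels equidistant from $i$ may
carry any pair of probabilities. Under the Hamming metric this makes
$\delta_H$-monotonicity coincide exactly with modality; a literal reading
of the biconditional would instead force all off-diagonal entries of a row
to be equal, which would make the Hamming form of the condition useless as
a modality check. Ties in the *function* values under strictly ordered
distances do falsify the condition. Second, `level_metric()` does not
enforce the triangle inequality or the order-respecting property at
construction — useful dissimilarity tables (including standard textbook
examples) violate the triangle axiom — and `check_metric_axioms()` /
`is_order_respecting()` report them on demand with explicit witnesses.

Half-monotonicity is the practically important notion because it does not
depend on which order-respecting metric generated the data: a function
monotone for *some* order-respecting metric is half-monotone for *every*
order-respecting metric. The test suite exercises this equivalence on
1,000 randomly generated (metric, metric, function) cases built from
random chain embeddings and concave power transforms.

## The rate reparameterization

Half-monotonicity is a system of linear inequalities among probabilities,
which no standard EM accommodates directly. The package instead
reparameterizes each row through decay rates
(`rate_parameters()`, `rates_to_epsilon()`, `epsilon_to_rates()`):
moving one level away from the diagonal multiplies the probability by an
*overrate* rate $\omega_{qik} = \epsilon_q(i,k)/\epsilon_q(i,k-1)$ (for
$k > i$) or an *underrate* rate $\upsilon_{qik} =
\epsilon_q(i,k)/\epsilon_q(i,k+1)$ (for $k < i$). Confining all rates to
$(0,1)$ is equivalent to half-monotonicity, and the diagonal entry is
pinned by the row-sum constraint:

```{r rates}
row <- epsilon_row_from_rates(upsilon = c(2, 1) / 10, omega = c(3, 5) / 10)
row * 157
```

This recovers the reference worked example: the row
$(2, 10, 100, 30, 15)/157$ sums to one, decays on each side of the
diagonal (half-monotone), yet violates full Manhattan monotonicity because
$\epsilon(2,4) = 15/157 > \epsilon(2,1) = 10/157$. Note the index
convention: the package indexes each rate by the *target* level $k$, as in
the worked example above (so $\upsilon_{q20}$ multiplies the step from
level 1 to level 0). The equivalent ratio definitions indexed by the
source level differ by a shift of one in the subscript; the parameter sets
are identical.

## Estimation

Three estimators are provided behind the common `polim()` front end.

**Unconstrained EM** (`em_fit()`). The E-step computes
$P(K \mid R) \propto P(R \mid K)\pi_K$ over distinct observed patterns;
the M-step is the closed-form complete-data maximizer ($\pi_K$ = mean
posterior mass; $\epsilon_q(i,j)$ = expected count of latent-$i$ /
observed-$j$ pairs, row-normalized). Probabilities are floored at
$10^{-12}$ and renormalized, approximating the open-interval constraint of
the model while avoiding $\log 0$. Convergence is declared when the
absolute log-likelihood change falls below `tol` (default $10^{-6}$, cap
2,000 iterations). Likelihood work is done in the log domain and on
aggregated distinct patterns.

The conventional flat start ($\epsilon = 1/|L|$, $\pi = 1/|\mathcal{K}|$)
is an *exact fixed point* of this EM map: with all rows equal,
$P(R \mid K)$ does not depend on $K$, and one M-step reproduces the same
flat parameters, so the algorithm would never leave the label-symmetric
saddle. The default initialization therefore adds a small diagonal nudge
($10^{-3}$ before renormalization) to the error matrices, anchoring the
truthful labeling; `init = "random"` draws Dirichlet(1) rows and a uniform
Dirichlet state distribution under a seed.

**Constrained EM** (`em_fit_constrained()`). The error matrices live in
rate space, so every iterate is half-monotone by construction. No closed
form is available for the rate M-step; each item row's expected
complete-data log-likelihood is maximized numerically (BFGS on the logit
scale, warm-started at the previous iterate), and only improving steps are
accepted — a generalized EM whose observed log-likelihood is
non-decreasing, which the tests assert on every fitted trace.

**Minimum discrepancy** (`md_fit()`). A non-iterative estimator resting on
the assumption that a pattern can only be generated by states at minimum
distance from it. The pattern-state distance is the additive per-item
metric sum (Manhattan or Hamming); tied minimum-distance states receive
uniform weight; the estimates are the same complete-data formulas with the
posterior replaced by these weights. Latent levels that no
minimum-distance state attains carry no information: those rows fall back
to the uniform distribution and are flagged.

`identifiability_check()` implements the empirical identifiability
diagnostic: fit repeatedly from random starts and, among fits within a
log-likelihood window (default $10^{-3}$) of the best, report the largest
per-parameter standard deviation; values below $10^{-3}$ are taken as
consistent with identifiability. The window default is a package choice —
the criterion as published fixes only the $10^{-3}$ standard-deviation
threshold.

## Structure extraction

When no structure is given a priori, `kmedian_extract()` builds one from
data by k-median clustering under the Manhattan discrepancy: patterns are
assigned to the nearest centroid (ties to the lowest index), and each
centroid is replaced by the frequency-weighted component-wise *lower*
median of its cluster (the smallest level whose cumulative frequency
reaches half the cluster mass — deterministic and order-respecting on an
ordinal scale). Both steps weakly decrease the within-cluster discrepancy,
so the algorithm terminates at a fixed point; empty clusters are dropped,
and the iteration cap defaults to 100.

`extraction_pipeline()` wraps the published validation design: random
respondent splits into an extraction set (two thirds) and a validation set
(one third), a grid of initial-centroid counts sampled without replacement
from the extraction set's observed patterns, and selection by the minimax
criterion $z = \min_{\mathcal{K}} \max\{\Delta(\mathcal{D}_2,
\mathcal{K}), \Delta(\mathcal{K}, \mathcal{D}_2)\}$. Following the
formulas' index sets, $\Delta(\mathcal{D}_2, \mathcal{K})$ averages over
respondents (frequency-weighted) while $\Delta(\mathcal{K},
\mathcal{D}_2)$ averages over states against the *distinct* observed
patterns; the asymmetry is deliberate and demonstrated in the tests.
Minimax ties break toward the smaller structure, then input order.

## The synthetic-data generator and the recovery study

`scenario_config()` fixes the study conditions of the parameter-recovery
experiment: a random structure drawn uniformly without replacement from
the pattern space (always containing the all-zero and all-maximum states;
at the reference scale of 10 items, 4 levels and 1,000 states each level's
share per item is close to $1/|L|$), a uniform state distribution,
diagonal error probabilities uniform on $[m, 1)$ with $m \in \{.75, .85,
.95\}$, and off-diagonal values drawn uniformly and normalized to the
remaining row mass — so every generated row satisfies the overall-error
condition. In the monotone-truth scenario the *same* off-diagonal values
are reassigned in decreasing order of distance from the diagonal (ties in
distance filled lower side first), so paired scenarios share diagonals and
per-row value multisets under the same seed and differ only in ordering.
One truth is drawn per scenario and shared across replications, since
per-parameter bias and replication-wise standard errors presuppose a fixed
truth. Replication seeds derive deterministically from the master seed, so
the experiment is reproducible and could be parallelized by replication.

`run_recovery()` reports, per method and parameter class ($\pi$;
$\epsilon$ above the diagonal; below), the mean bias and mean absolute
bias of replication-averaged estimates and the average and maximum
standard error (SD of each parameter's estimates across replications —
the standard parameter-recovery reading of "standard error").
`bootstrap_se()` complements it with nonparametric respondent-level
bootstrap standard errors for a single sample.

The acceptance test runs this experiment at a deliberately reduced scale —
6 items, 4 levels, a 100-state structure, $N = 1{,}000$, 20 replications
per scenario, $m = .95$, EM tolerance $10^{-4}$ — and checks the
qualitative conclusions at sign level: unconstrained EM unbiased in both
scenarios; constrained EM biased only when the truth violates
monotonicity; Manhattan-distance MD over-estimating at distance 1 and
under-estimating beyond, with the bias largely vanishing under a monotone
truth; Hamming-distance MD compressing estimates toward the middle in both
scenarios. What the generator does *not* emulate — respondent
heterogeneity beyond the state mixture, item dependence violating local
independence, non-uniform state distributions — bounds what these passing
checks say about real questionnaire data.

## Numerical choices, degenerate inputs, limitations

* Probability floor $10^{-12}$ on all estimated probabilities; row sums
  and $\pi$ validated to $10^{-10}$ at construction.
* Pattern enumeration refuses spaces above $2^{20}$ points by default;
  structure sampling switches from rejection to enumeration only when the
  space is small and the request dense.
* Zero-marginal patterns abort likelihood evaluation with the offending
  pattern named; empty data, ragged files and out-of-range levels are
  rejected at the boundary with cell-level messages.
* MD rows without mass and empty k-median clusters are handled as
  described above, never silently.
* Standard errors for MD estimates are available only by bootstrap; no
  analytic form exists.
* Identifiability is checked empirically, not proven: the multistart
  diagnostic can miss symmetries that random starts do not explore, and
  structures graded in an item are known to defeat it in the dichotomous
  case.
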