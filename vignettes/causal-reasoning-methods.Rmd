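---
title: "Methods: causal reasoning on discrete Bayesian networks"
author: "causalbn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: causal reasoning on discrete Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalbn)
```

This vignette records the modelling conventions, algorithmic choices and
known limitations of `causalbn` in enough detail to reproduce or audit
its results.

## Model and representations

A network is a DAG over discrete variables plus one conditional
probability table (CPT) per node. Internally a CPT is a numeric array
whose **first dimension is the child** and whose remaining dimensions are
the parents in **lexicographic order of their names**; `as_cpt()` permutes
any other layout into this canonical form. States are 0-based integers
`0 … k-1` internally; display labels default to the integer strings but
can be arbitrary. Data matrices are variables × samples with `NA` for
missing values.

Factors (`cbn_factor`) store a scope, per-variable cardinalities and a
column-major value vector in which the first scope variable varies
fastest. All inference reduces to three primitives: product,
marginalisation and reduction by evidence.

## Exact inference

`variable_elimination()` converts every CPT to a factor, reduces each by
the evidence and immediately sums the evidence variables out of that
factor (they are single-slice after reduction, so this is free and keeps
intermediate factors small), then eliminates all non-target variables
with the **min-fill** heuristic: at each step the variable whose removal
adds the fewest fill edges to the interaction graph is summed out.

Ties in min-fill are broken deterministically by node name
(lexicographically smallest by default; `tie = "revlex"` picks the
largest). The elimination order affects cost only, never the result; the
test suite checks this by comparing `lex`, `revlex` and explicit reversed
orders, and checks correctness against brute-force enumeration of the
joint on hundreds of random networks.

Evidence with zero probability raises an explicit "inconsistent
evidence" error rather than silently returning `0/0`.

## Parameter learning

With complete data, maximum likelihood is closed-form: counts per
(parent configuration, child state), normalised per configuration; a
configuration never observed gets a uniform row. An optional
pseudo-count implements Dirichlet smoothing.

With missing data, `em_fit()` runs expectation–maximisation:

* **E-step.** Samples are grouped into patterns of identical columns
  (this is what makes tens of thousands of samples cheap). For each
  pattern and each family with at least one unobserved member, the
  posterior over the missing family members given the observed entries
  is computed by variable elimination on the current parameters, and the
  expected counts are distributed accordingly.
* **M-step.** Expected counts are normalised exactly as in the complete
  case.
* **Convergence.** Iteration stops when the observed-data log-likelihood
  improves by less than `tol` or `max_iter` is reached. The
  log-likelihood trace is retained per restart; monotonicity (up to
  floating-point slack) is asserted in the tests.

Because the likelihood is multi-modal, `em_config()` supports multiple
restarts cycling through three initialisers: `uniform` (all rows
uniform), `random` (normalised random draws), and `complete_case`
(maximum likelihood on the complete columns only, uniform if there are
none). The restart with the best final log-likelihood wins; the full
restart table is kept on the fitted object. All randomness flows through
an explicit seed and restores the caller's RNG state afterwards.

## Discretisation conventions

Ten methods are available per variable via a JSON spec, plus `none` for
already-discrete non-negative integers. Conventions that matter for
reproducibility:

* Binary threshold methods (`threshold`, `arithmetic_mean`,
  `harmonic_mean`, `median`, `z_score`) map to state 1 iff
  `value > cut` — **strictly** greater, so a value equal to the cut goes
  to state 0.
* `z_score` standardises and thresholds at 0, which is equivalent to
  `value > mean`; it is retained as a separate name because specs in the
  wild use it.
* `bracket_medians` (equal-frequency buckets) and `pearson_tukey`
  (three classes cut at the 0.185 and 0.815 quantiles) use **type-1**
  (inverted empirical CDF) quantiles, so results are exactly reproducible
  across platforms.
* `round` uses R's banker's rounding (round-half-to-even); `ceil`,
  `floor` and `round` re-index the resulting integers densely in
  ascending order so states are always `0 … k-1`.

## Interventions and counterfactuals

`apply_do()` implements Pearl's do-operator by graph surgery: incoming
edges of the intervened node are removed and its CPT becomes a point
mass. Non-descendants of the intervened node are therefore provably
invariant, which the tests assert to `1e-9` on random networks.

Edge interventions (`+ X Y`, `- X Y`) modify the topology and re-estimate
only the affected child's CPT. If training data are retained on the
fitted network, the family is refit locally (EM on the family
subnetwork); without data, an added parent replicates the existing CPT
across the new parent's states, and a removed parent marginalises the CPT
weighted by that parent's current marginal. These are pragmatic
conventions, not identification results.

Counterfactuals use a **twin network**: variables whose mechanism changes
under the intervention, and their descendants in the post-intervention
graph, are duplicated with fresh copies; un-duplicated variables are
shared. The factual copy is conditioned on the observations, the
counterfactual copy receives the intervention, and the query is answered
on the counterfactual copy.

One semantic caveat is inherent to CPT-level models: a twin network built
from CPTs treats each duplicated mechanism as an **independent redraw**
of its conditional distribution rather than sharing latent exogenous
noise between the factual and counterfactual worlds. Deterministic
mechanisms are unaffected, but for genuinely stochastic CPTs the answers
correspond to the "independent response" interpretation, not to
functional structural equation models with shared noise. Queries whose
answer depends on that distinction should be treated with care.

## The query language

Queries are strings `? targets | evidence ! interventions`:
targets are `node = state` pairs and/or `argmax(node)`; evidence items
are `node = state`; interventions are `do node = state`, `+ from to`
(add edge) and `- from to` (remove edge). `parse_query()` produces an
AST, `format()` un-parses it to the identical surface string, and
`validate_query()` checks node names, state ranges and edge legality
(including cycles introduced by `+`) against a network before
evaluation. With both evidence and interventions,
`evaluate_query(..., worlds = "twin")` (the default) answers the
counterfactual reading; `worlds = "single"` conditions and intervenes in
one world.

## Synthetic fixtures and what the tests show

No real measurement data are shipped. The test suite and the acceptance
script use:

* the rain/sprinkler/wet network with its textbook CPTs, where
  interventional and observational answers are known exactly
  (`P(W=1 | do S=1) = 0.918` vs `P(W=1 | S=1) ≈ 0.9006`);
* random networks with random Dirichlet-style CPTs, checked against
  brute-force enumeration;
* the consensus 11-protein signalling topology of Sachs *et al.* (2005)
  with a clearly-labelled **synthetic** parameterisation, continuous
  Gaussian class-conditional observations, bracket-medians
  discretisation and EM fitting.

The problem sizes (sample counts, missingness rates, restart counts,
tolerances) are this package's own testing choices. The synthetic
signalling experiments demonstrate that the pipeline — discretise, fit,
query, intervene — runs end-to-end and respects the structural facts the
topology implies (e.g. intervening on a downstream kinase cannot move an
upstream one); they do **not** validate any biological claim about the
real signalling system, which would require the original flow-cytometry
measurements.

## Limitations

* Exact inference only; treewidth-hard networks will be slow. Min-fill
  is a heuristic with no optimality guarantee.
* Discrete variables only; continuous inputs must be discretised, and
  the answers depend on that choice.
* EM finds local optima; restarts mitigate but do not eliminate this.
* Counterfactuals use independent-redraw twin-network semantics (above).
* Structure learning is out of scope: the topology is an input.
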