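---
title: "Reconstructing a binary trait over a sample of phylogenies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing a binary trait over a sample of phylogenies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binasr)
```

`binasr` reconstructs the history of a binary morphological character —
the motivating case is unicellular (state 0) versus multicellular (state 1)
growth in cyanobacteria, scored from the classical morphological sections
(I–II unicellular, III–V multicellular) — on rooted phylogenies, and
aggregates those reconstructions over a posterior sample of trees so that
conclusions do not hinge on a single topology. This vignette describes the
models, the numerical choices, and the synthetic data used to validate the
machinery.

## The character and its models

A character state is attached to each tip of a rooted tree with branch
lengths in expected substitutions per site. Three inferential routes are
provided, deliberately mirroring the standard toolchain for this kind of
analysis:

**Parsimony.** Unordered, unit-cost (Fitch) parsimony, implemented as a
two-state Sankoff dynamic program. The DP formulation means polytomies and
missing tip states need no special-casing: a polytomous node simply sums
messages over all its children, and a missing tip contributes the state set
\{0, 1\}. Beyond the minimum step count, `mpr_state_sets()` reports, for
every node, which states occur in at least one most-parsimonious
reconstruction (MPR): a node is *uniquely best* when only one state does,
*equivocal* when both do. `directional_transitions()` counts gains
(0→1) and losses (1→0) either for one deterministically chosen
reconstruction or — via a second DP over the subtree-optimal choice sets,
never by brute enumeration — as the exact minimum and maximum of each
direction over all MPRs. Statements of the form "at least five reversals
to unicellularity" are operationalized as the minimum loss count over all
MPRs, a lower bound that holds no matter which optimal reconstruction one
prefers.

**Maximum likelihood.** A continuous-time two-state Markov chain with
instantaneous rates `fw` (0→1) and `bw` (1→0) per unit branch length: the
one-parameter Mk1 model constrains `fw = bw`, the two-parameter AsymmMk
model frees them. Transition probabilities use the closed form
`P00(t) = (bw + fw e^{-(fw+bw)t})/(fw+bw)`,
`P11(t) = (fw + bw e^{-(fw+bw)t})/(fw+bw)`. The root prior is fixed at the
stationary distribution `pi = (bw, fw)/(fw+bw)` ("root at equilibrium");
no flat-root option is offered in this version, because a flat root
coincides with `pi` only under Mk1 and offering both invites silent
mismatches. Likelihoods are computed by Felsenstein pruning in a small C++
kernel with per-character rescaling; `marginal_asr()` adds an outside
(down) pass, so each node's reported `(p0, p1)` is its marginal posterior
given *all* tips — the quantity drawn as a pie chart at internal nodes.
Reversibility of every stationary two-state chain makes these marginals
equivalent to re-rooting at each node, and the likelihood invariant to
root placement along any branch; the test suite checks both properties
numerically.

**Bayesian.** `run_rjmcmc()` samples the rates under exponential priors
whose common mean `m` carries a uniform hyperprior on (0, 10), with
reversible-jump moves between the equal-rates and free-rates models and a
uniform independence proposal over the tree sample. The hyperprior bounds,
the 30-million-iteration full-scale setting and the 50,000 burn-in are the
reference analysis's settings; the desk-scale defaults (300,000 iterations)
are ample for a single binary character, whose likelihood surface is
two-dimensional. Two design points deserve a note:

* *Tree moves are Metropolis–Hastings, not plain resampling.* Redrawing the
  tree index uniformly and accepting unconditionally would sample trees
  from their prior rather than their posterior weight given the character;
  the implementation therefore proposes uniformly and accepts with the
  likelihood ratio.
* *Node probabilities are Rao-Blackwellized.* At each recorded draw the
  marginal probability of state 1 at each query node is computed
  analytically given the current rates and tree, rather than sampling a
  latent node state. This reduces Monte-Carlo variance and produces the
  smooth posterior histograms users expect from this analysis style.

The reversible-jump split move draws `u ~ N(0, 0.7)` and proposes
`(fw, bw) = (r e^u, r e^{-u})` with Jacobian `2r`; the merge move inverts
it through `r = sqrt(fw bw)`. Only the equal-rates and free-rates classes
are visited; zero-rate model classes are excluded because a character with
both gains and losses in the data gives them negligible support while
complicating the sampler.

Model comparison uses `marginal_likelihood()`: stepping-stone sampling
over 32 power-posterior rungs spaced as `beta = (k/K)^{1/0.3}` (the
quantiles of Beta(0.3, 1), concentrating rungs near the prior where the
integrand changes fastest), with Bayes factors reported on the `2 ln`
scale. The harmonic-mean estimator is retained for comparability with
older practice but flagged unstable in its metadata; stepping-stone is the
default and is validated against two-dimensional quadrature in the tests.

## Aggregation over a tree sample

`summarize_ml()` and `summarize_mp()` follow the reporting conventions of
per-node pie charts over a posterior sample. A reference node is defined by
its tip content (`node_query()`), and two matching semantics are offered:
`exact_clade` (the node whose descendant tip set equals the query set,
counted *absent* otherwise — this reproduces the white "node absent"
slices) and `mrca` (always defined, tolerant of partial tip lists — the
semantics used for Bayesian node queries, and the right choice for the
bundled `cyano_clades()` lists, which name only the clade members stated
explicitly in the source study's text). Per-query ML summaries are the
arithmetic means of per-tree marginal probabilities over matched trees;
the alternative of averaging unnormalized likelihoods is deliberately not
the default, since per-tree normalization is what pie-chart summaries
display. Rates can be fixed (a `rate_model`, a grid token `F1`–`F6`, or an
`fw:bw` literal) or re-estimated independently on every tree
(`rates = "estimate"`), mirroring the two ways rates are handled in the
reference analysis; the consensus-tree estimate is reported separately by
`fit_mk()`.

The fixed grid F1–F6 — (0.90, 2.70), (2.70, 0.90), (5.40, 0.45),
(0.45, 5.40), (0.90, 0.90), (2.70, 2.70) — probes sensitivity to the rate
asymmetry. One property of these probes is easy to get backwards: with an
equilibrium root, detailed balance (`pi0 fw = pi1 bw`) makes the prior
asymmetry cancel the likelihood asymmetry on short branches, and on
balanced data the *minority-generating* process dominates — when gains are
rare, observed state-1 tips force ancestral multicellularity, so the root's
`p1` *decreases* as `fw/(fw+bw)` grows. The direction of grid-to-grid
differences at a node is therefore a property of the dataset, not of the
model; the tests pin down the exact symmetry instead (swapping the rates
equals flipping the states).

## The conservatism permutation test

`conservatism_test()` asks whether the character changes rarely on the
credible trees relative to chance: the observed distribution is the Fitch
step count of the real character on each sampled tree; the null
distribution shuffles the states across tips on the consensus tree,
preserving the state composition (29:29 in the bundled table) exactly.
Because tip labels are exchangeable under the null, permuting states is
equivalent to permuting terminal taxa and simpler to verify. The reference
analysis reports only "p < 0.01" without defining the statistic, so the
default here is stated precisely: `p = (1 + #{null_j <= mean(observed)}) /
(n_shuffles + 1)`, with an add-one correction so p is never zero; a
Mann–Whitney rank-sum variant is available behind `statistic =
"rank_sum"`, and both full distributions are returned so any variant can
be recomputed. Calibration under the null is verified by simulation:
with iid random states the p-value should be uniform. That check is run
on 128-tip trees: the step count is an integer statistic, and on small
trees its tie mass (≈0.15 of probability on the modal value at 58 tips)
dominates a continuous uniformity test; at 128 tips the distribution is
fine-grained enough for the comparison to be meaningful. This is a
property of any integer-valued permutation statistic, not of the
implementation; the exactness checks (constant character gives p = 1, a
perfectly conserved two-block character gives p = 1/(n+1)) hold at any
size.

## Synthetic data: what it emulates and what it does not

Real inputs for this analysis are a Bayesian posterior sample of 16S rDNA
trees and a 58-taxon character table; tree inference itself is out of
scope. The generator therefore produces data *shaped like* that input:

* `simulate_yule()`: pure-birth trees by forward simulation (waiting time
  `Exp(k * birth)` with `k` lineages, uniform lineage choice), rescaled to
  a target depth. Pure birth suffices because downstream methods consume
  only topology and branch lengths; extinction adds nothing testable here.
* `simulate_character()`: simulates the full jump process along each
  branch (not just endpoint draws), so the realized number of events is
  known exactly and expectation checks against the equilibrium flux
  `sum_b t_b (pi0 fw + pi1 bw)` are possible.
* `perturb_tree_sample()`: emulates a posterior sample as the base tree
  plus `Poisson(intensity)` random NNI moves and unit-mean log-normal
  branch-length multipliers per tree. This reproduces the only posterior
  features the summarizers consume — clade frequencies below one and
  length jitter — without re-running tree inference.
* `simulate_study()`: a 58-tip tree assembled from fixed-size clade blocks:
  two basal unicellular lineages, then a large clade whose stem carries
  the single gain of multicellularity, containing the three deep reference
  clades `C`, `AC` and `E`. Seven unicellular reversal clades are planted
  inside `AC` (four) and `E` (three), each separated along its clade's
  spine by multicellular blocks so the planted losses remain independent
  under parsimony, and each clade's spine carries one more multicellular
  block than reversal blocks so the deep ancestors are uniquely
  multicellular in every MPR. One tip nested *inside* an `E` reversal
  clade regains multicellularity (its clade's topology is pinned so the
  loss-plus-regain cannot collapse into a single loss). The block sizes
  are chosen once so that the tips split exactly 29:29 and the planted
  history has 9 transitions (1 gain, 7 losses, 1 regain) — the
  constructive equivalent of constraining the state ratio by rejection,
  but deterministic. Branch lengths give a root-to-tip depth of ≈ 0.45
  substitutions per site with 20% log-normal jitter, so implied transition
  rates fall in the same 0.5–5 per-unit-length range as the fixed grid.

Against these datasets, the planted pattern is recovered: the consensus
parsimony count equals the planted 9, the permutation test rejects at
p < 0.01 for ≥ 95% of generator seeds, and per-tree ML over 1,000 sampled
trees returns mean `p1 > 0.75` at all three deep nodes for ≥ 90% of seeds.
What passing these checks does *not* show: the generator's NNI
perturbation is not a real posterior (clade frequencies are controlled,
not inferred), characters evolve exactly under the fitted model (no rate
heterogeneity, no correlation with the tree inference), and the planted
history is parsimony-friendly by construction. Conclusions about real
data still require real posterior tree samples.

## Numerical choices and degenerate inputs

* Rates are optimized on the log scale with L-BFGS-B, bounds `[1e-8, 1e3]`,
  function tolerance `1e-8`, and five starting points spanning `1e-3`–`1e2`
  (per-tree fits inside `summarize_ml()` may use fewer; the study-scale
  runs here use three). Fits at a bound are flagged `boundary` — the
  expected outcome for constant characters. Ties between starts resolve to
  the lowest `fw`.
* Zero-length branches are legal (identity transition matrix); negative
  lengths are rejected. Likelihood methods require lengths on all edges;
  parsimony ignores lengths entirely, so consensus trees with stripped
  lengths remain analyzable by the parsimony route.
* Pruning partials are rescaled per node; posterior normalization at each
  node absorbs the scale factors exactly.
* Parsimony tie-breaks for a single reported reconstruction are
  deterministic: root ties resolve to state 0, child ties to the parent's
  state ("deltran"), to a change ("acctran"), or to the loss-minimizing
  choice (`minimize_losses`). The enumerated min/max ranges are
  tie-break-free and preferred for scientific statements.
* Node numbering is validated before any kernel call (some tree
  manipulation functions in the wider ecosystem can emit non-compact
  numbering); the root is always derived from the edge matrix rather than
  assumed to be `ntip + 1`.
* Problem sizes in the shipped checks are desk-scale by design: brute-force
  oracles run at ≤ 8 tips where enumeration is exact; recovery experiments
  use 500 characters on 64 tips; chain lengths of 2–3 × 10^4 suffice for
  the two-parameter posterior, and 1.5 × 10^5 for the study-scale rjMCMC
  run. The full-scale settings of the reference analysis remain available
  through `mcmc_config()`.

## Known limitations

Only binary characters (no multistate generalization, no weighted step
matrices); no rate variation across branches or covarion behaviour; no
joint tree-plus-trait inference — tree uncertainty enters only through the
supplied sample; no convergence diagnostics beyond per-move acceptance
rates (use the trace tibble with a dedicated MCMC-diagnostics package for
more); NEXUS is read but never written. The bundled clade lists are
partial (text-derived) and meant for MRCA queries, not exact-clade
matching.
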