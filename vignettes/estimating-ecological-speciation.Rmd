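---
title: "Estimating the prevalence of ecological speciation from niche shifts and sister pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the prevalence of ecological speciation from niche shifts and sister pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicheshifts)
```

## The question and the model

Ecological speciation is lineage splitting driven by divergent selection
arising from the use of different resources, as opposed to divergence by
drift or incompatibilities accumulated in allopatry. For herbivorous
insects the resource axis is concrete: a species' niche is its larval
feeding habit crossed with the set of host-plant taxa it uses. If
speciation is predominantly ecological, sister species should occupy
different niches from the moment they split; if niche shifts instead
accumulate gradually after speciation, old sister pairs will differ even
when the splits themselves were not ecological. `nicheshifts` implements
both ways of interrogating a dated phylogeny plus a species–niche table,
and a simulator that generates data where the truth is known.

### Niche coding and the generalist step matrix

`build_catalog()` enumerates every distinct (habit, host-set) combination
among ingroup species as one state of a single multistate character;
outgroups are coded unknown, which in parsimony means "any state at zero
cost". Two step matrices over this catalog are built by
`build_step_matrix()`:

* `all_one` — every change between distinct states costs one step; the
  tree length is the plain count of niche shifts.
* `generalist_zero` — a transition *into* a generalist state costs zero
  when the generalist subsumes the source niche (same feeding habit,
  source host set contained in the generalist's host range). The rationale
  is that a clear host-range overlap between two states is evidence
  against ecological divergence: a specialist lineage "expanding" into a
  superset of its hosts has not moved to a new adaptive zone.

Three consequences of taking the subset rule literally are worth stating.
The zero applies only in the direction into the subsuming generalist; the
reverse move (generalist to contained specialist) is a genuine host-range
contraction and costs one step (a `symmetric` switch zeroes both
directions for sensitivity analysis). Generalist-to-generalist moves with
partial overlap cost one step unless one host set contains the other,
because only the containment case is unambiguous. And a habit change
always costs one step, even within a shared host, since the niche is
defined as habit × hosts. Host labels are opaque strings: the analyst
decides whether they are families, genera or species, and coarser labels
yield fewer states and fewer counted shifts.

### Sankoff parsimony

`sankoff_min_cost()` minimizes the summed transition cost over all
ancestral assignments by the standard dynamic program
`C_v(s) = Σ_children min_t [cost(s,t) + C_child(t)]`, with tips costing 0
for admissible states and infinity otherwise. Polytomies are handled by
the sum over all children, and costs may be real-valued (the generalist
rule introduces zeros). Inadmissible states are marked with IEEE `Inf`,
which is exact under the additions and minima the recursion uses and
cannot overflow — no finite sentinel is needed. `ancestral_states()` adds
the up-pass and reports, per node, the full set of states attainable in
at least one minimum-cost reconstruction (the MPR set, with a `1e-9` tie
tolerance for real-valued costs); ambiguity is exposed as a set, never
resolved by an arbitrary tie-break, because any single painting of an
ambiguous node would be an artifact of traversal order.
`count_shifts_over_sample()` repeats the optimization over a posterior
tree sample and summarizes min/mean/max, the robustness check used with
post-burnin MCMC samples.

The shift count is compared with `required_speciation_events()`, i.e.
n − 1 for n sampled ingroup species: their ratio is an upper bound on the
fraction of splits that can have coincided with a niche shift, an upper
bound because taxon sampling that spreads over niches inflates apparent
shifts and parsimony undercounts changes in fast-evolving characters.

### Sister pairs and the age correction

`extract_sister_pairs()` takes every cherry (internal node whose two
children are both tips); its relative node height — node-to-tip distance
divided by root height — is the pair's relative split age in [0, 1]. On a
non-ultrametric tree the mean distance to descendant tips is used and a
warning is emitted (tip-depth spread above 1e-6 relative); the intended
input is an effectively ultrametric relaxed-clock MCC chronogram, where
the mean coincides with the common value. A would-be cherry that is a
polytomy of three or more tips is skipped with a warning rather than
decomposed into pairs: any pairing would be invented and its split age
biased.

`classify_pairs()` labels a pair 1 when the two niches are different —
distinct feeding habits and/or disjoint host sets — and 0 when identical
or overlapping, dropping pairs with an unknown member.
`proportion_different()` is the raw estimate; `fit_logistic()` fits
P(different) = logit⁻¹(β₀ + β₁·age) and `predict_probability(fit, 0)` is
the corrected estimate of the ecological fraction: the probability that a
pair of age zero, i.e. a fresh speciation event, already shows
non-overlapping niches.

### The logistic fitter

The fitter maximizes the Bernoulli likelihood by Newton/IRLS steps,
declaring convergence when the maximum absolute score drops below 1e-8 or
the parameter step below 1e-10 (both much finer than the data can
resolve). Standard errors come from the observed information; Wald
p-values are printed alongside likelihood-ratio p-values because
mainstream statistics packages differ in which they report, and on the
small n typical of sister-pair datasets the two can disagree noticeably.
Complete or quasi-complete separation is detected (linear predictor
exceeding 30 in absolute value while classifying the data perfectly, or a
singular information matrix) and returned as a flagged non-converged fit
instead of silently huge coefficients. Note that slopes of 10–20 are
*legitimate* on a [0, 1] age axis; the separation criterion is therefore
tied to the predictor scale, not to a coefficient threshold.

## The simulator: what it emulates and what it does not

`sim_config()` defaults describe the study conditions the package is
designed around: a radiation of ~125 sampled species on an ultrametric
tree with root height 1 (`ape::rphylo` birth–death conditioned on n tips,
pure birth by default), six larval feeding habits, a pool of 20 woody
host-plant genera, new niches drawn uniformly with a 0.15 probability of
being a two-host generalist (a minority of oligophages, as in real
host-use tables), and two outgroups with unknown niches. Under those
defaults a 125-tip realization carries ~40–60 distinct tip niches, the
catalog size a real table of this kind produces. The generator refuses
`death_rate >= birth_rate`, where conditioning on survival is not
well-posed for this simple simulator.

Niche evolution has exactly the two ingredients the inference tries to
separate: with probability `p_eco` a split is *cladogenetic* — one
daughter draws a fresh niche guaranteed non-overlapping with its sister's
at that moment — and along every branch *anagenetic* shifts arrive as a
Poisson process with rate `ana_rate` per unit branch length, each
replacing the current niche by a fresh draw. At age t the probability a
pair differs is therefore approximately
1 − (1 − p_eco)·exp(−2·ana_rate·t), which decays to p_eco at t = 0: the
age-zero extrapolation targets exactly the generating parameter, while
the raw proportion averages the inflated curve over observed cherry ages.
The test suite verifies this recovery at n_tips = 400 with 20 replicates
per p_eco ∈ {0.1, 0.2, 0.5} (mean age-zero estimate within ±0.07 of the
truth, raw proportion above it in ≥ 15/20 replicates); those sizes give
roughly a hundred cherries per replicate, enough for a stable two-
parameter fit while the whole study stays a desk-scale computation.

Posterior samples are emulated by random NNI perturbations of the true
tree (`generate_dataset(n_posterior_trees = ...)`): only the
counting-over-samples contract needs exercising, and perturbed topologies
cannot systematically *reduce* homoplasy, which the tests assert. The
simulator does not emulate several features of real data: phylogenetic
error correlated with branch lengths (NNI moves are topology-only, not an
MCMC approximation), host-taxonomy structure (hosts are exchangeable
labels, so there is no "nearby host" bias in shifts), extinction's effect
on cherry ages under the default pure-birth setting, and conspecific
duplicate exemplars. Passing tests therefore demonstrate correctness of
the estimators under the stated generative model, not robustness to
misspecified host taxonomies or tree error.

## Worked run

```{r example}
cfg <- sim_config(n_tips = 60, p_eco = 0.2, ana_rate = 1, seed = 42)
sim <- generate_dataset(cfg, n_posterior_trees = 20)
report <- run_analysis(sim$mcc, sim$niches, sim$posterior)
report
```

The report juxtaposes the three quantities of interest: the
shift-to-speciation ratio (upper bound), the raw sister-pair percentage
(inflated by anagenetic change), and the age-corrected probability at
split age zero. `write_report()` serializes it to JSON (percentages to one
decimal, probabilities to three) plus the classified pair table as TSV.

## Numerical and design choices

* Catalog order is the sorted order of state labels, making codings, step
  matrices and downstream counts deterministic for a given table.
* Sister pairs are sorted by split age, and within a pair tips are
  alphabetical; permuting input rows cannot change any statistic.
* Cost ties in MPR sets use a 1e-9 tolerance; step counts are reported as
  reals and print as integers when integral.
* All simulator randomness derives from a single integer seed; the tree,
  niche-evolution and posterior-perturbation stages use fixed offsets of
  it so each stage is individually reproducible.
* Degenerate inputs fail loudly: zero root height, empty host sets,
  single-class pair labels, zero-margin contingency tables.

## Limitations

Pairs are treated as exchangeable observations in the logistic regression
(no phylogenetic correlation among pairs), as is standard for
sister-pair designs since each pair is an independent contrast. The
parsimony counts are minimum-change estimates and inherit parsimony's
underestimation of changes along long branches. The generalist-zero rule
is deliberately literal about subset containment; host ranges that
overlap without containment are treated as distinct states, which a
coarser host taxonomy would merge. Probabilistic (ML/Bayesian) character
models and likelihood ancestral reconstruction are out of scope.
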