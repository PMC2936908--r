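# nicheshifts

How often does speciation coincide with an ecological niche shift? In
host-associated insect radiations — the motivating system is Holarctic
nematine sawflies whose larvae feed on willows, birches, conifers and other
woody plants — every species occupies an ecological niche defined as the
combination of its larval **feeding habit** (external folivory, galling,
leaf folding, catkin feeding, berry mining, needle feeding, ...) and the
**set of host-plant taxa** it uses. `nicheshifts` implements two
complementary phylogenetic estimators of the fraction of speciation events
that were ecological, for systematists and evolutionary ecologists working
with dated phylogenies and host-use tables.

## The methods

**1. Parsimony counting of niche shifts.** Every distinct niche
(habit × host set) among the ingroup species becomes one state of a single
multistate character; outgroups are coded unknown. The minimum number of
state changes on a tree is found by generalized (Sankoff) parsimony,

  C_v(s) = Σ_children min_t [ cost(s→t) + C_child(t) ],

with two costing rules: `all_one` (every change costs 1 step) and
`generalist_zero`, in which a transition *into* a generalist state that
subsumes the source niche — same habit, source hosts ⊆ generalist hosts —
costs 0, operationalizing the assumption that clearly overlapping host
ranges are not evidence of ecological speciation. Counting over a Bayesian
posterior tree sample quantifies robustness to phylogenetic uncertainty,
and the ratio of the count to the n − 1 speciation events implied by n
sampled species bounds the fraction of splits that can have been
ecological.

**2. Age-corrected sister-pair analysis.** Each cherry of the dated (MCC)
tree yields a terminal sister pair with a relative split age (relative node
height ∈ [0, 1]) and a binary label: niches *different* (distinct habits
and/or non-overlapping host ranges) or *same/overlapping*. The raw
proportion of different pairs overestimates ecological speciation because
post-speciational (anagenetic) host shifts accumulate with age, so a
logistic regression

  P(different) = 1 / (1 + exp(−(β₀ + β₁·age)))

is fitted by maximum likelihood (Newton/IRLS, with Wald and
likelihood-ratio inference and explicit separation detection) and
extrapolated to age 0: the intercept probability estimates the fraction of
splits at which the daughters already had non-overlapping niches.

A birth–death simulator with cladogenetic (at-speciation, probability
`p_eco`) and anagenetic (rate `ana_rate` per unit branch length) niche
shifts generates data with known truth, so the whole pipeline — including
recovery of `p_eco` by the age-zero extrapolation — is testable without any
external data.

## Worked example

```r
library(nicheshifts)

cfg <- sim_config(n_tips = 125, p_eco = 0.2, ana_rate = 1.0, seed = 42)
sim <- generate_dataset(cfg, n_posterior_trees = 100)

report <- run_analysis(sim$mcc, sim$niches, sim$posterior)
report
#> Ecological-speciation analysis
#>   125 ingroup species -> 124 speciation events; 46 niche states
#>   min niche shifts: 52 (generalist-zero), 52 (all-one)
#>   shift/speciation ratio: 0.419 (generalist-zero), 0.419 (all-one)
#>   sister pairs: 16 of 41 niche-different (39.0%)
#>   logistic: P(diff) = 1/(1+exp(-(-0.87 + 4.80*age)))
#>   corrected P(different) at split age 0: 0.294 (29.4%)

report$shift_counts$all_one$sample
#> Niche-shift counts over 100 tree(s): min 52, mean 52.13, max 53
```

Reading the numbers: 125 simulated species imply 124 speciation events, but
only 52 niche shifts are needed to explain the tip niches, so at most ~42%
of splits can have coincided with a shift. 39.0% of terminal sister pairs
differ in niche, but the logistic regression attributes much of that to
post-speciational change accumulating with split age; extrapolated to age
zero the corrected estimate is 29.4%, much closer to the generating
`p_eco = 0.2` than the raw proportion (a single replicate is noisy; the
test suite averages 20 replicates per setting). The posterior-sample
summary shows the count is stable across perturbed topologies (52–53
steps).

Real data enter the same way: `read_trees()` parses Newick and Nexus
(TRANSLATE tables resolved, BEAST-style `[&...]` annotations stripped),
`read_niche_table()` reads a TSV of `species`, `feeding_habit`, `hosts`
(semicolon-separated), `outgroup`. A thin command-line wrapper with
`simulate`, `count-shifts`, `pairs`, `fit` and `run-all` subcommands is in
`inst/cli/nicheshifts.R`.

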