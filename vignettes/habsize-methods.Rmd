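---
title: "Methods: multi-scale size-by-habitat comparisons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale size-by-habitat comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(habsize)
```

# The analysis in one paragraph

Given a rooted, branch-length-bearing phylogeny and a taxon table
assigning each species a habitat-use category (marine, freshwater,
brackish, marine–brackish, freshwater–brackish, euryhaline), a maximum
length, and optional trophic level / migratory / taxonomy fields, the
pipeline (i) partitions the tips into clades at several *scales of
observation*, (ii) compares log10 body size between every habitat pair
within every clade under five metrics, (iii) tallies, per scale and pair,
the percentage of clades in which one habitat's taxa are larger
("majority percentages"), (iv) maps habitat transitions with stochastic
character maps under a fitted Mk model, (v) reruns the size comparisons
on trophic-complete taxa and retains only direction-stable comparisons
("reduce and retain"), and (vi) scores each retained comparison against
four suites of candidate mechanisms.  Exclusively brackish taxa stay in
the dataset and in the transition analysis but are excluded from the
pairwise comparison set, which consists of the ten pairs among the other
five categories in the fixed canonical order (freshwater,
freshwater–brackish, marine, marine–brackish, euryhaline); all signed
differences are first-listed minus second-listed habitat.

# Statistical components and their assumptions

## Brownian covariance and GLS habitat means

All phylogenetic statistics share one covariance contract: `C[i, j]` is
the shared root-to-MRCA path length of tips *i* and *j*, the covariance
(up to a rate) of a Brownian trait.  Phylogenetic habitat means are the
GLS coefficients `(XᵀC⁻¹X)⁻¹XᵀC⁻¹y` for habitat indicator columns `X`.
On a star phylogeny `C ∝ I` and the GLS means reduce exactly to
arithmetic group means (asserted to 1e-10 in the tests).  When `C` is
numerically singular (zero-length cherries) a ridge of `1e-8 × mean
diagonal` is added with a warning.

## The five size metrics

1. *Difference of log10 means* — no phylogenetic correction.
2. *Difference of phylogenetic (GLS) means* — one GLS fit per clade with
   all habitat groups present; pairwise differences are differences of
   LS means.
3. *Wilcoxon rank-sum test* — exact enumeration when `n_a + n_b <= 12`
   and no ties, otherwise normal approximation with tie and continuity
   corrections.  The reported effect direction is the rank-biserial
   correlation.
4. *Simulation phylogenetic ANOVA* — the observed one-way F is referred
   to the F distribution of `n_sim` Brownian simulations on the clade
   tree (rate = ML estimate; REML by flag), groups held fixed.
5. *PGLS ANOVA with residual randomization* — trait and designs are
   whitened by the Cholesky factor of `C`; the statistic is the
   reduction in residual sum of squares from intercept-only to group
   model; the null permutes the whitened null residuals.

Both resampling tests use the `(1 + exceedances) / (1 + n)` convention so
p is never zero, and both hold their nominal type-I error under a
Brownian null (the acceptance suite runs 500 replicates at n = 200,
n_sim = n_perm = 199 and requires rejection rates in [0.03, 0.07]).
Assumption to keep in mind: the Brownian null is also the generator of
the synthetic data, so calibration there does not certify robustness to
non-Brownian evolution (OU, rate shifts); that robustness is untested by
design and out of scope.

## Observation scales

The four tree-partition scales split the phylogeny into 13, 9, 5 and 3
monophyletic sections (defaults, configurable).  The construction rule —
iteratively split the section with the most tips at its root, ties broken
by the lexicographically smallest contained tip label — is a
deterministic stand-in chosen here: the source analyses defer their exact
section construction to supplementary material, so this package fixes a
reproducible rule and documents it rather than guessing memberships.
The partition is invariant to the tip order of the input Newick (tested
by rotating internal nodes).  Family and order scales come from labels
and may legitimately be non-monophyletic; they are emitted with a
warning rather than an error.  Hotspot scales rank candidate clades (the
order scale by default) by mean stochastic-map transition events per tip
— again a documented, configurable stand-in — and `expand = TRUE` merges
each hotspot with its sister clade.

## Habitat transitions

Mk models over the six states are fitted by maximum likelihood with the
pruning algorithm; per-edge transition matrices come from one
eigendecomposition of the generator (`P(t) = V e^{Λt} V⁻¹`, clamped to
non-negative and renormalized; `ape::matexpo` is the fallback for
defective generators).  Rates are optimized on the log scale with
multi-start L-BFGS-B (default 5 starts) because a six-state
all-rates-different model has 30 rates that are weakly identified when
transitions are few; the nesting ER ⊆ SYM ⊆ ARD is respected by the
fitted likelihoods (tested).  Stochastic maps draw internal node states
from their exact conditionals (pre-order over pruning partials) and then
sample endpoint-conditioned paths per edge by uniformization, with a
rejection-sampling fallback if the jump-count series fails to converge.
The root prior defaults to equal frequencies — the source is silent on
this point — with stationary and FitzJohn options.

## Reduce and retain, alignment, mechanisms

Retention is anchored on the phylogenetic-mean metric: a comparison is
retained when its direction on trophic-complete taxa matches the
full-data direction and is not a tie.  The source text is ambiguous
about whether retention requires agreement on one or all metrics, so the
single-metric anchor is the default and `strict = TRUE` requires all
five.  Mechanism indicators per retained comparison: A (size-larger
habitat has the higher phylogenetic mean trophic level; A′ uses plain
means), Bi (its migratory percentage exceeds the other's by at least 20
points — the boundary counts as supported), Bii = A ∧ Bi,
Biii = Bi ∧ ¬A, C (strictly larger mean terminal branch duration), D
(strictly lower species richness *within the clade*), and the unions
A+Biii and A∨Bi∨C∨D in which no comparison is counted twice.  Missing
trophic or migration data yield `NA` indicators that drop out of the
aggregate denominators.  Migration bands for annotation: `M` above 30%,
`m` for 5–30% inclusive, none below 5%.

# The synthetic generator: the stated world

`sim_config()` fixes the world the tests exercise:

- a birth–death tree (`rphylo`, birth 1, death 0.25) conditioned on the
  tip count and rescaled to unit depth, so all rates are per unit depth;
- habitats evolved by a sparse Mk generator whose stationary
  distribution keeps freshwater and marine co-dominant (~35% each) with
  species-poor euryhaline and brackish states, whose routes between the
  pure states pass mostly through the brackish-associated and euryhaline
  states, and whose rates out of the euryhaline state exceed the rates
  in;
- log10 size = Brownian realization (rate 0.05, root 1.2 ≈ 16 cm) plus a
  habitat offset, default offsets (freshwater 0, freshwater–brackish
  0.2, marine 0.25, brackish 0.3, euryhaline 0.55, marine–brackish 0.6)
  encoding the three-tier pattern: small freshwater taxa; mid-sized
  freshwater–brackish and marine taxa; large euryhaline and
  marine–brackish taxa;
- trophic level = 0.6 × log10 size + habitat offset + N(0, 0.25),
  clipped to (1, 6], missing for 30% of taxa (the trophic dataset is
  much smaller than the size dataset, which is what makes reduce and
  retain non-trivial);
- migratory flags Bernoulli per habitat, ~30% in euryhaline and far
  lower elsewhere;
- order/family labels painted onto monophyletic partitions so the label
  scales are well defined.

The tip-level habitat offset (rather than an OU pull per regime) is a
deliberate simplification: it produces the mean-shift structure the
analysis targets while leaving the Brownian-based tests approximately
calibrated.  What the generator does *not* emulate: non-Brownian size
evolution, state-dependent diversification, polytomies, taxonomic
name conflicts, and sampling bias between molecular and supertree
datasets.  A green recovery test therefore establishes that the pipeline
detects the encoded offsets at multiple scales — not that the method is
robust to these unmodelled features.

# Numerical choices

- `min_n = 3` taxa per habitat per clade before a comparison runs (the
  source does not state its threshold); skipped pairs are logged.
- Significance bands at 0.1 and 0.05; resampling defaults 999 with the
  +1 convention.
- Exact ties in any metric make the comparison a `tie`, excluded from
  majority and alignment denominators and from retention.
- Cholesky with ridge fallback for near-singular covariances;
  eigendecomposition transition matrices clamped and renormalized (rows
  sum to 1 within 1e-9, tested).
- All randomness flows from one root seed through `derive_seeds()`;
  every stage seed stays below 2³¹ and is logged in the run manifest.
- Run configs are JSON (the environment provides no YAML parser).

# Known limitations

- The variance-versus-simulated quantile uses a plug-in Brownian rate
  estimated from the same clade, so its null distribution is only
  approximately uniform (slightly under-dispersed, since the simulations
  track the observed variance).  REML is the default to remove the rate
  bias; the residual under-dispersion is inherent to the plug-in design
  and the tests assert approximate rather than exact uniformity.
- Six-state ARD fits on small clades are weakly identified; multi-start
  optimization mitigates but does not remove this, and fitted rates
  should be read as a smoothing device for mapping rather than as
  precise estimates.
- Majority percentages are descriptive; no multiple-testing correction
  is applied across the comparison grid, mirroring the raw p-band
  reporting the pipeline reproduces.
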