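---
title: "Assessing the phylogenetic predictability of 16S gene copy numbers"
author: "phylogcn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the phylogenetic predictability of 16S gene copy numbers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylogcn)
```

## The problem

Amplicon surveys of the 16S rRNA gene estimate community composition from
read counts, but bacteria and archaea carry between 1 and more than 10
copies of the gene, so read counts are biased estimates of cell counts.
Correction tools predict each taxon's gene copy number (GCN) from its
position in a reference phylogeny — a *hidden state prediction* (HSP)
problem: given a rooted tree with branch lengths in expected nucleotide
substitutions per site and GCNs known for the subset of tips backed by
sequenced genomes, infer the GCNs of all remaining tips.

How well this can work is governed by two quantities:

* the **trait autocorrelation function (ACF)**: the correlation between
  the GCNs of two tips as a function of their patristic distance, which
  measures how quickly the trait decorrelates along the tree, and
* the **nearest-sequenced-taxon distance (NSTD)**: a tip's patristic
  distance to the closest tip with a known GCN (0 for the known tips
  themselves).  The abundance-weighted mean NSTD over a community sample is
  its **NSTI**.

Prediction can only succeed where the NSTD is small relative to the ACF's
decay scale.  This package implements the machinery to quantify that
statement — five HSP algorithms, the ACF/NSTD/NSTI statistics,
NSTD-stratified cross-validation, and community-level agreement analyses —
together with synthetic-data generators, so the whole pipeline runs and is
testable without any reference-database downloads.

## The five reconstruction algorithms

All methods take a rooted tree and a partially known trait table, return a
prediction for every tip, and reproduce known tips exactly (they are exact
interpolators).

**Sankoff maximum parsimony** (`hspSankoff`, codes `mpr_ae`, `mpr_pr`,
`mpr_exp`).  Dynamic programming over states $1..S$ with a symmetric
transition-cost matrix: `all_equal` ($c = 1$ for any change),
`proportional` ($c = |i-j|$) or `exponential` ($c = e^{|i-j|}$, for
changes).  The named schemes are conventional labels; the exact cost
formulas behind them are not standardized across software, and the
instantiations here are the simplest monotone ones.  An up-pass computes
per-node subtree cost vectors (unknown tips contribute a zero vector), a
down-pass adds the cost of the rest of the tree, and an unknown tip's MPR
set is the set of states minimizing its conditional total cost.  The point
prediction is the arithmetic mean of the MPR set (deterministic tie
handling suited to $R^2$ analyses; `tiePolicy = "min"`/`"max"` are
available).  Branch lengths play no role; polytomies are handled natively.

**Mk equal-rates maximum likelihood** (`hspMkEr`, code `mk_er`).  The
equal-rates Mk model puts rate $\lambda/(S-1)$ on every off-diagonal
transition (total leaving rate $\lambda$); along a branch of length
$\ell$, $P(\text{same}) = 1/S + (1 - 1/S)\,e^{-\lambda\ell S/(S-1)}$.
The rate is fitted by maximizing the Felsenstein-pruning likelihood with an
empirical root prior (known-tip state frequencies), optimizing in log-rate
space with `nlminb` over bounds $[10^{-6}, 10^{3}] / \bar\ell$ (where
$\bar\ell$ is the mean branch length), tolerance $10^{-8}$, and 5 restarts:
the first from a moment heuristic that inverts the expected mismatch
fraction of known tip pairs, the rest drawn uniformly in log-rate space.
Marginal posterior state probabilities at every node come from an
outside-likelihood down-pass, algebraically the same as rerooting the tree
at each node; the prediction is the posterior mean $\sum_s s\,P(s)$.  If
all known tips share one state the rate MLE sits at the lower bound; the
fit is flagged and predictions equal that state.

**Phylogenetic independent contrasts** (`hspPic`, code `pic`).  An upward
pass restricted to subtrees containing data: a node whose children carry
estimates $x_c$ with effective lengths $\ell_c + e_c$ receives the
inverse-length-weighted mean and the harmonic effective length
$e = 1/\sum_c w_c$.  Unknown tips read the estimate of their nearest
ancestor that has one.

**Weighted squared-change parsimony** (`hspWscp`, code `wscp`).  The
unique minimizer of $\sum_{\text{edges}} (x_p - x_c)^2/\ell$ with known
tips fixed — a tree-structured quadratic solved exactly by one upward
elimination and one downward back-substitution pass.  Unknown tips take
their parent's optimum (their own edge term is then zero).

**Subtree averaging** (`hspSubtreeAvg`, code `sa`).  Every node with known
descendants gets their arithmetic mean; unknown tips read their nearest
such ancestor.

### Polytomies and zero-length branches

Sankoff, Mk and subtree averaging are defined on arbitrary rooted trees.
PIC and WSCP are usually presented on bifurcating trees; a common recipe
resolves polytomies into zero-length ladders first.  We deliberately do
*not* do that: for both methods the multi-child combine used here is the
exact zero-length-ladder limit, and — unlike an explicit ladder — it is
independent of child order.  (A ladder also changes *which* ancestor is
nearest for an unknown tip hanging off a polytomy: in a four-tip star with
known values 1, 2, 3, a right ladder would predict the unknown tip as 3,
the last sibling, while the direct combine predicts 2, the root estimate.
Order-dependence of that kind would break the package's invariance
contract that relabeling tips and permuting child order never changes a
prediction.)  Wherever an algorithm divides by a branch length, zero or
missing lengths are floored at `branchLengthEpsilon()` ($10^{-8}$
substitutions/site); newick branch lengths that are absent are read as 0.

## The statistics

`coefficientOfDetermination(reference, predicted)` is
$1 - \sum(y - \hat y)^2 / \sum(y - \bar y)^2$ — the fraction of variance in
the reference explained by the predictions.  It is asymmetric and can be
negative (worse than predicting the mean); it is *not* the squared Pearson
correlation, which is provided separately as `pearsonR2` and used for the
NSTI–$R^2$ trend.  A zero-variance reference is an error at top level and a
flagged-`NA` in binned contexts (`binR2ByNstd`), where degenerate bins must
not abort a scan over many bins.

`computeNstd` finds every tip's distance to the nearest known tip by a
two-pass message-passing sweep (rootward minima within each subtree, then
leafward minima from outside), linear in tree size and exact.
`computeNsti` is the read-weighted mean NSTD of one sample.  When two
prediction sets carry different calibration sets, an OTU's NSTD for their
comparison is the arithmetic average of the two.

`relativeDeviation(A, B)` is $|A-B| / ((A+B)/2)$: 0 iff equal, bounded by
2.

### The ACF estimator and what it can and cannot see

`traitAcf` samples `npairs` ordered tip pairs uniformly with replacement
among the known tips, bins them into `nbins` equal-width patristic-distance
bins spanning $[0, \max d]$, and computes the Pearson correlation within
each bin over the symmetrized pair set.  Defaults are $10^6$ pairs and 25
bins — chosen so that at this package's default tree sizes every bin keeps
on the order of $10^3$ sampled pairs.  Equal-width binning, bin-local
means, and sampling with replacement are implementation choices; they are
stated here because other conventions exist.

One property deserves emphasis.  Under the equal-rates Mk model the
*ensemble* tip-pair correlation at distance $d$ is exactly
$e^{-\lambda d S/(S-1)}$ (for $S = 2$, $e^{-2qd}$ with per-direction rate
$q$), and the package verifies its simulator against that closed form
directly, by correlating many independent trait draws across a fixed tree.
The *empirical* ACF of a single trait realization is a different object:
within a bin, the Pearson computation centers values on the bin's own mean,
and when a bin's pair mass is dominated by a few deep clades that mean
absorbs the between-clade covariance that carries the signal.  On a
2000-tip tree, bins beyond roughly 0.3 substitutions/site are dominated by
a handful of deep splits, so their estimates shrink toward zero with $O(1)$
realization noise — for the deepest bin, whose pairs all straddle the root
split, the bin-centered covariance is in fact non-positive by construction.
This is not a defect of the implementation but of any single-realization
estimator at this scale; it is also why empirical trait ACFs plateau at
zero beyond the distance where many independent clades exist.  Users should
read the ACF quantitatively only in the shallow regime (distances where the
number of contributing clades is large) and qualitatively beyond it.

## The synthetic-data generators

`simConfig()` bundles the generator settings; the defaults define the
fixture used throughout the package's tests ("benchmark-small"):

* **Tree**: pure-birth, $N = 2000$ tips (`ape::rphylo`, conditioned on the
  tip count), branch lengths rescaled so the root-to-tip depth is 0.5
  substitutions/site — patristic distances then span roughly 0–1, the range
  over which 16S-based trees are typically read.
* **Trait**: equal-rates Mk on states 1..15 (GCNs observed in genomes
  rarely exceed 15), root drawn from the stationary (uniform) distribution
  so that tip-pair correlation depends only on patristic distance.  The
  rate is calibrated once, via the closed form (`calibrateAcfRate`), so the
  ACF is 0.5 at distance 0.15 — the half-correlation scale reported for
  real 16S GCN data.  A bounded ±1 random-walk model
  (`simulateTraitWalk`) is available as an alternative with more
  near-neighbor structure; events occur at rate $r$ and proposals leaving
  $[1, S]$ are rejected, which makes the uniform distribution stationary
  (and means the realized switching rate at $S = 2$ is $r/2$).  Both trait
  models are this package's constructs: no generative model of GCN
  evolution is established in the literature.
* **Masking**: whole clades are unlabeled (`clade_drop`) until 50% of tips
  remain known, emulating the clustered incompleteness of genome databases
  and producing a broad NSTD spectrum with long-NSTD regions; independent
  per-tip masking (`random`) is available for contrast.
* **Communities**: 50 samples; per sample each tip is present with
  probability 0.15, present tips get log-normal weights
  ($\mu = 0, \sigma = 2$), and 2000 reads are drawn multinomially.  The
  wide $\sigma$ reflects the heavy-tailed OTU abundance distributions of
  real surveys; the presence fraction gives a few hundred OTUs per sample,
  the scale seen in environmental data.

Every generator output is a pure function of the configuration seed; seeds
for internal stages are derived sub-streams.

What the generators do *not* emulate: 16S sequence evolution, primer or
PCR bias, OTU clustering artifacts, chimeras, or correlation between
abundance and phylogeny.  Passing tests on these fixtures therefore show
that the algorithms and statistics behave correctly on trees and traits
with the right correlation structure — not that any particular accuracy
level will be attained on real surveys, where tree error and trait-model
misspecification add further noise.

## Cross-validation and community comparisons

`crossvalR2Curve` holds out a random 2% of the known tips as a test set,
and for each NSTD cutoff removes from the training data every known tip
closer than the cutoff to *any* test tip (set-distance reading of
"distance to the test set").  Test sets are drawn independently per repeat
(3 by default) and shared across cutoffs within a repeat, which keeps
cutoff curves comparable; per-cutoff $R^2$ values are averaged over
repeats.  Cutoffs whose training set empties, or whose test truth is
constant, are flagged `NA` and skipped rather than failing — large cutoff
grids routinely empty the training set.  Held-out sets are recorded in the
result (`testSets`) so the no-leakage contract can be audited.

A caveat for desk-scale use: at cutoff 0 the attainable $R^2$ is limited by
the tree's nearest-neighbor spacing.  On the 2000-tip default fixture the
median nearest-known-neighbor distance is about 0.05 substitutions/site,
where the calibrated trait correlation is only ~0.8, capping even a perfect
nearest-neighbor predictor near $R^2 \approx 0.5$.  Reference-scale trees
(hundreds of thousands of tips) put near-duplicates next to most test taxa
and support the much higher low-NSTD accuracies reported on real data; the
fixture reproduces the *decay* of accuracy with NSTD, not its absolute
level at NSTD $\approx 0$.

`comparePredictionSets` scores the per-sample agreement of two prediction
sets ($R^2$ of the first explained by the second, over OTUs with reads and
both predictions) together with the sample's NSTI; samples with fewer than
two eligible OTUs or zero variance are flagged and excluded.
`nstiR2Trend` then computes the Pearson correlation between NSTI and
$R^2$ within a sample group and a permutation P value,
$P = (b+1)/(m+1)$ over $m = 1000$ shuffles of the $R^2$ vector — the
add-one form avoids reporting zero P values.

`correctAbundances` divides read counts by predicted GCNs and optionally
renormalizes each sample to proportions (cell-abundance estimates).

## Numerical and design notes

* Branch-length floor $10^{-8}$ substitutions/site wherever division
  occurs; how zero-length edges "should" be treated is genuinely open, and
  this constant is documented rather than hidden.
* Sankoff MPR sets use a relative tolerance of $10^{-9}$ on the minimal
  cost, so exponential-cost ties are detected stably.
* Mk likelihoods are computed with per-node rescaling (log-scale
  accumulators), and outside messages recompute exclusive products directly
  wherever a message underflows.
* The empirical root prior can contain zeros (states unseen among known
  tips); the likelihood handles them naturally.
* Group labels on samples are free strings; "animal"/"non-animal" is a
  fixture convention, not baked into any function.
* Problem sizes in the test suite are chosen to keep the full run in
  minutes on one core: enumeration oracles use trees of 3–8 tips and up to
  4 states (where exhaustive enumeration over all ancestral assignments is
  exact and fast), distance and quadratic-program oracles use 10–50-tip
  trees, and the simulation-scale analyses use the 2000-tip fixture.

## Limitations

* Only the equal-rates Mk model is implemented; no model selection, no
  rate heterogeneity, no stochastic character mapping.
* The ACF estimator's deep-bin behavior is realization-limited on small
  trees (discussed above).
* The pipeline evaluates *predictability given a correct tree*; branch
  length and topology error in real reference trees will degrade all
  methods in ways these simulations do not measure.
* GCN-corrected abundance tables propagate prediction error
  multiplicatively; the correction step itself is exact arithmetic.

## A minimal session

```{r example, eval = FALSE}
cfg <- simConfig(seed = 42)          # the benchmark-small regime
d <- simulateBenchmark(cfg)

acf <- traitAcf(d$tree, d$traits, npairs = 1e6, nbins = 25, seed = 1)
head(acfBins(acf))

nstd <- computeNstd(d$tree, knownTips(d$masked))

cv <- crossvalR2Curve(d$tree, d$masked, "mpr_exp",
                      cutoffs = seq(0, 0.4, by = 0.05), seed = 1)
cvMeanR2(cv)

pa <- hspPredict(d$tree, d$masked, "mpr_exp")
pb <- hspPredict(d$tree, d$masked, "pic")
cmp <- comparePredictionSets(pa, pb, d$abundances, nstd)
nstiR2Trend(cmp, seed = 1)
```
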