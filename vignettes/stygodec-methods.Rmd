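---
title: "Models and methods in stygodec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in stygodec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stygodec)
```

stygodec implements the inference stack used to study how a radiation of
diving beetles spread across the Australasian region and repeatedly
moved underground into isolated calcrete aquifers: ancestral range
estimation under the dispersal–extinction–cladogenesis (DEC) family
with founder-event speciation and time-stratified dispersal
multipliers; AICc-based comparison of biogeographic hypotheses;
constrained all-rates-different (ARD) Markov models for habitat and
altitude evolution with stochastic character mapping and
colonization counting; and a scanner for pseudogenizing lesions
(frameshifts and premature stop codons) in vision-gene alignments.
This vignette records the models, the tunable parameters, and the
design decisions a maintainer would want explained.

## The DEC-family range model

A geographic range is a nonempty subset of an area universe (by default
five areas, A–E: East Asia, Australia, New Guinea, the Pacific
archipelagos, and New Zealand). The state space contains the null range
`0` plus every subset of at most `max_range_size` areas, ordered by
size then lexicographically (`range_states()`).

**Anagenesis.** Along a branch, a range `R` gains an area `a` at rate
`d * sum_{i in R} m[i, a]`, where `m` is the current stratum's
dispersal multiplier matrix, and loses any held area at rate `e`
(singletons decay to the null range, which is absorbing and carries no
root prior and no observations). Both rates are per Ma.

**The `w` exponent** raises multipliers to a power, softening
(`w < 1`) or sharpening (`w > 1`) the effect of the multiplier matrix.
It is applied only to multipliers strictly inside (0, 1): an exact 0
encodes an area that has not yet emerged and must stay forbidden for
every `w` (otherwise `0^w -> 1` as `w -> 0` would silently reopen a
closed area), and an exact 1 is neutral by definition.

**Cladogenesis.** At a node an ancestor range is partitioned between
the two daughters. Base event weights are equal (`y = s = v = 1`):
sympatry for single-area ancestors; subset sympatry and
single-area-daughter vicariance for widespread ancestors (DEC);
all vicariant bipartitions and no subset sympatry (DIVALIKE); an exact
copy to both daughters (BAYAREALIKE). Founder events add a single-area
daughter outside the ancestor range with weight `j`, split evenly
between the two daughter orders so the likelihood is left/right
symmetric, and scaled by default by the mean dispersal multiplier from
the ancestor's areas into the target (`scale_jump = FALSE` turns this
off). Weights are normalized per ancestor state; with unit base
weights, useful `j` values lie below 3. `j = 0` recovers the
no-founder model exactly.

**Root handling.** By default no cladogenetic event is placed at the
root: the two basal lineages inherit the root state, and the
likelihood is averaged over a flat prior on nonempty ranges. This is
switchable (`root_clado = TRUE`). The choice matters: with all rates
zero and two tips in different single areas the likelihood is
correctly impossible under the default, whereas a root vicariance
event would make it positive.

**Time stratification.** Branches are sliced at stratum boundaries
(`slice_branch_by_strata()`), each segment propagated with its
stratum's rate matrix, oldest first. A stratum in which an area is
unavailable simply has zero multipliers into that area. With identical
matrices in every stratum the stratified likelihood equals the
unstratified one (a test asserts this).

**Numerics.** Likelihoods are computed by Felsenstein pruning over the
range states with per-node rescaling. Branch propagation is
matrix-free: `exp(Qt) x` is evaluated through an eigendecomposition of
each stratum's rate matrix, with a dense scaling-and-squaring Padé
exponential as the fallback when the eigenvector basis is
ill-conditioned (this happens systematically when `e` sits at its
lower bound, where Q is nearly defective). The two routes agree with
`Matrix::expm` to 1e-11 in the tests. At most 32 states arise
(5 areas), so no sparse machinery is used.

## Model fitting and hypothesis comparison

`fit_dec()` maximizes the likelihood over `d`, `e` (log scale) and
optionally `j` and `w`, by bounded quasi-Newton (L-BFGS-B) from a
fixed start grid (`d, e` in {0.01, 0.1, 1}; `j` in {0, 0.5}; `w` in
{0.5, 1}). All grid points are screened and the best is refined
(`n_refine` raises this), so fits are deterministic with no RNG.
Bounds: `d, e` in [1e-12, 5], `j` in [0, 3), `w` in [0, 10].
`extra_starts` lets a caller seed the optimization, which
`hypothesis_suite()` uses to start each free-`j` fit at the nested
fixed-`j` optimum — guaranteeing the free-`j` likelihood never falls
below the nested one.

AICc uses `n` = number of tips. This is a convention, not a theorem;
it shifts every model's score by the same pattern and is stated
prominently because published tables may have used `n` or `n - 1`.
Ties in "best model" break toward fewer parameters, then the family
order DEC < DIVALIKE < BAYAREALIKE.

`hypothesis_suite()` mirrors the usual presentation of such analyses:
one row per hypothesis (unguided M0-style, or custom stratified
multiplier matrices, optionally with free `w`), best family by AICc,
delta AICc against the overall best, and a root-areas summary — the
smallest set of root states whose cumulative marginal probability
reaches 0.95, reported as the union of their areas.

## Habitat and altitude models

The habitat space has one epigean state plus interstitial and
subterranean states per palaeovalley. The transition mask forbids
subterranean dispersal between palaeovalleys, interstitial-to-
subterranean moves across palaeovalleys, and (by default) any exit
from a subterranean state, treating groundwater specialization —
eye, wing and pigment loss — as irreversible; a flag
(`allow_subterranean_exit`) relaxes this for sensitivity analysis.
Direct epigean-to-subterranean colonization is allowed by default
(`direct_colonization = FALSE` forces the interstitial route).

Rates are tied by class pair (epigean→interstitial,
interstitial→epigean, epigean→subterranean per valley,
interstitial→subterranean within valley): with 10 palaeovalleys a
fully free masked ARD would carry ~40 rates, far beyond what ~95 tips
can identify, and the class-tied model is what a custom-matrix
ARD workflow expresses in practice. The rate-index matrix makes the
tying explicit (0 = forbidden, shared index = shared rate), and
`mk_Q()` assembles the rate matrix so masked entries are exactly zero.

The altitude model uses five maximum-altitude bands (≤1000 m to
>4000 m) under an unconstrained 20-rate ARD index, with a root prior
restricted to the two bands below 2000 m when reproducing the
root-state constraint of an epigean, low-altitude ancestor.

Tip ambiguity (a species spanning two bands) is coded `"band1|band2"`
with equal conditional likelihood; coding by maximum altitude is the
default in the simulators and examples.

## Stochastic character mapping and colonization counts

`simmap_sample()` draws complete histories conditional on the tip
data: node states from their joint conditional distributions (root
first, then each child given its parent), then each branch path
exactly from the endpoint-conditioned chain by uniformization —
the number of virtual jumps is drawn from its conditional
distribution, jump states from the forward–backward factorization, and
self-jumps collapsed. This is exact, so histories never contain masked
transitions, and no rejection budget is needed; a branch whose
endpoint pair has zero probability raises an error naming the branch.
The default is 1000 maps, the conventional number for such summaries.

`count_colonizations()` counts, per history, transitions into the
subterranean class (from any other class), transitions into the
interstitial class, subterranean speciation events (an internal node
whose own state and both daughters' initial branch states are
subterranean), and the within-palaeovalley subset (all three share one
valley id). Summaries are medians with 2.5/97.5 percentiles across
histories. Note that under the default irreversible mask the Mk model
passes the node state unchanged to both daughters, so every
subterranean speciation event is automatically within-palaeovalley;
the two counts can separate only under relaxed masks. Empirical
reports that distinguish them are implicitly counting sister lineages
rather than node-adjacent states.

## Pseudogene scanning

A coding alignment designates a reference open reading frame; codon
boundaries for every sequence are projected from the reference's
coordinates, so insertions relative to the reference never shift
downstream codon indices — lesion identity must be alignment-robust
for "shared lesion" comparisons between sister species to be
meaningful. Premature stops are stop codons (standard nuclear code,
{TAA, TAG, TGA}, configurable) strictly before the reference's
terminal codon; codons containing gaps or N are never called; only the
terminal codon is exempt (no percent-of-tail heuristic — the simplest
defensible rule). Frameshifts are maximal indel runs whose length is
not a multiple of three, called once at the run's first column.
Stops downstream of a frameshift in the same sequence are reported but
flagged `post_frameshift`, so both the inclusive and the conservative
view are derivable from one call table. Strand is not normalized here:
sequences must arrive oriented, and the alphabet/ORF validation
rejects anything else.

## Synthetic data

The simulators are first-class, tested code; they emit the same file
formats the fitting functions read, plus a truth record sufficient to
score any downstream inference (true node states, per-branch event
lists with ages, seeds).

- `simulate_bd_tree()`: forward birth–death from two crown lineages,
  stopping when the next birth would exceed the target tip count and
  rejecting attempts that die out. Under pure birth the expected crown
  age is `sum_{k=2}^{n} 1/(k*lambda)`, which the tests use as a
  numeric oracle. Rejection conditioning slightly biases tree shape
  relative to proper conditioned samplers; at the package's scales
  this is irrelevant, and the simplicity is worth it.
- `simulate_dec_tips()`: exact Gillespie anagenesis per stratum plus
  cladogenetic draws at nodes. Lineages absorbed into the null range
  are retained and flagged rather than silently redrawn (tests need
  the degenerate case); `redraw_null = TRUE` resamples whole datasets
  for analyses that require observable tips.
- `simulate_mk_tips()`: Gillespie under any masked rate matrix.
- `simulate_coding_alignment()`: a clean reference ORF with planned
  lesions injected (stops by codon replacement, frameshifts by 1–2 nt
  deletions); nothing else differs, so detector output on a fixture
  equals the plan exactly. Lesions are injected, not evolved — the
  fixture tests the scanner, not a substitution model.
- `study_mimic_dataset()`: the study-scale preset — 95 tips, crown
  17 Ma, five areas with proximity-graded multipliers (0.1–1) and
  New Guinea closed before 23 Ma, DEC+J truth (d = 0.03, e = 0.01,
  j = 0.3), ten palaeovalleys with rare irreversible colonization
  (epigean→subterranean 0.012 per valley per Ma, interstitial rates an
  order of magnitude smaller than the epigean↔interstitial churn), and
  seven gene alignments carrying shared lesions in four designated
  sister pairs. The habitat rates were chosen once so that groundwater
  colonization is rare per lineage per Ma yet accumulates to double
  digits over the whole tree, the regime the constrained model is
  meant for.

What passing tests on these simulations do **not** show: robustness to
tree misspecification (the tree is taken as known), to sampling biases
in which species were sequenced, or to model misfit in real data
(e.g., rate heterogeneity through time, which the homogeneous Mk and
DEC processes lack).

## Verification strategy and known limitations

Likelihoods are verified against brute-force enumeration over all
internal-node assignments (with `Matrix::expm` transition matrices and
an independently written cladogenesis enumerator) on trees of up to 4
tips — the engine and the oracle share no code. The simmap sampler is
checked against the analytic uniformization series for the expected
number of changes on an endpoint-conditioned branch, and the ARD
likelihood against phytools' independent implementation.

Recovery experiments use tree depths chosen a priori so that expected
event counts per root-to-tip path are of order one (depth 10 Ma for
the DEC experiment at d = 0.02, depth 30 Ma for the ARD experiment at
q = 0.10/0.05) — the regime in which rates are identifiable at all.

One honest negative result: under the DEC family the maximum-
likelihood estimate of the range-loss rate `e` collapses toward zero
on forward-simulated data even at generous tree depths, because
cladogenetic subset-sympatry and vicariance supply range contraction
"for free" and absorb the anagenetic loss signal. The dispersal rate
`d` and the founder weight `j` recover well (and `e` recovers cleanly
under BAYAREALIKE, whose cladogenesis is a pure copy — isolating the
effect in the cladogenetic model, not the engine). Joint `d`-and-`e`
recovery therefore fails the strict 90% factor-of-two bar in the
acceptance suite; the corresponding test is left failing rather than
weakened, as the collapse is a property of the model family that
users of DEC should know about.

Other limitations: no more than ~8 areas (dense matrices throughout);
no hidden-rate or threshold trait models; no posterior-sample
handling (point-estimate trees only); BAYAREALIKE is fitted by ML
rather than its original Bayesian sampler; alignment computation and
homology search are out of scope for the pseudogene scanner.

## Problem sizes in the shipped checks

The test suite and the acceptance script run entirely on simulated
data: oracle comparisons at 2–4 tips, recovery at 200–300 tips with
25–50 replicates, suite power at 150 tips with 15–30 replicates, a
million branch segments for the constraint-integrity check, and 1000
stochastic maps at the 95-tip study scale.
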