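---
title: "Methods: the SA-fusion null model and the clade-level pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the SA-fusion null model and the clade-level pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyofuse)
```

## The null model

The package starts from a counting argument: if a fusion occurs and
every chromosome is equally likely to fuse with every non-homologous
chromosome, the chance that the fused pair is two autosomes, two sex
chromosomes, or one of each is fixed by the karyotype alone. Fusions
between homologous chromosomes — including X with Y — are excluded,
since they would produce unbalanced gametes.

For a male-heterogametic karyotype with `Da` diploid autosomes, `Xs` X
and `Y` Y chromosomes in males, the male and female diploid numbers are
`Ds = Da + Xs + Y` and `Dd = Da + 2 Xs`. With a proportion `mu` of
fusions arising in females, the fusion-class probabilities are the
mixtures implemented in `p_aa()`, `p_ss()` and `p_sa()` (see the README
for the displayed forms); `p_sa()` is always computed as the complement
`1 - p_aa - p_ss`, so the triple sums to one by construction.

Three structural facts are worth knowing because the tests lean on them:

* each probability is affine in `mu`, so the value at `mu = 0.5` is the
  mean of the two single-sex branches;
* for a plain XY (or ZW) system the whole expression collapses to
  `4 / (Da + 2)`;
* the single-sex AA and SA fractions equal literal counts of ordered
  non-homologous chromosome pairs over the `D(D - 2)` denominator
  convention, which the test suite verifies by enumerating labelled
  chromosomes.

ZW systems are handled by exchanging the sex labels (the `mu` slot then
holds the proportion of fusions arising in males, the homogametic sex),
and UV systems by forcing `mu = 0` — there is no homogametic diploid
sex — with both sex chromosome slots carrying the V count. Unequal U
and V counts are rejected as unsupported rather than approximated.

One denominator deserves a note: the male multi-X term uses
`Ds (Ds + Xs - 1)`, which does not arise from the naive ordered-pair
count that explains the other denominators. It is implemented exactly
as stated; the enumeration-based tests therefore restrict themselves to
the single-X, single-Y configurations where the pair-counting argument
is unambiguous.

### Parameters and defaults

* `mu` (dimensionless, in [0, 1]) — proportion of fusions arising in
  the homogametic sex. Default **0.5** (equal contributions): under
  this value the 25% thresholds quoted below hold exactly, and absent
  any information on sex-biased mutation or drive it is the neutral
  choice. It is exposed everywhere so sensitivity can be probed.
* `autosomes` must be even: diploid autosomes come in homologous pairs,
  and an odd count is a data error we refuse to paper over.
* Probabilities are clamped to [0, 1] only within ~64 ulp; a larger
  excursion raises an internal-consistency error instead of being
  silently masked.

Two reference points: a plain XY system stays at or above 25%
SA-fusions until `Da = 16` (`4/16 = 0.25` at `Da = 14`), and an XXY
system until `Da` exceeds 22 (25.7% at 22, 23.9% at 24).

## The exact test

`sa_fusion_test()` treats the observed fusion counts as one multinomial
draw and computes the exact upper-tail probability of the SA count.
Because the AA/SS split of the remainder marginalizes out of that tail,
the tail equals a binomial tail in `p_sa`; the implementation computes
*both* the literal double sum (in log space, so totals in the thousands
cannot underflow even at p-values far below 1e-5) and the marginal
binomial form, and refuses to return if they disagree beyond 12
significant digits. The default direction is the upper tail (an excess
of SA-fusions); `tail = "lower"` gives the deficit direction, which is
the interesting one for clades that avoid SA-fusions.

For the spider-style worked example (X1X2O, 26 autosomes, 8 SA of 10
fusions) the package reports the tail under `mu = 0` (all fusions
paternal), the configuration under which the probability is below
1e-5; under `mu = 0.5` it is about 6e-5. The choice matters and both
values are one flag apart, which is why `mu` is a visible argument of
the test rather than a buried constant.

## The karyotype Markov model

For clades whose karyotype evolved along a phylogeny, a per-karyotype
null is not enough: the expected SA-fusion proportion must be averaged
over the karyotypes the clade actually passed through. The model state
is (male diploid number `i`, sex system XY or neoXY) with four
transitions: AA-fusion (`delta`, `i -> i - 2`), autosome fission
(`gamma`, `i -> i + 2`), SA-fusion (`sigma`, `i -> i - 2` and the
system becomes neoXY), and decay of a neoXY back to a plain XY (`rho`,
`i` unchanged). Design choices that were genuinely open:

* **Diploid counts move in twos.** `i` is the male diploid number; a
  fixed fusion merges two chromosome pairs and a fission splits one, so
  all transitions step `i` by 2 and the state space contains only even
  `i`. This matches fly-style diploid numbers (6–12, all even).
* **No SA-fusion from a neoXY state.** The model has exactly the four
  transitions above; a neoXY lineage must first revert via `rho` before
  another SA-fusion can occur. The alternative (chained SA-fusions)
  would add a fifth transition the model does not contain.
* **Boundaries reflect by omission.** Transitions that would leave the
  configured bounds (`karyo_states(min_i, max_i)`, default 6–12) simply
  get rate zero. No absorbing states, no renormalization.
* **Root condition.** Default is a fixed root at (12, XY), the ancestral
  condition appropriate for fly-style datasets; a flat prior or any
  explicit prior vector is accepted.
* **Null weighting of states.** When the closed form is evaluated for a
  state, (i, XY) and (i, neoXY) both map to the karyotype
  `Da = i - 2, Xs = 1, Y = 1`: the (possibly fused) sex chromosome pair
  counts as the sex chromosomes, and the remaining `i - 2` chromosomes
  as autosomes. A separate neoXY formula is not attempted; at equal `i`
  the two systems get the same null, which also makes the expectation
  invariant to XY/neoXY relabelling — an invariant the tests assert.

### Likelihood, fitting, and numerical choices

The tip-state likelihood is the standard post-order pruning sum with
per-node rescaling (so ~100-tip trees with small transition
probabilities do not underflow). Transition matrices `expm(Q t)` come
from an eigendecomposition of `Q` done once per likelihood evaluation,
with an unconditionally stable scaling-and-squaring Taylor fallback
whenever the eigenroute is defective or degrades at a particular `t`
(rows are required to sum to 1 within 1e-6 before rounding-level
cleanup, else the fallback runs; after cleanup rows are renormalized
exactly). `karyo_fit()` maximizes over log rates with L-BFGS-B inside
[1e-8, 100] events per unit branch length, from a fixed default start
plus random multistarts (default 3, seeded); it errors if no start
improves on its initial point. `include_rho = FALSE` pins `rho` at
zero, mirroring the usual sensitivity analysis about undetected neoXY
systems.

### Stochastic maps

`karyo_simmap()` draws histories conditional on the tip data in two
stages: node states are sampled root-to-tips from the pruning
conditionals, then each branch path is drawn conditional on its
endpoint states by uniformization — the chain is embedded in a Poisson
process at the dominating rate, the number of embedded jumps is sampled
from its endpoint-conditioned law, jump times are uniform order
statistics, and the jump chain is sampled by forward-backward weights;
virtual self-jumps are merged away. A branch with zero dominating rate
is necessarily constant and is emitted directly. Every draw flows from
a single top-level seed through named substreams (tree, history, maps,
optimizer starts), so any run is reproducible bit for bit.

`summarize_map()` reduces a map to the proportion of total tree length
per state plus event counts per class; `clade_report()` turns a set of
maps into the mean and equal-tail quantile interval (default 2.5%/97.5%;
the interval construction is a package choice, as no canonical
definition exists for map ensembles) of

* the **expected** SA proportion: occupancy-weighted closed-form
  `p_sa` over states, and
* the **observed** SA proportion: SA events / (SA + AA events). The
  denominator contains fusions only — the model has no SS transition,
  and fissions and neoXY decays are not fusions. Maps without any
  fusion event have no defined proportion; they are excluded from the
  observed distribution and counted in the report rather than being
  imputed.

The report's `overlap` flag is a plain interval-intersection test, the
coarse but transparent criterion for "the clade has credibly
fewer/more SA-fusions than chance".

## The synthetic-data generator

`synthesize()` builds a pure-birth (Yule) tree — only shape and total
branch length matter downstream, so the parameter-light pure-birth
process is preferred over birth–death — rescaled to unit depth, and
runs the karyotype chain forward from the root. The defaults (120 tips,
bounds 6–12, root (12, XY), rates `delta = 0.5, gamma = 0.5,
sigma = 0.4, rho = 1` per unit tree depth) emulate the geometry of a
fly-style comparative dataset: around a hundred species, even diploid
numbers within a narrow band, a minority of tips carrying a neoXY.
The rate values were chosen once so that a 120-tip history realizes on
the order of tens of events of the common classes (enough for
maximum-likelihood recovery to be meaningful) while keeping a clear
majority of plain-XY tips; they are defaults of the generator, not
estimates of anything.

What the generator does *not* emulate: real clade topologies or dated
branch lengths, extinction, unequal sampling, karyotype measurement
error, polyploidy, or chromosome numbers outside the configured band.
Tests passing on these synthetic data therefore validate the
*machinery* (likelihood, samplers, estimators, report logic), not any
empirical claim about a particular clade.

## Validation design and problem sizes

The suite validates each layer against an independent route: closed
forms against hand arithmetic and literal pair enumeration; the exact
test against `stats::dmultinom` sums and 1e6 Monte-Carlo draws; matrix
exponentials against `Matrix::expm`; pruning and node marginals against
exhaustive enumeration on trees small enough to enumerate (up to 4
tips, 8^3 internal assignments); conditional-map occupancy against
Simpson-integrated pointwise posterior marginals (5000 maps); the
clade report against a calibration construction — forward simulations
on a 50-tip tree in which the SA share of the fusion rate is matched to
the occupancy-weighted null (with fast neoXY decay, so the share is
state-independent), making observed minus expected centred at zero over
500 replicates — and against a separation construction (histories
generated with `sigma = 0`, 80 tips) where the fitted pipeline must
report zero interval overlap with the observed side below the expected.
Rate recovery is checked at the 120-tip design scale with a factor-of-2
criterion for rates whose realized event count is at least 10; rarer
transitions are not expected to be recoverable from a single history.

## Known limitations

* The multi-X male denominator is taken as given (see above); UV
  support requires equal U and V counts.
* The Markov model tracks one binary sex-system flag; sex-chromosome
  turnover, polyploidy and fissions of the neo-sex chromosome are out
  of scope.
* The observed/expected comparison is a descriptive interval-overlap
  check across maps, not a formal hypothesis test with error control.
* `clade_report()` inherits all conditioning from the fitted rates
  (empirical-Bayes style); rate uncertainty is not propagated into the
  map ensemble.
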