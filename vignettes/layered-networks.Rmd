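---
title: "Layered egocentric networks: models, methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layered egocentric networks: models, methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dunbargraph)
```

## The layered model

An egocentric network is modelled as a nested sequence of layers with
cumulative sizes $n_1 < n_2 < \dots$ (canonically 5, 15, 50, 150, 500,
1500, 5000).  The *annulus* of layer $i$ is its exclusive membership,
$a_i = n_i - n_{i-1}$, and the *scaling ratio* is $n_{i+1}/n_i$,
empirically close to 3 across personal networks, human community
structure and mammalian multilevel societies.  `layer_scheme()` enforces
the structural invariants (positive, strictly increasing), and
`annuli()`, `scaling_ratios()` and `mean_scaling_ratio()` compute the
descriptive statistics.  The bundled tables
(`dunbar_layer_datasets()`, `dunbar_community_sizes()`) hold published
layer sizes and community sizes so the headline statistics can be
recomputed rather than quoted.

Grouping-size entries published as ranges ("100–200") are resolved by a
`range_policy`; the default is the midpoint, which reproduces the
published community average (mean 158.0, sample s.d. 28.7 over the 12
bundled rows) exactly.  The low/high policies are exposed because
published tables rarely state their own convention.  The s.d. is the
sample ($n-1$) version.  The corresponding *egocentric* network table in
the same literature prints an average (153.6 ± 46.0) that is not
recoverable from its own printed rows under any of the three policies;
that table is therefore bundled only as layer data and not summarised.

## Social effort

Observed interaction diaries put about 40% of all social effort on the
innermost 5 alters and 20% on the next 10 — 60% of social time on just
15 people.  `default_effort_profile()` pins these two shares and
distributes the remaining 40% over the outer annuli with geometrically
decaying *per-capita* effort; the decay factor is the single free
parameter and is solved by `uniroot()` so the shares sum to 1.  For the
canonical 7-layer scheme the solved factor is ≈ 0.218 per layer
(≈ 4.6-fold less time per member with each step outward), consistent
with the steep outward fall-off of observed contact frequency.  The
outer-layer split is a calibration, not an observation: only the 40/20
anchors are empirical, and `cumulative_effort(profile, 2)` returns
0.60 regardless of how the tail is distributed.

## Layer detection

Contact rates within a layer are similar and drop sharply between
layers, so layer detection is 1-D clustering of rates.  Two choices
define the method:

* **Partitioning.**  `optimal_breaks()` computes the exact optimum of
  the contiguous-partition problem (Jenks natural breaks) by dynamic
  programming over sorted values: $O(k n^2)$ with prefix sums,
  mean-centred first to avoid catastrophic cancellation.  Because an
  optimal 1-D $k$-means solution is always contiguous in sorted order,
  the same routine is the exact 1-D $k$-means optimum — one core for
  both algorithm labels used across the source literature.  Ties are
  stable-sorted and identical values are co-clustered whenever the
  optimum permits.
* **Layer-count selection.**  `select_num_layers()` maximises the mean
  silhouette width of the optimal partition over `k_range` (default
  2–8), breaking ties toward fewer layers.  Rates are multiplicative
  quantities, so selection and partitioning default to the log10 scale
  (`transform = "identity"` is available; the source studies do not
  state which scale they clustered on).  Silhouette is undefined at
  $k = 1$; all-identical input returns a single layer with a warning.
  The silhouette implementation is $O(n^2)$ and is cross-checked in the
  test suite against `cluster::silhouette()`.

`detect_layers()` chains the two, orders classes from the
highest-rate (innermost) layer outward, reports cumulative layer sizes
and their mean scaling ratio, and back-transforms breaks to the rate
scale.

### Identifiability

Recovery of a planted layer structure depends on the ratio between the
log-scale layer separation and the within-layer noise.  With the
default generator (rate ratio 3 per layer, i.e. separation
$\log_{10} 3 \approx 0.477$), planted four-layer structure is recovered
in the majority of runs at `log10_noise_sd = 0.1` (≈ 4.8σ separation);
the regular test suite demonstrates this regime, asserting the modal
selected $k$ and median per-layer size error ≤ 20% over 30 seeds.  At
`log10_noise_sd = 0.3` the separation is only ≈ 1.6σ: about 13% of
alters in adjacent layers are rate-*misordered*, and no selection
statistic we evaluated (pooled or macro-averaged silhouette,
classification BIC, or an equal-variance Gaussian-mixture BIC fit)
prefers four components over two on such data — the fine structure is
genuinely blurred away, and silhouette then favours the single deepest
split.  This is a property of the data-generating regime, not of the
optimiser, which remains exactly optimal for every $k$; users applying
the detector to noisy diaries should expect conservative layer counts.

## Information reach

The layered acquisition model scores a community of $i$ layers by
$$P_i = \sum_{j \le i} n_j \, r_K \, c_j,$$
with $n_j$ the annulus size, $r_K$ the trait prevalence (default 0.01:
1% of the community seeded) and $c_j$ the per-dyad face-to-face contact
probability.  `reach()` implements this literal additive form, which is
an *expected count*: it is linear in $r_K$ and can exceed 1.  Because
the original formulation calls it a probability, the package also
provides `reach_complement()`, the strict probability
$1 - \prod_j (1 - r_K c_j)^{n_j}$ of at least one informative contact;
the two agree to first order as $r_K c_j \to 0$ and the complement
never exceeds the sum.  Both are reported by `reach_curve()`.

The default $c_j$ (`default_contact_probs()`) are *not* published
values — the original contact-rate curve exists only as a figure — but
are derived from the effort profile: per-capita effort share per
annulus, scaled so the innermost annulus has $c = 1$.  This calibration
is documented as such and fully overridable.  Extrapolation to the
5000 layer follows the same geometric per-capita decay.

`inflection_point()` finds the community size at which a saturating
curve has closed $1 - e^{-1}$ of the gap between baseline (default: the
first value) and asymptote (estimated as the final value), with linear
interpolation between samples.  For $y = A(1 - e^{-x/\lambda})$ with
baseline 0 this is exactly $x = \lambda$.  Saturation is tested by the
ratio of the final-segment slope to the steepest segment slope
(tolerance `1e-3`, exposed); a strictly linear curve has ratio 1 and is
rejected as having no asymptote.  Under the default calibration the
inflection of the literal curve falls at $x \approx 78$, inside the 50
layer; `optimal_community_size()` snaps to the nearest layer boundary
on the log scale (layer sizes are geometrically spaced) and returns 50.

## The urn allocation model

Relationships in layer $k$ cost $s_k$ (time per relationship); an
individual with $L$ ties allocates each independently to a layer with
probability
$$p_k = \frac{e^{-\mu s_k}}{\sum_j e^{-\mu s_j}},$$
where $\mu$ is the Lagrange multiplier of the total-resource
constraint.  Conditional on $L$ the occupancy vector is multinomial
(`allocation_pmf()`, computed in log space via `lgamma`; `layer_probs()`
max-shifts exponents so large $|\mu s_k|$ cannot overflow).  The prior
factor over $L$ itself is never given a functional form in the source
formulation, so the package deliberately conditions on $L$ everywhere
and treats the total resource $S$ as entering only through $\mu$.

`classify_shape()` reports the curvature of cumulative proportional
occupancy against layer rank: second differences are
$p_{k+1} - p_k$, so the curve is *convex* when occupancy grows with
rank, *concave* when it shrinks, *degenerate* (linear) at $\mu = 0$.
For any strictly monotone cost schedule the label flips exactly at
$\mu = 0$ — the phase transition between conventional and inverted
networks.  Note the geometric label depends on which end of the cost
schedule is "inner": with the empirical convention that inner ties cost
more (costs declining outward), $\mu > 0$ gives a convex cumulative
curve and the conventional few-close/many-weak structure, $\mu < 0$ the
inverted one.  Because published descriptions attach the words
concave/convex inconsistently to these regimes, `network_regime()`
provides the unambiguous behavioural label ("conventional" /
"inverted" / "uniform") by orienting layers from the costly end
outward.

## Cultural transmission on a lattice

`run_lattice()` simulates a binary cultural variant on a `width` ×
`height` torus (default 100 × 100 = 10,000 agents).  Each agent
interacts only with its eight nearest neighbours, split into four
orthogonal "friends" (direct) and four diagonal "friends-of-friends"
(indirect); the published verbal description of the two classes is
ambiguous (it places "direct" on the diagonals while also describing
diagonal cells as indirectly reachable corners), so the standard Moore
decomposition — orthogonal = direct — is adopted and documented here.
Per generation, synchronously and reading the previous generation's
states, each agent retains its variant with probability `b_self`, else
copies a member of the direct class (`b_direct`) or indirect class
(`b_indirect`); the three biases must sum to 1.

Design decisions worth stating:

* **Mutation only at seeding.**  The mutant is introduced at
  `seed_count` random nodes (default 1, frequency $10^{-4}$ on the
  default lattice) and thereafter spreads by imitation alone, so
  all-wild and all-mutant are absorbing and extinction statistics are
  well defined; `b_self` is interpreted as retention.  Runs end at
  fixation ("penetrant"), loss ("extinct") or `max_generations`
  ("censored").
* **Directional bias β.**  Neutral copying from a single seed fixes
  with probability $1/N$ — far too rarely to study penetrance times at
  $N = 10^4$.  The inheritance-bias functions of the original
  mean-field formulation are not published in closed form, so the
  package exposes a single directional-bias parameter: a copying agent
  samples its source with weight $1 + \beta$ for mutant carriers
  versus 1 for wild, giving adoption probability
  $(1+\beta)m/(4+\beta m)$ with $m$ mutant neighbours in the chosen
  class.  `beta = 0` (default) recovers exact neutral copying; β > 0
  makes fixation common enough to measure.  Published figures of
  44–60% extinction and 75–150 (mean-field) versus 150–300 (lattice)
  generations to penetrance depend on unpublished bias-steepness
  settings and are treated as qualitative calibration bands, not
  reproduction targets.
* **Mean field.**  `run_mean_field()` drops the spatial constraint: a
  copying agent samples `n_parents` cultural parents uniformly from the
  whole population (with replacement) and adopts from one, mutant
  parents weighted $1+\beta$ — equivalently $m \sim
  \mathrm{Binomial}(n_\mathrm{parents}, x)$.  With β = 0 the mutant
  fraction is a martingale (checked exactly at one step in the tests).
* **RNG.**  `run_ensemble()` derives one sub-seed per replicate from
  the master seed in a single draw and records it per run, so
  ensembles are bit-reproducible and replicates independent; R has no
  counter-based generator, so sub-seeding stands in for true
  substreams.

The simulator is validated against an exact absorbing-Markov-chain
oracle on the 3 × 3 torus (512 states; extinction probability and mean
absorption time by linear solve), and the structured-versus-mean-field
comparison — spatial structure slows penetrance because the mutant must
escape local eddies — is asserted directionally on paired 20 × 20
ensembles.

## Synthetic data

`gen_ego_contacts()` plants cumulative layers (default 5/15/50/150)
with base rate decaying by `layer_rate_ratio` (default 3) per layer
from `rate_innermost` (default 1 event/day, near-daily inner-layer
contact) and multiplies log-normal noise (`log10_noise_sd`, default
0.3).  It emulates the marginal rate distribution of layered egocentric
networks; it does *not* emulate alter-alter structure, burstiness,
channel multiplexity, or observation-window censoring of real contact
diaries, so detector performance on generated data bounds, rather than
guarantees, performance on field data.  `gen_community_graph()` builds
a deterministic ring-of-layers community: every node's $L-1$ nearest
ring neighbours fill its layers inside out, edge weights are the
per-capita effort of the tie's layer, symmetry is automatic and
connectivity is guaranteed by the distance-1 ring.

## Problem sizes and tolerances

The test suite runs the exhaustive partition oracle to $n = 12$ (all
$k$), the urn normalisation to $L \le 6$, $r \le 4$, the Markov-oracle
comparison at $10^4$ replicates (±3 s.e.), the paired
structured/mean-field ensembles at 200 replicates on 20 × 20, and the
recovery experiments at 30–100 seeds — sizes chosen to make the
statistical assertions sharp at interactive runtimes.  Monte-Carlo
assertions use 3–4 standard errors; exact assertions use published
printed precision (1–2 decimals) or 1e-12 for algebraic identities.

## Known limitations

* Layer detection is strictly 1-D: no graph community detection, no
  multi-channel fusion.
* The reach model treats prevalence as uniform across layers and dyads
  as independent; upward multi-hop flow toward ego is out of scope.
* The urn model's prior over total network size $L$ is not evaluated;
  all quantities are conditional on $L$, and µ is not fitted to data.
* The transmission model is binary-variant; multi-variant cultural
  spaces and time-varying networks are not modelled.
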