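---
title: "Models and methods behind primdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind primdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primdiv)
```

primdiv re-implements, as reusable and tested components, the analysis
pipeline of a large primate supermatrix study: auditing the occupancy of a
sparse concatenated alignment, reconstructing ancestral geographic ranges on
the resulting chronograms, detecting temporal shifts in diversification
rate, comparing molecular and fossil diversification signals, and building
and auditing fossil calibration bounds. This vignette explains the models,
their assumptions, the tunable parameters, and the design decisions taken
where the methods literature leaves choices open. Throughout, ages are Ma
before present, branch lengths Myr, and rates per lineage (or per area) per
Myr.

## Chronograms and lineage-through-time machinery

Trees are `ape::phylo` objects. A chronogram must be rooted, carry
non-negative branch lengths, and be ultrametric within a relative tolerance
of 1e-6 of the root age (`assertUltrametric()` names the worst tip pair on
failure). Diversification operations additionally require a fully
bifurcating tree; the parsimony operations accept polytomies, since Sankoff
dynamic programming generalizes to multifurcations and ignores branch
lengths anyway.

`lineagesAt()` counts reconstructed lineages crossing an age: two
immediately below the root split, one above it (the stem). `truncateAtAge()`
cuts a tree at an age line, so that Pleistocene branching (younger than
2.6 Ma) can be removed before shift fitting; each lineage crossing the
cutoff becomes a single tip, and the tip count equals the
lineage-through-time count at the cutoff — an identity the tests assert on a
grid of cutoffs.

## Supermatrix occupancy

`readOccupancyMatrix()` reads a FASTA or sequential NEXUS alignment plus a
RAxML-style partition table (`DNA, name = start-end`, 1-based inclusive,
converted internally to 0-based half-open intervals that must tile the
alignment). A cell is one taxon-column pair; a taxon *has* a locus iff at
least one character in the interval is determined. Gaps, `?`, `N`/`X` and
blanks count as missing; partial ambiguity codes (R, Y, ...) count as
determined. The published occupancy counts do not state how ambiguity codes
were treated; counting them as present matches common practice, and the
character set is an argument (`missingChars`) for users who disagree.
Percentages are rounded half-up to one decimal only at reporting
(`completenessFraction()`); full precision is kept internally.

## Ancestral ranges: MAC parsimony

Ranges are non-empty subsets of a small set of areas (four for extant
primates: Africa, Madagascar, Asia including Arabia, New World), encoded as
bitmasks. Ancestral ranges are capped at `maxRangeSize = 2` areas, matching
the observation that almost all living primate species occupy at most two
areas. The minimum-area-change (MAC) cost of an edge is the symmetric
difference cardinality — each area gained or lost counts one — which makes
the cost a metric; `macReconstruct()` runs Sankoff dynamic programming over
all `C(n,1) + C(n,2)` states with an exact up/down pass, so per-node MPR
sets contain precisely the states attainable in some globally minimal
reconstruction. Tip observations may be any non-empty set; internal states
respect the cap.

Because all most-parsimonious reconstructions share one total change count
but can split it differently into gains and losses, `macChangeBounds()`
computes the extremes of the gain/loss decomposition exactly, by a dynamic
program over (state, subtree cost) pairs carrying the minimum and maximum
gains reachable at each cost. This avoids enumerating MPRs and scales to
trees of any size. A consequence of the metric cost worth noting: a switch
between two single-area ranges costs two (one gain plus one loss), so on
single-area data the MAC minimum is exactly twice an ordinary Fitch
parsimony count — the tests verify this against an independent Fitch
implementation.

## Ancestral ranges: DEC likelihood

The dispersal-extinction-cladogenesis model evolves ranges along branches
by a continuous-time Markov chain: dispersal adds an area at rate
`d x |range|` (one route per occupied source area, uniform dispersal
multipliers), extirpation removes an occupied area at rate `e`, and the
empty range is absorbing. States above the range-size cap are excluded.
Transition probabilities come from matrix exponentials — an
eigendecomposition fast path checked against a scaling-and-squaring
reference at build time, with `Matrix::expm()` as fallback; zero-length
branches yield the identity exactly.

At speciation a single-area range is inherited by both daughters; a
two-area range `{a,b}` resolves into one of six equally weighted scenarios
(`({a},{b})` and its mirror; `{a}` or `{b}` against the full range, either
side). Equal scenario weights follow the Lagrange convention; the weights
are a deliberate, documented choice, not estimated. The root is weighted
uniformly over allowed non-null ranges (an equal-weight-per-size-class
alternative is exposed via `rootPrior`).

**Conditioning.** `decLoglik()` by default conditions on the observable
outcome that no lineage was ever absorbed into the null range
(`condition = "nonNull"`): the pruning likelihood is divided by the same
pruning run with unconstrained non-null tips. The unconditioned likelihood
(`condition = "none"`) silently spends probability mass on histories in
which the clade goes locally extinct everywhere, and in practice this pulls
the maximum-likelihood extirpation rate to the zero boundary — in our
simulation experiments the unconditioned fit returns `e` near 1e-5 when the
generating value is 0.01, while the conditioned fit recovers both `d` and
`e` within a factor of two (median over replicates). Node-range support
(`decNodeRanges()`) clamps each candidate state at each node and reports
those within 2 log-likelihood units of the best, the conventional support
window; the survival denominator cancels in these differences.

`decFit()` maximizes over `log d, log e` by bounded quasi-Newton from the
best point of a coarse log-grid, and never reports an optimum worse than
the grid scan. `countDispersals()` records one event per area present in a
child's range and absent from its parent's; cladogenetic range losses are
inheritance, not dispersal, and when a reconstruction is ambiguous the
lexicographically smallest optimal range is used, a tie-break that
determines where arrows fall on a plotted tree and is therefore fixed and
documented.

## Diversification shifts

The reconstructed birth-death likelihood with piecewise-constant rates and
a uniform sampling fraction rho at present is assembled from two
per-lineage quantities: `u(t)`, the probability that a lineage at age `t`
has at least one sampled extant descendant (a logistic ODE within each
epoch, solved in closed form and propagated across epoch boundaries), and
`q(t)`, the probability that it is represented by exactly one sampled tip,
whose log increments follow from `u`. The density of the branching times
`x1 >= x2 >= ...` is then

```
log L = 2 log q(x1) + sum_{k >= 2} [ log lambda(x_k) + log q(x_k) ] - 2 log u(x1),
```

conditioned on survival of both root lineages (the last term). No root
edge is used: conditioning starts at the root split. The constant-rate
special case is checked against an independently coded closed form on
hundreds of random draws, and the Yule case against the analytic maximum
likelihood estimator.

`fitShifts()` maximizes rates by multi-start bounded quasi-Newton in
log-rate space and shift times on a grid (default 0.1 Myr from 0.5 Ma to
root minus 0.5 Ma); detected shift times are therefore grid-quantized, and
the grid step is the first thing to vary when a detected time looks
suspicious. Shifts are added greedily — each new shift is scanned over the
grid with all rates re-optimized and previously accepted times retained —
which keeps the likelihood non-decreasing in the number of shifts because
the nested solution is always among the starting points. Model order is
chosen sequentially: accept `k` over `k-1` while twice the log-likelihood
gain exceeds the critical value, stopping at the first failure. A shift is
labelled an *increase* when net diversification `lambda - mu` is higher on
the younger side.

The nominal chi-square critical value (3 degrees of freedom: a time and
two rates per shift) does not control the real type-I error of a
grid-maximized statistic, so `calibrateType1()` simulates constant-rate
trees conditioned on tip count (rejection sampling, exact for 50 or fewer
tips, within 10% above that) and root age (by rescaling), and returns the
empirical 95th percentile of the null statistic. The returned value may
fall on either side of the chi-square quantile; neither direction is
assumed. `constrainedShiftTest()` restricts the two-rate model's shift time
to a window (for example 33.9 +/- 0.5 Ma, the Eocene-Oligocene boundary)
and compares against the one-rate model; with a window collapsed to a
point it reduces exactly to a fixed-shift fit.

## Fossil diversity and rate comparison

Standing diversity is range-through: a species counts at age `t` iff its
first-last occurrence interval spans `t`, boundaries inclusive (ranges are
the complete spanned interval). Occurrence pruning keeps species-level
records, collapses a genus represented only by indeterminate material into
one pseudo-species spanning its records, and drops indeterminate records
from genera that also have determinate ones.

Per-interval net diversification is reported as `ln(N_end/N_start)/dt`
from boundary standing counts — the standard exponential-growth estimator
of speciation minus extinction per lineage per Myr; the source tables
print only the verbal definition, so the arithmetic alternative
`(N_end-N_start)/(N_start dt)` is available behind a flag. Timetree rates
use lineage-through-time counts at the same boundaries; an interval
entirely above the root has no information and is reported missing, while
one straddling the root starts from the single stem lineage. Series are
compared by Pearson correlation (the `r` convention of the source tables)
with pairwise deletion; Spearman is an option.

## Calibration bounds

Minimum ages are the oldest unequivocal crown fossil of the clade, taken
as input. Maximum ages combine, by taking the largest: *stratigraphic
bounding* — walk rootward from the chronologic unit containing the oldest
occurrence until two successive units devoid of the clade's fossils have
been passed, and take the old boundary of the second (the walk starts
strictly above the unit holding the oldest fossil; when the 14-unit
Cenozoic table is exhausted first, the oldest boundary is returned
flagged); *phylogenetic bracketing* — the oldest stem fossil attached up
to two nodes rootward of the divergence; and a user-supplied *phylogenetic
uncertainty* age, for which no formula exists in the source methods, so it
enters only through `combineBounds()`. The unit table ships with boundary
ages after the Gradstein & Ogg time scale and is an ordinary data.frame a
user can edit. Audits (`auditViolations()`) measure violations against the
bounds themselves, not credibility intervals, and report the mean
magnitude over violations only.

## Synthetic data

Every input the pipeline consumes can be generated with a seed:

* `simBDTree()` — forward-time birth-death simulation from the root split
  with piecewise rates, rho-sampling applied at the end, and the
  reconstructed tree returned with the true event log. Conditioning on a
  tip count (for type-I calibration) is by rejection, exact for 50 or
  fewer tips.
* `simDECTips()` — Gillespie simulation of the DEC process along every
  branch with equal-weight cladogenetic scenarios; a branch absorbed into
  the null range is resimulated (bounded retries), which is precisely the
  survivorship conditioning that motivates the conditioned likelihood
  default above.
* `simFossilRanges()` — species durations arranged to track a target
  diversity curve, eroded into observed (first, last) pairs, with optional
  genus-indeterminate records.
* `simOccupancyMatrix()` — Bernoulli occupancy (default fill 0.314,
  emulating the roughly one-third occupancy of published primate
  supermatrices) with an optional block of high-completeness backbone
  taxa, written as FASTA plus partition file.

Each generator draws from a named pseudo-random stream derived from the
master seed, so adding a generator never changes existing fixtures. What
the generators deliberately do not emulate: phylogenetic signal in
occupancy patterns (real missingness is clustered by clade and by locus
class), spatial or taphonomic structure in fossil preservation, and
rate autocorrelation along branches. Tests passing on these synthetic data
therefore demonstrate correctness of the algorithms under the stated
models, not robustness to every pathology of real data.

## Problem sizes and numerical choices

The test suite exercises the estimators at deliberately modest sizes
chosen to give stable Monte-Carlo behavior: exhaustive-enumeration checks
of MAC parsimony on trees of up to 8 tips (50 instances), DEC oracle
checks on 2-tip trees to 1e-6 with parameter recovery on 200-tip trees
(10 replicates), shift-time recovery on ~300-tip trees (50 replicates,
0.5 Myr grid), and type-I calibration with 200 null simulations of 60-tip
trees followed by 500 fresh nulls. Matrix exponential row sums are
asserted to 1e-9; ultrametricity to a relative 1e-6; the Newick writer
round-trips branch lengths to 1e-9. Optimizer bounds keep rates in
(1e-8, ~150) per Myr, and every stochastic test fixes its seeds.

## Known limitations

Mass-extinction (past instantaneous sampling) and diversity-dependent
models are out of scope, as are founder-event speciation, time-stratified
dispersal matrices, and Bayesian range reconstruction. The sampling
fraction is uniform and applies at present only. Shift times are
grid-quantized. The calibration module takes the set of calibrated nodes
as input and does not model soft-bound probability tails.
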