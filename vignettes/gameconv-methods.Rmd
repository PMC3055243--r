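---
title: "Detecting, dating and orienting X-Y gene conversion: methods"
author: "gameconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting, dating and orienting X-Y gene conversion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gameconv)
```

## The model

A gametolog pair descends from a single sequence that stopped
recombining between the X and the Y at the stratum formation time
$T_s$. From then on the two copies accumulate substitutions
independently at chromosome-specific rates $r_X$ and $r_Y$ (per site
per year; the Y evolves faster because of the male mutation bias), so
the expected uncorrected X–Y difference at any site is the Jukes–Cantor
transition

$$p = \tfrac{3}{4}\left(1 - e^{-\tfrac{4}{3}(r_X + r_Y)\,T_s}\right),$$

about 0.10 for $T_s = 47$ myr at the default rates. An ectopic gene
conversion at time $t$ copies a tract from one chromosome over the
other; inside the tract the X–Y coalescence moves from $T_s$ to $t$,
which produces all three observable signals the package exploits:
a divergence valley in windowed profiles, a clade joining the converted
lineage's X and Y in local trees, and (for very recent events) a run of
X–Y identity among alleles.

Assumptions: substitutions are independent across sites and lineages
(Jukes–Cantor, no rate heterogeneity across sites); conversion is an
instantaneous whole-tract replacement; the species tree and its node
times are known; the alignment is taken as given (no realignment).

## Pipeline stages and their parameters

**Profiles** (`distanceProfile`). Uncorrected *p*-distances in tiling
windows (default 500 bp). Window *p* uses pairwise deletion; a window
with fewer than `min_valid_sites` (default half the window) unambiguous
sites reports a missing value rather than an unstable estimate —
deletion-riddled Y sequences otherwise generate spurious extreme
windows.

**Sliding trees** (`scanTopologies`). Complete-deletion *p*-distance
matrices per window (the matrix basis used for all trees, so every pair
is computed on one column set), neighbor-joining, and column-bootstrap
supports. Two scan styles are supported: coarse 2000/step 1000 and fine 500/step
400 (step = width − overlap). A trailing partial window is kept iff it has at least
`min_valid_sites` columns — which is exactly what makes a ~50-kb region
yield 50 trees at 2000/1000 and a 7.9-kb region 20 trees at 500/400.
The scan default of 100 bootstrap replicates per window is a deliberate
scale choice for the sliding stage: support enters only as a 70%
threshold, for which 1% resolution is ample; final reported trees use
the conventional 1000 (500 matches the figure-legend convention).

**Neighbor joining** (`njTree`). Saitou–Nei agglomeration on the
Q-criterion, written for exact reproducibility: ties in Q are broken by
the lexicographically smallest pair of original taxon indices, input
matrices are symmetrized to remove last-bit floating asymmetries, and
negative branch-length estimates are clamped to zero with the clamped
mass recorded in the `"deficit"` attribute. Internal nodes carry
bipartition bitmasks, so split bookkeeping (supports, monophyly checks)
is exact. `lsTopologySearch` provides an independent check: exhaustive
enumeration of all $(2n-5)!!$ unrooted topologies with ordinary
least-squares branch fitting; on additive matrices NJ must and does
recover its optimum.

**Classification** (`classifyTopology`). A *mixed clade* is a side of a
supported bipartition containing both the X and the Y sequences (all
alleles) of some species set and nothing else; with an outgroup present
only the side excluding the outgroup is eligible (without an outgroup a
conversion clade and its complement are indistinguishable on an
unrooted tree — supply an outgroup if the direction of reading
matters). Mixed clades are laminar; a clade exactly partitioned by its
child mixed clades carries no event of its own. The window signature
keeps only the *maximal* event-implying clades: a nested clade (a more
recent event inside an older one) hangs on a short terminal edge whose
support flickers from window to window, and is instead recovered
region-wide by the divergence rule below. The support threshold
defaults to 70%, the conventional bootstrap credibility cut; it is a
parameter, not a constant.

**Segmentation** (`segmentSubregions`). Maximal runs of identical
signature become sub-regions, with boundaries at the midpoint of the
overlap between the flanking windows (there is no canonical convention
for placing a boundary between overlapping windows; the midpoint is
this package's choice, and boundary placement is accurate only to
about one window step). UNRESOLVED runs are absorbed
into the flank sharing more windows (ties left). Boundary windows see
both flanking topologies at reduced per-clade site support, so four
absorption rules remove their artifacts: subset-family runs join a
longer (or, for single windows, any) neighbour whose family contains
theirs; a dip sandwiched between two runs of one identical containing
signature rejoins them; and interior or edge single-window runs that
share at least one clade with a longer neighbour join it. One window
cannot witness a sub-region at the scan's step size unless its
signature is unrelated to both neighbours — that is the method's
resolution limit, and sub-regions narrower than two windows should not
be over-interpreted.

**Event mapping** (`mapEvents`). Each event-implying clade maps to the
species-tree branch whose descendant set equals it; failing that, to
the unique minimal set of branches tiling it (for a laminar branch
family the maximal branches inside the set, which equals the
brute-force minimum — tested by enumeration). Events in adjacent
sub-regions on the same branch are *not* merged: each sub-region is an
independent witness. **Nested events**: within a multi-species clade, a
species whose X–Y divergence over the sub-region is below
`nesting_factor` (default 0.5) times the median of the other covered
species receives an additional event on its terminal branch — a second
conversion must have reset its clock after the shared event. The 0.5
default is the weakest nesting signal worth calling given binomial
noise on sub-region-sized intervals; it is configurable.

**Direction** (`inferDirection`). At sites where the unconverted
relatives' X sequences share one state, their Y sequences another, and
an outgroup matches one of the two (resolving it as ancestral), the
converted clade votes for the chromosome whose *derived* state it
carries. A determinate call needs a strict majority and at least
`min_votes` (default 3) voting sites; zero informative sites can never
produce a determinate direction. Limitation: for stacked conversions
(a recent event whose donor was itself converted earlier) the votes
report the deep ancestry of the tract — the donor of the older event —
because that is all polarizable sites record.

**Dating** (`lineageDivergence`, `substitutionRates`,
`dateConversion`). Divergence $d$ per chromosome is the mean tree-path
length from the calibration node to that chromosome's tips (a pairwise
half-distance estimator is available as `method = "pairwise"`; the two
generally agree to within sampling noise and the tree-path form is the
default because it weights shared branches once). Rates are $r = d /
(T \times 10^6)$ with the rhesus–hominoid split at $T = 30$ myr as the
default calibration. A conversion is dated from the converted clade's
post-conversion mean X and Y branch lengths, $\hat t_X = b_X / r_X$ and
$\hat t_Y = b_Y / r_Y$; the pair is reported as a (low, high) bracket
rather than pooled, because the two chromosomes give genuinely separate
clock readings whose spread is informative. Estimates are clipped to
the containing branch's existence interval (with the clip flagged).
All standard errors are site-bootstrap standard deviations (default 200
replicates; replicates in which the required clade dissolves are
dropped and counted) — the package's chosen, clearly-labelled error
convention, since uncorrected distances admit several analytic
variances. Dating requires the chromosome (or converted clade) to be
monophyletic in the region used and refuses otherwise: a region
straddling converted and unconverted segments has no single coalescence
to date.

**Tracts** (`findIdenticalTracts`, `scanTracts`). Maximal gap-free runs
where a focal X allele equals a Y allele, reported only when at least
`min_tract` (default 50) bp long *and* containing a diagnostic site at
which the focal allele carries the Y state — identity without
polarization cannot distinguish conversion from shared ancestry, and
gaps break runs because indel homoplasy is not modelled. The null
probability that all $n$ diagnostic sites converged by recurrent
substitution is $q^n$ with $q$ defaulting to the focal–Y divergence
outside the run divided by 3; this formalizes the verbal argument it
implements and is calibrated empirically on no-conversion allele
simulations rather than asymptotically.

**Breakpoints** (`locateBreakpoint`). For a region known to contain at
most one topology switch (such as the LINE element spanning the
boundary between the unconverted and converted regions), each candidate
column is scored by the monophyly-edge support on the flank to its left
plus the mean conversion-clade support on the flank to its right,
flanks bounded at `flank_width` (default 300) columns. Bounded flanks
are essential: whole-segment supports saturate at 100 over a wide
plateau around the true switch and the argmax degenerates to the
tie-break. 300 columns give roughly 30 informative sites per flank at
stratum divergence — enough for a stable tree, short enough that a
flank overlapping the switch loses support quickly. Scores within 2
support points of the maximum (the bootstrap resolution) are treated as
tied, resolving to the smallest column, which also handles the
fully-converted boundary case. A spread below 5 support points is
reported as "no switch".

## The simulator and what passing tests mean

`simulateGametologs` evolves a uniform-random root sequence down the
species tree; at $T_s$ each lineage's sequence forks into X and Y
copies with rates $r_X$ and $r_Y$ (before the fork a single copy
evolves at the average of the two — a convention that affects only
outgroup branch lengths, not any X–Y divergence). Per branch segment
each site changes with the exact JC transition probability
$\tfrac34(1 - e^{-\frac43 r t})$, so expectations compose across
segments and match the closed form above. Conversions are instantaneous
tract replacements at their scheduled (or Poisson-drawn) times;
deletions gap an interval for a lineage and chromosome, and a
conversion whose donor tract is deleted is refused. Output alleles
evolve an extra exponential time with mean $\theta/(2r)$, giving
expected within-species allele diversity $\theta$. Everything is
reproducible from one seed, and the truth ledger records realized
events and per-segment substitution counts.

The defaults are the primate stratum-4 conditions: $T_s = 47$ myr,
$r_X = 0.78\times10^{-9}$, $r_Y = 1.45\times10^{-9}$, calibration 30
myr, which place the unconverted backdrop at $p \approx 0.098$. The
canned fixtures (`makeFigureFixture`) provide the package's benchmark
scenarios: a 50-kb profile with two
conversion valleys and a Y deletion; a clean stratum null; a 7.9-kb
region carrying ten events across seven sub-regions (three in the
first, including a nested human-specific event, with a 5:5 direction
split) whose times were chosen within plausible ranges subject to every
planted clade edge leaving at least ~4 expected diagnostic sites per
500-bp window, the detectability floor of a 70% support cut; a
four-X/two-Y allele set with a planted 70-bp Y-identical tract
containing eight diagnostic sites; and a 3-kb element whose 3' half was
converted in two lineages, switching topology at column 1500.

What the simulator does **not** emulate bounds what green tests show:
no within-species coalescent (allele pairs are independent tip
perturbations, so no incomplete lineage sorting or ancestral
polymorphism), no indel process beyond configured deletions, no rate
heterogeneity or CpG effects, no alignment error, no
mismatch-repair mosaicism within tracts. On real data these produce
additional false-positive and false-negative modes (ILS in particular
can mimic species pairing for recently diverged species) that the
package's thresholds have not been calibrated against.

## Numerical conventions and degenerate inputs

Column coordinates are 0-based half-open everywhere internally and in
BED output; printed reports are 1-based inclusive. Gaps, `N` and IUPAC
ambiguity codes are kept on read and treated as missing by all distance
code. An interval with zero valid sites yields a missing value, never
zero. Species-tree input must be ultrametric within a relative
tolerance of 1% (dating needs node ages). All stochastic steps
(bootstrap, simulation) consume the R RNG, seeded once per entry point,
so identical inputs and seed give identical outputs, including written
files. Masks over tips use 32-bit integers, capping alignments at 30
sequences per tree — comfortably above the design point of 3–7 species
times two chromosomes plus outgroups.

## Known limitations

Boundary placement is accurate to about half a window step; sub-regions
narrower than two windows are absorbed unless unrelated to both
neighbours. Direction inference reports deep ancestry for stacked
conversions. Dating inherits the calibration's error wholesale (a
systematic shift in $T$ rescales every event age). The recurrent-
substitution null ignores phylogenetic correlation among diagnostic
sites; its empirical family-wise error is checked by simulation
instead. Crossovers are indistinguishable from conversions here; the
package deliberately calls everything a conversion-like event.
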