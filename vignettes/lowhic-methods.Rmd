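---
title: "lowhic: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lowhic: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the science implemented by `lowhic`, the defaults
and where they come from, the simulator's stated world, and the design
choices made where the methodology was genuinely open. It states no
empirical result that the test suite does not itself compute.

# From reads to valid pairs

A Hi-C library is a collection of proximity-ligation products. Two
sequenced mates may read through the ligation junction, so each read is
first scanned for the filled-in re-ligated restriction site (MboI
`GATC` + `GATC` = `GATCGATC`; HindIII `AAGCT` + `AGCTT` by the same
fill-in rule) and split at the junction midpoint, each sub-read keeping
its half-site. After alignment, records sharing a read ID form a group:

* 2 records — an ordinary mate pair;
* 3 records — one mate was split; the pair is kept when two records
  co-locate within **100 bp** on one chromosome (the junction spans the
  same locus twice), represented by the 5'-most of the two;
* 4+ records — the interacting loci cannot be identified; discarded.

Reads with mapping quality below **3** are removed first, and any group
losing a member falls through the same size rules.

Each locus is assigned to the restriction fragment containing it (from
an in-silico digest; fragments are 0-based half-open and tile each
chromosome exactly). Filters, with the reasoning behind them:

| flag | rule | rationale |
|------|------|-----------|
| `far_from_site` | site distance > **5 kb** | a true ligation product ends near a cut site |
| `same_fragment` | both loci on one fragment | no ligation between two fragments occurred |
| `inward_short` | `+/-` facing, separation < **10 kb** | unligated fragment with uncut sites between reads |
| `outward_short` | `-/+` facing, separation < **10 kb** | self-ligated (circularised) fragment |
| `duplicate` | both loci within **2 bp** of an earlier pair, same strands | PCR duplicate |

Same-orientation pairs are never orientation-flagged: they require a cut
and re-ligated site between the reads, so they are genuine products at
any separation. At large distances inward and outward pairs occur in
equal numbers; the fixed 10 kb cutoff is exposed as a parameter rather
than auto-estimated. Category accounting uses a fixed first-trigger
precedence (`same_fragment` → `far_from_site` → `inward_short` →
`outward_short` → `duplicate`) so library statistics are deterministic;
the underlying logical flags are all retained. Duplicate clustering is
greedy in input order — the first pair seen is the retained
representative.

The cis/trans ratio is reported raw (`cis/trans`) and
species-normalised: the trans count is multiplied by the ratio *f* of
possible intra- to inter-chromosomal bin pairs, which removes the
dependence on chromosome number and length.

# Matrices, balancing and O/E

Valid pairs are binned at a uniform resolution; matrix mass equals the
number of pairs binned. Bins with marginal coverage below **10% of the
median** positive coverage are masked (rows and columns zeroed, flagged
unmappable). Knight–Ruiz balancing then finds positive factors `b` with
`b_i * M[i,j] * b_j` having unit row sums over mappable bins; the
implementation is the KR inner–outer Newton iteration with a
Sinkhorn–Knopp fallback on stall, tolerance `1e-6` on the maximum
row-sum deviation, 300 outer iterations, and an explicit error naming
the offending chromosome on non-convergence. Balancing is genome-wide
by default (the rearrangement scan needs balanced trans pixels);
`per_chromosome = TRUE` gives the cis-only variant.

The expected profile `e(d)` is the mean balanced signal over mappable
pairs at bin distance `d`, per chromosome; the O/E transform divides
each pixel by `e(|i - j|)`. By construction the per-distance mean of a
chromosome's O/E pixels is 1, which the acceptance suite asserts to
`1e-10`. Difference matrices mask pixels lacking signal in **both**
inputs by default (masking pixels missing in *either* input would
discard exactly the one-sided gains and losses a case/control comparison
is looking for; the stricter mode is available via `no_signal =
"either"`). Distance-stratified correlations bin intra-chromosomal
pixels into strata of 250 kb (5 diagonals at 50 kb) and report Pearson
coefficients per stratum, `NA` under 3 pixel pairs.

# Insulation, boundaries, compartments

The insulation score at bin *i* is the mean balanced signal over the
k×k window spanning the k bins upstream versus the k bins downstream
(bin *i* excluded), undefined where the window leaves the chromosome or
covers more than 50% masked pixels (a choice the method's sources leave
open), then log2-normalised to the chromosomal mean — so per chromosome
the mean of `2^score` over defined bins is 1. The highlighted window is
**250 kb** (k = 5 at 50 kb); `insulation_multi()` produces the usual
100 kb–1 Mb ladder.

Boundaries are minima of the insulation valley: the delta vector at *i*
is the mean score over the `delta_window` (default **7**) bins to the
right minus the left; a boundary sits where delta crosses zero from
negative to positive, placed at the flanking insulation minimum.
Boundary strength is the delta span between the *nearest* local extremes
flanking the crossing. An earlier draft measured the extremes over a
fixed ±7-bin window; on Poisson-noise maps that inflates the strength of
shallow noise wiggles several-fold and produced spurious weak calls
inside long TADs, so the nearest-extreme definition (the classic one for
this statistic) is used. Calls below `min_strength = 0.1` are dropped.
These two defaults are **non-reproducing parameters**: the source
methodology cites the insulation literature without stating its values,
so they are package choices, exposed as arguments and CLI flags. On a
featureless Poisson map the caller still reports a noise floor of
roughly 10–20 weak boundaries per 800 bins at these defaults; raise
`min_strength` for conservative calling.

Compartments: per chromosome, the O/E matrix over mappable bins is
converted to the Pearson correlation matrix of its rows; the eigenvector
of the largest-magnitude eigenvalue is the compartment track and its
sign labels bins A or B. The sign of an eigenvector is arbitrary, so by
default "A" is oriented to the sign group with the higher mean
within-group O/E signal; a user reference track (GC content is the usual
choice) can re-orient it. Degenerate inputs (constant rows) warn and
return an undefined track.

# Aggregates and strength statistics

Aggregate TAD analysis extracts, per region, the O/E square over the
region expanded to **3×** its size (centred), resamples it to a fixed
grid by nearest-neighbour (half-open pixel-centre mapping, the same
convention as PIL/scipy "nearest"), and averages; the default **90×90**
grid is a package choice (the source figure does not state one).
Instances with more than half their pixels undefined, or windows leaving
the chromosome, are skipped and counted. Loop pileups use a **400 kb**
window in **25 kb** matrices (a 17-pixel square).

TAD strength = sum of O/E in the TAD square divided by the mean of the
two same-size neighbouring diagonal squares. Loop strength = sum over
the **300 kb** square at (a1, a2) divided by the mean of two control
squares at the same diagonal distance *d* = a2 − a1: control 1 at
(a2, a2 + d) and control 2 at (a1 − d, a1) — replacing one anchor by the
equidistant locus on the far side of the other keeps the controls on the
same diagonal, so the distance decay cancels and the statistics are
scale-invariant (both are ratios). Controls or neighbours leaving the
chromosome give `NA` with a warning.

# Loop calling

For every intra-chromosomal pixel in the candidate band (2–400 bins,
i.e. up to 10 Mb at 25 kb — a compute bound, exposed as arguments), four
local neighbourhood expectations are computed at radii `p = 2`,
`w = 5`: the square annulus between p and w minus the row/column cross
("donut"), its lower-left quadrant, and 3-wide horizontal/vertical
stripes. Each expected value rescales the distance-expected at the pixel
by the neighbourhood's observed-over-expected ratio, clipped at edges
and masked bins. The raw count is tested against a Poisson law with the
neighbourhood expectation divided by the pixel's bias product, and FDR
is controlled per neighbourhood by lambda-chunking: rates are grouped
into chunks spanning a factor `2^(1/3)`, and within a chunk the FDR at
count *k* is the Poisson-expected tail count over the observed tail
count, made monotone in *k*. Under a pure null the two tail counts
agree and the FDR saturates at 1 — this is what keeps decay-only maps
call-free, and it is why this empirical scheme is the default rather
than Benjamini–Hochberg on the p-values (per-chunk BH admits about one
false pixel per null map by construction; a `fdr_method = "bh"` mode is
kept for comparison).

Retained pixels must be ≥2-fold enriched over donut or lower-left,
≥1.5-fold over horizontal and vertical, ≥1.75-fold over both donut and
lower-left, and at FDR ≤ 0.1 in all four neighbourhoods. Adjacent
retained pixels (Chebyshev distance 1) merge into one call at the
strongest pixel, and a call must be backed by at least `min_cluster = 2`
adjacent enriched pixels: a single isolated pixel passing every filter
is statistically indistinguishable from a Poisson outlier, whereas a
genuine focal contact enriches a small neighbourhood. Set
`min_cluster = 1` to keep singletons.

# Virtual 4C and rearrangements

At the 50 kb scan resolution, every mappable bin *i* is a viewpoint; the
profile *v* is row *i* of the genome-wide balanced matrix. Viewpoints
with any unmappable bin within ±7 bins are skipped — mappability gaps
masquerade as rearrangements. An entry *v_j* is a peak when it exceeds
`0.15 * v_i` **and** strictly exceeds the empirical 99.5th percentile of
the other defined entries of *v* (exclusive of *v_i*; the percentile
convention is not fixed by the method's sources) **and**, when
intra-chromosomal, lies at least 50 bins from *i* (local contact
enrichment is never a rearrangement signal; the exclusion cannot apply
across chromosomes, where distance is undefined).

Case peaks with no control peak within ±2 bins at both coordinates
(a package tolerance; the original analysis curated candidates by eye,
which the `v4c_peaks` review columns support instead) are merged into
calls over adjacent runs. The reported breakpoint is the member pixel
with maximal target signal: a translocation places cis-like decay
*anchored at the breakpoint pair*, so the signal argmax is the anchor
itself. An explicit one-sided decay regression was considered and
rejected as noisier at desk-scale depth; the argmax recovers planted
breakpoints within ±1 bin in the acceptance suite.

TAD intensity differences merge the two samples' boundary sets (sorted
union, collapsing boundaries within 1 bin), then compare the mean signal
over each inter-boundary square between case and control.

# The simulator's stated world

`map_spec()` defaults describe a desk-scale genome chosen so every suite
runs in minutes: **two 20 Mb chromosomes at 50 kb** (400 bins each),
decay exponent **α = 1** (the classic fractal-globule scaling of
intra-chromosomal contact probability), depth **2×10⁶** expected pairs
(10⁶ per chromosome, the regime the recovery examples state),
inter-chromosomal weight 0.003 relative to the cis decay unit (giving a
raw cis/trans balance in the range of good libraries at this geometry).
Expected intensity is

```
lambda[i,j]  ∝  (|i−j| + 1)^(−α) × TAD × compartment × loop
```

with TAD block multipliers on within-TAD pixels, compartment multipliers
1.5 (same label) / 0.67 (cross label) — visible checkerboards at desk
depth — and loop foci as 2-D Gaussian bumps of σ = 1 bin reaching the
stated fold at the centre. Counts are independent Poisson draws at the
stated depth; the same seed gives identical output. Translocations add
cis-like decay to the inter-chromosomal block, anchored at the
breakpoints, with amplitude taken from the map's own per-distance mean
counts and default intensity 0.5 (one rearranged allele of two);
optional lost segments are binomially thinned by half. Read-pair
simulation plants each artefact class by its definition (jittered
copies, outward/inward short pairs, same-fragment pairs) with valid
pairs kept above the orientation cutoff so flags fire only on planted
artefacts.

**What the simulator does not emulate:** per-bin coverage bias (true
bias is 1), chromatin-state-dependent decay, sequencing error, copy
number, or polymer physics. A green recovery test therefore establishes
that an algorithm recovers its planted structure under Poisson noise —
not that it is robust to the bias structure of real libraries.

## Balancing and block-enriched maps

One interaction deserves explicit statement. The simulator's TAD model
is multiplicative: boosted within-TAD pixels *add* contact mass, so TAD
bins have inflated marginals. KR balancing — whose premise is that
marginal variation is technical bias — flattens those marginals and
thereby attenuates the planted block contrast (a multiplier of 3 comes
back as ≈1.4 after balancing; the effect also imprints a weak U-shaped
bias profile across each TAD). The alternative, a coverage-conserving
TAD model that pays for within-TAD enrichment by depleting cross
contacts, is *infeasible* at multiplier 3 for realistic TAD sizes at
α = 1: the boosted within-TAD mass alone exceeds a bin's entire
marginal budget. Real data sidesteps the dilemma because real domain
enrichments at fixed distance are mild (≈1.5–2×) and coverage-conserved.

Consequently, tests whose purpose is to verify a *statistic* against
planted ground truth (TAD strength, boundary recovery on block-tiled
chromosomes) evaluate it on the simulator's ground-truth normalisation
— `as_balanced()`, which stamps unit bias on a map whose generative
model genuinely has none — while everything else (O/E normalisation,
decay recovery, compartments, loop calling, the V4C scan) runs the full
mask → KR → O/E pipeline. Users analysing real data should always
balance; `as_balanced()` exists for bias-free synthetic input only.

# Numerical and interface conventions

Coordinates are 0-based half-open everywhere internally and in
BED/bedGraph/COO files; `.pairs` files are 1-based (both are those
formats' standards). Bin and fragment indices are 1-based globally in
chromosome-set order, R-style. Matrices are dense base-R matrices —
exact and fast at desk scale; a full mammalian genome at high resolution
would need a sparse backend, which is out of scope. All randomness is
seeded explicitly; simulator specs require a seed. KR tolerances and
iteration caps are arguments; every CLI subcommand logs its parameters
to stderr and writes outputs atomically (temp file + rename).

# Known limitations

* Dense matrices bound the practical genome size (memory grows with the
  square of the bin count).
* The loop caller implements a single resolution; no 5/10/25 kb merging.
* No ICE or vanilla-coverage normalisation; KR only.
* The V4C control-matching tolerance (±2 bins) substitutes for manual
  curation; borderline candidates should be reviewed with the emitted
  peak statistics.
* The boundary caller's `delta_window` and `min_strength` defaults are
  package choices, not reproductions of any published parameterisation.
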