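---
title: "Methods: origin colocalization, GC-matched motif nulls, and combing statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: origin colocalization, GC-matched motif nulls, and combing statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oritools)
```

This vignette records the models, parameter choices and numerical
decisions behind `oritools`, in the spirit of the methods sections of the
established omics packages. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

# The scientific setting

Metazoan replication origins can be mapped genome-wide by sequencing
short (0.5–1 kb) RNA-primed nascent strands (NS-seq). A sequence-specific
origin-binding protein, assayed by ChIP-seq, yields a second peak set.
Three quantitative questions connect them:

1. Do the protein's binding sites coincide with initiation sites, and how
   tightly (colocalization fractions, distance profiles, bound/unbound
   origin classes)?
2. Is a candidate binding motif enriched in bound regions beyond what
   length and GC composition alone would produce (GC-matched randomized
   null)?
3. What happens to replication dynamics when the protein is lost
   (DNA-combing fork statistics)?

# Colocalization model

**Distance rule.** "Within *d*" is evaluated edge-to-edge
(`gap_distance`): overlapping or book-ended intervals are at distance 0,
otherwise the minimum gap between edges counts. The published analyses do
not state whether distances were measured between edges or summits; the
edge-gap reading is the weaker (more inclusive) one and is consistent
with using the nascent-strand size (0.5–1 kb) to justify a 2-kb cutoff.
A centre-to-centre mode (`proximity_config(mode = "center")`) is provided
for sensitivity analysis. Both modes treat the cutoff inclusively
(`<= d`), so the fraction is continuous at `d = 0` for overlapping peaks.

**Fractions vs profiles.** An anchor adjacent to several events counts
once in the colocalization fraction (a per-region claim); every
in-window (anchor, event) pair contributes to the distance profile (an
event-density claim). Profile bins are half-open `[edge, edge + bin)`
with the final bin closed so the profile covers exactly
`|distance| <= half_window`; the default half-window of 10 kb mirrors a
20-kb analysis window, with 500-bp bins.

**Strand** is ignored throughout the colocalization math (binding and
initiation are strandless claims) and retained only for sequence
extraction and motif scanning.

**Chromosome naming** is exact string equality; peaks on chromosomes
absent from the partner set are simply never colocalized.

# Peak-subset selection

Motif discovery wants short, unambiguous, high-confidence sequences. The
selection rule keeps peaks with length < 400 bp, score ≥ 150, and an
edge gap > 1 kb to the nearest *other* peak of the full input set.
Because isolation is tested against the complete input rather than the
surviving subset, the operation is idempotent and invariant to input
order (both property-tested). The published criteria are worded once as
"greater than or equal to 150" and once as "greater than 150"; this
package follows the inclusive reading, and similarly treats "shorter
than 400 bp" and "more than 1 kb away" strictly.

# The GC-matched randomized null

A motif's containment frequency in bound regions is meaningless without
a composition-matched baseline: GC-rich motifs are common in GC-rich
regions regardless of binding. The null generator draws, for each
template region, a random locus with *identical length* and GC fraction
within a tolerance:

- Chromosomes are sampled proportional to the number of valid start
  positions; starts are uniform.
- Candidates are rejected when they overlap any template region, contain
  more than 10% `N`, or miss the template region's GC by more than the
  tolerance.
- GC is computed excluding `N` positions from numerator and denominator.

The GC tolerance is not stated in the original description ("same length
and GC content"); `oritools` defaults to ±0.02 absolute — tight enough
that GC-driven motif frequencies differ negligibly, loose enough that
matching a 150–400 bp region (GC granularity 1/length ≈ 0.003–0.007)
succeeds in a few hundred draws on a typical genome. The N-content and
template-overlap rejections are likewise this package's choices, made
configurable and logged (the achieved GC deviations are stored in the
output's metadata columns). A region that cannot be matched within
`max_attempts_per_region` raises an error naming the region rather than
silently relaxing the tolerance.

Motif matching is exact IUPAC containment on both strands — a string
search, not a PWM — because that is the operation whose output the null
calibrates. `N` in the *subject* matches nothing; ambiguity codes are
honoured in the pattern only. The implementation compiles the pattern to
a fixed-length regular expression; the test suite cross-checks it against
`Biostrings::countPattern(fixed = "subject")` as an independent oracle,
and against the closed-form expectation
`1 - (1 - 2*4^-12)^(L-11)` for a fixed 12-mer on i.i.d. uniform sequence.

# DNA-combing statistics

**Constants.** Stretched-fibre length converts at 2 kb/µm; both pulses
last 30 min. Fork speed divides the second-pulse (CldU) elongating track
by the pulse duration: the second label unambiguously bounds elongation
over a known interval, whereas the first label's start is unobserved for
forks established before the pulse. (Measuring IdU or averaging both is
available via `fiber_config(speed_label=)`.)

**Asymmetry.** A fork pair is asymmetric when the longer side exceeds
the shorter by strictly more than 33% (`max/min > 1.33`); a pair at
exactly 1.33 is symmetric. One side of zero length with the other
positive is asymmetric. The threshold is configurable.

**Inter-origin distances** are measured between origin centres on the
same fibre, located on `initiating` segments via cumulative segment
length. When an origin's initiating tract is recorded as sided
left/right rows, the centre is the junction between them — the point
from which the two forks diverged; otherwise the midpoint of the
initiating span is used. Medians are computed on raw, unbinned values.

**Rank test.** Condition comparisons use the two-sided Mann–Whitney
rank-sum test: exact enumeration of the U distribution over all group
assignments when both groups have ≤ 8 observations (valid under ties),
and the normal approximation with tie-corrected variance and continuity
correction otherwise. The exact path is verified against an independent
enumeration oracle; the approximate path against `stats::wilcox.test`.

**Fibre-signal fraction.** The denominator is every fibre present in the
input table (signal-free fibres are recorded as single `label = "none"`
rows); the published analyses do not define this denominator, so the
convention is documented here rather than inferred.

# The synthetic-data generators

The generators exist to give every analysis stage a closed-loop test
with known truth; their defaults are the wild-type conditions the
analyses describe, chosen once and not tuned against test outcomes.

**Genome**: i.i.d. bases at a chosen GC. No repeats, isochores or gaps —
a green motif-null test on this genome establishes correctness of the
machinery, not robustness to real genome structure.

**Peak pairs**: `round(colocal_fraction * n_anchors)` anchors receive an
event at an edge gap uniform in `[0, cutoff]`; all other anchors sit at
least `5 * cutoff` from every event, so "not colocalized" is unambiguous
under either distance mode (the colocalized side is guaranteed under the
edge-gap rule only). Placement uses jittered fixed-stride slots, which
caps density; requesting more peaks than the genome can hold at that
stride raises an error instead of degrading the guarantee.

**Fibres**: each labelled fibre carries `1 + Poisson(2)` origins with
gamma-distributed spacing. The gamma shape of 4 (coefficient of
variation 0.5) reflects the under-dispersion of origin spacing relative
to a Poisson process (origin interference); the scale is set so the
distribution's median equals the target (default 102.6 kb). Fork speeds
are truncated-normal (mean 1.570 kb/min, sd 0.3), drawn independently
per side. All origins fire at the start of the first pulse.

Two modelling decisions deserve emphasis:

- *Fork termination.* At these parameters each unobstructed fork tracks
  ~94 kb over the two pulses, more than the median spacing, so facing
  forks of adjacent origins must meet. The simulator terminates them at
  the meeting point and marks the truncated second-pulse segments
  `terminating`; speed statistics use `elongating` segments only, which
  is precisely the field's "elongating forks only" measurement rule.
  Termination removes a speed-biased subset (surviving interior forks
  are slower than average), which is why recovered median speeds sit
  ~1–2% below the draw mean — visible in the recovery tests, and within
  their 5% band.
- *Constructed fibre lengths.* Labelled fibres are built around the
  origins they carry (margins + drawn spacings) rather than dropping
  origins off a fixed-length fibre: truncating spacings on finite fibres
  length-biases the observed distances by several percent, corrupting
  the generator's stated target. Signal-free fibres use the configured
  length distribution instead. Consequently the measured inter-origin
  distances equal the drawn spacings exactly (a tested invariant).

*Quota randomization.* Stall outcomes (none/left/right/both) and the
fibre-signal flag are allocated by largest-remainder quota and then
permuted, so the realized mix equals the requested probability as
closely as the sample size allows. An i.i.d. Bernoulli draw could not
make "stall probability 0.5 with shortening 0.5 and no speed noise gives
exactly 50% asymmetric pairs" exact.

*Stalling* multiplies a stalled side's second-pulse track by the
shortening factor (default 0.5). It is applied to the measured length,
not modelled kinematically — a stalled fork does not change its
termination point in the simulator.

*Known limitation:* drawing sister-fork speeds independently with
sd = 0.3 implies a ~30% baseline asymmetry rate at the 1.33 threshold.
Real sister forks are strongly correlated (observed wild-type asymmetry
is closer to 8%), so simulated asymmetry percentages should be compared
between simulated conditions, not to published absolute values. The
default signal fraction is 1 (every simulated fibre labelled): recovery
tests need labelled fibres, and the fibre-signal statistic is exercised
by setting the dial explicitly (e.g. 0.156 → exactly 15.6%).

# The coexpression screen

Expression rows are z-scored across samples ((x − mean)/sd with the
sample sd, ddof = 1); constant rows are dropped with a warning rather
than aborting. Candidates are ranked by the mean Pearson correlation of
their profile with each member of a user-supplied replication-gene set.
Correlation is affine-invariant, so raw and z-scored matrices rank
identically (property-tested); the z-step is retained because it is the
transform under which the screen was defined. Spearman correlation is
available as an option. The upstream curation that produces the
candidate list (mass-spectrometry filtering, contaminant removal) is
manual and out of scope: the candidate and reference gene lists are
inputs.

# Numerical conventions

- Coordinates are BED 0-based half-open at every file interface;
  `GRanges` 1-based closed internally. Round-tripping a well-formed BED5
  file is byte-identical.
- Percentages round half-up (`format_percent`), so 20,841/24,222
  prints as "86%" at zero decimals.
- All generator randomness flows from explicit integer seeds; the
  generators restore the caller's RNG state. Identical seeds give
  byte-identical outputs (tested).
- Degenerate inputs fail loudly: all-`N` intervals, empty denominators,
  both-zero fork pairs and unmatched GC targets raise errors; the empty
  region set in `motif_fraction` returns 0 with a warning, since an
  empty observed set is a legitimate (if vacuous) scan result.

# What the acceptance checks do and do not establish

The acceptance suite verifies: printed-count arithmetic (86%), exact
agreement of the interval machinery with brute-force oracles,
monotonicity in the cutoff, the worked subset-selection example and its
permutation invariance, all null-model contracts, the closed-form motif
background, exact recovery of planted colocalization/enrichment/stall
fractions, and the 102.6 kb / 1.570 kb-min⁻¹ recovery at n = 1000
fibres. Reproducing the genome-scale published counts themselves would
require the deposited sequencing reads and the original external peak
callers, and is explicitly out of desk scope.
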