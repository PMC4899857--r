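# oritools

Tools for asking whether a sequence-specific DNA-binding protein marks
sites of replication initiation, and what happens to replication when it
is lost.

The package is aimed at epigenomics groups who have (i) ChIP-seq peaks for
a candidate origin-binding protein, (ii) replication-initiation peaks
mapped by nascent-strand sequencing (NS-seq), and optionally (iii)
single-molecule DNA-combing measurements and expression panels. It
implements the complete quantitative pipeline connecting those inputs:

- **Colocalization** — for anchor peaks *A* and event peaks *E*, an anchor
  `a` is colocalized when `min_e gap(a, e) <= d` (edge-to-edge gap;
  overlap counts as 0; default *d* = 2 kb, matching the 0.5–1 kb size of
  isolated nascent strands). Reports the fraction both ways, signed
  distance profiles of event centres around anchor centres (default
  ±10 kb in 500-bp bins), and the partition of origins into
  protein-bound/unbound classes.
- **Motif-discovery subset and GC-matched null** — selects compact
  (< 400 bp), isolated (> 1 kb gap), high-scoring (score ≥ 150) peaks;
  draws *n* randomized peak sets from the genome with identical length
  multisets and per-region GC within ±0.02; scans an IUPAC motif on both
  strands; and reports motif containment stratified by origin proximity
  (observed vs null).
- **DNA-combing statistics** — converts combed-fibre measurements at
  2 kb/µm, computes fork speed = CldU elongating-track length / 30 min,
  inter-origin distances between initiation-pattern centres, the strict
  ">33% longer" fork-asymmetry rule, the fraction of fibres with
  replication signal, and two-sided Mann–Whitney rank-sum comparisons
  (exact enumeration for small groups, tie-corrected normal approximation
  otherwise).
- **Coexpression screen** — z-scores each gene across cell lines
  ((x − mean)/sd, ddof = 1) and ranks candidate genes by mean Pearson
  correlation with a replication-gene reference set.
- **Synthetic data** — generators for random genomes with chosen GC,
  planted motifs, anchor/event peak pairs with a known colocalization
  fraction, and fibre populations with known spacing/speed/stalling, so
  every stage has a closed-loop ground-truth test.

Peak sets are `GRanges` (BED 0-based half-open at the interfaces),
genomes are `DNAStringSet`.

## Worked example

Simulate a peak pair with 80% planted colocalization and measure it:

```r
library(oritools)
pp <- simulate_peak_pair(n_anchors = 1000, colocal_fraction = 0.8,
                         cutoff_d = 2000, seed = 42)
fraction_within(pp$anchors, pp$events, proximity_config(cutoff_d = 2000))
#> colocalization (cutoff 2000 bp, gap distance)
#>   anchors: 800/1000 = 80.0%
#>   events:  800/1000 = 80.0%
```

800 of 1000 anchors sit within 2 kb of an event — the generator's planted
fraction recovered exactly. On real data this is the statistic behind
claims like "82.3% of binding sites lie within 2 kb of an initiation
site".

Simulate two fibre populations — a wild-type-like condition (median
spacing 102.6 kb, mean fork speed 1.570 kb/min) and a
initiation-deficient one (128.3 kb, 1.725 kb/min) — and compare:

```r
tab <- rbind(
  simulate_fibers(fiber_sim_spec(n_fibers = 400, seed = 42), "WT"),
  simulate_fibers(fiber_sim_spec(n_fibers = 400, spacing_median_kb = 128.3,
                                 speed_mean = 1.725, seed = 43), "KO"))
summarize_conditions(tab, condition_a = "WT", condition_b = "KO")
#>  condition n_fibers n_fibers_signal pct_fibers_signal n_distances
#>         WT      400             400               100         789
#>         KO      400             400               100         779
#>  median_interorigin_kb n_forks median_speed_kb_min n_fork_pairs pct_asymmetric
#>               101.2203     966            1.526698          136       27.94118
#>               124.3398    1022            1.693220          169       30.76923
#> Mann-Whitney (WT vs KO): inter-origin p = 2.243e-14, speed p = 1.827e-32
```

The recovered medians track the simulation targets (101.2 vs 102.6 kb;
the speed medians sit slightly below their means because termination
removes a biased subset of forks), and the rank-sum tests flag both the
spacing and the speed shift. `pct_asymmetric` near 30% in both conditions
is the false-positive rate implied by drawing the two sister-fork speeds
independently (sd 0.3) — see the methods vignette.

Command-line equivalents of every stage are available through the bundled
script:

```sh
Rscript inst/cli/oritools.R colocalize --anchors A.bed --events E.bed --cutoff 2000
Rscript inst/cli/oritools.R randomize  --template subset.bed --genome g.fa \
        --n 3 --gc-tol 0.02 --seed 7
Rscript inst/cli/oritools.R fibers     --table fibers.tsv \
        --condition-a WT --condition-b KO
```

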