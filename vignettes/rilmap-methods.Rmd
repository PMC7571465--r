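---
title: "Methods: bin-marker genotyping, linkage maps and ICIM in rilmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bin-marker genotyping, linkage maps and ICIM in rilmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rilmap)
```

rilmap reimplements, as a tested and scriptable pipeline, the analysis style
used for high-density RIL mapping by low-coverage resequencing: raw SNP calls
become bin markers through sliding-window genotyping, the bins become a
Kosambi-scale linkage map, leaflet shapes become three quantitative indices,
and QTL are mapped by additive inclusive composite interval mapping (ICIM)
with permutation thresholds. This vignette documents the model assumptions,
the tunable parameters, the numerical conventions, and the choices made where
the procedure is genuinely underdetermined.

## The population model

An RIL population is bred in silico by strict single seed descent: the F1 is
fully heterozygous, one selfed plant advances each line per generation, and
there is no selection or mortality. Meioses place a Poisson number of
crossovers (mean = chromosome length / 100 cM) uniformly along the
chromosome — a Haldane (no-interference) process, the simplest model
consistent with desk-scale mapping; interference enters the analysis side
only through the Kosambi mapping function. After `n_generations = 8`
(an RIL~8~), residual per-locus heterozygosity is 0.5^7^ ≈ 0.78% in
expectation, and the surviving heterozygosity is clustered in tracts, not
scattered — a property the line filter exploits (below).

Genotypes are observed through a read-depth model: depth is Poisson
(`mean_depth`, default 10); calls with zero depth or failing an independent
`missing_rate` (default 2%) are missing. Each read miscalls with probability
`error_rate` (default 1%), and a call is reported heterozygous only when both
alleles are covered by at least two reads — otherwise it collapses to the
majority homozygote. This calling heuristic is what makes a depth-4 floor
meaningful: at depth < 4 a true heterozygote can never be confirmed, and
error reads occasionally fabricate one. Contaminated lines (default 15 of
190, matching the line counts of the motivating study) additionally have each
call replaced by `ab` with probability 6%, which puts them far above the 2%
abnormal-call threshold without affecting clean lines.

Phenotypes are `trait mean + Σ additive QTL effects + Gaussian noise`; the
noise variance is solved from the realized genetic variance so the summed
target PVE holds in expectation. Apex counts are rounded and floored at zero.

## Window genotyping and breakpoint resolution

The genotyper keeps only SNPs where both parents are observed homozygous for
different alleles (the aa × bb pattern; progeny are recoded so `aa` is
parent-1-like), sets calls below `min_depth = 4` reads to missing, and slides
a `window_size = 15` SNP window one SNP at a time. A window is typed `aa`
when its aa count strictly exceeds `window_threshold = 11`; `bb`
symmetrically; otherwise `ab`. Missing calls count toward neither threshold.
The threshold is read symmetrically for both homozygotes because the literal
one-sided reading leaves bb segments untypeable. Each SNP takes the type of
the window centred on it, with the first and last ⌊15/2⌋ SNPs inheriting the
nearest full window's type; both conventions are ours, since the source
procedure does not state how window types map back to SNPs.

The symmetric rule has a deterministic consequence worth spelling out: around
every clean crossover there is a run of windows in which neither homozygote
count clears 11, so the smoothed genotypes carry an 8-SNP `ab` buffer centred
on the exchange. Left untreated, this buffer means adjacent bins differ only
by hom→het transitions, recombinant counts between adjacent bins are zero,
and the map collapses. Because the buffer is symmetric, the midpoint of a
non-homozygous run flanked by opposite homozygotes is an unbiased estimator
of the crossover position, and `resolve_breakpoints()` (applied by default in
`genotype_bins()`) replaces such runs with a clean switch at the midpoint.
Runs flanked by *equal* homozygotes are genuine residual-heterozygosity
tracts and are kept as `ab`. On error-free data this recovers every crossover
whose nearest neighbour is more than one window away exactly; double
crossovers closer than the window are invisible to the method by
construction, which is the main source of the modest (~5%) downward bias in
map length on noisy data.

Adjacent SNPs with identical genotype vectors across all lines are merged
into bins; bins with an inclusive physical span ≤ `min_bin_length` (10 kb,
strict "longer than") or with aa:bb counts failing the 1:1 χ² test at
`distortion_alpha = 0.01` are removed, with every removal logged by reason.

**The line filter.** Lines are dropped when their abnormal-call fraction
exceeds `max_abnormal_fraction = 2%`. "Abnormal" is not defined by the source
procedure; counting *all* heterozygous calls flags 30–45 of 190 simulated
lines, because legitimate residual-heterozygosity tracts at F~8~ cover on the
order of 1–2% of a line's genome — right at the threshold. rilmap therefore
counts only heterozygous calls in runs shorter than `min_het_run = 3`
consecutive non-missing calls: contamination and miscalls scatter isolated
hets genome-wide, while real residual heterozygosity is contiguous. Under
this reading the simulated 15 contaminated lines are flagged exactly and 175
of 190 lines are retained.

## Linkage-map construction

Linkage groups are preset to the reference chromosomes; within-group
connectivity at LOD ≥ 3 is checked and violations are reported, never
re-assigned. Pairwise recombination uses homozygous calls only: the observed
recombinant fraction *R* is transformed to the meiotic scale by the
Haldane–Waddington relation for selfed RILs, *r* = *R*/(2(1 − *R*)), clipped
to [0, 0.5); the linkage LOD is the base-10 likelihood ratio of a binomial at
*R̂* against independence. Pairs with fewer than 20 informative lines are
imputed *r* = 0.5, LOD 0.

Ordering minimizes SARF: a nearest-neighbour path seeded from the globally
closest pair, extended at whichever end is nearer to an unplaced marker, then
2-opt segment reversals (best-improvement, strictly decreasing, lowest-index
tie-breaks — the procedure is fully deterministic, so no RNG is involved),
then rippling with a 5-marker window trying all 120 permutations and
accepting only strict improvements until a pass changes nothing. Distances
are adjacent-pair Kosambi (no multipoint likelihood), cumulated from zero,
and each group is oriented so the first marker has the smaller bp position.
For ≤ 8 markers this matches an exhaustive minimal-SARF search in ≥ 99% of
noisy replicates (tested against an independent enumeration).

The summary table reports, per group, marker count, length, average adjacent
spacing `total/(n − 1)` (2 dp), maximum gap, and gaps > 5 cM. Published map
tables use `total/(n − 1)` within groups but `total/n` for the overall
average; both conventions are emitted (the total row uses `total/n`, the
adjacent-spacing convention is attached as an attribute) rather than silently
choosing one.

## Leaf morphometrics

Leaves are simple polygons, symmetric about the main vein (base at the
origin, tip at unit height, so all indices are scale-free). Apexes sit on a
smooth ovate envelope; between consecutive apexes a sinus vertex is pulled
toward the vein by `lobe_depth`, and the deepest sinus pair is placed so its
chord crosses the vein at `notch_position`, giving Q = 100 · notch by
construction. The "lobed area" closes each sinus with the chord between its
two neighbouring apexes (chord closure, not convex hull, so the tip cannot
inflate the total area); V is the shoelace area; L₁ comes from intersecting
the deepest pair's chord with the vein and L₂ is the base-to-tip distance.
R = V/(V + lobed) × 100 is 100 exactly iff the lobed area is zero. Apex
counts use the annotated landmark set when present, else strict circular
local maxima of centroid distance with a prominence floor of 1% of L₂ to
suppress discretization noise. Lines showing both lobed and indented
characters ("mixed") are excluded from QTL input. The generator's polygons
are stylized: they emulate the measurement geometry (areas, landmarks,
apexes), not photographic leaf outlines, so passing tests validate the
morphometric operations rather than any image-processing step.

## ICIM

Markers are coded +1/−1 for the homozygotes, with heterozygous and missing
calls at 0 (the midpoint — equivalent to mean imputation in a balanced RIL).
Forward–backward stepwise regression over all bins uses entry probability
`pin = 0.001` and removal probability `pout = 2·pin` (the source states only
the entry probability). The scan walks each group in `step_cM = 0.1` steps
(marker positions are always included in the grid). At a position between
flanking markers, each line's probability of carrying the aa QTL genotype
follows a two-state Markov chain along the chromosome whose transition
probabilities are RIL-scale recombination fractions from Kosambi-inverted map
gaps; het/missing flanks simply contribute no information. The
cofactor-adjusted phenotype (cofactors flanking the current interval are
released) is fitted with a two-component normal mixture by EM — at most 50
iterations, relative log-likelihood tolerance 10⁻⁸, class means initialized
from the prior-weighted flank means, σ² floored at 10⁻¹²·σ₀² to keep
noise-free phenotypes finite — and LOD = log₁₀ of the likelihood ratio
against the single normal on the same adjusted phenotype (clamped at 0; the
EM inner loop is compiled C++, as is usual for scan software). At a position
coinciding with a fully observed marker this reduces exactly to single-marker
regression LOD, which the tests verify to 10⁻⁶.

The permutation threshold permutes the phenotype, re-runs the full procedure
(stepwise included), and takes the ⌈(1 − α)·N⌉-th smallest genome-wide
maximum LOD — an order statistic, hence bit-reproducible under a fixed seed.
QTL are maximal supra-threshold runs, reported with peak position, nearest
flanking bins and their combined physical span (mirroring published QTL
tables), plus a 1.5-LOD-drop interval as a secondary column, since the
original interval convention is not stated. PVE at a position is
100 · (prior-weighted variance of the fitted two-point effect) / (ML variance
of the unadjusted trait). Traits are scanned independently; dominance and
epistasis are out of scope (RILs are essentially homozygous).

## Validation studies and problem sizes

The test suite and the acceptance script validate the pipeline at desk scale,
chosen so the whole suite runs in minutes while keeping each study
statistically meaningful:

* breakpoint/bin recovery: 3 chromosomes × 300 SNPs, 100 lines, error-free,
  bred to effective fixation (25 generations) so window buffers are not
  confounded with real het tracts; recovery is exact for crossovers separated
  by more than one window;
* ordering: 100 random 8-marker matrices (positions + binomial sampling
  noise at 150 lines) against exhaustive enumeration;
* map recovery: 3 groups × 30 evenly spaced bins over 90 cM, 200 lines,
  20 replicates — evenly spaced because markers closer than the resolution
  of 200 meioses make the true order statistically unidentifiable;
  order is recovered exactly (up to whole-group reversal) and the median
  group-length error is well under 15% (lengths are biased slightly short:
  Kosambi-on-Haldane plus finite-generation map expansion);
* null calibration: 50 independent null scans against a 200-permutation
  threshold on 3 × 20 bins, 150 lines — the exceedance count must fall in
  the exact central 95% binomial region around 0.05;
* QTL recovery: a single 40%-PVE QTL in 175 lines, 20 replicates, 0.5-cM
  scan step and 100 permutations per replicate.

What passing these studies does *not* show: performance on real read data
(alignment and variant calling are upstream of this package), behaviour under
segregation-distortion biology (the simulator breeds neutrally), or the
robustness of the leaf indices to photographic segmentation error.

## Known limitations

Adjacent-pair distances understate map length by a few percent relative to
multipoint likelihood when genotyping noise or close double crossovers are
present. The window caller cannot see double crossovers within ~one window
(here 15 SNPs), so very dense crossover clusters are merged or dropped. The
stepwise selector refits from scratch each forward step, which is fine for
thousands of bins but not for hundreds of thousands of raw SNPs. The
contamination and "abnormal call" models are explicit stand-ins for an
undocumented upstream filter and are documented as such above.
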