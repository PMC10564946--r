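---
title: "Models and methods behind m6ascape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind m6ascape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6ascape)
library(dplyr)
```

m6ascape implements the downstream statistics of a tumor-cohort MeRIP-seq
(m⁶A-seq) study: consensus peak processing, m⁶A quantification and
differential methylation, consensus-clustering subtypes with survival
contrasts, random-forest contribution ranking of candidate regulator RBPs,
miCLIP CIMS site calling with co-localization statistics, and GRO-seq
wave-peak elongation rates. This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## Coordinates and containers

All intervals are 0-based half-open tibbles (`chrom`, `start`, `end`,
`strand`), the BED convention, so files round-trip byte-identically.
Annotation is a `transcript_models` bundle (transcripts + exons, one
canonical transcript per gene — enforced, since region assignment is defined
against the canonical transcript only). Methylation data live in a long
tibble (`peak_id`, `sample_id`, `m6a_level`); matrix-shaped internals
(`level_matrix()`) are derived on demand. Overlap queries run on
GenomicRanges behind the tibble surface; sequence queries (always 5′→3′ on
the requested strand) on Biostrings.

## Peak pipeline

**Internal Poisson caller.** The package ships a window caller so the whole
pipeline is exercisable end to end; real analyses may substitute external
calls. Coverage is tiled into non-overlapping windows (default 50 bp); the
input is scaled to IP depth by the *median per-window IP/input ratio* over
informative windows (input > 0, joint count ≥ 10) rather than the library
totals — total-count scaling deflates the background estimate whenever
enrichment inflates the IP total, which manifests as spurious calls when the
roles of the tracks are swapped. A window is significant at a one-sided
Poisson tail below `p_cutoff` (default 1e-6), with the local input floored
at one read (a background cannot be estimated below sampling resolution);
adjacent significant windows merge into peaks.

**Two-caller consensus.** Only signal seen by both callers survives:
overlapping A/B pairs (≥ 1 bp, same strand) are merged to their union, and
overlapping unions collapsed. Union rather than intersection was chosen
because it preserves the full extent supported by either caller while the
two-caller requirement already controls specificity; an intersection variant
would only narrow the retained intervals, not change which signals survive.

**m⁶Am flagging.** m⁶Am sits on the first transcribed nucleotide and
cross-reacts with the m⁶A antibody. A peak is flagged when it overlaps the
5′UTR of a canonical transcript whose first base is adenosine in a BCA
context; the B base is anchored immediately 5′ of the TSS adenosine on the
transcript strand, which is where the dimethylated cap-adjacent adenosine
chemistry places it. Peaks from unstranded coverage carry a placeholder
strand, so the 5′UTR overlap ignores strand.

**Recurrence.** A catalogue peak is "present" in a sample when that sample's
consensus peaks overlap it by ≥ 1 bp — the simplest testable rule; the
default threshold keeps peaks present in ≥ 5 samples, counted over all
samples jointly (tumor and normal pools together).

**Region priority.** A peak straddling several regions is classified
start/stop-codon vicinity (± 100 bp around the codon) before 5′/3′UTR before
CDS before intron, reflecting the biological emphasis on codon-proximal
methylation; the flank is a parameter.

## Quantification and differential methylation

The relative m⁶A level is IP RPKM over input RPKM; peak length cancels, so
the value is `(ip/input) · (input_lib/ip_lib)`, missing where the input
count is zero. Missing values are excluded pairwise; peaks with fewer than 5
usable pairs are reported `ns` with a reason rather than imputed — a
pseudo-count would distort exactly the low-coverage peaks where the ratio is
least trustworthy.

The paired test is the two-sided Wilcoxon signed-rank test on tumor − normal
differences. Up to 25 complete pairs the p-value is exact, computed by
dynamic programming over doubled mid-ranks (exact also under ties, verified
against full 2ⁿ enumeration); above that, the normal approximation with tie
and continuity corrections. Directions come from the median paired
difference among peaks passing the BH threshold (default FDR < 0.1).

The permutation null swaps tumor/normal labels *within* pairs — sign flips
of the differences — because that is the exchangeability the signed-rank
test assumes; permuting across patients would break the pairing. Since
|d| ranks are invariant under sign flips, ranks are computed once and each
permutation reduces to a masked row sum, so 1,000 permutations on a
2,000-peak × 33-pair matrix take seconds. Both the observed and permuted
counts use the same vectorized approximation, keeping the comparison
internally consistent; counts are reported both at the BH threshold (the
cohort-level statistic) and at raw p < 0.05. The calibration property test
uses the raw-p count: under a pure null the FDR-significant count is ~0 for
observed and permuted alike, so their ratio is degenerate, while the raw-p
count has expectation 0.05 × peaks on both sides.

Two-condition calls use condition means (matching the scatter-plot framing
of knockdown/overexpression comparisons) with |fold change| > 1.2; swapping
conditions maps hyper ↔ hypo exactly.

## Subtyping

Consensus clustering draws ⌈0.8 n⌉ samples without replacement 1,000 times,
clusters each resample (agglomerative, average linkage, Euclidean distance
over peaks; k-means optional), and tallies co-clustering over co-sampling.
Peaks are standardized to zero mean/unit variance first (configurable) —
without it, high-baseline peaks dominate the distance. Final labels cut the
average-linkage tree of 1 − consensus; labels are `S1..Sk` ordered by first
sample occurrence, so they are deterministic but carry no meaning beyond
identity. Per-k PAC (proportion of ambiguous co-clustering, entries in
(0.1, 0.9)) and consensus-distance silhouettes are reported to support the
choice of k; k = 2 is the default because the package's subtype workflow
contrasts exactly two groups downstream.

Subtype contrasts are unpaired two-sided rank-sum tests with BH control;
clinical features use Fisher's exact test for 2×2 tables and chi-square
otherwise, falling back to Fisher when any expected cell is below 5. The
Kaplan–Meier median is the smallest time with S(t) ≤ 0.5 (the standard
product-limit convention); curves and the log-rank statistic come from the
survival package behind the `km_logrank()` surface, and the log-rank
arithmetic is cross-checked against the textbook observed-minus-expected
formula in the tests. Covariate-adjusted proportional-hazards modelling is
out of scope; the assignment table is exported for external modelling.

## Regulator ranking

For one peak, a regression forest (CART trees, variance-reduction splits,
bootstrap resampling, `mtry = ⌈p/3⌉`, implemented in C++) is fitted with the
peak's per-sample levels as response and RBP expression plus encoded
clinical covariates as predictors. Every prediction is decomposed along its
decision path: a split on feature j changes the running node mean, and that
change is credited to j, so per tree

y = c + Σ contrib(x, k),   c = root-node mean,

holds *exactly* (the test suite asserts the identity below 1e-9 across
random problems; it holds to machine epsilon). Defaults are 100 trees for
interactive sweeps (500 in the classical forest convention is equally valid
and only slows the sweep; the identity and ranking are insensitive to the
choice beyond Monte-Carlo noise), unlimited depth, minimum leaf 5.

Signed per-sample contributions necessarily average to ≈ 0 over a training
cohort — each tree's leaf-mean deviations cancel by construction — so the
*ranking* score is the mean absolute contribution over trees, samples and
hypermethylated peaks (a signed mode is retained for effect-direction
inspection). Clinical covariates participate in the regression but are never
ranked as candidate regulators.

The correlation screen computes Spearman's ρ for every RBP × peak pair
within hyper, hypo and unchanged strata; a pair is significant at |ρ| > 0.25
and p < 0.05. P-values use the t approximation on ρ, which is tie-safe and
vectorizes across the ~10⁴–10⁵ pairs a cohort produces; cor.test is the
cross-check on small vectors in the tests. Per RBP, Fisher's exact test
(one-sided) asks whether significant pairs are over-represented among hyper
peaks versus background, BH-corrected across RBPs.

The final rank is the product of the min-max-standardized contribution and
−log₁₀ FDR axes — an explicit, swappable rule; both axes are always emitted
raw. Ties resolve by raw contribution, then name, so that a saturated FDR
axis (many RBPs at FDR = 1 map to score 0) cannot impose alphabetical
artifacts.

## Colocalization and CIMS

CIMS calling keeps C→T records (read strand) that are not known SNPs, have
mutation fraction m/k ≤ 50 % (k = 0 records are skipped and tallied), and
whose base immediately 5′ in transcript orientation is adenosine; the
reported residue is that adenosine. "+1 position of the adenosine" is read
in transcript orientation — the crosslink-induced substitution sits directly
3′ of the methylated A — stated explicitly because coordinate orientation is
otherwise ambiguous on the minus strand. SNP exclusion accepts any user
position list; no database download is performed.

Distance profiles take, for each query anchor (midpoint by default;
edge-to-edge optional), the signed distance to the nearest subject anchor
within ± 2 kb, oriented by the query strand; equidistant neighbors resolve
3′-ward for determinism. Overlap association over a catalogue universe is a
one-sided Fisher test on the 2×2 membership table (≥ 1 bp, strand-ignored,
since DNA-binding tracks are unstranded).

## Elongation rates

Profiles cover −10 kb to +120 kb around the TSS, strand-oriented, with
0.01-trimmed means across replicate tracks; genes truncated by contig edges
are flagged. The profile can be binned (the rate analyses here use 50–100 bp
bins; at 2 kb/min a 50 bp quantization is a 0.2 % rate error, negligible
against Poisson noise). Smoothing is `stats::smooth.spline` with
`spar = 0.8` — the convention quoted for this analysis class is defined by
that function, so the parameter is exposed directly, with an
effective-degrees-of-freedom override for users who prefer that
parametrization. The wave peak is the spline maximum at positions ≥ 0; tied
maxima report the 5′-most and are flagged.

Gene filters: low expression (mean profile depth below the cohort's 25th
percentile by default — the cutoff is unstated in the source convention, so
it is explicit and data-adaptive), missing peaks, identical peak positions
across all times, non-strictly-increasing positions, and a latest-time peak
at or before +1 kb. The rate is the OLS slope of peak position (kb) on
release time (min) — the two-point case reduces to the difference quotient —
and conditions are compared with the two-sample two-sided KS test.

## Synthetic data: what it emulates, and what it does not

The generators define the study conditions for every test:

- `make_toy_annotation()`: symmetric three-exon genes alternating strands,
  planted GGACH motifs in designated peaks, a BCA-TSS subset for m⁶Am tests.
- `simulate_merip()`: Poisson background over gene bodies, 10× IP
  enrichment in planted peaks at ~1 read/base.
- `simulate_cohort()`: 33 tumor/normal pairs plus 32 unpaired tumors,
  2,000 peaks (scaled from the ~18,000 of a full catalogue for runtime, at
  identical per-peak statistics), 195 hyper / 93 hypo planted at 2×, a 40 %
  S2 subtype at 2× on hyper peaks, 30 RBPs, log-normal levels with 0.25
  log2-s.d. noise, exponential survival with medians 11.2 (S1) and 6.6 (S2)
  months. When `driver_effect > 0`, the S2 level shift is *mediated by* the
  driver RBP: S2 tumors express the driver higher and the planted shift
  arrives through the mixing term, mirroring a regulator whose
  over-expression defines the hypermethylated subtype. This matters: with an
  independent direct subtype effect, a decoy RBP that chances into
  correlation with the subtype label can legitimately outrank the driver —
  the benchmark would mis-specify its own ground truth. At
  `driver_effect = 0` the driver is exchangeable with the decoys (a clean
  null) and the subtype effect is applied directly.
- `simulate_groseq()`: per gene, a Gaussian wavefront (s.d. 1 kb, amplitude
  5 reads/base) centered `rate × time` downstream of the TSS over a basal
  gradient, Poisson-sampled at 10 and 25 min.
- `simulate_cims()`: true sites with C→T at the adenosine +1 position and
  m/k ≤ 0.5, plus one decoy class per rejection branch.

Deliberately not modelled: fragment-length and GC bias, antibody batch
effects, overdispersion beyond Poisson, peak-boundary uncertainty, clinical
covariates associated with subtype (they are independent by default so that
association tests can be calibration-tested), and RNA-seq expression noise
models. Passing tests therefore demonstrate correctness of the statistics
and recovery under idealized noise — not robustness to the full mess of real
libraries.

## Problem sizes and reproducibility

Every stochastic function takes a `seed` and is bit-reproducible. The test
suite runs the identity check on 100 random forests; driver recovery on 20
study-scale cohorts and the null-rank uniformity on 200 reduced cohorts
(200 peaks, 12 RBPs — rank exchangeability under the null is scale-free);
subtype ARI on 5 cohorts at 1,000 resamples; calibration on 20 null cohorts
of 1,000 peaks × 33 pairs with 100 permutations each; CIMS equivalence on
10⁴ records; and elongation recovery on 50 genes. The acceptance script
(`scripts/acceptance.R`) repeats the headline quantities at study scale from
a single command-line seed.

## Known limitations

- The internal peak caller is a stand-in: no local lambda tracking, no
  fragment-model shifting; supply external calls for real data.
- Consensus clustering reports PAC and silhouettes but does not choose k.
- The Spearman p-values are asymptotic; at n < 10 the exact permutation
  distribution would differ noticeably.
- The elongation module assumes one wave per gene; convergent or nested
  transcription units violate that silently.
- The regulator ranking is correlational; a top rank nominates a candidate,
  it does not establish regulation.
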