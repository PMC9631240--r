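---
title: "Methods and design notes for midasmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for midasmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical model behind each step of the MiDAS
analysis, the parameter conventions, and the reasoning behind the design
decisions — including the places where we deliberately chose one of several
defensible definitions. Nothing here asserts empirical results beyond what the
test suite and `scripts/acceptance.R` compute.

## Coordinates and data containers

All interval data are 0-based half-open (BED convention). Binned signal lives
in `bin_track` objects: one numeric value per fixed-width bin per chromosome,
with bin `floor(pos / bin_size)` and a 10-kb default width. Missing bins are
`NA`, never silently zero — a zero is a measurement, a missing bin is not.
Conversion to `GenomicRanges` (1-based closed) happens only inside interval
operations and never leaks into user-facing tables.

## Sigma normalization

Raw per-bin counts $c_i$ are library-normalized, $n_i = c_i / \bar{c}$, with
the mean taken over nonzero bins by default, so the normalized track is
invariant under uniform rescaling of sequencing depth (a property the test
suite checks for scale factors 2, 10 and 100). Sigma values are standard
scores of the normalized counts:

$$\sigma_i = \frac{n_i - \hat\mu}{\hat s}.$$

Two estimator choices matter here:

* **Robust by default.** $\hat\mu$ is the median and $\hat s$ is
  $1.4826\,\mathrm{MAD}$ of the normalized counts. MiDAS enrichment is sparse
  and extreme (planted peaks in the synthetic model reach 8× background);
  with moment estimators the enriched bins inflate the spread estimate and
  depress their own scores. `estimator = "plain"` provides the classical
  mean/SD version for comparison.
* **Centered by default.** An uncentered ratio $n_i / \hat s$ is *not* a
  standard score: for concentrated count distributions (Poisson with large
  mean), $\hat s$ is small and *every* bin, background included, lands at a
  large positive value, which makes a fixed threshold like $3\sigma$
  meaningless. Centering puts the background at 0 so that the threshold reads
  as "standard deviations above typical background". `center = FALSE` is kept
  as an explicit option.

Degenerate inputs (all-zero track, fewer than two nonzero bins, zero spread)
are errors, not silent `NaN`s.

## Site calling

A candidate region is a maximal run of bins with $\sigma_i \ge$ `threshold`
(default 3.0) of length at least `min_run` (default 2 bins, suppressing
single-bin shot noise). Runs shorter than `min_run` are discarded *before*
merging, so an isolated hot bin cannot chain two regions together. Candidate
regions separated by at most `merge_gap` (default 2) sub-threshold bins are
then merged, tolerating dips at strong sites without bridging unrelated loci.

Within a region, a peak bin is an above-threshold bin strictly greater than
both flanking values; a plateau of equal values counts once at its leftmost
bin, and chromosome ends count as $-\infty$. Sites with two or more peak bins
are classified `"multiple"` — the signature of large under-replicated regions
with nascent synthesis at both edges. The site *anchor*, the reference point
for every downstream window, is the midpoint of the maximal-σ peak bin
(leftmost on ties).

One subtlety worth recording: the number of called sites is **not** monotone
in the threshold. Raising the threshold can split a merged region in two and
*increase* the count. The invariant that does hold — and that the tests check
on random tracks — is containment: every region called at a higher threshold
lies inside a region called at a lower one. Equivalence with an independent,
exhaustive reference implementation is checked on 1,000 random tracks
covering plateaus, ties, edge runs and all parameter combinations.

## Window conventions

Downstream annotations use half-open windows around anchors:
gene assignment and R-loop coincidence at $[a - 50\,\mathrm{kb},
a + 50\,\mathrm{kb})$, G-quadruplex density over a 110-kb window reported per
kb, condition-catalog matching at anchor distance $\le 600$ kb (inclusive),
and tumor rearrangement windows at $\pm 200$ kb. Origin proximity is the
edge-to-edge distance between the 10-kb *anchor bin* and the nearest origin
interval, 0 if they intersect and `NA` (unassigned) when the chromosome has no
origin or a `max_distance` cap is exceeded — sites without an assignable
origin are excluded from distance summaries rather than imputed.

## Expression and transcription

TPM follows the standard length-normalized definition: $r_g = c_g /
(\ell_g/1000)$, $\mathrm{TPM}_g = r_g / \sum_h r_h \times 10^6$, so TPM sums
to $10^6$ by construction (verified to a relative tolerance of $10^{-9}$).
Comparisons use $\log_{10}(\mathrm{TPM}+1)$ with an unpaired two-tailed
t-test; gene-size comparisons use the Mann–Whitney test, appropriate for the
heavily skewed size distributions involved. The transcribed/untranscribed
call supports two interchangeable rules (window signal above background on
the stronger strand, or overlap with called nascent-RNA peaks) because the
published convention varies; the rule in force is an explicit argument.

## Orientation

Replication/transcription orientation is defined only for sites with exactly
one gene in the ±50 kb window; multi-gene and gene-free sites are
`"not_applicable"` and excluded from fractions. Mean fork directionality
(RFD, rightward-fork excess in $[-1, 1]$) over a 150-kb anchor window is
compared with the gene strand: matching signs at $|\overline{\mathrm{RFD}}|
\ge \tau$ (default 0.1) are co-directional, opposing signs head-on, and
$|\overline{\mathrm{RFD}}| < \tau$ ambiguous. The definition is antisymmetric
by construction — negating the RFD track must swap co-directional and head-on
site for site — and the tests verify both the antisymmetry and exact
classification whenever the planted $|\mathrm{RFD}| \ge 0.3$.

## Matched control regions

Control bins must satisfy three constraints simultaneously: bin center inside
an early-replicating domain, at least `exclusion_bins` (default 50, i.e. 500
kb) from *every* MiDAS peak bin, and at least one R-loop peak within ±50 kb.
The eligible pool is enumerated exhaustively, then each of the `n_sets`
(default 10) sets of `n` (default 150) regions is drawn without replacement
using the derived seed `seed + s` for set $s$, so the whole draw is
reproducible from one integer and sets are mutually independent. An
undersized pool is an explicit "infeasible sampling" error reporting the pool
size.

## Tumor rearrangement frequency

For each site and cohort we report the percentage of tumors with at least one
breakpoint (either end of any record, so translocations contribute both ends)
inside the ±200 kb anchor window; a tumor counts at most once per site. The
denominators are the full cohort sizes, supplied separately, since tumors
without rearrangements never appear in the records. Cohort contrasts use
one-way ANOVA with Tukey-adjusted pairwise comparisons.

## The synthetic generator: realism and limits

`generate_world()` builds genomes that carry every structure the analysis
assumes, with known ground truth: alternating 5-Mb early/mid/late timing
domains; log-normal gene sizes (median ≈ 40 kb) with one long (300–600 kb)
gene per late domain as the fragile-site-like substrate; origins on a
jittered 300-kb grid confined to early domains; R-loop peaks on the top
expression quartile; a G4 background with extra density near planted sites;
and planted enrichment sites — by default 20 "BRCA2-like" sites in early,
highly transcribed, R-loop-marked, origin-proximal genes, with an
`aph_fraction` option that moves sites into long late genes instead. Counts
are Poisson (optionally negative binomial via `dispersion`) around a
background mean of 50 reads/bin, with Gaussian bumps raising the center bin
to `enrichment_fold` × background; 20% of sites carry two bumps 20–60 bins
apart. The RFD track is the analytic sawtooth implied by origin placement:
+1 just right of each origin falling linearly to −1 just left of the next.

Known simplifications, deliberate at desk scale:

* chromosomes are uniform-length and mappability is perfect — no gaps,
  repeats or copy-number structure, so the false-discovery behaviour of the
  caller under real artifacts is *not* modelled;
* expression, R-loops and G4s are conditionally independent given the planted
  site assignments, whereas real covariates are correlated;
* the rearrangement model plants independent per-tumor Bernoulli breakpoints
  per site plus uniform background events. Per-cohort rate recovery is
  therefore only a clean estimate of the planted rates when background events
  are disabled (`n_background_svs = 0`), which is how the acceptance test
  phrases it;
* host-gene placement enforces a 150-bin anchor separation via randomized
  greedy packing with a first-fit fallback; very dense requests fail loudly
  ("generation error") rather than silently relaxing the separation.

Two seams are intentionally separated: the world seed fixes all *structure*
(genes, domains, sites), while count noise and the SV catalog take their own
seeds, so noise can be redrawn without moving the truth — this is what makes
multi-replicate recall/false-discovery estimates meaningful.

## Numerical choices

* Bin arithmetic stays in doubles; positions up to $2^{53}$ are exact, far
  beyond genome scale.
* Tracks serialize through bedGraph with 10 significant digits; the tests
  bound round-trip error at $10^{-8}$ for RFD and exactness for counts.
* Anchor matching uses width-1 ranges with `maxgap = window - 1`, which makes
  the distance criterion inclusive ($\le$ window) and exact at the boundary;
  the tests pin the inclusive edge and the just-outside exclusion explicitly.
* JSON is written with `digits = NA` (full precision) everywhere.
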