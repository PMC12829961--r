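---
title: "Wavelet-based TAD and loop calling: model, parameters, and design notes"
author: "waveTAD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-based TAD and loop calling: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waveTAD)
```

## The problem and the model

Topologically associating domains (TADs) and chromatin loops are regions
of elevated contact frequency in Hi-C maps. Most callers bin the contacts
into a matrix at a resolution chosen *a priori* and search that matrix;
the calls then depend strongly on the chosen resolution and on sequencing
depth, and are qualitative (a structure is called or not, with no usable
strength). waveTAD instead works on the raw per-base coverage of valid
contact pairs and produces probabilistic, resolution-free, hierarchical
calls.

The chain of reasoning:

1. **Strand-oriented coverage.** A valid intrachromosomal pair has an
   upstream (5') and a downstream (3') end. A left TAD/loop boundary
   accumulates upstream ends (contacts reach downstream from it), so the
   5' per-base coverage rises sharply at left boundaries; symmetrically
   the 3' coverage drops sharply at right boundaries. Zero-coverage
   positions are removed and the remaining depths natural-log
   transformed; the compressed index map remembers the genomic position
   of every retained base.

2. **MODWT decomposition.** The compressed signal is decomposed with the
   maximum-overlap (non-decimated) discrete wavelet transform using the
   coiflet c6 filter. Scale j detail coefficients
   W~(j,t)~ = Σ~l~ h~(j,l)~ X~((t−l) mod N)~ measure the change in signal
   between neighbouring regions of width ~2^j^, one coefficient per input
   position per scale, so location is never lost. A sharp coverage
   increase excites coefficients across a range of scales at that
   location.

3. **Variance null and p-values.** Under independent noise the
   detail-coefficient variance halves with each coarser scale, so the
   noise level of every scale can be anchored to the finest scales. Each
   coefficient, standardized by the conservative null standard deviation
   of its scale, is referred to the standard-normal upper tail (the tail
   oriented so that upward coverage steps are rejections; the orientation
   is calibrated once on a synthetic step). P-values from all tested
   scales and positions of a (chromosome, orientation) signal form one
   Holm family; adjusted p ≤ 0.05 marks significant positions, and
   maximal runs of consecutive significant positions collapse to a single
   boundary call at the run's mean genomic position, carrying the run's
   minimum adjusted p (Lp for left, Rp for right boundaries).

4. **Pairing and anchor validation.** Every left boundary is paired with
   every right boundary 40 kb to 5 Mb downstream. Each candidate's apex
   pixel (left bin, right bin) is tested for focal enrichment against a
   surrounding annulus (the HiCCUPS donut layout: window half-width w = 5
   bins, peak box half-width pw = 2, the focal row/column arms excluded)
   in iteratively corrected (ICE-balanced) matrices at a ladder of
   resolutions; the expected count is the annulus mean rescaled to raw
   counts through the focal bins' balancing weights, and the p-value is
   the Poisson upper tail. A significant call needs p ≤ 0.1, at least 10
   observed contacts and 1.5-fold enrichment. The candidate's anchor
   probability ANCp is the minimum p over all resolutions with a call
   overlapping the apex within one bin; candidates with no overlapping
   call are dropped.

5. **Diamond refinement.** The transform tends to call one physical
   boundary several times across adjacent scales at slightly shifted
   positions. Same-side calls within a proximity radius are clustered and
   each cluster is replaced by the member whose TopDom-style diamond
   statistic (mean contact in the w-bin square straddling the candidate
   bin, rank-sum tested one-sided against the flanking within-region
   values) attains the minimum p, at resolutions keyed to the TAD span
   (largest ladder resolution ≤ span/10 and its next finer neighbour;
   ties go to the leftmost location).

6. **Strength.** Each surviving call is scored
   TADp = Lp × Rp × ANCp, reported with −log~10~(TADp). Smaller TADp
   (larger −log~10~) marks a stronger — more frequent or more stable —
   structure; overlapping and nested calls are all retained, so the
   output is hierarchical.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| minInsert / maxInsert | 500 / 5×10^6^ | bp | valid-pair insert window (inclusive) |
| minMapq | 30 | — | operationalizes unique mapping; NA passes |
| readLength | 50 | bp | pseudo-read extension for positions-only inputs |
| alpha | 0.05 | — | boundary cutoff on Holm-adjusted p |
| minSize / maxSize | 4×10^4^ / 5×10^6^ | bp | candidate span window (inclusive) |
| resolutions | 1,5,10,25,50 kb (<500 Mb genomes), else 5–50 kb | bp | matrix ladder |
| pw / w | 2 / 5 | bins | donut peak and window half-widths |
| donutAlpha | 0.1 | — | anchor significance threshold |
| minObs / minRatio | 10 / 1.5 | counts / fold | anchor count and enrichment gates |
| J | automatic | — | max scale: smallest support covering maxSize, capped at ⌊log₂N⌋−2 and at the feasible filter width |
| minSupport | 50 | bp | smallest tested filter support (see below) |

## Numerical and design choices

Several choices were genuinely open; the package resolves them as
follows, and each is visible (and overridable) in the API.

**Variance null on correlated coverage.** Per-base coverage is serially
correlated over at least a read length, so the independence assumption
behind the factor-of-two variance cascade fails in a specific way: the
measured coefficient variance rises from scale 1 up to the read-length
scales before decaying. Extrapolating the null from scale 1
(`scaleNull(method = "cascade")`) is then anticonservative by orders of
magnitude at coarse scales. The conservative previous-scale rule is
therefore applied to the *measured* variances:
σ²~null~(j) = max(var(W~j−1~), var(W~j~)) (`method = "empirical"`, the
pipeline default). The two forms coincide in expectation under
independence — E var(W~j−1~) = σ̂²₁/2^(j−2)^ — so the factor-2
conservatism is preserved where the independence model holds, and the
null adapts where it does not. Boundary responses occupy a vanishing
fraction of positions, so the scale's own sample variance is a valid
(noise-dominated) floor under the null.

**Smallest tested scale.** Scales whose equivalent filter support is
below one read length (default `minSupport = 50` bp) respond to the
discreteness of sparse per-base coverage — the edges of individual read
pileups — rather than to contact-frequency changes; in sparse data those
edges reach astronomical z-scores. The finest scales therefore only
inform the variance estimate, and detection starts at the first scale
whose support reaches the read length. This mirrors the transform's
standard reading: the finest scale captures high-frequency noise used to
infer the noise level of coarser scales, while signal lives at coarser
scales.

**Coefficient alignment.** Raw MODWT coefficients lag the signal feature
that drives them by roughly the analyzing filter's width. Because the
boundary signature is a step, each scale's coefficients are advanced by
the lag at which the filter's unit-step response peaks
(`alignmentShift`), which centers the response on the genomic position of
the coverage change exactly, at every scale (verified on synthetic steps).
`modwtDetail` itself returns unshifted coefficients, so the transform
matches the textbook circular-convolution definition.

**Circular end effects.** The MODWT treats the signal circularly, so
coefficients within one equivalent-filter width of either end mix both
chromosome ends and respond to the artificial wrap-around discontinuity.
Significant runs in those zones are discarded per scale. On real
chromosomes (tens of Mb) this loses a negligible fringe; on desk-scale
test chromosomes it is essential.

**Donut feasibility cut.** When the genomic distance of a pixel
approaches the maximum pair distance (here also the chromosome length of
desk-scale fixtures), the feasible position range of the upstream end
collapses to L − d and long-range background funnels into the
anti-diagonal corner of the matrix; a local annulus then underestimates
the background and manufactures enrichment. Pixels whose window comes
within 2w + 1 bins of the distance ceiling are skipped.

**Anchor dot components.** Adjacent significant donut pixels at one
resolution are one physical corner dot and are merged into a component; a
component whose genomic footprint is re-detected at a finer resolution is
suppressed in favour of the better-localized fine call, and each retained
component keeps the single candidate with the smallest pairP × ANCp.
Without this, a corner dot smeared over coarse bins validates every
near-duplicate boundary pairing within ±2 bins (±100 kb at 50 kb), which
is exactly the multi-scale redundancy the refinement stage exists to
remove. The minimum-p-across-resolutions rule for ANCp and the
drop-if-no-overlap rule are unchanged.

**Probability floors.** One-sided normal and Poisson tails underflow at
the z-scores real boundaries reach; component probabilities are floored
at 10^−100^ so TADp stays positive and −log~10~ strengths finite (a
reported strength of 300 therefore means "at or below the floor").

**Other conventions.** Coordinates are 0-based half-open throughout;
insert and span windows are inclusive at both ends ("minimum/maximum"
read as attainable); the upstream read is identified by leftmost
alignment start; ties for a run's minimum p keep the smallest scale; ties
in diamond refinement keep the leftmost location; the Holm family is per
(chromosome × orientation); natural log is used for the coverage
transform (p-values are invariant to the base since the null variance is
estimated from the transformed data itself). Hull intersection volumes
for the polarization index use Monte-Carlo rejection sampling with a
fixed seed (default 10^5^ samples), deterministic given the seed.

## The synthetic-data generator

`simulateContacts` emulates the three features the caller relies on:
a power-law distance-decay background (P(d) ∝ d^−1^ truncated to
[500 bp, 5 Mb], the canonical Hi-C decay), block-enriched intra-TAD
contacts with known boundary positions, and corner-dot anchor contacts
within ±2 kb of each TAD's (start, end) — about one bin at 5 kb
resolution. Relative component weights default to background 1.0,
intra-TAD 0.5 and anchor 0.1 per TAD (scaled by the TAD's cell
`fraction`), giving roughly 30% background contacts when four TADs are
planted — a realistic share of structured contacts for a TAD-dense
region. Read length is 50 bp; both ends are reported as 5'-most
positions in 4DN pairs format. `mixtureContacts` mixes two generators at
a given ratio to emulate heterogeneous cell populations.

What the generator does **not** emulate: restriction-site placement, GC
and mappability bias, trans contacts, copy-number variation, or the
irregular decay exponents of real chromatin. Passing the recovery tests
therefore shows that the pipeline's stages compose correctly and detect
planted structure at realistic sparsity (0.1 M pairs/Mb); it does not
certify performance on real libraries, where bias fields and
non-idealities enter upstream of the model.

## Validation problem sizes

The test suite runs the full pipeline on a 2 Mb chromosome with four
planted non-nested TADs at 0.1 M pairs/Mb (boundary recovery against the
planted truth at 10 kb leeway), a 1.2 Mb chromosome with a 400 kb TAD
containing a 100 kb subTAD (hierarchy), and a 1 Mb chromosome with one
TAD planted at cell fractions 0.25/0.5/1.0 (strength monotonicity).
Transform correctness is checked against brute-force convolution at
N = 64, the variance ratio on white noise at N = 65536, and false-call
control on i.i.d. noise coverage at N = 2^15^. These sizes keep the whole
suite within a few minutes on one core while exercising every stage at
meaningful depth.

## Known limitations

* The false-positive control of the wavelet stage assumes the empirical
  per-scale variances are noise-dominated; a chromosome that is one
  dense block of structure would inflate the null and cost sensitivity
  (never specificity).
* On read-derived coverage the formal FWER guarantee applies under the
  independence null only; in practice specificity is carried jointly by
  the conservative null and the donut anchor requirement.
* Boundaries within one filter width of chromosome ends are not
  callable (circular end exclusion).
* The donut test uses a plain Poisson model against a local annulus;
  overdispersed technical noise would need the lambda-chunking FDR
  machinery of full HiCCUPS, which is out of scope here.
* Strength saturates at the 10^−100^ component floor; very strong
  structures are reported as −log₁₀ strength 300 and are not ordered
  among themselves.
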