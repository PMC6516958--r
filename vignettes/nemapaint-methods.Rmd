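---
title: "nemapaint: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nemapaint: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What the package models

Oligopaint DNA FISH labels genomic regions with pools of synthetic oligos.
Each *primary oligo* carries a short stretch of genomic homology (42 nt
here) flanked by non-genomic *barcodes*. Barcodes serve two purposes: the
outermost pair is a PCR priming site, so any sub-pool sharing a barcode can
be re-amplified indefinitely; and every barcode is an address that unlabeled
*bridge oligos* can hybridize to, presenting docking sites for dye-bearing
*detection oligos*. With a nested barcode architecture — whole chromosome,
3 Mb segment, 500 kb segment — a single synthesis run yields a library
addressable at three scales. `nemapaint` implements the full computational
side of this strategy: probe mining, even-density selection, barcode and
oligo assembly, in-silico sub-pool amplification, bridge/detection wiring
with combinatorial color codes, and the downstream 3D chromosome-territory
quantification, plus simulators that make everything testable on synthetic
data.

## Probe mining

A candidate is a 42-nt window that passes four independent screens
(`evaluate_probe()` returns each component and their conjunction):

1. **Uniqueness.** Every constituent 18-mer must occur exactly once
   genome-wide. Counts are canonical (a k-mer and its reverse complement
   share one count covering both strands); k-mers spanning an `N` are not
   indexed and fail the screen. A palindromic k-mer counts once per strand
   and therefore twice per site — a deliberately conservative reading.
   The screen is k-mer based, not alignment based: the index answers
   "does this exact 18-mer recur", which over-rejects near-repeats less
   than a seed-and-extend aligner would over-accept them, and is exactly
   reproducible by a dictionary scan (the test suite's oracle).
2. **Tm window** (default 60–80 °C) under the unified nearest-neighbor
   model with the entropic salt correction
   $\Delta S' = \Delta S + 0.368\,(N{-}1)\ln[\mathrm{Na}^+]$ at 0.39 M
   (2× SSC) and $T_m = \Delta H / (\Delta S' + R\ln(C_T/4))$ at
   $C_T = 50$ nM total strands. The hybridization buffer's 50% formamide
   depresses the *operational* Tm by a configurable 0.65 °C/% — that
   correction is applied by `melting_temperature()` on request but **not**
   during screening: a 42-mer's salt-only Tm sits in roughly 68–90 °C, so
   a 60–80 °C window is only meaningful pre-formamide. (We verified the
   numbers against an independent nearest-neighbor implementation; the
   formamide-corrected range, ~36–58 °C, cannot intersect the stated
   window.)
3. **GC window**, default 0.30–0.70.
4. **Repeat and structure screens.** No homopolymer run longer than 5, no
   dinucleotide tandem longer than 4 units, and no self-complementary
   hairpin stem longer than 7 bp with a loop of at least 3 nt (dynamic
   program over complementary position pairs, checked against quadratic
   enumeration in the tests).

Every start position is evaluated (stride 1) and the passing windows are
greedily thinned left-to-right to a non-overlapping set. That makes the
candidate list a deterministic function of genome and parameters, which in
turn makes "every fifth candidate" a well-defined selection rule. The
published library's own thresholds were never printed, so the defaults here
follow common Oligopaint practice and the per-chromosome candidate counts
of the original design are *not* treated as exact reproduction targets;
what is reproduced exactly is the downstream arithmetic (below).

## Even-density selection and the summary table

`subsample()` keeps candidates at indices $0, N, 2N, \dots$ (default
$N = 5$) **independently within each 500 kb segment**. Restarting per
segment guarantees every 500 kb sub-pool is populated and makes the
selection local: published chosen counts deviate slightly from
`ceil(candidates/5)`, consistent with per-bin decimation.

`spacing_stats()` follows published table semantics: the *endpoint mean*
is `(last - first) / n` — division by `n`, not `n - 1`, which is what
reproduces the printed 595.8 bp for the first chromosome (the `n - 1`
variant gives 595.9) — and density is `n / (span/1000)`. The totals row of
`summarize_library()` **sums** the two count columns and takes the
**unweighted mean** across chromosomes for per-kb and distance columns;
those semantics reproduce the printed 8.81 candidates/kb, 1.71 chosen/kb
and 584.8 bp values. One printed value resists this arithmetic: the third
chromosome's mean distance (595.9) is not `span/n` of its printed row
(596.6) although all five other rows agree to the decimal; the package
flags rather than guesses (nothing in the toolkit depends on it).
Coordinates are 0-based half-open internally (BED convention); printed
1-based table coordinates only ever enter via differences, where the
convention cancels.

## Barcodes, oligo assembly, and the PCR model

The 150-nt layout is, 5′→3′: chromosome-forward (20) | 3 Mb (23) | 500 kb
(23) | homology (42) | segment-specific (22) | chromosome-reverse (20).
Only the 42/150 split and the five roles are fixed by the architecture;
the individual slot lengths are this package's choice and are fully
configurable. The segment-specific slot is the "spare" per-500 kb barcode
reserved for boosting detection efficiency; the package both carries it
and uses it as the second addressable barcode for 500 kb-level pair codes.

Barcodes are rejection-sampled under: pairwise Hamming ≥ 8 within a role,
GC 0.40–0.60, hairpin stem ≤ 6, mutual 3′-end complementarity ≤ 4 bp
(primer-dimer guard), and genome exclusion — no 15-mer of any barcode may
occur in the target genome (so detection chemistry cannot nucleate on
genomic sequence). Generation is seeded and deterministic, and fails
loudly, naming the dominant violated bound, when the attempt budget is
exhausted (e.g. pigeonhole-infeasible requests).

The chromosome barcodes double as the PCR primer pair: the reverse slot
stores the reverse complement of the reverse primer's binding site, so an
oligo amplifies iff its 5′ end equals the forward primer and its 3′ end
equals the reverse complement of the reverse primer. `simulate_pcr()` is
deliberately an exact-string model — barcodes are designed orthogonal, and
exactness is what lets the test suite demand `simulate_pcr()` ≡
metadata-based `select_subpool()` on every synthetic library rather than
"approximately equal". Mismatch-tolerant priming would blur that oracle
without modeling anything the architecture relies on.

Segment indices are chromosome-wide ordinals (`floor(start / size)`), for
both 3 Mb and 500 kb levels; nesting (500 kb segment $j$ lies inside 3 Mb
segment $\lfloor j/6 \rfloor$) is asserted as an invariant.

## Bridges, detections, and color codes

A bridge is `revcomp(target barcode)` followed by two tandem copies of a
20-nt dock, so both detections on a bridge carry the same dye; its length
is the target barcode length plus 40 (63 nt for the 23-nt inner barcodes,
60 nt for the 20-nt chromosome barcodes). A detection oligo is the dock's
reverse complement, dye-labeled at both termini. With two bridges per
primary (5′ and 3′ barcodes), two detections per bridge, and two dyes per
detection, each primary oligo is recognized by $2{\times}2{\times}2 = 8$
fluorophores.

Color codes are nonempty channel subsets of size ≤ 2 by default:
$\sum_{s=1}^{2}\binom{3}{s} = 6$ targets on three channels. Assignment is
deterministic — singletons in channel order, then pairs lexicographically —
so six targets receive {A}, {B}, {C}, {A,B}, {A,C}, {B,C}. For a pair
code the two dyes are routed through *distinct* barcodes of the same
primary (5′ and 3′), one bridge each; whether the published experiments
used this routing or mixed bridge pools is not stated, so the package
picks the 5′/3′ routing (it preserves one-bridge-one-dye addressability)
and keeps the wiring in one place, `compile_hybridization()`. Each dye
owns exactly one dock, preventing color bleed by construction.

## Territory quantification

Mirrors the standard ImageJ workflow on per-nucleus crops: per channel,
an **isodata / iterative-intermeans** threshold is computed on the whole
stack's intensity histogram (threshold updated to the rounded midpoint of
the two class means until stable; "Default auto" thresholding behaves this
way, and thresholding the stack globally matches applying one 'auto'
threshold across every image of a stack), then 3D connected components are
extracted under **26-connectivity** (the 3D objects counter's default; 6
is available), components **strictly larger than 30 voxels** are kept, and
survivors are merged into one territory mask per channel. Volumes, the
symmetric pairwise intersection matrix, and row-normalized overlap
fractions are all emitted — the literature is ambiguous about whether
overlap was reported absolute or normalized, so both are available.

Degenerate inputs are explicit errors: a constant image has no isodata
threshold; mismatched channel dimensions refuse to combine.

## The simulators, and what a green test establishes

`simulate_genome()` draws i.i.d. bases at a target GC (default 0.36,
roughly the nematode genome's composition) and implants exact repeat
blocks at recorded coordinates. It emulates the *combinatorial* structure
mining depends on — uniqueness, GC, implanted duplications — but not real
genome features: no repeat families, no GC isochores, no assembly gaps.
Synthetic candidate densities (~20/kb at default filters) are therefore
higher than the ~9/kb observed on a real genome, and tests assert
reproducibility and filter monotonicity, not the real-genome density.

`simulate_nucleus_image()` renders each territory as a voxelized ellipsoid
in its own channel over a uniform background (default 10 vs 200 counts),
optionally Gaussian-blurred (σ in voxels) and Poisson-degraded — Poisson
only, since shot noise is what stresses a histogram threshold; camera read
noise adds nothing qualitatively and is omitted. Ground-truth volumes and
overlaps are recorded from the binary masks *before* blur and noise. For
partial-overlap placement the generator samples candidate positions and
accepts when the realized pairwise intersection fraction is near the
requested target, recording the realized (not requested) value as truth.
Across seeds 1–10 the pipeline recovers volumes within 10% and overlaps
within 15% at blur σ = 1 without noise; inflating territory radii 15%
(a 1.52× true volume change) produces a ≥ 40% measured volume increase —
the in-silico analogue of territory decondensation. A green run
establishes that the *measurement pipeline* is calibrated on ellipsoidal,
uniformly stained objects; it says nothing about segmentation of real
nuclei, chromatic registration, or optics, which are upstream of this
package's inputs.

TIFF support is a minimal built-in baseline reader/writer (uncompressed
grayscale, 8/16-bit, multi-page) because no TIFF package exists in the
supported R stack; it is validated in both directions against an external
reader in the test suite.

## Numerical and engineering choices

* Canonical k-mer = lexicographic min of k-mer and reverse complement,
  2-bit-packed (k ≤ 31); counting is exact, no sketches.
* Thinning, selection, barcode search, and color assignment are all
  deterministic given a seed; identical inputs give byte-identical
  outputs, which the suite asserts.
* The hairpin screen is evaluated last in the window scan (it is the only
  quadratic-cost filter) after the prefix-sum filters (uniqueness, GC,
  repeats, rolling nearest-neighbor Tm) have pruned.
* Ties in the isodata update are settled by integer rounding of the
  midpoint; iteration always terminates because the threshold moves
  monotonically within a finite histogram.
* Infeasible requests (barcode pigeonhole, unplaceable territories,
  over-capacity color schemes) raise typed conditions naming the bound.

## Known limitations

* Uniqueness is k-mer exact-match only; no alignment-based mappability or
  external repeat masking.
* The PCR model is exact-match by design (see above).
* Bridge/detection hybridization thermodynamics are not modeled; bridges
  are sequence-constructed, not energy-optimized.
* Selection is plain decimation; no optimal-spacing optimization.
* The quantification assumes per-nucleus crops; nucleus detection and
  segmentation are out of scope.
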