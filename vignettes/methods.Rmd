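---
title: "Models and methods behind spotcode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spotcode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotcode)
```

# The encoding model

`spotcode` implements combinatorial color barcoding for iterative FISH.
An experiment with `F` spectrally separable fluorophores and `N`
hybridize–image–strip rounds assigns each target a length-`N` string over
the digit alphabet `1..F`; the channel map defaults to Cy5 = 1, Cy3 = 2,
FAM = 3. The code space holds `F^N` strings, so three colors and two
rounds address nine targets, and the code capacity grows geometrically
with rounds rather than with fluorophores.

Codes are enumerated lexicographically and then shuffled with a
user-supplied seed before assignment. No assignment rule is implied by
the chemistry, so any deterministic rule is admissible; the
shuffle-by-seed makes assignments reproducible while avoiding an
accidental correlation between enumeration order and panel order. The
digit `0` never appears in a code: it is reserved for a round in which a
spot produced no detectable signal, so decoders can distinguish "missing
data" from any legitimate color.

Two panel modes exist. In `per_gene` mode each target carries its own
code (single-molecule readout). In `per_cell_type` mode, built with
`assign_panel()`, all marker genes of one cell type share the type's
code: individual transcripts are then not distinguishable within a cell,
but the cell as a whole displays one dominant color per round, which is
what the mask decoder exploits. We deliberately do not implement
error-correcting (Hamming-distance) code subsets: the design space here
is the full code space, and redundancy-based correction is a separate
concern left out of scope.

# Probe design arithmetic

Primary probes are 65-nt oligos: a 35-nt target-binding region followed
by a 30-nt readout region that recruits the amplifier. `validate_probe()`
checks the length partition, the DNA alphabet, the homopolymer rule (no
run of more than six identical bases; a run of exactly six passes), and
the target region's duplex melting temperature.

Melting temperatures come from unified nearest-neighbor thermodynamics:
per-dinucleotide stacking enthalpies and entropies plus terminal
initiation terms, an entropic salt correction of
`0.368 (L-1) ln[Na+]` cal/(mol K), and
`Tm = 1000 ΔH / (ΔS + R ln(C/4)) − 273.15`. Defaults are
`[Na+] = 0.39 M` (about 2× SSC, a typical hybridization buffer) and a
total strand concentration of `5e-7 M`. These conditions are
configuration, not constants, because published designs rarely state the
thermodynamic conditions under which their thresholds were computed; the
default minimum proper-duplex Tm is 70 °C.

Two optional screens are included. The off-target screen finds the
longest contiguous stretch of the target region whose reverse complement
occurs in a user-supplied background set and scores that stem's Tm. The
secondary-structure screen scores the strongest self-complementary stem
of at least six bases as a hairpin/self-dimer proxy. Both thresholds
(72 °C and 76 °C by default) carry explicit direction flags
(`*_is_upper`): conventional usage treats them as upper bounds (a strong
off-target or hairpin stem is bad), but the thresholds' published
descriptions are ambiguous about direction, so we expose the comparison
direction rather than guessing. The secondary screen is a stem-finding
heuristic, not a thermodynamic folding model; users needing real folding
energies should use a dedicated RNA/DNA folding tool.

All sequence windows are 0-based and half-open, everywhere.

## Amplifier arithmetic

The signal amplifier modeled here is a layered DNA-tetrahedron
dendrimer: a core monomer (layer 0) exposes three sticky ends, each
recruiting a layer-1 monomer, which in turn each recruit three layer-2
monomers; terminal monomers carry three dye strands each. Layer `k`
therefore holds `3^k` monomers, the default two-shell probe has
1 + 3 + 9 = 13 monomers and 9 × 3 = 27 fluorophores, and equal-
concentration assembly requires mixing volumes in the same geometric
ratio (5 µL core → 15 µL → 45 µL at ratio 3). Tetrahedron edges of 17 bp
at the B-form rise of 0.34 nm/bp give the characteristic 5.8 nm size.
`validate_sticky_ends()` checks that declared adjacent-layer overhangs
are exact reverse complements and exhaustively scans all overhang pairs
for unintended complements within one layer or across non-adjacent
layers, either of which would break the strictly layered assembly order.

# The synthetic acquisition model

The simulator exists so that registration, detection, linking, decoding
and QC can be exercised against exact ground truth without image
downloads. It emulates, per round and channel:

* **Spots** as isotropic 2-D Gaussians with σ = 1.3 px, the standard
  approximation of a diffraction-limited PSF at Nyquist-ish sampling
  (≈ 0.108 µm pixels). Amplitudes are drawn once per spot
  (normal, mean 3000, sd 300 counts, floored at a quarter of the mean)
  and reused across rounds.
* **Noise** as Poisson shot noise on the expected counts plus Gaussian
  read noise (sd 5), on a constant background of 100 counts, quantized
  to integers and clipped to the 16-bit range (never wrapped). The
  default contrast corresponds to a peak SNR well above 8.
* **Drift** as one rigid, possibly fractional translation per round
  (round 1 fixed at zero, others uniform integers in ±3 px by default),
  matching the rigid model the registration stage assumes. No rotation,
  scaling, or chromatic offset is simulated.
* **Stripping residue**: a fraction ρ (default 0.05) of the signal a
  spot emitted in round r persists into round r+1 in the same channel at
  the same physical position, emulating incomplete probe removal. This
  is the mechanism that makes the decoder's same-round conflict
  resolution necessary, because residual spots are bright enough to be
  detected at the default settings.
* **Dropout**: each spot independently fails to appear in a round with
  a configurable probability (default 0), exercising the missing-digit
  ("0") path of the decoder.
* A **fiducial channel** (DAPI stand-in): a static blob field, the only
  round-invariant structure, used for registration. In tissue mode the
  nuclei double as fiducials.

Tissue mode packs non-overlapping circular cells on a jittered grid
(radius 6–9 px), assigns types by frequency sampling or by horizontal
depth bands (`layered = TRUE`), and fills each cell with
Poisson-distributed spots that all carry the cell's type code (mean
10 markers × 3 spots per marker).

What the simulator does **not** emulate — and therefore what passing
tests cannot certify on real data: autofluorescence textures and
structured background, optical aberrations and z-extent, chromatic
misalignment between channels, cell-shape irregularity and touching
cells, expression of marker genes in off-type cells, and segmentation
errors (the mask is ground truth by construction). Accuracies measured
here are upper bounds for real experiments; the value of the simulation
is exactness of ground truth, not realism of difficulty.

A hybridize/strip cycle simulator renders a single labeled cell over
`n` rounds with bound signal `B_r = S + ρ B_{r-1}`; with fresh signal
`S = (k−1)·background` the post-hybridization contrast stays near `k`
(10 by default) while the post-strip frame decays toward background,
giving the QC retention statistics a controlled input over 15 rounds.

# Registration

Shifts are estimated as the argmax of the mean-subtracted, globally
normalized circular cross-correlation, computed by FFT and searched
within ±`max_shift` (default 10 px). The registration channel is the
fiducial/nuclear channel, the only signal that persists across rounds in
this protocol. Ties at the peak are broken by the smaller shift
magnitude, then row-major order, making results deterministic on
pathological inputs. Integer shifts are the default (the peak of the
discrete correlation); an optional subpixel mode refines the peak on a
10× upsampled local correlation evaluated by matrix-multiply DFT over a
±1.5 px neighborhood.

Undoing a shift uses pixel relocation with NA fill for integer shifts
(vacated pixels are masked from downstream statistics) and an exact
Fourier phase shift for fractional ones. The Fourier path wraps
periodically at the borders but round-trips losslessly, which the tests
exploit; border effects are confined to a `max_shift`-wide margin.

Constant images raise a degenerate-input error rather than returning an
arbitrary shift.

# Spot detection and localization

Detection mirrors the standard Laplacian-of-Gaussian single-molecule
detector: the image is filtered with a scale-normalized LoG at the PSF
scale, local maxima above a robust threshold are kept, and non-maximum
suppression enforces a minimum separation (default 2σ), greedily by
descending response with row-major tie-breaking. The threshold is
expressed in multiples (default 8) of the median absolute deviation of
the filter response, so one default transfers across intensity scales;
the scale is floored at `1e-6` of the peak response magnitude because on
noiseless synthetic planes the MAD collapses to FFT round-off and would
otherwise admit numerical ripple as detections. Positions are refined by
an intensity-weighted centroid on a background-subtracted window
(radius `⌈2σ⌉`), which recovers planted fractional positions to better
than 0.15 px noise-free; window clipping at the image border is flagged
per spot rather than silently tolerated.

# Decoding

**Single-molecule route.** Within each round, detections from different
channels closer than the conflict radius are collapsed; the brightest
member becomes the round's representative and the fainter members
(typically stripping residue, ~5% of the real amplitude) are retained
only to set the `ambiguous` flag. Representatives are then linked
between consecutive rounds by mutual nearest neighbors within
`link_radius` (default 1.5 px post-registration — half the default
minimum spot separation, and several times the expected subpixel
localization error). Chains have at most one representative per round by
construction; unlinked detections become single-round chains. Each
chain's digit string is looked up in the codebook and every chain
receives exactly one status: `decoded`, `ambiguous` (decoded with a
same-round conflict), `incomplete` (a "0" digit), or `unknown_code`
(complete but unassigned — reported, never reassigned). The
status counts partition the chain set exactly; nothing is dropped
silently.

**Cell-atlas route.** Planes are first normalized per (round, channel)
by `(I − median) / (q99 − median)`, clipped at zero — a strictly
monotone transform that makes the three color channels comparable
without assuming equal staining efficiency; flat planes are a hard
error. For every labeled region and round, the mean normalized intensity
of each channel over the region's pixels is computed and the winning
channel supplies the digit (mean, not median, so results are bit-for-bit
reproducible and ties are well-defined). Exact ties are flagged and
resolved by fixed channel priority (Cy5 > Cy3 > FAM, i.e. the smaller
digit). The concatenated digits type the cell through the codebook;
codes outside the panel leave the cell untyped and counted separately,
and atlas frequencies are computed over typed cells only.

# QC statistics

* **Colocalization** uses greedy one-to-one matching by ascending pair
  distance within a radius (default 2 px at the simulated scale). The
  matched fraction plus the test-only (false-positive) and
  reference-only (false-negative) rates partition both sets; swapping
  the inputs swaps the two rates exactly.
* **Retention** converts per-round post-hybridization and post-strip
  means into background-relative contrast ratios and flags rounds below
  a configurable floor.
* **Distance to nucleus** is the exact Euclidean distance from each
  (subpixel) spot to the nearest boundary pixel of a binary mask,
  negative inside. Boundary pixels are mask pixels with a 4-neighbor
  outside the mask; the tests verify equivalence with a brute-force
  all-boundary-pixel scan.
* **Depth profiles** are 1-D Gaussian KDEs of normalized cortical depth
  per cell type, with reflection at both ends of `[0, 1]` so every
  profile integrates to 1 on the unit interval (plain KDEs leak several
  percent of mass past the boundaries at realistic bandwidths, which
  would distort flat profiles). Bandwidth follows Scott's rule
  (`stats::bw.nrd`) unless overridden; types with fewer than two cells
  are skipped with a warning. Depth itself is
  `d_edge / (d_edge + d_deep)` between two user-supplied polylines
  (cortical edge and deep boundary), normalizing for local cortex
  thickness; the axis construction is a package choice, as no canonical
  definition exists.
* **Group comparisons** are limited to mean ± sd and an unpaired
  two-tailed Welch t test; no multiple-testing correction is applied at
  this level.

# Problem sizes and numerical choices

The bundled tests and the acceptance script run on simulated scenes
sized to exercise realistic densities while staying light: 512×512 px
fields with 600 spots (9 genes) or 300 cells (6 types at frequencies
0.4/0.2/0.1/0.1/0.1/0.1), 15-round retention series on 128×128 fields,
and 64–96 px images for the oracle-equivalence checks. At these sizes
the complete pipeline decodes a scene in a few seconds. Determinism is
end to end: every stochastic step runs under a caller-supplied seed
through an RNG-state-preserving wrapper, identical configurations
reproduce bit-identical stacks and output files, and all thresholds with
tie potential (correlation peaks, equal filter responses, equal channel
means) carry explicit deterministic tie-breaks.

# Known limitations

* Registration is rigid translation only; rotation, scaling and
  non-rigid deformation are out of scope, as is chromatic-aberration
  correction.
* Detection and localization are 2-D; volumetric stacks are not
  supported.
* The melting-temperature model covers perfectly matched DNA/DNA
  duplexes; mismatches, dangling ends and RNA/DNA hybrids are not
  parameterized.
* The off-target screen requires an explicit background sequence set and
  finds only contiguous exact complements; it is not a genome-scale
  thermodynamic cross-hybridization search.
* Codebook decoding is exact-match; no error correction is attempted for
  corrupted digit strings, which are reported as `unknown_code` or
  `incomplete` instead.
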