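---
title: "Quantifying RNA origami nanotubes: worm-like-chain inference, trajectory statistics and GUV morphometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RNA origami nanotubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanotrace)
```

## Scope

RNA origami tiles that fold during transcription can polymerize into
micrometre-long hollow nanotubes — genetically encodable cytoskeleton mimics
for synthetic cells.  Characterizing them raises three recurring
quantitative tasks:

1. **Stiffness from images.**  Nanotubes deposited on mica and imaged by
   AFM are traced, and the persistence length $P$ is inferred from how the
   end-to-end distance grows with contour length.
2. **Stiffness and structure from coarse-grained simulations.**
   Nucleotide-resolution trajectories of assembled tubes yield per-frame
   persistence lengths, mean structures, per-nucleotide fluctuations
   (RMSF), designed-bond occupancies and inter-duplex angles.
3. **Vesicle morphometrics.**  When the tubes are expressed inside giant
   unilamellar vesicles (GUVs), confocal images are reduced to vesicle
   detections, nanotube area fractions, radial distributions of the RNA
   signal (cortex vs lumen), and shape descriptors of deformed membranes.

`nanotrace` implements all three, together with a synthetic-data generator
that produces every input with a full ground-truth registry.  Because each
estimate can be checked against a known truth, the whole pipeline is
testable end to end — which is how the package's test suite uses it.

## The worm-like-chain model

A semiflexible filament of contour length $L$ and persistence length $P$
has mean squared end-to-end distance

$$\langle R^2 \rangle = 2sPL\left(1 - \frac{sP}{L}\left(1 -
e^{-L/sP}\right)\right),$$

where $s$ is a surface parameter describing how surface deposition modifies
the apparent chain statistics; it is fixed at $s = 1$ throughout
(equilibrated deposition).  Note that $s$ and $P$ enter only through the
product $sP$, so freeing $s$ cannot decouple the two; `fit_wlc(fix_s =
FALSE)` therefore estimates the product.

`wlc_r2_theory()` evaluates the relation; `fit_wlc()` inverts it.

### The sampler and its calibration

`sample_wlc_chain()` draws discrete chains of exactly equal segments
(default $\Delta = 5$ nm).  In 2D, successive segments turn by independent
Gaussian angles of variance $\sigma^2 = \kappa\,\Delta/P$ with
$\kappa = 2$ (the constant ships as `wlc_kappa_2d`).  This makes the
per-step tangent correlation $e^{-\Delta/P}$ exactly, and brute-force
ensemble fitting confirms that the discrete ensemble obeys the relation
above with $s = 1$: fitting exact discrete expectations recovers $P$ to
better than $0.01\%$ for $P$ between 500 and 5000 nm, and fitting $10^4$
sampled chains recovers it within 2% (a property test).  The 3D sampler
draws the polar angle from a von Mises–Fisher distribution whose
concentration is solved so that $\langle\cos\theta\rangle = e^{-\Delta/P}$
holds exactly as well.

Whether mica-deposited filaments are 2D-equilibrated or 3D-projected is an
open question for any such analysis; the generator commits to
2D-equilibrated chains *calibrated to the fitted relation*, which makes
recovery tests well-posed: the fitter is asked to return exactly the
number the generator was given.

Contour lengths follow a lognormal distribution parameterized by its target
mean and standard deviation (moment matching) and truncated at a minimum
length, reproducing the broad, positive length distributions of
co-transcriptionally grown populations.

### Fitting: weighting and masking

`fit_wlc()` performs nonlinear least squares of $R^2$ on $L$
(Levenberg–Marquardt, `minpack.lm`), initialized at $P_0 = \max(L)/4$ and
bounded in $(0, 10\max(L))$.  Two details matter in practice:

* **Variance weighting.**  The conditional spread of $R^2$ given $L$ grows
  steeply with $L$: for the calibrated 2D ensemble the relative standard
  deviation is well described by $\mathrm{cv}(x) \propto x/(1 + x/5)$ with
  $x = L/sP$ (measured by sampling 2000 chains per length over
  $x \in [0.06, 5]$).  An unweighted fit is therefore dominated by the few
  longest filaments and scatters wildly (tens of percent between
  replicate datasets).  The default fit runs an unweighted pilot pass,
  freezes model-based weights $1/\sigma_i^2$ with
  $\sigma_i = \hat\mu_i\,\mathrm{cv}(x_i)$ evaluated at the pilot estimate,
  and refits once.  Freezing the weights (rather than iterating them to
  convergence) avoids the well-known bias of mean-dependent weight
  iteration.  `weighting = "none"` restores the plain fit.
* **Residual masking.**  `mask_and_refit()` removes records whose raw
  residual exceeds one residual standard deviation and refits a single
  time.  Masking is one-pass by default; an iterate-to-convergence option
  exists but is off.  On noiseless data the residual spread is numerically
  zero and nothing is masked.

Records below 200 nm contour length are excluded before fitting
(`filter_records()`; "under 200 nm" is read strictly, so a 200.0 nm record
is kept) — short detections are dominated by imaging resolution.

## From image to records

`render_afm_scene()` rasterizes chains onto a calibrated pixel grid,
dilates with a disc of the nominal tip radius (a morphological stand-in
for tip convolution that reproduces the characteristic width broadening —
an 11 nm tube images at roughly twice its design width), adds the tube
height over a flat background, and optionally Gaussian height noise.  The
binary mask is exactly the tip-dilated union of the rasterized chains.

`skeletonize_mask()` thins the mask (Zhang–Suen, topology-preserving);
`trace_longest_path()` resolves branching by an exact search over all
leaf pairs of the weighted skeleton graph (axial steps 1 px, diagonal
steps $\sqrt 2$ px), returning the weighted-longest leaf-to-leaf geodesic
with deterministic lexicographic tie-breaking.  Closed rings are traversed
from the lexicographically smallest pixel; ring-shaped detections are
excluded from persistence fitting by default (`exclude_cycles = TRUE`),
since whether closed rings entered the published fits is not stated and a
ring has no meaningful end-to-end distance.

`measure_filament()` turns a pixel path into physical lengths.  Two
chain-code estimators are provided:

* `"freeman"` (default): axial steps count 1, diagonal steps $\sqrt 2$.
  This is the textbook rule, but it overestimates the length of digitized
  straight segments by up to 8% (mean $\approx 5.5\%$ over orientations).
* `"kulpa"`: the same weights rescaled by 0.9481, which removes that mean
  bias.

The choice matters: in the stiff regime ($L \lesssim P$) the fitted $P$ is
extremely sensitive to relative errors in $L$ at fixed $R^2$ — a 5%
contour inflation can depress the fitted persistence length by 30% or
more.  The AFM pipeline presets therefore measure with `"kulpa"`; the
plain Freeman weights remain the `measure_filament()` default so that the
elementary chain-code identities hold as documented.

Residual biases that remain after correction are genuine resolution
effects shared with any skeleton-based analysis: thinning a tip-dilated
flexible filament smooths wiggles below the tube half-width, so for the
most flexible preset (0.8 µm) the recovered median still sits a few
percent high.  End shortening by skeleton erosion, by contrast, is benign:
a sub-chain of a worm-like chain is itself a valid (shorter) record.

Row levelling of height images — the usual raster-AFM preprocessing — is
unnecessary for the synthetic renderer (its background is already flat)
and is deliberately not applied by default; masks come either from the
generator registry or from Otsu thresholding of the height image, a
documented switch (`mask_source`).

## Presets and end-to-end recovery

Two study-condition presets drive the recovery tests
(`afm_preset()`):

| preset | $P$ (µm) | contour mean ± s.d. (nm) | truncation |
|---|---|---|---|
| `wt-afm` | 3.4 | 970.9 ± 735.1 | 200 nm |
| `dsov-afm` | 0.8 | 706.1 ± 563.8 | 200 nm |

Scenes use 4 nm pixels, 6 nm tube height, 5 nm tip radius, no noise.
`run_afm_pipeline()` chains sampling, rendering, tracing, filtering,
fitting and masking; `recover_persistence_length()` reports the median
fitted $P$ over seeds.  The shipped checks use 300 filaments per seed and
5–7 seeds per preset (a few minutes per preset on one CPU); at that size
the median recovers both presets within the 15% band used by the tests.
A single 300-filament fit has ~5–8% spread, so the median over several
seeds is the meaningful summary.

The flexibility of a population is summarized by the ratio of persistence
length to mean contour length (`flexibility_ratio()`, two significant
figures): 3.4 µm over 970.9 nm gives 3.5 (semiflexible), 0.8 µm over
706.1 nm gives 1.1 (flexible).

## Coarse-grained trajectories

`build_tile_assembly()` places three-duplex tiles (intrinsic curvature
120°, three tiles closing each ring, 11 nm outer diameter) on a
cylindrical lattice, one single-stranded RNA molecule per tile, with a
designed-bond registry: intra-duplex stems, two internal kissing loops of
12 designed bonds per tile, and the corner-to-corner external kissing
loops (a–a′, b–b′) joining successive layers — 2 × 3 × 99 = 594 for a
100-layer tube.  A 100-layer assembly is 300 tiles and 90,000 nucleotides
at the default 300 nt per tile.  The layer rise defaults to 11 nm (the
tile length runs along the axis), so 100 layers span about 1.1 µm.
For tiles of at least 192 nt the registry windows are chosen so no
nucleotide belongs to two designed pairs, which keeps stochastic bond
breaking exactly pair-local.

`generate_nanotube_trajectory()` makes each frame an independent 3D
worm-like-chain realization of the tube axis at a prescribed bending
persistence length, decorates each layer rigidly (frames
parallel-transported along the axis), optionally jitters nucleotides, and
breaks designed bonds at a configurable per-frame rate by displacing one
partner beyond the bond-call distance.  Output is written in the classic
oxDNA text dialect (topology header `N_nt N_strands`; configurations with
`t =`, `b =`, `E =` header lines and one row of position, base vector,
normal vector, zeroed velocities per nucleotide; positions in simulation
units of 0.8518 nm).  The streaming reader never holds more than one frame
when given a callback.

Analyses mirror standard practice:

* `align_and_mean()` superposes frames by Kabsch rotation onto the first
  frame (a two-pass mean-reference mode exists), returns the mean
  structure and the frame closest to it (the centroid structure).
* `compute_rmsf()` is the per-nucleotide root-mean-square fluctuation;
  under isotropic jitter of s.d. $\sigma$ it converges to
  $\sigma\sqrt 3$ (a closed-form check in the tests).
* `bond_occupancy()` calls a designed bond formed when the partner
  distance is below a cutoff — an engine-independent proxy for energy
  based bond calls, exact on generator output.  The default cutoff
  (`default_bond_cutoff()`) is the maximum designed-pair distance of the
  ideal geometry plus 0.5 nm, so unperturbed frames have occupancy 1.
  Occupancy averages pairs within a frame, then frames; for a fixed
  region size this equals the overall fraction (the alternative ordering
  is a no-op here, but would differ for time-varying regions).
* `kl_quality_filter()` accepts a run only if every internal kissing loop
  keeps, on average over frames, at least 11 of its 12 designed bonds.
* `duplex_angle_beta()` reports the angle between best-fit duplex axes,
  oriented 5′→3′ so parallel reads 0° and antiparallel 180°.
* `convert_time()`: one reduced time unit is 3.03 ps, so `dt = 0.003`
  steps are 9.09 fs and $10^9$ of them 9.09 µs.
* `frame_schedule()` / `select_final_fraction()`: saving every
  $5\times10^5$ steps over $10^9$ steps yields 2000 frames; the final-10%
  rule ($t \ge 9\times10^8$, inclusive) keeps 201 per run, 603 over
  triplicates.

Per-frame persistence (`per_frame_persistence()`) restricts to the middle
80% of layers (dropping $\lceil 0.1 n \rceil$ at each end: layers 11–90 of
100), forms every layer pair with $L$ the summed centroid path and $R^2$
the squared direct distance, and runs the same fit-and-mask machinery per
frame.  No length filter is applied to simulated pairs by default (the
200 nm rule addresses imaging resolution, which simulations do not have);
a `min_length_nm` argument exposes it.  Pairs within one frame are highly
correlated, so per-frame estimates scatter widely and their median over a
few hundred frames sits systematically high by roughly 10% — within the
15% self-consistency band the tests assert, but worth remembering when
reading per-frame summaries.

## GUV morphometrics

`make_guv_scene()` renders a membrane annulus per vesicle — optionally
deformed as an ellipse and/or by low-order radial Fourier modes
$r(\theta) = r_e(\theta)\,(1 + a_2\cos(2\theta + \varphi_2) +
a_3\cos(3\theta + \varphi_3))$ — plus an RNA channel in one of four modes
(`none`, `lumen`, `cortex`, `network`).  Channels carry a nonzero uniform
background (defaults 0.1 and 0.05 of the membrane peak): real confocal
images always have a background mode, and minimum-cross-entropy
thresholding degenerates without one.  Overlapping vesicle interiors
beyond a tolerance are a placement error.

* `detect_guvs()`: circle Hough transform (edge pixels vote through
  ring-kernel convolution per candidate radius, FFT-based via `EBImage`),
  greedy peak extraction with non-maximum suppression.  The radius grid
  step and acceptance score are configuration values whose defaults were
  set on the synthetic fixtures.
* `segment_guv_particles()`: Gaussian blur (σ = 3) → Li auto-threshold →
  fill holes → erosion → particle extraction.  The Li threshold lands on
  the outer skirt of the blurred ring, so the filled particle overshoots
  by roughly the blur radius; the erosion radius therefore defaults to
  `round(sigma)` pixels, returning the boundary to the membrane
  (`erode_px = 1` restores a literal one-pixel erosion).
* `nanotube_area_fraction()`: blur, Otsu threshold, erode; a vesicle
  counts as nanotube-containing only above 1% area fraction.
* `radial_profile()` / `radial_com()`: 100 bins of normalized radius with
  centres $(i - 0.5)/100$, intensities normalized to maximum 1 (the
  normalization cancels in the centre-of-mass formula
  $x_c = \sum x_i y_i / \sum y_i$ but matches plotted profiles).  Cortex
  recruitment shifts $x_c$ towards 1.
* `circularity()`: $R = 4\pi A / P^2$.  The analytic mode (polygon) is
  exact: a circle gives 1, a square $\pi/4$.  The raster mode uses the
  pixel count as area and a Kulpa-corrected chain code along the traced
  boundary, plus a half-pixel convex offset, as perimeter; its accuracy is
  about 1% (better for larger regions), the isoperimetric bound is
  enforced by clamping at 1, and the estimator name is attached to every
  result because raster circularity is estimator-sensitive (plain
  $\sqrt 2$ weights depress a disc to ~0.89; both `"freeman"` and a
  two-direction `"crofton"` variant remain available).  Z-stacks are
  summarized by the mean slice circularity (`stack_circularity()`).
* `angular_intensity()`: for every 10th ordered boundary point, the mean
  intensity of a rectangle from the centroid towards that point, 3 µm
  wide, 80% of the centroid–membrane distance long; rectangles leaving
  the image are clipped with a warning.
* `welch_ttest()`: unpaired two-tailed Welch test (`stats::t.test`
  under the module surface); the test suite checks it against numeric
  integration of the t density.

## Reproducibility

Every stochastic operation takes an explicit integer seed and leaves the
caller's RNG state untouched; identical configuration and seed give
bit-identical images, tables and trajectory files.  `load_config()`
validates YAML configurations against the package defaults (unknown keys
are schema errors) and `write_manifest()` echoes every effective parameter
and seed as JSON next to the outputs.  A thin command-line front end over
these functions ships in `inst/cli/nanotrace-cli.R` with subcommands
`simulate-afm`, `trace`, `fit-wlc`, `simulate-guv`, `guv-analyze`,
`simulate-traj`, `traj-analyze` and `report`.

## What the synthetic benchmark does and does not show

The generator emulates the geometry and statistics that the estimators
rely on: worm-like-chain conformations with realistic length
distributions, tip-broadened ridges of the right height, two-channel
vesicle scenes with controlled deformation and RNA localization, and
nanotube trajectories with prescribed bending stiffness and bond-breaking.
It does not emulate scanner artefacts (line noise, drift, streaks),
filament crossings *between* different filaments in dense fields,
fluorophore photophysics, the point-spread function of a real confocal, or
sequence-level energetics of the RNA itself.  Passing recovery tests
therefore demonstrates that the estimators are unbiased and stable on
clean, well-calibrated data of the stated geometry — not that they are
robust to every artefact of real microscopy.  The measurement chain is
the same one a real analysis would run; only the data are idealized.

## Numerical choices at a glance

* Lengths in nm internally; µm only at I/O edges.  Pixel coordinates in
  results are 0-based (row, col), y-down.
* WLC fit: LM with `ftol = 1e-15`, bounds $(10^{-6}, 10\max L)$, pilot
  start $\max(L)/4$; stiff-limit flag when the estimate runs into its
  upper bound (data on $R^2 = L^2$ carry no curvature information).
* Masking threshold: 1 residual s.d., single pass; numerically zero
  residual spread (below $10^{-8}$ of the data scale) masks nothing.
* Tie-breaks in tracing: lexicographically smallest (row, col) endpoint;
  degenerate single-pixel components are flagged, not errors.
* Problem sizes in the shipped checks: $10^4$ chains for sampler
  calibration, 300 filaments × 5–7 seeds per preset for end-to-end
  recovery, 400 frames for per-frame self-consistency, 1000 frames for
  the RMSF closed form.

## Known limitations

* Raster circularity and perimeter are accurate to about 1%; do not read
  more precision into them.
* The per-frame persistence median carries an intrinsic ~+10% skew bias
  from correlated layer pairs.
* The most flexible AFM preset recovers a few percent high because
  thinning smooths sub-resolution wiggles; stiff presets are unbiased
  within seed noise.
* The bond-breaking model displaces nucleotides; for tiles smaller than
  192 nt, registry pairs can share nucleotides and breaking is then not
  strictly pair-local.
* The Hough detector assumes approximately circular vesicles; strongly
  deformed vesicles should be segmented with
  `segment_guv_particles()` instead.
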