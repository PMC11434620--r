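---
title: "The self-returning excluded-volume chromatin model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The self-returning excluded-volume chromatin model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Chromatin in interphase nuclei is neither a homogeneous melt nor a
hierarchy of fixed fibers: imaging shows dense packing domains of roughly
50-100 nm radius alternating with dilute, accessible space, while Hi-C
shows contact probabilities decaying with genomic distance with a slope
near -1 at supranucleosome scales. `srev` implements a minimal stochastic
model that produces both features from two ingredients: *rules of return*
and *excluded volume*.

The generator is a self-returning random walk (SRRW) at nucleosome
resolution. At each step the walk either

- **returns**, retracing the previous backbone segment, with probability
  \[ P_R(U_0) = \frac{U_0^{-\alpha}}{\alpha}, \]
  where \(U_0\) is the length of that segment in units of the minimum
  jump (10 nm, the nucleosome scale), or
- **jumps** in an isotropic random direction with length drawn from the
  heavy-tailed density
  \[ P_J(U) = (\alpha + 1)\, U^{-\alpha-2}, \qquad U \ge 1, \]
  truncated at a local cutoff.

The folding parameter \(\alpha > 1\) controls both the return frequency
and the jump tail: high-frequency short returns build dense clusters,
rare long jumps connect them. Consecutive returns walk back along the
backbone; at the origin a jump is forced. A spherical global cutoff of
radius \(R_c\), measured from the center of mass of the
already-generated vertices, confines the conformation: jump candidates
beyond it are rejected and resampled.

The SRRW revisits vertices, so it is a branched object that violates
excluded volume. The SR-EV step restores physicality: every vertex visit
becomes one bead of radius \(r_0 = 4.9\) nm on a *linear* chain, and the
chain is relaxed until no two non-bonded beads overlap. Each bead is one
nucleosome carrying 147 bp; bonds longer than the 9.8 nm contact
diameter carry linker DNA of \(\mathrm{round}((U - 9.8)/0.34)\) bp. The
overall volume fraction is \(\phi = N (r_0/R_c)^3\), which at full scale
(\(R_c = 650\) nm) gives \(N\) between 186,741 (\(\phi = 0.08\)) and
466,854 (\(\phi = 0.20\)).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` | -- | folding parameter (> 1); 1.10-1.20 is the physiological band |
| `phi` / `n_beads` | -- | overall volume fraction / bead count, \(\phi = N(r_0/R_c)^3\) |
| `rc_confine` | 650 nm | global spherical cutoff |
| `unit_length` | 10 nm | minimum jump, nucleosome diameter |
| `local_cutoff` | 30 units | maximum jump length |
| `bead_radius` | 4.9 nm | non-overlap radius |
| `overlap_tol` | 0.01 | relative residual overlap allowed at termination |

The local cutoff is stated by the model definition but its value is a
design choice here: 30 units (300 nm) keeps single jumps below the
confinement scale while leaving the heavy tail intact; the printed
return-step fractions (48.7/47.5/46.2% at \(\alpha\) = 1.10/1.15/1.20)
are reproduced with this value, which we verified before freezing it.

## Overlap relaxation

The relaxation is an athermal energy descent, not a thermodynamic
sampler; it stops the moment the last overlap is resolved.

- **Potential.** Harmonic half-spring repulsion
  \(k_r (d_0^\ast - d)^2\) between any two beads closer than
  \(d_0^\ast\), and harmonic bonds \(k_b (d - d_\mathrm{rest})^2\). The
  repulsion acts between *all* pairs, bonded included, because the
  non-overlap radius applies to every bead.
- **Rest lengths.** \(d_\mathrm{rest} = \max(\text{initial length},
  2 r_0)\). Return-derived bonds start essentially coincident; their
  physical rest state is contact. With raw initial rest lengths the
  combined bond + repulsion energy has its minimum at next-nearest
  distances *below* the overlap threshold and the relaxation can never
  terminate.
- **Repulsion range.** \(d_0^\ast = 2 r_0 (1 + 3\,\epsilon)\) with
  \(\epsilon\) the overlap tolerance. Extending the force slightly past
  contact guarantees that force-balanced minima sit above the
  termination threshold \(2 r_0 (1 - \epsilon)\) instead of just below
  it; bonds are twenty times softer than the repulsion for the same
  reason.
- **Integrator.** Damped inertial descent with an adaptive timestep
  (FIRE-style): velocities are mixed toward the force direction while
  the power \(F \cdot v\) is positive, and reset when it turns negative.
  Any step that raises the energy is reverted, so at zero temperature
  the accepted-energy sequence is non-increasing. An optional noise
  amplitude (`temperature_scale`) is available but the default descent
  is deterministic. Typical convergence: a 35,000-bead chain resolves
  ~120,000 initial overlaps in 400-800 iterations.
- **Confinement.** Beads are reflected at a sphere about the initial
  center of mass. Because the generation cutoff is measured from the
  *running* center of mass, the finished walk can extend beyond
  \(R_c\) about its final center; the reflecting radius is therefore
  the larger of \(R_c\) and the initial extent. Reflecting at \(R_c\)
  itself would teleport outlying beads every step and deadlock the
  descent.
- **Degeneracy.** Coincident beads are pre-jittered by up to 0.1 nm so
  that pair forces have defined directions.

## Observables

**Scaling curves.** End-to-end distance \(\langle R^2(n)\rangle^{1/2}\)
and contact probability \(\langle C_p(n)\rangle\) (cutoff 35 nm between
bead centers -- the model's resolution) are accumulated in log-spaced
genomic-distance bins, 20 per decade, from pairs sampled stratified by
bead separation (~30 separations per decade, a capped number of pairs
per separation, seeded). The contact probability is the per-pair contact
fraction; no normalization to the smallest bin is applied. Power-law
fits are unweighted least squares in log-log space. The intra-domain
window is 1,000-40,000 bp (above the bond scale, below the printed
crossover near \(4 \times 10^4\) bp); the inter-domain window defaults
to \(10^5\)-\(10^6\) bp at full scale and must be rescaled by the volume
ratio for reduced systems (see "Reduced-size ensembles").

**Density statistics.** The chromatin volume concentration (CVC) grid
uses \((120\,\mathrm{nm})^3\) cells about the center of mass; each
bead's volume is split over 27 subsample points on a \(3^3\) lattice
inside the bead, an approximation to the exact sphere-cube intersection
whose error is far below the sphere-packing ceiling (0.74 crystal,
~0.64 jamming) used as the support bound. Coordination numbers count
neighbors within 11.5 nm. The pair correlation \(g(r)\) is normalized
by the mean density inside a sphere of radius \(R_c - r_\mathrm{max}\)
about the center of mass, so every counted shell lies inside the
confinement sphere and no geometric edge correction is needed; its
cumulative integral \(G(r) = \int_0^r 4\pi r'^2 g(r')\,dr'\) is fitted
over 40-120 nm for the packing exponent \(D\). The per-configuration
\(D_i\) and the local volume fraction \(\phi_i\) share a 240 nm probe
sphere centered at the center of mass (one probe per configuration; the
center-of-mass choice keeps the probe independent of domain locations).
Ensemble \(D\) is fitted on the ensemble-averaged \(G\); fitting per
configuration and averaging is also available through `local_stats()`.

**Domain pipeline.** Configurations are rendered as density volumes by
Gaussian deposition (unit mass per bead, separable voxel integrals,
4-sigma truncation; mass conserved to <1e-3), projected over a 100 nm
z-slab, smoothed (Gaussian, 5 px), contrast-equalized (CLAHE, EBImage's
clip-limit convention), and searched for local density maxima above a
quantile noise floor. Around each center a weighted-average mass-scaling
curve \(M(r)\) is measured (11 x 11 window, weights = pixel values;
cumulative mass interpolated along sorted pixel distances to avoid
integer-shell binning wiggle). The domain radius is the smallest scale
at which (1) \(M(r)\) deviates by 5% from the power law fitted over the
base range (3-10 px), (2) the local log-log slope reaches 3, or (3) the
radial shell density reaches a smoothed local minimum followed by a
\(\ge 5\%\) rise; the triggering criterion is recorded. The pixel-unit
parameters mirror the experimental pipeline, which does not state a
physical pixel size; with the default 2.9 nm voxels the filter radius
and window correspond to ~15 and ~32 nm, and all pixel-unit parameters
are exposed.

## Reduced-size ensembles

Full-scale ensembles (1,000 configurations of up to 467k beads) are out
of desk reach; the package's own validation uses \(R_c = 325\) nm with
\(\phi\)-matched \(N\) (e.g. 35,014 beads at \(\phi = 0.12\)), 10-20
configurations per condition, and \(R_c = 200\) nm with 3 configurations
for property sweeps. Locally defined statistics transfer well at this
scale: return fractions, the intra-domain Flory exponent, CVC support,
coordination numbers, and the packing exponent \(D\) (fitted at
40-120 nm, far below \(R_c\)).

What does *not* transfer is the long-range regime: the confinement
leveling-off of \(R(n)\) moves down from ~\(10^6\) bp to
~\(1.25 \times 10^5\) bp (the volume ratio), leaving no window in which
the inter-domain Flory exponent exceeds the intra-domain one -- at full
scale that ordering is a ~0.01 effect (0.342 vs 0.353 at
\(\alpha = 1.10\)). The corresponding check in the test suite measures
this honestly and is expected to fail at reduced size; the exponent
values themselves reproduce within tolerance. Contact-slope assertions
near \(S \approx -1\) are likewise meaningful only at full scale and are
not asserted at reduced size.

The synthetic blob fields used to validate the domain pipeline emulate
isolated radial-profile domains with known centers and radii; they do not
emulate overlapping domains, anisotropy, or detector noise beyond
uniform pixel noise, so passing them shows the pipeline recovers planted
ground truth, not that it resolves every configuration ambiguity in real
projections.

## Numerical choices and degenerate inputs

- Jump lengths by inverse CDF \(U = (1-x)^{-1/(\alpha+1)}\) with re-draw
  above the cutoff, preserving the truncated pdf shape exactly.
- One seeded RNG (R's) drives everything; ensemble member \(i\) uses
  seed \(s + i - 1\). Walk generation is bit-reproducible for a fixed
  seed.
- A vertex that cannot be placed within the global cutoff after 10,000
  rejections raises a generation error (never observed at the studied
  parameters).
- `relax()` returns an already-overlap-free chain unchanged; failure to
  converge within `max_steps` (or a frozen descent, detected after 2,000
  stagnant iterations) raises an error reporting the residual overlap
  count.
- Empty histogram bins are reported as missing rows, not zeros; fits
  require at least 3 bins and error otherwise.
- Degenerate (constant) inputs to the rank correlation return `NA` with
  a warning rather than a value.
- Domain centers closer to the image edge than the sampling window are
  skipped with a warning.

## Known limitations

- Homopolymer only: no genomic identity, CTCF/cohesin placement, or
  A/B-compartment structure; contact curves represent no particular
  chromosome.
- The relaxation is an overlap-removal procedure, not thermodynamic
  sampling; configuration weights are defined by the generator, not a
  Boltzmann ensemble.
- Mean linker lengths depend on post-relaxation bond stretching;
  reproducing printed full-scale linker tables (36-44 bp) is treated as
  a consistency indicator, not a test, since the convention behind those
  averages is not fully specified.
- The domain pipeline's pixel-to-nm calibration is a stated choice;
  experimental comparisons of absolute radii should calibrate
  `voxel_size` against the instrument's pixel size.
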