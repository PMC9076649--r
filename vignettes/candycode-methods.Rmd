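---
title: "Methods: encoding, matching and simulating particle-coated pill identifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: encoding, matching and simulating particle-coated pill identifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(candycode)
```

## The model

A pill is coated with on the order of a hundred small colored candy spheres
(nonpareils) whose positions are determined by uncontrollable physics. The
pattern is a physical unclonable function: trivial to produce, effectively
impossible to reproduce deliberately at sub-millimeter accuracy, and cheap
to read out with a camera. The package operates on the abstracted readout —
a table of `(x, y, color)` particle records in image coordinates (y grows
downward, as in a photograph) — and everything downstream of the photograph
is implemented here: encoding, storage, matching, simulation, and a
synthetic render/detect loop that closes the photograph gap for testing.

### From pattern to string set

Matching raw point patterns directly would require rotation- and
scale-invariant point registration against millions of stored patterns.
Instead each pattern is reduced to a *set of short strings* describing local
neighborhoods, and set overlap does the matching:

1. **Neighbor graph.** Two particles are neighbors when the Delaunay
   triangulation of the particle centers connects them. Delaunay adjacency
   is invariant under translation, rotation and scaling, so the encoding
   survives camera framing differences.
2. **Neighborhood strings.** Each particle contributes one string: its
   color letter, then its neighbors' letters read clockwise (in the y-down
   frame, clockwise as displayed equals increasing `atan2`). The cycle has
   no natural starting point, so the rotation that is lexicographically
   smallest is used. This subsumes the natural rule "start at the
   alphabetically first neighbor and break ties by looking further along
   clockwise", and resolves ties of any depth deterministically.
3. **Filters.** Strings centered on convex-hull particles are discarded
   (their neighborhoods are truncated and unstable between photographs), as
   are strings with fewer than 4 distinct letters (with a heavily biased
   color mix such strings recur across pills and cause false matches) and
   strings with fewer than 2 neighbors. On a 94-particle pattern with the
   commercial color mix, roughly 40 of 94 candidates are discarded.
4. **Multisets.** If two neighborhoods of one pill produce the same string,
   both copies are kept; similarity is the multiset intersection
   cardinality (sum over distinct strings of the smaller multiplicity).

The shared-string count separates sharply: re-photographs of the same pill
retain roughly half their strings (20-30 of ~53), while different pills
share 0-2. The default verdict threshold of 10 sits between the regimes;
it is configurable because the separation, not the exact cut, carries the
information.

### Color alphabets

Three built-in alphabets describe the studied systems: `"A"`, eight colors
with white five times more probable than each other color (P(W) = 5/12 —
an idealization of the measured ~41.5% white fraction on commercial
candies); `"B"`, eight equiprobable colors; `"C"`, fifteen equiprobable
colors. The seven colors added in `"C"` (black, dark gray, light gray, dark
green, magenta, purple, brown) are assigned the letters K, A, E, N, M, U, B.
Bias matters: excess white both lowers per-string entropy and triggers the
distinct-color filter more often, so `"A"` keeps fewer, weaker strings than
`"B"` or `"C"`.

## The simulator

`simulate_candycode()` places `n` equal disks of radius `r` on a pill face
of radius `R` by random sequential adsorption (RSA): candidate centers are
proposed uniformly over the allowed disk (radius `R - r`, by rejection from
the bounding square, which is exactly uniform) and rejected on overlap, up
to `max_attempts = 10000` proposals per particle. Colors are drawn
independently from the alphabet probabilities.

Parameter choices:

* `n_particles = 94` — the median particle count of the physical test
  library the simulator emulates.
* `particle_radius = sqrt(0.45 / n) * R` — targets a covered area fraction
  of 0.45, below the RSA jamming limit (~0.547) so placement succeeds with
  overwhelming probability, while keeping the packing dense enough that
  Delaunay neighborhoods resemble a real coated pill. Configurations above
  area fraction 0.55 are rejected up front as infeasible.
* At area fraction 0.45 a single run still fails to seat its last particle
  about once per 10^5 codes. `simulate_candycode()` raises that error (it
  is the caller's signal that the density is too high);
  `simulate_library()` instead redraws the failed configuration from
  scratch. Conditioning on packability perturbs the ensemble negligibly,
  and library-scale sweeps must not die once per hundred thousand codes.

### Randomness

All randomness — proposals, colors, perturbations — flows through R's
global RNG (`unif_rand` in the compiled core), so `set.seed()` makes any
run exactly reproducible, and every function also accepts a `seed`
argument. A single sequential stream is used rather than per-code
substreams: it keeps the compiled and interpreted paths bit-identical and
makes whole-run reproducibility trivial; the cost (results depend on
generation order) is irrelevant here because order is fixed by the API.

### The re-photograph / wear model

`perturb_candycode()` displaces each particle by isotropic Gaussian noise
of scale `jitter_sigma` and optionally flips colors or drops particles.
The Delaunay graph is deliberately sensitive: small angular changes flip
edges, so even modest jitter loses strings. The default
`jitter_sigma = 0.25 * particle_radius` was calibrated so that a perturbed
copy of a 94-particle pattern retains on average roughly half of its
strings, bracketing the 40-61% retention observed between real photographs
of the same pill. Color errors and particle loss default to 0 because
re-photography in practice misreads color far less often than it perturbs
apparent positions.

## Library-scale uniqueness

`max_shared_in_library()` computes the worst-case pairwise overlap via an
inverted index (string → codes containing it) with a sparse accumulator, so
a 100 000-code library is counted in seconds and memory stays linear:
only code pairs that actually share a string cost work.

`run_sweep()` repeats this over a grid of library sizes. Worst-case overlap
grows logarithmically in library size, so `fit_scaling()` performs ordinary
least squares of the per-size *mean* maximum shared count on `log10(size)`
(unweighted — replicate counts are equal by construction). Size-1 libraries
have no pairs; they are recorded as 0 and excluded from the fit.
`extrapolate_shared()` evaluates the fitted line at a target size; the
benchmark target 10^17 is the number of version-4 UUIDs at which digital
collision probability reaches 1%.

Default sweep settings — sizes {10, 10^2, 10^3, 10^4} with 20 replicates —
are a desk-scale protocol chosen so a three-alphabet comparison completes
in minutes on one core; the slope estimates they give are stable to well
within the ±0.3 tolerance used in the tests. The package's own test suite
and the acceptance script use exactly these sizes, plus 100 replicates of
the 120-code library and a single 100 000-code library.

## Synthetic imaging

`render_candycode()` and `detect_particles()` close the photograph loop
without physical pills. Rendering draws the pill as a filled disk and each
particle as an anti-aliased filled circle: boundary pixels blend the
particle color with what lies beneath in proportion to geometric coverage,
as a real defocused camera pixel would. Particles are drawn at 90% of their
physical radius so tangent particles never merge into one connected
component after rasterization.

Detection inverts this by linear unmixing: every pixel is assigned to the
nearest of {pill color, background color, pill→letter segments in RGB
space}, where a pixel on a particle edge lies on its letter's segment with
projection equal to its coverage α. Pixels with α ≥ 0.5 form the particle
components (connected-component labeling via `EBImage::bwlabel`); each
component of at least `min_pixels = 4` pixels becomes one particle at its
coverage-weighted centroid, taken over the component plus a one-pixel
dilation ring so the sub-0.5-coverage edge pixels contribute their
sub-pixel information. On clean renders this recovers centers to about a
hundredth of a pixel — accurate enough that encoding the detected pattern
reproduces the directly encoded string set except when a Delaunay quad is
within that margin of exact cocircularity, which at the default scale
happens in well under one neighborhood per thousand.

The built-in palette keeps every pair of entries (15 letters, pill face,
background) at least 0.25 apart in unit-cube RGB distance; custom palettes
below 0.2 are rejected. What the synthetic loop does *not* model: shadows,
specular highlights, color constancy across cameras, perspective and
curvature, and touching or occluded particles. Passing the round-trip tests
therefore validates the geometry and color pipeline, not photographic
robustness.

## Numerical choices and degenerate inputs

* **Frame.** y grows downward; "clockwise" is defined as increasing
  `atan2(dy, dx)` in that frame, matching visual clockwise in photographs.
* **Triangulation.** Bowyer-Watson insertion with strict floating-point
  in-circle tests, implemented in compiled code because the fused
  pack→triangulate→encode pipeline runs close to a million times in a full
  analysis. The enclosing super-triangle is placed ~10^9 data-spans away,
  making circles through its vertices numerically indistinguishable from
  half-planes (the correct vertex-at-infinity semantics for hull edges);
  the result matches an established triangulation library edge-for-edge on
  random instances, and the brute-force empty-circumcircle oracle on small
  ones. Cocircular quads (e.g. a perfect square) get one of the two valid
  diagonals, implementation-defined but deterministic.
* **Degenerate input.** Fewer than 3 particles or an all-collinear pattern
  is an error ("degenerate geometry"); duplicate coordinates are rejected
  using exact equality, appropriate for pixel-precision data. Coordinates
  serialize with 6 fractional digits, lossless for pixel-scale values.
* **Ties in matching.** Equal best matches are resolved to the
  lexicographically smallest code id and reported in the match report's
  `tied` field; the verdict depends only on the shared count.

## Limitations

The simulator places disks on a flat face; strongly curved pills would need
spherical triangulation. The perturbation model captures geometric jitter
but not systematic distortions (perspective, rolling shutter). The encoder
treats color classification as solved; real-world color constancy across
phone cameras — especially for the 15-color system — is an open question
the imaging module deliberately does not answer. Finally, whether the
physical string lists of a worn pill are best treated as sets or multisets
is ambiguous in the source data; the package uses multisets throughout
because they preserve information and make the intersection count well
defined.
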