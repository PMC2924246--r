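---
title: "Statistical positioning of nucleosomes: model, fitting protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical positioning of nucleosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statpos)
```

## The model

Nucleosomes wrap about 147 bp of DNA and cannot overlap, so along a
chromosome they behave as a one-dimensional gas of impenetrable rods — the
Tonks gas of statistical physics. Two parameters describe it completely:
the rod width $b$ (fixed at 147 bp throughout, from the crystal structure)
and the mean center-to-center spacing $\bar d$, equivalently the mean
density $\bar\rho = 1/\bar d$ or the mean linker length
$\ell = \bar d - b$.

In the bulk the linkers are independent exponentials with mean $\ell$, so
the distance from a *perfectly positioned* nucleosome to its $k$-th
neighbour is a $k$-stage Erlang variable shifted by $k b$:

$$P_k(x) = \Theta(x - k b)\,\frac{(x-kb)^{k-1}}{\ell^k (k-1)!}
           \, e^{-(x-kb)/\ell},$$

and the mean density at distance $x$ from that nucleosome is the finite sum

$$\rho(x) = \sum_{k\ge 1} P_k(x),$$

finite because $P_k$ vanishes for $x < k b$ (only $k \le \lfloor x/b
\rfloor$ contribute — no truncation error, ever). This is the decaying
oscillation characteristic of *statistical positioning*: order created
purely by excluded volume plus a boundary, with no per-nucleosome sequence
preference. Denser packing (smaller $\ell$) sharpens the oscillations and
extends their range.

Aligned, gene-averaged read-density profiles are fitted with

$$f(x) = A\,\rho(x - x_0),$$

where $A$ absorbs the unknown reads-per-nucleosome normalization and $x_0$
distinguishes the two limiting boundary conditions: $x_0 \approx 0$ means
the anchor nucleosome itself is the barrier (*direct* positioning), while
$x_0 \approx -b$ means the barrier is a nucleosome-repelling region and
the anchor is merely the first free rod pressed against it (*indirect* or
statistical positioning). The two cases differ by a horizontal shift of
one nucleosome width.

## Boundary conditions beyond the two limits

`solve_density()` computes the exact grand-canonical midpoint density of
hard rods on a 1-bp lattice in an arbitrary external energy landscape
(energies act on the rod midpoint, in units of $k_BT$; $\beta = 1$), via
the standard forward/backward partition-function recursion. Partition
values are carried in log space, so long lattices cannot overflow. The rod
width must be odd so that the midpoint is a lattice site.

`tune_fugacity()` bisects on $\log z$ until the bulk spacing of the
field-free lattice (measured over the central half, away from the
end-induced depletion layers) hits a target, by default 177 bp within
0.1 bp. `boundary_family()` then produces the pattern for repellent
regions of strength $+\varepsilon$ (implemented as a finite region of
length $20b$, indistinguishable from a half-line beyond a depletion
layer), attractive wells of depth $-\varepsilon$ (default width 20 bp,
roughly the +1 peak width), and the hard-wall limit — all sharing one
fugacity. All members oscillate with the same period, set by $\bar d$, not
by $\varepsilon$.

Two numerical conventions matter when comparing the lattice solution with
the continuum formula:

* a lattice site carries a probability *mass*, so it is compared against
  the continuum density integrated over the matching 1-bp bin (lattice gap
  $g$ corresponds to continuum gaps in $[g, g+1)$). Point evaluation at
  the contact discontinuity would misstate the error.
* the lattice equation of state differs from the continuum one at order
  $1/\ell$: with geometric rather than exponential gaps the tuned fugacity
  is $z = (1 - e^{-\beta P}) e^{b \beta P}$ with $\beta P =
  \ln((\ell+1)/\ell)$, about 12% below the continuum value at
  $\ell = 30$ — a discretization offset, not an error. The density
  patterns themselves agree with the continuum curve to within ~1.7% at
  the first three peaks.

## What the synthetic cohort emulates

`simulate_cohort()` generates the three input tables the analysis needs
(reads, nucleosome calls, genes) with the statistical structure of real
promoter data:

* **genes** on their own slots of a synthetic contig, random strand,
  log-normal lengths (median ~1.3 kb, roughly a third longer than 2 kb);
* a **+1 nucleosome** targeted a truncated-Gaussian ~50 bp downstream of
  the TSS (the +1 is by definition at or downstream of it), a **-1
  nucleosome** one NFR gap upstream (gap mean 140 bp, sd 60 bp);
* per gene, `cells_per_gene = 6` independent hard-rod configurations
  ("cells") fill both flanks from the exact thermodynamic-limit half-line
  law (iid exponential linkers): a *pinned* boundary for direct
  positioning, a *repelling edge* with the first rod free for indirect
  positioning. The per-gene ensemble is what makes a consensus anchor call
  and cell-to-cell variability coexist, as in real chromatin maps;
* **reads**: per nucleosome and cell, Poisson counts (6 reads per
  nucleosome overall), dyad jitter of sd 10 bp (midpoint-inference/MNase
  trimming noise), random strand, 147-bp intervals, and 5% multi-mapped
  reads emitted as 5 alignment rows sharing one identifier;
* **calls**: the -1/+1 anchors only, since those are what the analysis
  consumes. A direct anchor is called at its pinned position; an indirect
  anchor at the NFR-proximal extreme of the first-rod dyads over cells
  (the mode of the exponential first-particle law sits at the wall), which
  biases the anchor by about $\ell/n_{\text{cells}} \approx 5$ bp toward
  the NFR. Call fuzziness is the empirical sd of that nucleosome's reads.

Features of real data deliberately *not* emulated: DNA sequence (no
FASTA), MNase sequence bias, the peak-calling pipeline that produces real
nucleosome lists, genome-wide call tables beyond the anchors,
inter-nucleosome interactions beyond the hard core, and replication or
remodeling dynamics. Passing tests therefore demonstrate that the
analysis machinery recovers the parameters and boundary conditions of a
gas that truly follows the model — not that real chromatin does.

`simulate_ratio_cohort()` is a separate construction for the
genic/intergenic density comparison: alternating segments tile the contig
completely, each filled canonically at its own spacing (segment lengths
snapped to whole rods so each segment's mean density is exactly
$1/\bar d$ with no round-off bias).

## The fitting protocol

Fits minimize the mean squared deviation per data point over offsets
200-2000 bp from the anchor (1-bp grid), with $b$ fixed, using
Levenberg-Marquardt from 300 random starts (A within 0.2-5 times the
data-scale guess, $\bar d$ in 150-250 bp, $x_0$ across the basin). The -1
alignment is mirrored at the origin and fitted like the +1 side; following
the original protocol its offset-only fit keeps $A$ and $\bar d$ from the
+1 fit. The four boundary-condition pairs (direct/indirect on each side)
are compared by simultaneous fits with $A$ and $\bar d$ shared across
sides, ranked by joint chi-square per data point.

Design choices worth stating:

* **Basins are bounds, not just seeds.** A scenario-imposing fit restricts
  $x_0$ to its basin ($|x_0| < b/2$ for direct, $x_0 < -b/2$ for
  indirect). Seeding alone is not enough: on smoothed data the optimizer
  can walk out of a shallow basin and two scenario fits collapse into one.
  The classification rule (direct iff $|x_0| < b/2$, ties indirect) is the
  natural midpoint separator and is exposed in the configuration.
* **Convolved model.** `fit_convolved()` convolves $f$ with the empirical
  anchor-peak shape (profile values in $\pm 80$ bp around zero, rescaled
  to unit mass; the window is configurable) and fixes $x_0 = 0$, since the
  kernel already carries the peak location. On synthetic cohorts with
  anchor positional spread, the plain fit overestimates $\bar d$ by a few
  bp (smearing mimics a slightly looser gas) while the convolved fit
  recovers the truth; the tests compute both.
* **Identifiability guard.** A flat profile leaves $\bar d$ undetermined;
  if restarts tying the best score disagree on $\bar d$ by more than 20 bp
  (or the data have no variance) the fit is flagged unconverged instead of
  returning arbitrary numbers.
* **Equal per-gene weighting** in profile averages (read-weighted
  averaging would overweight highly covered genes); configurable in
  principle by pre-scaling the density map.
* **Coordinates** are 0-based half-open internally; readers convert
  1-based inclusive tables on ingestion. Gaussian call densities use
  per-bp probability masses (`pnorm` differences), truncated at $\pm
  6\sigma$ and renormalized; calls with fuzziness below the floor (default
  1 bp) use the floor.

## Problem sizes and reproducibility

The test-suite and acceptance computations run at the sizes the package's
own calibration uses: $10^5$ canonical configurations for the
Monte-Carlo/analytic equivalence (5-bp bins over 0-2000 bp, compared at
the nominal 3-sigma confidence applied family-wise across the ~400 bins:
chi-square goodness of fit plus a Bonferroni per-bin bound), an 8-kb
lattice for the solver limits, a 2000-gene cohort for parameter recovery
and the four-scenario comparison, and 60-tile cohorts for the density
ratios. Every random stage is seeded; identical configurations and seeds
reproduce outputs byte for byte.

## Known limitations

* The unconvolved fit inherits an upward $\bar d$ bias of ~2-3 bp from
  read-midpoint jitter (and more if the anchor itself is fuzzy); the
  convolved fit removes most of it. Real-data analyses should treat the
  convolved estimate as the reference.
* The indirect-anchor call rule biases the anchor ~5 bp toward the NFR, so
  recovered indirect offsets sit near $-(b - 5)$ bp rather than exactly
  $-b$.
* The grand-canonical solver is exact for its lattice model; agreement
  with the continuum formula is limited by the $O(1/\ell)$ discretization
  (~1-2% at peak heights, ~12% on the fugacity itself).
* Per-gene fits are out of scope: at ~6 reads per nucleosome only
  cohort-averaged patterns carry enough signal, which is also why the
  package only analyzes average profiles.
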