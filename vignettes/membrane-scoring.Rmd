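---
title: "Scoring membrane proteins with depth-dependent lipophilicity profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring membrane proteins with depth-dependent lipophilicity profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memlipo)
```

## The model

Soluble-protein energy functions treat solvation as transfer into water.
Inside a lipid bilayer that model is wrong in a depth-dependent way: a
leucine buried at the bilayer midplane is *stabilised* by roughly
2 kcal/mol relative to alanine, a glycine is *penalised* by about the same
amount, and arginine and lysine strongly prefer the inner (cytoplasmic)
leaflet — the positive-inside rule. `memlipo` implements a scoring toolkit
built around experimentally derived, per-amino-acid insertion profiles
$\Delta\Delta G_{\mathrm{Ala}\to aa}(z)$, where $z$ is the signed distance
from the membrane midplane along the membrane normal (negative = inner
leaflet).

Three per-residue energy terms are provided:

1. **Lipophilicity.** The processed profile of the residue's amino acid,
   evaluated at its C$\alpha$ depth and gated by a burial weight:
   $E = w \cdot \mathrm{spline}_{aa}(z) + (1-w)\,E_{\mathrm{base}}$.
   The burial weight
   $w = \frac{1}{1+e^{S_6(N_6-O_6)}}\cdot\frac{1}{1+e^{S_{12}(N_{12}-O_{12})}}$
   is a product of two logistic functions of the heavy-atom neighbour
   counts within 6 and 12 Å of the residue's C$\beta$ (virtual for Gly),
   running from 0 (buried in protein) to 1 (lipid-exposed). Fully exposed
   positions feel the membrane profile, buried and water-embedded
   positions the base (water) solvation, intermediate positions a linear
   mix. The base solvation is a pluggable per-residue callable; the
   default is 0 (pure-profile mode), since the surrounding all-atom
   energy function is outside this package's scope.
2. **Helicality.** A paraboloid penalty on backbone dihedrals,
   $\frac{((\phi+60)^2+(\psi+45)^2)^2}{25^4}\cdot\frac{1}{1+(z/10)^4}\cdot w$,
   zero at the ideal α-helical centre $(-60^\circ,-45^\circ)$, maximal for
   lipid-exposed residues at the membrane core and attenuated outside the
   membrane and in buried interfaces. The depth gate's orientation
   (maximal at the midplane) follows the physical requirement that the
   low-dielectric core is where non-helical backbone is most costly.
3. **Helix tilt.** A knowledge-based penalty on the angle $\theta$ between
   a membrane span's axis and the membrane normal. Observed spans
   concentrate at 15–30°, while unbiased rigid-body sampling is
   proportional to $\sin\theta$. Boltzmann inversion of both densities
   and subtraction gives
   $-(\ln f(\theta) - \ln\sin\theta)$ with
   $f(\theta) = -2.36\times10^{-4}\theta^2 + 0.01095\,\theta + 0.0202$;
   at run time a cubic approximation
   $1.51\times10^{-4}\theta^3 - 8.925\times10^{-3}\theta^2 + 0.187\,\theta - 0.532$
   is used, which avoids the log-domain breakdown where the quadratic
   turns negative (≈48°).

## Profile processing

Raw profiles arrive as 27 positions per amino acid, in kcal/mol, mapped
linearly onto $[-20, +20]$ Å. The pipeline is deterministic:

1. centred moving average (window 3 knots by default; endpoints use
   shrunken windows) — the simplest smoother consistent with lightly noisy
   per-position estimates;
2. symmetrisation $E(z) \leftarrow (E(z)+E(-z))/2$, *except* Arg, His and
   Lys, whose leaflet asymmetry carries the positive-inside signal;
3. residue special cases, on the kcal/mol scale because the constants are
   defined there: His capped at 2.3 kcal/mol on $[0, 20]$ Å (the largest
   penalty actually observed experimentally), Cys replaced by a copy of
   Ser (Cys is rare in membranes and of similar polarity; its measured
   profile is an asymmetric outlier), and Asp/Glu/Gln/Asn — sparsely
   observed — flattened to their mean over the membrane core
   $[-10, 10]$ Å;
4. conversion to Rosetta energy units (× 2.94), refused twice;
5. cubic-spline encoding with clamped extrapolation: outside
   $[-20, 20]$ Å the boundary knot value is returned, because the profile
   is only defined within the membrane window and base water solvation
   dominates outside it.

Ala is the reference and is represented as an explicit all-zero profile.
Pro has no meaningful sidechain-lipophilicity profile (its insertion
signal reflects backbone perturbation), so it is assigned a zero profile
and the result is flagged `pro_zeroed`.

**Numerical choice — the His spline.** A natural cubic interpolant through
a capped plateau overshoots the cap between knots by ~1%. His (only) is
therefore fitted with the Fritsch–Carlson monotone cubic Hermite
(`splinefun(method = "monoH.FC")`), which is C¹, interpolates every knot,
and cannot leave the local knot range — so the cap bound holds exactly on
the continuous curve, not just at knots. The other 19 amino acids use the
natural cubic spline.

## Tilt-angle statistics: normalisation conventions

The observed-density quadratic and the $\sin\theta$ reference live on
different natural scales, and the package makes the choice explicit in
`fit_tilt_density(normalise = ...)`:

- `"radians"` (default): density per radian of tilt. On this scale
  $\sin\theta$ *is* the unit density of unbiased sampling on
  $[0, 90^\circ]$, so a fitted observed density is directly comparable to
  the reference in `derive_penalty()`. Angles drawn from $\sin\theta$ and
  refitted give penalties within sampling noise of zero.
- `"fraction"`: probability mass per 5° bin. This is the convention the
  shipped quadratic coefficients are on — its integral over the observed
  support (≈4.9) happens to match the 5° bin width, so a refit of angles
  sampled from the shipped density recovers the shipped coefficients to a
  few percent on this scale.
- `"degrees"`: density per degree (unit area in degree measure).

Because the two conventions differ by a multiplicative constant, the
derived penalty carries an additive offset that is immaterial for
conformational sampling (energies are defined up to a constant); the
run-time cubic is used as shipped.

The quadratic fit uses occupied histogram bins with midpoints at or below
60° by default: empty bins carry no density information, and a quadratic
is only an adequate model in the low-tilt regime where membrane spans are
actually observed — fitted against sine-shaped data over the full
quarter-circle it leaves pure model-bias residuals of ≈0.15 log units at
the 5° edge.

## Geometry

- Membrane depth is measured at C$\alpha$ (defined for every residue);
  neighbour counts are taken around C$\beta$, with an ideal virtual
  C$\beta$ constructed from N/CA/C for Gly (NeRF placement: bond 1.53 Å,
  angle 110.1°, torsion −122.6°).
- Neighbour counts exclude the target residue's own atoms (burial measures
  packing against *other* segments), count heavy atoms only, and keep
  altloc ''/'A' protein atoms.
- A span's axis is the principal component of its C$\alpha$ coordinates,
  oriented N→C; the tilt is folded into $[0, 90^\circ]$. The principal
  axis is robust for the 15–30-residue spans this toolkit targets; very
  short or strongly curved segments would need local rise vectors
  instead.
- All geometric quantities are invariant under rigid-body motion applied
  jointly to structure and frame (tested), and only the depth changes
  sign when the leaflet convention flips.

## Calibration loop

`calibrate()` implements the iterative residual-encoding contract: given a
base scorer (which may respond nonlinearly to the current correction,
emulating structural relaxation), each iteration scores every
(amino acid, depth) pair on a poly-Ala scan grid and adds the residual
(target − computed) to the correction table, stopping at a maximum
residual below `tol` (default 0.01 R.e.u. — well below the ~0.5 kcal/mol
resolution of the target data) or after `max_iter` (default 10) updates;
non-convergence is a reported condition, not an error. For a scorer that
captures a fraction $\alpha$ of the target directly and absorbs the
complementary fraction of the correction, the residual contracts by
exactly $\alpha$ per update (closed form, tested). Ala's correction is
pinned to zero as the reference residue. A damping factor below 1 is
available for noisy scorers.

## Model selection

The post-processing operations are deliberately composable: energy and
structure filters (`apply_filters`, thresholds fully configurable, absent
metric columns are a hard error unless explicitly skipped), lowest-energy
fraction with boundary ties kept (`top_fraction`), score-wise clustering
(seed each cluster with the lowest-energy unclustered model, absorb
everything within 4 Å RMSD, repeat up to 5 clusters), Kabsch RMSD,
inter-chain native-contact fractions (C$\beta$–C$\beta$ < 8 Å by default,
C$\alpha$ optional; a contactless reference yields `NA`, never a silent
0), and median-ΔΔG classification with a destabilising-exclusive boundary
(median > 0 → destabilising). Filters-then-top-fraction and the reverse
order are both one-liners; the documented default applies filters first.

## What the synthetic data emulates — and what it does not

`synth_raw_profiles()` generates the 20 × 27 raw table with the hallmark
features of the measured insertion energetics (midplane Gly ≈ +2,
Leu/Ile/Phe ≈ −2 kcal/mol, an ≈2 kcal/mol inner-leaflet preference for
Arg/Lys, a raw His exceeding its cap on the outer leaflet, smooth bump
shapes with per-knot Gaussian noise of 0.05 kcal/mol). It does **not**
emulate deep-sequencing count noise, position-specific coverage gaps, or
the correlated errors of a real selection experiment; passing tests on
synthetic profiles therefore demonstrate the correctness of the
processing and scoring machinery, not the biological accuracy of any
particular profile set. Real measured tables drop in through the same
`aa,depth,energy_kcal` CSV interface.

Decoy ensembles are rigid-body perturbations of one chain of an ideal
dimer around declared modes; they exercise clustering and
native-contact bookkeeping with construction-known ground truth, and make
no attempt to mimic the energy landscape of a docking run.

Problem sizes used in the shipped tests: 50,000-angle tilt samples,
25-residue fixture helices, 24-model decoy ensembles, 100 random
clustering instances — sizes at which the statistical checks (15%
coefficient recovery, |penalty| < 0.15) are comfortably inside sampling
noise.

## Known limitations

- Atomic-level solvation, depth-dependent electrostatics and C$\alpha$
  hydrogen-bond terms are out of scope; the base solvation is a pluggable
  callable and defaults to zero.
- Membrane placement is taken from the declared frame (default: z-axis
  normal, midplane at 0, matching OPM/PDBTM-style pre-oriented inputs);
  no automatic span detection is attempted.
- NMR multi-model files are read as their first model by the underlying
  parser convention.
- The shipped tilt quadratic turns negative near 48°; the exact
  log-ratio penalty is therefore only defined below that, which is why
  the runtime term is always the cubic.
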