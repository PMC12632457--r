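---
title: "Measuring subnuclear position and repeat stability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring subnuclear position and repeat stability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periloc)
```

# The problem

Repetitive genes — such as the fission-yeast flocculin-like (*pfl*) family
with their tandem intragenic repeats — can be tethered to the nuclear
periphery, and that spatial organization correlates with their genetic
stability. Measuring this requires three quantitative layers:

1. **Where is the locus?** A lacO array/lacI-GFP dot is localized in a 3D
   wide-field z-stack to sub-voxel precision.
2. **Where is the nuclear envelope?** The membrane-marker channel is turned
   into a closed triangulated surface, giving nuclear volume, an effective
   radius, and point-to-surface distances.
3. **How is a cohort distributed?** Per-cell scaled depths are pooled into a
   radial probability density with Poisson error bars.

Two further, non-imaging layers round the analysis out: a genomic
nearest-peak statistic (is a DNA-binding protein's peak within a threshold
distance of each gene?) and fluctuation-assay rate arithmetic (plating
counts to per-cell event rates and log fold changes).

Because raw imaging data for this kind of study are rarely deposited, the
package ships a fully ground-truthed synthetic generator so that every stage
is tested end to end against known answers.

# Spot localization

The locus channel is maximum-projected over z; candidate pixels are local
maxima within a 1.5-pixel radius above a robust threshold, and each
candidate seeds a least-squares fit of an axis-aligned 3D Gaussian

$$I(v) = B + A \exp\!\left(-\frac{(x-x_0)^2+(y-y_0)^2}{2\sigma_{xy}^2}
      - \frac{(z-z_0)^2}{2\sigma_z^2}\right)$$

over a 7×7×9-voxel window (Levenberg–Marquardt with analytic Jacobian,
box bounds keeping $\sigma$ within $[0.5, 4]\times$ the PSF priors and the
center inside the window). $\sigma_{xy} \ne \sigma_z$ reflects the axial
elongation of a wide-field PSF.

**Threshold.** The default is median $+\,7 \times 1.4826\,\mathrm{MAD}$ of
the projection. A maximum projection concentrates the background *median*
strongly (the max of ~40 noisy slices has a narrow bulk) while its extreme
tail across thousands of pixels still spans more than five MAD, so a 5-MAD
cut admits occasional pure-noise maxima; seven MAD clears that tail while
remaining far below any real diffraction-limited spot at usable SNR. The
threshold is a plain argument for images that differ.

Non-converged or boundary-clipped fits are dropped and counted, never
clamped: a forced fit biases the depth statistic downstream, a missing cell
only widens its error bars.

# Envelope reconstruction

An icosphere (subdivision 3, 642 vertices) is initialized from the membrane
channel — radius from the Otsu-thresholded, hole-filled maximum-projection
disk area ($r_0 = \sqrt{A/\pi} - 1.5\sigma_{xy}$, the subtraction removing
the rim's lateral blur skirt), lateral center from the disk centroid, axial
center from the background-subtracted intensity centroid along z. A
per-slice *brightness* rule cannot find the equator: every z-section through
a closed shell carries nearly the same membrane mass, and with z-spacing
coarser than the shell thickness the pole caps alias into bright pancakes.

Vertices $V$ then descend the energy

$$E = \lambda_b \underbrace{\sum_v \frac{\lVert v - \mathrm{mean}(N(v))\rVert^2}{h^2}}_{E_\mathrm{bend}}
 \;-\; \lambda_i \underbrace{\frac{1}{|V|}\sum_v \hat I(v)}_{-E_\mathrm{img}}$$

with $h$ the mean edge length and $\hat I$ the min–max-normalized membrane
intensity, trilinearly interpolated (zero outside the stack). The umbrella
(uniform-weight Laplacian) discretization of bending is stable on
near-spherical meshes and cheap; the image term attracts vertices to the
bright shell. Defaults $\lambda_b = 1$, $\lambda_i = 10$ let the shell term
dominate at the rim while bending keeps the surface coherent where the
membrane signal is weak (poles, under noise).

**Optimization.** Deterministic gradient descent with heavy-ball momentum:
a trial step is accepted only if the exact energy does not increase,
otherwise the momentum is zeroed and the step halved, so the accepted energy
path is non-increasing by construction. Momentum matters: plain descent
relaxes the umbrella term diffusively, with a relaxation time that scales as
(mesh diameter/$h$)² ≈ 700 iterations, and stalls short of any tight
tolerance. Two details were load-bearing in development and are worth
stating. First, the bending gradient must include the dependence of $h$ on
the vertices: $E_\mathrm{bend}$ is scale-invariant, but its fixed-$h$
gradient is not, and omitting the $\partial h/\partial v$ term leaves a
spurious net inward force that shrinks the mesh several percent below the
membrane. Second, convergence (relative energy change below `tol`, default
1e-6) is only declared on a step accepted without backtracking — a
post-restart step is small by construction and would otherwise fake
convergence. The iteration cap defaults to 800; typical runs converge in
100–650 iterations, well under a second per nucleus.

The result carries volume (signed tetrahedra), effective radius
$R_\mathrm{eff} = (3V/4\pi)^{1/3}$, and a convergence flag; a mesh that
self-intersects at termination (checked by segment–triangle tests with
bounding-box prefiltering) is flagged not converged and excluded downstream.

Residual systematic error on noiseless spheres is −1 to −7 % in volume
(−0.3 to −2.4 % in radius): the inscribed-polyhedron chord deficit of a
642-vertex sphere (~2 % in volume) plus mild faceting where bending
flattens patches. Noise adds little because hundreds of vertices average it.

# Scaled depth and the radial density

For each cell, $s = d/R_\mathrm{eff}$, where $d$ is the exact distance from
the fitted spot center to the nearest point of the mesh (per-triangle
vertex/edge/face cases), signed by the solid-angle winding number: $s=0$ on
the envelope, $s=1$ at the center of a sphere, $s<0$ outside. Exterior
spots — possible under localization plus mesh error for truly peripheral
loci — are excluded and counted, not clamped; clamping would inflate the
first shell, which is precisely the readout of interest. Depths marginally
above 1 (mesh error for near-central spots) are clamped to 1 up to a 5 %
slack.

Pooled depths are binned into ten concentric shells of scaled width
$w = 0.1$. With $p = c/N$ the per-shell probability and $r = 1 - s_\mathrm{mid}$
the scaled radial coordinate at the shell midpoint,

$$f = \frac{p}{4\pi r^2 w}, \qquad
  \sigma_f = \frac{\sqrt{c}}{N \cdot 4\pi r^2 w},$$

so $\sigma_f/f = 1/\sqrt{c}$ exactly — the Poisson counting uncertainty
propagated to the density. A uniformly distributed locus gives
$f = 3/4\pi \approx 0.2387$ in this scaling.

Two numerical caveats are documented rather than hidden. The innermost
shell ($r_\mathrm{mid} = 0.05$) has a tiny scaled volume: its $f$ amplifies
count noise, and the midpoint-rule shell area under-represents the true
shell volume there, so even a perfectly uniform sample has expectation
$0.318$, not $3/4\pi$, in that bin. Tests therefore compare against the
exact discretized uniform expectation per shell — stricter in the outer
shells, correct in the innermost. Second, $\sigma_f = \sqrt c/(\ldots)$ is a
normal approximation that breaks down in shells whose expected count is only
a few (an observed zero against an expectation of 3.6 sits at exact Poisson
$p = 0.055$, nowhere near a 3σ exceedance, yet has $\sigma_f = 0$); cohort
flatness checks therefore use the exact two-sided Poisson band at the
3σ level per shell, while the reported $\sigma_f$ keeps the propagated
closed form.

# Genomic proximity

Distances are body-to-body gaps between 0-based half-open intervals
(overlap counts as zero, different chromosomes as infinite), strand
ignored, and "within 600 bp" is inclusive — choices matching a criterion
phrased as distance from elements, not from transcription start sites. The
per-chromosome sorted sweep (cumulative-maximum end for the left side,
first start beyond the feature for the right) is exact and is tested
against an all-pairs scan.

# Fluctuation-assay rates

The rate is the per-cell frequency of resistant colony formation:

$$\mathrm{rate} = \frac{c_\mathrm{sel}/d_\mathrm{sel}}{c_\mathrm{perm}/d_\mathrm{perm}},$$

both counts scaled to the undiluted culture. This is deliberately *not* a
Luria–Delbrück estimator — it is the quantity the plating assays report.
Zero selective colonies give rate 0 with a censoring flag (no pseudo-count);
zero permissive colonies leave the culture size unestimable and error. Fold
change divides each rate (wild-type samples included) by the wild-type mean;
plots and tables use the natural log. As a ratio with a Poisson count in the
denominator, the per-culture estimator carries a Jensen bias of order
$1/\mathbb{E}[c_\mathrm{perm}]$ — about 2 % at the default fixture's 50
permissive colonies — which the unbiasedness test accounts for analytically.
Downstream hypothesis testing (ANOVA, Tukey, Dunnett, t-tests) is left to
standard tools; the package exports tidy per-sample tables.

# The synthetic generator

`render_nucleus_stack()` emulates a wide-field acquisition: 64×64×40 voxels
at 0.1065×0.1065×0.26 µm (40 z-sections at 0.26 µm spacing, the protocol
this pipeline targets; the xy pixel matches 100× EMCCD sampling and is
configurable), an
ellipsoidal nucleus of radius ~1–1.6 µm as a 0.1 µm shell in the membrane
channel, a single Gaussian spot (σ_xy 0.13 µm, σ_z 0.30 µm) in the locus
channel, Poisson shot noise, Gaussian read noise (SD 2), and integer camera
counts. Amplitudes (membrane 800, spot 500 over background 100) give peak
SNR ≈ 20 — a photon budget chosen once to be comfortably realistic for an
EMCCD lacO/lacI-GFP acquisition; all of these are plain arguments.

The membrane is rendered as the shell indicator convolved with the PSF,
computed as the exact 1D erf profile along the surface normal followed by
the residual anisotropic z-blur. Evaluating a binary indicator on the voxel
grid instead aliases badly — the shell is thinner than the z-spacing, so
pole caps land on or between z-planes depending on alignment — and that
aliasing, not noise, was the dominant reconstruction error in early
development. The planar-profile form is exact up to $O(\sigma^2/R)$
curvature terms; a real microscope image would additionally shift the
apparent shell peak slightly inward at high curvature, which this generator
intentionally does not model.

Cohort positions come from either a uniform-in-volume draw or a
periphery-biased draw (scaled depth from an exponential of scale 0.05
truncated to [0, 1], uniform direction). The biased scale mimics a tethered
locus hugging the envelope; it is a test harness, not a biological model.
Interval fixtures plant a known fraction of features within the threshold
of a peak and keep all others at least twice the threshold away, verified
internally by brute force. Colony fixtures draw Poisson counts at a planted
rate under plating parameters derived from the assay protocol (a ~5 mL
saturated culture at ~1e8 cells/mL, 1:100 selective and 1:10⁷ permissive
plating → 5×10⁶ and 50 cells deposited).

What passing these tests shows — and does not. The generator exercises
sub-voxel localization, surface recovery, depth statistics and rate
arithmetic under realistic photon budgets and geometry. It does not model
spot motion during acquisition, chromatic offsets between channels,
non-ellipsoidal (dividing) nuclei, camera gain structure, or autofluorescent
background texture; conclusions about those failure modes need real data.

# Problem sizes used by the tests

Unit tests run single scenes and small cohorts. The recovery checks use the
radius grid 1.0–1.6 µm, 100 noisy spots for the RMSE statistic, 10⁵ analytic
depths for the density law, 2000-replicate bootstraps, and cohorts of 200
cells (one biased-vs-uniform contrast plus 20 seeded uniform replicates for
flatness) — sizes typical of single-cell locus-position imaging, where
cohorts of one to a few hundred nuclei per condition are the norm. The
acceptance script reports the same quantities with 10 flatness replicates.

# Known limitations

* The energy minimum is not the true surface: faceting and chord deficit
  bias volume a few percent low; effective radius inherits a ≤ 2.5 % bias.
* The first shell's density is noise-amplified by construction (tiny scaled
  volume); compare cohorts there only with its $\sigma_f$ in hand.
* Meshes are single-nucleus, genus-0, star-shaped in practice; dividing
  nuclei and touching cells are out of scope.
* The proximity module reports raw fractions, not enrichment p-values, and
  the rate module performs no hypothesis tests.
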