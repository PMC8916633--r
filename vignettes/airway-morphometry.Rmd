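---
title: "Centerline-based upper airway morphometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centerline-based upper airway morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwaymorph)
```

This vignette is the package's account of its science: the measurement
model, the numerical choices behind each stage, what the synthetic phantoms
do and do not establish, and the design decisions taken where several
reasonable implementations existed.

## 1. The measurement problem

The upper airway between the choanae and the first tracheal ring is a
curved, roughly tubular lumen. Axial-slice measurements misrepresent it:
an axial cut through a segment tilted by angle $\theta$ against the
vertical overestimates the cross-sectional area by a factor
$1/\cos\theta$ (15.5 % at 30°). All planar quantities in this package are
therefore measured in planes orthogonal to the lumen **centerline**, and
region volumes are integrals of orthogonal cross-sectional area (CSA) over
centerline arc length — the natural frame of the airflow.

The deliverable for one scan is a 30-variable record: for each of four
regions (nasopharynx, oropharynx, laryngopharynx, subglottal) the
orthogonal volume, the centerline length, and a boundary section's CSA,
anterior–posterior distance (APDist) and lateral width; plus pharynx
totals, vocal tract length from the incisor (VTL$_i$), velum length and
piriform sinus lengths. Units are mm, mm², mm³ throughout.

## 2. Segmentation

**Threshold rule.** Air is ≈ −1000 HU and pharyngeal soft tissue
≈ +40…+300 HU, but partial-volume averaging at ≤ 2.5 mm slice thickness
blurs the interface, so a fixed threshold misplaces the wall differently
in every scan. The image-specific rule takes the **midpoint between the
air histogram peak and the soft-tissue histogram peak**. Histogram
construction: 10-HU bins with centres on multiples of 10 over
[−1100, +400] HU, a 3-bin moving-average smoothing, peak = modal bin
centre within the search window (air [−1100, −900], tissue [+50, +350];
the tissue window is slightly wider than the textbook +100…+300 to
tolerate noisy or unusual tissue mixtures). Ties after smoothing are
broken on the raw counts. The midpoint identity
`upper_threshold = (air_peak + tissue_peak)/2` holds exactly by
construction.

**Connectivity.** The lumen is the 26-connected component of
`HU ≤ threshold` containing a user seed, clipped axially to the
choanae / first-tracheal-ring levels. 26-connectivity is robust to thin,
oblique lumina sampled at coarse slice spacing; voxels exactly at the
threshold count as airway. Air not connected to the seed (outside the
body, disjoint cavities) is discarded by construction.

## 3. Surface extraction and fairing

The binary mask is converted to a triangulated surface as the level-0.5
isosurface over the voxel-centre lattice, after padding with one empty
layer so the surface is closed by construction. Cells are decomposed into
six tetrahedra (the Kuhn decomposition, which splits every shared cube
face the same way in adjacent cells), making the mesh **watertight and
consistently oriented by construction** — properties every downstream
stage relies on and the tests assert (each directed edge appears exactly
once; Euler characteristic 2 for a tube with caps).

**Implicit fairing.** The voxel staircase is smoothed by implicit
Laplacian diffusion: each iteration solves
$(I - \lambda\,\Delta t\,L)\,x' = x$ per coordinate, with $L$ the uniform
(umbrella) graph Laplacian. Umbrella weights are used because
marching-style triangulations have poor triangle quality where cotangent
weights degenerate. Implicit integration is unconditionally stable, so a
large step does not ripple. Defaults: $\lambda\,\Delta t = 0.5$, **3
iterations**. The iteration count was set from the fairing-bias bound we
impose on ourselves: smoothing shrinks a cylinder of radius $r$ by
roughly $\lambda n h^2/(4r)$ per unit edge length $h$; at 0.5 mm voxels
($h \approx 0.35$ mm) three iterations keep the CSA bias of a 3 mm-radius
tube (a pediatric glottis) under 2 %, whereas ten iterations would cost
about 5 %.

**Sub-voxel refinement.** A binary mask quantizes any extent measurement
to half a voxel — on a 7 mm glottal width at 0.5 mm voxels that is a
potential 7 % error before any algorithmic error. The HU field itself
localizes the wall much better: the partial-volume edge profile crosses
the segmentation threshold (the 50 % mixture point) at the interface. The
`refine_surface()` stage therefore samples the volume along each vertex
normal (trilinear interpolation, 13 offsets over ±0.75 voxel) and moves
the vertex to the threshold crossing nearest its current position.
Fairing runs first (it regularizes normals), refinement second. On
phantoms this reduces width errors from the ±¼-voxel floor to well under
0.1 mm.

## 4. Centerline

Stage 1 slices the mesh at levels 2 mm apart along the patient superior
axis; per level one closed contour is kept (largest area) and its area
centroid recorded. Stage 2 fits a cubic B-spline through the centroids —
basis functions evaluated by the de Boor recursion, knots uniform in
chord length, with the number of interior knots grown until the RMS
residual falls below a target. Stage 3 re-slices **orthogonally** to the
current tangents and refits, twice.

Numerical choices that matter here:

* **Robustness near clipped ends.** Where the airway is clipped obliquely
  (the choanae level cuts the tube at a steep angle), axial level
  contours near the end are cut by the end face and their centroids are
  biased by up to a millimetre. Refinement samples are therefore inset
  from each end by one end-lumen radius (estimated robustly from the
  first/last few level-contour areas), and the tips are recovered
  afterwards by a predictor–corrector **march**: step one resample step
  along the tangent, cut orthogonally, re-center on the contour centroid.
  A clean orthogonal cut re-centers by far less than a step, so a large
  correction is diagnostic of the plane striking the end cap and stops
  the march; a final straight extension by ray casting stops 0.1 mm
  inside the cap. On arc phantoms this keeps the whole centerline within
  about 0.1 mm of the true axis, ends included.
* **Two smoothing targets.** The initial fits use a stiff RMS target
  (contour spacing / 4 = 0.5 mm) so contaminated centroids cannot bend
  the curve; the final fit tightens to contour spacing / 20, because the
  refined orthogonal centroids carry only ~0.05 mm of noise and a loose
  final fit would leave ~0.2 mm of systematic deviation on curved tubes.
  A residual-based trimming pass drops isolated outlier centroids.
* **Multi-contour rule.** When a cutting plane intersects the mesh in
  several closed contours (the piriform sinuses flank the laryngeal
  vestibule at the laryngopharynx), the contour whose centroid is nearest
  the centerline point is kept. This is what makes the laryngopharynx
  width a measurement of the vestibule that excludes the piriform
  sinuses.
* **In-plane axes.** APDist and width are extents of the section polygon
  along the patient Anterior and Right axes projected into the section
  plane and renormalized. If the Anterior projection degenerates (plane
  nearly coronal-horizontal), the extents are flagged undefined rather
  than invented.

## 5. Regions and the 30 variables

Boundary localization: the palatal plane (through the ANS–PNS line,
spanned laterally — zero lateral tilt, the cephalometric convention) is
intersected with the centerline as a true crossing; the velum tip,
aryepiglottic-fold midpoint and glottis (midpoint of the anterior and
posterior glottis landmarks) are located as the nearest point on the
centerline polyline, computed continuously along segments rather than
snapped to resampled vertices. The subglottal region ends at the
centerline's inferior end, which is valid because segmentation was
clipped at the first tracheal ring.

Volumes integrate the sampled CSA profile trapezoidally between boundary
positions, with the boundary sections recomputed at their exact arc
positions (never interpolated from neighbours). Two identities hold
*exactly*, not approximately, because they are computed that way:
PharynxVolume = Nasopharynx + Oropharynx + Laryngopharynx, and likewise
for lengths (the sums are performed in the same floating-point order the
record stores).

One deliberate asymmetry: the tracheal-end boundary section is sampled
0.5 mm above the mesh end cap (`end_standoff`), because fairing rounds
the clipped rim and a section cut exactly at the end under-reads its CSA
by several percent. Lengths and volumes are unaffected by the standoff.

VTL$_i$ is the oral polyline ABI → maxilla midpoint → PNS → centerline
entry at the palatal crossing, plus the centerline arc to the glottis;
the oral segment is an acknowledged polyline approximation, since no
lumen centerline exists in the oral cavity on CT. Velum length is the
quadratic Bézier from PNS to the velum tip with the velum-back landmark
as middle control point: the curve lies in the convex hull of the three
landmarks, so its length is always bracketed by the straight PNS–VeEnd
distance and the landmark polyline, and collinear landmarks reduce it to
the straight distance. (An *interpolating* quadratic through the three
points was rejected: at bent configurations it overshoots the corner and
can exceed the polyline length, which is not a credible velum path.)

## 6. The phantom generator

Phantoms are tubes with elliptical cross-sections — lateral semi-axis
$a(s)$, anterior–posterior semi-axis $b(s)$, linear taper — swept along a
parametric centerline (line, planar arc, or cubic) in the midsagittal
plane. The default is the study-like condition used throughout the
acceptance tests: an arc of radius 30 mm sweeping 60°, oriented tilted
anteriorly at the superior end and **vertical at the inferior end**
(the trachea is vertical in patient space; the airway's anterior bow sits
superiorly), semi-axes tapering 5 → 3 mm, air −1000 HU in tissue
+100 HU, 0.3 mm Gaussian blur, 20 HU Gaussian noise, 0.5 mm voxels,
boundaries at fractions 0.08 / 0.35 / 0.60 / 0.78 of the tube length.
Sizes and taper match a young child's pharynx; the phantom ROI clears the
oblique end faces so the axial clip never truncates the tube that the
analytic truth describes.

Voxelization emulates the scanner's partial-volume averaging: each voxel
receives the fractional lumen occupancy, computed by 3×3×3 supersampling
with a per-subsample linear coverage ramp on the signed radial distance
to the wall. This makes the HU edge profile cross the midpoint threshold
at the true wall position irrespective of grid phase — the property the
sub-voxel refinement stage depends on, and the property real CT shares.
Landmarks are planted consistently with their anatomic roles (glottis
landmarks at $\pm b$ on the AP axis of the glottal section,
aryepiglottic-fold landmarks ±4 mm laterally with the piriform points
8 mm inferior, the palatal plane passing exactly through the planned
superior boundary). Ground truth comes from quadrature of
$\int \pi a(s) b(s)\, ds$ and closed forms for the boundary sections.

**What phantom validation shows — and does not.** Passing the 5 %
end-to-end bar on phantoms establishes that the geometry pipeline is
unbiased and sub-voxel accurate for smooth tubular lumina with known
topology under realistic blur and noise. It does not exercise mucosal
wall irregularity, adenoid encroachment, scanner texture, motion or
dental artifacts, or operator variability in landmark placement — on real
scans those, not the pipeline, dominate the error budget.

## 7. Growth model and inference

Each variable is fitted on the log scale with the random-intercept model
given in the README, by **maximum likelihood** (not REML), so that the
likelihood-ratio test between nested fixed-effect structures is valid.
The age-effect LRT removes both pediatric-age terms
($\beta_4 = \beta_5 = 0$; the reduced model drops the sex-by-age
interaction together with the slope, since an interaction without its
main effect is not a meaningful null) and refers
$2\,\Delta\ell$ to $\chi^2_2$. Wald sex contrasts use the normal
reference on $c^\top\hat\beta / \sqrt{c^\top V c}$ with $c$ encoding the
male − female difference at age <1 ($\beta_1$), age 5
($\beta_1 + 5\beta_5$; ages are evaluated at exactly 0 and 5 years) and
adulthood ($\beta_1 + \beta_3$). Outlier screening is a single pass on
the log scale: fit, drop observations with conditional standardized
residuals beyond 2.576 (the 0.995 normal quantile), refit once. Percent
growth uses fixed-effect point estimates only,
$100 \exp(\hat\eta_{\text{ped}}(5) - \hat\eta_{\text{adult}})$, with no
retransformation correction — a ratio of modeled geometric means, which
is invariant under rescaling of the raw variable.

Sex is coded male = 1, so contrasts report male − female differences;
significance markers follow the four-tier convention (* < .05, ** < .01,
*** < .001, **** below the Bonferroni level .0004 for thirty variables
at four tests each).

The simulator draws from exactly this model; its defaults (72 subjects,
a mix of single and repeat scans, log-scale SDs 0.25 between and 0.2
within subjects, a strong age slope) mirror a realistic single-center
pediatric CT cohort. Calibration of the tests is checked by simulation:
type-I error of the LRT and uniformity of the null Wald p-values are
verified at 500 replicates of 150 subjects with two scans each — a size
chosen to be in the regime where the asymptotic $\chi^2$/normal
references apply (at a few dozen subjects the ML-based LRT is mildly
anticonservative, as expected for asymptotic tests).

## 8. Problem sizes and degenerate inputs

The validation suite runs phantoms of 40–50 mm tubes at 0.5 mm voxels
(≈ 0.3–0.7 million voxels, 25–50 k mesh vertices), chosen so a full
segment → mesh → fair → refine → centerline → measure cycle takes a few
seconds and the entire suite a couple of minutes; accuracy at these sizes
is representative because every stage's error is governed by voxel size
relative to lumen radius, not by absolute extent. Degenerate inputs are
contracts, not surprises: zero-length regions yield zero volume (not an
error); planes that miss the mesh yield sections flagged empty (never
fabricated); a seed above threshold, a missing required landmark,
misordered boundaries, inconsistent slice spacing and inconsistent scan
provenance each raise a named error.

## 9. Known limitations

* Single-tube topology: no nasal cavity, no bronchial branching.
* The oral VTL$_i$ segment is a landmark polyline, not a lumen path.
* The centerline end treatment assumes roughly planar clipped caps; a
  heavily curved airway *at* a clip plane would blend into the straight
  tip extension.
* Wald inference uses the normal reference; small-sample df corrections
  (Satterthwaite) are deliberately not replicated, and p-values near the
  threshold should be read with that in mind.
* The kernel-harmonization filters are fixed 5×5 / 3×3 approximations;
  they do not emulate any specific scanner's modulation transfer
  function.
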