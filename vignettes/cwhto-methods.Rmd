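---
title: "Virtual closed-wedge high tibial osteotomy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual closed-wedge high tibial osteotomy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwhto)
```

## The surgical problem

Lateral closed-wedge high tibial osteotomy (CWHTO) corrects varus
malalignment of the knee by removing a laterally based bone wedge from the
proximal tibia and closing the gap, rotating the distal fragment about a
medial hinge. Technique variants differ in where the proximal cut runs and
where the hinge sits, and those choices change two clinically relevant
quantities even at identical correction angles: how much bone is resected
(bone stock, limb length, later arthroplasty) and how much of the cut
surfaces fail to meet after closure (the lateral overhang or medial gap,
which affects fixation and lateral anatomy).

`cwhto` turns that comparison into a reproducible computation. Four
techniques are modeled:

* **conventional** — proximal cut parallel to the joint line, 10 mm below
  it; hinge at the medial cortex.
* **oblique** — proximal cut from a medial cortex point 15 mm below the
  joint line to a lateral cortex point 35 mm below it; hinge at the medial
  cortex.
* **hybrid 3:1** and **hybrid 2:1** — same oblique proximal cut, hinge on
  the cut at a lateral:medial arm ratio of 3:1 (fraction 1/4 from the
  medial end) or 2:1 (fraction 1/3).

Both cutting planes contain the anterior-posterior (AP) axis, so the
correction is purely coronal: the distal plane is the proximal plane
rotated by the correction angle $\theta$ about the AP-directed hinge axis,
and the dihedral angle between the planes equals $\theta$ by construction.
Saw kerf is 0 mm in the reference protocol (it is a configuration
parameter for sensitivity work). The hinge-ratio convention — "3:1 from
the medial cortex" read as lateral:medial = 3:1 — is the reading under
which the 2:1 hinge resects *less* bone than the 3:1 hinge and the medial
gap of the 3:1 hinge is about one-ninth of its lateral wedge, matching how
these techniques are described clinically; the opposite reading would
invert both orderings.

## Geometry engine

Meshes are watertight triangle surfaces in mm. Cutting is exact plane
sectioning: vertices are classified by signed distance (near-zero
distances are snapped onto the plane and treated as belonging to the
proximal side), crossing edges get one shared intersection vertex each, and
the cross-section chords are chained into closed loops, ear-clipped, and
used to cap both fragments. Because both fragments reference bit-identical
vertices, each output is watertight by construction and

$$V_{\text{proximal}} + V_{\text{wedge}} + V_{\text{distal}} = V_{\text{original}}$$

holds to floating-point accuracy (observed relative error $\sim 10^{-16}$;
the package treats $10^{-6}$ as the acceptance bound). Volumes come from
the divergence theorem (summed signed tetrahedra), exact for polyhedra. No
mesh repair is ever attempted — a defective mesh is rejected with a named
diagnostic, because silent repair would corrupt the conservation
guarantee.

The wedge is extracted by slicing twice: the region distal to the proximal
plane and proximal to the distal plane. Since the planes intersect along
the hinge axis, this region automatically lies lateral of the hinge, and
the distal fragment of a hybrid cut keeps its proximal-plane surface
medial of the hinge, exactly as the physical cut ("from the lateral cortex
to the hinge") leaves it.

On the rectangular prism phantom the engine reproduces the closed forms
used as oracles in the test suite. For a cut of coronal inclination
$\alpha$ with horizontal lateral hinge arm $w$, depth $D$:

$$V_{\text{wedge}} = \tfrac{1}{2} w^2 \left(\tan(\alpha+\theta) - \tan\alpha\right) D,$$

which reduces to the familiar $\tfrac{1}{2}W^2 D\tan\theta$ for the
joint-line-parallel conventional cut. These forms were derived by hand
from the 2-D cross-section triangles before the engine was written and
the engine matches them to $10^{-9}$ relative.

### Closure and non-overlap

Closure is the rigid rotation by $-\theta$ about the hinge axis; it maps
the distal cutting plane exactly onto the proximal one and is an isometry.
The distal cut face is transformed into the proximal plane's 2-D chart
(hinge at the origin, $+u$ pointing lateral) and compared with the
proximal face there:

* **overlap** — polygon boolean intersection (Vatti clipping via
  `polyclip`), and the **total difference** = proximal area − overlap.
* **lateral / medial scanline components** — at each AP station (0.25 mm
  default step, midpoint rule; halving the step changes results by
  $<10^{-2}$ relative) the mismatch of the lateral-most boundaries
  (lateral overhang, attributed to whichever fragment protrudes) and the
  extent by which the proximal face reaches medial of the distal face
  (the uncovered medial surface). Stations where either face is absent —
  anterior/posterior rim slivers — are excluded, which is why the
  scanline components, not the raw boolean difference, are the primary
  reported quantities: the raw difference includes rim slivers that
  clinical measurements of the step-off do not.
* **signed non-overlap** — positive lateral overhang for the
  medial-cortex hinges (conventional, oblique), negative medial area for
  the hybrid hinges, following the convention of reporting the side on
  which the technique generates its mismatch.

On a tapered bone the distal cut passes through narrower sections, so even
the conventional technique shows a small medial scanline component from
rim curvature mismatch; the lateral component dominates it for the
conventional cut, while for hybrids the medial opening dominates by
construction. The exact operational definition behind published
single-number "non-overlapping areas" cannot be uniquely recovered from
printed tables (published oblique values are smaller than the printed
proximal-minus-distal difference, implying sliver exclusion), so the
engine reports overlap, total difference and both scanline components and
treats only the ratio semantics — not absolute non-overlap values — as
reproducible.

### Medial gap volume

For hybrid hinges, closing the lateral wedge opens a medial gap. The
package measures it as the mirror construction of the lateral wedge: the
bone between the proximal plane and the proximal plane rotated by
$-\theta$ (opening medially) about the hinge axis, computed with the same
slicing machinery. Defined this way the gap and wedge scale identically
with their hinge arms, so on a uniform-section (joint-line-parallel) cut

$$\frac{V_{\text{gap}}}{V_{\text{wedge}}} = \left(\frac{f}{1-f}\right)^2$$

exactly — $1/9$ for the 3:1 hinge, $1/4$ for 2:1. An alternative
definition, the swept solid between the stationary proximal face and the
rotated distal face, carries an extra factor $\cos\theta$ (its medial
boundary is the rotated cortex chord rather than the bone wall); the
mirror-wedge definition was chosen because it makes the gap and the wedge
commensurable — both are bone-bounded dihedral regions — and because the
arm-squared law is then exact rather than approximate. With the standard
inclined 15/35 mm cut the ratio acquires a factor
$\cos(\alpha+\theta)/\cos(\alpha-\theta) \approx 0.84$ at
$\theta = 15^\circ$, still "approximately one-ninth".

## The phantom generator

No patient meshes are distributed with the study the defaults emulate, so
the cohort is synthetic. Each phantom is a stack of elliptical
cross-sections whose medial-lateral width tapers from the plateau width to
the shaft width over a 40 mm flare (smoothstep interpolation, monotone by
construction), with AP depth scaled proportionally (depth/width = 0.72)
and total height 110 mm. Varus is modeled as a coronal tilt of the
joint-line plane by $90^\circ - \text{MPTA}$, blended out over the flare
so the shaft stays axis-aligned; only the joint-line orientation enters
the plane constructions, so a curved shaft would add nothing the cuts can
see. Landmarks (plateau edge points, joint center, anterior direction)
are placed on the rim during generation.

Cohort metadata are drawn from truncated normal distributions matching the
reference cohort of 11 varus knees: tibial width $70.8 \pm 6.2$ mm
truncated to $[60.4, 80.7]$; MPTA mean $82.1^\circ$ on $[75.9, 87.7]$;
JLCA mean $4.4^\circ$ on $[0.1, 10.1]$; HKA mean $10.5^\circ$ on
$[5.1, 16.5]$; age mean 58 years on $[51, 66]$; 5:6 male:female. Standard
deviations not published alongside a mean (range) are back-computed from
the range (for $n = 11$ the expected range of a normal sample is about
$3.2\sigma$), giving 3.3 (MPTA), 3.4 (HKA), 2.9 (JLCA) and 4.7 (age);
all are configurable. Sampling uses inverse-CDF truncation, so cohorts
are bit-reproducible from a seed. The shaft/plateau width ratio (0.6) and
depth ratio (0.72) are generic adult proximal-tibia proportions; they are
held fixed across the cohort so that width and MPTA are the only
anatomical drivers.

What the phantom deliberately lacks: condyles, the tibial tuberosity,
cortical/cancellous distinction, the fibula, and real cross-sectional
asymmetry. None of these enter the plane constructions, but they do enter
absolute areas and volumes. Consequently the package treats orderings,
conservation laws, scaling laws and ratio semantics as reproducible
claims, and **not** the published absolute per-technique means, which
depend on the unavailable patient anatomy. On the default phantoms the
oblique-family cuts pass through relatively narrower bone than on real
flared metaphyses, so the synthetic oblique/conventional volume ratio
(~0.57) is smaller than the published one (~0.87), while every ordering
and sign claim is preserved.

## Statistics

Group comparisons wrap the standard tests (`wilcox.test`, `t.test`,
`fisher.test`, `chisq.test`) behind one record format. Mann-Whitney is
the default for the small-n, right-skewed geometric metrics; the exact
distribution is used when both samples are tie-free with $\min(n) \le 8$,
otherwise the normal approximation with tie and continuity corrections.
The test suite verifies the exact Mann-Whitney and Fisher p-values against
full enumeration (all $\binom{n_1+n_2}{n_1}$ rank assignments; all
hypergeometric tables) rather than against other library calls. Summary
tables report mean ± sample SD (SD undefined and reported missing for
$n = 1$ cells) and two display ratios, both ratio-of-means: percent of
the conventional technique at the same angle, and non-overlap as percent
of the technique's own mean proximal area. Ratio-of-means (not
mean-of-ratios) is the convention under which the published parenthetical
percents are exactly recomputable from the published means, which the
acceptance suite verifies. Subgroup thresholds are inclusive: MPTA
$\le 83^\circ$ is vara, JLCA $\ge 7^\circ$ is high. Significance is
$p < 0.05$, strict.

## Numerical choices and problem sizes

* Vertex-plane snapping tolerance: $10^{-7}$ x the coordinate scale;
  snapped vertices are classified proximal. Snapping only relabels
  vertices, never moves them, so conservation is unaffected.
* Cap triangulation: ear clipping per loop; multi-loop (multi-component)
  sections are supported, nested loops (holes) are rejected — no
  osteotomy plane through a one-piece proximal tibia produces them.
* Scanline step 0.25 mm, midpoint rule, Richardson-checked at 0.125 mm.
* Polygon booleans resolve on the clipper's integer grid
  (~$10^{-9}$ relative).
* Default phantom resolution: 48 ring segments, 2.5 mm ring spacing
  (~4300 triangles). Batch sweeps in the test suite use 32 segments /
  3.5 mm, where every tested invariant is resolution-independent; a
  20-seed x 11-knee x 12-cell sweep completes in about two minutes on
  one CPU.
* $\theta$ is restricted to $(0^\circ, 45^\circ)$; $\theta = 0$
  (coincident planes) is a degenerate limit handled analytically in the
  oracles, not by the slicer.

## Known limitations

* Absolute areas/volumes are phantom-dependent; only orderings, ratios
  and conservation/scaling laws transfer to real anatomy.
* The hybrid distal cut is modeled as a full plane and metrics are
  restricted to the lateral side of the hinge; a real saw leaves a
  slightly different medial termination.
* No biplanar (tuberosity-sparing) cuts, no sagittal slope change, no
  fibular osteotomy, no fixation or contact mechanics.
* Non-overlap is measured in the closed configuration's shared plane;
  with a nonzero kerf the faces are parallel but offset, and the same
  in-plane projection is used.
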