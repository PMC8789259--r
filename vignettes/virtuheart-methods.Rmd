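---
title: "Methods: personalized virtual-heart assessment of arrhythmia risk in HCM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: personalized virtual-heart assessment of arrhythmia risk in HCM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(virtuheart)
```

`virtuheart` implements a personalized virtual-heart pipeline for
hypertrophic cardiomyopathy (HCM): fibrosis maps are reconstructed by
fusing late-gadolinium-enhancement (LGE) cardiac MRI with a
postcontrast T1 relaxation-time map, an electrophysiological substrate
model is built on that map, ventricular-arrhythmia (VA) inducibility is
probed by rapid pacing from seven endocardial sites, and per-patient
risk predictions are scored against outcomes.  This vignette describes
the models, their assumptions, the calibrated constants, and the
numerical choices, in the order the pipeline runs.

## Image fusion: from LGE + T1 to a tissue label map

LGE-CMR is an image of *relative* signal intensity: fibrotic tissue
retains gadolinium and appears bright, but the intensity scale differs
between scans.  The standard segmentation therefore works in units of
the standard deviation (SD) of the low-intensity "remote" myocardium:
voxels above `mean + 3·SD` are called fibrotic gray zone (here: diffuse
fibrosis) and above `mean + 5·SD` focal scar (dense fibrosis).  The
remote component is identified by a one- or two-component Gaussian
mixture on the masked intensities (`estimate_remote_stats()`), selected
by BIC; with two components the lower-mean one is remote.  A mixture
fit is a reproducible stand-in for the manual remote-region tracing
used in clinical practice.

Postcontrast T1 mapping is *parametric*: relaxation times have
physical units and absolute thresholds.  Times below 350 ms indicate
dense fibrosis, the band 350–450 ms diffuse fibrosis, longer times
normal myocardium (`classify_t1()`).  Band edges are assigned so the
closed interval [350, 450] is diffuse, mirroring the printed
conventions ("<350", "350–450").

The fusion step (`derive_personalized_thresholds()`) transfers the
T1-derived information to the whole LGE stack.  Only a single
mid-ventricular T1 slice is available, so the transfer runs through the
matching LGE slice (nearest z-coordinate, ties to the lower index):

1. classify the T1 map and resample its labels to the LGE grid
   (nearest neighbour; the in-plane resolutions differ, 1.5 vs 2 mm);
2. compute the T1-derived dense and diffuse *area fractions* on the
   masked slice;
3. choose personalized thresholds `T_Dense` and `T_Diffuse` as the
   intensity quantiles of the matching LGE slice that reproduce those
   fractions, expressed in remote-SD units;
4. apply the personalized thresholds to every slice of the stack, each
   slice with its own remote statistics.

Because empirical quantiles are exact inverses of empirical fractions,
applying the derived thresholds back to the matching slice reproduces
the T1 fractions to within one voxel's area fraction (the test suite
checks 50 seeded cases).  Only area fractions are transferable through
global thresholds; the spatial correspondence is implicit in the
monotone relationship between contrast retention and both modalities
(brighter LGE, shorter T1).  Whether the original normalization was a
linear rescale or a rank matching is not documented anywhere we could
find; quantile (rank) matching is used here because it is
scale-invariant and makes the round-trip property exact.  Remote
statistics are computed per slice ("in each image") rather than once
per patient.  With thresholds fixed at (3, 5) the code path is
identical to the LGE-only pipeline, which serves as the comparison
model throughout.

## Synthetic images

`generate_lge_t1_pair()` emulates the study inputs without patient
data: an annular short-axis left-ventricular stack (10 slices, 2-mm
in-plane, 8-mm slice spacing; wall ~9 mm, outer radius tapering toward
the apex), remote-myocardium texture N(100, 10²), and fibrosis from a
thresholded Gaussian random field (default correlation length 8 mm,
AR(1)-coupled across slices).  Intensity rises linearly with the field
above the fibrosis-onset quantile, scaled so dense tissue starts ~6
remote-SD above the remote mean; diffuse tissue therefore spans a
*continuum* from near-remote intensity upward.  That choice makes the
one-size-fits-all 3-SD threshold capture only the upper part of the
diffuse range (~9% burden) while the T1-personalized threshold, which
lands near 1 SD, recovers the full generated burden (~40%) — the
qualitative behavior reported for real HCM cohorts.  Default fractions
are the cohort means (diffuse 40.5%, dense 3.8%).

The T1 map samples the same underlying noiseless field on its own
1.5-mm grid and maps intensity to relaxation time through a strictly
decreasing piecewise-linear transform anchored at the generating
thresholds (450 ms and 350 ms), plus independent noise (20 ms per unit
`noise_sd`).  A piecewise-linear map rather than a single affine one
keeps the requested fractions inside the T1 bands exactly; with
`noise_sd = 0` the T1 rank order is exactly the reverse of the LGE rank
order, which the tests assert.  The generator does not emulate MRI
artifacts (aliasing, motion), partial-volume averaging, or realistic
HCM intensity distributions — the published intensity distribution of
HCM LGE is not available — so passing tests demonstrate correctness of
the algorithms, not clinical performance.

## Geometry and fibers

`build_grid()` subdivides label-map voxels into square elements near a
target edge length (default 355 µm, the mesh resolution regime in which
monodomain solutions are accepted as stable); dense-scar elements are
flagged non-conducting.  Desk-scale work uses a single 2D short-axis
slice; the algorithms are dimension-agnostic and patient-scale
tetrahedral meshing is out of scope.

Fiber orientation follows the rule-based Laplace–Dirichlet method:
`solve_laplace()` computes discrete harmonic fields (5-point stencil,
sparse direct solve) between Dirichlet surface sets — endo = 0, epi = 1
for the transmural coordinate — and `assign_fibers()` rotates the
circumferential direction about the wall normal by a helix angle
interpolated linearly in transmural depth from +60° (endo) to −60°
(epi), the convention of the rule-based literature (the study itself
does not print its angle set).  Fibers are unit vectors orthogonal to
the transmural gradient; elements with a vanishing gradient take the
neighbour average.  For a single short-axis slice the apicobasal
direction is the slice normal.

## Myocyte model and HCM remodeling

The membrane model is the ten Tusscher–Panfilov (2006) human
ventricular epicardial formulation — the cell type is not stated in the
study; epicardial is the common default in prior virtual-heart work and
its prominent phase-1 notch makes the reported notch diminution
observable — with an added late sodium current `I_NaL` (Hund–Rudy-style
gating: fast-Na-like activation `mL`, slow inactivation `hL`,
τ = 600 ms), integrated with Rush–Larsen updates for gates and forward
Euler for potential and concentrations (default dt = 0.02 ms; APD90
changes by <0.2 ms between dt = 0.02 and 0.05).

Diffuse-fibrosis ("remodeled") myocytes apply eight scalings to the
baseline: I_NaL ×2.07, I_CaL ×1.19, I_Kr ×0.66, I_Ks ×0.73, I_to
×0.15, I_K1 ×0.85, Na/Ca exchanger ×1.34, SERCA uptake ×0.57.

**Calibration.** The target baseline APD90 is 280 ms at a 1000-ms cycle
length (the pacing rate is not stated; 1 Hz is assumed and used
consistently).  The raw epicardial model sits near 309 ms, so a
non-negative late-sodium conductance cannot reach the target on its
own.  The package therefore fixes `g_NaL` = 0.004 nS/pF (a late:peak
sodium-conductance ratio of ~0.03%, the order of published late-sodium
formulations) and calibrates a joint rescale of the delayed-rectifier
conductances `g_Kr`/`g_Ks` (`gk_scale` = 1.240655) so that the
*steady-state* baseline APD90 equals 280.000 ms.  Because the model's
intracellular sodium drifts for many minutes of pacing, steady state is
defined at a 1000-beat horizon; the resulting paced steady states of
both variants are frozen in `vh_config()` and used as the starting
point of all single-cell protocols, so a 30-beat measurement reproduces
the steady-state value.  The remodeled APD90 is then a genuine
prediction of the eight scalings: 332.5 ms (+18.75%), against the
reported 330 ms (+18%).  APD90 is measured from maximum upstroke
velocity to 90% repolarization toward the pre-stimulus diastolic
potential.

## Monodomain tissue model

`simulate_monodomain()` advances the anisotropic monodomain equation by
first-order operator splitting: an explicit 9-point diffusion step
(face-averaged tensor entries; mixed-derivative terms dropped at
boundary-adjacent faces) followed by the ionic step per node.  Dense
scar is excluded from the conducting domain — an internal no-flux
boundary, numerically cleaner than zero-conductivity elements and
physiologically identical for inexcitable tissue.  Diffuse-fibrosis
tissue conducts with the *same* conductivities as normal myocardium but
uses the remodeled myocyte; this reflects the modeling assumption that
diffuse-fibrosis remodeling is ionic, not conductive.  A CFL guard
rejects unstable dt/dx combinations, and |V| > 200 mV aborts with
diagnostics.

The conductivities of the source models are cited but not printed, so
they are set by calibration: σ_l = 0.159 S/m (with surface-to-volume
ratio 1.4·10⁵ m⁻¹ and membrane capacitance 0.01 F/m²) gives a planar
conduction velocity of 0.602 m/s along the fiber at 350-µm spacing;
σ_t = σ_l/4 gives the standard ~2:1 velocity anisotropy.  The explicit
stencil's numerical dispersion makes CV grid-dependent (faster on finer
grids): the calibration holds within 5% at 350 and 400 µm, and the
anisotropy ratio reaches its continuum value 2.00 under first-order
Richardson extrapolation of measurements at 150 and 100 µm.  Within the
operating band this dispersion is an accepted property of the method,
not hidden by the tests.

## Desk-scale substrate studies and the pacing protocol

Reentrant wavelength in full-scale human tissue (CV × APD ≈ 17 cm)
far exceeds any desk-scale domain, so the substrate studies exploit the
monodomain equation's spatial scale invariance: scaling both
conductivities by `cv_scale²` maps the dynamics of a domain
`1/cv_scale` times larger onto a small grid.  `substrate_config()` uses
cv_scale = 0.37 at 0.5-mm spacing (dt = 0.045 ms).  At this ratio of
grid spacing to wavefront width the lattice itself slows conduction
further; the substrate studies are therefore *qualitative* models of
reentry mechanisms — unidirectional block at repolarization gradients,
protected-isthmus circuits — not quantitative reproductions of
patient-specific simulations, and the patient-level episode counts of
the source cohort are out of numerical reach at this scale by design.

Three substrate families are provided.  Sheet phantoms
(`generate_substrate_phantom()`): homogeneous (the negative control —
no heterogeneity, no circuit, never inducible), a scar isthmus (two
inexcitable dense blocks around a conducting channel; with a remodeled
channel the long-APD isthmus blocks premature beats unidirectionally
and supports figure-of-eight-like reentry), and a contiguous diffuse
patch.  Ring substrates (`ring_substrate()`) are mid-wall annuli — the
minimal anatomy supporting reentry around a cavity; angular arcs of
remodeled (diffuse) tissue create the repolarization gradients where
premature beats block.  The substrate studies use the isotropic
conductivity variant throughout: phantom circuits run in both grid
directions, and in the rings the large circumferential anisotropy at
this coarse lattice would leave the few transmural node layers weakly
coupled, so that conduction block becomes an artifact of the lattice
direction rather than of the substrate.  With isotropic coupling the
wavefront stays coherent across the wall and the homogeneous controls
are robustly non-inducible.

`generate_substrate_pair()` builds matched rings for the burden
comparison.  Both substrates carry an identical ~9% *speckle* of
scattered single-node diffuse fibrosis — the burden level a fixed
3/5-SD segmentation reports; at this grain the speckle is smoothed
electrotonically and creates no coherent repolarization gradient.  The
enriched ring adds nine coherent remodeled arcs (total ~40%, the
T1-personalized level) whose edges are functional block sites.  The
enriched diffuse region is a strict superset of the base one, so the
pair isolates the effect of adding *contiguous* diffuse fibrosis.
This design encodes the study's own mechanistic conclusion — the
distribution of diffuse fibrosis matters more than its amount — and
makes the directional comparison well-posed at desk scale: matched
pairs in which the base substrate itself hosts reentrant circuits
behave chaotically under small numerical perturbations in this
lattice-dominated regime, whereas gradient-free bases are robustly
non-inducible.

The pacing protocol (`pacing_protocol()`) delivers an S1 drive train
then progressively premature extrastimuli, decrementing until
induction, loss of capture, or schedule exhaustion; tissue state is
cached after the drive train so each coupling restarts without
re-simulating it.  The full protocol defaults to 6 S1 at 600 ms with
up to two extrastimulus levels (10-ms decrements), the family of
protocols used in prior virtual-heart studies; the desk protocol
(`desk_pacing_protocol()`) compresses this to 2 S1 at 450 ms and one
extrastimulus scanning 351/333/315/297 ms so that a full 7-site study
of a ~700-node substrate runs in about a minute.

Pacing sites (`place_pacing_sites()`) sit at the endocardial-boundary
node nearest the central angle of each of seven fixed AHA-style
sectors (basal anterior, basal inferolateral, basal inferoseptal, mid
anteroseptal, mid inferior, mid anterolateral, apical septal — the two
sectors named in the source are included; the exact set is not
printed).  On a single slice the sectors are angular; on sheet phantoms
without a cavity the outer boundary stands in for the endocardium.

**Reentry detection** (`detect_reentry()`): reentry is declared when
activity is self-sustained through the observation window (default
2000 ms full-scale, 1500 ms desk) *and* some node reactivates at least
twice after the last stimulus (three threshold crossings: the paced
beat plus two reentrant returns).  A single ectopic echo followed by
quiescence is not reentry.  The descriptor records the reentry cycle
length (median inter-activation interval at the core node) and the
sector of earliest reactivation.  Unique VA morphologies
(`count_unique_morphologies()`) cluster descriptors whose cores share a
sector and whose cycle lengths differ by <10% — the source gives no
operational definition, so this stated stand-in is used.

A heart is **at risk** iff at least one of the seven sites induces
(`classify_patient()`), exactly the study's criterion.

## Risk evaluation

`compute_metrics()` derives sensitivity, specificity, PPV, NPV and
accuracy from the 2×2 counts; undefined ratios (zero denominators)
report `NA`, never 0.  Reported values are rounded half-up at the
second and then the first decimal, the convention that reproduces the
printed tables (e.g. 7/13 = 53.846% → 53.9).  The clinical ACCF/AHA
and ESC verdicts enter as fixture booleans — the comparison, not the
clinical scores themselves, is the contribution — and
`cohort_outcomes_fixture()` encodes the 26-patient prediction counts:
13/13 outcome balance, LGE-T1 14 inducible (11 true positives),
LGE-only 12 (9), ACCF/AHA 6 and ESC 7 correct in the VA group.  Two
printed cells (LGE-T1 PPV 78.8, accuracy 80.1) are inconsistent with
those counts, which give 78.6 and 80.8; the package reports the
count-derived values.

## Problem sizes and known limitations

The test suite runs the single-cell studies at 20–30 beats from the
frozen steady states; solver verification on strips of ≤3000 nodes;
and the inducibility studies on 45×45 sheet phantoms and 31×31 rings
(~340 active nodes), 10 substrate pairs, with the desk protocol.  These
sizes were chosen so the full suite completes on a laptop-class single
core.

Known limitations: 2D substrates with a single slice (no RV, no
apicobasal structure); lattice-dominated conduction at the desk scale
(see above); ionic remodeling data transplanted from hypertrophied-
region recordings to diffuse-fibrosis regions, as in the source
modeling work; no mechanics, no ECG, no bidomain effects; the
morphology-equivalence rule and extrastimulus schedule are stated
stand-ins for protocol details the source does not print.
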