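---
title: "Physio-metabolic MRI mapping and radiomic IDH classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physio-metabolic MRI mapping and radiomic IDH classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(physiomap)
```

This vignette is the package's account of its science: the forward and
inverse models, the parameters that matter and why their defaults are what
they are, what the synthetic cohort does and does not emulate, and the
numerical choices made where the design was genuinely open.

## 1. The biological question

Gliomas with and without *IDH* mutation differ in energy metabolism.
Wildtype tumors rely on aerobic glycolysis under hypoxia and recruit new,
arteriole-dominated microvasculature; mutant tumors favour oxidative
phosphorylation and a more oxygenated, less vascularised microenvironment.
Two MRI techniques expose this contrast quantitatively: qBOLD oxygen
metabolism mapping and vascular architecture mapping (VAM). The package
implements both mapping chains, the radiomic summarisation of the resulting
maps, and the machine-learning classification of the genotype, all driven
by a digital phantom cohort so that every stage is testable against known
ground truth.

## 2. The qBOLD model

The reversible part of the transverse relaxation rate in a voxel containing
deoxygenated blood is, to first order,

$$R_2' \;=\; R_2^* - R_2 \;=\; k \cdot \mathrm{CBV}\cdot \mathrm{OEF},
\qquad k = \tfrac{4}{3}\pi\,\gamma\,\Delta\chi\,\mathrm{Hct}\,B_0 ,$$

which the package inverts voxelwise as
$\mathrm{OEF} = (R_2^*-R_2)/(k\,\mathrm{CBV})$, clamped to the physical
range $[0,1]$ with clamped voxels flagged. With the default constants
($\Delta\chi = 0.264\times10^{-6}$, microvascular haematocrit
$0.42\times0.85$, $\gamma = 2.67502\times10^{8}\,$rad/s/T, $B_0 = 3\,$T)
the coupling constant is $k \approx 316.8\ \mathrm{s^{-1}}$ per unit blood
volume fraction.

The metabolic rate follows Fick's principle,
$\mathrm{CMRO_2} = C_a\,\mathrm{CBF}\cdot\mathrm{OEF}$. The coupling
constant in the printed form of the metabolic-rate equation is not defined
in the source literature we follow; we adopt the same $k$ as in the OEF
equation, which is the only choice that reduces the expression to Fick's
principle and keeps the two equations mutually consistent. $C_a = 8.68$ is
carried with its printed unit label; CMRO2 is therefore reported in
"$C_a\times$flow" units without conversion, which is irrelevant for
classification (features are computed per map after range normalisation).

Oxygen tensions use the Gjedde form of the haemoglobin dissociation model
with Hill coefficient $h = 2.7$ and half-saturation tension
$P_{50} = 27$ mmHg:

$$\mathrm{capiPO_2} = P_{50}\left(\frac{2}{\mathrm{OEF}}-1\right)^{1/h},
\qquad
\mathrm{mitoPO_2} = \mathrm{capiPO_2} - \frac{\mathrm{CMRO_2}}{L},\; L = 4.4 .$$

At complete extraction ($\mathrm{OEF}=1$) the capillary tension equals
$P_{50}$ exactly; as $\mathrm{OEF}\to 0$ it diverges, so such voxels are
flagged invalid rather than propagated. Negative mitochondrial tensions
(demand exceeding diffusive supply) are clamped to zero and flagged. The
exponent placement $1/h$ is adopted deliberately: the flattened typography
of the source admits other parses, but only the Gjedde form reproduces the
$P_{50}$ limit.

## 3. Perfusion processing

DSC signal is converted to concentration via
$\Delta R_2(t) = -\tfrac{1}{TE}\log S(t)/\bar S_{\mathrm{base}}$ with the
baseline taken over the pre-bolus frames. The first pass of each voxel's
bolus is fitted with the gamma-variate
$K(t-t_0)^{\alpha}e^{-(t-t_0)/b}$ over a window from the 5%-of-peak onset
to the first post-peak crossing of 20% of peak; the post-peak cutoff is a
common recirculation-exclusion convention (the source does not state one)
and doubles as the leakage mitigation — a linear post-bolus drift of 10% of
peak moves the fitted first-pass area by well under 2%.

**Fitting.** For fixed arrival time $t_0$ the log of the model is linear in
$(\log K, \alpha, 1/b)$, so the fit is profile least squares: an inner
closed-form solve plus a one-dimensional search over $t_0$ (coarse grid,
then Brent refinement). On noise-free gamma-variates this recovers the
generating parameters to numerical precision, which is what makes the
phantom round-trip tests exact. For noisy curves the log transform
overweights the tails; rather than reweighting (which proved unstable at
low SNR), curves whose peak signal-to-noise ratio — noise estimated from
frame-to-frame differences — falls below 10 are pre-smoothed with a
unit-mass $[1\,2\,1]/4$ kernel (up to three passes). The kernel preserves
the curve integral, so area-based blood-volume estimates stay essentially
unbiased; noise-free curves pass through untouched.

**AIF selection.** Arterial input functions are found automatically and
separately for the GE and SE series: candidate voxels (prefiltered by raw
peak height) are fitted, scored by rank sum of early arrival ($t_0$), high
fitted peak, and narrow width ($\alpha b$), and the top ten fitted curves
are averaged. The phantom designates an arterial region with exactly these
properties, giving a construction oracle for the selector.

**CBV.** Relative blood volume is the ratio of first-pass areas,
tissue over AIF. Both areas are evaluated in closed form under the fitted
curve, $K\,b^{\alpha+1}\Gamma(\alpha+1)$ (shift-invariant), rather than by
numerical quadrature of sampled curves: the closed form is exact, and it is
what makes noise-free CBV recovery accurate to $10^{-6}$ instead of
quadrature-limited. Microvascular CBV applies the identical estimator to
the spin-echo series with its own AIF. All values are relative (the
proportionality constant defaults to 1); the qBOLD equations consume CBV as
a fraction, and the phantom's forward model and this inverse share that
convention, with the arterial region simulated at unit blood-volume
fraction.

**CBF.** Cerebral blood flow uses block-circulant SVD deconvolution of the
tissue curve by the AIF with singular values truncated below a fraction
$\lambda$ of the maximum ($\lambda = 0.2$ by default; a tissue curve that
is a delayed copy of the AIF deconvolves to a unit spike when $\lambda$ is
small). The phantom's dynamics encode blood *volume* (curve amplitude), not
an independent flow field, so recovered CBF is relative and the recovery
tests cover OEF/CBV/ADC/R2*/R2, not CBF.

## 4. Vascular architecture

The vascular hysteresis loop is the parametric curve of
$y = \Delta R_{2,GE}(t)$ against $x = (\Delta R_{2,SE}(t))^{3/2}$ over the
first pass, built from the *fitted* (smooth) curves — raw noisy samples
inflate unsigned area. Negative SE excursions are floored at zero before
the 3/2 power. The microvessel type indicator is the signed loop area by
the shoelace formula with clockwise traversal positive; a gradient-echo
bolus that leads the spin-echo bolus (arteriole-dominated inflow) traces a
clockwise loop. The tests verify this against an independent ear-clipping
triangulation oracle and the analytic ellipse area.

Two typographic ambiguities in the source equations were resolved once and
recorded in map metadata so that an alternative parse is a one-line change:

- $Q_{\max}$'s printed denominator carries a GE subscript, inconsistent
  with the loop's axes; the spin-echo reading
  $Q_{\max} = \max \Delta R_{2,GE} / \max(\Delta R_{2,SE})^{3/2}$ is used.
- the density equation's "$24\pi^2$" is read as $2^4\pi^2$.

With $\beta = 1.6781$ and mean vessel lumen radius $\bar R = 3\,\mu$m:
$\mathrm{MVD} = (Q_{\max}/\beta)\,[\mathrm{CBV}/(2^4\pi^2\,\mathrm{ADC}\,
\bar R^4)]^{1/3}$ (lengths in mm, so MVD is in mm$^{-2}$) and
$\mathrm{VSI} = [\mathrm{CBV}\cdot\mathrm{ADC}\cdot\beta^3/(2\pi
Q_{\max}^3)]^{1/2}$, reported in $\mu$m. $Q_{\max}$ is computed per voxel
from that voxel's fitted curves, consistent with voxelwise fitting.

## 5. The synthetic cohort

The phantom generator is the package's substitute for a patient cohort and
defines the study conditions:

- **Geometry.** Ellipsoidal brain, ellipsoidal tumor (fully inside the
  brain, enforced), and a small designated arterial region. Default grid
  $64^3$ at 1 mm for single-phantom work; cohort runs use $24^3$–$32^3$
  grids — a desk-scale choice that keeps a 140-patient experiment within
  minutes while leaving hundreds of tumor voxels for texture analysis.
- **Class effects.** Tumor physiology is drawn per patient from
  class-conditional normal distributions and per voxel from a smooth,
  moment-matched field (the tumor sample mean equals the class mean
  exactly; zero variance collapses to a constant). Defaults encode the
  genotype contrast at roughly two between-patient standard deviations on
  OEF and CBV (wildtype: OEF 0.55, CBV 0.085, µCBV 0.034, ADC
  0.95×10⁻³ mm²/s, loops mostly clockwise; mutant: OEF 0.35, CBV 0.050,
  µCBV 0.018, ADC 1.25×10⁻³, loops mostly counter-clockwise; normal brain
  OEF 0.40, CBV 0.030). The source cohort's class-conditional biomarker
  distributions are not published, so these are configuration chosen once
  for physiological plausibility, not a calibration; prevalence is 74%
  wildtype, allocated as round(0.74·n) with shuffled order.
- **Forward models.** Multi-echo signals decay mono-exponentially with
  $R_2^* = R_2 + k\,\mathrm{CBV}\,\mathrm{OEF}$ (GE) or $R_2$ (SE). DSC
  concentration curves are unit-area gamma-variates scaled by the voxel's
  blood volume — total for GE, microvascular for SE — with the arterial
  shape earlier, taller and narrower; the SE bolus is shifted by one frame
  with the sign of the voxel's loop orientation (the smallest shift that
  produces a nondegenerate loop). Site A acquires two separate 60-frame
  series; site B one 80-frame interleaved hybrid at double dose and
  different timing. Noise is Gaussian on magnitude (Rician optional);
  the default relative level of 1% of baseline gives tumor-curve peak SNRs
  in the single digits, which is the regime where the pre-smoothing of
  Section 3 matters.
- **Not emulated.** Realistic anatomy, partial-volume, motion and
  susceptibility artifacts, T1 leakage effects, and any independent flow
  field. Passing tests therefore demonstrate correctness of the
  computational chain and sensitivity under the modelled contrast, not
  robustness to the artifacts that cause real-world misclassifications.
  Similarly, the background-field and stimulated-echo corrections applied
  to real relaxometry data are omitted — the synthetic data has neither
  artifact — which is a documented fidelity gap of the mapping chain, not
  of the model.

## 6. Radiomics

Each map is normalised, resampled to 1 mm isotropic (trilinear for
intensities, nearest-neighbour for masks), and discretized. Anatomical
contrasts are z-scored over the brain mask and binned at fixed width 0.1;
quantitative biomarker maps are clipped to physiologically reasonable
ranges and binned at range/64, inside the 60–67-bin window (OEF [0,1],
capiPO2/mitoPO2 [0,100] mmHg, CMRO2 [0,350], CBV/µCBV [0,0.2], ADC
[0,4×10⁻³] mm²/s, MVD [0,5000] mm⁻², VSI [0,50] µm; the signed MTI has no
fixed scale and uses a symmetric range at the 99th percentile of |MTI|).
The per-map ranges in the source's appendix are unavailable; these defaults
are configurable policy.

107 features are extracted per map — 14 shape, 18 first-order, 75 texture
(GLCM 24, GLRLM 16, GLSZM 16, GLDM 14, NGTDM 5) — following the
standardized feature definitions, with texture matrices accumulated in
C++ over all 13 unique 3-D directions (merged aggregation). Two documented
departures from the reference tooling: first-order features are computed on
the discretized grey levels (which preserves the z-score invariance the
tests check), and surface area/diameters use exposed voxel faces and
boundary-voxel distances rather than a triangulated mesh. The 107-name
manifest is pinned in code and contract-tested; vectors concatenate in
canonical map order to 428 per category and 856 for the physio-metabolic
combination.

## 7. Learning

The selection pipeline order is fixed: ReliefF ranking → top-25% shortlist
→ wrapper selection → SMOTE → seeded shuffle → training; balancing is
applied to training data only. ReliefF uses 10 nearest hits/misses under
Manhattan distance on [0,1]-scaled features, deterministic ties broken by
feature name. The wrapper is a best-first forward search scored by
stratified 10-fold CV accuracy of a wrapped learner, stopping when the best
expansion improves accuracy by less than 0.01; a fast logistic learner is
wrapped by default (the search is the expensive stage, and the spec of the
procedure — not the wrapped learner's family — is what the selected-set
contracts test). SMOTE interpolates minority samples on segments to one of
five minority nearest neighbours until counts are equal.

Classifiers: an MLP with one hidden layer of (features + classes) units on
standardized inputs; AdaBoost.M1 over entropy-split pruned decision trees
(a C4.5-family stand-in, 10 boosting rounds); a 100-tree random forest; a
1D-CNN (conv–pool ×3, flatten, two dense layers; 32/64/64 filters of width
7/5/3 — unstated in the source, recorded as configuration; ReLU; dropout
0.2 after the second and third convolutions and the first dense layer;
sigmoid output) and an LSTM with one layer per map — each layer's serial
direction is that map's 107 features — with tanh activations, hard-sigmoid
gates, forward and recurrent dropout 0.2, 64 hidden units (configurable),
and two sigmoid dense layers. Both deep models train with binary
cross-entropy and Adam (lr 0.001, β₁ 0.9, β₂ 0.999, ε 10⁻⁸), batch 28, a
stratified 80/20 train/validation split reshuffled every epoch, no early
stopping, and the best-validation-epoch weights retained. The deep models'
forward/backward passes are implemented natively in matrix code and
verified against numerical gradients in the test suite; training runs in
the analyses use tens of epochs (the architecture, not the epoch count, is
the tested contract — the nominal budget is 300).

## 8. Evaluation

Test cohorts are unbalanced, so class-wise sensitivity, specificity,
precision and F1 are combined by support weighting; the support-weighted
recall is algebraically the plain accuracy, which the suite asserts on
random confusion matrices. AUROC uses the rank-sum (Mann–Whitney)
formulation with midrank tie handling, cross-checked against an
established ROC implementation. The worked examples pin the arithmetic:
12 wildtype with two errors plus 4 correct mutants give weighted accuracy
0.875 and weighted precision 0.917; six errors in 33 give 0.818.

## 9. Problem sizes and determinism

The shipped analyses use a 46-patient cohort on 24³ grids; the end-to-end
discrimination experiment in the test suite uses 100 training and 40
held-out patients (and three independent 50/40 null cohorts with the class
effect scaled to zero), with selection/training repeated under three seeds
and averaged — one simulated cohort pair with reseeded stochastic stages,
since the training stochasticity, not the cohort draw, is what the seed
average is meant to integrate out. All stochastic stages take explicit
seeds; a cohort seed fans out deterministically to per-patient seeds, and
fixed seeds give byte-identical maps, features, selections and reports.

## 10. Known limitations

- µCBV is the noisiest map: spin-echo tumor signal changes of ~2% against
  1% noise put single-voxel fits at the edge of identifiability; tumor
  medians for low-µCBV (mutant-like) tumors can deviate by 10–30% at the
  default noise level, while CBV/OEF medians stay within a few percent.
- Relative (not absolute) CBV/CBF; no leakage correction beyond the
  first-pass fit; no artifact simulation (see Section 5).
- The wrapper search is greedy best-first without backtracking; with tiny
  cohorts its selected sets are small and seed-stable, which is the
  behaviour the contracts require, but it is not an exhaustive subset
  search.
- Shape features use voxel-face surface area, which overestimates mesh
  surface area systematically; within-study comparisons are unaffected.
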