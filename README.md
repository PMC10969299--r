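# physiomap

Physio-metabolic MRI biomarker mapping and radiomic machine learning for
preoperative classification of glioma *IDH* genotype — built as a fully
simulation-driven R pipeline, so every stage runs and is tested without
patient data.

## The problem

The *IDH* (isocitrate dehydrogenase) mutation status of a glioma separates
tumors with fundamentally different energy metabolism: *IDH*-wildtype tumors
are hypoxic, glycolytic and strongly neovascularised, while *IDH*-mutant
tumors favour oxidative metabolism in a better-oxygenated, less vascularised
microenvironment. Physio-metabolic MRI makes this contrast measurable before
surgery by combining:

- **qBOLD oxygen metabolism** — from multi-echo gradient-echo and spin-echo
  relaxometry plus perfusion, the oxygen extraction fraction

  `OEF = (R2* − R2) / (k · CBV)`,  `k = (4/3)·π·γ·Δχ·Hct·B0`,

  the metabolic rate `CMRO2 = Ca·CBF·OEF` (Fick's principle), and the
  capillary and mitochondrial oxygen tensions
  `capiPO2 = P50·(2/OEF − 1)^(1/h)` and `mitoPO2 = capiPO2 − CMRO2/L`.

- **Vascular architecture mapping (VAM)** — gradient-echo DSC perfusion is
  sensitive to all vessel calibres, spin-echo DSC mainly to microvessels.
  Plotting `ΔR2,GE(t)` against `(ΔR2,SE(t))^{3/2}` over the first pass of a
  contrast bolus traces the *vascular hysteresis loop*; its signed area is
  the microvessel type indicator (MTI, clockwise = arteriole-dominated),
  and with `Q_max = max ΔR2,GE / max (ΔR2,SE)^{3/2}` the microvessel density
  and vessel size index follow

  `MVD = (Q_max/β)·[CBV/(2⁴π²·ADC·R̄⁴)]^{1/3}`,
  `VSI = [CBV·ADC·β³/(2π·Q_max³)]^{1/2}`.

Each of the twelve resulting maps (4 clinical, 4 oxygen-metabolic,
4 vascular) is summarised by 107 IBSI-style radiomic features over the tumor
volume; per-category 428-feature vectors (856 for the physio-metabolic
combination) feed a ReliefF + wrapper feature selection, SMOTE class
balancing, and five classifiers (MLP, adaptive boosting, random forest,
1D-CNN, LSTM), evaluated with support-weighted confusion-matrix metrics and
AUROC on independent internal and external test cohorts.

Because clinical cohorts of this kind are not publicly distributable, the
package ships a digital phantom generator that forward-simulates the raw
acquisitions (multi-echo series, 60-frame separate GE/SE DSC or 80-frame
hybrid GESE DSC at double dose, two-point DWI, anatomical composites) for
two tumor classes with the metabolic contrast described above, at the
cohort prevalence of 74% wildtype. Every inverse step is validated against
this known ground truth.

## Worked example

```r
library(physiomap)

spec   <- phantom_spec(grid_shape = c(32, 32, 32), tumor_center = c(20, 18, 16),
                       tumor_radii = 6, class_label = "IDHwt", seed = 7)
bundle <- simulate_patient(spec, class_effect_model(), noise_sd = 0)
maps   <- map_patient(bundle)

tm <- maps$tumor_mask
median(maps$OEF$data[tm])          # 0.5510  (simulated class mean 0.55)
median(maps$CBV$data[tm])          # 0.0852  (simulated class mean 0.085)
sign(median(maps$MTI$data[tm]))    # +1      (arteriole-dominated loop)

evaluate(scores = c(rep(.1, 10), rep(.9, 6)),
         labels = c(rep("IDHwt", 12), rep("IDHmut", 4)))
#> <evaluation NA/NA: acc 0.875, prec 0.917, AUROC 0.917, 2/16 errors>
```

On a noise-free phantom the mapped OEF, CBV, ADC, R2* and R2 agree with the
generating ground truth to better than one part in 10⁶, and the MTI sign
matches the simulated loop orientation in every tumor voxel.

## The analysis

`analysis/` holds the numbered drivers of the full study on a 46-patient
synthetic cohort; each writes small tables under `results/` (large
intermediates go to `scratch/`):

1. `01_simulate.R` — cohort simulation (prevalence 0.74, two site protocols)
2. `02_map_biomarkers.R` — all twelve maps for one patient + recovery table
3. `03_extract_features.R` — 428/856-feature radiomic tables per category
4. `04_train_models.R` — selection + SMOTE + the five classifiers
5. `05_evaluate.R` — independent internal and external (hybrid-protocol)
   testing, results matrices

In the shipped run all five oxygen-metabolism models classify the internal
test cohort nearly perfectly (e.g. MLP accuracy 1.000, AUROC 1.000; LSTM
accuracy 0.875), while on the external cohort — acquired with the other
site's 80-frame double-dose hybrid protocol — accuracies drop to 0.75–0.81
and AUROCs as low as 0.38: the domain shift between acquisition protocols,
not the biology, dominates external performance.

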