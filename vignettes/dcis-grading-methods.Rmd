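---
title: "Methods: automated DCIS grading with dcisgrade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated DCIS grading with dcisgrade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Ductal carcinoma in situ (DCIS) is graded 1-3 on nuclear morphology and
architecture (the Holland system): low-grade lesions show small, monotonous
nuclei and cribriform or micropapillary architecture; high-grade lesions
show large pleomorphic nuclei with conspicuous nucleoli, solid growth and
frequent central necrosis. Grading is clinically consequential — active
surveillance trials enroll by grade — yet inter-observer agreement is
modest. `dcisgrade` implements an automated grading pipeline that is
trained on the consensus of three observers *and* on how many of them
agreed, evaluated with the field's standard agreement statistic, quadratic
weighted Cohen's kappa (QWK).

## Labels from three observers

Each outlined lesion carries three grades in $\{1,2,3\}$. The consensus is
the majority grade; when all three observers disagree (necessarily
$\{1,2,3\}$) the consensus is defined as grade 2. The agreement count
$n_{agree} \in \{3, 2, 1\}$ (unanimous / majority / three-way split) is kept
as a second training target: a 2-1 split marks a borderline lesion, and
exposing that uncertainty to the classifier is the pipeline's central idea.
Patient-level grades for observers are the maximum lesion grade. Where a
patient-level *consensus* grade is needed (for split stratification) we use
the maximum of the lesion consensus grades, mirroring the observers' rule.

Patients are split into train/validation/test strata by patient-level
consensus grade, shuffled within each stratum by a seeded generator, and
apportioned by largest-remainder rounding. Splitting is always by patient,
so lesions of one patient never cross subsets.

## From annotation to network input

Slides are scanned at $\times 40$ with 0.22 µm/px. All geometry lives in
level-0 pixel coordinates and is converted to physical units through that
resolution; at the $\times 10$ working magnification the pixel size is
$0.22 \times 40/10 = 0.88$ µm/px. Around each lesion's bounding box a 90 µm
border is added (102 px at $\times 10$; 409 px at level 0, round half up)
to include tumour-associated stroma. The crop is downscaled $\times 4$ by
exact area averaging. Network inputs are 512 px patches (450.56 µm — "about
450 µm") sampled uniformly over the crop; lesions smaller than the patch
are centre-padded with white, approximating slide background rather than
fabricating tissue. Training-time augmentation applies flips, 90°
rotations, and hue/saturation/brightness/contrast jitter in HSV space
(defaults: hue ±0.05, saturation ×[0.7, 1.3], brightness ×[0.8, 1.2],
contrast ×[0.8, 1.2]); no augmentation is used at test time. The exact
jitter ranges are deliberate design choices exposed in `augment_params()` —
they stand in for staining variability and are not derived from a reference
protocol.

## The dual-head classifier

The grader is a convolutional trunk with two 3-class softmax heads (grade,
agreement) and loss

$$\mathcal{L} = \mathrm{CE}(\text{grade}) + \lambda\,\mathrm{CE}(n_{agree}),$$

with $\lambda = 0.5$ by default; $\lambda = 0$ is the consensus-only
baseline. Both targets are small discrete sets, so two softmax heads (not
regression) are the natural choice.

Two backbones share the head contract. `densenet121` is the full-fidelity
architecture (7×7/2 stem, dense blocks of 6/12/24/16 bottleneck layers,
growth 32, compression-0.5 transitions). `smallcnn` is a deliberately small
trunk for CPU-scale work: an average-pooling stem that reduces the patch to
about 64 px, three conv(3×3)-ReLU-avgpool(2) blocks (12/24/32 filters),
global average pooling, plus a *color shortcut* — the global mean RGB of
the stem output concatenated onto the trunk features — so stain-fraction
statistics, the strongest grade correlate at coarse resolution, are
available to the heads from the first optimization step.

The network engine itself (convolution as im2col + GEMM, pooling,
batch normalization, concatenation, dense layers, and reverse-mode
gradients with Adam) is implemented in base R on BLAS; the engine's
gradients are verified against numerical differentiation in the test suite.
Inputs are centred on a reference H&E tissue colour (RGB 212/173/201) and
scaled by 35, making the between-grade colour differences $O(1)$ features —
without this, head weights would need to grow by orders of magnitude before
the loss responds, which a 10-epoch budget does not allow.

Training samples one random augmented patch per sampled lesion per step and
minimizes the mean dual loss with Adam. Because the grade marginal is
heavily skewed toward grade 2 (64%), lesions are sampled with
inverse-frequency weights (with replacement) each epoch; without this the
classifier spends most of its budget at the majority-class plateau. After
each epoch the lesion-level QWK against the validation consensus is
computed via the lesion prediction rule below (a reduced number of patches,
default 4, keeps monitoring cheap); the best-epoch parameters are retained
and training stops after `early_stopping_patience` epochs without
improvement, but never before `min_epochs` (default 4), since the
validation kappa is uninformatively flat during the first escape from the
plateau.

## Lesion and patient predictions

A lesion is graded by drawing 10 random patches, taking each patch's hard
grade, and reporting the median; when the two central values of an even
count straddle a half-integer, the median is rounded *up*, biasing
borderline lesions toward the clinically cautious higher grade.

Patient-level model grades use the nearest-rank percentile of the lesion
grades: sort ascending and take the element at index
$\lceil P/100 \cdot n \rceil$. $P = 100$ reproduces the observers' max rule
exactly (the ceiling definition was chosen for precisely that limiting
behaviour); the default $P = 80$ damps the max rule so a single outlier
lesion does not determine the patient grade.

## Agreement evaluation

QWK uses disagreement weights $w_{ij} = (i-j)^2/(k-1)^2$:
$$\kappa = 1 - \frac{\sum_{ij} w_{ij} O_{ij}}{\sum_{ij} w_{ij} E_{ij}},$$
with $O$ the observed proportion matrix and $E$ the product of its
marginals. When both raters are constant and identical the expected
disagreement is zero; this is reported as a defined error rather than a
NaN. The 95% CI uses the Fleiss-Cohen-Everitt large-sample variance of
weighted kappa with a normal approximation; bounds are *not* clamped to
$[-1, 1]$ — reported DCIS agreement tables print small-sample upper bounds
above 1 (e.g. 0.49-1.05), identifying exactly this convention. The analytic
formula is validated in the tests against a $10^4$-resample bootstrap and
by a coverage simulation, since agreement tables rarely name the variance
formula behind their intervals.

## The synthetic cohort

Because no clinical images ship with the package, a generator renders
grade-dependent H&E-like duct images at 0.88 µm/px: eosin-pink stroma, a
duct ellipse, hematoxylin-purple elliptical nuclei whose mean diameter
(7 / 9.5 / 13 µm) and coefficient of variation (0.10 / 0.18 / 0.30 —
pleomorphism) grow with grade, nucleoli with grade-scaled probability
(0.05 / 0.25 / 0.70), cribriform lumina for grade 1, and a central necrosis
core for grade 3 (probability 0.6). Nuclear areal density is held constant
across grades, so nuclear size differences translate into stain-fraction
differences. The duct outline (inflated 5% so it encloses every duct pixel)
is emitted as an ASAP-dialect polygon in level-0 coordinates. Observers are
simulated with adjacent-only noise: the true grade with probability
$1-\varepsilon$ ($\varepsilon = 0.15$), otherwise an adjacent grade, grade-2
errors splitting evenly — grade 1-vs-3 disagreement is vanishingly rare in
practice, so the simulation omits it.

Lesion grades are drawn hierarchically. Drawing lesion grades i.i.d. would
make nearly every multi-lesion patient grade 3 under the max rule
($1 - 0.8^{17} \approx 0.98$), collapsing patient-level evaluation. Instead
a patient grade is drawn from the reference cohort's patient distribution
(7/24/19 of 50), and lesion grades conditionally with downward-adjacent
spill solved in closed form so the lesion marginal equals the reference
lesion distribution (152/645/204 of 1001) exactly. Both margins are thereby
reproduced, and patient-level max-of-lesions recovers the drawn patient
grade with high probability. (The printed 15%/64%/20% round to 0.99; the
exact count fractions are used so the priors sum to one.)

Regular lesions are rendered at 520-700 px (≈0.25-0.38 mm², matching the
reported mean lesion size of 0.48 mm²); 15% are rendered at 300-480 px to
exercise the small-lesion padding path. Lesion counts per patient are
uniform on 5-30 (reported mean ≈ 20).

What the generator does *not* emulate: real chromatin texture, stromal
cellularity, staining gradients, tissue folds, benign mimics, or the
annotation noise of real outlines. A model that passes the recovery
experiment has therefore demonstrated that the pipeline's plumbing, losses,
aggregation rules and statistics work — not that it grades clinical H&E at
expert level, which requires a clinical dataset and GPU-scale training of
the DenseNet backbone.

## The recovery experiment

`run_recovery_experiment()` is the package's end-to-end check, sized for a
single CPU: a 60-patient cohort (≈1000 lesions) split 40/10/10 patients,
the `smallcnn` backbone trained at most 8 epochs of 448 balanced-sampled
lesions each (learning rate 2e-3, batch 8, $\lambda = 0.5$; roughly 450
optimizer steps in total) on the simulated observers' consensus labels, and
evaluation of the 10-patch-median lesion grades against the synthetic
ground truth of the held-out test patients — lesion-level QWK, 80th-
percentile patient-level QWK, and a label-shuffled control that should sit
at chance. Training labels come from the noisy observers while evaluation
is against the ground truth, so the experiment also demonstrates that
consensus labeling denoises effectively.

## Numerical choices and edge cases

* Micron-to-pixel conversions round half up; downscaling requires an
  integer magnification ratio (4 for ×40→×10) and pads crops on the
  right/bottom with the pad colour to a block multiple.
* Polygons are implicitly closed; a duplicated closing vertex is dropped;
  self-intersecting polygons are rejected at construction.
* ASAP coordinates serialize at full double precision (`%.17g`), so
  write-then-parse is exactly the identity.
* Probabilities are clamped at $10^{-12}$ before logs in the loss.
* Degenerate kappa (both raters constant, identical) is an error of class
  `dcis_degenerate_agreement`; a validation epoch whose kappa is undefined
  scores $-\infty$ for model selection.
* All randomness flows through explicit integer seeds; derived streams are
  kept below $2^{31}$. Reruns of every command with the same config and
  seed are byte-identical.

## Known limitations

* The pure-R engine trains the small backbone comfortably but is not meant
  for GPU-scale replication of DenseNet-121 training; `densenet121` is
  provided as the fidelity architecture and verified for its head contract
  and gradient correctness, not trained in the test suite.
* The synthetic phenotype is a caricature; transfer of any trained weights
  to real slides is out of scope.
* Only three-observer panels are modelled; the consensus rule generalizes
  but is untested beyond three.
* The lesion median rule operates on hard patch grades rather than
  expected (probability-weighted) grades; hard grades match the "median of
  the predicted grades" reading and keep the output in the grade domain at
  every stage.
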