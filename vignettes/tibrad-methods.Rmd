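---
title: "Methods: tibial bone radiomics for knee osteoarthritis classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tibial bone radiomics for knee osteoarthritis classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`tibrad` implements a complete analysis chain for distinguishing knees
without and with MRI-defined tibiofemoral osteoarthritis (tfOA) from
radiomic features of tibial bone:

1. a synthetic knee-phantom cohort generator (images, ground-truth tibia
   masks, covariates, MOAKS score records, labels);
2. rule-based MOAKS outcome definitions;
3. tibia segmentation combining a multi-atlas model with a voxel-wise
   appearance model, evaluated by the Dice coefficient;
4. extraction of six volumes of interest (VOIs) below the cartilage-bone
   interface;
5. a radiomic feature engine (shape, orientation, histogram and texture
   families);
6. elastic-net penalized logistic regression with repeated stratified
   10-fold grid-search cross-validation;
7. ROC AUC / PR AUC evaluation with bootstrap confidence intervals.

The cohort the method was designed around (665 female knees, 1.5-T FIESTA
MRI) is not publicly deposited, so the package is built to be fully
exercised on synthetic phantoms whose statistical structure encodes the
qualitative biology the analysis assumes. Everything below is therefore
framed as: what the model is, which knobs matter, what the phantoms do and
do not emulate, and what a passing test suite does and does not demonstrate
about real data.

# Axis convention

All 3-D arrays are ordered (medial-lateral, inferior-superior,
anterior-posterior); a sagittal slice is `vol[i, , ]` and "up" is the
second axis. Volumes carry a `spacing` attribute in mm (see
`image_volume()`); NIfTI round-trips preserve it. The default phantom grid
is 96 x 96 x 64 voxels at 0.5 mm isotropic, which holds the plateau, two
tibial spines and three stacked 10-mm VOI tiers with margin.

# The phantom cohort

`generate_tibia_phantom()` builds a vertical shaft with an elliptical
cross-section flaring into a plateau whose top surface carries two Gaussian
spine bumps of distinct heights (4 and 3 mm by default). Bone intensity is
a base level (100) plus a stationary correlated Gaussian texture field plus
i.i.d. sensor noise; background is a dark level (10). The correlated field
is Gaussian-smoothed white noise with per-axis kernel sigma equal to the
correlation length divided by the voxel spacing, rescaled to the target
texture SD — the simplest stationary field with controllable homogeneity.

Disease is encoded in the two directions that the osteoarthritis imaging
literature associates with tfOA:

* **more homogeneous trabecular texture** — the OA texture correlation
  length (2.0 mm) exceeds the control value (0.8 mm) at equal texture SD
  (20), so OA phantoms have strictly lower local intensity variance and
  score higher on GLCM homogeneity and GLSZM large-zone emphasis;
* **less compact bone outline** — the OA surface irregularity amplitude
  (0.12 versus 0.02) drives both a `sin(6*theta)` perturbation of the
  plateau outline and a vertical radius ripple with a 3-mm period. The
  ripple exists because slice-wise compactness (`4*pi*A/P^2`) is measured
  on sagittal slices, to which a purely axial outline perturbation is
  nearly invisible.

Sensor noise defaults to SD 2 — well below the texture SD of 20 at bone
intensity 100, consistent with high-SNR steady-state bone imaging — so the
homogeneity ordering is carried by the trabecular texture rather than
masked by noise. Each phantom also carries seeded anatomical jitter
(centre +-3 voxels, overall size +-8%, interface 0-2 voxels, spine
positions +-2 voxels); without it, atlases and targets are geometrically
identical and registration quality is unmeasurable.

`generate_cohort()` assigns labels by stratification — exactly
`round(n * prevalence)` positives (default 76/665) — rather than Bernoulli
draws, so prevalence checks are exact. Age ~ N(54.6, 3.7) years and
BMI ~ N(26.8, 4.6) kg/m^2 are independent of the labels by default, so a
covariate-only model is near chance on synthetic data; a switch
(`covariate_label_assoc`) can plant a +0.8 SD shift for positives. A
stratified `needs_correction` flag (default 86/665) emulates the
segmentation-QC bookkeeping only; no manual correction is re-enacted.

`generate_moaks_record()` inverse-samples the outcome rules: positive tfOA
knees are realised through a randomly chosen route (both primary features,
or one primary plus two of the three secondary features) placed at
femoral/lateral sites so the medial tibial sub-outcome labels remain free;
the generator verifies the round trip through the classifiers and fails
loudly if it ever breaks.

**What the phantoms do not emulate:** cartilage, femur, menisci and all
MRI sequence physics; realistic trabecular microarchitecture (the texture
field is Gaussian, real bone texture is not); any correlation between
covariates and disease; bilateral knees. A green synthetic suite
demonstrates that the pipeline recovers effects *of the kind it plants*,
not that those effect sizes hold on real MRI.

# MOAKS outcome rules

Tibiofemoral OA is positive when both primary features are present (a
definite osteophyte = any osteophyte grade 2-3, and full-thickness
cartilage loss = any cartilage grade 3), or one primary plus at least two
of three secondaries: (1) a BML or cyst of grade >= 1 not associated with
meniscal or ligamentous attachments, (2) meniscal maceration/degeneration
grade >= 1 or a horizontal tear, (3) partial-thickness (grade 1-2)
cartilage loss. Grades are validated to 0-3. The three medial sub-outcomes
are grade >= 1 thresholds on the medial tibial sites. By default the
primary features may come from any tibiofemoral site (`tibia_only = FALSE`
restricts them); the definition does not state the restriction, so the
knee-level pooling is the default.

One structural caveat, verified by enumeration: the literal rule is not
monotone across the partial/full-thickness boundary — raising a cartilage
site from grade 2 to 3 can remove the partial-thickness secondary while
full-thickness already holds elsewhere, flipping a positive knee negative.
All other grade raises are monotone, and the property test covers exactly
that set.

# Tibia segmentation

The segmentation contract is: per atlas, an affine stage followed by a
non-rigid stage with mutual information (MI, 32-bin joint histogram) as the
global similarity; warped atlas masks are averaged into a tibia probability
map; a random-forest appearance model on Gaussian scale-space features
yields a second per-voxel probability; the two are fused by a weighted
arithmetic mean (default w = 0.5) and thresholded (default 0.5), keeping
the largest 6-connected component.

The registration backend implemented here is deliberately simple and
pluggable: the affine stage is a coarse integer translation search at 4x
downsampling followed by Nelder-Mead refinement of a 12-parameter affine
at 2x downsampling, both maximising MI; the non-rigid stage is block
matching on a control grid (spacing 12 voxels, patch radius 5, search
radius 3), using local normalised cross-correlation inside the small
matching windows (a 32-bin MI estimate on an 11^3 patch is statistically
empty) and trilinear interpolation of the smoothed control displacements
to a dense field. A final guard compares MI against the identity and the
affine stage and reverts to the best earlier stage, flagging
non-convergence, so a returned transform never decreases MI relative to
identity.

The appearance stack has exactly 49 channels: the raw intensity, plus at
each of three scales (0.5, 1, 2 mm) the smoothed image, three first
derivatives, six Hessian entries, gradient magnitude, Laplacian, Gaussian
curvature (Hessian determinant) and the three Hessian eigenvalues sorted
descending (1 + 3 x 16). The 1 + 3 x 16 decomposition and the scale triplet
are a recorded assumption — they are the only arithmetic consistent with
the channel families named above and the printed total of 49. Derivatives
are in per-mm units so the classifier transfers across resolutions; the
forest (ranger, 100 trees, balanced 2000 voxels per class per atlas,
seeded, single-threaded) can predict on a 2x-downsampled grid with
trilinear probability upsampling, which changes Dice negligibly on
phantoms and is the pipeline default.

In place of the visual inspection and manual correction used on real data,
`segment_tibia()` raises a QC flag when the fused mask's Dice against the
thresholded atlas consensus falls below 0.8.

# VOI extraction

The two tibial spines are the two separated local maxima of the top-surface
height profile over medial-lateral columns; flat peak runs count once at
their centre; equal-height peaks tie-break toward the smaller column index;
a minimum separation of 8 voxels is enforced and a flat-top mask is an
error. Compartments span from each spine to the outer border (the
inter-spine gap belongs to neither); medial = smaller column index for a
right knee, with a flip flag for left knees. The cartilage-bone interface
is proxied by the topmost bone voxel per column (the phantoms have no
cartilage, mirroring a bone-only segmentation), and the anchor is the
interface height at the compartment's middle column.

Each compartment gets three stacked boxes: subchondral (anchor down 10 mm),
mid (next 10 mm), trabecular (next 10 mm); heights are
`round(10 mm / vertical spacing)` voxels with round-half-away-from-zero,
so 20 voxels at 0.5 mm and 17 at 0.6 mm. The horizontal extent is the
central 80% of the compartment span in both horizontal axes (the original
description does not state it; 0.8 is configurable and recorded as an
assumption), clipped to the mask bounding box. The six boxes are pairwise
disjoint by construction and extraction is translation-equivariant.

# Radiomic features

Per VOI the engine emits 3 orientation, 12 histogram and 271 texture
features; 17 shape features are computed once on the whole tibia. The
271-feature decomposition is pinned in `feature_config()` and validated by
a count test:

| family | parameters | count |
|---|---|---|
| GLCM | 10 descriptors x mean/SD over the 13 unique 3-D directions | 20 |
| GLRLM | 16 descriptors x mean/SD over 13 directions | 32 |
| GLSZM | 16 descriptors (26-connected zones) | 16 |
| NGTDM | coarseness, contrast, busyness, complexity, strength | 5 |
| LBP | riu2 codes, P = 8, radii 1-3, 10 histogram bins each | 30 |
| Gabor | 7 frequencies x 12 angles x mean/SD of response magnitude | 168 |

Matrix families are computed in 3-D on a 16-level equal-width quantization
between the in-mask minimum and maximum (a constant VOI maps to level 1 by
convention, not an error); LBP and Gabor are computed slice-wise on
sagittal slices, matching common radiomics-workflow behaviour for those
families. Gabor kernels are complex, DC-free (zero response to constants),
with envelope sigma 0.56/frequency; frequencies above Nyquist are
rejected. NGTDM coarseness with a zero denominator returns the documented
constant 1e6, never infinity. The 12 histogram features are min, max,
mean, median, SD, skewness, kurtosis, range, IQR, 16-bin entropy and
energy, and the peak (most populated bin centre); zero-variance input
returns 0 for skewness/kurtosis. Where the published supplement's exact
itemization is not available, these parameter grids are the package's
pinned assumptions, chosen once to reproduce the printed family totals.

The 17 shape features are six sagittal-slice descriptors (compactness,
solidity, circular variance, normalised radial mean and SD, eccentricity)
aggregated as mean and SD across slices, plus volume (mm^3),
surface-to-volume ratio and the three bounding-box extents. Slice
perimeters come from the marching-squares contour smoothed by two passes of
Chaikin corner cutting, which brings a digital ball's compactness within
about 7% of the circle bound at the default resolution; single-voxel
slices are skipped. Orientation is three principal-axis angles (two
azimuths modulo 180 degrees and an inclination) of the mask's
second-moment tensor.

All feature names follow a `family_statistic_parameter` convention so CSV
columns are stable across runs.

# Elastic-net classification

Three designs are supported: covariates (age, BMI), image (features of the
selected VOIs, plus whole-bone shape when the selection is `All`), and
combined. The model is logistic regression penalized by
`lambda * (alpha * ||b||_1 + (1 - alpha)/2 * ||b||_2^2)` with an
unpenalized intercept and uniform class weights. The solver is iteratively
reweighted least squares with coordinate descent, sequential strong-rule
screening and KKT verification (the standard algorithm for this model); a
step-halving safeguard makes the recorded objective trace non-increasing,
and tests pin the solution against both an unpenalized `glm()` limit and a
generic Nelder-Mead oracle on the full objective. glmnet — which is also
installed — is used only as an independent cross-check in the test suite,
never as the implementation.

`grid_search_cv()` runs repeated stratified k-fold CV (defaults: k = 10,
R = 100 repetitions) over the grid alpha = 0.1..1 step 0.05 (19 values)
and lambda = 0.001..0.15 step 0.009 (17 values, ending at 0.145 because
0.15 is off-grid). Predictors are standardized with training-fold
statistics only — a property test verifies that corrupting one subject
never changes the out-of-fold scores of the other subjects in its test
fold. The selection criterion is the mean out-of-fold ROC AUC (the
headline metric); per-repetition AUCs are averaged by default (`pooling =
"averaged"`), with pooled scoring available, since the original protocol
does not state the pooling. Ties break toward larger lambda, then larger
alpha. Warm starts run down the lambda path within each fold.

On strongly separable synthetic cohorts many correlated texture features
reach univariate AUC near 1, and the lasso end of the grid keeps one
arbitrary representative while zeroing its correlates. Coefficient
*direction* checks therefore read the planted shape effect (compactness,
strictly negative) from the selected combined fit, and the planted texture
effect (GLCM homogeneity, positive) from a fit at the selected lambda with
the most ridge-leaning alpha in the grid, where the elastic net's grouping
behaviour distributes weight across the correlated planted features.

# Evaluation

ROC AUC uses the Mann-Whitney mid-rank formulation (ties count 0.5); PR
AUC is non-interpolated average precision with tied scores entering as one
threshold group, so a constant classifier scores exactly the prevalence.
Confidence intervals are stratified percentile bootstrap (B = 2000,
resampling positives and negatives separately, seeded); the original
report's CI construction is not stated, so bootstrap was chosen as a
metric-agnostic method and real-data CI widths are not expected to match.
`report_table()` lays results out as VOI-selection rows by model-mode
columns with `est (lo-hi)` cells and explicit `NA` for missing cells.

# Pipeline and reproducibility

`run_pipeline()` executes simulate -> segment -> voi -> features -> train
-> evaluate, each stage reading only the on-disk outputs of earlier stages
(NIfTI/CSV/JSON), and writes a manifest with per-stage seeds, timings and
MD5 checksums; identical config + seed reproduce identical feature CSVs. A
disabled upstream stage surfaces as an error naming the missing input.
`validate_config()` fills defaults, rejects unknown keys by name, and
checks value invariants before any stage runs. A thin command-line wrapper
(`inst/cli/tibrad.R`, subcommands simulate/segment/voi/features/train/
evaluate/run-all) exposes the same functions from a shell.

# Problem sizes used by the test suite

Chosen as the package's own desk-scale operating points and fixed:

* unit tests run on 64 x 96 x 48 phantoms at 0.5 mm;
* the matrix-family oracle suite compares 25 random 5^3 volumes x 4
  families against brute-force enumeration;
* the null study permutes labels at n = 200 with 10-fold CV and R = 5;
* the planted-effect study uses n = 200 default-grid phantoms, alpha
  {0.1, 0.55, 1.0}, lambda 0.01..0.145 step 0.009, 10-fold CV, R = 2;
* the segmentation study uses 10 phantoms against 5 atlas phantoms with
  appearance prediction at 2x downsampling;
* full-pipeline tests run n = 10 cohorts with 2 atlases.

# Known limitations

* The registration backend is a simple MI-affine + block-matching scheme;
  it satisfies the stated contract on phantoms but is not a substitute for
  a production registration toolchain on real MRI.
* The 271-texture decomposition, Gabor bank, LBP radii, grey-level count
  (G = 16), VOI horizontal extent (80%) and histogram "peak" are pinned
  assumptions where the original parameters are not printed.
* Synthetic effect sizes are free parameters; the package's discriminative
  results on phantoms say nothing quantitative about real cohorts.
* Bootstrap CIs differ by construction from the original (unstated) CI
  method.
* Only right-knee laterality is modelled directly; left knees are handled
  by a flip flag, and bilateral analysis is out of scope.
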