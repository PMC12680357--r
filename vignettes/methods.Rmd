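---
title: "Surrogate shape modelling for spring-assisted cranioplasty: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate shape modelling for spring-assisted cranioplasty: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Sagittal craniosynostosis — premature fusion of the midline suture — leaves an
infant's skull long and narrow (scaphocephaly, low cranial index). A common
correction is spring-assisted cranioplasty: a rectangular parietal osteotomy
is cut, and two compressed stainless-steel springs are seated in drilled
notches across the cut. The springs open over the following weeks, pushing
the two parietal flaps apart and widening the vault. Which spring model to
implant and where to cut are decided in theatre, largely from experience;
finite-element simulation can predict the outcome but takes hours of
engineering work per patient.

`sacshape` implements the machine-learning alternative end to end: simulate
many candidate surgeries across a population of skulls, compress all shapes
into a low-dimensional statistical shape space, and train a multi-output
regressor that maps *(age, osteotomy geometry, spring parameters,
pre-operative shape)* to the post-operative shape in milliseconds. Because
no imaging data ships with the package, a parametric synthetic-anatomy
module stands in for the CT-derived population, and a deterministic
quasi-static shell simulator stands in for the finite-element stage. The
learning pipeline itself — shape model, design of experiments, model
screening, Bayesian tuning, validation metrics — is the real thing.

## Synthetic anatomy

A patient is parameterised by age (days), skull thickness, soft-tissue
thickness, three ellipsoid semi-axes and a scaphocephaly severity
(`elongation`). Population defaults are the cohort statistics a clinical
series of spring-corrected infants reports: skull thickness
$2.02 \pm 0.33$ mm, skin thickness $3.42 \pm 0.51$ mm, age
$174 \pm 35$ days truncated to 90–300 days. Semi-axis defaults
(width 58, length 64, height 55 mm; elongation $1.18 \pm 0.06$) were chosen
once so that the synthetic cohort spans pre-operative cranial indices of
roughly 64–76 %, the range typical of scaphocephalic infants; they are
configurable through `population_spec()` (R arguments or a JSON file).

The neurocranium is the upper part of an ellipsoid cut by the
nasion–tragion analogue plane. The cut sits *below* the ellipsoid equator
(at $0.35\,c$ under the centre): a real head is widest above the skull
base, and this matters mechanically, because the base ring is clamped in
the simulator and a hemisphere cut exactly at its widest ring could never
widen. Severity is applied as a volume-preserving transform
$b \mapsto e\,b$, $a \mapsto a/\sqrt{e}$, $c \mapsto c/\sqrt{e}$, so the
cranial index scales as $e^{-3/2}$ while the enclosed volume is unchanged.
(Elongating $y$ and narrowing only $x$ by $1/\sqrt{e}$ would scale volume
by $\sqrt{e}$; narrowing the height as well restores exact invariance and
leaves the stated CI law intact.)

Every skull at a given resolution shares one quadrilateral-derived
triangulation (default ≈ 2000 vertices), so point correspondence across
the population holds *by construction* — the property the template
registration stage establishes for real meshes. Coronal and lambdoid
suture bands (declared width 2 mm, widened to the local edge length on
coarse meshes) sit at fixed fractions (0.30, 0.85) of the anteroposterior
extent from the anterior pole; the reference point for all osteotomy
measurements is the centre of the coronal suture on the midline.

The osteotomy rectangle is measured the way a surgeon with a tape measure
would: arc length along the midsagittal midline. With $L$ the midline arc
from the reference point to the lambdoid suture, the anterior notch pair
sits at $A\,L$, the posterior pair at $AP\,L$, and the pair separation is
$LAT\,L$ of cross-sectional arc. Valid ranges are $A \in [0.18, 0.30]$,
$AP \in [0.47, 0.63]$, $LAT \in [0.10, 0.25]$ (ratios of $L$). Notches are
5 mm marks at the rectangle corners. Faces inside the rectangle are
flagged rather than removed — the simulator softens them.

## The spring-distraction simulator

The simulator is a deliberately simple quasi-static elastic model chosen
for smoothness, determinism and speed (a fraction of a second per surgery);
it is a stand-in for a finite-element solve, not a re-implementation of
one, and no claim of material fidelity is made. Displacements $u$ minimise
$\tfrac12 u^\top K u - f^\top u$ with

$$K = \alpha\,L_{\mathrm{graph}} + \beta I$$

on the free vertices, where $L_{\mathrm{graph}}$ is the edge-weighted graph
Laplacian of the mesh applied blockwise to the three coordinates. Edge
weights encode tissue compliance: bone 1, suture bands 1/10, osteotomy
rectangle 1/50 (a soft hinge). The skull base ring is clamped ($u = 0$).
The global weight $\alpha$ scales linearly with `age_days / 174` — older
bone is stiffer — with $\alpha_0 = 0.7$ at the reference age, calibrated
once so that the condensed stiffness felt by a spring pair
(≈ 0.5–1 N/mm) is commensurate with the catalogue stiffnesses and typical
openings land mid-range (≈ 30–50 mm) rather than saturating at either end.
$\beta = 10^{-3}\alpha$ is a regularisation floor.

Springs have free length $L_0 = 60$ mm (the real device value) and push
with $F = k (L_0 - x)$, clamped at zero beyond the free length — they
never pull. The catalogue stiffnesses (0.5 / 1.0 / 1.5 N/mm for
S10 / S12 / S14) are placeholders: the measured per-model constants are
not published with this package, and users with bench data should supply
their own via `spring_catalogue()`. Each spring acts as an
equal-and-opposite force pair on the vertex sets of its two notch marks
(the drilled notches anchor in bone, so notch surroundings keep bone
stiffness even inside the rectangle), directed along the current pair
separation.

Force and opening are coupled self-consistently by fixed-point iteration
on the openings (tolerance $10^{-4}$ mm). The default `"linearised"`
coupling solves each iteration exactly: two unit-force solves give the
$2\times2$ condensed compliance, and the force balance
$(I + K_s D)\,F = K_s(L_0 - d_0)$ is solved directly with the push-only
clamp re-imposed; only the geometric nonlinearity (direction updates)
iterates, which converges in 2–3 rounds for any stiffness ratio. A
`"naive"` relaxed iteration is kept for diagnostics (one unrelaxed step is
exactly linear in the applied forces, a property the tests use). The
closed form $x^\ast = k L_0 / (k + c)$ against the statically condensed
stiffness $c$ is the solver's analytic oracle.

## Statistical shape modelling

Shapes are flattened to vectors $(x_1, y_1, z_1, \dots)$ and stacked as
columns. The model is standard PCA: mean shape $\bar m$, deviations
$d_i = m_i - \bar m$, eigenpairs of the sample covariance (divisor
$n - 1$), computed through the $n \times n$ Gram matrix of the deviation
matrix when $3N > n$ — algebraically identical to the dense
eigendecomposition (the tests verify this against an explicit small-case
oracle) and far cheaper at $3N \approx 6000$, $n \approx 2400$. A shape is
encoded as $b = \Phi^\top (m - \bar m)$ and reconstructed as
$\bar m + \Phi b$. Eigenvector signs are fixed (largest-magnitude entry
positive) so runs are reproducible. Modes are retained up to the smallest
count whose cumulative explained-variance fraction reaches the threshold;
the default 0.94 applies to both the pre-operative model (built on the 30
input skulls) and the outcome model (built on all simulated outcomes),
which are deliberately separate models.

## Design of experiments and the dataset

Per patient, the number of candidate surgeries is
$\mathrm{round}(\mathcal N(80, 2.5))$ clipped to $[75, 85]$ — an
$80 \pm 5$ band read as $\pm2\sigma$. The three ratios are independent
truncated normals centred mid-range with $\sigma = \text{range}/4$
(≈ 95 % of the untruncated mass in-range); spring models are uniform over
the catalogue, independently per site, and anterior and posterior springs
may differ. Draws with $AP \le A$ are rejected and redrawn. A Latin
hypercube option (`method = "lhs"`) provides a space-filling alternative.

One dataset row per simulation: age, $A$, $AP$, $LAT$, anterior $(k, L_0)$,
posterior $(k, L_0)$ — 8 features — plus the input-mode and output-mode
coefficients. With 11 + 11 modes this is the classic 30-column layout. The
split holds out $\lceil 0.33\,n \rceil$ rows; feature *and* output columns
are standardised with statistics fit on the training rows only. Outputs
are standardised as well as inputs so that the reported MSE/MAE are on a
scale-free mode scale and comparable across modes — a documented choice,
not asserted to be the only possible one. The spring free-length columns
are constant whenever all catalogue entries share $L_0 = 60$; such
zero-variance columns are centred, flagged, and handled by every learner.

## Surrogate models, screening and tuning

Seven families are implemented behind one interface: linear regression
(the baseline, natively multi-output), decision tree, random forest,
XGBoost, support vector regression, gradient boosting and AdaBoost.R2 —
the last two implemented in-package over `rpart` base learners (classic
least-squares/Huber gradient boosting and AdaBoost.R2 with linear loss),
since no maintained R equivalent was available in the target environment.
Single-output learners are wrapped per output dimension. Screening runs
5-fold cross-validation and discards families below the linear baseline or
with fold-to-fold standard deviation above 0.10 (the "high variability"
rule; the threshold is configurable as the reference value is visual, not
numeric). The baseline itself is never discarded.

Hyperparameter tuning is sequential model-based optimisation: a
Latin-hypercube initial design, then a Gaussian-process surrogate (RBF
kernel, median-heuristic length scale) with expected-improvement
acquisition over a random candidate pool — 50 objective evaluations, each
a seeded 5-fold CV of the mean R². The SVR space is degree [1–9], gamma
{scale, auto}, epsilon [0–5], kernel {linear, poly, rbf, sigmoid},
C [0.01–5]; spaces for RF/XGB/GB mirror the standard sklearn-style
domains, with two interface notes: `min_samples_split` maps onto ranger's
terminal-node size (the closest available knob), and the GB `criterion`
parameter is accepted but inert because rpart always splits on anova
deviance. Metrics are the uniformly-averaged per-output $R^2$, and MSE/MAE
averaged over all standardised output entries.

## Prediction and validation

`predict_outcome()` is the deployment path: register the pre-operative
head to the template (identity for synthetic meshes, NRICP otherwise),
strip soft tissue by an inward vertex-normal offset of $t_{skin}$, project
onto the input model, scale, predict the output coefficients, reconstruct
the post-operative skull, and restore soft tissue by an outward offset.
Vertex-normal offsetting (not a true Minkowski offset) is used because it
preserves topology, which point correspondence requires; on smooth convex
surfaces the roundtrip error is below 2 % of the offset.

`evaluate_validation()` compares a prediction with a reference surface
after rescaling the reference uniformly (isotropically, about its
centroid) to the predicted volume — the unchanged-volume normalisation
that removes interval growth when a follow-up scan is weeks younger than
the model's snapshot. Surface error is the exact point-to-triangle
distance (never point-to-vertex, which biases error upward on coarse
meshes), reported per-vertex with mean/95th/max summaries and exportable
as CSV or PLY scalars. `correlation_analysis()` reports Pearson r (with
unthresholded p-values) between per-case error and age, pre-operative CI
and spring stiffnesses.

Registration itself is two-stage: point-to-surface rigid ICP (closest
point on triangle, which avoids the lattice locking that nearest-vertex
correspondence exhibits between same-resolution meshes), then Amberg-style
NRICP — per-vertex affine transforms, a stiffness term penalising
neighbour-transform differences, solved as a sparse linear system per
level of the decreasing schedule {50, 20, 5, 2} with up to 10 inner
rounds. Landmark terms are omitted (none are defined for this anatomy);
in the all-synthetic pipeline correspondence is identity by construction
and NRICP is exercised by the tests and reserved for external meshes.

## What the synthetic pipeline does and does not show

The generator produces smooth, symmetric, ellipsoid-derived skulls with
exact correspondence and a noiseless deterministic simulator. Passing the
pipeline's acceptance-level checks therefore demonstrates that the
*method* — shape compression, DoE coverage, surrogate learning, tuning,
metrics — is implemented correctly and that a smooth simulator is
learnable to high accuracy at the stated corpus size. It does **not**
demonstrate clinical accuracy: real heads have frontal bossing,
fontanelles, asymmetry, imaging noise, imperfect registration, and
post-operative growth, none of which the generator emulates. Consistent
with that, the clinical-cohort validation numbers a real study reports
(multi-millimetre mean surface errors against follow-up photographs, and
their correlations with age and spring stiffness) are *not* reproduced
here and should not be expected from synthetic data: prediction of real
outcomes is much harder than prediction of simulated ones. The
`correlation_analysis()` tooling is provided for users with real paired
data.

Two further honest limitations: PCA is linear, so strongly nonlinear shape
variation would be under-modelled; and an RBF support-vector surrogate
saturates outside its training range — for spring stiffnesses below the
softest catalogue entry it predicts roughly the softest-spring outcome
rather than extrapolating to the unoperated shape (the simulator's exact
zero-force limit is a solver property, not a surrogate one).

## Numerical choices and problem sizes

All tolerances live in one place per module: STL vertex merging at
$10^{-6}$ mm; spring-coupling convergence at $10^{-4}$ mm on the openings
(≤ 100 iterations); solver residual asserted below $10^{-8}$; SSM
rank cut at $10^{-12}$ of the leading eigenvalue; ICP stops at
$10^{-6}$ mm residual improvement. Degenerate inputs are handled
explicitly: zero-area faces are dropped at mesh construction, open meshes
warn and flag their divergence-theorem volume, zero-variance dataset
columns are centred and flagged, empty epsilon-tube SVR models fall back
to the training mean, and collinear ICP targets are rejected.

The test suite runs the full default corpus once (30 patients × ~80
configurations at ~2000-vertex meshes — a few minutes of simulation and a
few more of tuning) and keeps every other fixture at few-hundred-vertex
scale; the vignette and README examples use the same scales. These sizes
are the package's reference study conditions, chosen to match the corpus
the method is specified at.
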