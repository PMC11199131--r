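---
title: "Modelling central-place forager distributions and bycatch risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling central-place forager distributions and bycatch risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpfrisk)
```

`cpfrisk` chains three analyses that are usually done with three different
toolboxes: telemetry quality control and presence building, presence-only
species distribution models for a central-place forager, and a spatially
explicit exposure–consequence risk assessment against fishing fleets. This
vignette explains the science implemented in each stage, the assumptions
behind it, the parameters that matter, and the design decisions made where
the methodology is genuinely open. Everything shown here is computed by the
package's own functions; the test suite exercises every claim.

## 1. The two-distributions view

For an animal that must return to a colony between foraging trips, a map of
"suitable habitat" answers a different question than a map of "used habitat".
The **potential distribution** is the population-level answer: where are
environmental conditions like the ones the animals select? It is deliberately
blind to accessibility, so it can flag suitable areas the tracked animals
never reached — relevant for assessing risk to untracked colonies. The
**realized distribution** is the individual-level answer: where do these
animals actually go, given the colony constraint and individual variability?

The package fits both:

* a binomial GLM (logit link) on pooled, spatially rarefied presences for the
  potential distribution, and
* a binomial GLMM with a random intercept per individual **plus a negative
  exponential kernel (NEK) accessibility covariate** for the realized
  distribution.

The NEK is the surface $a^{d/d_0}$ where $d$ is Euclidean distance from the
colony (km), $d_0$ a configurable distance scale (km per decay unit), and
$a \in (0, 1]$ the decay coefficient: $a = 1$ removes the constraint, small
$a$ confines occurrence near the colony. It enters the GLMM as a fixed-effect
covariate on the logit scale, so the fitted model is

$$\mathrm{logit}\,P(y_{ij} = 1) = \beta_0 + \boldsymbol\beta^\top
\mathbf{x}_{ij} + \beta_{\mathrm{nek}}\, a^{d_{ij}/d_0} + b_i,
\qquad b_i \sim N(0, \sigma^2_{id}).$$

We report the variance-partition $R^2$: marginal
$R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_{id} + \pi^2/3)$ with
$\sigma^2_f$ the variance of the fixed-effect linear predictor, and
conditional $R^2_c$ adding $\sigma^2_{id}$ to the numerator.

## 2. Telemetry processing

Fastloc-GPS fixes pass four filters, in a fixed order so each removed fix
carries exactly one reason: (1) quality — fewer than 5 satellites or residual
error above 35 removed; (2) land — the containing 1-km cell is land;
(3) speed — a forward sweep per individual removes fixes implying more than
5.5 m s⁻¹ from the *last retained* fix, which stays the anchor (the common
trajectory-QC convention; speeds exactly at the threshold are kept);
(4) study-area clip at 100 km from shore, which balances the relative
occurrence area and avoids extrapolating beyond typical foraging range. An
audit table reconciles per-filter removal counts with the input.

Presences are then rarefied to one per grid cell (population design) or one
per cell and individual (individual design), with the earliest fix winning
ties so results are deterministic. A per-individual random subsample
(default 30 fixes) supports reduced-data sensitivity analyses.

## 3. Pseudo-absences by environmental profiling

True absences do not exist in presence-only telemetry. The package assumes
absences are more probable in environments *dissimilar* to the presences: an
RBF one-class SVM is trained on the (rescaled) covariate vectors at
presences, every study-area cell is classified presence-like or dissimilar,
and pseudo-absences are sampled uniformly, one per presence, from dissimilar
cells — outside a 5 km presence buffer for the population design; inside the
convex hull of all presences, outside 2 km buffers, with profiling refit per
individual, for the individual design (realized-distribution absences should
be nearer to presences, in habitable but unoccupied places).

Tunables: `nu` (default 0.1) bounds the fraction of presences the envelope
may reject — smaller values give a more inclusive envelope and a more extreme
absence zone; `gamma` defaults to $1/(p \cdot \overline{\mathrm{var}})$ of
the presence covariates. Individuals with fewer than 10 rarefied presences
fall back to the pooled profile (with a warning) since a one-class fit on a
handful of points is meaningless. Degenerate hulls (collinear presences) are
inflated by one cell width.

## 4. Covariates and the grid

All spatial work happens on one planar, metre-based grid (row 1 = north,
values at cell centres); inputs must be pre-projected. The package provides
focal gap-filling (circular neighbourhood mean, radius 2 cells — patches the
small nearshore gaps typical of satellite products without extrapolating
beyond the observed range), bilinear resampling to the analysis grid,
per-layer transforms (log for right-skewed chlorophyll and depth, square root
for slope; a configurable offset, default $10^{-6}\times$ the layer maximum,
is added before log when zeros are present) and min–max rescaling to [0, 1].
Rescale bounds are computed from the full study-area raster and stored, so
predictions reuse the training scale.

Collinearity screening drops covariates until all pairwise Pearson
$|r| < 0.7$ and all VIF $\le 4.5$; the drop order is deterministic (the
worse-connected member of the worst pair goes first), and the report records
each drop and its trigger. On the synthetic system this reliably removes
distance-to-shore (and usually one of distance-to-shelf / depth /
river-distance, depending on the seed), mirroring how bathymetric and
distance layers alias each other in real coastal data.

## 5. Evaluation

* **Spatial block CV** (population model): square blocks with side set to the
  median spherical-variogram range of the covariates; blocks are assigned to
  k = 5 folds 100 times and the assignment minimising the L1 deviation of
  per-fold class shares from 1/k is kept.
* **Leave-one-individual-out CV** (individual model): the held-out animal is
  predicted with its random intercept at 0 ("novel" mode), measuring
  transferability to unseen individuals.
* **Metrics**: rank-based AUC (ties ½); sensitivity, specificity and TSS at
  the threshold maximising TSS on the training fold; and the continuous
  Boyce index (CBI) — the Spearman correlation between the
  presence-to-background ratio P/E in 101 moving score windows (width 10% of
  the score range) and the window centre.
* **Variograms** of model residuals (empirical semivariance, spherical model
  by count-weighted least squares with multiple range starts) quantify
  leftover spatial autocorrelation.

Two properties of the CBI matter for interpretation and are verified in the
tests. First, it is nearly invariant to monotone transforms of the score, so
it measures calibration ranking, not discrimination. Second, under a null
design (presences drawn from the background distribution) the P/E curve is
flat and its Spearman correlation with the window centre is noise with high
variance *regardless of sample size* — adjacent windows share 90% of their
data — so "null CBI ≈ 0" holds for the mean over replicates, not per run.

These same properties limit how sharply the NEK decay coefficient can be
selected: the candidate surfaces $a^{d/d_0}$ are all monotone in colony
distance, i.e. near-monotone transforms of one another once a free
coefficient is fitted, so held-out CBI differs across candidates only through
second-order calibration effects. On synthetic data the in-sample GLMM
deviance shows a shallow minimum near the generating value, but the CBI
argmax frequently lands elsewhere, often at a grid end. `select_nek_a`
implements the CBI criterion faithfully and returns the full score table so
users can see how flat the profile is; treat the selected value as a tuning
outcome, not an estimate with confidence.

## 6. Combining and classifying

Per-individual conditional predictions are aggregated cell-wise by mean and
by maximum; the maximum is the pipeline default for risk input (the
precautionary choice — imbalanced tagging tends to underestimate realized
suitability). Both the population and the aggregated individual surfaces are
cut at their terciles (type-7 quantiles over non-missing cells, ties to the
lower class), and the 3 × 3 joint class maps to overall low/medium/high
suitability with high *potential* emphasised: population tercile 3 is always
high; tercile 2 is high only when the individual tercile is 3; tercile 1
reaches at most medium. The mapping is a plain 3 × 3 matrix argument, so any
alternative weighting is one line of config. A second 9-entry mapping —
emphasising *agreement* (class 3 only where both terciles are 3) — produces
the species-distribution layer the risk model overlaps with fishing.

## 7. The risk model

For each fleet (stressor) and subregion, exposure E and consequence C are
weighted averages of criteria scored 1–3 (0 omits a row):

$$E = \frac{\sum_i x_i / (d_i w_i)}{\sum_i 1 / (d_i w_i)}$$

with data-quality $d_i$ and importance weight $w_i$ in 1–3 — better-known,
more important criteria count more. Spatially explicit criteria supply a
classed raster instead of a fixed score: fishing intensity (quartic kernel
density of set locations on a 3 km grid with 5 km search radius, quantile
reclassified to 1–3, zero-density cells class 1) and likelihood of
interaction (cell-wise sum of the intensity class and the distribution class,
remapped 2–3 → 1, 4 → 2, 5–6 → 3). Risk is the Euclidean distance from the
no-risk origin of E–C space, $\sqrt{(E-1)^2 + (C-1)^2}$, computed only where
the distribution and the fishery overlap (0 elsewhere); the single-stressor
maximum is $2\sqrt2 \approx 2.83$ and two overlapping stressors can sum to
$\approx 5.66$. Subregion statistics (nearshore = within 5 NM = 9,260 m of
shore) report mean risk over each stressor's overlap cells — the denominator
choice is recorded in the output metadata. A four-row stoplight table
characterising uncertainty in the input data types is echoed into the
outputs; it carries no scoring logic.

The shipped criteria table is a documented example for the synthetic system
(nearshore exposure scored higher for both fleets), not a set of published
expert ratings.

## 8. The synthetic study system

`make_environment()` builds a coastal domain (default 120 km offshore ×
300 km alongshore at 1 km cells — a long coastline with a 100 km offshore
clip, so alongshore variation is not swamped by the offshore gradient) with a
sinusoidal coastline, a mid-coast colony, two river mouths confined to one
half of the coast, and eight covariates: SST (weak offshore warming + strong
mesoscale field), chlorophyll (river plumes × lognormal patchiness), EKE
(bounded logistic field with a mild offshore trend), depth (shelf break at
30 km, multiplicative roughness), slope (gradient of the smooth bathymetry ×
an independent roughness factor, so slope is not a mere proxy for depth), and
distances to rivers, shore and shelf. True suitability is the inverse logit
of `default_beta_true()` on the rescaled covariates — three strong drivers
(chlorophyll +5, SST −4, depth −5) with the remaining layers carrying no true
effect, so variable selection has something to reject and the drivers stay
identifiable under profiled pseudo-absences (with many correlated informative
drivers, the presence-vs-dissimilar-absence contrast does not constrain
conditional coefficient signs).

`simulate_tracks()` samples positions from the stationary law
$\mathrm{invlogit}(\mathrm{logit}\,s(x) + b_i + \beta_{nek}(a^{d/d_0}-1))$ —
exactly the model family the GLMM fits, which is what makes parameter
recovery a fair test; $a = 1$ reduces to suitability-only sampling. The
sampler is a Metropolis chain whose proposal is uniform over cells within
$0.9 \times v_{max} \times \Delta t$ of the current fix, so clean consecutive
fixes can never violate the speed filter while the marginal stays the target
law. Defaults: 9 individuals, 40-min fix interval, $\sigma_{id} = 1$,
$a = 0.05$, $d_0 = 10$ km, $\beta_{nek} = 6$ (odds at unreachable distance
$e^{-6}$ times colony odds — foraging ranges of a few tens of km). A
configurable fraction of fixes (default 5%) is corrupted — low satellites,
high residual, displacement onto land, or a ≥ 30 km teleport — with
corruptions kept ≥ 3 fix indices apart so each triggers exactly one filter,
and all injections logged for exact audit reconciliation.

What the generator does *not* emulate: behaviourally realistic movement
(trips, haul-outs, correlated headings), temporal covariate dynamics,
tag-loss and duty cycling, and observation error below the cell scale.
Passing tests therefore demonstrate that the statistical machinery recovers
the structure it assumes, not that the models are adequate for any particular
real dataset.

`simulate_fishing()` draws industrial sets from a two-zone process with a
stated nearshore share (default 20%) and artisanal sets only within 5 NM,
aggregated to a 1 × 1 NM grid with counts, mirroring how shipowner reports
arrive pre-gridded.

## 9. Numerical and design choices

* Grid convention fixed (row 1 north, centre-referenced cells) so tests are
  bit-exact; raster I/O is plain-text ASCII grid.
* OCSVM `nu = 0.1` by default: one-class implementations commonly default to
  0.2; 0.1 keeps the envelope inclusive enough that the absence zone is
  genuinely dissimilar habitat. Exposed in the config.
* GLMM estimation: `lme4::glmer`; fits inside cross-validation loops use
  `nAGQ = 0` (much faster, adequate for rank-based scoring), final fits
  `nAGQ = 1`.
* Perfect separation: `fit_glm` errors by default (the estimates are
  meaningless); the pipeline orchestration proceeds with a warning because
  its downstream products (AUC, CBI, tercile maps) are rank-based. With a
  tight kernel a compact presence cloud versus dissimilar absences *can* be
  exactly separable — real data with observation noise rarely is.
* Backward elimination stops when no single removal improves mean CV AUC by
  more than 0.001; the full trace is returned because elimination paths on
  reduced datasets legitimately differ.
* Variogram fitting uses count-weighted least squares with three range
  initialisations (the objective is flat when the variogram has not
  plateaued); the spherical model's range is reported as the practical range.
* Default problem sizes (9 animals × 200 fixes on the 120 × 300 km world; 10
  NEK candidates; 100 fold-assignment iterations) were chosen so a full
  pipeline run completes in well under a minute while keeping ≥ 500
  population presences; recovery experiments in the tests use 300 fixes per
  animal.
* Everything random takes an explicit seed, and stage manifests record file
  hashes, so two runs of `run_pipeline("all")` under one seed are
  byte-identical.

## 10. Known limitations

The CBI-based NEK selection is weakly identified (Section 5); the kernel
itself, however, clearly matters for *simulation* and for conditional maps.
The population GLM on profiled pseudo-absences recovers coefficient signs
reliably only when the tracked sample ranges freely — with a tight
central-place constraint the accessibility term is an omitted confounder of
the environmental coefficients, which is precisely the motivation for
modelling the realized distribution separately. Exposure–consequence scores
inherit the subjectivity of their criteria tables; the package makes the
table explicit and machine-checkable rather than claiming objectivity.
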