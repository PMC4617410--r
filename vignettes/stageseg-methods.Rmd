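---
title: "Segregating cognitive task stages from multivariate BOLD time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segregating cognitive task stages from multivariate BOLD time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stageseg)
```

## The problem

In a self-paced task — here a virtual delayed win-shift radial arm maze, in
which a participant encodes the locations of six blocked maze arms during a
training phase, holds them across a delay, and retrieves them during a test
phase — the cognitive stages of a trial (encoding, choice, reward
expectation, reward consumption, delay, retrieval) are not fixed to the
scanner clock. Stage durations vary from trial to trial and participant to
participant. `stageseg` asks how much information about these stages is
carried in the *multivariate pattern* of voxel activity within a region of
interest (ROI), and whether an unsupervised learner would carve time on
task into similar stages without being told the labels.

Three analysis tracks share one data model: a time × voxel matrix paired
with one behavioral label per volume.

1. **Supervised discrimination.** MANOVA test statistics — Hotelling's
   generalized $T^2$ (the Hotelling–Lawley trace
   $\mathrm{tr}(\Sigma_w^{-1}\Sigma_b)$), Wilks'
   $\Lambda = \det \Sigma_w / \det(\Sigma_w + \Sigma_b)$, and Roy's greatest
   characteristic root $\lambda_{\max}(\Sigma_w^{-1}\Sigma_b)$ — quantify
   how separable the nine task stages are in voxel space. Because BOLD time
   series are autocorrelated, parametric F tests are invalid; significance
   comes from *block-permutation bootstraps* that shuffle whole runs of
   identical consecutive labels within each trial, preserving the
   autocorrelation of the labeling. Statistics are reported *normalized* by
   the mean of their bootstrap distribution, so 1 is the chance level.
2. **Hypothesis-driven contrasts.** The twelve choice blocks per trial are
   regrouped into two classes by working-memory load (early-training and
   late-test choices hold two items; late-training and early-test choices
   hold at least four), by the visual saliency of the landmark at the
   chosen arm, or at random. The Mahalanobis distance between the two
   classes of choice volumes, normalized by block bootstraps that permute
   class-to-block assignments within trial, attributes specific aspects of
   processing to an ROI. Regularized Fisher LDA on k-medoids-selected
   voxels provides the matching visualization.
3. **Unsupervised segmentation.** A Gaussian-emission hidden Markov model
   fitted by EM on a small set of representative voxels dissects time on
   task bottom-up. The state count is chosen by the minimum of a
   cubic-polynomial-smoothed AIC curve; the Viterbi state path is scored
   against the behavioral labels by a *Matching Index* (each state is
   assigned to the behavioral class whose binary indicator it best
   correlates with; the index is the percentage of volumes where the mapped
   path agrees with the labels), tested against cycle-shift, block- and
   random-permutation nulls.

## The synthetic study

No acquisition accompanies the package, so a first-class generator
reproduces the study conditions and every claim in the test suite is made
against planted structure.

* **Task template.** Each trial is: a visuomotor control phase (six control
  choice blocks) and a 30 s control delay, a training phase (choice blocks
  1–6, *encoding* navigation between blocks), a 30 s delay, and a test
  phase (blocks 7–12, *retrieval* navigation). Choice and
  reward-consumption segments are two volumes each by definition of the
  stage labels; navigation and reward-expectation segments draw
  shifted-geometric durations (minimum one volume) as a memoryless analog
  of self-pacing. At TR = 1.8 s these defaults give roughly 190 volumes per
  trial, i.e. about 950–1000 volumes for a five-trial run — the scale of a
  real session.
* **Emissions.** $y_t = \mu(\text{label}_t) + \text{participant offset} +
  \varepsilon_t$ with AR(1) noise (default $\varphi = 0.4$, innovation sd
  1) and optionally the canonical double-gamma HRF (peak 6 s, undershoot
  16 s, ratio 6) filtering the mean signal. State means are drawn i.i.d.
  Gaussian with sd `effect_size` — "effect size" is therefore the planted
  between-stage separation in noise-sd units.
* **Choice-block effects.** Optional mean shifts of $\pm\delta/2$ during
  choice volumes, by memory-load class on one voxel subset and by landmark
  saliency on another, let the grouping contrasts exercise a genuine double
  dissociation within one data set. The default landmark map balances the
  two factors: each load class holds two high-saliency and two neutral
  arms, and the saliency classes mix load conditions.
* **Errors.** Choice blocks fail independently with probability 0.01,
  which makes roughly one trial in ten an error trial — the proportion
  observed in the cohort the task was designed for.

What the generator does *not* emulate: physiological/vascular noise
spectra, motion, spatial voxel correlations within an ROI, and
nonstationary habituation effects. Passing tests therefore certify the
statistical machinery under its stated assumptions, not performance on any
particular scanner's data.

## Numerical choices

* **Preprocessing.** Per voxel: linear detrend, projection out of a
  discrete-cosine basis holding all components of period ≥ 256 s (an exact,
  phase-free high-pass), then z-scoring. The chain is idempotent to
  numerical precision. Zero-variance voxels are dropped, never imputed.
* **Deconvolution.** The hemodynamic response is removed by a
  frequency-domain Wiener filter
  $\hat{X} = Y H^* / (|H|^2 + \texttt{noise\_level})$ against the canonical
  HRF, with zero padding (no circular wrap). `noise_level` is the assumed
  noise-to-signal power ratio (reciprocal of assumed SNR; default 0.02).
  Two limitations are worth stating plainly: the final kernel-length worth
  of volumes of a truncated acquisition is only weakly constrained and is
  recovered poorly; and under genuine broadband measurement noise the
  *scalar*-regularized filter has an error floor — at a true power-SNR of
  10 the best achievable relative RMSE is about 0.3 (about 0.13 at
  amplitude-SNR 10) for band-limited signals, because the regularization
  cannot vary with frequency. The package's round-trip checks therefore
  quantify robustness to the assumed-SNR parameter on band-limited,
  noiseless convolutions, where the filter is accurate to a few percent.
* **Scatter convention.** "Within" and "between" are unscaled scatter
  matrices (the classical MANOVA convention); the Mahalanobis distance uses
  the pooled covariance $\Sigma_w / (N - 2)$. Because a bootstrap resample
  preserves the class-size multiset, any fixed rescaling cancels in the
  normalized statistics, so this choice is inert for the reported
  quantities.
* **Singularity.** The within matrix is ridge-regularized by
  `ridge * mean(diag(within))` on the diagonal (default `ridge = 1e-6`),
  never pseudo-inverted: deterministic and continuous in the data.
  Eigenvalues are obtained from the symmetric whitened form via Cholesky.
* **p-values.** All non-parametric p-values use the add-one estimator
  $(1 + \#\{\text{null} \ge \text{obs}\}) / (1 + B)$, which cannot return
  zero. For Wilks' $\Lambda$ the exceedance direction is reversed.
* **Normalization.** "Normalized by the bootstraps" is implemented as
  observed / mean(bootstrap), giving the interpretable ≈1-under-null scale;
  a bootstrap z-score is available via `normalization = "z"`.
* **Cycle shifts** draw offsets from `[min_shift, trial_length - min_shift]`
  with `min_shift = 3` volumes, excluding near-identity rotations.
* **EM.** Diagonal emission covariances (keeping the parameter count
  $(m-1) + m(m-1) + 2md$ well-defined and fits robust at small $T$); five
  random restarts by default, relative log-likelihood tolerance $10^{-5}$,
  500-iteration cap, variance floor $10^{-4}$. Trials are modeled as
  independent sequences: the state distribution resets to $\pi$ at each
  trial start, because a self-paced trial begins from the same behavioral
  state regardless of how the previous trial ended. Error volumes are
  excluded before fitting, consistent with the supervised analyses.
* **Viterbi and mapping ties** break toward the lower state/class index;
  zero-variance indicators get correlation 0.

## Design decisions that were genuinely open

* **k-medoids distance.** The prototyping objective is not pinned down by
  the method description; PAM on `1 - Pearson correlation` between voxel
  time courses is used (scale-free, the natural choice for time-course
  prototypes), with Euclidean distance as an option.
* **Random-grouping normalization order.** The ten random groupings are
  averaged — observed values and each bootstrap replicate alike — *before*
  normalization, matching the reading that a single average distance is
  carried forward for comparison.
* **Subsampled statistics** are compared against the pooled distribution of
  all `repeats × B` bootstrap values (not per-subset quantiles), matching
  the pooled-count reading.
* **AIC smoothing.** The smoothed curve is a global least-squares cubic in
  the state count, evaluated on the integer grid (the state count is
  integral); ties go to the smaller model. A property worth knowing: when
  states are *strongly* separated the AIC elbow is so deep that any cubic
  smoother shifts the argmin one state high; smoothing earns its keep in
  the moderate-separation regime, where the raw AIC minimum is noisy. The
  package's selection demonstration therefore plants three states at 0.4
  noise-sd mean separation (T = 600, five dimensions, mean dwell 8
  volumes), where smoothing measurably improves recovery; with strong
  separation one should trust the raw AIC minimum (also reported in the
  selection curve).
* **Lag profiles truncate** at trial edges rather than wrapping — circular
  shifts would fabricate transitions between trial end and start.
* **Error handling granularity.** Per-trial statistics retain error volumes
  and flag whole trials (the error analysis contrasts trials); all other
  analyses exclude error volumes, and grouping contrasts use only correct
  choice blocks.

## Problem sizes used by the test suite

The statistical property tests run at reduced but honest sizes chosen to
keep the full suite in the minutes range: calibration uses 200 null
simulations at B = 200 bootstraps; power uses 100 runs of the 5-trial,
50-voxel, one-sd design at B = 200; the double dissociation uses 50 runs at
B = 100; HMM recovery uses 20 seeds of the 9-state, 1000-volume, two-sd
configuration; Matching-Index calibration uses 200 runs at B = 99. The
acceptance script runs the full pipeline at the conventional settings
(B = 1000, 50 voxel subsets, k = 15 and k = 5 medoids).

## Known limitations

* Emission covariances are diagonal; strongly spatially correlated ROIs
  are better served by the full-covariance option (`stageseg` exposes the
  parameter count adjustment but the default stays diagonal).
* The Wiener stand-in for empirical-Bayes deconvolution shares its purpose,
  not its estimator; no fidelity to the original deconvolution operator is
  claimed, and its noise-floor behavior is described above.
* AIC-based state-count selection inherits AIC's mild overfitting: with
  deep likelihood elbows expect a one-state upward bias from the smoothing
  step.
* Group-level parametric inference (repeated-measures ANOVAs over real
  cohorts) is out of scope; the package stops at per-participant statistics
  and their non-parametric tests.

## A compact worked example

```{r example, eval = FALSE}
library(stageseg)

design <- task_design(n_trials = 5)
labels <- simulate_task_labels(design, seed = 1)
bold <- simulate_bold(labels,
                      generator_config(n_voxels = 30, effect_size = 1,
                                       ar = 0.4),
                      seed = 2)

x <- standardize_detrend_filter(bold, tr = 1.8) |>
  subtract_control_means(labels)
ok <- exclude_error_timepoints(x, labels)
task <- ok$labels$label %in% task_stage_labels()

r <- bootstrap_distribution(ok$bold[task, ], ok$labels[task, ],
                            statistic = "t2", B = 1000, scheme = "block",
                            seed = 3)
tidy(r)
autoplot(r)
```
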