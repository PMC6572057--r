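---
title: "metpipe: models, estimators and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metpipe: models, estimators and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metpipe)
```

This vignette is the package's own account of its statistics: what is being
modelled, which knobs matter, where the design was genuinely open and what
was decided, and what the simulation experiments do and do not demonstrate.

## 1. Identification: the four-layer hierarchical model

Identification asks, for every metabolite *j* in a user-supplied reference
library, whether it is present in the analysed sample. Four variables are
layered per library metabolite:

* **Presence** $Y_j \sim \mathrm{Bernoulli}(\rho)$ — latent; $\rho$ is the
  prior fraction of the library present in the sample.
* **Matching** $Z_j \mid Y_j \sim \mathrm{Bernoulli}(\gamma_{Y_j})$ —
  observed. Every *sample* spectrum is assigned to the library entry with
  the smallest cosine-angle dissimilarity (the argmin is total: even a
  spectrum dissimilar to everything is matched somewhere, and several
  sample spectra may select the same library entry, in which case the
  smallest of their scores is retained). A library entry is matched
  ($Z_j = 1$) when at least one sample spectrum selected it. $\gamma_1$ and
  $\gamma_0$ are the match rates for present and absent metabolites.
* **Correctness** $W_j \mid Y_j = 1, Z_j = 1 \sim \mathrm{Bernoulli}(\tau)$
  — latent. A match to an absent metabolite ($Y_j = 0$, $Z_j = 1$) is never
  correct, so $W_j \equiv 0$ there; when $Z_j = 0$ the variable is not
  defined.
* **Score** $S_j$ (degrees, observed when matched):
  $S_j \mid W_j = 1 \sim N(\mu_T, \sigma_T^2)$ for correct matches, and a
  one- or two-component normal mixture for incorrect ones
  ($n$-false-components is a user choice; 1 or 2 covers the two- or
  three-component overall mixtures seen in practice).

The joint density factorizes as
$[Y,Z,W,S] = [Y]\,[Z\mid Y]\,[W\mid Y,Z]\,[S\mid Y,Z,W]$, and the
complete-data log-likelihood is the sum of the four log-factors. The E-step
computes, per metabolite, posterior weights over the admissible
$(y, w, \text{component})$ configurations given $(z_j, s_j)$; the M-step has
closed-form weighted-proportion and weighted-moment updates. The per-library
deliverable is the confidence measure
$P_j = P(Y_j = 1 \mid Z_j, S_j;\hat\theta)$, reported in descending order.

### Assumptions worth stating

* Scores live on $[0^\circ, 90^\circ]$ but the component densities are
  untruncated normals. With the component means well inside the interval
  (correct matches near a few degrees, incorrect near 35–50°) the truncated
  mass is negligible; this is an approximation, not a constraint.
* Library metabolites are treated as independent. Several sample spectra
  competing for one library entry violates this mildly; the model absorbs it
  through the retained-minimum score convention.
* $\mu_T < $ every false-component mean is enforced after each M-step (by
  relabeling if necessary). This is the identifiability constraint that
  "correct matches are more similar", and it prevents label switching.

### Identifiability of $(\rho, \tau, \gamma_1, \gamma_0)$

The observed data enter the likelihood only through $P(Z=1)$ and the weight
$\rho\gamma_1\tau$ on the correct component: with all four probabilities
free, the likelihood is constant on a two-dimensional ridge, and the EM
fixed point depends on the start. All four are estimated by default because
in favourable data the ridge is short, but `fit_em(..., fixed =
list(gamma1 = , gamma0 = ))` freezes the match rates, and that is what the
package's own recovery experiments do: in a simulation the match rates are
known by design, and freezing them makes $(\rho, \tau)$ identifiable (the
match rate $\rho\gamma_1 + (1-\rho)\gamma_0$ then pins down $\rho$, and the
correct-component weight pins down $\tau$). In real use, a library of
spiked-in standards or a prior calibration run plays the same role.

### Numerical choices

* **Initialization** (`init = "auto"`): a deterministic k-means split of the
  matched scores (quantile-seeded centers, so refits are bit-identical);
  cluster moments seed the components, the lowest-mean cluster becoming the
  correct one; $\rho, \tau, \gamma_1, \gamma_0$ start at 0.5, 0.5, 0.9, 0.1.
* **Convergence**: relative change in the observed-data log-likelihood
  below `tol` $= 10^{-8}$, or 1000 iterations. The ascent property (the
  trace never decreases beyond $10^{-8}$ relative) is asserted in the test
  suite on every fit.
* **Degeneracy guards**: probabilities clamped to
  $[10^{-6}, 1 - 10^{-6}]$; variances floored at $10^{-6}$; a false
  component receiving essentially no posterior weight triggers a warning
  rather than a crash.
* At least 10 matched scores are required; below that the mixture is not
  meaningfully estimable and `fit_em()` refuses.
* The posterior is non-increasing in the score from $\mu_T$ upward. Below
  $\mu_T$ the unequal component variances make the Gaussian likelihood
  ratio bend back — a property of normal mixtures, not a defect — so the
  monotonicity check in the tests runs on $[\mu_T, 90]$, the scientifically
  relevant direction ("more dissimilar, less confident").

### Diagnostics

`fit_em()` records the full parameter trace per iteration (the trace plot
verifies fast convergence), and `density_overlay()` tabulates the fitted
matched-score mixture against a kernel density estimate
$\hat f(t) = (nh)^{-1}\sum_i K((t - s_i)/h)$ of the same scores. The KDE
default bandwidth is Silverman's rule of thumb
$0.9\,\min(\mathrm{sd}, \mathrm{IQR}/1.34)\,n^{-1/5}$ (no specific "optimal"
rule is canonical here; Silverman is the conventional default and the
bandwidth is user-selectable); kernels are Gaussian (default) or
Epanechnikov.

## 2. Spectral preliminaries

* **MSP dialect.** `read_msp()` accepts both common peak-pair syntaxes
  (`mz intensity` whitespace pairs and `mz:intensity;`), requires `Name:`,
  validates `Num Peaks:` when present, and ignores unknown `Key: value`
  headers. When `Area:` is absent the total ion count substitutes, with a
  warning — peak areas are assumed by the merging rule but not guaranteed
  by the format.
* **Peak merging.** Multiple detected peaks of one compound are collapsed
  to the single record with the largest area. Names are compared after
  whitespace trimming and case folding; equal areas keep the first
  occurrence (a documented, deterministic tie-break); surviving names keep
  their input order. Merging keys on the name only — retention-time
  clustering is out of scope.
* **Binning.** Two spectra are placed on a common coordinate by summing
  intensities within m/z bins of width 1 (nominal mass) by default, over
  the union of occupied bins. The bin width is user-configurable; 1 m/z is
  the natural choice for unit-resolution GC-MS data.
* **Cosine score.** Computed as $2\,\mathrm{atan2}(\|x-y\|, \|x+y\|)$ on
  the unit vectors — algebraically the arccos formula, but exactly zero for
  identical inputs and numerically stable at small angles. Argmin ties go
  to the lowest library index. No score threshold gates the matching; the
  identification model downstream absorbs bad matches through $W = 0$.

## 3. Biomarker discovery: fdr2d

For each metabolite the Welch statistic $T = (\bar X_1 - \bar X_2)/S_p$,
$S_p^2 = S_1^2/n_1 + S_2^2/n_2$, gives the coordinates
$z = (z_1, z_2) = (T, \log S_p)$. The two-dimensional local false discovery
rate $\mathrm{fdr2d}(z) = \pi_0 f_0(z)/f(z)$ uses the full bivariate
information: two hypotheses with the same $t$ but different standard errors
are distinct points in this plane, whereas any $t$-only rate must treat
them identically — the motivating example for the two-dimensional rate, and
an asserted test case.

Estimation proceeds by permutation: group labels are rearranged `np` times
and all statistics recomputed, giving $np$ null points per observed point.
The ratio
$$r(z) = \frac{np\, f_0(z)}{f(z) + np\, f_0(z)}$$
is exactly the local proportion of permutation points among all points near
$z$, so it is estimated as a smoothed binomial regression of point origin
on the binned plane, and the rate follows by plug-in:
$\mathrm{fdr2d}(z) = \pi_0\, r(z) / (np\,[1 - r(z)])$. A useful exact
identity anchors the implementation: if the permuted cloud equals the
observed cloud, $r \equiv np/(np+1)$ and the surface equals $\pi_0$
everywhere — asserted to machine precision in the tests with smoothing off.

### Design decisions

* **Smoother.** The ratio target admits many estimators; this package bins
  both clouds on a rectangular grid (default $50 \times 50$ cells spanning
  the pooled range padded by 5%) and fits a fixed-degrees-of-freedom
  thin-plate spline (`mgcv::gam`, logit link, `fx = TRUE`, default
  `smoothing_df = 8`) to the per-cell permuted/observed counts. Fixed df
  keeps the fit deterministic and cheap; `smoothing_df = 0` returns raw
  per-cell proportions, the form used wherever exact counting identities
  are asserted. Estimates are clamped to $[10^{-4}, 1 - 10^{-4}]$; cells
  with no data take the smoother's extrapolation and are flagged in a
  coverage mask.
* **$\pi_0$** is estimated by central matching: the ratio of observed to
  permuted point fractions inside the central 50% band of the permuted
  $z_1$ distribution, capped at 1. Truly differential metabolites vacate
  the centre, so the ratio estimates the null proportion; under a complete
  null it is near 1.
* **Rejection** at level $\alpha$ keeps every metabolite whose
  bilinearly-interpolated fdr2d is at most $\alpha$ — all points outside
  the $\alpha$-isoline. Sets are nested in $\alpha$ by construction. The
  control is of the local fdr, cell-wise, with no step-up layer on top.
  Default display levels are (0.05, 0.1, 0.2, 0.3).
* **p-values** (tornado axis and the results table) use the $t$ reference
  with Welch–Satterthwaite degrees of freedom; the isoline mapping into
  plot coordinates uses the median df. Isolines are extracted with
  marching-squares contours of the gridded surface and mapped via
  $\text{mean difference} = z_1 e^{z_2}$.
* **Degenerate rows** (zero within-group variance) have their standard
  error floored at $10^{-8} \times$ median se, with a warning, so every
  statistic stays finite and a constant row tests at $t = 0$.
* **Permutations** are label rearrangements without replacement,
  seed-reproducible; when `np` exceeds the number of distinct assignments
  the code warns and enumerates exhaustively. Unbalanced groups are
  allowed.

### Normalization

The matrix pipeline applies, in order: $\log(x + \text{pseudocount})$
(natural log by default, base configurable; pseudocount default 1 so zeros
are safe, and a zero with pseudocount 0 is an error naming the cells),
column scaling to relative proportions (each subject column sums to 1), and
optionally row centering. The three steps are independently toggleable
because published recipes vary between "log then column-scale" and
"centering and log"; the first is the default order and every applied step
is recorded in the object's `transform_log`.

## 4. What the simulators emulate — and what they do not

* `simulate_identification()` draws the hierarchy exactly as modelled. Its
  defaults ($\rho = 0.7$, $\tau = 0.8$, $\gamma_1 = 0.9$, $\gamma_0 = 0.1$,
  $\mu_T = 5^\circ$, $\sigma_T^2 = 4$, one false component at
  $N(40, 100)$) are the package's reference conditions: a majority-present
  library, high match rates for present metabolites, correct matches near
  $5^\circ$ and incorrect ones centred at $40^\circ$ — the separation seen
  in well-behaved GC-MS library searches. Because the data are generated
  from the fitted family, recovery experiments demonstrate correctness of
  the estimator, not robustness to misspecification (e.g. skewed score
  distributions or score-dependent match rates).
* `simulate_spectra()` builds paired sample/library tables: shared
  metabolites differ by multiplicative log-normal intensity noise
  (the standard noise model for MS intensities; the default
  `noise_sd = 0.1` perturbs relative intensities by about 10%), peak
  positions are distinct integer m/z values so unrelated spectra are
  near-orthogonal. Chromatographic peak shape, retention-time drift and
  shared fragment ions between different compounds are not emulated, so
  real-library score distributions will be broader than these.
* `simulate_matrix()` draws a $\pi_0$ fraction of null metabolites and
  shifts the rest by `effect_size` within-group SDs in group 2. Baselines
  are log-uniform on $[10^3, 10^6]$ (exercising the log/scale path);
  per-metabolite variances are log-uniform over a 10-fold range by default,
  which spreads $\log(\text{se})$ over about 1.2 units — enough structure
  for the $z_2$ axis to matter. Correlation between metabolites, batch
  effects and missingness are not simulated; the FDR-control results below
  are therefore statements about independent rows.

All simulators require a seed and are bit-reproducible.

## 5. Simulation experiments and their sizes

The test suite and `scripts/acceptance.R` run, at sizes chosen to make the
Monte-Carlo error small relative to the tolerances they assert:

* EM ascent, recovery and calibration: 20 simulated libraries of 2000
  metabolites at the reference conditions, match rates frozen at their
  design values (Section 1). Recovery is summarised by median absolute
  error for $\rho$, $\tau$ (tolerance 0.05) and $\mu_T$ (0.5°); calibration
  by decile-binned posterior-vs-frequency gaps (tolerance 0.1).
* Matching: 200 random 5 × 8 library instances against an exhaustive
  argmin oracle; cosine scores against an independent arccos oracle on
  1000 random pairs at $10^{-10}$.
* FDR control: 20 replicates of the default matrix (1000 metabolites,
  $\pi_0 = 0.8$, 2-SD shifts, $n = 15 + 15$, `np = 50`), asserting mean
  realized false-discovery proportion at nominal 0.05 below 0.10 and power
  increasing from level 0.05 to 0.10.

## 6. Known limitations

* The identification model's ridge (Section 1) means that with all four
  probability parameters free the reported $\rho$ and $\tau$ are one point
  on an equivalence set; confidence measures, which depend on the
  identified combinations, are less affected, but users wanting
  interpretable $\rho, \tau$ should freeze the match rates.
* fdr2d estimation inherits the usual local-fdr caveats: it is a density
  ratio, so sparse tail cells rely on the smoother's extrapolation (the
  coverage mask marks them), and `np` should be large enough that the
  permuted cloud fills the support (50–100 works well at $10^3$
  metabolites).
* Multi-group designs, retention-time alignment across many samples,
  instrument-level peak detection and pathway analysis are out of scope.
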