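---
title: "Transferable ErrP decoding with regularized optimal transport"
author: "ErrPOT authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transferable ErrP decoding with regularized optimal transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ErrPOT)
```

## The problem

When a brain–computer interface (BCI) misclassifies a motor-imagery command
and relays wrong feedback — a bar moving the wrong way, or electrical
stimulation delivered to the wrong limb — the user's EEG carries a
stereotyped *error-related potential* (ErrP): a fronto-central negative
deflection roughly 200–300 ms after the feedback is perceived, followed by
a positive rebound. Detecting single trials that carry an ErrP turns the
BCI's own user into an error monitor.

The catch is that users are never trained on error trials, so no
subject-specific training data exist. ErrPOT implements a *cross-subject*
decoder: a classifier is trained on the pooled trials of other subjects
and applied to a new one. Because EEG feature distributions shift between
subjects (electrode gains and impedances, latencies, volume conduction — a
*covariate shift*), the pooled training set is first *transported* onto the
held-out subject's feature distribution with regularized discrete optimal
transport (OT), and the classifier is trained on the transported points.

Real recordings of this kind are not publicly archived, so the package
ships a synthetic cohort generator that reproduces the statistical
structure the method assumes; everything downstream is exercised and tested
against it.

## The processing chain

Each trial is an epoch time-locked to the onset of the feedback period
(t = 0), with the actual feedback displayed or stimulated at +0.5 s (the
online decoder's relay latency). The feature pipeline is:

1. **Equiripple FIR low-pass**, passband 0–6 Hz, stopband from 8 Hz
   (Parks–McClellan/Remez design). The 6 Hz cutoff removes the 8–12 Hz
   motor-imagery rhythm that would otherwise contaminate the
   feedback-locked response. The default 385-tap design at 256 Hz achieves
   a DC gain of 0.998 and ≈56 dB stopband attenuation; the achieved
   numbers are recorded in the returned `FilterSpec` rather than assumed.
   A 257-tap design reaches only ≈39.8 dB over this 2 Hz transition, which
   is why the longer default was chosen. Filtering is single-pass
   convolution with group-delay compensation, so the equiripple magnitude
   spec applies exactly and event latencies are preserved; epoch edges are
   padded by edge replication.
2. **Surface Laplacian** at the midline centers FCz, Cz, CPz (closest to
   the anterior cingulate ErrP generator): each center minus the mean of
   its neighbors (Cz uses C1, FCz, C2, CPz; FCz uses Fz, FC3, FC4, Cz;
   CPz uses Cz, CP3, CP4, Pz — the nearest recorded 10–20 sites, and
   configurable).
3. **Baseline correction** over [−2.3, −2.0] s, the 300 ms before the
   motor-imagery instruction, a segment free of both imagery- and
   feedback-related activity.
4. **Analysis window** [0, 1.5) s — half-open, because 1.5 s at 256 Hz
   must give exactly 384 samples so that the next step yields the canonical
   24 bins per channel.
5. **Decimation ×16** (keep every 16th sample; the 0–6 Hz filter already
   provides anti-aliasing), then channel-major flattening into a
   trials × 72 matrix (3 channels × 24 bins).

One ordering subtlety: the baseline window lies *before* the analysis
window, so baseline means are taken on the full filtered epoch before the
[0, 1.5) s extraction. Filtering the full epoch first also keeps filter
edge transients away from the analysis window.

Trials are relabeled *correct*/*incorrect* by whether the feedback matched
the imagined limb, with left- and right-foot imagery merged into a single
foot class (so foot-imagery trials are correct when either foot receives
feedback; an unmerged rule is available via `footMerge = FALSE`).

## Regularized discrete optimal transport

Pooled source trials and target trials are represented as empirical
measures (uniform mass on each feature vector). With the squared-Euclidean
cost $J_{ij} = \lVert f_i^s - f_j^t \rVert^2$, the coupling $\tau$ solves

$$ \min_{\tau \in X} \; \langle \tau, J\rangle
   \;+\; \lambda \textstyle\sum_{ij} \tau_{ij} \log \tau_{ij}
   \;+\; \eta \, \Omega_{\mathrm{cls}}(\tau), $$

over the polytope $X$ of nonnegative matrices with the two empirical
distributions as row and column sums. The entropic term is solved by
Sinkhorn–Knopp scaling; the class term $\Omega_{\mathrm{cls}}$ penalizes
target points drawing mass from more than one source class. Each source
point is then relocated by **barycentric mapping**,
$\hat F_s = \mathrm{diag}(\tau \mathbf 1)^{-1}\,\tau\,F_t$, i.e. to the
coupling-weighted average of target points, and the classifier is trained
on $(\hat F_s, y_s)$. (The transposed form of this expression sometimes
seen in print is dimensionally inconsistent; the source-to-target
barycenter above is the only consistent reading and is what the package
implements.)

Numerical and design choices that were genuinely open:

* **Class regularizer.** The group penalty is implemented as the concave
  group-sparse form $\sum_j \sum_c \sqrt{m_{cj}}$, where $m_{cj}$ is the
  mass column $j$ receives from class $c$, solved by
  majorization–minimization: each outer step majorizes the penalty by its
  tangent, giving an adjusted-cost Sinkhorn problem with weights
  $\tfrac{\eta}{2} m_{cj}^{-1/2}$. Classes currently contributing little
  mass to a column become expensive for that column, so column mass
  collapses onto a single class — the intended "mass only to samples of
  the same class" behaviour. A per-column ℓ2 group norm is sometimes
  written for this penalty, but its gradient vanishes off-support and
  concentrates weakly under linearization; the concave form is the one
  whose MM solver actually enforces class purity (≥99% column purity at
  the default η = 10 on separable instances). η = 0 reduces exactly to
  plain entropic transport.
* **Cost scale and λ.** The cost matrix is divided by its positive median
  (`costNormalize`, on by default) so λ and η are unitless. The default
  λ = 0.05 balances two failure modes observed in method development:
  large λ (≈1) over-blurs the barycentric map (transported classes smear
  together even with no shift), while very small λ (≈0.01) makes the
  *unsupervised* coupling brittle — with nothing constraining class
  alignment, a near-deterministic map can lock onto a wrong matching.
  η = 10 throughout.
* **Solver numerics.** When λ is small relative to the cost scale the
  scaling runs in the log domain with ε-scaling warm starts (annealing the
  temperature down to λ); the MM outer loop warm-starts each inner solve
  from the previous dual potentials. The final iterate is rounded onto the
  marginal polytope (scale-down plus rank-one repair), so every returned
  plan satisfies its marginals to machine precision — well inside the
  10⁻⁹ tolerance contract — and is exactly nonnegative. An exact
  linear-programming oracle (`exactTransport`, simplex on instances up to
  400 variables) is kept alongside as an independent check: at
  λ = 10⁻³·median(J), the entropic cost agrees with the LP optimum to well
  under 1%.
* **Label modes.** `semisupervised_target` (default) additionally adds a
  large finite penalty (10 × max cost) to couplings between source and
  target points of *different* classes; this mirrors the offline analysis
  setting in which held-out labels steer the mass movement but never reach
  the classifier. The penalty is finite so the problem stays feasible when
  class proportions differ between the marginals. `unsupervised_target`
  uses no target labels anywhere and is the deployable mode; both modes
  are exercised by the evaluation harness.

## Evaluation

`losoEvaluate` runs leave-one-subject-out folds: the held-out subject is
the target, the remaining subjects pooled are the source; with OT the
classifier (random forest, 100 trees, Gini, bootstrap) is trained on the
transported source, without OT on the raw pooled source. Precision, recall
and F1 are reported in percent with *incorrect* as the positive class
(support-weighted two-class averages are carried alongside, since
published per-subject triples with near-equal precision/recall/F1 are also
consistent with averaged reporting). Arms are compared with a two-tailed
Wilcoxon signed-rank test, exact (dynamic programming over the doubled
midranks, zero differences dropped) for up to 25 pairs.

Comparison classifiers (LDA, logistic regression, linear SVM, bagged LDA,
AdaBoost with depth-1 stumps) are delegated to standard implementations
(`MASS`, `stats::glm`, `e1071`, `rpart`); they are deliberately not this
package's contribution. Two caveats: no Ledoit–Wolf-shrinkage LDA solver
is available in the dependency set, so plain LDA stands in; and the
logistic baseline is the unregularized maximum-likelihood fit (an L2
weight of C = 1000 is near-unregularized anyway).

ERP-level statistics (`erpStats`) compute condition-wise grand averages,
the incorrect-minus-correct difference wave, and a per-timepoint
Kruskal–Wallis p-series over trials pooled across subjects (a per-subject
averaging alternative would trade power for independence; pooling matches
the grand-average display the p-series annotates). Raw p-values are
reported per timepoint without multiplicity correction, matching the
descriptive use of the trace; a Benjamini–Hochberg adjustment can be
applied downstream if inferential use is intended.

## The synthetic cohort

`generateCohort` emulates the statistical structure the analysis assumes:

* a biphasic ErrP template (Gaussian lobes, defaults −6 µV at 0.25 s and
  +4 µV at 0.40 s after feedback display, 40 ms lobe SD) injected **only
  into incorrect trials**, time-locked to display at +0.5 s, with a scalp
  topography peaking at Cz/FCz/CPz and decaying laterally — the spatial
  gradient matters, because a topographically flat deflection would be
  cancelled by the surface Laplacian;
* 1/f (pink) Gaussian background noise (default SD 2.5 µV) plus a coherent
  8–12 Hz sinusoid of random frequency and phase per trial (default
  2 µV) standing in for the motor-imagery rhythm;
* Bernoulli trial correctness at the online error rate (default 25.68%
  incorrect, the complement of the emulated 74.32% online accuracy;
  use ≈34% for a visual-feedback-like cohort), with task and feedback
  labels drawn consistently with the merged-foot correctness rule;
* per-subject covariate shifts: multiplicative gain (log-uniform 0.5–2.5
  by default, the span of plausible inter-subject amplitude variability),
  DC offset (±5 µV; removed by baseline correction, included for realism),
  ERP latency jitter (±30 ms), and uniform cross-channel leakage
  (`M(m) = (1-m)I + (m/C)\mathbf{1}\mathbf{1}'`, m ≤ 0.3).

Seeding is hierarchical: one master seed, with per-subject streams derived
from (seed, subject id) by a string hash, so cohorts are bit-reproducible
and any subject can be regenerated in isolation.

What the generator does **not** emulate: ocular/muscle artifacts, session
drift, electrode pop, the online CSP+LDA pipeline (correctness is a plain
Bernoulli process), inter-trial ErrP amplitude variability, or the
pre-feedback motor-imagery differences reported in real data (a lingering
imagery effect; off by default, the null baseline region is clean here).
Passing tests on this cohort therefore demonstrate the *machinery* —
geometry, solver correctness, the direction and significance of the OT
benefit under covariate shift — not clinical-grade performance on real
EEG.

## Problem sizes and runtime choices

The study-scale evaluations use the 8-subject × 96-trial cohort (the
emulated cohort size); unit-level checks use 2–4 subjects with 16–48
trials, and the transport oracles use instances up to 5 × 5 (LP) and a few
hundred points (Sinkhorn). The type-I calibration of the per-timepoint
Kruskal–Wallis test uses 1000 independent replicates at the cohort's group
sizes. These sizes keep a full test sweep in a few minutes on one core
while leaving every claim computed, not asserted.

## Worked example

```{r example, eval = FALSE}
cc <- cohortConfig(nSubjects = 8, nTrials = 96, errorRate = 0.2568, seed = 1)
cohort <- generateCohort(cc, makeCohortShifts(8, seed = 102))
spec <- designLowpassFir()
features <- lapply(cohort, buildFeatures, spec = spec)

without <- losoEvaluate(features, useOT = FALSE)
withOt  <- losoEvaluate(features, useOT = TRUE,
                        otCfg = otConfig(labelMode = "semisupervised_target"))
meanF1(without); meanF1(withOt)
wilcoxonSignedRank(withOt@perSubject$f1, without@perSubject$f1)

st <- erpStats(lapply(cohort, function(ep)
  baselineCorrect(surfaceLaplacian(applyLowpass(ep, spec)))), "Cz")
plotErpStats(st)
```

## Known limitations

* The barycentric map is in-sample: new target trials require re-solving
  the transport problem (no out-of-sample extension is provided).
* Unsupervised transport is markedly weaker than the semisupervised mode
  on strongly shifted cohorts — expected, since nothing anchors class
  alignment — and is the main open problem for online deployment.
* The exact LP oracle is limited to ~400 coupling variables by design; it
  is a test oracle, not a production solver.
* Unbalanced OT, Gromov–Wasserstein couplings and minibatch variants are
  out of scope.
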