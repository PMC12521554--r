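---
title: "Modelling evidence accumulation in probabilistic reversal learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling evidence accumulation in probabilistic reversal learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`rlddm` implements a hybrid reinforcement-learning drift-diffusion model
(RLDDM) of two-alternative choice under a response deadline. Two processes
are coupled:

**Across trials**, the expected value \(Q\) of the chosen stimulus is
updated by the Rescorla–Wagner rule
\[
Q_{t+1} = Q_t + \alpha\,(R_t - Q_t),
\]
where \(R_t \in \{-1, +1\}\) is the unit-scaled feedback and \(\alpha\) the
learning rate. The unchosen stimulus keeps its value. Feedback stored in
behaviour files keeps its raw \(\pm 10\)-point scale; the update consumes
\(R = \text{feedback}/|\text{feedback}|\) so \(Q\) stays in \([-1, 1]\)
from a zero start and \(\kappa\) (below) absorbs the scale.

**Within a trial**, noisy evidence accumulates from an unbiased start
\(a/2\) between absorbing bounds at \(0\) and \(a\):
\[
EA^{i+1} = EA^i + \kappa\,\mathrm{DDR}_t\,dt + dW^i,
\qquad dW^i \sim \mathcal{N}(0, dt),
\]
with the *dynamic drift rate* \(\mathrm{DDR}_t = Q^1_t - Q^2_t\) scaled by
\(\kappa\). Response time is decision time plus a non-decision time,
\(RT_t = DT_t + nDT\). The diffusion coefficient is fixed at 1 — the
standard identifiability convention, so \(\kappa\), \(a\) and \(nDT\) are
expressed relative to unit accumulation noise.

The four free parameters, with units and the generator's defaults:

| parameter | meaning | unit | generator default |
|---|---|---|---|
| \(\kappa\) | drift scaling (evidence SNR) | evidence·s\(^{-1}\) per unit \(\Delta Q\) | log-normal, median 3 |
| \(a\) | boundary separation (caution) | evidence units | log-normal, median 1.3 |
| \(\alpha\) | learning rate | — | logit-normal, median 0.30 |
| \(nDT\) | non-decision time | s | scaled-logit, median 0.30 |

These medians were chosen once so that simulated RTs sit inside the 1 s
deadline with a modest late-trial fraction (roughly 5–10%), which is what a
deadline task that participants practised beforehand produces.

## The task generator

The probabilistic reversal learning task has 180 trials; the
high-probability stimulus pays \(+10\) with probability 0.70 and the other
with probability 0.30, both otherwise \(-10\). After five consecutive
choices of the high-probability stimulus, a buffer count drawn uniformly
from \(\{1,\dots,4\}\) is appended and the contingency then reverses, so
the criterion cannot be inferred from a fixed run length. The exact
schedule probabilities and criterion of the original task are not printed
anywhere accessible; these defaults are conventional PRL values and are
configurable in `task_config()`. Responses slower than the 1 s deadline are
*late*: no choice or feedback is recorded, no learning occurs, and the
reversal streak resets — the task withheld outcomes pending a response.

Trials are laid on a session clock (fixation jitter 1–4 s, stimulus
1.25 s, ISI jitter 1–4 s, outcome 0.65 s) so first-level designs can be
built from the same table.

What the generator deliberately does **not** emulate: within-subject
session effects (pre/post treatment change in behaviour), trial-history
effects beyond Rescorla–Wagner learning, lapses/guessing mixtures, and
any behavioural group difference — the two synthetic groups share one
parameter distribution by default, so every downstream "behavioural null"
is true by construction, not an empirical finding about real patients.

## Fitting

Each subject is fitted by maximum a posteriori estimation. The likelihood
of a non-late trial is the Navarro–Fuss approximation of the Wiener
first-passage-time density evaluated at \(DT = RT - nDT\). Drift is coded
relative to the chosen stimulus, \(v_t = \kappa (Q_\text{chosen} -
Q_\text{unchosen})\), and the observed response is scored at the boundary
the drift favours when the model predicts the choice; this is algebraically
the "lower boundary = model-predicted choice" convention with a sign flip
for non-predicted choices. Late trials contribute neither likelihood nor
learning, mirroring the simulator; whether the original fits let late
trials update values is not stated anywhere, so the package picks the
reading consistent with its own forward model.

Parameters are optimized in an unconstrained space: \(\log a\),
\(\mathrm{logit}\,\alpha\), a scaled logit for \(nDT\) with the subject's
minimum RT as upper bound, and \(\log \kappa\) (the positivity transform
for \(\kappa\) is implied by its role; only the other three transforms are
conventional enough to be stated outright). Priors are independent
Gaussians in that space with variance 10. The stated native-space prior
means \((\kappa, a, \alpha, nDT) = (1, 1, 0, 0.1)\) cannot all be mapped
through the transforms literally — \(\mathrm{logit}(0)\) is undefined — so
the package centres \(\kappa\) and \(a\) at native 1 (0 in log space),
\(\alpha\) at 0 *in logit space* (native 0.5), and \(nDT\) at native 0.1 s
through its scaled logit. With variance 10 these priors are weak and the
choice is immaterial in practice.

Optimization is multi-start BFGS with numerical gradients: one start at the
prior mean plus nine perturbed starts (±1 SD), 10 starts total by default.
The spread of converged objective values is reported as a multimodality
diagnostic. Points where the transform saturates floating point are given
a large finite penalty so a line search cannot kill a restart.

### Numerical choices

- WFPT series truncation error `eps = 1e-7` per density evaluation; the
  small-time or large-time expansion is chosen per point by whichever needs
  fewer terms. Densities are floored at `1e-300` before logging.
- `t <= 0` returns density 0 by contract rather than raising, keeping the
  objective finite at the `ndt` upper bound.
- Euler step `dt = 1e-3` s for agent simulation and regressor estimation;
  `1e-4` (or finer) for density-oracle comparisons. The first step at or
  beyond a bound absorbs, with the overshoot clipped to the bound — a
  simple scheme whose small positive bias in absorption times shrinks
  with `dt`.
- Degenerate zero drift uses the analytic limits (\(a^2/4\) mean decision
  time, absorption probability 0.5), not a perturbation.

## Integrated evidence and the first-level model

The trial-wise fMRI modulator is the mean area under the accumulation path
from onset to absorption, estimated by Monte-Carlo simulation at the
trial's fitted drift (the reference analysis uses 5000 paths per trial;
the bundled tests and acceptance runs use 300, which estimates a mean area
of ~0.3 evidence·s with a standard error well under 2%). The area is taken
from the zero axis by the rectangle rule, matching the usual depiction of
"shaded area under the ramp"; paths are unconditional on the observed
choice — whether the original regressor conditioned on choices is
unstated, and `integrated_evidence()` exposes the drift sign for callers
who want choice-conditioning.

The design has decision-phase sticks (EA-modulated, unmodulated visual,
RT-modulated motor, \(|Q^1 - Q^2|\)-modulated valuation) and outcome-phase
sticks (unmodulated visual, unmodulated late-response, signed-RPE), all
convolved with a canonical double-gamma HRF (peak 6 s, undershoot 16 s,
ratio 1/6, 32 s support — the conventional values; only "double gamma" is
specified upstream) and resampled at TR = 2 s. Parametric modulators are
demeaned before convolution so the modulated columns are decorrelated from
their unmodulated companions; whether the original setup demeaned or
orthogonalized is unstated, and demeaning is the choice that keeps the
design full-rank without reordering variance between columns.

Synthetic BOLD is `design × betas + AR(1) noise`. The synthetic voxel's
conditions were designed once: true EA betas of 1 (responders) and 3
(nonresponders) with SD 1, innovation SD 0.25, AR coefficient 0.3. At the
EA modulator's natural scale this puts the single-subject EA-beta standard
error near 0.9, so the 19-vs-18 group contrast has roughly the 80% design
power the study planned for — the point of the synthetic cohort is that
the *neural* coefficient carries the group difference while behaviour does
not.

## Statistics

- **10% percentage-bend correlation** (Wilcox): deviations are winsorized
  at the \((1-\beta)\)-quantile of absolute deviations from the median with
  \(\beta = 0.1\); the p-value uses the \(t\) approximation with \(n-2\)
  degrees of freedom, Wilcox's standard accompaniment to the estimator.
- **ANCOVA contrasts** `estimate = 1 + group + preBDI` via OLS.
- **Classification**: feature standardization fitted on training folds
  only, linear SVM at cost 1, pooled held-out decision values, trapezoidal
  AUC (ties count one half per pair), and a permutation p as the plain
  proportion of 100 label shuffles that reach the observed AUC, with the
  *whole cross-validation re-run per shuffle*. The re-run matters: the
  pooled cross-validated AUC has a negative small-sample bias under the
  null (held-out class means deviate against their training folds), so
  merely re-scoring the pooled decision values against shuffled labels
  compares a biased observation with unbiased permutations and is badly
  conservative — the package's own null-calibration test shows p-values
  piling up near 1 under that scheme. Re-running the CV gives observed and
  permuted statistics the same bias and restores a uniform null. An
  add-one (never-zero) variant is available behind a switch; the plain
  proportion is the default because that is the stated procedure.
- **Power**: exact noncentral-\(t\). The study's power statement
  ("80% at alpha = 0.5" for \(d = 0.42\), \(n = 37\)) is read as a typo
  for \(\alpha = 0.05\), one-sided — the only reading under which the
  arithmetic reproduces 80% (`power_one_sample_t(0.42, 37, 0.05, "one")`
  = 0.805).

## Problem sizes

The bundled tests and the acceptance script run: parameter recovery at 30
subjects × 180 trials; the generative check at 300 whole-task simulations
per subject; density oracles at \(10^5\) paths with `dt = 1e-4`; and the
end-to-end pipeline on the reference-size 19 + 18 cohort with 300 paths
per trial for the EA regressor. These sizes were picked so each study's
Monte-Carlo error is small relative to the effect being checked.

## Limitations

- MAP point estimates only; no hierarchical pooling or posterior
  uncertainty (deliberately out of scope).
- No across-trial variability in drift, start point or non-decision time
  (the full Ratcliff extensions), no collapsing bounds, no updating of the
  unchosen stimulus.
- The synthetic first-level model is a single voxel with AR(1) noise; no
  drift/motion confounds, spatial structure, or whole-brain inference.
- Generative-check correlations across synthetic subjects are limited by
  the modest between-subject heterogeneity the generator injects; real
  cohorts are more heterogeneous and typically show stronger
  across-subject correlations.
- \(\kappa\) is the least identified parameter at 180 trials: it scales
  the drift jointly with the learned \(Q\) difference, so its recovery
  correlation is consistently the lowest of the four (typically ~0.7 at 30
  subjects, against 0.75–0.98 for the others). More trials or stronger
  value contrasts would sharpen it.
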