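---
title: "Urgency gating and evidence accumulation in the tokens task: models, fitting and synthetic studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Urgency gating and evidence accumulation in the tokens task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tokensim)
```

## The task and the scientific question

In the tokens task, fifteen tokens sit in a central circle and jump, one
every 200 ms, toward a left or a right target. The observer must predict
which target will hold the token majority when all fifteen have jumped, and
may commit at any moment before the last jump. Because the evidence changes
within a trial, the task discriminates between two families of decision
models that are indistinguishable under constant evidence:

* the **evidence accumulation model (EAM)** — noisy integration of the
  momentary evidence between two fixed bounds, and
* the **urgency gating model (UGM)** — low-pass filtering of the momentary
  evidence, multiplied by an urgency signal that grows linearly with
  elapsed time.

Two visibility conditions matter. In *all-stay* trials jumped tokens remain
on screen, so the running count is always available. In *all-away* trials
each token disappears 200 ms after jumping, so the count must be held in
working memory — which is modeled as leaky. The decisive trial types are
*bias-for* (first three jumps toward the correct target, next three away)
and *bias-against* (the mirror image): with visible evidence the EAM
predicts slower responses on bias-against trials while the UGM predicts no
difference, and with leaky mnemonic evidence only the UGM predicts the
observed *faster* bias-against responses.

## Success probability

Given `n1` tokens in target one, `n2` in target two and `nr` in the center,
each remaining token jumps to either side with probability 1/2 and the
probability that target one ends with the majority is

$$P(C \mid N_1,N_2,N_r) \;=\; \frac{N_r!}{2^{N_r}}
  \sum_{k=0}^{\min(N_r,\,7-N_2)} \frac{1}{k!\,(N_r-k)!},$$

where 7 generalizes to $\lfloor n/2 \rfloor$ for other odd token counts.
`success_probability()` implements this sum exactly; the test suite checks
it against exhaustive enumeration of all $2^{N_r}$ completions for every
reachable state, and checks the complementarity
$P_1(N_1,N_2,N_r) + P_2(N_2,N_1,N_r) = 1$ (no ties are possible with an odd
token count).

## Trial generation

The five trial types are generated in a direction frame where `+1` means
"toward the reference target":

* **bias-for / bias-against** — the first six jumps are fixed
  (`+++---` or `---+++`); exactly 7 of the 9 remaining jumps go to the
  correct target in random order, guaranteeing a 10–5 win with a fixed,
  testable composition.
* **easy** — every jump favors the correct target with probability 0.85;
  sequences are rejection-sampled until the success probability stays at or
  above 0.60 from the third jump on.
* **ambiguous** — jumps 1–10 strictly alternate (random starting side) and
  jumps 11–15 favor the correct target with probability 0.85, accepted when
  the correct target wins. Strict alternation keeps the success probability
  inside $[22/64, 42/64] = [0.344, 0.656]$ through jump 10, so the
  acceptance envelope is set to $[0.34, 0.66]$ — the exact attainable band.
  (A nominally tighter band such as $[0.35, 0.65]$ would reject *every*
  strictly alternating sequence, because the profile reaches $42/64$ at
  jump 9 deterministically.)
* **random** — every jump is an independent fair coin; the winning target
  is whichever side ends with the majority. Random trials make the
  structured types unpredictable and are excluded from model fitting.

Blocks mix the types 50/15/15/10/10 (random/easy/ambiguous/bias-for/
bias-against), apportioned by largest remainder and shuffled.

## Evidence and the decision models

The momentary evidence $e$ is the running count difference, updated only at
jump onsets and frozen in between. Working memory applies a fractional leak
at each jump onset:

$$e_{\mathrm{leak}}[j] = (1 - L_e)\, e_{\mathrm{leak}}[j-1] + d_j,
  \qquad d_j \in \{+1, -1\},$$

with $L_e = 0$ recovering the raw count. The all-away condition without
leak is exactly the all-stay machinery run on all-away trials; there is no
separate code path.

Both models draw a trial-specific drift rate $v \sim N(\nu, \eta)$ and step
in $\Delta t = 10$ ms:

* **EAM** — $x_0 = \theta/2$ and
  $x \leftarrow x + v\,e\,\Delta t' + s\,\xi\,\sqrt{\Delta t'}$ with
  $\Delta t' = 0.01$ (the step expressed in seconds) and $s = 0.1$; the
  decision is target one when $x > \theta$, target two when $x < 0$.
* **UGM** — $x \leftarrow \frac{\tau}{\tau+\Delta t} x +
  \frac{\Delta t}{\tau+\Delta t}\,(v\,e + s\,\xi)$ with $\tau = 100$ ms,
  and the decision variable is $x \cdot u$ with urgency $u = t$ in ms,
  compared against $\pm\theta$.

In both cases the decision time is $t - \Delta t/2$ for a crossing at step
time $t$.

**Unit conventions.** Any time-unit choice inside the drift term is
absorbed by the free parameters during fitting, so the convention is fixed
by the magnitudes of published group-mean estimates: EAM boundaries near
0.29 require the drift step in seconds, while urgency thresholds near
$2.3 \times 10^4$ require the filter state to track $\nu e$ (order 10) and
the urgency signal to be elapsed milliseconds — their product at one to two
seconds is then of order $10^4$. Had the UGM drift term carried the extra
factor $\Delta t' = 0.01$, the decision variable could never reach such a
threshold before the 3000 ms deadline and every trial would be censored.

**Censoring.** A trial with no crossing before the last jump is flagged
censored: the choice is forced from the sign of the decision variable
(ties broken at random) and the decision time set to the deadline, which
places it in the final open-ended QMPE bin. Subjects had to respond before
the last jump, so censored model trials have no behavioral counterpart;
they are kept, flagged, rather than silently discarded.

**Scale invariance of the UGM.** The UGM decision rule is exactly invariant
under $(\nu, \eta, \theta, s) \to c\,(\nu, \eta, \theta, s)$, and with
$s$ fixed at 0.1 the noise contributes only ~0.1% of the drive at the
published parameter scale. The practical consequence — verified bit-exactly
for $c = 2$ in the test suite — is that $\nu$ and $\theta$ are not
separately identifiable from decision-time data: only ratios such as
$\theta/\nu$ and $\eta/\nu$, and the leak, are. This is why the
parameter-recovery suite recovers $\theta/\nu$ to a few percent and the
leak to ~0.01 absolute while the individual $\nu$ and $\theta$ drift along
the scale ridge to wherever the search box allows.

## Fitting: QMPE with differential evolution

Observed decision times are split into correct and error responses; each
outcome's deciles at probabilities (0.1, 0.3, 0.5, 0.7, 0.9) define six
bins with open outer edges. Outcomes with fewer than five observed error
trials collapse to a single error bin. The fit statistic is
$\sum_{\mathrm{bins}} n_{\mathrm{obs}} \log p_{\mathrm{pred}}$ with
predicted bin probabilities floored at $10^{-10}$; it is maximized exactly
when predicted proportions equal observed proportions (checked against a
grid-search oracle).

The search is a hand-rolled differential evolution ($F = 0.8$,
$CR = 0.9$; no DE optimizer ships with the environment) using the classic
rand/1/bin strategy — with scaled-down populations the greedier best/1/bin
variant converges prematurely onto a drift-variability-dominated local
mode that scores about 70 log-product points worse than the generative
basin — and operating in log10 coordinates for the scale parameters
$\nu$, $\theta$ and $\eta$, whose plausible values span decades inside the
wide boxes (a linear-uniform population almost never seeds the joint
basin; with log coordinates and rand/1/bin, scaled-down recovery runs
found the basin in 8 of 8 probe seeds instead of 2 of 6). It defaults to
100 particles, 500 iterations and 5 restarts over wide boxes
($\nu \in (0, 20]$, $\eta \in [0, 50]$, $\theta \in (0, 5]$ for the EAM and
$(0, 10^5]$ for the UGM, $L_e \in [0, 1]$). Candidate evaluation simulates
2,000 trials (the fitted trial set cycled), under common random numbers
within a restart so the objective is a deterministic function of the
parameters; final predictions use 10,000 replicates. Fitting pools correct
and error trials of the four structured types; random trials are excluded.

## Behavioral statistics

Decision times are raw reaction times minus the subject's baseline reaction
time (mean over single-token calibration trials); non-positive results are
flagged invalid and excluded. The success probability at decision time uses
the token state at the last jump with onset at or before the decision time
— states are piecewise constant, so no interpolation exists. Summaries use
correct trials only (the convention in this literature), with a flag for
the pooled sets used in fitting. Group contrasts are two-sided paired t
tests with JZS Bayes factors (Cauchy prior scale 3 for decision times,
where large effects are expected, and 0.707 for success probabilities);
the Bayes factor integrates the noncentral-t likelihood over the Cauchy
prior by adaptive quadrature and is checked against dense-grid integration
to four significant digits. No multiple-testing correction is applied, as
none is used in the source literature for these contrasts.

## The synthetic-study generator

`generate_study()` emulates the full design: 15 subjects by default, 12
blocks (6 per visibility condition), each block running until 70 correct
answers, the standard trial-type mix, a known generative model per
condition (UGM by default: leak 0 in all-stay, positive leak in all-away)
and a per-subject baseline reaction time (mean 0.347 s) added onto
simulated decision times — so the analysis stage must genuinely perform the
baseline subtraction. Ground-truth parameters are stored alongside for
parameter-recovery validation.

Per-subject parameters are jittered around the configured means with a
mean-preserving log-normal. The default spread is matched to the published
across-subject dispersion of the fitted parameters (group SEM times
$\sqrt{15}$, converted to a log-normal `sdlog` via the coefficient of
variation) rather than a nominal small jitter: the reported SEMs imply
coefficients of variation between about 0.2 and 1.7 depending on the
parameter, i.e. strongly heterogeneous subjects, and reproducing that
dispersion is precisely what the generator is for. The baseline reaction
time is jittered with the dispersion implied by its reported SEM
(0.009 s $\times \sqrt{15}$).

### What a green end-to-end test does and does not establish

The generator reproduces the *structure* of the study (trial mix, block
quotas, baseline embedding, per-subject heterogeneity), and the simulated
group mean decision times and accuracies are in the behavioral range. It
does not guarantee that every published group-level contrast re-emerges
when the generative parameters are the published *group means*: a group
mean of individually fitted parameters is not a typical subject. Most
notably, with the group-mean drift variability ($\eta \approx 13$ against
$\nu \approx 5$) roughly a third of simulated trials carry a negative
drift rate; conditioning on correct trials then *removes fast responses
asymmetrically* between bias-for and bias-against trials and reverses the
sign of the correct-only bias contrast, even though the pooled
(correct-and-error) contrast shows the published dissociation cleanly.
The model-signature acceptance suite therefore tests the pooled contrast,
and the end-to-end behavioral acceptance check is expected to stay red on
the correct-only bias sub-pattern at group-mean parameters — an honest
property of the stated generative world, documented rather than tuned
away. Reproducing the correct-only pattern requires per-subject drift
variability near the lower end of the published between-subject spread.

## Numerical choices

* All times are carried in ms; random number generation for trial
  simulation uses a self-contained splitmix64 stream with Marsaglia polar
  normals, one stream per (trial, replicate), so batch results are
  bit-reproducible across platforms and common random numbers are exact in
  the fitting loop.
* Quantiles use R's default type 7; bin membership uses `findInterval`,
  identical for observed and predicted samples, so tie-handling cancels.
* Predicted bin probabilities are floored at $10^{-10}$; degenerate
  concentrations (all mass in one bin) give the statistic's maximum, zero.
* The deadline is the last jump onset (3000 ms); decisions are allowed
  strictly before it.
* Block trial counts are apportioned by largest remainder with
  deterministic tie-breaking (larger proportion first), so a one-trial
  block contains the highest-proportion type.
* Rejection sampling for easy/ambiguous trials accepts within a few draws
  on average; the ambiguous envelope is the exact attainable band under
  strict alternation (see above).

## Known limitations

* No motor or non-decision time is added to simulated decision times;
  synthetic raw reaction times embed the baseline exactly, without
  trial-level motor jitter.
* The UGM's $\nu$ and $\theta$ are reported as fitted but are only jointly
  identified (see the scale-invariance discussion); comparisons across
  fits should use $\theta/\nu$, $\eta/\nu$ and $L_e$.
* Learning, fatigue and block-order effects are not modeled.
* Collapsing-boundary accumulators are out of scope; the urgency model is
  the time-pressure mechanism implemented here.
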