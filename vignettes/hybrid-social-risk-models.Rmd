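---
title: "Utility-based and heuristic routes to socially situated risky choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Utility-based and heuristic routes to socially situated risky choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskconform)
```

## The scientific problem

When people choose between risky options after seeing what others chose,
two qualitatively different processes can produce the same outward
behavior.  A decision-maker may *value* the option others picked more
highly — social information enters the utility computation — or they may
simply *copy* (or contradict) the others, bypassing valuation of the
gambles altogether.  Distinguishing these routes matters most when
utility-based risk processing is disrupted, for example in people with
focal lesions to regions implicated in risk valuation: if valuation is
unavailable, copying others may serve as a heuristic fallback.

`riskconform` implements the full modelling pipeline for this question:
the gambling task, a nested family of four choice models, hierarchical
Bayesian estimation, integrated-BIC model comparison, parameter- and
model-recovery protocols, model-agnostic conformity metrics, and the
pooled-bootstrap statistical battery.  Because no participant data are
deposited with the original study, the package ships a synthetic-cohort
generator that emulates the study's design and group structure; every
analysis runs end-to-end on simulated data with known ground truth.

## The task

Each trial presents one *safer* and one *riskier* gamble.  Both gambles
share the probability of winning their high payoff; the riskier gamble's
payoffs are more spread out, so its payoff variance is strictly larger at
every probability level.  Menus are multiplicative rescalings of the
classic Holt–Laury payoff quadruple (safer 2.00 / 1.60, riskier
3.85 / 0.10); the original study used eight unpublished menus with this
structure, so the exact payoff values are a package default that can be
overridden — none of the model code depends on them.

A session crosses 4 menus (drawn per subject from the set of 8) with 6
win probabilities (0.40–0.90) and 4 trial types — Solo (no social
information) and three Info compositions in which the two displayed
others chose both-safe, both-risky, or one each — giving 96 trials, 24
per type, in a per-subject random order:

```{r}
s <- build_session(make_menu_set(), "sub01", seed = 1)
nrow(s)
table(s$trial_type)
```

Unanimous social information is coded by an indicator `delta`: +1 when
both others chose the safer gamble, −1 when both chose the riskier, 0
otherwise.  The identities of the displayed others are not represented —
every model consumes only `delta`, so identity tracking would be dead
state.

## The model family

Four nested models map a trial to the probability of choosing the safer
gamble.

**Solo risk preference.**  Power utility with a softmax choice rule:
$U = P_{high} V_{high}^{\alpha} + (1-P_{high}) V_{low}^{\alpha}$, and
$P_{safe} = [1 + e^{-\beta (U_{safe} - U_{risky})}]^{-1}$.
The exponent $\alpha$ indexes risk preference (below 1 risk-averse, 1
neutral, above 1 seeking; some papers write the same exponent as
$\rho$); $\beta$ is the inverse temperature.

**OCU.**  Other-conferred utility adds a signed bonus to the option the
others unanimously chose:
$P_{OCU} = [1 + e^{-\beta (U_{safe} - U_{risky} + \delta\,OCU)}]^{-1}$.
With $OCU = 0$ this is exactly the solo model.

**OCU-free heuristic.**  On unanimous Info trials the subject follows
with probability $\omega_{follow}$ and opposes with probability
$\omega_{oppose} = 1 - \omega_{follow}$, ignoring the gambles; Solo and
mixed trials use the solo rule.

**Hybrid.**  A simplex mixture
$\omega_{follow} + \omega_{oppose} + \omega_{utility} = 1$ of the three
routes:

$$P_{safe} = \begin{cases}
\omega_{follow} + \omega_{utility} P_{OCU} & \text{Info: safe} \\
\omega_{oppose} + \omega_{utility} P_{OCU} & \text{Info: risky} \\
P_{OCU} & \text{Solo, Info: mix}
\end{cases}$$

The heuristic weights therefore *bound* the attainable safe-choice
probability on unanimous Info trials — within
$[\omega_{follow},\, 1-\omega_{oppose}]$ when others chose safe — which
is the property that makes the heuristic and utility routes separable in
principle.  Setting $\omega_{utility} = 1$ recovers the OCU model, and
$OCU = 0$ in turn recovers the solo model; the test suite asserts these
nestings to $10^{-12}$.

Free-parameter rosters follow the hierarchical convention of two
hyperparameters (mean, variance) per hierarchical parameter plus the
individually estimated weights minus one: 4 (solo), 6 (OCU), 5
(OCU-free), 8 (hybrid).

## Estimation

All models are estimated hierarchically: per-subject log $\beta$, log
$\alpha$ and OCU are drawn from common group-level normal distributions
with weak priors ($\mu \sim \mathrm{Normal}(0, 10)$,
$\sigma \sim \mathrm{half\text{-}Cauchy}(0, 2.5)$); $\beta$ and $\alpha$
are exponentiated, so their population distributions are log-normal.
The mixture weights are deliberately *not* hierarchical: each subject's
simplex gets a flat (uniform-on-simplex) prior, so weight estimates are
not shrunk toward a group mode and classical tests across subjects
remain valid.  When subjects carry group labels, an additive
group-difference offset on the log-$\beta$ group mean is estimated per
non-reference group with a Normal(0, 10) prior (the prior for such
offsets is a package choice, matching the mean priors; the offset lives
on the log scale so it acts multiplicatively on $\beta$), and group
differences are assessed by whether the offset's 95% credible interval
excludes zero.

Sampling uses JAGS (Gibbs/slice sampling) through `rjags`.  Two
consequences of that backend choice are worth stating.  First,
non-centred parameterisations are a reparameterisation trick for
Hamiltonian samplers; a Gibbs sampler needs no such device, so the model
is written in its natural centred form — the posterior is identical.
Second, divergent transitions are a Hamiltonian-specific diagnostic and
do not exist here; convergence is monitored with the split potential
scale reduction factor instead, and any fit with $\hat R \ge 1.1$ is
flagged with a warning and a `converged = FALSE` field, never a silent
success.  The full protocol runs 4 chains of 5000 draws with the first
2000 discarded (12,000 post-burn-in draws); recovery studies and the
test suite use reduced chains (for example 4 × 1500 with 500 burn-in),
which the timing studies below show is sufficient for stable medians.

Point estimates are per-subject posterior medians on the natural scale.
Componentwise medians of a simplex do not sum exactly to one, so the
weights are renormalized and the pre-normalization deficit recorded
(`w_median_deficit`); across the test fits the deficit stays well below
0.1.  Degenerate heuristic weights can drive a predicted probability to
exactly 0 or 1, so inside every likelihood the probability is clamped to
$[10^{-9}, 1-10^{-9}]$ — configurable, and wide enough never to affect a
non-degenerate fit.  A per-subject maximum-likelihood fitter (grid
search plus Nelder–Mead refinement) ships alongside as an independent
cross-check; it is used in the tests, never for headline numbers.

## Model comparison

Fit at the median parameters is summarised by the negative log
likelihood; the Solo-trial −LL under the solo model is the "disruption"
index used in the group analyses.  Formal comparison uses an integrated
BIC: each subject's marginal likelihood is estimated by averaging the
choice likelihood over draws from the *fitted group-level distribution*
(weights drawn uniformly on the simplex, matching their prior), then
$\mathrm{iBIC} = -2 \sum_i \log \hat m_i + k \log(\text{total choices})$
with $k$ the group-level roster above plus any group-difference offsets.
The exact placement of the penalty's sample-size term is a convention
choice (total choices = subjects × trials); it is stated in every report
and constant across models, so model rankings are unaffected.  The
Monte-Carlo estimate uses $K = 2000$ prior draws by default; its
standard error shrinks as $1/\sqrt K$ (verified in the tests), and
$K < 100$ triggers a warning.

For model recovery the per-subject "best fit" needs a subject-grain
criterion the original analysis does not spell out; the package uses the
subject's marginal likelihood with a BIC-style penalty, individual
free-parameter count × log(96).  It mirrors the iBIC logic at the
subject level and is isolated in one function so alternatives can be
swapped.

## The synthetic cohort

The generator emulates the study conditions: three groups — non-lesion
controls (n = 28) and two lesion-like groups (insula-like n = 10,
dACC-like n = 6) — with choices generated from the hybrid model.  The
group hyperparameters are not published, so the defaults encode the
qualitative pattern the study reports, chosen once and documented here:

* controls: $\log\beta \sim N(\log 4, 0.7)$, weight box
  $\omega_{follow} \le 0.5$, $\omega_{oppose} \le 0.3$,
  $\omega_{utility} \ge 0.3$ (utility-dominant);
* lesion-like: $\log\beta \sim N(\log 2, 0.7)$ (noisier utility-based
  choice), $\omega_{follow} \in [0.25, 0.9]$, $\omega_{oppose} \le 0.3$,
  $\omega_{utility} \le 0.6$ (follow-shifted, oppose low and comparable
  across groups, as the study found);
* both: $\log\alpha \sim N(\log 0.85, 0.35)$ (mild risk aversion),
  $OCU \sim N(0.25, 0.75)$.

Weights are sampled uniformly on the unit simplex and rejection-sampled
into the group's range box; an infeasible box is detected analytically
at spec construction.  The study's two a-priori behavioral exclusion
rules are applied to every simulated subject: (i) a *reversal* —
choosing the higher-high-payoff (riskier) option less often at the 90%
win probability than at 40% (evaluated on all trials by default, with a
Solo-only variant for sensitivity reruns; ties keep the subject); and
(ii) *degenerate Solo behavior* — all-safe or all-risky on the 24 Solo
trials, for whom bidirectional social influence is impossible.  Excluded
simulated subjects are replaced by freshly drawn agents until the cohort
is complete, mirroring the recovery protocol of the original analysis.

```{r, eval = FALSE}
cohort <- simulate_cohort(default_cohort_spec(), seed = 1)
apply_exclusions(cohort)$report
```

What the generator does *not* emulate: response times, demographics
(age, education, cognitive screening), session-level nonstationarity
(fatigue, learning), and any neuroanatomy.  Passing tests therefore show
that the pipeline recovers what it embeds under the model's own
assumptions — they cannot show that real lesion participants satisfy
those assumptions.

## Recovery protocols

Parameter recovery samples 44 true parameter sets (log
$\beta \sim N(1.1, 0.8)$, log $\alpha \sim N(-0.2, 0.35)$,
$OCU \sim N(0.2, 0.8)$, weights uniform on the simplex inside
follow ≤ 0.9, oppose ≤ 0.6, utility ∈ [0.05, 1]), simulates sessions,
re-applies the exclusion rules with resampling, refits the hybrid model,
and correlates truth with posterior medians for six quantities: log
$\beta$, $\alpha$, normalized OCU
($[1+e^{-\beta\,OCU}]^{-1}$, computed with each side's own $\beta$),
and the three weights.  With reduced chains the protocol takes about a
minute on one CPU.  The five structurally well-identified quantities
recover with $r$ around 0.75–0.9.  Normalized OCU recovers positively
and significantly but more weakly under these truth conditions
($r \approx 0.4$–0.6 across seeds): OCU influences choice only through
the $\omega_{utility}$ route on 48 Info trials, so agents with small
utility weights carry almost no OCU information, and the posterior
rightly shrinks them toward the group mean — the recovery error
anti-correlates with $\omega_{utility}$.  An unshrunk per-subject ML fit
recovers OCU *worse*, confirming this is an information limit of the
truth distribution, not an estimation artifact.

Model recovery simulates cohorts from each model, fits all models to
each cohort, and reports the group-level iBIC table, the confusion
matrix (row-normalized best-fit proportions) and the inversion matrix
(column-normalized).  At the group level the generating model wins its
row; at the individual level the models are *not* sharply dissociable —
they are nested, and the diagonal dominance is modest.  That mirrors the
original study's own conclusion and is asserted only at the level it
holds (group-level selection, row-maxima on the diagonal).

## Statistics

Group comparisons use the pooled bootstrap: values from all groups are
pooled, resampled with replacement into groups of the original sizes,
and the t (or one-way F, for three groups) statistic recomputed per
iteration; two-tailed significance compares $|t_{obs}|$ with the null's
absolute values (boundary ties count toward the null, which is the
conservative direction).  Association tests "unpair" x and y by
resampling each independently.  The type-I error of the group test under
an exchangeable null is verified at 0.049 ± 0.006 in the acceptance
suite.  The categorical analogue resamples labels under pooled margins
for a chi-squared statistic.

The robust correlation is a skipped Pearson: bivariate outliers are
flagged by projecting every point onto every direction through the
coordinatewise-median center and applying the 1.5 × IQR boxplot rule per
projection (the standard recipe in the robust-correlation literature —
the original analysis names only "robust correlation", so the flavor is
a documented package choice and the plain Pearson value is always
reported alongside).  Null Bayes factors use the JZS default prior
(Cauchy scale $\sqrt 2 / 2$) computed by quadrature, with correlations
assessed through the equivalent single-predictor regression t statistic;
the t-statistic integral is cross-checked against a Monte-Carlo
prior-integration oracle in the tests.  Covariate control is ordinary
least-squares residualization followed by the same tests on residuals.

One subtlety of the model-agnostic conformity distance (the orthogonal
distance from a subject's (follow-safe, follow-risky) rates to the
trade-off line $c_{risky} = 1 - c_{safe}$, scaled by $1/\sqrt 2$; the
scaling is stated explicitly because correlation-based uses are scale
invariant anyway): its *signed association* with $\omega_{follow}$ is
composition-dependent.  Followers and opposers both sit far from the
line, on opposite sides, so on a cohort with symmetric weight mass the
correlation washes out by construction; on realistic,
oppose-light/follow-varying cohorts it is strongly positive with
$\omega_{follow}$ and negative with $\omega_{oppose}$, which is the
regime in which the measure validates the weights.

## Numerical choices, sizes and limitations

* Likelihood clamp $10^{-9}$; simplex-median renormalization with
  recorded deficit; weight-box feasibility checked analytically.
* Chain seeds derive deterministically from one integer seed (chain $c$
  uses seed + $c$); every simulation function takes an explicit seed and
  restores the caller's RNG state, so full pipelines are reproducible
  bit-for-bit given the sampler version.
* Problem sizes used by the shipped studies: recovery at 44 subjects ×
  96 trials with 4 × 1500/500 chains (~1 minute); model recovery in the
  test suite at 2 models × 20 subjects with 2 × 1100/350 chains; the
  end-to-end group-direction study at 24 subjects.  These sizes were
  chosen so that the whole validation suite runs in a few minutes while
  leaving every qualitative conclusion stable across seeds.
* The package deliberately excludes alternative risk models
  (mean–variance, probability weighting), response-time analyses,
  history/learning effects across trials, and any lesion anatomy; the
  nested family above is the entire modelling scope.
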