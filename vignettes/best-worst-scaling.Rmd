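---
title: "Best-worst scaling: design, counting scores, and the maxdiff conditional logit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Best-worst scaling: design, counting scores, and the maxdiff conditional logit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bwstools)
```

## The problem

Hyper-prolific sows routinely farrow more piglets than they have functional
teats, so farrow-wean farms move surplus piglets onto *nurse sows* —
recently weaned sows that take on a foster litter. Which sow to pick is a
multi-attribute judgement: the health and size of her current litter, her
body condition, teat count, lactation stage, behaviour, and parity all
compete. Object-case best-worst scaling (BWS, also called maxdiff) elicits
such priorities by repeatedly showing a small subset of attributes and
asking for the *most* and *least* important one; because every answer is a
forced trade-off, it avoids the end-piling of rating scales and needs only
modest samples.

`bwstools` implements the three analysis layers such a study needs — the
choice-set design, the descriptive counting scores, and the maxdiff
conditional logit — plus a synthetic-respondent generator that stands in
for confidential survey data.

## Choice-set design

Tasks are laid out by a balanced incomplete block design. For $v$
attributes shown in $b$ tasks of $k$, with each attribute appearing $r$
times and each pair co-occurring $\lambda$ times, the identities
$bk = vr$ and $\lambda(v-1) = r(k-1)$ must hold. `construct_bibd()` builds
designs by cyclic development of a difference set: block $i$ is
$\{(d+i) \bmod v\}$ over the base set. For the seven nurse-sow attributes
the base set $\{0,1,3\}$ mod 7 (the Fano plane) yields
$(v,b,r,k,\lambda) = (7,7,3,3,1)$: seven tasks of three attributes, each
attribute shown three times, each pair exactly once.

Design choices here, made once:

* **Construction by difference sets, not search.** Determinism and
  auditability; an unsupported $(v,k,\lambda)$ raises an explicit error
  rather than silently substituting an unbalanced layout.
* **Ordering.** Blocks are listed in cyclic-development order with
  ascending indices inside a block. Task order carries no information and
  no downstream statistic depends on it (asserted by a shuffle-invariance
  test on the likelihood).
* **Binding.** Attribute $j$ of the attribute table maps to treatment
  index $j-1$ by default; any bijection can be supplied. The exact task
  compositions used in the original survey were not published, but all
  $(7,7,3,3,1)$ designs are statistically equivalent for both analysis
  layers, which condition only on what was shown.

`validate_bibd()` re-derives occurrence and co-occurrence by direct
counting and reports every violated condition; it is itself tested against
an independent brute-force counter on random (mostly invalid) block lists.

## Counting scores

With $B_j$ and $W_j$ the number of times attribute $j$ was picked best and
worst over all $T$ tasks, `bws_summary()` reports

* best-worst value $BW_j = B_j - W_j$ (sums to zero over attributes);
* standardized value $BW_j / (Nr)$, the value relative to its attainable
  extreme for $N$ respondents each seeing the attribute $r$ times, in
  $[-1, 1]$;
* ratio score $\sqrt{B_j / W_j}$, a scale-free multiplicative measure;
* relative importance $100\,\sqrt{B_j/W_j} / \max_j \sqrt{B_j/W_j}$, with
  the top attribute at 100; and a dense rank on that column.

Two formula variants circulate for the standardized and relative columns —
the ones above, and min–max rescalings of $BW_j$. Published tables in this
literature are frequently computed with the former even when the latter is
printed as the formula; the package therefore uses the $Nr$-normalisation
and the square-root-ratio scale as the primary columns (they reproduce the
motivating study's printed table to 2 d.p. for every internally consistent
attribute) and exposes the literal min–max rescalings as optional columns
(`minmax = TRUE`) for comparability.

Numerical conventions: rendered tables round half-away-from-zero to 2 d.p.
while machine output keeps full precision; $W_j = 0$ makes the ratio score
undefined and is a hard error unless an explicit $+0.5$ continuity
correction is requested (and then flagged in the output); rank ties share
the smaller rank and are flagged. When counts are *reconstructed* from a
published percentage table (`reconstruct_counts_from_percentages()`,
rounding half away from zero), best and worst totals can disagree by a task
or two because the printed percentages were themselves rounded — the
summary then warns and normalises each percentage column by its own total.

Per-respondent scores $s_{ij} \in \{-r,\dots,r\}$ (best picks minus worst
picks of attribute $j$ by respondent $i$) satisfy
$\sum_i s_{ij} = BW_j$; `score_distribution()` histograms them and
tabulates the task-level best / unchosen / worst trichotomy, which sums to
$Nr$ appearances per attribute.

## The maxdiff conditional logit

Each task of $k$ attributes is modelled as one choice among its $k(k-1)$
ordered (best, worst) pairs; pair $(b, w)$ has utility $u_b - u_w$ and
probability

$$P(b, w) = \frac{\exp(u_b - u_w)}{\sum_{i \ne j} \exp(u_i - u_j)},$$

with one reference attribute's utility fixed at 0 for identification
(default: the attribute with the lowest aggregate best-worst value, the
conventional "least important" baseline, so the remaining coefficients are
positive). The joint pair model — rather than a sequential best-then-worst
model — is the likelihood family used here; its null log-likelihood for
$T$ tasks of three attributes is $-T\ln 6$, which is exactly the null
value printed in the motivating study ($-357\ln 6 = -639.7$), pinning the
family its software used.

Estimation is plain maximum likelihood: log-sum-exp-stabilised objective,
analytic gradient, BFGS from $\beta = 0$, then Newton steps on the
observed information until the gradient max-norm is below $10^{-6}$
(configurable). The objective is concave, so the only numerical risk is
*separation* — an attribute never (or always) picked best when shown — in
which case the diverging coefficient is reported with a warning flag
rather than silently truncated. Degenerate subgroups therefore yield
flagged fits, not crashes.

Uncertainty:

* classical standard errors from the inverse observed information;
* robust standard errors from the cluster sandwich
  $A^{-1} \left(\tfrac{G}{G-1}\sum_c g_c g_c'\right) A^{-1}$ with scores
  summed within respondent ($G$ respondents). Respondent-level clustering
  is the standard treatment for repeated choice tasks; per-task clustering
  (heteroskedasticity-only) is available via `cluster = "task"` since the
  original report does not state which was used. On homogeneous simulated
  cohorts the robust/classical ratio stays in $[0.8, 1.25]$, as it should
  when clustering carries no extra dependence.

Fit statistics follow the usual definitions: McFadden pseudo-$R^2 =
1 - LL/LL_0$, $AIC = -2LL + 2K$, $BIC = -2LL + K\ln T$ with $K = v - 1$
parameters and $T$ tasks. Significance stars use two-sided Wald tests on
the robust errors at 0.05 / 0.01 / 0.001.

`subgroup_fit()` refits the model independently on the two categories of
one demographic variable, keeping the pooled reference. With five binary
variables a respondent belongs to five subgroups at once, so category
estimates are descriptive strata contrasts, not independent populations —
the same caveat the motivating study attaches to its subgroup tables.

## The synthetic cohort

`simulate_respondents()` draws rosters with the surveyed cohort's
demographic margins: 51 managers of whom 18 are female, 24 aged 18–40, 26
with at most ten years' experience, 15 with college-level education, and
19 managing at most 5,000 sows. Quota mode reproduces those counts
exactly (remainders go to the larger category) and is the default because
the study filled fixed quotas of one manager per site; multinomial mode
samples the margins instead. Variables are generated independently — only
marginals were published — though any joint structure can be injected by
editing the roster.

`simulate_choices()` draws each (respondent, task) pick from the maxdiff
pair probabilities. The default generating utilities are the published
pooled coefficient vector (SCLH 1.744 … SB 0.431, P = 0); they are
*illustrative*, chosen so simulated data resemble the study's preference
hierarchy, and carry no claim of being population truth. Seeding uses one
master seed with a deterministic per-respondent sub-stream keyed on the
respondent id, so removing one respondent never reshuffles another's
choices.

What the generator does *not* emulate: respondent inattention, position
bias, fatigue over long task sequences, or preference heterogeneity within
a stratum (unless per-stratum profiles are supplied). Passing tests on
synthetic cohorts therefore demonstrate correctness of the estimator and
pipeline under the stated model, not robustness to the behavioural
artefacts of real surveys.

## What is and is not reproducible

The study's individual-level choice data were not deposited. Consequently:

* the counting table is reproducible *from its own printed percentages*
  (all score columns, to 2 d.p., for every internally consistent
  attribute — one attribute's printed row is internally inconsistent: its
  best percentage reconstructs to a best-worst value two units away from
  the printed one, and the worst percentages sum to 100.6%; the package
  reproduces what the arithmetic supports and does not force agreement);
* the null log-likelihood, pseudo-$R^2$, AIC and BIC are reproducible
  exactly from the printed task count and converged log-likelihood;
* the coefficient vectors themselves are *not* recomputable; they serve as
  simulation scenarios. The package's substitute evidence is a
  parameter-recovery study: 20 cohorts of 500 respondents simulated from
  the published coefficients and refit. At that scale each coefficient's
  sampling error is roughly 0.05–0.08, so the package asserts (a) all six
  estimates land within ±0.1 of truth in at least 90% of replicates and
  (b) the 95% robust intervals cover truth in at least 90% of the pooled
  interval checks — two separate conditions; their conjunction per
  replicate is inherently a weaker event at this sample size. Subgroup
  refits at the survey's category sizes (18 and 33 respondents) are
  exercised for convergence and sampling-error agreement with truth.

Problem sizes in the test suite (cohorts of 300–500, up to 10,000 tasks
for distributional checks, 20 recovery replicates) were chosen as the
smallest at which the asserted sampling bounds are comfortably
discriminating.

## Limitations

* Only cyclic difference-set designs are stocked; there is no optimal
  design search, and no resolvable or partially balanced designs.
* No latent-class, mixed-logit or hierarchical-Bayes estimation: subgroup
  refits are the only heterogeneity device, mirroring the motivating
  analysis.
* The sequential best-then-worst likelihood variant is not implemented;
  for $k = 3$ its null log-likelihood coincides with the pair model's, so
  the printed null value cannot distinguish them, and the pair model is
  the standard treatment.
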