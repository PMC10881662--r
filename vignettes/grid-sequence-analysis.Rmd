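---
title: "Recovering dyadic aggression subtypes with grid sequence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering dyadic aggression subtypes with grid sequence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadgrid)
```

## The task and its data

In the interactive Taylor Aggression Paradigm (iTAP) two siblings play
repeated competitive trials. At the start of every trial each member
selects a monetary punishment for the other, from 0 to 90 cents in steps
of 10; the trial's (covertly preprogrammed) winner gains a fixed 50
cents and the loser forfeits the amount the winner selected. Failing to
respond costs a fixed 100 cents and the trial. A session has four
interactive blocks of 15 trials; between blocks two and three sits a
block of five *fake* trials on which each member is shown a scripted,
escalating "opponent selection" of 30-50-50-60-70 cents instead of the
sibling's true choice. Within every interactive block, wins, losses and
ties occur in equal proportion in a fixed order; since five scripted
trials cannot split evenly three ways, the fake block defaults to the
pattern win-A, win-B, tie, win-A, win-B (configurable).

Aggression is operationalised as the trial-wise punishment selection.
The unit of analysis is the *dyad*: a session is a joint time series of
two coupled selection streams.

```{r}
cfg <- itap_config()
cfg
table(build_outcome_schedule(cfg)[block_labels(cfg) == "B1"])
```

Two payoff corners are underdetermined by the task description and are
fixed here as package conventions: ties transfer nothing (the minimal
rule consistent with "winner gains, loser forfeits"), and when both
members fail to respond, both are penalised and the trial is recorded
as a tie. On fake trials the settlement uses the members' real
selections; since no derived score uses payoffs, this choice is inert
downstream.

## The synthetic cohort generator

The generator exists so every downstream stage is testable without the
original deposited data. It implements the simplest mechanism that
produces the three phenomena the analysis must be sensitive to:
tit-for-tat convergence, escalation under scripted provocation, and a
final-block decline. Member $i$ selects

$$s_i(t+1) = q\Big((1-\rho_i)\,\big(b_i - \delta_i \max(0, t-35)\big)
  + \rho_i\, d_i(t) + \gamma_i\, \mathbb{1}[\text{loss}_i(t)]
  + \varepsilon\Big), \qquad \varepsilon \sim N(0, \sigma_i^2),$$

where $d_i(t)$ is the punishment displayed to $i$ at trial $t$ (the
sibling's true selection, or the script during fake trials) and $q$
clips to $[0, 90]$ and rounds to the nearest multiple of 10 (half away
from zero). The parameters, all in cents where applicable:

* `b` — baseline selection, the member's unprovoked level;
* `rho` — reciprocity weight in $[0,1]$; at 1 the member is a pure
  tit-for-tat copier of what they were last shown;
* `gamma` — loss reactivity, an additive bump on the trial after a
  loss (default 5 in the shipped templates);
* `delta` — de-escalation in cents/trial, indexed to trial 35 because
  the decline to be emulated happens after the scripted provocation
  ends; the shipped default 0.5 produces a gentle ~15-cent drift over
  the last 30 trials rather than a collapse;
* `sigma` — Gaussian pre-quantisation noise (default 5).

Three planted dyad types mirror the subtypes the clustering should
find: `both_low` ($b = 10$ for both), `both_high` ($b = 75$), and
`mixed` ($b = 70$ vs $b = 20$). The default cohort is 10/10/8 dyads of
these types — the study's size of 28 pairs — with 13 brother pairs and
ages drawn from the study's demographic profile (mean 23.4, SD 3.4,
truncated to 18–35). Baselines, counts and demographics follow the
study conditions; reciprocity, loss bump, de-escalation and noise are
the package's own choices of what a plausibly realistic session looks
like, fixed once.

What the generator deliberately does *not* emulate: within-session
learning beyond the linear rule, autocorrelated mood dynamics,
individual response-time behaviour, or real non-response patterns
(a non-response probability exists but defaults to 0 because the study
does not report its rate). Passing recovery tests on this cohort shows
the pipeline can separate types whose baseline separation is large
relative to noise; it does not certify performance on real data, whose
cluster structure may be weaker.

```{r}
coh <- generate_cohort(cohort_spec(seed = 20240208))
summary(vapply(coh$trajectories, function(tr)
  mean(tr$trials$sel_a[!tr$trials$is_fake]), numeric(1)))
```

## Derived scores

Per member: five block means (the fake trials count as a block of
their own), the interactive mean over the 60 real trials, counts of
zero-cent selections over interactive and fake trials, the pre–post
difference (mean of the 30 trials before the fake block minus the mean
of the 30 after), and outcome-conditioned means — the mean selection on
trials whose preceding trial the member won, lost, or tied. The first
trial has no preceding outcome and is excluded from that grouping, so
the three groups partition the remaining 64 trials. Per dyad and block:
the members' mean and the *absolute* difference of their block means —
members are treated as indistinguishable, so a signed difference would
be arbitrary.

Missing selections are dropped from means; an all-missing block yields
a flagged `NaN`, never a silent zero. Questionnaire subscales are
sum-scored with reverse-keyed items mapped $x \mapsto \min + \max - x$
and person-mean imputation of missing items; Cronbach's alpha uses
listwise deletion (imputation is a scoring device, not a reliability
assumption).

## Grid sequence analysis

Each trial maps to a cell of a $10 \times 10$ grid of joint punishment
levels (level index = cents/10). Two encodings:

* **Indistinguishable** (interactive trials): members are
  interchangeable, so cells mirrored at the diagonal are identified by
  sorting each pair — 55 canonical cells, sequences of length 60 with
  the fake trials removed.
* **Distinguishable** (fake trials): each participant against the
  script, cells (participant level, scripted level), sequences of
  length 5; only the four scripted rows are feasible.

Dissimilarity between sequences is optimal-matching edit distance:
substitutions cost the Manhattan distance between cells, insertions
and deletions cost 1. The Manhattan substitution matrix makes
neighbouring cells cheap and distant cells stepwise dearer; on
canonical cells the sorted representation automatically realises the
minimum over diagonal reflections (verified exhaustively over all
55 × 55 cell pairs in the test suite). With indel 1 the effective
per-position cost is capped at 2, since deleting and re-inserting
dominates any dearer substitution; both costs are configurable because
the common alternative convention (indel = max substitution / 2)
changes results materially. Distances are not normalised by length —
all sequences within a mode have equal length, so normalisation would
only rescale.

The dissimilarity matrix feeds Ward agglomerative clustering
(`ward.D` by default, matching the historical "ward" of the ecosystem
this analysis style comes from; `ward.D2` selectable). The number of
clusters is the analyst's choice, supported by `select_k()`: it
recommends the cut with the largest ratio of consecutive merge heights
among cuts whose clusters all have at least `min_size = 3` members,
falling back to 1 when no ratio exceeds 2 (no dominant gap — a
homogeneous cohort).

```{r}
fit <- gsa(coh$trajectories, mode = "interactive", k = 3)
fit
table(cluster = fit$labels, planted = coh$truth$true_type)
```

## Inference

**Manipulation check.** Whether dyadic aggression responds to the
scripted provocation is tested with marginal models on the
dyad-by-block panel (five rows per dyad): generalized estimating
equations with Gaussian family, identity link, exchangeable working
correlation and dyad as the cluster unit, for the dyad mean and the
dyad difference score. Family, link and working correlation are the
standard choice for continuous repeated measures (the source analyses
do not state theirs); independence is available as an option. Wald
tests carry the design df: block 4, gender 1, interaction 4.

With 28 clusters and 10 coefficients the classic sandwich covariance
is noticeably too small and the chi-square reference for a 4-df Wald
statistic anti-conservative (empirically ~0.23 rejection at nominal
0.05 in null simulations). The package therefore defaults to the
Mancl–DeRouen bias-corrected sandwich and refers multi-df Wald
statistics to an F distribution via Hotelling's $T^2$ with
$\nu = K - p$ effective df: $F = W(\nu - q + 1)/(\nu q)$ on
$(q, \nu - q + 1)$ df. Null simulations with the shipped generator put
the block-term type-I error at ≈ 0.06; the uncorrected chi-square
route stays available via `gee_wald(fit, ref = "chisq")` and
`bias_correction = "none"`. Post-hoc block contrasts are model-based:
design rows averaged within block (marginalising over the observed
gender mix), Wald z with robust SE, Bonferroni over the 10 pairs.

**Outcome effect and correlates.** The effect of the preceding trial's
outcome uses a Kruskal–Wallis test across each participant's three
outcome-conditioned means. Treating a participant's three conditional
means as independent observations mirrors the source analysis; the
independence violation is documented here rather than repaired.
Spearman correlations use midranks with the t-approximation p-value
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$, reporting the Bonferroni-adjusted
alpha of the correlation family alongside.

**Cluster characterisation.** Clusters are compared variable-by-
variable with Kruskal–Wallis tests; the seven iTAP scores (dyad mean
and difference of the interactive mean, fake mean and zero count, plus
the dyad-mean pre–post difference) share a Bonferroni-adjusted
threshold $\alpha^* = 0.05/7 \approx 0.007$. Dunn's tests with
tie-corrected pooled variance and Bonferroni adjustment follow
significant results only — which also enforces, by construction, that
no post-hoc pair is flagged when the omnibus is not. Gender composition
is tested with a Pearson chi-square without continuity correction. For
radar-plot export every variable is z-normalized over the cohort and
averaged within cluster.

```{r}
panel <- score_panel(coh$trajectories)
cmp <- compare_clusters(fit$labels, panel)
round(cmp$panel_z, 2)
```

## Numerical conventions and degenerate inputs

* Quantisation rounds half away from zero to the nearest level after
  clipping to $[0, 90]$.
* Ward merges and cuts use `stats::hclust`/`stats::cutree`, whose
  deterministic tie handling the package inherits; the OM dynamic
  programme is exact, so ties in dissimilarities are data, not noise.
* All-identical samples make the Kruskal–Wallis tie correction divide
  by zero; the statistic is returned as flagged `NA`, as are
  zero-variance correlations and all-missing score blocks.
* The exchangeable correlation estimate is clipped to $(-0.99, 0.99)$;
  its closed-form inverse avoids any matrix inversion per cluster.
* Dunn adjusted p-values above 0.999 are labelled `">0.999"` in
  reports.
* Empty sequences are legal in `om_distance` (cost = length × indel);
  trials with a missing selection are dropped from encodings with a
  message.

## Problem sizes used in validation

The shipped test suite and the acceptance script validate on: the
28-dyad default cohort (single fit and 20 generator seeds for the
recovery check), 500 null replicates for GEE type-I calibration and
200 for power, exhaustive edit-script enumeration on a 3 × 3 sub-grid
up to sequence length 4, 1,000 random triples for the triangle
inequality, and the full 55 × 55 canonical-cell reflection check.

## Known limitations

* The linear reciprocity generator is a caricature: real dyads show
  richer dynamics (bursts, sulking, coalition shifts) that the
  recovery results do not speak to.
* The GEE small-sample correction is calibrated for this design in
  simulation; other panel shapes should re-check calibration before
  trusting nominal levels.
* `select_k`'s height-ratio heuristic formalises "inspecting the
  dendrogram" but, like any such rule, can be fooled by nested or
  chained structure; it is advisory only.
* The distinguishable (fake-trial) clustering characterises response
  styles to one fixed script; nothing transfers to other provocation
  schedules.
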