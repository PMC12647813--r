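---
title: "Semantic centrality and multi-session narrative recall: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic centrality and multi-session narrative recall: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(narrec)
```

## The problem

In naturalistic memory experiments, participants watch short videos of
everyday scenarios and later retell them. The videos are segmented by an
annotator into events, each with a free-text description; transcripts of the
participants' recall are segmented and scored against those reference events.
This package implements the quantitative layer of such a study: it turns
event descriptions into a per-video *semantic narrative network*, scores each
event's *semantic centrality*, and models how centrality predicts recall
success and the richness of recall across sessions and age groups.

## The semantic narrative network

Events of one video are nodes; the edge weight between two events is the
cosine similarity of their embedded descriptions. For the similarity matrix
$S$ of an $n$-event video, event $i$'s centrality is

$$d_i = \sum_{j \ne i} S_{ij}, \qquad c_i = \frac{d_i}{\sum_k d_k}, \qquad
z_i = \frac{c_i - \bar c}{\mathrm{sd}_{\mathrm{pop}}(c)}.$$

Numerical choices, all deliberate:

* **Self-similarity is excluded** from the degree: edges connect distinct
  events. Including the constant diagonal would shift all degrees equally and
  cancel in $z$, but the simple-graph convention is cleaner.
* **Population (divide-by-$n$) standard deviation** for the within-video
  z-score, the default of common scientific z-scoring routines; switchable
  via `semantic_centrality(sd_type = "sample")`, which rescales all $z$ by
  $\sqrt{n/(n-1)}$ and changes nothing downstream except the coefficient
  scale.
* **Negative cosine similarities are kept** — the statistic is defined on raw
  weights; a network whose degrees sum to zero is rejected as degenerate
  rather than silently clipped, and a video whose events are all equally
  central yields $z = 0$ with a warning.
* $z$ is invariant to any positive rescaling of $S$ and equivariant under
  event relabeling; these are tested properties, not accidents.

## Embedding backends

The pretrained sentence encoder used for real studies is deliberately
pluggable (`pretrained_embedder(encode_fun = ...)`) and never required. The
built-in fallback, `hash_embedder()`, is a signed bag-of-words feature
hasher: tokens (lowercased, non-alphanumerics stripped) are mapped by a
32-bit FNV-1a hash to one of 512 buckets, signed by the parity of a second,
independently seeded hash, accumulated and L2-normalized. It is a pure
function of the token multiset, fully deterministic, and reproduces the
geometry that matters for the pipeline — texts sharing vocabulary are close
in cosine — without any model download. It does **not** capture synonymy or
word order; conclusions about what a specific pretrained encoder would yield
on specific real descriptions cannot be drawn from it. For that reason a
published per-event centrality value from the original study materials is
treated as illustrative only and never asserted. Event-level descriptions
alone are embedded by default; `centrality_table(include_sub_events = TRUE)`
appends the finer-grained sub-event texts, a documented switch because
annotation practice varies.

## Boundary agreement

Two raters' boundary sets are compared with an inclusive temporal tolerance
(`|dt| <= tol_s`, default 1 s). The matcher is *optimal*, not greedy: a
dynamic program over the two sorted time lists maximizes the number of
matched pairs and, among maximum matchings, minimizes the total temporal
offset. For points on a line an optimal matching can always be taken
non-crossing (uncrossing two crossed pairs never increases cost or violates
the tolerance), which is what makes the quadratic DP exact; the test suite
verifies match counts against an exhaustive search and an independent
maximum-bipartite-matching routine. A greedy accept-smallest-offset rule —
the obvious alternative — is provably not maximum-cardinality (ref = [0, 1],
obs = [0.9, 1.1], tol = 1 is a counterexample), which is why it was not used.
Ties at equal cardinality and cost resolve to the earlier reference, then the
earlier observed boundary. Precision is the matched fraction of the observed
rater's boundaries, recall the matched fraction of the reference's; swapping
the arguments swaps P and R and leaves F1 and the mean offset unchanged.

Scoring reliability uses ICC(2,1) — single-rater, absolute agreement, both
targets and raters random — from the two-way ANOVA decomposition; the paper
family ("two-way random effects") admits an average-measures variant, which
is available as `type = "average"` but not the default, since the published
reliabilities describe a single rater's scores.

## Recall scoring and the analysis table

Transcript segments are categorized event / error / comment / other; only
event segments, mapped by the scorer to a reference event and subdivided into
central (story-essential) and peripheral (descriptive) details, enter the
analyses — the other categories are retained in the data model for audit but
contribute nothing downstream. Multiple segments mapped to the same event in
one session merge: recall is idempotent, detail counts sum, texts concatenate
with a single space (the merged text is what the lexical-consistency module
compares). The long-format table has one row per participant x cued video x
annotated event x session, with `recalled = 0` rows (zero detail counts) for
every unrecalled event, so denominators are always the annotated event count.
Detail counts are recorded per event; per-video aggregation, when wanted, is
left to the modeling layer.

## Mixed models

All models include participant and video random intercepts. Whether the
original analyses also used an event-level random effect is not stated in the
source materials; the default here is participant + video only, with
`random = c("participant", "video", "event")` available. Coding is treatment
contrasts with reference levels young / day1 / multiple-recall. Estimation is
lme4 maximum likelihood (Laplace; bobyqa, 500k function evaluations);
`nAGQ = 0` — lme4's penalized least-squares step — is used inside simulation
loops, where it agrees with Laplace to well under the Monte-Carlo noise at
this design and is several times faster. Singular fits (a variance component
at zero) are reported as converged; genuine optimizer failures are flagged,
never silent.

Inference is Wald throughout: 95% CIs as $\hat\beta \pm 1.96\,SE$, Type III
chi-square tests as $b^\top V^{-1} b$ over a term's coefficient block with
every other term present (for a single-coefficient term this is exactly
$(\hat\beta/SE)^2$), and simple slopes as linear combinations of coefficients
with delta-rule SEs — exact here, as the slope is linear in the coefficients.
Detail-count models use the Poisson family with log link: count outcomes
cannot be Bernoulli, and the Poisson reading is the one consistent with the
reported analyses. Centrality models are fitted separately per recall session
rather than with session terms. No multiple-testing correction is applied.

## Lexical consistency

The Jaccard index over *unique normalized words* deliberately measures
verbatim overlap, not meaning: lowercase, every non-alphanumeric character
(including apostrophes) becomes a separator, no stopword removal, no
stemming. The original study's tokenizer is not documented; this
normalization is a declared convention of the package, not a claim about the
original code. Within-participant consistency compares the merged recall text
of the same event across session pairs (day1–day2, day2–day8, day1–day8),
using only events recalled in both sessions of a pair — unrecalled events
contribute nothing rather than zeros. Between-participant consistency
averages all pairwise overlaps among the recallers of an event within an age
group and session, requiring at least 3 recallers. For group-level modeling,
within-participant values aggregate to participant x video x session-pair
means and between-participant values to one value per event x session x
group, mirroring the random-effects structures of the published analyses.

## The synthetic world

`generate_study()` simulates the full experiment from a seeded config:

* **Design:** 28 participants per age group, 8 videos of 10–25 events; the
  first half of the videos is recalled in all three sessions
  (`recall_type = "multiple"`), the second half only at one week (`"one"`).
  The multiple/one assignment is fixed rather than counterbalanced — the
  models never use video identity beyond a random intercept, so
  counterbalancing would add machinery without changing any estimand.
* **Recall:** Bernoulli with
  $\mathrm{logit}\,p = \beta_0 + \beta_c z + \beta_g G + \beta_{gc} Gz +
  \beta_{s} + \beta_{one} + u_p + w_v$, with $u_p, w_v$ Gaussian. The
  centrality $z$ entering the model is *computed by the real pipeline* (hash
  embedder, network, z-score) from the generated descriptions, so one
  coherent corpus exercises embedding, networks, Jaccard and inference
  simultaneously.
* **Details:** central counts Poisson with log-rate
  $\gamma_0 + \gamma_c z$, peripheral counts Poisson at rate $e^{\delta_0}$,
  both only for recalled events.
* **Text:** recall text reproduces a fraction $\rho$ of the description's
  words plus Poisson noise words; $\rho = 1$ with no noise gives Jaccard
  exactly 1 for repeated events, and mean within-participant Jaccard is
  strictly increasing in $\rho$ — a tested property.
* **Raters:** boundary sets derive from true event onsets with configurable
  miss rate, Gaussian jitter and false-alarm rate.

Default link-scale parameters ($\beta_0 = 0.3$, session offsets
$0/-0.05/-0.05$, $\beta_{one} = -0.9$, $\gamma_0 = \log 2$,
$\delta_0 = \log 1.7$) were chosen once so that marginal behaviour echoes the
published descriptive tables — event recall around 0.55–0.60 for repeatedly
recalled videos, roughly 0.35–0.40 for videos first recalled after a week,
about 16–20 central and 12–18 peripheral details per video — and are tuning
conventions of the synthetic world, not estimates of the study's true
parameters. The published study reports no variance components, so the
random-intercept SDs default to 0.5 on the link scale, likewise a documented
convention. Group and interaction effects default to zero: null calibration
is the generator's resting state. A `hub_event` option builds one event's
description from words borrowed from every other event's realized
description, yielding a designated semantic hub for network sanity checks.

What a green test establishes: that the estimators recover the parameters of
*this* generative world (logistic recall in centrality, Poisson details,
exchangeable Gaussian intercepts) at the study's scale, with calibrated error
rates. What it does not establish: anything about real transcripts — human
recall text is not a uniform subsample of an annotator's vocabulary, real
centrality effects need not be linear on the logit scale, and a pretrained
encoder's similarity structure differs from hashed bags of words. Published
fitted coefficients, group Jaccard means, ICCs and boundary F1 values depend
on the original participants and raters and are therefore not reproduction
targets; the acceptance suite instead checks oracle equivalence (centrality,
Jaccard, matching, ICC against independent recomputations), parameter
recovery ($\hat\beta_c$ within ±0.05 of 0.30 on average, ≥90% CI coverage),
type-I-error calibration (rejection rate in [0.02, 0.09] under the null), and
one analytic value — the exact binomial upper bound $1 - 0.025^{1/1000}
\approx 0.368\%$ for 0 significant replicates in 1000, the basis of the
power engine's reporting. The replicate count 1000 is itself an inference
from that printed interval, documented rather than asserted.

## Power engine

`power_simulation()` regenerates the study `nsim` times with the group x
centrality interaction forced to a chosen effect, refits the day-specific
logistic model per replicate, and counts Type III rejections at level
$\alpha$, returning the rejection fraction with an exact Clopper–Pearson 95%
CI. Replicates that fail to converge are excluded and counted, with a warning
above 10%. Replicate seeds are `template$seed + seed + r`, kept below
$2^{31}$; identical inputs give identical p-value streams.

## Known limitations

* The hash embedder's 512 buckets admit rare token collisions; with disjoint
  vocabularies the off-diagonal similarities are near but not exactly zero.
* The boundary DP is $O(nm)$ in the two set sizes — ample for human
  segmentations (tens of boundaries), not tuned for thousands.
* Gaussian rating models use ML (not REML) for coherence with the Wald
  machinery; variance components are mildly biased at small group counts.
* The generator's recall text has no morphology, synonymy or word order;
  consistency analyses on it exercise the bookkeeping and the measure's
  monotonicity, not linguistic realism.
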