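# narrec

Analysis toolkit for naturalistic episodic-memory experiments in which
participants watch short everyday-life videos and verbally recall them across
multiple sessions (immediately, after one day, after one week). The package
asks a structural question: are events that are *semantically central* to a
narrative remembered better, and does that advantage differ between young and
older adults or decay over a week?

## What it computes

**Semantic narrative network.** Each annotated video is an ordered list of
events with free-text descriptions. Descriptions are embedded as sentence
vectors (a deterministic feature-hashing backend is built in; a pretrained
sentence encoder can be plugged in) and every pair of events within a video is
connected by an edge weighted with the cosine similarity of their embeddings.
The **semantic centrality** of event *i* in a video with similarity matrix *S*
is its weighted degree, normalized and z-scored within the video:

    d_i = sum_{j != i} S_ij,   c_i = d_i / sum_k d_k,   z_i = (c_i - mean(c)) / sd_pop(c)

**Mixed-model inference.** On the long-format table (participant x video x
event x session), recall success is modeled with logistic mixed models —
`recalled ~ group * centrality_z + (1 | participant) + (1 | video)` — fitted
separately per recall session, with Type III Wald chi-square tests, Wald 95%
CIs, simple slopes per group, Poisson mixed models for central/peripheral
detail counts, Pearson correlations for rehearsal ratings, and a
simulation-based power engine with exact (Clopper–Pearson) binomial CIs.

**Reliability and consistency.** Event-boundary agreement between raters
(optimal one-to-one matching within ±1 s; precision/recall/F1 and mean
temporal offset), ICC(2,1) for detail scoring, and Jaccard overlap of the
unique words used to describe the same event — within participants across
sessions and between participants within a session.

**Synthetic studies.** A fully seeded generator produces annotation files,
boundary sets, scored transcripts with recall text, and ratings from known
ground-truth parameters (logistic recall model with random intercepts, Poisson
details, controllable verbatim overlap), so every estimator in the package can
be validated by parameter recovery and calibration.

## Worked example

```r
library(narrec)

cfg <- synthetic_config(seed = 2024)        # paper-scale: 2 x 28 participants, 8 videos
sim <- generate_study(cfg)

tab <- sim$analysis
mean(tab$recalled[tab$session == "day1"])   # 0.534

fit <- fit_glmm(
  tab[tab$session == "day1", ],
  model_spec("binomial", "recalled",
             fixed = c("group", "centrality_z", "group:centrality_z"))
)
fit
#> binomial mixed model on recalled (n = 2800, converged)
#>                     term estimate      se      z  ci_low ci_high         p
#>              (Intercept)  0.04973 0.32227 0.1543 -0.5819  0.6814 8.774e-01
#>               groupolder  0.09060 0.15688 0.5775 -0.2169  0.3981 5.636e-01
#>             centrality_z  0.26817 0.05867 4.5708  0.1532  0.3832 4.858e-06
#>  groupolder:centrality_z  0.01255 0.08347 0.1503 -0.1511  0.1761 8.805e-01
```

The generator's true centrality effect here is 0.30 on the logit scale; the
fitted coefficient 0.268 (SE 0.059, 95% CI [0.153, 0.383]) recovers it, and
the null group x centrality interaction is correctly non-significant
(chi²(1) = 0.02, p = 0.88). Simple slopes per group:

```r
simple_slopes(fit)
#>   level estimate     se ci_low ci_high    z        p
#> 1 young    0.268 0.0587  0.153   0.383 4.57 4.86e-06
#> 2 older    0.281 0.0596  0.164   0.397 4.71 2.44e-06
```

Boundary agreement of a simulated second rater against the reference
segmentation of video 1:

```r
truth <- truth_boundaries(sim$videos[[1]])
match_boundaries(truth, generate_rater(truth, cfg))
#> boundary agreement: P = 0.909, R = 1.000, F1 = 0.952, mean |dt| = 0.174 s (10 matches)
```

Lexical consistency of recall across sessions (the generator reproduced 70%
of each description's words, so overlap is high but imperfect):

```r
rows <- within_participant(sim$transcripts)
mean(rows$jaccard)                          # 0.463 over 2602 repeated events
```

## Command line

An installed script (`system.file("scripts", "narrec", package = "narrec")`)
wires the stages together:

```sh
narrec simulate --config cfg.json --out study/
narrec network build --annotations study/annotations.json --backend hash --out net/
narrec analyze recall --table study/analysis_table.csv --session day1 --out report.json
narrec agreement --ref a.csv --obs b.csv --tol 1.0
narrec consistency within --recalls study/recalls.csv
narrec power --config cfg.json --effect 0.2 --nsim 1000 --seed 7
```

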