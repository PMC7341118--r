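---
title: "Stage-stratified pathway imbalance analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-stratified pathway imbalance analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagepath)
library(dplyr)
```

## The problem

Tumor cohorts annotated with clinical stage (I–IV) carry a progression
signal that single-gene markers capture poorly: genes act in pathways, and
what changes with malignancy is often the *balance* of a pathway — which of
its members are pushed up and which down relative to a low-malignancy
baseline. `stagepath` implements a complete analysis chain that converts a
gene-by-sample expression matrix plus stage labels into (i) stage-specific
feature-gene sets, (ii) co-expression networks whose topology tracks
disease state, (iii) per-sample pathway *imbalance scores*, and (iv) a
binary early (stage I/II) versus advanced (stage III/IV) SVM classifier
built on those scores.

Stage I — the least malignant group — serves as the control throughout:
normalization, deviation baselines and direction labels are all anchored
to it.

## Preprocessing

Genes, then samples, with a missing fraction strictly above 10% are
removed (the order is a choice: gene-first preserves more samples, and
both passes are logged in `drop_log()`). Remaining missing cells are
imputed with the gene's observed mean. Every value is then z-scored
against the control stage: per gene, `z = (x - mu_g) / sigma_g` with
`mu_g`, `sigma_g` the mean and *sample* (n−1) standard deviation over
stage-I samples, so the control group of every gene is exactly standard
after the transform. Genes with zero control variance cannot be scaled
and are dropped with a logged reason. The transform is affine per gene,
so gene–gene Pearson correlations — and hence the networks downstream —
are unchanged by it. Input is assumed to already be on the analysis scale
(no log-transform is applied).

## Feature genes

On the control-anchored z scale the fluctuation statistic is the *signed*
coefficient of variation `CV = mean / sd` over all samples: genes drifting
up in tumors score high positive, genes drifting down high negative,
stage-independent genes sit near zero. Genes strictly outside the
empirical quartiles (type-7 quantiles; both cutpoints configurable) are
kept — about half the genes, discarding the middle half that fluctuates
tightly around the baseline.

Candidates are screened by four-group one-way fixed-effects ANOVA at raw
p < 0.05 (no multiple-testing correction — the screen is a filter, not an
inferential claim, and downstream validation is the classifier). Each
significant gene is then assigned to stage feature sets via Tukey HSD on
all six stage pairs (Tukey–Kramer handles the unequal group sizes typical
of staged cohorts, e.g. 277/122/84/25): a gene joins stage k's set when
at least one significant pair involves stage k. This any-significant-pair
rule is the simplest mapping consistent with overlapping per-stage sets
and is isolated in `tukey_assign()` so it can be swapped. The shared set
is the four-way intersection.

## Co-expression networks and degree weights

Edges join gene pairs whose Pearson correlation over the chosen samples
is strictly above 0.5 (positive) or strictly below −0.5 (negative);
ties at the threshold are excluded. Per-stage networks use that stage's
feature genes and samples; a *global* network (all feature genes, all
samples) supplies the gene weights for scoring, because scoring a sample
of unknown stage must not depend on its label.

Topology is summarised by the average shortest path over *connected*
ordered pairs (co-expression graphs are routinely disconnected; excluding
unreachable pairs keeps ASP finite), within-component closeness
(reachable count / summed distances; isolated nodes get 0), the local
clustering coefficient (degree < 2 gives 0) and the degree distribution.
A numerical consequence of the connected-pairs convention is worth
stating: deleting a *bridge* edge removes distant pairs from the average,
so ASP can drop and closeness rise on disconnection. The clean
monotonicity — edge loss lengthens geodesics, ASP never decreases,
closeness and degree never increase — holds exactly for deletions that
preserve the reachability relation, and that is the form verified in the
test suite (random non-bridge deletions).

Degree is converted to a gene weight with the logistic sigmoid
`omega = 1 / (1 + exp(-degree))`, mapping connectivity into (0.5, 1);
genes absent from the network take the minimum `sigmoid(0) = 0.5`. Hubs
therefore count up to twice as much as isolated genes in the pathway
score, a deliberately gentle weighting.

## Pathway enrichment and the imbalance score

Per stage, feature genes are tested for over-representation in each gene
set by a one-sided Fisher exact test over the *candidate universe* (the
CV-surviving genes) as background — feature genes were selected from that
universe, and a whole-genome background would inflate enrichment. Raw
p < 0.05 flags a pathway; again no correction, mirroring the screening
character of the step.

For each enriched pathway, member genes (pathway ∩ feature-gene union)
are labelled **up** or **down** by the sign of their mean deviation from
the control baseline over all non-control samples — once, cohort-wide,
never per stage, so an unlabelled sample can be scored. The per-sample
imbalance score is

$$A(P) = \log_2 \frac{\sum_{i \in \text{up}} \omega_i (X_i - \mu_i)^2}
                     {\sum_{j \in \text{down}} \omega_j (X_j - \mu_j)^2}$$

with `mu` the control-stage mean (0 on the z scale). `A(P) = 0` means the
two sides deviate equally ("balance"); positive values mean up-regulated
genes dominate, negative the reverse. The score is antisymmetric under
swapping the sides and shifts by exactly ±2 when one side's deviations
double — both identities are tested. Numerator and denominator are floored
at 1e-8 so a vanishing side yields a large finite score rather than an
infinity; a pathway with an empty up or down side is unscorable and is
excluded with a logged reason. Pathways whose score distribution differs
across the four stages (one-way ANOVA, raw p < 0.05) are the features
handed to the classifier.

## Classification

Stages I/II collapse to *early*, III/IV to *advanced*. The classifier is
a radial-kernel SVM on the screened pathway scores, evaluated by
stratified fivefold cross-validated ROC — stratified because the advanced
class is typically the small one (109 of 508 in the motivating cohort)
and unstratified folds can lose it. Hyperparameters are grid-searched by
inner CV inside each training fold (`C ∈ {0.1, 1, 10, 100}`,
`gamma ∈ {0.01, 0.1, 1/d, 1}`; a literal gamma of zero would make the
kernel constant, so the scale-free `1/d` anchors the grid instead), and
`rfe_step` optionally re-runs feature elimination on the training fold
alone, keeping the evaluation leak-free. The report also carries the
resubstitution accuracy of an untuned model for comparison with
training-set-only protocols.

Recursive feature elimination ranks a feature by the drop in CV accuracy
when it is left out, removing the `step_k` least important per iteration.
The returned subset is the one with the best mean CV accuracy (ties to
the smaller set), per the procedure's definition — but note that CV
accuracy plateaus over uninformative features, so this subset often
carries harmless passengers. The elimination *order* is the sharper
signal: `rfe_top_features(rfe, k)` returns the k last survivors, and that
is the quantity we validate against planted truth.

## The synthetic cohort generator

`generate_cohort()` realises the structure the analysis assumes, with
known truth. Control-stage expression is i.i.d. N(0, 1); each planted
pathway is an equicorrelated block (pairwise ρ = 0.7 by default, via a
shared factor) whose up-genes gain `effect_size` SD per stage step while
its down-genes move oppositely at half that rate (`balance_drift = 0.5`).
The attenuation is essential: a perfectly symmetric drift keeps
`A(P)` flat across stages and the pathway undetectable by design, whereas
attenuated down-drift makes the balance tip monotonically — the planted
signature the screen must find. Null pathways hold independent null genes
as negative controls. Missing cells are placed uniformly (2% default),
and `plant_balance_profile()` can override any pathway's per-stage
schedule to produce flat, rising or falling expected imbalance. Defaults
(1,000 genes, 20 pathways × 25 genes, 4 planted, effect 1.5 SD, 50
samples per stage) are the package's standard validation conditions.

What the generator does *not* emulate: count noise (negative binomial),
batch effects, correlated nulls, annotation error. Passing the planted
recovery checks therefore demonstrates the chain is correct and
well-calibrated, not that real cohorts will classify at the same
accuracy.

## Numerical choices and problem sizes

Quantiles are type 7; SDs use n−1; correlations exactly at ±0.5 form no
edge; the score floor is 1e-8; stage effects are linear in stage index by
default (the cleanest monotone recovery target). All randomness flows
from explicit seeds; identical seeds reproduce manifests byte for byte.
The shipped validation runs use cohorts of 200–2,000 genes and 100–200
samples — large enough for stable calibration (e.g. type-I rates at 2,000
null genes are estimated with SE ≈ 0.005) while keeping the full suite
under a minute on one CPU.

## Worked example

```{r example, eval = FALSE}
sc <- generate_cohort(synthetic_spec(), seed = 1)
pl <- run_pipeline(sc$expression, sc$cohort, sc$gene_sets, seed = 1)
print(pl)
glance(pl$results$report)
autoplot(pl$results$report)        # per-fold ROC curves
plot_score_by_stage(pl$results$scores, sc$cohort)
```

## Known limitations

The any-significant-pair stage assignment is one of several defensible
rules; the enrichment background is configurable but results are
sensitive to it; direction labels estimated on few non-control samples
are noisy coin flips for null genes (harmless — both sides stay
populated, scores stay calibrated); and the pipeline aborts, by design,
when a gate (ANOVA, enrichment, screen) empties — a cohort with no signal
produces a named error at the first empty gate rather than a chance-level
classifier.
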