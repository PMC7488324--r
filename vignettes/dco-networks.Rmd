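---
title: "Driver co-occurrence networks: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Driver co-occurrence networks: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dconet)
library(dplyr)
```

`dconet` predicts per-treatment drug response from binary driver-alteration
profiles. This vignette explains the statistical machinery, the tunable
parameters and their defaults, what the synthetic-cohort generator does and
does not emulate, and the numerical and design choices a maintainer should
know about. It states no empirical result beyond what the package's tests
and acceptance script themselves compute.

## The response phenotype

Tumor-volume trajectories are summarised per (model, treatment) by the
percent change from baseline, $\Delta Vol_t = (V_t - V_i)/V_i \cdot 100$.
Two summaries feed the volume-based response classification:
*best response* (the minimum $\Delta Vol_t$ over observations at day 10 or
later) and *best average response* (the minimum, over the same eligible
days, of the running mean of $\Delta Vol$ across all post-baseline
observations up to that day). Classes apply in fixed order — CR
(best < −95 and average < −40), PR (best < −50 and average < −20), SD
(best < 35 and average < 30) — and anything unmatched is PD. PD samples
are non-responders; SD/PR/CR are responders. Two conventions are worth
making explicit because the running-mean window is otherwise ambiguous:
the baseline's $\Delta Vol = 0$ never enters a mean, and observations
before the evaluation cutoff contribute to later running means but are
never themselves candidate minima (the cutoff qualifies the evaluation
time, not the data). A pair such as best = 40, average = 20 matches
neither the SD conjunction nor the PD conjunction; because classes apply
in order with PD last, it falls through to PD. Caliper measurements
convert to volumes as $l \cdot w^2 \cdot \pi/6$ with $l \ge w$ enforced.

Arms qualify for modeling only with at least 5 samples per response
group (`min_group = 5`); smaller arms carry too little inter-individual
heterogeneity to train on.

## Differential drivers: the beta-inequality probability

For a gene altered $k_1$ times among $n_1$ responders and $k_2$ among
$n_2$ non-responders, the group rates get independent
$\mathrm{Beta}(k + a,\; n - k + b)$ posteriors and the package computes

$$P(p_1 > p_2) \;=\; \int_0^1 f_{\mathrm{Beta}(k_1+a,\,n_1-k_1+b)}(x)\,
F_{\mathrm{Beta}(k_2+a,\,n_2-k_2+b)}(x)\,dx$$

by adaptive quadrature, with the integrand evaluated through log
densities and the interval split at both posterior means so the
quadrature sees each factor's mass (absolute tolerance $10^{-10}$;
exactly symmetric evidence short-circuits to exactly 0.5). The prior is
uniform, $a = b = 1$, and exposed as an argument: nothing in the
procedure pins down a particular pseudo-count choice, and the selection
is insensitive to it at the default thresholds. Results are memoised
within a session because the same small-count combinations recur
thousands of times during pair selection.

Gene sets per arm: responder-enriched ($P > 0.95$ plus altered at least
twice and at rate $\ge 5\%$ among responders), non-responder-enriched
(symmetric), and general ($\max(P, 1-P) > 0.95$, two-sided, with the
count/rate filters applied in whichever group is enriched). No
multiple-testing correction is applied — the method uses fixed
probability thresholds, not FDR control, at this stage; the permutation
null at the pair stage and the empirical type-I checks in the test suite
are the guard rails.

## Driver pairs: the margin-preserving rewiring null

Marginal alteration rates alone generate spurious co-occurrence, so
pairs are judged against permuted matrices with *exactly* the original
row and column sums, produced by checkerboard swaps (two altered entries
$(s_1, g_1), (s_2, g_2)$ with both opposite corners unaltered exchange
columns). Defaults: 1000 permutations, a swap budget of 10 successful
swaps per altered entry (comfortably past the usual mixing
recommendation for bipartite rewiring), both configurable. The swap loop
is compiled (Rcpp) and uses R's RNG, so permutations are reproducible
under a seed. Marginal preservation is asserted, not assumed, on every
permutation.

The full arm matrix is rewired once and the same permutations are reused
for the responder and non-responder restrictions. The alternative —
re-rewiring within each group — would decouple the two groups' nulls and
make the differential statistic incomparable across them; reusing one
permutation set keeps a permuted sample's driver load identical in both
restrictions. Restricting a full-matrix permutation to a sample subset
preserves that subset's per-sample loads exactly (row sums are
per-sample), though per-gene counts within the subset vary — which is
precisely the variation the null needs.

Per candidate pair (both genes altered at least twice in the arm; pairs
failing the count filter can never be selected, so this bounds compute
without changing results):

- *tendency*: the mean over permutations of the beta-inequality
  probability that the observed co-alteration count exceeds the permuted
  one, computed over all arm samples (general scope) and within each
  group;
- *differential co-occurrence*: the beta-inequality probability
  comparing responder vs non-responder co-alteration rates, plus the
  95th percentile of the same probability computed on each permuted
  matrix split by the true labels.

Selection mirrors the gene stage: general pairs need tendency > 0.95
plus count/rate filters in the arm; group-specific pairs need tendency
within the group, differential probability > 0.95, that probability
above its permutation-null 95th percentile, and the count/rate filters
within the group.

## Networks and classifiers

Per arm, three networks (General/Resp/NonResp): nodes are the flavor's
differential drivers and the genes of its selected pairs (sources
labeled `DiffD`, `DiP`, or `both`), edges the pairs; no self-loops, and
every edge endpoint is a node by construction. The downstream feature
matrix has exactly the sorted node genes as columns — node-set equality
is asserted in tests. When gene coordinates are available, each edge is
annotated as genomically `linked` when both genes share a chromosome arm
(with the basepair gap also reported), separating co-selection from
co-amplification-style linkage in interaction analyses.

Classifiers are gradient-boosted trees, 100 trees per model, with the
tuning grid depth 1–7 × learning rate {0.2, 0.4, 0.6, 0.8, 1} × L2 leaf
penalty {1, 3, 5, 10} searched by 30 repeats of stratified 5-fold
cross-validation on AUC, ties broken toward the simpler model (smaller
depth, then smaller learning rate, then larger penalty). The backend
contract is any tree-boosting implementation with class probabilities,
per-feature importances, per-sample additive explanations and pairwise
interactions; the package uses xgboost, single-threaded for
reproducibility, with labels encoded 1 = response, −1 = non-response and
a fixed base score of 0.5 so the margin scale is stable. Edges are
deliberately not features: depth-≥2 trees model pairwise interactions
natively. Tuning is done once per arm with the inner 5-fold loop; the
outer leave-one-out loop then measures generalisation (a fully nested
variant would multiply cost by n and is not the default). By default the
pipeline skips tuning and uses depth 3, learning rate 0.4, penalty 3 —
sensible mid-grid values for 0/1 features at cohort sizes of tens to
hundreds — since the tuned optimum on such data is flat; `tune = TRUE`
restores the full search.

LOOCV yields out-of-fold class probabilities, the balanced accuracy
(sensitivity + specificity)/2, and mean per-feature importances (used to
prune non-contributing genes from the networks). The three flavor
predictions combine per sample as a balanced-accuracy-weighted score:
the general model contributes with the sign of its prediction, the
responder-network model only when it predicts response, the
non-responder-network model only when it predicts non-response; an
untrainable flavor (empty network) contributes zero. The score's class
probabilities are read as the general model's probability of response
($P_s$) and of non-response ($P_r$); the combined score is bounded by
$BAcc_{Gen} + \max(BAcc_{Resp}, BAcc_{NonResp})$, and its sign is the
predicted class (zero = no call). The biomarker baseline scores each
sample by the signed, balanced-accuracy-weighted sum of its altered
response and non-response biomarker genes, with per-gene accuracies
computed on the full arm — the baseline is a comparator describing each
biomarker's standing in the arm, not a cross-validated product — and
duplicate catalog records collapsed first. Model variants (`dco`,
`biomarkers`, `dco+biomarkers`) run the identical pipeline on different
feature columns.

## Exact Shapley explanations

Per-sample, per-gene contributions are computed by the polynomial-time
tree-Shapley path algorithm, implemented in the package in double
precision directly from the parsed tree structures, with absent features
marginalised by cover-weighted averaging. One numerical subtlety
motivates this: per-node covers stored by the boosting backend are
rounded individually, so the two child covers need not sum exactly to
the parent's; the implementation normalises branch fractions by the
children's sum, which makes the additivity identity
$base + \sum_j \phi_j = \text{margin}$ hold to machine precision
(asserted at $10^{-6}$, observed around $10^{-15}$ to $10^{-9}$). The test
suite validates the fast algorithm against exhaustive subset enumeration
on models with up to 4 features. Interaction strengths (mean absolute
pairwise Shapley interaction) come from the backend and are
cross-checked against enumeration at a float32-appropriate tolerance;
status-stratified summaries then report each gene's mean contribution
within the four alteration categories of a pair (both, only A, only B,
neither), with empty categories reported as missing.

The overlap between network genes and annotated biomarkers is tested
with Fisher's exact test on the 2×2 table over the eligible drug–gene
universe; both the conditional-MLE odds ratio (what `fisher.test`
returns) and the sample odds ratio $ad/bc$ are reported since the two
differ at small counts and the method's published summary does not say
which convention it used. The odds ratio is invariant to swapping the
roles of the two association sets.

## Continuous outcomes

For treatment-duration endpoints, patients split into extreme tertiles:
cutoffs are the boundary order statistics ($s_{(\lfloor n/3 \rfloor)}$
and $s_{(n - \lfloor n/3 \rfloor + 1)}$), patients tied with a cutoff
resolve to the middle group, at least 9 patients are required, and an
all-tied cohort is entirely unlabeled (with a warning). The shortest
third are non-responders, the longest third responders, the middle third
unlabeled; the standard pipeline runs on the extremes only, and the
final models score everyone, middle third included — those patients
never enter a training fold (asserted in tests).

Confidence thresholds on the combined score are optimised independently
per side against a maximum false discovery rate (default 30%) computed
on the labeled LOOCV scores only: the response threshold is the least
extreme *positive* score whose predicted responders contain at most that
fraction of true non-responders, and symmetrically below zero for
non-response. Restricting candidates to the matching sign keeps the two
call regions disjoint and consistent with the score's sign convention; a
side with no attainable threshold returns a sentinel rather than a
forced call. Coverage is monotone in the bound (tested). Unlabeled
patients count toward coverage but never toward FDR. An optional
upstream filter excludes patients whose biopsy postdates therapy start
by more than 60 days.

Predicted groups are evaluated with Kaplan–Meier medians (`NA` = not
reached), the two-group log-rank test, and a Cox proportional-hazards
fit of the event hazard on the continuous score. Durations are treated
as right-censored via the event flag in the survival evaluation;
tertile labeling itself uses raw durations, which is the appropriate
reading when duration-on-therapy is itself the clinical-benefit measure.

## The synthetic cohort

The generator's defaults are the package's reference study condition: 40
responders vs 40 non-responders, 120 genes, background per-gene
alteration rates drawn from Beta(2, 23) (mean 8%, the frequency range of
recurrent drivers), three planted differential genes at rates 0.6 vs
0.05, and two planted responder-specific pairs driven by a latent
Bernoulli factor firing in 35% of responders vs 2% of non-responders
(both genes altered when it fires, plus 3% independent background). The
latent-factor construction inflates co-occurrence while keeping
marginals configurable — exactly the quantity the pair stage tests.
Tumor volumes follow
$V(t) = V_0\, e^{(g - e \cdot \text{responder})t}$ with growth
$g = 0.06$/day, effect $e = 0.12$/day, measurements every 4 days to day
28, and 5% lognormal measurement noise (baseline measured exactly), so
genotype-responders regress to PR/CR and the rest progress. Survival
times are Weibull (shape 1.2, scale 6 months for the low-risk group)
with a hazard ratio of 2.5 against genotype non-responders and 15%
independent uniform censoring. Everything is deterministic given the
mandatory seed.

What the generator does *not* emulate: mutational signatures, copy-number
segment structure, tissue covariates, panel-dependent gene coverage, or
correlated background genes. Passing tests on these cohorts demonstrate
that the statistics recover the structures they target at realistic
sizes and type-I behaviour on independent backgrounds — not that the
method's effect sizes transfer to any particular real cohort.

One calibration note: a *single* binary marker at rates 0.6 vs 0.05 has
a Bayes-optimal balanced accuracy of $(0.6 + 0.95)/2 = 0.775$, so no
classifier on that gene alone can reliably exceed 0.8. The package's
"separable arm" checks therefore use the default three-planted-gene
cohort (Bayes level ≈ 0.89), and a dedicated property test verifies that
single-gene LOOCV accuracy tracks its 0.775 Bayes level rather than
exceeding it.

## Problem sizes and determinism

The default pipeline (1000 permutations, LOOCV over 80 samples) runs in
minutes on one CPU. The test suite and the acceptance script scale
simulations to 100–200 permutations and 25–40 genes per cohort — chosen
so the whole suite exercises 20-seed (and one 50-seed) replications in a
few minutes — while keeping the planted effect sizes, thresholds and
group sizes of the reference condition. Selection frequencies are
insensitive to the permutation count at these scales; the permutation
count mainly sets the resolution of the null percentile. All stochastic
steps take explicit seeds; per-arm and per-permutation seeds derive from
one master seed, and two runs from the same configuration are
byte-identical (tested).

## Known limitations

- Pair statistics price in marginal rates but not population structure;
  a strongly clustered cohort (e.g. two tissue types with different
  alteration spectra) can still produce co-occurrence that the rewiring
  null does not explain. The method is deliberately tissue-agnostic.
- Balanced accuracy on small arms is noisy; the 0.6 high-confidence
  cutoff is a screening convention, not a guarantee.
- The FDR of the clinical thresholds is an in-sample LOOCV estimate on
  tens of patients; its sampling error is material and no correction for
  the threshold search is applied.
- Beta-inequality selection applies fixed probability cutoffs per gene;
  with thousands of genes, the expected number of false selections grows
  linearly (the null-cohort tests quantify this at the default sizes).
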