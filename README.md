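# dconet

Driver co-occurrence networks for pharmacogenomic response prediction.

Tumors respond to a drug — or fail to — as a function of the particular
combination of driver alterations they carry, yet annotated biomarkers
cover only a fraction of patients. `dconet` addresses this gap for
cohorts (typically patient-derived xenograft screens, or clinical series
with treatment-duration follow-up) in which each sample has a binary
driver-alteration profile and a per-treatment response label. It infers,
for every treatment, **driver co-occurrence (DCO) networks** that
discriminate responders from non-responders, trains gradient-boosted
classifiers on the network genes, combines and explains their
predictions, and adapts the whole procedure to continuous
progression-free-survival outcomes.

## The method

Given a treatment arm with `n_r` responders and `n_n` non-responders
(both at least 5), over a binary sample-by-gene alteration matrix:

1. **Differentially altered drivers (DiffD).** Each gene's alteration
   rate per group is modeled as a beta posterior over the observed
   counts; the gene is responder-enriched when
   `P(p_resp > p_nonresp) = ∫ f_Beta(k_r+a, n_r-k_r+b)(x) · F_Beta(k_n+a, n_n-k_n+b)(x) dx > 0.95`,
   computed analytically by quadrature, with the symmetric rule for
   non-responder enrichment and a two-sided rule for the general set.
   Selected genes must additionally be altered more than once and at a
   rate of at least 5% in the enriched group.

2. **Co-occurring driver pairs (Ps).** Excess co-occurrence is judged
   against a null that preserves every sample's driver load and every
   gene's alteration frequency, generated by checkerboard-swap rewiring
   of the alteration matrix (1000 permutations by default). A pair shows
   a co-occurrence *tendency* when the average probability that its
   observed co-alteration rate exceeds the permuted one (same beta
   inequality) is above 0.95. Group-specific pairs must further show
   `P(co-rate_resp > co-rate_nonresp) > 0.95`, and that probability must
   exceed the 95th percentile of its own permutation-null distribution.

3. **DCO networks.** For each arm, three networks (General, Resp,
   NonResp): nodes are the flavor's differential drivers plus the genes
   of its selected pairs; edges are the pairs. Exported as GraphML (for
   Cytoscape) or SIF.

4. **Classifiers.** One boosted-tree model (100 trees; xgboost backend)
   per network flavor on the binary node-gene features — edges are not
   encoded because tree ensembles model pairwise interactions natively.
   Each model is evaluated by leave-one-out cross-validation (LOOCV) and
   its balanced accuracy `BAcc = (sensitivity + specificity)/2` weights
   the combined per-sample score

   ```
   wComb = BAcc_Gen · (I{Gen=+1}·P_s − I{Gen=−1}·P_r)
         + BAcc_Resp · I{Resp=+1}·P_Resp
         − BAcc_NonResp · I{NonResp=−1}·P_NonResp
   ```

   whose sign is the predicted class. A gene-level biomarker baseline
   uses `wComb_bmk = Σ_{i∈Resp} BAcc_i·s_i − Σ_{j∈NonResp} BAcc_j·s_j`.

5. **Interpretation.** Per-sample, per-gene Shapley contributions are
   computed exactly in double precision from the parsed tree ensemble
   (additivity holds to machine precision), pairs are ranked by the
   backend's native interaction strength, and the overlap between DCO
   genes and annotated biomarkers is tested with Fisher's exact test.

6. **Clinical adaptation.** For continuous treatment durations, the
   cohort is split into extreme tertiles (longest-benefit third =
   responders, shortest = non-responders, middle unlabeled), the same
   pipeline runs on the extremes, and confidence thresholds on `wComb`
   are chosen per side to bound the false discovery rate (30% by
   default) in the labeled LOOCV scores. Predicted groups are compared
   by Kaplan-Meier medians, the log-rank test, and a Cox fit of hazard
   on the continuous score.

A synthetic-cohort module simulates all required inputs with planted
structure (differential genes, latent-factor co-occurring pairs,
genotype-linked exponential tumor growth, genotype-linked Weibull
survival), so the entire pipeline is testable without external data.

## Worked example

```r
library(dconet)

cfg <- cohort_config(n_resp = 40, n_nonresp = 40, n_genes = 60, seed = 11)
sim <- simulate_cohort(cfg)

# mRECIST calls from the simulated tumor-volume trajectories
calls <- call_response(sim$volumes)
table(calls$mrecist_class)
#> PD PR
#> 40 40

# full pipeline on one treatment arm
responses <- dplyr::mutate(sim$response, treatment_id = "T1")
res <- run_pipeline(sim$matrix, responses,
                    config = pipeline_config(n_permutations = 200), seed = 7)

res$treatments$T1$networks$Resp
#> <dco_network> treatment T1, Resp flavor: 9 nodes, 12 edges

glance(res$treatments$T1$bundle)
#> # A tibble: 1 × 8
#>   treatment_id variant n_resp n_nonresp bacc_general bacc_resp bacc_nonresp
#> 1 T1           dco         40        40        0.888     0.888           NA
```

The responder network recovers the planted structure: all three planted
differential genes (true rates 0.6 vs 0.05) and both planted pairs
(G004–G005, G006–G007) sit among its nine nodes, and the combined LOOCV
balanced accuracy is 0.887. Exact Shapley explanations point at the
planted drivers:

```r
b <- res$treatments$T1$bundle
X <- build_features(sim$matrix, b$flavors$General$feature_genes)
ex <- explain(b, X, flavor = "General")
head(dplyr::arrange(ex, dplyr::desc(abs(contribution))), 3)
#>   sample_id gene  contribution
#> 1 S004      G001          2.77
#> 2 S006      G001          2.77
#> 3 S079      G001          2.77

head(rank_interactions(b$flavors$General$model, X), 2)
#>   gene_a gene_b strength
#> 1 G001   G003     0.114
#> 2 G001   G002     0.102
```

A positive contribution pushes the sample toward the predicted-response
side on the log-odds scale; `strength` is the mean absolute pairwise
Shapley interaction. The biomarker-overlap test on published aggregate
counts (48 shared associations among 1856 network-captured and 359
annotated, universe 30,687):

```r
biomarker_overlap_fisher(48, 359, 1856, 30687)
#>   odds_ratio sample_odds_ratio     p_value ...
#> 1       2.43              2.43 0.000000273
```

A command-line wrapper over the same functions ships in
`inst/cli/dconet.R` (subcommands `simulate`, `call-response`,
`build-dco`, `train`, `predict`, `explain`, `clinical`, `evaluate`).

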