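# crowdcurate

Crowdsourced validation of distantly supervised biomedical relation
corpora.

Distant supervision labels a phenotype–gene sentence *known* when the pair
sits in a knowledge base and *unknown* otherwise — a silver standard whose
"unknown" class mixes genuinely false relations with relations the
knowledge base has not caught up with, on top of entity-tagging errors.
crowdcurate is for corpus builders who want to clean such a corpus with
paid microtask crowdsourcing: it turns a relation corpus into
classification task batches, ingests the platform's batch-results CSV,
collapses multi-worker votes into labels with a majority-consensus rule,
measures inter-rater agreement, models campaign cost and worker behaviour,
and merges the adjudicated partitions into a new corpus release with
class-weight suggestions for downstream relation-extraction systems. A
synthetic campaign generator with per-worker confusion-matrix reliability
makes the whole pipeline testable without touching a crowd platform.

## The core rules

**Consensus voting.** Each relation's `m` votes over
{true, false, exclude} are adjudicated as:

1. `EXCLUDE` if `n_exclude ≥ m/2` ("at least half");
2. else `TRUE` if `n_true > m/2` (a strict majority);
3. else `FALSE` — the default label, because false relations are the
   harder judgment and a wrong true label hurts downstream training more.

A single vote passes through unchanged (the single-judgment task).
Both steps are policy-configurable (`adjudication_policy()`).

**Agreement.** Fleiss' kappa for complete designs,
`κ = (P̄ − P̄ₑ)/(1 − P̄ₑ)` with `Pᵢ = (Σⱼ n²ᵢⱼ − n)/(n(n−1))` and
`P̄ₑ = Σⱼ p²ⱼ`, and nominal Krippendorff's alpha from the coincidence
matrix, `α = (A_o − A_e)/(1 − A_e)`, tolerant of ragged rater counts.
Both are reported side by side with their deviation and Landis–Koch
qualitative bands.

**Consensus quality.** For homogeneous binary workers with per-vote
accuracy θ and odd `a` assignments, the exact probability that consensus
recovers the truth is the binomial tail `Σ_{k>a/2} C(a,k) θᵏ(1−θ)^{a−k}`
(`expected_consensus_accuracy()`), the quantitative case for buying seven
assignments instead of one.

## Worked example

Simulate a campaign over the multi-judgment partition of a 2000-relation
synthetic corpus and adjudicate it:

```r
library(crowdcurate)

corpus <- synthetic_corpus(n_known = 620, n_unknown = 1380, seed = 7)
parts <- partition_corpus(corpus, fraction = 0.7, seed = 7)
parts$part2
#> <relation_corpus> 600 relations
#>   original labels: KNOWN=188 UNKNOWN=412

camp <- sample_campaign(
  campaign_config(n_items = n_relations(parts$part2), n_workers = 33,
                  assignments_per_item = 7, seed = 8)
)
camp$votes$relation_id <- parts$part2$instances$relation_id[
  as.integer(substr(camp$votes$relation_id, 2, 6))]

adj <- adjudicate_corpus(parts$part2, camp$votes)
label_distribution(adj$corpus)
#> true 326 (54.33%)  false 108 (18.00%)  excluded 166 (27.67%)  kept 434 (72.33%) of 600

agreement_report(camp$votes, groups = list(workers = "CROWD"))
#>   group   n_items raters_per_item fleiss_kappa krippendorff_alpha deviation qualitative
#> 1 workers     600               7        0.405              0.405  0.000142 fair to moderate

cost_total(cost_config(n_relations(parts$part2), 7, reward = 0.02, base_fee = 0.01))
#> [1] 126
```

The label distribution says 326 of the 600 relations (54.33% of the task)
reached a true majority, 166 (27.67%) were voted out as annotation errors,
and 434 relations (72.33%) survive into a release. The agreement report
shows the two coefficients nearly coincide (deviation 1.4e-4), landing on
the fair/moderate boundary — the mixed-reliability default worker pool at
work — and rating the 600 relations seven times at $0.02 reward + $0.01
fee costs $126.00.

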