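---
title: "Validating a distantly supervised relation corpus with paid crowdsourcing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a distantly supervised relation corpus with paid crowdsourcing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdcurate)
```

## The problem

Distant supervision builds relation-extraction corpora by aligning text with
a knowledge base: a sentence mentioning a human phenotype and a gene is
labelled *known* if the pair is in the knowledge base and *unknown*
otherwise. The result is a silver standard — cheap, large, and noisy in a
specific way: the *unknown* label conflates genuinely false relations with
relations the knowledge base simply has not recorded yet, and the named-
entity tagging itself makes mistakes that no label can repair.

crowdcurate implements a validation pipeline for such corpora using paid
microtask crowdsourcing. Workers are shown one sentence with the two entity
mentions emphasised and choose among three options: the relation is *true*,
the relation is *false*, or the instance is *wrongly labelled* (an entity
tagging or sentence-format error) and should be excluded. The pipeline
covers task construction, result ingestion, vote adjudication, inter-rater
agreement, campaign cost and worker statistics, and the assembly of a
revised corpus release — plus a synthetic campaign generator so every stage
can be exercised and tested end to end without any crowd data.

## The consensus voting scheme

Each multi-judgment relation receives `a` votes (the reference design uses
`a = 7` distinct workers, plus optionally an on-site rater for 8). The
adjudication rule, applied per relation to the vote counts
(`n_true`, `n_false`, `n_exclude`) out of `m` total votes:

1. **Exclusion first.** If `n_exclude >= m / 2` — at least half the votes —
   the relation is excluded. Errors flagged by half the raters are not worth
   keeping under either remaining label.
2. **True needs a majority.** Otherwise the relation is `TRUE` only if
   `n_true > m / 2`.
3. **Default false.** Anything else — ties, bare pluralities, three-way
   splits — is `FALSE`.

The default label is false because false relations are the harder judgment:
when raters cannot agree, a false label is the safer outcome for downstream
learning (a false positive in training damages a relation-extraction model
more than a false negative). A single-vote relation degenerates to
passing the vote through, which is exactly how the single-judgment task is
adjudicated.

Step 2 was a genuinely open design point. The source procedure is described
as *majority* consensus with a default of false "with no agreement", and its
worked example labels a 3-true / 2-false / 3-exclude split false even though
true holds a bare plurality over false; we therefore require an absolute
majority for true. The alternative reading — true wins whenever it strictly
beats false, with exclude votes diluting the contest — is retained as the
`PLURALITY_OVER_FALSE` switch of `adjudication_policy()`, and the exclusion
threshold is likewise a policy parameter (default 1/2). The two rules agree
on every odd-sized binary vote set, so none of the consensus-accuracy
analysis below depends on the choice.

Useful properties, both tested exhaustively over all count triples with
`m <= 9`: converting any vote to an exclude vote can never un-exclude a
relation, and a true/false tie without an exclusion majority is always
false.

## Inter-rater agreement

Two chance-corrected coefficients are computed over the items × categories
count table of a rater group:

* **Fleiss' kappa** for complete designs (every item rated by the same
  `n >= 2` raters): per-item agreement is the fraction of concordant rater
  pairs, `P_i = (Σ_j n_ij² − n) / (n(n−1))`, chance agreement is
  `P_e = Σ_j p_j²` from the pooled category proportions, and
  `κ = (P̄ − P_e) / (1 − P_e)`.
* **Krippendorff's alpha** (nominal) from the coincidence matrix: items with
  fewer than two ratings are ignored, each remaining item contributes its
  ordered rating pairs weighted by `1/(m_i − 1)`, and
  `α = (A_o − A_e) / (1 − A_e)` with `A_e` computed from the pooled totals
  `n_c(n_c − 1) / (n(n − 1))`. Alpha tolerates ragged designs, which kappa
  does not.

When every rating falls into a single category, chance agreement is 1 and
neither coefficient exists; both functions signal a classed condition
(`crowdcurate_undefined_agreement`) rather than silently returning `NaN`,
and `agreement_report()` converts that into an explicit `"undefined"`
status.

Reporting both coefficients is deliberate: a small `|α − κ|` supports an
unbiased estimate, and on complete designs the two converge as the item
count grows (the test suite requires `|α − κ| <= 0.01` at 1000 simulated
items). Neither coefficient's sampling assumptions exactly match a crowd
design in which a small worker pool rates overlapping subsets of items —
kappa assumes a fixed rater panel, alpha assumes exchangeable raters — so
rather than attempting a corrected estimator, `agreement_report()` surfaces
the overlap diagnostics (distinct raters, mean ratings per rater) alongside
the coefficients. Qualitative interpretation uses the Landis–Koch bands
(poor below 0, slight to 0.20, fair to 0.40, moderate to 0.60, substantial
to 0.80, almost perfect above); a value within 0.005 of a band boundary is
reported with both adjacent bands ("slight to fair") because the cutoffs
are conventional, not substantive.

## Costs, work times and worker volume

`cost_total()` computes `tasks × assignments × (reward + fee)` in exact
integer cents. The platform fee is modelled as the already-rounded billed
fee: microtask platforms round the per-assignment fee up to the cent, so
the sub-cent surcharge for restricting tasks to high-performing ("Masters")
workers (default $0.001) is absorbed whenever the base fee sits on a cent
boundary, and only pushes the fee to the next cent otherwise. The reference
campaign — 5574 single-assignment tasks and 2389 seven-assignment tasks at
$0.02 reward + $0.01 fee — totals $167.22 and $501.69.

Work-time statistics use a cutoff (default 50 s, with the boundary kept:
`work_time <= 50`). Times beyond the cutoff are mid-task breaks — real
exports show maxima above 11 hours — not slow judgments, so the cutoff
applies to descriptive statistics only. Adjudication always consumes the
unfiltered ledger; a pipeline test constructs a vote set where filtering
would flip the consensus label to pin this down. The histogram uses
1-second bins over `[0, cutoff]`, and assignments per worker is
rounded half-up to an integer (22,255 assignments over 64 workers → 348).

All table-style percentages are rounded half-up to two decimals against the
*original* task total, so the excluded share of a task and the kept share
sum to 100% with at most rounding slack. Half-up rounding (rather than R's
round-half-even) matches how published tables are rounded by hand.

## Release building and export

`build_release()` merges two adjudicated partitions, drops excluded
relations, and records a manifest. Abstract and annotation counts are
recomputed from the kept relations only: abstracts as distinct PubMed ids,
and entity annotations as distinct (pmid, identifier) mentions — an
annotation surviving only in excluded relations is not counted. The
manifest also reports the recomputed exclusion rate; on the reference
counts this is 1836/7963 = 23.06%.

`export_splits()` writes train/test rows with the two mentions replaced by
typed placeholders (`@PHENOTYPE$`, `@GENE$` — the common input convention
of sentence-level relation-extraction systems; configurable), refuses
overlapping or empty splits, and attaches class-weight metadata: the full
rebalancing multiplier `n_true / n_false` (14.9 on the reference training
set) and the chosen weight, default 5, following the practice of picking a
value between 1 and the full multiplier to avoid over-correcting the
natural imbalance.

## What the synthetic generator emulates — and what it does not

`sample_campaign()` draws, per item, a latent label from a configurable
distribution, a set of `a` *distinct* workers uniformly from the pool (the
platform guarantee), one vote per worker from that worker's 3×3 confusion
matrix conditional on the latent label, and a work time. Defaults encode
the reference study conditions: 7 assignments per item from a 33-worker
pool, and a latent mix of 53.6% true / 14.4% false / 32% exclude-worthy
(the expert-judged proportions of the multi-judgment task). The work-time
model is a lognormal with `meanlog = 2.4`, `sdlog = 0.6` (mode ≈ 11 s, mean
≈ 13 s, matching the observed ~13 s average) plus a rare break component
(probability 0.005, exponential with mean 3000 s) reproducing the heavy
upper tail. No per-worker reliability estimates exist for the real
campaign, so `default_worker_pool()` uses placeholder accuracies drawn from
{0.6, 0.8, 0.95} with a 5% malicious fraction answering uniformly at
random; these are stated as placeholders, not calibrated values.

Seeding is split per item from the master seed, so any single item's draws
are reproducible in isolation and the whole campaign is reproducible
end to end.

The generator deliberately does *not* emulate: worker learning or fatigue
over a session, item-difficulty heterogeneity (confusion depends only on
the latent label, not the sentence), correlated errors between workers, or
uneven workload distribution beyond what uniform assignment induces. A
passing simulation therefore shows that the pipeline's arithmetic and rule
application are correct under the stated generative model — it does not
show that real crowds behave like the model, and the agreement values of a
real campaign (which reflect sentence complexity and worker quality) are
not recoverable from simulation.

`expected_consensus_accuracy()` is the analytic companion: for homogeneous
binary workers with per-vote accuracy θ and odd `a`, the probability that
consensus recovers the latent label is the binomial upper tail
`Σ_{k > a/2} C(a, k) θ^k (1−θ)^{a−k}` — 0.9667 at θ = 0.8, a = 7. It is
non-decreasing in `a` and strictly beats a single worker for θ ∈ (0.5, 1),
which is the quantitative argument for paying for seven assignments rather
than one or three. `recover_parameters_check()` closes the loop: it
simulates, adjudicates, and requires the empirical accuracy to fall inside
the exact 95% binomial interval around the enumeration value, and compares
empirical κ/α against an independent re-simulation at 10× the item count.

## Numerical and format choices

* Character offsets are 0-based, half-open (`[start, end)`), validated
  against the sentence on construction and on read.
* The corpus serialisation is a 13-column UTF-8 TSV with no quoting;
  literal tabs/newlines in sentences are rejected at validation rather
  than escaped, keeping files diff-able.
* The 70/30 partition is a uniform shuffle under a stated seed taking the
  first `floor(f · N)` rows (5574/2389 at N = 7963); the observed source
  proportions (31.41% vs 30.51% known) indicate the original split was not
  stratified, so stratification is available but off by default.
* Results ingestion accepts the platform's batch-results dialect (`HITId`,
  `WorkerId`, `WorkTimeInSeconds`, `Answer.*`, `Input.*`) and a simplified
  internal dialect; the on-screen answer strings are mapped through a
  configurable normalisation table. Rows without a worker id are kept but
  counted (real exports contain such rows), and duplicate
  (relation, worker) pairs are reported as invariant violations rather
  than silently dropped.
* Exclusion-threshold comparisons use a small epsilon
  (`n_exclude >= t·m − 1e-9`) so that exact fractions like 4/8 are not lost
  to floating-point noise.

Test and simulation sizes (1000 items for the convergence property, 5000
for the chance-agreement property, 2000 for the consensus-accuracy
interval) were chosen so that the stated tolerances (0.01, 0.02, the 95%
CI) have comfortable Monte-Carlo margins while the whole suite stays fast.

## Known source discrepancies

Several published numbers are internally inconsistent and are handled
explicitly rather than reproduced blindly:

* One passage says 7983 relations where the corpus tables give
  2480 + 5483 = 7963; the tables are arithmetic-consistent, so 7963 is
  treated as authoritative.
* 5574 + 2389 × 7 = 22,297 expected assignments versus 22,255 reported
  HITs; the gap is not explained by the six unattributed rows alone, so
  both numbers are reported where relevant and neither is "corrected".
* The multi-judgment task's "77 sentences per worker" cannot be derived
  from the printed totals (2389/33 ≈ 72.4; 16,723/33 ≈ 506.8); the
  summaries report the computed value.
* A stated 16.46% exclusion rate conflicts with the count-level arithmetic
  (1836/7963 = 23.06%); the release manifest reports the recomputed rate.
* The published release's abstract/annotation counts (1921/1943/2207)
  depend on the real corpus text and cannot be reproduced from counts
  alone; the counting *rules* are implemented and tested on fixtures.

## Limitations

The package validates and rebuilds corpora; it does not submit tasks to any
platform (no network code), does not estimate worker confusion matrices
from data (no Dawid–Skene-style aggregation — majority consensus is the
implemented and published rule), and does not train or evaluate the
downstream relation-extraction systems: benchmark scores enter only as a
printed table to aggregate.
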