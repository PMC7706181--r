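#' Label distribution of an adjudicated task
#'
#' Counts true / false / excluded relations and expresses each as a
#' percentage of the original task total (half-up, two decimals, the
#' convention of published task summaries). The kept total is
#' `true + false`: excluded relations leave the dataset.
#'
#' @param labels A fully adjudicated `relation_corpus`, or a character
#'   vector of `TRUE`/`FALSE`/`EXCLUDE` labels.
#' @param original_total Denominator for the percentages; defaults to the
#'   number of labels supplied.
#' @return A list of class `label_distribution` with counts (`n_true`,
#'   `n_false`, `n_excluded`, `n_kept`) and percentages (`pct_true`,
#'   `pct_false`, `pct_excluded`, `pct_kept`).
#' @export
label_distribution <- function(labels, original_total = NULL) {
  if (inherits(labels, "relation_corpus")) {
    labels <- labels$instances$revised_label
  }
  if (anyNA(labels)) {
    abort("every instance must carry a revised label before computing a distribution")
  }
  assert_label(labels, REL_LABELS, "labels")
  counts <- table(factor(labels, REL_LABELS))
  total <- if (is.null(original_total)) length(labels) else original_total
  if (length(labels) > total) {
    abort("label counts exceed the original task total")
  }
  pct <- function(k) round_half_up(100 * k / total, 2)
  structure(
    list(
      n_true = unname(counts[["TRUE"]]),
      n_false = unname(counts[["FALSE"]]),
      n_excluded = unname(counts[["EXCLUDE"]]),
      n_kept = unname(counts[["TRUE"]] + counts[["FALSE"]]),
      original_total = total,
      pct_true = pct(counts[["TRUE"]]),
      pct_false = pct(counts[["FALSE"]]),
      pct_excluded = pct(counts[["EXCLUDE"]]),
      pct_kept = pct(counts[["TRUE"]] + counts[["FALSE"]])
    ),
    class = "label_distribution"
  )
}

#' @export
print.label_distribution <- function(x, ...) {
  cat(sprintf(
    "true %d (%.2f%%)  false %d (%.2f%%)  excluded %d (%.2f%%)  kept %d (%.2f%%) of %d\n",
    x$n_true, x$pct_true, x$n_false, x$pct_false,
    x$n_excluded, x$pct_excluded, x$n_kept, x$pct_kept, x$original_total
  ))
  invisible(x)
}

#' Crowdsourcing campaign cost configuration
#'
#' @param n_tasks Number of tasks in the batch.
#' @param assignments_per_task Assignments (distinct workers) per task.
#' @param reward Reward per assignment in USD (cent-aligned).
#' @param base_fee Platform fee per assignment in USD, as billed (already
#'   rounded up to the cent by the platform).
#' @param masters_surcharge Extra per-assignment fee for restricting tasks
#'   to the platform's high-performing ("Masters") workers, in USD.
#' @return A list of class `cost_config`.
#' @export
cost_config <- function(n_tasks, assignments_per_task = 1L, reward = 0.02,
                        base_fee = 0.01, masters_surcharge = 0.001) {
  if (any(c(n_tasks, assignments_per_task, reward, base_fee,
            masters_surcharge) < 0)) {
    abort("all cost components must be non-negative")
  }
  structure(
    list(n_tasks = as.integer(n_tasks),
         assignments_per_task = as.integer(assignments_per_task),
         reward = reward, base_fee = base_fee,
         masters_surcharge = masters_surcharge),
    class = "cost_config"
  )
}

# Per-assignment platform fee in integer cents. The platform bills fees
# rounded up to the cent; when the base fee already sits on a cent boundary
# the sub-cent Masters surcharge is absorbed by that rounding and the billed
# fee is unchanged. Otherwise the combined fee is rounded up.
fee_cents <- function(base_fee, masters_surcharge) {
  base_c <- base_fee * 100
  at_boundary <- abs(base_c - round(base_c)) < 1e-9
  if (at_boundary) {
    as.integer(round(base_c))
  } else {
    as.integer(ceiling(base_c + masters_surcharge * 100 - 1e-9))
  }
}

#' Total campaign cost
#'
#' `n_tasks * assignments_per_task * (reward + billed fee)`, carried out in
#' exact integer cents.
#'
#' @param config A [cost_config()].
#' @return Total cost in USD.
#' @export
cost_total <- function(config) {
  reward_c <- round(config$reward * 100)
  if (abs(reward_c - config$reward * 100) > 1e-9) {
    abort("reward must be an exact number of cents")
  }
  fee_c <- fee_cents(config$base_fee, config$masters_surcharge)
  total_c <- config$n_tasks * config$assignments_per_task * (reward_c + fee_c)
  total_c / 100
}

#' Worker-level summary of a vote ledger
#'
#' Counts workers and assignments, mean assignments per worker (half-up to
#' an integer), and work-time statistics restricted to times at or below
#' the cutoff (longer times are mid-task breaks, not judgment time). The
#' histogram uses 1-second bins over `[0, cutoff]`.
#'
#' @param votes A non-empty [vote_set()].
#' @param cutoff Work-time cutoff in seconds for the time statistics.
#' @return A list of class `worker_summary`: `n_workers`, `n_assignments`,
#'   `assignments_per_worker`, `n_missing_worker_id`, `n_under_cutoff`,
#'   `time_mean`, `time_median`, `time_sd`, `histogram` (named integer
#'   vector of 1-s bins).
#' @export
worker_summary <- function(votes, cutoff = 50) {
  if (nrow(votes) == 0) {
    abort("vote set is empty")
  }
  workers <- votes$worker_id[!is.na(votes$worker_id)]
  if (length(workers) == 0) {
    abort("no attributed workers in the vote set")
  }
  n_workers <- length(unique(workers))
  n_assignments <- nrow(votes)
  kept <- votes$work_time[!is.na(votes$work_time) & votes$work_time <= cutoff]
  # 1-second bins [j-1, j) over [0, cutoff]; a time equal to the cutoff
  # lands in the last bin
  if (is.finite(cutoff)) {
    n_bins <- max(1L, ceiling(cutoff))
    bins <- tabulate(pmin(floor(kept), n_bins - 1L) + 1L, nbins = n_bins)
    histogram <- setNames(as.integer(bins), seq_len(n_bins) - 1L)
  } else {
    histogram <- NULL
  }
  structure(
    list(
      n_workers = n_workers,
      n_assignments = n_assignments,
      assignments_per_worker = round_half_up(n_assignments / n_workers),
      n_missing_worker_id = sum(is.na(votes$worker_id)),
      n_under_cutoff = length(kept),
      time_mean = mean(kept),
      time_median = median(kept),
      time_sd = sd(kept),
      histogram = histogram
    ),
    class = "worker_summary"
  )
}

#' Class-weight "full multiplier" for an imbalanced training set
#'
#' The ratio of true to false relations in a training partition — the class
#' weight that would exactly rebalance the loss. Reported to one decimal;
#' practice is to choose a weight between 1 and this multiplier.
#'
#' @param n_true,n_false Label counts of the training partition.
#' @param digits Decimals for reporting (`NULL` for the exact ratio).
#' @return The multiplier `n_true / n_false`.
#' @export
class_weight_multiplier <- function(n_true, n_false, digits = 1) {
  if (n_false <= 0) {
    abort("n_false must be positive (the multiplier divides by it)")
  }
  ratio <- n_true / n_false
  if (is.null(digits)) ratio else round_half_up(ratio, digits)
}

#' Aggregate benchmark F-measures against a baseline corpus
#'
#' Averages the F-measures of all experiments not using the baseline corpus
#' and of the baseline experiments, and reports the difference — the
#' summary used to quantify the value of corpus revision for downstream
#' relation-extraction systems.
#'
#' @param rows Data frame with columns `method`, `experiment`, `fmeasure`.
#' @param baseline_tag Experiment label identifying the baseline rows
#'   (exact match).
#' @return A list with `avg_other`, `avg_baseline` and `delta`
#'   (`avg_other - avg_baseline`), all half-up to 4 decimals.
#' @export
fmeasure_aggregation <- function(rows, baseline_tag) {
  rows <- as_tibble(rows)
  is_base <- rows$experiment == baseline_tag
  if (!any(is_base) || all(is_base)) {
    abort("need at least one baseline and one non-baseline row")
  }
  avg_other <- mean(rows$fmeasure[!is_base])
  avg_base <- mean(rows$fmeasure[is_base])
  list(
    avg_other = round_half_up(avg_other, 4),
    avg_baseline = round_half_up(avg_base, 4),
    delta = round_half_up(avg_other - avg_base, 4)
  )
}

#' Benchmark scores of relation-extraction systems on corpus revisions
#'
#' The published precision / recall / F-measure / accuracy of two deep
#' learning relation-extraction systems trained and tested on the original
#' distantly supervised corpus, its crowd-revised releases, and
#' combinations — shipped as a plain-text table for the aggregation
#' utilities.
#'
#' @return A tibble with columns `method`, `experiment`, `precision`,
#'   `recall`, `fmeasure`, `accuracy` (12 rows).
#' @export
deep_learning_scores <- function() {
  path <- system.file("extdata", "deep_learning_scores.tsv",
                      package = "crowdcurate", mustWork = TRUE)
  readr::read_tsv(path, col_types = "ccdddd", progress = FALSE)
}
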