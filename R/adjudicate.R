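#' Majority-consensus adjudication policy
#'
#' Encodes the voting scheme used to collapse a relation's votes into one
#' label. A relation is excluded when at least `exclusion_threshold` of all
#' its votes are `EXCLUDE` ("at least half" by default). Otherwise, under
#' the default `ABSOLUTE_MAJORITY` rule, the relation is `TRUE` only when
#' true votes exceed half of all votes; anything short of a true majority —
#' including a bare true plurality with no overall agreement — yields the
#' default label `FALSE` (false relations being harder to assess, the
#' conservative label). The `PLURALITY_OVER_FALSE` switch instead lets true
#' win whenever true votes strictly outnumber false votes, with exclude
#' votes counting toward the total but not toward the true/false contest.
#'
#' @param exclusion_threshold Fraction of the total votes at or above which
#'   exclude votes win; in (0, 1].
#' @param default_label Label used when neither exclusion nor the true rule
#'   is reached (fixed design: `"FALSE"`).
#' @param true_rule `"ABSOLUTE_MAJORITY"` or `"PLURALITY_OVER_FALSE"`.
#' @return An object of class `adjudication_policy`.
#' @export
adjudication_policy <- function(exclusion_threshold = 0.5,
                                default_label = "FALSE",
                                true_rule = c("ABSOLUTE_MAJORITY",
                                              "PLURALITY_OVER_FALSE")) {
  true_rule <- arg_match(true_rule)
  if (!is.numeric(exclusion_threshold) || exclusion_threshold <= 0 ||
      exclusion_threshold > 1) {
    abort("exclusion_threshold must be in (0, 1]")
  }
  assert_label(default_label, REL_LABELS, "default_label")
  structure(
    list(exclusion_threshold = exclusion_threshold,
         default_label = default_label,
         true_rule = true_rule),
    class = "adjudication_policy"
  )
}

#' Adjudicate one relation's votes
#'
#' Applies the consensus policy to a multiset of votes. A single-vote input
#' degenerates to passing that vote through (the single-judgment task).
#'
#' @param votes Character vector of votes in `TRUE`/`FALSE`/`EXCLUDE`.
#' @param policy An [adjudication_policy()].
#' @return A list of class `adjudication_result`: `label`, `vote_counts`
#'   (named `n_true`, `n_false`, `n_exclude`) and `rule_fired` (one of
#'   `"exclusion_majority"`, `"true_plurality"`, `"true_majority"`,
#'   `"default_false"`).
#' @export
adjudicate <- function(votes, policy = adjudication_policy()) {
  if (length(votes) == 0) {
    abort("cannot adjudicate an empty vote set")
  }
  assert_label(votes, REL_LABELS, "votes")
  counts <- table(factor(votes, REL_LABELS))
  adjudicate_counts(counts[["TRUE"]], counts[["FALSE"]], counts[["EXCLUDE"]],
                    policy)
}

# Count-level core of the voting scheme; shared by adjudicate() and the
# corpus-level driver.
adjudicate_counts <- function(n_true, n_false, n_exclude,
                              policy = adjudication_policy()) {
  m <- n_true + n_false + n_exclude
  if (m == 0) {
    abort("cannot adjudicate an empty vote set")
  }
  if (n_exclude >= policy$exclusion_threshold * m - 1e-9) {
    label <- "EXCLUDE"
    rule <- "exclusion_majority"
  } else if (policy$true_rule == "PLURALITY_OVER_FALSE" && n_true > n_false) {
    label <- "TRUE"
    rule <- "true_plurality"
  } else if (policy$true_rule == "ABSOLUTE_MAJORITY" && n_true > m / 2) {
    label <- "TRUE"
    rule <- "true_majority"
  } else {
    label <- policy$default_label
    rule <- "default_false"
  }
  structure(
    list(label = label,
         vote_counts = c(n_true = n_true, n_false = n_false,
                         n_exclude = n_exclude),
         rule_fired = rule),
    class = "adjudication_result"
  )
}

#' Merge an additional rater's judgments into a vote ledger
#'
#' Adds one assignment per covered relation from an on-site rater or domain
#' expert, so a seven-worker relation becomes an eight-vote relation.
#'
#' @param votes A [vote_set()].
#' @param extra Data frame (or TSV/CSV path) with columns `relation_id`,
#'   `answer`, and optionally `worker_id` and `work_time`.
#' @param source_tag Rater source stamped on the merged assignments,
#'   `"EXTRA_RATER"` or `"EXPERT"`.
#' @return The combined `vote_set`.
#' @export
merge_rater <- function(votes, extra, source_tag = c("EXTRA_RATER", "EXPERT")) {
  source_tag <- arg_match(source_tag)
  if (!is.data.frame(extra)) {
    extra <- readr::read_delim(extra, delim = if (grepl("\\.csv$", extra)) "," else "\t",
                               col_types = readr::cols(.default = readr::col_character()),
                               progress = FALSE, show_col_types = FALSE)
  }
  extra <- as_tibble(extra)
  if (nrow(extra) == 0) {
    return(votes)
  }
  if (anyDuplicated(extra$relation_id)) {
    dup <- unique(extra$relation_id[duplicated(extra$relation_id)])
    abort(sprintf("duplicate extra rating for relation(s): %s",
                  paste(dup, collapse = ", ")))
  }
  unknown <- setdiff(extra$relation_id, votes$relation_id)
  if (length(unknown) > 0) {
    abort(sprintf("extra ratings for unknown relation(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  merged <- tibble(
    relation_id = as.character(extra$relation_id),
    worker_id = if ("worker_id" %in% names(extra)) {
      as.character(extra$worker_id)
    } else {
      tolower(source_tag)
    },
    answer = as.character(extra$answer),
    work_time = if ("work_time" %in% names(extra)) {
      as.numeric(extra$work_time)
    } else {
      NA_real_
    },
    rater_source = source_tag
  )
  vote_set(bind_rows(as_tibble(votes), merged), strict = FALSE)
}

#' Adjudicate an entire corpus from its vote ledger
#'
#' Applies the consensus policy relation by relation, writing the winning
#' label into `revised_label` and collecting the excluded relations.
#'
#' @param corpus A `relation_corpus`; every relation must have at least one
#'   vote.
#' @param votes A [vote_set()] covering the corpus.
#' @param policy An [adjudication_policy()].
#' @param sources Rater sources whose votes participate (default: all).
#' @return A list with `corpus` (revised labels set), `exclusions`
#'   (character vector of excluded relation ids) and `results` (one-row-per-
#'   relation tibble of labels, counts and the rule that fired).
#' @export
adjudicate_corpus <- function(corpus, votes, policy = adjudication_policy(),
                              sources = RATER_SOURCES) {
  votes <- votes[votes$rater_source %in% sources, ]
  unvoted <- setdiff(corpus$instances$relation_id, votes$relation_id)
  if (length(unvoted) > 0) {
    abort(sprintf(
      "relations without any vote: %s%s",
      paste(head(unvoted, 10), collapse = ", "),
      if (length(unvoted) > 10) sprintf(" (and %d more)", length(unvoted) - 10) else ""
    ))
  }
  counts <- as_tibble(votes) %>%
    count(.data$relation_id, .data$answer) %>%
    tidyr_pivot_counts()
  results <- lapply(seq_len(nrow(counts)), function(i) {
    r <- adjudicate_counts(counts$n_true[i], counts$n_false[i],
                           counts$n_exclude[i], policy)
    tibble(relation_id = counts$relation_id[i], label = r$label,
           n_true = counts$n_true[i], n_false = counts$n_false[i],
           n_exclude = counts$n_exclude[i], rule_fired = r$rule_fired)
  }) %>% bind_rows()
  ins <- corpus$instances
  ins$revised_label <- results$label[match(ins$relation_id, results$relation_id)]
  corpus$instances <- ins
  list(
    corpus = corpus,
    exclusions = results$relation_id[results$label == "EXCLUDE"],
    results = results[match(ins$relation_id, results$relation_id), ]
  )
}

# Wide per-relation vote counts without depending on tidyr.
tidyr_pivot_counts <- function(long) {
  ids <- unique(long$relation_id)
  out <- tibble(relation_id = ids, n_true = 0L, n_false = 0L, n_exclude = 0L)
  col <- c("TRUE" = "n_true", "FALSE" = "n_false", "EXCLUDE" = "n_exclude")
  for (lab in names(col)) {
    rows <- long[long$answer == lab, ]
    out[[col[[lab]]]][match(rows$relation_id, ids)] <- rows$n
  }
  out
}
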