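HIT_DIALECTS <- list(
  "double-asterisk" = c(open = "**", close = "**"),
  "html-bold" = c(open = "<b>", close = "</b>")
)

#' Default answer options shown to workers
#'
#' The three on-screen classification options of a task, in fixed order, and
#' their mapping onto the canonical labels. The exact option wording is
#' configurable in [parse_results()] via `answer_map`.
#' @return Named character vector mapping option text to
#'   `TRUE`/`FALSE`/`EXCLUDE`.
#' @export
default_answer_map <- function() {
  c(
    "True relation" = "TRUE",
    "False relation" = "FALSE",
    "Wrongly labeled relation" = "EXCLUDE",
    "TRUE" = "TRUE", "FALSE" = "FALSE", "EXCLUDE" = "EXCLUDE",
    "true" = "TRUE", "false" = "FALSE", "exclude" = "EXCLUDE"
  )
}

#' Render one relation instance as a crowd task
#'
#' Produces the worker-facing form of a relation: the sentence with the
#' phenotype and gene mentions wrapped in emphasis markers, plus the fixed
#' three-option answer set. Rendering is invertible ([unrender_sentence()]
#' recovers the original sentence).
#'
#' @param instance One-row slice of `relation_corpus` instances (or a list
#'   with the same fields).
#' @param dialect Marker dialect: `"double-asterisk"` or `"html-bold"`.
#' @return A list of class `hit` with `hit_id`, `relation_id`,
#'   `rendered_sentence` and `options`.
#' @export
render_hit <- function(instance, dialect = c("double-asterisk", "html-bold")) {
  dialect <- arg_match(dialect)
  mk <- HIT_DIALECTS[[dialect]]
  spans <- data.frame(
    start = c(instance$phen_start, instance$gene_start),
    end = c(instance$phen_end, instance$gene_end)
  )
  if (spans$start[1] < spans$end[2] && spans$start[2] < spans$end[1]) {
    abort(sprintf("entity spans overlap for relation %s", instance$relation_id))
  }
  sentence <- instance$sentence
  # insert markers right-to-left so earlier offsets stay valid
  for (i in order(spans$start, decreasing = TRUE)) {
    s <- spans$start[i]
    e <- spans$end[i]
    sentence <- paste0(
      substr(sentence, 1L, s),
      mk[["open"]], substr(sentence, s + 1L, e), mk[["close"]],
      substr(sentence, e + 1L, nchar(sentence))
    )
  }
  structure(
    list(
      hit_id = paste0("hit-", instance$relation_id),
      relation_id = instance$relation_id,
      rendered_sentence = sentence,
      options = names(default_answer_map())[1:3]
    ),
    class = "hit"
  )
}

#' Strip emphasis markers from a rendered task sentence
#'
#' @param rendered Rendered sentence containing exactly two marked spans.
#' @param dialect Marker dialect used at render time.
#' @return The original unmarked sentence.
#' @export
unrender_sentence <- function(rendered,
                              dialect = c("double-asterisk", "html-bold")) {
  dialect <- arg_match(dialect)
  mk <- HIT_DIALECTS[[dialect]]
  for (m in unique(mk)) {
    rendered <- gsub(m, "", rendered, fixed = TRUE)
  }
  rendered
}

#' Generate a crowd task batch from a corpus
#'
#' Writes (or returns) the batch input table submitted to the crowdsourcing
#' platform: one CSV row per relation with the rendered sentence. The
#' declared number of assignments per task is carried in the batch metadata,
#' so the expected assignment volume (`rows x assignments`) is known before
#' submission.
#'
#' @param corpus A `relation_corpus`.
#' @param assignments_per_hit Number of distinct workers requested per task.
#' @param path Optional output path for the batch CSV.
#' @param dialect Emphasis dialect for the rendered sentences.
#' @return A list of class `hit_batch`: `hits` (tibble with `hit_id`,
#'   `relation_id`, `rendered_sentence`), `assignments_per_hit` and
#'   `expected_assignments`.
#' @export
generate_hit_batch <- function(corpus, assignments_per_hit = 1L, path = NULL,
                               dialect = "double-asterisk") {
  if (!is.numeric(assignments_per_hit) || assignments_per_hit < 1) {
    abort("assignments_per_hit must be a positive integer")
  }
  ins <- corpus$instances
  hits <- lapply(seq_len(nrow(ins)), function(i) {
    h <- render_hit(ins[i, ], dialect = dialect)
    tibble(hit_id = h$hit_id, relation_id = h$relation_id,
           rendered_sentence = h$rendered_sentence)
  })
  hits <- if (length(hits) > 0) bind_rows(hits) else {
    tibble(hit_id = character(), relation_id = character(),
           rendered_sentence = character())
  }
  batch <- structure(
    list(
      hits = hits,
      assignments_per_hit = as.integer(assignments_per_hit),
      expected_assignments = nrow(hits) * as.integer(assignments_per_hit)
    ),
    class = "hit_batch"
  )
  if (!is.null(path)) {
    readr::write_csv(hits, path, progress = FALSE)
  }
  batch
}

#' Construct a vote ledger
#'
#' A vote set maps each relation to the multiset of assignments it received:
#' who rated it (worker id may be missing — observed in real platform
#' exports), the answer, the work time in seconds and the rater source
#' (`CROWD`, `EXTRA_RATER` or `EXPERT`).
#'
#' @param assignments Data frame with columns `relation_id`, `worker_id`,
#'   `answer`, `work_time`, `rater_source`.
#' @param strict Error on duplicate (relation, crowd worker) pairs? The
#'   platform guarantees distinct workers per task, so a duplicate is an
#'   invariant breach; [parse_results()] reports rather than errors.
#' @return A tibble of class `vote_set`.
#' @export
vote_set <- function(assignments, strict = TRUE) {
  votes <- as_tibble(assignments)
  needed <- c("relation_id", "worker_id", "answer", "work_time", "rater_source")
  missing_cols <- setdiff(needed, names(votes))
  if (length(missing_cols) > 0) {
    abort(sprintf("vote set is missing columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  votes <- votes[needed]
  votes$relation_id <- as.character(votes$relation_id)
  votes$worker_id <- as.character(votes$worker_id)
  votes$answer <- as.character(votes$answer)
  votes$work_time <- as.numeric(votes$work_time)
  votes$rater_source <- as.character(votes$rater_source)
  assert_label(votes$answer, REL_LABELS, "answer")
  assert_label(votes$rater_source, RATER_SOURCES, "rater_source")
  if (any(votes$work_time < 0, na.rm = TRUE)) {
    abort("work_time must be non-negative")
  }
  dup <- duplicate_crowd_pairs(votes)
  if (strict && nrow(dup) > 0) {
    abort(sprintf(
      "duplicate crowd worker on one relation (platform guarantees unique workers): %s",
      paste(sprintf("%s/%s", dup$relation_id, dup$worker_id), collapse = ", ")
    ))
  }
  class(votes) <- c("vote_set", class(votes))
  votes
}

duplicate_crowd_pairs <- function(votes) {
  crowd <- votes[votes$rater_source == "CROWD" & !is.na(votes$worker_id), ]
  key <- paste(crowd$relation_id, crowd$worker_id, sep = "\r")
  dup <- crowd[duplicated(key), ]
  distinct(tibble(relation_id = dup$relation_id, worker_id = dup$worker_id))
}

#' Parse crowd results into a vote ledger
#'
#' Accepts both the Mechanical Turk batch-results dialect (`HITId`,
#' `WorkerId`, `WorkTimeInSeconds`, an `Answer.*` column and optionally
#' `Input.relation_id`) and the package's internal dialect (`relation_id`,
#' `worker_id`, `answer`, `work_time`). Rows with an empty worker id are
#' kept but counted in the anomaly report; duplicate (relation, worker)
#' pairs are listed there as invariant violations.
#'
#' @param path CSV file of crowd results, or a data frame already in memory.
#' @param answer_map Named character vector translating on-screen answer
#'   strings to `TRUE`/`FALSE`/`EXCLUDE` (see [default_answer_map()]).
#' @param rater_source Source tag to stamp on the parsed assignments.
#' @return A list with `votes` (a [vote_set()]) and `anomalies` (list with
#'   `n_missing_worker_id` and `duplicate_pairs`).
#' @export
parse_results <- function(path, answer_map = default_answer_map(),
                          rater_source = "CROWD") {
  raw <- if (is.data.frame(path)) {
    as_tibble(path)
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, show_col_types = FALSE)
  }
  if (nrow(raw) == 0) {
    empty <- vote_set(tibble(
      relation_id = character(), worker_id = character(),
      answer = character(), work_time = numeric(), rater_source = character()
    ))
    return(list(votes = empty,
                anomalies = list(n_missing_worker_id = 0L,
                                 duplicate_pairs = tibble(relation_id = character(),
                                                          worker_id = character()))))
  }
  mturk <- "HITId" %in% names(raw)
  if (mturk) {
    relation <- if ("Input.relation_id" %in% names(raw)) {
      raw$`Input.relation_id`
    } else {
      raw$HITId
    }
    worker <- raw$WorkerId
    work_time <- as.numeric(raw$WorkTimeInSeconds)
    answer_col <- grep("^Answer\\.", names(raw), value = TRUE)
    if (length(answer_col) == 0) {
      abort("results file has no Answer.* column")
    }
    answer_raw <- raw[[answer_col[1]]]
  } else {
    needed <- c("relation_id", "answer")
    if (!all(needed %in% names(raw))) {
      abort("results must have either MTurk columns (HITId, WorkerId, WorkTimeInSeconds, Answer.*) or internal columns (relation_id, worker_id, answer, work_time)")
    }
    relation <- raw$relation_id
    worker <- if ("worker_id" %in% names(raw)) raw$worker_id else NA_character_
    work_time <- if ("work_time" %in% names(raw)) as.numeric(raw$work_time) else 0
    answer_raw <- raw$answer
  }
  worker <- as.character(worker)
  worker[!is.na(worker) & trimws(worker) == ""] <- NA_character_
  answer <- unname(answer_map[answer_raw])
  if (anyNA(answer)) {
    bad <- which(is.na(answer))
    abort(sprintf(
      "unknown answer string %s at result row(s) %s",
      paste(sQuote(unique(answer_raw[bad])), collapse = ", "),
      paste(bad, collapse = ", ")
    ))
  }
  votes <- vote_set(
    tibble(relation_id = as.character(relation), worker_id = worker,
           answer = answer, work_time = work_time,
           rater_source = rater_source),
    strict = FALSE
  )
  list(
    votes = votes,
    anomalies = list(
      n_missing_worker_id = sum(is.na(worker)),
      duplicate_pairs = duplicate_crowd_pairs(votes)
    )
  )
}

#' Filter a vote ledger by work time
#'
#' Retains assignments completed within the cutoff (`work_time <= cutoff`;
#' a 50-second cutoff keeps times up to and including 50 s). Intended for
#' descriptive statistics of genuine working time — long outliers are
#' mid-task breaks, not slow judgments. Adjudication always uses the
#' unfiltered ledger.
#'
#' @param votes A [vote_set()].
#' @param cutoff Positive time cutoff in seconds (may be `Inf`).
#' @return The filtered `vote_set`.
#' @export
filter_by_time <- function(votes, cutoff = 50) {
  if (!is.numeric(cutoff) || cutoff <= 0) {
    abort("cutoff must be a positive number of seconds")
  }
  out <- votes[votes$work_time <= cutoff, ]
  class(out) <- class(votes)
  out
}
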