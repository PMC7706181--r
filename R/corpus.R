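CORPUS_COLUMNS <- c(
  "relation_id", "pmid", "sentence",
  "phen_text", "phen_start", "phen_end", "phen_id",
  "gene_text", "gene_start", "gene_end", "gene_id",
  "original_label", "revised_label"
)

#' Construct a phenotype-gene relation corpus
#'
#' A relation corpus holds one row per candidate phenotype-gene relation: the
#' supporting sentence, the two entity mentions with 0-based half-open
#' character offsets, the original distant-supervision label
#' (`KNOWN`/`UNKNOWN`), and an optional revised label
#' (`TRUE`/`FALSE`/`EXCLUDE`) set by crowd adjudication or expert review.
#'
#' @param instances Data frame with columns `relation_id`, `pmid`, `sentence`,
#'   `phen_text`, `phen_start`, `phen_end`, `phen_id`, `gene_text`,
#'   `gene_start`, `gene_end`, `gene_id`, `original_label`, and (optionally)
#'   `revised_label`. Offsets are 0-based, end-exclusive.
#' @param metadata Named list of free-form corpus metadata (release tag,
#'   provenance, ...).
#' @return An object of class `relation_corpus`: a list with elements
#'   `instances` (a tibble) and `metadata`.
#' @export
relation_corpus <- function(instances, metadata = list()) {
  instances <- as_tibble(instances)
  if (!"revised_label" %in% names(instances)) {
    instances$revised_label <- NA_character_
  }
  missing_cols <- setdiff(CORPUS_COLUMNS, names(instances))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "corpus is missing columns: %s", paste(missing_cols, collapse = ", ")
    ))
  }
  instances <- instances[CORPUS_COLUMNS]
  for (col in c("phen_start", "phen_end", "gene_start", "gene_end")) {
    instances[[col]] <- as.integer(instances[[col]])
  }
  for (col in c("relation_id", "pmid", "sentence", "phen_text", "phen_id",
                "gene_text", "gene_id", "original_label", "revised_label")) {
    instances[[col]] <- as.character(instances[[col]])
  }
  corpus <- structure(
    list(instances = instances, metadata = metadata),
    class = "relation_corpus"
  )
  validate_corpus(corpus)
}

#' Validate a relation corpus
#'
#' Checks relation-id uniqueness, label spaces, span arithmetic (offsets in
#' range, surface text matching the sentence substring, non-overlapping
#' phenotype and gene spans) and the absence of literal tabs or newlines in
#' sentences (which would break the tab-separated serialisation).
#'
#' @param corpus A `relation_corpus`.
#' @return The corpus, invisibly unchanged, or an error describing every
#'   offending relation.
#' @export
validate_corpus <- function(corpus) {
  ins <- corpus$instances
  if (nrow(ins) == 0) {
    return(corpus)
  }
  if (anyDuplicated(ins$relation_id)) {
    dup <- unique(ins$relation_id[duplicated(ins$relation_id)])
    abort(sprintf("duplicate relation_id: %s", paste(dup, collapse = ", ")))
  }
  assert_label(ins$original_label, ORIG_LABELS, "original_label")
  assert_label(ins$revised_label, REL_LABELS, "revised_label")
  if (any(grepl("[\t\n\r]", ins$sentence))) {
    bad <- ins$relation_id[grepl("[\t\n\r]", ins$sentence)]
    abort(sprintf(
      "sentences contain literal tab/newline characters (forbidden by the TSV serialisation): %s",
      paste(bad, collapse = ", ")
    ))
  }
  check_span <- function(start, end, text, kind) {
    len <- nchar(ins$sentence)
    bad_range <- is.na(start) | is.na(end) | start < 0 | start >= end | end > len
    # 0-based half-open offsets: substring [start, end)
    surface <- substr(ins$sentence, start + 1L, end)
    bad_text <- !bad_range & surface != text
    if (any(bad_range | bad_text)) {
      bad <- ins$relation_id[bad_range | bad_text]
      abort(sprintf(
        "%s span does not match its sentence (offset out of range or surface mismatch) for: %s",
        kind, paste(bad, collapse = ", ")
      ))
    }
  }
  check_span(ins$phen_start, ins$phen_end, ins$phen_text, "phenotype")
  check_span(ins$gene_start, ins$gene_end, ins$gene_text, "gene")
  overlap <- ins$phen_start < ins$gene_end & ins$gene_start < ins$phen_end
  if (any(overlap)) {
    abort(sprintf(
      "phenotype and gene spans overlap for: %s",
      paste(ins$relation_id[overlap], collapse = ", ")
    ))
  }
  invisible(corpus)
}

#' @export
print.relation_corpus <- function(x, ...) {
  n <- nrow(x$instances)
  cat(sprintf("<relation_corpus> %d relation%s\n", n, if (n == 1) "" else "s"))
  if (n > 0) {
    orig <- table(factor(x$instances$original_label, ORIG_LABELS))
    cat(sprintf("  original labels: %s\n",
                paste(sprintf("%s=%d", names(orig), orig), collapse = " ")))
    rev <- x$instances$revised_label
    if (any(!is.na(rev))) {
      revt <- table(factor(rev, REL_LABELS))
      cat(sprintf("  revised labels:  %s\n",
                  paste(sprintf("%s=%d", names(revt), revt), collapse = " ")))
    }
  }
  if (length(x$metadata) > 0) {
    cat(sprintf("  metadata: %s\n", paste(names(x$metadata), collapse = ", ")))
  }
  invisible(x)
}

#' Number of relations in a corpus
#' @param corpus A `relation_corpus`.
#' @return Integer count of relation instances.
#' @export
n_relations <- function(corpus) {
  nrow(corpus$instances)
}

#' Read a relation corpus from a tab-separated file
#'
#' The file format is one row per relation with the thirteen documented
#' columns (see [relation_corpus()]), UTF-8, no quoting; literal tabs or
#' newlines inside fields are rejected. Missing `revised_label` cells are
#' read as `NA`.
#'
#' @param path Path to a corpus TSV written by [write_corpus()] (or any file
#'   matching the schema).
#' @return A `relation_corpus`.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("corpus file does not exist: %s", path))
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (!identical(header, CORPUS_COLUMNS)) {
    abort(sprintf(
      "corpus header does not match the expected schema; expected %s",
      paste(CORPUS_COLUMNS, collapse = ", ")
    ))
  }
  # parsing issues are re-signalled below as errors naming the line
  ins <- suppressWarnings(readr::read_delim(
    path,
    delim = "\t", quote = "", na = "",
    col_types = readr::cols(
      phen_start = readr::col_integer(), phen_end = readr::col_integer(),
      gene_start = readr::col_integer(), gene_end = readr::col_integer(),
      .default = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  ))
  probs <- readr::problems(ins)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "malformed corpus row(s) at line(s): %s",
      paste(unique(probs$row + 1L), collapse = ", ")
    ))
  }
  relation_corpus(ins)
}

#' Write a relation corpus to a tab-separated file
#'
#' @param corpus A `relation_corpus`.
#' @param path Output path.
#' @return The input corpus, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  validate_corpus(corpus)
  readr::write_tsv(corpus$instances, path, na = "", quote = "none",
                   escape = "none", progress = FALSE)
  invisible(corpus)
}

#' Map original distant-supervision labels onto the revised-label slot
#'
#' The distant-supervision baseline treats knowledge-base hits as true:
#' `KNOWN` maps to `TRUE` and `UNKNOWN` to `FALSE`. Refuses to overwrite a
#' corpus that already carries revised labels from adjudication.
#'
#' @param corpus A `relation_corpus` with no revised labels set.
#' @return The corpus with `revised_label` filled from `original_label`.
#' @export
map_original_labels <- function(corpus) {
  ins <- corpus$instances
  if (any(!is.na(ins$revised_label))) {
    abort("corpus already has revised labels; refusing to overwrite adjudicated labels")
  }
  ins$revised_label <- ifelse(ins$original_label == "KNOWN", "TRUE", "FALSE")
  corpus$instances <- ins
  corpus
}

#' Split a corpus into two annotation-task partitions
#'
#' Uniformly shuffles the corpus under `seed` and assigns the first
#' `floor(fraction * N)` relations to the first partition (the campaign's
#' single-judgment task) and the rest to the second (the multi-judgment
#' task). With `stratified = TRUE`, the split preserves the original-label
#' proportions within one instance per stratum (largest-remainder
#' allocation).
#'
#' @param corpus A non-empty `relation_corpus`.
#' @param fraction Fraction of relations assigned to the first partition,
#'   strictly between 0 and 1.
#' @param seed Integer seed making the shuffle reproducible.
#' @param stratified Preserve original-label proportions across partitions?
#' @return A list with elements `part1` and `part2`, both `relation_corpus`
#'   objects; disjoint and jointly exhaustive.
#' @export
partition_corpus <- function(corpus, fraction = 0.7, seed = 1L,
                             stratified = FALSE) {
  n <- n_relations(corpus)
  if (n == 0) {
    abort("cannot partition an empty corpus")
  }
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction >= 1) {
    abort("fraction must be a single number strictly between 0 and 1")
  }
  n1 <- floor(fraction * n + 1e-9)
  ins <- corpus$instances
  if (stratified) {
    idx1 <- with_seed(seed, {
      strata <- split(seq_len(n), ins$original_label)
      quota <- vapply(strata, function(i) fraction * length(i), numeric(1))
      base_take <- floor(quota + 1e-9)
      # largest-remainder top-up so the overall size is exactly floor(f * N)
      short <- n1 - sum(base_take)
      if (short > 0) {
        order_rem <- order(quota - base_take, decreasing = TRUE)
        base_take[order_rem[seq_len(short)]] <-
          base_take[order_rem[seq_len(short)]] + 1
      }
      unlist(Map(function(i, k) sample(i)[seq_len(k)], strata, base_take),
             use.names = FALSE)
    })
  } else {
    idx1 <- with_seed(seed, sample.int(n)[seq_len(n1)])
  }
  take <- seq_len(n) %in% idx1
  meta1 <- modifyList(corpus$metadata, list(partition = "task1",
                                            split_fraction = fraction,
                                            split_seed = seed))
  meta2 <- modifyList(corpus$metadata, list(partition = "task2",
                                            split_fraction = fraction,
                                            split_seed = seed))
  list(
    part1 = relation_corpus(ins[take, ], meta1),
    part2 = relation_corpus(ins[!take, ], meta2)
  )
}
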