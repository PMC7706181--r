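#' Merge adjudicated task partitions into a new corpus release
#'
#' Drops excluded relations, keeps true/false relations with their revised
#' labels, and assembles a manifest of recomputed counts: abstracts are
#' distinct PubMed ids among kept relations, and entity-annotation counts
#' are distinct (pmid, identifier) mentions participating in kept relations
#' — annotations that survive only in excluded relations are not counted.
#'
#' @param task1,task2 Fully adjudicated, disjoint `relation_corpus`
#'   partitions.
#' @param release_tag Tag recorded in the manifest.
#' @param provenance Named character vector describing how each partition
#'   was adjudicated (e.g. `c(task1 = "worker", task2 = "expert")`).
#' @param seed Optional seed recorded in the manifest for provenance.
#' @return A list with `corpus` (the merged release, excluded relations
#'   removed) and `manifest` (class `release_manifest`).
#' @export
build_release <- function(task1, task2, release_tag = "release-3",
                          provenance = c(task1 = "worker", task2 = "expert"),
                          seed = NA_integer_) {
  overlap <- intersect(task1$instances$relation_id, task2$instances$relation_id)
  if (length(overlap) > 0) {
    abort(sprintf("partitions overlap on relation(s): %s",
                  paste(head(overlap, 10), collapse = ", ")))
  }
  merged <- bind_rows(task1$instances, task2$instances)
  if (anyNA(merged$revised_label)) {
    abort("every instance must be adjudicated before building a release")
  }
  n_original <- nrow(merged)
  n_excluded <- sum(merged$revised_label == "EXCLUDE")
  kept <- merged[merged$revised_label != "EXCLUDE", ]
  corpus <- relation_corpus(kept, metadata = list(release_tag = release_tag))
  manifest <- structure(
    list(
      release_tag = release_tag,
      provenance = provenance,
      n_abstracts = n_distinct(kept$pmid),
      n_phenotype_annotations = nrow(distinct(kept[, c("pmid", "phen_id")])),
      n_gene_annotations = nrow(distinct(kept[, c("pmid", "gene_id")])),
      n_true = sum(kept$revised_label == "TRUE"),
      n_false = sum(kept$revised_label == "FALSE"),
      n_total = nrow(kept),
      n_excluded = n_excluded,
      exclusion_rate_pct = round_half_up(100 * n_excluded / n_original, 2),
      built_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = seed
    ),
    class = "release_manifest"
  )
  list(corpus = corpus, manifest = manifest)
}

#' Recompute a release manifest from a merged corpus
#'
#' Rebuilds the count block of a manifest from the release corpus itself,
#' for verifying that a manifest matches its data.
#'
#' @param corpus A release `relation_corpus` (no excluded relations).
#' @return Named list of counts, matching the manifest fields.
#' @export
rebuild_manifest_counts <- function(corpus) {
  kept <- corpus$instances
  list(
    n_abstracts = n_distinct(kept$pmid),
    n_phenotype_annotations = nrow(distinct(kept[, c("pmid", "phen_id")])),
    n_gene_annotations = nrow(distinct(kept[, c("pmid", "gene_id")])),
    n_true = sum(kept$revised_label == "TRUE"),
    n_false = sum(kept$revised_label == "FALSE"),
    n_total = nrow(kept)
  )
}

#' @export
print.release_manifest <- function(x, ...) {
  cat(sprintf("<release_manifest> %s\n", x$release_tag))
  cat(sprintf("  abstracts %d | phenotype annotations %d | gene annotations %d\n",
              x$n_abstracts, x$n_phenotype_annotations, x$n_gene_annotations))
  cat(sprintf("  relations: true %d + false %d = %d (excluded %d, %.2f%% of source)\n",
              x$n_true, x$n_false, x$n_total, x$n_excluded,
              x$exclusion_rate_pct))
  invisible(x)
}

#' Export train/test splits for relation-extraction systems
#'
#' Writes one row per relation with the entity mentions replaced by typed
#' placeholders (the common input convention of sentence-level RE systems)
#' and the revised true/false label, together with class-weight metadata:
#' the full rebalancing multiplier of the training set and the chosen class
#' weight (by convention a value between 1 and the multiplier).
#'
#' @param release Training `relation_corpus` (no excluded relations, all
#'   labels set).
#' @param test_source Test `relation_corpus`, disjoint from `release`.
#' @param dir Optional directory in which to write `train.tsv` and
#'   `test.tsv`.
#' @param class_weight Chosen weight for the false class.
#' @param placeholders Named character vector with the `phenotype` and
#'   `gene` placeholder tokens.
#' @return A list with `train` and `test` tibbles (`relation_id`,
#'   `sentence`, `label`) and `metadata` (`full_multiplier`,
#'   `class_weight`, row counts, file paths if written).
#' @export
export_splits <- function(release, test_source, dir = NULL, class_weight = 5,
                          placeholders = c(phenotype = "@PHENOTYPE$",
                                           gene = "@GENE$")) {
  if (n_relations(test_source) == 0) {
    abort("test set is empty; refusing to export a split with no evaluation data")
  }
  overlap <- intersect(release$instances$relation_id,
                       test_source$instances$relation_id)
  if (length(overlap) > 0) {
    abort(sprintf("train and test share relation(s): %s",
                  paste(head(overlap, 10), collapse = ", ")))
  }
  placeholder_rows <- function(corpus) {
    ins <- corpus$instances
    if (anyNA(ins$revised_label) || any(ins$revised_label == "EXCLUDE")) {
      abort("splits must contain only adjudicated TRUE/FALSE relations")
    }
    sentence <- vapply(seq_len(nrow(ins)), function(i) {
      s <- ins$sentence[i]
      spans <- data.frame(
        start = c(ins$phen_start[i], ins$gene_start[i]),
        end = c(ins$phen_end[i], ins$gene_end[i]),
        token = c(placeholders[["phenotype"]], placeholders[["gene"]])
      )
      for (j in order(spans$start, decreasing = TRUE)) {
        s <- paste0(substr(s, 1L, spans$start[j]), spans$token[j],
                    substr(s, spans$end[j] + 1L, nchar(s)))
      }
      s
    }, character(1))
    tibble(relation_id = ins$relation_id, sentence = sentence,
           label = ins$revised_label)
  }
  train <- placeholder_rows(release)
  test <- placeholder_rows(test_source)
  multiplier <- class_weight_multiplier(sum(train$label == "TRUE"),
                                        sum(train$label == "FALSE"))
  metadata <- list(
    full_multiplier = multiplier,
    class_weight = class_weight,
    n_train = nrow(train),
    n_test = nrow(test)
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    train_path <- file.path(dir, "train.tsv")
    test_path <- file.path(dir, "test.tsv")
    readr::write_tsv(train, train_path, progress = FALSE)
    readr::write_tsv(test, test_path, progress = FALSE)
    metadata$train_path <- train_path
    metadata$test_path <- test_path
  }
  list(train = train, test = test, metadata = metadata)
}
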