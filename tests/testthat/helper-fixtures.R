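# Small hand-built fixtures shared across tests.

# Three relations with hand-checked offsets, including a gene span flush
# against the sentence end.
fixture_corpus <- function() {
  relation_corpus(tibble::tibble(
    relation_id = c("r1", "r2", "r3"),
    pmid = c("10000001", "10000001", "10000002"),
    sentence = c(
      "TP53 mutations cause Li-Fraumeni syndrome.",
      "Deafness maps to variants of GJB2.",
      "Aniridia is linked to PAX6"
    ),
    phen_text = c("Li-Fraumeni syndrome", "Deafness", "Aniridia"),
    phen_start = c(21L, 0L, 0L),
    phen_end = c(41L, 8L, 8L),
    phen_id = c("HP:0000001", "HP:0000002", "HP:0000003"),
    gene_text = c("TP53", "GJB2", "PAX6"),
    gene_start = c(0L, 29L, 22L),
    gene_end = c(4L, 33L, 26L),
    gene_id = c("7157", "2706", "5080"),
    original_label = c("KNOWN", "UNKNOWN", "KNOWN"),
    revised_label = NA_character_
  ))
}

# A vote set over the fixture corpus: 7 crowd votes per relation with known
# count triples.
fixture_votes <- function() {
  make <- function(id, n_true, n_false, n_exclude) {
    answers <- rep(c("TRUE", "FALSE", "EXCLUDE"), c(n_true, n_false, n_exclude))
    tibble::tibble(
      relation_id = id,
      worker_id = sprintf("w%02d", seq_along(answers)),
      answer = answers,
      work_time = seq_along(answers) + 2,
      rater_source = "CROWD"
    )
  }
  vote_set(dplyr::bind_rows(
    make("r1", 5, 1, 1), # true plurality
    make("r2", 2, 2, 3), # no exclusion majority, tie -> false
    make("r3", 1, 2, 4)  # exclusion majority
  ))
}

expect_corpus_equal <- function(a, b) {
  expect_equal(a$instances, b$instances)
}
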