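test_that("ratings tables have the right shape and row sums per rater group", {
  votes <- fixture_votes()
  tab <- build_ratings_table(votes, "CROWD")
  expect_equal(dim(tab), c(3, 3))
  expect_true(all(rowSums(tab) == 7))
  expect_equal(attr(tab, "raters_per_item"), 7)

  extra <- tibble::tibble(relation_id = c("r1", "r2", "r3"),
                          answer = c("TRUE", "FALSE", "EXCLUDE"))
  merged <- merge_rater(votes, extra, "EXTRA_RATER")
  tab8 <- build_ratings_table(merged, c("CROWD", "EXTRA_RATER"))
  expect_true(all(rowSums(tab8) == 8))

  merged <- merge_rater(merged, extra, "EXPERT")
  tab2 <- build_ratings_table(merged, c("EXTRA_RATER", "EXPERT"))
  expect_true(all(rowSums(tab2) == 2))

  # ragged design is an error only when a fixed table is requested
  ragged <- merged[-1, ]
  expect_error(build_ratings_table(ragged, c("CROWD", "EXTRA_RATER")),
               "unequal rater counts.*r1")
  tab_ragged <- build_ratings_table(ragged, c("CROWD", "EXTRA_RATER"),
                                    fixed = FALSE)
  expect_equal(sort(unique(attr(tab_ragged, "raters_per_item"))), c(7, 8))
})

test_that("Fleiss' kappa reproduces hand-computed values and degenerate cases", {
  # perfect agreement across >= 2 categories
  perfect <- matrix(c(3, 0, 0, 0, 3, 0), nrow = 2, byrow = TRUE)
  expect_equal(fleiss_kappa(perfect), 1)

  # hand evaluation: N=2 items, n=2 raters, rows (2,0) and (1,1) -> -1/3
  micro <- matrix(c(2, 0, 1, 1), nrow = 2, byrow = TRUE)
  expect_equal(fleiss_kappa(micro), -1 / 3)

  # all ratings in one category: chance agreement is 1, kappa undefined
  degenerate <- matrix(c(4, 0, 0, 4, 0, 0), nrow = 2, byrow = TRUE)
  expect_error(fleiss_kappa(degenerate),
               class = "crowdcurate_undefined_agreement")

  expect_error(fleiss_kappa(matrix(c(2, 0, 1, 1, 1, 0), nrow = 3,
                                   byrow = TRUE)),
               "same number of raters")
})

test_that("Krippendorff's alpha reproduces the hand-built coincidence example", {
  expect_equal(krippendorff_alpha(list(c("a", "a"), c("a", "b")),
                                  categories = c("a", "b")),
               0)
  expect_equal(krippendorff_alpha(list(c("a", "a"), c("b", "b", "b")),
                                  categories = c("a", "b")),
               1)
  # an item with a single rating is ignored entirely
  with_single <- krippendorff_alpha(list(c("a", "a"), c("a", "b"), "b"),
                                    categories = c("a", "b"))
  expect_equal(with_single,
               krippendorff_alpha(list(c("a", "a"), c("a", "b")),
                                  categories = c("a", "b")))
  expect_error(krippendorff_alpha(list("a", "b")), "two or more ratings")
  expect_error(krippendorff_alpha(list(c("a", "a"), c("a", "a")),
                                  categories = c("a", "b")),
               class = "crowdcurate_undefined_agreement")
})

test_that("both coefficients match independent pair-counting oracles on random tables", {
  set.seed(101)
  for (rep in 1:10) {
    n_items <- sample(5:15, 1)
    n_raters <- sample(2:6, 1)
    ratings <- replicate(n_items,
                         sample(c("TRUE", "FALSE", "EXCLUDE"), n_raters,
                                replace = TRUE),
                         simplify = FALSE)
    tab <- t(vapply(ratings,
                    function(r) as.integer(table(factor(r, c("TRUE", "FALSE", "EXCLUDE")))),
                    integer(3)))
    if (length(unique(unlist(ratings))) < 2) next
    expect_equal(fleiss_kappa(tab), oracle_fleiss_kappa(ratings),
                 tolerance = 1e-12)
    expect_equal(krippendorff_alpha(tab), oracle_krippendorff_alpha(ratings),
                 tolerance = 1e-12)
  }
})

test_that("both coefficients are invariant to item order and category permutation", {
  set.seed(77)
  tab <- t(vapply(1:12, function(i) {
    as.integer(stats::rmultinom(1, 5, c(0.5, 0.3, 0.2)))
  }, integer(3)))
  k <- fleiss_kappa(tab)
  a <- krippendorff_alpha(tab)
  perm_items <- tab[sample(nrow(tab)), ]
  perm_cats <- tab[, c(3, 1, 2)]
  expect_equal(fleiss_kappa(perm_items), k)
  expect_equal(fleiss_kappa(perm_cats), k)
  expect_equal(krippendorff_alpha(perm_items), a)
  expect_equal(krippendorff_alpha(perm_cats), a)
})

test_that("alpha and kappa converge on complete designs and vanish for random raters", {
  pool <- lapply(1:21, function(i) worker_profile(sprintf("w%02d", i), 0.8))
  camp <- sample_campaign(
    campaign_config(n_items = 1000, n_workers = 21, assignments_per_item = 7,
                    seed = 21),
    profiles = pool
  )
  tab <- build_ratings_table(camp$votes, "CROWD")
  expect_lte(abs(krippendorff_alpha(tab) - fleiss_kappa(tab)), 0.01)

  random_pool <- lapply(1:15, function(i) {
    worker_profile(sprintf("m%02d", i), malicious = TRUE)
  })
  camp0 <- sample_campaign(
    campaign_config(n_items = 5000, n_workers = 15, assignments_per_item = 7,
                    seed = 99),
    profiles = random_pool
  )
  tab0 <- build_ratings_table(camp0$votes, "CROWD")
  expect_lte(abs(fleiss_kappa(tab0)), 0.02)
  expect_lte(abs(krippendorff_alpha(tab0)), 0.02)
})

test_that("qualitative banding follows the Landis-Koch scale with hedged boundaries", {
  expect_equal(qualitative_label(-0.5), "poor")
  expect_equal(qualitative_label(0.10), "slight")
  expect_equal(qualitative_label(0.20), "slight")
  expect_equal(qualitative_label(0.2050), "fair")
  expect_equal(qualitative_label(0.45), "moderate")
  expect_equal(qualitative_label(0.6549), "substantial")
  expect_equal(qualitative_label(0.80), "substantial")
  expect_equal(qualitative_label(0.95), "almost perfect")
  expect_error(qualitative_label(1.5), "\\[-1, 1\\]")

  # values within 0.005 of a cutoff report both adjacent bands
  expect_equal(qualitative_bands(0.2028), "slight to fair")
  expect_equal(qualitative_bands(0.2050), "slight to fair")
  expect_equal(qualitative_bands(0.6549), "substantial")
  expect_equal(qualitative_bands(0.45), "moderate")
})

test_that("the agreement report computes both metrics, deviation and diagnostics per group", {
  votes <- fixture_votes()
  extra <- tibble::tibble(relation_id = c("r1", "r2", "r3"),
                          answer = c("TRUE", "FALSE", "EXCLUDE"))
  merged <- merge_rater(votes, extra, "EXTRA_RATER")
  merged <- merge_rater(merged, extra, "EXPERT")
  report <- agreement_report(merged, groups = list(
    workers = "CROWD",
    `workers+extra` = c("CROWD", "EXTRA_RATER"),
    `extra+expert` = c("EXTRA_RATER", "EXPERT")
  ))
  expect_equal(nrow(report), 3)
  expect_equal(report$raters_per_item, c(7, 8, 2))
  expect_equal(report$deviation, abs(report$krippendorff_alpha -
                                       report$fleiss_kappa))
  expect_true(all(report$status == "ok"))
  # the two-rater group here agrees perfectly with itself
  expect_equal(report$fleiss_kappa[3], 1)
  expect_equal(report$krippendorff_alpha[3], 1)
  expect_equal(report$qualitative[3], "almost perfect")

  unanimous <- vote_set(tibble::tibble(
    relation_id = rep(c("x", "y"), each = 2),
    worker_id = rep(c("a", "b"), 2),
    answer = "TRUE", work_time = 1, rater_source = "CROWD"
  ))
  rep0 <- agreement_report(unanimous, groups = list(workers = "CROWD"))
  expect_equal(rep0$status, "undefined")
  expect_true(is.na(rep0$fleiss_kappa))
})
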