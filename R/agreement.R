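#' Build an items-by-categories ratings table
#'
#' Tabulates a rater group's votes into the N x K count matrix consumed by
#' the agreement coefficients: `counts[i, j]` is the number of selected
#' raters assigning category `j` to relation `i`.
#'
#' @param votes A [vote_set()].
#' @param sources Character vector of rater sources defining the group
#'   (e.g. `"CROWD"`, or `c("CROWD", "EXTRA_RATER")`, or
#'   `c("EXTRA_RATER", "EXPERT")`).
#' @param categories Category order of the columns.
#' @param fixed Require a complete design (every item rated by the same
#'   number of raters, as Fleiss' kappa assumes)? If `TRUE`, unequal row
#'   sums raise an error naming the offending items.
#' @return An integer matrix of class `ratings_table` with relation ids as
#'   row names and a `raters_per_item` attribute (scalar when fixed, vector
#'   otherwise).
#' @export
build_ratings_table <- function(votes, sources = "CROWD",
                                categories = REL_LABELS, fixed = TRUE) {
  sel <- votes[votes$rater_source %in% sources, ]
  if (nrow(sel) == 0) {
    abort("no votes match the requested rater sources")
  }
  tab <- table(factor(sel$relation_id, unique(sel$relation_id)),
               factor(sel$answer, categories))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = dimnames(tab))
  m_i <- rowSums(counts)
  if (fixed) {
    if (length(unique(m_i)) > 1) {
      off <- names(m_i)[m_i != max(m_i)]
      abort(sprintf(
        "unequal rater counts per item in a fixed-design table; offending items: %s%s",
        paste(head(off, 10), collapse = ", "),
        if (length(off) > 10) sprintf(" (and %d more)", length(off) - 10) else ""
      ))
    }
    if (m_i[1] < 2) {
      abort("fixed-design agreement needs at least 2 raters per item")
    }
    attr(counts, "raters_per_item") <- unname(m_i[1])
  } else {
    attr(counts, "raters_per_item") <- unname(m_i)
  }
  class(counts) <- c("ratings_table", class(counts))
  counts
}

undefined_agreement <- function(metric) {
  abort(
    sprintf("%s is undefined: all ratings fall in a single category (no chance-corrected agreement exists)", metric),
    class = "crowdcurate_undefined_agreement"
  )
}

#' Fleiss' kappa for a complete nominal design
#'
#' Chance-corrected agreement for N items each rated by the same n raters
#' over K nominal categories. Per-item agreement is the fraction of
#' concordant rater pairs, expected agreement is the sum of squared marginal
#' category proportions, and kappa is the usual normalised excess
#' `(Pbar - Pe) / (1 - Pe)`.
#'
#' @param table A [build_ratings_table()] matrix (or any N x K count matrix
#'   with constant row sums >= 2).
#' @return Kappa in `[-1, 1]`. When every rating falls in a single category
#'   the coefficient has no defined value and a classed error
#'   (`crowdcurate_undefined_agreement`) is signalled rather than a silent
#'   `NaN`.
#' @export
fleiss_kappa <- function(table) {
  counts <- unclass(table)
  n_i <- rowSums(counts)
  if (length(unique(n_i)) > 1) {
    abort("Fleiss' kappa requires the same number of raters for every item")
  }
  n <- n_i[1]
  if (n < 2) {
    abort("Fleiss' kappa requires at least 2 raters per item")
  }
  N <- nrow(counts)
  p_j <- colSums(counts) / (N * n)
  P_e <- sum(p_j^2)
  if (abs(1 - P_e) < 1e-12) {
    undefined_agreement("Fleiss' kappa")
  }
  P_i <- (rowSums(counts^2) - n) / (n * (n - 1))
  (mean(P_i) - P_e) / (1 - P_e)
}

#' Krippendorff's alpha for nominal data
#'
#' Agreement coefficient tolerating missing ratings and variable rater
#' counts, computed from the coincidence matrix: items with fewer than two
#' ratings are ignored, each remaining item contributes its rating pairs
#' weighted by `1 / (m_i - 1)`, and
#' `alpha = (A_o - A_e) / (1 - A_e)` with observed agreement `A_o` the
#' diagonal mass of the coincidence matrix and expected agreement `A_e`
#' from the pooled category totals.
#'
#' @param ratings Either a `ratings_table` count matrix (possibly ragged row
#'   sums) or a list of per-item rating vectors.
#' @param categories Category space (used when `ratings` is a list).
#' @return Alpha (at most 1; 1 on perfect agreement). Signals a classed
#'   error (`crowdcurate_undefined_agreement`) when no chance disagreement
#'   exists (single category) and an error when no item has two ratings.
#' @export
krippendorff_alpha <- function(ratings, categories = REL_LABELS) {
  counts <- if (is.list(ratings) && !is.data.frame(ratings)) {
    t(vapply(ratings,
             function(r) as.integer(table(factor(r, categories))),
             integer(length(categories))))
  } else {
    unclass(ratings)
  }
  m_i <- rowSums(counts)
  counts <- counts[m_i >= 2, , drop = FALSE]
  m_i <- m_i[m_i >= 2]
  if (nrow(counts) == 0) {
    abort("Krippendorff's alpha needs at least one item with two or more ratings")
  }
  # coincidence matrix: within each item, every ordered pair of ratings,
  # weighted by 1/(m_i - 1)
  n_c <- colSums(counts)
  n <- sum(n_c)
  o_diag <- colSums(counts * (counts - 1) / (m_i - 1))
  A_o <- sum(o_diag) / n
  A_e <- sum(n_c * (n_c - 1)) / (n * (n - 1))
  if (abs(1 - A_e) < 1e-12) {
    undefined_agreement("Krippendorff's alpha")
  }
  (A_o - A_e) / (1 - A_e)
}

#' Landis-Koch qualitative band for a kappa-type coefficient
#'
#' Maps an agreement coefficient onto the conventional qualitative scale:
#' below 0 poor, 0-0.20 slight, 0.20-0.40 fair, 0.40-0.60 moderate,
#' 0.60-0.80 substantial, above 0.80 almost perfect (upper bounds
#' inclusive).
#'
#' @param value Coefficient in `[-1, 1]`.
#' @return One of `"poor"`, `"slight"`, `"fair"`, `"moderate"`,
#'   `"substantial"`, `"almost perfect"`.
#' @seealso [qualitative_bands()] for boundary-aware labelling.
#' @export
qualitative_label <- function(value) {
  if (!is.numeric(value) || is.na(value) || value < -1 || value > 1) {
    abort("agreement value must be a number in [-1, 1]")
  }
  if (value < 0) "poor"
  else if (value <= 0.20) "slight"
  else if (value <= 0.40) "fair"
  else if (value <= 0.60) "moderate"
  else if (value <= 0.80) "substantial"
  else "almost perfect"
}

#' Qualitative band(s), hedging near scale boundaries
#'
#' A coefficient sitting within `slack` of a band boundary is reported with
#' both adjacent bands (e.g. 0.2028 as "slight to fair"), since the scale's
#' cutoffs are conventional rather than substantive.
#'
#' @param value Coefficient in `[-1, 1]`.
#' @param slack Half-width of the boundary zone.
#' @return A single string: either one band or `"<band> to <band>"`.
#' @export
qualitative_bands <- function(value, slack = 0.005) {
  bounds <- c(0, 0.20, 0.40, 0.60, 0.80)
  own <- qualitative_label(value)
  near <- bounds[abs(value - bounds) <= slack + 1e-12]
  if (length(near) == 0) {
    return(own)
  }
  lo <- qualitative_label(max(near[1] - slack, -1))
  hi <- qualitative_label(min(near[1] + slack, 1))
  if (lo == hi) own else paste(lo, "to", hi)
}

#' Inter-rater agreement report over rater groups
#'
#' Computes both coefficients for each requested rater group, the absolute
#' deviation between them (a small deviation supports an unbiased
#' estimate), the qualitative band, and rater-overlap diagnostics (number
#' of distinct raters and mean ratings per rater) — relevant because
#' neither coefficient's sampling assumptions exactly match a crowd design
#' where a small worker pool rates overlapping item subsets.
#'
#' @param votes A [vote_set()].
#' @param groups Named list of rater-source vectors, e.g.
#'   `list(workers = "CROWD", "workers+extra" = c("CROWD", "EXTRA_RATER"))`.
#' @return A tibble with one row per group: item and rater counts, both
#'   coefficients (`NA` with status `"undefined"` in the degenerate
#'   single-category case), their absolute deviation and the qualitative
#'   band of kappa.
#' @export
agreement_report <- function(votes, groups = list(workers = "CROWD")) {
  if (is.null(names(groups)) || any(names(groups) == "")) {
    abort("groups must be a fully named list of rater-source vectors")
  }
  rows <- lapply(names(groups), function(gname) {
    sources <- groups[[gname]]
    sel <- votes[votes$rater_source %in% sources, ]
    tab <- build_ratings_table(votes, sources, fixed = FALSE)
    m_i <- attr(tab, "raters_per_item")
    complete <- tab[m_i == max(m_i), , drop = FALSE]
    kappa <- tryCatch(fleiss_kappa(complete),
                      crowdcurate_undefined_agreement = function(e) NA_real_)
    alpha <- tryCatch(krippendorff_alpha(tab),
                      crowdcurate_undefined_agreement = function(e) NA_real_)
    rater_ids <- sel$worker_id[!is.na(sel$worker_id)]
    tibble(
      group = gname,
      n_items = nrow(tab),
      n_items_complete = nrow(complete),
      raters_per_item = max(m_i),
      n_distinct_raters = length(unique(rater_ids)),
      ratings_per_rater = if (length(rater_ids) > 0) {
        round_half_up(length(rater_ids) / length(unique(rater_ids)), 1)
      } else {
        NA_real_
      },
      fleiss_kappa = kappa,
      krippendorff_alpha = alpha,
      deviation = abs(alpha - kappa),
      status = if (is.na(kappa) || is.na(alpha)) "undefined" else "ok",
      qualitative = if (is.na(kappa)) NA_character_ else qualitative_bands(kappa)
    )
  })
  bind_rows(rows)
}
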