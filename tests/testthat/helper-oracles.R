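# Independent oracles, deliberately written in a different style from the
# package implementation so they can catch shared mistakes.

# Brute-force consensus rule on a count triple, transcribing the voting
# flowchart literally: exclusion wins at >= half the votes, then true needs
# a strict majority of all votes, everything else is false.
oracle_adjudicate <- function(n_true, n_false, n_exclude) {
  m <- n_true + n_false + n_exclude
  if (n_exclude * 2 >= m) {
    "EXCLUDE"
  } else if (n_true * 2 > m) {
    "TRUE"
  } else {
    "FALSE"
  }
}

# All count triples with m votes.
all_count_triples <- function(m) {
  grid <- expand.grid(n_true = 0:m, n_false = 0:m, n_exclude = 0:m)
  grid[rowSums(grid) == m, ]
}

# Fleiss' kappa by naive pair counting over raw per-item rating vectors:
# observed agreement is the fraction of concordant ordered rater pairs,
# chance agreement from pooled category proportions.
oracle_fleiss_kappa <- function(rating_lists) {
  n <- length(rating_lists[[1]])
  concordant <- vapply(rating_lists, function(r) {
    pairs <- 0
    for (i in seq_along(r)) {
      for (j in seq_along(r)) {
        if (i != j && r[i] == r[j]) pairs <- pairs + 1
      }
    }
    pairs / (n * (n - 1))
  }, numeric(1))
  pooled <- table(unlist(rating_lists))
  p <- pooled / sum(pooled)
  pe <- sum(p^2)
  (mean(concordant) - pe) / (1 - pe)
}

# Krippendorff's nominal alpha by explicit pair enumeration.
oracle_krippendorff_alpha <- function(rating_lists) {
  rating_lists <- Filter(function(r) length(r) >= 2, rating_lists)
  values <- unlist(rating_lists)
  cats <- sort(unique(values))
  o <- matrix(0, length(cats), length(cats), dimnames = list(cats, cats))
  for (r in rating_lists) {
    m <- length(r)
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i != j) {
          o[r[i], r[j]] <- o[r[i], r[j]] + 1 / (m - 1)
        }
      }
    }
  }
  n_c <- rowSums(o)
  n <- sum(n_c)
  d_o <- sum(o) - sum(diag(o))
  d_e <- (sum(outer(n_c, n_c)) - sum(n_c^2)) * 1 / (n - 1)
  1 - d_o / d_e
}

# Truncated mean of a lognormal on [0, cutoff] by numerical integration.
oracle_truncated_lnorm_mean <- function(meanlog, sdlog, cutoff) {
  num <- stats::integrate(function(x) x * stats::dlnorm(x, meanlog, sdlog),
                          0, cutoff, rel.tol = 1e-10)$value
  den <- stats::plnorm(cutoff, meanlog, sdlog)
  num / den
}
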