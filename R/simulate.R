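#' Worker reliability profile
#'
#' Generative model of one crowd worker: a 3x3 row-stochastic confusion
#' matrix giving the probability of each emitted label conditional on the
#' item's latent label, and a work-time model — lognormal "genuine"
#' judgment times plus a rare long-break component (workers occasionally
#' leave a task open for hours, producing the heavy upper tail seen in real
#' platform exports).
#'
#' @param worker_id Worker identifier.
#' @param accuracy Probability of emitting the latent label; the remaining
#'   mass is split evenly over the other two labels. Ignored when
#'   `confusion` is supplied.
#' @param confusion Optional explicit 3x3 confusion matrix (rows = latent
#'   `TRUE`/`FALSE`/`EXCLUDE`, columns = emitted label).
#' @param malicious If `TRUE`, the worker answers uniformly at random
#'   regardless of the latent label.
#' @param time_meanlog,time_sdlog Lognormal parameters of genuine judgment
#'   time in seconds (defaults give a ~11 s mode, ~13 s mean).
#' @param break_prob Probability an assignment includes a mid-task break.
#' @param break_scale Mean break duration in seconds (exponential).
#' @return A list of class `worker_profile`.
#' @export
worker_profile <- function(worker_id, accuracy = 0.8, confusion = NULL,
                           malicious = FALSE, time_meanlog = 2.4,
                           time_sdlog = 0.6, break_prob = 0.005,
                           break_scale = 3000) {
  if (malicious) {
    confusion <- matrix(1 / 3, 3, 3)
  } else if (is.null(confusion)) {
    off <- (1 - accuracy) / 2
    confusion <- matrix(off, 3, 3)
    diag(confusion) <- accuracy
  }
  confusion <- as.matrix(confusion)
  dimnames(confusion) <- list(REL_LABELS, REL_LABELS)
  if (any(confusion < 0) || any(abs(rowSums(confusion) - 1) > 1e-9)) {
    abort("confusion rows must be non-negative and sum to 1")
  }
  structure(
    list(worker_id = as.character(worker_id), confusion = confusion,
         malicious = malicious, time_meanlog = time_meanlog,
         time_sdlog = time_sdlog, break_prob = break_prob,
         break_scale = break_scale),
    class = "worker_profile"
  )
}

#' Default worker pool
#'
#' A pool with mixed reliability — accuracies drawn from {0.6, 0.8, 0.95}
#' — and a small malicious fraction answering uniformly at random. Real
#' campaigns provide no worker reliability estimates, so these defaults are
#' placeholders for exercising the pipeline, not calibrated values.
#'
#' @param n_workers Pool size.
#' @param seed Seed for the accuracy/malice draw.
#' @param accuracies Candidate accuracies for genuine workers.
#' @param malicious_frac Expected fraction of malicious workers.
#' @return List of [worker_profile()]s.
#' @export
default_worker_pool <- function(n_workers, seed = 1L,
                                accuracies = c(0.6, 0.8, 0.95),
                                malicious_frac = 0.05) {
  with_seed(seed, {
    lapply(seq_len(n_workers), function(i) {
      worker_profile(
        worker_id = sprintf("W%03d", i),
        accuracy = sample(accuracies, 1),
        malicious = runif(1) < malicious_frac
      )
    })
  })
}

#' Campaign configuration
#'
#' The design of a simulated crowdsourcing campaign: number of items, the
#' latent distribution over {true, false, exclude-worthy}, the worker pool
#' size, and assignments per item (each item rated by that many *distinct*
#' workers, as the platform guarantees). Defaults mirror the multi-judgment
#' task of a corpus-validation campaign: seven distinct workers per item
#' from a 33-worker pool, with the latent mix set to expert-judged
#' proportions (about 54% true, 14% false, 32% exclude-worthy).
#'
#' @param n_items Number of items.
#' @param latent_distribution Probabilities of latent
#'   `TRUE`/`FALSE`/`EXCLUDE`, summing to 1.
#' @param n_workers Worker pool size; must be at least
#'   `assignments_per_item`.
#' @param assignments_per_item Distinct workers per item.
#' @param seed Master seed.
#' @return A list of class `campaign_config`.
#' @export
campaign_config <- function(n_items = 100L,
                            latent_distribution = c("TRUE" = 0.536,
                                                    "FALSE" = 0.144,
                                                    "EXCLUDE" = 0.320),
                            n_workers = 33L, assignments_per_item = 7L,
                            seed = 1L) {
  if (n_workers < assignments_per_item) {
    abort("n_workers must be >= assignments_per_item (distinct workers per item)")
  }
  if (length(latent_distribution) != 3 ||
      abs(sum(latent_distribution) - 1) > 1e-9 ||
      any(latent_distribution < 0)) {
    abort("latent_distribution must be 3 non-negative probabilities summing to 1")
  }
  names(latent_distribution) <- REL_LABELS
  structure(
    list(n_items = as.integer(n_items),
         latent_distribution = latent_distribution,
         n_workers = as.integer(n_workers),
         assignments_per_item = as.integer(assignments_per_item),
         seed = as.integer(seed)),
    class = "campaign_config"
  )
}

#' Simulate a crowdsourcing campaign
#'
#' Draws a latent label per item, assigns `assignments_per_item` distinct
#' workers sampled uniformly from the pool, and emits each worker's vote
#' from their confusion row and a work time from their time model. Seeding
#' is split per item from the master seed, so any item's draw is
#' reproducible in isolation.
#'
#' @param config A [campaign_config()].
#' @param profiles Worker pool (list of [worker_profile()]s, length
#'   `config$n_workers`); defaults to [default_worker_pool()].
#' @param seed Overrides `config$seed` when given.
#' @return A list of class `campaign`: `truth` (tibble `relation_id`,
#'   `latent`), `votes` (a [vote_set()] with `CROWD` source) and
#'   `profiles`.
#' @export
sample_campaign <- function(config, profiles = NULL, seed = NULL) {
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  if (is.null(profiles)) {
    profiles <- default_worker_pool(config$n_workers, seed = seed)
  }
  if (length(profiles) != config$n_workers) {
    abort("profiles must have length n_workers")
  }
  n <- config$n_items
  a <- config$assignments_per_item
  item_seeds <- split_seed(seed, n + 1L)
  latent <- with_seed(item_seeds[n + 1L], {
    sample(REL_LABELS, n, replace = TRUE, prob = config$latent_distribution)
  })
  ids <- sprintf("R%05d", seq_len(n))
  per_item <- lapply(seq_len(n), function(i) {
    with_seed(item_seeds[i], {
      widx <- sample.int(config$n_workers, a)
      answers <- character(a)
      times <- numeric(a)
      for (k in seq_len(a)) {
        p <- profiles[[widx[k]]]
        answers[k] <- sample(REL_LABELS, 1, prob = p$confusion[latent[i], ])
        t <- rlnorm(1, p$time_meanlog, p$time_sdlog)
        if (runif(1) < p$break_prob) {
          t <- t + rexp(1, 1 / p$break_scale)
        }
        times[k] <- t
      }
      tibble(
        relation_id = ids[i],
        worker_id = vapply(profiles[widx], `[[`, character(1), "worker_id"),
        answer = answers,
        work_time = times,
        rater_source = "CROWD"
      )
    })
  })
  structure(
    list(
      truth = tibble(relation_id = ids, latent = latent),
      votes = vote_set(bind_rows(per_item)),
      profiles = profiles
    ),
    class = "campaign"
  )
}

#' Generate a synthetic relation corpus
#'
#' Builds a corpus of template sentences with consistent phenotype and gene
#' mention offsets and KNOWN/UNKNOWN original labels, for exercising the
#' corpus pipeline at arbitrary size without any real data. Synthetic
#' throughout — sentences, identifiers and PubMed ids are fabricated.
#'
#' @param n_known,n_unknown Number of knowledge-base-supported (`KNOWN`)
#'   and unsupported (`UNKNOWN`) relations.
#' @param seed Seed for the label shuffle and PubMed-id assignment.
#' @param relations_per_abstract Average number of relations sharing one
#'   synthetic PubMed id.
#' @return A `relation_corpus` of `n_known + n_unknown` instances.
#' @export
synthetic_corpus <- function(n_known, n_unknown = 0L, seed = 1L,
                             relations_per_abstract = 3) {
  n <- n_known + n_unknown
  if (n == 0) {
    return(relation_corpus(tibble(
      relation_id = character(), pmid = character(), sentence = character(),
      phen_text = character(), phen_start = integer(), phen_end = integer(),
      phen_id = character(), gene_text = character(), gene_start = integer(),
      gene_end = integer(), gene_id = character(),
      original_label = character(), revised_label = character()
    ), metadata = list(synthetic = TRUE)))
  }
  with_seed(seed, {
    i <- seq_len(n)
    gene_text <- sprintf("GENE%d", i)
    phen_text <- sprintf("phenotype %d", i)
    sentence <- sprintf("Mutations in %s are associated with %s in patients.",
                        gene_text, phen_text)
    gene_start <- rep(13L, n)
    gene_end <- gene_start + nchar(gene_text)
    phen_start <- gene_end + 21L
    phen_end <- phen_start + nchar(phen_text)
    n_abs <- max(1L, ceiling(n / relations_per_abstract))
    pmid <- sprintf("3%07d", sample.int(n_abs, n, replace = TRUE))
    labels <- sample(rep(c("KNOWN", "UNKNOWN"), c(n_known, n_unknown)))
    relation_corpus(tibble(
      relation_id = sprintf("SR%06d", i),
      pmid = pmid,
      sentence = sentence,
      phen_text = phen_text, phen_start = phen_start, phen_end = phen_end,
      phen_id = sprintf("HP:%07d", i),
      gene_text = gene_text, gene_start = gene_start, gene_end = gene_end,
      gene_id = sprintf("%d", 100000 + i),
      original_label = labels,
      revised_label = NA_character_
    ), metadata = list(synthetic = TRUE, seed = seed))
  })
}

#' Expected consensus accuracy under homogeneous binary workers
#'
#' Exact probability that majority consensus recovers the latent label when
#' every worker answers the correct binary label (true/false, never
#' exclude) with probability `theta`, for an odd number of assignments:
#' enumeration over all binomial vote outcomes, with the consensus rule
#' reducing to strict majority in the binary restriction. Quantifies the
#' quality gain of multiple assignments over a single judgment.
#'
#' @param theta Per-worker probability of the correct label, in (0, 1].
#' @param a Odd number of assignments per item.
#' @param policy An [adjudication_policy()]; both true-label rules coincide
#'   with strict majority in the binary odd-`a` setting.
#' @return The exact consensus accuracy.
#' @export
expected_consensus_accuracy <- function(theta, a,
                                        policy = adjudication_policy()) {
  if (a %% 2 == 0) {
    abort("a must be odd: with an even assignment count, binary ties change the consensus semantics")
  }
  if (theta <= 0 || theta > 1) {
    abort("theta must be in (0, 1]")
  }
  k <- seq((a + 1) / 2, a)
  sum(dbinom(k, a, theta))
}

#' End-to-end parameter recovery check for a simulated campaign
#'
#' Simulates a campaign, adjudicates it, and compares (i) the empirical
#' consensus accuracy against latent truth — with the exact enumeration
#' value and a 95% binomial confidence interval when the pool is
#' homogeneous and binary — and (ii) the empirical agreement coefficients
#' against Monte-Carlo reference values from an independent re-simulation
#' with `ref_multiplier` times as many items.
#'
#' @param config A [campaign_config()].
#' @param profiles Worker pool; defaults to [default_worker_pool()].
#' @param seed Master seed (defaults to `config$seed`).
#' @param policy An [adjudication_policy()].
#' @param ref_multiplier Size factor of the reference re-simulation.
#' @return A list of class `recovery_report`: `accuracy` (empirical, CI,
#'   exact oracle value when applicable), `agreement` (empirical and
#'   reference kappa/alpha and their differences), and the campaign sizes.
#' @export
recover_parameters_check <- function(config, profiles = NULL, seed = NULL,
                                     policy = adjudication_policy(),
                                     ref_multiplier = 10) {
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  if (is.null(profiles)) {
    profiles <- default_worker_pool(config$n_workers, seed = seed)
  }
  camp <- sample_campaign(config, profiles, seed = seed)
  adj <- as_tibble(camp$votes) %>%
    group_by(.data$relation_id) %>%
    summarise(label = adjudicate(.data$answer, policy)$label)
  truth <- camp$truth
  hits <- sum(adj$label[match(truth$relation_id, adj$relation_id)] ==
                truth$latent)
  n <- nrow(truth)
  ci <- stats::binom.test(hits, n)$conf.int
  # homogeneous binary pool -> the enumeration oracle applies exactly
  confusions <- lapply(profiles, `[[`, "confusion")
  binary <- all(vapply(confusions, function(cm) {
    all(cm[c("TRUE", "FALSE"), "EXCLUDE"] == 0)
  }, logical(1)))
  thetas <- vapply(confusions, function(cm) cm["TRUE", "TRUE"], numeric(1))
  homogeneous <- binary && length(unique(thetas)) == 1 &&
    all(vapply(confusions, function(cm) {
      cm["TRUE", "TRUE"] == cm["FALSE", "FALSE"]
    }, logical(1)))
  expected <- if (homogeneous && config$assignments_per_item %% 2 == 1) {
    expected_consensus_accuracy(thetas[1], config$assignments_per_item, policy)
  } else {
    NA_real_
  }
  tab <- build_ratings_table(camp$votes, "CROWD", fixed = TRUE)
  kappa <- tryCatch(fleiss_kappa(tab),
                    crowdcurate_undefined_agreement = function(e) NA_real_)
  alpha <- tryCatch(krippendorff_alpha(tab),
                    crowdcurate_undefined_agreement = function(e) NA_real_)
  ref_config <- config
  ref_config$n_items <- as.integer(config$n_items * ref_multiplier)
  ref <- sample_campaign(ref_config, profiles, seed = seed + 1L)
  ref_tab <- build_ratings_table(ref$votes, "CROWD", fixed = TRUE)
  ref_kappa <- tryCatch(fleiss_kappa(ref_tab),
                        crowdcurate_undefined_agreement = function(e) NA_real_)
  ref_alpha <- tryCatch(krippendorff_alpha(ref_tab),
                        crowdcurate_undefined_agreement = function(e) NA_real_)
  structure(
    list(
      accuracy = list(
        empirical = hits / n,
        ci95 = ci,
        expected = expected,
        within_ci = if (is.na(expected)) NA else
          expected >= ci[1] && expected <= ci[2]
      ),
      agreement = list(
        fleiss_kappa = kappa, krippendorff_alpha = alpha,
        ref_fleiss_kappa = ref_kappa, ref_krippendorff_alpha = ref_alpha,
        kappa_diff = abs(kappa - ref_kappa),
        alpha_diff = abs(alpha - ref_alpha)
      ),
      n_items = n,
      n_reference_items = ref_config$n_items
    ),
    class = "recovery_report"
  )
}
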