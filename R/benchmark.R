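# Statistical machinery for blinded model comparison: paired bootstrap Bayes
# factors, the ladder submission protocol, permutation nulls, and the
# replicate-measurement upper bound on achievable accuracy.

.metric_higher_better <- c(
  spearman = TRUE, pearson = TRUE, ci = TRUE, f1 = TRUE, avg_auc = TRUE,
  rmse = FALSE
)

metric_fun <- function(metric) {
  switch(metric,
    rmse = function(f, y) sqrt(mean((f - y)^2)),
    pearson = function(f, y) suppressWarnings(cor(f, y)),
    spearman = function(f, y) suppressWarnings(cor(f, y, method = "spearman")),
    ci = function(f, y) tryCatch(concordance_index(f, y), error = function(e) NA_real_),
    f1 = function(f, y) f1_score(f, y),
    avg_auc = function(f, y) tryCatch(average_auc(f, y), error = function(e) NA_real_),
    abort(sprintf("Unknown metric '%s'.", metric))
  )
}

check_metric <- function(metric) {
  if (!metric %in% names(.metric_higher_better)) {
    abort(sprintf("`metric` must be one of %s.",
                  paste(names(.metric_higher_better), collapse = ", ")))
  }
  metric
}

#' Paired bootstrap comparison of two prediction sets with a Bayes factor
#'
#' Both prediction sets are scored on `n_boot` bootstrap resamples of the
#' measured pairs (the same resample indices are applied to both sets — a
#' paired design). Per iteration the better score wins in the metric's
#' favorable direction (higher for correlations/CI/F1/AUC, lower for RMSE);
#' the Bayes factor is the win-count ratio with ties split evenly:
#' K = (wins_ref + ties/2) / (wins_cand + ties/2), so K > 1 favors the
#' reference set `pred_ref` and identical sets give exactly K = 1.
#' A zero denominator reports K = Inf.
#'
#' @param pred_cand,pred_ref Candidate and reference prediction tibbles
#'   covering the measured pairs (`pred_ref` is the set K counts evidence
#'   for).
#' @param measured Interaction table of measured pKd values.
#' @param metric One of `"rmse"`, `"pearson"`, `"spearman"`, `"ci"`, `"f1"`,
#'   `"avg_auc"`.
#' @param n_boot Number of bootstrap iterations (default 10000).
#' @param seed Integer seed; identical seeds reproduce identical comparisons.
#' @return A `"bootstrap_comparison"` object with per-iteration scores, win
#'   counts and `bayes_factor`; `tidy()` gives the per-iteration score
#'   tibble, `glance()` the summary row.
#' @export
bootstrap_compare <- function(pred_cand, pred_ref, measured,
                              metric = "spearman", n_boot = 10000, seed = 1) {
  check_metric(metric)
  if (n_boot < 1) abort("`n_boot` must be at least 1.")
  ja <- join_pred_measured(pred_cand, measured)
  jb <- join_pred_measured(pred_ref, measured)
  jb <- jb[match(pair_key(ja$compound_id, ja$protein_id),
                 pair_key(jb$compound_id, jb$protein_id)), , drop = FALSE]
  if (anyNA(jb$pkd_pred)) abort("The two prediction sets cover different pair sets.")
  y <- ja$pkd
  fa <- ja$pkd_pred
  fb <- jb$pkd_pred
  n <- length(y)
  fun <- metric_fun(metric)
  higher <- .metric_higher_better[[metric]]

  scores <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      c(fun(fa[idx], y[idx]), fun(fb[idx], y[idx]))
    }, numeric(2))
  })
  sa <- scores[1, ]
  sb <- scores[2, ]
  # an iteration where either score is undefined (e.g. zero-variance resample)
  # carries no evidence either way: count it as a tie
  undecided <- is.na(sa) | is.na(sb) | sa == sb
  cand_better <- !undecided & (if (higher) sa > sb else sa < sb)
  wins_cand <- sum(cand_better)
  wins_ref <- sum(!undecided & !cand_better)
  ties <- sum(undecided)
  num <- wins_ref + ties / 2
  den <- wins_cand + ties / 2
  structure(
    list(
      metric = metric,
      n_boot = n_boot,
      seed = seed,
      scores_cand = sa,
      scores_ref = sb,
      wins_cand = wins_cand,
      wins_ref = wins_ref,
      ties = ties,
      bayes_factor = if (den == 0) Inf else num / den
    ),
    class = "bootstrap_comparison"
  )
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_comparison> %s, %d iterations: ref wins %d, candidate wins %d, ties %d; K = %s\n",
    x$metric, x$n_boot, x$wins_ref, x$wins_cand, x$ties,
    if (is.infinite(x$bayes_factor)) "inf" else sprintf("%.3g", x$bayes_factor)
  ))
  invisible(x)
}

#' @rdname bootstrap_compare
#' @param x A `"bootstrap_comparison"` object.
#' @param ... Unused.
#' @export
tidy.bootstrap_comparison <- function(x, ...) {
  tibble(
    iteration = seq_len(x$n_boot),
    score_cand = x$scores_cand,
    score_ref = x$scores_ref
  )
}

#' @rdname bootstrap_compare
#' @export
glance.bootstrap_comparison <- function(x, ...) {
  tibble(
    metric = x$metric, n_boot = x$n_boot,
    wins_cand = x$wins_cand, wins_ref = x$wins_ref, ties = x$ties,
    bayes_factor = x$bayes_factor
  )
}

#' @rdname bootstrap_compare
#' @param object A `"bootstrap_comparison"` object.
#' @export
autoplot.bootstrap_comparison <- function(object, ...) {
  dat <- tidyr::pivot_longer(tidy(object), -"iteration",
                             names_to = "model", values_to = "score")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$score, fill = .data$model)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 50) +
    ggplot2::labs(
      x = object$metric, y = "bootstrap iterations",
      title = sprintf("Paired bootstrap (K = %.3g favoring reference)", object$bayes_factor)
    ) +
    ggplot2::theme_minimal()
}

#' Ladder protocol: accept a resubmission only if substantially better
#'
#' Anti-overfitting submission rule for blinded leaderboards: the first
#' submission is always accepted; a later one is accepted only when the
#' paired bootstrap Bayes factor favors the candidate over the previous
#' submission with K > `k_threshold` (default 3, "substantially better").
#'
#' @param previous Previously accepted prediction tibble, or `NULL` for the
#'   first submission.
#' @param candidate Candidate prediction tibble.
#' @inheritParams bootstrap_compare
#' @param k_threshold Bayes-factor acceptance threshold.
#' @return A list with `accepted` (logical), `bayes_factor` (NA for a first
#'   submission) and the underlying `comparison`.
#' @export
ladder_update <- function(previous, candidate, measured, metric = "spearman",
                          n_boot = 10000, seed = 1, k_threshold = 3) {
  if (is.null(previous)) {
    return(list(accepted = TRUE, bayes_factor = NA_real_, comparison = NULL))
  }
  # candidate as the reference: K > threshold means evidence for the candidate
  cmp <- bootstrap_compare(previous, candidate, measured,
                           metric = metric, n_boot = n_boot, seed = seed)
  list(
    accepted = cmp$bayes_factor > k_threshold,
    bayes_factor = cmp$bayes_factor,
    comparison = cmp
  )
}

#' Permutation null distribution for a scoring metric
#'
#' Shuffles the measured pKd values across the pair set `n_perm` times,
#' scoring each shuffled vector as a "prediction" against the original
#' measurements — the distribution of scores achievable by chance. The
#' observed prediction's empirical p is the fraction of null scores at least
#' as favorable; a prediction is flagged better than random when it beats
#' every permutation (empirical p = 0).
#'
#' @param pred Prediction tibble whose score is being calibrated.
#' @inheritParams bootstrap_compare
#' @param n_perm Number of permutations (default 10000).
#' @return A `"null_distribution"` object with `values`, `observed`,
#'   `empirical_p` and `better_than_random`.
#' @export
permutation_null <- function(pred, measured, metric = "spearman",
                             n_perm = 10000, seed = 1) {
  check_metric(metric)
  assert_interactions(measured, "measured")
  if (nrow(measured) < 2) abort("Permutation null needs at least 2 pairs.")
  joined <- join_pred_measured(pred, measured)
  y <- joined$pkd
  fun <- metric_fun(metric)
  higher <- .metric_higher_better[[metric]]
  observed <- fun(joined$pkd_pred, y)
  values <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) fun(sample(y), y), numeric(1))
  })
  ok <- !is.na(values)
  favorable <- if (higher) values[ok] >= observed else values[ok] <= observed
  structure(
    list(
      metric = metric,
      n_perm = n_perm,
      seed = seed,
      values = values,
      observed = observed,
      empirical_p = mean(favorable),
      better_than_random = !any(favorable)
    ),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> %s over %d permutations: observed %.4f, empirical p = %.4g%s\n",
    x$metric, x$n_perm, x$observed, x$empirical_p,
    if (x$better_than_random) " (better than all permutations)" else ""
  ))
  invisible(x)
}

#' @rdname permutation_null
#' @param object A `"null_distribution"` object.
#' @param ... Unused.
#' @export
autoplot.null_distribution <- function(object, ...) {
  ggplot2::ggplot(tibble(value = object$values), ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(
      x = object$metric, y = "permutations",
      title = sprintf("Permutation null (empirical p = %.4g)", object$empirical_p)
    ) +
    ggplot2::theme_minimal()
}

#' Replicate-measurement upper bound on achievable accuracy
#'
#' Replicate pKd measurements of the same compound-kinase pairs from two
#' independent studies bound what any predictor can achieve. The replicate
#' pool is first composed to match a target fraction of pKd = 5 rows
#' (the inactive-at-ceiling stratum, rows at the censoring floor in both
#' studies) by subsampling that stratum; then `n_boot` resamples of size
#' `n_sub` (with replacement) are scored — Spearman correlation and RMSE
#' between the two studies' values — giving the distribution of the
#' practical upper bound.
#'
#' @param replicates Data frame with columns `pkd_study1`, `pkd_study2`
#'   (one row per replicated pair).
#' @param target_frac_pkd5 Target fraction of pKd = 5 rows in the pool
#'   (e.g. 0.35 or 0.25 to match a test set's censored fraction).
#' @param n_sub Resample size (typically the test-set size).
#' @param n_boot Number of resamplings (default 10000).
#' @param seed Integer seed.
#' @param censor_floor pKd value identifying the inactive stratum (default 5).
#' @return A `"replicate_bound"` object with a `draws` tibble
#'   (`spearman`, `rmse` per resampling) and the composed `pool`.
#' @export
replicate_bound <- function(replicates, target_frac_pkd5, n_sub,
                            n_boot = 10000, seed = 1, censor_floor = 5) {
  need <- c("pkd_study1", "pkd_study2")
  if (!all(need %in% names(replicates))) {
    abort("`replicates` needs columns pkd_study1 and pkd_study2.")
  }
  check_scalar_number(target_frac_pkd5, "target_frac_pkd5", 0, 1)
  inactive <- replicates$pkd_study1 == censor_floor & replicates$pkd_study2 == censor_floor
  active_rows <- replicates[!inactive, , drop = FALSE]
  inactive_rows <- replicates[inactive, , drop = FALSE]
  n_active <- nrow(active_rows)
  if (n_active == 0) abort("`replicates` has no active rows.")
  n_inactive_needed <- round(target_frac_pkd5 / (1 - target_frac_pkd5) * n_active)
  if (n_inactive_needed > nrow(inactive_rows)) {
    abort(sprintf(
      "Need %d pKd = %g rows for a %.0f%% inactive fraction but only %d available.",
      n_inactive_needed, censor_floor, 100 * target_frac_pkd5, nrow(inactive_rows)
    ))
  }
  draws_and_pool <- withr::with_seed(seed, {
    keep <- sample.int(nrow(inactive_rows), n_inactive_needed)
    pool <- bind_rows(active_rows, inactive_rows[keep, , drop = FALSE])
    draws <- map(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(pool), n_sub, replace = TRUE)
      x <- pool$pkd_study1[idx]
      z <- pool$pkd_study2[idx]
      tibble(
        spearman = suppressWarnings(cor(x, z, method = "spearman")),
        rmse = sqrt(mean((x - z)^2))
      )
    })
    list(pool = pool, draws = list_rbind(draws))
  })
  structure(
    list(
      draws = draws_and_pool$draws,
      pool = draws_and_pool$pool,
      target_frac_pkd5 = target_frac_pkd5,
      n_sub = n_sub,
      n_boot = n_boot,
      seed = seed
    ),
    class = "replicate_bound"
  )
}

#' @export
print.replicate_bound <- function(x, ...) {
  cat(sprintf(
    "<replicate_bound> pool %d pairs (%.0f%% at floor), %d resamples of %d:\n  Spearman %.3f [%.3f, %.3f], RMSE %.3f [%.3f, %.3f]\n",
    nrow(x$pool), 100 * x$target_frac_pkd5, x$n_boot, x$n_sub,
    median(x$draws$spearman), quantile(x$draws$spearman, 0.025), quantile(x$draws$spearman, 0.975),
    median(x$draws$rmse), quantile(x$draws$rmse, 0.025), quantile(x$draws$rmse, 0.975)
  ))
  invisible(x)
}

#' @rdname replicate_bound
#' @param x A `"replicate_bound"` object.
#' @param ... Unused.
#' @export
tidy.replicate_bound <- function(x, ...) x$draws

#' @rdname replicate_bound
#' @export
glance.replicate_bound <- function(x, ...) {
  tibble(
    spearman_median = median(x$draws$spearman),
    spearman_lo = quantile(x$draws$spearman, 0.025),
    spearman_hi = quantile(x$draws$spearman, 0.975),
    rmse_median = median(x$draws$rmse),
    rmse_lo = quantile(x$draws$rmse, 0.025),
    rmse_hi = quantile(x$draws$rmse, 0.975),
    n_pool = nrow(x$pool),
    n_boot = x$n_boot
  )
}
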