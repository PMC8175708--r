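# Ensembling of prediction sets: the 440-regressor grid ensemble, general
# aggregation rules, top-k curves and random-ensemble controls.

#' The default KronRLS grid ensemble specification
#'
#' The grid enumerates one conjugate-gradient KronRLS regressor per
#' combination of regularization strength, training-epoch cap and compound
#' kernel (a single protein kernel is shared). The default grid —
#' 5 regularization strengths (0.1, 0.5, 1.0, 1.5, 2.0) x 11 epoch caps
#' (400, 410, ..., 500) x 8 compound kernels — has exactly 440 members. The
#' canonical 8 compound kernels are Tanimoto and Dice similarities over
#' 1024-bit circular fingerprints at radius 2 and 3, with and without
#' chirality.
#'
#' @param compound_kernels List of [kernel_matrix()] objects (one per
#'   compound representation).
#' @param protein_kernel A single [kernel_matrix()].
#' @param lams Regularization strengths.
#' @param epoch_list Training-epoch caps.
#' @return A `"qed_grid"` object; `n_members()` gives its size.
#' @export
qed_grid <- function(compound_kernels = vector("list", 8), protein_kernel = NULL,
                     lams = c(0.1, 0.5, 1.0, 1.5, 2.0),
                     epoch_list = seq(400, 500, by = 10)) {
  if (length(compound_kernels) < 1) abort("At least one compound kernel is required.")
  if (length(lams) < 1 || length(epoch_list) < 1) {
    abort("`lams` and `epoch_list` must be non-empty.")
  }
  structure(
    list(
      compound_kernels = compound_kernels,
      protein_kernel = protein_kernel,
      lams = lams,
      epoch_list = epoch_list
    ),
    class = "qed_grid"
  )
}

#' @rdname qed_grid
#' @param grid A `"qed_grid"` object.
#' @export
n_members <- function(grid) {
  length(grid$lams) * length(grid$epoch_list) * length(grid$compound_kernels)
}

#' @export
print.qed_grid <- function(x, ...) {
  cat(sprintf("<qed_grid> %d lambdas x %d epoch caps x %d compound kernels = %d regressors\n",
              length(x$lams), length(x$epoch_list), length(x$compound_kernels), n_members(x)))
  invisible(x)
}

#' Fit the grid ensemble and predict test pairs
#'
#' Fits one [kronrls_cg()] regressor per grid member in deterministic
#' lexicographic order (compound kernel, then lambda, then epochs) and
#' returns the uniform (unweighted) mean of the members' predictions per
#' pair.
#'
#' @param grid A [qed_grid()] whose kernels cover all entities of `train`
#'   and `test_pairs`.
#' @param train Training interaction table.
#' @param test_pairs Data frame of pairs to predict
#'   (`compound_id`, `protein_id`).
#' @param tol CG residual tolerance passed to each member.
#' @return A prediction tibble with `model_id` attribute `"qed_ensemble"`.
#' @export
qed_ensemble <- function(grid, train, test_pairs, tol = 1e-8) {
  if (!inherits(grid, "qed_grid")) abort("`grid` must be a qed_grid object.")
  if (n_members(grid) < 1) abort("Empty ensemble grid.")
  if (any(vapply(grid$compound_kernels, is.null, logical(1))) || is.null(grid$protein_kernel)) {
    abort("The grid's kernels must be filled in before fitting.")
  }
  members <- tidyr::expand_grid(
    kernel_idx = seq_along(grid$compound_kernels),
    lam = grid$lams,
    epochs = grid$epoch_list
  )
  acc <- numeric(nrow(test_pairs))
  for (i in seq_len(nrow(members))) {
    model <- kronrls_cg(
      grid$compound_kernels[[members$kernel_idx[i]]], grid$protein_kernel,
      train, lambda = members$lam[i], epochs = members$epochs[i], tol = tol
    )
    acc <- acc + predict(model, test_pairs)$pkd_pred
  }
  out <- tibble(
    compound_id = test_pairs$compound_id,
    protein_id = test_pairs$protein_id,
    pkd_pred = acc / nrow(members)
  )
  attr(out, "model_id") <- "qed_ensemble"
  out
}

check_same_pairs <- function(sets) {
  if (length(sets) < 1) abort("At least one prediction set is required.")
  for (s in sets) assert_predictions(s)
  ref_keys <- sort(pair_key(sets[[1]]$compound_id, sets[[1]]$protein_id))
  for (i in seq_along(sets)[-1]) {
    keys <- sort(pair_key(sets[[i]]$compound_id, sets[[i]]$protein_id))
    if (!identical(ref_keys, keys)) {
      diff_keys <- union(setdiff(ref_keys, keys), setdiff(keys, ref_keys))
      abort(sprintf(
        "Prediction set %d covers a different pair set (%d mismatching pair(s), e.g. %s).",
        i, length(diff_keys), gsub("\r", "/", diff_keys[1])
      ))
    }
  }
  invisible(sets)
}

#' Aggregate prediction sets into an ensemble prediction
#'
#' Combines per-pair predictions across models by arithmetic mean, median or
#' rank weighting. For rank weighting the input order encodes the ranking
#' (first = rank 1 = best) and the weight of rank r among N sets is
#' N + 1 - r, so the output is the weighted mean with weights summing to
#' N(N+1)/2 — a convex combination bounded by the member min/max per pair.
#' Ties on the ranking score should be broken by earlier file order before
#' calling.
#'
#' @param sets List of prediction tibbles sharing an identical pair set.
#' @param method `"mean"`, `"median"` or `"rank_weighted"`.
#' @return A prediction tibble.
#' @export
aggregate_predictions <- function(sets, method = c("mean", "median", "rank_weighted")) {
  method <- match.arg(method)
  check_same_pairs(sets)
  base <- sets[[1]][, c("compound_id", "protein_id")]
  base_keys <- pair_key(base$compound_id, base$protein_id)
  mat <- vapply(sets, function(s) {
    s$pkd_pred[match(base_keys, pair_key(s$compound_id, s$protein_id))]
  }, numeric(nrow(base)))
  mat <- matrix(mat, nrow = nrow(base))
  n <- length(sets)
  value <- switch(method,
    mean = rowMeans(mat),
    median = apply(mat, 1, median),
    rank_weighted = {
      w <- n + 1 - seq_len(n)
      as.numeric(mat %*% w) / sum(w)
    }
  )
  out <- mutate(base, pkd_pred = value)
  attr(out, "model_id") <- paste0("ensemble_", method)
  out
}

#' Top-k ensemble curve
#'
#' Given prediction sets pre-ranked by a score (best first), mean-aggregates
#' the first k sets for k = 1..max_k and scores each ensemble (Spearman and
#' RMSE) against the measured values — the curve showing whether adding more
#' models helps or hurts.
#'
#' @param sets List of prediction tibbles, ranked best-first.
#' @param measured Interaction table covering the pair set.
#' @param max_k Largest ensemble size (defaults to all sets).
#' @return An `"ensemble_curve"` object; its `$curve` tibble has one row per
#'   k with `spearman` and `rmse`, and `$best_k` is the argmax-Spearman k.
#'   Plot with [autoplot()].
#' @export
topk_curve <- function(sets, measured, max_k = length(sets)) {
  check_same_pairs(sets)
  if (max_k > length(sets)) abort("`max_k` cannot exceed the number of sets.")
  if (max_k < 1) abort("`max_k` must be at least 1.")
  curve <- map(seq_len(max_k), function(k) {
    ens <- aggregate_predictions(sets[seq_len(k)], "mean")
    rep <- score_report(ens, measured)
    tibble(k = k, spearman = rep$spearman, rmse = rep$rmse)
  }) |> list_rbind()
  structure(
    list(curve = curve, best_k = curve$k[which.max(curve$spearman)]),
    class = "ensemble_curve"
  )
}

#' @export
print.ensemble_curve <- function(x, ...) {
  cat(sprintf("<ensemble_curve> k = 1..%d, best Spearman %.3f at k = %d\n",
              max(x$curve$k), max(x$curve$spearman), x$best_k))
  invisible(x)
}

#' @rdname topk_curve
#' @param object,x An `"ensemble_curve"` object.
#' @param ... Unused.
#' @export
autoplot.ensemble_curve <- function(object, ...) {
  dat <- tidyr::pivot_longer(object$curve, c("spearman", "rmse"),
                             names_to = "metric", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_k, linetype = "dashed", colour = "grey60") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "ensemble size k", y = NULL,
                  title = "Top-k mean-aggregation ensemble") +
    ggplot2::theme_minimal()
}

#' @rdname topk_curve
#' @export
tidy.ensemble_curve <- function(x, ...) x$curve

#' Random-ensemble control distribution
#'
#' Draws `n_draws` uniform k-subsets of the prediction sets (without
#' replacement within a draw), mean-aggregates and scores each, and reports
#' the empirical probability that a random k-ensemble matches or beats a
#' reference score — the control showing whether a top-k ensemble's
#' performance could arise by chance.
#'
#' @inheritParams topk_curve
#' @param k Ensemble size per draw.
#' @param n_draws Number of random ensembles (default 1000).
#' @param seed Integer seed.
#' @param reference_score Score of the reference ensemble to compare against
#'   (optional).
#' @param metric `"spearman"` or `"rmse"`.
#' @return A `"random_ensembles"` object with the draw scores and, when a
#'   reference is given, `empirical_p` = fraction of draws at least as good.
#' @export
random_ensembles <- function(sets, measured, k, n_draws = 1000, seed = 1,
                             reference_score = NULL, metric = "spearman") {
  check_same_pairs(sets)
  check_metric(metric)
  if (k > length(sets)) abort("`k` cannot exceed the number of sets.")
  if (k < 1) abort("`k` must be at least 1.")
  scores <- withr::with_seed(seed, {
    map_dbl(seq_len(n_draws), function(i) {
      members <- sample.int(length(sets), k)
      ens <- aggregate_predictions(sets[members], "mean")
      rep <- score_report(ens, measured)
      rep[[metric]]
    })
  })
  higher <- .metric_higher_better[[metric]]
  empirical_p <- if (is.null(reference_score)) NA_real_ else {
    if (higher) mean(scores >= reference_score) else mean(scores <= reference_score)
  }
  structure(
    list(
      scores = scores, k = k, n_draws = n_draws, metric = metric,
      seed = seed, reference_score = reference_score, empirical_p = empirical_p
    ),
    class = "random_ensembles"
  )
}

#' @export
print.random_ensembles <- function(x, ...) {
  cat(sprintf("<random_ensembles> %d draws of %d models: %s median %.3f",
              x$n_draws, x$k, x$metric, median(x$scores)))
  if (!is.na(x$empirical_p)) {
    cat(sprintf("; empirical p = %.4g vs reference %.3f", x$empirical_p, x$reference_score))
  }
  cat("\n")
  invisible(x)
}

#' @rdname random_ensembles
#' @param object A `"random_ensembles"` object.
#' @param ... Unused.
#' @export
autoplot.random_ensembles <- function(object, ...) {
  p <- ggplot2::ggplot(tibble(score = object$scores), ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::labs(
      x = object$metric, y = "random ensembles",
      title = sprintf("Random %d-model ensembles (n = %d)", object$k, object$n_draws)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$reference_score)) {
    p <- p + ggplot2::geom_vline(xintercept = object$reference_score, colour = "red")
  }
  p
}
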