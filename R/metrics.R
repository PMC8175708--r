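# Challenge scoring metrics for quantitative pKd predictions, plus the
# post-challenge activity-classification metrics.

rank_auc <- function(scores, labels) {
  # Mann-Whitney ROC-AUC with midranks for ties; labels logical (TRUE = positive)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Concordance index of a pKd predictor
#'
#' The probability that, for two randomly drawn pairs with different measured
#' pKd values, the predictions are in the correct order: over all comparable
#' pair-of-pairs, a correctly ordered prediction counts 1, a tied prediction
#' 0.5, a discordant one 0.
#'
#' @param pred Prediction tibble (`compound_id`, `protein_id`, `pkd_pred`) or
#'   a numeric vector of predictions.
#' @param measured Interaction table covering the predicted pairs, or a
#'   numeric vector aligned with `pred`.
#' @return Concordance index in \[0, 1\].
#' @export
concordance_index <- function(pred, measured) {
  if (is.numeric(pred) && is.numeric(measured)) {
    f <- pred
    y <- measured
  } else {
    joined <- join_pred_measured(pred, measured)
    f <- joined$pkd_pred
    y <- joined$pkd
  }
  if (length(f) < 2) abort("Concordance needs at least 2 pairs.")
  dy <- sign(outer(y, y, `-`))
  comparable <- dy != 0 & upper.tri(dy)
  if (!any(comparable)) abort("Concordance is undefined when all measured values are equal.")
  df <- sign(outer(f, f, `-`))
  agree <- (df * dy)[comparable]
  mean((agree + 1) / 2) # +1 -> 1, 0 (tie) -> 0.5, -1 -> 0
}

#' Averaged ROC-AUC over the measured pKd interval \[6, 8\]
#'
#' Measured pKd values are binarized at ten evenly spaced thresholds spanning
#' \[6, 8\] inclusive; at each threshold with both classes present the ROC-AUC
#' of the predictions as a ranker is computed (Mann-Whitney with midranks) and
#' the mean over the non-degenerate thresholds is returned. Invariant under
#' strictly monotone transforms of the predictions.
#'
#' @inheritParams concordance_index
#' @return Averaged AUC in \[0, 1\].
#' @export
average_auc <- function(pred, measured) {
  if (is.numeric(pred) && is.numeric(measured)) {
    f <- pred
    y <- measured
  } else {
    joined <- join_pred_measured(pred, measured)
    f <- joined$pkd_pred
    y <- joined$pkd
  }
  thresholds <- seq(6, 8, length.out = 10)
  aucs <- map_dbl(thresholds, function(thr) rank_auc(f, y > thr))
  aucs <- aucs[!is.na(aucs)]
  if (length(aucs) == 0) {
    abort("Averaged AUC is undefined: every threshold yields a single class.")
  }
  mean(aucs)
}

f1_score <- function(f, y, cutoff = 7) {
  truth <- y > cutoff
  call_pos <- f > cutoff
  tp <- sum(truth & call_pos)
  fp <- sum(!truth & call_pos)
  fn <- sum(truth & !call_pos)
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

#' Score a prediction set with the six challenge metrics
#'
#' Computes RMSE, Pearson and Spearman correlations (midranks for ties), the
#' concordance index, the F1 score (both vectors binarized at pKd > 7), and
#' the averaged AUC over ten thresholds spanning measured pKd \[6, 8\].
#'
#' @inheritParams concordance_index
#' @return A one-row tibble with columns `rmse`, `pearson`, `spearman`, `ci`,
#'   `f1`, `avg_auc` and `n_pairs`.
#' @export
score_report <- function(pred, measured) {
  joined <- join_pred_measured(pred, measured)
  if (nrow(joined) < 2) abort("Scoring needs at least 2 pairs.")
  f <- joined$pkd_pred
  y <- joined$pkd
  if (sd(y) == 0 || sd(f) == 0) {
    abort("Correlation is undefined for a zero-variance vector.")
  }
  tibble(
    rmse = sqrt(mean((f - y)^2)),
    pearson = cor(f, y),
    spearman = cor(f, y, method = "spearman"),
    ci = concordance_index(f, y),
    f1 = f1_score(f, y),
    avg_auc = average_auc(f, y),
    n_pairs = nrow(joined)
  )
}

#' Confusion summary for activity classification
#'
#' Classifies compound-kinase pairs as active/inactive and summarises the
#' confusion matrix. Ground truth is `measured pKd > truth_cutoff`; the
#' positive call is `score > score_cutoff`, where the score is either a
#' predicted pKd (with `score_cutoff` on the pKd scale) or a measured
#' single-dose inhibition (with `score_cutoff` on the percent scale,
#' conventionally 80). Binarization is strict: ties at a cutoff are negative.
#'
#' `balanced_accuracy` is the arithmetic mean of precision and recall (the
#' convention used alongside PPV/FDR in single-dose screening analyses);
#' the conventional mean of sensitivity and specificity is reported separately
#' as `balanced_accuracy_ss` to avoid silent divergence.
#'
#' @param scores Data frame with `compound_id`, `protein_id` and a `score`
#'   column (predicted pKd or % inhibition).
#' @param measured Interaction table with the ground-truth pKd values.
#' @param truth_cutoff Measured pKd cutoff defining true activity (6 or 7).
#' @param score_cutoff Cutoff applied to `score` for a positive call.
#' @return A one-row tibble with counts `tp`, `fp`, `tn`, `fn` and rates
#'   `ppv`, `fdr`, `sensitivity`, `specificity`, `balanced_accuracy`,
#'   `balanced_accuracy_ss`, plus `ppv_defined` (FALSE when there are no
#'   positive calls, in which case ppv/fdr are NA rather than an error).
#' @export
classification_summary <- function(scores, measured, truth_cutoff = 6,
                                   score_cutoff = 6) {
  if (!"score" %in% names(scores)) abort("`scores` needs a `score` column.")
  assert_interactions(measured, "measured")
  joined <- inner_join(scores, measured, by = c("compound_id", "protein_id"))
  if (nrow(joined) < nrow(scores)) {
    abort("Some scored pairs are absent from the measured interaction table.")
  }
  truth <- joined$pkd > truth_cutoff
  call_pos <- joined$score > score_cutoff
  tp <- sum(truth & call_pos)
  fp <- sum(!truth & call_pos)
  tn <- sum(!truth & !call_pos)
  fn <- sum(truth & !call_pos)
  ppv_defined <- (tp + fp) > 0
  ppv <- if (ppv_defined) tp / (tp + fp) else NA_real_
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    ppv = ppv,
    fdr = 1 - ppv,
    sensitivity = sens,
    specificity = spec,
    balanced_accuracy = (ppv + sens) / 2,
    balanced_accuracy_ss = (sens + spec) / 2,
    ppv_defined = ppv_defined
  )
}

#' ROC and PR curves for ranking pairs by an activity score
#'
#' Ranks compound-kinase pairs by a continuous score (predicted pKd or
#' measured single-dose inhibition) against the binary ground truth
#' `measured pKd > truth_cutoff`, and returns both the ROC curve (via pROC)
#' and the precision-recall curve with their areas. The PR baseline is the
#' class prevalence.
#'
#' @inheritParams classification_summary
#' @return A `"kb_curves"` object with elements `roc` (tibble: `fpr`, `tpr`),
#'   `pr` (tibble: `recall`, `precision`), `au_roc`, `au_pr`, `prevalence`.
#'   Plot with [autoplot()].
#' @export
classification_curves <- function(scores, measured, truth_cutoff = 6) {
  if (!"score" %in% names(scores)) abort("`scores` needs a `score` column.")
  assert_interactions(measured, "measured")
  joined <- inner_join(scores, measured, by = c("compound_id", "protein_id"))
  truth <- joined$pkd > truth_cutoff
  if (all(truth) || !any(truth)) {
    abort("Both classes must be present for ROC/PR analysis.")
  }
  s <- joined$score
  roc_obj <- pROC::roc(response = truth, predictor = s,
                       direction = "<", quiet = TRUE)
  roc_tbl <- tibble(fpr = 1 - roc_obj$specificities, tpr = roc_obj$sensitivities) |>
    arrange(.data$fpr, .data$tpr)

  # PR curve over descending score thresholds
  ord <- order(s, decreasing = TRUE)
  truth_ord <- truth[ord]
  s_ord <- s[ord]
  cum_tp <- cumsum(truth_ord)
  cum_pos <- seq_along(truth_ord)
  # keep only the last index of each tied score block
  keep <- c(s_ord[-1] != s_ord[-length(s_ord)], TRUE)
  precision <- (cum_tp / cum_pos)[keep]
  recall <- (cum_tp / sum(truth))[keep]
  pr_tbl <- tibble(recall = c(0, recall), precision = c(precision[1], precision))
  au_pr <- sum(diff(pr_tbl$recall) *
                 (head(pr_tbl$precision, -1) + pr_tbl$precision[-1]) / 2)

  structure(
    list(
      roc = roc_tbl,
      pr = pr_tbl,
      au_roc = as.numeric(pROC::auc(roc_obj)),
      au_pr = au_pr,
      prevalence = mean(truth),
      truth_cutoff = truth_cutoff,
      n_pairs = nrow(joined)
    ),
    class = "kb_curves"
  )
}

#' @export
print.kb_curves <- function(x, ...) {
  cat(sprintf("<kb_curves> %d pairs, truth pKd > %g: AU-ROC %.3f, AU-PR %.3f (prevalence %.3f)\n",
              x$n_pairs, x$truth_cutoff, x$au_roc, x$au_pr, x$prevalence))
  invisible(x)
}

#' @rdname classification_curves
#' @param object,x A `"kb_curves"` object.
#' @param ... Unused.
#' @export
autoplot.kb_curves <- function(object, ...) {
  roc <- mutate(object$roc, curve = "ROC", x = .data$fpr, y = .data$tpr)
  pr <- mutate(object$pr, curve = "PR", x = .data$recall, y = .data$precision)
  dat <- bind_rows(roc[, c("curve", "x", "y")], pr[, c("curve", "x", "y")])
  ref <- tibble(
    curve = c("ROC", "PR"),
    intercept = c(0, object$prevalence),
    slope = c(1, 0)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(
      data = ref,
      ggplot2::aes(intercept = .data$intercept, slope = .data$slope),
      linetype = "dashed", colour = "grey60"
    ) +
    ggplot2::facet_wrap(~curve) +
    ggplot2::labs(
      x = "FPR / recall", y = "TPR / precision",
      title = sprintf("AU-ROC %.3f, AU-PR %.3f", object$au_roc, object$au_pr)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname classification_curves
#' @export
glance.kb_curves <- function(x, ...) {
  tibble(au_roc = x$au_roc, au_pr = x$au_pr,
         prevalence = x$prevalence, n_pairs = x$n_pairs,
         truth_cutoff = x$truth_cutoff)
}
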