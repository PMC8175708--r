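test_that("a perfect prediction earns the perfect score report", {
  measured <- tiny_ds$observed
  rep <- score_report(as_pred(measured, measured$pkd), measured)
  expect_equal(rep$rmse, 0)
  expect_equal(rep$pearson, 1)
  expect_equal(rep$spearman, 1)
  expect_equal(rep$ci, 1)
  expect_equal(rep$avg_auc, 1)
})

test_that("RMSE and F1 follow their definitions on worked examples", {
  measured <- tibble::tibble(compound_id = c("a", "b"), protein_id = "p", pkd = c(6, 8))
  rep <- score_report(as_pred(measured, c(5, 6)), measured)
  expect_equal(rep$rmse, sqrt((1 + 4) / 2)) # ~1.5811
  m3 <- tibble::tibble(compound_id = c("a", "b", "c"), protein_id = "p",
                       pkd = c(6, 8, 7.5))
  rep3 <- score_report(as_pred(m3, c(6.5, 8.2, 6.9)), m3)
  # cutoff 7: one true positive called, one missed -> precision 1, recall 1/2
  expect_equal(rep3$f1, 2 / 3)
  expect_error(score_report(as_pred(m3, c(7, 7, 7)), m3), "zero-variance")
  expect_error(
    score_report(as_pred(m3[1, ], 6), m3[1, ]),
    "at least 2"
  )
})

test_that("concordance agrees with brute-force pair enumeration", {
  expect_equal(concordance_index(c(5.5, 6.5, 6.0), c(5, 6, 7)), 2 / 3)
  expect_equal(concordance_index(c(1, 2, 3, 4), c(4, 5, 6, 7)), 1)
  expect_equal(concordance_index(rep(2, 4), c(4, 5, 6, 7)), 0.5) # all ties
  withr::with_seed(101, {
    for (i in 1:20) {
      n <- sample(3:30, 1)
      y <- round(runif(n, 4, 8), 1)
      f <- round(rnorm(n, y, 1), 1)
      if (length(unique(y)) < 2) next
      expect_equal(concordance_index(f, y), ci_oracle(f, y))
    }
  })
  expect_error(concordance_index(c(1, 2), c(5, 5)), "undefined")
})

test_that("concordance equals ROC-AUC for binary measured values", {
  withr::with_seed(102, {
    for (i in 1:10) {
      y <- rbinom(25, 1, 0.4)
      if (length(unique(y)) < 2) next
      f <- rnorm(25)
      expect_equal(concordance_index(f, y), kronbind:::rank_auc(f, y == 1))
    }
  })
})

test_that("averaged AUC matches a per-threshold Mann-Whitney oracle", {
  withr::with_seed(103, {
    y <- runif(25, 5, 9)
    f <- y + rnorm(25, 0, 1)
  })
  thresholds <- seq(6, 8, length.out = 10)
  oracle <- mean(vapply(thresholds, function(thr) {
    pos <- y > thr
    if (!any(pos) || all(pos)) return(NA_real_)
    # Mann-Whitney U / (n1 n0), midranks for ties
    r <- rank(f)
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  }, numeric(1)), na.rm = TRUE)
  expect_equal(average_auc(f, y), oracle)
  # pROC as an independent implementation at a single threshold
  pos <- y > thresholds[5]
  expect_equal(
    kronbind:::rank_auc(f, pos),
    as.numeric(pROC::auc(pROC::roc(response = pos, predictor = f,
                                   direction = "<", quiet = TRUE)))
  )
  # invariance under strictly monotone transforms; reversal flips to 0
  expect_equal(average_auc(exp(f), y), average_auc(f, y))
  expect_equal(average_auc(-f, rep(c(5, 9), length.out = 25)),
               1 - average_auc(f, rep(c(5, 9), length.out = 25)))
  expect_error(average_auc(f, rep(9, 25)), "single class")
})

test_that("classification summaries count the confusion matrix correctly", {
  measured <- tibble::tibble(
    compound_id = sprintf("c%d", 1:6), protein_id = "p",
    pkd = c(7, 7.5, 5, 5.5, 8, 4)
  )
  scores <- dplyr::mutate(measured[, 1:2], score = c(90, 85, 95, 10, 20, 15))
  s <- classification_summary(scores, measured, truth_cutoff = 6, score_cutoff = 80)
  expect_equal(c(s$tp, s$fp, s$tn, s$fn), c(2, 1, 2, 1))
  expect_equal(s$ppv, 2 / 3)
  expect_equal(s$fdr, 1 / 3)
  expect_equal(s$sensitivity, 2 / 3)
  expect_equal(s$balanced_accuracy, (2 / 3 + 2 / 3) / 2)
  # perfect predictor
  perf <- classification_summary(
    dplyr::mutate(measured[, 1:2], score = measured$pkd), measured,
    truth_cutoff = 6, score_cutoff = 6
  )
  expect_equal(c(perf$ppv, perf$fdr, perf$sensitivity), c(1, 0, 1))
  # no positive calls: ppv flagged undefined, not an error
  none <- classification_summary(
    dplyr::mutate(measured[, 1:2], score = 0), measured,
    truth_cutoff = 6, score_cutoff = 80
  )
  expect_false(none$ppv_defined)
  expect_true(is.na(none$ppv))
  expect_equal(none$sensitivity, 0)
})

test_that("fdr complements ppv whenever ppv is defined", {
  withr::with_seed(104, {
    for (i in 1:10) {
      measured <- tibble::tibble(
        compound_id = sprintf("c%d", 1:20), protein_id = "p",
        pkd = runif(20, 4, 9)
      )
      scores <- dplyr::mutate(measured[, 1:2], score = runif(20, 0, 100))
      s <- classification_summary(scores, measured, 6, 50)
      if (s$ppv_defined) expect_equal(s$ppv + s$fdr, 1)
    }
  })
})

test_that("ROC and PR curves match trapezoid oracles on a toy ranking", {
  measured <- tibble::tibble(
    compound_id = sprintf("c%d", 1:5), protein_id = "p",
    pkd = c(7, 7, 5, 5, 5)
  )
  scores <- dplyr::mutate(measured[, 1:2], score = c(0.9, 0.4, 0.6, 0.2, 0.1))
  cv <- classification_curves(scores, measured, truth_cutoff = 6)
  # hand enumeration, thresholds descending: ranks T N T N N
  # ROC steps: (0,.5) (1/3,.5) (1/3,1) (2/3,1) (1,1) -> AUC = 5/6... trapezoid:
  expect_equal(cv$au_roc, 1 - (1 / 3) * (1 / 2))
  # PR points at each rank block: (r=.5,p=1) (r=.5,p=.5) (r=1,p=2/3) (r=1,.5) (r=1,.4)
  pr_oracle <- 0.5 * 1 + 0.5 * (0.5 + 2 / 3) / 2
  expect_equal(cv$au_pr, pr_oracle)
  expect_equal(cv$prevalence, 0.4)
  # perfect and constant rankers
  perfect <- classification_curves(
    dplyr::mutate(measured[, 1:2], score = measured$pkd), measured, 6)
  expect_equal(perfect$au_roc, 1)
  expect_equal(perfect$au_pr, 1)
  constant <- classification_curves(
    dplyr::mutate(measured[, 1:2], score = 1), measured, 6)
  expect_equal(constant$au_roc, 0.5)
  expect_error(
    classification_curves(scores, dplyr::mutate(measured, pkd = 9), 6),
    "Both classes"
  )
})

test_that("score reports are invariant to pair ordering", {
  measured <- tiny_ds$observed
  pred <- as_pred(measured, measured$pkd + withr::with_seed(105, rnorm(nrow(measured), 0, 0.5)))
  shuffled <- pred[withr::with_seed(106, sample(nrow(pred))), ]
  expect_equal(score_report(shuffled, measured), score_report(pred, measured))
})
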