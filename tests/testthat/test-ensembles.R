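measured_en <- tiny_ds$observed
sets3 <- list(
  as_pred(measured_en, measured_en$pkd + withr::with_seed(301, rnorm(nrow(measured_en), 0, 0.3)), "m1"),
  as_pred(measured_en, measured_en$pkd + withr::with_seed(302, rnorm(nrow(measured_en), 0, 0.8)), "m2"),
  as_pred(measured_en, withr::with_seed(303, runif(nrow(measured_en), 4, 10)), "m3")
)

test_that("the default grid enumerates 5 x 11 x 8 = 440 regressors", {
  expect_equal(n_members(qed_grid()), 440)
  expect_equal(length(qed_grid()$epoch_list), 11)
  expect_equal(qed_grid()$lams, c(0.1, 0.5, 1.0, 1.5, 2.0))
  expect_error(qed_grid(compound_kernels = list()), "At least one")
})

test_that("a collapsed grid reproduces its single member and duplicates average out", {
  Kc <- tiny_ds$compound_kernel
  Kp <- tiny_ds$protein_kernel
  train <- tiny_ds$observed
  test_pairs <- tiny_ds$truth[seq(2, 96, by = 9), c("compound_id", "protein_id")]
  single <- qed_grid(list(Kc), Kp, lams = 0.5, epoch_list = 150)
  ens1 <- qed_ensemble(single, train, test_pairs)
  member <- predict(kronrls_cg(Kc, Kp, train, 0.5, 150), test_pairs)
  expect_equal(ens1$pkd_pred, member$pkd_pred)
  # identical members (duplicated kernel) leave the mean unchanged
  dup <- qed_grid(list(Kc, Kc), Kp, lams = 0.5, epoch_list = 150)
  expect_equal(qed_ensemble(dup, train, test_pairs)$pkd_pred, member$pkd_pred)
  expect_error(qed_ensemble(qed_grid(list(Kc)), train, test_pairs), "filled in")
})

test_that("a generous epoch budget drives the grid ensemble to the closed form", {
  Kc <- tiny_ds$compound_kernel
  Kp <- tiny_ds$protein_kernel
  Y <- matrix(tiny_ds$truth$pkd, nrow = 12, byrow = TRUE,
              dimnames = list(Kc$ids, Kp$ids))
  full <- tiny_ds$truth
  ens <- qed_ensemble(qed_grid(list(Kc), Kp, lams = 1, epoch_list = 3000),
                      full, full[, 1:2], tol = 1e-12)
  cf <- predict(kronrls_fit(Kc, Kp, Y, 1), full[, 1:2])
  expect_equal(ens$pkd_pred, cf$pkd_pred, tolerance = 1e-6)
})

test_that("aggregation rules follow their formulas", {
  m <- tibble::tibble(compound_id = "c", protein_id = "p", pkd = 7)
  sets <- lapply(c(6, 7, 8), function(v) as_pred(m, v))
  expect_equal(aggregate_predictions(sets, "mean")$pkd_pred, 7)
  expect_equal(aggregate_predictions(sets, "rank_weighted")$pkd_pred,
               (3 * 6 + 2 * 7 + 1 * 8) / 6) # weights N+1-r
  med_sets <- lapply(c(5, 6, 10), function(v) as_pred(m, v))
  expect_equal(aggregate_predictions(med_sets, "median")$pkd_pred, 6)
})

test_that("mean aggregation is order-invariant; rank weighting is not", {
  perm <- sets3[c(3, 1, 2)]
  expect_equal(
    dplyr::arrange(aggregate_predictions(sets3, "mean"), compound_id, protein_id)$pkd_pred,
    dplyr::arrange(aggregate_predictions(perm, "mean"), compound_id, protein_id)$pkd_pred
  )
  expect_false(isTRUE(all.equal(
    aggregate_predictions(sets3, "rank_weighted")$pkd_pred,
    aggregate_predictions(perm, "rank_weighted")$pkd_pred
  )))
  # convexity: bounded by member min/max per pair
  rw <- aggregate_predictions(sets3, "rank_weighted")
  mat <- sapply(sets3, function(s) s$pkd_pred)
  expect_true(all(rw$pkd_pred >= apply(mat, 1, min) - 1e-12))
  expect_true(all(rw$pkd_pred <= apply(mat, 1, max) + 1e-12))
  # mismatched pair sets are refused with the offending pairs
  expect_error(
    aggregate_predictions(list(sets3[[1]], sets3[[2]][-1, ]), "mean"),
    "different pair set"
  )
})

test_that("top-k curves equal per-k recomputation and find the best k", {
  curve <- topk_curve(sets3, measured_en)
  expect_equal(curve$curve$k, 1:3)
  for (k in 1:3) {
    direct <- score_report(aggregate_predictions(sets3[1:k], "mean"), measured_en)
    expect_equal(curve$curve$spearman[k], direct$spearman)
    expect_equal(curve$curve$rmse[k], direct$rmse)
  }
  # k = 1 point is the best single model's score
  expect_equal(curve$curve$spearman[1], score_report(sets3[[1]], measured_en)$spearman)
  # identical sets give a flat curve
  flat <- topk_curve(list(sets3[[1]], sets3[[1]], sets3[[1]]), measured_en)
  expect_equal(diff(flat$curve$spearman), c(0, 0))
  expect_error(topk_curve(sets3, measured_en, max_k = 4), "exceed")
})

test_that("random ensemble controls are reproducible and bounded by a strong reference", {
  top_score <- score_report(aggregate_predictions(sets3[1:2], "mean"), measured_en)$spearman
  re <- random_ensembles(sets3, measured_en, k = 2, n_draws = 30, seed = 11,
                         reference_score = 1, metric = "spearman")
  expect_equal(re$empirical_p, 0) # nothing matches a perfect reference
  re2 <- random_ensembles(sets3, measured_en, k = 2, n_draws = 30, seed = 11)
  expect_identical(re$scores, re2$scores)
  # k = all sets: every draw is the same ensemble
  all_k <- random_ensembles(sets3, measured_en, k = 3, n_draws = 10, seed = 1)
  expect_equal(length(unique(all_k$scores)), 1)
  expect_error(random_ensembles(sets3, measured_en, k = 4, n_draws = 5, seed = 1),
               "exceed")
})
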