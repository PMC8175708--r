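measured_bm <- tiny_ds$observed
good_pred <- as_pred(measured_bm,
                     measured_bm$pkd + withr::with_seed(201, rnorm(nrow(measured_bm), 0, 0.2)))
bad_pred <- as_pred(measured_bm, withr::with_seed(202, runif(nrow(measured_bm), 4, 10)))

test_that("identical prediction sets tie every bootstrap iteration (K = 1)", {
  cmp <- bootstrap_compare(good_pred, good_pred, measured_bm,
                           metric = "spearman", n_boot = 200, seed = 7)
  expect_equal(cmp$ties, 200)
  expect_equal(cmp$bayes_factor, 1)
})

test_that("the Bayes factor is the tie-split win ratio and inverts on swap", {
  cmp <- bootstrap_compare(bad_pred, good_pred, measured_bm,
                           metric = "spearman", n_boot = 300, seed = 7)
  expect_equal(cmp$wins_cand + cmp$wins_ref + cmp$ties, 300)
  expect_equal(cmp$bayes_factor,
               (cmp$wins_ref + cmp$ties / 2) / (cmp$wins_cand + cmp$ties / 2))
  swapped <- bootstrap_compare(good_pred, bad_pred, measured_bm,
                               metric = "spearman", n_boot = 300, seed = 7)
  expect_equal(swapped$bayes_factor, 1 / cmp$bayes_factor)
  # win counts mirror under the paired design with the same seed
  expect_equal(swapped$wins_cand, cmp$wins_ref)
  # rmse reverses the favorable direction
  cmp_rmse <- bootstrap_compare(bad_pred, good_pred, measured_bm,
                                metric = "rmse", n_boot = 300, seed = 7)
  expect_gt(cmp_rmse$bayes_factor, 3)
  # determinism: same seed, same K
  again <- bootstrap_compare(bad_pred, good_pred, measured_bm,
                             metric = "spearman", n_boot = 300, seed = 7)
  expect_equal(again$bayes_factor, cmp$bayes_factor)
  expect_error(bootstrap_compare(bad_pred, good_pred, measured_bm, n_boot = 0),
               "at least 1")
})

test_that("the ladder accepts first submissions and substantial improvements only", {
  first <- ladder_update(NULL, bad_pred, measured_bm, n_boot = 200, seed = 3)
  expect_true(first$accepted)
  expect_true(is.na(first$bayes_factor))
  same <- ladder_update(good_pred, good_pred, measured_bm, n_boot = 200, seed = 3)
  expect_false(same$accepted) # K = 1 <= 3
  expect_equal(same$bayes_factor, 1)
  improve <- ladder_update(bad_pred, good_pred, measured_bm, n_boot = 200, seed = 3)
  expect_true(improve$accepted)
  worse <- ladder_update(good_pred, bad_pred, measured_bm, n_boot = 200, seed = 3)
  expect_false(worse$accepted)
})

test_that("a perfect prediction beats every permutation of the labels", {
  nd <- permutation_null(as_pred(measured_bm, measured_bm$pkd), measured_bm,
                         metric = "spearman", n_perm = 300, seed = 5)
  expect_equal(nd$empirical_p, 0)
  expect_true(nd$better_than_random)
  # determinism
  nd2 <- permutation_null(as_pred(measured_bm, measured_bm$pkd), measured_bm,
                          metric = "spearman", n_perm = 300, seed = 5)
  expect_identical(nd$values, nd2$values)
})

test_that("permutation p-values are calibrated for null predictions", {
  # a prediction drawn from the null itself should have a roughly uniform p
  y <- withr::with_seed(210, runif(30, 4, 9))
  measured <- tibble::tibble(compound_id = sprintf("c%d", 1:30), protein_id = "p", pkd = y)
  # draw all null predictions and permutation seeds from one seeded stream
  # (consecutive integer seeds give correlated first draws)
  draws <- withr::with_seed(211, {
    list(preds = replicate(60, sample(y), simplify = FALSE),
         seeds = sample.int(1e6, 60))
  })
  pvals <- vapply(1:60, function(s) {
    null_pred <- as_pred(measured, draws$preds[[s]])
    permutation_null(null_pred, measured, "spearman", n_perm = 100,
                     seed = draws$seeds[s])$empirical_p
  }, numeric(1))
  # super-uniform up to the order-statistic resolution: under exchangeability
  # P(p <= alpha) = (floor(alpha m) + 1) / (m + 1) for m permutations, since
  # the plain fraction (which can reach exactly 0) excludes the observed draw
  for (alpha in c(0.1, 0.25, 0.5)) {
    bound <- (floor(alpha * 100) + 1) / 101
    expect_lte(mean(pvals <= alpha), bound + 3 * sqrt(bound * (1 - bound) / 60))
  }
  expect_gt(mean(pvals), 0.3) # not degenerate at zero
})

test_that("replicate bounds reflect the scatter between the two studies", {
  withr::with_seed(220, {
    true_pkd <- runif(150, 5.2, 9)
    reps <- tibble::tibble(
      pkd_study1 = true_pkd + rnorm(150, 0, 0.3),
      pkd_study2 = true_pkd + rnorm(150, 0, 0.3)
    )
    floor_rows <- tibble::tibble(pkd_study1 = rep(5, 120), pkd_study2 = rep(5, 120))
  })
  rb <- replicate_bound(dplyr::bind_rows(reps, floor_rows),
                        target_frac_pkd5 = 0.25, n_sub = 100,
                        n_boot = 300, seed = 9)
  expect_equal(nrow(rb$pool), 150 + 50)
  expect_equal(mean(rb$pool$pkd_study1 == 5 & rb$pool$pkd_study2 == 5), 0.25)
  # difference of two independent noisy copies has sd*sqrt(2) RMS on active rows;
  # the floored quarter contributes zeros, shrinking it by ~sqrt(0.75)
  expect_equal(median(rb$draws$rmse), 0.3 * sqrt(2) * sqrt(0.75), tolerance = 0.1)
  expect_true(all(rb$draws$spearman > 0.5))
  # identical studies give the degenerate bound
  same <- replicate_bound(
    dplyr::mutate(reps, pkd_study2 = pkd_study1), 0, n_sub = 50,
    n_boot = 50, seed = 2
  )
  expect_equal(same$draws$spearman, rep(1, 50), tolerance = 1e-12)
  expect_true(all(same$draws$rmse == 0))
  # impossible composition is refused
  expect_error(
    replicate_bound(reps, target_frac_pkd5 = 0.5, n_sub = 50, n_boot = 10, seed = 1),
    "only"
  )
  # determinism
  rb2 <- replicate_bound(dplyr::bind_rows(reps, floor_rows), 0.25, 100,
                         n_boot = 300, seed = 9)
  expect_identical(rb$draws, rb2$draws)
})
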