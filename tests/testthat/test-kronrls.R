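test_that("the closed-form solver matches a dense vectorized-system oracle", {
  for (case in list(c(2, 2, 31), c(4, 3, 32), c(8, 8, 33))) {
    nc <- case[1]; np <- case[2]; seed <- case[3]
    cids <- sprintf("c%d", seq_len(nc))
    pids <- sprintf("p%d", seq_len(np))
    Kc <- random_pd_kernel(cids, seed)
    Kp <- random_pd_kernel(pids, seed + 100)
    Y <- withr::with_seed(seed + 200,
      matrix(rnorm(nc * np), nc, np, dimnames = list(cids, pids)))
    lam <- 0.7
    model <- kronrls_fit(Kc, Kp, Y, lambda = lam)
    # oracle: solve the nc*np x nc*np vectorized system directly
    dense <- solve(kronecker(Kp$values, Kc$values) + lam * diag(nc * np), as.vector(Y))
    expect_equal(as.vector(model$coef), dense, tolerance = 1e-8)
  }
})

test_that("identity kernels reduce to ridge shrinkage Y/(1+lambda)", {
  ids <- c("a", "b", "c")
  I3 <- kernel_matrix(diag(3), ids)
  I2 <- kernel_matrix(diag(2), c("x", "y"))
  Y <- matrix(1:6, 3, 2, dimnames = list(ids, c("x", "y")))
  model <- kronrls_fit(I3, I2, Y, lambda = 0.5)
  pairs <- tidyr::expand_grid(compound_id = ids, protein_id = c("x", "y"))
  pred <- predict(model, pairs)
  fitted <- matrix(0, 3, 2, dimnames = dimnames(Y))
  fitted[cbind(pred$compound_id, pred$protein_id)] <- pred$pkd_pred
  expect_equal(fitted, Y / 1.5)
})

test_that("fitted values interpolate the labels as lambda approaches zero", {
  Kc <- random_pd_kernel(c("a", "b", "c"), 41)
  Kp <- random_pd_kernel(c("x", "y"), 42)
  Y <- matrix(rnorm(6), 3, 2, dimnames = list(Kc$ids, Kp$ids))
  pairs <- tidyr::expand_grid(compound_id = Kc$ids, protein_id = Kp$ids)
  model <- kronrls_fit(Kc, Kp, Y, lambda = 1e-10)
  pred <- predict(model, pairs)
  expect_equal(pred$pkd_pred, Y[cbind(pairs$compound_id, pairs$protein_id)],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("training RMSE is non-decreasing in lambda on complete data", {
  Kc <- random_pd_kernel(sprintf("c%d", 1:5), 51)
  Kp <- random_pd_kernel(sprintf("p%d", 1:4), 52)
  Y <- withr::with_seed(53, matrix(rnorm(20), 5, 4, dimnames = list(Kc$ids, Kp$ids)))
  pairs <- tidyr::expand_grid(compound_id = Kc$ids, protein_id = Kp$ids)
  rmse <- vapply(c(0.01, 0.1, 1, 10, 100), function(lam) {
    pred <- predict(kronrls_fit(Kc, Kp, Y, lam), pairs)
    sqrt(mean((pred$pkd_pred - Y[cbind(pairs$compound_id, pairs$protein_id)])^2))
  }, numeric(1))
  expect_true(all(diff(rmse) > 0))
})

test_that("the CG solver matches the dense sampled-Kronecker oracle", {
  Kc <- random_pd_kernel(c("a", "b", "c"), 61)
  Kp <- random_pd_kernel(c("x", "y", "z"), 62)
  train <- tibble::tibble(
    compound_id = c("a", "a", "b", "c", "c"),
    protein_id = c("x", "y", "z", "x", "z"),
    pkd = c(5, 6, 7, 8, 6.5)
  )
  query <- tidyr::expand_grid(compound_id = Kc$ids, protein_id = Kp$ids)
  model <- kronrls_cg(Kc, Kp, train, lambda = 0.3, epochs = 1000, tol = 1e-12)
  pred <- predict(model, query)
  expect_equal(pred$pkd_pred, dense_cg_oracle(Kc, Kp, train, 0.3, query),
               tolerance = 1e-8)
})

test_that("CG on fully labelled data agrees with the closed form", {
  Kc <- random_pd_kernel(sprintf("c%d", 1:6), 71)
  Kp <- random_pd_kernel(sprintf("p%d", 1:5), 72)
  Y <- withr::with_seed(73, matrix(rnorm(30), 6, 5, dimnames = list(Kc$ids, Kp$ids)))
  full <- tidyr::expand_grid(compound_id = Kc$ids, protein_id = Kp$ids) |>
    dplyr::mutate(pkd = Y[cbind(compound_id, protein_id)])
  cg <- kronrls_cg(Kc, Kp, full, lambda = 0.8, epochs = 2000, tol = 1e-12)
  cf <- kronrls_fit(Kc, Kp, Y, lambda = 0.8)
  expect_equal(predict(cg, full)$pkd_pred, predict(cf, full)$pkd_pred,
               tolerance = 1e-6)
})

test_that("zero CG epochs yield the all-zero model", {
  model <- kronrls_cg(tiny_ds$compound_kernel, tiny_ds$protein_kernel,
                      tiny_ds$observed, lambda = 1, epochs = 0)
  expect_true(all(model$coef == 0))
  expect_true(all(predict(model, tiny_ds$observed)$pkd_pred == 0))
})

test_that("predictions match brute-force summation and ignore query duplication", {
  model <- kronrls_cg(tiny_ds$compound_kernel, tiny_ds$protein_kernel,
                      tiny_ds$observed, lambda = 0.5, epochs = 200)
  query <- tiny_ds$truth[c(1, 5, 9, 5), ]
  pred <- predict(model, query)
  # brute force: f(c,p) = sum over train pairs of alpha * Kc(c,c') * Kp(p',p)
  brute <- vapply(seq_len(nrow(query)), function(q) {
    s <- 0
    for (t in seq_len(nrow(tiny_ds$observed))) {
      ct <- tiny_ds$observed$compound_id[t]
      pt <- tiny_ds$observed$protein_id[t]
      s <- s + model$coef[ct, pt] *
        tiny_ds$compound_kernel$values[query$compound_id[q], ct] *
        tiny_ds$protein_kernel$values[pt, query$protein_id[q]]
    }
    s
  }, numeric(1))
  expect_equal(pred$pkd_pred, brute, tolerance = 1e-10)
  expect_equal(pred$pkd_pred[2], pred$pkd_pred[4]) # duplicated query pair
  expect_error(predict(model, tibble::tibble(compound_id = "nope", protein_id = "P001")),
               "absent")
})

test_that("predictions are invariant to entity and row permutations", {
  Kc <- tiny_ds$compound_kernel
  Kp <- tiny_ds$protein_kernel
  train <- tiny_ds$observed
  model <- kronrls_cg(Kc, Kp, train, lambda = 0.5, epochs = 300)
  perm_c <- withr::with_seed(81, sample(seq_along(Kc$ids)))
  perm_p <- withr::with_seed(82, sample(seq_along(Kp$ids)))
  Kc2 <- kernel_matrix(Kc$values[perm_c, perm_c], Kc$ids[perm_c])
  Kp2 <- kernel_matrix(Kp$values[perm_p, perm_p], Kp$ids[perm_p])
  train2 <- train[withr::with_seed(83, sample(nrow(train))), ]
  model2 <- kronrls_cg(Kc2, Kp2, train2, lambda = 0.5, epochs = 300)
  q <- tiny_ds$truth[seq(1, 90, by = 7), ]
  expect_equal(predict(model2, q)$pkd_pred, predict(model, q)$pkd_pred,
               tolerance = 1e-8)
})

test_that("nested leave-compound-out CV holds compounds out cleanly", {
  ds <- tiny_ds
  cv <- loco_cv(ds$compound_kernel, ds$protein_kernel, ds$observed,
                lambda_grid = c(0.5), inner_folds = 2, epochs = 150)
  # a one-point grid is selected trivially everywhere
  expect_true(all(cv$selected$lambda == 0.5))
  # every training compound appears in exactly one outer fold, with all its rows
  expect_setequal(cv$selected$compound_id, unique(ds$observed$compound_id))
  expect_equal(nrow(cv$predictions), nrow(ds$observed))
  expect_equal(
    dplyr::count(cv$predictions, compound_id)$n,
    dplyr::count(ds$observed, compound_id)$n
  )
  expect_true(all(cv$predictions$fold == cv$predictions$compound_id))
  g <- glance(cv)
  expect_true(is.finite(g$rmse) && is.finite(g$spearman))
  expect_error(
    loco_cv(ds$compound_kernel, ds$protein_kernel, ds$observed[1:3, ] |>
              dplyr::mutate(compound_id = "onlyone")),
    "at least 2"
  )
})

test_that("held-out error shrinks as synthetic noise vanishes", {
  rmse_at <- function(noise) {
    ds <- generate_synthetic(synthetic_spec(
      n_compounds = 14, n_proteins = 8, fp_bits = 256, seq_length = 60,
      noise_sd = noise, frac_observed = 0.5, censor_floor = -Inf, seed = 91
    ))
    held <- dplyr::anti_join(ds$truth, ds$observed, by = c("compound_id", "protein_id"))
    m <- kronrls_cg(ds$compound_kernel, ds$protein_kernel, ds$observed,
                    lambda = 0.1, epochs = 300)
    sqrt(mean((predict(m, held)$pkd_pred - held$pkd)^2))
  }
  errs <- vapply(c(1, 0.3, 0), rmse_at, numeric(1))
  expect_true(all(diff(errs) < 0))
})
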