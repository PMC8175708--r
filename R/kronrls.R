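# Kronecker kernel regularized least squares (KronRLS).
#
# The pairwise kernel over (compound, protein) pairs is the Kronecker product
# K = Kc (x) Kp. Neither solver ever materializes the Kronecker product: the
# complete-matrix solver uses the eigendecomposition identity, the sparse
# solver uses the generalized vec trick inside conjugate gradient.

new_kronrls <- function(compound_kernel, protein_kernel, coef, lambda,
                        method, epochs = NA_integer_, residual = NA_real_,
                        converged = NA) {
  structure(
    list(
      compound_kernel = compound_kernel,
      protein_kernel = protein_kernel,
      coef = coef,
      lambda = lambda,
      method = method,
      epochs = epochs,
      residual = residual,
      converged = converged
    ),
    class = "kronrls"
  )
}

#' Fit KronRLS on a complete label matrix (closed form)
#'
#' Solves (Kc (x) Kp + lambda I) vec(A) = vec(Y) through the kernel
#' eigendecompositions: with Kc = Uc Sc Uc' and Kp = Up Sp Up', the dual
#' coefficient matrix is A = Uc ((Uc' Y Up) / (sc sp' + lambda)) Up'.
#' Cost is O(nc^3 + np^3 + nc np (nc + np)); the nc*np x nc*np pairwise
#' system is never formed. Eigenvalues below 1e-12 of the largest are
#' treated as zero (normalised kernels can be near-singular).
#'
#' @param compound_kernel,protein_kernel [kernel_matrix()] objects covering at
#'   least the entities of `Y` (extra entities are allowed and usable at
#'   prediction time).
#' @param Y Numeric label matrix, rows = compounds, cols = proteins, with
#'   dimnames giving the entity ids.
#' @param lambda Regularization weight, > 0.
#' @return A fitted `"kronrls"` model.
#' @seealso [kronrls_cg()] for sparsely labelled pairs, [predict.kronrls()].
#' @export
kronrls_fit <- function(compound_kernel, protein_kernel, Y, lambda = 1) {
  check_scalar_number(lambda, "lambda")
  if (lambda <= 0) abort("`lambda` must be positive.")
  if (!is.matrix(Y) || is.null(rownames(Y)) || is.null(colnames(Y))) {
    abort("`Y` must be a matrix with compound rownames and protein colnames.")
  }
  if (anyNA(Y)) abort("`Y` must be complete; use kronrls_cg() for sparse labels.")
  Kc <- kernel_values(compound_kernel, rownames(Y))
  Kp <- kernel_values(protein_kernel, colnames(Y))
  ec <- eigen(Kc, symmetric = TRUE)
  ep <- eigen(Kp, symmetric = TRUE)
  sc <- pmax(ec$values, 0)
  sp <- pmax(ep$values, 0)
  sc[sc < 1e-12 * max(sc, 1e-300)] <- 0
  sp[sp < 1e-12 * max(sp, 1e-300)] <- 0
  Yt <- crossprod(ec$vectors, Y) %*% ep$vectors
  A <- ec$vectors %*% (Yt / (outer(sc, sp) + lambda)) %*% t(ep$vectors)
  dimnames(A) <- dimnames(Y)
  new_kronrls(compound_kernel, protein_kernel, A, lambda, method = "complete")
}

#' Fit KronRLS on sparsely labelled pairs by conjugate gradient
#'
#' For a training table that labels only some cells of the compound x protein
#' grid, solves (S (Kc (x) Kp) S' + lambda I) a = y by conjugate gradient,
#' where S samples the labelled cells. Each matrix-vector product scatters the
#' coefficient vector into a compound x protein matrix A, computes Kc A Kp,
#' and gathers the labelled cells (the generalized vec identity) — the
#' Kronecker product itself is never built. CG starts at zero coefficients,
#' is fully deterministic, and stops after `epochs` iterations or when the
#' residual norm drops below `tol`, whichever comes first; the iteration cap
#' doubles as early-stopping regularization.
#'
#' @inheritParams kronrls_fit
#' @param train Interaction table (`compound_id`, `protein_id`, `pkd`); every
#'   entity must be present in the corresponding kernel.
#' @param epochs Iteration cap (>= 0; 0 returns the all-zero model).
#' @param tol Residual-norm stopping tolerance.
#' @return A fitted `"kronrls"` model.
#' @export
kronrls_cg <- function(compound_kernel, protein_kernel, train, lambda = 1,
                       epochs = 400, tol = 1e-8) {
  assert_interactions(train, "train")
  check_scalar_number(lambda, "lambda")
  if (lambda <= 0) abort("`lambda` must be positive.")
  if (epochs < 0 || epochs != round(epochs)) abort("`epochs` must be a non-negative integer.")
  cids <- sort(unique(train$compound_id))
  pids <- sort(unique(train$protein_id))
  Kc <- kernel_values(compound_kernel, cids)
  Kp <- kernel_values(protein_kernel, pids)
  idx <- cbind(match(train$compound_id, cids), match(train$protein_id, pids))
  y <- train$pkd
  n <- length(y)
  nc <- length(cids)
  np <- length(pids)

  matvec <- function(v) {
    A <- matrix(0, nc, np)
    A[idx] <- v
    (Kc %*% A %*% Kp)[idx] + lambda * v
  }

  a <- numeric(n)
  r <- y
  p <- r
  rs <- sum(r * r)
  iter <- 0L
  while (iter < epochs && sqrt(rs) >= tol) {
    Ap <- matvec(p)
    alpha <- rs / sum(p * Ap)
    a <- a + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
    iter <- iter + 1L
  }

  A <- matrix(0, nc, np, dimnames = list(cids, pids))
  A[idx] <- a
  new_kronrls(compound_kernel, protein_kernel, A, lambda,
              method = "cg", epochs = iter, residual = sqrt(rs),
              converged = sqrt(rs) < tol)
}

#' Predict pKd for compound-kinase pairs from a fitted KronRLS model
#'
#' The prediction for pair (c, p) is the kernel-weighted sum over training
#' pairs: f(c, p) = sum over (c', p') of A\[c', p'\] Kc(c, c') Kp(p', p).
#' Query entities must be present in the model's kernels (which may contain
#' entities beyond the training set).
#'
#' @param object A `"kronrls"` model.
#' @param pairs Data frame with columns `compound_id`, `protein_id`.
#' @param model_id Identifier attached to the returned prediction set.
#' @param ... Unused.
#' @return A prediction tibble (`compound_id`, `protein_id`, `pkd_pred`).
#' @export
predict.kronrls <- function(object, pairs, model_id = "kronrls", ...) {
  if (!all(c("compound_id", "protein_id") %in% names(pairs))) {
    abort("`pairs` needs compound_id and protein_id columns.")
  }
  qc <- unique(pairs$compound_id)
  qp <- unique(pairs$protein_id)
  missing_c <- setdiff(qc, object$compound_kernel$ids)
  if (length(missing_c) > 0) {
    abort(sprintf("Compound(s) absent from the model's kernel: %s.", paste(missing_c, collapse = ", ")))
  }
  missing_p <- setdiff(qp, object$protein_kernel$ids)
  if (length(missing_p) > 0) {
    abort(sprintf("Protein(s) absent from the model's kernel: %s.", paste(missing_p, collapse = ", ")))
  }
  Kc_cross <- object$compound_kernel$values[qc, rownames(object$coef), drop = FALSE]
  Kp_cross <- object$protein_kernel$values[colnames(object$coef), qp, drop = FALSE]
  F_grid <- Kc_cross %*% object$coef %*% Kp_cross
  vals <- F_grid[cbind(match(pairs$compound_id, qc), match(pairs$protein_id, qp))]
  out <- tibble(
    compound_id = pairs$compound_id,
    protein_id = pairs$protein_id,
    pkd_pred = as.numeric(vals)
  )
  attr(out, "model_id") <- model_id
  out
}

#' @export
print.kronrls <- function(x, ...) {
  cat(sprintf("<kronrls> %s solver, lambda = %g, %d x %d training grid\n",
              x$method, x$lambda, nrow(x$coef), ncol(x$coef)))
  if (x$method == "cg") {
    cat(sprintf("  %d CG iterations, residual %.3g (%s)\n", x$epochs, x$residual,
                if (isTRUE(x$converged)) "converged" else "iteration cap"))
  }
  invisible(x)
}

#' @rdname predict.kronrls
#' @param x A `"kronrls"` model.
#' @export
tidy.kronrls <- function(x, ...) {
  coef_tbl <- as_tibble(x$coef, rownames = "compound_id")
  tidyr::pivot_longer(coef_tbl, -"compound_id",
                      names_to = "protein_id", values_to = "alpha")
}

#' @rdname predict.kronrls
#' @export
glance.kronrls <- function(x, ...) {
  tibble(
    method = x$method,
    lambda = x$lambda,
    epochs = x$epochs,
    n_compounds = nrow(x$coef),
    n_proteins = ncol(x$coef),
    residual = x$residual,
    converged = x$converged
  )
}

#' Nested leave-compound-out cross-validation
#'
#' Mirrors the blinded-challenge setting in which test compounds are unseen:
#' the outer loop holds out all rows of one compound at a time; the inner loop
#' groups the remaining compounds into `inner_folds` compound-disjoint folds
#' and selects the regularization weight minimising inner RMSE (ties go to the
#' earliest grid entry). The selected model is refit on all outer-training
#' rows and scored on the held-out compound, yielding unbiased held-out
#' predictions.
#'
#' @inheritParams kronrls_cg
#' @param lambda_grid Candidate regularization weights.
#' @param inner_folds Number of inner compound folds (>= 2).
#' @return A `"loco_cv"` object: `$predictions` (held-out predictions with the
#'   measured pKd), `$selected` (chosen lambda per outer fold). `tidy()`
#'   returns the predictions, `glance()` the overall held-out RMSE and
#'   Spearman correlation.
#' @export
loco_cv <- function(compound_kernel, protein_kernel, train,
                    lambda_grid = c(0.1, 0.5, 1, 2), inner_folds = 3,
                    epochs = 400, tol = 1e-8) {
  assert_interactions(train, "train")
  compounds <- sort(unique(train$compound_id))
  if (length(compounds) < 2) abort("Leave-compound-out needs at least 2 distinct compounds.")
  if (length(lambda_grid) < 1) abort("`lambda_grid` must be non-empty.")

  fit_score <- function(tbl_train, tbl_test, lam) {
    model <- kronrls_cg(compound_kernel, protein_kernel, tbl_train,
                        lambda = lam, epochs = epochs, tol = tol)
    pred <- predict(model, tbl_test)
    sqrt(mean((pred$pkd_pred - tbl_test$pkd)^2))
  }

  results <- map(compounds, function(co) {
    test_rows <- filter(train, .data$compound_id == co)
    rest <- filter(train, .data$compound_id != co)
    if (nrow(rest) == 0) {
      abort(sprintf("Compound %s owns every training row; folds are degenerate.", co))
    }
    inner_cmpds <- sort(unique(rest$compound_id))
    k <- min(inner_folds, length(inner_cmpds))
    fold_of <- setNames(rep_len(seq_len(k), length(inner_cmpds)), inner_cmpds)
    inner_rmse <- map_dbl(lambda_grid, function(lam) {
      errs <- map_dbl(seq_len(k), function(f) {
        held <- inner_cmpds[fold_of == f]
        inner_test <- filter(rest, .data$compound_id %in% held)
        inner_train <- filter(rest, !.data$compound_id %in% held)
        if (nrow(inner_train) == 0 || nrow(inner_test) == 0) return(NA_real_)
        fit_score(inner_train, inner_test, lam)
      })
      mean(errs, na.rm = TRUE)
    })
    # which.min takes the first minimum: earliest grid entry wins ties; if no
    # inner fold was scoreable (too few compounds) fall back to the first entry
    best <- if (all(!is.finite(inner_rmse))) 1L else which.min(inner_rmse)
    lam <- lambda_grid[best]
    model <- kronrls_cg(compound_kernel, protein_kernel, rest,
                        lambda = lam, epochs = epochs, tol = tol)
    pred <- predict(model, test_rows)
    list(
      predictions = mutate(inner_join(pred, test_rows, by = c("compound_id", "protein_id")),
                           fold = co),
      selected = tibble(compound_id = co, lambda = lam, inner_rmse = inner_rmse[best])
    )
  })

  structure(
    list(
      predictions = list_rbind(map(results, "predictions")),
      selected = list_rbind(map(results, "selected")),
      lambda_grid = lambda_grid,
      inner_folds = inner_folds
    ),
    class = "loco_cv"
  )
}

#' @export
print.loco_cv <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<loco_cv> %d outer compound folds, held-out RMSE %.3f, Spearman %.3f\n",
              nrow(x$selected), g$rmse, g$spearman))
  invisible(x)
}

#' @rdname loco_cv
#' @param x A `"loco_cv"` object.
#' @param ... Unused.
#' @export
tidy.loco_cv <- function(x, ...) x$predictions

#' @rdname loco_cv
#' @export
glance.loco_cv <- function(x, ...) {
  p <- x$predictions
  tibble(
    n_pairs = nrow(p),
    n_folds = nrow(x$selected),
    rmse = sqrt(mean((p$pkd_pred - p$pkd)^2)),
    spearman = cor(p$pkd_pred, p$pkd, method = "spearman")
  )
}
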