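# Internal validation helpers shared across modules.

pair_key <- function(compound_id, protein_id) {
  paste(compound_id, protein_id, sep = "\r")
}

#' @noRd
assert_interactions <- function(tbl, arg = "interactions") {
  if (!is.data.frame(tbl)) {
    abort(sprintf("`%s` must be a data frame with columns compound_id, protein_id, pkd.", arg))
  }
  missing_cols <- setdiff(c("compound_id", "protein_id", "pkd"), names(tbl))
  if (length(missing_cols) > 0) {
    abort(sprintf("`%s` is missing column(s): %s.", arg, paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(tbl$pkd) || any(!is.finite(tbl$pkd))) {
    abort(sprintf("`%s` contains non-finite pkd values.", arg))
  }
  keys <- pair_key(tbl$compound_id, tbl$protein_id)
  if (anyDuplicated(keys)) {
    abort(sprintf("`%s` has more than one row for the same (compound, protein) pair.", arg))
  }
  invisible(tbl)
}

#' @noRd
assert_predictions <- function(tbl, arg = "pred") {
  if (!is.data.frame(tbl)) {
    abort(sprintf("`%s` must be a data frame with columns compound_id, protein_id, pkd_pred.", arg))
  }
  missing_cols <- setdiff(c("compound_id", "protein_id", "pkd_pred"), names(tbl))
  if (length(missing_cols) > 0) {
    abort(sprintf("`%s` is missing column(s): %s.", arg, paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(tbl$pkd_pred) || any(!is.finite(tbl$pkd_pred))) {
    abort(sprintf("`%s` contains non-finite predicted pkd values.", arg))
  }
  invisible(tbl)
}

# Inner join of a prediction table against measured interactions, erroring on
# predicted pairs absent from the measured set.
join_pred_measured <- function(pred, measured) {
  assert_predictions(pred)
  assert_interactions(measured, "measured")
  joined <- inner_join(pred, measured, by = c("compound_id", "protein_id"))
  if (nrow(joined) < nrow(pred)) {
    abort("Some predicted pairs are absent from the measured interaction table.")
  }
  joined
}

#' @noRd
check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s].", name, format(lower), format(upper)))
  }
  invisible(x)
}
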