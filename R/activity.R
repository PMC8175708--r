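# Occupancy-based conversion between pKd and expected single-dose inhibition,
# the combined measured+predicted activity predictor, and kinase-class
# enrichment over prediction-error rankings.

#' Assay context for occupancy calculations
#'
#' Fixes the concentrations of the two-step screening protocol: the fixed
#' ligand concentration of the single-dose inhibition assay (default 1 uM)
#' and the top concentration of the dose-response Kd assay (default 10 uM,
#' below which Kd is unresolvable and pKd is censored at 5).
#'
#' @param ligand_concentration Single-dose ligand concentration in molar
#'   (default 1e-6).
#' @param kd_ceiling Dose-response assay ceiling in molar (default 1e-5).
#' @return An `"assay_context"` list.
#' @export
assay_context <- function(ligand_concentration = 1e-6, kd_ceiling = 1e-5) {
  if (ligand_concentration <= 0 || kd_ceiling <= 0) {
    abort("Assay concentrations must be positive.")
  }
  structure(
    list(ligand_concentration = ligand_concentration, kd_ceiling = kd_ceiling),
    class = "assay_context"
  )
}

#' Expected single-dose inhibition from a pKd (ligand occupancy)
#'
#' At equilibrium the fraction of protein bound by a ligand at concentration
#' L is the occupancy L / (L + Kd). Expressed in percent against a measured
#' or predicted pKd:
#' expected inhibition = 100 L / (L + 10^-pKd).
#' At the 1 uM single-dose concentration, pKd 6 gives exactly 50%, pKd 4
#' about 1% and pKd 9 about 100%. The mapping is strictly increasing in pKd
#' and depends on (pKd, L) only through L * 10^pKd.
#'
#' @param pkd Numeric vector of pKd values.
#' @param ctx An [assay_context()] (its `ligand_concentration` is used).
#' @return Expected inhibition in percent, in (0, 100).
#' @seealso [pkd_from_inhibition()] for the inverse.
#' @export
expected_inhibition <- function(pkd, ctx = assay_context()) {
  if (anyNA(pkd) || any(!is.finite(pkd))) abort("`pkd` must be finite.")
  L <- ctx$ligand_concentration
  100 * L / (L + 10^(-pkd))
}

#' @rdname expected_inhibition
#' @param inhibition Inhibition percentage(s) strictly inside (0, 100).
#' @export
pkd_from_inhibition <- function(inhibition, ctx = assay_context()) {
  if (any(inhibition <= 0 | inhibition >= 100)) {
    abort("`inhibition` must be strictly inside (0, 100) to invert.")
  }
  L <- ctx$ligand_concentration
  occ <- inhibition / 100
  -log10(L * (1 - occ) / occ)
}

#' Combined measured + predicted activity score
#'
#' Averages the measured single-dose inhibition with the expected inhibition
#' implied by a model-predicted pKd, yielding a percent-scale score that
#' combines the cheap experimental screen with the computational prediction.
#' Monotone in both arguments.
#'
#' @param measured_inhibition Measured single-dose inhibition (%), clipped to
#'   \[0, 100\].
#' @param predicted_pkd Model-predicted pKd.
#' @param ctx An [assay_context()].
#' @return Combined score in percent.
#' @export
combined_predictor <- function(measured_inhibition, predicted_pkd,
                               ctx = assay_context()) {
  clipped <- pmin(pmax(measured_inhibition, 0), 100)
  (clipped + expected_inhibition(predicted_pkd, ctx)) / 2
}

#' Rank compound-kinase pairs by absolute prediction error
#'
#' The absolute error AE = |predicted - measured| per pair, sorted from
#' highest to lowest; ties keep a stable order by pair key. This ranking is
#' the input to kinase-class enrichment.
#'
#' @inheritParams concordance_index
#' @return A tibble (`compound_id`, `protein_id`, `pkd`, `pkd_pred`, `ae`)
#'   ordered by descending AE.
#' @export
absolute_errors <- function(pred, measured) {
  joined <- join_pred_measured(pred, measured)
  joined |>
    mutate(ae = abs(.data$pkd_pred - .data$pkd)) |>
    arrange(desc(.data$ae), .data$compound_id, .data$protein_id) |>
    select("compound_id", "protein_id", "pkd", "pkd_pred", "ae")
}

ks_running_score <- function(weights, member) {
  # GSEA-style running sum: member steps up proportional to its weight,
  # non-members step down uniformly; ES is the extreme deviation (signed).
  n <- length(member)
  n_mem <- sum(member)
  w_sum <- sum(weights[member])
  if (w_sum > 0) {
    up <- ifelse(member, weights / w_sum, 0)
  } else {
    up <- ifelse(member, 1 / n_mem, 0) # all-zero weights: fall back to uniform
  }
  down <- ifelse(member, 0, 1 / (n - n_mem))
  running <- cumsum(up - down)
  running[which.max(abs(running))]
}

#' Kinase-class enrichment over an absolute-error ranking
#'
#' Tests whether kinase classes (families or groups) concentrate at the top
#' (hard-to-predict) or bottom (easy-to-predict) of the AE ranking, using a
#' weighted Kolmogorov-Smirnov-like running statistic in the style of gene
#' set enrichment analysis: walking down the ranked pair list, class members
#' increment the running sum proportionally to their AE (weighting exponent
#' 1) and non-members decrement it uniformly; the enrichment score is the
#' signed extreme deviation. P values come from permuting class membership
#' over pairs, two-sided on |ES| with the +1 correction, followed by
#' Benjamini-Hochberg adjustment across classes.
#'
#' @param ranking AE-ranked tibble from [absolute_errors()].
#' @param annotations Kinase annotation tibble
#'   (`protein_id`, `group`, `family`).
#' @param level `"family"` or `"group"`.
#' @param n_perm Number of membership permutations (default 1000).
#' @param seed Integer seed.
#' @param min_size Smallest class size tested (default 2); classes covering
#'   every pair are untestable and are skipped.
#' @return A tibble with one row per tested class: `class_name`,
#'   `class_size`, `es`, `p_value`, `adjusted_p`.
#' @export
ks_enrichment <- function(ranking, annotations, level = c("family", "group"),
                          n_perm = 1000, seed = 1, min_size = 2) {
  level <- match.arg(level)
  if (!all(c("protein_id", "ae") %in% names(ranking))) {
    abort("`ranking` must come from absolute_errors() (needs protein_id and ae).")
  }
  ranking <- arrange(ranking, desc(.data$ae))
  missing_annot <- setdiff(unique(ranking$protein_id), annotations$protein_id)
  if (length(missing_annot) > 0) {
    abort(sprintf("Unannotated kinase(s): %s.", paste(missing_annot, collapse = ", ")))
  }
  class_of <- setNames(annotations[[level]], annotations$protein_id)
  pair_class <- unname(class_of[ranking$protein_id])
  weights <- ranking$ae
  n <- length(weights)
  classes <- sort(unique(pair_class))
  sizes <- table(pair_class)
  classes <- classes[sizes[classes] >= min_size & sizes[classes] < n]
  if (length(classes) == 0) abort("No testable class (size >= min_size and not all pairs).")

  perm_idx <- withr::with_seed(seed, {
    replicate(n_perm, sample.int(n), simplify = FALSE)
  })
  results <- map(classes, function(cl) {
    member <- pair_class == cl
    es <- ks_running_score(weights, member)
    es_null <- map_dbl(perm_idx, function(idx) ks_running_score(weights, member[idx]))
    p <- (1 + sum(abs(es_null) >= abs(es))) / (n_perm + 1)
    tibble(class_name = cl, class_size = sum(member), es = es, p_value = p)
  }) |> list_rbind()
  mutate(results, adjusted_p = p.adjust(.data$p_value, method = "BH"))
}
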