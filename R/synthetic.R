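# Synthetic compound-kinase datasets with the statistical structure the
# pipeline assumes: cluster-structured fingerprints, family-structured
# sequences, a low-rank bilinear ground-truth pKd surface, left-censored
# noisy observations, and occupancy-derived single-dose inhibition.

#' Specification of a synthetic compound-kinase dataset
#'
#' The generator emulates the structure of a blinded kinase-profiling
#' campaign: compounds fall into structural clusters (cluster prototype bit
#' fingerprints plus per-compound bit flips), proteins into sequence families
#' (family ancestor plus point substitutions), the ground-truth pKd surface
#' is a rank-`bilinear_rank` bilinear form of the generating kernels rescaled
#' into \[4, 10\], observations are a random subsample with Gaussian assay
#' noise applied before left-censoring at `censor_floor` (the 10 uM assay
#' ceiling maps to pKd 5), and single-dose inhibition at 1 uM follows the
#' ligand-occupancy curve of the true pKd plus Gaussian noise clipped to
#' \[0, 100\].
#'
#' @param n_compounds,n_proteins Entity counts (>= 1).
#' @param n_compound_clusters,n_protein_families Latent structure counts.
#' @param fp_bits Fingerprint length (default 1024).
#' @param bilinear_rank Rank of the latent bilinear interaction (default 5).
#' @param noise_sd Assay noise on observed pKd, in pKd units (default 0.2,
#'   of the order of replicate-measurement scatter).
#' @param frac_observed Fraction of the pair grid observed, in (0, 1\]
#'   (default 0.3 — affinity matrices are sparse).
#' @param censor_floor Left-censoring floor on observed pKd (default 5;
#'   use `-Inf` to disable).
#' @param inhibition_noise_sd Gaussian noise on the single-dose inhibition
#'   channel, in percentage points (default 10 — single-dose screens are not
#'   optimised for accuracy).
#' @param seq_length Protein sequence length (default 300: long enough for
#'   meaningful alignment scores, short enough for desk-scale tests).
#' @param seed Integer seed; the same spec generates the identical dataset.
#' @return A `"synthetic_spec"` list.
#' @export
synthetic_spec <- function(n_compounds = 40, n_proteins = 30,
                           n_compound_clusters = 4, n_protein_families = 3,
                           fp_bits = 1024, bilinear_rank = 5,
                           noise_sd = 0.2, frac_observed = 0.3,
                           censor_floor = 5, inhibition_noise_sd = 10,
                           seq_length = 300, seed = 1) {
  stopifnot(
    n_compounds >= 1, n_proteins >= 1,
    n_compound_clusters >= 1, n_protein_families >= 1,
    fp_bits >= 1, bilinear_rank >= 1, seq_length >= 1
  )
  if (noise_sd < 0 || inhibition_noise_sd < 0) abort("Noise SDs must be non-negative.")
  if (frac_observed <= 0 || frac_observed > 1) abort("`frac_observed` must be in (0, 1].")
  structure(
    list(
      n_compounds = as.integer(n_compounds),
      n_proteins = as.integer(n_proteins),
      n_compound_clusters = as.integer(n_compound_clusters),
      n_protein_families = as.integer(n_protein_families),
      fp_bits = as.integer(fp_bits),
      bilinear_rank = as.integer(bilinear_rank),
      noise_sd = noise_sd,
      frac_observed = frac_observed,
      censor_floor = censor_floor,
      inhibition_noise_sd = inhibition_noise_sd,
      seq_length = as.integer(seq_length),
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

.aa_letters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Generate a synthetic compound-kinase dataset
#'
#' See [synthetic_spec()] for what is emulated. The returned dataset carries
#' the generating kernels (Tanimoto over the synthetic fingerprints,
#' normalised Smith-Waterman over the synthetic sequences), so parameter
#' recovery with the matched model can be tested directly.
#'
#' @param spec A [synthetic_spec()].
#' @return A `"synthetic_dataset"` with elements `compounds`, `proteins`,
#'   `annotations`, `truth` (full uncensored pair grid), `observed`
#'   (censored, subsampled interaction table), `inhibition` (per-pair
#'   single-dose % at 1 uM), `compound_kernel`, `protein_kernel`, `spec`.
#' @export
generate_synthetic <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) abort("`spec` must come from synthetic_spec().")
  withr::with_seed(spec$seed, {
    nc <- spec$n_compounds
    np <- spec$n_proteins
    cids <- sprintf("C%03d", seq_len(nc))
    pids <- sprintf("P%03d", seq_len(np))

    # compounds: cluster prototype bits (density 0.1) + per-compound flips (2%)
    cluster <- rep_len(seq_len(spec$n_compound_clusters), nc)
    protos <- matrix(rbinom(spec$n_compound_clusters * spec$fp_bits, 1, 0.1),
                     spec$n_compound_clusters, spec$fp_bits)
    flips <- matrix(rbinom(nc * spec$fp_bits, 1, 0.02), nc, spec$fp_bits)
    fps <- abs(protos[cluster, , drop = FALSE] - flips)
    storage.mode(fps) <- "integer"
    zero <- rowSums(fps) == 0
    fps[zero, 1] <- 1L # guarantee a non-empty fingerprint
    rownames(fps) <- cids
    attr(fps, "fp_spec") <- fingerprint_spec("circular", 2, spec$fp_bits)

    # proteins: family ancestor sequences + 10% point substitutions
    fam_idx <- rep_len(seq_len(spec$n_protein_families), np)
    ancestors <- replicate(spec$n_protein_families,
                           sample(.aa_letters, spec$seq_length, replace = TRUE),
                           simplify = FALSE)
    seqs <- vapply(seq_len(np), function(i) {
      s <- ancestors[[fam_idx[i]]]
      mut <- runif(spec$seq_length) < 0.1
      s[mut] <- sample(.aa_letters, sum(mut), replace = TRUE)
      paste(s, collapse = "")
    }, character(1))
    n_groups <- max(1L, ceiling(spec$n_protein_families / 2))
    fam_group <- sprintf("G%d", ((seq_len(spec$n_protein_families) - 1L) %% n_groups) + 1L)

    compounds <- tibble(
      compound_id = cids,
      cluster = sprintf("CL%d", cluster),
      fingerprint = lapply(seq_len(nc), function(i) fps[i, ])
    )
    proteins <- tibble(
      protein_id = pids,
      family = sprintf("F%d", fam_idx),
      group = fam_group[fam_idx],
      sequence = seqs
    )
    annotations <- proteins[, c("protein_id", "group", "family")]

    Kc <- similarity_kernel(fps, "tanimoto")
    Kp <- protein_kernel(proteins)

    # ground truth: low-rank bilinear surface of the kernels, rescaled to [4, 10]
    U <- matrix(rnorm(nc * spec$bilinear_rank), nc, spec$bilinear_rank)
    V <- matrix(rnorm(np * spec$bilinear_rank), np, spec$bilinear_rank)
    scores <- Kc$values %*% U %*% t(V) %*% Kp$values
    rng <- range(scores)
    truth_mat <- if (diff(rng) > 0) 4 + 6 * (scores - rng[1]) / diff(rng) else
      matrix(7, nc, np)
    dimnames(truth_mat) <- list(cids, pids)
    truth <- tidyr::expand_grid(compound_id = cids, protein_id = pids) |>
      mutate(pkd = truth_mat[cbind(.data$compound_id, .data$protein_id)])

    # observed: random subsample, Gaussian noise, then left-censoring
    n_obs <- max(1L, round(spec$frac_observed * nrow(truth)))
    obs_idx <- sort(sample.int(nrow(truth), n_obs))
    observed <- truth[obs_idx, , drop = FALSE] |>
      mutate(pkd = pmax(.data$pkd + rnorm(n_obs, 0, spec$noise_sd), spec$censor_floor))

    # single-dose channel: occupancy of the true pKd at 1 uM plus noise
    inhibition <- truth |>
      mutate(
        inhibition = pmin(pmax(
          expected_inhibition(.data$pkd) +
            rnorm(nrow(truth), 0, spec$inhibition_noise_sd),
          0), 100)
      ) |>
      select("compound_id", "protein_id", "inhibition")

    structure(
      list(
        spec = spec,
        compounds = compounds,
        proteins = proteins,
        annotations = annotations,
        truth = truth,
        observed = observed,
        inhibition = inhibition,
        fingerprints = fps,
        compound_kernel = Kc,
        protein_kernel = Kp
      ),
      class = "synthetic_dataset"
    )
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d compounds x %d proteins; %d observed pKd (floor %g), seed %d\n",
    x$spec$n_compounds, x$spec$n_proteins, nrow(x$observed),
    x$spec$censor_floor, x$spec$seed
  ))
  invisible(x)
}

#' Export a synthetic dataset to the plain-text interchange formats
#'
#' Writes `bioactivity.csv` (observed pKd rows as molar KD records plus the
#' single-dose channel as INHIBITION_PCT rows), `proteins.fasta`,
#' `fingerprints.tsv`, `annotations.tsv` and a `spec.json` provenance
#' sidecar. Re-importing the bioactivity CSV with [merge_replicates()]
#' reproduces the observed interaction table.
#'
#' @param dataset A `"synthetic_dataset"`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
export_synthetic <- function(dataset, dir) {
  if (!inherits(dataset, "synthetic_dataset")) abort("`dataset` must come from generate_synthetic().")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    bioactivity = file.path(dir, "bioactivity.csv"),
    proteins = file.path(dir, "proteins.fasta"),
    fingerprints = file.path(dir, "fingerprints.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    spec = file.path(dir, "spec.json")
  )
  kd_rows <- dataset$observed |>
    mutate(assay_type = "KD", value = 10^(-.data$pkd), unit = "M") |>
    select("compound_id", "protein_id", "assay_type", "value", "unit")
  inh_rows <- dataset$inhibition |>
    mutate(assay_type = "INHIBITION_PCT", value = .data$inhibition, unit = "PCT") |>
    select("compound_id", "protein_id", "assay_type", "value", "unit")
  write_bioactivity(bind_rows(kd_rows, inh_rows), paths[["bioactivity"]])
  write_proteins(dataset$proteins, paths[["proteins"]])
  write_fingerprints(dataset$fingerprints, paths[["fingerprints"]])
  write_annotations(dataset$annotations, paths[["annotations"]])
  jsonlite::write_json(unclass(dataset$spec), paths[["spec"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
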