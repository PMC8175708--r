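# Fixtures and independent oracles shared across the suite. All fixtures are
# generated in code; nothing is read from disk.

# A small deterministic synthetic dataset reused where a realistic pipeline
# input is needed (computed once per test run).
tiny_ds <- generate_synthetic(synthetic_spec(
  n_compounds = 12, n_proteins = 8, n_compound_clusters = 3,
  n_protein_families = 2, fp_bits = 256, seq_length = 60,
  bilinear_rank = 3, seed = 3
))

# Random positive-definite kernel with unit diagonal.
random_pd_kernel <- function(ids, seed) {
  n <- length(ids)
  withr::with_seed(seed, {
    W <- matrix(rnorm(n * n), n, n)
    K <- W %*% t(W) + 0.5 * diag(n)
    d <- diag(K)
    kernel_matrix(K / sqrt(outer(d, d)), ids)
  })
}

# Random interaction table over given entity ids.
random_interactions <- function(cids, pids, n, seed) {
  withr::with_seed(seed, {
    grid <- expand.grid(compound_id = cids, protein_id = pids,
                        stringsAsFactors = FALSE)
    rows <- grid[sample.int(nrow(grid), n), ]
    tibble::tibble(
      compound_id = rows$compound_id,
      protein_id = rows$protein_id,
      pkd = runif(n, 4, 10)
    )
  })
}

as_pred <- function(measured, values, model_id = "fixture") {
  out <- tibble::tibble(
    compound_id = measured$compound_id,
    protein_id = measured$protein_id,
    pkd_pred = values
  )
  attr(out, "model_id") <- model_id
  out
}

# Quadratic-time affine-gap Smith-Waterman oracle. A gap of length L costs
# gap_open + L * gap_extend (the same convention as alignment_scoring()).
sw_oracle <- function(a, b, sub, gap_open = 11, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  neg <- -1e9
  H <- matrix(0, n + 1, m + 1)  # best ending in a match/mismatch or fresh start
  E <- matrix(neg, n + 1, m + 1) # gap in b (moving along a)
  F_ <- matrix(neg, n + 1, m + 1) # gap in a
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i - 1, j] - gap_open - gap_extend, E[i - 1, j] - gap_extend)
      F_[i, j] <- max(H[i, j - 1] - gap_open - gap_extend, F_[i, j - 1] - gap_extend)
      diag_best <- max(H[i - 1, j - 1], E[i - 1, j - 1], F_[i - 1, j - 1])
      H[i, j] <- max(0, diag_best + sub[A[i - 1], B[j - 1]])
      best <- max(best, H[i, j], E[i, j], F_[i, j])
    }
  }
  best
}

# Brute-force concordance index over all pair-of-pairs.
ci_oracle <- function(f, y) {
  num <- 0
  den <- 0
  n <- length(y)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (y[i] == y[j]) next
      den <- den + 1
      if (f[i] == f[j]) {
        num <- num + 0.5
      } else if ((f[i] - f[j]) * (y[i] - y[j]) > 0) {
        num <- num + 1
      }
    }
  }
  num / den
}

# Dense oracle for the sampled-Kronecker KronRLS system: builds the labelled
# pairwise kernel explicitly and solves it directly.
dense_cg_oracle <- function(Kc, Kp, train, lambda, query) {
  ci <- train$compound_id
  pi_ <- train$protein_id
  M <- Kc$values[ci, ci] * Kp$values[pi_, pi_]
  a <- solve(M + lambda * diag(nrow(train)), train$pkd)
  vapply(seq_len(nrow(query)), function(q) {
    sum(a * Kc$values[query$compound_id[q], ci] * Kp$values[query$protein_id[q], pi_])
  }, numeric(1))
}

blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

random_aa <- function(len, seed) {
  withr::with_seed(seed, paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                      len, replace = TRUE), collapse = ""))
}
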