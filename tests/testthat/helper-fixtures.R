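# shared fixtures, generated in code at test time

# the reference comparison of standard vs sparse designs for the two
# breeding scenarios (250 and 4500 treatments, 4 locations, 1 rep/location);
# columns: standard, sparse at 85/75/50/25/15% training, gains at the same
expected_scn1 <- rbind(
  Total_trts    = c(250, 294, 333, 500, 1000, 1667, 17.60, 33.20, 100.00, 300.00, 566.80),
  New_lines     = c(225, 269, 308, 475, 975, 1642, 19.56, 36.89, 111.11, 333.33, 629.78),
  Checks        = c(25, 25, 25, 25, 25, 25, 0, 0, 0, 0, 0),
  Reps          = c(1, 0.85, 0.75, 0.5, 0.25, 0.15, -15, -25, -50, -75, -85),
  Locs          = c(4, 4, 4, 4, 4, 4, 0, 0, 0, 0, 0),
  R             = c(4, 3.4, 3, 2, 1, 0.6, -15, -25, -50, -75, -85),
  Total_plots   = c(1000, 1000, 1000, 1000, 1000, 1000, 0, 0, 0, 0, 0),
  Total_trts2   = c(250, 294, 333, 500, 1000, 1667, 17.60, 33.20, 100.00, 300.00, 566.80),
  Plots_per_trt = c(4.44, 3.72, 3.25, 2.11, 1.03, 0.61, -16.36, -26.95, -52.63, -76.92, -86.30))

expected_scn2 <- rbind(
  Total_trts    = c(4500, 5294, 6000, 9000, 18000, 30000, 17.64, 33.33, 100.00, 300.00, 566.67),
  New_lines     = c(4450, 5244, 5950, 8950, 17950, 29950, 17.84, 33.71, 101.12, 303.37, 573.03),
  Checks        = c(50, 50, 50, 50, 50, 50, 0, 0, 0, 0, 0),
  Reps          = c(1, 0.85, 0.75, 0.5, 0.25, 0.15, -15, -25, -50, -75, -85),
  Locs          = c(4, 4, 4, 4, 4, 4, 0, 0, 0, 0, 0),
  R             = c(4, 3.4, 3, 2, 1, 0.6, -15, -25, -50, -75, -85),
  Total_plots   = c(18000, 18000, 18000, 18000, 18000, 18000, 0, 0, 0, 0, 0),
  Total_trts2   = c(4500, 5294, 6000, 9000, 18000, 30000, 17.64, 33.33, 100.00, 300.00, 566.67),
  Plots_per_trt = c(4.04, 3.43, 3.03, 2.01, 1.00, 0.60, -15.14, -25.21, -50.28, -75.21, -85.14))

line_names <- function(J) paste0("L", seq_len(J))
env_names <- function(I) paste0("E", seq_len(I))

# small marker panel + GRM, memoised per (J, p, seed)
fixture_panel <- local({
  cache <- list()
  function(J = 60, p = 300, seed = 11) {
    key <- paste(J, p, seed, sep = "_")
    if (is.null(cache[[key]])) {
      M <- sim_markers(J, p, seed = seed)
      cache[[key]] <<- list(M = M, G = compute_grm(M))
    }
    cache[[key]]
  }
})

# brute-force VanRaden GRM: per-pair double loop, no matrix algebra
naive_grm <- function(M) {
  p <- colMeans(M, na.rm = TRUE) / 2
  denom <- 2 * sum(p * (1 - p))
  W <- M
  for (k in seq_len(ncol(M))) {
    W[, k] <- M[, k] - 2 * p[k]
    W[is.na(M[, k]), k] <- 0
  }
  J <- nrow(M)
  G <- matrix(0, J, J)
  for (i in seq_len(J)) for (j in seq_len(J))
    G[i, j] <- sum(W[i, ] * W[j, ]) / denom
  dimnames(G) <- list(rownames(M), rownames(M))
  G
}

# brute-force concurrence: count co-occurrences environment by environment
naive_concurrence <- function(mask) {
  J <- nrow(mask); I <- ncol(mask)
  lam <- matrix(0L, J, J)
  for (e in seq_len(I)) for (i in seq_len(J)) for (j in seq_len(J))
    if (mask[i, e] == 1L && mask[j, e] == 1L) lam[i, j] <- lam[i, j] + 1L
  lam
}

# dense mixed-model-equations GBLUP solve on the observed cells only:
# environment effects fixed, line effects with covariance s2g * G
mme_gblup <- function(pheno_obs, G, s2g, s2e) {
  J <- nrow(G)
  env <- factor(pheno_obs$env_id)
  X <- stats::model.matrix(~ 0 + env)
  Z <- matrix(0, nrow(pheno_obs), J)
  Z[cbind(seq_len(nrow(pheno_obs)), match(pheno_obs$line_id, rownames(G)))] <- 1
  Ginv <- solve(regularize_psd(G))
  C <- rbind(cbind(crossprod(X) / s2e, crossprod(X, Z) / s2e),
             cbind(crossprod(Z, X) / s2e, crossprod(Z) / s2e + Ginv / s2g))
  rhs <- c(crossprod(X, pheno_obs$value), crossprod(Z, pheno_obs$value)) / s2e
  sol <- solve(C, rhs)
  list(beta = sol[seq_len(nlevels(env))], g = sol[-seq_len(nlevels(env))])
}

# keep only the training cells of a design in a phenotype table
training_cells <- function(pheno, design) {
  m <- design$mask[cbind(match(as.character(pheno$line_id), design$line_ids),
                         match(as.character(pheno$env_id), design$env_ids))]
  pheno[m == 1L, , drop = FALSE]
}

testing_cells <- function(pheno, design) {
  m <- design$mask[cbind(match(as.character(pheno$line_id), design$line_ids),
                         match(as.character(pheno$env_id), design$env_ids))]
  pheno[m == 0L, , drop = FALSE]
}
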