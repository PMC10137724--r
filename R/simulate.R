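#' Simulate a biallelic marker panel
#'
#' Per-marker allele frequencies are drawn uniformly in \code{maf_range} and
#' dosages independently as Binomial(2, p) per line — an unstructured panel
#' without linkage disequilibrium or stratification, sufficient to give the
#' genomic relationship matrix realistic spread.
#'
#' @param J number of lines.
#' @param p number of markers.
#' @param maf_range allele-frequency range (default \code{c(0.05, 0.5)}).
#' @param seed integer seed.
#' @return J x p dosage matrix with line/marker ids as dimnames.
#' @export
sim_markers <- function(J, p, maf_range = c(0.05, 0.5), seed = 1L) {
  stopifnot(J >= 2, p >= 1)
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] < 0 || maf_range[2] > 1)
    stop("degenerate allele-frequency range", call. = FALSE)
  with_seed(seed, {
    freq <- runif(p, maf_range[1], maf_range[2])
    M <- matrix(rbinom(J * p, 2L, rep(freq, each = J)), J, p)
  })
  dimnames(M) <- list(paste0("L", seq_len(J)), paste0("M", seq_len(p)))
  storage.mode(M) <- "double"
  M
}

cor_mat <- function(rho, nT) {
  C <- matrix(rho, nT, nT); diag(C) <- 1
  C
}

# matrix-normal draw MN(0, RowCov, ColCov) via Cholesky factors; zero
# covariances give exact zeros.
rmatnorm <- function(nr, Lrow, ColCov) {
  nT <- nrow(ColCov)
  if (max(abs(ColCov)) == 0) return(matrix(0, nr, nT))
  Z <- matrix(stats::rnorm(nr * nT), nr, nT)
  Lrow %*% Z %*% chol(ColCov)
}

#' Simulate multi-trait multi-environment phenotypes with known truth
#'
#' Forward-simulates the model fitted by \code{\link{sparse_gblup}}: line
#' main effects \eqn{g \sim MN(0, G, \Sigma_T)}, per-environment interaction
#' effects \eqn{g_{E,i} \sim MN(0, G, \Sigma_{T2})}, iid residual rows with
#' covariance R, and fixed environment effects. Variance components are
#' parameterized as proportions of a unit total phenotypic variance per
#' trait: \code{h2} is the genomic proportion, \code{prop_ge} the
#' interaction proportion, and the residual takes the remainder, so
#' \code{h2} reads as a (narrow-sense, plot-level) heritability.
#'
#' @param markers dosage matrix (the GRM is computed from it), or an
#'   already-computed GRM passed via \code{G}.
#' @param I number of environments.
#' @param nT number of traits.
#' @param h2 genomic variance proportion per trait (scalar or length nT).
#' @param prop_ge interaction variance proportion (scalar or length nT).
#' @param rg genetic correlation between traits (exchangeable structure).
#' @param rg_ge trait correlation of the interaction effects (default
#'   \code{rg}).
#' @param r_resid residual trait correlation (default 0).
#' @param env_means I x nT matrix of environment effects, or \code{NULL} to
#'   draw them as N(0, 1).
#' @param mu overall intercept per trait.
#' @param G optional GRM overriding \code{markers}.
#' @param seed integer seed.
#' @return list with \code{pheno} (tidy table of all J x I x nT values),
#'   \code{truth} (the realized \code{g}, \code{ge}, \code{beta_env},
#'   covariance matrices and variance proportions) and \code{G}.
#' @export
sim_phenotypes <- function(markers = NULL, I = 3, nT = 2, h2 = 0.5,
                           prop_ge = 0.2, rg = 0.7, rg_ge = rg,
                           r_resid = 0, env_means = NULL, mu = 0,
                           G = NULL, seed = 1L) {
  if (is.null(G)) G <- compute_grm(markers)
  G <- validate_grm(G, tol = 1e-6)
  J <- nrow(G)
  h2 <- rep_len(h2, nT); prop_ge <- rep_len(prop_ge, nT)
  resid_prop <- 1 - h2 - prop_ge
  if (any(h2 < 0) || any(prop_ge < 0) || any(resid_prop < 0))
    stop("variance proportions must be non-negative and sum to at most 1",
         call. = FALSE)
  sc <- function(props, C) diag(sqrt(props), nT) %*% C %*% diag(sqrt(props), nT)
  Sigma_T <- sc(h2, cor_mat(rg, nT))
  Sigma_T2 <- sc(prop_ge, cor_mat(rg_ge, nT))
  R <- sc(resid_prop, cor_mat(r_resid, nT))
  Lg <- t(chol(regularize_psd(G)))
  line_ids <- rownames(G)
  env_ids <- paste0("E", seq_len(I))
  mu <- rep_len(mu, nT)

  out <- with_seed(seed, {
    beta_env <- if (is.null(env_means))
      matrix(stats::rnorm(I * nT), I, nT) else as.matrix(env_means)
    g <- rmatnorm(J, Lg, Sigma_T)
    ge <- lapply(seq_len(I), function(i) rmatnorm(J, Lg, Sigma_T2))
    Y <- do.call(rbind, lapply(seq_len(I), function(i) {
      eps <- rmatnorm(J, diag(J), R)
      matrix(mu, J, nT, byrow = TRUE) +
        matrix(beta_env[i, ], J, nT, byrow = TRUE) + g + ge[[i]] + eps
    }))
    list(beta_env = beta_env, g = g, ge = ge, Y = Y)
  })

  traits <- paste0("trait", seq_len(nT))
  pheno <- data.frame(
    line_id = rep(rep(line_ids, times = I), times = nT),
    env_id = rep(rep(env_ids, each = J), times = nT),
    trait = rep(traits, each = I * J),
    value = as.vector(out$Y),
    stringsAsFactors = FALSE)
  g <- out$g; dimnames(g) <- list(line_ids, traits)
  list(pheno = pheno,
       truth = list(mu = mu, beta_env = out$beta_env, g = g, ge = out$ge,
                    Sigma_T = Sigma_T, Sigma_T2 = Sigma_T2, R = R,
                    h2 = h2, prop_ge = prop_ge,
                    line_ids = line_ids, env_ids = env_ids, traits = traits),
       G = G)
}

#' Simulate incomplete-block plot data around known genotype values
#'
#' Lays J genotypes out in an alpha-lattice-like design — \code{reps}
#' complete replicates, each randomly partitioned into incomplete blocks —
#' and generates plot values as genotype truth + fixed replicate shift +
#' random block effect + residual. Feeding the result to
#' \code{\link{fit_stage_one}} recovers the genotype values.
#'
#' @param genotype_values named numeric vector of true genotype means.
#' @param env_id environment label for the records.
#' @param reps number of complete replicates.
#' @param blocks_per_rep incomplete blocks per replicate.
#' @param sigma_block SD of the block-within-replicate effects.
#' @param sigma_e residual SD.
#' @param rep_shift_sd SD of the fixed replicate shifts (drawn once).
#' @param trait trait column name.
#' @param seed integer seed.
#' @return data.frame of plot records (\code{line_id}, \code{env_id},
#'   \code{rep}, \code{block}, trait column).
#' @export
sim_plot_data <- function(genotype_values, env_id = "E1", reps = 2,
                          blocks_per_rep = 10, sigma_block = 1,
                          sigma_e = 0.5, rep_shift_sd = 0.5,
                          trait = "trait1", seed = 1L) {
  J <- length(genotype_values)
  stopifnot(J >= 2, reps >= 1, blocks_per_rep >= 1, blocks_per_rep <= J)
  ids <- names(genotype_values)
  if (is.null(ids)) ids <- paste0("L", seq_len(J))
  bsize <- ceiling(J / blocks_per_rep)
  with_seed(seed, {
    rep_shift <- stats::rnorm(reps, 0, rep_shift_sd)
    recs <- lapply(seq_len(reps), function(r) {
      ord <- sample.int(J)
      block <- rep(seq_len(blocks_per_rep), each = bsize)[seq_len(J)]
      beff <- stats::rnorm(blocks_per_rep, 0, sigma_block)
      data.frame(line_id = ids[ord], env_id = env_id, rep = paste0("R", r),
                 block = paste0("B", block),
                 value = genotype_values[ord] + rep_shift[r] + beff[block] +
                   stats::rnorm(J, 0, sigma_e),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, recs)
    names(out)[names(out) == "value"] <- trait
    rownames(out) <- NULL
    out
  })
}
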