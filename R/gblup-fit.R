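#' Multi-trait Bayesian GBLUP with genotype-by-environment interaction
#'
#' Fits, by Gibbs sampling, the second-stage multi-environment model
#' \deqn{Y = 1_n \mu' + X_E \beta_E + Z_L g + Z_{EL} g_E + \epsilon,}
#' where Y is the n x nT response (cells ordered by environment, then line;
#' one column per trait), \eqn{\beta_E} are fixed environment effects, the
#' line main effects follow the matrix-variate normal
#' \eqn{g \sim MN(0, G, \Sigma_T)} with G the genomic relationship matrix
#' and \eqn{\Sigma_T} the trait covariance, the interaction effects are
#' independent across environments with \eqn{g_{E,i} \sim MN(0, G,
#' \Sigma_{T2})} (the environment-block-diagonal form of the Hadamard
#' interaction covariance under one-hot environment design), and residual
#' rows are iid \eqn{N(0, R)}. With a single trait all trait covariances
#' collapse to scalars and the model is the familiar uni-trait GBLUP with
#' G-by-E.
#'
#' Cells excluded by the \code{design} mask, or absent from \code{pheno},
#' are treated as missing and imputed within the sampler (data
#' augmentation); their observed values, if any, never enter the fit.
#' Trait covariance matrices get inverse-Wishart full conditionals with
#' weakly informative defaults (df nT + 4; scale set so each component's
#' prior expected variance is a quarter of the phenotypic variance); fixed
#' effects are flat. The line-effect and interaction updates are performed
#' in the eigenbasis of G (computed once) and a trait basis jointly
#' diagonalizing R and the relevant trait covariance, so each sweep costs
#' O(J nT) solves plus dense multiplications by the eigenvector matrix.
#'
#' @param pheno tidy phenotype table: columns \code{line_id}, \code{env_id},
#'   \code{trait}, \code{value}, optional \code{weight} (inverse variance of
#'   a stage-one BLUE; see \code{weights}).
#' @param G genomic relationship matrix with line ids as dimnames; it is
#'   ridge-regularized internally (\code{\link{regularize_psd}}).
#' @param design optional \code{\link{allocate_lines}} design; cells with
#'   mask 0 are forced missing (the testing set).
#' @param traits traits to fit (default: all in \code{pheno}, sorted).
#' @param weights \code{"auto"} uses the \code{weight} column when present
#'   (row weights; averaged across traits if they differ), \code{"none"}
#'   ignores it. Weights are normalized to mean 1 and scale the residual
#'   precision per cell row.
#' @param include_ge include the G-by-E interaction term (default TRUE).
#' @param niter,burnin,thin MCMC controls (defaults 10000 / 2000 / 5).
#' @param seed integer seed; chains are reproducible given the seed.
#' @param prior optional list overriding \code{nu} (df) and \code{S_T},
#'   \code{S_T2}, \code{S_R} (inverse-Wishart scale matrices).
#' @param fix optional list with any of \code{Sigma_T}, \code{Sigma_T2},
#'   \code{R}: matrices held fixed instead of sampled (used for validation
#'   against closed-form mixed-model solutions).
#' @param verbose print progress every 1000 iterations.
#' @return an object of class \code{sparse_gblup}; see
#'   \code{\link{summary.sparse_gblup}}, \code{\link{predict.sparse_gblup}}.
#' @seealso \code{\link{run_cv}} for the cross-validation harness built on
#'   this fit.
#' @export
sparse_gblup <- function(pheno, G, design = NULL, traits = NULL,
                         weights = c("auto", "none"), include_ge = TRUE,
                         niter = 10000L, burnin = 2000L, thin = 5L,
                         seed = 1L, prior = list(), fix = list(),
                         verbose = FALSE) {
  cl <- match.call()
  weights <- match.arg(weights)
  validate_pheno(pheno)
  G <- validate_grm(G, tol = 1e-6)
  stopifnot(niter > burnin, thin >= 1)

  traits <- if (is.null(traits)) sort(unique(as.character(pheno$trait)))
            else as.character(traits)
  nT <- length(traits)
  pheno <- pheno[pheno$trait %in% traits, , drop = FALSE]

  line_ids <- if (!is.null(design)) as.character(design$line_ids)
              else unique(as.character(pheno$line_id))
  env_ids <- if (!is.null(design)) as.character(design$env_ids)
             else unique(as.character(pheno$env_id))
  absent <- setdiff(line_ids, rownames(G))
  if (length(absent))
    stop("lines absent from G: ", paste(head(absent, 5), collapse = ", "),
         if (length(absent) > 5) " ...", call. = FALSE)
  bad <- setdiff(unique(as.character(pheno$line_id)), line_ids)
  if (length(bad))
    stop("phenotype lines not covered by the design/G: ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  G <- G[line_ids, line_ids]
  J <- length(line_ids); I <- length(env_ids); n <- I * J

  # grid ordered by environment then line
  line_idx <- rep(seq_len(J), times = I)
  env_idx <- rep(seq_len(I), each = J)

  Y <- matrix(NA_real_, n, nT)
  Wt <- matrix(NA_real_, n, nT)
  li <- match(as.character(pheno$line_id), line_ids)
  ei <- match(as.character(pheno$env_id), env_ids)
  ti <- match(as.character(pheno$trait), traits)
  rows <- (ei - 1L) * J + li
  Y[cbind(rows, ti)] <- pheno$value
  if (weights == "auto" && !is.null(pheno$weight))
    Wt[cbind(rows, ti)] <- pheno$weight

  if (!is.null(design)) {
    dmask <- design$mask[match(line_ids, design$line_ids),
                         match(env_ids, design$env_ids), drop = FALSE]
    masked <- dmask[cbind(line_idx, env_idx)] == 0L
    Y[masked, ] <- NA_real_
  }
  obs <- !is.na(Y)
  if (any(colSums(obs) == 0L))
    stop("a trait has no observed training values", call. = FALSE)

  w <- rowMeans(Wt, na.rm = TRUE)
  w[!is.finite(w)] <- NA_real_
  if (all(is.na(w))) w <- rep(1, n) else w[is.na(w)] <- mean(w, na.rm = TRUE)
  w <- w / mean(w)
  uniform_w <- max(abs(w - 1)) < 1e-12

  # priors
  vy <- apply(Y, 2, stats::var, na.rm = TRUE)
  vy[!is.finite(vy) | vy <= 0] <- 1
  nu0 <- if (is.null(prior$nu)) nT + 4 else prior$nu
  S0 <- diag(0.25 * vy * (nu0 - nT - 1), nT)
  S_T <- if (is.null(prior$S_T)) S0 else prior$S_T
  S_T2 <- if (is.null(prior$S_T2)) S0 else prior$S_T2
  S_R <- if (is.null(prior$S_R)) S0 else prior$S_R

  eg <- eigen(regularize_psd(G), symmetric = TRUE)
  U <- eg$vectors; dG <- eg$values
  Ginv <- if (uniform_w) NULL else U %*% (t(U) / dG)

  fit <- with_seed(seed, gibbs_mtgblup(
    Y = Y, obs = obs, w = w, uniform_w = uniform_w,
    U = U, dG = dG, Ginv = Ginv,
    line_idx = line_idx, env_idx = env_idx, J = J, I = I, nT = nT,
    include_ge = include_ge, niter = niter, burnin = burnin, thin = thin,
    nu0 = nu0, S_T = S_T, S_T2 = S_T2, S_R = S_R,
    fix = fix, vy = vy, verbose = verbose))

  structure(c(fit, list(
    call = cl, traits = traits, line_ids = line_ids, env_ids = env_ids,
    observed = obs, y = Y, weights_used = if (uniform_w) NULL else w,
    include_ge = include_ge, design = design,
    control = list(niter = niter, burnin = burnin, thin = thin, seed = seed)
  )), class = "sparse_gblup")
}

# the sampler core; all inputs prepared, RNG already seeded by the caller
gibbs_mtgblup <- function(Y, obs, w, uniform_w, U, dG, Ginv,
                          line_idx, env_idx, J, I, nT,
                          include_ge, niter, burnin, thin,
                          nu0, S_T, S_T2, S_R, fix, vy, verbose) {
  n <- nrow(Y)
  env_rows <- split(seq_len(n), env_idx)

  # initial values
  b <- matrix(0, I, nT)
  for (i in seq_len(I)) {
    m <- colMeans(Y[env_rows[[i]], , drop = FALSE], na.rm = TRUE)
    b[i, ] <- ifelse(is.finite(m), m, 0)
  }
  g <- matrix(0, J, nT)
  ge <- matrix(0, n, nT)
  Sigma_T <- if (!is.null(fix$Sigma_T)) as_mat(fix$Sigma_T, nT) else diag(0.25 * vy, nT)
  Sigma_T2 <- if (!is.null(fix$Sigma_T2)) as_mat(fix$Sigma_T2, nT) else diag(0.25 * vy, nT)
  R <- if (!is.null(fix$R)) as_mat(fix$R, nT) else diag(0.5 * vy, nT)
  Ycur <- Y
  Ycur[!obs] <- (b[env_idx, , drop = FALSE])[!obs]

  # missingness patterns (rows grouped by which traits are missing)
  miss_any <- rowSums(!obs) > 0L
  pat_key <- apply(!obs, 1L, function(z) paste(as.integer(z), collapse = ""))
  pat_rows <- split(which(miss_any), pat_key[miss_any])
  pat_miss <- lapply(names(pat_rows),
                     function(k) which(strsplit(k, "")[[1]] == "1"))

  nkeep <- length(seq(burnin + thin, niter, by = thin))
  sum_b <- matrix(0, I, nT); sum_b2 <- matrix(0, I, nT)
  sum_g <- matrix(0, J, nT); sum_g2 <- matrix(0, J, nT)
  sum_ge <- matrix(0, n, nT); sum_ge2 <- matrix(0, n, nT)
  sum_yhat <- matrix(0, n, nT); sum_yhat2 <- matrix(0, n, nT)
  draws_ST <- array(NA_real_, c(nkeep, nT, nT))
  draws_ST2 <- array(NA_real_, c(nkeep, nT, nT))
  draws_R <- array(NA_real_, c(nkeep, nT, nT))
  draws_g <- array(NA_real_, c(nkeep, J, nT))
  kept <- 0L

  sqw <- sqrt(w)
  a_line <- if (uniform_w) NULL else drop(rowsum(w, line_idx))

  for (it in seq_len(niter)) {
    ## current systematic part
    fitted <- b[env_idx, , drop = FALSE] + g[line_idx, , drop = FALSE] + ge

    ## 1. impute missing cells from their conditional normal
    if (any(miss_any)) {
      cR <- chol(R)
      for (p in seq_along(pat_rows)) {
        rws <- pat_rows[[p]]; mi <- pat_miss[[p]]
        if (length(mi) == nT) {
          z <- matrix(stats::rnorm(length(rws) * nT), ncol = nT) %*% cR
          Ycur[rws, ] <- fitted[rws, , drop = FALSE] + z / sqw[rws]
        } else {
          oi <- setdiff(seq_len(nT), mi)
          Roo_i <- solve(R[oi, oi, drop = FALSE])
          A <- R[mi, oi, drop = FALSE] %*% Roo_i
          Cm <- R[mi, mi, drop = FALSE] - A %*% R[oi, mi, drop = FALSE]
          cC <- chol((Cm + t(Cm)) / 2)
          dev <- Ycur[rws, oi, drop = FALSE] - fitted[rws, oi, drop = FALSE]
          mu_m <- fitted[rws, mi, drop = FALSE] + dev %*% t(A)
          z <- matrix(stats::rnorm(length(rws) * length(mi)),
                      ncol = length(mi)) %*% cC
          Ycur[rws, mi] <- mu_m + z / sqw[rws]
        }
      }
    }

    ## 2. environment fixed effects (flat prior)
    cR <- chol(R)
    for (i in seq_len(I)) {
      rws <- env_rows[[i]]
      res <- Ycur[rws, , drop = FALSE] - g[, , drop = FALSE] - ge[rws, , drop = FALSE]
      wi <- w[rws]; sw <- sum(wi)
      mu_b <- colSums(res * wi) / sw
      b[i, ] <- mu_b + drop(stats::rnorm(nT) %*% cR) / sqrt(sw)
    }

    ## 3. line main effects in the G eigenbasis
    Rinv <- chol2inv(cR)
    LR <- t(cR)                      # R = LR LR'
    tt <- trait_transform(LR, Sigma_T)
    E <- Ycur - b[env_idx, , drop = FALSE] - ge
    ZtWE <- rowsum(E * w, line_idx)
    B <- ZtWE %*% Rinv %*% tt$T
    if (uniform_w) {
      Bt <- crossprod(U, B)
      H <- matrix(0, J, nT)
      for (t in seq_len(nT)) {
        prec <- I + tt$lambda[t] / dG
        H[, t] <- Bt[, t] / prec + stats::rnorm(J) / sqrt(prec)
      }
      g <- U %*% H %*% t(tt$T)
    } else {
      H <- matrix(0, J, nT)
      for (t in seq_len(nT)) {
        P <- diag(a_line, J) + tt$lambda[t] * Ginv
        cP <- chol((P + t(P)) / 2)
        mu_h <- backsolve(cP, backsolve(cP, B[, t], transpose = TRUE))
        H[, t] <- mu_h + backsolve(cP, stats::rnorm(J))
      }
      g <- H %*% t(tt$T)
    }

    ## 4. interaction effects, one independent block per environment
    if (include_ge) {
      tt2 <- trait_transform(LR, Sigma_T2)
      for (i in seq_len(I)) {
        rws <- env_rows[[i]]
        Ei <- Ycur[rws, , drop = FALSE] -
          matrix(b[i, ], J, nT, byrow = TRUE) - g
        wi <- w[rws]
        B2 <- (Ei * wi) %*% Rinv %*% tt2$T
        if (uniform_w) {
          Bt <- crossprod(U, B2)
          H <- matrix(0, J, nT)
          for (t in seq_len(nT)) {
            prec <- 1 + tt2$lambda[t] / dG
            H[, t] <- Bt[, t] / prec + stats::rnorm(J) / sqrt(prec)
          }
          ge[rws, ] <- U %*% H %*% t(tt2$T)
        } else {
          H <- matrix(0, J, nT)
          for (t in seq_len(nT)) {
            P <- diag(wi, J) + tt2$lambda[t] * Ginv
            cP <- chol((P + t(P)) / 2)
            mu_h <- backsolve(cP, backsolve(cP, B2[, t], transpose = TRUE))
            H[, t] <- mu_h + backsolve(cP, stats::rnorm(J))
          }
          ge[rws, ] <- H %*% t(tt2$T)
        }
      }
    }

    ## 5. covariance updates (inverse-Wishart full conditionals)
    if (is.null(fix$Sigma_T)) {
      gt <- crossprod(U, g)
      Sg <- crossprod(gt, gt / dG)
      Sigma_T <- riwish(nu0 + J, S_T + Sg)
    }
    if (include_ge && is.null(fix$Sigma_T2)) {
      Sge <- matrix(0, nT, nT)
      for (i in seq_len(I)) {
        get <- crossprod(U, ge[env_rows[[i]], , drop = FALSE])
        Sge <- Sge + crossprod(get, get / dG)
      }
      Sigma_T2 <- riwish(nu0 + I * J, S_T2 + Sge)
    }
    if (is.null(fix$R)) {
      resid <- Ycur - (b[env_idx, , drop = FALSE] + g[line_idx, , drop = FALSE] + ge)
      Sr <- crossprod(resid * sqw)
      R <- riwish(nu0 + n, S_R + Sr)
    }

    ## 6. record
    if (it > burnin && (it - burnin) %% thin == 0L) {
      kept <- kept + 1L
      yhat <- b[env_idx, , drop = FALSE] + g[line_idx, , drop = FALSE] + ge
      sum_b <- sum_b + b; sum_b2 <- sum_b2 + b^2
      sum_g <- sum_g + g; sum_g2 <- sum_g2 + g^2
      sum_ge <- sum_ge + ge; sum_ge2 <- sum_ge2 + ge^2
      sum_yhat <- sum_yhat + yhat; sum_yhat2 <- sum_yhat2 + yhat^2
      draws_ST[kept, , ] <- Sigma_T
      draws_ST2[kept, , ] <- Sigma_T2
      draws_R[kept, , ] <- R
      draws_g[kept, , ] <- g
    }
    if (verbose && it %% 1000L == 0L)
      message(sprintf("iteration %d / %d", it, niter))
    if (anyNA(g) || anyNA(b))
      stop(sprintf("NaN in chain at iteration %d", it), call. = FALSE)
  }

  post_sd <- function(s, s2) sqrt(pmax(s2 / kept - (s / kept)^2, 0))
  list(
    nkeep = kept,
    b_mean = sum_b / kept, b_sd = post_sd(sum_b, sum_b2),
    g_mean = sum_g / kept, g_sd = post_sd(sum_g, sum_g2),
    ge_mean = sum_ge / kept, ge_sd = post_sd(sum_ge, sum_ge2),
    yhat = sum_yhat / kept, yhat_sd = post_sd(sum_yhat, sum_yhat2),
    Sigma_T = apply(draws_ST, c(2, 3), mean),
    Sigma_T2 = apply(draws_ST2, c(2, 3), mean),
    R = apply(draws_R, c(2, 3), mean),
    draws = list(Sigma_T = draws_ST, Sigma_T2 = draws_ST2, R = draws_R,
                 g = draws_g)
  )
}

as_mat <- function(x, nT) {
  m <- as.matrix(x)
  stopifnot(nrow(m) == nT, ncol(m) == nT)
  m
}

# basis T with T' R^{-1} T = I and T' Sigma^{-1} T = diag(lambda):
# take R = L L', eigendecompose L' Sigma^{-1} L = V diag(lambda) V', T = L V.
trait_transform <- function(LR, Sigma) {
  Sinv <- chol2inv(chol(Sigma))
  M <- crossprod(LR, Sinv %*% LR)
  eM <- eigen((M + t(M)) / 2, symmetric = TRUE)
  list(T = LR %*% eM$vectors, lambda = pmax(eM$values, 1e-12))
}

# inverse-Wishart draw via the Wishart on the inverted scale
riwish <- function(df, S) {
  S <- (S + t(S)) / 2
  W <- stats::rWishart(1L, df, chol2inv(chol(S)))[, , 1L]
  out <- chol2inv(chol(W))
  (out + t(out)) / 2
}

# batch-means Monte Carlo standard error of a scalar chain
mcse_batch <- function(x) {
  m <- length(x)
  nb <- max(2L, floor(sqrt(m)))
  bs <- floor(m / nb)
  if (bs < 2L) return(stats::sd(x) / sqrt(m))
  bm <- colMeans(matrix(x[seq_len(nb * bs)], nrow = bs))
  stats::sd(bm) / sqrt(nb)
}
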