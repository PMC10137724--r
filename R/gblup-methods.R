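#' @export
print.sparse_gblup <- function(x, ...) {
  cat("Multi-environment Bayesian GBLUP fit\n")
  cat(sprintf("  %d lines x %d environments x %d trait%s (%d cells, %d observed)\n",
              length(x$line_ids), length(x$env_ids), length(x$traits),
              if (length(x$traits) > 1) "s" else "",
              length(x$observed), sum(x$observed)))
  cat(sprintf("  G-by-E interaction: %s\n",
              if (x$include_ge) "included" else "excluded"))
  cat(sprintf("  MCMC: %d iterations, %d burn-in, thin %d (%d kept), seed %d\n",
              x$control$niter, x$control$burnin, x$control$thin,
              x$nkeep, x$control$seed))
  cat("  posterior mean trait variances:\n")
  vt <- rbind(genomic = diag(as.matrix(x$Sigma_T)),
              gxe = diag(as.matrix(x$Sigma_T2)),
              residual = diag(as.matrix(x$R)))
  colnames(vt) <- x$traits
  print(round(vt, 4))
  invisible(x)
}

#' Posterior summary of a sparse_gblup fit
#'
#' Reports posterior means of the trait covariance matrices, the implied
#' variance partition per trait (genomic, G-by-E, residual, as proportions),
#' batch-means Monte Carlo standard errors of the variance components, and
#' the fixed environment effects.
#'
#' @param object a \code{sparse_gblup} fit.
#' @param ... unused.
#' @return a list of class \code{summary.sparse_gblup}.
#' @export
summary.sparse_gblup <- function(object, ...) {
  nT <- length(object$traits)
  vg <- diag(as.matrix(object$Sigma_T))
  vge <- if (object$include_ge) diag(as.matrix(object$Sigma_T2)) else rep(0, nT)
  vr <- diag(as.matrix(object$R))
  tot <- vg + vge + vr
  part <- rbind(genomic = vg / tot, gxe = vge / tot, residual = vr / tot)
  colnames(part) <- object$traits
  mcse <- sapply(seq_len(nT), function(t) c(
    genomic = mcse_batch(object$draws$Sigma_T[, t, t]),
    gxe = mcse_batch(object$draws$Sigma_T2[, t, t]),
    residual = mcse_batch(object$draws$R[, t, t])))
  colnames(mcse) <- object$traits
  cor_T <- if (nT > 1) stats::cov2cor(object$Sigma_T) else matrix(1, 1, 1)
  out <- list(traits = object$traits,
              Sigma_T = object$Sigma_T, Sigma_T2 = object$Sigma_T2,
              R = object$R, trait_correlation = cor_T,
              variance_partition = part, mcse = mcse,
              mu = colMeans(object$b_mean),
              beta_env = sweep(object$b_mean, 2L, colMeans(object$b_mean)),
              env_ids = object$env_ids, nkeep = object$nkeep)
  class(out) <- "summary.sparse_gblup"
  out
}

#' @export
print.summary.sparse_gblup <- function(x, ...) {
  cat("Variance partition (posterior means, proportions of total):\n")
  print(round(x$variance_partition, 3))
  cat("\nMC standard errors of variance components:\n")
  print(signif(x$mcse, 3))
  if (length(x$traits) > 1) {
    cat("\nPosterior mean genetic trait correlation:\n")
    print(round(x$trait_correlation, 3))
  }
  cat("\nEnvironment effects (deviations from the overall intercept):\n")
  be <- x$beta_env; rownames(be) <- x$env_ids; colnames(be) <- x$traits
  print(round(be, 3))
  invisible(x)
}

#' Posterior mean line effects
#'
#' @param object a \code{sparse_gblup} fit.
#' @param ... unused.
#' @return J x nT matrix of posterior mean genomic line effects (the GBLUPs),
#'   with line ids as row names.
#' @export
coef.sparse_gblup <- function(object, ...) {
  g <- object$g_mean
  dimnames(g) <- list(object$line_ids, object$traits)
  g
}

grid_row <- function(object, line_id, env_id) {
  li <- match(as.character(line_id), object$line_ids)
  ei <- match(as.character(env_id), object$env_ids)
  if (anyNA(li)) stop("unknown line id(s)", call. = FALSE)
  if (anyNA(ei)) stop("unknown environment id(s)", call. = FALSE)
  (ei - 1L) * length(object$line_ids) + li
}

#' Predict line-by-environment cells from a fitted model
#'
#' Returns the posterior mean of the systematic part
#' \eqn{\hat\mu + \hat\beta_E + \hat g + \hat g_E} at the requested cells —
#' the model's prediction for both observed (fitted values) and unobserved
#' (sparse-testing) cells.
#'
#' @param object a \code{sparse_gblup} fit.
#' @param newdata data.frame with columns \code{line_id} and \code{env_id}
#'   (and optionally \code{trait} to select a single trait per row);
#'   \code{NULL} predicts the full grid.
#' @param ... unused.
#' @return with \code{newdata = NULL}, the full n x nT matrix of predictions;
#'   with a \code{trait} column, a vector (one value per row of
#'   \code{newdata}); otherwise a matrix with one row per requested cell.
#' @export
predict.sparse_gblup <- function(object, newdata = NULL, ...) {
  yhat <- object$yhat
  colnames(yhat) <- object$traits
  if (is.null(newdata)) {
    rownames(yhat) <- paste(object$env_ids[rep(seq_along(object$env_ids),
                                               each = length(object$line_ids))],
                            object$line_ids, sep = ":")
    return(yhat)
  }
  rows <- grid_row(object, newdata$line_id, newdata$env_id)
  if (!is.null(newdata$trait)) {
    ti <- match(as.character(newdata$trait), object$traits)
    if (anyNA(ti)) stop("unknown trait(s)", call. = FALSE)
    return(yhat[cbind(rows, ti)])
  }
  out <- yhat[rows, , drop = FALSE]
  rownames(out) <- paste(newdata$env_id, newdata$line_id, sep = ":")
  out
}

#' @export
fitted.sparse_gblup <- function(object, ...) predict(object)

#' Residuals at observed cells
#'
#' @param object a \code{sparse_gblup} fit.
#' @param ... unused.
#' @return n x nT matrix of observed minus predicted values, \code{NA} at
#'   unobserved cells.
#' @export
residuals.sparse_gblup <- function(object, ...) {
  r <- object$y - object$yhat
  colnames(r) <- object$traits
  r
}

#' Draw from the plug-in posterior predictive distribution
#'
#' Adds residual noise with covariance at the posterior mean of R to the
#' posterior mean predictions — a quick generator of plausible phenotype
#' realizations from a fitted model.
#'
#' @param object a \code{sparse_gblup} fit.
#' @param nsim number of replicate data sets.
#' @param seed integer seed or NULL.
#' @param ... unused.
#' @return a list of \code{nsim} matrices shaped like the response grid.
#' @export
simulate.sparse_gblup <- function(object, nsim = 1, seed = NULL, ...) {
  n <- nrow(object$yhat); nT <- ncol(object$yhat)
  cR <- chol(as.matrix(object$R))
  with_seed(seed, lapply(seq_len(nsim), function(s) {
    e <- matrix(stats::rnorm(n * nT), n, nT) %*% cR
    if (!is.null(object$weights_used)) e <- e / sqrt(object$weights_used)
    object$yhat + e
  }))
}

#' Observed-versus-predicted plot for a fit
#'
#' Scatter of observed values against posterior mean predictions at the
#' observed cells, one panel per trait, with the identity line.
#'
#' @param x a \code{sparse_gblup} fit.
#' @param ... passed to \code{plot}.
#' @export
plot.sparse_gblup <- function(x, ...) {
  nT <- length(x$traits)
  op <- par(mfrow = c(1, nT)); on.exit(par(op))
  for (t in seq_len(nT)) {
    ok <- x$observed[, t]
    plot(x$yhat[ok, t], x$y[ok, t],
         xlab = "predicted", ylab = "observed", main = x$traits[t], ...)
    abline(0, 1, lty = 2)
  }
  invisible(x)
}
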