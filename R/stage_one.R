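#' First-stage analysis: per-environment BLUEs from incomplete-block data
#'
#' Fits, separately within each environment, the incomplete-block model
#' \deqn{y_{irk} = \mu + R_r + B_{k[r]} + G_i + e_{irk}}
#' with replicate and genotype fixed and the incomplete block within
#' replicate random. Variance components are estimated by REML
#' (\code{lme4::lmer}); genotype BLUEs (adjusted means at the average
#' replicate) and their standard errors are then computed by generalized
#' least squares at those estimates. Non-positive block variance estimates
#' are clamped to \code{1e-8} with a warning.
#'
#' This is the first stage of the two-stage sparse-testing workflow: its
#' weighted BLUEs (weight = 1/SE^2) are the response for
#' \code{\link{sparse_gblup}}. Data already summarized to BLUEs elsewhere
#' (e.g. spatially adjusted trials) can bypass this stage and enter the
#' model directly as a phenotype table.
#'
#' @param plots data.frame with columns \code{line_id}, \code{env_id},
#'   \code{rep}, \code{block} and one column per trait.
#' @param trait name of the trait column to analyse.
#' @param fix_vc optional \code{c(block = , resid = )} variance components to
#'   use instead of REML estimates (e.g. \code{block = 0} for the pure
#'   fixed-effects analysis).
#' @return data.frame (one row per line x environment) with columns
#'   \code{line_id}, \code{env_id}, \code{trait}, \code{value} (the BLUE),
#'   \code{se} and \code{weight}.
#' @export
fit_stage_one <- function(plots, trait, fix_vc = NULL) {
  need <- c("line_id", "env_id", "rep", "block", trait)
  miss <- setdiff(need, names(plots))
  if (length(miss))
    stop("plot data lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(plots[, c("line_id", "env_id", "rep", "block")]))
    stop("duplicate (line, env, rep, block) plot records", call. = FALSE)
  out <- lapply(split(plots, plots$env_id), function(pe)
    fit_stage_one_env(pe, trait, fix_vc))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

fit_stage_one_env <- function(pe, trait, fix_vc = NULL) {
  env <- pe$env_id[1]
  y <- pe[[trait]]
  line <- factor(pe$line_id)
  rep_ <- factor(pe$rep)
  blk <- interaction(rep_, factor(pe$block), drop = TRUE)
  has_rep <- nlevels(rep_) > 1L
  X <- if (has_rep) stats::model.matrix(~ 0 + line + rep_)
       else stats::model.matrix(~ 0 + line)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("confounded fixed effects in environment %s: %s",
                 env, paste(aliased, collapse = ", ")), call. = FALSE)
  }
  vc <- if (is.null(fix_vc)) estimate_block_vc(y, line, rep_, blk)
        else c(block = unname(fix_vc["block"]), resid = unname(fix_vc["resid"]))
  s2b <- vc["block"]; s2e <- vc["resid"]
  if (s2b <= 0) {
    warning(sprintf("block variance estimated non-positive in %s; clamped to 1e-8", env))
    s2b <- 1e-8
  }
  if (s2e <= 0) {
    warning(sprintf("residual variance estimated non-positive in %s; clamped to 1e-8", env))
    s2e <- 1e-8
  }
  Zb <- stats::model.matrix(~ 0 + blk)
  V <- s2b * tcrossprod(Zb) + diag(s2e, length(y))
  Vi <- chol2inv(chol(V))
  XtVi <- crossprod(X, Vi)
  C <- solve(XtVi %*% X)
  beta <- drop(C %*% (XtVi %*% y))
  # adjusted mean: genotype effect plus the average replicate effect
  nl <- nlevels(line); nr <- nlevels(rep_)
  L <- if (has_rep) cbind(diag(nl), matrix(1 / nr, nl, nr - 1))  # rep 1 at 0
       else diag(nl)
  blue <- drop(L %*% beta)
  se <- sqrt(rowSums((L %*% C) * L))
  data.frame(line_id = levels(line), env_id = env, trait = trait,
             value = blue, se = se, weight = 1 / se^2,
             stringsAsFactors = FALSE)
}

# REML variance components for the block-within-replicate model; falls back
# to a near-zero block variance when the random term is degenerate (single
# block, or lmer cannot fit).
estimate_block_vc <- function(y, line, rep_, blk) {
  if (nlevels(blk) < 2L)
    return(c(block = 1e-8, resid = max(stats::var(y), 1e-8)))
  df <- data.frame(y = y, line = line, rep_ = rep_, blk = blk)
  form <- if (nlevels(rep_) > 1L) y ~ 0 + line + rep_ + (1 | blk)
          else y ~ 0 + line + (1 | blk)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(form, data = df,
                 control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                             check.nobs.vs.nRE = "ignore",
                                             calc.derivs = FALSE)))),
    error = function(e) NULL)
  if (is.null(fit)) {
    fixed <- if (nlevels(rep_) > 1L) y ~ 0 + line + rep_ else y ~ 0 + line
    r <- stats::resid(stats::lm(fixed, data = df))
    return(c(block = 1e-8, resid = max(mean(r^2), 1e-8)))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  c(block = vc$vcov[vc$grp == "blk"],
    resid = vc$vcov[vc$grp == "Residual"])
}

#' Merge per-environment BLUE tables into one phenotype table
#'
#' Binds per-environment stage-one outputs (or externally computed BLUE
#' tables) into the single tidy phenotype table used by
#' \code{\link{sparse_gblup}}; lines absent from an environment are simply
#' absent rows (treated as unobserved downstream). Conflicting duplicate
#' (line, environment, trait) records are an error.
#'
#' @param per_env a list of BLUE tables, or a single already-bound table.
#' @return data.frame with columns \code{line_id}, \code{env_id},
#'   \code{trait}, \code{value} and, when present, \code{se}/\code{weight}.
#' @export
merge_blues <- function(per_env) {
  tab <- if (is.data.frame(per_env)) per_env else do.call(rbind, per_env)
  need <- c("line_id", "env_id", "trait", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("BLUE table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  key <- tab[, c("line_id", "env_id", "trait")]
  if (anyDuplicated(key))
    stop("duplicate (line, env, trait) records in BLUE tables", call. = FALSE)
  rownames(tab) <- NULL
  tab
}

#' Validate a tidy phenotype table
#'
#' @param pheno data.frame with \code{line_id}, \code{env_id}, \code{trait},
#'   \code{value} and optional \code{weight} columns.
#' @return \code{pheno}, invisibly.
#' @export
validate_pheno <- function(pheno) {
  need <- c("line_id", "env_id", "trait", "value")
  miss <- setdiff(need, names(pheno))
  if (length(miss))
    stop("phenotype table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(pheno[, c("line_id", "env_id", "trait")]))
    stop("duplicate (line, env, trait) phenotype records", call. = FALSE)
  if (!is.numeric(pheno$value))
    stop("'value' must be numeric", call. = FALSE)
  invisible(pheno)
}
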