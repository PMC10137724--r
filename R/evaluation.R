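#' Prediction-accuracy metrics
#'
#' \code{pearson} is the sample Pearson correlation between observed and
#' predicted values; \code{nrmse} is the root mean squared error normalized
#' by the absolute mean of the observed values (or by their range with
#' \code{normalize = "range"}, for responses centered near zero).
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return a single number; \code{pearson} returns \code{NA} with a warning
#'   when either input is constant.
#' @export
pearson <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  if (length(observed) < 3)
    stop("need at least 3 pairs for a correlation", call. = FALSE)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    warning("constant input: Pearson correlation undefined, returning NA")
    return(NA_real_)
  }
  stats::cor(observed, predicted)
}

#' @rdname pearson
#' @param normalize \code{"mean"} (default) divides the RMSE by
#'   \code{|mean(observed)|}; \code{"range"} by
#'   \code{max(observed) - min(observed)}.
#' @export
nrmse <- function(observed, predicted, normalize = c("mean", "range")) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 1)
  normalize <- match.arg(normalize)
  rmse <- sqrt(mean((observed - predicted)^2))
  if (normalize == "mean") {
    m <- mean(observed)
    if (m == 0)
      stop("mean of observed values is zero; use normalize = \"range\"",
           call. = FALSE)
    rmse / abs(m)
  } else {
    rg <- diff(range(observed))
    if (rg == 0) stop("observed values are constant", call. = FALSE)
    rmse / rg
  }
}

#' Sparse-testing cross-validation
#'
#' For each allocation method, testing fraction and partition: draw a fresh
#' allocation with a partition-specific seed, mask the testing cells, fit
#' the genomic model on the training cells only, predict the masked cells,
#' and score per trait — Pearson correlation and NRMSE pooled across
#' environments. Partition seeds are derived from the single master
#' \code{seed}, so the whole study is reproducible from one integer. A fit
#' failure in one partition is recorded as missing and the run continues.
#'
#' M1/M2 are parameterized directly by the training fraction
#' \code{1 - test_fraction}; M3/M4 use \code{r = round((1 - f) * I)}
#' replications clamped to \code{[1, I - 1]}, so their attainable fractions
#' are multiples of 1/I.
#'
#' @param pheno tidy phenotype table (see \code{\link{sparse_gblup}}).
#' @param G genomic relationship matrix.
#' @param methods subset of \code{c("M1","M2","M3","M4")}.
#' @param test_fractions testing-set fractions, e.g.
#'   \code{c(0.15, 0.25, 0.5, 0.75, 0.85)}.
#' @param n_partitions random partitions per setting (default 10).
#' @param framework \code{"multi"} fits all traits jointly; \code{"uni"}
#'   fits each trait separately.
#' @param seed master seed.
#' @param include_ge,niter,burnin,thin,weights passed to
#'   \code{\link{sparse_gblup}}.
#' @param n_restarts restarts of the M4 exchange search.
#' @param verbose print per-partition progress.
#' @return a \code{metrics_table} data.frame with one row per method x
#'   fraction x trait x partition (\code{stat = "partition"}) plus
#'   aggregate rows (\code{stat} \code{"mean"}/\code{"sd"} over partitions).
#' @export
run_cv <- function(pheno, G, methods = c("M1", "M2", "M3", "M4"),
                   test_fractions = c(0.15, 0.25, 0.5, 0.75, 0.85),
                   n_partitions = 10L, framework = c("multi", "uni"),
                   seed = 1L, include_ge = TRUE,
                   niter = 10000L, burnin = 2000L, thin = 5L,
                   weights = "auto", n_restarts = 5L, verbose = FALSE) {
  framework <- match.arg(framework)
  validate_pheno(pheno)
  stopifnot(all(test_fractions > 0), all(test_fractions < 1),
            n_partitions >= 1)
  methods <- match.arg(methods, c("M1", "M2", "M3", "M4"), several.ok = TRUE)
  line_ids <- intersect(rownames(G), unique(as.character(pheno$line_id)))
  env_ids <- unique(as.character(pheno$env_id))
  traits <- sort(unique(as.character(pheno$trait)))
  I <- length(env_ids)
  n_settings <- length(methods) * length(test_fractions)
  seeds <- matrix(derive_seeds(seed, n_settings * n_partitions),
                  nrow = n_partitions)
  rows <- list(); si <- 0L
  for (method in methods) for (f_test in test_fractions) {
    si <- si + 1L
    for (part in seq_len(n_partitions)) {
      sp <- seeds[part, si]
      design <- allocate_lines(line_ids, env_ids, method,
                               train_fraction = 1 - f_test, seed = sp,
                               n_restarts = n_restarts)
      met <- tryCatch(
        score_partition(pheno, G, design, traits, framework, include_ge,
                        niter, burnin, thin, weights, sp),
        error = function(e) {
          warning(sprintf("%s f=%.2f partition %d failed: %s",
                          method, f_test, part, conditionMessage(e)))
          data.frame(trait = traits, pearson = NA_real_, nrmse = NA_real_)
        })
      if (verbose)
        message(sprintf("%s test=%.2f partition %d done", method, f_test, part))
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, framework = framework, test_fraction = f_test,
        trait = met$trait, partition = part, stat = "partition",
        pearson = met$pearson, nrmse = met$nrmse,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(
    split(tab, tab[, c("method", "test_fraction", "trait")], drop = TRUE),
    function(d) data.frame(
      method = d$method[1], framework = d$framework[1],
      test_fraction = d$test_fraction[1], trait = d$trait[1],
      partition = NA_integer_, stat = c("mean", "sd"),
      pearson = c(mean(d$pearson, na.rm = TRUE), stats::sd(d$pearson, na.rm = TRUE)),
      nrmse = c(mean(d$nrmse, na.rm = TRUE), stats::sd(d$nrmse, na.rm = TRUE)),
      stringsAsFactors = FALSE)))
  out <- rbind(tab, agg)
  rownames(out) <- NULL
  class(out) <- c("metrics_table", "data.frame")
  out
}

# fit on the training mask, score the masked cells that have observed truth
score_partition <- function(pheno, G, design, traits, framework, include_ge,
                            niter, burnin, thin, weights, sp) {
  fits <- if (framework == "multi") {
    list(sparse_gblup(pheno, G, design = design, traits = traits,
                      weights = weights, include_ge = include_ge,
                      niter = niter, burnin = burnin, thin = thin, seed = sp))
  } else {
    lapply(traits, function(tr)
      sparse_gblup(pheno, G, design = design, traits = tr,
                   weights = weights, include_ge = include_ge,
                   niter = niter, burnin = burnin, thin = thin, seed = sp))
  }
  test <- pheno[design$mask[cbind(match(as.character(pheno$line_id), design$line_ids),
                                  match(as.character(pheno$env_id), design$env_ids))] == 0L, ]
  do.call(rbind, lapply(seq_along(traits), function(k) {
    tr <- traits[k]
    fit <- if (framework == "multi") fits[[1]] else fits[[k]]
    cells <- test[test$trait == tr, ]
    if (nrow(cells) < 3)
      return(data.frame(trait = tr, pearson = NA_real_, nrmse = NA_real_))
    pred <- predict(fit, newdata = cells)
    data.frame(trait = tr,
               pearson = pearson(cells$value, pred),
               nrmse = nrmse(cells$value, pred))
  }))
}

#' Average accuracy over partitions
#'
#' Convenience accessor for the aggregate rows of a
#' \code{\link{run_cv}} result: the average Pearson correlation (APC) and
#' average NRMSE per method x fraction x trait.
#'
#' @param metrics a \code{metrics_table}.
#' @return data.frame of the \code{stat == "mean"} rows.
#' @export
apc <- function(metrics) {
  out <- metrics[metrics$stat == "mean", setdiff(names(metrics), c("partition", "stat"))]
  rownames(out) <- NULL
  out
}
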