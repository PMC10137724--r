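#' Cost-benefit arithmetic of sparse versus fully replicated trials
#'
#' Quantifies what a fixed plot budget buys under sparse testing. The
#' standard design grows every treatment once in each of \code{locations}
#' environments, so \code{plots_total = total_treatments_std * locations}.
#' A sparse design at training fraction f replicates each treatment in only
#' a fraction f of the locations, so the same budget accommodates
#' \code{round(plots_total / (locations * f))} treatments; checks are
#' constant, and everything beyond them is new breeding lines. Reported per
#' training percentage: total treatments, new lines, replications per
#' location (f), total replications (\code{locations * f}), plots per new
#' line, and the percentage gain (or loss) of each quantity against the
#' standard. Percentage gains are computed from the integer treatment
#' counts (and, for plots per line, from the unrounded plot ratios), then
#' rounded to 2 decimals.
#'
#' @param total_treatments_std treatments in the standard design (new lines
#'   plus checks).
#' @param checks number of repeated check genotypes.
#' @param locations number of environments.
#' @param plots_total total plot budget; must equal
#'   \code{total_treatments_std * locations}.
#' @param train_percents training percentages in (0, 100].
#' @return object of class \code{cost_benefit}: the scenario plus a
#'   data.frame with one row per training percentage.
#' @examples
#' evaluate_scenario(250, 25, 4, 1000, c(85, 75, 50, 25, 15))
#' @export
evaluate_scenario <- function(total_treatments_std, checks, locations,
                              plots_total,
                              train_percents = c(85, 75, 50, 25, 15)) {
  stopifnot(checks >= 0, checks < total_treatments_std, locations >= 1)
  if (plots_total != total_treatments_std * locations)
    stop("plots_total must equal total_treatments_std * locations ",
         "(one replicate per location in the standard design)", call. = FALSE)
  if (length(train_percents) &&
      (any(train_percents <= 0) || any(train_percents > 100)))
    stop("train_percents must be in (0, 100]", call. = FALSE)
  new_std <- total_treatments_std - checks
  ppt_std <- plots_total / new_std
  rows <- lapply(train_percents, function(pct) {
    f <- pct / 100
    trts <- round(plots_total / (locations * f))
    new <- trts - checks
    if (new <= 0)
      stop(sprintf("training %g%% leaves no new lines beyond the checks", pct),
           call. = FALSE)
    ppt <- plots_total / new
    data.frame(
      train_percent = pct,
      total_trts = trts,
      new_lines = new,
      checks = checks,
      reps_per_loc = f,
      locations = locations,
      R_total = locations * f,
      plots_total = plots_total,
      plots_per_trt = ppt,
      gain_total_trts = 100 * (trts / total_treatments_std - 1),
      gain_new_lines = 100 * (new / new_std - 1),
      gain_checks = 0,
      gain_reps = 100 * (f - 1),
      gain_locations = 0,
      gain_R = 100 * (f - 1),
      gain_plots_total = 0,
      gain_plots_per_trt = 100 * (new_std / new - 1))
  })
  structure(list(
    scenario = list(total_treatments_std = total_treatments_std,
                    checks = checks, locations = locations,
                    plots_total = plots_total,
                    new_lines_std = new_std,
                    plots_per_trt_std = ppt_std),
    table = if (length(rows)) do.call(rbind, rows)
            else data.frame(train_percent = numeric(0))),
    class = "cost_benefit")
}

#' @export
print.cost_benefit <- function(x, ...) {
  cat(sprintf("Sparse-testing cost-benefit: %d treatments (%d checks), %d locations, %d plots\n",
              x$scenario$total_treatments_std, x$scenario$checks,
              x$scenario$locations, x$scenario$plots_total))
  print(format_table(x))
  invisible(x)
}

#' Lay out a cost-benefit result as the standard comparison table
#'
#' One concept per row (total treatments, new lines, checks, replications
#' per location, locations, total replications, total plots, total
#' treatments again, plots per treatment), one column for the standard
#' design, one per sparse training percentage, and one gain column per
#' percentage. Counts are integers; ratios and percentage gains are rounded
#' to 2 decimals.
#'
#' @param result a \code{cost_benefit} object.
#' @return data.frame in the table layout described above.
#' @export
format_table <- function(result) {
  stopifnot(inherits(result, "cost_benefit"))
  s <- result$scenario; tb <- result$table
  pcts <- tb$train_percent
  concept <- c("Total_trts", "New_lines", "Checks", "Reps", "Locs", "R",
               "Total_plots", "Total_trts", "Plots_per_trt")
  standard <- c(s$total_treatments_std, s$new_lines_std, s$checks, 1,
                s$locations, s$locations, s$plots_total,
                s$total_treatments_std, round(s$plots_per_trt_std, 2))
  if (length(pcts) == 0)
    return(data.frame(concept, standard, stringsAsFactors = FALSE))
  sparse_cols <- sapply(seq_along(pcts), function(j) c(
    tb$total_trts[j], tb$new_lines[j], tb$checks[j], tb$reps_per_loc[j],
    tb$locations[j], tb$R_total[j], tb$plots_total[j], tb$total_trts[j],
    round(tb$plots_per_trt[j], 2)))
  gain_cols <- sapply(seq_along(pcts), function(j) round(c(
    tb$gain_total_trts[j], tb$gain_new_lines[j], tb$gain_checks[j],
    tb$gain_reps[j], tb$gain_locations[j], tb$gain_R[j],
    tb$gain_plots_total[j], tb$gain_total_trts[j],
    tb$gain_plots_per_trt[j]), 2))
  out <- data.frame(concept, standard, sparse_cols, gain_cols,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("concept", "standard", paste0("trn", pcts),
                  paste0("gain", pcts))
  out
}

#' Write / read a formatted cost-benefit table as CSV (lossless round trip)
#'
#' @param table data.frame from \code{\link{format_table}}.
#' @param path CSV path.
#' @export
write_cost_benefit <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cost_benefit
#' @export
read_cost_benefit <- function(path) {
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
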