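#' Lines per location for a sparse allocation
#'
#' For J lines each to be replicated in r of I environments, every
#' environment receives \eqn{k = \lceil J r / I \rceil} lines, so that the
#' total plot count is \eqn{N = J r = I k} (up to the ceiling).
#'
#' @param J number of lines.
#' @param r replications per line (environments in which a line appears).
#' @param I number of environments.
#' @return integer k, the number of lines phenotyped per environment.
#' @examples
#' lines_per_location(8, 2, 4)  # 4
#' @export
lines_per_location <- function(J, r, I) {
  stopifnot(J >= 1, r >= 1, I >= 1)
  if (r > I)
    stop("r > I: a line cannot appear more than once in one environment",
         call. = FALSE)
  as.integer(ceiling(J * r / I))
}

new_allocation_design <- function(mask, line_ids, env_ids, method,
                                  train_fraction, seed, r = NA_integer_) {
  mask <- matrix(as.integer(mask), nrow = length(line_ids),
                 dimnames = list(line_ids, env_ids))
  structure(list(mask = mask, line_ids = line_ids, env_ids = env_ids,
                 method = method, train_fraction = train_fraction,
                 r = r, seed = seed),
            class = "allocation_design")
}

#' @export
print.allocation_design <- function(x, ...) {
  J <- length(x$line_ids); I <- length(x$env_ids)
  cat(sprintf("Sparse-testing allocation (%s): %d lines x %d environments\n",
              x$method, J, I))
  cat(sprintf("  training plots: %d of %d (fraction %.3f)\n",
              sum(x$mask), J * I, training_fraction(x)))
  cat(sprintf("  column sums (lines/environment): %s\n",
              paste(colSums(x$mask), collapse = " ")))
  rs <- table(rowSums(x$mask))
  cat(sprintf("  row sums (environments/line): %s\n",
              paste(sprintf("%sx%s", rs, names(rs)), collapse = " ")))
  invisible(x)
}

check_alloc_args <- function(line_ids, env_ids) {
  stopifnot(length(line_ids) >= 2, length(env_ids) >= 1,
            !anyDuplicated(line_ids), !anyDuplicated(env_ids))
}

#' Allocation method M1: a fraction of lines in all environments
#'
#' A random subset of \code{round(train_fraction * J)} lines is phenotyped in
#' every environment; the remaining lines are never phenotyped and form the
#' testing set everywhere.
#'
#' @param line_ids character vector of J line identifiers.
#' @param env_ids character vector of I environment identifiers.
#' @param train_fraction fraction of lines used as training, in (0, 1].
#' @param seed integer seed; identical inputs and seed give identical designs.
#' @return an \code{allocation_design}.
#' @export
allocate_m1 <- function(line_ids, env_ids, train_fraction, seed = 1L) {
  check_alloc_args(line_ids, env_ids)
  J <- length(line_ids); I <- length(env_ids)
  if (train_fraction <= 0 || train_fraction > 1)
    stop("train_fraction must be in (0, 1]", call. = FALSE)
  n_train <- round(train_fraction * J)
  if (n_train < 1) stop("train_fraction selects zero training lines", call. = FALSE)
  idx <- with_seed(seed, sample.int(J, n_train))
  mask <- matrix(0L, J, I)
  mask[idx, ] <- 1L
  new_allocation_design(mask, line_ids, env_ids, "M1", train_fraction, seed)
}

#' Allocation method M2: shared core plus rotated testing slices
#'
#' As M1, a base subset of lines is phenotyped in all environments. The
#' remaining (testing) lines are split into I near-equal parts, and part i is
#' additionally phenotyped in environment i only. Every line is therefore
#' phenotyped somewhere, but each environment withholds the other I - 1
#' parts, which form its testing set.
#'
#' @inheritParams allocate_m1
#' @export
allocate_m2 <- function(line_ids, env_ids, train_fraction, seed = 1L) {
  check_alloc_args(line_ids, env_ids)
  J <- length(line_ids); I <- length(env_ids)
  if (I < 2) stop("M2 needs at least 2 environments", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1) for M2", call. = FALSE)
  n_base <- round(train_fraction * J)
  if (n_base < 1) stop("train_fraction selects zero base training lines", call. = FALSE)
  n_test <- J - n_base
  if (n_test < I)
    stop("testing set smaller than the number of environments: cannot split",
         call. = FALSE)
  mask <- matrix(0L, J, I)
  with_seed(seed, {
    base <- sample.int(J, n_base)
    test <- sample(setdiff(seq_len(J), base))
    mask[base, ] <- 1L
    # near-equal parts; remainder goes round-robin to the first environments
    part <- rep(seq_len(I), length.out = n_test)
    part <- sort(part)
    for (i in seq_len(I)) mask[test[part == i], i] <- 1L
  })
  new_allocation_design(mask, line_ids, env_ids, "M2", train_fraction, seed)
}

#' Allocation method M3: stratified random incomplete allocation
#'
#' Environments are filled sequentially with \eqn{k = \lceil J r / I \rceil}
#' lines each, drawn uniformly among lines currently appearing in fewer than
#' r environments; when fewer than k lines remain eligible, the shortfall is
#' filled from the lines with the smallest current counts. Column sums are
#' exactly k; row sums are r up to a deviation of 1.
#'
#' @inheritParams allocate_m1
#' @param r target replications per line, \code{1 <= r < I}.
#' @export
allocate_m3 <- function(line_ids, env_ids, r, seed = 1L) {
  check_alloc_args(line_ids, env_ids)
  J <- length(line_ids); I <- length(env_ids)
  if (r < 1 || r >= I) stop("need 1 <= r < I", call. = FALSE)
  k <- lines_per_location(J, r, I)
  mask <- matrix(0L, J, I)
  with_seed(seed, {
    count <- integer(J)
    for (i in seq_len(I)) {
      elig <- which(count < r)
      if (length(elig) >= k) {
        pick <- sample_int_from(elig, k)
      } else {
        rest <- setdiff(seq_len(J), elig)
        # fill from minimal-count lines, uniform among ties
        ord <- rest[order(count[rest], runif(length(rest)))]
        pick <- c(elig, ord[seq_len(k - length(elig))])
      }
      mask[pick, i] <- 1L
      count[pick] <- count[pick] + 1L
    }
  })
  new_allocation_design(mask, line_ids, env_ids, "M3",
                        k * I / (J * I), seed, r = as.integer(r))
}

# sample() with the length-1 surprise removed
sample_int_from <- function(x, size) {
  if (length(x) == 1L) return(x)
  sample(x, size)
}

#' Allocation method M4: concurrence-balanced incomplete allocation
#'
#' Builds a design with k lines per environment whose pairwise concurrence
#' counts (number of environments in which two lines are phenotyped
#' together) are as equal as possible — the balanced incomplete block
#' principle. Starting from an M3 draw, a steepest-descent exchange
#' heuristic swaps a line out of and a line into an environment whenever the
#' swap strictly reduces the variance of the off-diagonal concurrence counts
#' while never widening the spread of per-line replication; the best of
#' \code{n_restarts} random starts is returned. When an exact balanced
#' incomplete block design exists and is found, the balance score is 0.
#'
#' @inheritParams allocate_m3
#' @param n_restarts number of random restarts of the exchange search.
#' @export
allocate_m4 <- function(line_ids, env_ids, r, seed = 1L, n_restarts = 10L) {
  check_alloc_args(line_ids, env_ids)
  J <- length(line_ids); I <- length(env_ids)
  if (r < 1 || r >= I) stop("need 1 <= r < I", call. = FALSE)
  k <- lines_per_location(J, r, I)
  if (k > J) stop("k > J: no design exists", call. = FALSE)
  seeds <- derive_seeds(seed, n_restarts)
  best <- NULL; best_score <- Inf; best_trace <- NULL
  for (s in seeds) {
    start <- allocate_m3(line_ids, env_ids, r, seed = s)
    res <- exchange_balance(start$mask)
    if (res$score < best_score - 1e-12) {
      best_score <- res$score
      best <- res$mask
      best_trace <- res$trace
    }
    if (best_score == 0) break
  }
  d <- new_allocation_design(best, line_ids, env_ids, "M4",
                             k * I / (J * I), seed, r = as.integer(r))
  d$balance_score <- best_score
  d$score_trace <- best_trace
  d
}

# Steepest-descent exchange: per environment, find the (out, in) swap with
# the largest strict decrease in off-diagonal concurrence variance, subject
# to count(out) >= count(in) so the replication spread never grows. A swap
# leaves the off-diagonal sum unchanged (|S| pairs drop by 1, |S| pairs rise
# by 1), so minimizing the sum of squares minimizes the variance; the
# sum-of-squares change of swapping a out / b in is computed in closed form
# from the row sums of the concurrence matrix over the environment's members.
# Monotone by construction; the score after each accepted swap is recorded.
exchange_balance <- function(mask) {
  J <- nrow(mask); I <- ncol(mask)
  np <- J * (J - 1) / 2
  lam <- tcrossprod(mask)
  count <- rowSums(mask)
  off_score <- function(L) {
    off <- L[upper.tri(L)]
    mean(off^2) - mean(off)^2
  }
  trace <- off_score(lam)
  repeat {
    improved <- FALSE
    for (e in seq_len(I)) {
      ins <- which(mask[, e] == 1L)
      outs <- which(mask[, e] == 0L)
      if (!length(outs) || length(ins) < 1L) next
      ke <- length(ins)
      rs_in <- rowSums(lam[, ins, drop = FALSE])
      # d2[a, b] = change in sum of squared off-diagonal concurrences
      base_a <- -2 * (rs_in[ins] - diag(lam)[ins]) + (ke - 1)
      base_b <- 2 * rs_in[outs] + (ke - 1)
      D <- outer(base_a, base_b, "+") - 2 * t(lam[outs, ins, drop = FALSE])
      D[outer(count[ins], count[outs], "<")] <- Inf
      m <- which.min(D)
      if (is.finite(D[m]) && D[m] < -1e-9) {
        ai <- (m - 1L) %% ke + 1L
        bi <- (m - 1L) %/% ke + 1L
        a <- ins[ai]; b <- outs[bi]
        S <- setdiff(ins, a)
        lam[a, S] <- lam[a, S] - 1L; lam[S, a] <- lam[a, S]
        lam[b, S] <- lam[b, S] + 1L; lam[S, b] <- lam[b, S]
        lam[a, a] <- lam[a, a] - 1L; lam[b, b] <- lam[b, b] + 1L
        mask[a, e] <- 0L; mask[b, e] <- 1L
        count[a] <- count[a] - 1L; count[b] <- count[b] + 1L
        trace <- c(trace, off_score(lam))
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(mask = mask, score = off_score(lam), trace = trace)
}

#' Build a sparse-testing allocation by method name
#'
#' Dispatcher over \code{\link{allocate_m1}}–\code{\link{allocate_m4}}.
#' M1/M2 are parameterized by a training fraction of lines; M3/M4 by the
#' replication count r. When a fraction is given for M3/M4 it is mapped to
#' \code{r = round(train_fraction * I)} clamped to \code{[1, I - 1]}.
#'
#' @param line_ids,env_ids identifiers.
#' @param method one of "M1", "M2", "M3", "M4".
#' @param train_fraction training fraction (M1/M2, or mapped to r for M3/M4).
#' @param r replications per line (M3/M4; overrides the fraction mapping).
#' @param seed integer seed.
#' @param n_restarts restarts for the M4 exchange search.
#' @return an \code{allocation_design}.
#' @export
allocate_lines <- function(line_ids, env_ids, method,
                           train_fraction = NULL, r = NULL, seed = 1L,
                           n_restarts = 10L) {
  method <- match.arg(method, c("M1", "M2", "M3", "M4"))
  I <- length(env_ids)
  if (method %in% c("M3", "M4") && is.null(r)) {
    if (is.null(train_fraction))
      stop("give either 'r' or 'train_fraction' for M3/M4", call. = FALSE)
    r <- min(max(1L, round(train_fraction * I)), I - 1L)
  }
  switch(method,
         M1 = allocate_m1(line_ids, env_ids, train_fraction, seed),
         M2 = allocate_m2(line_ids, env_ids, train_fraction, seed),
         M3 = allocate_m3(line_ids, env_ids, r, seed),
         M4 = allocate_m4(line_ids, env_ids, r, seed, n_restarts))
}

#' Concurrence diagnostics of an allocation
#'
#' The concurrence matrix \eqn{\Lambda = M M'} counts, for each pair of
#' lines, the environments in which both are phenotyped; its diagonal is the
#' per-line replication. The balance score is the population variance of the
#' off-diagonal counts — zero exactly when every pair co-occurs equally
#' often, the balanced incomplete block ideal.
#'
#' @param design an \code{allocation_design}.
#' @return list with \code{lambda_matrix} (J x J integer),
#'   \code{replications} (length J) and \code{balance_score}.
#' @export
concurrence <- function(design) {
  stopifnot(inherits(design, "allocation_design"))
  lam <- tcrossprod(design$mask)
  storage.mode(lam) <- "integer"
  off <- lam[upper.tri(lam)]
  list(lambda_matrix = lam,
       replications = diag(lam),
       balance_score = mean(off^2) - mean(off)^2)
}

#' Realized training fraction of an allocation
#'
#' @param design an \code{allocation_design}.
#' @return \code{sum(mask) / (J * I)}.
#' @export
training_fraction <- function(design) {
  stopifnot(inherits(design, "allocation_design"))
  sum(design$mask) / length(design$mask)
}

#' Write / read an allocation as a long CSV plus JSON sidecar
#'
#' The CSV has one row per line x environment cell with a train/test role;
#' the sidecar records method, seed, fraction and balance score.
#'
#' @param design an \code{allocation_design}.
#' @param path CSV path; the sidecar is written at \code{paste0(path, ".json")}.
#' @export
write_design <- function(design, path) {
  long <- expand.grid(line_id = design$line_ids, env_id = design$env_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$role <- ifelse(design$mask[cbind(match(long$line_id, design$line_ids),
                                        match(long$env_id, design$env_ids))] == 1L,
                      "train", "test")
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  meta <- list(method = design$method, seed = design$seed,
               train_fraction = training_fraction(design),
               r = design$r,
               balance_score = concurrence(design)$balance_score)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  line_ids <- unique(long$line_id); env_ids <- unique(long$env_id)
  mask <- matrix(0L, length(line_ids), length(env_ids),
                 dimnames = list(line_ids, env_ids))
  tr <- long[long$role == "train", ]
  mask[cbind(match(tr$line_id, line_ids), match(tr$env_id, env_ids))] <- 1L
  new_allocation_design(mask, line_ids, env_ids, meta$method,
                        meta$train_fraction, meta$seed,
                        r = if (is.null(meta$r)) NA_integer_ else meta$r)
}
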