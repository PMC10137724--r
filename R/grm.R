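#' Validate a marker dosage matrix
#'
#' Checks the container used throughout the package for genotype data: a
#' numeric matrix of biallelic allele dosages coded 0/1/2 (minor-allele
#' counts), lines in rows, markers in columns, with unique row names (line
#' ids). Missing genotypes are \code{NA}.
#'
#' @param markers numeric matrix, J lines x p markers, entries in
#'   \{0, 1, 2, NA\}.
#' @return the matrix, invisibly, after validation.
#' @export
validate_markers <- function(markers) {
  if (!is.matrix(markers) || !is.numeric(markers))
    stop("'markers' must be a numeric matrix (lines x markers)", call. = FALSE)
  if (nrow(markers) < 2L) stop("need at least 2 lines", call. = FALSE)
  if (ncol(markers) < 1L) stop("need at least 1 marker", call. = FALSE)
  v <- markers[!is.na(markers)]
  if (length(v) == 0L) stop("all genotypes are missing", call. = FALSE)
  if (!all(v %in% c(0, 1, 2)))
    stop("non-missing dosages must be 0, 1 or 2", call. = FALSE)
  ids <- rownames(markers)
  if (is.null(ids)) {
    rownames(markers) <- paste0("L", seq_len(nrow(markers)))
  } else if (anyDuplicated(ids)) {
    stop("line ids (row names) must be unique", call. = FALSE)
  }
  invisible(markers)
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' Builds the J x J genomic relationship matrix G from allele dosages. With
#' per-marker allele frequency \eqn{p_j} estimated from the observed panel,
#' dosages are centered, \eqn{W = M - 2p}, and
#' \deqn{G = W W' / (2 \sum_j p_j (1 - p_j)),}
#' the standard VanRaden scaling under which the average diagonal is near 1
#' for an unstructured panel. Missing dosages are imputed to the marker mean
#' before centering, so they contribute zero to W.
#'
#' @param markers dosage matrix as accepted by \code{\link{validate_markers}}.
#' @param min_maf markers with minor allele frequency below this are dropped
#'   (default 0: keep all).
#' @param max_missing markers with a missing fraction above this are dropped
#'   (default 1: keep all).
#' @return J x J symmetric matrix with line ids as dimnames.
#' @examples
#' M <- rbind(L1 = c(0, 1), L2 = c(2, 1))
#' compute_grm(M)
#' @export
compute_grm <- function(markers, min_maf = 0, max_missing = 1) {
  markers <- validate_markers(markers)
  if (min_maf < 0 || min_maf >= 0.5) stop("min_maf must be in [0, 0.5)", call. = FALSE)
  if (max_missing < 0 || max_missing > 1) stop("max_missing must be in [0, 1]", call. = FALSE)
  p <- colMeans(markers, na.rm = TRUE) / 2
  miss <- colMeans(is.na(markers))
  keep <- !is.na(p) & pmin(p, 1 - p) >= min_maf & miss <= max_missing
  if (!any(keep)) stop("no markers remain after MAF/missingness filtering", call. = FALSE)
  M <- markers[, keep, drop = FALSE]
  p <- p[keep]
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("no markers remain: all retained markers are monomorphic (zero denominator)",
         call. = FALSE)
  W <- sweep(M, 2L, 2 * p)
  W[is.na(W)] <- 0  # mean imputation: centered missing dosage is 0
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(M), rownames(M))
  G
}

#' Validate a genomic relationship matrix
#'
#' @param G square numeric matrix with matching row/column names.
#' @param tol symmetry tolerance.
#' @return \code{G}, invisibly.
#' @export
validate_grm <- function(G, tol = 1e-10) {
  if (!is.matrix(G) || !is.numeric(G) || nrow(G) != ncol(G))
    stop("'G' must be a square numeric matrix", call. = FALSE)
  if (max(abs(G - t(G))) > tol)
    stop("'G' is not symmetric", call. = FALSE)
  if (is.null(rownames(G)))
    dimnames(G) <- list(paste0("L", seq_len(nrow(G))), paste0("L", seq_len(nrow(G))))
  invisible(G)
}

#' Regularize a relationship matrix to positive definiteness
#'
#' Genomic relationship matrices are often numerically singular (duplicated
#' genotypes, more lines than markers), which breaks Cholesky-based samplers.
#' This adds the smallest uniform ridge that lifts the minimum eigenvalue to
#' \code{jitter} times the mean diagonal, leaving already well-conditioned
#' matrices essentially untouched.
#'
#' @param G symmetric matrix.
#' @param jitter relative eigenvalue floor (default \code{1e-6}).
#' @return symmetric positive-definite matrix of the same dimension.
#' @export
regularize_psd <- function(G, jitter = 1e-6) {
  G <- validate_grm(G, tol = 1e-8)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  floor_ev <- jitter * mean(diag(G))
  if (floor_ev <= 0) floor_ev <- jitter
  lam_min <- min(ev)
  if (lam_min < floor_ev)
    G <- G + diag(floor_ev - lam_min, nrow(G))
  G
}

#' Read / write marker and relationship matrices as CSV
#'
#' \code{read_markers} expects a header of marker ids and a first column of
#' line ids; \code{read_grm} expects line ids both as header and first
#' column. Writers are the exact inverses.
#'
#' @param path file path.
#' @return a numeric matrix with dimnames.
#' @export
read_markers <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  validate_markers(m)
  m
}

#' @rdname read_markers
#' @param markers,G matrix to write.
#' @export
write_markers <- function(markers, path) {
  df <- data.frame(line_id = rownames(markers), markers,
                   check.names = FALSE, row.names = NULL)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_markers
#' @export
read_grm <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  validate_grm(m, tol = 1e-6)
  m
}

#' @rdname read_markers
#' @export
write_grm <- function(G, path) {
  df <- data.frame(line_id = rownames(G), G, check.names = FALSE, row.names = NULL)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
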