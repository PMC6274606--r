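#' Rogers-Tanimoto dissimilarity between two binary vectors
#'
#' With `a` = matches on 1, `d` = matches on 0 and `b + c` = mismatches,
#' the Rogers-Tanimoto similarity is `(a + d) / (a + d + 2 (b + c))` —
#' mismatches are double-weighted. The returned dissimilarity is
#' `1 - S = 2 (b + c) / (a + d + 2 (b + c))`, in `[0, 1]`.
#'
#' @param x,y binary (0/1) vectors of equal positive length.
#' @return dissimilarity in `[0, 1]`; 0 iff `x == y`, 1 iff `y` is the
#'   complement of `x`.
#' @export
rogers_tanimoto <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1L) {
    stop("vectors must have equal positive length", call. = FALSE)
  }
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1))) {
    stop("vectors must be binary (0/1)", call. = FALSE)
  }
  mism <- sum(x != y)
  2 * mism / (length(x) + mism)
}

#' Pairwise Rogers-Tanimoto dissimilarity matrix
#'
#' @param B binary matrix, one object per row.
#' @return symmetric dissimilarity matrix with zero diagonal and the row
#'   names of `B`.
#' @export
rogers_tanimoto_matrix <- function(B) {
  stopifnot(is.matrix(B), nrow(B) >= 2L)
  n <- nrow(B)
  D <- matrix(0, n, n, dimnames = list(rownames(B), rownames(B)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      D[i, j] <- D[j, i] <- rogers_tanimoto(B[i, ], B[j, ])
    }
  }
  D
}

#' Classical (Torgerson) metric multidimensional scaling
#'
#' Double-centers the squared dissimilarities,
#' \eqn{B = -\tfrac12 J D^{(2)} J}, eigendecomposes, and builds
#' coordinates from the leading positive eigenpairs. Negative eigenvalues
#' (non-Euclidean input) are excluded from both the coordinates and the
#' variance-explained denominator, with a message giving their count.
#' Each coordinate axis has its sign fixed so that its
#' largest-magnitude entry is positive, making the embedding
#' deterministic.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal.
#' @param n_dims number of dimensions to retain (default 4; truncated to
#'   the number of positive eigenvalues).
#' @return an `mds_result`: list with `points` (objects x dims, centered
#'   columns), `eigenvalues` (all, descending), `variance_explained`
#'   (fraction of the positive-eigenvalue total per retained dimension)
#'   and `n_negative` (count of negative eigenvalues).
#' @export
classical_mds <- function(D, n_dims = 4) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > 1e-8 || any(abs(diag(D)) > 1e-12)) {
    stop("D must be symmetric with a zero diagonal", call. = FALSE)
  }
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  ev <- eg$values
  tol <- 1e-9 * max(abs(ev), 1)
  pos <- which(ev > tol)
  n_neg <- sum(ev < -tol)
  if (n_neg > 0L) {
    message(sprintf("classical_mds: %d negative eigenvalue(s) excluded",
                    n_neg))
  }
  keep <- utils::head(pos, n_dims)
  if (length(keep) == 0L) {
    pts <- matrix(0, n, max(1L, n_dims),
                  dimnames = list(rownames(D), NULL))
    ve <- rep(0, ncol(pts))
  } else {
    pts <- eg$vectors[, keep, drop = FALSE] %*%
      diag(sqrt(ev[keep]), nrow = length(keep))
    for (j in seq_len(ncol(pts))) {
      if (pts[which.max(abs(pts[, j])), j] < 0) pts[, j] <- -pts[, j]
    }
    rownames(pts) <- rownames(D)
    ve <- ev[keep] / sum(ev[pos])
  }
  colnames(pts) <- paste0("dim", seq_len(ncol(pts)))
  structure(list(points = pts, eigenvalues = ev,
                 variance_explained = ve, n_negative = n_neg),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf("<mds_result> %d objects embedded in %d dimension(s)\n",
              nrow(x$points), ncol(x$points)))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
      "\n")
  invisible(x)
}

#' Cumulative variance explained by MDS dimension
#'
#' @param result an `mds_result`.
#' @return `data.frame` with `dim`, `eigenvalue`, `variance_explained`,
#'   `cumulative` (fractions of the positive-eigenvalue total).
#' @export
mds_report <- function(result) {
  stopifnot(inherits(result, "mds_result"))
  ve <- result$variance_explained
  ev <- result$eigenvalues[seq_along(ve)]
  data.frame(dim = seq_along(ve), eigenvalue = ev,
             variance_explained = ve, cumulative = cumsum(ve),
             row.names = NULL)
}
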