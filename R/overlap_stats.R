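#' Upper-tail hypergeometric probability (one-tailed Fisher's exact test)
#'
#' Computes \eqn{P(X \ge k)} where \eqn{X} is the number of marked genes in
#' a draw of size \eqn{n} from a universe of \eqn{N} genes of which \eqn{K}
#' are marked. This is the one-tailed (enrichment) Fisher's exact test
#' p-value for the overlap of two gene lists over a fixed gene universe.
#' The tail is summed in log space from log-binomial terms, so very small
#' p-values do not underflow term-by-term.
#'
#' @param N universe size.
#' @param K number of marked genes (size of list A).
#' @param n draw size (size of list B).
#' @param k observed overlap.
#' @return the upper-tail probability, in (0, 1]; exactly 1 when `k <= 0`.
#' @examples
#' hypergeom_upper_tail(22000, 175, 281, 6)
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  stopifnot(length(N) == 1L, length(K) == 1L, length(n) == 1L,
            length(k) == 1L)
  if (any(c(N, K, n, k) != floor(c(N, K, n, k))) || N < 0 || K < 0 || n < 0) {
    stop("N, K, n, k must be non-negative integers", call. = FALSE)
  }
  if (K > N || n > N) stop("infeasible margins: K and n must be <= N",
                           call. = FALSE)
  kmax <- min(K, n)
  kmin <- max(0L, K + n - N)
  if (k > kmax) stop("infeasible overlap: k > min(K, n)", call. = FALSE)
  if (k <= kmin) return(1)
  i <- seq.int(k, kmax)
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(logp)
  min(1, exp(m) * sum(exp(logp - m)))
}

#' Overlap test for a pair of gene sets
#'
#' @param a,b human-normalized `gene_set` objects.
#' @param universe gene-universe size (default 22000).
#' @return an `overlap_result`: set ids and sizes, shared count `k`,
#'   universe `N`, upper-tail `p_value`, and sorted `shared_symbols`.
#' @export
overlap_pair <- function(a, b, universe = 22000) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  if (length(a) > universe || length(b) > universe) {
    stop("gene set larger than the universe", call. = FALSE)
  }
  shared <- sort(intersect(a$symbols, b$symbols))
  k <- length(shared)
  structure(
    list(set_a = a$set_id, set_b = b$set_id,
         n_a = length(a), n_b = length(b), k = k, N = universe,
         p_value = hypergeom_upper_tail(universe, length(a), length(b), k),
         shared_symbols = shared),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap> %s (n=%d) vs %s (n=%d): k=%d of N=%d, p=%.4g\n",
              x$set_a, x$n_a, x$set_b, x$n_b, x$k, x$N, x$p_value))
  invisible(x)
}

#' All-pairs overlap matrix
#'
#' Tests every unordered pair of gene sets, in the deterministic order of
#' the input list, and flags significance at `alpha` (uncorrected by
#' default, with an optional BH adjustment).
#'
#' @param sets list of `gene_set` objects (>= 2).
#' @param universe gene-universe size.
#' @param alpha significance level for the flag (default 0.05).
#' @param bh also add BH-adjusted p-values and flag on them? Default FALSE.
#' @return a `data.frame` with one row per pair: `set_a`, `set_b`, `n_a`,
#'   `n_b`, `k`, `N`, `p_value`, `significant`, `shared_symbols`
#'   (comma-separated).
#' @export
overlap_matrix <- function(sets, universe = 22000, alpha = 0.05, bh = FALSE) {
  stopifnot(length(sets) >= 2L)
  ids <- vapply(sets, function(s) s$set_id, character(1))
  pairs <- utils::combn(seq_along(sets), 2L)
  rows <- apply(pairs, 2L, function(ij) {
    r <- overlap_pair(sets[[ij[1L]]], sets[[ij[2L]]], universe)
    data.frame(set_a = r$set_a, set_b = r$set_b, n_a = r$n_a, n_b = r$n_b,
               k = r$k, N = r$N, p_value = r$p_value,
               shared_symbols = paste(r$shared_symbols, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bh) {
    out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_bh < alpha
  } else {
    out$significant <- out$p_value < alpha
  }
  out
}

#' Category-level union overlap analysis
#'
#' Merges the evidence sets of each main category (gwas, transcriptome,
#' highrisk; control excluded) into union gene sets, tests the three
#' pairwise overlaps by the one-tailed Fisher test, and reports the triple
#' intersection.
#'
#' @param sets list of `gene_set` objects carrying category tags.
#' @param universe gene-universe size.
#' @return a list with `unions` (named list of symbol vectors), `pairwise`
#'   (data.frame as in [overlap_matrix()]) and `triple_intersection`
#'   (character vector of symbols present in all three category unions).
#' @export
merge_categories <- function(sets, universe = 22000) {
  cats <- c("gwas", "transcriptome", "highrisk")
  unions <- lapply(cats, function(cc) {
    members <- Filter(function(s) s$category == cc, sets)
    if (length(members) == 0L) {
      stop("no gene sets in category '", cc, "'", call. = FALSE)
    }
    sort(unique(unlist(lapply(members, `[[`, "symbols"))))
  })
  names(unions) <- cats
  union_sets <- lapply(cats, function(cc) {
    gene_set(unions[[cc]], set_id = cc, category = cc, species = "human",
             provenance = "category union")
  })
  pairwise <- overlap_matrix(union_sets, universe = universe)
  triple <- Reduce(intersect, unions)
  list(unions = unions, pairwise = pairwise,
       triple_intersection = sort(triple))
}
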