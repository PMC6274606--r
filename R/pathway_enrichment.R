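#' Canonical-pathway enrichment profile for one gene set
#'
#' For every pathway in the collection, tests over-representation of the
#' gene set's members by the upper-tail hypergeometric (one-tailed
#' Fisher's exact) test over a configured gene universe, reports
#' `-log10(p)`, and codes enrichment as a binary variable
#' (1 iff p < `alpha`, strictly).
#'
#' @param gs a non-empty `gene_set`.
#' @param pathways a `pathway_collection`.
#' @param universe gene-universe size (default 22000); must be at least as
#'   large as the set and every pathway.
#' @param alpha binary-coding cut-off (default 0.05).
#' @return an `enrichment_profile`: a `data.frame` with one row per
#'   pathway (`pathway`, `pathway_size`, `overlap`, `p_value`,
#'   `neg_log10_p`, `enriched`) plus attributes `set_id` and
#'   `collection_id`.
#' @export
enrich_set <- function(gs, pathways, universe = 22000, alpha = 0.05) {
  stopifnot(inherits(gs, "gene_set"), inherits(pathways,
                                               "pathway_collection"))
  sizes <- lengths(pathways)
  if (any(sizes > universe) || length(gs) > universe) {
    stop("pathway or gene set larger than the universe", call. = FALSE)
  }
  ov <- vapply(pathways, function(pw) length(intersect(gs$symbols, pw)),
               integer(1))
  p <- mapply(function(K, k) {
    hypergeom_upper_tail(universe, K, length(gs), k)
  }, sizes, ov)
  out <- data.frame(pathway = names(pathways),
                    pathway_size = as.integer(sizes),
                    overlap = as.integer(ov),
                    p_value = as.numeric(p),
                    neg_log10_p = -log10(as.numeric(p)),
                    enriched = as.integer(p < alpha),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("enrichment_profile", "data.frame"),
            set_id = gs$set_id,
            collection_id = attr(pathways, "collection_id"),
            alpha = alpha, universe = universe)
}

#' Pathways enriched in several gene sets at once
#'
#' @param profiles list of `enrichment_profile` objects over the same
#'   pathway collection.
#' @param min_sets minimum number of profiles in which a pathway must be
#'   coded enriched (default 3).
#' @return `data.frame` with `pathway`, `n_enriched` and `sets`
#'   (comma-separated contributing set ids), sorted by `n_enriched`
#'   descending then pathway name.
#' @export
shared_pathways <- function(profiles, min_sets = 3) {
  B <- profile_matrix(profiles, type = "binary")
  cnt <- colSums(B)
  keep <- cnt >= min_sets
  sets <- vapply(colnames(B)[keep], function(pw) {
    paste(rownames(B)[B[, pw] == 1], collapse = ",")
  }, character(1))
  out <- data.frame(pathway = colnames(B)[keep],
                    n_enriched = as.integer(cnt[keep]),
                    sets = unname(sets),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$n_enriched, out$pathway), , drop = FALSE]
}

#' Category-level overlap of enriched pathways
#'
#' Each category's binary pathway flag is the union of its member
#' profiles' flags (a pathway counts for the category if enriched in any
#' member set). Pairwise category overlaps are then tested by the
#' upper-tail Fisher test over a universe equal to the number of pathways
#' in the collection.
#'
#' @param profiles list of `enrichment_profile` objects.
#' @param categories character vector, one category per profile.
#' @return list with `flags` (categories x pathways binary matrix) and
#'   `pairwise` (`data.frame` of category pairs with `n_a`, `n_b`, `k`,
#'   `N`, `p_value`).
#' @export
category_pathway_overlap <- function(profiles, categories) {
  stopifnot(length(profiles) == length(categories))
  B <- profile_matrix(profiles, type = "binary")
  cats <- unique(categories)
  flags <- t(vapply(cats, function(cc) {
    as.integer(colSums(B[categories == cc, , drop = FALSE]) > 0)
  }, integer(ncol(B))))
  dimnames(flags) <- list(cats, colnames(B))
  n_pw <- ncol(B)
  pairs <- utils::combn(cats, 2L)
  pw <- apply(pairs, 2L, function(ab) {
    fa <- flags[ab[1L], ]; fb <- flags[ab[2L], ]
    na <- sum(fa); nb <- sum(fb); k <- sum(fa & fb)
    if (na == 0L || nb == 0L) {
      warning("category '", ab[which(c(na, nb) == 0L)[1L]],
              "' has no enriched pathway; p set to 1", call. = FALSE)
      p <- 1
    } else {
      p <- hypergeom_upper_tail(n_pw, na, nb, k)
    }
    data.frame(cat_a = ab[1L], cat_b = ab[2L], n_a = na, n_b = nb,
               k = k, N = n_pw, p_value = p, stringsAsFactors = FALSE)
  })
  list(flags = flags, pairwise = do.call(rbind, pw))
}

#' Combine enrichment profiles into a sets-by-pathways matrix
#'
#' @param profiles list of `enrichment_profile` objects over a common
#'   collection.
#' @param type `"binary"` (0/1 enrichment coding) or `"neglog10"`
#'   (-log10 p values).
#' @return numeric matrix, one row per gene set in input order, one column
#'   per pathway in collection order.
#' @export
profile_matrix <- function(profiles, type = c("binary", "neglog10")) {
  type <- match.arg(type)
  stopifnot(length(profiles) >= 1L)
  cols <- profiles[[1L]]$pathway
  coll <- attr(profiles[[1L]], "collection_id")
  for (pr in profiles) {
    if (!identical(pr$pathway, cols) ||
        !identical(attr(pr, "collection_id"), coll)) {
      stop("profiles are not over the same pathway collection",
           call. = FALSE)
    }
  }
  M <- t(vapply(profiles, function(pr) {
    if (type == "binary") as.numeric(pr$enriched) else pr$neg_log10_p
  }, numeric(length(cols))))
  dimnames(M) <- list(vapply(profiles, attr, character(1), "set_id"), cols)
  M
}
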