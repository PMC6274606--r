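DEFAULT_RANK_WEIGHTS <- c(gwas = 1, transcriptome = 0.5, highrisk = 1.5)

#' Count per-gene evidence occurrences across the evidence lists
#'
#' Membership is binary per list: a gene counts once per list regardless of
#' how often the source reported it. Occurrences are tallied by category:
#' `g` over the human GWAS lists, `r` over the rodent transcriptome lists,
#' `h` over the high-risk (OMIM + knockout-mouse) lists. The control
#' category is excluded.
#'
#' @param sets list of human-normalized `gene_set` objects; the canonical
#'   design has 2 gwas, 4 transcriptome and 2 highrisk sets (other
#'   multiplicities are allowed with a warning).
#' @return a `data.frame` with one row per gene appearing in at least one
#'   list: `symbol`, `g`, `r`, `h`, `occurrence_total`. A logical
#'   membership matrix (genes x sets) and per-set metadata are attached as
#'   attributes `membership` and `set_info` for downstream evidence-class
#'   assignment.
#' @export
count_occurrences <- function(sets) {
  sets <- Filter(function(s) s$category != "control", sets)
  stopifnot(length(sets) >= 1L)
  cats <- vapply(sets, `[[`, character(1), "category")
  mult <- c(gwas = sum(cats == "gwas"),
            transcriptome = sum(cats == "transcriptome"),
            highrisk = sum(cats == "highrisk"))
  if (!identical(unname(mult), c(2L, 4L, 2L))) {
    warning(sprintf(
      "category multiplicity (gwas=%d, transcriptome=%d, highrisk=%d) differs from the canonical (2, 4, 2) design",
      mult[1L], mult[2L], mult[3L]), call. = FALSE)
  }
  ids <- vapply(sets, `[[`, character(1), "set_id")
  all_genes <- sort(unique(unlist(lapply(sets, `[[`, "symbols"))))
  membership <- vapply(sets, function(s) all_genes %in% s$symbols,
                       logical(length(all_genes)))
  membership <- matrix(membership, nrow = length(all_genes),
                       dimnames = list(all_genes, ids))
  g <- rowSums(membership[, cats == "gwas", drop = FALSE])
  r <- rowSums(membership[, cats == "transcriptome", drop = FALSE])
  h <- rowSums(membership[, cats == "highrisk", drop = FALSE])
  out <- data.frame(symbol = all_genes, g = as.integer(g),
                    r = as.integer(r), h = as.integer(h),
                    occurrence_total = as.integer(g + r + h),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "membership") <- membership
  attr(out, "set_info") <- data.frame(
    set_id = ids, category = cats,
    species = vapply(sets, function(s) {
      if (!is.null(s$source_species)) s$source_species else s$species
    }, character(1)),
    stringsAsFactors = FALSE)
  out
}

#' Weighted aggression gene ranking
#'
#' Scores each gene as
#' \deqn{1 \cdot g + 0.5 \cdot r + 1.5 \cdot h}
#' where `g`, `r`, `h` are the per-category occurrence counts: GWAS
#' occurrences keep unit weight, rodent transcriptome evidence is
#' discounted to 0.5 (so four rodent lists cap at 2, the same maximum as
#' the two GWAS lists), and causal high-risk evidence (OMIM disorders,
#' knockout-mouse aggression phenotypes) is up-weighted to 1.5.
#'
#' @param records output of [count_occurrences()].
#' @param weights named numeric weights for `gwas`, `transcriptome`,
#'   `highrisk`.
#' @return the records with a `weighted_score` column, sorted by score
#'   descending, then `occurrence_total` descending, then symbol ascending
#'   (a deterministic total order).
#' @export
weighted_rank <- function(records, weights = DEFAULT_RANK_WEIGHTS) {
  stopifnot(all(c("g", "r", "h") %in% names(records)),
            all(c("gwas", "transcriptome", "highrisk") %in% names(weights)))
  records$weighted_score <- weights[["gwas"]] * records$g +
    weights[["transcriptome"]] * records$r +
    weights[["highrisk"]] * records$h
  ord <- order(-records$weighted_score, -records$occurrence_total,
               records$symbol)
  out <- records[ord, , drop = FALSE]
  attr(out, "membership") <- attr(records, "membership")
  attr(out, "set_info") <- attr(records, "set_info")
  rownames(out) <- NULL
  out
}

#' Top-ranked genes at a score threshold
#'
#' @param records output of [weighted_rank()].
#' @param score_threshold inclusive lower bound on `weighted_score`
#'   (default 2).
#' @return the subset with `weighted_score >= score_threshold`, order
#'   preserved; membership attributes carried along.
#' @export
top_genes <- function(records, score_threshold = 2) {
  keep <- records$weighted_score >= score_threshold
  out <- records[keep, , drop = FALSE]
  mb <- attr(records, "membership")
  if (!is.null(mb)) {
    attr(out, "membership") <- mb[out$symbol, , drop = FALSE]
  }
  attr(out, "set_info") <- attr(records, "set_info")
  rownames(out) <- NULL
  out
}
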