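#' Degrees of focus genes in an interaction network
#'
#' @param g an undirected simple [igraph::igraph] with gene-symbol vertex
#'   names.
#' @param focus gene symbols of interest; symbols absent from the network
#'   are excluded with a message.
#' @return named integer vector of degrees (number of distinct neighbors)
#'   for the focus genes present in the network.
#' @export
degrees <- function(g, focus) {
  vn <- igraph::V(g)$name
  missing <- setdiff(focus, vn)
  if (length(missing) > 0L) {
    message(sprintf("degrees: %d focus gene(s) absent from the network: %s",
                    length(missing),
                    paste(utils::head(missing, 5L), collapse = ", ")))
  }
  present <- intersect(focus, vn)
  stats::setNames(as.integer(igraph::degree(g, v = present)), present)
}

#' Assign evidence classes to ranked genes
#'
#' Genes whose evidence comes only from human sources (GWAS lists and
#' OMIM) are `human_only`; genes with evidence only from rodent sources
#' (rodent transcriptome lists and knockout-mouse reports) are
#' `rodent_only`; genes with both kinds are `both`. Note that the
#' high-risk weighting category mixes species: OMIM counts as human
#' evidence and the knockout-mouse list as rodent evidence here.
#'
#' @param records output of [count_occurrences()] / [weighted_rank()]
#'   (must carry the `membership` and `set_info` attributes).
#' @param evidence_species optional named character vector mapping set ids
#'   to `"human"` or `"rodent"`; by default derived from each set's
#'   species tag (`human` -> human evidence, `mouse`/`rat` -> rodent).
#' @return named factor of classes (levels `human_only`, `rodent_only`,
#'   `both`), one per gene in `records`.
#' @export
classify_evidence <- function(records, evidence_species = NULL) {
  mb <- attr(records, "membership")
  info <- attr(records, "set_info")
  if (is.null(mb) || is.null(info)) {
    stop("records must carry membership attributes from count_occurrences()",
         call. = FALSE)
  }
  if (is.null(evidence_species)) {
    evidence_species <- stats::setNames(
      ifelse(info$species == "human", "human", "rodent"), info$set_id)
  }
  if (!all(colnames(mb) %in% names(evidence_species))) {
    stop("evidence_species must cover every set", call. = FALSE)
  }
  mb <- mb[records$symbol, , drop = FALSE]
  es <- evidence_species[colnames(mb)]
  hu <- rowSums(mb[, es == "human", drop = FALSE]) > 0
  ro <- rowSums(mb[, es == "rodent", drop = FALSE]) > 0
  if (any(!hu & !ro)) {
    stop("gene(s) with zero evidence occurrences", call. = FALSE)
  }
  cls <- ifelse(hu & ro, "both", ifelse(hu, "human_only", "rodent_only"))
  stats::setNames(factor(cls, levels = c("human_only", "rodent_only",
                                         "both")), records$symbol)
}

#' Median regression of log-degree on an evidence-class contrast
#'
#' Fits a median (0.5-quantile) regression of `log10(degree)` on a binary
#' class indicator. With a single binary covariate the fitted slope equals
#' the difference of group medians of log10 degree,
#' `median(class_a) - median(class_b)`, which is computed directly.
#' Significance is assessed by a seeded stratified case bootstrap of the
#' slope (resampling genes with replacement within each class), with the
#' two-sided percentile p-value
#' `2 * min(P(slope* <= 0), P(slope* >= 0))` (add-one corrected).
#' Degree-zero genes are excluded with a warning (their log is undefined).
#'
#' @param degree_by_gene named numeric vector of degrees (from
#'   [degrees()]).
#' @param classes named factor/character of evidence classes covering the
#'   genes (from [classify_evidence()]).
#' @param contrast length-2 character vector `(class_a, class_b)`.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return a `degree_comparison`: list with `data` (per-gene symbol,
#'   class, degree, log10_degree), `contrast`, `slope`, `p_value`,
#'   `n_boot`, `n_per_class`.
#' @export
median_regression_logdeg <- function(degree_by_gene, classes,
                                     contrast = c("human_only",
                                                  "rodent_only"),
                                     n_boot = 1000, seed = 1) {
  stopifnot(length(contrast) == 2L, !is.null(names(degree_by_gene)))
  cls <- as.character(classes[names(degree_by_gene)])
  zero <- degree_by_gene == 0
  if (any(zero)) {
    warning(sprintf("excluding %d degree-0 gene(s): log undefined",
                    sum(zero)), call. = FALSE)
  }
  keep <- !zero & cls %in% contrast & !is.na(cls)
  y <- log10(degree_by_gene[keep])
  x <- cls[keep]
  na <- sum(x == contrast[1L]); nb <- sum(x == contrast[2L])
  if (na < 3L || nb < 3L) {
    stop("each contrasted class needs >= 3 genes with degree >= 1",
         call. = FALSE)
  }
  slope_of <- function(ya, yb) stats::median(ya) - stats::median(yb)
  ya <- y[x == contrast[1L]]; yb <- y[x == contrast[2L]]
  slope <- slope_of(ya, yb)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    slope_of(sample(ya, na, replace = TRUE),
             sample(yb, nb, replace = TRUE))
  }, numeric(1))
  p_lo <- (1 + sum(boot <= 0)) / (n_boot + 1)
  p_hi <- (1 + sum(boot >= 0)) / (n_boot + 1)
  p <- min(1, 2 * min(p_lo, p_hi))
  structure(
    list(data = data.frame(symbol = names(y), class = x, degree =
                             as.integer(degree_by_gene[keep]),
                           log10_degree = as.numeric(y),
                           stringsAsFactors = FALSE, row.names = NULL),
         contrast = contrast, slope = slope, p_value = p,
         n_boot = n_boot,
         n_per_class = stats::setNames(c(na, nb), contrast)),
    class = "degree_comparison"
  )
}

#' @export
print.degree_comparison <- function(x, ...) {
  cat(sprintf(
    "<degree_comparison> %s (n=%d) vs %s (n=%d)\n  median log10-degree difference = %.3f, bootstrap p = %.4g (%d resamples)\n",
    x$contrast[1L], x$n_per_class[1L], x$contrast[2L], x$n_per_class[2L],
    x$slope, x$p_value, x$n_boot))
  invisible(x)
}
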