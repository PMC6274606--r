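#' Pick the soft-thresholding power for the co-expression adjacency
#'
#' The adjacency between genes i and j is `|cor(x_i, x_j)|^power`. The
#' power is chosen as in weighted co-expression analysis: the smallest
#' candidate whose connectivity distribution fits a scale-free topology
#' with model R-squared at or above `fit_threshold`; if no candidate
#' qualifies, the power maximizing the fit is returned with a warning.
#' The fit index is signed: a positive slope of log-frequency on
#' log-connectivity contributes zero fit.
#'
#' @param m expression matrix, genes in rows, samples in columns.
#' @param candidate_powers ascending positive integers to try.
#' @param fit_threshold required scale-free fit R-squared (default 0.8).
#' @param n_bins number of connectivity bins for the fit.
#' @return the selected power (integer) with attribute `fit_r2` giving the
#'   R-squared per candidate.
#' @export
pick_soft_power <- function(m, candidate_powers = c(1:10, 12, 14, 16, 18, 20),
                            fit_threshold = 0.8, n_bins = 10) {
  stopifnot(is.matrix(m), nrow(m) >= 20L)
  if (any(apply(m, 1L, stats::sd) == 0)) {
    stop("constant-expression genes present; filter before module detection",
         call. = FALSE)
  }
  stopifnot(length(candidate_powers) >= 1L,
            !is.unsorted(candidate_powers), all(candidate_powers > 0))
  ac <- abs(stats::cor(t(m)))
  diag(ac) <- 0
  r2 <- vapply(candidate_powers, function(p) {
    k <- rowSums(ac^p)
    scale_free_fit(k, n_bins)
  }, numeric(1))
  names(r2) <- as.character(candidate_powers)
  ok <- which(r2 >= fit_threshold)
  power <- if (length(ok) > 0L) {
    candidate_powers[ok[1L]]
  } else {
    warning("no candidate power reaches the scale-free fit threshold; ",
            "using the best-fitting power", call. = FALSE)
    candidate_powers[which.max(r2)]
  }
  structure(as.integer(power), fit_r2 = r2)
}

# Signed scale-free topology fit index: R^2 of log10(p(k)) ~ log10(k)
# over connectivity bins, zeroed when the slope is positive.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3L) return(0)
  bins <- cut(k, breaks = n_bins)
  freq <- tapply(k, bins, length)
  mk <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3L) return(0)
  fit <- stats::lm(log10(freq[keep]) ~ log10(mk[keep]))
  r2 <- summary(fit)$r.squared
  if (stats::coef(fit)[2L] > 0) 0 else r2
}

#' Detect co-expression modules by hierarchical clustering
#'
#' Builds the unsigned adjacency `|cor|^power`, converts it to the
#' dissimilarity `1 - adjacency`, clusters genes by average-linkage
#' hierarchical clustering, and cuts the tree at a fixed height. Clusters
#' of at least `min_module_size` genes become modules; the rest go to an
#' unassigned pool that is excluded from association testing.
#'
#' @param m expression matrix, genes x samples.
#' @param power soft-thresholding power (see [pick_soft_power()]).
#' @param min_module_size smallest cluster size kept as a module
#'   (default 20).
#' @param cut_height static tree-cut height on the dissimilarity scale
#'   (default 0.88; at the conventional power 6 this admits members whose
#'   average correlation with the module exceeds roughly 0.7. Cuts close
#'   to 1 admit chance-level correlations — with few samples, absolute
#'   correlations around 0.6 arise by chance among a few hundred genes —
#'   which attaches unrelated background genes to real modules; weakly
#'   coherent modules whose internal merges finish above the cut can be
#'   recovered by raising it).
#' @return a list of `coexpression_module` objects (fields `module_id`,
#'   `members`); unassigned genes in attribute `unassigned`.
#' @export
detect_modules <- function(m, power, min_module_size = 20, cut_height = 0.88) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  if (nrow(m) < min_module_size) {
    warning("fewer genes than min_module_size; returning a single module",
            call. = FALSE)
    mod <- list(structure(list(module_id = "M1", members = rownames(m)),
                          class = "coexpression_module"))
    attr(mod, "unassigned") <- character(0)
    return(mod)
  }
  adj <- abs(stats::cor(t(m)))^power
  diss <- stats::as.dist(1 - adj)
  tree <- stats::hclust(diss, method = "average")
  labels <- stats::cutree(tree, h = cut_height)
  tab <- table(labels)
  keep <- names(tab)[tab >= min_module_size]
  # deterministic module ids: by decreasing size, ties by smallest member
  keep <- keep[order(-tab[keep],
                     vapply(keep, function(l) min(rownames(m)[labels == l]),
                            character(1)))]
  mods <- lapply(seq_along(keep), function(i) {
    structure(list(module_id = paste0("M", i),
                   members = sort(rownames(m)[labels == keep[i]])),
              class = "coexpression_module")
  })
  attr(mods, "unassigned") <-
    sort(rownames(m)[!labels %in% as.integer(keep)])
  mods
}

#' Module eigengene
#'
#' The eigengene is the first principal component of the gene-standardized
#' module submatrix: one value per sample, scaled to unit norm, with the
#' sign oriented so that its mean correlation with the member genes is
#' positive (falling back to a largest-magnitude-positive rule when that
#' mean is zero).
#'
#' @param m expression matrix, genes x samples.
#' @param members character vector of module member genes (>= 2).
#' @return numeric vector of per-sample eigengene values with attribute
#'   `explained_variance` (leading eigenvalue over total variance).
#' @export
eigengene <- function(m, members) {
  stopifnot(length(members) >= 2L, all(members %in% rownames(m)))
  x <- m[members, , drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  if (all(sds == 0)) stop("zero-variance module submatrix", call. = FALSE)
  z <- (x - rowMeans(x)) / ifelse(sds == 0, 1, sds)
  sv <- svd(z)
  e <- sv$v[, 1L]
  e <- e / sqrt(sum(e^2))
  cors <- suppressWarnings(apply(z, 1L, function(g) stats::cor(g, e)))
  mc <- mean(cors, na.rm = TRUE)
  if (is.finite(mc) && abs(mc) > 1e-12) {
    if (mc < 0) e <- -e
  } else if (e[which.max(abs(e))] < 0) {
    e <- -e
  }
  names(e) <- colnames(m)
  attr(e, "explained_variance") <- sv$d[1L]^2 / sum(sv$d^2)
  e
}

#' Test module eigengenes for association with the aggression group
#'
#' A two-sided two-sample t-test (pooled variance by default) compares the
#' eigengene between the high- and low-aggression groups; p-values are
#' BH-adjusted across all tested modules of the dataset. Direction is the
#' sign of (mean high - mean low).
#'
#' @param modules list of `coexpression_module` objects from
#'   [detect_modules()].
#' @param m expression matrix used to compute eigengenes.
#' @param metadata `data.frame` with columns `sample` and
#'   `group` (`"high"` / `"low"`), one row per column of `m`.
#' @param var_equal pooled-variance t-test (TRUE, default) or Welch.
#' @return the modules, each augmented with `eigengene`,
#'   `explained_variance`, `assoc_p`, `assoc_p_bh`, `direction`.
#' @export
associate_modules <- function(modules, m, metadata, var_equal = TRUE) {
  stopifnot(all(c("sample", "group") %in% names(metadata)),
            all(colnames(m) %in% metadata$sample))
  grp <- metadata$group[match(colnames(m), metadata$sample)]
  if (!all(grp %in% c("high", "low"))) {
    stop("group must be 'high' or 'low'", call. = FALSE)
  }
  if (min(table(grp)) < 2L) stop("need >= 2 samples per group",
                                 call. = FALSE)
  ps <- numeric(length(modules))
  for (i in seq_along(modules)) {
    e <- eigengene(m, modules[[i]]$members)
    hi <- e[grp == "high"]; lo <- e[grp == "low"]
    if (stats::var(hi) + stats::var(lo) == 0) {
      stop("zero pooled variance for module ", modules[[i]]$module_id,
           "; p undefined", call. = FALSE)
    }
    tt <- stats::t.test(hi, lo, var.equal = var_equal)
    modules[[i]]$eigengene <- e
    modules[[i]]$explained_variance <- attr(e, "explained_variance")
    modules[[i]]$assoc_p <- tt$p.value
    modules[[i]]$direction <- if (mean(hi) - mean(lo) > 0) "up" else "down"
    ps[i] <- tt$p.value
  }
  bh <- stats::p.adjust(ps, method = "BH")
  for (i in seq_along(modules)) modules[[i]]$assoc_p_bh <- bh[i]
  modules
}

#' Select significant modules as transcriptome gene sets
#'
#' Modules with BH-adjusted association p strictly below `bh_threshold`
#' become `gene_set` objects of category `transcriptome`. An optional
#' relaxed rule additionally admits modules with uncorrected p below
#' `relaxed_p` (for designs where a lenient pre-specified criterion is
#' wanted for a particular dataset).
#'
#' @param modules output of [associate_modules()].
#' @param bh_threshold BH cut-off (default 0.05, strict `<`).
#' @param set_prefix prefix for the emitted set ids.
#' @param species species tag for the emitted sets.
#' @param relaxed_p optional uncorrected-p admission rule (`NULL` = off).
#' @return list of `gene_set` objects (possibly empty, with a warning).
#' @export
select_significant <- function(modules, bh_threshold = 0.05,
                               set_prefix = "module", species = "mouse",
                               relaxed_p = NULL) {
  sel <- Filter(function(mo) {
    mo$assoc_p_bh < bh_threshold ||
      (!is.null(relaxed_p) && mo$assoc_p < relaxed_p)
  }, modules)
  if (length(sel) == 0L) {
    warning("no module passes the association threshold", call. = FALSE)
    return(list())
  }
  lapply(sel, function(mo) {
    gene_set(mo$members,
             set_id = paste0(set_prefix, "_", mo$module_id),
             category = "transcriptome", species = species,
             provenance = sprintf("coexpression module %s (%s, BH p=%.3g)",
                                  mo$module_id, mo$direction, mo$assoc_p_bh))
  })
}

#' Merge module gene sets into one combined set
#'
#' Union of members with concatenated provenance, e.g. combining the up-
#' and down-regulated modules of one strain pair into a single evidence
#' list for downstream analysis.
#'
#' @param sets list of `gene_set` objects (>= 1), same species.
#' @param set_id id for the merged set.
#' @return a `gene_set`.
#' @export
merge_module_sets <- function(sets, set_id = "merged") {
  stopifnot(length(sets) >= 1L)
  gene_set(unlist(lapply(sets, `[[`, "symbols")),
           set_id = set_id, category = "transcriptome",
           species = sets[[1L]]$species,
           provenance = paste(vapply(sets, `[[`, character(1), "provenance"),
                              collapse = " + "))
}
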