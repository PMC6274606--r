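#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generator. The defaults
#' reproduce the geometry of the study design the pipeline targets: nine
#' gene lists (two human GWAS, four rodent transcriptome, OMIM and
#' knockout-mouse high-risk lists, and a GWAS control list) drawn from a
#' 22,000-gene universe with the published pairwise overlaps, two-group
#' expression matrices with planted co-expression modules, a pathway
#' collection with planted enrichments, and an interaction network with
#' class-dependent expected degrees.
#'
#' @param seed integer root seed; each stage derives its own stream from
#'   it, so adding a stage does not shift the others.
#' @param universe_size gene-universe size (default 22000).
#' @param list_specs `data.frame` with columns `set_id`, `size`,
#'   `category`, `species`.
#' @param overlap_targets list of `list(sets = c(id, id, ...), count = n)`
#'   entries: `count` genes are allocated to exactly that combination of
#'   sets. When only pairs are given, every specified pairwise overlap is
#'   hit exactly.
#' @param module_spec list: `n_modules`, `genes_per_module`,
#'   `n_background`, `n_samples_per_group`, `n_assoc` (modules whose
#'   eigengene differs between groups), `eigengene_shift` (standardized
#'   group difference), `noise_sd`.
#' @param pathway_spec list: `n_pathways`, `size_range`, and `planted` — a
#'   `data.frame` with columns `set_id`, `n_planted`, `overlap_fraction`.
#' @param network_spec list: `mean_degree` — named numeric expected degree
#'   per node class (`human_only`, `rodent_only`, `both`, `background`) —
#'   and `n_background` nodes.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(
    seed = 1,
    universe_size = 22000,
    list_specs = default_list_specs(),
    overlap_targets = default_overlap_targets(),
    module_spec = list(n_modules = 3, genes_per_module = 25,
                       n_background = 150, n_samples_per_group = 6,
                       n_assoc = 1, eigengene_shift = 3, noise_sd = 0.5),
    pathway_spec = list(n_pathways = 50, size_range = c(20, 120),
                        planted = data.frame(
                          set_id = "GWAS_Child", n_planted = 3,
                          overlap_fraction = 0.4)),
    network_spec = list(mean_degree = c(human_only = 12, rodent_only = 4,
                                        both = 12, background = 3),
                        n_background = 160)) {
  stopifnot(universe_size >= 1, all(list_specs$size >= 1))
  for (ot in overlap_targets) {
    stopifnot(length(ot$sets) >= 2L, ot$count >= 0)
    sz <- list_specs$size[match(ot$sets, list_specs$set_id)]
    if (any(is.na(sz))) stop("overlap target names unknown set",
                             call. = FALSE)
    if (ot$count > min(sz)) {
      stop("overlap target ", ot$count, " exceeds the smallest list (",
           min(sz), ") among: ", paste(ot$sets, collapse = ", "),
           call. = FALSE)
    }
  }
  per_set <- vapply(list_specs$set_id, function(id) {
    sum(vapply(overlap_targets, function(ot) {
      if (id %in% ot$sets) ot$count else 0
    }, numeric(1)))
  }, numeric(1))
  if (any(per_set > list_specs$size)) {
    stop("infeasible overlap system: allocated shared genes exceed list ",
         "size for: ",
         paste(list_specs$set_id[per_set > list_specs$size],
               collapse = ", "), call. = FALSE)
  }
  if (universe_size < sum(list_specs$size)) {
    stop("universe smaller than the total list allocation", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), universe_size = universe_size,
                 list_specs = list_specs,
                 overlap_targets = overlap_targets,
                 module_spec = module_spec, pathway_spec = pathway_spec,
                 network_spec = network_spec),
            class = "simulation_config")
}

#' Default gene-list geometry (sizes of the nine study lists)
#' @return `data.frame` with `set_id`, `size`, `category`, `species`.
#' @export
default_list_specs <- function() {
  data.frame(
    set_id = c("GWAS_Adult", "GWAS_Child", "KO_Mice", "Mice_Finland",
               "Mice_Holland", "Mice_USA", "OMIM", "Rat", "GWAS_Control"),
    size = c(175L, 281L, 89L, 381L, 271L, 397L, 85L, 211L, 172L),
    category = c("gwas", "gwas", "highrisk", "transcriptome",
                 "transcriptome", "transcriptome", "highrisk",
                 "transcriptome", "control"),
    species = c("human", "human", "mouse", "mouse", "mouse", "mouse",
                "human", "rat", "human"),
    stringsAsFactors = FALSE)
}

#' Default pairwise overlap targets (the published overlap counts)
#' @return list of `list(sets, count)` entries.
#' @export
default_overlap_targets <- function() {
  tab <- list(
    c("GWAS_Adult", "GWAS_Child", 6), c("GWAS_Adult", "KO_Mice", 1),
    c("GWAS_Child", "KO_Mice", 4), c("GWAS_Adult", "Mice_Finland", 1),
    c("GWAS_Child", "Mice_Finland", 6), c("KO_Mice", "Mice_Finland", 6),
    c("GWAS_Adult", "Mice_Holland", 2), c("GWAS_Child", "Mice_Holland", 2),
    c("KO_Mice", "Mice_Holland", 1), c("Mice_Finland", "Mice_Holland", 13),
    c("GWAS_Adult", "Mice_USA", 3), c("GWAS_Child", "Mice_USA", 11),
    c("KO_Mice", "Mice_USA", 4), c("Mice_Finland", "Mice_USA", 11),
    c("Mice_Holland", "Mice_USA", 12), c("GWAS_Adult", "OMIM", 1),
    c("GWAS_Child", "OMIM", 3), c("KO_Mice", "OMIM", 4),
    c("Mice_Finland", "OMIM", 3), c("Mice_Holland", "OMIM", 1),
    c("Mice_USA", "OMIM", 1), c("GWAS_Adult", "Rat", 1),
    c("GWAS_Child", "Rat", 4), c("KO_Mice", "Rat", 6),
    c("Mice_Finland", "Rat", 5), c("Mice_Holland", "Rat", 5),
    c("Mice_USA", "Rat", 10), c("OMIM", "Rat", 3),
    c("GWAS_Adult", "GWAS_Control", 1), c("GWAS_Child", "GWAS_Control", 1),
    c("KO_Mice", "GWAS_Control", 2), c("Mice_Finland", "GWAS_Control", 1),
    c("Mice_Holland", "GWAS_Control", 4), c("Mice_USA", "GWAS_Control", 2),
    c("OMIM", "GWAS_Control", 1), c("Rat", "GWAS_Control", 2))
  lapply(tab, function(x) list(sets = x[1:2], count = as.integer(x[3])))
}

# Per-stage seed streams derived from the root seed (kept below 2^31).
stage_seed <- function(cfg, stage) {
  offsets <- c(lists = 101L, expression = 202L, pathways = 303L,
               network = 404L)
  (cfg$seed %% 1000000L) * 1000L + offsets[[stage]]
}

#' Simulate the evidence gene lists with exact pairwise overlaps
#'
#' Genes shared by a specified set combination are allocated first
#' (constructively, so every requested overlap is hit exactly), then each
#' list is filled to size with genes unique to it, all drawn from the
#' synthetic universe `G00001..GNNNNN`.
#'
#' @param cfg a [simulation_config()].
#' @return named list of `gene_set` objects; the universe symbols are
#'   attached as attribute `universe`.
#' @export
simulate_gene_lists <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(stage_seed(cfg, "lists"))
  universe <- sprintf("G%05d", seq_len(cfg$universe_size))
  pool <- sample(universe)
  take <- function(n) {
    if (n > length(pool)) stop("universe exhausted", call. = FALSE)
    got <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    got
  }
  specs <- cfg$list_specs
  members <- stats::setNames(vector("list", nrow(specs)), specs$set_id)
  for (ot in cfg$overlap_targets) {
    shared <- take(ot$count)
    for (id in ot$sets) members[[id]] <- c(members[[id]], shared)
  }
  for (i in seq_len(nrow(specs))) {
    id <- specs$set_id[i]
    fill <- specs$size[i] - length(members[[id]])
    members[[id]] <- c(members[[id]], take(fill))
  }
  out <- lapply(seq_len(nrow(specs)), function(i) {
    gene_set(members[[specs$set_id[i]]], set_id = specs$set_id[i],
             category = specs$category[i], species = "human",
             source_species = specs$species[i], provenance = "synthetic")
  })
  names(out) <- specs$set_id
  attr(out, "universe") <- universe
  out
}

#' Simulate a two-group expression matrix with planted modules
#'
#' Each planted module m has a per-sample eigengene; genes of the module
#' are `eigengene_m + Normal(0, noise_sd)`. For the first `n_assoc`
#' modules the eigengene mean differs between the high and low groups by
#' `eigengene_shift` standard deviations; the remaining modules and all
#' background genes carry no group signal.
#'
#' @param cfg a [simulation_config()].
#' @return list with `expr` (genes x samples matrix), `metadata`
#'   (`sample`, `group`), and `truth` (list: `module_members`,
#'   `associated_modules`).
#' @export
simulate_expression <- function(cfg) {
  ms <- cfg$module_spec
  if (ms$n_samples_per_group < 2L) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  set.seed(stage_seed(cfg, "expression"))
  n_s <- 2L * ms$n_samples_per_group
  group <- rep(c("high", "low"), each = ms$n_samples_per_group)
  samples <- sprintf("S%02d", seq_len(n_s))
  genes_mod <- lapply(seq_len(ms$n_modules), function(m) {
    sprintf("MOD%d_G%03d", m, seq_len(ms$genes_per_module))
  })
  bg <- sprintf("BG_G%04d", seq_len(ms$n_background))
  expr <- matrix(NA_real_, nrow = ms$n_modules * ms$genes_per_module +
                   ms$n_background, ncol = n_s,
                 dimnames = list(c(unlist(genes_mod), bg), samples))
  assoc <- seq_len(min(ms$n_assoc, ms$n_modules))
  for (m in seq_len(ms$n_modules)) {
    e <- stats::rnorm(n_s)
    if (m %in% assoc) e <- e + ms$eigengene_shift * (group == "high")
    for (g in genes_mod[[m]]) {
      expr[g, ] <- e + stats::rnorm(n_s, sd = ms$noise_sd)
    }
  }
  expr[bg, ] <- matrix(stats::rnorm(length(bg) * n_s), ncol = n_s)
  list(expr = expr,
       metadata = data.frame(sample = samples, group = group,
                             stringsAsFactors = FALSE),
       truth = list(module_members = genes_mod,
                    associated_modules = assoc))
}

#' Simulate a pathway collection with planted enrichments
#'
#' Planted pathways draw the requested fraction of their members from the
#' named gene set; all other members, and all non-planted pathways, are
#' drawn uniformly from the universe.
#'
#' @param cfg a [simulation_config()].
#' @param gene_sets output of [simulate_gene_lists()] (carries the
#'   universe).
#' @return list with `pathways` (a `pathway_collection`) and `truth`
#'   (`data.frame`: pathway, planted_for, n_from_set).
#' @export
simulate_pathways <- function(cfg, gene_sets) {
  ps <- cfg$pathway_spec
  universe <- attr(gene_sets, "universe")
  stopifnot(!is.null(universe), max(ps$size_range) <= length(universe))
  planted <- ps$planted
  if (!is.null(planted) && any(planted$overlap_fraction > 1 |
                               planted$overlap_fraction < 0)) {
    stop("overlap_fraction must be in [0, 1]", call. = FALSE)
  }
  set.seed(stage_seed(cfg, "pathways"))
  draw_size <- function() {
    sizes <- ps$size_range[1]:ps$size_range[2]
    if (length(sizes) == 1L) sizes else sample(sizes, 1L)
  }
  n_planted_total <- if (is.null(planted)) 0L else sum(planted$n_planted)
  stopifnot(n_planted_total <= ps$n_pathways)
  pw <- vector("list", ps$n_pathways)
  truth <- data.frame(pathway = sprintf("PW%03d", seq_len(ps$n_pathways)),
                      planted_for = NA_character_, n_from_set = 0L,
                      stringsAsFactors = FALSE)
  idx <- 1L
  if (n_planted_total > 0L) {
    for (r in seq_len(nrow(planted))) {
      gs <- gene_sets[[planted$set_id[r]]]
      if (is.null(gs)) stop("planted set_id not simulated: ",
                            planted$set_id[r], call. = FALSE)
      for (j in seq_len(planted$n_planted[r])) {
        size <- draw_size()
        n_in <- round(planted$overlap_fraction[r] * size)
        n_in <- min(n_in, length(gs))
        inside <- sample(gs$symbols, n_in)
        outside <- sample(setdiff(universe, gs$symbols), size - n_in)
        pw[[idx]] <- c(inside, outside)
        truth$planted_for[idx] <- gs$set_id
        truth$n_from_set[idx] <- as.integer(n_in)
        idx <- idx + 1L
      }
    }
  }
  while (idx <= ps$n_pathways) {
    size <- draw_size()
    pw[[idx]] <- sample(universe, size)
    idx <- idx + 1L
  }
  names(pw) <- truth$pathway
  list(pathways = pathway_collection(pw, "synthetic"), truth = truth)
}

#' Simulate an interaction network with class-dependent degrees
#'
#' A configured-degree (Chung-Lu) random graph: nodes carry target
#' expected degrees from their class, and each pair (i, j) is connected
#' independently with probability `min(1, w_i w_j / sum(w))`, so the
#' expected degree of node i is close to `w_i`.
#'
#' @param cfg a [simulation_config()].
#' @param node_classes named character vector assigning each focus node to
#'   `human_only`, `rodent_only` or `both`; background nodes are appended
#'   per `network_spec$n_background`.
#' @return an undirected simple [igraph::igraph] with a `class` vertex
#'   attribute.
#' @export
simulate_network <- function(cfg, node_classes) {
  ns <- cfg$network_spec
  if (any(ns$mean_degree < 0)) stop("degree parameters must be >= 0",
                                    call. = FALSE)
  stopifnot(all(node_classes %in% names(ns$mean_degree)))
  set.seed(stage_seed(cfg, "network"))
  bg <- stats::setNames(rep("background", ns$n_background),
                        sprintf("BGN%04d", seq_len(ns$n_background)))
  cls <- c(node_classes, bg)
  w <- ns$mean_degree[cls]
  n <- length(cls)
  prob <- outer(w, w) / sum(w)
  prob[prob > 1] <- 1
  up <- upper.tri(prob)
  draw <- matrix(FALSE, n, n)
  draw[up] <- stats::runif(sum(up)) < prob[up]
  g <- igraph::graph_from_adjacency_matrix(
    draw | t(draw), mode = "undirected", diag = FALSE)
  igraph::V(g)$name <- names(cls)
  igraph::V(g)$class <- unname(cls)
  g
}
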