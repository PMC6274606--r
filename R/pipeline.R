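PIPELINE_DEFAULTS <- list(
  seed = 1,
  universe = 22000,
  alpha = 0.05,
  weights = list(gwas = 1, transcriptome = 0.5, highrisk = 1.5),
  bh_threshold = 0.05,
  score_threshold = 2,
  min_sets = 3,
  mds_dims = 4,
  n_boot = 1000,
  stages = list(coexpression = FALSE, overlap = TRUE, rank = TRUE,
                enrich = TRUE, mds = TRUE, network = TRUE),
  inputs = list(gene_lists = NULL, gmt = NULL, edges = NULL,
                expression = NULL, metadata = NULL, orthologs = NULL),
  simulate = TRUE
)

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML or JSON configuration file (or accepts a list directly),
#' fills defaults (universe 22000, alpha 0.05, ranking weights 1/0.5/1.5,
#' BH threshold 0.05, MDS dimensions 4) and rejects unknown keys, so that
#' every analysis constant is explicit and auditable in the run report.
#'
#' @param config path to a `.yaml`/`.yml`/`.json` file, or a named list.
#' @return the normalized configuration list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(PIPELINE_DEFAULTS))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, config)
  errs <- character(0)
  if (!is.numeric(cfg$universe) || cfg$universe <= 0) {
    errs <- c(errs, "universe must be a positive number")
  }
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    errs <- c(errs, "alpha must be in (0, 1)")
  }
  if (!all(c("gwas", "transcriptome", "highrisk") %in%
           names(cfg$weights))) {
    errs <- c(errs, "weights must name gwas, transcriptome, highrisk")
  }
  if (!is.numeric(cfg$bh_threshold) || cfg$bh_threshold <= 0) {
    errs <- c(errs, "bh_threshold must be positive")
  }
  if (!is.numeric(cfg$mds_dims) || cfg$mds_dims < 1) {
    errs <- c(errs, "mds_dims must be >= 1")
  }
  if (length(errs) > 0L) {
    stop("configuration errors:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  cfg
}

#' Run the integration pipeline end to end
#'
#' Executes the stages in order — ingest (or simulate), optional
#' co-expression, overlap testing, weighted ranking, pathway enrichment,
#' profile MDS, optional network degree comparison — writing every stage
#' output as TSV under `output_dir` and returning a machine-readable run
#' report. Deterministic given the configured seed.
#'
#' @param config a configuration (path or list), see [validate_config()].
#' @param output_dir directory for stage outputs (created if needed).
#' @return a `run_report` list: config echo, per-stage output files with
#'   MD5 digests, counts, and accumulated warnings.
#' @export
run_pipeline <- function(config = list(), output_dir = tempfile("aggr_")) {
  cfg <- validate_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = cfg, stages = list(), counts = list(),
                 warnings = character(0))
  note <- function(w) report$warnings <<- c(report$warnings, w)
  emit <- function(stage, file) {
    report$stages[[stage]] <<-
      c(report$stages[[stage]],
        stats::setNames(unname(tools::md5sum(file)), basename(file)))
  }

  # -- ingest or simulate ---------------------------------------------
  sim_cfg <- simulation_config(seed = cfg$seed,
                               universe_size = cfg$universe)
  if (cfg$simulate) {
    sets <- simulate_gene_lists(sim_cfg)
  } else {
    gl <- cfg$inputs$gene_lists
    if (is.null(gl)) stop("stage 'ingest': inputs$gene_lists required ",
                          "when simulate = FALSE", call. = FALSE)
    sets <- lapply(seq_len(nrow(gl)), function(i) {
      withCallingHandlers(
        read_gene_list(gl$path[i], gl$set_id[i], gl$category[i],
                       gl$species[i]),
        message = function(m) { note(conditionMessage(m))
          invokeRestart("muffleMessage") })
    })
    names(sets) <- gl$set_id
    if (!is.null(cfg$inputs$orthologs)) {
      tab <- read_ortholog_table(cfg$inputs$orthologs)
      sets <- lapply(sets, function(s) {
        if (s$species == "human") s else map_orthologs(s, tab)
      })
    }
  }
  report$counts$lists_loaded <- length(sets)

  # -- optional co-expression stage -----------------------------------
  if (isTRUE(cfg$stages$coexpression)) {
    sim <- simulate_expression(sim_cfg)
    expr <- sim$expr; meta <- sim$metadata
    if (!cfg$simulate) {
      if (is.null(cfg$inputs$expression) || is.null(cfg$inputs$metadata)) {
        stop("stage 'coexpression': inputs$expression and inputs$metadata ",
             "required when simulate = FALSE", call. = FALSE)
      }
      expr <- as.matrix(utils::read.delim(cfg$inputs$expression,
                                          row.names = 1L))
      meta <- utils::read.delim(cfg$inputs$metadata,
                                stringsAsFactors = FALSE)
    }
    power <- suppressWarnings(pick_soft_power(expr))
    mods <- detect_modules(expr, power)
    mods <- associate_modules(mods, expr, meta)
    stats_df <- data.frame(
      module_id = vapply(mods, `[[`, character(1), "module_id"),
      n_genes = vapply(mods, function(m) length(m$members), integer(1)),
      explained_variance = vapply(mods, `[[`, numeric(1),
                                  "explained_variance"),
      assoc_p = vapply(mods, `[[`, numeric(1), "assoc_p"),
      assoc_p_bh = vapply(mods, `[[`, numeric(1), "assoc_p_bh"),
      direction = vapply(mods, `[[`, character(1), "direction"))
    f <- file.path(output_dir, "module_stats.tsv")
    write_table(stats_df, f, sort_by = "module_id"); emit("coexpression", f)
    report$counts$modules_selected <-
      sum(stats_df$assoc_p_bh < cfg$bh_threshold)
  }

  # -- overlap --------------------------------------------------------
  if (isTRUE(cfg$stages$overlap)) {
    om <- overlap_matrix(sets, universe = cfg$universe, alpha = cfg$alpha)
    f <- file.path(output_dir, "overlap_pairs.tsv")
    write_table(om, f); emit("overlap", f)
    aggr_sets <- Filter(function(s) s$category != "control", sets)
    mc <- merge_categories(aggr_sets, universe = cfg$universe)
    f <- file.path(output_dir, "category_overlap.tsv")
    write_table(mc$pairwise, f); emit("overlap", f)
    report$counts$pairs_tested <- nrow(om)
  }

  # -- ranking --------------------------------------------------------
  ranked <- NULL
  if (isTRUE(cfg$stages$rank)) {
    occ <- suppressWarnings(count_occurrences(sets))
    ranked <- weighted_rank(occ, weights = unlist(cfg$weights))
    f <- file.path(output_dir, "gene_ranking.tsv")
    write_table(ranked, f); emit("rank", f)
    top <- top_genes(ranked, cfg$score_threshold)
    f <- file.path(output_dir, "top_genes.tsv")
    write_table(top, f, allow_empty = TRUE); emit("rank", f)
    report$counts$genes_ranked <- nrow(ranked)
    report$counts$top_genes <- nrow(top)
  }

  # -- enrichment + MDS -----------------------------------------------
  if (isTRUE(cfg$stages$enrich)) {
    if (cfg$simulate) {
      pwsim <- simulate_pathways(sim_cfg, sets)
      pc <- pwsim$pathways
    } else {
      if (is.null(cfg$inputs$gmt)) {
        stop("stage 'enrich': inputs$gmt required when simulate = FALSE",
             call. = FALSE)
      }
      pc <- read_gmt(cfg$inputs$gmt)
    }
    aggr_sets <- Filter(function(s) s$category != "control", sets)
    profiles <- lapply(aggr_sets, enrich_set, pathways = pc,
                       universe = cfg$universe, alpha = cfg$alpha)
    B <- profile_matrix(profiles, "binary")
    f <- file.path(output_dir, "enrichment_binary.tsv")
    write_table(data.frame(set_id = rownames(B), B,
                           check.names = FALSE), f); emit("enrich", f)
    shared <- shared_pathways(profiles, min_sets = cfg$min_sets)
    f <- file.path(output_dir, "shared_pathways.tsv")
    write_table(shared, f, allow_empty = TRUE); emit("enrich", f)
    report$counts$pathways_flagged <- sum(colSums(B) > 0)

    if (isTRUE(cfg$stages$mds)) {
      D <- rogers_tanimoto_matrix(B)
      res <- suppressMessages(classical_mds(D, n_dims = cfg$mds_dims))
      f <- file.path(output_dir, "mds_coordinates.tsv")
      write_table(data.frame(set_id = rownames(res$points), res$points),
                  f); emit("mds", f)
      f <- file.path(output_dir, "mds_variance.tsv")
      write_table(mds_report(res), f); emit("mds", f)
    }
  }

  # -- network degree -------------------------------------------------
  if (isTRUE(cfg$stages$network) && !is.null(ranked)) {
    top <- top_genes(ranked, cfg$score_threshold)
    if (nrow(top) >= 6L) {
      classes <- classify_evidence(top)
      if (cfg$simulate) {
        g <- simulate_network(sim_cfg,
                              stats::setNames(as.character(classes),
                                              names(classes)))
      } else {
        if (is.null(cfg$inputs$edges)) {
          stop("stage 'network': inputs$edges required when simulate = ",
               "FALSE", call. = FALSE)
        }
        g <- read_edge_list(cfg$inputs$edges)
      }
      deg <- withCallingHandlers(
        degrees(g, names(classes)),
        message = function(m) { note(conditionMessage(m))
          invokeRestart("muffleMessage") })
      cmp <- tryCatch(
        median_regression_logdeg(deg, classes,
                                 contrast = c("human_only", "rodent_only"),
                                 n_boot = cfg$n_boot, seed = cfg$seed),
        error = function(e) { note(conditionMessage(e)); NULL })
      if (!is.null(cmp)) {
        f <- file.path(output_dir, "degree_by_gene.tsv")
        write_table(cmp$data, f, sort_by = "symbol"); emit("network", f)
        f <- file.path(output_dir, "degree_contrast.tsv")
        write_table(data.frame(class_a = cmp$contrast[1L],
                               class_b = cmp$contrast[2L],
                               n_a = cmp$n_per_class[1L],
                               n_b = cmp$n_per_class[2L],
                               slope = cmp$slope, p_value = cmp$p_value,
                               n_boot = cmp$n_boot), f)
        emit("network", f)
      }
    } else {
      note("network stage skipped: fewer than 6 top-ranked genes")
    }
  }

  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n  stages run:",
      paste(names(x$stages), collapse = ", "), "\n  counts:\n")
  for (nm in names(x$counts)) {
    cat(sprintf("    %s: %s\n", nm, x$counts[[nm]]))
  }
  if (length(x$warnings) > 0L) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("    -", trimws(w), "\n")
  }
  invisible(x)
}
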