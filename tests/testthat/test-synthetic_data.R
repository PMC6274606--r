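test_that("simulate_gene_lists hits requested sizes and pairwise overlaps exactly", {
  cfg <- simulation_config(seed = 5)
  sets <- simulate_gene_lists(cfg)
  sizes <- vapply(sets, length, integer(1))
  expect_identical(unname(sizes), cfg$list_specs$size)
  # every configured pairwise overlap is exact (pair-only allocations)
  for (ot in cfg$overlap_targets) {
    k <- length(intersect(sets[[ot$sets[1]]]$symbols,
                          sets[[ot$sets[2]]]$symbols))
    expect_identical(k, as.integer(ot$count))
  }
  # unspecified pairs are disjoint by construction under default targets
  expect_identical(
    length(intersect(sets$GWAS_Adult$symbols, sets$KO_Mice$symbols)), 1L)
})

test_that("simulate_gene_lists supports disjoint lists, custom overlaps and rejects infeasible ones", {
  specs <- data.frame(set_id = c("A", "B"), size = c(175L, 281L),
                      category = c("gwas", "gwas"),
                      species = c("human", "human"))
  cfg <- simulation_config(seed = 2, universe_size = 22000,
                           list_specs = specs,
                           overlap_targets = list(
                             list(sets = c("A", "B"), count = 6L)))
  sets <- simulate_gene_lists(cfg)
  expect_identical(length(intersect(sets$A$symbols, sets$B$symbols)), 6L)

  cfg0 <- simulation_config(seed = 2, universe_size = 22000,
                            list_specs = specs, overlap_targets = list())
  s0 <- simulate_gene_lists(cfg0)
  expect_identical(length(intersect(s0$A$symbols, s0$B$symbols)), 0L)

  expect_error(
    simulation_config(seed = 2, universe_size = 22000, list_specs = specs,
                      overlap_targets = list(
                        list(sets = c("A", "B"), count = 300L))),
    "exceeds the smallest list")
})

test_that("identical seed and config give byte-identical synthetic outputs", {
  cfg <- simulation_config(seed = 9)
  expect_identical(simulate_gene_lists(cfg), simulate_gene_lists(cfg))
  expect_identical(simulate_expression(cfg), simulate_expression(cfg))
  s <- simulate_gene_lists(cfg)
  expect_identical(simulate_pathways(cfg, s), simulate_pathways(cfg, s))
  cls <- c(A = "human_only", B = "rodent_only", C = "both")
  g1 <- simulate_network(cfg, cls); g2 <- simulate_network(cfg, cls)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  # a different seed perturbs the draw
  expect_false(identical(
    simulate_gene_lists(cfg),
    simulate_gene_lists(simulation_config(seed = 10))))
})

test_that("simulate_expression plants recoverable modules and validates inputs", {
  cfg <- simulation_config(seed = 31)
  sim <- simulate_expression(cfg)
  ms <- cfg$module_spec
  expect_equal(dim(sim$expr),
               c(ms$n_modules * ms$genes_per_module + ms$n_background,
                 2 * ms$n_samples_per_group))
  # noise_sd -> 0: within-module correlations -> 1
  cfg0 <- simulation_config(seed = 31, module_spec = modifyList(
    cfg$module_spec, list(noise_sd = 1e-8)))
  sim0 <- simulate_expression(cfg0)
  block <- sim0$expr[sim0$truth$module_members[[1]], ]
  expect_true(all(cor(t(block)) > 0.999999))
  # planted associated module recovered end to end (shift 3, noise 0.5)
  mods <- detect_modules(sim$expr, power = 6, min_module_size = 20)
  mods <- associate_modules(mods, sim$expr, sim$metadata)
  truth <- sim$truth$module_members[[sim$truth$associated_modules[1]]]
  jac <- vapply(mods, function(mo) {
    length(intersect(mo$members, truth)) /
      length(union(mo$members, truth))
  }, numeric(1))
  hit <- which.max(jac)
  expect_gte(jac[hit], 0.9)
  expect_lt(mods[[hit]]$assoc_p_bh, 0.05)

  expect_error(simulate_expression(simulation_config(
    seed = 1, module_spec = modifyList(cfg$module_spec,
                                       list(n_samples_per_group = 1)))),
    "2 samples")
})

test_that("simulate_pathways plants set-enriched pathways and draws the rest uniformly", {
  cfg <- simulation_config(seed = 13)
  sets <- simulate_gene_lists(cfg)
  sim <- simulate_pathways(cfg, sets)
  expect_length(sim$pathways, cfg$pathway_spec$n_pathways)
  planted <- sim$truth[!is.na(sim$truth$planted_for), ]
  expect_identical(nrow(planted), 3L)
  for (i in seq_len(nrow(planted))) {
    pw <- sim$pathways[[planted$pathway[i]]]
    gs <- sets[[planted$planted_for[i]]]
    expect_identical(length(intersect(pw, gs$symbols)),
                     planted$n_from_set[i])
    expect_identical(planted$n_from_set[i],
                     as.integer(round(0.4 * length(pw))))
  }
  # fraction 1.0 with matching sizes gives complete overlap
  cfg1 <- simulation_config(seed = 13, pathway_spec = list(
    n_pathways = 5, size_range = c(10, 10),
    planted = data.frame(set_id = "OMIM", n_planted = 1,
                         overlap_fraction = 1.0)))
  sim1 <- simulate_pathways(cfg1, sets)
  pw1 <- sim1$pathways[[sim1$truth$pathway[1]]]
  expect_identical(length(intersect(pw1, sets$OMIM$symbols)), 10L)

  # fraction 0: mean overlap over many draws near size_set*size_pw/universe
  cfg0 <- simulation_config(seed = 17, pathway_spec = list(
    n_pathways = 500, size_range = c(60, 60), planted = NULL))
  sim0 <- simulate_pathways(cfg0, sets)
  ov <- vapply(sim0$pathways, function(pw) {
    length(intersect(pw, sets$GWAS_Child$symbols))
  }, integer(1))
  expected <- 281 * 60 / 22000
  expect_lt(abs(mean(ov) - expected), 4 * sd(ov) / sqrt(500))

  expect_error(simulate_pathways(simulation_config(
    seed = 1, pathway_spec = list(n_pathways = 5, size_range = c(10, 10),
                                  planted = data.frame(
                                    set_id = "OMIM", n_planted = 1,
                                    overlap_fraction = 1.5))), sets),
    "overlap_fraction")
})

test_that("planted pathways rank first by enrichment in the profile", {
  cfg <- simulation_config(seed = 23)
  sets <- simulate_gene_lists(cfg)
  sim <- simulate_pathways(cfg, sets)
  prof <- enrich_set(sets$GWAS_Child, sim$pathways, universe = 22000)
  planted <- sim$truth$pathway[!is.na(sim$truth$planted_for)]
  top3 <- prof$pathway[order(-prof$neg_log10_p)][1:3]
  expect_setequal(top3, planted)
})

test_that("simulate_network respects class degree parameters and the handshake lemma", {
  cfg <- simulation_config(seed = 41)
  cls <- c(setNames(rep("human_only", 15), sprintf("HU%02d", 1:15)),
           setNames(rep("rodent_only", 15), sprintf("RO%02d", 1:15)),
           setNames(rep("both", 10), sprintf("BO%02d", 1:10)))
  g <- simulate_network(cfg, cls)
  expect_identical(sum(igraph::degree(g)), 2L * igraph::ecount(g))
  deg <- igraph::degree(g)
  expect_gt(mean(deg[names(cls)[cls == "human_only"]]),
            mean(deg[names(cls)[cls == "rodent_only"]]))

  # equal parameters: median log-degree difference near 0
  cfg_eq <- simulation_config(seed = 41, network_spec = list(
    mean_degree = c(human_only = 8, rodent_only = 8, both = 8,
                    background = 8), n_background = 160))
  geq <- simulate_network(cfg_eq, cls)
  dq <- igraph::degree(geq)
  d_hu <- dq[names(cls)[cls == "human_only"]]
  d_ro <- dq[names(cls)[cls == "rodent_only"]]
  expect_lt(abs(median(log10(d_hu[d_hu > 0])) -
                  median(log10(d_ro[d_ro > 0]))), 0.15)

  expect_error(simulate_network(simulation_config(
    seed = 1, network_spec = list(mean_degree = c(human_only = -1,
                                                  rodent_only = 4,
                                                  both = 4,
                                                  background = 3),
                                  n_background = 10)), cls),
    ">= 0")
})
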