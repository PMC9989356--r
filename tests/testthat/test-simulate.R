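test_that("without duplication or loss the gene tree mirrors the species tree", {
  cfg <- simulation_config(n0 = 1, lambda = 0, mu = 0, seed = 3)
  sim <- simulate_gene_tree(cfg)
  expect_equal(length(sim$tree$tip.label), 8)
  expect_setequal(tip_species(sim$tree$tip.label),
                  cnidarian_species_tree()$tip.label)
  expect_equal(sim$truth$dual_survivors, 1)
  expect_equal(sim$truth$focal_gene_count, 1)
  # topology congruent with the species tree
  st <- cnidarian_species_tree()
  gt <- sim$tree
  gt$tip.label <- tip_species(gt$tip.label)
  expect_equal(ape::dist.topo(ape::unroot(gt), ape::unroot(st)), 0,
               ignore_attr = TRUE)
  # n0 = 4: four congruent families, all recovered with perfect supports
  cfg4 <- simulation_config(n0 = 4, lambda = 0, mu = 0, seed = 4)
  sim4 <- simulate_gene_tree(cfg4)
  tr4 <- assign_supports(sim4$tree, cfg4, perfect = TRUE)
  expect_equal(count_ancestral(find_ancestral_groups(tr4, cnid_lmap)), 4)
  expect_equal(sim4$truth$dual_survivors, 4)
})

test_that("simulation and support draws are deterministic under a seed", {
  cfg <- simulation_config(n0 = 3, lambda = 0.4, mu = 0.2, seed = 77)
  a <- simulate_gene_tree(cfg); b <- simulate_gene_tree(cfg)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$truth, b$truth)
  sa <- assign_supports(a$tree, cfg); sb <- assign_supports(b$tree, cfg)
  expect_identical(sa$node.label, sb$node.label)
})

test_that("truth bookkeeping is consistent with the emitted tips", {
  cfg <- simulation_config(n0 = 5, lambda = 0.3, mu = 0.2, seed = 19)
  sim <- simulate_gene_tree(cfg)
  pg <- sim$truth$per_gene
  expect_lte(sim$truth$dual_survivors, sim$truth$focal_gene_count)
  expect_equal(sum(pg$n_tips), length(sim$tree$tip.label))
  genes <- as.integer(sub("^g(\\d+)\\..*", "\\1", sim$tree$tip.label))
  expect_equal(as.vector(table(factor(genes, levels = 1:5))), pg$n_tips)
  # per-species totals at the tips match node counts at species-tree tips
  st <- cnidarian_species_tree()
  spp <- tip_species(sim$tree$tip.label)
  expect_equal(sim$truth$node_counts[seq_along(st$tip.label)],
               as.integer(table(factor(spp, levels = st$tip.label))))
})

test_that("weak supports can only hide, never add, ancestral groups", {
  found <- 0
  for (s in 1:40) {
    cfg <- simulation_config(n0 = 3, lambda = 0.2, mu = 0.1, seed = 100 + s,
                             weak_fraction = 1, weak_range = c(0.2, 0.9))
    sim <- simulate_gene_tree(cfg)
    if (is.null(sim$tree)) next
    tr <- assign_supports(sim$tree, cfg)
    n <- count_ancestral(find_ancestral_groups(tr, cnid_lmap))
    expect_lte(n, sim$truth$dual_survivors)
    found <- found + 1
  }
  expect_gte(found, 30)
})

test_that("beta support model concentrates near its mean and flags weak nodes", {
  cfg <- simulation_config(n0 = 10, lambda = 0.5, mu = 0, seed = 5,
                           support_mean = 0.985, support_conc = 80,
                           weak_fraction = 0.2, weak_range = c(0.5, 0.94))
  sim <- simulate_gene_tree(cfg)
  tr <- assign_supports(sim$tree, cfg)
  sup <- node_supports(tr)
  expect_true(all(sup >= 0 & sup <= 1))
  n_weak <- round(0.2 * tr$Nnode)
  expect_gte(sum(sup < 0.95), n_weak)
  expect_gt(mean(sup > 0.95), 0.5)
})

test_that("zero substitution emits template copies; divergence lowers scores", {
  cfg <- simulation_config(n0 = 2, lambda = 0.2, mu = 0, subst_prob = 0,
                           r_fraction = 0, seed = 8)
  sim <- simulate_gene_tree(cfg)
  em <- emit_sequences(sim$tree, cfg, templates, subfamily = "Elk")
  expect_true(all(em$sequences$residues == templates$Elk$sequence))
  # self-score against the template decreases with the substitution rate
  mean_score <- vapply(c(0, 0.05, 0.15, 0.3), function(p) {
    cfgp <- simulation_config(n0 = 2, lambda = 0.2, mu = 0, subst_prob = p,
                              r_fraction = 0, seed = 8)
    simp <- simulate_gene_tree(cfgp)
    emp <- emit_sequences(simp$tree, cfgp, templates, subfamily = "Elk")
    mean(local_score_matrix(emp$sequences$residues, templates$Elk$sequence))
  }, numeric(1))
  expect_true(all(diff(mean_score) < 0))
  # missing template is fatal
  expect_error(emit_sequences(sim$tree, cfg, templates["Shaker"],
                              subfamily = "Elk"), "missing template")
})

test_that("benchmark bundles are reproducible and internally consistent", {
  cfg <- simulation_config(n0 = 4, lambda = 0.3, mu = 0.1, seed = 55)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  suppressMessages(generate_benchmark_bundle(cfg, d1, force = TRUE))
  suppressMessages(generate_benchmark_bundle(cfg, d2, force = TRUE))
  expect_identical(readLines(file.path(d1, "truth.tsv")),
                   readLines(file.path(d2, "truth.tsv")))
  expect_error(generate_benchmark_bundle(cfg, d1), "force")
  # end-to-end: groups on the bundle tree recover the truth with the
  # bundle's own supports replaced by perfect ones
  phy <- read_tree(file.path(d1, "gene_tree.nwk"))
  node_supports(phy) <- rep(1, phy$Nnode)
  lmap <- read_lineage_map(file.path(d1, "lineage_map.tsv"))
  truth <- read.delim(file.path(d1, "truth.tsv"))
  expect_equal(count_ancestral(find_ancestral_groups(phy, lmap)),
               sum(truth$dual))
  mani <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(mani$dual_survivors, sum(truth$dual))
  expect_equal(mani$seed, 55)
})

test_that("engineered class losses prune exactly the targeted tips", {
  cfg <- simulation_config(n0 = 3, lambda = 0, mu = 0, seed = 2)
  sim <- simulate_gene_tree(cfg)
  pruned <- suppressMessages(
    engineer_class_loss(sim$tree, 2, "Hydrozoa", cnid_lmap))
  lost <- setdiff(sim$tree$tip.label, pruned$tip.label)
  expect_true(all(grepl("^g2\\.", lost)))
  expect_true(all(tip_species(lost) == "Hydra"))
  expect_equal(length(sim$tree$tip.label) - length(pruned$tip.label),
               sum(grepl("^g2\\.", sim$tree$tip.label) &
                     tip_species(sim$tree$tip.label) == "Hydra"))
})
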