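lmap <- cnid_lmap

mk_aln <- function(...) {
  seqs <- c(...)
  seq_set(id = names(seqs),
          species = sub("^.*\\|", "", names(seqs)),
          residues = unname(seqs), aligned = TRUE)
}

test_that("gate extraction slices 1-based inclusive columns", {
  aln <- mk_aln(`a1|Acropora` = "AAAAPVPVIVAAAAAAAAAA",
                `a2|Hydra`    = "AAAA------AAAAAAAAAA")
  expect_equal(extract_gate(aln, "a1|Acropora", c(5, 10)), "PVPVIV")
  expect_equal(nchar(extract_gate(aln, "a1|Acropora", c(5, 10))), 6)
  expect_equal(extract_gate(aln, "a2|Hydra", c(5, 10)), "------")
  expect_error(extract_gate(aln, "a1|Acropora", c(15, 21)), "out of bounds")
  expect_error(extract_gate(aln, "nope", c(1, 3)), "not in alignment")
})

test_that("alpha consensus is plurality with class admissibility", {
  aln <- mk_aln(`a1|Acropora` = "PVPVIV", `a2|Renilla` = "PVPVIV",
                `a3|Hydra` = "PVPIIV")
  cons <- build_consensus(aln, c("a1|Acropora", "a2|Renilla"), c(1, 6))
  expect_equal(cons$consensus, "PVPVIV")
  # round-trip: extracting the consensus row returns the consensus
  expect_equal(extract_gate(aln, "a1|Acropora", c(1, 6)), cons$consensus)
  # with the variant member, column 4 admits V and I's (shared) class
  cons3 <- build_consensus(aln, aln$id, c(1, 6))
  expect_equal(cons3$consensus, "PVPVIV")
  expect_true("hydrophobic" %in% cons3$admissible[[4]])
  v_call <- classify_gate("PVPIIV", cons3)
  expect_equal(v_call$class, "alpha_like")
  # permuting alpha ids leaves the consensus unchanged
  cons_perm <- build_consensus(aln, rev(aln$id), c(1, 6))
  expect_equal(cons_perm$consensus, cons3$consensus)
  expect_equal(cons_perm$admissible, cons3$admissible)
  # all-missing column is fatal
  gap <- mk_aln(`x1|Hydra` = "-VPVIV", `x2|Renilla` = "-VPVIV")
  expect_error(build_consensus(gap, gap$id, c(1, 6)), "entirely missing")
})

test_that("gate classification flags nonconservative and special positions", {
  aln <- mk_aln(`a1|Acropora` = "PVPVIV", `a2|Renilla` = "PVPVIV")
  cons <- build_consensus(aln, aln$id, c(1, 6))
  expect_equal(classify_gate("PVPVIV", cons)$class, "alpha_like")
  # charged residue replacing a structurally critical proline
  pe <- classify_gate("PVEVIV", cons)
  expect_equal(pe$class, "degenerate")
  expect_equal(pe$flags[3], "nonconservative")
  # conservative hydrophobic swap at a non-special column
  expect_equal(classify_gate("PVPLIV", cons)$class, "alpha_like")
  # glycine replacing proline: special-residue violation
  expect_equal(classify_gate("GVPVIV", cons)$class, "degenerate")
  # missing positions are never nonconservative
  mm <- classify_gate("--PVIV", cons)
  expect_equal(mm$flags[1:2], c("missing", "missing"))
  expect_equal(mm$class, "alpha_like")
  expect_equal(classify_gate("------", cons)$class, "missing_data")
  expect_error(classify_gate("PVPV", cons), "length")
})

test_that("conservation scheme must partition the 20 amino acids", {
  expect_error(conservation_scheme(classes = list(a = c("A", "V"))),
               "partition")
  sch <- conservation_scheme()
  expect_equal(aa_class("K", sch), "basic")
  expect_equal(aa_class("P", sch), "proline")
})

test_that("group ancestral calls follow the per-lineage degeneration rule", {
  aln <- mk_aln(`al1|Acropora` = "PVPVIV", `al2|Sanderia` = "PVPVIV",
                `r1|Acropora` = "PVEVIV", `r2|Sanderia` = "PVKVIV",
                `r3|Renilla` = "PVDVIV", `ok1|Hydra` = "PVPVIV",
                `miss|Rhopilema` = "------")
  cons <- build_consensus(aln, c("al1|Acropora", "al2|Sanderia"), c(1, 6))
  calls <- setNames(lapply(aln$id, function(i)
    classify_gate(extract_gate(aln, i, c(1, 6)), cons)), aln$id)
  # degenerate on both sides of the split -> ancestral
  expect_equal(group_ancestral_call(c("r1|Acropora", "r2|Sanderia"),
                                    calls, lmap), "ancestral_degenerate")
  # degenerate only in Anthozoa -> lineage restricted
  expect_equal(group_ancestral_call(c("r3|Renilla", "ok1|Hydra"),
                                    calls, lmap), "lineage_restricted")
  # all alpha-like
  expect_equal(group_ancestral_call(c("al1|Acropora", "ok1|Hydra"),
                                    calls, lmap), "alpha_like")
  # missing-data members are excluded, not counted as evidence
  expect_equal(group_ancestral_call(c("r3|Renilla", "miss|Rhopilema"),
                                    calls, lmap), "lineage_restricted")
  # adding an alpha-like member never demotes an ancestral call
  expect_equal(group_ancestral_call(c("r1|Acropora", "r2|Sanderia",
                                      "ok1|Hydra", "al1|Acropora"),
                                    calls, lmap), "ancestral_degenerate")
})

test_that("simulator-emitted R and alpha subunits are recovered exactly", {
  cfg <- simulation_config(n0 = 6, lambda = 0.3, mu = 0.1, subst_prob = 0,
                           r_fraction = 0.5, seed = 41)
  sim <- simulate_gene_tree(cfg)
  em <- emit_sequences(sim$tree, cfg, templates, subfamily = "Shaker")
  alphas <- em$labels$id[!em$labels$r_subunit]
  cons <- build_consensus(em$sequences, alphas, em$gate_cols)
  cls <- vapply(em$sequences$id, function(i)
    classify_gate(extract_gate(em$sequences, i, em$gate_cols), cons)$class,
    character(1))
  expect_true(all(cls[em$labels$r_subunit] == "degenerate"))
  expect_true(all(cls[!em$labels$r_subunit] == "alpha_like"))
})
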