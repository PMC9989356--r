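lmap <- cnid_lmap

test_that("minimal dual-lineage clades are found on worked examples", {
  # two well-supported anthozoan/medusozoan pairs -> two groups
  t1 <- ape::read.tree(text = paste0("((a1|Acropora:1,m1|Hydra:1)0.99:1,",
                                     "(a2|Renilla:1,m2|Sanderia:1)0.97:1);"))
  g <- find_ancestral_groups(t1, lmap)
  expect_equal(count_ancestral(g), 2)
  expect_setequal(g$members[[1]], c("a1|Acropora", "m1|Hydra"))
  expect_setequal(g$members[[2]], c("a2|Renilla", "m2|Sanderia"))

  # single-lineage tree -> no ancestral gene
  t2 <- ape::read.tree(text = paste0("((a1|Acropora:1,a2|Acropora:1)1.0:1,",
                                     "(a3|Renilla:1,a4|Exaiptasia:1)1.0:1);"))
  expect_equal(count_ancestral(find_ancestral_groups(t2, lmap)), 0)

  # weakly supported inner clade dissolves into the enclosing clade
  t3 <- ape::read.tree(text = paste0("(((a1|Acropora:1,m1|Hydra:1)0.90:1,",
                                     "m2|Sanderia:1)0.99:1,a2|Renilla:1);"))
  g3 <- find_ancestral_groups(t3, lmap)
  expect_equal(count_ancestral(g3), 1)
  expect_setequal(g3$members[[1]], c("a1|Acropora", "m1|Hydra", "m2|Sanderia"))
})

test_that("root counts as a fully supported clade; polytomies allowed", {
  star <- ape::read.tree(text = "(a|Acropora,b|Hydra,c|Renilla,d|Sanderia);")
  g <- find_ancestral_groups(star, lmap, assume_support = TRUE)
  expect_equal(count_ancestral(g), 1)
  expect_equal(g$n_members, 4L)
  single <- ape::read.tree(text = "(a|Acropora:1);")
  expect_equal(count_ancestral(find_ancestral_groups(single, lmap)), 0)
})

test_that("threshold policy: strictness, overrides and merges", {
  t1 <- ape::read.tree(text = paste0("((a1|Acropora:1,m1|Hydra:1)0.95:1,",
                                     "(a2|Renilla:1,m2|Sanderia:1)0.93:1);"))
  # inclusive >= 0.95 admits the 0.95 clade; strict > 0.95 does not
  gi <- find_ancestral_groups(t1, lmap)
  expect_equal(gi$support, 0.95)  # only the 0.95 clade is minimal+admissible
  gs <- find_ancestral_groups(t1, lmap,
                              threshold_policy(comparison = "strict"))
  expect_equal(count_ancestral(gs), 1)  # falls back to the root clade
  expect_equal(gs$n_members, 4L)
  # per-clade override at 0.93 rescues the second pair without a global drop
  pol <- threshold_policy(overrides = list(
    list(tips = c("a2|Renilla", "m2|Sanderia"), theta = 0.93)))
  go <- suppressMessages(find_ancestral_groups(t1, lmap, pol))
  expect_equal(count_ancestral(go), 2)
  # merge directive: evaluate only at the joint ancestor
  t2 <- ape::read.tree(text = paste0("(((a1|Acropora:1,m1|Hydra:1)1.0:1,",
                                     "(a2|Renilla:1,m2|Sanderia:1)1.0:1)1.0:1,",
                                     "x|Rhopilema:1);"))
  gm <- suppressMessages(find_ancestral_groups(t2, lmap, threshold_policy(
    merges = list(c("a1|Acropora", "m1|Hydra", "a2|Renilla", "m2|Sanderia")))))
  expect_equal(count_ancestral(gm), 1)
  expect_equal(gm$n_members, 4L)
})

test_that("unannotated nodes fail the threshold unless configured to pass", {
  t1 <- ape::read.tree(text = "((a1|Acropora:1,m1|Hydra:1):1,a2|Renilla:1)1;")
  # inner node unannotated -> only root qualifies
  g <- find_ancestral_groups(t1, lmap)
  expect_equal(g$n_members, 3L)
  g2 <- find_ancestral_groups(t1, lmap, threshold_policy(unannotated = "pass"))
  expect_equal(g2$n_members, 2L)
  bare <- ape::read.tree(text = "((a|Acropora,b|Hydra),(c|Renilla,d|Sanderia));")
  expect_error(find_ancestral_groups(bare, lmap), "assume_support")
})

test_that("rooting by outgroup preserves bipartition supports", {
  set.seed(17)
  for (rep in 1:100) {
    phy <- ape::unroot(random_lineage_tree(10))
    og <- sample(phy$tip.label, 1)
    before <- .split_support_map(phy)
    rooted <- root_by_outgroup(phy, og)
    after <- .split_support_map(rooted)
    expect_true(ape::is.rooted(rooted))
    for (k in names(before)) expect_equal(after[[k]], before[[k]])
  }
  expect_error(root_by_outgroup(
    ape::read.tree(text = "((a,b),(c,d));"), c("a", "c")), "one side")
  four <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  r <- root_by_outgroup(four, "d")
  expect_true(ape::is.monophyletic(r, c("a", "b", "c")))
})

test_that("group count is non-increasing in theta and groups are disjoint", {
  set.seed(23)
  for (rep in 1:30) {
    phy <- random_lineage_tree(12)
    counts <- vapply(c(0.5, 0.7, 0.9, 0.99), function(th)
      count_ancestral(find_ancestral_groups(phy, lmap,
                                            threshold_policy(theta = th))),
      numeric(1))
    expect_true(all(diff(counts) <= 0))
    g <- find_ancestral_groups(phy, lmap, threshold_policy(theta = 0.5))
    mem <- unlist(g$members)
    expect_equal(anyDuplicated(mem), 0)
  }
})

test_that("output is invariant to tip-order permutation", {
  set.seed(29)
  phy <- random_lineage_tree(10)
  g1 <- find_ancestral_groups(phy, lmap, threshold_policy(theta = 0.5))
  phy2 <- ape::rotateConstr(phy, sample(phy$tip.label))
  phy2 <- normalize_supports(phy2)
  g2 <- find_ancestral_groups(phy2, lmap, threshold_policy(theta = 0.5))
  key <- function(g) sort(vapply(g$members,
                                 function(m) paste(sort(m), collapse = ","),
                                 character(1)))
  expect_equal(key(g1), key(g2))
})

test_that("brute-force oracle agrees with the tree recursion", {
  set.seed(31)
  for (rep in 1:60) {
    phy <- random_lineage_tree(sample(4:16, 1))
    pol <- threshold_policy(theta = sample(c(0.5, 0.8, 0.95), 1))
    expect_same_groups(find_ancestral_groups(phy, lmap, pol),
                       brute_force_groups(phy, lmap, pol))
  }
  expect_error(brute_force_groups(random_lineage_tree(17), lmap), "16 tips")
})
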