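# Shared fixtures built in code. Templates are deterministic, so build
# them once per test run.

templates <- make_family_templates()

template_refs <- function(tm = templates) {
  seq_set(id = names(tm), species = "reference",
          residues = vapply(tm, `[[`, character(1), "sequence"))
}

template_refdb <- function(tm = templates) {
  reference_db(template_refs(tm),
               data.frame(id = names(tm),
                          family = vapply(tm, `[[`, character(1), "family"),
                          subfamily = names(tm), stringsAsFactors = FALSE))
}

cnid_lmap <- cnidarian_lineage_map()

# Random support-annotated gene tree over the cnidarian species set:
# random topology, tips gene|species with species drawn at random, supports
# uniform (or as given).
random_lineage_tree <- function(ntip, supports = NULL,
                                species_pool = cnid_lmap$species) {
  phy <- ape::rtree(ntip)
  phy$tip.label <- sprintf("g%d|%s", seq_len(ntip),
                           sample(species_pool, ntip, replace = TRUE))
  if (is.null(supports)) supports <- round(runif(phy$Nnode), 2)
  node_supports(phy) <- supports
  phy
}

random_seq_set <- function(n, len = 60, aligned = FALSE, gap_frac = 0) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  res <- vapply(seq_len(n), function(i) {
    ch <- sample(aa, len, replace = TRUE)
    if (gap_frac > 0) {
      k <- round(gap_frac * len)
      if (k > 0) ch[sample(len, k)] <- "-"
    }
    paste(ch, collapse = "")
  }, character(1))
  seq_set(id = sprintf("s%d|sp%d", seq_len(n), seq_len(n)),
          species = sprintf("sp%d", seq_len(n)), residues = res,
          aligned = aligned)
}

# bipartition -> support map for nontrivial splits, canonicalised so the
# side not containing the first tip label keys the split
.split_support_map <- function(phy) {
  ntip <- length(phy$tip.label)
  sup <- node_supports(phy)
  sets <- kvancestry:::.node_tipsets(phy)
  all_tips <- sort(phy$tip.label)
  anchor <- all_tips[1]
  out <- list()
  for (nd in (ntip + 1):(ntip + phy$Nnode)) {
    tips <- sort(sets[[nd]])
    if (length(tips) >= ntip) next
    side <- if (anchor %in% tips) setdiff(all_tips, tips) else tips
    if (length(side) < 2 || length(side) > ntip - 2) next
    s <- sup[nd - ntip]
    if (!is.na(s)) out[[paste(side, collapse = ",")]] <- s
  }
  out
}

expect_same_groups <- function(a, b) {
  expect_equal(nrow(a), nrow(b))
  expect_equal(lapply(a$members, sort), lapply(b$members, sort))
  expect_equal(a$support, b$support)
}
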