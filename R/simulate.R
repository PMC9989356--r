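# Duplication-loss simulator: gene families evolve by birth (duplication)
# and death (loss) of gene lineages along an ultrametric species tree,
# with speciation copying every surviving lineage into both daughter
# branches. The simulator records the true gene count at every species-tree
# node and, for each gene present at the focal (root) split, whether it
# leaves surviving descendants in both focal lineages -- the quantity the
# ortholog-group counter is supposed to recover.

#' The default 8-species cnidarian species tree
#'
#' Ultrametric (unit depth, equal internal timings), rooted at the
#' Anthozoa/Medusozoa split. Anthozoa: Acropora, Stylophora, Exaiptasia,
#' Nematostella (Hexacorallia) and Renilla (Octocorallia); Medusozoa:
#' Rhopilema, Sanderia (Scyphozoa) and Hydra (Hydrozoa).
#'
#' @return An ape `phylo`.
#' @export
cnidarian_species_tree <- function() {
  ape::read.tree(text = paste0(
    "((((Acropora:0.25,Stylophora:0.25):0.25,",
    "(Exaiptasia:0.25,Nematostella:0.25):0.25):0.25,Renilla:0.75):0.25,",
    "((Rhopilema:0.4,Sanderia:0.4):0.3,Hydra:0.7):0.3);"))
}

#' The default cnidarian lineage map
#'
#' @param focal The two focal lineages.
#' @return A [lineage_map()] for the eight species of
#'   [cnidarian_species_tree()], with classes Hexacorallia, Octocorallia,
#'   Scyphozoa and Hydrozoa.
#' @export
cnidarian_lineage_map <- function(focal = c("Anthozoa", "Medusozoa")) {
  lineage_map(data.frame(
    species = c("Acropora", "Stylophora", "Exaiptasia", "Nematostella",
                "Renilla", "Rhopilema", "Sanderia", "Hydra"),
    lineage = c(rep("Anthozoa", 5), rep("Medusozoa", 3)),
    class = c(rep("Hexacorallia", 4), "Octocorallia",
              rep("Scyphozoa", 2), "Hydrozoa"),
    stringsAsFactors = FALSE), focal = focal)
}

#' Simulation configuration
#'
#' Defaults describe the study conditions the package emulates: the
#' 8-species cnidarian tree with 28 ancestral genes at the
#' Anthozoa/Medusozoa split, duplication and loss rates chosen so the
#' expected per-species channel count (`n0 * exp((lambda - mu) * depth)`)
#' lands near the mid-40s observed in cnidarian genomes, node supports
#' concentrated near 1 with an occasional weak node, and roughly 60% of
#' ancestral Kv genes carrying the R-subunit gate-degeneration phenotype.
#'
#' @param species_tree Ultrametric ape `phylo`; its root is the focal split.
#' @param lmap A [lineage_map()] covering the species tree tips.
#' @param n0 Gene count at the root (the focal ancestor).
#' @param lambda,mu Duplication and loss rates per gene lineage per unit
#'   time.
#' @param family Gene family emitted by [emit_sequences()] (`Kv`, `EAG`,
#'   `KCNQ`).
#' @param support_mean,support_conc Mean and concentration of the Beta
#'   distribution supports are drawn from.
#' @param weak_fraction Fraction of internal nodes forced below the
#'   acceptance threshold.
#' @param weak_range Support range for weak nodes.
#' @param subst_prob Per-site substitution probability per gene-tree branch.
#' @param r_fraction Fraction of root genes flagged as R-subunit lineages.
#' @param degrade_gates Force nonconservative gate substitutions in R tips.
#' @param seed Integer seed; every stochastic step derives from it.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(species_tree = cnidarian_species_tree(),
                              lmap = cnidarian_lineage_map(),
                              n0 = 28, lambda = 0.55, mu = 0.1,
                              family = "Kv",
                              support_mean = 0.985, support_conc = 80,
                              weak_fraction = 0.05,
                              weak_range = c(0.5, 0.94),
                              subst_prob = 0.02, r_fraction = 0.6,
                              degrade_gates = TRUE, seed = 1L) {
  stopifnot(lambda >= 0, mu >= 0, n0 >= 1)
  miss <- setdiff(species_tree$tip.label, lmap$species)
  if (length(miss))
    stop("species tree tips missing from lineage map: ",
         paste(miss, collapse = ", "))
  structure(list(species_tree = species_tree, lmap = lmap, n0 = as.integer(n0),
                 lambda = lambda, mu = mu, family = family,
                 support_mean = support_mean, support_conc = support_conc,
                 weak_fraction = weak_fraction, weak_range = weak_range,
                 subst_prob = subst_prob, r_fraction = r_fraction,
                 degrade_gates = degrade_gates, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a gene tree under duplication and loss
#'
#' Each of the `n0` root genes evolves independently: within every
#' species-tree branch a gene lineage waits an exponential time at rate
#' `lambda + mu`; a duplication splits it in two, a loss terminates it,
#' and reaching a speciation node copies it into both daughter branches
#' (Gillespie-style exact sampling). Unifurcations left by loss are
#' spliced out. Root-gene subtrees are joined at the gene-tree root, which
#' corresponds to the focal species split.
#'
#' @param cfg A [simulation_config()].
#' @return A list: `tree` (ape `phylo` with tips `gene|species`, or `NULL`
#'   if every lineage went extinct) and `truth`, a list with `n0`,
#'   `focal_gene_count`, `dual_survivors` (genes with surviving tips in
#'   both focal lineages), `per_gene` (data.frame `gene`, `n_tips`,
#'   per-lineage tip counts, `dual`), `node_counts` (gene count present at
#'   each species-tree node) and `extinct`.
#' @export
simulate_gene_tree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  sp <- cfg$species_tree
  ntip <- length(sp$tip.label)
  kids <- .children(sp)
  edge_len <- numeric(ntip + sp$Nnode)
  edge_len[sp$edge[, 2]] <- sp$edge.length
  env <- new.env()
  env$node_counts <- integer(ntip + sp$Nnode)
  env$tip_no <- 0L

  descend <- function(sp_node, t_rem) {
    rate <- cfg$lambda + cfg$mu
    w <- if (rate > 0) rexp(1, rate) else Inf
    if (w >= t_rem) {
      sub <- arrive(sp_node)
      if (is.null(sub)) return(NULL)
      sub$bl <- sub$bl + t_rem
      return(sub)
    }
    if (runif(1) < cfg$lambda / rate) {        # duplication
      a <- descend(sp_node, t_rem - w)
      b <- descend(sp_node, t_rem - w)
      if (!is.null(a) && !is.null(b))
        return(list(type = "dup", children = list(a, b), bl = w))
      keep <- if (!is.null(a)) a else b
      if (is.null(keep)) return(NULL)
      keep$bl <- keep$bl + w
      return(keep)
    }
    NULL                                        # loss
  }

  arrive <- function(sp_node) {
    env$node_counts[sp_node] <- env$node_counts[sp_node] + 1L
    if (sp_node <= ntip) {
      env$tip_no <- env$tip_no + 1L
      return(list(type = "tip",
                  label = sprintf("g%d.%d|%s", env$gene, env$tip_no,
                                  sp$tip.label[sp_node]),
                  bl = 0))
    }
    subs <- list()
    for (ch in kids[[sp_node]]) {
      s <- descend(ch, edge_len[ch])
      if (!is.null(s)) subs <- c(subs, list(s))
    }
    if (length(subs) == 0) return(NULL)
    if (length(subs) == 1) return(subs[[1]])
    list(type = "spec", children = subs, bl = 0)
  }

  root <- ntip + 1L
  gene_sub <- vector("list", cfg$n0)
  for (g in seq_len(cfg$n0)) {
    env$gene <- g
    env$tip_no <- 0L
    gene_sub[g] <- list(arrive(root))  # keep NULL (extinct) slots
  }
  # root was visited once per gene
  env$node_counts[root] <- cfg$n0

  focal <- focal_pair(cfg$lmap)
  sp_of <- function(node, acc = character(0)) {
    if (node$type == "tip") return(c(acc, sub("^.*\\|", "", node$label)))
    for (ch in node$children) acc <- sp_of(ch, acc)
    acc
  }
  lin_species <- split(cfg$lmap$species, cfg$lmap$lineage)
  per_gene <- do.call(rbind, lapply(seq_len(cfg$n0), function(g) {
    spp <- if (is.null(gene_sub[[g]])) character(0) else sp_of(gene_sub[[g]])
    nA <- sum(spp %in% lin_species[[focal[1]]])
    nB <- sum(spp %in% lin_species[[focal[2]]])
    data.frame(gene = g, n_tips = length(spp), n_tips_A = nA, n_tips_B = nB,
               dual = nA > 0 & nB > 0)
  }))
  names(per_gene)[3:4] <- paste0("n_tips_", focal)

  alive <- gene_sub[!vapply(gene_sub, is.null, logical(1))]
  tree <- if (length(alive)) .forest_to_phylo(alive) else NULL
  truth <- list(n0 = cfg$n0, focal_gene_count = cfg$n0,
                dual_survivors = sum(per_gene$dual),
                per_gene = per_gene,
                node_counts = env$node_counts,
                extinct = length(alive) == 0)
  list(tree = tree, truth = truth)
}

.subtree_newick <- function(node) {
  if (node$type == "tip")
    return(sprintf("%s:%s", node$label, format(node$bl, digits = 10)))
  inner <- paste(vapply(node$children, .subtree_newick, character(1)),
                 collapse = ",")
  sprintf("(%s):%s", inner, format(node$bl, digits = 10))
}

.forest_to_phylo <- function(subs) {
  if (length(subs) == 1 && subs[[1]]$type != "tip") {
    s <- .subtree_newick(subs[[1]])
    nwk <- paste0(sub(":[^:)]*$", "", s), ";")
  } else {
    nwk <- paste0("(", paste(vapply(subs, .subtree_newick, character(1)),
                             collapse = ","), ");")
  }
  ape::read.tree(text = nwk)
}

#' Draw node supports for a simulated gene tree
#'
#' Internal nodes get independent Beta draws with the configured mean and
#' concentration; a designated fraction of nodes is forced weak (uniform
#' on `weak_range`, below the usual acceptance threshold). With
#' `perfect = TRUE` every node gets support 1 (used for truth-recovery
#' runs).
#'
#' @param tree An ape `phylo`.
#' @param cfg A [simulation_config()] (support model fields are used).
#' @param perfect Logical; set all supports to 1.
#' @param seed Optional seed overriding `cfg$seed + 1`.
#' @return The tree with supports in `node.label`.
#' @export
assign_supports <- function(tree, cfg, perfect = FALSE, seed = NULL) {
  if (is.null(tree)) return(NULL)
  n <- tree$Nnode
  if (perfect) {
    node_supports(tree) <- rep(1, n)
    return(tree)
  }
  set.seed(if (is.null(seed)) cfg$seed + 1L else seed)
  a <- cfg$support_mean * cfg$support_conc
  b <- (1 - cfg$support_mean) * cfg$support_conc
  sup <- rbeta(n, a, b)
  n_weak <- round(cfg$weak_fraction * n)
  if (n_weak > 0) {
    weak <- sample.int(n, n_weak)
    sup[weak] <- runif(n_weak, cfg$weak_range[1], cfg$weak_range[2])
  }
  node_supports(tree) <- sup
  tree
}

# --- sequence emission ----------------------------------------------------

.random_block <- function(n) paste(sample(setdiff(.aa_alphabet, "X"), n,
                                          replace = TRUE), collapse = "")

.kv_gate <- "PVPVIV"  # canonical Shaker-type S6 activation gate

#' Family/subfamily sequence templates with diagnostic domain architecture
#'
#' Deterministic (seeded) protein templates mirroring the diagnostic
#' architecture of the three families: Kv = T1 + S1-S6 core ending in the
#' activation gate; EAG = (PAS) + core + C-linker/CNBHD, with the PAS
#' domain omitted from Erg (where it is evolutionarily labile); KCNQ =
#' core + C-terminal coiled-coil. Within a family, subfamily cores differ
#' at a fixed fraction of sites; assembly domains are shared.
#'
#' @param seed Integer seed fixing the template residues.
#' @param core_len,t1_len,cnbhd_len,cc_len,pas_len Block lengths (residues).
#' @param subfam_div Fraction of core sites differing between subfamilies.
#' @return Named list (one element per subfamily) of lists with `family`,
#'   `subfamily`, `blocks` (named residue strings), `sequence`
#'   (concatenation) and `gate_cols` (1-based gate window for Kv).
#' @export
make_family_templates <- function(seed = 101L, core_len = 240L, t1_len = 90L,
                                  cnbhd_len = 140L, cc_len = 60L,
                                  pas_len = 100L, subfam_div = 0.15) {
  set.seed(seed)
  fam_core <- list(Kv = .random_block(core_len - nchar(.kv_gate)),
                   EAG = .random_block(core_len),
                   KCNQ = .random_block(core_len))
  shared <- list(T1 = .random_block(t1_len),
                 CNBHD_Clinker = .random_block(cnbhd_len),
                 KCNQ_coiledcoil = .random_block(cc_len),
                 EAG_PAS = .random_block(pas_len))
  mutate_frac <- function(s, frac) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), round(frac * length(ch)))
    for (i in idx) ch[i] <- sample(setdiff(setdiff(.aa_alphabet, "X"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  out <- list()
  for (sf in names(.kv_subfamilies)) {
    fam <- .kv_subfamilies[[sf]]
    core <- mutate_frac(fam_core[[fam]], subfam_div)
    blocks <- switch(fam,
      Kv = c(T1 = shared$T1, S1S6_core = paste0(core, .kv_gate)),
      EAG = if (sf == "Erg") c(S1S6_core = core, CNBHD_Clinker = shared$CNBHD_Clinker)
            else c(EAG_PAS = shared$EAG_PAS, S1S6_core = core,
                   CNBHD_Clinker = shared$CNBHD_Clinker),
      KCNQ = c(S1S6_core = core, KCNQ_coiledcoil = shared$KCNQ_coiledcoil))
    seqn <- paste(blocks, collapse = "")
    gate_cols <- if (fam == "Kv") {
      end <- nchar(shared$T1) + nchar(blocks[["S1S6_core"]])
      c(end - nchar(.kv_gate) + 1L, end)
    } else NULL
    out[[sf]] <- list(family = fam, subfamily = sf, blocks = blocks,
                      sequence = seqn, gate_cols = gate_cols)
  }
  out
}

#' Domain profiles derived from the emitted templates
#'
#' Builds calibrated [domain_profile()]s for the diagnostic blocks of one
#' family, using the family's subfamily template cores as the aligned
#' reference set.
#'
#' @param templates Output of [make_family_templates()].
#' @param family `Kv`, `EAG` or `KCNQ`.
#' @param n_shuffles,seed Passed to [calibrate_domain_thresholds()].
#' @return Named list of calibrated profiles.
#' @export
template_domain_profiles <- function(templates, family, n_shuffles = 200L,
                                     seed = 1L) {
  sf <- names(.kv_subfamilies)[.kv_subfamilies == family]
  sf <- intersect(sf, names(templates))
  block_set <- function(block) {
    have <- sf[vapply(sf, function(s) block %in% names(templates[[s]]$blocks),
                      logical(1))]
    if (!length(have)) return(NULL)
    seq_set(id = paste0(have, "_", block), species = "template",
            residues = vapply(have, function(s) templates[[s]]$blocks[[block]],
                              character(1)),
            aligned = TRUE)
  }
  wanted <- switch(family,
                   Kv = c("S1S6_core", "T1"),
                   EAG = c("S1S6_core", "CNBHD_Clinker", "EAG_PAS"),
                   KCNQ = c("S1S6_core", "KCNQ_coiledcoil"))
  profs <- list()
  for (w in wanted) {
    ss <- block_set(w)
    if (!is.null(ss)) profs[[w]] <- domain_profile(w, ss)
  }
  calibrate_domain_thresholds(profs, n_shuffles = n_shuffles, seed = seed)
}

#' Emit protein sequences along a simulated gene tree
#'
#' The root sequence of each root gene is its subfamily template;
#' substitutions accumulate along each gene-tree branch with probability
#' `cfg$subst_prob` per site per branch. Root genes are flagged as
#' R-subunit lineages with probability `cfg$r_fraction`; when
#' `cfg$degrade_gates` is on, every tip of an R gene receives at least one
#' forced nonconservative substitution (under `scheme`) inside the gate
#' window. Because indels are not simulated, the emitted set is also a
#' gap-free alignment (equal lengths).
#'
#' @param tree A simulated gene tree (`tree` element of
#'   [simulate_gene_tree()]).
#' @param cfg A [simulation_config()].
#' @param templates Output of [make_family_templates()].
#' @param subfamily Template used for the root genes; default picks the
#'   first subfamily of `cfg$family`.
#' @param scheme A [conservation_scheme()].
#' @param seed Optional seed overriding `cfg$seed + 2`.
#' @return A list: `sequences` (an aligned [seq_set()]), `labels`
#'   (data.frame `id`, `species`, `gene`, `family`, `subfamily`,
#'   `r_subunit`), `gate_cols`.
#' @export
emit_sequences <- function(tree, cfg, templates = make_family_templates(),
                           subfamily = NULL, scheme = conservation_scheme(),
                           seed = NULL) {
  if (is.null(tree)) stop("cannot emit sequences from an empty (extinct) tree")
  if (is.null(subfamily))
    subfamily <- names(.kv_subfamilies)[.kv_subfamilies == cfg$family][1]
  if (is.null(templates[[subfamily]]))
    stop("missing template for subfamily ", subfamily)
  tmpl <- templates[[subfamily]]
  set.seed(if (is.null(seed)) cfg$seed + 2L else seed)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  kids <- .children(tree)
  blen <- numeric(ntip + nnode)
  blen[tree$edge[, 2]] <- tree$edge.length
  aa <- setdiff(.aa_alphabet, "X")
  mutate <- function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(runif(length(ch)) < cfg$subst_prob)
    for (i in hit) ch[i] <- sample(setdiff(aa, ch[i]), 1)
    paste(ch, collapse = "")
  }
  seqs <- character(ntip)
  walk <- function(node, s) {
    if (node <= ntip) { seqs[node] <<- s; return(invisible()) }
    for (ch in kids[[node]]) walk(ch, mutate(s))
  }
  # root sequence = template; root-to-child branches mutate once each
  walk(ntip + 1L, tmpl$sequence)
  genes <- as.integer(sub("^g(\\d+)\\..*$", "\\1", tree$tip.label))
  r_gene <- runif(max(genes)) < cfg$r_fraction
  r_tip <- r_gene[genes]
  if (cfg$degrade_gates && !is.null(tmpl$gate_cols) && any(r_tip)) {
    gc <- tmpl$gate_cols
    for (i in which(r_tip)) {
      ch <- strsplit(seqs[i], "")[[1]]
      pos <- gc[1]:gc[2]
      hit <- pos[runif(length(pos)) < 0.5]
      if (!length(hit)) hit <- sample(pos, 1)
      for (p in hit) ch[p] <- .nonconservative_sub(ch[p], scheme)
      seqs[i] <- paste(ch, collapse = "")
    }
  }
  species <- tip_species(tree$tip.label)
  list(sequences = seq_set(id = tree$tip.label, species = species,
                           residues = seqs, aligned = TRUE),
       labels = data.frame(id = tree$tip.label, species = species,
                           gene = genes, family = tmpl$family,
                           subfamily = tmpl$subfamily, r_subunit = r_tip,
                           stringsAsFactors = FALSE),
       gate_cols = tmpl$gate_cols)
}

# A residue whose chemical class differs from aa's (always nonconservative
# against a single-class consensus column, and against special residues).
.nonconservative_sub <- function(aa_res, scheme) {
  cls <- aa_class(aa_res, scheme)
  pool <- unlist(scheme$classes[setdiff(names(scheme$classes), cls)],
                 use.names = FALSE)
  sample(pool, 1)
}

#' Prune one gene's tips in chosen lineage classes (engineered loss)
#'
#' Removes every tip of root gene `gene` whose species belongs to one of
#' `classes`, emulating a class-specific gene loss with known ground
#' truth.
#'
#' @param tree A simulated gene tree.
#' @param gene Root-gene index.
#' @param classes Character vector of lineage classes to lose the gene.
#' @param lmap A [lineage_map()].
#' @return The pruned tree (possibly `NULL` if nothing remains).
#' @export
engineer_class_loss <- function(tree, gene, classes, lmap) {
  gidx <- as.integer(sub("^g(\\d+)\\..*$", "\\1", tree$tip.label))
  cls <- tip_lineages(tree$tip.label, lmap, "class")
  drop <- which(gidx == gene & cls %in% classes)
  if (!length(drop)) return(tree)
  ka_log(sprintf("engineered loss: gene g%d in class(es) %s (%d tips)",
                 gene, paste(classes, collapse = ","), length(drop)))
  if (length(drop) == length(tree$tip.label)) return(NULL)
  ape::drop.tip(tree, tree$tip.label[drop], collapse.singles = TRUE)
}

#' Write a reproducible benchmark bundle to disk
#'
#' Runs the simulator end to end and writes: `proteins.faa` (emitted
#' sequences), `alignment.faa` (same records; the emission model is
#' indel-free so they are column-aligned), `gene_tree.nwk` (Newick with
#' node-label supports), `lineage_map.tsv`, `truth.tsv` (per-gene truth),
#' `tip_labels.tsv` (per-tip family/subfamily/R flags) and
#' `manifest.json` (seed, config fingerprint, truth summary).
#'
#' @param cfg A [simulation_config()].
#' @param out_dir Output directory.
#' @param force Overwrite an existing directory.
#' @return `out_dir`, invisibly; the bundle files as side effect.
#' @export
generate_benchmark_bundle <- function(cfg, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stop("output directory exists (use force = TRUE): ", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_gene_tree(cfg)
  if (is.null(sim$tree))
    stop("simulated family went extinct; choose a different seed or rates")
  tree <- assign_supports(sim$tree, cfg)
  em <- emit_sequences(tree, cfg)
  write_fasta(em$sequences, file.path(out_dir, "proteins.faa"))
  write_fasta(em$sequences, file.path(out_dir, "alignment.faa"))
  ape::write.tree(tree, file.path(out_dir, "gene_tree.nwk"))
  write.table(as.data.frame(cfg$lmap), file.path(out_dir, "lineage_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$per_gene, file.path(out_dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(em$labels, file.path(out_dir, "tip_labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg_txt <- paste(deparse(cfg[setdiff(names(cfg), c("species_tree", "lmap"))]),
                   collapse = "")
  manifest <- list(
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(.write_temp(cfg_txt))),
    n0 = cfg$n0, lambda = cfg$lambda, mu = cfg$mu,
    dual_survivors = sim$truth$dual_survivors,
    n_tips = length(tree$tip.label))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

.write_temp <- function(txt) {
  f <- tempfile()
  writeLines(txt, f)
  f
}
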