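# Ancestral ortholog groups: the minimal clades of a rooted,
# support-annotated gene tree that contain at least one tip from each of
# two focal lineages and whose support meets the acceptance threshold. One
# qualifying clade = one gene inferred in the last common ancestor of the
# two lineages.

#' Support-threshold policy for ancestral clade acceptance
#'
#' @param theta Default support threshold (posterior probability scale).
#' @param comparison `"inclusive"` (support >= theta, default) or
#'   `"strict"` (support > theta).
#' @param overrides List of per-clade threshold exceptions, each a list
#'   with `tips` (character vector identifying the clade as the MRCA of
#'   those tips) and `theta` (the local threshold). Used to reproduce
#'   documented manual exceptions without loosening the global rule.
#' @param merges List of character vectors; each names a set of tips whose
#'   joint ancestor is the only clade evaluated in that region of the tree
#'   (all proper descendants of the MRCA are dissolved as candidates).
#' @param unannotated How an internal node without a support value is
#'   treated: `"fail"` (default, consensus-tree semantics) or `"pass"`.
#' @return A list of class `threshold_policy`.
#' @export
threshold_policy <- function(theta = 0.95,
                             comparison = c("inclusive", "strict"),
                             overrides = list(), merges = list(),
                             unannotated = c("fail", "pass")) {
  stopifnot(theta >= 0, theta <= 1)
  structure(list(theta = theta, comparison = match.arg(comparison),
                 overrides = overrides, merges = merges,
                 unannotated = match.arg(unannotated)),
            class = "threshold_policy")
}

#' Root a tree on an outgroup, preserving bipartition supports
#'
#' Reroots so the outgroup tips are one daughter of the root. Node supports
#' are treated as annotations of the bipartition (edge) below each node and
#' are reattached to the same bipartitions after rooting
#' (`ape::root(edgelabel = TRUE)`).
#'
#' @param phy An ape `phylo` (rooted or unrooted).
#' @param outgroup Character vector of tip labels.
#' @return A rooted `phylo`.
#' @export
root_by_outgroup <- function(phy, outgroup) {
  miss <- setdiff(outgroup, phy$tip.label)
  if (length(miss)) stop("outgroup tips not in tree: ", paste(miss, collapse = ", "))
  if (is.null(phy$node.label)) phy$node.label <- rep("", phy$Nnode)
  out <- tryCatch(
    ape::root(phy, outgroup = outgroup, resolve.root = TRUE, edgelabel = TRUE),
    error = function(e)
      stop("outgroup {", paste(outgroup, collapse = ","),
           "} does not form one side of any branch: ", conditionMessage(e)))
  if (!ape::is.monophyletic(out, outgroup))
    stop("outgroup {", paste(outgroup, collapse = ","),
         "} is not monophyletic after rooting")
  out
}

# children list indexed by node id
.children <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  kids <- vector("list", n)
  for (i in seq_len(nrow(phy$edge)))
    kids[[phy$edge[i, 1]]] <- c(kids[[phy$edge[i, 1]]], phy$edge[i, 2])
  kids
}

# tip label sets for every node (tips + internal), as a list
.node_tipsets <- function(phy) {
  ntip <- length(phy$tip.label)
  kids <- .children(phy)
  n <- ntip + phy$Nnode
  sets <- vector("list", n)
  for (i in seq_len(ntip)) sets[[i]] <- phy$tip.label[i]
  po <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    par <- po$edge[i, 1]; ch <- po$edge[i, 2]
    sets[[par]] <- c(sets[[par]], sets[[ch]])
  }
  sets
}

# effective support per internal node: root -> 1.0, NA handled by policy
.effective_supports <- function(phy, policy) {
  ntip <- length(phy$tip.label)
  sup <- node_supports(phy)
  if (all(is.na(sup)) && phy$Nnode > 1)
    stop("tree has no node supports anywhere; if supports are genuinely ",
         "absent, rerun with assume_support = TRUE")
  eff <- sup
  eff[1] <- 1.0  # node.label[1] is the root in ape order
  if (policy$unannotated == "pass") eff[is.na(eff)] <- 1.0
  eff
}

.meets <- function(support, theta, comparison) {
  if (is.na(support)) return(FALSE)
  if (comparison == "inclusive") support >= theta else support > theta
}

# resolve override/merge tip sets to node ids (MRCA); returns integer vector
.mrca_node <- function(phy, tips) {
  miss <- setdiff(tips, phy$tip.label)
  if (length(miss))
    stop("clade-identifier tips not in tree: ", paste(miss, collapse = ", "))
  if (length(tips) == 1) return(match(tips, phy$tip.label))
  ape::getMRCA(phy, tips)
}

#' Find ancestral ortholog groups on a rooted gene tree
#'
#' Scans every clade (including polytomy nodes; the root counts as a clade
#' with support 1.0) and keeps those whose support satisfies the effective
#' threshold and whose tips cover both focal lineages. The returned groups
#' are the minimal such clades under containment, labelled `G1, G2, ...`
#' in depth-first order. Per-clade threshold overrides and merge directives
#' from the [threshold_policy()] are applied first and logged.
#'
#' @param phy A rooted ape `phylo` with supports in `node.label`.
#' @param lmap A [lineage_map()]; every tip species must be present.
#' @param policy A [threshold_policy()].
#' @param assume_support If `TRUE`, a tree with no supports at all is
#'   treated as fully supported (used for simulator truth runs).
#' @param delimiter Tip-label delimiter for species parsing.
#' @return A data.frame of class `ortholog_groups`: `label`, `node`,
#'   `support`, `n_members`, `members` (list column), `lineages`
#'   (comma-joined).
#' @export
find_ancestral_groups <- function(phy, lmap, policy = threshold_policy(),
                                  assume_support = FALSE, delimiter = "|") {
  if (!ape::is.rooted(phy) && phy$Nnode > 1)
    ka_log("tree has a basal multifurcation; it is treated as the root clade",
           "debug")
  ntip <- length(phy$tip.label)
  if (ntip == 0) return(.empty_groups())
  if (assume_support) {
    if (is.null(phy$node.label) || all(node_supports(phy) %in% NA))
      phy$node.label <- rep("1", phy$Nnode)
  }
  lin <- tip_lineages(phy$tip.label, lmap, "lineage", delimiter)
  focal <- focal_pair(lmap)
  if (ntip == 1) return(.empty_groups())
  sets <- .node_tipsets(phy)
  eff <- .effective_supports(phy, policy)
  root <- ntip + 1L
  # per-clade overrides
  theta_local <- rep(policy$theta, phy$Nnode)
  for (ov in policy$overrides) {
    nd <- .mrca_node(phy, ov$tips)
    if (nd <= ntip) next
    theta_local[nd - ntip] <- ov$theta
    ka_log(sprintf("threshold override at clade {%s}: theta = %g",
                   paste(ov$tips, collapse = ","), ov$theta))
  }
  # merge directives dissolve all proper descendants of the joint ancestor
  dissolved <- rep(FALSE, ntip + phy$Nnode)
  for (mg in policy$merges) {
    anc <- .mrca_node(phy, mg)
    if (is.null(anc) || anc <= ntip) next
    desc <- setdiff(.descendant_nodes(phy, anc), anc)
    dissolved[desc] <- TRUE
    ka_log(sprintf("merge directive: clades within {%s} evaluated only at their joint ancestor",
                   paste(mg, collapse = ",")))
  }
  names(lin) <- phy$tip.label
  is_candidate <- rep(FALSE, ntip + phy$Nnode)
  for (nd in (ntip + 1L):(ntip + phy$Nnode)) {
    if (dissolved[nd]) next
    sup <- if (nd == root) 1.0 else eff[nd - ntip]
    covers <- all(focal %in% unique(lin[sets[[nd]]]))
    if (covers && .meets(sup, theta_local[nd - ntip], policy$comparison))
      is_candidate[nd] <- TRUE
  }
  # minimal candidates: no candidate among proper descendants
  minimal <- integer(0)
  for (nd in which(is_candidate)) {
    desc <- setdiff(.descendant_nodes(phy, nd), nd)
    if (!any(is_candidate[desc])) minimal <- c(minimal, nd)
  }
  # depth-first (preorder) labelling
  pre <- .preorder_nodes(phy)
  minimal <- minimal[order(match(minimal, pre))]
  .groups_df(phy, minimal, eff, lin, root, ntip)
}

.descendant_nodes <- function(phy, node) {
  ntip <- length(phy$tip.label)
  kids <- .children(phy)
  out <- integer(0); stack <- node
  while (length(stack)) {
    nd <- stack[1]; stack <- stack[-1]
    out <- c(out, nd)
    stack <- c(stack, kids[[nd]])
  }
  out
}

.preorder_nodes <- function(phy) {
  ntip <- length(phy$tip.label)
  kids <- .children(phy)
  out <- integer(0); stack <- ntip + 1L
  while (length(stack)) {
    nd <- stack[1]; stack <- stack[-1]
    out <- c(out, nd)
    stack <- c(kids[[nd]], stack)
  }
  out
}

.groups_df <- function(phy, nodes, eff, lin, root, ntip) {
  sets <- .node_tipsets(phy)
  out <- data.frame(
    label = if (length(nodes)) paste0("G", seq_along(nodes)) else character(0),
    node = nodes,
    support = vapply(nodes, function(nd) if (nd == root) 1.0 else eff[nd - ntip],
                     numeric(1)),
    n_members = vapply(nodes, function(nd) length(sets[[nd]]), integer(1)),
    stringsAsFactors = FALSE)
  out$members <- lapply(nodes, function(nd) sets[[nd]])
  out$lineages <- vapply(nodes, function(nd)
    paste(sort(unique(lin[sets[[nd]]])), collapse = ","), character(1))
  class(out) <- c("ortholog_groups", "data.frame")
  out
}

.empty_groups <- function() {
  out <- data.frame(label = character(0), node = integer(0),
                    support = numeric(0), n_members = integer(0),
                    stringsAsFactors = FALSE)
  out$members <- list()
  out$lineages <- character(0)
  class(out) <- c("ortholog_groups", "data.frame")
  out
}

#' Number of ancestral genes implied by a set of ortholog groups
#'
#' @param groups Output of [find_ancestral_groups()].
#' @return Integer count (one group = one inferred ancestral gene).
#' @export
count_ancestral <- function(groups) {
  stopifnot(inherits(groups, "ortholog_groups"))
  nrow(groups)
}

#' Brute-force reference implementation of ancestral group finding
#'
#' Independent oracle for [find_ancestral_groups()]: enumerates every
#' node's tip set explicitly, filters by support, lineage coverage and
#' merge directives, then selects minimal sets by pairwise containment
#' tests. Restricted to small trees (<= 16 tips).
#'
#' @inheritParams find_ancestral_groups
#' @return An `ortholog_groups` data.frame, identical in content to
#'   [find_ancestral_groups()] output.
#' @export
brute_force_groups <- function(phy, lmap, policy = threshold_policy(),
                               assume_support = FALSE, delimiter = "|") {
  ntip <- length(phy$tip.label)
  if (ntip > 16) stop("brute_force_groups is limited to trees with <= 16 tips")
  if (ntip <= 1) return(.empty_groups())
  if (assume_support) {
    if (is.null(phy$node.label) || all(node_supports(phy) %in% NA))
      phy$node.label <- rep("1", phy$Nnode)
  }
  lin <- tip_lineages(phy$tip.label, lmap, "lineage", delimiter)
  names(lin) <- phy$tip.label
  focal <- focal_pair(lmap)
  sets <- .node_tipsets(phy)
  eff <- .effective_supports(phy, policy)
  root <- ntip + 1L
  inodes <- (ntip + 1L):(ntip + phy$Nnode)
  theta_of <- function(nd) {
    for (ov in policy$overrides) {
      anc <- .mrca_node(phy, ov$tips)
      if (!is.null(anc) && anc == nd) return(ov$theta)
    }
    policy$theta
  }
  dissolved_by_merge <- function(nd) {
    for (mg in policy$merges) {
      anc <- .mrca_node(phy, mg)
      if (is.null(anc) || anc <= ntip) next
      # proper descendant test via tip sets
      if (nd != anc && all(sets[[nd]] %in% sets[[anc]])) return(TRUE)
    }
    FALSE
  }
  cand <- inodes[vapply(inodes, function(nd) {
    sup <- if (nd == root) 1.0 else eff[nd - ntip]
    all(focal %in% unique(lin[sets[[nd]]])) &&
      .meets(sup, theta_of(nd), policy$comparison) &&
      !dissolved_by_merge(nd)
  }, logical(1))]
  # minimal by pairwise containment on explicit tip sets
  keep <- vapply(cand, function(nd) {
    !any(vapply(cand, function(other)
      other != nd && all(sets[[other]] %in% sets[[nd]]) &&
        length(sets[[other]]) < length(sets[[nd]]), logical(1)))
  }, logical(1))
  minimal <- cand[keep]
  pre <- .preorder_nodes(phy)
  minimal <- minimal[order(match(minimal, pre))]
  .groups_df(phy, minimal, eff, lin, root, ntip)
}

#' Write ortholog groups to TSV
#'
#' @param groups An `ortholog_groups` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_groups <- function(groups, path) {
  flat <- as.data.frame(groups[, c("label", "support", "n_members", "lineages")])
  flat$members <- vapply(groups$members, paste, character(1), collapse = ";")
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
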