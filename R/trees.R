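# Support-annotated gene trees. Representation: an ape "phylo" whose
# node.label slot carries supports as printed strings ("" = unannotated),
# so ape::root(edgelabel = TRUE) can move them by bipartition. Accessors
# below convert to numeric in [0, 1].

#' Read a gene phylogeny with node support values
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`newick_nodelabel`}{Plain Newick where numeric internal-node
#'     labels are clade supports, e.g. `((a:1,b:1)0.97:1,c:1);`.}
#'   \item{`nexus_comment`}{NEXUS trees (e.g. MrBayes `.con.tre` consensus
#'     files) where per-node comments such as `[&prob=0.97,...]` carry
#'     posterior probabilities. The `prob` (or `posterior`) field of each
#'     node comment becomes that node's support.}
#' }
#' Supports given as percentages (values > 1 and <= 100) are rescaled to
#' `[0, 1]` with a warning. Supports outside `[0, 1]` after rescaling are a
#' hard error.
#'
#' @param path Path to the tree file.
#' @param dialect `"newick_nodelabel"` or `"nexus_comment"`.
#' @return An ape `phylo` with supports in `node.label`; use
#'   [node_supports()] to read them as numbers. Unrooted trees are returned
#'   as ape represents them (basal polytomy); see [ape::is.rooted()].
#' @export
read_tree <- function(path, dialect = c("newick_nodelabel", "nexus_comment")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (dialect == "newick_nodelabel") {
    phy <- tryCatch(suppressWarnings(ape::read.tree(text = txt)),
                    error = function(e) stop("unparseable Newick in ", path,
                                             ": ", conditionMessage(e)))
    if (is.null(phy)) stop("unparseable Newick in ", path)
  } else {
    phy <- read_nexus_support(txt, path)
  }
  normalize_supports(phy, path)
}

# Convert "0.97" / "95" / "" node labels to validated [0,1] supports.
normalize_supports <- function(phy, path = "<tree>") {
  lab <- phy$node.label
  if (is.null(lab)) return(phy)
  num <- suppressWarnings(as.numeric(lab))
  pct <- !is.na(num) & num > 1 & num <= 100
  if (any(pct)) {
    warning("rescaling ", sum(pct), " support value(s) from percentages to [0,1] in ",
            path)
    num[pct] <- num[pct] / 100
  }
  if (any(!is.na(num) & (num < 0 | num > 1))) {
    stop("node support outside [0,1] after rescaling in ", path, ": ",
         paste(lab[!is.na(num) & (num < 0 | num > 1)], collapse = ", "))
  }
  phy$node.label <- ifelse(is.na(num), "", format_support(num))
  phy
}

format_support <- function(x) {
  out <- ifelse(is.na(x), "", sub("0+$", "", sprintf("%.6f", x)))
  sub("\\.$", "", out)
}

#' Numeric node supports of a tree
#'
#' @param phy An ape `phylo`.
#' @return Numeric vector of length `phy$Nnode` (internal nodes in ape
#'   order), `NA` where unannotated.
#' @export
node_supports <- function(phy) {
  if (is.null(phy$node.label)) return(rep(NA_real_, phy$Nnode))
  suppressWarnings(as.numeric(phy$node.label))
}

#' Attach numeric supports to a tree
#'
#' @param phy An ape `phylo`.
#' @param value Numeric vector, length `phy$Nnode`, `NA` = unannotated.
#' @return `phy` with supports written into `node.label`.
#' @export
`node_supports<-` <- function(phy, value) {
  stopifnot(length(value) == phy$Nnode)
  if (any(!is.na(value) & (value < 0 | value > 1)))
    stop("supports must lie in [0,1]")
  phy$node.label <- format_support(value)
  phy
}

# --- NEXUS with [&prob=...] node comments (MrBayes .con.tre style) --------

read_nexus_support <- function(txt, path) {
  lines <- strsplit(txt, "\n")[[1]]
  tree_ln <- grep("^\\s*tree\\s+\\S+\\s*=", lines, ignore.case = TRUE)
  if (length(tree_ln) == 0)
    stop("no 'tree' statement found in NEXUS file ", path)
  # Translate table, if present.
  translate <- parse_nexus_translate(lines)
  stmt <- lines[tree_ln[1]]
  # A tree statement can span lines until ';'
  j <- tree_ln[1]
  while (!grepl(";", stmt) && j < length(lines)) {
    j <- j + 1
    stmt <- paste0(stmt, lines[j])
  }
  nwk <- sub("^[^=]*=\\s*", "", stmt)
  nwk <- sub("^\\[[^]]*\\]\\s*", "", nwk)  # leading rooting comment [&U]/[&R]
  nwk <- convert_prob_comments(nwk, path)
  phy <- tryCatch(ape::read.tree(text = nwk),
                  error = function(e) stop("unparseable NEXUS tree in ", path,
                                           ": ", conditionMessage(e)))
  if (is.null(phy)) stop("unparseable NEXUS tree in ", path)
  if (!is.null(translate)) {
    idx <- match(phy$tip.label, names(translate))
    phy$tip.label <- ifelse(is.na(idx), phy$tip.label, unname(translate[idx]))
  }
  phy
}

parse_nexus_translate <- function(lines) {
  beg <- grep("^\\s*translate\\b", lines, ignore.case = TRUE)
  if (length(beg) == 0) return(NULL)
  out <- character(0)
  j <- beg[1] + 1
  repeat {
    ln <- sub(";.*$", "", lines[j])
    toks <- regmatches(ln, gregexpr("[^\\s,]+", ln, perl = TRUE))[[1]]
    if (length(toks) >= 2) out[toks[1]] <- gsub("'", "", toks[2])
    if (grepl(";", lines[j]) || j >= length(lines)) break
    j <- j + 1
  }
  out
}

# Replace [&...prob=x...] comments that FOLLOW a ')' (node comments) with a
# node label holding x; drop every other [...] comment (branch annotations).
convert_prob_comments <- function(nwk, path) {
  chars <- strsplit(nwk, "")[[1]]
  out <- character(0)
  i <- 1
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      depth <- 1; j <- i + 1
      while (j <= n && depth > 0) {
        if (chars[j] == "[") depth <- depth + 1
        if (chars[j] == "]") depth <- depth - 1
        j <- j + 1
      }
      if (depth > 0) stop("unbalanced '[' comment in NEXUS tree ", path,
                          " at position ", i)
      com <- paste(chars[(i + 1):(j - 2)], collapse = "")
      prev <- if (length(out)) out[length(out)] else ""
      m <- regmatches(com, regexec("(?:^|[&,])(?:prob|posterior)=([0-9.eE+-]+)", com))[[1]]
      if (length(m) == 2 && identical(prev, ")")) {
        out <- c(out, format_support(as.numeric(m[2])))
      }
      i <- j
    } else {
      out <- c(out, ch)
      i <- i + 1
    }
  }
  paste(out, collapse = "")
}

#' Read a species-to-lineage map
#'
#' Tab-separated file with columns `species`, `lineage` and optionally
#' `class`; an empty or missing `class` defaults to the lineage. The focal
#' lineage pair names the two clades whose minimal shared clades date genes
#' to their common ancestor (for cnidarians, Anthozoa and Medusozoa).
#'
#' @param path Path to a TSV file.
#' @param focal Character vector of length 2: the two focal lineages.
#' @return A data.frame of class `lineage_map` with columns `species`,
#'   `lineage`, `class` and attribute `focal`.
#' @export
read_lineage_map <- function(path, focal = c("Anthozoa", "Medusozoa")) {
  tb <- read.delim(path, stringsAsFactors = FALSE)
  lineage_map(tb, focal = focal)
}

#' @rdname read_lineage_map
#' @param entries A data.frame with columns `species`, `lineage` and
#'   optionally `class`.
#' @export
lineage_map <- function(entries, focal = c("Anthozoa", "Medusozoa")) {
  need <- c("species", "lineage")
  if (!all(need %in% names(entries)))
    stop("lineage map must have columns: ", paste(need, collapse = ", "))
  if (is.null(entries$class)) entries$class <- NA_character_
  entries$class <- ifelse(is.na(entries$class) | entries$class == "",
                          entries$lineage, entries$class)
  dup <- duplicated(entries$species)
  if (any(dup)) {
    conflicting <- vapply(unique(entries$species[dup]), function(s) {
      sub <- entries[entries$species == s, c("lineage", "class")]
      nrow(unique(sub)) > 1
    }, logical(1))
    if (any(conflicting))
      stop("conflicting duplicate species row(s): ",
           paste(unique(entries$species[dup])[conflicting], collapse = ", "))
    entries <- entries[!dup, ]
  }
  stopifnot(length(focal) == 2)
  out <- entries[, c("species", "lineage", "class")]
  attr(out, "focal") <- as.character(focal)
  class(out) <- c("lineage_map", "data.frame")
  out
}

focal_pair <- function(lmap) attr(lmap, "focal")

# Species of a tip label under the geneId|speciesId convention.
tip_species <- function(labels, delimiter = "|") {
  sp <- parse_species(labels, delimiter = delimiter)
  ifelse(is.na(sp), labels, sp)  # bare species names allowed as tips
}

# lineage (or class) for each tip label; hard error listing missing species.
tip_lineages <- function(labels, lmap, what = c("lineage", "class"),
                         delimiter = "|") {
  what <- match.arg(what)
  sp <- tip_species(labels, delimiter)
  idx <- match(sp, lmap$species)
  if (anyNA(idx)) {
    stop("species missing from lineage map: ",
         paste(sort(unique(sp[is.na(idx)])), collapse = ", "))
  }
  lmap[[what]][idx]
}
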