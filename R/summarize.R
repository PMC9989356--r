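# Per-species channel count tables and ancestral presence/absence
# matrices across lineage classes.

.subfamily_order <- c("Shaker", "Shab", "Shaw", "Shal", "Eag", "Erg", "Elk", "KCNQ")

#' Construct a per-species x subfamily count table
#'
#' @param counts Integer matrix or data.frame, rows = species (rownames),
#'   columns = the 8 subfamily categories (Shaker, Shab, Shaw, Shal, Eag,
#'   Erg, Elk, KCNQ).
#' @return A matrix of class `count_table` with a `total` attribute
#'   (row sums).
#' @export
count_table <- function(counts) {
  m <- as.matrix(counts)
  if (!all(.subfamily_order %in% colnames(m)))
    stop("count table needs columns: ", paste(.subfamily_order, collapse = ", "))
  m <- m[, .subfamily_order, drop = FALSE]
  storage.mode(m) <- "integer"
  if (any(m < 0)) stop("counts must be nonnegative")
  if (anyDuplicated(rownames(m))) stop("duplicate species rows")
  structure(m, total = rowSums(m), class = c("count_table", class(m)))
}

#' Tabulate classified channel records into a count table
#'
#' Cells count complete, classified records per species and subfamily.
#' Records without a subfamily call are excluded and logged.
#'
#' @param records A `channel_records` data.frame (see
#'   [reciprocal_classify()]) with a logical `complete` column.
#' @return A [count_table()].
#' @export
tabulate_counts <- function(records) {
  complete <- if (is.null(records$complete)) rep(TRUE, nrow(records))
              else records$complete
  keep <- !is.na(records$subfamily) & complete
  if (any(!keep))
    ka_log(paste0(sum(!keep), " record(s) unclassified or incomplete, ",
                  "excluded from counts: ",
                  paste(records$id[!keep], collapse = ", ")))
  rec <- records[keep, , drop = FALSE]
  species <- sort(unique(records$species))
  m <- matrix(0L, length(species), length(.subfamily_order),
              dimnames = list(species, .subfamily_order))
  if (nrow(rec)) {
    tb <- table(factor(rec$species, levels = species),
                factor(rec$subfamily, levels = .subfamily_order))
    m[] <- as.integer(tb)
  }
  count_table(m)
}

#' Summary statistics of per-species channel totals
#'
#' @param tab A [count_table()].
#' @param species Optional subset of species (default: all rows).
#' @return A list: `mean` (unrounded), `mean_display` (rounded half-up to
#'   integer), `min`, `max`, `argmin`, `argmax`, `totals`.
#' @export
summarize_totals <- function(tab, species = rownames(tab)) {
  stopifnot(inherits(tab, "count_table"), length(species) >= 1)
  miss <- setdiff(species, rownames(tab))
  if (length(miss)) stop("species not in table: ", paste(miss, collapse = ", "))
  tot <- rowSums(tab[species, , drop = FALSE])
  list(mean = mean(tot),
       mean_display = floor(mean(tot) + 0.5),
       min = min(tot), argmin = names(tot)[which.min(tot)],
       max = max(tot), argmax = names(tot)[which.max(tot)],
       totals = tot)
}

#' Ancestral presence/absence matrix across lineage classes
#'
#' Rows are ancestral ortholog-group labels, columns are lineage classes;
#' a cell is `TRUE` (present) when the class contributes at least one
#' member to that group. Accepts either a single `ortholog_groups` table
#' or a list of them (e.g. one per gene family); group labels must be
#' drawn from `labels`.
#'
#' @param groups An `ortholog_groups` data.frame, or a list of them.
#' @param lmap A [lineage_map()] with a `class` column.
#' @param labels Ordered character vector of ancestral group labels
#'   (matrix row order).
#' @param classes Optional ordered class list (default: classes in `lmap`).
#' @param delimiter Tip-label delimiter.
#' @return Logical matrix of class `presence_matrix`.
#' @export
build_presence_matrix <- function(groups, lmap, labels,
                                  classes = unique(lmap$class),
                                  delimiter = "|") {
  if (inherits(groups, "ortholog_groups")) groups <- list(groups)
  all_groups <- do.call(rbind, lapply(groups, function(g)
    data.frame(label = g$label,
               members = I(g$members), stringsAsFactors = FALSE)))
  bad <- setdiff(all_groups$label, labels)
  if (length(bad))
    stop("group label(s) not in ancestral label list: ",
         paste(bad, collapse = ", "))
  m <- matrix(FALSE, length(labels), length(classes),
              dimnames = list(labels, classes))
  for (i in seq_len(nrow(all_groups))) {
    cls <- tip_lineages(all_groups$members[[i]], lmap, "class", delimiter)
    m[all_groups$label[i], intersect(unique(cls), classes)] <- TRUE
  }
  empty <- rownames(m)[rowSums(m) == 0]
  if (length(empty))
    ka_log(paste0("ancestral label(s) with no contributing class: ",
                  paste(empty, collapse = ", ")), "warn")
  structure(m, class = c("presence_matrix", class(m)))
}

#' Relabel ortholog groups by anchor members
#'
#' Assigns each group the ancestral label of the anchor sequence it
#' contains (e.g. a *Nematostella* gene per ancestral group), the join
#' rule used to align groups across per-family trees.
#'
#' @param groups An `ortholog_groups` data.frame.
#' @param anchors Named character vector: anchor tip label -> ancestral
#'   group label.
#' @return `groups` with `label` replaced where an anchor matched; groups
#'   containing no anchor (or several conflicting ones, logged) keep their
#'   positional label.
#' @export
anchor_labels <- function(groups, anchors) {
  stopifnot(inherits(groups, "ortholog_groups"))
  for (i in seq_len(nrow(groups))) {
    hit <- intersect(groups$members[[i]], names(anchors))
    labs <- unique(unname(anchors[hit]))
    if (length(labs) == 1) {
      groups$label[i] <- labs
    } else if (length(labs) > 1) {
      ka_log(sprintf("group %s contains %d conflicting anchors (%s); keeping positional label",
                     groups$label[i], length(labs), paste(labs, collapse = ",")),
             "warn")
    }
  }
  groups
}
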