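# S6 activation-gate degeneration scoring. Kv "regulatory" (R-type)
# subunits, which cannot form functional homotetramers, tend to accumulate
# nonconservative substitutions in the otherwise highly conserved S6
# activation gate of alpha-subunits. This module builds the alpha-subunit
# gate consensus, flags nonconservative positions in candidate sequences,
# and makes per-ortholog-group ancestral degeneration calls.

#' Chemical conservation scheme for gate scoring
#'
#' Partitions the 20 amino acids into named chemical classes; a
#' substitution within a class is conservative. Residues in
#' `special` (default proline and glycine, which set backbone geometry at
#' the gate) are structurally critical: any substitution away from a
#' special consensus residue is nonconservative regardless of class.
#'
#' @param classes Named list of character vectors partitioning the 20
#'   amino-acid letters.
#' @param special Character vector of structurally critical residues.
#' @return A list of class `conservation_scheme`.
#' @export
conservation_scheme <- function(
    classes = list(hydrophobic = c("A","V","L","I","M","F","W","Y","C"),
                   polar = c("S","T","N","Q"),
                   basic = c("K","R","H"),
                   acidic = c("D","E"),
                   proline = "P",
                   glycine = "G"),
    special = c("P", "G")) {
  all_aa <- sort(unlist(classes, use.names = FALSE))
  expected <- sort(setdiff(.aa_alphabet, "X"))
  if (!identical(all_aa, expected))
    stop("classes must partition the 20 amino acids exactly; got: ",
         paste(all_aa, collapse = ""))
  structure(list(classes = classes, special = special),
            class = "conservation_scheme")
}

aa_class <- function(aa, scheme) {
  for (nm in names(scheme$classes))
    if (aa %in% scheme$classes[[nm]]) return(nm)
  NA_character_
}

#' Extract the gate region of one aligned sequence
#'
#' @param aln An aligned [seq_set()].
#' @param id Record id to extract.
#' @param columns Integer vector `c(first, last)`, 1-based inclusive
#'   alignment columns of the gate window.
#' @return The gate string; gaps (`-`) and `X` mark missing positions.
#' @export
extract_gate <- function(aln, id, columns) {
  stopifnot(inherits(aln, "seq_set"), length(columns) == 2)
  i <- match(id, aln$id)
  if (is.na(i)) stop("id not in alignment: ", id)
  len <- nchar(aln$residues[i])
  if (columns[1] < 1 || columns[2] > len || columns[1] > columns[2])
    stop("gate columns ", columns[1], "-", columns[2],
         " out of bounds for ", len, "-column alignment")
  substr(aln$residues[i], columns[1], columns[2])
}

#' Build the alpha-subunit gate consensus
#'
#' Per-column consensus is the plurality residue among designated
#' alpha-subunits (ties broken lexicographically and logged); the
#' admissible classes at a column are the chemical classes observed among
#' the alpha-subunits there.
#'
#' @param aln An aligned [seq_set()].
#' @param alpha_ids Ids (>= 2) of the alpha-subunit rows.
#' @param columns Gate window, `c(first, last)` 1-based inclusive.
#' @param scheme A [conservation_scheme()].
#' @return A list of class `gate_consensus`: `columns`, `consensus`,
#'   `admissible` (list of class-name vectors per position), `scheme`.
#' @export
build_consensus <- function(aln, alpha_ids, columns,
                            scheme = conservation_scheme()) {
  if (length(alpha_ids) < 2) stop("need >= 2 alpha-subunit ids")
  gates <- vapply(alpha_ids, function(id) extract_gate(aln, id, columns),
                  character(1))
  mat <- do.call(rbind, strsplit(gates, ""))
  width <- ncol(mat)
  cons <- character(width)
  adm <- vector("list", width)
  for (j in seq_len(width)) {
    col <- mat[, j]
    col <- col[!col %in% c("-", "X")]
    if (!length(col))
      stop("gate column ", columns[1] + j - 1,
           " entirely missing in the alpha set")
    tb <- sort(table(col), decreasing = TRUE)
    top <- sort(names(tb)[tb == tb[1]])
    if (length(top) > 1)
      ka_log(sprintf("consensus tie at gate position %d (%s); using %s",
                     j, paste(top, collapse = "/"), top[1]))
    cons[j] <- top[1]
    adm[[j]] <- unique(vapply(unique(col), aa_class, character(1),
                              scheme = scheme))
  }
  structure(list(columns = columns, consensus = paste(cons, collapse = ""),
                 admissible = adm, scheme = scheme),
            class = "gate_consensus")
}

#' Classify one gate sequence against the alpha consensus
#'
#' A position is nonconservative when the observed residue's chemical
#' class is not among the classes seen in alpha-subunits at that column,
#' or when the consensus residue is structurally critical (P/G by default)
#' and the observed residue differs from it. Missing positions (`-`, `X`)
#' are never counted as nonconservative. The call is `degenerate` iff at
#' least one position is nonconservative, `missing_data` if every
#' position is missing, otherwise `alpha_like`.
#'
#' @param gate Gate string, same length as the consensus.
#' @param cons A [build_consensus()] result.
#' @param scheme A [conservation_scheme()]; defaults to the consensus's.
#' @return A list of class `gate_call`: `gate`, `flags` (per-position
#'   `"conservative"`/`"nonconservative"`/`"missing"`), `class`.
#' @export
classify_gate <- function(gate, cons, scheme = NULL) {
  if (is.null(scheme)) scheme <- cons$scheme
  width <- nchar(cons$consensus)
  if (nchar(gate) != width)
    stop("gate length ", nchar(gate), " != consensus length ", width)
  obs <- strsplit(toupper(gate), "")[[1]]
  ref <- strsplit(cons$consensus, "")[[1]]
  flags <- character(width)
  for (j in seq_len(width)) {
    if (obs[j] %in% c("-", "X")) { flags[j] <- "missing"; next }
    special_violation <- ref[j] %in% scheme$special && obs[j] != ref[j]
    class_violation <- !aa_class(obs[j], scheme) %in% cons$admissible[[j]]
    flags[j] <- if (special_violation || class_violation)
      "nonconservative" else "conservative"
  }
  cls <- if (all(flags == "missing")) "missing_data"
  else if (any(flags == "nonconservative")) "degenerate"
  else "alpha_like"
  structure(list(gate = gate, flags = flags, class = cls),
            class = "gate_call")
}

#' Ancestral degeneration call for an ortholog group
#'
#' `ancestral_degenerate` when at least one member from each focal lineage
#' is degenerate (the alteration predates the lineage split);
#' `lineage_restricted` when degenerate members occur in exactly one focal
#' lineage; otherwise `alpha_like`. Members with `missing_data` calls are
#' excluded.
#'
#' @param members Character vector of member tip labels (one group).
#' @param calls Named list of [classify_gate()] results, keyed by member.
#' @param lmap A [lineage_map()].
#' @param delimiter Tip-label delimiter.
#' @return One of `"ancestral_degenerate"`, `"lineage_restricted"`,
#'   `"alpha_like"`.
#' @export
group_ancestral_call <- function(members, calls, lmap, delimiter = "|") {
  lin <- tip_lineages(members, lmap, "lineage", delimiter)
  cls <- vapply(members, function(m) {
    if (is.null(calls[[m]])) "missing_data" else calls[[m]]$class
  }, character(1))
  keep <- cls != "missing_data"
  deg_lineages <- unique(lin[keep & cls == "degenerate"])
  focal <- focal_pair(lmap)
  n_focal_deg <- sum(focal %in% deg_lineages)
  if (n_focal_deg == 2) "ancestral_degenerate"
  else if (n_focal_deg == 1) "lineage_restricted"
  else "alpha_like"
}
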