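# Family/subfamily classification of candidate channel proteins by
# reciprocal best-hit local alignment against an annotated reference set,
# plus diagnostic-domain detection and the completeness filters used to
# admit sequences into phylogenetic analysis.

.kv_subfamilies <- c(Shaker = "Kv", Shab = "Kv", Shaw = "Kv", Shal = "Kv",
                     Eag = "EAG", Erg = "EAG", Elk = "EAG", KCNQ = "KCNQ")

#' Annotated reference channel database
#'
#' @param sequences A [seq_set()] of reference proteins.
#' @param annotation Data.frame with columns `id`, `family` (one of `Kv`,
#'   `EAG`, `KCNQ`) and `subfamily` (one of `Shaker`, `Shab`, `Shaw`,
#'   `Shal`, `Eag`, `Erg`, `Elk`, `KCNQ`). Every reference id must be
#'   annotated and the subfamily must belong to the stated family.
#' @return A list of class `reference_db`.
#' @export
reference_db <- function(sequences, annotation) {
  stopifnot(inherits(sequences, "seq_set"))
  need <- c("id", "family", "subfamily")
  if (!all(need %in% names(annotation)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  miss <- setdiff(sequences$id, annotation$id)
  if (length(miss))
    stop("unannotated reference id(s): ", paste(miss, collapse = ", "))
  ann <- annotation[match(sequences$id, annotation$id), need]
  bad <- .kv_subfamilies[ann$subfamily] != ann$family
  if (anyNA(bad) || any(bad))
    stop("subfamily inconsistent with family for: ",
         paste(ann$id[is.na(bad) | bad], collapse = ", "))
  structure(list(sequences = sequences, annotation = ann),
            class = "reference_db")
}

#' Classify query proteins by reciprocal best hit against references
#'
#' Each query is aligned locally against every reference; its best hit
#' (highest raw score, ties broken by lexicographic target id and logged)
#' proposes a family/subfamily call. The best reference target is then
#' aligned back against all queries. In `"cohort"` mode (default) the
#' reciprocal test passes when the back-hit query's own proposed call
#' matches the original query's proposed call; in `"strict"` mode the
#' back-hit must be the original query itself. A call is assigned only when
#' the reciprocal test passes and the forward E-value is strictly below
#' `e_threshold`. Unassignable queries are returned with `NA` calls, never
#' dropped.
#'
#' @param queries A [seq_set()] of candidate proteins.
#' @param ref A [reference_db()].
#' @param e_threshold E-value acceptance threshold (strict `<`).
#' @param mode `"cohort"` or `"strict"` reciprocal test.
#' @param matrix,gap_open,gap_extend Scoring scheme, see [local_align()].
#' @return A data.frame of class `channel_records`: one row per query with
#'   `id`, `species`, `family`, `subfamily`, `reciprocal_valid`,
#'   `best_target`, `score`, `e_value`, `coverage`.
#' @export
reciprocal_classify <- function(queries, ref, e_threshold = 0.01,
                                mode = c("cohort", "strict"),
                                matrix = "BLOSUM62", gap_open = 11,
                                gap_extend = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(queries, "seq_set"), inherits(ref, "reference_db"))
  if (nrow(queries) == 0 || nrow(ref$sequences) == 0)
    stop("queries and reference must be nonempty")
  S <- local_score_matrix(queries$residues, ref$sequences$residues,
                          matrix = matrix, gap_open = gap_open,
                          gap_extend = gap_extend)
  rid <- ref$sequences$id
  # Best reference per query: max score, ties -> lexicographic target id.
  best_j <- apply(S, 1, function(row) {
    top <- which(row == max(row))
    if (length(top) > 1) top <- top[order(rid[top])][1]
    top
  })
  ties <- apply(S, 1, function(row) sum(row == max(row)) > 1)
  if (any(ties))
    ka_log(paste0("tie-broken best hits (lexicographic target id) for: ",
                  paste(queries$id[ties], collapse = ", ")))
  # Back-hit of each reference within the queries, from the same matrix.
  back_q <- apply(S, 2, function(col) {
    top <- which(col == max(col))
    if (length(top) > 1) top <- top[order(queries$id[top])][1]
    top
  })
  prop_family <- ref$annotation$family[best_j]
  prop_subfam <- ref$annotation$subfamily[best_j]
  m <- nchar(queries$residues)
  n <- nchar(ref$sequences$residues)[best_j]
  best_score <- S[cbind(seq_len(nrow(S)), best_j)]
  ev <- karlin_evalue(best_score, m, n)
  recip <- vapply(seq_len(nrow(queries)), function(i) {
    bq <- back_q[best_j[i]]
    if (mode == "strict") return(bq == i)
    # cohort: the back-hit query's own proposed call matches this query's.
    prop_family[bq] == prop_family[i] && prop_subfam[bq] == prop_subfam[i]
  }, logical(1))
  accept <- recip & ev < e_threshold
  rejected <- queries$id[!accept]
  if (length(rejected))
    ka_log(paste0("no call (reciprocal/E-value filter) for: ",
                  paste(rejected, collapse = ", ")))
  out <- data.frame(
    id = queries$id, species = queries$species,
    family = ifelse(accept, prop_family, NA_character_),
    subfamily = ifelse(accept, prop_subfam, NA_character_),
    reciprocal_valid = recip,
    best_target = rid[best_j],
    score = best_score, e_value = ev,
    coverage = NA_real_,
    stringsAsFactors = FALSE)
  class(out) <- c("channel_records", "data.frame")
  out
}

# --- diagnostic domains ---------------------------------------------------

#' Build a diagnostic domain profile from an aligned reference block
#'
#' The profile's consensus is the per-column plurality residue over the
#' aligned members (gap columns contribute nothing; ties broken
#' lexicographically). Candidate sequences are scored by optimal local
#' alignment against this consensus; `threshold` is the minimum score at
#' which the domain is called present.
#'
#' @param name Domain name, one of `S1S6_core`, `T1`, `EAG_PAS`,
#'   `CNBHD_Clinker`, `KCNQ_coiledcoil` (other names permitted).
#' @param reference An aligned, nonempty [seq_set()] of domain examples.
#' @param threshold Score threshold; see [calibrate_domain_thresholds()].
#' @return A list of class `domain_profile`.
#' @export
domain_profile <- function(name, reference, threshold = NA_real_) {
  stopifnot(inherits(reference, "seq_set"))
  if (nrow(reference) == 0) stop("empty domain profile: ", name)
  if (length(unique(nchar(reference$residues))) != 1)
    stop("profile members must have equal aligned length: ", name)
  cons <- consensus_string(reference$residues)
  structure(list(name = name, reference = reference,
                 consensus = cons, threshold = threshold),
            class = "domain_profile")
}

consensus_string <- function(residues) {
  mat <- do.call(rbind, strsplit(residues, ""))
  cols <- apply(mat, 2, function(col) {
    col <- col[!col %in% c("-", "X")]
    if (!length(col)) return(NA_character_)
    tb <- sort(table(col), decreasing = TRUE)
    cands <- names(tb)[tb == tb[1]]
    sort(cands)[1]
  })
  paste(cols[!is.na(cols)], collapse = "")
}

#' Calibrate domain-presence thresholds from a shuffled-sequence null
#'
#' For each profile, the consensus is shuffled `n_shuffles` times and
#' aligned back to itself; the threshold is the `quantile` of the null
#' score distribution. Seeded and deterministic.
#'
#' @param profiles List of [domain_profile()]s.
#' @param n_shuffles Number of shuffles per profile.
#' @param q Null quantile used as the presence threshold.
#' @param seed Integer seed.
#' @return The profiles, with thresholds filled in.
#' @export
calibrate_domain_thresholds <- function(profiles, n_shuffles = 1000,
                                        q = 0.999, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lapply(profiles, function(p) {
    ch <- strsplit(p$consensus, "")[[1]]
    null <- vapply(seq_len(n_shuffles), function(i) {
      shuf <- paste(sample(ch), collapse = "")
      local_align(shuf, p$consensus)$score
    }, numeric(1))
    p$threshold <- as.numeric(quantile(null, q, type = 1))
    ka_log(sprintf("domain %s: null %g-quantile threshold = %g",
                   p$name, q, p$threshold), level = "debug")
    p
  })
}

#' Detect diagnostic domains in a protein sequence
#'
#' A domain is present when the optimal local-alignment score of the
#' sequence against the profile consensus reaches the profile threshold.
#'
#' @param seq A gap-free amino-acid string.
#' @param profiles Nonempty list of calibrated [domain_profile()]s.
#' @return Named logical vector, one element per profile.
#' @export
detect_domains <- function(seq, profiles) {
  if (!length(profiles)) stop("empty profile list")
  res <- vapply(profiles, function(p) {
    if (is.na(p$threshold))
      stop("profile ", p$name, " has no threshold; run calibrate_domain_thresholds()")
    local_align(seq, p$consensus)$score >= p$threshold
  }, logical(1))
  names(res) <- vapply(profiles, `[[`, character(1), "name")
  res
}

#' Completeness rule for phylogenetic analysis
#'
#' A classified channel is complete when it carries the transmembrane core
#' (S1-S6) plus its family's diagnostic assembly domain: T1 for Kv, the
#' C-terminal coiled-coil for KCNQ, and the C-linker/CNBHD for EAG. The
#' N-terminal PAS (eag) domain is not required for EAG-family channels
#' because Erg-subfamily genes can lack it.
#'
#' @param family Family call (`Kv`, `EAG`, `KCNQ`); `NA` is a hard error.
#' @param flags Named logical vector as returned by [detect_domains()].
#' @return `TRUE` when the family's required domains are all present.
#' @export
completeness_check <- function(family, flags) {
  if (is.na(family) || !family %in% c("Kv", "EAG", "KCNQ"))
    stop("completeness_check requires a family call")
  has <- function(d) isTRUE(unname(flags[d]))
  switch(family,
         Kv = has("S1S6_core") && has("T1"),
         KCNQ = has("S1S6_core") && has("KCNQ_coiledcoil"),
         EAG = has("S1S6_core") && has("CNBHD_Clinker"))
}

#' Drop alignment rows with too much missing data
#'
#' Removes sequences whose fraction of gap (`-`) or unknown (`X`)
#' characters over the aligned columns exceeds `max_missing`; a sequence
#' exactly at the boundary survives. Survivors are returned unchanged and
#' removals are logged.
#'
#' @param aln An aligned [seq_set()] (equal lengths enforced).
#' @param max_missing Maximum tolerated missing fraction (default 0.10).
#' @return The filtered [seq_set()].
#' @export
alignment_missing_filter <- function(aln, max_missing = 0.10) {
  stopifnot(inherits(aln, "seq_set"))
  len <- unique(nchar(aln$residues))
  if (length(len) != 1) stop("ragged alignment")
  frac <- vapply(strsplit(aln$residues, ""),
                 function(ch) mean(ch %in% c("-", "X")), numeric(1))
  drop <- frac > max_missing
  if (any(drop))
    ka_log(paste0("removed (missing >", max_missing * 100, "% of aligned region): ",
                  paste(sprintf("%s (%.1f%%)", aln$id[drop], 100 * frac[drop]),
                        collapse = ", ")))
  out <- aln[!drop, , drop = FALSE]
  attr(out, "aligned") <- TRUE
  attr(out, "source_path") <- attr(aln, "source_path")
  class(out) <- class(aln)
  out
}
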