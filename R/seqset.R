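# Sequence sets: ordered collections of protein records with a species tag
# parsed from the FASTA header. Backed by a plain data.frame so downstream
# code can subset with base idioms.

.aa_alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' Construct a sequence set
#'
#' A `seq_set` is an ordered collection of protein records, each with a
#' unique `id`, a `species` tag and an amino-acid string. Residues are
#' restricted to the 20 standard amino-acid letters plus `X`; gap characters
#' (`-`) are permitted only when `aligned = TRUE`.
#'
#' @param id Character vector of unique record identifiers.
#' @param species Character vector of species tags (recycled if length 1).
#' @param residues Character vector of amino-acid strings.
#' @param aligned Logical; if `TRUE` all records must have equal length and
#'   may contain gaps.
#' @param source_path Optional path the records were read from.
#' @return A data.frame of class `seq_set` with columns `id`, `species`,
#'   `residues`.
#' @export
seq_set <- function(id, species, residues, aligned = FALSE, source_path = NA_character_) {
  id <- as.character(id)
  species <- rep_len(as.character(species), length(id))
  residues <- toupper(as.character(residues))
  if (anyDuplicated(id)) {
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  ok <- c(.aa_alphabet, if (aligned) "-")
  bad <- vapply(strsplit(residues, ""), function(ch) any(!ch %in% ok), logical(1))
  if (any(bad)) {
    stop("invalid residue letters in: ", paste(id[bad], collapse = ", "),
         if (!aligned) " (gaps only allowed in alignment sets)")
  }
  if (aligned && length(unique(nchar(residues))) > 1) {
    stop("ragged alignment: sequences differ in length")
  }
  out <- data.frame(id = id, species = species, residues = residues,
                    stringsAsFactors = FALSE)
  attr(out, "aligned") <- aligned
  attr(out, "source_path") <- source_path
  class(out) <- c("seq_set", "data.frame")
  out
}

is_aligned <- function(x) isTRUE(attr(x, "aligned"))

#' Read a protein FASTA file into a sequence set
#'
#' Headers are split into a gene id and a species tag at the first
#' occurrence of `delimiter` (default `"|"`, i.e. the `geneId|speciesId`
#' tip-label convention used throughout the package). Headers without the
#' delimiter get species `NA`.
#'
#' @param path Path to a FASTA file.
#' @param delimiter Single character separating gene id from species in the
#'   header. Set `species_regex` instead for irregular conventions.
#' @param species_regex Optional regex with one capture group applied to the
#'   full header to extract the species; overrides `delimiter`.
#' @param aligned Logical; pass `TRUE` when reading an alignment (permits
#'   gap characters and enforces equal lengths).
#' @return A [seq_set()] preserving record order.
#' @export
read_fasta <- function(path, delimiter = "|", species_regex = NULL, aligned = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop("empty FASTA file: ", path)
  headers <- names(aa)
  sp <- parse_species(headers, delimiter = delimiter, species_regex = species_regex)
  seq_set(id = headers, species = sp, residues = as.character(aa),
          aligned = aligned, source_path = path)
}

parse_species <- function(headers, delimiter = "|", species_regex = NULL) {
  if (!is.null(species_regex)) {
    m <- regmatches(headers, regexec(species_regex, headers))
    return(vapply(m, function(x) if (length(x) >= 2) x[2] else NA_character_,
                  character(1)))
  }
  parts <- strsplit(headers, delimiter, fixed = TRUE)
  vapply(parts, function(x) if (length(x) >= 2) x[2] else NA_character_,
         character(1))
}

#' Write a sequence set to FASTA
#'
#' @param x A [seq_set()].
#' @param path Output path.
#' @param width Line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(inherits(x, "seq_set"))
  aa <- Biostrings::AAStringSet(setNames(x$residues, x$id))
  Biostrings::writeXStringSet(aa, filepath = path, width = width)
  invisible(path)
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("<seq_set> %d record(s)%s\n", nrow(x),
              if (is_aligned(x)) sprintf(", aligned (%d columns)",
                                         nchar(x$residues[1])) else ""))
  print.data.frame(head(transform(as.data.frame(x),
                                  residues = paste0(substr(residues, 1, 24),
                                                    ifelse(nchar(residues) > 24, "...", ""))),
                        10), row.names = FALSE)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
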