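#' @keywords internal
#' @useDynLib hcbprimer, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Canonical rank order for taxonomy paths. Deeper ranks in input paths are
## ignored; genus is the sixth field.
TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

## Alphabet accepted in reference sequences: the four bases plus IUPAC
## ambiguity codes. 'U' is normalized to 'T' on read and never stored.
SEQ_ALPHABET <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V")

#' Construct a reference sequence set
#'
#' A reference set is the central container of the package: one row per 16S
#' rRNA gene sequence, carrying its identifier, the sequence itself (DNA
#' alphabet, upper case), an ordered taxonomy path, a genus label, a
#' type-strain flag, and an abundance (the number of identical reads the
#' record stands for).
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param sequence character vector of sequences over the DNA/IUPAC
#'   alphabet; lower case and 'U' are normalized.
#' @param taxonomy semicolon-delimited rank paths (domain to genus); may be
#'   empty strings.
#' @param is_type_strain logical; defaults to \code{FALSE}.
#' @param abundance positive integer counts; defaults to 1.
#' @param description free-text header remainder; defaults to "".
#' @return a \code{data.frame} with columns \code{id}, \code{sequence},
#'   \code{taxonomy}, \code{genus}, \code{is_type_strain}, \code{abundance},
#'   \code{description}.
#' @export
reference_set <- function(id, sequence, taxonomy = "",
                          is_type_strain = FALSE, abundance = 1L,
                          description = "") {
  n <- length(id)
  sequence <- normalize_sequence(sequence)
  refs <- data.frame(
    id = as.character(id),
    sequence = sequence,
    taxonomy = rep_len(as.character(taxonomy), n),
    genus = genus_of(rep_len(as.character(taxonomy), n)),
    is_type_strain = rep_len(as.logical(is_type_strain), n),
    abundance = rep_len(as.integer(abundance), n),
    description = rep_len(as.character(description), n),
    stringsAsFactors = FALSE
  )
  validate_reference_set(refs)
  refs
}

#' Validate a reference set
#'
#' Checks the invariants of the container: unique non-empty ids, non-empty
#' sequences over the allowed alphabet, positive abundances.
#'
#' @param refs a reference set data.frame.
#' @return \code{refs}, invisibly.
#' @export
validate_reference_set <- function(refs) {
  stopifnot(is.data.frame(refs))
  if (any(!nzchar(refs$id))) stop("empty sequence id")
  dup <- refs$id[duplicated(refs$id)]
  if (length(dup) > 0L)
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(refs$sequence))) {
    bad <- refs$id[!nzchar(refs$sequence)][1L]
    stop("zero-length sequence for id '", bad, "'")
  }
  check_alphabet(refs$sequence, refs$id)
  if (any(is.na(refs$abundance)) || any(refs$abundance < 1L))
    stop("abundance must be a positive integer")
  invisible(refs)
}

## Uppercase and U->T; primer matching operates in DNA space.
normalize_sequence <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(as.character(x))))
}

check_alphabet <- function(seqs, ids) {
  bad <- regexpr(sprintf("[^%s]", paste(SEQ_ALPHABET, collapse = "")), seqs)
  hit <- which(bad > 0L)
  if (length(hit) > 0L) {
    i <- hit[1L]
    stop(sprintf("illegal character '%s' at position %d of sequence '%s'",
                 substr(seqs[i], bad[i], bad[i]), bad[i], ids[i]))
  }
  invisible(TRUE)
}

#' Extract the genus from a semicolon-delimited taxonomy path
#'
#' Paths run domain;phylum;class;order;family;genus; ranks past genus are
#' ignored and a path shorter than six ranks yields an empty genus.
#'
#' @param taxonomy character vector of paths.
#' @return character vector of genus labels ("" when unclassified).
#' @export
genus_of <- function(taxonomy) {
  vapply(strsplit(as.character(taxonomy), ";", fixed = TRUE), function(p) {
    p <- trimws(p)
    if (length(p) >= 6L && nzchar(p[6L])) p[6L] else ""
  }, character(1))
}

#' Group reference ids into taxon sets by genus
#'
#' @param refs a reference set.
#' @param genera optional character vector restricting which genera to
#'   return; default is all non-empty genus labels present.
#' @return named list of character id vectors, one per genus.
#' @export
taxon_sets <- function(refs, genera = NULL) {
  if (is.null(genera)) genera <- sort(unique(refs$genus[nzchar(refs$genus)]))
  sets <- lapply(genera, function(g) refs$id[refs$genus == g])
  names(sets) <- genera
  empty <- genera[lengths(sets) == 0L]
  if (length(empty) > 0L)
    stop("empty taxon set(s): ", paste(empty, collapse = ", "))
  sets
}

#' Construct a multiple sequence alignment
#'
#' Rows are stored as equal-length gapped strings over the sequence alphabet
#' plus '-'; ungapping any row reproduces its source sequence.
#'
#' @param ids character row identifiers (unique).
#' @param rows character gapped sequences, all the same number of columns.
#' @return an object of class \code{seq_alignment} with elements \code{ids},
#'   \code{rows} and \code{width}.
#' @export
new_alignment <- function(ids, rows) {
  ids <- as.character(ids)
  rows <- toupper(as.character(rows))
  if (length(ids) != length(rows)) stop("ids and rows differ in length")
  if (anyDuplicated(ids)) stop("duplicate alignment row ids")
  w <- unique(nchar(rows))
  if (length(w) > 1L) stop("alignment rows have unequal widths")
  if (length(w) == 0L) w <- 0L
  structure(list(ids = ids, rows = rows, width = as.integer(w)),
            class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("seq_alignment: %d rows x %d columns\n",
              length(x$ids), x$width))
  invisible(x)
}

#' Alignment rows as a character matrix (one column per alignment column)
#' @param aln a \code{seq_alignment}.
#' @return character matrix with rownames = row ids.
#' @export
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  if (is.null(m)) m <- matrix(character(0), nrow = 0, ncol = aln$width)
  rownames(m) <- aln$ids
  m
}

#' Remove gaps from aligned rows
#' @param aln a \code{seq_alignment}.
#' @return named character vector of ungapped sequences.
#' @export
ungap_alignment <- function(aln) {
  out <- gsub("-", "", aln$rows, fixed = TRUE)
  names(out) <- aln$ids
  out
}
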