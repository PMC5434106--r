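#' Read a FASTA file into a reference set
#'
#' The id is the header token before the first whitespace; the remainder of
#' the header is kept as a free-text description. Sequences are upper-cased
#' and 'U' is normalized to 'T' so that downstream primer matching operates
#' in DNA space. Records are returned in file order.
#'
#' @param path path to a FASTA file.
#' @return a reference set data.frame (taxonomy empty; join it with
#'   \code{\link{read_taxonomy_table}} via \code{\link{join_taxonomy}}).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) {
    warning("no FASTA records in ", path)
    return(reference_set(character(0), character(0)))
  }
  ends <- c(hdr[-1L] - 1L, length(lines))
  headers <- sub("^>", "", lines[hdr])
  seqs <- vapply(seq_along(hdr), function(i) {
    if (ends[i] > hdr[i])
      paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
    else ""
  }, character(1))
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  reference_set(id = ids, sequence = seqs, description = desc)
}

#' Write a reference set to FASTA
#'
#' Standard FASTA with 80-column sequence wrapping; descriptions, when
#' present, follow the id after one space. Round-trips losslessly with
#' \code{\link{read_fasta}}.
#'
#' @param refs a reference set.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(refs, path, width = 80L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(refs))) {
    hdr <- if (nzchar(refs$description[i]))
      paste(refs$id[i], refs$description[i]) else refs$id[i]
    writeLines(paste0(">", hdr), con)
    s <- refs$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a taxonomy table
#'
#' Tab-delimited with columns id, semicolon-delimited rank path
#' (domain;phylum;class;order;family;genus), and an optional 0/1 type-strain
#' flag. Lines starting with '#' are skipped; a missing flag defaults to
#' FALSE.
#'
#' @param path path to the TSV.
#' @return data.frame with columns \code{id}, \code{taxonomy}, \code{genus},
#'   \code{is_type_strain}.
#' @export
read_taxonomy_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (length(lines) == 0L)
    return(data.frame(id = character(0), taxonomy = character(0),
                      genus = character(0), is_type_strain = logical(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("taxonomy table rows need at least id and rank path")
  id <- vapply(parts, `[`, character(1), 1L)
  tax <- vapply(parts, `[`, character(1), 2L)
  flag <- vapply(parts, function(p)
    length(p) >= 3L && p[3L] %in% c("1", "TRUE", "true"), logical(1))
  if (anyDuplicated(id))
    stop("duplicate id(s) in taxonomy table: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  data.frame(id = id, taxonomy = tax, genus = genus_of(tax),
             is_type_strain = flag, stringsAsFactors = FALSE)
}

#' Join a taxonomy table onto a reference set
#'
#' Every sequence id must be present in the taxonomy table; unmatched ids
#' raise an error listing them.
#'
#' @param refs reference set from \code{\link{read_fasta}}.
#' @param tax table from \code{\link{read_taxonomy_table}}.
#' @return the reference set with taxonomy, genus and type-strain columns
#'   filled in.
#' @export
join_taxonomy <- function(refs, tax) {
  idx <- match(refs$id, tax$id)
  if (anyNA(idx))
    stop("ids missing from taxonomy table: ",
         paste(refs$id[is.na(idx)], collapse = ", "))
  refs$taxonomy <- tax$taxonomy[idx]
  refs$genus <- tax$genus[idx]
  refs$is_type_strain <- tax$is_type_strain[idx]
  refs
}

#' Write a taxonomy table
#' @param refs a reference set.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_taxonomy_table <- function(refs, path) {
  writeLines(sprintf("%s\t%s\t%d", refs$id, refs$taxonomy,
                     as.integer(refs$is_type_strain)), path)
  invisible(path)
}

#' Read a primer-pair table
#'
#' Tab-delimited with columns pair_id, fwd_name, fwd_seq, rev_name, rev_seq
#' ('#' comment lines skipped). Primer sequences are validated over the
#' IUPAC alphabet. Where primer names follow the standardized 16S
#' nomenclature (e.g. "S-D-Bact-0343-a-S-15") the nominal position,
#' orientation and length are parsed; for other names (e.g. "27F") the
#' positional metadata stays NA. The nominal amplicon length and size class
#' are derived where both positions parse.
#'
#' @param path path to the TSV.
#' @return data.frame with one row per pair: \code{pair_id},
#'   \code{fwd_name}, \code{fwd_seq}, \code{rev_name}, \code{rev_seq},
#'   \code{fwd_pos}, \code{fwd_len}, \code{rev_pos}, \code{rev_len},
#'   \code{nominal_length}, \code{size_class}.
#' @export
read_primer_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 5L))
    stop("primer table rows need pair_id, fwd_name, fwd_seq, rev_name, rev_seq")
  tab <- data.frame(
    pair_id  = vapply(parts, `[`, character(1), 1L),
    fwd_name = vapply(parts, `[`, character(1), 2L),
    fwd_seq  = toupper(vapply(parts, `[`, character(1), 3L)),
    rev_name = vapply(parts, `[`, character(1), 4L),
    rev_seq  = toupper(vapply(parts, `[`, character(1), 5L)),
    stringsAsFactors = FALSE
  )
  for (col in c("fwd_seq", "rev_seq")) {
    ok <- grepl(sprintf("^[%s]+$", paste(IUPAC_CODES, collapse = "")),
                tab[[col]])
    if (any(!ok))
      stop("non-IUPAC primer sequence in pair(s): ",
           paste(tab$pair_id[!ok], collapse = ", "))
  }
  annotate_primer_pairs(tab)
}

## Fill in parsed nomenclature metadata, nominal length and size class.
annotate_primer_pairs <- function(tab) {
  f <- lapply(tab$fwd_name, parse_primer_name)
  r <- lapply(tab$rev_name, parse_primer_name)
  tab$fwd_pos <- vapply(f, function(p) p$position %||% NA_integer_, integer(1))
  tab$fwd_len <- vapply(f, function(p) p$length %||% NA_integer_, integer(1))
  tab$rev_pos <- vapply(r, function(p) p$position %||% NA_integer_, integer(1))
  tab$rev_len <- vapply(r, function(p) p$length %||% NA_integer_, integer(1))
  tab$nominal_length <- mapply(function(fp, rp, rl) {
    if (is.na(fp) || is.na(rp) || is.na(rl)) NA_integer_
    else nominal_amplicon_length(fp, rp, rl)
  }, tab$fwd_pos, tab$rev_pos, tab$rev_len)
  tab$size_class <- vapply(tab$nominal_length, assign_size_class, character(1))
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
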