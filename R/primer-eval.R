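## IUPAC nucleotide codes and the base sets they denote.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
IUPAC_CODES <- names(IUPAC_SETS)

## Complement of each code, as the code denoting the complemented base set.
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S", W = "W",
  K = "M", M = "K", B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Perfect-match compatibility of a primer base with a target base
#'
#' A primer position matches a target base iff the target base is one of
#' the concrete bases denoted by the primer's IUPAC code. Ambiguity codes in
#' the TARGET never satisfy a perfect match: only A, C, G or T in the target
#' can match (the conservative semantics used throughout the coverage
#' computation).
#'
#' @param primer_base single IUPAC character (primer side).
#' @param target_base single character (target side).
#' @return logical.
#' @export
iupac_compatible <- function(primer_base, target_base) {
  if (!primer_base %in% IUPAC_CODES) stop("invalid primer base: ", primer_base)
  target_base %in% c("A", "C", "G", "T") &&
    target_base %in% IUPAC_SETS[[primer_base]]
}

#' IUPAC-aware reverse complement
#'
#' Complements every code to the code of the complemented base set and
#' reverses the string; an involution over the full IUPAC alphabet.
#'
#' @param seq IUPAC string.
#' @return reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, IUPAC_CODES)
  if (length(bad) > 0L)
    stop("invalid IUPAC character(s): ", paste(unique(bad), collapse = ", "))
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Parse standardized 16S primer nomenclature
#'
#' Names of the form \code{S-D-Bact-<pos>-<variant>-<S|A>-<len>} encode the
#' primer's 5' position on the reference coordinate system, its strand
#' (S = sense, A = antisense) and its length. Names not following the
#' pattern (e.g. "27F") yield NULL fields rather than an error.
#'
#' @param name primer name.
#' @return list with \code{position}, \code{orientation} ("sense" or
#'   "antisense") and \code{length}, each NULL when the name does not parse.
#' @export
parse_primer_name <- function(name) {
  m <- regmatches(name,
    regexec("^S-D-Bact-([0-9]+)-[A-Za-z0-9]+-(S|A)-([0-9]+)$", name))[[1]]
  if (length(m) == 0L)
    return(list(position = NULL, orientation = NULL, length = NULL))
  list(position = as.integer(m[2]),
       orientation = if (m[3] == "S") "sense" else "antisense",
       length = as.integer(m[4]))
}

#' Nominal amplicon length from nomenclature positions
#'
#' The inclusive reference-coordinate span from the forward primer's 5'
#' start through the reverse primer's 3'-terminal position, i.e. including
#' both primer-binding regions:
#' \code{(rev_pos + rev_len - 1) - fwd_pos + 1}.
#'
#' @param fwd_pos forward primer nominal 5' position.
#' @param rev_pos reverse primer nominal 5' position (on the sense
#'   coordinate of its binding site).
#' @param rev_len reverse primer length.
#' @return integer span in bp, or NA if any input is NA.
#' @export
nominal_amplicon_length <- function(fwd_pos, rev_pos, rev_len) {
  if (anyNA(c(fwd_pos, rev_pos, rev_len))) return(NA_integer_)
  as.integer((rev_pos + rev_len - 1L) - fwd_pos + 1L)
}

#' Amplicon size class
#'
#' Small is 100-400 bp, medium >400 and <1000 bp, large >=1000 bp; lengths
#' below 100 bp or unknown lengths are "unknown". A length of exactly
#' 1000 bp, left unassigned by the published interval notation, is placed
#' in the large class.
#'
#' @param length amplicon length in bp (may be NA).
#' @return one of "small", "medium", "large", "unknown".
#' @export
assign_size_class <- function(length) {
  if (is.na(length)) return("unknown")
  if (length >= 100 && length <= 400) "small"
  else if (length > 400 && length < 1000) "medium"
  else if (length >= 1000) "large"
  else "unknown"
}

## Precomputed lookup: compat[primer_code, target_char] over the 15 codes x
## ACGT; any other target character is incompatible.
.iupac_lookup <- local({
  m <- matrix(FALSE, nrow = length(IUPAC_CODES), ncol = 4,
              dimnames = list(IUPAC_CODES, c("A", "C", "G", "T")))
  for (code in IUPAC_CODES) m[code, IUPAC_SETS[[code]]] <- TRUE
  m
})

#' Find perfect-match binding sites of a primer on a target strand
#'
#' Sense primers are scanned as written against the target (sense strand);
#' antisense primers are scanned as their IUPAC-aware reverse complement, so
#' the positions returned always refer to the 5' end of the binding site on
#' the sense strand. A site requires every primer position to be compatible
#' with the target base under \code{\link{iupac_compatible}}.
#'
#' @param seq primer sequence, IUPAC, 5' to 3'.
#' @param target target sequence (sense strand).
#' @param orientation "sense" or "antisense".
#' @return integer vector of 1-based site start positions, ascending.
#' @export
find_sites <- function(seq, target, orientation = c("sense", "antisense")) {
  orientation <- match.arg(orientation)
  query <- if (orientation == "antisense") reverse_complement(seq)
           else toupper(seq)
  qc <- strsplit(query, "", fixed = TRUE)[[1]]
  if (!all(qc %in% IUPAC_CODES))
    stop("primer contains non-IUPAC characters")
  tc <- strsplit(toupper(target), "", fixed = TRUE)[[1]]
  k <- length(qc)
  n <- length(tc)
  if (n < k) return(integer(0))
  ## target chars -> column index in the lookup; non-ACGT -> NA (never match)
  tcol <- match(tc, c("A", "C", "G", "T"))
  ok <- rep(TRUE, n - k + 1L)
  for (j in seq_len(k)) {
    cols <- tcol[j:(j + n - k)]
    hit <- unname(.iupac_lookup[qc[j], ])
    ok <- ok & !is.na(cols) & hit[cols]
  }
  which(ok)
}

#' Extract the in-silico amplicon of a primer pair from one target
#'
#' Candidate amplicons pair a forward binding site strictly upstream of a
#' reverse binding site, spanning the forward primer's 5' position through
#' the reverse binding site's 3' position (both binding regions included).
#' Among candidates with span within \code{[min_len, max_len]} the shortest
#' span wins, ties broken by the smallest forward position (mimicking
#' preferential amplification of shorter products).
#'
#' @param pair one-row primer-pair data.frame (or list) with \code{fwd_seq}
#'   and \code{rev_seq}.
#' @param target target sequence string.
#' @param min_len,max_len span guards in bp.
#' @return list with \code{start}, \code{end} (1-based inclusive, sense
#'   strand) and \code{amplicon} (the substring), or \code{NULL} when the
#'   pair has no valid pair of sites.
#' @export
evaluate_pair <- function(pair, target, min_len = 50L, max_len = 3000L) {
  f_sites <- find_sites(pair$fwd_seq, target, "sense")
  if (length(f_sites) == 0L) return(NULL)
  r_sites <- find_sites(pair$rev_seq, target, "antisense")
  if (length(r_sites) == 0L) return(NULL)
  r_len <- nchar(pair$rev_seq)
  best <- NULL
  for (r in r_sites) {
    r_end <- r + r_len - 1L
    for (f in f_sites) {
      if (f >= r) next             # forward strictly upstream of the site
      span <- r_end - f + 1L
      if (span < min_len || span > max_len) next
      if (is.null(best) || span < best$span ||
          (span == best$span && f < best$start)) {
        best <- list(start = f, end = r_end, span = span)
      }
    }
  }
  if (is.null(best)) return(NULL)
  list(start = best$start, end = best$end,
       amplicon = substr(target, best$start, best$end))
}

#' Extract amplicons of one pair across a reference set
#'
#' @param pair one-row primer-pair data.frame.
#' @param refs reference set.
#' @inheritParams evaluate_pair
#' @return data.frame with one row per matched target: \code{seq_id},
#'   \code{pair_id}, \code{start}, \code{end}, \code{amplicon}.
#' @export
extract_amplicons <- function(pair, refs, min_len = 50L, max_len = 3000L) {
  hits <- lapply(seq_len(nrow(refs)), function(i) {
    a <- evaluate_pair(pair, refs$sequence[i], min_len, max_len)
    if (is.null(a)) return(NULL)
    data.frame(seq_id = refs$id[i], pair_id = pair$pair_id,
               start = a$start, end = a$end, amplicon = a$amplicon,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(seq_id = character(0), pair_id = character(0),
                      start = integer(0), end = integer(0),
                      amplicon = character(0), stringsAsFactors = FALSE)
  out
}

#' Perfect-match coverage of primer pairs per taxon
#'
#' For every (pair, taxon) combination, the fraction of the taxon's
#' sequences from which the pair extracts a valid amplicon
#' (\code{\link{evaluate_pair}} returns a record).
#'
#' @param pairs primer-pair data.frame (one or more rows).
#' @param taxa named list of id vectors (see \code{\link{taxon_sets}}).
#' @param refs reference set resolving every member id.
#' @inheritParams evaluate_pair
#' @return data.frame with columns \code{pair_id}, \code{taxon},
#'   \code{n_targets}, \code{n_matched}, \code{coverage}.
#' @export
coverage_by_taxon <- function(pairs, taxa, refs, min_len = 50L,
                              max_len = 3000L) {
  if (length(taxa) == 0L) stop("no taxa supplied")
  if (any(lengths(taxa) == 0L))
    stop("empty taxon set(s): ",
         paste(names(taxa)[lengths(taxa) == 0L], collapse = ", "))
  unresolved <- setdiff(unique(unlist(taxa)), refs$id)
  if (length(unresolved) > 0L)
    stop("taxon member id(s) not in reference set: ",
         paste(unresolved, collapse = ", "))
  seq_of <- stats::setNames(refs$sequence, refs$id)
  rows <- list()
  for (p in seq_len(nrow(pairs))) {
    pair <- pairs[p, , drop = FALSE]
    ## match status per unique member id, computed once per pair
    ids <- unique(unlist(taxa))
    matched <- vapply(ids, function(sid)
      !is.null(evaluate_pair(pair, seq_of[[sid]], min_len, max_len)),
      logical(1))
    names(matched) <- ids
    for (tx in names(taxa)) {
      members <- taxa[[tx]]
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = pair$pair_id, taxon = tx,
        n_targets = length(members),
        n_matched = sum(matched[members]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$coverage <- out$n_matched / out$n_targets
  out
}

#' Coverage of a pair over a whole reference set
#'
#' The same computation as \code{\link{coverage_by_taxon}} with a single
#' taxon holding every sequence; used to re-check high-coverage pairs
#' against a broader (all-Bacteria-like) reference set.
#'
#' @param pair one-row primer-pair data.frame.
#' @param refs reference set.
#' @inheritParams evaluate_pair
#' @return coverage fraction in [0, 1].
#' @export
overall_coverage <- function(pair, refs, min_len = 50L, max_len = 3000L) {
  tab <- coverage_by_taxon(pair, list(all = refs$id), refs, min_len, max_len)
  tab$coverage
}

#' Retain primer pairs with high coverage for every taxon
#'
#' @param table coverage table from \code{\link{coverage_by_taxon}},
#'   complete over all (pair, taxon) combinations.
#' @param min_cov minimum coverage, inclusive ("at least"); default 0.95.
#' @return character vector of pair_ids whose coverage is >= \code{min_cov}
#'   for EVERY taxon.
#' @export
filter_min_coverage <- function(table, min_cov = 0.95) {
  keep <- tapply(table$coverage >= min_cov, table$pair_id, all)
  names(keep)[keep]
}

#' Histogram of coverage values in 10% bins
#'
#' Bins are [0,10), [10,20), ..., [90,100] in percent (the top bin is
#' closed). Counts are reported per (taxon, size_class, bin) and sum to the
#' number of pairs per (taxon, size_class) panel.
#'
#' @param table coverage table with a \code{size_class} column (join the
#'   primer table if needed).
#' @param bin_width bin width in percent (default 10).
#' @return data.frame with \code{taxon}, \code{size_class}, \code{bin_lo},
#'   \code{bin_hi}, \code{count}.
#' @export
coverage_histogram <- function(table, bin_width = 10) {
  lo <- seq(0, 100 - bin_width, by = bin_width)
  hi <- lo + bin_width
  pct <- table$coverage * 100
  bin <- pmin(floor(pct / bin_width), length(lo) - 1L) + 1L  # 100% -> top bin
  panels <- unique(table[, c("taxon", "size_class")])
  rows <- lapply(seq_len(nrow(panels)), function(i) {
    sel <- table$taxon == panels$taxon[i] &
      table$size_class == panels$size_class[i]
    counts <- tabulate(bin[sel], nbins = length(lo))
    data.frame(taxon = panels$taxon[i], size_class = panels$size_class[i],
               bin_lo = lo, bin_hi = hi, count = counts,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
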