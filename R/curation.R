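#' Collapse identical sequences into single records
#'
#' One record is kept per distinct sequence string; abundances of merged
#' duplicates are summed and the id of the first-seen duplicate is kept.
#' Output is ordered by descending abundance, ties broken lexicographically
#' by id, which fixes the processing order of the greedy clustering.
#'
#' @param refs a reference set.
#' @return dereplicated reference set.
#' @export
dereplicate <- function(refs) {
  if (nrow(refs) == 0L) return(refs)
  first <- !duplicated(refs$sequence)
  key <- match(refs$sequence, refs$sequence[first])
  out <- refs[first, , drop = FALSE]
  out$abundance <- as.integer(tapply(refs$abundance, key, sum))
  out <- out[order(-out$abundance, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Global (Needleman-Wunsch, affine) alignment with the package's fixed
## scoring: match +1, mismatch -1, gap open -2 plus -1 per gap position.
## Vectorized over `a`: every sequence in `a` is aligned to the single
## sequence `b` in one C call. Returns parallel character vectors of
## gapped strings.
align_global_many <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 2, gapExtension = 1)
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)))
}

align_global <- function(a, b) {
  g <- align_global_many(a, b)
  list(a = g$a[1L], b = g$b[1L])
}

## Identity of each sequence in `seqs` against `ref` (same metric as
## pairwise_identity), vectorized in C.
identity_to_ref <- function(seqs, ref, band = NULL) {
  if (is.null(band)) band <- max(nchar(seqs), nchar(ref))
  .banded_identity(seqs, ref, as.integer(band))
}

#' Pairwise sequence identity
#'
#' Identity of the global alignment of two sequences (match +1, mismatch
#' -1, gap open -2, gap extend -1 per position): matching columns divided
#' by alignment columns, excluding terminal-gap columns (columns before
#' the first or after the last aligned position of either sequence).
#' Internal gap columns count in the denominator. The default is the
#' exact full alignment; a finite \code{band} restricts the dynamic
#' program to a diagonal band of that half-width, exact whenever the
#' optimal path stays inside it -- always the case for the highly similar
#' pairs on which the 97% clustering decision turns.
#'
#' @param a,b non-empty sequence strings.
#' @param band diagonal band half-width; \code{NULL} (default) for the
#'   full alignment.
#' @return identity fraction in [0, 1].
#' @export
pairwise_identity <- function(a, b, band = NULL) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (is.null(band)) band <- max(nchar(a), nchar(b))
  .banded_identity(a, b, as.integer(band))[1L]
}

## Columns inside both sequences' first..last non-gap positions.
aligned_core <- function(ac, bc) {
  na <- which(ac != "-")
  nb <- which(bc != "-")
  lo <- max(na[1L], nb[1L])
  hi <- min(na[length(na)], nb[length(nb)])
  if (lo > hi) integer(0) else lo:hi
}

#' Greedy centroid clustering into OTUs
#'
#' Records are processed in descending abundance (ties broken
#' lexicographically by id, the order \code{\link{dereplicate}} emits). A
#' record joins the first existing centroid with identity >= threshold;
#' otherwise it founds a new OTU with itself as centroid. The centroid is by
#' construction the most abundant unique sequence in its OTU and serves as
#' the representative. With \code{assign = "best"} a record instead joins
#' the centroid of highest identity among those above threshold.
#'
#' @param refs dereplicated reference set.
#' @param threshold identity threshold (default 0.97).
#' @param assign "first" (default greedy dialect) or "best".
#' @param band band half-width for the banded identity alignment (see
#'   \code{\link{pairwise_identity}}); wide enough to be exact for any
#'   pair near the clustering threshold.
#' @return data.frame with one row per record: \code{id}, \code{otu}
#'   (integer cluster index), \code{representative_id},
#'   \code{is_representative}.
#' @export
cluster_otus <- function(refs, threshold = 0.97,
                         assign = c("first", "best"), band = 64L) {
  assign <- match.arg(assign)
  ord <- order(-refs$abundance, refs$id)
  refs <- refs[ord, , drop = FALSE]
  ## conservative 8-mer prescreen: sequences at >= 90% identity share far
  ## more than 40% of their 8-mers, so pairs below the cutoff cannot reach
  ## a 97% threshold and skip the alignment entirely
  words <- lapply(refs$sequence, function(s)
    if (nchar(s) >= 8L) extract_words(s, 8L) else integer(0))
  word_screen <- threshold >= 0.93
  shared_frac <- function(a, b) {
    if (length(a) == 0L || length(b) == 0L) return(1)
    length(intersect(a, b)) / min(length(a), length(b))
  }
  centroids <- integer(0)              # row indices of centroids
  otu <- integer(nrow(refs))
  for (i in seq_len(nrow(refs))) {
    cand <- centroids
    if (word_screen && length(cand) > 0L) {
      pass <- vapply(cand, function(ci)
        shared_frac(words[[i]], words[[ci]]) >= 0.4, logical(1))
      cand <- cand[pass]
    }
    hit <- 0L
    if (length(cand) > 0L) {
      ident <- identity_to_ref(refs$sequence[cand], refs$sequence[i], band)
      above <- which(ident >= threshold)
      if (length(above) > 0L) {
        ci <- if (assign == "first") above[1L]
              else above[which.max(ident[above])]
        hit <- match(cand[ci], centroids)
      }
    }
    if (hit == 0L) {
      centroids <- c(centroids, i)
      otu[i] <- length(centroids)
    } else {
      otu[i] <- hit
    }
  }
  data.frame(id = refs$id, otu = otu,
             representative_id = refs$id[centroids[otu]],
             is_representative = seq_len(nrow(refs)) %in% centroids,
             stringsAsFactors = FALSE)
}

#' Align records to a fixed-coordinate template
#'
#' Each record is globally aligned to the (ungapped) template reference and
#' projected onto the template's columns: record bases falling on template
#' columns are placed there, and record positions inserted relative to the
#' template are DISCARDED (their count is reported per record). The output
#' therefore has exactly the template's width, preserving the fixed
#' coordinates needed for downstream column filtering. Records with fewer
#' than half their bases alignable to the template are dropped with a
#' warning.
#'
#' @param refs reference set to align.
#' @param template a \code{seq_alignment} whose first row is the reference;
#'   it may contain gap columns, which are preserved in the output
#'   coordinates.
#' @return a \code{seq_alignment} of the aligned records (template rows not
#'   included), with attribute \code{discarded} (named integer vector of
#'   discarded insertion counts) and attribute \code{dropped} (ids of
#'   records that failed the 50% rule).
#' @export
align_to_template <- function(refs, template) {
  if (length(template$ids) < 1L) stop("template needs at least one row")
  tmpl_row <- strsplit(template$rows[1L], "", fixed = TRUE)[[1]]
  base_cols <- which(tmpl_row != "-")       # template columns holding bases
  tmpl_seq <- paste(tmpl_row[base_cols], collapse = "")
  ids <- character(0); rows <- character(0)
  discarded <- integer(0); dropped <- character(0)
  g_all <- if (nrow(refs) > 0L) align_global_many(refs$sequence, tmpl_seq)
           else list(a = character(0), b = character(0))
  for (i in seq_len(nrow(refs))) {
    rc <- strsplit(g_all$a[i], "", fixed = TRUE)[[1]]
    tc <- strsplit(g_all$b[i], "", fixed = TRUE)[[1]]
    placed <- rep("-", length(base_cols))
    tpos <- cumsum(tc != "-")              # template base index per column
    keep <- tc != "-"
    placed[tpos[keep]] <- rc[keep]
    n_ins <- sum(!keep & rc != "-")        # record bases with no template col
    n_placed <- sum(rc[keep] != "-")
    if (n_placed < 0.5 * nchar(refs$sequence[i])) {
      warning("record '", refs$id[i],
              "' aligned over less than half its length; dropped")
      dropped <- c(dropped, refs$id[i])
      next
    }
    out_row <- rep("-", template$width)
    out_row[base_cols] <- placed
    ids <- c(ids, refs$id[i])
    rows <- c(rows, paste(out_row, collapse = ""))
    discarded[refs$id[i]] <- n_ins
  }
  aln <- new_alignment(ids, rows)
  attr(aln, "discarded") <- discarded
  attr(aln, "dropped") <- dropped
  aln
}

#' Remove alignment columns that are mostly gaps
#'
#' Columns whose gap fraction is at least \code{max_gap_fraction} are
#' removed ("at least": the boundary value is removed); other columns keep
#' their order. Intended to strip automatic-aligner artifacts before
#' distance computation.
#'
#' @param aln a \code{seq_alignment}.
#' @param max_gap_fraction removal threshold (default 0.90).
#' @return the filtered \code{seq_alignment}, with attribute
#'   \code{removed_columns} (indices removed, in original coordinates).
#' @export
filter_gap_columns <- function(aln, max_gap_fraction = 0.90) {
  if (length(aln$ids) == 0L) stop("empty alignment")
  m <- alignment_matrix(aln)
  gap_frac <- colMeans(m == "-")
  drop <- which(gap_frac >= max_gap_fraction)
  if (length(drop) == ncol(m))
    stop("all columns removed: degenerate alignment")
  keep <- m[, setdiff(seq_len(ncol(m)), drop), drop = FALSE]
  out <- new_alignment(aln$ids, apply(keep, 1, paste, collapse = ""))
  attr(out, "removed_columns") <- drop
  out
}
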