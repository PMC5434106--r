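#' Pairwise distance matrix from an alignment
#'
#' Distances use pairwise deletion: for each pair, columns where either row
#' has a gap or a non-ACGT character are excluded. The p-distance is
#' mismatches over compared columns; the Jukes-Cantor correction (the
#' default, matching the uniform-substitution model of the synthetic
#' generator) is -(3/4) log(1 - 4p/3), defined only for p < 0.75.
#'
#' @param aln a \code{seq_alignment} with at least 3 rows.
#' @param correction "jukes_cantor" (default) or "none".
#' @return symmetric numeric matrix (substitutions per site) with zero
#'   diagonal, dimnames = row ids.
#' @export
distance_matrix <- function(aln, correction = c("jukes_cantor", "none")) {
  correction <- match.arg(correction)
  if (length(aln$ids) < 3L) stop("need at least 3 sequences")
  distance_from_matrix(alignment_matrix(aln), correction)
}

## Vectorized pairwise-deletion distances from a character matrix: match
## and comparable-column counts via cross-products of base indicators.
distance_from_matrix <- function(m, correction = "jukes_cantor") {
  ids <- rownames(m)
  matches <- matrix(0, nrow(m), nrow(m))
  valid <- matrix(FALSE, nrow(m), ncol(m))
  for (b in c("A", "C", "G", "T")) {
    ind <- m == b
    matches <- matches + tcrossprod(ind * 1)
    valid <- valid | ind
  }
  comp <- tcrossprod(valid * 1)
  off <- upper.tri(comp)
  if (any(comp[off] == 0)) {
    bad <- which(comp == 0 & upper.tri(comp), arr.ind = TRUE)[1L, ]
    stop("no comparable columns between '", ids[bad[1]], "' and '",
         ids[bad[2]], "'")
  }
  p <- 1 - matches / comp
  if (correction == "jukes_cantor") {
    if (any(p[off] >= 0.75)) {
      bad <- which(p >= 0.75 & upper.tri(p), arr.ind = TRUE)[1L, ]
      stop("saturated distance (p >= 0.75) between '", ids[bad[1]],
           "' and '", ids[bad[2]], "'")
    }
    p <- -0.75 * log(1 - 4 * p / 3)
  }
  diag(p) <- 0
  dimnames(p) <- list(ids, ids)
  (p + t(p)) / 2   # enforce exact symmetry against float asymmetry
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Ties in Q are
#' broken by the smallest (i, j) index pair in the current matrix order, so
#' the result is deterministic. Negative estimated branch lengths are
#' clamped to zero with the deficit added to the sister branch, preserving
#' the path length between the joined pair. The returned tree is unrooted.
#'
#' @param dm symmetric distance matrix with >= 3 taxa and dimnames.
#' @return an \code{ape} \code{phylo} object.
#' @export
neighbor_joining <- function(dm) {
  if (!isSymmetric(unname(dm)) || any(dm < 0) || any(diag(dm) != 0))
    stop("invalid distance matrix")
  n <- nrow(dm)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(dm)
  if (is.null(labels)) stop("distance matrix needs dimnames")
  ## each active node is a Newick fragment
  node <- labels
  d <- dm
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    ## smallest (i, j), i < j, among minima
    qmin <- min(q)
    cand <- which(q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    merged <- sprintf("(%s:%.15g,%s:%.15g)", node[i], li, node[j], lj)
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    node <- c(node[keep], merged)
    rownames(d2) <- colnames(d2) <- seq_len(m - 1L)
    d <- d2
  }
  ## resolve the final three nodes around the central vertex
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  newick <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                    node[1], la, node[2], lb, node[3], lc)
  ape::read.tree(text = newick)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Alignment columns are resampled with replacement per replicate, the tree
#' is rebuilt, and the support of each internal edge of the full-data tree
#' is the percentage of replicate trees containing the same bipartition.
#' Supports are stored as integer-rounded node labels.
#'
#' @param aln a \code{seq_alignment}.
#' @param n_reps number of bootstrap replicates (default 100); 0 returns
#'   the full-data tree with no supports.
#' @param seed integer seed for the column resampling.
#' @param correction passed to \code{\link{distance_matrix}}.
#' @return a \code{phylo} with \code{node.label} carrying supports in
#'   [0, 100] (NA for the root pseudo-node).
#' @export
bootstrap_support <- function(aln, n_reps = 100L, seed = 1L,
                              correction = "jukes_cantor") {
  full <- neighbor_joining(distance_matrix(aln, correction))
  if (n_reps == 0L) return(full)
  m <- alignment_matrix(aln)
  boots <- withr_seed(seed, {
    lapply(seq_len(n_reps), function(b) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      neighbor_joining(distance_from_matrix(m[, cols, drop = FALSE],
                                            correction))
    })
  })
  counts <- ape::prop.clades(full, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / n_reps)
  full$node.label <- as.character(support)
  full
}

## Evaluate expr with a local RNG seeded at `seed`, restoring global state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Check genus monophyly around type-strain anchors
#'
#' The tree is rooted on the outgroup leaf and the smallest rooted clade
#' containing all anchors together with every leaf labeled with the anchor
#' genus is inspected. The genus is monophyletic iff every
#' leaf of that clade carries the anchor genus label or no genus label at
#' all (environmental sequences without genus labels do not break
#' monophyly; clade membership is the genus call). When monophyletic, the
#' whole clade is selected into the validated genus set; otherwise only the
#' anchors are kept (the conservative fallback for poorly supported
#' groups).
#'
#' @param tree a \code{phylo}, optionally with supports in
#'   \code{node.label}.
#' @param anchor_ids type-strain leaf ids anchoring the genus.
#' @param outgroup_id leaf id to root on.
#' @param genus_labels named character vector id -> genus ("" = unlabeled).
#' @param genus the anchor genus name (default: label of the first anchor).
#' @return list with \code{genus}, \code{anchor_ids},
#'   \code{is_monophyletic}, \code{clade_member_ids}, \code{support}
#'   (bootstrap value of the clade's subtending edge, NA if absent) and
#'   \code{selected_ids}.
#' @export
check_monophyly <- function(tree, anchor_ids, outgroup_id, genus_labels,
                            genus = NULL) {
  miss <- setdiff(c(anchor_ids, outgroup_id), tree$tip.label)
  if (length(miss) > 0L)
    stop("leaf id(s) not in tree: ", paste(miss, collapse = ", "))
  if (is.null(genus)) genus <- unname(genus_labels[anchor_ids[1L]])
  rooted <- ape::root(tree, outgroup = outgroup_id, resolve.root = TRUE,
                      edgelabel = TRUE)
  ## the candidate clade spans every leaf labeled with the genus plus the
  ## anchors; the genus is monophyletic iff that clade contains no leaf of
  ## a different genus (genus-unlabeled leaves inside do not break it)
  lab <- genus_labels[rooted$tip.label]
  lab[is.na(lab)] <- ""
  group_ids <- union(anchor_ids,
                     rooted$tip.label[lab == genus & nzchar(genus)])
  tips <- match(group_ids, rooted$tip.label)
  if (length(tips) == 1L) {
    clade_ids <- group_ids
    support <- NA_real_
  } else {
    mrca <- ape::getMRCA(rooted, tips)
    clade_ids <- ape::extract.clade(rooted, mrca)$tip.label
    support <- if (!is.null(rooted$node.label)) {
      nl <- rooted$node.label[mrca - ape::Ntip(rooted)]
      suppressWarnings(as.numeric(nl))
    } else NA_real_
  }
  clade_genera <- unname(genus_labels[clade_ids])
  clade_genera[is.na(clade_genera)] <- ""
  mono <- all(clade_genera %in% c(genus, ""))
  list(genus = genus,
       anchor_ids = anchor_ids,
       is_monophyletic = mono,
       clade_member_ids = clade_ids,
       support = support,
       selected_ids = if (mono) clade_ids else anchor_ids)
}
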