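#' Configuration of the end-to-end analysis
#'
#' Aggregates the thresholds used across the stages: 97% OTU identity, 90%
#' gap-column filtering, 100 bootstrap replicates for tree support, 95%
#' minimum primer coverage, word size 8 and 100 bootstrap replicates for
#' the classifier, one top-level seed feeding every source of randomness.
#'
#' @param identity_threshold OTU clustering identity (default 0.97).
#' @param gap_threshold gap-column removal fraction (default 0.90).
#' @param tree_boot_reps bootstrap replicates for the NJ tree.
#' @param min_coverage minimum per-taxon coverage (default 0.95).
#' @param nbc_k classifier word size (default 8).
#' @param nbc_boot_reps classifier bootstrap replicates (default 100).
#' @param min_conf confidence threshold for the classification report.
#' @param min_len,max_len amplicon span guards in bp.
#' @param seed top-level integer seed.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(identity_threshold = 0.97,
                            gap_threshold = 0.90,
                            tree_boot_reps = 100L,
                            min_coverage = 0.95,
                            nbc_k = 8L,
                            nbc_boot_reps = 100L,
                            min_conf = 0.80,
                            min_len = 50L, max_len = 3000L,
                            seed = 1L) {
  cfg <- list(identity_threshold = identity_threshold,
              gap_threshold = gap_threshold,
              tree_boot_reps = as.integer(tree_boot_reps),
              min_coverage = min_coverage,
              nbc_k = as.integer(nbc_k),
              nbc_boot_reps = as.integer(nbc_boot_reps),
              min_conf = min_conf,
              min_len = as.integer(min_len),
              max_len = as.integer(max_len),
              seed = as.integer(seed))
  for (v in c(cfg$identity_threshold, cfg$gap_threshold, cfg$min_coverage))
    if (v < 0 || v > 1) stop("thresholds must lie in [0, 1]")
  if (cfg$tree_boot_reps < 0L || cfg$nbc_boot_reps < 0L)
    stop("bootstrap replicate counts must be >= 0")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full primer-evaluation analysis
#'
#' Executes the whole chain on an in-memory reference set:
#' dereplication; greedy OTU clustering; template-based alignment of the
#' OTU representatives plus all type strains; gap-column filtering;
#' post-filter dereplication; Jukes-Cantor distances; neighbor-joining
#' with bootstrap support; per-genus monophyly validation anchored on type
#' strains (rooted on the outgroup); assembly of validated taxon sets
#' (every member of every OTU whose representative sits in a validated
#' clade); perfect-match coverage of every primer pair per validated
#' taxon; the >= min_coverage filter; overall coverage of the survivors
#' against the full set; amplicon extraction for the recommended pair (the
#' medium-size-class survivor with the highest mean per-taxon coverage,
#' ties broken by the smaller nominal amplicon); and genus-classification
#' testing of those amplicons with a model trained on full-length
#' sequences disjoint from the evaluation targets.
#'
#' @param refs reference set (genus labels and type-strain flags set).
#' @param pairs primer-pair table (see \code{\link{read_primer_table}} /
#'   \code{\link{annotate_primer_pairs}}).
#' @param template single-row \code{seq_alignment} fixing alignment
#'   coordinates.
#' @param outgroup_genus genus treated as outgroup for rooting; its first
#'   type strain (or first member) is the rooting leaf and the genus is
#'   excluded from coverage targets.
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir optional directory; when given, every intermediate
#'   artifact and a run log are written (deterministically, no
#'   timestamps).
#' @return a report bundle: list with elements \code{derep}, \code{otus},
#'   \code{alignment}, \code{tree}, \code{clades}, \code{validated_taxa},
#'   \code{coverage}, \code{passing_pairs}, \code{overall},
#'   \code{recommended_pair}, \code{amplicons}, \code{classification},
#'   \code{log} (character vector of stage counts).
#' @export
run_pipeline <- function(refs, pairs, template, outgroup_genus,
                         config = pipeline_config(), out_dir = NULL) {
  if (nrow(pairs) == 0L) stop("no primer pairs")
  validate_reference_set(refs)
  log <- c(sprintf("seed: %d", config$seed),
           sprintf("input sequences: %d", nrow(refs)))

  ## --- curation ---------------------------------------------------------
  derep <- dereplicate(refs)
  log <- c(log, sprintf("dereplicated: %d", nrow(derep)))
  otus <- cluster_otus(derep, config$identity_threshold)
  log <- c(log, sprintf("otus: %d", length(unique(otus$otu))))
  rep_ids <- unique(otus$representative_id)
  ts_ids <- derep$id[derep$is_type_strain]
  phylo_ids <- union(rep_ids, ts_ids)
  phylo_refs <- derep[match(phylo_ids, derep$id), , drop = FALSE]
  aln <- align_to_template(phylo_refs, template)
  aln <- filter_gap_columns(aln, config$gap_threshold)
  log <- c(log, sprintf("alignment: %d rows x %d columns",
                        length(aln$ids), aln$width))
  ## post-filter dereplication: collapse rows identical after filtering
  keep <- !duplicated(aln$rows)
  aln <- new_alignment(aln$ids[keep], aln$rows[keep])
  log <- c(log, sprintf("post-filter unique rows: %d", length(aln$ids)))

  ## --- phylogeny --------------------------------------------------------
  tree <- bootstrap_support(aln, config$tree_boot_reps, seed = config$seed)
  genus_of_id <- stats::setNames(derep$genus, derep$id)
  out_members <- derep$id[derep$genus == outgroup_genus]
  if (length(out_members) == 0L)
    stop("outgroup genus '", outgroup_genus, "' has no sequences")
  out_ts <- derep$id[derep$genus == outgroup_genus & derep$is_type_strain]
  outgroup_id <- if (length(out_ts) > 0L) out_ts[1L] else out_members[1L]
  if (!outgroup_id %in% tree$tip.label)
    stop("outgroup leaf '", outgroup_id, "' absent from tree")
  target_genera <- setdiff(sort(unique(derep$genus[nzchar(derep$genus)])),
                           outgroup_genus)
  clades <- lapply(target_genera, function(g) {
    anchors <- intersect(derep$id[derep$genus == g & derep$is_type_strain],
                         tree$tip.label)
    if (length(anchors) == 0L)
      anchors <- intersect(derep$id[derep$genus == g], tree$tip.label)[1L]
    check_monophyly(tree, anchors, outgroup_id, genus_of_id, genus = g)
  })
  names(clades) <- target_genera

  ## --- validated taxon sets --------------------------------------------
  ## a validated genus set contains every ORIGINAL sequence belonging to an
  ## OTU whose representative (or type strain) was selected in the clade
  seq_to_derep <- derep$id[match(refs$sequence, derep$sequence)]
  validated_taxa <- lapply(clades, function(cl) {
    sel_otus <- unique(otus$otu[otus$id %in% cl$selected_ids])
    derep_members <- otus$id[otus$otu %in% sel_otus]
    refs$id[seq_to_derep %in% derep_members]
  })
  validated_taxa <- validated_taxa[lengths(validated_taxa) > 0L]
  log <- c(log, sprintf("validated taxa: %d (%s)", length(validated_taxa),
                        paste(sprintf("%s=%d", names(validated_taxa),
                                      lengths(validated_taxa)),
                              collapse = ", ")))
  if (length(validated_taxa) == 0L) stop("no validated taxon sets")

  ## --- primer coverage --------------------------------------------------
  coverage <- coverage_by_taxon(pairs, validated_taxa, refs,
                                config$min_len, config$max_len)
  ## pairs without nomenclature-derived lengths get their size class from
  ## the median realized amplicon length across matched targets
  member_refs <- refs[refs$id %in% unlist(validated_taxa), , drop = FALSE]
  for (p in which(pairs$size_class == "unknown")) {
    amp <- extract_amplicons(pairs[p, , drop = FALSE], member_refs,
                             config$min_len, config$max_len)
    if (nrow(amp) > 0L)
      pairs$size_class[p] <- assign_size_class(
        as.integer(stats::median(amp$end - amp$start + 1L)))
  }
  coverage$size_class <- pairs$size_class[match(coverage$pair_id,
                                                pairs$pair_id)]
  passing <- filter_min_coverage(coverage, config$min_coverage)
  log <- c(log, sprintf("pairs passing %.0f%% coverage: %d",
                        100 * config$min_coverage, length(passing)))
  overall <- vapply(passing, function(pid)
    overall_coverage(pairs[pairs$pair_id == pid, , drop = FALSE], refs,
                     config$min_len, config$max_len), numeric(1))

  ## --- recommended pair and classification test ------------------------
  rec <- recommend_pair(coverage, pairs, passing)
  amplicons <- NULL; classification <- NULL
  if (!is.null(rec)) {
    log <- c(log, sprintf("recommended pair: %s", rec$pair_id))
    eval_ids <- unlist(lapply(validated_taxa, function(ids)
      ids[seq_along(ids) %% 2L == 0L]))      # held-out halves, by position
    train_ids <- setdiff(unlist(validated_taxa), eval_ids)
    train_refs <- refs[refs$id %in% train_ids, , drop = FALSE]
    eval_refs <- refs[refs$id %in% eval_ids, , drop = FALSE]
    ## drop eval sequences whose full-length string also occurs in training
    eval_refs <- eval_refs[!(eval_refs$sequence %in% train_refs$sequence), ,
                           drop = FALSE]
    model <- nbc_train(train_refs, config$nbc_k)
    amplicons <- extract_amplicons(rec, eval_refs,
                                   config$min_len, config$max_len)
    if (nrow(amplicons) > 0L) {
      amplicons$genus <- eval_refs$genus[match(amplicons$seq_id,
                                               eval_refs$id)]
      classification <- evaluate_amplicon_classification(
        model, amplicons, config$nbc_boot_reps, config$seed,
        config$min_conf)
      log <- c(log, sprintf("amplicons classified: %d",
                            nrow(classification$calls)))
    }
  } else {
    log <- c(log, "recommended pair: none (no medium-class survivor)")
  }

  bundle <- list(derep = derep, otus = otus, alignment = aln, tree = tree,
                 clades = clades, validated_taxa = validated_taxa,
                 coverage = coverage, passing_pairs = passing,
                 overall = overall, recommended_pair = rec,
                 amplicons = amplicons, classification = classification,
                 config = config, log = log)
  if (!is.null(out_dir)) write_bundle(bundle, refs, out_dir)
  bundle
}

## The medium-size-class pair passing the coverage filter with the highest
## mean per-taxon coverage; ties broken by smaller nominal amplicon, then
## pair_id. NULL when no medium-class pair passes.
recommend_pair <- function(coverage, pairs, passing) {
  med <- pairs[pairs$pair_id %in% passing &
                 pairs$size_class == "medium", , drop = FALSE]
  if (nrow(med) == 0L) return(NULL)
  mean_cov <- vapply(med$pair_id, function(pid)
    mean(coverage$coverage[coverage$pair_id == pid]), numeric(1))
  nl <- med$nominal_length
  nl[is.na(nl)] <- .Machine$integer.max
  ord <- order(-mean_cov, nl, med$pair_id)
  med[ord[1L], , drop = FALSE]
}

write_bundle <- function(bundle, refs, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_fasta(bundle$derep, file.path(out_dir, "dereplicated.fasta"))
  tsv(bundle$otus, "otus.tsv")
  writeLines(sprintf(">%s\n%s", bundle$alignment$ids,
                     bundle$alignment$rows),
             file.path(out_dir, "filtered_alignment.fasta"))
  ape::write.tree(bundle$tree, file.path(out_dir, "tree.nwk"))
  clade_df <- do.call(rbind, lapply(bundle$clades, function(cl)
    data.frame(genus = cl$genus, is_monophyletic = cl$is_monophyletic,
               support = cl$support, n_selected = length(cl$selected_ids),
               stringsAsFactors = FALSE)))
  tsv(clade_df, "clades.tsv")
  tsv(bundle$coverage, "coverage.tsv")
  writeLines(bundle$passing_pairs, file.path(out_dir, "passing_pairs.txt"))
  if (length(bundle$overall) > 0L)
    tsv(data.frame(pair_id = names(bundle$overall),
                   overall_coverage = unname(bundle$overall)),
        "overall_coverage.tsv")
  if (!is.null(bundle$amplicons) && nrow(bundle$amplicons) > 0L)
    tsv(bundle$amplicons, "amplicons.tsv")
  if (!is.null(bundle$classification)) {
    tsv(bundle$classification$calls, "classification_calls.tsv")
    tsv(bundle$classification$by_genus, "classification_by_genus.tsv")
  }
  hist <- coverage_histogram(bundle$coverage)
  tsv(hist, "coverage_histogram.tsv")
  writeLines(bundle$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Summary report of a pipeline bundle
#'
#' Assembles the human-readable pieces: the ranked primer-pair table
#' (mean per-taxon coverage, size class, pass/fail), the per-panel
#' coverage histogram, and the per-genus classification accuracy table.
#'
#' @param bundle result of \code{\link{run_pipeline}}.
#' @return list with \code{ranked_pairs}, \code{histogram},
#'   \code{classification} data.frames.
#' @export
make_report <- function(bundle) {
  cov <- bundle$coverage
  ids <- unique(cov$pair_id)
  ranked <- data.frame(
    pair_id = ids,
    size_class = cov$size_class[match(ids, cov$pair_id)],
    mean_coverage = vapply(ids, function(p)
      mean(cov$coverage[cov$pair_id == p]), numeric(1)),
    min_coverage = vapply(ids, function(p)
      min(cov$coverage[cov$pair_id == p]), numeric(1)),
    passes = ids %in% bundle$passing_pairs,
    stringsAsFactors = FALSE)
  ranked <- ranked[order(-ranked$mean_coverage, ranked$pair_id), ,
                   drop = FALSE]
  rownames(ranked) <- NULL
  list(ranked_pairs = ranked,
       histogram = coverage_histogram(cov),
       classification = if (!is.null(bundle$classification))
         bundle$classification$by_genus else NULL)
}

#' Plot coverage histograms per taxon and size class
#'
#' Faceted bar panels of the 10%-bin coverage histogram, one panel per
#' (taxon, size class); requires ggplot2.
#'
#' @param histogram output of \code{\link{coverage_histogram}}.
#' @return a ggplot object.
#' @export
plot_coverage_histogram <- function(histogram) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  histogram$bin <- sprintf("%d-%d", histogram$bin_lo, histogram$bin_hi)
  histogram$bin <- factor(histogram$bin,
                          levels = unique(histogram$bin[order(histogram$bin_lo)]))
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(size_class ~ taxon) +
    ggplot2::labs(x = "coverage (%)", y = "primer pairs") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
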