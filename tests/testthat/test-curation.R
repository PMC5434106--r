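test_that("dereplication merges duplicates, sums abundance, is idempotent", {
  refs <- reference_set(c("x1", "x2", "x3", "y1"),
                        c("AAAT", "AAAT", "AAAT", "CCCG"),
                        abundance = c(1L, 2L, 1L, 1L))
  d <- dereplicate(refs)
  expect_equal(nrow(d), 2L)
  expect_equal(d$abundance, c(4L, 1L))
  expect_equal(d$id, c("x1", "y1"))          # first-seen id, abundance order
  expect_identical(dereplicate(d), d)
  # all-unique input comes back re-sorted, not altered
  u <- reference_set(c("b", "a"), c("ACGT", "TTTT"))
  expect_equal(dereplicate(u)$id, c("a", "b"))
})

test_that("pairwise identity matches an independent DP oracle", {
  expect_equal(pairwise_identity("ACGT", "ACGA"), 0.75)
  expect_equal(pairwise_identity(strrep("ACGT", 25), strrep("ACGT", 25)), 1)
  withr::with_seed(13, {
    for (i in 1:60) {
      n <- sample(8:60, 1)
      a <- rand_seq(n)
      b <- if (i %% 2 == 0) mutate_seq(a, sample(1:4, 1))
           else rand_seq(sample(8:60, 1))
      o <- nw_oracle(a, b)
      st <- hcbprimer:::.align_stats(a, b, max(nchar(a), nchar(b)))
      expect_equal(st$score, o$score, info = paste(a, b))
      expect_equal(pairwise_identity(a, b), o$identity,
                   info = paste(a, b))
    }
  })
})

test_that("alignment scores agree with Biostrings' global aligner", {
  withr::with_seed(29, {
    for (i in 1:40) {
      a <- rand_seq(sample(10:80, 1))
      b <- rand_seq(sample(10:80, 1))
      s <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(a), Biostrings::DNAString(b),
        type = "global",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -1, baseOnly = FALSE),
        gapOpening = 2, gapExtension = 1, scoreOnly = TRUE)
      expect_equal(hcbprimer:::.align_stats(a, b,
                                            max(nchar(a), nchar(b)))$score,
                   s)
    }
  })
})

test_that("clustering respects the identity threshold at its boundary", {
  # two groups: within identical, between ~85%
  withr::with_seed(5, {
    a <- rand_seq(200)
    b <- mutate_seq(a, 30)
    refs <- reference_set(c("a1", "a2", "b1", "b2"), c(a, a, b, b))
  })
  d <- dereplicate(refs)
  expect_equal(length(unique(cluster_otus(d, 0.97)$otu)), 2L)
  # bracketing: a pair at known identity clusters at 0.97 but not 0.99
  withr::with_seed(6, {
    x <- rand_seq(100)
    y <- mutate_seq(x, 2)   # identity 0.98
  })
  refs2 <- dereplicate(reference_set(c("p", "q"), c(x, y)))
  expect_equal(length(unique(cluster_otus(refs2, 0.97)$otu)), 1L)
  expect_equal(length(unique(cluster_otus(refs2, 0.99)$otu)), 2L)
})

test_that("every member is within threshold of its representative", {
  gen <- generate_reference_set(
    synth_config(n_genera = 3, seqs_per_genus = 6, seq_length = 1200,
                 within_genus_divergence = 0.005, indel_rate = 0,
                 seed = 31))
  d <- dereplicate(gen$refs)
  cl <- cluster_otus(d, 0.97)
  seq_of <- setNames(d$sequence, d$id)
  for (i in seq_len(nrow(cl))) {
    expect_gte(pairwise_identity(seq_of[[cl$id[i]]],
                                 seq_of[[cl$representative_id[i]]]),
               0.97)
  }
  # with small within-divergence the OTUs recover the genera
  expect_equal(length(unique(cl$otu)), 3L)
})

test_that("clustering is invariant to input order", {
  gen <- generate_reference_set(
    synth_config(n_genera = 2, seqs_per_genus = 8, seq_length = 1200,
                 within_genus_divergence = 0.005, seed = 37))
  d <- dereplicate(gen$refs)
  base <- cluster_otus(d, 0.97)
  withr::with_seed(1, {
    for (rep in 1:3) {
      perm <- d[sample(nrow(d)), , drop = FALSE]
      out <- cluster_otus(perm, 0.97)
      out <- out[match(base$id, out$id), ]
      expect_equal(out$representative_id, base$representative_id)
    }
  })
})

test_that("template alignment preserves coordinates and logs insertions", {
  tmpl_seq <- withr::with_seed(41, rand_seq(120))
  template <- new_alignment("tmpl", tmpl_seq)
  # identical record reproduces the reference row
  refs <- reference_set("same", tmpl_seq)
  aln <- align_to_template(refs, template)
  expect_equal(aln$rows, tmpl_seq)
  # one internal deletion becomes one gap at the right column
  del_pos <- 60L
  chars <- strsplit(tmpl_seq, "")[[1]]
  refs_del <- reference_set("del", paste(chars[-del_pos], collapse = ""))
  row <- strsplit(align_to_template(refs_del, template)$rows, "")[[1]]
  expect_equal(which(row == "-"), del_pos)
  expect_equal(nchar(align_to_template(refs_del, template)$rows),
               nchar(tmpl_seq))
  # a 5-nt insertion is discarded and counted; the row equals the reference
  ins <- paste0(substr(tmpl_seq, 1, 60), "AACCG",
                substr(tmpl_seq, 61, 120))
  aln_ins <- align_to_template(reference_set("ins", ins), template)
  expect_equal(aln_ins$rows, tmpl_seq)
  expect_equal(unname(attr(aln_ins, "discarded")["ins"]), 5L)
  # ungapping recovers the input minus discarded insertions
  expect_equal(unname(ungap_alignment(aln_ins)),
               gsub("-", "", tmpl_seq))
})

test_that("poorly alignable records are dropped with a warning", {
  # a record three times the template length can place at most a third of
  # its bases on template columns, falling under the 50% rule
  tmpl_seq <- withr::with_seed(43, rand_seq(100))
  template <- new_alignment("tmpl", tmpl_seq)
  refs <- reference_set("junk",
                        withr::with_seed(44,
                                         paste0(rand_seq(100), tmpl_seq,
                                                rand_seq(100))))
  expect_warning(aln <- align_to_template(refs, template),
                 "less than half")
  expect_length(aln$ids, 0L)
})

test_that("gap-column filtering removes exactly the >= 90% gap columns", {
  # 10 rows; col 1: 9 gaps (0.90, removed), col 2: 8 gaps (kept),
  # col 3: 10 gaps (removed), col 4: none (kept)
  rows <- vapply(1:10, function(i) {
    paste0(if (i <= 9) "-" else "A",
           if (i <= 8) "-" else "C",
           "-",
           "G")
  }, character(1))
  aln <- new_alignment(sprintf("r%02d", 1:10), rows)
  out <- filter_gap_columns(aln, 0.90)
  expect_equal(attr(out, "removed_columns"), c(1L, 3L))
  expect_equal(out$width, 2L)
  # gap-free alignment unchanged
  clean <- new_alignment(c("a", "b"), c("ACGT", "ACGA"))
  expect_equal(filter_gap_columns(clean)$rows, clean$rows)
  # degenerate case errors
  allgap <- new_alignment(c("a", "b"), c("--", "--"))
  expect_error(filter_gap_columns(allgap), "degenerate")
})

test_that("gap filtering boundary holds on random alignments", {
  withr::with_seed(47, {
    for (rep in 1:10) {
      nrow_ <- sample(4:12, 1)
      ncol_ <- sample(5:30, 1)
      m <- matrix(sample(c("A", "C", "G", "T", "-"), nrow_ * ncol_,
                         replace = TRUE, prob = c(rep(0.15, 4), 0.4)),
                  nrow_, ncol_)
      aln <- new_alignment(sprintf("r%d", seq_len(nrow_)),
                           apply(m, 1, paste, collapse = ""))
      gap_frac <- colMeans(m == "-")
      res <- tryCatch(filter_gap_columns(aln, 0.9), error = function(e) NULL)
      if (is.null(res)) {
        expect_true(all(gap_frac >= 0.9))
      } else {
        expect_setequal(attr(res, "removed_columns"), which(gap_frac >= 0.9))
      }
    }
  })
})
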