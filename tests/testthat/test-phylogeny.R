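test_that("distances use pairwise deletion and the JC closed form", {
  aln <- new_alignment(c("a", "b", "c"),
                       c("ACGT", "ACGA", "AC-A"))
  d <- distance_matrix(aln, correction = "none")
  expect_equal(unname(d["a", "b"]), 0.25)
  expect_equal(unname(d["b", "c"]), 0)       # gap column excluded
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_true(isSymmetric(d))
  # JC correction -(3/4) log(1 - 4p/3) on a constructed p = 39/400 pair
  w <- withr::with_seed(53, {
    x <- rand_seq(400)
    y <- strsplit(x, "")[[1]]
    flip <- sample(400, 39)
    for (i in flip) y[i] <- sample(setdiff(BASES, y[i]), 1)
    list(x = x, y = paste(y, collapse = ""))
  })
  aln2 <- new_alignment(c("a", "b", "c"), c(w$x, w$y, w$x))
  p <- 39 / 400
  expect_equal(unname(distance_matrix(aln2)["a", "b"]),
               -0.75 * log(1 - 4 * p / 3))
  expect_equal(-0.75 * log(1 - 4 * 0.10 / 3), 0.10733, tolerance = 1e-4)
})

test_that("saturated and incomparable pairs raise informative errors", {
  aln <- new_alignment(c("a", "b", "c"),
                       c("AAAA", "CCCC", "AAAA"))
  expect_error(distance_matrix(aln, "jukes_cantor"), "saturated")
  aln2 <- new_alignment(c("a", "b", "c"),
                        c("AA--", "--CC", "AACC"))
  expect_error(distance_matrix(aln2), "no comparable columns.*a.*b")
})

test_that("neighbor joining resolves the additive four-taxon case", {
  dm <- matrix(c(0, 2, 3, 3,
                 2, 0, 3, 3,
                 3, 3, 0, 2,
                 3, 3, 2, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"),
                               c("A", "B", "C", "D")))
  tr <- neighbor_joining(dm)
  expect_s3_class(tr, "phylo")
  pd <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
  expect_equal(pd, dm, tolerance = 1e-12)
  # split AB|CD present: dropping the internal edge separates {A,B}
  parts <- ape::prop.part(ape::unroot(tr))
  labs <- attr(parts, "labels")
  splits <- lapply(parts, function(p) sort(labs[p]))
  expect_true(list(c("A", "B")) %in% splits ||
              list(c("C", "D")) %in% splits)
})

test_that("three taxa solve the closed-form branch lengths", {
  dm <- matrix(c(0, 3, 4,
                 3, 0, 5,
                 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(dm)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["a"]), (3 + 4 - 5) / 2)
  expect_equal(unname(bl["b"]), (3 + 5 - 4) / 2)
  expect_equal(unname(bl["c"]), (4 + 5 - 3) / 2)
})

test_that("NJ recovers random additive trees exactly", {
  withr::with_seed(59, {
    for (trial in 1:40) {
      nt <- sample(5:12, 1)
      t0 <- ape::rtree(nt, rooted = FALSE,
                       br = function(n) stats::runif(n, 0.01, 1))
      D <- ape::cophenetic.phylo(t0)
      tr <- neighbor_joining(D)
      expect_equal(ape::dist.topo(ape::unroot(t0), ape::unroot(tr)), 0,
                   ignore_attr = TRUE)
      pd <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
      expect_lt(max(abs(pd - D)), 1e-9)
    }
  })
})

test_that("bootstrap supports are certain for unambiguous alignments", {
  # two clearly separated pairs: strong, consistent signal in every column
  rows <- withr::with_seed(61, {
    base_a <- rand_seq(200)
    base_b <- mutate_seq(base_a, 60)
    c(base_a, mutate_seq(base_a, 2), base_b, mutate_seq(base_b, 2))
  })
  aln <- new_alignment(c("a1", "a2", "b1", "b2"), rows)
  tr <- bootstrap_support(aln, n_reps = 50, seed = 3)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] >= 95))
  # n_reps = 0 leaves supports unset
  expect_null(bootstrap_support(aln, n_reps = 0)$node.label)
  # reproducibility from seed
  tr2 <- bootstrap_support(aln, n_reps = 50, seed = 3)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
})

test_that("genus-separating edges get high support on synthetic data", {
  gen <- generate_reference_set(
    synth_config(n_genera = 2, seqs_per_genus = 4, seq_length = 1200,
                 indel_rate = 0, seed = 67))
  aln <- new_alignment(gen$refs$id, gen$refs$sequence)
  tr <- bootstrap_support(aln, n_reps = 100, seed = 5)
  rooted <- ape::root(tr, outgroup = "Genus02_seq001",
                      resolve.root = TRUE, edgelabel = TRUE)
  g1 <- paste0("Genus01_seq00", 1:4)
  mrca <- ape::getMRCA(rooted, g1)
  expect_setequal(ape::extract.clade(rooted, mrca)$tip.label, g1)
  sup <- as.numeric(rooted$node.label[mrca - ape::Ntip(rooted)])
  expect_gte(sup, 95)
})

test_that("monophyly rule selects clades and falls back to anchors", {
  # ((T,a),x,o): a same genus as anchor T -> monophyletic, {T, a}
  tr <- ape::read.tree(text = "((T:1,a:1):1,x:1,o:3);")
  labels <- c(T = "G1", a = "G1", x = "G2", o = "Out")
  rep1 <- check_monophyly(tr, "T", "o", labels, genus = "G1")
  expect_true(rep1$is_monophyletic)
  expect_setequal(rep1$selected_ids, c("T", "a"))
  # intruder of another genus inside the clade -> anchors only
  tr2 <- ape::read.tree(text = "((T:1,x:1):1,a:1,o:3);")
  labels2 <- c(T = "G1", a = "G1", x = "G2", o = "Out")
  rep2 <- check_monophyly(tr2, "T", "o", labels2, genus = "G1")
  expect_false(rep2$is_monophyletic)
  expect_equal(rep2$selected_ids, "T")
  # unlabeled leaves inside the clade do not break monophyly
  labels3 <- c(T = "G1", a = "G1", x = "", o = "Out")
  rep3 <- check_monophyly(tr2, "T", "o", labels3, genus = "G1")
  expect_true(rep3$is_monophyletic)
  expect_setequal(rep3$clade_member_ids, c("T", "x", "a"))
  # missing leaves error
  expect_error(check_monophyly(tr, "nope", "o", labels), "nope")
})

test_that("outgroup rooting preserves the unrooted bipartitions", {
  withr::with_seed(71, {
    tr <- ape::rtree(8, rooted = FALSE)
    rooted <- ape::root(tr, outgroup = tr$tip.label[1], resolve.root = TRUE)
    expect_equal(ape::dist.topo(ape::unroot(rooted), ape::unroot(tr)), 0,
                 ignore_attr = TRUE)
  })
})

test_that("synthetic genera come back as monophyletic truth-equal sets", {
  gen <- generate_reference_set(
    synth_config(n_genera = 4, seqs_per_genus = 5, seq_length = 1200,
                 indel_rate = 0, seed = 73))
  aln <- new_alignment(gen$refs$id, gen$refs$sequence)
  tr <- neighbor_joining(distance_matrix(aln))
  labels <- setNames(gen$refs$genus, gen$refs$id)
  out_id <- "Genus04_seq001"
  truth <- gen$truth$sequences
  for (g in c("Genus01", "Genus02", "Genus03")) {
    anchors <- gen$refs$id[gen$refs$genus == g & gen$refs$is_type_strain]
    rep <- check_monophyly(tr, anchors, out_id, labels, genus = g)
    expect_true(rep$is_monophyletic)
    expect_setequal(rep$selected_ids, truth$id[truth$genus == g])
  }
})
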