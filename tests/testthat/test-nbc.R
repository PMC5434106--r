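test_that("word extraction yields distinct ACGT k-mers only", {
  expect_equal(decode_word(extract_words("ACGTACGT", 8)), "ACGTACGT")
  expect_equal(decode_word(extract_words("AAAAAAAAA", 8)), "AAAAAAAA")
  expect_error(extract_words("ACGT", 8), "shorter")
  # windows containing non-ACGT characters are skipped
  w <- extract_words("ACGTNACGTACGT", 8)
  expect_length(w, 1L)
  expect_equal(decode_word(w), "ACGTACGT")
  withr::with_seed(139, {
    for (i in 1:10) {
      s <- rand_seq(sample(10:60, 1))
      w <- extract_words(s, 8)
      expect_lte(length(w), nchar(s) - 7L)
      expect_setequal(
        decode_word(w),
        unique(substring(s, 1:(nchar(s) - 7), 8:nchar(s))))
    }
  })
})

test_that("training reproduces the stated smoothing formulas", {
  # N = 2 training sequences (one per genus), word absent everywhere has
  # prior (0 + 0.5) / (2 + 1) = 1/6; a genus with M = 1 not containing it
  # has conditional (0 + 1/6) / (1 + 1) = 1/12
  refs <- reference_set(c("a", "b"),
                        c(strrep("A", 10), strrep("C", 10)),
                        taxonomy = c("B;P;C;O;F;G1", "B;P;C;O;F;G2"))
  model <- nbc_train(refs, k = 8)
  absent <- extract_words(strrep("G", 8), 8)
  expect_equal(model$word_prior[absent], 0.5 / 3)
  expect_equal(unname(model$cond_log["G1", absent]), log((0.5 / 3) / 2))
  # the word present in all of G1 (m = 1 of M = 1): (1 + p) / 2
  aaaa <- extract_words(strrep("A", 8), 8)
  p <- model$word_prior[aaaa]
  expect_equal(unname(model$cond_log["G1", aaaa]), log((1 + p) / 2))
  expect_lt(max(exp(model$cond_log)), 1)
  expect_gt(min(model$word_prior), 0)
})

test_that("model probabilities match an independent recount", {
  refs <- toy_refs(n_genera = 2, per_genus = 5, len = 60, muts = 3,
                   seed = 149)
  k <- 8
  model <- nbc_train(refs, k = k)
  # recount: straightforward per-genus tallies over distinct words
  words_of <- lapply(refs$sequence, function(s)
    unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s))))
  all_words <- unique(unlist(words_of))
  N <- nrow(refs)
  for (w in withr::with_seed(3, sample(all_words, 25))) {
    wi <- extract_words(w, k)
    nw <- sum(vapply(words_of, function(x) w %in% x, logical(1)))
    expect_equal(model$word_prior[wi], (nw + 0.5) / (N + 1))
    for (g in model$genera) {
      sel <- refs$genus == g
      mg <- sum(vapply(words_of[sel], function(x) w %in% x, logical(1)))
      expect_equal(unname(model$cond_log[g, wi]),
                   log((mg + (nw + 0.5) / (N + 1)) / (sum(sel) + 1)))
    }
  }
})

test_that("classification maximizes the summed log conditionals", {
  refs <- toy_refs(n_genera = 3, per_genus = 5, len = 100, muts = 2,
                   seed = 151)
  model <- nbc_train(refs)
  # training sequences classify to their own genus on separable data
  for (i in seq_len(nrow(refs)))
    expect_equal(nbc_classify(model, refs$sequence[i]), refs$genus[i])
  # posterior scores equal a brute-force summation
  q <- refs$sequence[1]
  w <- extract_words(q, model$k)
  brute <- vapply(model$genera, function(g)
    sum(model$cond_log[g, w]), numeric(1))
  expect_equal(nbc_classify(model, q),
               names(brute)[which.max(brute)])
  # duplicate words in the query do not change the call
  expect_equal(nbc_classify(model, paste0(q, q)),
               nbc_classify(model, q))
})

test_that("ties break lexicographically by genus label", {
  refs <- reference_set(c("a", "b"), c("ACGTACGTAC", "ACGTACGTAC"),
                        taxonomy = c("B;P;C;O;F;Zeta", "B;P;C;O;F;Alpha"))
  model <- nbc_train(refs)
  # both genera have identical statistics -> scores tie -> "Alpha"
  expect_equal(nbc_classify(model, "ACGTACGTAC"), "Alpha")
})

test_that("bootstrap confidence is high for separable data, reproducible", {
  refs <- toy_refs(n_genera = 2, per_genus = 6, len = 150, muts = 2,
                   seed = 157)
  model <- nbc_train(refs)
  q <- refs$sequence[1]
  r1 <- nbc_classify_bootstrap(model, q, n_boot = 100, seed = 5,
                               seq_id = "q1")
  expect_equal(r1$genus, refs$genus[1])
  expect_equal(r1$confidence, 1.0)
  r2 <- nbc_classify_bootstrap(model, q, n_boot = 100, seed = 5,
                               seq_id = "q1")
  expect_identical(r1, r2)
  # one replicate -> confidence is 0 or 1
  r3 <- nbc_classify_bootstrap(model, q, n_boot = 1, seed = 5)
  expect_true(r3$confidence %in% c(0, 1))
})

test_that("confidence drops as genera converge", {
  # 3-point sweep: smaller between-genus divergence, lower mean confidence
  mean_conf <- vapply(c(0.15, 0.03, 0.008), function(div) {
    gen <- generate_reference_set(
      synth_config(n_genera = 2, seqs_per_genus = 8, seq_length = 1200,
                   between_genus_divergence = div, indel_rate = 0,
                   seed = 163))
    model <- nbc_train(gen$refs)
    confs <- vapply(1:6, function(i) {
      nbc_classify_bootstrap(model, substr(gen$refs$sequence[i], 300, 900),
                             n_boot = 60, seed = 7,
                             seq_id = gen$refs$id[i])$confidence
    }, numeric(1))
    mean(confs)
  }, numeric(1))
  expect_true(mean_conf[1] >= mean_conf[2] - 1e-9)
  expect_true(mean_conf[2] >= mean_conf[3] - 1e-9)
})

test_that("amplicon evaluation reports per-genus accuracy on held-out data", {
  gen <- generate_reference_set(
    synth_config(n_genera = 3, seqs_per_genus = 10, seq_length = 1200,
                 indel_rate = 0, seed = 167))
  train <- gen$refs[rep(c(TRUE, FALSE), length.out = nrow(gen$refs)), ]
  eval_ <- gen$refs[rep(c(FALSE, TRUE), length.out = nrow(gen$refs)), ]
  model <- nbc_train(train)
  pair <- default_primer_pairs()[1, , drop = FALSE]
  amp <- extract_amplicons(pair, eval_)
  amp$genus <- eval_$genus[match(amp$seq_id, eval_$id)]
  res <- evaluate_amplicon_classification(model, amp, n_boot = 50, seed = 9)
  expect_equal(res$by_genus$accuracy, rep(1, 3))
  expect_true(all(res$by_genus$conf_fraction >= 0.95))
  # a truth genus missing from the model counts as incorrect with warning
  amp_bad <- amp[1:2, ]
  amp_bad$genus <- "Nonexistent"
  expect_warning(res_bad <- evaluate_amplicon_classification(
    model, amp_bad, n_boot = 10, seed = 9), "Nonexistent")
  expect_equal(res_bad$by_genus$accuracy, 0)
})

test_that("log scores stay finite over arbitrary ACGT queries", {
  refs <- toy_refs(n_genera = 2, per_genus = 3, len = 80, muts = 2,
                   seed = 173)
  model <- nbc_train(refs)
  withr::with_seed(2, {
    for (i in 1:10) {
      q <- rand_seq(sample(10:200, 1))
      w <- extract_words(q, model$k)
      expect_true(all(is.finite(model$cond_log[, w])))
    }
  })
})
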