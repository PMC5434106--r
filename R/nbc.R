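## 2-bit base codes for k-mer indexing: A=0, C=1, G=2, T=3.
.base_code <- c(A = 0L, C = 1L, G = 2L, T = 3L)

#' Distinct overlapping k-mer indices of a sequence
#'
#' Words are used as presence/absence features: each distinct k-mer over
#' {A,C,G,T} is returned once, encoded as a 1-based integer index into the
#' 4^k word space. Windows containing any other character are skipped.
#'
#' @param seq sequence string, length >= k.
#' @param k word size (default 8).
#' @return sorted integer vector of distinct word indices.
#' @export
extract_words <- function(seq, k = 8L) {
  n <- nchar(seq)
  if (n < k) stop("sequence shorter than word size")
  codes <- .base_code[strsplit(toupper(seq), "", fixed = TRUE)[[1]]]
  ## windows: embed() row i = codes[(i+k-1):i], i.e. reversed window
  win <- stats::embed(codes, k)
  idx <- as.vector(win %*% 4L^(0:(k - 1L))) + 1L  # NA if window had non-ACGT
  sort(unique(idx[!is.na(idx)]))
}

#' Decode a word index back to its k-mer string
#' @param idx integer indices from \code{\link{extract_words}}.
#' @param k word size.
#' @return character vector of k-mers.
#' @export
decode_word <- function(idx, k = 8L) {
  bases <- c("A", "C", "G", "T")
  vapply(idx, function(i) {
    i <- i - 1L
    out <- character(k)
    for (j in k:1) { out[j] <- bases[i %% 4L + 1L]; i <- i %/% 4L }
    paste(out, collapse = "")
  }, character(1))
}

#' Train the word-based naive Bayesian genus classifier
#'
#' Word priors and genus-conditional probabilities follow the standard
#' word-presence formulation: with n(w) the number of training sequences
#' containing word w out of N total, the prior is
#' (n(w) + 0.5) / (N + 1); with m_g(w) the count among the M_g sequences of
#' genus g, the conditional probability is
#' (m_g(w) + prior(w)) / (M_g + 1). Probabilities are stored as logs.
#'
#' @param refs reference set with non-empty genus labels for at least 2
#'   genera, each with >= 1 sequence.
#' @param k word size (default 8).
#' @return an object of class \code{nbc_model}: list with \code{k},
#'   \code{genera}, \code{n_train}, \code{word_prior} (length 4^k) and
#'   \code{cond_log} (genera x 4^k matrix of log conditional
#'   probabilities).
#' @export
nbc_train <- function(refs, k = 8L) {
  refs <- refs[nzchar(refs$genus), , drop = FALSE]
  genera <- sort(unique(refs$genus))
  if (length(genera) < 2L) stop("need at least 2 genera to train")
  nwords <- 4L^k
  words <- lapply(refs$sequence, extract_words, k = k)
  N <- nrow(refs)
  nw <- tabulate(unlist(words), nbins = nwords)           # n(w)
  prior <- (nw + 0.5) / (N + 1)
  cond_log <- matrix(NA_real_, nrow = length(genera), ncol = nwords,
                     dimnames = list(genera, NULL))
  n_train <- stats::setNames(integer(length(genera)), genera)
  for (g in genera) {
    sel <- refs$genus == g
    Mg <- sum(sel)
    n_train[g] <- Mg
    mw <- tabulate(unlist(words[sel]), nbins = nwords)    # m_g(w)
    cond_log[g, ] <- log((mw + prior) / (Mg + 1))
  }
  structure(list(k = as.integer(k), genera = genera, n_train = n_train,
                 word_prior = prior, cond_log = cond_log),
            class = "nbc_model")
}

#' @export
print.nbc_model <- function(x, ...) {
  cat(sprintf("nbc_model: k = %d, %d genera, %d training sequences\n",
              x$k, length(x$genera), sum(x$n_train)))
  invisible(x)
}

## Log-score of every genus for a set of word indices (duplicates allowed:
## each occurrence contributes).
nbc_scores <- function(model, word_idx) {
  if (length(word_idx) == 1L) model$cond_log[, word_idx]
  else rowSums(model$cond_log[, word_idx, drop = FALSE])
}

#' Classify a sequence to genus
#'
#' The predicted genus maximizes the summed log conditional probability of
#' the query's distinct words; ties are broken lexicographically by genus
#' label.
#'
#' @param model an \code{nbc_model}.
#' @param seq query sequence (length >= k).
#' @return genus label.
#' @export
nbc_classify <- function(model, seq) {
  w <- extract_words(seq, model$k)
  s <- nbc_scores(model, w)
  names(s)[which(s == max(s))][1L]   # genera sorted, so first = lexicographic
}

#' Classify with bootstrap confidence
#'
#' Each replicate draws floor(W/8) words (minimum 1) with replacement from
#' the query's W distinct words and classifies on that subset; the
#' confidence is the fraction of replicates agreeing with the full-word
#' call. The per-query RNG stream is derived deterministically from the
#' global seed and the query id, so batch runs are reproducible regardless
#' of order.
#'
#' @param model an \code{nbc_model}.
#' @param seq query sequence.
#' @param n_boot bootstrap replicates (default 100).
#' @param seed integer seed.
#' @param seq_id optional query id mixed into the seed.
#' @return list with \code{genus} and \code{confidence} in [0, 1].
#' @export
nbc_classify_bootstrap <- function(model, seq, n_boot = 100L, seed = 1L,
                                   seq_id = "") {
  w <- extract_words(seq, model$k)
  full_call <- {
    s <- nbc_scores(model, w)
    names(s)[which(s == max(s))][1L]
  }
  if (n_boot == 0L) return(list(genus = full_call, confidence = NA_real_))
  nsub <- max(1L, length(w) %/% 8L)
  agree <- withr_seed(mix_seed(seed, seq_id), {
    vapply(seq_len(n_boot), function(b) {
      sub <- w[sample.int(length(w), nsub, replace = TRUE)]
      s <- nbc_scores(model, sub)
      names(s)[which(s == max(s))][1L] == full_call
    }, logical(1))
  })
  list(genus = full_call, confidence = mean(agree))
}

## Deterministic 31-bit seed from an integer seed and a string id
## (polynomial rolling hash in double precision; 131 * 2^31 < 2^53).
mix_seed <- function(seed, id) {
  h <- as.numeric(seed) %% 2147483647
  for (v in utf8ToInt(as.character(id)))
    h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

#' Evaluate genus classification of extracted amplicons
#'
#' Amplicons are dereplicated (identical sequences collapsed) before
#' classification, then classified with bootstrap confidence against a
#' model trained on full-length sequences. Reports, per true genus, the
#' fraction of amplicons classified to the correct genus and the fraction
#' of CORRECT calls carrying confidence >= \code{min_conf}. A true genus
#' absent from the model is counted as incorrect with a warning.
#'
#' @param model an \code{nbc_model} trained on sequences disjoint from the
#'   evaluation targets.
#' @param amplicons data.frame with columns \code{seq_id}, \code{amplicon}
#'   and \code{genus} (truth).
#' @param n_boot,seed bootstrap parameters.
#' @param min_conf confidence threshold (default 0.80).
#' @return list with \code{calls} (per-amplicon data.frame: seq_id, genus,
#'   predicted, confidence, correct) and \code{by_genus} (data.frame:
#'   genus, n, accuracy, conf_fraction).
#' @export
evaluate_amplicon_classification <- function(model, amplicons,
                                             n_boot = 100L, seed = 1L,
                                             min_conf = 0.80) {
  if (nrow(amplicons) == 0L) stop("no amplicons to evaluate")
  amplicons <- amplicons[!duplicated(amplicons$amplicon), , drop = FALSE]
  unknown <- setdiff(unique(amplicons$genus), model$genera)
  if (length(unknown) > 0L)
    warning("genus label(s) absent from model: ",
            paste(unknown, collapse = ", "))
  calls <- lapply(seq_len(nrow(amplicons)), function(i) {
    cl <- nbc_classify_bootstrap(model, amplicons$amplicon[i], n_boot,
                                 seed, amplicons$seq_id[i])
    data.frame(seq_id = amplicons$seq_id[i], genus = amplicons$genus[i],
               predicted = cl$genus, confidence = cl$confidence,
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, calls)
  calls$correct <- calls$predicted == calls$genus
  by_genus <- do.call(rbind, lapply(sort(unique(calls$genus)), function(g) {
    sel <- calls[calls$genus == g, , drop = FALSE]
    correct <- sel[sel$correct, , drop = FALSE]
    data.frame(genus = g, n = nrow(sel),
               accuracy = mean(sel$correct),
               conf_fraction = if (nrow(correct) > 0)
                 mean(correct$confidence >= min_conf) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(calls = calls, by_genus = by_genus)
}
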