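# Independent oracles used across the suite. Each is a deliberately
# straightforward second implementation, kept free of any code path it
# checks.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# mutate a sequence with k random substitutions
mutate_seq <- function(s, k) {
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  for (i in sample(length(x), min(k, length(x))))
    x[i] <- sample(setdiff(BASES, x[i]), 1)
  paste(x, collapse = "")
}

# Full-matrix affine-gap global alignment oracle (match +1, mismatch -1,
# gap open -2 plus -1 per position), plain R, same tie preference
# (diagonal, then gap-in-first, then gap-in-second). Returns list(score,
# identity) with identity excluding terminal-gap columns.
nw_oracle <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  H <- matrix(NEG, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)   # gap in x (consumes y)
  F <- matrix(NEG, n + 1, m + 1)   # gap in y (consumes x)
  H[1, 1] <- 0
  for (j in 1:m) E[1, j + 1] <- -2 - j
  for (i in 1:n) F[i + 1, 1] <- -2 - i
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (x[i] == y[j]) 1 else -1
      H[i + 1, j + 1] <- max(H[i, j], E[i, j], F[i, j]) + s
      E[i + 1, j + 1] <- max(H[i + 1, j] - 3, F[i + 1, j] - 3,
                             E[i + 1, j] - 1)
      F[i + 1, j + 1] <- max(H[i, j + 1] - 3, E[i, j + 1] - 3,
                             F[i, j + 1] - 1)
    }
  }
  score <- max(H[n + 1, m + 1], E[n + 1, m + 1], F[n + 1, m + 1])
  # traceback with H > E > F preference
  i <- n; j <- m
  state <- which.max(c(H[n + 1, m + 1], E[n + 1, m + 1], F[n + 1, m + 1]))
  ops <- integer(0)  # 0 diag, 1 gap-in-x, 2 gap-in-y (end to start)
  while (i > 0 || j > 0) {
    if (state == 1) {
      ops <- c(ops, 0L)
      s <- if (x[i] == y[j]) 1 else -1
      tgt <- H[i + 1, j + 1] - s
      state <- if (i - 1 == 0 && j - 1 == 0) 1
      else if (H[i, j] == tgt) 1 else if (E[i, j] == tgt) 2 else 3
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      ops <- c(ops, 1L)
      tgt <- E[i + 1, j + 1]
      state <- if (j - 1 == 0 && i == 0) 1
      else if (H[i + 1, j] - 3 == tgt) 1
      else if (E[i + 1, j] - 1 == tgt) 2 else 3
      j <- j - 1
    } else {
      ops <- c(ops, 2L)
      tgt <- F[i + 1, j + 1]
      state <- if (i - 1 == 0 && j == 0) 1
      else if (H[i, j + 1] - 3 == tgt) 1
      else if (F[i, j + 1] - 1 == tgt) 3 else 2
      i <- i - 1
    }
  }
  dpos <- which(ops == 0L)
  if (length(dpos) == 0L) return(list(score = score, identity = 0))
  core <- min(dpos):max(dpos)
  # replay to count matches
  xi <- n; yj <- m; matches <- 0
  for (k in seq_along(ops)) {
    if (ops[k] == 0L) {
      if (k %in% core && x[xi] == y[yj]) matches <- matches + 1
      xi <- xi - 1; yj <- yj - 1
    } else if (ops[k] == 1L) yj <- yj - 1 else xi <- xi - 1
  }
  list(score = score, identity = matches / length(core))
}

# IUPAC expansion oracle for primer site finding: expand the degenerate
# primer into every concrete variant and locate exact substring matches.
iupac_sets_oracle <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

expand_primer <- function(p) {
  sets <- iupac_sets_oracle[strsplit(p, "", fixed = TRUE)[[1]]]
  apply(do.call(expand.grid, rev(sets)), 1,
        function(r) paste(rev(r), collapse = ""))
}

find_sites_oracle <- function(primer, target) {
  hits <- integer(0)
  for (v in expand_primer(primer)) {
    g <- gregexpr(paste0("(?=", v, ")"), target, perl = TRUE)[[1]]
    if (g[1] != -1) hits <- c(hits, as.integer(g))
  }
  sort(unique(hits))
}

rc_oracle <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

# small genus-labeled reference set with clean separation, for NBC and
# clustering fixtures
toy_refs <- function(n_genera = 2, per_genus = 4, len = 120, muts = 2,
                     seed = 1) {
  withr::with_seed(seed, {
    ids <- character(0); seqs <- character(0); tax <- character(0)
    for (g in seq_len(n_genera)) {
      anc <- rand_seq(len)
      for (i in seq_len(per_genus)) {
        ids <- c(ids, sprintf("g%d_s%d", g, i))
        seqs <- c(seqs, mutate_seq(anc, muts))
        tax <- c(tax, sprintf("Bacteria;P;C;O;F;Genus%02d", g))
      }
    }
    reference_set(ids, seqs, tax,
                  is_type_strain = rep(c(TRUE, rep(FALSE, per_genus - 1)),
                                       n_genera))
  })
}

# IUPAC-aware reverse complement via Biostrings, independent of the
# package's complement table
rc_oracle_iupac <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
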