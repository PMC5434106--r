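## Default engineered primer-binding sites: the forward site carries a
## widely used V3 forward primer motif and the reverse site carries the
## sense-strand binding motif (reverse complement) of a V5 reverse primer,
## at their canonical reference coordinates.
default_primer_sites <- function() {
  list(
    list(name = "fwd343", motif = "TACGGRAGGCAGCAG", start = 343L),
    list(name = "rev908", motif = "ACTYAAAKGAATTGACGG", start = 908L)
  )
}

#' Default primer-pair panel matching the default engineered sites
#'
#' Three pairs exercising the evaluation: a medium-amplicon pair whose
#' binding sites are the generator's default engineered motifs (the
#' V3-forward / V5-reverse pair the package recommends on synthetic data),
#' a medium-amplicon pair whose motifs are absent from generated sequences
#' (expected coverage 0), and the same good pair under free-form names so
#' its size class must be derived from realized amplicon lengths.
#'
#' @return annotated primer-pair data.frame (see
#'   \code{\link{read_primer_table}} for columns).
#' @export
default_primer_pairs <- function() {
  tab <- data.frame(
    pair_id = c("Bact0343_0908", "Bact0515_0930", "Custom343_908"),
    fwd_name = c("S-D-Bact-0343-a-S-15", "S-D-Bact-0515-a-S-18", "343F"),
    fwd_seq = c("TACGGRAGGCAGCAG", "GTGCCAGCMGCCGCGGTA", "TACGGRAGGCAGCAG"),
    rev_name = c("S-D-Bact-0908-a-A-18", "S-D-Bact-0930-a-A-20", "908R"),
    rev_seq = c("CCGTCAATTCMTTTRAGT", "CCGYCAATTYMTTTRAGTTT",
                "CCGTCAATTCMTTTRAGT"),
    stringsAsFactors = FALSE)
  annotate_primer_pairs(tab)
}

#' Configuration for the synthetic 16S-like reference generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' several genera whose members are much more similar within than between
#' genera, conserved primer-binding motifs embedded at known coordinates,
#' and genus-labeled type strains. Defaults are the package's standard
#' study conditions: 5 genera of 40 sequences, 1500-nt sequences,
#' between-genus divergence 0.15 and within-genus divergence 0.02
#' substitutions per site (keeping average within-genus identity above the
#' 0.97 clustering threshold), indel rate 0.005 per site on tip branches.
#'
#' @param n_genera number of genera (>= 2).
#' @param seqs_per_genus sequences per genus (>= 1).
#' @param seq_length root sequence length in nt.
#' @param between_genus_divergence substitution fraction per site on genus
#'   ancestor branches.
#' @param within_genus_divergence substitution fraction per site on tip
#'   branches.
#' @param indel_rate per-site probability of a 1-3 nt indel on tip
#'   branches (indels never touch primer sites).
#' @param primer_sites list of sites, each a list with \code{name},
#'   \code{motif} (IUPAC string), \code{start} (1-based root coordinate)
#'   and optionally \code{perfect_fraction} (named numeric vector genus ->
#'   fraction of tips keeping a perfect site; default 1 for all genera).
#' @param n_type_strains_per_genus type strains flagged per genus.
#' @param seed integer seed; generation is a pure function of the config.
#' @return a validated list of class \code{synth_config}.
#' @export
synth_config <- function(n_genera = 5L, seqs_per_genus = 40L,
                         seq_length = 1500L,
                         between_genus_divergence = 0.15,
                         within_genus_divergence = 0.02,
                         indel_rate = 0.005,
                         primer_sites = default_primer_sites(),
                         n_type_strains_per_genus = 1L,
                         seed = 1L) {
  cfg <- list(n_genera = as.integer(n_genera),
              seqs_per_genus = as.integer(seqs_per_genus),
              seq_length = as.integer(seq_length),
              between_genus_divergence = between_genus_divergence,
              within_genus_divergence = within_genus_divergence,
              indel_rate = indel_rate,
              primer_sites = primer_sites,
              n_type_strains_per_genus = as.integer(n_type_strains_per_genus),
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_genera >= 2L, cfg$seqs_per_genus >= 1L,
            cfg$seq_length >= 1L, cfg$n_type_strains_per_genus >= 1L,
            cfg$n_type_strains_per_genus <= cfg$seqs_per_genus)
  for (v in c(cfg$between_genus_divergence, cfg$within_genus_divergence,
              cfg$indel_rate))
    if (is.na(v) || v < 0 || v > 1) stop("rates must lie in [0, 1]")
  iv <- site_intervals(cfg)
  if (nrow(iv) > 0L) {
    if (any(iv$start < 1L) || any(iv$end > cfg$seq_length))
      stop("primer site outside [1, seq_length]")
    o <- order(iv$start)
    if (nrow(iv) > 1L &&
        any(iv$start[o][-1L] <= iv$end[o][-nrow(iv)]))
      stop("primer site intervals overlap")
  }
  for (s in cfg$primer_sites) {
    pf <- s$perfect_fraction
    if (!is.null(pf) && (any(pf < 0) || any(pf > 1)))
      stop("perfect_fraction must lie in [0, 1]")
  }
  invisible(cfg)
}

site_intervals <- function(cfg) {
  if (length(cfg$primer_sites) == 0L)
    return(data.frame(name = character(0), start = integer(0),
                      end = integer(0)))
  data.frame(
    name = vapply(cfg$primer_sites, `[[`, character(1), "name"),
    start = vapply(cfg$primer_sites, function(s) as.integer(s$start),
                   integer(1)),
    end = vapply(cfg$primer_sites, function(s)
      as.integer(s$start) + nchar(s$motif) - 1L, integer(1)),
    stringsAsFactors = FALSE)
}

## Substitute each position in `pos` with probability `rate`, drawing the
## replacement uniformly from the 3 alternative bases (Jukes-Cantor-like).
mutate_positions <- function(chars, pos, rate) {
  hit <- pos[stats::runif(length(pos)) < rate]
  if (length(hit) > 0L) {
    bases <- c("A", "C", "G", "T")
    for (p in hit)
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
  }
  chars
}

#' Generate a genus-labeled synthetic reference set with known truth
#'
#' A root sequence is drawn uniformly over {A,C,G,T} and the primer motifs
#' are written at their start positions, degenerate motif positions
#' instantiated to one concrete base (recorded in the truth table). Genus
#' ancestors derive from the root by substitutions at the between-genus
#' rate outside primer sites; tips derive from their ancestor at the
#' within-genus rate plus indels, again outside primer sites, so that
#' primer-match status is controlled solely by the engineered perfect
#' fractions. Within each genus, exactly \code{round(perfect_fraction * n)}
#' tips keep a perfect site; each remaining tip receives exactly one
#' substitution at a uniformly chosen breakable site position, changed to a
#' base incompatible with the motif. The first
#' \code{n_type_strains_per_genus} tips per genus are flagged as type
#' strains. Generation is a pure function of the config (including its
#' seed).
#'
#' @param cfg a \code{\link{synth_config}}.
#' @return list with \code{refs} (a reference set; genus labels
#'   \code{Genus01}, ...), and \code{truth}: list with \code{sequences}
#'   (id, genus, is_type_strain), \code{sites} (id, site, perfect, start,
#'   end: true coordinates after indels), \code{root} (the root sequence)
#'   and \code{template} (a single-row \code{seq_alignment} of the root,
#'   usable as alignment template).
#' @export
generate_reference_set <- function(cfg) {
  validate_synth_config(cfg)
  withr_seed(cfg$seed, generate_impl(cfg))
}

generate_impl <- function(cfg) {
  L <- cfg$seq_length
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, L, replace = TRUE)
  iv <- site_intervals(cfg)
  site_pos <- integer(0)
  motif_chars <- list()
  for (k in seq_along(cfg$primer_sites)) {
    s <- cfg$primer_sites[[k]]
    mc <- strsplit(toupper(s$motif), "", fixed = TRUE)[[1]]
    inst <- vapply(mc, function(code) {
      set <- IUPAC_SETS[[code]]
      if (is.null(set)) stop("invalid IUPAC code in motif: ", code)
      if (length(set) == 1L) set else sample(set, 1L)
    }, character(1))
    root[iv$start[k]:iv$end[k]] <- inst
    motif_chars[[iv$name[k]]] <- mc
    site_pos <- c(site_pos, iv$start[k]:iv$end[k])
  }
  free_pos <- setdiff(seq_len(L), site_pos)

  genera <- sprintf("Genus%02d", seq_len(cfg$n_genera))
  ids <- character(0); seqs <- character(0)
  tax <- character(0); type_flag <- logical(0)
  site_rows <- list(); seq_rows <- list()

  for (gi in seq_len(cfg$n_genera)) {
    g <- genera[gi]
    anc <- mutate_positions(root, free_pos, cfg$between_genus_divergence)
    n <- cfg$seqs_per_genus
    ## which tips keep each site perfect: exactly round(fraction * n)
    keep_perfect <- list()
    for (k in seq_along(cfg$primer_sites)) {
      s <- cfg$primer_sites[[k]]
      pf <- 1
      if (!is.null(s$perfect_fraction) && g %in% names(s$perfect_fraction))
        pf <- s$perfect_fraction[[g]]
      n_perf <- round(pf * n)
      keep_perfect[[iv$name[k]]] <-
        seq_len(n) %in% sample.int(n, n_perf)
    }
    for (ti in seq_len(n)) {
      sid <- sprintf("%s_seq%03d", g, ti)
      tip <- mutate_positions(anc, free_pos, cfg$within_genus_divergence)
      ## break designated sites with one incompatible substitution
      broken <- character(0)
      for (k in seq_along(cfg$primer_sites)) {
        nm <- iv$name[k]
        if (!keep_perfect[[nm]][ti]) {
          mc <- motif_chars[[nm]]
          breakable <- which(vapply(mc, function(code)
            length(IUPAC_SETS[[code]]) < 4L, logical(1)))
          if (length(breakable) > 0L) {
            off <- breakable[sample.int(length(breakable), 1L)]
            pos <- iv$start[k] + off - 1L
            tip[pos] <- sample(setdiff(bases, IUPAC_SETS[[mc[off]]]), 1L)
            broken <- c(broken, nm)
          }
        }
      }
      res <- apply_indels(tip, iv, cfg$indel_rate)
      ids <- c(ids, sid)
      seqs <- c(seqs, paste(res$chars, collapse = ""))
      tax <- c(tax, sprintf("Bacteria;SynPhylum;SynClass;SynOrder;SynFamily;%s", g))
      is_ts <- ti <= cfg$n_type_strains_per_genus
      type_flag <- c(type_flag, is_ts)
      seq_rows[[sid]] <- data.frame(id = sid, genus = g,
                                    is_type_strain = is_ts,
                                    stringsAsFactors = FALSE)
      for (k in seq_len(nrow(iv))) {
        nm <- iv$name[k]
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          id = sid, site = nm,
          perfect = !(nm %in% broken),
          start = res$site_start[k],
          end = res$site_start[k] + (iv$end[k] - iv$start[k]),
          stringsAsFactors = FALSE)
      }
    }
  }

  refs <- reference_set(id = ids, sequence = seqs, taxonomy = tax,
                        is_type_strain = type_flag, abundance = 1L)
  root_str <- paste(root, collapse = "")
  truth <- list(
    sequences = do.call(rbind, unname(seq_rows)),
    sites = if (length(site_rows) > 0L) do.call(rbind, site_rows)
            else data.frame(id = character(0), site = character(0),
                            perfect = logical(0), start = integer(0),
                            end = integer(0)),
    root = root_str,
    template = new_alignment("template_root", root_str)
  )
  list(refs = refs, truth = truth)
}

## Apply 1-3 nt indels at per-site rate outside the shielded intervals;
## returns mutated chars and the shifted start coordinate of every site.
apply_indels <- function(chars, iv, rate) {
  L <- length(chars)
  site_start <- iv$start
  if (rate <= 0 || L == 0L)
    return(list(chars = chars, site_start = site_start))
  in_site <- rep(FALSE, L)
  for (k in seq_len(nrow(iv))) in_site[iv$start[k]:iv$end[k]] <- TRUE
  events <- which(stats::runif(L) < rate & !in_site)
  bases <- c("A", "C", "G", "T")
  ## process right-to-left so earlier coordinates stay valid
  for (p in rev(events)) {
    len <- sample.int(3L, 1L)
    if (stats::runif(1) < 0.5) {
      ## deletion of [p, p+len-1], truncated at L and at the next site
      dend <- min(p + len - 1L, L)
      while (dend >= p && any(in_site[p:dend])) dend <- dend - 1L
      if (dend < p) next
      ndel <- dend - p + 1L
      chars <- chars[-(p:dend)]
      in_site <- in_site[-(p:dend)]
      site_start <- ifelse(site_start > p, site_start - ndel, site_start)
    } else {
      ins <- sample(bases, len, replace = TRUE)
      chars <- append(chars, ins, after = p)
      in_site <- append(in_site, rep(FALSE, len), after = p)
      site_start <- ifelse(site_start > p, site_start + len, site_start)
    }
  }
  list(chars = chars, site_start = site_start)
}

#' Expected pairwise identity under the generator's substitution model
#'
#' Closed-form expectation of the identity between two generated sequences
#' for the indel-free case, obtained by enumerating the independent
#' substitution events at a single site and averaging over shielded
#' (primer-site) and free positions. Under the uniform 3-alternative
#' substitution model a branch with rate d leaves a site unchanged with
#' probability (1 - d) + d * 0 and two independently mutated copies agree
#' with probability 1/3.
#'
#' @param cfg a \code{\link{synth_config}} with \code{indel_rate = 0}.
#' @return named numeric vector with elements \code{within} and
#'   \code{between}.
#' @export
expected_pairwise_identity <- function(cfg) {
  if (cfg$indel_rate != 0)
    stop("closed form requires indel_rate = 0")
  w <- cfg$within_genus_divergence
  b <- cfg$between_genus_divergence
  ## per-site transition matrix of one branch at rate p
  branch <- function(p) {
    m <- matrix(p / 3, 4, 4)
    diag(m) <- 1 - p
    m
  }
  ## P(tip = root base) after the stated branches
  agree_prob <- function(mats) {
    m <- Reduce(`%*%`, mats)
    m[1, 1]           # symmetric: same for every starting base
  }
  ## two tips are equal iff both chains land on the same base
  pair_identity <- function(a) a^2 + (1 - a)^2 / 3
  a_within <- agree_prob(list(branch(w)))
  a_between <- agree_prob(list(branch(b), branch(w)))
  iv <- site_intervals(cfg)
  n_shield <- if (nrow(iv) == 0L) 0L else sum(iv$end - iv$start + 1L)
  f_free <- (cfg$seq_length - n_shield) / cfg$seq_length
  ## shielded positions are identical between any two sequences with fully
  ## perfect sites; identity there is 1
  c(within = f_free * pair_identity(a_within) + (1 - f_free),
    between = f_free * pair_identity(a_between) + (1 - f_free))
}

#' Write a generated set to disk
#'
#' Emits the FASTA, the taxonomy TSV, and a truth TSV (site match status
#' and true coordinates per sequence).
#'
#' @param gen result of \code{\link{generate_reference_set}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_synthetic_set <- function(gen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(gen$refs, file.path(dir, "sequences.fasta"))
  write_taxonomy_table(gen$refs, file.path(dir, "taxonomy.tsv"))
  s <- gen$truth$sites
  writeLines(c("#id\tsite\tperfect\tstart\tend",
               sprintf("%s\t%s\t%d\t%d\t%d", s$id, s$site,
                       as.integer(s$perfect), s$start, s$end)),
             file.path(dir, "truth_sites.tsv"))
  write_fasta(reference_set("template_root", gen$truth$root),
              file.path(dir, "template.fasta"))
  invisible(dir)
}
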