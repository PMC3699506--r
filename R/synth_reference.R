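# Synthetic reference database: full-length 16S-like sequences evolved down
# a fixed six-rank taxonomy (domain..genus) by per-rank substitutions, with
# intact 27F / 357R primer-binding sites so region extraction behaves as it
# would on curated full-length records.

#' Describe one genus of the synthetic taxonomy
#'
#' @param lineage Character vector of exactly six ranked labels
#'   (domain, phylum, class, order, family, genus).
#' @param n_ref_seqs Number of reference sequences to emit for the genus.
#' @param divergence Numeric vector of six per-rank expected substitution
#'   proportions between sibling taxa (each in `[0, 0.75)`).
#' @return A `taxon_spec` list.
#' @export
taxon_spec <- function(lineage, n_ref_seqs = 3L,
                       divergence = c(0, 0.20, 0.12, 0.10, 0.08, 0.08)) {
  lineage <- as.character(lineage)
  if (length(lineage) != 6L || anyNA(lineage) || any(lineage == "")) {
    stop("lineage must have exactly 6 non-empty ranks (domain..genus)")
  }
  if (length(divergence) != 6L || any(divergence < 0) || any(divergence >= 0.75)) {
    stop("divergence must be 6 values in [0, 0.75)")
  }
  if (n_ref_seqs < 1L) stop("n_ref_seqs must be >= 1")
  structure(list(lineage = lineage, n_ref_seqs = as.integer(n_ref_seqs),
                 divergence = as.numeric(divergence)),
            class = "taxon_spec")
}

# Break single-base runs longer than `max_run` by substituting the excess
# positions with bases differing from both the run base and the previous
# replacement.  Reference 16S sequences rarely carry long homopolymers,
# and emitting them would make the read quality filter (which rejects
# runs over 6) discard whole genera of error-free reads.
cap_homopolymers <- function(chars, max_run = 5L) {
  bases <- c("A", "C", "G", "T")
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  for (j in which(r$lengths > max_run)) {
    run_base <- r$values[j]
    pos <- (ends[j] - r$lengths[j] + max_run + 1L):ends[j]
    for (p in pos) {
      prev <- chars[p - 1L]
      chars[p] <- sample(setdiff(bases, c(run_base, prev)), 1L)
    }
  }
  chars
}

# Substitute a fixed proportion of sites, never touching masked positions.
# Positions are drawn by stratified jittered sampling (one uniform draw per
# even-width stratum), so the realized substitution proportion is close to
# `rate` in any sub-region of the molecule, not just globally — divergence
# specified for a taxon is then delivered tightly within the sequenced
# region as well.
mutate_sequence <- function(chars, rate, mask = integer()) {
  if (rate <= 0) return(chars)
  mutable <- setdiff(seq_along(chars), mask)
  m <- length(mutable)
  k <- round(rate * m)
  if (k < 1L) return(chars)
  spacing <- m / k
  picks <- floor((seq_len(k) - 1L) * spacing + runif(k, 0, spacing)) + 1L
  hit <- mutable[unique(pmin(picks, m))]
  bases <- c("A", "C", "G", "T")
  n <- length(chars)
  # substitute to a base differing from the original and from both
  # neighbours, so substitutions never extend or bridge homopolymer runs
  # (stratified spacing keeps hits far apart, so pre-mutation neighbours
  # are valid)
  repl <- vapply(hit, function(p) {
    forbid <- c(chars[p],
                if (p > 1L) chars[p - 1L],
                if (p < n) chars[p + 1L])
    sample(setdiff(bases, forbid), 1L)
  }, character(1L))
  chars[hit] <- repl
  chars
}

#' Generate a synthetic full-length reference database
#'
#' A random root sequence of `root_length` nt carries the 27F site and the
#' 357R binding site (the reverse complement of the reverse primer) at fixed
#' coordinates.  Taxa are then evolved down the shared taxonomy: each node
#' at rank r mutates its parent's sequence at half the rank-r divergence, so
#' sibling taxa differ at roughly the stated proportion.  Reference
#' sequences within a genus are near-identical copies differing at
#' `within_divergence`.  Primer sites are masked from mutation.
#'
#' @param taxon_specs List of [taxon_spec()] objects with distinct lineages.
#' @param root_length Length of the root sequence (>= 1200 nt).
#' @param seed Integer RNG seed; identical seeds give identical databases.
#' @param within_divergence Expected substitution proportion between
#'   reference sequences of the same genus.
#' @return A `reference_set`: list with `records` (see [seq_records()]) and
#'   `lineage` (`data.frame` of `seq_id` plus the six rank columns).
#' @export
make_reference <- function(taxon_specs, root_length = 1300L, seed = 1L,
                           within_divergence = 0.005) {
  if (root_length < 1200L) stop("root_length must be >= 1200")
  if (inherits(taxon_specs, "taxon_spec")) taxon_specs <- list(taxon_specs)
  lineages <- t(vapply(taxon_specs, function(s) s$lineage, character(6L)))
  if (anyDuplicated(apply(lineages, 1L, paste, collapse = ";"))) {
    stop("duplicate lineages in taxon_specs")
  }
  # Taxonomy must be a tree: a label at rank r determines its parent path.
  for (r in 2:6) {
    key <- lineages[, r]
    parent <- apply(lineages[, seq_len(r - 1L), drop = FALSE], 1L,
                    paste, collapse = ";")
    if (any(tapply(parent, key, function(p) length(unique(p))) > 1L)) {
      stop("duplicate ", TAXO_RANKS[r],
           " label under different parents: taxonomy must be a tree")
    }
  }
  with_seed(seed, {
    root <- cap_homopolymers(
      sample(c("A", "C", "G", "T"), root_length, replace = TRUE))
    fwd_start <- 21L                               # 1-based
    rev_site <- revcomp(PRIMER_357R)
    rev_start <- 351L
    root[fwd_start:(fwd_start + nchar(PRIMER_27F) - 1L)] <-
      strsplit(PRIMER_27F, "")[[1]]
    root[rev_start:(rev_start + nchar(rev_site) - 1L)] <-
      strsplit(rev_site, "")[[1]]
    mask <- c(fwd_start:(fwd_start + nchar(PRIMER_27F) - 1L),
              rev_start:(rev_start + nchar(rev_site) - 1L))

    node_seq <- new.env(parent = emptyenv())
    assign("<root>", root, envir = node_seq)
    ids <- character(0); seqs <- character(0); lin_rows <- list()
    for (spec in taxon_specs) {
      parent_key <- "<root>"
      for (r in 1:6) {
        key <- paste(spec$lineage[seq_len(r)], collapse = ";")
        if (!exists(key, envir = node_seq, inherits = FALSE)) {
          parent <- get(parent_key, envir = node_seq)
          assign(key, mutate_sequence(parent, spec$divergence[r] / 2, mask),
                 envir = node_seq)
        }
        parent_key <- key
      }
      genus_chars <- get(parent_key, envir = node_seq)
      for (i in seq_len(spec$n_ref_seqs)) {
        chars <- mutate_sequence(genus_chars, within_divergence / 2, mask)
        ids <- c(ids, sprintf("%s_%d", spec$lineage[6], i))
        seqs <- c(seqs, paste(chars, collapse = ""))
        lin_rows[[length(lin_rows) + 1L]] <- spec$lineage
      }
    }
    lineage <- data.frame(seq_id = ids,
                          do.call(rbind, lin_rows),
                          stringsAsFactors = FALSE)
    names(lineage) <- c("seq_id", TAXO_RANKS)
    rownames(lineage) <- NULL
    structure(list(records = seq_records(ids, seqs), lineage = lineage),
              class = "reference_set")
  })
}

#' Write a reference set to FASTA plus a lineage TSV
#'
#' @param ref A `reference_set` from [make_reference()].
#' @param fasta_path,lineage_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_reference <- function(ref, fasta_path, lineage_path) {
  write_sequences(ref$records, fasta_path, "fasta")
  utils::write.table(ref$lineage, lineage_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, lineage_path))
}

#' Read a lineage TSV (seq_id plus six rank columns)
#' @param path TSV path.
#' @return `data.frame` with `seq_id` and the six rank columns.
#' @export
read_lineage_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("seq_id", TAXO_RANKS)
  if (!all(need %in% names(df))) {
    stop("lineage table must have columns: ", paste(need, collapse = ", "))
  }
  df[, need]
}

#' Default rumen-like taxonomy for the synthetic generators
#'
#' Ten genera spanning five phyla with abundances and treatment responses
#' reminiscent of the rumen bacterial community of concentrate-fed dairy
#' cattle.
#'
#' @param n_ref_seqs Reference sequences per genus.
#' @return List of [taxon_spec()] objects.
#' @export
rumen_taxon_specs <- function(n_ref_seqs = 3L) {
  g <- function(phy, cls, ord, fam, gen) {
    taxon_spec(c("Bacteria", phy, cls, ord, fam, gen),
               n_ref_seqs = n_ref_seqs)
  }
  list(
    g("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Prevotellaceae",
      "Prevotella"),
    g("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae",
      "Butyrivibrio"),
    g("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae",
      "Syntrophococcus"),
    g("Firmicutes", "Clostridia", "Clostridiales", "Ruminococcaceae",
      "Ruminococcus"),
    g("Firmicutes", "Negativicutes", "Selenomonadales", "Veillonellaceae",
      "Megasphaera"),
    g("Firmicutes", "Negativicutes", "Selenomonadales", "Veillonellaceae",
      "Selenomonas"),
    g("Firmicutes", "Negativicutes", "Selenomonadales", "Veillonellaceae",
      "Mitsuokella"),
    g("Proteobacteria", "Gammaproteobacteria", "Aeromonadales",
      "Succinivibrionaceae", "Succinivibrio"),
    g("Fibrobacteres", "Fibrobacteria", "Fibrobacterales",
      "Fibrobacteraceae", "Fibrobacter"),
    g("Actinobacteria", "Actinobacteria_c", "Bifidobacteriales",
      "Bifidobacteriaceae", "Bifidobacterium")
  )
}
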