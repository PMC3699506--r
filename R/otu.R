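# Greedy identity clustering into OTUs (CD-HIT-style: longest-first,
# identity = matches / shorter length, word prefilter, multi-step cascade),
# rank-wise consensus classification at 80% agreement, and the
# threshold-calibration scan comparing clustered to unclustered
# composition by Spearman rank correlation.

# Identity between a sequence and each of several OTU representatives:
# alignment matches divided by the shorter sequence length (batched into
# one alignment call).
batch_pair_identity <- function(query, reps) {
  out <- numeric(length(reps))
  # the shorter sequence being an exact substring of the longer gives
  # identity 1 under the shorter-length denominator
  exact <- vapply(reps, function(r) {
    if (nchar(query) <= nchar(r)) grepl(query, r, fixed = TRUE)
    else grepl(r, query, fixed = TRUE)
  }, logical(1L), USE.NAMES = FALSE)
  out[exact] <- 1
  todo <- which(!exact)
  if (length(todo)) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(reps[todo]), query, type = "overlap",
      substitutionMatrix = align_submat(), gapOpening = 5, gapExtension = 2)
    out[todo] <- Biostrings::nmatch(al) /
      pmin(nchar(query), nchar(reps[todo]))
  }
  out
}

pair_identity <- function(a, b) batch_pair_identity(a, b)

# One greedy pass at a fixed threshold.  `ids`/`seqs` are parallel; input
# is processed longest-first (ties by id) and each sequence joins the
# first OTU (in creation order) whose representative it matches at or
# above the threshold, else founds a new OTU.
cluster_step <- function(ids, seqs, threshold, word = 5L) {
  ord <- order(-nchar(seqs), ids)
  ids <- ids[ord]; seqs <- seqs[ord]
  rep_id <- character(0); rep_seq <- character(0)
  members <- list()
  exact <- new.env(parent = emptyenv())     # rep sequence -> OTU index
  kindex <- new.env(parent = emptyenv())    # word -> OTU indices
  for (i in seq_along(seqs)) {
    sq <- seqs[i]
    hit <- exact[[sq]]
    if (is.null(hit)) {
      kms <- distinct_kmers(sq, word)
      cand <- sort(unique(unlist(lapply(kms, function(km) kindex[[km]]),
                                 use.names = FALSE)))
      if (length(cand)) {
        ident <- batch_pair_identity(sq, rep_seq[cand])
        ok <- which(ident >= threshold - 1e-9)
        if (length(ok)) hit <- cand[ok[1L]]
      }
    }
    if (is.null(hit)) {
      j <- length(rep_id) + 1L
      rep_id[j] <- ids[i]; rep_seq[j] <- sq
      members[[j]] <- ids[i]
      exact[[sq]] <- j
      for (km in distinct_kmers(sq, word)) {
        kindex[[km]] <- c(kindex[[km]], j)
      }
    } else {
      members[[hit]] <- c(members[[hit]], ids[i])
    }
  }
  list(rep_id = rep_id, rep_seq = rep_seq, members = members)
}

#' Greedy identity clustering into OTUs
#'
#' Sequences are clustered longest-first: each joins the first existing
#' OTU whose representative it matches at or above the identity threshold
#' (identity = alignment matches divided by the shorter sequence length,
#' with a shared-word prefilter), otherwise it founds a new OTU.  In
#' multi-step mode the clustering cascades through decreasing thresholds
#' (100%, 99%, ... down to the target, with a direct final step below
#' 90%), re-clustering representatives and merging member lists at each
#' step.
#'
#' @param seqs Named character vector of sequences (names are ids), or a
#'   sequence-record table.
#' @param threshold Identity threshold in `[0.5, 1]`.
#' @param word Word size of the candidate prefilter.
#' @param multi_step Use the iterated cascade (recommended; matches the
#'   calibration scan).
#' @return List of class `otu_set`: `rep_id`, `rep_seq`, `members` (list
#'   of member id vectors).  Every input sequence belongs to exactly one
#'   OTU.
#' @export
greedy_cluster <- function(seqs, threshold, word = 5L, multi_step = TRUE) {
  if (is.data.frame(seqs)) {
    ids <- seqs$id; sqs <- seqs$seq
  } else {
    sqs <- unname(seqs)
    ids <- if (is.null(names(seqs))) {
      sprintf("seq_%05d", seq_along(seqs))
    } else names(seqs)
  }
  if (length(sqs) == 0L) stop("no sequences to cluster")
  if (threshold < 0.5 || threshold > 1) stop("threshold must be in [0.5, 1]")
  steps <- if (multi_step) {
    base <- round(seq(1.00, 0.90, by = -0.01), 2L)
    c(base[base > threshold + 1e-9], threshold)
  } else {
    threshold
  }
  snaps <- cluster_cascade(ids, sqs, steps, word)
  snaps[[length(snaps)]]
}

# Run the threshold cascade once, returning the otu_set after every step.
cluster_cascade <- function(ids, sqs, steps, word = 5L) {
  res <- cluster_step(ids, sqs, steps[1L], word)
  snaps <- list(structure(res, class = "otu_set"))
  for (s in steps[-1L]) {
    nxt <- cluster_step(res$rep_id, res$rep_seq, s, word)
    merged <- lapply(nxt$members, function(m) {
      unlist(res$members[match(m, res$rep_id)], use.names = FALSE)
    })
    res <- list(rep_id = nxt$rep_id, rep_seq = nxt$rep_seq,
                members = merged)
    snaps[[length(snaps) + 1L]] <- structure(res, class = "otu_set")
  }
  names(snaps) <- format(steps)
  snaps
}

#' Consensus classification of an OTU
#'
#' Walks from genus up to domain: the first rank at which at least
#' `agreement` of the members share one full lineage prefix labels the OTU
#' at that depth (members unclassified at the rank count against
#' agreement).  If no rank reaches agreement the OTU is unclassified.
#'
#' @param lineages Character matrix (members x 6 ranks, `NA` =
#'   unclassified), or `data.frame` with the six rank columns.
#' @param agreement Required fraction of members sharing a prefix.
#' @return Character vector of 6 ranks, `NA` beyond the consensus depth
#'   (all `NA` when unclassified).
#' @export
consensus_classify <- function(lineages, agreement = 0.80) {
  if (is.data.frame(lineages)) {
    lineages <- as.matrix(lineages[, TAXO_RANKS, drop = FALSE])
  }
  n <- nrow(lineages)
  if (n == 0L) stop("empty OTU")
  for (r in 6:1) {
    has <- !is.na(lineages[, r])
    # members must be classified through rank r for their prefix to count
    full <- has & rowSums(is.na(lineages[, seq_len(r), drop = FALSE])) == 0L
    if (!any(full)) next
    keys <- apply(lineages[full, seq_len(r), drop = FALSE], 1L,
                  paste, collapse = "\r")
    tab <- sort(table(keys), decreasing = TRUE)
    if (tab[1L] >= agreement * n - 1e-9) {
      win <- names(tab)[1L]
      out <- rep(NA_character_, 6L)
      out[seq_len(r)] <- strsplit(win, "\r", fixed = TRUE)[[1]]
      return(out)
    }
  }
  rep(NA_character_, 6L)
}

# Member-weighted composition at one rank: named numeric of summed weights
# per full lineage prefix (unclassified-at-rank mass excluded).
rank_composition <- function(lin_mat, rank_idx, weights) {
  full <- rowSums(is.na(lin_mat[, seq_len(rank_idx), drop = FALSE])) == 0L
  if (!any(full)) return(numeric(0))
  keys <- apply(lin_mat[full, seq_len(rank_idx), drop = FALSE], 1L,
                paste, collapse = "\r")
  v <- tapply(weights[full], keys, sum)
  p <- as.numeric(v) / sum(v)
  names(p) <- names(v)
  p
}

#' Clustering-threshold calibration scan
#'
#' For each identity threshold (100% down to 90% in 1% steps plus a final
#' 85% run), sequences are clustered, each OTU receives its consensus
#' classification, and the member-weighted per-rank relative abundances
#' are compared with the unclustered composition by Spearman rank
#' correlation over the union of taxa (absent taxa counted as zero).  At
#' 100% the clustering is a dereplication, so the correlation is exactly 1
#' at every defined rank.
#'
#' @param seqs Named character vector (names = ids) of sequences.
#' @param lineages `data.frame`/matrix of per-sequence lineages (rows
#'   aligned with `seqs`; six rank columns, `NA` = unclassified).
#' @param weights Per-sequence weights (e.g. read multiplicities); default
#'   1.
#' @param thresholds Thresholds to scan.
#' @param agreement Consensus agreement level.
#' @param word Clustering word size.
#' @return `data.frame`: threshold, n_otus, and one Spearman-rho column
#'   per rank phylum..genus (`NA` when fewer than 3 taxa are defined at a
#'   rank).
#' @export
threshold_scan <- function(seqs, lineages, weights = NULL,
                           thresholds = c(round(seq(1, 0.90, -0.01), 2L), 0.85),
                           agreement = 0.80, word = 5L) {
  ids <- names(seqs)
  if (is.null(ids)) stop("seqs must be named by sequence id")
  if (is.null(weights)) weights <- rep(1, length(seqs))
  lineages <- as.data.frame(lineages, stringsAsFactors = FALSE)
  if (!all(TAXO_RANKS %in% names(lineages))) {
    if (ncol(lineages) != 6L) {
      stop("lineages must have the six rank columns (domain..genus)")
    }
    names(lineages) <- TAXO_RANKS
  }
  lin_mat <- as.matrix(lineages[, TAXO_RANKS, drop = FALSE])
  rownames(lin_mat) <- ids
  scan_ranks <- TAXO_RANKS[-1L]           # phylum .. genus
  base <- lapply(2:6, function(r) rank_composition(lin_mat, r, weights))
  names(base) <- scan_ranks
  thresholds <- sort(thresholds, decreasing = TRUE)
  snaps <- cluster_cascade(ids, unname(seqs), thresholds, word)
  rows <- lapply(seq_along(thresholds), function(ti) {
    th <- thresholds[ti]
    otus <- snaps[[ti]]
    otu_w <- vapply(otus$members, function(m) {
      sum(weights[match(m, ids)])
    }, numeric(1L))
    cons <- t(vapply(otus$members, function(m) {
      consensus_classify(lin_mat[m, , drop = FALSE], agreement)
    }, character(6L)))
    rho <- vapply(seq_along(scan_ranks), function(k) {
      r <- k + 1L
      comp <- rank_composition(cons, r, otu_w)
      ref <- base[[k]]
      taxa <- union(names(ref), names(comp))
      if (length(taxa) < 3L) return(NA_real_)
      x <- setNames(rep(0, length(taxa)), taxa); x[names(ref)] <- ref
      y <- setNames(rep(0, length(taxa)), taxa); y[names(comp)] <- comp
      if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
      cor(x, y, method = "spearman")
    }, numeric(1L))
    c(threshold = th, n_otus = length(otus$members),
      setNames(rho, scan_ranks))
  })
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
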