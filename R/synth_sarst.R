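# Synthetic serial-tag concatemers: V1 ribosomal sequence tags (RSTs)
# joined by the 8-nt head-tail border, as produced by concatemer cloning of
# short V1 amplicons.

SARST_BORDER <- "ACGGGTCG"

#' Build synthetic tag concatemers
#'
#' Joins randomly drawn V1 tags into clone inserts, separated by the 8-nt
#' head-tail border.  Because ligation orientation is random, each junction
#' uses either the border or its reverse complement.  Ground truth (the
#' ordered tags of every clone) is returned as a sidecar table.
#'
#' @param rsts Character vector of V1 tag sequences (lengths 40-70 nt).
#' @param n_clones Number of clone inserts to build.
#' @param tags_per_clone Integer vector of possible tag counts per clone,
#'   sampled uniformly; maximum allowed is 15.
#' @param border 8-nt head-tail border sequence.
#' @param terminal_borders Also place borders at both ends of the insert.
#' @param seed RNG seed.
#' @return List with `records` (insert sequence table, ids `clone_<i>`) and
#'   `truth` (`data.frame`: clone_id, index, rst).
#' @export
build_concatemers <- function(rsts, n_clones = 96L, tags_per_clone = 1:15,
                              border = SARST_BORDER,
                              terminal_borders = FALSE, seed = 1L) {
  if (any(tags_per_clone > 15L)) stop("tags_per_clone must not exceed 15")
  if (any(tags_per_clone < 1L)) stop("tags_per_clone must be >= 1")
  len <- nchar(rsts)
  if (any(len < 40L | len > 70L)) {
    stop("RST lengths must lie in [40, 70]")
  }
  border_rc <- revcomp(border)
  with_seed(seed, {
    ids <- character(n_clones); seqs <- character(n_clones)
    rows <- vector("list", n_clones)
    for (i in seq_len(n_clones)) {
      k <- tags_per_clone[sample.int(length(tags_per_clone), 1L)]
      picks <- sample.int(length(rsts), k, replace = TRUE)
      tags <- rsts[picks]
      n_borders <- (k - 1L) + if (terminal_borders) 2L else 0L
      forms <- if (n_borders > 0L) {
        sample(c(border, border_rc), n_borders, replace = TRUE)
      } else character(0)
      pieces <- character(0)
      bi <- 0L
      if (terminal_borders) { bi <- bi + 1L; pieces <- forms[bi] }
      for (j in seq_len(k)) {
        pieces <- c(pieces, tags[j])
        if (j < k) { bi <- bi + 1L; pieces <- c(pieces, forms[bi]) }
      }
      if (terminal_borders) { bi <- bi + 1L; pieces <- c(pieces, forms[bi]) }
      ids[i] <- sprintf("clone_%04d", i)
      seqs[i] <- paste(pieces, collapse = "")
      rows[[i]] <- data.frame(clone_id = ids[i], index = seq_len(k),
                              rst = tags, stringsAsFactors = FALSE)
    }
    list(records = seq_records(ids, seqs), truth = do.call(rbind, rows))
  })
}
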