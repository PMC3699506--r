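# Deconcatenation of serial-tag clone inserts: split at every occurrence of
# the 8-nt head-tail border (either orientation), keep fragments inside the
# tag length window.

#' Split a concatemer insert into ribosomal sequence tags
#'
#' The insert is cut at every non-overlapping occurrence of the head-tail
#' border `5'-ACGGGTCG-3'` or its reverse complement `5'-CGACCCGT-3'`,
#' scanning left to right (both forms searched simultaneously, greedy).
#' Fragments outside the length window are discarded and counted; surviving
#' fragments become tags in insert order.  An insert without any border is
#' evaluated as a single candidate fragment.
#'
#' @param insert DNA string (vector-trimmed clone insert).
#' @param border Head-tail border (its reverse complement is searched too).
#' @param window Length-2 numeric: admissible tag length range.
#' @param clone_id Identifier used for tag ids.
#' @return List with `rsts` (`data.frame`: clone_id, index, sequence) and
#'   `n_discarded` / `discarded_lengths` for out-of-window fragments.
#' @export
split_concatemer <- function(insert, border = SARST_BORDER,
                             window = c(40L, 70L), clone_id = "clone") {
  insert <- normalise_dna(insert)
  forms <- unique(c(border, revcomp(border)))
  pat <- paste(forms, collapse = "|")
  frags <- strsplit(insert, pat)[[1]]
  if (length(frags) == 0L) frags <- ""   # insert made only of borders
  keep <- nchar(frags) >= window[1L] & nchar(frags) <= window[2L]
  kept <- frags[keep]
  out <- if (length(kept)) {
    data.frame(clone_id = clone_id, index = seq_along(kept),
               sequence = kept, stringsAsFactors = FALSE)
  } else {
    data.frame(clone_id = character(0), index = integer(0),
               sequence = character(0), stringsAsFactors = FALSE)
  }
  list(rsts = out, n_discarded = sum(!keep),
       discarded_lengths = nchar(frags[!keep]))
}

#' Split every insert of a record set
#'
#' @param records Sequence-record table of clone inserts.
#' @param ... Passed to [split_concatemer()].
#' @return List with `rsts` (table over all clones, ids
#'   `<clone_id>.<index>`) and `n_discarded` (total out-of-window
#'   fragments).
#' @export
split_concatemers <- function(records, ...) {
  pieces <- lapply(seq_len(nrow(records)), function(i) {
    split_concatemer(records$seq[i], clone_id = records$id[i], ...)
  })
  rsts <- do.call(rbind, lapply(pieces, `[[`, "rsts"))
  rsts$id <- paste(rsts$clone_id, rsts$index, sep = ".")
  list(rsts = rsts,
       n_discarded = sum(vapply(pieces, `[[`, numeric(1L), "n_discarded")))
}
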