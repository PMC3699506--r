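# Demultiplexing of barcoded pyrosequencing-style reads and the quality
# filters applied before taxonomy assignment: at most 2 Ns, mean Phred
# quality >= 20, trimmed length in [200, 400], no single-base run longer
# than 6.

#' Demultiplexing rule
#'
#' @param tags Named character vector: 4-nt barcode -> sample label.
#' @param reverse_primer Reverse (357R) primer expected after the barcode.
#' @param forward_primer Forward (27F) primer (bookkeeping; reads are
#'   sequenced from the reverse end).
#' @param max_tag_mismatch Maximum mismatches allowed on the barcode.
#' @param max_primer_mismatch Maximum mismatches allowed on the primer.
#' @return A `demux_rule` list.  Tags must be distinct with pairwise
#'   Hamming distance >= 2; otherwise loading fails.
#' @export
demux_rule <- function(tags, reverse_primer = PRIMER_357R,
                       forward_primer = PRIMER_27F,
                       max_tag_mismatch = 1L, max_primer_mismatch = 2L) {
  if (is.null(names(tags)) || any(names(tags) == "")) {
    stop("tags must be a named vector (barcode names are sample labels)")
  }
  tags <- setNames(normalise_dna(tags), names(tags))
  if (any(nchar(tags) != 4L)) stop("barcodes must be 4 nt")
  if (anyDuplicated(tags)) stop("duplicate barcodes")
  if (length(tags) > 1L) {
    prs <- combn(seq_along(tags), 2L)
    dd <- apply(prs, 2L, function(ij) hamming(tags[ij[1L]], tags[ij[2L]]))
    if (any(dd < 2L)) {
      stop("barcodes must have pairwise Hamming distance >= 2")
    }
  }
  structure(list(tags = tags, reverse_primer = normalise_dna(reverse_primer),
                 forward_primer = normalise_dna(forward_primer),
                 max_tag_mismatch = as.integer(max_tag_mismatch),
                 max_primer_mismatch = as.integer(max_primer_mismatch)),
            class = "demux_rule")
}

#' Demultiplex barcoded reads
#'
#' Reads are expected tag-first in sequencing orientation: 4-nt barcode,
#' reverse primer, insert.  The barcode is matched with at most
#' `max_tag_mismatch` mismatches (two barcodes both matching sends the read
#' to the unassigned bin with reason `"ambiguous"`), then the reverse
#' primer with at most `max_primer_mismatch` mismatches.  Matched reads
#' have tag and primer trimmed and the insert reverse-complemented into
#' plus (27F -> 357R) orientation; qualities are trimmed and reversed
#' alongside.
#'
#' @param reads Sequence-record table (see [read_sequences()]).
#' @param rule A [demux_rule()].
#' @return A `data.frame` with columns `read_id`, `sample`, `status`
#'   (`assigned` / `rejected` / `unassigned`), `reason`, `insert`, and list
#'   column `qual` (insert-oriented qualities).
#' @export
demultiplex <- function(reads, rule) {
  stopifnot(inherits(rule, "demux_rule"))
  tag_names <- names(rule$tags)
  plen <- nchar(rule$reverse_primer)
  n <- nrow(reads)
  sample <- rep(NA_character_, n)
  status <- rep("unassigned", n)
  reason <- rep(NA_character_, n)
  insert <- rep(NA_character_, n)
  qual <- vector("list", n)
  for (i in seq_len(n)) {
    sq <- reads$seq[i]
    if (nchar(sq) < 4L + plen + 1L) {
      reason[i] <- "tag"
      next
    }
    tg <- substr(sq, 1L, 4L)
    dists <- vapply(rule$tags, function(t) hamming(tg, t), integer(1L))
    ok <- which(dists <= rule$max_tag_mismatch)
    if (length(ok) == 0L) {
      reason[i] <- "tag"
      next
    }
    if (length(ok) > 1L) {
      reason[i] <- "ambiguous"
      next
    }
    pr <- substr(sq, 5L, 4L + plen)
    if (hamming(pr, rule$reverse_primer) > rule$max_primer_mismatch) {
      status[i] <- "rejected"
      sample[i] <- tag_names[ok]
      reason[i] <- "primer"
      next
    }
    status[i] <- "assigned"
    sample[i] <- tag_names[ok]
    insert[i] <- substr(sq, 4L + plen + 1L, nchar(sq))
    q <- reads$qual[[i]]
    if (!is.null(q)) {
      qual[[i]] <- rev(q[(4L + plen + 1L):length(q)])
    }
  }
  hit <- !is.na(insert)
  insert[hit] <- revcomp(insert[hit])   # one batched call
  out <- data.frame(read_id = reads$id, sample = sample, status = status,
                    reason = reason, insert = insert,
                    stringsAsFactors = FALSE)
  out$qual <- qual
  out
}

#' Quality-filter demultiplexed inserts
#'
#' A read passes iff it has at most 2 Ns, mean quality >= 20, trimmed
#' length between 200 and 400 nt, and no single-base run longer than 6.
#' Rules are evaluated in the fixed order ns, quality, length,
#' homopolymer; the first failing rule is recorded as the reason, so
#' reason counts are reproducible.
#'
#' @param inserts Character vector of plus-orientation inserts.
#' @param quals List of per-base integer qualities (one per insert;
#'   missing qualities are an error).
#' @param max_n,min_mean_quality,min_length,max_length,max_homopolymer
#'   Filter thresholds.
#' @return `data.frame` with columns `verdict` (`pass`/`reject`) and
#'   `reason` (`NA` for passes).
#' @export
quality_filter <- function(inserts, quals, max_n = 2L,
                           min_mean_quality = 20, min_length = 200L,
                           max_length = 400L, max_homopolymer = 6L) {
  n <- length(inserts)
  if (length(quals) != n) stop("inserts and quals lengths differ")
  verdict <- character(n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    q <- quals[[i]]
    if (is.null(q)) stop("missing qualities for insert ", i)
    chars <- strsplit(inserts[i], "")[[1]]
    if (sum(chars == "N") > max_n) {
      verdict[i] <- "reject"; reason[i] <- "ns"; next
    }
    if (mean(q) < min_mean_quality) {
      verdict[i] <- "reject"; reason[i] <- "quality"; next
    }
    len <- length(chars)
    if (len < min_length || len > max_length) {
      verdict[i] <- "reject"; reason[i] <- "length"; next
    }
    if (max(rle(chars)$lengths) > max_homopolymer) {
      verdict[i] <- "reject"; reason[i] <- "homopolymer"; next
    }
    verdict[i] <- "pass"
  }
  data.frame(verdict = verdict, reason = reason, stringsAsFactors = FALSE)
}

#' Demultiplex and quality-filter in one pass
#'
#' Runs [demultiplex()] then [quality_filter()] on the assigned inserts and
#' summarises per-sample pass counts.
#'
#' @param reads Sequence-record table with qualities.
#' @param rule A [demux_rule()].
#' @param ... Passed to [quality_filter()].
#' @return List with `reads` (per-read table: read_id, sample, status,
#'   reason, insert, qual), and `per_sample` (pass counts by sample).
#'   Every input read lands in exactly one of assigned-pass,
#'   assigned-reject, unassigned.
#' @export
run_qc <- function(reads, rule, ...) {
  dm <- demultiplex(reads, rule)
  idx <- which(dm$status == "assigned")
  if (length(idx)) {
    qf <- quality_filter(dm$insert[idx], dm$qual[idx], ...)
    fail <- qf$verdict == "reject"
    dm$status[idx[fail]] <- "rejected"
    dm$reason[idx[fail]] <- qf$reason[fail]
  }
  passed <- dm[dm$status == "assigned", , drop = FALSE]
  per_sample <- if (nrow(passed)) table(passed$sample) else table(character(0))
  list(reads = dm, per_sample = per_sample)
}
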