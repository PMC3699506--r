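# Nearest-neighbour taxonomy transfer: extract the sequenced region from
# full-length references, dereplicate, find candidate neighbours by shared
# 7-mers, screen candidates by global-alignment identity (>= 95% over a
# span within +/-5 nt of the query length, rejecting likely chimeras), and
# transfer the lineage of the closest neighbour under the Jukes-Cantor
# distance.

# Scoring used for all query-vs-reference alignments: match +1, mismatch
# -1, gap open 5, gap extend 2, free end gaps (semi-global).  N never
# matches anything, including another N.
align_submat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      bases <- c("A", "C", "G", "T", "N")
      mm <- matrix(-1, 5L, 5L, dimnames = list(bases, bases))
      diag(mm) <- 1
      mm["N", ] <- -1; mm[, "N"] <- -1
      m <<- mm
    }
    m
  }
})

#' Extract the amplified region from full-length references
#'
#' Keeps records on which both the forward and reverse primer sites are
#' found exactly once (each with at most `max_mismatch` mismatches, in the
#' correct order and orientation) and stores the inter-primer region,
#' inclusive of neither primer.  Records missing a site, or with a site
#' found twice, are dropped with a reason count.
#'
#' @param ref A `reference_set` (see [make_reference()]), or a list with
#'   `records` and `lineage` in the same layout.
#' @param fwd_primer,rev_primer Primer sequences (reverse primer in
#'   sequencing orientation).
#' @param max_mismatch Mismatches tolerated per primer site.
#' @return A `reference_db`: list with `records` (`data.frame`: id, region,
#'   plus lineage columns), `dropped` (named reason counts), and alignment
#'   bookkeeping slots filled by [build_kmer_index()].
#' @export
extract_region <- function(ref, fwd_primer = PRIMER_27F,
                           rev_primer = PRIMER_357R, max_mismatch = 2L) {
  rc <- region_coords(ref$records$seq, fwd_primer, rev_primer, max_mismatch)
  keep <- !is.na(rc$start)
  dropped <- table(rc$reason[!keep])
  recs <- data.frame(id = ref$records$id[keep],
                     region = substr(ref$records$seq, rc$start, rc$end)[keep],
                     stringsAsFactors = FALSE)
  lin <- ref$lineage[keep, TAXO_RANKS, drop = FALSE]
  rownames(lin) <- NULL
  recs <- cbind(recs, lin)
  ord <- order(recs$id)
  recs <- recs[ord, , drop = FALSE]
  rownames(recs) <- NULL
  structure(list(records = recs, dropped = dropped,
                 kmer_index = NULL, word = NULL),
            class = "reference_db")
}

# Deepest shared classified prefix of a set of lineages (rows of a
# character matrix, NA = unclassified).
common_lineage <- function(lin_mat) {
  out <- rep(NA_character_, 6L)
  for (r in 1:6) {
    vals <- lin_mat[, r]
    if (anyNA(vals) || length(unique(vals)) != 1L) break
    out[r] <- vals[1L]
  }
  out
}

#' Collapse duplicate reference regions
#'
#' Exact-duplicate region sequences are collapsed to a single
#' representative (smallest id); the representative's lineage is the
#' duplicate set's deepest common classified lineage.
#'
#' @param db A `reference_db` from [extract_region()].
#' @return A `reference_db` with unique regions.
#' @export
dereplicate <- function(db) {
  recs <- db$records
  grp <- split(seq_len(nrow(recs)), recs$region)
  rows <- lapply(grp, function(idx) {
    idx <- idx[order(recs$id[idx])]
    lin <- common_lineage(as.matrix(recs[idx, TAXO_RANKS, drop = FALSE]))
    out <- recs[idx[1L], c("id", "region"), drop = FALSE]
    out[, TAXO_RANKS] <- as.list(lin)
    out
  })
  recs2 <- do.call(rbind, rows)
  recs2 <- recs2[order(recs2$id), , drop = FALSE]
  rownames(recs2) <- NULL
  structure(list(records = recs2, dropped = db$dropped,
                 kmer_index = NULL, word = NULL),
            class = "reference_db")
}

#' Build the word index used for candidate search
#'
#' @param db A `reference_db`.
#' @param word Word (k-mer) size.
#' @return The `reference_db` with its `kmer_index` populated.
#' @export
build_kmer_index <- function(db, word = 7L) {
  env <- new.env(parent = emptyenv(), size = 4L * nrow(db$records))
  for (i in seq_len(nrow(db$records))) {
    for (km in distinct_kmers(db$records$region[i], word)) {
      env[[km]] <- c(env[[km]], i)
    }
  }
  db$kmer_index <- env
  db$word <- as.integer(word)
  db
}

distinct_kmers <- function(seq, word) {
  n <- nchar(seq)
  if (n < word) return(character(0))
  unique(substring(seq, seq_len(n - word + 1L),
                   seq_len(n - word + 1L) + word - 1L))
}

#' Prepare a reference database for assignment
#'
#' Convenience chain: [extract_region()], [dereplicate()],
#' [build_kmer_index()].
#'
#' @inheritParams extract_region
#' @param word Word size for the candidate index.
#' @return A ready-to-query `reference_db`.
#' @export
prepare_reference_db <- function(ref, fwd_primer = PRIMER_27F,
                                 rev_primer = PRIMER_357R,
                                 max_mismatch = 2L, word = 7L) {
  build_kmer_index(dereplicate(
    extract_region(ref, fwd_primer, rev_primer, max_mismatch)), word)
}

#' Rank candidate references by shared words
#'
#' References are ranked by the number of distinct words shared with the
#' query (queries are plus-oriented; the reverse complement is not
#' searched); ties break by reference id order.  At most `max_hits`
#' references are returned.
#'
#' @param query Query DNA string.
#' @param db An indexed `reference_db`.
#' @param max_hits Maximum candidates returned.
#' @return Integer vector of row indices into `db$records` (possibly
#'   empty).
#' @export
find_candidates <- function(query, db, max_hits = 50L) {
  if (is.null(db$kmer_index)) stop("reference_db has no kmer index")
  kms <- distinct_kmers(normalise_dna(query), db$word)
  if (length(kms) == 0L) return(integer(0))
  posts <- unlist(lapply(kms, function(km) db$kmer_index[[km]]),
                  use.names = FALSE)
  if (length(posts) == 0L) return(integer(0))
  counts <- tabulate(posts, nbins = nrow(db$records))
  hits <- which(counts > 0L)
  hits <- hits[order(-counts[hits], hits)]
  head(hits, max_hits)
}

#' Globally align a query to a candidate and screen for identity
#'
#' Semi-global alignment (match +1, mismatch -1, gap open 5, gap extend 2,
#' free end gaps).  Identity is matches over alignment columns excluding
#' end-gap overhangs; the screen passes iff identity >= `min_identity` and
#' the non-overhang aligned span is within `span_tol` nt of the query
#' length (a short best span flags a likely chimera).  The mismatch
#' proportion `p_distance` is computed over gap-free columns only, as the
#' Jukes-Cantor model concerns substitutions.
#'
#' @param query,candidate DNA strings (candidate = a reference region).
#' @param min_identity Identity threshold.
#' @param span_tol Span tolerance in nt around the query length.
#' @return List: `identity`, `span`, `p_distance`, `n_mismatch`,
#'   `gap_free`, `pass`.
#' @export
align_and_screen <- function(query, candidate, min_identity = 0.95,
                             span_tol = 5L) {
  st <- batch_align_screen(query, candidate, min_identity, span_tol)
  as.list(st[1L, ])
}

# Vectorised core of align_and_screen: one query against many candidate
# regions in a single alignment call.
batch_align_screen <- function(query, candidates, min_identity = 0.95,
                               span_tol = 5L) {
  n <- length(candidates)
  out <- data.frame(identity = numeric(n), span = integer(n),
                    p_distance = rep(NA_real_, n),
                    n_mismatch = rep(NA_integer_, n),
                    gap_free = integer(n), pass = logical(n))
  # An exact substring match needs no alignment: identity 1, zero
  # mismatches, span equal to the query length.
  sub_hit <- !is.na(query) & vapply(candidates, function(cc) {
    grepl(query, cc, fixed = TRUE)
  }, logical(1L), USE.NAMES = FALSE)
  if (any(sub_hit)) {
    qlen <- nchar(query)
    out$identity[sub_hit] <- 1
    out$span[sub_hit] <- qlen
    out$p_distance[sub_hit] <- 0
    out$n_mismatch[sub_hit] <- 0L
    out$gap_free[sub_hit] <- qlen
    out$pass[sub_hit] <- TRUE
  }
  if (all(sub_hit)) return(out)
  todo <- which(!sub_hit)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(candidates[todo]), query, type = "overlap",
    substitutionMatrix = align_submat(),
    gapOpening = 5, gapExtension = 2)
  if (!grepl("N", query, fixed = TRUE)) {
    # vectorised accessors: columns of the aligned region, literal
    # matches and mismatches (gap-free columns = matches + mismatches)
    cols <- Biostrings::nchar(al)
    nm <- Biostrings::nmatch(al)
    nmm <- Biostrings::nmismatch(al)
    gf <- nm + nmm
    out$identity[todo] <- ifelse(cols > 0L, nm / cols, 0)
    out$span[todo] <- cols
    out$p_distance[todo] <- ifelse(gf > 0L, nmm / gf, NA_real_)
    out$n_mismatch[todo] <- nmm
    out$gap_free[todo] <- gf
    out$pass[todo] <- cols > 0L & out$identity[todo] >= min_identity &
      abs(cols - nchar(query)) <= span_tol
    return(out)
  }
  # N-containing query: N columns are excluded from the substitution
  # denominator, so walk the aligned strings explicitly.
  ca <- as.character(Biostrings::alignedPattern(al))
  qa <- as.character(Biostrings::alignedSubject(al))
  for (k in seq_along(todo)) {
    i <- todo[k]
    pa <- strsplit(qa[k], "")[[1]]
    sa <- strsplit(ca[k], "")[[1]]
    columns <- length(pa)
    if (columns == 0L) next
    gap_free <- pa != "-" & sa != "-"
    informative <- gap_free & pa != "N" & sa != "N"
    matches <- sum(informative & pa == sa)
    mismatches <- sum(informative & pa != sa)
    out$identity[i] <- matches / columns
    out$span[i] <- columns
    if (sum(informative) > 0L) {
      out$p_distance[i] <- mismatches / sum(informative)
    }
    out$n_mismatch[i] <- mismatches
    out$gap_free[i] <- sum(informative)
    out$pass[i] <- out$identity[i] >= min_identity &&
      abs(columns - nchar(query)) <= span_tol
  }
  out
}

#' Jukes-Cantor distance from a mismatch proportion
#'
#' `d = -(3/4) * log(1 - 4p/3)`, the expected substitutions per site under
#' the one-parameter substitution model.  Defined for `0 <= p < 0.75`;
#' `d >= p` with equality at 0.
#'
#' @param p Mismatch proportion(s).
#' @return Substitutions per site.
#' @export
#' @examples
#' jukes_cantor(c(0, 0.1))
jukes_cantor <- function(p) {
  if (any(p < 0 | p >= 0.75)) {
    stop("Jukes-Cantor distance undefined for p outside [0, 0.75)")
  }
  -0.75 * log(1 - 4 * p / 3)
}

# Assign one query sequence given its candidate row indices.
assign_one <- function(query, db, candidates, min_identity = 0.95,
                       span_tol = 5L) {
  blank <- list(status = "filtered_no_hit", neighbour_id = NA_character_,
                p_distance = NA_real_, jc_distance = NA_real_,
                lineage = rep(NA_character_, 6L))
  if (length(candidates) == 0L) return(blank)
  stats <- batch_align_screen(query, db$records$region[candidates],
                              min_identity, span_tol)
  ok <- stats$pass
  if (!any(ok)) {
    blank$status <- "filtered_identity"
    return(blank)
  }
  idx <- candidates[ok]
  p <- stats$p_distance[ok]
  jc <- jukes_cantor(p)
  best <- jc <= min(jc) + 1e-12
  if (sum(best) > 1L) {
    lin <- as.matrix(db$records[idx, TAXO_RANKS, drop = FALSE])
    depth <- rowSums(!is.na(lin))
    best <- best & depth == max(depth[best])
  }
  # remaining ties: smallest reference id (db rows are id-ordered)
  win <- which(best)[1L]
  i <- idx[win]
  list(status = "assigned", neighbour_id = db$records$id[i],
       p_distance = p[win], jc_distance = jc[win],
       lineage = as.character(db$records[i, TAXO_RANKS]))
}

#' Assign taxonomy to query sequences
#'
#' For each query: candidate search by shared words, identity screening by
#' global alignment, then transfer of the lineage of the closest neighbour
#' (smallest Jukes-Cantor distance).  Distance ties go to the candidate
#' classified to the deepest rank; remaining ties to the smallest
#' reference id.  Queries with no word hits get status `filtered_no_hit`;
#' queries whose candidates all fail the identity screen get
#' `filtered_identity`.
#'
#' Identical query sequences are assigned once and the result reused.
#'
#' @param queries Sequence-record table, or character vector of sequences.
#' @param db An indexed `reference_db` (see [prepare_reference_db()]).
#' @param max_hits Candidate list size.
#' @param min_identity,span_tol Screening parameters
#'   (see [align_and_screen()]).
#' @return `data.frame`: query_id, status, neighbour_id, p_distance,
#'   jc_distance, and the six rank columns.
#' @export
assign_taxonomy <- function(queries, db, max_hits = 50L,
                            min_identity = 0.95, span_tol = 5L) {
  if (is.character(queries)) {
    ids <- if (is.null(names(queries))) {
      sprintf("query_%05d", seq_along(queries))
    } else names(queries)
    queries <- data.frame(id = ids, seq = normalise_dna(queries),
                          stringsAsFactors = FALSE)
  }
  uniq <- unique(queries$seq)
  res <- lapply(uniq, function(sq) {
    cand <- find_candidates(sq, db, max_hits)
    assign_one(sq, db, cand, min_identity, span_tol)
  })
  at <- match(queries$seq, uniq)
  out <- data.frame(
    query_id = queries$id,
    status = vapply(res, `[[`, character(1L), "status")[at],
    neighbour_id = vapply(res, `[[`, character(1L), "neighbour_id")[at],
    p_distance = vapply(res, `[[`, numeric(1L), "p_distance")[at],
    jc_distance = vapply(res, `[[`, numeric(1L), "jc_distance")[at],
    stringsAsFactors = FALSE)
  lin <- t(vapply(res, `[[`, character(6L), "lineage"))[at, , drop = FALSE]
  colnames(lin) <- TAXO_RANKS
  out <- cbind(out, as.data.frame(lin, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
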