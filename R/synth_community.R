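# Synthetic communities and reads: multinomial genus draws under
# treatment-dependent proportions, and pyrosequencing-style reads (barcoded
# V1-V2, or bare V1 tags) with a configurable error model and ground-truth
# sidecars.

#' Define a community with treatment-dependent proportions
#'
#' @param proportions Named list, one element per treatment level, each a
#'   named numeric vector of genus proportions summing to 1.
#' @param fold_changes Optional named list per treatment of multiplicative
#'   genus effects (bookkeeping only; see [apply_fold_changes()]).
#' @return A `community_spec` object.
#' @export
community_spec <- function(proportions, fold_changes = NULL) {
  if (!is.list(proportions) || is.null(names(proportions))) {
    stop("proportions must be a named list (one element per treatment)")
  }
  for (tr in names(proportions)) {
    p <- proportions[[tr]]
    if (is.null(names(p)) || any(p < 0)) {
      stop("treatment ", tr, ": proportions must be named and non-negative")
    }
    if (abs(sum(p) - 1) > 1e-9) {
      stop("treatment ", tr, ": proportions must sum to 1")
    }
  }
  structure(list(proportions = proportions, fold_changes = fold_changes),
            class = "community_spec")
}

#' Apply multiplicative fold changes to baseline proportions
#'
#' Multiplies each genus by its fold (genera absent from `folds` keep fold
#' 1) and renormalises to sum to one, so the stated folds are effects on
#' unnormalised expected occurrence.
#'
#' @param base Named numeric vector of baseline proportions.
#' @param folds Named numeric vector of multiplicative effects.
#' @return Named numeric proportions summing to 1.
#' @export
apply_fold_changes <- function(base, folds) {
  v <- base
  idx <- intersect(names(folds), names(v))
  v[idx] <- v[idx] * folds[idx]
  extra <- setdiff(names(folds), names(v))
  if (length(extra)) v[extra] <- folds[extra]   # appear from undetected
  v / sum(v)
}

#' Rumen-like community specification with yeast-responsive genera
#'
#' Baseline (L0, control) proportions over the ten genera of
#' [rumen_taxon_specs()], with treatment levels L1 (low yeast dose) and L2
#' (high dose) derived by multiplicative fold changes on lactate-utilising
#' and fibrolytic genera (e.g. a 3.1-fold Megasphaera increase at L2) and a
#' modest Prevotella decrease.
#'
#' @return A [community_spec()].
#' @export
rumen_community_spec <- function() {
  base <- c(Prevotella = 0.40, Butyrivibrio = 0.12, Syntrophococcus = 0.05,
            Ruminococcus = 0.10, Megasphaera = 0.06, Selenomonas = 0.03,
            Mitsuokella = 0.06, Succinivibrio = 0.09, Fibrobacter = 0.05,
            Bifidobacterium = 0.04)
  l2_folds <- c(Megasphaera = 3.1, Ruminococcus = 2.7, Fibrobacter = 4.4,
                Selenomonas = 2.8, Prevotella = 1 / 1.2,
                Syntrophococcus = 1 / 4, Mitsuokella = 1 / 6.4)
  l1_folds <- c(Megasphaera = 1.8, Ruminococcus = 1.5, Prevotella = 1 / 1.1)
  community_spec(
    proportions = list(L0 = base,
                       L1 = apply_fold_changes(base, l1_folds),
                       L2 = apply_fold_changes(base, l2_folds)),
    fold_changes = list(L1 = l1_folds, L2 = l2_folds)
  )
}

#' Draw genus read counts for one sample
#'
#' Multinomial draw of `n_reads` over genera using the proportions of the
#' given treatment level.
#'
#' @param spec A [community_spec()].
#' @param treatment Treatment level present in `spec`.
#' @param n_reads Total reads to draw (> 0).
#' @param seed RNG seed.
#' @return Named integer vector of genus counts summing to `n_reads`.
#' @export
simulate_community <- function(spec, treatment, n_reads, seed = 1L) {
  stopifnot(inherits(spec, "community_spec"))
  if (!treatment %in% names(spec$proportions)) {
    stop("unknown treatment: ", treatment)
  }
  if (n_reads <= 0) stop("n_reads must be positive")
  p <- spec$proportions[[treatment]]
  with_seed(seed, {
    counts <- as.integer(rmultinom(1L, n_reads, p))
    names(counts) <- names(p)
    counts
  })
}

#' Sequencing error model for synthetic reads
#'
#' @param sub_rate Per-base substitution probability.
#' @param indel_rate Per-base indel probability.
#' @param homopolymer_indel_multiplier Indel-rate multiplier inside
#'   single-base runs of length >= 3 (the dominant pyrosequencing artefact).
#' @param chimera_rate Per-read probability of a two-parent chimera.
#' @return An `error_model` list.
#' @export
error_model <- function(sub_rate = 0, indel_rate = 0,
                        homopolymer_indel_multiplier = 1, chimera_rate = 0) {
  rates <- c(sub_rate, indel_rate, chimera_rate)
  if (any(rates < 0) || any(rates > 1)) stop("rates must be in [0, 1]")
  if (homopolymer_indel_multiplier < 1) stop("multiplier must be >= 1")
  structure(list(sub_rate = sub_rate, indel_rate = indel_rate,
                 homopolymer_indel_multiplier = homopolymer_indel_multiplier,
                 chimera_rate = chimera_rate),
            class = "error_model")
}

# Locate the amplified region on plus-strand references: after the forward
# primer, before the plus-strand site of the reverse primer (neither primer
# included).  Returns NA coordinates when either site is absent or found
# more than once.
region_coords <- function(seqs, fwd = PRIMER_27F, rev = PRIMER_357R,
                          max_mismatch = 0L) {
  subject <- Biostrings::DNAStringSet(seqs)
  rev_site <- revcomp(rev)
  fhits <- Biostrings::vmatchPattern(fwd, subject, max.mismatch = max_mismatch)
  rhits <- Biostrings::vmatchPattern(rev_site, subject,
                                     max.mismatch = max_mismatch)
  n <- length(seqs)
  out <- data.frame(start = rep(NA_integer_, n), end = rep(NA_integer_, n),
                    reason = rep("", n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    f <- fhits[[i]]; r <- rhits[[i]]
    if (length(f) == 0L || length(r) == 0L) {
      out$reason[i] <- "missing_primer"
    } else if (length(f) > 1L || length(r) > 1L) {
      out$reason[i] <- "ambiguous_primer"
    } else {
      s <- BiocGenerics::end(f)[1L] + 1L
      e <- BiocGenerics::start(r)[1L] - 1L
      if (e < s) {
        out$reason[i] <- "inverted_primers"
      } else {
        out$start[i] <- s; out$end[i] <- e
      }
    }
  }
  out
}

# Apply the per-base error model to one sequence.
apply_read_errors <- function(seq, em) {
  if (em$sub_rate <= 0 && em$indel_rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  if (em$sub_rate > 0) {
    hit <- which(runif(length(chars)) < em$sub_rate)
    if (length(hit)) {
      chars[hit] <- vapply(chars[hit],
                           function(b) sample(setdiff(bases, b), 1L),
                           character(1L), USE.NAMES = FALSE)
    }
  }
  if (em$indel_rate > 0) {
    runs <- rle(chars)
    in_run <- rep(runs$lengths >= 3L, runs$lengths)
    rate <- ifelse(in_run,
                   pmin(1, em$indel_rate * em$homopolymer_indel_multiplier),
                   em$indel_rate)
    hit <- which(runif(length(chars)) < rate)
    if (length(hit)) {
      pieces <- as.list(chars)
      for (j in hit) {
        if (runif(1L) < 0.5) {
          pieces[[j]] <- ""                       # deletion
        } else {
          pieces[[j]] <- c(chars[j], sample(bases, 1L))  # insertion after
        }
      }
      chars <- unlist(pieces)
    }
  }
  paste(chars, collapse = "")
}

#' Simulate amplicon reads from a community
#'
#' Draws one read per community count from the genus's reference sequences.
#' `region = "V1V2"` emits reads in sequenced orientation — 4-nt barcode,
#' then the reverse (357R) primer, then the reverse-complemented insert —
#' with synthetic Phred qualities, emulating unidirectional pyrosequencing
#' from the reverse end.  `region = "V1"` emits bare plus-orientation V1
#' tags of `v1_length` nt (the unit sequence of serial tag analysis), with
#' no barcode or qualities.  Chimeric reads splice two parent inserts at a
#' uniform breakpoint before errors are applied.
#'
#' @param counts Named genus counts (e.g. from [simulate_community()]).
#' @param ref A `reference_set`.
#' @param region `"V1V2"` or `"V1"`.
#' @param em An [error_model()].
#' @param barcode 4-nt sample barcode (required for V1V2).
#' @param v1_length Length of the V1 tag region.
#' @param mean_quality,quality_sd Parameters of the truncated-normal
#'   per-base quality distribution (bounds 2..40).
#' @param seed RNG seed.
#' @param id_prefix Prefix for read identifiers.
#' @return List with `records` (sequence-record table) and `truth`
#'   (`data.frame`: read_id, genus, ref_id, chimera, parent2_genus), plus
#'   `n_excluded_refs` counting references lacking primer sites.
#' @export
sample_reads <- function(counts, ref, region = c("V1V2", "V1"),
                         em = error_model(), barcode = NULL,
                         v1_length = 55L, mean_quality = 32,
                         quality_sd = 4, seed = 1L, id_prefix = "read") {
  region <- match.arg(region)
  stopifnot(inherits(ref, "reference_set"))
  if (region == "V1V2") {
    if (is.null(barcode) || nchar(barcode) != 4L) {
      stop("V1V2 reads require a 4-nt barcode")
    }
  }
  rc <- region_coords(ref$records$seq)
  usable <- !is.na(rc$start)
  n_excluded <- sum(!usable)
  if (n_excluded > 0L) {
    warning(n_excluded, " reference record(s) without usable primer sites excluded")
  }
  genus_of <- ref$lineage$genus
  inserts <- ifelse(usable,
                    substr(ref$records$seq, rc$start, rc$end), NA_character_)
  if (region == "V1") {
    inserts <- ifelse(usable,
                      substr(ref$records$seq, rc$start,
                             rc$start + v1_length - 1L), NA_character_)
  }
  with_seed(seed, {
    pick_idx <- integer(0); genus_vec <- character(0)
    for (genus in names(counts)) {
      cnt <- counts[[genus]]
      if (cnt <= 0L) next
      pool <- which(genus_of == genus & usable)
      if (length(pool) == 0L) stop("no usable reference for genus ", genus)
      pick_idx <- c(pick_idx, pool[sample.int(length(pool), cnt,
                                              replace = TRUE)])
      genus_vec <- c(genus_vec, rep(genus, cnt))
    }
    n <- length(pick_idx)
    ins <- inserts[pick_idx]
    is_chim <- runif(n) < em$chimera_rate
    p2_genus <- rep(NA_character_, n)
    all_pool <- which(usable)
    for (i in which(is_chim)) {
      idx2 <- all_pool[sample.int(length(all_pool), 1L)]
      p2_genus[i] <- genus_of[idx2]
      ins2 <- inserts[idx2]
      bp <- sample.int(min(nchar(ins[i]), nchar(ins2)) - 1L, 1L)
      ins[i] <- paste0(substr(ins[i], 1L, bp),
                       substr(ins2, bp + 1L, nchar(ins2)))
    }
    if (em$sub_rate > 0 || em$indel_rate > 0) {
      ins <- vapply(ins, apply_read_errors, character(1L), em = em,
                    USE.NAMES = FALSE)
    }
    if (region == "V1V2") {
      seqs <- paste0(barcode, PRIMER_357R, revcomp(ins))
      lens <- nchar(seqs)
      qall <- pmin(40L, pmax(2L, as.integer(round(
        rnorm(sum(lens), mean_quality, quality_sd)))))
      quals <- split(qall, rep.int(seq_len(n), lens))
      names(quals) <- NULL
    } else {
      seqs <- ins
      quals <- NULL
    }
    truth <- data.frame(
      read_id = sprintf("%s_%05d", id_prefix, seq_len(n)),
      genus = genus_vec, ref_id = ref$records$id[pick_idx],
      chimera = is_chim, parent2_genus = p2_genus,
      stringsAsFactors = FALSE)
    records <- seq_records(truth$read_id, seqs, quals)
    list(records = records, truth = truth, n_excluded_refs = n_excluded)
  })
}
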