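# In-silico T-RFLP: terminal restriction fragment lengths from the
# 5'-labelled (27F) end of each amplicon to the first recognition site of
# each enzyme, with peak areas proportional to community counts plus
# small-area noise peaks.

# Recognition sites and cut offsets (0-based position of the cut within the
# site, on the labelled strand): HaeIII GG^CC, MspI C^CGG, HhaI GCG^C,
# RsaI GT^AC.
TRFLP_ENZYMES <- list(
  HaeIII = list(site = "GGCC", offset = 2L),
  MspI   = list(site = "CCGG", offset = 1L),
  HhaI   = list(site = "GCGC", offset = 3L),
  RsaI   = list(site = "GTAC", offset = 2L)
)

#' Predict a terminal restriction fragment length
#'
#' Length from the labelled 5' end of `seq` to the first cut of `enzyme`:
#' 0-based position of the first recognition-site occurrence plus the cut
#' offset within the site.  `NA` if the site is absent (uncut fragment).
#'
#' @param seq DNA string (the labelled amplicon, 5' end first).
#' @param enzyme One of `"HaeIII"`, `"MspI"`, `"HhaI"`, `"RsaI"`.
#' @return Integer fragment length in bp, or `NA_integer_`.
#' @export
terminal_fragment_length <- function(seq, enzyme) {
  enz <- TRFLP_ENZYMES[[enzyme]]
  if (is.null(enz)) stop("unknown enzyme: ", enzyme)
  pos <- regexpr(enz$site, seq, fixed = TRUE)[1L]
  if (pos < 0L) return(NA_integer_)
  (pos - 1L) + enz$offset                   # 0-based site start + cut offset
}

#' Simulate multi-enzyme T-RFLP peak tables for one sample
#'
#' For every reference sequence of a genus present in `counts`, the
#' terminal fragment from the 27F-labelled end of the amplicon to the first
#' cut site is computed per enzyme; its peak area is proportional to the
#' genus count (split equally over the genus's reference sequences), so
#' doubling a count doubles the areas it contributes.  Sequences without a
#' recognition site contribute an uncut full-length fragment, flagged in the
#' truth table.  Baseline noise peaks with bounded areas drawn uniformly
#' on `(0, noise_area_scale)` are added at uniform random sizes; bounded
#' noise is the regime the standard-deviation detection method assumes.
#'
#' @param counts Named genus counts.
#' @param ref A `reference_set`.
#' @param enzymes Subset of `c("HaeIII","MspI","HhaI","RsaI")`.
#' @param noise_peaks Noise peaks per enzyme.
#' @param noise_area_scale Scale of noise-peak areas (fluorescence units).
#' @param sample Sample label.
#' @param seed RNG seed.
#' @return `data.frame` with columns sample, enzyme, size_bp, area, true
#'   (logical ground-truth label) and uncut (flag for full-length
#'   fragments).
#' @export
simulate_trflp <- function(counts, ref, enzymes = names(TRFLP_ENZYMES),
                           noise_peaks = 200L, noise_area_scale = 1,
                           sample = "S1", seed = 1L) {
  if (!all(enzymes %in% names(TRFLP_ENZYMES))) {
    stop("enzymes must be drawn from: ",
         paste(names(TRFLP_ENZYMES), collapse = ", "))
  }
  stopifnot(inherits(ref, "reference_set"))
  rc <- region_coords(ref$records$seq)
  # Labelled amplicon: from the forward-primer start (the labelled
  # extremity) to the end of the reference record.
  fwd_start <- rc$start - nchar(PRIMER_27F)
  genus_of <- ref$lineage$genus
  with_seed(seed, {
    out <- list()
    for (enz in enzymes) {
      sizes <- numeric(0); areas <- numeric(0); uncut <- logical(0)
      for (genus in names(counts)) {
        cnt <- counts[[genus]]
        if (cnt <= 0) next
        pool <- which(genus_of == genus & !is.na(rc$start))
        for (idx in pool) {
          amp <- substr(ref$records$seq[idx], fwd_start[idx],
                        nchar(ref$records$seq[idx]))
          frag <- terminal_fragment_length(amp, enz)
          is_uncut <- is.na(frag)
          if (is_uncut) frag <- nchar(amp)
          sizes <- c(sizes, frag)
          areas <- c(areas, cnt / length(pool))
          uncut <- c(uncut, is_uncut)
        }
      }
      sig <- data.frame(sample = sample, enzyme = enz, size_bp = sizes,
                        area = areas, true = TRUE, uncut = uncut,
                        stringsAsFactors = FALSE)
      # Coincident fragments co-migrate: sum their areas.
      if (nrow(sig) > 0L) {
        agg <- stats::aggregate(area ~ size_bp, data = sig, FUN = sum)
        unc <- tapply(sig$uncut, sig$size_bp, any)
        sig <- data.frame(sample = sample, enzyme = enz,
                          size_bp = agg$size_bp, area = agg$area,
                          true = TRUE,
                          uncut = as.logical(unc[as.character(agg$size_bp)]),
                          stringsAsFactors = FALSE)
      }
      if (noise_peaks > 0L) {
        nz <- data.frame(sample = sample, enzyme = enz,
                         size_bp = round(runif(noise_peaks, 50, 600), 1L),
                         area = runif(noise_peaks, 0, noise_area_scale),
                         true = FALSE, uncut = FALSE,
                         stringsAsFactors = FALSE)
        sig <- rbind(sig, nz)
      }
      sig <- sig[order(sig$size_bp), ]
      out[[enz]] <- sig
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
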