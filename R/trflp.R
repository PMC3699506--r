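# T-RFLP electropherogram processing: iterative 3-SD true-peak detection
# under a zero-mean noise model, cross-sample +/-1 bp binning, relative-
# abundance log transform, and column-wise concatenation of the
# per-enzyme matrices.

#' Iterative standard-deviation true-peak detection
#'
#' Starting with every peak labelled noise, the noise standard deviation
#' is taken as `sqrt(sum(area^2) / n)` over currently-noise peaks (zero-
#' mean noise assumption); peaks with area above `k` standard deviations
#' are relabelled true and the iteration repeats until a fixed point.
#' Re-running on the labelled output changes nothing, and adding a
#' noise-level peak can never demote an already-true peak.
#'
#' @param areas Numeric peak areas (>= 1 peak).
#' @param k Exclusion threshold in noise standard deviations.
#' @return Logical vector: `TRUE` for true peaks.  An all-noise outcome
#'   (e.g. all areas equal) is valid.
#' @export
detect_true_peaks <- function(areas, k = 3) {
  if (length(areas) == 0L) stop("no peaks")
  if (any(areas < 0)) stop("areas must be non-negative")
  true <- rep(FALSE, length(areas))
  repeat {
    noise <- areas[!true]
    if (length(noise) == 0L) break
    sigma <- sqrt(sum(noise^2) / length(noise))
    promote <- !true & areas > k * sigma
    if (!any(promote)) break
    true <- true | promote
  }
  true
}

#' Label true peaks in a grouped peak table
#'
#' Applies [detect_true_peaks()] independently to every (sample, enzyme)
#' peak list.
#'
#' @param peaks `data.frame` with columns sample, enzyme, size_bp, area.
#' @param k Exclusion threshold.
#' @return The table with a logical `label_true` column.
#' @export
label_peaks <- function(peaks, k = 3) {
  peaks$label_true <- FALSE
  for (grp in split(seq_len(nrow(peaks)),
                    paste(peaks$sample, peaks$enzyme, sep = "\r"))) {
    peaks$label_true[grp] <- detect_true_peaks(peaks$area[grp], k)
  }
  peaks
}

#' Bin true peaks across samples
#'
#' Per enzyme: sizes are rounded to the nearest integer; bins are seeded
#' greedily by descending total area (a rounded size within `tol` bp of an
#' existing bin centre does not seed a new bin), with each bin centre the
#' area-weighted mean of the sizes that seeded it, fixed after the
#' seeding pass.  Every true peak is then assigned to the first bin whose
#' centre is within `tol` bp of its size.
#'
#' @param peaks Labelled peak table (see [label_peaks()]); only
#'   `label_true` rows are binned.
#' @param tol Binning tolerance in bp.
#' @return Named list per enzyme of samples x bins area matrices (column
#'   names `<enzyme>_<centre>`).
#' @export
bin_trfs <- function(peaks, tol = 1) {
  stopifnot("label_true" %in% names(peaks))
  pk <- peaks[peaks$label_true, , drop = FALSE]
  samples <- unique(peaks$sample)
  out <- list()
  for (enz in unique(pk$enzyme)) {
    sub <- pk[pk$enzyme == enz, , drop = FALSE]
    sub$rounded <- round(sub$size_bp)
    tot <- tapply(sub$area, sub$rounded, sum)
    seeds <- as.numeric(names(tot))
    seeds <- seeds[order(-as.numeric(tot), seeds)]
    centers <- numeric(0)
    for (s in seeds) {
      if (length(centers) == 0L || min(abs(centers - s)) > tol) {
        rows <- sub$rounded == s
        centers <- c(centers,
                     sum(sub$size_bp[rows] * sub$area[rows]) /
                       sum(sub$area[rows]))
      }
    }
    mat <- matrix(0, length(samples), length(centers),
                  dimnames = list(samples,
                                  sprintf("%s_%.1f", enz, centers)))
    for (r in seq_len(nrow(sub))) {
      hit <- which(abs(centers - sub$size_bp[r]) <= tol)[1L]
      if (is.na(hit)) {       # straggler outside every seeded bin
        centers <- c(centers, sub$size_bp[r])
        mat <- cbind(mat, 0)
        colnames(mat)[ncol(mat)] <- sprintf("%s_%.1f", enz, sub$size_bp[r])
        hit <- length(centers)
      }
      mat[sub$sample[r], hit] <- mat[sub$sample[r], hit] + sub$area[r]
    }
    ord <- order(centers)
    out[[enz]] <- mat[, ord, drop = FALSE]
  }
  out
}

#' Log-transform a binned T-RFLP matrix
#'
#' Converts each sample's areas to relative abundance in percent and
#' applies `ln(1 + r)`, so structural zeros stay zero and the transform
#' is strictly monotone.
#'
#' @param mat Samples x bins area matrix (one enzyme).
#' @return Transformed matrix.
#' @export
trf_transform <- function(mat) {
  mat <- as.matrix(mat)
  rs <- rowSums(mat)
  rel <- sweep(mat, 1L, ifelse(rs > 0, rs, 1), "/") * 100
  log1p(rel)
}

#' Concatenate per-enzyme T-RFLP matrices
#'
#' @param mats Named list of samples x bins matrices with identical
#'   sample sets (identical row order); a sample-set mismatch is an
#'   error.
#' @return Single matrix with enzyme-qualified, unique column names.
#' @export
trf_concatenate <- function(mats) {
  if (length(mats) == 0L) stop("no matrices to concatenate")
  rows <- rownames(mats[[1L]])
  for (nm in names(mats)) {
    if (!identical(rownames(mats[[nm]]), rows)) {
      stop("sample sets differ between enzyme matrices (", nm, ")")
    }
  }
  out <- do.call(cbind, mats)
  if (anyDuplicated(colnames(out))) stop("duplicate column labels")
  out
}

#' Full T-RFLP matrix pipeline
#'
#' Detection, binning, log transform and concatenation in one call.
#'
#' @param peaks Peak table (sample, enzyme, size_bp, area).
#' @param k Detection threshold in noise SDs.
#' @param tol Binning tolerance in bp.
#' @return List: `labelled` (peak table with `label_true`), `binned`
#'   (per-enzyme area matrices), `matrix` (concatenated transformed
#'   matrix).
#' @export
trflp_matrix <- function(peaks, k = 3, tol = 1) {
  lab <- label_peaks(peaks, k)
  binned <- bin_trfs(lab, tol)
  transformed <- lapply(binned, trf_transform)
  list(labelled = lab, binned = binned,
       matrix = trf_concatenate(transformed))
}
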