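# Depth-matched subsampling and the diversity estimators used on the
# OTU tables: bias-corrected Chao1 richness, Good's coverage, Shannon
# entropy, and the shared (core) OTU analysis across animals.

#' Subsample a count vector without replacement
#'
#' Uniform draw of `depth` individuals from the finite pool described by
#' `counts` (multivariate hypergeometric), emulating depth matching to the
#' smallest sample.
#'
#' @param counts Named non-negative integer vector.
#' @param depth Number of individuals to keep (`<= sum(counts)`).
#' @param seed RNG seed.
#' @return Named integer vector with `sum == depth` (taxa order
#'   preserved).
#' @export
subsample_counts <- function(counts, depth, seed = 1L) {
  total <- sum(counts)
  if (depth > total) stop("depth exceeds total count")
  if (depth == total) return(counts)
  with_seed(seed, {
    pool <- rep(names(counts), counts)
    draw <- sample(pool, depth)
    out <- table(factor(draw, levels = names(counts)))
    setNames(as.integer(out), names(counts))
  })
}

#' Bias-corrected Chao1 richness
#'
#' `S_chao1 = S_obs + F1 (F1 - 1) / (2 (F2 + 1))` with `F1` the singleton
#' and `F2` the doubleton count.  Always `>= S_obs`, with equality iff
#' `F1 <= 1`.
#'
#' @param counts Non-negative integer counts.
#' @return Estimated richness.
#' @export
chao1 <- function(counts) {
  if (length(counts) == 0L) stop("empty count vector")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Good's coverage
#'
#' `C = 1 - F1 / N`: the estimated fraction of the community represented
#' by the sample.
#'
#' @param counts Non-negative integer counts with positive total.
#' @return Coverage in `[0, 1]`.
#' @export
goods_coverage <- function(counts) {
  n <- sum(counts)
  if (n <= 0) stop("total count must be positive")
  1 - sum(counts == 1) / n
}

#' Shannon diversity index
#'
#' `H = -sum(p_i log p_i)` over non-zero proportions after normalisation
#' (natural log).
#'
#' @param x Non-negative abundances (counts, areas or proportions).
#' @return Shannon index `H`.
#' @export
shannon <- function(x) {
  if (any(x < 0)) stop("abundances must be non-negative")
  s <- sum(x)
  if (s <= 0) stop("all-zero abundance vector")
  p <- x[x > 0] / s
  -sum(p * log(p))
}

#' Core (shared) OTU analysis across animals
#'
#' OTUs present in every animal form the core.  Reports the core's share
#' of the OTU union, its share of total abundance, and optionally its
#' family breakdown.
#'
#' @param tables Matrix (animals x OTUs) of counts, or a list of named
#'   per-animal count vectors.
#' @param families Optional named character vector OTU -> family for the
#'   breakdown of core abundance.
#' @return List: `core_otus` (ids), `otu_fraction`
#'   (`|core| / |union|`), `abundance_share` (core abundance over total),
#'   `family_breakdown` (named proportions of core abundance, or `NULL`).
#' @export
core_otus <- function(tables, families = NULL) {
  if (is.list(tables) && !is.data.frame(tables)) {
    taxa <- unique(unlist(lapply(tables, names)))
    mat <- t(vapply(tables, function(v) {
      out <- setNames(rep(0, length(taxa)), taxa)
      out[names(v)] <- v
      out
    }, numeric(length(taxa))))
  } else {
    mat <- as.matrix(tables)
  }
  if (nrow(mat) < 2L) stop("core analysis needs at least 2 animals")
  present <- mat > 0
  in_union <- colSums(present) > 0
  in_all <- colSums(present) == nrow(mat)
  core <- colnames(mat)[in_all]
  share <- if (sum(mat) > 0) sum(mat[, in_all, drop = FALSE]) / sum(mat) else 0
  breakdown <- NULL
  if (!is.null(families) && length(core)) {
    fam <- families[core]
    ab <- colSums(mat[, core, drop = FALSE])
    v <- tapply(ab, fam, sum)
    breakdown <- sort(as.numeric(v) / sum(ab), decreasing = TRUE)
    names(breakdown) <- names(sort(tapply(ab, fam, sum) / sum(ab),
                                   decreasing = TRUE))
    breakdown <- tapply(ab, fam, sum) / sum(ab)
    breakdown <- sort(breakdown, decreasing = TRUE)
  }
  list(core_otus = core,
       otu_fraction = if (sum(in_union)) sum(in_all) / sum(in_union) else 0,
       abundance_share = share,
       family_breakdown = breakdown)
}
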