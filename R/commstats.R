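# Community-level statistics: Bray-Curtis and Morisita-Horn distances,
# UPGMA clustering with a deterministic tie-break, one-way PERMANOVA with
# restricted (strata) permutations, per-taxon differential abundance with
# a sparse-count exact-test route, and the Firmicutes/Bacteroidetes ratio
# ANOVA.

#' Bray-Curtis dissimilarity
#'
#' `d = sum|x_i - y_i| / sum(x_i + y_i)`; bounded in `[0, 1]`, zero on
#' identical vectors, one on disjoint supports.
#'
#' @param x,y Non-negative abundance vectors over the same labels.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  check_pair(x, y)
  if (sum(x) + sum(y) <= 0) stop("both vectors are all-zero")
  sum(abs(x - y)) / sum(x + y)
}

#' Morisita-Horn dissimilarity
#'
#' `1 - 2 sum(x_i y_i) / ((dx + dy) X Y)` with `X = sum(x)`,
#' `dx = sum(x^2)/X^2` (likewise for y).  Invariant to uniform rescaling
#' of either vector, which is what makes it robust to unequal sample
#' sizes.
#'
#' @param x,y Non-negative abundance vectors over the same labels.
#' @return Dissimilarity in `[0, 1]`.
#' @export
morisita_horn <- function(x, y) {
  check_pair(x, y)
  X <- sum(x); Y <- sum(y)
  if (X <= 0 || Y <= 0) stop("zero-total abundance vector")
  dx <- sum(x^2) / X^2
  dy <- sum(y^2) / Y^2
  1 - 2 * sum(x * y) / ((dx + dy) * X * Y)
}

check_pair <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (!is.null(names(x)) && !is.null(names(y)) &&
      !identical(names(x), names(y))) {
    stop("vectors must share the same label set and order")
  }
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  invisible(TRUE)
}

#' Pairwise distance matrix over samples
#'
#' @param mat Samples x taxa abundance matrix.
#' @param metric `"bray_curtis"` or `"morisita_horn"`.
#' @return Symmetric matrix with zero diagonal, attribute `metric`.
#' @export
community_distance <- function(mat, metric = c("bray_curtis",
                                               "morisita_horn")) {
  metric <- match.arg(metric)
  f <- if (metric == "bray_curtis") bray_curtis else morisita_horn
  mat <- as.matrix(mat)
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- f(mat[i, ], mat[j, ])
    }
  }
  attr(d, "metric") <- metric
  d
}

#' Mean between-group distances
#'
#' Averages the pairwise sample distances for every pair of groups (e.g.
#' treatment x fraction combinations), producing the reduced matrix used
#' for group-level clustering.
#'
#' @param dm Sample distance matrix.
#' @param groups Group label per sample (row of `dm`).
#' @return Symmetric group-level matrix with zero diagonal.
#' @export
group_mean_distance <- function(dm, groups) {
  groups <- as.character(groups)
  levs <- unique(groups)
  k <- length(levs)
  out <- matrix(0, k, k, dimnames = list(levs, levs))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      out[i, j] <- out[j, i] <-
        mean(dm[groups == levs[i], groups == levs[j], drop = FALSE])
    }
  }
  out
}

dendro_leaves <- function(node) {
  if (!is.null(node$leaf)) return(node$leaf)
  sort(unlist(lapply(node$children, dendro_leaves)))
}

#' UPGMA clustering of a distance matrix
#'
#' Iteratively merges the closest pair of clusters; the distance from a
#' merged cluster to the others is the size-weighted average (arithmetic
#' mean over all member pairs) and the merge node sits at half the merge
#' distance.  Distance ties break lexicographically on the merged leaf
#' sets, making the tree deterministic.
#'
#' @param dm Symmetric distance matrix with labelled rows.
#' @return A `rumen_dendro`: nested list with `children`, `height` and
#'   `leaf` fields, serialisable with [write_dendrogram()].
#' @export
upgma <- function(dm) {
  dm <- as.matrix(dm)
  if (any(is.na(dm))) stop("distance matrix contains NA")
  n <- nrow(dm)
  if (n < 2L) stop("UPGMA needs at least 2 samples")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("S", seq_len(n))
  nodes <- lapply(labels, function(l) list(leaf = l, height = 0))
  sizes <- rep(1L, n)
  keys <- labels
  d <- dm
  while (length(nodes) > 1L) {
    m <- length(nodes)
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        key <- paste(sort(c(keys[i], keys[j])), collapse = "|")
        if (d[i, j] < best_d - 1e-12 ||
            (abs(d[i, j] - best_d) <= 1e-12 && key < best_key)) {
          best <- c(i, j); best_d <- d[i, j]; best_key <- key
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    kids <- nodes[c(i, j)]
    kids <- kids[order(vapply(kids, function(k) {
      paste(dendro_leaves(k), collapse = "|")
    }, character(1L)))]
    new_node <- list(children = kids, height = best_d / 2)
    new_size <- sizes[i] + sizes[j]
    others <- setdiff(seq_len(m), c(i, j))
    new_d <- (sizes[i] * d[i, others] + sizes[j] * d[j, others]) / new_size
    d <- rbind(cbind(d[others, others, drop = FALSE], new_d),
               c(new_d, 0))
    nodes <- c(nodes[others], list(new_node))
    sizes <- c(sizes[others], new_size)
    keys <- c(keys[others], best_key)
  }
  structure(nodes[[1L]], class = "rumen_dendro")
}

#' Cophenetic distances implied by a dendrogram
#'
#' @param tree A `rumen_dendro` from [upgma()].
#' @return Symmetric matrix of twice the height of each pair's lowest
#'   common ancestor.
#' @export
dendro_cophenetic <- function(tree) {
  leaves <- dendro_leaves(tree)
  out <- matrix(0, length(leaves), length(leaves),
                dimnames = list(leaves, leaves))
  fill <- function(node) {
    if (!is.null(node$leaf)) return(node$leaf)
    sets <- lapply(node$children, fill)
    for (a in seq_along(sets)) {
      for (b in seq_along(sets)) {
        if (a < b) {
          out[sets[[a]], sets[[b]]] <<- 2 * node$height
          out[sets[[b]], sets[[a]]] <<- 2 * node$height
        }
      }
    }
    unlist(sets)
  }
  fill(tree)
  out
}

all_permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (p in all_permutations(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], p)
    }
  }
  out
}

# Pseudo-F for a one-way partition of a distance matrix.
pseudo_f <- function(d2, groups) {
  n <- nrow(d2)
  levs <- unique(groups)
  a <- length(levs)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in levs) {
    idx <- which(groups == g)
    ss_within <- ss_within +
      sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

#' Permutational multivariate analysis of variance (one-way, restricted
#' permutations)
#'
#' Anderson's pseudo-F on a distance matrix: total sum of squares
#' `sum(d_ij^2)/N` over all pairs, within-group sums analogously per
#' group, `F = (SS_b/(a-1)) / (SS_w/(N-a))`.  The null distribution
#' permutes group labels, within strata when given (e.g. within animal,
#' honouring a Latin-square layout).  When the restricted permutation
#' group is small enough it is enumerated exhaustively and the p-value is
#' exact; otherwise `p = (1 + #{F* >= F}) / (1 + n_perm)`.
#'
#' @param dm Sample distance matrix.
#' @param groups Factor to test (one label per sample).
#' @param n_perm Number of random permutations when not enumerating.
#' @param seed RNG seed for random permutations.
#' @param strata Optional stratum label per sample; permutations shuffle
#'   labels only within strata.
#' @param exhaustive_limit Enumerate exhaustively when the permutation
#'   group has at most this many elements.
#' @return List: `f`, `p`, `n_perm_used`, `exact`.
#' @export
permanova <- function(dm, groups, n_perm = 999L, seed = 1L, strata = NULL,
                      exhaustive_limit = 10000L) {
  d2 <- as.matrix(dm)^2
  n <- nrow(d2)
  groups <- as.character(groups)
  if (length(groups) != n) stop("groups length must match dm")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 samples")
  f_obs <- pseudo_f(d2, groups)
  strata_list <- if (is.null(strata)) {
    list(seq_len(n))
  } else {
    split(seq_len(n), as.character(strata))
  }
  group_size <- prod(vapply(strata_list, function(s) factorial(length(s)),
                            numeric(1L)))
  if (group_size <= exhaustive_limit) {
    per_stratum <- lapply(strata_list, all_permutations)
    grid <- expand.grid(lapply(per_stratum, seq_along))
    f_all <- numeric(nrow(grid))
    for (r in seq_len(nrow(grid))) {
      perm <- seq_len(n)
      for (s in seq_along(strata_list)) {
        perm[strata_list[[s]]] <- per_stratum[[s]][[grid[r, s]]]
      }
      f_all[r] <- pseudo_f(d2, groups[perm])
    }
    p <- mean(f_all >= f_obs - 1e-12)
    list(f = f_obs, p = p, n_perm_used = length(f_all), exact = TRUE)
  } else {
    f_perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(k) {
        perm <- seq_len(n)
        for (s in strata_list) perm[s] <- s[sample.int(length(s))]
        pseudo_f(d2, groups[perm])
      }, numeric(1L))
    })
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
    list(f = f_obs, p = p, n_perm_used = n_perm, exact = FALSE)
  }
}

welch_t <- function(x, y) {
  m <- mean(x) - mean(y)
  se2 <- var(x) / length(x) + var(y) / length(y)
  if (se2 <= 0) {
    if (abs(m) < 1e-15) return(0)
    return(sign(m) * Inf)
  }
  m / sqrt(se2)
}

#' Per-taxon differential abundance between two groups
#'
#' Abundant taxa are tested by a two-sample (Welch) t statistic on
#' per-sample proportions.  P-values come from permutation of the group
#' labels with the permuted statistics pooled across all abundant taxa
#' (the shared-null device of Metastats-style testing, which keeps the
#' p-value granularity fine even for tiny group sizes where per-taxon
#' enumeration would bottom out at a coarse minimum).  All distinct
#' relabellings are enumerated when there are at most `n_perm`; otherwise
#' `n_perm` random relabellings are drawn.  Taxa with pooled count below
#' `sparse_total` are routed to Fisher's exact test on the pooled
#' taxon-versus-rest 2x2 table.  Benjamini-Hochberg q-values are computed
#' over all tested taxa.
#'
#' @param counts Samples x taxa count matrix.
#' @param groups Two-level group label per sample (>= 2 samples each).
#' @param n_perm Permutation budget.
#' @param sparse_total Pooled-count threshold below which the exact test
#'   is used.
#' @param seed RNG seed (used only when sampling permutations).
#' @return `data.frame`: taxon, test (`t_perm`/`fisher`), stat, p, q,
#'   and group mean proportions.
#' @export
diff_abundance <- function(counts, groups, n_perm = 1000L,
                           sparse_total = 10L, seed = 1L) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  levs <- unique(groups)
  if (length(levs) != 2L) stop("diff_abundance needs exactly two groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 samples")
  props <- counts / rowSums(counts)
  i1 <- which(groups == levs[1L]); i2 <- which(groups == levs[2L])
  n1 <- length(i1)
  n <- nrow(counts)
  taxa <- colnames(counts)
  sparse <- colSums(counts) < sparse_total
  out <- data.frame(taxon = taxa,
                    test = ifelse(sparse, "fisher", "t_perm"),
                    stat = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (tx in taxa[sparse]) {
    tab <- rbind(c(sum(counts[i1, tx]), sum(counts[i1, ]) - sum(counts[i1, tx])),
                 c(sum(counts[i2, tx]), sum(counts[i2, ]) - sum(counts[i2, tx])))
    out$p[out$taxon == tx] <- fisher.test(tab)$p.value
  }
  dense <- taxa[!sparse]
  if (length(dense)) {
    t_obs <- vapply(dense, function(tx) {
      welch_t(props[i1, tx], props[i2, tx])
    }, numeric(1L))
    combos <- combn(n, n1)
    perm_sets <- if (ncol(combos) <= n_perm) {
      lapply(seq_len(ncol(combos)), function(j) combos[, j])
    } else {
      with_seed(seed, {
        lapply(seq_len(n_perm), function(k) sample.int(n, n1))
      })
    }
    perm_mat <- vapply(perm_sets, function(idx) {
      vapply(dense, function(tx) {
        abs(welch_t(props[idx, tx], props[-idx, tx]))
      }, numeric(length(dense) * 0 + 1))
    }, numeric(length(dense)))
    perm_mat <- matrix(perm_mat, nrow = length(dense))
    for (j in seq_along(dense)) {
      # leave-own-taxon-out pooled null: the taxon's own permuted
      # statistics (which always include the observed one under the
      # identity relabelling) are excluded, so the permutation
      # granularity does not impose a hard floor on the p-value
      null_j <- if (length(dense) > 1L) {
        as.numeric(perm_mat[-j, , drop = FALSE])
      } else {
        as.numeric(perm_mat[j, ])
      }
      cnt <- sum(null_j >= abs(t_obs[j]) - 1e-12)
      p <- (1 + cnt) / (1 + length(null_j))
      row <- out$taxon == dense[j]
      out$stat[row] <- t_obs[j]
      out$p[row] <- p
    }
  }
  out$q <- p.adjust(out$p, method = "BH")
  out$mean_prop_1 <- colMeans(props[i1, , drop = FALSE])[out$taxon]
  out$mean_prop_2 <- colMeans(props[i2, , drop = FALSE])[out$taxon]
  rownames(out) <- NULL
  out
}

#' One-way ANOVA on Firmicutes/Bacteroidetes ratios
#'
#' Samples with a non-finite ratio (zero Bacteroidetes abundance) are
#' excluded with a warning.
#'
#' @param ratios Per-sample Firmicutes/Bacteroidetes ratios.
#' @param treatments Treatment label per sample.
#' @return List: `f`, `p`, `df`, `n_used`.
#' @export
ratio_anova <- function(ratios, treatments) {
  keep <- is.finite(ratios)
  if (any(!keep)) {
    warning(sum(!keep), " sample(s) with non-finite ratio excluded")
  }
  ratios <- ratios[keep]
  treatments <- factor(as.character(treatments)[keep])
  if (nlevels(treatments) < 2L || any(table(treatments) < 2L)) {
    stop("ratio_anova needs >= 2 treatments with >= 2 samples each")
  }
  fit <- aov(ratios ~ treatments)
  s <- summary(fit)[[1L]]
  list(f = s[["F value"]][1L], p = s[["Pr(>F)"]][1L],
       df = s[["Df"]], n_used = length(ratios))
}

#' Firmicutes/Bacteroidetes ratio per sample
#'
#' @param mat Samples x genus abundance matrix.
#' @param genus_phylum Named character vector genus -> phylum.
#' @return Numeric ratio per sample (`Inf` when Bacteroidetes is absent).
#' @export
fb_ratio <- function(mat, genus_phylum) {
  mat <- as.matrix(mat)
  phyla <- genus_phylum[colnames(mat)]
  f <- rowSums(mat[, which(phyla == "Firmicutes"), drop = FALSE])
  b <- rowSums(mat[, which(phyla == "Bacteroidetes"), drop = FALSE])
  f / b
}
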