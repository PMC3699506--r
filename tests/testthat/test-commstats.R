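test_that("Bray-Curtis matches hand arithmetic and its bounds", {
  expect_equal(bray_curtis(c(4, 2), c(4, 2)), 0)
  expect_equal(bray_curtis(c(4, 0), c(0, 4)), 1)
  expect_equal(bray_curtis(c(4, 2), c(2, 4)), 4 / 12)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("Morisita-Horn is scale-invariant and bounded", {
  x <- c(3, 1, 0, 6)
  expect_equal(morisita_horn(x, x), 0)
  expect_equal(morisita_horn(x, 3 * x), 0)       # unequal sample sizes
  expect_equal(morisita_horn(c(1, 0), c(0, 5)), 1)
  expect_error(morisita_horn(c(0, 0), c(1, 2)), "zero-total")
})

test_that("both distances agree with vegan on random communities", {
  skip_if_not_installed("vegan")
  for (s in 1:20) {
    m <- withr::with_seed(s, matrix(rpois(2 * 15, 8), 2, 15))
    expect_equal(bray_curtis(m[1, ], m[2, ]),
                 as.numeric(vegan::vegdist(m, "bray")), tolerance = 1e-9)
    expect_equal(morisita_horn(m[1, ], m[2, ]),
                 as.numeric(vegan::vegdist(m, "horn")), tolerance = 1e-9)
  }
})

test_that("UPGMA reproduces hand-computed merges and heights", {
  m <- matrix(c(0, 0.2, 0.6, 0.2, 0, 0.6, 0.6, 0.6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma(m)
  expect_equal(tree$height, 0.3)                 # C joins at 0.6 / 2
  inner <- tree$children[[1L]]
  if (!is.null(inner$leaf)) inner <- tree$children[[2L]]
  expect_equal(inner$height, 0.1)                # (A,B) merge at 0.2 / 2
  coph <- dendro_cophenetic(tree)
  expect_equal(coph["A", "B"], 0.2)
  expect_equal(coph["A", "C"], 0.6)
})

test_that("UPGMA is a fixed point on ultrametric input", {
  m <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  m["A", "B"] <- m["B", "A"] <- 0.2
  m["A", "C"] <- m["C", "A"] <- m["B", "C"] <- m["C", "B"] <- 0.5
  m[1:3, "D"] <- m["D", 1:3] <- 0.8
  tree <- upgma(m)
  expect_equal(dendro_cophenetic(tree)[rownames(m), colnames(m)], m)
})

test_that("UPGMA heights match average-linkage clustering", {
  skip_if_not_installed("vegan")
  for (s in 1:5) {
    mat <- withr::with_seed(s, matrix(rpois(6 * 10, 10), 6, 10))
    rownames(mat) <- paste0("S", 1:6)
    dm <- community_distance(mat, "bray_curtis")
    tree <- upgma(dm)
    hc <- stats::hclust(stats::as.dist(dm), method = "average")
    expect_equal(tree$height * 2, max(hc$height), tolerance = 1e-12)
    expect_equal(sort(unique(round(unlist(all_heights(tree)) * 2, 10))),
                 sort(unique(round(hc$height, 10))))
  }
})

test_that("equal distances resolve deterministically with equal heights", {
  m <- matrix(0.4, 3, 3, dimnames = list(c("B", "A", "C"), c("B", "A", "C")))
  diag(m) <- 0
  t1 <- upgma(m)
  t2 <- upgma(m[c(3, 1, 2), c(3, 1, 2)])     # order must not matter
  expect_identical(write_dendrogram(t1), write_dendrogram(t2))
  expect_equal(t1$height, 0.2)
})

test_that("PERMANOVA pseudo-F matches vegan::adonis2", {
  skip_if_not_installed("vegan")
  for (s in 1:5) {
    mat <- withr::with_seed(s, matrix(rgamma(12 * 8, 2), 12, 8))
    rownames(mat) <- paste0("S", 1:12)
    g <- rep(c("A", "B", "C"), each = 4)
    dm <- community_distance(mat, "bray_curtis")
    ours <- permanova(dm, g, n_perm = 49L, exhaustive_limit = 0L)
    ref <- vegan::adonis2(stats::as.dist(dm) ~ g, permutations = 49)
    expect_equal(ours$f, ref$F[1L], tolerance = 1e-9)
  }
})

test_that("PERMANOVA F is invariant under group-preserving relabelling", {
  mat <- withr::with_seed(7L, matrix(rgamma(8 * 6, 2), 8, 6))
  rownames(mat) <- paste0("S", 1:8)
  g <- rep(c("A", "B"), each = 4)
  dm <- community_distance(mat, "bray_curtis")
  f1 <- permanova(dm, g, exhaustive_limit = 0L, n_perm = 9L)$f
  perm <- c(2, 1, 4, 3, 6, 5, 8, 7)          # shuffles within groups
  f2 <- permanova(dm[perm, perm], g[perm], exhaustive_limit = 0L,
                  n_perm = 9L)$f
  expect_equal(f1, f2)
  expect_error(permanova(dm, c("A", rep("B", 7))), "at least 2")
})

test_that("separated groups reach the smallest enumerable p-value", {
  # two groups with disjoint supports
  mat <- rbind(matrix(c(10, 9, 11, 10, 0, 0, 0, 0), 4, 2),
               matrix(c(0, 0, 0, 0, 10, 11, 9, 10), 4, 2))
  rownames(mat) <- paste0("S", 1:8)
  g <- rep(c("A", "B"), each = 4)
  dm <- community_distance(mat, "bray_curtis")
  res <- permanova(dm, g, exhaustive_limit = 50000L)
  expect_true(res$exact)
  # all 8! permutations enumerated; only group-preserving ones tie F_obs
  min_p <- factorial(4) * factorial(4) * 2 / factorial(8)
  expect_equal(res$p, min_p)
})

test_that("restricted permutations stay within strata", {
  mat <- withr::with_seed(8L, matrix(rgamma(6 * 5, 2), 6, 5))
  rownames(mat) <- paste0("S", 1:6)
  dm <- community_distance(mat, "bray_curtis")
  g <- c("A", "B", "A", "B", "A", "B")
  strata <- c("c1", "c1", "c2", "c2", "c3", "c3")
  res <- permanova(dm, g, strata = strata, exhaustive_limit = 100L)
  expect_true(res$exact)
  expect_equal(res$n_perm_used, 2^3)         # (2!)^3 stratum permutations
})

test_that("differential abundance flags an enriched genus and routes sparse taxa", {
  base <- c(0.20, rep(0.80 / 9, 9))
  names(base) <- paste0("T", 1:10)
  alt <- base; alt["T1"] <- alt["T1"] * 3; alt <- alt / sum(alt)
  cnt <- withr::with_seed(31L, {
    rbind(t(rmultinom(3, 1000, base)), t(rmultinom(3, 1000, alt)))
  })
  colnames(cnt) <- names(base)
  g <- rep(c("A", "B"), each = 3)
  da <- diff_abundance(cnt, g, seed = 31L)
  expect_equal(nrow(da), 10L)
  expect_lt(da$q[da$taxon == "T1"], 0.1)
  expect_true(all(da$test == "t_perm"))

  # sparse taxon (4 reads, all in one group) goes to the exact test
  cnt2 <- cbind(cnt, Rare = c(4L, 0L, 0L, 0L, 0L, 0L))
  da2 <- diff_abundance(cnt2, g, seed = 31L)
  expect_equal(da2$test[da2$taxon == "Rare"], "fisher")

  # identical compositions: nothing can reach small q
  same <- matrix(rep(c(100L, 200L, 300L), 6L), 6L, 3L, byrow = TRUE)
  colnames(same) <- c("X", "Y", "Z")
  da3 <- diff_abundance(same, g)
  expect_true(all(da3$q >= 0.5))
  expect_error(diff_abundance(cnt, rep("A", 6)), "two groups")
})

test_that("ratio ANOVA matches aov and excludes non-finite ratios", {
  r_same <- rep(c(1.2, 1.3), 3L)
  g <- rep(c("A", "B", "C"), each = 2)
  res0 <- ratio_anova(r_same, g)
  expect_equal(res0$f, 0)
  r <- c(0.9, 1.0, 1.1, 2.9, 3.0, 3.1)
  res <- ratio_anova(r, rep(c("A", "B"), each = 3))
  expect_lt(res$p, 0.01)
  expect_warning(
    res2 <- ratio_anova(c(r, Inf), c(rep(c("A", "B"), each = 3), "A")),
    "non-finite")
  expect_equal(res2$n_used, 6L)
  expect_equal(res2$f, res$f)
})

test_that("Firmicutes/Bacteroidetes ratios flow from genus tables", {
  mat <- rbind(S1 = c(Prevotella = 40, Ruminococcus = 40, Megasphaera = 20),
               S2 = c(Prevotella = 0, Ruminococcus = 50, Megasphaera = 50))
  gp <- c(Prevotella = "Bacteroidetes", Ruminococcus = "Firmicutes",
          Megasphaera = "Firmicutes")
  r <- fb_ratio(mat, gp)
  expect_equal(unname(r["S1"]), 60 / 40)
  expect_true(is.infinite(r["S2"]))
})
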