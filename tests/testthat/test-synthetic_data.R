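test_that("zero divergence propagates the root sequence unchanged", {
  specs <- list(taxon_spec(lin_row("GenA"), n_ref_seqs = 1L,
                           divergence = rep(0, 6)),
                taxon_spec(lin_row("GenB"), n_ref_seqs = 1L,
                           divergence = rep(0, 6)))
  ref <- make_reference(specs, seed = 3L, within_divergence = 0)
  expect_equal(ref$records$seq[1L], ref$records$seq[2L])
})

test_that("sibling genera diverge at roughly the stated proportion", {
  diffs <- vapply(1:10, function(s) {
    specs <- list(
      taxon_spec(lin_row("GenA"), n_ref_seqs = 1L,
                 divergence = c(0, 0, 0, 0, 0, 0.05)),
      taxon_spec(lin_row("GenB"), n_ref_seqs = 1L,
                 divergence = c(0, 0, 0, 0, 0, 0.05)))
    ref <- make_reference(specs, seed = s, within_divergence = 0)
    a <- strsplit(ref$records$seq[1L], "")[[1]]
    b <- strsplit(ref$records$seq[2L], "")[[1]]
    mean(a != b)
  }, numeric(1L))
  expect_true(abs(mean(diffs) - 0.05) < 0.02)
})

test_that("reference generation is seed-deterministic, byte for byte", {
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  l1 <- withr::local_tempfile(fileext = ".tsv")
  ref1 <- make_reference(rumen_taxon_specs(n_ref_seqs = 2L), seed = 11L)
  ref2 <- make_reference(rumen_taxon_specs(n_ref_seqs = 2L), seed = 11L)
  write_reference(ref1, f1, l1)
  write_reference(ref2, f2, withr::local_tempfile(fileext = ".tsv"))
  expect_identical(readLines(f1), readLines(f2))
  back <- read_lineage_table(l1)
  expect_equal(back$genus, ref1$lineage$genus)
})

test_that("taxonomy label reuse under different parents is rejected", {
  specs <- list(
    taxon_spec(c("Bacteria", "P1", "C1", "O1", "F1", "GenX")),
    taxon_spec(c("Bacteria", "P2", "C2", "O2", "F1", "GenY")))
  expect_error(make_reference(specs), "tree")
})

test_that("community draws respect proportions and conserve totals", {
  spec <- community_spec(list(T1 = c(A = 1)))
  cnt <- simulate_community(spec, "T1", 100L, seed = 1L)
  expect_equal(unname(cnt["A"]), 100L)

  spec2 <- community_spec(list(T1 = c(A = 0.5, B = 0.5)))
  cnt2 <- simulate_community(spec2, "T1", 10000L, seed = 5L)
  expect_equal(sum(cnt2), 10000L)
  expect_true(abs(cnt2[["A"]] - 5000) <= 200)   # 4-sigma binomial bound

  for (s in 1:5) {
    cnt3 <- simulate_community(rumen_community_spec(), "L2", 777L, seed = s)
    expect_equal(sum(cnt3), 777L)
  }
  expect_error(simulate_community(spec, "T1", 0L), "positive")
  expect_error(simulate_community(spec, "T9", 10L), "unknown treatment")
})

test_that("fold changes multiply and renormalise baseline proportions", {
  base <- c(A = 0.5, B = 0.5)
  out <- apply_fold_changes(base, c(A = 3))
  expect_equal(sum(out), 1)
  expect_equal(unname(out["A"] / out["B"]), 3)
})

test_that("error-free V1V2 reads reverse-complement back into their source", {
  ref <- make_reference(rumen_taxon_specs(n_ref_seqs = 2L), seed = 21L)
  cnt <- simulate_community(rumen_community_spec(), "L0", 60L, seed = 2L)
  rd <- sample_reads(cnt, ref, region = "V1V2", barcode = "ACAC", seed = 2L)
  expect_equal(nrow(rd$records), 60L)
  expect_equal(nrow(rd$truth), 60L)            # ground-truth closure
  for (i in seq_len(10L)) {
    insert <- substr(rd$records$seq[i], 4L + nchar(default_primers()[["rev"]]) + 1L,
                     nchar(rd$records$seq[i]))
    plus <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(insert)))
    src <- ref$records$seq[ref$records$id == rd$truth$ref_id[i]]
    expect_true(grepl(plus, src, fixed = TRUE))
  }
})

test_that("chimera_rate one flags two parents on every read", {
  ref <- make_reference(rumen_taxon_specs(n_ref_seqs = 1L), seed = 22L)
  cnt <- simulate_community(rumen_community_spec(), "L0", 40L, seed = 3L)
  rd <- sample_reads(cnt, ref, region = "V1V2",
                     em = error_model(chimera_rate = 1),
                     barcode = "ACAC", seed = 3L)
  expect_true(all(rd$truth$chimera))
  expect_true(all(!is.na(rd$truth$parent2_genus)))
})

test_that("substitution errors hit at the configured rate", {
  ref <- make_reference(rumen_taxon_specs(n_ref_seqs = 1L), seed = 23L,
                        within_divergence = 0)
  cnt <- setNames(rep(4L, 10L), names(rumen_community_spec()$proportions$L0))
  rd <- sample_reads(cnt, ref, region = "V1V2",
                     em = error_model(sub_rate = 0.01),
                     barcode = "ACAC", seed = 9L)
  rd0 <- sample_reads(cnt, ref, region = "V1V2", barcode = "ACAC", seed = 9L)
  # ~40 reads x ~310 nt = ~12 kb; compare to the same draws without errors
  mism <- sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, rd$records$seq, rd0$records$seq))
  expected <- 0.01 * sum(nchar(rd0$records$seq) - 24L)  # barcode+primer exempt
  expect_true(abs(mism - expected) < 4 * sqrt(expected))
})

test_that("V1 tags are plus-orientation prefixes of the source region", {
  ref <- make_reference(rumen_taxon_specs(n_ref_seqs = 2L), seed = 24L)
  cnt <- simulate_community(rumen_community_spec(), "L0", 30L, seed = 4L)
  rd <- sample_reads(cnt, ref, region = "V1", v1_length = 55L, seed = 4L)
  expect_true(all(nchar(rd$records$seq) == 55L))
  for (i in seq_len(5L)) {
    src <- ref$records$seq[ref$records$id == rd$truth$ref_id[i]]
    expect_true(grepl(rd$records$seq[i], src, fixed = TRUE))
  }
})

test_that("concatemer layout: junction borders only, correct lengths", {
  rsts <- c(random_dna(50, seed = 1), random_dna(55, seed = 2))
  cc <- build_concatemers(rsts, n_clones = 20L, tags_per_clone = 2L,
                          seed = 6L)
  k2 <- cc$truth[cc$truth$clone_id == cc$records$id[1L], ]
  expect_equal(nrow(k2), 2L)
  expect_equal(nchar(cc$records$seq[1L]),
               sum(nchar(k2$rst)) + 8L)         # tag + border + tag

  one <- build_concatemers(rsts, n_clones = 5L, tags_per_clone = 1L,
                           seed = 7L)
  expect_false(any(grepl("ACGGGTCG", one$records$seq, fixed = TRUE)))
  expect_false(any(grepl("CGACCCGT", one$records$seq, fixed = TRUE)))

  expect_error(build_concatemers(rsts, tags_per_clone = 16L), "15")
  expect_error(build_concatemers("ACGT", tags_per_clone = 1L), "40")
})

test_that("in-silico digestion cuts at the documented offsets", {
  # first GGCC at 0-based position 100 -> terminal fragment of 102
  seq <- paste0(random_dna(100, seed = 31, avoid = c("GGCC")), "GGCC",
                random_dna(60, seed = 32))
  expect_equal(terminal_fragment_length(seq, "HaeIII"), 102L)
  expect_equal(terminal_fragment_length("AACCGGTT", "MspI"), 3L)  # C^CGG
  expect_equal(terminal_fragment_length("AGCGCT", "HhaI"), 4L)    # GCG^C
  expect_equal(terminal_fragment_length("TTGTACAA", "RsaI"), 4L)  # GT^AC
  expect_true(is.na(terminal_fragment_length("AAAA", "HaeIII")))
})

test_that("simulated peaks scale linearly with counts and respect noise=0", {
  ref <- make_reference(rumen_taxon_specs(n_ref_seqs = 1L), seed = 25L)
  cnt1 <- c(Prevotella = 100L)
  cnt2 <- c(Prevotella = 200L)
  p1 <- simulate_trflp(cnt1, ref, enzymes = "HaeIII", noise_peaks = 0L,
                       seed = 5L)
  p2 <- simulate_trflp(cnt2, ref, enzymes = "HaeIII", noise_peaks = 0L,
                       seed = 5L)
  expect_equal(nrow(p1), 1L)                  # one taxon, one site pattern
  expect_equal(p2$area, 2 * p1$area)          # exact linearity
  expect_equal(p2$size_bp, p1$size_bp)
  expect_true(all(p1$true))
})

test_that("all generators are seed-deterministic", {
  spec <- rumen_community_spec()
  expect_identical(simulate_community(spec, "L1", 500L, seed = 8L),
                   simulate_community(spec, "L1", 500L, seed = 8L))
  ref <- make_reference(rumen_taxon_specs(n_ref_seqs = 1L), seed = 26L)
  cnt <- simulate_community(spec, "L0", 50L, seed = 8L)
  expect_identical(sample_reads(cnt, ref, barcode = "ACAC", seed = 12L),
                   sample_reads(cnt, ref, barcode = "ACAC", seed = 12L))
  expect_identical(simulate_trflp(cnt, ref, seed = 13L),
                   simulate_trflp(cnt, ref, seed = 13L))
  rsts <- vapply(1:5, function(i) random_dna(52, seed = i), character(1L))
  expect_identical(build_concatemers(rsts, n_clones = 10L, seed = 14L),
                   build_concatemers(rsts, n_clones = 10L, seed = 14L))
})
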