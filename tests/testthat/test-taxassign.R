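test_that("region extraction keeps inter-primer coordinates exactly", {
  region <- random_dna(310, seed = 71, avoid = c(FWD, REV_SITE))
  ref <- fixture_reference("A_1", region, rbind(lin_row("GenA")))
  db <- extract_region(ref)
  expect_equal(db$records$region, region)

  # record missing the reverse-primer site is dropped with a count
  no_rev <- ref
  no_rev$records$seq[1L] <- sub(REV_SITE, random_dna(20, seed = 72),
                                no_rev$records$seq[1L], fixed = TRUE)
  db2 <- extract_region(no_rev)
  expect_equal(nrow(db2$records), 0L)
  expect_equal(unname(db2$dropped["missing_primer"]), 1L)

  # duplicated forward site -> ambiguous primer, dropped
  twice <- ref
  twice$records$seq[1L] <- paste0(FWD, twice$records$seq[1L])
  db3 <- extract_region(twice)
  expect_equal(nrow(db3$records), 0L)
  expect_equal(unname(db3$dropped["ambiguous_primer"]), 1L)
})

test_that("primer mismatch tolerance is monotone in records kept", {
  regions <- vapply(1:4, function(i) {
    random_dna(300, seed = 720L + i, avoid = c(FWD, REV_SITE))
  }, character(1L))
  ref <- fixture_reference(paste0("R_", 1:4), regions,
                           do.call(rbind, lapply(paste0("G", 1:4), lin_row)))
  # corrupt one forward primer site by two substitutions
  s <- ref$records$seq[2L]
  site <- regexpr(FWD, s, fixed = TRUE)[1L]
  broken <- mutate_positions(s, c(site + 3L, site + 9L))
  ref$records$seq[2L] <- broken
  kept0 <- nrow(extract_region(ref, max_mismatch = 0L)$records)
  kept2 <- nrow(extract_region(ref, max_mismatch = 2L)$records)
  expect_equal(kept0, 3L)
  expect_equal(kept2, 4L)
  expect_gte(kept2, kept0)
})

test_that("dereplication collapses duplicates to the common lineage", {
  region <- random_dna(280, seed = 73, avoid = c(FWD, REV_SITE))
  other <- random_dna(280, seed = 74, avoid = c(FWD, REV_SITE))
  # identical regions, same genus -> one record, genus kept
  ref <- fixture_reference(c("A_1", "A_2"), c(region, region),
                           rbind(lin_row("GenA"), lin_row("GenA")))
  db <- dereplicate(extract_region(ref))
  expect_equal(nrow(db$records), 1L)
  expect_equal(db$records$genus, "GenA")

  # identical regions, different genera in one family -> family level
  ref2 <- fixture_reference(c("A_1", "B_1"), c(region, region),
                            rbind(lin_row("GenA", family = "FamX"),
                                  lin_row("GenB", family = "FamX")))
  db2 <- dereplicate(extract_region(ref2))
  expect_equal(nrow(db2$records), 1L)
  expect_equal(db2$records$family, "FamX")
  expect_true(is.na(db2$records$genus))

  # all-unique input is untouched
  ref3 <- fixture_reference(c("A_1", "B_1"), c(region, other),
                            rbind(lin_row("GenA"), lin_row("GenB")))
  db3 <- dereplicate(extract_region(ref3))
  expect_equal(nrow(db3$records), 2L)
})

test_that("candidate search ranks by shared words with stable ties", {
  regions <- vapply(1:6, function(i) {
    random_dna(260, seed = 740L + i, avoid = c(FWD, REV_SITE))
  }, character(1L))
  ref <- fixture_reference(paste0("R_", 1:6), regions,
                           do.call(rbind, lapply(paste0("G", 1:6), lin_row)))
  db <- prepare_reference_db(ref)
  ord <- match(paste0("R_", 1:6), db$records$id)
  hit <- find_candidates(regions[3L], db)
  expect_equal(hit[1L], ord[3L])

  # no shared words -> empty candidate list
  expect_length(find_candidates(strrep("A", 40L), db), 0L)
  # query shorter than the word size
  expect_length(find_candidates("ACG", db), 0L)
  # max_hits = 1 returns the top element of the full ranking
  expect_equal(find_candidates(regions[3L], db, max_hits = 1L),
               find_candidates(regions[3L], db, max_hits = 50L)[1L])
})

test_that("alignment screen measures identity, span and p-distance", {
  cand <- random_dna(200, seed = 75)
  # exact substring: identity 1, p 0
  q <- substr(cand, 41L, 140L)
  st <- align_and_screen(q, cand)
  expect_equal(st$identity, 1)
  expect_equal(st$p_distance, 0)
  expect_true(st$pass)

  # 100-nt query whose best span is ~80 nt -> screened out
  q80 <- paste0(substr(cand, 41L, 120L), random_dna(20, seed = 76))
  st80 <- align_and_screen(q80, substr(cand, 1L, 130L))
  expect_false(st80$pass)
  expect_lt(st80$span, 95L)

  # 4 substitutions over 100 gap-free columns -> p = 0.04
  q4 <- mutate_positions(substr(cand, 41L, 140L), c(10L, 30L, 55L, 80L))
  st4 <- align_and_screen(q4, cand)
  expect_equal(st4$p_distance, 0.04)
  expect_equal(st4$span, 100L)
  expect_equal(st4$identity, 0.96)
})

test_that("Jukes-Cantor distance matches the closed form on its domain", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.1), 0.107326, tolerance = 1e-5)
  expect_error(jukes_cantor(0.75), "undefined")
  expect_error(jukes_cantor(-0.01), "undefined")
  p <- seq(0, 0.74, by = 0.01)
  d <- jukes_cantor(p)
  expect_true(all(d >= p - 1e-12))          # d >= p
  expect_true(all(diff(d) > 0))             # strictly increasing
  expect_true(all(diff(diff(d)) > 0))       # convex
})

test_that("closest neighbour wins; ties go to deeper classification then id", {
  base <- random_dna(250, seed = 77, avoid = c(FWD, REV_SITE))
  r1 <- mutate_positions(base, 10L)          # 1 substitution each
  r2 <- mutate_positions(base, 200L)
  lin_genus <- lin_row("GenA", family = "FamX")
  lin_family <- c("Bacteria", "PhyA", "PhyA_c", "PhyA_o", "FamX", NA)
  ref <- fixture_reference(c("B_1", "A_1"), c(r1, r2),
                           rbind(lin_genus, lin_family))
  db <- prepare_reference_db(ref)
  a <- assign_taxonomy(setNames(base, "q1"), db)
  expect_equal(a$status, "assigned")
  expect_equal(a$neighbour_id, "B_1")        # deeper classification wins
  expect_equal(a$genus, "GenA")
  expect_equal(a$jc_distance, jukes_cantor(1 / 250))

  # equal depth: smallest reference id wins
  ref2 <- fixture_reference(c("B_1", "A_1"), c(r1, r2),
                            rbind(lin_row("GenB"), lin_row("GenA")))
  db2 <- prepare_reference_db(ref2)
  a2 <- assign_taxonomy(setNames(base, "q1"), db2)
  expect_equal(a2$neighbour_id, "A_1")
})

test_that("queries without a confident neighbour are filtered", {
  region <- random_dna(260, seed = 78, avoid = c(FWD, REV_SITE))
  ref <- fixture_reference("A_1", region, rbind(lin_row("GenA")))
  db <- prepare_reference_db(ref)
  # unrelated query shares no 7-mers
  a <- assign_taxonomy(setNames(strrep("AT", 60L), "q1"), db)
  expect_equal(a$status, "filtered_no_hit")
  # ~10% divergent query finds candidates but fails the 95% screen
  far <- mutate_positions(region, seq(5L, 255L, by = 10L))
  a2 <- assign_taxonomy(setNames(far, "q2"), db)
  expect_equal(a2$status, "filtered_identity")
  expect_true(is.na(a2$genus))
})

test_that("chimeras of distant genera are filtered by the identity screen", {
  specs <- rumen_taxon_specs(n_ref_seqs = 2L)
  ref <- make_reference(specs, seed = 79L)
  db <- prepare_reference_db(ref)
  cnt <- simulate_community(rumen_community_spec(), "L0", 120L, seed = 6L)
  rd <- sample_reads(cnt, ref, region = "V1V2",
                     em = error_model(chimera_rate = 1), barcode = "ACAC",
                     seed = 6L)
  qc <- run_qc(rd$records, demux_rule(c(S1 = "ACAC")))
  kept <- qc$reads[qc$reads$status == "assigned", ]
  a <- assign_taxonomy(data.frame(id = kept$read_id, seq = kept$insert), db)
  cross <- rd$truth$genus != rd$truth$parent2_genus
  filtered <- a$status == "filtered_identity"
  # most cross-genus chimeras must be caught by the screen
  expect_gt(mean(filtered[cross]), 0.5)
})
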