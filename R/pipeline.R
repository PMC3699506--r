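# End-to-end orchestration on synthetic data: the sequence arm
# (community -> barcoded reads -> QC -> taxonomy -> OTU scan -> diversity
# -> community statistics) and the T-RFLP arm (peak simulation ->
# detection/binning -> distances -> UPGMA -> PERMANOVA), each under a
# single seeded configuration.

#' Latin-square experimental design
#'
#' Cyclic assignment of treatments over an animals x periods grid: each
#' treatment occurs exactly once per animal and once per period.
#'
#' @param animals,periods,treatments Level labels; all three must have
#'   equal length.
#' @return `data.frame`: sample, animal, period, treatment.
#' @export
latin_square_design <- function(animals = c("C1", "C2", "C3"),
                                periods = c("P1", "P2", "P3"),
                                treatments = c("L0", "L1", "L2")) {
  k <- length(treatments)
  if (length(animals) != k || length(periods) != k) {
    stop("animals, periods and treatments must have equal length")
  }
  rows <- list()
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      rows[[length(rows) + 1L]] <- data.frame(
        animal = animals[i], period = periods[j],
        treatment = treatments[((i + j - 2L) %% k) + 1L],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$sample <- paste(out$animal, out$period, sep = ".")
  out[, c("sample", "animal", "period", "treatment")]
}

#' Validate a Latin-square design
#'
#' @param design `data.frame` with columns animal, period, treatment.
#' @return `TRUE` invisibly; error when any treatment repeats within an
#'   animal or period.
#' @export
validate_latin_square <- function(design) {
  for (fac in c("animal", "period")) {
    tab <- table(design[[fac]], design$treatment)
    if (any(tab != 1L)) {
      stop("design is not a Latin square: each treatment must occur ",
           "exactly once per ", fac)
    }
  }
  invisible(TRUE)
}

#' Default configuration for the synthetic pipeline runs
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param reads_per_sample Reads drawn per sample.
#' @return Named list of run parameters.
#' @export
default_run_config <- function(seed = 1L, reads_per_sample = 1000L) {
  list(seed = as.integer(seed),
       reads_per_sample = as.integer(reads_per_sample),
       region = "V1V2",
       cluster_threshold = 0.93,
       error_model = error_model(),
       enzymes = names(TRFLP_ENZYMES),
       noise_peaks = 200L,
       noise_area_scale = 1)
}

# Deterministic per-sample barcodes with pairwise Hamming distance >= 2.
sample_barcodes <- function(n) {
  pool <- c("ACAC", "AGTG", "ATGA", "CATT", "CGCG", "CTAA",
            "GACG", "GGTC", "GTAT", "TCGT", "TGCC", "TAGG")
  if (n > length(pool)) stop("too many samples for the barcode pool")
  pool[seq_len(n)]
}

#' Run the sequence analysis arm on synthetic data
#'
#' Generates a reference database and a Latin-square design, draws a
#' community and barcoded reads per sample, demultiplexes and
#' quality-filters, assigns taxonomy, clusters at the configured
#' threshold with a consensus classification, computes per-sample genus
#' composition, Morisita-Horn distances with UPGMA grouping and a
#' treatment PERMANOVA (permutations restricted within animal), and
#' per-genus differential abundance between the extreme treatments.
#'
#' @param config List from [default_run_config()].
#' @param out_dir Optional directory: when given, the main tables are
#'   written there (assignments TSV, genus table CSV, distance CSV,
#'   newick tree).
#' @return List with the design, truth and result tables of every stage.
#' @export
run_sequence_arm <- function(config = default_run_config(),
                             out_dir = NULL) {
  design <- latin_square_design()
  validate_latin_square(design)
  ref <- make_reference(rumen_taxon_specs(), seed = config$seed)
  db <- prepare_reference_db(ref)
  spec <- rumen_community_spec()
  barcodes <- sample_barcodes(nrow(design))
  rule <- demux_rule(setNames(barcodes, design$sample))

  all_reads <- list(); all_truth <- list()
  for (i in seq_len(nrow(design))) {
    cnt <- simulate_community(spec, design$treatment[i],
                              config$reads_per_sample,
                              seed = config$seed + 11L * i)
    rd <- sample_reads(cnt, ref, region = config$region,
                       em = config$error_model,
                       barcode = barcodes[i],
                       seed = config$seed + 13L * i,
                       id_prefix = design$sample[i])
    all_reads[[i]] <- rd$records
    tr <- rd$truth
    tr$sample <- design$sample[i]
    all_truth[[i]] <- tr
  }
  reads <- do.call(rbind, all_reads)
  truth <- do.call(rbind, all_truth)

  qc <- run_qc(reads, rule)
  kept <- qc$reads[qc$reads$status == "assigned", , drop = FALSE]
  queries <- data.frame(id = kept$read_id, seq = kept$insert,
                        stringsAsFactors = FALSE)
  assign <- assign_taxonomy(queries, db)
  assign$sample <- kept$sample[match(assign$query_id, kept$read_id)]

  assigned <- assign[assign$status == "assigned" & !is.na(assign$genus), ]
  genus_table <- as.matrix(table(assigned$sample, assigned$genus))
  class(genus_table) <- "matrix"

  uniq <- !duplicated(queries$seq)
  seqs <- setNames(queries$seq[uniq], queries$id[uniq])
  w <- as.numeric(table(queries$seq)[queries$seq[uniq]])
  lin <- assign[match(names(seqs), assign$query_id), TAXO_RANKS]
  scan <- threshold_scan(seqs, lin, weights = w)

  depth <- min(rowSums(genus_table))
  div <- do.call(rbind, lapply(rownames(genus_table), function(s) {
    cnt <- subsample_counts(genus_table[s, ], depth,
                            seed = config$seed + 17L)
    data.frame(sample = s, depth = depth, s_obs = sum(cnt > 0),
               chao1 = chao1(cnt), coverage = goods_coverage(cnt),
               shannon = shannon(cnt), stringsAsFactors = FALSE)
  }))

  dm <- community_distance(genus_table, "morisita_horn")
  tree <- upgma(dm)
  idx <- match(rownames(genus_table), design$sample)
  pmv <- permanova(dm, design$treatment[idx], seed = config$seed,
                   strata = design$animal[idx])
  extreme <- design$treatment[idx] %in% c("L0", "L2")
  da <- diff_abundance(genus_table[extreme, , drop = FALSE],
                       design$treatment[idx][extreme],
                       seed = config$seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(assign, file.path(out_dir, "assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write.csv(genus_table, file.path(out_dir, "genus_table.csv"))
    write.csv(dm, file.path(out_dir, "morisita_horn.csv"))
    write_dendrogram(tree, file.path(out_dir, "upgma.nwk"))
    write.csv(scan, file.path(out_dir, "threshold_scan.csv"),
              row.names = FALSE)
  }
  list(design = design, truth = truth, qc = qc, assignments = assign,
       genus_table = genus_table, scan = scan, diversity = div,
       distance = dm, tree = tree, permanova = pmv,
       diff_abundance = da)
}

# Fraction-dependent community: fibre-attached genera are enriched in the
# solid fraction and depleted in the liquid, flattening dominance in the
# solid phase (higher evenness, as observed for fibre-adherent
# communities).
fraction_folds <- function(fraction) {
  fib <- c(Fibrobacter = 2.5, Ruminococcus = 2.5, Butyrivibrio = 2)
  switch(fraction,
         SO = fib,
         LI = 1 / fib,
         LS = setNames(rep(1, 3L), names(fib)))
}

#' Run the T-RFLP analysis arm on synthetic data
#'
#' Simulates multi-enzyme peak tables for every animal x period x
#' fraction x day profile under the Latin-square treatments, labels true
#' peaks, bins and log-transforms, concatenates the enzyme matrices, and
#' computes Bray-Curtis distances, mean treatment-by-fraction distances
#' with UPGMA grouping, and PERMANOVAs for treatment and fraction with
#' permutations restricted within animal.
#'
#' @param config List from [default_run_config()].
#' @param fractions Sampled phases (liquid, whole content, solid).
#' @param days Sampling days per combination.
#' @param out_dir Optional output directory (binned matrix CSV, distance
#'   CSV, newick tree).
#' @return List with the design, peak tables, matrices, distances, tree
#'   and PERMANOVA results.
#' @export
run_trflp_arm <- function(config = default_run_config(),
                          fractions = c("LI", "LS", "SO"),
                          days = c("D1", "D2"), out_dir = NULL) {
  design <- latin_square_design()
  validate_latin_square(design)
  spec <- rumen_community_spec()
  rows <- list(); peaks <- list()
  k <- 0L
  for (i in seq_len(nrow(design))) {
    base <- spec$proportions[[design$treatment[i]]]
    for (fr in fractions) {
      p <- apply_fold_changes(base, fraction_folds(fr))
      for (d in days) {
        k <- k + 1L
        id <- paste(design$sample[i], fr, d, sep = ".")
        cnt <- with_seed(config$seed + 101L * k, {
          v <- as.integer(rmultinom(1L, config$reads_per_sample, p))
          setNames(v, names(p))
        })
        rows[[k]] <- data.frame(sample = id, animal = design$animal[i],
                                period = design$period[i],
                                treatment = design$treatment[i],
                                fraction = fr, day = d,
                                stringsAsFactors = FALSE)
        peaks[[k]] <- list(id = id, counts = cnt)
      }
    }
  }
  meta <- do.call(rbind, rows)
  ref <- make_reference(rumen_taxon_specs(), seed = config$seed)
  peak_tab <- do.call(rbind, lapply(seq_along(peaks), function(j) {
    simulate_trflp(peaks[[j]]$counts, ref, enzymes = config$enzymes,
                   noise_peaks = config$noise_peaks,
                   noise_area_scale = config$noise_area_scale,
                   sample = peaks[[j]]$id,
                   seed = config$seed + 7L * j)
  }))
  res <- trflp_matrix(peak_tab[, c("sample", "enzyme", "size_bp", "area")])
  dm <- community_distance(res$matrix, "bray_curtis")
  grp <- paste(meta$treatment, meta$fraction, sep = ".")
  mean_dm <- group_mean_distance(dm, grp[match(rownames(res$matrix),
                                               meta$sample)])
  tree <- upgma(mean_dm)
  idx <- match(rownames(res$matrix), meta$sample)
  pmv_treat <- permanova(dm, meta$treatment[idx], seed = config$seed,
                         strata = meta$animal[idx],
                         exhaustive_limit = 1000L,
                         n_perm = 999L)
  pmv_frac <- permanova(dm, meta$fraction[idx], seed = config$seed + 1L,
                        strata = meta$animal[idx],
                        exhaustive_limit = 1000L,
                        n_perm = 999L)
  # Shannon on the binned true-peak relative abundances (concatenated
  # across enzymes), not on the log-transformed matrix
  areas <- do.call(cbind, res$binned)
  shannon_by_fraction <- tapply(seq_len(nrow(areas)), meta$fraction[idx],
                                function(ii) {
                                  mean(apply(areas[ii, , drop = FALSE],
                                             1L, shannon))
                                })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(res$matrix, file.path(out_dir, "trf_matrix.csv"))
    write.csv(dm, file.path(out_dir, "bray_curtis.csv"))
    write_dendrogram(tree, file.path(out_dir, "upgma_groups.nwk"))
  }
  list(design = meta, peaks = peak_tab, trflp = res, distance = dm,
       mean_distance = mean_dm, tree = tree,
       permanova_treatment = pmv_treat, permanova_fraction = pmv_frac,
       shannon_by_fraction = shannon_by_fraction)
}
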