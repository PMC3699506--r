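# Shared fixture builders: tiny reference sets with hand-placed primer
# sites, and random DNA without unwanted motifs.

FWD <- default_primers()[["fwd"]]
REV <- default_primers()[["rev"]]
REV_SITE <- as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(REV)))
RANKS6 <- c("domain", "phylum", "class", "order", "family", "genus")

random_dna <- function(n, seed = NULL, avoid = NULL) {
  draw <- function() {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }
  gen <- function() {
    s <- draw()
    while (!is.null(avoid) &&
           any(vapply(avoid, grepl, logical(1L), x = s, fixed = TRUE))) {
      s <- draw()
    }
    s
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Reference set from explicit ids / bare regions / lineage matrix: each
# region is wrapped in the primer sites plus random flanks, so the
# extracted region equals the bare region exactly.
fixture_reference <- function(ids, regions, lin_mat, flank = 25L,
                              seed = 99L) {
  seqs <- withr::with_seed(seed, {
    vapply(regions, function(rg) {
      paste0(random_dna(flank), FWD, rg, REV_SITE, random_dna(flank))
    }, character(1L), USE.NAMES = FALSE)
  })
  lin <- as.data.frame(lin_mat, stringsAsFactors = FALSE)
  names(lin) <- RANKS6
  structure(list(records = seq_records(ids, seqs),
                 lineage = cbind(data.frame(seq_id = ids,
                                            stringsAsFactors = FALSE),
                                 lin)),
            class = "reference_set")
}

lin_row <- function(genus, family = paste0(genus, "_fam"),
                    phylum = "PhyA") {
  c("Bacteria", phylum, paste0(phylum, "_c"), paste0(phylum, "_o"),
    family, genus)
}

# Pool of V1-like tags safe for concatemer round-trips: no border form
# inside a tag, and no terminus that can complete a border across a
# junction (suffix ACGGGT before a CGACCCGT border, or prefix ACCCGT
# after an ACGGGTCG border, would create a spurious split point).
sarst_tag_pool <- function(n, lens, seed) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      repeat {
        s <- paste(sample(c("A", "C", "G", "T"), lens[i], replace = TRUE),
                   collapse = "")
        if (!grepl("ACGGGTCG", s, fixed = TRUE) &&
            !grepl("CGACCCGT", s, fixed = TRUE) &&
            !endsWith(s, "ACGGGT") && !startsWith(s, "ACCCGT")) {
          return(s)
        }
      }
    }, character(1L))
  })
}

# Collect internal-node heights of a rumen_dendro recursively.
all_heights <- function(node) {
  if (!is.null(node$leaf)) return(numeric(0))
  c(node$height, unlist(lapply(node$children, all_heights)))
}

# Substitute scattered positions of a sequence (deterministic).
mutate_positions <- function(seq, pos, to = NULL) {
  chars <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(pos)) {
    p <- pos[i]
    repl <- if (is.null(to)) setdiff(bases, chars[p])[1L] else to[i]
    chars[p] <- repl
  }
  paste(chars, collapse = "")
}
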