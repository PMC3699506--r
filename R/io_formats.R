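# Readers and writers for the external representations the pipeline
# touches: FASTA/FASTQ sequence sets, T-RFLP peak tables and newick
# dendrograms.  All readers validate rather than coerce: malformed input is
# an error, not a silent fix-up.

#' Construct a sequence-record table
#'
#' The internal sequence container is a plain `data.frame` with columns
#' `id` (character), `seq` (uppercase DNA, alphabet A/C/G/T/N) and a list
#' column `qual` holding per-base integer Phred scores (or `NULL` when no
#' qualities exist, as for FASTA input).
#'
#' @param id Character vector of record identifiers.
#' @param seq Character vector of DNA sequences (case-insensitive; `U` is
#'   converted to `T`).
#' @param qual Optional list of integer vectors, one per record, each the
#'   same length as its sequence.
#' @return A `data.frame` with columns `id`, `seq`, `qual`.
#' @export
seq_records <- function(id, seq, qual = NULL) {
  id <- as.character(id)
  seq <- normalise_dna(seq)
  if (length(id) != length(seq)) stop("id and seq lengths differ")
  if (anyNA(id) || any(id == "")) stop("record ids must be non-empty")
  if (any(nchar(seq) == 0L)) stop("empty sequence in record set")
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("non-IUPAC characters (outside A/C/G/T/N) in record(s): ",
         paste(head(id[bad], 3L), collapse = ", "))
  }
  if (is.null(qual)) {
    qual <- vector("list", length(seq))
  } else {
    if (length(qual) != length(seq)) stop("qual and seq lengths differ")
    ok <- mapply(function(q, s) is.null(q) || length(q) == nchar(s),
                 qual, seq)
    if (!all(ok)) {
      stop("quality length mismatch for record(s): ",
           paste(head(id[!ok], 3L), collapse = ", "))
    }
  }
  out <- data.frame(id = id, seq = seq, stringsAsFactors = FALSE)
  out$qual <- qual
  out
}

normalise_dna <- function(x) {
  x <- toupper(as.character(x))
  gsub("U", "T", x, fixed = TRUE)
}

#' Read sequences from FASTA or FASTQ
#'
#' Wraps [Biostrings::readDNAStringSet()] with strict validation.  Record
#' order is preserved, lowercase bases are normalised to uppercase and `U`
#' is mapped to `T`.  FASTQ quality strings are decoded as Phred+33; a
#' quality string whose length differs from its sequence is an error.
#'
#' @param path Path to the file.
#' @param format `"fasta"` or `"fastq"`.
#' @return A sequence-record table (see [seq_records()]).
#' @export
read_sequences <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "fastq") {
    validate_fastq_layout(path)
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    quals <- as(Biostrings::PhredQuality(S4Vectors::mcols(x)$qualities),
                "IntegerList")
    qual <- as.list(quals)
  } else {
    x <- Biostrings::readDNAStringSet(path, format = "fasta")
    qual <- NULL
  }
  ids <- sub("\\s.*$", "", names(x))
  seq_records(ids, as.character(x), qual)
}

# Biostrings tolerates some malformed FASTQ; pre-check the 4-line layout so
# errors can name the offending line.
validate_fastq_layout <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ (line count not a multiple of 4): ", path)
  }
  n <- length(lines) %/% 4L
  for (i in seq_len(n)) {
    base <- (i - 1L) * 4L
    if (!startsWith(lines[base + 1L], "@")) {
      stop("malformed FASTQ header at line ", base + 1L)
    }
    if (!startsWith(lines[base + 3L], "+")) {
      stop("malformed FASTQ separator at line ", base + 3L)
    }
    if (nchar(lines[base + 2L]) != nchar(lines[base + 4L])) {
      stop("FASTQ quality/sequence length mismatch at line ", base + 4L)
    }
  }
  invisible(TRUE)
}

#' Write sequences to FASTA or FASTQ
#'
#' @param records A sequence-record table.
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"`; FASTQ requires qualities on every
#'   record.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(records, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- Biostrings::DNAStringSet(records$seq)
  names(x) <- records$id
  if (format == "fastq") {
    if (any(vapply(records$qual, is.null, logical(1L)))) {
      stop("FASTQ output requires qualities on every record")
    }
    qtxt <- vapply(records$qual, function(q) {
      as.character(Biostrings::PhredQuality(as.integer(q)))
    }, character(1L))
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(qtxt))
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta")
  }
  invisible(path)
}

#' Read a T-RFLP peak table
#'
#' Expects a CSV with columns `sample`, `enzyme`, `size_bp`, `area`.
#' Duplicate (sample, enzyme, size) rows are summed.  Non-positive sizes or
#' negative areas are errors.
#'
#' @param path CSV path.
#' @return A `data.frame` of peaks grouped by (sample, enzyme), ordered by
#'   sample, enzyme, size.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("empty peak table: ", path)
    return(data.frame(sample = character(), enzyme = character(),
                      size_bp = numeric(), area = numeric()))
  }
  need <- c("sample", "enzyme", "size_bp", "area")
  if (!all(need %in% names(df))) {
    stop("peak table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(df$size_bp)) || any(df$size_bp <= 0)) {
    stop("peak sizes must be positive")
  }
  if (any(!is.finite(df$area)) || any(df$area < 0)) {
    stop("peak areas must be non-negative")
  }
  agg <- stats::aggregate(area ~ sample + enzyme + size_bp, data = df, FUN = sum)
  agg <- agg[order(agg$sample, agg$enzyme, agg$size_bp), ]
  rownames(agg) <- NULL
  agg[, c("sample", "enzyme", "size_bp", "area")]
}

#' Write an ultrametric dendrogram as newick
#'
#' Serialises a tree produced by [upgma()] (a nested merge structure with
#' node heights) to a newick string with branch lengths equal to parent
#' height minus child height.  A negative branch length (non-ultrametric
#' input) is an error.
#'
#' @param tree A `rumen_dendro` object from [upgma()], or a single leaf
#'   label.
#' @param path Optional path; when given the string is also written to file.
#' @return The newick string.
#' @export
write_dendrogram <- function(tree, path = NULL) {
  nwk <- paste0(newick_node(tree, parent_height = NULL), ";")
  if (!is.null(path)) writeLines(nwk, path)
  nwk
}

newick_node <- function(node, parent_height) {
  if (is.character(node)) {            # bare leaf (single-sample tree)
    return(node)
  }
  if (!is.null(node$leaf)) {
    if (is.null(parent_height)) return(node$leaf)
    return(paste0(node$leaf, ":", format_bl(parent_height)))
  }
  kids <- vapply(node$children, newick_node, character(1L),
                 parent_height = node$height)
  inner <- paste0("(", paste(kids, collapse = ","), ")")
  if (is.null(parent_height)) return(inner)
  bl <- parent_height - node$height
  paste0(inner, ":", format_bl(bl))
}

format_bl <- function(bl) {
  if (bl < -1e-12) stop("negative branch length: tree is not ultrametric")
  format(max(bl, 0), scientific = FALSE, trim = TRUE)
}

#' Assemble an abundance table
#'
#' Samples-by-taxa numeric matrix with an attached unit tag.  Proportion
#' tables must have rows summing to one.
#'
#' @param mat Numeric matrix, rows = samples, columns = taxa/OTUs/TRF bins.
#' @param unit One of `"count"`, `"area"`, `"proportion"`.
#' @return The matrix with attribute `unit` and class `abundance_table`.
#' @export
abundance_table <- function(mat, unit = c("count", "area", "proportion")) {
  unit <- match.arg(unit)
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("abundance table cells must be non-negative")
  if (unit == "proportion") {
    rs <- rowSums(mat)
    if (any(abs(rs - 1) > 1e-9)) {
      stop("proportion rows must sum to 1 (max deviation ",
           format(max(abs(rs - 1))), ")")
    }
  }
  structure(mat, unit = unit, class = c("abundance_table", "matrix", "array"))
}
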