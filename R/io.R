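# TSV dialect used throughout: tab-separated, UTF-8, '#' comment lines ignored,
# no quoting. Fixing the dialect makes parse -> serialise -> parse the identity.

read_tsv_strict <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    quote = "", check.names = FALSE, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}

write_tsv_strict <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a gene-by-sample count matrix
#'
#' Checks the invariants of the count container used across the pipeline:
#' unique gene and sample labels, non-negative numeric values, dimensions
#' consistent with the label sets.
#'
#' @param counts Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @return The matrix, invisibly, if valid; otherwise an error naming the
#'   offending label or cell.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene ids as rownames and sample ids as colnames")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  if (anyNA(counts))
    stop("counts contain missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count for gene '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  invisible(counts)
}

#' Read a gene-by-sample count table
#'
#' The file is tab-separated with a header row of sample ids and gene ids in
#' the first column. Row and column order are preserved.
#'
#' @param path Path to the TSV file.
#' @return A validated numeric matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- read_tsv_strict(path)
  if (ncol(df) < 2)
    stop("count table needs a gene id column plus at least one sample column")
  genes <- as.character(df[[1]])
  sample_ids <- names(df)[-1]   # keep verbatim: subsetting repairs duplicates
  vals <- df[-1]
  non_num <- !vapply(vals, is.numeric, logical(1))
  if (any(non_num))
    stop("non-numeric count column(s): ",
         paste(sample_ids[non_num], collapse = ", "))
  m <- as.matrix(vals)
  dimnames(m) <- list(genes, sample_ids)
  validate_counts(m)
  m
}

#' Write a count matrix in the canonical tab-separated layout
#'
#' @param counts Validated count matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_strict(df, path)
}

#' Read and validate a sample sheet
#'
#' The sheet has columns \code{sample_id}, \code{condition} (\code{case} or
#' \code{control}), \code{fraction} (\code{total} or \code{polysomal}) and
#' \code{replicate} (positive integer). Each (condition, fraction, replicate)
#' triple must be unique and every condition-by-fraction cell must hold at
#' least one replicate.
#'
#' @param path Path to the TSV file.
#' @param counts Optional count matrix to cross-validate against: every count
#'   column must appear exactly once in the sheet and vice versa.
#' @return A data.frame with the four validated columns.
#' @export
read_sample_sheet <- function(path, counts = NULL) {
  df <- read_tsv_strict(path)
  need <- c("sample_id", "condition", "fraction", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  df$sample_id <- as.character(df$sample_id)
  df$condition <- as.character(df$condition)
  df$fraction <- as.character(df$fraction)
  validate_sample_sheet(df, counts)
}

#' Validate a sample sheet against the shared vocabulary
#'
#' @param sheet Data.frame with sample_id, condition, fraction, replicate.
#' @param counts Optional count matrix for cross-validation.
#' @return The validated sheet (replicate coerced to integer).
#' @export
validate_sample_sheet <- function(sheet, counts = NULL) {
  bad <- setdiff(unique(sheet$condition), c("case", "control"))
  if (length(bad))
    stop("unknown condition token(s): ", paste(bad, collapse = ", "),
         " (vocabulary: case, control)")
  bad <- setdiff(unique(sheet$fraction), c("total", "polysomal"))
  if (length(bad))
    stop("unknown fraction token(s): ", paste(bad, collapse = ", "),
         " (vocabulary: total, polysomal)")
  rep_num <- suppressWarnings(as.integer(sheet$replicate))
  if (anyNA(rep_num) || any(rep_num < 1))
    stop("replicate must be a positive integer for every sample")
  sheet$replicate <- rep_num
  dup <- duplicated(sheet$sample_id)
  if (any(dup))
    stop("duplicate sample id(s): ",
         paste(unique(sheet$sample_id[dup]), collapse = ", "))
  key <- paste(sheet$condition, sheet$fraction, sheet$replicate)
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate (condition, fraction, replicate) triple(s): ",
         paste(unique(key[dup]), collapse = "; "))
  cells <- table(sheet$condition, sheet$fraction)
  if (!all(dim(cells) == c(2, 2)) || any(cells < 1))
    stop("every condition x fraction cell needs at least one replicate")
  if (!is.null(counts)) {
    miss <- setdiff(colnames(counts), sheet$sample_id)
    if (length(miss))
      stop("count matrix sample(s) absent from sheet: ",
           paste(miss, collapse = ", "))
    miss <- setdiff(sheet$sample_id, colnames(counts))
    if (length(miss))
      stop("sheet sample(s) absent from count matrix: ",
           paste(miss, collapse = ", "))
  }
  sheet
}

#' Write a sample sheet
#' @param sheet Validated sample sheet.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  write_tsv_strict(sheet[c("sample_id", "condition", "fraction", "replicate")],
                   path)
}

# Canonicalise a nucleotide string: uppercase DNA, U -> T. The annotation
# mixes RNA (AUG) and DNA (ATG) alphabets; internally everything is DNA.
canonical_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Validate transcript records
#'
#' A transcript record carries \code{transcript_id}, \code{gene_id},
#' \code{tss_id}, a 0-based \code{cds_start} and the transcript
#' \code{sequence} (5' to 3'). The triplet at \code{cds_start} must be ATG;
#' the transcript leader is \code{sequence[0, cds_start)}, half-open.
#'
#' @param records Data.frame with the five columns above.
#' @return The records with canonicalised (uppercase DNA) sequences.
#' @export
validate_transcripts <- function(records) {
  need <- c("transcript_id", "gene_id", "tss_id", "cds_start", "sequence")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("transcript table missing column(s): ", paste(miss, collapse = ", "))
  dup <- records$transcript_id[duplicated(records$transcript_id)]
  if (length(dup))
    stop("duplicate transcript id(s): ", paste(unique(dup), collapse = ", "))
  records$sequence <- canonical_dna(records$sequence)
  records$cds_start <- as.integer(records$cds_start)
  len <- nchar(records$sequence)
  bad <- which(is.na(records$cds_start) | records$cds_start < 0 |
                 records$cds_start > len - 3L)
  if (length(bad))
    stop("cds_start out of bounds for transcript(s): ",
         paste(records$transcript_id[bad], collapse = ", "))
  start_codon <- substr(records$sequence, records$cds_start + 1L,
                        records$cds_start + 3L)
  bad <- which(start_codon != "ATG")
  if (length(bad))
    stop("triplet at cds_start is not ATG for transcript(s): ",
         paste(records$transcript_id[bad], collapse = ", "))
  records
}

#' Read transcript sequences and coordinates
#'
#' Joins a FASTA file of transcript sequences with a tab-separated table of
#' columns \code{transcript_id}, \code{gene_id}, \code{tss_id},
#' \code{cds_start} (0-based offset of the first base of the principal ATG).
#' Sequences are canonicalised to uppercase DNA (U mapped to T).
#'
#' @param fasta Path to the FASTA file.
#' @param table Path to the transcript table (TSV).
#' @return A validated data.frame of transcript records, in table order.
#' @export
read_transcript_table <- function(fasta, table) {
  # BStringSet: the raw alphabet may be RNA or lowercase; canonicalised below
  seqs <- Biostrings::readBStringSet(fasta)
  tab <- read_tsv_strict(table)
  need <- c("transcript_id", "gene_id", "tss_id", "cds_start")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("transcript table missing column(s): ", paste(miss, collapse = ", "))
  # FASTA headers may carry descriptions after the id
  fasta_ids <- sub("\\s.*$", "", names(seqs))
  idx <- match(as.character(tab$transcript_id), fasta_ids)
  if (anyNA(idx))
    stop("no FASTA sequence for transcript(s): ",
         paste(tab$transcript_id[is.na(idx)], collapse = ", "))
  records <- data.frame(
    transcript_id = as.character(tab$transcript_id),
    gene_id = as.character(tab$gene_id),
    tss_id = as.character(tab$tss_id),
    cds_start = as.integer(tab$cds_start),
    sequence = as.character(seqs[idx]),
    stringsAsFactors = FALSE
  )
  validate_transcripts(records)
}

#' Write transcript records as FASTA plus table
#'
#' @param records Validated transcript records.
#' @param fasta Output FASTA path.
#' @param table Output TSV path.
#' @return Invisibly, a list of the two paths.
#' @export
write_transcript_table <- function(records, fasta, table) {
  records <- validate_transcripts(records)
  seqs <- Biostrings::DNAStringSet(records$sequence)
  names(seqs) <- records$transcript_id
  Biostrings::writeXStringSet(seqs, fasta, width = 70L)
  write_tsv_strict(records[c("transcript_id", "gene_id", "tss_id",
                             "cds_start")], table)
  invisible(list(fasta = fasta, table = table))
}
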