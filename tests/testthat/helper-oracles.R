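# Independent brute-force oracles and fixture builders shared by the tests.
# These deliberately avoid the package's own code paths.

STOPS <- c("TAA", "TAG", "TGA")

# Brute-force uORF scanner: check every offset for ATG by substring
# comparison, then translate codon-by-codon with explicit indices.
brute_force_uorfs <- function(sequence, cds_start) {
  rows <- list()
  if (cds_start >= 3) {
    for (i in 0:(cds_start - 3)) {
      if (substr(sequence, i + 1, i + 3) != "ATG") next
      frame <- ((i - cds_start) %% 3 + 3) %% 3
      stop_pos <- NA
      j <- i
      while (j + 3 <= nchar(sequence)) {
        if (substr(sequence, j + 1, j + 3) %in% STOPS) { stop_pos <- j; break }
        j <- j + 3
      }
      stop_end <- if (is.na(stop_pos)) NA else stop_pos + 3
      if (!is.na(stop_end) && stop_end <= cds_start) {
        cls <- "upstream"
        n_cod <- (stop_pos - i) / 3
        gap <- cds_start - stop_end
      } else if (frame == 0) {
        cls <- "in_frame_extension"; n_cod <- NA; gap <- NA
      } else {
        cls <- "overlapping"
        n_cod <- if (is.na(stop_pos)) NA else (stop_pos - i) / 3
        gap <- NA
      }
      rows[[length(rows) + 1]] <- data.frame(
        start = i, frame = frame, orf_class = cls,
        n_codons = as.integer(n_cod), stop_end = as.integer(stop_end),
        gap_to_main = as.integer(gap), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0), frame = integer(0),
                      orf_class = character(0), n_codons = integer(0),
                      stop_end = integer(0), gap_to_main = integer(0)))
  do.call(rbind, rows)
}

# Fully random transcript with an ATG forced at a random cds_start.
random_transcript <- function(id, max_len = 500, gc_range = c(0.25, 0.75)) {
  gc <- runif(1, gc_range[1], gc_range[2])
  len <- sample(30:max_len, 1)
  bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  cds_start <- sample(0:(len - 3), 1)
  bases[cds_start + 1:3] <- c("A", "T", "G")
  data.frame(transcript_id = id, gene_id = id, tss_id = id,
             cds_start = cds_start, sequence = paste(bases, collapse = ""),
             stringsAsFactors = FALSE)
}

# Minimal 2x2x{reps} study fixture with hand-settable counts.
make_sheet <- function(reps = 3) {
  g <- expand.grid(replicate = seq_len(reps),
                   fraction = c("total", "polysomal"),
                   condition = c("case", "control"),
                   stringsAsFactors = FALSE)
  g$sample_id <- sprintf("%s_%s_%d", g$condition, g$fraction, g$replicate)
  g[c("sample_id", "condition", "fraction", "replicate")]
}

# Rank-statistic AUROC, independent of any package code.
rank_auc <- function(score, positive) {
  r <- rank(score)
  (mean(r[positive]) - (sum(positive) + 1) / 2) / sum(!positive)
}

swap_conditions <- function(sheet) {
  sheet$condition <- ifelse(sheet$condition == "case", "control", "case")
  sheet
}
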