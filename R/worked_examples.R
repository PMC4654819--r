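# Deterministic ATG-free filler: "CTT" repeated contains no adenine, so it
# can never take part in an ATG triplet, and "CTT" is a sense codon in every
# frame. Used to realise reference TL architectures exactly.
ctt_filler <- function(n) {
  if (n == 0L) return("")
  substr(strrep("CTT", ceiling(n / 3) + 1L), 1L, n)
}

uorf_block <- function(n_codons) {
  paste0("ATG", strrep("CTT", n_codons - 1L), "TAA")
}

#' Synthetic reference transcript-leader architectures
#'
#' Five constructed transcripts realising well-characterised human TL
#' architectures reported for breast-cell TSS variants, built on
#' deterministic ATG-free backgrounds so that each leader contains exactly
#' the features listed and nothing else. These are synthetic stand-ins, not
#' the RefSeq sequences: the uORF geometry (codon counts, spacings, cap
#' distances, Kozak context of the main start where reported) matches the
#' published architecture, while background bases are filler.
#'
#' \describe{
#'   \item{s53bp1_v3_synthetic}{a 5-codon uORF ending 15 nt upstream of the
#'     main AUG.}
#'   \item{wnt5b_v1_synthetic}{two short uORFs (1 codon — a uAUG followed
#'     immediately by a stop — and 3 codons), the second ending 62 nt
#'     upstream of a main AUG in an ACCAUGC context.}
#'   \item{wnt5b_v2_synthetic}{a single 6-codon uORF whose uAUG sits 12 nt
#'     from the 5' cap.}
#'   \item{cldn7_v1_3_synthetic}{a 902-nt leader with no uAUG at all.}
#'   \item{cldn7_v2_synthetic}{a short leader carrying a 50-codon uORF.}
#' }
#'
#' @return A validated transcript-record data.frame (5 rows).
#' @export
tl_reference_architectures <- function() {
  main_orf <- paste0("ATG", strrep("CTT", 10L), "TAA")
  tl <- list(
    s53bp1_v3_synthetic = paste0(ctt_filler(30L), uorf_block(5L),
                                 ctt_filler(15L)),
    wnt5b_v1_synthetic = paste0(ctt_filler(20L), uorf_block(1L),
                                ctt_filler(10L), uorf_block(3L),
                                ctt_filler(59L), "ACC"),
    wnt5b_v2_synthetic = paste0(ctt_filler(12L), uorf_block(6L),
                                ctt_filler(24L)),
    cldn7_v1_3_synthetic = ctt_filler(902L),
    cldn7_v2_synthetic = paste0(ctt_filler(20L), uorf_block(50L),
                                ctt_filler(30L))
  )
  genes <- c("S53BP1_SYN", "WNT5B_SYN", "WNT5B_SYN", "CLDN7_SYN",
             "CLDN7_SYN")
  tss <- c("tssA", "tssB", "tssC", "tssD", "tssE")
  records <- data.frame(
    transcript_id = names(tl),
    gene_id = genes,
    tss_id = tss,
    cds_start = vapply(tl, nchar, integer(1)),
    sequence = paste0(unlist(tl), main_orf),
    row.names = NULL, stringsAsFactors = FALSE
  )
  validate_transcripts(records)
}
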