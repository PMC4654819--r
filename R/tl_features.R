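STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Extract the 5' transcript leader
#'
#' The transcript leader (TL) is the region 5' of the principal start codon:
#' \code{sequence[0, cds_start)}, half-open, 0-based. An empty TL
#' (\code{cds_start = 0}) is valid.
#'
#' @param record A single transcript record (one row of a validated
#'   transcript table, or a list with \code{sequence} and \code{cds_start}).
#' @return The TL nucleotide string.
#' @export
extract_tl <- function(record) {
  substr(record$sequence, 1L, record$cds_start)
}

#' Find upstream AUG positions in a transcript leader
#'
#' Returns every 0-based offset at which the triplet ATG occurs, including
#' overlapping occurrences.
#'
#' @param tl TL nucleotide string in the canonical uppercase-DNA alphabet.
#' @return Strictly increasing integer vector of 0-based positions.
#' @export
scan_uaugs <- function(tl) {
  if (nchar(tl) < 3L) return(integer(0))
  hits <- gregexpr("(?=ATG)", tl, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

# First in-frame stop codon at or after 0-based position `from`, scanning the
# full transcript. Returns the 0-based offset of the stop's first base, or NA.
first_inframe_stop <- function(sequence, from) {
  len <- nchar(sequence)
  pos <- from
  while (pos + 3L <= len) {
    if (substr(sequence, pos + 1L, pos + 3L) %in% STOP_CODONS)
      return(pos)
    pos <- pos + 3L
  }
  NA_integer_
}

#' Enumerate upstream open reading frames
#'
#' For each upstream AUG the reading frame is translated forward through the
#' full transcript until the first stop codon (TAA/TAG/TGA), and the putative
#' uORF is classified:
#' \describe{
#'   \item{upstream}{terminates at or before the principal start
#'     (\code{stop_end <= cds_start}); a classical uORF.}
#'   \item{in_frame_extension}{in frame 0 with no in-frame stop before the
#'     principal start — initiation here yields an N-terminally extended
#'     protein sharing the main ORF.}
#'   \item{overlapping}{out of frame with its first stop (if any) at or
#'     beyond the principal start — an internal ORF overlapping the 5' end
#'     of the coding sequence.}
#' }
#' \code{n_codons} counts sense codons including the initiator ATG and
#' excluding the stop; it is NA when no independent stop exists (in-frame
#' extensions, and overlapping ORFs running off the 3' end).
#' \code{gap_to_main}, defined for upstream uORFs only, is the number of
#' nucleotides strictly between the stop codon and the principal ATG.
#'
#' @param record A single validated transcript record.
#' @return Data.frame with one row per upstream AUG: \code{transcript_id},
#'   \code{start}, \code{frame}, \code{orf_class}, \code{n_codons},
#'   \code{stop_end}, \code{gap_to_main}, \code{cap_distance},
#'   \code{kozak_class}, \code{context}. All coordinates 0-based.
#' @export
enumerate_uorfs <- function(record) {
  tl <- extract_tl(record)
  starts <- scan_uaugs(tl)
  n <- length(starts)
  out <- data.frame(
    transcript_id = rep(record$transcript_id, n),
    start = starts,
    frame = (starts - record$cds_start) %% 3L,
    orf_class = character(n),
    n_codons = rep(NA_integer_, n),
    stop_end = rep(NA_integer_, n),
    gap_to_main = rep(NA_integer_, n),
    cap_distance = starts,
    kozak_class = character(n),
    context = character(n),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    s <- starts[i]
    stop_pos <- first_inframe_stop(record$sequence, s)
    stop_end <- if (is.na(stop_pos)) NA_integer_ else stop_pos + 3L
    if (!is.na(stop_end) && stop_end <= record$cds_start) {
      out$orf_class[i] <- "upstream"
      out$n_codons[i] <- (stop_pos - s) %/% 3L
      out$stop_end[i] <- stop_end
      out$gap_to_main[i] <- record$cds_start - stop_end
    } else if (out$frame[i] == 0L) {
      out$orf_class[i] <- "in_frame_extension"
      out$stop_end[i] <- stop_end
    } else {
      out$orf_class[i] <- "overlapping"
      out$stop_end[i] <- stop_end
      if (!is.na(stop_pos)) out$n_codons[i] <- (stop_pos - s) %/% 3L
    }
    kz <- classify_kozak(record$sequence, s)
    out$kozak_class[i] <- kz$class
    out$context[i] <- kz$context
  }
  out
}

#' Classify the Kozak context of an AUG
#'
#' Initiation efficiency is governed mainly by the bases at positions -3 and
#' +4 around the AUG (A of the AUG = +1): the ideal context is
#' (A/G)CC\strong{AUG}G. The class is \code{strong} when both a purine at -3
#' and G at +4 hold, \code{moderate} when exactly one holds, \code{weak} when
#' neither. Positions beyond the sequence ends are padded with N, which
#' satisfies neither criterion.
#'
#' @param sequence Transcript sequence (canonical uppercase DNA).
#' @param aug_pos 0-based offset of an ATG triplet.
#' @return List with \code{class} and \code{context} (the 7-mer from -3 to
#'   +4, N-padded at the edges).
#' @export
classify_kozak <- function(sequence, aug_pos) {
  if (substr(sequence, aug_pos + 1L, aug_pos + 3L) != "ATG")
    stop(sprintf("no ATG at position %d", aug_pos))
  len <- nchar(sequence)
  base_at <- function(pos0) {  # 0-based; N outside [0, len)
    if (pos0 < 0L || pos0 >= len) "N" else substr(sequence, pos0 + 1L, pos0 + 1L)
  }
  context <- paste(vapply((aug_pos - 3L):(aug_pos + 3L), base_at,
                          character(1)), collapse = "")
  minus3 <- base_at(aug_pos - 3L) %in% c("A", "G")
  plus4 <- base_at(aug_pos + 3L) == "G"
  class <- if (minus3 && plus4) "strong" else if (minus3 || plus4) "moderate" else "weak"
  list(class = class, context = context)
}

#' Annotate one transcript's 5' leader
#'
#' Assembles the full TL report for a transcript: leader length, upstream AUG
#' positions, uORF records, the Kozak context of the principal start, and
#' flags for cap-proximal upstream AUGs. An AUG closer to the 5' cap than
#' \code{cap_threshold} nucleotides is unlikely to be recognised by the
#' scanning 43S subunit and is flagged.
#'
#' @param record A single validated transcript record.
#' @param cap_threshold Upstream AUGs with cap distance strictly below this
#'   are flagged cap-proximal (default 15 nt).
#' @return List of class \code{tl_annotation}: \code{transcript_id},
#'   \code{tl_length}, \code{uaug_positions}, \code{uorfs} (data.frame from
#'   \code{\link{enumerate_uorfs}}), \code{main_kozak},
#'   \code{cap_proximal} (0-based positions of flagged uAUGs).
#' @export
annotate_transcript <- function(record, cap_threshold = 15L) {
  uorfs <- enumerate_uorfs(record)
  structure(list(
    transcript_id = record$transcript_id,
    tl_length = record$cds_start,
    uaug_positions = uorfs$start,
    uorfs = uorfs,
    main_kozak = classify_kozak(record$sequence, record$cds_start),
    cap_proximal = uorfs$start[uorfs$cap_distance < cap_threshold]
  ), class = "tl_annotation")
}

#' Annotate a transcript table
#'
#' Batch version of \code{\link{annotate_transcript}} producing report
#' tables.
#'
#' @param records Validated transcript records.
#' @param cap_threshold Cap-proximity flag threshold in nucleotides.
#' @return List with \code{transcripts} (one summary row per transcript:
#'   \code{transcript_id}, \code{gene_id}, \code{tl_length}, \code{n_uaugs},
#'   \code{n_uorfs_upstream}, \code{n_cap_proximal}, \code{main_kozak_class},
#'   \code{main_kozak_context}) and \code{uorfs} (one row per upstream AUG,
#'   0-based coordinates; see \code{\link{enumerate_uorfs}}, plus a
#'   \code{cap_proximal} flag).
#' @export
annotate_transcripts <- function(records, cap_threshold = 15L) {
  anns <- lapply(seq_len(nrow(records)), function(i)
    annotate_transcript(records[i, ], cap_threshold))
  uorfs <- do.call(rbind, lapply(anns, `[[`, "uorfs"))
  uorfs$cap_proximal <- uorfs$cap_distance < cap_threshold
  transcripts <- data.frame(
    transcript_id = records$transcript_id,
    gene_id = records$gene_id,
    tl_length = records$cds_start,
    n_uaugs = vapply(anns, function(a) length(a$uaug_positions), integer(1)),
    n_uorfs_upstream = vapply(anns, function(a)
      sum(a$uorfs$orf_class == "upstream"), integer(1)),
    n_cap_proximal = vapply(anns, function(a) length(a$cap_proximal),
                            integer(1)),
    main_kozak_class = vapply(anns, function(a) a$main_kozak$class,
                              character(1)),
    main_kozak_context = vapply(anns, function(a) a$main_kozak$context,
                                character(1)),
    stringsAsFactors = FALSE
  )
  list(transcripts = transcripts, uorfs = uorfs)
}

#' @export
print.tl_annotation <- function(x, ...) {
  cat(sprintf("TL annotation for %s: leader %d nt, %d uAUG(s)\n",
              x$transcript_id, x$tl_length, length(x$uaug_positions)))
  cat(sprintf("  main start Kozak: %s (%s)\n",
              x$main_kozak$class, x$main_kozak$context))
  if (nrow(x$uorfs)) {
    for (i in seq_len(nrow(x$uorfs))) {
      u <- x$uorfs[i, ]
      cat(sprintf("  uAUG @%d (frame %d): %s%s%s%s\n", u$start, u$frame,
                  u$orf_class,
                  if (!is.na(u$n_codons)) sprintf(", %d codons", u$n_codons) else "",
                  if (!is.na(u$gap_to_main)) sprintf(", %d nt to main AUG", u$gap_to_main) else "",
                  if (u$start %in% x$cap_proximal) ", cap-proximal" else ""))
    }
  }
  invisible(x)
}
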