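rec <- function(sequence, cds_start, id = "t") {
  data.frame(transcript_id = id, gene_id = id, tss_id = id,
             cds_start = as.integer(cds_start), sequence = sequence,
             stringsAsFactors = FALSE)
}

test_that("TL extraction is the half-open prefix before the start codon", {
  expect_identical(extract_tl(rec("ATGAAATAA", 0)), "")
  expect_identical(extract_tl(rec("GGGATGAAATAA", 3)), "GGG")
  withr::local_seed(30)
  for (i in 1:20) {
    r <- random_transcript(sprintf("t%d", i))
    expect_identical(nchar(extract_tl(r)), r$cds_start)
  }
})

test_that("uAUG scan finds all occurrences, overlapping included", {
  expect_identical(scan_uaugs("ATGATG"), c(0L, 3L))
  expect_identical(scan_uaugs("CCCCCC"), integer(0))
  expect_identical(scan_uaugs("ATATGG"), 2L)
  expect_identical(scan_uaugs("AT"), integer(0))
  withr::local_seed(31)
  for (i in 1:200) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
    brute <- which(vapply(1:58, function(j)
      substr(s, j, j + 2) == "ATG", logical(1))) - 1L
    expect_identical(scan_uaugs(s), as.integer(brute))
  }
})

test_that("uORF enumeration handles the canonical class cases", {
  # TL "ATGAAATAG" then main ORF: upstream uORF of 2 codons, gap 0
  u <- enumerate_uorfs(rec("ATGAAATAGATGCCCTAA", 9))
  expect_identical(u$orf_class, "upstream")
  expect_identical(u$n_codons, 2L)
  expect_identical(u$gap_to_main, 0L)
  expect_identical(u$stop_end, 9L)
  # frame-0 uAUG with no stop before the main start: N-terminal extension
  u <- enumerate_uorfs(rec("ATGGGGATGCCCTAA", 6))
  expect_identical(u$orf_class, "in_frame_extension")
  expect_true(is.na(u$n_codons))
  # out-of-frame uAUG terminating inside the CDS: overlapping internal ORF
  u <- enumerate_uorfs(rec("CATGCATGCCTAA", 5))
  expect_identical(u$orf_class, "overlapping")
  expect_identical(u$frame, 2L)
  expect_identical(u$n_codons, 3L)  # ATG CAT GCC, stop TAA at offset 10
  expect_identical(u$stop_end, 13L)
  # out-of-frame uAUG with no stop anywhere: overlapping, n_codons undefined
  u <- enumerate_uorfs(rec("CATGCATGCCCCCCCC", 5))
  expect_identical(u$orf_class, "overlapping")
  expect_true(is.na(u$n_codons))
})

test_that("Kozak classification follows the -3 purine / +4 G rule", {
  expect_identical(classify_kozak("GCCATGG", 3)$class, "strong")
  expect_identical(classify_kozak("GCCATGG", 3)$context, "GCCATGG")
  expect_identical(classify_kozak("ACCATGC", 3)$class, "moderate")
  expect_identical(classify_kozak("TTTATGT", 3)$class, "weak")
  expect_identical(classify_kozak("TCCATGG", 3)$class, "moderate")
  # edge padding with N satisfies neither criterion
  k <- classify_kozak("ATGG", 0)
  expect_identical(k$context, "NNNATGG")
  expect_identical(k$class, "moderate")  # only the +4 G holds
  expect_identical(classify_kozak("ATG", 0)$class, "weak")
  expect_error(classify_kozak("GCCAAGG", 3), "no ATG")
})

test_that("cap-proximal uAUGs are flagged below the threshold", {
  # uAUG 12 nt from the cap: too close for efficient 43S recognition
  r <- rec(paste0(strrep("CTT", 4), "ATGTAA", strrep("CTT", 5), "ATGCCCTAA"),
           12 + 6 + 15)
  a <- annotate_transcript(r, cap_threshold = 15)
  expect_identical(a$cap_proximal, 12L)
  a2 <- annotate_transcript(r, cap_threshold = 12)
  expect_identical(a2$cap_proximal, integer(0))
  # empty TL: no uAUGs, main Kozak still reported
  a3 <- annotate_transcript(rec("ATGCCCTAA", 0))
  expect_identical(a3$tl_length, 0L)
  expect_identical(length(a3$uaug_positions), 0L)
  expect_identical(a3$main_kozak$class, "weak")  # N at -3, C at +4
  expect_identical(a3$main_kozak$context, "NNNATGC")
})

test_that("scanner equals the brute-force translator on random transcripts", {
  withr::local_seed(33)
  cols <- c("start", "frame", "orf_class", "n_codons", "stop_end",
            "gap_to_main")
  for (i in 1:300) {
    r <- random_transcript(sprintf("t%04d", i), max_len = 300)
    got <- enumerate_uorfs(r)[cols]
    want <- brute_force_uorfs(r$sequence, r$cds_start)[cols]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = r$sequence)
  }
})

test_that("every uAUG gets exactly one record and one class", {
  withr::local_seed(34)
  for (i in 1:50) {
    r <- random_transcript(sprintf("t%d", i))
    u <- enumerate_uorfs(r)
    expect_identical(u$start, scan_uaugs(extract_tl(r)))
    expect_true(all(u$orf_class %in%
                      c("upstream", "overlapping", "in_frame_extension")))
    up <- u[u$orf_class == "upstream", ]
    expect_true(all(up$stop_end <= r$cds_start))
    expect_true(all(up$gap_to_main == r$cds_start - up$stop_end))
    ife <- u[u$orf_class == "in_frame_extension", ]
    expect_true(all(ife$frame == 0L))
  }
})

test_that("appending 3' sequence never changes TL-level fields", {
  withr::local_seed(35)
  for (i in 1:25) {
    r <- random_transcript(sprintf("t%d", i), max_len = 200)
    r2 <- r
    r2$sequence <- paste0(r$sequence, "GATTACAGATTACA")
    a1 <- annotate_transcript(r)
    a2 <- annotate_transcript(r2)
    expect_identical(a1$tl_length, a2$tl_length)
    expect_identical(a1$uaug_positions, a2$uaug_positions)
    expect_identical(a1$uorfs$orf_class[a1$uorfs$orf_class == "upstream"],
                     a2$uorfs$orf_class[a2$uorfs$orf_class == "upstream"])
  }
})
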