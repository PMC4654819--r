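test_that("identical spec and seed reproduce the dataset bit-for-bit", {
  spec <- sim_spec(n_genes = 300, n_transcripts = 20, n_usage_genes = 15,
                   seed = 99)
  d1 <- simulate_dataset(spec)
  d2 <- simulate_dataset(spec)
  expect_identical(d1$counts$counts, d2$counts$counts)
  expect_identical(d1$transcripts$records, d2$transcripts$records)
  expect_identical(d1$usage$abundances, d2$usage$abundances)
  # a different seed changes the draws
  d3 <- simulate_counts(sim_spec(n_genes = 300, seed = 100))
  expect_false(identical(d1$counts$counts, d3$counts))
})

test_that("component streams are independent of each other", {
  # drawing the transcripts must not shift the count stream
  spec <- sim_spec(n_genes = 200, n_transcripts = 10, seed = 55)
  lone <- simulate_counts(spec)
  invisible(simulate_transcripts(spec))
  again <- simulate_counts(spec)
  expect_identical(lone$counts, again$counts)
})

test_that("planted TE effects follow the spec and are absent when disabled", {
  none <- simulate_counts(sim_spec(n_genes = 500, fraction_regulated = 0,
                                   seed = 13))
  expect_identical(sum(none$truth$regulated), 0L)
  some <- simulate_counts(sim_spec(n_genes = 500, fraction_regulated = 0.1,
                                   effect_size = 1.5, seed = 13))
  expect_identical(sum(some$truth$regulated), 50L)
  expect_true(all(abs(some$truth$true_delta[some$truth$regulated]) == 1.5))
  expect_true(all(some$truth$true_delta[!some$truth$regulated] == 0))
  floored <- simulate_counts(sim_spec(n_genes = 500,
                                      fraction_regulated = 0.05,
                                      regulated_min_mean = 50, seed = 13))
  expect_true(all(floored$truth$baseline[floored$truth$regulated] >= 50))
})

test_that("phi -> 0 gives Poisson-like counts; observed TE matches planted", {
  # variance ~ mean at zero dispersion, checked over many genes at one mean
  sim <- simulate_counts(sim_spec(n_genes = 4000, replicates = 3, phi = 0,
                                  baseline_log2_mean = 6,
                                  baseline_log2_sd = 0,
                                  lib_factor_range = c(1, 1),
                                  fraction_regulated = 0, seed = 23))
  x <- as.vector(sim$counts[, sim$sheet$fraction == "total"])
  expect_lt(abs(var(x) / mean(x) - 1), 0.1)

  # mean observed log2 TE difference over regulated genes ~ planted effect
  sim2 <- simulate_counts(sim_spec(n_genes = 2000, fraction_regulated = 0.5,
                                   effect_size = 1, regulated_min_mean = 30,
                                   seed = 24))
  norm <- normalize_depth(sim2$counts, sim2$sheet)
  E <- filter_genes(summarize_expression(norm$counts, sim2$sheet))
  D <- compute_te_delta(E[E$analysable, ])
  D <- merge(D, sim2$truth, by = "gene_id")
  obs <- mean(D$delta[D$regulated] * D$direction[D$regulated])
  expect_lt(abs(obs - 1), 0.1)
})

test_that("planted transcript leaders contain exactly the planted features", {
  zero <- simulate_transcripts(sim_spec(n_transcripts = 10,
                                        uorf_count_range = c(0, 0),
                                        seed = 31))
  for (i in 1:10)
    expect_identical(
      length(annotate_transcript(zero$records[i, ])$uaug_positions), 0L)

  spec <- sim_spec(n_transcripts = 150, seed = 32)
  st <- simulate_transcripts(spec)
  got <- do.call(rbind, lapply(seq_len(nrow(st$records)), function(i)
    enumerate_uorfs(st$records[i, ])))
  got <- got[c("transcript_id", "start", "stop_end", "n_codons",
               "gap_to_main", "orf_class")]
  rownames(got) <- NULL
  expect_equal(got, st$truth, ignore_attr = TRUE)
  # leader lengths respect the spec range
  expect_true(all(st$records$cds_start >= spec$tl_length_range[1] &
                    st$records$cds_start <= spec$tl_length_range[2]))
})

test_that("infeasible uORF packing is rejected at spec validation", {
  expect_error(sim_spec(tl_length_range = c(10, 20),
                        uorf_count_range = c(3, 3), seed = 1),
               "infeasible packing")
  expect_error(sim_spec(n_genes = 100), "seed is mandatory")
})

test_that("usage truth is consistent and planted shifts are recoverable", {
  spec <- sim_spec(n_usage_genes = 120, seed = 44)
  su <- simulate_usage(spec)
  expect_identical(sum(su$truth$shifted),
                   as.integer(round(0.1 * 120)))
  # truth proportions parse back and sum to 1
  p <- lapply(strsplit(su$truth$p_total, ","), as.numeric)
  expect_true(all(abs(vapply(p, sum, numeric(1)) - 1) < 1e-6))
  # every planted shift clears the minimum-magnitude floor
  expect_true(all(su$truth$true_jsd[su$truth$shifted] >=
                    spec$usage_min_shift))
  expect_true(all(su$truth$true_jsd[!su$truth$shifted] == 0))
  # ranking genes by measured total-vs-polysomal JSD recovers the planted set
  u <- compute_usage(su$abundances, su$transcripts, su$sheet)
  m <- merge(u$divergence, su$truth, by = "gene_id")
  score <- (m$jsd_fraction_case + m$jsd_fraction_control) / 2
  expect_gt(rank_auc(score, m$shifted), 0.9)
})

test_that("written simulations read back into the same objects", {
  outdir <- withr::local_tempdir()
  sim <- simulate_dataset(sim_spec(n_genes = 120, n_transcripts = 12,
                                   n_usage_genes = 10, seed = 77))
  paths <- write_simulation(sim, outdir)
  expect_equal(read_counts(paths[["counts"]]), sim$counts$counts)
  expect_equal(read_sample_sheet(paths[["samples"]]), sim$counts$sheet,
               ignore_attr = TRUE)
  back <- read_transcript_table(paths[["fasta"]], paths[["table"]])
  expect_equal(back, sim$transcripts$records, ignore_attr = TRUE)
})
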