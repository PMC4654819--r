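test_that("JSD is symmetric, bounded and zero iff equal", {
  expect_equal(usage_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(usage_divergence(c(1, 0), c(0, 1)), 1)  # disjoint support
  withr::local_seed(40)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    p <- as.numeric(rmultinom(1, 1000, runif(k))) / 1000
    q <- as.numeric(rmultinom(1, 1000, runif(k))) / 1000
    d <- usage_divergence(p, q)
    expect_equal(d, usage_divergence(q, p))
    expect_gte(d, 0); expect_lte(d, 1)
    # direct-formula recomputation with explicit sums
    m <- (p + q) / 2
    kl <- function(a) sum(ifelse(a > 0, a * log2(a / m), 0))
    expect_equal(d, (kl(p) + kl(q)) / 2)
    expect_equal(usage_divergence(p, p), 0)
  }
  expect_error(usage_divergence(c(1, 0), c(1, 0, 0)), "length")
  expect_error(usage_divergence(c(0.7, 0.7), c(0.5, 0.5)), "sum to 1")
})

test_that("usage profiles pool transcripts by TSS and normalise per cell", {
  sheet <- make_sheet(2)
  tx <- data.frame(
    transcript_id = c("t1", "t2", "t3", "s1"),
    gene_id = c("gA", "gA", "gA", "gB"),
    tss_id = c("tssA1", "tssA1", "tssA2", "tssB1"),
    stringsAsFactors = FALSE)
  ab <- matrix(4, 4, 8, dimnames = list(tx$transcript_id, sheet$sample_id))
  u <- compute_usage(ab, tx, sheet)
  # single-TSS gene gB is excluded
  expect_false("gB" %in% u$usage$gene_id)
  # t1 + t2 share tssA1: abundance 8 vs 4, proportions 2/3 and 1/3
  cell <- u$usage[u$usage$condition == "case" & u$usage$fraction == "total", ]
  expect_equal(cell$proportion[cell$tss_id == "tssA1"], 2 / 3)
  expect_equal(cell$proportion[cell$tss_id == "tssA2"], 1 / 3)
  # equal fingerprints everywhere -> zero divergence
  expect_equal(u$divergence$jsd_fraction_case, 0)

  # zero gene total in one cell -> NA proportions there, NA divergence
  ab2 <- ab
  ab2[1:3, sheet$sample_id[sheet$condition == "case" &
                             sheet$fraction == "polysomal"]] <- 0
  u2 <- compute_usage(ab2, tx, sheet)
  na_cell <- u2$usage[u2$usage$condition == "case" &
                        u2$usage$fraction == "polysomal", ]
  expect_true(all(is.na(na_cell$proportion)))
  expect_true(is.na(u2$divergence$jsd_fraction_case))
  expect_false(is.na(u2$divergence$jsd_fraction_control))
})

test_that("usage proportions are invariant to common within-gene scaling", {
  su <- simulate_usage(sim_spec(n_usage_genes = 20, seed = 41))
  u1 <- compute_usage(su$abundances, su$transcripts, su$sheet)
  u2 <- compute_usage(su$abundances * 7, su$transcripts, su$sheet)
  expect_equal(u1$usage$proportion, u2$usage$proportion)
  # per defined cell the proportions sum to 1
  key <- paste(u1$usage$gene_id, u1$usage$condition, u1$usage$fraction)
  sums <- tapply(u1$usage$proportion, key, sum)
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-12))
})

test_that("permutation p-values obey the add-one rule and the seed", {
  A <- matrix(c(0.5, 0.5, 0.6, 0.4, 0.55, 0.45), 3, 2, byrow = TRUE)
  # identical groups: nothing exceeds the observed 0 divergence strictly,
  # every permutation ties -> p = 1
  expect_equal(permutation_pvalue(A, A, 99, seed = 2)$p, 1)
  B <- matrix(c(0.95, 0.05, 0.9, 0.1, 0.99, 0.01), 3, 2, byrow = TRUE)
  p1 <- permutation_pvalue(A, B, 199, seed = 7)
  p2 <- permutation_pvalue(A, B, 199, seed = 7)
  expect_identical(p1, p2)                     # deterministic given seed
  expect_gte(p1$p, 1 / 200)                    # smallest attainable p
  expect_error(permutation_pvalue(A[1, , drop = FALSE], B, 99, seed = 1),
               "2 replicates")
  expect_error(permutation_pvalue(A, B, 99), "seed")
})

test_that("gradient distributions normalise and split by the masks", {
  # all signal in the RNP fractions: polysome share 0
  g <- gradient_distribution(c(5, 5, 0, 0, 0, 0), sprintf("f%d", 1:6),
                             polysome_mask = c(F, F, T, T, T, T),
                             heavy_mask = c(F, F, F, F, T, T))
  expect_equal(g$polysome_share, 0)
  expect_equal(g$heavy_share, 0)
  # uniform intensity over 10 fractions, 6 polysomal -> share 0.6
  g2 <- gradient_distribution(rep(1, 10), sprintf("f%d", 1:10),
                              polysome_mask = c(rep(FALSE, 4), rep(TRUE, 6)))
  expect_equal(g2$polysome_share, 0.6)
  expect_equal(sum(g2$distribution), 1)
  withr::local_seed(42)
  for (i in 1:20) {
    x <- rgamma(8, 1)
    pm <- sample(c(TRUE, FALSE), 8, replace = TRUE)
    hm <- pm & sample(c(TRUE, FALSE), 8, replace = TRUE)
    g3 <- gradient_distribution(x, sprintf("f%d", 1:8), pm, hm)
    expect_equal(sum(g3$distribution), 1)
    expect_equal(g3$polysome_share, sum(x[pm]) / sum(x))
    expect_equal(g3$heavy_share, sum(x[hm]) / sum(x))
    expect_lte(g3$heavy_share, g3$polysome_share)
  }
  expect_error(gradient_distribution(c(0, 0), c("a", "b"), c(TRUE, TRUE)),
               "all-zero")
  expect_error(gradient_distribution(c(1, 1), c("a", "b"),
                                     c(FALSE, TRUE), c(TRUE, FALSE)),
               "subset")
})
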