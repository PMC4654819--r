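# Jensen-Shannon divergence in bits, for already-validated proportion
# vectors. 0 log 0 = 0.
jsd_bits <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Jensen-Shannon divergence between two usage-proportion vectors
#'
#' Symmetric, bounded divergence (base-2 logarithms, so the range is
#' [0, 1]) between two proportion vectors over the same TSS variants; 0 iff
#' the vectors are equal, 1 for disjoint support.
#'
#' @param p,q Non-negative numeric vectors of equal length, each summing
#'   to 1 (tolerance 1e-6).
#' @return The divergence in bits.
#' @export
usage_divergence <- function(p, q) {
  if (length(p) != length(q))
    stop("p and q must have equal length")
  if (any(p < 0) || any(q < 0))
    stop("proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("proportions must each sum to 1")
  jsd_bits(p, q)
}

#' TSS-variant usage profiles per condition and fraction
#'
#' For each gene with more than one transcription start site, pools the
#' abundances of transcripts sharing a TSS, averages over replicates within
#' each condition-by-fraction cell, and converts to proportions — the gene's
#' "TSS fingerprint" in that RNA population. The Jensen-Shannon divergence
#' between fingerprints scores differential recruitment of TSS variants onto
#' polysomes (total vs polysomal within each condition) and cell-type
#' promoter shifts (case vs control within each fraction).
#'
#' @param abundances Transcript-by-sample abundance matrix (rownames =
#'   transcript ids), non-negative.
#' @param transcripts Validated transcript records mapping transcript to
#'   gene and TSS.
#' @param sheet Sample sheet covering every abundance column.
#' @return List of class \code{tss_usage} with \code{usage} (long
#'   data.frame: gene_id, tss_id, condition, fraction, abundance,
#'   proportion — proportion is NA in cells whose gene total is 0) and
#'   \code{divergence} (per gene: jsd_fraction_case, jsd_fraction_control,
#'   jsd_condition_total, jsd_condition_polysomal; NA where either
#'   fingerprint is undefined). Single-TSS genes are excluded.
#' @export
compute_usage <- function(abundances, transcripts, sheet) {
  if (is.null(rownames(abundances)))
    stop("abundance matrix must carry transcript ids as rownames")
  if (any(abundances < 0))
    stop("abundances must be non-negative")
  sheet <- validate_sample_sheet(sheet)
  miss <- setdiff(sheet$sample_id, colnames(abundances))
  if (length(miss))
    stop("sheet sample(s) absent from abundance matrix: ",
         paste(miss, collapse = ", "))
  idx <- match(rownames(abundances), transcripts$transcript_id)
  if (anyNA(idx))
    stop("transcript(s) absent from transcript table: ",
         paste(rownames(abundances)[is.na(idx)], collapse = ", "))
  gene <- transcripts$gene_id[idx]
  tss <- transcripts$tss_id[idx]

  multi <- names(which(vapply(split(tss, gene),
                              function(x) length(unique(x)), integer(1)) > 1L))
  keep <- gene %in% multi
  if (!any(keep))
    return(structure(list(usage = data.frame(), divergence = data.frame()),
                     class = "tss_usage"))
  ab <- abundances[keep, , drop = FALSE]
  gene <- gene[keep]; tss <- tss[keep]

  cells <- expand.grid(condition = c("case", "control"),
                       fraction = c("total", "polysomal"),
                       stringsAsFactors = FALSE)
  usage <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    ids <- sheet$sample_id[sheet$condition == cells$condition[k] &
                             sheet$fraction == cells$fraction[k]]
    cell_mean <- rowMeans(ab[, ids, drop = FALSE])
    agg <- rowsum(cell_mean, paste(gene, tss, sep = "\r"))
    key <- strsplit(rownames(agg), "\r", fixed = TRUE)
    df <- data.frame(
      gene_id = vapply(key, `[`, character(1), 1L),
      tss_id = vapply(key, `[`, character(1), 2L),
      condition = cells$condition[k],
      fraction = cells$fraction[k],
      abundance = agg[, 1L],
      row.names = NULL, stringsAsFactors = FALSE
    )
    tot <- stats::ave(df$abundance, df$gene_id, FUN = sum)
    df$proportion <- ifelse(tot > 0, df$abundance / tot, NA_real_)
    df
  }))
  usage <- usage[order(usage$gene_id, usage$tss_id,
                       usage$condition, usage$fraction), ]
  rownames(usage) <- NULL

  pair_jsd <- function(g, cond1, frac1, cond2, frac2) {
    a <- usage[usage$gene_id == g & usage$condition == cond1 &
                 usage$fraction == frac1, ]
    b <- usage[usage$gene_id == g & usage$condition == cond2 &
                 usage$fraction == frac2, ]
    p <- a$proportion[order(a$tss_id)]
    q <- b$proportion[order(b$tss_id)]
    if (anyNA(p) || anyNA(q)) NA_real_ else jsd_bits(p, q)
  }
  genes <- sort(unique(usage$gene_id))
  divergence <- data.frame(
    gene_id = genes,
    jsd_fraction_case = vapply(genes, pair_jsd, numeric(1),
                               "case", "total", "case", "polysomal"),
    jsd_fraction_control = vapply(genes, pair_jsd, numeric(1),
                                  "control", "total", "control", "polysomal"),
    jsd_condition_total = vapply(genes, pair_jsd, numeric(1),
                                 "case", "total", "control", "total"),
    jsd_condition_polysomal = vapply(genes, pair_jsd, numeric(1),
                                     "case", "polysomal", "control", "polysomal"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(usage = usage, divergence = divergence),
            class = "tss_usage")
}

#' Permutation p-value for a usage divergence
#'
#' Tests whether the divergence between two groups' mean TSS fingerprints
#' exceeds what replicate-label exchange produces. The statistic is the
#' Jensen-Shannon divergence of the two group-mean proportion vectors;
#' replicate rows are permuted between groups and the p-value uses the
#' add-one rule p = (1 + #{permuted >= observed}) / (n_perm + 1), so the
#' smallest attainable p is 1/(n_perm + 1).
#'
#' @param A,B Matrices of replicate-level proportion vectors (replicates in
#'   rows, TSS variants in columns), at least 2 rows each.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return List with \code{observed} (the group-mean JSD) and \code{p}.
#' @export
permutation_pvalue <- function(A, B, n_perm = 999L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) < 2L || nrow(B) < 2L)
    stop("need at least 2 replicates per group")
  if (ncol(A) != ncol(B))
    stop("A and B must cover the same TSS variants")
  obs <- jsd_bits(colMeans(A) / sum(colMeans(A)),
                  colMeans(B) / sum(colMeans(B)))
  pool <- rbind(A, B)
  nA <- nrow(A); ntot <- nrow(pool)
  count <- 0L
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      pick <- sample.int(ntot, nA)
      pa <- colMeans(pool[pick, , drop = FALSE])
      pb <- colMeans(pool[-pick, , drop = FALSE])
      stat <- jsd_bits(pa / sum(pa), pb / sum(pb))
      if (stat >= obs) count <- count + 1L
    }
  })
  list(observed = obs, p = (1 + count) / (n_perm + 1))
}

#' Distribution of a transcript variant across polysome-gradient fractions
#'
#' Normalises per-fraction signal intensities (e.g. quantitated RT-PCR
#' amplicons) to a distribution over the gradient and summarises ribosome
#' loading: \code{polysome_share} is the mass over the fractions at or
#' beyond disomes, \code{heavy_share} the mass over the heavy-polysome
#' fractions. Which fractions count as polysomal or heavy is an experimental
#' labelling choice, so the masks are supplied by the caller; heavy
#' fractions must be a subset of polysomal ones.
#'
#' @param intensities Non-negative numeric vector, one value per gradient
#'   fraction, not all zero.
#' @param fraction_labels Character labels, parallel to
#'   \code{intensities}.
#' @param polysome_mask Logical mask of fractions at >= disomes.
#' @param heavy_mask Logical mask of heavy-polysome fractions.
#' @param variant_id Identifier carried into the output.
#' @return List of class \code{gradient_profile}: \code{variant_id},
#'   \code{fraction_labels}, \code{intensities}, \code{distribution}
#'   (sums to 1), \code{polysome_share}, \code{heavy_share}.
#' @export
gradient_distribution <- function(intensities, fraction_labels,
                                  polysome_mask, heavy_mask = NULL,
                                  variant_id = NA_character_) {
  n <- length(intensities)
  stopifnot(length(fraction_labels) == n, length(polysome_mask) == n)
  if (is.null(heavy_mask)) heavy_mask <- rep(FALSE, n)
  stopifnot(length(heavy_mask) == n)
  if (any(intensities < 0))
    stop("intensities must be non-negative")
  if (sum(intensities) == 0)
    stop("all-zero intensity vector: distribution undefined")
  if (any(heavy_mask & !polysome_mask))
    stop("heavy fractions must be a subset of polysome fractions")
  dist <- intensities / sum(intensities)
  structure(list(
    variant_id = variant_id,
    fraction_labels = fraction_labels,
    intensities = intensities,
    distribution = dist,
    polysome_share = sum(dist[polysome_mask]),
    heavy_share = sum(dist[heavy_mask])
  ), class = "gradient_profile")
}

#' @export
print.gradient_profile <- function(x, ...) {
  cat(sprintf("Gradient profile%s over %d fractions\n",
              if (is.na(x$variant_id)) "" else paste0(" for ", x$variant_id),
              length(x$distribution)))
  cat(sprintf("  polysome share: %.3f, heavy share: %.3f\n",
              x$polysome_share, x$heavy_share))
  invisible(x)
}
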