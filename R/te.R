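#' Per-gene expression means for the four condition-by-fraction cells
#'
#' Averages normalised counts over replicates within each of the four
#' condition-by-fraction cells (case/control crossed with total/polysomal),
#' yielding four measures of expression per gene.
#'
#' @param norm_counts Normalised count matrix.
#' @param sheet Sample sheet covering every column.
#' @return Data.frame with columns \code{gene_id}, \code{E_case_total},
#'   \code{E_case_polysomal}, \code{E_control_total},
#'   \code{E_control_polysomal}, \code{min_expression} (the lowest of the
#'   four means).
#' @export
summarize_expression <- function(norm_counts, sheet) {
  validate_counts(norm_counts)
  sheet <- validate_sample_sheet(sheet, norm_counts)
  cell_mean <- function(cond, frac) {
    ids <- sheet$sample_id[sheet$condition == cond & sheet$fraction == frac]
    if (!length(ids))
      stop(sprintf("no samples in cell (%s, %s)", cond, frac))
    rowMeans(norm_counts[, ids, drop = FALSE])
  }
  E <- data.frame(
    gene_id = rownames(norm_counts),
    E_case_total = cell_mean("case", "total"),
    E_case_polysomal = cell_mean("case", "polysomal"),
    E_control_total = cell_mean("control", "total"),
    E_control_polysomal = cell_mean("control", "polysomal"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  E$min_expression <- pmin(E$E_case_total, E$E_case_polysomal,
                           E$E_control_total, E$E_control_polysomal)
  E
}

#' Partition genes into analysable and filtered
#'
#' The TE ratio is undefined when any of the four expression means is zero,
#' so by default (\code{min_count = 0}) any gene with a zero cell is
#' filtered. A \code{pseudocount} added to all four means beforehand turns
#' filtering off without fabricating direction (it shrinks ratios toward 1).
#'
#' @param E Expression table from \code{\link{summarize_expression}}.
#' @param min_count Genes with any cell mean <= \code{min_count} are filtered.
#' @param pseudocount Value added to all four cell means before filtering.
#' @return \code{E} with the pseudocount applied, \code{min_expression}
#'   recomputed, and a logical column \code{analysable}.
#' @export
filter_genes <- function(E, min_count = 0, pseudocount = 0) {
  stopifnot(min_count >= 0, pseudocount >= 0)
  cols <- c("E_case_total", "E_case_polysomal",
            "E_control_total", "E_control_polysomal")
  E[cols] <- E[cols] + pseudocount
  E$min_expression <- do.call(pmin, E[cols])
  E$analysable <- E$min_expression > min_count
  E
}

#' TE ratios and their case-vs-control fold change
#'
#' Translational efficiency of a gene is its polysomal-to-total expression
#' ratio. The differential-TE statistic is the log2 fold change of this ratio
#' between case and control:
#' delta = log2((E_case_poly / E_case_total) / (E_ctrl_poly / E_ctrl_total)).
#' With \code{scale = "ratio"} the raw ratio of ratios is returned instead of
#' its log2 (sensitivity mode; the log scale is the default because it makes
#' up- and down-regulation symmetric).
#'
#' @param E Expression table restricted to analysable genes (all four cell
#'   means strictly positive).
#' @param scale \code{"log2"} (default) or \code{"ratio"}.
#' @return \code{E} with columns \code{te_case}, \code{te_control},
#'   \code{delta} appended.
#' @export
compute_te_delta <- function(E, scale = c("log2", "ratio")) {
  scale <- match.arg(scale)
  if (any(E$E_case_total <= 0 | E$E_control_total <= 0 |
            E$E_case_polysomal <= 0 | E$E_control_polysomal <= 0))
    stop("internal error: non-positive expression reached compute_te_delta; ",
         "filter_genes() must be applied first")
  E$te_case <- E$E_case_polysomal / E$E_case_total
  E$te_control <- E$E_control_polysomal / E$E_control_total
  ratio <- E$te_case / E$te_control
  E$delta <- if (scale == "log2") log2(ratio) else ratio
  E
}

#' Group genes into expression bins
#'
#' Count noise scales with expression level, so the fold change of a weakly
#' expressed gene is not comparable with that of a strongly expressed one.
#' Genes are sorted ascending by minimum expression (ties broken by gene id)
#' and cut into consecutive blocks of \code{bin_size}; a trailing remainder
#' smaller than \code{bin_size} is merged into the preceding bin so that no
#' bin relies on an unstable standard deviation.
#'
#' @param min_expressions Named numeric vector (names = gene ids) of per-gene
#'   minimum expression.
#' @param bin_size Target genes per bin (default 300).
#' @return Integer vector of bin indices, parallel to the input.
#' @export
assign_bins <- function(min_expressions, bin_size = 300L) {
  n <- length(min_expressions)
  if (n < 2L)
    stop("need at least 2 analysable genes to form bins")
  stopifnot(bin_size >= 2L)
  ord <- order(min_expressions, names(min_expressions))
  n_bins <- max(1L, n %/% bin_size)
  bin_sorted <- pmin(ceiling(seq_len(n) / bin_size), n_bins)
  bin <- integer(n)
  bin[ord] <- bin_sorted
  bin
}

#' Expression-binned Z-scores of TE fold changes
#'
#' Standardises each gene's fold change against the mean and standard
#' deviation (denominator n - 1) of its expression bin, so the score measures
#' how far a gene's TE change deviates from genes expressed at a similar
#' level.
#'
#' @param deltas Numeric vector of fold changes.
#' @param bin_indices Integer vector of bin assignments from
#'   \code{\link{assign_bins}}.
#' @return A list with \code{z} (per-gene scores) and \code{bins}
#'   (data.frame of per-bin \code{bin}, \code{n}, \code{mean}, \code{sd}).
#' @export
binned_zscore <- function(deltas, bin_indices) {
  stopifnot(length(deltas) == length(bin_indices))
  sizes <- table(bin_indices)
  if (any(sizes < 2L))
    stop("bin(s) with fewer than 2 genes: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  mu <- tapply(deltas, bin_indices, mean)
  sd_ <- tapply(deltas, bin_indices, stats::sd)
  if (any(sd_ == 0))
    stop("zero within-bin standard deviation in bin(s): ",
         paste(names(sd_)[sd_ == 0], collapse = ", "))
  key <- as.character(bin_indices)
  z <- (deltas - mu[key]) / sd_[key]
  list(
    z = as.numeric(z),
    bins = data.frame(bin = as.integer(names(mu)),
                      n = as.integer(sizes[names(mu)]),
                      mean = unname(mu), sd = unname(sd_))
  )
}

#' Call differential TE from Z-scores
#'
#' A gene is called \code{up} when z > threshold and \code{down} when
#' z < -threshold (strict inequalities); anything in between is
#' \code{unchanged}.
#'
#' @param z Numeric vector of finite Z-scores.
#' @param threshold Calling threshold on |z| (default 2).
#' @return Character vector of calls.
#' @export
classify_te <- function(z, threshold = 2) {
  stopifnot(all(is.finite(z)), threshold > 0)
  ifelse(z > threshold, "up", ifelse(z < -threshold, "down", "unchanged"))
}

#' Differential-TE analysis of a normalised count matrix
#'
#' Full per-gene pipeline: replicate averaging, zero filtering, TE fold
#' change, expression-binned Z-score, and calling.
#'
#' @param norm_counts Normalised count matrix (see
#'   \code{\link{normalize_depth}}).
#' @param sheet Sample sheet.
#' @param bin_size Genes per expression bin (default 300).
#' @param threshold Z-score calling threshold (default 2).
#' @param min_count Filtering floor on the four cell means (default 0).
#' @param pseudocount Optional global pseudocount (default 0 = hard filter).
#' @param scale Fold-change scale, \code{"log2"} (default) or \code{"ratio"}.
#' @return A list of class \code{te_result} with \code{genes} (one row per
#'   gene: expression means, TE ratios, delta, bin, z, call — call is
#'   \code{"filtered"} with NA statistics for non-analysable genes) and
#'   \code{bins} (per-bin mean/sd table).
#' @export
te_analysis <- function(norm_counts, sheet, bin_size = 300L, threshold = 2,
                        min_count = 0, pseudocount = 0,
                        scale = c("log2", "ratio")) {
  scale <- match.arg(scale)
  E <- summarize_expression(norm_counts, sheet)
  E <- filter_genes(E, min_count = min_count, pseudocount = pseudocount)
  keep <- E$analysable
  A <- compute_te_delta(E[keep, , drop = FALSE], scale = scale)
  bin <- assign_bins(stats::setNames(A$min_expression, A$gene_id),
                     bin_size = bin_size)
  zs <- binned_zscore(A$delta, bin)
  A$bin <- bin
  A$z <- zs$z
  A$call <- classify_te(zs$z, threshold)

  genes <- E[c("gene_id", "E_case_total", "E_case_polysomal",
               "E_control_total", "E_control_polysomal", "min_expression")]
  genes$te_case <- genes$te_control <- genes$delta <- NA_real_
  genes$bin <- NA_integer_
  genes$z <- NA_real_
  genes$call <- "filtered"
  i <- match(A$gene_id, genes$gene_id)
  genes$te_case[i] <- A$te_case
  genes$te_control[i] <- A$te_control
  genes$delta[i] <- A$delta
  genes$bin[i] <- A$bin
  genes$z[i] <- A$z
  genes$call[i] <- A$call
  structure(list(genes = genes, bins = zs$bins,
                 params = list(bin_size = bin_size, threshold = threshold,
                               min_count = min_count,
                               pseudocount = pseudocount, scale = scale)),
            class = "te_result")
}

#' @export
print.te_result <- function(x, ...) {
  tab <- table(factor(x$genes$call,
                      levels = c("up", "down", "unchanged", "filtered")))
  cat("Differential-TE analysis\n")
  cat(sprintf("  genes: %d (%d analysable in %d bins of size %s)\n",
              nrow(x$genes), sum(x$genes$call != "filtered"),
              nrow(x$bins), x$params$bin_size))
  cat(sprintf("  calls at |z| > %s: up %d, down %d, unchanged %d, filtered %d\n",
              format(x$params$threshold), tab[["up"]], tab[["down"]],
              tab[["unchanged"]], tab[["filtered"]]))
  invisible(x)
}
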