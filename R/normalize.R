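#' Compute depth-equalising rescale factors
#'
#' Sequencing depth differs between libraries, so raw fragment counts are not
#' comparable across samples. For each sample n with depth x_n (the column sum
#' of its counts) the rescale factor is x_n / min(X), where the minimum is
#' taken over the samples of its group. With \code{grouping = "by-fraction"}
#' (the default) the total and polysomal libraries are treated as independent
#' groups, so each fraction is equalised to its own shallowest library.
#'
#' @param counts Validated count matrix.
#' @param sheet Sample sheet covering every count column.
#' @param grouping Either \code{"by-fraction"} (minima within the total and
#'   polysomal groups separately) or \code{"all"} (one global minimum).
#' @return A data.frame with columns \code{sample_id}, \code{group},
#'   \code{depth}, \code{group_min}, \code{factor}. Every factor is >= 1 and
#'   at least one sample per group has factor exactly 1.
#' @export
compute_rescale_factors <- function(counts, sheet,
                                    grouping = c("by-fraction", "all")) {
  grouping <- match.arg(grouping)
  validate_counts(counts)
  sheet <- validate_sample_sheet(sheet, counts)
  depth <- colSums(counts)
  zero <- names(depth)[depth <= 0]
  if (length(zero))
    stop("zero sequencing depth for sample(s): ", paste(zero, collapse = ", "))
  group <- if (grouping == "by-fraction") {
    sheet$fraction[match(colnames(counts), sheet$sample_id)]
  } else {
    rep("all", ncol(counts))
  }
  group_min <- stats::ave(depth, group, FUN = min)
  data.frame(
    sample_id = colnames(counts),
    group = group,
    depth = unname(depth),
    group_min = unname(group_min),
    factor = unname(depth / group_min),
    stringsAsFactors = FALSE
  )
}

#' Down-sample counts to the shallowest library of each group
#'
#' Each count is divided by its sample's rescale factor. The division is
#' deterministic and the result is kept as a real number (no re-rounding):
#' rounding would break the conservation property that within-group column
#' sums are identical after normalisation. Samples at the group minimum have
#' factor 1 and pass through unchanged.
#'
#' @param counts Validated count matrix.
#' @param factors Output of \code{\link{compute_rescale_factors}} covering
#'   every sample of \code{counts}.
#' @return Normalised count matrix of the same shape.
#' @export
downsample_counts <- function(counts, factors) {
  validate_counts(counts)
  idx <- match(colnames(counts), factors$sample_id)
  if (anyNA(idx))
    stop("no rescale factor for sample(s): ",
         paste(colnames(counts)[is.na(idx)], collapse = ", "))
  sweep(counts, 2L, factors$factor[idx], `/`)
}

#' Normalise a count matrix in one call
#'
#' Convenience wrapper chaining \code{\link{compute_rescale_factors}} and
#' \code{\link{downsample_counts}}.
#'
#' @inheritParams compute_rescale_factors
#' @return A list with elements \code{counts} (the normalised matrix) and
#'   \code{factors} (the rescale-factor table).
#' @export
normalize_depth <- function(counts, sheet,
                            grouping = c("by-fraction", "all")) {
  factors <- compute_rescale_factors(counts, sheet, grouping)
  list(counts = downsample_counts(counts, factors), factors = factors)
}
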