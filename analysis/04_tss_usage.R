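#!/usr/bin/env Rscript
# Stage 4: TSS fingerprints and polysome-gradient summaries.
#
# Pools transcript abundances by TSS, computes each multi-TSS gene's usage
# fingerprint per condition x fraction, and scores differential recruitment
# of TSS variants onto polysomes as the Jensen-Shannon divergence between
# the total and polysomal fingerprints (permutation p-values for the top
# genes). Closes with gradient-distribution summaries for an illustrative
# pair of variants.

suppressPackageStartupMessages(library(leaderTE))

ab_df <- read.delim("results/sim/expr.tsv", check.names = FALSE)
ab <- as.matrix(ab_df[-1]); rownames(ab) <- ab_df[[1]]
tx <- read.delim("results/sim/usage_transcripts.tsv")
sheet <- read_sample_sheet("results/sim/samples.tsv")
truth <- read.delim("results/sim/truth_usage.tsv")

usage <- compute_usage(ab, tx, sheet)
write.table(usage$usage, "results/tss_usage.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(usage$divergence, "results/tss_divergence.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

m <- merge(usage$divergence, truth, by = "gene_id")
m$score <- (m$jsd_fraction_case + m$jsd_fraction_control) / 2
r <- rank(m$score)
auc <- (mean(r[m$shifted]) - (sum(m$shifted) + 1) / 2) / sum(!m$shifted)
cat(sprintf("%d multi-TSS genes; JSD ranking recovers planted shifts with AUROC %.3f\n",
            nrow(m), auc))

# permutation p-values for the five highest-divergence genes (case samples)
top <- head(m$gene_id[order(-m$score)], 5)
cat("top diverging genes (case, total vs polysomal):\n")
for (g in top) {
  ids_t <- sheet$sample_id[sheet$condition == "case" &
                             sheet$fraction == "total"]
  ids_p <- sheet$sample_id[sheet$condition == "case" &
                             sheet$fraction == "polysomal"]
  tx_g <- tx$transcript_id[tx$gene_id == g]
  prop <- function(ids) t(apply(ab[tx_g, ids, drop = FALSE], 2,
                                function(x) x / sum(x)))
  pv <- permutation_pvalue(prop(ids_t), prop(ids_p), n_perm = 999, seed = 17)
  cat(sprintf("  %s  JSD=%.3f  p=%.3f  (planted shift: %s)\n", g,
              pv$observed, pv$p, m$shifted[m$gene_id == g]))
}

# gradient summaries: a variant engaged by heavy polysomes in the case
# state but confined to the RNP fractions in the control state
labels <- c("RNP1", "RNP2", "40S/60S", "mono", "disome", "poly1", "poly2",
            "heavy1", "heavy2", "heavy3")
polysome <- labels %in% c("disome", "poly1", "poly2", "heavy1", "heavy2",
                          "heavy3")
heavy <- labels %in% c("heavy1", "heavy2", "heavy3")
case_v <- gradient_distribution(c(2, 1, 1, 2, 5, 9, 12, 10, 6, 2), labels,
                                polysome, heavy, "V_case")
ctrl_v <- gradient_distribution(c(18, 12, 6, 3, 1, 0, 0, 0, 0, 0), labels,
                                polysome, heavy, "V_control")
cat("\ngradient shares (polysome / heavy):\n")
cat(sprintf("  case:    %.2f / %.2f\n", case_v$polysome_share,
            case_v$heavy_share))
cat(sprintf("  control: %.2f / %.2f\n", ctrl_v$polysome_share,
            ctrl_v$heavy_share))
grad <- data.frame(variant = c("V_case", "V_control"),
                   polysome_share = c(case_v$polysome_share,
                                      ctrl_v$polysome_share),
                   heavy_share = c(case_v$heavy_share, ctrl_v$heavy_share))
write.table(grad, "results/gradient_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
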