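# Evaluate code under a temporary RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# One master seed, documented per-component streams: each simulator component
# draws from its own derived seed so adding draws to one component never
# shifts another. Kept well below 2^31.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 16777216L) * 64L + as.integer(stream)
}

#' Specification of a synthetic polysome-profiling study
#'
#' Collects every knob of the synthetic-data generator and validates ranges.
#' The defaults emulate the study design the pipeline targets: 3 biological
#' replicates of total and polysomal RNA in each of two conditions,
#' negative-binomial gene counts with moderate overdispersion and unequal
#' library depths, a minority of genes carrying a multiplicative TE shift in
#' the case condition, multi-TSS genes with condition/fraction-specific
#' usage, and transcript leaders with planted uORFs on ATG-free backgrounds.
#'
#' @param n_genes Number of genes in the count simulation.
#' @param replicates Biological replicates per condition-by-fraction cell.
#' @param baseline_log2_mean,baseline_log2_sd Normal distribution of per-gene
#'   baseline log2 mean counts.
#' @param phi Negative-binomial dispersion: variance = mu (1 + phi mu).
#'   \code{phi = 0} gives Poisson counts.
#' @param lib_factor_range Range of uniform per-sample library-size factors.
#' @param fraction_regulated Fraction of genes with a planted TE shift.
#' @param effect_size Planted |log2 TE fold change| for regulated genes.
#' @param regulated_min_mean If non-NULL, TE shifts are planted only on
#'   genes with baseline mean at or above this value.
#' @param n_transcripts Number of transcripts in the sequence simulation.
#' @param tl_length_range Range of transcript-leader lengths (nt).
#' @param uorf_count_range Range of planted upstream uORFs per transcript.
#' @param uorf_codon_range Range of planted uORF lengths in sense codons
#'   (initiator included, stop excluded).
#' @param gc GC content of background sequence.
#' @param n_usage_genes Number of multi-TSS genes in the usage simulation.
#' @param tss_range Range of TSS variants per usage gene.
#' @param usage_fraction_shifted Fraction of usage genes with a planted
#'   total-vs-polysomal recruitment shift.
#' @param usage_concentration Dirichlet concentration of usage proportions.
#' @param usage_min_shift Minimum Jensen-Shannon divergence (bits) between
#'   the total and polysomal fingerprints of a shifted gene; redraws below
#'   it are rejected so every planted shift is genuinely distinct.
#' @param usage_phi Negative-binomial dispersion of transcript abundances.
#' @param seed Master seed (mandatory); every component derives its own
#'   stream from it.
#' @return Validated list of class \code{sim_spec}.
#' @export
sim_spec <- function(n_genes = 6000L, replicates = 3L,
                     baseline_log2_mean = 6, baseline_log2_sd = 2,
                     phi = 0.1, lib_factor_range = c(0.7, 1.3),
                     fraction_regulated = 0.05, effect_size = 2,
                     regulated_min_mean = NULL,
                     n_transcripts = 100L, tl_length_range = c(60L, 300L),
                     uorf_count_range = c(0L, 3L),
                     uorf_codon_range = c(1L, 8L), gc = 0.5,
                     n_usage_genes = 200L, tss_range = c(2L, 3L),
                     usage_fraction_shifted = 0.1,
                     usage_concentration = 5, usage_min_shift = 0.05,
                     usage_phi = 0.05, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  spec <- list(n_genes = as.integer(n_genes),
               replicates = as.integer(replicates),
               baseline_log2_mean = baseline_log2_mean,
               baseline_log2_sd = baseline_log2_sd,
               phi = phi, lib_factor_range = lib_factor_range,
               fraction_regulated = fraction_regulated,
               effect_size = effect_size,
               regulated_min_mean = regulated_min_mean,
               n_transcripts = as.integer(n_transcripts),
               tl_length_range = as.integer(tl_length_range),
               uorf_count_range = as.integer(uorf_count_range),
               uorf_codon_range = as.integer(uorf_codon_range),
               gc = gc, n_usage_genes = as.integer(n_usage_genes),
               tss_range = as.integer(tss_range),
               usage_fraction_shifted = usage_fraction_shifted,
               usage_concentration = usage_concentration,
               usage_min_shift = usage_min_shift,
               usage_phi = usage_phi, seed = as.integer(seed))
  with(spec, {
    stopifnot(n_genes >= 1, replicates >= 1, baseline_log2_sd >= 0,
              phi >= 0, length(lib_factor_range) == 2,
              all(lib_factor_range > 0),
              lib_factor_range[1] <= lib_factor_range[2],
              fraction_regulated >= 0, fraction_regulated <= 1,
              effect_size >= 0, n_transcripts >= 0,
              tl_length_range[1] >= 0,
              tl_length_range[1] <= tl_length_range[2],
              uorf_count_range[1] >= 0,
              uorf_count_range[1] <= uorf_count_range[2],
              uorf_codon_range[1] >= 1,
              uorf_codon_range[1] <= uorf_codon_range[2],
              gc > 0, gc < 1, n_usage_genes >= 0,
              tss_range[1] >= 2, tss_range[1] <= tss_range[2],
              usage_fraction_shifted >= 0, usage_fraction_shifted <= 1,
              usage_concentration > 0, usage_min_shift >= 0,
              usage_min_shift < 1, usage_phi >= 0)
  })
  # every planted uORF needs at least 6 nt (ATG + stop)
  if (spec$uorf_count_range[2] * 6L > spec$tl_length_range[1])
    stop("infeasible packing: ", spec$uorf_count_range[2],
         " uORFs cannot fit in a ", spec$tl_length_range[1], " nt leader")
  structure(spec, class = "sim_spec")
}

rnb <- function(n, mu, phi) {
  if (phi == 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

#' Simulate a paired total/polysomal count study with planted TE shifts
#'
#' Each gene gets a baseline mean drawn log-normally; the total-fraction mean
#' equals the baseline in both conditions and the polysomal mean equals
#' baseline times the gene's TE multiplier. Control TE is 1 for every gene;
#' in the case condition a planted subset carries a multiplicative shift of
#' +/- \code{effect_size} log2 units on the polysomal mean only, so
#' transcription and translation effects stay separable in the truth table.
#' Counts are negative-binomial, independent across replicates, with
#' per-sample library-size factors.
#'
#' @param spec A \code{\link{sim_spec}}.
#' @return List with \code{counts} (matrix), \code{sheet} (sample sheet),
#'   \code{truth} (per gene: \code{gene_id}, \code{baseline},
#'   \code{true_delta}, \code{direction}, \code{regulated}) and
#'   \code{lib_factors}.
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(derive_seed(spec$seed, 1L), {
    n <- spec$n_genes
    gene_ids <- sprintf("g%05d", seq_len(n))
    baseline <- 2^stats::rnorm(n, spec$baseline_log2_mean,
                               spec$baseline_log2_sd)
    eligible <- if (is.null(spec$regulated_min_mean)) seq_len(n) else
      which(baseline >= spec$regulated_min_mean)
    n_reg <- round(spec$fraction_regulated * n)
    if (n_reg > length(eligible))
      stop("not enough eligible genes to plant ", n_reg, " TE shifts")
    reg <- sort(sample(eligible, n_reg))
    direction <- integer(n)
    direction[reg] <- sample(c(-1L, 1L), n_reg, replace = TRUE)
    true_delta <- direction * spec$effect_size

    sheet <- expand.grid(replicate = seq_len(spec$replicates),
                         fraction = c("total", "polysomal"),
                         condition = c("case", "control"),
                         stringsAsFactors = FALSE)
    sheet$sample_id <- sprintf("%s_%s_%d", sheet$condition, sheet$fraction,
                               sheet$replicate)
    sheet <- sheet[c("sample_id", "condition", "fraction", "replicate")]
    lib <- stats::runif(nrow(sheet), spec$lib_factor_range[1],
                        spec$lib_factor_range[2])
    names(lib) <- sheet$sample_id

    counts <- matrix(0, n, nrow(sheet),
                     dimnames = list(gene_ids, sheet$sample_id))
    for (j in seq_len(nrow(sheet))) {
      te <- if (sheet$fraction[j] == "total") 1 else
        2^(if (sheet$condition[j] == "case") true_delta else 0)
      counts[, j] <- rnb(n, baseline * te * lib[j], spec$phi)
    }
    list(
      counts = counts,
      sheet = sheet,
      truth = data.frame(gene_id = gene_ids, baseline = baseline,
                         true_delta = true_delta, direction = direction,
                         regulated = direction != 0L,
                         stringsAsFactors = FALSE),
      lib_factors = lib
    )
  })
}

# Background generator that can never emit an ATG triplet, even across the
# junction with preceding sequence: when the running 2-mer is "AT" the next
# base is drawn from {A, C, T}. `prev2` seeds the memory.
atg_free_bg <- function(n, gc, prev2 = "") {
  if (n == 0L) return("")
  bases <- c("A", "C", "G", "T")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  out <- character(n)
  mem <- prev2
  for (i in seq_len(n)) {
    pi <- p
    if (nchar(mem) >= 2L &&
          substr(mem, nchar(mem) - 1L, nchar(mem)) == "AT")
      pi[3] <- 0
    b <- sample(bases, 1L, prob = pi)
    out[i] <- b
    mem <- paste0(substr(mem, nchar(mem), nchar(mem)), b)
  }
  paste(out, collapse = "")
}

last2 <- function(x) substr(x, max(1L, nchar(x) - 1L), nchar(x))

# A sense codon that is neither a stop nor able to complete an ATG given the
# preceding two bases.
sense_codon <- function(gc, prev2) {
  repeat {
    cod <- atg_free_bg(3L, gc, prev2)
    if (!(cod %in% STOP_CODONS)) return(cod)
  }
}

# A stop codon that cannot complete an ATG with the preceding base.
safe_stop <- function(prev2) {
  pool <- if (substr(prev2, nchar(prev2), nchar(prev2)) == "A")
    c("TAA", "TAG") else STOP_CODONS
  sample(pool, 1L)
}

# Assemble one transcript with upstream uORFs planted at exact coordinates.
# uorf_codons: sense-codon counts; gaps: nucleotides before each uORF plus a
# final gap to the main ATG (length = length(uorf_codons) + 1).
build_planted_transcript <- function(uorf_codons, gaps, gc, cds_codons = 12L) {
  stopifnot(length(gaps) == length(uorf_codons) + 1L)
  seqs <- character(0)
  cur <- ""
  emit <- function(piece) {
    seqs[[length(seqs) + 1L]] <<- piece
    cur <<- last2(paste0(cur, piece))
  }
  starts <- integer(length(uorf_codons))
  stop_ends <- integer(length(uorf_codons))
  pos <- 0L
  for (i in seq_along(uorf_codons)) {
    emit(atg_free_bg(gaps[i], gc, cur)); pos <- pos + gaps[i]
    starts[i] <- pos
    emit("ATG"); pos <- pos + 3L
    for (k in seq_len(uorf_codons[i] - 1L)) {
      emit(sense_codon(gc, cur)); pos <- pos + 3L
    }
    emit(safe_stop(cur)); pos <- pos + 3L
    stop_ends[i] <- pos
  }
  emit(atg_free_bg(gaps[length(gaps)], gc, cur))
  pos <- pos + gaps[length(gaps)]
  cds_start <- pos
  emit("ATG")
  for (k in seq_len(cds_codons)) emit(sense_codon(gc, cur))
  emit(safe_stop(cur))
  list(sequence = paste(seqs, collapse = ""), cds_start = cds_start,
       starts = starts, stop_ends = stop_ends)
}

#' Simulate transcripts with planted transcript-leader uORFs
#'
#' Transcript leaders are random-background sequences at the requested GC
#' content, generated so that no ATG triplet can occur outside the planted
#' positions; each transcript carries a drawn number of non-overlapping
#' upstream uORFs of drawn codon lengths, separated by random gaps, followed
#' by the principal ATG and a short coding sequence. The emitted truth table
#' is exactly what the annotation scanner should recover.
#'
#' @param spec A \code{\link{sim_spec}}.
#' @return List with \code{records} (validated transcript records) and
#'   \code{truth} (per planted uORF: \code{transcript_id}, \code{start},
#'   \code{stop_end}, \code{n_codons}, \code{gap_to_main},
#'   \code{orf_class}; 0-based half-open coordinates).
#' @export
simulate_transcripts <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(derive_seed(spec$seed, 2L), {
    recs <- vector("list", spec$n_transcripts)
    truths <- vector("list", spec$n_transcripts)
    for (t in seq_len(spec$n_transcripts)) {
      id <- sprintf("tx%04d", t)
      tl_len <- sample(spec$tl_length_range[1]:spec$tl_length_range[2], 1L)
      n_uorf <- sample(spec$uorf_count_range[1]:spec$uorf_count_range[2], 1L)
      # cap codon draws so the blocks always fit the drawn leader length
      codons <- integer(0)
      if (n_uorf > 0L) {
        budget <- tl_len
        for (i in seq_len(n_uorf)) {
          reserve <- (n_uorf - i) * 6L   # minimal blocks still to place
          max_cod <- min(spec$uorf_codon_range[2],
                         (budget - reserve - 3L) %/% 3L)
          if (max_cod < spec$uorf_codon_range[1])
            stop("infeasible packing: leader of ", tl_len,
                 " nt cannot hold ", n_uorf, " uORFs")
          ci <- sample(spec$uorf_codon_range[1]:max_cod, 1L)
          codons <- c(codons, ci)
          budget <- budget - 3L * (ci + 1L)
        }
      }
      leftover <- tl_len - sum(3L * (codons + 1L))
      gaps <- as.integer(stats::rmultinom(1L, leftover,
                                          rep(1, n_uorf + 1L)))
      built <- build_planted_transcript(codons, gaps, spec$gc)
      recs[[t]] <- data.frame(
        transcript_id = id, gene_id = sprintf("g%04d", t),
        tss_id = sprintf("tss%04d", t),
        cds_start = built$cds_start, sequence = built$sequence,
        stringsAsFactors = FALSE)
      if (n_uorf > 0L)
        truths[[t]] <- data.frame(
          transcript_id = id, start = built$starts,
          stop_end = built$stop_ends, n_codons = codons,
          gap_to_main = built$cds_start - built$stop_ends,
          orf_class = "upstream", stringsAsFactors = FALSE)
    }
    records <- validate_transcripts(do.call(rbind, recs))
    truth <- if (all(vapply(truths, is.null, logical(1))))
      data.frame(transcript_id = character(0), start = integer(0),
                 stop_end = integer(0), n_codons = integer(0),
                 gap_to_main = integer(0), orf_class = character(0))
    else do.call(rbind, truths[!vapply(truths, is.null, logical(1))])
    rownames(truth) <- NULL
    list(records = records, truth = truth)
  })
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  x / sum(x)
}

#' Simulate transcript abundances with planted TSS-usage shifts
#'
#' Multi-TSS genes receive Dirichlet-drawn TSS usage proportions. In the
#' total fraction the proportions are shared between conditions; a planted
#' subset of genes gets an independently drawn fingerprint in the polysomal
#' fraction (differential recruitment of TSS variants onto polysomes), while
#' unshifted genes reuse their total-fraction fingerprint. Transcript
#' abundances are negative-binomial around gene expression times the
#' variant proportion.
#'
#' @param spec A \code{\link{sim_spec}}.
#' @return List with \code{abundances} (transcript-by-sample matrix),
#'   \code{transcripts} (transcript-to-gene/TSS map, sufficient for
#'   \code{\link{compute_usage}}), \code{sheet}, and \code{truth}
#'   (per gene: TSS count, shifted flag, plus the true proportion vectors
#'   as comma-joined strings in TSS order).
#' @export
simulate_usage <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(derive_seed(spec$seed, 3L), {
    sheet <- expand.grid(replicate = seq_len(spec$replicates),
                         fraction = c("total", "polysomal"),
                         condition = c("case", "control"),
                         stringsAsFactors = FALSE)
    sheet$sample_id <- sprintf("%s_%s_%d", sheet$condition, sheet$fraction,
                               sheet$replicate)
    sheet <- sheet[c("sample_id", "condition", "fraction", "replicate")]

    n_shift <- round(spec$usage_fraction_shifted * spec$n_usage_genes)
    shifted <- rep(FALSE, spec$n_usage_genes)
    if (n_shift > 0L)
      shifted[sample(spec$n_usage_genes, n_shift)] <- TRUE

    tx_rows <- list(); ab_rows <- list(); truth_rows <- list()
    for (g in seq_len(spec$n_usage_genes)) {
      gid <- sprintf("ug%04d", g)
      k <- sample(spec$tss_range[1]:spec$tss_range[2], 1L)
      tss_ids <- sprintf("%s_tss%d", gid, seq_len(k))
      p_total <- rdirichlet1(rep(spec$usage_concentration, k))
      p_poly <- p_total
      if (shifted[g]) {
        repeat {
          p_poly <- rdirichlet1(rep(spec$usage_concentration, k))
          if (jsd_bits(p_total, p_poly) >= spec$usage_min_shift) break
        }
      }
      mu <- 2^stats::rnorm(1, spec$baseline_log2_mean, spec$baseline_log2_sd)
      tx_rows[[g]] <- data.frame(
        transcript_id = sprintf("%s_v%d", gid, seq_len(k)),
        gene_id = gid, tss_id = tss_ids, stringsAsFactors = FALSE)
      ab <- matrix(0, k, nrow(sheet),
                   dimnames = list(tx_rows[[g]]$transcript_id,
                                   sheet$sample_id))
      for (j in seq_len(nrow(sheet))) {
        p <- if (sheet$fraction[j] == "total") p_total else p_poly
        ab[, j] <- rnb(k, mu * p, spec$usage_phi)
      }
      ab_rows[[g]] <- ab
      truth_rows[[g]] <- data.frame(
        gene_id = gid, n_tss = k, shifted = shifted[g],
        p_total = paste(signif(p_total, 10), collapse = ","),
        p_polysomal = paste(signif(p_poly, 10), collapse = ","),
        true_jsd = jsd_bits(p_total, p_poly), stringsAsFactors = FALSE)
    }
    transcripts <- do.call(rbind, tx_rows)
    list(abundances = do.call(rbind, ab_rows),
         transcripts = transcripts, sheet = sheet,
         truth = do.call(rbind, truth_rows))
  })
}

#' Simulate a complete synthetic study
#'
#' Runs all three simulators of a \code{\link{sim_spec}} and returns their
#' outputs in one list.
#'
#' @param spec A \code{\link{sim_spec}}.
#' @return List with elements \code{counts} (from
#'   \code{\link{simulate_counts}}), \code{transcripts} (from
#'   \code{\link{simulate_transcripts}}), \code{usage} (from
#'   \code{\link{simulate_usage}}) and \code{spec}.
#' @export
simulate_dataset <- function(spec) {
  list(counts = simulate_counts(spec),
       transcripts = simulate_transcripts(spec),
       usage = simulate_usage(spec),
       spec = spec)
}

#' Write a simulated dataset to a directory
#'
#' Serialises every pipeline input plus the planted-truth tables as
#' tab-separated text (sequences as FASTA).
#'
#' @param sim Output of \code{\link{simulate_dataset}}.
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- c(counts = file.path(outdir, "counts.tsv"),
         samples = file.path(outdir, "samples.tsv"),
         fasta = file.path(outdir, "transcripts.fa"),
         table = file.path(outdir, "transcripts.tsv"),
         expr = file.path(outdir, "expr.tsv"),
         usage_table = file.path(outdir, "usage_transcripts.tsv"),
         truth_te = file.path(outdir, "truth_te.tsv"),
         truth_uorfs = file.path(outdir, "truth_uorfs.tsv"),
         truth_usage = file.path(outdir, "truth_usage.tsv"))
  write_counts(sim$counts$counts, p[["counts"]])
  write_sample_sheet(sim$counts$sheet, p[["samples"]])
  write_transcript_table(sim$transcripts$records, p[["fasta"]], p[["table"]])
  ab <- data.frame(transcript_id = rownames(sim$usage$abundances),
                   sim$usage$abundances, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_strict(ab, p[["expr"]])
  write_tsv_strict(sim$usage$transcripts, p[["usage_table"]])
  write_tsv_strict(sim$counts$truth, p[["truth_te"]])
  write_tsv_strict(sim$transcripts$truth, p[["truth_uorfs"]])
  write_tsv_strict(sim$usage$truth, p[["truth_usage"]])
  invisible(p)
}
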