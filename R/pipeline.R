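#' Assemble and validate a pipeline run configuration
#'
#' @param counts Path to the gene-by-sample count TSV.
#' @param samples Path to the sample sheet TSV.
#' @param fasta,transcript_table Paths to the transcript FASTA and table
#'   (optional; TL annotation is skipped when absent).
#' @param abundance Path to a transcript-level abundance TSV (optional;
#'   TSS-usage analysis is skipped when absent).
#' @param usage_table Path to the transcript-to-gene/TSS map for the
#'   abundance table (columns transcript_id, gene_id, tss_id). Defaults to
#'   \code{transcript_table} when the abundances cover the same transcripts.
#' @param outdir Output directory for all reports.
#' @param grouping Normalisation grouping, \code{"by-fraction"} or
#'   \code{"all"}.
#' @param bin_size,threshold,min_count,pseudocount,scale Differential-TE
#'   parameters, see \code{\link{te_analysis}}.
#' @param cap_threshold Cap-proximity threshold (nt), see
#'   \code{\link{annotate_transcripts}}.
#' @param n_perm Permutations for TSS-usage p-values (0 disables them).
#' @param seed Integer seed used for the permutation test.
#' @return Validated configuration list of class \code{run_config}.
#' @export
run_config <- function(counts, samples, fasta = NULL,
                       transcript_table = NULL, abundance = NULL,
                       usage_table = NULL,
                       outdir, grouping = "by-fraction", bin_size = 300L,
                       threshold = 2, min_count = 0, pseudocount = 0,
                       scale = "log2", cap_threshold = 15L, n_perm = 0L,
                       seed = 1L) {
  cfg <- list(counts = counts, samples = samples, fasta = fasta,
              transcript_table = transcript_table, abundance = abundance,
              usage_table = usage_table,
              outdir = outdir, grouping = grouping,
              bin_size = as.integer(bin_size), threshold = threshold,
              min_count = min_count, pseudocount = pseudocount,
              scale = scale, cap_threshold = as.integer(cap_threshold),
              n_perm = as.integer(n_perm), seed = as.integer(seed))
  stopifnot(cfg$grouping %in% c("by-fraction", "all"),
            cfg$scale %in% c("log2", "ratio"),
            cfg$bin_size >= 2L, cfg$threshold > 0, cfg$min_count >= 0,
            cfg$pseudocount >= 0, cfg$cap_threshold >= 0, cfg$n_perm >= 0)
  for (f in c("counts", "samples", "fasta", "transcript_table",
              "abundance", "usage_table")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop(sprintf("config: %s file does not exist: %s", f, cfg[[f]]))
  }
  structure(cfg, class = "run_config")
}

stage <- function(name, code) {
  tryCatch(code, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

# Reports use 1-based inclusive coordinates; internal frames are 0-based
# half-open.
uorf_report_1based <- function(uorfs) {
  data.frame(
    transcript_id = uorfs$transcript_id,
    start = uorfs$start + 1L,
    stop_last = uorfs$stop_end,   # 0-based one-past == 1-based last base
    frame = uorfs$frame,
    orf_class = uorfs$orf_class,
    n_codons = uorfs$n_codons,
    gap_to_main = uorfs$gap_to_main,
    cap_distance = uorfs$cap_distance,
    cap_proximal = uorfs$cap_proximal,
    kozak_class = uorfs$kozak_class,
    context = uorfs$context,
    stringsAsFactors = FALSE
  )
}

#' Run the full analysis pipeline on files
#'
#' Executes normalisation, differential TE, TL annotation and TSS-usage
#' analysis in order, writing one TSV report per stage plus a JSON manifest
#' recording the parameters, input checksums and package version. Reruns
#' with an identical configuration produce byte-identical reports. Any
#' stage error aborts with a stage-labelled message.
#'
#' @param config A \code{\link{run_config}}.
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  written <- character(0)

  inputs <- stage("read", {
    counts <- read_counts(config$counts)
    sheet <- read_sample_sheet(config$samples, counts)
    list(counts = counts, sheet = sheet)
  })

  norm <- stage("normalize", {
    r <- normalize_depth(inputs$counts, inputs$sheet, config$grouping)
    write_tsv_strict(r$factors, out("rescale_factors.tsv"))
    write_counts(r$counts, out("normalized.tsv"))
    written <- c(written, "rescale_factors.tsv", "normalized.tsv")
    r
  })

  te <- stage("te", {
    r <- te_analysis(norm$counts, inputs$sheet, bin_size = config$bin_size,
                     threshold = config$threshold,
                     min_count = config$min_count,
                     pseudocount = config$pseudocount, scale = config$scale)
    write_tsv_strict(r$genes, out("te_report.tsv"))
    write_tsv_strict(r$bins, out("te_bins.tsv"))
    written <- c(written, "te_report.tsv", "te_bins.tsv")
    r
  })

  tl <- NULL
  if (!is.null(config$fasta) && !is.null(config$transcript_table)) {
    tl <- stage("annotate-tl", {
      records <- read_transcript_table(config$fasta, config$transcript_table)
      r <- annotate_transcripts(records, config$cap_threshold)
      write_tsv_strict(r$transcripts, out("tl_transcripts.tsv"))
      write_tsv_strict(uorf_report_1based(r$uorfs), out("tl_uorfs.tsv"))
      written <- c(written, "tl_transcripts.tsv", "tl_uorfs.tsv")
      r
    })
  }

  tss <- NULL
  if (!is.null(config$abundance)) {
    tss <- stage("tss", {
      map_path <- if (!is.null(config$usage_table)) config$usage_table
                  else config$transcript_table
      if (is.null(map_path))
        stop("TSS-usage analysis needs a transcript-to-TSS map")
      ab_df <- read_tsv_strict(config$abundance)
      ab <- as.matrix(ab_df[-1])
      rownames(ab) <- as.character(ab_df[[1]])
      tx <- read_tsv_strict(map_path)
      r <- compute_usage(ab, tx, inputs$sheet)
      write_tsv_strict(r$usage, out("tss_usage.tsv"))
      write_tsv_strict(r$divergence, out("tss_divergence.tsv"))
      written <- c(written, "tss_usage.tsv", "tss_divergence.tsv")
      r
    })
  }

  manifest <- stage("manifest", {
    in_files <- Filter(Negate(is.null),
                       config[c("counts", "samples", "fasta",
                                "transcript_table", "abundance",
                                "usage_table")])
    m <- list(
      package = "leaderTE",
      version = as.character(utils::packageVersion("leaderTE")),
      parameters = config[c("grouping", "bin_size", "threshold",
                            "min_count", "pseudocount", "scale",
                            "cap_threshold", "n_perm", "seed")],
      inputs = lapply(in_files, function(f)
        list(path = f, md5 = unname(tools::md5sum(f)))),
      reports = sort(unique(written))
    )
    jsonlite::write_json(m, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    m
  })

  invisible(list(normalization = norm, te = te, tl = tl, tss = tss,
                 manifest = manifest))
}
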