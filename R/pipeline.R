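#' Run the full methylome analysis pipeline
#'
#' Executes, in order: (optional) read QC, CGI scanning, peak-to-feature
#' annotation, methylation density, gene-body metaprofile, CGI-methylation
#' summary, two-sample DMR calling with per-class DMR density, TSS-centered
#' k-means clustering and per-chromosome correlation diagnostics. With
#' `simulate = TRUE` (default) all inputs are generated by
#' [simulate_genome()] / [simulate_methylome()] under `config`; otherwise
#' supply file paths. All stage outputs are written as TSV/BED into
#' `out_dir` together with a JSON run manifest (parameters, seed, stage log,
#' input checksums).
#'
#' @param out_dir Output directory.
#' @param config A `sim_config` (used when `simulate = TRUE`).
#' @param simulate Generate inputs synthetically (default TRUE).
#' @param inputs When `simulate = FALSE`, a named list with paths:
#'   `genome` (FASTA), `genes` (GFF-lite), `repeats` (BED),
#'   `peaks_a`, `peaks_b`, `reads_a`, `reads_b` (BED) and optionally
#'   `fastq_1`, `fastq_2`.
#' @param k Number of k-means clusters (default 5).
#' @return Invisibly, a list with every stage's result and the manifest.
#' @export
run_pipeline <- function(out_dir, config = sim_config(), simulate = TRUE,
                         inputs = NULL, k = 5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  log_stage <- function(name, msg) {
    stages <<- c(stages, name)
    message("[", name, "] ", msg)
  }
  run <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (simulate) {
    sim <- run("simulate", simulate_genome(config))
    genome <- sim$genome; gm <- sim$gm; repeats <- sim$repeats
    ms <- run("simulate", simulate_methylome(sim))
    annotation <- ms$annotation
    peaks_a <- ms$peaks$a; peaks_b <- ms$peaks$b
    reads_a <- ms$reads$a; reads_b <- ms$reads$b
    fq1 <- ms$fastq$r1; fq2 <- ms$fastq$r2
    log_stage("simulate", sprintf("%d peaks, %d/%d reads",
              length(peaks_a), length(reads_a), length(reads_b)))
  } else {
    if (is.null(inputs)) stop("inputs required when simulate = FALSE")
    genome <- run("load", read_genome_fasta(inputs$genome))
    gm <- run("load", read_gene_models(inputs$genes))
    repeats <- run("load", read_bed(inputs$repeats, genome$seqinfo))
    annotation <- derive_features(gm, genome$seqinfo, repeats = repeats)
    peaks_a <- run("load", read_bed(inputs$peaks_a, genome$seqinfo))
    peaks_b <- run("load", read_bed(inputs$peaks_b, genome$seqinfo))
    reads_a <- run("load", read_bed(inputs$reads_a, genome$seqinfo))
    reads_b <- run("load", read_bed(inputs$reads_b, genome$seqinfo))
    fq1 <- if (!is.null(inputs$fastq_1)) read_fastq(inputs$fastq_1)
    fq2 <- if (!is.null(inputs$fastq_2)) read_fastq(inputs$fastq_2)
    log_stage("load", sprintf("%d peaks (A), %d (B)", length(peaks_a),
                              length(peaks_b)))
  }

  qc <- NULL
  if (!is.null(fq1) && !is.null(fq2)) {
    qc <- run("qc", filter_reads(fq1, fq2))
    jsonlite::write_json(unclass(qc$report),
                         file.path(out_dir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA)
    log_stage("qc", sprintf("%.1f%% clean", 100 * qc$report$clean_fraction))
  }

  cgis <- run("cgi-scan", scan_cgi(genome))
  write_bed(cgis, file.path(out_dir, "cgi.bed"))
  log_stage("cgi-scan", sprintf("%d islands", length(cgis)))

  ann_a <- run("annotate", annotate_peaks(peaks_a, annotation))
  tab1 <- rbind(A = ann_a$counts, B = annotate_peaks(peaks_b, annotation)$counts)
  write.table(data.frame(sample = rownames(tab1), tab1),
              file.path(out_dir, "peak_distribution.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("annotate", sprintf("%d peaks assigned", ann_a$counts[["total"]]))

  dens <- run("density", rbind(
    A = methylation_density(peaks_a, annotation),
    B = methylation_density(peaks_b, annotation)))
  write.table(data.frame(sample = rownames(dens), dens),
              file.path(out_dir, "methylation_density.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("density", sprintf("%d classes", ncol(dens)))

  prof <- run("metaprofile",
              gene_body_profile(peaks_a, gm, genome$seqinfo))
  write.table(data.frame(bin = seq_along(prof), density = as.numeric(prof)),
              file.path(out_dir, "gene_body_profile.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("metaprofile", sprintf("%d bins, %d genes", length(prof),
                                   attr(prof, "n_genes")))

  cgi_sum <- run("cgi-summary",
                 cgi_methylation_summary(cgis, peaks_a, annotation))
  write.table(data.frame(category = names(cgi_sum$category_counts),
                         methylated = as.numeric(cgi_sum$category_counts)),
              file.path(out_dir, "cgi_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("cgi-summary", sprintf("%.2f%% methylated",
                                   cgi_sum$percent_methylated))

  dmr <- run("dmr", call_dmrs(peaks_a, peaks_b, reads_a, reads_b))
  write.table(dmr$table, file.path(out_dir, "dmr_full.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(dmr$dmrs))
    write_bed(dmr$dmrs, file.path(out_dir, "dmr.bed"), extra_cols = TRUE)
  dmr_sum <- summarize_dmrs(dmr, annotation)
  log_stage("dmr", sprintf("%d DMRs (%d hyper / %d hypo)",
                           length(dmr$dmrs), dmr_sum$counts[["hyper"]],
                           dmr_sum$counts[["hypo"]]))

  clu_input <- if (length(dmr$dmrs) >= 1) dmr$dmrs else peaks_a
  tssm <- run("cluster", build_tss_matrix(clu_input, gm, genome$seqinfo))
  km <- run("cluster", kmeans_profiles(tssm, k = min(k, nrow(tssm)),
                                       seed = config$seed))
  write.table(data.frame(gene_id = names(km$assignments),
                         cluster = as.integer(km$assignments)),
              file.path(out_dir, "clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("cluster", sprintf("k = %d, inertia = %.3f", km$k, km$inertia))

  corr <- run("correlate",
              correlate_chromosome_stats(peaks_a, genome$seqinfo, gm))
  write.table(corr$stats, file.path(out_dir, "chromosome_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("correlate", sprintf("r(length) = %.3f, r(genes) = %.3f",
                                 corr$r_length, corr$r_genes))

  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package = "medipmap",
    version = as.character(utils::packageVersion("medipmap")),
    seed = config$seed,
    simulate = simulate,
    k = k,
    stages = stages,
    parameters = if (simulate) cfg_for_json(config) else NULL,
    output_md5 = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("manifest", sprintf("%d stages logged", length(unique(stages))))

  invisible(list(qc = qc, cgis = cgis, annotation = annotation,
                 peak_counts = tab1, density = dens, profile = prof,
                 cgi_summary = cgi_sum, dmr = dmr, dmr_summary = dmr_sum,
                 tss_matrix = tssm, clusters = km, correlation = corr,
                 manifest = manifest))
}

cfg_for_json <- function(cfg) {
  lapply(unclass(cfg), function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x)
}
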