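#' Gene models and the GFF-lite format
#'
#' A gene model is a strand-aware gene span with an ordered, disjoint exon
#' chain and an optional CDS span (absent for non-coding genes). The on-disk
#' format ("GFF-lite") is a minimal tab-separated dialect: lines
#' `chrom  feature  start  end  strand  gene_id` with `feature` one of
#' `gene`, `exon`, `CDS`; coordinates 1-based inclusive, exon/CDS lines keyed
#' to their gene line by `gene_id`. CDS is written as a single spanning
#' interval (start of first coding base to end of last).
#'
#' @param path Path to a GFF-lite file.
#' @return An object of class `gene_models`: list with `genes` (GRanges with
#'   `gene_id`, stranded), `exons` (GRangesList named by gene_id) and `cds`
#'   (named numeric matrix of CDS span start/end, NA rows for non-coding).
#' @export
read_gene_models <- function(path) {
  if (file.size(path) == 0L) return(gene_models_from_df(NULL))
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("chrom", "feature", "start", "end",
                                 "strand", "gene_id"))
  gene_models_from_df(df)
}

gene_models_from_df <- function(df) {
  if (is.null(df) || nrow(df) == 0L) {
    genes <- GenomicRanges::GRanges(gene_id = character(0))
    return(structure(list(genes = genes,
                          exons = GenomicRanges::GRangesList(),
                          cds = matrix(NA_real_, 0, 2,
                                       dimnames = list(NULL,
                                                       c("start", "end")))),
                     class = "gene_models"))
  }
  g <- df[df$feature == "gene", ]
  e <- df[df$feature == "exon", ]
  cds <- df[df$feature == "CDS", ]
  if (anyDuplicated(g$gene_id)) stop("duplicate gene_id in gene models")
  genes <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                                  strand = g$strand, gene_id = g$gene_id)
  names(genes) <- g$gene_id
  exons <- GenomicRanges::GRangesList(lapply(g$gene_id, function(id) {
    ei <- e[e$gene_id == id, , drop = FALSE]
    if (nrow(ei) == 0L)
      return(genes[id])  # single-exon default: whole span
    gr <- GenomicRanges::sort(GenomicRanges::GRanges(
      ei$chrom, IRanges::IRanges(ei$start, ei$end), strand = ei$strand))
    gr
  }))
  names(exons) <- g$gene_id
  cds_mat <- matrix(NA_real_, nrow = length(genes), ncol = 2,
                    dimnames = list(g$gene_id, c("start", "end")))
  if (nrow(cds) > 0L) {
    for (i in seq_len(nrow(cds)))
      cds_mat[cds$gene_id[i], ] <- c(cds$start[i], cds$end[i])
  }
  validate_gene_models(structure(list(genes = genes, exons = exons,
                                      cds = cds_mat), class = "gene_models"))
}

validate_gene_models <- function(gm) {
  for (id in names(gm$genes)) {
    ex <- gm$exons[[id]]
    gene <- gm$genes[id]
    if (!all(IRanges::overlapsAny(ex, gene, type = "within")))
      stop("exons of ", id, " extend beyond the gene span")
    if (length(ex) > 1L &&
        any(GenomicRanges::width(GenomicRanges::reduce(ex)) !=
            GenomicRanges::width(ex)[order(GenomicRanges::start(ex))]))
      stop("overlapping exons in ", id)
    cd <- gm$cds[id, ]
    if (!any(is.na(cd)) &&
        (cd["start"] < GenomicRanges::start(gene) ||
         cd["end"] > GenomicRanges::end(gene)))
      stop("CDS span of ", id, " outside the gene")
  }
  gm
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", length(x$genes), "gene(s),",
      sum(!is.na(x$cds[, 1])), "coding\n")
  invisible(x)
}

#' @rdname read_gene_models
#' @param gm A `gene_models` object.
#' @export
write_gene_models <- function(gm, path) {
  if (length(gm$genes) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  rows <- list()
  for (id in names(gm$genes)) {
    g <- gm$genes[id]
    ch <- as.character(GenomeInfoDb::seqnames(g))
    st <- as.character(GenomicRanges::strand(g))
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = ch, feature = "gene", start = GenomicRanges::start(g),
      end = GenomicRanges::end(g), strand = st, gene_id = id)
    ex <- gm$exons[[id]]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = ch, feature = "exon", start = GenomicRanges::start(ex),
      end = GenomicRanges::end(ex), strand = st, gene_id = id)
    cd <- gm$cds[id, ]
    if (!any(is.na(cd)))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, feature = "CDS", start = cd[["start"]],
        end = cd[["end"]], strand = st, gene_id = id)
  }
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Transcription start sites of gene models
#'
#' @param gm A `gene_models` object.
#' @return A GRanges of 1-bp TSS positions (strand-aware: gene start on `+`,
#'   gene end on `-`).
#' @export
tss_sites <- function(gm) {
  GenomicRanges::resize(gm$genes, width = 1L, fix = "start")
}
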