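#' The seven genomic feature categories
#'
#' Partition categories, in the precedence order used to resolve overlaps
#' between gene-derived categories of different genes when building the
#' disjoint genome partition: CDS > 5'UTR > 3'UTR > intron > upstream 2 kb >
#' downstream 2 kb > intergenic.
#'
#' @export
FEATURE_CATEGORIES <- c("cds", "utr5", "utr3", "intron",
                        "upstream2kb", "downstream2kb", "intergenic")

#' Repeat classes recognised in repeat tracks
#' @export
REPEAT_CLASSES <- c("LINE", "SINE", "LTR", "DNA", "satellite",
                    "simple", "low_complexity", "other")

#' Derive the disjoint genomic feature partition from gene models
#'
#' Builds, per gene: the 2-kb upstream flank before the TSS and 2-kb
#' downstream flank after the TTS (transcription orientation, clipped at
#' chromosome ends), 5'/3' UTRs (exonic sequence outside the CDS span on each
#' side), CDS (exonic sequence within the CDS span) and introns (gene span
#' minus exons). Categories from all genes are merged and made pairwise
#' disjoint by the precedence order of [FEATURE_CATEGORIES]; intergenic is the
#' genome minus everything gene-derived, so the seven categories partition the
#' genome exactly. A repeat track, when given, is kept as an independent
#' overlay (a base can be e.g. both intronic and LINE).
#'
#' @param gm A `gene_models` object.
#' @param seqinfo A [GenomeInfoDb::Seqinfo] for the genome.
#' @param flank Flank size in bp (default 2000).
#' @param repeats Optional GRanges of repeat elements with class labels in
#'   metadata column `name` (or `class`).
#' @return An object of class `feature_annotation`: list with `categories`
#'   (named [GenomicRanges::GRangesList], the disjoint partition), `repeats`
#'   (GRanges with `class` column, possibly empty) and `seqinfo`.
#' @export
derive_features <- function(gm, seqinfo, flank = 2000, repeats = NULL) {
  stopifnot(flank > 0)
  genes <- gm$genes
  lens <- GenomeInfoDb::seqlengths(seqinfo)
  chrom <- as.character(GenomeInfoDb::seqnames(genes))
  if (any(GenomicRanges::start(genes) < 1L) ||
      any(GenomicRanges::end(genes) > lens[chrom]))
    stop("gene extends beyond chromosome bounds")

  # vectorised construction of the raw (pre-precedence) category sets
  genes_u <- GenomicRanges::granges(genes)
  GenomicRanges::strand(genes_u) <- "*"
  ex_ul <- unlist(gm$exons, use.names = FALSE)
  GenomicRanges::strand(ex_ul) <- "*"
  ex_gl <- IRanges::relist(ex_ul, gm$exons)
  plus <- as.character(GenomicRanges::strand(genes)) == "+"
  coding <- !is.na(gm$cds[, "start"])
  cds_s <- gm$cds[, "start"]; cds_e <- gm$cds[, "end"]
  chrom_g <- as.character(GenomeInfoDb::seqnames(genes))
  gs <- GenomicRanges::start(genes); ge <- GenomicRanges::end(genes)

  pint <- function(gl, spans) {
    if (length(gl) == 0L)
      return(GenomicRanges::GRanges())
    out <- unlist(GenomicRanges::pintersect(gl, spans,
                                            drop.nohit.ranges = TRUE),
                  use.names = FALSE)
    S4Vectors::mcols(out) <- NULL
    out
  }
  span_gr <- function(sel, s, e) GenomicRanges::GRanges(
    chrom_g[sel], IRanges::IRanges(s[sel], e[sel]))

  cds_cat <- pint(ex_gl[coding], span_gr(coding, cds_s, cds_e))
  # UTR = exonic sequence outside the CDS on each side; 5' side is the gene
  # start for + genes, the gene end for - genes
  sel_l <- coding & cds_s > gs
  sel_r <- coding & cds_e < ge
  left_utr <- function(sel) pint(ex_gl[sel],
                                 span_gr(sel, gs, pmax(gs, cds_s - 1)))
  right_utr <- function(sel) pint(ex_gl[sel],
                                  span_gr(sel, pmin(ge, cds_e + 1), ge))
  noncoding_ex <- if (any(!coding))
    unlist(ex_gl[!coding], use.names = FALSE) else GenomicRanges::GRanges()
  utr5 <- c(left_utr(sel_l & plus), right_utr(sel_r & !plus), noncoding_ex)
  utr3 <- c(right_utr(sel_r & plus), left_utr(sel_l & !plus))

  raw <- list(
    cds = list(cds_cat),
    utr5 = list(utr5),
    utr3 = list(utr3),
    intron = list(unlist(GenomicRanges::psetdiff(genes_u, ex_gl),
                         use.names = FALSE)),
    upstream2kb = list(GenomicRanges::granges(
      GenomicRanges::flank(genes, width = flank, start = TRUE))),
    downstream2kb = list(GenomicRanges::granges(
      GenomicRanges::flank(genes, width = flank, start = FALSE))))

  collapse <- function(lst) {
    lst <- Filter(function(x) length(x) > 0, lst)
    if (length(lst) == 0L)
      return(GenomicRanges::GRanges(seqinfo = seqinfo))
    gr <- do.call(c, unname(lapply(lst, function(x) {
      GenomicRanges::strand(x) <- "*"
      names(x) <- NULL
      S4Vectors::mcols(x) <- NULL
      # clip flanks at chromosome edges before attaching seqinfo
      len <- lens[as.character(GenomeInfoDb::seqnames(x))]
      s <- pmax(GenomicRanges::start(x), 1L)
      e <- pmin(GenomicRanges::end(x), len)
      keep <- s <= e
      GenomicRanges::GRanges(GenomeInfoDb::seqnames(x)[keep],
                             IRanges::IRanges(s[keep], e[keep]))
    })))
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(seqinfo)
    GenomeInfoDb::seqinfo(gr) <- seqinfo
    GenomicRanges::reduce(GenomicRanges::sort(gr))
  }

  cats <- list()
  taken <- GenomicRanges::GRanges(seqinfo = seqinfo)
  for (cat in setdiff(FEATURE_CATEGORIES, "intergenic")) {
    merged <- collapse(raw[[cat]])
    cats[[cat]] <- GenomicRanges::setdiff(merged, taken, ignore.strand = TRUE)
    taken <- GenomicRanges::reduce(GenomicRanges::union(taken, merged,
                                                        ignore.strand = TRUE))
  }
  cats$intergenic <- GenomicRanges::setdiff(genome_ranges(seqinfo), taken,
                                            ignore.strand = TRUE)
  cats <- cats[FEATURE_CATEGORIES]

  rep_gr <- GenomicRanges::GRanges(seqinfo = seqinfo)
  if (!is.null(repeats) && length(repeats) > 0) {
    cls <- if ("class" %in% names(S4Vectors::mcols(repeats)))
      repeats$class else repeats$name
    if (is.null(cls)) stop("repeat track must carry class labels")
    rep_gr <- GenomicRanges::granges(repeats)
    GenomeInfoDb::seqlevels(rep_gr) <- GenomeInfoDb::seqnames(seqinfo)
    GenomeInfoDb::seqinfo(rep_gr) <- seqinfo
    rep_gr$class <- ifelse(cls %in% REPEAT_CLASSES, cls, "other")
  }

  structure(list(categories = GenomicRanges::GRangesList(cats),
                 repeats = rep_gr, seqinfo = seqinfo),
            class = "feature_annotation")
}

#' @export
print.feature_annotation <- function(x, ...) {
  w <- vapply(x$categories, function(g) sum(as.numeric(GenomicRanges::width(g))),
              numeric(1))
  cat("feature_annotation over",
      format(sum(as.numeric(GenomeInfoDb::seqlengths(x$seqinfo))),
             big.mark = ","), "bp\n")
  print(round(w / sum(w), 4))
  if (length(x$repeats)) cat("repeat overlay:", length(x$repeats), "elements\n")
  invisible(x)
}

# total bp in a GRanges (after merge)
total_bp <- function(gr) {
  sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(gr,
                                                            ignore.strand = TRUE))))
}
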