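#' Assign methylation peaks to genomic feature categories
#'
#' A peak belongs to a category when at least half of its length overlaps that
#' category (the "50% rule"). Because the seven partition categories are
#' disjoint, a peak can reach 50% in at most one of them, except for an exact
#' 50/50 split, which is resolved by the precedence order of
#' [FEATURE_CATEGORIES]. The repeat track is an independent overlay: the same
#' peak may additionally count as a repeat peak (aggregate and per repeat
#' class), so repeat counts are peak-repeat-class incidences and may exceed
#' the total peak number.
#'
#' @param peaks GRanges of methylation peaks.
#' @param annotation A `feature_annotation` from [derive_features()].
#' @param min_frac Minimum fraction of the peak overlapping a category
#'   (default 0.5).
#' @return An object of class `peak_annotation`: list with `assignment`
#'   (character vector, one partition category or NA per peak), `in_repeats`
#'   (logical per peak), `repeat_class_hits` (logical matrix peaks x repeat
#'   classes) and `counts` (named vector in Table-1 column order: total, the
#'   seven categories, repeats).
#' @export
annotate_peaks <- function(peaks, annotation, min_frac = 0.5) {
  stopifnot(is(annotation, "feature_annotation"))
  check_in_genome(peaks, annotation$seqinfo)
  n <- length(peaks)
  w <- GenomicRanges::width(peaks)

  ov_bp <- vapply(FEATURE_CATEGORIES, function(cat)
    overlap_bp_per_query(peaks, annotation$categories[[cat]]), numeric(n))
  ov_bp <- matrix(ov_bp, nrow = n,
                  dimnames = list(NULL, FEATURE_CATEGORIES))
  hit <- ov_bp >= min_frac * w
  assignment <- rep(NA_character_, n)
  for (cat in FEATURE_CATEGORIES) {           # precedence resolves 50/50 ties
    take <- is.na(assignment) & hit[, cat]
    assignment[take] <- cat
  }

  rep_union <- GenomicRanges::reduce(annotation$repeats, ignore.strand = TRUE)
  in_repeats <- overlap_bp_per_query(peaks, rep_union) >= min_frac * w
  rep_hits <- matrix(FALSE, n, length(REPEAT_CLASSES),
                     dimnames = list(NULL, REPEAT_CLASSES))
  if (length(annotation$repeats) > 0) {
    for (cl in unique(annotation$repeats$class)) {
      cl_gr <- annotation$repeats[annotation$repeats$class == cl]
      rep_hits[, cl] <- overlap_bp_per_query(peaks, cl_gr) >= min_frac * w
    }
  }

  counts <- c(total = n,
              vapply(FEATURE_CATEGORIES, function(cat)
                sum(assignment == cat, na.rm = TRUE), numeric(1)),
              repeats = sum(in_repeats),
              repeat_incidences = sum(rep_hits))
  structure(list(assignment = assignment, in_repeats = in_repeats,
                 repeat_class_hits = rep_hits, counts = counts),
            class = "peak_annotation")
}

#' @export
print.peak_annotation <- function(x, ...) {
  cat("peak_annotation:\n")
  print(x$counts)
  invisible(x)
}

#' Methylation density per feature or repeat class
#'
#' Density of a class = total peak base pairs overlapping the class divided
#' by the total base pairs of the class (peaks are merged first, so the value
#' is a coverage fraction in \[0, 1\] and invariant to peak fragmentation).
#' The pseudo-class `genome` gives the overall genome coverage fraction of
#' the peak set. Classes with zero area are reported as NA.
#'
#' @param peaks GRanges of methylation peaks.
#' @param annotation A `feature_annotation`.
#' @param classes Character vector of classes: any of [FEATURE_CATEGORIES],
#'   repeat classes present in the annotation, `"repeats"` (all repeats) and
#'   `"genome"`. Default: the seven categories plus genome and any repeat
#'   classes present.
#' @return Named numeric vector of densities.
#' @export
methylation_density <- function(peaks, annotation, classes = NULL) {
  stopifnot(is(annotation, "feature_annotation"))
  merged <- GenomicRanges::reduce(GenomicRanges::granges(peaks),
                                  ignore.strand = TRUE)
  present_rep <- if (length(annotation$repeats))
    unique(annotation$repeats$class) else character(0)
  if (is.null(classes))
    classes <- c(FEATURE_CATEGORIES, "genome",
                 if (length(present_rep)) "repeats", present_rep)
  class_gr <- function(cl) {
    if (cl %in% FEATURE_CATEGORIES) return(annotation$categories[[cl]])
    if (cl == "genome") return(genome_ranges(annotation$seqinfo))
    if (cl == "repeats")
      return(GenomicRanges::reduce(annotation$repeats, ignore.strand = TRUE))
    if (cl %in% present_rep)
      return(GenomicRanges::reduce(
        annotation$repeats[annotation$repeats$class == cl],
        ignore.strand = TRUE))
    stop("unknown class: ", cl)
  }
  vapply(classes, function(cl) {
    gr <- class_gr(cl)
    area <- total_bp(gr)
    if (area == 0) return(NA_real_)
    total_bp(GenomicRanges::intersect(merged, gr, ignore.strand = TRUE)) / area
  }, numeric(1))
}

#' Gene-body methylation metaprofile
#'
#' Mean peak-coverage fraction in fixed bins around and across gene bodies:
#' `flank/flank_bin` absolute bins upstream of the TSS, `body_bins` equal
#' relative bins across the gene body, and `flank/flank_bin` absolute bins
#' downstream of the TTS, orientation-flipped for minus-strand genes so the
#' first bin is always most upstream. Genes shorter than `body_bins` bp are
#' skipped (and counted in the `n_skipped` attribute).
#'
#' @param peaks GRanges of peaks (merged internally).
#' @param gm A `gene_models` object.
#' @param seqinfo Genome [GenomeInfoDb::Seqinfo] used to clip flank bins.
#' @param flank Flank size in bp (default 2000).
#' @param body_bins Number of relative bins across the gene body (default 40).
#' @param flank_bin Width of the absolute flank bins in bp (default 100).
#' @return Numeric vector of per-bin mean coverage fractions (length
#'   `2 * flank / flank_bin + body_bins`), with attributes `n_genes` and
#'   `n_skipped`.
#' @export
gene_body_profile <- function(peaks, gm, seqinfo, flank = 2000,
                              body_bins = 40, flank_bin = 100) {
  stopifnot(flank > 0, body_bins >= 1, flank %% flank_bin == 0)
  nfl <- flank %/% flank_bin
  nb <- 2L * nfl + body_bins
  merged <- GenomicRanges::reduce(GenomicRanges::granges(peaks),
                                  ignore.strand = TRUE)
  lens <- GenomeInfoDb::seqlengths(seqinfo)
  acc <- matrix(0, nrow = 0, ncol = nb)
  skipped <- 0L
  rows <- list()
  for (id in names(gm$genes)) {
    g <- gm$genes[id]
    if (GenomicRanges::width(g) < body_bins) { skipped <- skipped + 1L; next }
    rows[[id]] <- gene_bin_cover(g, merged, lens, flank, body_bins, flank_bin)
  }
  prof <- if (length(rows)) colMeans(do.call(rbind, rows)) else rep(0, nb)
  attr(prof, "n_genes") <- length(rows)
  attr(prof, "n_skipped") <- skipped
  prof
}

# coverage fraction per bin for one gene; bins ordered 5'->3' in
# transcription orientation
gene_bin_cover <- function(g, merged, lens, flank, body_bins, flank_bin) {
  chrom <- as.character(GenomeInfoDb::seqnames(g))
  s <- GenomicRanges::start(g); e <- GenomicRanges::end(g)
  plus <- as.character(GenomicRanges::strand(g)) == "+"
  nfl <- flank %/% flank_bin

  up_edges <- (s - flank) + flank_bin * (0:nfl)            # genomic left flank
  dn_edges <- e + flank_bin * (0:nfl)                      # genomic right flank
  body_edges <- s - 1 + round((e - s + 1) * (0:body_bins) / body_bins)

  bin_df <- rbind(
    data.frame(start = up_edges[-length(up_edges)], end = up_edges[-1] - 1),
    data.frame(start = body_edges[-length(body_edges)] + 1, end = body_edges[-1]),
    data.frame(start = dn_edges[-length(dn_edges)] + 1, end = dn_edges[-1]))
  # clip to chromosome; bins falling fully outside contribute 0
  width0 <- bin_df$end - bin_df$start + 1
  cs <- pmax(bin_df$start, 1); ce <- pmin(bin_df$end, lens[chrom])
  frac <- numeric(nrow(bin_df))
  ok <- cs <= ce
  if (any(ok)) {
    bins <- GenomicRanges::GRanges(chrom, IRanges::IRanges(cs[ok], ce[ok]))
    cov <- overlap_bp_per_query(bins, merged)
    frac[ok] <- cov / width0[ok]
  }
  if (plus) frac else rev(frac)
}

#' Percent of methylated CpG islands
#'
#' @param methylated Number of methylated CGIs.
#' @param total Total number of CGIs.
#' @return Percentage, rounded to 2 decimals.
#' @export
cgi_percent <- function(methylated, total) {
  stopifnot(total > 0, methylated >= 0, methylated <= total)
  round(100 * methylated / total, 2)
}

#' Summarise CpG-island methylation
#'
#' A CGI is called methylated when at least `min_overlap_frac` of it (default:
#' any single bp) overlaps a methylation peak. Each methylated CGI is
#' attributed to one genic partition category by the 50%-of-CGI rule; CGIs
#' reaching 50% in no genic category (including intergenic ones) are counted
#' as `other`.
#'
#' @param cgis GRanges of CpG islands (e.g. from [scan_cgi()]).
#' @param peaks GRanges of methylation peaks.
#' @param annotation A `feature_annotation`.
#' @param min_overlap_frac Fraction of the CGI that must overlap peaks to call
#'   it methylated; 0 means any overlap of at least 1 bp (default).
#' @return Object of class `cgi_summary`: list with `category_counts` (named,
#'   six genic categories plus other), `total_methylated`, `total_cgis`,
#'   `percent_methylated` (2 decimals) and the per-CGI logical `methylated`.
#' @export
cgi_methylation_summary <- function(cgis, peaks, annotation,
                                    min_overlap_frac = 0) {
  stopifnot(is(annotation, "feature_annotation"))
  n <- length(cgis)
  merged <- GenomicRanges::reduce(GenomicRanges::granges(peaks),
                                  ignore.strand = TRUE)
  ov <- overlap_bp_per_query(cgis, merged)
  meth <- if (min_overlap_frac > 0)
    ov >= min_overlap_frac * GenomicRanges::width(cgis) else ov >= 1

  genic <- setdiff(FEATURE_CATEGORIES, "intergenic")
  cat_assign <- rep("other", n)
  if (n > 0) {
    w <- GenomicRanges::width(cgis)
    for (cat in genic) {
      bp <- overlap_bp_per_query(cgis, annotation$categories[[cat]])
      take <- cat_assign == "other" & bp >= 0.5 * w
      cat_assign[take] <- cat
    }
  }
  cats <- c(genic, "other")
  counts <- vapply(cats, function(cc) sum(meth & cat_assign == cc), numeric(1))
  structure(list(category_counts = counts,
                 total_methylated = sum(meth),
                 total_cgis = n,
                 percent_methylated = if (n > 0) cgi_percent(sum(meth), n)
                                      else 0,
                 methylated = meth),
            class = "cgi_summary")
}

#' @export
print.cgi_summary <- function(x, ...) {
  cat("cgi_summary:", x$total_methylated, "of", x$total_cgis,
      "CGIs methylated (", sprintf("%.2f", x$percent_methylated), "%)\n")
  print(x$category_counts)
  invisible(x)
}

# ---- shared interval helpers -------------------------------------------

# bp of each query range covered by the (merged) subject set
overlap_bp_per_query <- function(query, subject) {
  if (length(query) == 0L) return(numeric(0))
  subject <- GenomicRanges::reduce(GenomicRanges::granges(subject),
                                   ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(query, subject, ignore.strand = TRUE)
  if (length(hits) == 0L) return(numeric(length(query)))
  inter <- GenomicRanges::pintersect(
    GenomicRanges::granges(query)[S4Vectors::queryHits(hits)],
    subject[S4Vectors::subjectHits(hits)], ignore.strand = TRUE)
  bp <- tapply(GenomicRanges::width(inter), S4Vectors::queryHits(hits), sum)
  out <- numeric(length(query))
  out[as.integer(names(bp))] <- bp
  out
}

check_in_genome <- function(gr, seqinfo) {
  lens <- GenomeInfoDb::seqlengths(seqinfo)
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  if (!all(chrom %in% names(lens)))
    stop("intervals on unknown chromosome(s)")
  if (any(GenomicRanges::start(gr) < 1L) ||
      any(GenomicRanges::end(gr) > lens[chrom]))
    stop("interval outside genome bounds")
  invisible(TRUE)
}
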