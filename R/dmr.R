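#' Merge the peak sets of two samples
#'
#' Returns the connected components of the union of both peak sets:
#' overlapping or book-ended peaks are joined; output is sorted and disjoint.
#'
#' @param peaks_a,peaks_b GRanges of peaks for the two samples.
#' @return A sorted, disjoint GRanges.
#' @export
merge_peak_sets <- function(peaks_a, peaks_b) {
  GenomicRanges::reduce(GenomicRanges::sort(c(
    GenomicRanges::granges(peaks_a), GenomicRanges::granges(peaks_b))),
    ignore.strand = TRUE)
}

#' Count reads in regions
#'
#' A read is counted toward a region when at least `min_overlap_frac` of the
#' read overlaps it; each read is counted at most once, toward the region of
#' maximal overlap (ties broken by region coordinate order).
#'
#' @param regions Disjoint GRanges of regions.
#' @param reads GRanges of read alignment intervals.
#' @param min_overlap_frac Minimum fraction of the read length that must
#'   overlap (default 0.5).
#' @return Integer vector of counts, one per region.
#' @export
count_reads <- function(regions, reads, min_overlap_frac = 0.5) {
  n <- length(regions)
  if (length(reads) == 0L || n == 0L) return(integer(n))
  hits <- GenomicRanges::findOverlaps(reads, regions, ignore.strand = TRUE)
  if (length(hits) == 0L) return(integer(n))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    GenomicRanges::granges(reads)[qh], regions[sh], ignore.strand = TRUE))
  ok <- ov >= min_overlap_frac * GenomicRanges::width(reads)[qh]
  qh <- qh[ok]; sh <- sh[ok]; ov <- ov[ok]
  if (length(qh) == 0L) return(integer(n))
  # per read: region of maximal overlap, first region on ties
  o <- order(qh, -ov, sh)
  first <- !duplicated(qh[o])
  tabulate(sh[o][first], nbins = n)
}

#' Chi-square test of two-sample read counts in regions
#'
#' For each region, a 2x2 chi-square (1 df, no continuity correction) on
#' \[\[count_a, total_a - count_a\], \[count_b, total_b - count_b\]\]. The
#' fold-change is computed on library-size-normalised rates,
#' (count_a/total_a) / (count_b/total_b), with a pseudocount of 0.5 replacing
#' zero counts for the fold only (never for the chi-square). Set
#' `normalize = FALSE` to compare raw read numbers instead (fold =
#' count_a/count_b).
#'
#' @param count_a,count_b Integer vectors of per-region read counts.
#' @param total_a,total_b Library sizes (total mapped reads per sample).
#' @param normalize Library-size-normalise the fold-change (default TRUE).
#' @return data.frame with columns `count_a`, `count_b`, `chi2`, `p`, `fold`,
#'   `direction` ("hyper" when sample A's normalised rate exceeds B's,
#'   "hypo" otherwise).
#' @export
test_regions <- function(count_a, count_b, total_a, total_b,
                         normalize = TRUE) {
  stopifnot(length(count_a) == length(count_b), total_a > 0, total_b > 0,
            all(count_a <= total_a), all(count_b <= total_b))
  a <- as.numeric(count_a); c_ <- as.numeric(count_b)
  b <- total_a - a; d <- total_b - c_
  n <- total_a + total_b
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  chi2 <- ifelse(denom > 0, n * (a * d - b * c_)^2 / denom, 0)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  fa <- ifelse(a == 0, 0.5, a)
  fb <- ifelse(c_ == 0, 0.5, c_)
  fold <- if (normalize) (fa / total_a) / (fb / total_b) else fa / fb
  rate_a <- a / total_a; rate_b <- c_ / total_b
  direction <- ifelse(if (normalize) rate_a > rate_b else a > c_,
                      "hyper", "hypo")
  data.frame(count_a = count_a, count_b = count_b, chi2 = chi2, p = p,
             fold = fold, direction = direction)
}

#' Call differentially methylated regions between two samples
#'
#' Pipeline: merge both samples' peaks into candidate regions
#' ([merge_peak_sets()]), count reads of each sample per region
#' ([count_reads()]), test each region with a 2x2 chi-square
#' ([test_regions()]), adjust p-values across all tested regions by
#' Benjamini-Hochberg, and retain regions with adjusted `q < alpha` and a
#' normalised fold-change above `min_fold` in either direction
#' (strictly greater than). Regions with fewer than `min_count` reads
#' combined are dropped before testing (chi-square invalid) and reported.
#'
#' @param peaks_a,peaks_b GRanges of peaks per sample.
#' @param reads_a,reads_b GRanges of read alignment intervals per sample.
#' @param alpha Significance threshold on the BH-adjusted q (default 0.05).
#' @param min_fold DMRs require `max(fold, 1/fold) > min_fold` (default 2).
#' @param min_count Minimum combined read count to test a region (default 5).
#' @param min_overlap_frac Read-in-region overlap fraction (default 0.5).
#' @param normalize Library-size-normalise fold-changes (default TRUE).
#' @param use_raw_p Threshold the raw p instead of the BH q (default FALSE).
#' @return Object of class `dmr_result`: list with `dmrs` (GRanges of
#'   selected DMRs with count/statistic metadata and `direction`), `table`
#'   (the full per-region data.frame including non-significant regions),
#'   `n_regions`, `n_tested`, `n_dropped_low_count`, `totals` and the
#'   parameters used.
#' @export
call_dmrs <- function(peaks_a, peaks_b, reads_a, reads_b, alpha = 0.05,
                      min_fold = 2.0, min_count = 5,
                      min_overlap_frac = 0.5, normalize = TRUE,
                      use_raw_p = FALSE) {
  regions <- merge_peak_sets(peaks_a, peaks_b)
  total_a <- length(reads_a); total_b <- length(reads_b)
  if (total_a == 0L || total_b == 0L)
    stop("zero total reads in a sample")
  count_a <- count_reads(regions, reads_a, min_overlap_frac)
  count_b <- count_reads(regions, reads_b, min_overlap_frac)

  testable <- count_a + count_b >= min_count
  tab <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(regions)),
                    start = GenomicRanges::start(regions),
                    end = GenomicRanges::end(regions),
                    count_a = count_a, count_b = count_b,
                    tested = testable,
                    chi2 = NA_real_, p = NA_real_, q = NA_real_,
                    fold = NA_real_, direction = NA_character_,
                    is_dmr = FALSE)
  if (any(testable)) {
    tst <- test_regions(count_a[testable], count_b[testable],
                        total_a, total_b, normalize = normalize)
    tab$chi2[testable] <- tst$chi2
    tab$p[testable] <- tst$p
    tab$q[testable] <- stats::p.adjust(tst$p, method = "BH")
    tab$fold[testable] <- tst$fold
    tab$direction[testable] <- tst$direction
    sel_p <- if (use_raw_p) tab$p else tab$q
    tab$is_dmr <- testable & sel_p < alpha &
      pmax(tab$fold, 1 / tab$fold) > min_fold
    tab$is_dmr[is.na(tab$is_dmr)] <- FALSE
  }

  dmrs <- regions[tab$is_dmr]
  if (length(dmrs)) {
    sub <- tab[tab$is_dmr, ]
    S4Vectors::mcols(dmrs) <- S4Vectors::DataFrame(
      name = sub$direction,
      score = pmin(round(-10 * log10(pmax(sub$q, 1e-100))), 1000),
      count_a = sub$count_a, count_b = sub$count_b,
      fold = sub$fold, p = sub$p, q = sub$q, direction = sub$direction)
  }
  structure(list(dmrs = dmrs, table = tab,
                 n_regions = length(regions), n_tested = sum(testable),
                 n_dropped_low_count = sum(!testable),
                 totals = c(a = total_a, b = total_b),
                 params = list(alpha = alpha, min_fold = min_fold,
                               min_count = min_count,
                               min_overlap_frac = min_overlap_frac,
                               normalize = normalize,
                               use_raw_p = use_raw_p,
                               fdr_method = "BH")),
            class = "dmr_result")
}

#' @export
print.dmr_result <- function(x, ...) {
  cat("dmr_result:", length(x$dmrs), "DMRs from", x$n_tested, "tested of",
      x$n_regions, "merged regions (",
      x$n_dropped_low_count, "dropped, <", x$params$min_count, "reads)\n")
  if (length(x$dmrs))
    print(table(x$dmrs$direction))
  invisible(x)
}

#' Summarise DMRs by direction and genomic class
#'
#' Counts hyper- and hypomethylated DMRs and computes DMR density (DMR bp in
#' class / class bp, the same coverage-fraction definition used for peaks)
#' per genomic class and per repeat class, separately for each direction.
#'
#' @param dmr A `dmr_result` from [call_dmrs()] (or a GRanges of DMRs with a
#'   `direction` metadata column).
#' @param annotation A `feature_annotation`.
#' @param classes Classes to report (default: intergenic, gene body classes,
#'   promoter-like upstream flank, and repeat classes present).
#' @return List with `counts` (hyper/hypo) and `density` (matrix
#'   classes x \{hyper, hypo\}).
#' @export
summarize_dmrs <- function(dmr, annotation, classes = NULL) {
  gr <- if (is(dmr, "dmr_result")) dmr$dmrs else dmr
  if (is.null(classes)) {
    present_rep <- if (length(annotation$repeats))
      unique(annotation$repeats$class) else character(0)
    classes <- c(FEATURE_CATEGORIES, present_rep)
  }
  counts <- c(hyper = sum(gr$direction == "hyper"),
              hypo = sum(gr$direction == "hypo"))
  dens <- sapply(c("hyper", "hypo"), function(dir) {
    sub <- gr[gr$direction == dir]
    methylation_density(sub, annotation, classes = classes)
  })
  if (is.null(dim(dens)))
    dens <- matrix(dens, ncol = 2, dimnames = list(classes, c("hyper", "hypo")))
  list(counts = counts, density = dens)
}
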