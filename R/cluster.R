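#' Build a TSS-centered signal matrix
#'
#' One row per gene, fixed-width bins spanning TSS +/- `window`; the value of
#' a bin is the fraction of its bases covered by the (merged) intervals.
#' Minus-strand rows are reversed so column 1 is always most upstream. Bins
#' extending beyond chromosome ends contribute their out-of-bounds bases as
#' uncovered.
#'
#' @param intervals GRanges of signal intervals (DMRs or peaks).
#' @param gm A `gene_models` object.
#' @param seqinfo Genome [GenomeInfoDb::Seqinfo].
#' @param window Half-window around the TSS in bp (default 5000).
#' @param bin_width Bin width in bp (default 100; must divide `window`).
#' @return Numeric matrix genes x (2*window/bin_width) with gene ids as row
#'   names.
#' @export
build_tss_matrix <- function(intervals, gm, seqinfo, window = 5000,
                             bin_width = 100) {
  if (window %% bin_width != 0) stop("window must be divisible by bin_width")
  nb <- 2L * window %/% bin_width
  merged <- GenomicRanges::reduce(GenomicRanges::granges(intervals),
                                  ignore.strand = TRUE)
  lens <- GenomeInfoDb::seqlengths(seqinfo)
  tss <- tss_sites(gm)
  mat <- matrix(0, nrow = length(tss), ncol = nb,
                dimnames = list(names(gm$genes), NULL))
  for (i in seq_along(tss)) {
    chrom <- as.character(GenomeInfoDb::seqnames(tss))[i]
    pos <- GenomicRanges::start(tss)[i]
    minus <- as.character(GenomicRanges::strand(tss))[i] == "-"
    # [TSS-window, TSS+window-1] on +; the mirror image on - so that a
    # reflected gene/interval pair yields identical rows
    off <- if (minus) pos - window + 1 else pos - window
    edges <- off + bin_width * (0:nb)              # genomic left -> right
    bs <- edges[-length(edges)]; be <- edges[-1] - 1
    cs <- pmax(bs, 1); ce <- pmin(be, lens[chrom])
    frac <- numeric(nb)
    ok <- cs <= ce
    if (any(ok)) {
      bins <- GenomicRanges::GRanges(chrom, IRanges::IRanges(cs[ok], ce[ok]))
      frac[ok] <- overlap_bp_per_query(bins, merged) / bin_width
    }
    if (minus) frac <- rev(frac)
    mat[i, ] <- frac
  }
  mat
}

#' k-means clustering of TSS-centered profiles
#'
#' Lloyd's algorithm with k-means++ initialisation, best of `n_init` restarts
#' by within-cluster sum of squares (inertia). Deterministic under a fixed
#' seed. An empty cluster arising during iteration is repaired by re-seeding
#' its centroid with the point farthest from the centroid of the largest
#' cluster.
#'
#' @param mat Numeric matrix (rows = genes, columns = bins).
#' @param k Number of clusters (default 5).
#' @param seed Random seed.
#' @param n_init Number of restarts (default 25; cheap relative to the
#'   matrix sizes involved, and small instances have many local minima).
#' @param max_iter Maximum Lloyd iterations per restart (default 300).
#' @return Object of class `kmeans_profiles`: list with `k`, `assignments`
#'   (named integer vector), `centroids` (k x bins matrix), `inertia`,
#'   `iter`, `seed`.
#' @export
kmeans_profiles <- function(mat, k = 5, seed = 1, n_init = 25,
                            max_iter = 300) {
  stopifnot(k >= 1, is.matrix(mat))
  if (k > nrow(mat)) stop("k exceeds the number of rows")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_init)) {
      res <- lloyd_once(mat, k, max_iter)
      if (is.null(best) || res$inertia < best$inertia) best <- res
    }
  })
  structure(list(k = k, assignments = stats::setNames(best$assign,
                                                      rownames(mat)),
                 centroids = best$centers, inertia = best$inertia,
                 iter = best$iter, seed = seed),
            class = "kmeans_profiles")
}

#' @export
print.kmeans_profiles <- function(x, ...) {
  cat("kmeans_profiles: k =", x$k, "inertia =", signif(x$inertia, 6), "\n")
  print(table(x$assignments))
  invisible(x)
}

# squared euclidean distances rows of m to rows of centers
sq_dist_to <- function(m, centers) {
  d2 <- outer(rowSums(m^2), rowSums(centers^2), "+") - 2 * m %*% t(centers)
  pmax(d2, 0)
}

lloyd_once <- function(mat, k, max_iter) {
  n <- nrow(mat)
  # k-means++ seeding
  centers <- mat[sample.int(n, 1L), , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- apply(sq_dist_to(mat, centers), 1, min)
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers <- rbind(centers, mat[sample.int(n, 1L, prob = probs), ,
                                  drop = FALSE])
  }
  assign <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- sq_dist_to(mat, centers)
    new_assign <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {
      if (!any(new_assign == j)) {      # empty-cluster repair
        big <- which.max(tabulate(new_assign, k))
        members <- which(new_assign == big)
        far <- members[which.max(d2[cbind(members, big)])]
        new_assign[far] <- j
      }
    }
    changed <- !identical(new_assign, assign)
    assign <- new_assign
    for (j in seq_len(k))
      centers[j, ] <- colMeans(mat[assign == j, , drop = FALSE])
    if (!changed && it > 1L) break
  }
  d2 <- sq_dist_to(mat, centers)
  inertia <- sum(d2[cbind(seq_len(n), assign)])
  list(assign = assign, centers = centers, inertia = inertia, iter = it)
}

#' Per-chromosome correlation of peak counts with length and gene number
#'
#' Counts methylation peaks per chromosome and reports Pearson's r between
#' peak count and chromosome length, and between peak count and gene number.
#'
#' @param peaks GRanges of peaks.
#' @param seqinfo Genome [GenomeInfoDb::Seqinfo] (at least 3 chromosomes).
#' @param gm A `gene_models` object.
#' @return List with `r_length`, `r_genes`, `n` (number of chromosomes) and
#'   the per-chromosome data.frame `stats`.
#' @export
correlate_chromosome_stats <- function(peaks, seqinfo, gm) {
  chroms <- GenomeInfoDb::seqnames(seqinfo)
  if (length(chroms) < 3) stop("need at least 3 chromosomes")
  pk <- table(factor(as.character(GenomeInfoDb::seqnames(peaks)),
                     levels = chroms))
  gn <- table(factor(as.character(GenomeInfoDb::seqnames(gm$genes)),
                     levels = chroms))
  len <- as.numeric(GenomeInfoDb::seqlengths(seqinfo))
  if (stats::sd(pk) == 0 || stats::sd(len) == 0 || stats::sd(gn) == 0)
    stop("zero variance in peak counts, lengths or gene counts")
  df <- data.frame(chrom = as.character(chroms), length = len,
                   n_peaks = as.numeric(pk), n_genes = as.numeric(gn))
  list(r_length = stats::cor(df$n_peaks, df$length),
       r_genes = stats::cor(df$n_peaks, df$n_genes),
       n = nrow(df), stats = df)
}
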