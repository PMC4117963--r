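#' Scan a genome for CpG islands
#'
#' Sliding-window CpG-island detection under the three classical criteria:
#' length greater than 200 bp, GC content of at least 50%, and CpG
#' observed/expected ratio of at least 0.6, where
#' O/E = (#CpG x N) / (#C x #G) over the N non-N bases of the window.
#'
#' A 200-bp window slides at 1-bp steps; every window meeting the GC and O/E
#' thresholds is marked, overlapping or book-ended qualifying windows are
#' merged, merged regions not longer than 200 bp are discarded, and each
#' remaining region is re-verified against all three criteria on its full
#' extent. A region failing re-verification is trimmed 1 bp at a time,
#' alternating left and right ends, until it satisfies the criteria or shrinks
#' to 200 bp (then discarded). N bases are excluded from the denominator N;
#' windows that are more than half N are disqualified.
#'
#' @param genome A `medip_genome` from [read_genome_fasta()].
#' @param window Window size in bp (default 200; also the minimum length).
#' @param min_gc Minimum GC fraction (default 0.5).
#' @param min_oe Minimum CpG observed/expected ratio (default 0.6).
#' @return A [GenomicRanges::GRanges] of islands sorted by coordinate, with
#'   metadata columns `gc_fraction` and `obs_exp` computed on the reported
#'   interval.
#' @export
scan_cgi <- function(genome, window = 200L, min_gc = 0.5, min_oe = 0.6) {
  stopifnot(is(genome, "medip_genome"))
  res <- list()
  for (chrom in names(genome$seq)) {
    seq <- genome$seq[[chrom]]
    if (length(seq) < window) next
    ir <- scan_cgi_one(seq, window, min_gc, min_oe)
    if (nrow(ir) == 0L) next
    res[[chrom]] <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(ir$start, ir$end),
      gc_fraction = ir$gc, obs_exp = ir$oe, seqinfo = genome$seqinfo)
  }
  if (length(res) == 0L)
    return(GenomicRanges::GRanges(seqinfo = genome$seqinfo,
                                  gc_fraction = numeric(0),
                                  obs_exp = numeric(0)))
  GenomicRanges::sort(do.call(c, unname(res)))
}

# Per-chromosome scan; returns data.frame(start, end, gc, oe) in 1-based
# closed coordinates.
scan_cgi_one <- function(seq, window, min_gc, min_oe) {
  L <- length(seq)
  # per-position indicators, cumulated for O(1) span queries
  lf <- Biostrings::letterFrequencyInSlidingView(seq, window, c("C", "G", "N"))
  n_c <- lf[, "C"]; n_g <- lf[, "G"]; n_n <- lf[, "N"]
  cg_starts <- IRanges::start(Biostrings::matchPattern("CG", seq))
  cg_ind <- integer(L)
  cg_ind[cg_starts] <- 1L
  cg_cum <- c(0L, cumsum(cg_ind))
  # CpG whose 2 bases fall inside window starting at i: starts in [i, i+w-2]
  idx <- seq_len(L - window + 1L)
  n_cpg <- cg_cum[idx + window - 1L] - cg_cum[idx]

  n_eff <- window - n_n
  gc <- ifelse(n_eff > 0, (n_c + n_g) / n_eff, 0)
  oe <- ifelse(n_c > 0 & n_g > 0, n_cpg * n_eff / (n_c * n_g), 0)
  qual <- gc >= min_gc & oe >= min_oe & n_n <= window / 2

  if (!any(qual)) return(data.frame(start = integer(0), end = integer(0),
                                    gc = numeric(0), oe = numeric(0)))
  cand <- IRanges::reduce(IRanges::IRanges(which(qual), width = window))
  cand <- cand[IRanges::width(cand) > window]
  if (length(cand) == 0L) return(data.frame(start = integer(0),
                                            end = integer(0),
                                            gc = numeric(0), oe = numeric(0)))

  # cumulative letter counts for arbitrary-span statistics
  base <- strsplit(as.character(seq), "")[[1]]
  c_cum <- c(0L, cumsum(base == "C"))
  g_cum <- c(0L, cumsum(base == "G"))
  n_cum <- c(0L, cumsum(base == "N"))
  span_stats <- function(s, e) {
    nc <- c_cum[e + 1L] - c_cum[s]
    ng <- g_cum[e + 1L] - g_cum[s]
    nn <- n_cum[e + 1L] - n_cum[s]
    ncpg <- if (e > s) cg_cum[e] - cg_cum[s] else 0L
    neff <- (e - s + 1L) - nn
    gc <- if (neff > 0) (nc + ng) / neff else 0
    oe <- if (nc > 0 && ng > 0) ncpg * neff / (nc * ng) else 0
    list(gc = gc, oe = oe)
  }

  out <- data.frame(start = integer(0), end = integer(0),
                    gc = numeric(0), oe = numeric(0))
  for (i in seq_along(cand)) {
    s <- IRanges::start(cand)[i]; e <- IRanges::end(cand)[i]
    trim_left <- TRUE
    repeat {
      if (e - s + 1L <= window) break
      st <- span_stats(s, e)
      if (st$gc >= min_gc && st$oe >= min_oe) {
        out <- rbind(out, data.frame(start = s, end = e,
                                     gc = st$gc, oe = st$oe))
        break
      }
      if (trim_left) s <- s + 1L else e <- e - 1L
      trim_left <- !trim_left
    }
  }
  out
}
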