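#' Simulation configuration
#'
#' Default study conditions for the synthetic genome and methylome: a
#' multi-megabase multi-chromosome genome at mammalian background GC (0.41)
#' with planted CpG islands (by construction satisfying the three CGI
#' criteria), non-overlapping coding genes with at least flank-sized spacing,
#' class-labelled repeats in intergenic/intronic space, per-feature-class
#' target peak densities ranked as in the horse methylome (CDS highest,
#' promoter/5'UTR lowest; LINE above SINE/LTR among repeats), MeDIP-like
#' peaks of 100-500 bp, 50-bp reads with Poisson counts per peak, and
#' planted two-sample fold-change differences.
#'
#' @param seed Random seed; a fixed seed makes all outputs byte-identical.
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param n_genes Total number of genes.
#' @param n_repeats Named vector: repeat elements to place per class.
#' @param gc_background Background GC fraction.
#' @param cgi_per_promoter_prob Probability a promoter carries a planted CGI.
#' @param n_intergenic_cgis Extra CGIs planted in intergenic space.
#' @param class_density Named target peak density per partition category.
#' @param repeat_density Named target peak density per repeat class.
#' @param n_planted_dmrs Number of planted DMR peaks.
#' @param dmr_depths Read-count means (high, low) realising the planted fold.
#' @param reads_per_peak_mean Poisson mean read count per non-DMR peak.
#' @param read_length Read length (bp).
#' @param background_read_rate Background reads per Mb outside peaks.
#' @param peak_len_range Peak length range (bp).
#' @param n_read_pairs FASTQ pairs to synthesise for the QC stage.
#' @param qc_fail_fracs Named fractions of pairs failing each QC criterion.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 3,
                       chrom_length = 1e6,
                       n_genes = 45,
                       n_repeats = c(LINE = 30, SINE = 40, LTR = 25,
                                     DNA = 20, satellite = 10, simple = 15,
                                     low_complexity = 15),
                       gc_background = 0.41,
                       cgi_per_promoter_prob = 0.6,
                       n_intergenic_cgis = 20,
                       class_density = c(cds = 0.35, intergenic = 0.14,
                                         intron = 0.11, utr3 = 0.09,
                                         downstream2kb = 0.07,
                                         upstream2kb = 0.04, utr5 = 0.02),
                       repeat_density = c(LINE = 0.30, SINE = 0.16,
                                          LTR = 0.13, DNA = 0.09,
                                          satellite = 0.06, simple = 0.05,
                                          low_complexity = 0.04),
                       n_planted_dmrs = 12,
                       dmr_depths = c(hi = 40, lo = 10),
                       reads_per_peak_mean = 25,
                       read_length = 50,
                       background_read_rate = 30,
                       peak_len_range = c(100, 500),
                       n_read_pairs = 500,
                       qc_fail_fracs = c(n_frac = 0.04, mean_q = 0.05,
                                         low_q_frac = 0.05,
                                         pair_identical = 0.02)) {
  stopifnot(all(class_density >= 0 & class_density <= 1),
            all(repeat_density >= 0 & repeat_density <= 1),
            chrom_length > 0, n_chroms >= 1)
  structure(as.list(environment()), class = "sim_config")
}

# length ranges of repeat elements per class
REPEAT_LEN <- list(LINE = c(600, 5000), SINE = c(100, 350),
                   LTR = c(300, 1200), DNA = c(200, 1500),
                   satellite = c(500, 2000), simple = c(100, 350),
                   low_complexity = c(100, 350))

#' Simulate a genome with planted CpG islands, genes and repeats
#'
#' See [sim_config()] for the study conditions. Planted CGIs satisfy GC >=
#' 0.6 locally and CpG O/E >= 0.8 with lengths of 300-1500 bp (promoter CGIs
#' 300-800 bp, inside the upstream 2-kb flank); genes are non-overlapping
#' with at least flank-sized spacing; repeats sit in intergenic or intronic
#' space.
#'
#' @param config A `sim_config`.
#' @param out_dir Optional directory; when given, writes `genome.fa`,
#'   `genes.gff`, `repeats.bed`, `cgi_truth.bed` and `truth.json`.
#' @return List of class `sim_genome`: `genome` (a `medip_genome`), `gm`
#'   (`gene_models`), `repeats` (GRanges with `class`), `cgi_truth`
#'   (GRanges of planted islands) and `config`.
#' @export
simulate_genome <- function(config = sim_config(), out_dir = NULL) {
  cfg <- config
  with_seed(cfg$seed, {
    chrom_names <- paste0("chr", seq_len(cfg$n_chroms))
    # decreasing chromosome sizes (largest = chrom_length), as in real
    # karyotypes, so per-chromosome statistics have variance
    lens_chr <- as.integer(round(cfg$chrom_length *
      seq(1, 0.6, length.out = cfg$n_chroms)))
    names(lens_chr) <- chrom_names
    # Mammalian background is CpG-depleted (O/E ~ 0.2): draw iid bases at a
    # raised GC, then mutate 80% of CG dinucleotides' G to A/T. The initial
    # GC q solves q - 0.2 q^2 = gc_background so the final GC matches.
    deplete <- 0.8
    q <- (1 - sqrt(1 - 4 * (deplete / 4) * cfg$gc_background)) /
      (2 * (deplete / 4))
    base_probs <- c(A = (1 - q) / 2, C = q / 2, G = q / 2, T = (1 - q) / 2)
    seqs_chr <- lapply(chrom_names, function(ch) {
      n <- lens_chr[[ch]]
      x <- sample(names(base_probs), n, replace = TRUE, prob = base_probs)
      cg <- which(x[-n] == "C" & x[-1] == "G")
      mut <- cg[stats::runif(length(cg)) < deplete]
      x[mut + 1L] <- sample(c("A", "T"), length(mut), replace = TRUE)
      x
    })
    names(seqs_chr) <- chrom_names

    # ---- genes -----------------------------------------------------------
    flank <- 2000L
    # apportion genes to chromosomes by length
    genes_per_chrom <- diff(round(cfg$n_genes *
      cumsum(c(0, lens_chr)) / sum(as.numeric(lens_chr))))
    gene_rows <- list()
    occupied <- list()  # per chrom: IRanges of gene spans incl. flanks
    gid <- 0L
    for (ci in seq_len(cfg$n_chroms)) {
      ch <- chrom_names[ci]
      occ <- IRanges::IRanges()
      cursor <- flank + sample(1000:4000, 1)
      for (gi in seq_len(genes_per_chrom[ci])) {
        glen <- sample(3000:12000, 1)
        if (cursor + glen + flank + 1000 > lens_chr[[ch]]) break
        gid <- gid + 1L
        id <- sprintf("gene%03d", gid)
        strand <- sample(c("+", "-"), 1)
        gs <- cursor; ge <- cursor + glen - 1L
        # exon chain: first/last exon anchored at gene ends and at least
        # 800 bp so UTRs can hold whole peaks
        n_ex <- sample(2:6, 1)
        cuts <- sort(sample(seq(gs + 800, ge - 800, by = 50),
                            2L * (n_ex - 1L)))
        ex_s <- c(gs, cuts[seq(2, length(cuts), by = 2)] + 1L)
        ex_e <- c(cuts[seq(1, length(cuts), by = 2)], ge)
        # CDS span strictly inside the exon chain -> 300-700 bp UTRs
        cds_s <- ex_s[1] + sample(300:700, 1)
        cds_e <- ex_e[n_ex] - sample(300:700, 1)
        gene_rows[[id]] <- list(
          gene = data.frame(chrom = ch, feature = "gene", start = gs,
                            end = ge, strand = strand, gene_id = id),
          exon = data.frame(chrom = ch, feature = "exon", start = ex_s,
                            end = ex_e, strand = strand, gene_id = id),
          cds = data.frame(chrom = ch, feature = "CDS", start = cds_s,
                           end = cds_e, strand = strand, gene_id = id))
        occ <- c(occ, IRanges::IRanges(gs - flank, ge + flank))
        cursor <- ge + flank + sample(3000:12000, 1)
      }
      occupied[[ch]] <- IRanges::reduce(occ)
    }
    gff <- if (length(gene_rows))
      do.call(rbind, unlist(lapply(gene_rows, function(x)
        list(x$gene, x$exon, x$cds)), recursive = FALSE))
    else NULL
    rownames(gff) <- NULL
    gm <- gene_models_from_df(gff)

    # ---- planted CpG islands --------------------------------------------
    cgi_list <- list()
    # islands get short AT-rich shoulders so their boundaries are sharp:
    # windows straddling the edge fail the GC criterion and the full-extent
    # re-verification trims any residual overhang back to the island
    shoulder <- 150L
    plant_cgi <- function(ch, start, len) {
      isl <- make_cgi_seq(len)
      seqs_chr[[ch]][start:(start + len - 1L)] <<- isl
      ls <- max(1L, start - shoulder)
      rs <- min(lens_chr[[ch]], start + len - 1L + shoulder)
      if (ls < start)
        seqs_chr[[ch]][ls:(start - 1L)] <<-
          sample(c("A", "T"), start - ls, replace = TRUE)
      if (rs > start + len - 1L)
        seqs_chr[[ch]][(start + len):rs] <<-
          sample(c("A", "T"), rs - start - len + 1L, replace = TRUE)
      cgi_list[[length(cgi_list) + 1L]] <<-
        data.frame(chrom = ch, start = start, end = start + len - 1L)
    }
    # promoter CGIs: end 100-900 bp upstream of the TSS
    tss <- tss_sites(gm)
    for (i in seq_along(tss)) {
      if (stats::runif(1) > cfg$cgi_per_promoter_prob) next
      len <- sample(300:800, 1)
      ch <- as.character(GenomeInfoDb::seqnames(tss))[i]
      pos <- GenomicRanges::start(tss)[i]
      if (as.character(GenomicRanges::strand(tss))[i] == "+") {
        end <- pos - sample(100:900, 1)
        start <- end - len + 1L
      } else {
        start <- pos + sample(100:900, 1)
        end <- start + len - 1L
      }
      if (start < 1 || end > lens_chr[[ch]]) next
      plant_cgi(ch, start, len)
    }
    # intergenic CGIs: in gaps between gene+flank blocks
    for (i in seq_len(cfg$n_intergenic_cgis)) {
      ch <- sample(chrom_names, 1)
      len <- sample(300:1500, 1)
      gap <- IRanges::setdiff(IRanges::IRanges(1L, lens_chr[[ch]]), occupied[[ch]])
      gap <- gap[IRanges::width(gap) > len + 2000]
      if (length(gap) == 0L) next
      g <- gap[sample(length(gap), 1)]
      start <- IRanges::start(g) + 1000 +
        sample.int(IRanges::width(g) - len - 2000, 1)
      # avoid colliding with an earlier island
      if (length(cgi_list)) {
        prev <- do.call(rbind, cgi_list)
        prev <- prev[prev$chrom == ch, , drop = FALSE]
        if (nrow(prev) && any(start <= prev$end + 500 &
                              start + len - 1L >= prev$start - 500)) next
      }
      plant_cgi(ch, start, len)
    }
    cgi_df <- do.call(rbind, cgi_list)
    cgi_truth <- if (is.null(cgi_df)) GenomicRanges::GRanges()
    else GenomicRanges::sort(GenomicRanges::GRanges(
      cgi_df$chrom, IRanges::IRanges(cgi_df$start, cgi_df$end)))

    # ---- repeats in intergenic/intronic space ---------------------------
    rep_rows <- list()
    placed_rep <- lapply(chrom_names, function(ch) IRanges::IRanges())
    names(placed_rep) <- chrom_names
    cgi_ir <- if (is.null(cgi_df)) list()
    else split(IRanges::IRanges(cgi_df$start, cgi_df$end), cgi_df$chrom)
    for (cl in names(cfg$n_repeats)) {
      lr <- REPEAT_LEN[[cl]]
      for (i in seq_len(cfg$n_repeats[[cl]])) {
        ch <- sample(chrom_names, 1)
        len <- sample(lr[1]:lr[2], 1)
        gap <- IRanges::setdiff(IRanges::IRanges(1L, lens_chr[[ch]]), occupied[[ch]])
        gap <- IRanges::setdiff(gap, placed_rep[[ch]])
        if (!is.null(cgi_ir[[ch]])) gap <- IRanges::setdiff(gap, cgi_ir[[ch]])
        gap <- gap[IRanges::width(gap) > len + 200]
        if (length(gap) == 0L) next
        g <- gap[sample(length(gap), 1)]
        start <- IRanges::start(g) + 100 +
          sample.int(IRanges::width(g) - len - 200, 1)
        rep_rows[[length(rep_rows) + 1L]] <-
          data.frame(chrom = ch, start = start, end = start + len - 1L,
                     class = cl)
        placed_rep[[ch]] <- c(placed_rep[[ch]],
                              IRanges::IRanges(start, start + len - 1L))
      }
    }
    rep_df <- do.call(rbind, rep_rows)
    repeats <- if (is.null(rep_df)) {
      r0 <- GenomicRanges::GRanges(); r0$class <- character(0); r0
    } else GenomicRanges::sort(GenomicRanges::GRanges(
      rep_df$chrom, IRanges::IRanges(rep_df$start, rep_df$end),
      class = rep_df$class))

    seqs <- Biostrings::DNAStringSet(vapply(seqs_chr, paste0,
                                            character(1), collapse = ""))
    names(seqs) <- chrom_names
    genome <- new_medip_genome(seqs)
    set_si <- function(x) {
      GenomeInfoDb::seqlevels(x) <- GenomeInfoDb::seqnames(genome$seqinfo)
      GenomeInfoDb::seqinfo(x) <- genome$seqinfo
      x
    }
    cgi_truth <- set_si(cgi_truth)
    repeats <- set_si(repeats)

    out <- structure(list(genome = genome, gm = gm, repeats = repeats,
                          cgi_truth = cgi_truth, config = cfg),
                     class = "sim_genome")
    if (!is.null(out_dir)) write_sim_genome(out, out_dir)
    out
  })
}

new_medip_genome <- function(seqs) {
  si <- GenomeInfoDb::Seqinfo(seqnames = names(seqs),
                              seqlengths = Biostrings::width(seqs))
  structure(list(seq = seqs, seqinfo = si,
                 total_size = sum(as.numeric(Biostrings::width(seqs)))),
            class = "medip_genome")
}

# Place ~target_bp of peak coverage inside the available intervals: each
# interval receives one contiguous chunk proportional to its width, with a
# carry of unplaced base pairs rolled into the next interval so the total
# placed coverage tracks the target almost exactly even when individual
# shares fall below the minimum peak length. Chunks sit at random offsets
# and are split into peaks of lo..hi bp; output peaks are disjoint and fully
# inside `avail`.
place_chunks <- function(avail, target_bp, peak_len_range, seqinfo) {
  lo <- peak_len_range[1]; hi <- peak_len_range[2]
  empty <- GenomicRanges::GRanges(seqinfo = seqinfo)
  avail <- avail[GenomicRanges::width(avail) >= lo]
  if (length(avail) == 0L || target_bp < lo) return(empty)
  avail <- avail[sample.int(length(avail))]
  ws <- as.numeric(GenomicRanges::width(avail))
  frac <- min(1, target_bp / sum(ws))
  # pass 1: chunk length per interval ~ proportional share, minimum lo,
  # rolling the unplaced remainder forward
  lens <- numeric(length(ws))
  carry <- 0
  for (i in seq_along(ws)) {
    want <- frac * ws[i] + carry
    len <- min(floor(want), ws[i])
    if (len < lo) { carry <- want; next }
    lens[i] <- len
    carry <- want - len
  }
  if (all(lens == 0)) {                 # tiny class: single minimal chunk
    i <- which.max(ws)
    lens[i] <- min(ws[i], max(lo, round(target_bp)))
  }
  # pass 2: settle the residual exactly by growing (or shrinking) placed
  # chunks within their intervals; chunks stay >= lo
  deficit <- target_bp - sum(lens)
  for (i in order(ws - lens, decreasing = TRUE)) {
    if (abs(deficit) < 1) break
    if (lens[i] == 0) next
    if (deficit > 0) {
      add <- min(ws[i] - lens[i], floor(deficit))
    } else {
      add <- -min(lens[i] - lo, floor(-deficit))
    }
    lens[i] <- lens[i] + add
    deficit <- deficit - add
  }
  out_s <- integer(0); out_e <- integer(0); out_ch <- character(0)
  chroms <- as.character(GenomeInfoDb::seqnames(avail))
  starts <- GenomicRanges::start(avail)
  for (i in seq_along(ws)) {
    len <- lens[i]
    if (len < lo) next
    off <- sample.int(ws[i] - len + 1L, 1) - 1L
    s0 <- starts[i] + off
    n_p <- ceiling(len / hi)
    bnd <- round(seq(0, len, length.out = n_p + 1))
    out_s <- c(out_s, s0 + bnd[-length(bnd)])
    out_e <- c(out_e, s0 + bnd[-1] - 1L)
    out_ch <- c(out_ch, rep(chroms[i], n_p))
  }
  if (length(out_s) == 0L) return(empty)
  GenomicRanges::GRanges(out_ch, IRanges::IRanges(out_s, out_e),
                         seqinfo = seqinfo)
}

# CG-rich sequence passing GC >= 0.6 and O/E >= 0.8 on its full length; iid
# draws are resampled until the criteria hold. GC is kept close to 0.6 (not
# higher): the sharper the GC contrast with the flanks, the further
# boundary-straddling windows extend the detected island beyond the planted
# tract.
make_cgi_seq <- function(len) {
  probs <- c(A = 0.195, C = 0.305, G = 0.305, T = 0.195)
  repeat {
    s <- sample(names(probs), len, replace = TRUE, prob = probs)
    nc <- sum(s == "C"); ng <- sum(s == "G")
    ncpg <- sum(s[-len] == "C" & s[-1] == "G")
    gc <- (nc + ng) / len
    oe <- if (nc > 0 && ng > 0) ncpg * len / (nc * ng) else 0
    if (gc >= 0.60 && gc <= 0.635 && oe >= 0.85) return(s)
  }
}

write_sim_genome <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome$seq, file.path(out_dir, "genome.fa"))
  write_gene_models(sim$gm, file.path(out_dir, "genes.gff"))
  rep_out <- sim$repeats; rep_out$name <- rep_out$class; rep_out$class <- NULL
  write_bed(rep_out, file.path(out_dir, "repeats.bed"))
  write_bed(sim$cgi_truth, file.path(out_dir, "cgi_truth.bed"))
  invisible(out_dir)
}

#' Simulate a two-sample methylome over a simulated genome
#'
#' Places MeDIP-like peaks (100-500 bp) so that the measured methylation
#' density of each feature and repeat class approaches its configured target;
#' draws 50-bp reads within peaks with Poisson counts plus uniform background
#' reads; realises planted DMRs as peaks whose read-count means differ by the
#' configured depths between the two samples (hyper = sample A deeper);
#' and synthesises a FASTQ pair in which configured fractions of read pairs
#' fail each of the four QC criteria.
#'
#' @param sim A `sim_genome` from [simulate_genome()].
#' @param annotation Optional `feature_annotation`; derived from `sim` when
#'   missing.
#' @param out_dir Optional output directory for BED/FASTQ files.
#' @return List of class `sim_methylome`: `peaks` (list a/b of GRanges),
#'   `reads` (list a/b of GRanges), `fastq` (list r1/r2 of `fastq_reads`),
#'   `annotation`, and `truth` (list with `class_density`, `repeat_density`,
#'   `dmrs` GRanges with `direction` and `fold`, `qc_fail_fracs`).
#' @export
simulate_methylome <- function(sim, annotation = NULL, out_dir = NULL) {
  cfg <- sim$config
  if (is.null(annotation))
    annotation <- derive_features(sim$gm, sim$genome$seqinfo,
                                  repeats = sim$repeats)
  with_seed(cfg$seed + 1L, {
    placed <- GenomicRanges::GRanges(seqinfo = sim$genome$seqinfo)

    # 1) repeat-class peaks: cover each element of the class at the class
    #    target density (one contiguous chunk per element, split into
    #    100-500 bp peaks)
    for (cl in names(cfg$repeat_density)) {
      els <- annotation$repeats[annotation$repeats$class == cl]
      if (length(els) == 0L) next
      pk <- place_chunks(els, cfg$repeat_density[[cl]] * total_bp(els),
                         cfg$peak_len_range, sim$genome$seqinfo)
      placed <- c(placed, pk)
    }

    # 2) partition-class peaks: top up each category to its target density,
    #    accounting for repeat peaks already falling inside it
    for (cl in names(cfg$class_density)) {
      cat_gr <- annotation$categories[[cl]]
      area <- total_bp(cat_gr)
      if (area == 0) next
      contributed <- total_bp(GenomicRanges::intersect(
        GenomicRanges::reduce(placed), cat_gr, ignore.strand = TRUE))
      target <- cfg$class_density[[cl]] * area - contributed
      if (target <= 0) next
      avail <- GenomicRanges::setdiff(cat_gr,
        GenomicRanges::reduce(c(GenomicRanges::granges(placed),
                                GenomicRanges::granges(annotation$repeats))),
        ignore.strand = TRUE)
      placed <- c(placed, place_chunks(avail, target, cfg$peak_len_range,
                                       sim$genome$seqinfo))
    }
    placed <- GenomicRanges::sort(placed)

    # 3) planted DMRs: a subset of *isolated* peaks (not book-ended with a
    #    neighbour, so each stays its own merged region) gets a depth
    #    asymmetry between the samples
    red <- GenomicRanges::reduce(placed)
    solo_regions <- red[GenomicRanges::countOverlaps(red, placed) == 1L]
    solo_idx <- which(IRanges::overlapsAny(placed, solo_regions))
    n_dmr <- min(cfg$n_planted_dmrs, length(solo_idx))
    dmr_idx <- sort(sample(solo_idx, n_dmr))
    dmr_dir <- sample(c("hyper", "hypo"), n_dmr, replace = TRUE)
    lambda_a <- rep(cfg$reads_per_peak_mean, length(placed))
    lambda_b <- rep(cfg$reads_per_peak_mean, length(placed))
    lambda_a[dmr_idx] <- ifelse(dmr_dir == "hyper",
                                cfg$dmr_depths[["hi"]],
                                cfg$dmr_depths[["lo"]])
    lambda_b[dmr_idx] <- ifelse(dmr_dir == "hyper",
                                cfg$dmr_depths[["lo"]],
                                cfg$dmr_depths[["hi"]])
    dmr_truth <- placed[dmr_idx]
    dmr_truth$direction <- dmr_dir
    dmr_truth$fold <- cfg$dmr_depths[["hi"]] / cfg$dmr_depths[["lo"]]

    draw_reads <- function(lambda) {
      counts <- stats::rpois(length(placed), lambda)
      rows <- which(counts > 0)
      if (length(rows) == 0L)
        return(GenomicRanges::GRanges(seqinfo = sim$genome$seqinfo))
      starts <- unlist(lapply(rows, function(i) {
        lo <- GenomicRanges::start(placed)[i]
        hi <- max(lo, GenomicRanges::end(placed)[i] - cfg$read_length + 1L)
        lo + sample.int(hi - lo + 1L, counts[i], replace = TRUE) - 1L
      }))
      chroms <- rep(as.character(GenomeInfoDb::seqnames(placed))[rows],
                    counts[rows])
      gr <- GenomicRanges::GRanges(chroms,
        IRanges::IRanges(starts, width = cfg$read_length),
        seqinfo = sim$genome$seqinfo)
      # uniform background
      lens <- GenomeInfoDb::seqlengths(sim$genome$seqinfo)
      n_bg <- stats::rpois(1, cfg$background_read_rate *
                             sum(as.numeric(lens)) / 1e6)
      if (n_bg > 0) {
        bg_ch <- sample(names(lens), n_bg, replace = TRUE,
                        prob = as.numeric(lens))
        bg_st <- vapply(bg_ch, function(ch)
          sample.int(lens[[ch]] - cfg$read_length, 1), numeric(1))
        gr <- c(gr, GenomicRanges::GRanges(bg_ch,
          IRanges::IRanges(bg_st, width = cfg$read_length),
          seqinfo = sim$genome$seqinfo))
      }
      GenomicRanges::sort(gr)
    }
    reads_a <- draw_reads(lambda_a)
    reads_b <- draw_reads(lambda_b)

    fastq <- simulate_fastq(cfg)

    out <- structure(list(
      peaks = list(a = placed, b = placed),
      reads = list(a = reads_a, b = reads_b),
      fastq = fastq,
      annotation = annotation,
      truth = list(class_density = cfg$class_density,
                   repeat_density = cfg$repeat_density,
                   dmrs = dmr_truth,
                   qc_fail_fracs = cfg$qc_fail_fracs)),
      class = "sim_methylome")
    if (!is.null(out_dir)) write_sim_methylome(out, out_dir)
    out
  })
}

write_sim_methylome <- function(ms, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_bed(ms$peaks$a, file.path(out_dir, "sampleA.peaks.bed"))
  write_bed(ms$peaks$b, file.path(out_dir, "sampleB.peaks.bed"))
  write_bed(ms$reads$a, file.path(out_dir, "sampleA.reads.bed"))
  write_bed(ms$reads$b, file.path(out_dir, "sampleB.reads.bed"))
  write_fastq(ms$fastq$r1, file.path(out_dir, "sample_1.fastq"))
  write_fastq(ms$fastq$r2, file.path(out_dir, "sample_2.fastq"))
  truth <- ms$truth
  truth$dmrs <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(truth$dmrs)),
                           start = GenomicRanges::start(truth$dmrs),
                           end = GenomicRanges::end(truth$dmrs),
                           direction = truth$dmrs$direction,
                           fold = truth$dmrs$fold)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

# FASTQ pairs with configured fractions failing each QC criterion
simulate_fastq <- function(cfg) {
  n <- cfg$n_read_pairs
  rl <- cfg$read_length
  f <- cfg$qc_fail_fracs
  status <- sample(c(names(f), "good"), n, replace = TRUE,
                   prob = c(f, 1 - sum(f)))
  rand_seq <- function() paste(sample(c("A", "C", "G", "T"), rl,
                                      replace = TRUE), collapse = "")
  good_q <- function() sample(30:40, rl, replace = TRUE)
  mk <- function(i, mate) {
    s <- rand_seq(); q <- good_q()
    st <- status[i]
    if (st == "n_frac" && mate == 1L) {
      pos <- sample.int(rl, ceiling(0.12 * rl))
      s <- strsplit(s, "")[[1]]; s[pos] <- "N"; s <- paste(s, collapse = "")
    } else if (st == "mean_q" && mate == 1L) {
      q <- sample(10:18, rl, replace = TRUE)
    } else if (st == "low_q_frac" && mate == 1L) {
      pos <- sample.int(rl, ceiling(0.06 * rl))
      q[pos] <- 10L
    }
    list(s = s, q = q)
  }
  r1 <- lapply(seq_len(n), mk, mate = 1L)
  r2 <- lapply(seq_len(n), mk, mate = 2L)
  ident <- which(status == "pair_identical")
  for (i in ident) r2[[i]]$s <- r1[[i]]$s
  ids <- sprintf("read%05d", seq_len(n))
  as_fq <- function(lst, suffix) {
    structure(list(id = paste0(ids, suffix),
                   seq = Biostrings::DNAStringSet(vapply(lst, `[[`, "",
                                                         "s")),
                   qual = lapply(lst, `[[`, "q"),
                   offset = 33L),
              class = "fastq_reads")
  }
  list(r1 = as_fq(r1, "/1"), r2 = as_fq(r2, "/2"), status = status)
}

#' Simulate a two-sample DMR read-count experiment at interval level
#'
#' Builds one chromosome with `n_null + n_dmr` well-separated candidate peak
#' regions (identical peak calls in both samples), draws per-region Poisson
#' read counts — `depth_null` in both samples for null regions, `depth_hi`
#' versus `depth_lo` for planted DMRs — and materialises the reads as
#' uniform intervals inside their regions. The first `n_dmr` regions are the
#' planted DMRs; directions alternate hyper/hypo so the two libraries stay
#' balanced (no composition bias in the library-size normalisation).
#'
#' @param n_null,n_dmr Numbers of null and planted regions.
#' @param depth_null Poisson mean in both samples for null regions.
#' @param depth_hi,depth_lo Poisson means for the planted regions in the
#'   hypermethylated and hypomethylated sample respectively.
#' @param region_len Region length (bp).
#' @param read_len Read length (bp).
#' @param seed Random seed.
#' @return List with `peaks_a`, `peaks_b`, `reads_a`, `reads_b` (GRanges),
#'   `dmr_truth` (GRanges of planted regions) and `regions`.
#' @export
simulate_dmr_experiment <- function(n_null = 500, n_dmr = 50,
                                    depth_null = 20, depth_hi = 40,
                                    depth_lo = 10, region_len = 300,
                                    read_len = 50, seed = 1) {
  n <- n_null + n_dmr
  gap <- 200L
  starts <- gap + (seq_len(n) - 1L) * (region_len + gap)
  L <- starts[n] + region_len + gap
  si <- GenomeInfoDb::Seqinfo("chrSim", L)
  regions <- GenomicRanges::GRanges("chrSim",
    IRanges::IRanges(starts, width = region_len), seqinfo = si)
  is_dmr <- c(rep(TRUE, n_dmr), rep(FALSE, n_null))
  hyper <- is_dmr & (seq_len(n) %% 2L == 1L)
  with_seed(seed, {
    lam_a <- ifelse(is_dmr, ifelse(hyper, depth_hi, depth_lo), depth_null)
    lam_b <- ifelse(is_dmr, ifelse(hyper, depth_lo, depth_hi), depth_null)
    draw <- function(lam) {
      counts <- stats::rpois(n, lam)
      idx <- rep(seq_len(n), counts)
      if (length(idx) == 0L)
        return(GenomicRanges::GRanges(seqinfo = si))
      off <- sample.int(region_len - read_len + 1L, length(idx),
                        replace = TRUE) - 1L
      GenomicRanges::GRanges("chrSim",
        IRanges::IRanges(starts[idx] + off, width = read_len), seqinfo = si)
    }
    truth <- regions[is_dmr]
    truth$direction <- ifelse(hyper[is_dmr], "hyper", "hypo")
    list(peaks_a = regions, peaks_b = regions,
         reads_a = draw(lam_a), reads_b = draw(lam_b),
         dmr_truth = truth, regions = regions)
  })
}

#' Simulate per-region two-sample read counts (count level)
#'
#' The count-level analogue of [simulate_dmr_experiment()]: Poisson counts
#' per region without materialising read intervals, for fast replicated
#' calibration studies.
#'
#' @inheritParams simulate_dmr_experiment
#' @return List with `count_a`, `count_b`, `is_dmr` (logical) and
#'   `total_a`, `total_b` (library sizes, counts plus a fixed background).
#' @export
simulate_dmr_counts <- function(n_null = 500, n_dmr = 0, depth_null = 20,
                                depth_hi = 40, depth_lo = 10, seed = 1) {
  n <- n_null + n_dmr
  is_dmr <- c(rep(TRUE, n_dmr), rep(FALSE, n_null))
  with_seed(seed, {
    count_a <- stats::rpois(n, ifelse(is_dmr, depth_hi, depth_null))
    count_b <- stats::rpois(n, ifelse(is_dmr, depth_lo, depth_null))
    # equal library sizes, comfortably above any per-region count
    total <- n * depth_null + 5000L
    list(count_a = count_a, count_b = count_b, is_dmr = is_dmr,
         total_a = total, total_b = total)
  })
}
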