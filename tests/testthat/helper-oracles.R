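# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately avoid the package's code paths: they work on raw
# character vectors and per-base-pair logical arrays.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

# ---- sequence fixtures --------------------------------------------------

# write named character sequences as FASTA and load through the package API
genome_from_strings <- function(seqs) {
  fa <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]]))), fa)
  read_genome_fasta(fa)
}

rand_dna <- function(n, gc = 0.41) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# CG-rich tract used to plant islands in scanner tests
cg_rich_dna <- function(n) {
  p <- c(A = 0.17, C = 0.33, G = 0.33, T = 0.17)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# ---- per-base-pair array helpers ---------------------------------------

# logical coverage vector of a GRanges on one chromosome of length L
cover_vec <- function(gr, chrom, L) {
  v <- logical(L)
  gr <- gr[as.character(seqnames(gr)) == chrom]
  for (i in seq_along(gr)) {
    s <- max(1L, start(gr)[i]); e <- min(L, end(gr)[i])
    if (s <= e) v[s:e] <- TRUE
  }
  v
}

# ---- gene fixtures ------------------------------------------------------

# n non-overlapping coding genes per chromosome, written via GFF-lite text
random_gene_models <- function(lens, n_per_chrom = 4, flank = 2000) {
  rows <- list()
  gid <- 0
  for (ch in names(lens)) {
    cursor <- flank + sample(500:1500, 1)
    for (i in seq_len(n_per_chrom)) {
      glen <- sample(3000:6000, 1)
      if (cursor + glen + flank > lens[[ch]]) break
      gid <- gid + 1
      id <- sprintf("g%03d", gid)
      strand <- sample(c("+", "-"), 1)
      gs <- cursor; ge <- cursor + glen - 1
      mid <- sample(seq(gs + 1000, ge - 1000, by = 10), 2)
      ex_s <- c(gs, max(mid) + 1); ex_e <- c(min(mid), ge)
      cds_s <- gs + sample(200:500, 1); cds_e <- ge - sample(200:500, 1)
      rows[[length(rows) + 1]] <- sprintf("%s\tgene\t%d\t%d\t%s\t%s",
                                          ch, gs, ge, strand, id)
      rows[[length(rows) + 1]] <- sprintf("%s\texon\t%d\t%d\t%s\t%s",
                                          ch, ex_s[1], ex_e[1], strand, id)
      rows[[length(rows) + 1]] <- sprintf("%s\texon\t%d\t%d\t%s\t%s",
                                          ch, ex_s[2], ex_e[2], strand, id)
      rows[[length(rows) + 1]] <- sprintf("%s\tCDS\t%d\t%d\t%s\t%s",
                                          ch, cds_s, cds_e, strand, id)
      cursor <- ge + flank + sample(2000:5000, 1)
    }
  }
  gff <- tempfile(fileext = ".gff")
  writeLines(unlist(rows), gff)
  read_gene_models(gff)
}

# ---- per-bp feature-partition oracle ------------------------------------

# label every base of every chromosome by the seven categories, painting in
# reverse precedence so higher-precedence categories overwrite lower ones
bp_partition_oracle <- function(gm, lens, flank = 2000) {
  lab <- lapply(lens, function(L) rep("intergenic", L))
  paint <- function(ch, pos, cat) {
    pos <- pos[pos >= 1 & pos <= lens[[ch]]]
    if (length(pos)) lab[[ch]][pos] <<- cat
  }
  order_rev <- c("downstream2kb", "upstream2kb", "intron", "utr3", "utr5",
                 "cds")
  sets <- list()
  for (id in names(gm$genes)) {
    g <- gm$genes[id]
    ch <- as.character(seqnames(g))
    gs <- start(g); ge <- end(g)
    plus <- as.character(strand(g)) == "+"
    ex <- sort(gm$exons[[id]])
    ex_pos <- unlist(lapply(seq_along(ex), function(i)
      start(ex)[i]:end(ex)[i]))
    cd <- gm$cds[id, ]
    if (any(is.na(cd))) {
      cds_pos <- integer(0); utr5_pos <- ex_pos; utr3_pos <- integer(0)
    } else {
      cds_pos <- ex_pos[ex_pos >= cd[["start"]] & ex_pos <= cd[["end"]]]
      left <- ex_pos[ex_pos < cd[["start"]]]
      right <- ex_pos[ex_pos > cd[["end"]]]
      utr5_pos <- if (plus) left else right
      utr3_pos <- if (plus) right else left
    }
    sets[[id]] <- list(
      cds = cds_pos, utr5 = utr5_pos, utr3 = utr3_pos,
      intron = setdiff(gs:ge, ex_pos),
      upstream2kb = if (plus) (gs - flank):(gs - 1) else (ge + 1):(ge + flank),
      downstream2kb = if (plus) (ge + 1):(ge + flank) else (gs - flank):(gs - 1),
      chrom = ch)
  }
  for (cat in order_rev)
    for (id in names(sets))
      paint(sets[[id]]$chrom, sets[[id]][[cat]], cat)
  lab
}

# ---- exhaustive CpG-island window oracle --------------------------------

# mark every base lying in ANY qualifying 200-bp window (windows evaluated
# with rolling sums over raw character vectors), merge runs, drop short
# regions, and apply the same alternate-trim re-verification rule
cgi_window_oracle <- function(seq_string, window = 200, min_gc = 0.5,
                              min_oe = 0.6) {
  x <- strsplit(seq_string, "")[[1]]
  L <- length(x)
  if (L < window) return(data.frame(start = integer(0), end = integer(0)))
  isC <- as.numeric(x == "C"); isG <- as.numeric(x == "G")
  isN <- as.numeric(x == "N")
  isCG <- c(as.numeric(x[-L] == "C" & x[-1] == "G"), 0)
  roll <- function(v, w) {
    f <- stats::filter(v, rep(1, w), sides = 1)
    as.numeric(f[w:L])
  }
  nC <- roll(isC, window); nG <- roll(isG, window); nN <- roll(isN, window)
  # CpG starts fully inside the window: positions i..i+window-2
  nCG <- roll(isCG, window - 1)
  nCG <- nCG[seq_len(L - window + 1)]
  neff <- window - nN
  gc <- ifelse(neff > 0, (nC + nG) / neff, 0)
  oe <- ifelse(nC > 0 & nG > 0, nCG * neff / (nC * nG), 0)
  qual <- gc >= min_gc & oe >= min_oe & nN <= window / 2
  covered <- logical(L)
  for (i in which(qual)) covered[i:(i + window - 1)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  reg <- data.frame(start = starts[r$values], end = ends[r$values])
  reg <- reg[reg$end - reg$start + 1 > window, , drop = FALSE]
  span_ok <- function(s, e) {
    xx <- x[s:e]
    n <- length(xx)
    nc <- sum(xx == "C"); ng <- sum(xx == "G"); nn <- sum(xx == "N")
    ncg <- sum(xx[-n] == "C" & xx[-1] == "G")
    neff <- n - nn
    gc <- if (neff > 0) (nc + ng) / neff else 0
    oe <- if (nc > 0 && ng > 0) ncg * neff / (nc * ng) else 0
    gc >= min_gc && oe >= min_oe
  }
  out <- data.frame(start = integer(0), end = integer(0))
  for (i in seq_len(nrow(reg))) {
    s <- reg$start[i]; e <- reg$end[i]
    trim_left <- TRUE
    repeat {
      if (e - s + 1 <= window) break
      if (span_ok(s, e)) {
        out <- rbind(out, data.frame(start = s, end = e))
        break
      }
      if (trim_left) s <- s + 1 else e <- e - 1
      trim_left <- !trim_left
    }
  }
  out
}

# ---- statistics oracles -------------------------------------------------

chi2_oracle <- function(a, b, ta, tb) {
  m <- matrix(c(a, ta - a, b, tb - b), nrow = 2, byrow = TRUE)
  suppressWarnings(stats::chisq.test(m, correct = FALSE))
}

# Benjamini-Hochberg step-up from its definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  q
}

# exhaustive minimum within-cluster sum of squares over all 2-partitions
kmeans2_bruteforce <- function(mat) {
  n <- nrow(mat)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    g <- c(0, as.integer(intToBits(code))[seq_len(n - 1)])
    if (length(unique(g)) < 2) next
    ss <- 0
    for (k in unique(g)) {
      sub <- mat[g == k, , drop = FALSE]
      ctr <- colMeans(sub)
      ss <- ss + sum(sweep(sub, 2, ctr)^2)
    }
    best <- min(best, ss)
  }
  best
}

# fastq_reads fixture from raw vectors
make_reads <- function(ids, seqs, quals) {
  structure(list(id = ids, seq = Biostrings::DNAStringSet(seqs),
                 qual = quals, offset = 33L),
            class = "fastq_reads")
}

# small simulation config shared by pipeline-level tests
small_sim_config <- function(seed = 5, n_read_pairs = 200, ...) {
  sim_config(seed = seed, n_chroms = 3, chrom_length = 2e5, n_genes = 15,
             n_repeats = c(LINE = 8, SINE = 10, LTR = 6, DNA = 5,
                           satellite = 3, simple = 5, low_complexity = 5),
             n_intergenic_cgis = 6, n_planted_dmrs = 5,
             n_read_pairs = n_read_pairs, ...)
}
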