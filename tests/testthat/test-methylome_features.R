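# helper: one-gene annotation with a repeat overlay, for peak-rule tests
one_gene_annotation <- function() {
  gff <- tempfile(fileext = ".gff")
  writeLines(c("chr1\tgene\t5001\t8000\t+\tgA",
               "chr1\texon\t5001\t8000\t+\tgA",
               "chr1\tCDS\t5501\t7500\t+\tgA"), gff)
  gm <- read_gene_models(gff)
  si <- GenomeInfoDb::Seqinfo("chr1", 20000)
  rep_gr <- GRanges("chr1", IRanges(6000, 6400))
  rep_gr$class <- "LINE"
  derive_features(gm, si, repeats = rep_gr)
}

test_that("CpG island scanner handles the degenerate and forced cases", {
  g <- genome_from_strings(list(chr1 = strrep("A", 1000)))
  expect_length(scan_cgi(g), 0)

  # (CG)x150: GC = 1, O/E = 150*300/(150*150) = 2 -> one island, full span
  g <- genome_from_strings(list(chr1 = strrep("CG", 150)))
  isl <- scan_cgi(g)
  expect_length(isl, 1)
  expect_equal(start(isl), 1L)
  expect_equal(end(isl), 300L)
  expect_equal(isl$gc_fraction, 1.0)
  expect_equal(isl$obs_exp, 2.0)

  # chromosome shorter than the window: no islands, no error
  g <- genome_from_strings(list(chr1 = strrep("CG", 50)))
  expect_length(scan_cgi(g), 0)
})

test_that("scanner equals the exhaustive window oracle on planted sequences", {
  for (seed in c(31, 32, 33)) {
    set.seed(seed)
    parts <- character(7)
    parts[c(1, 3, 5, 7)] <- vapply(c(2500, 2000, 2000, 1500), rand_dna, "")
    parts[c(2, 4, 6)] <- vapply(sample(250:700, 3), cg_rich_dna, "")
    s <- paste(parts, collapse = "")
    g <- genome_from_strings(list(chr1 = s))
    got <- scan_cgi(g)
    exp <- cgi_window_oracle(s)
    expect_equal(start(got), exp$start, label = paste("seed", seed))
    expect_equal(end(got), exp$end, label = paste("seed", seed))

    # every reported island independently satisfies the three criteria
    for (i in seq_along(got)) {
      xx <- strsplit(substr(s, start(got)[i], end(got)[i]), "")[[1]]
      n <- length(xx)
      nc <- sum(xx == "C"); ng <- sum(xx == "G")
      ncg <- sum(xx[-n] == "C" & xx[-1] == "G")
      expect_gt(n, 200)
      expect_gte((nc + ng) / n, 0.5)
      expect_gte(ncg * n / (nc * ng), 0.6)
      expect_equal(got$gc_fraction[i], (nc + ng) / n)
      expect_equal(got$obs_exp[i], ncg * n / (nc * ng))
    }
  }
})

test_that("N bases are excluded from island statistics", {
  set.seed(34)
  s <- paste0(rand_dna(1000), cg_rich_dna(400),
              strrep("N", 300), rand_dna(1000))
  g <- genome_from_strings(list(chr1 = s))
  got <- scan_cgi(g)
  exp <- cgi_window_oracle(s)
  expect_equal(start(got), exp$start)
  expect_equal(end(got), exp$end)
})

test_that("peaks are assigned by the 50%-overlap rule", {
  ann <- one_gene_annotation()
  # fully inside the CDS (and >= 50% inside the repeat overlay)
  pk <- GRanges("chr1", IRanges(c(6101, 9000, 5451), width = c(100, 100, 100)))
  res <- annotate_peaks(pk, ann)
  expect_equal(res$assignment[1], "cds")
  expect_true(res$in_repeats[1])
  expect_true(res$repeat_class_hits[1, "LINE"])
  # fully intergenic
  expect_equal(res$assignment[2], "downstream2kb")
  # 50/50 split utr5/cds resolved by precedence (cds wins)
  expect_equal(res$assignment[3], "cds")

  # 49 bp in CDS (5452..5500 in utr5 side): 49 utr5 + 51 cds? construct the
  # printed example: 49 in one category, 51 in the other -> majority wins
  pk2 <- GRanges("chr1", IRanges(5452, 5551))  # 49 bp utr5, 51 bp cds
  expect_equal(annotate_peaks(pk2, ann)$assignment, "cds")
  pk3 <- GRanges("chr1", IRanges(5450, 5549))  # 51 bp utr5, 49 bp cds
  expect_equal(annotate_peaks(pk3, ann)$assignment, "utr5")
})

test_that("peak assignment counts equal a per-bp overlap oracle", {
  set.seed(41)
  lens <- c(chr1 = 50000L, chr2 = 50000L)
  gm <- random_gene_models(lens, n_per_chrom = 5)
  si <- GenomeInfoDb::Seqinfo(names(lens), unname(lens))
  rep_gr <- GRanges(sample(names(lens), 30, replace = TRUE),
                    IRanges(sample.int(49000, 30), width = sample(100:900, 30)))
  rep_gr$class <- sample(c("LINE", "SINE", "LTR"), 30, replace = TRUE)
  ann <- derive_features(gm, si, repeats = rep_gr)

  n <- 500
  peaks <- GRanges(sample(names(lens), n, replace = TRUE),
                   IRanges(sample.int(49000, n),
                           width = sample(100:500, n, replace = TRUE)))
  res <- annotate_peaks(peaks, ann)

  lab <- bp_partition_oracle(gm, lens)
  repcov <- lapply(names(lens), function(ch) cover_vec(rep_gr, ch, lens[[ch]]))
  names(repcov) <- names(lens)
  for (i in seq_len(n)) {
    ch <- as.character(seqnames(peaks))[i]
    span <- start(peaks)[i]:min(end(peaks)[i], lens[[ch]])
    w <- width(peaks)[i]
    cnt <- table(factor(lab[[ch]][span], levels = FEATURE_CATEGORIES))
    hit <- names(cnt)[cnt >= 0.5 * w]
    want <- if (length(hit)) FEATURE_CATEGORIES[
      min(match(hit, FEATURE_CATEGORIES))] else NA_character_
    expect_identical(res$assignment[i], want)
    expect_identical(res$in_repeats[i],
                     sum(repcov[[ch]][span]) >= 0.5 * w)
  }
})

test_that("methylation density equals a bp-array oracle and is invariant to fragmentation", {
  set.seed(42)
  lens <- c(chr1 = 50000L)
  gm <- random_gene_models(lens, n_per_chrom = 4)
  si <- GenomeInfoDb::Seqinfo(names(lens), unname(lens))
  ann <- derive_features(gm, si)
  n <- 200
  peaks <- GRanges("chr1", IRanges(sample.int(49000, n),
                                   width = sample(100:500, n)))
  dens <- methylation_density(peaks, ann)

  pv <- cover_vec(peaks, "chr1", lens[["chr1"]])
  lab <- bp_partition_oracle(gm, lens)[["chr1"]]
  for (cat in FEATURE_CATEGORIES) {
    area <- sum(lab == cat)
    if (area == 0) next
    expect_equal(unname(dens[cat]), sum(pv & lab == cat) / area,
                 tolerance = 1e-12, label = cat)
  }
  expect_equal(unname(dens["genome"]), mean(pv), tolerance = 1e-12)

  # splitting peaks into adjacent pieces changes nothing
  mid <- floor((start(peaks) + end(peaks)) / 2)
  frag <- c(GRanges("chr1", IRanges(start(peaks), mid)),
            GRanges("chr1", IRanges(mid + 1, end(peaks))))
  expect_equal(methylation_density(frag, ann), dens)

  # peaks exactly tiling a class -> density 1; empty peaks -> 0
  expect_equal(unname(methylation_density(ann$categories$cds, ann)["cds"]), 1)
  d0 <- methylation_density(GRanges(), ann)
  expect_true(all(d0[!is.na(d0)] == 0))
})

test_that("gene body metaprofile behaves at the extremes and under mirroring", {
  gff <- tempfile(fileext = ".gff")
  writeLines(c("chr1\tgene\t10001\t14000\t+\tgP",
               "chr1\texon\t10001\t14000\t+\tgP",
               "chr1\tCDS\t10501\t13500\t+\tgP"), gff)
  gm <- read_gene_models(gff)
  si <- GenomeInfoDb::Seqinfo("chr1", 30000)

  # peaks covering the body exactly: body bins 1, flank bins 0
  prof <- gene_body_profile(GRanges("chr1", IRanges(10001, 14000)), gm, si)
  expect_length(prof, 80)
  expect_equal(as.numeric(prof[21:60]), rep(1, 40))
  expect_equal(as.numeric(prof[c(1:20, 61:80)]), rep(0, 40))
  expect_equal(attr(prof, "n_genes"), 1)

  # no peaks: all bins zero
  expect_equal(as.numeric(gene_body_profile(GRanges(), gm, si)), rep(0, 80))

  # mirrored minus-strand gene with reflected peaks gives the same profile
  L <- 30000
  set.seed(51)
  pk <- GRanges("chr1", IRanges(sample(8000:16000, 20), width = 120))
  gffm <- tempfile(fileext = ".gff")
  writeLines(c(sprintf("chr1\tgene\t%d\t%d\t-\tgM", L - 14000 + 1, L - 10001 + 1),
               sprintf("chr1\texon\t%d\t%d\t-\tgM", L - 14000 + 1, L - 10001 + 1),
               sprintf("chr1\tCDS\t%d\t%d\t-\tgM", L - 13500 + 1, L - 10501 + 1)),
             gffm)
  gmm <- read_gene_models(gffm)
  pkm <- GRanges("chr1", IRanges(L - end(pk) + 1, L - start(pk) + 1))
  p1 <- gene_body_profile(pk, gm, si)
  p2 <- gene_body_profile(pkm, gmm, si)
  expect_equal(as.numeric(p1), as.numeric(p2))
})

test_that("CGI methylation summary counts and percentages are exact", {
  ann <- one_gene_annotation()
  cgis <- GRanges("chr1", IRanges(c(3501, 6001, 9500, 12000),
                                  width = c(400, 400, 400, 400)))
  # peaks: 1 bp overlap with CGI 1; full overlap with CGI 2; none else
  peaks <- GRanges("chr1", IRanges(c(3900, 6001), width = c(100, 400)))
  s <- cgi_methylation_summary(cgis, peaks, ann)
  expect_equal(s$total_cgis, 4)
  expect_equal(s$total_methylated, 2)
  expect_equal(s$percent_methylated, 50.00)
  # CGI 1 sits fully in upstream2kb; CGI 2 fully in cds
  expect_equal(unname(s$category_counts["upstream2kb"]), 1)
  expect_equal(unname(s$category_counts["cds"]), 1)
  expect_equal(sum(s$category_counts), s$total_methylated)

  # an intergenic CGI counts under "other" when methylated
  s2 <- cgi_methylation_summary(cgis, GRanges("chr1", IRanges(12100, 12200)),
                                ann)
  expect_equal(unname(s2$category_counts["other"]), 1)

  # fractional-overlap option
  s3 <- cgi_methylation_summary(cgis, peaks, ann, min_overlap_frac = 0.5)
  expect_equal(s3$total_methylated, 1)

  # zero peaks
  s0 <- cgi_methylation_summary(cgis, GRanges(), ann)
  expect_equal(s0$total_methylated, 0)
  expect_equal(s0$percent_methylated, 0.00)
})
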