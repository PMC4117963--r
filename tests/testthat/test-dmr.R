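test_that("peak-set merging forms connected components of the union", {
  a <- GRanges("chr1", IRanges(101, 200))
  b <- GRanges("chr1", IRanges(151, 300))
  m <- merge_peak_sets(a, b)
  expect_length(m, 1)
  expect_equal(start(m), 101L)
  expect_equal(end(m), 300L)

  # disjoint sets concatenate
  a <- GRanges("chr1", IRanges(c(100, 1000), width = 50))
  b <- GRanges("chr1", IRanges(c(5000, 9000), width = 50))
  expect_length(merge_peak_sets(a, b), 4)

  # book-ended peaks are joined
  a <- GRanges("chr1", IRanges(101, 200))
  b <- GRanges("chr1", IRanges(201, 250))
  expect_length(merge_peak_sets(a, b), 1)

  # random sets equal a per-bp union oracle
  set.seed(61)
  L <- 20000
  a <- GRanges("chr1", IRanges(sample.int(L - 500, 60), width = sample(50:400, 60)))
  b <- GRanges("chr1", IRanges(sample.int(L - 500, 60), width = sample(50:400, 60)))
  m <- merge_peak_sets(a, b)
  v <- cover_vec(a, "chr1", L) | cover_vec(b, "chr1", L)
  expect_identical(cover_vec(m, "chr1", L), v)
  expect_false(is.unsorted(start(m)))
  expect_true(all(start(m)[-1] > end(m)[-length(m)] + 1))
})

test_that("reads are counted by the 50%-of-read rule, once each", {
  regions <- GRanges("chr1", IRanges(c(1001, 2001), width = 500))
  # fully inside; 40% overlap (20 of 50 bp); exactly 50%
  reads <- GRanges("chr1", IRanges(c(1101, 971, 976), width = 50))
  expect_equal(count_reads(regions, reads), c(2L, 0L))
  # a read straddling two adjacent regions goes to the larger overlap only
  regions2 <- GRanges("chr1", IRanges(c(1001, 1501), width = 500))
  straddle <- GRanges("chr1", IRanges(1481, 1530))  # 20 bp | 30 bp
  expect_equal(count_reads(regions2, straddle), c(0L, 1L))

  # random reads/regions vs brute force
  set.seed(62)
  L <- 50000
  regions <- reduce(GRanges("chr1", IRanges(sample.int(L, 40),
                                            width = sample(200:600, 40))))
  reads <- GRanges("chr1", IRanges(sample.int(L - 50, 800), width = 50))
  got <- count_reads(regions, reads)
  brute <- integer(length(regions))
  for (i in seq_along(reads)) {
    ov <- pmin(end(reads)[i], end(regions)) - pmax(start(reads)[i],
                                                   start(regions)) + 1
    ov[ov < 0] <- 0
    if (max(ov) >= 0.5 * width(reads)[i])
      brute[which.max(ov)] <- brute[which.max(ov)] + 1L
  }
  expect_equal(got, brute)
})

test_that("the 2x2 chi-square matches stats::chisq.test without correction", {
  cases <- rbind(c(30, 10, 1000, 1000), c(5, 25, 2000, 1500),
                 c(100, 80, 5000, 5000), c(1, 9, 300, 300),
                 c(40, 10, 12000, 10500))
  for (i in seq_len(nrow(cases))) {
    a <- cases[i, 1]; b <- cases[i, 2]; ta <- cases[i, 3]; tb <- cases[i, 4]
    got <- test_regions(a, b, ta, tb)
    ref <- chi2_oracle(a, b, ta, tb)
    expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, unname(ref$p.value), tolerance = 1e-12)
  }
  # printed example: 30 vs 10 at equal totals -> fold 3
  expect_equal(test_regions(30, 10, 1000, 1000)$fold, 3.0)
  # symmetric table: chi2 0, p 1, fold 1
  sym <- test_regions(20, 20, 1000, 1000)
  expect_equal(sym$chi2, 0)
  expect_equal(sym$p, 1)
  expect_equal(sym$fold, 1)
  # pseudocount only for the fold, not the statistic
  z <- test_regions(0, 12, 1000, 1000)
  expect_equal(z$fold, (0.5 / 1000) / (12 / 1000))
  expect_equal(z$chi2, unname(chi2_oracle(0, 12, 1000, 1000)$statistic),
               tolerance = 1e-12)
})

test_that("a fold of exactly 2 is excluded (strictly greater-than rule)", {
  sim <- simulate_dmr_experiment(n_null = 0, n_dmr = 2, seed = 3)
  regions <- sim$regions
  # craft reads: region 1 gets 40 vs 20, region 2 gets 20 vs 40 -> equal
  # totals, normalised folds exactly 2 and 0.5
  mk <- function(n1, n2) {
    GRanges("chrSim", IRanges(c(rep(start(regions)[1] + 10, n1),
                                rep(start(regions)[2] + 10, n2)),
                              width = 50))
  }
  res <- call_dmrs(regions, regions, mk(40, 20), mk(20, 40))
  expect_equal(res$table$fold, c(2, 0.5))
  expect_true(any(res$table$q < 0.05))
  expect_length(res$dmrs, 0)
  # a slightly lower bar admits both
  res2 <- call_dmrs(regions, regions, mk(40, 20), mk(20, 40), min_fold = 1.9)
  expect_length(res2$dmrs, 2)
})

test_that("identical samples yield no DMRs and a single region has q = p", {
  sim <- simulate_dmr_experiment(n_null = 30, n_dmr = 0, seed = 4)
  res <- call_dmrs(sim$peaks_a, sim$peaks_b, sim$reads_a, sim$reads_a)
  expect_length(res$dmrs, 0)
  expect_true(all(res$table$chi2[res$table$tested] == 0))

  one <- simulate_dmr_experiment(n_null = 1, n_dmr = 0, seed = 5)
  r1 <- call_dmrs(one$peaks_a, one$peaks_b, one$reads_a, one$reads_b)
  expect_equal(r1$table$q[r1$table$tested], r1$table$p[r1$table$tested])
})

test_that("BH adjustment in call_dmrs matches the step-up definition", {
  sim <- simulate_dmr_experiment(n_null = 18, n_dmr = 2, seed = 6)
  res <- call_dmrs(sim$peaks_a, sim$peaks_b, sim$reads_a, sim$reads_b)
  tab <- res$table[res$table$tested, ]
  expect_equal(tab$q, bh_oracle(tab$p), tolerance = 1e-12)
  expect_true(all(tab$q >= tab$p))
})

test_that("swapping samples mirrors direction and inverts folds", {
  sim <- simulate_dmr_experiment(n_null = 50, n_dmr = 10, seed = 7)
  ab <- call_dmrs(sim$peaks_a, sim$peaks_b, sim$reads_a, sim$reads_b)
  ba <- call_dmrs(sim$peaks_b, sim$peaks_a, sim$reads_b, sim$reads_a)
  expect_equal(ab$table$chi2, ba$table$chi2)
  expect_equal(ab$table$p, ba$table$p)
  expect_equal(ab$table$q, ba$table$q)
  t1 <- ab$table[ab$table$tested, ]; t2 <- ba$table[ba$table$tested, ]
  expect_equal(t1$fold, 1 / t2$fold, tolerance = 1e-12)
  swap <- c(hyper = "hypo", hypo = "hyper")
  expect_equal(unname(swap[t1$direction]), t2$direction)
  expect_equal(length(ab$dmrs), length(ba$dmrs))
})

test_that("raising min_fold never increases the number of DMRs", {
  sim <- simulate_dmr_experiment(n_null = 100, n_dmr = 20, seed = 8)
  ns <- vapply(c(1.5, 2, 2.5, 3, 4), function(f)
    length(call_dmrs(sim$peaks_a, sim$peaks_b, sim$reads_a, sim$reads_b,
                     min_fold = f)$dmrs), numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("low-count regions are dropped before testing and reported", {
  sim <- simulate_dmr_experiment(n_null = 20, n_dmr = 0, depth_null = 1,
                                 seed = 9)
  res <- call_dmrs(sim$peaks_a, sim$peaks_b, sim$reads_a, sim$reads_b)
  expect_equal(res$n_tested + res$n_dropped_low_count, res$n_regions)
  expect_true(all(is.na(res$table$p[!res$table$tested])))
  low <- res$table$count_a + res$table$count_b < 5
  expect_equal(sum(low), res$n_dropped_low_count)
})

test_that("DMR summaries count directions and measure per-class density", {
  set.seed(71)
  lens <- c(chr1 = 50000L)
  gm <- random_gene_models(lens, n_per_chrom = 3)
  si <- GenomeInfoDb::Seqinfo(names(lens), unname(lens))
  rep_gr <- GRanges("chr1", IRanges(c(30000, 40000), width = c(1000, 800)))
  rep_gr$class <- c("LINE", "SINE")
  ann <- derive_features(gm, si, repeats = rep_gr)

  dmrs <- GRanges("chr1", IRanges(c(30000, 30500, 40100), width = 300))
  dmrs$direction <- c("hyper", "hyper", "hypo")
  s <- summarize_dmrs(dmrs, ann)
  expect_equal(unname(s$counts), c(2, 1))
  # hypo DMR tiles 300 of the 800-bp SINE
  expect_equal(s$density["SINE", "hypo"], 300 / 800)
  expect_equal(s$density["SINE", "hyper"], 0)

  # DMRs exactly tiling the LINE element give density 1
  tile <- GRanges("chr1", IRanges(30000, 30999))
  tile$direction <- "hyper"
  s2 <- summarize_dmrs(tile, ann)
  expect_equal(s2$density["LINE", "hyper"], 1)
  expect_equal(unname(s2$counts), c(1, 0))
})
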