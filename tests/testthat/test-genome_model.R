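test_that("FASTA reading indexes records and retrieves exact subsequences", {
  set.seed(101)
  seqs <- list(chr1 = rand_dna(1000), chr2 = rand_dna(700),
               chr3 = rand_dna(450))
  g <- genome_from_strings(seqs)
  expect_equal(GenomeInfoDb::seqnames(g$seqinfo), c("chr1", "chr2", "chr3"))
  expect_equal(unname(GenomeInfoDb::seqlengths(g$seqinfo)),
               c(1000L, 700L, 450L))
  expect_equal(g$total_size, 2150)

  # first 10 bases verbatim
  expect_equal(as.character(get_sequence(g,
    GRanges("chr1", IRanges(1, 10)))), substr(seqs$chr1, 1, 10))

  # shuffled retrievals against plain substring slicing
  for (i in 1:25) {
    ch <- sample(names(seqs), 1)
    L <- nchar(seqs[[ch]])
    s <- sample.int(L - 20, 1); e <- s + sample.int(20, 1)
    got <- as.character(get_sequence(g, GRanges(ch, IRanges(s, e))))
    expect_equal(got, substr(seqs[[ch]], s, e))
    expect_equal(nchar(got), e - s + 1)
  }

  expect_error(get_sequence(g, GRanges("chr1", IRanges(990, 1010))),
               "bounds")
  expect_error(get_sequence(g, GRanges("chrX", IRanges(1, 10))),
               "unknown")
})

test_that("duplicate or empty FASTA records are rejected", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GGCC"), fa)
  expect_error(read_genome_fasta(fa), "duplicate")
  writeLines(c(">a", "ACGT", ">b", ""), fa)
  expect_error(read_genome_fasta(fa), "empty")
})

test_that("BED round-trips preserve coordinates, names and classes", {
  set.seed(102)
  n <- 100
  gr <- GRanges(sample(c("chr1", "chr2"), n, replace = TRUE),
                IRanges(start = sample.int(5000, n),
                        width = sample.int(300, n)))
  gr$name <- sample(c("LINE", "SINE", "LTR"), n, replace = TRUE)
  bed <- tempfile(fileext = ".bed")
  write_bed(gr, bed)
  back <- read_bed(bed)
  expect_equal(start(back), start(gr))
  expect_equal(end(back), end(gr))
  expect_equal(as.character(seqnames(back)), as.character(seqnames(gr)))
  expect_equal(back$name, gr$name)

  # 0-based half-open on disk: "chr1\t100\t250" is 1-based 101..250
  writeLines("chr1\t100\t250", bed)
  one <- read_bed(bed)
  expect_equal(start(one), 101L)
  expect_equal(end(one), 250L)
  expect_equal(width(one), 150L)

  # unknown chromosome handling against a genome index
  si <- GenomeInfoDb::Seqinfo(c("chr1"), 10000)
  writeLines(c("chr1\t10\t20", "chrUn\t5\t9"), bed)
  expect_error(read_bed(bed, seqinfo = si), "unknown")
  expect_message(ok <- read_bed(bed, seqinfo = si, unknown_chrom = "skip"),
                 "skipping")
  expect_length(ok, 1)
})

test_that("gene models round-trip through GFF-lite", {
  set.seed(103)
  gm <- random_gene_models(c(chr1 = 60000, chr2 = 40000))
  path <- tempfile(fileext = ".gff")
  write_gene_models(gm, path)
  back <- read_gene_models(path)
  expect_equal(names(back$genes), names(gm$genes))
  expect_equal(start(back$genes), start(gm$genes))
  expect_equal(as.character(strand(back$genes)),
               as.character(strand(gm$genes)))
  expect_equal(back$cds, gm$cds)
  for (id in names(gm$genes))
    expect_equal(start(back$exons[[id]]), start(sort(gm$exons[[id]])))
})

test_that("derive_features follows the category definitions exactly", {
  gff <- tempfile(fileext = ".gff")
  writeLines(c("chr1\tgene\t5001\t8000\t+\tgA",
               "chr1\texon\t5001\t8000\t+\tgA",
               "chr1\tCDS\t5501\t7500\t+\tgA"), gff)
  gm <- read_gene_models(gff)
  si <- GenomeInfoDb::Seqinfo("chr1", 20000)
  ann <- derive_features(gm, si)
  cats <- ann$categories
  expect_equal(as.data.frame(cats$upstream2kb)[, c("start", "end")],
               data.frame(start = 3001L, end = 5000L))
  expect_equal(as.data.frame(cats$utr5)[, c("start", "end")],
               data.frame(start = 5001L, end = 5500L))
  expect_equal(as.data.frame(cats$cds)[, c("start", "end")],
               data.frame(start = 5501L, end = 7500L))
  expect_equal(as.data.frame(cats$utr3)[, c("start", "end")],
               data.frame(start = 7501L, end = 8000L))
  expect_equal(as.data.frame(cats$downstream2kb)[, c("start", "end")],
               data.frame(start = 8001L, end = 10000L))
  expect_length(cats$intron, 0)

  # minus-strand gene: the upstream flank lies above the gene span
  writeLines(c("chr1\tgene\t5001\t8000\t-\tgB",
               "chr1\texon\t5001\t8000\t-\tgB",
               "chr1\tCDS\t5501\t7500\t-\tgB"), gff)
  ann2 <- derive_features(read_gene_models(gff), si)
  expect_equal(start(ann2$categories$upstream2kb), 8001L)
  expect_equal(end(ann2$categories$upstream2kb), 10000L)
  expect_equal(as.data.frame(ann2$categories$utr5)[, c("start", "end")],
               data.frame(start = 7501L, end = 8000L))
})

test_that("derived categories partition the genome and match a per-bp oracle", {
  for (seed in c(11, 42)) {
    set.seed(seed)
    lens <- c(chr1 = 50000L, chr2 = 50000L)
    gm <- random_gene_models(lens, n_per_chrom = 5)
    si <- GenomeInfoDb::Seqinfo(names(lens), unname(lens))
    ann <- derive_features(gm, si)

    w <- vapply(ann$categories, function(g)
      sum(as.numeric(width(reduce(g)))), numeric(1))
    expect_equal(sum(w), sum(as.numeric(lens)))
    for (i in 1:6) for (j in (i + 1):7)
      expect_length(GenomicRanges::intersect(ann$categories[[i]],
                                             ann$categories[[j]],
                                             ignore.strand = TRUE), 0)

    lab <- bp_partition_oracle(gm, lens)
    for (cat in FEATURE_CATEGORIES) {
      for (ch in names(lens)) {
        got <- cover_vec(ann$categories[[cat]], ch, lens[[ch]])
        expect_identical(got, lab[[ch]] == cat,
                         label = paste(seed, cat, ch))
      }
    }
  }
})

test_that("flanks are clipped at chromosome edges", {
  gff <- tempfile(fileext = ".gff")
  writeLines(c("chr1\tgene\t501\t4000\t+\tgE",
               "chr1\texon\t501\t4000\t+\tgE",
               "chr1\tCDS\t901\t3600\t+\tgE"), gff)
  gm <- read_gene_models(gff)
  ann <- derive_features(gm, GenomeInfoDb::Seqinfo("chr1", 5000))
  expect_equal(start(ann$categories$upstream2kb), 1L)
  expect_equal(end(ann$categories$upstream2kb), 500L)
  expect_equal(end(ann$categories$downstream2kb), 5000L)
})
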