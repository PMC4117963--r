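#' Read a FASTQ file
#'
#' The Phred offset (33 or 64) is auto-detected from the quality characters:
#' any character below ASCII 59 implies offset 33; a minimum at or above
#' ASCII 64 implies 64.
#'
#' @param path Path to an (uncompressed or gzipped) FASTQ file.
#' @return Object of class `fastq_reads`: list with `id` (character), `seq`
#'   ([Biostrings::DNAStringSet]), `qual` (list of integer Phred vectors) and
#'   `offset` (the detected Phred offset).
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
  ids <- sub("\\s.*$", "", names(seqs))
  qchar <- as.character(S4Vectors::mcols(seqs)$qualities)
  codes <- lapply(qchar, utf8ToInt)
  mn <- if (length(codes)) min(vapply(codes, min, numeric(1))) else 33L
  mx <- if (length(codes)) max(vapply(codes, max, numeric(1))) else 33L
  # chars below ";" only occur in Phred+33; chars above "J" (Q41 at +33)
  # only in Phred+64
  offset <- if (mn < 59) 33L else if (mx > 74) 64L else 33L
  qual <- lapply(codes, function(x) x - offset)
  names(seqs) <- NULL
  structure(list(id = ids, seq = seqs, qual = qual, offset = offset),
            class = "fastq_reads")
}

#' @export
print.fastq_reads <- function(x, ...) {
  cat("fastq_reads:", length(x$id), "reads (Phred+", x$offset, ")\n", sep = "")
  invisible(x)
}

#' Write FASTQ
#'
#' @param reads A `fastq_reads` object.
#' @param path Output path.
#' @param offset Phred offset for encoding (default 33).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, offset = 33L) {
  qs <- Biostrings::BStringSet(vapply(reads$qual, function(q)
    intToUtf8(q + offset), character(1)))
  seqs <- reads$seq
  names(seqs) <- reads$id
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = qs)
  invisible(path)
}

#' Filter paired-end reads by the four-criteria quality rule
#'
#' A read pair is removed when either mate (1) has 10% or more N bases,
#' (2) has a mean Phred quality below 20, or (3) has 5% or more bases with
#' quality below 20 — or when (4) both mates called exactly the same base
#' string (switchable, see `pair_identical_filter`). Removal is attributed to
#' the first failing criterion in order 1-4. Kept pairs preserve input order.
#'
#' Adapter trimming is not performed here; adapters are assumed removed
#' upstream.
#'
#' @param r1,r2 `fastq_reads` objects for the two mates, paired by position
#'   and read id (a trailing `/1`, `/2` suffix is ignored when pairing).
#' @param max_n_frac Criterion 1 threshold (default 0.10, inclusive).
#' @param min_mean_q Criterion 2 threshold (default 20; mean < 20 removes).
#' @param max_lowq_frac Criterion 3 threshold (default 0.05, inclusive) on the
#'   fraction of bases with quality below `low_q`.
#' @param low_q Quality defining a low-quality base (default 20).
#' @param pair_identical_filter Apply criterion 4 (default TRUE).
#' @return List with `r1`, `r2` (kept mates, `fastq_reads`) and `report`
#'   (class `qc_report`: `total_reads` [pairs], `kept_reads`,
#'   `removed_by_criterion` named vector over
#'   n_frac/mean_q/low_q_frac/pair_identical, `clean_fraction`,
#'   `phred_offset`).
#' @export
filter_reads <- function(r1, r2, max_n_frac = 0.10, min_mean_q = 20,
                         max_lowq_frac = 0.05, low_q = 20,
                         pair_identical_filter = TRUE) {
  stopifnot(is(r1, "fastq_reads"), is(r2, "fastq_reads"))
  if (length(r1$id) != length(r2$id)) stop("mate files differ in read count")
  strip <- function(x) sub("/[12]$", "", x)
  if (!all(strip(r1$id) == strip(r2$id)))
    stop("unpaired read id(s): mates must be in matching order")
  bad_len <- function(r) any(Biostrings::width(r$seq) != lengths(r$qual))
  if (bad_len(r1) || bad_len(r2))
    stop("length mismatch between bases and qualities")

  stats <- function(r) {
    nfrac <- as.numeric(Biostrings::letterFrequency(r$seq, "N")) /
      Biostrings::width(r$seq)
    meanq <- vapply(r$qual, mean, numeric(1))
    lowq <- vapply(r$qual, function(q) mean(q < low_q), numeric(1))
    list(nfrac = nfrac, meanq = meanq, lowq = lowq)
  }
  s1 <- stats(r1); s2 <- stats(r2)

  fail1 <- s1$nfrac >= max_n_frac | s2$nfrac >= max_n_frac
  fail2 <- s1$meanq < min_mean_q | s2$meanq < min_mean_q
  fail3 <- s1$lowq >= max_lowq_frac | s2$lowq >= max_lowq_frac
  fail4 <- if (pair_identical_filter)
    as.character(r1$seq) == as.character(r2$seq) else rep(FALSE, length(r1$id))

  first_fail <- rep(NA_character_, length(r1$id))
  first_fail[fail4] <- "pair_identical"
  first_fail[fail3] <- "low_q_frac"
  first_fail[fail2] <- "mean_q"
  first_fail[fail1] <- "n_frac"
  keep <- is.na(first_fail)

  removed <- vapply(c("n_frac", "mean_q", "low_q_frac", "pair_identical"),
                    function(k) sum(first_fail == k, na.rm = TRUE), numeric(1))
  report <- structure(list(
    total_reads = length(r1$id),
    kept_reads = sum(keep),
    removed_by_criterion = removed,
    clean_fraction = sum(keep) / max(1L, length(r1$id)),
    phred_offset = c(r1 = r1$offset, r2 = r2$offset)),
    class = "qc_report")

  subset_reads <- function(r) {
    structure(list(id = r$id[keep], seq = r$seq[keep], qual = r$qual[keep],
                   offset = r$offset), class = "fastq_reads")
  }
  list(r1 = subset_reads(r1), r2 = subset_reads(r2), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d of %d pairs kept (%.1f%% clean)\n",
              x$kept_reads, x$total_reads, 100 * x$clean_fraction))
  print(x$removed_by_criterion)
  invisible(x)
}
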