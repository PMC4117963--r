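#' Read a genome FASTA into an indexed object
#'
#' Loads all records of a FASTA file and builds a genome index (ordered
#' chromosome names and lengths). Sequence is held in memory; retrieval by
#' interval is exact and uppercased.
#'
#' @param path Path to a FASTA file.
#' @return An object of class `medip_genome`: a list with elements
#'   `seq` (a [Biostrings::DNAStringSet]), `seqinfo` (a
#'   [GenomeInfoDb::Seqinfo]) and `total_size` (total genome length in bp).
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate record names in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty FASTA record(s): ",
         paste(names(seqs)[Biostrings::width(seqs) == 0L], collapse = ", "))
  seqs <- Biostrings::DNAStringSet(toupper(seqs))
  si <- GenomeInfoDb::Seqinfo(seqnames = names(seqs),
                              seqlengths = Biostrings::width(seqs))
  structure(list(seq = seqs, seqinfo = si,
                 total_size = sum(as.numeric(Biostrings::width(seqs)))),
            class = "medip_genome")
}

#' @export
print.medip_genome <- function(x, ...) {
  cat("medip_genome:", length(x$seq), "sequence(s),",
      format(x$total_size, big.mark = ","), "bp total\n")
  invisible(x)
}

#' Whole-genome intervals for a genome or annotation
#'
#' @param x A `medip_genome` or any object with a `Seqinfo`.
#' @return A [GenomicRanges::GRanges] with one range per chromosome.
#' @export
genome_ranges <- function(x) {
  si <- if (is(x, "Seqinfo")) x else x$seqinfo
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(si),
                         IRanges::IRanges(1L, GenomeInfoDb::seqlengths(si)),
                         seqinfo = si)
}

#' Retrieve genome sequence over intervals
#'
#' @param genome A `medip_genome` from [read_genome_fasta()].
#' @param gr A [GenomicRanges::GRanges] of regions to extract.
#' @return A [Biostrings::DNAStringSet], one sequence per range, each of
#'   exactly `width(gr)` characters (plus strand returned as-is; no
#'   reverse-complementing).
#' @export
get_sequence <- function(genome, gr) {
  stopifnot(is(genome, "medip_genome"), is(gr, "GRanges"))
  chroms <- as.character(GenomeInfoDb::seqnames(gr))
  bad <- !chroms %in% names(genome$seq)
  if (any(bad)) stop("unknown chromosome(s): ", paste(unique(chroms[bad]), collapse = ", "))
  lens <- GenomeInfoDb::seqlengths(genome$seqinfo)[chroms]
  if (any(GenomicRanges::start(gr) < 1L) || any(GenomicRanges::end(gr) > lens))
    stop("interval outside chromosome bounds")
  out <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i) {
    as.character(Biostrings::subseq(genome$seq[[chroms[i]]],
                                    start = GenomicRanges::start(gr)[i],
                                    end = GenomicRanges::end(gr)[i]))
  }, character(1)))
  names(out) <- if (!is.null(names(gr))) names(gr) else NULL
  out
}

#' Read a BED file as GRanges
#'
#' BED is 0-based half-open on disk; ranges are returned in the 1-based closed
#' convention of [GenomicRanges::GRanges] (conversion handled by
#' [rtracklayer::import]). Input order is preserved. A 4th column is kept as
#' metadata column `name` (used for repeat class labels), a 5th as `score` and
#' a 6th as strand.
#'
#' @param path Path to a BED3+ file.
#' @param seqinfo Optional [GenomeInfoDb::Seqinfo]; when supplied, intervals on
#'   unknown chromosomes raise an error (`unknown_chrom = "error"`) or are
#'   dropped with a message (`"skip"`).
#' @param unknown_chrom `"error"` or `"skip"`.
#' @return A [GenomicRanges::GRanges].
#' @export
read_bed <- function(path, seqinfo = NULL, unknown_chrom = c("error", "skip")) {
  unknown_chrom <- match.arg(unknown_chrom)
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(seqinfo)) {
    known <- as.character(GenomeInfoDb::seqnames(gr)) %in%
      GenomeInfoDb::seqnames(seqinfo)
    if (!all(known)) {
      if (unknown_chrom == "error")
        stop("BED intervals on unknown chromosome(s): ",
             paste(unique(as.character(GenomeInfoDb::seqnames(gr))[!known]),
                   collapse = ", "))
      message("read_bed: skipping ", sum(!known),
              " interval(s) on unknown chromosomes")
      gr <- gr[known]
    }
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(seqinfo)
    GenomeInfoDb::seqinfo(gr) <- seqinfo
  }
  gr
}

#' Write GRanges to a BED file
#'
#' Emits tab-separated BED (0-based half-open) with as many columns as the
#' object carries: name (metadata column `name`), score, strand. Extra
#' metadata columns are appended as BED6+ columns when `extra_cols = TRUE`.
#'
#' @param gr A [GenomicRanges::GRanges].
#' @param path Output path.
#' @param extra_cols Append remaining metadata columns after the first six.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path, extra_cols = FALSE) {
  mc <- S4Vectors::mcols(gr)
  nm <- if ("name" %in% names(mc)) as.character(mc$name)
        else rep(".", length(gr))
  sc <- if ("score" %in% names(mc)) mc$score else rep(0, length(gr))
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "."
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = nm, score = sc, strand = st,
                   stringsAsFactors = FALSE)
  if (extra_cols) {
    keep <- setdiff(names(mc), c("name", "score"))
    for (k in keep) df[[k]] <- mc[[k]]
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
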