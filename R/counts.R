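# Read-pair and haplotype-block counting over segments.

#' Count read pairs fully contained in segments
#'
#' Each uniquely aligned concordant read pair is counted in the single
#' segment that fully contains its fragment span; pairs straddling a segment
#' boundary are counted nowhere. Input can be a coordinate-sorted BAM file
#' (fragment spans taken from proper pairs, leftmost mate) or a data.frame
#' of fragment intervals.
#'
#' @param alignments either a path to a coordinate-sorted BAM file
#'   (requires \pkg{Rsamtools}) or a data.frame with columns \code{chrom},
#'   \code{start}, \code{end} (fragment span, 0-based half-open),
#'   coordinate-sorted within chromosome.
#' @param segments GRanges of segments (\code{\link{partitionGenome}}).
#' @param minMapq minimum mapping quality for BAM input (default 30; reads
#'   below are treated as non-unique).
#' @return \code{segments} with a \code{readcount} metadata column filled.
#' @export
countReadPairs <- function(alignments, segments, minMapq = 30L) {
  if (is.character(alignments)) {
    frags <- bamFragments(alignments, minMapq)
  } else {
    stopifnot(all(c("chrom", "start", "end") %in% names(alignments)))
    frags <- alignments
    byChrom <- split(frags$start, frags$chrom)
    if (any(vapply(byChrom, is.unsorted, logical(1))))
      stop("alignments must be coordinate-sorted")
  }
  fr <- grFromZeroBased(frags$chrom, frags$start, frags$end)
  within <- GenomicRanges::findOverlaps(fr, segments, type = "within",
                                        ignore.strand = TRUE)
  counts <- tabulate(S4Vectors::subjectHits(within), nbins = length(segments))
  S4Vectors::mcols(segments)$readcount <- counts
  segments
}

bamFragments <- function(path, minMapq) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("BAM input requires the Rsamtools package")
  hdr <- Rsamtools::scanBamHeader(path)[[1]]$text
  so <- unlist(hdr[names(hdr) == "@HD"])
  if (!any(grepl("SO:coordinate", so)))
    stop("BAM must be coordinate-sorted")
  flag <- Rsamtools::scanBamFlag(isProperPair = TRUE, isSecondaryAlignment = FALSE,
                                 isDuplicate = FALSE, isNotPassingQualityControls = FALSE)
  p <- Rsamtools::ScanBamParam(flag = flag, what = c("rname", "pos", "isize", "mapq"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(b$isize) & b$isize > 0 & b$mapq >= minMapq
  data.frame(chrom = as.character(b$rname)[keep],
             start = b$pos[keep] - 1,
             end = b$pos[keep] - 1 + b$isize[keep],
             stringsAsFactors = FALSE)
}

#' Aggregate haplotype-block allele counts into segments
#'
#' Haplotype blocks carry phased allele-1/allele-2 read counts; each block is
#' assigned to the segment containing its midpoint (unambiguous and stable
#' under boundary jitter) and counts are summed per segment.
#'
#' @param blocks data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open), \code{allele_1}, \code{allele_2}.
#' @param segments GRanges of segments.
#' @return \code{segments} with \code{allele_a_readcount} and
#'   \code{allele_b_readcount} metadata columns (allele A = block allele 1).
#' @export
aggregateAlleleCounts <- function(blocks, segments) {
  n <- length(segments)
  xa <- integer(n); xb <- integer(n)
  if (!is.null(blocks) && nrow(blocks) > 0) {
    stopifnot(all(c("chrom", "start", "end", "allele_1", "allele_2") %in% names(blocks)))
    mid <- floor((blocks$start + blocks$end) / 2)
    midGr <- grFromZeroBased(blocks$chrom, mid, mid + 1)
    hit <- GenomicRanges::findOverlaps(midGr, segments, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hit); si <- S4Vectors::subjectHits(hit)
    xa <- as.integer(tapplySum(blocks$allele_1[qi], si, n))
    xb <- as.integer(tapplySum(blocks$allele_2[qi], si, n))
  }
  S4Vectors::mcols(segments)$allele_a_readcount <- xa
  S4Vectors::mcols(segments)$allele_b_readcount <- xb
  segments
}

tapplySum <- function(x, idx, n) {
  out <- numeric(n)
  if (length(x)) {
    s <- tapply(x, factor(idx, levels = seq_len(n)), sum, default = 0)
    out <- as.numeric(s)
    out[is.na(out)] <- 0
  }
  out
}
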