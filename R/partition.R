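# Genome partitioning and segment containers.
#
# All coordinates in tables and breakend positions are 0-based half-open;
# GRanges containers (1-based closed) are converted at the boundary.

#' Convert 0-based half-open intervals to GRanges
#' @param chrom,start,end vectors (0-based half-open)
#' @param seqlengths optional named chromosome lengths
#' @return GRanges
#' @keywords internal
grFromZeroBased <- function(chrom, start, end, seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1, end = end))
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

segStart0 <- function(gr) GenomicRanges::start(gr) - 1
segEnd0 <- function(gr) GenomicRanges::end(gr)

# canonical chrom:position key; %.0f avoids scientific notation on doubles
posKey <- function(chrom, pos) sprintf("%s:%.0f", chrom, pos)

#' Validate a breakpoint table
#'
#' A breakpoint is a pair of oriented breakends; orientation +1 attaches the
#' junction to the segment ending at the breakend position (copy number may
#' drop across the boundary), -1 to the segment starting there.
#'
#' @param breakpoints data.frame with columns \code{id}, \code{chrom_1},
#'   \code{position_1}, \code{orientation_1}, \code{chrom_2},
#'   \code{position_2}, \code{orientation_2}; orientations coded +1/-1 (or
#'   "+"/"-"); positions 0-based boundary coordinates.
#' @return the normalised data.frame (orientations as integers)
#' @export
normalizeBreakpoints <- function(breakpoints) {
  if (is.null(breakpoints) || nrow(breakpoints) == 0) {
    return(data.frame(id = character(), chrom_1 = character(), position_1 = numeric(),
                      orientation_1 = integer(), chrom_2 = character(),
                      position_2 = numeric(), orientation_2 = integer(),
                      stringsAsFactors = FALSE))
  }
  need <- c("id", "chrom_1", "position_1", "orientation_1",
            "chrom_2", "position_2", "orientation_2")
  if (!all(need %in% names(breakpoints)))
    stop("breakpoint table must have columns: ", paste(need, collapse = ", "))
  bp <- breakpoints[, need]
  fixOri <- function(o) {
    if (is.character(o)) o <- ifelse(o %in% c("+", "+1", "1"), 1L, ifelse(o %in% c("-", "-1"), -1L, NA_integer_))
    o <- as.integer(o)
    if (any(is.na(o)) || !all(o %in% c(-1L, 1L))) stop("orientations must be +1/-1")
    o
  }
  bp$orientation_1 <- fixOri(bp$orientation_1)
  bp$orientation_2 <- fixOri(bp$orientation_2)
  bp$id <- as.character(bp$id)
  same <- bp$chrom_1 == bp$chrom_2 & bp$position_1 == bp$position_2
  if (any(same)) stop("breakpoint breakends must be distinct loci")
  bp
}

#' Partition a genome into segments at bin and breakend boundaries
#'
#' Tiles each chromosome with regular bins and further splits any bin
#' containing a breakend, so that every breakend coincides exactly with a
#' segment boundary. Segments are 0-based half-open internally; the returned
#' GRanges uses the usual 1-based convention.
#'
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @param breakpoints optional breakpoint table (see
#'   \code{\link{normalizeBreakpoints}}).
#' @param binSize regular bin length in bp (default 500 kb, a typical bin
#'   for 30X whole-genome copy-number analysis).
#' @return GRanges of segments with logical metadata columns
#'   \code{isBreakendBoundaryLeft}/\code{Right}.
#' @examples
#' partitionGenome(c(chr1 = 3000), binSize = 1000)
#' @export
partitionGenome <- function(chromLengths, breakpoints = NULL, binSize = 5e5) {
  stopifnot(binSize > 0, length(chromLengths) > 0, !is.null(names(chromLengths)))
  bp <- normalizeBreakpoints(breakpoints)
  bends <- data.frame(
    chrom = c(bp$chrom_1, bp$chrom_2),
    pos = c(bp$position_1, bp$position_2))
  if (nrow(bends)) {
    if (!all(bends$chrom %in% names(chromLengths)))
      stop("breakend on unknown chromosome")
    if (any(bends$pos < 0 | bends$pos > chromLengths[bends$chrom]))
      stop("breakend position outside chromosome bounds")
  }
  out <- lapply(names(chromLengths), function(ch) {
    len <- chromLengths[[ch]]
    cuts <- seq(0, len, by = binSize)
    if (cuts[length(cuts)] < len) cuts <- c(cuts, len)
    bpos <- sort(unique(bends$pos[bends$chrom == ch]))
    bpos <- bpos[bpos > 0 & bpos < len]
    allCuts <- sort(unique(c(cuts, bpos)))
    data.frame(chrom = ch, start = allCuts[-length(allCuts)],
               end = allCuts[-1],
               bendLeft = allCuts[-length(allCuts)] %in% bpos,
               bendRight = allCuts[-1] %in% bpos,
               stringsAsFactors = FALSE)
  })
  segs <- do.call(rbind, out)
  gr <- grFromZeroBased(segs$chrom, segs$start, segs$end,
                        seqlengths = unlist(chromLengths))
  S4Vectors::mcols(gr)$isBreakendBoundaryLeft <- segs$bendLeft
  S4Vectors::mcols(gr)$isBreakendBoundaryRight <- segs$bendRight
  S4Vectors::mcols(gr)$length <- GenomicRanges::width(gr)
  gr
}

#' Bias-adjusted effective segment lengths
#'
#' The effective length of a segment is the sum of per-position bias weights
#' over the segment; with unit weights it equals the segment length.
#'
#' @param segments GRanges of segments.
#' @param bias either \code{NULL} (unit weights), a single non-negative
#'   number (uniform weight), or a function \code{function(chrom, positions)}
#'   returning a non-negative weight per 0-based position.
#' @return numeric vector of effective lengths (bp).
#' @examples
#' gr <- partitionGenome(c(chr1 = 1000), binSize = 1000)
#' effectiveLengths(gr)            # 1000
#' effectiveLengths(gr, bias = .5) # 500
#' @export
effectiveLengths <- function(segments, bias = NULL) {
  w <- GenomicRanges::width(segments)
  if (is.null(bias)) return(as.numeric(w))
  if (is.numeric(bias) && length(bias) == 1) {
    if (bias < 0) stop("bias weight must be non-negative")
    return(as.numeric(w) * bias)
  }
  stopifnot(is.function(bias))
  chrom <- as.character(GenomicRanges::seqnames(segments))
  s0 <- segStart0(segments); e0 <- segEnd0(segments)
  vapply(seq_along(segments), function(i) {
    ww <- bias(chrom[i], seq.int(s0[i], e0[i] - 1))
    if (any(ww < 0)) stop("bias weight must be non-negative")
    sum(ww)
  }, numeric(1))
}

#' GC-quantile bias lookup
#'
#' Builds a per-position weight function from a coarse GC track: positions
#' are weighted by the value of a quantile-bin lookup table at their local
#' GC fraction. This stands in for position-specific bias models fitted to
#' real data; the simulator does not emulate GC bias, so unit weights are
#' the default elsewhere.
#'
#' @param gcTrack data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open) and \code{gc} (fraction in [0,1]).
#' @param lookup numeric vector of weights per GC quantile bin.
#' @return a function usable as the \code{bias} argument of
#'   \code{\link{effectiveLengths}}.
#' @export
gcQuantileBias <- function(gcTrack, lookup) {
  stopifnot(all(c("chrom", "start", "end", "gc") %in% names(gcTrack)),
            all(lookup >= 0))
  qs <- stats::quantile(gcTrack$gc, probs = seq(0, 1, length.out = length(lookup) + 1))
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  function(chrom, positions) {
    rows <- gcTrack[gcTrack$chrom == chrom, , drop = FALSE]
    idx <- findInterval(positions, rows$start)
    idx[idx < 1] <- 1
    gc <- rows$gc[pmin(idx, nrow(rows))]
    bin <- findInterval(gc, qs, rightmost.closed = TRUE)
    lookup[pmin(pmax(bin, 1), length(lookup))]
  }
}

#' Raw (continuous) copy numbers for visualisation
#'
#' Computes per-segment raw total, major and minor copy values from observed
#' depth and allele ratio given normal haploid depth and total tumour
#' haploid depth. Values may be negative or fractional; they are intended
#' for plotting, not inference.
#'
#' @param segments GRanges with metadata columns \code{readcount},
#'   \code{allele_a_readcount}, \code{allele_b_readcount},
#'   \code{effective_length}.
#' @param h per-clone haploid depths (normal first).
#' @param normalDepth haploid depth of the normal clone; defaults to
#'   \code{h[1]}.
#' @return data.frame with columns \code{raw_total}, \code{raw_major},
#'   \code{raw_minor} (the latter two \code{NA} where no allele counts).
#' @export
rawCopyNumbers <- function(segments, h, normalDepth = h[1]) {
  mc <- S4Vectors::mcols(segments)
  hT <- sum(h[-1])
  if (!hT > 0) stop("total tumour haploid depth must be positive")
  leff <- mc$effective_length
  rawTotal <- (mc$readcount / leff - 2 * normalDepth) / hT
  nab <- mc$allele_a_readcount + mc$allele_b_readcount
  fracMajor <- ifelse(nab > 0,
                      pmax(mc$allele_a_readcount, mc$allele_b_readcount) / nab, NA)
  rawMajor <- rawTotal * fracMajor
  data.frame(raw_total = rawTotal, raw_major = rawMajor,
             raw_minor = rawTotal - rawMajor)
}
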