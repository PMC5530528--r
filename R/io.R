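# Tab-separated tables (0-based half-open coordinates), config YAML and
# summary JSON.

#' Read a segment table
#'
#' TSV with header: chromosome, start, end, length, effective_length,
#' readcount, allele_a_readcount, allele_b_readcount (coordinates 0-based
#' half-open).
#'
#' @param path file path.
#' @return GRanges with the count metadata columns.
#' @export
readSegmentTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chromosome", "start", "end", "readcount")
  if (!all(need %in% names(d))) stop("segment table missing required columns")
  gr <- grFromZeroBased(d$chromosome, d$start, d$end)
  mc <- S4Vectors::mcols(gr)
  mc$length <- if (!is.null(d$length)) d$length else d$end - d$start
  mc$effective_length <- if (!is.null(d$effective_length)) d$effective_length else d$end - d$start
  mc$readcount <- d$readcount
  mc$allele_a_readcount <- if (!is.null(d$allele_a_readcount)) d$allele_a_readcount else 0L
  mc$allele_b_readcount <- if (!is.null(d$allele_b_readcount)) d$allele_b_readcount else 0L
  S4Vectors::mcols(gr) <- mc
  gr
}

#' Write a segment table
#' @param segments GRanges with count metadata columns.
#' @param path output file.
#' @export
writeSegmentTable <- function(segments, path) {
  mc <- S4Vectors::mcols(segments)
  d <- data.frame(
    chromosome = as.character(GenomicRanges::seqnames(segments)),
    start = segStart0(segments), end = segEnd0(segments),
    length = GenomicRanges::width(segments),
    effective_length = if (!is.null(mc$effective_length)) mc$effective_length
                       else GenomicRanges::width(segments),
    readcount = if (!is.null(mc$readcount)) mc$readcount else NA,
    allele_a_readcount = if (!is.null(mc$allele_a_readcount)) mc$allele_a_readcount else NA,
    allele_b_readcount = if (!is.null(mc$allele_b_readcount)) mc$allele_b_readcount else NA)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a breakpoint table
#'
#' TSV with header: breakpoint_id, chrom_1, position_1, orientation_1,
#' chrom_2, position_2, orientation_2; orientations "+"/"-".
#'
#' @param path file path.
#' @return normalised breakpoint data.frame (orientations +1/-1).
#' @export
readBreakpointTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(orientation_1 = "character",
                                 orientation_2 = "character"))
  if ("breakpoint_id" %in% names(d)) names(d)[names(d) == "breakpoint_id"] <- "id"
  normalizeBreakpoints(d)
}

#' Write a breakpoint table
#' @param breakpoints breakpoint data.frame (internal +1/-1 orientations).
#' @param path output file.
#' @export
writeBreakpointTable <- function(breakpoints, path) {
  bp <- normalizeBreakpoints(breakpoints)
  extra <- setdiff(names(breakpoints), names(bp))
  d <- data.frame(breakpoint_id = bp$id,
                  chrom_1 = bp$chrom_1, position_1 = bp$position_1,
                  orientation_1 = ifelse(bp$orientation_1 == 1, "+", "-"),
                  chrom_2 = bp$chrom_2, position_2 = bp$position_2,
                  orientation_2 = ifelse(bp$orientation_2 == 1, "+", "-"))
  for (cn in extra) d[[cn]] <- breakpoints[[cn]]
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write fit results (segment TSV, breakpoint TSV, summary JSON)
#'
#' @param fit a \linkS4class{CloneCNFit}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeFitResults <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  segs <- fit@segments
  mc <- S4Vectors::mcols(segs)
  d <- data.frame(
    chromosome = as.character(GenomicRanges::seqnames(segs)),
    start = segStart0(segs), end = segEnd0(segs))
  for (m in seq_len(ncol(mc$major))) {
    d[[paste0("major_", m)]] <- mc$major[, m]
    d[[paste0("minor_", m)]] <- mc$minor[, m]
  }
  segPath <- file.path(dir, "segment_copies.tsv")
  write.table(d, segPath, sep = "\t", quote = FALSE, row.names = FALSE)
  bpPath <- file.path(dir, "breakpoint_copies.tsv")
  if (nrow(fit@breakpoints)) writeBreakpointTable(fit@breakpoints, bpPath)
  sumPath <- file.path(dir, "summary.json")
  jsonlite::write_json(list(
    mode = fit@mode, h = fit@h, rho = fit@rho, elbo = fit@elbo,
    iterations = fit@iterations, converged = fit@converged,
    restartELBOs = fit@diagnostics$restartELBOs %||% numeric(0)),
    sumPath, auto_unbox = TRUE, digits = NA)
  invisible(c(segPath, bpPath, sumPath))
}

#' Read fit results back from a results directory
#'
#' Reconstructs a \linkS4class{CloneCNFit} from the TSV/JSON files written
#' by \code{\link{writeFitResults}} (copy-number calls, haploid depths and
#' summary only; variational internals are not serialised).
#'
#' @param dir directory written by \code{\link{writeFitResults}}.
#' @return a \linkS4class{CloneCNFit}.
#' @export
readFitResults <- function(dir) {
  d <- read.delim(file.path(dir, "segment_copies.tsv"))
  gr <- grFromZeroBased(d$chromosome, d$start, d$end)
  majCols <- grep("^major_", names(d), value = TRUE)
  minCols <- grep("^minor_", names(d), value = TRUE)
  S4Vectors::mcols(gr)$major <- as.matrix(d[, majCols])
  S4Vectors::mcols(gr)$minor <- as.matrix(d[, minCols])
  js <- jsonlite::read_json(file.path(dir, "summary.json"), simplifyVector = TRUE)
  bpPath <- file.path(dir, "breakpoint_copies.tsv")
  bp <- if (file.exists(bpPath)) readBreakpointTableFull(bpPath) else data.frame()
  new("CloneCNFit", segments = gr, breakpoints = bp,
      h = as.numeric(js$h), rho = as.numeric(js$rho),
      elbo = as.numeric(js$elbo), elboTrace = numeric(0),
      iterations = as.integer(js$iterations),
      converged = isTRUE(js$converged), mode = as.character(js$mode),
      posthoc = data.frame(), config = cloneCNConfig(), diagnostics = list())
}

readBreakpointTableFull <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(orientation_1 = "character",
                                 orientation_2 = "character"))
  if ("breakpoint_id" %in% names(d)) names(d)[names(d) == "breakpoint_id"] <- "id"
  base <- normalizeBreakpoints(d)
  extra <- setdiff(names(d), names(base))
  cbind(base, d[, extra, drop = FALSE])
}

#' Read a fit/simulation configuration from YAML
#'
#' Recognised keys: lambda, cMax, bMax, nTumour, family, nbInvDispersion,
#' nbMixWeight, alleleDispersion, outlierWeight, tol, maxIter, pilotIter,
#' normalFractions, cloneSplits, fitTheta, seed.
#'
#' @param path YAML file.
#' @return a \linkS4class{CloneCNConfig}.
#' @export
readConfigYAML <- function(path) {
  y <- yaml::read_yaml(path)
  pkeys <- c("family", "nbInvDispersion", "nbMixWeight", "alleleDispersion",
             "outlierWeight", "outlierLogDensity")
  params <- do.call(likelihoodParams, y[intersect(names(y), pkeys)])
  ckeys <- c("lambda", "cMax", "bMax", "nTumour", "tol", "maxIter", "pilotIter",
             "normalFractions", "cloneSplits", "fitTheta", "seed")
  do.call(cloneCNConfig, c(y[intersect(names(y), ckeys)], list(params = params)))
}
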