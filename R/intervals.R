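# Interval sets are GRanges throughout; BED's 0-based half-open coordinates
# are converted to GRanges' 1-based closed convention on read and back on
# write, so files round-trip bit-exactly.

#' Read a BED file into a GRanges
#'
#' Accepts BED3+ records (tab-separated).  Strand is taken from column 6 when
#' present; column 4 becomes `name`, column 5 `score`.  Records on
#' chromosomes absent from `genome` (when given) are dropped with a message.
#'
#' @param path Path to a BED file.
#' @param genome Optional [genome()]; attaches seqinfo and filters records.
#' @return A coordinate-sorted `GRanges`.
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges()
    if (!is.null(genome)) GenomeInfoDb::seqinfo(gr) <- genome_seqinfo(genome)[character(0)]
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L))
    stop("BED parse error at line ", which(ncol < 3L)[1L], ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(!is.finite(start0) | !is.finite(end0) |
                 start0 != floor(start0) | end0 != floor(end0))
  if (length(bad))
    stop("BED parse error at line ", bad[1L], ": non-integer coordinates")
  bad <- which(start0 >= end0 | start0 < 0)
  if (length(bad))
    stop("BED parse error at line ", bad[1L], ": start >= end")
  name <- ifelse(ncol >= 4L, vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, ""), NA_character_)
  score <- ifelse(ncol >= 5L, suppressWarnings(as.numeric(
    vapply(fields, function(f) if (length(f) >= 5) f[[5]] else NA_character_, ""))), NA_real_)
  strand <- ifelse(ncol >= 6L, vapply(fields, function(f) if (length(f) >= 6) f[[6]] else "*", ""), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  if (!is.null(genome)) {
    keep <- chrom %in% genome$chroms
    if (any(!keep))
      message(sum(!keep), " BED record(s) on chromosomes absent from genome dropped")
    chrom <- chrom[keep]; start0 <- start0[keep]; end0 <- end0[keep]
    name <- name[keep]; score <- score[keep]; strand <- strand[keep]
  }
  gr <- GenomicRanges::GRanges(
    seqnames = if (is.null(genome)) chrom else factor(chrom, levels = genome$chroms),
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    strand = strand
  )
  if (!all(is.na(name))) S4Vectors::mcols(gr)$name <- name
  if (!all(is.na(score))) S4Vectors::mcols(gr)$score <- score
  if (!is.null(genome)) GenomeInfoDb::seqinfo(gr) <- genome_seqinfo(genome)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write a GRanges as BED
#'
#' Writes BED3 when neither name/score/strand information is present,
#' otherwise BED6 (missing names become ".", missing scores 0).
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  mc <- S4Vectors::mcols(gr)
  has_meta <- "name" %in% names(mc) || "score" %in% names(mc) ||
    any(as.character(GenomicRanges::strand(gr)) != "*")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = format(GenomicRanges::start(gr) - 1, scientific = FALSE, trim = TRUE),
    end = format(GenomicRanges::end(gr), scientific = FALSE, trim = TRUE),
    stringsAsFactors = FALSE
  )
  if (has_meta) {
    df$name <- if ("name" %in% names(mc)) ifelse(is.na(mc$name), ".", mc$name) else "."
    df$score <- if ("score" %in% names(mc)) ifelse(is.na(mc$score), 0, mc$score) else 0
    strand <- as.character(GenomicRanges::strand(gr))
    df$strand <- ifelse(strand == "*", ".", strand)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge overlapping and bookended intervals
#'
#' Returns the minimal set of disjoint intervals covering the same bases.
#' Touching intervals (zero gap) are merged; strand is ignored, mirroring how
#' replicate peak sets are pooled within a condition before comparison.
#'
#' @param gr A `GRanges`.
#' @return A disjoint, sorted `GRanges`.
#' @export
merge_intervals <- function(gr) {
  GenomicRanges::reduce(gr, ignore.strand = TRUE)
}

#' Count query intervals overlapping a feature set
#'
#' An interval counts if it shares at least one base with at least one
#' feature interval (strand-blind), the bedtools `intersect -u` convention.
#'
#' @param query,feature `GRanges`.
#' @return Integer count in `[0, length(query)]`.
#' @export
count_overlaps <- function(query, feature) {
  sum(GenomicRanges::countOverlaps(query, feature, ignore.strand = TRUE) > 0L)
}

# GRanges constructor from parallel vectors (1-based closed), with optional
# genome-attached seqinfo.
make_granges <- function(chrom, start, end, strand = "*", genome = NULL) {
  if (length(chrom) == 0) strand <- character(0)
  gr <- GenomicRanges::GRanges(
    seqnames = if (is.null(genome)) chrom else factor(chrom, levels = genome$chroms),
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand
  )
  if (!is.null(genome)) GenomeInfoDb::seqinfo(gr) <- genome_seqinfo(genome)
  gr
}
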