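#' Construct a genome description
#'
#' A genome is an ordered set of chromosome names with their lengths in bp.
#' Chromosome rank is the order given here (typically the order of the
#' chromosome-size table), not lexicographic, so sorting is stable across
#' assemblies and toy genomes alike.
#'
#' @param sizes Named numeric vector of chromosome lengths (bp, > 0).
#' @return An object of class `Genome`.
#' @examples
#' genome(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genome <- function(sizes) {
  if (is.null(names(sizes)) || any(names(sizes) == ""))
    stop("chromosome sizes must be named")
  if (anyDuplicated(names(sizes)))
    stop("chromosome names must be unique")
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("chromosome sizes must be positive")
  structure(
    list(chroms = names(sizes), sizes = stats::setNames(as.numeric(sizes), names(sizes))),
    class = "Genome"
  )
}

#' @export
print.Genome <- function(x, ...) {
  cat("Genome with", length(x$chroms), "chromosomes,",
      format(sum(x$sizes), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Read a two-column chromosome-size table
#'
#' @param path Tab-separated file with columns chrom, size.
#' @return A [genome()] object with chromosomes in file order.
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "size")[1:2])
  genome(stats::setNames(as.numeric(dt$size), dt$chrom))
}

#' Write a chromosome-size table
#' @param g A `Genome`.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(g, path) {
  utils::write.table(data.frame(g$chroms, format(g$sizes, scientific = FALSE, trim = TRUE)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Seqinfo carrying the genome's chromosome order and lengths.
genome_seqinfo <- function(g) {
  GenomeInfoDb::Seqinfo(seqnames = g$chroms, seqlengths = as.integer(g$sizes))
}

is_genome <- function(x) inherits(x, "Genome")

# Number of bins per chromosome at a given bin size.
genome_nbins <- function(g, bin_size) {
  stats::setNames(as.integer(ceiling(g$sizes / bin_size)), g$chroms)
}
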