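#' Genome assembly descriptor
#'
#' A lightweight container holding the ordered chromosome names and lengths
#' of the working genome, plus an optional path to its FASTA sequence (only
#' needed for the dinucleotide periodicity QC metric).
#'
#' @param names character vector of unique chromosome names.
#' @param lengths integer vector of chromosome lengths in bp, parallel to
#'   `names`; all lengths must be positive.
#' @param fasta optional path to the genome FASTA file.
#' @return An object of class `genome_assembly` with elements `names`,
#'   `lengths` (named integer vector) and `fasta`.
#' @examples
#' genome_assembly(c("chr1", "chr2"), c(10000L, 8000L))
#' @export
genome_assembly <- function(names, lengths, fasta = NULL) {
  names <- as.character(names)
  lengths <- as.numeric(lengths)
  if (length(names) == 0L) stop("assembly needs at least one chromosome")
  if (anyDuplicated(names)) stop("chromosome names must be unique")
  if (length(lengths) != length(names)) {
    stop("'names' and 'lengths' must have the same length")
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("chromosome lengths must be positive")
  }
  structure(
    list(names = names, lengths = stats::setNames(lengths, names),
         fasta = fasta),
    class = "genome_assembly"
  )
}

#' Read a chrom.sizes table
#'
#' Reads the standard two-column (name, length) tab-separated chromosome
#' size file used throughout genomics tooling.
#'
#' @param path path to a two-column TSV.
#' @param fasta optional FASTA path recorded on the assembly.
#' @return A [genome_assembly()].
#' @export
read_chrom_sizes <- function(path, fasta = NULL) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("name", "length"),
                           colClasses = c("character", "numeric"))
  genome_assembly(tab$name, tab$length, fasta = fasta)
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("<genome_assembly> ", length(x$names), " chromosome(s), ",
      format(sum(x$lengths), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

#' Total genome size of an assembly
#'
#' @param assembly a [genome_assembly()].
#' @return Total length in bp.
#' @export
genome_size <- function(assembly) {
  stopifnot(inherits(assembly, "genome_assembly"))
  sum(assembly$lengths)
}
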