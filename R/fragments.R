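#' Fragment set container
#'
#' Holds MNase-protected fragments as 0-based half-open genomic intervals,
#' together with sample metadata. Fragments are the raw evidence for all
#' downstream occupancy, QC and feature computation.
#'
#' @param fragments data.frame with columns `chrom` (character), `start`,
#'   `end` (numeric, 0-based half-open).
#' @param sample_id sample identifier.
#' @param cell_type cell or tissue type label.
#' @param treatment treatment/condition label.
#' @return An object of class `fragment_set`.
#' @export
fragment_set <- function(fragments, sample_id = "sample",
                         cell_type = "unknown", treatment = "none") {
  stopifnot(is.data.frame(fragments),
            all(c("chrom", "start", "end") %in% names(fragments)))
  fragments <- data.frame(chrom = as.character(fragments$chrom),
                          start = as.numeric(fragments$start),
                          end = as.numeric(fragments$end),
                          stringsAsFactors = FALSE)
  if (nrow(fragments) > 0 && any(fragments$end <= fragments$start)) {
    stop("all fragments must satisfy start < end")
  }
  structure(
    list(sample_id = sample_id, cell_type = cell_type,
         treatment = treatment, fragments = fragments),
    class = "fragment_set"
  )
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("<fragment_set> ", x$sample_id, " (", x$cell_type, "/", x$treatment,
      "): ", nrow(x$fragments), " fragments\n", sep = "")
  invisible(x)
}

#' Number of fragments
#' @param frags a [fragment_set()].
#' @return Integer fragment count.
#' @export
n_fragments <- function(frags) nrow(frags$fragments)

#' Fragment lengths in bp
#' @param frags a [fragment_set()].
#' @return Numeric vector of per-fragment lengths (end - start).
#' @export
fragment_lengths <- function(frags) {
  frags$fragments$end - frags$fragments$start
}

#' Read fragments from a BED or SAM/BAM file
#'
#' Reads MNase-seq fragments and validates them against the assembly.
#' BED records are taken as fragments directly (0-based half-open). For
#' SAM/BAM input, properly paired reads are reduced to one fragment per
#' template: the interval from the leftmost mate start spanning the
#' template length (TLEN).
#'
#' Records on chromosomes absent from the assembly, and records extending
#' beyond the chromosome end, are dropped with a warning giving the counts;
#' dropping (rather than clipping) avoids silently distorting coverage.
#'
#' @param path path to a `.bed` (BED3+) or `.sam`/`.bam` file.
#' @param assembly a [genome_assembly()].
#' @param sample_id,cell_type,treatment sample metadata labels.
#' @return A [fragment_set()].
#' @export
read_fragments <- function(path, assembly, sample_id = NULL,
                           cell_type = "unknown", treatment = "none") {
  stopifnot(inherits(assembly, "genome_assembly"))
  if (!file.exists(path)) stop("fragment file not found: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(bed|sam|bam)$", "", basename(path))
  }
  ext <- tolower(tools::file_ext(path))
  frag <- if (ext %in% c("sam", "bam")) {
    .read_fragments_sam(path)
  } else {
    .read_fragments_bed(path)
  }
  if (nrow(frag) == 0L) stop("no fragments parsed from ", path)

  unknown <- !(frag$chrom %in% assembly$names)
  n_unknown <- sum(unknown)
  frag <- frag[!unknown, , drop = FALSE]
  oob <- frag$start < 0 | frag$end > unname(assembly$lengths[frag$chrom])
  n_oob <- sum(oob)
  frag <- frag[!oob, , drop = FALSE]
  if (n_unknown > 0L) {
    warning(n_unknown, " fragment(s) on chromosomes absent from the ",
            "assembly were dropped", call. = FALSE)
  }
  if (n_oob > 0L) {
    warning(n_oob, " out-of-bounds fragment(s) were dropped", call. = FALSE)
  }
  if (nrow(frag) == 0L) {
    stop("no fragments remain after chromosome/bounds filtering for ", path)
  }
  rownames(frag) <- NULL
  fragment_set(frag, sample_id = sample_id, cell_type = cell_type,
               treatment = treatment)
}

.read_fragments_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("failed to read BED file ", path,
                                          ": ", conditionMessage(e)))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

.read_fragments_sam <- function(path) {
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isProperPair = TRUE),
    what = c("rname", "pos", "isize")
  )
  bam <- tryCatch(Rsamtools::scanBam(Rsamtools::BamFile(.as_bam(path)),
                                     param = param)[[1]],
                  error = function(e) stop("failed to read alignment file ",
                                           path, ": ", conditionMessage(e)))
  # each properly paired template has exactly one alignment with TLEN > 0
  # (the leftmost mate); its POS + TLEN spans the fragment
  keep <- !is.na(bam$pos) & !is.na(bam$isize) & bam$isize > 0
  data.frame(chrom = as.character(bam$rname)[keep],
             start = bam$pos[keep] - 1,
             end = bam$pos[keep] - 1 + bam$isize[keep],
             stringsAsFactors = FALSE)
}

.as_bam <- function(path) {
  if (tolower(tools::file_ext(path)) == "bam") return(path)
  Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                   indexDestination = FALSE)
}

#' Merge several fragment sets into a pooled sample
#'
#' @param frag_list list of [fragment_set()] objects on the same assembly.
#' @param sample_id identifier for the pooled sample.
#' @return A [fragment_set()] holding the union (concatenation) of all
#'   member fragments.
#' @export
pool_fragments <- function(frag_list, sample_id = "pooled") {
  stopifnot(length(frag_list) >= 1,
            all(vapply(frag_list, inherits, logical(1), "fragment_set")))
  frag <- do.call(rbind, lapply(frag_list, function(f) f$fragments))
  cell <- unique(vapply(frag_list, function(f) f$cell_type, character(1)))
  trt <- unique(vapply(frag_list, function(f) f$treatment, character(1)))
  fragment_set(frag, sample_id = sample_id,
               cell_type = paste(cell, collapse = "+"),
               treatment = paste(trt, collapse = "+"))
}
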