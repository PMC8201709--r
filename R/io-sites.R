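#' Read a BED site annotation into a data.frame
#'
#' Reads BED3/BED6 (and narrowPeak-style files: a 10th column is kept as
#' the `summit` offset) into the package's 0-based half-open data.frame
#' convention. Used for TSS, DHS, motif-hit and peak annotations.
#'
#' @param path BED file path.
#' @return data.frame with columns `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`, `summit`.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop("site file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0L) stop("no records in ", path)
  tab <- utils::read.table(text = lines, sep = "\t",
                           stringsAsFactors = FALSE, header = FALSE,
                           fill = TRUE)
  nc <- ncol(tab)
  names(tab)[1:min(nc, 6L)] <-
    c("chrom", "start", "end", "name", "score", "strand")[1:min(nc, 6L)]
  if (nc >= 10L) names(tab)[10L] <- "summit"
  if (!is.numeric(tab$start) || !is.numeric(tab$end)) {
    stop("non-numeric coordinates in ", path)
  }
  bad <- which(is.na(tab$start) | is.na(tab$end) | tab$end <= tab$start)
  if (length(bad) > 0L) {
    stop("malformed BED record at line ", bad[1], " in ", path)
  }
  tab
}
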