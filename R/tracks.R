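#' Signal track container
#'
#' Per-base numeric genome signal, one vector per chromosome. Two roles are
#' used throughout the package: `"occupancy"` (nucleosome footprint counts,
#' optionally normalized to genome-wide mean 1) and `"array"` (local
#' nucleosome spacing regularity in `[0, 1]`).
#'
#' @param data named list of numeric vectors, one per chromosome.
#' @param role `"occupancy"` or `"array"`.
#' @param resolution bp per vector element (1 = per-base).
#' @param normalized logical; whether an occupancy track was scaled to
#'   genome-wide mean 1.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(data, role = c("occupancy", "array"),
                         resolution = 1L, normalized = FALSE) {
  role <- match.arg(role)
  stopifnot(is.list(data), !is.null(names(data)),
            all(vapply(data, is.numeric, logical(1))))
  if (role == "occupancy" &&
      any(vapply(data, function(v) any(v < 0), logical(1)))) {
    stop("occupancy signal must be non-negative")
  }
  structure(
    list(role = role, resolution = as.integer(resolution),
         normalized = isTRUE(normalized), data = data),
    class = "signal_track"
  )
}

#' @export
print.signal_track <- function(x, ...) {
  cat("<signal_track> role=", x$role, ", ", length(x$data),
      " chromosome(s), resolution ", x$resolution, " bp",
      if (x$normalized) ", normalized" else "", "\n", sep = "")
  invisible(x)
}

#' Genome-wide mean of a signal track
#' @param track a [signal_track()].
#' @return Mean signal over all positions of all chromosomes.
#' @export
track_mean <- function(track) {
  stopifnot(inherits(track, "signal_track"))
  tot <- sum(vapply(track$data, sum, numeric(1)))
  len <- sum(vapply(track$data, length, numeric(1)))
  tot / len
}

#' Build a nucleosome occupancy track from fragments
#'
#' Each fragment is reduced to its midpoint `floor((start + end) / 2)` and
#' extended to a fixed nucleosome footprint: the footprint interval is
#' `[mid - floor(footprint/2), mid - floor(footprint/2) + footprint)`,
#' clipped at chromosome ends. Occupancy at a base is the number of
#' footprints covering it. With `normalize = TRUE` the track is divided by
#' its genome-wide mean so that the mean over all positions is exactly 1;
#' this makes depletion ratios and cross-sample correlations comparable
#' across sequencing depths.
#'
#' @param frags a [fragment_set()].
#' @param assembly a [genome_assembly()].
#' @param footprint footprint width in bp (default 147, the canonical
#'   nucleosomal DNA length).
#' @param normalize divide by the genome-wide mean (default TRUE).
#' @return A [signal_track()] with role `"occupancy"` at 1 bp resolution.
#' @export
build_occupancy_track <- function(frags, assembly, footprint = 147L,
                                  normalize = TRUE) {
  stopifnot(inherits(frags, "fragment_set"),
            inherits(assembly, "genome_assembly"))
  if (n_fragments(frags) == 0L) stop("fragment set is empty")
  footprint <- as.integer(footprint)
  if (footprint <= 0L) stop("footprint must be positive")
  half <- footprint %/% 2L
  fr <- frags$fragments
  data <- lapply(assembly$names, function(chrom) {
    len <- unname(assembly$lengths[[chrom]])
    sel <- fr$chrom == chrom
    if (!any(sel)) return(numeric(len))
    mid <- (fr$start[sel] + fr$end[sel]) %/% 2
    # 0-based half-open [mid - half, mid - half + footprint), clipped
    s0 <- pmax(mid - half, 0)
    e0 <- pmin(mid - half + footprint, len)
    ok <- e0 > s0
    if (!any(ok)) return(numeric(len))
    cov <- IRanges::coverage(IRanges::IRanges(start = s0[ok] + 1L,
                                              end = e0[ok]),
                             width = len)
    as.numeric(cov)
  })
  names(data) <- assembly$names
  track <- signal_track(data, role = "occupancy", resolution = 1L,
                        normalized = FALSE)
  if (normalize) {
    m <- track_mean(track)
    if (m > 0) {
      track$data <- lapply(track$data, function(v) v / m)
      track$normalized <- TRUE
    }
  }
  track
}

#' Build a nucleosome array-regularity track
#'
#' Scores how regularly spaced (phased) nucleosomes are around each
#' position. For a sliding window (default 2 kb) centered on every `step`
#' bp bin, the occupancy signal is mean-subtracted and its normalized
#' autocorrelation is evaluated over lags in the nucleosome repeat-length
#' range (default 150-220 bp); the window score is the maximum
#' autocorrelation over those lags, clipped to `[0, 1]`. Windows with zero
#' variance (flat occupancy) score 0. The score is assigned to every base
#' of the window's central step bin.
#'
#' @param occ occupancy [signal_track()] at 1 bp resolution.
#' @param window window width in bp.
#' @param step bin width in bp at which windows are centered.
#' @param lag_range two-element numeric, lag interval in bp over which the
#'   autocorrelation is maximized.
#' @return A [signal_track()] with role `"array"` at 1 bp resolution.
#' @export
build_array_track <- function(occ, window = 2000L, step = 100L,
                              lag_range = c(150L, 220L)) {
  stopifnot(inherits(occ, "signal_track"))
  if (occ$role != "occupancy") stop("array track must be built from an occupancy track")
  if (occ$resolution != 1L) stop("array track requires 1 bp resolution occupancy")
  window <- as.integer(window); step <- as.integer(step)
  lags <- as.integer(lag_range[1]):as.integer(lag_range[2])
  if (window < 2L * max(lags)) {
    stop("window must be at least twice the maximum lag (",
         2L * max(lags), " bp)")
  }
  data <- lapply(occ$data, function(v) {
    .array_signal_chrom(v, window, step, lags)
  })
  names(data) <- names(occ$data)
  signal_track(data, role = "array", resolution = 1L, normalized = FALSE)
}

# Windowed autocorrelation peak, vectorized across windows with cumulative
# sums. For window [s, e) of length N with mean m, lag l:
#   num(l) = sum_{i=s}^{e-1-l} (v_i - m)(v_{i+l} - m)
#          = A_l - m (B_l + C_l) + (N - l) m^2
#   den    = sum_{i=s}^{e-1} (v_i - m)^2 = S2 - N m^2
# with A_l, B_l, C_l, S2 all window partial sums of v, v^2 and v_i*v_{i+l}.
.array_signal_chrom <- function(v, window, step, lags) {
  n <- length(v)
  out <- numeric(n)
  if (n < window) return(out)
  nbin <- n %/% step
  if (nbin == 0L) return(out)
  centers <- (seq_len(nbin) - 1L) * step + step %/% 2L   # 0-based centers
  ws <- centers - window %/% 2L
  we <- ws + window
  valid <- ws >= 0L & we <= n
  if (!any(valid)) return(out)
  s <- ws[valid]; e <- we[valid]                          # 0-based half-open
  N <- window
  cs1 <- c(0, cumsum(v))
  cs2 <- c(0, cumsum(v * v))
  m <- (cs1[e + 1L] - cs1[s + 1L]) / N
  den <- (cs2[e + 1L] - cs2[s + 1L]) - N * m * m
  best <- rep(-Inf, length(s))
  for (l in lags) {
    p <- v[seq_len(n - l)] * v[(l + 1L):n]
    csp <- c(0, cumsum(p))
    A <- csp[pmin(e - l, n - l) + 1L] - csp[s + 1L]
    B <- cs1[e - l + 1L] - cs1[s + 1L]
    C <- cs1[e + 1L] - cs1[s + l + 1L]
    num <- A - m * (B + C) + (N - l) * m * m
    best <- pmax(best, num)
  }
  score <- ifelse(den > 0, best / den, 0)
  score <- pmin(pmax(score, 0), 1)
  bins <- which(valid)
  for (k in seq_along(bins)) {
    b0 <- (bins[k] - 1L) * step
    out[(b0 + 1L):min(b0 + step, n)] <- score[k]
  }
  out
}

#' Sequencing coverage summary
#'
#' Fold coverage is the total number of sequenced fragment bases divided by
#' the genome size. Samples below five-fold coverage are conventionally
#' excluded from reference landscape selection (see
#' [select_reference()]).
#'
#' @param frags a [fragment_set()].
#' @param assembly a [genome_assembly()].
#' @return A list of class `coverage_summary` with `total_bases`,
#'   `genome_size` and `fold`.
#' @export
compute_coverage <- function(frags, assembly) {
  stopifnot(inherits(frags, "fragment_set"),
            inherits(assembly, "genome_assembly"))
  if (n_fragments(frags) == 0L) stop("fragment set is empty")
  total <- sum(fragment_lengths(frags))
  gs <- genome_size(assembly)
  structure(list(total_bases = total, genome_size = gs, fold = total / gs),
            class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("<coverage_summary> %.0f bases / %.0f bp genome = %.2f-fold\n",
              x$total_bases, x$genome_size, x$fold))
  invisible(x)
}

#' Write a signal track to bedGraph or bigWig
#'
#' bedGraph output is run-length encoded: consecutive equal values are
#' merged into one interval and zero-valued runs are omitted (bedGraph
#' semantics treat uncovered positions as 0).
#'
#' @param track a [signal_track()] at 1 bp resolution.
#' @param path output path; format chosen by extension (`.bedgraph`/`.bdg`
#'   or `.bw`/`.bigwig`).
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("bw", "bigwig")) {
    rtracklayer::export.bw(.track_as_granges(track), path)
    return(invisible(path))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(track$data)) {
    r <- rle(track$data[[chrom]])
    ends <- cumsum(r$lengths) * track$resolution
    starts <- ends - r$lengths * track$resolution
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%.10g", chrom,
                       as.integer(starts[keep]), as.integer(ends[keep]),
                       r$values[keep]), con)
  }
  invisible(path)
}

.track_as_granges <- function(track) {
  grl <- lapply(names(track$data), function(chrom) {
    r <- rle(track$data[[chrom]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                           score = r$values)
  })
  gr <- suppressWarnings(do.call(c, grl))
  lens <- vapply(track$data, length, numeric(1))
  GenomeInfoDb::seqlengths(gr) <- lens[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Read a signal track from bedGraph or bigWig
#'
#' @param path path to a bedGraph (or bigWig) track.
#' @param assembly a [genome_assembly()] giving chromosome lengths.
#' @param role role tag for the returned track.
#' @return A [signal_track()] at 1 bp resolution. Positions not covered by
#'   any interval are 0. Overlapping bedGraph intervals are a fatal error
#'   reported with the offending line number.
#' @export
read_track <- function(path, assembly,
                       role = c("occupancy", "array")) {
  role <- match.arg(role)
  stopifnot(inherits(assembly, "genome_assembly"))
  if (!file.exists(path)) stop("track file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  data <- stats::setNames(
    lapply(assembly$lengths, function(len) numeric(len)),
    assembly$names)
  if (ext %in% c("bw", "bigwig")) {
    gr <- rtracklayer::import.bw(path)
    for (chrom in intersect(unique(as.character(
      GenomicRanges::seqnames(gr))), assembly$names)) {
      sel <- as.character(GenomicRanges::seqnames(gr)) == chrom
      s <- GenomicRanges::start(gr)[sel]; e <- GenomicRanges::end(gr)[sel]
      sc <- gr$score[sel]
      for (i in seq_along(s)) data[[chrom]][s[i]:e[i]] <- sc[i]
    }
    return(signal_track(data, role = role, resolution = 1L,
                        normalized = role == "occupancy"))
  }
  lines <- readLines(path)
  body <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(body)
  if (length(idx) == 0L) stop("no data lines in track file ", path)
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4L)) {
    stop("malformed bedGraph line ", idx[which(nf < 4L)[1]], " in ", path)
  }
  chrom <- vapply(parts, `[[`, character(1), 1L)
  s <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  e <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
  val <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 4L)))
  bad <- is.na(s) | is.na(e) | is.na(val) | s < 0 | e <= s
  if (any(bad)) stop("malformed bedGraph line ", idx[which(bad)[1]],
                     " in ", path)
  for (ch in unique(chrom)) {
    if (!ch %in% assembly$names) {
      stop("bedGraph line ", idx[which(chrom == ch)[1]],
           ": unknown chromosome ", ch)
    }
    sel <- which(chrom == ch)
    ord <- sel[order(s[sel])]
    if (any(e[ord] > length(data[[ch]]))) {
      stop("bedGraph line ", idx[ord[which(e[ord] > length(data[[ch]]))[1]]],
           ": interval exceeds chromosome length")
    }
    if (length(ord) > 1L && any(s[ord][-1] < e[ord][-length(ord)])) {
      k <- which(s[ord][-1] < e[ord][-length(ord)])[1]
      stop("overlapping bedGraph intervals at line ", idx[ord[k + 1L]],
           " in ", path)
    }
    for (i in ord) data[[ch]][(s[i] + 1L):e[i]] <- val[i]
  }
  signal_track(data, role = role, resolution = 1L,
               normalized = role == "occupancy")
}
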