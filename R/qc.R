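#' Modal fragment length
#'
#' The mode of the 1 bp fragment-length histogram. High-quality
#' mononucleosomal MNase-seq libraries peak near the 146 bp of DNA in
#' tight contact with the histone octamer, so samples are ranked by
#' `|mode - 146|` (smaller is better).
#'
#' @param frags a [fragment_set()].
#' @return Modal fragment length in bp. With fewer than 100 fragments the
#'   value is still computed but carries attribute `low_confidence = TRUE`.
#' @export
qc_fragment_length <- function(frags) {
  lens <- fragment_lengths(frags)
  if (length(lens) == 0L) stop("fragment set is empty")
  tab <- table(lens)
  mode_len <- as.numeric(names(tab)[which.max(tab)])
  if (length(lens) < 100L) attr(mode_len, "low_confidence") <- TRUE
  mode_len
}

#' AA/TT/AT dinucleotide periodicity
#'
#' Nucleosomal DNA shows an ~10 bp rotational periodicity of AA/TT/AT
#' dinucleotides. The positional frequency of {AA, TT, AT} is profiled
#' over 147 bp windows centered on fragment midpoints; the score is the
#' spectral power of the mean-subtracted profile in the 9-11 bp period
#' band divided by the total power, a value in `[0, 1]`. A flat profile
#' scores 0.
#'
#' @param frags a [fragment_set()].
#' @param assembly a [genome_assembly()] whose `fasta` is set (or pass
#'   `fasta`).
#' @param fasta optional path to the genome FASTA (overrides the
#'   assembly's).
#' @param max_fragments cap on the number of fragments profiled (the first
#'   `max_fragments` are used; the profile converges quickly).
#' @return Periodicity score in `[0, 1]`, or `NA` when no FASTA is
#'   available.
#' @export
qc_dinucleotide_periodicity <- function(frags, assembly, fasta = NULL,
                                        max_fragments = 50000L) {
  if (is.null(fasta)) fasta <- assembly$fasta
  if (is.null(fasta) || !file.exists(fasta)) return(NA_real_)
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  fr <- frags$fragments
  if (nrow(fr) > max_fragments) fr <- fr[seq_len(max_fragments), ]
  mid <- (fr$start + fr$end) %/% 2
  s0 <- mid - 73L                       # 147 bp window [mid-73, mid+73]
  e0 <- mid + 73L
  keep <- fr$chrom %in% names(genome)
  glen <- stats::setNames(Biostrings::width(genome), names(genome))
  keep[keep] <- s0[keep] >= 0 & e0[keep] < unname(glen[fr$chrom[keep]])
  if (sum(keep) < 1L) return(NA_real_)
  views <- Biostrings::DNAStringSet(mapply(
    function(ch, a, b) Biostrings::subseq(genome[[ch]], a, b),
    fr$chrom[keep], s0[keep] + 1L, e0[keep] + 1L, SIMPLIFY = FALSE))
  mat <- as.matrix(views)
  is_a <- mat == "A"; is_t <- mat == "T"
  np <- ncol(mat) - 1L
  prof <- vapply(seq_len(np), function(j) {
    mean((is_a[, j] & is_a[, j + 1L]) |
         (is_t[, j] & is_t[, j + 1L]) |
         (is_a[, j] & is_t[, j + 1L]))
  }, numeric(1))
  periodicity_score(prof)
}

#' Spectral periodicity score of a positional profile
#'
#' Fraction of the (DC-removed) spectral power of a profile that falls in
#' the 9-11 bp period band.
#'
#' @param prof numeric positional frequency profile.
#' @param period_range two-element numeric, period band in bp.
#' @return Score in `[0, 1]`; 0 for a zero-variance profile.
#' @export
periodicity_score <- function(prof, period_range = c(9, 11)) {
  n <- length(prof)
  if (n < 4L || stats::var(prof) == 0) return(0)
  x <- prof - mean(prof)
  p <- Mod(stats::fft(x))^2
  k <- seq_len(n %/% 2L)                # positive frequencies
  periods <- n / k
  band <- periods >= period_range[1] & periods <= period_range[2]
  if (!any(band)) return(0)
  sum(p[k[band] + 1L]) / sum(p[k + 1L])
}

#' Mean nucleosome depletion at TSSs
#'
#' Mean of the per-site [depletion_level()] over a TSS set; higher values
#' indicate the expected promoter nucleosome-free regions. Ranked
#' descending across samples.
#'
#' @param occ occupancy [signal_track()].
#' @param tss TSS data.frame (`chrom`, `start`, `end`, optional `strand`).
#' @return Mean depletion level over usable TSSs.
#' @export
qc_tss_depletion <- function(occ, tss) {
  strand <- if ("strand" %in% names(tss)) as.character(tss$strand)
            else rep("+", nrow(tss))
  pos <- ifelse(strand == "-", tss$end - 1, tss$start)
  vals <- vapply(seq_len(nrow(tss)), function(i) {
    depletion_level(occ, as.character(tss$chrom[i]), pos[i])
  }, numeric(1))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("no usable TSS for depletion QC")
  mean(vals)
}

#' Aggregate strand-aware TSS occupancy profile
#'
#' Averages the occupancy over `[TSS, TSS + span)` across all TSSs whose
#' window lies fully on the chromosome, reversing minus-strand profiles
#' before averaging.
#'
#' @param occ occupancy [signal_track()].
#' @param tss TSS data.frame.
#' @param span profile width in bp.
#' @return Numeric vector of length `span` (offset 0 .. span-1), or
#'   `NULL` if no TSS window is usable.
#' @export
aggregate_tss_profile <- function(occ, tss, span = 1500L) {
  strand <- if ("strand" %in% names(tss)) as.character(tss$strand)
            else rep("+", nrow(tss))
  pos <- ifelse(strand == "-", tss$end - 1, tss$start)
  acc <- numeric(span)
  n_used <- 0L
  for (i in seq_len(nrow(tss))) {
    v <- occ$data[[as.character(tss$chrom[i])]]
    if (is.null(v)) next
    p <- pos[i]
    if (strand[i] == "-") {
      if (p - span + 1 < 0 || p + 1 > length(v)) next
      prof <- rev(v[(p - span + 1 + 1):(p + 1)])
    } else {
      if (p < 0 || p + span > length(v)) next
      prof <- v[(p + 1):(p + span)]
    }
    acc <- acc + prof
    n_used <- n_used + 1L
  }
  if (n_used == 0L) return(NULL)
  acc / n_used
}

#' Nucleosome fuzziness downstream of TSSs
#'
#' The coefficient of variation (population SD / mean) of the distances
#' between the +1, +2, +3 and +4 nucleosomes called on the aggregate
#' strand-aware TSS occupancy profile. Low values indicate well-phased
#' downstream arrays; samples with fuzziness below 0.4 are labelled
#' 'Pass'. Ranked ascending.
#'
#' @param occ occupancy [signal_track()].
#' @param tss TSS data.frame.
#' @param span aggregate profile width in bp (default 1500, enough for
#'   four nucleosomes at typical repeat lengths).
#' @param smooth_window,merge_dist passed to the position caller.
#' @return CV of the three +1..+4 spacings, or `NA` when fewer than four
#'   aggregate peaks are detected.
#' @export
qc_tss_fuzziness <- function(occ, tss, span = 1500L, smooth_window = 50L,
                             merge_dist = 100L) {
  prof <- aggregate_tss_profile(occ, tss, span = span)
  if (is.null(prof)) return(NA_real_)
  calls <- .call_positions_profile(prof, smooth_window, merge_dist)
  if (length(calls$offsets) < 4L) return(NA_real_)
  spac <- diff(calls$offsets[1:4])
  if (mean(spac) == 0) return(NA_real_)
  sqrt(mean((spac - mean(spac))^2)) / mean(spac)
}

#' Nucleosome array enrichment at DHSs
#'
#' Mean array-regularity signal over DHS +/- 1 kb windows divided by the
#' genome-wide mean array signal. Values above 1 indicate that
#' well-positioned nucleosome arrays are enriched around accessible
#' regions, as expected for informative samples. Ranked descending.
#'
#' @param arr array [signal_track()].
#' @param dhs DHS data.frame (`chrom`, `start`, `end`).
#' @param flank half-window in bp around the DHS anchor (default 1000).
#' @return Enrichment ratio (>= 0).
#' @export
qc_dhs_array_enrichment <- function(arr, dhs, flank = 1000L) {
  gmean <- track_mean(arr)
  if (gmean <= 0) stop("degenerate array track: genome-wide mean is zero")
  anchor <- if ("summit" %in% names(dhs)) dhs$start + dhs$summit
            else (dhs$start + dhs$end) %/% 2
  tot <- 0; nbp <- 0
  for (i in seq_len(nrow(dhs))) {
    v <- arr$data[[as.character(dhs$chrom[i])]]
    if (is.null(v)) next
    lo <- max(anchor[i] - flank, 0); hi <- min(anchor[i] + flank, length(v))
    if (hi <= lo) next
    tot <- tot + sum(v[(lo + 1):hi])
    nbp <- nbp + (hi - lo)
  }
  if (nbp == 0) stop("no usable DHS window")
  (tot / nbp) / gmean
}

#' Default Pass/Fail thresholds for the QC panel
#'
#' The fuzziness rule (Pass iff CV < 0.4) is fixed. The other four
#' thresholds are package defaults chosen from the expected behaviour of
#' informative mononucleosomal libraries, and are overridable:
#' depletion >= 0.2, DHS array enrichment >= 1.2, modal fragment length
#' within 146 +/- 20 bp, and dinucleotide periodicity at least twice the
#' white-noise expectation for the 9-11 bp band (3 of 73 spectral bins).
#'
#' @return Named list of threshold values.
#' @export
qc_default_thresholds <- function() {
  list(
    tss_depletion_min = 0.2,
    dhs_array_enrichment_min = 1.2,
    fragment_length_target = 146,
    fragment_length_tol = 20,
    dinucleotide_periodicity_min = 2 * 3 / 73,
    tss_fuzziness_max = 0.4          # fixed rule: Pass iff CV < 0.4
  )
}

#' Compute the six-metric QC panel for one sample
#'
#' @param frags a [fragment_set()].
#' @param assembly a [genome_assembly()].
#' @param tss,dhs annotation data.frames.
#' @param occ,arr optional precomputed tracks (built from `frags` if
#'   omitted).
#' @param fasta optional genome FASTA for the dinucleotide metric (NA
#'   metric when unavailable).
#' @return An object of class `sample_qc`: sample metadata, the six
#'   metric values, Pass/Fail labels for the five labelled metrics
#'   (coverage has no label) and a slot for rank quantiles (filled by
#'   [rank_quantiles()]).
#' @export
compute_sample_qc <- function(frags, assembly, tss, dhs, occ = NULL,
                              arr = NULL, fasta = NULL) {
  if (is.null(occ)) occ <- build_occupancy_track(frags, assembly)
  if (is.null(arr)) arr <- build_array_track(occ)
  values <- c(
    coverage_fold = compute_coverage(frags, assembly)$fold,
    dinucleotide_periodicity =
      as.numeric(qc_dinucleotide_periodicity(frags, assembly, fasta)),
    fragment_length = as.numeric(qc_fragment_length(frags)),
    tss_depletion = qc_tss_depletion(occ, tss),
    tss_fuzziness = qc_tss_fuzziness(occ, tss),
    dhs_array_enrichment = qc_dhs_array_enrichment(arr, dhs)
  )
  qc <- structure(
    list(sample_id = frags$sample_id, cell_type = frags$cell_type,
         treatment = frags$treatment, values = values,
         labels = NULL, quantiles = NULL),
    class = "sample_qc")
  assign_labels(qc)
}

#' Metric names of the QC panel
#' @return Character vector of the six metric names, coverage first.
#' @export
qc_metrics <- function() {
  c("coverage_fold", "dinucleotide_periodicity", "fragment_length",
    "tss_depletion", "tss_fuzziness", "dhs_array_enrichment")
}

#' Assign Pass/Fail labels to a QC panel
#'
#' Every metric except sequencing coverage receives a label. The
#' fuzziness rule is fixed: Pass iff CV < 0.4 (strict). The other four
#' labels use the (overridable) defaults of [qc_default_thresholds()].
#' NA metric values are labelled Fail.
#'
#' @param qc a `sample_qc` object.
#' @param thresholds named list as from [qc_default_thresholds()].
#' @return The `sample_qc` with its five labels set.
#' @export
assign_labels <- function(qc, thresholds = qc_default_thresholds()) {
  stopifnot(inherits(qc, "sample_qc"))
  v <- qc$values
  pf <- function(ok) {
    if (is.na(ok)) "Fail" else if (ok) "Pass" else "Fail"
  }
  labels <- c(
    dinucleotide_periodicity =
      pf(v[["dinucleotide_periodicity"]] >=
           thresholds$dinucleotide_periodicity_min),
    fragment_length =
      pf(abs(v[["fragment_length"]] - thresholds$fragment_length_target) <=
           thresholds$fragment_length_tol),
    tss_depletion = pf(v[["tss_depletion"]] >= thresholds$tss_depletion_min),
    tss_fuzziness = pf(v[["tss_fuzziness"]] < thresholds$tss_fuzziness_max),
    dhs_array_enrichment =
      pf(v[["dhs_array_enrichment"]] >=
           thresholds$dhs_array_enrichment_min)
  )
  qc$labels <- labels
  qc
}

#' @export
print.sample_qc <- function(x, ...) {
  cat("<sample_qc> ", x$sample_id, " (", x$cell_type, "/", x$treatment,
      ")\n", sep = "")
  for (m in qc_metrics()) {
    lab <- if (!is.null(x$labels) && m %in% names(x$labels))
      paste0(" [", x$labels[[m]], "]") else ""
    q <- if (!is.null(x$quantiles) && m %in% names(x$quantiles))
      sprintf(" q=%.2f", x$quantiles[[m]]) else ""
    cat(sprintf("  %-26s %8.4f%s%s\n", m, x$values[[m]], lab, q))
  }
  invisible(x)
}

#' Per-metric rank quantiles across a sample collection
#'
#' Ranks every sample on each of the six metrics using the metric's
#' quality direction -- fragment length by deviation from 146 bp
#' (ascending), fuzziness ascending, the other four descending -- with
#' average ranks for ties, and converts ranks to quantiles
#' `1 - (rank - 1) / (n - 1)` (best = 1). A single sample gets quantile 1
#' on every metric. NA metric values rank behind all non-NA values and
#' receive quantile 0.
#'
#' @param collection list of `sample_qc` objects.
#' @return The list with each element's `quantiles` filled (all six
#'   metrics, coverage included).
#' @export
rank_quantiles <- function(collection) {
  stopifnot(length(collection) >= 1L,
            all(vapply(collection, inherits, logical(1), "sample_qc")))
  n <- length(collection)
  vals <- sapply(collection, function(q) q$values)   # metrics x samples
  keys <- vals
  keys["fragment_length", ] <- abs(vals["fragment_length", ] - 146)
  # directions: key ascending = better for fragment-length deviation and
  # fuzziness; the other four are better when larger
  asc <- c(coverage_fold = FALSE, dinucleotide_periodicity = FALSE,
           fragment_length = TRUE, tss_depletion = FALSE,
           tss_fuzziness = TRUE, dhs_array_enrichment = FALSE)
  qmat <- matrix(NA_real_, nrow = length(qc_metrics()), ncol = n,
                 dimnames = list(qc_metrics(), NULL))
  for (m in qc_metrics()) {
    key <- keys[m, ]
    if (!asc[[m]]) key <- -key
    if (n == 1L) {
      qmat[m, ] <- if (is.na(key)) 0 else 1
      next
    }
    r <- rank(key, ties.method = "average", na.last = "keep")
    q <- 1 - (r - 1) / (n - 1)
    q[is.na(q)] <- 0
    qmat[m, ] <- q
  }
  for (i in seq_len(n)) {
    collection[[i]]$quantiles <- stats::setNames(qmat[, i], qc_metrics())
  }
  collection
}

#' QC collection as a data.frame
#'
#' One row per sample: metadata, metric values, labels and quantiles.
#'
#' @param collection list of `sample_qc` objects.
#' @return data.frame suitable for TSV export.
#' @export
qc_table <- function(collection) {
  rows <- lapply(collection, function(q) {
    row <- data.frame(sample_id = q$sample_id, cell_type = q$cell_type,
                      treatment = q$treatment, stringsAsFactors = FALSE)
    for (m in qc_metrics()) row[[m]] <- q$values[[m]]
    for (m in names(q$labels)) row[[paste0("label_", m)]] <- q$labels[[m]]
    if (!is.null(q$quantiles)) {
      for (m in qc_metrics()) row[[paste0("q_", m)]] <- q$quantiles[[m]]
    }
    row
  })
  do.call(rbind, rows)
}
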