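#' Nucleosome depletion level at a site
#'
#' Quantifies how depleted of nucleosomes a site is relative to its
#' immediate flanks. `N_center` is the maximum occupancy in the central
#' 200 bp bin (`[site - 100, site + 100)`); `N_background` is the maximum
#' occupancy over the two flanking 200 bp bins
#' (`[site - 300, site - 100)` and `[site + 100, site + 300)`). If
#' `N_center > N_background` the depletion level is 0; otherwise it is
#' `1 - N_center / N_background`. A zero background also yields 0.
#'
#' @param occ occupancy [signal_track()] at 1 bp resolution.
#' @param chrom chromosome name.
#' @param pos 0-based site position.
#' @return Depletion level in `[0, 1)`, or `NA` if the `site +/- 300` bp
#'   window falls off the chromosome.
#' @export
depletion_level <- function(occ, chrom, pos) {
  v <- occ$data[[chrom]]
  if (is.null(v)) return(NA_real_)
  if (pos - 300 < 0 || pos + 300 > length(v)) return(NA_real_)
  center <- max(v[(pos - 100 + 1):(pos + 100)])
  bg <- max(v[(pos - 300 + 1):(pos - 100)], v[(pos + 100 + 1):(pos + 300)])
  if (center > bg || bg == 0) return(0)
  1 - center / bg
}

#' Mean nucleosome occupancy at a site
#'
#' Average occupancy over the central 100 bp bin
#' (`[site - 50, site + 50)`).
#'
#' @inheritParams depletion_level
#' @return Mean occupancy, or `NA` if the window is off-chromosome.
#' @export
occupancy_at_site <- function(occ, chrom, pos) {
  v <- occ$data[[chrom]]
  if (is.null(v)) return(NA_real_)
  if (pos - 50 < 0 || pos + 50 > length(v)) return(NA_real_)
  mean(v[(pos - 50 + 1):(pos + 50)])
}

#' Nucleosome array score at a site
#'
#' Mean array-regularity signal over the 1 kb window on the requested side
#' of the site, divided by the genome-wide mean array signal. Windows are
#' strand-aware: downstream of a minus-strand site is `[site - span, site)`.
#'
#' @inheritParams depletion_level
#' @param arr array [signal_track()].
#' @param side `"down"` or `"up"` relative to the site on its strand.
#' @param span window width in bp (default 1000).
#' @param strand `"+"` or `"-"`.
#' @param genome_mean optional precomputed genome-wide mean of `arr`
#'   (avoids recomputation in loops).
#' @return Array score ratio (>= 0), or `NA` if off-chromosome.
#' @export
array_score <- function(arr, chrom, pos, side = c("down", "up"),
                        span = 1000L, strand = "+", genome_mean = NULL) {
  side <- match.arg(side)
  v <- arr$data[[chrom]]
  if (is.null(v)) return(NA_real_)
  if (is.null(genome_mean)) genome_mean <- track_mean(arr)
  if (genome_mean <= 0) stop("genome-wide mean array signal is zero")
  downstream <- (side == "down") == (strand != "-")
  if (downstream) {
    lo <- pos; hi <- pos + span          # [pos, pos + span)
  } else {
    lo <- pos - span; hi <- pos          # [pos - span, pos)
  }
  if (lo < 0 || hi > length(v)) return(NA_real_)
  mean(v[(lo + 1):hi]) / genome_mean
}

# Centered moving average with edge windows truncated (partial windows are
# normalized by the number of in-range positions), so no NA padding.
.smooth_profile <- function(x, window) {
  if (window <= 1L) return(x)
  half <- window %/% 2L
  n <- length(x)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Strict local maxima of a numeric profile after run-length collapsing;
# plateaus contribute their leftmost index. Boundary runs are never maxima.
.local_maxima <- function(x) {
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-k]))
  idx <- 2L:(k - 1L)
  is_max <- r$values[idx] > r$values[idx - 1L] &
    r$values[idx] > r$values[idx + 1L]
  starts[idx][is_max]
}

# Iteratively resolve peaks closer than merge_dist: remove the globally
# lowest peak participating in any violating adjacent pair; on equal
# heights drop the peak farther from the anchor (larger offset).
.merge_close_peaks <- function(offsets, heights, merge_dist) {
  while (length(offsets) > 1L) {
    gaps <- diff(offsets)
    viol <- which(gaps < merge_dist)
    if (length(viol) == 0L) break
    cand <- sort(unique(c(viol, viol + 1L)))
    h <- heights[cand]
    worst <- cand[h == min(h)]
    drop <- worst[which.max(offsets[worst])]
    offsets <- offsets[-drop]
    heights <- heights[-drop]
  }
  list(offsets = offsets, heights = heights)
}

#' Call nucleosome positions near an anchor
#'
#' Scans the occupancy profile from the anchor over `span` bp in the given
#' direction, smooths it with a centered moving average, detects strict
#' local maxima (plateaus resolved to their leftmost base), and resolves
#' maxima closer than `merge_dist` bp by keeping the one with the higher
#' occupancy. Offsets are strictly positive: a maximum at the anchor
#' itself is excluded.
#'
#' @param occ occupancy [signal_track()].
#' @param chrom chromosome name.
#' @param pos 0-based anchor position.
#' @param direction `+1` to scan downstream (increasing coordinates) or
#'   `-1` upstream. For a minus-strand TSS pass `-1`.
#' @param span scan width in bp (default 1000).
#' @param smooth_window moving-average window in bp (default 50).
#' @param merge_dist minimum distance between retained positions (default
#'   100 bp; two equal maxima exactly 100 bp apart are both retained).
#' @return A list of class `nucleosome_positions` with `offsets` (ordered
#'   unsigned bp offsets from the anchor, in `(0, span]`) and `heights`
#'   (smoothed occupancy at each retained position).
#' @export
call_positions <- function(occ, chrom, pos, direction = 1L, span = 1000L,
                           smooth_window = 50L, merge_dist = 100L) {
  v <- occ$data[[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  prof <- .anchored_profile(v, pos, direction, span, smooth_window)
  .call_positions_profile(prof, smooth_window, merge_dist,
                          presmoothed = TRUE)
}

# Extract the profile at offsets 1..span from the anchor (direction -1
# reads decreasing coordinates), with smoothing context taken from the
# genome so peaks near the window edge are not biased. Out-of-chromosome
# offsets are truncated.
.anchored_profile <- function(v, pos, direction, span, smooth_window) {
  margin <- smooth_window %/% 2L + 1L
  n <- length(v)
  if (direction >= 0) {
    # 1-based indices of offsets 1..span downstream of 0-based pos
    lo <- pos + 2L; hi <- min(pos + 1L + span, n)
  } else {
    # offsets 1..span upstream: 0-based pos-1 .. pos-span
    lo <- max(pos - span + 1L, 1L); hi <- pos
  }
  if (hi < lo || hi < 1L || lo > n) return(numeric(0))
  elo <- max(lo - margin, 1L); ehi <- min(hi + margin, n)
  seg <- .smooth_profile(v[elo:ehi], smooth_window)
  out <- seg[(lo - elo + 1L):(hi - elo + 1L)]
  if (direction >= 0) out else rev(out)
}

# Core detector on an already-extracted (and optionally pre-smoothed)
# anchored profile whose index i corresponds to offset i bp.
.call_positions_profile <- function(prof, smooth_window = 50L,
                                    merge_dist = 100L,
                                    presmoothed = FALSE) {
  if (length(prof) == 0L) {
    return(structure(list(offsets = integer(0), heights = numeric(0)),
                     class = "nucleosome_positions"))
  }
  sm <- if (presmoothed) prof else .smooth_profile(prof, smooth_window)
  # quantize so cumulative-sum rounding noise on flat stretches cannot
  # masquerade as strict local maxima
  sm <- round(sm, 9L)
  peaks <- .local_maxima(sm)
  merged <- .merge_close_peaks(peaks, sm[peaks], merge_dist)
  structure(list(offsets = as.integer(merged$offsets),
                 heights = as.numeric(merged$heights)),
            class = "nucleosome_positions")
}

#' @export
print.nucleosome_positions <- function(x, ...) {
  cat("<nucleosome_positions> ", length(x$offsets), " position(s): ",
      paste(x$offsets, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Linker statistics from called nucleosome positions
#'
#' The first called position is the +1 nucleosome (or -1 for an upstream
#' scan). Linker length is the mean distance between adjacent positions
#' minus 147 bp of nucleosomal DNA; its standard deviation is the
#' population SD of the adjacent spacings. Undefined quantities use the -1
#' sentinel: fewer than 2 nucleosomes leaves linker length and SD at -1,
#' fewer than 3 leaves the SD at -1, and an undetectable first nucleosome
#' sets all three to -1.
#'
#' @param positions a `nucleosome_positions` object from
#'   [call_positions()].
#' @return A list with `first_position`, `linker_length`, `linker_sd` and
#'   `count`.
#' @export
linker_stats <- function(positions) {
  offs <- positions$offsets
  count <- length(offs)
  if (count == 0L) {
    return(list(first_position = -1, linker_length = -1, linker_sd = -1,
                count = 0L))
  }
  first <- offs[1]
  if (count < 2L) {
    return(list(first_position = first, linker_length = -1, linker_sd = -1,
                count = count))
  }
  spac <- diff(offs)
  linker <- mean(spac) - 147
  sd_l <- if (count < 3L) -1 else sqrt(mean((spac - mean(spac))^2))
  list(first_position = first, linker_length = linker, linker_sd = sd_l,
       count = count)
}

#' Per-TSS nucleosome organization feature table
#'
#' For each TSS (strand-aware), computes the downstream 1 kb array score,
#' the depletion level and mean occupancy at the TSS, and the +1
#' nucleosome position, linker length, linker-length SD and nucleosome
#' count from the downstream 1 kb position calls. Sentinel value -1 marks
#' undefined position/linker quantities; NA marks sites whose windows fall
#' off the chromosome.
#'
#' @param occ occupancy [signal_track()].
#' @param arr array [signal_track()].
#' @param tss data.frame of TSS records with columns `chrom`, `start`,
#'   `end` (0-based half-open), optional `name`, and `strand`
#'   (`"+"`/`"-"`). The TSS point is `start` on the plus strand and
#'   `end - 1` on the minus strand.
#' @param span scan width in bp for position calling and array scoring.
#' @param smooth_window,merge_dist passed to [call_positions()].
#' @return A data.frame, one row per input TSS (input order), with columns
#'   `name`, `chrom`, `pos`, `strand`, `array_score_down`,
#'   `depletion_level`, `occupancy`, `plus1_position`, `linker_length`,
#'   `linker_sd`, `nucleosome_count`.
#' @export
tss_feature_table <- function(occ, arr, tss, span = 1000L,
                              smooth_window = 50L, merge_dist = 100L) {
  stopifnot(is.data.frame(tss),
            all(c("chrom", "start", "end") %in% names(tss)))
  strand <- if ("strand" %in% names(tss)) as.character(tss$strand)
            else rep("+", nrow(tss))
  strand[!strand %in% c("+", "-")] <- "+"
  nm <- if ("name" %in% names(tss)) as.character(tss$name)
        else paste0("tss_", seq_len(nrow(tss)))
  gmean <- track_mean(arr)
  pos <- ifelse(strand == "-", tss$end - 1, tss$start)
  rows <- lapply(seq_len(nrow(tss)), function(i) {
    ch <- as.character(tss$chrom[i]); p <- pos[i]; st <- strand[i]
    dir <- if (st == "-") -1L else 1L
    calls <- call_positions(occ, ch, p, direction = dir, span = span,
                            smooth_window = smooth_window,
                            merge_dist = merge_dist)
    ls <- linker_stats(calls)
    data.frame(
      name = nm[i], chrom = ch, pos = p, strand = st,
      array_score_down = array_score(arr, ch, p, side = "down",
                                     span = span, strand = st,
                                     genome_mean = gmean),
      depletion_level = depletion_level(occ, ch, p),
      occupancy = occupancy_at_site(occ, ch, p),
      plus1_position = ls$first_position,
      linker_length = ls$linker_length,
      linker_sd = ls$linker_sd,
      nucleosome_count = ls$count,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-DHS nucleosome organization feature table
#'
#' As [tss_feature_table()], but DHSs are unstranded (reference
#' orientation) and features are computed on both sides of the anchor:
#' downstream (+1 nucleosome, downstream linker statistics,
#' `array_score_down`) and upstream (-1 nucleosome, upstream linker
#' statistics, `array_score_up`). The anchor is the summit
#' (`start + summit` if a `summit` offset column is present, narrowPeak
#' style) or the interval midpoint.
#'
#' @inheritParams tss_feature_table
#' @param dhs data.frame of DHS intervals with columns `chrom`, `start`,
#'   `end`, optional `name` and `summit` (offset from `start`).
#' @return A data.frame, one row per DHS, with downstream columns as in
#'   [tss_feature_table()] (with `minus1_position`, `up_*` columns added
#'   for the upstream scan).
#' @export
dhs_feature_table <- function(occ, arr, dhs, span = 1000L,
                              smooth_window = 50L, merge_dist = 100L) {
  stopifnot(is.data.frame(dhs),
            all(c("chrom", "start", "end") %in% names(dhs)))
  nm <- if ("name" %in% names(dhs)) as.character(dhs$name)
        else paste0("dhs_", seq_len(nrow(dhs)))
  anchor <- if ("summit" %in% names(dhs)) dhs$start + dhs$summit
            else (dhs$start + dhs$end) %/% 2
  gmean <- track_mean(arr)
  rows <- lapply(seq_len(nrow(dhs)), function(i) {
    ch <- as.character(dhs$chrom[i]); p <- anchor[i]
    down <- linker_stats(call_positions(occ, ch, p, direction = 1L,
                                        span = span,
                                        smooth_window = smooth_window,
                                        merge_dist = merge_dist))
    up <- linker_stats(call_positions(occ, ch, p, direction = -1L,
                                      span = span,
                                      smooth_window = smooth_window,
                                      merge_dist = merge_dist))
    data.frame(
      name = nm[i], chrom = ch, pos = p,
      array_score_down = array_score(arr, ch, p, side = "down",
                                     span = span, genome_mean = gmean),
      array_score_up = array_score(arr, ch, p, side = "up",
                                   span = span, genome_mean = gmean),
      depletion_level = depletion_level(occ, ch, p),
      occupancy = occupancy_at_site(occ, ch, p),
      plus1_position = down$first_position,
      linker_length = down$linker_length,
      linker_sd = down$linker_sd,
      nucleosome_count = down$count,
      minus1_position = up$first_position,
      up_linker_length = up$linker_length,
      up_linker_sd = up$linker_sd,
      up_nucleosome_count = up$count,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
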