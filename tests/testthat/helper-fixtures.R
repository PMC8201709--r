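# Small in-code fixtures shared across the suite.

# single-chromosome assembly
toy_assembly <- function(len = 1000L, n = 1L) {
  genome_assembly(paste0("chr", seq_len(n)), rep(len, n))
}

# wrap per-chromosome numeric vectors into a track
toy_track <- function(..., role = "occupancy", normalized = FALSE) {
  signal_track(list(...), role = role, normalized = normalized)
}

# occupancy vector with symmetric triangular peaks of a given half-width
# centered at 0-based positions
peak_profile <- function(len, centers, half = 60L, height = 1) {
  v <- numeric(len)
  for (p in centers) {
    idx <- (p - half):(p + half)
    ok <- idx >= 0 & idx < len
    v[idx[ok] + 1L] <- pmax(v[idx[ok] + 1L],
                            height * (1 - abs(idx[ok] - p) / (half + 1)))
  }
  v
}

# fragment_set from a plain data.frame
toy_frags <- function(df, id = "toy") {
  fragment_set(df, sample_id = id, cell_type = "toy", treatment = "none")
}

# brute-force per-base occupancy oracle (dyad-centered footprint pileup)
oracle_occupancy <- function(frag_df, len, footprint = 147L) {
  v <- numeric(len)
  half <- footprint %/% 2L
  for (i in seq_len(nrow(frag_df))) {
    mid <- (frag_df$start[i] + frag_df$end[i]) %/% 2
    for (x in max(mid - half, 0):(min(mid - half + footprint, len) - 1)) {
      v[x + 1] <- v[x + 1] + 1
    }
  }
  v
}

# brute-force windowed autocorrelation-peak oracle for the array signal
oracle_array_window <- function(v, s, e, lags) {
  x <- v[(s + 1):e]
  m <- mean(x); xc <- x - m
  den <- sum(xc^2)
  if (den == 0) return(0)
  best <- max(vapply(lags, function(l) {
    sum(xc[1:(length(xc) - l)] * xc[(l + 1):length(xc)])
  }, numeric(1)))
  min(max(best / den, 0), 1)
}

# brute-force local-maxima + merge oracle for nucleosome position calling
oracle_positions <- function(prof, merge_dist = 100L) {
  n <- length(prof)
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (prof[i] > prof[i - 1L]) {
      j <- i
      while (j < n && prof[j + 1L] == prof[i]) j <- j + 1L
      if (j < n && prof[j + 1L] < prof[i]) peaks <- c(peaks, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  h <- prof[peaks]
  while (length(peaks) > 1L) {
    gaps <- diff(peaks)
    viol <- which(gaps < merge_dist)
    if (length(viol) == 0L) break
    cand <- sort(unique(c(viol, viol + 1L)))
    worst <- cand[h[cand] == min(h[cand])]
    drop <- worst[which.max(peaks[worst])]
    peaks <- peaks[-drop]; h <- h[-drop]
  }
  peaks
}
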