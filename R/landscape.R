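#' Ranking indicators for a QC'd sample collection
#'
#' Computes the three summary indicators used to rank samples within a
#' cell type / treatment group:
#' \describe{
#'   \item{N_good}{number of 'Pass' QC labels (0-5; coverage carries no
#'     label).}
#'   \item{C_better}{number of the six metrics on which the sample's rank
#'     quantile is strictly greater than the mean quantile of its
#'     cell-type group for that metric (0-6).}
#'   \item{R_better}{sum of the sample's six rank quantiles (0-6).}
#' }
#' The final ordering sorts on (N_good, C_better, R_better) successively,
#' descending; residual ties are broken by higher coverage fold, then by
#' sample id, so the ordering is total and deterministic.
#'
#' @param collection list of `sample_qc` objects with quantiles filled
#'   (see [rank_quantiles()]).
#' @return data.frame, one row per sample, with columns `sample_id`,
#'   `cell_type`, `treatment`, `n_good`, `c_better`, `r_better`,
#'   `coverage_fold` and `rank` (1 = best), ordered by rank.
#' @export
compute_indicators <- function(collection) {
  stopifnot(length(collection) >= 1L,
            all(vapply(collection, function(q)
              !is.null(q$quantiles), logical(1))))
  metrics <- qc_metrics()
  df <- data.frame(
    sample_id = vapply(collection, function(q) q$sample_id, character(1)),
    cell_type = vapply(collection, function(q) q$cell_type, character(1)),
    treatment = vapply(collection, function(q) q$treatment, character(1)),
    n_good = vapply(collection, function(q)
      sum(q$labels == "Pass"), numeric(1)),
    coverage_fold = vapply(collection, function(q)
      q$values[["coverage_fold"]], numeric(1)),
    stringsAsFactors = FALSE)
  qmat <- sapply(collection, function(q) q$quantiles[metrics])
  df$r_better <- colSums(qmat)
  group <- paste(df$cell_type, df$treatment, sep = "\r")
  c_better <- numeric(nrow(df))
  for (g in unique(group)) {
    idx <- which(group == g)
    gmean <- rowMeans(qmat[, idx, drop = FALSE])
    for (i in idx) c_better[i] <- sum(qmat[, i] > gmean)
  }
  df$c_better <- c_better
  ord <- order(-df$n_good, -df$c_better, -df$r_better, -df$coverage_fold,
               df$sample_id)
  df <- df[ord, c("sample_id", "cell_type", "treatment", "n_good",
                  "c_better", "r_better", "coverage_fold")]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Mean occupancy in non-overlapping genomic windows
#'
#' @param track occupancy [signal_track()] at 1 bp resolution.
#' @param window window width in bp (default 1000). Trailing partial
#'   windows are dropped.
#' @return Numeric vector of window means, concatenated across
#'   chromosomes.
#' @export
bin_track <- function(track, window = 1000L) {
  stopifnot(inherits(track, "signal_track"), track$resolution == 1L)
  unlist(lapply(track$data, function(v) {
    nw <- length(v) %/% window
    if (nw == 0L) return(numeric(0))
    colMeans(matrix(v[seq_len(nw * window)], nrow = window))
  }), use.names = FALSE)
}

#' Pool highly correlated samples
#'
#' Occupancy is averaged in non-overlapping 1 kb windows genome-wide and
#' Pearson correlation is computed for every sample pair; windows with
#' zero occupancy in both members of a pair are excluded so unmappable
#' regions do not inflate the correlation. Samples are pooled by
#' single-linkage: the groups are the connected components (of size >= 2)
#' of the graph whose edges join pairs with `r > r_min`.
#'
#' @param tracks named list of occupancy [signal_track()] objects (one
#'   per sample, same assembly).
#' @param window correlation window width in bp.
#' @param r_min correlation threshold; pairs correlate into the same pool
#'   only when `r` is strictly greater (default 0.6).
#' @return An object of class `pool_plan`: `groups` (list of member-id
#'   character vectors, each named by a pooled-sample id), `cor`
#'   (pairwise correlation matrix) and `r_min`.
#' @export
pool_samples <- function(tracks, window = 1000L, r_min = 0.6) {
  stopifnot(length(tracks) >= 2L, !is.null(names(tracks)))
  lens <- lapply(tracks, function(t) vapply(t$data, length, numeric(1)))
  if (length(unique(lapply(lens, unname))) != 1L ||
      length(unique(lapply(tracks, function(t) names(t$data)))) != 1L) {
    stop("all tracks must share the same assembly")
  }
  W <- sapply(tracks, bin_track, window = window)
  ids <- names(tracks)
  n <- length(ids)
  cm <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(cm) <- 1
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      use <- W[, i] != 0 | W[, j] != 0
      cm[i, j] <- cm[j, i] <- if (sum(use) >= 3L)
        stats::cor(W[use, i], W[use, j]) else NA_real_
    }
  }
  # connected components over edges r > r_min (single linkage)
  comp <- seq_len(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!is.na(cm[i, j]) && cm[i, j] > r_min) {
        old <- comp[j]; comp[comp == old] <- comp[i]
      }
    }
  }
  groups <- list()
  for (cid in unique(comp)) {
    members <- ids[comp == cid]
    if (length(members) >= 2L) groups[[length(groups) + 1L]] <- members
  }
  if (length(groups)) {
    names(groups) <- paste0("pooled_", seq_along(groups))
  }
  structure(list(groups = groups, cor = cm, r_min = r_min),
            class = "pool_plan")
}

#' @export
print.pool_plan <- function(x, ...) {
  cat("<pool_plan> r_min=", x$r_min, ", ", length(x$groups),
      " pool(s)\n", sep = "")
  for (nm in names(x$groups)) {
    cat("  ", nm, ": ", paste(x$groups[[nm]], collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Select the referenced nucleosome organization landscape
#'
#' The top-ranked sample is the 'High Quality Sample'. It defines the
#' referenced landscape for the group, unless it is a member of a pooled
#' sample, in which case the pooled sample (whose coverage fold is the
#' sum of its members') is the reference. A reference with coverage below
#' `min_fold` (default five-fold) is discarded and the group reports no
#' reference.
#'
#' @param ranking data.frame from [compute_indicators()] for one group.
#' @param pools a `pool_plan` from [pool_samples()] (or `NULL` for no
#'   pooling).
#' @param coverages named numeric vector of per-sample coverage folds.
#' @param min_fold minimum acceptable coverage fold (default 5).
#' @return A list of class `reference_selection`: `reference_id`,
#'   `provenance` (`"high_quality"`, `"pooled"` or `"none"`), `members`
#'   and `coverage_fold`.
#' @export
select_reference <- function(ranking, pools = NULL, coverages,
                             min_fold = 5) {
  stopifnot(nrow(ranking) >= 1L)
  hq <- ranking$sample_id[ranking$rank == 1L]
  group_label <- paste(ranking$cell_type[1], ranking$treatment[1],
                       sep = "/")
  pool_of <- NULL
  if (!is.null(pools)) {
    for (nm in names(pools$groups)) {
      if (hq %in% pools$groups[[nm]]) { pool_of <- nm; break }
    }
  }
  if (!is.null(pool_of)) {
    members <- pools$groups[[pool_of]]
    fold <- sum(coverages[members])
    ref <- list(group = group_label, reference_id = pool_of,
                provenance = "pooled", members = members,
                coverage_fold = fold)
  } else {
    fold <- unname(coverages[[hq]])
    ref <- list(group = group_label, reference_id = hq,
                provenance = "high_quality", members = hq,
                coverage_fold = fold)
  }
  if (is.na(ref$coverage_fold) || ref$coverage_fold < min_fold) {
    ref <- list(group = group_label, reference_id = NA_character_,
                provenance = "none", members = character(0),
                coverage_fold = ref$coverage_fold)
  }
  structure(ref, class = "reference_selection")
}

#' @export
print.reference_selection <- function(x, ...) {
  if (x$provenance == "none") {
    cat("<reference_selection> ", x$group, ": no reference (coverage ",
        sprintf("%.2f", x$coverage_fold), "-fold)\n", sep = "")
  } else {
    cat("<reference_selection> ", x$group, ": ", x$reference_id, " (",
        x$provenance, ", ", sprintf("%.2f", x$coverage_fold),
        "-fold)\n", sep = "")
  }
  invisible(x)
}
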