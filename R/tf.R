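#' Label motif hits by ChIP-seq peak overlap
#'
#' A motif hit is 'bound' when it overlaps (by at least 1 bp, half-open
#' intervals) any ChIP-seq peak; all other hits are 'unbound'. All hits
#' are retained.
#'
#' @param hits data.frame of motif hits with columns `chrom`, `start`,
#'   `end` (0-based half-open) and `motif_score` (or BED `score`).
#' @param peaks data.frame of peak intervals (`chrom`, `start`, `end`).
#' @return The `hits` data.frame with a logical `bound` column and a
#'   normalized `motif_score` column.
#' @export
label_sites <- function(hits, peaks) {
  stopifnot(is.data.frame(hits), is.data.frame(peaks))
  if (nrow(hits) == 0L) stop("no motif hits supplied")
  if (nrow(peaks) == 0L) stop("no peak intervals supplied")
  if (!"motif_score" %in% names(hits)) {
    if ("score" %in% names(hits)) hits$motif_score <- hits$score
    else stop("hits must carry a 'motif_score' (or 'score') column")
  }
  if (!is.numeric(hits$motif_score) || any(!is.finite(hits$motif_score))) {
    stop("motif scores must be finite numbers")
  }
  gr_h <- GenomicRanges::GRanges(
    hits$chrom, IRanges::IRanges(hits$start + 1, hits$end))
  gr_p <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1, peaks$end))
  hits$bound <- IRanges::overlapsAny(gr_h, gr_p)
  hits
}

#' Extract nucleosome organization predictors at motif hits
#'
#' Computes the four nucleosome predictors at each hit center
#' `floor((start + end) / 2)` by delegating to the locus-feature
#' operations: depletion level, mean occupancy over the central 100 bp,
#' and the up-/downstream 1 kb array scores. Hits are treated as
#' unstranded (reference orientation). Hits whose windows fall off the
#' chromosome are dropped with a message.
#'
#' @param sites labelled hits from [label_sites()].
#' @param occ occupancy [signal_track()].
#' @param arr array [signal_track()].
#' @return `sites` with columns `depletion`, `occupancy`, `array_up`,
#'   `array_down` added and off-chromosome rows removed.
#' @export
extract_predictors <- function(sites, occ, arr) {
  stopifnot(is.data.frame(sites), "bound" %in% names(sites))
  center <- (sites$start + sites$end) %/% 2
  gmean <- track_mean(arr)
  n <- nrow(sites)
  dep <- occu <- aup <- adown <- numeric(n)
  for (i in seq_len(n)) {
    ch <- as.character(sites$chrom[i]); p <- center[i]
    dep[i] <- depletion_level(occ, ch, p)
    occu[i] <- occupancy_at_site(occ, ch, p)
    aup[i] <- array_score(arr, ch, p, side = "up", genome_mean = gmean)
    adown[i] <- array_score(arr, ch, p, side = "down", genome_mean = gmean)
  }
  sites$depletion <- dep
  sites$occupancy <- occu
  sites$array_up <- aup
  sites$array_down <- adown
  keep <- stats::complete.cases(
    sites[, c("depletion", "occupancy", "array_up", "array_down")])
  if (any(!keep)) {
    message(sum(!keep), " site(s) with off-chromosome windows dropped")
    sites <- sites[keep, , drop = FALSE]
  }
  rownames(sites) <- NULL
  sites
}

#' Rank-based ROC AUC
#'
#' Area under the ROC curve computed from the Mann-Whitney U statistic
#' (average ranks for ties), equivalent to trapezoidal integration of the
#' ROC curve.
#'
#' @param scores numeric prediction scores.
#' @param labels logical (or 0/1) class labels; `TRUE` = positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Logistic fit robust to complete separation: plain ML via glm; if glm
# reports separation or fails to converge, refit as a barely-regularized
# ridge so predictions stay defined.
.fit_logistic <- function(x, y) {
  x <- as.matrix(x)
  df <- data.frame(y = y, x)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!sep && fit$converged) {
    return(list(predict = function(newx) {
      stats::predict(fit, newdata = data.frame(as.matrix(newx)),
                     type = "response")
    }, coef = stats::coef(fit), ridge = FALSE))
  }
  # ridge fallback (penalty 1e-6)
  xr <- cbind(x, .jitter_col = 0)  # glmnet needs >= 2 columns
  gfit <- suppressWarnings(
    glmnet::glmnet(xr, y, family = "binomial", alpha = 0,
                   lambda = 1e-6, standardize = FALSE))
  list(predict = function(newx) {
    as.numeric(stats::predict(gfit, newx = cbind(as.matrix(newx),
                                                 .jitter_col = 0),
                              type = "response"))
  }, coef = {
    cf <- as.numeric(stats::coef(gfit))
    names(cf) <- rownames(stats::coef(gfit))
    cf[names(cf) != ".jitter_col"]
  }, ridge = TRUE)
}

#' Fit and cross-validate the TF binding prediction models
#'
#' Fits two logistic regression models of binding status -- motif score
#' only, and motif score plus the four nucleosome organization predictors
#' -- and evaluates both with stratified k-fold cross-validation on
#' identical folds. Out-of-fold predicted probabilities are pooled for the
#' primary AUC (rank statistic); per-fold AUCs are also reported.
#' Classification metrics (sensitivity, specificity, precision, F1, FPR)
#' are computed at probability threshold 0.5 on the pooled out-of-fold
#' predictions. The AUC improvement is
#' AUC(motif + nucleosome) - AUC(motif).
#'
#' @param sites data.frame from [extract_predictors()] with `bound`,
#'   `motif_score`, `depletion`, `occupancy`, `array_up`, `array_down`.
#' @param folds number of CV folds (default 10; reduced with a message if
#'   a class has fewer members than folds).
#' @param seed RNG seed for the stratified fold assignment.
#' @return An object of class `tf_model_result`: `auc` (pooled and
#'   mean-per-fold AUC for both models), `fold_auc`, `coefficients`
#'   (full-data fits), `metrics` (threshold-0.5 classification metrics
#'   per model), `auc_improvement`, `n`, `folds`.
#' @export
fit_and_evaluate <- function(sites, folds = 10L, seed = 1234L) {
  req <- c("bound", "motif_score", "depletion", "occupancy", "array_up",
           "array_down")
  stopifnot(all(req %in% names(sites)))
  y <- as.logical(sites$bound)
  if (all(y) || all(!y)) stop("both bound and unbound sites are required")
  n1 <- sum(y); n0 <- sum(!y)
  folds <- as.integer(folds)
  if (min(n1, n0) < folds) {
    folds <- max(2L, min(n1, n0))
    message("reducing to ", folds, "-fold CV (smallest class has ",
            min(n1, n0), " sites)")
  }
  preds_motif <- c("motif_score")
  preds_full <- c("motif_score", "depletion", "occupancy", "array_up",
                  "array_down")
  fold_id <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- which(y == cls)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  oof <- list(motif = numeric(length(y)), full = numeric(length(y)))
  fold_auc <- matrix(NA_real_, nrow = folds, ncol = 2,
                     dimnames = list(NULL, c("motif", "full")))
  for (k in seq_len(folds)) {
    test <- fold_id == k
    fm <- .fit_logistic(sites[!test, preds_motif, drop = FALSE], y[!test])
    ff <- .fit_logistic(sites[!test, preds_full, drop = FALSE], y[!test])
    oof$motif[test] <- fm$predict(sites[test, preds_motif, drop = FALSE])
    oof$full[test] <- ff$predict(sites[test, preds_full, drop = FALSE])
    fold_auc[k, "motif"] <- roc_auc(oof$motif[test], y[test])
    fold_auc[k, "full"] <- roc_auc(oof$full[test], y[test])
  }
  auc <- data.frame(
    model = c("motif", "full"),
    auc_pooled = c(roc_auc(oof$motif, y), roc_auc(oof$full, y)),
    auc_mean_fold = c(mean(fold_auc[, "motif"], na.rm = TRUE),
                      mean(fold_auc[, "full"], na.rm = TRUE)),
    stringsAsFactors = FALSE)
  full_motif <- .fit_logistic(sites[, preds_motif, drop = FALSE], y)
  full_full <- .fit_logistic(sites[, preds_full, drop = FALSE], y)
  metrics <- rbind(motif = .class_metrics(oof$motif >= 0.5, y),
                   full = .class_metrics(oof$full >= 0.5, y))
  structure(list(
    auc = auc,
    fold_auc = fold_auc,
    coefficients = list(motif = full_motif$coef, full = full_full$coef),
    metrics = as.data.frame(metrics),
    auc_improvement = auc$auc_pooled[auc$model == "full"] -
      auc$auc_pooled[auc$model == "motif"],
    n = length(y), folds = folds, seed = seed,
    oof = oof, labels = y
  ), class = "tf_model_result")
}

.class_metrics <- function(pred, truth) {
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  c(sensitivity = sens, specificity = spec, precision = prec, f1 = f1,
    fpr = if (!is.na(spec)) 1 - spec else NA_real_)
}

#' AUC improvement from nucleosome organization features
#'
#' @param result a `tf_model_result` from [fit_and_evaluate()].
#' @return AUC(motif + nucleosome features) - AUC(motif only), on the
#'   pooled out-of-fold predictions.
#' @export
auc_improvement <- function(result) {
  stopifnot(inherits(result, "tf_model_result"))
  result$auc_improvement
}

#' @export
print.tf_model_result <- function(x, ...) {
  cat("<tf_model_result> n=", x$n, ", ", x$folds, "-fold CV\n", sep = "")
  cat(sprintf("  motif-only AUC: %.4f (pooled), %.4f (mean fold)\n",
              x$auc$auc_pooled[1], x$auc$auc_mean_fold[1]))
  cat(sprintf("  full model AUC: %.4f (pooled), %.4f (mean fold)\n",
              x$auc$auc_pooled[2], x$auc$auc_mean_fold[2]))
  cat(sprintf("  AUC improvement: %+.4f\n", x$auc_improvement))
  invisible(x)
}
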