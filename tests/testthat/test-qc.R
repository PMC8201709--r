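test_that("fragment length metric is the histogram mode", {
  mk <- function(lens) {
    toy_frags(data.frame(chrom = "chr1", start = 1000,
                         end = 1000 + lens))
  }
  expect_equal(as.numeric(qc_fragment_length(mk(rep(147, 120)))), 147)
  lens <- c(rep(140, 10), rep(147, 50), rep(160, 5))
  expect_equal(as.numeric(qc_fragment_length(mk(lens))), 147)
  small <- qc_fragment_length(mk(lens))
  expect_true(isTRUE(attr(small, "low_confidence")))

  set.seed(99)
  lens <- round(rnorm(10000, 150, 10))
  mode_len <- as.numeric(qc_fragment_length(mk(lens)))
  expect_true(mode_len >= 147 && mode_len <= 153)
  # matches an independent histogram oracle
  h <- table(lens)
  expect_equal(mode_len, as.numeric(names(h)[which.max(h)]))
})

test_that("planted 10 bp AA periodicity scores above a shuffled genome", {
  wins <- 0L
  for (s in 1:5) {
    spec <- synthetic_spec(seed = s, n_chrom = 1L, chrom_length = 60000L,
                           n_tss_per_chrom = 4L, n_dhs_per_chrom = 4L,
                           n_fragments = 4000L, jitter_sd = 0,
                           noise_fraction = 0)
    sim <- simulate_sample(spec)
    fa_planted <- tempfile(fileext = ".fa")
    fa_shuffled <- tempfile(fileext = ".fa")
    write_synthetic_genome(sim, fa_planted, plant = TRUE)
    write_synthetic_genome(sim, fa_shuffled, plant = FALSE)
    sc_p <- qc_dinucleotide_periodicity(sim$fragments, sim$assembly,
                                        fasta = fa_planted)
    sc_s <- qc_dinucleotide_periodicity(sim$fragments, sim$assembly,
                                        fasta = fa_shuffled)
    expect_true(sc_p >= 0 && sc_p <= 1)
    expect_true(sc_s >= 0 && sc_s <= 1)
    if (sc_p > sc_s) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("periodicity score handles degenerate and ideal profiles", {
  expect_equal(periodicity_score(rep(0.25, 146)), 0)
  expect_equal(periodicity_score(numeric(0)), 0)
  # pure 10 bp cosine concentrates most power in the band (spectral
  # leakage from the non-integer cycle count spreads the remainder)
  x <- cos(2 * pi * (0:145) / 10)
  expect_gt(periodicity_score(x), 0.8)
  # missing FASTA reports NA
  frags <- toy_frags(data.frame(chrom = "chr1", start = 0, end = 147))
  asm <- toy_assembly(1000L)
  expect_true(is.na(qc_dinucleotide_periodicity(frags, asm)))
})

test_that("TSS depletion QC averages per-site depletion", {
  len <- 5000L
  # 300 bp zero-valley at the TSS inside uniform occupancy
  v <- rep(4, len); v[(2500 - 150 + 1):(2500 + 150)] <- 0
  tr <- toy_track(chr1 = v)
  tss1 <- data.frame(chrom = "chr1", start = 2500, end = 2501,
                     strand = "+")
  expect_equal(qc_tss_depletion(tr, tss1), 1.0)

  flat <- toy_track(chr1 = rep(2, len))
  expect_equal(qc_tss_depletion(flat, tss1), 0)

  # mixed set: mean of the per-class values
  v2 <- rep(4, len)
  v2[(1000 - 100 + 1):(1000 + 100)] <- 1   # central max 1, background 4
  two <- data.frame(chrom = "chr1", start = c(1000, 3000),
                    end = c(1001, 3001), strand = "+")
  expect_equal(qc_tss_depletion(toy_track(chr1 = v2), two),
               mean(c(1 - 1 / 4, 0)))
  expect_error(qc_tss_depletion(tr, data.frame(chrom = "chrZ", start = 10,
                                               end = 11, strand = "+")),
               "no usable TSS")
})

test_that("fuzziness is the CV of the +1..+4 spacings with hand-checked values", {
  len <- 3000L
  mk_track <- function(offsets) {
    toy_track(chr1 = 0.05 + peak_profile(len, centers = 1000 + offsets,
                                         half = 40L))
  }
  tss <- data.frame(chrom = "chr1", start = 1000, end = 1001,
                    strand = "+")
  # equal 190 bp spacings -> CV = 0
  expect_equal(qc_tss_fuzziness(mk_track(c(100, 290, 480, 670)), tss,
                                smooth_window = 20), 0)
  # spacings 150/200/250 -> population SD / mean = 0.204124
  tr <- mk_track(cumsum(c(150, 150, 200, 250)))
  expect_equal(qc_tss_fuzziness(tr, tss, smooth_window = 20),
               sqrt(mean((c(150, 200, 250) - 200)^2)) / 200,
               tolerance = 1e-12)
  expect_equal(qc_tss_fuzziness(tr, tss, smooth_window = 20), 0.2041241,
               tolerance = 1e-6)
  # spacings 100/200/400 -> CV ~ 0.5346 (a 'Fail' value)
  tr2 <- mk_track(cumsum(c(120, 100, 200, 400)))
  expect_equal(qc_tss_fuzziness(tr2, tss, smooth_window = 20), 0.5345225,
               tolerance = 1e-6)
  # fewer than four aggregate peaks -> NA
  expect_true(is.na(qc_tss_fuzziness(mk_track(c(200, 400)), tss,
                                     smooth_window = 20)))
})

test_that("fuzziness of a regular synthetic array is 0 and grows with jitter", {
  base <- function(j, s) {
    synthetic_spec(seed = s, n_chrom = 1L, chrom_length = 150000L,
                   n_tss_per_chrom = 8L, n_dhs_per_chrom = 2L,
                   jitter_sd = j, noise_fraction = 0,
                   n_fragments = 20000L)
  }
  sim0 <- simulate_sample(base(0, 1))
  occ0 <- build_occupancy_track(sim0$fragments, sim0$assembly)
  expect_equal(qc_tss_fuzziness(occ0, sim0$tss), 0)

  cv_at <- function(j) {
    mean(vapply(1:4, function(s) {
      sim <- simulate_sample(base(j, s))
      occ <- build_occupancy_track(sim$fragments, sim$assembly)
      v <- qc_tss_fuzziness(occ, sim$tss)
      if (is.na(v)) 1 else v
    }, numeric(1)))
  }
  cvs <- c(cv_at(0), cv_at(25), cv_at(60))
  expect_true(all(diff(cvs) > 0))
})

test_that("DHS array enrichment is the windowed mean over the genome mean", {
  len <- 20000L
  a <- rep(0.4, len)
  dhs <- data.frame(chrom = "chr1", start = c(5000, 12000) - 100,
                    end = c(5000, 12000) + 100)
  for (c0 in c(5000, 12000)) a[(c0 - 1000 + 1):(c0 + 1000)] <- 0.8
  arr <- toy_track(chr1 = a, role = "array")
  expect_equal(qc_dhs_array_enrichment(arr, dhs), 0.8 / mean(a))
  # uniform track -> exactly 1
  expect_equal(qc_dhs_array_enrichment(
    toy_track(chr1 = rep(0.3, len), role = "array"), dhs), 1.0)
  expect_error(qc_dhs_array_enrichment(
    toy_track(chr1 = numeric(len), role = "array"), dhs), "degenerate")
})

test_that("phased arrays planted at DHSs raise the enrichment above 1", {
  sim <- simulate_sample(synthetic_spec(seed = 12))
  occ <- build_occupancy_track(sim$fragments, sim$assembly)
  arr <- build_array_track(occ)
  enr <- qc_dhs_array_enrichment(arr, sim$dhs)
  expect_gt(enr, 1)
  # matches a direct windowed computation
  anchors <- (sim$dhs$start + sim$dhs$end) %/% 2
  vals <- unlist(lapply(seq_len(nrow(sim$dhs)), function(i) {
    v <- arr$data[[sim$dhs$chrom[i]]]
    v[(anchors[i] - 1000 + 1):(anchors[i] + 1000)]
  }))
  expect_equal(enr, mean(vals) / track_mean(arr), tolerance = 1e-12)
})

test_that("labels follow the printed fuzziness rule and NA fails", {
  mk_qc <- function(fuzz) {
    structure(list(sample_id = "s", cell_type = "c", treatment = "n",
                   values = c(coverage_fold = 10,
                              dinucleotide_periodicity = 0.2,
                              fragment_length = 146,
                              tss_depletion = 0.5,
                              tss_fuzziness = fuzz,
                              dhs_array_enrichment = 1.5),
                   labels = NULL, quantiles = NULL),
              class = "sample_qc")
  }
  expect_equal(unname(assign_labels(mk_qc(0.39))$labels["tss_fuzziness"]),
               "Pass")
  expect_equal(unname(assign_labels(mk_qc(0.40))$labels["tss_fuzziness"]),
               "Fail")
  expect_equal(unname(assign_labels(mk_qc(NA))$labels["tss_fuzziness"]),
               "Fail")
  lab <- assign_labels(mk_qc(0.1))$labels
  # exactly five labels; coverage is never labelled
  expect_equal(length(lab), 5L)
  expect_false("coverage_fold" %in% names(lab))
})

test_that("rank quantiles follow the printed per-metric directions", {
  mk <- function(id, cov = 10, dinu = 0.2, fl = 146, dep = 0.5,
                 fuzz = 0.2, enr = 1.5, cell = "c") {
    q <- structure(list(sample_id = id, cell_type = cell, treatment = "n",
                        values = c(coverage_fold = cov,
                                   dinucleotide_periodicity = dinu,
                                   fragment_length = fl,
                                   tss_depletion = dep,
                                   tss_fuzziness = fuzz,
                                   dhs_array_enrichment = enr),
                        labels = NULL, quantiles = NULL),
                   class = "sample_qc")
    assign_labels(q)
  }
  # two samples: higher coverage gets quantile 1
  col <- rank_quantiles(list(mk("a", cov = 10), mk("b", cov = 5)))
  expect_equal(unname(col[[1]]$quantiles["coverage_fold"]), 1.0)
  expect_equal(unname(col[[2]]$quantiles["coverage_fold"]), 0.0)

  # fragment length ranked by |value - 146|: 146/150/138 -> 1.0/0.5/0.0
  col <- rank_quantiles(list(mk("a", fl = 146), mk("b", fl = 150),
                             mk("c", fl = 138)))
  expect_equal(vapply(col, function(q)
    unname(q$quantiles["fragment_length"]), numeric(1)), c(1.0, 0.5, 0.0))

  # fuzziness ascending: smallest CV is best
  col <- rank_quantiles(list(mk("a", fuzz = 0.3), mk("b", fuzz = 0.1),
                             mk("c", fuzz = 0.2)))
  expect_equal(vapply(col, function(q)
    unname(q$quantiles["tss_fuzziness"]), numeric(1)), c(0.0, 1.0, 0.5))

  # singleton collection: quantile 1 everywhere
  col <- rank_quantiles(list(mk("a")))
  expect_true(all(col[[1]]$quantiles == 1))

  # every sample gets six quantiles in [0, 1]
  col <- rank_quantiles(list(mk("a"), mk("b", cov = 3)))
  for (q in col) {
    expect_equal(length(q$quantiles), 6L)
    expect_true(all(q$quantiles >= 0 & q$quantiles <= 1))
  }

  # NA metric: quantile 0
  qa <- mk("a"); qa$values["dinucleotide_periodicity"] <- NA
  col <- rank_quantiles(list(qa, mk("b")))
  expect_equal(unname(col[[1]]$quantiles["dinucleotide_periodicity"]), 0)
})

test_that("tied metrics receive average-rank quantiles (brute-force oracle)", {
  mk <- function(id, cov) {
    structure(list(sample_id = id, cell_type = "c", treatment = "n",
                   values = c(coverage_fold = cov,
                              dinucleotide_periodicity = 0.2,
                              fragment_length = 146, tss_depletion = 0.5,
                              tss_fuzziness = 0.2,
                              dhs_array_enrichment = 1.5),
                   labels = NULL, quantiles = NULL),
              class = "sample_qc")
  }
  covs <- c(10, 7, 7, 7, 3)
  col <- rank_quantiles(lapply(seq_along(covs), function(i)
    mk(paste0("s", i), covs[i])))
  got <- vapply(col, function(q)
    unname(q$quantiles["coverage_fold"]), numeric(1))
  # oracle: average rank of descending coverage, mapped to quantiles
  r <- rank(-covs, ties.method = "average")
  expect_equal(got, 1 - (r - 1) / (length(covs) - 1))
})

test_that("quantiles are permutation-equivariant and rescale-invariant", {
  mk <- function(id, cov, dep) {
    structure(list(sample_id = id, cell_type = "c", treatment = "n",
                   values = c(coverage_fold = cov,
                              dinucleotide_periodicity = 0.2,
                              fragment_length = 146, tss_depletion = dep,
                              tss_fuzziness = 0.2,
                              dhs_array_enrichment = 1.5),
                   labels = NULL, quantiles = NULL),
              class = "sample_qc")
  }
  set.seed(4)
  covs <- runif(6, 1, 20); deps <- runif(6)
  base <- lapply(1:6, function(i) mk(paste0("s", i), covs[i], deps[i]))
  q1 <- rank_quantiles(base)
  perm <- c(3, 1, 6, 2, 5, 4)
  q2 <- rank_quantiles(base[perm])
  for (k in 1:6) {
    expect_equal(q2[[k]]$quantiles, q1[[perm[k]]]$quantiles)
  }
  # strictly monotone rescaling of a descending metric preserves quantiles
  resc <- lapply(1:6, function(i) mk(paste0("s", i), exp(covs[i] / 3),
                                     deps[i]))
  q3 <- rank_quantiles(resc)
  for (k in 1:6) expect_equal(q3[[k]]$quantiles, q1[[k]]$quantiles)
})

test_that("compute_sample_qc assembles the full six-metric panel", {
  sim <- simulate_sample(synthetic_spec(seed = 5))
  occ <- build_occupancy_track(sim$fragments, sim$assembly)
  arr <- build_array_track(occ)
  qc <- compute_sample_qc(sim$fragments, sim$assembly, sim$tss, sim$dhs,
                          occ = occ, arr = arr)
  expect_s3_class(qc, "sample_qc")
  expect_equal(names(qc$values), qc_metrics())
  expect_equal(length(qc$labels), 5L)
  expect_true(all(qc$labels %in% c("Pass", "Fail")))
  # a clean default-condition sample passes the four computable labels
  expect_equal(unname(qc$labels["tss_fuzziness"]), "Pass")
  expect_equal(unname(qc$labels["tss_depletion"]), "Pass")
  expect_equal(unname(qc$labels["dhs_array_enrichment"]), "Pass")
  expect_equal(unname(qc$labels["fragment_length"]), "Pass")
  tab <- qc_table(rank_quantiles(list(qc)))
  expect_equal(nrow(tab), 1L)
  expect_true(all(paste0("q_", qc_metrics()) %in% names(tab)))
})
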