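#' Specification for a synthetic MNase-seq sample
#'
#' Defines a fully synthetic study condition: a genome, promoter (TSS)
#' and accessible-region (DHS) architecture, and fragment sampling
#' parameters. Defaults describe a clean mononucleosomal library over a
#' compact genome: nucleosome-free regions at every TSS/DHS, phased
#' downstream arrays at a 190 bp repeat, fragment lengths near 147 bp and
#' a 10% unpositioned background.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_tss_per_chrom TSS count per chromosome (alternating strands).
#' @param n_dhs_per_chrom DHS count per chromosome.
#' @param nfr_width nucleosome-free region width in bp centered on each
#'   anchor.
#' @param spacing nucleosome repeat length in bp (dyad-to-dyad); must be
#'   at least 100 bp.
#' @param n_nucleosomes positioned nucleosomes per array.
#' @param jitter_sd per-fragment positional jitter SD in bp around the
#'   dyad (0 = perfectly positioned).
#' @param n_fragments total fragment count.
#' @param fragment_length_mean,fragment_length_sd Normal fragment-length
#'   model in bp, truncated to `[80, 250]`.
#' @param noise_fraction fraction of fragments placed uniformly at random
#'   (unpositioned background), in `[0, 1]`.
#' @param plant_dinucleotide plant AA dinucleotides at a 10 bp phase
#'   inside nucleosomal DNA when generating sequence (makes the
#'   dinucleotide periodicity metric informative).
#' @param seed RNG seed; recorded in every output.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_chrom = 2L, chrom_length = 300000L,
                           n_tss_per_chrom = 10L, n_dhs_per_chrom = 10L,
                           nfr_width = 300L, spacing = 190L,
                           n_nucleosomes = 5L, jitter_sd = 20,
                           n_fragments = 60000L,
                           fragment_length_mean = 147,
                           fragment_length_sd = 15,
                           noise_fraction = 0.1,
                           plant_dinucleotide = TRUE,
                           seed = 1L) {
  if (spacing < 100) stop("infeasible spec: nucleosome spacing < 100 bp")
  if (noise_fraction < 0 || noise_fraction > 1) {
    stop("noise_fraction must be in [0, 1]")
  }
  stopifnot(n_chrom >= 1, chrom_length > 0, nfr_width > 0,
            n_nucleosomes >= 1, n_fragments > 0, jitter_sd >= 0)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Simulate an MNase-seq sample with known ground truth
#'
#' Lays out TSSs and DHSs on each chromosome, places nucleosome dyads as
#' phased arrays flanking each anchor (downstream of TSSs; both sides of
#' DHSs) separated from the anchor by half the nucleosome-free region,
#' then samples fragments: a `1 - noise_fraction` share centered on
#' randomly chosen dyads with Normal positional jitter, the rest
#' uniformly across the genome. Fragment lengths are
#' Normal(mean, sd) truncated to `[80, 250]`.
#'
#' @param spec a [synthetic_spec()].
#' @return A list of class `synthetic_sample`: `fragments`
#'   ([fragment_set()]), `assembly`, `tss` / `dhs` annotation
#'   data.frames, `dyads` truth table, `expected_spacing` and `spec`.
#'   Fully deterministic given `spec$seed`.
#' @export
simulate_sample <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, .simulate_sample_impl(spec))
}

.simulate_sample_impl <- function(spec) {
  chroms <- paste0("chr", seq_len(spec$n_chrom))
  assembly <- genome_assembly(chroms, rep(spec$chrom_length, spec$n_chrom))
  gap <- spec$chrom_length %/% (spec$n_tss_per_chrom +
                                  spec$n_dhs_per_chrom + 1L)
  arm <- spec$nfr_width %/% 2L + 73L   # anchor-to-first-dyad distance
  tss <- dhs <- dyads <- list()
  for (ci in seq_along(chroms)) {
    anchors <- gap * seq_len(spec$n_tss_per_chrom + spec$n_dhs_per_chrom)
    is_tss <- rep(c(TRUE, FALSE),
                  length.out = length(anchors))
    tpos <- anchors[is_tss]
    dpos <- anchors[!is_tss]
    tstrand <- rep(c("+", "-"), length.out = length(tpos))
    tss[[ci]] <- data.frame(
      chrom = chroms[ci],
      start = tpos,
      end = tpos + 1L,
      name = sprintf("%s_tss%d", chroms[ci], seq_along(tpos)),
      score = 0L, strand = tstrand, stringsAsFactors = FALSE)
    dhs[[ci]] <- data.frame(
      chrom = chroms[ci], start = dpos - 150L, end = dpos + 150L,
      name = sprintf("%s_dhs%d", chroms[ci], seq_along(dpos)),
      stringsAsFactors = FALSE)
    dy <- list()
    for (k in seq_along(tpos)) {
      sgn <- if (tstrand[k] == "+") 1L else -1L
      dy[[k]] <- data.frame(
        chrom = chroms[ci],
        pos = tpos[k] + sgn * (arm + spec$spacing *
                                 (seq_len(spec$n_nucleosomes) - 1L)),
        origin = "tss", stringsAsFactors = FALSE)
    }
    for (k in seq_along(dpos)) {
      offs <- arm + spec$spacing * (seq_len(spec$n_nucleosomes) - 1L)
      dy[[length(tpos) + k]] <- data.frame(
        chrom = chroms[ci], pos = c(dpos[k] + offs, dpos[k] - offs),
        origin = "dhs", stringsAsFactors = FALSE)
    }
    dyads[[ci]] <- do.call(rbind, dy)
  }
  tss <- do.call(rbind, tss); dhs <- do.call(rbind, dhs)
  dyads <- do.call(rbind, dyads)
  dyads <- dyads[dyads$pos - 100 >= 0 &
                   dyads$pos + 100 < spec$chrom_length, ]
  rownames(dyads) <- NULL

  n_pos <- round(spec$n_fragments * (1 - spec$noise_fraction))
  n_bg <- spec$n_fragments - n_pos
  lens <- round(stats::rnorm(spec$n_fragments, spec$fragment_length_mean,
                             spec$fragment_length_sd))
  lens <- pmin(pmax(lens, 80L), 250L)
  centers <- chrom <- NULL
  if (n_pos > 0) {
    pick <- sample.int(nrow(dyads), n_pos, replace = TRUE)
    jit <- if (spec$jitter_sd > 0)
      round(stats::rnorm(n_pos, 0, spec$jitter_sd)) else 0
    centers <- dyads$pos[pick] + jit
    chrom <- dyads$chrom[pick]
  }
  if (n_bg > 0) {
    bg_chrom <- sample(chroms, n_bg, replace = TRUE)
    bg_center <- floor(stats::runif(n_bg, 130, spec$chrom_length - 130))
    centers <- c(centers, bg_center)
    chrom <- c(chrom, bg_chrom)
  }
  start <- centers - lens %/% 2L
  end <- start + lens
  ok <- start >= 0 & end <= spec$chrom_length
  frag <- data.frame(chrom = chrom[ok], start = start[ok], end = end[ok],
                     stringsAsFactors = FALSE)
  frags <- fragment_set(frag,
                        sample_id = paste0("sim_seed", spec$seed),
                        cell_type = "synthetic", treatment = "none")
  list(fragments = frags, assembly = assembly, tss = tss, dhs = dhs,
       dyads = dyads, expected_spacing = spec$spacing, spec = spec) |>
    structure(class = "synthetic_sample")
}

#' Generate a synthetic genome sequence for a simulated sample
#'
#' Random uniform A/C/G/T sequence; when the spec requests it, AA
#' dinucleotides are planted every 10 bp within each positioned
#' nucleosome's footprint (dyad +/- 73 bp), reproducing the rotational
#' dinucleotide periodicity of real nucleosomal DNA.
#'
#' @param sim a `synthetic_sample` from [simulate_sample()].
#' @param path output FASTA path.
#' @param plant overrides `spec$plant_dinucleotide` when not `NULL`.
#' @return `path`, invisibly. Deterministic given the sample's seed.
#' @export
write_synthetic_genome <- function(sim, path, plant = NULL) {
  spec <- sim$spec
  if (is.null(plant)) plant <- spec$plant_dinucleotide
  seqs <- withr::with_seed(spec$seed + 1L, {
    out <- lapply(sim$assembly$names, function(chrom) {
      s <- sample(c("A", "C", "G", "T"), spec$chrom_length, replace = TRUE)
      if (plant) {
        dp <- sim$dyads$pos[sim$dyads$chrom == chrom]
        for (p in dp) {
          at <- p - 73L + seq(0L, 140L, by = 10L)   # 10 bp phase
          at <- at[at >= 0 & at + 1 < spec$chrom_length]
          s[at + 1L] <- "A"; s[at + 2L] <- "A"
        }
      }
      paste(s, collapse = "")
    })
    names(out) <- sim$assembly$names
    out
  })
  dss <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Write a synthetic sample to disk
#'
#' Emits plain-text files: `fragments.bed`, `tss.bed` (BED6), `dhs.bed`,
#' `chrom.sizes`, `dyads.tsv` (truth table), `spec.json` (including the
#' seed) and, optionally, `genome.fa`.
#'
#' @param sim a `synthetic_sample`.
#' @param dir output directory (created if needed).
#' @param genome also write the synthetic genome FASTA.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sample_files <- function(sim, dir, genome = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fragments = file.path(dir, "fragments.bed"),
    tss = file.path(dir, "tss.bed"),
    dhs = file.path(dir, "dhs.bed"),
    sizes = file.path(dir, "chrom.sizes"),
    dyads = file.path(dir, "dyads.tsv"),
    spec = file.path(dir, "spec.json"))
  fr <- sim$fragments$fragments
  utils::write.table(fr, paths[["fragments"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$tss, paths[["tss"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$dhs, paths[["dhs"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(sim$assembly$names, unname(sim$assembly$lengths)),
    paths[["sizes"]], sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  utils::write.table(sim$dyads, paths[["dyads"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(sim$spec), paths[["spec"]],
                       auto_unbox = TRUE)
  if (genome) {
    paths <- c(paths, genome = file.path(dir, "genome.fa"))
    write_synthetic_genome(sim, paths[["genome"]])
  }
  invisible(paths)
}

#' Simulate a TF binding dataset with known coefficients
#'
#' Draws motif-hit sites uniformly over the genome, assigns motif scores
#' from a standard Normal, computes the nucleosome predictors on the
#' supplied tracks, and draws bound labels from the logistic model
#' `P(bound) = plogis(beta0 + beta . x)` using the *true* coefficients.
#' Peaks are written as bound hits extended 150 bp each side, so
#' hit/peak overlap reproduces the labels exactly.
#'
#' @param sim a `synthetic_sample` (provides assembly and seed).
#' @param occ,arr tracks built from the simulated sample.
#' @param n_sites number of motif hits.
#' @param beta named numeric vector of true coefficients for
#'   `motif_score`, `depletion`, `occupancy`, `array_up`, `array_down`
#'   (missing names default to 0).
#' @param beta0 intercept.
#' @param seed RNG seed (defaults to the sample's seed + 2).
#' @return A list: `hits` (data.frame with `motif_score`, predictors,
#'   `bound`), `peaks` (data.frame), `beta` and `beta0` truth.
#' @export
simulate_binding <- function(sim, occ, arr, n_sites = 2000L,
                             beta = c(motif_score = 1), beta0 = -0.5,
                             seed = NULL) {
  stopifnot(inherits(sim, "synthetic_sample"))
  if (is.null(seed)) seed <- sim$spec$seed + 2L
  full <- c(motif_score = 0, depletion = 0, occupancy = 0, array_up = 0,
            array_down = 0)
  full[names(beta)] <- beta
  withr::with_seed(seed, {
    chroms <- sim$assembly$names
    len <- sim$spec$chrom_length
    # hit centers at least 340 bp apart so a bound hit's +/-150 bp peak
    # can never touch a neighbouring hit: peak overlap then reproduces
    # the drawn labels exactly
    grid <- lapply(chroms, function(ch) {
      data.frame(chrom = ch,
                 center = seq(1100L, len - 1100L, by = 340L),
                 stringsAsFactors = FALSE)
    })
    grid <- do.call(rbind, grid)
    if (n_sites > nrow(grid)) {
      stop("n_sites exceeds the genome's hit capacity (", nrow(grid), ")")
    }
    pick <- grid[sample.int(nrow(grid), n_sites), ]
    chrom <- pick$chrom
    center <- pick$center
    hits <- data.frame(chrom = chrom, start = center - 10L,
                       end = center + 10L,
                       name = sprintf("hit%d", seq_len(n_sites)),
                       motif_score = stats::rnorm(n_sites),
                       strand = "+", stringsAsFactors = FALSE)
    hits$bound <- FALSE
    hits <- extract_predictors(hits, occ, arr)
    X <- as.matrix(hits[, names(full)])
    p <- stats::plogis(beta0 + drop(X %*% full))
    hits$bound <- stats::runif(nrow(hits)) < p
    peaks <- data.frame(chrom = hits$chrom[hits$bound],
                        start = hits$start[hits$bound] - 150L,
                        end = hits$end[hits$bound] + 150L,
                        stringsAsFactors = FALSE)
    list(hits = hits, peaks = peaks, beta = full, beta0 = beta0,
         seed = seed)
  })
}
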