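#' Configuration for the synthetic SNP-array cohort generator
#'
#' Collects every knob of the simulator in one validated object. The
#' defaults describe a down-scaled autosomal genome with array-like marker
#' density and the loss-dominated CNV landscape typical of SNP-array
#' surveys of livestock cohorts (roughly ten loss events per gain event at
#' the region level).
#'
#' @param seed integer seed; the generator is fully deterministic given it
#'   (R's default Mersenne-Twister RNG).
#' @param n_samples cohort size.
#' @param chr_lengths named vector of chromosome lengths in bp.
#' @param density marker density in markers per Mb.
#' @param cnv_rate expected CNVs per sample per Mb of genome.
#' @param len_range CNV length bounds in bp; lengths are log-uniform
#'   between them. Lower bound must be >= 1 kb.
#' @param loss_gain_odds odds of a CNV being a loss rather than a gain.
#' @param mu per-state LRR means for copy numbers 0..4. Diploid is 0 by
#'   construction.
#' @param lrr_sd Gaussian LRR noise SD.
#' @param baf_sd Gaussian BAF cluster SD.
#' @param baf_drift fraction of homozygous BAFs replaced by values in the
#'   artifact bands `[0.2, 0.25]` and `[0.75, 0.8]`.
#' @param waviness_amp,waviness_period amplitude and period (bp) of a
#'   sinusoidal long-range LRR wave; amplitude 0 disables it.
#' @param missing_rate fraction of genotype calls set to `"NC"`.
#' @param pfb_shape two Beta shape parameters for marker PFB values
#'   (clamped to `[0.01, 0.99]`).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 20L,
                       chr_lengths = setNames(rep(40e6, 6), as.character(1:6)),
                       density = 60,
                       cnv_rate = 0.05,
                       len_range = c(2e5, 1e6),
                       loss_gain_odds = 10,
                       mu = c(`0` = -3.5, `1` = -0.66, `2` = 0,
                              `3` = 0.40, `4` = 0.68),
                       lrr_sd = 0.2,
                       baf_sd = 0.03,
                       baf_drift = 0,
                       waviness_amp = 0,
                       waviness_period = 8e6,
                       missing_rate = 0.01,
                       pfb_shape = c(0.8, 0.8)) {
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              chr_lengths = chr_lengths, density = density,
              cnv_rate = cnv_rate, len_range = len_range,
              loss_gain_odds = loss_gain_odds, mu = mu, lrr_sd = lrr_sd,
              baf_sd = baf_sd, baf_drift = baf_drift,
              waviness_amp = waviness_amp, waviness_period = waviness_period,
              missing_rate = missing_rate, pfb_shape = pfb_shape)
  stopifnot(cfg$n_samples >= 1, all(cfg$chr_lengths > 0), cfg$density > 0,
            cfg$cnv_rate >= 0, cfg$loss_gain_odds > 0,
            length(cfg$mu) == 5, cfg$mu[["2"]] == 0,
            cfg$lrr_sd >= 0, cfg$baf_sd >= 0,
            cfg$baf_drift >= 0, cfg$baf_drift <= 1,
            cfg$missing_rate >= 0, cfg$missing_rate < 1)
  if (cfg$len_range[1] < 1e3)
    stop("CNV length lower bound must be at least 1 kb")
  if (is.null(names(cfg$chr_lengths)))
    names(cfg$chr_lengths) <- as.character(seq_along(cfg$chr_lengths))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a genome, marker map and ground-truth CNVs
#'
#' Markers are placed uniformly at random along each chromosome (then
#' sorted), PFB values are Beta-distributed and clamped to `[0.01, 0.99]`.
#' Each sample receives a Poisson number of CNVs (`cnv_rate` per Mb),
#' placed uniformly with log-uniform lengths; placements overlapping an
#' earlier CNV of the same sample are rejected so per-sample truth is
#' disjoint. Copy numbers: losses (odds `loss_gain_odds : 1`) are cn 1
#' (90%) or cn 0; gains are cn 3 (90%) or cn 4.
#'
#' @param config a [sim_config()].
#' @return list with `truth` (data.frame `sample`, `chr`, `start`, `end`,
#'   `cn`, `state`), `map` (a [marker_map()]) and `genome` (a
#'   [genome_build()]).
#' @export
simulate_truth <- function(config) {
  set.seed(config$seed)
  genome <- genome_build(config$chr_lengths)
  chrs <- names(genome$lengths)

  maps <- lapply(chrs, function(ch) {
    n <- max(2L, round(genome$lengths[[ch]] / 1e6 * config$density))
    pos <- sort(sample.int(genome$lengths[[ch]], n))
    data.frame(chr = ch, pos = pos)
  })
  mdf <- do.call(rbind, maps)
  pfb <- pmin(0.99, pmax(0.01, rbeta(nrow(mdf), config$pfb_shape[1],
                                     config$pfb_shape[2])))
  map <- marker_map(sprintf("snp%06d", seq_len(nrow(mdf))),
                    mdf$chr, mdf$pos, pfb)

  if (config$len_range[1] * config$density / 1e6 < 1)
    warning("marker density too low to cover the shortest CNV with >= 1 marker")

  genome_mb <- sum(genome$lengths) / 1e6
  p_loss <- config$loss_gain_odds / (config$loss_gain_odds + 1)
  rows <- list()
  for (s in seq_len(config$n_samples)) {
    sid <- sprintf("S%02d", s)
    n_cnv <- rpois(1, config$cnv_rate * genome_mb)
    placed <- data.frame(chr = character(), start = numeric(), end = numeric())
    k <- 0L; tries <- 0L
    while (k < n_cnv && tries < 50L * max(n_cnv, 1L)) {
      tries <- tries + 1L
      ch <- sample(chrs, 1, prob = genome$lengths)
      len <- round(exp(runif(1, log(config$len_range[1]),
                             log(config$len_range[2]))))
      if (len > genome$lengths[[ch]]) next
      st <- sample.int(genome$lengths[[ch]] - len + 1L, 1)
      en <- st + len - 1
      same <- placed[placed$chr == ch, , drop = FALSE]
      if (any(st <= same$end & same$start <= en)) next  # reject overlap
      is_loss <- runif(1) < p_loss
      cn <- if (is_loss) {
        if (runif(1) < 0.9) 1L else 0L
      } else {
        if (runif(1) < 0.9) 3L else 4L
      }
      placed <- rbind(placed, data.frame(chr = ch, start = st, end = en))
      rows[[length(rows) + 1L]] <-
        data.frame(sample = sid, chr = ch, start = st, end = en, cn = cn,
                   stringsAsFactors = FALSE)
      k <- k + 1L
    }
  }
  truth <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(sample = character(), chr = character(), start = numeric(),
               end = numeric(), cn = integer())
  if (nrow(truth) > 0) {
    truth$state <- ifelse(truth$cn < 2, "loss", "gain")
    truth <- truth[order(truth$sample, order_chr(truth$chr, truth$start)), ]
    rownames(truth) <- NULL
  } else truth$state <- character()
  list(truth = truth, map = map, genome = genome)
}

#' Simulate LRR/BAF/genotype signals for a cohort
#'
#' Every marker starts diploid; markers inside a sample's truth CNVs take
#' that CNV's copy number. LRR is Gaussian around the per-state mean
#' (`mu[cn]`, diploid 0) with optional sinusoidal waviness; BAF is drawn
#' from the genotype mixture implied by the marker PFB and the copy number
#' (cn 2 clusters near 0/0.5/1; cn 3 near 0/1/3/2/3/1; cn 1 near 0/1;
#' cn 0 is uniform), with half-Gaussian clusters at the 0 and 1 boundaries.
#' Genotypes are called only for diploid markers (`"NC"` inside CNVs).
#' An optional BAF-drift artifact replaces a configured fraction of
#' homozygous BAFs with values uniform in `[0.2, 0.25]` or `[0.75, 0.8]`.
#'
#' @param truth truth data.frame from [simulate_truth()].
#' @param map the matching [marker_map()].
#' @param config the same [sim_config()]; signal noise is seeded from
#'   `config$seed + 1` so signals are reproducible independently of truth
#'   generation.
#' @return a [signal_set()].
#' @export
simulate_signals <- function(truth, map, config) {
  set.seed(config$seed + 1L)
  n <- nrow(map)
  ids <- sprintf("S%02d", seq_len(config$n_samples))
  lrr <- matrix(NA_real_, n, length(ids), dimnames = list(NULL, ids))
  baf <- lrr
  gt <- matrix("NC", n, length(ids), dimnames = list(NULL, ids))
  mu <- config$mu

  for (j in seq_along(ids)) {
    cn <- rep(2L, n)
    tr <- truth[truth$sample == ids[j], , drop = FALSE]
    for (i in seq_len(nrow(tr))) {
      hit <- map$chr == tr$chr[i] & map$pos >= tr$start[i] & map$pos <= tr$end[i]
      cn[hit] <- tr$cn[i]
    }
    lrr[, j] <- mu[as.character(cn)] + rnorm(n, 0, config$lrr_sd)
    if (config$waviness_amp > 0) {
      phase <- runif(1, 0, 2 * pi)
      lrr[, j] <- lrr[, j] + config$waviness_amp *
        sin(2 * pi * map$pos / config$waviness_period + phase)
    }
    b <- rep(NA_integer_, n)
    pos_cn <- cn > 0
    b[pos_cn] <- rbinom(sum(pos_cn), cn[pos_cn], map$pfb[pos_cn])
    x <- numeric(n)
    x[!pos_cn] <- runif(sum(!pos_cn))                      # cn = 0: no signal
    lo <- pos_cn & b == 0
    hi <- pos_cn & b == cn
    mid <- pos_cn & !lo & !hi
    x[lo] <- abs(rnorm(sum(lo), 0, config$baf_sd))          # half-Gaussian at 0
    x[hi] <- 1 - abs(rnorm(sum(hi), 0, config$baf_sd))      # half-Gaussian at 1
    x[mid] <- b[mid] / cn[mid] + rnorm(sum(mid), 0, config$baf_sd)
    x <- pmin(1, pmax(0, x))
    if (config$baf_drift > 0) {
      hom <- which((lo | hi) & runif(n) < config$baf_drift)
      band <- runif(length(hom), 0.2, 0.25)
      flip <- runif(length(hom)) < 0.5
      x[hom] <- ifelse(flip, band, 1 - band)               # i.e. [0.75, 0.8]
    }
    baf[, j] <- x
    dip <- cn == 2L
    gt[dip, j] <- c("AA", "AB", "BB")[b[dip] + 1L]
    if (config$missing_rate > 0)
      gt[runif(n) < config$missing_rate, j] <- "NC"
  }
  signal_set(map, lrr, baf, gt)
}

#' Simulate CNVR tables for several studies with controlled overlap
#'
#' Builds `n_studies` study tables from a pool of candidate regions: each
#' study independently receives a fraction `overlap_fraction` of the shared
#' pool (boundaries jittered by up to `jitter` bp) plus `n_private`
#' regions of its own, placed so that private regions overlap nothing
#' else. The generator's bookkeeping (which pool region / private region
#' each record came from) is attached so that downstream comparison
#' operations can be validated against known labels.
#'
#' @param regions data.frame with columns `chr`, `start`, `end` (and
#'   optionally `state`): the shared candidate pool. Regions must be
#'   pairwise non-overlapping.
#' @param n_studies number of studies to fabricate.
#' @param overlap_fraction fraction of the shared pool each study receives,
#'   in `[0, 1]`.
#' @param seed RNG seed.
#' @param jitter maximal absolute boundary perturbation in bp.
#' @param n_private number of study-private regions per study.
#' @param genome a [genome_build()]; required when `n_private > 0`.
#' @param private_len length of private regions in bp.
#' @return list with `studies` (named list of study tables, see
#'   [read_study_table()]) and `truth` (data.frame `study`, `chr`, `start`,
#'   `end`, `origin` = "shared"/"private", `region_id`).
#' @export
simulate_study_tables <- function(regions, n_studies, overlap_fraction,
                                  seed = 1L, jitter = 0, n_private = 0L,
                                  genome = NULL, private_len = 2e5) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1, n_studies >= 1)
  set.seed(seed)
  regions <- as.data.frame(regions)
  regions$chr <- norm_chr(regions$chr)
  if ( !("state" %in% names(regions)) ) regions$state <- "loss"
  n_shared <- round(overlap_fraction * nrow(regions))

  if (n_private > 0 && is.null(genome))
    stop("a genome build is required to place private regions")

  # reserve disjoint slots for private regions, clear of the shared pool
  private_slots <- list()
  if (n_private > 0) {
    need <- n_private * n_studies
    occupied <- regions[, c("chr", "start", "end")]
    tries <- 0L
    while (length(private_slots) < need && tries < 200L * need) {
      tries <- tries + 1L
      ch <- sample(names(genome$lengths), 1, prob = genome$lengths)
      if (genome$lengths[[ch]] <= private_len) next
      st <- sample.int(genome$lengths[[ch]] - private_len, 1)
      en <- st + private_len - 1
      if (any(occupied$chr == ch & st <= occupied$end & occupied$start <= en))
        next
      occupied <- rbind(occupied, data.frame(chr = ch, start = st, end = en))
      private_slots[[length(private_slots) + 1L]] <-
        data.frame(chr = ch, start = st, end = en)
    }
    if (length(private_slots) < need)
      stop("could not place the requested private regions disjointly")
  }

  studies <- list(); truth <- list()
  slot <- 0L
  for (k in seq_len(n_studies)) {
    lab <- sprintf("study%02d", k)
    pick <- if (n_shared > 0) sort(sample.int(nrow(regions), n_shared)) else integer()
    shared <- regions[pick, , drop = FALSE]
    if (nrow(shared) > 0 && jitter > 0) {
      shared$start <- pmax(1, shared$start +
                             round(runif(nrow(shared), -jitter, jitter)))
      shared$end <- pmax(shared$start, shared$end +
                           round(runif(nrow(shared), -jitter, jitter)))
    }
    rows <- data.frame(study = rep(lab, nrow(shared)), chr = shared$chr,
                       start = shared$start, end = shared$end,
                       state = shared$state,
                       origin = rep("shared", nrow(shared)),
                       region_id = sprintf("pool%d", pick),
                       stringsAsFactors = FALSE)
    for (p in seq_len(n_private)) {
      slot <- slot + 1L
      pr <- private_slots[[slot]]
      rows <- rbind(rows, data.frame(
        study = lab, chr = pr$chr, start = pr$start, end = pr$end,
        state = "loss", origin = "private",
        region_id = sprintf("%s_priv%d", lab, p)))
    }
    rows <- rows[order_chr(rows$chr, rows$start), , drop = FALSE]
    rownames(rows) <- NULL
    studies[[lab]] <- rows[, c("study", "chr", "start", "end", "state")]
    truth[[lab]] <- rows
  }
  list(studies = studies, truth = do.call(rbind, truth))
}
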