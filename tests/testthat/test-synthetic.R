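cfg_small <- function(...) {
  defaults <- list(seed = 101, n_samples = 4,
                   chr_lengths = setNames(c(20e6, 15e6), c("1", "2")),
                   density = 50, cnv_rate = 0.1)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("truth generation is deterministic and respects its configuration", {
  cfg <- cfg_small()
  a <- simulate_truth(cfg)
  b <- simulate_truth(cfg)
  expect_identical(a, b)

  # zero rate -> zero CNVs
  z <- simulate_truth(cfg_small(cnv_rate = 0))
  expect_equal(nrow(z$truth), 0)

  # lengths inside bounds, per-sample truth disjoint, cn never 2
  tr <- a$truth
  expect_true(all(tr$end - tr$start + 1 >= cfg$len_range[1]))
  expect_true(all(tr$end - tr$start + 1 <= cfg$len_range[2] + 1))
  expect_true(all(tr$cn != 2))
  for (s in unique(tr$sample)) for (ch in unique(tr$chr)) {
    x <- tr[tr$sample == s & tr$chr == ch, ]
    if (nrow(x) > 1) {
      x <- x[order(x$start), ]
      expect_true(all(x$start[-1] > x$end[-nrow(x)]))
    }
  }
  # marker map invariants hold by construction
  expect_s3_class(a$map, "marker_map")
  expect_true(all(a$map$pfb >= 0.01 & a$map$pfb <= 0.99))
})

test_that("loss fraction tracks the configured loss:gain odds", {
  cfg <- sim_config(seed = 31, n_samples = 25,
                    chr_lengths = setNames(rep(50e6, 4), 1:4),
                    density = 15, cnv_rate = 0.4, loss_gain_odds = 10)
  tr <- simulate_truth(cfg)$truth
  expect_gt(nrow(tr), 1500)
  n_loss <- sum(tr$state == "loss")
  ci <- qbinom(c(0.005, 0.995), nrow(tr), 10 / 11)
  expect_gte(n_loss, ci[1])
  expect_lte(n_loss, ci[2])
})

test_that("noise-free signals collapse onto the genotype clusters", {
  cfg <- cfg_small(lrr_sd = 0, baf_sd = 0, cnv_rate = 0, missing_rate = 0)
  sim <- simulate_truth(cfg)
  sig <- simulate_signals(sim$truth, sim$map, cfg)
  expect_true(all(sig$lrr == 0))
  expect_true(all(sig$baf %in% c(0, 0.5, 1)))
  expect_true(all(sig$gtype %in% c("AA", "AB", "BB")))

  # a hemizygous (cn=1) segment has no heterozygote cluster
  cfg1 <- cfg_small(lrr_sd = 0, baf_sd = 0, missing_rate = 0)
  sim1 <- simulate_truth(cfg1)
  tr <- sim1$truth[sim1$truth$cn == 1, ][1, ]
  sig1 <- simulate_signals(sim1$truth, sim1$map, cfg1)
  inside <- sim1$map$chr == tr$chr & sim1$map$pos >= tr$start &
    sim1$map$pos <= tr$end
  expect_true(any(inside))
  expect_true(all(sig1$lrr[inside, tr$sample] == cfg1$mu[["1"]]))
  expect_true(all(sig1$baf[inside, tr$sample] %in% c(0, 1)))
})

test_that("signal moments match the configured noise model", {
  cfg <- sim_config(seed = 5, n_samples = 1,
                    chr_lengths = c(`1` = 50e6), density = 220,
                    cnv_rate = 0, lrr_sd = 0.17, missing_rate = 0)
  sim <- simulate_truth(cfg)
  expect_gt(nrow(sim$map), 1e4)
  sig <- simulate_signals(sim$truth, sim$map, cfg)
  expect_equal(sd(sig$lrr[, 1]), 0.17, tolerance = 0.05)  # within 5%
  expect_equal(mean(sig$lrr[, 1]), 0, tolerance = 3 * 0.17 / sqrt(nrow(sim$map)))
})

test_that("per-state LRR means converge to the configured mu", {
  cfg <- sim_config(seed = 17, n_samples = 6,
                    chr_lengths = setNames(rep(40e6, 3), 1:3), density = 80,
                    cnv_rate = 0.15, lrr_sd = 0.2, missing_rate = 0)
  sim <- simulate_truth(cfg)
  sig <- simulate_signals(sim$truth, sim$map, cfg)
  for (state in c(1L, 3L)) {
    vals <- c()
    for (i in which(sim$truth$cn == state)) {
      tr <- sim$truth[i, ]
      inside <- sim$map$chr == tr$chr & sim$map$pos >= tr$start &
        sim$map$pos <= tr$end
      vals <- c(vals, sig$lrr[inside, tr$sample])
    }
    expect_gt(length(vals), 50)
    expect_equal(mean(vals), unname(cfg$mu[as.character(state)]),
                 tolerance = 3 * cfg$lrr_sd / sqrt(length(vals)))
  }
})

test_that("BAF drift and waviness artifacts appear at the configured level", {
  cfg <- sim_config(seed = 23, n_samples = 2, chr_lengths = c(`1` = 40e6),
                    density = 150, cnv_rate = 0, baf_drift = 0.05,
                    waviness_amp = 0.2, waviness_period = 5e6,
                    missing_rate = 0)
  sim <- simulate_truth(cfg)
  sig <- simulate_signals(sim$truth, sim$map, cfg)
  qc <- sample_qc(sig)
  expect_true(all(qc$baf_drift > 0.01))   # artifact detected by the QC metric
  expect_true(all(qc$waviness > 0.05))
  expect_false(any(qc$pass))
})

test_that("study table fabrication honours overlap_fraction and bookkeeping", {
  set.seed(2)
  start <- seq(1e5, 9e6, by = 1e6)
  pool <- data.frame(chr = "1", start = start, end = start + 2e5 - 1)
  gb <- genome_build(c(`1` = 50e6))

  all_shared <- simulate_study_tables(pool, 3, overlap_fraction = 1,
                                      seed = 9, jitter = 0)
  expect_identical(all_shared$studies[[1]][, -1],
                   all_shared$studies[[2]][, -1])
  expect_identical(all_shared$studies[[2]][, -1],
                   all_shared$studies[[3]][, -1])

  none <- simulate_study_tables(pool, 3, overlap_fraction = 0, seed = 9,
                                n_private = 4, genome = gb)
  for (i in 1:2) for (j in (i + 1):3) {
    a <- none$studies[[i]]; b <- none$studies[[j]]
    expect_equal(sum(oracle_overlaps_any(a, b)), 0)
  }
  expect_true(all(none$truth$origin == "private"))

  # deterministic under the seed
  again <- simulate_study_tables(pool, 3, overlap_fraction = 0, seed = 9,
                                 n_private = 4, genome = gb)
  expect_identical(none, again)
})
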