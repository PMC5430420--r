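test_that("clean constant signals yield zero metrics and a pass", {
  sig <- toy_signal_set(n = 100)
  qc <- sample_qc(sig)
  expect_equal(qc$sd_lrr, c(0, 0))
  expect_equal(qc$baf_drift, c(0, 0))
  expect_equal(qc$waviness, c(0, 0))
  expect_equal(qc$call_rate, c(1, 1))
  expect_true(all(qc$pass))
})

test_that("BAF drift counts the artifact bands and gates at 1%", {
  sig <- toy_signal_set(n = 100, samples = "A")
  sig$baf[c(10, 20), 1] <- 0.22
  qc <- sample_qc(sig)
  expect_equal(qc$baf_drift, 0.02)
  expect_false(qc$pass)           # 0.02 >= 0.01
})

test_that("sd_lrr recovers the LRR noise scale and gates at 0.30", {
  set.seed(8)
  sig_ok <- toy_signal_set(n = 1000, samples = "A")
  x <- rnorm(1000, 0, 0.25)
  sig_ok$lrr[, 1] <- x
  qc_ok <- sample_qc(sig_ok)
  # independent two-pass formula for the SD
  manual <- sqrt(sum((x - sum(x) / 1000)^2) / 999)
  expect_equal(qc_ok$sd_lrr, manual, tolerance = 1e-12)
  expect_equal(qc_ok$sd_lrr, 0.25, tolerance = 0.03)
  expect_true(qc_ok$pass)

  sig_bad <- toy_signal_set(n = 1000, samples = "A")
  sig_bad$lrr[, 1] <- rnorm(1000, 0, 0.35)
  expect_false(sample_qc(sig_bad)$pass)
})

test_that("sample QC errors with fewer than two informative markers", {
  sig <- toy_signal_set(n = 10, samples = "A")
  sig$lrr[2:10, 1] <- NA
  expect_error(sample_qc(sig), "fewer than 2")
})

test_that("marker QC applies the missingness, MAF and HWE filters", {
  # exact HW proportions: chi-square 0, P 1
  g <- matrix(rep(c("AA", "AB", "BB"), times = c(25, 50, 25)), ncol = 100)
  qc <- marker_qc(g)
  expect_equal(qc$hwe_p, 1)
  expect_true(qc$pass)

  # 11% missing fails; 10% passes (threshold is "> 10%")
  g2 <- rbind(rep(c("AB", "NC"), times = c(89, 11)),
              rep(c("AB", "NC"), times = c(90, 10)))
  qc2 <- marker_qc(g2)
  expect_false(qc2$pass[1])
  # row 2 would fail HWE (all het) but not missingness
  expect_lte(qc2$missing[2], 0.10)

  # MAF gate
  g3 <- matrix(rep(c("AA", "AB"), times = c(96, 4)), ncol = 100)
  expect_lt(marker_qc(g3)$maf, 0.05)
  expect_false(marker_qc(g3)$pass)

  # monomorphic marker: HWE P defined as 1
  g4 <- matrix("AA", 1, 50)
  expect_equal(marker_qc(g4)$hwe_p, 1)
})

test_that("chi-square HWE P agrees with the exact conditional test", {
  qc <- marker_qc(matrix(rep(c("AA", "AB", "BB"), times = c(40, 20, 40)),
                         ncol = 100))
  exact <- oracle_hwe_exact(40, 20, 40)
  # asymptotic vs exact: same order of magnitude
  expect_lt(abs(log10(qc$hwe_p) - log10(exact)), 1)
})

test_that("PFB is the clamped mean BAF across the cohort", {
  map <- marker_map(c("a", "b", "c"), c(1, 1, 1), c(10, 20, 30))
  baf <- matrix(c(0, 0, 0,
                  1, 0, NA,
                  1, 0, NA), nrow = 3,
                dimnames = list(NULL, c("s1", "s2", "s3")))
  # marker a: {0,1,1} -> 2/3; marker b: {0,0,0} -> clamped 0.01; c: {0,NA,NA} -> 0.01
  sig <- signal_set(map, matrix(0, 3, 3), baf)
  pfb <- compute_pfb(sig)
  expect_equal(pfb$pfb, c(2 / 3, 0.01, 0.01))

  # {0, 1} -> 0.5, and an all-missing marker warns and gets 0.5
  baf2 <- matrix(c(0, NA, 1, NA), 2, 2, dimnames = list(NULL, c("x", "y")))
  sig2 <- signal_set(marker_map(c("a", "b"), c(1, 1), c(1, 2)),
                     matrix(0, 2, 2), baf2)
  expect_warning(pfb2 <- compute_pfb(sig2), "0.5")
  expect_equal(pfb2$pfb, c(0.5, 0.5))

  # random BAFs: PFB equals the arithmetic mean, independently computed
  set.seed(3)
  b <- matrix(runif(50), 1)
  colnames(b) <- paste0("s", 1:50)
  sig3 <- signal_set(marker_map("m", "1", 1), matrix(0, 1, 50), b)
  expect_equal(compute_pfb(sig3)$pfb, sum(b) / 50, tolerance = 1e-12)
})

test_that("QC filters are idempotent and order-invariant where claimed", {
  set.seed(12)
  g <- matrix(sample(c("AA", "AB", "BB", "NC"), 50 * 40, TRUE,
                     prob = c(0.3, 0.4, 0.25, 0.05)), nrow = 50)
  qc1 <- marker_qc(g)
  # marker pass/fail invariant under sample reordering
  qc_perm <- marker_qc(g[, sample(ncol(g))])
  expect_identical(qc1$pass, qc_perm$pass)
  # idempotence: re-running on the passing subset flags nothing new,
  # modulo the Bonferroni denominator, which is held at the original count
  keep <- which(qc1$pass)
  qc2 <- marker_qc(g[keep, , drop = FALSE], hwe_alpha = 1e-5)
  expect_true(all(qc2$missing <= 0.10 & qc2$maf >= 0.05))

  # sample QC: sd_lrr and baf_drift invariant under within-chromosome
  # marker shuffling; waviness is genuinely position-dependent
  cfg <- sim_config(seed = 77, n_samples = 2, chr_lengths = c(`1` = 30e6),
                    density = 60, cnv_rate = 0, waviness_amp = 0.15,
                    waviness_period = 4e6)
  sim <- simulate_truth(cfg)
  sig <- simulate_signals(sim$truth, sim$map, cfg)
  qc_a <- sample_qc(sig)
  perm <- sample(nrow(sig$map))
  sig_p <- sig
  sig_p$lrr <- sig$lrr[perm, , drop = FALSE]
  sig_p$baf <- sig$baf[perm, , drop = FALSE]
  sig_p$gtype <- sig$gtype[perm, , drop = FALSE]
  qc_b <- sample_qc(sig_p)     # markers now sit at the wrong positions
  expect_equal(qc_b$sd_lrr, qc_a$sd_lrr)
  expect_equal(qc_b$baf_drift, qc_a$baf_drift)
  expect_false(isTRUE(all.equal(qc_b$waviness, qc_a$waviness)))
})
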