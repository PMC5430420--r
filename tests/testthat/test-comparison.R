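reg <- function(chr, start, end)
  data.frame(chr = as.character(chr), start = start, end = end,
             stringsAsFactors = FALSE)

test_that("novelty classification follows the 1-bp overlap rule", {
  q <- reg(1, c(100, 1000), c(200, 2000))
  refs <- list(a = reg(1, 200, 500))      # touches the first query at one bp
  res <- classify_novelty(q, refs)
  expect_equal(res$known, c(TRUE, FALSE))
  expect_equal(res$n_known, 1)
  expect_equal(res$n_novel, 1)
  expect_equal(unname(res$per_study), 1L)

  # empty reference set: everything is novel
  res0 <- classify_novelty(q, list(a = reg(character(), numeric(), numeric())))
  expect_equal(res0$n_novel, 2)
})

test_that("per-study overlap counts match an all-pairs scan on random sets", {
  set.seed(33)
  for (rep in 1:10) {
    q <- random_intervals(20, 1e6, min_len = 100, max_len = 5e4)
    refs <- list(r1 = random_intervals(15, 1e6, 100, 5e4),
                 r2 = random_intervals(25, 1e6, 100, 5e4))
    res <- classify_novelty(q, refs)
    expect_equal(res$known,
                 oracle_overlaps_any(q, refs$r1) | oracle_overlaps_any(q, refs$r2))
    expect_equal(unname(res$per_study),
                 c(sum(oracle_overlaps_any(q, refs$r1)),
                   sum(oracle_overlaps_any(q, refs$r2))))
  }
})

test_that("composite construction merges across studies and fills presence", {
  two_same <- list(a = reg(1, 100, 200), b = reg(1, 150, 250))
  res <- build_composite(two_same)
  expect_equal(nrow(res$composite), 1)
  expect_true(all(res$presence == 1))

  disjoint <- list(a = reg(1, c(100, 1000), c(200, 1100)),
                   b = reg(2, 100, 200))
  res2 <- build_composite(disjoint)
  expect_equal(nrow(res2$composite), 3)
  expect_equal(sum(res2$presence), 3)   # block indicator: one study per region
  expect_equal(unname(rowSums(res2$presence)), c(2, 1))

  # composite independent of dataset order
  res3 <- build_composite(rev(disjoint))
  expect_equal(res3$composite, res2$composite)
})

test_that("fabricated studies recover shared-region bookkeeping at jitter 0", {
  start <- seq(1e5, 2e7, by = 1e6)
  pool <- data.frame(chr = "1", start = start, end = start + 3e5 - 1)
  gb <- genome_build(c(`1` = 60e6))
  fab <- simulate_study_tables(pool, 3, overlap_fraction = 0.6, seed = 44,
                               jitter = 0, n_private = 3, genome = gb)
  comp <- build_composite(fab$studies)
  used <- unique(fab$truth$region_id[fab$truth$origin == "shared"])
  n_private <- sum(fab$truth$origin == "private")
  expect_equal(nrow(comp$composite), length(used) + n_private)

  # query-study novelty equals the generator's shared/private labels
  q <- fab$studies[[1]]
  res <- classify_novelty(q, fab$studies[-1])
  t1 <- fab$truth[fab$truth$study == "study01", ]
  others <- fab$truth[fab$truth$study != "study01" &
                        fab$truth$origin == "shared", "region_id"]
  expected_known <- t1$origin == "shared" & t1$region_id %in% others
  expect_equal(res$known, expected_known)
})

test_that("ordination separates complementary studies and collapses identical ones", {
  pres <- rbind(a = c(1, 1, 1, 0, 0, 0), b = c(0, 0, 0, 1, 1, 1))
  ord <- ordinate(pres)
  expect_equal(sign(ord$scores["a", 1]) * sign(ord$scores["b", 1]), -1)

  pres2 <- rbind(a = c(1, 0, 1, 0), b = c(1, 0, 1, 0), c = c(0, 1, 0, 1))
  ord2 <- ordinate(pres2)
  expect_equal(as.matrix(ord2$dist)["a", "b"], 0)
  expect_equal(min(ord2$hclust$height), 0)
  # the Newick export parses back to a 3-tip tree
  tree <- ape::read.tree(text = ord2$newick)
  expect_equal(sort(tree$tip.label), c("a", "b", "c"))

  expect_error(ordinate(matrix(1, 3, 4)), "zero variance")
})

test_that("PC scores match a brute-force covariance eigen-solve", {
  set.seed(51)
  pres <- matrix(rbinom(5 * 20, 1, 0.4), 5, 20,
                 dimnames = list(paste0("st", 1:5), NULL))
  ord <- ordinate(pres)
  xc <- pres - rowMeans(pres)
  ev <- eigen(xc %*% t(xc), symmetric = TRUE)
  k <- ncol(ord$scores)
  for (j in seq_len(k)) {
    oracle <- ev$vectors[, j] * sqrt(ev$values[j])
    # eigenvectors are defined up to sign
    expect_lt(min(max(abs(ord$scores[, j] - oracle)),
                  max(abs(ord$scores[, j] + oracle))), 1e-8)
  }
  # cophenetic distances respect the merge heights (ultrametric tree)
  coph <- as.matrix(stats::cophenetic(ord$hclust))
  expect_gte(min(coph[upper.tri(coph)]), min(ord$hclust$height) - 1e-12)
})

test_that("breed-specific regions honour the 100-kb filter and privacy", {
  a <- reg(1, c(1e6, 5e6), c(1e6 + 15e4 - 1, 5e6 + 9e4 - 1))  # 150 kb + 90 kb
  b <- reg(1, 8e6, 8e6 + 2e5 - 1)
  res <- breed_specific(list(A = a, B = b))
  # the 150-kb region is specific to A; the 90-kb one was filtered out
  expect_equal(res$n_specific[["A"]], 1)
  expect_equal(res$specific$A$start, 1e6)
  expect_equal(res$n_specific[["B"]], 1)

  # a region shared by both breeds is specific to neither
  shared <- reg(1, 2e6, 2e6 + 3e5)
  res2 <- breed_specific(list(A = rbind(a, shared), B = rbind(b, shared)))
  expect_equal(unname(res2$n_specific), c(1L, 1L))
  expect_true(any(grepl("\\+", res2$membership$pattern)))
})

test_that("Venn counts equal exhaustive membership enumeration on 4 breeds", {
  set.seed(61)
  for (rep in 1:5) {
    breeds <- lapply(1:4, function(i)
      random_intervals(50, 1e6, min_len = 800, max_len = 4e4))
    names(breeds) <- paste0("b", 1:4)
    res <- breed_specific(breeds, min_len = 1000)
    # oracle: merge each breed by brute force, then all-pairs privacy scan
    merged <- lapply(breeds, function(d) {
      d <- d[(d$end - d$start + 1) >= 1000, ]
      oracle_single_linkage(d)
    })
    for (nm in names(breeds)) {
      other <- do.call(rbind, merged[setdiff(names(breeds), nm)])
      expect_equal(res$n_specific[[nm]],
                   sum(!oracle_overlaps_any(merged[[nm]], other)))
    }
  }
})
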