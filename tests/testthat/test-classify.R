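test_that("isolation flag matches the pairwise brute-force rule", {
  expect_true(flag_isolated(make_loci(100, 172))[[1]])
  # 1499 bp gap: both fail the 1.5 kb rule; 1500 bp: both pass
  two <- make_loci(c(0, 1571), c(72, 1643))
  expect_equal(unname(flag_isolated(two)), c(FALSE, FALSE))
  two_ok <- make_loci(c(0, 1572), c(72, 1644))
  expect_equal(unname(flag_isolated(two_ok)), c(TRUE, TRUE))

  set.seed(21)
  for (trial in 1:20) {
    n <- 50
    s <- sort(sample(0:1e5, n))
    loci <- make_loci(s, s + sample(50:300, n, replace = TRUE),
                      chrom = sample(c("chr1", "chr2"), n, replace = TRUE))
    got <- flag_isolated(loci, min_gap = 1500)
    # O(n^2) oracle
    want <- vapply(seq_len(n), function(i) {
      d <- Inf
      for (j in seq_len(n)[-i]) {
        if (loci$chrom[i] != loci$chrom[j]) next
        d <- min(d, max(loci$start[i] - loci$end[j],
                        loci$start[j] - loci$end[i]))
      }
      d >= 1500
    }, logical(1))
    expect_equal(unname(got), want)
  }
})

test_that("Pol II proximity flag is boundary-inclusive and matches brute force", {
  l <- make_loci(10000, 10072)
  p <- data.frame(chrom = "chr1", pos = 10072 - 1 + 2650, type = "TSS",
                  stringsAsFactors = FALSE)
  expect_true(flag_near_pol2(l, p)[[1]])
  p$pos <- p$pos + 1
  expect_false(flag_near_pol2(l, p)[[1]])
  expect_false(flag_near_pol2(l, p[0, ])[[1]])

  set.seed(22)
  for (trial in 1:20) {
    n <- 30
    s <- sample(0:5e4, n)
    loci <- make_loci(s, s + 72,
                      chrom = sample(c("chr1", "chr2"), n, replace = TRUE))
    pol2 <- data.frame(chrom = sample(c("chr1", "chr2"), 8, replace = TRUE),
                       pos = sample(0:5e4, 8),
                       type = sample(c("TSS", "polyA"), 8, replace = TRUE),
                       stringsAsFactors = FALSE)
    got <- flag_near_pol2(loci, pol2, max_dist = 2650)
    want <- vapply(seq_len(n), function(i) {
      d <- Inf
      for (j in seq_len(nrow(pol2))) {
        if (pol2$chrom[j] != loci$chrom[i]) next
        d <- min(d, max(loci$start[i] - pol2$pos[j],
                        pol2$pos[j] - (loci$end[i] - 1), 0))
      }
      d <= 2650
    }, logical(1))
    expect_equal(unname(got), want)
  }
})

test_that("CpG flag tests overlap with the 1 kb TSS window", {
  l <- make_loci(5000, 5072)  # tss 5000
  isl <- data.frame(chrom = "chr1", start = 5999, end = 6100)
  expect_true(flag_cpg(l, isl)[[1]])       # island at distance 999
  isl2 <- data.frame(chrom = "chr1", start = 6000, end = 6100)
  expect_false(flag_cpg(l, isl2)[[1]])     # window is half-open at +1000
  expect_false(flag_cpg(l, isl[0, ])[[1]])

  set.seed(23)
  for (trial in 1:20) {
    n <- 25
    s <- sample(2000:5e4, n)
    loci <- make_loci(s, s + 72, strand = sample(c("+", "-"), n, TRUE))
    cpg <- data.frame(chrom = "chr1", start = sample(0:5e4, 10))
    cpg$end <- cpg$start + sample(200:800, 10, replace = TRUE)
    got <- flag_cpg(loci, cpg)
    want <- vapply(seq_len(n), function(i) {
      w0 <- loci$tss[i] - 1000; w1 <- loci$tss[i] + 1000
      any(cpg$start < w1 & cpg$end > w0)
    }, logical(1))
    expect_equal(unname(got), want)
  }
})

test_that("peak-presence groups partition the loci", {
  set.seed(31)
  sc <- matrix(rnorm(60, 1, 1.5), 20, 3,
               dimnames = list(NULL, c("RPC4_r1", "H3_r2", "RPB2_r1")))
  st <- make_score_table(sc, thresholds = 1,
                         factors = c("RPC4", "H3K4me3", "RPB2"))
  map <- c(RPC4 = "RPC4_r1", H3K4me3 = "H3_r2", RPB2 = "RPB2_r1")
  g <- assign_groups(st, map)
  expect_equal(length(g), 20)
  expect_false(any(is.na(g)))            # every locus in exactly one group
  # direct recomputation of membership
  want_rpc4 <- grepl("RPC4", as.character(g))
  expect_equal(want_rpc4, unname(sc[, "RPC4_r1"] > 1))

  # all below threshold -> everything in the "none" group
  st0 <- make_score_table(sc, thresholds = 99,
                          factors = c("RPC4", "H3K4me3", "RPB2"))
  expect_true(all(assign_groups(st0, map) == "none"))

  expect_error(assign_groups(st, c(RPC4 = "nope")), "not in score table")

  summ <- peak_group_summary(st, list(rep1 = map))
  tot <- tapply(summ$count_rep1, summ$locus_type, sum)
  expect_equal(unname(tot["tRNA"]), 20)
  pct <- tapply(summ$pct_rep1, summ$locus_type, sum)
  expect_equal(unname(pct["tRNA"]), 100, tolerance = 0.1)
})

test_that("permutation t test matches exhaustive enumeration on tiny input", {
  x <- c(1.0, 2.0, 4.0); y <- c(0.5, 3.5)
  welch <- function(a, b)
    (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  z <- c(x, y)
  splits <- combn(5, 3)
  tstats <- apply(splits, 2, function(i) welch(z[i], z[-i]))
  p_exact <- mean(abs(tstats) >= abs(welch(x, y)))
  got <- permutation_t_test(x, y, n_perm = 20000, seed = 4)
  expect_equal(got$p_value, p_exact, tolerance = 0.05)
  expect_equal(got$statistic, welch(x, y))

  # identical sets: p near 1
  set.seed(9)
  v <- rnorm(8)
  same <- permutation_t_test(v, sample(v), n_perm = 2000, seed = 5)
  expect_gt(same$p_value, 0.5)

  expect_warning(p0 <- permutation_t_test(c(1, 1), c(1, 1)), "zero variance")
  expect_equal(p0$p_value, 1)
})

test_that("permutation t test keeps its type-I error near nominal", {
  set.seed(77)
  rej <- 0; trials <- 200
  for (i in seq_len(trials)) {
    p <- permutation_t_test(rnorm(10), rnorm(12), n_perm = 199,
                            seed = i)$p_value
    if (p < 0.05) rej <- rej + 1
  }
  se3 <- 3 * sqrt(0.05 * 0.95 / trials)
  expect_lt(rej / trials, 0.05 + se3)
})
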