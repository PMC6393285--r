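# brute-force maximal-chain oracle for cluster calling
brute_clusters <- function(loci, max_gap = 5000, min_size = 3) {
  out <- list()
  for (ch in sort(unique(loci$chrom))) {
    l <- loci[loci$chrom == ch, ]
    l <- l[order(l$start), ]
    if (nrow(l) == 0) next
    chain <- list(l$locus_id[1])
    for (i in seq_len(nrow(l))[-1]) {
      if (l$start[i] - l$end[i - 1] < max_gap)
        chain[[length(chain)]] <- c(chain[[length(chain)]], l$locus_id[i])
      else chain[[length(chain) + 1]] <- l$locus_id[i]
    }
    out <- c(out, chain[lengths(chain) >= min_size])
  }
  out
}

test_that("cluster calling chains genes under the 5 kb gap rule", {
  # three genes, 4 kb gaps -> one cluster of three
  l <- make_loci(c(0, 4072, 8144), c(72, 4144, 8216))
  cl <- call_clusters(l)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_genes, 3)
  expect_equal(cl$members, "L001,L002,L003")

  # gaps 4 kb, 6 kb, 4 kb -> longest chain has 2 genes, no cluster
  s <- c(0, 4072, 10144, 14216)
  l2 <- make_loci(s, s + 72)
  expect_equal(nrow(call_clusters(l2)), 0)

  # boundary: a gap of exactly 5000 breaks the chain
  s3 <- c(0, 5072, 10144)
  l3 <- make_loci(s3, s3 + 72)  # gaps exactly 5000
  expect_equal(nrow(call_clusters(l3)), 0)
  l4 <- make_loci(c(0, 5071, 10142), c(72, 5143, 10214))  # gaps 4999
  expect_equal(nrow(call_clusters(l4)), 1)
})

test_that("cluster calling matches the brute-force oracle and is stable", {
  set.seed(41)
  for (trial in 1:30) {
    n <- sample(5:25, 1)
    s <- sort(sample(seq(0, 2e5, by = 100), n))
    loci <- make_loci(s, s + 72,
                      chrom = sort(sample(c("chr1", "chr2"), n,
                                          replace = TRUE)))
    got <- call_clusters(loci)
    want <- brute_clusters(loci)
    expect_equal(nrow(got), length(want))
    if (nrow(got))
      expect_equal(strsplit(got$members, ","), unname(want))
    # input order invariance
    got2 <- call_clusters(loci[sample(n), ])
    expect_equal(got, got2)
  }
})

test_that("clusters are disjoint and separated by at least the gap limit", {
  set.seed(43)
  s <- sort(sample(seq(0, 3e5, by = 50), 60))
  loci <- make_loci(s, s + 72)
  cl <- call_clusters(loci)
  if (nrow(cl) > 1) {
    expect_true(all(cl$start[-1] - cl$end[-nrow(cl)] >= 5000))
  }
  ids <- unlist(strsplit(cl$members, ","))
  expect_equal(anyDuplicated(ids), 0)
})

test_that("in- versus out-of-cluster KS tests flag shifted clusters", {
  l <- make_loci(c(seq(0, by = 2000, length.out = 4),
                   seq(50000, by = 8000, length.out = 6)),
                 c(seq(72, by = 2000, length.out = 4),
                   seq(50072, by = 8000, length.out = 6)))
  cl <- call_clusters(l)
  expect_equal(nrow(cl), 1)

  # identical values inside and out -> D = 0, p = 1
  fc0 <- setNames(rep(c(1, 2), 5), l$locus_id)
  r0 <- cluster_ks_tests(fc0, cl, l)
  expect_equal(r0$D, 0)
  expect_equal(r0$p_value, 1)

  # strong shift -> D = 1 and a flagged cluster
  fc1 <- setNames(c(rep(5, 4), rep(0.1, 6)) + rnorm(10, 0, 0.01),
                  l$locus_id)
  r1 <- cluster_ks_tests(fc1, cl, l)
  expect_equal(r1$D, 1)
  expect_true(r1$flagged)
})

test_that("KS test type-I error is near nominal under the null", {
  set.seed(45)
  rej <- 0; trials <- 300
  for (i in seq_len(trials)) {
    p <- suppressWarnings(ks.test(rnorm(50), rnorm(50),
                                  exact = FALSE))$p.value
    if (p < 0.05) rej <- rej + 1
  }
  expect_lt(rej / trials, 0.05 + 3 * sqrt(0.05 * 0.95 / trials))
})

test_that("chromosome chi-square matches direct computation", {
  # perfectly proportional table -> zero statistic
  status <- setNames(rep(c("changing", "stable"), c(4, 4)), paste0("L", 1:8))
  chrom <- setNames(rep(c("chr1", "chr2"), 4), paste0("L", 1:8))
  r <- chromosome_chisq(status, chrom)
  expect_equal(r$chi2, 0)
  expect_equal(r$p_value, 1)

  # printed 2x2 toy table, brute-force sum((O-E)^2/E)
  status2 <- setNames(rep(c("changing", "stable", "changing", "stable"),
                          c(10, 90, 50, 50)), paste0("g", 1:200))
  chrom2 <- setNames(rep(c("chrA", "chrB"), c(100, 100)), paste0("g", 1:200))
  r2 <- chromosome_chisq(status2, chrom2)
  O <- matrix(c(10, 50, 90, 50), 2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(r2$chi2, sum((O - E)^2 / E), tolerance = 1e-9)
  expect_equal(r2$df, 1)

  # random tables: statistic equals the brute-force formula
  set.seed(47)
  for (trial in 1:20) {
    n <- 120
    status3 <- setNames(sample(c("changing", "stable"), n, TRUE),
                        paste0("x", 1:n))
    chrom3 <- setNames(sample(paste0("chr", 1:4), n, TRUE),
                       paste0("x", 1:n))
    tab <- table(chrom3, status3)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    r3 <- chromosome_chisq(status3, chrom3)
    E3 <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(r3$chi2, sum((tab - E3)^2 / E3), tolerance = 1e-9)
  }
  expect_error(chromosome_chisq(status2, setNames(rep("chr1", 200),
                                                  paste0("g", 1:200))),
               "two chromosomes")
})

test_that("chi-square p-values are calibrated under independence", {
  set.seed(48)
  ps <- replicate(300, {
    status <- setNames(sample(c("changing", "stable"), 200, TRUE),
                       paste0("x", 1:200))
    chrom <- setNames(sample(paste0("chr", 1:3), 200, TRUE),
                      paste0("x", 1:200))
    chromosome_chisq(status, chrom)$p_value
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("overlap enrichment reproduces the hypergeometric tail", {
  # counts as printed for the regeneration/development comparison
  r <- overlap_enrichment(107, 97, 51, 433)
  expect_equal(r$expected, 107 * 97 / 433, tolerance = 1e-12)
  expect_equal(r$fold, 51 / (107 * 97 / 433), tolerance = 1e-12)
  expect_lt(r$p_value, 1e-6)

  # overlap equal to expectation -> fold exactly 1
  r1 <- overlap_enrichment(20, 30, 6, 100)
  expect_equal(r1$fold, 1)

  # exhaustive enumeration oracle on a universe of 10
  a <- 4; b <- 5; N <- 10
  for (ov in 2:4) {
    subsets <- combn(N, b)
    frac <- mean(apply(subsets, 2, function(s) sum(s <= a) >= ov))
    expect_equal(overlap_enrichment(a, b, ov, N)$p_value, frac,
                 tolerance = 1e-12)
  }
  expect_error(overlap_enrichment(5, 5, 6, 100), "inconsistent")
})
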