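# Window construction and per-window FST / pi / dXY with independent
# oracles.

# independent scalar transcription of the two-level unbiased
# variance-component estimator for one biallelic site in two populations
wc_oracle <- function(p1, p2, n1, n2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  c(a = a, d = a + b + c_)
}

make_rad_table <- function(n_loci = 5, locus_len = 200, n_snp_per_locus = 2,
                           n_samp = 8, seed = 1) {
  set.seed(seed)
  pos <- integer(0); rad <- integer(0)
  for (l in seq_len(n_loci)) {
    p <- sort(sample(locus_len, n_snp_per_locus)) + (l - 1) * 10000
    pos <- c(pos, p); rad <- c(rad, rep(l, n_snp_per_locus))
  }
  mono <- do.call(rbind, lapply(seq_len(n_loci), function(l)
    data.frame(chrom = "chr1",
               pos = setdiff((l - 1) * 10000 + seq_len(locus_len),
                             pos[rad == l]),
               rad_locus_id = l)))
  g <- matrix(sample(0:2, length(pos) * n_samp, replace = TRUE),
              length(pos), n_samp)
  toy_table(g, pos = pos, samples = paste0("s", seq_len(n_samp)),
            monomorphic = mono, rad = rad)
}

test_that("non-overlapping windows accumulate whole RAD loci", {
  tab <- make_rad_table(n_loci = 30, locus_len = 200, n_snp_per_locus = 1)
  w <- build_windows(tab, min_sites = 2500, mode = "non_overlapping")
  # loci of 200 sites: 13 loci reach 2600 >= 2500
  expect_equal(w$n_sites[1], 2600)
  expect_equal(w$n_sites[2], 2600)
  expect_equal(nrow(w), 3)
  expect_true(w$undersized[3])        # 4 leftover loci
  # no RAD locus is split across windows
  sites <- radpopgen:::all_sites_df(tab)
  win_of_locus <- vapply(unique(sites$rad), function(l) {
    p <- sites$pos[sites$rad == l]
    hits <- which(w$start <= min(p) & w$end >= max(p))
    length(hits)
  }, numeric(1))
  expect_true(all(win_of_locus == 1))
})

test_that("sliding windows follow the size/step arithmetic", {
  tab <- toy_table(matrix(1L, 2, 2), chrom = c("chr1", "chr1"),
                   pos = c(1L, 2000000L), samples = c("a", "b"))
  w <- build_windows(tab, mode = "sliding", size_bp = 1e6, step_bp = 2e5)
  expect_equal(w$start, seq(1, 1000001, by = 2e5))
  expect_equal(w$end, w$start + 1e6 - 1)
  expect_equal(nrow(w), 6)
})

test_that("per-site variance components match fixation and null expectations", {
  # p1 = 0, p2 = 1 with 20 diploids each: FST = 1 exactly
  g <- matrix(c(rep(0L, 20), rep(2L, 20)), 1)
  tab <- toy_table(g, samples = paste0("s", 1:40))
  pm <- toy_popmap(paste0("s", 1:40), rep(c("A", "B"), each = 20))
  comp <- site_fst_components(tab, pm, c("A", "B"))
  expect_equal(comp$num / comp$den, 1)
  # equal frequencies: numerator near zero (may be slightly negative)
  g2 <- matrix(rep(c(0L, 1L, 2L, 1L), 10), 1)
  tab2 <- toy_table(g2, samples = paste0("s", 1:40))
  comp2 <- site_fst_components(tab2, pm, c("A", "B"))
  expect_lt(abs(comp2$num), 0.02)
  # monomorphic across the pair contributes nothing
  tab3 <- toy_table(matrix(2L, 1, 40), samples = paste0("s", 1:40))
  comp3 <- site_fst_components(tab3, pm, c("A", "B"))
  expect_equal(c(comp3$num, comp3$den), c(0, 0))
})

test_that("variance components equal the independent scalar oracle", {
  set.seed(91)
  for (rep in 1:10) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    g1 <- sample(0:2, n1, replace = TRUE)
    g2 <- sample(0:2, n2, replace = TRUE)
    tab <- toy_table(matrix(c(g1, g2), 1), samples = paste0("s", 1:(n1 + n2)))
    pm <- toy_popmap(paste0("s", 1:(n1 + n2)), rep(c("A", "B"), c(n1, n2)))
    comp <- site_fst_components(tab, pm, c("A", "B"))
    o <- wc_oracle(sum(g1) / (2 * n1), sum(g2) / (2 * n2), n1, n2,
                   mean(g1 == 1), mean(g2 == 1))
    if ((sum(g1) + sum(g2)) %in% c(0, 2 * (n1 + n2))) {
      expect_equal(c(comp$num, comp$den), c(0, 0))
    } else {
      expect_equal(comp$num, unname(o["a"]), tolerance = 1e-12)
      expect_equal(comp$den, unname(o["d"]), tolerance = 1e-12)
    }
  }
})

test_that("window FST is the ratio of summed components", {
  w <- data.frame(chrom = "chr1", start = 1, end = 10000, n_sites = 2,
                  undersized = FALSE)
  sc <- data.frame(chrom = "chr1", pos = c(100, 200),
                   num = c(0.5, 0.0), den = c(1.0, 1.0))
  expect_equal(window_weighted_fst(w, sc)$fst, 0.25)
  # single-SNP window equals that SNP's FST
  sc1 <- data.frame(chrom = "chr1", pos = 100, num = 0.3, den = 0.6)
  expect_equal(window_weighted_fst(w, sc1)$fst, 0.5)
  # all-monomorphic window: undefined
  sc0 <- data.frame(chrom = "chr1", pos = c(100, 200), num = 0, den = 0)
  expect_true(is.na(window_weighted_fst(w, sc0)$fst))
  # weighted FST lies within the per-site range when denominators are
  # positive
  set.seed(92)
  num <- runif(20, -0.05, 0.5); den <- num + runif(20, 0.2, 1)
  scr <- data.frame(chrom = "chr1", pos = 1:20 * 10, num = num, den = den)
  fst <- window_weighted_fst(w, scr)$fst
  expect_gte(fst, min(num / den))
  expect_lte(fst, max(num / den))
})

test_that("windowed pi and dXY equal direct haplotype computations", {
  # n = 2 haplotypes, one heterozygous-pattern site, 100 sequenced sites
  tab <- toy_table(matrix(1L, 1, 1), pos = 1L, samples = "i1",
                   monomorphic = data.frame(chrom = "chr1", pos = 2:100,
                                            rad_locus_id = 1))
  pm <- toy_popmap("i1", "A")
  w <- data.frame(chrom = "chr1", start = 1, end = 100, n_sites = 100)
  expect_equal(window_pi(tab, pm, w, "A"), 0.01)
  # monomorphic window: pi = 0
  tab0 <- toy_table(matrix(integer(0), 0, 1), samples = "i1",
                    monomorphic = data.frame(chrom = "chr1", pos = 1:100))
  expect_equal(window_pi(tab0, pm, w, "A"), 0)
  # one fixed difference in 100 sites: dXY = 0.01; identical pops: 0
  tab2 <- toy_table(matrix(c(0L, 2L), 1, 2), pos = 1L,
                    samples = c("i1", "i2"),
                    monomorphic = data.frame(chrom = "chr1", pos = 2:100))
  pm2 <- toy_popmap(c("i1", "i2"), c("A", "B"))
  expect_equal(window_dxy(tab2, pm2, w, c("A", "B")), 0.01)
  tab3 <- toy_table(matrix(c(0L, 0L), 1, 2), pos = 1L,
                    samples = c("i1", "i2"),
                    monomorphic = data.frame(chrom = "chr1", pos = 2:100))
  expect_equal(window_dxy(tab3, pm2, w, c("A", "B")), 0)
})

test_that("SFS-route pi and dXY equal pairwise-difference oracles exactly", {
  set.seed(93)
  # known haplotypes -> diploids; pi/dXY are phase-free so the haplotype
  # oracle applies to the genotype table
  n_hapA <- 6; n_hapB <- 4; S <- 40; L <- 500
  hapA <- matrix(rbinom(S * n_hapA, 1, 0.3), S, n_hapA)
  hapB <- matrix(rbinom(S * n_hapB, 1, 0.6), S, n_hapB)
  gA <- hapA[, seq(1, n_hapA, 2)] + hapA[, seq(2, n_hapA, 2)]
  gB <- hapB[, seq(1, n_hapB, 2)] + hapB[, seq(2, n_hapB, 2)]
  tab <- toy_table(cbind(gA, gB), pos = sort(sample(L, S)),
                   samples = paste0("s", 1:5),
                   monomorphic = data.frame(chrom = "chr1", pos = L + 1:460))
  pm <- toy_popmap(paste0("s", 1:5), rep(c("A", "B"), c(3, 2)))
  w <- data.frame(chrom = "chr1", start = 1, end = L + 460, n_sites = 500)
  # oracle: average pairwise difference over haplotype pairs
  pairs_within <- function(h) {
    n <- ncol(h); tot <- 0; cnt <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      tot <- tot + sum(h[, i] != h[, j]); cnt <- cnt + 1
    }
    tot / cnt / 500
  }
  pairs_between <- function(h1, h2) {
    tot <- 0; cnt <- 0
    for (i in seq_len(ncol(h1))) for (j in seq_len(ncol(h2))) {
      tot <- tot + sum(h1[, i] != h2[, j]); cnt <- cnt + 1
    }
    tot / cnt / 500
  }
  expect_equal(window_pi(tab, pm, w, "A"), pairs_within(hapA))
  expect_equal(window_pi(tab, pm, w, "B"), pairs_within(hapB))
  expect_equal(window_dxy(tab, pm, w, c("A", "B")),
               pairs_between(hapA, hapB))
  expect_true(window_pi(tab, pm, w, "A") >= 0 &&
                window_dxy(tab, pm, w, c("A", "B")) >= 0)
})

test_that("landscape correlation handles alignment, nulls and pairing", {
  w <- data.frame(chrom = "chr1", start = seq(1, 1e6, 1e4), end = 0)
  w$end <- w$start + 1e4 - 1
  a <- cbind(w, value = rnorm(nrow(w)))
  b <- cbind(w, value = 2 * a$value + 1)
  expect_equal(correlate_landscapes(a, b)$r, 1)
  # independent landscapes: |r| < 0.1 in most replicates at 1000 windows
  set.seed(94)
  hits <- vapply(1:20, function(i) {
    w2 <- data.frame(chrom = "chr1", start = seq(1, 1e7, 1e4))
    w2$end <- w2$start + 1e4 - 1
    aa <- cbind(w2, value = rnorm(nrow(w2)))
    bb <- cbind(w2, value = rnorm(nrow(w2)))
    abs(correlate_landscapes(aa, bb)$r) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # shared populations between pairwise landscapes are rejected
  expect_error(correlate_landscapes(a, b, pops_a = c("L1", "AGS1"),
                                    pops_b = c("L1", "PLS1")), "share")
  # fewer than 3 complete windows: undefined
  small <- a[1:2, ]
  expect_true(is.na(correlate_landscapes(small, small)$r))
})
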