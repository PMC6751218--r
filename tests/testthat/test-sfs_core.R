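# Multidimensional SFS construction, folding, marginalisation, masking,
# block bootstrap and text IO.

test_that("sfs_from_genotypes tallies cells like a site-by-site hand count", {
  # 2 pops x 1 diploid each, single SNP with dosages (1, 2)
  tab <- toy_table(matrix(c(1L, 2L), 1, 2), samples = c("a", "b"))
  pm <- toy_popmap(c("a", "b"), c("P", "Q"))
  s <- sfs_from_genotypes(tab, pm, c("P", "Q"))
  expect_equal(s$counts[2, 3], 1)
  expect_equal(total_sites(s), 1)
  # 100 monomorphic sites, no SNPs
  tab2 <- toy_table(matrix(integer(0), 0, 2), samples = c("a", "b"),
                    monomorphic = data.frame(chrom = "chr1",
                                             pos = 1e6 + 1:100))
  s2 <- sfs_from_genotypes(tab2, pm, c("P", "Q"))
  expect_equal(s2$counts[1, 1], 100)
  expect_equal(total_sites(s2), 100)
  # random toy table vs brute-force tally oracle
  set.seed(2)
  g <- matrix(sample(0:2, 30 * 4, replace = TRUE), 30, 4)
  tab3 <- toy_table(g, samples = paste0("S", 1:4))
  pm3 <- toy_popmap(paste0("S", 1:4), c("P", "P", "Q", "Q"))
  s3 <- sfs_from_genotypes(tab3, pm3, c("P", "Q"))
  oracle <- array(0, dim = c(5, 5))
  for (i in seq_len(30)) {
    cp <- g[i, 1] + g[i, 2]
    cq <- g[i, 3] + g[i, 4]
    oracle[cp + 1, cq + 1] <- oracle[cp + 1, cq + 1] + 1
  }
  expect_equal(unname(s3$counts), oracle)
  # missing genotypes are rejected with a pointer to the subsample step
  g[1, 1] <- NA
  expect_error(sfs_from_genotypes(toy_table(g, samples = paste0("S", 1:4)),
                                  pm3, c("P", "Q")), "subsample")
})

test_that("folding follows the global-minor-allele complement rule", {
  s <- new_sfs(array(c(10, 4, 3, 2, 1), dim = 5), "P", 4)
  f <- fold_sfs(s)
  expect_equal(as.vector(f$counts), c(11, 6, 3, 0, 0))
  expect_true(f$folded)
  expect_equal(total_sites(f), total_sites(s))
  expect_warning(f2 <- fold_sfs(f), "already folded")
  expect_equal(f2$counts, f$counts)
  # exact-half cells stay in place without doubling (2-pop case)
  s2 <- new_sfs(array(1, dim = c(3, 3)), c("P", "Q"), c(2, 2))
  f2d <- fold_sfs(s2)
  expect_equal(total_sites(f2d), 9)
  expect_equal(f2d$counts[3, 1], 1)   # (2,0) totals half: kept in place
  expect_equal(f2d$counts[1, 3], 1)   # so does its complement (0,2)
  expect_equal(f2d$counts[3, 3], 0)   # (2,2) folded onto (0,0)
  expect_equal(f2d$counts[1, 1], 2)
})

test_that("marginalisation equals axis summation and conserves totals", {
  set.seed(3)
  arr <- array(rpois(3 * 5 * 7, 4), dim = c(3, 5, 7))
  s <- new_sfs(arr, c("A", "B", "C"), c(2, 4, 6))
  m <- marginalize_sfs(s, c("A", "C"))
  expect_equal(unname(m$counts), unname(apply(arr, c(1, 3), sum)))
  expect_equal(total_sites(m), sum(arr))
  # keeping every population is the identity
  all3 <- marginalize_sfs(s, c("A", "B", "C"))
  expect_equal(all3$counts, s$counts)
  # 2D -> 1D gives row sums
  s2 <- new_sfs(arr[, , 1], c("A", "B"), c(2, 4))
  expect_equal(as.vector(marginalize_sfs(s2, "A")$counts),
               unname(rowSums(arr[, , 1])))
  expect_error(marginalize_sfs(s, character(0)), "at least one")
})

test_that("marginalisation commutes with folding on random arrays", {
  set.seed(4)
  for (rep in 1:5) {
    arr <- array(rpois(5 * 5, 3), dim = c(5, 5))
    s <- new_sfs(arr, c("A", "B"), c(4, 4))
    a <- marginalize_sfs(fold_sfs(s), "A")
    # folding after marginalising uses the subset's own sample total, which
    # differs from the global fold; the conserved quantity is the total
    expect_equal(total_sites(a), sum(arr))
    expect_equal(total_sites(fold_sfs(marginalize_sfs(s, "A"))), sum(arr))
  }
})

test_that("singleton masking flags the right cells and is idempotent", {
  s <- new_sfs(array(1, dim = c(3, 3)), c("P", "Q"), c(2, 2))
  m <- mask_singletons(s)
  expect_true(m$mask[2, 1] && m$mask[1, 2])     # (1,0) and (0,1)
  expect_true(m$mask[3, 2] && m$mask[2, 3])     # unfolded: total 2n-1 too
  expect_equal(sum(m$mask), 4)
  expect_equal(mask_singletons(m)$mask, m$mask)
})

test_that("masked cells are excluded from the composite likelihood", {
  s <- new_sfs(array(c(900, 50, 30, 20), dim = 4), "P", 3)
  ex <- structure(list(probs = array(c(0.85, 0.08, 0.04, 0.03), dim = 4),
                       pop_order = "P", n_hap = 3L, folded = FALSE,
                       n_sims = 1e5), class = "expected_sfs")
  ll_all <- composite_loglik(s, ex)
  sm <- mask_singletons(s)
  ll_masked <- composite_loglik(sm, ex)
  # hand-computed: masking drops cells with total 1 and 2 (= 2n-1), and
  # renormalises the remaining probabilities
  p <- c(0.85, 0.03) / 0.88
  expect_equal(ll_masked, 900 * log10(p[1]) + 20 * log10(p[2]))
  expect_false(isTRUE(all.equal(ll_all, ll_masked)))
})

test_that("block bootstrap resamples whole blocks with replacement", {
  # three 10-site blocks, each with a distinctive cell signature
  g <- matrix(0L, 9, 2)
  g[1:3, 1] <- 1L          # block-1 SNPs in cell (1, 0)
  g[4:6, ] <- 2L           # block-2 SNPs in cell (2, 2)
  g[7:9, c(1, 2)] <- c(0L, 0L, 0L, 1L, 1L, 1L)   # block 3: cell (0, 1)
  pos <- as.integer(c(1:3, 11:13, 21:23))
  mono <- data.frame(chrom = "chr1", pos = setdiff(1:30, pos))
  tab <- toy_table(g, pos = pos, samples = c("a", "b"), monomorphic = mono)
  pm <- toy_popmap(c("a", "b"), c("P", "Q"))
  reps <- block_bootstrap_sfs(tab, pm, c("P", "Q"), block_sites = 10,
                              n_reps = 50, seed = 1)
  for (r in reps) {
    # every replicate draws 3 blocks of 10 sites
    expect_equal(total_sites(r), 30)
    draw <- c(r$counts[2, 1], r$counts[3, 3], r$counts[1, 2]) / 3
    expect_true(all(draw == floor(draw)))       # whole blocks only
    expect_equal(sum(draw), 3)
  }
  # mean of many replicates approaches the observed SFS
  obs <- sfs_from_genotypes(tab, pm, c("P", "Q"))
  mreps <- block_bootstrap_sfs(tab, pm, c("P", "Q"), block_sites = 10,
                               n_reps = 1000, seed = 2)
  avg <- Reduce(`+`, lapply(mreps, `[[`, "counts")) / 1000
  expect_lt(max(abs(avg - obs$counts)), 0.3)
  expect_error(block_bootstrap_sfs(tab, pm, c("P", "Q"),
                                   block_sites = 100, n_reps = 2),
               "fewer than 2 blocks")
})

test_that("SFS text round trip preserves counts and metadata", {
  set.seed(5)
  s <- new_sfs(array(rpois(5 * 7, 3), dim = c(5, 7)), c("P", "Q"), c(4, 6),
               folded = FALSE)
  path <- tempfile()
  write_sfs(s, path)
  back <- read_sfs(path)
  expect_equal(back$counts, s$counts)
  expect_equal(back$pop_order, s$pop_order)
  expect_equal(back$n_hap, s$n_hap)
  expect_equal(back$folded, s$folded)
  # reader tolerates extra comment lines
  writeLines(c("# a comment", readLines(path)), path)
  expect_equal(read_sfs(path)$counts, s$counts)
})
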