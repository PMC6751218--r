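# VCF IO and the pre-SFS filtering chain.

write_toy_vcf <- function(path, lines) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    lines), path)
  path
}

test_that("read_vcf routes variant and invariant records and reads popmap", {
  vcf <- write_toy_vcf(tempfile(fileext = ".vcf"), c(
    "chr1\t100\t.\tA\tC\t.\tPASS\t.\tGT:DP\t0/0:20\t0/1:15\t1/1:22",
    "chr1\t150\t.\tG\t.\t.\tPASS\t.\tGT:DP\t0/0:18\t0/0:12\t0/0:30",
    "chr1\t200\t.\tT\tG\t.\tPASS\t.\tGT:DP\t0/1:9\t./.:0\t0/0:25"))
  pm <- tempfile()
  writeLines(c("S1 popA", "S2 popA", "S3 popB"), pm)
  res <- read_vcf(vcf, pm)
  expect_equal(nrow(res$table$variants), 2)
  expect_equal(nrow(res$table$monomorphic), 1)
  expect_equal(res$table$monomorphic$pos, 150)
  expect_equal(unname(res$table$geno[1, ]), c(0L, 1L, 2L))
  expect_equal(unname(res$table$depth[2, ]), c(9L, 0L, 25L))
  expect_true(is.na(res$table$geno[2, 2]))
  expect_equal(res$popmap$pop, c("popA", "popA", "popB"))

  writeLines(c("S1 popA", "SX popB"), pm)
  expect_error(read_vcf(vcf, pm), "SX")
})

test_that("triallelic records pass through read and fall to the biallelic filter", {
  vcf <- write_toy_vcf(tempfile(fileext = ".vcf"), c(
    "chr1\t100\t.\tA\tC,G\t.\tPASS\t.\tGT:DP\t0/1:20\t1/2:15\t0/0:22",
    "chr1\t200\t.\tT\tG\t.\tPASS\t.\tGT:DP\t0/1:9\t0/0:8\t0/0:25",
    "chrXIX\t300\t.\tT\tG\t.\tPASS\t.\tGT:DP\t0/1:9\t0/0:8\t0/0:25",
    "chr2\t400\t.\tT\tTA\t.\tPASS\t.\tGT:DP\t0/1:9\t0/0:8\t0/0:25"))
  tab <- read_vcf(vcf)
  expect_equal(nrow(tab$variants), 4)      # everything retained at read time
  filt <- filter_biallelic_autosomal(tab, sex_chrom = "chrXIX")
  expect_equal(nrow(filt$variants), 1)     # indel, chrXIX, triallelic gone
  expect_equal(filt$variants$pos, 200)
  # all-autosomal biallelic input is untouched
  expect_equal(filter_biallelic_autosomal(filt)$variants, filt$variants)
})

test_that("VCF write/read round trip preserves the table", {
  set.seed(1)
  g <- matrix(sample(c(0:2, NA), 12, replace = TRUE), 4, 3)
  tab <- toy_table(g, depth = matrix(15:26, 4, 3),
                   monomorphic = data.frame(chrom = "chr1",
                                            pos = c(10L, 20L),
                                            rad_locus_id = c(1L, 1L)))
  path <- tempfile(fileext = ".vcf")
  write_vcf(tab, path)
  back <- read_vcf(path)
  expect_equal(back$variants$pos, tab$variants$pos)
  expect_equal(unname(back$geno), unname(tab$geno))
  expect_equal(unname(back$depth), unname(tab$depth))
  expect_equal(back$monomorphic$pos, tab$monomorphic$pos)
  # second round trip is exact
  path2 <- tempfile(fileext = ".vcf")
  write_vcf(back, path2)
  expect_identical(readLines(path), readLines(path2))
  # the monomorphic-site registry exports as a readable TSV
  reg <- tempfile(fileext = ".tsv")
  write_site_registry(tab, reg)
  expect_equal(read.table(reg, header = TRUE)$pos, c(10L, 20L))
})

test_that("depth-IQR filter removes upper-fence outliers", {
  depths <- c(10, 10, 10, 10, 1000)
  tab <- toy_table(matrix(1L, 5, 1), depth = matrix(depths, 5, 1))
  # quartiles of the five totals by linear interpolation: Q1 = Q3 = 10,
  # IQR = 0, fence = 10 -> only the 1000-depth site falls
  filt <- filter_depth_iqr(tab, factor = 1.5)
  expect_equal(nrow(filt$variants), 4)
  # equal depths: nothing removed (boundary kept at <=)
  tab2 <- toy_table(matrix(1L, 5, 1), depth = matrix(10L, 5, 1))
  expect_equal(nrow(filter_depth_iqr(tab2)$variants), 5)
  # infinite factor disables the filter
  expect_equal(nrow(filter_depth_iqr(tab, factor = Inf)$variants), 5)
  expect_warning(filter_depth_iqr(toy_table(matrix(0L, 0, 1))), "empty")
})

test_that("low-depth masking and missingness filter follow the thresholds", {
  tab <- toy_table(matrix(c(0L, 1L, 2L, 0L), 1, 4),
                   depth = matrix(c(12L, 9L, 30L, 0L), 1, 4))
  out <- mask_and_drop_missing(tab, min_depth = 10, max_missing = 0.5)
  expect_equal(nrow(out$variants), 1)            # exactly 50% missing: kept
  expect_equal(sum(is.na(out$geno)), 2)
  tab2 <- toy_table(matrix(c(0L, 1L, 2L, 0L), 1, 4),
                    depth = matrix(c(9L, 9L, 9L, 30L), 1, 4))
  expect_equal(nrow(mask_and_drop_missing(tab2, 10, 0.5)$variants), 0)
  out3 <- mask_and_drop_missing(tab2, min_depth = 0, max_missing = 0.5)
  expect_equal(sum(is.na(out3$geno)), 0)         # nothing masked
})

test_that("exact heterozygote-excess test matches closed-form enumeration", {
  # 10 diploids, all heterozygous (10 alt copies): under the exact HWE null
  # the all-heterozygote configuration has probability 2^10 / C(20,10)
  p_expected <- 2^10 / choose(20, 10)
  expect_equal(hwe_het_excess_p(0, 10, 0), p_expected, tolerance = 1e-12)
  # all-homozygous sites can never show excess
  expect_equal(hwe_het_excess_p(5, 0, 5), 1)
  expect_equal(hwe_het_excess_p(10, 0, 0), 1)
})

test_that("HWE filter flags het-excess sites and removes the buffer", {
  g_bad <- matrix(1L, 1, 10)                     # all het in 10 diploids
  g_good <- matrix(rep(c(0L, 2L), 5), 1, 10)     # all hom
  g_near <- matrix(c(0L, rep(2L, 9)), 1, 10)
  tab <- toy_table(rbind(g_bad, g_near, g_good),
                   pos = c(500L, 450L, 5000L),
                   samples = paste0("S", 1:10),
                   monomorphic = data.frame(chrom = "chr1",
                                            pos = c(520L, 4000L)))
  pm <- toy_popmap(paste0("S", 1:10), rep("A", 10))
  out <- hwe_het_excess_filter(tab, pm, alpha = 0.05, buffer_bp = 100)
  # flagged site at 500 removes itself, the variant at 450 and mono at 520
  expect_equal(out$variants$pos, 5000)
  expect_equal(out$monomorphic$pos, 4000)
})

test_that("LD pruning is greedy left-to-right within the window", {
  s1 <- c(0L, 0L, 1L, 1L, 2L, 2L, 0L, 2L)
  tab <- toy_table(rbind(s1, s1), pos = c(100L, 150L),
                   samples = paste0("S", 1:8))
  expect_equal(ld_prune(tab, 0.95, 200)$variants$pos, 100)
  # same pair far apart: both kept
  tab2 <- toy_table(rbind(s1, s1), pos = c(100L, 5100L),
                    samples = paste0("S", 1:8))
  expect_equal(nrow(ld_prune(tab2, 0.95, 200)$variants), 2)
  # chain with pairwise r2 (1.0, ~0.5): middle removed, third kept because
  # its r2 with the first survivor is below the cutoff
  s3 <- c(0L, 1L, 0L, 1L, 2L, 1L, 1L, 2L)
  r2_13 <- cor(s1, s3)^2
  expect_lt(r2_13, 0.95)
  tab3 <- toy_table(rbind(s1, s1, s3), pos = c(100L, 150L, 190L),
                    samples = paste0("S", 1:8))
  expect_equal(ld_prune(tab3, 0.95, 200)$variants$pos, c(100, 190))
})

test_that("per-site genotype subsampling yields complete constant-size data", {
  set.seed(9)
  g <- matrix(sample(c(0:2, NA), 50 * 5, replace = TRUE,
                     prob = c(0.3, 0.3, 0.3, 0.1)), 50, 5)
  tab <- toy_table(g, samples = paste0("S", 1:5))
  pm <- toy_popmap(paste0("S", 1:5), rep("A", 5))
  out <- subsample_genotypes(tab, pm, c(A = 4), seed = 3)
  expect_false(anyNA(out$geno))
  expect_equal(ncol(out$geno), 4)
  # only sites with >= 4 genotyped survive
  expect_equal(nrow(out$variants), sum(rowSums(!is.na(g)) >= 4))
  # forced choice: site with exactly 4 non-missing keeps those genotypes
  i <- which(rowSums(!is.na(g)) == 4)[1]
  j <- match(tab$variants$pos[i], out$variants$pos)
  expect_equal(sort(unname(out$geno[j, ])), sort(unname(g[i, !is.na(g[i, ])])))
  # determinism
  out2 <- subsample_genotypes(tab, pm, c(A = 4), seed = 3)
  expect_identical(out$geno, out2$geno)
  # k exceeding the population size errors upfront
  expect_error(subsample_genotypes(tab, pm, c(A = 6)), "exceeds")
})

test_that("haploidisation preserves allele frequencies in expectation", {
  hom <- matrix(rep(c(0L, 2L), 50), 10, 10)
  expect_identical(unname(haploidize(toy_table(hom), seed = 1)$geno), hom)
  het <- matrix(1L, 100, 100)
  het[1, 1] <- NA
  out <- haploidize(toy_table(het), seed = 5)
  expect_true(is.na(out$geno[1, 1]))
  vals <- out$geno[!is.na(out$geno)]
  expect_true(all(vals %in% c(0L, 2L)))
  n2 <- sum(vals == 2L)
  bounds <- qbinom(c(0.005, 0.995), length(vals), 0.5)
  expect_gte(n2, bounds[1])
  expect_lte(n2, bounds[2])
})

test_that("monomorphic rebalancing is proportional to retained SNPs", {
  mono <- data.frame(chrom = "chr1", pos = 10000L + seq_len(10000))
  tab <- toy_table(matrix(1L, 100, 2), monomorphic = mono,
                   pos = seq_len(100) * 2L)
  out <- rebalance_monomorphic(tab, n_snps_retained = 80, s_pre = 1000,
                               seed = 1)
  expect_equal(nrow(out$monomorphic), 800)
  expect_false(is.unsorted(out$monomorphic$pos))
  # retained = s_pre keeps everything
  expect_equal(nrow(rebalance_monomorphic(tab, 1000, 1000)$monomorphic),
               10000)
  expect_equal(nrow(rebalance_monomorphic(tab, 0, 1000)$monomorphic), 0)
})

test_that("allele-imbalance screen flags skewed individuals", {
  g <- matrix(1L, 20, 3)
  ad_ref <- matrix(10L, 20, 3); ad_alt <- matrix(10L, 20, 3)
  ad_ref[, 2] <- 19L; ad_alt[, 2] <- 1L         # 5:95-style skew
  g[, 3] <- 0L                                   # no het calls at all
  tab <- geno_table(
    variants = data.frame(chrom = "chr1", pos = seq_len(20) * 100L,
                          ref = "A", alt = "C", rad_locus_id = seq_len(20)),
    geno = g, depth = matrix(20L, 20, 3), samples = c("bal", "skew", "nohet"),
    ad_ref = ad_ref, ad_alt = ad_alt)
  expect_equal(suppressMessages(
    flag_allele_imbalance_individuals(tab, 0.3)), "skew")
  tab$ad_ref <- tab$ad_alt <- NULL
  expect_warning(out <- flag_allele_imbalance_individuals(tab), "inoperative")
  expect_length(out, 0)
})

test_that("filters are idempotent", {
  set.seed(11)
  g <- matrix(sample(c(0:2, NA), 40 * 10, replace = TRUE), 40, 10)
  d <- matrix(rpois(400, 30), 40, 10)
  tab <- toy_table(g, depth = d, samples = paste0("S", 1:10))
  pm <- toy_popmap(paste0("S", 1:10), rep(c("A", "B"), each = 5))
  # (the depth-IQR fence is re-estimated from whatever data it sees, so its
  # idempotence is only guaranteed when no site is removed; the fixed-
  # predicate filters must be exactly idempotent)
  for (f in list(function(x) filter_biallelic_autosomal(x),
                 function(x) mask_and_drop_missing(x, 10, 0.5),
                 function(x) hwe_het_excess_filter(x, pm, 0.05, 100),
                 function(x) ld_prune(x, 0.95, 2000))) {
    once <- f(tab)
    twice <- f(once)
    expect_equal(twice$variants, once$variants)
    expect_equal(twice$geno, once$geno)
  }
})
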