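# The pre-SFS filtering chain: depth outliers, biallelic/autosomal
# restriction, depth-based missingness, Hardy-Weinberg heterozygote excess
# (with positional buffer), LD pruning, per-site genotype subsampling,
# haploidisation and monomorphic-site rebalancing. All filters are
# idempotent and preserve (chrom, pos) ordering.

subset_variants <- function(table, keep) {
  geno_table(table$variants[keep, , drop = FALSE],
             table$geno[keep, , drop = FALSE],
             table$depth[keep, , drop = FALSE],
             table$samples, table$monomorphic,
             ad_ref = if (!is.null(table$ad_ref)) table$ad_ref[keep, , drop = FALSE],
             ad_alt = if (!is.null(table$ad_alt)) table$ad_alt[keep, , drop = FALSE])
}

#' Remove sites with outlying total read depth
#'
#' Site depth is the sum of per-sample depths; sites above the upper fence
#' `Q3 + factor * IQR` of the site-depth distribution are removed (quartiles
#' by linear interpolation). This targets collapsed repeats, which inflate
#' apparent depth.
#'
#' @param table a `geno_table`
#' @param factor fence multiplier (default 1.5); `Inf` disables the filter
#' @return filtered `geno_table`
#' @export
filter_depth_iqr <- function(table, factor = 1.5) {
  stopifnot(factor > 0)
  if (nrow(table$variants) == 0) {
    warning("empty genotype table: depth filter is a no-op")
    return(table)
  }
  total <- rowSums(table$depth, na.rm = TRUE)
  q <- quantile(total, c(0.25, 0.75), type = 7, names = FALSE)
  cutoff <- q[2] + factor * (q[2] - q[1])
  if (is.nan(cutoff)) cutoff <- Inf   # infinite factor with zero IQR
  subset_variants(table, total <= cutoff)
}

#' Keep only biallelic autosomal SNPs
#'
#' Removes indels, multiallelic records and all sites (variant or
#' monomorphic) on the sex chromosome.
#'
#' @param table a `geno_table`
#' @param sex_chrom sex chromosome name (default `"chrXIX"`)
#' @export
filter_biallelic_autosomal <- function(table, sex_chrom = "chrXIX") {
  v <- table$variants
  is_snp <- nchar(v$ref) == 1 & nchar(v$alt) == 1 & !grepl(",", v$alt) &
    v$ref %in% c("A", "C", "G", "T", "N") & v$alt %in% c("A", "C", "G", "T")
  keep <- is_snp & v$chrom != sex_chrom
  out <- subset_variants(table, keep)
  out$monomorphic <- out$monomorphic[out$monomorphic$chrom != sex_chrom, ,
                                     drop = FALSE]
  rownames(out$monomorphic) <- NULL
  out
}

#' Mask low-depth genotypes and drop high-missingness sites
#'
#' Genotypes sequenced to fewer than `min_depth` reads are set missing;
#' sites whose missing fraction then exceeds `max_missing` are removed.
#'
#' @param table a `geno_table`
#' @param min_depth minimum per-genotype read depth (default 10)
#' @param max_missing maximum tolerated missing fraction per site (default 0.5)
#' @export
mask_and_drop_missing <- function(table, min_depth = 10, max_missing = 0.5) {
  stopifnot(min_depth >= 0, max_missing >= 0, max_missing <= 1)
  table$geno[table$depth < min_depth] <- NA_integer_
  miss <- rowMeans(is.na(table$geno))
  subset_variants(table, miss <= max_missing)
}

# Exact Hardy-Weinberg heterozygote distribution (Levene): one-sided upper
# tail P(N_het >= h_obs | n diploids, n_minor minor-allele copies).
hwe_het_excess_p <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  na <- 2 * n_hom_alt + n_het          # alt allele copies
  if (n < 2 || na == 0 || na == 2 * n) return(1)
  hs <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  logp <- hs * log(2) + lgamma(n + 1) - lgamma((na - hs) / 2 + 1) -
    lgamma(hs + 1) - lgamma((2 * n - na - hs) / 2 + 1) +
    lgamma(na + 1) + lgamma(2 * n - na + 1) - lgamma(2 * n + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  sum(p[hs >= n_het])
}

#' Remove sites showing heterozygote excess, with a positional buffer
#'
#' Per population, each variant is tested with a one-sided exact
#' Hardy-Weinberg test toward heterozygote excess (a hallmark of collapsed
#' paralogs). Sites flagged in *any* population (the union), together with
#' every sequenced site within `buffer_bp` of a flagged site, are removed
#' from both the variant set and the monomorphic registry.
#'
#' @param table a `geno_table`
#' @param popmap popmap data.frame (`sample`, `pop`)
#' @param alpha per-site significance level (default 0.05)
#' @param buffer_bp removal buffer around flagged sites (default 100)
#' @export
hwe_het_excess_filter <- function(table, popmap, alpha = 0.05,
                                  buffer_bp = 100) {
  check_popmap(table, popmap)
  pops <- pops_of(table, popmap)
  flagged <- rep(FALSE, nrow(table$variants))
  for (p in unique(pops)) {
    g <- table$geno[, pops == p, drop = FALSE]
    n0 <- rowSums(g == 0, na.rm = TRUE)
    n1 <- rowSums(g == 1, na.rm = TRUE)
    n2 <- rowSums(g == 2, na.rm = TRUE)
    ok <- (n0 + n1 + n2) >= 2      # populations with < 2 genotypes: skipped
    pv <- rep(1, nrow(g))
    idx <- which(ok & n1 > 0)
    pv[idx] <- mapply(hwe_het_excess_p, n0[idx], n1[idx], n2[idx])
    flagged <- flagged | (ok & pv < alpha)
  }
  v <- table$variants
  bad <- data.frame(chrom = v$chrom[flagged], pos = v$pos[flagged])
  in_buffer <- function(chrom, pos) {
    hit <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(bad))) {
      hit <- hit | (chrom == bad$chrom[i] & abs(pos - bad$pos[i]) <= buffer_bp)
    }
    hit
  }
  if (nrow(bad) == 0) return(table)
  out <- subset_variants(table, !in_buffer(v$chrom, v$pos))
  m <- out$monomorphic
  if (nrow(m) > 0) {
    out$monomorphic <- m[!in_buffer(m$chrom, m$pos), , drop = FALSE]
    rownames(out$monomorphic) <- NULL
  }
  out
}

#' Prune linked SNPs
#'
#' Greedy left-to-right scan within each chromosome: a site is dropped when
#' its genotypic r-squared with any previously retained site within
#' `window_bp` exceeds `r2_max`. r-squared is computed from dosages over
#' samples non-missing at both sites; sites monomorphic in-sample give
#' undefined r-squared, treated as 0.
#'
#' @param table a `geno_table`
#' @param r2_max maximum tolerated r-squared (default 0.95)
#' @param window_bp comparison window in bp (default 200)
#' @export
ld_prune <- function(table, r2_max = 0.95, window_bp = 200) {
  v <- table$variants
  n <- nrow(v)
  keep <- rep(TRUE, n)
  if (n < 2) return(table)
  for (j in 2:n) {
    cand <- which(keep[seq_len(j - 1)] & v$chrom[seq_len(j - 1)] == v$chrom[j] &
                    v$pos[j] - v$pos[seq_len(j - 1)] <= window_bp)
    for (i in rev(cand)) {
      r2 <- dosage_r2(table$geno[i, ], table$geno[j, ])
      if (!is.na(r2) && r2 > r2_max) { keep[j] <- FALSE; break }
    }
  }
  subset_variants(table, keep)
}

dosage_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(0)
  sa <- stats::sd(a[ok]); sb <- stats::sd(b[ok])
  if (sa == 0 || sb == 0) return(0)
  cor(a[ok], b[ok])^2
}

#' Subsample a fixed number of genotypes per population at every site
#'
#' At each site, `k_per_pop[pop]` genotypes are drawn uniformly without
#' replacement among the non-missing genotypes of each population; sites
#' where any population has fewer than the required number are discarded.
#' The result has no missing data and constant per-population sample sizes.
#' Because the drawn individuals differ between sites, output columns are
#' anonymous per-population slots named `<pop>.1 ... <pop>.k`; use
#' [subsample_popmap()] to recover a popmap for them.
#'
#' @param table a `geno_table`
#' @param popmap popmap data.frame
#' @param k_per_pop named integer vector: population -> required genotypes
#' @param seed RNG seed
#' @return a complete-data `geno_table` with per-population slot columns
#' @export
subsample_genotypes <- function(table, popmap, k_per_pop, seed = 1) {
  check_popmap(table, popmap)
  pops <- pops_of(table, popmap)
  k_per_pop <- k_per_pop[!is.na(names(k_per_pop))]
  for (p in names(k_per_pop)) {
    if (k_per_pop[p] > sum(pops == p))
      stop("k = ", k_per_pop[p], " exceeds the ", sum(pops == p),
           " samples of population ", p)
  }
  set.seed(seed)
  popnames <- names(k_per_pop)
  cols <- unlist(lapply(popnames, function(p) paste0(p, ".", seq_len(k_per_pop[p]))))
  nv <- nrow(table$variants)
  newg <- matrix(NA_integer_, nv, length(cols))
  newd <- matrix(0L, nv, length(cols))
  keep <- rep(TRUE, nv)
  colidx <- split(seq_along(cols), rep(popnames, k_per_pop[popnames]))
  sampidx <- lapply(popnames, function(p) which(pops == p))
  names(sampidx) <- popnames
  for (s in seq_len(nv)) {
    for (p in popnames) {
      avail <- sampidx[[p]][!is.na(table$geno[s, sampidx[[p]]])]
      k <- k_per_pop[[p]]
      if (length(avail) < k) { keep[s] <- FALSE; break }
      pick <- if (length(avail) == 1) avail else sample(avail, k)
      newg[s, colidx[[p]]] <- table$geno[s, pick]
      newd[s, colidx[[p]]] <- table$depth[s, pick]
    }
  }
  geno_table(table$variants[keep, , drop = FALSE],
             newg[keep, , drop = FALSE], newd[keep, , drop = FALSE],
             cols, table$monomorphic)
}

#' Popmap for the anonymous slots produced by [subsample_genotypes()]
#' @param table a subsampled `geno_table`
#' @export
subsample_popmap <- function(table) {
  data.frame(sample = table$samples,
             pop = sub("\\.[0-9]+$", "", table$samples),
             stringsAsFactors = FALSE)
}

#' Haploidise genotypes (mimic allelic dropout)
#'
#' One allele is sampled at random from every heterozygous genotype, turning
#' it into a fake homozygote (dosage 0 or 2 with probability one half each).
#' Homozygous and missing genotypes are unchanged. Matching the dropout
#' level across samples removes dropout-driven heterozygosity differences.
#'
#' @param table a `geno_table`
#' @param seed RNG seed
#' @export
haploidize <- function(table, seed = 1) {
  set.seed(seed)
  het <- which(table$geno == 1)
  table$geno[het] <- 2L * rbinom(length(het), 1, 0.5)
  table
}

#' Rebalance the monomorphic-site registry after SNP pruning
#'
#' Keeps `N = round(M_pre * n_snps_retained / s_pre)` monomorphic sites,
#' sampled uniformly without replacement, so that the SNP:monomorphic ratio
#' of the pre-pruning dataset is preserved.
#'
#' @param table a `geno_table` whose registry still holds all `M_pre` sites
#' @param n_snps_retained SNP count after LD pruning
#' @param s_pre SNP count before pruning (default: the table's own count)
#' @param seed RNG seed
#' @export
rebalance_monomorphic <- function(table, n_snps_retained, s_pre = NULL,
                                  seed = 1) {
  if (is.null(s_pre)) s_pre <- nrow(table$variants)
  stopifnot(s_pre > 0)
  m_pre <- nrow(table$monomorphic)
  n_keep <- round(m_pre * n_snps_retained / s_pre)
  if (n_keep >= m_pre) {
    if (n_keep > m_pre)
      warning("requested ", n_keep, " monomorphic sites but only ", m_pre,
              " available; keeping all")
    return(table)
  }
  set.seed(seed)
  pick <- sort(sample(m_pre, n_keep))
  table$monomorphic <- table$monomorphic[pick, , drop = FALSE]
  rownames(table$monomorphic) <- NULL
  table
}

#' Flag individuals with strong allelic-read imbalance
#'
#' PCR artifacts show up as heterozygous calls whose minor-allele read
#' fraction deviates strongly from one half. For each individual the mean
#' minor fraction `minor / (minor + major)` over its heterozygous calls is
#' computed; individuals below `threshold` are flagged.
#'
#' @param table a `geno_table` carrying allelic depths (`AD`)
#' @param threshold minimum acceptable mean minor fraction (default 0.3)
#' @return character vector of flagged sample ids
#' @export
flag_allele_imbalance_individuals <- function(table, threshold = 0.3) {
  if (is.null(table$ad_ref) || is.null(table$ad_alt)) {
    warning("no allelic-depth (AD) data: allele-imbalance screen inoperative")
    return(character(0))
  }
  het <- table$geno == 1
  minor <- pmin(table$ad_ref, table$ad_alt)
  total <- table$ad_ref + table$ad_alt
  frac <- ifelse(het & total > 0, minor / total, NA_real_)
  mean_frac <- colMeans(frac, na.rm = TRUE)
  no_het <- !is.finite(mean_frac)
  if (any(no_het))
    message("individual(s) without heterozygous calls skipped: ",
            paste(table$samples[no_het], collapse = ", "))
  table$samples[!no_het & mean_frac < threshold]
}
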