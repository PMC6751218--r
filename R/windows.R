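# Genomic windows and per-window differentiation/diversity statistics:
# weighted (ratio-of-averages) FST from per-site variance components,
# nucleotide diversity and absolute divergence from windowed 1D/2D-SFS.

all_sites_df <- function(table) {
  v <- table$variants
  m <- table$monomorphic
  mono_rad <- if (!is.null(m$rad_locus_id)) m$rad_locus_id
              else if (nrow(m) > 0) paste0("m", seq_len(nrow(m)))
              else character(0)
  df <- rbind(
    data.frame(chrom = v$chrom, pos = v$pos,
               rad = as.character(v$rad_locus_id),
               vidx = seq_len(nrow(v)), stringsAsFactors = FALSE),
    if (nrow(m) > 0)
      data.frame(chrom = m$chrom, pos = m$pos, rad = as.character(mono_rad),
                 vidx = NA_integer_, stringsAsFactors = FALSE))
  df[order(df$chrom, df$pos), , drop = FALSE]
}

#' Build genomic windows
#'
#' `non_overlapping` mode accumulates whole RAD loci along each chromosome
#' until a window holds at least `min_sites` sequenced sites (variant plus
#' monomorphic), then closes it; RAD loci are never split across windows.
#' A trailing window short of `min_sites` (or a chromosome with fewer than
#' `min_sites` sites altogether) is kept but flagged `undersized`.
#' `sliding` mode lays fixed-size windows at fixed steps.
#'
#' @param table a `geno_table`
#' @param min_sites minimum sequenced sites per non-overlapping window
#'   (default 2500)
#' @param mode `"non_overlapping"` or `"sliding"`
#' @param size_bp,step_bp sliding-window geometry (defaults 1 Mb / 200 kb)
#' @return data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `n_sites`, `undersized`
#' @export
build_windows <- function(table, min_sites = 2500,
                          mode = c("non_overlapping", "sliding"),
                          size_bp = 1e6, step_bp = 2e5) {
  mode <- match.arg(mode)
  sites <- all_sites_df(table)
  out <- list()
  if (mode == "sliding") {
    for (chr in unique(sites$chrom)) {
      s <- sites[sites$chrom == chr, ]
      chrlen <- max(s$pos)
      starts <- seq(1, max(1, chrlen - size_bp + 1), by = step_bp)
      for (st in starts) {
        en <- st + size_bp - 1
        n <- sum(s$pos >= st & s$pos <= en)
        out[[length(out) + 1]] <- data.frame(
          chrom = chr, start = st, end = en, n_sites = n,
          undersized = FALSE)
      }
    }
  } else {
    for (chr in unique(sites$chrom)) {
      s <- sites[sites$chrom == chr, ]
      # per-locus site counts, in coordinate order
      loci <- unique(s$rad)
      lsize <- vapply(loci, function(l) sum(s$rad == l), numeric(1))
      lstart <- vapply(loci, function(l) min(s$pos[s$rad == l]), numeric(1))
      lend <- vapply(loci, function(l) max(s$pos[s$rad == l]), numeric(1))
      acc <- 0; first <- 1
      for (i in seq_along(loci)) {
        acc <- acc + lsize[i]
        if (acc >= min_sites || i == length(loci)) {
          out[[length(out) + 1]] <- data.frame(
            chrom = chr, start = lstart[first], end = lend[i],
            n_sites = acc, undersized = acc < min_sites)
          acc <- 0; first <- i + 1
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-site FST variance components (two-level, two-allele)
#'
#' The standard unbiased two-level variance decomposition for a biallelic
#' site scored in two populations with unequal sample sizes (the
#' locus-by-locus AMOVA estimator): returns the among-population component
#' `a` as numerator and `a + b + c` as denominator per site, for later
#' ratio-of-averages aggregation. Sites monomorphic across the pair yield
#' (0, 0); sites with fewer than 2 genotyped diploids in either population
#' yield `NA`.
#'
#' @param table a `geno_table`
#' @param popmap popmap data.frame
#' @param pop_pair character vector of the two populations
#' @return data.frame: `chrom`, `pos`, `num`, `den`
#' @export
site_fst_components <- function(table, popmap, pop_pair) {
  stopifnot(length(pop_pair) == 2)
  check_popmap(table, popmap)
  pops <- pops_of(table, popmap)
  g1 <- table$geno[, pops == pop_pair[1], drop = FALSE]
  g2 <- table$geno[, pops == pop_pair[2], drop = FALSE]
  n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
  p1 <- rowSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(g1 == 1, na.rm = TRUE) / n1
  h2 <- rowSums(g2 == 1, na.rm = TRUE) / n2
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  num <- a
  den <- a + b + cc
  mono <- pbar %in% c(0, 1)
  num[mono] <- 0; den[mono] <- 0
  bad <- n1 < 2 | n2 < 2
  num[bad] <- NA; den[bad] <- NA
  data.frame(chrom = table$variants$chrom, pos = table$variants$pos,
             num = num, den = den, stringsAsFactors = FALSE)
}

#' Weighted window FST by ratio of averages
#'
#' Sums the per-site variance-component numerators and denominators over
#' each window and divides once (ratio of averages), the weighted
#' estimator that is robust to low-information sites. Windows whose summed
#' denominator is 0 get `NA`.
#'
#' @param windows window data.frame from [build_windows()]
#' @param site_components data.frame from [site_fst_components()]
#' @return `windows` with an added `fst` column
#' @export
window_weighted_fst <- function(windows, site_components) {
  sc <- site_components[!is.na(site_components$num), , drop = FALSE]
  windows$fst <- vapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    s <- sc[sc$chrom == w$chrom & sc$pos >= w$start & sc$pos <= w$end, ]
    den <- sum(s$den)
    if (nrow(s) == 0 || den == 0) return(NA_real_)
    sum(s$num) / den
  }, numeric(1))
  windows
}

# 1D folded-agnostic SFS of a window for one population (complete data)
window_acounts <- function(table, popmap, pop, w) {
  v <- table$variants
  sel <- v$chrom == w$chrom & v$pos >= w$start & v$pos <= w$end
  pops <- pops_of(table, popmap)
  rowSums(table$geno[sel, pops == pop, drop = FALSE])
}

#' Per-site nucleotide diversity of a window
#'
#' Computed through the window's 1D-SFS: with `xi_i` sites at alternate
#' count i among n haploid genomes, `pi = sum_i xi_i * 2 i (n-i) / (n (n-1))
#' / L`, where L is the window's sequenced-site count. Requires complete
#' data (subsample first); `pi` is invariant to folding.
#'
#' @param table complete-data `geno_table`
#' @param popmap popmap data.frame
#' @param windows window data.frame
#' @param pop population label
#' @return per-window numeric vector of `pi`
#' @export
window_pi <- function(table, popmap, windows, pop) {
  pops <- pops_of(table, popmap)
  n <- 2 * sum(pops == pop)
  vapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    if (w$n_sites == 0) return(NA_real_)
    ac <- window_acounts(table, popmap, pop, w)
    xi <- tabulate(ac + 1, nbins = n + 1)   # SFS including invariant classes
    ii <- 0:n
    sum(xi * 2 * ii * (n - ii) / (n * (n - 1))) / w$n_sites
  }, numeric(1))
}

#' Per-site absolute divergence (dXY) of a window
#'
#' Computed through the window's joint 2D-SFS: each site with alternate
#' counts (i, j) in populations of n1 and n2 haploid genomes contributes
#' `(i/n1)(1 - j/n2) + (j/n2)(1 - i/n1)`; the sum over sites is divided by
#' the window's sequenced-site count.
#'
#' @param table complete-data `geno_table`
#' @param popmap popmap data.frame
#' @param windows window data.frame
#' @param pop_pair two population labels
#' @return per-window numeric vector of `dxy`
#' @export
window_dxy <- function(table, popmap, windows, pop_pair) {
  stopifnot(length(pop_pair) == 2)
  pops <- pops_of(table, popmap)
  n1 <- 2 * sum(pops == pop_pair[1])
  n2 <- 2 * sum(pops == pop_pair[2])
  vapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    if (w$n_sites == 0) return(NA_real_)
    a1 <- window_acounts(table, popmap, pop_pair[1], w)
    a2 <- window_acounts(table, popmap, pop_pair[2], w)
    # joint 2D-SFS of the window
    sfs2 <- matrix(0, n1 + 1, n2 + 1)
    if (length(a1) > 0)
      for (s in seq_along(a1))
        sfs2[a1[s] + 1, a2[s] + 1] <- sfs2[a1[s] + 1, a2[s] + 1] + 1
    ii <- matrix(0:n1, n1 + 1, n2 + 1)
    jj <- matrix(0:n2, n1 + 1, n2 + 1, byrow = TRUE)
    contrib <- (ii / n1) * (1 - jj / n2) + (jj / n2) * (1 - ii / n1)
    sum(sfs2 * contrib) / w$n_sites
  }, numeric(1))
}

#' Correlate two per-window landscapes
#'
#' Pearson correlation over windows with complete values in both
#' landscapes, aligned by (chrom, start, end). For pairwise statistics
#' (FST, dXY), `pops_a`/`pops_b` declare the population pairs behind each
#' landscape; overlapping pairs are rejected, since shared populations
#' autocorrelate the two landscapes trivially.
#'
#' @param stats_a,stats_b data.frames with `chrom`, `start`, `end` and a
#'   `value` column
#' @param pops_a,pops_b populations underlying each landscape (optional for
#'   single-population statistics)
#' @param value_col name of the value column (default `"value"`)
#' @return list with `r` and `n_windows`
#' @export
correlate_landscapes <- function(stats_a, stats_b, pops_a = NULL,
                                 pops_b = NULL, value_col = "value") {
  if (!is.null(pops_a) && !is.null(pops_b) &&
      length(intersect(pops_a, pops_b)) > 0)
    stop("landscapes share population(s): ",
         paste(intersect(pops_a, pops_b), collapse = ", "),
         "; use non-overlapping population pairs")
  key_a <- paste(stats_a$chrom, stats_a$start, stats_a$end)
  key_b <- paste(stats_b$chrom, stats_b$start, stats_b$end)
  common <- intersect(key_a, key_b)
  va <- stats_a[[value_col]][match(common, key_a)]
  vb <- stats_b[[value_col]][match(common, key_b)]
  ok <- complete.cases(va, vb)
  if (sum(ok) < 3)
    return(list(r = NA_real_, n_windows = sum(ok)))
  list(r = cor(va[ok], vb[ok]), n_windows = sum(ok))
}

#' Export windows as BED
#'
#' BED uses 0-based half-open coordinates; the package's windows are
#' 1-based inclusive, so starts are shifted by one.
#'
#' @param windows window data.frame
#' @param path output path
#' @export
write_windows_bed <- function(windows, path) {
  writeLines(paste(windows$chrom, windows$start - 1, windows$end,
                   sep = "\t"), path)
  invisible(path)
}
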