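# Multidimensional site-frequency spectra. Counts are k-dimensional arrays
# indexed by per-population alternate (or minor, once folded) allele counts;
# dimension p has length n_p + 1 for n_p sampled haploid genomes. The
# monomorphic corner is part of the spectrum, so sum(counts) equals the
# number of sequenced sites.

#' Construct an SFS object
#'
#' @param counts k-dimensional numeric array (dimension p has length
#'   `n_hap[p] + 1`)
#' @param pop_order character vector of population labels, one per dimension
#' @param n_hap integer vector of haploid sample sizes
#' @param folded has the spectrum been folded to minor-allele counts?
#' @param mask optional logical array congruent with `counts`; masked cells
#'   are excluded from likelihood computations but keep their counts
#' @export
new_sfs <- function(counts, pop_order, n_hap, folded = FALSE, mask = NULL) {
  counts <- as.array(counts)
  if (length(dim(counts)) != length(pop_order))
    stop("counts dimensionality does not match pop_order")
  if (!all(dim(counts) == n_hap + 1))
    stop("dimension p of counts must have length n_hap[p] + 1")
  if (any(counts < 0)) stop("negative SFS entries")
  if (!is.null(mask) && !all(dim(mask) == dim(counts)))
    stop("mask shape mismatch")
  structure(list(counts = counts, pop_order = as.character(pop_order),
                 n_hap = as.integer(n_hap), folded = isTRUE(folded),
                 mask = mask),
            class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("%s %s-SFS over (%s), n_hap = (%s), %s sites%s\n",
              if (x$folded) "folded" else "unfolded",
              paste0(length(x$pop_order), "D"),
              paste(x$pop_order, collapse = ", "),
              paste(x$n_hap, collapse = ", "),
              format(sum(x$counts), big.mark = ","),
              if (!is.null(x$mask)) sprintf(" (%d cells masked)",
                                            sum(x$mask)) else ""))
  invisible(x)
}

#' Total number of sites in an SFS (monomorphic corner included)
#' @param x an `sfs`
#' @export
total_sites <- function(x) sum(x$counts)

# 0-based index vectors for every cell of an array with dims `d`
cell_index_grid <- function(d) {
  g <- arrayInd(seq_len(prod(d)), d) - 1L
  colnames(g) <- NULL
  g
}

#' Build a multidimensional SFS from a complete-data genotype table
#'
#' Each variant increments the cell addressed by its per-population
#' alternate-allele counts; each monomorphic registry site increments the
#' all-zero corner. The table must have no missing genotypes and constant
#' per-population sample sizes (use [subsample_genotypes()] first).
#'
#' @param table complete-data `geno_table`
#' @param popmap popmap data.frame
#' @param pop_order populations defining the SFS dimensions (default: order
#'   of appearance in the popmap)
#' @return an unfolded `sfs` (alternate allele as provisional derived state)
#' @export
sfs_from_genotypes <- function(table, popmap, pop_order = unique(popmap$pop)) {
  check_popmap(table, popmap)
  if (anyNA(table$geno[, popmap$sample[popmap$pop %in% pop_order]]))
    stop("genotype table has missing data; run subsample_genotypes() first")
  pops <- pops_of(table, popmap)
  n_hap <- unname(vapply(pop_order, function(p) 2L * sum(pops == p),
                         integer(1)))
  if (any(n_hap == 0)) stop("pop_order names a population with no samples")
  d <- n_hap + 1L
  nv <- nrow(table$variants)
  if (nv > 0) {
    ac <- vapply(pop_order, function(p)
      rowSums(table$geno[, pops == p, drop = FALSE]), numeric(nv))
    ac <- matrix(ac, nrow = nv)
    flat <- as.vector(1 + ac %*% cumprod(c(1, d[-length(d)])))
    tab <- tabulate(flat, nbins = prod(d))
  } else tab <- numeric(prod(d))
  tab[1] <- tab[1] + nrow(table$monomorphic)
  new_sfs(array(tab, dim = d), pop_order, n_hap, folded = FALSE)
}

# Fold a numeric array by the global minor allele: a cell whose total count
# exceeds half the total sample size is added to its complement; exact-half
# cells stay in place (not doubled), conserving the total.
fold_array <- function(arr, n_hap) {
  d <- dim(arr)
  grid <- cell_index_grid(d)
  tot <- rowSums(grid)
  half <- sum(n_hap) / 2
  compl <- matrix(rep(n_hap, each = nrow(grid)), nrow(grid)) - grid
  mult <- cumprod(c(1, d[-length(d)]))
  target <- ifelse(tot > half,
                   1 + as.vector(compl %*% mult),
                   seq_len(prod(d)))
  out <- numeric(prod(d))
  agg <- rowsum(as.vector(arr), target)
  out[as.integer(rownames(agg))] <- agg
  array(out, dim = d)
}

#' Fold an SFS to minor-allele counts
#'
#' Folding uses the global minor allele: the total alternate count across
#' all populations decides whether a cell is mapped onto its complement.
#' Cells at exactly half the total sample size are kept in place. The mask,
#' when present, is propagated by OR onto target cells.
#'
#' @param x an unfolded `sfs`
#' @export
fold_sfs <- function(x) {
  if (x$folded) {
    warning("SFS is already folded; returning unchanged")
    return(x)
  }
  counts <- fold_array(x$counts, x$n_hap)
  mask <- NULL
  if (!is.null(x$mask))
    mask <- fold_array(x$mask + 0, x$n_hap) > 0
  new_sfs(counts, x$pop_order, x$n_hap, folded = TRUE, mask = mask)
}

#' Marginalise an SFS onto a subset of populations
#'
#' Sums the spectrum over the dropped dimensions; the total site count is
#' conserved.
#'
#' @param x an `sfs`
#' @param keep_pops populations to retain (order defines the result's
#'   dimensions)
#' @export
marginalize_sfs <- function(x, keep_pops) {
  if (length(keep_pops) == 0) stop("keep_pops must name at least one population")
  idx <- match(keep_pops, x$pop_order)
  if (anyNA(idx)) stop("unknown population(s): ",
                       paste(keep_pops[is.na(idx)], collapse = ", "))
  counts <- apply(x$counts, idx, sum)
  if (length(idx) == 1) counts <- array(counts, dim = length(counts))
  new_sfs(counts, x$pop_order[idx], x$n_hap[idx], folded = x$folded)
}

#' Mask singleton cells of an SFS
#'
#' Cells whose index vector sums to 1 (and, for unfolded spectra, to one
#' less than the total sample size) are flagged masked. Masked cells keep
#' their counts but are excluded from composite-likelihood sums; masking is
#' idempotent.
#'
#' @param x an `sfs`
#' @export
mask_singletons <- function(x) {
  grid <- cell_index_grid(dim(x$counts))
  tot <- rowSums(grid)
  m <- tot == 1
  if (!x$folded) m <- m | tot == sum(x$n_hap) - 1
  mask <- array(m, dim = dim(x$counts))
  if (!is.null(x$mask)) mask <- mask | x$mask
  x$mask <- mask
  x
}

#' Block-bootstrap replicates of an observed SFS
#'
#' Sequenced sites (variant and monomorphic) are split, chromosome by
#' chromosome, into consecutive blocks of `block_sites` sites (the final
#' partial block forms its own block); each replicate draws as many blocks
#' with replacement as were observed and tallies their joint SFS. Block
#' resampling preserves the linkage between nearby sites that ordinary
#' site-wise resampling would destroy.
#'
#' @param table complete-data `geno_table`
#' @param popmap popmap data.frame
#' @param pop_order populations defining the SFS dimensions
#' @param block_sites sites per block (default 10000)
#' @param n_reps number of bootstrap replicates
#' @param seed RNG seed
#' @return list of `sfs` objects
#' @export
block_bootstrap_sfs <- function(table, popmap, pop_order,
                                block_sites = 10000, n_reps = 100, seed = 1) {
  base <- sfs_from_genotypes(table, popmap, pop_order)   # validates input
  d <- dim(base$counts)
  pops <- pops_of(table, popmap)
  nv <- nrow(table$variants)
  sites <- rbind(
    data.frame(chrom = table$variants$chrom, pos = table$variants$pos,
               vidx = seq_len(nv)),
    if (nrow(table$monomorphic) > 0)
      data.frame(chrom = table$monomorphic$chrom,
                 pos = table$monomorphic$pos, vidx = NA_integer_))
  sites <- sites[order(sites$chrom, sites$pos), ]
  sites$block <- unsplit(lapply(split(seq_len(nrow(sites)), sites$chrom),
                                function(i) ceiling(seq_along(i) / block_sites)),
                         sites$chrom)
  sites$block <- paste(sites$chrom, sites$block)
  blocks <- unique(sites$block)
  if (length(blocks) < 2) stop("fewer than 2 blocks: bootstrap is meaningless")
  # per-block cell tallies
  mult <- cumprod(c(1, d[-length(d)]))
  cellof <- rep(1, nrow(sites))   # monomorphic corner
  if (nv > 0) {
    ac <- vapply(pop_order, function(p)
      rowSums(table$geno[, pops == p, drop = FALSE]), numeric(nv))
    ac <- matrix(ac, nrow = nv)
    flatv <- as.vector(1 + ac %*% mult)
    cellof[!is.na(sites$vidx)] <- flatv[sites$vidx[!is.na(sites$vidx)]]
  }
  tallies <- vapply(blocks, function(b)
    tabulate(cellof[sites$block == b], nbins = prod(d)), numeric(prod(d)))
  set.seed(seed)
  lapply(seq_len(n_reps), function(r) {
    draw <- sample(length(blocks), length(blocks), replace = TRUE)
    new_sfs(array(rowSums(tallies[, draw, drop = FALSE]), dim = d),
            base$pop_order, base$n_hap, folded = FALSE)
  })
}

#' Write an SFS in the package's plain-text exchange format
#'
#' Header comment lines give population order, haploid sample sizes and the
#' folded flag; the body is the flattened count array in row-major order
#' (last population's index varying fastest).
#'
#' @param x an `sfs`
#' @param path output path
#' @export
write_sfs <- function(x, path) {
  k <- length(dim(x$counts))
  flat <- as.vector(aperm(x$counts, rev(seq_len(k))))
  writeLines(c(
    "# radpopgen SFS",
    paste("# pops:", paste(x$pop_order, collapse = " ")),
    paste("# n_hap:", paste(x$n_hap, collapse = " ")),
    paste("# folded:", x$folded),
    paste(format(flat, scientific = FALSE, trim = TRUE), collapse = " ")),
    path)
  invisible(path)
}

#' Read an SFS written by [write_sfs()]
#' @param path input path
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  getfield <- function(name) {
    ln <- meta[grepl(paste0("^# ", name, ":"), meta)]
    if (length(ln) == 0) stop("missing '", name, "' header in SFS file")
    strsplit(trimws(sub(paste0("^# ", name, ":"), "", ln[1])), "\\s+")[[1]]
  }
  pops <- getfield("pops")
  n_hap <- as.integer(getfield("n_hap"))
  folded <- as.logical(getfield("folded"))
  flat <- as.numeric(strsplit(paste(body, collapse = " "), "\\s+")[[1]])
  d <- n_hap + 1L
  counts <- aperm(array(flat, dim = rev(d)), rev(seq_along(d)))
  new_sfs(counts, pops, n_hap, folded = folded)
}
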