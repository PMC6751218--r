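# Admixture statistics: frequency-based ABBA-BABA D with weighted block
# jackknife, diagnostic SNP panels, and per-individual hybrid indices.

pop_freqs <- function(table, popmap, pop) {
  pops <- pops_of(table, popmap)
  g <- table$geno[, pops == pop, drop = FALSE]
  n <- rowSums(!is.na(g))
  ifelse(n > 0, rowSums(g, na.rm = TRUE) / (2 * n), NA_real_)
}

#' ABBA-BABA D-statistic for a population quartet
#'
#' Frequency-based D over the quartet (P1, P2; P3, Out): with derived
#' allele frequencies `p_k` per site (polarised so the outgroup carries the
#' ancestral allele),
#' `D = sum((1-p1) p2 p3 - p1 (1-p2) p3) / sum((1-p1) p2 p3 + p1 (1-p2) p3)`.
#' A positive D means excess derived-allele sharing between P2 and P3.
#' Sites where the outgroup is missing or polymorphic are dropped. The
#' standard error comes from a weighted block jackknife over `block_bp`
#' windows (weights = informative-site content per block), and `z = D/se`;
#' `|z| >= 3` is the conventional significance flag.
#'
#' @param table a `geno_table`
#' @param popmap popmap data.frame
#' @param p1,p2,p3,outgroup population labels
#' @param block_bp jackknife block size in bp (default 5e6)
#' @return list of class `quartet_result`: `labels`, `D`, `se`, `z`,
#'   `n_informative_blocks`, `n_sites_used`, `undefined` flag
#' @export
d_statistic <- function(table, popmap, p1, p2, p3, outgroup,
                        block_bp = 5e6) {
  check_popmap(table, popmap)
  f1 <- pop_freqs(table, popmap, p1)
  f2 <- pop_freqs(table, popmap, p2)
  f3 <- pop_freqs(table, popmap, p3)
  fo <- pop_freqs(table, popmap, outgroup)
  usable <- !is.na(fo) & fo %in% c(0, 1) &
    !is.na(f1) & !is.na(f2) & !is.na(f3)
  # polarise: outgroup allele is ancestral; derived frequency = 1 - match
  d1 <- ifelse(fo == 1, 1 - f1, f1)
  d2 <- ifelse(fo == 1, 1 - f2, f2)
  d3 <- ifelse(fo == 1, 1 - f3, f3)
  num <- (1 - d1) * d2 * d3 - d1 * (1 - d2) * d3
  den <- (1 - d1) * d2 * d3 + d1 * (1 - d2) * d3
  num[!usable] <- 0; den[!usable] <- 0
  tot_num <- sum(num); tot_den <- sum(den)
  if (tot_den == 0)
    return(structure(list(labels = c(p1, p2, p3, outgroup), D = NA_real_,
                          se = NA_real_, z = NA_real_,
                          n_informative_blocks = 0, n_sites_used = 0,
                          undefined = TRUE), class = "quartet_result"))
  D <- tot_num / tot_den
  block <- paste(table$variants$chrom,
                 floor((table$variants$pos - 1) / block_bp))
  bnum <- rowsum(num, block); bden <- rowsum(den, block)
  informative <- bden[, 1] > 0
  bnum <- bnum[informative, 1]; bden <- bden[informative, 1]
  g <- length(bnum)
  if (g < 2)
    return(structure(list(labels = c(p1, p2, p3, outgroup), D = D,
                          se = NA_real_, z = NA_real_,
                          n_informative_blocks = g,
                          n_sites_used = sum(usable), undefined = FALSE),
                     class = "quartet_result"))
  # weighted delete-one block jackknife (Busing et al. 1999)
  w <- bden
  n_tot <- sum(w)
  theta_j <- (tot_num - bnum) / (tot_den - bden)
  theta_dot <- g * D - sum((1 - w / n_tot) * theta_j)
  h <- n_tot / w
  var_j <- mean((h * D - (h - 1) * theta_j - theta_dot)^2 / (h - 1))
  se <- sqrt(var_j)
  structure(list(labels = c(p1, p2, p3, outgroup), D = D, se = se,
                 z = if (se > 0) D / se else NA_real_,
                 n_informative_blocks = g, n_sites_used = sum(usable),
                 undefined = FALSE),
            class = "quartet_result")
}

#' @export
print.quartet_result <- function(x, ...) {
  cat(sprintf("D(%s, %s; %s | %s) = %.4f +- %.4f (z = %.2f, %d blocks)\n",
              x$labels[1], x$labels[2], x$labels[3], x$labels[4],
              x$D, x$se, x$z, x$n_informative_blocks))
  invisible(x)
}

#' Find diagnostic SNPs divergently fixed between two parental groups
#'
#' A site qualifies when, among samples with non-missing genotypes, all
#' East-group alleles are one allele and all West-group alleles the other,
#' each group contributing at least `min_genotypes` scored diploids.
#' Qualifying sites closer than `min_spacing_bp` to the previously
#' retained site are dropped (greedy left-to-right), thinning out linked
#' markers.
#'
#' @param table a `geno_table`
#' @param popmap popmap data.frame
#' @param east_pops,west_pops population labels pooled into each parental
#'   group
#' @param min_genotypes minimum scored diploids per group per site
#'   (default 3)
#' @param min_spacing_bp minimum spacing between panel SNPs (default 1e5)
#' @return data.frame of class `diagnostic_panel`: `chrom`, `pos`,
#'   `west_allele`, `east_allele` (allele base strings)
#' @export
find_diagnostic_snps <- function(table, popmap, east_pops, west_pops,
                                 min_genotypes = 3, min_spacing_bp = 1e5) {
  check_popmap(table, popmap)
  pops <- pops_of(table, popmap)
  ge <- table$geno[, pops %in% east_pops, drop = FALSE]
  gw <- table$geno[, pops %in% west_pops, drop = FALSE]
  ne <- rowSums(!is.na(ge)); nw <- rowSums(!is.na(gw))
  se_ <- rowSums(ge, na.rm = TRUE)   # east alt-allele copies
  sw <- rowSums(gw, na.rm = TRUE)
  east_ref <- se_ == 0; east_alt <- se_ == 2 * ne
  west_ref <- sw == 0; west_alt <- sw == 2 * nw
  qual <- ne >= min_genotypes & nw >= min_genotypes &
    ((east_ref & west_alt) | (east_alt & west_ref))
  v <- table$variants
  idx <- which(qual)
  idx <- idx[order(v$chrom[idx], v$pos[idx])]
  keep <- logical(length(idx))
  last_chrom <- ""; last_pos <- -Inf
  for (i in seq_along(idx)) {
    ch <- v$chrom[idx[i]]; po <- v$pos[idx[i]]
    if (ch != last_chrom || po - last_pos >= min_spacing_bp) {
      keep[i] <- TRUE
      last_chrom <- ch; last_pos <- po
    }
  }
  idx <- idx[keep]
  if (length(idx) == 0)
    warning("no divergently fixed SNPs found; empty panel")
  panel <- data.frame(
    chrom = v$chrom[idx], pos = v$pos[idx],
    west_allele = ifelse(west_alt[idx], v$alt[idx], v$ref[idx]),
    east_allele = ifelse(west_alt[idx], v$ref[idx], v$alt[idx]),
    stringsAsFactors = FALSE)
  class(panel) <- c("diagnostic_panel", "data.frame")
  panel
}

#' Per-individual hybrid index over a diagnostic panel
#'
#' The hybrid index is the fraction of an individual's alleles of West
#' parental origin over the panel loci it is scored at: h = 0 means all
#' loci fixed for the East allele, h = 1 fixation for West alleles. For
#' divergently fixed codominant markers the allele-count fraction is the
#' exact maximum-likelihood estimator; the 95% CI is the exact binomial
#' interval on the allele count.
#'
#' @param table a `geno_table`
#' @param panel a `diagnostic_panel`
#' @param individuals sample ids to score (default: all)
#' @return data.frame: `sample`, `h`, `n_loci_scored`, `ci_lower`,
#'   `ci_upper`
#' @export
hybrid_index <- function(table, panel, individuals = NULL) {
  if (is.null(individuals)) individuals <- table$samples
  v <- table$variants
  key <- paste(v$chrom, v$pos)
  pk <- paste(panel$chrom, panel$pos)
  ridx <- match(pk, key)
  if (anyNA(ridx)) stop("panel locus missing from the genotype table")
  west_is_alt <- panel$west_allele == v$alt[ridx]
  res <- lapply(individuals, function(id) {
    ci_ <- match(id, table$samples)
    if (is.na(ci_)) stop("unknown sample ", id)
    g <- table$geno[ridx, ci_]
    scored <- !is.na(g)
    L <- sum(scored)
    if (L == 0) return(NULL)
    west <- sum(ifelse(west_is_alt[scored], g[scored], 2 - g[scored]))
    bt <- binom.test(west, 2 * L)
    data.frame(sample = id, h = west / (2 * L), n_loci_scored = L,
               ci_lower = bt$conf.int[1], ci_upper = bt$conf.int[2],
               stringsAsFactors = FALSE)
  })
  dropped <- individuals[vapply(res, is.null, logical(1))]
  if (length(dropped) > 0)
    warning("individual(s) scored at 0 panel loci excluded: ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
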