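# Genomic islands of differentiation: positional permutation tests against
# the genome-wide background, and West/East ancestry painting of
# ecotype-differentiated SNPs.

#' Read a BED file of intervals
#'
#' Converts BED's 0-based half-open intervals to the package's 1-based
#' inclusive convention.
#'
#' @param path BED file (first three columns used)
#' @return data.frame: `chrom`, `start`, `end`
#' @export
read_bed <- function(path) {
  b <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = as.character(b[[1]]), start = as.integer(b[[2]]) + 1L,
             end = as.integer(b[[3]]), stringsAsFactors = FALSE)
}

#' Write intervals as BED
#' @param intervals data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive)
#' @param path output path
#' @export
write_bed <- function(intervals, path) {
  writeLines(paste(intervals$chrom, intervals$start - 1, intervals$end,
                   sep = "\t"), path)
  invisible(path)
}

overlaps_any <- function(chrom, start, end, iv) {
  vapply(seq_along(chrom), function(i)
    any(iv$chrom == chrom[i] & iv$start <= end[i] & iv$end >= start[i]),
    logical(1))
}

#' Positional permutation test for genomic-island differentiation
#'
#' Tests whether the mean (weighted) FST of windows overlapping a set of
#' genomic islands deviates from the genome-wide expectation. Each
#' permutation relocates every island — its length preserved — to a
#' uniform position in the genome (chromosome chosen with probability
#' proportional to its length, wraparound disallowed) and recomputes the
#' mean statistic over the windows the relocated islands overlap. The
#' two-sided empirical p-value uses the add-one correction
#' `(r + 1) / (n + 1)` and is flagged at the 5% and 1% levels.
#'
#' @param window_stats window data.frame with `chrom`, `start`, `end` and
#'   the statistic column
#' @param islands interval data.frame (`chrom`, `start`, `end`)
#' @param n_perm number of permutations (default 10000)
#' @param seed RNG seed
#' @param value_col statistic column name (default `"fst"`)
#' @return list: `observed_mean`, `null_quantile` (empirical quantile of
#'   the observed mean), `p_two_sided`, `sig_05`, `sig_01`, `null` (the
#'   permutation means), `n_windows_observed`
#' @export
island_permutation_test <- function(window_stats, islands, n_perm = 10000,
                                    seed = 1, value_col = "fst") {
  stopifnot(nrow(islands) > 0)
  vals <- window_stats[[value_col]]
  ok <- !is.na(vals)
  ws <- window_stats[ok, , drop = FALSE]
  vals <- vals[ok]
  hit <- overlaps_any(ws$chrom, ws$start, ws$end, islands)
  island_has_window <- overlaps_any(islands$chrom, islands$start,
                                    islands$end, ws)
  if (any(!island_has_window))
    stop("island(s) overlapping no window: ",
         paste(sprintf("%s:%d-%d", islands$chrom[!island_has_window],
                       islands$start[!island_has_window],
                       islands$end[!island_has_window]), collapse = ", "))
  observed <- mean(vals[hit])
  chroms <- unique(ws$chrom)
  chrlen <- vapply(chroms, function(ch) max(ws$end[ws$chrom == ch]),
                   numeric(1))
  lens <- islands$end - islands$start + 1
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(r) {
    ch <- sample(chroms, length(lens), replace = TRUE,
                 prob = chrlen / sum(chrlen))
    maxstart <- pmax(1, chrlen[ch] - lens + 1)
    st <- 1 + floor(runif(length(lens)) * maxstart)
    en <- st + lens - 1
    h <- rep(FALSE, nrow(ws))
    for (i in seq_along(lens)) {
      h <- h | (ws$chrom == ch[i] & ws$start <= en[i] & ws$end >= st[i])
    }
    if (!any(h)) return(NA_real_)
    mean(vals[h])
  }, numeric(1))
  null <- null[!is.na(null)]
  n <- length(null)
  p_lo <- (sum(null <= observed) + 1) / (n + 1)
  p_hi <- (sum(null >= observed) + 1) / (n + 1)
  p <- min(1, 2 * min(p_lo, p_hi))
  list(observed_mean = observed,
       null_quantile = mean(null < observed) + 0.5 * mean(null == observed),
       p_two_sided = p, sig_05 = p < 0.05, sig_01 = p < 0.01,
       null = null, n_windows_observed = sum(hit))
}

#' Paint ecotype-differentiated SNPs by parental-lineage ancestry
#'
#' A SNP qualifies as lake-stream differentiated when the absolute
#' frequency difference between the pooled lake and pooled stream
#' populations reaches `diff_threshold`; its alleles are assigned a West
#' or East parental origin when the pooled West/East parental frequency
#' difference reaches `parental_delta`. Qualifying, assignable SNPs are
#' labelled `"blue"` when the lake ecotype carries the East-derived allele
#' and the stream ecotype the West-derived allele, `"red"` for the
#' opposite arrangement, and `"unassigned"` otherwise.
#'
#' @param table a `geno_table`
#' @param popmap popmap data.frame
#' @param lake_pops,stream_pops ecotype population labels
#' @param west_pops,east_pops parental reference population labels
#' @param diff_threshold minimum lake-stream frequency difference
#'   (default 0.5)
#' @param parental_delta minimum West-East frequency difference
#'   (default 0.9)
#' @return data.frame: `chrom`, `pos`, `pattern`, `lake_origin`,
#'   `stream_origin`
#' @export
paint_ancestry <- function(table, popmap, lake_pops, stream_pops,
                           west_pops, east_pops, diff_threshold = 0.5,
                           parental_delta = 0.9) {
  check_popmap(table, popmap)
  pooled_freq <- function(popset) {
    pops <- pops_of(table, popmap)
    g <- table$geno[, pops %in% popset, drop = FALSE]
    n <- rowSums(!is.na(g))
    ifelse(n > 0, rowSums(g, na.rm = TRUE) / (2 * n), NA_real_)
  }
  pl <- pooled_freq(lake_pops); ps <- pooled_freq(stream_pops)
  pw <- pooled_freq(west_pops); pe <- pooled_freq(east_pops)
  qualifies <- !is.na(pl) & !is.na(ps) & abs(pl - ps) >= diff_threshold
  assignable <- !is.na(pw) & !is.na(pe) & abs(pw - pe) >= parental_delta
  # allele of West origin: alt when alt is the West-frequent allele
  west_is_alt <- pw > pe
  lake_major_alt <- pl > ps       # among differentiated SNPs
  lake_origin <- stream_origin <- rep("unassigned", nrow(table$variants))
  both <- qualifies & assignable
  lake_west <- both & (lake_major_alt == west_is_alt)
  lake_origin[both] <- ifelse(lake_west[both], "West", "East")
  stream_origin[both] <- ifelse(lake_west[both], "East", "West")
  pattern <- rep("unassigned", nrow(table$variants))
  pattern[both & lake_origin == "East"] <- "blue"
  pattern[both & lake_origin == "West"] <- "red"
  out <- data.frame(chrom = table$variants$chrom,
                    pos = table$variants$pos,
                    pattern = pattern, lake_origin = lake_origin,
                    stream_origin = stream_origin,
                    stringsAsFactors = FALSE)
  out[qualifies, , drop = FALSE]
}
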