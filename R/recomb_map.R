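# Local recombination rates from a genetic map: cubic smoothing spline of
# the genetic (cM) on the physical (bp) position per chromosome; the first
# derivative, scaled to cM/Mb, is the local rate.

#' Read a genetic map
#'
#' Tab-separated columns `chrom`, `bp`, `cM`; physical positions must be
#' strictly increasing and genetic positions non-decreasing within each
#' chromosome.
#'
#' @param path input path
#' @return data.frame of class `genetic_map`
#' @export
read_genetic_map <- function(path) {
  gm <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "bp", "cM") %in% names(gm)))
  genetic_map(gm)
}

#' Validate and class a genetic map data.frame
#' @param gm data.frame with columns `chrom`, `bp`, `cM`
#' @export
genetic_map <- function(gm) {
  gm <- gm[order(gm$chrom, gm$bp), , drop = FALSE]
  for (chr in unique(gm$chrom)) {
    g <- gm[gm$chrom == chr, ]
    if (any(diff(g$bp) <= 0))
      stop("physical positions not strictly increasing on ", chr)
    if (any(diff(g$cM) < 0))
      stop("genetic positions decreasing on ", chr)
  }
  rownames(gm) <- NULL
  class(gm) <- c("genetic_map", "data.frame")
  gm
}

#' Fit per-chromosome recombination-rate splines
#'
#' Cubic smoothing spline of cM on bp for each chromosome, with the
#' smoothing parameter on the standard normalized scale of
#' [stats::smooth.spline()]'s `spar` (0 = interpolating, 1 = maximally
#' penalised); the local recombination rate is the first derivative of the
#' smoothed curve scaled to cM/Mb, with negative derivatives clipped to 0.
#'
#' @param map a `genetic_map`
#' @param smoothing spline parameter in (0, 1] (default 0.7)
#' @return object of class `rate_function`; evaluate with [rate_at()]
#' @export
fit_rate_spline <- function(map, smoothing = 0.7) {
  stopifnot(smoothing > 0, smoothing <= 1)
  fits <- lapply(split(map, map$chrom), function(g) {
    if (nrow(g) < 4)
      stop("chromosome ", g$chrom[1], " has fewer than 4 markers")
    smooth.spline(g$bp, g$cM, spar = smoothing, all.knots = TRUE,
                  keep.data = FALSE)
  })
  structure(list(fits = fits, smoothing = smoothing), class = "rate_function")
}

#' Evaluate a recombination-rate function
#'
#' @param rate_fn a `rate_function` from [fit_rate_spline()]
#' @param chrom chromosome id (scalar)
#' @param bp physical positions
#' @return rates in cM/Mb (`NA` for chromosomes absent from the map)
#' @export
rate_at <- function(rate_fn, chrom, bp) {
  fit <- rate_fn$fits[[as.character(chrom)]]
  if (is.null(fit)) return(rep(NA_real_, length(bp)))
  pmax(predict(fit, as.numeric(bp), deriv = 1)$y * 1e6, 0)
}

#' Remove sites in low-recombination regions
#'
#' Variant and monomorphic sites whose local recombination rate falls
#' below `min_rate` are removed (linked selection depresses diversity
#' disproportionately there, biasing the SFS). Sites on chromosomes absent
#' from the map are removed too, with a warning giving their number.
#'
#' @param table a `geno_table`
#' @param rate_fn a `rate_function`
#' @param min_rate minimum rate in cM/Mb (default 1.5)
#' @export
filter_low_recombination <- function(table, rate_fn, min_rate = 1.5) {
  site_rate <- function(chrom, pos) {
    r <- rep(NA_real_, length(pos))
    for (chr in unique(chrom)) {
      i <- chrom == chr
      r[i] <- rate_at(rate_fn, chr, pos[i])
    }
    r
  }
  rv <- site_rate(table$variants$chrom, table$variants$pos)
  rm_ <- site_rate(table$monomorphic$chrom, table$monomorphic$pos)
  n_unmapped <- sum(is.na(rv)) + sum(is.na(rm_))
  if (n_unmapped > 0)
    warning(n_unmapped, " site(s) on chromosomes absent from the map removed")
  out <- subset_variants(table, !is.na(rv) & rv >= min_rate)
  keep_m <- !is.na(rm_) & rm_ >= min_rate
  out$monomorphic <- out$monomorphic[keep_m, , drop = FALSE]
  rownames(out$monomorphic) <- NULL
  out
}

#' Mean recombination rate of a genomic window
#'
#' Arithmetic mean of the rate at `n_points` equally spaced positions
#' spanning the window, endpoints included.
#'
#' @param window list or one-row data.frame with `chrom`, `start`, `end`
#' @param rate_fn a `rate_function`
#' @param n_points number of evaluation points (default 10)
#' @export
window_mean_rate <- function(window, rate_fn, n_points = 10) {
  xs <- seq(window$start, window$end, length.out = n_points)
  mean(rate_at(rate_fn, window$chrom, xs))
}

#' Export a rate function as BEDGRAPH
#'
#' @param rate_fn a `rate_function`
#' @param path output path
#' @param chrom_lengths named vector of chromosome lengths
#' @param step evaluation step in bp (default 100000)
#' @export
export_bedgraph <- function(rate_fn, path, chrom_lengths, step = 1e5) {
  lines <- character(0)
  for (chr in names(chrom_lengths)) {
    starts <- seq(0, chrom_lengths[[chr]] - 1, by = step)
    ends <- pmin(starts + step, chrom_lengths[[chr]])
    mids <- (starts + ends) / 2
    r <- rate_at(rate_fn, chr, mids)
    lines <- c(lines, paste(chr, starts, ends, signif(r, 6), sep = "\t"))
  }
  writeLines(c("track type=bedGraph name=recomb_rate", lines), path)
  invisible(path)
}
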