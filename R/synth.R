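# Synthetic-data generators: RAD-like multi-population VCF cohorts under
# the catalog demographic models, diagnostic-panel admixture cohorts, and
# piecewise-linear genetic maps. Every generator is deterministic under a
# fixed seed and writes a truth record so downstream tests can compare
# generated against recovered values.

#' Specify a RAD-sequencing simulation scenario
#'
#' @param model a parameterised `dem_model` (default: the best-estimate
#'   three-lineage model); sampled demes contribute individuals
#' @param n_rad_loci number of RAD loci (default 200)
#' @param locus_length locus length in bp (default 200, i.e. 100 bp up- and
#'   downstream of a restriction site)
#' @param depth_mean,depth_dispersion negative-binomial read-depth model
#'   per genotype (mean 30, size 5)
#' @param dropout_rate probability that a locus drops out entirely in one
#'   individual (depth 0 across the locus)
#' @param locus_spacing_bp distance between restriction sites (default
#'   20 kb)
#' @param n_chrom number of chromosomes the loci are spread over
#' @param seed RNG seed
#' @export
scenario_spec <- function(model = best_estimates()$m3a, n_rad_loci = 200,
                          locus_length = 200, depth_mean = 30,
                          depth_dispersion = 5, dropout_rate = 0.05,
                          locus_spacing_bp = 2e4, n_chrom = 4, seed = 1) {
  stopifnot(n_rad_loci >= 1, locus_length >= 1, depth_mean > 0,
            dropout_rate >= 0, dropout_rate <= 1)
  structure(list(model = model, n_rad_loci = n_rad_loci,
                 locus_length = locus_length, depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 dropout_rate = dropout_rate,
                 locus_spacing_bp = locus_spacing_bp, n_chrom = n_chrom,
                 seed = seed),
            class = "scenario_spec")
}

#' Generate a RAD-like multi-population VCF under a demographic model
#'
#' Simulates one non-recombining genealogy per RAD locus under the
#' scenario's coalescent model, scatters mutations, pairs haplotypes into
#' diploid individuals, overlays negative-binomial read depths with
#' locus-wise dropout, and writes a VCF (variant records plus invariant
#' records for all remaining locus positions), a popmap and a truth file.
#' Genotypes at dropped-out loci are written as missing.
#'
#' @param spec a `scenario_spec`
#' @param dir output directory (created if needed)
#' @param prefix file name prefix (default `"scenario"`)
#' @return list: `vcf`, `popmap`, `truth` (file paths), `table` (the
#'   generated `geno_table`), `truth_record` (true parameters and per-site
#'   derived-allele frequencies)
#' @export
generate_scenario_vcf <- function(spec, dir = tempdir(),
                                  prefix = "scenario") {
  stopifnot(inherits(spec, "scenario_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- sim_rad_haplotypes(spec$model, spec$n_rad_loci, spec$locus_length,
                            seed = spec$seed)
  n_hap <- sim$n_hap
  if (any(n_hap %% 2 != 0)) stop("odd haploid sample size cannot be paired")
  n_dip <- n_hap / 2
  pop_of_ind <- rep(names(n_dip), n_dip)
  ind_names <- unlist(lapply(names(n_dip), function(p)
    paste0(p, "_", seq_len(n_dip[p]))))
  # locus coordinates: restriction sites spread over n_chrom chromosomes
  loci_chrom <- paste0("chr", 1 + (seq_len(spec$n_rad_loci) - 1) %%
                         spec$n_chrom)
  loci_idx_on_chrom <- stats::ave(seq_len(spec$n_rad_loci), loci_chrom,
                                  FUN = seq_along)
  loci_start <- 1 + (loci_idx_on_chrom - 1) * spec$locus_spacing_bp

  # mutated sites: assign distinct positions within their locus
  ca <- sim$carriers
  nmut <- nrow(ca)
  offs <- integer(nmut)
  for (l in unique(sim$locus)) {
    i <- which(sim$locus == l)
    offs[i] <- sample(spec$locus_length, length(i))
  }
  chrom <- loci_chrom[sim$locus]
  pos <- loci_start[sim$locus] + offs - 1
  # diploid dosages: pair consecutive haplotype columns
  n_ind <- sum(n_dip)
  dos <- ca[, 2 * seq_len(n_ind) - 1, drop = FALSE] +
    ca[, 2 * seq_len(n_ind), drop = FALSE]
  dos <- matrix(as.integer(dos), nrow = nmut)
  # drop sites fixed in the sample (mutation on a branch subtending all)
  seg <- rowSums(dos) > 0 & rowSums(dos) < 2 * n_ind
  # collapse duplicate positions (two mutations landing on one site)
  keyp <- paste(chrom, pos)
  seg <- seg & !duplicated(keyp)
  dos <- dos[seg, , drop = FALSE]
  chrom <- chrom[seg]; pos <- pos[seg]
  locus_of_site <- sim$locus[seg]

  # depth overlay: NB depth per genotype, whole-locus dropout per individual
  depth_l <- matrix(rnbinom(spec$n_rad_loci * n_ind,
                            mu = spec$depth_mean,
                            size = spec$depth_dispersion),
                    spec$n_rad_loci, n_ind)
  drop <- matrix(runif(spec$n_rad_loci * n_ind) < spec$dropout_rate,
                 spec$n_rad_loci, n_ind)
  depth_l[drop] <- 0L
  depth <- depth_l[locus_of_site, , drop = FALSE]
  geno <- dos
  geno[depth == 0] <- NA_integer_
  # allelic depths: binomial split for heterozygotes
  ad_alt <- matrix(0L, nrow(geno), n_ind)
  het <- which(geno == 1)
  ad_alt[het] <- rbinom(length(het), depth[het], 0.5)
  ad_alt[which(geno == 2)] <- depth[which(geno == 2)]
  ad_ref <- depth - ad_alt
  ad_ref[is.na(geno)] <- 0L; ad_alt[is.na(geno)] <- 0L

  # monomorphic registry: all locus positions not holding a variant
  mono <- do.call(rbind, lapply(seq_len(spec$n_rad_loci), function(l) {
    allpos <- loci_start[l]:(loci_start[l] + spec$locus_length - 1)
    vhere <- pos[locus_of_site == l]
    data.frame(chrom = loci_chrom[l], pos = setdiff(allpos, vhere),
               rad_locus_id = l, stringsAsFactors = FALSE)
  }))
  bases <- c("A", "C", "G", "T")
  refs <- sample(bases, length(pos), replace = TRUE)
  alts <- vapply(refs, function(r) sample(setdiff(bases, r), 1), character(1))
  tab <- geno_table(
    variants = data.frame(chrom = chrom, pos = pos, ref = refs, alt = alts,
                          rad_locus_id = locus_of_site,
                          stringsAsFactors = FALSE),
    geno = geno, depth = depth, samples = ind_names, monomorphic = mono,
    ad_ref = ad_ref, ad_alt = ad_alt)

  vcf_path <- file.path(dir, paste0(prefix, ".vcf"))
  pop_path <- file.path(dir, paste0(prefix, ".popmap"))
  truth_path <- file.path(dir, paste0(prefix, ".truth.tsv"))
  write_vcf(tab, vcf_path)
  writeLines(paste(ind_names, pop_of_ind, sep = "\t"), pop_path)
  # truth: per-site true derived-haplotype frequencies per population
  ord <- order(chrom, pos)
  freqs <- vapply(names(n_hap), function(p)
    rowSums(ca[seg, sim$leaf_pop == p, drop = FALSE]) / n_hap[p],
    numeric(sum(seg)))
  truth <- data.frame(chrom = chrom, pos = pos,
                      matrix(freqs, ncol = length(n_hap),
                             dimnames = list(NULL, paste0("freq_",
                                                          names(n_hap)))),
                      stringsAsFactors = FALSE)[ord, , drop = FALSE]
  write.table(truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth_record <- list(params = model_params(spec$model),
                       model_id = spec$model$model_id,
                       site_freqs = truth)
  list(vcf = vcf_path, popmap = pop_path, truth = truth_path,
       table = tab, truth_record = truth_record)
}

#' Generate a diagnostic-panel admixture cohort
#'
#' Builds parental reference groups fixed for opposite alleles at `n_loci`
#' panel SNPs (spaced `spacing_bp` apart) and an admixed cohort whose
#' alleles are independently of West origin with probability `west_prob` —
#' the generative model behind the hybrid-index scale.
#'
#' @param n_individuals admixed individuals (default 8)
#' @param n_loci panel size (default 299)
#' @param west_prob per-allele probability of West parental origin
#' @param seed RNG seed
#' @param n_east,n_west parental reference diploids (defaults 4 and 7)
#' @param spacing_bp panel locus spacing (default 1e5)
#' @return list: `table` (`geno_table`), `popmap`, `panel` (the generating
#'   `diagnostic_panel`), `truth` (per-individual true West fractions)
#' @export
generate_admixture_cohort <- function(n_individuals = 8, n_loci = 299,
                                      west_prob = 0.5, seed = 1,
                                      n_east = 4, n_west = 7,
                                      spacing_bp = 1e5) {
  stopifnot(west_prob >= 0, west_prob <= 1, n_loci >= 1)
  set.seed(seed)
  samples <- c(paste0("EAST_", seq_len(n_east)),
               paste0("WEST_", seq_len(n_west)),
               paste0("ADM_", seq_len(n_individuals)))
  popmap <- data.frame(
    sample = samples,
    pop = rep(c("EAST", "WEST", "ADM"), c(n_east, n_west, n_individuals)),
    stringsAsFactors = FALSE)
  # alt allele is the West allele at every panel locus
  g_east <- matrix(0L, n_loci, n_east)
  g_west <- matrix(2L, n_loci, n_west)
  g_adm <- matrix(rbinom(n_loci * n_individuals, 2, west_prob),
                  n_loci, n_individuals)
  geno <- cbind(g_east, g_west, g_adm)
  depth <- matrix(30L, n_loci, ncol(geno))
  chrom <- paste0("chr", 1 + (seq_len(n_loci) - 1) %/% 100)
  posi <- stats::ave(seq_len(n_loci), chrom, FUN = seq_along)
  pos <- 1 + (posi - 1) * spacing_bp
  tab <- geno_table(
    variants = data.frame(chrom = chrom, pos = pos, ref = "A", alt = "C",
                          rad_locus_id = seq_len(n_loci),
                          stringsAsFactors = FALSE),
    geno = geno, depth = depth, samples = samples)
  ord <- order(chrom, pos)
  panel <- data.frame(chrom = chrom[ord], pos = pos[ord],
                      west_allele = "C", east_allele = "A",
                      stringsAsFactors = FALSE)
  class(panel) <- c("diagnostic_panel", "data.frame")
  truth <- data.frame(sample = paste0("ADM_", seq_len(n_individuals)),
                      true_west_fraction = colSums(g_adm) / (2 * n_loci))
  list(table = tab, popmap = popmap, panel = panel, truth = truth,
       west_prob = west_prob)
}

#' Generate a piecewise-linear genetic map with low-recombination segments
#'
#' Each chromosome is divided into `n_segments` equal segments; a fraction
#' of them (chosen at random) recombine at `low_rate`, the rest at
#' `base_rate`. Markers every `marker_spacing` bp carry the cumulative cM
#' position plus optional Gaussian noise. The truth record gives the
#' segment boundaries and rates for recovery tests.
#'
#' @param chrom_lengths named vector of chromosome lengths in bp
#' @param base_rate background rate in cM/Mb (default 3, must exceed the
#'   1.5 cM/Mb filtering threshold)
#' @param low_rate_fraction fraction of segments at the low rate
#' @param low_rate low-recombination rate in cM/Mb (default 0.5)
#' @param marker_spacing marker spacing in bp (default 250 kb)
#' @param noise_sd marker noise in cM (default 0)
#' @param n_segments segments per chromosome (default 10)
#' @param seed RNG seed
#' @return list: `map` (a `genetic_map`), `truth` (segment table)
#' @export
generate_genetic_map <- function(chrom_lengths, base_rate = 3,
                                 low_rate_fraction = 0.3, low_rate = 0.5,
                                 marker_spacing = 2.5e5, noise_sd = 0,
                                 n_segments = 10, seed = 1) {
  stopifnot(base_rate > 1.5, low_rate < 1.5, low_rate >= 0,
            low_rate_fraction >= 0, low_rate_fraction <= 1)
  set.seed(seed)
  maps <- list(); truths <- list()
  for (chr in names(chrom_lengths)) {
    L <- chrom_lengths[[chr]]
    bounds <- round(seq(0, L, length.out = n_segments + 1))
    n_low <- round(low_rate_fraction * n_segments)
    low <- rep(FALSE, n_segments)
    if (n_low > 0) low[sample(n_segments, n_low)] <- TRUE
    rates <- ifelse(low, low_rate, base_rate)
    bp <- seq(1, L, by = marker_spacing)
    cm_at <- function(x) {
      # cumulative cM at physical position x
      seg_len <- diff(bounds)
      full <- pmax(pmin(x - bounds[-length(bounds)], seg_len), 0)
      as.vector(full %*% (rates / 1e6))
    }
    cM <- vapply(bp, cm_at, numeric(1))
    if (noise_sd > 0) {
      cM <- cM + rnorm(length(cM), 0, noise_sd)
      cM <- cummax(cM)   # keep the map monotone
    }
    maps[[chr]] <- data.frame(chrom = chr, bp = bp, cM = cM,
                              stringsAsFactors = FALSE)
    truths[[chr]] <- data.frame(
      chrom = chr, start = bounds[-length(bounds)] + 1, end = bounds[-1],
      rate = rates, stringsAsFactors = FALSE)
  }
  list(map = genetic_map(do.call(rbind, maps)),
       truth = do.call(rbind, truths))
}
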