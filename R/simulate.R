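# Expected SFS under a demographic model, via coalescent simulation.

#' Expected site-frequency spectrum under a demographic model
#'
#' Simulates `n_sims` independent single-site genealogies of the sampled
#' lineages under the structured coalescent defined by the model (splits,
#' admixture pulses, migration, ghost demes) and converts mean branch
#' lengths into per-site SFS cell probabilities: under the infinite-sites
#' model at per-site mutation rate `mu`, the probability that a site shows
#' count configuration `v` is `mu * E[L_v]`, where `L_v` is the total
#' length of branches subtending exactly `v`; the remaining mass sits in
#' the monomorphic corner. This is the expectation of scattering Poisson
#' mutations on each genealogy, computed without the Poisson noise.
#'
#' Unit conventions: deme sizes are in 2Ne units (gene copies), so the
#' within-deme pairwise coalescence rate is 1/N; forward migration of m
#' haploid genomes per generation into deme j becomes a backward
#' per-lineage jump rate m/N_j; a forward pulse replacing a percent of the
#' target becomes a backward per-lineage relocation probability a/100.
#'
#' @param model a `dem_model`
#' @param n_sims number of simulated genealogies (default 100000)
#' @param seed RNG seed (optional)
#' @param folded fold the spectrum to global minor-allele counts?
#' @param sample_hap optional named vector of haploid sample sizes per deme
#'   (default: twice the model's `n_diploids`)
#' @return object of class `expected_sfs`: probability array plus metadata
#' @export
simulate_expected_sfs <- function(model, n_sims = 1e5, seed = NULL,
                                  folded = TRUE, sample_hap = NULL) {
  stopifnot(n_sims >= 1)
  inst <- instantiate_model(model)
  if (is.null(sample_hap))
    sample_hap <- setNames(2L * inst$demes$n_diploids, inst$demes$name)
  cfg <- sim_config(inst, sample_hap)
  if (!is.null(seed)) set.seed(seed)
  acc <- coal_branch_sfs(cfg$sizes, cfg$samples, cfg$mig, cfg$events,
                         as.integer(n_sims))
  p <- inst$mu * acc
  tot <- sum(p)
  if (tot >= 1)
    stop("polymorphism probability exceeds 1: mutation rate too high for ",
         "the per-site approximation")
  p[1] <- p[1] + (1 - tot)
  d <- cfg$n_hap + 1L
  probs <- array(p, dim = d)
  if (folded) probs <- fold_array(probs, cfg$n_hap)
  structure(list(probs = probs, pop_order = cfg$sampled, n_hap = cfg$n_hap,
                 folded = folded, n_sims = n_sims,
                 model_id = model$model_id),
            class = "expected_sfs")
}

#' @export
print.expected_sfs <- function(x, ...) {
  cat(sprintf("expected %s SFS under %s over (%s), %s genealogies\n",
              if (x$folded) "folded" else "unfolded", x$model_id,
              paste(x$pop_order, collapse = ", "),
              format(x$n_sims, big.mark = ",")))
  invisible(x)
}

#' Simulate an observed SFS of a given size under a model
#'
#' Draws `n_sites` sites from the expected per-site cell probabilities
#' (multinomial sampling), mirroring a dataset of independent sequenced
#' sites of which most are monomorphic.
#'
#' @inheritParams simulate_expected_sfs
#' @param n_sites number of sequenced sites to draw
#' @return an `sfs` of counts
#' @export
simulate_sfs_counts <- function(model, n_sites, n_sims = 1e5, seed = NULL,
                                folded = TRUE, sample_hap = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ex <- simulate_expected_sfs(model, n_sims = n_sims, seed = NULL,
                              folded = folded, sample_hap = sample_hap)
  counts <- rmultinom(1, n_sites, as.vector(ex$probs))
  new_sfs(array(as.numeric(counts), dim = dim(ex$probs)), ex$pop_order,
          ex$n_hap, folded = folded)
}

#' Simulate RAD-locus haplotypes under a demographic model
#'
#' One non-recombining genealogy is drawn per RAD locus and mutations are
#' scattered on it (Poisson with rate `mu * locus_length`), so sites within
#' a locus are linked exactly as RAD sites are. Returns the derived-allele
#' carrier matrix of all mutated sites.
#'
#' @param model a `dem_model`
#' @param n_loci number of RAD loci
#' @param locus_length locus length in bp
#' @param seed RNG seed
#' @return list: `carriers` (mutations x haploid samples 0/1 matrix),
#'   `locus` (locus index per mutation), `leaf_pop` (population of each
#'   haploid sample column), `n_hap` (named haploid sample sizes)
#' @export
sim_rad_haplotypes <- function(model, n_loci, locus_length = 200,
                               seed = NULL) {
  inst <- instantiate_model(model)
  sample_hap <- setNames(2L * inst$demes$n_diploids, inst$demes$name)
  cfg <- sim_config(inst, sample_hap)
  if (!is.null(seed)) set.seed(seed)
  res <- coal_locus_mutations(cfg$sizes, cfg$samples, cfg$mig, cfg$events,
                              as.integer(n_loci), inst$mu * locus_length)
  leaf_pop <- rep(cfg$sampled, cfg$n_hap)
  list(carriers = res$carriers, locus = res$locus, leaf_pop = leaf_pop,
       n_hap = setNames(cfg$n_hap, cfg$sampled))
}
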