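# Composite likelihood, model fitting, AIC comparison, bootstrap CIs and
# model distinguishability.

fake_expected <- function(probs, pop_order = "P", folded = FALSE,
                          n_sims = 1e6) {
  probs <- as.array(probs)
  structure(list(probs = probs, pop_order = pop_order,
                 n_hap = as.integer(dim(probs) - 1), folded = folded,
                 n_sims = n_sims), class = "expected_sfs")
}

test_that("composite log10-likelihood matches direct evaluation", {
  obs <- new_sfs(array(c(60, 30, 10), dim = 3), "P", 2)
  ex <- fake_expected(array(c(0.6, 0.3, 0.1), dim = 3))
  expect_equal(composite_loglik(obs, ex),
               60 * log10(0.6) + 30 * log10(0.3) + 10 * log10(0.1),
               tolerance = 1e-12)
  expect_equal(composite_loglik(obs, ex), -38.99, tolerance = 1e-3)
  # shape mismatch is an error
  ex2 <- fake_expected(array(c(0.6, 0.3, 0.05, 0.05), dim = 4))
  expect_error(composite_loglik(obs, ex2), "shapes differ")
})

test_that("observed proportions maximise the composite likelihood", {
  set.seed(10)
  for (rep in 1:20) {
    m <- rmultinom(1, 500, runif(5))[, 1]
    obs <- new_sfs(array(m, dim = 5), "P", 4)
    ll_sat <- composite_loglik(obs, fake_expected(array(m / sum(m), dim = 5)))
    q <- runif(5); q <- q / sum(q)
    expect_gte(ll_sat, composite_loglik(obs, fake_expected(array(q, dim = 5))))
  }
})

test_that("the probability floor guards against Monte-Carlo zeros", {
  obs <- new_sfs(array(c(99, 0, 1), dim = 3), "P", 2)
  ex <- fake_expected(array(c(0.99, 0.01, 0), dim = 3), n_sims = 1e4)
  ll <- composite_loglik(obs, ex)
  expect_true(is.finite(ll))
  expect_equal(ll, 99 * log10(0.99) + 1 * log10(1 / 1e5))
})

test_that("a one-deme model refits its own simulated spectrum", {
  truth <- one_deme_model(N = 5000, n_diploids = 3)
  obs <- simulate_sfs_counts(truth, n_sites = 2e5, n_sims = 1e5, seed = 21,
                             folded = TRUE)
  start <- one_deme_model(N = 800, n_diploids = 3)   # start far from truth
  fit <- fit_model(obs, start, n_starts = 2, min_cycles = 2, max_cycles = 6,
                   n_sims = 2e4, seed = 1, line_iter = 10)
  expect_true(is.finite(fit$loglik10))
  expect_equal(unname(fit$ml_params["N"]), 5000, tolerance = 0.15)
  # aic consistency with the declared convention
  expect_equal(fit$aic, 2 * 1 - 2 * log(10) * fit$loglik10)
})

test_that("starting at the truth converges quickly to a near-truth likelihood", {
  truth <- one_deme_model(N = 4000, n_diploids = 2)
  obs <- simulate_sfs_counts(truth, n_sites = 1e5, n_sims = 5e4, seed = 22,
                             folded = TRUE)
  fit <- fit_model(obs, truth, n_starts = 1, min_cycles = 1, max_cycles = 8,
                   n_sims = 2e4, seed = 2, line_iter = 8)
  expect_true(fit$converged)
  ex_truth <- simulate_expected_sfs(truth, n_sims = 5e4, seed = 23,
                                    folded = TRUE)
  expect_gte(fit$loglik10, composite_loglik(obs, ex_truth) - 1)
})

test_that("model comparison reports delta-LL and delta-AIC as documented", {
  f1 <- structure(list(model_id = "A", loglik10 = -100, n_free_params = 3,
                       aic = 2 * 3 - 2 * log(10) * (-100)),
                  class = "fit_result")
  f2 <- structure(list(model_id = "B", loglik10 = -100, n_free_params = 4,
                       aic = 2 * 4 - 2 * log(10) * (-100)),
                  class = "fit_result")
  f3 <- structure(list(model_id = "C", loglik10 = -130, n_free_params = 3,
                       aic = 2 * 3 - 2 * log(10) * (-130)),
                  class = "fit_result")
  obs <- new_sfs(array(c(800, 150, 50), dim = 3), "P", 2)
  cmp <- compare_models(list(f1, f2, f3), obs)
  expect_equal(cmp$model[1], "A")
  expect_equal(cmp$delta_aic[1], 0)
  # equal likelihood, one extra parameter: delta-AIC of exactly 2
  expect_equal(cmp$delta_aic[cmp$model == "B"], 2)
  expect_false(is.unsorted(cmp$delta_aic))
  # delta-LL is measured from the saturated likelihood
  expect_equal(cmp$delta_ll[cmp$model == "A"],
               radpopgen:::ideal_loglik(obs) + 100)
  # AIC ordering is invariant to the saturated-likelihood offset
  expect_equal(order(cmp$delta_aic), order(cmp$aic))
})

test_that("bootstrap CIs collapse on degenerate replicates and widen with fewer blocks", {
  truth <- one_deme_model(N = 3000, n_diploids = 2)
  obs <- simulate_sfs_counts(truth, n_sites = 5e4, n_sims = 5e4, seed = 31,
                             folded = TRUE)
  # degenerate replicate set: every replicate equals the observed SFS, so
  # the percentile interval collapses onto the refitted ML point (up to
  # line-search noise)
  reps <- rep(list(obs), 20)
  ci <- suppressWarnings(
    bootstrap_ci(truth, reps, n_opts_per_rep = 2, n_sims = 1e4, seed = 1,
                 cycles = 2, line_iter = 14))
  expect_lt(ci$ci["N", "upper"] / ci$ci["N", "lower"], 1.2)
  # On linked data (RAD loci sharing genealogies), blocks much smaller than
  # a locus break the within-locus correlation and understate the
  # uncertainty; fewer, locus-spanning blocks give the wider, honest CI.
  truth <- one_deme_model(N = 20000, n_diploids = 2)
  set.seed(33)
  locus_len <- 3000; n_loci <- 60
  sim <- sim_rad_haplotypes(truth, n_loci = n_loci,
                            locus_length = locus_len, seed = 34)
  dos <- sim$carriers[, c(1, 3)] + sim$carriers[, c(2, 4)]
  seg <- rowSums(dos) > 0 & rowSums(dos) < 4
  off <- unlist(lapply(split(seq_along(sim$locus), sim$locus), function(i)
    sample(locus_len, length(i))))
  pos <- (sim$locus - 1) * locus_len + off
  seg <- seg & !duplicated(pos)
  mono <- data.frame(chrom = "chr1",
                     pos = setdiff(seq_len(n_loci * locus_len), pos[seg]))
  tab <- toy_table(matrix(as.integer(dos[seg, ]), sum(seg)),
                   pos = as.integer(pos[seg]), samples = c("i1", "i2"),
                   monomorphic = mono, rad = sim$locus[seg])
  pm <- toy_popmap(c("i1", "i2"), c("A", "A"))
  reps_small <- block_bootstrap_sfs(tab, pm, "A", block_sites = 100,
                                    n_reps = 20, seed = 35)
  reps_big <- block_bootstrap_sfs(tab, pm, "A", block_sites = 6000,
                                  n_reps = 20, seed = 36)
  ci_many <- bootstrap_ci(truth, reps_small, n_opts_per_rep = 2,
                          n_sims = 8e3, seed = 2, cycles = 2, line_iter = 12)
  ci_few <- bootstrap_ci(truth, reps_big, n_opts_per_rep = 2,
                         n_sims = 8e3, seed = 3, cycles = 2, line_iter = 12)
  width <- function(ci) diff(log(ci$ci["N", ]))
  expect_gt(width(ci_few), width(ci_many))
})

test_that("identical models are indistinguishable; a large pulse is not", {
  base <- two_deme_model(N1 = 4000, N2 = 4000, NA_ = 4000, T_ = 3000,
                         n1 = 3, n2 = 3)
  pulsed <- dem_model("big_pulse", base$demes,
                      c(base$events,
                        list(list(kind = "pulse", time = 300, source = "A",
                                  target = "B", a = 50))),
                      base$bindings)
  res_same <- model_distinguishability(
    list(m1 = base, m2 = base), n_rep_sfs = 20, n_sites = 1e5,
    n_sims = 2e4, seed = 51)
  expect_gte(res_same$misranked["m1", "m2"], 0.45)
  res_diff <- model_distinguishability(
    list(null = base, pulse = pulsed), n_rep_sfs = 20, n_sites = 1e5,
    n_sims = 2e4, seed = 52)
  expect_lte(res_diff$misranked["null", "pulse"], 0.1)
  expect_lte(res_diff$misranked["pulse", "null"], 0.1)
})

test_that("model overlap shrinks as the number of sites grows", {
  base <- two_deme_model(N1 = 4000, N2 = 4000, NA_ = 4000, T_ = 3000,
                         n1 = 3, n2 = 3)
  pulsed <- dem_model("mid_pulse", base$demes,
                      c(base$events,
                        list(list(kind = "pulse", time = 300, source = "A",
                                  target = "B", a = 25))),
                      base$bindings)
  overlap <- vapply(c(2e3, 2e4, 2e5), function(ns) {
    r <- model_distinguishability(list(null = base, pulse = pulsed),
                                  n_rep_sfs = 20, n_sites = ns,
                                  n_sims = 4e4, seed = 61)
    (r$misranked["null", "pulse"] + r$misranked["pulse", "null"]) / 2
  }, numeric(1))
  expect_gte(overlap[1], overlap[3])
  expect_lte(overlap[3], 0.2)
})
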