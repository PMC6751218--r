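# Composite-likelihood fitting of demographic models to observed SFS,
# AIC-based model comparison, block-bootstrap confidence intervals and
# model-distinguishability analysis.

check_congruent <- function(obs, expected) {
  if (!identical(dim(obs$counts), dim(expected$probs)))
    stop("observed and expected SFS shapes differ")
  if (!identical(obs$folded, expected$folded))
    stop("observed and expected SFS folding states differ")
  if (!identical(as.character(obs$pop_order),
                 as.character(expected$pop_order)))
    stop("observed and expected SFS population orders differ")
  invisible(TRUE)
}

#' Composite log10-likelihood of an observed SFS
#'
#' Treating sites as independent, the observed SFS is multinomial with the
#' expected cell probabilities: the composite log-likelihood is
#' `sum(m_i * log10(p_i))` over unmasked cells with observed counts.
#' Expected probabilities are renormalised over unmasked cells, floored at
#' `1 / (10 * n_sims)` to protect against Monte-Carlo zeros, and (with
#' `polymorphic_only = TRUE`) renormalised once more after dropping the
#' monomorphic corner.
#'
#' @param obs an `sfs` of counts (mask honoured)
#' @param expected an `expected_sfs`
#' @param floor probability floor (default `1 / (10 * expected$n_sims)`)
#' @param polymorphic_only exclude the monomorphic corner and renormalise?
#' @return composite log-likelihood in log10 units
#' @export
composite_loglik <- function(obs, expected, floor = NULL,
                             polymorphic_only = FALSE) {
  check_congruent(obs, expected)
  if (is.null(floor)) floor <- 1 / (10 * (expected$n_sims %||% 1e6))
  m <- as.vector(obs$counts)
  p <- as.vector(expected$probs)
  keep <- rep(TRUE, length(m))
  if (!is.null(obs$mask)) keep <- keep & !as.vector(obs$mask)
  if (polymorphic_only) keep[1] <- FALSE
  p <- p * keep
  s <- sum(p)
  if (s <= 0) stop("no unmasked probability mass")
  p <- p / s
  use <- keep & m > 0
  sum(m[use] * log10(pmax(p[use], floor)))
}

#' Pairwise composite log10-likelihood over joint 2D marginal spectra
#'
#' For models with several sampled populations, the full joint SFS is
#' sparse and its simulated cell probabilities noisy; the standard remedy
#' is to sum the composite log-likelihood over the joint 2D-SFS of every
#' population pair, marginalising both the observed counts and the
#' expected probabilities. `mask_singletons_flag` masks 2D cells whose
#' pair allele-count totals 1 before each pair's likelihood.
#'
#' @inheritParams composite_loglik
#' @param mask_singletons_flag mask pairwise singleton cells?
#' @return summed composite log10-likelihood over all population pairs
#' @export
composite_loglik_pairwise <- function(obs, expected, floor = NULL,
                                      mask_singletons_flag = FALSE) {
  check_congruent(obs, expected)
  k <- length(obs$pop_order)
  if (k < 2) stop("pairwise likelihood needs at least two populations")
  if (is.null(floor)) floor <- 1 / (10 * (expected$n_sims %||% 1e6))
  total <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    mo <- apply(obs$counts, c(i, j), sum)
    pe <- apply(expected$probs, c(i, j), sum)
    keep <- matrix(TRUE, nrow(mo), ncol(mo))
    if (mask_singletons_flag) {
      tot <- outer(0:(nrow(mo) - 1), 0:(ncol(mo) - 1), `+`)
      keep <- tot != 1
    }
    pe <- pe * keep
    pe <- pe / sum(pe)
    use <- keep & mo > 0
    total <- total + sum(mo[use] * log10(pmax(pe[use], floor)))
  }
  total
}

# the multinomial-saturated ("ideal") likelihood: observed proportions
ideal_loglik <- function(obs, polymorphic_only = FALSE) {
  m <- as.vector(obs$counts)
  keep <- rep(TRUE, length(m))
  if (!is.null(obs$mask)) keep <- keep & !as.vector(obs$mask)
  if (polymorphic_only) keep[1] <- FALSE
  m <- m * keep
  tot <- sum(m)
  use <- m > 0
  sum(m[use] * log10(m[use] / tot))
}

#' Profile the composite likelihood over one parameter
#'
#' Re-simulates the expected SFS at each grid value with the same seed
#' (common random numbers), holding all other parameters fixed, and
#' records the composite log10-likelihood.
#'
#' @param obs observed `sfs`
#' @param model a `dem_model`
#' @param param name of the profiled parameter
#' @param values grid of parameter values
#' @param n_sims genealogies per expected-SFS evaluation
#' @param seed RNG seed reused at every grid point
#' @param likelihood `"full"` (joint SFS) or `"pairwise"` (sum over 2D
#'   marginals, see [composite_loglik_pairwise()])
#' @param ... passed to the likelihood function
#' @return data.frame with columns `value` and `loglik10`
#' @export
profile_loglik <- function(obs, model, param, values, n_sims = 5e4,
                           seed = 1, likelihood = c("full", "pairwise"),
                           ...) {
  likelihood <- match.arg(likelihood)
  llfun <- if (likelihood == "pairwise") composite_loglik_pairwise
           else composite_loglik
  ll <- vapply(values, function(v) {
    m2 <- try(set_params(model, setNames(v, param)), silent = TRUE)
    if (inherits(m2, "try-error")) return(-Inf)   # outside the support
    ex <- simulate_expected_sfs(m2, n_sims = n_sims, seed = seed,
                                folded = obs$folded)
    llfun(obs, ex, ...)
  }, numeric(1))
  data.frame(value = values, loglik10 = ll)
}

#' Geometric profile grid around a centre value
#'
#' @param center grid centre (included as the middle point)
#' @param span half-range factor: the grid covers `center/span` to
#'   `center*span` (default 1.5)
#' @param n_points odd number of grid points (default 13)
#' @export
profile_grid <- function(center, span = 1.5, n_points = 13) {
  stopifnot(n_points %% 2 == 1, span > 1)
  center * span^seq(-1, 1, length.out = n_points)
}

#' Maximising value of a likelihood profile
#'
#' With `method = "grid"` the grid point with the highest likelihood is
#' returned. `method = "quadratic"` (the default) additionally fits a
#' parabola in log-parameter space through the points neighbouring the
#' grid maximum and returns its peak, which averages out evaluation noise
#' across the profile; the result is clipped to the grid range.
#'
#' @param profile data.frame from [profile_loglik()]
#' @param method `"quadratic"` or `"grid"`
#' @param window number of grid points around the maximum used for the
#'   quadratic fit (default 7)
#' @export
profile_estimate <- function(profile, method = c("quadratic", "grid"),
                             window = 7) {
  method <- match.arg(method)
  profile <- profile[is.finite(profile$loglik10), , drop = FALSE]
  if (nrow(profile) == 0) stop("no finite profile points")
  i_max <- which.max(profile$loglik10)
  if (method == "grid" || nrow(profile) < 4)
    return(profile$value[i_max])
  half <- (window - 1) %/% 2
  idx <- max(1, i_max - half):min(nrow(profile), i_max + half)
  x <- log(profile$value[idx])
  y <- profile$loglik10[idx]
  fit <- stats::lm(y ~ x + I(x^2))
  b <- stats::coef(fit)
  if (!is.finite(b[3]) || b[3] >= 0) return(profile$value[i_max])
  peak <- exp(-b[2] / (2 * b[3]))
  min(max(peak, min(profile$value)), max(profile$value))
}

aic_of <- function(loglik10, k) 2 * k - 2 * log(10) * loglik10

#' Profile-likelihood parameter-recovery experiment
#'
#' Simulates an observed folded SFS of `n_sites` sites under the model at
#' its current ("generating") parameter values, then re-estimates one
#' parameter by profiling the composite likelihood over a geometric grid
#' centred on the generating value, all other parameters held fixed at
#' truth. The grid centre and span are part of the experimental design:
#' the profile must bracket the generating value for the experiment to
#' measure recovery, and grid values that violate the model's event
#' ordering are treated as outside the support.
#'
#' @param model a fully parameterised `dem_model`
#' @param param name of the parameter to recover
#' @param n_sites sites in the simulated dataset (default 5e5)
#' @param seed RNG seed for the experiment
#' @param data_n_sims genealogies for the generating expected SFS
#' @param profile_n_sims genealogies per profile evaluation
#' @param span,n_points profile-grid geometry (see [profile_grid()])
#' @param mask_singletons_flag mask singleton cells before the likelihood
#'   (as done for datasets with suspected singleton artifacts)?
#' @param likelihood `"full"` or `"pairwise"`; the default follows the
#'   fitting protocol of the reconstruction: the full joint SFS up to
#'   three sampled populations, the sum over pairwise joint 2D-SFS beyond
#' @return list: `estimate` (the recovered value), `truth`, `profile`
#' @export
recovery_experiment <- function(model, param, n_sites = 5e5, seed = 1,
                                data_n_sims = 6e5, profile_n_sims = 3e5,
                                span = 1.5, n_points = 13,
                                mask_singletons_flag = FALSE,
                                likelihood = NULL) {
  truth <- model_params(model)[[param]]
  obs <- simulate_sfs_counts(model, n_sites = n_sites,
                             n_sims = data_n_sims, seed = seed,
                             folded = TRUE)
  if (is.null(likelihood))
    likelihood <- if (length(obs$pop_order) > 3) "pairwise" else "full"
  if (mask_singletons_flag && likelihood == "full")
    obs <- mask_singletons(obs)
  grid <- profile_grid(truth, span = span, n_points = n_points)
  args <- list(obs, model, param, grid, n_sims = profile_n_sims,
               seed = seed + 13, likelihood = likelihood)
  if (likelihood == "pairwise")
    args$mask_singletons_flag <- mask_singletons_flag
  pr <- do.call(profile_loglik, args)
  list(estimate = profile_estimate(pr), truth = truth, profile = pr)
}

#' Fit a demographic model to an observed SFS
#'
#' Multistart maximisation of the composite likelihood by cyclic
#' conditional maximisation: each cycle runs a bounded golden-section line
#' search over every free parameter in turn, and cycling stops when the
#' relative log10-likelihood improvement drops below `tol` (after at least
#' `min_cycles` cycles, at most `max_cycles`). Starting points are drawn
#' log-uniformly (parameters with `scale = "log"`) or uniformly within the
#' binding bounds; the first start is the model's current parameter values.
#'
#' @param obs observed `sfs`
#' @param model a `dem_model` with free parameters
#' @param n_starts number of starting parameter combinations
#' @param min_cycles,max_cycles bounds on conditional-maximisation cycles
#' @param tol relative log-likelihood stopping criterion (default 0.001)
#' @param n_sims genealogies per likelihood evaluation
#' @param seed RNG seed (controls starts and, via common random numbers,
#'   the expected-SFS evaluations)
#' @param line_iter golden-section iterations per parameter per cycle
#' @param ... passed to [composite_loglik()]
#' @return a `fit_result`: ml parameters, log10 likelihood, AIC,
#'   convergence flag
#' @export
fit_model <- function(obs, model, n_starts = 10, min_cycles = 10,
                      max_cycles = 50, tol = 1e-3, n_sims = 1e4, seed = 1,
                      line_iter = 8, ...) {
  fp <- model$bindings[model$bindings$free, , drop = FALSE]
  if (nrow(fp) == 0) stop("model has no free parameters")
  set.seed(seed)
  eval_seed <- sample.int(.Machine$integer.max, 1)
  objective <- function(pvec) {
    m2 <- try(set_params(model, setNames(pvec, fp$param)), silent = TRUE)
    if (inherits(m2, "try-error")) return(-Inf)
    ex <- try(simulate_expected_sfs(m2, n_sims = n_sims, seed = eval_seed,
                                    folded = obs$folded), silent = TRUE)
    if (inherits(ex, "try-error")) return(-Inf)
    composite_loglik(obs, ex, ...)
  }
  draw_start <- function() {
    vapply(seq_len(nrow(fp)), function(i) {
      if (fp$scale[i] == "log") {
        lo <- max(fp$lower[i], 1e-8)
        exp(runif(1, log(lo), log(fp$upper[i])))
      } else runif(1, fp$lower[i], fp$upper[i])
    }, numeric(1))
  }
  golden <- function(f, lo, hi, iters) {
    gr <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
    f1 <- f(x1); f2 <- f(x2)
    for (i in seq_len(iters)) {
      if (f1 < f2) {
        a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + gr * (b - a); f2 <- f(x2)
      } else {
        b <- x2; x2 <- x1; f2 <- f1
        x1 <- b - gr * (b - a); f1 <- f(x1)
      }
    }
    if (f1 >= f2) c(x1, f1) else c(x2, f2)
  }
  best <- list(ll = -Inf, par = NULL, converged = FALSE)
  for (s in seq_len(n_starts)) {
    par <- if (s == 1) setNames(fp$value, fp$param) else draw_start()
    ll <- objective(par)
    if (!is.finite(ll) && s == 1) next
    converged <- FALSE
    for (cycle in seq_len(max_cycles)) {
      ll_prev <- ll
      for (i in seq_len(nrow(fp))) {
        f1 <- function(x) { p2 <- par; p2[i] <- x; objective(p2) }
        res <- if (fp$scale[i] == "log") {
          lo <- max(fp$lower[i], 1e-8)
          r <- golden(function(z) f1(exp(z)), log(lo), log(fp$upper[i]),
                      line_iter)
          c(exp(r[1]), r[2])
        } else golden(f1, fp$lower[i], fp$upper[i], line_iter)
        if (is.finite(res[2]) && res[2] >= ll) {
          par[i] <- res[1]; ll <- res[2]
        }
      }
      if (cycle >= min_cycles && is.finite(ll) && is.finite(ll_prev) &&
          abs(ll - ll_prev) <= tol * abs(ll_prev)) {
        converged <- TRUE
        break
      }
    }
    if (is.finite(ll) && ll > best$ll)
      best <- list(ll = ll, par = par, converged = converged)
  }
  if (!is.finite(best$ll))
    stop("no starting point yielded a finite likelihood; check parameter ",
         "bounds and model validity")
  structure(list(model_id = model$model_id,
                 ml_params = setNames(as.numeric(best$par), fp$param),
                 loglik10 = best$ll,
                 aic = aic_of(best$ll, nrow(fp)),
                 n_free_params = nrow(fp),
                 n_starts_used = n_starts,
                 converged = best$converged),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit %s: log10 L = %.2f, AIC = %.2f, k = %d%s\n", x$model_id,
              x$loglik10, x$aic, x$n_free_params,
              if (x$converged) "" else " (not converged)"))
  print(round(x$ml_params, 4))
  invisible(x)
}

#' Compare fitted models by composite likelihood and AIC
#'
#' `delta_ll` is the log10-likelihood gap between the saturated
#' (observed-proportions) likelihood and each model; `delta_aic` is each
#' model's AIC minus the best model's (0 marks the best model). The AIC
#' convention is `AIC = 2k - 2 ln(10) * loglik10`.
#'
#' @param fits list of `fit_result`s for the same observed SFS
#' @param obs the observed `sfs` the fits were computed on
#' @param ... passed to [ideal_loglik()] (e.g. `polymorphic_only`)
#' @return data.frame sorted by increasing `delta_aic`
#' @export
compare_models <- function(fits, obs, ...) {
  stopifnot(length(fits) >= 2)
  ll_ideal <- ideal_loglik(obs, ...)
  df <- data.frame(
    model = vapply(fits, `[[`, character(1), "model_id"),
    loglik10 = vapply(fits, `[[`, numeric(1), "loglik10"),
    k = vapply(fits, `[[`, numeric(1), "n_free_params"),
    aic = vapply(fits, `[[`, numeric(1), "aic"))
  df$delta_ll <- ll_ideal - df$loglik10
  df$delta_aic <- df$aic - min(df$aic)
  df[order(df$delta_aic), , drop = FALSE]
}

#' Block-bootstrap confidence intervals for fitted parameters
#'
#' For every bootstrap SFS replicate, `n_opts_per_rep` short conditional-
#' maximisation runs are started from the maximum-likelihood parameters
#' (each multiplicatively perturbed); the best run's parameters enter the
#' empirical 2.5/97.5 percentile interval.
#'
#' @param obs_model `dem_model` with values at the ML fit
#' @param bootstrap_sfs list of bootstrap `sfs` replicates (see
#'   [block_bootstrap_sfs()])
#' @param n_opts_per_rep optimisations per replicate (default 10)
#' @param perturb relative sd of the multiplicative start perturbation
#' @param n_sims,seed,cycles,line_iter optimisation controls
#' @param ... passed to [composite_loglik()]
#' @return list: `ci` (parameter x (lower, upper) matrix), `estimates`
#'   (replicates x parameters), `n_replicates`
#' @export
bootstrap_ci <- function(obs_model, bootstrap_sfs, n_opts_per_rep = 10,
                         perturb = 0.1, n_sims = 5e3, seed = 1, cycles = 3,
                         line_iter = 5, ...) {
  if (length(bootstrap_sfs) < 20)
    warning("fewer than 20 bootstrap replicates: percentile CIs unstable")
  fp <- obs_model$bindings[obs_model$bindings$free, , drop = FALSE]
  set.seed(seed)
  est <- matrix(NA_real_, length(bootstrap_sfs), nrow(fp),
                dimnames = list(NULL, fp$param))
  for (r in seq_along(bootstrap_sfs)) {
    o <- bootstrap_sfs[[r]]
    best_ll <- -Inf
    for (j in seq_len(n_opts_per_rep)) {
      start <- fp$value * exp(rnorm(nrow(fp), 0, perturb))
      start <- pmin(pmax(start, fp$lower), fp$upper)
      m2 <- set_params(obs_model, setNames(start, fp$param), check = FALSE)
      fit <- try(fit_model(o, m2, n_starts = 1, min_cycles = 1,
                           max_cycles = cycles, n_sims = n_sims,
                           seed = sample.int(1e8, 1),
                           line_iter = line_iter, ...), silent = TRUE)
      if (!inherits(fit, "try-error") && fit$loglik10 > best_ll) {
        best_ll <- fit$loglik10
        est[r, ] <- fit$ml_params
      }
    }
  }
  ci <- t(apply(est, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE))
  colnames(ci) <- c("lower", "upper")
  list(ci = ci, estimates = est, n_replicates = length(bootstrap_sfs))
}

#' Distinguishability of demographic models
#'
#' Simulates `n_rep_sfs` datasets under every model (at its current
#' parameter values), evaluates each dataset's composite likelihood under
#' every model, and reports the pairwise overlap of the likelihood
#' distributions: entry (g, m) of `misranked` is the fraction of datasets
#' generated under model g whose likelihood under model m is at least as
#' high as under g. High off-diagonal values mean the pair cannot be told
#' apart at this data size.
#'
#' @param models named list of parameterised `dem_model`s
#' @param n_rep_sfs replicate datasets per model (default 100)
#' @param n_sites sites per simulated dataset
#' @param n_sims genealogies per expected SFS
#' @param seed RNG seed
#' @param folded fold the spectra?
#' @return list: `logliks` (generator x replicate x scorer array),
#'   `misranked` (generator x scorer matrix)
#' @export
model_distinguishability <- function(models, n_rep_sfs = 100, n_sites = 1e5,
                                     n_sims = 2e4, seed = 1, folded = TRUE) {
  stopifnot(length(models) >= 2)
  if (is.null(names(models)))
    names(models) <- vapply(models, `[[`, character(1), "model_id")
  set.seed(seed)
  seeds <- sample.int(1e8, length(models) * (1 + n_rep_sfs))
  expected <- lapply(seq_along(models), function(i)
    simulate_expected_sfs(models[[i]], n_sims = n_sims, seed = seeds[i],
                          folded = folded))
  nm <- length(models)
  ll <- array(NA_real_, c(nm, n_rep_sfs, nm),
              dimnames = list(names(models), NULL, names(models)))
  k <- nm
  for (g in seq_len(nm)) {
    for (r in seq_len(n_rep_sfs)) {
      k <- k + 1
      set.seed(seeds[k])
      counts <- rmultinom(1, n_sites, as.vector(expected[[g]]$probs))
      obs <- new_sfs(array(as.numeric(counts),
                           dim = dim(expected[[g]]$probs)),
                     expected[[g]]$pop_order, expected[[g]]$n_hap,
                     folded = folded)
      for (m in seq_len(nm))
        ll[g, r, m] <- composite_loglik(obs, expected[[m]])
    }
  }
  mis <- matrix(NA_real_, nm, nm, dimnames = list(names(models),
                                                  names(models)))
  for (g in seq_len(nm)) for (m in seq_len(nm))
    mis[g, m] <- mean(ll[g, , m] >= ll[g, , g])
  list(logliks = ll, misranked = mis)
}
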