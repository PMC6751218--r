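# Demographic models: demes, split/pulse/migration events, and free/fixed
# parameter bindings. Units follow the reporting convention of the model
# catalog: population sizes N_i in 2Ne units (gene copies, so the pairwise
# coalescence rate in a deme of size N is 1/N per generation), times in
# generations before present, admixture pulses a_ij in percent of the
# target population, and migration m_ij in 2Ne*m units, i.e. number of
# haploid migrant genomes per generation, forward in time. Backward
# conversions for the simulator are documented in `sim_config()`.

DEFAULT_MU <- 1.7e-8

#' Construct a demographic model
#'
#' @param model_id short identifier (e.g. `"3a"`, `"HOci"`)
#' @param demes data.frame with columns `name`, `size` (numeric or the name
#'   of a bound parameter), `n_diploids` (default number of sampled diploid
#'   genotypes; 0 marks an unsampled "ghost" deme)
#' @param events list of event lists:
#'   * `list(kind = "split", time, child, parent)` — forward in time, deme
#'     `child` originates from `parent` at `time`;
#'   * `list(kind = "pulse", time, source, target, a)` — at `time`, `a`
#'     percent of `target` is replaced by migrants from `source`;
#'   * `list(kind = "migration", t_start, t_end, from, to, m)` — during the
#'     (backward-time) interval, `m` haploid genomes per generation move
#'     from `from` into `to` (forward); `t_end = NA` extends the epoch to
#'     the end of both demes' existence.
#'   `time`, `a` and `m` entries may name bound parameters.
#' @param bindings data.frame with columns `param`, `value`, `lower`,
#'   `upper`, `free`, `scale` (`"log"` or `"linear"`, used for random
#'   restarts)
#' @param mu per-site per-generation mutation rate
#' @param description free-text note (interpretive choices are flagged here)
#' @return object of class `dem_model`
#' @export
dem_model <- function(model_id, demes, events, bindings,
                      mu = DEFAULT_MU, description = "") {
  demes <- as.data.frame(demes)
  stopifnot(all(c("name", "size", "n_diploids") %in% names(demes)))
  if (anyDuplicated(demes$name)) stop("duplicate deme names")
  bindings <- as.data.frame(bindings)
  if (nrow(bindings) > 0 && anyDuplicated(bindings$param))
    stop("duplicate parameter names in bindings")
  m <- structure(list(model_id = model_id, demes = demes, events = events,
                      bindings = bindings, mu = mu,
                      description = description),
                 class = "dem_model")
  instantiate_model(m)   # validates
  m
}

#' @export
print.dem_model <- function(x, ...) {
  ghost <- sum(x$demes$n_diploids == 0)
  cat(sprintf("dem_model %s: %d demes (%d ghost), %d events, %d free parameters\n",
              x$model_id, nrow(x$demes), ghost, length(x$events),
              n_free_params(x)))
  if (nzchar(x$description)) cat(" ", x$description, "\n")
  invisible(x)
}

binding_row <- function(param, value, lower, upper, free = TRUE,
                        scale = "log") {
  data.frame(param = param, value = value, lower = lower, upper = upper,
             free = free, scale = scale, stringsAsFactors = FALSE)
}

#' Named vector of a model's current parameter values
#' @param model a `dem_model`
#' @export
model_params <- function(model) {
  setNames(model$bindings$value, model$bindings$param)
}

#' Number of free parameters (the k of the AIC)
#' @param model a `dem_model`
#' @export
n_free_params <- function(model) sum(model$bindings$free)

#' Update bound parameter values
#' @param model a `dem_model`
#' @param params named numeric vector
#' @param check validate the updated model (set FALSE inside optimisers that
#'   handle invalid proposals themselves)
#' @export
set_params <- function(model, params, check = TRUE) {
  idx <- match(names(params), model$bindings$param)
  if (anyNA(idx))
    stop("unknown parameter(s): ", paste(names(params)[is.na(idx)],
                                         collapse = ", "))
  model$bindings$value[idx] <- as.numeric(params)
  if (check) instantiate_model(model)
  model
}

resolve_value <- function(x, params) {
  if (is.character(x)) {
    if (!x %in% names(params)) stop("unbound parameter reference: ", x)
    unname(params[x])
  } else as.numeric(x)
}

#' Resolve all parameter references of a model to numbers
#'
#' Returns a fully numeric internal representation (and validates it):
#' deme sizes positive; pulse proportions within [0, 100]; every deme
#' reachable from a single root through the split events; pulses and
#' migration epochs confined to the lifetime of the demes they touch.
#'
#' @param model a `dem_model`
#' @keywords internal
instantiate_model <- function(model) {
  p <- model_params(model)
  demes <- model$demes
  demes$size <- vapply(demes$size, resolve_value, numeric(1), params = p)
  if (any(demes$size <= 0)) stop("deme sizes must be positive")
  ev <- lapply(model$events, function(e) {
    e2 <- e
    for (f in intersect(names(e), c("time", "t_start", "t_end", "a", "m")))
      if (!is.null(e[[f]]) && !is.na(e[[f]]))
        e2[[f]] <- resolve_value(e[[f]], p)
    e2
  })
  dn <- demes$name
  # deme lifetime: alive on [0, end_time); root alive forever
  end_time <- setNames(rep(Inf, length(dn)), dn)
  parent_of <- setNames(rep(NA_character_, length(dn)), dn)
  for (e in ev) {
    if (e$kind != "split") next
    if (!e$child %in% dn || !e$parent %in% dn)
      stop("split references unknown deme")
    if (!is.na(parent_of[e$child]))
      stop("deme ", e$child, " is the child of two splits")
    if (e$time < 0) stop("negative event time")
    parent_of[e$child] <- e$parent
    end_time[e$child] <- e$time
  }
  roots <- dn[is.na(parent_of)]
  if (length(roots) != 1)
    stop("model must have exactly one root deme (found: ",
         paste(roots, collapse = ", "), ")")
  # ancestors must outlive children
  for (d in dn) {
    if (!is.na(parent_of[d]) && end_time[parent_of[d]] < end_time[d])
      stop("deme ", parent_of[d], " ends before its child ", d)
  }
  for (e in ev) {
    if (e$kind == "pulse") {
      if (e$a < 0 || e$a > 100)
        stop("pulse proportion must lie in [0, 100] (got ", e$a, ")")
      if (e$time < 0) stop("negative event time")
      if (e$time > min(end_time[e$source], end_time[e$target]))
        stop("pulse at t=", e$time, " outlives deme ", e$source, " or ",
             e$target)
    } else if (e$kind == "migration") {
      if (e$m < 0) stop("negative migration rate")
      lim <- min(end_time[e$from], end_time[e$to])
      if (is.na(e$t_end)) e$t_end <- lim
      if (e$t_end > lim)
        stop("migration epoch outlives deme ", e$from, " or ", e$to)
      if (e$t_start >= e$t_end) stop("empty migration epoch")
    } else if (!e$kind %in% c("split")) stop("unknown event kind: ", e$kind)
  }
  list(model_id = model$model_id, demes = demes, events = ev, mu = model$mu,
       end_time = end_time, root = roots)
}

# Build the low-level simulator configuration. Backward-time conversions:
#  - a forward split (child from parent at T) moves, backward, all child
#    lineages into the parent at T;
#  - a forward pulse replacing a% of `target` with `source` migrants moves,
#    backward, each target lineage into `source` with probability a/100;
#  - forward migration of m haploid genomes per generation into deme j
#    replaces a fraction m / N_j of j per generation, so backward each
#    lineage in j jumps to the source at rate m / N_j.
sim_config <- function(inst, sample_hap) {
  dn <- inst$demes$name
  nd <- length(dn)
  di <- setNames(seq_len(nd) - 1L, dn)     # 0-based for C++
  sizes <- inst$demes$size
  samples <- as.integer(sample_hap[dn])
  samples[is.na(samples)] <- 0L
  mig0 <- matrix(0, nd, nd)
  rows <- list()
  add <- function(time, kind, d1, d2, x)
    rows[[length(rows) + 1]] <<- c(time, kind, d1, d2, x)
  for (e in inst$events) {
    if (e$kind == "split") {
      add(e$time, 1, di[e$child], di[e$parent], 0)
    } else if (e$kind == "pulse") {
      add(e$time, 2, di[e$target], di[e$source], e$a / 100)
    } else if (e$kind == "migration") {
      t_end <- e$t_end
      if (is.na(t_end))
        t_end <- min(inst$end_time[e$from], inst$end_time[e$to])
      # forward from -> to  ==>  backward: lineages in `to` jump to `from`
      rate_to <- e$m / sizes[di[e$to] + 1]
      if (e$t_start == 0) mig0[di[e$to] + 1, di[e$from] + 1] <-
          mig0[di[e$to] + 1, di[e$from] + 1] + rate_to
      else add(e$t_start, 3, di[e$to], di[e$from], rate_to)
      if (is.finite(t_end)) add(t_end, 3, di[e$to], di[e$from], 0)
    }
  }
  if (length(rows) > 0) {
    em <- do.call(rbind, rows)
    # rate changes first, then pulses, then splits at equal times
    kind_rank <- c(`1` = 3, `2` = 2, `3` = 1, `4` = 1)
    em <- em[order(em[, 1], kind_rank[as.character(em[, 2])]), , drop = FALSE]
  } else em <- matrix(numeric(0), 0, 5)
  list(sizes = sizes, samples = samples, mig = mig0, events = em,
       sampled = dn[samples > 0], n_hap = samples[samples > 0])
}

#' Serialise a demographic model to a YAML file
#' @param model a `dem_model`
#' @param path output path
#' @export
write_model_yaml <- function(model, path) {
  yaml::write_yaml(list(
    model_id = model$model_id, mu = model$mu,
    description = model$description,
    demes = lapply(seq_len(nrow(model$demes)), function(i)
      as.list(model$demes[i, ])),
    events = model$events,
    bindings = lapply(seq_len(nrow(model$bindings)), function(i)
      as.list(model$bindings[i, ]))), path)
  invisible(path)
}

#' Read a demographic model written by [write_model_yaml()]
#' @param path input path
#' @export
read_model_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  dem_model(y$model_id,
            do.call(rbind, lapply(y$demes, as.data.frame)),
            y$events,
            do.call(rbind, lapply(y$bindings, as.data.frame)),
            mu = y$mu, description = y$description %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
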