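# The hierarchical model catalog for lake-stream ecotype divergence between
# an East European (Vistula) and two West European (upper Rhone, Rhine)
# stickleback lineages:
#
#   level 1 (trios, 3D-SFS):       3a (West clade), 3b, 3c (alternative
#                                  rooted trios), 3d (trichotomy)
#   level 2/3 (quartets, 4D-SFS):  3L*/3S* — one Constance lake or stream
#                                  population attached to lineage o/i/v,
#                                  optionally receiving admixture pulses
#                                  from Rhone ('o'), Rhine ('i') or both ('x')
#   level 4 (lake-stream pairs):   PD (primary divergence), EVa/EVb
#                                  (ecological vicariance), SCi/SCo
#                                  (secondary contact), HO{a,b,c}{x,i,o}
#                                  (hybrid origin: pulse into the stream,
#                                  the lake, or their common ancestor)
#
# The a/b/c pulse targets and the 3b/3c/3d and EV reconstructions are
# interpretive choices (the original alternative topologies are only shown
# in supplementary material); they are isolated here so they can be edited
# without touching the simulator.

SIZE_BOUNDS <- c(100, 1e6)
TIME_BOUNDS <- c(1, 2e4)

size_binding <- function(param, value)
  binding_row(param, value, SIZE_BOUNDS[1], SIZE_BOUNDS[2], scale = "log")
time_binding <- function(param, value)
  binding_row(param, value, TIME_BOUNDS[1], TIME_BOUNDS[2], scale = "log")
prop_binding <- function(param, value)
  binding_row(param, value, 0, 100, scale = "linear")
mig_binding <- function(param, value)
  binding_row(param, value, 0, 20, scale = "linear")

deme_row <- function(name, size, n_diploids = 0)
  data.frame(name = name, size = size, n_diploids = n_diploids,
             stringsAsFactors = FALSE)

# European lineage demes shared by all models. Sizes for these lineages are
# not part of the encoded reconstruction; defaults encode old riverine lineages
# with larger effective sizes than the recently founded lake populations.
lineage_demes <- function(n_rhone = 4, n_rhine = 3, n_vistula = 4) {
  rbind(deme_row("Rhone", "N_RHONE", n_rhone),
        deme_row("Rhine", "N_RHINE", n_rhine),
        deme_row("Vistula", "N_VISTULA", n_vistula))
}

lineage_bindings <- function() {
  rbind(size_binding("N_RHONE", 8000),
        size_binding("N_RHINE", 10000),
        size_binding("N_VISTULA", 12000))
}

#' Three-population lineage models (3a-3d)
#'
#' `3a` groups the two West European lineages (Rhone, Rhine) against the
#' East European Vistula lineage; `3b` and `3c` are the two alternative
#' rooted trios; `3d` is a simultaneous three-way split.
#'
#' @param topology one of `"3a"`, `"3b"`, `"3c"`, `"3d"`
#' @param n_rhone,n_rhine,n_vistula sampled diploids per lineage
#' @export
model_trio <- function(topology = c("3a", "3b", "3c", "3d"),
                       n_rhone = 4, n_rhine = 3, n_vistula = 4) {
  topology <- match.arg(topology)
  demes <- rbind(lineage_demes(n_rhone, n_rhine, n_vistula),
                 if (topology != "3d") deme_row("Anc1", "N_ANC1"),
                 deme_row("Root", "N_ROOT"))
  b <- rbind(lineage_bindings(),
             if (topology != "3d") size_binding("N_ANC1", 10000),
             size_binding("N_ROOT", 12000),
             time_binding("T_DEEP", 3665),
             if (topology != "3d") time_binding("T_SHALLOW", 1710))
  clade <- switch(topology, `3a` = c("Rhone", "Rhine"),
                  `3b` = c("Rhone", "Vistula"), `3c` = c("Rhine", "Vistula"),
                  `3d` = NULL)
  if (topology == "3d") {
    ev <- lapply(c("Rhone", "Rhine", "Vistula"), function(d)
      list(kind = "split", time = "T_DEEP", child = d, parent = "Root"))
  } else {
    outsider <- setdiff(c("Rhone", "Rhine", "Vistula"), clade)
    ev <- c(lapply(clade, function(d)
      list(kind = "split", time = "T_SHALLOW", child = d, parent = "Anc1")),
      list(list(kind = "split", time = "T_DEEP", child = "Anc1",
                parent = "Root"),
           list(kind = "split", time = "T_DEEP", child = outsider,
                parent = "Root")))
  }
  dem_model(topology, demes, ev, b,
            description = switch(topology,
              `3a` = "West clade (Rhone,Rhine) vs Vistula",
              `3d` = "simultaneous trichotomy (interpretive)",
              "alternative rooted trio (interpretive)"))
}

#' Four-population models: one focal population attached to a lineage
#'
#' The focal (Constance lake or stream) population splits from lineage
#' `source` at `T_COL`; the `admix` suffix optionally adds admixture pulses
#' from the Rhine (`"i"`), the Rhone (`"o"`) or both (`"x"`).
#'
#' @param focal focal population name (e.g. `"NID"`)
#' @param source majority-origin lineage: `"o"` Rhone, `"i"` Rhine, `"v"` Vistula
#' @param admix `"none"`, `"i"`, `"o"` or `"x"`
#' @param kind `"L"` (lake) or `"S"` (stream); only affects the model id
#' @param n_focal sampled diploids of the focal population
#' @export
model_quartet <- function(focal, source = c("v", "o", "i"),
                          admix = c("none", "x", "i", "o"),
                          kind = c("L", "S"), n_focal = 6) {
  source <- match.arg(source)
  admix <- match.arg(admix)
  kind <- match.arg(kind)
  src_deme <- c(o = "Rhone", i = "Rhine", v = "Vistula")[source]
  id <- paste0("3", kind, source, if (admix == "none") "" else admix)
  demes <- rbind(lineage_demes(),
                 deme_row(focal, "N_FOCAL", n_focal),
                 deme_row("WAnc", "N_WANC"),
                 deme_row("Root", "N_ROOT"))
  ev <- list(
    list(kind = "split", time = "T_COL", child = focal, parent = src_deme),
    list(kind = "split", time = "T_OI", child = "Rhone", parent = "WAnc"),
    list(kind = "split", time = "T_OI", child = "Rhine", parent = "WAnc"),
    list(kind = "split", time = "T_WE", child = "WAnc", parent = "Root"),
    list(kind = "split", time = "T_WE", child = "Vistula", parent = "Root"))
  b <- rbind(lineage_bindings(),
             size_binding("N_FOCAL", 5000),
             size_binding("N_WANC", 10000),
             size_binding("N_ROOT", 12000),
             time_binding("T_COL", 1500),
             time_binding("T_OI", 1710),
             time_binding("T_WE", 3665))
  if (admix %in% c("i", "x")) {
    ev <- c(ev, list(list(kind = "pulse", time = "T_ADM_I", source = "Rhine",
                          target = focal, a = "A_I")))
    b <- rbind(b, prop_binding("A_I", 10), time_binding("T_ADM_I", 100))
  }
  if (admix %in% c("o", "x")) {
    ev <- c(ev, list(list(kind = "pulse", time = "T_ADM_O", source = "Rhone",
                          target = focal, a = "A_O")))
    b <- rbind(b, prop_binding("A_O", 10), time_binding("T_ADM_O", 110))
  }
  dem_model(id, demes, ev, b,
            description = paste0("focal ", focal, " from ", src_deme,
                                 if (admix != "none")
                                   paste0(" + pulse(s) '", admix, "'")))
}

#' Five-population lake-stream mode-of-divergence models
#'
#' Encodes the four competing modes of ecotype divergence for one
#' lake-stream pair embedded in the three-lineage European background:
#' * `PD` — primary divergence: lake and stream split from a single
#'   East-derived colonising population, with lake-stream migration;
#' * `EVa`/`EVb` — ecological vicariance: the stream is colonised first;
#'   the lake population derives from the stream (`a`) or from a second
#'   colonisation by the same lineage (`b`);
#' * `SCi`/`SCo` — secondary contact: the stream *is* the Rhine (`i`) or
#'   Rhone (`o`) lineage, meeting the East-derived lake with gene flow;
#' * `HO{a,b,c}{x,i,o}` — hybrid origin: the lake-stream pair splits from
#'   an East-derived ancestor, and admixture pulse(s) from the Rhine
#'   (`i`), the Rhone (`o`) or both (`x`) enter the stream (`a`), the lake
#'   (`b`) or their common ancestor (`c`).
#'
#' By default the three European lineages are unsampled (ghost) demes, as
#' in fitting a lake-stream joint 2D-SFS; pass positive lineage sample
#' sizes to expose them.
#'
#' @param mode one of `"PD"`, `"EVa"`, `"EVb"`, `"SCi"`, `"SCo"`, or
#'   `"HO"` combined with `ho_target`/`ho_source`
#' @param lake,stream population names
#' @param ho_target `"a"` stream, `"b"` lake, `"c"` common ancestor
#' @param ho_source `"x"` both, `"i"` Rhine, `"o"` Rhone
#' @param n_lake,n_stream sampled diploids
#' @param n_lineages sampled diploids per European lineage (0 = ghost)
#' @export
model_pair <- function(mode = c("PD", "EVa", "EVb", "SCi", "SCo", "HO"),
                       lake = "L2", stream = "S2",
                       ho_target = c("a", "b", "c"),
                       ho_source = c("x", "i", "o"),
                       n_lake = 6, n_stream = 6, n_lineages = c(0, 0, 0)) {
  mode <- match.arg(mode)
  ho_target <- match.arg(ho_target)
  ho_source <- match.arg(ho_source)
  id <- if (mode == "HO") paste0("HO", ho_target, ho_source) else mode
  has_canc <- mode %in% c("PD", "HO")
  demes <- rbind(lineage_demes(n_lineages[1], n_lineages[2], n_lineages[3]),
                 deme_row(lake, "N_LAKE", n_lake),
                 deme_row(stream, "N_STREAM", n_stream),
                 if (has_canc) deme_row("CAnc", "N_CANC"),
                 deme_row("WAnc", "N_WANC"),
                 deme_row("Root", "N_ROOT"))
  base_ev <- list(
    list(kind = "split", time = "T_OI", child = "Rhone", parent = "WAnc"),
    list(kind = "split", time = "T_OI", child = "Rhine", parent = "WAnc"),
    list(kind = "split", time = "T_WE", child = "WAnc", parent = "Root"),
    list(kind = "split", time = "T_WE", child = "Vistula", parent = "Root"))
  b <- rbind(lineage_bindings(),
             size_binding("N_LAKE", 5000),
             size_binding("N_STREAM", 5000),
             if (has_canc) size_binding("N_CANC", 5000),
             size_binding("N_WANC", 10000),
             size_binding("N_ROOT", 12000),
             time_binding("T_OI", 1710),
             time_binding("T_WE", 3665),
             time_binding("T_COL", 1500),
             time_binding("T_LS", 500),
             mig_binding("M_LS", 1),
             mig_binding("M_SL", 1))
  mig_ev <- list(
    list(kind = "migration", t_start = 0, t_end = NA, from = lake,
         to = stream, m = "M_LS"),
    list(kind = "migration", t_start = 0, t_end = NA, from = stream,
         to = lake, m = "M_SL"))
  if (mode == "PD" || mode == "HO") {
    ev <- c(base_ev, mig_ev, list(
      list(kind = "split", time = "T_COL", child = "CAnc", parent = "Vistula"),
      list(kind = "split", time = "T_LS", child = lake, parent = "CAnc"),
      list(kind = "split", time = "T_LS", child = stream, parent = "CAnc")))
  } else if (mode == "EVa") {
    ev <- c(base_ev, mig_ev, list(
      list(kind = "split", time = "T_COL", child = stream, parent = "Vistula"),
      list(kind = "split", time = "T_LS", child = lake, parent = stream)))
  } else if (mode == "EVb") {
    ev <- c(base_ev, mig_ev, list(
      list(kind = "split", time = "T_COL", child = stream, parent = "Vistula"),
      list(kind = "split", time = "T_LS", child = lake, parent = "Vistula")))
  } else {  # secondary contact
    src <- if (mode == "SCi") "Rhine" else "Rhone"
    ev <- c(base_ev, mig_ev, list(
      list(kind = "split", time = "T_COL", child = lake, parent = "Vistula"),
      list(kind = "split", time = "T_LS", child = stream, parent = src)))
  }
  if (mode == "HO") {
    target <- switch(ho_target, a = stream, b = lake, c = "CAnc")
    if (ho_source %in% c("i", "x")) {
      ev <- c(ev, list(list(kind = "pulse", time = "T_ADM_I",
                            source = "Rhine", target = target, a = "A_I")))
      b <- rbind(b, prop_binding("A_I", 20), time_binding("T_ADM_I", 250))
    }
    if (ho_source %in% c("o", "x")) {
      ev <- c(ev, list(list(kind = "pulse", time = "T_ADM_O",
                            source = "Rhone", target = target, a = "A_O")))
      b <- rbind(b, prop_binding("A_O", 20), time_binding("T_ADM_O", 260))
    }
    if (ho_target == "c") {
      # ancestor pulses happen between the lake-stream split and colonisation
      b$value[b$param %in% c("T_ADM_I", "T_ADM_O")] <- c(950, 960)[
        seq_len(sum(b$param %in% c("T_ADM_I", "T_ADM_O")))]
    }
  }
  dem_model(id, demes, ev, b,
            description = paste0(lake, "-", stream, " ", mode,
                                 if (mode == "HO")
                                   paste0(" target=", ho_target,
                                          " source=", ho_source)))
}

#' The full model catalog
#'
#' Returns every model family of the hierarchical comparison: the lineage
#' trios 3a-3d, the twelve lake/stream quartet models, and the fourteen
#' lake-stream pair models, parameterised with placeholder values and free
#' bindings. Use [best_estimates()] for the maximum-likelihood
#' parameterisations that the synthetic-data generators and recovery
#' experiments build on.
#'
#' @param lake,stream focal population names used for the quartet and pair
#'   models
#' @param n_lake,n_stream sampled diploids for the focal populations
#' @return named list of `dem_model` objects
#' @export
model_catalog <- function(lake = "L2", stream = "S2", n_lake = 6,
                          n_stream = 6) {
  out <- list()
  for (t in c("3a", "3b", "3c", "3d")) out[[t]] <- model_trio(t)
  for (src in c("o", "i", "v")) {
    out[[paste0("3L", src)]] <- model_quartet(lake, src, "none", "L", n_lake)
    out[[paste0("3S", src)]] <- model_quartet(stream, src, "none", "S",
                                              n_stream)
  }
  for (adm in c("x", "o", "i")) {
    out[[paste0("3Lv", adm)]] <- model_quartet(lake, "v", adm, "L", n_lake)
    out[[paste0("3Sv", adm)]] <- model_quartet(stream, "v", adm, "S",
                                               n_stream)
  }
  for (m in c("PD", "EVa", "EVb")) out[[m]] <- model_pair(
    m, lake, stream, n_lake = n_lake, n_stream = n_stream)
  for (s in c("i", "o")) out[[paste0("SC", s)]] <- model_pair(
    paste0("SC", s), lake, stream, n_lake = n_lake, n_stream = n_stream)
  for (tg in c("a", "b", "c")) for (s in c("x", "i", "o"))
    out[[paste0("HO", tg, s)]] <- model_pair(
      "HO", lake, stream, ho_target = tg, ho_source = s,
      n_lake = n_lake, n_stream = n_stream)
  out
}

#' Look up one catalog model by id
#' @param model_id catalog identifier
#' @param ... passed to [model_catalog()]
#' @export
catalog_model <- function(model_id, ...) {
  cat_ <- model_catalog(...)
  if (!model_id %in% names(cat_))
    stop("unknown model id '", model_id, "'; valid ids: ",
         paste(names(cat_), collapse = ", "))
  cat_[[model_id]]
}

#' Best-estimate parameterisations of the selected models
#'
#' Encodes the maximum-likelihood demographic reconstruction used by the
#' synthetic-data generators and the parameter-recovery experiments:
#' the West/East European lineage split at 3665 generations and the upper
#' Rhone/Rhine split at 1710 generations (model 3a); Rhine/Rhone admixture
#' pulses of 27.2/0.2 percent into the stream population NID, 16.6/0.1 into
#' S2 and 6.7/0.7 into the lake population L2 (quartet models); and the
#' hybrid-origin lake-stream reconstructions — an ancestor pulse of 14
#' percent West European ancestry for the L2-S2 pair (lake-stream split 408
#' generations), and stream pulses of 31, 32 and 48 percent for NID, BOH
#' and GRA (splits 1276, 2819 and 1065 generations) against the lake
#' population ROM. Lineage sizes, colonisation/pulse times and lake-stream
#' migration are not part of the printed reconstruction; the packaged
#' values are representative choices discussed in the methods vignette.
#' `hybrid_index_nid` carries the observed mean West-ancestry fraction of
#' the admixed stream population NID (0.44) used by the diagnostic-panel
#' cohort generator.
#'
#' @return named list: `dem_model` entries `m3a`, `m4_L2`, `m4_S2`,
#'   `m4_NID`, `m5_L2_S2`, `m5_ROM_NID`, `m5_ROM_BOH`, `m5_ROM_GRA`, plus
#'   scalars `hybrid_index_nid` and `mu`
#' @export
best_estimates <- function() {
  list(
    m3a = set_params(model_trio("3a"),
                     c(T_DEEP = 3665, T_SHALLOW = 1710)),
    m4_L2 = set_params(model_quartet("L2", "v", "x", "L", n_focal = 6),
                       c(A_I = 6.7, A_O = 0.7, N_FOCAL = 4000,
                         T_COL = 1500, T_OI = 1710, T_WE = 3665)),
    m4_S2 = set_params(model_quartet("S2", "v", "x", "S", n_focal = 6),
                       c(A_I = 16.6, A_O = 0.1, N_FOCAL = 2000,
                         T_COL = 1500, T_OI = 1710, T_WE = 3665)),
    m4_NID = set_params(model_quartet("NID", "v", "x", "S", n_focal = 6),
                        c(A_I = 27.2, A_O = 0.2, N_FOCAL = 5000,
                          T_COL = 1500, T_OI = 1710, T_WE = 3665)),
    m5_L2_S2 = set_params(
      model_pair("HO", "L2", "S2", ho_target = "c", ho_source = "i",
                 n_lake = 6, n_stream = 6, n_lineages = c(4, 3, 4)),
      c(A_I = 14, T_ADM_I = 950, T_LS = 408, T_COL = 1500,
        N_LAKE = 4000, N_STREAM = 2000, N_CANC = 4000,
        M_LS = 1, M_SL = 1)),
    m5_ROM_NID = set_params(
      model_pair("HO", "ROM", "NID", ho_target = "a", ho_source = "i",
                 n_lake = 7, n_stream = 9),
      c(A_I = 31, T_ADM_I = 638, T_LS = 1276, T_COL = 3000,
        N_LAKE = 6000, N_STREAM = 5000, N_CANC = 5000,
        M_LS = 1, M_SL = 1)),
    m5_ROM_BOH = set_params(
      model_pair("HO", "ROM", "BOH", ho_target = "a", ho_source = "i",
                 n_lake = 7, n_stream = 9),
      c(A_I = 32, T_ADM_I = 1400, T_LS = 2819, T_COL = 3400,
        N_LAKE = 6000, N_STREAM = 6000, N_CANC = 6000,
        M_LS = 1, M_SL = 1)),
    m5_ROM_GRA = set_params(
      model_pair("HO", "ROM", "GRA", ho_target = "a", ho_source = "i",
                 n_lake = 7, n_stream = 9),
      c(A_I = 48, T_ADM_I = 532, T_LS = 1065, T_COL = 3000,
        N_LAKE = 6000, N_STREAM = 8000, N_CANC = 6000,
        M_LS = 1, M_SL = 1)),
    hybrid_index_nid = 0.44,
    mu = DEFAULT_MU)
}
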