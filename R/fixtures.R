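#' Deterministic toy metabolic networks
#'
#' Generators for small, fully self-contained metabolic models (plus a
#' matching full-coverage view) so that every layer of the package is
#' testable offline. Topologies:
#'
#' * `chain` — a linear pathway: an uptake exchange (lower bound
#'   `-bound_scale`, upper 0), `n_reactions - 2` conversions, an export
#'   exchange. The optimum pushes `bound_scale` units through the chain.
#' * `parallel` — `n_reactions` alternative routes between one substrate and
#'   one product, flanked by an uptake and an export exchange (knocking out
#'   one branch reroutes all flux through the survivors).
#' * `branched` — a diamond: the pathway splits into two branches that merge
#'   again before export.
#' * `random` — a chain backbone (so a nontrivial optimum always exists,
#'   with at least one inlet and one outlet) decorated with seeded random
#'   cross-links, bounds, compartments and subsystem labels.
#'
#' The zero flux vector is always feasible, every generated model solves to
#' status `"optimal"`, and the same seed yields byte-identical SBML/CyJson.
#'
#' @param topology one of `"chain"`, `"parallel"`, `"branched"`, `"random"`.
#' @param n_reactions size parameter (total reactions for `chain`; branch
#'   count for `parallel`; approximate internal reactions otherwise), >= 1.
#' @param seed integer seed (only `random` draws from it).
#' @param bound_scale uptake capacity in flux units (mmol·gDW^-1·h^-1).
#' @return list with `model` (a `model_record`), `sbml` (string) and
#'   `cyjs` (string, full-coverage grid view).
#' @export
generate_toy_model <- function(topology = c("chain", "parallel", "branched", "random"),
                               n_reactions = 3L, seed = 1L, bound_scale = 10) {
  if (length(topology) != 1L || !topology %in% c("chain", "parallel", "branched", "random"))
    ft_abort(sprintf("unsupported topology '%s'", paste(topology, collapse = "/")),
             "config_error")
  if (n_reactions < 1L)
    ft_abort("n_reactions must be >= 1", "config_error")
  model <- switch(topology,
    chain = toy_chain(n_reactions, bound_scale),
    parallel = toy_parallel(n_reactions, bound_scale),
    branched = toy_branched(n_reactions, bound_scale),
    random = toy_random(n_reactions, seed, bound_scale))
  sbml <- write_sbml_model(model)
  cyjs <- serialize_view(default_grid_layout(model))
  list(model = model, sbml = sbml, cyjs = cyjs)
}

new_toy <- function(model_id, species, compartment, reactions, stoich,
                    objective, subsystem = NULL) {
  rx <- data.frame(reaction_id = names(stoich),
                   name = names(stoich),
                   lower_bound = reactions$lb, upper_bound = reactions$ub,
                   subsystem = subsystem %||% rep(NA_character_, length(stoich)),
                   stringsAsFactors = FALSE)
  structure(list(
    model_id = model_id, source_db = "fixture",
    species = data.frame(species_id = species, name = species,
                         compartment = compartment, stringsAsFactors = FALSE),
    reactions = rx, stoichiometry = stoich,
    objective = objective, objective_sense = "maximize"),
    class = "model_record")
}

toy_chain <- function(n, scale) {
  if (n < 2L) ft_abort("chain topology needs n_reactions >= 2", "config_error")
  k <- n - 1L                             # number of species
  sp <- sprintf("M%d", seq_len(k))
  stoich <- c(
    list(EX_up = stats::setNames(-1, sp[1L])),
    if (n > 2L) stats::setNames(lapply(seq_len(n - 2L), function(i)
      stats::setNames(c(-1, 1), sp[c(i, i + 1L)])), sprintf("R%d", seq_len(n - 2L))),
    list(EX_out = stats::setNames(-1, sp[k])))
  # objective: the first internal conversion when one exists, else the export
  obj_rx <- if (n > 2L) "R1" else "EX_out"
  new_toy(sprintf("chain%d", n), sp, rep("c", k),
          list(lb = c(-scale, rep(0, n - 1L)), ub = c(0, rep(100 * scale, n - 1L))),
          stoich, stats::setNames(1, obj_rx))
}

toy_parallel <- function(n, scale) {
  sp <- c("A", "B")
  branches <- stats::setNames(lapply(seq_len(n), function(i)
    c(A = -1, B = 1)), sprintf("R%d", seq_len(n)))
  stoich <- c(list(EX_up = c(A = -1)), branches, list(EX_out = c(B = -1)))
  new_toy(sprintf("parallel%d", n), sp, c("c", "c"),
          list(lb = c(-scale, rep(0, n + 1L)), ub = c(0, rep(100 * scale, n + 1L))),
          stoich, c(EX_out = 1))
}

toy_branched <- function(n, scale) {
  half <- max(1L, ceiling((n - 2L) / 4L))  # reactions per branch arm
  sp <- c("A",
          sprintf("U%d", seq_len(half)),   # upper branch intermediates
          sprintf("L%d", seq_len(half)),   # lower branch intermediates
          "D")
  arm <- function(prefix, chainsp) {
    path <- c("A", chainsp, "D")
    stats::setNames(lapply(seq_len(length(path) - 1L), function(i)
      stats::setNames(c(-1, 1), path[c(i, i + 1L)])),
      sprintf("%s%d", prefix, seq_len(length(path) - 1L)))
  }
  stoich <- c(list(EX_up = c(A = -1)),
              arm("RU", sprintf("U%d", seq_len(half))),
              arm("RL", sprintf("L%d", seq_len(half))),
              list(EX_out = c(D = -1)))
  m <- length(stoich)
  new_toy(sprintf("branched%d", n), sp, rep("c", length(sp)),
          list(lb = c(-scale, rep(0, m - 1L)), ub = c(0, rep(100 * scale, m - 1L))),
          stoich,
          c(EX_out = 1))
}

toy_random <- function(n, seed, scale) {
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  n <- max(3L, n)
  k <- max(2L, n - 1L)                    # backbone species
  sp <- sprintf("M%d", seq_len(k))
  backbone_len <- min(k - 1L, max(1L, n - 2L))
  stoich <- list(EX_up = stats::setNames(-1, sp[1L]))
  lb <- -scale; ub <- 0
  for (i in seq_len(backbone_len)) {
    stoich[[sprintf("R%d", i)]] <- stats::setNames(c(-1, 1), sp[c(i, i + 1L)])
    lb <- c(lb, 0); ub <- c(ub, 100 * scale)
  }
  # decorate with random cross-links until n reactions (besides exchanges)
  extra <- n - 2L - backbone_len
  if (extra > 0L) for (j in seq_len(extra)) {
    pair <- sample(k, 2L)
    rev <- stats::runif(1) < 0.4
    stoich[[sprintf("X%d", j)]] <- stats::setNames(
      c(-sample(1:2, 1L), sample(1:2, 1L)), sp[pair])
    lb <- c(lb, if (rev) -scale * stats::runif(1, 0.2, 1) else 0)
    ub <- c(ub, 100 * scale * stats::runif(1, 0.1, 1))
  }
  out_sp <- sp[backbone_len + 1L]
  stoich$EX_out <- stats::setNames(-1, out_sp)
  lb <- c(lb, 0); ub <- c(ub, 100 * scale)
  subsystems <- sample(c("Glycolysis", "TCA", NA_character_),
                       length(stoich), replace = TRUE)
  new_toy(sprintf("rand%d_s%d", n, seed), sp,
          sample(c("c", "e"), k, replace = TRUE),
          list(lb = lb, ub = ub), stoich, stats::setNames(1, "EX_out"),
          subsystem = subsystems)
}

# seed the RNG locally and restore the caller's state on exit
local_rng <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv())
  set.seed(seed)
  function() {
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Generate a modification-file lineage over a toy model
#'
#' Builds a chain model large enough that `depth * entries_per_file` distinct
#' reactions exist, then a parent chain of modification files of the given
#' depth; targets are drawn without replacement, so the lineage expansion of
#' the deepest child has exactly `depth * entries_per_file` entries.
#'
#' @param depth number of files in the parent chain (>= 1).
#' @param entries_per_file entries in each file (>= 1).
#' @param seed integer seed.
#' @return list with `model` (a `model_record`) and `files` (list of
#'   `modification_file`, ancestors first; `files[[i + 1]]`'s parent is
#'   `files[[i]]`).
#' @export
generate_lineage_fixture <- function(depth, entries_per_file = 2L, seed = 1L) {
  if (depth < 1L) ft_abort("depth must be >= 1", "config_error")
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  n_targets <- depth * entries_per_file
  model <- toy_chain(n_targets + 2L, 10)
  targets <- sample(model$reactions$reaction_id, n_targets)
  files <- vector("list", depth)
  for (d in seq_len(depth)) {
    idx <- (d - 1L) * entries_per_file + seq_len(entries_per_file)
    entries <- lapply(targets[idx], function(t) {
      if (stats::runif(1) < 0.5) mod_entry(t, "knockout")
      else {
        b <- sort(round(stats::runif(2, 0, 10), 3))
        mod_entry(t, "set_bounds", b[1], b[2])
      }
    })
    files[[d]] <- modification_file(
      file_name = sprintf("lineage_s%d_d%d", seed, d),
      author = sprintf("author%d", d),
      root_model = model$model_id,
      entries = entries,
      parent = if (d > 1L) files[[d - 1L]]$file_name,
      date = sprintf("2024-01-%02dT00:00:00Z", d))
  }
  list(model = model, files = files)
}

#' Synthetic central-metabolism demonstration model
#'
#' A hand-built, deliberately small stand-in for the central carbon
#' metabolism of *E. coli* (it is synthetic — no genome-scale reconstruction
#' is bundled). It exists to exercise the demonstration workflow: glucose
#' enters through an exchange with the conventional default uptake bound of
#' -10 mmol·gDW^-1·h^-1, crosses the outer membrane, and is phosphorylated on
#' import either by the periplasmic PTS reaction (`GLCptspp`, consuming
#' phosphoenolpyruvate) or by a deliberately less efficient ABC-transport +
#' kinase route (`GLCabcpp` + `HEX1`). At the optimum all glucose flows
#' through the PTS, whose flux therefore equals the uptake bound (10);
#' knocking `GLCptspp` out reroutes the full uptake through the ABC branch at
#' a lower objective. Lumped glycolysis, pyruvate kinase, an overall
#' oxidation step and a CO2 exchange close the network; subsystem and
#' compartment metadata make the grouping machinery exercisable.
#'
#' @return list with `model`, `sbml`, `cyjs` as in [generate_toy_model()].
#' @export
synthetic_central_metabolism <- function() {
  sp <- c("glc_e", "glc_p", "glc_c", "g6p_c", "pep_c", "pyr_c", "co2_c", "co2_e")
  comp <- c("e", "p", "c", "c", "c", "c", "c", "e")
  stoich <- list(
    EX_glc_e = c(glc_e = -1),
    GLCtex   = c(glc_e = -1, glc_p = 1),
    GLCptspp = c(glc_p = -1, pep_c = -1, g6p_c = 1, pyr_c = 1),
    GLCabcpp = c(glc_p = -1, glc_c = 1),
    HEX1     = c(glc_c = -1, g6p_c = 0.9),
    GLYC     = c(g6p_c = -1, pep_c = 2),
    PYK      = c(pep_c = -1, pyr_c = 1),
    OXID     = c(pyr_c = -1, co2_c = 3),
    CO2t     = c(co2_c = -1, co2_e = 1),
    EX_co2_e = c(co2_e = -1),
    BIOMASS_syn = c(g6p_c = -0.2, pep_c = -0.2, pyr_c = -0.6))
  n <- length(stoich)
  lb <- c(-10, rep(0, n - 1L)); lb[9] <- -1000
  ub <- c(0, rep(1000, n - 1L))
  subsystem <- c("Exchange", "Transport", "Transport", "Transport",
                 "Glycolysis", "Glycolysis", "Glycolysis", "TCA",
                 "Transport", "Exchange", "Biomass")
  model <- new_toy("synthCentral", sp, comp, list(lb = lb, ub = ub),
                   stoich, c(BIOMASS_syn = 1), subsystem = subsystem)
  list(model = model, sbml = write_sbml_model(model),
       cyjs = serialize_view(default_grid_layout(model)))
}
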