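#' Build the flux balance LP for a model under a modification state
#'
#' Assembles the steady-state problem: maximise `c'v` subject to `S v = 0`
#' and `lb <= v <= ub`, where `S` is the species-by-reactions stoichiometric
#' matrix (signed, negative = consumed) and the bounds come from the model's
#' fbc annotations. The effective modification state is then applied on top:
#' `knockout` pins a reaction's bounds to (0, 0), `set_bounds` replaces them
#' with the payload. Every modification is applied whether or not any view
#' displays the targeted reaction. Reversible reactions stay single signed
#' columns — fluxes keep their sign.
#'
#' @param model a `model_record`.
#' @param state an `effective_state` from [resolve_effective_state()], or
#'   `NULL` for the unmodified model.
#' @return an `fba_problem`: list with `S` (dense matrix, species x
#'   reactions), `lb`, `ub`, `c` (objective coefficients, sign-flipped for
#'   minimisation objectives so the LP always maximises), `reaction_ids`,
#'   `species_ids`.
#' @export
build_fba_problem <- function(model, state = NULL) {
  stopifnot(inherits(model, "model_record"))
  rx <- model$reactions$reaction_id
  sp <- model$species$species_id
  S <- matrix(0, nrow = length(sp), ncol = length(rx),
              dimnames = list(sp, rx))
  for (r in rx) {
    st <- model$stoichiometry[[r]]
    if (length(st)) S[names(st), r] <- unname(st)
  }
  lb <- stats::setNames(model$reactions$lower_bound, rx)
  ub <- stats::setNames(model$reactions$upper_bound, rx)
  if (!is.null(state)) {
    stopifnot(inherits(state, "effective_state"))
    unknown <- setdiff(state$target, rx)
    if (length(unknown))
      ft_abort(sprintf("modification target(s) not reactions of model '%s': %s",
                       model$model_id, paste(unknown, collapse = ", ")),
               "consistency_error")
    for (i in seq_len(nrow(state))) {
      t <- state$target[i]
      if (state$operation[i] == "knockout") {
        lb[t] <- 0; ub[t] <- 0
      } else {
        lb[t] <- state$lower[i]; ub[t] <- state$upper[i]
      }
    }
  }
  obj <- stats::setNames(numeric(length(rx)), rx)
  obj[names(model$objective)] <- model$objective
  if (identical(model$objective_sense, "minimize")) obj <- -obj
  structure(list(S = S, lb = unname(lb), ub = unname(ub), c = unname(obj),
                 reaction_ids = rx, species_ids = sp),
            class = "fba_problem")
}

#' @export
print.fba_problem <- function(x, ...) {
  cat(sprintf("<fba_problem> %d species x %d reactions, %d objective term(s)\n",
              nrow(x$S), ncol(x$S), sum(x$c != 0)))
  invisible(x)
}

#' Solve a flux balance problem
#'
#' Runs the bounded-variable simplex on the steady-state LP. When the problem
#' is degenerate (alternate optima), the returned flux vector is one optimal
#' vertex; the objective value is unique but individual fluxes — and hence
#' `v_min`/`v_max` — may be solver-dependent.
#'
#' @param problem an `fba_problem` from [build_fba_problem()].
#' @param tol LP pivot tolerance.
#' @param feas_tol mass-balance feasibility tolerance checked on the
#'   returned solution.
#' @param view optionally, a `view_graph`: restrict the reported
#'   `v_min`/`v_max` extrema to reactions present in the view (the mapped
#'   pathway), leaving the flux vector itself untouched.
#' @return a `flux_solution`: list with `status` ("optimal", "infeasible",
#'   "unbounded"), `fluxes` (named numeric over all reactions), `objective_value`,
#'   `v_min`, `v_max`.
#' @export
solve_fba <- function(problem, tol = 1e-9, feas_tol = 1e-6, view = NULL) {
  stopifnot(inherits(problem, "fba_problem"))
  n <- ncol(problem$S)
  res <- lp_solve_bounded(problem$c, problem$S, rep(0, nrow(problem$S)),
                          problem$lb, problem$ub, tol = tol)
  if (res$status %in% c("infeasible", "unbounded"))
    return(structure(list(status = res$status, fluxes = NULL,
                          objective_value = NA_real_,
                          v_min = NA_real_, v_max = NA_real_),
                     class = "flux_solution"))
  if (res$status != "optimal")
    ft_abort(sprintf("LP solver failed with status '%s'", res$status),
             "solver_error", solver_status = res$status)
  v <- stats::setNames(res$x, problem$reaction_ids)
  resid <- if (nrow(problem$S)) max(abs(problem$S %*% v)) else 0
  if (resid > feas_tol)
    ft_abort(sprintf("mass-balance residual %.3g exceeds tolerance %.3g",
                     resid, feas_tol), "solver_error", solver_status = "residual")
  report <- v
  if (!is.null(view)) {
    stopifnot(inherits(view, "view_graph"))
    mapped <- intersect(problem$reaction_ids,
                        unique(view$edges$model_element_id))
    if (length(mapped)) report <- v[mapped]
  }
  structure(list(status = "optimal", fluxes = v,
                 objective_value = res$value,
                 v_min = if (length(report)) min(report) else NA_real_,
                 v_max = if (length(report)) max(report) else NA_real_),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> status %s", x$status))
  if (identical(x$status, "optimal"))
    cat(sprintf(", objective %.6g, flux range [%.6g, %.6g]",
                x$objective_value, x$v_min, x$v_max))
  cat("\n")
  invisible(x)
}

#' End-to-end FBA on a stored model
#'
#' Convenience wrapper joining the store, the modification layer and the
#' solver: loads the model, resolves the effective state of the modification
#' files in the given load order (last loaded wins), builds and solves the LP.
#'
#' @param store a `model_store`.
#' @param model_id registered model id.
#' @param mod_files modification files (stored names or objects) in load
#'   order; empty for the unmodified model.
#' @param view_name optional registered view restricting the reported
#'   extrema to the mapped pathway.
#' @inheritParams solve_fba
#' @return a `flux_solution`.
#' @export
fba <- function(store, model_id, mod_files = list(), view_name = NULL,
                tol = 1e-9, feas_tol = 1e-6) {
  model <- get_model(store, model_id)
  state <- if (length(mod_files))
    resolve_effective_state(mod_files, store) else NULL
  if (!is.null(state) && nrow(state)) {
    mixed <- unique(vapply(
      lapply(mod_files, function(f)
        if (is.character(f)) get_modification_file(store, f) else f),
      function(f) f$root_model, ""))
    if (!identical(mixed, model_id))
      ft_abort("modification files target a different root model",
               "consistency_error")
  }
  view <- if (!is.null(view_name)) get_view(store, view_name) else NULL
  solve_fba(build_fba_problem(model, state), tol = tol, feas_tol = feas_tol,
            view = view)
}

#' JSON flux report
#'
#' @param solution a `flux_solution`.
#' @return single JSON string with `status`, `objective_value`, `fluxes`,
#'   `v_min`, `v_max`.
#' @export
flux_report_json <- function(solution) {
  stopifnot(inherits(solution, "flux_solution"))
  doc <- list(status = solution$status,
              objective_value = solution$objective_value,
              fluxes = as.list(solution$fluxes %||% stats::setNames(list(), character(0))),
              v_min = solution$v_min, v_max = solution$v_max)
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null"))
}

#' Visual scalars of a flux solution
#'
#' Maps fluxes to the three per-reaction display scalars used by graphical
#' clients: `color_t` in \[0, 1\] interpolates linearly between the
#' solution's reported minimal (blue) and maximal (red) flux — the
#' view-restricted extrema when the solve was view-restricted — clamped into
#' \[0, 1\], non-decreasing in the flux, invariant under affine rescaling of
#' the flux vector, and 0.5 for every reaction when the extrema coincide;
#' `width` maps |flux| linearly onto and
#' clamps into `[w_min, w_max]`; `particle_rate` (particles per second) is
#' `rate_per_flux * |flux|`, so a zero flux emits no particles.
#'
#' @param solution an optimal `flux_solution`.
#' @param w_min,w_max edge-width clamp, `w_min <= w_max`.
#' @param rate_per_flux particles per second per unit flux (>= 0).
#' @return data.frame with `reaction_id`, `flux`, `color_t`, `width`,
#'   `particle_rate`.
#' @export
compute_visual_scalars <- function(solution, w_min = 0.1, w_max = 2,
                                   rate_per_flux = 1) {
  stopifnot(inherits(solution, "flux_solution"))
  if (!identical(solution$status, "optimal"))
    ft_abort("visual scalars require an optimal solution", "state_error")
  if (w_min > w_max)
    ft_abort("w_min must not exceed w_max", "state_error")
  v <- solution$fluxes
  vmin <- solution$v_min; vmax <- solution$v_max
  color_t <- if (vmax > vmin)
    pmin(pmax((v - vmin) / (vmax - vmin), 0), 1) else rep(0.5, length(v))
  amax <- max(abs(v))
  width <- if (amax > 0) w_min + (w_max - w_min) * abs(v) / amax
           else rep(w_min, length(v))
  width <- pmin(pmax(width, w_min), w_max)
  data.frame(reaction_id = names(v), flux = unname(v),
             color_t = unname(color_t), width = unname(width),
             particle_rate = rate_per_flux * abs(unname(v)),
             row.names = NULL, stringsAsFactors = FALSE)
}
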