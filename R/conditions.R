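#' Structured error conditions
#'
#' Every user-facing failure in the package signals a classed condition so
#' callers (and the HTTP layer) can distinguish, e.g., a missing identifier
#' from a malformed document. Classes in use:
#' `fluxtrace_conflict_error` (duplicate ids/names),
#' `fluxtrace_format_error` (unparsable or incomplete documents),
#' `fluxtrace_config_error` (missing tables/unsupported options),
#' `fluxtrace_not_found_error` (unknown ids),
#' `fluxtrace_structure_error` (dangling references inside one document),
#' `fluxtrace_consistency_error` (document disagrees with the model/store),
#' `fluxtrace_reference_error` (missing parent file),
#' `fluxtrace_lineage_error` (parent cycles),
#' `fluxtrace_state_error` (operation invalid in the current state),
#' `fluxtrace_solver_error` (numerical failure in the LP).
#'
#' @param message error message.
#' @param class short class stem, e.g. `"not_found_error"`.
#' @param ... fields attached to the condition.
#' @keywords internal
ft_abort <- function(message, class, ...) {
  stop(structure(
    class = c(paste0("fluxtrace_", class), "fluxtrace_error",
              "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
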