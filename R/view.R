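#' View graphs: spatial projections of a model
#'
#' A view is a positioned graph covering all or part of one model: metabolite
#' and reaction nodes with (x, y) layout coordinates, and directed edges each
#' tied to the model element (reaction) it depicts. Views are read and written
#' as Cytoscape CyJson (`.cyjs`); coordinates are kept exactly as stored
#' (screen convention, y growing downward) — any flipping is the renderer's
#' concern. Views never modify the model they project.
#'
#' @param view_name identifier of the view.
#' @param model_id id of the projected model.
#' @param nodes data.frame with `node_id`, `label`, `x`, `y`, `node_class`
#'   (`"metabolite"` or `"reaction"`).
#' @param edges data.frame with `edge_id`, `source`, `target`,
#'   `model_element_id`.
#' @return a `view_graph`.
#' @export
view_graph <- function(view_name, model_id, nodes, edges) {
  structure(list(view_name = view_name, model_id = model_id,
                 nodes = nodes, edges = edges),
            class = "view_graph")
}

#' @export
print.view_graph <- function(x, ...) {
  cat(sprintf("<view_graph> %s on model %s  (%d nodes, %d edges)\n",
              x$view_name, x$model_id, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

empty_nodes <- function() data.frame(node_id = character(), label = character(),
                                     x = numeric(), y = numeric(),
                                     node_class = character(), stringsAsFactors = FALSE)
empty_edges <- function() data.frame(edge_id = character(), source = character(),
                                     target = character(),
                                     model_element_id = character(),
                                     stringsAsFactors = FALSE)

#' Parse a CyJson view file against a model
#'
#' Reads the Cytoscape `.cyjs` dialect: nodes under
#' `elements$nodes[[i]]$data$id` with `position$x`/`position$y`, edges under
#' `elements$edges[[i]]$data$source`/`$target`. Every edge endpoint must be a
#' declared node (structure error otherwise) and every node must resolve to a
#' species or reaction of the model (consistency error otherwise) — a view may
#' cover any subset of the model, but never elements outside it. The model
#' element an edge depicts is taken from `data$model_element_id` when present,
#' else inferred as the reaction-classed endpoint.
#'
#' @param view_bytes raw vector, JSON string, or path to a `.cyjs` file.
#' @param model the `model_record` the view projects.
#' @param view_name name given to the parsed view (default: the CyJson
#'   network name, else `"view"`).
#' @return a `view_graph`.
#' @export
parse_view <- function(view_bytes, model, view_name = NULL) {
  txt <- view_text(view_bytes)
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e)
                    ft_abort(paste0("not parseable as CyJson: ", conditionMessage(e)),
                             "format_error"))
  els <- doc$elements
  if (is.null(els))
    ft_abort("CyJson document has no 'elements' member", "format_error")

  nodes_raw <- els$nodes %||% list()
  edges_raw <- els$edges %||% list()

  nodes <- if (length(nodes_raw)) data.frame(
    node_id = vapply(nodes_raw, function(n) as.character(n$data$id), ""),
    label = vapply(nodes_raw, function(n)
      as.character(n$data$name %||% n$data$id), ""),
    x = vapply(nodes_raw, function(n) as.numeric(n$position$x %||% NA_real_), numeric(1)),
    y = vapply(nodes_raw, function(n) as.numeric(n$position$y %||% NA_real_), numeric(1)),
    stringsAsFactors = FALSE) else empty_nodes()[, c("node_id", "label", "x", "y")]

  species_ids <- model$species$species_id
  reaction_ids <- model$reactions$reaction_id
  node_class <- ifelse(nodes$node_id %in% species_ids, "metabolite",
                ifelse(nodes$node_id %in% reaction_ids, "reaction", NA_character_))
  if (anyNA(node_class))
    ft_abort(sprintf("view node(s) not found in model '%s': %s", model$model_id,
                     paste(nodes$node_id[is.na(node_class)], collapse = ", ")),
             "consistency_error")
  nodes$node_class <- node_class

  edges <- if (length(edges_raw)) data.frame(
    edge_id = vapply(seq_along(edges_raw), function(i)
      as.character(edges_raw[[i]]$data$id %||% paste0("e", i)), ""),
    source = vapply(edges_raw, function(e) as.character(e$data$source), ""),
    target = vapply(edges_raw, function(e) as.character(e$data$target), ""),
    model_element_id = vapply(edges_raw, function(e)
      as.character(e$data$model_element_id %||% NA_character_), ""),
    stringsAsFactors = FALSE) else empty_edges()

  dangling <- setdiff(c(edges$source, edges$target), nodes$node_id)
  if (length(dangling))
    ft_abort(sprintf("edge endpoint(s) not declared as nodes: %s",
                     paste(dangling, collapse = ", ")), "structure_error")

  if (nrow(edges)) {
    infer <- is.na(edges$model_element_id)
    if (any(infer)) {
      src_rx <- edges$source %in% reaction_ids
      tgt_rx <- edges$target %in% reaction_ids
      inferred <- ifelse(src_rx, edges$source, ifelse(tgt_rx, edges$target, NA))
      edges$model_element_id[infer] <- inferred[infer]
    }
    bad <- is.na(edges$model_element_id) |
      !edges$model_element_id %in% c(reaction_ids, species_ids)
    if (any(bad))
      ft_abort(sprintf("edge(s) with no resolvable model element: %s",
                       paste(edges$edge_id[bad], collapse = ", ")),
               "consistency_error")
  }

  view_graph(view_name %||% as.character(doc$data$name %||% "view"),
             model$model_id, nodes, edges)
}

view_text <- function(x) {
  if (is.raw(x)) return(rawToChar(x))
  if (is.character(x) && length(x) == 1L && !grepl("{", x, fixed = TRUE)) {
    if (!file.exists(x)) ft_abort(sprintf("no such file: %s", x), "format_error")
    return(paste(readLines(x, warn = FALSE), collapse = "\n"))
  }
  paste(x, collapse = "\n")
}

#' Serialise a view graph to CyJson
#'
#' Deterministic writer (fixed member order, full-precision coordinates):
#' serialising the same `view_graph` twice yields byte-identical documents,
#' and `parse_view(serialize_view(v))` restores every field.
#'
#' @param view a `view_graph`.
#' @return single JSON string in the Cytoscape `.cyjs` dialect.
#' @export
serialize_view <- function(view) {
  stopifnot(inherits(view, "view_graph"))
  nodes <- lapply(seq_len(nrow(view$nodes)), function(i) {
    n <- view$nodes[i, ]
    list(data = list(id = n$node_id, name = n$label, node_class = n$node_class),
         position = list(x = n$x, y = n$y))
  })
  edges <- lapply(seq_len(nrow(view$edges)), function(i) {
    e <- view$edges[i, ]
    list(data = list(id = e$edge_id, source = e$source, target = e$target,
                     model_element_id = e$model_element_id))
  })
  doc <- list(format_version = "1.0",
              generated_by = "fluxtrace",
              data = list(name = view$view_name, model_id = view$model_id),
              elements = list(nodes = nodes, edges = edges))
  paste0(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE), "\n")
}

#' Default planar grid layout for a model
#'
#' Deterministic fallback projection guaranteeing that every registered model
#' has at least one view: metabolite nodes first, then reaction nodes, in
#' registration order, placed row-major on a ceiling(sqrt(N)) x ceiling(sqrt(N))
#' grid on the plane with fixed positive spacing (so no two nodes collide).
#' The bipartite edges follow stoichiometry signs: consumed species ->
#' reaction, reaction -> produced species; one edge per nonzero coefficient.
#'
#' @param model a `model_record`.
#' @param view_name name for the generated view.
#' @param spacing grid spacing in layout units (> 0).
#' @return a `view_graph` covering the full model.
#' @export
default_grid_layout <- function(model, view_name = paste0(model$model_id, "__default"),
                                spacing = 100) {
  stopifnot(inherits(model, "model_record"), spacing > 0)
  ids <- c(model$species$species_id, model$reactions$reaction_id)
  labels <- c(model$species$name, model$reactions$name)
  classes <- c(rep("metabolite", nrow(model$species)),
               rep("reaction", nrow(model$reactions)))
  n <- length(ids)
  if (n == 0L)
    return(view_graph(view_name, model$model_id, empty_nodes(), empty_edges()))
  side <- ceiling(sqrt(n))
  nodes <- data.frame(node_id = ids, label = labels,
                      x = ((seq_len(n) - 1L) %% side) * spacing,
                      y = ((seq_len(n) - 1L) %/% side) * spacing,
                      node_class = classes, stringsAsFactors = FALSE)
  edges <- empty_edges()
  k <- 0L
  for (rid in model$reactions$reaction_id) {
    st <- model$stoichiometry[[rid]]
    for (sp in names(st)) {
      k <- k + 1L
      if (st[[sp]] < 0)
        edges[k, ] <- list(sprintf("e%d", k), sp, rid, rid)
      else
        edges[k, ] <- list(sprintf("e%d", k), rid, sp, rid)
    }
  }
  view_graph(view_name, model$model_id, nodes, edges)
}

#' Group view elements by model metadata
#'
#' Detects the groupable parts of a projected model: metabolite nodes are
#' grouped by the compartment of the species they depict, and edges by the
#' subsystem of the reaction they depict. Elements whose metadata is missing
#' fall into the `"ungrouped"` group.
#'
#' @param view a `view_graph` parsed against `model`.
#' @param model the `model_record` the view projects.
#' @return list with `metabolites` (named list: compartment -> node ids) and
#'   `reactions` (named list: subsystem -> edge ids).
#' @export
group_by_metadata <- function(view, model) {
  stopifnot(inherits(view, "view_graph"), inherits(model, "model_record"))
  met_nodes <- view$nodes[view$nodes$node_class == "metabolite", , drop = FALSE]
  comp <- model$species$compartment[match(met_nodes$node_id, model$species$species_id)]
  comp[is.na(comp) | !nzchar(comp)] <- "ungrouped"
  metabolites <- split(met_nodes$node_id, comp)

  rx_edges <- view$edges[view$edges$model_element_id %in% model$reactions$reaction_id, ,
                         drop = FALSE]
  subs <- model$reactions$subsystem[match(rx_edges$model_element_id,
                                          model$reactions$reaction_id)]
  subs[is.na(subs) | !nzchar(subs)] <- "ungrouped"
  reactions <- split(rx_edges$edge_id, subs)

  list(metabolites = metabolites[order(names(metabolites))],
       reactions = reactions[order(names(reactions))])
}

## ---- store-side view registry ---------------------------------------------

#' Register a view file for a model
#'
#' Validates the view against the model and stores its CyJson serialisation.
#' View names are unique across the store (they are what clients import by).
#'
#' @param store a `model_store`.
#' @param view a `view_graph`, or raw/character CyJson.
#' @param view_name unique view name.
#' @param model_id registered model the view projects.
#' @export
register_view <- function(store, view, view_name, model_id) {
  model <- get_model(store, model_id)
  vg <- if (inherits(view, "view_graph")) view else parse_view(view, model, view_name)
  vg$view_name <- view_name
  vg$model_id <- model_id
  idx <- read_index(store)
  if (view_name %in% names(idx$views))
    ft_abort(sprintf("view '%s' is already registered", view_name), "conflict_error")
  path <- file.path(store$dir, "views", paste0(view_name, ".cyjs"))
  writeLines(sub("\n$", "", serialize_view(vg)), path)
  idx$views[[view_name]] <- list(model_id = model_id, file = basename(path))
  write_index(store, idx)
  invisible(vg)
}

#' List views of a model
#' @param store a `model_store`.
#' @param model_id registered model id.
#' @return character vector of view names, sorted.
#' @export
list_views <- function(store, model_id) {
  idx <- read_index(store)
  if (!model_id %in% names(idx$models))
    ft_abort(sprintf("unknown model '%s'", model_id), "not_found_error")
  sort(names(idx$views)[vapply(idx$views, function(v)
    identical(v$model_id, model_id), logical(1))])
}

#' Fetch the raw CyJson document of a registered view
#' @param store a `model_store`.
#' @param view_name registered view name.
#' @return raw vector of the stored `.cyjs` bytes.
#' @export
get_view_bytes <- function(store, view_name) {
  idx <- read_index(store)
  if (!view_name %in% names(idx$views))
    ft_abort(sprintf("unknown view '%s'", view_name), "not_found_error")
  path <- file.path(store$dir, "views", idx$views[[view_name]]$file)
  readBin(path, "raw", file.size(path))
}

#' Parse a registered view against its model
#' @param store a `model_store`.
#' @param view_name registered view name.
#' @return a `view_graph`.
#' @export
get_view <- function(store, view_name) {
  idx <- read_index(store)
  if (!view_name %in% names(idx$views))
    ft_abort(sprintf("unknown view '%s'", view_name), "not_found_error")
  model <- get_model(store, idx$views[[view_name]]$model_id)
  parse_view(get_view_bytes(store, view_name), model, view_name)
}
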