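#' Open or create a model store
#'
#' The store is a plain directory: `models/` holds the SBML documents exactly
#' as registered (they are never rewritten — model files are immutable),
#' `views/` the CyJson projections, `mods/` the YAML modification files,
#' `tables/` the two-column ID translation tables, and `index.json` the
#' registry. No database engine is involved, matching a workflow built on
#' locally downloaded copies of database content.
#'
#' @param dir directory path; created (recursively) if absent.
#' @return a `model_store` handle.
#' @export
#' @examples
#' store <- store_open(tempfile("store"))
#' list_models(store)
store_open <- function(dir) {
  for (d in c("", "models", "views", "mods", "tables", "logs"))
    dir.create(file.path(dir, d), showWarnings = FALSE, recursive = TRUE)
  st <- new.env(parent = emptyenv())
  st$dir <- normalizePath(dir)
  st$cache <- new.env(parent = emptyenv())
  st$tables <- new.env(parent = emptyenv())
  if (!file.exists(index_path(st))) write_index(st, empty_index())
  # reload translation tables registered in the index
  idx <- read_index(st)
  for (tb in idx$tables) {
    st$tables[[table_key(tb$from_db, tb$to_db)]] <-
      read_translation_tsv(file.path(st$dir, "tables", tb$file))
  }
  class(st) <- "model_store"
  st
}

index_path <- function(store) file.path(store$dir, "index.json")
empty_index <- function() list(models = list(), views = list(), tables = list())
read_index <- function(store)
  jsonlite::fromJSON(index_path(store), simplifyVector = FALSE)
write_index <- function(store, idx)
  writeLines(jsonlite::toJSON(idx, auto_unbox = TRUE, pretty = TRUE, digits = NA),
             index_path(store))

#' @export
print.model_store <- function(x, ...) {
  idx <- read_index(x)
  cat(sprintf("<model_store> %s  (%d models, %d views, %d translation tables)\n",
              x$dir, length(idx$models), length(idx$views), length(idx$tables)))
  invisible(x)
}

#' Register a model file
#'
#' Stores the SBML document byte-for-byte under the given id and parses it
#' into a [read_sbml_model()] record. A default grid-layout view is generated
#' immediately so that every model owns at least one view file. The stored
#' bytes are never modified by any later operation.
#'
#' @param store a `model_store`.
#' @param sbml raw vector, SBML string, or path to an SBML file.
#' @param model_id unique short name (e.g. `"iJO1366"`).
#' @param source_db label of the database of origin.
#' @return the parsed `model_record`, invisibly.
#' @export
register_model <- function(store, sbml, model_id, source_db = "local") {
  stopifnot(inherits(store, "model_store"))
  if (!is.character(model_id) || length(model_id) != 1L || !nzchar(model_id))
    ft_abort("model_id must be a non-empty string", "format_error")
  idx <- read_index(store)
  if (model_id %in% names(idx$models))
    ft_abort(sprintf("model '%s' is already registered", model_id), "conflict_error")

  bytes <- sbml_bytes(sbml)
  record <- read_sbml_model(bytes)      # format_error on bad input, pre-write
  record$model_id <- model_id
  record$source_db <- source_db

  path <- file.path(store$dir, "models", paste0(model_id, ".xml"))
  writeBin(bytes, path)
  idx$models[[model_id]] <- list(source_db = source_db,
                                 file = basename(path),
                                 registered = utc_now())
  write_index(store, idx)
  assign(model_id, record, envir = store$cache)

  default <- default_grid_layout(record,
                                 view_name = paste0(model_id, "__default"))
  register_view(store, default, view_name = default$view_name,
                model_id = model_id)
  invisible(record)
}

sbml_bytes <- function(sbml) {
  if (is.raw(sbml)) return(sbml)
  if (is.character(sbml) && length(sbml) == 1L && !grepl("<", sbml, fixed = TRUE)) {
    if (!file.exists(sbml))
      ft_abort(sprintf("no such file: %s", sbml), "format_error")
    return(readBin(sbml, "raw", file.size(sbml)))
  }
  charToRaw(paste(sbml, collapse = "\n"))
}

utc_now <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Retrieve a registered model
#'
#' @param store a `model_store`.
#' @param model_id registered model id.
#' @return the parsed `model_record`.
#' @export
get_model <- function(store, model_id) {
  if (exists(model_id, envir = store$cache, inherits = FALSE))
    return(get(model_id, envir = store$cache))
  idx <- read_index(store)
  if (!model_id %in% names(idx$models))
    ft_abort(sprintf("unknown model '%s'", model_id), "not_found_error")
  record <- read_sbml_model(file.path(store$dir, "models", idx$models[[model_id]]$file))
  record$model_id <- model_id
  record$source_db <- idx$models[[model_id]]$source_db
  assign(model_id, record, envir = store$cache)
  record
}

#' Raw stored bytes of a model file
#'
#' Exposed so integrity can be audited: these bytes must be identical before
#' and after any sequence of view, modification, or FBA operations.
#' @param store a `model_store`.
#' @param model_id registered model id.
#' @return raw vector.
#' @export
model_bytes <- function(store, model_id) {
  idx <- read_index(store)
  if (!model_id %in% names(idx$models))
    ft_abort(sprintf("unknown model '%s'", model_id), "not_found_error")
  path <- file.path(store$dir, "models", idx$models[[model_id]]$file)
  readBin(path, "raw", file.size(path))
}

#' List registered models
#'
#' @param store a `model_store`.
#' @return data.frame with `model_id`, `source_db`, `n_views`,
#'   `n_modification_files`, ordered lexicographically by `model_id`.
#' @export
list_models <- function(store) {
  idx <- read_index(store)
  ids <- sort(names(idx$models))
  view_models <- vapply(idx$views, function(v) v$model_id, "")
  data.frame(
    model_id = ids,
    source_db = vapply(ids, function(i) idx$models[[i]]$source_db, ""),
    n_views = vapply(ids, function(i) sum(view_models == i), integer(1)),
    n_modification_files = vapply(ids, function(i)
      nrow(list_modification_files(store, i)), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

## ---- ID translation tables -------------------------------------------------

table_key <- function(from_db, to_db) paste0(from_db, "\r", to_db)

read_translation_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          col.names = c("from_id", "to_id"))
  split(df$to_id, df$from_id)
}

#' Register an ID translation table
#'
#' Tables are direction-specific: one table per ordered `(from_db, to_db)`
#' pair, loaded from two-column tab-separated text (`from_id<TAB>to_id`, one
#' mapping per line; several lines per `from_id` make a multi-map). Register
#' the reverse file too if round-trip lookups are wanted.
#'
#' @param store a `model_store`.
#' @param from_db,to_db database labels (e.g. `"bigg"`, `"metanetx"`).
#' @param table path to a TSV file, or a data.frame with columns
#'   `from_id`, `to_id`.
#' @export
register_translation_table <- function(store, from_db, to_db, table) {
  if (is.data.frame(table)) {
    path <- file.path(store$dir, "tables", paste0(from_db, "__", to_db, ".tsv"))
    utils::write.table(table[, c("from_id", "to_id")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    if (!file.exists(table))
      ft_abort(sprintf("no such translation table file: %s", table), "config_error")
    path <- file.path(store$dir, "tables", paste0(from_db, "__", to_db, ".tsv"))
    file.copy(table, path, overwrite = TRUE)
  }
  idx <- read_index(store)
  keep <- vapply(idx$tables, function(t)
    !(identical(t$from_db, from_db) && identical(t$to_db, to_db)), logical(1))
  idx$tables <- c(idx$tables[keep],
                  list(list(from_db = from_db, to_db = to_db, file = basename(path))))
  write_index(store, idx)
  store$tables[[table_key(from_db, to_db)]] <- read_translation_tsv(path)
  invisible(store)
}

#' Translate an identifier between database namespaces
#'
#' @param store a `model_store`.
#' @param identifier identifier in the `from_db` namespace.
#' @param from_db,to_db database labels of a registered table.
#' @return sorted character vector of mapped identifiers (never empty: an
#'   absent identifier raises a not-found error, distinct from an empty set).
#' @export
translate_id <- function(store, identifier, from_db, to_db) {
  key <- table_key(from_db, to_db)
  if (!exists(key, envir = store$tables, inherits = FALSE))
    ft_abort(sprintf("no translation table registered for %s -> %s", from_db, to_db),
             "config_error")
  tab <- get(key, envir = store$tables)
  if (!identifier %in% names(tab))
    ft_abort(sprintf("identifier '%s' not present in %s -> %s table",
                     identifier, from_db, to_db), "not_found_error")
  sort(unique(tab[[identifier]]))
}
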