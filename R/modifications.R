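#' Modification entries and files
#'
#' All user alterations of a model live outside the model file, as ordered
#' entries in YAML modification files. An entry targets one model element and
#' is either a `knockout` (flux forced to zero at analysis time) or a
#' `set_bounds` with a `(lower, upper)` payload in flux units
#' (mmol·gDW^-1·h^-1). A file carries `author`, an ISO-8601 UTC `date`, the
#' `root_model` it applies to, an optional `parent` file whose entries are
#' prepended on load, and the ordered `modifications` list. Together the
#' parent lineage (temporal traceability) and entry-list diffs (differential
#' traceability) recover and compare every intermediate state of a model
#' without ever touching the model file itself.
#'
#' @param target model element id the entry targets.
#' @param operation `"knockout"` or `"set_bounds"`.
#' @param lower,upper bounds payload, required for `set_bounds`.
#' @return a `mod_entry`.
#' @export
mod_entry <- function(target, operation = c("knockout", "set_bounds"),
                      lower = NULL, upper = NULL) {
  if (!is.character(target) || length(target) != 1L || !nzchar(target))
    ft_abort("entry target must be a non-empty string", "format_error")
  if (length(operation) != 1L || !operation %in% c("knockout", "set_bounds"))
    ft_abort(sprintf("unknown modification operation '%s'",
                     paste(operation, collapse = "/")), "format_error")
  if (operation == "set_bounds") {
    if (is.null(lower) || is.null(upper))
      ft_abort("set_bounds requires a (lower, upper) payload", "format_error")
    lower <- as.numeric(lower); upper <- as.numeric(upper)
    if (is.na(lower) || is.na(upper) || lower > upper)
      ft_abort("set_bounds payload must satisfy lower <= upper", "format_error")
  } else {
    lower <- NULL; upper <- NULL
  }
  structure(list(target = target, operation = operation,
                 lower = lower, upper = upper), class = "mod_entry")
}

entry_key <- function(e)
  paste(e$target, e$operation,
        if (is.null(e$lower)) "" else format(e$lower, digits = 15),
        if (is.null(e$upper)) "" else format(e$upper, digits = 15),
        sep = "\r")

#' Construct a modification file in memory
#'
#' @param file_name unique name of the file in the store.
#' @param author free-text author.
#' @param root_model id of the model the file modifies.
#' @param entries list of [mod_entry()] in application order.
#' @param parent optional name of the parent modification file.
#' @param date ISO-8601 UTC timestamp; defaults to now.
#' @return a `modification_file`.
#' @export
modification_file <- function(file_name, author, root_model, entries = list(),
                              parent = NULL, date = utc_now()) {
  entries <- lapply(entries, function(e)
    if (inherits(e, "mod_entry")) e else do.call(mod_entry, e))
  structure(list(file_name = file_name, author = author, date = date,
                 root_model = root_model, parent = parent, entries = entries),
            class = "modification_file")
}

#' @export
print.modification_file <- function(x, ...) {
  cat(sprintf("<modification_file> %s  (root %s, %d entries%s)\n",
              x$file_name, x$root_model, length(x$entries),
              if (is.null(x$parent)) "" else paste0(", parent ", x$parent)))
  for (e in x$entries)
    cat(sprintf("  - %s %s%s\n", e$operation, e$target,
                if (e$operation == "set_bounds")
                  sprintf(" (%g, %g)", e$lower, e$upper) else ""))
  invisible(x)
}

#' Parse a YAML modification file
#'
#' Mandatory fields: `author`, `date`, `root_model`, `modifications`
#' (possibly empty); `parent` is optional. Entry order is preserved; unknown
#' operations and malformed payloads are rejected.
#'
#' @param yaml_bytes raw vector, YAML string, or path to a YAML file.
#' @param file_name name to give the parsed file (default: the `file_name`
#'   field if present, else `"modfile"`).
#' @return a `modification_file`.
#' @export
parse_modification_file <- function(yaml_bytes, file_name = NULL) {
  txt <- if (is.raw(yaml_bytes)) rawToChar(yaml_bytes)
         else if (length(yaml_bytes) == 1L && file.exists(yaml_bytes))
           paste(readLines(yaml_bytes, warn = FALSE), collapse = "\n")
         else paste(yaml_bytes, collapse = "\n")
  doc <- tryCatch(yaml::yaml.load(txt), error = function(e)
    ft_abort(paste0("not parseable as YAML: ", conditionMessage(e)), "format_error"))
  for (field in c("author", "date", "root_model"))
    if (is.null(doc[[field]]))
      ft_abort(sprintf("modification file missing mandatory field '%s'", field),
               "format_error")
  if (is.null(doc$modifications)) doc$modifications <- list()
  entries <- lapply(doc$modifications, function(m) {
    if (is.null(m$target) || is.null(m$operation))
      ft_abort("modification entry must name a target and an operation",
               "format_error")
    mod_entry(m$target, m$operation, m$lower, m$upper)
  })
  modification_file(
    file_name = file_name %||% doc$file_name %||% "modfile",
    author = doc$author, root_model = doc$root_model,
    entries = entries, parent = doc$parent, date = doc$date)
}

#' Serialise a modification file to YAML
#'
#' Canonical writer (fixed field order): re-serialising a parsed document is
#' byte-stable, which keeps diffs and integrity checks meaningful.
#'
#' @param file a `modification_file`.
#' @return single YAML string.
#' @export
serialize_modification_file <- function(file) {
  stopifnot(inherits(file, "modification_file"))
  doc <- list(file_name = file$file_name, author = file$author,
              date = file$date, root_model = file$root_model)
  if (!is.null(file$parent)) doc$parent <- file$parent
  doc$modifications <- lapply(file$entries, function(e) {
    m <- list(target = e$target, operation = e$operation)
    if (e$operation == "set_bounds") { m$lower <- e$lower; m$upper <- e$upper }
    m
  })
  yaml::as.yaml(doc, precision = 15)
}

## ---- store-side registry ---------------------------------------------------

mod_path <- function(store, file_name)
  file.path(store$dir, "mods", paste0(file_name, ".yaml"))

#' Persist a modification file in the store
#' @param store a `model_store`.
#' @param file a `modification_file`; its `root_model` must be registered and
#'   its parent, if any, already stored.
#' @export
put_modification_file <- function(store, file) {
  stopifnot(inherits(file, "modification_file"))
  get_model(store, file$root_model)      # not_found_error if unregistered
  if (file.exists(mod_path(store, file$file_name)))
    ft_abort(sprintf("modification file '%s' already exists", file$file_name),
             "conflict_error")
  if (!is.null(file$parent)) {
    parent <- get_modification_file(store, file$parent)
    if (!identical(parent$root_model, file$root_model))
      ft_abort("parent modification file has a different root model",
               "consistency_error")
  }
  writeLines(sub("\n$", "", serialize_modification_file(file)),
             mod_path(store, file$file_name))
  invisible(file)
}

#' Load a stored modification file
#' @param store a `model_store`.
#' @param file_name stored file name.
#' @return a `modification_file`.
#' @export
get_modification_file <- function(store, file_name) {
  p <- mod_path(store, file_name)
  if (!file.exists(p))
    ft_abort(sprintf("unknown modification file '%s'", file_name),
             "reference_error")
  parse_modification_file(p, file_name = file_name)
}

#' List stored modification files of a model
#' @param store a `model_store`.
#' @param model_id registered model id.
#' @return data.frame with `file_name`, `author`, `date`, `parent`,
#'   `n_entries`, sorted by `file_name`.
#' @export
list_modification_files <- function(store, model_id) {
  files <- sort(list.files(file.path(store$dir, "mods"), pattern = "\\.yaml$"))
  rows <- list()
  for (f in files) {
    mf <- parse_modification_file(file.path(store$dir, "mods", f),
                                  file_name = sub("\\.yaml$", "", f))
    if (!identical(mf$root_model, model_id)) next
    rows[[length(rows) + 1L]] <- data.frame(
      file_name = mf$file_name, author = mf$author, date = mf$date,
      parent = mf$parent %||% NA_character_,
      n_entries = length(mf$entries), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(file_name = character(), author = character(),
                      date = character(), parent = character(),
                      n_entries = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

## ---- lineage, effective state, diff, save ----------------------------------

#' Expand a modification file through its parent lineage
#'
#' Walks the parent chain to the root and concatenates entries ancestors
#' first, so that loading a child file behaves as if every ancestor had been
#' loaded before it. Duplicate identical entries (same target, operation and
#' payload) are collapsed, keeping the first occurrence.
#'
#' @param file a `modification_file` (or stored file name).
#' @param store a `model_store` holding the ancestors.
#' @return list of `mod_entry`, ancestors first.
#' @export
resolve_lineage <- function(file, store) {
  if (is.character(file)) file <- get_modification_file(store, file)
  seen <- character()
  expand <- function(f) {
    if (f$file_name %in% seen)
      ft_abort(sprintf("cycle in modification-file lineage at '%s'", f$file_name),
               "lineage_error")
    seen <<- c(seen, f$file_name)
    if (is.null(f$parent)) return(f$entries)
    c(expand(get_modification_file(store, f$parent)), f$entries)
  }
  entries <- expand(file)
  entries[!duplicated(vapply(entries, entry_key, ""))]
}

#' Resolve the effective modification state of a load sequence
#'
#' Each file is first lineage-expanded; conflicts are then resolved by giving
#' priority to the last file loaded: an entry in the n-th loaded file
#' targeting element e overrides any earlier entry targeting e, and within one
#' expanded file the later entry wins. The result maps each touched target to
#' exactly one winning entry plus its provenance (which loaded file, at which
#' load index, decided it).
#'
#' @param files list of `modification_file` objects (or stored names), in
#'   load order.
#' @param store a `model_store`.
#' @return an `effective_state`: data.frame with `target`, `operation`,
#'   `lower`, `upper`, `provenance`, `load_index`, one row per target,
#'   ordered by target.
#' @export
resolve_effective_state <- function(files, store) {
  files <- lapply(files, function(f)
    if (is.character(f)) get_modification_file(store, f) else f)
  roots <- unique(vapply(files, function(f) f$root_model, ""))
  if (length(roots) > 1L)
    ft_abort(sprintf("loaded files mix root models: %s",
                     paste(roots, collapse = ", ")), "consistency_error")
  winners <- list()
  for (i in seq_along(files)) {
    for (e in resolve_lineage(files[[i]], store)) {
      winners[[e$target]] <- list(entry = e,
                                  provenance = files[[i]]$file_name,
                                  load_index = i)
    }
  }
  targets <- sort(names(winners))
  out <- data.frame(
    target = targets,
    operation = vapply(targets, function(t) winners[[t]]$entry$operation, ""),
    lower = vapply(targets, function(t) winners[[t]]$entry$lower %||% NA_real_, numeric(1)),
    upper = vapply(targets, function(t) winners[[t]]$entry$upper %||% NA_real_, numeric(1)),
    provenance = vapply(targets, function(t) winners[[t]]$provenance, ""),
    load_index = vapply(targets, function(t) winners[[t]]$load_index, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("effective_state", "data.frame")
  out
}

#' Compare two modification files entry-by-entry
#'
#' Both files are lineage-expanded first; entries are identified by
#' (target, operation, payload) — authorship and dates are bookkeeping, not
#' modifications. The three partitions are disjoint and jointly cover both
#' expanded lists.
#'
#' @param a,b `modification_file` objects (or stored names).
#' @param store a `model_store` (needed to expand parents).
#' @return list with `only_in_a`, `common`, `only_in_b`, each a list of
#'   `mod_entry` in expanded order.
#' @export
diff_modification_files <- function(a, b, store) {
  ea <- resolve_lineage(a, store)
  eb <- resolve_lineage(b, store)
  ka <- vapply(ea, entry_key, "")
  kb <- vapply(eb, entry_key, "")
  list(only_in_a = ea[!ka %in% kb],
       common    = ea[ka %in% kb],
       only_in_b = eb[!kb %in% ka])
}

#' Save the current session as a new modification file
#'
#' Implements the checkpoint rule of the lineage system: the parent of the
#' saved file is the last file loaded (none if nothing was loaded), so the
#' parent's expanded entries travel implicitly and only what the parent does
#' not already determine is written out. Concretely, the recorded entries are
#' the effective (winning) entries contributed by earlier-loaded files — not
#' by the parent's own lineage — in load order, followed by the session's own
#' entries. Loading the saved file alone therefore reproduces exactly the
#' effective state of the original load sequence plus the session.
#'
#' @param store a `model_store`.
#' @param loaded list of `modification_file` objects (or stored names) in
#'   load order; may be empty.
#' @param session_entries list of [mod_entry()] made during the session, in
#'   order; may be empty (a pure checkpoint).
#' @param author author recorded in the new file.
#' @param file_name name for the new file; a conflict error is raised if a
#'   stored file already uses it.
#' @param root_model required when `loaded` is empty; otherwise taken from
#'   the loaded files.
#' @return the persisted `modification_file`.
#' @export
save_modification_file <- function(store, loaded, session_entries, author,
                                   file_name, root_model = NULL) {
  loaded <- lapply(loaded, function(f)
    if (is.character(f)) get_modification_file(store, f) else f)
  session_entries <- lapply(session_entries, function(e)
    if (inherits(e, "mod_entry")) e else do.call(mod_entry, e))
  if (length(loaded)) {
    root_model <- unique(vapply(loaded, function(f) f$root_model, ""))
    if (length(root_model) > 1L)
      ft_abort("loaded files mix root models", "consistency_error")
    parent <- loaded[[length(loaded)]]$file_name
  } else {
    if (is.null(root_model))
      ft_abort("root_model is required when no files are loaded", "format_error")
    parent <- NULL
  }
  model <- get_model(store, root_model)
  known <- c(model$reactions$reaction_id, model$species$species_id)
  for (e in session_entries)
    if (!e$target %in% known)
      ft_abort(sprintf("session entry targets unknown element '%s'", e$target),
               "consistency_error")

  new_entries <- list()
  if (length(loaded) > 1L) {
    state <- resolve_effective_state(loaded, store)
    parent_keys <- vapply(resolve_lineage(loaded[[length(loaded)]], store),
                          entry_key, "")
    # winning entries decided by earlier files, not already carried by the
    # parent's lineage, in load order
    for (i in seq_len(length(loaded) - 1L)) {
      for (e in resolve_lineage(loaded[[i]], store)) {
        row <- state[state$target == e$target, ]
        if (nrow(row) == 0L || row$load_index != i) next
        if (entry_key(e) %in% parent_keys) next
        win <- winner_matches(row, e)
        if (win) new_entries[[length(new_entries) + 1L]] <- e
      }
    }
  }
  all_entries <- c(new_entries, session_entries)
  mf <- modification_file(file_name = file_name, author = author,
                          root_model = root_model, entries = all_entries,
                          parent = parent)
  put_modification_file(store, mf)
  mf
}

winner_matches <- function(row, e) {
  identical(row$operation, e$operation) &&
    (e$operation != "set_bounds" ||
       (isTRUE(all.equal(row$lower, e$lower)) &&
        isTRUE(all.equal(row$upper, e$upper))))
}
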