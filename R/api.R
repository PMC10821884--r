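#' Action-schema handshake
#'
#' A client module declares the set of server commands it cannot work
#' without; a server publishes the list of commands it implements (see
#' [server_commands()] and the `/commands` route). A module is unlocked
#' exactly when its required set is a subset of the server's command list —
#' an empty requirement is vacuously satisfied.
#'
#' @param schema named list: module name -> character vector of required
#'   command names.
#' @param commands character vector of commands the server implements.
#' @return named logical: module name -> unlocked.
#' @export
check_action_schema <- function(schema, commands) {
  if (!is.list(schema) || (length(schema) && is.null(names(schema))))
    ft_abort("schema must be a named list of command sets", "format_error")
  vapply(schema, function(req) all(req %in% commands), logical(1))
}

#' Commands implemented by this server
#'
#' The published command list always matches what [handle_query()] actually
#' routes, so a handshake of any first-party schema against the server's own
#' `/commands` response unlocks every module.
#' @return character vector of command names.
#' @export
server_commands <- function() {
  c("commands", "listModels", "listViews", "importViewFile",
    "listModificationFiles", "saveModificationFile", "solveFBA")
}

#' Route an HTTP query against a store
#'
#' Pure request router (no sockets involved): the first path segment names
#' the query, the remaining segments are its parameters. Routes:
#'
#' * `GET /commands` — self-description for the action-schema handshake.
#' * `GET /listModels`
#' * `GET /listViews/<model_id>`
#' * `GET /importViewFile/<view_name>` — returns the raw CyJson document.
#' * `GET /listModificationFiles/<model_id>`
#' * `POST /saveModificationFile` — body is a YAML document with `file_name`,
#'   `author`, `root_model`, optional `loaded` (stored file names in load
#'   order) and `modifications` (the session's entries).
#' * `GET /solveFBA/<model_id>[/<mod_file>...]` — extra segments are
#'   modification files applied in URL order, which is the load order for
#'   the last-loaded-wins rule. An infeasible FBA is a result, not a
#'   transport error: it returns 200 with status `"infeasible"`.
#'
#' Unknown queries and unknown ids give 404; malformed bodies give 400.
#' Every response body is JSON except `importViewFile`, which returns the
#' stored view document under its own media type.
#'
#' @param store a `model_store`.
#' @param path URL path, e.g. `"/solveFBA/toy3/ko1"`.
#' @param method `"GET"` or `"POST"`.
#' @param body request body (character or raw), for POST routes.
#' @return list with `status` (integer), `content_type`, `body` (string).
#' @export
handle_query <- function(store, path, method = "GET", body = NULL) {
  segs <- strsplit(sub("^/+", "", path), "/")[[1L]]
  segs <- vapply(segs, utils::URLdecode, "")
  query <- if (length(segs)) segs[[1L]] else ""
  params <- if (length(segs) > 1L) segs[-1L] else character(0)

  json <- function(x, status = 200L)
    list(status = status, content_type = "application/json",
         body = as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                              null = "null", na = "null")))
  err <- function(status, message)
    json(list(error = message), status = status)

  catching <- function(expr) {
    tryCatch(expr,
      fluxtrace_not_found_error = function(e) err(404L, conditionMessage(e)),
      fluxtrace_reference_error = function(e) err(404L, conditionMessage(e)),
      fluxtrace_format_error = function(e) err(400L, conditionMessage(e)),
      fluxtrace_conflict_error = function(e) err(409L, conditionMessage(e)),
      fluxtrace_error = function(e) err(400L, conditionMessage(e)))
  }

  res <- switch(query,
    commands = json(list(commands = server_commands())),
    listModels = json(df_rows(list_models(store))),
    listViews = {
      if (length(params) < 1L) err(400L, "listViews needs a model id")
      else catching(json(list_views(store, params[[1L]])))
    },
    importViewFile = {
      if (length(params) < 1L) err(400L, "importViewFile needs a view name")
      else catching({
        bytes <- get_view_bytes(store, params[[1L]])
        list(status = 200L, content_type = "application/vnd.cyjs+json",
             body = rawToChar(bytes))
      })
    },
    listModificationFiles = {
      if (length(params) < 1L) err(400L, "listModificationFiles needs a model id")
      else catching({
        get_model(store, params[[1L]])
        json(df_rows(list_modification_files(store, params[[1L]])))
      })
    },
    saveModificationFile = {
      if (!identical(method, "POST")) err(400L, "saveModificationFile requires POST")
      else if (is.null(body)) err(400L, "saveModificationFile requires a YAML body")
      else catching({
        doc <- tryCatch(
          yaml::yaml.load(if (is.raw(body)) rawToChar(body) else body),
          error = function(e) ft_abort("body is not valid YAML", "format_error"))
        if (!is.list(doc)) ft_abort("body is not a YAML mapping", "format_error")
        for (f in c("file_name", "author"))
          if (is.null(doc[[f]]))
            ft_abort(sprintf("save request missing '%s'", f), "format_error")
        entries <- lapply(doc$modifications %||% list(), function(m)
          mod_entry(m$target, m$operation, m$lower, m$upper))
        mf <- save_modification_file(
          store, loaded = as.list(doc$loaded %||% list()),
          session_entries = entries, author = doc$author,
          file_name = doc$file_name, root_model = doc$root_model)
        json(list(file_name = mf$file_name, parent = mf$parent,
                  root_model = mf$root_model, date = mf$date,
                  n_entries = length(mf$entries)))
      })
    },
    solveFBA = {
      if (length(params) < 1L) err(400L, "solveFBA needs a model id")
      else catching({
        sol <- fba(store, params[[1L]],
                   mod_files = as.list(params[-1L]))
        list(status = 200L, content_type = "application/json",
             body = flux_report_json(sol))
      })
    },
    err(404L, sprintf("unknown query '%s'", query))
  )
  log_query(store, method, path, res$status)
  res
}

# data.frame -> list of row records (stable JSON shape, [] when empty)
df_rows <- function(df) {
  if (!nrow(df)) return(list())
  lapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, , drop = FALSE])
    lapply(row, function(v) if (is.na(v)) NULL else v)
  })
}

log_query <- function(store, method, path, status) {
  line <- jsonlite::toJSON(list(time = utc_now(), method = method,
                                path = path, status = status),
                           auto_unbox = TRUE)
  cat(line, "\n", sep = "", file = file.path(store$dir, "logs", "queries.jsonl"),
      append = TRUE)
  invisible(NULL)
}

#' Serve the query API over HTTP
#'
#' Minimal serial HTTP/1.1 loop over a listening socket: one request per
#' connection, each dispatched through [handle_query()]. Intended for a
#' single trusted client on a desk-scale deployment — there is no TLS, no
#' authentication and no concurrency. The server never writes to any model
#' file; all state changes go through modification files.
#'
#' @param store a `model_store`.
#' @param host interface to bind (connections are accepted locally).
#' @param port TCP port.
#' @param max_requests stop after this many requests (default: serve
#'   forever); useful for tests and scripted runs.
#' @param quiet suppress the per-request console line.
#' @export
serve_api <- function(store, host = "127.0.0.1", port = 8585L,
                      max_requests = Inf, quiet = FALSE) {
  served <- 0
  while (served < max_requests) {
    con <- suppressWarnings(socketConnection(
      host = host, port = port, server = TRUE, blocking = TRUE,
      open = "r+b", timeout = 60))
    ok <- tryCatch({
      req <- read_http_request(con)
      if (!is.null(req)) {
        res <- handle_query(store, req$path, req$method, req$body)
        write_http_response(con, res)
        if (!quiet)
          message(sprintf("%s %s -> %d", req$method, req$path, res$status))
      }
      TRUE
    }, error = function(e) {
      if (!quiet) message("request failed: ", conditionMessage(e))
      FALSE
    })
    close(con)
    served <- served + 1
  }
  invisible(served)
}

read_http_request <- function(con) {
  line <- readLines(con, n = 1L, warn = FALSE)
  if (!length(line) || !nzchar(line)) return(NULL)
  parts <- strsplit(trimws(line), " +")[[1L]]
  if (length(parts) < 2L) return(NULL)
  method <- toupper(parts[[1L]])
  path <- parts[[2L]]
  clen <- 0L
  repeat {
    h <- readLines(con, n = 1L, warn = FALSE)
    if (!length(h) || !nzchar(trimws(h))) break
    if (grepl("^content-length:", h, ignore.case = TRUE))
      clen <- as.integer(trimws(sub("^[^:]*:", "", h)))
  }
  body <- if (clen > 0L) readBin(con, "raw", clen) else NULL
  list(method = method, path = path, body = body)
}

write_http_response <- function(con, res) {
  payload <- charToRaw(res$body %||% "")
  reason <- c("200" = "OK", "400" = "Bad Request", "404" = "Not Found",
              "409" = "Conflict")[as.character(res$status)]
  head <- paste0(
    sprintf("HTTP/1.1 %d %s\r\n", res$status, reason %||% "OK"),
    sprintf("Content-Type: %s\r\n", res$content_type),
    sprintf("Content-Length: %d\r\n", length(payload)),
    "Connection: close\r\n\r\n")
  writeBin(charToRaw(head), con)
  writeBin(payload, con)
  flush(con)
}

#' Machine-readable API description
#'
#' A compact OpenAPI-style description generated from the route table, for
#' clients that want more than the bare command list.
#' @return list (serialise with `jsonlite::toJSON`).
#' @export
api_description <- function() {
  list(
    openapi = "3.0.0",
    info = list(title = "fluxtrace query API", version = "0.1.0"),
    paths = list(
      "/commands" = list(get = list(summary = "command list for the action-schema handshake")),
      "/listModels" = list(get = list(summary = "registered models with view/modification counts")),
      "/listViews/{model_id}" = list(get = list(summary = "view names of a model")),
      "/importViewFile/{view_name}" = list(get = list(summary = "raw CyJson view document")),
      "/listModificationFiles/{model_id}" = list(get = list(summary = "modification files of a model")),
      "/saveModificationFile" = list(post = list(summary = "save a session as a new modification file (YAML body)")),
      "/solveFBA/{model_id}" = list(get = list(summary = "flux balance analysis; extra path segments are modification files in load order"))))
}
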