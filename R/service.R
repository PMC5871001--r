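SUGGESTION_PATH_PREFIX <- "/api/v1/semanticsuggestion/"

#' Handle one suggestion-service request
#'
#' Pure request handler behind the HTTP server: given a method and a raw
#' (still URL-encoded) request path, produces the status, content type and
#' JSON body of the response. The contract: `GET
#' /api/v1/semanticsuggestion/<query>` returns `{"suggestions": [...]}`
#' with at most `k` entries, underscore-joined phrases rendered with
#' spaces. A fully out-of-vocabulary query is a valid request with an
#' empty suggestion list; an empty query is a 400; a missing model a 503.
#'
#' @param model An `embedding_model`, or `NULL` (service unavailable).
#' @param method HTTP method string.
#' @param path Request path (URL-encoded).
#' @param k Maximum number of suggestions (default 5).
#' @return List with `status`, `content_type`, `body` (JSON string).
#' @export
handle_suggestion_request <- function(model, method, path, k = 5L) {
  json_error <- function(status, msg) {
    list(status = status, content_type = "application/json",
         body = as.character(jsonlite::toJSON(list(error = msg),
                                              auto_unbox = TRUE)))
  }
  if (!identical(toupper(method), "GET")) {
    return(json_error(405L, "only GET is supported"))
  }
  path <- sub("\\?.*$", "", path)
  if (!startsWith(path, SUGGESTION_PATH_PREFIX)) {
    return(json_error(404L, "unknown path"))
  }
  if (is.null(model)) {
    return(json_error(503L, "suggestion model not loaded"))
  }
  query <- utils::URLdecode(substring(path, nchar(SUGGESTION_PATH_PREFIX) + 1L))
  if (!nzchar(trimws(query))) {
    return(json_error(400L, "empty query"))
  }
  sugg <- tryCatch(top_k(model, query, k = k),
                   error = function(e) empty_suggestion_list())
  terms <- gsub("_", " ", sugg$term, fixed = TRUE)
  body <- jsonlite::toJSON(list(suggestions = terms))
  list(status = 200L, content_type = "application/json",
       body = as.character(body))
}

http_status_text <- function(status) {
  switch(as.character(status),
         "200" = "OK", "400" = "Bad Request", "404" = "Not Found",
         "405" = "Method Not Allowed", "503" = "Service Unavailable",
         "Unknown")
}

#' Serve top-k query suggestions over HTTP
#'
#' Minimal single-threaded HTTP/1.0 server over base R sockets exposing
#' `GET /api/v1/semanticsuggestion/<query>`. The model is loaded once at
#' startup; each request is stateless. Intended for local or
#' reverse-proxied deployments and for tests; requests are logged one per
#' line (timestamp, decoded query, latency, result count).
#'
#' @param model An `embedding_model`, or a path to a QSM1 model file.
#' @param host Bind address (informational; base R sockets listen on all
#'   interfaces).
#' @param port Port to listen on; 0 picks a free port in 20000-59999.
#' @param k Suggestions per response (default 5).
#' @param port_file Optional path: the chosen port is written there once
#'   the socket is listening (used by callers that picked port 0).
#' @param max_requests Stop after this many requests (default `Inf`).
#' @param quiet Suppress request logging.
#' @return Number of requests served, invisibly.
#' @export
serve_suggestions <- function(model, host = "127.0.0.1", port = 0L, k = 5L,
                              port_file = NULL, max_requests = Inf,
                              quiet = FALSE) {
  if (is.character(model)) model <- load_model(model)
  srv <- NULL
  if (port == 0L) {
    for (p in sample(20000:59999, 50L)) {
      srv <- tryCatch(serverSocket(p), error = function(e) NULL)
      if (!is.null(srv)) { port <- p; break }
    }
  } else {
    srv <- serverSocket(port)
  }
  if (is.null(srv)) stop("serve_suggestions: could not bind a port")
  on.exit(close(srv), add = TRUE)
  if (!is.null(port_file)) writeLines(as.character(port), port_file)
  if (!quiet) message("listening on ", host, ":", port)
  served <- 0L
  while (served < max_requests) {
    con <- socketAccept(srv, blocking = TRUE, open = "r+b", timeout = 30)
    t0 <- Sys.time()
    req <- tryCatch(readLines(con, n = 1L, warn = FALSE),
                    error = function(e) character(0))
    # drain headers so well-behaved clients are not reset mid-send
    repeat {
      h <- tryCatch(readLines(con, n = 1L, warn = FALSE),
                    error = function(e) character(0))
      if (length(h) == 0L || !nzchar(h)) break
    }
    if (length(req) == 1L) {
      parts <- strsplit(trimws(req), "[[:space:]]+")[[1L]]
      method <- if (length(parts) >= 1L) parts[1L] else ""
      path <- if (length(parts) >= 2L) parts[2L] else "/"
      resp <- handle_suggestion_request(model, method, path, k = k)
      payload <- charToRaw(resp$body)
      writeLines(c(paste0("HTTP/1.0 ", resp$status, " ",
                          http_status_text(resp$status)),
                   paste0("Content-Type: ", resp$content_type,
                          "; charset=utf-8"),
                   paste0("Content-Length: ", length(payload)),
                   "Connection: close", ""),
                 con, sep = "\r\n")
      writeBin(payload, con)
      flush(con)
      served <- served + 1L
      if (!quiet) {
        n_sugg <- if (resp$status == 200L) {
          length(jsonlite::fromJSON(resp$body)$suggestions)
        } else {
          0L
        }
        message(sprintf("[%s] %s -> %d (%d suggestions, %.1f ms)",
                        format(t0, "%Y-%m-%dT%H:%M:%S"),
                        utils::URLdecode(path), resp$status, n_sugg,
                        1000 * as.numeric(Sys.time() - t0)))
      }
    }
    close(con)
  }
  invisible(served)
}

#' Perform one HTTP GET against a local suggestion service
#'
#' Tiny HTTP/1.0 client used by tests and examples; returns the parsed
#' status line and body.
#'
#' @param host,port Server address.
#' @param path Request path (already URL-encoded).
#' @param timeout Socket timeout in seconds.
#' @return List with `status` (integer) and `body` (string).
#' @export
http_get <- function(host, port, path, timeout = 10) {
  con <- socketConnection(host, port, blocking = TRUE, open = "r+b",
                          timeout = timeout)
  on.exit(close(con))
  writeLines(c(paste("GET", path, "HTTP/1.0"),
               paste0("Host: ", host), ""), con, sep = "\r\n")
  flush(con)
  lines <- character(0)
  repeat {
    l <- readLines(con, n = 1L, warn = FALSE)
    if (length(l) == 0L) break
    lines <- c(lines, l)
  }
  if (length(lines) == 0L) stop("http_get: empty response")
  status <- as.integer(strsplit(lines[1L], " ")[[1L]][2L])
  blank <- which(!nzchar(trimws(lines)))[1L]
  body <- if (is.na(blank)) "" else paste(lines[-seq_len(blank)],
                                          collapse = "\n")
  list(status = status, body = body)
}
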