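## Multi-user collaboration layer: a TCP session server speaking
## newline-delimited JSON records, a simulated client that streams epochs
## and applies closed-loop stimulus feedback, route-based analysis dispatch,
## and lossless session archives. The server is poll-driven (server_poll()),
## so a client and server can be interleaved deterministically inside one R
## process; serve() wraps the poll loop for standalone use.

MESSAGE_TYPES <- c("JOIN", "ACK", "START_PARADIGM", "STIM_SYNC", "EEG_DATA",
                   "ANALYSIS_RESULT", "FEEDBACK", "STOP_PARADIGM", "ERROR")

#' Construct one protocol message
#'
#' @param type one of JOIN, ACK, START_PARADIGM, STIM_SYNC, EEG_DATA,
#'   ANALYSIS_RESULT, FEEDBACK, STOP_PARADIGM, ERROR.
#' @param session_id,participant_id session membership.
#' @param seq per-(session, participant, direction) strictly increasing
#'   sequence number.
#' @param route analysis route for EEG_DATA/ANALYSIS_RESULT
#'   (e.g. `/analysis/ssvep`).
#' @param payload type-specific list.
#' @return a `session_message` (a named list).
#' @export
session_message <- function(type, session_id = "", participant_id = "",
                            seq = 1L, route = NULL, payload = NULL) {
  if (!type %in% MESSAGE_TYPES) abort("unknown message type '%s'", type)
  structure(list(type = type, session_id = session_id,
                 participant_id = participant_id, seq = as.integer(seq),
                 timestamp_ms = as.numeric(Sys.time()) * 1000,
                 route = route, payload = payload),
            class = "session_message")
}

encode_message <- function(msg) {
  as.character(jsonlite::toJSON(unclass(msg), auto_unbox = TRUE, digits = I(17),
                                null = "null"))
}

decode_message <- function(line) {
  msg <- jsonlite::fromJSON(line, simplifyVector = TRUE)
  class(msg) <- "session_message"
  msg
}

## ---- low-level non-blocking line transport --------------------------------

sock_send <- function(ep, line) {
  writeBin(charToRaw(paste0(line, "\n")), ep$con)
  flush(ep$con)
}

sock_read_lines <- function(ep) {
  repeat {
    chunk <- readBin(ep$con, "raw", 65536L)
    if (length(chunk) == 0L) break
    ep$buf <- c(ep$buf, chunk)
  }
  if (length(ep$buf) == 0L) return(character(0))
  txt <- rawToChar(ep$buf)
  if (!grepl("\n", txt, fixed = TRUE)) return(character(0))
  parts <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  complete <- endsWith(txt, "\n")
  if (complete) {
    ep$buf <- raw(0)
    parts
  } else {
    ep$buf <- charToRaw(parts[length(parts)])
    parts[-length(parts)]
  }
}

## ---- server ---------------------------------------------------------------

#' Start a collaboration session server
#'
#' Listens on a TCP port and manages sessions: membership (JOIN/ACK),
#' paradigm start/stop with stimulation-mode synchronization (START_PARADIGM
#' and STIM_SYNC reach every member before any EEG_DATA is accepted),
#' route-dispatched analysis of streamed epochs with closed-loop
#' ANALYSIS_RESULT replies, inter-brain coupling at STOP_PARADIGM, and
#' archival. The returned handle is poll-driven: call [server_poll()] (or
#' [serve()]) to make progress.
#'
#' @param port TCP port; 0 picks a free port (see `handle$port`).
#' @param archive_root directory under which sessions are archived at stop
#'   (`NULL` disables archiving).
#' @param host interface to bind.
#' @return a server handle (environment).
#' @export
start_server <- function(port = 0, archive_root = NULL, host = "127.0.0.1") {
  srv <- new.env(parent = emptyenv())
  if (port == 0) {
    for (i in 1:50) {
      port_try <- sample(20000:60000, 1)
      ok <- tryCatch({srv$sock <- serverSocket(port_try); TRUE},
                     error = function(e) FALSE)
      if (ok) { port <- port_try; break }
    }
    if (port == 0) abort("could not find a free port")
  } else {
    srv$sock <- serverSocket(port)   # errors if the port is in use
  }
  srv$port <- port
  srv$host <- host
  srv$connections <- list()
  srv$sessions <- new.env(parent = emptyenv())
  srv$archive_root <- archive_root
  srv$routes <- list()
  srv$running <- TRUE
  register_route(srv, "/analysis/ssvep", route_ssvep)
  register_route(srv, "/analysis/coupling", route_coupling)
  class(srv) <- "collab_server"
  srv
}

#' @export
print.collab_server <- function(x, ...) {
  cat(sprintf("<collab_server> %s:%d, %d connection(s), %d session(s)\n",
              x$host, x$port, length(x$connections),
              length(ls(x$sessions))))
  invisible(x)
}

#' Register a custom analysis route
#'
#' Routes map a routing address to a handler `function(server, session,
#' msg)` returning a result payload; this is the extension point for
#' user-defined analyses.
#'
#' @param server a server handle.
#' @param route routing address string, e.g. `/analysis/mymethod`.
#' @param handler handler function.
#' @return the server handle, invisibly.
#' @export
register_route <- function(server, route, handler) {
  server$routes[[route]] <- handler
  invisible(server)
}

get_session <- function(server, session_id, create = FALSE) {
  if (!exists(session_id, server$sessions)) {
    if (!create) return(NULL)
    s <- new.env(parent = emptyenv())
    s$session_id <- session_id
    s$members <- character(0)
    s$paradigm <- NULL
    s$started <- FALSE
    s$stopped <- FALSE
    s$buffers <- list()        # participant -> list of eeg_epoch
    s$results <- list()        # analysis results in computation order
    s$transcript <- list()     # every message touching this session
    s$stimulus <- NULL
    assign(session_id, s, server$sessions)
  }
  get(session_id, server$sessions)
}

log_msg <- function(session, direction, msg) {
  rec <- unclass(msg)
  rec$direction <- direction
  session$transcript[[length(session$transcript) + 1L]] <- rec
}

send_to <- function(server, conn, session, msg) {
  conn$seq_out <- conn$seq_out + 1L
  msg$seq <- conn$seq_out
  if (!is.null(session)) log_msg(session, "server_to_client", msg)
  sock_send(conn, encode_message(msg))
}

broadcast <- function(server, session, type, route = NULL, payload = NULL) {
  for (conn in server$connections) {
    if (is.null(conn$session_id) || conn$session_id != session$session_id)
      next
    send_to(server, conn, session,
            session_message(type, session$session_id, conn$participant_id,
                            route = route, payload = payload))
  }
}

send_error <- function(server, conn, reason) {
  session <- if (!is.null(conn$session_id))
    get_session(server, conn$session_id) else NULL
  send_to(server, conn, session,
          session_message("ERROR", conn$session_id %||% "",
                          conn$participant_id %||% "",
                          payload = list(reason = reason)))
}

#' Poll the server once
#'
#' Accepts pending connections, reads complete protocol lines from every
#' client, and handles them. Returns the number of messages processed.
#'
#' @param server a server handle.
#' @param timeout seconds to wait for socket activity (0 = return at once).
#' @return integer count of handled messages, invisibly.
#' @export
server_poll <- function(server, timeout = 0) {
  while (socketSelect(list(server$sock), timeout = 0)) {
    con <- socketAccept(server$sock, blocking = FALSE, open = "r+b")
    ep <- new.env(parent = emptyenv())
    ep$con <- con; ep$buf <- raw(0)
    ep$session_id <- NULL; ep$participant_id <- NULL
    ep$seq_in <- 0L; ep$seq_out <- 0L
    server$connections[[length(server$connections) + 1L]] <- ep
  }
  handled <- 0L
  if (length(server$connections)) {
    ready <- socketSelect(lapply(server$connections, `[[`, "con"),
                          timeout = timeout)
    for (k in which(ready | vapply(server$connections,
                                   function(e) length(e$buf) > 0,
                                   logical(1)))) {
      conn <- server$connections[[k]]
      for (line in sock_read_lines(conn)) {
        handled <- handled + 1L
        handle_line(server, conn, line)
      }
    }
  }
  invisible(handled)
}

handle_line <- function(server, conn, line) {
  msg <- tryCatch(decode_message(line), error = function(e) NULL)
  if (is.null(msg) || is.null(msg$type) || !msg$type %in% MESSAGE_TYPES) {
    send_error(server, conn, "malformed message")
    return(invisible())
  }
  if (!is.null(msg$seq) && msg$seq <= conn$seq_in) {
    send_error(server, conn, sprintf(
      "sequence number %d not strictly increasing (last was %d)",
      msg$seq, conn$seq_in))
    return(invisible())
  }
  conn$seq_in <- msg$seq %||% (conn$seq_in + 1L)
  tryCatch(handle_message(server, conn, msg),
           error = function(e) send_error(server, conn, conditionMessage(e)))
  invisible()
}

handle_message <- function(server, conn, msg) {
  switch(msg$type,
    JOIN = {
      session <- get_session(server, msg$session_id, create = TRUE)
      conn$session_id <- msg$session_id
      conn$participant_id <- msg$participant_id
      if (!msg$participant_id %in% session$members)
        session$members <- c(session$members, msg$participant_id)
      log_msg(session, "client_to_server", msg)
      broadcast(server, session, "ACK",
                payload = list(participants = session$members))
    },
    START_PARADIGM = {
      session <- need_session(server, conn)
      log_msg(session, "client_to_server", msg)
      paradigm <- msg$payload
      if (is.null(paradigm$target_frequencies))
        abort("paradigm config must name target_frequencies")
      session$paradigm <- paradigm
      session$stimulus <- default_stimulus_state(paradigm$target_frequencies)
      session$started <- TRUE
      broadcast(server, session, "START_PARADIGM", payload = paradigm)
      broadcast(server, session, "STIM_SYNC",
                payload = list(stimuli = session$stimulus))
    },
    EEG_DATA = {
      session <- need_session(server, conn)
      if (!isTRUE(session$started)) {
        log_msg(session, "client_to_server", msg)
        abort("paradigm not started")
      }
      log_msg(session, "client_to_server", msg)
      epoch <- payload_to_epoch(msg$payload, session$paradigm)
      pid <- msg$participant_id
      epoch$participant_id <- pid
      session$buffers[[pid]] <- c(session$buffers[[pid]], list(epoch))
      route <- msg$route %||% "/analysis/ssvep"
      result <- dispatch_analysis(server, route,
                                  list(kind = "epoch", epoch = epoch),
                                  session)
      if (!is.null(result)) {
        session$results[[length(session$results) + 1L]] <- result
        send_to(server, conn, session,
                session_message("ANALYSIS_RESULT", session$session_id, pid,
                                route = route,
                                payload = result_to_record(result)))
      }
    },
    FEEDBACK = {
      session <- need_session(server, conn)
      log_msg(session, "client_to_server", msg)
      if (!is.null(msg$payload$stimuli))
        session$stimulus <- msg$payload$stimuli
    },
    STOP_PARADIGM = {
      session <- need_session(server, conn)
      log_msg(session, "client_to_server", msg)
      finish_session(server, session)
    },
    abort("unexpected message type '%s' from client", msg$type))
  invisible()
}

need_session <- function(server, conn) {
  if (is.null(conn$session_id)) abort("JOIN required before this message")
  get_session(server, conn$session_id)
}

finish_session <- function(server, session) {
  if (isTRUE(session$stopped)) return(invisible())
  # coupling for every participant pair at every paradigm target
  members <- names(session$buffers)
  if (length(members) >= 2L && isTRUE(session$started)) {
    for (i in seq_len(length(members) - 1L)) for (j in (i + 1):length(members)) {
      for (f in session$paradigm$target_frequencies) {
        res <- tryCatch(
          dispatch_analysis(server, "/analysis/coupling",
                            list(kind = "pair", a = members[i],
                                 b = members[j], target_frequency = f),
                            session),
          error = function(e) NULL)
        if (is.null(res)) next
        session$results[[length(session$results) + 1L]] <- res
        broadcast(server, session, "ANALYSIS_RESULT",
                  route = "/analysis/coupling",
                  payload = result_to_record(res))
      }
    }
  }
  session$stopped <- TRUE
  broadcast(server, session, "STOP_PARADIGM",
            payload = list(reason = "stopped"))
  if (!is.null(server$archive_root))
    session$archive_dir <- archive_session(server, session$session_id)
  invisible()
}

#' Dispatch an analysis payload by routing address
#'
#' Looks up the route in the server's registry (see [register_route()]) and
#' invokes its handler; unknown routes raise an error naming the route.
#'
#' @param server a server handle.
#' @param route routing address string.
#' @param payload handler-specific payload.
#' @param session session environment the payload belongs to.
#' @return the handler's result (a result object or `NULL`).
#' @export
dispatch_analysis <- function(server, route, payload, session) {
  h <- server$routes[[route]]
  if (is.null(h)) abort("unknown route '%s'", route)
  h(server, session, payload)
}

# /analysis/ssvep: Welch PSD + occipital argmax on one epoch. Epochs are
# expected preprocessed at the paradigm rate (the client filters its full
# recording; filtering isolated 1-s chunks would not match the offline
# pipeline); raw-rate epochs are resampled and band-passed as a fallback.
route_ssvep <- function(server, session, payload) {
  if (!identical(payload$kind, "epoch")) abort("route expects an epoch payload")
  epoch <- payload$epoch
  paradigm <- session$paradigm
  rate <- paradigm$rate %||% 512
  if (epoch$sampling_rate != rate) {
    n_out <- floor(ncol(epoch$samples) * rate / epoch$sampling_rate)
    x <- t(apply(epoch$samples, 1, fft_resample, n_out = n_out))
    band <- paradigm$band %||% c(4, 45)
    filt <- butter_bandpass(band[1], band[2], rate)
    x <- t(apply(x, 1, function(v) filtfilt(filt, v)))
    epoch <- new_epoch(epoch$participant_id, epoch$trial_index,
                       epoch$epoch_index, epoch$true_frequency,
                       epoch$channel_labels, rate, x)
  }
  decode_individual(welch_psd(epoch),
                    occipital_channels = paradigm$occipital_channels %||%
                      c("O1", "O2", "Oz"),
                    candidates = paradigm$target_frequencies)
}

# /analysis/coupling: Fisher-Z aggregated band-power correlation between two
# participants' buffered trials at one target frequency.
route_coupling <- function(server, session, payload) {
  if (!identical(payload$kind, "pair")) abort("route expects a pair payload")
  trials_of <- function(pid) {
    eps <- session$buffers[[pid]]
    if (is.null(eps)) abort("no buffered data for participant '%s'", pid)
    psds <- lapply(eps, welch_psd)
    tr <- group_psds_by_trial(psds)
    tr[vapply(tr, function(t) t[[1]]$epoch_info$true_frequency,
              numeric(1)) == payload$target_frequency]
  }
  coupling_analysis(trials_of(payload$a), trials_of(payload$b),
                    payload$target_frequency)
}

#' Run the server as a blocking loop
#'
#' Polls until `stop_after` seconds have elapsed (or indefinitely), then
#' shuts down cleanly, flushing archives for any unstopped sessions.
#'
#' @param server a server handle from [start_server()].
#' @param stop_after seconds to serve, `Inf` to serve until interrupted.
#' @return the server handle, invisibly.
#' @export
serve <- function(server, stop_after = Inf) {
  t0 <- Sys.time()
  while (as.numeric(Sys.time() - t0, units = "secs") < stop_after)
    server_poll(server, timeout = 0.1)
  stop_server(server)
  invisible(server)
}

#' Shut a server down
#'
#' Archives any started-but-unstopped sessions, then closes every
#' connection and the listening socket.
#'
#' @param server a server handle.
#' @export
stop_server <- function(server) {
  for (sid in ls(server$sessions)) {
    s <- get(sid, server$sessions)
    if (isTRUE(s$started) && !isTRUE(s$stopped)) finish_session(server, s)
  }
  for (conn in server$connections)
    tryCatch(close(conn$con), error = function(e) NULL)
  server$connections <- list()
  tryCatch(close(server$sock), error = function(e) NULL)
  server$running <- FALSE
  invisible(server)
}

## ---- payload helpers ------------------------------------------------------

epoch_to_payload <- function(epoch) {
  list(trial_index = epoch$trial_index,
       epoch_index = epoch$epoch_index,
       true_frequency = epoch$true_frequency,
       channel_labels = epoch$channel_labels,
       n_channels = nrow(epoch$samples),
       n_samples = ncol(epoch$samples),
       sampling_rate = epoch$sampling_rate,
       samples = encode_samples(as.vector(epoch$samples)))
}

payload_to_epoch <- function(payload, paradigm) {
  need <- c("channel_labels", "n_channels", "n_samples", "sampling_rate",
            "samples")
  miss <- setdiff(need, names(payload))
  if (length(miss))
    abort("EEG_DATA payload missing field(s): %s", paste(miss, collapse = ", "))
  if (length(payload$channel_labels) != payload$n_channels)
    abort("EEG_DATA payload channel count mismatch")
  if (!is.null(paradigm$n_channels) &&
      payload$n_channels != paradigm$n_channels)
    abort("EEG_DATA channel count %d does not match paradigm (%d)",
          payload$n_channels, paradigm$n_channels)
  x <- matrix(decode_samples(payload$samples,
                             payload$n_channels * payload$n_samples),
              nrow = payload$n_channels)
  new_epoch(participant_id = payload$participant_id %||% "",
            trial_index = payload$trial_index %||% 1L,
            epoch_index = payload$epoch_index %||% 1L,
            true_frequency = payload$true_frequency,
            channel_labels = payload$channel_labels,
            sampling_rate = payload$sampling_rate,
            samples = x)
}

#' Default stimulus state for a paradigm
#'
#' One descriptor per target: flicker frequency, color, size and form, plus
#' an active flag toggled by feedback policies.
#'
#' @param target_frequencies Hz, unique within the paradigm.
#' @return data.frame stimulus state.
#' @export
default_stimulus_state <- function(target_frequencies) {
  if (anyDuplicated(target_frequencies))
    abort("target frequencies must be unique within a paradigm")
  data.frame(frequency = target_frequencies,
             color = "#FFFFFF", size = 1,
             form = "checkerboard", active = FALSE)
}

#' Closed-loop policy: highlight the decoded target
#'
#' Enlarges and recolors the stimulus whose frequency was just decoded and
#' resets the others: the canonical closed-loop feedback rule.
#'
#' @param state stimulus state data.frame.
#' @param result a `decoding_result`.
#' @return updated state.
#' @export
feedback_highlight <- function(state, result) {
  hit <- state$frequency == result$predicted_frequency
  state$size <- ifelse(hit, 1.2, 1)
  state$color <- ifelse(hit, "#FFD700", "#FFFFFF")
  state$active <- hit
  state
}
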