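## Simulated client side of the collaboration protocol and the in-process
## session orchestrator used by tests, the demo and the CLI.

#' Connect a client to a running session server
#'
#' @param host,port server address.
#' @param server optional in-process server handle; when given, waiting
#'   operations pump the server between socket polls so a single R process
#'   can drive both ends deterministically.
#' @return a client handle (environment).
#' @export
connect_client <- function(host = "127.0.0.1", port, server = NULL) {
  cl <- new.env(parent = emptyenv())
  cl$con <- socketConnection(host, port, blocking = FALSE, open = "r+b")
  cl$buf <- raw(0)
  cl$seq_out <- 0L
  cl$seq_in <- 0L
  cl$inbox <- list()
  cl$transcript <- list()
  cl$local_server <- server
  class(cl) <- "collab_client"
  cl
}

#' @export
print.collab_client <- function(x, ...) {
  cat(sprintf("<collab_client> %s@%s: %d message(s) sent, %d received\n",
              x$participant_id %||% "?", x$session_id %||% "?",
              x$seq_out, x$seq_in))
  invisible(x)
}

client_send <- function(cl, type, route = NULL, payload = NULL) {
  cl$seq_out <- cl$seq_out + 1L
  msg <- session_message(type, cl$session_id %||% "",
                         cl$participant_id %||% "", seq = cl$seq_out,
                         route = route, payload = payload)
  rec <- unclass(msg); rec$direction <- "sent"
  cl$transcript[[length(cl$transcript) + 1L]] <- rec
  sock_send(cl, encode_message(msg))
  invisible(msg)
}

client_poll <- function(cl) {
  got <- 0L
  for (line in sock_read_lines(cl)) {
    msg <- decode_message(line)
    if (!is.null(msg$seq)) {
      if (msg$seq != cl$seq_in + 1L)
        abort("gap in server sequence numbers: got %d after %d",
              msg$seq, cl$seq_in)
      cl$seq_in <- msg$seq
    }
    rec <- unclass(msg); rec$direction <- "received"
    cl$transcript[[length(cl$transcript) + 1L]] <- rec
    cl$inbox[[length(cl$inbox) + 1L]] <- msg
    got <- got + 1L
  }
  got
}

# Wait until `n` messages of the given type(s) have arrived, pumping the
# in-process server if there is one.
client_wait <- function(cl, types, n = 1L, timeout = 10) {
  t0 <- Sys.time()
  count <- function() sum(vapply(cl$inbox, function(m) m$type %in% types,
                                 logical(1)))
  while (count() < n) {
    if (!is.null(cl$local_server)) server_poll(cl$local_server)
    client_poll(cl)
    if (as.numeric(Sys.time() - t0, units = "secs") > timeout)
      abort("timed out waiting for %s", paste(types, collapse = "/"))
  }
  Filter(function(m) m$type %in% types, cl$inbox)
}

client_take <- function(cl, types) {
  keep <- vapply(cl$inbox, function(m) m$type %in% types, logical(1))
  out <- cl$inbox[keep]
  cl$inbox <- cl$inbox[!keep]
  out
}

client_join <- function(cl, session_id, participant_id) {
  cl$session_id <- session_id
  cl$participant_id <- participant_id
  client_send(cl, "JOIN")
  client_wait(cl, "ACK")
  invisible(cl)
}

#' Simulate one client streaming a recording through the server
#'
#' Joins the session, (optionally) starts the paradigm, preprocesses its
#' recording with the standard chain, streams it epoch by epoch as EEG_DATA
#' to `route`, applies `feedback_policy` to its stimulus state on every
#' ANALYSIS_RESULT (logging a FEEDBACK message whenever the state changes),
#' and returns its full ordered transcript.
#'
#' @param cl a connected client handle ([connect_client()]).
#' @param session_id,participant_id membership.
#' @param recording an annotated `eeg_recording` matching the paradigm.
#' @param paradigm paradigm config list (required from the participant that
#'   starts the paradigm; later joiners pass `NULL` and inherit it).
#' @param feedback_policy `function(state, result) -> state`, e.g.
#'   [feedback_highlight()]; `NULL` leaves the stimulus untouched.
#' @param route analysis route for the streamed epochs.
#' @param stop_when_done send STOP_PARADIGM after the last epoch.
#' @return list with `transcript`, per-epoch `results` (decoded), and the
#'   final `stimulus` state.
#' @export
simulate_client <- function(cl, session_id, participant_id, recording,
                            paradigm = NULL, feedback_policy = NULL,
                            route = "/analysis/ssvep",
                            stop_when_done = TRUE) {
  client_join(cl, session_id, participant_id)
  if (!is.null(paradigm)) {
    client_send(cl, "START_PARADIGM", payload = paradigm)
  }
  client_wait(cl, "START_PARADIGM")
  client_wait(cl, "STIM_SYNC")
  started <- Filter(function(m) m$type == "START_PARADIGM", cl$inbox)
  paradigm <- started[[length(started)]]$payload
  cl$stimulus <- default_stimulus_state(paradigm$target_frequencies)

  epochs <- preprocess_pipeline(recording,
                                rate = paradigm$rate %||% 512,
                                band = paradigm$band %||% c(4, 45),
                                epoch_duration = paradigm$epoch_duration %||% 1)
  results <- stream_epochs(cl, epochs, route, feedback_policy)
  if (stop_when_done) {
    client_send(cl, "STOP_PARADIGM")
    client_wait(cl, "STOP_PARADIGM")
  }
  list(transcript = cl$transcript, results = results, stimulus = cl$stimulus)
}

# Stream epochs one at a time; each EEG_DATA is answered by exactly one
# ANALYSIS_RESULT (or ERROR), which is consumed from the inbox so later
# waits never match stale messages.
stream_epochs <- function(cl, epochs, route, feedback_policy) {
  results <- list()
  for (ep in epochs) {
    client_send(cl, "EEG_DATA", route = route,
                payload = epoch_to_payload(ep))
    client_wait(cl, c("ANALYSIS_RESULT", "ERROR"), n = 1L)
    m <- client_take(cl, c("ANALYSIS_RESULT", "ERROR"))[[1]]
    if (m$type == "ERROR")
      abort("server error: %s", m$payload$reason)
    res <- record_to_result(m$payload)
    results[[length(results) + 1L]] <- res
    if (!is.null(feedback_policy) && inherits(res, "decoding_result")) {
      new_state <- feedback_policy(cl$stimulus, res)
      if (!identical(new_state, cl$stimulus)) {
        cl$stimulus <- new_state
        client_send(cl, "FEEDBACK", payload = list(stimuli = new_state))
      }
    }
  }
  results
}

#' Run a complete multi-participant collaborative session in-process
#'
#' Starts a server, connects one simulated client per recording, joins them
#' to one session, starts the paradigm (every member receives
#' START_PARADIGM and STIM_SYNC before any data flows), streams all
#' recordings trial-by-trial interleaved across participants, stops the
#' paradigm (triggering inter-brain coupling for every pair and target),
#' optionally archives, and shuts down.
#'
#' @param recordings list of annotated `eeg_recording` (shared schedule).
#' @param paradigm paradigm config; `NULL` derives it from the first
#'   recording's annotations (targets, trial structure) with the standard
#'   preprocessing defaults (512 Hz, 4-45 Hz, 1-s epochs).
#' @param feedback_policy closed-loop policy applied by every client.
#' @param archive_root directory for session archives (`NULL` = no archive).
#' @param session_id session identifier.
#' @param route analysis route for streamed epochs.
#' @return list with per-participant `transcripts` and `decoding` results,
#'   `coupling` results, the final `stimulus` states, and `archive_dir`.
#' @export
run_collab_session <- function(recordings, paradigm = NULL,
                               feedback_policy = NULL, archive_root = NULL,
                               session_id = "session-1",
                               route = "/analysis/ssvep") {
  if (is.null(paradigm)) paradigm <- paradigm_from_recording(recordings[[1]])
  server <- start_server(port = 0, archive_root = archive_root)
  on.exit(stop_server(server), add = TRUE)
  clients <- lapply(seq_along(recordings), function(i)
    connect_client(port = server$port, server = server))
  pids <- vapply(recordings, `[[`, "", "participant_id")
  for (i in seq_along(clients))
    client_join(clients[[i]], session_id, pids[i])
  client_send(clients[[1]], "START_PARADIGM", payload = paradigm)
  for (cl in clients) {
    client_wait(cl, "START_PARADIGM")
    client_wait(cl, "STIM_SYNC")
    cl$stimulus <- default_stimulus_state(paradigm$target_frequencies)
  }
  epochs <- lapply(recordings, preprocess_pipeline,
                   rate = paradigm$rate %||% 512,
                   band = paradigm$band %||% c(4, 45),
                   epoch_duration = paradigm$epoch_duration %||% 1)
  results <- lapply(clients, function(cl) list())
  trials <- unique(vapply(epochs[[1]], `[[`, integer(1), "trial_index"))
  for (tr in trials) {
    for (i in seq_along(clients)) {
      eps <- Filter(function(e) e$trial_index == tr, epochs[[i]])
      results[[i]] <- c(results[[i]],
                        stream_epochs(clients[[i]], eps, route,
                                      feedback_policy))
    }
  }
  client_send(clients[[1]], "STOP_PARADIGM")
  for (cl in clients) client_wait(cl, "STOP_PARADIGM")
  coupling <- lapply(client_take(clients[[1]], "ANALYSIS_RESULT"),
                     function(m) record_to_result(m$payload))
  coupling <- Filter(function(r) inherits(r, "coupling_result"), coupling)
  session <- get_session(server, session_id)
  out <- list(transcripts = lapply(clients, `[[`, "transcript"),
              decoding = stats::setNames(results, pids),
              coupling = coupling,
              stimulus = lapply(clients, `[[`, "stimulus"),
              archive_dir = session$archive_dir %||% NULL,
              paradigm = paradigm)
  for (cl in clients) tryCatch(close(cl$con), error = function(e) NULL)
  out
}

#' Derive a paradigm config from an annotated recording
#'
#' @param recording an annotated `eeg_recording`.
#' @param rate,band,epoch_duration preprocessing parameters to advertise.
#' @return paradigm config list for START_PARADIGM.
#' @export
paradigm_from_recording <- function(recording, rate = 512, band = c(4, 45),
                                    epoch_duration = 1) {
  freqs <- sort(unique(annotation_frequency(recording$annotations$label)))
  list(paradigm_type = "SSVEP",
       target_frequencies = freqs,
       trial_duration = recording$annotations$duration[1],
       n_trials = nrow(recording$annotations),
       n_channels = length(recording$channel_labels),
       channel_labels = recording$channel_labels,
       rate = rate, band = band, epoch_duration = epoch_duration,
       occipital_channels = c("O1", "O2", "Oz"))
}
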