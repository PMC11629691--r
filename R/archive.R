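#' Archive a session to disk
#'
#' Writes, under `<archive_root>/<session_id>/`: a JSON manifest (members,
#' paradigm, stimulus configuration), one EDF file per participant
#' reassembled from the streamed epochs (sample counts match the streamed
#' totals exactly), the full message transcript as line-delimited JSON, and
#' every analysis result via [write_results()]. [read_archive()] restores
#' all of it.
#'
#' @param server a server handle.
#' @param session_id id of an existing session.
#' @return the archive directory path.
#' @export
archive_session <- function(server, session_id) {
  session <- get_session(server, session_id)
  if (is.null(session)) abort("no such session '%s'", session_id)
  root <- server$archive_root %||% tempfile("archive-")
  dir <- file.path(root, session_id)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort("cannot create archive directory '%s'", dir)

  edf_files <- list()
  for (pid in names(session$buffers)) {
    rec <- epochs_to_recording(session$buffers[[pid]], pid)
    fn <- paste0(gsub("[^A-Za-z0-9_-]", "_", pid), ".edf")
    write_edf(rec, file.path(dir, fn))
    edf_files[[pid]] <- fn
  }
  manifest <- list(schema = RESULTS_SCHEMA,
                   session_id = session_id,
                   participants = session$members,
                   paradigm = session$paradigm,
                   stimulus = session$stimulus,
                   eeg_files = edf_files,
                   n_messages = length(session$transcript),
                   n_results = length(session$results))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null")
  writeLines(vapply(session$transcript, function(m)
    as.character(jsonlite::toJSON(m, auto_unbox = TRUE, digits = I(17),
                                  null = "null")), character(1)),
    file.path(dir, "transcript.ndjson"))
  write_results(session$results, file.path(dir, "results.ndjson"))
  dir
}

# Reassemble one participant's streamed epochs into a continuous recording
# with one annotation per trial (duration = streamed epochs per trial).
epochs_to_recording <- function(epochs, participant_id) {
  if (length(epochs) == 0L)
    abort("no epochs buffered for participant '%s'", participant_id)
  fs <- epochs[[1]]$sampling_rate
  samples <- do.call(cbind, lapply(epochs, `[[`, "samples"))
  ep_dur <- ncol(epochs[[1]]$samples) / fs
  trials <- vapply(epochs, `[[`, integer(1), "trial_index")
  freqs <- vapply(epochs, `[[`, numeric(1), "true_frequency")
  onset <- c(0, cumsum(rep(ep_dur, length(epochs))))[seq_along(epochs)]
  keep <- !duplicated(trials)
  ann <- data.frame(onset = onset[keep],
                    duration = vapply(trials[keep], function(tr)
                      sum(trials == tr) * ep_dur, numeric(1)),
                    label = sprintf("target:%g", freqs[keep]))
  new_recording(participant_id, epochs[[1]]$channel_labels, fs, samples, ann)
}

#' Read a session archive back
#'
#' @param dir archive directory written by [archive_session()].
#' @return list with `manifest`, `recordings` (named by participant),
#'   `transcript` (list of messages) and `results`.
#' @export
read_archive <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) abort("not a session archive: missing manifest.json")
  manifest <- jsonlite::fromJSON(mf, simplifyVector = TRUE)
  if (!identical(manifest$schema, RESULTS_SCHEMA))
    abort("unsupported archive schema '%s'", manifest$schema %||% "<missing>")
  recs <- lapply(manifest$eeg_files, function(fn)
    read_edf(file.path(dir, fn)))
  transcript <- lapply(readLines(file.path(dir, "transcript.ndjson")),
                       jsonlite::fromJSON, simplifyVector = TRUE)
  results <- read_results(file.path(dir, "results.ndjson"))
  list(manifest = manifest, recordings = recs, transcript = transcript,
       results = results)
}
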