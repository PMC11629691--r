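# The server is poll-driven, so client and server run interleaved inside
# this process over real loopback TCP sockets.

local_server <- function(archive_root = NULL) {
  srv <- start_server(archive_root = archive_root)
  withr::defer(stop_server(srv), envir = parent.frame())
  srv
}

local_client <- function(srv) {
  cl <- connect_client(port = srv$port, server = srv)
  withr::defer(tryCatch(close(cl$con), error = function(e) NULL),
               envir = parent.frame())
  cl
}

small_session <- function(n_participants = 2, seed = 7, noise = 2,
                          gain = 1) {
  cfg <- quick_cfg(trial_duration = 2, trials_per_target = 2,
                   noise_amplitude = noise, coupling_gain = gain,
                   n_participants = n_participants, seed = seed)
  generate_group_session(cfg)
}

test_that("JOIN membership is acknowledged to every member", {
  srv <- local_server()
  c1 <- local_client(srv)
  c2 <- local_client(srv)
  ssvepcollab:::client_join(c1, "s1", "alice")
  ssvepcollab:::client_join(c2, "s1", "bob")
  ssvepcollab:::client_wait(c1, "ACK", n = 2)
  acks1 <- Filter(function(m) m$type == "ACK", c1$inbox)
  expect_equal(acks1[[2]]$payload$participants, c("alice", "bob"))
  expect_equal(Filter(function(m) m$type == "ACK",
                      c2$inbox)[[1]]$payload$participants,
               c("alice", "bob"))
})

test_that("EEG_DATA before START_PARADIGM draws the ordering error", {
  srv <- local_server()
  cl <- local_client(srv)
  ssvepcollab:::client_join(cl, "s1", "alice")
  ep <- tone_epoch(10)
  ssvepcollab:::client_send(cl, "EEG_DATA", route = "/analysis/ssvep",
                            payload = ssvepcollab:::epoch_to_payload(ep))
  msgs <- ssvepcollab:::client_wait(cl, "ERROR")
  expect_match(msgs[[1]]$payload$reason, "paradigm not started")
})

test_that("malformed messages get an ERROR reply on a live connection", {
  srv <- local_server()
  cl <- local_client(srv)
  ssvepcollab:::sock_send(cl, "this is not json")
  msgs <- ssvepcollab:::client_wait(cl, "ERROR")
  expect_match(msgs[[1]]$payload$reason, "malformed")
  # connection survives: a JOIN still works
  cl$session_id <- "s1"; cl$participant_id <- "alice"
  ssvepcollab:::client_send(cl, "JOIN")
  expect_length(ssvepcollab:::client_wait(cl, "ACK"), 1)
})

test_that("unknown routes are rejected by name", {
  srv <- local_server()
  session <- ssvepcollab:::get_session(srv, "s", create = TRUE)
  expect_error(dispatch_analysis(srv, "/analysis/foo", list(), session),
               "unknown route '/analysis/foo'")
})

test_that("custom routes can be registered and dispatched", {
  srv <- local_server()
  register_route(srv, "/analysis/echo",
                 function(server, session, payload)
                   decode_individual(welch_psd(payload$epoch)))
  session <- ssvepcollab:::get_session(srv, "s", create = TRUE)
  res <- dispatch_analysis(srv, "/analysis/echo",
                           list(epoch = tone_epoch(13)), session)
  expect_equal(res$predicted_frequency, 13)
})

test_that("a noiseless session decodes correctly through the wire", {
  recs <- small_session(n_participants = 1, noise = 0, gain = 0)
  out <- run_collab_session(recs)
  expect_equal(recognition_accuracy(out$decoding[[1]]), 1.0)
})

test_that("streamed results equal the offline pipeline bit-for-bit", {
  recs <- small_session()
  out <- run_collab_session(recs)
  for (p in 1:2) {
    off <- lapply(lapply(preprocess_pipeline(recs[[p]]), welch_psd),
                  decode_individual)
    expect_identical(
      lapply(out$decoding[[p]], function(x) unname(x$pooled_power)),
      lapply(off, function(x) unname(x$pooled_power)))
    expect_identical(vapply(out$decoding[[p]], `[[`, numeric(1),
                            "predicted_frequency"),
                     vapply(off, `[[`, numeric(1), "predicted_frequency"))
  }
  offc <- coupling_from_recordings(recs[[1]], recs[[2]], 8)
  onc <- Filter(function(r) r$target_frequency == 8, out$coupling)[[1]]
  expect_identical(onc$mean_z, offc$mean_z)
  expect_identical(onc$p_value, offc$p_value)
  expect_identical(onc$per_trial_r, offc$per_trial_r)
})

test_that("transcripts have gapless monotone sequence numbers and shared STIM_SYNC", {
  recs <- small_session()
  out <- run_collab_session(recs, feedback_policy = feedback_highlight)
  for (tr in out$transcripts) {
    for (dir in c("sent", "received")) {
      seqs <- vapply(Filter(function(m) m$direction == dir, tr),
                     `[[`, integer(1), "seq")
      expect_identical(seqs, seq_along(seqs))
    }
  }
  sync <- lapply(out$transcripts, function(tr)
    Filter(function(m) m$type == "STIM_SYNC", tr)[[1]]$payload$stimuli)
  expect_identical(sync[[1]], sync[[2]])
})

test_that("closed-loop feedback highlights the true target on clean data", {
  recs <- small_session(n_participants = 1, noise = 0, gain = 0)
  out <- run_collab_session(recs, feedback_policy = feedback_highlight)
  fb <- Filter(function(m) m$type == "FEEDBACK" && m$direction == "sent",
               out$transcripts[[1]])
  expect_gt(length(fb), 0)
  # the last feedback of the session highlights the last trial's target
  last_target <- utils::tail(ssvepcollab:::annotation_frequency(
    recs[[1]]$annotations$label), 1)
  final <- fb[[length(fb)]]$payload$stimuli
  expect_equal(final$frequency[which(final$active)], last_target)
  # identity policy emits no feedback and leaves the stimulus untouched
  out2 <- run_collab_session(recs, feedback_policy = function(s, r) s)
  expect_length(Filter(function(m) m$type == "FEEDBACK",
                       out2$transcripts[[1]]), 0)
  expect_false(any(out2$stimulus[[1]]$active))
})

test_that("session archives roundtrip losslessly", {
  root <- withr::local_tempdir()
  recs <- small_session(seed = 12)
  out <- run_collab_session(recs, archive_root = root)
  ar <- read_archive(out$archive_dir)
  expect_setequal(ar$manifest$participants, c("sub-01", "sub-02"))
  dec <- Filter(function(r) inherits(r, "decoding_result"), ar$results)
  p1 <- Filter(function(r) identical(r$epoch_info$participant_id, "sub-01"),
               dec)
  expect_identical(lapply(p1, function(x) unname(x$pooled_power)),
                   lapply(out$decoding[[1]],
                          function(x) unname(x$pooled_power)))
  cpl <- Filter(function(r) inherits(r, "coupling_result"), ar$results)
  expect_identical(vapply(cpl, `[[`, numeric(1), "mean_z"),
                   vapply(out$coupling, `[[`, numeric(1), "mean_z"))
  # streamed sample bookkeeping: EDF length = epochs x epoch samples
  expect_equal(ncol(ar$recordings[["sub-01"]]$samples),
               length(out$decoding[[1]]) * 512)
  expect_equal(length(ar$transcript), ar$manifest$n_messages)
})

test_that("an empty session still archives a manifest and empty files", {
  root <- withr::local_tempdir()
  srv <- local_server(archive_root = root)
  cl <- local_client(srv)
  ssvepcollab:::client_join(cl, "empty", "alice")
  ssvepcollab:::client_send(cl, "STOP_PARADIGM")
  ssvepcollab:::client_wait(cl, "STOP_PARADIGM")
  dir <- file.path(root, "empty")
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_length(read_results(file.path(dir, "results.ndjson")), 0)
})

test_that("a busy port fails loudly at startup", {
  srv <- local_server()
  expect_error(start_server(port = srv$port), "")
})
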