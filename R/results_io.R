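RESULTS_SCHEMA <- "ssvepcollab/v1"

result_to_record <- function(x) {
  if (inherits(x, "decoding_result")) {
    list(schema = RESULTS_SCHEMA, type = "decoding",
         data = list(epoch_info = x$epoch_info,
                     candidate_frequencies = x$candidate_frequencies,
                     pooled_power = unname(x$pooled_power),
                     predicted_frequency = x$predicted_frequency,
                     true_frequency = x$true_frequency,
                     correct = x$correct,
                     mode = x$mode,
                     n_participants = x$n_participants))
  } else if (inherits(x, "coupling_result")) {
    list(schema = RESULTS_SCHEMA, type = "coupling",
         data = list(participant_pair = x$participant_pair,
                     target_frequency = x$target_frequency,
                     per_trial_r = x$per_trial_r,
                     per_trial_z = x$per_trial_z,
                     mean_z = x$mean_z, mean_r = x$mean_r,
                     p_value = x$p_value,
                     n_trials = x$n_trials, n_channels = x$n_channels))
  } else abort("cannot serialise object of class %s", class(x)[1])
}

record_to_result <- function(rec) {
  if (!identical(rec$schema, RESULTS_SCHEMA))
    abort("unsupported results schema '%s' (this build reads %s)",
          rec$schema %||% "<missing>", RESULTS_SCHEMA)
  d <- rec$data
  if (rec$type == "decoding") {
    structure(list(epoch_info = d$epoch_info,
                   candidate_frequencies = d$candidate_frequencies,
                   pooled_power = stats::setNames(d$pooled_power,
                                                  d$candidate_frequencies),
                   predicted_frequency = d$predicted_frequency,
                   true_frequency = d$true_frequency,
                   correct = d$correct, mode = d$mode,
                   n_participants = d$n_participants),
              class = "decoding_result")
  } else if (rec$type == "coupling") {
    structure(list(participant_pair = d$participant_pair,
                   target_frequency = d$target_frequency,
                   per_trial_r = d$per_trial_r, per_trial_z = d$per_trial_z,
                   mean_z = d$mean_z, mean_r = d$mean_r,
                   p_value = d$p_value, n_trials = d$n_trials,
                   n_channels = d$n_channels),
              class = "coupling_result")
  } else abort("unknown result type '%s'", rec$type)
}

#' Write analysis results as line-delimited JSON
#'
#' One schema-versioned JSON record per line; decoding and coupling results
#' may be mixed and their order is preserved. Numeric values are written at
#' full precision so the roundtrip is lossless.
#'
#' @param results list of `decoding_result` / `coupling_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  lines <- vapply(results, function(x)
    as.character(jsonlite::toJSON(result_to_record(x), auto_unbox = TRUE,
                                  digits = I(17), null = "null")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read back a results file written by [write_results()]
#'
#' @param path file path.
#' @return list of result objects, in file order.
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l)
    record_to_result(jsonlite::fromJSON(l, simplifyVector = TRUE)))
}
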