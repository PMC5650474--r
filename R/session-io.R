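# On-disk session bundles: one directory per session with trials.csv,
# eye.csv, spikes.csv and ground_truth.json.  All times are session-relative,
# 0-based, in milliseconds; velocities are derived downstream from positions.

#' Write a session bundle to disk
#'
#' @param session an `mp_session`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session_bundle <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trials <- session$trials
  tr_tab <- do.call(rbind, lapply(trials, function(tr) {
    data.frame(trial_id = tr$trial_id, condition = tr$condition,
               target_x = tr$target[["x"]], target_y = tr$target[["y"]],
               target_on = tr$events$target_on %||% NA_real_,
               go_cue = tr$events$go_cue %||% NA_real_,
               blink_on = tr$events$blink_on %||% NA_real_)
  }))
  utils::write.csv(tr_tab, file.path(dir, "trials.csv"), row.names = FALSE)
  eye <- do.call(rbind, lapply(trials, function(tr) {
    data.frame(trial_id = tr$trial_id, time = tr$time,
               h_pos = round(tr$h_pos, 5), v_pos = round(tr$v_pos, 5))
  }))
  utils::write.csv(eye, file.path(dir, "eye.csv"), row.names = FALSE)
  spk <- do.call(rbind, lapply(trials, function(tr) {
    if (!length(tr$spikes)) return(NULL)
    data.frame(trial_id = tr$trial_id, spike_time = round(tr$spikes, 3))
  }))
  if (is.null(spk))
    spk <- data.frame(trial_id = integer(0), spike_time = numeric(0))
  utils::write.csv(spk, file.path(dir, "spikes.csv"), row.names = FALSE)
  gt <- list(ground_truth = session$ground_truth,
             config = unclass(session$config))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE, na = "null")
  invisible(dir)
}

#' Read a session bundle from disk
#'
#' Reconstructs an `mp_session` from the CSV/JSON bundle layout written by
#' [write_session_bundle()].
#'
#' @param dir bundle directory.
#' @return an `mp_session`.
#' @export
read_session_bundle <- function(dir) {
  tr_tab <- utils::read.csv(file.path(dir, "trials.csv"))
  eye <- utils::read.csv(file.path(dir, "eye.csv"))
  spk <- utils::read.csv(file.path(dir, "spikes.csv"))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  eye_split <- split(eye, eye$trial_id)
  spk_split <- split(spk$spike_time, spk$trial_id)
  trials <- lapply(seq_len(nrow(tr_tab)), function(i) {
    row <- tr_tab[i, ]
    e <- eye_split[[as.character(row$trial_id)]]
    list(trial_id = row$trial_id, condition = row$condition,
         target = c(x = row$target_x, y = row$target_y),
         events = list(target_on = row$target_on, go_cue = row$go_cue,
                       blink_on = row$blink_on),
         time = e$time, h_pos = e$h_pos, v_pos = e$v_pos,
         spikes = spk_split[[as.character(row$trial_id)]] %||% numeric(0))
  })
  cfg <- gt$config
  class(cfg) <- "mp_config"
  out <- list(trials = trials,
              ground_truth = as.data.frame(gt$ground_truth),
              config = cfg)
  class(out) <- "mp_session"
  out
}
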