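# The calibration staircase, expressed as a pure, replayable state machine.
#
# Descent: start at calib_start_std_ms; every passed block deducts one step
# from the STD. The first failed block ends the descent and opens
# verification at the last passed speed (the failed speed plus one step).
# Verification: blocks repeat at the candidate speed until it accumulates
# `verification_passes_required` passes (the descent pass at that speed
# counts); a failed verification block promotes the candidate one step
# slower, retaining any passes already recorded there. A candidate promoted
# beyond the representable ceiling, or a run exceeding the safety cap,
# declares the run ineligible.

#' Initialise a calibration state
#'
#' @param config A [task_config()].
#' @return A `tload_calib_state` in the `descent` phase at the configured
#'   starting STD, with an empty pass/fail ledger and empty trajectory.
#' @export
calibration_init <- function(config = task_config()) {
  structure(
    list(current_std_ms = config$calib_start_std_ms,
         phase = "descent",
         # named by STD: pass and fail counts per visited speed
         ledger_pass = integer(0), ledger_fail = integer(0),
         blocks_run = 0L,
         trajectory = list(),  # one list row per block; data.frame on finalize
         final_std_ms = NA_integer_),
    class = "tload_calib_state"
  )
}

pass_count_at <- function(state, std) {
  key <- as.character(std)
  if (key %in% names(state$ledger_pass)) state$ledger_pass[[key]] else 0L
}

ledger_add <- function(state, std, passed) {
  key <- as.character(std)
  if (!key %in% names(state$ledger_pass)) {
    state$ledger_pass[key] <- 0L
    state$ledger_fail[key] <- 0L
  }
  if (passed) state$ledger_pass[key] <- state$ledger_pass[key] + 1L
  else state$ledger_fail[key] <- state$ledger_fail[key] + 1L
  state
}

ledger_frame <- function(state) {
  std <- as.integer(names(state$ledger_pass))
  ord <- order(std)
  data.frame(std_ms = std[ord],
             pass_count = unname(state$ledger_pass)[ord],
             fail_count = unname(state$ledger_fail)[ord])
}

#' Advance the staircase by one scored block
#'
#' Pure transition function: the same state and block score always produce
#' the same next state, so a logged session can be replayed exactly.
#'
#' @param state A `tload_calib_state` in phase `descent` or `verification`.
#' @param block_score A `tload_score` (or any list with `composite`,
#'   `passed`, and optionally `letter_accuracy`/`number_accuracy`).
#' @param config A [task_config()].
#' @return The next `tload_calib_state`; phase becomes `done` when a speed
#'   accumulates the required passes and `ineligible` when the candidate
#'   escalates beyond the ceiling or the block cap is exceeded.
#' @export
calibration_step <- function(state, block_score, config = task_config()) {
  stopifnot(inherits(state, "tload_calib_state"))
  if (!state$phase %in% c("descent", "verification")) {
    stop("calibration_step called on a finished state (phase '",
         state$phase, "')", call. = FALSE)
  }
  passed <- isTRUE(block_score$passed)
  std <- state$current_std_ms
  step_ms <- config$std_step_ms

  state$blocks_run <- state$blocks_run + 1L
  state$trajectory[[state$blocks_run]] <-
    list(block_no = state$blocks_run, std_ms = as.integer(std),
         letter_accuracy = block_score$letter_accuracy %||% NA_real_,
         number_accuracy = block_score$number_accuracy %||% NA_real_,
         composite = block_score$composite, passed = passed,
         phase = state$phase)
  state <- ledger_add(state, std, passed)

  advance_candidate <- function(state, candidate) {
    if (candidate > config$std_ceiling_ms) {
      state$phase <- "ineligible"
      return(state)
    }
    state$phase <- "verification"
    state$current_std_ms <- candidate
    if (pass_count_at(state, candidate) >=
        config$verification_passes_required) {
      state$phase <- "done"
      state$final_std_ms <- as.integer(candidate)
    }
    state
  }

  if (state$phase == "descent") {
    if (passed) {
      if (std <= config$std_floor_ms) {
        # Cannot go faster: verify at the floor (this pass already counts).
        state <- advance_candidate(state, std)
      } else {
        state$current_std_ms <- std - step_ms
      }
    } else {
      state <- advance_candidate(state, std + step_ms)
    }
  } else { # verification at candidate `std`
    if (passed) {
      if (pass_count_at(state, std) >=
          config$verification_passes_required) {
        state$phase <- "done"
        state$final_std_ms <- as.integer(std)
      }
    } else {
      state <- advance_candidate(state, std + step_ms)
    }
  }

  if (state$phase %in% c("descent", "verification") &&
      state$blocks_run >= config$max_calibration_blocks) {
    state$phase <- "ineligible"
  }
  state
}

finalize_calibration <- function(state) {
  tr <- state$trajectory
  trajectory <- data.frame(
    block_no = vapply(tr, `[[`, 1L, "block_no"),
    std_ms = vapply(tr, `[[`, 1L, "std_ms"),
    letter_accuracy = vapply(tr, `[[`, 1, "letter_accuracy"),
    number_accuracy = vapply(tr, `[[`, 1, "number_accuracy"),
    composite = vapply(tr, `[[`, 1, "composite"),
    passed = vapply(tr, `[[`, TRUE, "passed"),
    phase = vapply(tr, `[[`, "", "phase")
  )
  structure(
    list(final_std_ms = state$final_std_ms,
         n_blocks = state$blocks_run,
         eligible = state$phase == "done",
         trajectory = trajectory,
         ledger = ledger_frame(state)),
    class = "tload_calib_result"
  )
}

#' Run a full calibration against a responder
#'
#' Repeatedly generates a combined block at the current STD, collects the
#' responder's events, scores the block and advances the staircase until it
#' terminates. A responder is any `function(block, session_index)` returning
#' a [response_events()] set; [profile_responder()] wraps a simulated
#' observer, and [replay_calibration()] re-derives a result from a logged
#' trajectory without a responder.
#'
#' @param responder A responder function.
#' @param config A [task_config()].
#' @param seed Integer seed controlling block generation and any randomness
#'   inside the responder; the same `(responder, config, seed)` triple
#'   reproduces the result exactly.
#' @param session_index Session number passed through to the responder
#'   (1-based).
#' @return A `tload_calib_result`: `final_std_ms`, `n_blocks`, `eligible`,
#'   the block-by-block `trajectory`, and the per-STD pass/fail `ledger`.
#' @examples
#' res <- run_calibration(threshold_responder(800), seed = 1)
#' res$final_std_ms
#' @export
run_calibration <- function(responder, config = task_config(), seed = NULL,
                            session_index = 1L) {
  stopifnot(is.function(responder))
  with_seed(seed, {
    state <- calibration_init(config)
    while (state$phase %in% c("descent", "verification")) {
      phase <- if (state$phase == "descent") "calibration" else "verification"
      block <- make_combined_block(state$current_std_ms, config, seed = NULL,
                                   phase = phase)
      responses <- responder(block, session_index)
      score <- score_block(block, responses, config)
      state <- calibration_step(state, score, config)
    }
    finalize_calibration(state)
  })
}

#' Run the familiarization phase
#'
#' One single-task number block and one single-task letter block at the
#' familiarization STD, then combined blocks at the same STD until one
#' passes the composite criterion or the block cap is reached. Participants
#' who never pass a combined familiarization block are ineligible for
#' calibration.
#'
#' @inheritParams run_calibration
#' @return A `tload_fam_result`: `passed` plus blocks used per phase and
#'   the combined-block scores.
#' @export
run_familiarization <- function(responder, config = task_config(),
                                seed = NULL, session_index = 1L) {
  stopifnot(is.function(responder))
  with_seed(seed, {
    for (kind in c("fam_number", "fam_letter")) {
      block <- make_single_task_block(kind, config)
      responses <- responder(block, session_index)
      score_block(block, responses, config)  # familiarization only; not gating
    }
    scores <- numeric(0)
    passed <- FALSE
    used <- 0L
    while (!passed && used < config$fam_block_cap) {
      block <- make_combined_block(config$fam_std_ms, config,
                                   phase = "fam_combined")
      responses <- responder(block, session_index)
      sc <- score_block(block, responses, config)
      used <- used + 1L
      scores <- c(scores, sc$composite)
      passed <- isTRUE(sc$passed)
    }
    structure(
      list(passed = passed,
           blocks_used = c(fam_number = 1L, fam_letter = 1L,
                           fam_combined = used),
           combined_composites = scores),
      class = "tload_fam_result"
    )
  })
}

#' Replay a trajectory through the state machine
#'
#' Feeds a sequence of (composite, passed) rows through
#' [calibration_step()]; used to verify that the engine is
#' history-deterministic and to re-derive results from logged sessions.
#'
#' @param trajectory A data.frame with at least `composite` and `passed`.
#' @param config A [task_config()].
#' @return A `tload_calib_result`.
#' @export
replay_calibration <- function(trajectory, config = task_config()) {
  state <- calibration_init(config)
  for (i in seq_len(nrow(trajectory))) {
    if (!state$phase %in% c("descent", "verification")) break
    state <- calibration_step(
      state,
      list(composite = trajectory$composite[i],
           passed = trajectory$passed[i],
           letter_accuracy = trajectory$letter_accuracy[i] %||% NA_real_,
           number_accuracy = trajectory$number_accuracy[i] %||% NA_real_),
      config)
  }
  finalize_calibration(state)
}

#' @export
print.tload_calib_result <- function(x, ...) {
  if (x$eligible) {
    cat(sprintf("calibrated STD: %d ms after %d blocks\n",
                x$final_std_ms, x$n_blocks))
  } else {
    cat(sprintf("ineligible after %d blocks (no stable passing speed)\n",
                x$n_blocks))
  }
  invisible(x)
}
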