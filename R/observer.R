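# Simulated participants: a psychometric response model with
# between-session learning, standing in for human performance.
#
# Per-item correctness is logistic in the STD. Each channel has a guessing
# floor and a lapse ceiling; the letter channel can be made harder than the
# number channel by a fixed threshold gap. The anchor parameter theta_ms is
# defined on the composite scale: at STD = theta_ms (session 1) the
# expected composite equals the pass criterion exactly, which makes theta
# the observer's nominal calibration threshold up to grid rounding.

#' Create a simulated-observer profile
#'
#' @param theta_ms Session-1 STD (ms) at which the expected composite
#'   accuracy equals the pass criterion.
#' @param slope_ms Psychometric slope scale (ms); smaller is steeper. The
#'   limit `slope_ms -> 0` is a step observer.
#' @param lapse Probability of an attention lapse on any item, capping
#'   accuracy at `1 - lapse`; bounded by 0.1.
#' @param session_deltas_ms Length-2 numeric: additive improvement (ms) of
#'   the threshold for sessions 2 and 3 relative to the previous session.
#'   Positive values mean the observer gets faster.
#' @param letter_number_gap Threshold gap (ms) by which the letter channel
#'   is harder than the number channel.
#' @param guess_letter,guess_number Guessing floors of the two channels.
#' @param config A [task_config()]; supplies the weights and pass criterion
#'   the theta anchor is solved against.
#' @return An `observer_profile` list with the calibrated internal offset.
#' @examples
#' p <- observer_profile(theta_ms = 850)
#' expected_composite(p, 850)  # equals the pass criterion
#' @export
observer_profile <- function(theta_ms = 850, slope_ms = 60, lapse = 0.02,
                             session_deltas_ms = c(0, 0),
                             letter_number_gap = 80,
                             guess_letter = 0.5, guess_number = 0.5,
                             config = task_config()) {
  stopifnot(theta_ms > config$std_floor_ms, theta_ms < config$std_ceiling_ms,
            slope_ms >= 0, lapse >= 0, lapse <= 0.1,
            length(session_deltas_ms) == 2,
            guess_letter >= 0, guess_letter < 1,
            guess_number >= 0, guess_number < 1)
  p <- list(theta_ms = theta_ms, slope_ms = slope_ms, lapse = lapse,
            session_deltas_ms = session_deltas_ms,
            letter_number_gap = letter_number_gap,
            guess_letter = guess_letter, guess_number = guess_number,
            w_letter = config$w_letter, w_number = config$w_number,
            pass_criterion = config$pass_criterion, offset = 0)
  class(p) <- "observer_profile"
  # Solve the internal offset so that expected composite at theta is the
  # pass criterion exactly (the channel gap and lapse shift the raw curve).
  f <- function(off) {
    p$offset <- off
    raw_composite(p, theta_ms) - config$pass_criterion
  }
  span <- max(4 * slope_ms + 2 * abs(letter_number_gap), 400)
  p$offset <- stats::uniroot(f, c(-span - 2000, span + 2000),
                             tol = 1e-10)$root
  p
}

channel_prob <- function(p, std_ms, kind) {
  gap <- if (kind == "letter") p$letter_number_gap / 2 else
    -p$letter_number_gap / 2
  guess <- if (kind == "letter") p$guess_letter else p$guess_number
  x <- std_ms - p$offset - gap
  base <- if (p$slope_ms == 0) as.numeric(x >= 0) else
    stats::plogis(x / p$slope_ms)
  guess + (1 - p$lapse - guess) * base
}

raw_composite <- function(p, std_ms) {
  p$w_letter * channel_prob(p, std_ms, "letter") +
    p$w_number * channel_prob(p, std_ms, "number")
}

session_shift <- function(profile, session_index) {
  if (!session_index %in% 1:3) {
    stop("session_index must be 1, 2 or 3", call. = FALSE)
  }
  d <- profile$session_deltas_ms
  c(0, d[1], d[1] + d[2])[session_index]
}

#' Per-item correctness probability of a simulated observer
#'
#' Logistic in the STD with a session-shifted threshold: a positive session
#' delta moves the whole curve toward faster speeds. The letter channel is
#' shifted harder by the profile's channel gap.
#'
#' @param profile An [observer_profile()].
#' @param std_ms STD in ms (> 0); vectorised.
#' @param task_kind `"letter"` or `"number"`.
#' @param session_index Session number (1-3).
#' @return Probability of answering one item of that kind correctly, in
#'   `[guess, 1 - lapse]`.
#' @export
item_accuracy <- function(profile, std_ms, task_kind = "letter",
                          session_index = 1L) {
  stopifnot(inherits(profile, "observer_profile"), all(std_ms > 0),
            task_kind %in% c("letter", "number"))
  channel_prob(profile, std_ms + session_shift(profile, session_index),
               task_kind)
}

#' Expected composite accuracy of a simulated observer at a given STD
#'
#' @inheritParams item_accuracy
#' @return `w_letter * p_letter + w_number * p_number`, strictly increasing
#'   in `std_ms` below saturation.
#' @export
expected_composite <- function(profile, std_ms, session_index = 1L) {
  profile$w_letter *
    item_accuracy(profile, std_ms, "letter", session_index) +
    profile$w_number *
    item_accuracy(profile, std_ms, "number", session_index)
}

#' Nominal calibration threshold of a profile
#'
#' The smallest grid STD at which the expected composite reaches the pass
#' criterion — the value a noise-free calibration should recover.
#'
#' @inheritParams item_accuracy
#' @param config A [task_config()].
#' @return STD in ms on the grid, or `NA` if no grid speed reaches the
#'   criterion.
#' @export
nominal_threshold <- function(profile, session_index = 1L,
                              config = task_config()) {
  grid <- seq(config$std_floor_ms, config$std_ceiling_ms,
              by = config$std_step_ms)
  ok <- expected_composite(profile, grid, session_index) >=
    config$pass_criterion
  if (!any(ok)) return(NA_integer_)
  as.integer(grid[which(ok)[1L]])
}

#' Simulate an observer's responses to a block
#'
#' Each item is answered correctly with probability [item_accuracy()],
#' independently. Correct items emit the required action at a latency
#' uniform in the presentation window (withhold items emit nothing).
#' Incorrect letter targets are missed; incorrect letter non-targets get a
#' spurious space press; incorrect number items get the wrong parity key
#' with probability `wrong_key_share`, otherwise no response.
#'
#' @param profile An [observer_profile()].
#' @param block A `tload_block`.
#' @param session_index Session number (1-3).
#' @param wrong_key_share Share of number errors that are commissions.
#' @return A [response_events()] set. Consumes the ambient RNG stream;
#'   wrap in a seeded context (or use [run_calibration()]'s `seed`) for
#'   reproducibility.
#' @export
respond <- function(profile, block, session_index = 1L,
                    wrong_key_share = 0.7) {
  n <- length(block$kind)
  is_letter <- block$kind == "letter"
  p <- numeric(n)
  p[is_letter] <- item_accuracy(profile, block$std_ms, "letter",
                                session_index)
  p[!is_letter] <- item_accuracy(profile, block$std_ms, "number",
                                 session_index)
  correct <- stats::runif(n) < p

  action <- rep("none", n)
  req <- block$required_action
  # correct responses
  action[correct & req == "press_space"] <- "space"
  action[correct & req == "press_even_key"] <- "even_key"
  action[correct & req == "press_odd_key"] <- "odd_key"
  # incorrect non-target letters: spurious press
  action[!correct & req == "withhold"] <- "space"
  # incorrect numbers: wrong key or omission
  wrong_num <- !correct & !is_letter
  commits <- wrong_num & stats::runif(n) < wrong_key_share
  action[commits & req == "press_even_key"] <- "odd_key"
  action[commits & req == "press_odd_key"] <- "even_key"

  emitted <- action != "none"
  response_events(
    item_index = block$index[emitted],
    action = action[emitted],
    latency_ms = stats::runif(sum(emitted), 0, block$std_ms * 0.999)
  )
}

#' Wrap an observer profile as a responder
#'
#' @param profile An [observer_profile()].
#' @return A `function(block, session_index)` suitable for
#'   [run_calibration()] and [run_familiarization()].
#' @export
profile_responder <- function(profile) {
  force(profile)
  function(block, session_index) respond(profile, block, session_index)
}

#' Deterministic step-function responder
#'
#' Answers every item correctly when the block's STD is at or above the
#' threshold, and every item incorrectly below it. Used for exact
#' parameter-recovery checks of the staircase.
#'
#' @param threshold_ms Threshold STD in ms.
#' @return A responder function.
#' @export
threshold_responder <- function(threshold_ms) {
  force(threshold_ms)
  function(block, session_index) {
    if (block$std_ms >= threshold_ms) {
      perfect_responses(block)
    } else {
      # all items wrong: press space on non-targets, wrong key on numbers
      act <- rep("none", length(block$kind))
      act[block$required_action == "withhold"] <- "space"
      act[block$required_action == "press_even_key"] <- "odd_key"
      act[block$required_action == "press_odd_key"] <- "even_key"
      emitted <- act != "none"
      response_events(block$index[emitted], act[emitted],
                      rep(block$std_ms / 2, sum(emitted)))
    }
  }
}
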