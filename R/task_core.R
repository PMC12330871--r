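# Stimulus-stream generation and response scoring.
#
# A block is stored column-wise (parallel vectors) rather than as a
# data.frame: block construction and scoring sit on the hot path of the
# cohort simulator, which generates hundreds of thousands of blocks.

TLOAD_LETTERS <- c("A", "C", "E", "L", "N", "P", "R", "T", "U")
TLOAD_NUMBERS <- c("1", "2", "3", "4", "6", "7", "8", "9")
TLOAD_EVEN <- c("2", "4", "6", "8")
TLOAD_ODD <- c("1", "3", "7", "9")

# Sample k target slots out of `slots` candidate positions, forbidding
# adjacent slots where feasible (two adjacent 1-back targets would put three
# identical letters in a row). Falls back to unconstrained sampling when k
# is too large for the non-adjacency constraint.
sample_target_slots <- function(k, slots) {
  if (k == 0L) return(integer(0))
  max_nonadjacent <- ceiling(slots / 2)
  if (k > max_nonadjacent) {
    return(sort(sample.int(slots, k)))
  }
  # Classic stars-and-bars bijection: choose k from slots - k + 1, then
  # spread them out so no two chosen slots are adjacent.
  base <- sort(sample.int(slots - k + 1L, k))
  base + seq_len(k) - 1L
}

# Generate a letter stream of length n with exactly `targets` 1-back
# repeats. Non-target letters are drawn uniformly among letters different
# from their predecessor.
make_letter_stream <- function(n, targets) {
  symbols <- character(n)
  is_target <- logical(n)
  if (n == 0L) return(list(symbols = symbols, is_target = is_target))
  if (targets > 0L) {
    is_target[sample_target_slots(targets, n - 1L) + 1L] <- TRUE
  }
  # Pre-draw uniform picks; non-target letters take the r-th letter among
  # the 8 alternatives to their predecessor (skip over the predecessor).
  nl <- length(TLOAD_LETTERS)
  pick <- sample.int(nl - 1L, n, replace = TRUE)
  prev <- sample.int(nl, 1L)
  out <- integer(n)
  out[1L] <- prev
  for (i in seq_len(n)[-1L]) {
    if (!is_target[i]) {
      prev <- pick[i] + (pick[i] >= prev)
    }
    out[i] <- prev
  }
  list(symbols = TLOAD_LETTERS[out], is_target = is_target)
}

# Generate n digits with |#even - #odd| <= 1, uniformly within parity class.
make_number_stream <- function(n) {
  n_even <- n %/% 2L
  n_odd <- n - n_even
  if (n %% 2L == 1L && stats::runif(1) < 0.5) {
    n_even <- n_even + 1L
    n_odd <- n_odd - 1L
  }
  parity <- sample(c(rep("even", n_even), rep("odd", n_odd)))
  symbols <- character(n)
  symbols[parity == "even"] <- sample(TLOAD_EVEN, n_even, replace = TRUE)
  symbols[parity == "odd"] <- sample(TLOAD_ODD, n_odd, replace = TRUE)
  list(symbols = symbols, parity = parity)
}

new_block <- function(kind, symbol, is_repeat_target, parity, std_ms, phase,
                      seed = NULL) {
  n <- length(kind)
  required <- character(n)
  lets <- kind == "letter"
  required[lets] <-
    c("withhold", "press_space")[is_repeat_target[lets] + 1L]
  required[!lets] <-
    c(even = "press_even_key", odd = "press_odd_key")[parity[!lets]]
  structure(
    list(index = seq_len(n) - 1L, kind = kind, symbol = symbol,
         is_repeat_target = is_repeat_target, parity = parity,
         required_action = required, std_ms = std_ms, phase = phase,
         seed = seed),
    class = "tload_block"
  )
}

check_std <- function(std_ms, config) {
  if (!on_grid(std_ms, config$std_step_ms) ||
      std_ms < config$std_floor_ms || std_ms > config$std_ceiling_ms) {
    stop(sprintf(
      "std_ms must be a multiple of %d ms within [%d, %d]; got %s",
      config$std_step_ms, config$std_floor_ms, config$std_ceiling_ms,
      format(std_ms)), call. = FALSE)
  }
  invisible(std_ms)
}

#' Generate a combined letter-number block
#'
#' Builds the alternating 60-item stream of the combined task: letters and
#' digits in strict alternation starting with a letter. Letters are drawn
#' from A, C, E, L, N, P, R, T, U with a configurable number of 1-back
#' repeat targets (never two targets in adjacent letter positions, so no
#' symbol appears three times in a row); digits are drawn from 1-9 without 5
#' with evens and odds balanced to within one item.
#'
#' @param std_ms Stimulus time duration in ms; must be a positive multiple
#'   of `config$std_step_ms` within the configured range.
#' @param config A [task_config()] object.
#' @param seed Optional integer seed; the same seed reproduces the block
#'   exactly. `NULL` draws from the ambient RNG stream.
#' @param phase Block phase label.
#' @return A `tload_block`: parallel vectors `index`, `kind`, `symbol`,
#'   `is_repeat_target`, `parity`, `required_action`, plus `std_ms`,
#'   `phase`, `seed`.
#' @examples
#' b <- make_combined_block(1400, task_config(), seed = 7)
#' table(b$kind)
#' sum(b$is_repeat_target, na.rm = TRUE)
#' @export
make_combined_block <- function(std_ms, config = task_config(), seed = NULL,
                                phase = "calibration") {
  check_std(std_ms, config)
  n <- config$items_combined
  n_half <- n %/% 2L
  with_seed(seed, {
    let <- make_letter_stream(n_half, config$repeat_target_count)
    num <- make_number_stream(n_half)
    kind <- rep(c("letter", "number"), n_half)
    symbol <- character(n)
    symbol[kind == "letter"] <- let$symbols
    symbol[kind == "number"] <- num$symbols
    is_target <- rep(NA, n)
    is_target[kind == "letter"] <- let$is_target
    parity <- rep(NA_character_, n)
    parity[kind == "number"] <- num$parity
    new_block(kind, symbol, is_target, parity, std_ms, phase, seed)
  })
}

#' Generate a single-task familiarization block
#'
#' A 30-item block of one channel only: `"fam_letter"` gives a 1-back letter
#' stream with `config$repeat_target_count_single` targets, `"fam_number"` a
#' parity-balanced digit stream.
#'
#' @param kind `"fam_letter"` or `"fam_number"`.
#' @inheritParams make_combined_block
#' @return A `tload_block` of `config$items_single` items.
#' @examples
#' b <- make_single_task_block("fam_number", seed = 2)
#' table(b$parity)
#' @export
make_single_task_block <- function(kind, config = task_config(), seed = NULL) {
  if (!kind %in% c("fam_letter", "fam_number")) {
    stop("kind must be 'fam_letter' or 'fam_number'", call. = FALSE)
  }
  n <- config$items_single
  check_std(config$fam_std_ms, config)
  with_seed(seed, {
    if (kind == "fam_letter") {
      let <- make_letter_stream(n, config$repeat_target_count_single)
      new_block(rep("letter", n), let$symbols, let$is_target,
                rep(NA_character_, n), config$fam_std_ms, kind, seed)
    } else {
      num <- make_number_stream(n)
      new_block(rep("number", n), num$symbols, rep(NA, n), num$parity,
                config$fam_std_ms, kind, seed)
    }
  })
}

#' Construct a set of response events
#'
#' @param item_index 0-based indices of the responded items.
#' @param action One of `"space"`, `"even_key"`, `"odd_key"`, `"none"` per
#'   event.
#' @param latency_ms Time from item onset in ms (non-negative).
#' @return A `data.frame` with class `tload_responses`.
#' @export
response_events <- function(item_index = integer(0),
                            action = character(0),
                            latency_ms = numeric(0)) {
  stopifnot(length(item_index) == length(action),
            length(action) == length(latency_ms))
  bad <- !action %in% c("space", "even_key", "odd_key", "none")
  if (any(bad)) {
    stop("unknown action: ", paste(unique(action[bad]), collapse = ", "),
         call. = FALSE)
  }
  if (any(latency_ms < 0)) stop("latency_ms must be >= 0", call. = FALSE)
  new_responses(as.integer(item_index), action, as.numeric(latency_ms))
}

# Fast constructor without validation (hot path).
new_responses <- function(item_index, action, latency_ms) {
  structure(
    list(item_index = item_index, action = action,
         latency_ms = latency_ms),
    class = c("tload_responses", "data.frame"),
    row.names = if (length(item_index)) seq_along(item_index) else
      integer(0)
  )
}

#' Ideal response set for a block
#'
#' Emits every required action at half the presentation window and nothing
#' on withhold items; scores 1.0 by construction.
#'
#' @param block A `tload_block`.
#' @return A [response_events()] set.
#' @export
perfect_responses <- function(block) {
  act <- block$required_action
  keep <- act != "withhold"
  response_events(
    item_index = block$index[keep],
    action = c(press_space = "space", press_even_key = "even_key",
               press_odd_key = "odd_key")[act[keep]],
    latency_ms = rep(block$std_ms / 2, sum(keep))
  )
}

#' Score a block against a set of response events
#'
#' Letter items are correct when a repeat target receives a creditable
#' space-bar press, or a non-target receives none. Number items are correct
#' when a creditable parity key matches the digit's parity. A press is
#' creditable only if it lands inside the item's presentation window
#' (`latency_ms < std_ms`) and belongs to the item's channel (space for
#' letters, parity keys for numbers); cross-channel presses are ignored, and
#' only the first creditable press per item counts. The composite is the
#' configured weighted mean of the two channel accuracies, and the block
#' passes when the composite reaches the pass criterion (inclusive).
#'
#' @param block A `tload_block`.
#' @param responses A [response_events()] object (or data.frame with the
#'   same columns).
#' @param config A [task_config()].
#' @return A `tload_score`: list with `letter_accuracy`, `number_accuracy`,
#'   `composite`, `passed`, and the per-item `correct` vector.
#' @examples
#' b <- make_combined_block(1400, seed = 1)
#' score_block(b, response_events())$letter_accuracy  # withholding only
#' @export
score_block <- function(block, responses, config = task_config()) {
  if (!inherits(block, "tload_block")) {
    stop("block must be a tload_block", call. = FALSE)
  }
  n <- length(block$kind)
  idx <- as.integer(responses$item_index)
  if (length(idx) && (any(idx < 0L) || any(idx >= n))) {
    stop("response item_index out of range for this block", call. = FALSE)
  }
  act <- as.character(responses$action)
  lat <- as.numeric(responses$latency_ms)

  # Keep creditable, channel-matched events; first press per item wins.
  creditable <- lat >= 0 & lat < block$std_ms & act != "none"
  kind_of <- block$kind[idx + 1L]
  channel_ok <- (act == "space" & kind_of == "letter") |
    (act %in% c("even_key", "odd_key") & kind_of == "number")
  keep <- which(creditable & channel_ok)
  effective_action <- rep("none", n)
  if (length(keep)) {
    ord <- keep[order(lat[keep], seq_along(keep))]
    first <- ord[!duplicated(idx[ord])]
    effective_action[idx[first] + 1L] <- act[first]
  }

  is_letter <- block$kind == "letter"
  is_number <- !is_letter
  correct <- logical(n)
  # letters: space pressed exactly when the item is a repeat target
  correct[is_letter] <- (effective_action[is_letter] == "space") ==
    block$is_repeat_target[is_letter]
  correct[is_number] <- effective_action[is_number] ==
    c(even = "even_key", odd = "odd_key")[block$parity[is_number]]

  letter_acc <- if (any(is_letter)) mean(correct[is_letter]) else NA_real_
  number_acc <- if (any(is_number)) mean(correct[is_number]) else NA_real_
  composite <- if (any(is_letter) && any(is_number)) {
    config$w_letter * letter_acc + config$w_number * number_acc
  } else if (any(is_letter)) letter_acc else number_acc

  structure(
    list(letter_accuracy = letter_acc, number_accuracy = number_acc,
         composite = composite,
         passed = composite >= config$pass_criterion,
         correct = correct),
    class = "tload_score"
  )
}

#' @export
print.tload_score <- function(x, ...) {
  cat(sprintf(
    "block score: letters %.3f, numbers %.3f, composite %.3f -> %s\n",
    x$letter_accuracy, x$number_accuracy, x$composite,
    if (isTRUE(x$passed)) "PASS" else "FAIL"))
  invisible(x)
}

#' @export
print.tload_block <- function(x, ...) {
  cat(sprintf("%s block, %d items at %d ms: %s\n", x$phase,
              length(x$kind), x$std_ms,
              paste(utils::head(x$symbol, 12), collapse = " ")))
  invisible(x)
}

#' Convert a block to a data.frame (one row per item)
#'
#' @param x A `tload_block`.
#' @param ... Unused.
#' @return A data.frame with columns index, kind, symbol, is_repeat_target,
#'   parity, required_action.
#' @export
as.data.frame.tload_block <- function(x, ...) {
  data.frame(index = x$index, kind = x$kind, symbol = x$symbol,
             is_repeat_target = x$is_repeat_target, parity = x$parity,
             required_action = x$required_action)
}

#' Validate a block's internal consistency
#'
#' Recomputes every item-level invariant from the raw symbol stream:
#' alphabet membership, alternation (combined blocks), 1-back target flags,
#' parity flags and required actions.
#'
#' @param block A `tload_block`.
#' @return Invisibly `TRUE`; stops with a message on the first violation.
#' @export
validate_block <- function(block) {
  stopifnot(inherits(block, "tload_block"))
  is_letter <- block$kind == "letter"
  if (!all(block$symbol[is_letter] %in% TLOAD_LETTERS)) {
    stop("letter symbol outside the allowed alphabet")
  }
  if (!all(block$symbol[!is_letter] %in% TLOAD_NUMBERS)) {
    stop("number symbol outside the allowed digit set")
  }
  lets <- which(is_letter)
  if (length(lets) > 1L) {
    expected <- c(NA, block$symbol[lets[-length(lets)]]) == block$symbol[lets]
    expected[1L] <- FALSE
    if (!identical(as.logical(block$is_repeat_target[lets]), expected)) {
      stop("is_repeat_target inconsistent with the symbol stream")
    }
  }
  nums <- which(!is_letter)
  if (length(nums)) {
    par <- ifelse(block$symbol[nums] %in% TLOAD_EVEN, "even", "odd")
    if (!identical(block$parity[nums], par)) {
      stop("parity flags inconsistent with symbols")
    }
  }
  if (block$phase %in% c("fam_combined", "calibration", "verification")) {
    if (!identical(block$kind, rep(c("letter", "number"),
                                   length(block$kind) %/% 2L))) {
      stop("combined block must strictly alternate letter/number, starting with a letter")
    }
  }
  req <- block$required_action
  ok <- (is_letter & ifelse(block$is_repeat_target, req == "press_space",
                            req == "withhold")) |
    (!is_letter & req == ifelse(block$parity == "even", "press_even_key",
                                "press_odd_key"))
  if (!all(ok)) stop("required_action inconsistent with item flags")
  invisible(TRUE)
}
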