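#' Task configuration for the TloadDback calibration
#'
#' Bundles every constant of the task procedure: the accuracy weighting of
#' the two sub-tasks, the pass criterion, the familiarization and starting
#' stimulus time durations (STD), the staircase step, block sizes, and the
#' verification rule.
#'
#' @param w_letter Weight of letter (1-back) accuracy in the composite.
#'   Letters carry more weight because working-memory updating makes the
#'   letter stream the harder channel.
#' @param w_number Weight of number (parity) accuracy; must sum to 1 with
#'   `w_letter`.
#' @param pass_criterion Composite accuracy at or above which a block counts
#'   as passed (inclusive).
#' @param fam_std_ms STD (ms) used for all familiarization blocks.
#' @param calib_start_std_ms STD (ms) of the first calibration block.
#' @param std_step_ms Staircase step (ms); all STDs live on this grid.
#' @param items_combined Number of items in a combined block (half letters,
#'   half numbers, alternating).
#' @param items_single Number of items in a single-task familiarization
#'   block.
#' @param fam_block_cap Maximum number of combined familiarization blocks a
#'   participant may attempt before being declared ineligible.
#' @param verification_passes_required Number of passes (including the
#'   descent pass) required at one STD for calibration to finish there.
#' @param std_floor_ms Lowest STD (ms) the staircase may reach.
#' @param std_ceiling_ms Highest representable STD (ms); also the
#'   familiarization speed.
#' @param repeat_target_count Number of 1-back letter targets per combined
#'   block.
#' @param repeat_target_count_single Number of 1-back targets per
#'   single-task letter block.
#' @param max_calibration_blocks Safety cap on calibration blocks; runs
#'   exceeding it are declared ineligible.
#'
#' @return An object of class `tload_config` (a validated list).
#' @examples
#' cfg <- task_config()
#' cfg$pass_criterion
#' @export
task_config <- function(w_letter = 0.65,
                        w_number = 0.35,
                        pass_criterion = 0.85,
                        fam_std_ms = 1500,
                        calib_start_std_ms = 1400,
                        std_step_ms = 100,
                        items_combined = 60,
                        items_single = 30,
                        fam_block_cap = 5,
                        verification_passes_required = 3,
                        std_floor_ms = 100,
                        std_ceiling_ms = 1500,
                        repeat_target_count = 10,
                        repeat_target_count_single = 5,
                        max_calibration_blocks = 60) {
  cfg <- list(
    w_letter = w_letter, w_number = w_number,
    pass_criterion = pass_criterion,
    fam_std_ms = fam_std_ms,
    calib_start_std_ms = calib_start_std_ms,
    std_step_ms = std_step_ms,
    items_combined = items_combined,
    items_single = items_single,
    fam_block_cap = fam_block_cap,
    verification_passes_required = verification_passes_required,
    std_floor_ms = std_floor_ms,
    std_ceiling_ms = std_ceiling_ms,
    repeat_target_count = repeat_target_count,
    repeat_target_count_single = repeat_target_count_single,
    max_calibration_blocks = max_calibration_blocks
  )
  class(cfg) <- "tload_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "tload_config"))
  if (abs(cfg$w_letter + cfg$w_number - 1) > 1e-12) {
    stop("w_letter + w_number must equal 1", call. = FALSE)
  }
  if (cfg$w_letter < 0 || cfg$w_number < 0) {
    stop("accuracy weights must be non-negative", call. = FALSE)
  }
  if (cfg$pass_criterion <= 0 || cfg$pass_criterion > 1) {
    stop("pass_criterion must be in (0, 1]", call. = FALSE)
  }
  ms_fields <- c("fam_std_ms", "calib_start_std_ms", "std_floor_ms",
                 "std_ceiling_ms")
  for (f in ms_fields) {
    if (!on_grid(cfg[[f]], cfg$std_step_ms)) {
      stop(sprintf("%s must be a positive multiple of std_step_ms", f),
           call. = FALSE)
    }
  }
  if (cfg$std_floor_ms > cfg$calib_start_std_ms ||
      cfg$calib_start_std_ms > cfg$std_ceiling_ms) {
    stop("need std_floor_ms <= calib_start_std_ms <= std_ceiling_ms",
         call. = FALSE)
  }
  stopifnot(is_count(cfg$items_combined), cfg$items_combined >= 2,
            cfg$items_combined %% 2 == 0,
            is_count(cfg$items_single), cfg$items_single >= 1,
            is_count(cfg$fam_block_cap), cfg$fam_block_cap >= 1,
            is_count(cfg$verification_passes_required),
            cfg$verification_passes_required >= 1,
            is_count(cfg$repeat_target_count),
            is_count(cfg$repeat_target_count_single),
            is_count(cfg$max_calibration_blocks))
  n_letters <- cfg$items_combined / 2
  if (cfg$repeat_target_count > n_letters - 1) {
    stop("repeat_target_count must be at most one less than the number of letters",
         call. = FALSE)
  }
  if (cfg$repeat_target_count_single > cfg$items_single - 1) {
    stop("repeat_target_count_single must be at most items_single - 1",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.tload_config <- function(x, ...) {
  cat("TloadDback task configuration\n")
  cat(sprintf("  composite = %.2f * letter + %.2f * number, pass at >= %.2f\n",
              x$w_letter, x$w_number, x$pass_criterion))
  cat(sprintf("  familiarization at %d ms, calibration from %d ms in %d ms steps (floor %d ms)\n",
              x$fam_std_ms, x$calib_start_std_ms, x$std_step_ms, x$std_floor_ms))
  cat(sprintf("  blocks: %d items combined / %d single; %d verification passes required\n",
              x$items_combined, x$items_single, x$verification_passes_required))
  invisible(x)
}
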