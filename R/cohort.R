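# Cohort simulation: a three-session, counterbalanced calibration study
# with sleep / sleepiness / fatigue covariates.

TIME_OF_DAY_ORDERS <- list(
  c("morning", "afternoon", "evening"),
  c("morning", "evening", "afternoon"),
  c("afternoon", "morning", "evening"),
  c("afternoon", "evening", "morning"),
  c("evening", "morning", "afternoon"),
  c("evening", "afternoon", "morning")
)

COHORT_SCHEMA_VERSION <- 1L

# Default change-score distribution for the session 1 -> 2 threshold shift
# (ms of improvement; positive = faster second session), expressed as
# observed frequencies in a 51-participant reliability cohort: 19/51 improve
# by 100 ms, 14/51 unchanged, 8/51 by 200 ms, 4/51 by 300 ms, 4/51 slower by
# 100 ms and 2/51 slower by 200 ms. Expectation: ~76.5 ms.
default_delta12 <- function() {
  c(`100` = 19 / 51, `0` = 14 / 51, `200` = 8 / 51, `300` = 4 / 51,
    `-100` = 4 / 51, `-200` = 2 / 51)
}

# Session 2 -> 3: no significant further change, slight continued
# improvement on average (+10 ms in expectation).
default_delta23 <- function() {
  c(`0` = 0.60, `100` = 0.25, `-100` = 0.15)
}

#' Describe a simulated calibration cohort
#'
#' Collects every knob of the cohort generator: sample size, the
#' distribution of individual thresholds, observer noise, the categorical
#' distributions of between-session threshold change on the 100 ms grid,
#' and the covariate model. Defaults reproduce a 51-participant,
#' three-session test-retest design whose session-1 to session-2 change
#' distribution has expectation ~76.5 ms of improvement.
#'
#' @param n_participants Number of participants.
#' @param theta_mean,theta_sd Mean and SD (ms) of the Gaussian individual
#'   threshold distribution, truncated to `theta_range`.
#' @param theta_range Length-2 truncation bounds (ms) for thetas.
#' @param slope_ms,lapse,letter_number_gap Observer noise parameters passed
#'   to [observer_profile()].
#' @param delta12,delta23 Named numeric vectors: categorical distributions
#'   of the threshold improvement (ms, on the grid; names are the values)
#'   between sessions 1-2 and 2-3. Probabilities must sum to 1.
#' @param deterministic If `TRUE`, participants are step observers at their
#'   grid-rounded thresholds (no response noise); used for exactness checks.
#' @param sleep_hours_mean,sleep_hours_sd Previous-night sleep duration
#'   model (hours), truncated to the 3-12 h range.
#' @param wakeups_rate Poisson rate of nightly wakeups.
#' @param quality_levels Integer scale of subjective sleep quality.
#' @param kss_range Inclusive integer range of Karolinska Sleepiness Scale
#'   scores drawn (full scale is 1-9).
#' @param vasf_mean,vasf_sd Visual-analog fatigue model on a 0-100 scale.
#' @param covariate_coupling Coupling coefficient between a participant's
#'   session STD (standardised) and the KSS/VASf draws; 0 (default) makes
#'   all covariates independent of performance.
#' @param retry_cap Maximum number of profile re-draws when a simulated
#'   participant fails calibration.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_participants = 51,
                          theta_mean = 900, theta_sd = 200,
                          theta_range = c(250, 1350),
                          slope_ms = 60, lapse = 0.02,
                          letter_number_gap = 80,
                          delta12 = default_delta12(),
                          delta23 = default_delta23(),
                          deterministic = FALSE,
                          sleep_hours_mean = 7.5, sleep_hours_sd = 1,
                          wakeups_rate = 1,
                          quality_levels = 1:5,
                          kss_range = c(2, 7),
                          vasf_mean = 40, vasf_sd = 20,
                          covariate_coupling = 0,
                          retry_cap = 5) {
  stopifnot(is_count(n_participants), n_participants >= 1,
            abs(sum(delta12) - 1) < 1e-8, abs(sum(delta23) - 1) < 1e-8,
            !is.null(names(delta12)), !is.null(names(delta23)),
            length(kss_range) == 2, kss_range[1] >= 1, kss_range[2] <= 9)
  structure(
    list(n_participants = as.integer(n_participants),
         sessions = 3L,
         theta_mean = theta_mean, theta_sd = theta_sd,
         theta_range = theta_range,
         slope_ms = slope_ms, lapse = lapse,
         letter_number_gap = letter_number_gap,
         delta12 = delta12, delta23 = delta23,
         deterministic = isTRUE(deterministic),
         sleep_hours_mean = sleep_hours_mean,
         sleep_hours_sd = sleep_hours_sd,
         wakeups_rate = wakeups_rate,
         quality_levels = quality_levels,
         kss_range = kss_range,
         vasf_mean = vasf_mean, vasf_sd = vasf_sd,
         covariate_coupling = covariate_coupling,
         retry_cap = as.integer(retry_cap)),
    class = "cohort_design"
  )
}

draw_categorical <- function(dist, n = 1) {
  vals <- as.numeric(names(dist))
  vals[sample.int(length(dist), n, replace = TRUE, prob = dist)]
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

# Run the three calibration sessions of one simulated participant.
simulate_participant <- function(theta, d12, d23, design, config) {
  if (design$deterministic) {
    deltas <- c(0, d12, d12 + d23)
    lapply(1:3, function(s) {
      thr <- round((theta - deltas[s]) / config$std_step_ms) *
        config$std_step_ms
      run_calibration(threshold_responder(thr), config,
                      session_index = s)
    })
  } else {
    profile <- observer_profile(
      theta_ms = theta, slope_ms = design$slope_ms, lapse = design$lapse,
      session_deltas_ms = c(d12, d23),
      letter_number_gap = design$letter_number_gap, config = config)
    responder <- profile_responder(profile)
    lapply(1:3, function(s)
      run_calibration(responder, config, session_index = s))
  }
}

#' Simulate a full calibration cohort
#'
#' Draws one observer per participant, assigns counterbalanced time-of-day
#' orders round-robin over the six permutations, runs the complete
#' calibration staircase once per session (with the participant's threshold
#' shifted by draws from the between-session change distributions), and
#' attaches sleep, sleepiness and fatigue covariates. With the default
#' `covariate_coupling = 0` the covariates are drawn independently of
#' performance. Participants whose calibration ends ineligible are re-drawn
#' up to `design$retry_cap` times (with a message).
#'
#' @param design A [cohort_design()].
#' @param config A [task_config()].
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A `tload_cohort` data.frame, one row per participant x session:
#'   `participant_id`, `session`, `time_of_day`, `std_ms`, `n_blocks`,
#'   `sleep_hours`, `n_wakeups`, `sleep_quality`, `kss`, `vasf`. The design
#'   is attached as attribute `design`.
#' @examples
#' coh <- simulate_cohort(cohort_design(n_participants = 4), seed = 1)
#' head(coh)
#' @export
simulate_cohort <- function(design = cohort_design(),
                            config = task_config(), seed = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(seed, {
    n <- design$n_participants
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      tod <- TIME_OF_DAY_ORDERS[[(i - 1L) %% 6L + 1L]]
      attempt <- 0L
      repeat {
        attempt <- attempt + 1L
        theta <- rnorm_trunc(1, design$theta_mean, design$theta_sd,
                             design$theta_range[1], design$theta_range[2])
        d12 <- draw_categorical(design$delta12)
        d23 <- draw_categorical(design$delta23)
        res <- simulate_participant(theta, d12, d23, design, config)
        if (all(vapply(res, `[[`, TRUE, "eligible"))) break
        if (attempt > design$retry_cap) {
          stop("participant ", i, " failed calibration after ",
               design$retry_cap, " re-draws", call. = FALSE)
        }
        message("participant ", i,
                " ineligible in at least one session; re-drawing profile")
      }
      std <- vapply(res, `[[`, 1L, "final_std_ms")
      coupling <- design$covariate_coupling *
        (std - design$theta_mean) / max(design$theta_sd, 1)
      rows[[i]] <- data.frame(
        participant_id = sprintf("P%03d", i),
        session = 1:3,
        time_of_day = tod,
        std_ms = std,
        n_blocks = vapply(res, `[[`, 1L, "n_blocks"),
        sleep_hours = round(rnorm_trunc(3, design$sleep_hours_mean,
                                        design$sleep_hours_sd, 3, 12), 1),
        n_wakeups = stats::rpois(3, design$wakeups_rate),
        sleep_quality = sample(design$quality_levels, 3, replace = TRUE),
        kss = as.integer(pmin(9, pmax(1, round(
          stats::runif(3, design$kss_range[1] - 0.49,
                       design$kss_range[2] + 0.49) + coupling)))),
        vasf = round(pmin(100, pmax(0,
          stats::rnorm(3, design$vasf_mean, design$vasf_sd) +
            10 * coupling)), 1)
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "design") <- design
    attr(out, "schema_version") <- COHORT_SCHEMA_VERSION
    class(out) <- c("tload_cohort", "data.frame")
    out
  })
}

#' Reshape a cohort to the participants x sessions STD matrix
#'
#' @param cohort A `tload_cohort` (or any data.frame with participant_id,
#'   session and a value column).
#' @param value Column to spread (default `"std_ms"`).
#' @return A numeric matrix, rows = participants, columns = sessions.
#' @export
cohort_matrix <- function(cohort, value = "std_ms") {
  stopifnot(all(c("participant_id", "session", value) %in% names(cohort)))
  wide <- stats::reshape(
    as.data.frame(cohort)[c("participant_id", "session", value)],
    idvar = "participant_id", timevar = "session", direction = "wide")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$participant_id
  colnames(m) <- sub(paste0("^", value, "\\."), "session_",
                     colnames(m))
  m[order(rownames(m)), , drop = FALSE]
}

#' Check the time-of-day counterbalancing of a cohort
#'
#' @param cohort A `tload_cohort`.
#' @return `TRUE` if every participant sees each time of day exactly once.
#' @export
check_counterbalancing <- function(cohort) {
  tab <- table(cohort$participant_id, cohort$time_of_day)
  all(dim(tab) == c(length(unique(cohort$participant_id)), 3)) &&
    all(tab == 1)
}
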