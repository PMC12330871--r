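# The full reliability analysis battery over a three-session cohort.

#' Run the complete reliability battery on a cohort
#'
#' Applies, in one pass: the tie-corrected Friedman test and Durbin-Conover
#' pairwise comparisons on the session STDs (with the Bonferroni-adjusted
#' threshold), the Spearman correlation matrix among session STDs,
#' Cronbach's alpha / ICC(3,k), the change-score frequency distributions
#' for sessions 1-2 and 2-3, per-item Friedman tests on the three sleep
#' measures across nights, the STD-vs-covariate Spearman matrix (raw p
#' values, uncorrected), the blocks-vs-improvement correlations, and a
#' one-way repeated-measures ANOVA of STD by time of day. Participants with
#' incomplete sessions are dropped listwise (with a message).
#'
#' @param cohort A `tload_cohort` data.frame (simulated or read from CSV).
#' @param alpha_family Family-wise alpha for the pairwise comparisons.
#' @return A `reliability_report` list; see the print method for a summary.
#' @examples
#' coh <- simulate_cohort(cohort_design(n_participants = 8), seed = 1)
#' rep <- analyze_cohort(coh)
#' rep$friedman$chi2
#' @export
analyze_cohort <- function(cohort, alpha_family = 0.05) {
  cohort <- as.data.frame(cohort)
  need <- c("participant_id", "session", "std_ms")
  stopifnot(all(need %in% names(cohort)))
  counts <- table(cohort$participant_id)
  complete <- names(counts)[counts == 3]
  dropped <- sum(counts != 3)
  if (dropped > 0) {
    message(dropped, " participant(s) dropped for incomplete sessions")
    cohort <- cohort[cohort$participant_id %in% complete, ]
  }

  stds <- cohort_matrix(cohort, "std_ms")
  report <- list(
    n = nrow(stds),
    dropped = dropped,
    session_means = colMeans(stds),
    friedman = friedman_test(stds),
    pairwise = durbin_conover(stds, alpha_family),
    bonferroni_threshold = bonferroni_threshold(alpha_family, 3),
    spearman_sessions = spearman_matrix(stds),
    cronbach_alpha = cronbach_alpha(stds),
    icc3k = icc_3k(stds),
    change_12 = change_histogram(stds, 1, 2),
    change_23 = change_histogram(stds, 2, 3)
  )

  # Covariate battery: Friedman across the three nights per sleep item,
  # and the uncorrected STD-vs-covariate Spearman matrix.
  sleep_items <- intersect(c("sleep_hours", "n_wakeups", "sleep_quality"),
                           names(cohort))
  report$covariate_friedman <- lapply(stats::setNames(sleep_items,
                                                      sleep_items),
    function(v) friedman_test(cohort_matrix(cohort, v)))

  covars <- intersect(c("sleep_hours", "n_wakeups", "sleep_quality",
                        "kss", "vasf"), names(cohort))
  if (length(covars)) {
    cov_cor <- expand.grid(session = 1:3, covariate = covars,
                           stringsAsFactors = FALSE)
    cov_cor$rho <- NA_real_; cov_cor$p_value <- NA_real_
    for (r in seq_len(nrow(cov_cor))) {
      cm <- cohort_matrix(cohort, cov_cor$covariate[r])
      s <- spearman(stds[, cov_cor$session[r]], cm[, cov_cor$session[r]])
      cov_cor$rho[r] <- s$rho; cov_cor$p_value[r] <- s$p_value
    }
    report$covariate_correlations <- cov_cor
  }

  # Blocks completed in a session vs improvement to the next session.
  if ("n_blocks" %in% names(cohort)) {
    blocks <- cohort_matrix(cohort, "n_blocks")
    report$blocks_vs_change <- list(
      s1_blocks_vs_change12 = spearman(blocks[, 1],
                                       stds[, 1] - stds[, 2]),
      s2_blocks_vs_change23 = spearman(blocks[, 2],
                                       stds[, 2] - stds[, 3])
    )
  }

  # Time-of-day control: STD rearranged into a subjects x time-of-day
  # matrix (each participant saw each time of day exactly once).
  if ("time_of_day" %in% names(cohort)) {
    tod <- cohort
    tod$session <- NULL
    tods <- c("morning", "afternoon", "evening")
    if (all(cohort$time_of_day %in% tods) &&
        isTRUE(check_counterbalancing(cohort))) {
      wide <- stats::reshape(
        tod[c("participant_id", "time_of_day", "std_ms")],
        idvar = "participant_id", timevar = "time_of_day",
        direction = "wide")
      m <- as.matrix(wide[, paste0("std_ms.", tods)])
      report$rm_anova_time_of_day <- rm_anova_oneway(m)
    }
  }

  class(report) <- "reliability_report"
  report
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("Reliability report (n = %d complete participants%s)\n",
              x$n, if (x$dropped) sprintf(", %d dropped", x$dropped) else ""))
  cat(sprintf("  session mean STDs: %s ms\n",
              paste(sprintf("%.0f", x$session_means), collapse = ", ")))
  cat(sprintf("  Friedman chi2(%d) = %.2f, p = %.4g\n",
              x$friedman$df, x$friedman$chi2, x$friedman$p_value))
  for (r in seq_len(nrow(x$pairwise))) {
    pw <- x$pairwise[r, ]
    cat(sprintf("  sessions %d-%d: t(%d) = %.2f, p = %.4g%s\n",
                pw$i, pw$j, pw$df, pw$statistic, pw$p_raw,
                if (isTRUE(pw$significant))
                  sprintf(" (sig. at %.4f)", pw$significant_at) else ""))
  }
  cat(sprintf("  Cronbach's alpha = %.3f (ICC(3,k) = %.3f)\n",
              x$cronbach_alpha$alpha, x$icc3k$icc))
  cat(sprintf("  mean change session 1->2: %.1f ms; 2->3: %.1f ms\n",
              attr(x$change_12, "mean_change"),
              attr(x$change_23, "mean_change")))
  if (!is.null(x$rm_anova_time_of_day)) {
    a <- x$rm_anova_time_of_day
    cat(sprintf("  time of day: F(%d, %d) = %.3f, p = %.3f\n",
                a$df1, a$df2, a$F, a$p_value))
  }
  invisible(x)
}

report_to_list <- function(report) {
  clean <- function(x) {
    if (is.data.frame(x)) {
      mc <- attr(x, "mean_change")
      out <- as.list(x)
      if (!is.null(mc)) out$mean_change <- mc
      out
    } else if (is.matrix(x)) {
      list(dimnames = dimnames(x), values = x)
    } else if (is.list(x)) lapply(x, clean)
    else x
  }
  c(list(schema_version = COHORT_SCHEMA_VERSION), clean(unclass(report)))
}

#' Write a reliability report as JSON
#'
#' @param report A `reliability_report`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Write standard report figures as PNG files
#'
#' Mean STD per session (with subject lines), the session 1-2 change
#' histogram, and pairwise session scatterplots.
#'
#' @param cohort A `tload_cohort`.
#' @param report The matching `reliability_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
report_figures <- function(cohort, report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stds <- cohort_matrix(cohort, "std_ms")
  paths <- character(0)

  f1 <- file.path(dir, "mean_std_by_session.png")
  grDevices::png(f1, width = 700, height = 500)
  graphics::matplot(t(stds), type = "l", lty = 1,
                    col = grDevices::adjustcolor("grey40", 0.35),
                    xlab = "Calibration session", ylab = "STD (ms)",
                    xaxt = "n", main = "Calibrated STD per session")
  graphics::axis(1, at = 1:ncol(stds), labels = 1:ncol(stds))
  graphics::lines(colMeans(stds), lwd = 3, col = "firebrick")
  grDevices::dev.off()
  paths <- c(paths, f1)

  f2 <- file.path(dir, "change_histogram_12.png")
  grDevices::png(f2, width = 700, height = 500)
  h <- report$change_12
  graphics::barplot(h$count, names.arg = h$change_ms,
                    xlab = "STD change session 1 - session 2 (ms; positive = faster)",
                    ylab = "Participants",
                    main = "Change-score distribution, sessions 1-2")
  grDevices::dev.off()
  paths <- c(paths, f2)

  f3 <- file.path(dir, "session_scatterplots.png")
  grDevices::png(f3, width = 900, height = 350)
  op <- graphics::par(mfrow = c(1, 3))
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  for (pr in pairs) {
    rho <- report$spearman_sessions$rho[pr[1], pr[2]]
    graphics::plot(stds[, pr[1]], stds[, pr[2]],
                   xlab = sprintf("Session %d STD (ms)", pr[1]),
                   ylab = sprintf("Session %d STD (ms)", pr[2]),
                   main = sprintf("rho = %.3f", rho))
    graphics::abline(0, 1, lty = 2)
  }
  graphics::par(op)
  grDevices::dev.off()
  paths <- c(paths, f3)

  invisible(paths)
}
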