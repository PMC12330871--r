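# Independent oracle implementations for the reliability battery. These
# deliberately take different code paths from the package: base R's own
# tests where available, otherwise straight-line textbook formulas with
# counting-based ranks.

# Midrank computed by counting, not by rank().
counting_rank <- function(v) {
  vapply(seq_along(v), function(i) {
    sum(v < v[i]) + (1 + sum(v == v[i])) / 2
  }, 0)
}

oracle_friedman <- function(m) {
  out <- stats::friedman.test(m)
  list(chi2 = unname(out$statistic), df = unname(out$parameter),
       p_value = out$p.value)
}

# Conover's pairwise statistic, written out longhand from the rank sums.
oracle_durbin_conover <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- matrix(0, n, k)
  for (i in seq_len(n)) r[i, ] <- counting_rank(m[i, ])
  Rj <- colSums(r)
  A <- sum(r * r)
  B <- sum(Rj^2) / n
  df <- (n - 1) * (k - 1)
  denom <- sqrt(2 * n * (A - B) / df)
  res <- NULL
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      stat <- if (denom == 0) {
        if (Rj[i] == Rj[j]) 0 else Inf * sign(Rj[i] - Rj[j])
      } else (Rj[i] - Rj[j]) / denom
      p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
      res <- rbind(res, data.frame(i = i, j = j, statistic = stat,
                                   p_raw = p))
    }
  }
  res
}

oracle_spearman <- function(x, y) {
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

# Mean squares through base aov (lm machinery), for both ICC(3,k) and the
# repeated-measures ANOVA oracle.
oracle_mean_squares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  subject = factor(rep(seq_len(n), k)),
                  condition = factor(rep(seq_len(k), each = n)))
  tab <- stats::anova(stats::lm(y ~ subject + condition, data = d))
  list(ms_subject = tab["subject", "Mean Sq"],
       ms_condition = tab["condition", "Mean Sq"],
       ms_error = tab["Residuals", "Mean Sq"],
       df_condition = tab["condition", "Df"],
       df_error = tab["Residuals", "Df"])
}

oracle_icc3k <- function(m) {
  ms <- oracle_mean_squares(m)
  (ms$ms_subject - ms$ms_error) / ms$ms_subject
}

oracle_rm_anova <- function(m) {
  ms <- oracle_mean_squares(m)
  f <- ms$ms_condition / ms$ms_error
  list(F = f, df1 = ms$df_condition, df2 = ms$df_error,
       p_value = stats::pf(f, ms$df_condition, ms$df_error,
                           lower.tail = FALSE))
}

# Random repeated-measures matrix with grid-induced ties.
random_rm_matrix <- function(n, k, gridded = TRUE) {
  if (gridded) {
    matrix(sample(seq(300, 1200, by = 100), n * k, replace = TRUE), n, k)
  } else {
    matrix(stats::rnorm(n * k, 800, 150), n, k)
  }
}

# Brute-force item-by-item scoring used to cross-check score_block.
oracle_score <- function(block, responses, config = task_config()) {
  n <- length(block$kind)
  correct <- logical(n)
  for (i in seq_len(n)) {
    idx0 <- i - 1L
    hits <- which(responses$item_index == idx0 &
                    responses$latency_ms >= 0 &
                    responses$latency_ms < block$std_ms &
                    responses$action != "none")
    if (block$kind[i] == "letter") {
      hits <- hits[responses$action[hits] == "space"]
    } else {
      hits <- hits[responses$action[hits] %in% c("even_key", "odd_key")]
    }
    act <- if (length(hits)) {
      responses$action[hits[order(responses$latency_ms[hits])][1]]
    } else "none"
    correct[i] <- if (block$kind[i] == "letter") {
      if (isTRUE(block$is_repeat_target[i])) act == "space" else
        act != "space"
    } else {
      act == (if (block$parity[i] == "even") "even_key" else "odd_key")
    }
  }
  lets <- block$kind == "letter"
  la <- mean(correct[lets]); na <- mean(correct[!lets])
  comp <- config$w_letter * la + config$w_number * na
  list(letter_accuracy = la, number_accuracy = na, composite = comp,
       passed = comp >= config$pass_criterion)
}
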