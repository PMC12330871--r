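# Test-retest reliability battery for repeated-measures matrices
# (n subjects x k conditions), implemented from the classical formulas.
# STDs live on a 100 ms grid, so ties are pervasive: within-subject ranking
# uses midranks and the Friedman statistic carries the tie-corrected
# denominator (the form matched by the common GUI statistics packages).

check_rm_matrix <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("matrix must be numeric", call. = FALSE)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("need at least 2 subjects and 2 conditions", call. = FALSE)
  }
  if (anyNA(m)) stop("matrix must have no missing cells", call. = FALSE)
  m
}

# Within-subject midranks and the quantities shared by the Friedman and
# Durbin-Conover statistics.
rank_decomposition <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  list(r = r, n = n, k = k,
       Rj = colSums(r),
       A = sum(r^2),                # sum of squared ranks
       C = n * k * (k + 1)^2 / 4)   # its value under total ties
}

#' Tie-corrected Friedman test
#'
#' Nonparametric repeated-measures ANOVA on within-subject midranks, with
#' the tie-corrected denominator: `chi2 = (k - 1) * sum((Rj - n(k+1)/2)^2)
#' / (A - C)` where `A` is the sum of squared midranks and `C` its value
#' when all observations in a row are tied. Reduces to the classical
#' statistic for tie-free data. An all-constant matrix gives statistic 0
#' and p = 1.
#'
#' @param m Numeric matrix, subjects in rows, conditions in columns; no
#'   missing cells.
#' @return List with `chi2`, `df = k - 1`, `p_value`, `tie_corrected`, `n`,
#'   `k`.
#' @examples
#' friedman_test(matrix(c(1, 2, 3, 2, 4, 6, 1, 3, 5), 3, byrow = TRUE))
#' @export
friedman_test <- function(m) {
  m <- check_rm_matrix(m)
  d <- rank_decomposition(m)
  denom <- d$A - d$C
  num <- sum((d$Rj - d$n * (d$k + 1) / 2)^2)
  chi2 <- if (denom <= 0) 0 else (d$k - 1) * num / denom
  list(chi2 = chi2, df = d$k - 1L,
       p_value = stats::pchisq(chi2, d$k - 1, lower.tail = FALSE),
       tie_corrected = TRUE, n = d$n, k = d$k)
}

#' Durbin-Conover pairwise comparisons
#'
#' Conover's post-hoc test following a Friedman test: for each pair of
#' conditions, `t = (R_i - R_j) / sqrt(2n(A - B) / ((n-1)(k-1)))` with
#' `A` the sum of squared within-subject midranks and `B = sum(Rj^2) / n`,
#' referred to a t distribution with `(n-1)(k-1)` degrees of freedom.
#'
#' @inheritParams friedman_test
#' @param alpha_family Family-wise alpha used to report the
#'   Bonferroni-adjusted per-comparison threshold.
#' @return data.frame with one row per unordered pair: `i`, `j`,
#'   `statistic`, `df`, `p_raw`, `significant_at` (the adjusted threshold),
#'   `significant`.
#' @export
durbin_conover <- function(m, alpha_family = 0.05) {
  m <- check_rm_matrix(m)
  d <- rank_decomposition(m)
  n <- d$n; k <- d$k
  B <- sum(d$Rj^2) / n
  df <- (n - 1) * (k - 1)
  se <- sqrt(pmax(2 * n * (d$A - B) / df, 0))
  pairs <- utils::combn(k, 2)
  thr <- bonferroni_threshold(alpha_family, ncol(pairs))
  out <- data.frame(
    i = pairs[1, ], j = pairs[2, ],
    statistic = NA_real_, df = df, p_raw = NA_real_,
    significant_at = thr, significant = NA
  )
  for (idx in seq_len(ncol(pairs))) {
    diffRank <- d$Rj[pairs[1, idx]] - d$Rj[pairs[2, idx]]
    stat <- if (se == 0) {
      if (diffRank == 0) 0 else Inf * sign(diffRank)
    } else diffRank / se
    out$statistic[idx] <- stat
    out$p_raw[idx] <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  }
  out$significant <- out$p_raw < thr
  out
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha_family Family-wise alpha.
#' @param m Number of comparisons.
#' @return `alpha_family / m`, rounded to 4 decimals (so 0.05 over 3
#'   comparisons reports 0.0167).
#' @export
bonferroni_threshold <- function(alpha_family = 0.05, m = 3) {
  if (!is_count(m) || m < 1) stop("m must be a positive integer",
                                  call. = FALSE)
  round(alpha_family / m, 4)
}

#' Spearman rank correlation with t-approximation p value
#'
#' Pearson correlation of midranks; the p value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Zero rank variance in either vector yields a flagged undefined result
#' rather than an error.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p_value`, `n`, `undefined`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) return(list(rho = NA_real_, p_value = NA_real_, n = n,
                         undefined = TRUE))
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                undefined = TRUE))
  }
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p_value = p, n = n, undefined = FALSE)
}

#' Spearman correlation matrix of a set of columns
#'
#' @param m Numeric matrix or data.frame.
#' @return List of matrices `rho` and `p_value` (diagonal 1 / NA).
#' @export
spearman_matrix <- function(m) {
  m <- as.matrix(m)
  k <- ncol(m)
  rho <- diag(1, k); p <- matrix(NA_real_, k, k)
  dimnames(rho) <- dimnames(p) <- list(colnames(m), colnames(m))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      s <- spearman(m[, i], m[, j])
      rho[i, j] <- rho[j, i] <- s$rho
      p[i, j] <- p[j, i] <- s$p_value
    }
  }
  list(rho = rho, p_value = p)
}

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`.
#' Numerically identical to ICC(3,k) (two-way mixed, consistency, average
#' measures). Zero total-score variance yields a flagged undefined result.
#'
#' @inheritParams friedman_test
#' @return List with `alpha`, `k`, `n`, `undefined`.
#' @export
cronbach_alpha <- function(m) {
  m <- check_rm_matrix(m)
  k <- ncol(m)
  vtot <- stats::var(rowSums(m))
  if (vtot == 0) return(list(alpha = NA_real_, k = k, n = nrow(m),
                             undefined = TRUE))
  a <- k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / vtot)
  list(alpha = a, k = k, n = nrow(m), undefined = FALSE)
}

#' Intraclass correlation ICC(3,k)
#'
#' Two-way mixed model, consistency, average of k measurements:
#' `(MS_rows - MS_error) / MS_rows` from the subjects x conditions
#' mean-square decomposition. Agrees with [cronbach_alpha()] to numerical
#' precision.
#'
#' @inheritParams friedman_test
#' @return List with `icc`, `ms_rows`, `ms_error`, `undefined`.
#' @export
icc_3k <- function(m) {
  m <- check_rm_matrix(m)
  n <- nrow(m); k <- ncol(m)
  row_means <- rowMeans(m); col_means <- colMeans(m); grand <- mean(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  if (ms_rows == 0) return(list(icc = NA_real_, ms_rows = ms_rows,
                                ms_error = ms_err, undefined = TRUE))
  list(icc = (ms_rows - ms_err) / ms_rows, ms_rows = ms_rows,
       ms_error = ms_err, undefined = FALSE)
}

#' Change-score frequency distribution between two sessions
#'
#' Per-subject difference `value[, session_a] - value[, session_b]`,
#' counted on the staircase grid. With STDs, a positive score means the
#' later session was faster (an improvement).
#'
#' @param m Repeated-measures matrix of STDs (ms).
#' @param session_a,session_b Column indices (difference is a - b).
#' @param bin_ms Grid step for binning.
#' @return data.frame with `change_ms`, `count`, `percent`; attribute
#'   `mean_change` carries the mean difference.
#' @export
change_histogram <- function(m, session_a = 1, session_b = 2,
                             bin_ms = 100) {
  m <- check_rm_matrix(m)
  diffs <- m[, session_a] - m[, session_b]
  binned <- round(diffs / bin_ms) * bin_ms
  tab <- table(binned)
  out <- data.frame(change_ms = as.numeric(names(tab)),
                    count = as.integer(tab))
  out <- out[order(-out$change_ms), ]
  rownames(out) <- NULL
  out$percent <- 100 * out$count / sum(out$count)
  attr(out, "mean_change") <- mean(diffs)
  out
}

#' One-way repeated-measures ANOVA
#'
#' Classical within-subject one-way ANOVA: each subject is measured once
#' under each condition; F = MS_conditions / MS_error with df (k-1) and
#' (n-1)(k-1).
#'
#' @param m Numeric matrix, subjects in rows, conditions (e.g. times of
#'   day) in columns.
#' @return List with `F`, `df1`, `df2`, `p_value`.
#' @export
rm_anova_oneway <- function(m) {
  m <- check_rm_matrix(m)
  n <- nrow(m); k <- ncol(m)
  row_means <- rowMeans(m); col_means <- colMeans(m); grand <- mean(m)
  ss_cond <- n * sum((col_means - grand)^2)
  ss_subj <- k * sum((row_means - grand)^2)
  ss_err <- sum((m - grand)^2) - ss_cond - ss_subj
  df1 <- as.integer(k - 1); df2 <- as.integer((n - 1) * (k - 1))
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  f <- if (ms_err == 0) {
    if (ms_cond == 0) 0 else Inf
  } else ms_cond / ms_err
  p <- if (is.infinite(f)) 0 else
    stats::pf(f, df1, df2, lower.tail = FALSE)
  list(F = f, df1 = df1, df2 = df2, p_value = p)
}
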