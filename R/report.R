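# Pooled-vs-non-pooled quality comparison and accounting tables.

#' Welch (unequal-variance) two-sample t-test
#'
#' Implements the Welch statistic and Satterthwaite degrees of freedom
#' directly so that the degenerate zero-variance case is defined: when both
#' groups have zero variance, equal means give `t = 0, p = 1` and unequal
#' means give `t = +/-Inf, p = 0`. Two-sided p-value.
#'
#' @param x,y numeric vectors, each of length >= 2 with finite values.
#' @return a `welch_test` list: `t`, `df` (real), `p`, group means.
#' @export
welch_t_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) stop("both groups need n >= 2")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    t <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    out <- list(t = t, df = NA_real_, p = if (m1 == m2) 1 else 0,
                mean_x = m1, mean_y = m2)
    class(out) <- "welch_test"
    return(out)
  }
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(t = t, df = df, p = p, mean_x = m1, mean_y = m2),
            class = "welch_test")
}

#' Per-group descriptive statistics of sample quality
#'
#' n, mean, SD and median of DQC, QC call rate and call rate per group
#' (e.g. species x pooled). Per-metric `n` counts the samples contributing
#' a non-missing value; call-rate statistics are therefore restricted to
#' QC-passing samples, which are the only ones with a call rate. SD is NA
#' for groups of one.
#'
#' @param sample_qc a `sample_qc` data.frame (or any data.frame with
#'   columns `dqc`, `qc_call_rate`, `call_rate`).
#' @param grouping vector, factor, or data.frame of grouping variables
#'   covering all samples (error otherwise).
#' @return data.frame, one row per group x metric, with columns `metric`,
#'   `n`, `mean`, `sd`, `median`; empty groups yield NA rows.
#' @export
group_quality_stats <- function(sample_qc, grouping) {
  if (!is.data.frame(grouping)) grouping <- data.frame(group = grouping)
  if (nrow(grouping) != nrow(sample_qc))
    stop("grouping must cover all samples")
  if (any(vapply(grouping, function(g) any(is.na(g)), logical(1))))
    stop("grouping must cover all samples (NA labels found)")
  key <- interaction(grouping, drop = FALSE, lex.order = TRUE)
  metrics <- c("dqc", "qc_call_rate", "call_rate")
  rows <- list()
  for (lev in levels(key)) {
    sel <- key == lev
    glab <- grouping[which(sel)[1], , drop = FALSE]  # NA row for empty groups
    rownames(glab) <- NULL
    for (m in metrics) {
      v <- sample_qc[[m]][sel]
      v <- v[!is.na(v)]
      rows[[length(rows) + 1L]] <- cbind(
        glab,
        data.frame(metric = m, n = length(v),
                   mean = if (length(v)) mean(v) else NA_real_,
                   sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
                   median = if (length(v)) stats::median(v) else NA_real_))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sample accounting table
#'
#' Exact integer partition of a screened sample set:
#' `passed = screened - fail_dqc - fail_qccr - later_removed`. Inconsistent
#' inputs (negative pass count) are an error.
#'
#' @param screened,fail_dqc,fail_qccr,later_removed nonnegative integers.
#' @return data.frame with rows `screened`, `fail_dqc`, `fail_qccr`,
#'   `later_removed`, `passed`.
#' @export
sample_accounting <- function(screened, fail_dqc, fail_qccr, later_removed = 0) {
  v <- c(screened = screened, fail_dqc = fail_dqc, fail_qccr = fail_qccr,
         later_removed = later_removed)
  if (any(v < 0) || any(v != round(v))) stop("counts must be nonnegative integers")
  passed <- screened - fail_dqc - fail_qccr - later_removed
  if (passed < 0) stop("inconsistent accounting: more failures than screened samples")
  data.frame(stage = c(names(v), "passed"),
             n = as.integer(c(v, passed)),
             stringsAsFactors = FALSE)
}

#' Pooled-vs-non-pooled quality comparison
#'
#' For each species, Welch-tests each quality metric between pooled and
#' non-pooled samples, alongside the group descriptive statistics.
#'
#' @param sample_qc a `sample_qc` data.frame.
#' @param species character vector of species per sample.
#' @param pooled logical vector per sample (TRUE = pooled reaction).
#' @param alpha significance level reported against (default 0.05).
#' @return data.frame with one row per species x metric: group means, `t`,
#'   `df`, `p`, `significant`.
#' @export
compare_pooling <- function(sample_qc, species, pooled, alpha = 0.05) {
  stopifnot(length(species) == nrow(sample_qc), length(pooled) == nrow(sample_qc))
  rows <- list()
  for (sp in unique(species)) {
    for (m in c("dqc", "qc_call_rate", "call_rate")) {
      v <- sample_qc[[m]][species == sp]
      pl <- pooled[species == sp]
      x <- v[pl & !is.na(v)]; y <- v[!pl & !is.na(v)]
      if (length(x) < 2 || length(y) < 2) {
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, metric = m, n_pooled = length(x), n_nonpooled = length(y),
          mean_pooled = if (length(x)) mean(x) else NA_real_,
          mean_nonpooled = if (length(y)) mean(y) else NA_real_,
          t = NA_real_, df = NA_real_, p = NA_real_, significant = NA)
        next
      }
      wt <- welch_t_test(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, metric = m, n_pooled = length(x), n_nonpooled = length(y),
        mean_pooled = wt$mean_x, mean_nonpooled = wt$mean_y,
        t = wt$t, df = wt$df, p = wt$p, significant = wt$p < alpha)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
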