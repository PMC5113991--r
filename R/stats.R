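#' Replicate-level summary: mean and SEM
#'
#' @param values Numeric vector of replicate values (NA removed).
#' @return List of class `group_summary` with `mean`, `sem` (sample SD over
#'   sqrt(n), `NA` for n = 1) and `n`.
#' @examples
#' summarize_replicates(c(1, 2, 3, 4))  # mean 2.5, sem ~0.6455
#' @export
summarize_replicates <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) stop("no values to summarize")
  structure(list(mean = mean(values),
                 sem = if (n >= 2) stats::sd(values) / sqrt(n) else NA_real_,
                 n = n),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%.4g +/- %.3g (mean +/- SEM, n = %d)\n",
              x$mean, x$sem, x$n))
  invisible(x)
}

#' Two-sample t-test between replicate groups
#'
#' Unpaired two-sided t-test, pooled-variance (classic Student) by default,
#' Welch by `welch = TRUE`. When both groups have zero variance the t
#' statistic is undefined; the convention used is p = 1 (t = 0) for equal
#' means and p = 0 (t = Inf, sign of the mean difference) otherwise.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @param welch Use Welch's unequal-variance test instead of the pooled
#'   test.
#' @return List with `t`, `p`, `significant`.
#' @export
compare_groups <- function(a, b, alpha = 0.05, welch = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 replicates")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      t <- 0; p <- 1
    } else {
      t <- sign(mean(a) - mean(b)) * Inf; p <- 0
    }
  } else {
    ht <- stats::t.test(a, b, var.equal = !welch, alternative = "two.sided")
    t <- unname(ht$statistic); p <- ht$p.value
  }
  list(t = t, p = p, significant = p < alpha)
}
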