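# The statistical comparisons used throughout: pooled-variance two-sided
# t-tests (also from summary statistics), paired t-tests, exact Fisher
# tests, and the two-sample Kolmogorov-Smirnov test. No multiple-testing
# adjustment anywhere, by design.

#' Summary statistics of one group
#'
#' @param mean group mean
#' @param sd sample standard deviation (>= 0)
#' @param n group size (>= 2)
#' @return a `summary_stat` object
#' @export
summary_stat <- function(mean, sd, n) {
  assert_that(is.numeric(mean) && length(mean) == 1L, "mean must be scalar")
  assert_that(is.numeric(sd) && sd >= 0, "sd must be >= 0")
  assert_that(is_count(n) && n >= 2, "n must be an integer >= 2")
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "summary_stat")
}

test_result <- function(statistic, df, p, name) {
  structure(list(statistic = statistic, df = df, p.value = p, test = name),
            class = "mutaccum_test")
}

#' @export
print.mutaccum_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g\n", x$test, x$statistic,
              if (!is.null(x$df) && !is.na(x$df))
                sprintf(", df = %g", x$df) else "", x$p.value))
  invisible(x)
}

#' Pooled-variance two-sided t-test from summary statistics
#'
#' Student's (equal-variance) t-test on two groups given as mean, sample sd
#' and n, with `df = n_a + n_b - 2`. When both sds are zero and the means
#' are equal, `t = 0` and `p = 1` by convention; when the sds are zero and
#' the means differ, `p = 0`.
#'
#' @param a,b [summary_stat()] objects (or lists with mean, sd, n)
#' @return a test result with statistic, df and two-sided p-value
#' @export
t_test_from_summary <- function(a, b) {
  for (g in list(a, b)) {
    assert_that(is.list(g) && all(c("mean", "sd", "n") %in% names(g)),
                "groups must have mean, sd and n")
    assert_that(g$n >= 2, "group size must be >= 2")
    assert_that(g$sd >= 0, "sd must be >= 0")
  }
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  if (se == 0) {
    if (a$mean == b$mean) {
      return(test_result(0, df, 1, "Two-sided pooled t-test"))
    }
    return(test_result(sign(a$mean - b$mean) * Inf, df, 0,
                       "Two-sided pooled t-test"))
  }
  t <- (a$mean - b$mean) / se
  test_result(t, df, 2 * stats::pt(-abs(t), df), "Two-sided pooled t-test")
}

#' Two-sided t-test on raw samples
#'
#' Unpaired: pooled-variance Student's t-test, identical to
#' [t_test_from_summary()] on the groups' summaries. Paired: one-sample
#' t-test on the differences; identical pairs give `p = 1` by convention.
#'
#' @param x,y numeric vectors (equal length when `paired`)
#' @param paired logical
#' @return a test result
#' @export
t_test_samples <- function(x, y, paired = FALSE) {
  assert_that(length(x) >= 2 && length(y) >= 2, "need n >= 2 per group")
  if (!paired) {
    return(t_test_from_summary(
      summary_stat(mean(x), stats::sd(x), length(x)),
      summary_stat(mean(y), stats::sd(y), length(y))))
  }
  assert_that(length(x) == length(y), "paired test needs equal lengths")
  d <- x - y
  df <- length(d) - 1
  se <- stats::sd(d) / sqrt(length(d))
  if (se == 0) {
    p <- if (mean(d) == 0) 1 else 0
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(test_result(t, df, p, "Two-sided paired t-test"))
  }
  t <- mean(d) / se
  test_result(t, df, 2 * stats::pt(-abs(t), df), "Two-sided paired t-test")
}

# upper tail of the asymptotic Kolmogorov distribution for the two-sided
# two-sample statistic, lambda = sqrt(mn/(m+n)) * D
kolmogorov_upper <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- 1:100
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum of the absolute ECDF difference evaluated at the
#' pooled points (ties contribute through the ECDF jumps). The p-value is
#' exact (conditional on the tie pattern) when both samples have at most 25
#' observations, and asymptotic otherwise.
#'
#' @param x,y non-empty numeric vectors
#' @return a test result with statistic `D` and two-sided p-value
#' @export
ks_two_sample <- function(x, y) {
  assert_that(length(x) >= 1 && length(y) >= 1, "both samples must be non-empty")
  m <- length(x); n <- length(y)
  pts <- sort(unique(c(x, y)))
  D <- max(abs(stats::ecdf(x)(pts) - stats::ecdf(y)(pts)))
  p <- if (m <= 25 && n <= 25) {
    stats::psmirnov(D, sizes = c(m, n), z = c(x, y), exact = TRUE,
                    lower.tail = FALSE)
  } else {
    kolmogorov_upper(sqrt(m * n / (m + n)) * D)
  }
  test_result(D, NA_real_, p, "Two-sample Kolmogorov-Smirnov test")
}

# two-sided exact p for a 2x2 table via hypergeometric enumeration: sum the
# probabilities of all tables with the observed margins that are no more
# probable than the observed one (with a relative tolerance for float ties,
# as in the classical definition)
fisher_2x2_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(c1, r1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Fisher's exact test for count tables
#'
#' For 2x2 tables the two-sided p-value is computed by hypergeometric
#' enumeration, summing all tables with the observed margins that are as or
#' more extreme (no more probable) than the observed table. Larger R x C
#' tables use the exact network algorithm of [stats::fisher.test()].
#'
#' @param tab matrix of non-negative integer counts, at least 2x2
#' @return a test result with the two-sided exact p-value
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  assert_that(nrow(tab) >= 2 && ncol(tab) >= 2,
              "table must have at least 2 rows and 2 columns")
  assert_that(all(tab >= 0) && all(tab == floor(tab)),
              "table entries must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stopf("degenerate table: a row or column margin is zero")
  }
  p <- if (all(dim(tab) == c(2L, 2L))) {
    fisher_2x2_p(tab)
  } else {
    stats::fisher.test(tab)$p.value
  }
  test_result(NA_real_, NA_real_, min(1, p), "Fisher's exact test")
}
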