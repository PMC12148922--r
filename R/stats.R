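#' Kruskal-Wallis rank sum test across groups
#'
#' Omnibus nonparametric comparison of k groups: the tie-corrected H
#' statistic with p from the chi-square approximation on k-1 degrees of
#' freedom (via [stats::kruskal.test()]). With all values identical across
#' groups, H = 0 and p = 1.
#'
#' @param samples List of numeric vectors, one per group (k >= 2, each
#'   non-empty). Names, if present, label the groups.
#' @param alpha Significance level recorded in the result (default 0.05);
#'   pairwise follow-up is conventionally run only when `p_value < alpha`.
#' @return A `swe_group_test` list: `statistic` (H), `df`, `p_value`,
#'   `alpha`, `pairs` (`NULL`; see [pairwise_wilcoxon()]).
#' @export
kruskal_wallis <- function(samples, alpha = 0.05) {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (any(lengths(samples) < 1)) stop("each group needs at least one value")
  x <- unlist(samples, use.names = FALSE)
  g <- factor(rep(seq_along(samples), lengths(samples)))
  if (length(unique(x)) == 1) {
    kt <- list(statistic = c(H = 0), parameter = length(samples) - 1,
               p.value = 1)
  } else {
    kt <- stats::kruskal.test(x, g)
  }
  structure(
    list(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = unname(kt$p.value), alpha = alpha, pairs = NULL),
    class = "swe_group_test")
}

# rank-sum of group 1, z with tie-corrected variance, asymptotic p
.wilcoxon_pair <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- if (sigma2 > 0) (w - mu) / sqrt(sigma2) else 0
  p <- if (sigma2 > 0) 2 * stats::pnorm(-abs(z)) else 1
  c(w = w, z = z, p = p)
}

#' Pairwise asymptotic Wilcoxon rank sum tests
#'
#' Post-hoc identification of which groups differ, after a significant
#' omnibus test: for each pair of groups, the rank-sum statistic W of the
#' first group, the standardized z with tie-corrected variance, and the
#' two-sided normal-approximation p. No multiplicity adjustment is applied
#' by default; Holm or Bonferroni are available by argument.
#'
#' @param samples Named or unnamed list of numeric vectors (k >= 2).
#' @param adjust `"none"` (default), `"holm"`, or `"bonferroni"`.
#' @return Tibble with one row per pair: `group1`, `group2`, `w`, `z`,
#'   `p_value`.
#' @export
pairwise_wilcoxon <- function(samples, adjust = c("none", "holm",
                                                  "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(is.list(samples), length(samples) >= 2)
  if (any(lengths(samples) < 1)) stop("each group needs at least one value")
  nm <- names(samples) %||% paste0("group", seq_along(samples))
  pairs <- utils::combn(length(samples), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    s <- .wilcoxon_pair(samples[[i1]], samples[[i2]])
    tibble::tibble(group1 = nm[i1], group2 = nm[i2],
                   w = unname(s["w"]), z = unname(s["z"]),
                   p_value = unname(s["p"]))
  })
  out <- dplyr::bind_rows(rows)
  if (adjust != "none") out$p_value <- stats::p.adjust(out$p_value, adjust)
  out
}

#' Spearman rank correlation with interpretive band
#'
#' Rank correlation with average ranks for ties and the asymptotic p-value
#' (via [stats::cor.test()], `exact = FALSE`). Incomplete pairs are dropped.
#' The coefficient is banded on `|rho|`:
#' below_fair `[0, 0.25)`, fair `[0.25, 0.50)`, moderate_to_good
#' `[0.50, 0.75)`, good_to_excellent `[0.75, 1]`.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A `swe_correlation` list: `rho`, `p_value`, `n`, `band`.
#'   Zero variance in either variable gives `rho = NA`, `band = NA`, and
#'   `degenerate = TRUE`.
#' @export
spearman_corr <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(rho = NA_real_, p_value = NA_real_, n = n,
                          band = NA_character_, degenerate = TRUE),
                     class = "swe_correlation"))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  structure(
    list(rho = unname(ct$estimate), p_value = ct$p.value, n = n,
         band = rho_band(unname(ct$estimate)), degenerate = FALSE),
    class = "swe_correlation")
}

#' Interpretive band for a correlation coefficient
#'
#' Pure function of `|rho|`: `[0, 0.25)` below_fair, `[0.25, 0.50)` fair,
#' `[0.50, 0.75)` moderate_to_good, `[0.75, 1]` good_to_excellent.
#'
#' @param rho Correlation coefficient in \[-1, 1\].
#' @return Character band label.
#' @export
rho_band <- function(rho) {
  a <- abs(rho)
  dplyr::case_when(
    a >= 0.75 ~ "good_to_excellent",
    a >= 0.50 ~ "moderate_to_good",
    a >= 0.25 ~ "fair",
    TRUE ~ "below_fair")
}

#' Average-measures intraclass correlation, two-way model
#'
#' Test-retest reliability of the average of k repeated measurements under
#' the two-way model with absolute agreement (the estimator computed by
#' SPSS's "two-way mixed, absolute agreement, average measures" menu choice,
#' often labelled ICC(3,k) there despite matching the ICC(A,k) definition;
#' the consistency variant is available by argument). From the two-way mean
#' squares MSR (subjects), MSC (repetitions) and MSE:
#' \deqn{ICC(A,k) = (MSR - MSE) / (MSR + (MSC - MSE)/n)}
#' \deqn{ICC(C,k) = (MSR - MSE) / MSR}
#' The 95% CI is F-based (Satterthwaite df for the agreement variant). The
#' standard error of measurement is `SEM = pooled_sd * sqrt(1 - ICC)`, with
#' the pooled SD the square root of the mean per-repetition variance across
#' subjects.
#'
#' @param data Numeric matrix or data frame, subjects in rows, repetitions
#'   in columns (k = 3 in the intended design; other k are accepted).
#'   Rows with missing values are dropped (listwise deletion).
#' @param type `"agreement"` (default) or `"consistency"`.
#' @param conf_level Confidence level, default 0.95.
#' @return A `swe_icc` list: `icc`, `ci95` (lower, upper), `sem`, `model`
#'   (label recording the exact variant), `n`, `k`.
#' @export
icc_3_3 <- function(data, type = c("agreement", "consistency"),
                    conf_level = 0.95) {
  type <- match.arg(type)
  m <- as.matrix(data)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2) stop("need at least 2 complete subjects")
  if (k < 2) stop("need at least 2 repetitions")

  row_means <- rowMeans(m); col_means <- colMeans(m); grand <- mean(m)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sse <- sum((m - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  alpha <- 1 - conf_level
  if (type == "consistency") {
    icc <- (msr - mse) / msr
    f <- msr / mse
    fu <- stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fl <- stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci <- c(1 - fu / f, 1 - 1 / (f * fl))
    model <- sprintf("two-way, consistency, average of k=%d: (MSR-MSE)/MSR", k)
  } else {
    icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    icc <- (msr - mse) / (msr + (msc - mse) / n)
    # Satterthwaite df for the agreement CI, then step up to average measures
    fj <- msc / mse
    a <- k * icc1 / (n * (1 - icc1))
    b <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_u <- stats::qf(1 - alpha / 2, n - 1, v)
    f_l <- stats::qf(1 - alpha / 2, v, n - 1)
    l1 <- n * (msr - f_u * mse) /
      (f_u * (k * msc + (k * n - k - n) * mse) + n * msr)
    u1 <- n * (f_l * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_l * msr)
    ci <- c(l1 * k / (1 + l1 * (k - 1)), u1 * k / (1 + u1 * (k - 1)))
    model <- sprintf(
      "two-way, absolute agreement, average of k=%d: (MSR-MSE)/(MSR+(MSC-MSE)/n)",
      k)
  }
  pooled_sd <- sqrt(mean(apply(m, 2, stats::var)))
  sem <- pooled_sd * sqrt(max(1 - icc, 0))
  structure(
    list(icc = icc, ci95 = ci, sem = sem, model = model, n = n, k = k),
    class = "swe_icc")
}

#' @export
print.swe_icc <- function(x, ...) {
  cat(sprintf("<swe_icc> ICC = %.3f (95%% CI %.3f-%.3f), SEM = %.3f\n",
              x$icc, x$ci95[1], x$ci95[2], x$sem))
  cat("  model:", x$model, sprintf("(n = %d subjects)\n", x$n))
  invisible(x)
}

.anova_power <- function(N, f, k, alpha) {
  if (N <= k) return(0)
  1 - stats::pf(stats::qf(1 - alpha, k - 1, N - k), k - 1, N - k,
                ncp = f^2 * N)
}

#' A-priori total sample size for the one-way ANOVA
#'
#' Smallest total N such that the fixed-effects one-way ANOVA F test with
#' noncentrality `f^2 * N` (df1 = k-1, df2 = N-k) reaches the requested
#' power at level `alpha`. The standard parametric stand-in when planning a
#' Kruskal-Wallis comparison.
#'
#' @param effect_f Cohen's f (> 0).
#' @param alpha Significance level, default 0.05.
#' @param power Target power, default 0.80.
#' @param k_groups Number of groups, default 3.
#' @return Total N (integer) with attribute `achieved_power`.
#' @examples
#' anova_power_n(0.48) # 45
#' @export
anova_power_n <- function(effect_f, alpha = 0.05, power = 0.80,
                          k_groups = 3) {
  if (effect_f <= 0) stop("effect_f must be > 0")
  if (power <= 0 || power >= 1 || alpha <= 0 || alpha >= 1)
    stop("alpha and power must lie in (0, 1)")
  N <- k_groups + 1
  repeat {
    p <- .anova_power(N, effect_f, k_groups, alpha)
    if (p >= power) break
    N <- N + 1
    if (N > 1e6) stop("requested power unreachable")
  }
  structure(N, achieved_power = p)
}

.t_power <- function(n_per_group, d, alpha) {
  df <- 2 * n_per_group - 2
  if (df <= 0) return(0)
  ncp <- d * sqrt(n_per_group / 2)
  q <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(q, df, ncp) + stats::pt(-q, df, ncp)
}

#' A-priori total sample size for the Wilcoxon-Mann-Whitney test
#'
#' Two-group sample size by the asymptotic-relative-efficiency (ARE) method:
#' solve the two-sided two-sample t-test size for effect d via the
#' noncentral-t distribution (continuous n, 1:1 allocation), inflate the
#' total by the reciprocal of the Pitman ARE of the Wilcoxon test against
#' the t-test (3/pi for normal parent distributions), and round up to the
#' smallest even total N whose ARE-adjusted power reaches the target. For a
#' pairwise comparison within a k-group design planned on Cohen's f, the
#' two-group effect is d = 2f.
#'
#' @param effect_d Two-group effect size d; if missing, computed as
#'   `2 * effect_f`.
#' @param effect_f Cohen's f from the omnibus design (used when `effect_d`
#'   is missing).
#' @param alpha Two-sided level, default 0.05.
#' @param power Target power, default 0.80.
#' @param are Pitman ARE; default `3 / pi` (normal parents). `are = 1`
#'   recovers the plain t-test size.
#' @return Total N (even integer) with attribute `achieved_power` (the
#'   ARE-adjusted power at N).
#' @examples
#' wmw_power_n(effect_f = 0.48) # 38
#' @export
wmw_power_n <- function(effect_d = NULL, effect_f = NULL, alpha = 0.05,
                        power = 0.80, are = 3 / pi) {
  if (is.null(effect_d)) {
    if (is.null(effect_f)) stop("supply effect_d or effect_f")
    effect_d <- 2 * effect_f
  }
  if (effect_d <= 0) stop("effect size must be > 0")
  # ARE-adjusted power of a total N: the WMW test at total N has the power
  # of a t-test on an effective total of N * are
  wmw_power <- function(N) .t_power(N * are / 2, effect_d, alpha)
  N <- 4
  repeat {
    p <- wmw_power(N)
    if (p >= power) break
    N <- N + 2
    if (N > 1e6) stop("requested power unreachable")
  }
  structure(N, achieved_power = p)
}
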