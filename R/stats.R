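# Group comparison statistics: Shapiro-Wilk normality routing, pooled-
# variance t-test or exact Mann-Whitney U, Hedges' g with CI, and paired
# stress-effect tests (paired t / exact Wilcoxon signed rank).

#' Route a two-group comparison by normality
#'
#' Chooses the pooled-variance Student t-test when Shapiro-Wilk finds no
#' evidence against normality (p >= `alpha`) in *both* groups, otherwise
#' the Mann-Whitney U test with an exact sampling distribution for U.
#' Groups too small (n < 3) or constant, where Shapiro-Wilk is undefined,
#' fall back to the non-parametric route with a warning.
#'
#' @param x_high,x_low Numeric vectors of per-subject values.
#' @param alpha Normality-test significance level (default 0.05).
#' @return `"student_t"` or `"mann_whitney_exact"`.
#' @export
normality_route <- function(x_high, x_low, alpha = 0.05) {
  sw_p <- function(x) {
    if (length(x) < 3 || length(unique(x)) == 1) {
      return(NA_real_)
    }
    stats::shapiro.test(x)$p.value
  }
  p1 <- sw_p(x_high)
  p2 <- sw_p(x_low)
  if (is.na(p1) || is.na(p2)) {
    warning(
      "Shapiro-Wilk undefined for a group (n < 3 or constant); ",
      "falling back to the non-parametric route",
      call. = FALSE
    )
    return("mann_whitney_exact")
  }
  if (p1 >= alpha && p2 >= alpha) "student_t" else "mann_whitney_exact"
}

# Exact null distribution of the Mann-Whitney U statistic (no ties):
# count[u + 1] = number of labelings of sizes (m, n) with U = u. Standard
# recursion on whether the largest pooled value belongs to the first group:
# c(m, n, u) = c(m - 1, n, u - n) + c(m, n - 1, u).
mwu_count <- function(m, n) {
  umax <- m * n
  a <- array(0, dim = c(m + 1, n + 1, umax + 1))
  a[1, , 1] <- 1
  a[, 1, 1] <- 1
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      from_first <- c(rep(0, j), a[i, j + 1, seq_len(umax + 1 - j)])
      a[i + 1, j + 1, ] <- from_first + a[i + 1, j, ]
    }
  }
  a[m + 1, n + 1, ]
}

#' Exact Mann-Whitney U test
#'
#' U is computed from mid-rank sums; the two-sided p-value comes from the
#' exact null distribution of U. Without ties the distribution is obtained
#' by dynamic programming over all `choose(n1+n2, n1)` labelings. With ties
#' the exact permutation distribution of the mid-rank U is enumerated in
#' full when `n1+n2 <= max_exact`, otherwise a tie-corrected normal
#' approximation is used; both tie paths are flagged in the result.
#'
#' The two-sided p is `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param x1,x2 Numeric vectors (non-empty).
#' @param max_exact Largest `n1+n2` for which the tied-data permutation
#'   distribution is fully enumerated.
#' @return List: `U` (for `x1`), `U2` (= `n1*n2 - U`), `p`, `method`
#'   (`"exact_dp"`, `"exact_permutation"`, or `"normal_approx"`), `ties`.
#' @export
exact_mwu <- function(x1, x2, max_exact = 16) {
  n1 <- length(x1)
  n2 <- length(x2)
  if (n1 == 0 || n2 == 0) stop("empty group", call. = FALSE)
  pooled <- c(x1, x2)
  r <- rank(pooled)
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (!ties && n1 + n2 <= 40) {
    counts <- mwu_count(n1, n2)
    total <- sum(counts)
    cdf <- cumsum(counts)
    p_le <- cdf[u1 + 1] / total
    p_ge <- (total - if (u1 >= 1) cdf[u1] else 0) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact_dp"
  } else if (n1 + n2 <= max_exact) {
    idx <- utils::combn(n1 + n2, n1)
    half <- n1 * (n1 + 1) / 2
    us <- colSums(matrix(r[idx], nrow = n1)) - half
    eps <- 1e-9
    p <- min(
      1,
      2 * min(mean(us <= u1 + eps), mean(us >= u1 - eps))
    )
    method <- "exact_permutation"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    nn <- n1 + n2
    sigma2 <- n1 * n2 / 12 *
      (nn + 1 - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
    z <- (u1 - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(U = u1, U2 = n1 * n2 - u1, p = p, method = method, ties = ties)
}

#' Hedges' g standardised mean difference
#'
#' `d = (m1 - m2) / s_pooled` with the pooled SD
#' `sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2))`, corrected for
#' small-sample bias by `J = 1 - 3 / (4 df - 1)` with `df = n1+n2-2`. The
#' 95% CI uses the normal approximation with
#' `SE^2 = (n1+n2)/(n1 n2) + g^2 / (2 (n1+n2))`.
#'
#' Accepts either raw vectors or the summary form (`m1, s1, n1, m2, s2,
#' n2`).
#'
#' @param x1,x2 Numeric vectors, or `NULL` when using the summary form.
#' @param m1,s1,n1,m2,s2,n2 Group means, SDs and sizes (summary form).
#' @param conf_level Confidence level of the CI.
#' @return Tibble: `g`, `ci_low`, `ci_high`, `d`, `s_pooled`, `n1`, `n2`.
#' @examples
#' hedges_g(m1 = 181.13, s1 = 5.76, n1 = 10, m2 = 174.05, s2 = 6.67, n2 = 10)
#' @export
hedges_g <- function(x1 = NULL, x2 = NULL,
                     m1 = mean(x1), s1 = stats::sd(x1), n1 = length(x1),
                     m2 = mean(x2), s2 = stats::sd(x2), n2 = length(x2),
                     conf_level = 0.95) {
  stopifnot(n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2
  s_pooled <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df)
  if (s_pooled <= 0) stop("zero pooled SD", call. = FALSE)
  d <- (m1 - m2) / s_pooled
  j <- 1 - 3 / (4 * df - 1)
  g <- d * j
  se <- sqrt((n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2)))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    g = g, ci_low = g - zq * se, ci_high = g + zq * se,
    d = d, s_pooled = s_pooled, n1 = n1, n2 = n2
  )
}

iqr_hinge <- function(x) {
  # SPSS HAVERAGE (weighted-average percentile) quartiles
  q <- unname(stats::quantile(x, c(0.25, 0.75), type = 6))
  q[2] - q[1]
}

#' Compare one variable between resilience groups
#'
#' Routes through [normality_route()]: normally distributed in both groups
#' gives a pooled-variance two-sided t-test with group mean +/- SD
#' summaries and, when significant, Hedges' g with CI; otherwise the exact
#' Mann-Whitney U test with median [IQR] summaries (IQR by the
#' weighted-average percentile method).
#'
#' @param data Data frame holding per-subject values and group labels.
#' @param value,group Column names (tidy-eval) of the value and the group
#'   label; `group` must contain exactly the two levels `positive` and one
#'   other.
#' @param positive Group treated as group 1 / the positive class
#'   (default `"high"`).
#' @param alpha Two-sided significance level for both routing and the
#'   effect-size attachment rule.
#' @return One-row tibble: `test`, `statistic`, `p`, `significant`, group
#'   summaries (`mean_high`, `sd_high`, `mean_low`, `sd_low`, `median_high`,
#'   `iqr_high`, `median_low`, `iqr_low` -- filled according to the test),
#'   `g`, `g_ci_low`, `g_ci_high`, `n_high`, `n_low`.
#' @export
compare_groups <- function(data, value, group, positive = "high",
                           alpha = 0.05) {
  v <- dplyr::pull(data, {{ value }})
  grp <- dplyr::pull(data, {{ group }})
  x1 <- v[grp == positive]
  x2 <- v[grp != positive]
  x1 <- x1[!is.na(x1)]
  x2 <- x2[!is.na(x2)]
  if (length(x1) == 0 || length(x2) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  out <- tibble::tibble(
    test = NA_character_, statistic = NA_real_, p = NA_real_,
    significant = NA,
    mean_high = NA_real_, sd_high = NA_real_,
    mean_low = NA_real_, sd_low = NA_real_,
    median_high = NA_real_, iqr_high = NA_real_,
    median_low = NA_real_, iqr_low = NA_real_,
    g = NA_real_, g_ci_low = NA_real_, g_ci_high = NA_real_,
    n_high = length(x1), n_low = length(x2)
  )
  degenerate <- length(unique(c(x1, x2))) == 1
  if (degenerate) {
    out$test <- "degenerate"
    out$p <- 1
    out$significant <- FALSE
    out$mean_high <- mean(x1)
    out$mean_low <- mean(x2)
    return(out)
  }
  route <- suppressWarnings(normality_route(x1, x2, alpha))
  if (route == "student_t") {
    tt <- stats::t.test(x1, x2, var.equal = TRUE)
    out$test <- "student_t"
    out$statistic <- unname(tt$statistic)
    out$p <- tt$p.value
    out$mean_high <- mean(x1)
    out$sd_high <- stats::sd(x1)
    out$mean_low <- mean(x2)
    out$sd_low <- stats::sd(x2)
    if (tt$p.value < alpha) {
      gg <- hedges_g(x1, x2)
      out$g <- gg$g
      out$g_ci_low <- gg$ci_low
      out$g_ci_high <- gg$ci_high
    }
  } else {
    mw <- exact_mwu(x1, x2)
    out$test <- "mann_whitney_exact"
    out$statistic <- mw$U
    out$p <- mw$p
    out$median_high <- stats::median(x1)
    out$iqr_high <- iqr_hinge(x1)
    out$median_low <- stats::median(x2)
    out$iqr_low <- iqr_hinge(x2)
  }
  out$significant <- out$p < alpha
  out
}

# Exact two-sided signed-rank p via full sign enumeration on mid-ranks of
# |d|; used for tied data at small n.
signed_rank_enum_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  eps <- 1e-9
  min(1, 2 * min(mean(ws <= w_obs + eps), mean(ws >= w_obs - eps)))
}

#' Paired stress-effect test
#'
#' Tests whether a quantity changed from baseline to peak stress within
#' subjects. Shapiro-Wilk on the paired differences routes to the paired
#' t-test (normal) or the exact Wilcoxon signed-rank test (otherwise). All
#' differences zero is degenerate: p = 1, flagged.
#'
#' For the signed-rank route, zeros are dropped; without ties among the
#' absolute differences the exact distribution of the rank sum is used,
#' with ties the full `2^n` sign enumeration when `n <= 16`, else a normal
#' approximation (flagged).
#'
#' @param pre,post Paired numeric vectors of equal length >= 3.
#' @param alpha Routing significance level for Shapiro-Wilk.
#' @return One-row tibble: `test`, `statistic`, `p`, `n`, `mean_change`,
#'   `flag`.
#' @export
paired_change_test <- function(pre, post, alpha = 0.05) {
  stopifnot(length(pre) == length(post), length(pre) >= 3)
  d <- post - pre
  out <- tibble::tibble(
    test = NA_character_, statistic = NA_real_, p = NA_real_,
    n = length(d), mean_change = mean(d), flag = NA_character_
  )
  if (all(d == 0)) {
    out$test <- "degenerate"
    out$p <- 1
    out$flag <- "all differences zero"
    return(out)
  }
  sw_ok <- length(unique(d)) > 1
  sw_p <- if (sw_ok) stats::shapiro.test(d)$p.value else 0
  if (sw_ok && sw_p >= alpha) {
    tt <- stats::t.test(post, pre, paired = TRUE)
    out$test <- "paired_t"
    out$statistic <- unname(tt$statistic)
    out$p <- tt$p.value
    return(out)
  }
  dz <- d[d != 0]
  n <- length(dz)
  if (length(dz) < length(d)) out$flag <- "zero differences dropped"
  r <- rank(abs(dz))
  w <- sum(r[dz > 0])
  out$statistic <- w
  ties <- anyDuplicated(abs(dz)) > 0
  if (!ties) {
    p_le <- stats::psignrank(w, n)
    p_ge <- 1 - stats::psignrank(w - 1, n)
    out$p <- min(1, 2 * min(p_le, p_ge))
    out$test <- "wilcoxon_signed_rank_exact"
  } else if (n <= 16) {
    out$p <- signed_rank_enum_p(dz)
    out$test <- "wilcoxon_signed_rank_exact"
    out$flag <- paste(
      stats::na.omit(c(out$flag, "ties: full sign enumeration")),
      collapse = "; "
    )
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(abs(dz))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu) / sqrt(sigma2)
    out$p <- min(1, 2 * stats::pnorm(-abs(z)))
    out$test <- "wilcoxon_signed_rank_normal"
    out$flag <- paste(
      stats::na.omit(c(out$flag, "ties: normal approximation")),
      collapse = "; "
    )
  }
  out
}

#' Stress-effect and group-difference analysis of a biomarker panel
#'
#' For each analyte: (a) the overall baseline to peak-stress change across
#' all subjects via [paired_change_test()], and (b) the between-group
#' comparison of individual change scores via [compare_groups()].
#'
#' @param panel Long tibble: `subject_id`, `group`, `analyte`, `timepoint`
#'   (`D0`/`D3`), `value` (as from [generate_biomarkers()]).
#' @param alpha Significance level.
#' @return List of two tibbles: `stress_effect` (one row per analyte) and
#'   `group_comparison` (one row per analyte, on change scores).
#' @export
analyze_biomarkers <- function(panel, alpha = 0.05) {
  wide <- tidyr::pivot_wider(panel,
    names_from = "timepoint", values_from = "value"
  )
  stress <- dplyr::group_modify(
    dplyr::group_by(wide, .data$analyte),
    function(df, key) paired_change_test(df$D0, df$D3, alpha)
  )
  stress <- dplyr::ungroup(stress)
  comp <- dplyr::group_modify(
    dplyr::group_by(
      dplyr::mutate(wide, change = .data$D3 - .data$D0),
      .data$analyte
    ),
    function(df, key) compare_groups(df, .data$change, .data$group, alpha = alpha)
  )
  comp <- dplyr::ungroup(comp)
  list(stress_effect = stress, group_comparison = comp)
}
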