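test_that("normality routing follows Shapiro-Wilk in both groups", {
  set.seed(1)
  x1 <- rnorm(10)
  x2 <- rnorm(10)
  expect_equal(normality_route(x1, x2), "student_t")
  expect_equal(
    shapiro.test(x1)$p.value >= 0.05 && shapiro.test(x2)$p.value >= 0.05,
    TRUE
  )
  # a heavily skewed group should usually trip the non-parametric route
  nonpar <- 0
  for (seed in 1:100) {
    set.seed(seed)
    a <- rnorm(10)
    b <- rlnorm(10, sdlog = 2)
    if (normality_route(a, b) == "mann_whitney_exact") nonpar <- nonpar + 1
  }
  expect_gt(nonpar / 100, 0.5)
  expect_warning(
    route <- normality_route(rep(1, 10), rnorm(10)),
    "undefined"
  )
  expect_equal(route, "mann_whitney_exact")
})

test_that("exact Mann-Whitney reproduces small worked examples", {
  r <- exact_mwu(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3) # 2 * (1 / choose(4, 2))
  expect_equal(r$method, "exact_dp")
  expect_equal(r$U + r$U2, 4)

  set.seed(4)
  x <- rnorm(8)
  near_identical <- x + rnorm(8, sd = 1e-6)
  expect_gt(exact_mwu(x, near_identical)$p, 0.5)
})

test_that("exact Mann-Whitney p equals full labeling enumeration", {
  enum_p <- function(x1, x2) {
    pooled <- c(x1, x2)
    n1 <- length(x1)
    r <- rank(pooled)
    u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combos <- combn(length(pooled), n1)
    us <- apply(combos, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
    min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
  }
  for (seed in 1:40) {
    set.seed(seed)
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    x1 <- rnorm(n1)
    x2 <- rnorm(n2)
    got <- exact_mwu(x1, x2)
    expect_equal(got$p, enum_p(x1, x2), tolerance = 1e-12)
    expect_equal(got$U + got$U2, n1 * n2)
    # cross-check against the reference implementation (no ties)
    ref <- wilcox.test(x1, x2, exact = TRUE)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    expect_equal(got$U, unname(ref$statistic))
  }
})

test_that("tied data use the exact mid-rank permutation distribution", {
  x1 <- c(1, 2, 2, 5)
  x2 <- c(2, 3, 4, 6)
  got <- exact_mwu(x1, x2)
  expect_true(got$ties)
  expect_equal(got$method, "exact_permutation")
  enum <- {
    pooled <- c(x1, x2)
    r <- rank(pooled)
    u_obs <- sum(r[1:4]) - 10
    us <- apply(combn(8, 4), 2, function(ix) sum(r[ix]) - 10)
    min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
  }
  expect_equal(got$p, enum, tolerance = 1e-12)

  # large tied samples fall back to the flagged normal approximation
  set.seed(2)
  big1 <- sample(1:5, 12, replace = TRUE)
  big2 <- sample(1:5, 12, replace = TRUE)
  expect_equal(exact_mwu(big1, big2)$method, "normal_approx")
})

test_that("Hedges' g reproduces the published height example", {
  g <- hedges_g(
    m1 = 181.13, s1 = 5.76, n1 = 10,
    m2 = 174.05, s2 = 6.67, n2 = 10
  )
  expect_equal(round(g$g, 2), 1.09)
  expect_equal(g$ci_low, 0.15, tolerance = 0.02)
  expect_equal(g$ci_high, 2.03, tolerance = 0.02)
})

test_that("Hedges' g is antisymmetric, location-scale invariant, zero at equality", {
  set.seed(9)
  x1 <- rnorm(10, 2)
  x2 <- rnorm(12)
  g12 <- hedges_g(x1, x2)
  g21 <- hedges_g(x2, x1)
  expect_equal(g12$g, -g21$g)
  expect_equal(g12$ci_low, -g21$ci_high)
  expect_equal(g12$ci_high, -g21$ci_low)
  scaled <- hedges_g(3 * x1 + 7, 3 * x2 + 7)
  expect_equal(scaled$g, g12$g, tolerance = 1e-12)
  expect_equal(hedges_g(m1 = 5, s1 = 1, n1 = 10, m2 = 5, s2 = 2, n2 = 10)$g, 0)
  expect_error(hedges_g(rep(1, 5), rep(1, 6)), "pooled SD")
})

test_that("compare_groups routes, summarises and attaches effect sizes", {
  set.seed(3)
  df <- tibble::tibble(
    value = c(rnorm(10, 3), rnorm(10, 0)),
    group = rep(c("high", "low"), each = 10)
  )
  res <- compare_groups(df, value, group)
  expect_equal(res$test, "student_t")
  expect_true(res$significant)
  expect_false(is.na(res$g))
  expect_equal(res$mean_high - res$mean_low,
    mean(df$value[1:10]) - mean(df$value[11:20]),
    tolerance = 1e-12
  )
  expect_true(is.na(res$median_high)) # parametric row reports mean +/- SD

  skewed <- tibble::tibble(
    value = c(rlnorm(10, sdlog = 2.5), rlnorm(10, 3, sdlog = 2.5)),
    group = rep(c("high", "low"), each = 10)
  )
  res2 <- compare_groups(skewed, value, group)
  if (res2$test == "mann_whitney_exact") {
    expect_false(is.na(res2$median_high))
    expect_true(is.na(res2$mean_high))
  }

  degen <- tibble::tibble(value = rep(1, 8), group = rep(c("high", "low"), 4))
  expect_equal(compare_groups(degen, value, group)$p, 1)
})

test_that("paired stress tests route and match sign enumeration", {
  pre <- c(5, 6, 7, 8, 9)
  expect_equal(paired_change_test(pre, pre)$p, 1)
  expect_match(paired_change_test(pre, pre)$flag, "zero")

  # exact signed-rank p for n = 5 against full 2^5 sign enumeration
  set.seed(13)
  for (i in 1:10) {
    d <- rnorm(5)
    post <- pre + d
    got <- paired_change_test(pre, post)
    if (got$test == "paired_t") next
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 5)))
    ws <- as.vector(signs %*% r)
    manual <- min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
    expect_equal(got$p, manual, tolerance = 1e-12)
  }

  # force the signed-rank route with a clearly non-normal difference set
  set.seed(14)
  pre2 <- rnorm(12)
  d2 <- c(seq(0.01, 0.1, length.out = 10), 50, 60)
  got2 <- paired_change_test(pre2, pre2 + d2)
  expect_match(got2$test, "wilcoxon")
  ref <- suppressWarnings(
    wilcox.test(pre2 + d2, pre2, paired = TRUE, exact = TRUE)
  )
  expect_equal(got2$p, ref$p.value, tolerance = 1e-10)
})

test_that("implanted biomarker declines are detected in most cohorts", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    subjects <- tibble::tibble(
      subject_id = sprintf("S%02d", 1:20),
      group = rep(c("high", "low"), each = 10)
    )
    panel <- generate_biomarkers(subjects, effect_spec())
    wide <- tidyr::pivot_wider(
      panel[panel$analyte == "IGF1", ],
      names_from = "timepoint", values_from = "value"
    )
    res <- paired_change_test(wide$D0, wide$D3)
    if (res$p < 0.05 && res$mean_change < 0) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.8)
})

test_that("biomarker panel analysis returns both test families", {
  set.seed(20)
  subjects <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:20),
    group = rep(c("high", "low"), each = 10)
  )
  panel <- generate_biomarkers(subjects, effect_spec())
  res <- analyze_biomarkers(panel)
  expect_setequal(
    res$stress_effect$analyte,
    c("Klotho", "BDNF", "NPY", "IGF1", "Cortisol")
  )
  expect_true(all(res$stress_effect$test %in%
    c("paired_t", "wilcoxon_signed_rank_exact", "wilcoxon_signed_rank_normal")))
  expect_true(all(res$group_comparison$test %in%
    c("student_t", "mann_whitney_exact")))
  expect_true(all(res$group_comparison$p >= 0 & res$group_comparison$p <= 1))
})
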