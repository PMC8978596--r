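test_that("a perfectly separable step is split at the midpoint", {
  y <- c(rep(0, 5), rep(10, 5))
  X <- cbind(x = 1:10)
  cfg <- cart_config(min_parent = 10, min_terminal = 5)
  sp <- best_split(y, X, cfg)
  expect_equal(sp$variable, "x")
  expect_equal(sp$threshold, 5.5)
  # children are pure: improvement equals the full outcome variance
  expect_equal(sp$improvement, mean((y - mean(y))^2))
  expect_equal(sp$improvement_norm, 1)
})

test_that("constant outcomes and inadmissible nodes return no split", {
  cfg <- cart_config(min_parent = 4, min_terminal = 2)
  expect_null(best_split(rep(5, 10), cbind(x = 1:10), cfg))
  expect_null(best_split(c(1, 2), cbind(x = 1:2), cfg)) # below min_parent
  expect_null(best_split(rnorm(10), cbind(x = rep(1, 10)), cfg)) # constant x
})

test_that("best_split agrees with an independent exhaustive enumerator", {
  cfg <- cart_config(min_parent = 4, min_terminal = 2, max_depth = 1)
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(8:12, 1)
    X <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- runif(n)
    got <- best_split(y, X, cfg)
    best <- NULL
    for (j in 1:3) {
      for (thr in sort(unique(X[, j]))[-n]) {
        l <- y[X[, j] <= thr]
        r <- y[X[, j] > thr]
        if (length(l) < 2 || length(r) < 2) next
        gain <- sum((y - mean(y))^2) -
          sum((l - mean(l))^2) - sum((r - mean(r))^2)
        if (is.null(best) || gain > best$gain + 1e-9 * sum((y - mean(y))^2)) {
          best <- list(j = j, thr = thr, gain = gain)
        }
      }
    }
    expect_equal(got$variable, c("a", "b", "c")[best$j])
    expect_equal(got$improvement * n, best$gain, tolerance = 1e-10)
  }
})

test_that("small samples yield a root-only tree with normalised risk 1", {
  set.seed(1)
  tr <- fit_tree(rnorm(6), cbind(x = rnorm(6)), cart_config())
  expect_equal(nrow(tr$nodes), 1)
  expect_equal(tr$normalized_risk, 1)
  expect_equal(splitter_variables(tr), character(0))
})

test_that("a bimodal outcome is recovered by a depth-1 split", {
  set.seed(2)
  y <- c(rnorm(10, 94.9, 3), rnorm(10, 70, 6))
  X <- cbind(
    signal = c(rnorm(10, 5), rnorm(10, 0)),
    noise = rnorm(20)
  )
  tr <- fit_tree(y, X, cart_config())
  expect_equal(splitter_variables(tr)[1], "signal")
  kids <- tr$nodes[tr$nodes$parent == 1 & !is.na(tr$nodes$parent), ]
  expect_equal(sort(kids$mean), sort(c(mean(y[1:10]), mean(y[11:20]))),
    tolerance = 1e-10
  )
})

test_that("the depth limit binds even when purer splits exist", {
  set.seed(3)
  n <- 64
  y <- as.numeric(1:n)
  X <- cbind(x = 1:n)
  tr <- fit_tree(y, X, cart_config(min_parent = 4, min_terminal = 2, max_depth = 3))
  expect_lte(max(tr$nodes$depth), 3)
})

test_that("accepted splits strictly decrease risk by the minimum improvement", {
  cfg <- cart_config(min_parent = 6, min_terminal = 3, max_depth = 3,
    min_improvement = 1e-4
  )
  for (seed in 1:20) {
    set.seed(seed + 100)
    n <- 24
    X <- matrix(rnorm(n * 4), n, 4,
      dimnames = list(NULL, paste0("v", 1:4))
    )
    y <- rnorm(n)
    tr <- fit_tree(y, X, cfg)
    splits <- tr$nodes[!tr$nodes$terminal, ]
    if (nrow(splits) > 0) {
      expect_true(all(splits$improvement_norm >= cfg$min_improvement))
    }
    # risk never exceeds the root risk
    expect_lte(tr$risk, tr$nodes$sse[1] / tr$n + 1e-12)
  }
})

test_that("tree risk matches an independent per-node SSE recomputation", {
  set.seed(5)
  n <- 30
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(n)
  cfg <- cart_config(min_parent = 6, min_terminal = 3)
  tr <- fit_tree(y, X, cfg)
  r <- tree_risk(tr, y)
  term <- tr$nodes[tr$nodes$terminal, ]
  manual <- sum(vapply(
    term$idx,
    function(ix) sum((y[ix] - mean(y[ix]))^2),
    numeric(1)
  )) / n
  expect_equal(r$risk, manual)
  expect_equal(r$normalized_risk, manual / mean((y - mean(y))^2))
  # pure children give zero risk
  pure <- fit_tree(
    c(rep(0, 5), rep(1, 5)), cbind(x = 1:10),
    cart_config(min_parent = 10, min_terminal = 5)
  )
  expect_equal(pure$risk, 0)
})

test_that("fitted trees are invariant to row permutation", {
  set.seed(6)
  n <- 25
  X <- matrix(sample(1:5, n * 3, replace = TRUE), n, 3,
    dimnames = list(NULL, c("a", "b", "c"))
  ) * 1.0
  y <- rnorm(n)
  cfg <- cart_config(min_parent = 6, min_terminal = 3)
  tr1 <- fit_tree(y, X, cfg)
  perm <- sample(n)
  tr2 <- fit_tree(y[perm], X[perm, ], cfg)
  expect_equal(
    tr1$nodes[, c("depth", "n", "mean", "split_variable", "threshold")],
    tr2$nodes[, c("depth", "n", "mean", "split_variable", "threshold")]
  )
  expect_equal(tr1$risk, tr2$risk)
})

test_that("whole fitted trees match the naive recursive oracle", {
  cfg <- cart_config(min_parent = 4, min_terminal = 2, max_depth = 3)
  for (seed in 1:60) {
    set.seed(seed + 500)
    n <- sample(8:12, 1)
    p <- sample(1:3, 1)
    X <- matrix(runif(n * p), n, p,
      dimnames = list(NULL, paste0("v", seq_len(p)))
    )
    y <- runif(n)
    tr <- fit_tree(y, X, cfg)
    orc <- oracle_fit_tree(y, X, cfg)
    got <- tree_splits_dfs(tr)
    want <- oracle_splits(orc)
    expect_equal(length(got), length(want))
    if (length(got) > 0) {
      expect_equal(
        vapply(got, `[[`, character(1), "variable"),
        vapply(want, `[[`, character(1), "variable")
      )
      expect_equal(
        vapply(got, `[[`, numeric(1), "threshold"),
        vapply(want, `[[`, numeric(1), "threshold"),
        tolerance = 1e-10
      )
    }
    expect_equal(tr$risk, oracle_risk(orc, n), tolerance = 1e-10)
  }
})

test_that("the first split agrees with rpart's anova tree", {
  skip_if_not_installed("rpart")
  set.seed(11)
  n <- 40
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 2 * (X$a > 0.3) + rnorm(n, sd = 0.3)
  tr <- fit_tree(y, as.matrix(X),
    cart_config(min_parent = 10, min_terminal = 5, max_depth = 1)
  )
  rp <- rpart::rpart(y ~ .,
    data = cbind(X, y), method = "anova",
    control = rpart::rpart.control(
      minsplit = 10, minbucket = 5, maxdepth = 1, cp = 0, xval = 0
    )
  )
  expect_equal(
    splitter_variables(tr),
    as.character(rp$frame$var[rp$frame$var != "<leaf>"])
  )
  expect_equal(
    tr$nodes$threshold[1],
    unname(rp$splits[1, "index"]),
    tolerance = 1e-8
  )
})

test_that("non-finite outcomes are rejected", {
  expect_error(fit_tree(c(1, NA, 3), cbind(x = 1:3)), "non-finite")
  expect_error(
    fit_tree(1:10, matrix(1:20, 10, 2)), # no column names
    "column names"
  )
})
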