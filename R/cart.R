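# Least-squared-deviation (LSD) regression trees, written from scratch:
# exhaustive binary splitting of a continuous outcome with the three
# stopping rules used for small-cohort feature selection, and SPSS-style
# risk estimates (within-terminal-node variance, normalised by the outcome
# variance). No pruning, no surrogate splits, no cross-validation.

#' Regression-tree settings
#'
#' Stopping rules for [fit_tree()]. Defaults are the small-cohort settings:
#' at least 5 observations in a terminal node, at least 10 in a node before
#' it may be split, and a maximum depth of three levels below the root.
#' `min_improvement` is the minimum decrease in normalised risk (risk /
#' outcome variance) a split must achieve to be accepted.
#'
#' @param min_terminal Minimum terminal-node size (>= 1).
#' @param min_parent Minimum node size before splitting (> `min_terminal`).
#' @param max_depth Maximum number of split levels below the root (>= 1).
#' @param min_improvement Minimum normalised-risk improvement per split.
#' @return List of class `ev_cart_config`.
#' @export
cart_config <- function(min_terminal = 5, min_parent = 10, max_depth = 3,
                        min_improvement = 1e-4) {
  stopifnot(
    min_terminal >= 1, min_parent > min_terminal, max_depth >= 1,
    min_improvement >= 0
  )
  structure(
    list(
      min_terminal = as.integer(min_terminal),
      min_parent = as.integer(min_parent),
      max_depth = as.integer(max_depth),
      min_improvement = min_improvement
    ),
    class = "ev_cart_config"
  )
}

pop_var <- function(y) mean((y - mean(y))^2)

node_sse <- function(y) sum((y - mean(y))^2)

#' Best least-squared-deviation split of a node
#'
#' Exhaustively searches every variable and every midpoint between
#' consecutive distinct sorted values, and returns the split maximising the
#' decrease in within-node sum of squared deviations, subject to both
#' children containing at least `min_terminal` observations. Returns `NULL`
#' if no admissible split exists or the best improvement, expressed on the
#' normalised-risk scale (divided by `n_root * var_root`), falls below
#' `cfg$min_improvement`.
#'
#' Ties are broken deterministically: within a variable towards the
#' smallest threshold, across variables towards the earliest column. The
#' search operates on sorted values, so the result is invariant to row
#' permutation.
#'
#' @param y Numeric outcome at the node.
#' @param X Numeric matrix (node rows x variables) with column names.
#' @param cfg An [`ev_cart_config`][cart_config].
#' @param n_root,var_root Size and population variance of the outcome at
#'   the tree root, used to normalise the improvement; default to the
#'   node's own, so a standalone call treats the node as a root.
#' @return List (`variable`, `threshold`, `improvement` on the risk scale
#'   `delta-SSE / n_root`, `improvement_norm`) or `NULL`.
#' @export
best_split <- function(y, X, cfg = cart_config(), n_root = length(y),
                       var_root = pop_var(y)) {
  n <- length(y)
  if (n < cfg$min_parent || var_root <= 0) {
    return(NULL)
  }
  X <- as.matrix(X)
  sse_parent <- node_sse(y)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ord <- order(x, y)
    xs <- x[ord]
    ys <- y[ord]
    cut_at <- which(xs[-n] < xs[-1]) # split after position k
    cut_at <- cut_at[cut_at >= cfg$min_terminal & (n - cut_at) >= cfg$min_terminal]
    if (length(cut_at) == 0) next
    c1 <- cumsum(ys)
    c2 <- cumsum(ys^2)
    sse_l <- c2[cut_at] - c1[cut_at]^2 / cut_at
    sse_r <- (c2[n] - c2[cut_at]) - (c1[n] - c1[cut_at])^2 / (n - cut_at)
    gain <- sse_parent - sse_l - sse_r
    k <- cut_at[which.max(gain)] # which.max takes the first = smallest threshold
    g <- max(gain)
    # earlier columns win ties; the tolerance absorbs float noise between
    # algebraically identical partitions computed along different paths
    if (is.null(best) || g > best$gain + 1e-9 * sse_parent) {
      best <- list(
        variable = colnames(X)[j],
        threshold = (xs[k] + xs[k + 1]) / 2,
        gain = g
      )
    }
  }
  if (is.null(best)) {
    return(NULL)
  }
  improvement_norm <- best$gain / (n_root * var_root)
  if (improvement_norm < cfg$min_improvement) {
    return(NULL)
  }
  list(
    variable = best$variable,
    threshold = best$threshold,
    improvement = best$gain / n_root,
    improvement_norm = improvement_norm
  )
}

#' Fit a least-squared-deviation regression tree
#'
#' Recursively applies [best_split()] breadth-first until the stopping rules
#' bind: a node is terminal when it is smaller than `min_parent`, sits at
#' `max_depth`, is pure, or admits no split improving the normalised risk
#' by at least `min_improvement`. Deterministic for fixed input (row order
#' does not matter; ties break by column order, then threshold).
#'
#' @param y Numeric outcome (finite, length >= 1), e.g. a resilience score.
#' @param X Numeric matrix or data frame of candidate split variables with
#'   unique column names; no missing values.
#' @param cfg An [`ev_cart_config`][cart_config].
#' @return Object of class `ev_tree`: list with `nodes` (tibble: `node_id`,
#'   `parent`, `depth`, `n`, `mean`, `sse`, `terminal`, `split_variable`,
#'   `threshold`, `improvement_norm`, `left`, `right`), `cfg`, `n`,
#'   `var_root`, `risk`, `normalized_risk`.
#' @export
fit_tree <- function(y, X, cfg = cart_config()) {
  if (any(!is.finite(y))) stop("non-finite values in outcome", call. = FALSE)
  X <- as.matrix(X)
  if (is.null(colnames(X)) || anyDuplicated(colnames(X))) {
    stop("X must have unique column names", call. = FALSE)
  }
  if (nrow(X) != length(y)) stop("nrow(X) != length(y)", call. = FALSE)
  if (anyNA(X)) stop("missing values in X; exclude such variables first", call. = FALSE)
  n_root <- length(y)
  var_root <- pop_var(y)

  nodes <- list()
  queue <- list(list(idx = seq_len(n_root), depth = 0L, parent = NA_integer_))
  while (length(queue) > 0) {
    item <- queue[[1]]
    queue <- queue[-1]
    idx <- item$idx
    id <- length(nodes) + 1L
    node <- list(
      node_id = id, parent = item$parent, depth = item$depth,
      n = length(idx), mean = mean(y[idx]), sse = node_sse(y[idx]),
      terminal = TRUE, split_variable = NA_character_,
      threshold = NA_real_, improvement_norm = NA_real_,
      left = NA_integer_, right = NA_integer_, idx = list(idx)
    )
    can_split <- length(idx) >= cfg$min_parent && item$depth < cfg$max_depth
    if (can_split && var_root > 0) {
      sp <- best_split(
        y[idx], X[idx, , drop = FALSE], cfg,
        n_root = n_root, var_root = var_root
      )
      if (!is.null(sp)) {
        go_left <- X[idx, sp$variable] <= sp$threshold
        node$terminal <- FALSE
        node$split_variable <- sp$variable
        node$threshold <- sp$threshold
        node$improvement_norm <- sp$improvement_norm
        node$left <- id + length(queue) + 1L
        node$right <- id + length(queue) + 2L
        queue <- c(queue, list(
          list(idx = idx[go_left], depth = item$depth + 1L, parent = id),
          list(idx = idx[!go_left], depth = item$depth + 1L, parent = id)
        ))
      }
    }
    nodes[[id]] <- node
  }
  nodes_df <- dplyr::bind_rows(lapply(nodes, tibble::as_tibble))
  tree <- structure(
    list(
      nodes = nodes_df, cfg = cfg, n = n_root, var_root = var_root,
      y_mean = mean(y)
    ),
    class = "ev_tree"
  )
  r <- tree_risk(tree)
  tree$risk <- r$risk
  tree$normalized_risk <- r$normalized_risk
  tree
}

#' Risk estimate of a fitted tree
#'
#' The risk estimate is the within-terminal-node variance of the outcome:
#' `(1/N) * sum over terminal nodes of the node's squared deviations from
#' its mean`. The normalised risk divides by the population variance
#' (1/N denominator) of the outcome, so a root-only tree has normalised
#' risk exactly 1 and pure terminal nodes give risk 0. A zero-variance
#' outcome leaves the normalised risk undefined (`NA`).
#'
#' @param tree An `ev_tree`.
#' @param y Optional outcome vector to recompute against; defaults to the
#'   node statistics stored at fit time.
#' @return List (`risk`, `normalized_risk`).
#' @export
tree_risk <- function(tree, y = NULL) {
  term <- tree$nodes[tree$nodes$terminal, ]
  if (is.null(y)) {
    risk <- sum(term$sse) / tree$n
    var_root <- tree$var_root
  } else {
    sse <- vapply(
      term$idx, function(ix) node_sse(y[ix]), numeric(1)
    )
    risk <- sum(sse) / length(y)
    var_root <- pop_var(y)
  }
  list(
    risk = risk,
    normalized_risk = if (var_root > 0) risk / var_root else NA_real_
  )
}

#' Variables used as splitters in a fitted tree
#'
#' Distinct variable ids used in any split, in first-use (breadth-first)
#' order. A root-only tree yields an empty character vector.
#'
#' @param tree An `ev_tree`.
#' @return Character vector.
#' @export
splitter_variables <- function(tree) {
  sv <- tree$nodes$split_variable[!tree$nodes$terminal]
  unique(sv)
}

#' @export
print.ev_tree <- function(x, ...) {
  cat(
    "<ev_tree> n=", x$n, ", ", sum(x$nodes$terminal), " terminal node(s), ",
    "depth ", max(x$nodes$depth), ", normalized risk ",
    format(x$normalized_risk, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a fitted regression tree
#'
#' One row per node with its size, outcome mean, within-node sum of squares
#' and split description.
#'
#' @param x An `ev_tree`.
#' @param ... Unused.
#' @return Tibble of nodes.
#' @export
tidy.ev_tree <- function(x, ...) {
  dplyr::select(x$nodes, -"idx")
}

#' One-row summary of a fitted regression tree
#'
#' @param x An `ev_tree`.
#' @param ... Unused.
#' @return Tibble: `n`, `n_nodes`, `n_terminal`, `depth`, `n_splitters`,
#'   `risk`, `normalized_risk`.
#' @export
glance.ev_tree <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_nodes = nrow(x$nodes),
    n_terminal = sum(x$nodes$terminal),
    depth = max(x$nodes$depth),
    n_splitters = length(splitter_variables(x)),
    risk = x$risk,
    normalized_risk = x$normalized_risk
  )
}

# JSON-serialisable representation of a tree (used in selection reports).
tree_to_list <- function(tree) {
  list(
    n = tree$n,
    risk = tree$risk,
    normalized_risk = tree$normalized_risk,
    splitters = as.list(splitter_variables(tree)),
    nodes = dplyr::select(tree$nodes, -"idx")
  )
}
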