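# Shared fixtures: all synthetic, built in code at test time.

# A small in-memory cohort: full data structure, desk-scale event counts.
small_cohort <- function(seed = 1, n_high = 10, n_low = 10,
                         events = c(150, 300), effects = effect_spec()) {
  generate_cohort(
    spec = cohort_spec(
      n_high = n_high, n_low = n_low,
      events_per_sample = events
    ),
    effects = effects,
    seed = seed
  )
}

# One synthetic event table with canonical columns.
small_events <- function(seed = 1, n = 200, timepoint = "D0",
                         group = "high", model = event_model(),
                         effects = effect_spec()) {
  set.seed(seed)
  m <- default_feature_manifest()
  u <- stats::setNames(as.list(rnorm(3, 0, model$sigma_subject)), m$channels)
  generate_event_sample(
    list(u = u, group = group, timepoint = timepoint),
    n_events = n, model = model, effects = effects
  )
}

# Hand-built 3-event toy table covering every required column, with known
# values for the channel of interest.
toy_events <- function() {
  m <- default_feature_manifest()
  n <- 3
  cols <- list(Area_BF = c(0.02, 0.5, 1.2))
  for (ch in m$channels) {
    cols[[paste0("SaturationCount_", ch)]] <- c(0L, 0L, 0L)
    for (f in m$features$feature[!m$features$derived]) {
      cols[[paste0(f, "_", ch)]] <- c(1, 2, 3)
    }
    cols[[paste0("RawMaxPixel_", ch)]] <- c(100, 80, 60)
    cols[[paste0("RawMinPixel_", ch)]] <- c(40, 20, 60)
    cols[[paste0("AspectRatio_", ch)]] <- c(0.5, 0.9, 1)
  }
  tibble::as_tibble(cols)
}

# Independent greedy-tree oracle: naive loops over every (variable,
# threshold) pair, recursing with the same stopping rules. Used to check
# fit_tree; shares no code with it.
oracle_fit_tree <- function(y, X, cfg) {
  n_root <- length(y)
  var_root <- mean((y - mean(y))^2)
  grow <- function(idx, depth) {
    node <- list(
      n = length(idx), mean = mean(y[idx]),
      sse = sum((y[idx] - mean(y[idx]))^2), terminal = TRUE
    )
    if (length(idx) < cfg$min_parent || depth >= cfg$max_depth ||
      var_root <= 0) {
      return(node)
    }
    best <- NULL
    for (j in seq_len(ncol(X))) {
      xv <- X[idx, j]
      for (thr in sort(unique(xv))) {
        l <- idx[xv <= thr]
        r <- idx[xv > thr]
        if (length(l) < cfg$min_terminal || length(r) < cfg$min_terminal) next
        gain <- node$sse -
          sum((y[l] - mean(y[l]))^2) - sum((y[r] - mean(y[r]))^2)
        # midpoint threshold equivalent to <= distinct-value cut
        mid <- (thr + min(xv[xv > thr])) / 2
        if (is.null(best) || gain > best$gain + 1e-9 * node$sse) {
          best <- list(
            var = colnames(X)[j], thr = mid, gain = gain, l = l, r = r
          )
        }
      }
    }
    if (is.null(best) || best$gain / (n_root * var_root) < cfg$min_improvement) {
      return(node)
    }
    node$terminal <- FALSE
    node$split_variable <- best$var
    node$threshold <- best$thr
    node$left <- grow(best$l, depth + 1)
    node$right <- grow(best$r, depth + 1)
    node
  }
  grow(seq_len(n_root), 0)
}

# Flatten an oracle tree to comparable (depth-first) split records.
oracle_splits <- function(node, out = list()) {
  if (node$terminal) {
    return(out)
  }
  out[[length(out) + 1]] <- list(
    variable = node$split_variable, threshold = node$threshold
  )
  out <- oracle_splits(node$left, out)
  oracle_splits(node$right, out)
}

oracle_risk <- function(node, n_root) {
  if (node$terminal) {
    return(node$sse / n_root)
  }
  oracle_risk(node$left, n_root) + oracle_risk(node$right, n_root)
}

# Depth-first split records of a fitted ev_tree, for comparison with the
# oracle.
tree_splits_dfs <- function(tree) {
  nodes <- tree$nodes
  walk <- function(id, out) {
    row <- nodes[nodes$node_id == id, ]
    if (row$terminal) {
      return(out)
    }
    out[[length(out) + 1]] <- list(
      variable = row$split_variable, threshold = row$threshold
    )
    out <- walk(row$left, out)
    walk(row$right, out)
  }
  walk(1L, list())
}
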