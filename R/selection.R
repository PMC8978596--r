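# Two-level regression-tree feature selection: per statistic, one tree per
# feature category feeds a final per-statistic tree; the final trees'
# splitters form the candidate set taken to group comparison.

#' Two-level regression-tree feature selection
#'
#' For each summary statistic (AVG, MED, SD), fits one regression tree per
#' feature category (size, shape, texture, signal strength) on that
#' category's variables against the continuous resilience score, collects
#' the splitter variables of the four category trees (level 1), fits a
#' final tree on their union (level 2), and takes the final tree's
#' splitters. The overall candidate set is the union of the three final
#' trees' splitters across statistics. The three per-statistic pipelines
#' never mix variables across statistics before that final union.
#'
#' Variables missing for any subject are excluded from the analysis
#' (listwise by variable: the trees have no surrogate splits), as are
#' zero-variance variables, which can never split.
#'
#' @param variables Long cohort variables table ([reduce_cohort()]) or a
#'   pre-built list as returned by [variables_wide()].
#' @param mode `"baseline"` (D0 values) or `"change"` (D3 - D0 scores);
#'   ignored when `variables` is already a `variables_wide()` list.
#' @param cfg An [`ev_cart_config`][cart_config].
#' @param manifest An `ev_manifest` (defines the variable universe and
#'   category map).
#' @param level1_scope `"all_splitters"` forwards every splitter of a
#'   category tree to the final tree (default); `"root_only"` forwards only
#'   the root splitter.
#' @return Object of class `ev_selection`: list with `candidates`
#'   (character), `per_statistic` (named list with `level1`, `final`
#'   splitters and trees), `trees` (all fitted trees), `mode`, `cfg`,
#'   `n_subjects`, `n_variables_used`.
#' @export
select_features <- function(variables, mode = c("baseline", "change"),
                            cfg = cart_config(),
                            manifest = default_feature_manifest(),
                            level1_scope = c("all_splitters", "root_only")) {
  mode <- match.arg(mode)
  level1_scope <- match.arg(level1_scope)
  wide <- if (is.list(variables) && !is.data.frame(variables) &&
    all(c("subjects", "X") %in% names(variables))) {
    variables
  } else {
    variables_wide(variables, mode)
  }
  y <- wide$subjects$cdrisc
  if (length(y) < cfg$min_parent) {
    stop("need at least min_parent (", cfg$min_parent, ") subjects; got ",
      length(y),
      call. = FALSE
    )
  }
  X <- wide$X
  complete <- colSums(is.na(X)) == 0
  X <- X[, complete, drop = FALSE]
  if (ncol(X) == 0) {
    stop("empty variable universe after missingness exclusion", call. = FALSE)
  }
  # constant variables can never split; dropping them may leave nothing to
  # select, which is a valid (empty) result, not an error
  nonconst <- apply(X, 2, function(v) any(v != v[1]))
  X <- X[, nonconst, drop = FALSE]
  if (ncol(X) == 0) {
    return(structure(
      list(
        candidates = character(0), per_statistic = list(), trees = list(),
        mode = mode, cfg = cfg, n_subjects = length(y), n_variables_used = 0L
      ),
      class = "ev_selection"
    ))
  }
  uni <- variable_universe(manifest)
  uni <- uni[match(colnames(X), uni$variable_id), ]

  categories <- c("size", "shape", "texture", "signal_strength")
  per_statistic <- list()
  trees <- list()
  for (s in manifest$statistics) {
    level1 <- character(0)
    cat_trees <- list()
    for (cat in categories) {
      ids <- uni$variable_id[uni$statistic == s & uni$category == cat]
      if (length(ids) == 0) next
      tr <- fit_tree(y, X[, ids, drop = FALSE], cfg)
      cat_trees[[cat]] <- tr
      trees[[paste(s, cat, sep = ".")]] <- tr
      sv <- splitter_variables(tr)
      if (level1_scope == "root_only") sv <- utils::head(sv, 1)
      level1 <- c(level1, sv)
    }
    level1 <- unique(level1)
    final_tree <- NULL
    final <- character(0)
    if (length(level1) > 0) {
      final_tree <- fit_tree(y, X[, level1, drop = FALSE], cfg)
      trees[[paste(s, "final", sep = ".")]] <- final_tree
      final <- splitter_variables(final_tree)
    }
    per_statistic[[s]] <- list(
      level1 = level1, final = final,
      category_trees = cat_trees, final_tree = final_tree
    )
  }
  candidates <- unique(unlist(lapply(per_statistic, `[[`, "final")))
  structure(
    list(
      candidates = candidates %||% character(0),
      per_statistic = per_statistic,
      trees = trees,
      mode = mode, cfg = cfg,
      n_subjects = length(y),
      n_variables_used = ncol(X)
    ),
    class = "ev_selection"
  )
}

#' @export
print.ev_selection <- function(x, ...) {
  cat(
    "<ev_selection> mode=", x$mode, ", ", x$n_subjects, " subjects, ",
    x$n_variables_used, " variables; ",
    length(x$candidates), " candidate(s)\n",
    sep = ""
  )
  if (length(x$candidates) > 0) {
    cat(paste0("  - ", x$candidates, collapse = "\n"), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a selection result
#'
#' One row per candidate variable with its parsed components and the
#' statistic pipeline(s) whose final tree selected it.
#'
#' @param x An `ev_selection`.
#' @param ... Unused.
#' @return Tibble: `variable_id`, `feature`, `channel`, `stratum`,
#'   `statistic`, `selected_by`.
#' @export
tidy.ev_selection <- function(x, ...) {
  if (length(x$candidates) == 0) {
    return(tibble::tibble(
      variable_id = character(0), feature = character(0),
      channel = character(0), stratum = character(0),
      statistic = character(0), selected_by = character(0)
    ))
  }
  by_stat <- vapply(
    x$candidates,
    function(v) {
      paste(
        names(Filter(function(p) v %in% p$final, x$per_statistic)),
        collapse = ","
      )
    },
    character(1)
  )
  dplyr::mutate(parse_variable_id(x$candidates), selected_by = unname(by_stat))
}

#' One-row summary of a selection result
#'
#' @param x An `ev_selection`.
#' @param ... Unused.
#' @return Tibble with candidate counts and final-tree normalised risks.
#' @export
glance.ev_selection <- function(x, ...) {
  nr <- vapply(
    c("AVG", "MED", "SD"),
    function(s) {
      p <- x$per_statistic[[s]]
      if (is.null(p) || is.null(p$final_tree)) {
        NA_real_
      } else {
        p$final_tree$normalized_risk
      }
    },
    numeric(1)
  )
  tibble::tibble(
    mode = x$mode,
    n_subjects = x$n_subjects,
    n_variables_used = x$n_variables_used,
    n_level1 = length(unique(unlist(lapply(x$per_statistic, `[[`, "level1")))),
    n_candidates = length(x$candidates),
    risk_AVG = nr[["AVG"]], risk_MED = nr[["MED"]], risk_SD = nr[["SD"]]
  )
}

# JSON-serialisable representation of a selection result.
selection_to_list <- function(sel) {
  list(
    mode = sel$mode,
    n_subjects = sel$n_subjects,
    n_variables_used = sel$n_variables_used,
    candidates = as.list(sel$candidates),
    per_statistic = lapply(sel$per_statistic, function(p) {
      list(
        level1 = as.list(p$level1),
        final = as.list(p$final),
        final_normalized_risk = if (is.null(p$final_tree)) {
          NA_real_
        } else {
          p$final_tree$normalized_risk
        }
      )
    }),
    trees = lapply(sel$trees, tree_to_list)
  )
}
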