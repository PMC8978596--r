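# Data reduction: collapse a per-event table to the per-sample variable
# profile (feature x channel x stratum x statistic), and D3 - D0 change
# scores.

#' Summarise a per-event table into the per-sample variable profile
#'
#' For every active (feature, channel) pair, computes the mean (`AVG`),
#' median (`MED`) and sample standard deviation (`SD`, n-1 denominator) of
#' the feature over the events of each size stratum (`small`, `medium`,
#' `large`) and over the whole sample (`total`). Under the default manifest
#' this yields 1116 variables: 31 features x 3 channels x 4 strata x 3
#' statistics.
#'
#' Strata are assigned from the brightfield-area column via [stratify()].
#' Missingness is data, not an error: a stratum with no events has `AVG` and
#' `MED` missing, and a stratum with fewer than two events has `SD` missing.
#' If the manifest carries a per-channel positivity gate, only events whose
#' channel intensity exceeds the gate contribute to that channel's
#' summaries.
#'
#' The input is expected to be already saturation-filtered
#' ([filter_events()]) and to carry the derived pixel-range columns
#' ([derive_pixel_range()]); use [reduce_sample()] for the full chain.
#'
#' @param events Filtered, derived event tibble.
#' @param manifest An `ev_manifest`.
#' @return Tibble with columns `variable_id`, `feature`, `category`,
#'   `channel`, `stratum`, `statistic`, `value`, one row per variable of the
#'   manifest universe, plus a `stratum_counts` attribute (named integer,
#'   event count per stratum over all channels).
#' @export
summarize_sample <- function(events, manifest = default_feature_manifest()) {
  uni <- variable_universe(manifest)
  area <- events[[manifest$area_column]]
  strat <- stratify(area, manifest)
  idx_by_stratum <- list(
    small = which(strat == "small"),
    medium = which(strat == "medium"),
    large = which(strat == "large"),
    total = seq_along(strat)
  )
  feats <- manifest$features$feature
  values <- numeric(0)
  for (ch in manifest$channels) {
    cols <- feature_column(feats, ch)
    missing <- setdiff(cols, names(events))
    if (length(missing) > 0) {
      stop("feature column(s) absent: ", paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    rows <- seq_len(nrow(events))
    gate <- manifest$positivity_gate
    if (!is.null(gate) && ch %in% names(gate)) {
      rows <- rows[events[[feature_column("Intensity", ch)]] > gate[[ch]]]
    }
    X <- as.matrix(events[rows, cols])
    for (stratum in ev_strata()) {
      idx <- intersect(idx_by_stratum[[stratum]], rows)
      sub <- X[match(idx, rows), , drop = FALSE]
      n <- nrow(sub)
      if (n == 0) {
        avg <- med <- sdv <- rep(NA_real_, length(feats))
      } else {
        avg <- colMeans(sub)
        med <- apply(sub, 2, stats::median)
        if (n >= 2) {
          sdv <- sqrt(pmax(colSums(sub^2) - n * avg^2, 0) / (n - 1))
        } else {
          sdv <- rep(NA_real_, length(feats))
        }
      }
      values[variable_id(feats, ch, stratum, "AVG")] <- avg
      values[variable_id(feats, ch, stratum, "MED")] <- med
      values[variable_id(feats, ch, stratum, "SD")] <- sdv
    }
  }
  out <- dplyr::mutate(uni, value = unname(values[.data$variable_id]))
  attr(out, "stratum_counts") <- vapply(idx_by_stratum, length, integer(1))
  out
}

#' Full single-sample reduction chain
#'
#' Convenience wrapper: [filter_events()] then [derive_pixel_range()] then
#' [summarize_sample()].
#'
#' @inheritParams summarize_sample
#' @return See [summarize_sample()]; additionally carries the saturation
#'   removal count as attribute `n_removed`.
#' @export
reduce_sample <- function(events, manifest = default_feature_manifest()) {
  filtered <- filter_events(events, manifest)
  derived <- derive_pixel_range(filtered, manifest)
  out <- summarize_sample(derived, manifest)
  attr(out, "n_removed") <- attr(filtered, "n_removed")
  out
}

#' Reduce a whole cohort to a long variables table
#'
#' Applies the per-sample reduction to every (subject, timepoint) event
#' table of a cohort and binds the results into the long per-sample
#' variables table used by selection and statistics.
#'
#' @param cohort A cohort as returned by [generate_cohort()] or
#'   [read_cohort()]: a list with `manifest` (tibble with `subject_id`,
#'   `group`, `cdrisc`, `timepoint` and either `event_table_path` or an
#'   `events` list-column of in-memory tables).
#' @param manifest An `ev_manifest`.
#' @return Tibble: `subject_id`, `group`, `cdrisc`, `timepoint`,
#'   `variable_id`, `value`.
#' @export
reduce_cohort <- function(cohort, manifest = default_feature_manifest()) {
  man <- cohort$manifest
  purrr::map_dfr(
    seq_len(nrow(man)),
    function(i) {
      row <- man[i, ]
      events <- if ("events" %in% names(man)) {
        row$events[[1]]
      } else {
        read_event_table(row$event_table_path, manifest)
      }
      prof <- reduce_sample(events, manifest)
      tibble::tibble(
        subject_id = row$subject_id,
        group = row$group,
        cdrisc = row$cdrisc,
        timepoint = row$timepoint,
        variable_id = prof$variable_id,
        value = prof$value
      )
    }
  )
}

#' Change scores between two per-sample profiles
#'
#' Elementwise `d3 - d0` over a matched pair of variable profiles (the
#' peak-stress minus baseline change score). The two profiles must cover the
#' same variable ids; the result is missing wherever either input is
#' missing.
#'
#' @param d0,d3 Profiles as returned by [summarize_sample()] (tibbles with
#'   `variable_id` and `value`) or named numeric vectors.
#' @return Same form as the inputs, with `value` (or the vector) holding
#'   `d3 - d0`.
#' @export
change_scores <- function(d0, d3) {
  v0 <- as_profile_vector(d0)
  v3 <- as_profile_vector(d3)
  if (length(v0) != length(v3) || !setequal(names(v0), names(v3))) {
    stop("change_scores: variable-id sets differ between D0 and D3",
      call. = FALSE
    )
  }
  delta <- v3[names(v0)] - v0
  if (is.data.frame(d0)) {
    dplyr::mutate(d0, value = unname(delta[d0$variable_id]))
  } else {
    delta
  }
}

as_profile_vector <- function(x) {
  if (is.data.frame(x)) {
    stats::setNames(x$value, x$variable_id)
  } else if (is.numeric(x) && !is.null(names(x))) {
    x
  } else {
    stop("profile must be a summarize_sample() tibble or a named numeric vector",
      call. = FALSE
    )
  }
}

#' Cohort-level change scores
#'
#' Per-subject D3 - D0 change scores from a long cohort variables table.
#' Subjects lacking either timepoint are excluded.
#'
#' @param variables Long table from [reduce_cohort()].
#' @return Tibble: `subject_id`, `group`, `cdrisc`, `variable_id`, `value`
#'   (the change score).
#' @export
cohort_change_scores <- function(variables) {
  wide <- tidyr::pivot_wider(variables,
    names_from = "timepoint", values_from = "value"
  )
  if (!all(c("D0", "D3") %in% names(wide))) {
    stop("cohort variables must contain both D0 and D3 timepoints",
      call. = FALSE
    )
  }
  complete <- dplyr::group_by(wide, .data$subject_id)
  complete <- dplyr::filter(
    complete,
    !all(is.na(.data$D0)) && !all(is.na(.data$D3))
  )
  complete <- dplyr::ungroup(complete)
  dplyr::transmute(complete,
    subject_id = .data$subject_id, group = .data$group,
    cdrisc = .data$cdrisc, variable_id = .data$variable_id,
    value = .data$D3 - .data$D0
  )
}

#' Wide subject-by-variable matrix for one analysis mode
#'
#' @param variables Long cohort table ([reduce_cohort()]).
#' @param mode `"baseline"` (D0 values) or `"change"` (D3 - D0 scores).
#' @return List: `subjects` (tibble `subject_id`, `group`, `cdrisc`) and `X`
#'   (numeric matrix, subjects x variable ids, in universe order).
#' @export
variables_wide <- function(variables, mode = c("baseline", "change")) {
  mode <- match.arg(mode)
  long <- if (mode == "baseline") {
    dplyr::select(
      dplyr::filter(variables, .data$timepoint == "D0"),
      "subject_id", "group", "cdrisc", "variable_id", "value"
    )
  } else {
    cohort_change_scores(variables)
  }
  wide <- tidyr::pivot_wider(long,
    names_from = "variable_id", values_from = "value"
  )
  subjects <- wide[, c("subject_id", "group", "cdrisc")]
  X <- as.matrix(wide[, setdiff(names(wide), names(subjects))])
  rownames(X) <- subjects$subject_id
  list(subjects = subjects, X = X)
}

#' Write / read the long variables table
#'
#' Tidy TSV with one row per (subject, timepoint, variable): columns
#' `subject_id`, `group`, `cdrisc`, `timepoint`, `feature`, `channel`,
#' `stratum`, `statistic`, `value`. Reading the written file restores the
#' [reduce_cohort()] table exactly (round trip).
#'
#' @param variables Long cohort table.
#' @param path TSV path.
#' @return `write_variables_table()`: `path` invisibly;
#'   `read_variables_table()`: the long table.
#' @export
write_variables_table <- function(variables, path) {
  out <- dplyr::bind_cols(
    variables[, c("subject_id", "group", "cdrisc", "timepoint")],
    parse_variable_id(variables$variable_id)[, c("feature", "channel", "stratum", "statistic")],
    variables[, "value"]
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_variables_table
#' @export
read_variables_table <- function(path) {
  raw <- readr::read_tsv(path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      group = readr::col_character(),
      timepoint = readr::col_character(),
      feature = readr::col_character(),
      channel = readr::col_character(),
      stratum = readr::col_character(),
      statistic = readr::col_character(),
      cdrisc = readr::col_double(),
      value = readr::col_double()
    )
  )
  dplyr::transmute(raw,
    subject_id = .data$subject_id, group = .data$group,
    cdrisc = .data$cdrisc, timepoint = .data$timepoint,
    variable_id = variable_id(
      .data$feature, .data$channel, .data$stratum, .data$statistic
    ),
    value = .data$value
  )
}
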