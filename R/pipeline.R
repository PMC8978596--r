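# Pipeline orchestration: cohort manifests, the reduction -> selection ->
# comparison -> ROC chain for baseline and/or change-score analyses, and
# tidy TSV / JSON report output.

#' Pipeline configuration
#'
#' Collects everything one run needs. `cohort` may be an in-memory
#' [`ev_cohort`][generate_cohort] or `NULL` with `manifest_path` pointing at
#' a cohort manifest TSV/YAML on disk.
#'
#' @param cohort Optional `ev_cohort`.
#' @param manifest_path Optional path to a cohort manifest (TSV or YAML).
#' @param feature_manifest An `ev_manifest`.
#' @param cart An [`ev_cart_config`][cart_config].
#' @param alpha Significance level for normality routing, group tests and
#'   the ROC gate.
#' @param mode `"baseline"`, `"change"` or `"both"`.
#' @param level1_scope Passed to [select_features()].
#' @param out_dir Optional output directory; when set, reports are written.
#' @param seed Integer recorded in provenance (and used by the `simulate`
#'   entry point).
#' @return List of class `ev_pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, manifest_path = NULL,
                            feature_manifest = default_feature_manifest(),
                            cart = cart_config(), alpha = 0.05,
                            mode = c("change", "baseline", "both"),
                            level1_scope = "all_splitters",
                            out_dir = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(cohort) && is.null(manifest_path)) {
    stop("either an in-memory cohort or a manifest_path is required",
      call. = FALSE
    )
  }
  stopifnot(cart$min_parent > cart$min_terminal)
  structure(
    list(
      cohort = cohort, manifest_path = manifest_path,
      feature_manifest = feature_manifest, cart = cart, alpha = alpha,
      mode = mode, level1_scope = level1_scope,
      out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "ev_pipeline_config"
  )
}

#' Read and validate a cohort manifest
#'
#' Accepts a TSV (columns `subject_id`, `group`, `cdrisc`, `timepoint`,
#' `event_table_path`) or a YAML file with a `subjects` list carrying the
#' same fields (with per-timepoint paths). Errors on duplicate
#' (subject, timepoint) pairs, unknown group labels and scores outside
#' [0, 100]; warns when a group label is inconsistent with the score rule
#' (high > 90, low <= 79) and when a subject lacks one of the two
#' timepoints (such subjects are excluded from change-score analyses).
#'
#' @param path Manifest file path.
#' @return Tibble: `subject_id`, `group`, `cdrisc`, `timepoint`,
#'   `event_table_path`.
#' @export
read_cohort_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  if (file.info(path)$size == 0) stop("empty manifest: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    doc <- yaml::read_yaml(path)
    if (is.null(doc$subjects) || length(doc$subjects) == 0) {
      stop("empty manifest: ", path, call. = FALSE)
    }
    man <- purrr::map_dfr(doc$subjects, function(s) {
      tps <- names(s$event_tables)
      tibble::tibble(
        subject_id = s$subject_id, group = s$group,
        cdrisc = as.numeric(s$cdrisc), timepoint = tps,
        event_table_path = unlist(s$event_tables, use.names = FALSE)
      )
    })
  } else {
    man <- readr::read_tsv(path,
      show_col_types = FALSE, progress = FALSE,
      col_types = readr::cols(
        subject_id = readr::col_character(),
        group = readr::col_character(),
        cdrisc = readr::col_double(),
        timepoint = readr::col_character(),
        event_table_path = readr::col_character()
      )
    )
  }
  required <- c("subject_id", "group", "cdrisc", "timepoint", "event_table_path")
  missing <- setdiff(required, names(man))
  if (length(missing) > 0) {
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(man) == 0) stop("empty manifest: ", path, call. = FALSE)
  if (anyDuplicated(man[, c("subject_id", "timepoint")]) > 0) {
    stop("duplicate subject/timepoint entries in manifest", call. = FALSE)
  }
  if (!all(man$group %in% c("high", "low"))) {
    stop("unknown group label(s): ",
      paste(setdiff(unique(man$group), c("high", "low")), collapse = ", "),
      call. = FALSE
    )
  }
  if (any(man$cdrisc < 0 | man$cdrisc > 100)) {
    stop("resilience scores must lie in [0, 100]", call. = FALSE)
  }
  bad <- (man$group == "high" & man$cdrisc <= 90) |
    (man$group == "low" & man$cdrisc > 79)
  if (any(bad)) {
    warning(
      "group label inconsistent with score rule (high > 90, low <= 79) for: ",
      paste(unique(man$subject_id[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  tp_count <- table(man$subject_id)
  incomplete <- names(tp_count)[tp_count < 2]
  if (length(incomplete) > 0) {
    warning(
      "subject(s) lacking both timepoints (excluded from change-score ",
      "analyses): ", paste(incomplete, collapse = ", "),
      call. = FALSE
    )
  }
  man[, required]
}

#' Read an on-disk cohort
#'
#' Wraps a validated manifest (plus optional biomarker and NTA panels) into
#' the cohort list [reduce_cohort()] and [run_pipeline()] consume; event
#' tables are read lazily during reduction.
#'
#' @param manifest_path Cohort manifest path ([read_cohort_manifest()]).
#' @param biomarkers_path,nta_path Optional TSV panels.
#' @return List of class `ev_cohort` (paths variant).
#' @export
read_cohort <- function(manifest_path, biomarkers_path = NULL,
                        nta_path = NULL) {
  man <- read_cohort_manifest(manifest_path)
  read_panel <- function(p) {
    if (is.null(p) || !file.exists(p)) {
      return(NULL)
    }
    readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
  }
  structure(
    list(
      manifest = man,
      biomarkers = read_panel(biomarkers_path),
      nta = read_panel(nta_path)
    ),
    class = "ev_cohort"
  )
}

config_hash <- function(config) {
  desc <- list(
    feature_manifest = list(
      features = config$feature_manifest$features,
      channels = config$feature_manifest$channels,
      cutoffs = c(
        config$feature_manifest$cutoff_small,
        config$feature_manifest$cutoff_large
      )
    ),
    cart = unclass(config$cart), alpha = config$alpha,
    mode = config$mode, level1_scope = config$level1_scope,
    seed = config$seed
  )
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(desc, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

analyze_mode <- function(variables, mode, config) {
  wide <- variables_wide(variables, mode)
  sel <- select_features(wide,
    mode = mode, cfg = config$cart,
    manifest = config$feature_manifest,
    level1_scope = config$level1_scope
  )
  comparisons <- purrr::map_dfr(sel$candidates, function(v) {
    df <- tibble::tibble(
      value = wide$X[, v], group = wide$subjects$group
    )
    res <- compare_groups(df, .data$value, .data$group, alpha = config$alpha)
    dplyr::bind_cols(tibble::tibble(variable_id = v, mode = mode), res)
  })
  roc_vars <- if (nrow(comparisons) > 0) {
    comparisons$variable_id[comparisons$significant]
  } else {
    character(0)
  }
  roc <- purrr::map_dfr(roc_vars, function(v) {
    df <- tibble::tibble(score = wide$X[, v], group = wide$subjects$group)
    dplyr::bind_cols(
      tibble::tibble(variable_id = v, mode = mode),
      roc_analysis(df, .data$score, .data$group)
    )
  })
  list(selection = sel, comparisons = comparisons, roc = roc)
}

#' Run the full analysis pipeline
#'
#' Reduction to per-sample profiles, two-level regression-tree selection,
#' normality-routed group comparisons of the candidates, and ROC analysis
#' of every significant candidate -- for the baseline values, the D3 - D0
#' change scores, or both. If the cohort carries biomarker or NTA panels,
#' paired stress-effect tests and group comparisons of their change scores
#' are included. With `out_dir` set, writes `variables.tsv`,
#' `selection.json`, `comparisons.tsv`, `roc.tsv` and `report.json`.
#'
#' For a fixed configuration, seed and inputs the returned report (and the
#' written files) are identical across runs.
#'
#' @param config An [`ev_pipeline_config`][pipeline_config].
#' @return Object of class `ev_report`: list with `variables` (long table),
#'   per-mode `selection`/`comparisons`/`roc`, optional `biomarkers` and
#'   `nta` analyses, and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ev_pipeline_config"))
  cohort <- config$cohort
  if (is.null(cohort)) cohort <- read_cohort(config$manifest_path)
  variables <- tryCatch(
    reduce_cohort(cohort, config$feature_manifest),
    error = function(e) {
      stop("stage reduction failed: ", conditionMessage(e), call. = FALSE)
    }
  )
  modes <- if (config$mode == "both") c("baseline", "change") else config$mode
  analyses <- list()
  for (m in modes) {
    analyses[[m]] <- tryCatch(
      analyze_mode(variables, m, config),
      error = function(e) {
        stop("stage ", m, "-analysis failed: ", conditionMessage(e),
          call. = FALSE
        )
      }
    )
  }
  biomarkers <- NULL
  if (!is.null(cohort$biomarkers)) {
    biomarkers <- analyze_biomarkers(cohort$biomarkers, config$alpha)
  }
  nta <- NULL
  if (!is.null(cohort$nta)) {
    long <- tidyr::pivot_longer(cohort$nta, c("concentration", "mean_size"),
      names_to = "analyte", values_to = "value"
    )
    nta <- analyze_biomarkers(
      long[, c("subject_id", "group", "analyte", "timepoint", "value")],
      config$alpha
    )
  }
  report <- structure(
    list(
      variables = variables,
      analyses = analyses,
      biomarkers = biomarkers,
      nta = nta,
      provenance = list(
        package_version = as.character(utils::packageVersion("evresilience")),
        config_hash = config_hash(config),
        seed = config$seed,
        alpha = config$alpha,
        mode = config$mode,
        n_subjects = length(unique(variables$subject_id)),
        n_samples = nrow(dplyr::distinct(
          variables[, c("subject_id", "timepoint")]
        ))
      )
    ),
    class = "ev_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' Tidy TSVs plus a single JSON summary: `variables.tsv` (long per-sample
#' profile), `selection.json` (all trees and candidate sets per mode),
#' `comparisons.tsv`, `roc.tsv` and `report.json`. Every reported p-value
#' row carries the test that produced it.
#'
#' @param report An `ev_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_variables_table(report$variables, file.path(dir, "variables.tsv"))
  jsonlite::write_json(
    lapply(report$analyses, function(a) selection_to_list(a$selection)),
    file.path(dir, "selection.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  comparisons <- purrr::map_dfr(report$analyses, "comparisons")
  roc <- purrr::map_dfr(report$analyses, "roc")
  readr::write_tsv(comparisons, file.path(dir, "comparisons.tsv"),
    progress = FALSE
  )
  readr::write_tsv(roc, file.path(dir, "roc.tsv"), progress = FALSE)
  summary <- list(
    provenance = report$provenance,
    candidates = lapply(report$analyses, function(a) a$selection$candidates),
    comparisons = comparisons,
    roc = roc,
    biomarkers = report$biomarkers,
    nta = report$nta
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' @export
print.ev_report <- function(x, ...) {
  cat("<ev_report> modes: ", paste(names(x$analyses), collapse = ", "),
    "; ", x$provenance$n_subjects, " subjects\n",
    sep = ""
  )
  for (m in names(x$analyses)) {
    a <- x$analyses[[m]]
    cat(
      "  ", m, ": ", length(a$selection$candidates), " candidate(s), ",
      sum(a$comparisons$significant %||% logical(0)), " significant, ",
      nrow(a$roc), " ROC analysis(es)\n",
      sep = ""
    )
  }
  invisible(x)
}
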