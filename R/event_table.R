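# Per-event tables: reading vendor CSV exports, saturation filtering, and the
# derived pixel-range feature.

#' Read a per-event IFC feature export
#'
#' Reads one sample's per-object feature table (one CSV per sample, one row
#' per detected object) and resolves its columns against a feature manifest.
#' Column names are matched to canonical `feature_channel` names, to the
#' brightfield-area column, and to the per-channel saturation-count columns,
#' consulting the manifest's alias map so differently templated exports
#' still resolve. Columns that resolve to excluded or unknown features are
#' dropped with a warning; missing required columns are an error.
#'
#' @param path Path to a CSV with a header row and numeric feature values.
#' @param manifest An [`ev_manifest`][default_feature_manifest].
#' @return A tibble of class `ev_events` with one row per event, canonical
#'   column names, and attributes `manifest` and `sample_path`.
#' @export
read_event_table <- function(path, manifest = default_feature_manifest()) {
  if (!file.exists(path)) stop("event table not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(raw) <- resolve_aliases(names(raw), manifest)
  required <- c(
    manifest$area_column, manifest$saturation_columns,
    measured_columns(manifest)
  )
  missing <- setdiff(required, names(raw))
  if (manifest$area_column %in% missing) {
    stop("no resolvable brightfield area column in ", path, call. = FALSE)
  }
  if (length(missing) > 0) {
    stop(
      "required feature absent from ", path, ": ",
      paste(utils::head(missing, 5), collapse = ", "),
      if (length(missing) > 5) " ...",
      call. = FALSE
    )
  }
  extra <- setdiff(names(raw), c(required, active_columns(manifest)))
  if (length(extra) > 0) {
    warning(
      "ignoring ", length(extra), " unresolvable column(s): ",
      paste(utils::head(extra, 5), collapse = ", "),
      call. = FALSE
    )
  }
  tab <- raw[, intersect(names(raw), required)]
  bad <- names(tab)[!vapply(tab, is.numeric, logical(1))]
  if (length(bad) > 0) {
    stop("non-numeric values in feature column(s): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  validate_event_table(tab, manifest)
  new_event_table(tab, manifest, sample_path = path)
}

resolve_aliases <- function(nms, manifest) {
  for (canonical in names(manifest$aliases)) {
    hits <- nms %in% manifest$aliases[[canonical]]
    if (any(hits) && !(canonical %in% nms)) nms[which(hits)[1]] <- canonical
  }
  nms
}

new_event_table <- function(tab, manifest, sample_path = NA_character_) {
  out <- tibble::as_tibble(tab)
  attr(out, "manifest") <- manifest
  attr(out, "sample_path") <- sample_path
  class(out) <- c("ev_events", class(out))
  out
}

validate_event_table <- function(tab, manifest) {
  area <- tab[[manifest$area_column]]
  if (any(!is.finite(area) | area <= 0)) {
    stop("brightfield area must be positive for every event", call. = FALSE)
  }
  for (sc in intersect(manifest$saturation_columns, names(tab))) {
    v <- tab[[sc]]
    if (any(v < 0 | v != round(v))) {
      stop("saturation counts must be non-negative integers (", sc, ")",
        call. = FALSE
      )
    }
  }
  invisible(tab)
}

#' Write a per-event table as a vendor-style CSV
#'
#' Inverse of [read_event_table()]; used by the synthetic generator to emit
#' files in the same format the reader consumes.
#'
#' @param events Event tibble (canonical column names).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  readr::write_csv(tibble::as_tibble(events), path, progress = FALSE)
  invisible(path)
}

#' Remove saturated events
#'
#' Drops every object with a saturation count of 1 or more in any of the
#' manifest's fluorescence channels; such objects are treated as possible
#' debris or fluorochrome aggregates rather than vesicles. The number of
#' events removed is recorded in the `n_removed` attribute and reported via
#' `message()`; a sample losing all its events is flagged with a warning.
#'
#' @param events Event tibble containing the per-channel saturation-count
#'   columns.
#' @param manifest An `ev_manifest`.
#' @param quiet Suppress the removal-count message.
#' @return Filtered event tibble with saturation-count and excluded columns
#'   dropped.
#' @export
filter_events <- function(events, manifest = default_feature_manifest(),
                          quiet = TRUE) {
  sat_cols <- manifest$saturation_columns
  missing <- setdiff(sat_cols, names(events))
  if (length(missing) > 0) {
    stop("saturation-count column(s) absent: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  sat <- as.matrix(events[, sat_cols])
  keep <- rowSums(sat >= 1) == 0
  n_removed <- sum(!keep)
  if (!quiet) {
    message(
      "filter_events: removed ", n_removed, " of ", length(keep),
      " events with saturation count >= 1"
    )
  }
  drop_cols <- c(
    sat_cols,
    as.vector(outer(manifest$excluded$feature, manifest$channels, feature_column)),
    manifest$excluded$feature
  )
  out <- events[keep, setdiff(names(events), drop_cols)]
  if (nrow(out) == 0) {
    warning("all events removed by saturation filter; sample flagged",
      call. = FALSE
    )
  }
  attr(out, "n_removed") <- n_removed
  attr(out, "manifest") <- attr(events, "manifest")
  attr(out, "sample_path") <- attr(events, "sample_path")
  out
}

#' Derive the per-channel pixel-range feature
#'
#' Adds, for every channel, `PixelRange = RawMaxPixel - RawMinPixel`, the
#' spread of raw pixel intensities within an object's image. Raw max below
#' raw min violates the event-table invariant and is an error.
#'
#' @inheritParams filter_events
#' @return Event tibble with one `PixelRange_<channel>` column per channel.
#' @export
derive_pixel_range <- function(events, manifest = default_feature_manifest()) {
  for (ch in manifest$channels) {
    hi <- events[[feature_column("RawMaxPixel", ch)]]
    lo <- events[[feature_column("RawMinPixel", ch)]]
    if (is.null(hi) || is.null(lo)) {
      stop("RawMaxPixel/RawMinPixel absent for channel ", ch, call. = FALSE)
    }
    if (any(hi < lo)) {
      stop("RawMaxPixel < RawMinPixel in channel ", ch,
        ": event-table invariant violated",
        call. = FALSE
      )
    }
    events[[feature_column("PixelRange", ch)]] <- hi - lo
  }
  events
}
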