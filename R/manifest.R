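# Feature manifest: the catalogue of per-object IFC features that survive data
# reduction, the fluorescence channels they are measured in, the size-stratum
# cutoffs, and the summary statistics computed per sample.

#' Default feature manifest
#'
#' Builds the manifest describing how per-event imaging-flow-cytometry (IFC)
#' exports are reduced to the per-sample variable profile. The default
#' manifest retains 31 features across four categories -- 8 size, 1 shape,
#' 6 texture, and 16 signal-strength features -- each measured in three
#' fluorescence channels (CD63, VAMP3, THSD1) and summarised in four size
#' strata (small, medium, large, total) by three statistics (AVG, MED, SD).
#' That yields 96 size, 12 shape, 72 texture and 192 signal-strength
#' variables per statistic: 372 variables per statistic and 1116 per sample.
#'
#' Vendor exports carry many more columns than are analysed; the manifest
#' also records features excluded up front as redundant or irrelevant, and an
#' alias map so differently templated exports resolve to canonical names.
#'
#' Size-stratum cutoffs default to the brightfield areas of circles of
#' diameter 200 nm and 1000 nm (`pi * 0.1^2` and `pi * 0.5^2` square microns,
#' i.e. 0.031416 and 0.785398), the conventional diameter boundaries between
#' exosomes, microvesicles and apoptotic bodies.
#'
#' @param channels Character vector of fluorescence channel names.
#' @param cutoff_small,cutoff_large Brightfield-area cutoffs in square
#'   microns separating small/medium and medium/large events. Must satisfy
#'   `cutoff_small < cutoff_large`.
#' @param positivity_gate Optional named numeric vector of per-channel
#'   intensity thresholds; events at or below a channel's threshold are
#'   dropped from that channel's summaries. Default `NULL`: no gate, every
#'   retained event contributes to every channel.
#'
#' @return An object of class `ev_manifest`: a list with elements `features`
#'   (tibble: `feature`, `category`, `derived`), `excluded` (tibble:
#'   `feature`, `reason`), `channels`, `statistics`, `cutoff_small`,
#'   `cutoff_large`, `area_column`, `saturation_columns`, `aliases`, and
#'   `positivity_gate`.
#'
#' @examples
#' m <- default_feature_manifest()
#' nrow(m$features) # 31 active features
#' variable_universe(m) # 1116 variable ids
#' @export
default_feature_manifest <- function(channels = c("CD63", "VAMP3", "THSD1"),
                                     cutoff_small = 0.031416,
                                     cutoff_large = 0.785398,
                                     positivity_gate = NULL) {
  stopifnot(cutoff_small < cutoff_large, cutoff_small > 0)
  features <- tibble::tribble(
    ~feature,                 ~category,        ~derived,
    "Area",                   "size",            FALSE,
    "Diameter",               "size",            FALSE,
    "Length",                 "size",            FALSE,
    "Width",                  "size",            FALSE,
    "Height",                 "size",            FALSE,
    "Perimeter",              "size",            FALSE,
    "MajorAxis",              "size",            FALSE,
    "MinorAxis",              "size",            FALSE,
    "AspectRatio",            "shape",           FALSE,
    "BrightDetailIntensity",  "texture",         FALSE,
    "BrightDetailSimilarity", "texture",         FALSE,
    "Contrast",               "texture",         FALSE,
    "GradientRMS",            "texture",         FALSE,
    "Modulation",             "texture",         FALSE,
    "StdDev",                 "texture",         FALSE,
    "Intensity",              "signal_strength", FALSE,
    "RawIntensity",           "signal_strength", FALSE,
    "MaxPixel",               "signal_strength", FALSE,
    "MinPixel",               "signal_strength", FALSE,
    "MeanPixel",              "signal_strength", FALSE,
    "MedianPixel",            "signal_strength", FALSE,
    "RawMaxPixel",            "signal_strength", FALSE,
    "RawMinPixel",            "signal_strength", FALSE,
    "RawMeanPixel",           "signal_strength", FALSE,
    "RawMedianPixel",         "signal_strength", FALSE,
    "BkgdMean",               "signal_strength", FALSE,
    "BkgdStdDev",             "signal_strength", FALSE,
    "RawBkgdMean",            "signal_strength", FALSE,
    "SaturationPercent",      "signal_strength", FALSE,
    "UncompensatedIntensity", "signal_strength", FALSE,
    "PixelRange",             "signal_strength", TRUE
  )
  excluded <- tibble::tribble(
    ~feature,        ~reason,
    "Elongatedness", "redundant",
    "Circularity",   "redundant",
    "SpotArea",      "redundant",
    "Time",          "irrelevant",
    "ObjectNumber",  "irrelevant",
    "CameraLine",    "irrelevant",
    "CentroidX",     "irrelevant",
    "CentroidY",     "irrelevant"
  )
  aliases <- list(
    Area_BF = c("Area_M01", "Area_M04", "Area_Brightfield", "BF_Area"),
    AspectRatio = c("Aspect Ratio", "AspectRatioIntensity")
  )
  structure(
    list(
      features = features,
      excluded = excluded,
      channels = channels,
      statistics = c("AVG", "MED", "SD"),
      cutoff_small = cutoff_small,
      cutoff_large = cutoff_large,
      area_column = "Area_BF",
      saturation_columns = paste0("SaturationCount_", channels),
      aliases = aliases,
      positivity_gate = positivity_gate
    ),
    class = "ev_manifest"
  )
}

#' @export
print.ev_manifest <- function(x, ...) {
  counts <- table(x$features$category)
  cat("<ev_manifest>\n")
  cat("  features: ", nrow(x$features), " active (",
    paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
    "), ", nrow(x$excluded), " excluded\n",
    sep = ""
  )
  cat("  channels: ", paste(x$channels, collapse = ", "), "\n", sep = "")
  cat("  statistics: ", paste(x$statistics, collapse = ", "), "\n", sep = "")
  cat(sprintf(
    "  strata: small < %g <= medium <= %g < large (um^2)\n",
    x$cutoff_small, x$cutoff_large
  ))
  invisible(x)
}

#' Size strata
#'
#' The four stratum labels used throughout: the three disjoint size classes
#' plus `total` (all events, no stratification).
#' @export
ev_strata <- function() c("small", "medium", "large", "total")

#' Assign events to size strata by brightfield area
#'
#' Classifies each object by its brightfield image area: `small` below
#' `cutoff_small`, `medium` from `cutoff_small` up to and including
#' `cutoff_large`, `large` above `cutoff_large`. Both cutoffs belong to the
#' medium stratum.
#'
#' @param area Numeric vector of brightfield areas (square microns), all
#'   strictly positive.
#' @param manifest An `ev_manifest`.
#' @return Factor with levels `small`, `medium`, `large`.
#' @examples
#' m <- default_feature_manifest()
#' stratify(c(0.02, 0.031416, 0.785398, 0.8), m)
#' @export
stratify <- function(area, manifest = default_feature_manifest()) {
  if (any(!is.finite(area)) || any(area <= 0)) {
    stop("brightfield area must be finite and strictly positive", call. = FALSE)
  }
  out <- ifelse(area < manifest$cutoff_small, "small",
    ifelse(area <= manifest$cutoff_large, "medium", "large")
  )
  factor(out, levels = c("small", "medium", "large"))
}

#' Enumerate the variable universe of a manifest
#'
#' Every variable id of the per-sample profile, in manifest order:
#' feature-major, then channel, stratum, statistic. Ids are formed as
#' `feature_channel_stratum_statistic`.
#'
#' @inheritParams stratify
#' @return Tibble with columns `variable_id`, `feature`, `category`,
#'   `channel`, `stratum`, `statistic`.
#' @export
variable_universe <- function(manifest = default_feature_manifest()) {
  grid <- tidyr::expand_grid(
    manifest$features[, c("feature", "category")],
    channel = manifest$channels,
    stratum = ev_strata(),
    statistic = manifest$statistics
  )
  dplyr::mutate(grid,
    variable_id = variable_id(.data$feature, .data$channel, .data$stratum, .data$statistic),
    .before = 1
  )
}

#' Compose and parse variable ids
#'
#' A variable id names one entry of the per-sample profile:
#' `feature_channel_stratum_statistic`, e.g.
#' `BrightDetailIntensity_THSD1_large_SD`.
#'
#' @param feature,channel,stratum,statistic Character vectors (recycled).
#' @return `variable_id()`: character vector of ids. `parse_variable_id()`:
#'   tibble with the four components.
#' @export
variable_id <- function(feature, channel, stratum, statistic) {
  paste(feature, channel, stratum, statistic, sep = "_")
}

#' @rdname variable_id
#' @param variable_id Character vector of ids to split.
#' @export
parse_variable_id <- function(variable_id) {
  parts <- stringr::str_split_fixed(variable_id, "_", 4)
  tibble::tibble(
    variable_id = variable_id,
    feature = parts[, 1], channel = parts[, 2],
    stratum = parts[, 3], statistic = parts[, 4]
  )
}

# Canonical event-table column for a feature measured in a channel.
feature_column <- function(feature, channel) paste0(feature, "_", channel)

# All canonical measured (non-derived) feature columns of a manifest.
measured_columns <- function(manifest) {
  feats <- manifest$features$feature[!manifest$features$derived]
  as.vector(outer(feats, manifest$channels, feature_column))
}

# All canonical feature columns including derived ones.
active_columns <- function(manifest) {
  as.vector(outer(manifest$features$feature, manifest$channels, feature_column))
}
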