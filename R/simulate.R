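# Synthetic cohort generator: per-event IFC feature tables with implantable
# group-by-timepoint effects, plus neuroendocrine biomarker and
# nanoparticle-tracking (NTA) panels, matching the formats the pipeline
# consumes.

#' Cohort specification
#'
#' Sizes and resilience-score distributions for a synthetic cohort. Scores
#' are drawn from truncated normals: the high-resilience group from
#' Normal(94.90, 3.04) truncated to (90, 100], the low-resilience group from
#' Normal(70.00, 5.89) truncated to [0, 79] -- the group means/SDs and the
#' tertile score boundaries of the study design being emulated. Event counts
#' per sample are drawn uniformly from `events_per_sample[1]:events_per_sample[2]`.
#'
#' @param n_high,n_low Subjects per group (>= 1).
#' @param cdrisc_high,cdrisc_low Length-2 `c(mean, sd)` of the untruncated
#'   score distributions.
#' @param high_range,low_range Truncation intervals for the two groups.
#' @param events_per_sample Length-2 integer range of events per sample.
#' @return List of class `ev_cohort_spec`.
#' @export
cohort_spec <- function(n_high = 10, n_low = 10,
                        cdrisc_high = c(94.90, 3.04),
                        cdrisc_low = c(70.00, 5.89),
                        high_range = c(90, 100),
                        low_range = c(0, 79),
                        events_per_sample = c(2000L, 10000L)) {
  stopifnot(n_high >= 1, n_low >= 1, events_per_sample[1] >= 1)
  structure(
    list(
      n_high = n_high, n_low = n_low,
      cdrisc_high = cdrisc_high, cdrisc_low = cdrisc_low,
      high_range = high_range, low_range = low_range,
      events_per_sample = as.integer(events_per_sample)
    ),
    class = "ev_cohort_spec"
  )
}

#' Per-event generative model
#'
#' Distributional settings for one sample's events. Brightfield area is a
#' three-component lognormal mixture (one component per intended size
#' stratum, with component medians of 0.012, 0.15 and 1.5 square microns,
#' i.e. roughly exosome-, microvesicle- and apoptotic-body-sized objects).
#' Intensity-like features are lognormal with a per-subject, per-channel
#' random effect of SD `sigma_subject` on the log-mean, giving realistic
#' between-sample heterogeneity while staying strictly positive and
#' right-skewed like cytometry intensities. Raw max pixel is raw min pixel
#' plus a positive lognormal draw, so `RawMaxPixel >= RawMinPixel >= 0`
#' holds by construction. Aspect ratio is Beta-distributed on (0, 1] (1 = a
#' perfect circle). A fraction `p_sat` of events receives a saturation count
#' of at least 1 in one fluorescence channel.
#'
#' @param area_meanlog,area_sdlog,area_weights Length-3 mixture parameters
#'   (small, medium, large components); weights are normalised internally.
#' @param intensity_meanlog,intensity_sdlog Log-scale location/spread of
#'   generic intensity-like features.
#' @param sigma_subject SD of the subject-level random effect on log-mean.
#' @param rawmin_mean,rawmin_sd Raw-min-pixel baseline noise (normal,
#'   truncated at 0).
#' @param rawrange_meanlog,rawrange_sdlog Lognormal increment from raw min
#'   to raw max pixel.
#' @param minpixel_mean,minpixel_sd Compensated min-pixel noise (normal,
#'   truncated at 0).
#' @param aspect_shape Length-2 Beta shape parameters of the aspect ratio.
#' @param p_sat Saturation injection probability per event.
#' @return List of class `ev_event_model`.
#' @export
event_model <- function(area_meanlog = log(c(0.012, 0.15, 1.5)),
                        area_sdlog = c(0.5, 0.6, 0.5),
                        area_weights = c(0.6, 0.3, 0.1),
                        intensity_meanlog = log(20),
                        intensity_sdlog = 0.8,
                        sigma_subject = 0.3,
                        rawmin_mean = 10, rawmin_sd = 2,
                        rawrange_meanlog = log(40), rawrange_sdlog = 0.6,
                        minpixel_mean = 5, minpixel_sd = 1.5,
                        aspect_shape = c(4, 1.3),
                        p_sat = 0.02) {
  stopifnot(
    length(area_meanlog) == 3, length(area_sdlog) == 3,
    length(area_weights) == 3, all(area_weights >= 0),
    sum(area_weights) > 0, p_sat >= 0, p_sat <= 1
  )
  structure(
    list(
      area_meanlog = area_meanlog, area_sdlog = area_sdlog,
      area_weights = area_weights / sum(area_weights),
      intensity_meanlog = intensity_meanlog,
      intensity_sdlog = intensity_sdlog,
      sigma_subject = sigma_subject,
      rawmin_mean = rawmin_mean, rawmin_sd = rawmin_sd,
      rawrange_meanlog = rawrange_meanlog, rawrange_sdlog = rawrange_sdlog,
      minpixel_mean = minpixel_mean, minpixel_sd = minpixel_sd,
      aspect_shape = aspect_shape, p_sat = p_sat
    ),
    class = "ev_event_model"
  )
}

#' Implantable group-by-timepoint effects
#'
#' Effects are implanted at the peak-stress timepoint (D3) only, so that
#' group differences appear in change scores rather than at baseline --
#' the structure the analysis is designed to detect.
#'
#' Effect A multiplies the within-sample spread (on the log scale) of the
#' bright-detail-intensity feature of the designated channel among
#' large-stratum events; with the default factor 2 in the high-resilience
#' group and 1 in the low group, the change score of the corresponding SD
#' variable separates the groups. Effect B shifts the compensated
#' minimum-pixel feature of a designated channel additively among
#' medium-stratum events.
#'
#' Biomarker declines are per-analyte fractional changes of the D3 mean
#' relative to D0: defaults are -8.9% for alpha-Klotho, -17.2% for NPY and
#' -13.5% for IGF-I, with no systematic change for BDNF or cortisol.
#'
#' @param bdi_sd_factor Named `c(high=, low=)` multiplicative factors (> 0)
#'   on the log-scale spread of bright detail intensity among large events
#'   at D3.
#' @param bdi_channel Channel carrying effect A (default `"THSD1"`).
#' @param minpixel_shift Named `c(high=, low=)` additive shifts applied to
#'   the min-pixel feature among medium events at D3.
#' @param minpixel_channel Channel carrying effect B (default `"VAMP3"`).
#' @param biomarker_decline Named fractional declines in (-1, 1) per analyte.
#' @param biomarker_sd_within Within-subject log-scale noise SD of the
#'   D0 -> D3 biomarker ratio.
#' @return List of class `ev_effect_spec`.
#' @export
effect_spec <- function(bdi_sd_factor = c(high = 2.0, low = 1.0),
                        bdi_channel = "THSD1",
                        minpixel_shift = c(high = -2.0, low = 0.0),
                        minpixel_channel = "VAMP3",
                        biomarker_decline = c(
                          Klotho = -0.089, BDNF = 0, NPY = -0.172,
                          IGF1 = -0.135, Cortisol = 0
                        ),
                        biomarker_sd_within = 0.1) {
  stopifnot(all(bdi_sd_factor > 0), all(biomarker_decline > -1))
  structure(
    list(
      bdi_sd_factor = bdi_sd_factor, bdi_channel = bdi_channel,
      minpixel_shift = minpixel_shift, minpixel_channel = minpixel_channel,
      biomarker_decline = biomarker_decline,
      biomarker_sd_within = biomarker_sd_within
    ),
    class = "ev_effect_spec"
  )
}

#' Variable id targeted by effect A
#'
#' The change-score variable the default implanted effect is designed to
#' light up: the SD of bright detail intensity among large events in the
#' effect channel.
#' @param effects An `ev_effect_spec`.
#' @export
effect_target_variable <- function(effects = effect_spec()) {
  variable_id("BrightDetailIntensity", effects$bdi_channel, "large", "SD")
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi - plo < 1e-12) {
    stop("infeasible truncation: bounds [", lower, ", ", upper,
      "] exclude essentially all mass of Normal(", mean, ", ", sd, ")",
      call. = FALSE
    )
  }
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate one sample's per-event table
#'
#' Draws `n_events` objects from the event model for one subject at one
#' timepoint, with any group-by-timepoint effects applied. Saturation
#' counts, brightfield area and every measured per-channel feature of the
#' default manifest are emitted; the derived pixel-range column is left to
#' [derive_pixel_range()], as in a real export.
#'
#' @param subject_params List with `u` (named per-channel subject random
#'   effects on the log-mean), `group` (`"high"`/`"low"`) and `timepoint`
#'   (`"D0"`/`"D3"`).
#' @param n_events Number of events (>= 1), before any filtering.
#' @param model An [`ev_event_model`][event_model].
#' @param effects An [`ev_effect_spec`][effect_spec].
#' @param manifest An `ev_manifest`.
#' @param seed Optional integer; if supplied the sample is drawn under its
#'   own seed.
#' @return Event tibble with `n_events` rows.
#' @export
generate_event_sample <- function(subject_params, n_events,
                                  model = event_model(),
                                  effects = effect_spec(),
                                  manifest = default_feature_manifest(),
                                  seed = NULL) {
  stopifnot(n_events >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_events)
  comp <- sample.int(3, n, replace = TRUE, prob = model$area_weights)
  # each mixture component is truncated to its stratum, so the weights are
  # exactly the stratum occupancy probabilities
  bounds <- list(
    c(0, manifest$cutoff_small),
    c(manifest$cutoff_small, manifest$cutoff_large),
    c(manifest$cutoff_large, Inf)
  )
  area <- numeric(n)
  for (k in 1:3) {
    idx <- which(comp == k)
    if (length(idx) == 0) next
    plo <- stats::plnorm(bounds[[k]][1], model$area_meanlog[k], model$area_sdlog[k])
    phi <- stats::plnorm(bounds[[k]][2], model$area_meanlog[k], model$area_sdlog[k])
    area[idx] <- stats::qlnorm(
      stats::runif(length(idx), plo, phi),
      model$area_meanlog[k], model$area_sdlog[k]
    )
  }
  strat <- stratify(area, manifest)
  at_d3 <- identical(subject_params$timepoint, "D3")
  group <- subject_params$group

  cols <- list(Area_BF = area)
  # saturation injection: affected events get count >= 1 in one channel
  nch <- length(manifest$channels)
  sat <- matrix(0L, n, nch, dimnames = list(NULL, manifest$channels))
  hit <- which(stats::runif(n) < model$p_sat)
  if (length(hit) > 0) {
    ch_idx <- sample.int(nch, length(hit), replace = TRUE)
    sat[cbind(hit, ch_idx)] <- 1L + stats::rpois(length(hit), 0.5)
  }
  for (ch in manifest$channels) {
    cols[[paste0("SaturationCount_", ch)]] <- sat[, ch]
  }

  diam <- 2 * sqrt(area / pi)
  size_base <- list(
    Area = area, Diameter = diam, Length = 1.1 * diam, Width = 0.9 * diam,
    Height = 0.9 * diam, Perimeter = pi * diam, MajorAxis = 1.05 * diam,
    MinorAxis = 0.95 * diam
  )
  generic <- c(
    "BrightDetailSimilarity", "Contrast", "GradientRMS", "Modulation",
    "StdDev", "Intensity", "RawIntensity", "MeanPixel", "MedianPixel",
    "RawMeanPixel", "RawMedianPixel", "BkgdMean", "BkgdStdDev",
    "RawBkgdMean", "SaturationPercent", "UncompensatedIntensity"
  )
  for (ch in manifest$channels) {
    u <- subject_params$u[[ch]]
    mu <- model$intensity_meanlog + u
    for (f in names(size_base)) {
      cols[[feature_column(f, ch)]] <-
        size_base[[f]] * exp(stats::rnorm(n, 0, 0.05))
    }
    cols[[feature_column("AspectRatio", ch)]] <-
      stats::rbeta(n, model$aspect_shape[1], model$aspect_shape[2])
    for (f in generic) {
      cols[[feature_column(f, ch)]] <-
        stats::rlnorm(n, mu, model$intensity_sdlog)
    }
    # bright detail intensity: carrier of effect A (log-scale spread factor)
    z <- stats::rnorm(n)
    sdlog <- rep(model$intensity_sdlog, n)
    if (at_d3 && ch == effects$bdi_channel) {
      f_grp <- unname(effects$bdi_sd_factor[[group]])
      sdlog[strat == "large"] <- model$intensity_sdlog * f_grp
    }
    cols[[feature_column("BrightDetailIntensity", ch)]] <- exp(mu + sdlog * z)

    rawmin <- pmax(stats::rnorm(n, model$rawmin_mean, model$rawmin_sd), 0)
    cols[[feature_column("RawMinPixel", ch)]] <- rawmin
    cols[[feature_column("RawMaxPixel", ch)]] <-
      rawmin + stats::rlnorm(n, model$rawrange_meanlog, model$rawrange_sdlog)
    minpix <- pmax(stats::rnorm(n, model$minpixel_mean, model$minpixel_sd), 0)
    # min pixel: carrier of effect B (additive shift, medium stratum, D3)
    if (at_d3 && ch == effects$minpixel_channel) {
      shift <- unname(effects$minpixel_shift[[group]])
      minpix[strat == "medium"] <- minpix[strat == "medium"] + shift
    }
    cols[[feature_column("MinPixel", ch)]] <- minpix
    cols[[feature_column("MaxPixel", ch)]] <-
      minpix + stats::rlnorm(n, log(30), 0.6)
  }
  new_event_table(tibble::as_tibble(cols), manifest)
}

#' Generate a full synthetic cohort
#'
#' Draws a cohort of `n_high + n_low` subjects, each with a D0 (baseline)
#' and D3 (peak stress) per-event table, plus neuroendocrine biomarker and
#' NTA panels. Effects are implanted at D3 only, per group. Fully
#' reproducible from `seed`.
#'
#' @param spec An [`ev_cohort_spec`][cohort_spec].
#' @param model An [`ev_event_model`][event_model].
#' @param effects An [`ev_effect_spec`][effect_spec].
#' @param manifest An `ev_manifest`.
#' @param seed Integer seed.
#' @return List of class `ev_cohort`: `manifest` (tibble `subject_id`,
#'   `group`, `cdrisc`, `timepoint`, `n_events`, `events` list-column),
#'   `biomarkers`, `nta`, and the specs used.
#' @export
generate_cohort <- function(spec = cohort_spec(), model = event_model(),
                            effects = effect_spec(),
                            manifest = default_feature_manifest(),
                            seed = 1L) {
  set.seed(seed)
  n <- spec$n_high + spec$n_low
  subjects <- tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n)),
    group = rep(c("high", "low"), c(spec$n_high, spec$n_low)),
    cdrisc = c(
      rtruncnorm1(
        spec$n_high, spec$cdrisc_high[1], spec$cdrisc_high[2],
        spec$high_range[1], spec$high_range[2]
      ),
      rtruncnorm1(
        spec$n_low, spec$cdrisc_low[1], spec$cdrisc_low[2],
        spec$low_range[1], spec$low_range[2]
      )
    )
  )
  rows <- list()
  for (i in seq_len(n)) {
    u <- stats::setNames(
      as.list(stats::rnorm(length(manifest$channels), 0, model$sigma_subject)),
      manifest$channels
    )
    for (tp in c("D0", "D3")) {
      n_events <- sample(
        seq(spec$events_per_sample[1], spec$events_per_sample[2]), 1
      )
      sp <- list(u = u, group = subjects$group[i], timepoint = tp)
      ev <- generate_event_sample(sp, n_events, model, effects, manifest)
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = subjects$subject_id[i],
        group = subjects$group[i],
        cdrisc = subjects$cdrisc[i],
        timepoint = tp,
        n_events = n_events,
        events = list(ev)
      )
    }
  }
  structure(
    list(
      manifest = dplyr::bind_rows(rows),
      biomarkers = generate_biomarkers(subjects, effects),
      nta = generate_nta(subjects),
      spec = spec, model = model, effects = effects,
      feature_manifest = manifest, seed = seed
    ),
    class = "ev_cohort"
  )
}

#' @export
print.ev_cohort <- function(x, ...) {
  cat(
    "<ev_cohort> ", sum(x$manifest$timepoint == "D0"), " subjects (",
    sum(x$manifest$group == "high" & x$manifest$timepoint == "D0"), " high, ",
    sum(x$manifest$group == "low" & x$manifest$timepoint == "D0"), " low), ",
    nrow(x$manifest), " event tables, seed ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

# Baseline concentration parameters per analyte and group: mean, SD of the
# D0 distribution (units: Klotho/BDNF/NPY pg/ml, IGF1 ng/ml, Cortisol ug/dl).
biomarker_baseline_params <- function() {
  tibble::tribble(
    ~analyte,   ~group, ~mean,   ~sd,
    "Klotho",   "low",  1013.69, 332.89,
    "Klotho",   "high", 956.37,  341.04,
    "BDNF",     "low",  5595.60, 6548.55,
    "BDNF",     "high", 6273.00, 4592.35,
    "NPY",      "low",  2210.53, 993.55,
    "NPY",      "high", 3594.32, 2496.45,
    "IGF1",     "low",  273.57,  64.37,
    "IGF1",     "high", 293.05,  91.62,
    "Cortisol", "low",  26.15,   11.63,
    "Cortisol", "high", 28.21,   9.57
  )
}

lnorm_params <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate the neuroendocrine biomarker panel
#'
#' D0 concentrations are lognormal draws matched (moment-matched) to each
#' group's baseline mean and SD. D3 concentrations are the subject's D0
#' value times `(1 + decline)` for the analyte, times a mean-one lognormal
#' within-subject noise term -- so the D3 mean equals the D0 mean scaled by
#' the decline fraction, and the D3 SD scales with it.
#'
#' @param subjects Tibble with `subject_id`, `group`.
#' @param effects An `ev_effect_spec` (declines and within-subject noise).
#' @param params Baseline parameter table (analyte, group, mean, sd).
#' @return Tibble: `subject_id`, `group`, `analyte`, `timepoint`, `value`.
#' @export
generate_biomarkers <- function(subjects, effects = effect_spec(),
                                params = biomarker_baseline_params()) {
  declines <- effects$biomarker_decline
  unknown <- setdiff(names(declines), unique(params$analyte))
  if (length(unknown) > 0) {
    stop("unknown analyte(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  sw <- effects$biomarker_sd_within
  out <- list()
  for (a in names(declines)) {
    for (g in c("high", "low")) {
      p <- params[params$analyte == a & params$group == g, ]
      idx <- which(subjects$group == g)
      lp <- lnorm_params(p$mean, p$sd)
      d0 <- stats::rlnorm(length(idx), lp$meanlog, lp$sdlog)
      noise <- exp(stats::rnorm(length(idx), -sw^2 / 2, sw))
      d3 <- d0 * (1 + declines[[a]]) * noise
      out[[length(out) + 1]] <- tibble::tibble(
        subject_id = rep(subjects$subject_id[idx], 2),
        group = g, analyte = a,
        timepoint = rep(c("D0", "D3"), each = length(idx)),
        value = c(d0, d3)
      )
    }
  }
  dplyr::arrange(
    dplyr::bind_rows(out),
    .data$analyte, .data$subject_id, .data$timepoint
  )
}

#' Generate the NTA panel
#'
#' Particle concentration (x 10^10 nanoparticles/ml) and mean size (nm) per
#' subject and timepoint, lognormal-matched to each group's baseline
#' summaries; no systematic D0 -> D3 shift is implanted, matching the
#' observed null stress effect on EV concentration and size.
#'
#' @param subjects Tibble with `subject_id`, `group`.
#' @param sd_within Within-subject log-scale noise of the D0 -> D3 ratio.
#' @return Tibble: `subject_id`, `group`, `timepoint`, `concentration`,
#'   `mean_size`.
#' @export
generate_nta <- function(subjects, sd_within = 0.1) {
  params <- list(
    concentration = list(
      low = lnorm_params(2.78, 1.81), high = lnorm_params(2.60, 1.67)
    ),
    mean_size = list(
      low = lnorm_params(112.63, 24.86), high = lnorm_params(97.68, 18.96)
    )
  )
  n <- nrow(subjects)
  draw <- function(var) {
    d0 <- numeric(n)
    for (g in c("high", "low")) {
      idx <- which(subjects$group == g)
      p <- params[[var]][[g]]
      d0[idx] <- stats::rlnorm(length(idx), p$meanlog, p$sdlog)
    }
    d3 <- d0 * exp(stats::rnorm(n, -sd_within^2 / 2, sd_within))
    c(d0, d3)
  }
  tibble::tibble(
    subject_id = rep(subjects$subject_id, 2),
    group = rep(subjects$group, 2),
    timepoint = rep(c("D0", "D3"), each = n),
    concentration = draw("concentration"),
    mean_size = draw("mean_size")
  )
}

#' Write a synthetic cohort to disk in pipeline input format
#'
#' Emits one CSV per (subject, timepoint) event table plus `manifest.tsv`,
#' `biomarkers.tsv` and `nta.tsv`, the formats [read_cohort()] and the
#' pipeline consume.
#'
#' @param cohort An `ev_cohort`.
#' @param dir Output directory (created if needed).
#' @return Path to the written manifest TSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  paths <- file.path(
    dir, sprintf("%s_%s.csv", man$subject_id, man$timepoint)
  )
  for (i in seq_len(nrow(man))) {
    write_event_table(man$events[[i]], paths[i])
  }
  out <- dplyr::mutate(
    man[, c("subject_id", "group", "cdrisc", "timepoint")],
    event_table_path = paths
  )
  manifest_path <- file.path(dir, "manifest.tsv")
  readr::write_tsv(out, manifest_path, progress = FALSE)
  readr::write_tsv(cohort$biomarkers, file.path(dir, "biomarkers.tsv"),
    progress = FALSE
  )
  readr::write_tsv(cohort$nta, file.path(dir, "nta.tsv"), progress = FALSE)
  invisible(manifest_path)
}
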