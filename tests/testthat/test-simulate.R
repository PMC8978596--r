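test_that("generated events respect the physical invariants", {
  m <- default_feature_manifest()
  for (seed in 1:5) {
    ev <- small_events(seed = seed, n = 400)
    expect_true(all(ev$Area_BF > 0))
    for (ch in m$channels) {
      expect_true(all(ev[[paste0("RawMinPixel_", ch)]] >= 0))
      expect_true(all(
        ev[[paste0("RawMaxPixel_", ch)]] >= ev[[paste0("RawMinPixel_", ch)]]
      ))
      ar <- ev[[paste0("AspectRatio_", ch)]]
      expect_true(all(ar > 0 & ar <= 1))
    }
  }
})

test_that("saturation injection matches its nominal rate", {
  m <- default_feature_manifest()
  ev <- small_events(
    seed = 3, n = 1000,
    model = event_model(p_sat = 0.02)
  )
  sat <- rowSums(as.matrix(ev[, paste0("SaturationCount_", m$channels)]) >= 1) > 0
  # binomial(1000, 0.02): ~20 events, allow +/- 4 sd
  expect_gt(sum(sat), 20 - 4 * sqrt(1000 * 0.02 * 0.98))
  expect_lt(sum(sat), 20 + 4 * sqrt(1000 * 0.02 * 0.98))

  ev0 <- small_events(seed = 4, n = 500, model = event_model(p_sat = 0))
  sat0 <- as.matrix(ev0[, paste0("SaturationCount_", m$channels)])
  expect_equal(sum(sat0 >= 1), 0)
})

test_that("a degenerate area mixture puts every event in one stratum", {
  ev <- small_events(
    seed = 5, n = 300,
    model = event_model(area_weights = c(1, 0, 0))
  )
  expect_true(all(stratify(ev$Area_BF) == "small"))
})

test_that("resilience scores match the group distributions and bounds", {
  co <- generate_cohort(
    cohort_spec(n_high = 150, n_low = 150, events_per_sample = c(1, 1)),
    seed = 2
  )
  subj <- dplyr::distinct(co$manifest[, c("subject_id", "group", "cdrisc")])
  hi <- subj$cdrisc[subj$group == "high"]
  lo <- subj$cdrisc[subj$group == "low"]
  expect_true(all(hi > 90 & hi <= 100))
  expect_true(all(lo >= 0 & lo <= 79))
  # truncation barely moves the means; Monte-Carlo tolerance ~4 SE
  expect_equal(mean(hi), 94.9, tolerance = 4 * 3.04 / sqrt(150) / 94.9)
  expect_equal(mean(lo), 70.0, tolerance = 4 * 5.89 / sqrt(150) / 70.0)

  expect_error(
    generate_cohort(
      cohort_spec(cdrisc_high = c(30, 0.5), events_per_sample = c(1, 1)),
      seed = 1
    ),
    "infeasible truncation"
  )
})

test_that("cohorts are reproducible from the seed", {
  a <- small_cohort(seed = 9, n_high = 2, n_low = 2, events = c(50, 80))
  b <- small_cohort(seed = 9, n_high = 2, n_low = 2, events = c(50, 80))
  expect_equal(a$manifest$cdrisc, b$manifest$cdrisc)
  expect_equal(
    as.data.frame(a$manifest$events[[1]]),
    as.data.frame(b$manifest$events[[1]])
  )
  expect_equal(a$biomarkers$value, b$biomarkers$value)
})

test_that("biomarker panel reproduces baseline levels and declines", {
  subjects <- tibble::tibble(
    subject_id = sprintf("S%04d", 1:1000),
    group = rep(c("high", "low"), 500)
  )
  set.seed(31)
  panel <- generate_biomarkers(subjects, effect_spec())
  wide <- tidyr::pivot_wider(panel,
    names_from = "timepoint", values_from = "value"
  )
  igf <- wide[wide$analyte == "IGF1", ]
  expect_true(all(igf$D0 > 0) && all(igf$D3 > 0))
  # law of large numbers: mean D3/D0 ratio ~ 1 + decline = 0.865
  expect_equal(mean(igf$D3 / igf$D0), 0.865, tolerance = 0.02)
  igf_low <- igf[igf$group == "low", ]
  expect_equal(mean(igf_low$D0), 273.57, tolerance = 0.03)
  expect_equal(sd(igf_low$D0), 64.37, tolerance = 0.15)
  cort <- wide[wide$analyte == "Cortisol", ]
  expect_equal(mean(cort$D3 / cort$D0), 1, tolerance = 0.02)

  expect_error(
    generate_biomarkers(
      subjects,
      effect_spec(biomarker_decline = c(Mystery = -0.1))
    ),
    "unknown analyte"
  )
})

test_that("NTA panel matches the baseline summaries by group", {
  subjects <- tibble::tibble(
    subject_id = sprintf("S%04d", 1:2000),
    group = rep(c("high", "low"), 1000)
  )
  set.seed(7)
  nta <- generate_nta(subjects)
  d0 <- nta[nta$timepoint == "D0", ]
  expect_true(all(d0$concentration > 0) && all(d0$mean_size > 0))
  expect_equal(
    mean(d0$mean_size[d0$group == "low"]), 112.63,
    tolerance = 0.03
  )
  expect_equal(
    mean(d0$mean_size[d0$group == "high"]), 97.68,
    tolerance = 0.03
  )
  d3 <- nta[nta$timepoint == "D3", ]
  expect_equal(mean(d3$concentration) / mean(d0$concentration), 1,
    tolerance = 0.05
  )
})

test_that("effect A raises the D3 spread of the target feature in the high group", {
  m <- default_feature_manifest()
  col <- "BrightDetailIntensity_THSD1"
  hits <- 0
  n_seeds <- 50
  for (seed in seq_len(n_seeds)) {
    set.seed(seed)
    u <- stats::setNames(as.list(rnorm(3, 0, 0.3)), m$channels)
    sd_of <- function(group) {
      ev <- generate_event_sample(
        list(u = u, group = group, timepoint = "D3"),
        n_events = 600
      )
      large <- stratify(ev$Area_BF) == "large"
      sd(ev[[col]][large])
    }
    if (sd_of("high") > sd_of("low")) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("neutral effects leave D0 and D3 exchangeable", {
  neutral <- effect_spec(
    bdi_sd_factor = c(high = 1, low = 1),
    minpixel_shift = c(high = 0, low = 0)
  )
  m <- default_feature_manifest()
  u <- list(CD63 = 0, VAMP3 = 0, THSD1 = 0)
  set.seed(21)
  d0 <- generate_event_sample(
    list(u = u, group = "high", timepoint = "D0"),
    n_events = 4000, effects = neutral
  )
  d3 <- generate_event_sample(
    list(u = u, group = "high", timepoint = "D3"),
    n_events = 4000, effects = neutral
  )
  for (col in c(
    "BrightDetailIntensity_THSD1", "MinPixel_VAMP3", "Intensity_CD63"
  )) {
    p <- suppressWarnings(ks.test(d0[[col]], d3[[col]])$p.value)
    expect_gt(p, 1e-4)
  }
})

test_that("written cohorts reload to the same analysis inputs", {
  co <- small_cohort(seed = 13, n_high = 2, n_low = 2, events = c(60, 90))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(
    file.path(dir, "manifest.tsv"),
    biomarkers_path = file.path(dir, "biomarkers.tsv"),
    nta_path = file.path(dir, "nta.tsv")
  )
  expect_equal(nrow(back$manifest), 8)
  vars_mem <- reduce_cohort(co)
  vars_disk <- reduce_cohort(back)
  expect_equal(vars_disk$value, vars_mem$value, tolerance = 1e-10)
  expect_equal(back$biomarkers$value, co$biomarkers$value, tolerance = 1e-10)
})
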