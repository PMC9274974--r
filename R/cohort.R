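#' Configuration of the synthetic rat cohort
#'
#' Defines the generative model for every input modality the pipeline
#' consumes. Distributional families mirror what the analyses assume:
#' gamma-distributed heart-rate AUCs arise from positive baseline-scaled
#' traces, serum baselines are log-normal with multiplicative post/pre
#' effects (log-normal ratios), freezing observations are beta-distributed
#' around acquisition / extinction mean curves, and nanoparticle deposits
#' are placed by per-zone probabilities.
#'
#' @param n_per_condition Rats per condition (default 14, a 28-rat cohort).
#' @param seed Mandatory RNG seed.
#' @param hr Heart-rate model: `baseline_mean`/`baseline_sd` (bpm),
#'   `rise_fraction` (mean fractional HR rise during stimulation in active
#'   rats, pre-conditioning) with per-rat sd `rise_sd`, `blunting`
#'   (multiplier on the rise on post-conditioning day 4; 0 = fully
#'   blunted), `gap_rate` (missing-sample probability), `noise_sd` (bpm,
#'   white), `drift_sd` (bpm per sqrt(s), slow random-walk physiologic
#'   wander), `duration` (s), `rate` (Hz).
#' @param hormone Serum model: `baseline_meanlog`/`baseline_sdlog` (pre
#'   values, log-normal), `effect_active`/`effect_control` (multiplicative
#'   post/pre effects), `noise_sdlog` (log-normal ratio noise).
#' @param freezing Behavior model: conditioning acquisition
#'   `f_max (1 - exp(-k trial))`, extinction decay
#'   `f_end + (f_start - f_end) exp(-lambda trial)` with `lambda`
#'   multiplied by `treatment_modifier` in active rats, beta observation
#'   `precision`, `nonacquirer_fraction` (rats generated flat at
#'   habituation level), `hab_mean`.
#' @param histology Section model: `axes_px` (ellipse semi-axes),
#'   `img_dim`, `zone_probs` (blob placement probabilities; ZG defaults to
#'   0, the observed pattern), `n_blobs`, `blob_radius_px`,
#'   `pixel_size_um`.
#' @param calorimetry `true_slp` (W/g), `noise_sd` (K), `frequency` (kHz),
#'   `amplitude` (kA/m), `solution_mass` (kg), `iron_mass` (kg).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_condition = 14, seed = 1,
                          hr = list(), hormone = list(), freezing = list(),
                          histology = list(), calorimetry = list()) {
  defaults <- list(
    hr = list(baseline_mean = 380, baseline_sd = 20, rise_fraction = 0.10,
              rise_sd = 0.04, blunting = 0, gap_rate = 0.10, noise_sd = 5,
              drift_sd = 0.4, duration = 480, rate = 1),
    hormone = list(baseline_meanlog = log(100), baseline_sdlog = 0.4,
                   effect_active = 0.7, effect_control = 1.0,
                   noise_sdlog = 0.3),
    freezing = list(k = 0.6, f_max = 0.8, f_end = 0.1, lambda = 0.15,
                    treatment_modifier = 1.0, precision = 20,
                    nonacquirer_fraction = 0.15, hab_mean = 0.05),
    histology = list(axes_px = c(110, 44), img_dim = c(280, 130),
                     zone_probs = c(medulla = 0.35, ZR = 0.35, ZF = 0.30,
                                    ZG = 0),
                     n_blobs = 2, blob_radius_px = 9, pixel_size_um = 25),
    calorimetry = list(true_slp = 880, noise_sd = 0.05, frequency = 515,
                       amplitude = 15, solution_mass = 1e-3,
                       iron_mass = 1e-6, heat_capacity = 4180))
  cfg <- list(n_per_condition = n_per_condition, seed = seed,
              hr = utils::modifyList(defaults$hr, hr),
              hormone = utils::modifyList(defaults$hormone, hormone),
              freezing = utils::modifyList(defaults$freezing, freezing),
              histology = utils::modifyList(defaults$histology, histology),
              calorimetry = utils::modifyList(defaults$calorimetry,
                                              calorimetry))
  stopifnot(cfg$hr$gap_rate >= 0, cfg$hr$gap_rate <= 1,
            cfg$freezing$nonacquirer_fraction >= 0,
            cfg$freezing$nonacquirer_fraction <= 1,
            !is.null(seed))
  structure(cfg, class = "cohort_config")
}

#' Generate heart-rate traces for one rat
#'
#' Baseline plus (for active rats) a logistic heart-rate rise during the
#' 300-360 s stimulation window that decays after field-off, Gaussian
#' observation noise, and samples dropped at the configured gap rate (the
#' first and last samples are always kept so imputation preconditions
#' hold). Day 4 rises are multiplied by the post-conditioning blunting
#' factor. Uses the current RNG state; seed via the cohort config /
#' [gen_cohort()].
#'
#' @param cfg A `cohort_config`.
#' @param rat Rat id.
#' @param condition `"active"` or `"control"`.
#' @param day Session day (1, 2 = pre-conditioning; 4 = post-conditioning).
#' @return An `hr_trace` with attribute `true_rise` (fraction).
#' @export
gen_heart_rate <- function(cfg, rat, condition, day) {
  p <- cfg$hr
  times <- seq(0, p$duration, by = 1 / p$rate)
  base <- rnorm(1, p$baseline_mean, p$baseline_sd)
  rise <- if (condition == "active" && p$rise_fraction > 0)
    max(0, rnorm(1, p$rise_fraction, p$rise_sd)) else 0
  if (day >= 3) rise <- rise * p$blunting
  shape <- numeric(length(times))
  stim <- times >= 300 & times <= 360
  shape[stim] <- plogis((times[stim] - 310) / 6)
  post <- times > 360
  shape[post] <- plogis((360 - 310) / 6) * exp(-(times[post] - 360) / 40)
  drift <- cumsum(rnorm(length(times), 0, p$drift_sd))  # slow physiologic wander
  bpm <- base * (1 + rise * shape) + drift +
    rnorm(length(times), 0, p$noise_sd)
  bpm <- pmax(bpm, 1)
  drop <- runif(length(times)) < p$gap_rate
  drop[c(1, length(times))] <- FALSE
  bpm[drop] <- NA
  tr <- hr_trace(times, bpm, stim_window = c(300, 360), rat = rat,
                 day = day, condition = condition)
  attr(tr, "true_rise") <- rise
  tr
}

#' Generate serum hormone samples for one rat
#'
#' Pre-stimulation values are log-normal; post values are the same day's
#' pre value times the condition-specific multiplicative effect times
#' log-normal noise.
#'
#' @param cfg A `cohort_config`.
#' @param rat Rat id.
#' @param condition `"active"` or `"control"`.
#' @param hormone Label stored in the output (e.g. `"CORT"`).
#' @param days Collection days (default two).
#' @return Data frame `rat, condition, hormone, day, phase, value` with
#'   attribute `true_effect`.
#' @export
gen_hormones <- function(cfg, rat, condition, hormone = "CORT",
                         days = c(1, 2)) {
  p <- cfg$hormone
  eff <- if (condition == "active") p$effect_active else p$effect_control
  out <- do.call(rbind, lapply(days, function(d) {
    pre <- rlnorm(1, p$baseline_meanlog, p$baseline_sdlog)
    post <- pre * eff * rlnorm(1, 0, p$noise_sdlog)
    data.frame(rat = rat, condition = condition, hormone = hormone,
               day = d, phase = c("pre", "post"), value = c(pre, post))
  }))
  attr(out, "true_effect") <- eff
  out
}

#' Generate a freezing series for one rat
#'
#' Habituation stays near `hab_mean`; conditioning follows the acquisition
#' curve `f_max (1 - exp(-k trial))`; extinction decays as
#' `f_end + (f_start - f_end) exp(-lambda trial)` with `lambda` scaled by
#' `treatment_modifier` for active rats; recall starts from the extinction
#' endpoint. Observations are beta-distributed around the mean curve with
#' the configured precision. Non-acquirers (probability
#' `nonacquirer_fraction`) stay flat at habituation level in every phase.
#'
#' @inheritParams gen_heart_rate
#' @return Freezing data frame (`rat`, `condition`, `phase`, `trial`,
#'   `fraction`) with attributes `nonacquirer`, `true_lambda`.
#' @export
gen_freezing <- function(cfg, rat, condition) {
  p <- cfg$freezing
  ph <- freezing_phases()
  nonacq <- runif(1) < p$nonacquirer_fraction
  lam <- p$lambda * if (condition == "active") p$treatment_modifier else 1
  means <- list(
    habituation = rep(p$hab_mean, ph["habituation"]),
    conditioning = p$f_max * (1 - exp(-p$k * seq_len(ph["conditioning"]))),
    extinction = NA, recall = NA)
  f_start <- p$f_max * (1 - exp(-p$k * ph["conditioning"]))
  means$extinction <- p$f_end + (f_start - p$f_end) *
    exp(-lam * seq_len(ph["extinction"]))
  means$recall <- rep(tail(means$extinction, 1), ph["recall"])
  if (nonacq) means <- lapply(means, function(m) rep(p$hab_mean, length(m)))
  out <- do.call(rbind, lapply(names(ph), function(phase) {
    mu <- pmin(pmax(means[[phase]], 0.01), 0.99)
    y <- rbeta(length(mu), mu * p$precision, (1 - mu) * p$precision)
    data.frame(rat = rat, condition = condition, phase = phase,
               trial = seq_along(mu), fraction = y)
  }))
  attr(out, "nonacquirer") <- nonacq
  attr(out, "true_lambda") <- lam
  out
}

disk_mask <- function(dim, center, radius) {
  r <- matrix(seq_len(dim[1]), dim[1], dim[2]) - center[1]
  c <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE) - center[2]
  (r^2 + c^2 <= radius^2) * 1L
}

#' Generate a synthetic adrenal section mask pair
#'
#' Elliptical tissue mask with particle blobs placed at radii sampled from
#' the configured per-zone probabilities (default: medulla/ZR/ZF only,
#' none in the ZG, the experimentally observed deposition pattern).
#'
#' @inheritParams gen_heart_rate
#' @param bands Radial bands used to translate zones into radii (default
#'   `c(0.4, 0.7, 0.9)`).
#' @return A `section_mask` with attribute `true_zones` (zone of each
#'   blob center).
#' @export
gen_section_masks <- function(cfg, rat, bands = c(0.4, 0.7, 0.9)) {
  p <- cfg$histology
  dimg <- p$img_dim
  ctr <- dimg / 2
  rr <- matrix(seq_len(dimg[1]), dimg[1], dimg[2]) - ctr[1]
  cc <- matrix(seq_len(dimg[2]), dimg[1], dimg[2], byrow = TRUE) - ctr[2]
  tissue <- ((rr / p$axes_px[1])^2 + (cc / p$axes_px[2])^2 <= 1) * 1L
  zones <- names(p$zone_probs)
  lims <- rbind(medulla = c(0, bands[1]), ZR = c(bands[1], bands[2]),
                ZF = c(bands[2], bands[3]), ZG = c(bands[3], 1))
  rnorm_ell <- sqrt((rr / p$axes_px[1])^2 + (cc / p$axes_px[2])^2)
  particles <- matrix(0L, dimg[1], dimg[2])
  placed <- character(0)
  margin <- 0.015
  for (b in seq_len(p$n_blobs)) {
    z <- sample(zones, 1, prob = p$zone_probs)
    rad <- runif(1, lims[z, 1], lims[z, 2])
    th <- runif(1, 0, 2 * pi)
    at <- ctr + c(rad * p$axes_px[1] * cos(th), rad * p$axes_px[2] * sin(th))
    blob <- disk_mask(dimg, at, p$blob_radius_px)
    # deposits conform to the zone's elliptical annulus (unambiguous truth)
    blob[rnorm_ell < lims[z, 1] + margin | rnorm_ell > lims[z, 2] - margin] <- 0L
    particles <- pmax(particles, blob)
    placed <- c(placed, z)
  }
  particles <- particles * tissue
  m <- section_mask(tissue, particles, pixel_size = p$pixel_size_um)
  attr(m, "true_zones") <- placed
  m
}

#' Generate a synthetic calorimetry trace
#'
#' Flat (drift-free) baseline before field-on, then linear heating at the
#' slope implied by the configured true SLP, plus Gaussian temperature
#' noise.
#'
#' @param cfg A `cohort_config`.
#' @return A `calorimetry_trace` with attribute `true_slp`.
#' @export
gen_calorimetry <- function(cfg) {
  p <- cfg$calorimetry
  slope <- p$true_slp * 1000 * p$iron_mass / (p$heat_capacity * p$solution_mass)
  times <- seq(0, 40, by = 0.5)
  on_t <- 20
  temp <- 25 + pmax(0, times - on_t) * slope +
    rnorm(length(times), 0, p$noise_sd)
  tr <- calorimetry_trace(times, temp, field_on_time = on_t,
                          solution_mass = p$solution_mass,
                          iron_mass = p$iron_mass,
                          solution_heat_capacity = p$heat_capacity,
                          condition = field_condition(p$frequency,
                                                      p$amplitude))
  attr(tr, "true_slp") <- p$true_slp
  tr
}

#' Generate the full synthetic cohort
#'
#' Seeds the RNG from the config and generates, for every rat, heart-rate
#' traces (days 1, 2, 4), serum samples for both hormones (2 collection
#' days, pre/post), a freezing series, and a section mask pair, plus one
#' calorimetry trace. With `out_dir`, writes the CSV/PNG layout the
#' analysis entry points consume plus a ground-truth JSON.
#'
#' @param cfg A `cohort_config`.
#' @param out_dir Optional directory to write input files into.
#' @return List with `rats` (per-rat records), `calorimetry`, `config`,
#'   and (if written) `paths`.
#' @export
gen_cohort <- function(cfg, out_dir = NULL) {
  set.seed(cfg$seed)
  n <- cfg$n_per_condition
  ids <- sprintf("rat%02d", seq_len(2 * n))
  conds <- rep(c("control", "active"), each = n)
  rats <- Map(function(id, cond) {
    hr <- lapply(c(1, 2, 4), function(d) gen_heart_rate(cfg, id, cond, d))
    names(hr) <- paste0("day", c(1, 2, 4))
    horm <- rbind(gen_hormones(cfg, id, cond, "CORT"),
                  gen_hormones(cfg, id, cond, "EPI"))
    fz <- gen_freezing(cfg, id, cond)
    mask <- gen_section_masks(cfg, id)
    list(rat = id, condition = cond, hr = hr, hormones = horm,
         freezing = fz, mask = mask,
         truth = list(nonacquirer = attr(fz, "nonacquirer"),
                      hr_rise = attr(hr$day1, "true_rise"),
                      hormone_effect = attr(horm, "true_effect"),
                      blob_zones = attr(mask, "true_zones")))
  }, ids, conds)
  names(rats) <- ids
  calo <- gen_calorimetry(cfg)
  res <- list(rats = rats, calorimetry = calo, config = cfg)
  if (!is.null(out_dir)) res$paths <- write_cohort(res, out_dir)
  res
}

# write the on-disk layout the analyze-* entry points read
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hr_dir <- file.path(out_dir, "hr")
  mask_dir <- file.path(out_dir, "masks")
  dir.create(hr_dir, showWarnings = FALSE)
  dir.create(mask_dir, showWarnings = FALSE)
  manifest <- list()
  for (r in cohort$rats) {
    for (d in names(r$hr)) {
      f <- file.path(hr_dir, paste0(r$rat, "_", d, ".csv"))
      tr <- r$hr[[d]]
      write.csv(data.frame(time_s = tr$times, bpm = tr$bpm), f,
                row.names = FALSE, na = "")
      manifest[[length(manifest) + 1]] <-
        data.frame(rat = r$rat, day = sub("day", "", d),
                   condition = r$condition, file = basename(f))
    }
  }
  empty_manifest <- data.frame(rat = character(0), day = character(0),
                               condition = character(0), file = character(0))
  write.csv(if (length(manifest)) do.call(rbind, manifest) else empty_manifest,
            file.path(hr_dir, "manifest.csv"), row.names = FALSE)
  horm <- do.call(rbind, lapply(cohort$rats, `[[`, "hormones"))
  if (is.null(horm))
    horm <- data.frame(rat = character(0), condition = character(0),
                       hormone = character(0), day = numeric(0),
                       phase = character(0), value = numeric(0))
  write.csv(horm, file.path(out_dir, "hormones.csv"), row.names = FALSE)
  fz <- do.call(rbind, lapply(cohort$rats, `[[`, "freezing"))
  if (is.null(fz))
    fz <- data.frame(rat = character(0), condition = character(0),
                     phase = character(0), trial = numeric(0),
                     fraction = numeric(0))
  write.csv(fz, file.path(out_dir, "freezing.csv"), row.names = FALSE)
  for (r in cohort$rats) {
    png::writePNG(r$mask$tissue * 1.0,
                  file.path(mask_dir, paste0(r$rat, "_tissue.png")))
    png::writePNG(r$mask$particles * 1.0,
                  file.path(mask_dir, paste0(r$rat, "_particles.png")))
  }
  calo <- cohort$calorimetry
  write.csv(data.frame(time_s = calo$times, temp_c = calo$temperatures),
            file.path(out_dir, "calorimetry.csv"), row.names = FALSE)
  truth <- lapply(cohort$rats, `[[`, "truth")
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(root = out_dir, hr = hr_dir, masks = mask_dir,
       hormones = file.path(out_dir, "hormones.csv"),
       freezing = file.path(out_dir, "freezing.csv"),
       calorimetry = file.path(out_dir, "calorimetry.csv"))
}
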