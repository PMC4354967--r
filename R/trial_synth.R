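#' Randomized complete block trial design
#'
#' The trial layout the calibration assumes: N treatment levels crossed with
#' replicate blocks, observed at successive growth stages.
#'
#' @param n_levels applied N rates in kg N/ha; at least 3 distinct values.
#'   Default `c(0, 30, 60, 90, 120, 150)`.
#' @param replicates number of blocks; default 3.
#' @param stages ordered growth stages; default all three of tillering,
#'   booting, ear_emergence.
#' @param seed integer seed driving all noise draws in [simulate_trial()].
#' @return An object of class `"trial_design"`.
#' @export
trial_design <- function(n_levels = c(0, 30, 60, 90, 120, 150),
                         replicates = 3, stages = .STAGES, seed = 1L) {
  if (length(unique(n_levels)) < 3L)
    stop("need at least 3 distinct N levels", call. = FALSE)
  if (any(n_levels < 0))
    stop("N levels must be non-negative", call. = FALSE)
  if (replicates < 1L)
    stop("need at least 1 replicate", call. = FALSE)
  stages <- canonical_stage(stages)
  structure(list(
    n_levels = sort(unique(n_levels)),
    replicates = as.integer(replicates),
    stages = stages,
    seed = as.integer(seed)
  ), class = "trial_design")
}

#' Urea split-dose schedule
#'
#' Splits a seasonal N total into the standard urea application timings:
#' 50% basal, 25% at first irrigation, 25% at second irrigation. The
#' components always sum exactly to the total.
#'
#' @param total_n total seasonal rate(s), kg N/ha, non-negative. Vectorized.
#' @return data frame of class `"dose_schedule"` with columns `total_n`,
#'   `basal`, `first_irrigation`, `second_irrigation`.
#' @export
#' @examples
#' dose_schedule(150)  # 75 / 37.5 / 37.5
dose_schedule <- function(total_n) {
  if (any(!is.finite(total_n)) || any(total_n < 0))
    stop("total_n must be finite and non-negative", call. = FALSE)
  out <- data.frame(
    total_n = total_n,
    basal = 0.5 * total_n,
    first_irrigation = 0.25 * total_n,
    second_irrigation = 0.25 * total_n
  )
  class(out) <- c("dose_schedule", "data.frame")
  out
}

#' Ground-truth parameters for the synthetic trial generator
#'
#' Defines the generative model behind [simulate_trial()]: per-stage
#' quadratic SPAD sufficiency-index responses to N rate, per-stage linear
#' sensor bridges, attribute scaling constants and noise standard
#' deviations. The defaults describe a realistic wheat trial: concave
#' responses peaking at 150 kg N/ha, response amplitude shrinking with
#' stage (canopy closure makes late-stage sensing less discriminating), and
#' noise growing with stage so that sensor--laboratory correlations are
#' strongest at tillering.
#'
#' @param quadratic named list (per stage) of `c(a0, a1, a2)` response
#'   coefficients, `a2 < 0`.
#' @param bridge named list (per stage) of `c(b0, b1)` bridge coefficients,
#'   `b1 > 0`.
#' @param reference_spad SPAD reading of an N-sufficient canopy; cancels in
#'   every sufficiency-index computation. Default 50.
#' @param reference_ndvi named per-stage NDVI of the well-fertilized
#'   reference.
#' @param sn_scale,biomass_scale named per-stage slopes mapping the sensor
#'   sufficiency index to the raw SN and biomass scales.
#' @param lab_n_base,lab_n_gain leaf N (% by weight) as an affine function
#'   of the true SPAD sufficiency index.
#' @param lab_chl_base,lab_chl_gain leaf chlorophyll (mg/g) likewise.
#' @param yield_base,yield_slope,yield_plateau grain yield (t/ha) as a
#'   linear-plateau function of applied N.
#' @param block_effects per-replicate additive yield offsets (t/ha),
#'   recycled over replicates.
#' @param noise_sd named baseline noise standard deviations (attribute
#'   units) for `si_spad`, `si_sensor`, `sn`, `biomass`, `lab_n`,
#'   `lab_chl`, `yield`.
#' @param stage_noise_mult named per-stage multipliers applied to every
#'   baseline noise sd; increasing with stage by default.
#' @return An object of class `"truth_params"`.
#' @seealso [truth_presets()] for the published-coefficient presets.
#' @export
truth_params <- function(
    quadratic = list(
      tillering     = c(a0 = 0.60, a1 = 0.0054,  a2 = -1.8e-5),
      booting       = c(a0 = 0.66, a1 = 0.0045,  a2 = -1.5e-5),
      ear_emergence = c(a0 = 0.78, a1 = 0.0030,  a2 = -1.0e-5)),
    bridge = list(
      tillering     = c(b0 = -0.05, b1 = 1.05),
      booting       = c(b0 = -0.10, b1 = 1.10),
      ear_emergence = c(b0 = -0.02, b1 = 1.02)),
    reference_spad = 50,
    reference_ndvi = c(tillering = 0.65, booting = 0.75, ear_emergence = 0.72),
    sn_scale = c(tillering = 35, booting = 80, ear_emergence = 90),
    biomass_scale = c(tillering = 40, booting = 70, ear_emergence = 85),
    lab_n_base = 1.2, lab_n_gain = 2.2,
    lab_chl_base = 0.8, lab_chl_gain = 2.0,
    yield_base = 2.3, yield_slope = 0.024, yield_plateau = 130,
    block_effects = c(-0.15, 0, 0.15),
    noise_sd = c(si_spad = 0.02, si_sensor = 0.02, sn = 1.5, biomass = 2,
                 lab_n = 0.12, lab_chl = 0.35, yield = 0.25),
    stage_noise_mult = c(tillering = 1, booting = 1.8, ear_emergence = 3)) {
  for (s in names(quadratic)) {
    if (quadratic[[s]][["a2"]] >= 0)
      stop("truth quadratic for stage '", s, "' must be concave (a2 < 0)",
           call. = FALSE)
  }
  for (s in names(bridge)) {
    if (bridge[[s]][["b1"]] <= 0)
      stop("truth bridge for stage '", s, "' must have b1 > 0", call. = FALSE)
  }
  if (any(noise_sd < 0) || any(stage_noise_mult < 0))
    stop("noise standard deviations and multipliers must be non-negative",
         call. = FALSE)
  structure(list(
    quadratic = quadratic, bridge = bridge,
    reference_spad = reference_spad, reference_ndvi = reference_ndvi,
    sn_scale = sn_scale, biomass_scale = biomass_scale,
    lab_n_base = lab_n_base, lab_n_gain = lab_n_gain,
    lab_chl_base = lab_chl_base, lab_chl_gain = lab_chl_gain,
    yield_base = yield_base, yield_slope = yield_slope,
    yield_plateau = yield_plateau,
    block_effects = block_effects,
    noise_sd = noise_sd, stage_noise_mult = stage_noise_mult
  ), class = "truth_params")
}

#' Default realistic ground truth
#'
#' @return The default [truth_params()] object.
#' @export
default_truth <- function() truth_params()

#' Ground-truth presets from the published calibrations
#'
#' Truth parameters whose quadratic response and bridge are the published
#' coefficient sets, applied identically at every stage. Intended for exact
#' coefficient-recovery checks, so sufficiency-index noise defaults to zero
#' (set `si_noise_sd` for noisy recovery studies). Note that both published
#' quadratics have their vertex far from 150 kg N/ha, so the generated
#' indices are not confined to a realistic range over the trial's N levels;
#' use [default_truth()] for realistic trials.
#'
#' @param name `"paper_tillering"` or `"paper_booting"`.
#' @param si_noise_sd noise sd applied to both sufficiency indices;
#'   default 0.
#' @return A [truth_params()] object.
#' @export
#' @examples
#' truth_presets("paper_booting")$quadratic$tillering
truth_presets <- function(name = c("paper_tillering", "paper_booting"),
                          si_noise_sd = 0) {
  name <- match.arg(name)
  stage <- sub("^paper_", "", name)
  pub <- .PUBLISHED[[stage]]
  q <- pub$quadratic; b <- pub$bridge
  quad <- stats::setNames(rep(list(q), length(.STAGES)), .STAGES)
  brid <- stats::setNames(rep(list(b), length(.STAGES)), .STAGES)
  truth_params(
    quadratic = quad, bridge = brid,
    noise_sd = c(si_spad = si_noise_sd, si_sensor = si_noise_sd,
                 sn = 0, biomass = 0, lab_n = 0, lab_chl = 0, yield = 0),
    stage_noise_mult = c(tillering = 1, booting = 1, ear_emergence = 1)
  )
}

#' Simulate a synthetic sensor calibration trial
#'
#' Generates one plot-by-stage observation table from a
#' [trial_design()] and [truth_params()]. For each plot and stage the true
#' SPAD sufficiency index is the stage quadratic evaluated at the plot's N
#' rate; Gaussian noise is added, SPAD is the index times the reference
#' SPAD, the sensor sufficiency index comes from inverting the stage
#' bridge (plus noise), NDVI is the sensor index times the stage reference
#' NDVI, and SN and biomass are increasing linear transforms of the sensor
#' index plus noise. Laboratory N and chlorophyll are affine in the true
#' index with stage-dependent noise; grain yield is simulated once per plot
#' (stage-invariant) as a linear-plateau function of N with a block effect.
#'
#' Noise uses a counter-based scheme keyed on (seed, plot, stage,
#' attribute): output is deterministic for a fixed design seed, and the
#' global RNG stream is never consumed.
#'
#' @param design a [trial_design()] object.
#' @param truth a [truth_params()] object.
#' @return data frame with one row per plot and stage and columns
#'   `plot_id`, `replicate`, `stage`, `n_rate`, `spad`, `sn`, `biomass`,
#'   `ndvi`, `lab_n`, `lab_chl`, `yield_t_ha`.
#' @export
#' @examples
#' obs <- simulate_trial(trial_design(seed = 7), default_truth())
#' nrow(obs)  # 54
simulate_trial <- function(design = trial_design(), truth = default_truth()) {
  stopifnot(inherits(design, "trial_design"), inherits(truth, "truth_params"))
  missing_stage <- setdiff(design$stages, names(truth$quadratic))
  if (length(missing_stage))
    stop("truth parameters missing for stage(s): ",
         paste(missing_stage, collapse = ", "), call. = FALSE)

  plots <- expand.grid(replicate = seq_len(design$replicates),
                       n_rate = design$n_levels,
                       KEEP.OUT.ATTRS = FALSE)
  level_index <- match(plots$n_rate, design$n_levels)
  plots$plot_id <- sprintf("R%dN%d", plots$replicate, level_index)

  seed <- design$seed
  sd0 <- truth$noise_sd
  blk <- truth$block_effects[((plots$replicate - 1L) %%
                                length(truth$block_effects)) + 1L]

  # yield: once per plot, stage-invariant
  y_true <- truth$yield_base +
    truth$yield_slope * pmin(plots$n_rate, truth$yield_plateau) + blk
  y_noise <- .keyed_normal(seed, plots$plot_id, "all", "yield")
  yield <- pmax(y_true + sd0[["yield"]] * y_noise, 0)

  rows <- lapply(design$stages, function(stg) {
    qa <- truth$quadratic[[stg]]
    br <- truth$bridge[[stg]]
    mult <- truth$stage_noise_mult[[stg]]
    nr <- plots$n_rate
    si_spad_true <- qa[["a0"]] + qa[["a1"]] * nr + qa[["a2"]] * nr^2
    si_spad <- si_spad_true + sd0[["si_spad"]] * mult *
      .keyed_normal(seed, plots$plot_id, stg, "si_spad")
    si_sensor_true <- (si_spad_true - br[["b0"]]) / br[["b1"]]
    si_sensor <- si_sensor_true + sd0[["si_sensor"]] * mult *
      .keyed_normal(seed, plots$plot_id, stg, "si_sensor")
    ndvi_val <- truth$reference_ndvi[[stg]] * si_sensor
    if (any(abs(ndvi_val) > 1))
      warning("stage '", stg, "': generated NDVI outside [-1, 1]; the ",
              "truth parameters place the response outside the physical ",
              "range at these N rates", call. = FALSE)
    sn <- pmax(truth$sn_scale[[stg]] * si_sensor + sd0[["sn"]] * mult *
                 .keyed_normal(seed, plots$plot_id, stg, "sn"), 0)
    biomass <- pmax(truth$biomass_scale[[stg]] * si_sensor +
                      sd0[["biomass"]] * mult *
                      .keyed_normal(seed, plots$plot_id, stg, "biomass"), 0)
    lab_n <- pmax(truth$lab_n_base + truth$lab_n_gain * si_spad_true +
                    sd0[["lab_n"]] * mult *
                    .keyed_normal(seed, plots$plot_id, stg, "lab_n"), 0)
    lab_chl <- pmax(truth$lab_chl_base + truth$lab_chl_gain * si_spad_true +
                      sd0[["lab_chl"]] * mult *
                      .keyed_normal(seed, plots$plot_id, stg, "lab_chl"), 0)
    data.frame(
      plot_id = plots$plot_id,
      replicate = plots$replicate,
      stage = stg,
      n_rate = nr,
      spad = truth$reference_spad * si_spad,
      sn = sn,
      biomass = biomass,
      ndvi = ndvi_val,
      lab_n = lab_n,
      lab_chl = lab_chl,
      yield_t_ha = yield
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
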