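#' Calibrate the N-sensor against SPAD for one growth stage
#'
#' The package's central fitting function. From a plot observation table it
#' (1) selects the well-fertilized reference values for SPAD and NDVI,
#' (2) computes SPAD and sensor (NDVI) sufficiency indices,
#' (3) fits the quadratic SPAD response to applied N and the linear
#' sensor-to-SPAD bridge by ordinary least squares, and
#' (4) derives the deployable parametric recommendation algorithm
#' \eqn{N_{app} = R\sqrt{SI_R - SI_{sensor}}}.
#'
#' @param data observation data frame (canonical columns; see
#'   [read_observations()]).
#' @param stage growth stage to calibrate (any accepted alias).
#' @param reference reference rule: `"max_n_mean"` (default; per-stage mean
#'   of the plots at the highest applied N rate) or `"fixed"` (use
#'   `ref_spad` / `ref_ndvi` as given).
#' @param ref_spad,ref_ndvi fixed reference values, required when
#'   `reference = "fixed"`.
#' @param aggregate fitting unit: `"plots"` (default; per-plot indices) or
#'   `"means"` (treatment means per N rate before fitting).
#' @param cap soft sufficiency-index cap passed to [sufficiency_index()].
#' @return An object of class `"nsens_cal"`: list with elements `stage`,
#'   `reference` (rule and values used), `quadratic`
#'   ([`quad_response`][fit_quadratic_response]), `bridge`
#'   ([`si_bridge`][fit_si_bridge]), `algorithm`
#'   ([`napp_algorithm`][derive_parametric]), `data` (the stage subset with
#'   `si_spad` and `si_sensor` columns appended) and `call`. Methods:
#'   `print`, `summary`, `coef`, `predict`, `residuals`, `fitted`, `plot`,
#'   `simulate`.
#' @export
#' @examples
#' obs <- simulate_trial(trial_design(seed = 42), default_truth())
#' cal <- calibrate_nsensor(obs, "booting")
#' coef(cal)
#' predict(cal, data.frame(ndvi = c(0.45, 0.70)))
calibrate_nsensor <- function(data, stage,
                              reference = c("max_n_mean", "fixed"),
                              ref_spad = NULL, ref_ndvi = NULL,
                              aggregate = c("plots", "means"),
                              cap = 2) {
  reference <- match.arg(reference)
  aggregate <- match.arg(aggregate)
  stage <- canonical_stage(stage)
  need <- c("stage", "n_rate", "spad", "ndvi")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("data missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  obs <- data[canonical_stage(data$stage) == stage, , drop = FALSE]
  if (nrow(obs) == 0L)
    stop("no observations at stage '", stage, "'", call. = FALSE)

  if (reference == "max_n_mean") {
    ref_spad <- reference_from_trial(obs, stage, "spad")
    ref_ndvi <- reference_from_trial(obs, stage, "ndvi")
  } else {
    if (is.null(ref_spad) || is.null(ref_ndvi))
      stop("reference = \"fixed\" requires ref_spad and ref_ndvi",
           call. = FALSE)
  }
  obs$si_spad <- as.numeric(sufficiency_index(obs$spad, ref_spad,
                                              basis = "spad", cap = cap))
  obs$si_sensor <- as.numeric(si_ndvi(obs$ndvi, ref_ndvi, cap = cap))

  if (aggregate == "means") {
    fit_df <- stats::aggregate(obs[c("si_spad", "si_sensor")],
                               by = list(n_rate = obs$n_rate), FUN = mean)
  } else {
    fit_df <- obs
  }
  quad <- fit_quadratic_response(fit_df$n_rate, fit_df$si_spad)
  bridge <- fit_si_bridge(fit_df$si_sensor, fit_df$si_spad)
  alg <- derive_parametric(quad, bridge, stage)

  structure(list(
    stage = stage,
    reference = list(rule = reference, spad = ref_spad, ndvi = ref_ndvi),
    quadratic = quad,
    bridge = bridge,
    algorithm = alg,
    aggregate = aggregate,
    data = obs,
    call = match.call()
  ), class = "nsens_cal")
}

#' @export
print.nsens_cal <- function(x, ...) {
  cat("N-sensor calibration -- stage:", x$stage, "\n")
  qa <- x$quadratic$coefficients; br <- x$bridge$coefficients
  cat(sprintf("  SI_SPAD  = %.6g + %.6g N + %.6g N^2\n",
              qa[["a0"]], qa[["a1"]], qa[["a2"]]))
  cat(sprintf("  SI_SPAD  = %.6g + %.6g SI_sensor\n",
              br[["b0"]], br[["b1"]]))
  cat(sprintf("  N_app    = %.2f * sqrt(%.4g - SI_sensor)  [kg N/ha]\n",
              x$algorithm$R, x$algorithm$SI_R))
  invisible(x)
}

#' @export
summary.nsens_cal <- function(object, ...) {
  out <- list(
    stage = object$stage,
    reference = object$reference,
    coefficients = coef(object),
    r_squared = c(quadratic = object$quadratic$r_squared,
                  bridge = object$bridge$r_squared),
    n = c(quadratic = object$quadratic$n_points,
          bridge = object$bridge$n_points),
    nrate_max = nrate_max(object$quadratic),
    si_max = si_max(object$quadratic)
  )
  class(out) <- "summary.nsens_cal"
  out
}

#' @export
print.summary.nsens_cal <- function(x, ...) {
  cat("N-sensor calibration summary -- stage:", x$stage, "\n")
  cat("  reference rule:", x$reference$rule,
      sprintf(" (SPAD %.4g, NDVI %.4g)\n", x$reference$spad, x$reference$ndvi))
  cat("  coefficients:\n")
  print(round(x$coefficients, 6))
  cat(sprintf("  R-squared: quadratic %.4f, bridge %.4f  (n = %d, %d)\n",
              x$r_squared[["quadratic"]], x$r_squared[["bridge"]],
              x$n[["quadratic"]], x$n[["bridge"]]))
  cat(sprintf("  N rate at max SI: %.4g kg N/ha, SI_max: %.4g\n",
              x$nrate_max, x$si_max))
  invisible(x)
}

#' @export
coef.nsens_cal <- function(object, ...) {
  c(object$quadratic$coefficients, object$bridge$coefficients,
    R = object$algorithm$R, SI_R = object$algorithm$SI_R)
}

#' Predict per-plot N recommendations from a calibration
#'
#' @param object an [`nsens_cal`][calibrate_nsensor] object.
#' @param newdata data frame with an `si_sensor` column, or an `ndvi`
#'   column (converted using the calibration's stored NDVI reference).
#'   Default: the calibration's own data.
#' @param mode `"algorithm"` (the parametric algorithm, default) or
#'   `"spad"` (invert the quadratic from the SPAD sufficiency index in
#'   `newdata$si_spad` / `newdata$spad`).
#' @param ... unused.
#' @return numeric vector of recommended rates (kg N/ha) with the flag
#'   attributes of [napp()] / [napp_from_si_spad()].
#' @export
predict.nsens_cal <- function(object, newdata = NULL,
                              mode = c("algorithm", "spad"), ...) {
  mode <- match.arg(mode)
  if (is.null(newdata)) newdata <- object$data
  if (mode == "algorithm") {
    si <- if ("si_sensor" %in% names(newdata)) newdata$si_sensor
          else if ("ndvi" %in% names(newdata))
            as.numeric(si_ndvi(newdata$ndvi, object$reference$ndvi))
          else stop("newdata needs an si_sensor or ndvi column", call. = FALSE)
    napp(object$algorithm, pmax(si, 0))
  } else {
    si <- if ("si_spad" %in% names(newdata)) newdata$si_spad
          else if ("spad" %in% names(newdata))
            as.numeric(sufficiency_index(newdata$spad, object$reference$spad,
                                         basis = "spad"))
          else stop("newdata needs an si_spad or spad column", call. = FALSE)
    napp_from_si_spad(object$quadratic, si)
  }
}

#' @export
residuals.nsens_cal <- function(object,
                                model = c("quadratic", "bridge"), ...) {
  model <- match.arg(model)
  if (model == "quadratic") object$quadratic$residuals
  else object$bridge$residuals
}

#' @export
fitted.nsens_cal <- function(object, model = c("quadratic", "bridge"), ...) {
  model <- match.arg(model)
  if (model == "quadratic") object$quadratic$fitted else object$bridge$fitted
}

#' Diagnostic plots for an N-sensor calibration
#'
#' Three base-graphics panels: the quadratic SPAD sufficiency-index
#' response to applied N, the linear sensor-to-SPAD bridge, and the derived
#' recommendation curve \eqn{N_{app}(SI_{sensor})}.
#'
#' @param x an [`nsens_cal`][calibrate_nsensor] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.nsens_cal <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  d <- x$data
  if (!is.null(d)) {
    graphics::plot(d$n_rate, d$si_spad, xlab = "N rate (kg N/ha)",
                   ylab = "SI_SPAD", main = paste("Response,", x$stage), ...)
    nn <- seq(min(d$n_rate), max(d$n_rate), length.out = 101)
    graphics::lines(nn, predict(x$quadratic, nn))
    graphics::plot(d$si_sensor, d$si_spad, xlab = "SI_sensor",
                   ylab = "SI_SPAD", main = "Bridge", ...)
    ss <- range(d$si_sensor)
    graphics::abline(x$bridge$coefficients[["b0"]],
                     x$bridge$coefficients[["b1"]])
  }
  si <- seq(0, x$algorithm$SI_R * 1.1, length.out = 201)
  graphics::plot(si, as.numeric(napp(x$algorithm, si)), type = "l",
                 xlab = "SI_sensor", ylab = "N_app (kg N/ha)",
                 main = "Recommendation", ...)
  invisible(x)
}

#' Simulate sufficiency-index data from a fitted calibration
#'
#' Draws new (N rate, SI_SPAD, SI_sensor) triples from the fitted quadratic
#' response and bridge, with Gaussian noise at the fits' residual standard
#' deviations, at the calibration data's N rates.
#'
#' @param object an [`nsens_cal`][calibrate_nsensor] object fitted to data.
#' @param nsim number of simulated datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of `nsim` data frames with columns `n_rate`, `si_spad`,
#'   `si_sensor`.
#' @export
simulate.nsens_cal <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$data))
    stop("calibration carries no data to resimulate from", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nr <- object$data$n_rate
  sd_q <- stats::sd(object$quadratic$residuals)
  sd_b <- stats::sd(object$bridge$residuals)
  br <- object$bridge$coefficients
  lapply(seq_len(nsim), function(i) {
    si_spad_true <- predict(object$quadratic, nr)
    si_sensor <- (si_spad_true - br[["b0"]]) / br[["b1"]] +
      stats::rnorm(length(nr), sd = sd_b / br[["b1"]])
    si_spad <- si_spad_true + stats::rnorm(length(nr), sd = sd_q)
    data.frame(n_rate = nr, si_spad = si_spad, si_sensor = si_sensor)
  })
}

#' Per-plot N recommendations from observations
#'
#' Issues a recommendation for every plot of a stage, either through a
#' parametric algorithm (`mode = "algorithm"`) applied to the sensor
#' sufficiency index, or through an SN-value lookup table (`mode = "sn"`)
#' applied to the raw sensor value. Rates are reported to 1 decimal
#' kg N/ha; flags record plots at sufficiency, interpolated lookups and
#' extrapolated sensor values.
#'
#' @param observations observation data frame.
#' @param stage growth stage.
#' @param mode `"algorithm"` or `"sn"`.
#' @param algorithm a [`napp_algorithm`][derive_parametric] object;
#'   default the published algorithm for the stage.
#' @param table an [`sn_table`][sn_table]; default the published table for
#'   the stage.
#' @param reference_ndvi NDVI reference for converting the `ndvi` column to
#'   the sensor sufficiency index (algorithm mode). Default: trial
#'   reference via [reference_from_trial()]. Ignored if the data already
#'   has an `si_sensor` column.
#' @return data frame with columns `plot_id`, `stage`, the sensor input
#'   (`si_sensor` or `sn`), `n_app_kg_ha` and `flags`.
#' @export
recommend_n <- function(observations, stage, mode = c("algorithm", "sn"),
                        algorithm = NULL, table = NULL,
                        reference_ndvi = NULL) {
  mode <- match.arg(mode)
  stage <- canonical_stage(stage)
  obs <- observations[canonical_stage(observations$stage) == stage, ,
                      drop = FALSE]
  if (nrow(obs) == 0L)
    stop("no observations at stage '", stage, "'", call. = FALSE)
  if (mode == "algorithm") {
    if (is.null(algorithm)) algorithm <- published_algorithm(stage)
    if ("si_sensor" %in% names(obs)) {
      si <- obs$si_sensor
    } else {
      if (is.null(reference_ndvi))
        reference_ndvi <- reference_from_trial(obs, stage, "ndvi")
      si <- as.numeric(si_ndvi(obs$ndvi, reference_ndvi))
    }
    rate <- napp(algorithm, pmax(si, 0))
    flags <- ifelse(attr(rate, "at_sufficiency"), "at_sufficiency", "")
    data.frame(plot_id = obs$plot_id, stage = stage,
               si_sensor = si, n_app_kg_ha = round(as.numeric(rate), 1),
               flags = flags)
  } else {
    if (is.null(table)) table <- sn_lookup_table(stage)
    rate <- recommend_from_sn(table, obs$sn)
    flags <- rep("", nrow(obs))
    flags[attr(rate, "interpolated")] <- "interpolated"
    flags[attr(rate, "extrapolated")] <- "extrapolated"
    data.frame(plot_id = obs$plot_id, stage = stage,
               sn = obs$sn, n_app_kg_ha = round(as.numeric(rate), 1),
               flags = flags)
  }
}

#' Run the calibrate-and-recommend pipeline end to end
#'
#' Reads (or takes) an observation table, calibrates the requested stage
#' ([calibrate_nsensor()]), issues per-plot recommendations with the
#' derived algorithm, and optionally writes the calibration artifact JSON
#' and the recommendation CSV.
#'
#' @param observations observation data frame or a CSV path (read via
#'   [read_observations()]).
#' @param stage growth stage.
#' @param out_dir optional output directory; when given,
#'   `calibration_<stage>.json` and `recommendations_<stage>.csv` are
#'   written there.
#' @param mode recommendation mode, `"algorithm"` (default, using the
#'   derived calibration) or `"sn"` (published SN lookup).
#' @param verbose log fitted coefficients to the console.
#' @inheritParams calibrate_nsensor
#' @return list with `calibration` (`nsens_cal`), `recommendations`
#'   (data frame), `artifact` (list) and `paths` (written files, if any).
#' @export
run_pipeline <- function(observations, stage,
                         reference = c("max_n_mean", "fixed"),
                         ref_spad = NULL, ref_ndvi = NULL,
                         aggregate = c("plots", "means"),
                         mode = c("algorithm", "sn"),
                         out_dir = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  input <- NULL
  if (is.character(observations)) {
    input <- observations
    observations <- read_observations(observations)
  }
  stage <- canonical_stage(stage)
  cal <- calibrate_nsensor(observations, stage, reference = reference,
                           ref_spad = ref_spad, ref_ndvi = ref_ndvi,
                           aggregate = aggregate)
  cal$artifact <- .build_artifact(
    cal, input = input,
    options = list(aggregate = cal$aggregate, mode = mode))
  if (verbose) {
    message("stage ", stage, ": a = (",
            paste(signif(cal$quadratic$coefficients, 6), collapse = ", "),
            "), b = (",
            paste(signif(cal$bridge$coefficients, 6), collapse = ", "),
            "), R = ", signif(cal$algorithm$R, 6),
            ", SI_R = ", signif(cal$algorithm$SI_R, 6))
  }
  rec <- if (mode == "algorithm") {
    recommend_n(cal$data, stage, mode = "algorithm",
                algorithm = cal$algorithm,
                reference_ndvi = cal$reference$ndvi)
  } else {
    recommend_n(observations, stage, mode = "sn")
  }
  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths$artifact <- file.path(out_dir,
                                paste0("calibration_", stage, ".json"))
    write_calibration(cal, paths$artifact)
    paths$recommendations <- file.path(
      out_dir, paste0("recommendations_", stage, ".csv"))
    utils::write.csv(rec, paths$recommendations, row.names = FALSE,
                     quote = FALSE)
  }
  list(calibration = cal, recommendations = rec,
       artifact = cal$artifact, paths = paths)
}
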