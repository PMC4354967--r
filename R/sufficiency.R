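#' Normalized difference vegetation index
#'
#' NDVI from red and near-infrared canopy reflectance,
#' \eqn{(NIR - red)/(NIR + red)}. Always in `[-1, 1]`.
#'
#' @param red,nir reflectance in each band, dimensionless, non-negative with
#'   `red + nir > 0`. Vectorized.
#' @return numeric vector of NDVI values.
#' @export
#' @examples
#' ndvi(red = 0.1, nir = 0.5)  # 0.6667
ndvi <- function(red, nir) {
  if (length(red) != length(nir))
    stop("red and nir must have the same length", call. = FALSE)
  if (any(!is.finite(red)) || any(!is.finite(nir)) ||
      any(red < 0) || any(nir < 0))
    stop("reflectance values must be finite and non-negative", call. = FALSE)
  if (any(red + nir == 0))
    stop("undefined NDVI: red + nir must be > 0", call. = FALSE)
  (nir - red) / (nir + red)
}

#' Sufficiency index relative to a well-fertilized reference
#'
#' The sufficiency index (SI) is the ratio of a target plot's reading to the
#' reading of a non-N-limited reference: SI = target / reference. An SI of 1
#' means the crop is N sufficient; values below 1 indicate deficiency (the
#' lower the SI, the more N is needed). Values above 1 (target greener than
#' the reference) are passed through unchanged; values above `cap` are
#' flagged as suspicious rather than clamped.
#'
#' @param target reading(s) of the target plot (reflectance, NDVI or SPAD
#'   scale). Vectorized.
#' @param reference scalar reading of the reference; must be strictly
#'   positive.
#' @param basis which scale the readings are on: `"reflectance"`, `"ndvi"`
#'   or `"spad"`. Informational.
#' @param cap soft upper bound; SI values above it are flagged via the
#'   `"flagged"` attribute and a warning. Default 2.
#' @return numeric vector of SI values with attributes `basis` and
#'   `flagged` (logical vector).
#' @export
#' @examples
#' sufficiency_index(0.40, 0.80)  # 0.5: deficient
sufficiency_index <- function(target,
                              reference,
                              basis = c("reflectance", "ndvi", "spad"),
                              cap = 2) {
  basis <- match.arg(basis)
  .check_scalar_number(reference, "reference", lower = 0, strict_lower = TRUE)
  if (any(!is.finite(target)))
    stop("target readings must be finite", call. = FALSE)
  value <- target / reference
  flagged <- value > cap
  if (any(flagged))
    warning(sum(flagged), " sufficiency index value(s) exceed the cap of ",
            cap, "; flagged, not clamped", call. = FALSE)
  structure(value, basis = basis, flagged = flagged)
}

#' NDVI-based sufficiency index
#'
#' SI_sensor computed from NDVI: target NDVI over the NDVI of the
#' well-fertilized reference.
#'
#' @param target_ndvi NDVI of the target plot(s).
#' @param reference_ndvi scalar NDVI of the reference; must be positive.
#' @param cap see [sufficiency_index()].
#' @return numeric vector of SI values (basis `"ndvi"`).
#' @export
si_ndvi <- function(target_ndvi, reference_ndvi, cap = 2) {
  sufficiency_index(target_ndvi, reference_ndvi, basis = "ndvi", cap = cap)
}

#' Reference value from the trial's well-fertilized plots
#'
#' The reference for SI normalization defaults to the mean of the chosen
#' attribute over the plots receiving the highest applied N rate at the
#' requested stage (the trial's stand-in for a dedicated reference strip).
#'
#' @param observations data frame of plot observations (see
#'   [simulate_trial()] / [read_observations()] for the canonical columns).
#' @param stage growth stage (any accepted alias).
#' @param attribute column to average; default `"ndvi"`.
#' @param level N rate (kg N/ha) defining the reference treatment; default
#'   the highest rate present at the stage.
#' @param statistic aggregation over qualifying plots: `"mean"` (default) or
#'   `"median"`.
#' @return scalar reference value.
#' @export
reference_from_trial <- function(observations, stage, attribute = "ndvi",
                                 level = NULL,
                                 statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  stage <- canonical_stage(stage)
  if (!attribute %in% names(observations))
    stop("attribute column '", attribute, "' not found in observations",
         call. = FALSE)
  obs <- observations[canonical_stage(observations$stage) == stage, ,
                      drop = FALSE]
  if (nrow(obs) == 0L)
    stop("no observations at stage '", stage, "'", call. = FALSE)
  if (is.null(level)) level <- max(obs$n_rate)
  ref <- obs[obs$n_rate == level, attribute]
  ref <- ref[is.finite(ref)]
  if (length(ref) == 0L)
    stop("no reference plots at ", level, " kg N/ha for stage '", stage, "'",
         call. = FALSE)
  if (statistic == "mean") mean(ref) else stats::median(ref)
}
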