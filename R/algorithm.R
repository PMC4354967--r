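#' N rate maximizing the quadratic SPAD response
#'
#' Vertex abscissa of the concave quadratic response:
#' \eqn{N_{rate,max} = -a_1 / (2 a_2)}. Requires \eqn{a_2 < 0}; a negative
#' vertex (decreasing response over the whole positive range) warns.
#'
#' @param q a [`quad_response`][fit_quadratic_response] object.
#' @return scalar kg N/ha.
#' @export
nrate_max <- function(q) {
  cf <- q$coefficients
  if (cf[["a2"]] >= 0)
    stop("non-concave response (a2 >= 0): N rate at maximum is undefined",
         call. = FALSE)
  v <- -cf[["a1"]] / (2 * cf[["a2"]])
  if (v < 0)
    warning("vertex N rate is negative (", signif(v, 4),
            " kg N/ha); the response decreases over the whole positive range",
            call. = FALSE)
  v
}

#' Maximum attainable SPAD sufficiency index
#'
#' Value of the concave quadratic at its vertex:
#' \eqn{SI_{max} = a_0 - a_1^2 / (4 a_2)}.
#'
#' @inheritParams nrate_max
#' @return scalar SI value.
#' @export
si_max <- function(q) {
  cf <- q$coefficients
  if (cf[["a2"]] >= 0)
    stop("non-concave response (a2 >= 0): SI maximum is undefined",
         call. = FALSE)
  cf[["a0"]] - cf[["a1"]]^2 / (4 * cf[["a2"]])
}

#' Invert the quadratic response: N rate for a target SPAD sufficiency index
#'
#' Solves \eqn{SI_{SPAD} = a_0 + a_1 N + a_2 N^2} for \eqn{N}, taking the
#' root on the ascending branch (the one at or below [nrate_max()]), clamped
#' to be non-negative. SI values above the attainable maximum return
#' `nrate_max` with the `at_max` flag set; values below the zero-N response
#' clamp to 0 with the `clamped` flag set.
#'
#' @inheritParams nrate_max
#' @param si_spad target SPAD sufficiency index (vectorized).
#' @return numeric vector of N rates (kg N/ha) with logical attribute
#'   vectors `at_max` and `clamped`.
#' @export
nrate_for_si <- function(q, si_spad) {
  cf <- q$coefficients
  a0 <- cf[["a0"]]; a1 <- cf[["a1"]]; a2 <- cf[["a2"]]
  if (a2 >= 0)
    stop("non-concave response (a2 >= 0): inversion is undefined",
         call. = FALSE)
  vmax <- -a1 / (2 * a2)
  disc <- a1^2 - 4 * a2 * (a0 - si_spad)
  at_max <- disc < 0
  root <- rep(NA_real_, length(si_spad))
  # ascending branch: with a2 < 0 the "+sqrt" root is the smaller one
  root[!at_max] <- (-a1 + sqrt(disc[!at_max])) / (2 * a2)
  root[at_max] <- vmax
  clamped <- !at_max & root < 0
  root[clamped] <- 0
  structure(root, at_max = at_max, clamped = clamped)
}

#' N application rate from a SPAD sufficiency index
#'
#' The deficit between the yield-maximizing rate and the rate the crop's
#' current status corresponds to:
#' \eqn{N_{app} = N_{rate,max} - N_{rate}(SI_{SPAD})}. Equivalently, for
#' \eqn{SI \le SI_{max}}, \eqn{N_{app} = \sqrt{(SI_{max} - SI)/|a_2|}}.
#' Zero at or above the attainable maximum SI.
#'
#' @inheritParams nrate_for_si
#' @return numeric vector of recommended rates (kg N/ha), non-negative,
#'   with attributes carried over from [nrate_for_si()].
#' @export
napp_from_si_spad <- function(q, si_spad) {
  n <- nrate_for_si(q, si_spad)
  out <- pmax(nrate_max(q) - as.numeric(n), 0)
  structure(out, at_max = attr(n, "at_max"), clamped = attr(n, "clamped"))
}

#' Derive the parametric recommendation algorithm from a calibration
#'
#' Composes the quadratic response inversion with the linear
#' sensor-to-SPAD bridge into the closed-form recommendation
#' \deqn{N_{app} = R \sqrt{SI_R - SI_{sensor}},}
#' with \eqn{R = \sqrt{-b_1 / a_2}} and
#' \eqn{SI_R = (4 a_2 a_0 - a_1^2 - 4 a_2 b_0) / (4 a_2 b_1)}
#' (the sensor SI at which the recommendation reaches zero). Requires a
#' concave response (\eqn{a_2 < 0}) and an increasing bridge
#' (\eqn{b_1 > 0}).
#'
#' @param q a [`quad_response`][fit_quadratic_response] object with
#'   \eqn{a_2 < 0}.
#' @param m an [`si_bridge`][fit_si_bridge] object with \eqn{b_1 > 0}.
#' @param stage optional growth-stage label attached to the result.
#' @return An object of class `"napp_algorithm"`: list with `R`
#'   (kg N/ha per unit \eqn{\sqrt{SI}}), `SI_R`, `stage`,
#'   `provenance = "derived"` and the source `coefficients`.
#' @export
#' @examples
#' cal <- published_coefficients("booting")
#' derive_parametric(cal$quadratic, cal$bridge, "booting")$R  # ~51.90
derive_parametric <- function(q, m, stage = NULL) {
  a <- q$coefficients; b <- m$coefficients
  a0 <- a[["a0"]]; a1 <- a[["a1"]]; a2 <- a[["a2"]]
  b0 <- b[["b0"]]; b1 <- b[["b1"]]
  if (a2 >= 0)
    stop("cannot derive algorithm: quadratic response is not concave (a2 >= 0)",
         call. = FALSE)
  if (b1 <= 0)
    stop("cannot derive algorithm: bridge slope b1 must be positive",
         call. = FALSE)
  if (-b1 / a2 <= 0)
    stop("cannot derive algorithm: -b1/a2 must be positive", call. = FALSE)
  R <- sqrt(-b1 / a2)
  SI_R <- (4 * a2 * a0 - a1^2 - 4 * a2 * b0) / (4 * a2 * b1)
  if (!is.null(stage)) stage <- canonical_stage(stage)
  structure(list(
    R = R, SI_R = SI_R, stage = stage, provenance = "derived",
    coefficients = list(quadratic = a, bridge = b)
  ), class = "napp_algorithm")
}

#' Published stage recommendation algorithms
#'
#' The deployable parametric algorithms published for tillering
#' (\eqn{N_{app} = 87.17\sqrt{1.35 - SI_{sensor}}}) and booting
#' (\eqn{N_{app} = 51.89\sqrt{1.33 - SI_{sensor}}}), as fixtures.
#'
#' @param stage `"tillering"` or `"booting"` (aliases accepted).
#' @return A `"napp_algorithm"` object with `provenance = "published"`.
#' @export
published_algorithm <- function(stage) {
  stage <- canonical_stage(stage)
  if (!stage %in% names(.PUBLISHED))
    stop("no published algorithm for stage '", stage,
         "'; available: ", paste(names(.PUBLISHED), collapse = ", "),
         call. = FALSE)
  alg <- .PUBLISHED[[stage]]$algorithm
  structure(list(
    R = alg[["R"]], SI_R = alg[["SI_R"]], stage = stage,
    provenance = "published", coefficients = NULL
  ), class = "napp_algorithm")
}

#' N recommendation from the parametric algorithm
#'
#' Evaluates \eqn{N_{app} = R \sqrt{\max(SI_R - SI_{sensor},\, 0)}}: zero at
#' or above \eqn{SI_R} (crop at sufficiency), strictly decreasing in the
#' sensor sufficiency index below it.
#'
#' @param alg a [`napp_algorithm`][derive_parametric] object.
#' @param si_sensor sensor sufficiency index values (vectorized,
#'   non-negative).
#' @return numeric vector of recommended rates (kg N/ha) with logical
#'   attribute `at_sufficiency`.
#' @export
#' @examples
#' napp(published_algorithm("booting"), 0.33)  # 51.89
napp <- function(alg, si_sensor) {
  if (any(!is.finite(si_sensor)) || any(si_sensor < 0))
    stop("si_sensor values must be finite and non-negative", call. = FALSE)
  deficit <- alg$SI_R - si_sensor
  at_suff <- deficit <= 0
  structure(alg$R * sqrt(pmax(deficit, 0)), at_sufficiency = at_suff)
}

#' @export
print.napp_algorithm <- function(x, ...) {
  cat("Parametric N recommendation algorithm (", x$provenance, ")\n", sep = "")
  if (!is.null(x$stage)) cat("  stage: ", x$stage, "\n", sep = "")
  cat(sprintf("  N_app = %.2f * sqrt(%.4g - SI_sensor)  [kg N/ha]\n",
              x$R, x$SI_R))
  invisible(x)
}

#' @export
predict.napp_algorithm <- function(object, si_sensor, ...) {
  napp(object, si_sensor)
}

#' @export
coef.napp_algorithm <- function(object, ...) {
  c(R = object$R, SI_R = object$SI_R)
}
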