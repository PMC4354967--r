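#' Fit the quadratic SPAD sufficiency-index response to applied N
#'
#' Ordinary least squares fit of the concave response model
#' \deqn{SI_{SPAD} = a_0 + a_1 N_{rate} + a_2 N_{rate}^2.}
#' A usable calibration has \eqn{a_2 < 0} (concave): a non-negative
#' quadratic term triggers a warning here and a hard error when the fit is
#' passed to [derive_parametric()], so exploratory fits remain inspectable.
#'
#' @param n_rate applied N rates, kg N/ha; at least 3 distinct values.
#' @param si_spad SPAD sufficiency indices, same length.
#' @return An object of class `"quad_response"`: list with `coefficients`
#'   (named `a0`, `a1`, `a2`), `r_squared`, `n_points`, `fitted`,
#'   `residuals`, `concave` (logical) and `provenance = "fitted"`.
#' @seealso [fit_si_bridge()], [derive_parametric()], [nrate_max()]
#' @export
#' @examples
#' n <- c(0, 30, 60, 90, 120, 150)
#' si <- 0.542 + 0.003 * n - 0.0006 * n^2
#' fit_quadratic_response(n, si)$coefficients
fit_quadratic_response <- function(n_rate, si_spad) {
  if (length(n_rate) != length(si_spad))
    stop("n_rate and si_spad must have the same length", call. = FALSE)
  ok <- is.finite(n_rate) & is.finite(si_spad)
  n_rate <- n_rate[ok]; si_spad <- si_spad[ok]
  if (length(n_rate) < 3L || length(unique(n_rate)) < 3L)
    stop("rank deficiency: need at least 3 distinct N rates to fit a quadratic",
         call. = FALSE)
  fit <- stats::lm(si_spad ~ n_rate + I(n_rate^2))
  cf <- unname(stats::coef(fit))
  res <- unname(stats::residuals(fit))
  sst <- sum((si_spad - mean(si_spad))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
  concave <- cf[3] < 0
  if (!concave)
    warning("fitted quadratic term a2 >= 0: response is not concave; ",
            "this calibration cannot be used for algorithm derivation",
            call. = FALSE)
  structure(list(
    coefficients = c(a0 = cf[1], a1 = cf[2], a2 = cf[3]),
    r_squared = r2,
    n_points = length(n_rate),
    fitted = unname(stats::fitted(fit)),
    residuals = res,
    concave = concave,
    provenance = "fitted"
  ), class = "quad_response")
}

#' Fit the linear sensor-to-SPAD sufficiency-index bridge
#'
#' Ordinary least squares fit of
#' \deqn{SI_{SPAD} = b_0 + b_1 \, SI_{sensor}.}
#' A usable bridge has \eqn{b_1 > 0} (SPAD sufficiency must increase with
#' the sensor index); a non-positive slope warns here and errors at
#' derivation time.
#'
#' @param si_sensor sensor (NDVI-based) sufficiency indices; at least 2
#'   distinct values.
#' @param si_spad SPAD sufficiency indices, same length.
#' @return An object of class `"si_bridge"`: list with `coefficients`
#'   (named `b0`, `b1`), `r_squared`, `n_points`, `fitted`, `residuals`,
#'   `increasing` (logical) and `provenance = "fitted"`.
#' @export
#' @examples
#' x <- c(0.6, 0.8, 1.0); fit_si_bridge(x, -0.608 + 1.616 * x)$coefficients
fit_si_bridge <- function(si_sensor, si_spad) {
  if (length(si_sensor) != length(si_spad))
    stop("si_sensor and si_spad must have the same length", call. = FALSE)
  ok <- is.finite(si_sensor) & is.finite(si_spad)
  si_sensor <- si_sensor[ok]; si_spad <- si_spad[ok]
  if (length(si_sensor) < 2L || length(unique(si_sensor)) < 2L)
    stop("rank deficiency: need at least 2 distinct si_sensor values",
         call. = FALSE)
  fit <- stats::lm(si_spad ~ si_sensor)
  cf <- unname(stats::coef(fit))
  res <- unname(stats::residuals(fit))
  sst <- sum((si_spad - mean(si_spad))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
  increasing <- cf[2] > 0
  if (!increasing)
    warning("fitted bridge slope b1 <= 0: SI_SPAD does not increase with ",
            "SI_sensor; this calibration cannot be used for algorithm ",
            "derivation", call. = FALSE)
  structure(list(
    coefficients = c(b0 = cf[1], b1 = cf[2]),
    r_squared = r2,
    n_points = length(si_sensor),
    fitted = unname(stats::fitted(fit)),
    residuals = res,
    increasing = increasing,
    provenance = "fitted"
  ), class = "si_bridge")
}

# Constructors for calibrations supplied as bare coefficients (published
# fixtures, artifacts reloaded from JSON).
.quad_response_from_coef <- function(a0, a1, a2, r_squared = NA_real_,
                                     n_points = NA_integer_,
                                     provenance = "published") {
  structure(list(
    coefficients = c(a0 = a0, a1 = a1, a2 = a2),
    r_squared = r_squared, n_points = n_points,
    fitted = NULL, residuals = NULL,
    concave = a2 < 0, provenance = provenance
  ), class = "quad_response")
}

.si_bridge_from_coef <- function(b0, b1, r_squared = NA_real_,
                                 n_points = NA_integer_,
                                 provenance = "published") {
  structure(list(
    coefficients = c(b0 = b0, b1 = b1),
    r_squared = r_squared, n_points = n_points,
    fitted = NULL, residuals = NULL,
    increasing = b1 > 0, provenance = provenance
  ), class = "si_bridge")
}

# Published per-stage calibration coefficient sets, stored verbatim.
# The tillering quadratic implies SI_SPAD values far outside the plausible
# sufficiency range at high N (a misprinted scale in the source material);
# it is kept verbatim and flagged wherever it matters.
.PUBLISHED <- list(
  tillering = list(quadratic = c(a0 = -0.047, a1 = 0.2649, a2 = -0.00013),
                   bridge = c(b0 = -0.0056, b1 = 1.0461),
                   algorithm = c(R = 87.17, SI_R = 1.35)),
  booting   = list(quadratic = c(a0 = 0.542, a1 = 0.003, a2 = -0.0006),
                   bridge = c(b0 = -0.608, b1 = 1.616),
                   algorithm = c(R = 51.89, SI_R = 1.33))
)

#' Published stage calibration coefficients
#'
#' Returns the published quadratic-response and linear-bridge coefficient
#' sets for a growth stage, verbatim, as fixture objects. Calibrations are
#' published for tillering and booting only.
#'
#' @param stage `"tillering"` or `"booting"` (aliases accepted).
#' @return list with elements `quadratic` (a [`quad_response`
#'   object][fit_quadratic_response]) and `bridge` (an [`si_bridge`
#'   object][fit_si_bridge]), both with `provenance = "published"`.
#' @export
#' @examples
#' published_coefficients("booting")$quadratic$coefficients
published_coefficients <- function(stage) {
  stage <- canonical_stage(stage)
  if (!stage %in% names(.PUBLISHED))
    stop("no published calibration for stage '", stage,
         "'; available: ", paste(names(.PUBLISHED), collapse = ", "),
         call. = FALSE)
  p <- .PUBLISHED[[stage]]
  q <- p$quadratic; b <- p$bridge
  list(
    quadratic = .quad_response_from_coef(q[["a0"]], q[["a1"]], q[["a2"]]),
    bridge = .si_bridge_from_coef(b[["b0"]], b[["b1"]]),
    stage = stage
  )
}

#' @export
print.quad_response <- function(x, ...) {
  cf <- x$coefficients
  cat("Quadratic SI_SPAD response to N rate (", x$provenance, ")\n", sep = "")
  cat(sprintf("  SI_SPAD = %.6g + %.6g * N + %.6g * N^2\n",
              cf[["a0"]], cf[["a1"]], cf[["a2"]]))
  if (!is.na(x$r_squared)) cat(sprintf("  R-squared: %.4f", x$r_squared))
  if (!is.na(x$n_points)) cat(sprintf("   n = %d", x$n_points))
  cat("\n")
  if (!x$concave) cat("  WARNING: not concave (a2 >= 0)\n")
  invisible(x)
}

#' @export
print.si_bridge <- function(x, ...) {
  cf <- x$coefficients
  cat("Linear SI_sensor -> SI_SPAD bridge (", x$provenance, ")\n", sep = "")
  cat(sprintf("  SI_SPAD = %.6g + %.6g * SI_sensor\n",
              cf[["b0"]], cf[["b1"]]))
  if (!is.na(x$r_squared)) cat(sprintf("  R-squared: %.4f", x$r_squared))
  if (!is.na(x$n_points)) cat(sprintf("   n = %d", x$n_points))
  cat("\n")
  if (!x$increasing) cat("  WARNING: non-increasing (b1 <= 0)\n")
  invisible(x)
}

#' @export
coef.quad_response <- function(object, ...) object$coefficients

#' @export
coef.si_bridge <- function(object, ...) object$coefficients

#' @export
predict.quad_response <- function(object, n_rate, ...) {
  cf <- object$coefficients
  cf[["a0"]] + cf[["a1"]] * n_rate + cf[["a2"]] * n_rate^2
}

#' @export
predict.si_bridge <- function(object, si_sensor, ...) {
  cf <- object$coefficients
  cf[["b0"]] + cf[["b1"]] * si_sensor
}
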