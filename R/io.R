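# Canonical observation CSV columns.
.OBS_COLUMNS <- c("plot_id", "replicate", "stage", "n_rate", "spad", "sn",
                  "biomass", "ndvi", "lab_n", "lab_chl", "yield_t_ha")
.OBS_NUMERIC <- setdiff(.OBS_COLUMNS, c("plot_id", "stage"))

#' Read a plot observation CSV
#'
#' Reads and validates the canonical observation table
#' (`plot_id, replicate, stage, n_rate, spad, sn, biomass, ndvi, lab_n,
#' lab_chl, yield_t_ha`). Stage labels are canonicalized (names, DAS codes
#' and decimal codes accepted); unknown extra columns are preserved but
#' ignored. Validation is fail-fast with row-numbered diagnostics:
#' non-numeric cells and NDVI outside `[-1, 1]` are errors.
#'
#' @param path CSV file path.
#' @return validated observation data frame.
#' @export
read_observations <- function(path) {
  if (!file.exists(path))
    stop("observation file not found: ", path, call. = FALSE)
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.OBS_COLUMNS, names(obs))
  if (length(missing_cols))
    stop("observation file missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in .OBS_NUMERIC) {
    v <- obs[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(num))
    if (length(bad))
      stop("non-numeric value in column '", col, "' at data row ",
           bad[1L], ": '", v[bad[1L]], "'", call. = FALSE)
    obs[[col]] <- num
  }
  bad_ndvi <- which(is.finite(obs$ndvi) & abs(obs$ndvi) > 1)
  if (length(bad_ndvi))
    stop("ndvi outside [-1, 1] at data row ", bad_ndvi[1L], ": ",
         obs$ndvi[bad_ndvi[1L]], call. = FALSE)
  obs$stage <- canonical_stage(obs$stage)
  obs
}

#' Write a plot observation CSV
#'
#' @param observations observation data frame.
#' @param path output CSV file path.
#' @return the path, invisibly.
#' @export
write_observations <- function(observations, path) {
  utils::write.csv(observations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a calibration to a JSON artifact
#'
#' Writes the fitted coefficients, the derived algorithm constants and
#' provenance metadata to JSON. The artifact round-trips losslessly:
#' reading it back with [read_calibration()] and writing it again produces
#' byte-identical output.
#'
#' @param cal an [`nsens_cal`][calibrate_nsensor] object.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "nsens_cal"))
  art <- cal$artifact
  if (is.null(art)) art <- .build_artifact(cal)
  jsonlite::write_json(art, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

.build_artifact <- function(cal, input = NULL, options = NULL) {
  qa <- cal$quadratic$coefficients
  br <- cal$bridge$coefficients
  list(
    stage = cal$stage,
    a0 = qa[["a0"]], a1 = qa[["a1"]], a2 = qa[["a2"]],
    b0 = br[["b0"]], b1 = br[["b1"]],
    r_squared_quadratic = cal$quadratic$r_squared,
    r_squared_bridge = cal$bridge$r_squared,
    n_quadratic = cal$quadratic$n_points,
    n_bridge = cal$bridge$n_points,
    R = cal$algorithm$R,
    SI_R = cal$algorithm$SI_R,
    provenance = list(
      kind = cal$algorithm$provenance,
      reference = cal$reference,
      input = input,
      options = options,
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  )
}

#' Read a calibration JSON artifact
#'
#' Reconstructs an [`nsens_cal`][calibrate_nsensor] object (coefficients,
#' derived algorithm, reference metadata) from an artifact written by
#' [write_calibration()]. The derived constants are recomputed from the
#' coefficients and checked against the stored values.
#'
#' @param path JSON artifact path.
#' @return an `nsens_cal` object (without the fitting data).
#' @export
read_calibration <- function(path) {
  art <- jsonlite::read_json(path)
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  art[c("a0", "a1", "a2", "b0", "b1", "R", "SI_R")] <-
    lapply(art[c("a0", "a1", "a2", "b0", "b1", "R", "SI_R")], num)
  q <- .quad_response_from_coef(art$a0, art$a1, art$a2,
                                r_squared = art$r_squared_quadratic %||% NA_real_,
                                n_points = art$n_quadratic %||% NA_integer_,
                                provenance = "artifact")
  b <- .si_bridge_from_coef(art$b0, art$b1,
                            r_squared = art$r_squared_bridge %||% NA_real_,
                            n_points = art$n_bridge %||% NA_integer_,
                            provenance = "artifact")
  alg <- derive_parametric(q, b, art$stage)
  if (!is.null(art$R) &&
      (abs(alg$R - art$R) > 1e-8 * max(1, abs(art$R)) ||
       abs(alg$SI_R - art$SI_R) > 1e-8 * max(1, abs(art$SI_R))))
    stop("inconsistent artifact: stored R/SI_R do not match the stored ",
         "coefficients", call. = FALSE)
  structure(list(
    stage = art$stage,
    reference = art$provenance$reference,
    quadratic = q, bridge = b, algorithm = alg,
    data = NULL, artifact = art,
    call = match.call()
  ), class = "nsens_cal")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
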