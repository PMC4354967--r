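#' Construct an SN-value lookup table
#'
#' A lookup table mapping raw sensor values (SN) to N application rates.
#' Anchors are non-overlapping SN ranges, sorted ascending, with rates
#' non-increasing as SN increases (greener crop needs less N).
#'
#' @param anchors data frame with columns `sn_low`, `sn_high`, `n_app`
#'   (kg N/ha).
#' @param stage optional growth-stage label.
#' @return An object of class `"sn_table"`.
#' @seealso [sn_lookup_table()] for the published stage tables,
#'   [recommend_from_sn()] to evaluate one.
#' @export
sn_table <- function(anchors, stage = NULL) {
  req <- c("sn_low", "sn_high", "n_app")
  if (!is.data.frame(anchors) || !all(req %in% names(anchors)))
    stop("anchors must be a data frame with columns sn_low, sn_high, n_app",
         call. = FALSE)
  if (nrow(anchors) == 0L)
    stop("empty SN lookup table", call. = FALSE)
  anchors <- anchors[order(anchors$sn_low), req, drop = FALSE]
  if (any(anchors$sn_high < anchors$sn_low))
    stop("each anchor needs sn_high >= sn_low", call. = FALSE)
  if (nrow(anchors) > 1L) {
    if (any(anchors$sn_low[-1L] <= anchors$sn_high[-nrow(anchors)]))
      stop("anchor SN ranges must not overlap", call. = FALSE)
    if (any(diff(anchors$n_app) > 0))
      stop("n_app must be non-increasing as SN increases", call. = FALSE)
  }
  if (!is.null(stage)) stage <- canonical_stage(stage)
  structure(list(stage = stage, anchors = anchors), class = "sn_table")
}

# Published SN-range -> N rate anchors for wheat. Between the published
# anchors the table is evaluated by midpoint interpolation (the full binning
# is not published).
.SN_TABLES <- list(
  tillering = data.frame(sn_low = c(7, 33.1), sn_high = c(11, 37),
                         n_app = c(75, 45)),
  booting   = data.frame(sn_low = c(17, 76.1), sn_high = c(24, 84),
                         n_app = c(40, 25))
)

#' Published SN lookup tables by growth stage
#'
#' The published sensor-value recommendation anchors for wheat: at
#' tillering, SN 7--11 maps to 75 kg N/ha and SN 33.1--37 to 45 kg N/ha; at
#' booting, SN 17--24 maps to 40 kg N/ha and SN 76.1--84 to 25 kg N/ha.
#'
#' @param stage `"tillering"` or `"booting"` (aliases accepted).
#' @return An [`sn_table`][sn_table] object.
#' @export
#' @examples
#' recommend_from_sn(sn_lookup_table("tillering"), 9)  # 75
sn_lookup_table <- function(stage) {
  stage <- canonical_stage(stage)
  if (!stage %in% names(.SN_TABLES))
    stop("no published SN table for stage '", stage,
         "'; available: ", paste(names(.SN_TABLES), collapse = ", "),
         call. = FALSE)
  sn_table(.SN_TABLES[[stage]], stage = stage)
}

#' Recommend an N rate from a raw sensor value
#'
#' An SN inside an anchor range returns that anchor's rate exactly. Between
#' two anchor ranges the rate is linearly interpolated between the flanking
#' anchors' (range midpoint, rate) pairs. Below the first or above the last
#' range the nearest anchor's rate is returned with an extrapolation
#' warning.
#'
#' @param table an [`sn_table`][sn_table] object.
#' @param sn sensor value(s), non-negative. Vectorized.
#' @return numeric vector of rates (kg N/ha) with logical attribute vectors
#'   `interpolated` and `extrapolated`.
#' @export
recommend_from_sn <- function(table, sn) {
  if (!inherits(table, "sn_table"))
    stop("table must be an sn_table object", call. = FALSE)
  if (any(!is.finite(sn)) || any(sn < 0))
    stop("sn values must be finite and non-negative", call. = FALSE)
  a <- table$anchors
  mids <- (a$sn_low + a$sn_high) / 2
  k <- nrow(a)
  out <- numeric(length(sn))
  interpolated <- logical(length(sn))
  extrapolated <- logical(length(sn))
  for (i in seq_along(sn)) {
    s <- sn[i]
    hit <- which(s >= a$sn_low & s <= a$sn_high)
    if (length(hit)) {
      out[i] <- a$n_app[hit[1L]]
    } else if (s < a$sn_low[1L]) {
      out[i] <- a$n_app[1L]; extrapolated[i] <- TRUE
    } else if (s > a$sn_high[k]) {
      out[i] <- a$n_app[k]; extrapolated[i] <- TRUE
    } else {
      j <- max(which(a$sn_high < s))  # flanking anchors j, j+1
      w <- (s - mids[j]) / (mids[j + 1L] - mids[j])
      out[i] <- a$n_app[j] + w * (a$n_app[j + 1L] - a$n_app[j])
      interpolated[i] <- TRUE
    }
  }
  if (any(extrapolated))
    warning(sum(extrapolated), " SN value(s) outside the table range; ",
            "nearest anchor rate used", call. = FALSE)
  structure(out, interpolated = interpolated, extrapolated = extrapolated)
}

#' @export
print.sn_table <- function(x, ...) {
  cat("SN-value lookup table")
  if (!is.null(x$stage)) cat(" (", x$stage, ")", sep = "")
  cat("\n")
  a <- x$anchors
  for (i in seq_len(nrow(a)))
    cat(sprintf("  SN %5.1f - %5.1f  ->  %5.1f kg N/ha\n",
                a$sn_low[i], a$sn_high[i], a$n_app[i]))
  invisible(x)
}
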