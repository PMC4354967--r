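#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation between two attribute vectors, with the
#' two-sided p-value from the t transform with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, at least 3 complete pairs,
#'   both non-constant.
#' @return list with `r`, `p_value`, `n`.
#' @export
#' @examples
#' pearson(1:10, 2 * (1:10) + 1)$r  # 1
pearson <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have the same length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input vector", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Correlation table of sensor attributes against crop measurements
#'
#' One Pearson correlation per (sensor attribute, laboratory/agronomic
#' target, growth stage) cell, plus "overall" rows pooling the raw
#' observations of all stages. Cells with insufficient or degenerate data
#' are flagged, not fatal.
#'
#' @param observations observation data frame (canonical columns).
#' @param attributes sensor attribute columns; default `sn`, `biomass`,
#'   `ndvi`.
#' @param targets target columns; default leaf N, leaf chlorophyll, grain
#'   yield.
#' @return data frame with columns `attribute`, `target`, `stage`, `r`,
#'   `p_value`, `n`, `flag` (`""` or `"insufficient"`).
#' @export
correlation_table <- function(observations,
                              attributes = c("sn", "biomass", "ndvi"),
                              targets = c(lab_n = "lab_n",
                                          lab_chl = "lab_chl",
                                          yield = "yield_t_ha")) {
  if (is.null(names(targets)) || any(names(targets) == ""))
    names(targets) <- targets
  need <- c("stage", attributes, unname(targets))
  missing_cols <- setdiff(need, names(observations))
  if (length(missing_cols))
    stop("observations missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  stage_canon <- canonical_stage(observations$stage)
  stages <- c(intersect(.STAGES, unique(stage_canon)), "overall")
  grid <- expand.grid(attribute = attributes, target = names(targets),
                      stage = stages, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  cells <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    rows <- if (g$stage == "overall") rep(TRUE, nrow(observations))
            else stage_canon == g$stage
    x <- observations[rows, g$attribute]
    y <- observations[rows, targets[[g$target]]]
    cell <- tryCatch(pearson(x, y), error = function(e) NULL)
    if (is.null(cell)) {
      data.frame(attribute = g$attribute, target = g$target, stage = g$stage,
                 r = NA_real_, p_value = NA_real_,
                 n = sum(is.finite(x) & is.finite(y)), flag = "insufficient")
    } else {
      data.frame(attribute = g$attribute, target = g$target, stage = g$stage,
                 r = cell$r, p_value = cell$p_value, n = cell$n, flag = "")
    }
  })
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  out
}

#' Polynomial trend fit of an attribute against N level
#'
#' Ordinary least squares polynomial (default quadratic) fit of a sensor
#' attribute against applied N rate, with the coefficient of
#' determination.
#'
#' @param n_rates applied N rates; at least `degree + 1` distinct values.
#' @param values attribute values, same length.
#' @param degree polynomial degree; default 2.
#' @return list with `coefficients` (intercept first), `r_squared`,
#'   `degree`, `n`.
#' @export
#' @examples
#' trend_fit(c(0, 30, 60, 90), c(1, 2, 2.5, 2.6))$r_squared
trend_fit <- function(n_rates, values, degree = 2) {
  if (length(n_rates) != length(values))
    stop("n_rates and values must have the same length", call. = FALSE)
  ok <- is.finite(n_rates) & is.finite(values)
  n_rates <- n_rates[ok]; values <- values[ok]
  if (length(unique(n_rates)) < degree + 1L)
    stop("rank deficiency: need at least ", degree + 1L,
         " distinct N rates for degree ", degree, call. = FALSE)
  fit <- stats::lm(values ~ stats::poly(n_rates, degree, raw = TRUE))
  res <- unname(stats::residuals(fit))
  sst <- sum((values - mean(values))^2)
  r2 <- if (sst > 0) max(0, 1 - sum(res^2) / sst) else 0
  cf <- unname(stats::coef(fit))
  names(cf) <- paste0("c", seq_along(cf) - 1L)
  list(coefficients = cf, r_squared = r2, degree = degree,
       n = length(n_rates))
}
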