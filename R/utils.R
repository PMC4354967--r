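#' @keywords internal
"_PACKAGE"

# Canonical growth-stage tokens used throughout the package.
.STAGES <- c("tillering", "booting", "ear_emergence")

# Alias table: stage names, days-after-sowing codes (~55/85/115 DAS) and
# Zadoks-style decimal codes are accepted in input files.
.STAGE_ALIASES <- list(
  tillering     = c("tillering", "till", "55", "55das", "z28", "28"),
  booting       = c("booting", "boot", "85", "85das", "z45", "45"),
  ear_emergence = c("ear_emergence", "earemergence", "ear emergence", "ear",
                    "115", "115das", "z59", "59")
)

#' Canonicalize a growth-stage label
#'
#' Maps stage names, days-after-sowing codes (55/85/115 DAS) and decimal
#' growth-stage codes onto the canonical tokens `"tillering"`, `"booting"`,
#' `"ear_emergence"`.
#'
#' @param stage character vector of stage labels (any accepted alias).
#' @return character vector of canonical stage tokens.
#' @export
#' @examples
#' canonical_stage(c("Tillering", "85DAS", "ear emergence"))
canonical_stage <- function(stage) {
  key <- gsub("[-_ ]+", " ", tolower(trimws(as.character(stage))))
  key <- trimws(key)
  out <- character(length(key))
  for (canon in names(.STAGE_ALIASES)) {
    aliases <- gsub("[-_ ]+", " ", .STAGE_ALIASES[[canon]])
    out[key %in% aliases] <- canon
  }
  bad <- out == ""
  if (any(bad)) {
    stop("unknown growth stage label(s): ",
         paste(unique(stage[bad]), collapse = ", "),
         "; expected one of ", paste(.STAGES, collapse = ", "),
         " (or an accepted alias)", call. = FALSE)
  }
  out
}

.check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(name, " must be a single finite number", call. = FALSE)
  if (strict_lower && x <= lower)
    stop(name, " must be > ", lower, call. = FALSE)
  if (!strict_lower && x < lower)
    stop(name, " must be >= ", lower, call. = FALSE)
  if (x > upper)
    stop(name, " must be <= ", upper, call. = FALSE)
  invisible(x)
}

# Deterministic 31-bit hash of a string key (djb2 variant kept in double
# arithmetic so it never overflows R's integer range).
.key_hash <- function(key) {
  vapply(key, function(k) {
    h <- 5381
    for (ch in utf8ToInt(k)) h <- (h * 33 + ch) %% 2147483629
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# Counter-based Gaussian noise: one standard-normal draw per
# (seed, unit, stage, attribute) key. Adding attributes never perturbs the
# draws of existing ones, and the global RNG stream is left untouched.
.keyed_normal <- function(seed, unit, stage, attribute) {
  keys <- paste(seed, unit, stage, attribute, sep = "/")
  hashes <- .key_hash(keys)
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  vapply(hashes, function(h) {
    set.seed(h)
    stats::rnorm(1L)
  }, numeric(1))
}
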