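#' @keywords internal
#' @importFrom rlang .data
#' @importFrom Rcpp sourceCpp
#' @useDynLib nfkbgrn, .registration = TRUE
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  force(expr)
}

# Unit conversions for the "minute" model time convention.
MINUTES_PER_DAY <- 1440
MINUTES_PER_YEAR <- 525600

#' Convert between model minutes, days and years
#'
#' The model time unit is the minute; long-horizon results are usually
#' reported in days or years.
#'
#' @param x Numeric time values.
#' @param from,to One of `"minute"`, `"day"`, `"year"`.
#' @return Numeric vector in the target unit.
#' @export
convert_time <- function(x, from = "minute", to = "day") {
  per_min <- c(minute = 1, day = MINUTES_PER_DAY, year = MINUTES_PER_YEAR)
  if (!from %in% names(per_min) || !to %in% names(per_min)) {
    stop("units must be one of: ", paste(names(per_min), collapse = ", "),
         call. = FALSE)
  }
  x * per_min[[from]] / per_min[[to]]
}
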