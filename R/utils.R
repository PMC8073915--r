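# internal helpers shared across the pipeline

`%||%` <- function(a, b) if (is.null(a)) b else a

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

# numerically safe log(1 + exp(x))
.log1pexp <- function(x) {
  out <- x
  lo <- x <= 30
  out[lo] <- log1p(exp(x[lo]))
  out
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# parse ISO-8601 UTC timestamps ("2018-03-12T23:00:00Z" or with space)
.parse_utc <- function(x) {
  x <- sub("Z$", "", sub("T", " ", x))
  out <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  miss <- is.na(out) & !is.na(x)
  if (any(miss))
    out[miss] <- as.POSIXct(strptime(x[miss], "%Y-%m-%d %H:%M", tz = "UTC"))
  out
}

.format_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Round half away from zero
#'
#' Integer rounding with ties going away from zero (so 0.5 -> 1), the
#' convention used for the reported whole-number percentages.
#' @param x numeric vector
#' @return integer vector
#' @keywords internal
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
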