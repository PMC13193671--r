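`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for every reported percentage so
#' that printed proportions such as 5/39 -> 12.8 and 7/39 -> 17.9 are stable
#' across platforms (base [round()] rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(100 * 5 / 39, 1) # 12.8
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# one-decimal percentage; NA when the denominator is zero
pct1 <- function(num, den) {
  if (is.na(den) || den <= 0) return(NA_real_)
  round_half_up(100 * num / den, 1)
}

# integer count scaled by a fraction, half-up
scale_count <- function(n, s) as.integer(round_half_up(n * s, 0))

#' Largest-remainder apportionment
#'
#' Splits an integer total across categories proportionally to `weights`,
#' assigning leftover units to the largest fractional remainders (ties go to
#' the earlier category). Guarantees the parts sum exactly to `total`.
#'
#' @param weights Nonnegative numeric weights.
#' @param total Nonnegative integer total to distribute.
#' @return Integer vector summing to `total`.
#' @export
#' @examples
#' apportion(c(886489, 911664), 100) # 49 + 51
apportion <- function(weights, total) {
  stopifnot(total >= 0, all(weights >= 0))
  total <- as.integer(total)
  if (length(weights) == 0L) return(integer(0))
  if (sum(weights) == 0) {
    out <- integer(length(weights))
    return(out)
  }
  q <- weights / sum(weights) * total
  base <- as.integer(floor(q + 1e-9))
  rem <- total - sum(base)
  if (rem > 0L) {
    ord <- order(q - base, seq_along(q), decreasing = c(TRUE, FALSE), method = "radix")
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  base
}

# evaluate code under a temporary RNG seed, restoring global RNG state after
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# strict ISO-8601 calendar dates; anything else is NA (treated as missing)
parse_iso_date <- function(x) {
  x <- trimws(as.character(x))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out <- rep(as.Date(NA), length(x))
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

# months since year 0, for gap-free month arithmetic
month_index <- function(d) {
  lt <- as.POSIXlt(d)
  (lt$year + 1900L) * 12L + lt$mon
}

month_label <- function(mi) sprintf("%04d-%02d", mi %/% 12L, mi %% 12L + 1L)

# "2005-01" -> month index
parse_month <- function(x) {
  stopifnot(grepl("^\\d{4}-\\d{2}$", x))
  as.integer(substr(x, 1, 4)) * 12L + as.integer(substr(x, 6, 7)) - 1L
}

# sample k elements of x without the length-1 surprise of sample()
sample_rows <- function(x, k) {
  if (k == 0L) return(integer(0))
  if (length(x) == 1L) return(x)
  sample(x, k)
}

usage_error <- function(msg) {
  stop(structure(class = c("cdm_usage_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

data_error <- function(msg, class = "cdm_data_error") {
  stop(structure(class = c(class, "cdm_data_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

validation_error <- function(msg) data_error(msg, class = "cdm_validation_error")

not_available_error <- function(table_name) {
  data_error(sprintf("table '%s' is not available in the dataset", table_name),
             class = "cdm_not_available_error")
}
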