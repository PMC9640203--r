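`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero to a fixed number of decimals
#'
#' Base `round()` rounds half to even; summary tables here follow the
#' convention of commercial rounding (half-up), so that e.g. 37.5 prints
#' as 38, matching how counts-over-denominators are conventionally reported.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # nudge by a relative epsilon so that exact .5 values survive binary
  # representation error (e.g. 100 * 30/81)
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Normalize free text for matching
#'
#' Lower-cases, strips punctuation and collapses whitespace. Both user
#' input and configured patterns pass through this before comparison, so
#' "I'm SAD!!" and "i'm sad" match the same patterns.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[‘’']", "", x)        # drop apostrophes: "i'm" -> "im"
  x <- gsub("[^[:alnum:][:space:]]", " ", x) # other punctuation -> space
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

tokenize <- function(x) {
  x <- normalize_text(x)
  if (!nzchar(x)) return(character(0))
  strsplit(x, " ", fixed = TRUE)[[1]]
}

# Deterministic ISO-8601 timestamps from a logical clock: `epoch` plus a
# number of seconds. Keeps transcripts and event logs byte-identical across
# replays of the same seed.
iso_time <- function(offset_s, epoch = "2020-04-07T00:00:00Z") {
  t0 <- as.POSIXct(epoch, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  format(t0 + offset_s, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

is_scalar_character <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

stop_cf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Sort the keys of a named list recursively (mappings only; unnamed lists
# are sequences whose order is meaningful and preserved).
sort_keys <- function(x) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  if (!is.null(nm) && all(nzchar(nm))) {
    x <- x[order(nm, method = "radix")]
  }
  lapply(x, sort_keys)
}

compact <- function(x) x[!vapply(x, is.null, logical(1))]
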