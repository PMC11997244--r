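#' @keywords internal
#' @useDynLib thermoresp, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Typed condition helpers: every user-facing failure is a classed error so the
# pipeline driver can label the stage and offending entity.
stop_data <- function(msg, ..., class = "thermoresp_data_error") {
  stop(structure(
    class = c(class, "thermoresp_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_config <- function(msg, ...) {
  stop_data(msg, ..., class = "thermoresp_config_error")
}

warn_data <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}

#' Deterministic RNG substream seed
#'
#' Derives a 31-bit seed from a master seed and a set of string labels
#' (e.g. GO term id and species id), so that every (gene set, species)
#' combination consumes its own reproducible random stream regardless of the
#' order in which sets are processed.
#'
#' @param master_seed integer master seed.
#' @param ... character labels identifying the substream.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(master_seed, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  m <- 2147483647  # 2^31 - 1, prime
  h <- 0
  for (code in utf8ToInt(labels)) h <- (h * 31 + code) %% m
  as.integer((as.numeric(master_seed) %% m * 48271 + h) %% m)
}

# Evaluate `expr` under a local seed without disturbing the caller's RNG.
with_substream <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# Half-up rounding to the nearest integer (round() in R rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
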