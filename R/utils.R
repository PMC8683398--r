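# Internal helpers: seeding substreams, lower-median convention, logging.

#' Derive a reproducible sub-seed from a master seed and a purpose label
#'
#' One user-visible seed governs every random mechanism in the package;
#' independent substreams for each purpose (intensity simulation, MNAR
#' masking, imputation of a given sample, k-means restarts, ...) are derived
#' by hashing a purpose string, so that toggling one mechanism or reordering
#' samples does not perturb the draws of another.
#'
#' @param seed integer master seed.
#' @param purpose character label naming the consumer of the substream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, purpose) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(purpose))
  h <- 0
  for (code in utf8ToInt(purpose)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer((abs(as.numeric(seed)) + h) %% 2147483647)
}

# Lower median: for an even number of observations take the lower of the two
# middle order statistics (so the median is always an observed value).
lower_median <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sort(x, method = "radix")[floor((n + 1) / 2)]
}

# Timestamped log line on stderr; tables and summaries never carry clocks so
# that identical runs produce byte-identical files.
log_msg <- function(...) {
  message(format(Sys.time(), "%H:%M:%S "), "[lfqdiscover] ", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
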