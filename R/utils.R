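# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Derive an operation-specific seed from a master seed
#'
#' All stochastic operations in the package draw their randomness from one
#' integer master seed combined with a short operation key, so that unrelated
#' operations driven by the same master seed do not share RNG streams.
#'
#' @param seed Integer master seed.
#' @param key Character key naming the consumer (e.g. `"wgs"`).
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(seed, key = "") {
  if (length(seed) != 1L || is.na(seed) || seed != as.integer(seed)) {
    stopf("`seed` must be a single integer")
  }
  ints <- utf8ToInt(key)
  h <- 0
  for (i in seq_along(ints)) h <- (h * 131 + ints[i]) %% 2147483647
  as.integer((abs(as.double(seed)) * 48271 + h * 7919 + 17) %% 2147483647)
}

# Evaluate `code` under a seed derived from (seed, key), restoring RNG state.
with_op_seed <- function(seed, key, code) {
  withr::with_seed(derive_seed(seed, key), code)
}

# data.frame of 0-based half-open intervals -> GRanges (1-based closed)
gr_from_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (any(df$end < df$start)) stopf("negative-length interval")
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# GRanges -> data.frame of 0-based half-open intervals, sorted
intervals_from_gr <- function(gr) {
  gr <- GenomicRanges::sort(gr)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

check_fraction <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stopf("`%s` must lie in [0, 1]", name)
  }
  invisible(x)
}
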