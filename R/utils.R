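# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded generators behave as pure functions of (inputs, seed).
#'
#' @param seed Integer seed, or `NULL` to leave the RNG stream untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stage seed from a global seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

# Validate a peaks data.frame (chrom/start/end at minimum).
check_peaks <- function(peaks, what = "peaks") {
  if (!is.data.frame(peaks)) stop(sprintf("'%s' must be a data.frame", what), call. = FALSE)
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) {
    stop(sprintf("'%s' is missing column(s): %s", what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(peaks)) {
    if (any(is.na(peaks$start)) || any(is.na(peaks$end)) ||
        any(peaks$start < 0) || any(peaks$end <= peaks$start)) {
      stop(sprintf("'%s' has invalid coordinates (need 0 <= start < end)", what), call. = FALSE)
    }
    if (any(is.na(peaks$chrom)) || any(!nzchar(as.character(peaks$chrom)))) {
      stop(sprintf("'%s' has empty chromosome names", what), call. = FALSE)
    }
  }
  invisible(peaks)
}

# Convert 0-based half-open peaks to GRanges (1-based closed).
peaks_gr <- function(peaks) {
  check_peaks(peaks)
  GenomicRanges::GRanges(
    seqnames = as.character(peaks$chrom),
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
}

# TRUE when rows are sorted by (chrom, start).
is_sorted_peaks <- function(peaks) {
  if (nrow(peaks) < 2L) return(TRUE)
  ord <- order(as.character(peaks$chrom), peaks$start, method = "radix")
  identical(ord, seq_len(nrow(peaks)))
}
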