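# Minimal local-lambda Poisson peak caller: windowed treatment counts are
# tested against a dynamic lambda taken as the maximum of the genome-wide
# control rate and control rates in several local windows, after scaling the
# larger library to the smaller one.

#' Peak caller configuration
#'
#' @param window Sliding window width in bp (default 300).
#' @param step Window step in bp (default 100).
#' @param local_lambda_windows Widths (bp) of the control windows, centred
#'   on each test window, whose maximum rate forms the dynamic lambda
#'   (default 1000, 5000, 10000).
#' @param pvalue_threshold Poisson upper-tail threshold (default 1e-5).
#' @param merge_gap Significant windows closer than this are merged into one
#'   peak (default 100 bp).
#' @param lambda_pseudo_bp Local control-rate estimates are shrunk towards
#'   the genome-wide rate by this many base pairs of pseudo-counts
#'   (default 2000). Stabilises the small local windows when the control
#'   library is sparse; genuine wide local biases still raise lambda.
#' @return A list of class `peak_caller_config`.
#' @export
peak_caller_config <- function(window = 300L, step = 100L,
                               local_lambda_windows = c(1000L, 5000L, 10000L),
                               pvalue_threshold = 1e-5, merge_gap = 100L,
                               lambda_pseudo_bp = 2000L) {
  stopifnot(window > 0, step > 0, all(local_lambda_windows > 0),
            pvalue_threshold > 0, pvalue_threshold < 1, merge_gap >= 0,
            lambda_pseudo_bp >= 0)
  structure(list(window = as.integer(window), step = as.integer(step),
                 local_lambda_windows = as.integer(local_lambda_windows),
                 pvalue_threshold = pvalue_threshold,
                 merge_gap = as.integer(merge_gap),
                 lambda_pseudo_bp = as.integer(lambda_pseudo_bp)),
            class = "peak_caller_config")
}

#' Build a tag library from a position table
#'
#' @param tags Data.frame with columns chrom, pos (0-based 5' tag position)
#'   and optionally strand.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @return List of class `tag_library`: positions (named list of sorted
#'   integer vectors), total, chrom_sizes.
#' @export
tag_library <- function(tags, chrom_sizes) {
  stopifnot(is.data.frame(tags), all(c("chrom", "pos") %in% names(tags)))
  miss <- setdiff(unique(as.character(tags$chrom)), names(chrom_sizes))
  if (length(miss)) stop(sprintf("no chromosome size for: %s", paste(miss, collapse = ", ")), call. = FALSE)
  sizes <- chrom_sizes[as.character(tags$chrom)]
  if (nrow(tags) && (any(tags$pos < 0) || any(tags$pos >= sizes))) {
    stop("tag positions outside chromosome bounds", call. = FALSE)
  }
  pos <- lapply(split(tags$pos, as.character(tags$chrom)), sort.int)
  structure(list(positions = pos, total = nrow(tags), chrom_sizes = chrom_sizes),
            class = "tag_library")
}

#' Read / write tag libraries as 3-column TSV (chrom, pos, strand)
#'
#' @param path TSV path.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @return `read_tags()`: a `tag_library`; `write_tags()`: `path`, invisibly.
#' @export
read_tags <- function(path, chrom_sizes) {
  tab <- utils::read.delim(path, header = FALSE,
                           col.names = c("chrom", "pos", "strand"),
                           stringsAsFactors = FALSE)
  tag_library(tab, chrom_sizes)
}

#' @rdname read_tags
#' @param tags Data.frame with chrom, pos, strand.
#' @export
write_tags <- function(tags, path) {
  strand <- tags$strand %||% rep("+", nrow(tags))
  utils::write.table(data.frame(tags$chrom, tags$pos, strand),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Library scale factor
#'
#' The larger library is scaled down to the smaller:
#' factor = min(totals) / max(totals). Symmetric in its arguments.
#'
#' @param treatment,control `tag_library` objects.
#' @return The scale factor in (0, 1].
#' @export
scale_libraries <- function(treatment, control) {
  if (treatment$total == 0 || control$total == 0) {
    stop("empty tag library; cannot scale", call. = FALSE)
  }
  min(treatment$total, control$total) / max(treatment$total, control$total)
}

#' Poisson upper tail P(X >= k)
#'
#' Exact upper tail of a Poisson(lambda) count.
#'
#' @param k Non-negative integer count (vectorised).
#' @param lambda Positive rate.
#' @return P(X >= k).
#' @export
poisson_upper_tail <- function(k, lambda) {
  if (any(lambda <= 0)) stop("lambda must be positive", call. = FALSE)
  if (any(k < 0) || any(k != floor(k))) stop("k must be a non-negative integer", call. = FALSE)
  stats::ppois(k - 1, lambda, lower.tail = FALSE)
}

# Continuous extension of the Poisson upper tail via the gamma identity
# P(Pois(lambda) >= k) = P(Gamma(k, 1) <= lambda); used when treatment
# counts have been scaled down by a non-integer factor.
pois_upper_cont <- function(k, lambda) {
  p <- rep(1, length(k))
  pos <- k > 0
  p[pos] <- stats::pgamma(lambda[pos], shape = k[pos], lower.tail = TRUE)
  p
}

# Count sorted integer positions falling in [starts, ends) (vectorised).
count_in_windows <- function(pos, starts, ends) {
  findInterval(ends - 0.5, pos) - findInterval(starts - 0.5, pos)
}

#' Call peaks from treatment and control tag libraries
#'
#' Slides a window along each chromosome, forms a dynamic lambda from the
#' control (maximum of the genome-wide rate and local-window rates, floored
#' at the genome-wide rate), scales the larger library to the smaller, and
#' keeps windows whose Poisson upper-tail p-value passes the threshold.
#' Overlapping or near-adjacent significant windows are merged; the peak
#' score is the best window's -log10 p and the summit the tag-densest
#' position.
#'
#' @param treatment,control `tag_library` objects on the same genome.
#' @param config A [peak_caller_config()].
#' @return Peak data.frame: chrom, start, end, name, score (-log10 p),
#'   lambda_local, summit_offset.
#' @export
call_peaks <- function(treatment, control, config = peak_caller_config()) {
  if (!identical(names(treatment$chrom_sizes), names(control$chrom_sizes))) {
    stop("treatment and control must be on the same genome", call. = FALSE)
  }
  if (treatment$total == 0 || control$total == 0) stop("empty tag library", call. = FALSE)
  ratio <- treatment$total / control$total  # treatment-to-control depth
  genome_len <- sum(control$chrom_sizes)
  bg_rate <- control$total / genome_len     # control tags per bp
  w <- config$window
  out <- list()
  for (chr in names(treatment$chrom_sizes)) {
    L <- unname(treatment$chrom_sizes[chr])
    if (L < w) next
    tpos <- treatment$positions[[chr]] %||% integer()
    cpos <- control$positions[[chr]] %||% integer()
    starts <- seq.int(0L, L - w, by = config$step)
    k <- count_in_windows(tpos, starts, starts + w)
    centers <- starts + w / 2
    lam_rate <- rep(bg_rate, length(starts))
    pseudo <- config$lambda_pseudo_bp
    for (lw in config$local_lambda_windows) {
      cs <- pmax(0, centers - lw / 2); ce <- pmin(L, centers + lw / 2)
      # shrink each window's rate towards the genome-wide control rate
      est <- (count_in_windows(cpos, cs, ce) + bg_rate * pseudo) /
        (ce - cs + pseudo)
      lam_rate <- pmax(lam_rate, est)
    }
    lam <- lam_rate * w
    if (ratio <= 1) {
      # control is the larger library: scale its expected counts down
      p <- poisson_upper_tail(k, lam * ratio)
      lam_used <- lam * ratio
    } else {
      # treatment is larger: scale treatment counts down to control depth
      p <- pois_upper_cont(k / ratio, lam)
      lam_used <- lam
    }
    sig <- which(p <= config$pvalue_threshold)
    if (!length(sig)) next
    # merge significant windows when the gap between spans is small
    ws <- starts[sig]; we <- ws + w
    grp <- cumsum(c(1L, as.integer(ws[-1] - cummax(we[-length(we)]) > config$merge_gap)))
    for (g in unique(grp)) {
      idx <- sig[grp == g]
      ps <- starts[idx[1]]; pe <- starts[idx[length(idx)]] + w
      best <- idx[which.min(p[idx])]
      in_peak <- tpos[tpos >= ps & tpos < pe]
      summit <- if (length(in_peak)) {
        dens <- count_in_windows(in_peak, in_peak - 50L, in_peak + 50L)
        in_peak[which.max(dens)] - ps
      } else NA_integer_
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = ps, end = pe,
        score = -log10(max(p[best], 1e-300)),
        lambda_local = lam_used[best], summit_offset = summit,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(),
                      lambda_local = numeric(), summit_offset = integer()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, method = "radix"), , drop = FALSE]
  res$name <- paste0("called_", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[c("chrom", "start", "end", "name", "score", "lambda_local", "summit_offset")]
}
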