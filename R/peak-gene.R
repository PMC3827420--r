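# Peak-to-gene association: basal-plus-extension regulatory domains,
# TSS-distance binning, peak-set / gene-set overlaps and track overlap.

DIST_BINS <- c("<1kb", "1-5kb", "5-50kb", ">50kb")

#' Regulatory-domain configuration
#'
#' Basal-plus-extension rule: each gene gets a strand-oriented basal window
#' around its TSS, extended on both sides up to the nearest neighbouring
#' basal domain, capped at `max_extension` from the TSS and at chromosome
#' ends.
#'
#' @param basal_upstream Basal window upstream of the TSS (bp).
#' @param basal_downstream Basal window downstream of the TSS (bp).
#' @param max_extension Maximum extension from the TSS (bp).
#' @return A list of class `domain_config`.
#' @export
domain_config <- function(basal_upstream = 5000, basal_downstream = 1000,
                          max_extension = 1e6) {
  stopifnot(basal_upstream > 0, basal_downstream > 0,
            max_extension >= basal_upstream)
  structure(list(basal_upstream = basal_upstream,
                 basal_downstream = basal_downstream,
                 max_extension = max_extension),
            class = "domain_config")
}

# Strand-oriented basal window, 0-based half-open, clipped to [0, chrom size).
basal_window <- function(genes, config, chrom_sizes) {
  up <- config$basal_upstream; down <- config$basal_downstream
  bs <- ifelse(genes$strand == "+", genes$tss - up, genes$tss - down)
  be <- ifelse(genes$strand == "+", genes$tss + down, genes$tss + up)
  size <- chrom_sizes[as.character(genes$chrom)]
  data.frame(start = pmax(0, bs), end = pmin(size, be))
}

#' Build basal-plus-extension regulatory domains
#'
#' @param genes Gene model data.frame.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param config A [domain_config()].
#' @return Data.frame: gene_id, chrom, start, end, basal_start, basal_end.
#' @export
build_domains <- function(genes, chrom_sizes, config = domain_config()) {
  if (!nrow(genes)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      basal_start = numeric(), basal_end = numeric()))
  }
  miss <- setdiff(unique(as.character(genes$chrom)), names(chrom_sizes))
  if (length(miss)) stop(sprintf("no chromosome size for: %s", paste(miss, collapse = ", ")), call. = FALSE)
  basal <- basal_window(genes, config, chrom_sizes)
  out <- vector("list", length(unique(genes$chrom)))
  k <- 0L
  for (chr in unique(as.character(genes$chrom))) {
    idx <- which(as.character(genes$chrom) == chr)
    g <- genes[idx, , drop = FALSE]
    b <- basal[idx, , drop = FALSE]
    L <- unname(chrom_sizes[chr])
    ord <- order(b$start, b$end, method = "radix")
    bs <- b$start[ord]; be <- b$end[ord]
    n <- length(ord)
    # nearest basal end at or left of each basal start (excluding self)
    left_lim <- numeric(n); right_lim <- numeric(n)
    for (i in seq_len(n)) {
      prev_ends <- if (i > 1L) be[seq_len(i - 1L)] else numeric()
      cand <- prev_ends[prev_ends <= bs[i]]
      left_lim[i] <- if (length(cand)) max(cand) else 0
      nxt_starts <- if (i < n) bs[(i + 1L):n] else numeric()
      cand2 <- nxt_starts[nxt_starts >= be[i]]
      right_lim[i] <- if (length(cand2)) min(cand2) else L
    }
    tss_s <- g$tss[ord]
    dstart <- pmax(0, pmax(left_lim, tss_s - config$max_extension))
    dend <- pmin(L, pmin(right_lim, tss_s + config$max_extension))
    dstart <- pmin(dstart, bs)  # domain always contains the basal window
    dend <- pmax(dend, be)
    res <- data.frame(gene_id = g$gene_id[ord], chrom = chr,
                      start = dstart, end = dend,
                      basal_start = bs, basal_end = be,
                      stringsAsFactors = FALSE)
    k <- k + 1L
    out[[k]] <- res
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

#' Assign peaks to genes
#'
#' Domain mode: a peak is assigned to every gene whose regulatory domain
#' contains the peak midpoint. Nearest mode: to the single gene with the
#' closest TSS. Distance is unsigned midpoint-to-TSS, binned at 1/5/50 kb.
#'
#' @param peaks Peak data.frame.
#' @param domains Output of [build_domains()] (domain mode).
#' @param genes Gene model data.frame.
#' @param mode `"domains"` (default) or `"nearest"`.
#' @return Data.frame: peak (name), gene_id, distance, bin.
#' @export
assign_peaks <- function(peaks, domains, genes, mode = c("domains", "nearest")) {
  mode <- match.arg(mode)
  check_peaks(peaks)
  empty <- data.frame(peak = character(), gene_id = character(),
                      distance = numeric(), bin = character())
  if (!nrow(peaks) || !nrow(genes)) return(empty)
  mid <- floor((peaks$start + peaks$end) / 2)
  pname <- peaks$name %||% paste0("peak_", seq_len(nrow(peaks)))
  if (mode == "domains") {
    mid_gr <- GenomicRanges::GRanges(as.character(peaks$chrom),
                                     IRanges::IRanges(mid + 1L, mid + 1L))
    dom_gr <- GenomicRanges::GRanges(as.character(domains$chrom),
                                     IRanges::IRanges(domains$start + 1L, domains$end))
    hits <- GenomicRanges::findOverlaps(mid_gr, dom_gr)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    gid <- domains$gene_id[si]
    tss <- genes$tss[match(gid, genes$gene_id)]
    dist <- abs(mid[qi] - tss)
  } else {
    qi <- integer(); gid <- character(); dist <- numeric()
    for (chr in unique(as.character(peaks$chrom))) {
      pi <- which(as.character(peaks$chrom) == chr)
      gi <- which(as.character(genes$chrom) == chr)
      if (!length(gi)) next
      d <- abs(outer(mid[pi], genes$tss[gi], "-"))
      best <- max.col(-d, ties.method = "first")
      qi <- c(qi, pi)
      gid <- c(gid, genes$gene_id[gi][best])
      dist <- c(dist, d[cbind(seq_along(pi), best)])
    }
  }
  if (!length(qi)) return(empty)
  bin <- cut(dist, breaks = c(-1, 1000 - 1e-9, 5000 - 1e-9, 50000 - 1e-9, Inf),
             labels = DIST_BINS)
  out <- data.frame(peak = pname[qi], gene_id = gid, distance = dist,
                    bin = as.character(bin), stringsAsFactors = FALSE)
  out <- out[order(match(out$peak, pname), out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' TSS-distance bin fractions over peak assignments
#'
#' @param assignments Output of [assign_peaks()].
#' @return Named numeric vector of fractions over the four bins (sums to 1).
#' @export
distance_bin_fractions <- function(assignments) {
  if (!nrow(assignments)) stop("no assignments to bin", call. = FALSE)
  tab <- table(factor(assignments$bin, levels = DIST_BINS))
  fr <- as.numeric(tab) / nrow(assignments)
  names(fr) <- DIST_BINS
  fr
}

#' Peak-set overlap summary
#'
#' Counts peaks of `a` sharing at least 1 bp with any peak of `b`.
#'
#' @param a,b Peak data.frames.
#' @return List: n_a, n_b, n_a_overlapping, fraction.
#' @export
peak_set_overlap <- function(a, b) {
  check_peaks(a, "a"); check_peaks(b, "b")
  if (!nrow(a)) stop("peak set 'a' is empty; overlap fraction undefined", call. = FALSE)
  n_ov <- if (nrow(b)) sum(GenomicRanges::countOverlaps(peaks_gr(a), peaks_gr(b)) > 0L) else 0L
  list(n_a = nrow(a), n_b = nrow(b), n_a_overlapping = n_ov,
       fraction = n_ov / nrow(a))
}

#' Gene-set overlap summary
#'
#' Exact set intersection between two id vectors, with the percentage of `a`
#' shared reported to the nearest integer.
#'
#' @param a,b Character vectors of gene ids.
#' @return List: n_a, n_b, n_common, fraction_of_a, percent_of_a.
#' @export
gene_set_overlap <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  k <- length(intersect(a, b))
  list(n_a = length(a), n_b = length(b), n_common = k,
       fraction_of_a = if (length(a)) k / length(a) else NA_real_,
       percent_of_a = if (length(a)) round(100 * k / length(a)) else NA_real_)
}

#' Compare occupancy between two states
#'
#' Partitions the union into maintained (present in both), lost
#' (resting-only) and de novo (activated-only) sets, at the region or gene
#' level.
#'
#' @param resting,activated Peak data.frames (region level) or gene-id
#'   vectors (gene level).
#' @param level `"region"` or `"gene"`.
#' @return List of class `state_comparison` with maintained/lost/de_novo.
#' @export
compare_states <- function(resting, activated, level = c("region", "gene")) {
  level <- match.arg(level)
  if (level == "gene") {
    r <- unique(as.character(resting)); a <- unique(as.character(activated))
    out <- list(maintained = intersect(r, a), lost = setdiff(r, a),
                de_novo = setdiff(a, r))
  } else {
    check_peaks(resting, "resting"); check_peaks(activated, "activated")
    r_ov <- if (nrow(resting) && nrow(activated)) {
      GenomicRanges::countOverlaps(peaks_gr(resting), peaks_gr(activated)) > 0L
    } else rep(FALSE, nrow(resting))
    a_ov <- if (nrow(activated) && nrow(resting)) {
      GenomicRanges::countOverlaps(peaks_gr(activated), peaks_gr(resting)) > 0L
    } else rep(FALSE, nrow(activated))
    resting$state <- "resting"; activated$state <- "activated"
    out <- list(
      maintained = rbind(resting[r_ov, , drop = FALSE], activated[a_ov, , drop = FALSE]),
      lost = resting[!r_ov, , drop = FALSE],
      de_novo = activated[!a_ov, , drop = FALSE]
    )
  }
  structure(c(out, list(level = level)), class = "state_comparison")
}

#' Fraction of peaks overlapping a second track
#'
#' Applies the 1-bp overlap rule against a histone-mark or coactivator track;
#' optionally also reports the gene-level overlap (fraction of bound genes
#' having at least one track-overlapping peak).
#'
#' @param peaks Peak data.frame.
#' @param track Interval data.frame (chrom, start, end).
#' @param assignments Optional output of [assign_peaks()] for the gene level.
#' @return List: n_peaks, n_overlapping, fraction, and (when assignments are
#'   given) gene_fraction.
#' @export
track_overlap_fraction <- function(peaks, track, assignments = NULL) {
  check_peaks(peaks); check_peaks(track, "track")
  if (!nrow(peaks)) stop("empty peak set", call. = FALSE)
  ov <- if (nrow(track)) {
    GenomicRanges::countOverlaps(peaks_gr(peaks), peaks_gr(track)) > 0L
  } else rep(FALSE, nrow(peaks))
  out <- list(n_peaks = nrow(peaks), n_overlapping = sum(ov),
              fraction = mean(ov))
  if (!is.null(assignments) && nrow(assignments)) {
    pname <- peaks$name %||% paste0("peak_", seq_len(nrow(peaks)))
    ov_peaks <- pname[ov]
    bound <- unique(assignments$gene_id)
    g_ov <- unique(assignments$gene_id[assignments$peak %in% ov_peaks])
    out$gene_fraction <- length(g_ov) / length(bound)
  }
  out
}
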