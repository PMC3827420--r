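# Pre-ranked gene set enrichment analysis: genes ranked by absolute linear
# fold change, weighted running-sum enrichment score, and a permutation null
# over random same-size gene sets for NES and nominal p.

#' Pre-ranked GSEA configuration
#'
#' @param weight_exponent Exponent p applied to the ranking weights in hit
#'   increments (default 1; 0 gives the unweighted Kolmogorov-Smirnov-style
#'   statistic).
#' @param n_permutations Number of random gene sets for the null
#'   (default 1000, minimum 100).
#' @param seed Integer seed for the permutation null.
#' @param tie_policy How ties in the ranking weight are broken: `"input"`
#'   keeps the input order (stable), `"gene_id"` sorts tied genes by id.
#' @return A list of class `gsea_config`.
#' @export
gsea_config <- function(weight_exponent = 1, n_permutations = 1000L,
                        seed = NULL, tie_policy = c("input", "gene_id")) {
  stopifnot(weight_exponent >= 0, n_permutations >= 100)
  structure(list(weight_exponent = weight_exponent,
                 n_permutations = as.integer(n_permutations),
                 seed = seed, tie_policy = match.arg(tie_policy)),
            class = "gsea_config")
}

#' Rank genes by absolute linear fold change
#'
#' @param de_results Output of [differential_genes()] (or any data.frame
#'   with gene_id and linear_fc).
#' @param tie_policy See [gsea_config()].
#' @return Data.frame: gene_id, weight (= |linear fold change|), descending;
#'   attribute `fully_tied` flags an all-equal ranking.
#' @export
rank_by_abs_fc <- function(de_results, tie_policy = c("input", "gene_id")) {
  tie_policy <- match.arg(tie_policy)
  if (anyNA(de_results$linear_fc)) stop("missing fold change in ranking input", call. = FALSE)
  w <- abs(de_results$linear_fc)
  ord <- if (tie_policy == "gene_id") {
    order(-w, de_results$gene_id, method = "radix")
  } else {
    order(-w, method = "radix")  # radix sort is stable: ties keep input order
  }
  out <- data.frame(gene_id = de_results$gene_id[ord], weight = w[ord],
                    stringsAsFactors = FALSE)
  attr(out, "fully_tied") <- length(unique(w)) == 1L
  out
}

# Extremum-only ES from sorted hit ranks, given weight^p over the full list.
# Exact: the running sum rises only at hits and falls linearly between them,
# so the signed extremum is attained either at a hit or just before one (or
# at the very end).
es_from_hits <- function(hit_ranks, wp, n) {
  nh <- length(hit_ranks)
  denom_miss <- n - nh
  wh <- wp[hit_ranks]
  sumw <- sum(wh)
  if (sumw == 0) wh <- rep(1 / nh, nh) else wh <- wh / sumw
  s_at_hit <- cumsum(wh) - (hit_ranks - seq_len(nh)) / denom_miss
  # minima just before each hit and after the last hit
  prev_s <- c(0, s_at_hit[-nh])
  prev_r <- c(0L, hit_ranks[-nh])
  mins <- prev_s - (hit_ranks - prev_r - 1L) / denom_miss
  mins <- c(mins, s_at_hit[nh] - (n - hit_ranks[nh]) / denom_miss)
  mx <- max(s_at_hit); mn <- min(mins)
  if (mx >= -mn) mx else mn
}

#' Weighted running-sum enrichment score
#'
#' Hits increment the running sum by |w|^p normalised over hit weights;
#' misses decrement by 1/(N - Nh). The enrichment score is the signed
#' extremum of the running sum.
#'
#' @param ranked Output of [rank_by_abs_fc()] (data.frame gene_id, weight).
#' @param gene_set Character vector of gene ids.
#' @param weight_exponent Exponent p (default 1).
#' @return List: es, running_sum (full profile), hit_ranks, n, n_hits.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  n <- nrow(ranked)
  is_hit <- ranked$gene_id %in% gene_set
  nh <- sum(is_hit)
  if (nh == 0L) stop("gene set does not intersect the ranked list", call. = FALSE)
  if (nh == n) stop("gene set equals the whole ranked list; miss decrement undefined", call. = FALSE)
  wp <- abs(ranked$weight)^weight_exponent
  wh <- wp * is_hit
  sumw <- sum(wh)
  inc <- if (sumw == 0) is_hit / nh else wh / sumw
  step <- inc - (!is_hit) / (n - nh)
  running <- cumsum(step)
  es_pos <- max(running); es_neg <- min(c(0, running))
  es <- if (es_pos >= -es_neg) es_pos else es_neg
  list(es = es, running_sum = running, hit_ranks = which(is_hit),
       n = n, n_hits = nh)
}

#' Normalised enrichment score and nominal p from a permutation null
#'
#' The null distribution of ES comes from `n_permutations` random gene sets
#' of the same size drawn from the ranked universe (seeded). NES is the ES
#' divided by the mean of same-sign null ES values; the nominal p is the
#' same-sign null fraction at least as extreme as the observed ES.
#'
#' @param ranked Output of [rank_by_abs_fc()].
#' @param gene_set Character vector of gene ids.
#' @param config A [gsea_config()].
#' @return List of class `gsea_result`: es, nes, nominal_p, p_is_bound
#'   (TRUE when no null value reached the observed ES, so p is reported as
#'   < 1/n_same_sign), leading_edge, n_hits, null_es.
#' @export
nes_and_pvalue <- function(ranked, gene_set, config = gsea_config()) {
  esr <- enrichment_score(ranked, gene_set, config$weight_exponent)
  n <- esr$n; nh <- esr$n_hits
  wp <- abs(ranked$weight)^config$weight_exponent
  null_es <- with_seed(config$seed, {
    vapply(seq_len(config$n_permutations), function(i) {
      es_from_hits(sort.int(sample.int(n, nh)), wp, n)
    }, 0)
  })
  same <- null_es[sign(null_es) == sign(esr$es)]
  if (length(same)) {
    nes <- esr$es / mean(abs(same))
    n_extreme <- sum(abs(same) >= abs(esr$es))
    p_bound <- n_extreme == 0L
    nominal_p <- if (p_bound) 1 / length(same) else n_extreme / length(same)
  } else {
    nes <- NA_real_
    nominal_p <- 1 / config$n_permutations
    p_bound <- TRUE
  }
  # leading edge: hits at or before (after, for negative ES) the extremum
  run <- esr$running_sum
  if (esr$es >= 0) {
    peak <- which.max(run)
    le <- sum(esr$hit_ranks <= peak)
  } else {
    trough <- which.min(run)
    le <- sum(esr$hit_ranks > trough)
  }
  structure(list(es = esr$es, nes = nes, nominal_p = nominal_p,
                 p_is_bound = p_bound, leading_edge = le, n_hits = nh,
                 null_es = null_es, seed = config$seed),
            class = "gsea_result")
}
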