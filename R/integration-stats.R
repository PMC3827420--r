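# Gene-set integration statistics: bound / responsive / regulated set
# derivation, contingency-table association tests, expected-by-chance
# overlap with a hypergeometric tail, direction concordance, category
# fraction tests and printed-style ratio summaries.

#' Derive bound / responsive / regulated gene sets
#'
#' Bound genes carry at least one assigned peak; the motif-bearing subset
#' additionally requires a consensus-motif hit in at least one assigned
#' peak; responsive genes pass the differential-expression filter; regulated
#' genes are responsive AND motif-bearing bound. Provenance (peak and motif
#' variant) is retained per regulated gene.
#'
#' @param assignments Output of [assign_peaks()].
#' @param motif_summary Output of [region_motif_summary()] for the same
#'   peaks, or a character vector of motif-bearing region names.
#' @param de_results Output of [differential_genes()].
#' @param universe Character vector of all gene ids on the platform.
#' @return List of class `gene_sets`: universe, bound, bound_with_motif,
#'   responsive, regulated, provenance.
#' @export
derive_gene_sets <- function(assignments, motif_summary, de_results, universe) {
  universe <- unique(as.character(universe))
  missing_de <- setdiff(de_results$gene_id, universe)
  if (length(missing_de)) {
    stop(sprintf("DE gene(s) absent from universe: %s",
                 paste(utils::head(missing_de, 5L), collapse = ", ")), call. = FALSE)
  }
  motif_regions <- if (is.character(motif_summary)) motif_summary else
    rownames(motif_summary$counts)[rowSums(motif_summary$counts) > 0]
  bound <- intersect(unique(assignments$gene_id), universe)
  with_motif_rows <- assignments[assignments$peak %in% motif_regions, , drop = FALSE]
  bound_with_motif <- intersect(unique(with_motif_rows$gene_id), universe)
  responsive <- de_results$gene_id[de_results$status != "ns"]
  regulated <- intersect(responsive, bound_with_motif)
  prov <- with_motif_rows[with_motif_rows$gene_id %in% regulated,
                          c("gene_id", "peak"), drop = FALSE]
  sets <- structure(list(universe = universe, bound = bound,
                         bound_with_motif = bound_with_motif,
                         responsive = responsive, regulated = regulated,
                         provenance = prov),
                    class = "gene_sets")
  check_gene_sets(sets)
  sets
}

# Invariant chain: regulated <= responsive; regulated <= bound_with_motif
# <= bound <= universe. Asserted on every pipeline run.
check_gene_sets <- function(sets) {
  stopifnot(all(sets$regulated %in% sets$responsive),
            all(sets$regulated %in% sets$bound_with_motif),
            all(sets$bound_with_motif %in% sets$bound),
            all(sets$bound %in% sets$universe))
  invisible(sets)
}

#' Two-sided Fisher exact p for a 2x2 table
#'
#' Sums the hypergeometric point masses not exceeding the observed table's
#' mass (with the usual 1e-7 relative tolerance), conditioning on the
#' margins.
#'
#' @param a,b,c,d The 2x2 cell counts (a = both, b = first only, c = second
#'   only, d = neither).
#' @return The two-sided p-value.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  x <- max(0, c1 - r2):min(r1, c1)
  mass <- stats::dhyper(x, r1, r2, c1)
  obs <- stats::dhyper(a, r1, r2, c1)
  sum(mass[mass <= obs * (1 + 1e-7)])
}

#' Association between two gene sets by 2x2 contingency table
#'
#' Pearson chi-square (no continuity correction) and two-sided Fisher exact
#' test of membership in `set_a` against membership in `set_b` within a
#' common universe. The odds ratio uses a Haldane 0.5 correction when any
#' cell is zero.
#'
#' @param set_a,set_b Character vectors of gene ids, subsets of `universe`.
#' @param universe Character vector of all genes considered.
#' @return List of class `contingency_result`: table, chi_square, chi_p,
#'   fisher_p, odds_ratio.
#' @export
contingency_association <- function(set_a, set_b, universe) {
  universe <- unique(as.character(universe))
  set_a <- unique(as.character(set_a)); set_b <- unique(as.character(set_b))
  extra <- setdiff(union(set_a, set_b), universe)
  if (length(extra)) {
    stop("universe smaller than the union of the two sets", call. = FALSE)
  }
  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  c <- length(setdiff(set_b, set_a))
  d <- length(universe) - a - b - c
  contingency_from_counts(a, b, c, d)
}

# Shared 2x2 machinery for contingency_association() and
# category_fraction_test().
contingency_from_counts <- function(a, b, c, d) {
  tab <- matrix(c(a, c, b, d), nrow = 2,
                dimnames = list(in_a = c("yes", "no"), in_b = c("yes", "no")))
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  or <- if (any(tab == 0)) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)) else (a * d) / (b * c)
  structure(list(table = tab,
                 chi_square = unname(chi$statistic), chi_p = chi$p.value,
                 fisher_p = fisher_exact_p(a, b, c, d),
                 odds_ratio = or),
            class = "contingency_result")
}

#' Expected-by-chance overlap of two gene lists
#'
#' For lists of sizes n1 and n2 drawn from a universe of N genes, the
#' expected overlap is n1*n2/N and the significance of an observed overlap
#' k is the exact hypergeometric upper tail P(X >= k).
#'
#' @param list1,list2 Character vectors of gene ids within `universe`.
#' @param universe Character vector of all genes in the common universe.
#' @return List of class `overlap_stat`: n1, n2, N, k, expected, p.
#' @export
expected_overlap <- function(list1, list2, universe) {
  universe <- unique(as.character(universe))
  list1 <- unique(as.character(list1)); list2 <- unique(as.character(list2))
  if (length(setdiff(list1, universe)) || length(setdiff(list2, universe))) {
    stop("gene lists must be subsets of the universe", call. = FALSE)
  }
  k <- length(intersect(list1, list2))
  expected_overlap_counts(length(list1), length(list2), length(universe), k)
}

#' @rdname expected_overlap
#' @param n1,n2 List sizes.
#' @param N Universe size.
#' @param k Observed overlap.
#' @export
expected_overlap_counts <- function(n1, n2, N, k) {
  stopifnot(n1 >= 0, n2 >= 0, N >= max(n1, n2), k >= 0)
  if (k > min(n1, n2)) stop("observed overlap exceeds the smaller list", call. = FALSE)
  structure(list(n1 = n1, n2 = n2, N = N, k = k,
                 expected = n1 * n2 / N,
                 p = stats::phyper(k - 1, n1, N - n1, n2, lower.tail = FALSE)),
            class = "overlap_stat")
}

#' Monte-Carlo cross-check of the overlap p-value
#'
#' Draws two independent random lists of the given sizes from the universe
#' and reports the frequency of overlaps at least as large as observed.
#'
#' @param n1,n2 List sizes.
#' @param N Universe size.
#' @param k Observed overlap.
#' @param n_draws Number of Monte-Carlo draws.
#' @param seed Integer seed.
#' @return Estimated upper-tail probability.
#' @export
overlap_p_montecarlo <- function(n1, n2, N, k, n_draws = 1e4, seed) {
  with_seed(seed, {
    hits <- stats::rhyper(n_draws, n1, N - n1, n2)
    mean(hits >= k)
  })
}

#' Direction concordance between two regulated-gene lists
#'
#' For genes regulated in both analyses, the fraction whose up/down labels
#' agree.
#'
#' @param common Character vector of genes regulated in both.
#' @param de_a,de_b Outputs of [differential_genes()] for the two analyses.
#' @return List: n_common, n_same_direction, fraction, percent.
#' @export
direction_concordance <- function(common, de_a, de_b) {
  common <- unique(as.character(common))
  sa <- de_a$status[match(common, de_a$gene_id)]
  sb <- de_b$status[match(common, de_b$gene_id)]
  if (anyNA(sa) || anyNA(sb) || any(sa == "ns") || any(sb == "ns")) {
    stop("every common gene must have an up/down status in both analyses", call. = FALSE)
  }
  same <- sum(sa == sb)
  list(n_common = length(common), n_same_direction = same,
       fraction = same / length(common),
       percent = round(100 * same / length(common)))
}

#' Test a category fraction against its genome-wide frequency
#'
#' 2x2 test of category membership (e.g. "is a transcription factor") inside
#' a gene set against the rest of the genome, given the genome-wide category
#' fraction and gene total.
#'
#' @param n_in_set Category members inside the set.
#' @param set_total Size of the set.
#' @param genome_fraction Genome-wide category fraction, in (0, 1).
#' @param genome_total Total number of genes in the genome.
#' @return A `contingency_result` (see [contingency_association()]).
#' @export
category_fraction_test <- function(n_in_set, set_total, genome_fraction,
                                   genome_total) {
  if (missing(genome_total) || is.null(genome_total)) {
    stop("'genome_total' is required", call. = FALSE)
  }
  stopifnot(genome_fraction > 0, genome_fraction < 1,
            n_in_set <= set_total, set_total <= genome_total)
  k_genome <- round(genome_fraction * genome_total)
  a <- n_in_set
  b <- set_total - n_in_set
  c <- k_genome - n_in_set
  d <- genome_total - set_total - c
  if (c < 0 || d < 0) stop("inconsistent category counts", call. = FALSE)
  contingency_from_counts(a, b, c, d)
}

#' Printed-style ratios and percentages
#'
#' Reports numerator/denominator pairs the way summary text prints them:
#' ratios to one decimal and percentages to the nearest integer, alongside
#' the full-precision value.
#'
#' @param numerator,denominator Numeric vectors (recycled).
#' @param type `"ratio"` or `"percent"`, recycled.
#' @param label Optional labels.
#' @return Data.frame: label, numerator, denominator, value, printed.
#' @export
summarize_ratios <- function(numerator, denominator, type = "ratio",
                             label = NULL) {
  if (any(denominator == 0)) stop("division by zero in ratio summary", call. = FALSE)
  if (!all(type %in% c("ratio", "percent"))) {
    stop("type must be 'ratio' or 'percent'", call. = FALSE)
  }
  n <- max(length(numerator), length(denominator))
  numerator <- rep_len(numerator, n); denominator <- rep_len(denominator, n)
  type <- rep_len(type, n)
  value <- ifelse(type == "percent", 100 * numerator / denominator,
                  numerator / denominator)
  printed <- ifelse(type == "percent", round(value), round(value, 1))
  data.frame(label = label %||% paste0(numerator, "/", denominator),
             numerator = numerator, denominator = denominator,
             type = type, value = value, printed = printed,
             stringsAsFactors = FALSE)
}
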