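# Differential-expression filter on normalized log2 matrices: linear
# fold-change cutoff, Welch p-value cutoff and an above-background
# requirement, with up/down direction labels.

#' Differential-expression filter configuration
#'
#' @param fc_cutoff Linear fold-change cutoff (> 1; default 1.5).
#' @param alpha P-value cutoff (default 0.05).
#' @param background_floor Log2 signal floor separating expressed from
#'   background (required; depends on the platform).
#' @param min_above_background_arrays Minimum number of arrays above the
#'   floor for a gene to count as expressed (default 1).
#' @param adjust P-value adjustment method passed to [stats::p.adjust()];
#'   the default `"none"` filters on the raw p-value. `"BH"` gives an
#'   optional FDR mode.
#' @param test `"student"` (pooled-variance two-sample t, equivalent to a
#'   two-group ANOVA and the default) or `"welch"` (unequal variances).
#'   At 3-replicate microarray depth the pooled test keeps the extra degree
#'   of freedom that the Welch correction spends.
#' @return A list of class `de_config`.
#' @export
de_config <- function(fc_cutoff = 1.5, alpha = 0.05, background_floor,
                      min_above_background_arrays = 1L, adjust = "none",
                      test = c("student", "welch")) {
  if (missing(background_floor)) stop("'background_floor' must be supplied", call. = FALSE)
  stopifnot(fc_cutoff > 1, alpha > 0, alpha < 1, min_above_background_arrays >= 1)
  structure(list(fc_cutoff = fc_cutoff, alpha = alpha,
                 background_floor = background_floor,
                 min_above_background_arrays = as.integer(min_above_background_arrays),
                 adjust = adjust, test = match.arg(test)),
            class = "de_config")
}

#' Above-background flag per gene
#'
#' TRUE when at least `min_above_background_arrays` samples exceed the
#' configured log2 floor.
#'
#' @param values Numeric matrix of log2 intensities (genes x samples).
#' @param config A [de_config()].
#' @return Named logical vector.
#' @export
above_background <- function(values, config) {
  stopifnot(is.matrix(values))
  rowSums(values > config$background_floor) >= config$min_above_background_arrays
}

# Vectorised two-sample test on rows of two matrices; pooled-variance
# (Student/ANOVA) or Welch.
ttest_rows <- function(wt, ko, test = "student") {
  n1 <- ncol(wt); n2 <- ncol(ko)
  m1 <- rowMeans(wt); m2 <- rowMeans(ko)
  v1 <- apply(wt, 1L, stats::var); v2 <- apply(ko, 1L, stats::var)
  diff <- m2 - m1
  if (test == "welch") {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(diff))
  }
  p <- rep(NA_real_, length(diff))
  zero_var <- se2 == 0
  # noiseless fixtures: zero within-group variance classifies deterministically
  p[zero_var & diff != 0] <- 1e-12
  p[zero_var & diff == 0] <- 1
  ok <- !zero_var
  if (any(ok)) {
    tstat <- diff[ok] / sqrt(se2[ok])
    p[ok] <- 2 * stats::pt(-abs(tstat), df[ok])
  }
  list(log2fc = diff, p = p, degenerate = zero_var & diff != 0)
}

#' Differential genes between WT and KO groups
#'
#' Log2 fold change is the difference of group means (KO minus WT, i.e. a
#' geometric-mean ratio on the linear scale); the p-value comes from a
#' two-sided two-sample test on log2 values (pooled-variance by default,
#' Welch via the config). A gene is called up/down when its
#' linear fold change reaches `fc_cutoff`, its (optionally adjusted) p-value
#' is below `alpha`, and it is expressed above background.
#'
#' @param wt,ko Numeric matrices of log2 intensities with identical rownames
#'   (genes) and at least 2 replicate columns each.
#' @param config A [de_config()].
#' @return Data.frame: gene_id, log2fc, linear_fc (= 2^|log2fc|), p_value,
#'   above_background, status (up/down/ns), degenerate_p.
#' @export
differential_genes <- function(wt, ko, config) {
  stopifnot(is.matrix(wt), is.matrix(ko))
  if (ncol(wt) < 2L || ncol(ko) < 2L) {
    stop("need at least 2 replicates per group", call. = FALSE)
  }
  if (!identical(rownames(wt), rownames(ko))) {
    stop("WT and KO matrices must cover the same genes in the same order", call. = FALSE)
  }
  if (anyNA(wt) || anyNA(ko)) stop("expression matrices contain missing values", call. = FALSE)
  w <- ttest_rows(wt, ko, config$test %||% "student")
  p_eff <- stats::p.adjust(w$p, method = config$adjust)
  ab <- above_background(cbind(wt, ko), config)
  linear_fc <- 2^abs(w$log2fc)
  sig <- linear_fc >= config$fc_cutoff & p_eff < config$alpha & ab
  status <- ifelse(!sig, "ns", ifelse(w$log2fc > 0, "up", "down"))
  data.frame(gene_id = rownames(wt), log2fc = w$log2fc, linear_fc = linear_fc,
             p_value = w$p, above_background = ab, status = status,
             degenerate_p = w$degenerate, stringsAsFactors = FALSE)
}

#' Fractions of up- and down-regulated genes among responsive genes
#'
#' @param results Output of [differential_genes()].
#' @return List: n_responsive, n_up, n_down, fraction_up, fraction_down.
#' @export
direction_split <- function(results) {
  resp <- results[results$status != "ns", , drop = FALSE]
  if (!nrow(resp)) stop("no responsive genes; direction split undefined", call. = FALSE)
  n_up <- sum(resp$status == "up"); n_down <- sum(resp$status == "down")
  list(n_responsive = nrow(resp), n_up = n_up, n_down = n_down,
       fraction_up = n_up / nrow(resp), fraction_down = n_down / nrow(resp))
}
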