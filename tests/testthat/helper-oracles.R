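# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (position-wise loops, explicit series, lchoose-based
# masses) so they share no code path with the implementation they check.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N")
)

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# All 0-based offsets where the IUPAC pattern matches, one strand.
oracle_scan_one <- function(seq, iupac) {
  sl <- strsplit(seq, "")[[1]]
  ml <- strsplit(iupac, "")[[1]]
  w <- length(ml); n <- length(sl)
  hits <- integer()
  if (n >= w) {
    for (i in 0:(n - w)) {
      ok <- TRUE
      for (j in seq_len(w)) {
        if (!(sl[i + j] %in% ORACLE_IUPAC[[ml[j]]])) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, i)
    }
  }
  hits
}

oracle_scan <- function(seq, iupac, both_strands = TRUE) {
  fwd <- oracle_scan_one(seq, iupac)
  out <- data.frame(offset = fwd, strand = rep("+", length(fwd)))
  if (both_strands) {
    rev_hits <- oracle_scan_one(seq, oracle_revcomp(iupac))
    out <- rbind(out,
                 data.frame(offset = rev_hits, strand = rep("-", length(rev_hits))))
  }
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# All-pairs interval intersection.
oracle_intersect <- function(a, b) {
  res <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          min(a$end[i], b$end[j]) > max(a$start[i], b$start[j])) {
        res[[length(res) + 1L]] <- c(i = i, j = j)
      }
    }
  }
  if (!length(res)) return(data.frame(i = integer(), j = integer()))
  out <- as.data.frame(do.call(rbind, res))
  out[order(out$i, out$j), , drop = FALSE]
}

# Poisson upper tail by direct series summation.
oracle_pois_upper <- function(k, lambda) {
  i <- k:(k + 500 + ceiling(10 * lambda))
  sum(exp(-lambda + i * log(lambda) - lgamma(i + 1)))
}

# Two-sided Fisher p from lchoose-based hypergeometric masses.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  mass <- exp(lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(N, c1))
  obs <- mass[xs == a]
  sum(mass[mass <= obs * (1 + 1e-7)])
}

# Hypergeometric upper tail P(X >= k) from lchoose-based masses.
oracle_hyper_upper <- function(k, n1, n2, N) {
  if (k > min(n1, n2)) return(0)
  i <- k:min(n1, n2)
  sum(exp(lchoose(n1, i) + lchoose(N - n1, n2 - i) - lchoose(N, n2)))
}

# Full running-sum GSEA enrichment score by an explicit loop.
oracle_es <- function(weights, is_hit, p = 1) {
  N <- length(weights); nh <- sum(is_hit)
  wp <- abs(weights)^p
  W <- sum(wp[is_hit])
  s <- 0; run <- numeric(N)
  for (i in seq_len(N)) {
    s <- s + if (is_hit[i]) {
      if (W == 0) 1 / nh else wp[i] / W
    } else -1 / (N - nh)
    run[i] <- s
  }
  mx <- max(run); mn <- min(c(0, run))
  if (mx >= -mn) mx else mn
}

# Minimal gene table on one chromosome.
make_genes <- function(tss, strand = rep("+", length(tss)), chrom = "chr1") {
  data.frame(gene_id = sprintf("g%02d", seq_along(tss)),
             symbol = sprintf("G%d", seq_along(tss)),
             chrom = chrom, strand = strand, tss = tss,
             tes = tss + ifelse(strand == "+", 2000, -2000),
             stringsAsFactors = FALSE)
}

make_peaks <- function(chrom, start, end, name = NULL) {
  data.frame(chrom = chrom, start = start, end = end,
             name = name %||% paste0("p", seq_along(start)),
             score = NA_real_, stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Reduced-size study configuration for fast end-to-end tests.
small_sim <- function(...) {
  args <- list(n_chroms = 1L, chrom_length = 8e5, n_genes = 60L,
               n_peaks = 30L, n_track_background = 20L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
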