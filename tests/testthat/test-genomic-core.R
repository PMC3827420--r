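# Interval and I/O primitives.

test_that("read_bed parses, validates and sorts records", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20", path)
  p <- read_bed(path)
  expect_equal(p$chrom, "chr1")
  expect_equal(p$start, 10L)
  expect_equal(p$end, 20L)

  writeLines("chr1\t20\t10", path)
  expect_error(read_bed(path), "line 1")

  writeLines(c("chr1\t10\t20", "chr1\tten\t20"), path)
  expect_error(read_bed(path), "line 2")

  writeLines("chr1\t10", path)
  expect_error(read_bed(path), "fewer than 3")

  # sorted output equals a naive sort oracle
  set.seed(7)
  recs <- data.frame(chrom = sample(c("chr2", "chr1"), 30, replace = TRUE),
                     start = sample(0:1000, 30), stringsAsFactors = FALSE)
  recs$end <- recs$start + sample(10:50, 30, replace = TRUE)
  writeLines(sprintf("%s\t%d\t%d\tr%d", recs$chrom, recs$start, recs$end,
                     seq_len(30)), path)
  got <- read_bed(path)
  ord <- order(recs$chrom, recs$start)  # naive oracle
  expect_equal(got$start, recs$start[ord])
  expect_equal(got$chrom, recs$chrom[ord])
})

test_that("write_bed / read_bed round-trip canonical records", {
  peaks <- make_peaks("chr1", c(10L, 200L), c(50L, 400L))
  peaks$score <- c(1.5, 2.25)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(peaks, path)
  back <- read_bed(path)
  expect_equal(back[c("chrom", "start", "end", "name", "score")],
               peaks[c("chrom", "start", "end", "name", "score")])
})

test_that("read_gene_table enforces schema and uniqueness", {
  path <- withr::local_tempfile(fileext = ".tsv")
  g1 <- make_genes(5000)
  write_gene_table(g1, path)
  got <- read_gene_table(path)
  expect_equal(got$tss, 5000)
  expect_equal(got$strand, "+")

  write_gene_table(rbind(g1, g1), path)
  expect_error(read_gene_table(path), "duplicate gene_id")

  writeLines("gene_id\tsymbol\tchrom\nx\ty\tchr1", path)
  expect_error(read_gene_table(path), "strand")
})

test_that("gene tables round-trip through write/read", {
  set.seed(11)
  genes <- make_genes(sort(sample(seq(10000, 5e5, by = 3000), 100)),
                      strand = sample(c("+", "-"), 100, replace = TRUE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(genes, path)
  expect_equal(read_gene_table(path), genes, ignore_attr = TRUE)
})

test_that("collapse_symbols keeps the longest gene per symbol", {
  genes <- make_genes(c(1000, 50000))
  genes$symbol <- "SAME"
  genes$tes <- c(2000, 60000)  # second gene is longer
  out <- collapse_symbols(genes)
  expect_equal(nrow(out), 1L)
  expect_equal(out$gene_id, "g02")
})

test_that("interval_overlap_bp follows half-open arithmetic", {
  a <- make_peaks("chr1", 10, 20)
  expect_equal(interval_overlap_bp(a, make_peaks("chr1", 15, 25)), 5L)
  expect_equal(interval_overlap_bp(a, make_peaks("chr1", 20, 30)), 0L)
  expect_equal(interval_overlap_bp(a, a), 10L)
  expect_equal(interval_overlap_bp(a, make_peaks("chr2", 10, 20)), 0L)

  # commutative and bounded by the shorter interval
  set.seed(3)
  for (i in 1:50) {
    x <- make_peaks("chr1", s <- sample(100, 1), s + sample(50, 1))
    y <- make_peaks("chr1", t <- sample(100, 1), t + sample(50, 1))
    ov <- interval_overlap_bp(x, y)
    expect_identical(ov, interval_overlap_bp(y, x))
    expect_lte(ov, min(x$end - x$start, y$end - y$start))
  }
})

test_that("intersect_sets matches the all-pairs oracle", {
  expect_equal(nrow(intersect_sets(make_peaks("chr1", 0, 10),
                                   make_peaks("chr1", 100, 110))), 0L)
  a <- make_peaks("chr1", c(0, 50), c(10, 70))
  self <- intersect_sets(a, a)
  expect_equal(self, data.frame(i = 1:2, j = 1:2))

  set.seed(5)
  rand_set <- function(n) {
    s <- sample(0:(1e6 - 400), n)
    p <- make_peaks(sample(c("chr1", "chr2"), n, replace = TRUE), s,
                    s + sample(50:400, n, replace = TRUE))
    p[order(p$chrom, p$start), ]
  }
  a <- rand_set(500); b <- rand_set(500)
  got <- intersect_sets(a, b)
  want <- oracle_intersect(a, b)
  expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
  # symmetric up to pair order
  swapped <- intersect_sets(b, a)
  expect_equal(nrow(swapped), nrow(got))

  expect_error(intersect_sets(a[rev(seq_len(nrow(a))), ], b), "sort")
})

test_that("expression matrices round-trip with their sample sheet", {
  vals <- matrix(rnorm(12), 3, 4,
                 dimnames = list(c("g1", "g2", "g3"),
                                 c("wt1", "wt2", "ko1", "ko2")))
  sheet <- data.frame(sample = colnames(vals),
                      group = c("WT", "WT", "KO", "KO"))
  mp <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(vals, sheet, mp, sp)
  back <- read_expression_matrix(mp, sp)
  expect_equal(back$values, vals)
  expect_equal(back$samples$group, sheet$group)

  sheet_bad <- sheet; sheet_bad$sample[1] <- "nope"
  write_expression_matrix(vals, sheet_bad, mp, sp)
  expect_error(read_expression_matrix(mp, sp), "disagree")
})
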