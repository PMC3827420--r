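# Regulatory domains, peak assignment, overlaps and state comparisons.

test_that("build_domains applies the basal-plus-extension rule", {
  sizes <- c(chr1 = 300000)
  # single gene, no neighbours: domain capped by the chromosome
  d <- build_domains(make_genes(100000), sizes)
  expect_equal(d$start, 0)
  expect_equal(d$end, 300000)

  # two genes: extension stops at the neighbour's basal window
  d2 <- build_domains(make_genes(c(100000, 200000)), sizes)
  expect_equal(d2$end[1], 195000)   # B's basal start
  expect_equal(d2$start[2], 101000) # A's basal end

  # basal window always contained in the domain
  set.seed(2)
  for (rep_i in 1:20) {
    genes <- make_genes(sort(sample(seq(8000, 280000, by = 500), 8)),
                        strand = sample(c("+", "-"), 8, replace = TRUE))
    dd <- build_domains(genes, sizes)
    expect_true(all(dd$start <= dd$basal_start))
    expect_true(all(dd$end >= dd$basal_end))
  }
})

test_that("max_extension caps the domain", {
  sizes <- c(chr1 = 3e6)
  d <- build_domains(make_genes(1.5e6), sizes,
                     domain_config(max_extension = 20000))
  expect_equal(d$start, 1.5e6 - 20000)
  expect_equal(d$end, 1.5e6 + 20000)
})

test_that("assign_peaks bins by midpoint-to-TSS distance", {
  sizes <- c(chr1 = 300000)
  genes <- make_genes(100000)
  doms <- build_domains(genes, sizes)
  # midpoint 300 bp from the TSS
  near <- make_peaks("chr1", 100200, 100400)
  a1 <- assign_peaks(near, doms, genes)
  expect_equal(a1$bin, "<1kb")
  expect_equal(a1$distance, 300)
  # midpoint at 60 kb
  far <- make_peaks("chr1", 159900, 160100)
  expect_equal(assign_peaks(far, doms, genes)$bin, ">50kb")
  # boundary bins
  expect_equal(assign_peaks(make_peaks("chr1", 102900, 103100), doms, genes)$bin,
               "1-5kb")
  expect_equal(assign_peaks(make_peaks("chr1", 107900, 108100), doms, genes)$bin,
               "5-50kb")
})

test_that("an intergenic peak can be assigned to two flanking genes", {
  sizes <- c(chr1 = 400000)
  genes <- make_genes(c(100000, 300000))
  doms <- build_domains(genes, sizes)
  mid_peak <- make_peaks("chr1", 199900, 200100)
  asn <- assign_peaks(mid_peak, doms, genes)
  expect_equal(nrow(asn), 2L)
  expect_setequal(asn$gene_id, c("g01", "g02"))
  # bound-gene count can therefore exceed the peak count
  expect_gt(length(unique(asn$gene_id)), nrow(mid_peak))
})

test_that("nearest mode assigns exactly one gene per peak", {
  genes <- make_genes(c(100000, 300000))
  asn <- assign_peaks(make_peaks("chr1", c(120000, 280000), c(120200, 280200)),
                      domains = NULL, genes = genes, mode = "nearest")
  expect_equal(asn$gene_id, c("g01", "g02"))
})

test_that("distance bin fractions sum to one", {
  sizes <- c(chr1 = 400000)
  genes <- make_genes(c(100000, 300000))
  doms <- build_domains(genes, sizes)
  set.seed(4)
  s <- sample(5000:390000, 50)
  asn <- assign_peaks(make_peaks("chr1", s, s + 200), doms, genes)
  fr <- distance_bin_fractions(asn)
  expect_equal(sum(fr), 1)
})

test_that("peak_set_overlap counts the 1-bp rule from set A's side", {
  a <- make_peaks("chr1", c(0, 100), c(50, 150))
  expect_equal(peak_set_overlap(a, a)$fraction, 1)
  disjoint <- make_peaks("chr1", c(1000, 2000), c(1050, 2050))
  expect_equal(peak_set_overlap(a, disjoint)$fraction, 0)
  expect_error(peak_set_overlap(a[0, ], a), "empty")
})

test_that("gene_set_overlap reports integer percentages", {
  a <- paste0("g", 1:10)
  b <- paste0("g", 6:30)
  ov <- gene_set_overlap(a, b)
  expect_equal(ov$n_common, 5L)
  expect_equal(ov$percent_of_a, 50)
  expect_equal(gene_set_overlap(a, c(a, "x"))$percent_of_a, 100)
  # intersection symmetric, fractions not necessarily
  ov2 <- gene_set_overlap(b, a)
  expect_equal(ov2$n_common, ov$n_common)
})

test_that("compare_states partitions the union", {
  r <- paste0("g", 1:10)
  a <- paste0("g", 6:15)
  cs <- compare_states(r, a, level = "gene")
  expect_setequal(cs$maintained, paste0("g", 6:10))
  expect_setequal(cs$lost, paste0("g", 1:5))
  expect_setequal(cs$de_novo, paste0("g", 11:15))
  expect_equal(length(cs$maintained) + length(cs$lost) + length(cs$de_novo),
               length(union(r, a)))
  # identical and disjoint degenerate cases
  same <- compare_states(r, r, level = "gene")
  expect_length(same$lost, 0)
  expect_length(same$de_novo, 0)
  disj <- compare_states(r, paste0("x", 1:3), level = "gene")
  expect_length(disj$maintained, 0)

  # region level: every record lands in exactly one part
  pr <- make_peaks("chr1", c(0, 1000, 2000), c(200, 1200, 2200))
  pa <- make_peaks("chr1", c(1100, 5000), c(1300, 5200))
  csr <- compare_states(pr, pa, level = "region")
  expect_equal(nrow(csr$maintained) + nrow(csr$lost) + nrow(csr$de_novo),
               nrow(pr) + nrow(pa))
  expect_equal(nrow(csr$lost), 2L)
  expect_equal(nrow(csr$de_novo), 1L)
})

test_that("track_overlap_fraction handles saturating and empty tracks", {
  peaks <- make_peaks("chr1", c(100, 5000), c(300, 5200))
  whole <- make_peaks("chr1", 0, 1e6)
  expect_equal(track_overlap_fraction(peaks, whole)$fraction, 1)
  expect_equal(track_overlap_fraction(peaks, whole[0, ])$fraction, 0)
})
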