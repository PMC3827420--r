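# IUPAC scanner, background sampling, Z-scores and module detection.

test_that("scan_motif finds consensus matches on both strands", {
  h <- scan_motif("TGTGGT", runx_motif())
  expect_equal(h$offset, 0L)
  expect_equal(h$strand, "+")
  expect_equal(h$match, "TGTGGT")

  h2 <- scan_motif("ACCACA", runx_motif())
  expect_equal(h2$strand, "-")
  expect_equal(h2$match, "TGTGGT")  # motif-strand orientation

  expect_equal(nrow(scan_motif("AAAAAAA", runx_motif())), 0L)
  expect_error(motif_consensus("bad", "TGXGGT"), "invalid IUPAC")
  expect_error(scan_motif("TGQGGT", runx_motif()), "A/C/G/T/N")
})

test_that("sequence N matches only the N code", {
  expect_equal(nrow(scan_motif("TGNGGT", "TGYGGY")), 0L)
  expect_equal(scan_motif("ANT", "ANT", both_strands = FALSE)$offset, 0L)
})

test_that("scanner equals the naive oracle, including planted motifs", {
  set.seed(21)
  seq10k <- random_dna(10000)
  for (pos in c(100, 2500, 5000, 7777, 9990)) {
    substr(seq10k, pos, pos + 5) <- "TGCGGC"
  }
  got <- scan_motif(seq10k, runx_motif())
  want <- oracle_scan(seq10k, "TGYGGY")
  expect_equal(got$offset, want$offset)
  expect_equal(got$strand, want$strand)
  expect_true(all(c(99, 2499, 4999, 7776, 9989) %in% got$offset))

  # parameterised random cases across motif alphabets
  motifs <- c("TGYGGY", "MGGAA", "TGASTCA", "RNCGH", "WWSSKK")
  for (i in 1:60) {
    s <- random_dna(sample(40:150, 1))
    m <- sample(motifs, 1)
    got <- scan_motif(s, m)
    want <- oracle_scan(s, m)
    expect_equal(got$offset, want$offset, info = paste(m, s))
    expect_equal(got$strand, want$strand, info = paste(m, s))
  }
})

test_that("reverse-complementing the sequence swaps strands but keeps hits", {
  set.seed(8)
  for (i in 1:20) {
    s <- random_dna(300)
    rc <- oracle_revcomp(s)
    h <- scan_motif(s, runx_motif())
    hrc <- scan_motif(rc, runx_motif())
    expect_equal(nrow(h), nrow(hrc))
    expect_equal(sum(h$strand == "+"), sum(hrc$strand == "-"))
    expect_equal(sort(as.vector(table(h$match))),
                 sort(as.vector(table(hrc$match))))
  }
})

test_that("region_motif_summary counts per region and flags bad bounds", {
  genome <- c(chr1 = paste0(strrep("A", 100), "TGTGGT", strrep("A", 94)))
  peaks <- make_peaks("chr1", c(0, 90), c(50, 140))
  sm <- region_motif_summary(peaks, genome, runx_variants())
  expect_equal(unname(rowSums(sm$counts)), c(0, 1))
  expect_equal(sm$fraction_with_hit, 0.5)

  # counting is additive over disjoint sub-regions
  halves <- make_peaks("chr1", c(90, 115), c(115, 140))
  sm2 <- region_motif_summary(halves, genome, runx_variants())
  expect_equal(sum(sm2$counts), sum(sm$counts[2, ]))

  expect_error(region_motif_summary(make_peaks("chr1", 150, 500), genome,
                                    runx_variants()),
               "beyond the end")
})

test_that("sample_background is seeded, length-matched and respects exclusion", {
  sizes <- c(chr1 = 50000, chr2 = 30000)
  src_len <- c(200, 300, 400)
  a <- sample_background(sizes, 50, src_len, seed = 9)
  b <- sample_background(sizes, 50, src_len, seed = 9)
  expect_identical(a, b)
  expect_true(all((a$end - a$start) %in% src_len))

  excl <- make_peaks(c("chr1", "chr2"), c(0, 0), c(50000, 30000))
  expect_error(sample_background(sizes, 5, 200, seed = 1, exclusion = excl),
               "could not place")

  # sampled lengths reproduce the source distribution
  set.seed(1)
  src <- sample(150:500, 200, replace = TRUE)
  bg <- sample_background(c(chr1 = 2e6), 1000, src, seed = 33)
  ks <- suppressWarnings(stats::ks.test(bg$end - bg$start, src))
  expect_gt(ks$p.value, 0.01)
})

test_that("motif Z-scores are near-null for background-like regions and grow with planting", {
  set.seed(12)
  genome <- c(chr1 = random_dna(200000))
  s <- seq(1000, 180000, by = 2000)[1:60]
  null_regions <- make_peaks("chr1", s, s + 300)
  z0 <- motif_zscore(null_regions, genome, runx_motif(), n_background = 60,
                     seed = 5, exclusion = NULL)
  expect_lt(abs(z0$z), 3.5)

  planted <- genome
  for (p in s + 100) substr(planted["chr1"], p, p + 5) <- "TGTGGT"
  z1 <- motif_zscore(null_regions, planted, runx_motif(), n_background = 60,
                     seed = 5, exclusion = NULL)
  expect_gt(z1$z, 5)
  expect_gt(z1$z, z0$z)
  expect_error(motif_zscore(null_regions, genome, runx_motif(),
                            n_background = 10, seed = 1), "30")
})

test_that("find_modules applies the edge-to-edge gap rule", {
  hit <- function(region, offset, match) {
    data.frame(region = region, offset = offset, strand = "+", match = match,
               stringsAsFactors = FALSE)
  }
  runx_hit <- hit("r1", 100L, "TGTGGT")   # spans [100, 106)
  ets_hit <- hit("r1", 140L, "MGGAA")     # gap = 34
  m <- find_modules(runx_hit, ets_hit, max_gap = 50)
  expect_equal(m$gap, 34L)
  # boundary: gap 51 is out, 50 is in
  expect_equal(nrow(find_modules(runx_hit, hit("r1", 157L, "MGGAA"), 50)), 0L)
  expect_equal(find_modules(runx_hit, hit("r1", 156L, "MGGAA"), 50)$gap, 50L)
  # overlap counts as gap 0
  expect_equal(find_modules(runx_hit, hit("r1", 103L, "MGGAA"), 50)$gap, 0L)
  # same-motif modules need two distinct hits
  expect_equal(nrow(find_modules(runx_hit, runx_hit, 50)), 0L)
  two <- rbind(runx_hit, hit("r1", 120L, "TGCGGC"))
  expect_equal(nrow(find_modules(two, two, 50)), 1L)
})

test_that("find_modules equals the all-pairs oracle on random hit sets", {
  set.seed(14)
  rand_hits <- function(n, w) {
    data.frame(region = sample(c("r1", "r2", "r3"), n, replace = TRUE),
               offset = sample(0:400, n), strand = "+",
               match = strrep("A", w), stringsAsFactors = FALSE)
  }
  for (i in 1:10) {
    ha <- rand_hits(12, 6); hb <- rand_hits(12, 5)
    got <- find_modules(ha, hb, 50)
    # oracle: explicit double loop
    cnt <- 0L
    for (x in seq_len(nrow(ha))) for (y in seq_len(nrow(hb))) {
      if (ha$region[x] == hb$region[y]) {
        gap <- max(0, max(hb$offset[y] - (ha$offset[x] + 6),
                          ha$offset[x] - (hb$offset[y] + 5)))
        if (gap <= 50) cnt <- cnt + 1L
      }
    }
    expect_equal(nrow(got), cnt)
  }
})

test_that("module_enrichment is ~1 on background and detects planted density", {
  set.seed(15)
  genome <- c(chr1 = random_dna(300000))
  plant_pair <- function(genome, pos) {
    substr(genome["chr1"], pos, pos + 5) <- "TGTGGT"
    substr(genome["chr1"], pos + 20, pos + 24) <- "AGGAA"
    genome
  }
  s <- seq(1000, 250000, by = 2500)
  bg_regions <- make_peaks("chr1", s[1:40], s[1:40] + 300)
  part_regions <- make_peaks("chr1", s[41:80], s[41:80] + 300)
  for (p in part_regions$start + 100) genome <- plant_pair(genome, p)
  fe <- module_enrichment(list(planted = part_regions, null = bg_regions),
                          genome, motif_consensus("ETS", "MGGAA"), runx_motif(),
                          background = bg_regions)
  expect_equal(fe$fold[fe$partition == "null"], 1)
  expect_gt(fe$fold[fe$partition == "planted"], 2)
  # empty partition reports NA
  fe2 <- module_enrichment(list(none = bg_regions[0, ]), genome,
                           runx_motif(), runx_motif(), background = bg_regions)
  expect_true(is.na(fe2$fold))
})
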