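# Gene-set derivation and overlap/contingency statistics.

test_that("derive_gene_sets applies the regulated definition", {
  asn <- data.frame(peak = c("p1", "p2", "p3"),
                    gene_id = c("gA", "gB", "gC"),
                    distance = c(100, 200, 300), bin = "<1kb")
  de <- data.frame(gene_id = c("gA", "gB", "gC", "gD"),
                   linear_fc = c(2, 2, 1, 2),
                   status = c("up", "down", "ns", "up"))
  universe <- c("gA", "gB", "gC", "gD", "gE")
  # p1 and p3 carry a motif; p2 does not
  sets <- derive_gene_sets(asn, c("p1", "p3"), de, universe)
  expect_setequal(sets$bound, c("gA", "gB", "gC"))
  expect_setequal(sets$bound_with_motif, c("gA", "gC"))
  expect_setequal(sets$responsive, c("gA", "gB", "gD"))
  # gA: bound + motif + DE -> regulated; gB bound without motif -> not
  expect_equal(sets$regulated, "gA")
  # invariant chain
  expect_true(all(sets$regulated %in% sets$bound_with_motif))
  expect_true(all(sets$bound_with_motif %in% sets$bound))

  de_bad <- rbind(de, data.frame(gene_id = "gZ", linear_fc = 2, status = "up"))
  expect_error(derive_gene_sets(asn, c("p1"), de_bad, universe),
               "absent from universe")
})

test_that("fisher_exact_p equals enumeration and fisher.test", {
  expect_equal(fisher_exact_p(1, 9, 11, 3), oracle_fisher(1, 9, 11, 3),
               tolerance = 1e-12)
  expect_equal(fisher_exact_p(1, 9, 11, 3),
               fisher.test(matrix(c(1, 11, 9, 3), 2))$p.value,
               tolerance = 1e-9)
  set.seed(17)
  for (i in 1:150) {
    cells <- as.integer(rmultinom(1, sample(10:80, 1), runif(4, 0.05, 1)))
    mine <- fisher_exact_p(cells[1], cells[2], cells[3], cells[4])
    ref <- fisher.test(matrix(c(cells[1], cells[3], cells[2], cells[4]), 2))
    expect_equal(mine, ref$p.value, tolerance = 1e-9,
                 info = paste(cells, collapse = ","))
  }
})

test_that("contingency_association computes the Pearson 2x2 chi-square", {
  universe <- sprintf("g%03d", 1:200)
  a <- universe[1:80]
  b <- universe[41:120]
  res <- contingency_association(a, b, universe)
  O <- res$table
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$chi_square, sum((O - E)^2 / E), tolerance = 1e-12)
  expect_equal(res$chi_p, pchisq(res$chi_square, 1, lower.tail = FALSE))
  expect_error(contingency_association(c(a, "zzz"), b, universe), "universe")

  # complete dependence on a large universe is overwhelmingly significant
  big <- sprintf("g%04d", 1:400)
  half <- big[1:200]
  dep <- contingency_association(half, half, big)
  expect_lt(dep$fisher_p, 1e-10)
  expect_lt(dep$chi_p, 1e-10)
})

test_that("contingency p-values are uniform under independent random sets", {
  set.seed(19)
  universe <- sprintf("g%03d", 1:200)
  ps <- replicate(400, {
    a <- sample(universe, 60)
    b <- sample(universe, 80)
    contingency_association(a, b, universe)$fisher_p
  })
  # Fisher's p is conservative/discrete; check no anti-conservative excess
  expect_gte(mean(ps), 0.45)
  expect_lte(mean(ps <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
  # chi-square p on a 2x2 is discrete, so check calibration through the
  # mean and the alpha-level rejection rate rather than a raw KS distance
  chi_ps <- replicate(400, {
    a <- sample(universe, 60)
    b <- sample(universe, 80)
    contingency_association(a, b, universe)$chi_p
  })
  expect_lt(abs(mean(chi_ps) - 0.5), 3 * sqrt(1 / 12 / 400) + 0.03)
  expect_lte(mean(chi_ps <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("expected_overlap follows the n1*n2/N rule with an exact tail", {
  ov <- expected_overlap_counts(10, 10, 100, 1)
  expect_equal(ov$expected, 1)
  expect_equal(ov$p, oracle_hyper_upper(1, 10, 10, 100), tolerance = 1e-12)
  # degenerate: both lists are the whole universe
  u <- sprintf("g%02d", 1:40)
  full <- expected_overlap(u, u, u)
  expect_equal(full$k, 40)
  expect_equal(full$p, 1)
  # symmetric in the two lists
  a <- expected_overlap_counts(23, 81, 1000, 5)
  b <- expected_overlap_counts(81, 23, 1000, 5)
  expect_equal(a$expected, b$expected)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_error(expected_overlap_counts(5, 8, 100, 7), "exceeds")
})

test_that("hypergeometric tail agrees with Monte-Carlo frequency", {
  p_exact <- expected_overlap_counts(20, 30, 120, 9)$p
  p_mc <- overlap_p_montecarlo(20, 30, 120, 9, n_draws = 1e5, seed = 23)
  mc_sigma <- sqrt(p_exact * (1 - p_exact) / 1e5)
  expect_lt(abs(p_mc - p_exact), 3 * mc_sigma + 1e-12)
})

test_that("direction_concordance counts matching labels", {
  common <- c("g1", "g2", "g3", "g4")
  de_a <- data.frame(gene_id = common, status = c("up", "down", "up", "down"))
  de_b <- data.frame(gene_id = common, status = c("up", "down", "down", "down"))
  cc <- direction_concordance(common, de_a, de_b)
  expect_equal(cc$n_same_direction, 3)
  expect_equal(cc$percent, 75)
  expect_equal(direction_concordance(common, de_a, de_a)$percent, 100)
  de_b$status[2] <- "ns"
  expect_error(direction_concordance(common, de_a, de_b), "status")
})

test_that("category_fraction_test behaves under null and signal", {
  # set fraction equal to the genome fraction: no signal
  null_res <- category_fraction_test(34, 500, 0.068, 20000)
  expect_gt(null_res$fisher_p, 0.5)
  sig <- category_fraction_test(20, 118, 0.068, 22000)
  expect_lt(sig$fisher_p, 0.05)
  expect_lt(sig$chi_p, 0.05)
  # doubling all counts strengthens the evidence
  dbl <- category_fraction_test(40, 236, 0.068, 44000)
  expect_lt(dbl$fisher_p, sig$fisher_p)
  expect_error(category_fraction_test(20, 118, 0.068, NULL), "genome_total")
})

test_that("summarize_ratios prints one-decimal ratios and integer percents", {
  r <- summarize_ratios(c(341, 92), c(231, 118), type = c("ratio", "percent"))
  expect_equal(r$printed, c(1.5, 78))
  expect_equal(r$value[1], 341 / 231)
  expect_error(summarize_ratios(1, 0), "zero")
})
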