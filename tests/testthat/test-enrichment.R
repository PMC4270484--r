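ws1 <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L)

test_that("saturated reference gives fold 1 and p near 1", {
  q <- tibble::tibble(chrom = "chr1", start = c(100L, 500L), end = c(200L, 650L))
  r <- permutation_enrichment(q, reference = ws1, workspace = ws1,
    n_perm = 200L, seed = 3)
  expect_equal(r$fold, 1.0)
  expect_gt(r$p_perm, 0.9)
})

test_that("permutation mean matches the exhaustive placement expectation", {
  # 1 kb workspace, one 100 bp query segment, one 100 bp reference
  # segment: expectation over all 901 placements is exactly enumerable
  ref <- tibble::tibble(chrom = "chr1", start = 400L, end = 500L)
  q <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L)
  placements <- sapply(0:900, function(s) {
    max(0, min(s + 100, 500) - max(s, 400))
  })
  exact <- mean(placements)
  r <- permutation_enrichment(q, ref, ws1, n_perm = 20000L, seed = 9)
  mc_se <- stats::sd(placements) / sqrt(20000)
  expect_lt(abs(r$expected - exact), 4 * mc_se)
  # p floor: add-one rule keeps p >= 1/(n_perm + 1)
  expect_gte(r$p_perm, 1 / 20001)
})

test_that("non-overlap of placed segments is enforced and errors when impossible", {
  q <- tibble::tibble(chrom = "chr1", start = c(0L, 600L), end = c(450L, 1000L))
  expect_error(
    permutation_enrichment(q, ws1,
      workspace = tibble::tibble(chrom = "chr1", start = 0L, end = 880L),
      n_perm = 10L, seed = 1
    ),
    "query must lie inside|too dense|too small"
  )
  big <- tibble::tibble(chrom = "chr1", start = 0L, end = 2000L)
  expect_error(
    permutation_enrichment(big, ws1, ws1, n_perm = 10L, seed = 1),
    "query must lie inside"
  )
})

test_that("permutation p-values are calibrated under a true null", {
  # query drawn from the same uniform placement null as the permutations
  withr::local_seed(123)
  ws <- tibble::tibble(chrom = "chr1", start = 0L, end = 20000L)
  ref <- tibble::tibble(
    chrom = "chr1", start = seq(0L, 19000L, by = 2000L),
    end = seq(0L, 19000L, by = 2000L) + 400L
  )
  n_rep <- 200
  queries <- lapply(seq_len(n_rep), function(i) {
    s <- sort(sample(0:19700, 3))
    while (any(diff(s) < 300)) s <- sort(sample(0:19700, 3))
    tibble::tibble(chrom = "chr1", start = s, end = s + 300L)
  })
  seeds <- sample.int(2^30, n_rep)
  hits <- 0
  for (i in seq_len(n_rep)) {
    p <- permutation_enrichment(queries[[i]], ref, ws,
      n_perm = 99L, seed = seeds[i]
    )$p_perm
    if (p <= 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.01)
  expect_lte(hits / n_rep, 0.10)
})

test_that("state folds follow the base-fraction arithmetic and per-base oracle", {
  seg <- tibble::tibble(
    chrom = "chr1",
    start = c(0L, 100L, 1000L), end = c(100L, 1000L, 1000L + 0L),
    state = c(5L, 1L, 1L)
  )[1:2, ]
  # query entirely inside state 5, which is 10% of the workspace
  q <- tibble::tibble(chrom = "chr1", start = 20L, end = 70L)
  enr <- state_overlap_enrichment(seg, q)
  expect_equal(enr$fold[enr$state == 5], 10)

  # random fixture against per-base tallies
  withr::local_seed(14)
  bins <- seq(0L, 975L, by = 25L)
  seg2 <- tibble::tibble(
    chrom = "chr1", start = bins, end = bins + 25L,
    state = sample(1:3, length(bins), TRUE)
  )
  s <- sample(0:950, 5)
  q2 <- interval_union(tibble::tibble(chrom = "chr1", start = s, end = s + 40L))
  enr2 <- state_overlap_enrichment(seg2, q2)
  per_base_state <- rep(seg2$state, each = 25)
  q_mask <- oracle_base_set(q2, "chr1", 1000)
  for (st in 1:3) {
    expect_equal(
      enr2$query_bases[enr2$state == st],
      sum(per_base_state == st & q_mask)
    )
    expect_equal(enr2$workspace_bases[enr2$state == st], sum(per_base_state == st))
  }
  # workspace-weighted mean fold is 1 when the query lies inside
  expect_equal(sum(enr2$workspace_frac * enr2$fold, na.rm = TRUE), 1)

  # coordinate scaling leaves folds unchanged
  seg3 <- dplyr::mutate(seg2, start = start * 7L, end = end * 7L)
  q3 <- dplyr::mutate(q2, start = start * 7L, end = end * 7L)
  enr3 <- state_overlap_enrichment(seg3, q3)
  expect_equal(enr3$fold, enr2$fold)

  # bases outside the segmentation go to an unassigned state
  q4 <- tibble::tibble(chrom = "chr1", start = 990L, end = 1020L)
  expect_warning(enr4 <- state_overlap_enrichment(seg2, q4), "unassigned")
  expect_equal(enr4$query_bases[is.na(enr4$state)], 20)
})

test_that("planted active-state enrichment is recovered", {
  cfg <- sim_config(seed = 91, chrom_length = 2e7, n_peaks = 500L, n_gain = 100L)
  gp <- generate_genome_pair(cfg)
  sites <- make_peaks(
    names(gp$chrom_sizes_b)[1],
    seq(100000L, 15000000L, by = 30000L)
  )[, c("chrom", "start", "end")]
  seg <- generate_segmentation(cfg, gp$chrom_sizes_b, sites)
  enr <- state_overlap_enrichment(seg, sites)
  f <- enr$fold[enr$state == cfg$active_state]
  expect_gt(f, 0.8 * cfg$state_fold)
  expect_lt(f, 1.2 * cfg$state_fold)
})

test_that("odds ratios follow the 2x2 arithmetic with zero-cell correction", {
  special <- sprintf("s%03d", 1:100)
  rest <- sprintf("r%03d", 1:900)
  occupied <- c(special[1:30], rest[1:90])
  o <- gene_odds_ratio(special, rest, occupied)
  expect_equal(o$odds_ratio, (30 / 70) / (90 / 810))
  expect_equal(o$log2_or, log2(27 / 7))
  # equal frequencies: log2 OR exactly 0
  o2 <- gene_odds_ratio(special, rest, c(special[1:10], rest[1:90]))
  expect_equal(o2$log2_or, 0)
  # zero cell: Haldane-Anscombe correction, checked against the formula
  o3 <- gene_odds_ratio(special, rest, rest[1:90])
  expect_equal(
    o3$odds_ratio, ((0 + 0.5) / (100 + 0.5)) / ((90 + 0.5) / (810 + 0.5))
  )
  expect_error(gene_odds_ratio(character(), rest, occupied), "non-empty")
  expect_error(gene_odds_ratio(special, special, occupied), "disjoint")
})

test_that("rank-sum comparison gives exact small-sample p-values", {
  # fully separated n = m = 5: exact two-sided p = 2/choose(10,5)
  r <- rank_sum_compare(1:5, 11:15)
  expect_equal(r$p_value, 2 / choose(10, 5))
  # identical samples: p = 1
  x <- c(1, 2, 3, 4)
  expect_equal(rank_sum_compare(x, x)$p_value, 1)
  # single observations: exact enumeration gives p = 1 (2 * 1/2)
  expect_equal(rank_sum_compare(1, 2)$p_value, 1)
})
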