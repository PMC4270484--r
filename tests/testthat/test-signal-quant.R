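chrom_sizes <- c(chr1 = 5000L)

test_that("fragment extension and pileup match the per-base oracle", {
  tags <- tibble::tibble(
    chrom = "chr1", start = c(1000L, 1100L, 4950L), end = c(1036L, 1136L, 4986L),
    strand = c("+", "+", "+")
  )
  tr <- extend_and_pileup(tags, chrom_sizes, fragment_length = 200L, bin = 1L)
  cov <- oracle_pileup(tags, 5000L, 200L)
  expect_equal(tr$values$chr1, as.numeric(cov))
  # one '+' tag covers [start, start + 200)
  expect_equal(sum(cov[1001:1200] >= 1), 200)
  # total mass = n_tags x fragment_length before clipping; last tag clipped
  expect_equal(sum(cov), 2 * 200 + 50)

  # '-' strand tag extends leftward from its 5' end
  neg <- tibble::tibble(
    chrom = "chr1", start = 3000L, end = 3036L, strand = "-"
  )
  trn <- extend_and_pileup(neg, chrom_sizes, 200L, 1L)
  expect_equal(which(trn$values$chr1 > 0), 2837:3036)

  expect_warning(
    extend_and_pileup(
      tibble::tibble(chrom = "chr1", start = 1L, end = 37L, strand = "."),
      chrom_sizes
    ),
    "unstranded"
  )
  z <- extend_and_pileup(tags[0, ], chrom_sizes)
  expect_true(all(z$values$chr1 == 0))
})

test_that("binned pileup conserves read mass at any bin width", {
  withr::local_seed(5)
  s <- sample(0:4500, 200, replace = TRUE)
  tags <- tibble::tibble(
    chrom = "chr1", start = s, end = s + 36L,
    strand = sample(c("+", "-"), 200, TRUE)
  )
  tags <- tags[tags$start >= 200, ] # avoid left clipping for '-' frags
  for (bin in c(1L, 25L, 100L)) {
    tr <- extend_and_pileup(tags, chrom_sizes, 200L, bin)
    widths <- diff(c(seq(0, by = bin, length.out = length(tr$values$chr1)), 5000))
    expect_equal(sum(tr$values$chr1 * widths), nrow(tags) * 200)
  }
})

test_that("RPM normalization subtracts input and floors at zero", {
  t1 <- extend_and_pileup(
    tibble::tibble(chrom = "chr1", start = 1000L, end = 1036L, strand = "+"),
    chrom_sizes
  )
  # self-subtraction is identically zero
  z <- normalize_subtract(t1, t1, 1e6, 1e6)
  expect_true(all(unlist(z$values) == 0))
  # 10 reads/bin at 1e6 total, zero input -> 10 RPM
  t10 <- t1
  t10$values$chr1 <- rep(10, length(t10$values$chr1))
  t0 <- t1
  t0$values$chr1 <- rep(0, length(t0$values$chr1))
  expect_true(all(normalize_subtract(t10, t0, 1e6, 1e6)$values$chr1 == 10))
  # input exceeding treatment floors at 0
  expect_true(all(normalize_subtract(t0, t10, 1e6, 1e6)$values$chr1 == 0))
})

test_that("promoter matrix is constant-correct and strand-reflective", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"), ortholog_id = NA, chrom = "chr1",
    start = c(2000L, 2000L), end = c(3000L, 3000L), strand = c("+", "-"),
    tss = c(2000L, 2999L), tes = c(2999L, 2000L)
  )
  flat <- new_track_for_test(rep(3, 200), bin = 25L, size = 5000L)
  pm <- promoter_matrix(list(M = flat), genes)
  expect_equal(pm$M, rep(log2(4), 2)) # constant 3 RPM -> log2(1 + 3)
  zero <- new_track_for_test(rep(0, 200), bin = 25L, size = 5000L)
  expect_equal(promoter_matrix(list(M = zero), genes)$M, c(0, 0))

  # minus-strand window equals the plus computation on reflected coordinates
  withr::local_seed(9)
  vals <- runif(5000)
  tr_fwd <- new_track_for_test(vals, bin = 1L, size = 5000L)
  tr_rev <- new_track_for_test(rev(vals), bin = 1L, size = 5000L)
  g_minus <- genes[2, ]
  g_plus_reflected <- genes[1, ]
  g_plus_reflected$tss <- 5000L - 1L - g_minus$tss
  pm_minus <- promoter_matrix(list(M = tr_fwd), g_minus)
  pm_plus <- promoter_matrix(list(M = tr_rev), g_plus_reflected)
  expect_equal(pm_minus$M, pm_plus$M, tolerance = 1e-12)
})

test_that("promoter matrix is bin-phase invariant against the bin=1 oracle", {
  withr::local_seed(21)
  vals <- pmax(0, rnorm(5000, 2))
  genes <- tibble::tibble(
    gene_id = "g1", ortholog_id = NA, chrom = "chr1", start = 2000L,
    end = 3000L, strand = "+", tss = 2400L, tes = 2999L
  )
  fine <- new_track_for_test(vals, bin = 1L, size = 5000L)
  coarse_vals <- colMeans(matrix(vals, nrow = 25))
  coarse <- new_track_for_test(coarse_vals, bin = 25L, size = 5000L)
  a <- promoter_matrix(list(M = fine), genes)$M
  b <- promoter_matrix(list(M = coarse), genes)$M
  # one bin's worth of edge effect at each window end
  expect_lt(abs(2^a - 2^b), 2 * 25 * max(vals) / 4000)
})

test_that("metagene profiles have the documented layout and flatness", {
  genes <- tibble::tibble(
    gene_id = sprintf("g%d", 1:4), ortholog_id = NA, chrom = "chr1",
    start = c(2000L, 2200L, 2400L, 2600L), end = c(3000L, 3400L, 3600L, 3800L),
    strand = c("+", "+", "-", "-"),
    tss = c(2000L, 2200L, 3599L, 3799L), tes = c(2999L, 3399L, 2400L, 2600L)
  )
  const <- new_track_for_test(rep(2.5, 200), bin = 25L, size = 5000L)
  prof <- metagene_profile(const, genes, flank = 500L, body_bins = 40L)
  expect_equal(nrow(prof), 2 * 500 / 25 + 40)
  expect_equal(unique(prof$zone), c("upstream", "body", "downstream"))
  expect_true(all(abs(prof$value - 2.5) < 1e-9))

  # step signal at the TSS lands at the flank/body boundary
  step_vals <- c(rep(0, 2000), rep(4, 3000))
  step <- new_track_for_test(step_vals, bin = 1L, size = 5000L)
  g1 <- genes[1, ]
  p2 <- metagene_profile(step, g1, flank = 500L, body_bins = 40L)
  n_up <- sum(p2$zone == "upstream")
  expect_true(all(p2$value[seq_len(n_up)] == 0))
  expect_true(all(p2$value[(n_up + 1):nrow(p2)] == 4))

  expect_error(
    metagene_profile(const, genes[0, ], flank = 500L, body_bins = 40L),
    "no genes"
  )
})

test_that("promoter H3K4me3/H3K27me3 classification follows the RPM thresholds", {
  pm <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    H3K4me3 = log2(1 + c(2, 0, 2, 0)),
    H3K27me3 = log2(1 + c(0, 1, 1, 0))
  )
  cls <- promoter_mark_class(pm)
  expect_equal(cls$class, c("active", "repressed", "bivalent", "neither"))
  expect_error(promoter_mark_class(pm[, 1:2]), "H3K27me3")
})

test_that("promoter correlations match the textbook formula", {
  pm <- tibble::tibble(
    gene_id = sprintf("g%d", 1:5),
    A = c(1, 2, 3, 4, 5), B = c(2, 1, 4, 3, 6)
  )
  r <- promoter_correlation(pm)
  expect_equal(r$r[r$mark_a == "A" & r$mark_b == "A"], 1.0)
  # hand-computed Pearson for (1..5) vs (2,1,4,3,6)
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  manual <- sum((x - 3) * (y - 3.2)) /
    sqrt(sum((x - 3)^2) * sum((y - 3.2)^2))
  expect_equal(r$r[r$mark_a == "A" & r$mark_b == "B"], manual)
  pm2 <- dplyr::mutate(pm, B = -.data$A)
  r2 <- promoter_correlation(pm2)
  expect_equal(r2$r[r2$mark_a == "A" & r2$mark_b == "B"], -1.0)
  pm3 <- dplyr::mutate(pm, B = 1)
  expect_warning(r3 <- promoter_correlation(pm3), "zero variance")
  expect_true(is.na(r3$r[r3$mark_a == "A" & r3$mark_b == "B"]))
})
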