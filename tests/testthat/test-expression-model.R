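test_that("quantile normalization matches mean-of-order-statistics and is idempotent", {
  a <- tibble::tibble(gene_id = c("g1", "g2", "g3"), M = c(1, 2, 3))
  b <- tibble::tibble(gene_id = c("g1", "g2", "g3"), M = c(10, 20, 30))
  qn <- quantile_normalize(list(a = a, b = b))
  expect_equal(qn$a$M, c(5.5, 11, 16.5))
  expect_equal(qn$b$M, c(5.5, 11, 16.5))

  # identical inputs unchanged
  qn2 <- quantile_normalize(list(a = a, b = a))
  expect_equal(qn2$a$M, a$M)

  # ties: agree with an independent rank-then-average oracle
  withr::local_seed(8)
  n <- 50
  mk <- function() {
    tibble::tibble(
      gene_id = sprintf("g%02d", 1:n),
      X = sample(round(rnorm(n, 5), 1)), Y = rnorm(n)
    )
  }
  m1 <- mk()
  m2 <- mk()
  qn3 <- quantile_normalize(list(m1, m2))
  oX <- oracle_quantile_normalize(cbind(m1$X, m2$X))
  expect_equal(qn3[[1]]$X, oX[, 1], tolerance = 1e-10)
  expect_equal(qn3[[2]]$X, oX[, 2], tolerance = 1e-10)

  # idempotence (on tie-free columns, where it holds exactly)
  m3 <- list(
    tibble::tibble(gene_id = m1$gene_id, X = rnorm(n)),
    tibble::tibble(gene_id = m1$gene_id, X = rnorm(n))
  )
  qn_once <- quantile_normalize(m3)
  qn_twice <- quantile_normalize(qn_once)
  expect_equal(qn_twice[[1]]$X, qn_once[[1]]$X, tolerance = 1e-12)

  expect_error(
    quantile_normalize(list(a, dplyr::rename(b, Z = "M"))),
    "same mark columns"
  )
})

test_that("noiseless lasso recovers the generating coefficient", {
  withr::local_seed(42)
  n <- 300
  pm <- tibble::tibble(gene_id = sprintf("g%03d", 1:n), x1 = rnorm(n))
  y <- 2 * pm$x1
  fit <- fit_lasso_cv(pm, y, seed = 1, one_se = FALSE)
  expect_equal(unname(fit$beta[["x1"]]), 2, tolerance = 0.05)
  expect_gt(fit$r_squared, 0.99)
})

test_that("penalty at or above lambda_max zeroes all coefficients", {
  withr::local_seed(43)
  n <- 200
  pm <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:n), x1 = rnorm(n), x2 = rnorm(n)
  )
  y <- 0.3 * pm$x1 + rnorm(n)
  fit <- fit_lasso_cv(pm, y, seed = 2)
  b_max <- as.numeric(stats::coef(fit$fit$glmnet.fit, s = max(fit$lambda_grid)))[-1]
  expect_true(all(b_max == 0))
  # training RSS is non-increasing as lambda decreases
  yhat <- stats::predict(fit$fit$glmnet.fit, newx = as.matrix(pm[, c("x1", "x2")]))
  rss <- colSums((y - yhat)^2)
  expect_true(all(diff(rss) < 1e-8))
  # one-SE lambda is never smaller than the CV-minimum lambda
  expect_gte(fit$lambda_1se, fit$lambda_best)
})

test_that("the lasso path limits to ordinary least squares as lambda -> 0", {
  withr::local_seed(44)
  n <- 500
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- x %*% c(1, -0.5, 0.25, 0) + rnorm(n, sd = 0.5)
  fit <- glmnet::glmnet(x, y,
    lambda = c(0.5, 0.1, 0.01, 1e-5), thresh = 1e-16, standardize = TRUE
  )
  b <- as.numeric(stats::coef(fit, s = 0, exact = TRUE, x = x, y = y))
  ols <- as.numeric(stats::coef(lm(y ~ x)))
  expect_equal(b, ols, tolerance = 1e-6)
})

test_that("errors on constant response and excess folds", {
  pm <- tibble::tibble(gene_id = c("a", "b", "c"), x = 1:3)
  expect_error(fit_lasso_cv(pm, c(1, 1, 1)), "constant")
  expect_error(fit_lasso_cv(pm, c(1, 2, 3), n_folds = 10), "folds")
})

test_that("consensus model pools species and reduces to one species when empty", {
  withr::local_seed(45)
  n <- 400
  beta <- c(2, -1, 0)
  mk <- function(prefix) {
    x <- matrix(rnorm(n * 3), n, 3)
    pm <- tibble::tibble(
      gene_id = sprintf("%s%03d", prefix, 1:n),
      m1 = x[, 1], m2 = x[, 2], m3 = x[, 3]
    )
    list(pm = pm, resp = tibble::tibble(
      gene_id = pm$gene_id, expr = as.numeric(x %*% beta) + rnorm(n, sd = 1)
    ))
  }
  a <- mk("a")
  b <- mk("b")
  cm <- fit_consensus(a$pm, a$resp, b$pm, b$resp, seed = 3)
  fa <- fit_lasso_cv(a$pm, a$resp, seed = 3)
  # consensus coefficients close to the single-species fit
  expect_equal(unname(cm$beta), unname(fa$beta), tolerance = 0.15)
  expect_length(cm$r_squared_by_species, 2)
  expect_true(all(cm$r_squared_by_species > 0.5))

  cm2 <- fit_consensus(a$pm[0, ], a$resp[0, ], b$pm, b$resp, seed = 3)
  fb <- fit_lasso_cv(b$pm, b$resp, seed = 3)
  expect_equal(cm2$beta, fb$beta)

  expect_error(
    fit_consensus(a$pm, a$resp, dplyr::rename(b$pm, z = "m1"), b$resp),
    "different mark sets"
  )
})

test_that("identical marks across species predict zero difference", {
  withr::local_seed(46)
  n <- 200
  pm <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:n), m1 = rnorm(n), m2 = rnorm(n)
  )
  resp <- tibble::tibble(gene_id = pm$gene_id, expr = pm$m1 + rnorm(n, sd = .2))
  fit <- fit_lasso_cv(pm, resp, seed = 4, one_se = FALSE)
  d <- predict_difference(fit, pm, pm, resp, resp)
  expect_true(all(d$predictions$delta_pred == 0))
})

test_that("difference-model R2 matches the closed form on shared-coefficient data", {
  withr::local_seed(47)
  cfg <- sim_config(seed = 47, n_genes = 1200L, chrom_length = 3e7)
  gp <- generate_genome_pair(cfg)
  mx <- generate_marks_expression(cfg, gp)
  ra <- expression_response(mx$expr_a)
  rb <- expression_response(mx$expr_b)
  cm <- fit_consensus(mx$pm_a, ra, mx$pm_b, rb, seed = 47)
  d <- predict_difference(cm, cm$pm_norm$a, cm$pm_norm$b, ra, rb)
  xd <- as.matrix(mx$pm_a[, -1]) - as.matrix(mx$pm_b[, -1])
  v <- stats::var(as.numeric(xd %*% mx$truth$beta))
  closed <- v / (v + 2 * mx$truth$sigma^2)
  expect_lt(abs(d$r_squared - closed), 0.05)
  # planted divergent subset concentrates signal
  d_spec <- predict_difference(cm, cm$pm_norm$a, cm$pm_norm$b, ra, rb,
    genes = mx$truth$divergent_genes
  )
  expect_gt(d_spec$r_squared, d$r_squared)
})

test_that("species-specific gene sets have the documented sizes and recover planted groups", {
  withr::local_seed(48)
  n <- 100
  ids <- sprintf("g%03d", 1:n)
  ea <- tibble::tibble(
    gene_id = ids, stage = "ProE", replicate = 1L, fpkm = rep(10, n)
  )
  eb <- ea
  eb$fpkm <- c(rep(0.5, 10), rep(10, 80), rep(100, 10)) # 10 up, 10 down
  sets <- define_species_specific_genes(ea, eb, fraction = 0.10)
  expect_equal(sum(sets$set == "a_specific"), 10)
  expect_equal(sum(sets$set == "b_specific"), 10)
  expect_equal(sum(sets$set == "rest"), 80)
  expect_setequal(sets$gene_id[sets$set == "a_specific"], ids[1:10])
  expect_setequal(sets$gene_id[sets$set == "b_specific"], ids[91:100])
  expect_error(define_species_specific_genes(ea, eb, fraction = 0.6), "fraction")
})

test_that("per-category expression summaries match direct computation", {
  ids <- c("g1", "g2", "g3", "g4")
  expr <- tidyr::expand_grid(
    gene_id = ids, stage = c("ProE", "BasoE"), replicate = 1:2
  )
  expr$fpkm <- c(3, 5, 3, 5, 1, 3, 1, 3, 7, 9, 7, 9, 0, 0, 0, 0)
  cats <- tibble::tibble(
    gene_id = ids, category = c("conserved", "conserved", "lost", "lost")
  )
  out <- expression_by_category(expr, cats)
  cons_proe <- out[out$category == "conserved" & out$stage == "ProE", ]
  expect_equal(cons_proe$n, 2)
  # replicate averaging precedes the log and the median
  vals <- c(log2(1 + 4), log2(1 + 2))
  expect_equal(cons_proe$median, median(vals))
  expect_equal(cons_proe$q25, unname(quantile(vals, 0.25)))

  # single category, constant expression
  e2 <- dplyr::mutate(expr, fpkm = 7)
  out2 <- expression_by_category(e2, tibble::tibble(gene_id = ids, category = "conserved"))
  expect_true(all(out2$median == log2(8)))
})

test_that("planted category ordering shows up in expression summaries", {
  offs <- c(conserved = 8, strongly_gained = 6, compensatory = 4, gained = 2, lost = 0)
  cfg <- sim_config(
    seed = 49, n_genes = 600L, chrom_length = 3e7,
    category_offsets = offs
  )
  gp <- generate_genome_pair(cfg)
  orth <- gp$genes_a$gene_id[!is.na(gp$genes_a$ortholog_id)]
  withr::local_seed(49)
  cats <- tibble::tibble(
    gene_id = orth,
    category = sample(names(offs), length(orth), TRUE)
  )
  mx <- generate_marks_expression(cfg, gp, gene_categories = cats)
  out <- dplyr::filter(expression_by_category(mx$expr_a, cats), stage == "OrthE")
  med <- setNames(out$median, out$category)[names(offs)]
  expect_true(all(diff(med) < 0))
})

test_that("expression correlations are 1 on the diagonal and match manual Spearman", {
  ids <- sprintf("g%d", 1:6)
  ea <- tibble::tibble(
    gene_id = ids, stage = "ProE", replicate = 1L,
    fpkm = c(0, 1, 4, 9, 16, 25)
  )
  eb <- tibble::tibble(
    gene_id = ids, stage = "ProE", replicate = 1L,
    fpkm = c(1, 0, 2, 30, 9, 18)
  )
  cm <- expression_correlation(list(h = ea, m = eb))
  expect_equal(cm$r[cm$sample_a == "h.ProE" & cm$sample_b == "h.ProE"], 1)
  manual <- stats::cor(
    rank(log2(1 + ea$fpkm)), rank(log2(1 + eb$fpkm))
  )
  expect_equal(cm$r[cm$sample_a == "h.ProE" & cm$sample_b == "m.ProE"], manual)
  # pairing is by id: permuting one table's rows changes nothing
  cm2 <- expression_correlation(list(h = ea[sample(6), ], m = eb))
  expect_equal(cm2$r, cm$r)
})

test_that("gene categories follow the priority rule near peaks", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"), ortholog_id = NA, chrom = "chr1",
    start = c(100000L, 500000L), end = c(110000L, 510000L), strand = "+",
    tss = c(100000L, 500000L), tes = c(109999L, 509999L)
  )
  pks <- dplyr::bind_rows(
    dplyr::mutate(make_peaks("chr1", 105000L), label = "lost"),
    dplyr::mutate(make_peaks("chr1", 108000L), label = "conserved"),
    dplyr::mutate(make_peaks("chr1", 505000L), label = "gained")
  )
  out <- gene_peak_categories(genes, pks)
  expect_equal(out$category, c("conserved", "gained"))
})
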