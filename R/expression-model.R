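# Penalized models of gene expression from promoter epigenomic marks.
# Promoter matrices are quantile-normalized across species per mark, a
# lasso (L1-penalized least squares) is cross-validated over a log-spaced
# lambda grid, and the penalty one standard error above the CV minimum
# (the sparser side) is selected. A consensus model pools both species'
# rows; applied to the between-species difference of marks (no intercept)
# it predicts between-species expression differences.

#' Quantile-normalize promoter matrices across species
#'
#' Standard mean-of-order-statistics quantile normalization, applied per
#' mark column across the supplied matrices (ties share the mean of their
#' quantile block). After normalization the sorted values of each
#' matrix's column are identical.
#'
#' @param matrices Named list of promoter matrices sharing the same mark
#'   columns and equal gene counts.
#' @return List of normalized matrices in the same order.
#' @export
quantile_normalize <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  marks <- setdiff(names(matrices[[1]]), "gene_id")
  for (m in matrices[-1]) {
    if (!setequal(setdiff(names(m), "gene_id"), marks)) {
      abort("all matrices must share the same mark columns")
    }
    if (nrow(m) != nrow(matrices[[1]])) {
      abort("all matrices must have the same number of genes")
    }
  }
  for (mk in marks) {
    mat <- vapply(matrices, function(m) m[[mk]], numeric(nrow(matrices[[1]])))
    norm <- limma::normalizeQuantiles(mat, ties = TRUE)
    for (i in seq_along(matrices)) matrices[[i]][[mk]] <- norm[, i]
  }
  matrices
}

#' Log-scale expression response per gene
#'
#' `log2(1 + FPKM)` averaged over replicates at one stage.
#'
#' @param expr Expression tibble (`gene_id, stage, replicate, fpkm`).
#' @param stage Stage to extract (default `"ProE"`).
#' @return Tibble `gene_id, expr` with `expr = log2(1 + mean FPKM)`.
#' @export
expression_response <- function(expr, stage = "ProE") {
  expr %>%
    filter(.data$stage == .env$stage) %>%
    group_by(.data$gene_id) %>%
    summarise(expr = log2(1 + mean(.data$fpkm)), .groups = "drop")
}

model_frame <- function(pm, response) {
  d <- dplyr::inner_join(pm, response, by = "gene_id")
  marks <- setdiff(names(pm), "gene_id")
  list(
    x = as.matrix(d[, marks, drop = FALSE]),
    y = d$expr, gene_id = d$gene_id, marks = marks
  )
}

# fold ids stratified by response decile for CV stability
stratified_folds <- function(y, n_folds, seed) {
  set.seed(as.integer(seed))
  dec <- dplyr::ntile(y, 10)
  foldid <- integer(length(y))
  for (d in unique(dec)) {
    idx <- which(dec == d)
    foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  foldid
}

#' Cross-validated lasso of expression on promoter marks
#'
#' L1-penalized least squares (via glmnet) with predictors standardized
#' internally and a log-spaced lambda grid spanning three decades below
#' the all-zero solution. With `one_se = TRUE` the largest lambda whose
#' CV error is within one standard error of the minimum is used (the
#' sparser side); the model is refit on the full data at that lambda.
#'
#' @param pm Promoter matrix (`gene_id` + mark columns).
#' @param response Tibble `gene_id, expr` (see [expression_response()])
#'   or a numeric vector aligned to `pm` rows.
#' @param n_folds Cross-validation folds (default 10; the penalty is
#'   insensitive to using many more).
#' @param one_se Use the one-standard-error rule (default) or the CV
#'   minimum.
#' @param seed Seed for fold assignment (stratified by response decile).
#' @return Object of class `lasso_expr_model`: coefficients `beta`,
#'   `intercept`, `lambda_grid`, `cv_mean`, `cv_se`, `lambda_best`,
#'   `lambda_1se`, `lambda_used`, in-sample `r_squared`,
#'   cross-validated `r_squared_cv`, `n`, and the underlying glmnet fit.
#' @export
fit_lasso_cv <- function(pm, response, n_folds = 10L, one_se = TRUE, seed = 1L) {
  if (is.numeric(response)) {
    response <- tibble(gene_id = pm$gene_id, expr = response)
  }
  mf <- model_frame(pm, response)
  if (sd(mf$y) == 0) abort("response is constant")
  if (nrow(mf$x) < n_folds) abort("more folds than observations")
  x_fit <- mf$x
  if (ncol(x_fit) == 1) { # glmnet requires >= 2 columns; pad an inert one
    x_fit <- cbind(x_fit, `.pad` = 0)
  }
  foldid <- stratified_folds(mf$y, n_folds, seed)
  cv <- glmnet::cv.glmnet(
    x_fit, mf$y,
    foldid = foldid, lambda.min.ratio = 0.001,
    nlambda = 100, standardize = TRUE
  )
  lambda_used <- if (one_se) cv$lambda.1se else cv$lambda.min
  beta <- as.numeric(coef(cv, s = lambda_used))[seq_len(1 + length(mf$marks))]
  names(beta) <- c("(Intercept)", mf$marks)
  yhat <- as.numeric(predict(cv, newx = x_fit, s = lambda_used))
  rss <- sum((mf$y - yhat)^2)
  tss <- sum((mf$y - mean(mf$y))^2)
  i_used <- which.min(abs(cv$lambda - lambda_used))
  structure(
    list(
      beta = beta[-1], intercept = beta[1], marks = mf$marks,
      lambda_grid = cv$lambda, cv_mean = cv$cvm, cv_se = cv$cvsd,
      lambda_best = cv$lambda.min, lambda_1se = cv$lambda.1se,
      lambda_used = lambda_used, one_se = one_se,
      r_squared = 1 - rss / tss,
      r_squared_cv = 1 - cv$cvm[i_used] / mean((mf$y - mean(mf$y))^2),
      n = length(mf$y), n_folds = n_folds, seed = seed, fit = cv
    ),
    class = "lasso_expr_model"
  )
}

#' @export
print.lasso_expr_model <- function(x, ...) {
  cat(sprintf(
    "lasso expression model: n = %d, lambda = %.4g (%s), R^2 = %.3f, %d/%d nonzero\n",
    x$n, x$lambda_used, if (x$one_se) "1-SE" else "min",
    x$r_squared, sum(x$beta != 0), length(x$beta)
  ))
  invisible(x)
}

#' @export
tidy.lasso_expr_model <- function(x, ...) {
  tibble(term = names(x$beta), estimate = unname(x$beta))
}

#' @export
glance.lasso_expr_model <- function(x, ...) {
  tibble(
    n = x$n, lambda_used = x$lambda_used, lambda_best = x$lambda_best,
    lambda_1se = x$lambda_1se, r_squared = x$r_squared,
    r_squared_cv = x$r_squared_cv, df = sum(x$beta != 0)
  )
}

#' Predict expression from a promoter matrix
#' @param object A `lasso_expr_model`.
#' @param pm Promoter matrix with the model's mark columns.
#' @param ... Unused.
#' @return Tibble `gene_id, .pred`.
#' @export
predict.lasso_expr_model <- function(object, pm, ...) {
  x <- as.matrix(pm[, object$marks, drop = FALSE])
  tibble(
    gene_id = pm$gene_id,
    .pred = object$intercept + as.numeric(x %*% object$beta)
  )
}

#' Consensus cross-species expression model
#'
#' Quantile-normalizes the two species' promoter matrices (unless told
#' not to), stacks their rows, fits one lasso, and reports per-species
#' in-sample R-squared from that single model.
#'
#' @param pm_a,pm_b Promoter matrices for the two species (same marks).
#' @param resp_a,resp_b Response tibbles (`gene_id, expr`).
#' @param quantile_norm Quantile-normalize matrices first (default TRUE).
#' @inheritParams fit_lasso_cv
#' @return A `lasso_expr_model` with extra fields `r_squared_by_species`
#'   (named vector) and the normalized matrices.
#' @export
fit_consensus <- function(pm_a, resp_a, pm_b, resp_b, quantile_norm = TRUE,
                          n_folds = 10L, one_se = TRUE, seed = 1L) {
  marks <- setdiff(names(pm_a), "gene_id")
  if (!setequal(marks, setdiff(names(pm_b), "gene_id"))) {
    abort("promoter matrices have different mark sets")
  }
  if (nrow(pm_a) == 0 || nrow(pm_b) == 0) {
    one <- if (nrow(pm_a) > 0) list(pm_a, resp_a) else list(pm_b, resp_b)
    return(fit_lasso_cv(one[[1]], one[[2]], n_folds, one_se, seed))
  }
  if (quantile_norm && nrow(pm_a) == nrow(pm_b)) {
    qn <- quantile_normalize(list(a = pm_a, b = pm_b))
    pm_a <- qn$a
    pm_b <- qn$b
  }
  pooled_pm <- bind_rows(
    pm_a %>% mutate(gene_id = paste0("a:", .data$gene_id)),
    pm_b %>% mutate(gene_id = paste0("b:", .data$gene_id))
  )
  pooled_resp <- bind_rows(
    resp_a %>% mutate(gene_id = paste0("a:", .data$gene_id)),
    resp_b %>% mutate(gene_id = paste0("b:", .data$gene_id))
  )
  fit <- fit_lasso_cv(pooled_pm, pooled_resp, n_folds, one_se, seed)
  r2 <- function(pm, resp) {
    d <- dplyr::inner_join(predict(fit, pm), resp, by = "gene_id")
    1 - sum((d$expr - d$.pred)^2) / sum((d$expr - mean(d$expr))^2)
  }
  fit$r_squared_by_species <- c(a = r2(pm_a, resp_a), b = r2(pm_b, resp_b))
  fit$pm_norm <- list(a = pm_a, b = pm_b)
  class(fit) <- c("consensus_expr_model", class(fit))
  fit
}

#' Predict between-species expression differences
#'
#' Applies the consensus coefficients to the per-gene difference of
#' promoter marks, `f(Xa - Xb)` with no intercept contribution, and
#' scores the prediction against the observed expression difference
#' `ya - yb`. Optionally restricted to a gene subset (e.g. the planted or
#' measured species-specific genes).
#'
#' @param model A fitted `lasso_expr_model`/`consensus_expr_model`.
#' @param pm_a,pm_b Promoter matrices with rows pairable by `gene_id`
#'   (ortholog-paired identifiers).
#' @param resp_a,resp_b Response tibbles.
#' @param genes Optional character vector restricting the evaluation.
#' @return List: `predictions` (tibble `gene_id, delta_pred,
#'   delta_obs`), `r_squared`, `n` (and `n_dropped` unpaired genes).
#' @export
predict_difference <- function(model, pm_a, pm_b, resp_a, resp_b, genes = NULL) {
  marks <- model$marks
  paired <- dplyr::inner_join(pm_a, pm_b, by = "gene_id", suffix = c(".a", ".b"))
  n_dropped <- nrow(pm_a) + nrow(pm_b) - 2 * nrow(paired)
  if (n_dropped > 0) {
    rlang::inform(sprintf("%d unpaired gene row(s) dropped", n_dropped))
  }
  xd <- as.matrix(paired[, paste0(marks, ".a")]) -
    as.matrix(paired[, paste0(marks, ".b")])
  delta_pred <- as.numeric(xd %*% model$beta)
  obs <- dplyr::inner_join(
    rename(resp_a, expr_a = "expr"), rename(resp_b, expr_b = "expr"),
    by = "gene_id"
  )
  d <- tibble(gene_id = paired$gene_id, delta_pred = delta_pred) %>%
    dplyr::inner_join(obs, by = "gene_id") %>%
    mutate(delta_obs = .data$expr_a - .data$expr_b)
  if (!is.null(genes)) d <- filter(d, .data$gene_id %in% genes)
  r2 <- 1 - sum((d$delta_obs - d$delta_pred)^2) /
    sum((d$delta_obs - mean(d$delta_obs))^2)
  list(
    predictions = d[, c("gene_id", "delta_pred", "delta_obs")],
    r_squared = r2, n = nrow(d), n_dropped = n_dropped
  )
}

#' Define species-specific gene sets from expression
#'
#' Genes are ranked by the signed ratio
#' `log2((FPKM_a + 1) / (FPKM_b + 1))` at one stage (replicates
#' averaged); the top `fraction` are a-specific and the bottom `fraction`
#' b-specific (sizes `floor(fraction * N)`).
#'
#' @param expr_a,expr_b Expression tibbles for the two species with
#'   ortholog-paired `gene_id`s.
#' @param stage Stage used for the ranking (default `"ProE"`).
#' @param fraction Fraction per tail, in (0, 0.5].
#' @return Tibble `gene_id, ratio, set` with
#'   `set in {a_specific, b_specific, rest}`.
#' @export
define_species_specific_genes <- function(expr_a, expr_b, stage = "ProE",
                                          fraction = 0.10) {
  if (fraction <= 0 || fraction > 0.5) abort("fraction must be in (0, 0.5]")
  fa <- expr_a %>%
    filter(.data$stage == .env$stage) %>%
    group_by(.data$gene_id) %>%
    summarise(fpkm_a = mean(.data$fpkm), .groups = "drop")
  fb <- expr_b %>%
    filter(.data$stage == .env$stage) %>%
    group_by(.data$gene_id) %>%
    summarise(fpkm_b = mean(.data$fpkm), .groups = "drop")
  d <- dplyr::inner_join(fa, fb, by = "gene_id") %>%
    mutate(ratio = log2((.data$fpkm_a + 1) / (.data$fpkm_b + 1))) %>%
    arrange(dplyr::desc(.data$ratio), .data$gene_id)
  n <- nrow(d)
  k <- floor(fraction * n)
  d$set <- "rest"
  if (k > 0) {
    d$set[seq_len(k)] <- "a_specific"
    d$set[seq(n - k + 1, n)] <- "b_specific"
  }
  if (k > 0 && d$ratio[k] == d$ratio[k + 1]) {
    rlang::inform("ties at the species-specific cutoff; order is deterministic by gene_id")
  }
  d[, c("gene_id", "ratio", "set")]
}

#' Assign genes a conservation category from nearby peaks
#'
#' A gene near peaks of several classes gets the highest-priority class:
#' conserved > strongly_gained > compensatory > gained > lost.
#'
#' @param genes Gene tibble.
#' @param labeled_peaks Peak tibble with a `label` column.
#' @param window Gene-body expansion in bp used for proximity (10 kb).
#' @param priority Category priority order.
#' @return Tibble `gene_id, category` (`"none"` when no peak is near).
#' @export
gene_peak_categories <- function(genes, labeled_peaks, window = 10000L,
                                 priority = c(
                                   "conserved", "strongly_gained",
                                   "compensatory", "gained", "lost"
                                 )) {
  cat <- rep("none", nrow(genes))
  for (lab in rev(priority)) {
    pk <- labeled_peaks %>% filter(.data$label == lab)
    if (!nrow(pk)) next
    hit <- genes$gene_id %in% genes_near_peaks(genes, pk, window)
    cat[hit] <- lab
  }
  tibble(gene_id = genes$gene_id, category = cat)
}

#' Expression summaries per conservation category
#'
#' Per category and stage: median and quartiles of `log2(1 + FPKM)`
#' (replicates averaged first). With a second species' table the same
#' summaries are produced for the expression difference `a - b`.
#'
#' @param expr Expression tibble.
#' @param categories Tibble `gene_id, category`.
#' @param expr_b Optional partner-species table for difference summaries.
#' @return Tibble `category, stage, n, median, q25, q75`.
#' @export
expression_by_category <- function(expr, categories, expr_b = NULL) {
  val <- expr %>%
    group_by(.data$gene_id, .data$stage) %>%
    summarise(value = log2(1 + mean(.data$fpkm)), .groups = "drop")
  if (!is.null(expr_b)) {
    vb <- expr_b %>%
      group_by(.data$gene_id, .data$stage) %>%
      summarise(value_b = log2(1 + mean(.data$fpkm)), .groups = "drop")
    val <- dplyr::inner_join(val, vb, by = c("gene_id", "stage")) %>%
      mutate(value = .data$value - .data$value_b) %>%
      select("gene_id", "stage", "value")
  }
  out <- dplyr::inner_join(val, categories, by = "gene_id") %>%
    group_by(.data$category, .data$stage) %>%
    summarise(
      n = dplyr::n(),
      median = median(.data$value),
      q25 = unname(quantile(.data$value, 0.25)),
      q75 = unname(quantile(.data$value, 0.75)),
      .groups = "drop"
    )
  empty <- setdiff(unique(categories$category), unique(out$category))
  if (length(empty)) {
    warn(sprintf("empty categor%s omitted: %s",
      if (length(empty) > 1) "ies" else "y", paste(empty, collapse = ", ")))
  }
  out
}

#' Stage-by-stage expression correlation matrix
#'
#' Correlations (default Spearman) of `log2(1 + FPKM)` profiles between
#' all stage columns of the supplied tables, over ortholog-paired genes.
#'
#' @param tables Named list of expression tibbles (names = species).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Tibble `sample_a, sample_b, r` where sample = species.stage.
#' @export
expression_correlation <- function(tables, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  wide <- purrr::imap(tables, function(e, sp) {
    e %>%
      group_by(.data$gene_id, .data$stage) %>%
      summarise(value = log2(1 + mean(.data$fpkm)), .groups = "drop") %>%
      mutate(sample = paste(sp, .data$stage, sep = "."))
  }) %>%
    bind_rows() %>%
    select("gene_id", "sample", "value") %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "value") %>%
    tidyr::drop_na()
  samples <- setdiff(names(wide), "gene_id")
  cm <- cor(as.matrix(wide[, samples]), method = method)
  as_tibble(as.data.frame.table(cm, responseName = "r")) %>%
    rename(sample_a = "Var1", sample_b = "Var2") %>%
    mutate(
      sample_a = as.character(.data$sample_a),
      sample_b = as.character(.data$sample_b)
    )
}
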