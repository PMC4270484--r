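# ggplot2 views of the main result types.

#' Plot a conservation summary across TFs
#'
#' Stacked conserved/lost counts over mapped peaks, one bar per TF.
#'
#' @param summary Tibble with `factor`, `n_conserved`, `n_lost`.
#' @return A ggplot.
#' @export
plot_conservation <- function(summary) {
  d <- summary %>%
    tidyr::pivot_longer(c("n_conserved", "n_lost"),
      names_to = "class", values_to = "n"
    ) %>%
    mutate(class = sub("^n_", "", .data$class))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$factor, y = .data$n, fill = .data$class
  )) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "mapped peaks", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a metagene profile
#'
#' @param profile Tibble from [metagene_profile()].
#' @return A ggplot with TSS/TES boundaries marked.
#' @export
plot_metagene <- function(profile) {
  bounds <- cumsum(rle(profile$zone)$lengths)
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = bounds[1:2] + 0.5, linetype = "dashed") +
    ggplot2::labs(x = "metagene position (TSS ... TES)", y = "mean signal") +
    ggplot2::theme_minimal()
}

#' Plot chromatin-state fold enrichments
#'
#' @param enr Tibble from [state_overlap_enrichment()], optionally with a
#'   `category` column for faceting.
#' @return A ggplot heat/bar chart of per-state folds.
#' @export
plot_state_enrichment <- function(enr) {
  p <- ggplot2::ggplot(
    enr %>% filter(!is.na(.data$state)),
    ggplot2::aes(x = factor(.data$state), y = .data$fold)
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "chromatin state", y = "fold enrichment") +
    ggplot2::theme_minimal()
  if ("category" %in% names(enr)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$category))
  }
  p
}

#' Plot a co-occupancy transfer matrix
#'
#' @param transfer A `region_transfer` or its `matrix` tibble.
#' @return A ggplot tile map of source -> destination proportions.
#' @export
plot_transfer <- function(transfer) {
  m <- if (inherits(transfer, "region_transfer")) transfer$matrix else transfer
  ggplot2::ggplot(m, ggplot2::aes(
    x = .data$dst_group, y = .data$src_group, fill = .data$proportion
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$proportion)
    ), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "grey20", limits = c(0, 1)) +
    ggplot2::labs(x = "destination group", y = "source group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' CV curve of a lasso expression model
#'
#' @param object A `lasso_expr_model`.
#' @param ... Unused.
#' @return A ggplot of CV error vs log lambda with the chosen penalty.
#' @export
autoplot.lasso_expr_model <- function(object, ...) {
  d <- tibble(
    log_lambda = log(object$lambda_grid),
    cvm = object$cv_mean, cvsd = object$cv_se
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log_lambda, y = .data$cvm)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$cvm - .data$cvsd, ymax = .data$cvm + .data$cvsd),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      xintercept = log(c(object$lambda_best, object$lambda_used)),
      linetype = c("dotted", "dashed")
    ) +
    ggplot2::labs(x = "log(lambda)", y = "CV mean-squared error") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
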