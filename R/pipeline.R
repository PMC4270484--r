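# End-to-end orchestration over the synthetic study or user-supplied
# files: conservation classification per TF, combinatorial co-occupancy
# transfer, enrichment statistics, expression modeling, and a summary
# JSON. Deterministic under the config seed.

#' Default pipeline configuration
#'
#' All analysis parameters at their study defaults (flank 50 bp,
#' compensatory window 5,000 bp, strongly-gained fraction 0.10, cluster
#' radius 1,000 bp, minimum match 0.10, 10 CV folds). The permutation
#' count for the enrichment stage is 2,000 here (a desk-scale setting;
#' [permutation_enrichment()] itself defaults to 100,000).
#'
#' @param seed Master seed.
#' @param ... Overrides for any field.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    flank = 50L, comp_window = 5000L, strong_fraction = 0.10,
    radius = 1000L, min_match = 0.10, n_perm = 2000L,
    n_folds = 10L, one_se = TRUE, promoter_window = 2000L,
    proximity_window = 10000L, crm_panel = c("GATA1", "KLF1", "TAL1"),
    specific_fraction = 0.10,
    sim = sim_config(seed = as.integer(seed))
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Run the full comparative pipeline
#'
#' Simulates (or accepts) a paired-species study, then runs conservation
#' classification per TF, co-occupancy transfer over the configured
#' panel, chromatin-state and permutation enrichment, the consensus
#' expression model and difference model, species-specific gene sets and
#' per-category expression summaries. Artifacts (TSV/JSON) are written
#' under `out_dir` when given.
#'
#' @param cfg A `run_config`.
#' @param study Optional study list as from [simulate_study()]; simulated
#'   from `cfg$sim` when NULL.
#' @param out_dir Optional output directory for artifacts.
#' @return List of stage results plus `summary` (the JSON-serializable
#'   bundle).
#' @export
run_pipeline <- function(cfg = run_config(), study = NULL, out_dir = NULL) {
  if (is.null(study)) study <- simulate_study(cfg$sim)
  gp <- study$genomes
  pk <- study$peaks

  # --- conservation per TF ---------------------------------------------
  cons <- list()
  dst_labeled <- list()
  for (tf in unique(pk$src$factor)) {
    res <- classify_source_peaks(
      pk$src %>% filter(.data$factor == tf),
      pk$dst %>% filter(.data$factor == tf),
      gp$chains,
      flank = cfg$flank, comp_window = cfg$comp_window,
      min_match = cfg$min_match
    )
    cons[[tf]] <- res
    dst_labeled[[tf]] <- classify_target_peaks(
      res$target_flags,
      strong_fraction = cfg$strong_fraction
    )
  }
  dst_labeled <- bind_rows(dst_labeled)
  cons_summary <- purrr::imap_dfr(cons, ~ mutate(.x$summary, factor = .y, .before = 1))

  # --- co-occupancy transfer -------------------------------------------
  panel <- cfg$crm_panel
  co_src <- if (!is.null(study$coocc)) study$coocc$src else pk$src
  co_dst <- if (!is.null(study$coocc)) study$coocc$dst else pk$dst
  src_regions <- build_regions(
    co_src %>% filter(.data$factor %in% panel),
    radius = cfg$radius, flank = cfg$flank
  )
  dst_regions <- build_regions(
    co_dst %>% filter(.data$factor %in% panel),
    radius = cfg$radius, flank = cfg$flank
  )
  transfer <- transfer_regions(src_regions, dst_regions, gp$chains,
    flank = cfg$flank, min_match = cfg$min_match
  )
  crms <- conserved_crms(transfer, src_regions, panel)
  crm_genes <- assign_regions_to_genes(crms, gp$genes_a)

  # --- enrichment -------------------------------------------------------
  workspace <- tibble(
    chrom = names(gp$chrom_sizes_b), start = 0L,
    end = as.integer(unlist(gp$chrom_sizes_b))
  )
  state_enr <- purrr::map_dfr(
    c("conserved", "compensatory", "gained", "strongly_gained"),
    function(lab) {
      q <- dst_labeled %>% filter(.data$label == lab)
      if (!nrow(q)) return(NULL)
      state_overlap_enrichment(study$segmentation, q[, c("chrom", "start", "end")]) %>%
        mutate(category = lab, .before = 1)
    }
  )
  cons_sites <- dst_labeled %>% filter(.data$label == "conserved")
  perm <- permutation_enrichment(
    query = utils::head(cons_sites[, c("chrom", "start", "end")], 200),
    reference = study$segmentation %>%
      filter(.data$state == cfg$sim$active_state) %>%
      select("chrom", "start", "end"),
    workspace = workspace, n_perm = cfg$n_perm, seed = cfg$seed
  )

  # --- expression model -------------------------------------------------
  mx <- study$marks
  resp_a <- expression_response(mx$expr_a)
  resp_b <- expression_response(mx$expr_b)
  consensus <- fit_consensus(mx$pm_a, resp_a, mx$pm_b, resp_b,
    n_folds = cfg$n_folds, one_se = cfg$one_se, seed = cfg$seed
  )
  qn <- consensus$pm_norm
  spec_genes <- define_species_specific_genes(mx$expr_a, mx$expr_b,
    fraction = cfg$specific_fraction
  )
  specific_ids <- spec_genes$gene_id[spec_genes$set != "rest"]
  diff_all <- predict_difference(consensus, qn$a, qn$b, resp_a, resp_b)
  diff_spec <- predict_difference(consensus, qn$a, qn$b, resp_a, resp_b,
    genes = specific_ids
  )
  categories <- gene_peak_categories(gp$genes_b, dst_labeled,
    window = cfg$proximity_window
  )
  expr_cat <- expression_by_category(mx$expr_b, categories)
  odds <- gene_odds_ratio(
    genes_special = spec_genes$gene_id[spec_genes$set == "a_specific"],
    genes_rest = spec_genes$gene_id[spec_genes$set == "rest"],
    occupied_genes = genes_near_peaks(
      gp$genes_b, dst_labeled %>% filter(.data$label == "gained"),
      window = cfg$proximity_window
    )
  )

  summary <- list(
    seed = cfg$seed,
    conservation = cons_summary,
    strongly_gained = dst_labeled %>%
      filter(.data$label == "strongly_gained") %>%
      count(.data$factor),
    transfer = transfer$matrix,
    n_conserved_crms = nrow(crms),
    state_enrichment = state_enr %>%
      select("category", "state", "fold"),
    permutation = perm,
    model = glance(consensus),
    model_beta = tidy(consensus),
    r_squared_by_species = as.list(consensus$r_squared_by_species),
    difference_r2_all = diff_all$r_squared,
    difference_r2_specific = diff_spec$r_squared,
    species_specific_odds = odds,
    expression_by_category = expr_cat
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(cons_summary, file.path(out_dir, "conservation_summary.tsv"))
    write_peaks(
      dst_labeled %>% mutate(name = paste(.data$name, .data$label, sep = "|")),
      file.path(out_dir, "target_peaks_labeled.narrowPeak")
    )
    readr::write_tsv(transfer$matrix, file.path(out_dir, "transfer_matrix.tsv"))
    readr::write_tsv(
      crm_genes %>% select(-"member_rows"),
      file.path(out_dir, "conserved_crms.tsv")
    )
    readr::write_tsv(state_enr, file.path(out_dir, "state_enrichment.tsv"))
    readr::write_tsv(expr_cat, file.path(out_dir, "expression_by_category.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  validate_summary(summary)
  invisible(list(
    conservation = cons, target_peaks = dst_labeled, transfer = transfer,
    conserved_crms = crm_genes, state_enrichment = state_enr,
    permutation = perm, consensus = consensus, spec_genes = spec_genes,
    difference = list(all = diff_all, specific = diff_spec),
    expression_by_category = expr_cat, summary = summary
  ))
}

# structural check of the summary bundle (shapes, ranges)
validate_summary <- function(s) {
  stopifnot(
    is.data.frame(s$conservation),
    all(c("factor", "n_mapped", "rate_conserved") %in% names(s$conservation)),
    all(s$conservation$rate_conserved >= 0 & s$conservation$rate_conserved <= 1),
    is.data.frame(s$transfer),
    all(abs(tapply(s$transfer$proportion, s$transfer$src_group, sum) - 1) < 1e-9),
    s$n_conserved_crms >= 0,
    is.finite(s$difference_r2_all), is.finite(s$difference_r2_specific),
    all(c("r_squared", "lambda_used") %in% names(s$model))
  )
  invisible(TRUE)
}
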