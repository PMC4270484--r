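# Five-way conservation classification of TF occupancy sites. Source
# (species A) summit windows are lifted onto species B; mapped windows
# overlapping a B peak are "conserved", otherwise "lost". B peaks sitting
# within +/- comp_window of a lost lifted window are "compensatory"; the
# remaining B peaks are "gained", and the top strong_fraction of gained
# peaks by read score are relabeled "strongly_gained". Rates use the
# number of successfully mapped source peaks as denominator.

#' Classify source-species peaks as conserved or lost
#'
#' Lifts each source peak's summit window (`summit +/- flank`) through the
#' chain; unmapped peaks are excluded from the rate denominator. A mapped
#' window overlapping (>= 1 bp) any destination peak is `conserved`,
#' otherwise `lost`. Destination peaks overlapping a lost window expanded
#' by `comp_window` on each side are flagged compensatory (the source
#' peak stays lost); destination peaks overlapping an unexpanded mapped
#' window are flagged conserved, with priority conserved > compensatory.
#'
#' @param src Source-species peak tibble (needs `summit`).
#' @param dst Destination-species peak tibble.
#' @param chains Chain tibble mapping source -> destination.
#' @param flank Summit-window half-width (bp).
#' @param comp_window Expansion (bp) on each side when searching for
#'   compensatory sites near lost windows.
#' @param min_match Minimum aligned fraction for the lift.
#' @return Object of class `peak_conservation`: list with `source`
#'   (source peaks + `status`, lifted coordinates, `label`),
#'   `target_flags` (destination peaks + `is_conserved`,
#'   `is_compensatory`) and `summary` (one-row tibble of counts/rates).
#' @export
classify_source_peaks <- function(src, dst, chains, flank = 50L,
                                  comp_window = 5000L, min_match = 0.10) {
  stopifnot("summit" %in% names(src))
  w <- summit_window(src$summit, flank)
  windows <- tibble(chrom = src$chrom, start = w$start, end = w$end)
  lifted <- lift_intervals(windows, chains, min_match = min_match)
  src <- src %>% mutate(
    status = lifted$status,
    lifted_chrom = lifted$lifted_chrom,
    lifted_start = lifted$lifted_start,
    lifted_end = lifted$lifted_end,
    match_fraction = lifted$match_fraction
  )
  mapped <- src$status == "mapped"
  dst_iv <- tibble(chrom = dst$chrom, start = dst$start, end = dst$end)
  lifted_iv <- tibble(
    chrom = src$lifted_chrom[mapped],
    start = src$lifted_start[mapped],
    end = src$lifted_end[mapped]
  )
  conserved <- logical(nrow(src))
  if (any(mapped) && nrow(dst)) {
    conserved[mapped] <- interval_overlaps_any(lifted_iv, dst_iv)
  }
  src$label <- dplyr::case_when(
    !mapped ~ NA_character_,
    conserved ~ "conserved",
    TRUE ~ "lost"
  )

  # destination-side flags
  is_cons <- rep(FALSE, nrow(dst))
  is_comp <- rep(FALSE, nrow(dst))
  src$has_compensatory <- FALSE
  lost <- which(src$label %in% "lost")
  if (nrow(dst) && any(mapped)) {
    is_cons <- interval_overlaps_any(dst_iv, lifted_iv)
    if (length(lost)) {
      lost_iv <- tibble(
        chrom = src$lifted_chrom[lost],
        start = pmax(0L, src$lifted_start[lost] - as.integer(comp_window)),
        end = src$lifted_end[lost] + as.integer(comp_window)
      )
      # source view: lost peaks whose expanded window regains an overlap
      src$has_compensatory[lost] <- interval_overlaps_any(lost_iv, dst_iv)
      # destination view: peaks explaining a lost site (conserved wins)
      is_comp <- interval_overlaps_any(dst_iv, lost_iv) & !is_cons
    }
  }
  dst$is_conserved <- is_cons
  dst$is_compensatory <- is_comp

  n_mapped <- sum(mapped)
  n_cons <- sum(src$label %in% "conserved")
  n_lost <- length(lost)
  summary <- tibble(
    n_source_peaks = nrow(src),
    n_mapped = n_mapped,
    n_conserved = n_cons,
    n_lost = n_lost,
    n_compensatory = sum(src$has_compensatory),
    rate_conserved = if (n_mapped > 0) n_cons / n_mapped else NA_real_,
    compensatory_fraction_of_lost = if (n_lost > 0) {
      sum(src$has_compensatory) / n_lost
    } else {
      NA_real_
    }
  )
  structure(
    list(source = src, target_flags = dst, summary = summary),
    class = "peak_conservation"
  )
}

#' @export
print.peak_conservation <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "peak conservation: %d source peaks, %d mapped, %d conserved (rate %.3f), %d compensatory\n",
    s$n_source_peaks, s$n_mapped, s$n_conserved, s$rate_conserved, s$n_compensatory
  ))
  invisible(x)
}

#' @export
tidy.peak_conservation <- function(x, ...) x$summary

#' Label destination-species peaks
#'
#' Destination peaks that are neither conserved nor compensatory are
#' `gained`; the top `strong_fraction` of gained peaks by read score
#' (per TF by default) are relabeled `strongly_gained`. Score ties at the
#' cutoff are broken by genomic order (chrom, start).
#'
#' @param target_flags Destination peak tibble carrying `is_conserved`
#'   and `is_compensatory` (from [classify_source_peaks()]).
#' @param strong_fraction Fraction of gained peaks relabeled strongly
#'   gained (default 0.10, the "top 10%" rule).
#' @param per_factor Take the top fraction within each TF (`factor`
#'   column) rather than pooled.
#' @return `target_flags` with a `label` column in
#'   {conserved, compensatory, gained, strongly_gained}.
#' @export
classify_target_peaks <- function(target_flags, strong_fraction = 0.10,
                                  per_factor = TRUE) {
  stopifnot(
    all(c("is_conserved", "is_compensatory", "score") %in% names(target_flags)),
    strong_fraction >= 0, strong_fraction <= 1
  )
  dst <- target_flags %>% mutate(
    label = dplyr::case_when(
      .data$is_conserved ~ "conserved",
      .data$is_compensatory ~ "compensatory",
      TRUE ~ "gained"
    ),
    .row_id = dplyr::row_number()
  )
  grp <- if (per_factor && "factor" %in% names(dst)) dst$factor else "all"
  gained <- which(dst$label == "gained")
  for (g in unique(grp[gained])) {
    idx <- gained[grp[gained] == g]
    k <- ceiling(strong_fraction * length(idx))
    if (k > 0) {
      ord <- idx[order(-dst$score[idx], dst$chrom[idx], dst$start[idx])]
      dst$label[ord[seq_len(k)]] <- "strongly_gained"
    }
  }
  dst %>% select(-".row_id")
}

#' Keep the top-scoring fraction of peaks
#'
#' Retains the `ceiling(top_fraction * n)` peaks with the highest read
#' score (ties broken by genomic order), mirroring top-percentile peak
#' filtering on total mapped reads.
#'
#' @param peaks Peak tibble with a `score` column.
#' @param top_fraction Fraction in (0, 1].
#' @return Filtered peak tibble (original row order preserved).
#' @export
rank_filter_peaks <- function(peaks, top_fraction) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  n <- nrow(peaks)
  if (!n) return(peaks)
  k <- ceiling(top_fraction * n)
  ord <- order(-peaks$score, peaks$chrom, peaks$start)
  keep <- sort(ord[seq_len(k)])
  peaks[keep, , drop = FALSE]
}
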