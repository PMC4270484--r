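# Combinatorial co-occupancy regions: summits of all TFs on one genome
# are single-linkage clustered at a distance radius (default +/- 1000 bp,
# so a panel of k TFs yields 2^k - 1 combinatorial groups), regions are
# lifted across the chain, and the transfer of each source group into
# destination groups (or "absent") is tabulated as row-stochastic
# proportions x_ij / n_i over mapped regions.

#' Cluster TF summits into co-occupancy regions
#'
#' Single-linkage clustering of peak summits (all TFs pooled) on each
#' chromosome: consecutive summits at distance <= `radius` join one
#' region. On a line this equals the transitive closure of the pairwise
#' "within radius" relation.
#'
#' @param peaks Peak tibble with `summit` and `factor` columns (the TF
#'   panel).
#' @param radius Linkage distance in bp (default 1000).
#' @param flank Half-width added around the outermost summits to form the
#'   region interval.
#' @return Region tibble: `region_id, chrom, start, end, group` (sorted
#'   "+"-joined TF names), `n_tfs, n_peaks, mid_summit`, plus a
#'   `member_rows` list-column of row indices into `peaks`.
#' @export
build_regions <- function(peaks, radius = 1000L, flank = 50L) {
  stopifnot(all(c("summit", "factor") %in% names(peaks)))
  if (!nrow(peaks)) {
    return(tibble(
      region_id = character(), chrom = character(), start = integer(),
      end = integer(), group = character(), n_tfs = integer(),
      n_peaks = integer(), mid_summit = integer(), member_rows = list()
    ))
  }
  pk <- peaks %>% mutate(.row = dplyr::row_number())
  out <- purrr::map_dfr(split_by_chrom(pk), function(d) {
    d <- arrange(d, .data$summit)
    gap <- c(Inf, diff(d$summit))
    cluster <- cumsum(gap > radius)
    d %>%
      group_by(cluster = cluster) %>%
      summarise(
        chrom = .data$chrom[1],
        start = pmax(0L, min(.data$summit) - as.integer(flank)),
        end = max(.data$summit) + as.integer(flank) + 1L,
        group = paste(sort(unique(.data$factor)), collapse = "+"),
        n_tfs = dplyr::n_distinct(.data$factor),
        n_peaks = dplyr::n(),
        mid_summit = as.integer(round(median(.data$summit))),
        member_rows = list(.data$.row),
        .groups = "drop"
      ) %>%
      select(-"cluster")
  }) %>% arrange(.data$chrom, .data$start)
  out$region_id <- sprintf("R%05d", seq_len(nrow(out)))
  out[, c(
    "region_id", "chrom", "start", "end", "group", "n_tfs", "n_peaks",
    "mid_summit", "member_rows"
  )]
}

# representative window for lifting a region: the full span when narrow,
# otherwise the flank window around the median summit
region_rep_window <- function(regions, max_span = 500L, flank = 50L) {
  wide <- (regions$end - regions$start) >= max_span
  tibble(
    chrom = regions$chrom,
    start = ifelse(wide, pmax(0L, regions$mid_summit - flank), regions$start),
    end = ifelse(wide, regions$mid_summit + flank + 1L, regions$end)
  )
}

#' Cross-species transfer of co-occupancy regions
#'
#' Lifts each source region's representative window (full span when
#' < 500 bp, else median summit +/- `flank`) and assigns it to the
#' destination region it overlaps (>= 1 bp; ambiguity resolved by larger
#' overlap, then nearer median summit) or to `"absent"`. Unmapped source
#' regions are excluded from the denominators.
#'
#' @param src_regions,dst_regions Region tibbles from [build_regions()]
#'   built with the same TF panel.
#' @param chains Chain tibble, source -> destination.
#' @param flank Half-width of the representative summit window.
#' @param min_match Minimum aligned fraction for the lift.
#' @return Object of class `region_transfer`: `assignments` (per source
#'   region: `status`, destination `dst_group`, `dst_region_id`) and
#'   `matrix` (tibble `src_group, n, dst_group, x, proportion` with
#'   row-stochastic proportions over mapped regions).
#' @export
transfer_regions <- function(src_regions, dst_regions, chains,
                             flank = 50L, min_match = 0.10) {
  rep_w <- region_rep_window(src_regions, flank = flank)
  lifted <- lift_intervals(rep_w, chains, min_match = min_match)
  dst_iv <- dst_regions
  assign_one <- function(ch, s, e) {
    cand <- which(dst_iv$chrom == ch & dst_iv$start < e & dst_iv$end > s)
    if (!length(cand)) {
      return(NA_integer_)
    }
    ovl <- pmin(dst_iv$end[cand], e) - pmax(dst_iv$start[cand], s)
    cand <- cand[ovl == max(ovl)]
    if (length(cand) > 1) {
      mid <- (s + e) / 2
      cand <- cand[order(abs(dst_iv$mid_summit[cand] - mid))]
    }
    cand[1]
  }
  hit <- rep(NA_integer_, nrow(src_regions))
  mapped <- lifted$status == "mapped"
  for (k in which(mapped)) {
    hit[k] <- assign_one(
      lifted$lifted_chrom[k], lifted$lifted_start[k], lifted$lifted_end[k]
    )
  }
  assignments <- tibble(
    region_id = src_regions$region_id,
    src_group = src_regions$group,
    status = lifted$status,
    dst_region_id = ifelse(is.na(hit), NA_character_, dst_iv$region_id[hit]),
    dst_group = dplyr::case_when(
      !mapped ~ NA_character_,
      is.na(hit) ~ "absent",
      TRUE ~ dst_iv$group[hit]
    )
  )
  mat <- assignments %>%
    filter(.data$status == "mapped") %>%
    group_by(.data$src_group) %>%
    mutate(n = dplyr::n()) %>%
    group_by(.data$src_group, .data$n, .data$dst_group) %>%
    summarise(x = dplyr::n(), .groups = "drop") %>%
    mutate(proportion = .data$x / .data$n) %>%
    arrange(.data$src_group, dplyr::desc(.data$x))
  structure(list(assignments = assignments, matrix = mat),
    class = "region_transfer"
  )
}

#' @export
print.region_transfer <- function(x, ...) {
  cat(sprintf(
    "region transfer: %d source regions (%d mapped), %d source groups\n",
    nrow(x$assignments), sum(x$assignments$status == "mapped"),
    dplyr::n_distinct(x$assignments$src_group)
  ))
  print(x$matrix, n = 20)
  invisible(x)
}

#' @export
tidy.region_transfer <- function(x, ...) x$matrix

#' Extract conserved cis-regulatory modules
#'
#' Source regions co-occupied by the full TF panel whose lifted window
#' lands in a destination region also co-occupied by the full panel --
#' the fully-retained combinatorial regions.
#'
#' @param transfer A `region_transfer` object.
#' @param src_regions Region tibble used on the source side.
#' @param panel Character vector of TF names constituting the full panel.
#' @return Subset of `src_regions` (with `dst_region_id`) that transfer
#'   panel-complete to panel-complete.
#' @export
conserved_crms <- function(transfer, src_regions, panel) {
  full <- paste(sort(panel), collapse = "+")
  keep <- transfer$assignments %>%
    filter(
      .data$src_group == full, .data$status == "mapped",
      .data$dst_group %in% full
    )
  src_regions %>%
    dplyr::inner_join(keep[, c("region_id", "dst_region_id")], by = "region_id")
}

#' Assign regions to the nearest gene TSS
#'
#' Each region is assigned to the gene whose TSS is nearest to the region
#' midpoint, within `max_distance`; ties are broken by lexicographic
#' `gene_id`.
#'
#' @param regions Region tibble.
#' @param genes Gene tibble with `tss`.
#' @param max_distance Maximum midpoint-to-TSS distance in bp.
#' @return `regions` with `gene_id` (NA when unassigned) and
#'   `gene_distance` appended.
#' @export
assign_regions_to_genes <- function(regions, genes, max_distance = 50000L) {
  mid <- (regions$start + regions$end) / 2
  gene_id <- rep(NA_character_, nrow(regions))
  gene_dist <- rep(NA_real_, nrow(regions))
  for (ch in unique(regions$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) next
    g <- g[order(g$gene_id), , drop = FALSE] # lexicographic tie-break
    ir <- which(regions$chrom == ch)
    for (k in ir) {
      d <- abs(g$tss - mid[k])
      j <- which.min(d) # first minimum = lexicographically smallest id
      if (d[j] <= max_distance) {
        gene_id[k] <- g$gene_id[j]
        gene_dist[k] <- d[j]
      }
    }
  }
  regions$gene_id <- gene_id
  regions$gene_distance <- gene_dist
  regions
}
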