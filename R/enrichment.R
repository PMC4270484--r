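# Permutation-based genomic association (GAT-style): query segments are
# re-placed uniformly at random inside a workspace, preserving their
# lengths and forbidding overlap among placed segments; the shared-base
# overlap with a reference annotation under each permutation gives the
# null for fold enrichment and an add-one permutation p-value. Chromatin
# -state overlap enrichment is the deterministic base-fraction analogue.

# map workspace intervals to a concatenated coordinate space
workspace_layout <- function(workspace) {
  ws <- interval_union(workspace)
  ws$len <- ws$end - ws$start
  ws$offset <- cumsum(c(0, head(ws$len, -1)))
  ws
}

to_concat <- function(iv, ws) {
  pieces <- purrr::map_dfr(seq_len(nrow(ws)), function(i) {
    s <- pmax(iv$start, ws$start[i])
    e <- pmin(iv$end, ws$end[i])
    keep <- iv$chrom == ws$chrom[i] & s < e
    tibble(
      start = s[keep] - ws$start[i] + ws$offset[i],
      end = e[keep] - ws$start[i] + ws$offset[i]
    )
  })
  pieces
}

#' Permutation test of overlap between interval sets
#'
#' Observed statistic: bases shared between `query` and `reference`
#' (both clipped to the workspace). Null: each query segment re-placed
#' uniformly at random wholly inside one workspace interval, lengths
#' preserved, placed segments non-overlapping. The p-value uses the
#' add-one rule `(1 + #permutations >= observed) / (1 + n_perm)`, so it
#' is never zero; the two-sided variant doubles the smaller tail.
#'
#' @param query,reference,workspace Interval tibbles; `query` must lie
#'   inside `workspace`.
#' @param n_perm Number of permutations (default 100000).
#' @param seed Integer seed for the placement RNG.
#' @param alternative `"greater"` (enrichment) or `"two.sided"`.
#' @return One-row tibble: `observed, expected, fold, p_perm, n_perm,
#'   alternative`.
#' @export
permutation_enrichment <- function(query, reference, workspace,
                                   n_perm = 100000L, seed = 1L,
                                   alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  ws <- workspace_layout(workspace)
  qc <- to_concat(query, ws)
  if (sum(qc$end - qc$start) < sum(as.numeric(query$end - query$start))) {
    abort("query must lie inside the workspace")
  }
  lens <- sort(qc$end - qc$start, decreasing = TRUE)
  k <- length(lens)
  rc <- to_concat(reference, ws)
  pf <- step_prefix(rc$start, rc$end)
  observed <- sum(pf(qc$end) - pf(qc$start))

  # valid placements per workspace interval for each segment length
  place <- function(len, n) {
    room <- pmax(ws$len - len + 1, 0)
    total <- sum(room)
    if (total <= 0) abort("workspace too small to place query segments")
    u <- floor(runif(n) * total)
    j <- findInterval(u, cumsum(c(0, room)), left.open = FALSE)
    j <- pmin(pmax(j, 1L), nrow(ws))
    off <- u - cumsum(c(0, room))[j]
    ws$offset[j] + off
  }
  set.seed(as.integer(seed))
  starts <- matrix(0, nrow = n_perm, ncol = k)
  for (j in seq_len(k)) starts[, j] <- place(lens[j], n_perm)
  if (k > 1) {
    # reject permutations with overlapping placements and redraw
    bad <- rep(TRUE, n_perm)
    tries <- 0L
    while (any(bad) && tries < 200L) {
      idx <- which(bad)
      for (i in idx) {
        o <- order(starts[i, ])
        ss <- starts[i, o]
        ee <- ss + lens[o]
        bad[i] <- any(ss[-1] < ee[-k])
      }
      redo <- which(bad)
      if (length(redo)) {
        for (j in seq_len(k)) starts[redo, j] <- place(lens[j], length(redo))
      }
      tries <- tries + 1L
    }
    if (any(bad)) abort("workspace too dense to place non-overlapping query segments")
  }
  perm_overlap <- numeric(n_perm)
  for (j in seq_len(k)) {
    perm_overlap <- perm_overlap + (pf(starts[, j] + lens[j]) - pf(starts[, j]))
  }
  expected <- mean(perm_overlap)
  p_hi <- (1 + sum(perm_overlap >= observed)) / (1 + n_perm)
  p_lo <- (1 + sum(perm_overlap <= observed)) / (1 + n_perm)
  p <- if (alternative == "greater") p_hi else min(1, 2 * min(p_hi, p_lo))
  tibble(
    observed = observed, expected = expected,
    fold = if (expected > 0) observed / expected else NA_real_,
    p_perm = p, n_perm = as.integer(n_perm), alternative = alternative
  )
}

#' Chromatin-state overlap enrichment
#'
#' Per state: (fraction of query bases in the state) / (fraction of
#' workspace bases in the state). Query bases outside the segmentation
#' are tallied to state `NA` ("unassigned") with a warning.
#'
#' @param seg Segmentation tibble (`chrom, start, end, state`).
#' @param query Interval tibble.
#' @param workspace Optional interval tibble; defaults to the
#'   segmentation's own span.
#' @return Tibble `state, query_bases, workspace_bases, query_frac,
#'   workspace_frac, fold`.
#' @export
state_overlap_enrichment <- function(seg, query, workspace = NULL) {
  if (is.null(workspace)) workspace <- seg[, c("chrom", "start", "end")]
  seg_w <- interval_intersect_keep_state(seg, workspace)
  ws_by_state <- seg_w %>%
    group_by(.data$state) %>%
    summarise(workspace_bases = sum(as.numeric(.data$end - .data$start)), .groups = "drop")
  q <- interval_union(query)
  q_total <- sum(as.numeric(q$end - q$start))
  q_by_state <- purrr::map_dfr(split(seg_w, seg_w$state), function(d) {
    tibble(state = d$state[1], query_bases = interval_overlap_bp(q, d))
  })
  res <- dplyr::full_join(ws_by_state, q_by_state, by = "state") %>%
    mutate(query_bases = dplyr::coalesce(.data$query_bases, 0))
  assigned <- sum(res$query_bases)
  if (assigned < q_total - 1e-6) {
    warn(sprintf(
      "%g query base(s) fall outside the segmentation; tallied as unassigned",
      q_total - assigned
    ))
    res <- bind_rows(res, tibble(
      state = NA_integer_, workspace_bases = 0, query_bases = q_total - assigned
    ))
  }
  ws_total <- sum(res$workspace_bases)
  res %>%
    mutate(
      query_frac = .data$query_bases / q_total,
      workspace_frac = .data$workspace_bases / ws_total,
      fold = ifelse(.data$workspace_frac > 0,
        .data$query_frac / .data$workspace_frac, NA_real_
      )
    ) %>%
    arrange(.data$state)
}

interval_intersect_keep_state <- function(seg, workspace) {
  wsu <- interval_union(workspace)
  purrr::map_dfr(seq_len(nrow(wsu)), function(i) {
    sel <- seg$chrom == wsu$chrom[i] &
      seg$start < wsu$end[i] & seg$end > wsu$start[i]
    if (!any(sel)) {
      return(NULL)
    }
    tibble(
      chrom = wsu$chrom[i],
      start = pmax(seg$start[sel], wsu$start[i]),
      end = pmin(seg$end[sel], wsu$end[i]),
      state = seg$state[sel]
    )
  })
}

#' Occupancy odds ratio for a special gene set
#'
#' 2x2 comparison of peak-proximity frequency between a special gene set
#' (e.g. the top 10% species-specific genes) and the remaining genes:
#' `OR = [a/(n1-a)] / [b/(n2-b)]`, reported as `log2(OR)` with the
#' Haldane-Anscombe 0.5 correction when any cell is zero, plus Fisher's
#' exact p-value.
#'
#' @param genes_special,genes_rest Disjoint character vectors of gene
#'   ids.
#' @param occupied_genes Character vector of gene ids flagged as near a
#'   peak of the category under test.
#' @return One-row tibble: `a, n1, b, n2, odds_ratio, log2_or, p_fisher`.
#' @export
gene_odds_ratio <- function(genes_special, genes_rest, occupied_genes) {
  if (!length(genes_special) || !length(genes_rest)) {
    abort("both gene sets must be non-empty")
  }
  if (length(intersect(genes_special, genes_rest))) {
    abort("gene sets must be disjoint")
  }
  a <- sum(genes_special %in% occupied_genes)
  b <- sum(genes_rest %in% occupied_genes)
  n1 <- length(genes_special)
  n2 <- length(genes_rest)
  cells <- c(a, n1 - a, b, n2 - b)
  cc <- if (any(cells == 0)) 0.5 else 0
  or <- ((a + cc) / (n1 - a + cc)) / ((b + cc) / (n2 - b + cc))
  p <- fisher.test(matrix(c(a, n1 - a, b, n2 - b), nrow = 2))$p.value
  tibble(
    a = a, n1 = n1, b = b, n2 = n2,
    odds_ratio = or, log2_or = log2(or), p_fisher = p
  )
}

#' Flag genes near peaks
#'
#' A gene is "occupied" when any peak interval overlaps its body expanded
#' by `window` on each side.
#'
#' @param genes Gene tibble.
#' @param peaks Peak tibble.
#' @param window Expansion in bp (default 10 kb).
#' @return Character vector of occupied gene ids.
#' @export
genes_near_peaks <- function(genes, peaks, window = 10000L) {
  g <- tibble(
    chrom = genes$chrom,
    start = pmax(0L, genes$start - as.integer(window)),
    end = genes$end + as.integer(window)
  )
  genes$gene_id[interval_overlaps_any(g, peaks)]
}

#' Two-sided Mann-Whitney rank-sum comparison
#'
#' Wrapper over the standard rank-sum test: exact for small samples
#' without ties, normal approximation with tie correction otherwise.
#'
#' @param x,y Numeric vectors of enrichment values.
#' @return One-row tibble `statistic` (U for `x`), `p_value`.
#' @export
rank_sum_compare <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value)
}
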