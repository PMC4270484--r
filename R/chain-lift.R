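# Chain-based interval mapping (liftOver semantics). An interval on the
# target genome is mapped through the gap-separated alignment blocks of
# the best-overlapping chain; the mapped interval is the bounding span of
# the images of its first and last aligned bases, on forward-strand query
# coordinates. Mapping fails when too few bases are aligned
# (unmapped_low_match), when a second chain also covers at least
# `min_match` of the interval (unmapped_split; the "one:one matching"
# rule) or when no chain touches the chromosome (unmapped_no_chain).

# aligned target sub-intervals of [s, e) within one chain's blocks,
# together with query images; returns list(t0, t1, q_img0, q_img1, bases)
chain_block_overlap <- function(blocks, s, e) {
  bs <- blocks$t_start
  be <- blocks$t_start + blocks$size
  lo <- pmax(bs, s)
  hi <- pmin(be, e)
  keep <- lo < hi
  list(
    t_lo = lo[keep], t_hi = hi[keep],
    q_lo = blocks$q_start[keep] + (lo[keep] - bs[keep]),
    q_hi = blocks$q_start[keep] + (hi[keep] - bs[keep]),
    bases = sum(hi[keep] - lo[keep])
  )
}

# convert query-frame coordinates (UCSC reverse-complement frame for '-'
# chains) of half-open [lo, hi) pieces into forward-strand coordinates
q_forward <- function(lo, hi, q_strand, q_size) {
  if (q_strand == "-") {
    tibble(start = q_size - hi, end = q_size - lo)
  } else {
    tibble(start = lo, end = hi)
  }
}

#' Map one interval across a chain alignment
#'
#' Reimplements liftOver-style mapping: the chain with the most aligned
#' bases overlapping the interval is selected (ties: higher score, then
#' lower id); the interval maps iff at least `min_match` of its bases lie
#' in aligned blocks and, when `require_unique`, no second chain also
#' covers `min_match` of it.
#'
#' @param iv One-row tibble (or list) with `chrom`, `start`, `end`.
#' @param chains Chain tibble from [read_chain()].
#' @param min_match Minimum fraction of interval bases that must be
#'   aligned (default 0.10, the study's liftOver setting).
#' @param require_unique Reject intervals covered by two chains.
#' @return One-row tibble: `status` (`mapped`, `unmapped_low_match`,
#'   `unmapped_split`, `unmapped_no_chain`), `chrom`, `start`, `end`
#'   (mapped span, forward-strand query coordinates; NA if unmapped) and
#'   `match_fraction`.
#' @export
lift_interval <- function(iv, chains, min_match = 0.10, require_unique = TRUE) {
  stopifnot(min_match > 0, min_match <= 1)
  s <- as.integer(iv$start)
  e <- as.integer(iv$end)
  width <- e - s
  cand <- which(chains$t_name == iv$chrom &
    chains$t_start < e & chains$t_end > s)
  unmapped <- function(status, frac = 0) {
    tibble(
      status = status, chrom = NA_character_,
      start = NA_integer_, end = NA_integer_, match_fraction = frac
    )
  }
  if (!any(chains$t_name == iv$chrom)) {
    return(unmapped("unmapped_no_chain"))
  }
  if (!length(cand)) {
    return(unmapped("unmapped_low_match"))
  }
  ovl <- lapply(cand, function(i) chain_block_overlap(chains$blocks[[i]], s, e))
  bases <- purrr::map_dbl(ovl, "bases")
  ord <- order(-bases, -chains$score[cand], chains$id[cand])
  best <- ord[1]
  frac <- bases[best] / width
  if (frac < min_match) {
    return(unmapped("unmapped_low_match", frac))
  }
  if (require_unique && length(ord) > 1 && bases[ord[2]] / width >= min_match) {
    return(unmapped("unmapped_split", frac))
  }
  i <- cand[best]
  o <- ovl[[best]]
  fw <- q_forward(min(o$q_lo), max(o$q_hi), chains$q_strand[i], chains$q_size[i])
  tibble(
    status = "mapped", chrom = chains$q_name[i],
    start = as.integer(fw$start), end = as.integer(fw$end),
    match_fraction = frac
  )
}

#' Map many intervals across a chain alignment
#'
#' Vectorized driver over [lift_interval()]; input rows are preserved in
#' order and the lift columns are appended with a `lifted_` prefix.
#'
#' @param iv Interval tibble.
#' @inheritParams lift_interval
#' @return `iv` with `status`, `lifted_chrom`, `lifted_start`,
#'   `lifted_end`, `match_fraction` appended.
#' @export
lift_intervals <- function(iv, chains, min_match = 0.10, require_unique = TRUE) {
  validate_intervals(iv)
  res <- purrr::map_dfr(seq_len(nrow(iv)), function(k) {
    lift_interval(iv[k, ], chains, min_match, require_unique)
  })
  dplyr::bind_cols(
    iv,
    tibble(
      status = res$status, lifted_chrom = res$chrom,
      lifted_start = res$start, lifted_end = res$end,
      match_fraction = res$match_fraction
    )
  )
}

#' Map a peak's summit window across species
#'
#' Lifts the narrow window `[summit - flank, summit + flank + 1)` (the
#' summit +/- 50 bp convention by default), clipped at position 0 and, if
#' `chrom_size` is given, at the chromosome end.
#'
#' @param peak One-row peak tibble with `chrom` and `summit`.
#' @param chains Chain tibble.
#' @param flank Half-width of the summit window in bp.
#' @param min_match Minimum aligned fraction of the window.
#' @param chrom_size Optional chromosome length for right clipping.
#' @return One-row lift-result tibble (see [lift_interval()]).
#' @export
lift_summit_window <- function(peak, chains, flank = 50L, min_match = 0.10,
                               chrom_size = NULL) {
  stopifnot(flank >= 0)
  w <- summit_window(peak$summit, flank, chrom_size)
  lift_interval(
    tibble(chrom = peak$chrom, start = w$start, end = w$end),
    chains,
    min_match = min_match
  )
}

summit_window <- function(summit, flank = 50L, chrom_size = NULL) {
  start <- pmax(0L, as.integer(summit) - as.integer(flank))
  end <- as.integer(summit) + as.integer(flank) + 1L
  if (!is.null(chrom_size)) end <- pmin(end, as.integer(chrom_size))
  list(start = start, end = end)
}

# swap target and query sides of every chain (for round-trip mapping)
swap_chain <- function(chains) {
  stopifnot(all(chains$q_strand == "+")) # reverse-frame swap not needed here
  chains %>%
    mutate(blocks = purrr::map(.data$blocks, function(b) {
      tibble(
        size = b$size, dt = b$dq, dq = b$dt,
        t_start = b$q_start, q_start = b$t_start
      )
    })) %>%
    rename(
      t_name = "q_name", t_size = "q_size", t_strand = "q_strand",
      t_start = "q_start", t_end = "q_end",
      q_name = "t_name", q_size = "t_size", q_strand = "t_strand",
      q_start = "t_start", q_end = "t_end"
    )
}
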